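#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Banded unit-cost edit distance with early exit.
// Returns min(d(a,b), cap + 1); any value > cap means "further than cap".
static int lev_bounded_impl(const char* a, int la, const char* b, int lb, int cap) {
  if (cap < 0) cap = 0;
  int diff = la - lb; if (diff < 0) diff = -diff;
  if (diff > cap) return cap + 1;
  if (la == 0 || lb == 0) return std::max(la, lb) <= cap ? std::max(la, lb) : cap + 1;
  const int INF = cap + 1;
  std::vector<int> prev(lb + 1, INF), cur(lb + 1, INF);
  for (int j = 0; j <= std::min(lb, cap); ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    int jlo = std::max(1, i - cap), jhi = std::min(lb, i + cap);
    int rowmin = INF;
    cur[jlo - 1] = (i - (jlo - 1) <= cap && jlo - 1 == 0) ? i : INF;
    if (jlo - 1 == 0 && i <= cap) rowmin = i;
    for (int j = jlo; j <= jhi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = (j <= i + cap - 1) ? prev[j] + 1 : INF;
      int ins = cur[j - 1] + 1;
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      if (v > INF) v = INF;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (jhi < lb) cur[jhi] = std::min(cur[jhi], INF); // outside band stays INF
    if (rowmin > cap) return INF;
    std::swap(prev, cur);
    std::fill(cur.begin(), cur.end(), INF);
  }
  return prev[lb] <= cap ? prev[lb] : INF;
}

//' @noRd
// [[Rcpp::export(name = ".lev_bounded")]]
IntegerVector lev_bounded_cpp(CharacterVector a, CharacterVector b, int cap) {
  R_xlen_t n = std::max(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* sa = CHAR(STRING_ELT(a, i % a.size()));
    const char* sb = CHAR(STRING_ELT(b, i % b.size()));
    out[i] = lev_bounded_impl(sa, (int)std::strlen(sa), sb, (int)std::strlen(sb), cap);
  }
  return out;
}

// All pairs (i < j) with edit distance <= max_dist. O(n^2) with cheap
// admissible prefilters (length difference; base-composition L1 bound:
// every edit changes the A/C/G/T counts by at most 2 in L1) ahead of the
// banded early-exit DP; intended for desk scale (<= ~2e4 sequences).
// [[Rcpp::export(name = ".lev_neighbor_pairs")]]
DataFrame lev_neighbor_pairs_cpp(CharacterVector seqs, int max_dist) {
  int n = seqs.size();
  std::vector<const char*> ptr(n);
  std::vector<int> len(n);
  std::vector<std::array<int, 4>> comp(n);
  for (int i = 0; i < n; ++i) {
    ptr[i] = CHAR(STRING_ELT(seqs, i));
    len[i] = (int)std::strlen(ptr[i]);
    std::array<int, 4> c = {0, 0, 0, 0};
    for (int k = 0; k < len[i]; ++k) {
      switch (ptr[i][k]) {
        case 'A': ++c[0]; break; case 'C': ++c[1]; break;
        case 'G': ++c[2]; break; case 'T': ++c[3]; break;
      }
    }
    comp[i] = c;
  }
  const int l1cap = 2 * max_dist;
  std::vector<int> ii, jj, dd;
  for (int i = 0; i < n; ++i) {
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
    for (int j = i + 1; j < n; ++j) {
      int diff = len[i] - len[j]; if (diff < 0) diff = -diff;
      if (diff > max_dist) continue;
      int l1 = 0;
      for (int b = 0; b < 4; ++b) {
        int db = comp[i][b] - comp[j][b];
        l1 += db < 0 ? -db : db;
      }
      if (l1 > l1cap) continue;
      int d = lev_bounded_impl(ptr[i], len[i], ptr[j], len[j], max_dist);
      if (d <= max_dist) { ii.push_back(i + 1); jj.push_back(j + 1); dd.push_back(d); }
    }
  }
  return DataFrame::create(_["i"] = ii, _["j"] = jj, _["d"] = dd);
}

// Leftmost occurrence of `pattern` in each read allowing <= max_mm
// substitutions, scanning from 1-based position `from`. Returns 1-based
// position or NA.
// [[Rcpp::export(name = ".hamming_search")]]
IntegerVector hamming_search_cpp(CharacterVector reads, std::string pattern,
                                 int max_mm, IntegerVector from) {
  int n = reads.size(), pl = (int)pattern.size();
  IntegerVector out(n, NA_INTEGER);
  for (int r = 0; r < n; ++r) {
    if (STRING_ELT(reads, r) == NA_STRING) continue;
    const char* s = CHAR(STRING_ELT(reads, r));
    int ls = (int)std::strlen(s);
    int f0 = from[r % from.size()];
    if (f0 == NA_INTEGER || f0 < 1) f0 = 1;
    for (int pos = f0 - 1; pos + pl <= ls; ++pos) {
      int mm = 0;
      for (int k = 0; k < pl; ++k) {
        if (s[pos + k] != pattern[k] && ++mm > max_mm) break;
      }
      if (mm <= max_mm) { out[r] = pos + 1; break; }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (STRING_ELT(seqs, i) == NA_STRING) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
        default: c = 'N';
      }
    }
    out[i] = r;
  }
  return out;
}

// Minimum phred score (offset 33) over quals[start..end] (1-based, inclusive).
// [[Rcpp::export(name = ".min_phred_in")]]
IntegerVector min_phred_in_cpp(CharacterVector quals, IntegerVector start, IntegerVector end) {
  int n = quals.size();
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (STRING_ELT(quals, i) == NA_STRING) continue;
    int s = start[i % start.size()], e = end[i % end.size()];
    if (s == NA_INTEGER || e == NA_INTEGER) continue;
    const char* q = CHAR(STRING_ELT(quals, i));
    int lq = (int)std::strlen(q);
    if (s < 1 || e > lq || s > e) continue;
    int m = 10000;
    for (int k = s - 1; k < e; ++k) { int v = (int)q[k] - 33; if (v < m) m = v; }
    out[i] = m;
  }
  return out;
}

// Semiglobal (glocal) affine-gap alignment of `frag` against `window`:
// the fragment is aligned end to end, the window has free leading and
// trailing overhangs. Gap of length g costs gap_open + g * gap_ext
// (penalties passed as negative numbers). Returns c(score, start0, end0):
// 0-based half-open window coordinates of the aligned region.
// [[Rcpp::export(name = ".semiglobal_align")]]
IntegerVector semiglobal_align_cpp(std::string frag, std::string window,
                                   int match, int mismatch, int gap_open, int gap_ext) {
  int n = (int)frag.size(), w = (int)window.size();
  const int NEG = -1000000;
  // Gotoh with rolling rows; track alignment start column per cell.
  std::vector<int> Hp(w + 1), Hc(w + 1), Xp(w + 1), Xc(w + 1), Yp(w + 1), Yc(w + 1);
  std::vector<int> sHp(w + 1), sHc(w + 1), sXp(w + 1), sXc(w + 1), sYp(w + 1), sYc(w + 1);
  for (int j = 0; j <= w; ++j) { Hp[j] = 0; sHp[j] = j; Xp[j] = NEG; sXp[j] = j; Yp[j] = NEG; sYp[j] = j; }
  for (int i = 1; i <= n; ++i) {
    Hc[0] = NEG; Xc[0] = NEG;
    Yc[0] = std::max(Hp[0] + gap_open + gap_ext, Yp[0] + gap_ext);
    sYc[0] = (Hp[0] + gap_open + gap_ext >= Yp[0] + gap_ext) ? sHp[0] : sYp[0];
    sHc[0] = 0; sXc[0] = 0;
    for (int j = 1; j <= w; ++j) {
      int s = (frag[i - 1] == window[j - 1]) ? match : mismatch;
      // H: diagonal step from best of H/X/Y at (i-1, j-1)
      int best = Hp[j - 1], sb = sHp[j - 1];
      if (Xp[j - 1] > best) { best = Xp[j - 1]; sb = sXp[j - 1]; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; sb = sYp[j - 1]; }
      Hc[j] = best + s; sHc[j] = sb;
      // X: gap in fragment (consume window base j)
      int xo = Hc[j - 1] + gap_open + gap_ext, xe = Xc[j - 1] + gap_ext;
      if (xo >= xe) { Xc[j] = xo; sXc[j] = sHc[j - 1]; } else { Xc[j] = xe; sXc[j] = sXc[j - 1]; }
      // Y: gap in window (consume fragment base i)
      int yo = Hp[j] + gap_open + gap_ext, ye = Yp[j] + gap_ext;
      if (yo >= ye) { Yc[j] = yo; sYc[j] = sHp[j]; } else { Yc[j] = ye; sYc[j] = sYp[j]; }
    }
    std::swap(Hp, Hc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    std::swap(sHp, sHc); std::swap(sXp, sXc); std::swap(sYp, sYc);
  }
  int best = NEG, endj = 0, startj = 0;
  for (int j = 0; j <= w; ++j) {
    int v = std::max(Hp[j], Yp[j]); // trailing window overhang is free
    if (v > best) {
      best = v; endj = j;
      startj = (Hp[j] >= Yp[j]) ? sHp[j] : sYp[j];
    }
  }
  return IntegerVector::create(best, startj, endj);
}
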
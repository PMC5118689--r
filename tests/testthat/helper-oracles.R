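# Independent oracles and small generators shared across the suite.
# These deliberately use naive R loops / base utilities (utils::adist) so
# they stay independent of the package's own code paths.

random_dna <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

# Brute-force purity per barcode: plain loops, no data.table. Tie-break
# mirrors the documented rule (highest count, then smallest start, end,
# strand) so exact equality with the implementation is meaningful.
brute_purity <- function(pairs, tol_bp = 20) {
  pairs$barcode <- toupper(pairs$barcode)
  out <- numeric(0)
  for (bc in unique(pairs$barcode)) {
    g <- pairs[pairs$barcode == bc, , drop = FALSE]
    if (nrow(g) < 2) next
    key <- paste(g$start, g$end, g$strand)
    tab <- table(key)
    mx <- names(tab)[tab == max(tab)]
    parts <- do.call(rbind, strsplit(mx, " ", fixed = TRUE))
    ord <- order(as.integer(parts[, 1]), as.integer(parts[, 2]), parts[, 3])
    ts <- as.integer(parts[ord[1], 1])
    te <- as.integer(parts[ord[1], 2])
    td <- parts[ord[1], 3]
    inc <- abs(g$start - ts) <= tol_bp & abs(g$end - te) <= tol_bp & g$strand == td
    out[bc] <- sum(inc) / nrow(g)
  }
  out
}

# One-substitution / one-indel neighbours used to build error halos.
perturb_seq <- function(s, n_edits = 1) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  for (e in seq_len(n_edits)) {
    op <- sample(c("sub", "ins", "del"), 1, prob = c(0.8, 0.1, 0.1))
    pos <- sample.int(length(v), 1)
    if (op == "sub") v[pos] <- sample(setdiff(bases, v[pos]), 1)
    else if (op == "ins") v <- append(v, sample(bases, 1), after = pos)
    else if (length(v) > 2) v <- v[-pos]
  }
  paste(v, collapse = "")
}

# Barcode-count input resembling a sequenced library: a few true barcodes
# with error halos of much lower count.
halo_counts <- function(n_true = 5, pattern = "(VHDB)x3") {
  spec <- barcode_spec(pattern, min_len = nchar(expand_pattern_test(pattern)) - 2,
                       max_len = nchar(expand_pattern_test(pattern)) + 2)
  true <- generate_barcodes(n_true, spec)
  seqs <- true
  cnts <- sample(10:50, n_true, replace = TRUE)
  for (b in true) {
    for (h in seq_len(sample(0:3, 1))) {
      seqs <- c(seqs, perturb_seq(b, sample(1:2, 1)))
      cnts <- c(cnts, sample(1:3, 1))
    }
  }
  keep <- !duplicated(seqs)
  data.frame(sequence = seqs[keep], count = cnts[keep], stringsAsFactors = FALSE)
}

expand_pattern_test <- function(p) {
  m <- regmatches(p, regexec("^\\(([A-Za-z]+)\\)x([0-9]+)$", p))[[1]]
  if (length(m) == 3) strrep(m[2], as.integer(m[3])) else p
}

# Small end-to-end simulation bundle reused across tests.
make_sim <- function(n_clones = 100, ref_len = 600, chimera_rate = 0,
                     sub_rate = 0, ins_rate = 0, del_rate = 0,
                     mean_depth = 10, singlet_inflation = 0, seed = 1,
                     n_frag_reps = 20) {
  set.seed(seed)
  ref <- random_dna(ref_len)
  pool <- do.call(rbind, lapply(seq_len(n_frag_reps), function(i)
    fragment_template(ref, fragmentation_config())))
  truth <- build_library(pool, n_clones, barcode_spec())
  cfg <- read_sim_config(mean_depth = mean_depth,
                         singlet_inflation = singlet_inflation,
                         sub_rate = sub_rate, ins_rate = ins_rate,
                         del_rate = del_rate, chimera_rate = chimera_rate,
                         seed = seed + 1000L)
  sim <- simulate_reads(truth, ref, cfg)
  list(ref = ref, pool = pool, truth = truth, sim = sim, cfg = cfg)
}
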
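# Seed-and-extend local alignment against a short reference with a
# uniqueness filter: only fragments with a single best-scoring location (on
# either strand) yield a range; ties and sub-threshold scores are reported
# as unmapped. Coordinates are 0-based half-open throughout.

#' Build a k-mer index over a reference sequence
#'
#' @param reference DNA string, or path to a FASTA file (first record used),
#'   or a \code{Biostrings::DNAStringSet}.
#' @param k seed length (default 15).
#' @param id reference identifier carried into output ranges.
#' @return object of class \code{reference_index}.
#' @export
reference_index <- function(reference, k = 15L, id = NULL) {
  if (inherits(reference, "DNAStringSet")) {
    if (is.null(id)) id <- sub("\\s.*$", "", names(reference)[1])
    reference <- as.character(reference[[1]])
  } else if (length(reference) == 1 && file.exists(reference) &&
             grepl("\\.(fa|fasta|fna)(\\.gz)?$", reference, ignore.case = TRUE)) {
    ss <- Biostrings::readDNAStringSet(reference)
    if (is.null(id)) id <- sub("\\s.*$", "", names(ss)[1])
    reference <- as.character(ss[[1]])
  }
  if (is.null(id)) id <- "ref"
  reference <- toupper(reference)
  L <- nchar(reference)
  k <- as.integer(k)
  if (L < k) stop("reference shorter than the seed length k")
  kmers <- substring(reference, 1:(L - k + 1L), k:L)
  index <- split(seq_len(L - k + 1L), kmers)
  env <- list2env(index, hash = TRUE, size = length(index))
  structure(list(sequence = reference, length = L, k = k, id = id, env = env),
            class = "reference_index")
}

# Candidate fragment-start positions (1-based) on the indexed strand.
seed_candidates <- function(s, idx) {
  n <- nchar(s); k <- idx$k
  if (n < k) return(integer(0))
  offs <- unique(c(seq(1L, n - k + 1L, by = k), n - k + 1L))
  cand <- integer(0)
  for (o in offs) {
    hits <- idx$env[[substr(s, o, o + k - 1L)]]
    if (!is.null(hits)) cand <- c(cand, hits - o + 1L)
  }
  sort(unique(cand))
}

# Collapse candidate diagonals closer than `band` into one evaluation window.
cluster_candidates <- function(cand, band) {
  if (length(cand) == 0) return(list())
  grp <- cumsum(c(1L, diff(cand) > band))
  split(cand, grp)
}

align_one <- function(frag, idx, band, min_score, params) {
  best <- NULL; tie <- FALSE
  n <- nchar(frag)
  for (str in c("+", "-")) {
    s <- if (str == "+") frag else revcomp(frag)
    for (cl in cluster_candidates(seed_candidates(s, idx), band)) {
      c0 <- cl[1]
      # fast path: exact substring at a candidate diagonal
      hitdf <- NULL
      for (cpos in cl) {
        if (cpos >= 1 && cpos + n - 1L <= idx$length &&
            substr(idx$sequence, cpos, cpos + n - 1L) == s) {
          hitdf <- c(score = n, start = cpos - 1L, end = cpos - 1L + n)
          break
        }
      }
      if (is.null(hitdf)) {
        w0 <- max(1L, c0 - band)
        w1 <- min(idx$length, cl[length(cl)] + n - 1L + band)
        r <- .semiglobal_align(s, substr(idx$sequence, w0, w1),
                               params$match, params$mismatch,
                               params$gap_open, params$gap_ext)
        hitdf <- c(score = r[1], start = w0 - 1L + r[2], end = w0 - 1L + r[3])
      }
      if (hitdf["score"] < min_score) next
      if (is.null(best) || hitdf["score"] > best$score) {
        best <- list(score = hitdf[["score"]], start = hitdf[["start"]],
                     end = hitdf[["end"]], strand = str)
        tie <- FALSE
      } else if (hitdf["score"] == best$score &&
                 (hitdf["start"] != best$start || str != best$strand)) {
        tie <- TRUE
      }
    }
  }
  if (is.null(best)) return(list(reason = "no_alignment"))
  if (tie) return(list(reason = "non_unique"))
  c(best, list(reason = "none"))
}

#' Align fragments to an indexed reference
#'
#' Seed-and-extend on both strands with affine-gap extension (match +1,
#' mismatch -1, gap open -2, gap extend -1). A fragment maps iff its best
#' local alignment clears the score floor implied by
#' \code{max_mismatch_rate} and no second location or strand ties that best
#' score (the unique-valid-alignment filter).
#'
#' @param fragments character vector of fragment sequences (NA allowed).
#' @param index a [reference_index()].
#' @param max_mismatch_rate tolerated error rate; converted to the score
#'   floor \code{ceiling(len * (1 - 3 * rate))}.
#' @param min_len fragments shorter than this are reported unmapped.
#' @param band window padding (and candidate-merging slack) in nt.
#' @param read_id optional identifiers carried through.
#' @return \code{data.frame}: read_id, start, end (0-based half-open),
#'   strand, score, mapped, reason.
#' @export
align_fragments <- function(fragments, index, max_mismatch_rate = 0.1,
                            min_len = 20L, band = 8L, read_id = NULL) {
  params <- list(match = 1L, mismatch = -1L, gap_open = -2L, gap_ext = -1L)
  nfr <- length(fragments)
  if (is.null(read_id)) read_id <- sprintf("frag_%07d", seq_len(nfr))
  out <- data.frame(read_id = read_id,
                    start = rep(NA_integer_, nfr), end = NA_integer_,
                    strand = NA_character_, score = NA_integer_,
                    mapped = FALSE, reason = "no_alignment",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nfr)) {
    f <- fragments[i]
    if (is.na(f) || nchar(f) == 0) { out$reason[i] <- "missing"; next }
    if (nchar(f) < min_len) { out$reason[i] <- "too_short"; next }
    min_score <- ceiling(nchar(f) * (1 - 3 * max_mismatch_rate))
    r <- align_one(toupper(f), index, band, min_score, params)
    out$reason[i] <- r$reason
    if (r$reason == "none") {
      out$start[i] <- r$start; out$end[i] <- r$end
      out$strand[i] <- r$strand; out$score[i] <- r$score
      out$mapped[i] <- TRUE
    }
  }
  attr(out, "ref_id") <- index$id
  out
}

#' Join aligned ranges with extracted barcodes
#'
#' Keyed join on read_id keeping pairs where both the barcode extraction and
#' the alignment succeeded; unmatched or failed reads are dropped with their
#' counts reported in the \code{dropped} attribute.
#'
#' @param alignments output of [align_fragments()] (with read_id).
#' @param extraction output of [extract_barcodes()].
#' @return \code{data.frame}: read_id, barcode, ref_id, start, end, strand.
#' @export
attach_barcode <- function(alignments, extraction) {
  if (anyDuplicated(alignments$read_id)) stop("duplicate read_id among alignments")
  if (anyDuplicated(extraction$read_id)) stop("duplicate read_id among extractions")
  ok_bc <- extraction[extraction$fail_reason == "none", c("read_id", "barcode")]
  ok_al <- alignments[alignments$mapped, c("read_id", "start", "end", "strand")]
  merged <- merge(ok_bc, ok_al, by = "read_id")
  dropped <- c(barcode_failed = nrow(extraction) - nrow(ok_bc),
               unmapped = nrow(alignments) - nrow(ok_al),
               unpaired = (nrow(ok_bc) - nrow(merged)) + (nrow(ok_al) - nrow(merged)))
  if (nrow(merged) == 0) warning("no joinable read pairs")
  out <- data.frame(read_id = merged$read_id, barcode = merged$barcode,
                    ref_id = rep(attr(alignments, "ref_id") %||% "ref", nrow(merged)),
                    start = merged$start, end = merged$end,
                    strand = merged$strand, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
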
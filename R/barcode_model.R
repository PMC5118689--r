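# Degenerate barcode design: IUPAC pattern, generation, validation and
# design-level analytics (diversity, homopolymer bound, length filter).

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

expand_pattern <- function(pattern) {
  # "(VHDB)x5" shorthand -> "VHDBVHDB..."
  m <- regmatches(pattern, regexec("^\\(([A-Za-z]+)\\)x([0-9]+)$", pattern))[[1]]
  if (length(m) == 3) pattern <- strrep(m[2], as.integer(m[3]))
  toupper(pattern)
}

#' Degenerate barcode specification
#'
#' Describes the barcode design used during library construction: an IUPAC
#' ambiguity pattern (one code per synthesis position) plus the length window
#' accepted downstream. The default is the base-cycling design
#' \code{(VHDB)x5}: V = not T, H = not G, D = not C, B = not A, repeated five
#' times, so no base can ever form a homopolymer longer than three, with a
#' length filter of 18-22 nt to absorb synthesis truncations.
#'
#' @param pattern IUPAC pattern string; the shorthand \code{"(VHDB)x5"} is
#'   expanded to five repeats.
#' @param min_len,max_len accepted barcode length bounds (nt).
#' @return An object of class \code{barcode_spec}.
#' @export
#' @examples
#' spec <- barcode_spec()
#' design_diversity(spec)   # 3^20
barcode_spec <- function(pattern = "(VHDB)x5", min_len = 18L, max_len = 22L) {
  pattern <- expand_pattern(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_DNA))
  if (length(bad) > 0)
    stop("unknown IUPAC ambiguity code(s) in pattern: ", paste(unique(bad), collapse = ", "))
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  if (!(min_len <= nchar(pattern) && nchar(pattern) <= max_len))
    stop("pattern length must lie within [min_len, max_len]")
  structure(
    list(pattern = pattern, alphabets = IUPAC_DNA[chars],
         min_len = min_len, max_len = max_len),
    class = "barcode_spec"
  )
}

#' @export
print.barcode_spec <- function(x, ...) {
  cat("barcode_spec:", x$pattern,
      sprintf("(%d nt, accepted length %d-%d, diversity %s)\n",
              nchar(x$pattern), x$min_len, x$max_len,
              format(design_diversity(x), big.mark = ",")))
  invisible(x)
}

#' Generate degenerate barcodes
#'
#' Draws barcodes from the design, one base per position, uniformly over each
#' position's allowed alphabet (or with optional per-base weights to emulate
#' synthesis skew). With \code{unique = TRUE} duplicates are replaced by
#' rejection sampling, reflecting a single-cycle extension in which each
#' unique barcode is used only once.
#'
#' @param n number of barcodes.
#' @param spec a [barcode_spec()].
#' @param weights optional named numeric vector (names in A/C/G/T) of relative
#'   base weights applied within each position's allowed alphabet.
#' @param unique enforce distinct sequences by rejection sampling.
#' @param seed optional integer seed.
#' @return character vector of length \code{n}.
#' @export
generate_barcodes <- function(n, spec = barcode_spec(), weights = NULL,
                              unique = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  if (unique && n > design_diversity(spec))
    stop("barcode space exhausted: n exceeds the design diversity")
  draw <- function(m) {
    cols <- lapply(spec$alphabets, function(ab) {
      p <- if (is.null(weights)) NULL else {
        w <- weights[ab]; w[is.na(w)] <- 0
        if (sum(w) <= 0) NULL else w / sum(w)
      }
      sample(ab, m, replace = TRUE, prob = p)
    })
    do.call(paste0, cols)
  }
  out <- draw(n)
  if (unique) {
    reps <- 0L
    while (anyDuplicated(out)) {
      idx <- which(duplicated(out))
      out[idx] <- draw(length(idx))
      reps <- reps + 1L
      if (reps > 1000L) stop("rejection sampling failed to reach uniqueness")
    }
  }
  out
}

#' Validate barcodes against the design
#'
#' TRUE iff the sequence has the pattern's length and each base belongs to its
#' position's allowed alphabet. N or any off-alphabet base fails.
#'
#' @param seq character vector of DNA sequences.
#' @param spec a [barcode_spec()].
#' @return logical vector.
#' @export
validate_barcode <- function(seq, spec = barcode_spec()) {
  L <- nchar(spec$pattern)
  ok <- !is.na(seq) & nchar(seq) == L
  if (!any(ok)) return(ok)
  sub <- toupper(seq[ok])
  conform <- rep(TRUE, length(sub))
  for (i in seq_len(L)) {
    conform <- conform & substr(sub, i, i) %in% spec$alphabets[[i]]
  }
  ok[ok] <- conform
  ok
}

#' Barcode length filter
#'
#' The downstream acceptance window for observed barcode lengths
#' (default 18-22 nt for the 20-nt design).
#'
#' @inheritParams validate_barcode
#' @return logical vector.
#' @export
passes_length_filter <- function(seq, spec = barcode_spec()) {
  l <- nchar(seq)
  !is.na(l) & l >= spec$min_len & l <= spec$max_len
}

#' Design diversity
#'
#' Number of distinct sequences the pattern can realize: the product over
#' positions of the allowed-alphabet sizes. For \code{(VHDB)x5} this is
#' \eqn{3^{20} \approx 3.5} billion. Returned as a double (exactly
#' representable far beyond this range).
#'
#' @param spec a [barcode_spec()].
#' @return numeric scalar.
#' @export
design_diversity <- function(spec = barcode_spec()) {
  prod(vapply(spec$alphabets, length, 1L))
}

#' Maximum realizable homopolymer run
#'
#' Longest same-base run any sequence conforming to the pattern can contain,
#' found by exact search: for each base, the longest stretch of consecutive
#' positions whose alphabet admits that base. The \code{(VHDB)x5} cycling
#' design bounds this at 3.
#'
#' @param spec a [barcode_spec()].
#' @return integer scalar.
#' @export
max_homopolymer_run <- function(spec = barcode_spec()) {
  best <- 0L
  for (b in c("A", "C", "G", "T")) {
    allowed <- vapply(spec$alphabets, function(ab) b %in% ab, logical(1))
    r <- rle(allowed)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
  }
  as.integer(best)
}

#' Per-position base composition of unique barcodes
#'
#' Sequence-logo style frequency table: each unique barcode counted once
#' (read counts deliberately ignored, so amplification bias does not weight
#' the logo). Sequences not of the modal length are dropped with a message.
#'
#' @param barcodes character vector of barcode sequences (possibly repeated).
#' @return numeric matrix, rows A/C/G/T, one column per position; columns sum
#'   to 1.
#' @export
base_composition_logo <- function(barcodes) {
  if (length(barcodes) == 0) stop("no barcodes supplied")
  u <- unique(toupper(barcodes))
  lens <- nchar(u)
  L <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  if (any(lens != L)) {
    message(sum(lens != L), " barcode(s) not of modal length ", L, " dropped from logo")
    u <- u[lens == L]
  }
  mat <- matrix(0, nrow = 4, ncol = L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_len(L)) {
    tab <- table(factor(substr(u, i, i), levels = rownames(mat)))
    mat[, i] <- as.numeric(tab) / length(u)
  }
  mat
}
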
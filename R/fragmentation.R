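# dUTP/UDG fragmentation model: uracil is incorporated opposite of a T
# position with a probability set by the dUTP fraction in the reaction, every
# incorporated uracil is excised by UDG and the backbone broken by NaOH.
# Single-strand abstraction: cuts happen at T positions of the given strand,
# the cleaved base is excised (abasic site lost), and maximal uncut intervals
# become fragments.

#' Fragmentation reaction configuration
#'
#' @param dutp_fraction fraction of dUTP among dUTP+dTTP in the PCR, in
#'   \[0, 1\]. 0.10 is the fraction used for the libraries this model emulates.
#' @param incorporation_ratio efficiency of dUTP incorporation relative to
#'   dTTP (proof-reading polymerases incorporate U less readily); default 1.
#' @param min_fragment_len fragments shorter than this are discarded,
#'   mirroring the 50 bp AMPure size cut.
#' @return object of class \code{fragmentation_config}.
#' @export
fragmentation_config <- function(dutp_fraction = 0.10, incorporation_ratio = 1,
                                 min_fragment_len = 50L) {
  if (dutp_fraction < 0 || dutp_fraction > 1) stop("dutp_fraction must be in [0, 1]")
  if (incorporation_ratio <= 0) stop("incorporation_ratio must be > 0")
  if (min_fragment_len < 0) stop("min_fragment_len must be >= 0")
  structure(list(dutp_fraction = dutp_fraction,
                 incorporation_ratio = incorporation_ratio,
                 min_fragment_len = as.integer(min_fragment_len)),
            class = "fragmentation_config")
}

#' Per-base cleavage probability
#'
#' A T position incorporates uracil with probability
#' \deqn{p = \frac{f \cdot r}{f \cdot r + (1 - f)}}
#' where \eqn{f} is the dUTP fraction and \eqn{r} the relative incorporation
#' efficiency; every incorporated uracil is cleaved. Non-T bases are never
#' cleaved.
#'
#' @param config a [fragmentation_config()].
#' @param base character vector of bases in A/C/G/T.
#' @return numeric vector of cleavage probabilities.
#' @export
cleavage_probability <- function(config, base = "T") {
  base <- toupper(base)
  if (!all(base %in% c("A", "C", "G", "T")))
    stop("base must be one of A, C, G, T")
  f <- config$dutp_fraction; r <- config$incorporation_ratio
  pT <- if (f == 0) 0 else (f * r) / (f * r + (1 - f))
  ifelse(base == "T", pT, 0)
}

#' Fragment a template by the dUTP/UDG model
#'
#' Marks each T of the template independently with the cleavage probability,
#' excises marked bases and returns the maximal remaining intervals as
#' fragments (0-based half-open coordinates on the template, strand +).
#' Fragments shorter than \code{min_fragment_len} are dropped.
#'
#' @param template DNA string.
#' @param config a [fragmentation_config()].
#' @param seed optional integer seed.
#' @param with_sequence attach fragment sequences (default TRUE).
#' @return \code{data.frame} with columns start, end, length, strand and
#'   optionally sequence; attribute \code{n_cuts} records the number of
#'   excised bases.
#' @export
fragment_template <- function(template, config = fragmentation_config(),
                              seed = NULL, with_sequence = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(template) || nchar(template) == 0) stop("template must be non-empty")
  template <- toupper(template)
  L <- nchar(template)
  tpos <- which(strsplit(template, "", fixed = TRUE)[[1]] == "T")
  p <- cleavage_probability(config, "T")
  cuts <- if (p >= 1) tpos else tpos[runif(length(tpos)) < p]
  starts <- c(0L, cuts)            # fragment starts just after each excised base
  ends <- c(cuts - 1L, L)          # and ends just before the next one
  len <- ends - starts
  keep <- len > 0L & len >= config$min_fragment_len
  out <- data.frame(start = starts[keep], end = ends[keep], length = len[keep],
                    strand = rep("+", sum(keep)), stringsAsFactors = FALSE)
  if (with_sequence)
    out$sequence <- substring(template, out$start + 1L, out$end)
  attr(out, "n_cuts") <- length(cuts)
  attr(out, "template_length") <- L
  out
}

#' Monte-Carlo fragment length distribution
#'
#' Repeats the fragmentation \code{n_reps} times and aggregates fragment
#' lengths, the in-silico analogue of predicting a fragmentation gel from the
#' dUTP fraction.
#'
#' @param template DNA string.
#' @param config a [fragmentation_config()].
#' @param n_reps number of independent fragmentations (>= 1).
#' @param seed optional integer seed.
#' @return list of class \code{length_distribution} with \code{lengths} (all
#'   fragment lengths pooled) and \code{histogram} (data.frame length, count,
#'   density).
#' @export
predicted_length_distribution <- function(template, config = fragmentation_config(),
                                          n_reps = 1000L, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lens <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    lens[[r]] <- fragment_template(template, config, with_sequence = FALSE)$length
  }
  lens <- unlist(lens)
  tab <- table(lens)
  hist <- data.frame(length = as.integer(names(tab)),
                     count = as.integer(tab),
                     density = as.numeric(tab) / length(lens))
  structure(list(lengths = lens, histogram = hist,
                 n_reps = n_reps, config = config),
            class = "length_distribution")
}

#' Analytic mean fragment length
#'
#' For a template of length L with nT cleavable positions at per-position
#' cleavage probability p, the expected number of cuts is \eqn{p\,nT}, so
#' surviving sequence totals \eqn{L - p\,nT} split across \eqn{p\,nT + 1}
#' intervals -- minus the expected number of empty intervals (two adjacent
#' cleavable positions both cut, or a cut at the first/last base), which the
#' fragmenter does not emit. For small p and large L the result approaches
#' the geometric cut spacing \eqn{1/(p f_T)}, with \eqn{f_T} the template's
#' T density.
#'
#' @param template DNA string.
#' @param config a [fragmentation_config()].
#' @return numeric scalar (expectation with no size cut applied).
#' @export
expected_mean_fragment_length <- function(template, config = fragmentation_config()) {
  v <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  L <- length(v)
  nT <- sum(v == "T")
  nTT <- sum(v[-L] == "T" & v[-1] == "T")
  p <- cleavage_probability(config, "T")
  e_cuts <- p * nT
  e_empty <- p^2 * nTT + p * (v[1] == "T") + p * (v[L] == "T")
  (L - e_cuts) / (e_cuts + 1 - e_empty)
}
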
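# The optimized assessment workflow end to end: extraction -> alignment ->
# reduce (-> optional clustering + validation), with stage counters and
# reporting.

#' Run the library assessment pipeline
#'
#' Composes the stages on a set of read pairs: barcode extraction (flank
#' matching, length and phred filtration), fragment extraction and
#' seed-and-extend unique alignment, the keyed barcode/range join, and the
#' reduce to a purity-annotated look-up table. Optionally clusters the
#' observed barcodes and re-validates via the purity readout.
#'
#' @param reads \code{data.frame} (read_id, seq1, qual1, seq2, qual2) from
#'   [simulate_reads()] / [read_paired_fastq()], or a length-2 character
#'   vector of FASTQ paths.
#' @param reference reference DNA string, FASTA path, or a
#'   [reference_index()].
#' @param flanks a [flank_definition()].
#' @param spec a [barcode_spec()].
#' @param min_phred phred filtration level inside the barcode (0 = off).
#' @param tol_bp consensus inclusion tolerance (default 20).
#' @param max_mismatch_rate,align_min_len,k aligner parameters.
#' @param clustering optional list(algorithm = "sphere" or
#'   "message_passing", max_dist = integer, min_ratio = numeric) to append
#'   the clustering + validation stage.
#' @param seed optional integer seed (recorded in the result).
#' @return list of class \code{bclut_pipeline}: \code{table}
#'   ([lookup_table()]), \code{purity}, \code{pairs}, \code{extraction},
#'   \code{alignments}, \code{counters}, and \code{clustered} when
#'   requested.
#' @export
run_pipeline <- function(reads, reference, flanks = flank_definition(),
                         spec = barcode_spec(), min_phred = 0L, tol_bp = 20L,
                         max_mismatch_rate = 0.1, align_min_len = 20L,
                         k = 15L, clustering = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(reads) && length(reads) == 2)
    reads <- read_paired_fastq(reads[1], reads[2])
  if (nrow(reads) == 0) stop("no reads supplied")
  idx <- if (inherits(reference, "reference_index")) reference
         else reference_index(reference, k = k)

  extraction <- extract_barcodes(reads, flanks, spec, min_phred = min_phred)
  fragments <- extract_fragments(reads, flanks)
  alignments <- align_fragments(fragments$fragment, idx,
                                max_mismatch_rate = max_mismatch_rate,
                                min_len = align_min_len,
                                read_id = fragments$read_id)
  pairs <- attach_barcode(alignments, extraction)
  table <- lookup_table(pairs, tol_bp = tol_bp)

  counters <- list(
    reads_in = nrow(reads),
    extraction = extraction_tally(extraction),
    aligned = sum(alignments$mapped),
    unaligned = sum(!alignments$mapped),
    paired = nrow(pairs),
    dropped_at_join = attr(pairs, "dropped"),
    singlets = attr(table, "n_singlets"),
    multi_barcodes = nrow(table))

  out <- list(table = table,
              purity = if (nrow(table)) purity_distribution(table) else NULL,
              pairs = pairs, extraction = extraction, alignments = alignments,
              counters = counters, seed = seed,
              params = list(min_phred = min_phred, tol_bp = tol_bp,
                            max_mismatch_rate = max_mismatch_rate))
  if (!is.null(clustering)) {
    counts <- barcode_tally(pairs$barcode)
    cl <- if (identical(clustering$algorithm, "sphere")) {
      sphere_cluster(counts, clustering$max_dist,
                     neighbors = clustering$neighbors)
    } else {
      message_passing_cluster(counts, clustering$max_dist,
                              min_ratio = clustering$min_ratio %||% 1,
                              neighbors = clustering$neighbors)
    }
    out$clustered <- c(list(clustering = cl),
                       validate_clustering(cl, pairs, tol_bp = tol_bp))
  }
  class(out) <- "bclut_pipeline"
  out
}

#' @export
print.bclut_pipeline <- function(x, ...) {
  cat("bclut pipeline run\n")
  cat(sprintf("  reads in:        %d\n", x$counters$reads_in))
  cat(sprintf("  barcode pass:    %d\n", x$counters$extraction[["none"]]))
  cat(sprintf("  aligned:         %d\n", x$counters$aligned))
  cat(sprintf("  joined pairs:    %d\n", x$counters$paired))
  cat(sprintf("  singlets:        %d\n", x$counters$singlets))
  cat(sprintf("  multi barcodes:  %d\n", x$counters$multi_barcodes))
  if (!is.null(x$purity))
    cat(sprintf("  mean purity:     %.4f\n", x$purity$mean))
  invisible(x)
}

#' Library QC report
#'
#' Descriptive summaries of a look-up table: barcode read-count histogram
#' (the Poisson-shaped depth structure), fragment-length histogram,
#' per-base coverage of the consensus fragments, orientation tally with a
#' two-sided binomial test, and the purity summary. With ground truth
#' supplied, adds confusion counts (correct / chimeric / lost links).
#'
#' @param table a [lookup_table()].
#' @param truth optional [build_library()] table.
#' @param reference_length optional reference length for the coverage track.
#' @param tol_bp tolerance used when comparing against truth.
#' @return list of class \code{bclut_report}.
#' @export
report <- function(table, truth = NULL, reference_length = NULL, tol_bp = 20L) {
  if (nrow(table) == 0) stop("empty look-up table")
  counts <- table$total_count
  count_hist <- as.data.frame(table(reads = counts), stringsAsFactors = FALSE)
  count_hist$reads <- as.integer(count_hist$reads)
  names(count_hist) <- c("reads_per_barcode", "n_barcodes")

  flen <- table$end - table$start
  flen_hist <- as.data.frame(table(length = flen), stringsAsFactors = FALSE)
  flen_hist$length <- as.integer(flen_hist$length)
  names(flen_hist) <- c("fragment_length", "n_barcodes")

  L <- reference_length %||% max(table$end)
  cov <- IRanges::coverage(IRanges::IRanges(start = table$start + 1L,
                                            end = table$end), width = L)
  coverage <- as.integer(cov)

  n_plus <- sum(table$strand == "+"); n_minus <- sum(table$strand == "-")
  orientation <- list(plus = n_plus, minus = n_minus,
                      binom_p = stats::binom.test(n_plus, n_plus + n_minus)$p.value)

  out <- list(n_barcodes = nrow(table),
              barcode_count_hist = count_hist,
              fragment_length_hist = flen_hist,
              coverage = coverage,
              orientation = orientation,
              purity = purity_distribution(table))
  if (!is.null(truth)) {
    m <- match(table$barcode, truth$barcode)
    matched <- !is.na(m)
    correct <- matched &
      abs(table$start - truth$start[m]) <= tol_bp &
      abs(table$end - truth$end[m]) <= tol_bp &
      table$strand == truth$strand[m]
    out$confusion <- list(
      correct_link = sum(correct, na.rm = TRUE),
      chimeric_link = sum(matched & !correct, na.rm = TRUE),
      novel_barcode = sum(!matched),
      lost_clones = sum(!(truth$barcode %in% table$barcode)))
  }
  class(out) <- "bclut_report"
  out
}

#' @export
print.bclut_report <- function(x, ...) {
  cat(sprintf("library report: %d multi-read barcodes\n", x$n_barcodes))
  cat(sprintf("  orientation: %d (+) / %d (-), binomial p = %.3g\n",
              x$orientation$plus, x$orientation$minus, x$orientation$binom_p))
  cat(sprintf("  mean purity: %.4f\n", x$purity$mean))
  if (!is.null(x$confusion))
    cat(sprintf("  links: %d correct, %d chimeric, %d novel, %d lost\n",
                x$confusion$correct_link, x$confusion$chimeric_link,
                x$confusion$novel_barcode, x$confusion$lost_clones))
  invisible(x)
}
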
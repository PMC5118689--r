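# The reduce stage: group aligned ranges by barcode, set singlets aside,
# derive each barcode's consensus range by count ordering with the +/-20 bp
# inclusion criterion, and compute the purity parameter -- the look-up table.

#' Group (barcode, range) pairs by barcode
#'
#' Barcodes are normalized to upper case and grouped by exact string match;
#' the total number of ranges is conserved.
#'
#' @param pairs \code{data.frame} with columns barcode, start, end, strand
#'   (and optionally read_id, ref_id), e.g. from [attach_barcode()].
#' @return \code{data.table} keyed by barcode, with attribute
#'   \code{group_sizes}.
#' @export
group_by_barcode <- function(pairs) {
  dt <- data.table::as.data.table(pairs)
  if (nrow(dt)) dt[, barcode := toupper(barcode)]
  data.table::setkeyv(dt, "barcode")
  attr(dt, "group_sizes") <- if (nrow(dt)) dt[, .N, by = barcode] else
    data.table::data.table(barcode = character(0), N = integer(0))
  dt
}

#' Separate singlet barcodes from multi-read barcodes
#'
#' Barcodes observed in exactly one read are set aside: purity is undefined
#' for them, so they are reported but excluded from purity distributions.
#'
#' @param groups output of [group_by_barcode()].
#' @return list with elements \code{singlets} and \code{multis} (both
#'   \code{data.table}s) and \code{n_singlets}.
#' @export
split_singlets <- function(groups) {
  dt <- data.table::as.data.table(groups)
  if (nrow(dt) == 0) {
    return(list(singlets = dt, multis = dt, n_singlets = 0L))
  }
  dt[, n_reads := .N, by = barcode]
  singlets <- dt[n_reads == 1L][, n_reads := NULL]
  multis <- dt[n_reads > 1L][, n_reads := NULL]
  dt[, n_reads := NULL]
  list(singlets = singlets, multis = multis,
       n_singlets = nrow(singlets))
}

# Consensus + purity for one set of ranges (vectors of equal length >= 2).
consensus_core <- function(ref_id, start, end, strand, tol_bp) {
  cnt <- data.table::data.table(ref_id = ref_id, start = start,
                                end = end, strand = strand)[
    , .N, by = .(ref_id, start, end, strand)]
  data.table::setorder(cnt, -N, ref_id, start, end, strand)
  top <- cnt[1]
  incl <- cnt[abs(start - top$start) <= tol_bp & abs(end - top$end) <= tol_bp &
                strand == top$strand & ref_id == top$ref_id]
  list(ref_id = top$ref_id, start = top$start, end = top$end,
       strand = top$strand, consensus_count = sum(incl$N),
       total_count = length(start))
}

#' Consensus range and purity for one barcode group
#'
#' Identical ranges (same start, end, strand) are counted; the most frequent
#' identical range is the consensus (ties broken deterministically by highest
#' count, then lexicographically smallest ref_id, start, end, strand). The
#' consensus count then absorbs every range whose start and end both lie
#' within \code{tol_bp} of the consensus on the same strand, and
#' purity = consensus_count / total_count.
#'
#' @param group \code{data.frame} of ranges for one barcode (columns start,
#'   end, strand; optional ref_id, barcode); at least 2 rows.
#' @param tol_bp inclusion tolerance on each endpoint (default 20).
#' @return one-row \code{data.frame}: barcode, ref_id, start, end, strand,
#'   consensus_count, total_count, purity.
#' @export
consensus_and_purity <- function(group, tol_bp = 20L) {
  if (nrow(group) < 2) stop("purity is undefined for a singlet group")
  bc <- if ("barcode" %in% names(group)) toupper(group$barcode[1]) else NA_character_
  rid <- if ("ref_id" %in% names(group)) group$ref_id else rep("ref", nrow(group))
  cc <- consensus_core(rid, group$start, group$end, group$strand, tol_bp)
  data.frame(barcode = bc, ref_id = cc$ref_id, start = cc$start, end = cc$end,
             strand = cc$strand, consensus_count = cc$consensus_count,
             total_count = cc$total_count,
             purity = cc$consensus_count / cc$total_count,
             stringsAsFactors = FALSE)
}

#' Build the barcode-to-fragment look-up table
#'
#' Runs the full reduce on (barcode, range) pairs: group by barcode, set
#' singlets aside, and compute consensus + purity per multi-read barcode.
#'
#' @param pairs \code{data.frame} from [attach_barcode()] (or compatible).
#' @param tol_bp inclusion tolerance (default 20).
#' @return \code{data.table} of class \code{lookup_table}, one row per
#'   multi-read barcode (barcode, ref_id, start, end, strand,
#'   consensus_count, total_count, purity), with metadata attributes
#'   \code{n_singlets}, \code{tol_bp}, \code{n_reads}.
#' @export
lookup_table <- function(pairs, tol_bp = 20L) {
  grp <- group_by_barcode(pairs)
  parts <- split_singlets(grp)
  multis <- parts$multis
  if (nrow(multis) == 0) {
    tbl <- data.table::data.table(
      barcode = character(0), ref_id = character(0), start = integer(0),
      end = integer(0), strand = character(0), consensus_count = integer(0),
      total_count = integer(0), purity = numeric(0))
  } else {
    if (!"ref_id" %in% names(multis)) multis[, ref_id := "ref"]
    tbl <- multis[, consensus_core(ref_id, start, end, strand, tol_bp),
                  by = barcode]
    tbl[, purity := consensus_count / total_count]
  }
  build_lookup_table(tbl, n_singlets = parts$n_singlets,
                     tol_bp = tol_bp, n_reads = nrow(grp))
}

#' Assemble consensus records into a keyed look-up table
#'
#' @param records \code{data.frame} of consensus records (one per barcode).
#' @param n_singlets,tol_bp,n_reads metadata carried as attributes.
#' @return \code{lookup_table} keyed by barcode.
#' @export
build_lookup_table <- function(records, n_singlets = 0L, tol_bp = 20L,
                               n_reads = NA_integer_) {
  dt <- data.table::as.data.table(records)
  if (anyDuplicated(dt$barcode)) stop("duplicate barcode keys in look-up table")
  data.table::setkeyv(dt, "barcode")
  data.table::setattr(dt, "n_singlets", as.integer(n_singlets))
  data.table::setattr(dt, "tol_bp", as.integer(tol_bp))
  data.table::setattr(dt, "n_reads", n_reads)
  data.table::setattr(dt, "class", c("lookup_table", class(dt)))
  dt
}

#' Summarize the purity distribution of a look-up table
#'
#' @param table a [lookup_table()].
#' @return list of class \code{purity_distribution}: n, mean, quantiles
#'   (0/25/50/75/100\%), and a fixed 101-bin histogram on \[0, 1\] for
#'   beanplot-style reporting.
#' @export
purity_distribution <- function(table) {
  if (nrow(table) == 0) stop("empty look-up table")
  p <- table$purity
  breaks <- seq(0, 1, length.out = 102L)
  h <- hist(p, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  structure(list(n = length(p), mean = mean(p),
                 quantiles = quantile(p, c(0, 0.25, 0.5, 0.75, 1)),
                 histogram = data.frame(mid = h$mids, count = h$counts)),
            class = "purity_distribution")
}

#' @export
print.purity_distribution <- function(x, ...) {
  cat(sprintf("purity over %d barcodes: mean %.4f, median %.4f, IQR [%.4f, %.4f]\n",
              x$n, x$mean, x$quantiles[["50%"]],
              x$quantiles[["25%"]], x$quantiles[["75%"]]))
  invisible(x)
}

#' Write / read a look-up table as TSV with a JSON metadata sidecar
#'
#' @param table a [lookup_table()].
#' @param path TSV path; metadata goes to \code{paste0(path, ".meta.json")}.
#' @return invisibly, \code{path}.
#' @export
write_lookup_table <- function(table, path) {
  data.table::fwrite(data.table::as.data.table(table), path, sep = "\t")
  meta <- list(n_singlets = attr(table, "n_singlets"),
               tol_bp = attr(table, "tol_bp"),
               n_reads = attr(table, "n_reads"),
               n_barcodes = nrow(table))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lookup_table
#' @export
read_lookup_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = c("barcode", "ref_id", "strand")))
  metafile <- paste0(path, ".meta.json")
  meta <- if (file.exists(metafile)) jsonlite::read_json(metafile) else list()
  build_lookup_table(dt,
                     n_singlets = meta$n_singlets %||% 0L,
                     tol_bp = meta$tol_bp %||% 20L,
                     n_reads = meta$n_reads %||% NA_integer_)
}

#' Look-up table as GRanges
#'
#' @param table a [lookup_table()].
#' @return \code{GenomicRanges::GRanges} with barcode, counts and purity as
#'   metadata columns (coordinates converted to 1-based).
#' @export
as_granges <- function(table) {
  GenomicRanges::GRanges(
    seqnames = table$ref_id,
    ranges = IRanges::IRanges(start = table$start + 1L, end = table$end),
    strand = table$strand,
    barcode = table$barcode,
    consensus_count = table$consensus_count,
    total_count = table$total_count,
    purity = table$purity)
}
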
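# Barcode error-correction clustering over the Levenshtein distance:
# greedy sphere clustering and message-passing clustering (count flows to
# the nearest sufficiently-larger neighbour), both with tie discarding, plus
# the purity-based validation harness and supporting utilities.

#' Bounded Levenshtein distance
#'
#' Unit-cost edit distance with a cap: values provably greater than
#' \code{cap} are returned as \code{cap + 1} (banded dynamic program with
#' early exit).
#'
#' @param a,b character vectors (recycled to a common length).
#' @param cap distance cap; \code{Inf} computes the exact distance.
#' @return integer vector of distances (capped at \code{cap + 1}).
#' @export
#' @examples
#' levenshtein("kitten", "sitting")      # 3
levenshtein <- function(a, b, cap = Inf) {
  if (is.infinite(cap)) cap <- max(nchar(a), nchar(b), 1L)
  .lev_bounded(as.character(a), as.character(b), as.integer(cap))
}

#' All sequence pairs within a Levenshtein radius
#'
#' All-pairs scan with a length prefilter and capped banded DP; intended for
#' desk scale (up to ~2e4 sequences). The edge list can be shared between
#' clustering runs at different (smaller) thresholds.
#'
#' @param sequences character vector of distinct sequences.
#' @param max_dist Levenshtein radius.
#' @return \code{data.frame} with columns a, b (sequences) and d (distance).
#' @export
lev_neighbors <- function(sequences, max_dist) {
  ed <- .lev_neighbor_pairs(as.character(sequences), as.integer(max_dist))
  data.frame(a = sequences[ed$i], b = sequences[ed$j], d = ed$d,
             stringsAsFactors = FALSE)
}

#' Tally barcode sequences into counts
#'
#' @param barcodes character vector of observed (extracted, passing)
#'   barcodes.
#' @return \code{data.frame} with sequence, count, sorted by decreasing
#'   count then sequence.
#' @export
barcode_tally <- function(barcodes) {
  tab <- table(barcodes)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$sequence), , drop = FALSE]
}

# Canonical processing order: count descending, then lexicographic; returns
# counts df, id maps and an adjacency list built from the edge list.
cluster_prep <- function(counts, max_dist, neighbors) {
  if (anyDuplicated(counts$sequence)) stop("sequences must be distinct")
  counts <- counts[order(-counts$count, counts$sequence), , drop = FALSE]
  rownames(counts) <- NULL
  if (is.null(neighbors)) neighbors <- lev_neighbors(counts$sequence, max_dist)
  nb <- neighbors[neighbors$d <= max_dist, , drop = FALSE]
  id <- seq_len(nrow(counts)); names(id) <- counts$sequence
  ia <- unname(id[nb$a]); ib <- unname(id[nb$b])
  keep <- !is.na(ia) & !is.na(ib)
  adj <- vector("list", nrow(counts))
  if (any(keep)) {
    ia <- ia[keep]; ib <- ib[keep]; dd <- nb$d[keep]
    ord <- c(ia, ib); tgt <- c(ib, ia); dst <- c(dd, dd)
    sp <- split(data.frame(t = tgt, d = dst), ord)
    adj[as.integer(names(sp))] <- sp
  }
  list(counts = counts, adj = adj)
}

finish_clustering <- function(counts, centroid_id, discarded, algorithm,
                              max_dist, params = list()) {
  assignments <- data.frame(
    sequence = counts$sequence, count = counts$count,
    centroid = ifelse(discarded, NA_character_, counts$sequence[centroid_id]),
    discarded = discarded, stringsAsFactors = FALSE)
  dt <- data.table::as.data.table(assignments[!assignments$discarded, ])
  clusters <- if (nrow(dt)) {
    as.data.frame(dt[, .(n_members = .N, total_count = sum(count)),
                     by = centroid])
  } else {
    data.frame(centroid = character(0), n_members = integer(0),
               total_count = integer(0))
  }
  structure(list(assignments = assignments, clusters = clusters,
                 n_clusters = nrow(clusters),
                 discarded = assignments$sequence[assignments$discarded],
                 discarded_count = sum(assignments$count[assignments$discarded]),
                 algorithm = algorithm, max_dist = max_dist, params = params),
            class = "barcode_clustering")
}

#' @export
print.barcode_clustering <- function(x, ...) {
  cat(sprintf("%s clustering (Levenshtein <= %d): %d sequences -> %d clusters, %d discarded\n",
              x$algorithm, x$max_dist, nrow(x$assignments), x$n_clusters,
              length(x$discarded)))
  invisible(x)
}

#' Sphere clustering
#'
#' Sequences are processed in descending count order. A sequence becomes a
#' centroid unless an existing centroid of strictly greater count lies
#' within \code{max_dist}, in which case the nearest such centroid claims
#' it; a sequence at equal minimal distance to two or more formed centroids
#' is ambiguous at the point of clustering and is discarded.
#'
#' @param counts \code{data.frame} with sequence, count (from
#'   [barcode_tally()]).
#' @param max_dist Levenshtein radius.
#' @param neighbors optional precomputed [lev_neighbors()] edge list
#'   (computed at this or a larger radius).
#' @return object of class \code{barcode_clustering} with elements
#'   \code{assignments}, \code{clusters}, \code{discarded}.
#' @export
sphere_cluster <- function(counts, max_dist, neighbors = NULL) {
  pr <- cluster_prep(counts, max_dist, neighbors)
  counts <- pr$counts; adj <- pr$adj
  n <- nrow(counts)
  centroid_id <- integer(n); is_centroid <- logical(n)
  discarded <- logical(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    claimants <- integer(0)
    if (!is.null(nb) && nrow(nb)) {
      cand <- nb[is_centroid[nb$t] & counts$count[nb$t] > counts$count[i], ,
                 drop = FALSE]
      if (nrow(cand)) claimants <- cand$t[cand$d == min(cand$d)]
    }
    if (length(claimants) == 0) {
      is_centroid[i] <- TRUE; centroid_id[i] <- i
    } else if (length(claimants) == 1) {
      centroid_id[i] <- claimants
    } else {
      discarded[i] <- TRUE
    }
  }
  finish_clustering(counts, centroid_id, discarded, "sphere", max_dist)
}

#' Message-passing clustering
#'
#' Each sequence passes its count toward its nearest neighbour of strictly
#' higher count (subject to the count-ratio gate) within \code{max_dist};
#' counts propagate transitively, so the surviving parentless sequences are
#' the cluster centroids. A sequence whose equally-near candidate parents
#' resolve to different centroids is ambiguous and discarded (as is anything
#' beneath it).
#'
#' @inheritParams sphere_cluster
#' @param min_ratio optional count-ratio gate: a parent is eligible only if
#'   \code{parent_count >= min_ratio * child_count}. Default 1 (off; the
#'   strict count ordering alone decides). Raising it blocks merges between
#'   barcodes of comparable abundance at the price of stranding error halos
#'   of shallowly sequenced clones.
#' @return object of class \code{barcode_clustering}.
#' @export
message_passing_cluster <- function(counts, max_dist, min_ratio = 1,
                                    neighbors = NULL) {
  pr <- cluster_prep(counts, max_dist, neighbors)
  counts <- pr$counts; adj <- pr$adj
  n <- nrow(counts)
  root <- integer(n)          # 0 = pending, -1 = discarded
  for (i in seq_len(n)) {     # descending count: parents resolved first
    nb <- adj[[i]]
    parents <- integer(0)
    if (!is.null(nb) && nrow(nb)) {
      ok <- counts$count[nb$t] > counts$count[i] &
        counts$count[nb$t] >= min_ratio * counts$count[i]
      cand <- nb[ok, , drop = FALSE]
      if (nrow(cand)) parents <- cand$t[cand$d == min(cand$d)]
    }
    if (length(parents) == 0) { root[i] <- i; next }
    proots <- unique(root[parents])
    if (length(proots) == 1 && proots[1] > 0) {
      root[i] <- proots[1]
    } else {
      root[i] <- -1L          # ambiguous parents or a discarded parent
    }
  }
  discarded <- root < 0
  centroid_id <- ifelse(discarded, NA_integer_, root)
  centroid_id[discarded] <- 1L  # placeholder, masked by discarded flag
  finish_clustering(counts, centroid_id, discarded, "message_passing",
                    max_dist, params = list(min_ratio = min_ratio))
}

#' Validate a clustering with the purity readout
#'
#' Relabels every read's barcode by its cluster centroid (reads of discarded
#' barcodes are dropped and counted), re-runs the reduce stage, and returns
#' the post-clustering purity distribution: a false merge of two truly
#' distinct barcodes pulls purity down because the merged barcode now points
#' to different fragments.
#'
#' @param clustering a [sphere_cluster()] / [message_passing_cluster()]
#'   result.
#' @param pairs (barcode, range) pairs as for [lookup_table()].
#' @param tol_bp inclusion tolerance for the reduce stage.
#' @return list: \code{purity} ([purity_distribution()]), \code{table}
#'   (post-clustering [lookup_table()]), \code{n_dropped_reads},
#'   \code{n_unclustered_reads}.
#' @export
validate_clustering <- function(clustering, pairs, tol_bp = 20L) {
  map <- clustering$assignments
  idx <- match(toupper(pairs$barcode), map$sequence)
  centroid <- map$centroid[idx]
  drop_discard <- !is.na(idx) & map$discarded[idx]
  drop_unknown <- is.na(idx)
  keep <- !(drop_discard | drop_unknown)
  relabeled <- pairs[keep, , drop = FALSE]
  relabeled$barcode <- centroid[keep]
  tbl <- lookup_table(relabeled, tol_bp = tol_bp)
  list(purity = purity_distribution(tbl), table = tbl,
       n_dropped_reads = sum(drop_discard),
       n_unclustered_reads = sum(drop_unknown))
}

#' Bernoulli subsampling of read pairs
#'
#' Seeded per-read thinning used to emulate lower sequencing depth.
#'
#' @param pairs \code{data.frame} of reads/pairs.
#' @param fraction keep probability in (0, 1\].
#' @param seed optional integer seed.
#' @return subset of \code{pairs}.
#' @export
subsample_reads <- function(pairs, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(pairs)
  if (!is.null(seed)) set.seed(seed)
  pairs[runif(nrow(pairs)) < fraction, , drop = FALSE]
}

#' Overlap between two barcode look-up tables
#'
#' Exact-string intersection of barcode keys and, when at least three are
#' shared, the Pearson correlation of their read counts -- the
#' orthogonality / reproducibility readout for independently constructed
#' libraries.
#'
#' @param tableA,tableB [lookup_table()] objects.
#' @return list: shared (count), correlation (NA if < 3 shared),
#'   shared_barcodes.
#' @export
library_overlap <- function(tableA, tableB) {
  shared <- intersect(tableA$barcode, tableB$barcode)
  correlation <- if (length(shared) >= 3) {
    stats::cor(tableA$total_count[match(shared, tableA$barcode)],
               tableB$total_count[match(shared, tableB$barcode)])
  } else NA_real_
  list(shared = length(shared), correlation = correlation,
       shared_barcodes = shared)
}
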
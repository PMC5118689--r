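test_that("bounded Levenshtein matches the full DP oracle and metric laws", {
  expect_identical(levenshtein("AAA", "AAA"), 0L)
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  expect_identical(levenshtein("", "ACGT"), 4L)
  # capped values exceed the cap by exactly one
  expect_identical(levenshtein("AAAAAAAA", "TTTTTTTT", cap = 3), 4L)
  set.seed(40)
  for (i in 1:300) {
    a <- random_dna(sample(0:24, 1)); b <- random_dna(sample(0:24, 1))
    expect_identical(levenshtein(a, b), as.integer(adist(a, b)))
    expect_identical(levenshtein(a, b), levenshtein(b, a))
  }
  # triangle inequality on random triples
  for (i in 1:100) {
    x <- random_dna(12); y <- random_dna(12); z <- random_dna(12)
    expect_lte(levenshtein(x, z), levenshtein(x, y) + levenshtein(y, z))
  }
})

test_that("neighbour enumeration agrees with exhaustive pairwise distances", {
  set.seed(41)
  seqs <- unique(replicate(60, perturb_seq(random_dna(10), sample(0:3, 1))))
  nb <- lev_neighbors(seqs, 2)
  full <- adist(seqs)
  want <- which(full <= 2 & upper.tri(full), arr.ind = TRUE)
  expect_identical(nrow(nb), nrow(want))
  got_keys <- paste(pmin(nb$a, nb$b), pmax(nb$a, nb$b))
  want_keys <- paste(pmin(seqs[want[, 1]], seqs[want[, 2]]),
                     pmax(seqs[want[, 1]], seqs[want[, 2]]))
  expect_setequal(got_keys, want_keys)
  expect_identical(nb$d, as.integer(full[cbind(match(nb$a, seqs), match(nb$b, seqs))]))
})

test_that("sphere clustering claims by descending count with tie discarding", {
  counts <- data.frame(sequence = c("AAA", "AAT", "TTT"), count = c(10L, 2L, 5L))
  cl <- sphere_cluster(counts, max_dist = 1)
  expect_identical(cl$n_clusters, 2L)
  expect_identical(sort(cl$clusters$centroid), c("AAA", "TTT"))
  expect_identical(cl$assignments$centroid[cl$assignments$sequence == "AAT"], "AAA")

  # equidistant to two formed clusters -> discarded
  tie <- data.frame(sequence = c("AAC", "AAG", "AAT"), count = c(10L, 10L, 1L))
  cl2 <- sphere_cluster(tie, max_dist = 1)
  expect_identical(cl2$n_clusters, 2L)
  expect_identical(cl2$discarded, "AAT")

  # radius 0: identity clustering
  cl0 <- sphere_cluster(tie, max_dist = 0)
  expect_identical(cl0$n_clusters, 3L)
  expect_length(cl0$discarded, 0)
})

test_that("message passing absorbs error halos and separates distant truths", {
  set.seed(42)
  true <- "ACGTACGTACGTACGTACGT"
  halo <- unique(vapply(1:10, function(i) perturb_seq(true, sample(1:2, 1)), ""))
  counts <- data.frame(sequence = c(true, halo),
                       count = c(100L, sample(1:3, length(halo), TRUE)))
  cl <- message_passing_cluster(counts, max_dist = 2)
  expect_identical(cl$n_clusters, 1L)
  expect_identical(cl$clusters$centroid, true)
  expect_identical(cl$clusters$total_count + cl$discarded_count, sum(counts$count))

  # two well-separated true barcodes keep separate halos
  t2 <- "TTGGCCAATTGGCCAATTGG"
  stopifnot(levenshtein(true, t2) > 8)
  halo2 <- unique(vapply(1:8, function(i) perturb_seq(t2, 1), ""))
  counts2 <- rbind(counts,
                   data.frame(sequence = c(t2, halo2),
                              count = c(80L, sample(1:3, length(halo2), TRUE))))
  counts2 <- counts2[!duplicated(counts2$sequence), ]
  cl2 <- message_passing_cluster(counts2, max_dist = 3)
  expect_identical(cl2$n_clusters, 2L)
  expect_setequal(cl2$clusters$centroid, c(true, t2))

  # radius 0: identity
  cl0 <- message_passing_cluster(counts, max_dist = 0)
  expect_identical(cl0$n_clusters, nrow(counts))
})

test_that("the ratio gate blocks merges between comparable counts", {
  counts <- data.frame(sequence = c("AAAAAAAA", "AAAAAAAT"), count = c(12L, 9L))
  open <- message_passing_cluster(counts, max_dist = 1, min_ratio = 1)
  expect_identical(open$n_clusters, 1L)
  gated <- message_passing_cluster(counts, max_dist = 1, min_ratio = 5)
  expect_identical(gated$n_clusters, 2L)
})

test_that("sphere cluster counts can rise with the radius through claim chains", {
  # characterization: when a larger radius lets the top centroid claim a
  # mid-count sequence that was itself a centroid at a smaller radius, that
  # sequence's satellites become centroids of their own -- greedy sphere
  # clustering is not radius-monotone (message passing is).
  counts <- data.frame(
    sequence = c("ATACATACATGC", "GCGGAATTACAT", "CAGCACGGGAGT", "CTACAAACGTGC",
                 "GTACATTCATGC", "TTACATACATGC", "ATACATAATGC", "TCGGATTACAT",
                 "GCGGAATTTCTT", "GCGGAATGACAT", "CAGTACGGAAGT", "CAGCACGGAAGT"),
    count = c(24L, 25L, 36L, 45L, 3L, 2L, 3L, 3L, 1L, 2L, 3L, 1L),
    stringsAsFactors = FALSE)
  sizes_sphere <- vapply(0:3, function(d) sphere_cluster(counts, d)$n_clusters,
                         numeric(1))
  expect_identical(sizes_sphere, c(12, 7, 4, 5))   # rises at d = 3
  sizes_mp <- vapply(0:3, function(d)
    message_passing_cluster(counts, d)$n_clusters, numeric(1))
  expect_true(all(diff(sizes_mp) <= 0))
})

test_that("clustering validation relabels reads and reflects false merges", {
  # two clones pointing at different fragments
  pairs <- rbind(
    data.frame(read_id = sprintf("a%02d", 1:6), barcode = "AAAAAAAA", ref_id = "ref",
               start = 100L, end = 200L, strand = "+", stringsAsFactors = FALSE),
    data.frame(read_id = sprintf("b%02d", 1:4), barcode = "CCCCCCCC", ref_id = "ref",
               start = 400L, end = 480L, strand = "+", stringsAsFactors = FALSE))
  counts <- barcode_tally(pairs$barcode)
  ident <- sphere_cluster(counts, max_dist = 0)
  v0 <- validate_clustering(ident, pairs)
  expect_equal(v0$purity$mean, 1)
  # deliberately merging the two barcodes gives the count-weighted max share
  forced <- ident
  forced$assignments$centroid <- "AAAAAAAA"
  v1 <- validate_clustering(forced, pairs)
  expect_equal(v1$purity$mean, 0.6)
  expect_identical(v1$table$total_count, 10L)
})

test_that("subsampling is seeded Bernoulli thinning", {
  pairs <- data.frame(read_id = as.character(1:10000), x = 1)
  expect_identical(subsample_reads(pairs, 1), pairs)
  s1 <- subsample_reads(pairs, 0.5, seed = 7)
  s2 <- subsample_reads(pairs, 0.5, seed = 7)
  expect_identical(s1, s2)
  # kept count within the binomial 99% interval
  expect_true(abs(nrow(s1) - 5000) < qnorm(0.995) * sqrt(10000 * 0.25))
  expect_error(subsample_reads(pairs, 0))
})

test_that("library overlap reports shared keys and count correlation", {
  mk_tbl <- function(bcs, counts) {
    build_lookup_table(data.frame(barcode = bcs, ref_id = "ref", start = 0L,
                                  end = 50L, strand = "+",
                                  consensus_count = counts, total_count = counts,
                                  purity = 1))
  }
  a <- mk_tbl(c("AAAA", "CCCC", "GGGG", "TTTT"), c(5L, 8L, 2L, 9L))
  expect_identical(library_overlap(a, a)$shared, 4L)
  expect_equal(library_overlap(a, a)$correlation, 1)
  b <- mk_tbl(c("ACAC", "GTGT"), c(3L, 4L))
  ov <- library_overlap(a, b)
  expect_identical(ov$shared, 0L)
  expect_true(is.na(ov$correlation))
})

test_that("two independent 50k-barcode libraries share at most a handful of keys", {
  a <- generate_barcodes(50000, barcode_spec(), seed = 43)
  b <- generate_barcodes(50000, barcode_spec(), seed = 44)
  expect_lte(length(intersect(a, b)), 5)
})
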
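mk_pairs <- function(spec_list) {
  # spec_list: list of c(barcode, start, end, strand, n)
  do.call(rbind, lapply(spec_list, function(x) {
    n <- as.integer(x[[5]])
    data.frame(read_id = replicate(n, paste0("r", paste(sample(letters, 8, TRUE), collapse = ""))),
               barcode = x[[1]], ref_id = "ref",
               start = as.integer(x[[2]]), end = as.integer(x[[3]]),
               strand = x[[4]], stringsAsFactors = FALSE)
  }))
}

test_that("grouping conserves reads and normalizes barcode case", {
  p <- mk_pairs(list(list("AAAA", 0, 50, "+", 4), list("cccc", 10, 60, "-", 3),
                     list("GGGG", 5, 55, "+", 3)))
  g <- group_by_barcode(p)
  expect_identical(nrow(g), 10L)
  sizes <- attr(g, "group_sizes")
  expect_identical(sum(sizes$N), 10L)
  expect_true("CCCC" %in% sizes$barcode)
  expect_identical(nrow(group_by_barcode(p[0, ])), 0L)
})

test_that("singlets are set aside, multis kept", {
  p <- mk_pairs(list(list("AAAA", 0, 50, "+", 1), list("CCCC", 0, 50, "+", 1),
                     list("GGGG", 0, 50, "+", 5)))
  sp <- split_singlets(group_by_barcode(p))
  expect_identical(sp$n_singlets, 2L)
  expect_identical(unique(sp$multis$barcode), "GGGG")
  all_single <- split_singlets(group_by_barcode(
    mk_pairs(list(list("AAAA", 0, 50, "+", 1)))))
  expect_identical(nrow(all_single$multis), 0L)
})

test_that("consensus and purity follow the count-then-inclusion rule", {
  # 5 identical + 3 within tolerance + 2 elsewhere -> purity 0.8
  g <- mk_pairs(list(list("B1", 100, 200, "+", 5), list("B1", 110, 190, "+", 3),
                     list("B1", 300, 400, "+", 2)))
  rec <- consensus_and_purity(g, tol_bp = 20)
  expect_identical(rec$start, 100L); expect_identical(rec$end, 200L)
  expect_identical(rec$consensus_count, 8L)
  expect_identical(rec$total_count, 10L)
  expect_equal(rec$purity, 0.8)

  # all identical -> purity exactly 1
  all_same <- mk_pairs(list(list("B2", 10, 90, "-", 7)))
  expect_identical(consensus_and_purity(all_same)$purity, 1)

  # strand tie: deterministic tie-break, opposite strand not included
  tie <- mk_pairs(list(list("B3", 100, 200, "+", 2), list("B3", 100, 200, "-", 2)))
  rec3 <- consensus_and_purity(tie)
  expect_identical(rec3$strand, "+")
  expect_equal(rec3$purity, 0.5)

  expect_error(consensus_and_purity(mk_pairs(list(list("B4", 0, 5, "+", 1)))),
               "singlet")
})

test_that("the tolerance box is applied to both endpoints independently", {
  g <- mk_pairs(list(list("B", 100, 200, "+", 3),
                     list("B", 120, 200, "+", 1),   # start at +20: in
                     list("B", 121, 200, "+", 1),   # start at +21: out
                     list("B", 100, 179, "+", 1),   # end at -21: out
                     list("B", 80, 220, "+", 1)))   # both at 20: in
  rec <- consensus_and_purity(g, tol_bp = 20)
  expect_identical(rec$consensus_count, 5L)
  expect_equal(rec$purity, 5 / 7)
})

test_that("the look-up table build is conservative, keyed, and idempotent", {
  set.seed(33)
  p <- mk_pairs(list(list("AAAA", 0, 50, "+", 4), list("CCCC", 10, 60, "-", 3),
                     list("TTTT", 5, 55, "+", 1)))
  tbl <- lookup_table(p)
  expect_s3_class(tbl, "lookup_table")
  expect_identical(nrow(tbl), 2L)
  expect_identical(attr(tbl, "n_singlets"), 1L)
  expect_identical(sum(tbl$total_count) + attr(tbl, "n_singlets"), nrow(p))
  # re-reducing the consensus representation changes nothing
  again <- lookup_table(data.frame(read_id = seq_len(sum(tbl$total_count)),
                                   barcode = rep(tbl$barcode, tbl$total_count),
                                   ref_id = "ref",
                                   start = rep(tbl$start, tbl$total_count),
                                   end = rep(tbl$end, tbl$total_count),
                                   strand = rep(tbl$strand, tbl$total_count)))
  expect_identical(again$barcode, tbl$barcode)
  expect_identical(again$start, tbl$start)
  expect_identical(again$total_count, tbl$total_count)
  expect_error(build_lookup_table(rbind(as.data.frame(tbl), as.data.frame(tbl))),
               "duplicate")
})

test_that("look-up tables round-trip through TSV with metadata", {
  p <- mk_pairs(list(list("AAAA", 0, 50, "+", 4), list("CCCC", 10, 60, "-", 3)))
  tbl <- lookup_table(p)
  path <- tempfile(fileext = ".tsv")
  write_lookup_table(tbl, path)
  back <- read_lookup_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl))
  expect_identical(attr(back, "tol_bp"), attr(tbl, "tol_bp"))
  unlink(c(path, paste0(path, ".meta.json")))
})

test_that("purity distribution summarises correctly", {
  p <- mk_pairs(list(list("AAAA", 0, 50, "+", 4)))
  tbl <- lookup_table(p)
  d <- purity_distribution(tbl)
  expect_identical(d$mean, 1)
  expect_identical(sum(d$histogram$count), 1L)

  mixed <- rbind(mk_pairs(list(list("AAAA", 0, 50, "+", 2))),
                 mk_pairs(list(list("CCCC", 0, 50, "+", 1), list("CCCC", 300, 350, "+", 1))))
  d2 <- purity_distribution(lookup_table(mixed))
  expect_equal(d2$mean, 0.75)
  expect_identical(nrow(d2$histogram), 101L)
  expect_error(purity_distribution(lookup_table(mixed[0, ])))
})

test_that("purity matches the brute-force oracle on simulated data", {
  b <- make_sim(n_clones = 150, chimera_rate = 0.3, mean_depth = 8, seed = 34)
  res <- run_pipeline(b$sim$reads, b$ref)
  oracle <- brute_purity(data.frame(barcode = b$sim$tags$true_barcode,
                                    start = b$sim$tags$start, end = b$sim$tags$end,
                                    strand = b$sim$tags$strand))
  expect_identical(sort(names(oracle)), sort(res$table$barcode))
  expect_equal(unname(oracle[res$table$barcode]), res$table$purity)
})

test_that("as_granges exports 1-based consensus ranges", {
  p <- mk_pairs(list(list("AAAA", 0, 50, "+", 4)))
  gr <- as_granges(lookup_table(p))
  expect_identical(GenomicRanges::start(gr), 1L)
  expect_identical(GenomicRanges::end(gr), 50L)
  expect_identical(gr$barcode, "AAAA")
})
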
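test_that("cleavage probability follows the incorporation formula", {
  expect_equal(cleavage_probability(fragmentation_config(0), "T"), 0)
  expect_equal(cleavage_probability(fragmentation_config(1), "T"), 1)
  expect_equal(cleavage_probability(fragmentation_config(0.10), "T"), 0.10)
  # reduced incorporation efficiency shifts the effective fraction
  expect_equal(cleavage_probability(fragmentation_config(0.10, incorporation_ratio = 0.5), "T"),
               0.05 / (0.05 + 0.9))
  expect_equal(cleavage_probability(fragmentation_config(0.5), c("A", "C", "G")),
               c(0, 0, 0))
  expect_error(cleavage_probability(fragmentation_config(0.5), "U"))
})

test_that("deterministic limits: no dUTP keeps the template, full dUTP cuts every T", {
  tmpl <- "ACGTACGTACGT"
  f0 <- fragment_template(tmpl, fragmentation_config(0, min_fragment_len = 0))
  expect_identical(nrow(f0), 1L)
  expect_identical(f0$sequence, tmpl)
  f1 <- fragment_template("ATATAT", fragmentation_config(1, min_fragment_len = 0))
  expect_identical(f1$sequence, c("A", "A", "A"))
  expect_identical(attr(f1, "n_cuts"), 3L)
})

test_that("fragment lengths plus excised bases conserve the template length", {
  set.seed(7)
  for (i in 1:50) {
    tmpl <- random_dna(sample(200:800, 1))
    fr <- fragment_template(tmpl, fragmentation_config(runif(1, 0.05, 0.6),
                                                       min_fragment_len = 0))
    expect_identical(sum(fr$length) + attr(fr, "n_cuts"), nchar(tmpl))
    expect_true(all(fr$start >= 0 & fr$end <= nchar(tmpl) & fr$start < fr$end))
    expect_identical(fr$sequence, substring(tmpl, fr$start + 1, fr$end))
  }
})

test_that("size cut removes short fragments only", {
  set.seed(8)
  tmpl <- random_dna(2000)
  fr <- fragment_template(tmpl, fragmentation_config(0.2, min_fragment_len = 50))
  expect_true(all(fr$length >= 50))
})

test_that("mean fragment length decreases with the dUTP fraction (paired seeds)", {
  tmpl <- random_dna(3000)
  means <- vapply(c(0.02, 0.05, 0.1, 0.2, 0.4), function(p) {
    fr <- fragment_template(tmpl, fragmentation_config(p, min_fragment_len = 0),
                            seed = 42)
    mean(fr$length)
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("simulated mean fragment length matches the analytic expectation", {
  set.seed(12)
  tmpl <- random_dna(1500)
  cfg <- fragmentation_config(0.1, min_fragment_len = 0)
  reps <- replicate(2000, {
    fr <- fragment_template(tmpl, cfg, with_sequence = FALSE)
    c(total = sum(fr$length), n = nrow(fr))
  })
  pooled <- sum(reps["total", ]) / sum(reps["n", ])
  theo <- expected_mean_fragment_length(tmpl, cfg)
  # ratio-estimator standard error over replicates
  resid <- reps["total", ] - pooled * reps["n", ]
  se <- sqrt(sum(resid^2) / (ncol(reps) - 1) / ncol(reps)) / mean(reps["n", ])
  expect_lt(abs(pooled - theo), 3 * se + 1e-9)
})

test_that("aggregate coverage is uniform over a composition-balanced template", {
  # periodic template: every 8 bp window has identical base (and T) content,
  # so binned coverage is uniform in expectation and the chi-square applies
  tmpl <- strrep("ACGTTGCA", 50)
  set.seed(9)
  L <- nchar(tmpl)
  cov <- integer(L)
  for (r in 1:200) {
    fr <- fragment_template(tmpl, fragmentation_config(0.1, min_fragment_len = 0),
                            with_sequence = FALSE)
    for (i in seq_len(nrow(fr))) {
      cov[(fr$start[i] + 1):fr$end[i]] <- cov[(fr$start[i] + 1):fr$end[i]] + 1L
    }
  }
  bins <- colSums(matrix(cov, nrow = 8))
  p <- suppressWarnings(stats::chisq.test(bins)$p.value)
  expect_gt(p, 0.01)
})

test_that("length distributions respond to the dUTP gradient and are self-consistent", {
  tmpl <- random_dna(1200)
  d0 <- predicted_length_distribution(tmpl, fragmentation_config(0, min_fragment_len = 0),
                                      n_reps = 5, seed = 1)
  expect_identical(unique(d0$lengths), nchar(tmpl))
  lo <- predicted_length_distribution(tmpl, fragmentation_config(0.10, min_fragment_len = 0),
                                      n_reps = 300, seed = 2)
  hi <- predicted_length_distribution(tmpl, fragmentation_config(0.30, min_fragment_len = 0),
                                      n_reps = 300, seed = 3)
  # stochastic dominance: higher dUTP gives smaller fragments
  grid <- seq(0, nchar(tmpl), by = 10)
  cdf_lo <- ecdf(lo$lengths)(grid); cdf_hi <- ecdf(hi$lengths)(grid)
  expect_true(all(cdf_hi >= cdf_lo - 0.02))
  expect_gt(mean(lo$lengths), mean(hi$lengths))
  # two seeds, same configuration: indistinguishable by two-sample KS
  a <- predicted_length_distribution(tmpl, fragmentation_config(0.10, min_fragment_len = 0),
                                     n_reps = 2000, seed = 4)
  b <- predicted_length_distribution(tmpl, fragmentation_config(0.10, min_fragment_len = 0),
                                     n_reps = 2000, seed = 5)
  ks <- suppressWarnings(stats::ks.test(a$lengths, b$lengths))
  expect_gt(ks$p.value, 0.01)
})
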
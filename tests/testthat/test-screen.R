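test_that("reporter normalization is a guarded log2 ratio", {
  expect_equal(normalize_reporter(100, 100), 0)
  expect_equal(normalize_reporter(200, 100), 1)
  expect_equal(normalize_reporter(0, 100), -Inf)
  expect_error(normalize_reporter(100, 0), "invalid well")
  expect_error(normalize_reporter(-1, 100), "invalid well")
})

test_that("robust z-scores follow the MAD formula and its invariances", {
  expect_equal(robust_zscore(c(1, 2, 3)),
               c(-0.6745, 0, 0.6745), tolerance = 1e-3)
  expect_error(robust_zscore(c(2, 2, 2)), "degenerate")
  expect_error(robust_zscore(c(1, 2)), "at least 3")

  set.seed(11)
  x <- rnorm(51)
  z <- robust_zscore(x)
  # symmetric/median-centered output
  expect_equal(median(z), 0)
  # shift invariance and positive-scale equivariance
  expect_equal(robust_zscore(x + 5), z)
  expect_equal(robust_zscore(3 * x), z)
})

test_that("median centering subtracts the per-miRNA analog baseline", {
  analog <- matrix(c(0.5, 0.7, 0.9), 1, dimnames = list("a", NULL))
  expect_equal(unname(median_center(c(a = -1), analog)), -1.7)

  zero_base <- matrix(0, 2, 3, dimnames = list(c("a", "b"), NULL))
  fz <- c(a = -2, b = 1.5)
  expect_equal(median_center(fz, zero_base), fz)

  all_missing <- matrix(NA_real_, 1, 3, dimnames = list("a", NULL))
  expect_warning(res <- median_center(c(a = -1, b = 2),
                                      rbind(all_missing,
                                            matrix(0, 1, 3, dimnames = list("b", NULL)))),
                 "excluded")
  expect_equal(names(res), "b")

  # any per-miRNA bias shared by focal and analog screens cancels
  set.seed(21)
  base <- matrix(rnorm(15), 3, dimnames = list(c("a", "b", "c"), NULL))
  fz <- c(a = -1, b = 0, c = 2)
  bias <- c(a = 3, b = -1, c = 0.5)
  expect_equal(median_center(fz + bias, base + bias),
               median_center(fz, base))
})

test_that("replicate combination averages available scores and flags gaps", {
  tab <- combine_replicates(list(c(a = -2, b = 0), c(a = -1, b = 1)))
  expect_equal(tab$score_avg[tab$mirna_id == "a"], -1.5)
  expect_true(all(tab$complete))

  single <- combine_replicates(list(c(a = -2)))
  expect_equal(single$score_avg, -2)

  partial <- combine_replicates(list(c(a = -2, b = 0), c(a = -1)))
  expect_equal(partial$n_replicates[partial$mirna_id == "b"], 1)
  expect_false(partial$complete[partial$mirna_id == "b"])
  expect_equal(partial$score_avg[partial$mirna_id == "b"], 0)

  expect_error(combine_replicates(list()), "at least one")
})

test_that("ROC cutoff maximizes accuracy with the specificity tie-break", {
  roc <- determine_cutoff(c(-3, -2.5, -0.5), c(-1, 0, 1, 2))
  expect_equal(roc$cutoff, -1.75)
  expect_equal(roc$accuracy, 6 / 7)
  expect_equal(roc$sensitivity, 2 / 3)
  expect_equal(roc$specificity, 1)

  sep <- determine_cutoff(c(-5, -4), c(0, 1))
  expect_equal(sep$accuracy, 1)

  same <- determine_cutoff(c(-1, 0, 2), c(-1, 0, 2))
  expect_lte(same$accuracy, 0.5)

  expect_error(determine_cutoff(numeric(), c(1)), "non-empty")
})

test_that("chosen cutoff accuracy equals the exhaustive-enumeration optimum", {
  set.seed(31)
  for (i in 1:25) {
    pos <- rnorm(sample(2:8, 1), mean = -2)
    neg <- rnorm(sample(2:8, 1), mean = 0)
    roc <- determine_cutoff(pos, neg)
    expect_equal(roc$accuracy, oracle_best_accuracy(pos, neg))
  }
})

test_that("hit calls use a strict less-than threshold on the average score", {
  tab <- data.frame(mirna_id = c("a", "b", "c"),
                    score_avg = c(-2.0, -1.94, -1.0),
                    stringsAsFactors = FALSE)
  called <- call_hits(tab, -1.94)
  expect_equal(called$mirna_id[called$hit], "a") # exact cutoff is not a hit
  empty <- call_hits(tab[0, ], -1.94)
  expect_equal(sum(empty$hit), 0)
  expect_error(call_hits(tab, Inf), "finite")
})

test_that("screen scoring pipeline recovers planted effects under bias", {
  # bias inflates the per-screen robust-z scale too, so keep it moderate
  # relative to the planted effect
  cfg <- screen_sim_config(n_mirnas = 60, n_targeting = 8, effect_log2 = -3,
                           noise_sd = 0.2, bias_sd = 0.5,
                           n_analog_screens = 12, seed = 7)
  sim <- simulate_screen(cfg)
  scored <- call_hits(score_screen(sim$plates), -1.94)
  expect_setequal(scored$mirna_id[scored$hit],
                  sim$truth$mirna_id[sim$truth$targeting])
})
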
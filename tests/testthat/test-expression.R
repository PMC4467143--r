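test_that("perfect anticorrelation yields an inverse call with pi < 0", {
  set.seed(81)
  mycn <- rnorm(20)
  mat <- rbind(anti = -mycn, noise = rnorm(20))
  res <- correlate_to_mycn(mat, mycn)
  anti <- res[res$mirna_id == "anti", ]
  expect_equal(anti$coefficient, -1)
  expect_equal(anti$call, "inverse")
  expect_lt(anti$pi_value, 0)
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))
})

test_that("constant miRNA rows are flagged not-testable", {
  set.seed(82)
  mycn <- rnorm(10)
  mat <- rbind(flat = rep(1, 10), ok = rnorm(10))
  res <- correlate_to_mycn(mat, mycn)
  expect_equal(res$call[res$mirna_id == "flat"], "not-testable")
  expect_true(is.na(res$pi_value[res$mirna_id == "flat"]))
})

test_that("null cohorts produce inverse calls at about the BH false-positive rate", {
  # no planted coupling: expected fraction of q<=0.05 calls stays near zero
  n_calls <- vapply(1:20, function(s) {
    sim <- simulate_cohort(cohort_sim_config(n_samples = 40, n_mirnas = 50,
                                             n_genes = 10, seed = 100 + s))
    res <- correlate_to_mycn(sim$mirna, sim$mrna["MYCN", ])
    sum(res$call != "n.s.")
  }, numeric(1))
  expect_lt(mean(n_calls / 50), 0.05)
})

test_that("gene ranking is deterministic, tie-stable and rank-invariant", {
  samples <- 10
  set.seed(83)
  mir <- rnorm(samples)
  mat <- rbind(
    g1 = rank(mir),        # Spearman +1
    g3 = -rank(mir),       # Spearman -1
    g2 = rep(1, samples)   # constant -> 0, flagged
  )
  ranked <- rank_genes_for_mirna(mir, mat)
  expect_equal(ranked$gene_id, c("g1", "g2", "g3"))
  expect_true(ranked$constant[ranked$gene_id == "g2"])

  # ties at 0 broken lexicographically
  mat2 <- rbind(zz = rep(1, samples), aa = rep(2, samples))
  r2 <- rank_genes_for_mirna(mir, mat2)
  expect_equal(r2$gene_id, c("aa", "zz"))

  # invariance to monotone transforms of the miRNA vector
  set.seed(84)
  mat3 <- matrix(rnorm(5 * samples), 5,
                 dimnames = list(paste0("g", 1:5), NULL))
  r_raw <- rank_genes_for_mirna(mir, mat3)
  r_exp <- rank_genes_for_mirna(exp(3 * mir), mat3)
  expect_equal(r_raw, r_exp)
})

test_that("relevance classification covers all final categories", {
  hits <- c("h1", "h2", "h3", "h4", "h5")
  expr <- data.frame(
    mirna_id = c("h1", "h2", "h3", "h4"),
    call = c("inverse", "n.s.", "inverse", "positive"),
    stringsAsFactors = FALSE
  )
  act <- data.frame(
    mirna_id = c("h1", "h2", "h3", "h4"),
    activity_call = c("none", "none", "positive", "none"),
    stringsAsFactors = FALSE
  )
  rel <- classify_relevance(hits, expr, act)
  expect_equal(rel$final[rel$mirna_id == "h1"], "NB-relevant MYCN-targeting")
  expect_equal(rel$final[rel$mirna_id == "h2"], "not-supported")
  expect_equal(rel$final[rel$mirna_id == "h3"], "conflicting-excluded")
  expect_equal(rel$final[rel$mirna_id == "h4"], "MYCN-induced")
  expect_equal(rel$final[rel$mirna_id == "h5"], "no-data")
  # pure function: identical inputs give identical calls
  expect_identical(rel, classify_relevance(hits, expr, act))
  # the finals partition the hits
  expect_equal(nrow(rel), length(hits))
})

test_that("planted inverse coupling is recovered and shifts pi-values", {
  planted <- sprintf("miR-%03d", 1:10)
  sim <- simulate_cohort(cohort_sim_config(
    n_samples = 80, n_mirnas = 60, n_genes = 10,
    planted_inverse = planted, coupling_r = 0.6, seed = 85
  ))
  res <- correlate_to_mycn(sim$mirna, sim$mrna["MYCN", ])
  called <- res$mirna_id[res$call == "inverse"]
  expect_gte(mean(planted %in% called), 0.9)
  ks <- ks_two_sample(res$pi_value[res$mirna_id %in% planted],
                      res$pi_value[!res$mirna_id %in% planted])
  expect_lt(ks$p_value, 0.01)
})

test_that("activity calls recover planted coupling through GSEA", {
  planted <- c("miR-001", "miR-002")
  sim <- simulate_cohort(cohort_sim_config(
    n_samples = 60, n_mirnas = 4, n_genes = 400,
    planted_inverse = planted, coupling_r = 0.8,
    activity_gene_fraction = 0.1, seed = 86
  ))
  sets <- list(ACTIVITY_UP = sim$truth$activity_genes)
  act <- activity_calls(sim$mirna, sim$mrna, sets,
                        n_permutations = 200, seed = 3)
  calls <- setNames(act$calls$activity_call, act$calls$mirna_id)
  expect_true(all(calls[planted] == "negative"))
  expect_true(all(calls[setdiff(names(calls), planted)] == "none"))
})
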
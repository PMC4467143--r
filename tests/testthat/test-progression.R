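test_that("Cq preprocessing filters at the detection cutoff and centers samples", {
  cq <- matrix(c(20, 30,
                 33, 25,
                 24, 26), nrow = 3, byrow = TRUE,
               dimnames = list(c("m1", "m2", "m3"), c("s1", "s2")))
  norm <- preprocess_cq(cq)
  expect_true(is.na(norm["m2", "s1"])) # Cq 33 >= 32 is filtered, not zeroed
  expect_equal(unname(norm[, "s1"]), c(2, NA, -2)) # mean of retained = 22
  expect_equal(unname(norm[, "s2"]), c(-3, 2, 1)) # mean 27

  # a two-value sample: [20, 30] -> [+5, -5]
  one <- matrix(c(20, 30), 2, 1, dimnames = list(c("a", "b"), "s"))
  expect_equal(unname(preprocess_cq(one)[, 1]), c(5, -5))

  # per-sample mean of retained normalized values is exactly zero
  set.seed(91)
  big <- matrix(rnorm(200, 28, 3), 20, 10,
                dimnames = list(paste0("m", 1:20), paste0("s", 1:10)))
  normed <- preprocess_cq(big)
  expect_equal(unname(colMeans(normed, na.rm = TRUE)), rep(0, 10))

  # samples with < 2 retained values are dropped with a warning
  bad <- matrix(c(33, 33, 20, 25, 21, 26), 2,
                dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_warning(res <- preprocess_cq(bad), "dropping 1 sample")
  expect_equal(colnames(res), c("s2", "s3"))
})

test_that("genotype-by-time regression recovers planted coefficients exactly", {
  ann <- expand.grid(replicate = 1:4, time_weeks = c(1, 2, 6),
                     genotype = c("TG", "WT"), stringsAsFactors = FALSE)
  ann$sample_id <- sprintf("%s_w%g_r%d", ann$genotype, ann$time_weeks,
                           ann$replicate)
  expr <- matrix(NA_real_, 2, nrow(ann),
                 dimnames = list(c("planted", "flat"), ann$sample_id))
  expr["planted", ] <- ifelse(ann$genotype == "TG", -1, 0) * ann$time_weeks
  expr["flat", ] <- 0.5 # degenerate but testable shape via noise below
  expr["flat", ] <- rep(c(0.4, 0.6), length.out = nrow(ann))

  prog <- suppressWarnings(fit_genotype_time_regression(expr, ann))
  p <- prog[prog$mirna_id == "planted", ]
  expect_equal(p$delta_slope, -1)
  expect_equal(p$slope_tg, -1)
  expect_equal(p$slope_wt, 0)
  expect_equal(p$call, "down")
  expect_lt(p$pi_value, 0)

  # identical TG and WT data: delta-slope and pi are (near) zero
  expr2 <- matrix(rep(ann$time_weeks * 0.3 + rep(c(-0.1, 0.1), 12), each = 1),
                  1, nrow(ann), dimnames = list("same", ann$sample_id))
  prog2 <- fit_genotype_time_regression(expr2, ann)
  expect_equal(prog2$delta_slope, 0, tolerance = 1e-10)
  expect_equal(prog2$pi_value, 0, tolerance = 1e-8)

  # one genotype missing -> not-testable
  tg_only <- ann$sample_id[ann$genotype == "TG"]
  prog3 <- fit_genotype_time_regression(expr[, tg_only, drop = FALSE],
                                        ann[ann$genotype == "TG", ])
  expect_equal(unique(prog3$call), "not-testable")
})

test_that("pi-value sign equals the delta-slope sign across noisy fits", {
  sim <- simulate_timecourse(timecourse_sim_config(
    planted_slopes = list(`miR-001` = c(TG = -0.8, WT = 0),
                          `miR-002` = c(TG = 0.8, WT = 0)),
    mirna_ids = sprintf("miR-%03d", 1:30), cq_noise_sd = 0.25, seed = 92
  ))
  prog <- fit_genotype_time_regression(preprocess_cq(sim$cq), sim$annotations)
  ok <- is.finite(prog$pi_value) & prog$p_value < 1 & prog$delta_slope != 0
  expect_true(all(sign(prog$pi_value[ok]) == sign(prog$delta_slope[ok])))
})

test_that("signature score averages direction-signed z-scores", {
  set.seed(93)
  expr <- matrix(rnorm(40), 4, 10,
                 dimnames = list(paste0("m", 1:4), paste0("s", 1:10)))
  sig <- data.frame(mirna_id = c("m1", "m2", "absent"),
                    direction = c(1, -1, 1), stringsAsFactors = FALSE)
  sc <- signature_score(expr, sig)
  expect_equal(nrow(sc), 10)
  expect_equal(attr(sc, "coverage"), 2 / 3)
  manual <- (scale(expr["m1", ])[, 1] - scale(expr["m2", ])[, 1]) / 2
  expect_equal(sc$score, unname(manual))

  # single member at the matrix mean scores zero
  one <- signature_score(expr, data.frame(mirna_id = "m1", direction = 1))
  at_mean <- which.min(abs(expr["m1", ] - mean(expr["m1", ])))
  expect_equal(one$score[at_mean],
               (expr["m1", at_mean] - mean(expr["m1", ])) / sd(expr["m1", ]))

  # constant members are skipped; zero overlap errors
  flat <- matrix(1, 1, 10, dimnames = list("m1", paste0("s", 1:10)))
  expect_error(signature_score(flat, data.frame(mirna_id = "m1", direction = 1)),
               "no usable")
  expect_error(signature_score(expr, sig[0, ]), "empty signature")
})

test_that("a planted upward drift produces a monotone signature trajectory", {
  cfg <- timecourse_sim_config(
    planted_slopes = list(`miR-001` = c(TG = 1, WT = 0),
                          `miR-002` = c(TG = 0.8, WT = 0)),
    mirna_ids = sprintf("miR-%03d", 1:10), cq_noise_sd = 0, seed = 94
  )
  sim <- simulate_timecourse(cfg)
  sc <- signature_score(preprocess_cq(sim$cq),
                        data.frame(mirna_id = c("miR-001", "miR-002"),
                                   direction = c(1, 1)))
  ann <- sim$annotations
  tg_means <- tapply(sc$score[ann$genotype == "TG"],
                     ann$time_weeks[ann$genotype == "TG"], mean)
  expect_true(all(diff(tg_means[order(as.numeric(names(tg_means)))]) > 0))
})

test_that("differential expression: symmetry, guards and power", {
  set.seed(95)
  a <- matrix(rnorm(20), 2, 10, dimnames = list(c("m1", "m2"), paste0("a", 1:10)))
  b <- a + 0 # identical groups with internal variance
  colnames(b) <- paste0("b", 1:10)
  mat <- cbind(a, b)
  de <- differential_expression(mat, colnames(a), colnames(b))
  expect_equal(de$log2_fc, c(0, 0))
  expect_equal(de$p_value, c(1, 1))

  # zero-variance groups with a planted offset: FC reported, p not testable
  flat <- matrix(rep(c(1, 2), each = 4), 1, 8,
                 dimnames = list("m", paste0("s", 1:8)))
  de_flat <- differential_expression(flat, paste0("s", 5:8), paste0("s", 1:4))
  expect_equal(de_flat$log2_fc, 1)
  expect_equal(de_flat$call, "not-testable")

  # antisymmetric FC, invariant p under group swap
  set.seed(96)
  m <- matrix(rnorm(60), 3, 20,
              dimnames = list(paste0("m", 1:3), paste0("s", 1:20)))
  ga <- paste0("s", 1:10); gb <- paste0("s", 11:20)
  d1 <- differential_expression(m, ga, gb)
  d2 <- differential_expression(m, gb, ga)
  expect_equal(d1$log2_fc, -d2$log2_fc)
  expect_equal(d1$p_value, d2$p_value)

  # power: planted FC -1 at noise 0.3, n = 5 vs 5, 20 planted of 100
  set.seed(97)
  n_mirnas <- 100
  planted <- paste0("m", 1:20)
  grp_a <- matrix(rnorm(n_mirnas * 5, 0, 0.3), n_mirnas, 5)
  grp_b <- matrix(rnorm(n_mirnas * 5, 0, 0.3), n_mirnas, 5)
  grp_a[1:20, ] <- grp_a[1:20, ] - 1
  mat <- cbind(grp_a, grp_b)
  dimnames(mat) <- list(paste0("m", 1:n_mirnas), paste0("s", 1:10))
  de <- differential_expression(mat, paste0("s", 1:5), paste0("s", 6:10))
  called_down <- de$mirna_id[de$call == "down"]
  expect_gte(mean(planted %in% called_down), 0.8)
})

test_that("targeting-vs-others dynamics comparison flags a planted shift", {
  set.seed(98)
  prog <- data.frame(
    mirna_id = paste0("m", 1:162),
    pi_value = c(rnorm(12, -1.5, 0.5), rnorm(150, 0, 0.5)),
    stringsAsFactors = FALSE
  )
  ks <- compare_target_vs_nontarget_dynamics(prog, paste0("m", 1:12))
  expect_lt(ks$p_value, 0.05)
  expect_error(compare_target_vs_nontarget_dynamics(prog, "m1"), "at least 2")
})

test_that("cross-species mapping renames and restricts assay rows", {
  expr <- matrix(rnorm(20), 4, 5,
                 dimnames = list(c("mmu-a1", "mmu-a2", "mmu-a3", "unmapped"),
                                 paste0("s", 1:5)))
  mapping <- data.frame(assay_id = c("mmu-a1", "mmu-a2", "mmu-a3"),
                        human_id = c("miR-001", "miR-002", "miR-003"),
                        stringsAsFactors = FALSE)
  mapped <- apply_mirna_mapping(expr, mapping)
  expect_equal(rownames(mapped), c("miR-001", "miR-002", "miR-003"))
  expect_equal(unname(mapped["miR-002", ]), unname(expr["mmu-a2", ]))
  dup <- rbind(mapping, data.frame(assay_id = "unmapped", human_id = "miR-001"))
  expect_error(apply_mirna_mapping(expr, dup), "several assays")

  # shipped synthetic fixtures parse and are usable
  map_fix <- read.delim(system.file("extdata",
                                    "murine_human_mapping_synthetic.tsv",
                                    package = "mirmycn"))
  expect_equal(names(map_fix), c("assay_id", "human_id"))
  sig_fix <- read.delim(system.file("extdata",
                                    "mycn_mirna_signature_synthetic.tsv",
                                    package = "mirmycn"))
  expect_equal(nrow(sig_fix), 50)
  expect_true(all(sig_fix$direction %in% c(-1, 1)))
})
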
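# Independent reference implementations used as oracles. They are written
# deliberately in plain-loop style, separate from the package's vectorized
# code paths.

# Brute-force preranked GSEA: explicit running-sum loop, same null-draw order
# (set.seed(seed), then sample.int(N, Nh) per permutation).
oracle_gsea <- function(statistics, gene_set, n_permutations, seed) {
  ord <- order(-statistics, names(statistics), method = "radix")
  s <- statistics[ord]
  genes <- names(s)
  n <- length(s)

  es_loop <- function(member) {
    nh <- sum(member)
    nr <- sum(abs(s[member]))
    run <- 0
    hi <- -Inf
    lo <- Inf
    for (i in seq_len(n)) {
      if (member[i]) {
        run <- run + if (nr > 0) abs(s[i]) / nr else 1 / nh
      } else {
        run <- run - 1 / (n - nh)
      }
      if (run > hi) hi <- run
      if (run < lo) lo <- run
    }
    # magnitude ties (within 1e-12) resolve to the negative extremum
    unname(if (hi + lo > 1e-12) hi else lo)
  }

  member <- genes %in% gene_set
  es <- es_loop(member)
  nh <- sum(member)

  set.seed(seed)
  null_es <- numeric(n_permutations)
  for (k in seq_len(n_permutations)) {
    idx <- sample.int(n, nh)
    m <- rep(FALSE, n)
    m[idx] <- TRUE
    null_es[k] <- es_loop(m)
  }
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
  list(es = es, nes = nes, null_es = null_es)
}

# Exhaustive best accuracy over all candidate cutoffs (midpoints + sentinels),
# scanning with a plain loop.
oracle_best_accuracy <- function(pos, neg) {
  pooled <- sort(unique(c(pos, neg)))
  cand <- c(pooled[1] - 1, pooled[length(pooled)] + 1)
  if (length(pooled) > 1) {
    for (i in seq_len(length(pooled) - 1)) {
      cand <- c(cand, (pooled[i] + pooled[i + 1]) / 2)
    }
  }
  best <- -Inf
  for (c in cand) {
    acc <- (sum(pos < c) + sum(neg >= c)) / (length(pos) + length(neg))
    if (acc > best) best <- acc
  }
  best
}

# Small deterministic interaction-score table for seed-class tests.
make_class_scores <- function(n_per_class, shift_8mer = 0, noise_sd = 0.3,
                              seed = 1) {
  set.seed(seed)
  classes <- rep(c("none", "6mer", "7mer", "8mer"), each = n_per_class)
  ids <- sprintf("miR-%03d", seq_along(classes))
  scores <- rnorm(length(classes), 0, noise_sd) +
    ifelse(classes == "8mer", shift_8mer, 0)
  list(
    score_table = data.frame(mirna_id = ids, score_avg = scores,
                             stringsAsFactors = FALSE),
    seed_classes = data.frame(mirna_id = ids, seed_class = classes,
                              stringsAsFactors = FALSE)
  )
}
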
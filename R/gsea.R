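# Preranked gene-set enrichment analysis with a gene-permutation null:
# weighted Kolmogorov-Smirnov-like running-sum enrichment score, sign-matched
# NES normalization, and the pooled-null FDR convention.

#' Order a ranking statistic for GSEA
#'
#' Sorts decreasingly by statistic with ties broken by gene id (lexicographic),
#' so the ranking is fully deterministic.
#'
#' @param statistics Named numeric vector (gene -> ranking statistic).
#' @return The same vector, sorted.
#' @export
order_ranked_list <- function(statistics) {
  if (is.null(names(statistics)) || anyDuplicated(names(statistics))) {
    stop("`statistics` must be named with unique gene ids")
  }
  statistics[order(-statistics, names(statistics), method = "radix")]
}

# Weighted running-sum enrichment score on an already-sorted statistic.
# In-set positions increment by |s|^1 normalized over in-set genes; out-of-set
# positions decrement by 1 / (N - Nh). ES is the running-sum extremum of
# largest magnitude; when the positive and negative extrema tie in magnitude
# (within 1e-12) the negative one is taken, so the rule is stable under
# floating-point accumulation order.
running_sum_es <- function(sorted_stats, in_set) {
  n <- length(sorted_stats)
  nh <- sum(in_set)
  if (nh == 0L) stop("gene set does not intersect the ranked list")
  if (nh == n) stop("gene set covers the whole ranked list")
  w <- abs(sorted_stats[in_set])
  total <- sum(w)
  steps <- numeric(n)
  steps[in_set] <- if (total > 0) w / total else 1 / nh
  steps[!in_set] <- -1 / (n - nh)
  running <- cumsum(steps)
  mx <- max(running)
  mn <- min(running)
  if (mx + mn > 1e-12) mx else mn
}

#' Preranked GSEA for a single gene set
#'
#' Computes the weighted running-sum enrichment score (weight exponent 1) of
#' `gene_set` on the ranked list, builds a null distribution from
#' `n_permutations` random gene sets of the same size (drawn with
#' `sample.int` after `set.seed(seed)`), and normalizes the ES by the mean
#' magnitude of same-sign null scores.
#'
#' @param statistics Named numeric vector of ranking statistics (e.g. per-gene
#'   Spearman correlation with a miRNA). Sorted internally via
#'   [order_ranked_list()].
#' @param gene_set Character vector of member gene ids; must intersect the
#'   ranked list and not cover it entirely.
#' @param n_permutations Number of random gene-set draws (>= 100).
#' @param seed Integer seed for the null draws.
#' @return A list of class `"mirmycn_gsea"`: `es`, `nes`, `p_nominal`,
#'   `n_genes`, `set_size`, `n_permutations`, `seed`, and `null_es` (the raw
#'   null enrichment scores, used by [gsea_collection()] for pooled FDR).
#' @export
gsea_preranked <- function(statistics, gene_set, n_permutations = 1000,
                           seed = 1) {
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  ranked <- order_ranked_list(statistics)
  genes <- names(ranked)
  in_set <- genes %in% gene_set
  es <- running_sum_es(ranked, in_set)
  nh <- sum(in_set)
  n <- length(ranked)

  null_es <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      idx <- sample.int(n, nh)
      member <- logical(n)
      member[idx] <- TRUE
      running_sum_es(ranked, member)
    }, numeric(1))
  })

  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same_sign) > 0L) es / mean(abs(same_sign)) else NA_real_
  p_nominal <- if (length(same_sign) > 0L) {
    mean(abs(same_sign) >= abs(es))
  } else {
    NA_real_
  }

  structure(
    list(es = es, nes = nes, p_nominal = p_nominal,
         n_genes = n, set_size = nh,
         n_permutations = n_permutations, seed = seed, null_es = null_es),
    class = "mirmycn_gsea"
  )
}

#' @export
print.mirmycn_gsea <- function(x, ...) {
  cat(sprintf(
    "Preranked GSEA: ES = %.4f, NES = %.4f, nominal p = %.4g (set %d/%d genes, %d permutations)\n",
    x$es, x$nes, x$p_nominal, x$set_size, x$n_genes, x$n_permutations
  ))
  invisible(x)
}

#' Preranked GSEA over a collection of gene sets, with pooled-null FDR
#'
#' Runs [gsea_preranked()] for every set (per-set seed = `seed + index - 1`),
#' then computes the false discovery rate with the matched-sign pooled-null
#' convention: null enrichment scores of each set are normalized to null NES
#' the same way as the observed ES, pooled across sets, and for each observed
#' NES the FDR is the ratio of the null tail fraction to the observed tail
#' fraction on the matching side, capped at 1.
#'
#' @inheritParams gsea_preranked
#' @param gene_sets Named list of gene-id vectors.
#' @return Data frame: `gene_set`, `es`, `nes`, `p_nominal`, `fdr`,
#'   `set_size`, `n_permutations`, `seed`.
#' @export
gsea_collection <- function(statistics, gene_sets, n_permutations = 1000,
                            seed = 1) {
  if (length(gene_sets) == 0L) stop("`gene_sets` is empty")
  if (is.null(names(gene_sets))) stop("`gene_sets` must be named")
  runs <- lapply(seq_along(gene_sets), function(i) {
    gsea_preranked(statistics, gene_sets[[i]], n_permutations,
                   seed = seed + i - 1L)
  })
  obs_nes <- vapply(runs, `[[`, numeric(1), "nes")
  null_nes <- unlist(lapply(runs, function(r) {
    pos <- r$null_es[r$null_es >= 0]
    neg <- r$null_es[r$null_es < 0]
    c(
      if (length(pos) > 0L) pos / mean(pos) else numeric(),
      if (length(neg) > 0L) neg / mean(abs(neg)) else numeric()
    )
  }))
  fdr <- vapply(obs_nes, function(nes) {
    if (!is.finite(nes)) return(NA_real_)
    if (nes >= 0) {
      num_pool <- null_nes[null_nes >= 0]
      num <- if (length(num_pool)) mean(num_pool >= nes) else NA_real_
      obs_side <- obs_nes[is.finite(obs_nes) & obs_nes >= 0]
      den <- if (length(obs_side)) mean(obs_side >= nes) else NA_real_
    } else {
      num_pool <- null_nes[null_nes < 0]
      num <- if (length(num_pool)) mean(num_pool <= nes) else NA_real_
      obs_side <- obs_nes[is.finite(obs_nes) & obs_nes < 0]
      den <- if (length(obs_side)) mean(obs_side <= nes) else NA_real_
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  data.frame(
    gene_set = names(gene_sets),
    es = vapply(runs, `[[`, numeric(1), "es"),
    nes = obs_nes,
    p_nominal = vapply(runs, `[[`, numeric(1), "p_nominal"),
    fdr = fdr,
    set_size = vapply(runs, `[[`, numeric(1), "set_size"),
    n_permutations = n_permutations,
    seed = seed,
    stringsAsFactors = FALSE
  )
}
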
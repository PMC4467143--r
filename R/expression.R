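# Expression integration: per-miRNA correlation to MYCN mRNA, per-miRNA
# ranked gene lists and GSEA-based MYCN-activity calls, and the final
# relevance classification of screen hits.

#' Correlate miRNA expression with MYCN mRNA expression
#'
#' Per miRNA: correlation coefficient and two-sided p against the MYCN
#' expression vector, Benjamini-Hochberg adjustment across all testable
#' miRNAs, the signed-significance pi-value, and a call: `inverse` when
#' q <= 0.05 and the coefficient is negative, `positive` when q <= 0.05 and
#' positive, otherwise `n.s.`. Constant miRNA rows are flagged
#' `not-testable`.
#'
#' @param mirna_matrix miRNA x sample numeric matrix.
#' @param mycn Numeric vector of MYCN expression, one value per sample (same
#'   column order).
#' @param method `"spearman"` (default, used for significance calls) or
#'   `"pearson"`.
#' @param q_threshold Significance level on the adjusted p (default 0.05).
#' @return Data frame of `CorrelationRecord`s: `mirna_id`, `method`,
#'   `coefficient`, `p_value`, `q_value`, `pi_value`, `call`.
#' @export
correlate_to_mycn <- function(mirna_matrix, mycn,
                              method = c("spearman", "pearson"),
                              q_threshold = 0.05) {
  method <- match.arg(method)
  mirna_matrix <- as.matrix(mirna_matrix)
  if (ncol(mirna_matrix) != length(mycn)) {
    stop("`mycn` length must equal the number of samples")
  }
  if (length(mycn) < 4L) stop("need at least 4 samples")
  if (is.null(rownames(mirna_matrix))) stop("`mirna_matrix` must have rownames")

  res <- lapply(seq_len(nrow(mirna_matrix)), function(i) {
    x <- mirna_matrix[i, ]
    ok <- is.finite(x) & is.finite(mycn)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0 || stats::sd(mycn[ok]) == 0) {
      return(c(coefficient = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], mycn[ok], method = method, exact = FALSE)
    )
    c(coefficient = unname(ct$estimate), p_value = ct$p.value)
  })
  res <- do.call(rbind, res)
  q <- bh_adjust(res[, "p_value"])
  testable <- is.finite(res[, "p_value"])
  call <- rep("not-testable", nrow(res))
  call[testable] <- ifelse(
    q[testable] <= q_threshold,
    ifelse(res[testable, "coefficient"] < 0, "inverse", "positive"),
    "n.s."
  )
  data.frame(
    mirna_id = rownames(mirna_matrix),
    method = method,
    coefficient = res[, "coefficient"],
    p_value = res[, "p_value"],
    q_value = q,
    pi_value = ifelse(testable,
                      pi_value(res[, "p_value"], res[, "coefficient"]),
                      NA_real_),
    call = call,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Rank genes by correlation with a miRNA
#'
#' Genes are sorted by decreasing correlation coefficient with the miRNA
#' expression vector; ties (including constant genes, which get coefficient 0
#' and a flag) are broken by gene id in lexicographic order so that the
#' ranking is deterministic.
#'
#' @param mirna_vector Numeric expression of one miRNA across samples.
#' @param mrna_matrix Gene x sample numeric matrix with rownames.
#' @param method Correlation method, default `"spearman"`.
#' @return Data frame `gene_id`, `statistic`, `constant` (flag), sorted; the
#'   `statistic` column (named by gene) is the GSEA input.
#' @export
rank_genes_for_mirna <- function(mirna_vector, mrna_matrix,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  mrna_matrix <- as.matrix(mrna_matrix)
  if (ncol(mrna_matrix) != length(mirna_vector)) {
    stop("sample count mismatch between miRNA vector and mRNA matrix")
  }
  if (length(mirna_vector) < 4L) stop("need at least 4 samples")
  coefs <- suppressWarnings(
    stats::cor(t(mrna_matrix), mirna_vector, method = method)[, 1L]
  )
  constant <- !is.finite(coefs)
  coefs[constant] <- 0
  ord <- order(-coefs, rownames(mrna_matrix), method = "radix")
  data.frame(
    gene_id = rownames(mrna_matrix)[ord],
    statistic = unname(coefs[ord]),
    constant = unname(constant[ord]),
    stringsAsFactors = FALSE
  )
}

#' Classify a miRNA's relation to MYCN activity from GSEA results
#'
#' A miRNA is negatively related to MYCN activity when at least one
#' MYC(N)-up gene set is significantly negatively enriched (NES < -2 and
#' FDR < 0.25) in its correlation-ranked gene list; the positive call mirrors
#' the rule (NES > +2, FDR < 0.25) and applies only when no set qualifies
#' negative. If both directions qualify the call is negative with an
#' `ambiguous` flag.
#'
#' @param gsea_results Data frame from [gsea_collection()] (columns `nes`,
#'   `fdr`).
#' @param nes_threshold Magnitude threshold on NES (default 2).
#' @param fdr_threshold FDR threshold (default 0.25).
#' @return List with `call` (`"negative"`, `"positive"`, `"none"`) and
#'   `ambiguous` flag.
#' @export
classify_activity_relation <- function(gsea_results, nes_threshold = 2,
                                       fdr_threshold = 0.25) {
  if (nrow(gsea_results) == 0L) stop("need at least one gene-set result")
  nes <- gsea_results$nes
  fdr <- gsea_results$fdr
  ok <- is.finite(nes) & is.finite(fdr)
  neg <- any(ok & nes < -nes_threshold & fdr < fdr_threshold)
  pos <- any(ok & nes > nes_threshold & fdr < fdr_threshold)
  call <- if (neg) "negative" else if (pos) "positive" else "none"
  list(call = call, ambiguous = neg && pos)
}

#' MYCN-activity calls for a set of miRNAs
#'
#' Convenience wrapper: for each miRNA, ranks all genes (MYCN row excluded)
#' by correlation and runs GSEA over the MYC(N)-up gene-set collection, then
#' classifies the activity relation.
#'
#' @param mirna_matrix miRNA x sample matrix (rows restricted to the miRNAs
#'   of interest, typically the screen hits).
#' @param mrna_matrix Gene x sample matrix; a row named `"MYCN"` is dropped
#'   from the ranked list.
#' @param gene_sets Named list of MYC(N)-upregulated gene sets.
#' @param n_permutations,seed Passed to [gsea_collection()].
#' @param method Correlation method for the ranking.
#' @return List with `calls` (data frame `mirna_id`, `activity_call`,
#'   `ambiguous`) and `gsea` (long data frame of all per-miRNA, per-set
#'   results).
#' @export
activity_calls <- function(mirna_matrix, mrna_matrix, gene_sets,
                           n_permutations = 1000, seed = 1,
                           method = "spearman") {
  mrna <- mrna_matrix[setdiff(rownames(mrna_matrix), "MYCN"), , drop = FALSE]
  all_res <- lapply(rownames(mirna_matrix), function(id) {
    ranked <- rank_genes_for_mirna(mirna_matrix[id, ], mrna, method = method)
    stats <- stats::setNames(ranked$statistic, ranked$gene_id)
    res <- gsea_collection(stats, gene_sets, n_permutations, seed = seed)
    res$mirna_id <- id
    res
  })
  gsea_long <- do.call(rbind, all_res)
  calls <- do.call(rbind, lapply(all_res, function(res) {
    cl <- classify_activity_relation(res)
    data.frame(mirna_id = res$mirna_id[1L], activity_call = cl$call,
               ambiguous = cl$ambiguous, stringsAsFactors = FALSE)
  }))
  list(calls = calls, gsea = gsea_long)
}

#' Final relevance classification of screen hits
#'
#' Combines the expression-correlation call and the MYCN-activity call for
#' each screen hit:
#' * `NB-relevant MYCN-targeting` — inverse correlation or negative activity
#'   relation, with no positive evidence on the other axis;
#' * `MYCN-induced` — positive correlation or positive activity relation,
#'   with no inverse evidence;
#' * `conflicting-excluded` — one axis inverse/negative, the other positive;
#' * `not-supported` — neither axis significant;
#' * `no-data` — the hit is absent from the expression platform.
#'
#' @param hits Character vector of screen-hit miRNA ids.
#' @param expression_calls Data frame with `mirna_id` and `call` (from
#'   [correlate_to_mycn()]); miRNAs absent here are treated as off-platform.
#' @param activity_calls Data frame with `mirna_id` and `activity_call` (from
#'   [activity_calls()]); absence means no activity information (`none`).
#' @return Data frame of `RelevanceCall`s: `mirna_id`, `screen_hit`,
#'   `expression_call`, `activity_call`, `final`.
#' @export
classify_relevance <- function(hits, expression_calls, activity_calls) {
  expr_map <- stats::setNames(expression_calls$call, expression_calls$mirna_id)
  act_map <- stats::setNames(activity_calls$activity_call,
                             activity_calls$mirna_id)
  finals <- vapply(hits, function(id) {
    ec <- expr_map[id]
    if (is.na(ec)) return("no-data")
    ac <- if (id %in% names(act_map)) act_map[[id]] else "none"
    down <- identical(unname(ec), "inverse") || identical(ac, "negative")
    up <- identical(unname(ec), "positive") || identical(ac, "positive")
    if (down && up) {
      "conflicting-excluded"
    } else if (down) {
      "NB-relevant MYCN-targeting"
    } else if (up) {
      "MYCN-induced"
    } else {
      "not-supported"
    }
  }, character(1))
  data.frame(
    mirna_id = hits,
    screen_hit = TRUE,
    expression_call = ifelse(hits %in% names(expr_map), expr_map[hits], NA),
    activity_call = ifelse(hits %in% names(act_map), act_map[hits], "none"),
    final = unname(finals),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
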
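# Murine progression dynamics: Cq preprocessing with global-mean
# normalization, genotype x time regression with delta-slope pi-values,
# signature scoring, and two-group differential expression.

#' Preprocess a qPCR Cq table
#'
#' Applies the detection filter (only Cq values strictly below `max_cq` are
#' retained; filtered entries become missing) and global mean normalization:
#' per sample, expression = mean(retained Cq of that sample) - Cq. The result
#' is in log2-like units with higher values meaning higher expression, and
#' the per-sample mean of normalized retained values is exactly zero.
#' Samples with fewer than `min_retained` retained values are dropped with a
#' warning.
#'
#' @param cq miRNA x sample numeric matrix of Cq cycle values.
#' @param max_cq Detection cutoff (default 32).
#' @param min_retained Minimum retained values per sample (default 2).
#' @return Normalized expression matrix (same shape, minus dropped samples),
#'   with `NA` where the Cq was filtered.
#' @export
preprocess_cq <- function(cq, max_cq = 32, min_retained = 2L) {
  cq <- as.matrix(cq)
  cq[!is.finite(cq) | cq >= max_cq] <- NA_real_
  retained <- colSums(!is.na(cq))
  drop <- retained < min_retained
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) with fewer than %d retained Cq values: %s",
                    sum(drop), min_retained,
                    paste(colnames(cq)[drop], collapse = ", ")))
    cq <- cq[, !drop, drop = FALSE]
  }
  if (ncol(cq) == 0L) stop("no samples left after Cq filtering")
  sample_means <- colMeans(cq, na.rm = TRUE)
  sweep(-cq, 2L, sample_means, `+`)
}

#' Genotype-by-time regression of miRNA expression
#'
#' Fits, per miRNA, the single linear model
#' `expression ~ time + genotype + time:genotype` with time numeric in weeks
#' and WT as the reference genotype. The interaction coefficient is the
#' delta-slope (TG slope minus WT slope); its two-sided t-test p-value is
#' adjusted across miRNAs with Benjamini-Hochberg, and the signed
#' significance is summarized as `pi = -log10(p) * delta_slope`. Calls:
#' `down`/`up` by delta-slope sign when q <= 0.05, else `n.s.`; miRNAs whose
#' data do not cover both genotypes at >= 2 distinct timepoints each (or
#' fewer than `min_obs` observations) are `not-testable`.
#'
#' @param expression miRNA x sample numeric matrix (NAs allowed).
#' @param annotations Data frame with `sample_id`, `genotype` (`"TG"`/`"WT"`),
#'   `time_weeks`; `sample_id` must match the matrix columns.
#' @param min_obs Minimum total observations per miRNA (default 6).
#' @param q_threshold Significance level on the adjusted p (default 0.05).
#' @return Data frame of `ProgressionRecord`s: `mirna_id`, `slope_tg`,
#'   `slope_wt`, `delta_slope`, `p_value`, `q_value`, `pi_value`, `call`.
#' @export
fit_genotype_time_regression <- function(expression, annotations,
                                         min_obs = 6L, q_threshold = 0.05) {
  expression <- as.matrix(expression)
  req <- c("sample_id", "genotype", "time_weeks")
  if (!all(req %in% names(annotations))) {
    stop("`annotations` must have columns ", paste(req, collapse = ", "))
  }
  if (!all(colnames(expression) %in% annotations$sample_id)) {
    stop("every expression column needs a sample annotation")
  }
  ann <- annotations[match(colnames(expression), annotations$sample_id), ]
  if (!all(ann$genotype %in% c("TG", "WT"))) {
    stop("genotype must be 'TG' or 'WT'")
  }
  geno <- factor(ann$genotype, levels = c("WT", "TG"))
  time <- as.numeric(ann$time_weeks)

  fit_one <- function(y) {
    ok <- is.finite(y)
    if (sum(ok) < min_obs) return(NULL)
    tp_per_geno <- tapply(time[ok], geno[ok], function(t) length(unique(t)))
    if (any(is.na(tp_per_geno)) || any(tp_per_geno < 2L)) return(NULL)
    fit <- stats::lm(y ~ time * geno, subset = ok)
    cf <- summary(fit)$coefficients
    if (!"time:genoTG" %in% rownames(cf)) return(NULL)
    slope_wt <- cf["time", "Estimate"]
    delta <- cf["time:genoTG", "Estimate"]
    c(slope_tg = slope_wt + delta, slope_wt = slope_wt, delta_slope = delta,
      p_value = cf["time:genoTG", "Pr(>|t|)"])
  }

  rows <- lapply(seq_len(nrow(expression)), function(i) fit_one(expression[i, ]))
  testable <- !vapply(rows, is.null, logical(1))
  out <- data.frame(
    mirna_id = rownames(expression),
    slope_tg = NA_real_, slope_wt = NA_real_, delta_slope = NA_real_,
    p_value = NA_real_, q_value = NA_real_, pi_value = NA_real_,
    call = "not-testable",
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (any(testable)) {
    vals <- do.call(rbind, rows[testable])
    out[testable, c("slope_tg", "slope_wt", "delta_slope", "p_value")] <- vals
    out$q_value[testable] <- bh_adjust(out$p_value[testable])
    out$pi_value[testable] <- pi_value(out$p_value[testable],
                                       out$delta_slope[testable])
    out$call[testable] <- ifelse(
      out$q_value[testable] <= q_threshold,
      ifelse(out$delta_slope[testable] < 0, "down", "up"),
      "n.s."
    )
  }
  out
}

#' Per-sample signature score
#'
#' Each signature miRNA is z-scored across all samples; the score of a sample
#' is the mean over signature members of `direction * z`. Members missing
#' from the matrix, or with zero variance, are skipped; the fraction of
#' usable members is reported as the `coverage` attribute.
#'
#' @param expression miRNA x sample numeric matrix.
#' @param signature Data frame with `mirna_id` and `direction` (+1 for
#'   miRNAs induced with MYCN activity, -1 for repressed).
#' @return Data frame `sample_id`, `score`, with attribute `coverage`.
#' @export
signature_score <- function(expression, signature) {
  if (nrow(signature) == 0L) stop("empty signature")
  if (!all(c("mirna_id", "direction") %in% names(signature))) {
    stop("`signature` needs columns mirna_id and direction")
  }
  expression <- as.matrix(expression)
  present <- signature$mirna_id %in% rownames(expression)
  usable <- logical(nrow(signature))
  z_rows <- list()
  for (i in which(present)) {
    x <- expression[signature$mirna_id[i], ]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.finite(s) && s > 0) {
      usable[i] <- TRUE
      z_rows[[length(z_rows) + 1L]] <-
        signature$direction[i] * (x - mean(x, na.rm = TRUE)) / s
    }
  }
  if (!any(usable)) stop("no usable signature miRNA in the expression matrix")
  zmat <- do.call(rbind, z_rows)
  out <- data.frame(
    sample_id = colnames(expression),
    score = colMeans(zmat, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "coverage") <- mean(usable)
  out
}

#' Two-group differential expression of miRNAs
#'
#' Per miRNA: log2 fold change = mean(group A) - mean(group B) on
#' log2-scale expression, two-sided Student t-test (equal variance by
#' default; set `var_equal = FALSE` for Welch), Benjamini-Hochberg adjustment
#' across miRNAs. Calls: `up`/`down` by fold-change sign when q <= 0.05,
#' `n.s.` otherwise, `not-testable` when the t-statistic is undefined (e.g.
#' zero variance in both groups).
#'
#' @param expression miRNA x sample numeric matrix.
#' @param group_a,group_b Column names (or indices) of the two groups; each
#'   needs >= 2 samples.
#' @param var_equal Use the pooled-variance Student t-test (default `TRUE`).
#' @param q_threshold Significance level on the adjusted p (default 0.05).
#' @return Data frame of `DiffExprRecord`s: `mirna_id`, `log2_fc`, `p_value`,
#'   `q_value`, `call`.
#' @export
differential_expression <- function(expression, group_a, group_b,
                                    var_equal = TRUE, q_threshold = 0.05) {
  expression <- as.matrix(expression)
  a <- expression[, group_a, drop = FALSE]
  b <- expression[, group_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L) stop("each group needs >= 2 samples")

  res <- lapply(seq_len(nrow(expression)), function(i) {
    xa <- a[i, ][is.finite(a[i, ])]
    xb <- b[i, ][is.finite(b[i, ])]
    fc <- mean(xa) - mean(xb)
    if (length(xa) < 2L || length(xb) < 2L) {
      return(c(log2_fc = fc, p_value = NA_real_))
    }
    p <- tryCatch(
      stats::t.test(xa, xb, var.equal = var_equal)$p.value,
      error = function(e) NA_real_
    )
    c(log2_fc = fc, p_value = p)
  })
  res <- do.call(rbind, res)
  q <- bh_adjust(res[, "p_value"])
  testable <- is.finite(res[, "p_value"])
  call <- rep("not-testable", nrow(res))
  call[testable] <- ifelse(
    q[testable] <= q_threshold,
    ifelse(res[testable, "log2_fc"] < 0, "down", "up"),
    "n.s."
  )
  data.frame(
    mirna_id = rownames(expression),
    log2_fc = res[, "log2_fc"],
    p_value = res[, "p_value"],
    q_value = q,
    call = call,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Map murine assay ids to human miRNA ids
#'
#' Cross-species integration uses a two-column lookup table (murine assay id
#' to human miRNA id) restricted to assays whose target sequences match the
#' human library; no sequence-based matching is attempted here. Unmapped
#' rows are dropped; a mapping that would duplicate a human id is an error.
#'
#' @param expression Murine miRNA x sample matrix (rownames = assay ids).
#' @param mapping Data frame with columns `assay_id` and `human_id`.
#' @return The expression matrix restricted to mapped assays, with rows
#'   renamed to human miRNA ids.
#' @export
apply_mirna_mapping <- function(expression, mapping) {
  if (!all(c("assay_id", "human_id") %in% names(mapping))) {
    stop("`mapping` needs columns assay_id and human_id")
  }
  expression <- as.matrix(expression)
  keep <- rownames(expression) %in% mapping$assay_id
  out <- expression[keep, , drop = FALSE]
  human <- mapping$human_id[match(rownames(out), mapping$assay_id)]
  if (anyDuplicated(human)) stop("mapping assigns one human id to several assays")
  rownames(out) <- human
  out
}

#' Compare progression dynamics of targeting vs non-targeting miRNAs
#'
#' Two-sample Kolmogorov-Smirnov test of the delta-slope pi-value
#' distributions: MYCN-targeting miRNAs against all others. A negative shift
#' of the targeting distribution indicates preferential downregulation during
#' MYCN-driven tumor development.
#'
#' @param progression Data frame from [fit_genotype_time_regression()].
#' @param target_ids Character vector of targeting miRNA ids.
#' @return A [ks_two_sample()] result.
#' @export
compare_target_vs_nontarget_dynamics <- function(progression, target_ids) {
  is_target <- progression$mirna_id %in% target_ids
  pi_t <- progression$pi_value[is_target]
  pi_n <- progression$pi_value[!is_target]
  ks_two_sample(pi_t, pi_n)
}
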
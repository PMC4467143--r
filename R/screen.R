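# Screen scoring: dual-luciferase readings -> per-miRNA interaction scores,
# ROC max-accuracy cutoff, hit calls.

#' Normalize a dual-luciferase reporter reading
#'
#' Firefly activity (reporter carrying the 3'UTR) is normalized to the
#' co-transfected Renilla control and log2-transformed, giving a per-well
#' log-ratio on the fold-change scale.
#'
#' @param firefly Non-negative Firefly reading(s).
#' @param renilla Positive Renilla reading(s).
#' @return `log2(firefly / renilla)`. A zero Firefly reading yields `-Inf`,
#'   which downstream steps treat as an unusable well.
#' @examples
#' normalize_reporter(200, 100) # 1
#' @export
normalize_reporter <- function(firefly, renilla) {
  if (any(!is.finite(renilla)) || any(renilla <= 0)) {
    stop("invalid well: Renilla reading must be positive")
  }
  if (any(is.na(firefly)) || any(firefly < 0)) {
    stop("invalid well: Firefly reading must be non-negative")
  }
  log2(firefly / renilla)
}

#' Robust z-scores
#'
#' `z_i = (x_i - median(x)) / (1.4826 * MAD(x))` with
#' `MAD = median(|x_i - median(x)|)`; the 1.4826 factor makes the scale
#' estimate consistent with the standard deviation under normality.
#'
#' @param values Numeric vector with at least 3 finite values.
#' @param mad_fallback If `TRUE` and the MAD is zero (degenerate spread, e.g.
#'   noiseless synthetic data), return unscaled deviations from the median
#'   instead of failing. Default `FALSE`: a zero MAD is an error.
#' @return Numeric vector of robust z-scores (NA where the input is not
#'   finite).
#' @examples
#' robust_zscore(c(1, 2, 3))
#' @export
robust_zscore <- function(values, mad_fallback = FALSE) {
  fin <- is.finite(values)
  if (sum(fin) < 3L) stop("need at least 3 finite values")
  med <- stats::median(values[fin])
  scale <- stats::mad(values[fin], center = med) # includes the 1.4826 factor
  out <- rep(NA_real_, length(values))
  if (scale == 0) {
    if (!mad_fallback) {
      stop("degenerate distribution: median absolute deviation is zero")
    }
    out[fin] <- values[fin] - med
    return(out)
  }
  out[fin] <- (values[fin] - med) / scale
  out
}

#' Median-center focal z-scores against analog screens
#'
#' Subtracts, per miRNA, the median robust z across analog screens (screens of
#' unrelated 3'UTRs run with the same library) from the focal-screen z. This
#' removes systematic per-miRNA bias, e.g. mimics that are globally toxic or
#' boost transfection; resulting scores are more negative for miRNAs that
#' specifically repress the focal reporter.
#'
#' @param focal_z Named numeric vector: per-miRNA robust z of the focal screen.
#' @param analog_z Numeric matrix, miRNAs x analog screens, rownames = miRNA
#'   ids. Must cover every miRNA in `focal_z` with at least one finite value;
#'   miRNAs without a usable baseline are dropped with a warning.
#' @return Named numeric vector of centered scores (possibly shorter than
#'   `focal_z` if baselines were missing).
#' @examples
#' median_center(
#'   c(a = -1),
#'   matrix(c(0.5, 0.7, 0.9), 1, dimnames = list("a", NULL))
#' ) # -1.7
#' @export
median_center <- function(focal_z, analog_z) {
  if (is.null(names(focal_z))) stop("`focal_z` must be named by miRNA id")
  analog_z <- as.matrix(analog_z)
  ids <- names(focal_z)
  missing_ids <- setdiff(ids, rownames(analog_z))
  baseline <- rep(NA_real_, length(ids))
  present <- ids %in% rownames(analog_z)
  if (any(present)) {
    baseline[present] <- apply(
      analog_z[ids[present], , drop = FALSE], 1L,
      function(r) {
        r <- r[is.finite(r)]
        if (length(r) == 0L) NA_real_ else stats::median(r)
      }
    )
  }
  drop <- !is.finite(baseline)
  if (any(drop)) {
    warning(sprintf(
      "no analog baseline for %d miRNA(s), excluded: %s",
      sum(drop), paste(utils::head(c(missing_ids, ids[drop & present]), 5L), collapse = ", ")
    ))
  }
  focal_z[!drop] - baseline[!drop]
}

#' Average interaction scores across independent screens
#'
#' @param replicate_scores A list of named numeric vectors (one per
#'   independent screen replicate) or a miRNA x replicate numeric matrix of
#'   centered scores.
#' @return A data frame (`InteractionScoreTable` without hit flags):
#'   `mirna_id`, one `score_rep<k>` column per replicate, `score_avg` (mean of
#'   available replicates), `n_replicates`, and `complete` (present in every
#'   replicate).
#' @export
combine_replicates <- function(replicate_scores) {
  if (is.matrix(replicate_scores)) {
    replicate_scores <- lapply(
      seq_len(ncol(replicate_scores)),
      function(j) replicate_scores[, j]
    )
  }
  if (!is.list(replicate_scores) || length(replicate_scores) == 0L) {
    stop("need at least one replicate score vector")
  }
  if (any(!vapply(replicate_scores, function(x) !is.null(names(x)), logical(1)))) {
    stop("replicate score vectors must be named by miRNA id")
  }
  ids <- sort(unique(unlist(lapply(replicate_scores, names))))
  if (length(ids) == 0L) stop("no miRNAs in input")
  mat <- vapply(
    replicate_scores,
    function(x) unname(x[ids]),
    numeric(length(ids))
  )
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, paste0("score_rep", seq_along(replicate_scores))))
  avail <- rowSums(is.finite(mat))
  out <- data.frame(
    mirna_id = ids,
    mat,
    score_avg = rowMeans(mat, na.rm = TRUE),
    n_replicates = avail,
    complete = avail == length(replicate_scores),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out$score_avg[avail == 0L] <- NA_real_
  out
}

#' ROC maximum-accuracy cutoff for interaction scores
#'
#' Scores of validated positive interactions and of negative controls (from an
#' empty-3'UTR screen) define a ROC curve; the cutoff is the candidate
#' threshold with the highest accuracy. A score is predicted "interaction"
#' when it falls strictly below the cutoff. Candidates are the midpoints
#' between consecutive distinct pooled scores plus sentinels below the minimum
#' and above the maximum; accuracy ties are broken towards higher specificity,
#' then towards the more negative cutoff.
#'
#' @param positive_scores Scores of validated true interactions.
#' @param negative_scores Scores of negative-control interactions.
#' @return A list of class `"mirmycn_roc"`: `cutoff`, `sensitivity`,
#'   `specificity`, `accuracy`, `n_positive`, `n_negative`.
#' @examples
#' determine_cutoff(c(-3, -2.5, -0.5), c(-1, 0, 1, 2))
#' @export
determine_cutoff <- function(positive_scores, negative_scores) {
  pos <- positive_scores[is.finite(positive_scores)]
  neg <- negative_scores[is.finite(negative_scores)]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both positive and negative score sets must be non-empty")
  }
  pooled <- sort(unique(c(pos, neg)))
  cand <- c(
    pooled[1L] - 1,
    if (length(pooled) > 1L) (pooled[-length(pooled)] + pooled[-1L]) / 2,
    pooled[length(pooled)] + 1
  )
  tp <- vapply(cand, function(c) sum(pos < c), numeric(1))
  tn <- vapply(cand, function(c) sum(neg >= c), numeric(1))
  acc <- (tp + tn) / (length(pos) + length(neg))
  sens <- tp / length(pos)
  spec <- tn / length(neg)
  # best accuracy; ties -> higher specificity, then more negative cutoff
  ord <- order(-acc, -spec, cand)
  best <- ord[1L]
  structure(
    list(
      cutoff = cand[best],
      sensitivity = sens[best],
      specificity = spec[best],
      accuracy = acc[best],
      n_positive = length(pos),
      n_negative = length(neg)
    ),
    class = "mirmycn_roc"
  )
}

#' @export
print.mirmycn_roc <- function(x, ...) {
  cat(sprintf(
    "ROC max-accuracy cutoff: %.4g (accuracy %.3f, sensitivity %.3f, specificity %.3f)\n",
    x$cutoff, x$accuracy, x$sensitivity, x$specificity
  ))
  invisible(x)
}

#' Call screen hits below an interaction-score cutoff
#'
#' A miRNA is a hit when its average interaction score is strictly below the
#' cutoff; a score exactly equal to the cutoff is not a hit.
#'
#' @param score_table Data frame from [combine_replicates()] (needs columns
#'   `mirna_id`, `score_avg`).
#' @param cutoff Finite score threshold (the screen used -1.94).
#' @return `score_table` with a logical `hit` column added.
#' @export
call_hits <- function(score_table, cutoff) {
  if (!is.finite(cutoff)) stop("`cutoff` must be finite")
  stopifnot(all(c("mirna_id", "score_avg") %in% names(score_table)))
  score_table$hit <- !is.na(score_table$score_avg) & score_table$score_avg < cutoff
  score_table
}

#' Score a reporter screen end to end
#'
#' Runs the full scoring pipeline on a plate table: per-well log2
#' Firefly/Renilla ratios, per-screen-replicate robust z-scores across miRNAs,
#' median-centering of the focal screen against the analog screens, and
#' averaging across focal replicates.
#'
#' Analog screens (every `screen_id` other than `focal_screen`) are z-scored
#' per (screen, replicate) and collapsed to one column per screen-replicate
#' combination when building the per-miRNA baseline. When a screen-replicate
#' has zero median absolute deviation (possible in noiseless synthetic data)
#' the z-score falls back to unscaled deviations from the median.
#'
#' @param plates Data frame with columns `screen_id`, `replicate`, `mirna_id`,
#'   `firefly`, `renilla` (the `ScreenPlateTable` layout).
#' @param focal_screen `screen_id` of the screen being scored
#'   (default `"MYCN"`).
#' @return Interaction-score data frame from [combine_replicates()].
#' @seealso [call_hits()], [determine_cutoff()]
#' @export
score_screen <- function(plates, focal_screen = "MYCN") {
  req <- c("screen_id", "replicate", "mirna_id", "firefly", "renilla")
  if (!all(req %in% names(plates))) {
    stop("`plates` must have columns ", paste(req, collapse = ", "))
  }
  if (!focal_screen %in% plates$screen_id) {
    stop("focal screen '", focal_screen, "' not present in plate table")
  }
  key <- paste(plates$screen_id, plates$replicate, plates$mirna_id, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (screen, replicate, miRNA) wells")

  plates$log_ratio <- normalize_reporter(plates$firefly, plates$renilla)
  split_key <- interaction(plates$screen_id, plates$replicate, drop = TRUE)
  z_by_screen_rep <- lapply(split(plates, split_key), function(d) {
    z <- robust_zscore(d$log_ratio, mad_fallback = TRUE)
    stats::setNames(z, d$mirna_id)
  })
  is_focal <- vapply(
    split(plates$screen_id, split_key),
    function(s) s[1L] == focal_screen, logical(1)
  )
  focal_list <- z_by_screen_rep[is_focal]
  analog_list <- z_by_screen_rep[!is_focal]
  if (length(analog_list) == 0L) stop("no analog screens available for centering")

  ids <- sort(unique(plates$mirna_id[plates$screen_id != focal_screen]))
  analog_z <- vapply(analog_list, function(x) unname(x[ids]), numeric(length(ids)))
  analog_z <- matrix(analog_z, nrow = length(ids),
                     dimnames = list(ids, names(analog_list)))

  centered <- lapply(focal_list, median_center, analog_z = analog_z)
  combine_replicates(centered)
}
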
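# Shared statistical primitives used across the screen, expression and
# progression stages.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: `q_(i) = min_{j >= i}(p_(j) * m / j)`,
#' capped at 1 and returned in the input order. A thin validating wrapper around
#' [stats::p.adjust()].
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`. `NA` entries are
#'   propagated and do not count towards the number of tests.
#' @return Numeric vector of adjusted q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Signed-significance pi-value
#'
#' The pi-value combines statistical significance with effect direction and
#' size: `pi = -log10(p) * effect`, where the effect is a correlation
#' coefficient or a regression slope difference. Its sign follows the effect;
#' its magnitude grows with significance.
#'
#' @param p Raw p-value(s). Floored at `p_floor` before taking the log so that
#'   underflowed p-values remain finite.
#' @param effect Effect measure(s) of the same length as `p` (correlation
#'   coefficient, delta-slope, ...).
#' @param p_floor Smallest p-value used in the log; defaults to `2.2e-16`.
#' @return Numeric vector of pi-values.
#' @examples
#' pi_value(0.01, -0.5) # -1
#' @export
pi_value <- function(p, effect, p_floor = 2.2e-16) {
  -log10(pmax(p, p_floor)) * effect
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum distance between the two empirical cumulative distribution
#' functions, with the asymptotic Kolmogorov p-value at effective sample size
#' `n_a * n_b / (n_a + n_b)` (delegates to [stats::ks.test()] with
#' `exact = FALSE`).
#'
#' @param group_a,group_b Numeric vectors with at least 2 finite values each.
#' @return A list of class `"mirmycn_ks"` with elements `statistic` (D),
#'   `p_value`, `n_a`, `n_b`.
#' @examples
#' ks_two_sample(c(1, 3), c(2, 4))
#' @export
ks_two_sample <- function(group_a, group_b) {
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("both groups need at least 2 finite values")
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(
    list(
      statistic = unname(kt$statistic),
      p_value = max(unname(kt$p.value), 2.2e-16),
      n_a = length(a),
      n_b = length(b)
    ),
    class = "mirmycn_ks"
  )
}

#' @export
print.mirmycn_ks <- function(x, ...) {
  cat(sprintf(
    "Two-sample KS test: D = %.4g, p = %.4g (n = %d vs %d)\n",
    x$statistic, x$p_value, x$n_a, x$n_b
  ))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson chi-square without continuity correction, 1 degree of freedom.
#' Used to test whether negative activity enrichment is over-represented
#' among screen-hit miRNAs.
#'
#' @param table 2x2 matrix of non-negative integer counts; all row and column
#'   margins must be positive.
#' @return A list with `statistic`, `p_value`, `df`.
#' @examples
#' chi_square_2x2(matrix(c(10, 5, 5, 10), nrow = 2))
#' @export
chi_square_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("`table` must be 2x2")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(
    statistic = unname(ct$statistic),
    p_value = unname(ct$p.value),
    df = unname(ct$parameter)
  )
}
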
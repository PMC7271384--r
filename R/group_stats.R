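#' Unpaired two-tailed t test between two score groups
#'
#' Compares per-cell scores (or any two samples) with an unpaired
#' two-tailed t test. The default `"student"` variant uses the pooled
#' variance with `n_a + n_b - 2` degrees of freedom; `"welch"` does not
#' assume equal variances. Degenerate inputs where both groups are
#' constant are handled explicitly: equal constants give `t = 0, p = 1`;
#' unequal constants are an error (the statistic is undefined).
#'
#' @param scores_a,scores_b Numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return A list of class `group_comparison` with `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `t_statistic`, `degrees_of_freedom`,
#'   `p_two_tailed` and `variant`. The sign convention is
#'   `mean_a - mean_b` in the numerator.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))$t_statistic   # -3.674
#' @export
compare_groups <- function(scores_a, scores_b,
                           variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (length(scores_a) < 2L || length(scores_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  va <- stats::var(scores_a)
  vb <- stats::var(scores_b)
  out <- list(n_a = length(scores_a), n_b = length(scores_b),
              mean_a = mean(scores_a), mean_b = mean(scores_b),
              variant = variant)
  if (va == 0 && vb == 0) {
    if (out$mean_a == out$mean_b) {
      out$t_statistic <- 0
      out$degrees_of_freedom <- if (variant == "student")
        out$n_a + out$n_b - 2 else NA_real_
      out$p_two_tailed <- 1
      return(structure(out, class = "group_comparison"))
    }
    stop("degenerate comparison: both groups constant with unequal means")
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = variant == "student")
  out$t_statistic <- unname(tt$statistic)
  out$degrees_of_freedom <- unname(tt$parameter)
  out$p_two_tailed <- tt$p.value
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Unpaired two-tailed t test (%s)\n  group a: n = %d, mean = %.4g\n  group b: n = %d, mean = %.4g\n  t = %.4g, df = %.4g, p = %.4g\n",
    x$variant, x$n_a, x$mean_a, x$n_b, x$mean_b,
    x$t_statistic, x$degrees_of_freedom, x$p_two_tailed))
  invisible(x)
}

#' Summary statistics of one score group
#'
#' @param scores Non-empty numeric vector.
#' @return A list with `n`, `mean`, `sd` (sample SD, `n - 1`
#'   denominator) and `sem` (`sd / sqrt(n)`). For `n = 1`, `sd` and
#'   `sem` are `NA` (undefined) while `n` and `mean` are valid.
#' @examples
#' summarize_scores(c(1, 2, 3))   # sd = 1, sem = 0.5774
#' @export
summarize_scores <- function(scores) {
  if (length(scores) == 0L) stop("scores must be non-empty")
  n <- length(scores)
  s <- if (n >= 2L) stats::sd(scores) else NA_real_
  list(n = n, mean = mean(scores), sd = s, sem = s / sqrt(n))
}
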
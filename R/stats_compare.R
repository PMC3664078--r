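#' Normality verdict for a sample
#'
#' Shapiro-Wilk test at the given alpha for 3 <= n <= 5000; for larger
#' samples (beyond Shapiro-Wilk's range) the Anderson-Darling test from
#' \pkg{nortest} is used. Fewer than 3 values, or a degenerate
#' (zero-variance) sample, returns `FALSE`.
#'
#' @param values Numeric vector.
#' @param alpha Significance level for the normality test (default 0.05).
#' @return Logical: `TRUE` when the sample is consistent with normality
#'   (test p-value >= `alpha`).
#' @export
is_normal <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || stats::sd(values) == 0) return(FALSE)
  p <- tryCatch(
    if (n <= 5000) stats::shapiro.test(values)$p.value
    else nortest::ad.test(values)$p.value,
    error = function(e) 0)
  p >= alpha
}

#' Summarise one group of measurements
#'
#' Mean/SD and median/quartiles (quartiles by linear interpolation of order
#' statistics, the default quantile convention), plus a normality verdict
#' from [is_normal()].
#'
#' @param values Numeric vector, length >= 1.
#' @param alpha Significance level for the normality test.
#' @return An object of class `group_summary`: list with `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `normal`.
#' @export
summarize_group <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 1)
    stop("`values` must contain at least one finite value", call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  structure(list(n = length(values),
                 mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 median = q[2], q1 = q[1], q3 = q[3],
                 normal = is_normal(values, alpha)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("n=%d mean=%.4g sd=%.4g median=%.4g IQR=(%.4g-%.4g) normal=%s\n",
              x$n, x$mean, x$sd, x$median, x$q1, x$q3, x$normal))
  invisible(x)
}

#' Two-group comparison with normality gating
#'
#' Compares two independent samples the way clinical haemodynamic studies
#' commonly do: when both groups pass the normality check, an independent
#' two-sample t-test (Welch by default); otherwise the two-sided
#' Mann-Whitney U test. The Mann-Whitney p-value is exact (distribution of
#' the U statistic) when the combined sample size is at most 10 and there
#' are no ties, and uses the normal approximation with tie correction
#' otherwise. No multiple-testing correction is applied.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param force_test Optional: `"independent-t"` or `"mann-whitney"` to
#'   bypass the normality gate.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return An object of class `comparison_result`: list with `test_name`,
#'   `statistic`, `p_value`, `group_a`, `group_b` ([summarize_group()]
#'   summaries), `alpha` and `significant` (`p_value < alpha`).
#' @export
compare_groups <- function(a, b, force_test = NULL, alpha = 0.05,
                           var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 values", call. = FALSE)
  sa <- summarize_group(a, alpha)
  sb <- summarize_group(b, alpha)
  test <- if (!is.null(force_test)) {
    match.arg(force_test, c("independent-t", "mann-whitney"))
  } else if (sa$normal && sb$normal) "independent-t" else "mann-whitney"

  if (test == "independent-t") {
    ht <- stats::t.test(a, b, var.equal = var_equal)
  } else {
    exact <- (length(a) + length(b)) <= 10 && !anyDuplicated(c(a, b))
    ht <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = !exact))
  }
  structure(list(test_name = test,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 group_a = sa, group_b = sb,
                 alpha = alpha,
                 significant = ht$p.value < alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic=%.4g, p=%.4g (%ssignificant at %.2g)\n",
              x$test_name, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha))
  cat("  group A: "); print(x$group_a)
  cat("  group B: "); print(x$group_b)
  invisible(x)
}

#' Two-tailed correlation with automatic method choice
#'
#' `method = "auto"` uses Pearson only when both inputs pass the normality
#' check, Spearman otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param alpha Significance level for the normality gate.
#' @return An object of class `correlation_result`: list with `method`, `r`,
#'   `p_value`, `n`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (method == "auto")
    method <- if (is_normal(x, alpha) && is_normal(y, alpha))
      "pearson" else "spearman"
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  structure(list(method = method, r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: r=%.3f, p=%.4g, n=%d\n",
              x$method, x$r, x$p_value, x$n))
  invisible(x)
}
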
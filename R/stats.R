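#' Group summary for a two-sample comparison
#'
#' @param label Group label.
#' @param mean Group mean.
#' @param se Standard error of the mean (> 0).
#' @param n Sample size (>= 2).
#' @return List of class `group_summary`.
#' @export
group_summary <- function(label, mean, se, n) {
  if (n < 2) stop("group summary requires n >= 2")
  if (se <= 0) stop("group summary requires se > 0")
  structure(list(label = label, mean = mean, se = se, n = as.integer(n)),
            class = "group_summary")
}

#' Pooled two-sample Student's t-test from summary statistics
#'
#' Reconstructs each group's SD from its standard error
#' (`SD = se * sqrt(n)`), pools the variances with `n - 1` weights, and
#' returns the classical equal-variance t statistic with
#' `n_a + n_b - 2` degrees of freedom and a two-sided p-value. This is
#' the form that reproduces published group comparisons reported as
#' mean +/- SEM with n.
#'
#' @param a,b [group_summary()] objects.
#' @return List: `t`, `df`, `p`, plus the pooled SD `sd_pooled`.
#' @examples
#' pooled_t_from_summaries(group_summary("control", 12.96, 2.30, 6),
#'                         group_summary("runner", 5.33, 1.54, 9))$p
#' @export
pooled_t_from_summaries <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sd_a <- a$se * sqrt(a$n)
  sd_b <- b$se * sqrt(b$n)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * sd_a^2 + (b$n - 1) * sd_b^2) / df
  t <- (a$mean - b$mean) / (sqrt(sp2) * sqrt(1 / a$n + 1 / b$n))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, sd_pooled = sqrt(sp2))
}

#' Pooled t-test from raw values
#'
#' Convenience wrapper computing the group summaries from raw data and
#' delegating to [pooled_t_from_summaries()]; agrees with
#' `t.test(var.equal = TRUE)` to machine precision.
#'
#' @param x,y Numeric vectors (length >= 2 each).
#' @return As [pooled_t_from_summaries()].
#' @export
pooled_t_from_raw <- function(x, y) {
  pooled_t_from_summaries(
    group_summary("x", mean(x), stats::sd(x) / sqrt(length(x)), length(x)),
    group_summary("y", mean(y), stats::sd(y) / sqrt(length(y)), length(y)))
}

#' Simple linear regression with R^2 and F-test p-value
#'
#' Ordinary least squares of `y` on `x`; the coefficient of
#' determination is `1 - SSE/SST` and the p-value comes from the
#' F(1, n - 2) test of the slope.
#'
#' @param x,y Equal-length numeric vectors, `n >= 3`, `var(x) > 0`.
#' @return List of class `regression_fit`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
simple_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("regression requires n >= 3")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("var(x) must be positive")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - intercept - slope * x)^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  f <- if (sse > 0) (sst - sse) / (sse / (n - 2)) else Inf
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 p_value = p, n = n), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> slope %.4g, intercept %.4g, R^2 %.4f, p %.4g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}
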
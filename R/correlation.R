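#' Fisher-z confidence interval from a printed correlation
#'
#' Builds the confidence interval for a Pearson correlation from just `r` and
#' `n`, via the variance-stabilizing Fisher z-transform: z = atanh(r) is
#' treated as normal with standard error 1/sqrt(n - 3), and the interval
#' z +/- z_(1-alpha/2)/sqrt(n-3) is mapped back through tanh. Exposing this
#' standalone makes published (r, n) pairs checkable without the raw data.
#'
#' @param r Correlation, strictly inside (-1, 1) (atanh diverges at the
#'   boundary).
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level (default 0.05 for a 95% CI).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
#' @examples
#' ci_from_r(0.7644, 307)
ci_from_r <- function(r, n, alpha = 0.05) {
  stopifnot(length(r) == 1, length(n) == 1)
  if (abs(r) >= 1) {
    rlang::abort("|r| >= 1: Fisher-z interval undefined (atanh diverges)")
  }
  if (n < 4) rlang::abort("need n >= 4 for a Fisher-z interval")
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must be in (0, 1)")
  z <- atanh(r)
  hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  c(ci_low = tanh(z - hw), ci_high = tanh(z + hw))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson correlation of two vectors with a two-sided p-value from
#' the exact t-statistic t = r sqrt((n-2)/(1-r^2)) on n - 2 degrees of
#' freedom, and the Fisher-z confidence interval of [ci_from_r()].
#'
#' @param x,y Numeric vectors of equal length (n >= 4), each with non-zero
#'   variance.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `gv_correlation` object (also a one-row tibble) with columns
#'   `r`, `ci_low`, `ci_high`, `p_value`, `n`, `alpha`.
#' @export
#' @examples
#' pearson_with_ci(c(1, 2, 3, 4), c(1, 3, 2, 4))
pearson_with_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) rlang::abort("missing values in correlation input")
  n <- length(x)
  if (n < 4) rlang::abort("need n >= 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("constant vector: correlation undefined")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    rlang::abort("|r| = 1: degenerate (perfectly collinear) input; CI undefined")
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  ci <- ci_from_r(r, n, alpha)
  out <- tibble::new_tibble(
    tibble::tibble(
      r = r, ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]],
      p_value = p, n = n, alpha = alpha
    ),
    class = "gv_correlation"
  )
  out
}

#' @export
print.gv_correlation <- function(x, ...) {
  cat(sprintf(
    "Pearson r = %.4f, %d%% CI [%.4f, %.4f], p = %.4g, n = %d\n",
    x$r, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$p_value, x$n
  ))
  invisible(x)
}

#' Tidy a correlation result
#'
#' Broom-style one-row summary of a [pearson_with_ci()] result.
#'
#' @param x A `gv_correlation` object.
#' @param ... Unused.
#' @return A plain tibble with `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n`.
#' @importFrom generics tidy
#' @method tidy gv_correlation
#' @export
tidy.gv_correlation <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, conf.low = x$ci_low, conf.high = x$ci_high,
    p.value = x$p_value, n = x$n
  )
}

#' @export
generics::tidy
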
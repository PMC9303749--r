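#' Linear regression with standard and relative standard error
#'
#' Ordinary least squares of y on x, reporting the coefficient of
#' determination, the regression standard error
#' `SE = sqrt(sum((y - yhat)^2) / (N - 2))`, and the relative standard
#' error `RSE = SE / mean(y) * 100` (percent), the scale-free form used to
#' compare methods across traits with different units.
#'
#' @param x,y Numeric vectors of equal length, n >= 3; x must vary.
#' @return List of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `se`, `rse_pct`, `n`, and the underlying `lm` fit.
#' @export
linear_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations (SE uses N - 2)")
  if (stats::sd(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  se <- sqrt(ssr / (n - 2))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (sst == 0) 0 else 1 - ssr / sst,
                 se = se,
                 rse_pct = se / mean(y) * 100,
                 n = n, fit = fit),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4f x + %.4f, R2 = %.3f, SE = %.4f, RSE = %.1f%%, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$se, x$rse_pct, x$n))
  invisible(x)
}

#' Welch's two-sample t-test from group summary statistics
#'
#' Unequal-variance t-test computed from means, variances and sizes alone,
#' for use when only published group summaries are available:
#' `t = (m1 - m2) / sqrt(v1/n1 + v2/n2)` with Welch-Satterthwaite degrees
#' of freedom and a two-tailed p-value from the exact t distribution.
#'
#' @param mean1,var1,n1 First group: mean, sample variance (> 0), size
#'   (>= 2).
#' @param mean2,var2,n2 Second group.
#' @return List of class `welch_result`: `t`, `df`, `p_two_tailed`.
#' @examples
#' welch_from_summary(0.0038, 0.2842, 30, -0.0023, 0.2597, 30)
#' @export
welch_from_summary <- function(mean1, var1, n1, mean2, var2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (var1 <= 0 || var2 <= 0) stop("variances must be positive")
  s1 <- var1 / n1
  s2 <- var2 / n2
  t <- (mean1 - mean2) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (n1 - 1) + s2^2 / (n2 - 1))
  structure(list(t = t, df = df,
                 p_two_tailed = 2 * stats::pt(abs(t), df, lower.tail = FALSE)),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_result> t = %.4f, df = %.1f, p (two-tailed) = %.4f\n",
              x$t, x$df, x$p_two_tailed))
  invisible(x)
}

#' Mean blue-band intensity of an image
#'
#' Exposure proxy: the arithmetic mean of the blue channel over inside
#' pixels, on the raw 0-255 scale with no gamma applied. The blue band is
#' used because sky/foliage contrast (and hence threshold sensitivity to
#' exposure) is strongest there.
#'
#' @param image h x w x 3 array in `[0, 255]`, or a `hemi_image` holding
#'   one (its `outside_mask` is applied automatically).
#' @param outside_mask Optional logical matrix of pixels to exclude.
#' @return Mean blue intensity, 0-255.
#' @export
exposure_metric <- function(image, outside_mask = NULL) {
  if (inherits(image, "hemi_image")) {
    if (is.null(outside_mask)) outside_mask <- image$outside_mask
    image <- image$pixels
  }
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("exposure metric needs a 3-channel image")
  blue <- image[, , 3]
  if (!is.null(outside_mask)) blue <- blue[!outside_mask]
  mean(blue)
}
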
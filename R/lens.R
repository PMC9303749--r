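#' Lens projection function
#'
#' A lens function maps zenith angle to radial position on a hemispherical
#' image: `r/R = f(theta/theta_max)`, where `R` is the image radius. The
#' equidistant ("linear") projection, `r/R = theta/theta_max`, is the default
#' and matches the built-in reprojection used by most panorama software.
#' Calibrated fisheye lenses are described by a polynomial in
#' `theta/theta_max` whose coefficients come from an external calibration;
#' the polynomial must be strictly increasing on `[0, 1]` with `f(0) = 0`
#' and `f(1) = 1`.
#'
#' @param kind `"linear"` or `"polynomial"`.
#' @param coefficients For `"polynomial"`, coefficients `c1, c2, ...` of
#'   `f(t) = c1 t + c2 t^2 + ...` (no constant term). Ignored for
#'   `"linear"`.
#' @param theta_max Maximum zenith angle imaged, degrees. Default 90 (full
#'   upper hemisphere).
#' @return An object of class `lens_function`.
#' @examples
#' lens_function()                                  # equidistant
#' lens_function("polynomial", c(1.2, -0.2))        # mild distortion
#' @export
lens_function <- function(kind = c("linear", "polynomial"),
                          coefficients = NULL, theta_max = 90) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(theta_max), length(theta_max) == 1L,
            theta_max > 0, theta_max <= 90)
  if (kind == "polynomial") {
    if (is.null(coefficients) || !is.numeric(coefficients))
      stop("polynomial lens needs numeric coefficients")
    if (abs(sum(coefficients) - 1) > 1e-8)
      stop("polynomial lens must satisfy f(1) = 1 (coefficients sum to 1)")
    tt <- seq(0, 1, length.out = 512L)
    if (any(diff(.poly_eval(coefficients, tt)) <= 0))
      stop("lens function must be strictly increasing on [0, theta_max]")
  } else {
    coefficients <- 1
  }
  structure(list(kind = kind, coefficients = as.numeric(coefficients),
                 theta_max = as.numeric(theta_max)),
            class = "lens_function")
}

.poly_eval <- function(coef, t) {
  out <- 0
  for (j in rev(seq_along(coef))) out <- (out + coef[j]) * t
  out
}

#' Forward lens mapping: zenith angle to relative radius
#'
#' @param lens A [lens_function()].
#' @param theta Zenith angle(s), degrees, in `[0, theta_max]`.
#' @return Relative radius `r/R` in `[0, 1]`.
#' @export
lens_forward <- function(lens, theta) {
  stopifnot(inherits(lens, "lens_function"))
  t <- theta / lens$theta_max
  if (any(t < -1e-12 | t > 1 + 1e-12)) stop("theta outside [0, theta_max]")
  t <- pmin(pmax(t, 0), 1)
  if (lens$kind == "linear") t else .poly_eval(lens$coefficients, t)
}

#' Inverse lens mapping: relative radius to zenith angle
#'
#' Linear lenses invert in closed form; polynomial lenses by monotone
#' bisection to 1e-10 relative tolerance.
#'
#' @param lens A [lens_function()].
#' @param x Relative radius `r/R` in `[0, 1]` (values are clamped).
#' @return Zenith angle(s), degrees.
#' @export
lens_inverse <- function(lens, x) {
  stopifnot(inherits(lens, "lens_function"))
  x <- pmin(pmax(x, 0), 1)
  if (lens$kind == "linear") return(x * lens$theta_max)
  lo <- rep(0, length(x)); hi <- rep(1, length(x))
  # 50 bisections: interval < 1e-15, well under the 1e-10 target
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    below <- .poly_eval(lens$coefficients, mid) < x
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2 * lens$theta_max
}
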
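#' Per-annulus gap fractions from a binary sky/plant mask
#'
#' The gap fraction of an annulus is the proportion of its inside pixels
#' classified as sky, an estimate of the canopy transmission probability
#' P(theta) at that ring's zenith angles.
#'
#' @param mask A `binary_mask` from [binarize()] or [segment_image()],
#'   defined on a square hemispherical raster.
#' @param annuli An [annulus_set()].
#' @param lens The [lens_function()] of the source image (maps pixel radius
#'   back to zenith angle).
#' @return An object of class `gap_profile`: `annuli`, `P` (gap fraction
#'   per annulus), `pixel_counts` (inside pixels per annulus), `sky_counts`.
#' @export
gap_fractions <- function(mask, annuli = annulus_set(), lens = lens_function()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(annuli, "annulus_set"))
  size <- nrow(mask$sky)
  if (ncol(mask$sky) != size) stop("mask must be square")
  img <- structure(list(size = size, radius = size / 2, lens = lens,
                        outside_mask = mask$outside_mask),
                   class = "hemi_image")
  idx <- annulus_index(img, annuli)
  n <- integer(annuli$n_annuli)
  s <- integer(annuli$n_annuli)
  for (i in seq_len(annuli$n_annuli)) {
    in_ring <- !is.na(idx) & idx == i
    n[i] <- sum(in_ring)
    if (n[i] == 0L) stop(sprintf("empty annulus %d", i))
    s[i] <- sum(mask$sky[in_ring], na.rm = TRUE)
  }
  gap_profile(annuli, s / n, pixel_counts = n, sky_counts = s)
}

#' Construct a gap profile directly
#'
#' @param annuli An [annulus_set()].
#' @param P Gap fraction per annulus, each in `[0, 1]`.
#' @param pixel_counts,sky_counts Optional pixel tallies backing `P`.
#' @return An object of class `gap_profile`.
#' @export
gap_profile <- function(annuli, P, pixel_counts = NULL, sky_counts = NULL) {
  stopifnot(inherits(annuli, "annulus_set"), length(P) == annuli$n_annuli,
            all(P >= 0), all(P <= 1))
  structure(list(annuli = annuli, P = as.numeric(P),
                 pixel_counts = pixel_counts, sky_counts = sky_counts),
            class = "gap_profile")
}

#' @export
print.gap_profile <- function(x, ...) {
  cat("<gap_profile>\n")
  print(data.frame(theta_mid = x$annuli$midpoints, P = round(x$P, 4)))
  invisible(x)
}

#' Plant area index by the discretized Miller integral
#'
#' Inverts per-annulus gap fractions to PAI via
#' `PAI = 2 * sum_i (-ln P_i) cos(theta_i) sin(theta_i) dtheta / C`,
#' with `theta_i` the annulus midpoints and `dtheta` the annulus width in
#' radians. The Miller integral runs over the full 0-90 degree range; when
#' the annuli stop short of the horizon (the usual 5 x 15 degree layout
#' stops at 75 degrees) the truncation factor `C = 1 - cos(theta_last)`
#' renormalizes the integral. The factor is exact for a spherical leaf
#' angle distribution, where `-ln P(theta) * cos(theta)` is constant, and
#' is applied by default.
#'
#' Saturated annuli (no sky pixels) make the logarithm blow up; gap
#' fractions below `p_floor` are raised to it before the inversion. The
#' default floor is one sky pixel out of the annulus pixel count when
#' counts are available, otherwise 0 (in which case a zero gap fraction is
#' an error).
#'
#' @param gp A `gap_profile`.
#' @param truncation_correct Apply the truncation factor (default `TRUE`).
#' @param p_floor Gap-fraction floor; `NULL` for the one-pixel default.
#' @param star Optional silhouette-to-total-area ratio; when given, the
#'   clumping-corrected PAI `pai_raw / (4 * star)` is filled in.
#' @return An object of class `pai_estimate`: `pai_raw`,
#'   `pai_clumping_corrected` (`NA` if no `star`), `star`, `theta_max`,
#'   `truncation_corrected`.
#' @examples
#' ann <- annulus_set()
#' # spherical canopy with PAI 3: P = exp(-0.5 * 3 / cos(theta))
#' P <- exp(-1.5 / cos(ann$midpoints * pi / 180))
#' miller_pai(gap_profile(ann, P))$pai_raw   # ~3 (midpoint-rule error < 1%)
#' @export
miller_pai <- function(gp, truncation_correct = TRUE, p_floor = NULL,
                       star = NULL) {
  stopifnot(inherits(gp, "gap_profile"))
  P <- gp$P
  if (is.null(p_floor)) {
    p_floor <- if (!is.null(gp$pixel_counts)) 1 / gp$pixel_counts else 0
  }
  P <- pmax(P, p_floor)
  if (any(P <= 0)) stop("saturated annulus: gap fraction 0 with no floor")
  theta <- gp$annuli$midpoints * pi / 180
  dtheta <- gp$annuli$width_deg * pi / 180
  theta_max <- max(gp$annuli$boundaries)
  C <- if (truncation_correct) 1 - cos(theta_max * pi / 180) else 1
  pai_raw <- 2 * sum(-log(P) * cos(theta) * sin(theta) * dtheta) / C
  structure(list(pai_raw = pai_raw,
                 pai_clumping_corrected =
                   if (is.null(star)) NA_real_ else clumping_correct(pai_raw, star),
                 star = if (is.null(star)) NA_real_ else star,
                 theta_max = theta_max,
                 truncation_corrected = truncation_correct,
                 P_used = P),
            class = "pai_estimate")
}

#' @export
print.pai_estimate <- function(x, ...) {
  cat(sprintf("<pai_estimate> PAI_raw = %.4f m2/m2", x$pai_raw))
  if (!is.na(x$star))
    cat(sprintf(", clumping-corrected = %.4f (STAR %.3f)",
                x$pai_clumping_corrected, x$star))
  cat("\n")
  invisible(x)
}

#' Shoot-level clumping correction
#'
#' Conifer needles are clumped into shoots, so the effective plant area
#' seen by gap-fraction inversion underestimates the true area. Dividing
#' by four times the mean shoot silhouette-to-total-area ratio (STAR)
#' corrects for this: STAR = 0.25 corresponds to unclumped (spherical)
#' foliage and leaves the PAI unchanged. Typical boreal values are 0.147
#' for Scots pine and 0.161 for Norway spruce; broadleaves are left
#' uncorrected.
#'
#' @param pai_raw Uncorrected PAI, m^2 m^-2.
#' @param star Mean STAR, in `(0, 0.25]`.
#' @return Corrected PAI, `pai_raw / (4 * star)`.
#' @export
clumping_correct <- function(pai_raw, star) {
  if (!is.numeric(star) || any(star <= 0))
    stop("star must be positive")
  if (any(star > 0.25))
    warning("star > 0.25 implies a correction factor below 1")
  stopifnot(all(pai_raw >= 0))
  pai_raw / (4 * star)
}
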
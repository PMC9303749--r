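#' Equirectangular spherical panorama
#'
#' Wraps a full-sphere equirectangular raster. Columns map linearly to
#' azimuth (0-360 degrees) and rows to zenith angle (0 degrees at row 1,
#' 180 degrees at the last row), so the top half of the image is the upper
#' hemisphere. The raster must therefore be exactly twice as wide as it is
#' tall.
#'
#' @param pixels Numeric matrix (grayscale) or h x w x 3 array (RGB) of
#'   intensities in `[0, 255]`.
#' @param azimuth_origin Compass azimuth of image column 1, degrees.
#' @return An object of class `panorama` with elements `pixels`, `width`,
#'   `height`, `azimuth_origin`.
#' @export
panorama <- function(pixels, azimuth_origin = 0) {
  d <- dim(pixels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("pixels must be a matrix or a 3-channel array")
  if (length(d) == 3L && d[3] != 3L)
    stop("3-d pixel arrays must have exactly 3 channels")
  h <- d[1]; w <- d[2]
  if (w != 2L * h)
    stop("not an equirectangular full-sphere panorama: width must equal 2 x height")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie in [0, 255]")
  structure(list(pixels = pixels, width = w, height = h,
                 azimuth_origin = azimuth_origin),
            class = "panorama")
}

#' @export
print.panorama <- function(x, ...) {
  cat(sprintf("<panorama> %d x %d (%s), azimuth origin %g deg\n",
              x$height, x$width,
              if (length(dim(x$pixels)) == 3L) "RGB" else "gray",
              x$azimuth_origin))
  invisible(x)
}

# polar geometry of a square hemispherical raster: distance from center (px),
# image azimuth (deg, clockwise from up) per pixel; 1-based pixel centers
.hemi_polar <- function(size) {
  c0 <- (size + 1) / 2
  dx <- matrix(rep(seq_len(size) - c0, each = size), size, size)   # +x right
  dy <- matrix(rep(c0 - seq_len(size), times = size), size, size)  # +y up
  r <- sqrt(dx^2 + dy^2)
  phi <- (atan2(dx, dy) * 180 / pi) %% 360
  list(r = r, phi = phi)
}

#' Reproject a panorama to an upward-looking hemispherical image
#'
#' Resamples the upper hemisphere of an equirectangular panorama onto a
#' square polar raster, emulating the geometry of a fisheye photograph
#' pointed at the zenith. For an output pixel at distance `r` from the
#' center and image azimuth `phi` (up = 0, clockwise positive), the zenith
#' angle is `theta = lens_inverse(r/R)` and the source location is column
#' `(phi + azimuth_offset) mod 360` and row `theta/180` of the panorama.
#' Pixels beyond the image radius are set to 0 and flagged in
#' `outside_mask`; all downstream statistics use the mask, never the fill
#' value.
#'
#' @param pano A [panorama()].
#' @param out_size Side length of the square output, pixels (even, >= 2).
#' @param lens A [lens_function()]; default equidistant over 90 degrees.
#' @param interpolation `"bilinear"` (default, smoother for segmentation) or
#'   `"nearest"` (bit-exact resampling for geometric tests).
#' @param azimuth_offset Degrees added to the image azimuth before sampling;
#'   rotates the output about its center. Gap fractions and PAI are
#'   rotation-invariant, so this matters only for visual comparison with
#'   compass-aligned hemispherical photographs.
#' @return An object of class `hemi_image`: `pixels` (matrix or 3-channel
#'   array), `size`, `radius`, `lens`, `azimuth_offset`, and logical
#'   `outside_mask` (`TRUE` beyond the radius).
#' @examples
#' pano <- panorama(matrix(200, 50, 100))
#' h <- reproject_to_hemisphere(pano, out_size = 64)
#' mean(h$pixels[!h$outside_mask])   # 200: constant field is preserved
#' @export
reproject_to_hemisphere <- function(pano, out_size = 2000,
                                    lens = lens_function(),
                                    interpolation = c("bilinear", "nearest"),
                                    azimuth_offset = 0) {
  stopifnot(inherits(pano, "panorama"), inherits(lens, "lens_function"))
  interpolation <- match.arg(interpolation)
  if (!is.numeric(out_size) || out_size < 2) stop("out_size must be >= 2")
  out_size <- as.integer(out_size)
  if (out_size %% 2L != 0L) stop("out_size must be even")

  R <- out_size / 2
  g <- .hemi_polar(out_size)
  inside <- g$r <= R
  theta <- matrix(NA_real_, out_size, out_size)
  theta[inside] <- lens_inverse(lens, g$r[inside] / R)

  h <- pano$height; w <- pano$width
  u <- ((g$phi[inside] + azimuth_offset) %% 360) / 360 * w  # [0, w)
  v <- theta[inside] / 180 * h                              # [0, h/2]
  top_row <- h %/% 2L  # never sample below the horizon

  sample_channel <- function(px) {
    out <- matrix(0, out_size, out_size)
    if (interpolation == "nearest") {
      cc <- floor(u) + 1L; cc[cc > w] <- 1L
      rr <- pmin(floor(v) + 1L, top_row)
      rr <- pmax(rr, 1L)
      out[inside] <- px[cbind(rr, cc)]
    } else {
      a <- u - 0.5
      c0 <- floor(a); fx <- a - c0
      c1 <- (as.integer(c0) %% w) + 1L
      c2 <- (as.integer(c0 + 1) %% w) + 1L
      b <- v - 0.5
      r0 <- floor(b); fy <- b - r0
      r1 <- pmin(pmax(as.integer(r0) + 1L, 1L), top_row)
      r2 <- pmin(pmax(as.integer(r0) + 2L, 1L), top_row)
      out[inside] <-
        (1 - fy) * ((1 - fx) * px[cbind(r1, c1)] + fx * px[cbind(r1, c2)]) +
        fy       * ((1 - fx) * px[cbind(r2, c1)] + fx * px[cbind(r2, c2)])
    }
    out
  }

  if (length(dim(pano$pixels)) == 3L) {
    pixels <- array(0, dim = c(out_size, out_size, 3L))
    for (ch in 1:3) pixels[, , ch] <- sample_channel(pano$pixels[, , ch])
  } else {
    pixels <- sample_channel(pano$pixels)
  }

  structure(list(pixels = pixels, size = out_size, radius = R, lens = lens,
                 azimuth_offset = azimuth_offset, outside_mask = !inside),
            class = "hemi_image")
}

#' @export
print.hemi_image <- function(x, ...) {
  cat(sprintf("<hemi_image> %d x %d, radius %g px, %s lens (theta_max %g deg)\n",
              x$size, x$size, x$radius, x$lens$kind, x$lens$theta_max))
  invisible(x)
}

#' Zenith-angle map of a hemispherical image
#'
#' @param img A `hemi_image`.
#' @return Matrix of zenith angles (degrees) per pixel; `NA` outside the
#'   image radius.
#' @export
hemi_theta <- function(img) {
  stopifnot(inherits(img, "hemi_image"))
  g <- .hemi_polar(img$size)
  theta <- matrix(NA_real_, img$size, img$size)
  inside <- !img$outside_mask
  theta[inside] <- lens_inverse(img$lens, g$r[inside] / img$radius)
  theta
}

#' Concentric zenith annuli
#'
#' Partition of the zenith range into contiguous equal-width rings starting
#' at the zenith, on which gap fractions are computed. The conventional
#' division is five rings of 15 degrees, covering 0-75 degrees and leaving
#' the near-horizon band unused.
#'
#' @param n_annuli Number of rings (default 5).
#' @param width_deg Ring width, degrees (default 15). `n_annuli * width_deg`
#'   must not exceed 90.
#' @return An object of class `annulus_set` with `boundaries` (two-column
#'   matrix of lower/upper zenith angles), `midpoints`, `n_annuli`,
#'   `width_deg`.
#' @export
annulus_set <- function(n_annuli = 5, width_deg = 15) {
  stopifnot(n_annuli >= 1, width_deg > 0)
  if (n_annuli * width_deg > 90 + 1e-9)
    stop("annuli must fit within the hemisphere: n_annuli * width_deg <= 90")
  lo <- (seq_len(n_annuli) - 1) * width_deg
  structure(list(n_annuli = as.integer(n_annuli), width_deg = width_deg,
                 boundaries = cbind(theta_lo = lo, theta_hi = lo + width_deg),
                 midpoints = lo + width_deg / 2),
            class = "annulus_set")
}

#' Assign hemispherical-image pixels to zenith annuli
#'
#' @param img A `hemi_image`.
#' @param annuli An [annulus_set()]; must lie within the lens `theta_max`.
#' @return Integer matrix: annulus index per pixel, 0 for inside pixels
#'   beyond the last ring, `NA` outside the image radius.
#' @export
annulus_index <- function(img, annuli = annulus_set()) {
  stopifnot(inherits(annuli, "annulus_set"))
  if (max(annuli$boundaries) > img$lens$theta_max + 1e-9)
    stop("annuli extend beyond the lens theta_max")
  theta <- hemi_theta(img)
  idx <- findInterval(theta, c(annuli$boundaries[, 1], max(annuli$boundaries)),
                      rightmost.closed = TRUE)
  idx[idx > annuli$n_annuli] <- 0L
  matrix(as.integer(idx), img$size, img$size)
}

#' Per-annulus boolean masks
#'
#' @param img A `hemi_image`.
#' @param annuli An [annulus_set()].
#' @return List of logical matrices, one per annulus; each inside pixel
#'   belongs to at most one.
#' @export
annulus_masks <- function(img, annuli = annulus_set()) {
  idx <- annulus_index(img, annuli)
  lapply(seq_len(annuli$n_annuli),
         function(i) !is.na(idx) & idx == i)
}
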
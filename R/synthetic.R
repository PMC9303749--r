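# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Horizontally homogeneous slab canopy
#'
#' A stack of non-overlapping horizontal layers, each with a constant
#' plant area density, attenuating light by Beer's law with projection
#' coefficient `g` (0.5 for a spherical leaf angle distribution). The
#' closed-form gap fraction of such a canopy makes it the ground truth for
#' validating the photographic and laser pipelines.
#'
#' @param z_lo,z_hi Layer bounds, m (vectors of equal length; layers must
#'   not overlap).
#' @param pad Plant area density per layer, m^2 m^-3 (>= 0).
#' @param g Projection coefficient in `(0, 1]` (default 0.5, spherical).
#' @return An object of class `slab_canopy`.
#' @examples
#' slab_canopy(0, 6, 1.0)        # PAI 6 slab from the ground to 6 m
#' @export
slab_canopy <- function(z_lo, z_hi, pad, g = 0.5) {
  stopifnot(length(z_lo) == length(z_hi), length(pad) == length(z_lo),
            all(z_hi > z_lo), all(pad >= 0), g > 0, g <= 1)
  o <- order(z_lo)
  z_lo <- z_lo[o]; z_hi <- z_hi[o]; pad <- pad[o]
  if (length(z_lo) > 1 && any(z_lo[-1] < z_hi[-length(z_hi)]))
    stop("layers must not overlap")
  structure(list(layers = data.frame(z_lo = z_lo, z_hi = z_hi, pad = pad),
                 g = g),
            class = "slab_canopy")
}

#' Cumulative plant area above a height
#'
#' @param canopy A [slab_canopy()].
#' @param z Height(s), m.
#' @return PAI above each `z`, m^2 m^-2.
#' @export
pai_above <- function(canopy, z) {
  stopifnot(inherits(canopy, "slab_canopy"))
  L <- canopy$layers
  vapply(z, function(zz) {
    sum(L$pad * pmax(0, L$z_hi - pmax(L$z_lo, zz)))
  }, numeric(1))
}

#' Closed-form gap fraction of a slab canopy
#'
#' `P(theta) = exp(-g * PAI_above(camera) / cos(theta))`: Beer's-law
#' attenuation along a slant path through everything above the camera.
#'
#' @param canopy A [slab_canopy()].
#' @param camera_height Camera height, m.
#' @param theta Zenith angle(s), degrees, in `[0, 90)`.
#' @return Gap probability per `theta`.
#' @export
true_gap <- function(canopy, camera_height, theta) {
  stopifnot(inherits(canopy, "slab_canopy"), camera_height >= 0)
  if (any(theta < 0 | theta >= 90))
    stop("theta must lie in [0, 90): horizontal paths never clear a slab")
  L <- pai_above(canopy, camera_height)
  exp(-canopy$g * L / cos(theta * pi / 180))
}

#' Rendering configuration for synthetic panoramas
#'
#' @param camera_height Camera height above ground, m.
#' @param pano_height Panorama height in pixels (width is twice this).
#' @param seed Integer RNG seed; `NULL` leaves the RNG state alone.
#' @param sky_level,plant_level Intensities (0-255) written for sky and
#'   plant pixels; well separated by default so segmentation is
#'   unambiguous.
#' @param noise_sd Gaussian intensity noise added per pixel (0 disables);
#'   exercises the thresholding realistically.
#' @return An object of class `render_config`.
#' @export
render_config <- function(camera_height = 0, pano_height = 500, seed = 1L,
                          sky_level = 230, plant_level = 20, noise_sd = 0) {
  stopifnot(camera_height >= 0, pano_height >= 2, sky_level > plant_level,
            sky_level <= 255, plant_level >= 0, noise_sd >= 0)
  structure(list(camera_height = camera_height,
                 pano_height = as.integer(pano_height),
                 seed = seed, sky_level = sky_level,
                 plant_level = plant_level, noise_sd = noise_sd),
            class = "render_config")
}

#' Render a synthetic equirectangular panorama of a slab canopy
#'
#' Each upper-hemisphere pixel at zenith angle theta (taken at the row
#' center) is sky with probability `P(theta)` and plant otherwise,
#' independently (Bernoulli dithering). This gives exact closed-form
#' expected gap fractions per annulus after reprojection -- the
#' pixel-area-weighted mean of P(theta) over the annulus -- which is what
#' pipeline validation needs; no attempt is made at geometric crown
#' realism. The lower hemisphere is filled with the plant level.
#'
#' @param canopy A [slab_canopy()].
#' @param cfg A [render_config()].
#' @return A grayscale [panorama()]. Same seed, same panorama, bit for bit.
#' @export
render_panorama <- function(canopy, cfg = render_config()) {
  stopifnot(inherits(canopy, "slab_canopy"), inherits(cfg, "render_config"))
  h <- cfg$pano_height
  w <- 2L * h
  theta_row <- (seq_len(h) - 0.5) / h * 180
  upper <- theta_row < 90
  P_row <- numeric(h)
  P_row[upper] <- true_gap(canopy, cfg$camera_height, theta_row[upper])
  px <- with_seed(cfg$seed, {
    sky <- matrix(stats::runif(h * w) < P_row, h, w)  # P recycles by row
    m <- matrix(cfg$plant_level, h, w)
    m[sky] <- cfg$sky_level
    m[!upper, ] <- cfg$plant_level
    if (cfg$noise_sd > 0)
      m <- pmin(pmax(m + stats::rnorm(h * w, 0, cfg$noise_sd), 0), 255)
    m
  })
  panorama(px)
}

#' Simulate a vertically scanning laser point cloud over a slab canopy
#'
#' Pulses descend vertically at uniform random positions in a disc. Each
#' pulse is intercepted where its survival probability
#' `S(z) = exp(-k_true * PAI_above(z))` falls to a uniform draw (inverse
#' transform on the cumulative plant area); pulses that clear the whole
#' canopy become ground returns at `ground_z`. One return per pulse.
#'
#' @param canopy A [slab_canopy()].
#' @param k_true Extinction coefficient used to attenuate pulses (> 0).
#' @param n_pulses Number of pulses (>= 1).
#' @param plot_radius Disc radius, m (default 10).
#' @param seed Integer RNG seed.
#' @param ground_z Height assigned to ground returns, m (default 0.5,
#'   below the conventional 1.5 m ground cut).
#' @return A `point_cloud` with `source = "synthetic"`.
#' @export
simulate_point_cloud <- function(canopy, k_true, n_pulses, plot_radius = 10,
                                 seed = 1L, ground_z = 0.5) {
  stopifnot(inherits(canopy, "slab_canopy"), k_true > 0, n_pulses >= 1)
  L <- canopy$layers[order(-canopy$layers$z_lo), , drop = FALSE]
  # cumulative PAI from the top down at layer boundaries
  cum_top <- c(0, cumsum(L$pad * (L$z_hi - L$z_lo)))
  total <- cum_top[length(cum_top)]
  with_seed(seed, {
    ang <- stats::runif(n_pulses, 0, 2 * pi)
    rr <- plot_radius * sqrt(stats::runif(n_pulses))
    tau <- -log(stats::runif(n_pulses)) / k_true  # plant area each pulse can cross
    z <- rep(ground_z, n_pulses)
    hit <- tau < total
    if (any(hit)) {
      band <- findInterval(tau[hit], cum_top, rightmost.closed = TRUE)
      band <- pmin(band, nrow(L))
      z[hit] <- L$z_hi[band] - (tau[hit] - cum_top[band]) / L$pad[band]
    }
    point_cloud(cbind(rr * cos(ang), rr * sin(ang), z), source = "synthetic")
  })
}

#' Simulate a photographic PAI profile through the full pipeline
#'
#' For each capture height, renders replicate panoramas (distinct
#' sub-seeds), reprojects them to hemispherical images, segments them, and
#' inverts the gap fractions to PAI -- the complete measurement chain an
#' airborne camera would produce over a known canopy.
#'
#' @param canopy A [slab_canopy()].
#' @param heights Capture heights, m.
#' @param cfg A [render_config()] (its `camera_height` is overridden per
#'   height; its `seed` seeds the replicate sub-seeds).
#' @param n_replicates Panoramas per height (default 3).
#' @param out_size Hemispherical image size, pixels; default twice the
#'   panorama height.
#' @param annuli,lens,seg_cfg Analysis settings, defaulting to five
#'   15-degree annuli, an equidistant lens and gamma-2.2 isodata
#'   segmentation.
#' @param interpolation Resampling kernel for the reprojection. Default
#'   `"nearest"`: each hemispherical pixel copies one panorama pixel, so
#'   its sky probability is exactly the Bernoulli P(theta) of the dithered
#'   render and the closed-form expectations hold. Bilinear sampling mixes
#'   sky and plant intensities before thresholding, which votes mixed
#'   pixels toward the locally dominant class and biases the gap fraction
#'   of a dithered field (it remains the better choice for real imagery,
#'   where intensities vary smoothly).
#' @return Data frame with columns `height`, `replicate`, `pai`, suitable
#'   for [height_profile()].
#' @export
simulate_uas_profile <- function(canopy, heights, cfg = render_config(),
                                 n_replicates = 3,
                                 out_size = 2L * cfg$pano_height,
                                 annuli = annulus_set(),
                                 lens = lens_function(),
                                 seg_cfg = segmentation_config(),
                                 interpolation = "nearest") {
  stopifnot(inherits(canopy, "slab_canopy"), all(heights >= 0))
  rows <- list()
  counter <- 0L
  for (h in heights) {
    for (rep_i in seq_len(n_replicates)) {
      counter <- counter + 1L
      sub_seed <- (cfg$seed + 7919L * counter) %% .Machine$integer.max
      rcfg <- cfg
      rcfg$camera_height <- h
      rcfg$seed <- sub_seed
      pano <- render_panorama(canopy, rcfg)
      hemi <- reproject_to_hemisphere(pano, out_size = out_size, lens = lens,
                                      interpolation = interpolation)
      mask <- segment_image(hemi, seg_cfg)
      gp <- gap_fractions(mask, annuli, lens)
      est <- miller_pai(gp)
      rows[[counter]] <- data.frame(height = h, replicate = rep_i,
                                    pai = est$pai_raw)
    }
  }
  do.call(rbind, rows)
}
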
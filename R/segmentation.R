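#' Segmentation configuration
#'
#' Settings for converting an RGB hemispherical image to a binary sky/plant
#' mask. Stored JPEG/PNG intensities are treated as gamma-encoded and are
#' linearized as `(v/255)^gamma` before any thresholding; the conventional
#' display gamma of 2.2 is the default. By default all three bands
#' contribute equally (`rgb_mean`); the blue band alone is a common
#' alternative because it gives the strongest sky/foliage contrast.
#'
#' @param gamma Gamma value for linearization (> 0, default 2.2).
#' @param channel_mode `"rgb_mean"`, `"blue"`, `"red"`, or `"green"`.
#' @param threshold_mode `"ridler_calvard"` (automatic isodata) or
#'   `"manual"`.
#' @param manual_threshold Threshold on the linearized `[0, 1]` scale, used
#'   only in manual mode.
#' @param max_iterations Iteration cap for the isodata recurrence.
#' @param tolerance Convergence tolerance on the `[0, 1]` intensity scale.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(gamma = 2.2,
                                channel_mode = c("rgb_mean", "blue", "red", "green"),
                                threshold_mode = c("ridler_calvard", "manual"),
                                manual_threshold = 0.5,
                                max_iterations = 100L,
                                tolerance = 1e-4) {
  channel_mode <- match.arg(channel_mode)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(gamma > 0, manual_threshold >= 0, manual_threshold <= 1,
            max_iterations >= 1, tolerance > 0)
  structure(list(gamma = gamma, channel_mode = channel_mode,
                 threshold_mode = threshold_mode,
                 manual_threshold = manual_threshold,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance),
            class = "segmentation_config")
}

#' Gamma-linearize and collapse an image to a single grayscale band
#'
#' Each channel is linearized as `(v/255)^gamma`, then the channels are
#' combined according to `channel_mode` (`rgb_mean` is the unweighted mean
#' of the three linearized channels). Single-band input is linearized
#' directly regardless of `channel_mode`, except that `rgb_mean` on a
#' single band is rejected to catch accidental channel loss.
#'
#' @param image Matrix or h x w x 3 array of intensities in `[0, 255]`, or
#'   a `hemi_image` / `panorama` (its pixels are used).
#' @param cfg A [segmentation_config()].
#' @return Matrix of linearized intensities in `[0, 1]`.
#' @export
to_gray <- function(image, cfg = segmentation_config()) {
  px <- if (inherits(image, c("hemi_image", "panorama"))) image$pixels else image
  if (min(px) < 0 || max(px) > 255) stop("intensities must lie in [0, 255]")
  lin <- (px / 255)^cfg$gamma
  if (length(dim(px)) == 3L) {
    switch(cfg$channel_mode,
           rgb_mean = (lin[, , 1] + lin[, , 2] + lin[, , 3]) / 3,
           red = lin[, , 1], green = lin[, , 2], blue = lin[, , 3])
  } else {
    if (cfg$channel_mode == "rgb_mean" && !is.matrix(px))
      stop("rgb_mean needs a 3-channel image")
    lin
  }
}

#' Ridler-Calvard (isodata) automatic threshold
#'
#' Iterates `t <- (mean below t + mean at/above t) / 2` from the global
#' mean until the change falls under `tolerance`, returning the fixed point
#' at which the threshold lies midway between the two class means. If one
#' side of the split is empty at some iterate, that side's mean is taken to
#' be the current threshold.
#'
#' @param gray Matrix of intensities in `[0, 1]` (see [to_gray()]).
#' @param mask Logical matrix of pixels to use (`TRUE` = include), e.g. the
#'   complement of a `hemi_image` `outside_mask`. `NULL` uses all pixels.
#' @param cfg A [segmentation_config()] (supplies `tolerance` and
#'   `max_iterations`).
#' @return Threshold in `[0, 1]`, with attributes `iterations` and
#'   `converged`.
#' @examples
#' g <- matrix(c(rep(0.1, 60), rep(0.9, 40)), 10, 10)
#' ridler_calvard_threshold(g)   # 0.5: midpoint of the two class means
#' @export
ridler_calvard_threshold <- function(gray, mask = NULL,
                                     cfg = segmentation_config()) {
  vals <- if (is.null(mask)) as.numeric(gray) else gray[mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L || diff(range(vals)) == 0)
    stop("degenerate histogram: need at least two distinct intensities")
  t_cur <- mean(vals)
  iter <- 0L
  converged <- FALSE
  while (iter < cfg$max_iterations) {
    iter <- iter + 1L
    below <- vals < t_cur
    m_lo <- if (any(below)) mean(vals[below]) else t_cur
    m_hi <- if (any(!below)) mean(vals[!below]) else t_cur
    t_new <- (m_lo + m_hi) / 2
    if (abs(t_new - t_cur) < cfg$tolerance) {
      t_cur <- t_new
      converged <- TRUE
      break
    }
    t_cur <- t_new
  }
  structure(t_cur, iterations = iter, converged = converged)
}

#' Binarize a grayscale image into a sky/plant mask
#'
#' @param gray Matrix in `[0, 1]`.
#' @param threshold Threshold in `[0, 1]`; pixels at or above it are sky.
#' @param outside_mask Logical matrix of pixels outside the image area
#'   (`TRUE` = outside), or `NULL` if all pixels are valid.
#' @return An object of class `binary_mask`: logical `sky` (defined on
#'   inside pixels only) and `outside_mask`.
#' @export
binarize <- function(gray, threshold, outside_mask = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  if (is.null(outside_mask))
    outside_mask <- matrix(FALSE, nrow(gray), ncol(gray))
  sky <- gray >= as.numeric(threshold)
  sky[outside_mask] <- NA
  structure(list(sky = sky, outside_mask = outside_mask,
                 threshold = as.numeric(threshold)),
            class = "binary_mask")
}

#' Segment a hemispherical image into sky and plant
#'
#' Convenience wrapper: [to_gray()], then automatic or manual thresholding,
#' then [binarize()]. If the automatic isodata threshold fails on a
#' degenerate (constant) image -- e.g. a view entirely of open sky -- the
#' manual threshold is used as a fallback.
#'
#' @param img A `hemi_image` (RGB or grayscale).
#' @param cfg A [segmentation_config()].
#' @return A `binary_mask`, with the threshold used stored alongside.
#' @export
segment_image <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(img, "hemi_image"))
  gray <- to_gray(img, cfg)
  thr <- if (cfg$threshold_mode == "manual") {
    cfg$manual_threshold
  } else {
    tryCatch(as.numeric(ridler_calvard_threshold(gray, !img$outside_mask, cfg)),
             error = function(e) cfg$manual_threshold)
  }
  binarize(gray, thr, img$outside_mask)
}
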
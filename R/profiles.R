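#' Aggregate replicate PAI measurements per capture height
#'
#' Vertical profiling repeats the photographic PAI estimate (typically
#' three times) at each capture height. Replicates are averaged
#' arithmetically, and the within-height spread is summarized as the range
#' deviation `(max - min) / mean * 100` (percent), the statistic used to
#' judge replicate consistency.
#'
#' @param measurements Either a data frame with columns `height` and `pai`
#'   (one row per replicate), or a list of lists each holding `height` and
#'   `replicate_pais`.
#' @return Data frame sorted by ascending height: `height`, `pai_mean`,
#'   `deviation_pct`, `n_replicates`. Duplicate height entries are merged
#'   with a warning.
#' @examples
#' aggregate_heights(data.frame(height = c(2, 2, 2, 4, 4, 4),
#'                              pai = c(1.9, 2.0, 2.1, 1.0, 1.1, 0.9)))
#' @export
aggregate_heights <- function(measurements) {
  if (is.data.frame(measurements)) {
    stopifnot(all(c("height", "pai") %in% names(measurements)))
    df <- measurements[, c("height", "pai")]
  } else {
    hs <- vapply(measurements, function(m) m$height, numeric(1))
    if (anyDuplicated(hs))
      warning("duplicate heights merged")
    df <- do.call(rbind, lapply(measurements, function(m) {
      stopifnot(m$height >= 0, length(m$replicate_pais) >= 1)
      data.frame(height = m$height, pai = m$replicate_pais)
    }))
  }
  stopifnot(all(df$height >= 0))
  agg <- do.call(rbind, lapply(split(df, df$height), function(d) {
    m <- mean(d$pai)
    data.frame(height = d$height[1], pai_mean = m,
               deviation_pct = if (m == 0) 0 else (max(d$pai) - min(d$pai)) / m * 100,
               n_replicates = nrow(d))
  }))
  agg <- agg[order(agg$height), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Plant area density per layer from a vertical PAI profile
#'
#' PAI measured at height z integrates all plant area above z, so the
#' density of the layer between two consecutive capture heights is the
#' downward difference divided by the layer thickness:
#' `pad = (pai_lower - pai_upper) / (z_upper - z_lower)`.
#' Negative layers arise when the upper PAI exceeds the lower one
#' (measurement noise or horizontal drift); they are kept by default
#' because clipping them to zero breaks the telescoping identity
#' `sum(pad * dz) == pai(lowest) - pai(highest)`.
#'
#' @param heights Strictly increasing capture heights, m.
#' @param pai Mean PAI at each height, m^2 m^-2.
#' @param clip_negative Set negative layer densities to zero (default
#'   `FALSE`; recorded in the `clipped` attribute when used).
#' @return Data frame with one row per layer: `z_lo`, `z_hi`, `midpoint`,
#'   `pad` (m^2 m^-3). Attribute `clipped` is `TRUE` if any layer was
#'   clipped.
#' @examples
#' pad_profile(c(1, 3), c(3, 2))   # one layer, pad = 0.5
#' @export
pad_profile <- function(heights, pai, clip_negative = FALSE) {
  stopifnot(length(heights) == length(pai), length(heights) >= 2)
  if (any(diff(heights) <= 0)) stop("heights must be strictly increasing")
  k <- length(heights)
  dz <- diff(heights)
  pad <- (pai[-k] - pai[-1]) / dz
  clipped <- clip_negative && any(pad < 0)
  if (clip_negative) pad <- pmax(pad, 0)
  out <- data.frame(z_lo = heights[-k], z_hi = heights[-1],
                    midpoint = (heights[-k] + heights[-1]) / 2,
                    pad = pad)
  attr(out, "clipped") <- clipped
  out
}

#' Vertical profile of PAI and PAD
#'
#' Bundles a set of per-height (replicate) PAI measurements into the
#' standard profile container: mean PAI vs height plus the derived
#' layer densities.
#'
#' @param measurements As in [aggregate_heights()].
#' @param clip_negative Passed to [pad_profile()].
#' @return An object of class `height_profile`: `heights`, `pai`,
#'   `deviation_pct`, `layers` (the [pad_profile()] data frame, `NULL` for
#'   a single height).
#' @export
height_profile <- function(measurements, clip_negative = FALSE) {
  agg <- aggregate_heights(measurements)
  layers <- if (nrow(agg) >= 2)
    pad_profile(agg$height, agg$pai_mean, clip_negative) else NULL
  structure(list(heights = agg$height, pai = agg$pai_mean,
                 deviation_pct = agg$deviation_pct,
                 n_replicates = agg$n_replicates, layers = layers),
            class = "height_profile")
}

#' @export
print.height_profile <- function(x, ...) {
  cat("<height_profile>\n")
  print(data.frame(height = x$heights, pai = round(x$pai, 3),
                   deviation_pct = round(x$deviation_pct, 1)))
  if (!is.null(x$layers)) {
    cat("layers:\n")
    print(data.frame(midpoint = x$layers$midpoint, pad = round(x$layers$pad, 3)))
  }
  invisible(x)
}
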
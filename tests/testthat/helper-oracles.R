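# Independent brute-force oracles: plain per-pixel / per-point loops that
# re-derive each quantity from its definition, kept free of the package's
# vectorized implementations.

# nearest-neighbour equirectangular -> hemisphere mapping, one pixel at a time
oracle_reproject_nearest <- function(px, out_size, theta_max = 90,
                                     azimuth_offset = 0) {
  h <- nrow(px); w <- ncol(px)
  out <- matrix(0, out_size, out_size)
  c0 <- (out_size + 1) / 2
  R <- out_size / 2
  for (i in seq_len(out_size)) {
    for (j in seq_len(out_size)) {
      dx <- j - c0; dy <- c0 - i
      r <- sqrt(dx^2 + dy^2)
      if (r > R) next
      phi <- (atan2(dx, dy) * 180 / pi) %% 360
      theta <- r / R * theta_max              # linear lens
      u <- ((phi + azimuth_offset) %% 360) / 360 * w
      v <- theta / 180 * h
      cc <- floor(u) + 1; if (cc > w) cc <- 1
      rr <- max(min(floor(v) + 1, h %/% 2), 1)
      out[i, j] <- px[rr, cc]
    }
  }
  out
}

# per-pixel zenith classification into annuli (linear lens), returning counts
oracle_annulus_counts <- function(out_size, n_annuli, width_deg,
                                  theta_max = 90) {
  c0 <- (out_size + 1) / 2
  R <- out_size / 2
  counts <- integer(n_annuli)
  for (i in seq_len(out_size)) {
    for (j in seq_len(out_size)) {
      r <- sqrt((j - c0)^2 + (c0 - i)^2)
      if (r > R) next
      theta <- r / R * theta_max
      k <- floor(theta / width_deg) + 1
      if (theta == n_annuli * width_deg) k <- n_annuli  # closed last edge
      if (k >= 1 && k <= n_annuli) counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# exhaustive isodata threshold: scan 256 quantized candidates for the one
# closest to satisfying t = (mean below + mean at/above) / 2
oracle_isodata_scan <- function(vals) {
  cand <- (1:255) / 256
  gap <- vapply(cand, function(t) {
    lo <- vals[vals < t]; hi <- vals[vals >= t]
    if (!length(lo) || !length(hi)) return(Inf)
    abs(t - (mean(lo) + mean(hi)) / 2)
  }, numeric(1))
  cand[which.min(gap)]
}

# horizontal-distance cylinder membership, point by point
oracle_cylinder_keep <- function(xyz, center, radius) {
  keep <- logical(nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    keep[i] <- sqrt((xyz[i, 1] - center[1])^2 +
                    (xyz[i, 2] - center[2])^2) <= radius
  }
  keep
}

# average fine-grid PAD layers within coarse layers, then sum squared residuals
oracle_compare_pad <- function(uas_layers, als_layers) {
  rss <- 0; worst <- -Inf; worst_mid <- NA_real_
  for (i in seq_len(nrow(uas_layers))) {
    vals <- c()
    for (j in seq_len(nrow(als_layers))) {
      m <- als_layers$midpoint[j]
      if (m >= uas_layers$z_lo[i] && m < uas_layers$z_hi[i])
        vals <- c(vals, als_layers$pad[j])
    }
    if (!length(vals)) next
    res <- uas_layers$pad[i] - mean(vals)
    rss <- rss + res^2
    if (abs(res) > worst) { worst <- abs(res); worst_mid <- uas_layers$midpoint[i] }
  }
  list(rss = rss, height_max_residual = worst_mid)
}

# gray image with a 60/40 two-level split, used in several threshold tests
two_level_image <- function(a = 0.1, b = 0.9) matrix(c(rep(a, 60), rep(b, 40)), 10, 10)
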
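#' Point cloud container
#'
#' @param xyz Three-column numeric matrix (x, y, z), meters; z is height
#'   above ground (clouds are assumed height-normalized on input).
#' @param source `"las"`, `"xyz"`, or `"synthetic"`.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(xyz, source = c("xyz", "las", "synthetic")) {
  source <- match.arg(source)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have three columns")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  colnames(xyz) <- c("x", "y", "z")
  structure(list(points = xyz, source = source), class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points (%s), z range %.2f-%.2f m\n",
              nrow(x$points), x$source, min(x$points[, 3]), max(x$points[, 3])))
  invisible(x)
}

#' Read a whitespace-delimited XYZ point cloud
#'
#' @param path Text file with at least three whitespace-separated numeric
#'   columns (x, y, z); extra columns are ignored.
#' @return A `point_cloud`.
#' @export
read_xyz <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) < 3L) stop("XYZ file needs at least three columns")
  point_cloud(m[, 1:3, drop = FALSE], source = "xyz")
}

#' Read point records from a LAS file
#'
#' Minimal reader for uncompressed LAS 1.0-1.4 (any point record format):
#' only the x, y, z coordinates are decoded, using the header scale and
#' offset; classification, intensity and echo fields are ignored.
#' Compressed LAZ is not supported.
#'
#' @param path Path to a `.las` file.
#' @return A `point_cloud` with `source = "las"`.
#' @export
read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file (missing LASF signature)")
  seek(con, 24)
  ver <- readBin(con, "integer", 2L, size = 1L, signed = FALSE)
  seek(con, 96)
  offset_to_points <- readBin(con, "integer", 1L, size = 4L)
  seek(con, 104)
  readBin(con, "integer", 1L, size = 1L, signed = FALSE)  # point format id
  rec_len <- readBin(con, "integer", 1L, size = 2L, signed = FALSE)
  n_legacy <- readBin(con, "integer", 1L, size = 4L)
  seek(con, 131)
  sc <- readBin(con, "double", 6L, size = 8L)  # x/y/z scale then offset
  n <- n_legacy
  if (ver[1] == 1L && ver[2] >= 4L && n == 0L) {
    seek(con, 247)
    n <- readBin(con, "double", 1L, size = 8L)  # uint64; fine below 2^53
    n <- as.integer(n)
  }
  if (n <= 0L) stop("LAS file holds no point records")
  seek(con, offset_to_points)
  raw <- readBin(con, "raw", n * rec_len)
  if (length(raw) < n * rec_len) stop("truncated LAS point data")
  rec <- matrix(raw, nrow = rec_len)
  decode_i32 <- function(rows) {
    readBin(as.vector(rec[rows, ]), "integer", n, size = 4L)
  }
  xyz <- cbind(decode_i32(1:4) * sc[1] + sc[4],
               decode_i32(5:8) * sc[2] + sc[5],
               decode_i32(9:12) * sc[3] + sc[6])
  point_cloud(xyz, source = "las")
}

#' Write a point cloud as a minimal LAS 1.2 file
#'
#' Point format 0 records with zeroed attribute fields; intended for data
#' exchange and round-trip testing of [read_las()].
#'
#' @param cloud A `point_cloud`.
#' @param path Output path.
#' @param scale Coordinate quantization step, m (default 0.001).
#' @return `path`, invisibly.
#' @export
write_las <- function(cloud, path, scale = 0.001) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  n <- nrow(p)
  off <- apply(p, 2, min)
  header_size <- 227L; rec_len <- 20L
  hdr <- raw(header_size)
  patch <- function(at, bytes) {  # 0-based byte offset
    hdr[(at + 1):(at + length(bytes))] <<- bytes
  }
  patch(0, charToRaw("LASF"))
  patch(24, as.raw(c(1L, 2L)))                              # version 1.2
  patch(94, writeBin(header_size, raw(), size = 2L))
  patch(96, writeBin(header_size, raw(), size = 4L))        # offset to points
  patch(100, writeBin(0L, raw(), size = 4L))                # no VLRs
  patch(104, as.raw(0L))                                    # point format 0
  patch(105, writeBin(rec_len, raw(), size = 2L))
  patch(107, writeBin(n, raw(), size = 4L))                 # legacy count
  patch(131, writeBin(c(rep(scale, 3), off), raw(), size = 8L))
  patch(179, writeBin(as.numeric(rbind(apply(p, 2, max), off)), raw(),
                      size = 8L))                           # max/min x, y, z
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  q <- round(sweep(p, 2, off) / scale)
  rec <- matrix(as.raw(0), nrow = rec_len, ncol = n)
  for (j in 1:3) {
    b <- writeBin(as.integer(q[, j]), raw(), size = 4L)
    rec[(4 * j - 3):(4 * j), ] <- matrix(b, nrow = 4L)
  }
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Restrict a point cloud to a vertical cylinder
#'
#' @param cloud A `point_cloud`.
#' @param center Length-2 numeric `(x, y)` of the cylinder axis.
#' @param radius Cylinder radius, m (default 10). The boundary is closed:
#'   points exactly at the radius are retained.
#' @return A `point_cloud` of the retained points.
#' @export
cylinder_filter <- function(cloud, center, radius = 10) {
  stopifnot(inherits(cloud, "point_cloud"), length(center) == 2L, radius > 0)
  d2 <- (cloud$points[, 1] - center[1])^2 + (cloud$points[, 2] - center[2])^2
  keep <- d2 <= radius^2
  if (!any(keep)) stop("no points in cylinder")
  point_cloud(cloud$points[keep, , drop = FALSE], source = cloud$source)
}

#' Canopy transmission profile from return counts
#'
#' Points below `ground_cut` are classed as ground returns; the
#' transmission at a level z is `T(z) = 1 - N_c(z) / N_t`, where `N_c(z)`
#' counts returns above z and `N_t` all returns including ground. Levels
#' are `n_levels` equally spaced layer boundaries spanning `ground_cut` to
#' the highest return, so T rises from the below-canopy transmission to 1
#' at the cloud top.
#'
#' @param cloud A `point_cloud` (height-normalized z).
#' @param n_levels Number of level boundaries (default 50).
#' @param ground_cut Ground-return height threshold, m (default 1.5).
#' @return An object of class `transmission_profile`: `levels`, `T`,
#'   `n_above`, `n_total`, `ground_cut`, `layer_width`.
#' @export
transmission_profile <- function(cloud, n_levels = 50, ground_cut = 1.5) {
  stopifnot(inherits(cloud, "point_cloud"), n_levels >= 1)
  z <- cloud$points[, 3]
  n_total <- length(z)
  zmax <- max(z)
  if (zmax <= ground_cut) stop("no canopy returns above the ground cut")
  levels <- seq(ground_cut, zmax, length.out = n_levels)
  n_above <- vapply(levels, function(l) sum(z > l), numeric(1))
  structure(list(levels = levels, T = 1 - n_above / n_total,
                 n_above = n_above, n_total = n_total,
                 ground_cut = ground_cut,
                 layer_width = if (n_levels > 1) diff(levels[1:2]) else NA_real_,
                 radius = NA_real_),
            class = "transmission_profile")
}

#' Fit a Beer's-law extinction coefficient to matched transmission and PAI
#'
#' The transmission model `T = exp(-k * PAI)` implies a through-origin
#' regression of `-ln T` on PAI; the least-squares slope is
#' `k = sum(x y) / sum(x^2)`. Photographic capture heights rarely coincide
#' with the laser level boundaries, so each PAI height is matched to the
#' nearest transmission level, and the pair is dropped if the gap exceeds
#' one layer width. Pairs with `T = 0` (no returns above) carry an infinite
#' response and are dropped with a warning.
#'
#' @param tp A `transmission_profile`, or a data frame with columns
#'   `height` and `T`.
#' @param uas_pai Data frame with columns `height` (m) and `pai`
#'   (m^2 m^-2), typically from a photographic [height_profile()].
#' @param intercept Fit an ordinary intercept model instead of the
#'   through-origin model (default `FALSE`; the physics forces PAI = 0 at
#'   T = 1).
#' @return List of class `extinction_fit`: `k`, `n_pairs`, `pairs`
#'   (matched data with residuals), `intercept` (0 for through-origin).
#' @export
fit_extinction <- function(tp, uas_pai, intercept = FALSE) {
  if (inherits(tp, "transmission_profile")) {
    levels <- tp$levels; Tv <- tp$T
    max_gap <- if (is.na(tp$layer_width)) Inf else tp$layer_width
  } else {
    stopifnot(all(c("height", "T") %in% names(tp)))
    levels <- tp$height; Tv <- tp$T
    max_gap <- if (length(levels) > 1) max(diff(sort(levels))) else Inf
  }
  stopifnot(all(c("height", "pai") %in% names(uas_pai)))
  idx <- vapply(uas_pai$height, function(h) which.min(abs(levels - h)), integer(1))
  gap <- abs(levels[idx] - uas_pai$height)
  ok <- gap <= max_gap + 1e-9
  Tm <- Tv[idx]
  zero <- ok & Tm <= 0
  if (any(zero)) {
    warning(sprintf("dropping %d pair(s) with T = 0", sum(zero)))
    ok <- ok & Tm > 0
  }
  x <- uas_pai$pai[ok]
  y <- -log(Tm[ok])
  if (sum(ok) < 2L) stop("need at least 2 usable (T, PAI) pairs")
  if (intercept) {
    fit <- stats::lm(y ~ x)
    k <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  } else {
    k <- sum(x * y) / sum(x^2); b <- 0
  }
  pairs <- data.frame(height = uas_pai$height[ok], level = levels[idx][ok],
                      pai = x, T = Tm[ok], neg_log_T = y,
                      residual = y - (b + k * x))
  structure(list(k = k, intercept = b, n_pairs = nrow(pairs), pairs = pairs),
            class = "extinction_fit")
}

#' Laser-proxy PAI and PAD profiles from a transmission profile
#'
#' Inverts `T = exp(-k PAI)` level by level: `pai(z) = -ln T(z) / k`.
#' Transmission values are floored at `1/N_t` (the resolution of the count
#' ratio) before the logarithm. Layer densities follow by downward
#' differencing between consecutive levels.
#'
#' @param tp A `transmission_profile`.
#' @param k Extinction coefficient (> 0), e.g. from [fit_extinction()].
#' @return An object of class `als_profile`: `k`, `levels`, `pai` per
#'   level, `layers` (data frame `z_lo`, `z_hi`, `midpoint`, `pad`).
#' @export
als_pai_pad <- function(tp, k) {
  stopifnot(inherits(tp, "transmission_profile"), is.numeric(k), k > 0)
  Tf <- pmax(tp$T, 1 / tp$n_total)
  pai <- -log(Tf) / k
  layers <- if (length(tp$levels) > 1)
    pad_profile(tp$levels, pai) else NULL
  structure(list(k = k, levels = tp$levels, pai = pai, T = Tf,
                 layers = layers),
            class = "als_profile")
}

#' Compare photographic and laser-proxy PAD profiles
#'
#' The laser profile is resolved on a much finer height grid (about 0.5 m)
#' than the photographic one (about 2 m), so laser layer densities are
#' first averaged within each photographic layer (a laser layer belongs to
#' the photographic layer containing its midpoint). The summary statistics
#' are the residual sum of squares over the shared layers and the height
#' (layer midpoint) of the largest absolute residual.
#'
#' @param uas A `height_profile` with at least one layer.
#' @param als An `als_profile`.
#' @return List: `rss` ((m^2 m^-3)^2 scale), `height_max_residual` (m),
#'   `layers` (per-layer comparison data frame).
#' @export
compare_pad <- function(uas, als) {
  stopifnot(inherits(uas, "height_profile"), inherits(als, "als_profile"))
  if (is.null(uas$layers) || is.null(als$layers)) stop("both profiles need layers")
  ul <- uas$layers
  al <- als$layers
  pad_als <- vapply(seq_len(nrow(ul)), function(i) {
    sel <- al$midpoint >= ul$z_lo[i] & al$midpoint < ul$z_hi[i]
    if (!any(sel)) NA_real_ else mean(al$pad[sel])
  }, numeric(1))
  ok <- !is.na(pad_als)
  if (!any(ok)) stop("no overlapping layers")
  resid <- ul$pad[ok] - pad_als[ok]
  layers <- data.frame(z_lo = ul$z_lo[ok], z_hi = ul$z_hi[ok],
                       midpoint = ul$midpoint[ok],
                       pad_uas = ul$pad[ok], pad_als = pad_als[ok],
                       residual = resid)
  list(rss = sum(resid^2),
       height_max_residual = layers$midpoint[which.max(abs(resid))],
       layers = layers)
}
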
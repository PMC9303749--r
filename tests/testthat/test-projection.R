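test_that("panorama rejects rasters that are not 2:1 equirectangular", {
  expect_error(panorama(matrix(0, 50, 99)), "width must equal 2 x height")
  expect_error(panorama(array(0, c(50, 100, 2))), "3 channels")
  expect_error(panorama(matrix(300, 50, 100)), "\\[0, 255\\]")
  expect_s3_class(panorama(matrix(0, 50, 100)), "panorama")
})

test_that("lens functions are validated, invert correctly, and round-trip", {
  lin <- lens_function()
  expect_equal(lens_forward(lin, c(0, 45, 90)), c(0, 0.5, 1))
  expect_equal(lens_inverse(lin, c(0, 0.5, 1)), c(0, 45, 90))
  poly <- lens_function("polynomial", c(1.3, -0.5, 0.2))
  theta <- seq(0, 90, by = 3)
  expect_equal(lens_inverse(poly, lens_forward(poly, theta)), theta,
               tolerance = 1e-9)
  expect_error(lens_function("polynomial", c(2, -0.5)), "sum to 1")
  expect_error(lens_function("polynomial", c(4, -5, 2)), "increasing")
})

test_that("uniform and hemisphere-split panoramas reproject to constant discs", {
  h <- reproject_to_hemisphere(panorama(matrix(200, 50, 100)), 64)
  inside <- !h$outside_mask
  expect_true(all(h$pixels[inside] == 200))
  expect_true(all(h$pixels[!inside] == 0))
  # only the upper hemisphere is ever sampled
  px <- matrix(0, 50, 100); px[1:25, ] <- 255
  for (interp in c("nearest", "bilinear")) {
    h2 <- reproject_to_hemisphere(panorama(px), 64, interpolation = interp)
    expect_true(all(h2$pixels[!h2$outside_mask] == 255), info = interp)
  }
  expect_error(reproject_to_hemisphere(panorama(matrix(0, 4, 8)), 1), ">= 2")
  expect_error(reproject_to_hemisphere(panorama(matrix(0, 4, 8)), 63), "even")
})

test_that("nearest-neighbour reprojection equals the exhaustive per-pixel oracle", {
  set.seed(11)
  px <- matrix(sample(0:255, 60 * 120, replace = TRUE), 60, 120)
  pano <- panorama(px)
  for (off in c(0, 37.5)) {
    got <- reproject_to_hemisphere(pano, 80, interpolation = "nearest",
                                   azimuth_offset = off)
    expect_equal(got$pixels, oracle_reproject_nearest(px, 80,
                                                      azimuth_offset = off),
                 info = paste("offset", off))
  }
})

test_that("a point source at zenith 45, azimuth 90 lands east at half radius", {
  px <- matrix(0, 90, 180)
  # theta 45 -> row 23 covers [44,46); azimuth 90 -> col 46 covers [90,92)
  px[23, 46] <- 255
  h <- reproject_to_hemisphere(panorama(px), 200, interpolation = "nearest")
  bright <- which(h$pixels == 255, arr.ind = TRUE)
  expect_gt(nrow(bright), 0)
  c0 <- (200 + 1) / 2
  dx <- mean(bright[, 2]) - c0
  dy <- c0 - mean(bright[, 1])
  # east of center (positive dx), no north component, r/R ~ f(45) = 0.5
  expect_lt(abs(dy), 2.5)
  expect_equal(dx / 100, 0.5, tolerance = 0.03)
})

test_that("azimuth offset rotates a point source about the center", {
  px <- matrix(0, 90, 180)
  px[23, 46] <- 255
  pano <- panorama(px)
  c0 <- (200 + 1) / 2
  pos <- function(off) {
    h <- reproject_to_hemisphere(pano, 200, interpolation = "nearest",
                                 azimuth_offset = off)
    b <- which(h$pixels == 255, arr.ind = TRUE)
    c(dx = mean(b[, 2]) - c0, dy = c0 - mean(b[, 1]))
  }
  p0 <- pos(0)
  p90 <- pos(90)
  # sampling azimuth gains 90, so the feature appears 90 deg counterclockwise:
  # (dx, dy) -> (-dy, dx)
  expect_equal(unname(p90["dx"]), unname(-p0["dy"]), tolerance = 2.5)
  expect_equal(unname(p90["dy"]), unname(p0["dx"]), tolerance = 2.5)
})

test_that("masked area matches the square-minus-disc fraction", {
  for (size in c(64, 200)) {
    h <- reproject_to_hemisphere(panorama(matrix(1, 32, 64)), size)
    expect_equal(mean(h$outside_mask), 1 - pi / 4,
                 tolerance = 2 / size)
  }
})

test_that("annuli partition the disc and counts match brute-force classification", {
  h <- reproject_to_hemisphere(panorama(matrix(1, 32, 64)), 120)
  ann <- annulus_set()
  masks <- annulus_masks(h, ann)
  idx <- annulus_index(h, ann)
  # every pixel is outside, unassigned, or in exactly one annulus
  tally <- Reduce(`+`, lapply(masks, function(m) m + 0))
  expect_true(all(tally[!h$outside_mask] %in% c(0, 1)))
  expect_true(all(tally[h$outside_mask] == 0))
  expect_true(all(is.na(idx[h$outside_mask])))
  got <- vapply(masks, sum, numeric(1))
  expect_equal(got, as.numeric(oracle_annulus_counts(120, 5, 15)))
  # linear lens: outer radii of the 5 x 15 deg annuli sit at theta/90
  theta <- hemi_theta(h)
  for (i in 1:5) {
    expect_true(all(theta[masks[[i]]] >= (i - 1) * 15))
    expect_true(all(theta[masks[[i]]] <= i * 15 + 1e-9))
  }
  expect_error(annulus_set(7, 15), "<= 90")
  h75 <- reproject_to_hemisphere(panorama(matrix(1, 16, 32)), 40,
                                 lens = lens_function(theta_max = 75))
  expect_error(annulus_index(h75, annulus_set(6, 15)), "beyond the lens")
})
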
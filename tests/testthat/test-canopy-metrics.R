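make_mask <- function(size, sky_value) {
  hemi <- reproject_to_hemisphere(panorama(matrix(200, 16, 32)), size)
  gray <- matrix(sky_value, size, size)
  binarize(gray, 0.5, hemi$outside_mask)
}

test_that("gap fractions hit 0 and 1 on all-plant and all-sky masks", {
  ann <- annulus_set()
  expect_equal(gap_fractions(make_mask(200, 1), ann)$P, rep(1, 5))
  expect_equal(gap_fractions(make_mask(200, 0), ann)$P, rep(0, 5))
  # tiny image: innermost annulus has no pixels
  expect_error(gap_fractions(make_mask(6, 1), ann), "empty annulus")
})

test_that("gap fractions of a dithered slab panorama match the Beer's-law field", {
  # g * PAI = 1, so P(theta) = exp(-1 / cos theta)
  canopy <- slab_canopy(0, 2, 1.0)
  pano <- render_panorama(canopy, render_config(camera_height = 0,
                                                pano_height = 1000, seed = 31))
  # subsample the panorama (out_size < pano height) so hemisphere pixels draw
  # from essentially distinct Bernoulli source pixels
  hemi <- reproject_to_hemisphere(pano, 500, interpolation = "nearest")
  mask <- binarize(hemi$pixels / 255, 125 / 255, hemi$outside_mask)
  gp <- gap_fractions(mask)
  # expectation per annulus: mean of P(theta) over that annulus's pixels
  theta <- hemi_theta(hemi)
  idx <- annulus_index(hemi, gp$annuli)
  for (i in 1:5) {
    th <- theta[!is.na(idx) & idx == i]
    expected <- mean(true_gap(canopy, 0, th))
    se <- sqrt(expected * (1 - expected) / gp$pixel_counts[i])
    expect_lt(abs(gp$P[i] - expected), 3 * se + 1e-6,
              label = sprintf("annulus %d: |%.4f - %.4f|", i, gp$P[i], expected))
  }
})

test_that("Miller inversion recovers spherical-canopy PAI and scales linearly", {
  ann <- annulus_set()
  expect_equal(miller_pai(gap_profile(ann, rep(1, 5)))$pai_raw, 0)
  for (L in c(0.5, 1, 3, 6)) {
    P <- exp(-0.5 * L / cos(ann$midpoints * pi / 180))
    est <- miller_pai(gap_profile(ann, P))
    expect_equal(est$pai_raw, L, tolerance = 0.01)
  }
  # 1-degree annuli: midpoint-rule error collapses
  ann1 <- annulus_set(75, 1)
  P1 <- exp(-0.5 * 3 / cos(ann1$midpoints * pi / 180))
  expect_equal(miller_pai(gap_profile(ann1, P1))$pai_raw, 3, tolerance = 0.001)
  # squaring P doubles -ln P in every annulus, hence doubles PAI exactly
  P <- exp(-0.5 * 2 / cos(ann$midpoints * pi / 180))
  expect_equal(miller_pai(gap_profile(ann, P^2))$pai_raw,
               2 * miller_pai(gap_profile(ann, P))$pai_raw)
})

test_that("saturated annuli floor at one pixel or error without a floor", {
  ann <- annulus_set()
  P <- c(0.5, 0.4, 0.3, 0.2, 0)
  expect_error(miller_pai(gap_profile(ann, P)), "saturated annulus")
  gp <- gap_profile(ann, P, pixel_counts = rep(1000L, 5))
  est <- miller_pai(gp)
  expect_equal(est$P_used[5], 1e-3)   # one-pixel floor
  expect_true(est$pai_raw > 0)
})

test_that("decreasing any gap fraction strictly increases PAI", {
  ann <- annulus_set()
  P <- exp(-0.5 * 2 / cos(ann$midpoints * pi / 180))
  base <- miller_pai(gap_profile(ann, P))$pai_raw
  for (i in 1:5) {
    P2 <- P; P2[i] <- P2[i] * 0.9
    expect_gt(miller_pai(gap_profile(ann, P2))$pai_raw, base)
  }
})

test_that("shoot clumping correction applies the 4-STAR divisor", {
  expect_equal(clumping_correct(1.0, 0.147), 1 / 0.588, tolerance = 1e-10)
  expect_equal(clumping_correct(2.0, 0.161), 2 / 0.644, tolerance = 1e-10)
  expect_equal(clumping_correct(1.7, 0.25), 1.7)   # spherical, no correction
  expect_error(clumping_correct(1.0, 0), "positive")
  expect_error(clumping_correct(1.0, -0.1), "positive")
  est <- miller_pai(gap_profile(annulus_set(), rep(0.5, 5)), star = 0.147)
  expect_equal(est$pai_clumping_corrected, est$pai_raw / (4 * 0.147))
  expect_gt(est$pai_clumping_corrected, est$pai_raw)
})

test_that("overall gap fraction is the count-weighted mean of annulus values", {
  canopy <- slab_canopy(0, 2, 1.0)
  pano <- render_panorama(canopy, render_config(pano_height = 300, seed = 5))
  hemi <- reproject_to_hemisphere(pano, 300, interpolation = "nearest")
  mask <- binarize(hemi$pixels / 255, 125 / 255, hemi$outside_mask)
  gp <- gap_fractions(mask)
  idx <- annulus_index(hemi, gp$annuli)
  union_sky <- mean(mask$sky[!is.na(idx) & idx > 0])
  expect_equal(union_sky,
               sum(gp$P * gp$pixel_counts) / sum(gp$pixel_counts))
})
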
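test_that("cylinder filter keeps the closed boundary and matches brute force", {
  xyz <- cbind(c(0, 3, 0, 10), c(0, 4, 10, 0), c(1, 2, 3, 4))
  cl <- point_cloud(xyz)
  kept <- cylinder_filter(cl, c(0, 0), 5)
  expect_equal(nrow(kept$points), 2)       # (0,0) and the 3-4-5 boundary point
  expect_true(any(kept$points[, 1] == 3))  # exactly at radius: retained
  expect_error(cylinder_filter(cl, c(100, 100), 5), "no points in cylinder")
  set.seed(21)
  big <- point_cloud(cbind(runif(500, -20, 20), runif(500, -20, 20),
                           runif(500, 0, 30)))
  keep <- oracle_cylinder_keep(big$points, c(2, -3), 10)
  expect_equal(cylinder_filter(big, c(2, -3), 10)$points,
               big$points[keep, , drop = FALSE])
})

test_that("transmission is the return-count ratio and is monotone in height", {
  # 40 ground returns, 60 canopy returns spread upward
  z <- c(rep(0.5, 40), seq(2, 20, length.out = 60))
  cl <- point_cloud(cbind(0, 0, z))
  tp <- transmission_profile(cl, n_levels = 10, ground_cut = 1.5)
  expect_equal(tp$T[1], 1 - 60 / 100)   # all canopy returns above the cut
  expect_equal(tp$T[10], 1)             # top level: nothing above
  expect_true(all(diff(tp$T) >= 0))
  expect_true(all(tp$T >= 0 & tp$T <= 1))
  expect_error(transmission_profile(point_cloud(cbind(0, 0, c(0.2, 0.4))),
                                    10, 1.5), "no canopy returns")
})

test_that("empirical transmission of a simulated cloud matches Beer's law", {
  canopy <- slab_canopy(2, 5, 1.0)   # PAI 3
  cloud <- simulate_point_cloud(canopy, k_true = 0.5, n_pulses = 50000,
                                seed = 13)
  tp <- transmission_profile(cloud, 50, 1.5)
  p <- exp(-0.5 * 3)
  se <- sqrt(p * (1 - p) / 50000)
  expect_lt(abs(tp$T[1] - p), 3 * se)
})

test_that("extinction fit matches the closed form and an independent lm fit", {
  # noiseless through-origin data
  exact <- fit_extinction(data.frame(height = 1:5, T = exp(-0.5 * (1:5))),
                          data.frame(height = 1:5, pai = 1:5))
  expect_equal(exact$k, 0.5, tolerance = 1e-12)
  # noisy data: equals sum(xy)/sum(x^2) and lm(y ~ 0 + x)
  set.seed(99)
  x <- runif(10, 0.5, 5)
  y <- 0.4 * x + rnorm(10, 0, 0.05)
  fit <- fit_extinction(data.frame(height = 1:10, T = exp(-y)),
                        data.frame(height = 1:10, pai = x))
  expect_equal(fit$k, sum(x * y) / sum(x^2), tolerance = 1e-10)
  expect_equal(fit$k, unname(coef(lm(y ~ 0 + x))), tolerance = 1e-10)
  expect_gt(fit$k, 0.3); expect_lt(fit$k, 0.5)
  # intercept variant
  fit_i <- fit_extinction(data.frame(height = 1:10, T = exp(-y)),
                          data.frame(height = 1:10, pai = x),
                          intercept = TRUE)
  expect_equal(fit_i$k, unname(coef(lm(y ~ x))[2]), tolerance = 1e-10)
})

test_that("extinction fit drops T = 0 pairs and needs two usable pairs", {
  tp <- data.frame(height = 1:3, T = c(0.5, 0, 0.1))
  uas <- data.frame(height = 1:3, pai = c(1, 2, 3))
  expect_warning(fit <- fit_extinction(tp, uas), "T = 0")
  expect_equal(fit$n_pairs, 2)
  expect_error(suppressWarnings(
    fit_extinction(data.frame(height = 1:2, T = c(0.5, 0)),
                   data.frame(height = 1:2, pai = c(1, 2)))),
    "at least 2")
})

test_that("transmission inverts to PAI with flooring, and profiles compare", {
  z <- c(rep(0.5, 50), seq(2, 10, length.out = 50))
  tp <- transmission_profile(point_cloud(cbind(0, 0, z)), 20, 1.5)
  als <- als_pai_pad(tp, k = 0.5)
  expect_equal(als$pai, -log(pmax(tp$T, 1 / 100)) / 0.5)
  expect_equal(als$pai[length(als$pai)], 0)   # T = 1 at the top
  expect_true(all(diff(als$pai) <= 1e-12))    # non-increasing with height
  # closed form: T = e^-1 with k = 0.5 gives PAI 2
  tp1 <- structure(list(levels = c(1.5, 10), T = c(exp(-1), 1),
                        n_above = c(10, 0), n_total = 20, ground_cut = 1.5,
                        layer_width = 8.5), class = "transmission_profile")
  expect_equal(als_pai_pad(tp1, 0.5)$pai[1], 2)
})

test_that("PAD comparison equals the brute-force per-layer averaging", {
  uas <- height_profile(data.frame(height = rep(c(0, 2, 4, 6), each = 1),
                                   pai = c(4, 2.6, 1.2, 0.2)))
  z <- c(rep(0.5, 100), seq(2, 7, length.out = 200))
  tp <- transmission_profile(point_cloud(cbind(0, 0, z)), 30, 1.5)
  als <- als_pai_pad(tp, 0.45)
  got <- compare_pad(uas, als)
  want <- oracle_compare_pad(uas$layers, als$layers)
  expect_equal(got$rss, want$rss)
  expect_equal(got$height_max_residual, want$height_max_residual)
  # identical profiles have zero RSS; a constant offset accumulates exactly
  self <- list(layers = uas$layers, k = 1)
  class(self) <- "als_profile"
  expect_equal(compare_pad(uas, self)$rss, 0)
  shifted <- uas$layers; shifted$pad <- shifted$pad + 0.1
  off <- list(layers = shifted, k = 1)
  class(off) <- "als_profile"
  expect_equal(compare_pad(uas, off)$rss, 3 * 0.1^2)
})

test_that("LAS files round-trip through the minimal reader and writer", {
  set.seed(55)
  pts <- cbind(runif(200, 500000, 500100), runif(200, 6800000, 6800100),
               runif(200, 0, 35))
  cl <- point_cloud(pts)
  f <- tempfile(fileext = ".las")
  write_las(cl, f)
  back <- read_las(f)
  expect_equal(back$source, "las")
  expect_equal(back$points, cl$points, tolerance = 1e-3)  # quantization step
  expect_error(read_las(system.file("DESCRIPTION", package = "canopysphere")),
               "LASF")
})

test_that("XYZ text clouds read with extra columns ignored", {
  f <- tempfile(fileext = ".xyz")
  write.table(cbind(1:5, 6:10, 11:15, 99), f, row.names = FALSE,
              col.names = FALSE)
  cl <- read_xyz(f)
  expect_equal(unname(cl$points[, 3]), 11:15 + 0)
})
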
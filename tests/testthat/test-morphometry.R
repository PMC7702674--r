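test_that("compactness counts bone pixels over the filled silhouette", {
  expect_equal(compactness(disc_mask(10L)), 1.0)

  # ring: 10x10 filled interior, 16 cavity pixels, away from the border
  m <- matrix(0L, 14, 14)
  m[3:12, 3:12] <- 1L
  m[6:9, 6:9] <- 0L
  expect_equal(compactness(m), (100 - 16) / 100)

  expect_error(compactness(matrix(0L, 5, 5)), "no foreground")
})

test_that("compactness is invariant to translation and rotation and falls with cavities", {
  m <- matrix(0L, 20, 20)
  m[5:15, 4:16] <- 1L
  m[8:9, 8:10] <- 0L
  c0 <- compactness(m)
  shifted <- matrix(0L, 26, 26)
  shifted[9:19, 10:22] <- m[5:15, 4:16]                  # translation
  expect_equal(compactness(shifted), c0)
  rot90 <- t(m)[ncol(m):1, ]                             # 90-degree rotation
  expect_equal(compactness(rot90), c0)
  m2 <- m
  m2[12, 12] <- 0L                                       # one more cavity px
  expect_lt(compactness(m2), c0)
})

test_that("mean local thickness matches disc diameter, bar width, and the brute-force oracle", {
  d <- disc_mask(10L)                                    # diameter 20 px
  expect_equal(mean_thickness(section_mask(d, 0.01, "frontal", 1L)), 0.20,
               tolerance = 0.01)

  b <- bar_mask(8L, 200L)
  th <- mean_thickness(section_mask(b, 0.01, "nasal", 1L))
  expect_equal(th, 0.08, tolerance = 0.002)              # small end effects

  # fill-first contract: a disc with an interior hole measures like a solid one
  hole <- disc_mask(10L)
  ctr <- which(hole == 1L, arr.ind = TRUE)
  hole[12:14, 12:14] <- 0L
  expect_equal(mean_thickness(section_mask(hole, 0.01, "frontal", 1L)),
               mean_thickness(section_mask(disc_mask(10L), 0.01, "frontal", 1L)))

  # brute-force disc-coverage oracle on small random masks
  set.seed(21)
  for (i in 1:4) {
    m <- matrix(0L, 24, 24)
    m[sample(4:20, 1):sample(21:23, 1), 4:20] <- 1L
    m[sample(8:16, 2), sample(8:16, 2)] <- 0L
    m <- fill_mask_holes(m)
    expect_equal(local_thickness(m), oracle_local_thickness(m),
                 tolerance = 1e-10)
  }
})

test_that("cranial profile is cumulative normalized chord length", {
  pts <- cbind(seq(0, 9), 0)
  expect_equal(build_profile(pts)$s, seq(0, 1, by = 1 / 9))

  tri <- rbind(c(0, 0), c(3, 0), c(3, 4))
  expect_equal(build_profile(tri)$s, c(0, 3 / 7, 1))
  expect_equal(build_profile(tri)$length_mm, 7)

  expect_equal(build_profile(rbind(c(0, 0), c(2, 0)))$s, c(0, 1))
  expect_error(build_profile(rbind(c(0, 0), c(0, 0), c(1, 1))), "zero-length")
  expect_error(build_profile(rbind(c(0, 0))), "at least 2")
})

test_that("anteroposterior overlap reproduces its anchors and the long form", {
  # centred equal-length bones: 100%
  expect_equal(overlap(2, 2, -(2 + 2) / 6), 100)
  # exactly abutting bones: 0%
  expect_equal(overlap(1.2, 1.8, (1.2 + 1.8) / 3), 0)
  expect_equal(overlap(3, 3, 1), 100 / 3)
  expect_error(overlap(0, 1, 0), "positive")

  # algebraic identity between the long and the reduced form
  set.seed(31)
  for (i in 1:50) {
    LA <- runif(1, 0.1, 10); LB <- runif(1, 0.1, 10)
    delta <- rnorm(1, 0, 3)
    long <- 100 * (((LA + LB) / 2 - (delta + LA / 6 + LB / 6)) / ((LA + LB) / 2))
    expect_equal(overlap(LA, LB, delta), long, tolerance = 1e-12)
  }
})

test_that("scalar traits follow the geometric-mean diameter definitions", {
  s <- scalar_traits(12, 4, 9, 2, 4)
  expect_equal(s$dia, 6)
  expect_equal(s$elo, 2)
  expect_equal(s$rfp, 0.5)
  expect_error(scalar_traits(12, -4, 9, 2, 4), "positive")
})

test_that("thickness integral handles constant, linear and sparse profiles", {
  expect_equal(thickness_integral(c(0.1, 0.5, 0.9), c(3, 3, 3)), 1.5)

  s <- seq(0.005, 0.995, length.out = 200)
  expect_equal(thickness_integral(s, 100 * s), 12.5, tolerance = 1e-3 * 12.5)

  # constant extrapolation to s = 0 plus exact trapezoids
  s5 <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_equal(thickness_integral(s5, 100 * s5), 13.0)
  expect_equal(thickness_integral(s5, 100 * s5, extrapolate = "truncate"), 12.0)

  expect_error(thickness_integral(c(0.6, 0.8), c(1, 2)), "0.5")
  expect_error(thickness_integral(c(0.2, 0.2), c(1, 2)), "increasing")
})

test_that("log-compactness transform fixes its anchor points and is monotone", {
  expect_equal(log_compactness(0), 0)
  expect_equal(log_compactness(100), log10(21), tolerance = 1e-12)
  expect_equal(log_compactness(52.5), log10(2), tolerance = 1e-12)
  x <- seq(0, 100, by = 0.5)
  expect_true(all(diff(log_compactness(x)) > 0))
  expect_error(log_compactness(106), "105")
})

test_that("LOESS profile is exact on linear data and smooths noise", {
  x <- seq(0, 1, length.out = 30)
  fit <- loess_profile(x, 2 + 3 * x, span = 0.6)
  expect_lt(max(abs(fit$fitted - (2 + 3 * fit$grid))), 1e-8)

  fitc <- loess_profile(x, rep(5, 30), span = 0.75)
  expect_lt(max(abs(fitc$fitted - 5)), 1e-8)

  set.seed(41)
  xd <- seq(0, 1, length.out = 150)
  truth <- sin(2 * pi * xd)
  noisy <- truth + rnorm(150, 0, 0.6)
  fs <- loess_profile(xd, noisy, span = 0.75, n_grid = 150L)
  rmse_fit <- sqrt(mean((fs$fitted - sin(2 * pi * fs$grid))^2))
  expect_lt(rmse_fit, sqrt(mean((noisy - truth)^2)))
  expect_error(loess_profile(x[1:3], noisy[1:3]), "at least 4")
})

test_that("specimen_traits orchestrates the full measurement chain", {
  bones <- c("premaxilla", "nasal", "frontal", "parietal")
  solid <- bar_mask(10L, 40L)
  masks <- setNames(
    lapply(seq_len(8L), function(j)
      section_mask(solid, 0.02, rep(bones, each = 2L)[j], rep(1:2, 4L)[j])),
    paste0(rep(bones, each = 2L), rep(1:2, 4L)))
  sections <- data.frame(
    bone = rep(bones, each = 2L), section_index = rep(1:2, 4L),
    s_position = c(0.03, 0.06, 0.2, 0.3, 0.45, 0.6, 0.7, 0.9),
    bone_length_mm = rep(c(0.9, 3, 4.5, 6), each = 2L))
  dims <- list(l_cran = 10, w_cran = 4, h_cran = 4)
  tv <- specimen_traits(masks, sections, dims, taxon = "tx")
  expect_equal(tv$c, 1.0)
  expect_equal(tv$dia, 4)
  expect_equal(tv$elo, 2.5)
  expect_equal(tv$rfp, 4.5 / 6)
  expect_false(tv$missing)
  expect_equal(tv$n_sections, 8L)

  tv7 <- specimen_traits(masks[-3L], sections, dims, taxon = "tx")
  expect_true(tv7$missing)
  expect_equal(tv7$n_sections, 7L)
  expect_equal(tv7$c, 1.0)
})
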
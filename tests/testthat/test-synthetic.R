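test_that("fraction fields close to one and are seed-deterministic", {
  cfg <- sceneConfig(n_rows = 24, n_cols = 24, seed = 5, months = 1L)
  fr1 <- generateFractions(cfg)
  fr2 <- generateFractions(cfg)
  expect_identical(fr1, fr2)
  sums <- apply(fr1, 1:2, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_true(all(fr1 >= 0 & fr1 <= 1))
  # neighbouring pixels are similar (spatial autocorrelation)
  d_neighbour <- mean(abs(fr1[-1, , 1] - fr1[-nrow(fr1), , 1]))
  d_shuffled <- mean(abs(outer(as.vector(fr1[, , 1]),
                               as.vector(fr1[, , 1]), "-")))
  expect_lt(d_neighbour, d_shuffled / 2)
})

test_that("surface variables are exact mixtures when noiseless", {
  cfg <- sceneConfig(n_rows = 10, n_cols = 10, seed = 2, months = 1:3)
  truth <- generateGroundTruth(cfg, spatial_sd = 0.02)
  k <- dim(truth@pureValues)[3L]
  # fully covered pixel equals the pure value
  frac <- array(0, c(10, 10, k),
                dimnames = list(NULL, NULL, truth@classLabels))
  frac[, , 3] <- 1
  y <- generateSurfaceVariable(frac, truth, noise_sd = 0)
  expect_equal(y[4, 7, 2], unname(truth@pureValues[4, 7, 3, 2]),
               tolerance = 1e-15)
  # generic composition: dot product of fractions and pure values
  fr <- generateFractions(cfg)
  y2 <- generateSurfaceVariable(fr, truth, noise_sd = 0)
  i <- 6; j <- 9; m <- 3
  expect_equal(y2[i, j, m],
               sum(fr[i, j, ] * truth@pureValues[i, j, , m]),
               tolerance = 1e-12)
})

test_that("observation noise has the requested standard deviation", {
  cfg <- sceneConfig(n_rows = 100, n_cols = 100, seed = 8, months = 1L)
  k <- cfg@nVegClasses + cfg@nNonvegClasses
  labels <- c(sprintf("V%02d", 1:4), sprintf("N%02d", 1:4))
  # identical composition and spatially uniform truth: all variation is noise
  frac <- array(1 / k, c(100, 100, k), dimnames = list(NULL, NULL, labels))
  truth <- generateGroundTruth(cfg, spatial_sd = 0)
  y <- generateSurfaceVariable(frac, truth, noise_sd = 0.05, seed = 9)
  expect_lt(abs(sd(as.vector(y)) - 0.05) / 0.05, 0.05)
})

test_that("DEM generator: flat scenes, determinism, relief drives masking", {
  cfg <- sceneConfig(n_rows = 20, n_cols = 20, seed = 4, months = 1L)
  flat <- generateDEM(cfg, relief_amplitude = 0)
  expect_true(all(flat$mu_h == flat$mu_h[1, 1]))
  expect_true(all(flat$sigma_h == 0))
  d1 <- generateDEM(cfg, relief_amplitude = 500, relief_scale = 3)
  d2 <- generateDEM(cfg, relief_amplitude = 500, relief_scale = 3)
  expect_identical(d1, d2)
  expect_true(all(d1$sigma_h >= 0))
  ind <- topoIndicators(d1$mu_h, d1$sigma_h)
  keep <- topoMask(ind)
  interior <- matrix(FALSE, 20, 20); interior[3:18, 3:18] <- TRUE
  expect_gt(sum(!keep & interior), 0)
})

test_that("coarse radiation fields are constant when unsmoothed", {
  cfg <- sceneConfig(n_rows = 40, n_cols = 40, seed = 1, months = 1:2)
  rad <- generateCoarseRadiation(cfg, sw_down = 200, lw_ratio = 1)
  expect_true(all(rad@swDown == 200))
  expect_identical(rad@lwUpAllsky, rad@lwUpClearsky)  # ratio 1: identity
  expect_error(generateCoarseRadiation(cfg, sw_down = -1), "non-negative")
  expect_error(generateCoarseRadiation(cfg, lw_ratio = 0), "lw_ratio")
})

test_that("true transition delta is antisymmetric and zero on identity", {
  cfg <- sceneConfig(n_rows = 8, n_cols = 8, seed = 6, months = 1L)
  truth <- generateGroundTruth(cfg)
  lab <- truth@classLabels
  expect_identical(trueTransitionDelta(truth, lab[1], lab[1], c(2, 2), 1), 0)
  ab <- trueTransitionDelta(truth, lab[1], lab[2], c(3, 5), 1)
  ba <- trueTransitionDelta(truth, lab[2], lab[1], c(3, 5), 1)
  expect_identical(ab, -ba)
  expect_error(trueTransitionDelta(truth, "nope", lab[1], c(1, 1), 1),
               "unknown class")
})

test_that("deterministic fixtures span the simplex edge as intended", {
  frac <- edgeGradientFractions(5, 5)
  # one window-wide map: presences sample the edge evenly
  pa <- as.vector(frac[, , "FOR"]); pb <- as.vector(frac[, , "SHR"])
  expect_gt(cooccurrenceIndex(pa, pb), 0.9)
  chk <- checkerboardFractions(6, 6)
  sums <- apply(chk, 1:2, sum)
  expect_true(all(sums == 1))
  expect_true(all(chk %in% c(0, 1)))
})
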
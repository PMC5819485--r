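test_that("distinct-composition counting uses 6-decimal rounding", {
  X <- matrix(rep(c(0.5, 0.5), each = 25), 25, 2)
  expect_identical(distinctCompositions(X), 1L)
  X2 <- spreadWindow(seed = 1)
  expect_identical(distinctCompositions(X2), 25L)
  X3 <- rbind(X2, X2[1, ] + c(1e-9, -1e-9, 0, 0))
  expect_identical(distinctCompositions(X3), 25L)
})

test_that("local fit refuses windows that fail the distinct gate", {
  base <- spreadWindow(seed = 2)
  # 9 distinct rows out of 25: below the gate
  X9 <- base[c(rep(1:9, 2), rep(1, 7)), ]
  expect_null(fitLocalModel(X9, rnorm(25)))
  # 10 distinct rows: at the gate, fitted
  X10 <- base[c(rep(1:10, 2), rep(1, 5)), ]
  expect_s4_class(fitLocalModel(X10, mixResponse(X10, c(3, 7, 1, 2))),
                  "LocalRegressionModel")
  # missing data anywhere in the window: skip signal
  Xna <- base; Xna[3, 1] <- NA
  expect_null(fitLocalModel(Xna, rnorm(25)))
  yna <- rnorm(25); yna[12] <- NA
  expect_null(fitLocalModel(base, yna))
})

test_that("constant response gives an intercept-only model", {
  X <- spreadWindow(seed = 3)
  m <- fitLocalModel(X, rep(4.2, 25))
  expect_equal(m@beta[1], 4.2)
  expect_equal(m@beta[-1], rep(0, m@nRetained), tolerance = 1e-12)
  pr <- predictPure(m, colnames(X)[1:2])
  expect_equal(unname(purePredictionValues(pr)), c(4.2, 4.2))
  expect_lt(max(abs(predictionCovariance(pr))), 1e-20)
})

test_that("noiseless mixtures are recovered exactly", {
  X <- spreadWindow(seed = 4)
  pure <- c(3, 7, 1, 2)
  m <- fitLocalModel(X, mixResponse(X, pure))
  pr <- predictPure(m, colnames(X))
  expect_equal(unname(purePredictionValues(pr)), pure, tolerance = 1e-9)
})

test_that("coefficients match a brute-force normal-equations solve", {
  X <- spreadWindow(seed = 5)
  y <- mixResponse(X, c(0.3, 0.1, 0.25, 0.2), noise_sd = 0.02, seed = 6)
  m <- fitLocalModel(X, y)
  Z <- cbind(1, sweep(X, 2, m@M) %*% m@Vz)
  beta_bf <- solve(t(Z) %*% Z, t(Z) %*% y)
  expect_equal(m@beta, drop(beta_bf), tolerance = 1e-10)
})

test_that("pure predictions equal a pseudoinverse fit without the SVD
           shortcut", {
  X <- spreadWindow(seed = 7)
  y <- mixResponse(X, c(10, 20, 5, 8), noise_sd = 0.5, seed = 8)
  m <- fitLocalModel(X, y)
  pr <- predictPure(m, colnames(X))
  # independent route: minimum-norm least squares on the centred fractions
  Xc <- cbind(1, sweep(X, 2, colMeans(X)))
  beta_mn <- MASS::ginv(Xc) %*% y
  P <- cbind(1, diag(ncol(X)) - matrix(colMeans(X), ncol(X), ncol(X),
                                       byrow = TRUE))
  expect_equal(unname(purePredictionValues(pr)),
               drop(P %*% beta_mn), tolerance = 1e-10)
})

test_that("transition estimates are antisymmetric with correct uncertainty
           algebra", {
  X <- spreadWindow(seed = 9)
  y <- mixResponse(X, c(1, 4, 2, 3), noise_sd = 0.1, seed = 10)
  pr <- predictPure(fitLocalModel(X, y), colnames(X)[1:2])
  te <- transitionEstimates(pr, igbpGen())
  expect_equal(nrow(te), 1L)
  expect_equal(te$delta,
               unname(diff(purePredictionValues(pr))), tolerance = 1e-14)
  S <- predictionCovariance(pr)
  expect_equal(te$sd, sqrt(S[1, 1] + S[2, 2] - 2 * S[1, 2]),
               tolerance = 1e-14)
  # hand-built covariance cases
  mk <- function(S, yp) new("PurePredictions",
    yp = setNames(yp, c("FOR", "SHR")), Sigma = S,
    classes = c("FOR", "SHR"))
  # independent predictions with variances 9 and 16 -> sd 5
  t1 <- transitionEstimates(mk(diag(c(9, 16)), c(0, 1)), igbpGen())
  expect_equal(t1$sd, 5)
  # perfectly correlated equal-variance predictions -> sd 0
  t2 <- transitionEstimates(mk(matrix(4, 2, 2), c(2, 2)), igbpGen())
  expect_equal(t2$sd, 0)
  expect_equal(t2$delta, 0)
})

test_that("moving window honours completeness and window membership", {
  cfg <- sceneConfig(n_rows = 14, n_cols = 14, noise_sd = 0, months = 1L,
                     seed = 12)
  scene <- generateScene(cfg, truth_spatial_sd = 0)
  frac <- coverFractions(scene)
  y <- sceneVariable(scene, "LE")
  tm <- runMovingWindow(frac, y, scene@scheme, months = 1L)
  d <- deltaLayer(tm)[, , 1, 1]
  # 2-pixel rim has no estimates, interior is fully estimated
  expect_true(all(is.na(d[1:2, ])) && all(is.na(d[, 13:14])))
  expect_true(all(!is.na(d[3:12, 3:12])))
  # one missing observation invalidates exactly the windows containing it
  y2 <- y; y2[7, 8, 1] <- NA
  tm2 <- runMovingWindow(frac, y2, scene@scheme, months = 1L)
  d2 <- deltaLayer(tm2)[, , 1, 1]
  lost <- which(is.na(d2) & !is.na(d), arr.ind = TRUE)
  expect_true(all(abs(lost[, 1] - 7) <= 2 & abs(lost[, 2] - 8) <= 2))
  expect_identical(nrow(lost), 25L)
  expect_true(all(uncertaintyLayer(tm)[!is.na(uncertaintyLayer(tm))] >= 0))
})

test_that("moving-window estimates recover spatially uniform truth", {
  cfg <- sceneConfig(n_rows = 20, n_cols = 20, noise_sd = 0, months = 1:2,
                     seed = 13)
  scene <- generateScene(cfg, truth_spatial_sd = 0)
  tm <- runMovingWindow(coverFractions(scene), sceneVariable(scene, "LE"),
                        scene@scheme, months = cfg@months)
  expect_lt(recoveryError(tm, groundTruth(scene, "LE"), scene@scheme), 1e-8)
})
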
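test_that("window overlap fractions follow window geometry", {
  expect_equal(windowOverlap(c(10, 10), c(10, 10)), 1.0)
  expect_equal(windowOverlap(c(10, 10), c(10, 11)), 20 / 25)
  expect_equal(windowOverlap(c(10, 10), c(15, 10)), 0.0)
  expect_equal(windowOverlap(c(10, 10), c(12, 12)), 9 / 25)
  # the largest shared count between distinct windows is 20 pixels
  offs <- expand.grid(dr = -6:6, dc = -6:6)
  offs <- offs[offs$dr != 0 | offs$dc != 0, ]
  shared <- mapply(function(dr, dc)
    25 * windowOverlap(c(50, 50), c(50 + dr, 50 + dc)), offs$dr, offs$dc)
  expect_equal(max(shared), 20)
  # overlap matrix for a full 20x20 cell is 400 x 400, symmetric, unit diag
  centers <- as.matrix(expand.grid(1:20, 1:20))
  R <- overlapMatrix(centers)
  expect_identical(dim(R), c(400L, 400L))
  expect_equal(R, t(R))
  expect_true(all(diag(R) == 1))
  expect_true(all(R >= 0 & R <= 1))
})

test_that("inverse-variance aggregation follows the classical formulas", {
  expect_equal(inverseVarianceAggregate(c(2, 4), c(1, 1)),
               list(delta = 3, sd = 1 / sqrt(2)))
  # equal uncertainties: simple mean
  r <- inverseVarianceAggregate(c(1, 2, 6), c(3, 3, 3))
  expect_equal(r$delta, 3)
  # dominance of the precise member
  r2 <- inverseVarianceAggregate(c(5, -100), c(1, 1e6))
  expect_equal(r2$delta, 5, tolerance = 1e-6)
  expect_error(inverseVarianceAggregate(c(1, 2), c(1, 0)), "positive")
})

test_that("GLS aggregation reduces to inverse variance when windows do not
           overlap", {
  set.seed(41)
  for (r in 1:10) {
    n <- sample(2:30, 1)
    deltas <- rnorm(n)
    sds <- runif(n, 0.5, 3)
    g <- glsAggregate(deltas, sds, diag(n))
    iv <- inverseVarianceAggregate(deltas, sds)
    expect_equal(g$delta, iv$delta, tolerance = 1e-10)
    expect_equal(g$sd, iv$sd, tolerance = 1e-10)
    expect_equal(sum(g$weights), 1, tolerance = 1e-10)
  }
})

test_that("GLS handles single members and equicorrelated pairs exactly", {
  g1 <- glsAggregate(2.5, 0.7)
  expect_equal(g1$delta, 2.5)
  expect_equal(g1$sd, 0.7)
  # two members, equal sd s, overlap rho: var = s^2 (1 + rho) / 2
  s <- 1.3
  for (rho in c(0, 0.2, 0.8)) {
    g <- glsAggregate(c(1, 3), c(s, s), matrix(c(1, rho, rho, 1), 2))
    expect_equal(g$delta, 2)
    expect_equal(g$sd^2, s^2 * (1 + rho) / 2, tolerance = 1e-12)
  }
})

test_that("window overlap inflates the uncertainty of homogeneous
           estimates", {
  # with equal member sds, positive overlap correlation can only increase
  # the aggregated uncertainty relative to treating members as independent
  # (with heterogeneous sds GLS may legitimately exploit the correlation)
  set.seed(42)
  for (r in 1:20) {
    nn <- sample(3:8, 1)
    pts <- as.matrix(expand.grid(seq_len(nn), seq_len(nn)))
    sel <- sample(nrow(pts), sample(2:nrow(pts), 1))
    R <- overlapMatrix(pts[sel, , drop = FALSE])
    n <- nrow(R)
    deltas <- rnorm(n)
    sds <- rep(runif(1, 0.5, 2), n)
    g <- glsAggregate(deltas, sds, R)
    iv <- inverseVarianceAggregate(deltas, sds)
    expect_gte(g$sd + 1e-12, iv$sd)
    # exact-preserving: constant member values aggregate to that constant
    gc <- glsAggregate(rep(1.7, n), sds, R)
    expect_equal(gc$delta, 1.7, tolerance = 1e-10)
  }
})

test_that("aggregated uncertainty is calibrated under correlated noise", {
  set.seed(43)
  centers <- as.matrix(expand.grid(1:10, 1:10))
  R <- overlapMatrix(centers)
  n <- nrow(centers)
  sds <- runif(n, 0.8, 1.2)
  Sigma <- R * tcrossprod(sds)
  L <- t(chol(Sigma))
  n_rep <- 10000L
  means <- numeric(n_rep)
  g <- glsAggregate(rnorm(n), sds, R)
  for (r in seq_len(n_rep)) {
    x <- drop(L %*% rnorm(n))          # zero-mean correlated estimates
    means[r] <- sum(g$weights * x)
  }
  expect_lt(abs(sd(means) - g$sd) / g$sd, 0.10)
})

test_that("cell filtering enforces the sample floor and the outlier fence", {
  delta <- matrix(0.1, 2, 2)
  n19 <- toyDataset(delta, matrix(c(19, 20, 25, 40), 2, 2))
  f <- filterCells(n19, quiet = TRUE)
  expect_true(is.na(deltaLayer(f)[1, 1, 1, 1]))     # 19 samples: removed
  expect_false(is.na(deltaLayer(f)[2, 1, 1, 1]))    # 20 samples: kept
  expect_identical(unname(attr(f, "filter_counts")[["low_n"]]),
                   6L)                               # one cell x 6 iTr
  # a value 100x the rest trips the pooled 3*IQR fence
  dd <- matrix(rnorm(64, 1, 0.1), 8, 8)
  dd[4, 4] <- 100
  big <- toyDataset(dd, matrix(30, 8, 8))
  fb <- filterCells(big, quiet = TRUE)
  expect_true(all(is.na(deltaLayer(fb)[4, 4, 1, ])))
  expect_false(any(is.na(deltaLayer(fb)[1, , 1, ])))
})

test_that("aggregation of transition maps respects masks and counts", {
  cfg <- sceneConfig(n_rows = 20, n_cols = 20, noise_sd = 0.005,
                     months = 1L, seed = 44)
  scene <- generateScene(cfg, truth_spatial_sd = 0)
  tm <- runMovingWindow(coverFractions(scene), sceneVariable(scene, "LE"),
                        scene@scheme, months = 1L)
  ds <- aggregateTransitions(tm, variable = "LE")
  # 16x16 interior estimates per transition in the single coarse cell
  expect_identical(dim(deltaLayer(ds)), c(1L, 1L, 1L, 6L))
  expect_true(all(sampleCount(ds) == 256L))
  # a full mask empties the cell
  ds0 <- aggregateTransitions(tm, keep = matrix(FALSE, 20, 20),
                              variable = "LE")
  expect_true(all(is.na(deltaLayer(ds0))))
  expect_true(all(sampleCount(ds0) == 0L))
})
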
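test_that("co-occurrence index extremes and midpoint", {
  # both classes absent everywhere: worst case, index 0
  expect_equal(cooccurrenceIndex(rep(0, 25), rep(0, 25)), 0)
  # presences exactly on the ideal line: index 1
  qa <- seq(0, 1, length.out = 11)
  expect_equal(cooccurrenceIndex(qa, 1 - qa), 1)
  # sum(d_min) = sum(d_max)/2 gives exactly 0.5: with two ideal points
  # (0,1) and (1,0), presences at (0, 0.5) and (0.5, 0) are each nearest to
  # one ideal point at exactly half its origin distance
  expect_equal(cooccurrenceIndex(c(0, 0.5), c(0.5, 0), n_q = 2L), 0.5)
  # same property at the default n_q: scale the ideal points towards the
  # origin by the factor (found with the independent direct oracle) at which
  # the summed nearest distances reach half the reference sum
  ic_scaled <- function(c) directCooccurrence(c * qa, c * (1 - qa)) - 0.5
  cc <- uniroot(ic_scaled, c(0.05, 0.95), tol = 1e-12)$root
  expect_equal(cooccurrenceIndex(cc * qa, cc * (1 - qa)), 0.5,
               tolerance = 1e-9)
  expect_error(cooccurrenceIndex(numeric(0), numeric(0)), "empty")
})

test_that("co-occurrence index agrees with a direct loop evaluation", {
  set.seed(31)
  for (r in 1:20) {
    pa <- runif(25, 0, 0.7)
    pb <- pmin(runif(25, 0, 0.7), 1 - pa)
    expect_equal(cooccurrenceIndex(pa, pb), directCooccurrence(pa, pb))
  }
})

test_that("co-occurrence index is symmetric and permutation-invariant", {
  set.seed(32)
  pa <- runif(25, 0, 0.5); pb <- runif(25, 0, 0.5)
  expect_equal(cooccurrenceIndex(pa, pb), cooccurrenceIndex(pb, pa))
  o <- sample(25)
  expect_equal(cooccurrenceIndex(pa, pb), cooccurrenceIndex(pa[o], pb[o]))
})

test_that("co-occurrence mask keeps windows with balanced presences", {
  # one class absent: its windows are dropped at the 0.5 threshold
  frac <- edgeGradientFractions(9, 9)
  frac[, , "SHR"] <- 0
  frac[, , "WET"] <- 1 - frac[, , "FOR"]
  m0 <- cooccurrenceMask(frac, "FOR", "SHR")
  expect_false(any(m0))
  # checkerboard of the pair: kept (index 0.613 at n_q = 11)
  chk <- checkerboardFractions(9, 9)
  m1 <- cooccurrenceMask(chk, "FOR", "SHR")
  expect_true(all(m1[3:7, 3:7]))
  expect_false(any(m1[1:2, ]))   # rim windows never computable
  # threshold 0: every computable window kept
  m2 <- cooccurrenceMask(chk, "FOR", "SHR", threshold = 0)
  expect_true(all(m2[3:7, 3:7]))
  # masks are idempotent by construction (logical AND with itself)
  expect_identical(m1 & m1, m1)
})

test_that("topographic indicators evaluate windows correctly", {
  mu <- matrix(0, 9, 9); sg <- matrix(0, 9, 9)
  ind <- topoIndicators(mu, sg)
  expect_equal(ind$v1[5, 5], 0)
  expect_equal(ind$v2[5, 5], 0)
  expect_equal(ind$v3[5, 5], 0)
  # centre mean elevation 600 among 450s: v2 from the definition
  mu3 <- matrix(450, 5, 5); mu3[3, 3] <- 600
  ind3 <- topoIndicators(mu3, matrix(0, 5, 5))
  expect_equal(ind3$v2[3, 3], abs(600 - mean(mu3)))
  # centre sigma 120, rest 0: v1 = 4.8, v3 = 115.2
  sg4 <- matrix(0, 5, 5); sg4[3, 3] <- 120
  ind4 <- topoIndicators(matrix(0, 5, 5), sg4)
  expect_equal(ind4$v1[3, 3], 4.8)
  expect_equal(ind4$v3[3, 3], 115.2)
})

test_that("topographic mask applies strict thresholds", {
  mk <- function(v1, v2, v3) list(v1 = matrix(v1), v2 = matrix(v2),
                                  v3 = matrix(v3))
  expect_true(topoMask(mk(0, 0, 0))[1, 1])
  expect_false(topoMask(mk(50, 0, 0))[1, 1])     # v1 bound is strict
  expect_false(topoMask(mk(0, 100, 0))[1, 1])
  expect_false(topoMask(mk(0, 0, 100))[1, 1])
  expect_true(topoMask(mk(49.9, 99.9, 99.9))[1, 1])
  expect_false(topoMask(mk(NA, 0, 0))[1, 1])     # missing indicators drop
})
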
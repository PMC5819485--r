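test_that("transition encoding matches the digit-concatenation convention", {
  expect_identical(encodeTransition(1, 9), 19L)
  expect_identical(encodeTransition(2, 3), 23L)
  expect_identical(encodeTransition(1, 10), 110L)
  expect_error(encodeTransition(3, 2), "not encoded")
  expect_error(encodeTransition(5, 5), "not encoded")
  expect_identical(decodeTransition(110), cbind(class_from = 1L,
                                                class_to = 10L))
  expect_identical(decodeTransition(23), cbind(class_from = 2L,
                                               class_to = 3L))
  expect_error(decodeTransition(32), "malformed")
})

test_that("encode/decode are mutual inverses over all scheme codes", {
  for (s in c("IGBPdet", "IGBPgen")) {
    codes <- schemeTransitions(s)
    pairs <- decodeTransition(codes)
    expect_identical(encodeTransition(pairs[, 1], pairs[, 2]), codes)
  }
  expect_length(schemeTransitions("IGBPdet"), 45L)
  expect_length(schemeTransitions("IGBPgen"), 6L)
  # three-digit codes are exactly the transitions into class 10
  det <- schemeTransitions("IGBPdet")
  expect_identical(det[det >= 100], encodeTransition(1:9, rep(10L, 9)))
})

test_that("product files round-trip bit-exactly", {
  itr <- schemeTransitions("IGBPgen")
  d <- c(3L, 4L, 2L, length(itr))
  set.seed(61)
  delta <- array(rnorm(prod(d)), d)
  sdv <- array(abs(rnorm(prod(d))), d)
  n <- array(sample(0:50, prod(d), replace = TRUE), d)
  delta[2, 2, 1, 1] <- NA; sdv[2, 2, 1, 1] <- NA; n[2, 2, 1, 1] <- 0L
  ds <- new("BiophysicalDataset", variable = "LE", scheme = "IGBPgen",
            lat = c(0.5, 1.5, 2.5), lon = c(0.5, 1.5, 2.5, 3.5), mon = 1:2,
            itr = itr, delta = delta, sd = sdv, n = n)
  f <- file.path(tempdir(), productFileName("LE", "IGBPgen"))
  writeProduct(ds, f)
  r <- readProduct(f)
  expect_identical(deltaLayer(r), deltaLayer(ds))
  expect_identical(uncertaintyLayer(r), uncertaintyLayer(ds))
  expect_identical(sampleCount(r), sampleCount(ds))
  expect_identical(transitionCodes(r), itr)
  expect_identical(r@lat, ds@lat)
  expect_identical(monthsOf(r), 1:2)
  expect_identical(schemeName(r), "IGBPgen")
  # writing must not mutate the in-memory object (fill-value substitution)
  expect_true(is.na(deltaLayer(ds)[2, 2, 1, 1]))
  unlink(f)
})

test_that("writing validates the transition axis against the scheme", {
  itr <- schemeTransitions("IGBPgen")[1:3]
  d <- c(1L, 1L, 1L, 3L)
  ds <- new("BiophysicalDataset", variable = "LE", scheme = "IGBPgen",
            lat = 0.5, lon = 0.5, mon = 1L, itr = itr,
            delta = array(0, d), sd = array(0, d),
            n = array(1L, d))
  expect_error(writeProduct(ds, tempfile(fileext = ".nc")),
               "6 transitions")
})

test_that("product files are readable by an independent netCDF stack", {
  py <- Sys.which("python")
  itr <- schemeTransitions("IGBPgen")
  d <- c(2L, 2L, 1L, length(itr))
  ds <- new("BiophysicalDataset", variable = "albedo", scheme = "IGBPgen",
            lat = c(0.5, 1.5), lon = c(0.5, 1.5), mon = 1L, itr = itr,
            delta = array(seq_len(prod(d)) / 10, d),
            sd = array(0.1, d), n = array(25L, d))
  f <- file.path(tempdir(), productFileName("albedo", "IGBPgen"))
  writeProduct(ds, f)
  script <- paste(
    "import sys, scipy.io",
    sprintf("nc = scipy.io.netcdf_file('%s', mmap=False)", f),
    "v = nc.variables['Delta_albedo']",
    "print(v.shape, float(v[0,0,0,0]), int(nc.variables['iTr'][0]))",
    sep = "; ")
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  # on disk the dimension list is slowest-first, so the reader reports the
  # reversed shape (iTr, mon, lon, lat)
  expect_match(out, "\\(6, 1, 2, 2\\)")
  expect_match(out, "0.1")   # first stored value (lat-major on disk)
  expect_match(out, " 12$")  # first IGBPgen transition code
  unlink(f)
})

test_that("scene files store fractions, truth and radiation", {
  cfg <- sceneConfig(n_rows = 20, n_cols = 20, months = 1L, seed = 62)
  scene <- generateScene(cfg)
  f <- tempfile(fileext = ".nc")
  writeScene(scene, f)
  nc <- ncdf4::nc_open(f)
  expect_true(all(c("fractions", "LE", "pure_LE", "dem_mean", "sw_down")
                  %in% names(nc$var)))
  fr <- ncdf4::ncvar_get(nc, "fractions", collapse_degen = FALSE)
  expect_equal(array(fr, dim(coverFractions(scene))),
               unname(coverFractions(scene)), tolerance = 0)
  ncdf4::nc_close(nc)
  unlink(f)
})

test_that("the canonical manifest lists the sixteen product files", {
  m <- productManifest()
  expect_length(m, 16L)
  expect_true("HG_IGBPdet.nc" %in% m)
  expect_true("albedo_IGBPgen.nc" %in% m)
  expect_identical(anyDuplicated(m), 0L)
})
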
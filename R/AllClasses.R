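#' @import methods
NULL

#' Vegetation classification scheme
#'
#' Holds the class coding of a vegetation classification scheme: the detailed
#' 10-class scheme (\code{"IGBPdet"}) or the generic 4-class scheme
#' (\code{"IGBPgen"}), each extended with the non-vegetated classes that enter
#' the compositional regression but are never predicted.
#'
#' @slot name scheme name, e.g. \code{"IGBPdet"}.
#' @slot codes named integer vector of class codes; names are class
#'   abbreviations (EBF, DBF, ...). Codes of vegetated classes follow the
#'   product's coding (1..10 or 1..4); non-vegetated classes get codes above.
#' @slot vegetated named logical vector, parallel to \code{codes}; TRUE for
#'   classes for which pure-class predictions and transitions are produced.
#'
#' @seealso [igbpDet()], [igbpGen()], [classScheme()]
#' @export
setClass("ClassScheme",
  representation(name = "character", codes = "integer", vegetated = "logical"))

setValidity("ClassScheme", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@codes) != length(object@vegetated))
    msg <- c(msg, "'codes' and 'vegetated' must have equal length")
  if (anyDuplicated(object@codes))
    msg <- c(msg, "class codes must be unique")
  if (any(object@codes <= 0L))
    msg <- c(msg, "class codes must be positive integers")
  if (is.null(names(object@codes)) || any(!nzchar(names(object@codes))))
    msg <- c(msg, "class codes must be named by class abbreviation")
  if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic scene
#'
#' Dimensions, class counts, noise level and smoothness of a seeded synthetic
#' scene used to exercise the unmixing pipeline against known ground truth.
#'
#' @slot nRows,nCols fine-grid pixel counts. Must be positive multiples of 20
#'   when the scene will be aggregated to 1-degree cells (20 fine pixels of
#'   0.05 degrees per coarse cell side).
#' @slot pixelSizeDeg fine pixel size in degrees (default 0.05).
#' @slot nVegClasses number of vegetated classes (4 or 10).
#' @slot nNonvegClasses number of non-vegetated classes (default 4).
#' @slot noiseSd observation noise standard deviation, in the units of the
#'   surface variable being generated.
#' @slot smoothnessScale length scale, in pixels, of the spatial variation of
#'   the latent class-abundance fields and of smooth truth components.
#' @slot seed integer random seed; all generators are deterministic given it.
#' @slot months month indices (subset of 1..12) to generate.
#'
#' @export
setClass("SceneConfig",
  representation(nRows = "integer", nCols = "integer",
    pixelSizeDeg = "numeric", nVegClasses = "integer",
    nNonvegClasses = "integer", noiseSd = "numeric",
    smoothnessScale = "numeric", seed = "integer", months = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid dimensions must be positive")
  if (object@pixelSizeDeg <= 0)
    msg <- c(msg, "pixelSizeDeg must be positive")
  if (object@nVegClasses < 2L)
    msg <- c(msg, "at least two vegetated classes are required")
  if (object@nNonvegClasses < 0L)
    msg <- c(msg, "nNonvegClasses must be non-negative")
  if (object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be non-negative")
  if (object@smoothnessScale < 0)
    msg <- c(msg, "smoothnessScale must be non-negative")
  if (length(object@months) < 1L || any(object@months < 1L | object@months > 12L))
    msg <- c(msg, "months must be a non-empty subset of 1..12")
  if (length(msg)) msg else TRUE
})

#' Per-class ground truth of a synthetic surface variable
#'
#' The "pure" value a surface variable would take under 100 % cover of each
#' class, per pixel and month. Downstream recovery tests compare unmixed
#' transition differences against differences of these fields.
#'
#' @slot pureValues 4-D array \code{[row, col, class, month]}.
#' @slot classLabels class abbreviations, parallel to the class dimension.
#' @slot months month indices, parallel to the month dimension.
#' @export
setClass("GroundTruth",
  representation(pureValues = "array", classLabels = "character",
    months = "integer"))

setValidity("GroundTruth", function(object) {
  d <- dim(object@pureValues)
  msg <- character()
  if (length(d) != 4L)
    msg <- c(msg, "pureValues must be a 4-D [row, col, class, month] array")
  else {
    if (d[3L] != length(object@classLabels))
      msg <- c(msg, "class dimension does not match classLabels")
    if (d[4L] != length(object@months))
      msg <- c(msg, "month dimension does not match months")
  }
  if (length(msg)) msg else TRUE
})

#' Coarse-resolution radiation fields
#'
#' Monthly 1-degree fields of downwelling shortwave radiation and of all-sky /
#' clear-sky upwelling longwave radiation, used for the cloudiness correction
#' and the energy-balance closure.
#'
#' @slot swDown downwelling shortwave, W m-2, array \code{[clat, clon, mon]}.
#' @slot lwUpAllsky all-sky upwelling longwave, W m-2, same shape.
#' @slot lwUpClearsky clear-sky upwelling longwave, W m-2, same shape.
#' @slot months month indices, parallel to the third dimension.
#' @export
setClass("CoarseRadiation",
  representation(swDown = "array", lwUpAllsky = "array",
    lwUpClearsky = "array", months = "integer"))

setValidity("CoarseRadiation", function(object) {
  msg <- character()
  d <- dim(object@swDown)
  if (length(d) != 3L)
    msg <- c(msg, "fields must be 3-D [clat, clon, mon] arrays")
  if (!identical(d, dim(object@lwUpAllsky)) ||
      !identical(d, dim(object@lwUpClearsky)))
    msg <- c(msg, "all three fields must share dimensions")
  if (any(object@swDown < 0, na.rm = TRUE))
    msg <- c(msg, "swDown must be non-negative")
  if (any(object@lwUpClearsky <= 0, na.rm = TRUE) ||
      any(object@lwUpAllsky <= 0, na.rm = TRUE))
    msg <- c(msg, "upwelling longwave fields must be positive")
  if (length(msg)) msg else TRUE
})

#' A complete synthetic scene
#'
#' Bundles everything one processing run consumes: cover fractions, raw
#' surface-variable rasters, per-variable ground truth, DEM summary layers and
#' coarse radiation, together with the configuration and class scheme that
#' produced them.
#'
#' @slot config the [SceneConfig-class] used.
#' @slot scheme the [ClassScheme-class] whose classes the fractions follow.
#' @slot fractions array \code{[row, col, class]} of cover fractions; each
#'   pixel's fractions sum to one.
#' @slot variables named list of 3-D arrays \code{[row, col, mon]}: raw inputs
#'   \code{black_sky}, \code{white_sky}, \code{LE}, \code{LSTday},
#'   \code{LSTnight} and emissivities \code{eps29}, \code{eps31}, \code{eps32}.
#' @slot truth named list of [GroundTruth-class] objects, one per mixed
#'   variable.
#' @slot demMean,demSd elevation mean and standard deviation per pixel, m.
#' @slot radiation a [CoarseRadiation-class] object.
#' @export
setClass("SyntheticScene",
  representation(config = "SceneConfig", scheme = "ClassScheme",
    fractions = "array", variables = "list", truth = "list",
    demMean = "matrix", demSd = "matrix", radiation = "CoarseRadiation"))

#' Local compositional regression model
#'
#' The fitted centred-SVD regression of one 5x5 window: column means, retained
#' right singular vectors, regression coefficients (intercept first) and their
#' covariance.
#'
#' @slot M column means of the window's composition matrix.
#' @slot Vz retained right singular vectors (columns).
#' @slot D retained singular values.
#' @slot beta regression coefficients; \code{beta[1]} is the intercept.
#' @slot varBeta coefficient covariance matrix, s^2 (Z'Z)^-1.
#' @slot nRetained number of retained SVD dimensions.
#' @slot nDistinct number of distinct compositions in the window.
#' @slot classes class abbreviations, parallel to \code{M}.
#' @export
setClass("LocalRegressionModel",
  representation(M = "numeric", Vz = "matrix", D = "numeric",
    beta = "numeric", varBeta = "matrix", nRetained = "integer",
    nDistinct = "integer", classes = "character"))

setValidity("LocalRegressionModel", function(object) {
  msg <- character()
  if (object@nRetained != ncol(object@Vz))
    msg <- c(msg, "nRetained must equal ncol(Vz)")
  if (length(object@beta) != object@nRetained + 1L)
    msg <- c(msg, "beta must have length nRetained + 1 (intercept first)")
  if (!isTRUE(all.equal(object@varBeta, t(object@varBeta),
                        tolerance = 1e-8, check.attributes = FALSE)))
    msg <- c(msg, "varBeta must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Pure-class predictions with covariance
#'
#' Predicted surface-variable values for hypothetical pixels fully covered by
#' a single vegetated class ("dummy pixels"), with the full covariance matrix
#' of those predictions.
#'
#' @slot yp named numeric vector of predictions, one per vegetated class.
#' @slot Sigma prediction covariance matrix; diagonal entries are the
#'   prediction variances (tiny negative values from floating-point
#'   cancellation are clipped to zero).
#' @slot classes class abbreviations, parallel to \code{yp}.
#' @export
setClass("PurePredictions",
  representation(yp = "numeric", Sigma = "matrix", classes = "character"))

setValidity("PurePredictions", function(object) {
  msg <- character()
  if (length(object@yp) != nrow(object@Sigma) ||
      nrow(object@Sigma) != ncol(object@Sigma))
    msg <- c(msg, "Sigma must be square with one row per prediction")
  if (any(diag(object@Sigma) < 0))
    msg <- c(msg, "Sigma diagonal must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Fine-resolution transition estimate maps
#'
#' Output of the moving-window unmixing: per-pixel transition differences and
#' their standard deviations for every ordered class pair (lower code to
#' higher code), month by month. Pixels whose window is incomplete or fails
#' the distinct-composition gate are NA.
#'
#' @slot delta array \code{[row, col, mon, iTr]} of transition differences.
#' @slot sd matching array of standard deviations.
#' @slot itr integer transition codes along the fourth dimension.
#' @slot months month indices along the third dimension.
#' @slot scheme name of the classification scheme.
#' @slot windowSize moving-window side length (pixels).
#' @slot counts named integer vector of bookkeeping counts (windows fitted,
#'   skipped for incompleteness, skipped by the distinct-composition gate).
#' @export
setClass("TransitionMaps",
  representation(delta = "array", sd = "array", itr = "integer",
    months = "integer", scheme = "character", windowSize = "integer",
    counts = "integer"))

setValidity("TransitionMaps", function(object) {
  msg <- character()
  if (!identical(dim(object@delta), dim(object@sd)))
    msg <- c(msg, "delta and sd must share dimensions")
  d <- dim(object@delta)
  if (length(d) != 4L)
    msg <- c(msg, "delta must be [row, col, mon, iTr]")
  else {
    if (d[3L] != length(object@months))
      msg <- c(msg, "month dimension does not match months")
    if (d[4L] != length(object@itr))
      msg <- c(msg, "transition dimension does not match itr codes")
  }
  if (any(object@sd < 0, na.rm = TRUE))
    msg <- c(msg, "standard deviations must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Aggregated biophysical product for one variable
#'
#' The 1-degree product layer for one surface variable Z and one
#' classification scheme: the transition difference \code{Delta_Z}, its
#' standard deviation \code{SD_Delta_Z} and the number of fine-resolution
#' samples \code{N_Z}, on dimensions (lat, lon, mon, iTr).
#'
#' @slot variable variable name (e.g. \code{"albedo"}, \code{"HG"}).
#' @slot scheme classification scheme name (\code{"IGBPdet"} or
#'   \code{"IGBPgen"}).
#' @slot lat,lon coarse cell-centre coordinates, degrees, ascending.
#' @slot mon month indices.
#' @slot itr transition codes along the fourth dimension.
#' @slot delta array \code{[lat, lon, mon, iTr]}: Delta_Z.
#' @slot sd matching array: SD_Delta_Z.
#' @slot n matching integer array: N_Z.
#' @export
setClass("BiophysicalDataset",
  representation(variable = "character", scheme = "character",
    lat = "numeric", lon = "numeric", mon = "integer", itr = "integer",
    delta = "array", sd = "array", n = "array"))

setValidity("BiophysicalDataset", function(object) {
  msg <- character()
  want <- c(length(object@lat), length(object@lon), length(object@mon),
            length(object@itr))
  for (nm in c("delta", "sd", "n")) {
    if (!identical(dim(slot(object, nm)), as.integer(want)))
      msg <- c(msg, sprintf("'%s' dimensions must be (lat, lon, mon, iTr)", nm))
  }
  if (any(object@n < 0, na.rm = TRUE))
    msg <- c(msg, "sample counts must be non-negative")
  bad <- !is.na(object@delta) & (is.na(object@sd) | object@sd < 0)
  if (any(bad))
    msg <- c(msg, "SD must be present and non-negative wherever Delta is present")
  if (length(msg)) msg else TRUE
})
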
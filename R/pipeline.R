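#' Default pipeline configuration
#'
#' All thresholds default to the method's canonical values: co-occurrence
#' index threshold 0.5; topographic bounds v1 < 50 m, v2 < 100 m,
#' v3 < 100 m; at least 20 fine samples per coarse cell; at least 10
#' distinct compositions per window. The remaining numerical knobs
#' (n_q = 11 ideal points, SVD relative tolerance 1e-8, 3*IQR outlier fence)
#' are interpretive defaults and are echoed into product metadata.
#'
#' @param ... named overrides of any default.
#' @return named list of configuration values.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    n_rows = 60L, n_cols = 60L, pixel_size_deg = 0.05,
    scheme = "IGBPgen", noise_sd = 0.01, smoothness_scale = 2,
    truth_spatial_sd = 0.1, relief_amplitude = 0,
    sw_down = 200, lw_ratio = 0.9,
    months = 1:12, seed = 42L,
    ic_threshold = 0.5, v1_max = 50, v2_max = 100, v3_max = 100,
    min_samples = 20L, min_distinct = 10L, n_q = 11L, svd_rtol = 1e-8,
    outlier_fence = 3, window = 5L, block = 20L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration file
#'
#' Plain-text \code{key = value} format, one pair per line; \code{#} starts a
#' comment. Values are parsed as numeric where possible; \code{months} may be
#' a comma-separated list or a range \code{a:b}. Unset keys keep their
#' [pipelineConfig()] defaults.
#'
#' @param path file path.
#' @return named configuration list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    over[[key]] <- if (key == "months") {
      if (grepl(":", val)) {
        ab <- as.integer(strsplit(val, ":")[[1L]])
        ab[1L]:ab[2L]
      } else as.integer(strsplit(val, ",")[[1L]])
    } else if (key == "scheme") val
    else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) val else num
    }
  }
  do.call(pipelineConfig, over)
}

# scene config from a pipeline config
.sceneFromPipeline <- function(cfg) {
  scheme <- getScheme(cfg$scheme)
  sceneConfig(n_rows = cfg$n_rows, n_cols = cfg$n_cols,
    pixel_size_deg = cfg$pixel_size_deg,
    n_veg_classes = sum(scheme@vegetated),
    n_nonveg_classes = sum(!scheme@vegetated),
    noise_sd = cfg$noise_sd, smoothness_scale = cfg$smoothness_scale,
    seed = cfg$seed, months = cfg$months)
}

#' Simulate a scene from a pipeline configuration
#'
#' Generates the seeded synthetic scene a pipeline run consumes and
#' (optionally) writes it to netCDF.
#'
#' @param cfg configuration list from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param path optional output netCDF path.
#' @return a [SyntheticScene-class], invisibly when \code{path} is given.
#' @export
simulateScene <- function(cfg = pipelineConfig(), path = NULL) {
  scene <- generateScene(.sceneFromPipeline(cfg),
    scheme = getScheme(cfg$scheme),
    truth_spatial_sd = cfg$truth_spatial_sd,
    relief_amplitude = cfg$relief_amplitude,
    sw_down = cfg$sw_down, lw_ratio = cfg$lw_ratio)
  if (!is.null(path)) {
    writeScene(scene, path)
    return(invisible(scene))
  }
  scene
}

#' Run the full pipeline on a synthetic scene
#'
#' Executes the processing chain end to end: derive the unmixable surface
#' variables (albedo from black-/white-sky, clear-sky upwelling longwave from
#' the LSTs and emissivities), unmix each variable over moving windows,
#' build the topographic and per-pair co-occurrence masks, aggregate to
#' coarse cells with overlap-aware weights, filter by sample count and
#' outlier fence, close the surface energy balance, and write the eight
#' product files. Returns the products and a per-stage report.
#'
#' @param cfg configuration list (see [pipelineConfig()]).
#' @param out_dir output directory for the product files; \code{NULL} to
#'   skip writing.
#' @param scene optional pre-built [SyntheticScene-class] (must match the
#'   configuration's scheme); generated from \code{cfg} when omitted.
#' @param quiet suppress progress messages.
#' @return list with elements \code{products} (named list of eight
#'   [BiophysicalDataset-class]), \code{report} (per-stage counts),
#'   \code{files} (paths written, if any) and \code{scene}.
#' @export
runPipeline <- function(cfg = pipelineConfig(), out_dir = NULL,
                        scene = NULL, quiet = FALSE) {
  scheme <- getScheme(cfg$scheme)
  if (is.null(scene)) scene <- simulateScene(cfg)
  say <- function(...) if (!quiet) message(...)

  say("preprocess: deriving albedo and clear-sky upwelling longwave")
  albedo <- combineAlbedo(sceneVariable(scene, "black_sky"),
                          sceneVariable(scene, "white_sky"))
  epsb <- broadbandEmissivity(sceneVariable(scene, "eps29"),
                              sceneVariable(scene, "eps31"),
                              sceneVariable(scene, "eps32"))
  lwsfc <- clearskyLwUp(sceneVariable(scene, "LSTday"),
                        sceneVariable(scene, "LSTnight"), epsb)
  stacks <- list(albedo = albedo, LE = sceneVariable(scene, "LE"),
                 LWsfc = lwsfc, LSTday = sceneVariable(scene, "LSTday"),
                 LSTnight = sceneVariable(scene, "LSTnight"))

  frac <- coverFractions(scene)
  report <- list()
  tms <- list()
  for (vn in names(stacks)) {
    say("unmix: ", vn)
    tm <- runMovingWindow(frac, stacks[[vn]], scheme,
      months = scene@config@months, window = cfg$window,
      rtol = cfg$svd_rtol, min_distinct = cfg$min_distinct)
    tms[[vn]] <- tm
    report[[paste0("unmix_", vn)]] <- tm@counts
  }

  say("mask: topography and co-occurrence")
  ind <- topoIndicators(scene@demMean, scene@demSd, window = cfg$window)
  tmask <- topoMask(ind, cfg$v1_max, cfg$v2_max, cfg$v3_max)
  itr <- tms[[1L]]@itr
  pairs <- decodeTransition(itr)
  veg <- vegetatedClasses(scheme)
  keep <- array(FALSE, c(dim(frac)[1:2], length(itr)))
  cmask_count <- integer(length(itr))
  interior <- matrix(FALSE, dim(frac)[1L], dim(frac)[2L])
  h <- cfg$window %/% 2L
  interior[(1L + h):(nrow(interior) - h), (1L + h):(ncol(interior) - h)] <- TRUE
  for (p in seq_along(itr)) {
    ca <- names(veg)[match(pairs[p, 1L], veg)]
    cb <- names(veg)[match(pairs[p, 2L], veg)]
    cm <- cooccurrenceMask(frac, ca, cb, threshold = cfg$ic_threshold,
                           n_q = cfg$n_q, window = cfg$window)
    keep[, , p] <- cm & tmask
    cmask_count[p] <- sum(!cm & interior)
  }
  report$masked_topo <- sum(!tmask & interior)
  report$masked_cooccurrence <- stats::setNames(cmask_count, itr)

  say("aggregate: ", cfg$block, "x", cfg$block, " pixel cells")
  products <- list()
  for (vn in names(tms)) {
    ds <- aggregateTransitions(tms[[vn]], keep = keep, block = cfg$block,
      lat0 = cfg$block * cfg$pixel_size_deg / 2,
      lon0 = cfg$block * cfg$pixel_size_deg / 2,
      pixel = cfg$pixel_size_deg, variable = vn,
      scheme_name = cfg$scheme)
    ds <- filterCells(ds, min_samples = cfg$min_samples,
                      fence = cfg$outlier_fence, quiet = TRUE)
    report[[paste0("filter_", vn)]] <- attr(ds, "filter_counts")
    products[[vn]] <- ds
  }

  say("energy balance closure")
  eb <- closeEnergyBalance(products$albedo, products$LWsfc, products$LE,
                           scene@radiation)
  products <- c(products, eb)

  files <- character()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    interp <- list(n_q = cfg$n_q, svd_rtol = cfg$svd_rtol,
      outlier_fence = paste0(cfg$outlier_fence, "*IQR"),
      interpretive_parameters = "n_q, svd_rtol, outlier_fence")
    for (vn in names(products)) {
      f <- file.path(out_dir, productFileName(vn, cfg$scheme))
      writeProduct(products[[vn]], f, params = interp)
      files <- c(files, f)
    }
    say("wrote ", length(files), " product files to ", out_dir)
  }
  list(products = products, report = report, files = files, scene = scene)
}

#' Recovery error of unmixed transitions against ground truth
#'
#' Compares the fine-resolution unmixed transition differences of one
#' variable against the scene's ground truth at every valid pixel/month and
#' returns the maximum absolute error. On a noiseless scene with spatially
#' uniform pure values this error is at numerical-precision level.
#'
#' @param tm a [TransitionMaps-class] for one variable.
#' @param truth the matching [GroundTruth-class].
#' @param scheme the [ClassScheme-class] used.
#' @return maximum absolute difference over all valid estimates.
#' @export
recoveryError <- function(tm, truth, scheme) {
  pairs <- decodeTransition(tm@itr)
  veg <- vegetatedClasses(scheme)
  maxerr <- 0
  for (p in seq_len(nrow(pairs))) {
    ca <- names(veg)[match(pairs[p, 1L], veg)]
    cb <- names(veg)[match(pairs[p, 2L], veg)]
    ia <- match(ca, truth@classLabels)
    ib <- match(cb, truth@classLabels)
    for (mi in seq_along(tm@months)) {
      est <- tm@delta[, , mi, p]
      tru <- truth@pureValues[, , ib, mi] - truth@pureValues[, , ia, mi]
      err <- abs(est - tru)
      if (any(!is.na(err)))
        maxerr <- max(maxerr, max(err, na.rm = TRUE))
    }
  }
  maxerr
}
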
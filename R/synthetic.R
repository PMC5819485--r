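#' Scene configuration
#'
#' Builds the configuration of a seeded synthetic scene. The defaults describe
#' the reference test scene: a 60x60 fine grid of 0.05-degree pixels (3x3
#' one-degree cells), the generic 4-class vegetation scheme plus non-vegetated
#' classes, moderate spatial smoothness, and observation noise quoted on the
#' albedo scale.
#'
#' @param n_rows,n_cols fine-grid dimensions; use multiples of 20 when the
#'   scene will be aggregated to 1-degree cells.
#' @param pixel_size_deg fine pixel size in degrees.
#' @param n_veg_classes 4 or 10 vegetated classes.
#' @param n_nonveg_classes non-vegetated classes entering the regressions.
#' @param noise_sd observation-noise standard deviation on the albedo scale
#'   (dimensionless); other variables scale it by their dynamic range, see
#'   [generateScene()].
#' @param smoothness_scale length scale (pixels) of the latent smooth fields.
#' @param seed integer random seed.
#' @param months month indices to generate.
#' @return a [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(n_rows = 40, n_cols = 40, months = 1:2)
#' @export
sceneConfig <- function(n_rows = 60L, n_cols = 60L, pixel_size_deg = 0.05,
                        n_veg_classes = 4L, n_nonveg_classes = 4L,
                        noise_sd = 0.01, smoothness_scale = 2,
                        seed = 42L, months = 1:12) {
  new("SceneConfig", nRows = as.integer(n_rows), nCols = as.integer(n_cols),
      pixelSizeDeg = pixel_size_deg, nVegClasses = as.integer(n_veg_classes),
      nNonvegClasses = as.integer(n_nonveg_classes), noiseSd = noise_sd,
      smoothnessScale = smoothness_scale, seed = as.integer(seed),
      months = as.integer(months))
}

# Smooth standardized Gaussian random field via separable Gaussian filtering.
# Row/column smoothing matrices are built explicitly so the result is exactly
# reproducible and has no FFT wrap-around. Caller controls the RNG state.
.smoothField <- function(n_rows, n_cols, scale) {
  w <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale > 0) {
    smat <- function(n) {
      d <- abs(outer(seq_len(n), seq_len(n), "-"))
      k <- exp(-d^2 / (2 * scale^2))
      k / rowSums(k)
    }
    w <- smat(n_rows) %*% w %*% t(smat(n_cols))
  }
  s <- stats::sd(w)
  if (s > 0) (w - mean(w)) / s else w - mean(w)
}

.classLabels <- function(config, scheme = NULL) {
  if (!is.null(scheme)) return(names(classCodes(scheme)))
  c(sprintf("V%02d", seq_len(config@nVegClasses)),
    sprintf("N%02d", seq_len(config@nNonvegClasses)))
}

#' Generate a spatially coherent cover-fraction field
#'
#' Samples one smooth latent field per class and maps them to the simplex with
#' a softmax, so every pixel's fractions are positive, sum to one, and vary
#' smoothly in space.
#'
#' @param config a [SceneConfig-class].
#' @param scheme optional [ClassScheme-class]; when supplied its full class
#'   set (vegetated + non-vegetated) defines the class dimension, otherwise
#'   the config's class counts are used with generic labels.
#' @param contrast softmax gain; larger values spread compositions further
#'   across the simplex (more class dominance contrast between pixels).
#' @return array \code{[row, col, class]} with dimnames on the class axis.
#' @export
generateFractions <- function(config, scheme = NULL, contrast = 2.5) {
  validObject(config)
  labels <- .classLabels(config, scheme)
  k <- length(labels)
  set.seed(config@seed)
  lat <- vapply(seq_len(k), function(j)
    .smoothField(config@nRows, config@nCols, config@smoothnessScale),
    matrix(0, config@nRows, config@nCols))
  u <- exp(contrast * lat)
  frac <- u / as.vector(rowSums(u, dims = 2L))
  dimnames(frac) <- list(NULL, NULL, labels)
  frac
}

#' Deterministic two-class checkerboard fractions
#'
#' A fixture in which pixels alternate between 100 % cover of two classes, so
#' window compositions sit at the two ends of the simplex edge.
#'
#' @param n_rows,n_cols grid size.
#' @param scheme a [ClassScheme-class].
#' @param classes two class abbreviations; defaults to the first two
#'   vegetated classes.
#' @return fraction array \code{[row, col, class]}.
#' @export
checkerboardFractions <- function(n_rows, n_cols, scheme = igbpGen(),
                                  classes = NULL) {
  labels <- names(classCodes(scheme))
  if (is.null(classes))
    classes <- names(vegetatedClasses(scheme))[1:2]
  stopifnot(all(classes %in% labels))
  frac <- array(0, c(n_rows, n_cols, length(labels)),
                dimnames = list(NULL, NULL, labels))
  parity <- outer(seq_len(n_rows), seq_len(n_cols), "+") %% 2L
  frac[, , classes[1L]] <- parity
  frac[, , classes[2L]] <- 1 - parity
  frac
}

#' Deterministic two-class edge-gradient fractions
#'
#' A fixture in which the cover of one class ramps linearly from 0 to 1 across
#' the columns (the other class making up the rest), so window compositions
#' sample the simplex edge evenly.
#'
#' @inheritParams checkerboardFractions
#' @return fraction array \code{[row, col, class]}.
#' @export
edgeGradientFractions <- function(n_rows, n_cols, scheme = igbpGen(),
                                  classes = NULL) {
  labels <- names(classCodes(scheme))
  if (is.null(classes))
    classes <- names(vegetatedClasses(scheme))[1:2]
  stopifnot(all(classes %in% labels))
  frac <- array(0, c(n_rows, n_cols, length(labels)),
                dimnames = list(NULL, NULL, labels))
  ramp <- matrix(rep((seq_len(n_cols) - 1) / (n_cols - 1), each = n_rows),
                 n_rows, n_cols)
  frac[, , classes[1L]] <- 1 - ramp
  frac[, , classes[2L]] <- ramp
  frac
}

#' Generate per-class ground truth for one surface variable
#'
#' The pure value of class j at pixel x and month m is
#' \code{base + offset_j + seasonal_j(m) + spatial_sd * f_j(x)} where
#' \code{offset_j} spreads the classes evenly over \code{+/- class_spread},
#' \code{seasonal_j} is a class-phased annual sinusoid, and \code{f_j} is a
#' standardized smooth field. With \code{spatial_sd = 0} the pure values are
#' spatially uniform, so the local uniform-climate assumption of the unmixing
#' holds exactly and noiseless recovery is exact.
#'
#' @param config a [SceneConfig-class].
#' @param scheme optional [ClassScheme-class] supplying class labels.
#' @param base overall mean level, variable units.
#' @param class_spread half-range of the per-class offsets.
#' @param seasonal_amplitude amplitude of the annual cycle.
#' @param spatial_sd standard deviation of the smooth spatial component.
#' @param seed RNG seed for the spatial component (defaults to
#'   \code{config@seed + 1000}).
#' @return a [GroundTruth-class].
#' @export
generateGroundTruth <- function(config, scheme = NULL, base = 0.2,
                                class_spread = 0.1, seasonal_amplitude = 0.02,
                                spatial_sd = 0.02, seed = NULL) {
  validObject(config)
  labels <- .classLabels(config, scheme)
  k <- length(labels)
  months <- config@months
  if (is.null(seed)) seed <- config@seed + 1000L
  set.seed(as.integer(seed))
  offsets <- if (k > 1) seq(-class_spread, class_spread, length.out = k) else 0
  pure <- array(0, c(config@nRows, config@nCols, k, length(months)),
                dimnames = list(NULL, NULL, labels, NULL))
  spatial <- vapply(seq_len(k), function(j)
    .smoothField(config@nRows, config@nCols, config@smoothnessScale),
    matrix(0, config@nRows, config@nCols))
  for (mi in seq_along(months)) {
    seas <- seasonal_amplitude *
      sin(2 * pi * (months[mi] - seq_len(k)) / 12)
    for (j in seq_len(k))
      pure[, , j, mi] <- base + offsets[j] + seas[j] +
        spatial_sd * spatial[, , j]
  }
  new("GroundTruth", pureValues = pure, classLabels = labels,
      months = months)
}

#' Mix a surface variable from fractions and ground truth
#'
#' Each pixel's value is the composition-weighted mixture of the per-class
#' pure values plus independent Gaussian observation noise:
#' \code{y(x, m) = sum_j frac_j(x) * pure_j(x, m) + N(0, noise_sd)}.
#'
#' @param fractions array \code{[row, col, class]}.
#' @param truth a [GroundTruth-class] on the same grid and class set.
#' @param noise_sd observation noise SD (variable units).
#' @param seed RNG seed for the noise.
#' @return array \code{[row, col, mon]}.
#' @export
generateSurfaceVariable <- function(fractions, truth, noise_sd = 0,
                                    seed = 1L) {
  stopifnot(is(truth, "GroundTruth"))
  d <- dim(truth@pureValues)
  if (!identical(dim(fractions), d[1:3]))
    stop("fractions and ground truth are on different grids or class sets")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  nm <- d[4L]
  y <- array(0, c(d[1L], d[2L], nm))
  fr <- matrix(fractions, ncol = d[3L])
  for (mi in seq_len(nm)) {
    pm <- matrix(truth@pureValues[, , , mi], ncol = d[3L])
    y[, , mi] <- matrix(rowSums(fr * pm), d[1L], d[2L])
  }
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + array(stats::rnorm(length(y), sd = noise_sd), dim(y))
  }
  y
}

#' True transition difference from ground truth
#'
#' The ground-truth counterpart of the unmixed transition difference: the
#' pure value of the destination class minus that of the origin class at one
#' pixel and month. Serves as the recovery oracle for noiseless scenes.
#'
#' @param truth a [GroundTruth-class].
#' @param class_a,class_b class abbreviations (origin, destination).
#' @param pixel integer \code{c(row, col)}.
#' @param month month index (must be among the truth's months).
#' @return numeric difference, variable units.
#' @export
trueTransitionDelta <- function(truth, class_a, class_b, pixel, month) {
  stopifnot(is(truth, "GroundTruth"))
  ia <- match(class_a, truth@classLabels)
  ib <- match(class_b, truth@classLabels)
  if (is.na(ia) || is.na(ib))
    stop("unknown class: ", paste(c(class_a, class_b)[is.na(c(ia, ib))],
                                  collapse = ", "))
  mi <- match(month, truth@months)
  if (is.na(mi)) stop("month ", month, " not present in ground truth")
  unname(truth@pureValues[pixel[1L], pixel[2L], ib, mi] -
         truth@pureValues[pixel[1L], pixel[2L], ia, mi])
}

#' Generate DEM summary layers
#'
#' Produces the per-pixel elevation mean \code{mu_h} (a smooth field with the
#' requested relief amplitude) and standard deviation \code{sigma_h}
#' (proportional to the local slope magnitude of \code{mu_h}, emulating
#' sub-pixel elevation spread). A zero-amplitude scene is perfectly flat.
#'
#' @param config a [SceneConfig-class].
#' @param relief_amplitude standard deviation of \code{mu_h}, metres.
#' @param relief_scale length scale (pixels) of the relief.
#' @param seed RNG seed (defaults to \code{config@seed + 2000}).
#' @return list with matrices \code{mu_h} and \code{sigma_h}.
#' @export
generateDEM <- function(config, relief_amplitude = 0, relief_scale = 3,
                        seed = NULL) {
  validObject(config)
  if (relief_amplitude < 0) stop("relief_amplitude must be non-negative")
  if (is.null(seed)) seed <- config@seed + 2000L
  set.seed(as.integer(seed))
  mu <- relief_amplitude *
    .smoothField(config@nRows, config@nCols, relief_scale)
  nr <- nrow(mu); nc <- ncol(mu)
  # central differences with replicated edges
  gx <- (mu[, pmin(seq_len(nc) + 1L, nc)] - mu[, pmax(seq_len(nc) - 1L, 1L)]) / 2
  gy <- (mu[pmin(seq_len(nr) + 1L, nr), ] - mu[pmax(seq_len(nr) - 1L, 1L), ]) / 2
  sigma <- 0.5 * sqrt(gx^2 + gy^2)
  list(mu_h = mu, sigma_h = sigma)
}

#' Generate coarse radiation fields
#'
#' Monthly 1-degree fields of downwelling shortwave and of all-sky/clear-sky
#' upwelling longwave radiation, either spatially constant or smoothly
#' varying. One coarse cell spans 20x20 fine pixels.
#'
#' @param config a [SceneConfig-class].
#' @param sw_down downwelling shortwave level, W m-2.
#' @param lw_ratio all-sky to clear-sky upwelling longwave ratio, in (0, 1.5].
#' @param lw_clearsky clear-sky upwelling longwave level, W m-2.
#' @param smooth if TRUE, add a small smooth spatial modulation.
#' @param seed RNG seed used when \code{smooth} (defaults
#'   \code{config@seed + 3000}).
#' @return a [CoarseRadiation-class].
#' @export
generateCoarseRadiation <- function(config, sw_down = 200, lw_ratio = 0.9,
                                    lw_clearsky = 400, smooth = FALSE,
                                    seed = NULL) {
  validObject(config)
  if (sw_down < 0) stop("sw_down must be non-negative")
  if (lw_ratio <= 0 || lw_ratio > 1.5) stop("lw_ratio must be in (0, 1.5]")
  nr <- max(1L, config@nRows %/% 20L)
  nc <- max(1L, config@nCols %/% 20L)
  nm <- length(config@months)
  mod <- matrix(1, nr, nc)
  if (smooth) {
    if (is.null(seed)) seed <- config@seed + 3000L
    set.seed(as.integer(seed))
    mod <- 1 + 0.1 * .smoothField(nr, nc, 1)
    mod <- pmax(mod, 0.5)
  }
  sw <- array(rep(sw_down * mod, nm), c(nr, nc, nm))
  cs <- array(rep(lw_clearsky * mod, nm), c(nr, nc, nm))
  new("CoarseRadiation", swDown = sw, lwUpAllsky = cs * lw_ratio,
      lwUpClearsky = cs, months = config@months)
}

# Per-variable generation presets: level, class spread, seasonal amplitude,
# and the factor by which the config's albedo-scale noise SD is multiplied.
.VAR_PRESETS <- list(
  black_sky = list(base = 0.16, spread = 0.08, seasonal = 0.02, noise = 1),
  white_sky = list(base = 0.18, spread = 0.08, seasonal = 0.02, noise = 1),
  LE        = list(base = 80,   spread = 40,   seasonal = 20,   noise = 400),
  LSTday    = list(base = 300,  spread = 6,    seasonal = 8,    noise = 40),
  LSTnight  = list(base = 285,  spread = 3,    seasonal = 6,    noise = 40)
)

#' Generate a complete synthetic scene
#'
#' Builds cover fractions, the five mixed surface variables (black- and
#' white-sky albedo, latent heat flux, day and night land surface
#' temperature), constant narrowband emissivities, DEM summary layers and
#' coarse radiation, with per-variable ground truth retained for recovery
#' checks. A derived albedo ground truth (mean of the black- and white-sky
#' truths) is stored alongside the raw variables' truths.
#'
#' @param config a [SceneConfig-class].
#' @param scheme optional [ClassScheme-class]; defaults to [igbpGen()] for 4
#'   vegetated classes and [igbpDet()] for 10.
#' @param truth_spatial_sd relative SD of the smooth spatial component of the
#'   pure-class fields (scaled by each variable's class spread); 0 makes pure
#'   values spatially uniform so noiseless unmixing recovery is exact.
#' @param relief_amplitude DEM relief amplitude, metres.
#' @param sw_down,lw_ratio coarse radiation parameters, see
#'   [generateCoarseRadiation()].
#' @param contrast softmax gain of the fraction generator.
#' @return a [SyntheticScene-class].
#' @export
generateScene <- function(config, scheme = NULL, truth_spatial_sd = 0.1,
                          relief_amplitude = 0, sw_down = 200,
                          lw_ratio = 0.9, contrast = 2.5) {
  validObject(config)
  if (is.null(scheme))
    scheme <- if (config@nVegClasses >= 10L) igbpDet() else igbpGen()
  frac <- generateFractions(config, scheme, contrast = contrast)
  vars <- list()
  truths <- list()
  for (vi in seq_along(.VAR_PRESETS)) {
    vn <- names(.VAR_PRESETS)[vi]
    p <- .VAR_PRESETS[[vn]]
    tr <- generateGroundTruth(config, scheme, base = p$base,
      class_spread = p$spread, seasonal_amplitude = p$seasonal,
      spatial_sd = truth_spatial_sd * p$spread,
      seed = config@seed + 1000L + vi)
    vars[[vn]] <- generateSurfaceVariable(frac, tr,
      noise_sd = config@noiseSd * p$noise, seed = config@seed + 100L + vi)
    truths[[vn]] <- tr
  }
  # derived albedo truth: the pipeline averages black- and white-sky albedo,
  # and the mean of two exact mixtures is an exact mixture of the mean truths
  alb <- truths$black_sky
  alb@pureValues <- (truths$black_sky@pureValues +
                     truths$white_sky@pureValues) / 2
  truths$albedo <- alb
  nm <- length(config@months)
  eps <- array(0.98, c(config@nRows, config@nCols, nm))
  vars$eps29 <- eps; vars$eps31 <- eps; vars$eps32 <- eps
  dem <- generateDEM(config, relief_amplitude = relief_amplitude)
  rad <- generateCoarseRadiation(config, sw_down = sw_down,
                                 lw_ratio = lw_ratio)
  new("SyntheticScene", config = config, scheme = scheme, fractions = frac,
      variables = vars, truth = truths, demMean = dem$mu_h,
      demSd = dem$sigma_h, radiation = rad)
}

#' @rdname accessors
#' @export
setMethod("coverFractions", "SyntheticScene", function(object) object@fractions)

#' @rdname accessors
#' @param name variable name.
#' @export
setMethod("sceneVariable", "SyntheticScene", function(object, name) {
  if (!name %in% names(object@variables))
    stop("scene has no variable '", name, "'")
  object@variables[[name]]
})

#' @rdname accessors
#' @export
setMethod("groundTruth", "SyntheticScene", function(object, name) {
  if (!name %in% names(object@truth))
    stop("scene has no ground truth for '", name, "'")
  object@truth[[name]]
})

setMethod("show", "SyntheticScene", function(object) {
  cfg <- object@config
  cat("SyntheticScene ", cfg@nRows, "x", cfg@nCols, " pixels, ",
      length(cfg@months), " month(s), scheme ", object@scheme@name,
      " (", nClasses(object@scheme), " classes), seed ", cfg@seed, "\n",
      sep = "")
  cat("  variables:", paste(names(object@variables), collapse = " "), "\n")
})
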
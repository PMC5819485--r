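#' Fractional overlap of two moving windows
#'
#' The share of pixels common to the centred square windows of two fine-grid
#' estimates: for 5x5 windows, up to 20 of the 25 pixels can be shared by
#' distinct centres, and centres at least one window-width apart share none.
#'
#' @param center_i,center_j integer \code{c(row, col)} window centres.
#' @param window odd window side length.
#' @return overlap fraction in \code{[0, 1]}.
#' @examples
#' windowOverlap(c(10, 10), c(10, 11))  # 20/25
#' @export
windowOverlap <- function(center_i, center_j, window = 5L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window size must be odd")
  ox <- max(0L, window - abs(center_i[1L] - center_j[1L]))
  oy <- max(0L, window - abs(center_i[2L] - center_j[2L]))
  (ox * oy) / window^2
}

#' Window-overlap matrix for a set of estimate centres
#'
#' Symmetric matrix of pairwise window-overlap fractions for the surviving
#' fine-pixel estimates inside one coarse cell (up to 400 centres for a full
#' 1-degree cell of 20x20 pixels); the diagonal is 1.
#'
#' @param centers integer matrix with columns (row, col).
#' @param window odd window side length.
#' @return n x n matrix of overlap fractions.
#' @export
overlapMatrix <- function(centers, window = 5L) {
  window <- as.integer(window)
  dr <- abs(outer(centers[, 1L], centers[, 1L], "-"))
  dc <- abs(outer(centers[, 2L], centers[, 2L], "-"))
  pmax(window - dr, 0L) * pmax(window - dc, 0L) / window^2
}

#' Inverse-variance weighted aggregation
#'
#' The classical uncertainty-weighted mean,
#' \code{mean = sum(delta_i / sd_i^2) / sum(1 / sd_i^2)} with variance
#' \code{1 / sum(1 / sd_i^2)}; the special case of the overlap-aware
#' aggregation when no windows overlap. Serves as its oracle and fallback.
#'
#' @param deltas estimate values.
#' @param sds their standard deviations (> 0).
#' @return list with \code{delta} and \code{sd}.
#' @export
inverseVarianceAggregate <- function(deltas, sds) {
  if (length(deltas) == 0L) return(list(delta = NA_real_, sd = NA_real_))
  if (length(deltas) != length(sds)) stop("deltas and sds differ in length")
  if (any(sds <= 0)) stop("standard deviations must be positive")
  wi <- 1 / sds^2
  list(delta = sum(deltas * wi) / sum(wi), sd = sqrt(1 / sum(wi)))
}

#' Overlap-aware generalized-least-squares aggregation
#'
#' Aggregates the fine-pixel estimates of one coarse cell with weights that
#' account both for individual uncertainties and for the spatial
#' autocorrelation induced by window overlap. With \code{D} the diagonal
#' matrix of standard deviations and \code{R} the window-overlap matrix, the
#' assumed covariance is \code{Sigma = D R D}; the best linear unbiased
#' weights are \code{w = Sigma^-1 1 / (1' Sigma^-1 1)}, giving
#' \code{mean = sum(w_i delta_i)} and variance
#' \code{1 / (1' Sigma^-1 1) = w' Sigma w} (both forms are computed and
#' checked to agree to 1e-8 relative).
#'
#' Standard deviations are floored at \code{sd_floor} before inversion (zero
#' residual variance occurs in noiseless scenes). A numerically singular
#' covariance gets one ridge of \code{1e-10 tr(Sigma)/n}; if still singular
#' the cell is flagged missing.
#'
#' @param deltas estimate values.
#' @param sds their standard deviations.
#' @param R window-overlap matrix (identity when omitted).
#' @param sd_floor lower bound applied to \code{sds}.
#' @return list with \code{delta}, \code{sd}, \code{weights}.
#' @export
glsAggregate <- function(deltas, sds, R = NULL, sd_floor = 1e-9) {
  n <- length(deltas)
  if (n == 0L) return(list(delta = NA_real_, sd = NA_real_, weights = numeric()))
  if (length(sds) != n) stop("deltas and sds differ in length")
  if (is.null(R)) R <- diag(n)
  if (!identical(dim(R), c(n, n))) stop("overlap matrix has wrong dimensions")
  d <- pmax(sds, sd_floor)
  Sigma <- R * tcrossprod(d)
  ones <- rep(1, n)
  x <- tryCatch(solve(Sigma, ones), error = function(e) NULL)
  if (is.null(x)) {
    Sigma <- Sigma + diag(1e-10 * sum(diag(Sigma)) / n, n)
    x <- tryCatch(solve(Sigma, ones), error = function(e) NULL)
    if (is.null(x)) return(list(delta = NA_real_, sd = NA_real_,
                                weights = rep(NA_real_, n)))
  }
  denom <- sum(x)
  w <- x / denom
  v1 <- 1 / denom
  v2 <- drop(crossprod(w, Sigma %*% w))
  if (abs(v1 - v2) > 1e-8 * max(abs(v1), .Machine$double.eps))
    warning("GLS variance forms disagree beyond 1e-8 relative tolerance")
  list(delta = sum(w * deltas), sd = sqrt(v1), weights = w)
}

#' Aggregate transition maps to coarse cells
#'
#' Splits the fine grid into aligned blocks of \code{block} x \code{block}
#' pixels (20 fine pixels of 0.05 degrees per 1-degree cell side; no partial
#' cells) and aggregates, per coarse cell, month and transition, the
#' surviving fine-pixel estimates with [glsAggregate()]. The overlap matrix
#' is built from surviving members only, since masked estimates never enter
#' the aggregation.
#'
#' @param tm a [TransitionMaps-class].
#' @param keep optional mask: a logical \code{[row, col]} matrix applied to
#'   every transition (e.g. the topographic mask), or a logical
#'   \code{[row, col, iTr]} array with per-transition masks (e.g. combined
#'   with co-occurrence masks).
#' @param block coarse cell side length in fine pixels.
#' @param sd_floor see [glsAggregate()].
#' @param lat0,lon0 geographic coordinate of the centre of the first coarse
#'   cell (degrees); cells advance by \code{block * pixel} degrees.
#' @param pixel fine pixel size, degrees.
#' @param variable variable name recorded in the output.
#' @param scheme_name scheme name recorded in the output.
#' @return a [BiophysicalDataset-class] at coarse resolution.
#' @export
aggregateTransitions <- function(tm, keep = NULL, block = 20L,
                                 sd_floor = 1e-9, lat0 = 0.5, lon0 = 0.5,
                                 pixel = 0.05, variable = "Z",
                                 scheme_name = tm@scheme) {
  stopifnot(is(tm, "TransitionMaps"))
  block <- as.integer(block)
  d <- dim(tm@delta)
  nr <- d[1L]; nc <- d[2L]; nm <- d[3L]; np <- d[4L]
  nbr <- nr %/% block; nbc <- nc %/% block
  if (nbr < 1L || nbc < 1L)
    stop("grid smaller than one coarse cell")
  if (!is.null(keep)) {
    kd <- dim(keep)
    if (length(kd) == 2L) keep <- array(keep, c(nr, nc, np))
    else if (!identical(kd, c(nr, nc, np)))
      stop("keep mask has wrong dimensions")
  }
  delta <- array(NA_real_, c(nbr, nbc, nm, np))
  sdv <- array(NA_real_, c(nbr, nbc, nm, np))
  nsamp <- array(0L, c(nbr, nbc, nm, np))
  for (bi in seq_len(nbr)) {
    rows <- ((bi - 1L) * block + 1L):(bi * block)
    for (bj in seq_len(nbc)) {
      cols <- ((bj - 1L) * block + 1L):(bj * block)
      rc <- cbind(rep(rows, times = block), rep(cols, each = block))
      for (p in seq_len(np)) {
        kp <- if (is.null(keep)) rep(TRUE, nrow(rc))
              else keep[cbind(rc, p)]
        for (mi in seq_len(nm)) {
          dv <- tm@delta[cbind(rc, mi, p)]
          sv <- tm@sd[cbind(rc, mi, p)]
          ok <- kp & !is.na(dv) & !is.na(sv)
          nsamp[bi, bj, mi, p] <- sum(ok)
          if (!any(ok)) next
          centers <- rc[ok, , drop = FALSE]
          R <- overlapMatrix(centers, window = tm@windowSize)
          ag <- glsAggregate(dv[ok], sv[ok], R, sd_floor = sd_floor)
          delta[bi, bj, mi, p] <- ag$delta
          sdv[bi, bj, mi, p] <- ag$sd
        }
      }
    }
  }
  step <- block * pixel
  new("BiophysicalDataset", variable = variable, scheme = scheme_name,
      lat = lat0 + (seq_len(nbr) - 1L) * step,
      lon = lon0 + (seq_len(nbc) - 1L) * step,
      mon = tm@months, itr = tm@itr, delta = delta, sd = sdv, n = nsamp)
}

#' Sample-count and outlier filtering of an aggregated product
#'
#' First removes cells backed by fewer than \code{min_samples} fine-pixel
#' estimates (the bound is inclusive: exactly \code{min_samples} survives).
#' Then, per transition, removes values outside
#' \code{[Q1 - fence*IQR, Q3 + fence*IQR]} of the pooled distribution over
#' all cells and months. Counts of removed values are reported via
#' \code{message()} and returned as an attribute.
#'
#' @param ds a [BiophysicalDataset-class].
#' @param min_samples minimum fine-sample count (default 20).
#' @param fence IQR multiplier of the outlier fence (default 3).
#' @param quiet suppress the log message.
#' @return the filtered [BiophysicalDataset-class], with attribute
#'   \code{"filter_counts"} = c(low_n, outlier).
#' @export
filterCells <- function(ds, min_samples = 20L, fence = 3, quiet = FALSE) {
  stopifnot(is(ds, "BiophysicalDataset"))
  low <- !is.na(ds@delta) & ds@n < min_samples
  ds@delta[low] <- NA_real_
  ds@sd[low] <- NA_real_
  n_out <- 0L
  np <- length(ds@itr)
  for (p in seq_len(np)) {
    vals <- ds@delta[, , , p]
    if (all(is.na(vals))) next
    qs <- stats::quantile(vals, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- qs[2L] - qs[1L]
    bad <- !is.na(vals) & (vals < qs[1L] - fence * iqr |
                           vals > qs[2L] + fence * iqr)
    n_out <- n_out + sum(bad)
    vals[bad] <- NA_real_
    ds@delta[, , , p] <- vals
    sds <- ds@sd[, , , p]
    sds[bad] <- NA_real_
    ds@sd[, , , p] <- sds
  }
  counts <- c(low_n = sum(low), outlier = n_out)
  if (!quiet)
    message("filterCells: removed ", counts[["low_n"]],
            " value(s) with N < ", min_samples, " and ",
            counts[["outlier"]], " outlier(s) beyond ", fence, "*IQR")
  attr(ds, "filter_counts") <- counts
  ds
}
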
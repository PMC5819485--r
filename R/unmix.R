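#' Count distinct compositions in a window
#'
#' Number of unique composition rows, with uniqueness judged after rounding
#' each fraction to 6 decimals (fraction inputs carry limited precision, so
#' rows differing only at the 1e-9 level count as one). A window must contain
#' at least 10 distinct compositions for the local regression to be fitted.
#'
#' @param X n x m matrix of cover fractions (rows are pixels).
#' @return integer count of distinct rows.
#' @export
distinctCompositions <- function(X) {
  nrow(unique(round(X, 6L)))
}

# core fit on one window; returns a plain list or NULL (skip signal).
# rtol: singular values below rtol * d_max are treated as numerically zero,
# i.e. only the numerically nonzero rank is retained (conserving 100% of the
# composition matrix's variation while dropping redundant dimensions).
.fitWindow <- function(X, y, rtol = 1e-8, min_distinct = 10L) {
  n <- nrow(X)
  if (anyNA(X) || anyNA(y)) return(NULL)
  nd <- distinctCompositions(X)
  if (nd < min_distinct) return(NULL)
  M <- colMeans(X)
  Xc <- sweep(X, 2L, M)
  sv <- svd(Xc)
  keep <- sv$d > rtol * sv$d[1L]
  r <- sum(keep)
  if (r == 0L) return(NULL)
  Vz <- sv$v[, keep, drop = FALSE]
  Z <- cbind(1, Xc %*% Vz)
  ZtZ <- crossprod(Z)
  ZtZinv <- tryCatch(chol2inv(chol(ZtZ)), error = function(e) NULL)
  if (is.null(ZtZinv)) return(NULL)
  beta <- drop(ZtZinv %*% crossprod(Z, y))
  resid <- y - drop(Z %*% beta)
  dof <- n - (r + 1L)
  s2 <- if (dof > 0L) sum(resid^2) / dof else 0
  list(M = M, Vz = Vz, D = sv$d[keep], beta = beta,
       varBeta = s2 * ZtZinv, nRetained = r, nDistinct = nd)
}

#' Fit the local compositional regression of one window
#'
#' Centres the window's composition matrix by its column means, takes the
#' singular value decomposition, retains the numerically nonzero dimensions
#' (singular values above \code{rtol} times the largest), forms the reduced
#' predictor matrix \code{Z = (X - M) Vz} with a leading intercept column,
#' and solves the ordinary least squares problem. The coefficient covariance
#' is \code{s^2 (Z'Z)^-1} with the unbiased residual variance
#' \code{s^2 = RSS / (n - n_retained - 1)}.
#'
#' The fit is refused (returns \code{NULL}, the window-skip signal) when the
#' window contains missing values, fewer than \code{min_distinct} distinct
#' compositions, or a degenerate reduced design.
#'
#' @param X n x m composition matrix (n pixels, m classes; rows sum to one).
#' @param y response vector of length n (one surface-variable value per
#'   pixel).
#' @param rtol relative singular-value tolerance for rank retention.
#' @param min_distinct minimum number of distinct compositions (default 10).
#' @param classes optional class abbreviations for the columns of \code{X}.
#' @return a [LocalRegressionModel-class], or \code{NULL} if the window must
#'   be skipped.
#' @export
fitLocalModel <- function(X, y, rtol = 1e-8, min_distinct = 10L,
                          classes = colnames(X)) {
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop("length of y must match the number of composition rows")
  fit <- .fitWindow(X, y, rtol = rtol, min_distinct = as.integer(min_distinct))
  if (is.null(fit)) return(NULL)
  if (is.null(classes)) classes <- sprintf("C%02d", seq_len(ncol(X)))
  new("LocalRegressionModel", M = fit$M, Vz = fit$Vz, D = fit$D,
      beta = fit$beta, varBeta = fit$varBeta,
      nRetained = as.integer(fit$nRetained),
      nDistinct = as.integer(fit$nDistinct), classes = classes)
}

# dummy-pixel prediction from a plain fit list; veg_idx indexes columns of X
.predictPure <- function(fit, veg_idx, m) {
  P <- matrix(0, length(veg_idx), m)
  P[cbind(seq_along(veg_idx), veg_idx)] <- 1
  Pc <- sweep(P, 2L, fit$M)
  Zp <- cbind(1, Pc %*% fit$Vz)
  yp <- drop(Zp %*% fit$beta)
  Sigma <- Zp %*% fit$varBeta %*% t(Zp)
  Sigma <- (Sigma + t(Sigma)) / 2
  d <- diag(Sigma)
  d[d < 0 & d > -1e-12] <- 0
  diag(Sigma) <- pmax(d, 0)
  list(yp = yp, Sigma = Sigma)
}

#' Predict pure-class values with covariance
#'
#' For each requested vegetated class, defines a "dummy pixel" fully covered
#' by that class (all other classes, including non-vegetated ones, zero),
#' centres it on the window's column means, projects it onto the retained
#' singular vectors and predicts: \code{y_p = Z_p beta}. The prediction
#' covariance is \code{Sigma = Z_p Var[beta] Z_p'}; its off-diagonal terms
#' matter because all predictions derive from the same regression.
#'
#' @param model a [LocalRegressionModel-class].
#' @param veg_classes abbreviations of the classes to predict; defaults to
#'   all classes whose names do not start with a non-vegetated marker --
#'   pass explicitly in normal use.
#' @return a [PurePredictions-class].
#' @export
predictPure <- function(model, veg_classes) {
  stopifnot(is(model, "LocalRegressionModel"))
  idx <- match(veg_classes, model@classes)
  if (anyNA(idx))
    stop("class not in model: ",
         paste(veg_classes[is.na(idx)], collapse = ", "))
  pr <- .predictPure(list(M = model@M, Vz = model@Vz, beta = model@beta,
                          varBeta = model@varBeta),
                     idx, length(model@M))
  new("PurePredictions", yp = stats::setNames(pr$yp, veg_classes),
      Sigma = pr$Sigma, classes = veg_classes)
}

#' @rdname accessors
#' @export
setMethod("purePredictionValues", "PurePredictions", function(object) object@yp)

#' @rdname accessors
#' @export
setMethod("predictionCovariance", "PurePredictions",
  function(object) object@Sigma)

setMethod("show", "PurePredictions", function(object) {
  cat("PurePredictions for", length(object@yp), "classes\n")
  print(round(object@yp, 6))
})

setMethod("show", "LocalRegressionModel", function(object) {
  cat("LocalRegressionModel: ", length(object@M), " classes, ",
      object@nRetained, " retained dimension(s), ", object@nDistinct,
      " distinct compositions\n", sep = "")
})

#' Transition differences between pure-class predictions
#'
#' For every ordered pair of vegetated classes (lower code to higher code),
#' the transition difference is \code{delta = y_B - y_A} with standard
#' deviation \code{sqrt(sigma_A^2 + sigma_B^2 - 2 sigma_AB)}; the covariance
#' term comes from the shared regression. Negative variances arising from
#' floating-point cancellation are clipped to zero.
#'
#' @param pred a [PurePredictions-class].
#' @param scheme a [ClassScheme-class] providing the class codes that order
#'   the pairs.
#' @return data.frame with columns \code{itr}, \code{class_from},
#'   \code{class_to}, \code{delta}, \code{sd}.
#' @export
transitionEstimates <- function(pred, scheme) {
  stopifnot(is(pred, "PurePredictions"), is(scheme, "ClassScheme"))
  codes <- classCodes(scheme)[pred@classes]
  if (anyNA(codes))
    stop("prediction classes not all present in scheme")
  ord <- order(codes)
  k <- length(ord)
  out <- vector("list", (k * (k - 1L)) %/% 2L)
  n <- 0L
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    ia <- ord[a]; ib <- ord[b]
    v <- pred@Sigma[ia, ia] + pred@Sigma[ib, ib] - 2 * pred@Sigma[ia, ib]
    n <- n + 1L
    out[[n]] <- data.frame(
      itr = encodeTransition(codes[ia], codes[ib]),
      class_from = names(codes)[ia], class_to = names(codes)[ib],
      delta = unname(pred@yp[ib] - pred@yp[ia]),
      sd = sqrt(max(v, 0)))
  }
  do.call(rbind, out)
}

#' Moving-window unmixing over a scene
#'
#' Applies the centred-SVD compositional regression over every centred 5x5
#' window of the fraction and surface-variable rasters, month by month,
#' producing per-pixel transition-difference and uncertainty maps for every
#' ordered vegetated class pair. Estimates are attached to the window's
#' centre pixel. A pixel gets estimates only when all 25 window pixels have
#' complete data and the window passes the distinct-composition gate; rim
#' pixels (whose windows would extend outside the map) and skipped windows
#' are missing. Windows never wrap or shrink.
#'
#' @param fractions array \code{[row, col, class]} with class dimnames
#'   matching the scheme.
#' @param values array \code{[row, col, mon]} of the surface variable.
#' @param scheme a [ClassScheme-class].
#' @param months month indices labelling the third dimension of
#'   \code{values}.
#' @param window odd window side length (default 5).
#' @param rtol,min_distinct see [fitLocalModel()].
#' @return a [TransitionMaps-class].
#' @export
runMovingWindow <- function(fractions, values, scheme, months = NULL,
                            window = 5L, rtol = 1e-8, min_distinct = 10L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window size must be odd")
  d <- dim(fractions)
  nr <- d[1L]; nc <- d[2L]; k <- d[3L]
  if (!identical(dim(values)[1:2], d[1:2]))
    stop("fractions and values are not co-registered")
  nm <- dim(values)[3L]
  if (is.null(months)) months <- seq_len(nm)
  if (length(months) != nm) stop("months must label dim 3 of values")
  labels <- dimnames(fractions)[[3L]]
  if (is.null(labels)) labels <- names(classCodes(scheme))
  codes <- classCodes(scheme)[labels]
  if (anyNA(codes))
    stop("fraction class labels not all present in scheme")
  vegsel <- which(labels %in% names(vegetatedClasses(scheme)))
  vegcodes <- codes[vegsel]
  ovg <- order(vegcodes)
  vegsel <- vegsel[ovg]; vegcodes <- vegcodes[ovg]
  nveg <- length(vegsel)
  npair <- (nveg * (nveg - 1L)) %/% 2L
  pa <- integer(npair); pb <- integer(npair); itr <- integer(npair)
  n <- 0L
  for (a in seq_len(nveg - 1L)) for (b in (a + 1L):nveg) {
    n <- n + 1L
    pa[n] <- a; pb[n] <- b
    itr[n] <- encodeTransition(vegcodes[a], vegcodes[b])
  }
  h <- window %/% 2L
  delta <- array(NA_real_, c(nr, nc, nm, npair))
  sdv <- array(NA_real_, c(nr, nc, nm, npair))
  counts <- c(fitted = 0L, incomplete = 0L, few_distinct = 0L,
              degenerate = 0L)
  fr <- matrix(fractions, ncol = k)  # row-major index: i + (j-1)*nr
  for (mi in seq_len(nm)) {
    ym <- values[, , mi]
    for (j in (1L + h):(nc - h)) {
      cols <- (j - h):(j + h)
      for (i in (1L + h):(nr - h)) {
        rows <- (i - h):(i + h)
        idx <- rep(rows, times = window) + rep((cols - 1L) * nr, each = window)
        y <- ym[idx]
        X <- fr[idx, , drop = FALSE]
        if (anyNA(y) || anyNA(X)) {
          counts["incomplete"] <- counts["incomplete"] + 1L
          next
        }
        fit <- .fitWindow(X, y, rtol = rtol, min_distinct = min_distinct)
        if (is.null(fit)) {
          if (distinctCompositions(X) < min_distinct)
            counts["few_distinct"] <- counts["few_distinct"] + 1L
          else counts["degenerate"] <- counts["degenerate"] + 1L
          next
        }
        pr <- .predictPure(fit, vegsel, k)
        dv <- pr$yp[pb] - pr$yp[pa]
        vv <- pr$Sigma[cbind(pa, pa)] + pr$Sigma[cbind(pb, pb)] -
          2 * pr$Sigma[cbind(pa, pb)]
        delta[i, j, mi, ] <- dv
        sdv[i, j, mi, ] <- sqrt(pmax(vv, 0))
        counts["fitted"] <- counts["fitted"] + 1L
      }
    }
  }
  new("TransitionMaps", delta = delta, sd = sdv, itr = itr,
      months = as.integer(months), scheme = schemeName(scheme),
      windowSize = window, counts = counts)
}

#' @rdname accessors
#' @export
setMethod("deltaLayer", "TransitionMaps", function(object) object@delta)

#' @rdname accessors
#' @export
setMethod("uncertaintyLayer", "TransitionMaps", function(object) object@sd)

#' @rdname accessors
#' @export
setMethod("transitionCodes", "TransitionMaps", function(object) object@itr)

#' @rdname accessors
#' @export
setMethod("monthsOf", "TransitionMaps", function(object) object@months)

setMethod("show", "TransitionMaps", function(object) {
  d <- dim(object@delta)
  cat("TransitionMaps ", d[1L], "x", d[2L], " pixels, ", d[3L],
      " month(s), ", d[4L], " transition(s) [", object@scheme, "]\n",
      sep = "")
  cat("  windows fitted: ", object@counts[["fitted"]],
      ", incomplete: ", object@counts[["incomplete"]],
      ", <min distinct: ", object@counts[["few_distinct"]],
      ", degenerate: ", object@counts[["degenerate"]], "\n", sep = "")
})
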
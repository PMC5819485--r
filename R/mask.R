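#' Vegetation co-occurrence index
#'
#' Scores, between 0 and 1, how abundantly and how evenly two vegetation
#' classes jointly span the local compositional range of a window. In the
#' plane of the two classes' presences, \code{n_q} ideal points are spread
#' evenly along the segment B = 1 - A from (0, 1) to (1, 0). For each ideal
#' point the distance to the nearest observed presence pair is taken
#' (\code{d_min}); the reference distance is the distance from the origin
#' (\code{d_max = sqrt(q_A^2 + q_B^2)}), the worst case in which neither
#' class is present anywhere. The index is
#' \deqn{I_c = 1 - \sum_k d_{min,k} / \sum_k d_{max,k},}
#' clipped to \code{[0, 1]}: 0 when both classes are absent everywhere, 1
#' when the presences sit exactly on the ideal line.
#'
#' @param p_a,p_b presence (cover fraction) vectors of the two classes over
#'   the window pixels.
#' @param n_q number of ideal points (>= 2), endpoints included.
#' @return index in \code{[0, 1]}.
#' @examples
#' cooccurrenceIndex(rep(0, 25), rep(0, 25))  # 0
#' @export
cooccurrenceIndex <- function(p_a, p_b, n_q = 11L) {
  if (length(p_a) != length(p_b))
    stop("presence vectors must have equal length")
  if (length(p_a) == 0L) stop("empty window")
  if (n_q < 2L) stop("n_q must be at least 2")
  qa <- seq(0, 1, length.out = n_q)
  qb <- 1 - qa
  d2 <- outer(qa, p_a, "-")^2 + outer(qb, p_b, "-")^2
  d_min <- sqrt(apply(d2, 1L, min))
  d_max <- sqrt(qa^2 + qb^2)
  min(max(1 - sum(d_min) / sum(d_max), 0), 1)
}

#' Per-pixel co-occurrence mask for a class pair
#'
#' Evaluates the co-occurrence index on the centred window of every pixel and
#' keeps the pixel iff the index reaches the threshold. The mask is specific
#' to the class pair; windows extending outside the map are dropped.
#'
#' @param fractions array \code{[row, col, class]} with class dimnames.
#' @param class_a,class_b class abbreviations of the pair.
#' @param threshold minimum index to keep a pixel (default 0.5).
#' @param n_q number of ideal points.
#' @param window odd window side length.
#' @return logical matrix \code{[row, col]}: TRUE = keep.
#' @export
cooccurrenceMask <- function(fractions, class_a, class_b, threshold = 0.5,
                             n_q = 11L, window = 5L) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  labels <- dimnames(fractions)[[3L]]
  ia <- match(class_a, labels); ib <- match(class_b, labels)
  if (is.na(ia) || is.na(ib))
    stop("class not present in fraction field")
  nr <- dim(fractions)[1L]; nc <- dim(fractions)[2L]
  h <- as.integer(window) %/% 2L
  keep <- matrix(FALSE, nr, nc)
  fa <- fractions[, , ia]; fb <- fractions[, , ib]
  for (j in (1L + h):(nc - h)) for (i in (1L + h):(nr - h)) {
    pa <- fa[(i - h):(i + h), (j - h):(j + h)]
    pb <- fb[(i - h):(i + h), (j - h):(j + h)]
    if (anyNA(pa) || anyNA(pb)) next
    keep[i, j] <- cooccurrenceIndex(as.vector(pa), as.vector(pb),
                                    n_q = n_q) >= threshold
  }
  keep
}

#' Topographic-relief indicators over moving windows
#'
#' From per-pixel elevation mean \code{mu_h} and standard deviation
#' \code{sigma_h}, computes for every centred window: \code{v1}, the mean of
#' \code{sigma_h} over the window; \code{v2}, the absolute difference between
#' the centre pixel's \code{mu_h} and the window mean of \code{mu_h}; and
#' \code{v3}, the absolute difference between the centre pixel's
#' \code{sigma_h} and \code{v1}. Windows extending outside the map yield
#' missing indicators.
#'
#' @param mu_h,sigma_h numeric matrices, metres.
#' @param window odd window side length.
#' @return list of matrices \code{v1}, \code{v2}, \code{v3}.
#' @export
topoIndicators <- function(mu_h, sigma_h, window = 5L) {
  if (!identical(dim(mu_h), dim(sigma_h)))
    stop("mu_h and sigma_h must share dimensions")
  nr <- nrow(mu_h); nc <- ncol(mu_h)
  h <- as.integer(window) %/% 2L
  v1 <- v2 <- v3 <- matrix(NA_real_, nr, nc)
  for (j in (1L + h):(nc - h)) for (i in (1L + h):(nr - h)) {
    ws <- sigma_h[(i - h):(i + h), (j - h):(j + h)]
    wm <- mu_h[(i - h):(i + h), (j - h):(j + h)]
    if (anyNA(ws) || anyNA(wm)) next
    v1[i, j] <- mean(ws)
    v2[i, j] <- abs(mu_h[i, j] - mean(wm))
    v3[i, j] <- abs(sigma_h[i, j] - v1[i, j])
  }
  list(v1 = v1, v2 = v2, v3 = v3)
}

#' Topographic mask from relief indicators
#'
#' Keeps a pixel iff all three indicators satisfy their strict bounds:
#' \code{v1 < 50 m}, \code{v2 < 100 m}, \code{v3 < 100 m}. Pixels failing any
#' condition -- or with missing indicators -- are dropped from all result
#' layers.
#'
#' @param ind list with matrices \code{v1}, \code{v2}, \code{v3} (from
#'   [topoIndicators()]).
#' @param v1_max,v2_max,v3_max strict thresholds, metres.
#' @return logical matrix: TRUE = keep.
#' @export
topoMask <- function(ind, v1_max = 50, v2_max = 100, v3_max = 100) {
  keep <- ind$v1 < v1_max & ind$v2 < v2_max & ind$v3 < v3_max
  keep[is.na(keep)] <- FALSE
  keep
}
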
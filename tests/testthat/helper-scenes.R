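# shared fixtures: small deterministic windows and scenes built in code

# a well-spread 25 x k composition window drawn from the fraction generator
spreadWindow <- function(seed = 3L, k_veg = 2L, k_nonveg = 2L,
                         contrast = 2.5) {
  cfg <- sceneConfig(n_rows = 5, n_cols = 5, n_veg_classes = max(k_veg, 2L),
                     n_nonveg_classes = k_nonveg, smoothness_scale = 1,
                     seed = seed, months = 1L)
  fr <- generateFractions(cfg, contrast = contrast)
  labs <- c(c("FOR", "SHR", "C+G", "SAV")[seq_len(max(k_veg, 2L))],
            c("WET", "URB", "WAT", "SNO")[seq_len(k_nonveg)])
  matrix(fr, nrow = 25L, dimnames = list(NULL, labs))
}

# exact mixture response for a window given per-class pure values
mixResponse <- function(X, pure, noise_sd = 0, seed = 1L) {
  y <- drop(X %*% pure)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), sd = noise_sd)
  }
  y
}

# direct (loop-based) co-occurrence index, independent of the package path
directCooccurrence <- function(p_a, p_b, n_q = 11L) {
  qa <- seq(0, 1, length.out = n_q)
  qb <- rev(qa)
  dmin <- numeric(n_q)
  dmax <- numeric(n_q)
  for (k in seq_len(n_q)) {
    dd <- Inf
    for (i in seq_along(p_a))
      dd <- min(dd, sqrt((qa[k] - p_a[i])^2 + (qb[k] - p_b[i])^2))
    dmin[k] <- dd
    dmax[k] <- sqrt(qa[k]^2 + qb[k]^2)
  }
  min(max(1 - sum(dmin) / sum(dmax), 0), 1)
}

# a small aggregated product with prescribed sample counts, for filter tests
toyDataset <- function(delta, n, sd = NULL, scheme = "IGBPgen") {
  itr <- schemeTransitions(scheme)
  d <- c(dim(delta)[1:2], 1L, length(itr))
  da <- array(rep(delta, length(itr)), d)
  na <- array(rep(as.integer(n), length(itr)), d)
  sa <- if (is.null(sd)) array(ifelse(is.na(da), NA_real_, 1), d)
        else array(rep(sd, length(itr)), d)
  new("BiophysicalDataset", variable = "Z", scheme = scheme,
      lat = seq_len(d[1L]) - 0.5, lon = seq_len(d[2L]) - 0.5,
      mon = 1L, itr = itr, delta = da, sd = sa, n = na)
}
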
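# Small programmatic fixtures shared across test files.

# random 4D BOLD image with identity affine and all-in mask
rand_bold <- function(xyz = c(4, 4, 3), tpoints = 30, tr = 2, seed = 1) {
  set.seed(seed)
  new("BoldImage",
      data = array(rnorm(prod(xyz) * tpoints), dim = c(xyz, tpoints)),
      trSeconds = tr, affine = diag(4),
      mask = array(TRUE, dim = xyz))
}

# dense brute-force DC oracle: full correlation matrix, thresholded
# positive edges, summed weights (independent of the blockwise path)
dense_dc_oracle <- function(seriesTxV, thresholdR, edgeKind) {
  r <- stats::cor(seriesTxV)
  diag(r) <- 0
  w <- matrix(0, nrow(r), ncol(r))
  sel <- r > thresholdR
  w[sel] <- switch(edgeKind,
                   weighted_z = atanh(pmin(pmax(r[sel], -(1 - 1e-6)), 1 - 1e-6)),
                   weighted_r = r[sel],
                   binary = 1)
  rowSums(w)
}

# exhaustive Mann-Whitney oracle: enumerate every assignment of the
# pooled values to group x via rank sums (a different route than the
# package's pair-counting enumeration)
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  rk <- rank(pooled)
  u_from_ranks <- function(ix) sum(rk[ix]) - nx * (nx + 1) / 2
  u_obs <- u_from_ranks(seq_len(nx))
  mu <- nx * length(y) / 2
  us <- apply(utils::combn(length(pooled), nx), 2, function(ix) {
    rr <- rank(pooled) # ranks fixed; assignment varies
    sum(rr[ix]) - nx * (nx + 1) / 2
  })
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# tiny ROI cohort -> feature experiment, via the package generator
small_cohort_features <- function(seed, nPerGroup = 5, nRois = 20,
                                  tpoints = 60, planted = numeric(0)) {
  cfg <- simConfig(nPerGroup = nPerGroup, nRois = nRois,
                   nVolumes = tpoints, plantedEffects = planted,
                   seed = seed)
  co <- simulateCohort(cfg)
  co$features
}
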
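# Synthetic two-group cohort generator: modular Gaussian correlation
# structure, signed "degree" perturbations planted on selected ROIs in
# the expertise group, common AR(1) temporal coloring, and behavioral
# scores with a calibrated brain-behavior correlation.

# canonical planted subregions with the sign convention of the group
# difference (positive = higher DC in the expertise group)
PLANTED_SUBREGIONS <- c(
  MFG_L_7_7 = -1, OrG_R_6_4 = -1, FuG_L_3_3 = +1,
  PhG_L_6_1 = -1, PhG_R_6_4 = -1, SFG_R_7_6 = -1, SFG_L_7_7 = +1)

default_behavior_targets <- function() {
  list(
    ret  = list(expertise = c(mean = 0.80,  sd = 0.04),
                control   = c(mean = 0.53,  sd = 0.04)),
    rt   = list(expertise = c(mean = 2.6,   sd = 0.4),
                control   = c(mean = 3.7,   sd = 0.7)),
    cfmt = list(expertise = c(mean = 56.95, sd = 5.23),
                control   = c(mean = 58.68, sd = 5.31)),
    corTarget = 0.5, corMeasure = "ret", corRoi = "FuG_L_3_3")
}

#' Construct a synthetic-cohort configuration
#'
#' Builds a validated [SimConfig] describing a two-group resting-state
#' cohort: `nPerGroup` subjects per group, `nVolumes` volumes at TR
#' `trSeconds`, an `nRois`-region atlas whose correlation matrix has
#' `nModules` contiguous modules (`rhoWithin` inside, `rhoBetween`
#' across), and signed degree perturbations (`plantedEffects`) applied to
#' selected ROI rows/columns in the expertise group only. Behavioral
#' targets default to expertise-vs-control radiological-expertise scores
#' (RET, fraction correct), RET response times and face-memory (CFMT)
#' scores, with the RET score coupled to the fusiform-analog ROI's DC at
#' a target within-group correlation of 0.5.
#'
#' @param nPerGroup subjects per group (default 22).
#' @param nRois atlas regions (default 246).
#' @param nModules correlation modules (default 6).
#' @param rhoWithin,rhoBetween module correlations (defaults 0.3, 0.1).
#' @param plantedEffects named numeric mapping ROI index to signed
#'   correlation delta. `NULL` (default) places seven effects with the
#'   canonical subregion signs at evenly spread indices, magnitude
#'   `plantedMagnitude`; `numeric(0)` plants nothing.
#' @param plantedMagnitude magnitude of the default deltas (0.3).
#' @param arPhi AR(1) coefficient (default 0.4).
#' @param nVolumes volumes per subject (default 190).
#' @param trSeconds repetition time in seconds (default 2).
#' @param voxelGrid voxel-mode grid (default `c(12, 12, 12)`).
#' @param voxelsPerRoi voxels per region in voxel mode (default 4).
#' @param voxelNoiseSd additive voxel noise SD (default 1).
#' @param behaviorTargets list of behavioral targets; see Details.
#' @param seed integer RNG seed (default 1).
#'
#' @return a [SimConfig].
#' @examples
#' cfg <- simConfig(nRois = 50, seed = 7)
#' cfg
#' @export
simConfig <- function(nPerGroup = 22L, nRois = 246L, nModules = 6L,
                      rhoWithin = 0.3, rhoBetween = 0.1,
                      plantedEffects = NULL, plantedMagnitude = 0.3,
                      arPhi = 0.4, nVolumes = 190L, trSeconds = 2,
                      voxelGrid = c(12L, 12L, 12L), voxelsPerRoi = 4L,
                      voxelNoiseSd = 1, behaviorTargets = NULL,
                      seed = 1L) {
  nRois <- as.integer(nRois)
  roiNames <- sprintf("ROI_%03d", seq_len(nRois))
  if (is.null(plantedEffects)) {
    idx <- unique(round(seq(0.1, 0.9, length.out = length(PLANTED_SUBREGIONS)) * nRois))
    if (length(idx) < length(PLANTED_SUBREGIONS))
      stop("nRois too small to place the default planted effects")
    plantedEffects <- stats::setNames(unname(PLANTED_SUBREGIONS) * plantedMagnitude,
                                      as.character(idx))
    roiNames[idx] <- names(PLANTED_SUBREGIONS)
  } else if (length(plantedEffects) && !is.null(attr(plantedEffects, "roiNames"))) {
    roiNames[as.integer(names(plantedEffects))] <- attr(plantedEffects, "roiNames")
  }
  bt <- default_behavior_targets()
  if (!is.null(behaviorTargets)) bt[names(behaviorTargets)] <- behaviorTargets
  if (!bt$corRoi %in% roiNames) bt$corRoi <- roiNames[1L]
  new("SimConfig", nPerGroup = as.integer(nPerGroup), nRois = nRois,
      nModules = as.integer(nModules), rhoWithin = rhoWithin,
      rhoBetween = rhoBetween,
      plantedEffects = if (length(plantedEffects)) plantedEffects else numeric(0),
      arPhi = arPhi, nVolumes = as.integer(nVolumes),
      trSeconds = trSeconds, voxelGrid = as.integer(voxelGrid),
      voxelsPerRoi = as.integer(voxelsPerRoi), voxelNoiseSd = voxelNoiseSd,
      behaviorTargets = bt, roiNames = roiNames, seed = as.integer(seed))
}

# floor eigenvalues at `floor` and restore the unit diagonal; iterate
# because the diagonal rescale can nudge the spectrum
repair_positive_definite <- function(m, floor = 1e-6, maxit = 50L) {
  for (i in seq_len(maxit)) {
    e <- eigen(m, symmetric = TRUE)
    if (min(e$values) >= floor) return(m)
    v <- pmax(e$values, floor)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    m <- (m + t(m)) / 2
    diag(m) <- 1
  }
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < floor)
    stop("correlation matrix could not be repaired to positive definite")
  m
}

#' Build the per-group target correlation matrices
#'
#' Constructs the modular base correlation matrix (`rhoWithin` inside
#' contiguous modules, `rhoBetween` across), applies each planted ROI's
#' signed delta to that ROI's off-diagonal row/column in the expertise
#' matrix (clipping to `[-0.95, 0.95]`, with a warning when the shift
#' would push `|r| >= 1`), and repairs both matrices to positive
#' definiteness by eigenvalue flooring at 1e-6 with unit-diagonal
#' restoration. The control matrix never carries planted deltas.
#'
#' @param config a [SimConfig].
#' @return a [CorrelationStructure].
#' @examples
#' cs <- buildGroupCovariance(simConfig(nRois = 20, plantedEffects = numeric(0)))
#' cs
#' @export
buildGroupCovariance <- function(config) {
  validObject(config)
  n <- config@nRois
  modules <- sort(rep_len(seq_len(config@nModules), n))
  base <- matrix(config@rhoBetween, n, n)
  same <- outer(modules, modules, "==")
  base[same] <- config@rhoWithin
  diag(base) <- 1
  expertise <- base
  deltas <- config@plantedEffects
  if (length(deltas)) {
    for (j in seq_along(deltas)) {
      k <- as.integer(names(deltas)[j])
      d <- deltas[[j]]
      shifted <- expertise[k, ] + d
      shifted[k] <- 1
      if (any(abs(shifted[-k]) >= 1))
        warning(sprintf("planted delta on ROI %d pushes |r| >= 1; clipping", k))
      shifted[-k] <- pmin(pmax(shifted[-k], -0.95), 0.95)
      expertise[k, ] <- shifted
      expertise[, k] <- shifted
    }
  }
  control <- repair_positive_definite(base)
  expertise <- repair_positive_definite(expertise)
  mineig <- c(
    control = min(eigen(control, symmetric = TRUE, only.values = TRUE)$values),
    expertise = min(eigen(expertise, symmetric = TRUE, only.values = TRUE)$values))
  dimnames(control) <- dimnames(expertise) <-
    list(config@roiNames, config@roiNames)
  new("CorrelationStructure", control = control, expertise = expertise,
      moduleAssignment = as.integer(modules), appliedDeltas = deltas,
      minEigenvalue = mineig)
}

# x_t = phi x_{t-1} + eps_t with eps ~ N(0, Sigma); started from the
# stationary distribution so the lag-0 covariance is Sigma / (1 - phi^2)
# at every t (lag-0 correlation = innovation correlation).
simulate_ar1_series <- function(L, phi, tpoints) {
  n <- nrow(L)
  eps <- L %*% matrix(stats::rnorm(n * tpoints), n, tpoints)
  x <- matrix(0, n, tpoints)
  x[, 1] <- eps[, 1] / sqrt(1 - phi^2)
  for (t in seq_len(tpoints)[-1]) x[, t] <- phi * x[, t - 1] + eps[, t]
  x
}

block_parcellation <- function(config) {
  grid <- config@voxelGrid
  need <- config@nRois * config@voxelsPerRoi
  if (need > prod(grid))
    stop(sprintf("voxel grid %s cannot host %d ROIs x %d voxels",
                 paste(grid, collapse = "x"), config@nRois,
                 config@voxelsPerRoi))
  labels <- array(0L, dim = grid)
  labels[seq_len(need)] <- rep(seq_len(config@nRois),
                               each = config@voxelsPerRoi)
  new("Parcellation", labels = labels,
      names = stats::setNames(config@roiNames,
                              as.character(seq_len(config@nRois))),
      affine = diag(4))
}

#' Simulate a two-group resting-state cohort
#'
#' Draws per-subject multivariate AR(1) ROI time series whose innovation
#' correlation is the subject's group matrix from
#' [buildGroupCovariance()], optionally expands each ROI series onto a
#' contiguous-block voxel parcellation with additive voxel noise, and
#' generates a matched behavioral table via [generateBehavior()].
#' Deterministic given `config@seed`.
#'
#' @param config a [SimConfig].
#' @param mode `"roi"` (ROI-by-time series only, default) or `"voxel"`
#'   (additionally builds per-subject [BoldImage] volumes and the
#'   [Parcellation]).
#'
#' @return a list with elements `series` (named list of nRois x T
#'   matrices), `bold` (list of [BoldImage], voxel mode only),
#'   `parcellation` ([Parcellation], voxel mode only), `behavior`
#'   (data.frame), `features` (a [DCExperiment] of generator-side ROI DC
#'   used for behavioral coupling), `groundTruth` ([GroundTruth]) and
#'   `config`.
#' @examples
#' cohort <- simulateCohort(simConfig(nPerGroup = 4, nRois = 10, nVolumes = 40))
#' length(cohort$series)
#' @export
simulateCohort <- function(config, mode = c("roi", "voxel")) {
  mode <- match.arg(mode)
  validObject(config)
  cs <- buildGroupCovariance(config)
  set.seed(config@seed)
  n <- config@nPerGroup
  groups <- factor(rep(c("expertise", "control"), each = n),
                   levels = c("control", "expertise"))
  ids <- sprintf("sub-%03d", seq_len(2L * n))
  Lx <- t(chol(cs@expertise))
  Lc <- t(chol(cs@control))
  series <- vector("list", 2L * n)
  names(series) <- ids
  for (i in seq_along(series)) {
    L <- if (groups[i] == "expertise") Lx else Lc
    s <- simulate_ar1_series(L, config@arPhi, config@nVolumes)
    rownames(s) <- config@roiNames
    series[[i]] <- s
  }
  bold <- NULL; parc <- NULL
  if (mode == "voxel") {
    parc <- block_parcellation(config)
    mask <- roiLabels(parc) > 0
    bold <- lapply(series, function(s) {
      lab <- roiLabels(parc)
      vox <- array(0, dim = c(dim(lab), config@nVolumes))
      flat <- matrix(0, prod(dim(lab)), config@nVolumes)
      inmask <- which(lab > 0)
      flat[inmask, ] <- s[lab[inmask], , drop = FALSE] +
        config@voxelNoiseSd * matrix(stats::rnorm(length(inmask) * config@nVolumes),
                                     length(inmask))
      vox[] <- flat
      new("BoldImage", data = vox, trSeconds = config@trSeconds,
          affine = diag(4), mask = mask)
    })
  }
  feat <- t(vapply(series, function(s) roiDC(t(s)), numeric(config@nRois)))
  features <- dcExperiment(feat, groups, roiNames = config@roiNames)
  behavior <- generateBehavior(features, config)
  gt <- new("GroundTruth", plantedRois = config@plantedEffects,
            groupLabels = stats::setNames(groups, ids),
            behaviorParams = config@behaviorTargets)
  list(series = series, bold = bold, parcellation = parc,
       behavior = behavior, features = features, groundTruth = gt,
       config = config)
}

#' Generate behavioral scores matched to the cohort
#'
#' Draws per-group behavioral scores at their target means/SDs
#' (radiological-expertise score RET as fraction correct, RET response
#' time in seconds, and the CFMT face-memory score). Within the
#' expertise group, the expertise measure is a linear function of the
#' designated ROI's DC plus Gaussian noise calibrated to the target
#' brain-behavior correlation; response time and CFMT carry no brain
#' coupling.
#'
#' @param dcFeatures a [DCExperiment] containing the designated ROI.
#' @param config a [SimConfig] (supplies `behaviorTargets`).
#' @return data.frame with columns `subject`, `group`, `ret`,
#'   `rt_seconds`, `cfmt`.
#' @export
generateBehavior <- function(dcFeatures, config) {
  bt <- config@behaviorTargets
  rho <- bt$corTarget
  if (rho <= -1 || rho >= 1)
    stop("target brain-behavior correlation must lie in (-1, 1)")
  if (!bt$corRoi %in% rownames(dcFeatures))
    stop(sprintf("designated ROI '%s' not present in features", bt$corRoi))
  groups <- groupLabels(dcFeatures)
  nsub <- ncol(dcFeatures)
  out <- data.frame(subject = colnames(dcFeatures), group = groups,
                    ret = NA_real_, rt_seconds = NA_real_,
                    cfmt = NA_real_, stringsAsFactors = FALSE)
  cols <- c(ret = "ret", rt = "rt_seconds", cfmt = "cfmt")
  for (meas in names(cols)) {
    for (g in levels(groups)) {
      sel <- groups == g
      tgt <- bt[[meas]][[g]]
      ng <- sum(sel)
      if (meas == bt$corMeasure && g == "expertise") {
        x <- dcAssay(dcFeatures)[bt$corRoi, sel]
        z <- (x - mean(x)) / stats::sd(x)
        y <- rho * z + sqrt(1 - rho^2) * stats::rnorm(ng)
        out[sel, cols[meas]] <- tgt["mean"] + tgt["sd"] * y
      } else {
        out[sel, cols[meas]] <- stats::rnorm(ng, tgt["mean"], tgt["sd"])
      }
    }
  }
  out$ret <- pmin(pmax(out$ret, 0), 1)
  out$rt_seconds <- pmax(out$rt_seconds, .Machine$double.eps)
  out
}
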
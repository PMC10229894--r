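#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib restDC, .registration = TRUE
NULL

#' BoldImage: a 4D BOLD series with acquisition metadata
#'
#' Container for a single subject's blood-oxygen-level-dependent (BOLD)
#' time series: a 4D array (X, Y, Z, T), the repetition time (TR, the
#' sampling interval along the fourth axis), a 4x4 voxel-to-world affine,
#' and a 3D logical brain mask.
#'
#' @slot data 4D numeric array (X, Y, Z, T).
#' @slot trSeconds repetition time in seconds (> 0).
#' @slot affine 4x4 voxel-to-world transform.
#' @slot mask 3D logical array matching the spatial shape of `data`.
#'
#' @export
setClass("BoldImage",
  representation(data = "array", trSeconds = "numeric",
                 affine = "matrix", mask = "array"))

setValidity("BoldImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array (X, Y, Z, T)")
  if (!identical(dim(object@mask), d[1:3]))
    return("mask shape must equal the spatial shape of data")
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    return("trSeconds must be a single positive number")
  if (!identical(dim(object@affine), c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  TRUE
})

#' Parcellation: an integer label volume with region names
#'
#' A 3D integer label volume assigning each voxel to a region of interest
#' (ROI); 0 is background. Region names follow the Brainnetome subregion
#' convention (e.g. `"FuG_L_3_3"`).
#'
#' @slot labels 3D integer array, values >= 0 (0 = background).
#' @slot names character vector of region names, named by label id.
#' @slot affine 4x4 voxel-to-world transform.
#'
#' @export
setClass("Parcellation",
  representation(labels = "array", names = "character", affine = "matrix"))

setValidity("Parcellation", function(object) {
  if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
  lab <- object@labels
  if (any(lab < 0) || any(lab != round(lab)))
    return("labels must be non-negative integers")
  present <- sort(unique(as.integer(lab[lab > 0])))
  ids <- as.integer(names(object@names))
  if (anyNA(ids)) return("names must be named by integer label ids")
  if (!all(ids %in% present))
    return("every named label must occur in the label volume")
  TRUE
})

#' DCMap: a per-subject degree-centrality map
#'
#' A 3D map of voxel-wise degree centrality (DC) with the provenance of
#' its computation: the correlation threshold, the edge-weight kind, and
#' whether the map has been normalized by its whole-brain mean.
#'
#' @slot values 3D numeric array; values outside the mask are `NA`.
#' @slot thresholdR correlation threshold (edges require r > thresholdR).
#' @slot edgeKind one of `"weighted_z"`, `"weighted_r"`, `"binary"`.
#' @slot normalized logical: divided by in-mask mean yet?
#' @slot mask 3D logical array.
#'
#' @export
setClass("DCMap",
  representation(values = "array", thresholdR = "numeric",
                 edgeKind = "character", normalized = "logical",
                 mask = "array"))

setValidity("DCMap", function(object) {
  if (!identical(dim(object@values), dim(object@mask)))
    return("values and mask shapes differ")
  if (!object@edgeKind %in% c("weighted_z", "weighted_r", "binary"))
    return("edgeKind must be weighted_z, weighted_r or binary")
  v <- object@values[object@mask]
  if (any(v < 0, na.rm = TRUE)) return("in-mask DC values must be >= 0")
  if (isTRUE(object@normalized)) {
    if (abs(mean(v) - 1) > 1e-9)
      return("normalized map must have in-mask mean 1")
  }
  TRUE
})

#' DCExperiment: subjects-by-ROI degree-centrality features
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' region-wise DC feature matrix (assay `"dc"`, ROIs in rows, subjects in
#' columns) with a binary `group` factor in `colData` (levels
#' `control`, `expertise`). This is the substrate for classification and
#' brain-behavior correlation.
#'
#' @export
setClass("DCExperiment", contains = "SummarizedExperiment")

setValidity("DCExperiment", function(object) {
  if (!"dc" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dc' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!"group" %in% colnames(cd)) return("colData must contain 'group'")
  g <- cd$group
  if (!is.factor(g) || !identical(levels(g), c("control", "expertise")))
    return("group must be a factor with levels control, expertise")
  if (anyNA(SummarizedExperiment::assay(object, "dc")))
    return("dc assay must not contain missing values")
  TRUE
})

#' SimConfig: parameters of the synthetic cohort generator
#'
#' Describes a two-group synthetic resting-state cohort: a modular
#' ROI-by-ROI correlation structure shared by both groups, signed
#' "degree" perturbations planted on selected ROIs in the expertise
#' group, a common AR(1) temporal model, and behavioral score targets.
#'
#' @slot nPerGroup subjects per group (>= 2).
#' @slot nRois number of atlas regions.
#' @slot nModules number of correlation modules.
#' @slot rhoWithin within-module correlation, in `[0, 1)`.
#' @slot rhoBetween between-module correlation, `0 <= rhoBetween <= rhoWithin`.
#' @slot plantedEffects named numeric: ROI index (as name) -> signed
#'   correlation delta applied to that ROI's row/column in the expertise
#'   group; `|delta| < 1`.
#' @slot arPhi AR(1) coefficient in (-1, 1).
#' @slot nVolumes acquired volumes per subject.
#' @slot trSeconds repetition time (s).
#' @slot voxelGrid integer(3), voxel-mode grid size.
#' @slot voxelsPerRoi voxels per region in voxel mode.
#' @slot voxelNoiseSd additive voxel noise SD (signal units).
#' @slot behaviorTargets list of per-group behavioral means/SDs, the
#'   target brain-behavior correlation and the designated ROI.
#' @slot roiNames character vector of region names (length nRois).
#' @slot seed integer RNG seed.
#'
#' @export
setClass("SimConfig",
  representation(nPerGroup = "integer", nRois = "integer",
                 nModules = "integer", rhoWithin = "numeric",
                 rhoBetween = "numeric", plantedEffects = "numeric",
                 arPhi = "numeric", nVolumes = "integer",
                 trSeconds = "numeric", voxelGrid = "integer",
                 voxelsPerRoi = "integer", voxelNoiseSd = "numeric",
                 behaviorTargets = "list", roiNames = "character",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nPerGroup < 2L) return("nPerGroup must be >= 2")
  if (object@rhoBetween < 0 || object@rhoBetween > object@rhoWithin ||
      object@rhoWithin >= 1)
    return("need 0 <= rhoBetween <= rhoWithin < 1")
  if (length(object@plantedEffects)) {
    idx <- suppressWarnings(as.integer(names(object@plantedEffects)))
    if (anyNA(idx) || any(idx < 1L) || any(idx > object@nRois))
      return("plantedEffects names must be ROI indices in 1..nRois")
    if (any(abs(object@plantedEffects) >= 1))
      return("planted deltas must satisfy |delta| < 1")
  }
  if (abs(object@arPhi) >= 1) return("arPhi must lie in (-1, 1)")
  if (object@nVolumes <= 12L)
    return("nVolumes must exceed the dropped volumes + 2")
  if (object@trSeconds <= 0) return("trSeconds must be positive")
  if (length(object@voxelGrid) != 3L) return("voxelGrid must have 3 entries")
  if (length(object@roiNames) != object@nRois)
    return("roiNames must have one name per ROI")
  ct <- object@behaviorTargets$corTarget
  if (!is.null(ct) && (ct <= -1 || ct >= 1))
    return("target brain-behavior correlation must lie in (-1, 1)")
  TRUE
})

#' CorrelationStructure: per-group target correlation matrices
#'
#' The generator's ground-truth lag-0 correlation structure: one
#' ROI-by-ROI matrix per group, the module assignment, the planted deltas
#' actually applied, and the minimum eigenvalue after positive-definite
#' repair.
#'
#' @slot control,expertise symmetric unit-diagonal positive-definite
#'   correlation matrices.
#' @slot moduleAssignment integer module id per ROI.
#' @slot appliedDeltas named numeric of planted deltas (expertise only).
#' @slot minEigenvalue smallest eigenvalue of each matrix after repair.
#'
#' @export
setClass("CorrelationStructure",
  representation(control = "matrix", expertise = "matrix",
                 moduleAssignment = "integer", appliedDeltas = "numeric",
                 minEigenvalue = "numeric"))

setValidity("CorrelationStructure", function(object) {
  for (nm in c("control", "expertise")) {
    m <- slot(object, nm)
    if (!isSymmetric(m, tol = 1e-10)) return(paste(nm, "matrix not symmetric"))
    if (max(abs(diag(m) - 1)) > 1e-9) return(paste(nm, "diagonal not unit"))
  }
  if (any(object@minEigenvalue < 1e-6 - 1e-12))
    return("matrices must be positive definite (min eigenvalue >= 1e-6)")
  TRUE
})

#' GroundTruth: what the generator planted
#'
#' Stored alongside every simulated cohort so recovery can be scored:
#' the planted ROI indices with their signed deltas, the per-subject
#' group labels, and the behavioral generative parameters.
#'
#' @slot plantedRois named numeric (ROI index -> delta).
#' @slot groupLabels factor per subject (control/expertise).
#' @slot behaviorParams list of generative behavioral parameters.
#'
#' @export
setClass("GroundTruth",
  representation(plantedRois = "numeric", groupLabels = "factor",
                 behaviorParams = "list"))

#' SelectionTrace: the RFE-SVM elimination history
#'
#' One entry per elimination iteration: the active feature set, each
#' feature's contribution to leave-one-out accuracy, the features
#' removed, and the inner-LOOCV accuracy of the active set. The chosen
#' subset is the recorded set with maximal accuracy (ties toward the
#' smaller set, then the earlier iteration).
#'
#' @slot iterations list of per-iteration records.
#' @slot chosen character vector of chosen feature names.
#' @slot chosenAccuracy inner-LOOCV accuracy of the chosen subset.
#'
#' @export
setClass("SelectionTrace",
  representation(iterations = "list", chosen = "character",
                 chosenAccuracy = "numeric"))

setValidity("SelectionTrace", function(object) {
  sizes <- vapply(object@iterations, function(it) length(it$active), 1L)
  if (length(sizes) > 1 && any(diff(sizes) >= 0))
    return("active-set size must strictly decrease across iterations")
  if (length(object@chosen) == 0L) return("chosen subset must be non-empty")
  accs <- vapply(object@iterations, function(it) it$accuracy, 1.0)
  if (object@chosenAccuracy < max(accs) - 1e-12)
    return("chosen subset must attain the maximum recorded accuracy")
  TRUE
})

#' SvmModel: a trained linear soft-margin SVM
#'
#' Linear SVM with hinge loss, trained on standardized features. The
#' decision value is `w . standardized(x) + b`; labels are coded
#' expertise = +1, so a positive weight means higher DC in the expertise
#' group.
#'
#' @slot weights named numeric weight per feature.
#' @slot bias intercept.
#' @slot cost soft-margin regularization C.
#' @slot center,scale per-feature standardization parameters from the
#'   training fold.
#'
#' @export
setClass("SvmModel",
  representation(weights = "numeric", bias = "numeric", cost = "numeric",
                 center = "numeric", scale = "numeric"))

#' ClassificationReport: LOOCV classification results
#'
#' Confusion counts, percent metrics, the ROC staircase, AUC, per-fold
#' predictions/decision values/selections, and the consensus ROI weights
#' of a descriptive pooled-selection model.
#'
#' @slot confusion named integer (TP, FN, TN, FP); positives = expertise.
#' @slot accuracy,sensitivity,specificity percent, rounded half-up to 2
#'   decimals.
#' @slot auc area under the ROC curve (pair-counting), 4 decimals.
#' @slot roc data.frame of (fpr, tpr) staircase points.
#' @slot folds data.frame of per-fold subject, truth, prediction and
#'   decision value.
#' @slot foldSelections list of per-fold selected feature names.
#' @slot consensusWeights named numeric, descriptive pooled-model weights.
#' @slot mode `"nested"` or `"pooled (optimistically biased)"`.
#'
#' @export
setClass("ClassificationReport",
  representation(confusion = "integer", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 auc = "numeric", roc = "data.frame", folds = "data.frame",
                 foldSelections = "list", consensusWeights = "numeric",
                 mode = "character"))

setValidity("ClassificationReport", function(object) {
  cf <- object@confusion
  if (!all(c("TP", "FN", "TN", "FP") %in% names(cf)))
    return("confusion must contain TP, FN, TN, FP")
  if (any(cf < 0)) return("confusion counts must be non-negative")
  if (object@auc < 0 || object@auc > 1) return("AUC must lie in [0, 1]")
  TRUE
})
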
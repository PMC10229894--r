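#' Accessors for restDC classes
#'
#' Small accessor generics so downstream code never touches slots
#' directly: `boldData()`, `trSeconds()`, `brainMask()`, `dcValues()`,
#' `roiLabels()`, `roiNames()`, `groupLabels()`, `dcAssay()`.
#'
#' @param x a restDC object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("dcValues", function(x) standardGeneric("dcValues"))
#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("dcAssay", function(x) standardGeneric("dcAssay"))

#' @rdname accessors
#' @export
setMethod("boldData", "BoldImage", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("trSeconds", "BoldImage", function(x) x@trSeconds)
#' @rdname accessors
#' @export
setMethod("brainMask", "BoldImage", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("dcValues", "DCMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("brainMask", "DCMap", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("roiLabels", "Parcellation", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("roiNames", "Parcellation", function(x) x@names)
#' @rdname accessors
#' @export
setMethod("roiNames", "SimConfig", function(x) x@roiNames)
#' @rdname accessors
#' @export
setMethod("groupLabels", "GroundTruth", function(x) x@groupLabels)
#' @rdname accessors
#' @export
setMethod("groupLabels", "DCExperiment",
          function(x) SummarizedExperiment::colData(x)$group)
#' @rdname accessors
#' @export
setMethod("dcAssay", "DCExperiment",
          function(x) SummarizedExperiment::assay(x, "dc"))

setMethod("show", "BoldImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("BoldImage: %d x %d x %d voxels, %d volumes, TR = %gs, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], object@trSeconds, sum(object@mask)))
})

setMethod("show", "Parcellation", function(object) {
  d <- dim(object@labels)
  cat(sprintf("Parcellation: %d x %d x %d grid, %d regions\n",
              d[1], d[2], d[3], length(object@names)))
})

setMethod("show", "DCMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("DCMap (%s, r > %g)%s: %d in-mask voxels, mean %.4f\n",
              object@edgeKind, object@thresholdR,
              if (object@normalized) ", normalized" else "",
              length(v), mean(v)))
})

setMethod("show", "DCExperiment", function(object) {
  callNextMethod()
  cat(sprintf("group: %d control, %d expertise\n",
              sum(groupLabels(object) == "control"),
              sum(groupLabels(object) == "expertise")))
})

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace: %d iterations, chosen %d feature(s) (inner-LOOCV accuracy %.3f)\n",
              length(object@iterations), length(object@chosen),
              object@chosenAccuracy))
  cat("chosen:", paste(object@chosen, collapse = ", "), "\n")
})

setMethod("show", "ClassificationReport", function(object) {
  cf <- object@confusion
  cat(sprintf("ClassificationReport (%s)\n", object@mode))
  cat(sprintf("  confusion: TP=%d FN=%d TN=%d FP=%d\n",
              cf["TP"], cf["FN"], cf["TN"], cf["FP"]))
  cat(sprintf("  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.4f\n",
              object@accuracy, object@sensitivity, object@specificity,
              object@auc))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d + %d subjects, %d ROIs (%d modules), T = %d, TR = %gs\n",
              object@nPerGroup, object@nPerGroup, object@nRois,
              object@nModules, object@nVolumes, object@trSeconds))
  cat(sprintf("  rho within/between = %g / %g, AR(1) phi = %g, %d planted effect(s), seed = %d\n",
              object@rhoWithin, object@rhoBetween, object@arPhi,
              length(object@plantedEffects), object@seed))
})

setMethod("show", "CorrelationStructure", function(object) {
  cat(sprintf("CorrelationStructure: %d ROIs, %d planted delta(s), min eigenvalue %.2e\n",
              nrow(object@control), length(object@appliedDeltas),
              min(object@minEigenvalue)))
})
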
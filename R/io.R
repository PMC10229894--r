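# File formats: NIfTI-1 volumes via RNifti, diff-able TSV tables for
# everything tabular, JSON for nested reports.

#' Read a 4D BOLD NIfTI file
#'
#' Accepts `.nii` and `.nii.gz`. The repetition time is taken from the
#' header's time-axis spacing (`pixdim[4]`); an explicit `tr` argument
#' overrides the header with a warning. When no mask is given, the
#' variance-positive voxels form the brain mask.
#'
#' @param path NIfTI file path.
#' @param tr optional TR override in seconds.
#' @param mask optional 3D logical mask.
#' @return a [BoldImage].
#' @export
readBold <- function(path, tr = NULL, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("'%s' is %dD; a BOLD image must be 4D", path, length(d)))
  headerTr <- RNifti::pixdim(img)[4]
  if (is.null(tr)) {
    if (!is.finite(headerTr) || headerTr <= 0)
      stop("header has no usable TR; pass an explicit tr override")
    tr <- headerTr
  } else if (is.finite(headerTr) && headerTr > 0 &&
             abs(headerTr - tr) > 1e-9) {
    warning(sprintf("TR override %gs replaces header TR %gs", tr, headerTr))
  }
  data <- array(as.numeric(img), dim = d)
  if (is.null(mask)) {
    x <- matrix(data, prod(d[1:3]), d[4])
    v <- matrixStats_rowVars(x)
    mask <- array(v > 0, dim = d[1:3])
  }
  new("BoldImage", data = data, trSeconds = tr,
      affine = structure(as.matrix(RNifti::xform(img)),
                         imagedim = NULL, code = NULL),
      mask = mask)
}

# row variances without matrixStats: two-pass, vectorized
matrixStats_rowVars <- function(x) {
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (ncol(x) - 1)
}

#' Write a BOLD image as NIfTI-1
#'
#' Lossless (double precision) round trip of data, affine and TR.
#'
#' @param bold a [BoldImage].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeBold <- function(bold, path) {
  img <- RNifti::asNifti(boldData(bold))
  attr(img, "pixdim") <- c(1, 1, 1, bold@trSeconds)
  RNifti::`sform<-`(img, structure(bold@affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a parcellation label volume
#'
#' The label volume is a 3D integer NIfTI; region names travel in a
#' two-column TSV (`label`, `name`).
#'
#' @param path label-volume NIfTI path.
#' @param namesPath path of the label-names TSV.
#' @return a [Parcellation].
#' @export
readParcellation <- function(path, namesPath) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("a label volume must be 3D")
  lab <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  tab <- utils::read.delim(namesPath, stringsAsFactors = FALSE)
  new("Parcellation", labels = lab,
      names = stats::setNames(as.character(tab$name), tab$label),
      affine = structure(as.matrix(RNifti::xform(img)),
                         imagedim = NULL, code = NULL))
}

#' @rdname readParcellation
#' @param parcellation a [Parcellation].
#' @export
writeParcellation <- function(parcellation, path, namesPath) {
  img <- RNifti::asNifti(roiLabels(parcellation))
  RNifti::`sform<-`(img, structure(parcellation@affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "int32")
  utils::write.table(
    data.frame(label = names(roiNames(parcellation)),
               name = unname(roiNames(parcellation))),
    namesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read DC features as TSV
#'
#' Features: one row per subject (`subject` column first), one column
#' per ROI. Group labels travel in a participants TSV (`subject`,
#' `group`).
#'
#' @param features a [DCExperiment].
#' @param path features TSV path.
#' @param participantsPath participants TSV path.
#' @export
writeFeatures <- function(features, path, participantsPath) {
  tab <- data.frame(subject = colnames(features),
                    t(dcAssay(features)), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(subject = colnames(features),
               group = as.character(groupLabels(features))),
    participantsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path, participantsPath) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  part <- utils::read.delim(participantsPath, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$subject
  dcExperiment(m, part$group[match(tab$subject, part$subject)])
}

#' Write per-subject ROI time-series tables
#'
#' One TSV per subject (`<id>_timeseries.tsv`): time points in rows,
#' named ROI columns.
#'
#' @param series named list of ROI x time matrices.
#' @param dir output directory.
#' @return the file paths, invisibly.
#' @export
writeRoiSeries <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(series), function(id) {
    p <- file.path(dir, paste0(id, "_timeseries.tsv"))
    utils::write.table(as.data.frame(t(series[[id]])), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Serialize a classification report to JSON
#'
#' @param report a [ClassificationReport].
#' @param path output JSON path.
#' @export
writeReport <- function(report, path) {
  obj <- list(
    mode = report@mode,
    confusion = as.list(report@confusion),
    accuracy = report@accuracy, sensitivity = report@sensitivity,
    specificity = report@specificity, auc = report@auc,
    roc = report@roc, folds = report@folds,
    fold_selections = report@foldSelections,
    consensus_weights = as.list(report@consensusWeights))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
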
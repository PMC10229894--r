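# Degree centrality (DC): thresholded positive-correlation node strength
# on the voxel (or ROI) graph, Fisher r-to-z edge weights by default,
# normalized by the whole-brain mean, then aggregated to atlas parcels.

#' Fisher r-to-z transform
#'
#' `z = atanh(r)` after clipping `|r|` at `1 - 1e-6`, so degenerate
#' duplicated series yield a large but bounded edge weight. Monotone
#' increasing.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return z value(s).
#' @examples
#' fisherZ(c(0, 0.2, 0.5))
#' @export
fisherZ <- function(r) {
  lim <- 1 - 1e-6
  atanh(pmin(pmax(r, -lim), lim))
}

edge_weight <- function(r, edgeKind) {
  switch(edgeKind,
         weighted_z = fisherZ(r),
         weighted_r = r,
         binary = rep(1, length(r)) * (r == r), # keeps shape
         stop("unknown edgeKind: ", edgeKind))
}

# columns scaled to zero mean / unit norm so crossprod gives Pearson r
unit_scale <- function(x) {
  x <- sweep(x, 2, colMeans(x), "-")
  nrm <- sqrt(colSums(x^2))
  sweep(x, 2, nrm, "/")
}

dc_from_cor_block <- function(rblock, selfIndex, thresholdR, edgeKind) {
  w <- matrix(0, nrow(rblock), ncol(rblock))
  sup <- rblock > thresholdR
  if (any(sup)) {
    w[sup] <- switch(edgeKind,
                     weighted_z = fisherZ(rblock[sup]),
                     weighted_r = rblock[sup],
                     binary = 1)
  }
  # self-correlations (r = 1) must not count as edges
  w[cbind(selfIndex, seq_along(selfIndex))] <- 0
  colSums(w)
}

#' Voxel-wise degree centrality
#'
#' For each in-mask voxel i, `DC(i) = sum over j != i of
#' w(r_ij) * [r_ij > thresholdR]` where `r_ij` is the Pearson
#' correlation between the two voxels' time courses and `w` is the
#' Fisher z transform (`edgeKind = "weighted_z"`, default), the raw
#' correlation (`"weighted_r"`), or 1 (`"binary"`). Only positive
#' suprathreshold edges count; self-edges are excluded. The voxel-by-
#' voxel correlation matrix is processed in column blocks and never
#' materialized in full; the result is independent of the block size.
#'
#' Zero-variance voxels cannot carry a correlation and are removed from
#' the mask with a warning.
#'
#' @param bold a [BoldImage].
#' @param mask 3D logical; defaults to the image's brain mask.
#' @param thresholdR strict positive correlation threshold (default 0.2).
#' @param edgeKind edge weight kind (see above).
#' @param blockSize number of voxels per block (default 2048).
#' @return an unnormalized [DCMap].
#' @seealso [normalizeDC()], [parcelAverage()], [roiDC()]
#' @export
voxelwiseDC <- function(bold, mask = brainMask(bold), thresholdR = 0.2,
                        edgeKind = c("weighted_z", "weighted_r", "binary"),
                        blockSize = 2048L) {
  edgeKind <- match.arg(edgeKind)
  if (!any(mask)) stop("mask is empty")
  d <- dim(boldData(bold))
  if (d[4] < 3L) stop("need at least 3 time points")
  x <- matrix(boldData(bold), prod(d[1:3]), d[4])
  idx <- which(mask)
  series <- t(x[idx, , drop = FALSE])          # T x V
  v <- apply(series, 2, stats::var)
  if (any(v <= 0)) {
    warning(sprintf("%d zero-variance voxel(s) removed from mask", sum(v <= 0)))
    keep <- v > 0
    idx <- idx[keep]
    series <- series[, keep, drop = FALSE]
    mask[which(mask)[!keep]] <- FALSE
  }
  nv <- length(idx)
  if (nv < 2L) stop("need at least 2 in-mask voxels with variance")
  xs <- unit_scale(series)
  dc <- numeric(nv)
  starts <- seq(1L, nv, by = blockSize)
  for (s in starts) {
    cols <- s:min(s + blockSize - 1L, nv)
    rblock <- crossprod(xs, xs[, cols, drop = FALSE])
    dc[cols] <- dc_from_cor_block(rblock, cols, thresholdR, edgeKind)
  }
  values <- array(NA_real_, dim = d[1:3])
  values[idx] <- dc
  new("DCMap", values = values, thresholdR = thresholdR,
      edgeKind = edgeKind, normalized = FALSE, mask = mask)
}

#' Normalize a DC map by its whole-brain mean
#'
#' Divides every in-mask value by the in-mask mean so each subject's map
#' has mean 1, removing global inter-individual scaling differences.
#'
#' @param dc an unnormalized [DCMap].
#' @return the normalized [DCMap].
#' @export
normalizeDC <- function(dc) {
  v <- dc@values[dc@mask]
  m <- mean(v)
  if (m <= 0)
    stop("in-mask mean DC is 0 (graph fully disconnected); review thresholdR")
  dc@values[dc@mask] <- v / m
  dc@normalized <- TRUE
  validObject(dc)
  dc
}

#' Average a DC map within atlas parcels
#'
#' For every labeled region, the mean of the in-mask DC values of its
#' voxels. Regions with no in-mask voxels are returned as `NA` so
#' callers can drop them consistently across all subjects (see
#' [dcExperiment()]).
#'
#' @param dc a [DCMap].
#' @param parcellation a [Parcellation] on the same grid.
#' @return named numeric vector, one entry per named region.
#' @export
parcelAverage <- function(dc, parcellation) {
  lab <- roiLabels(parcellation)
  if (!identical(dim(lab), dim(dc@values)))
    stop("parcellation and DC map shapes differ")
  usable <- lab > 0 & dc@mask
  if (!any(usable)) stop("no atlas labels overlap the mask")
  means <- tapply(dc@values[usable], lab[usable], mean)
  ids <- names(roiNames(parcellation))
  out <- stats::setNames(rep(NA_real_, length(ids)),
                         unname(roiNames(parcellation)))
  hit <- ids %in% names(means)
  out[hit] <- means[ids[hit]]
  out
}

#' Region-wise degree centrality from ROI time series
#'
#' The same thresholded positive-correlation edge rule as
#' [voxelwiseDC()] applied directly to the ROI-by-ROI correlation
#' matrix, followed by whole-set mean normalization. This is the fast
#' ROI-level path; the voxel path averages a voxel-wise map into parcels
#' instead.
#'
#' @param roiSeries numeric matrix, time points in rows, ROIs in columns.
#' @param thresholdR strict positive correlation threshold (default 0.2).
#' @param edgeKind edge weight kind as in [voxelwiseDC()].
#' @param normalize divide by the mean DC (default TRUE).
#' @return named numeric vector of (normalized) ROI DC values.
#' @export
roiDC <- function(roiSeries, thresholdR = 0.2,
                  edgeKind = c("weighted_z", "weighted_r", "binary"),
                  normalize = TRUE) {
  edgeKind <- match.arg(edgeKind)
  roiSeries <- as.matrix(roiSeries)
  if (ncol(roiSeries) < 2L) stop("need at least 2 ROIs")
  if (nrow(roiSeries) < 3L) stop("need at least 3 time points")
  v <- apply(roiSeries, 2, stats::var)
  if (any(v <= 0))
    stop("zero-variance ROI(s): ",
         paste(colnames(roiSeries)[v <= 0] %||% which(v <= 0), collapse = ", "))
  r <- stats::cor(roiSeries)
  w <- matrix(0, ncol(r), ncol(r))
  sup <- r > thresholdR
  diag(sup) <- FALSE
  if (any(sup)) {
    w[sup] <- switch(edgeKind,
                     weighted_z = fisherZ(r[sup]),
                     weighted_r = r[sup],
                     binary = 1)
  }
  dc <- rowSums(w)
  names(dc) <- colnames(roiSeries)
  if (normalize) {
    m <- mean(dc)
    if (m <= 0)
      stop("mean ROI DC is 0 (no suprathreshold edges); review thresholdR")
    dc <- dc / m
  }
  dc
}

#' Assemble a DC feature experiment
#'
#' Builds a [DCExperiment] from a subjects-by-ROI feature matrix and a
#' group factor. ROIs that are missing (`NA`) for any subject — e.g.
#' atlas labels with no in-mask voxels — are dropped from all subjects
#' consistently, with a message naming them.
#'
#' @param features numeric matrix, subjects in rows, ROIs in columns.
#' @param group factor (or character) with levels control/expertise.
#' @param roiNames optional ROI names (default: column names).
#' @return a [DCExperiment].
#' @export
dcExperiment <- function(features, group, roiNames = colnames(features)) {
  features <- as.matrix(features)
  if (is.null(roiNames)) roiNames <- sprintf("ROI_%03d", seq_len(ncol(features)))
  colnames(features) <- roiNames
  group <- factor(as.character(group), levels = c("control", "expertise"))
  if (anyNA(group)) stop("group must be control/expertise")
  bad <- apply(features, 2, anyNA)
  if (any(bad)) {
    message("dropping ROI(s) with missing values in at least one subject: ",
            paste(roiNames[bad], collapse = ", "))
    features <- features[, !bad, drop = FALSE]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dc = t(features)),
    colData = S4Vectors::DataFrame(group = group,
                                   row.names = rownames(features)))
  new("DCExperiment", se)
}
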
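# Temporal preprocessing of BOLD series: volume dropping, Friston-24
# motion expansion, nuisance-signal extraction, confound regression,
# linear detrending, ideal band-pass filtering and (optional) Gaussian
# smoothing. Spatial registration stages (realignment, normalization)
# are out of scope; inputs are assumed already in a common space.

#' Drop initial volumes
#'
#' Removes the first `k` volumes of a BOLD series (scanner
#' equilibration / subject adaptation period); metadata are preserved.
#'
#' @param bold a [BoldImage].
#' @param k number of leading volumes to drop (default 10).
#' @return a [BoldImage] with `T - k` volumes.
#' @export
dropInitialVolumes <- function(bold, k = 10L) {
  d <- dim(boldData(bold))
  if (k >= d[4]) stop(sprintf("cannot drop %d of %d volumes", k, d[4]))
  if (k == 0L) return(bold)
  bold@data <- boldData(bold)[, , , -(seq_len(k)), drop = FALSE]
  validObject(bold)
  bold
}

#' Friston 24-parameter motion expansion
#'
#' Expands the six rigid-body motion parameters into the 24-regressor
#' motion model: the parameters, their one-volume lags, and the squares
#' of both, ordered `[R_t, R_{t-1}, R_t^2, R_{t-1}^2]`. The first row of
#' each lagged regressor is 0.
#'
#' @param motion6 T x 6 numeric matrix or data.frame.
#' @return T x 24 numeric matrix with descriptive column names.
#' @export
friston24Expand <- function(motion6) {
  m <- as.matrix(motion6)
  if (ncol(m) != 6L) stop("motion table must have exactly 6 columns")
  lag <- rbind(0, m[-nrow(m), , drop = FALSE])
  out <- cbind(m, lag, m^2, lag^2)
  base <- colnames(m) %||% paste0("mot", 1:6)
  colnames(out) <- c(base, paste0(base, "_lag"),
                     paste0(base, "_sq"), paste0(base, "_lagsq"))
  out
}

#' Extract nuisance signals from tissue masks
#'
#' One confound column per mask: the spatial mean of the in-mask voxels
#' at each volume (global, white-matter and cerebrospinal-fluid signals
#' in the usual pipeline).
#'
#' @param bold a [BoldImage].
#' @param masks named list of 3D logical arrays.
#' @return T x length(masks) numeric matrix, one named column per mask.
#' @export
extractNuisanceSignals <- function(bold, masks) {
  d <- dim(boldData(bold))
  x <- matrix(boldData(bold), prod(d[1:3]), d[4])
  out <- vapply(names(masks), function(nm) {
    msk <- masks[[nm]]
    if (!identical(dim(msk), d[1:3]))
      stop(sprintf("mask '%s' shape does not match the image", nm))
    idx <- which(msk)
    if (!length(idx)) stop(sprintf("mask '%s' is empty", nm))
    colMeans(x[idx, , drop = FALSE])
  }, numeric(d[4]))
  colnames(out) <- names(masks)
  out
}

#' Regress confounds out of a time-by-channels series
#'
#' Ordinary least-squares residuals per channel against the confound
#' columns plus an intercept (added internally). Collinear confound
#' columns are dropped with a warning before fitting, so the design is
#' full rank; residuals are orthogonal to every retained confound.
#'
#' @param series T x channels numeric matrix.
#' @param confounds T x K numeric matrix (no intercept column needed).
#' @return residual series, same shape as `series`.
#' @export
regressConfounds <- function(series, confounds) {
  series <- as.matrix(series)
  confounds <- as.matrix(confounds)
  if (nrow(series) != nrow(confounds))
    stop("series and confounds must have the same number of rows")
  design <- cbind(intercept = 1, confounds)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    dropped <- colnames(design)[setdiff(seq_len(ncol(design)), keep)]
    warning("dropping collinear confound column(s): ",
            paste(dropped, collapse = ", "))
    design <- design[, sort(keep), drop = FALSE]
    qrd <- qr(design)
  }
  out <- qr.resid(qrd, series)
  dimnames(out) <- dimnames(series)
  out
}

#' Remove per-channel linear trends
#'
#' Fits and subtracts the best least-squares straight line (intercept +
#' slope over time) from every channel.
#'
#' @param series T x channels numeric matrix, T >= 3.
#' @return detrended series.
#' @export
detrendLinear <- function(series) {
  series <- as.matrix(series)
  if (nrow(series) < 3L) stop("need at least 3 time points")
  regressConfounds(series, cbind(t = seq_len(nrow(series))))
}

#' Ideal band-pass filter
#'
#' Discrete-Fourier ideal filter: frequency bins `f` with
#' `low <= f <= high` (inclusive on both edges) are retained, all others
#' zeroed. The 0 Hz bin is removed whenever `low > 0`, so the output is
#' mean-free. The filter is idempotent and exactly preserves/suppresses
#' sinusoids that fall on DFT bins.
#'
#' @param series T x channels numeric matrix.
#' @param tr sampling interval in seconds.
#' @param low,high band edges in Hz; `high` must not exceed the Nyquist
#'   frequency `1/(2 tr)`.
#' @return filtered series (real-valued).
#' @export
bandpassFilter <- function(series, tr, low = 0.01, high = 0.08) {
  series <- as.matrix(series)
  nyq <- 1 / (2 * tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high > nyq + 1e-12)
    stop(sprintf("high edge %.4g Hz exceeds Nyquist %.4g Hz", high, nyq))
  tp <- nrow(series)
  k <- seq_len(tp) - 1L
  f <- pmin(k, tp - k) / (tp * tr)
  keep <- f >= low - 1e-12 & f <= high + 1e-12
  spec <- stats::mvfft(series)
  spec[!keep, ] <- 0
  out <- Re(stats::mvfft(spec, inverse = TRUE)) / tp
  dimnames(out) <- dimnames(series)
  out
}

conv_axis <- function(vol, kern, axis) {
  r <- (length(kern) - 1L) / 2L
  out <- array(0, dim = dim(vol))
  n <- dim(vol)[axis]
  idx <- function(shift) {
    src <- seq_len(n) + shift
    ok <- src >= 1L & src <= n
    list(dst = seq_len(n)[ok], src = src[ok])
  }
  for (o in -r:r) {
    ii <- idx(o)
    w <- kern[o + r + 1L]
    if (axis == 1L) out[ii$dst, , ] <- out[ii$dst, , ] + w * vol[ii$src, , ]
    if (axis == 2L) out[, ii$dst, ] <- out[, ii$dst, ] + w * vol[, ii$src, ]
    if (axis == 3L) out[, , ii$dst] <- out[, , ii$dst] + w * vol[, , ii$src]
  }
  out
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` converted to voxels via the affine.
#' Edges are renormalized (convolution of a constant volume returns the
#' constant). Only isotropic voxels are supported; `fwhmMm = 0` is the
#' identity. Off by default in synthetic runs.
#'
#' @param bold a [BoldImage].
#' @param fwhmMm kernel full width at half maximum in mm (e.g. 6).
#' @return smoothed [BoldImage].
#' @export
smoothGaussian <- function(bold, fwhmMm) {
  if (fwhmMm == 0) return(bold)
  vox <- sqrt(colSums(bold@affine[1:3, 1:3]^2))
  if (diff(range(vox)) > 1e-6 * mean(vox))
    stop("anisotropic voxels are not supported (resampling is out of scope)")
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / vox[1]
  r <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  d <- dim(boldData(bold))
  # edge weight: the same separable convolution applied to a ones volume
  ones <- array(1, dim = d[1:3])
  wvol <- conv_axis(conv_axis(conv_axis(ones, kern, 1L), kern, 2L), kern, 3L)
  out <- boldData(bold)
  for (t in seq_len(d[4])) {
    v <- conv_axis(conv_axis(conv_axis(out[, , , t], kern, 1L), kern, 2L),
                   kern, 3L)
    out[, , , t] <- v / wvol
  }
  bold@data <- out
  bold
}

#' Run the default temporal preprocessing chain on ROI series
#'
#' Convenience wrapper applying, in order: initial-volume dropping,
#' confound regression (when confounds are supplied), linear detrending
#' and ideal band-pass filtering. The stages actually applied are
#' recorded in the `"stages"` attribute of the result.
#'
#' @param series T x channels matrix (ROI time courses, time in rows).
#' @param tr sampling interval (s).
#' @param drop leading volumes to drop (default 10).
#' @param confounds optional T-after-drop x K confound matrix.
#' @param band band edges in Hz (default `c(0.01, 0.08)`); `NULL` skips
#'   filtering.
#' @return processed series with attribute `"stages"`.
#' @export
preprocessSeries <- function(series, tr, drop = 10L, confounds = NULL,
                             band = c(0.01, 0.08)) {
  series <- as.matrix(series)
  stages <- character(0)
  if (drop > 0L) {
    if (drop >= nrow(series)) stop("cannot drop all time points")
    series <- series[-seq_len(drop), , drop = FALSE]
    stages <- c(stages, sprintf("drop:%d", drop))
  }
  if (!is.null(confounds)) {
    series <- regressConfounds(series, confounds)
    stages <- c(stages, "confound_regression")
  }
  series <- detrendLinear(series)
  stages <- c(stages, "detrend")
  if (!is.null(band)) {
    series <- bandpassFilter(series, tr, band[1], band[2])
    stages <- c(stages, sprintf("bandpass:%g-%g", band[1], band[2]))
  }
  attr(series, "stages") <- stages
  series
}
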
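# Behavioral group comparisons and ROI-wise brain-behavior correlation
# with false-discovery-rate control.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with tie handling. For combined samples of at
#' most `exactLimit` observations the p-value is exact, computed by
#' enumerating every assignment of the pooled values to the two groups
#' (tie-aware); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param exactLimit maximum combined size for exact enumeration
#'   (default 12).
#' @return list with `U` (statistic for `x`) and `p` (two-sided).
#' @export
mannWhitneyU <- function(x, y, exactLimit = 12L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u <- u_stat(x, y)
  mu <- nx * ny / 2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(list(U = u, p = 1))
  if (nx + ny <= exactLimit) {
    picks <- utils::combn(nx + ny, nx)
    dev <- abs(u - mu)
    us <- apply(picks, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
    p <- mean(abs(us - mu) >= dev - 1e-12)
  } else {
    n <- nx + ny
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = u, p = 1))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u, p = p)
}

#' Two-sample Student's t-test
#'
#' Pooled-variance two-sided t-test (Welch's variant via
#' `pooled = FALSE`). Samples with zero pooled variance are handled as
#' in [ttestFilter()]: p = 1 when the means are equal, p = 0 otherwise.
#'
#' @param x,y numeric samples with >= 2 observations each.
#' @param pooled use the pooled-variance statistic (default TRUE).
#' @return list with `t`, `df` and `p`.
#' @export
studentsTTwoSample <- function(x, y, pooled = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 observations per sample")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- mean(x) == mean(y)
    return(list(t = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = if (eq) 1 else 0))
  }
  ht <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the t-based two-sided p-value
#' `t = r sqrt((n-2)/(1-r^2))` on n-2 degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 3, both with nonzero variance.
#' @return list with `r` and `p`.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired samples with n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, mapped back
#' to the input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' ROI-wise brain-behavior correlation with FDR control
#'
#' Within the named group, correlates every ROI's DC value with each
#' behavioral measure (Pearson), adjusts the p-values across ROIs per
#' measure by Benjamini-Hochberg, and flags significance at adjusted
#' p < `q`.
#'
#' @param features a [DCExperiment].
#' @param behavior data.frame with columns `subject`, `group` and the
#'   behavioral measures.
#' @param group group to analyze (default `"expertise"`).
#' @param measures behavioral columns to use (default all numeric ones).
#' @param q significance level on the adjusted p (default 0.05).
#' @return data.frame with columns `roi`, `measure`, `r`, `p`, `p_fdr`,
#'   `significant`. Regions with constant DC within the group (fully
#'   disconnected nodes) are reported `NA` with a warning; a constant
#'   behavioral column is an error naming the column.
#' @export
dcBehaviorCorrelation <- function(features, behavior, group = "expertise",
                                  measures = NULL, q = 0.05) {
  g <- groupLabels(features)
  sel <- g == group
  if (sum(sel) < 3L) stop("need >= 3 subjects within the group")
  beh <- behavior[match(colnames(features)[sel], behavior$subject), ,
                  drop = FALSE]
  if (anyNA(beh$subject)) stop("behavior table is missing subjects")
  if (is.null(measures))
    measures <- setdiff(names(beh)[vapply(beh, is.numeric, TRUE)],
                        c("subject", "group"))
  dc <- dcAssay(features)[, sel, drop = FALSE]
  # a fully disconnected region has constant (zero) DC in every subject;
  # its correlation is undefined and reported NA rather than fatal
  flat <- apply(dc, 1, stats::var) == 0
  if (any(flat))
    warning("constant DC within the group, reported as NA: ",
            paste(rownames(dc)[flat], collapse = ", "))
  out <- vector("list", length(measures))
  for (mi in seq_along(measures)) {
    m <- measures[mi]
    yv <- beh[[m]]
    if (stats::var(yv) == 0)
      stop(sprintf("behavioral column '%s' is constant", m))
    res <- vapply(seq_len(nrow(dc)), function(i) {
      if (flat[i]) return(c(r = NA_real_, p = NA_real_))
      unlist(pearsonCorr(dc[i, ], yv))
    }, c(r = 0, p = 0))
    padj <- bhFdr(res["p", ])
    out[[mi]] <- data.frame(roi = rownames(dc), measure = m,
                            r = unname(res["r", ]), p = unname(res["p", ]),
                            p_fdr = unname(padj),
                            significant = !is.na(padj) & padj < q,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
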
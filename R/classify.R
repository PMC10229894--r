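# Two-stage feature selection (fold-wise two-sample t filter, then
# contribution-based RFE-SVM with inner LOOCV) and linear soft-margin
# SVM evaluation under nested leave-one-out cross-validation.
#
# Label coding throughout: expertise = +1, control = -1, so a positive
# SVM weight means higher DC in the expertise group.

labels_pm1 <- function(group) {
  g <- factor(as.character(group), levels = c("control", "expertise"))
  if (anyNA(g)) stop("labels must be control/expertise")
  ifelse(g == "expertise", 1, -1)
}

#' Train a linear soft-margin SVM
#'
#' Standardizes the features (training mean/SD), solves the hinge-loss
#' soft-margin dual by SMO, and returns an [SvmModel] whose decision
#' value is `w . standardized(x) + b` with expertise coded +1.
#'
#' @param x subjects x features numeric matrix.
#' @param group control/expertise factor (or +1/-1 numeric).
#' @param cost soft-margin regularization C (default 1).
#' @return an [SvmModel].
#' @export
trainSvm <- function(x, group, cost = 1) {
  x <- as.matrix(x)
  y <- if (is.numeric(group)) group else labels_pm1(group)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  fit <- standardize_fit(x)
  xs <- standardize_apply(x, fit)
  sol <- .smo_linear_svm(xs, y, cost)
  new("SvmModel",
      weights = stats::setNames(as.numeric(sol$w),
                                colnames(x) %||% paste0("f", seq_len(ncol(x)))),
      bias = sol$b, cost = cost, center = fit$center, scale = fit$scale)
}

#' Decision values of a trained SVM
#'
#' @param model an [SvmModel].
#' @param x subjects x features matrix on the original scale.
#' @return numeric decision values; positive predicts expertise.
#' @export
decisionValues <- function(model, x) {
  xs <- standardize_apply(as.matrix(x),
                          list(center = model@center, scale = model@scale))
  as.numeric(xs %*% model@weights + model@bias)
}

#' Fold-wise two-sample t-test feature filter
#'
#' Student's pooled-variance two-sample t-test per feature; features
#' with two-sided `p < alpha` (uncorrected) are retained. A feature with
#' zero pooled variance is retained with `p = 0` when the group means
#' differ and discarded with `p = 1` when they are equal.
#'
#' @param x subjects x features matrix.
#' @param group control/expertise labels.
#' @param alpha retention threshold (default 0.05).
#' @return integer indices of retained features, with the per-feature
#'   p-values in attribute `"p"`.
#' @export
ttestFilter <- function(x, group, alpha = 0.05) {
  x <- as.matrix(x)
  y <- labels_pm1(group)
  a <- x[y > 0, , drop = FALSE]
  b <- x[y < 0, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L) stop("need at least 2 subjects per group")
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tt), df = na + nb - 2, lower.tail = FALSE)
  degen <- se == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  keep <- which(p < alpha)
  attr(keep, "p") <- p
  keep
}

#' Inner leave-one-out SVM accuracy
#'
#' For each subject: standardize on the remaining subjects, train the
#' linear SVM on them, and predict the held-out subject. Accuracy is the
#' fraction of correct predictions. Deterministic.
#'
#' @param x subjects x features matrix.
#' @param group control/expertise labels (or +1/-1).
#' @param cost soft-margin C.
#' @return accuracy fraction in `[0, 1]`.
#' @export
innerLoocvAccuracy <- function(x, group, cost = 1) {
  x <- as.matrix(x)
  y <- if (is.numeric(group)) group else labels_pm1(group)
  if (min(sum(y > 0), sum(y < 0)) < 2L)
    stop("leave-one-out would strip a whole class: need >= 2 per group")
  dec <- .smo_loocv_decisions(x, y, cost)
  mean(ifelse(dec > 0, 1, -1) == y)
}

#' Contribution-based recursive feature elimination (RFE-SVM)
#'
#' Iteratively measures each active feature's contribution to
#' leave-one-out SVM accuracy, `contribution(f) = acc(S) - acc(S \ {f})`,
#' and removes every feature whose contribution is <= 0 (it does not
#' help classification). When every feature contributes, the single
#' feature with the smallest contribution is removed (ties: the larger
#' original column index goes first). If no feature contributes, the
#' feature with the largest contribution (ties: smallest index) is kept
#' so the active set never empties. The loop records every iteration and
#' stops at one feature; the chosen subset is the recorded set with the
#' highest accuracy, ties broken toward the smaller set, then the
#' earlier iteration.
#'
#' @param x subjects x features matrix (>= 2 features).
#' @param group control/expertise labels.
#' @param cost soft-margin C.
#' @return a [SelectionTrace].
#' @export
rfeSvm <- function(x, group, cost = 1) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("RFE needs at least 2 features")
  nms <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(x) <- nms
  y <- labels_pm1(group)
  cache <- new.env(parent = emptyenv())
  acc_of <- function(set) {
    key <- paste(set, collapse = ",")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    a <- innerLoocvAccuracy(x[, set, drop = FALSE], y, cost)
    cache[[key]] <- a
    a
  }
  active <- seq_len(ncol(x))
  iterations <- list()
  while (length(active) > 1L) {
    accS <- acc_of(active)
    contrib <- vapply(active, function(f) accS - acc_of(setdiff(active, f)),
                      numeric(1))
    removable <- active[contrib <= 0]
    if (length(removable) == length(active)) {
      keep_at <- which(contrib == max(contrib))[1L] # ties: smallest index
      removable <- active[-keep_at]
    } else if (length(removable) == 0L) {
      worst <- which(contrib == min(contrib))
      keep <- worst[length(worst)] # ties: larger original index removed
      removable <- active[keep]
    }
    iterations[[length(iterations) + 1L]] <- list(
      active = active, accuracy = accS,
      contributions = stats::setNames(contrib, nms[active]),
      removed = removable)
    active <- setdiff(active, removable)
  }
  iterations[[length(iterations) + 1L]] <- list(
    active = active, accuracy = acc_of(active),
    contributions = stats::setNames(NA_real_, nms[active]),
    removed = integer(0))
  accs <- vapply(iterations, `[[`, numeric(1), "accuracy")
  sizes <- vapply(iterations, function(it) length(it$active), integer(1))
  best <- which(accs == max(accs))
  best <- best[sizes[best] == min(sizes[best])]
  best <- best[1L]
  new("SelectionTrace", iterations = iterations,
      chosen = nms[iterations[[best]]$active],
      chosenAccuracy = accs[best])
}

select_features <- function(x, y, alpha, cost) {
  keep <- ttestFilter(x, y, alpha)
  fallback <- FALSE
  if (length(keep) == 0L) {
    # no feature passes the filter; keep the best-separating one so the
    # fold can still train and emit a prediction
    keep <- which.min(attr(keep, "p"))
    fallback <- TRUE
  }
  if (length(keep) == 1L) {
    chosen <- colnames(x)[keep]
  } else {
    trace <- rfeSvm(x[, keep, drop = FALSE], y, cost)
    chosen <- trace@chosen
  }
  list(chosen = chosen, fallback = fallback)
}

#' Nested LOOCV evaluation of the DC classifier
#'
#' Outer leave-one-out cross-validation over subjects. In `"nested"`
#' mode (the scientific default), the t-test filter and RFE-SVM run on
#' each outer fold's training subjects only; the held-out subject never
#' touches standardization, filtering or elimination for its own fold.
#' In `"pooled"` mode, selection runs once on all subjects and only the
#' SVM is cross-validated; this mirrors reporting a single consensus
#' region list but is optimistically biased, and is labeled as such.
#'
#' @param features a [DCExperiment], or a subjects x features matrix.
#' @param group labels (ignored when `features` is a [DCExperiment]).
#' @param alpha t-filter threshold (default 0.05).
#' @param cost soft-margin C (default 1).
#' @param mode `"nested"` or `"pooled"`.
#' @param consensus also fit the descriptive pooled-selection model and
#'   report its signed ROI weights (default TRUE; always on in pooled
#'   mode).
#' @return a [ClassificationReport].
#' @export
nestedEvaluate <- function(features, group = NULL, alpha = 0.05, cost = 1,
                           mode = c("nested", "pooled"), consensus = TRUE) {
  mode <- match.arg(mode)
  if (is(features, "DCExperiment")) {
    x <- t(dcAssay(features))
    group <- groupLabels(features)
  } else {
    x <- as.matrix(features)
    if (is.null(group)) stop("group labels required for a plain matrix")
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  g <- factor(as.character(group), levels = c("control", "expertise"))
  n <- nrow(x)
  if (min(table(g)) < 3L) stop("need at least 3 subjects per group")
  pooled_sel <- NULL
  if (mode == "pooled" || consensus)
    pooled_sel <- select_features(x, g, alpha, cost)
  dec <- numeric(n)
  pred <- character(n)
  selections <- vector("list", n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    gtr <- g[-i]
    sel <- if (mode == "nested") select_features(xtr, gtr, alpha, cost)
           else pooled_sel
    chosen <- sel$chosen
    model <- trainSvm(xtr[, chosen, drop = FALSE], gtr, cost)
    dec[i] <- decisionValues(model, x[i, chosen, drop = FALSE])
    pred[i] <- if (dec[i] > 0) "expertise" else "control"
    selections[[i]] <- chosen
    if (sel$fallback) attr(selections[[i]], "fallback") <- TRUE
  }
  names(selections) <- rownames(x) %||% paste0("s", seq_len(n))
  confusion <- c(
    TP = sum(pred == "expertise" & g == "expertise"),
    FN = sum(pred == "control"   & g == "expertise"),
    TN = sum(pred == "control"   & g == "control"),
    FP = sum(pred == "expertise" & g == "control"))
  met <- computeMetrics(confusion, dec, g)
  weights <- numeric(0)
  if (!is.null(pooled_sel)) {
    cm <- trainSvm(x[, pooled_sel$chosen, drop = FALSE], g, cost)
    weights <- cm@weights
  }
  new("ClassificationReport",
      confusion = as.integer(confusion) |> stats::setNames(names(confusion)),
      accuracy = met$accuracy, sensitivity = met$sensitivity,
      specificity = met$specificity, auc = met$auc, roc = met$roc,
      folds = data.frame(subject = names(selections), truth = as.character(g),
                         prediction = pred, decision = dec,
                         stringsAsFactors = FALSE),
      foldSelections = selections, consensusWeights = weights,
      mode = if (mode == "nested") "nested" else "pooled (optimistically biased)")
}

#' Classification metrics from confusion counts and decision values
#'
#' Accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)` (expertise recall) and
#' specificity `TN/(TN+FP)`, reported as percent rounded half-up to two
#' decimals; AUC by the pair-counting (Mann-Whitney) formulation with
#' ties counted 0.5, reported to four decimals; and the empirical ROC
#' staircase from (0,0) to (1,1).
#'
#' @param confusion named counts TP, FN, TN, FP.
#' @param decisions per-subject decision values (positive = expertise).
#' @param group per-subject control/expertise labels.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent),
#'   `auc`, and `roc` (data.frame of fpr/tpr points).
#' @export
computeMetrics <- function(confusion, decisions, group) {
  cf <- confusion[c("TP", "FN", "TN", "FP")]
  if (anyNA(cf) || any(cf < 0)) stop("confusion must supply TP, FN, TN, FP >= 0")
  npos <- cf[["TP"]] + cf[["FN"]]
  nneg <- cf[["TN"]] + cf[["FP"]]
  if (npos == 0L || nneg == 0L)
    stop("metrics undefined: one class is empty")
  g <- factor(as.character(group), levels = c("control", "expertise"))
  if (sum(g == "expertise") != npos || sum(g == "control") != nneg)
    stop("confusion totals do not match the labels")
  acc <- round_half_up(100 * (cf[["TP"]] + cf[["TN"]]) / (npos + nneg), 2)
  sen <- round_half_up(100 * cf[["TP"]] / npos, 2)
  spe <- round_half_up(100 * cf[["TN"]] / nneg, 2)
  pos <- decisions[g == "expertise"]
  neg <- decisions[g == "control"]
  rk <- rank(c(pos, neg), ties.method = "average")
  auc <- (sum(rk[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  ord <- order(decisions, decreasing = TRUE)
  tp <- cumsum(g[ord] == "expertise")
  fp <- cumsum(g[ord] == "control")
  # collapse tied decision values onto a single ROC point
  last <- !duplicated(decisions[ord], fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / nneg), tpr = c(0, tp[last] / npos))
  list(accuracy = acc, sensitivity = sen, specificity = spe,
       auc = round_half_up(auc, 4), roc = roc)
}
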
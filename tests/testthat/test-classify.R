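test_that("the SMO linear SVM agrees with libsvm", {
  skip_if_not_installed("e1071")
  set.seed(14)
  for (trial in 1:4) {
    n <- sample(20:50, 1); p <- sample(2:8, 1)
    x <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, -1), length.out = n)
    x[y > 0, 1] <- x[y > 0, 1] + runif(1, 0.8, 2)
    xs <- scale(x)
    ours <- restDC:::.smo_linear_svm(xs, y, 1)
    ref <- e1071::svm(xs, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = 1, scale = FALSE)
    wref <- as.numeric(t(ref$coefs) %*% ref$SV)
    sgn <- if (y[1] > 0) 1 else -1   # libsvm codes the first-seen class +1
    expect_equal(as.numeric(ours$w), sgn * wref, tolerance = 5e-3)
    expect_equal(ours$b, sgn * -ref$rho, tolerance = 5e-3)
  }
})

test_that("the t filter retains separated features and flags degenerate ones", {
  set.seed(15)
  g <- rep(c("control", "expertise"), each = 5)
  x <- cbind(sep = c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)),
             null = rnorm(10),
             const_eq = rep(2, 10),
             const_ne = rep(c(0, 1), each = 5))
  keep <- ttestFilter(x, g)
  p <- attr(keep, "p")
  expect_true(1 %in% keep)            # extreme separation retained
  expect_false(3 %in% keep)           # zero variance, equal means -> p = 1
  expect_equal(unname(p[3]), 1)
  expect_true(4 %in% keep)            # zero variance, unequal means -> p = 0
  expect_equal(unname(p[4]), 0)
  # identical group values retain nothing
  xeq <- matrix(rep(rnorm(5), 2), 10, byrow = FALSE)
  xeq <- rbind(xeq[1:5, , drop = FALSE], xeq[1:5, , drop = FALSE])
  expect_length(ttestFilter(xeq, g), 0)
  # p-values match t.test on a random feature
  ref <- t.test(x[g == "expertise", 2], x[g == "control", 2],
                var.equal = TRUE)$p.value
  expect_equal(unname(p[2]), ref, tolerance = 1e-12)
})

test_that("inner LOOCV is perfect on separated data and order-invariant", {
  set.seed(16)
  x <- cbind(c(rnorm(10, -1, 0.01), rnorm(10, 1, 0.01)))
  g <- rep(c("control", "expertise"), each = 10)
  expect_equal(innerLoocvAccuracy(x, g), 1.0)
  xm <- matrix(rnorm(24 * 5), 24, 5)
  gm <- rep(c("control", "expertise"), each = 12)
  acc <- innerLoocvAccuracy(xm, gm)
  expect_equal(innerLoocvAccuracy(xm[, sample(5)], gm), acc)
  expect_error(innerLoocvAccuracy(xm[c(1, 13:24), ], gm[c(1, 13:24)]),
               "whole class")
})

test_that("RFE keeps the separating feature and discards pure noise", {
  set.seed(17)
  n <- 20
  g <- rep(c("control", "expertise"), each = n / 2)
  x <- cbind(sep = c(rnorm(n / 2, -2, 0.05), rnorm(n / 2, 2, 0.05)),
             noise = rnorm(n))
  tr <- rfeSvm(x, g)
  expect_equal(tr@chosen, "sep")
  expect_equal(tr@chosenAccuracy, 1.0)
  # iteration sizes strictly decrease to 1
  sizes <- vapply(tr@iterations, function(it) length(it$active), 1L)
  expect_true(all(diff(sizes) < 0))
  expect_equal(sizes[length(sizes)], 1L)
  # identical copies of a separator: non-empty choice, single-feature accuracy
  xc <- cbind(a = x[, "sep"], b = x[, "sep"], c = x[, "sep"])
  trc <- rfeSvm(xc, g)
  expect_gt(length(trc@chosen), 0)
  expect_equal(trc@chosenAccuracy, innerLoocvAccuracy(x[, 1, drop = FALSE], g))
  # random input still shrinks to one feature without error
  xr <- matrix(rnorm(16 * 4), 16, 4)
  gr <- rep(c("control", "expertise"), each = 8)
  trr <- rfeSvm(xr, gr)
  expect_gt(length(trr@chosen), 0)
})

test_that("nested evaluation never lets the held-out subject into selection", {
  fx <- small_cohort_features(31, nPerGroup = 5, nRois = 12, tpoints = 50)
  rep1 <- nestedEvaluate(fx, consensus = FALSE)
  # corrupt one held-out subject's features wildly: its fold's selection
  # must not change (only its own prediction may)
  x <- t(dcAssay(fx))
  k <- 3
  x2 <- x; x2[k, ] <- x2[k, ] * 100 + 50
  rep2 <- nestedEvaluate(x2, groupLabels(fx), consensus = FALSE)
  expect_identical(rep1@foldSelections[[k]], rep2@foldSelections[[k]])
  # all other folds see the corrupted row, so overall results may differ;
  # determinism: identical input -> identical report
  rep3 <- nestedEvaluate(fx, consensus = FALSE)
  expect_identical(rep1@folds, rep3@folds)
  expect_identical(rep1@confusion, rep3@confusion)
})

test_that("nested evaluation is invariant to subject order on separated data", {
  fx <- small_cohort_features(32, nPerGroup = 5, nRois = 10, tpoints = 60,
                              planted = c(`2` = 0.45, `7` = 0.35))
  x <- t(dcAssay(fx)); g <- groupLabels(fx)
  r1 <- nestedEvaluate(x, g, consensus = FALSE)
  set.seed(1); p <- sample(nrow(x))
  r2 <- nestedEvaluate(x[p, ], g[p], consensus = FALSE)
  expect_identical(r1@confusion, r2@confusion)
})

test_that("swapping group labels swaps sensitivity and specificity and negates weights", {
  fx <- small_cohort_features(33, nPerGroup = 6, nRois = 10, tpoints = 60,
                              planted = c(`3` = 0.5))
  x <- t(dcAssay(fx)); g <- groupLabels(fx)
  gsw <- factor(ifelse(g == "control", "expertise", "control"),
                levels = c("control", "expertise"))
  m1 <- trainSvm(x, g); m2 <- trainSvm(x, gsw)
  expect_equal(m2@weights, -m1@weights, tolerance = 1e-2)
  r1 <- nestedEvaluate(x, g, consensus = FALSE)
  r2 <- nestedEvaluate(x, gsw, consensus = FALSE)
  expect_equal(r1@sensitivity, r2@specificity)
  expect_equal(r1@specificity, r2@sensitivity)
})

test_that("pooled selection is optimistically biased on null data", {
  accs <- vapply(1:10, function(seed) {
    fx <- small_cohort_features(seed + 400, nPerGroup = 5, nRois = 25,
                                tpoints = 50)
    nested <- nestedEvaluate(fx, mode = "nested", consensus = FALSE)
    pooled <- nestedEvaluate(fx, mode = "pooled")
    c(nested = unname((nested@confusion["TP"] + nested@confusion["TN"]) / 10),
      pooled = unname((pooled@confusion["TP"] + pooled@confusion["TN"]) / 10))
  }, c(nested = 0, pooled = 0))
  expect_gt(mean(accs["pooled", ]), mean(accs["nested", ]))
  # pooled mode is labeled as biased
  fx <- small_cohort_features(401, nPerGroup = 5, nRois = 10, tpoints = 50)
  expect_match(nestedEvaluate(fx, mode = "pooled")@mode, "biased")
})

test_that("metrics follow their closed forms and AUC equals the ROC area", {
  skip_if_not_installed("pROC")
  g <- factor(rep(c("expertise", "control"), each = 6),
              levels = c("control", "expertise"))
  dec <- c(2, 1.5, 1, .5, -.5, -1, -.2, -.6, -1.2, -2, .3, .1)
  pred <- ifelse(dec > 0, "expertise", "control")
  cf <- c(TP = sum(pred == "expertise" & g == "expertise"),
          FN = sum(pred == "control" & g == "expertise"),
          TN = sum(pred == "control" & g == "control"),
          FP = sum(pred == "expertise" & g == "control"))
  met <- computeMetrics(cf, dec, g)
  expect_equal(met$accuracy, round(100 * (cf[["TP"]] + cf[["TN"]]) / 12, 2))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = as.integer(g == "expertise"), predictor = dec, quiet = TRUE)))
  expect_equal(met$auc, round(ref, 4))
  # trapezoidal area under our staircase equals the pair-count AUC
  roc <- met$roc
  trap <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  expect_equal(trap, met$auc, tolerance = 1e-4)
  # all-correct case
  dec2 <- ifelse(g == "expertise", 1, -1) * seq(0.5, 6, length.out = 12)
  met2 <- computeMetrics(c(TP = 6, FN = 0, TN = 6, FP = 0),
                         ifelse(g == "expertise", abs(dec2), -abs(dec2)), g)
  expect_equal(c(met2$accuracy, met2$sensitivity, met2$specificity),
               c(100, 100, 100))
  expect_equal(met2$auc, 1)
  expect_equal(met2$roc$fpr[1], 0); expect_equal(met2$roc$tpr[1], 0)
  expect_equal(tail(met2$roc$fpr, 1), 1); expect_equal(tail(met2$roc$tpr, 1), 1)
  expect_error(computeMetrics(c(TP = 5, FN = 0, TN = 6, FP = 0), dec, g),
               "totals")
})
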
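test_that("Fisher z matches atanh and clips at the boundary", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.549306, tolerance = 1e-5)
  expect_equal(fisherZ(0.2), 0.202733, tolerance = 1e-5)
  expect_equal(fisherZ(1), atanh(1 - 1e-6))
  expect_equal(fisherZ(-1), -atanh(1 - 1e-6))
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_true(all(diff(fisherZ(r)) > 0))
})

test_that("voxelwise DC handles duplicated and uncorrelated voxels", {
  # voxel 1 == voxel 2 (r = 1, clipped); voxel 3 exactly uncorrelated
  s <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, -1, -1, 1))
  bold <- new("BoldImage",
              data = array(t(s), dim = c(3, 1, 1, 4)),
              trSeconds = 2, affine = diag(4),
              mask = array(TRUE, c(3, 1, 1)))
  dc <- voxelwiseDC(bold, thresholdR = 0.2)
  zc <- atanh(1 - 1e-6)
  expect_equal(as.numeric(dcValues(dc)[, 1, 1]), c(zc, zc, 0),
               tolerance = 1e-6)
  # all pairwise r at or below threshold -> all-zero DC
  s2 <- qr.Q(qr(matrix(rnorm(20 * 4), 20)))[, 1:4] # orthogonal columns
  bold2 <- new("BoldImage", data = array(t(s2), dim = c(4, 1, 1, 20)),
               trSeconds = 2, affine = diag(4),
               mask = array(TRUE, c(4, 1, 1)))
  expect_equal(max(abs(dcValues(voxelwiseDC(bold2)))), 0)
})

test_that("blockwise DC equals the dense oracle for every edge kind", {
  for (seed in 1:3) {
    bold <- rand_bold(c(5, 3, 2), tpoints = 50, seed = seed)
    s <- t(matrix(boldData(bold), 30, 50))
    for (kind in c("weighted_z", "weighted_r", "binary")) {
      oracle <- dense_dc_oracle(s, 0.2, kind)
      for (bs in c(7L, 30L, 1000L)) {
        dc <- voxelwiseDC(bold, thresholdR = 0.2, edgeKind = kind,
                          blockSize = bs)
        expect_equal(as.numeric(dcValues(dc)[brainMask(dc)]), oracle,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("zero-variance voxels are dropped from the mask with a warning", {
  bold <- rand_bold(c(3, 1, 1), tpoints = 20)
  bold@data[2, 1, 1, ] <- 4
  expect_warning(dc <- voxelwiseDC(bold), "zero-variance")
  expect_false(brainMask(dc)[2, 1, 1])
  expect_true(is.na(dcValues(dc)[2, 1, 1]))
})

test_that("normalization divides by the in-mask mean", {
  mk <- function(v) new("DCMap", values = array(v, c(3, 1, 1)),
                        thresholdR = 0.2, edgeKind = "weighted_z",
                        normalized = FALSE, mask = array(TRUE, c(3, 1, 1)))
  expect_equal(as.numeric(dcValues(normalizeDC(mk(c(2, 4, 6))))),
               c(0.5, 1, 1.5))
  expect_equal(as.numeric(dcValues(normalizeDC(mk(c(7, 7, 7))))), c(1, 1, 1))
  set.seed(3)
  n <- normalizeDC(mk(runif(3, 1, 5)))
  expect_equal(mean(dcValues(n)[brainMask(n)]), 1, tolerance = 1e-9)
  expect_error(normalizeDC(mk(c(0, 0, 0))), "thresholdR")
})

test_that("parcel averaging equals an independent group-by mean", {
  vals <- array(c(2, 2, 3, 1), c(4, 1, 1))
  lab <- array(c(1L, 2L, 1L, 0L), c(4, 1, 1))
  dc <- new("DCMap", values = vals, thresholdR = 0.2,
            edgeKind = "weighted_z", normalized = FALSE,
            mask = array(TRUE, c(4, 1, 1)))
  parc <- new("Parcellation", labels = lab,
              names = c(`1` = "A", `2` = "B"), affine = diag(4))
  expect_equal(parcelAverage(dc, parc), c(A = 2.5, B = 2))
  # randomized map vs brute-force loop
  set.seed(8)
  lab2 <- array(sample(0:5, 60, replace = TRUE), c(5, 4, 3))
  vals2 <- array(rnorm(60), c(5, 4, 3))
  dc2 <- new("DCMap", values = abs(vals2), thresholdR = 0.2,
             edgeKind = "weighted_z", normalized = FALSE,
             mask = array(TRUE, c(5, 4, 3)))
  parc2 <- new("Parcellation", labels = lab2,
               names = setNames(paste0("R", 1:5), 1:5), affine = diag(4))
  got <- parcelAverage(dc2, parc2)
  for (l in 1:5)
    expect_equal(unname(got[paste0("R", l)]), mean(abs(vals2)[lab2 == l]))
  # a label entirely outside the mask comes back NA
  msk <- array(TRUE, c(5, 4, 3)); msk[lab2 == 3] <- FALSE
  dc3 <- dc2; dc3@mask <- msk; dc3@values[!msk] <- NA
  expect_true(is.na(parcelAverage(dc3, parc2)["R3"]))
  expect_error(parcelAverage(dc2, parc), "shapes differ")
})

test_that("ROI DC matches the dense oracle and normalizes to mean 1", {
  set.seed(5)
  s <- matrix(rnorm(40 * 10), 40, 10)
  for (kind in c("weighted_z", "weighted_r", "binary")) {
    oracle <- dense_dc_oracle(s, 0.2, kind)
    expect_equal(unname(roiDC(s, edgeKind = kind, normalize = FALSE)),
                 oracle, tolerance = 1e-10)
  }
  expect_equal(mean(roiDC(s)), 1, tolerance = 1e-12)
  # two correlated ROIs normalize to (1, 1)
  tt <- seq_len(30)
  two <- cbind(sin(tt) + rnorm(30, sd = 0.1), sin(tt) + rnorm(30, sd = 0.1))
  expect_equal(unname(roiDC(two)), c(1, 1), tolerance = 1e-12)
  # fully subthreshold graph cannot be normalized
  orth <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))[, 1:3]
  expect_error(roiDC(orth), "thresholdR")
  # zero-variance ROI is named in the error
  s2 <- s; s2[, 4] <- 2; colnames(s2) <- paste0("R", 1:10)
  expect_error(roiDC(s2), "R4")
})

test_that("DC is invariant to affine channel rescaling and equivariant to permutation", {
  set.seed(6)
  s <- matrix(rnorm(50 * 8), 50, 8)
  base <- roiDC(s, normalize = FALSE)
  s2 <- s; s2[, 3] <- 5 * s2[, 3] + 7
  expect_equal(roiDC(s2, normalize = FALSE), base, tolerance = 1e-10)
  p <- sample(8)
  expect_equal(unname(roiDC(s[, p], normalize = FALSE)), unname(base[p]),
               tolerance = 1e-10)
  # weighted_z DC is non-negative; lowering the threshold never lowers DC
  expect_true(all(base >= 0))
  lower <- roiDC(s, thresholdR = 0.05, normalize = FALSE)
  expect_true(all(lower - base >= -1e-12))
})

test_that("voxel-level and ROI-level DC agree on the sign of planted effects", {
  cfg <- simConfig(nPerGroup = 4, nRois = 6, nModules = 2,
                   nVolumes = 60, voxelGrid = c(6, 6, 6), voxelsPerRoi = 8,
                   voxelNoiseSd = 0.3,
                   plantedEffects = structure(c(`2` = 0.5, `5` = -0.25)),
                   seed = 21)
  co <- simulateCohort(cfg, mode = "voxel")
  groups <- co$groundTruth@groupLabels
  voxfeat <- t(vapply(co$bold, function(b)
    parcelAverage(normalizeDC(voxelwiseDC(b)), co$parcellation),
    numeric(6)))
  roifeat <- t(vapply(co$series, function(s) roiDC(t(s)), numeric(6)))
  for (k in c(2, 5)) {
    dvox <- mean(voxfeat[groups == "expertise", k]) -
      mean(voxfeat[groups == "control", k])
    droi <- mean(roifeat[groups == "expertise", k]) -
      mean(roifeat[groups == "control", k])
    expect_equal(sign(dvox), sign(droi))
    expect_equal(sign(droi), sign(cfg@plantedEffects[[as.character(k)]]))
  }
})

test_that("feature assembly drops missing ROIs consistently", {
  m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), c("A", "B", "C")))
  m[2, 2] <- NA
  expect_message(fx <- dcExperiment(m, c("control", "control", "expertise", "expertise")),
                 "B")
  expect_equal(rownames(fx), c("A", "C"))
  expect_equal(dim(dcAssay(fx)), c(2L, 4L))
})
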
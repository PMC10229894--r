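test_that("initial-volume dropping keeps the tail and the metadata", {
  bold <- rand_bold(c(3, 3, 2), tpoints = 190)
  out <- dropInitialVolumes(bold, 10L)
  expect_equal(dim(boldData(out))[4], 180L)
  expect_identical(boldData(out), boldData(bold)[, , , 11:190])
  expect_identical(trSeconds(out), trSeconds(bold))
  expect_identical(brainMask(out), brainMask(bold))
  expect_identical(dropInitialVolumes(bold, 0L), bold)
  expect_error(dropInitialVolumes(bold, 190L), "cannot drop")
})

test_that("Friston-24 expansion lags and squares each motion parameter", {
  tpoints <- 12
  zero <- matrix(0, tpoints, 6)
  expect_equal(friston24Expand(zero), matrix(0, tpoints, 24),
               ignore_attr = TRUE)
  m <- matrix(rnorm(tpoints * 6), tpoints, 6)
  out <- friston24Expand(m)
  expect_equal(dim(out), c(tpoints, 24L))
  # constant column: lag is (0, c, c, ...), square is c^2
  m2 <- matrix(3, tpoints, 6)
  out2 <- friston24Expand(m2)
  expect_equal(unname(out2[, 7]), c(0, rep(3, tpoints - 1)))
  expect_equal(unname(out2[, 13]), rep(9, tpoints))
  expect_equal(unname(out2[1, 19]), 0)
  expect_equal(unname(out2[2:tpoints, 19]), rep(9, tpoints - 1))
  # ordering contract [R, R_lag, R^2, R_lag^2]
  expect_equal(out[, 1:6], m, ignore_attr = TRUE)
  expect_equal(out[, 7:12], rbind(0, m[-tpoints, ]), ignore_attr = TRUE)
  expect_equal(out[, 13:18], m^2, ignore_attr = TRUE)
  expect_error(friston24Expand(m[, 1:5]), "6 columns")
})

test_that("nuisance signals are the in-mask spatial means", {
  bold <- rand_bold(c(3, 3, 2), tpoints = 8)
  d <- dim(boldData(bold))
  full <- array(TRUE, d[1:3])
  one <- array(FALSE, d[1:3]); one[2, 2, 1] <- TRUE
  two <- array(FALSE, d[1:3]); two[1, 1, 1] <- TRUE; two[3, 3, 2] <- TRUE
  sig <- extractNuisanceSignals(bold, list(global = full, a = one, b = two))
  expect_equal(colnames(sig), c("global", "a", "b"))
  expect_equal(sig[, "a"], boldData(bold)[2, 2, 1, ])
  expect_equal(sig[, "b"],
               (boldData(bold)[1, 1, 1, ] + boldData(bold)[3, 3, 2, ]) / 2)
  # constant image -> constant column
  boldc <- bold; boldc@data[] <- 7
  expect_equal(unname(extractNuisanceSignals(boldc, list(g = full))[, 1]),
               rep(7, 8))
  empty <- array(FALSE, d[1:3])
  expect_error(extractNuisanceSignals(bold, list(csf = empty)), "csf")
})

test_that("confound regression leaves residuals orthogonal to the design", {
  set.seed(4)
  tpoints <- 40
  conf <- matrix(rnorm(tpoints * 3), tpoints, 3)
  # channel equal to a confound column vanishes
  res <- regressConfounds(cbind(conf[, 2]), conf)
  expect_lt(max(abs(res)), 1e-10)
  # intercept only -> demeaning
  x <- matrix(rnorm(tpoints * 2), tpoints, 2)
  res2 <- regressConfounds(x, matrix(nrow = tpoints, ncol = 0))
  expect_equal(res2, scale(x, scale = FALSE), ignore_attr = TRUE)
  # orthogonal channel passes through
  q <- qr.Q(qr(cbind(1, conf, rnorm(tpoints))))
  ortho <- q[, 5]
  expect_equal(regressConfounds(cbind(ortho), conf)[, 1], ortho,
               tolerance = 1e-10)
  # residuals orthogonal to every confound column
  res3 <- regressConfounds(x, conf)
  expect_lt(max(abs(crossprod(conf, res3))), 1e-8 * max(abs(x)))
  expect_warning(regressConfounds(x, cbind(conf, conf[, 1])), "collinear")
})

test_that("linear detrending removes exactly straight lines", {
  tpoints <- 30
  tt <- seq_len(tpoints)
  expect_lt(max(abs(detrendLinear(cbind(2 * tt + 5)))), 1e-10)
  # zero-mean detrended input is unchanged
  set.seed(9)
  x <- cbind(rnorm(tpoints))
  x0 <- detrendLinear(x)
  expect_equal(detrendLinear(x0), x0, tolerance = 1e-12)
  # quadratic: residual equals the lm oracle
  y <- (0:9)^2
  fit <- lm(y ~ seq_along(y))
  expect_equal(detrendLinear(cbind(y))[, 1], unname(resid(fit)),
               tolerance = 1e-10)
})

test_that("ideal bandpass keeps in-band bins and kills out-of-band bins", {
  tr <- 2; tpoints <- 360
  tt <- seq_len(tpoints)
  inband <- sin(2 * pi * 0.05 * tr * tt)       # 0.05 Hz, exact bin
  outband <- sin(2 * pi * 0.125 * tr * tt)     # 0.125 Hz, exact bin
  bp <- function(x) bandpassFilter(cbind(x), tr, 0.01, 0.08)[, 1]
  expect_equal(bp(inband), inband, tolerance = 1e-8)
  expect_lt(max(abs(bp(outband))), 1e-8)
  expect_lt(max(abs(bp(rep(5, tpoints)))), 1e-12)  # DC removed when low > 0
  # idempotence
  set.seed(2)
  x <- matrix(rnorm(tpoints * 3), tpoints, 3)
  once <- bandpassFilter(x, tr, 0.01, 0.08)
  expect_equal(bandpassFilter(once, tr, 0.01, 0.08), once,
               tolerance = 1e-10)
  expect_error(bandpassFilter(x, tr, 0.01, 0.3), "Nyquist")
})

test_that("Gaussian smoothing is a normalized separable kernel", {
  bold <- rand_bold(c(11, 11, 11), tpoints = 2)
  bold@affine <- diag(c(3, 3, 3, 1)) # 3 mm isotropic voxels
  expect_identical(smoothGaussian(bold, 0), bold)
  const <- bold; const@data[] <- 3
  expect_equal(boldData(smoothGaussian(const, 6)), boldData(const),
               tolerance = 1e-12)
  # a unit impulse at an interior voxel reproduces the closed-form
  # separable Gaussian at its neighbors
  imp <- bold
  imp@data[] <- 0; imp@data[6, 6, 6, 1] <- 1
  sm <- smoothGaussian(imp, 6)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3 # in voxels
  r <- max(1L, ceiling(4 * sigma))
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  kat <- function(d) k1[d + r + 1]
  expect_equal(boldData(sm)[6, 6, 6, 1], kat(0)^3, tolerance = 1e-10)
  expect_equal(boldData(sm)[7, 6, 6, 1], kat(1) * kat(0)^2, tolerance = 1e-10)
  expect_equal(boldData(sm)[7, 5, 6, 1], kat(1)^2 * kat(0), tolerance = 1e-10)
  aniso <- bold
  aniso@affine <- diag(c(1, 2, 1, 1))
  expect_error(smoothGaussian(aniso, 6), "anisotropic")
})

test_that("the preprocessing chain records its stages and preserves shape", {
  set.seed(11)
  x <- matrix(rnorm(60 * 4), 60, 4)
  out <- preprocessSeries(x, tr = 2, drop = 10)
  expect_equal(dim(out), c(50L, 4L))
  expect_equal(attr(out, "stages"),
               c("drop:10", "detrend", "bandpass:0.01-0.08"))
  conf <- matrix(rnorm(50 * 2), 50, 2)
  out2 <- preprocessSeries(x, tr = 2, drop = 10, confounds = conf)
  expect_true("confound_regression" %in% attr(out2, "stages"))
})
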
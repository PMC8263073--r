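test_that("stable epoch selection matches the exhaustive definition", {
  calm <- matrix(0, 1800, 6)
  expect_equal(unname(selectStableEpoch(calm, 900)), c(1, 901))

  spiked <- calm
  spiked[11, 1] <- 1  # 1 mm excursion at volume 11
  sel <- selectStableEpoch(spiked, 900)
  expect_equal(unname(sel), c(12, 912))

  drift <- matrix(0, 1000, 6)
  drift[, 1] <- seq(0, 5, length.out = 1000)  # >0.2 mm in every window
  expect_null(selectStableEpoch(drift, 900))

  # random motion vs an independent exhaustive scan
  set.seed(1)
  m <- matrix(rnorm(300 * 6, sd = 0.08), 300, 6)
  m[, 4:6] <- m[, 4:6] * 1.5
  L <- 60
  oracle <- NA
  for (s in 1:(300 - L + 1)) {
    w <- m[s:(s + L - 1), ]
    ptp <- apply(w, 2, function(x) max(x) - min(x))
    if (all(ptp < c(rep(0.2, 3), rep(0.3, 3)))) { oracle <- s; break }
  }
  got <- selectStableEpoch(m, L)
  if (is.na(oracle)) expect_null(got) else expect_equal(got[["start"]], oracle)

  expect_error(selectStableEpoch(calm, 2000), "exceeds")
})

test_that("Fourier low-pass keeps the pass band and kills the stop band", {
  tt <- 0:599
  slow <- sin(2 * pi * 0.05 * tt)
  fast <- sin(2 * pi * 0.3 * tt)
  ts <- roiTimeSeries(cbind(const = rep(5, 600), mix = slow + fast,
                            fast = sin(2 * pi * 0.2 * tt)), tr = 1)
  out <- tsMatrix(lowpassFourier(ts, 0.1))
  expect_equal(out[, "const"], rep(5, 600))
  expect_lt(max(abs(out[, "fast"])), 1e-8)
  expect_gt(cor(out[, "mix"], slow), 0.99)
  expect_error(lowpassFourier(ts, 0.5), "Nyquist")
})

test_that("low-pass filtering is idempotent and linear", {
  set.seed(2)
  x <- matrix(rnorm(400), 200, 2)
  ts <- roiTimeSeries(x, tr = 1)
  once <- tsMatrix(lowpassFourier(ts, 0.1))
  twice <- tsMatrix(lowpassFourier(roiTimeSeries(once, 1), 0.1))
  expect_equal(twice, once, tolerance = 1e-10)
  y <- matrix(rnorm(400), 200, 2)
  lhs <- tsMatrix(lowpassFourier(roiTimeSeries(2 * x + 3 * y, 1), 0.1))
  rhs <- 2 * once + 3 * tsMatrix(lowpassFourier(roiTimeSeries(y, 1), 0.1))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("global-signal regression residuals are orthogonal to the mean", {
  # identical regions: the global signal explains everything
  set.seed(3)
  v <- rnorm(100)
  same <- roiTimeSeries(cbind(a = v, b = v, c = v), tr = 1)
  expect_lt(max(abs(tsMatrix(regressGlobalSignal(same)))), 1e-10)

  x <- matrix(rnorm(5 * 300), 300, 5) +
    outer(sin(seq_len(300) / 10), rep(1, 5))
  ts <- roiTimeSeries(x, tr = 1)
  res <- tsMatrix(regressGlobalSignal(ts))
  g <- rowMeans(x)
  expect_lt(max(abs(cor(res, g))), 1e-10)
  # normal-equations oracle
  X <- cbind(1, g)
  oracle <- x - X %*% solve(crossprod(X), crossprod(X, x))
  expect_equal(res, oracle, tolerance = 1e-8, ignore_attr = TRUE)

  flat <- roiTimeSeries(cbind(a = rep(1, 10), b = rep(2, 10)), tr = 1)
  expect_warning(out <- regressGlobalSignal(flat), "constant")
  expect_equal(max(abs(tsMatrix(out))), 0)
})

test_that("in-plane Gaussian smoothing matches direct convolution", {
  img <- array(0, c(9, 9, 1, 1))
  img[5, 5, 1, 1] <- 1
  sm <- smoothImage(img, pixelSize = c(0.32, 0.35))
  K <- sm[4:6, 4:6, 1, 1]
  expect_equal(sum(K), 1, tolerance = 1e-12)
  expect_true(K[2, 2] == max(K))
  expect_equal(sum(sm), 1, tolerance = 1e-12)  # interior impulse: sum kept

  # constant image unchanged in the interior
  con <- array(3, c(8, 8, 2, 2))
  smc <- smoothImage(con, pixelSize = c(0.3, 0.3))
  expect_equal(smc[2:7, 2:7, , ], con[2:7, 2:7, , ])

  # two impulses: output is the sum of two shifted stencils
  two <- array(0, c(9, 9, 1, 1))
  two[3, 3, 1, 1] <- 1; two[7, 6, 1, 1] <- 2
  sm2 <- smoothImage(two, pixelSize = c(0.32, 0.35))
  one <- array(0, c(9, 9, 1, 1)); one[3, 3, 1, 1] <- 1
  oneB <- array(0, c(9, 9, 1, 1)); oneB[7, 6, 1, 1] <- 2
  expect_equal(sm2, smoothImage(one, pixelSize = c(0.32, 0.35)) +
                 smoothImage(oneB, pixelSize = c(0.32, 0.35)),
               tolerance = 1e-12)

  expect_error(smoothImage(img, pixelSize = NULL), "pixelSize")
})

test_that("ROI extraction equals the per-label voxel mean", {
  atlas <- generateAtlas(2, c(limbic = 1, thalamus = 1))
  d <- c(4, 4, 2, 5)
  lab <- array(0L, d[1:3])
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L
  lab[3, 3, 1] <- 2L
  lab[1:2, 4, 2] <- 3L
  lab[4, 4, 2] <- 4L
  set.seed(4)
  vol <- array(rnorm(prod(d)), d)
  ts <- extractRoiTimeseries(vol, lab, atlas, tr = 1)
  expect_equal(regionLabels(ts), atlas$region)
  # brute-force voxel loop
  for (t in seq_len(d[4])) for (r in 1:4) {
    vals <- c()
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      if (lab[i, j, k] == r) vals <- c(vals, vol[i, j, k, t])
    expect_equal(unname(tsMatrix(ts)[t, r]), mean(vals))
  }

  # uniform image: constant series
  u <- array(7, d)
  expect_true(all(tsMatrix(extractRoiTimeseries(u, lab, atlas)) == 7))

  # commutes with temporal subsetting
  sub <- extractRoiTimeseries(vol[, , , 2:4, drop = FALSE], lab, atlas)
  expect_equal(tsMatrix(sub), tsMatrix(ts)[2:4, ], ignore_attr = TRUE)

  lab2 <- lab; lab2[lab2 == 3L] <- 0L
  expect_error(extractRoiTimeseries(vol, lab2, atlas), atlas$region[3])
})

test_that("temporal SNR matches its definition", {
  set.seed(5)
  d <- c(5, 5, 1, 800)
  vol <- array(100 + rnorm(prod(d)), d)
  mask <- array(TRUE, d[1:3])
  expect_equal(as.numeric(temporalSNR(vol, mask)), 100, tolerance = 0.05 * 100)

  noise <- array(rnorm(prod(d)), d)
  expect_lt(abs(as.numeric(temporalSNR(noise, mask))), 1)

  expect_error(temporalSNR(vol, array(FALSE, d[1:3])), "empty")
  flat <- array(1, d)
  expect_error(temporalSNR(flat, mask), "zero temporal SD")
})

test_that("NIfTI and CSV round trips preserve the data", {
  d <- c(6, 6, 3, 4)
  set.seed(6)
  vol <- array(rnorm(prod(d)), d)
  f <- tempfile(fileext = ".nii.gz")
  writeVolumeSeries(vol, f, pixdim = c(0.32, 0.35, 1.2))
  back <- readVolumeSeries(f)
  expect_equal(back$data, vol, tolerance = 1e-6)
  expect_equal(back$pixdim, c(0.32, 0.35, 1.2), tolerance = 1e-6)

  ts <- roiTimeSeries(matrix(rnorm(20), 10, 2,
                             dimnames = list(NULL, c("a", "b"))), tr = 1.5)
  f2 <- tempfile(fileext = ".csv")
  writeTimeSeries(ts, f2)
  ts2 <- readTimeSeries(f2)
  expect_equal(repetitionTime(ts2), 1.5)
  expect_equal(tsMatrix(ts2), tsMatrix(ts), tolerance = 1e-6)

  mm <- rnorm(36); dim(mm) <- c(6, 6)
  w <- abs(mm + t(mm)) / 4; diag(w) <- 0
  cm <- connFromWeights(pmin(w, 0.9), n = 50)
  f3 <- tempfile(fileext = ".csv")
  writeConnectivityMatrix(cm, f3)
  cm2 <- readConnectivityMatrix(f3)
  expect_equal(connWeights(cm2), connWeights(cm), tolerance = 1e-6)
  expect_equal(cm2@nTimepoints, 50L)

  tr <- generateCaTrace(5, samplingRate = 80, burstDuty = 0.5, seed = 1)
  f4 <- tempfile(fileext = ".csv")
  writeCaTrace(tr, f4)
  tr2 <- readCaTrace(f4)
  expect_equal(samplingRate(tr2), 80)
  expect_equal(traceSamples(tr2), traceSamples(tr), tolerance = 1e-6)
})
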
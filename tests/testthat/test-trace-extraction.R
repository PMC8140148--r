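test_that("trace extraction averages the pixel set", {
  d <- array(0, c(3, 5, 5))
  d[, 2, 2] <- c(10, 11, 12)
  d[, 4, 4] <- c(20, 21, 22)
  m <- Movie(d, frameRate = 30)
  one <- extractTrace(m, rbind(c(2, 2)))
  expect_equal(traceValues(one), c(10, 11, 12))
  two <- extractTrace(m, rbind(c(2, 2), c(4, 4)))
  expect_equal(traceValues(two), c(15, 16, 17))
  expect_error(extractTrace(m, matrix(numeric(0), 0, 2)), "empty")
  expect_error(extractTrace(m, rbind(c(9, 1))), "out-of-bounds")
})

test_that("neuropil annulus matches brute-force Chebyshev distances", {
  # one disk ROI centred in a large image
  center <- c(20, 20)
  grid <- as.matrix(expand.grid(row = 1:39, col = 1:39))
  roiPx <- grid[(grid[, 1] - center[1])^2 + (grid[, 2] - center[2])^2 <= 9, ]
  rs <- RoiSet(list(roi001 = roiPx), imageDim = c(39L, 39L))
  mask <- makeNeuropilMask(rs, "roi001", innerPx = 2L, outerPx = 8L)
  # oracle: per-pixel Chebyshev distance to the ROI set
  cheb <- apply(grid, 1, function(p) {
    min(pmax(abs(p[1] - roiPx[, 1]), abs(p[2] - roiPx[, 2])))
  })
  want <- grid[cheb > 2 & cheb <= 8, ]
  got <- mask[order(mask[, 1], mask[, 2]), ]
  want <- want[order(want[, 1], want[, 2]), ]
  expect_equal(unname(got), unname(want))
})

test_that("neuropil masks exclude all ROIs and clip at image borders", {
  roiA <- as.matrix(expand.grid(row = 4:6, col = 4:6))
  roiB <- as.matrix(expand.grid(row = 4:6, col = 10:12))
  rs <- RoiSet(list(a = roiA, b = roiB), imageDim = c(16L, 16L))
  mA <- makeNeuropilMask(rs, "a", 1L, 6L)
  mB <- makeNeuropilMask(rs, "b", 1L, 6L)
  keyed <- function(px) paste(px[, 1], px[, 2])
  expect_length(intersect(keyed(mA), keyed(roiB)), 0)
  expect_length(intersect(keyed(mB), keyed(roiA)), 0)
  # close to the border: mask clipped but valid
  expect_true(all(mA[, 1] >= 1 & mA[, 2] >= 1))
  # a fully enclosed tiny image errors with an empty-mask signal
  rsTiny <- RoiSet(list(a = as.matrix(expand.grid(row = 1:5, col = 1:5))),
                   imageDim = c(5L, 5L))
  expect_error(makeNeuropilMask(rsTiny, "a", 1L, 3L), "empty")
})

test_that("neuropil compensation implements the printed rule", {
  fr <- FluorescenceTrace(c(10, 12), 30, "a", "raw")
  fn <- FluorescenceTrace(c(2, 4), 30, "a", "neuropil")
  expect_equal(traceValues(compensateNeuropil(fr, fn, 0.7)), c(10.7, 11.3))
  # constant neuropil: identity
  fc <- FluorescenceTrace(rep(5, 2), 30, "a", "neuropil")
  expect_equal(traceValues(compensateNeuropil(fr, fc, 0.7)), c(10, 12))
  # r = 0: identity
  expect_equal(traceValues(compensateNeuropil(fr, fn, 0)), c(10, 12))
  expect_error(compensateNeuropil(fr, FluorescenceTrace(1:3, 30), 0.7),
               "lengths")
  expect_error(compensateNeuropil(fr, fn, 1.2), "'r'")
})

test_that("compensation shifts output by -r*(N - median(N)), independent of F", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    f <- stats::runif(n, 50, 150)
    np <- stats::runif(n, 0, 60)
    r <- stats::runif(1)
    out <- traceValues(compensateNeuropil(
      FluorescenceTrace(f, 30), FluorescenceTrace(np, 30, stage = "neuropil"), r))
    expect_equal(out - f, -r * (np - stats::median(np)), tolerance = 1e-12)
  }
})

test_that("pipeline inversion: compensation removes simulated contamination", {
  cfg <- traceSimConfig(n_cells = 3, duration_s = 20, noise_sd = 0, seed = 23)
  sim <- simulateTraces(cfg)
  np <- FluorescenceTrace(sim$neuropil, 30, "np", "neuropil")
  for (i in 1:3) {
    obs <- FluorescenceTrace(sim$observed[, i], 30)
    comp <- compensateNeuropil(obs, np, cfg$neuropil_coeff)
    expect_equal(traceValues(comp),
                 sim$signal[, i] +
                   cfg$neuropil_coeff * stats::median(sim$neuropil),
                 tolerance = 1e-10)
  }
})

test_that("low-pass filter preserves DC and discriminates frequencies", {
  fs <- 30
  const <- FluorescenceTrace(rep(7, 300), fs)
  out <- lowpassTrace(const, 10)
  expect_equal(traceValues(out), rep(7, 300), tolerance = 1e-6)
  t <- (0:(30 * fs - 1)) / fs
  ampOf <- function(x, fHz) {
    # FFT amplitude at a given frequency
    n <- length(x)
    k <- round(fHz * n / fs)
    2 * Mod(stats::fft(x - mean(x)))[k + 1] / n
  }
  slow <- 100 + sin(2 * pi * 2 * t)
  filt <- traceValues(lowpassTrace(FluorescenceTrace(slow, fs), 10))
  expect_gte(ampOf(filt, 2), 0.95 * ampOf(slow, 2))
  expect_equal(mean(filt), mean(slow), tolerance = 1e-6)
  mixed <- 100 + sin(2 * pi * 2 * t) + sin(2 * pi * 14 * t)
  mf <- traceValues(lowpassTrace(FluorescenceTrace(mixed, fs), 10))
  att2 <- ampOf(mf, 2) / ampOf(mixed, 2)
  att14 <- ampOf(mf, 14) / ampOf(mixed, 14)
  expect_lt(att14, att2)
  expect_lt(att14, 0.2)
  expect_error(lowpassTrace(const, 15), "Nyquist")
  expect_identical(nFrames(out), 300L)
  expect_identical(frameRate(out), 30)
})

test_that("dF/F handles constant traces, excursions, and bad baselines", {
  fs <- 30
  const <- FluorescenceTrace(rep(100, 200), fs)
  expect_equal(traceValues(computeDff(const)), rep(0, 200))
  x <- rep(100, 600)
  x[300:320] <- 150
  dff <- traceValues(computeDff(FluorescenceTrace(x, fs), windowS = 10))
  expect_equal(max(dff), 0.5, tolerance = 1e-12)
  bad <- FluorescenceTrace(c(rep(0.0, 100)), fs)
  # all-zero baseline is non-positive
  expect_error(computeDff(bad), "non-positive")
})

test_that("dF/F recovers simulated event amplitudes on clean traces", {
  cfg <- traceSimConfig(n_cells = 1, duration_s = 120, event_rate_hz = 0.05,
                        noise_sd = 0, np_mean_f = 0, np_sd_f = 0, seed = 61)
  sim <- simulateTraces(cfg)
  dff <- computeDff(FluorescenceTrace(sim$observed[, 1], 30))
  ev <- sim$truth@eventTimes[[1]]
  am <- sim$truth@eventAmps[[1]]
  # well-separated events only (>= 6 s from the previous one)
  sep <- which(c(Inf, diff(ev)) > 6 & ev < 115)
  expect_gt(length(sep), 0)
  for (j in sep) {
    frames <- round(ev[j] * 30):min(round((ev[j] + 2) * 30), 3600)
    expect_equal(max(traceValues(dff)[frames]), am[j], tolerance = 0.05)
  }
})

test_that("full extraction table carries every stage for every ROI", {
  cfg <- traceSimConfig(n_cells = 4, duration_s = 3, seed = 3)
  sim <- simulateMovie(cfg, imageDim = c(48, 48))
  ex <- extractAllTraces(sim$movie, sim$rois, windowS = 2)
  expect_setequal(unique(ex$table$stage),
                  c("raw", "neuropil", "compensated", "filtered", "dff"))
  expect_length(ex$dff, 4)
  expect_s4_class(ex$dff[[1]], "FluorescenceTrace")
  expect_identical(traceStage(ex$dff[[1]]), "dff")
  expect_equal(nrow(ex$table), 4 * 5 * cfg$n_frames)
})
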
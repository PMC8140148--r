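test_that("degenerate and empty traces yield no events", {
  flat <- FluorescenceTrace(rep(0, 100), 30, stage = "dff")
  ev <- detectTransients(flat)
  expect_equal(nrow(ev), 0)
  expect_true(attr(ev, "degenerate"))
  set.seed(2)
  noise <- FluorescenceTrace(rnorm(500, 0, 0.02), 30, stage = "dff")
  evn <- detectTransients(noise)
  expect_false(attr(evn, "degenerate"))
  expect_error(detectTransients(FluorescenceTrace(1:10, 30, stage = "raw")),
               "dff")
})

test_that("the minimum-run boundary is exact: 19 frames no, 20 frames yes", {
  set.seed(11)
  for (rep in 1:50) {
    onset <- sample(50:800, 1)
    tr19 <- pulseTrace(1000, onset, 19L)
    tr20 <- pulseTrace(1000, onset, 20L)
    e19 <- detectTransients(tr19, minRun = 20L)
    e20 <- detectTransients(tr20, minRun = 20L)
    expect_equal(nrow(e19), 0)
    expect_equal(nrow(e20), 1)
    expect_equal(e20$onset_frame, onset - 1L)
    expect_equal(e20$offset_frame - e20$onset_frame, e20$duration_frames)
  }
})

test_that("single-frame dips are bridged; larger gaps split events", {
  set.seed(3)
  x <- rnorm(600, 0, 0.01)
  x[100:119] <- 1; x[120] <- 0; x[121:140] <- 1   # 1-frame dip: one event
  x[300:319] <- 1; x[322:341] <- 1                # 2-frame gap: two events
  ev <- detectTransients(FluorescenceTrace(x, 30, stage = "dff"),
                         minRun = 20L, minGap = 1L)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$onset_frame[1], 99)
  expect_equal(ev$offset_frame[1], 140)
})

test_that("raising the threshold never adds events", {
  set.seed(9)
  cfg <- traceSimConfig(n_cells = 1, duration_s = 100, seed = 9)
  sim <- simulateTraces(cfg)
  dff <- computeDff(lowpassTrace(compensateNeuropil(
    FluorescenceTrace(sim$observed[, 1], 30),
    FluorescenceTrace(sim$neuropil, 30, stage = "neuropil"))))
  counts <- vapply(c(1, 2, 3, 4, 6, 10),
                   function(k) nrow(detectTransients(dff, kSigma = k)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events never overlap and cover only supra-threshold frames", {
  set.seed(13)
  cfg <- traceSimConfig(n_cells = 3, duration_s = 200, seed = 13)
  sim <- simulateTraces(cfg)
  for (i in 1:3) {
    dff <- computeDff(lowpassTrace(compensateNeuropil(
      FluorescenceTrace(sim$observed[, i], 30),
      FluorescenceTrace(sim$neuropil, 30, stage = "neuropil"))))
    ev <- detectTransients(dff)
    if (nrow(ev) > 1) {
      expect_true(all(ev$onset_frame[-1] >= ev$offset_frame[-nrow(ev)]))
    }
    x <- traceValues(dff)
    theta <- stats::median(x) + 3 * 1.4826 * stats::median(abs(x - stats::median(x)))
    for (r in seq_len(nrow(ev))) {
      seg <- x[(ev$onset_frame[r] + 1):(ev$offset_frame[r])]
      # ends of each merged run are genuinely supra-threshold
      expect_gt(seg[1], theta)
      expect_gt(seg[length(seg)], theta)
      expect_equal(ev$amplitude[r], max(seg))
    }
  }
})

test_that("activity classification needs at least one event", {
  none <- data.frame()
  one <- data.frame(onset_frame = 1)
  expect_false(classifyActive(none))
  expect_true(classifyActive(one))
  expect_true(classifyActive(do.call(rbind, replicate(100, one, simplify = FALSE))))
})

test_that("cell metrics arithmetic", {
  ev <- data.frame(onset_frame = c(0, 100, 200, 300),
                   offset_frame = c(30, 130, 230, 330),
                   peak_frame = c(10, 110, 210, 310),
                   amplitude = c(0.2, 0.4, 0.3, 0.5),
                   duration_frames = rep(30, 4))
  cm <- cellMetrics(ev, nFrames = 15000, frameRateHz = 30)
  expect_equal(cm$frequency_per_min, 0.48)
  expect_equal(cm$mean_amplitude, 0.35)
  expect_true(cm$is_active)
  cm0 <- cellMetrics(ev[0, ], nFrames = 15000, frameRateHz = 30)
  expect_equal(cm0$frequency_per_min, 0)
  expect_true(is.na(cm0$mean_amplitude))
  expect_false(cm0$is_active)
  expect_equal(cellMetrics(data.frame(amplitude = c(0.2, 0.4),
                                      onset_frame = c(1, 50)),
                           900, 30)$mean_amplitude, 0.3)
})

test_that("FOV summaries report exact active fractions", {
  mk <- function(active) data.frame(roi_id = sprintf("r%02d", seq_along(active)),
                                    is_active = active,
                                    n_transients = as.integer(active),
                                    frequency_per_min = as.numeric(active),
                                    mean_amplitude = ifelse(active, 0.3, NA))
  expect_equal(summarizeFov(mk(c(TRUE, TRUE, TRUE)))$fraction_active, 1)
  expect_equal(summarizeFov(mk(c(FALSE, FALSE)))$fraction_active, 0)
  expect_equal(summarizeFov(mk(c(TRUE, TRUE, TRUE, FALSE)))$fraction_active, 0.75)
  expect_error(summarizeFov(mk(logical(0))), "at least one")
})

test_that("a mixed FOV recovers the active fraction", {
  # 3 silent and 5 active cells: silent cells get rate 0 via a spliced sim
  cfgA <- traceSimConfig(n_cells = 5, duration_s = 120, event_rate_hz = 0.1,
                         seed = 41)
  cfgS <- traceSimConfig(n_cells = 3, duration_s = 120, event_rate_hz = 0,
                         seed = 42)
  simA <- simulateTraces(cfgA); simS <- simulateTraces(cfgS)
  dffs <- list()
  mk <- function(sim, i, id) {
    computeDff(lowpassTrace(compensateNeuropil(
      FluorescenceTrace(sim$observed[, i], 30, roiId = id),
      FluorescenceTrace(sim$neuropil, 30, stage = "neuropil"))))
  }
  for (i in 1:5) dffs[[sprintf("a%02d", i)]] <- mk(simA, i, sprintf("a%02d", i))
  for (i in 1:3) dffs[[sprintf("s%02d", i)]] <- mk(simS, i, sprintf("s%02d", i))
  res <- analyzeFov(dffs)
  active <- res$cells$is_active[order(res$cells$roi_id)]
  expect_true(all(!active[6:8]))
  expect_gte(res$fov$fraction_active, 4 / 8)
  expect_lte(res$fov$fraction_active, 5 / 8)
})
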
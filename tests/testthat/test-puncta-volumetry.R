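test_that("empty stacks and empty diameter lists give zero counts", {
  vox <- c(0.1, 0.1, 0.1)
  ph <- simulatePunctaStack(c(10, 20, 20), vox, numeric(0), seed = 1)
  expect_equal(sum(ph$stack), 0)
  res <- punctaDensity(ph$stack, vox)
  expect_equal(res$count, 0L)
  expect_equal(res$density_per_um3, 0)
})

test_that("five half-micron spheres are counted exactly with exact density", {
  vox <- c(0.1, 0.1, 0.1)
  shape <- c(20, 40, 40)
  ph <- simulatePunctaStack(shape, vox, rep(0.5, 5), seed = 7)
  lab <- labelComponents3d(ph$stack)
  expect_equal(max(lab), 5)
  res <- punctaDensity(ph$stack, vox)
  expect_equal(res$count, 5L)
  expect_equal(res$density_per_um3, 5 / prod(shape * vox))
  # per-component voxel counts match the generator record
  expect_setequal(res$sizes$n_voxels, ph$truth$n_voxels)
})

test_that("the 1 um high-pass filter removes a 2 um sphere", {
  vox <- c(0.1, 0.1, 0.1)
  ph <- simulatePunctaStack(c(30, 60, 60), vox, c(2, 0.5), seed = 3)
  res <- punctaDensity(ph$stack, vox, minDiamUm = 0.01, maxDiamUm = 1)
  expect_equal(res$count, 1L)
  expect_equal(sum(!res$sizes$kept), 1)
  big <- res$sizes[!res$sizes$kept, ]
  expect_gt(big$equiv_diameter_um, 1)
  # without the high-pass both survive
  resAll <- punctaDensity(ph$stack, vox, minDiamUm = 0.01, maxDiamUm = 10)
  expect_equal(resAll$count, 2L)
})

test_that("dropping z slices shrinks the analysed volume accordingly", {
  vox <- c(0.5, 0.2, 0.2)
  stack <- array(FALSE, c(10, 8, 8))
  stack[5, 4, 4] <- TRUE
  res <- punctaDensity(stack, vox, dropZSlices = c(2, 2))
  expect_equal(res$volume_um3, 6 * 8 * 8 * prod(vox))
  expect_equal(res$count, 1L)
  expect_error(punctaDensity(stack, vox, dropZSlices = c(5, 5)),
               "no analysed volume")
})

test_that("26- and 6-connectivity label a corner-touching pair differently", {
  stack <- array(FALSE, c(2, 2, 2))
  stack[1, 1, 1] <- TRUE
  stack[2, 2, 2] <- TRUE
  expect_equal(max(labelComponents3d(stack, 26L)), 1)
  expect_equal(max(labelComponents3d(stack, 6L)), 2)
})

test_that("infeasible sphere packings are rejected", {
  expect_error(simulatePunctaStack(c(6, 6, 6), c(0.1, 0.1, 0.1),
                                   rep(0.4, 30), seed = 1, maxTries = 50),
               "overlap|fit")
})

test_that("Cavalieri estimator: single slice, zeros, sphere phantom", {
  expect_equal(cavalieriVolume(3.5, sliceIncrement = 0.2), 0.7)
  expect_equal(cavalieriVolume(rep(0, 10), sliceIncrement = 1), 0)
  tab <- simulateSliceAreas("sphere", 1, 0.01)
  vol <- cavalieriVolume(tab)
  expect_equal(vol, 4 * pi / 3, tolerance = 0.01 * 4 * pi / 3)
  # equatorial slice of the unit sphere has area ~pi
  expect_equal(max(tab$area_mm2), pi, tolerance = 1e-3)
})

test_that("halving the increment never worsens the Cavalieri error", {
  truth <- 4 * pi / 3
  errs <- vapply(c(0.08, 0.04, 0.02, 0.01), function(t) {
    abs(cavalieriVolume(simulateSliceAreas("sphere", 1, t)) - truth)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("ellipsoid phantom converges to 4/3 pi abc", {
  tab <- simulateSliceAreas("ellipsoid", c(1, 2, 0.5), 0.005)
  expect_equal(cavalieriVolume(tab), 4 * pi / 3 * 1 * 2 * 0.5,
               tolerance = 0.01 * 4 * pi)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSliceAreasCsv(tab, path)
  back <- readSliceAreasCsv(path)
  expect_equal(cavalieriVolume(back), cavalieriVolume(tab))
})

test_that("ICV normalization is a percentage", {
  expect_equal(normalizeToIcv(1, 1), 100)
  expect_equal(normalizeToIcv(0, 2), 0)
  expect_equal(normalizeToIcv(0.9852, 1), 98.52)
  expect_error(normalizeToIcv(1, 0), "icvVolume")
})

test_that("laminar profile conserves counts and bins correctly", {
  roi <- rbind(c(0, 0), c(10, 0), c(10, 20), c(0, 20))
  # all points in band 4 of 10 (y in [6, 8))
  pts <- cbind(stats::runif(25, 1, 9), stats::runif(25, 6.1, 7.9))
  prof <- laminarDensityProfile(pts, roi, 10, axis = c(0, 1))
  expect_equal(prof, c(0, 0, 0, 25L, 0, 0, 0, 0, 0, 0))
  # uniform grid: equal counts per band
  g <- as.matrix(expand.grid(x = seq(0.5, 9.5, 1), y = seq(1, 19, 2)))
  profG <- laminarDensityProfile(g, roi, 10)
  expect_true(all(profG == profG[1]))
  # out-of-ROI objects are ignored; empty profile when none inside
  far <- cbind(stats::runif(5, 100, 110), stats::runif(5, 100, 110))
  expect_equal(sum(laminarDensityProfile(far, roi, 10)), 0)
  mixed <- rbind(pts, far)
  expect_equal(sum(laminarDensityProfile(mixed, roi, 10)), 25)
  # boundary object at the top edge lands in the closed last band
  top <- rbind(c(5, 20))
  expect_equal(laminarDensityProfile(top, roi, 10)[10], 1L)
})

test_that("laminar profile respects an arbitrary axis", {
  roi <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  pts <- cbind(seq(0.5, 9.5, 1), rep(5, 10))
  profX <- laminarDensityProfile(pts, roi, 10, axis = c(1, 0))
  expect_equal(profX, rep(1L, 10))
  expect_error(laminarDensityProfile(pts, roi, 10, axis = c(0, 0)),
               "axis")
})
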
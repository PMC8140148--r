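test_that("shoelace area: unit square, orientation independence, validation", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygonArea(sq), 1)
  expect_equal(polygonArea(sq[4:1, ]), 1)
  expect_error(polygonArea(sq[1:2, ]), ">= 3")
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygonArea(bow), "self-intersecting")
})

test_that("polygon area matches the fan-triangulation oracle on random polygons", {
  set.seed(31)
  for (rep in 1:200) {
    poly <- randomStarPolygon(sample(5:14, 1), scale = stats::runif(1, 0.5, 200))
    expect_equal(polygonArea(poly), oracleFanArea(poly),
                 tolerance = 1e-9)
  }
})

test_that("polyline lengths: 3-4-5, square perimeter, semicircle arc", {
  expect_equal(polylineLength(rbind(c(0, 0), c(3, 4))), 5)
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0, 0))
  expect_equal(polylineLength(sq), 8)
  theta <- seq(0, pi, length.out = 1000)
  semi <- cbind(100 * cos(theta), 100 * sin(theta))
  expect_equal(polylineLength(semi), 100 * pi, tolerance = 0.001 * 100 * pi)
  expect_error(polylineLength(rbind(c(0, 0))), ">= 2")
})

test_that("beeline distances: on-line, perpendicular foot, endpoint clamp", {
  seg <- rbind(c(0, 0), c(10, 0))
  expect_equal(pointPolylineDistance(c(5, 0), seg), 0)
  expect_equal(pointPolylineDistance(c(5, 7), seg), 7)
  expect_equal(pointPolylineDistance(c(-3, 4), seg), 5)  # clamps to (0,0)
  zig <- rbind(c(0, 0), c(1, 1), c(2, 0))
  expect_equal(pointPolylineDistance(c(1, 1), zig), 0)
})

test_that("beeline distance matches the dense-sampling oracle", {
  set.seed(17)
  for (rep in 1:25) {
    pl <- cbind(cumsum(stats::runif(4, -2, 2)), cumsum(stats::runif(4, -2, 2)))
    p <- stats::runif(2, -3, 3)
    expect_equal(pointPolylineDistance(p, pl),
                 oracleDenseDistance(p, pl, 1e5),
                 tolerance = 1e-3)
  }
})

test_that("geometry is scale-equivariant", {
  set.seed(8)
  poly <- randomStarPolygon(9)
  pl <- poly[1:4, ]
  p <- c(0.2, -0.3)
  for (s in c(0.01, 3, 1000)) {
    expect_equal(polygonArea(poly * s), s^2 * polygonArea(poly),
                 tolerance = 1e-9)
    expect_equal(polylineLength(pl * s), s * polylineLength(pl),
                 tolerance = 1e-9)
    expect_equal(pointPolylineDistance(p * s, pl * s),
                 s * pointPolylineDistance(p, pl), tolerance = 1e-9)
  }
})

test_that("synapse classification follows the mitochondrion-first rule", {
  mk <- function(pre, post, psd) {
    SynapseAnnotation("s", rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                      rbind(c(0, 0), c(10, 0)), mitoPre = pre, mitoPost = post,
                      psdAsymmetric = psd)
  }
  expect_equal(classifySynapse(mk(1, 1, FALSE)), "inhibitory")
  expect_equal(classifySynapse(mk(2, 3, TRUE)), "inhibitory")
  expect_equal(classifySynapse(mk(1, 0, TRUE)), "excitatory")
  expect_equal(classifySynapse(mk(0, 1, FALSE)), "unclassified")
  expect_equal(classifySynapse(mk(0, 0, FALSE)), "unclassified")
})

test_that("synapse metrics reproduce generator ground truth", {
  sim <- simulateSynapses(synapseSimConfig(n_synapses = 12, seed = 5))
  met <- synapseMetrics(sim$annotations)
  expect_equal(met$synapses$area, sim$truth$area, tolerance = 1e-6)
  expect_equal(met$synapses$az_length, sim$truth$azLength, tolerance = 1e-6)
  expect_equal(met$synapses$class, sim$truth$class)
  expect_equal(met$synapses$vesicle_count,
               vapply(sim$annotations, function(a) nrow(a@vesicles), integer(1)))
  for (i in seq_along(sim$annotations)) {
    got <- met$vesicles$distance[met$vesicles$synapse_id ==
                                   sim$annotations[[i]]@synapseId]
    expect_equal(got, sim$truth$vesicleDistances[[i]], tolerance = 1e-6)
  }
})

test_that("synapse edge cases: zero synapses, zero vesicles, determinism", {
  empty <- simulateSynapses(synapseSimConfig(n_synapses = 0, seed = 1))
  expect_length(empty$annotations, 0)
  expect_equal(nrow(synapseMetrics(empty$annotations)$synapses), 0)
  noVes <- simulateSynapses(synapseSimConfig(n_synapses = 4,
                                             vesicle_count_mean = 0, seed = 2))
  met <- synapseMetrics(noVes$annotations)
  expect_true(all(met$synapses$vesicle_count == 0))
  expect_equal(nrow(met$vesicles), 0)
  a <- simulateSynapses(synapseSimConfig(n_synapses = 5, seed = 9))
  b <- simulateSynapses(synapseSimConfig(n_synapses = 5, seed = 9))
  expect_equal(synapseMetrics(a$annotations), synapseMetrics(b$annotations))
})

test_that("mixing coordinate units across annotations is rejected", {
  mk <- function(u) SynapseAnnotation("s", rbind(c(0, 0), c(10, 0), c(5, 8)),
                                      rbind(c(0, 0), c(10, 0)), units = u)
  expect_error(synapseMetrics(list(mk("nm"), mk("um"))), "units")
})

test_that("annotations round-trip through the JSON schema", {
  sim <- simulateSynapses(synapseSimConfig(n_synapses = 4, seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  writeSynapseJson(sim$annotations, path)
  back <- readSynapseJson(path)
  m1 <- synapseMetrics(sim$annotations)
  m2 <- synapseMetrics(back)
  expect_equal(m2, m1, tolerance = 1e-12)
})
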
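test_that("hard-core mosaics respect the exclusion radius and the seed", {
  m <- simulateMosaic(898, 18, region = c(0, 1000, 0, 1000), seed = 5)
  pts <- mosaicPoints(m)
  expect_equal(nrow(pts), 898)
  expect_gte(min(dist(pts)), 18)
  m2 <- simulateMosaic(898, 18, region = c(0, 1000, 0, 1000), seed = 5)
  expect_identical(pts, mosaicPoints(m2))
  expect_equal(mosaicDensity(m), 898)
  expect_error(simulateMosaic(5000, 18), "packing")
})

test_that("density recovery profiles of CSR mosaics are flat", {
  worst <- 0
  for (s in 1:20) {
    m <- simulateMosaic(898, 0, seed = 100 + s)
    pr <- drp(m, binWidth = 5, maxRadius = 60)
    dens <- pr@annulusDensity
    edges <- pr@binEdges
    # Poisson counting SE per annulus
    areas <- pi * diff(edges^2)
    nRef <- sum(mosaicPoints(m)[, 1] >= 60 & mosaicPoints(m)[, 1] <= 940 &
                  mosaicPoints(m)[, 2] >= 60 & mosaicPoints(m)[, 2] <= 940)
    expCount <- pr@meanDensity / 1e6 * areas * nRef
    se <- sqrt(expCount) / (nRef * areas) * 1e6
    worst <- max(worst, abs(dens - pr@meanDensity) / se)
  }
  expect_lt(worst, 4)
})

test_that("the effective radius recovers a known hard core", {
  eff <- vapply(1:20, function(s)
    effectiveRadius(drp(simulateMosaic(898, 18, seed = 200 + s),
                        binWidth = 2, maxRadius = 60)), numeric(1))
  expect_lt(abs(median(eff) - 18) / 18, 0.15)
  effCSR <- vapply(1:20, function(s)
    effectiveRadius(drp(simulateMosaic(898, 0, seed = 300 + s),
                        binWidth = 2, maxRadius = 60)), numeric(1))
  expect_lte(median(effCSR), 2)
  expect_error(drp(simulateMosaic(40, 0, region = c(0, 200, 0, 200))),
               "at least 50")
})

test_that("territory area matches closed-form polygons and is rigid-motion invariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(territoryArea(sq), 1)
  s <- 3
  hexAngles <- seq(0, 300, by = 60) * pi / 180
  hex <- cbind(s * cos(hexAngles), s * sin(hexAngles))
  expect_equal(territoryArea(hex), 3 * sqrt(3) / 2 * s^2, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(territoryArea(hex %*% R), territoryArea(hex), tolerance = 1e-9)
  # dense samples of a disc approach pi R^2 from below
  set.seed(7)
  r <- sqrt(runif(5000)); a <- runif(5000, 0, 2 * pi)
  disc <- 10 * cbind(r * cos(a), r * sin(a))
  area <- territoryArea(disc)
  expect_lt(area, pi * 100)
  expect_gt(area, 0.95 * pi * 100)
  expect_error(territoryArea(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(territoryArea(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("apposition fractions hit the trivial geometric anchors", {
  sc <- simulateNeuriteScene(nPuncta = 60, connectedFraction = 1, seed = 9)
  expect_equal(appositionFraction(sc, 0.5)$fraction, 1)
  far <- simulateNeuriteScene(volume = c(12, 12, 6), tubeRadius = 0.3,
                              nPuncta = 40, connectedFraction = 0, seed = 10,
                              skeleton = rbind(c(1, 1, 0.6), c(1, 11, 0.6)),
                              layerBounds = c(4.5, 5.4))
  # puncta live in a z-slab more than 1 um above the tube
  af <- appositionFraction(far, 1)
  expect_equal(af$fraction, 0)
  expect_true(all(af$distances > 1))
})

test_that("apposition fraction is monotone in the threshold", {
  sc <- simulateNeuriteScene(nPuncta = 120, connectedFraction = 0.4, seed = 12)
  sw <- appositionSweep(sc, seq(0.25, 1, by = 0.25))
  expect_true(all(diff(sw$fraction) >= 0))
  expect_error(appositionFraction(
    new("NeuriteScene", mask = sc@mask, voxelSize = sc@voxelSize,
        puncta = matrix(numeric(0), 0, 3), layerBounds = sc@layerBounds)),
    "no puncta")
  empty <- new("NeuriteScene", mask = array(FALSE, dim(sc@mask)),
               voxelSize = sc@voxelSize, puncta = sc@puncta,
               layerBounds = sc@layerBounds)
  expect_warning(af <- appositionFraction(empty, 0.5), "empty")
  expect_equal(af$fraction, 0)
})

test_that("the Monte Carlo null is reproducible and detects connected scenes", {
  sc <- simulateNeuriteScene(nPuncta = 100, connectedFraction = 0.6, seed = 13)
  a <- randomizedNull(sc, nIter = 199, seed = 31)
  b <- randomizedNull(sc, nIter = 199, seed = 31)
  expect_identical(a$nullFractions, b$nullFractions)
  expect_gt(a$observed, a$nullMean + 6 * a$nullSd)
  expect_lt(a$p, 0.01)
  expect_warning(randomizedNull(sc, nIter = 50, seed = 1), "100")
})

test_that("masks and puncta round-trip through TIFF and CSV", {
  sc <- simulateNeuriteScene(volume = c(5, 5, 3), nPuncta = 10,
                             connectedFraction = 0.5, seed = 14)
  tf <- tempfile(fileext = ".tif")
  writeMask(sc@mask, tf)
  expect_identical(readMask(tf), sc@mask)
  pf <- tempfile(fileext = ".csv")
  writePointsCsv(puncta(sc), pf)
  expect_equal(unname(readPointsCsv(pf)), unname(puncta(sc)),
               tolerance = 1e-12)
  unlink(c(tf, pf))
})
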
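test_that("the response-weighted ensemble matches a brute-force oracle", {
  set.seed(21)
  s <- rnorm(40)
  w <- rnorm(40)
  ens <- responseWeightedEnsemble(s, w, lagFrames = 5)
  # brute force with explicit loops
  sc <- s - mean(s); wc <- w - mean(w)
  for (row in 1:3) {
    t <- 4 + row
    expect_equal(ens$segments[row, ],
                 wc[t] * sc[t - 0:4], tolerance = 1e-12)
  }
  expect_equal(ens$globalAverage, colMeans(ens$segments))
})

test_that("a one-frame-delayed copy response peaks at lag 1", {
  set.seed(22)
  s <- rnorm(3000)
  resp <- c(0, s[-3000])             # response = stimulus delayed by 1 frame
  ens <- responseWeightedEnsemble(s, resp, lagFrames = 8)
  expect_equal(which.max(abs(ens$globalAverage)), 2L)  # lag index 2 = 1 frame
})

test_that("uncorrelated responses give a vanishing global average", {
  set.seed(23)
  s <- rnorm(18000); resp <- rnorm(18000)
  ens <- responseWeightedEnsemble(s, resp, lagFrames = 10)
  expect_lt(max(abs(ens$globalAverage)), 5 / sqrt(18000))
  expect_error(responseWeightedEnsemble(s, rep(2, 18000), lagFrames = 10),
               "weights are zero")
})

test_that("ON/OFF splitting recovers known LN kernels and honors the contract", {
  set.seed(42)
  s <- rnorm(18000, 0, 0.2)
  kOn <- biphasicKernel(troughWeight = 0.6)
  kOff <- biphasicKernel(troughWeight = 0.05)
  resp <- pmax(causalConv(s, kOn), 0) + 1.5 * pmax(-causalConv(s, kOff), 0)
  fp <- recoverFilters(s, resp, lagFrames = 15)
  expect_gt(cor(onFilter(fp), kOn), 0.9)
  expect_gt(cor(offFilter(fp), -kOff), 0.9)
  expect_equal(sum(onFilter(fp)) + sum(offFilter(fp)),
               sum(fp@globalAverage), tolerance = 1e-12)
  expect_equal(fp@scaleChecksum, sum(onFilter(fp)) + sum(offFilter(fp)))
})

test_that("a purely linear cell collapses onto one kernel-shaped filter", {
  set.seed(43)
  s <- rnorm(18000, 0, 0.2)
  k <- biphasicKernel(troughWeight = 0.4)
  ens <- responseWeightedEnsemble(s, causalConv(s, k), lagFrames = 15)
  # the global response-weighted average is proportional to the kernel
  expect_gt(cor(ens$globalAverage, k), 0.99)
  # with no rectification the windows project onto one side of the variance
  # axis: the dominant recovered filter carries the kernel, the other is empty
  fp <- splitOnOff(ens)
  filters <- list(onFilter(fp), offFilter(fp))
  dom <- filters[[which.max(c(sum(filters[[1]]^2), sum(filters[[2]]^2)))]]
  expect_gt(abs(cor(dom, k)), 0.95)
})

test_that("an ON-only rectified cell leaves only a weak OFF filter", {
  set.seed(44)
  s <- rnorm(18000, 0, 0.2)
  k <- biphasicKernel(troughWeight = 0.4)
  fp <- recoverFilters(s, pmax(causalConv(s, k), 0), lagFrames = 15)
  expect_lt(sqrt(sum(offFilter(fp)^2)) / sqrt(sum(onFilter(fp)^2)), 0.2)
})

test_that("recovery is deterministic and demands enough windows", {
  set.seed(45)
  s <- rnorm(2000, 0, 0.2)
  resp <- pmax(causalConv(s, biphasicKernel()), 0)
  a <- recoverFilters(s, resp); b <- recoverFilters(s, resp)
  expect_identical(onFilter(a), onFilter(b))
  expect_error(splitOnOff(responseWeightedEnsemble(s[1:60], resp[1:60],
                                                   lagFrames = 15)),
               "100")
})

test_that("filter metrics report peak time, biphasic index and spectra", {
  mono <- c(0, 0, 0, 1, 0.5, 0.1, rep(0, 9))
  bi <- c(0, 0.4, 1, 0.2, -0.5, -0.3, rep(0, 9))
  fp <- new("FilterPair", onFilter = bi, offFilter = -mono, refreshHz = 30,
            globalAverage = numeric(0),
            scaleChecksum = sum(bi) + sum(-mono))
  m <- filterMetrics(fp)
  expect_equal(unname(m$peakTime_s["on"]), 2 / 30)
  expect_equal(unname(m$peakTime_s["off"]), 0.1)
  expect_equal(unname(m$biphasicIndex["on"]), 0.5)    # |trough| / peak
  expect_equal(unname(m$biphasicIndex["off"]), 0)     # monophasic
  # frequency tuning equals the closed-form DFT amplitude
  n <- length(bi)
  k <- 3
  oracle <- 2 * Mod(sum(bi * exp(-2i * pi * k * (0:(n - 1)) / n))) / n
  expect_equal(m$frequencyTuning$onAmplitude[k + 1], oracle, tolerance = 1e-9)
  zero <- new("FilterPair", onFilter = rep(0, 5), offFilter = rep(0, 5),
              refreshHz = 30, globalAverage = numeric(0), scaleChecksum = 0)
  expect_error(filterMetrics(zero), "zero filter")
})

test_that("filters recovered from simulated conductances match the circuit kernels", {
  p <- circuitParams()
  cors <- vapply(1:3, function(sd) {
    cl <- makeWhiteNoise(duration_s = 600, seed = sd)
    sim <- simulateVG3(cl, p)
    fp <- recoverFilters(cl, sim$gExc)
    c(cor(onFilter(fp), p@kernelOn), cor(offFilter(fp), -p@kernelOff))
  }, numeric(2))
  expect_gte(median(cors[1, ]), 0.9)
  expect_gte(median(cors[2, ]), 0.9)
})
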
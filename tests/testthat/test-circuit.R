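test_that("zero-contrast input silences the subunit layer and the cell rests", {
  cl <- uniformClip(rep(0, 60))
  p <- quietParams()
  sub <- bipolarLayer(cl, p)
  expect_equal(max(abs(sub$on)), 0)
  expect_equal(max(abs(sub$off)), 0)
  sim <- simulateVG3(cl, p)
  expect_equal(mean(traceSamples(sim$voltage)), p@restingMv, tolerance = 1e-6)
  expect_equal(max(abs(traceSamples(sim$epsc))), 0, tolerance = 1e-9)
})

test_that("summed rectified ON+OFF output of a full-field tone is |sin|-like", {
  fr <- 30
  tt <- (seq_len(8 * fr) - 0.5) / fr
  cl <- uniformClip(0.4 * sin(2 * pi * 2 * tt), frameRate = fr)
  delta <- c(1, 0, 0, 0, 0)
  p <- quietParams(kernelOn = delta, kernelOff = delta, gainOffOverOn = 1)
  sub <- bipolarLayer(cl, p)
  total <- colSums(sub$on) + colSums(sub$off)
  h <- harmonicAmplitudes(total, 2, rate = fr)
  nsub <- nrow(sub$on)
  # Fourier series of |A sin|: F1 = 0, F2 = A * 4 / (3 pi)
  expect_lt(h$f1Amplitude / (nsub * 0.4), 0.02)
  # 30-Hz sampling aliases distant harmonics of |sin| onto the F2 bin
  expect_equal(h$f2Amplitude / nsub, 0.4 * 4 / (3 * pi), tolerance = 0.02)
  # with rectification disabled the pathways are linear in the input
  plin <- quietParams(kernelOn = delta, kernelOff = delta, gainOffOverOn = 1,
                      rectifySubunits = FALSE)
  sublin <- bipolarLayer(cl, plin)
  hlin <- harmonicAmplitudes(colSums(sublin$on) + colSums(sublin$off), 2,
                             rate = fr)
  expect_lt(hlin$f2Amplitude, 1e-9)
})

test_that("even split-field drive is frequency-doubled on the summed ON lattice", {
  cl <- makeSplitField(0.5, fieldSize = 480, pixelPitch = 8)
  sub <- bipolarLayer(cl, quietParams())
  ev <- events(cl)
  idx <- omsretina:::.windowIdx(ev$start_s, ev$end_s, frameRate(cl),
                                ncol(sub$on))
  h <- harmonicAmplitudes(colSums(sub$on)[idx], 2, rate = frameRate(cl))
  expect_gt(h$f2Amplitude / max(h$f1Amplitude, 1e-12), 5)
})

test_that("the wide-field population is silenced by TTX and by weak input", {
  cl <- makeCounterphaseAnnulus(barWidth = 50, innerR = 160, outerR = 230,
                                fieldSize = 480, pixelPitch = 8)
  p <- quietParams()
  sub <- bipolarLayer(cl, p)
  drive <- wideFieldAC(sub, p)
  expect_gt(max(drive), 0)
  # frequency-doubled inhibitory drive from rectified subunits
  ev <- events(cl)
  idx <- omsretina:::.windowIdx(ev$start_s, ev$end_s, frameRate(cl),
                                length(drive))
  h <- harmonicAmplitudes(drive[idx], 2, rate = frameRate(cl))
  expect_gt(h$f2Amplitude, h$f1Amplitude)
  pTtx <- quietParams(ttx = TRUE)
  expect_equal(max(abs(wideFieldAC(sub, pTtx))), 0)
  weak <- makeCounterphaseAnnulus(barWidth = 50, innerR = 160, outerR = 230,
                                  contrast = 0.01, fieldSize = 480,
                                  pixelPitch = 8)
  expect_equal(max(wideFieldAC(bipolarLayer(weak, p), p)), 0)
})

test_that("conductances stay non-negative and voltage stays between reversals", {
  cl <- textureClips()$global
  p <- circuitParams(seed = 3)
  sim <- simulateVG3(cl, p)
  expect_gte(min(traceSamples(sim$gExc)), 0)
  expect_gte(min(traceSamples(sim$gInh)), 0)
  v <- traceSamples(sim$voltage)
  expect_gte(min(v), p@inhReversalMv)
  expect_lte(max(v), p@excReversalMv)
})

test_that("simulations replay bit-identically from the seed", {
  cl <- uniformClip(c(rep(0, 15), rep(0.3, 15), rep(0, 15)))
  p <- circuitParams(seed = 11)
  a <- simulateVG3(cl, p); b <- simulateVG3(cl, p)
  expect_identical(traceSamples(a$voltage), traceSamples(b$voltage))
  w1 <- simulateW3(cl, p); w2 <- simulateW3(cl, p)
  expect_identical(traceSamples(w1$spikes), traceSamples(w2$spikes))
  expect_identical(traceSamples(w1$epsc), traceSamples(w2$epsc))
})

test_that("W3 spike trains respect the refractory period and stay quiet at rest", {
  cl <- uniformClip(rep(c(0.4, -0.4), each = 8, times = 6))
  p <- circuitParams(seed = 2)
  w <- simulateW3(cl, p)
  st <- traceSamples(w$spikes)
  if (length(st) > 1) expect_gt(min(diff(st)), p@refractoryMs / 1000)
  quiet <- simulateW3(uniformClip(rep(0, 90)), p)
  expect_lt(length(traceSamples(quiet$spikes)) / 3, 5)  # low spontaneous floor
})

test_that("clips must be long enough and finely sampled for the subunit layer", {
  short <- uniformClip(rep(0.2, 5))
  expect_error(bipolarLayer(short, quietParams()), "shorter than")
  coarse <- makeSplitField(0.5, fieldSize = 320, pixelPitch = 16)
  expect_error(bipolarLayer(coarse, quietParams()), "finer")
})

test_that("knockout forces the VG3 arm of W3 excitation to zero", {
  p <- circuitParams(vglut3Ko = TRUE)
  expect_equal(p@w3Vg3Weight, 0)
  expect_error(validObject({
    q <- circuitParams(); q@vglut3Ko <- TRUE; q
  }), "w3Vg3Weight")
})

test_that("the effective kernel is a smoothed, delay-preserving image of the kernel", {
  p <- circuitParams()
  eff <- effectiveKernel(p, "on")
  expect_length(eff, length(p@kernelOn))
  expect_gt(cor(eff, p@kernelOn), 0.9)
})
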
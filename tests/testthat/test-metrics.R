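mkTrace <- function(samples, rate = 1000, baseline = c(0, 0.5),
                    modality = "voltage_mV") {
  epochedTrace(samples, rate = rate, modality = modality,
               baselineWindow = baseline)
}

test_that("epoch amplitude is the baseline-subtracted window mean", {
  tr <- mkTrace(rep(3, 2000))
  expect_equal(epochAmplitude(tr, c(1, 1.5)), 0)
  step <- mkTrace(c(rep(2, 1000), rep(12, 1000)))
  expect_equal(epochAmplitude(step, c(1, 1.5)), 10)
  expect_error(epochAmplitude(step, c(1.5, 3)), "outside")
})

test_that("epoch amplitude matches the analytic mean of an alpha transient", {
  tau <- 0.05
  rate <- 1e4
  t <- (seq_len(2 * rate) - 0.5) / rate
  alpha <- ifelse(t > 1, (t - 1) / tau * exp(-(t - 1) / tau), 0)
  tr <- mkTrace(alpha, rate = rate)
  w <- c(1.05, 1.2)
  # oracle: closed-form antiderivative of (s/tau) exp(-s/tau)
  F <- function(s) -exp(-s / tau) * (s + tau)
  oracle <- (F(w[2] - 1) - F(w[1] - 1)) / diff(w)
  expect_equal(epochAmplitude(tr, w), oracle, tolerance = 1e-3)
})

test_that("epoch amplitude is linear in the trace", {
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(3000); y <- rnorm(3000)
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    tx <- mkTrace(x); ty <- mkTrace(y); tz <- mkTrace(a * x + b * y)
    w <- c(1, 1.2)
    expect_equal(epochAmplitude(tz, w),
                 a * epochAmplitude(tx, w) + b * epochAmplitude(ty, w),
                 tolerance = 1e-12)
  }
})

test_that("conductance extraction follows Ohm's law and inverts exactly", {
  tr <- mkTrace(rep(-600, 100), rate = 100, baseline = c(0, 0.1),
                modality = "current_pA")
  g <- currentToConductance(tr, holdingMv = -60, reversalMv = 0)
  expect_equal(traceSamples(g), rep(10, 100))
  expect_identical(modality(g), "conductance_nS")
  tr2 <- mkTrace(rep(300, 100), rate = 100, baseline = c(0, 0.1),
                 modality = "current_pA")
  expect_equal(traceSamples(currentToConductance(tr2, 0, -60)), rep(5, 100))
  zero <- mkTrace(rep(0, 10), rate = 100, baseline = c(0, 0.05),
                  modality = "current_pA")
  expect_equal(traceSamples(currentToConductance(zero, -60, 0)), rep(0, 10))
  # round trip (exact up to one floating divide/multiply)
  set.seed(2)
  noisy <- mkTrace(rnorm(500), rate = 100, baseline = c(0, 1),
                   modality = "current_pA")
  back <- conductanceToCurrent(currentToConductance(noisy, -60, 0), -60, 0)
  expect_equal(traceSamples(back), traceSamples(noisy), tolerance = 1e-15)
  bitExact <- conductanceToCurrent(currentToConductance(noisy, -64, 0),
                                   -64, 0)       # power-of-two divisor
  expect_identical(traceSamples(bitExact), traceSamples(noisy))
  expect_error(currentToConductance(noisy, -60, -60), "differ")
})

test_that("harmonic amplitudes match rectified-sinusoid closed forms", {
  rate <- 1e4
  t <- (seq_len(2 * rate) - 1) / rate
  tone <- 3.2 * sin(2 * pi * 2 * t)
  h <- harmonicAmplitudes(tone, 2, rate = rate)
  expect_equal(h$f1Amplitude, 3.2, tolerance = 1e-9)
  expect_lt(h$f2Amplitude, 1e-9)
  expect_equal(h$f2Hz, 4)

  half <- pmax(sin(2 * pi * 2 * t), 0)
  hh <- harmonicAmplitudes(half, 2, rate = rate)
  expect_equal(hh$f1Amplitude, 0.5, tolerance = 1e-6)
  expect_equal(hh$f2Amplitude, 2 / (3 * pi), tolerance = 1e-6)

  full <- abs(sin(2 * pi * 2 * t))   # sum of two anti-phase half-wave tones
  hf <- harmonicAmplitudes(full, 2, rate = rate)
  expect_lt(hf$f1Amplitude, 1e-6)
  expect_equal(hf$f2Amplitude, 4 / (3 * pi), tolerance = 1e-6)
})

test_that("harmonic amplitudes agree with a regression oracle on tone mixtures", {
  rate <- 500
  t <- (seq_len(1000) - 1) / rate
  set.seed(4)
  for (i in 1:5) {
    a <- runif(2, 0.2, 2); ph <- runif(2, 0, 2 * pi)
    y <- a[1] * sin(2 * pi * 2 * t + ph[1]) + a[2] * sin(2 * pi * 4 * t + ph[2])
    h <- harmonicAmplitudes(y, 2, rate = rate)
    # independent oracle: least-squares projection on sine/cosine pairs
    oracle <- function(f) {
      fit <- lm(y ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
      sqrt(sum(coef(fit)[2:3]^2))
    }
    expect_equal(h$f1Amplitude, oracle(2), tolerance = 1e-9)
    expect_equal(h$f2Amplitude, oracle(4), tolerance = 1e-9)
  }
})

test_that("harmonic analysis truncates to whole periods and needs one period", {
  rate <- 100
  t <- (seq_len(130) - 1) / rate
  y <- sin(2 * pi * 2 * t)
  h <- harmonicAmplitudes(y, 2, rate = rate)
  expect_equal(h$truncated_s, 0.3, tolerance = 1e-9)
  expect_equal(h$f1Amplitude, 1, tolerance = 1e-6)
  expect_error(harmonicAmplitudes(y[1:40], 2, rate = rate), "period")
})

test_that("DSI matches closed forms and its invariances", {
  expect_equal(dsi(rep(1, 8)), 0, tolerance = 1e-12)
  expect_equal(dsi(c(1, rep(0, 7))), 1)
  expect_equal(dsi(c(2, rep(1, 7))), 1 / 9, tolerance = 1e-12)
  set.seed(5)
  f1 <- runif(8)
  expect_equal(dsi(f1), dsi(10 * f1), tolerance = 1e-12)
  rot <- c(f1[-1], f1[1])                       # rotate direction labels
  expect_equal(dsi(f1), dsi(rot), tolerance = 1e-12)
  expect_error(dsi(rep(0, 8)), "undefined")
  expect_error(dsi(c(-1, rep(1, 7))), "non-negative")
})

test_that("motion selectivity reports one signed amplitude per segment", {
  mk <- function(label, wave) {
    epochedTrace(wave, rate = 1000, modality = "voltage_mV",
                 baselineWindow = c(0.5, 1),
                 events = data.frame(label = label, start_s = 1, end_s = 2))
  }
  flat <- rep(-38, 3000)
  trs <- list(global = mk("global", flat),
              diff_center = mk("diff_center", flat),
              diff_surround = mk("diff_surround", flat))
  m <- motionSelectivity(trs)
  expect_equal(m$amplitude, c(0, 0, 0))
  # signed: a hyperpolarizing segment comes out negative
  dip <- flat; dip[1200:1600] <- -50
  trs$global <- mk("global", dip)
  expect_lt(motionSelectivity(trs)$amplitude[1], -10)
  expect_error(motionSelectivity(trs[1:2]), "missing segment")
})

test_that("speed and size tuning tabulate edge amplitudes per condition", {
  mkBar <- function(tLead, tTrail, aLead, aTrail) {
    x <- rep(0, 6000)
    x[(tLead * 1000):(tLead * 1000 + 200)] <- aLead
    x[(tTrail * 1000):(tTrail * 1000 + 200)] <- aTrail
    epochedTrace(x, rate = 1000, modality = "voltage_mV",
                 baselineWindow = c(0, 0.4),
                 events = data.frame(label = c("leading_edge", "trailing_edge"),
                                     start_s = c(tLead, tTrail),
                                     end_s = c(tLead, tTrail)))
  }
  sp <- speedTuning(list(mkBar(1, 3, 6, 4), mkBar(1, 2, 5, 3)),
                    speeds = c(400, 800))
  expect_equal(sp$amplitude[sp$speed == 400 & sp$edge == "leading"], 6,
               tolerance = 0.05)
  expect_equal(sp$amplitude[sp$speed == 800 & sp$edge == "trailing"], 3,
               tolerance = 0.05)
  st <- sizeTuning(list(mkBar(1, 3, 10, 4), mkBar(1, 3, 5, 4)),
                   heights = c(200, 600))
  expect_equal(st$suppressionIndex, 0.5, tolerance = 0.02)
  expect_error(sizeTuning(list(mkBar(1, 3, 1, 1)), heights = c(1, 2)),
               "one trace per height")
})

test_that("segment amplitude works on spike-time traces", {
  st <- epochedTrace(seq(1.0, 1.5, by = 0.01), rate = 1000,
                     modality = "spike_times_s", baselineWindow = c(0, 0.9),
                     duration_s = 3,
                     events = data.frame(label = "m", start_s = 1, end_s = 2))
  a <- segmentAmplitude(st, 1, 2, windowLength = 0.2)
  expect_gt(a, 50)   # ~100 Hz burst against a silent baseline
})
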
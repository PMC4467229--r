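test_that("spot series alternates disc intensity at the stated contrast", {
  clips <- makeSpotSeries(radii = 100, contrast = 0.96, nPeriods = 1,
                          fieldSize = 480, pixelPitch = 8)
  expect_length(clips, 2)            # single radius + stability repeat
  cl <- clips[[1]]
  ev <- events(cl)
  onIdx <- round((ev$start_s[ev$label == "on"][1] + 0.5) * frameRate(cl))
  offIdx <- round((ev$start_s[ev$label == "off"][1] + 0.5) * frameRate(cl))
  ctr <- dim(frames(cl))[2] / 2
  expect_equal(frames(cl)[onIdx, ctr, ctr], 0.5 * (1 + 0.96))
  expect_equal(frames(cl)[offIdx, ctr, ctr], 0.5 * (1 - 0.96))
  # pixels outside the disc stay at mean intensity
  expect_equal(frames(cl)[onIdx, 1, 1], 0.5)
})

test_that("spot presentation order replays from the seed, first re-appended", {
  a <- makeSpotSeries(c(50, 100, 150), orderSeed = 7, nPeriods = 1,
                      fieldSize = 480, pixelPitch = 8)
  b <- makeSpotSeries(c(50, 100, 150), orderSeed = 7, nPeriods = 1,
                      fieldSize = 480, pixelPitch = 8)
  radA <- vapply(a, function(x) x@params$radius, numeric(1))
  radB <- vapply(b, function(x) x@params$radius, numeric(1))
  expect_identical(radA, radB)
  expect_length(a, 4)
  expect_identical(radA[4], radA[1])
})

test_that("spot series rejects radii beyond the field and zero contrast is static", {
  expect_error(makeSpotSeries(500, fieldSize = 480), "field of view")
  cl <- makeSpotSeries(100, contrast = 0, nPeriods = 1, fieldSize = 480,
                       pixelPitch = 8)[[1]]
  expect_equal(max(frames(cl)) - min(frames(cl)), 0)
})

test_that("even split field is luminance neutral, biased split modulates as 2b-1", {
  even <- makeSplitField(0.5, fieldSize = 480, pixelPitch = 8)
  fm <- apply(frames(even), 1, mean)
  expect_lt(max(abs(fm - 0.5)), 0.005)   # within 1% of mean intensity

  ampOf <- function(b) {
    cl <- makeSplitField(b, fieldSize = 480, pixelPitch = 8)
    ev <- events(cl)
    idx <- omsretina:::.windowIdx(ev$start_s, ev$end_s, frameRate(cl),
                                  nFrames(cl))
    harmonicAmplitudes(apply(frames(cl)[idx, , ], 1, mean), 2,
                       rate = frameRate(cl))$f1Amplitude
  }
  expect_equal(ampOf(0.75) / ampOf(0.625), (2 * 0.75 - 1) / (2 * 0.625 - 1),
               tolerance = 0.05)
  expect_error(makeSplitField(1.2), "biasFraction")
})

test_that("split-field pixel time courses are pure 2 Hz tones", {
  cl <- makeSplitField(0.5, temporalFrequency = 2, fieldSize = 480,
                       pixelPitch = 8)
  ev <- events(cl)
  idx <- omsretina:::.windowIdx(ev$start_s, ev$end_s, frameRate(cl),
                                nFrames(cl))
  ctr <- dim(frames(cl))[2] / 2
  px <- frames(cl)[idx, ctr, ctr - 5]
  h <- harmonicAmplitudes(px, 2, rate = frameRate(cl))
  expect_gt(h$f1Amplitude, 0.4)
  expect_lt(h$f2Amplitude / h$f1Amplitude, 1e-6)
})

test_that("counterphase annulus cancels in the mean; a single bar does not", {
  for (bw in c(25, 50)) {
    cl <- makeCounterphaseAnnulus(barWidth = bw, innerR = 100, outerR = 200,
                                  fieldSize = 480, pixelPitch = 4)
    fm <- apply(frames(cl), 1, mean)
    expect_lt(max(abs(fm - 0.5)), 0.005)
  }
  one <- makeCounterphaseAnnulus(barWidth = 400, innerR = 100, outerR = 200,
                                 fieldSize = 480, pixelPitch = 4)
  ev <- events(one)
  idx <- omsretina:::.windowIdx(ev$start_s, ev$end_s, frameRate(one),
                                nFrames(one))
  h <- harmonicAmplitudes(apply(frames(one)[idx, , ], 1, mean), 2, rate = 30)
  expect_gt(h$f1Amplitude, 0.01)
  expect_error(makeCounterphaseAnnulus(barWidth = -5), "positive")
})

test_that("texture motion is luminance neutral and moves only the stated region", {
  for (seg in c("global", "diff_center", "diff_surround")) {
    cl <- makeTextureMotion(segment = seg, fieldSize = 600, pixelPitch = 8)
    fm <- apply(frames(cl), 1, mean)
    expect_lt(max(abs(fm - 0.5)) / 0.5, 0.01)
    expect_identical(events(cl)$label, seg)
  }
  cc <- makeTextureMotion(segment = "diff_center", fieldSize = 600,
                          pixelPitch = 8)
  n <- dim(frames(cc))[2]
  surroundPx <- frames(cc)[, 2, 2]     # corner pixel, surround grating
  expect_equal(max(surroundPx) - min(surroundPx), 0)  # never moves
  expect_error(makeTextureMotion(segment = "sideways"))
})

test_that("moving-bar edge events follow the kinematics", {
  cl <- makeMovingBar(height = 200, width = 800, speed = 400,
                      fieldSize = 480, pixelPitch = 8)
  ev <- events(cl)
  lead <- ev$start_s[ev$label == "leading_edge"]
  trail <- ev$start_s[ev$label == "trailing_edge"]
  expect_equal(trail - lead, 800 / 400)
  cl2 <- makeMovingBar(height = 200, width = 800, speed = 800,
                       fieldSize = 480, pixelPitch = 8)
  ev2 <- events(cl2)
  expect_equal(ev2$start_s[ev2$label == "trailing_edge"] -
                 ev2$start_s[ev2$label == "leading_edge"],
               (trail - lead) / 2)
  # dark polarity: bar pixels at mean * (1 - c)
  k <- round((0.5 + lead) * frameRate(cl) / 2) + nFrames(cl) %/% 3
  expect_equal(min(frames(cl)), 0.5 * (1 - 0.96))
  expect_error(makeMovingBar(speed = 0), "speed")
})

test_that("drifting gratings give one clip per direction, neutral over periods", {
  clips <- lapply(seq(0, 315, by = 45), makeDriftingGrating,
                  fieldSize = 400, pixelPitch = 8, duration_s = 2)
  expect_length(clips, 8)
  cl <- clips[[2]]
  ev <- events(cl)
  idx <- omsretina:::.windowIdx(ev$start_s, ev$end_s, frameRate(cl),
                                nFrames(cl))
  expect_lt(max(abs(apply(frames(cl)[idx, , ], 1, mean) - 0.5)), 0.01)
  ctr <- dim(frames(cl))[2] / 2
  h <- harmonicAmplitudes(frames(cl)[idx, ctr, ctr], 2, rate = frameRate(cl))
  expect_gt(h$f1Amplitude, 0.3)
})

test_that("white noise honors count, RMS contrast, clipping log and the seed", {
  cl <- makeWhiteNoise(duration_s = 60, seed = 3)
  vals <- cl@params$values
  expect_length(vals, 60 * 30)
  expect_equal(sd(vals) / 0.5, 0.4, tolerance = 0.05)
  expect_true(cl@params$clipFraction >= 0 && cl@params$clipFraction < 0.05)
  cl2 <- makeWhiteNoise(duration_s = 60, seed = 3)
  expect_identical(vals, cl2@params$values)
  expect_identical(frames(cl), frames(cl2))
  flat <- makeWhiteNoise(duration_s = 2, rmsContrast = 0, seed = 1)
  expect_equal(max(frames(flat)) - min(frames(flat)), 0)
  expect_error(makeWhiteNoise(rmsContrast = 1.2), "rmsContrast")
})

test_that("clips round-trip through the on-disk format bit-exactly", {
  cl <- makeSplitField(0.6, fieldSize = 320, pixelPitch = 8)
  f <- tempfile(fileext = ".rds")
  writeClip(cl, f)
  expect_true(identical(readClip(f), cl))
  ef <- tempfile(fileext = ".csv")
  writeEventsCsv(cl, ef)
  ev <- readEventsCsv(ef)
  expect_equal(ev$start_s, events(cl)$start_s)
  unlink(c(f, ef))
})

test_that("event tables are sorted and validated", {
  expect_error(new("StimulusClip",
                   frames = array(0.5, c(2, 4, 4)), frameRate = 30,
                   pixelPitch = 8, meanIntensity = 0.5,
                   events = data.frame(label = c("a", "a"),
                                       start_s = c(0, 0.01),
                                       end_s = c(0.05, 0.06)),
                   stimClass = "x", params = list()),
               "overlap")
  expect_error(new("StimulusClip",
                   frames = array(2, c(2, 4, 4)), frameRate = 30,
                   pixelPitch = 8, meanIntensity = 0.5,
                   events = data.frame(label = character(),
                                       start_s = numeric(),
                                       end_s = numeric()),
                   stimClass = "x", params = list()),
               "0, 1")
})
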
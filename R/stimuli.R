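## Stimulus engine: every stimulus class as a discretized space-time intensity
## array plus a machine-readable event table.  Conventions: intensity is
## unitless in [0, 1] with mean 0.5; space is in micrometres with the origin at
## the field center (= soma of the recorded cell); frames are (t, y, x).

#' Default stimulus geometry
#'
#' Field of view, pixel pitch and frame rate shared by the stimulus
#' generators.  The field comfortably covers the wide-field inhibitory
#' surround of VG3 amacrine cells (1-SD inhibition diameter 258 um) while
#' the pitch stays well below the bipolar-subunit sigma (12.5 um), so the
#' subunit lattice of the circuit simulator is finely sampled.
#'
#' @return named list with `fieldSize` (um), `pixelPitch` (um/px) and
#'   `frameRate` (Hz).
#' @export
stimulusDefaults <- function() {
  list(fieldSize = 800, pixelPitch = 4, frameRate = 30)
}

## Expand a per-frame modulation of one spatial profile into a clip array:
## frames[t, , ] = mean + modulation[t] * profile  (profile in contrast units).
.profileClip <- function(modulation, profile, mean_int) {
  nt <- length(modulation)
  m <- outer(modulation, as.vector(profile))
  dim(m) <- c(nt, dim(profile))
  m + mean_int
}

#' Area-response spot series
#'
#' One clip per spot radius: the luminance of a disc centered on the cell is
#' square-wave modulated (default 2 s ON, 2 s OFF at 96% Michelson contrast).
#' Clips are returned in a pseudorandom presentation order derived from
#' `orderSeed`, with the first stimulus of the sequence repeated at its end as
#' a recording-stability check.  Event tables mark every ON and OFF epoch.
#'
#' @param radii spot radii, micrometres (positive, unique).
#' @param period_s full ON+OFF period (default 4 s: 2 s ON, 2 s OFF).
#' @param contrast Michelson contrast in \[0, 1\].
#' @param orderSeed integer seed for the presentation order.
#' @param nPeriods modulation periods per clip.
#' @param leadIn_s gray adaptation time before the first transition.
#' @param fieldSize,pixelPitch,frameRate stimulus geometry
#'   (see [stimulusDefaults()]).
#' @param meanIntensity background intensity.
#' @return list of [StimulusClip-class], one per presentation (first radius
#'   re-appended); each clip's `params$radius` holds its radius.
#' @export
makeSpotSeries <- function(radii, period_s = 4, contrast = 0.96,
                           orderSeed = 1L, nPeriods = 2, leadIn_s = 1,
                           fieldSize = stimulusDefaults()$fieldSize,
                           pixelPitch = stimulusDefaults()$pixelPitch,
                           frameRate = stimulusDefaults()$frameRate,
                           meanIntensity = 0.5) {
  .assert(all(radii > 0), "radii must be positive")
  .assert(!anyDuplicated(radii), "radii must be unique")
  .assert(contrast >= 0 && contrast <= 1, "contrast must lie in [0, 1]")
  .assert(all(radii <= fieldSize / 2),
          "radius %g um exceeds the field of view (half-size %g um)",
          max(radii), fieldSize / 2)

  g <- .pixelGrid(fieldSize, pixelPitch)
  r2 <- outer(g$y^2, g$x^2, "+")

  halfFrames <- round(period_s / 2 * frameRate)
  leadFrames <- round(leadIn_s * frameRate)
  oneClip <- function(radius) {
    disc <- (r2 <= radius^2) * contrast * meanIntensity
    mod <- c(rep(0, leadFrames),
             rep(rep(c(1, -1), nPeriods), each = halfFrames))
    tr <- leadIn_s + (seq_len(2 * nPeriods) - 1) * period_s / 2
    ev <- data.frame(label = rep(c("on", "off"), nPeriods),
                     start_s = tr, end_s = tr + period_s / 2)
    .newClip(.profileClip(mod, disc, meanIntensity), frameRate, pixelPitch,
             meanIntensity, ev, "spot",
             params = list(radius = radius, contrast = contrast,
                           period_s = period_s))
  }
  clips <- lapply(radii, oneClip)
  ord <- .withSeed(orderSeed, function() sample(seq_along(radii)))
  clips <- clips[ord]
  c(clips, clips[1])
}

#' Split-field stimulus
#'
#' The receptive-field center disc is divided by a vertical line into two
#' regions whose intensities are modulated by anti-phase sinusoids.
#' `biasFraction` is the area fraction of the left region: 0.5 gives the
#' luminance-neutral even split, values away from 0.5 give a biased split
#' whose frame-mean luminance is modulated at the stimulus frequency with
#' amplitude proportional to `2 * biasFraction - 1`.
#'
#' @param biasFraction area fraction of the left region, in (0, 1).
#' @param temporalFrequency modulation frequency, Hz.
#' @param diameter disc diameter, micrometres.
#' @param contrast peak contrast of each region's sinusoid.
#' @param duration_s modulated epoch duration (whole periods recommended).
#' @param leadIn_s,tail_s gray epochs before/after modulation.
#' @inheritParams makeSpotSeries
#' @return a [StimulusClip-class] with a `modulation` event.
#' @export
makeSplitField <- function(biasFraction = 0.5, temporalFrequency = 2,
                           diameter = 300, contrast = 0.96, duration_s = 4,
                           leadIn_s = 1, tail_s = 0.5,
                           fieldSize = stimulusDefaults()$fieldSize,
                           pixelPitch = stimulusDefaults()$pixelPitch,
                           frameRate = stimulusDefaults()$frameRate,
                           meanIntensity = 0.5) {
  .assert(biasFraction > 0 && biasFraction < 1,
          "biasFraction must lie strictly inside (0, 1)")
  R <- diameter / 2
  .assert(diameter <= fieldSize, "diameter exceeds the field of view")

  ## split line x0 such that the disc area left of it is biasFraction:
  ## A(x0)/A = (asin(u) + u sqrt(1-u^2))/pi + 1/2, u = x0/R
  afrac <- function(u) (asin(u) + u * sqrt(1 - u^2)) / pi + 0.5
  x0 <- if (abs(biasFraction - 0.5) < 1e-12) 0 else
    R * stats::uniroot(function(u) afrac(u) - biasFraction,
                       c(-1, 1), tol = 1e-12)$root

  g <- .pixelGrid(fieldSize, pixelPitch)
  r2 <- outer(g$y^2, g$x^2, "+")
  inDisc <- r2 <= R^2
  left <- outer(rep(TRUE, g$n), g$x <= x0)
  profile <- (inDisc & left) - (inDisc & !left)  # +1 left, -1 right

  leadFrames <- round(leadIn_s * frameRate)
  modFrames <- round(duration_s * frameRate)
  tailFrames <- round(tail_s * frameRate)
  tmod <- (seq_len(modFrames) - 0.5) / frameRate
  mod <- c(rep(0, leadFrames),
           contrast * meanIntensity * sin(2 * pi * temporalFrequency * tmod),
           rep(0, tailFrames))
  ev <- data.frame(label = "modulation", start_s = leadIn_s,
                   end_s = leadIn_s + duration_s)
  .newClip(.profileClip(mod, profile, meanIntensity), frameRate, pixelPitch,
           meanIntensity, ev, "split_field",
           params = list(biasFraction = biasFraction,
                         temporalFrequency = temporalFrequency,
                         diameter = diameter, contrast = contrast))
}

#' Counterphase annulus gratings
#'
#' The receptive-field surround (an annulus) is divided into vertical bars of
#' a given width; adjacent bars are modulated by anti-phase sinusoids.  Bar
#' boundaries are placed symmetrically about the vertical midline so that the
#' annulus-mean intensity is constant over time.
#'
#' @param barWidth bar width, micrometres (must not exceed the annulus width).
#' @param innerR,outerR annulus radii, micrometres.
#' @param temporalFrequency modulation frequency, Hz.
#' @inheritParams makeSplitField
#' @return a [StimulusClip-class] with a `modulation` event.
#' @export
makeCounterphaseAnnulus <- function(barWidth = 25, innerR = 150, outerR = 350,
                                    temporalFrequency = 2, contrast = 0.96,
                                    duration_s = 4, leadIn_s = 1, tail_s = 0.5,
                                    fieldSize = stimulusDefaults()$fieldSize,
                                    pixelPitch = stimulusDefaults()$pixelPitch,
                                    frameRate = stimulusDefaults()$frameRate,
                                    meanIntensity = 0.5) {
  .assert(barWidth > 0, "bar width must be positive")
  .assert(outerR > innerR, "outerR must exceed innerR")
  .assert(barWidth <= 2 * outerR, "bar width must fit the annulus")
  .assert(outerR <= fieldSize / 2, "annulus exceeds the field of view")

  g <- .pixelGrid(fieldSize, pixelPitch)
  r2 <- outer(g$y^2, g$x^2, "+")
  inAnn <- r2 >= innerR^2 & r2 <= outerR^2
  if (barWidth >= 2 * outerR) {
    barSign <- rep(1, g$n)       # one bar covers the annulus: no partner
  } else {
    ## boundary at x = 0 makes mirror bars anti-phase with equal areas, so
    ## the annulus mean cancels exactly; pixel columns exactly on a bar
    ## boundary are left unmodulated to preserve that symmetry
    barSign <- 1 - 2 * (floor(g$x / barWidth) %% 2)
    barSign[g$x %% barWidth == 0] <- 0
  }
  profile <- inAnn * outer(rep(1, g$n), barSign)

  leadFrames <- round(leadIn_s * frameRate)
  modFrames <- round(duration_s * frameRate)
  tailFrames <- round(tail_s * frameRate)
  tmod <- (seq_len(modFrames) - 0.5) / frameRate
  mod <- c(rep(0, leadFrames),
           contrast * meanIntensity * sin(2 * pi * temporalFrequency * tmod),
           rep(0, tailFrames))
  ev <- data.frame(label = "modulation", start_s = leadIn_s,
                   end_s = leadIn_s + duration_s)
  .newClip(.profileClip(mod, profile, meanIntensity), frameRate, pixelPitch,
           meanIntensity, ev, "counterphase_annulus",
           params = list(barWidth = barWidth, innerR = innerR,
                         outerR = outerR,
                         temporalFrequency = temporalFrequency))
}

#' Differential texture-motion stimulus
#'
#' Two square-wave gratings, one over the receptive-field center disc and one
#' over the surround, separated by a static gray annulus.  In the `global`
#' segment both gratings drift together; in `diff_center` only the center
#' grating moves; in `diff_surround` only the surround grating moves.  The
#' gratings are luminance-neutral: the frame-mean intensity stays within 1% of
#' the background.
#'
#' @param segment one of `"global"`, `"diff_center"`, `"diff_surround"`.
#' @param barWidth grating bar width, micrometres (50-75 in the standard
#'   battery).
#' @param gap width of the gray annulus between center and surround, um.
#' @param speed drift speed, micrometres per second.
#' @param centerRadius radius of the center grating disc, um.
#' @param motion_s duration of the motion segment.
#' @inheritParams makeSplitField
#' @return a [StimulusClip-class]; the motion epoch is labeled with `segment`.
#' @export
makeTextureMotion <- function(segment = c("global", "diff_center",
                                          "diff_surround"),
                              barWidth = 50, gap = 25, speed = 300,
                              centerRadius = 150, contrast = 0.9,
                              motion_s = 2, leadIn_s = 1, tail_s = 1,
                              fieldSize = stimulusDefaults()$fieldSize,
                              pixelPitch = stimulusDefaults()$pixelPitch,
                              frameRate = stimulusDefaults()$frameRate,
                              meanIntensity = 0.5) {
  segment <- match.arg(segment)
  .assert(barWidth > 0 && gap >= 0 && speed > 0, "invalid texture parameters")

  g <- .pixelGrid(fieldSize, pixelPitch)
  r2 <- outer(g$y^2, g$x^2, "+")
  inCenter <- r2 <= centerRadius^2
  inSurround <- r2 >= (centerRadius + gap)^2
  period <- 2 * barWidth

  leadFrames <- round(leadIn_s * frameRate)
  motFrames <- round(motion_s * frameRate)
  tailFrames <- round(tail_s * frameRate)
  nt <- leadFrames + motFrames + tailFrames

  ## displacement time courses (um) per region
  dmot <- cumsum(rep(speed / frameRate, motFrames))
  disp <- c(rep(0, leadFrames), dmot, rep(dmot[motFrames], tailFrames))
  zero <- rep(0, nt)
  dispC <- if (segment %in% c("global", "diff_center")) disp else zero
  dispS <- if (segment %in% c("global", "diff_surround")) disp else zero

  grating <- function(shift) {
    ph <- sign(sin(2 * pi * (g$x - shift) / period))
    ph[ph == 0] <- 1
    ph
  }
  amp <- contrast * meanIntensity
  fr <- array(meanIntensity, dim = c(nt, g$n, g$n))
  ## each region's grating is balanced to zero mean over the region per
  ## frame, so the stimulus is luminance-neutral by construction (the
  ## average intensity of all stimuli is kept constant)
  for (t in seq_len(nt)) {
    f <- matrix(meanIntensity, g$n, g$n)
    gc <- outer(rep(1, g$n), grating(dispC[t]))[inCenter]
    gs <- outer(rep(1, g$n), grating(dispS[t] + barWidth / 2))[inSurround]
    f[inCenter] <- meanIntensity + amp * (gc - mean(gc))
    f[inSurround] <- meanIntensity + amp * (gs - mean(gs))
    fr[t, , ] <- f
  }
  ev <- data.frame(label = segment, start_s = leadIn_s,
                   end_s = leadIn_s + motion_s)
  .newClip(fr, frameRate, pixelPitch, meanIntensity, ev, "texture_motion",
           params = list(segment = segment, barWidth = barWidth, gap = gap,
                         speed = speed, centerRadius = centerRadius))
}

#' Moving bar
#'
#' A dark or light bar moves across the field along x at constant speed.  The
#' bar's *width* (800 um default) lies along the motion axis, so the trailing
#' edge crosses the field center `width / speed` seconds after the leading
#' edge; its *height* (50-600 um in the standard battery) is the cross-motion
#' extent that determines how much of the inhibitory surround an edge
#' recruits.  The event table contains the leading- and trailing-edge
#' center-crossing times.
#'
#' @param height bar extent perpendicular to motion, micrometres.
#' @param width bar extent along motion, micrometres.
#' @param speed micrometres per second (> 0).
#' @param polarity `"dark"` (intensity `mean * (1 - contrast)`) or `"light"`.
#' @inheritParams makeSplitField
#' @return a [StimulusClip-class] with `motion`, `leading_edge` and
#'   `trailing_edge` events.
#' @export
makeMovingBar <- function(height = 200, width = 800, speed = 400,
                          polarity = c("dark", "light"), contrast = 0.96,
                          leadIn_s = 0.5, tail_s = 0.5,
                          fieldSize = stimulusDefaults()$fieldSize,
                          pixelPitch = stimulusDefaults()$pixelPitch,
                          frameRate = stimulusDefaults()$frameRate,
                          meanIntensity = 0.5) {
  polarity <- match.arg(polarity)
  .assert(speed > 0, "speed must be positive")
  .assert(height > 0 && width > 0, "bar dimensions must be positive")

  g <- .pixelGrid(fieldSize, pixelPitch)
  inRow <- abs(g$y) <= height / 2
  sgn <- if (polarity == "dark") -1 else 1
  amp <- sgn * contrast * meanIntensity

  travel <- fieldSize + width            # leading edge start -> trailing exit
  motion_s <- travel / speed
  leadFrames <- round(leadIn_s * frameRate)
  motFrames <- ceiling(motion_s * frameRate)
  tailFrames <- round(tail_s * frameRate)
  nt <- leadFrames + motFrames + tailFrames

  fr <- array(meanIntensity, dim = c(nt, g$n, g$n))
  for (k in seq_len(motFrames)) {
    tt <- (k - 0.5) / frameRate
    xLead <- -fieldSize / 2 + speed * tt
    inCol <- g$x <= xLead & g$x > xLead - width
    if (!any(inCol)) next
    f <- matrix(meanIntensity, g$n, g$n)
    f[inRow, inCol] <- meanIntensity + amp
    fr[leadFrames + k, , ] <- f
  }
  tLead <- leadIn_s + (fieldSize / 2) / speed
  tTrail <- tLead + width / speed
  ev <- data.frame(
    label = c("motion", "leading_edge", "trailing_edge"),
    start_s = c(leadIn_s, tLead, tTrail),
    end_s = c(leadIn_s + motion_s, tLead, tTrail))
  .newClip(fr, frameRate, pixelPitch, meanIntensity, ev, "moving_bar",
           params = list(height = height, width = width, speed = speed,
                         polarity = polarity, contrast = contrast))
}

#' Drifting sine grating
#'
#' Full-field sine grating drifting in a given direction at a given temporal
#' frequency (2 Hz in the standard eight-direction battery).
#'
#' @param directionDeg drift direction, degrees (0 = rightward).
#' @param temporalFrequency Hz.
#' @param spatialPeriod grating period, micrometres.
#' @inheritParams makeSplitField
#' @return a [StimulusClip-class] with a `drift` event.
#' @export
makeDriftingGrating <- function(directionDeg = 0, temporalFrequency = 2,
                                spatialPeriod = 200, contrast = 0.96,
                                duration_s = 3, leadIn_s = 0.5, tail_s = 0.5,
                                fieldSize = stimulusDefaults()$fieldSize,
                                pixelPitch = stimulusDefaults()$pixelPitch,
                                frameRate = stimulusDefaults()$frameRate,
                                meanIntensity = 0.5) {
  g <- .pixelGrid(fieldSize, pixelPitch)
  th <- directionDeg * pi / 180
  proj <- outer(sin(th) * g$y, cos(th) * g$x, "+")  # position along direction

  leadFrames <- round(leadIn_s * frameRate)
  driftFrames <- round(duration_s * frameRate)
  tailFrames <- round(tail_s * frameRate)
  nt <- leadFrames + driftFrames + tailFrames
  amp <- contrast * meanIntensity

  fr <- array(meanIntensity, dim = c(nt, g$n, g$n))
  for (k in seq_len(driftFrames)) {
    tt <- (k - 0.5) / frameRate
    gpat <- amp * sin(2 * pi * (proj / spatialPeriod - temporalFrequency * tt))
    # balanced per frame: the field holds whole periods only along the axes
    fr[leadFrames + k, , ] <- meanIntensity + (gpat - mean(gpat))
  }
  ev <- data.frame(label = "drift", start_s = leadIn_s,
                   end_s = leadIn_s + duration_s)
  .newClip(fr, frameRate, pixelPitch, meanIntensity, ev, "drifting_grating",
           params = list(directionDeg = directionDeg,
                         temporalFrequency = temporalFrequency,
                         spatialPeriod = spatialPeriod))
}

#' Gaussian white-noise stimulus
#'
#' The intensity of a uniform circular region over the receptive-field center
#' (or an annulus over the surround) is drawn i.i.d. from a normal
#' distribution with the stated RMS contrast about the mean and updated at the
#' refresh rate (30 Hz, 10 min in the standard battery).  Values falling
#' outside \[0, 1\] are clipped; the clipped fraction is recorded in
#' `params$clipFraction`.  The full sequence is reproducible from `seed` and
#' kept in `params$values`.
#'
#' @param refreshHz update rate; must divide `frameRate`.
#' @param rmsContrast RMS contrast (SD / mean), < 1.
#' @param duration_s stimulus duration, seconds.
#' @param region `"center"` (disc) or `"surround_annulus"`.
#' @param seed integer RNG seed.
#' @param diameter disc diameter for `region = "center"`, um.
#' @param annulus `(inner, outer)` radii for the surround region, um.
#' @inheritParams makeSplitField
#' @return a [StimulusClip-class] with a `noise` event.
#' @export
makeWhiteNoise <- function(refreshHz = 30, rmsContrast = 0.4,
                           duration_s = 600,
                           region = c("center", "surround_annulus"),
                           seed = 1L, diameter = 240, annulus = c(175, 350),
                           fieldSize = NULL, pixelPitch = 8,
                           frameRate = 30, meanIntensity = 0.5) {
  region <- match.arg(region)
  .assert(rmsContrast < 1, "rmsContrast must be < 1")
  .assert(rmsContrast >= 0, "rmsContrast must be >= 0")
  .assert(abs(frameRate / refreshHz - round(frameRate / refreshHz)) < 1e-9,
          "refreshHz must divide frameRate")
  if (is.null(fieldSize))
    fieldSize <- if (region == "center") diameter + 2 * pixelPitch
                 else 2 * annulus[2] + 2 * pixelPitch

  g <- .pixelGrid(fieldSize, pixelPitch)
  r2 <- outer(g$y^2, g$x^2, "+")
  inRegion <- if (region == "center") r2 <= (diameter / 2)^2
              else r2 >= annulus[1]^2 & r2 <= annulus[2]^2

  nVals <- round(duration_s * refreshHz)
  vals <- .withSeed(seed, function()
    meanIntensity * (1 + rmsContrast * stats::rnorm(nVals)))
  clipFraction <- mean(vals < 0 | vals > 1)
  vals <- pmin(1, pmax(0, vals))

  hold <- round(frameRate / refreshHz)
  mod <- rep(vals - meanIntensity, each = hold)
  fr <- .profileClip(mod, inRegion * 1, meanIntensity)
  ev <- data.frame(label = "noise", start_s = 0, end_s = duration_s)
  .newClip(fr, frameRate, pixelPitch, meanIntensity, ev, "white_noise",
           params = list(refreshHz = refreshHz, rmsContrast = rmsContrast,
                         region = region, seed = seed, values = vals,
                         clipFraction = clipFraction))
}
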
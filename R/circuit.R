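## Rectified-subunit linear-nonlinear circuit model of the object-motion
## detection circuit: ON/OFF bipolar subunit lattices -> (i) center-pooled
## excitation of a VG3 amacrine cell with presynaptic surround inhibition,
## (ii) a spiking wide-field amacrine cell pooling the surround (silenced by
## TTX), and (iii) a W3 ganglion cell receiving delayed VG3 glutamate release
## plus a direct bipolar pool (the VG3 arm is removed by the VGluT3 knockout).

#' Biphasic temporal kernel
#'
#' Difference-of-gamma-lobe kernel sampled on the stimulus refresh grid
#' (lag 0 = simultaneous frame), peak normalized to 1.
#'
#' @param rate sampling rate of the kernel, Hz.
#' @param nTaps kernel length in frames.
#' @param tPeak,tTrough lobe peak times, seconds.
#' @param troughWeight relative amplitude of the rebound lobe (its ratio to
#'   the peak sets the biphasic index of the kernel); ignored when
#'   `balanced = TRUE`.
#' @param balanced scale the rebound lobe so the kernel integrates to zero —
#'   a fully transient kernel with no sustained response to static patterns
#'   (the default for the circuit model).
#' @return numeric kernel of length `nTaps`.
#' @export
biphasicKernel <- function(rate = 30, nTaps = 15, tPeak = 0.08,
                           tTrough = 0.16, troughWeight = 0.55,
                           balanced = FALSE) {
  t <- (seq_len(nTaps) - 1) / rate
  lobe <- function(tp, n = 4) (t / tp)^n * exp(-n * (t / tp - 1))
  l1 <- lobe(tPeak); l2 <- lobe(tTrough)
  if (balanced) troughWeight <- sum(l1) / sum(l2)
  k <- l1 - troughWeight * l2
  k / max(k)
}

#' CircuitParams: parameters of the rectified-subunit circuit model
#'
#' See [circuitParams()] for the constructor, defaults and units.
#'
#' @export
setClass("CircuitParams",
  representation(
    subunitSpacing = "numeric", subunitSigma = "numeric",
    kernelOn = "numeric", kernelOff = "numeric", kernelRate = "numeric",
    gainOffOverOn = "numeric",
    centerSigmaOn = "numeric", centerSigmaOff = "numeric",
    wacSigmaOn = "numeric", wacSigmaOff = "numeric",
    wacInnerRadius = "numeric", wacThreshold = "numeric",
    wacUnitSpacing = "numeric", wacPoolSigma = "numeric",
    presynWeight = "numeric", postsynWeight = "numeric",
    excGain = "numeric", inhGain = "numeric",
    restingMv = "numeric", tauMembraneMs = "numeric",
    excReversalMv = "numeric", inhReversalMv = "numeric",
    leakConductance = "numeric",
    vg3ReleaseThresholdMv = "numeric", vg3ReleaseGain = "numeric",
    w3Vg3Weight = "numeric", w3DirectWeight = "numeric",
    w3DirectGain = "numeric", w3CenterSigma = "numeric",
    vg3ToW3DelayMs = "numeric",
    w3SpikeGain = "numeric", w3SpikeThreshold = "numeric",
    w3InhWeight = "numeric", refractoryMs = "numeric",
    ttx = "logical", vglut3Ko = "logical", rectifySubunits = "logical",
    noiseSd = "numeric", seed = "numeric",
    simRate = "numeric", outputRate = "numeric"
  )
)

setValidity("CircuitParams", function(object) {
  msg <- character()
  pos <- c(subunitSpacing = object@subunitSpacing,
           subunitSigma = object@subunitSigma,
           gainOffOverOn = object@gainOffOverOn,
           centerSigmaOn = object@centerSigmaOn,
           centerSigmaOff = object@centerSigmaOff,
           wacSigmaOn = object@wacSigmaOn, wacSigmaOff = object@wacSigmaOff,
           tauMembraneMs = object@tauMembraneMs,
           leakConductance = object@leakConductance,
           simRate = object@simRate, outputRate = object@outputRate)
  if (any(pos <= 0))
    msg <- c(msg, paste("must be > 0:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  if (object@vg3ToW3DelayMs < 0) msg <- c(msg, "delay must be >= 0")
  if (object@vglut3Ko && object@w3Vg3Weight != 0)
    msg <- c(msg, "with vglut3Ko set, w3Vg3Weight must be 0")
  if (object@excReversalMv <= object@inhReversalMv)
    msg <- c(msg, "excitatory reversal must exceed inhibitory reversal")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CircuitParams", function(object) {
  cat(sprintf("CircuitParams: subunits %g um apart (sigma %g um), OFF/ON gain %g\n",
              object@subunitSpacing, object@subunitSigma,
              object@gainOffOverOn))
  cat(sprintf("  VG3 center sigma ON/OFF %g/%g um; wide-field sigma ON/OFF %g/%g um (inner %g um)\n",
              object@centerSigmaOn, object@centerSigmaOff,
              object@wacSigmaOn, object@wacSigmaOff, object@wacInnerRadius))
  cat(sprintf("  ttx=%s vglut3Ko=%s rectify=%s seed=%g\n",
              object@ttx, object@vglut3Ko, object@rectifySubunits,
              object@seed))
})

#' Construct circuit-model parameters
#'
#' Defaults reproduce the qualitative physiology of the VG3/W3 circuit:
#' bipolar subunits 25 um apart with 12.5 um pooling sigma (so that the F2
#' power of surround inhibition to counterphase gratings steps up between
#' 25 um and 50 um bars); VG3 center pooling sigmas from the measured 1-SD
#' excitatory receptive-field diameters (ON 137 um -> sigma 68.5 um, OFF
#' 83.1 um -> 41.5 um); wide-field inhibitory pooling sigmas from the measured
#' inhibition diameters (ON 258 um -> 129 um, OFF 148.2 um -> 74.1 um) with
#' an inner exclusion radius so the wide-field pool samples the surround;
#' OFF-over-ON gain 1.5 (OFF responses exceed ON responses); resting
#' potential -38 mV; VG3-to-W3 glutamatergic delay 10 ms; the knockout
#' switch zeroes the VG3 arm of W3 excitation (approximately half of W3
#' excitation at default weights); the TTX switch silences the spiking
#' wide-field amacrine cell.
#'
#' @param subunitSpacing,subunitSigma bipolar lattice spacing / pooling SD, um.
#' @param kernelOn,kernelOff temporal kernels at `kernelRate` (lag 0 first).
#' @param kernelRate sampling rate of the kernels, Hz.
#' @param gainOffOverOn OFF pathway gain relative to ON.
#' @param centerSigmaOn,centerSigmaOff VG3 excitatory pooling SDs, um.
#' @param wacSigmaOn,wacSigmaOff wide-field inhibitory pooling SDs, um.
#' @param wacInnerRadius inner exclusion radius of the wide-field pool, um:
#'   only subunits beyond this distance from the soma (i.e. the receptive
#'   field surround) feed the wide-field population.
#' @param wacThreshold hard spike threshold of each wide-field unit
#'   (subunit-drive units); local drive below it produces no inhibition.
#' @param wacUnitSpacing grid spacing of the wide-field units, um.
#' @param wacPoolSigma SD of each unit's local Gaussian pool of surround
#'   subunits, um.
#' @param presynWeight,postsynWeight pre-/post-synaptic surround inhibition
#'   weights (presynaptic acts subtractively before release rectification,
#'   postsynaptic as an inhibitory conductance).
#' @param excGain,inhGain conductance per unit drive, nS.
#' @param restingMv,tauMembraneMs,leakConductance membrane parameters.
#' @param excReversalMv,inhReversalMv synaptic reversal potentials, mV.
#' @param vg3ReleaseThresholdMv,vg3ReleaseGain VG3 glutamate release:
#'   rectified above threshold (mV), nS per mV of depolarization.
#' @param w3Vg3Weight,w3DirectWeight VG3 vs direct-bipolar share of W3
#'   excitation (forced to 0 / unchanged by `vglut3Ko`).
#' @param w3DirectGain,w3CenterSigma direct bipolar pool of the W3 cell.
#' @param vg3ToW3DelayMs synaptic delay of the VG3 arm, ms.
#' @param w3SpikeGain,w3SpikeThreshold,w3InhWeight,refractoryMs W3 spike
#'   generator (inhomogeneous Poisson with absolute refractory period).
#' @param ttx silence the spiking wide-field amacrine cell.
#' @param vglut3Ko remove VGluT3-mediated VG3 output to W3.
#' @param rectifySubunits diagnostic switch; `FALSE` makes subunits linear.
#' @param noiseSd additive Gaussian conductance noise SD, nS.
#' @param seed RNG seed for all stochastic stages.
#' @param simRate,outputRate internal simulation / output trace rates, Hz.
#' @return a [CircuitParams-class] object.
#' @export
circuitParams <- function(subunitSpacing = 25, subunitSigma = 12.5,
                          kernelOn = biphasicKernel(tTrough = 0.16,
                                                    balanced = TRUE),
                          kernelOff = biphasicKernel(tTrough = 0.22,
                                                     balanced = TRUE),
                          kernelRate = 30,
                          gainOffOverOn = 1.5,
                          centerSigmaOn = 68.5, centerSigmaOff = 41.5,
                          wacSigmaOn = 129, wacSigmaOff = 74.1,
                          wacInnerRadius = 150, wacThreshold = 0.05,
                          wacUnitSpacing = 50, wacPoolSigma = 75,
                          presynWeight = 20, postsynWeight = 1,
                          excGain = 6, inhGain = 100,
                          restingMv = -38, tauMembraneMs = 20,
                          excReversalMv = 0, inhReversalMv = -60,
                          leakConductance = 1,
                          vg3ReleaseThresholdMv = -38, vg3ReleaseGain = 0.7,
                          w3Vg3Weight = 0.5, w3DirectWeight = 0.5,
                          w3DirectGain = 6, w3CenterSigma = 50,
                          vg3ToW3DelayMs = 10,
                          w3SpikeGain = 60, w3SpikeThreshold = 0.1,
                          w3InhWeight = 0.5, refractoryMs = 2,
                          ttx = FALSE, vglut3Ko = FALSE,
                          rectifySubunits = TRUE,
                          noiseSd = 0.05, seed = 1,
                          simRate = 1000, outputRate = 10000) {
  if (vglut3Ko) w3Vg3Weight <- 0
  new("CircuitParams",
      subunitSpacing = subunitSpacing, subunitSigma = subunitSigma,
      kernelOn = kernelOn, kernelOff = kernelOff, kernelRate = kernelRate,
      gainOffOverOn = gainOffOverOn,
      centerSigmaOn = centerSigmaOn, centerSigmaOff = centerSigmaOff,
      wacSigmaOn = wacSigmaOn, wacSigmaOff = wacSigmaOff,
      wacInnerRadius = wacInnerRadius, wacThreshold = wacThreshold,
      wacUnitSpacing = wacUnitSpacing, wacPoolSigma = wacPoolSigma,
      presynWeight = presynWeight, postsynWeight = postsynWeight,
      excGain = excGain, inhGain = inhGain,
      restingMv = restingMv, tauMembraneMs = tauMembraneMs,
      excReversalMv = excReversalMv, inhReversalMv = inhReversalMv,
      leakConductance = leakConductance,
      vg3ReleaseThresholdMv = vg3ReleaseThresholdMv,
      vg3ReleaseGain = vg3ReleaseGain,
      w3Vg3Weight = w3Vg3Weight, w3DirectWeight = w3DirectWeight,
      w3DirectGain = w3DirectGain, w3CenterSigma = w3CenterSigma,
      vg3ToW3DelayMs = vg3ToW3DelayMs,
      w3SpikeGain = w3SpikeGain, w3SpikeThreshold = w3SpikeThreshold,
      w3InhWeight = w3InhWeight, refractoryMs = refractoryMs,
      ttx = ttx, vglut3Ko = vglut3Ko, rectifySubunits = rectifySubunits,
      noiseSd = noiseSd, seed = seed,
      simRate = simRate, outputRate = outputRate)
}

#' Pathway kernel as expressed in recorded traces
#'
#' The stimulus kernels of the subunit pathways act at the stimulus refresh
#' rate; the recorded traces additionally pass through the linear temporal
#' chain of the simulator (upsampling to the simulation rate, the first-order
#' membrane filter, the output resampling and the frame binning used when
#' filters are recovered from white noise).  This helper pushes a pathway
#' kernel through that chain, giving the ground truth that white-noise filter
#' recovery from simulated traces converges to.
#'
#' @param params a [CircuitParams-class].
#' @param pathway `"on"` or `"off"`.
#' @return numeric kernel on the `kernelRate` lag base, peak-normalized like
#'   the input kernels.
#' @export
effectiveKernel <- function(params, pathway = c("on", "off")) {
  pathway <- match.arg(pathway)
  k <- if (pathway == "on") params@kernelOn else params@kernelOff
  up <- .resample(c(k, numeric(length(k))), params@kernelRate, params@simRate)
  a <- (1 / params@simRate) / (params@tauMembraneMs / 1000)
  y <- as.numeric(stats::filter(a * up, 1 - a, method = "recursive"))
  down <- .binToFrames(.resample(y, params@simRate, params@outputRate),
                       params@outputRate, params@kernelRate)
  down[seq_along(k)] / max(abs(down[seq_along(k)])) * max(abs(k))
}

## Subunit lattice centers for a square field, offset half a spacing so the
## lattice is mirror-symmetric about both axes (no subunit on the midlines).
.subunitLattice <- function(fieldSize, spacing) {
  n <- max(2L, floor(fieldSize / spacing))
  coord <- (seq_len(n) - (n + 1) / 2) * spacing
  cbind(x = rep(coord, each = n), y = rep(coord, times = n))
}

## Sparse (nsub x npix) Gaussian pooling matrix, rows normalized to sum 1.
.gaussPoolMatrix <- function(centers, gx, gy, sigma) {
  cutoff <- 3 * sigma
  npx <- length(gx) * length(gy)
  ii <- jj <- ww <- vector("list", nrow(centers))
  for (s in seq_len(nrow(centers))) {
    cx <- centers[s, 1]; cy <- centers[s, 2]
    xi <- which(abs(gx - cx) <= cutoff)
    yi <- which(abs(gy - cy) <= cutoff)
    if (!length(xi) || !length(yi)) next
    d2 <- outer((gy[yi] - cy)^2, (gx[xi] - cx)^2, "+")
    w <- exp(-d2 / (2 * sigma^2))
    w <- w / sum(w)
    ## pixel linear index for frame matrix (y fastest, column-major)
    pix <- outer(yi, (xi - 1) * length(gy), "+")
    ii[[s]] <- rep.int(s, length(pix))
    jj[[s]] <- as.vector(pix)
    ww[[s]] <- as.vector(w)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                       dims = c(nrow(centers), npx))
}

## Resample a kernel defined at `fromRate` onto `toRate`, preserving its
## time-integral.
.kernelAtRate <- function(kernel, fromRate, toRate) {
  if (abs(fromRate - toRate) < 1e-9) return(kernel)
  t0 <- (seq_along(kernel) - 1) / fromRate
  n2 <- ceiling(length(kernel) * toRate / fromRate)
  t1 <- (seq_len(n2) - 1) / toRate
  stats::approx(t0, kernel, xout = t1, rule = 2, yleft = 0, yright = 0)$y *
    fromRate / toRate
}

#' Bipolar subunit layer
#'
#' Each subunit half-wave rectifies the result of spatial Gaussian pooling
#' followed by temporal kernel convolution of the stimulus contrast
#' (intensity minus mean).  The OFF lattice uses sign-inverted contrast, its
#' own kernel and the OFF/ON gain ratio.  With `rectifySubunits = FALSE`
#' (diagnostic) the rectification is skipped and the subunits are linear.
#'
#' @param clip a [StimulusClip-class]; pixel pitch must be finer than the
#'   subunit sigma and the clip at least as long as the kernel.
#' @param params a [CircuitParams-class].
#' @return list with `on` and `off` (subunit x time drive matrices, one row
#'   per lattice site), `centers` (subunit positions, um) and `frameRate`.
#' @export
bipolarLayer <- function(clip, params = circuitParams()) {
  .assert(pixelPitch(clip) < params@subunitSigma,
          "clip pixel pitch (%g um) must be finer than the subunit sigma (%g um)",
          pixelPitch(clip), params@subunitSigma)
  d <- dim(frames(clip))
  fieldSize <- d[2] * pixelPitch(clip)
  kOn <- .kernelAtRate(params@kernelOn, params@kernelRate, frameRate(clip))
  kOff <- .kernelAtRate(params@kernelOff, params@kernelRate, frameRate(clip))
  .assert(d[1] >= max(length(kOn), length(kOff)),
          "clip (%d frames) is shorter than the temporal kernel", d[1])

  g <- .pixelGrid(fieldSize, pixelPitch(clip))
  centers <- .subunitLattice(fieldSize, params@subunitSpacing)
  W <- .gaussPoolMatrix(centers, g$x, g$y, params@subunitSigma)

  contrast <- matrix(aperm(frames(clip), c(2, 3, 1)), ncol = d[1]) -
    meanIntensity(clip)
  pooled <- as.matrix(W %*% contrast)
  on <- .causalFilter(pooled, kOn)
  off <- -params@gainOffOverOn * .causalFilter(pooled, kOff)
  if (params@rectifySubunits) {
    on[on < 0] <- 0
    off[off < 0] <- 0
  }
  list(on = on, off = off, centers = centers, frameRate = frameRate(clip))
}

#' Spiking wide-field amacrine cell population
#'
#' The wide-field inhibition sampling the receptive-field surround is carried
#' by a lattice of spiking wide-field units (`wacUnitSpacing` apart).  Each
#' unit takes the Gaussian-weighted (`wacPoolSigma`) local mean of the
#' rectified subunit outputs beyond `wacInnerRadius` from the soma, passed
#' through a hard spike threshold (output 0 below `wacThreshold`).  The
#' inhibitory drive onto the recorded cell is the Gaussian-weighted mean of
#' the unit outputs, with the weight profile set by the measured 1-SD
#' inhibition receptive-field sigmas (`wacSigmaOn`/`wacSigmaOff`).  The TTX
#' switch silences the population entirely.
#'
#' @param subunits output of [bipolarLayer()].
#' @param params a [CircuitParams-class].
#' @return numeric inhibitory drive per frame.
#' @export
wideFieldAC <- function(subunits, params = circuitParams()) {
  nt <- ncol(subunits$on)
  if (params@ttx) return(numeric(nt))
  r2sub <- rowSums(subunits$centers^2)
  surround <- r2sub >= params@wacInnerRadius^2
  if (!any(surround)) return(numeric(nt))

  fieldSize <- 2 * max(abs(subunits$centers)) + params@subunitSpacing
  units <- .subunitLattice(fieldSize, params@wacUnitSpacing)
  ## local pool of each unit over surround subunits (rows normalized)
  d2 <- outer(units[, 1], subunits$centers[, 1], "-")^2 +
        outer(units[, 2], subunits$centers[, 2], "-")^2
  P <- exp(-d2 / (2 * params@wacPoolSigma^2))
  P[, !surround] <- 0
  mass <- rowSums(P)
  keep <- mass > 0.1 * max(mass)
  if (!any(keep)) return(numeric(nt))
  P <- P[keep, , drop = FALSE] / mass[keep]
  unitDrive <- P %*% (subunits$on + subunits$off)
  unitOut <- pmax(unitDrive - params@wacThreshold, 0)

  r2u <- rowSums(units[keep, , drop = FALSE]^2)
  G <- (exp(-r2u / (2 * params@wacSigmaOn^2)) +
        exp(-r2u / (2 * params@wacSigmaOff^2))) / 2
  as.vector(crossprod(unitOut, G)) / sum(G)
}

## Center-Gaussian pooling of subunit outputs (rows normalized within lattice)
.centerPool <- function(subunits, sigmaOn, sigmaOff) {
  r2 <- rowSums(subunits$centers^2)
  wOn <- exp(-r2 / (2 * sigmaOn^2)); wOn <- wOn / sum(wOn)
  wOff <- exp(-r2 / (2 * sigmaOff^2)); wOff <- wOff / sum(wOff)
  as.vector(crossprod(subunits$on, wOn)) +
    as.vector(crossprod(subunits$off, wOff))
}

## Membrane integration at simRate: first-order relaxation toward the
## quasi-static conductance mix.
.membrane <- function(gE, gI, params) {
  gL <- params@leakConductance
  EL <- params@restingMv; Ee <- params@excReversalMv; Ei <- params@inhReversalMv
  vInf <- (gL * EL + gE * Ee + gI * Ei) / (gL + gE + gI)
  tau <- params@tauMembraneMs / 1000
  dt <- 1 / params@simRate
  a <- dt / tau
  v <- numeric(length(vInf))
  vPrev <- EL
  for (t in seq_along(vInf)) {
    vPrev <- vPrev + a * (vInf[t] - vPrev)
    v[t] <- vPrev
  }
  v
}

## Baseline: the last 0.5 s of the pre-stimulus lead-in (clear of any onset
## transient at clip start).
.baselineFor <- function(clip) {
  ev <- events(clip)
  lead <- if (nrow(ev)) min(ev$start_s) else 0
  if (lead > 0.05) c(max(0, lead - 0.5), lead) else c(0, 0)
}

.traceFrom <- function(x, rate, outRate, modality, clip) {
  ev <- events(clip)
  bw <- .baselineFor(clip)
  epochedTrace(.resample(x, rate, outRate), rate = outRate,
               modality = modality, baselineWindow = bw, events = ev)
}

## Shared deterministic front end of both cell models.
.circuitFrontEnd <- function(clip, params) {
  sub <- bipolarLayer(clip, params)
  wac <- wideFieldAC(sub, params)
  excDrive <- .centerPool(sub, params@centerSigmaOn, params@centerSigmaOff)
  gE <- params@excGain * pmax(excDrive - params@presynWeight * wac, 0)
  gI <- params@inhGain * params@postsynWeight * wac
  up <- function(x) pmax(.resample(x, sub$frameRate, params@simRate), 0)
  list(sub = sub, wac = wac, gE = up(gE), gI = up(gI))
}

#' Simulate a VG3 amacrine cell
#'
#' Runs the rectified-subunit circuit for a stimulus clip and returns graded
#' voltage, EPSC and IPSC traces of a VG3 amacrine cell.  Excitation is the
#' center-Gaussian pool of the subunit drive minus presynaptic (subtractive,
#' floored at zero) wide-field inhibition; postsynaptic inhibition enters as a
#' conductance.  Voltage is the quasi-static conductance mix relaxed by the
#' membrane time constant toward the resting potential; EPSC/IPSC are computed
#' at the standard holding potentials (inhibitory reversal -60 mV for EPSCs,
#' excitatory reversal 0 mV for IPSCs) with additive, seeded Gaussian
#' conductance noise.
#'
#' @param clip a [StimulusClip-class].
#' @param params a [CircuitParams-class].
#' @return list of [EpochedTrace-class]: `voltage` (mV), `epsc`, `ipsc` (pA),
#'   `gExc`, `gInh` (nS), all at `params@outputRate`.
#' @export
simulateVG3 <- function(clip, params = circuitParams()) {
  fe <- .circuitFrontEnd(clip, params)
  .withSeed(params@seed, function() {
    n <- length(fe$gE)
    gEn <- pmax(fe$gE + stats::rnorm(n, sd = params@noiseSd), 0)
    gIn <- pmax(fe$gI + stats::rnorm(n, sd = params@noiseSd), 0)
    v <- .membrane(gEn, gIn, params)
    epsc <- gEn * (params@inhReversalMv - params@excReversalMv)
    ipsc <- gIn * (params@excReversalMv - params@inhReversalMv)
    sr <- params@simRate; orate <- params@outputRate
    list(voltage = .traceFrom(v, sr, orate, "voltage_mV", clip),
         epsc = .traceFrom(epsc, sr, orate, "current_pA", clip),
         ipsc = .traceFrom(ipsc, sr, orate, "current_pA", clip),
         gExc = .traceFrom(gEn, sr, orate, "conductance_nS", clip),
         gInh = .traceFrom(gIn, sr, orate, "conductance_nS", clip))
  })
}

#' Simulate a W3 ganglion cell
#'
#' W3 excitation is the sum of (i) thresholded, delayed glutamate release from
#' the simulated VG3 amacrine cell, weighted by `w3Vg3Weight` (zero in the
#' VGluT3 knockout), and (ii) a direct center bipolar pool weighted by
#' `w3DirectWeight`.  Inhibition is the shared wide-field drive.  Spikes are
#' drawn as an inhomogeneous Poisson process from the rectified net drive with
#' an absolute refractory period.  All randomness derives from `params@seed`.
#'
#' @param clip a [StimulusClip-class].
#' @param params a [CircuitParams-class].
#' @return list of [EpochedTrace-class]: `epsc`, `ipsc` (pA), `gExc`, `gInh`
#'   (nS), `rate` (spike_rate_Hz, at `simRate` resampled to output rate) and
#'   `spikes` (spike_times_s).
#' @export
simulateW3 <- function(clip, params = circuitParams()) {
  fe <- .circuitFrontEnd(clip, params)
  direct <- params@w3DirectGain *
    .centerPool(fe$sub, params@w3CenterSigma, params@w3CenterSigma)
  directUp <- pmax(.resample(direct, fe$sub$frameRate, params@simRate), 0)

  .withSeed(params@seed, function() {
    n <- length(fe$gE)
    ## VG3 voltage (noisy, as in simulateVG3) -> thresholded release, delayed
    gEv <- pmax(fe$gE + stats::rnorm(n, sd = params@noiseSd), 0)
    gIv <- pmax(fe$gI + stats::rnorm(n, sd = params@noiseSd), 0)
    v <- .membrane(gEv, gIv, params)
    release <- params@vg3ReleaseGain * pmax(v - params@vg3ReleaseThresholdMv, 0)
    dly <- round(params@vg3ToW3DelayMs / 1000 * params@simRate)
    if (dly > 0) release <- c(numeric(dly), release)[seq_len(n)]

    gE <- params@w3Vg3Weight * release + params@w3DirectWeight * directUp
    gE <- pmax(gE + stats::rnorm(n, sd = params@noiseSd), 0)
    gI <- pmax(fe$gI + stats::rnorm(n, sd = params@noiseSd), 0)

    drive <- gE - params@w3InhWeight * gI - params@w3SpikeThreshold
    rate <- params@w3SpikeGain * pmax(drive, 0)
    dt <- 1 / params@simRate
    refr <- params@refractoryMs / 1000
    u <- stats::runif(n)
    spike <- u < rate * dt
    if (any(spike)) {
      tsp <- (which(spike) - 0.5) * dt
      keep <- c(TRUE, diff(tsp) > refr)
      while (!all(keep)) {           # enforce absolute refractory period
        tsp <- tsp[keep]
        keep <- c(TRUE, diff(tsp) > refr)
      }
    } else tsp <- numeric(0)

    sr <- params@simRate; orate <- params@outputRate
    ev <- events(clip)
    bw <- .baselineFor(clip)
    epsc <- gE * (params@inhReversalMv - params@excReversalMv)
    ipsc <- gI * (params@excReversalMv - params@inhReversalMv)
    list(epsc = .traceFrom(epsc, sr, orate, "current_pA", clip),
         ipsc = .traceFrom(ipsc, sr, orate, "current_pA", clip),
         gExc = .traceFrom(gE, sr, orate, "conductance_nS", clip),
         gInh = .traceFrom(gI, sr, orate, "conductance_nS", clip),
         rate = .traceFrom(rate, sr, orate, "spike_rate_Hz", clip),
         spikes = epochedTrace(tsp, rate = sr, modality = "spike_times_s",
                               baselineWindow = bw, events = ev,
                               duration_s = n * dt))
  })
}
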
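## Response metrics: baseline-subtracted epoch amplitudes, conductance
## extraction, F1/F2 harmonic analysis, and motion/size/speed/direction tuning.

## Mean of a trace within [t0, t1): sample mean for sampled modalities,
## spike count / duration for spike-time traces.
.windowMean <- function(trace, t0, t1) {
  if (modality(trace) == "spike_times_s") {
    .assert(t1 > t0, "empty window")
    sum(traceSamples(trace) >= t0 & traceSamples(trace) < t1) / (t1 - t0)
  } else {
    idx <- .windowIdx(t0, t1, traceRate(trace), length(traceSamples(trace)))
    mean(traceSamples(trace)[idx])
  }
}

.baselineMean <- function(trace, baseline = baselineWindow(trace)) {
  if (length(baseline) != 2 || baseline[2] <= baseline[1]) return(0)
  .windowMean(trace, baseline[1], baseline[2])
}

#' Baseline-subtracted epoch amplitude
#'
#' Mean of the response within a measurement window minus the mean within the
#' baseline window — the standard amplitude measure for spot, bar, grating and
#' texture responses (window lengths of 100-200 ms).  Signed:
#' hyperpolarizations and suppressions come out negative.
#'
#' @param trace an [EpochedTrace-class].
#' @param window `(start_s, end_s)` measurement window.
#' @param baseline `(start_s, end_s)`; defaults to the trace's baseline
#'   window.  A zero-length baseline contributes 0.
#' @return signed amplitude in the trace's units.
#' @export
epochAmplitude <- function(trace, window, baseline = baselineWindow(trace)) {
  .assert(length(window) == 2 && window[2] > window[1],
          "window must be (start_s, end_s)")
  .assert(window[1] >= -1e-9 && window[2] <= duration(trace) + 1e-9,
          "window [%g, %g] s lies outside the trace", window[1], window[2])
  .windowMean(trace, window[1], window[2]) - .baselineMean(trace, baseline)
}

#' Peak epoch amplitude within a stimulus segment
#'
#' Slides a window of `windowLength` over `[start_s, end_s + lag_s]` and
#' returns the baseline-subtracted window mean of largest magnitude (signed).
#' This places the measurement window at the response peak within the
#' segment, accommodating response latency via `lag_s`.
#'
#' @param trace an [EpochedTrace-class] (sampled modality).
#' @param start_s,end_s segment bounds, seconds.
#' @param windowLength window length in seconds (default 0.15).
#' @param lag_s extra time appended after the segment for late responses.
#' @param baseline baseline window.
#' @return signed amplitude.
#' @export
segmentAmplitude <- function(trace, start_s, end_s, windowLength = 0.15,
                             lag_s = 0.3, baseline = baselineWindow(trace)) {
  end_s <- min(end_s + lag_s, duration(trace))
  if (modality(trace) == "spike_times_s") {
    ## windowed spike rate on a 10-ms grid
    grid <- seq(start_s, end_s - windowLength, by = 0.01)
    .assert(length(grid) > 0, "segment shorter than the window")
    rates <- vapply(grid, function(t0)
      .windowMean(trace, t0, t0 + windowLength), numeric(1))
    vals <- rates - .baselineMean(trace, baseline)
  } else {
    rate <- traceRate(trace)
    idx <- .windowIdx(start_s, end_s, rate, length(traceSamples(trace)))
    w <- max(2L, round(windowLength * rate))
    .assert(length(idx) >= w, "segment shorter than the window")
    vals <- .slidingMean(traceSamples(trace)[idx], w) -
      .baselineMean(trace, baseline)
  }
  vals[which.max(abs(vals))]
}

#' Convert a clamped current trace to a conductance trace
#'
#' `g(t) = I(t) / (holding - reversal)` in nS for pA and mV; with the standard
#' holding potentials (EPSCs at the inhibitory reversal -60 mV, IPSCs at the
#' excitatory reversal 0 mV) physiological currents give non-negative
#' conductances.
#'
#' @param trace an [EpochedTrace-class] with `modality = "current_pA"`.
#' @param holdingMv,reversalMv holding and synaptic reversal potentials, mV
#'   (must differ).
#' @return an [EpochedTrace-class] with `modality = "conductance_nS"`.
#' @seealso [conductanceToCurrent()] for the exact inverse.
#' @export
currentToConductance <- function(trace, holdingMv, reversalMv) {
  .assert(holdingMv != reversalMv, "holding and reversal potentials must differ")
  epochedTrace(traceSamples(trace) / (holdingMv - reversalMv),
               rate = traceRate(trace), modality = "conductance_nS",
               baselineWindow = baselineWindow(trace), events = events(trace))
}

#' @rdname currentToConductance
#' @export
conductanceToCurrent <- function(trace, holdingMv, reversalMv) {
  .assert(holdingMv != reversalMv, "holding and reversal potentials must differ")
  epochedTrace(traceSamples(trace) * (holdingMv - reversalMv),
               rate = traceRate(trace), modality = "current_pA",
               baselineWindow = baselineWindow(trace), events = events(trace))
}

#' F1/F2 harmonic amplitudes
#'
#' Fourier amplitudes of a response at once (F1) and twice (F2) the stimulus
#' modulation frequency.  The analyzed stretch is truncated to the largest
#' whole number of fundamental periods (the truncated tail length is returned)
#' and the mean is removed before projection.  Amplitudes use the convention
#' in which a pure tone `A sin(2 pi f t)` has F1 = A.
#'
#' @param x numeric vector or [EpochedTrace-class].
#' @param fundamentalHz stimulus modulation frequency (F1 frequency), Hz.
#' @param rate sampling rate (taken from the trace if `x` is one).
#' @param window optional `(start_s, end_s)` restricting the analysis (e.g.
#'   the modulation epoch).
#' @return list with `f1Amplitude`, `f2Amplitude`, `f1Hz`, `f2Hz`,
#'   `f1Power`, `f2Power` (squared amplitudes) and `truncated_s`.
#' @export
harmonicAmplitudes <- function(x, fundamentalHz, rate = NULL, window = NULL) {
  if (methods::is(x, "EpochedTrace")) {
    rate <- traceRate(x)
    s <- traceSamples(x)
    if (!is.null(window))
      s <- s[.windowIdx(window[1], window[2], rate, length(s))]
  } else {
    .assert(!is.null(rate), "rate is required for a plain numeric input")
    s <- as.numeric(x)
  }
  perN <- rate / fundamentalHz
  nPer <- floor(length(s) / perN)
  .assert(nPer >= 1, "trace spans less than one fundamental period")
  n <- floor(nPer * perN)
  truncated <- (length(s) - n) / rate
  s <- s[seq_len(n)] - mean(s[seq_len(n)])
  t <- (seq_len(n) - 1) / rate
  amp <- function(f) {
    z <- sum(s * exp(-2i * pi * f * t))
    2 * Mod(z) / n
  }
  f1 <- amp(fundamentalHz); f2 <- amp(2 * fundamentalHz)
  list(f1Amplitude = f1, f2Amplitude = f2,
       f1Hz = fundamentalHz, f2Hz = 2 * fundamentalHz,
       f1Power = f1^2, f2Power = f2^2, truncated_s = truncated)
}

#' Direction selectivity index
#'
#' `DSI = |sum F1(theta) e^{i theta}| / sum F1(theta)` over equally spaced
#' directions; 0 for a flat tuning curve, 1 for a single responsive direction.
#'
#' @param f1 non-negative F1 amplitudes, one per direction (not all zero).
#' @param directionsDeg directions in degrees; defaults to equal spacing over
#'   the full circle (eight directions at 45 degrees for `length(f1) == 8`).
#' @return DSI in \[0, 1\].
#' @export
dsi <- function(f1, directionsDeg = seq(0, 360, length.out = length(f1) + 1)[-(length(f1) + 1)]) {
  .assert(all(f1 >= 0), "F1 amplitudes must be non-negative")
  .assert(sum(f1) > 0, "DSI is undefined for all-zero amplitudes")
  th <- directionsDeg * pi / 180
  Mod(sum(f1 * exp(1i * th))) / sum(f1)
}

#' Motion-selectivity amplitudes
#'
#' Peak baseline-subtracted amplitudes for the three texture-motion segments
#' (`global`, `diff_center`, `diff_surround`), each measured with the same
#' window rule ([segmentAmplitude()]) on the trace's own motion epoch.
#' Depolarizations/excitations are positive, hyperpolarizations and
#' suppressions negative.
#'
#' @param traces named list of [EpochedTrace-class] with names (or event
#'   labels) `global`, `diff_center`, `diff_surround`.
#' @param windowLength,lag_s passed to [segmentAmplitude()].
#' @return data.frame with columns `segment`, `amplitude`, `modality`.
#' @export
motionSelectivity <- function(traces, windowLength = 0.15, lag_s = 0.3) {
  need <- c("global", "diff_center", "diff_surround")
  .assert(all(need %in% names(traces)),
          "missing segment(s): %s",
          paste(setdiff(need, names(traces)), collapse = ", "))
  amp <- vapply(need, function(seg) {
    tr <- traces[[seg]]
    ev <- events(tr)
    row <- ev[ev$label == seg, , drop = FALSE]
    .assert(nrow(row) >= 1, "trace for '%s' lacks a matching epoch", seg)
    segmentAmplitude(tr, row$start_s[1], row$end_s[1],
                     windowLength = windowLength, lag_s = lag_s)
  }, numeric(1))
  data.frame(segment = need, amplitude = unname(amp),
             modality = modality(traces[[1]]))
}

## Amplitude of the response to one edge transit: window centered on the
## center-crossing event (plus a latency shift), peak-searched around it.
.edgeAmplitude <- function(trace, label, windowLength = 0.15, latency = 0.05,
                           search_s = 0.35) {
  ev <- events(trace)
  row <- ev[ev$label == label, , drop = FALSE]
  .assert(nrow(row) >= 1, "missing edge event '%s'", label)
  t0 <- row$start_s[1] + latency
  segmentAmplitude(trace, max(0, t0 - windowLength / 2),
                   min(duration(trace), t0 + search_s),
                   windowLength = windowLength, lag_s = 0)
}

#' Size tuning of edge responses
#'
#' Leading- and trailing-edge response amplitudes for moving bars of several
#' heights, and the suppression index `1 - amp(600) / amp(200)` quantifying
#' the loss of edge responses for tall bars.
#'
#' @param traces list of [EpochedTrace-class], one per bar height, each
#'   carrying `leading_edge` / `trailing_edge` events.
#' @param heights bar heights (um), parallel to `traces`.
#' @param windowLength,latency edge measurement window (s) and latency shift.
#' @param refHeights the two heights compared by the suppression index.
#' @return list with `table` (height, edge, amplitude) and
#'   `suppressionIndex` (NA unless both reference heights are present).
#' @export
sizeTuning <- function(traces, heights, windowLength = 0.15, latency = 0.05,
                       refHeights = c(200, 600)) {
  .assert(length(traces) == length(heights), "one trace per height required")
  tab <- do.call(rbind, lapply(seq_along(traces), function(i) {
    data.frame(height = heights[i],
               edge = c("leading", "trailing"),
               amplitude = c(
                 .edgeAmplitude(traces[[i]], "leading_edge", windowLength,
                                latency),
                 .edgeAmplitude(traces[[i]], "trailing_edge", windowLength,
                                latency)))
  }))
  si <- NA_real_
  if (all(refHeights %in% heights)) {
    ampAt <- function(h)
      tab$amplitude[tab$height == h & tab$edge == "leading"]
    si <- 1 - ampAt(refHeights[2]) / ampAt(refHeights[1])
  }
  list(table = tab, suppressionIndex = si)
}

#' Speed tuning of edge responses
#'
#' Edge-response amplitudes of a bar of fixed height moving at several speeds.
#'
#' @param traces list of [EpochedTrace-class], one per speed.
#' @param speeds speeds (um/s), parallel to `traces`.
#' @param windowLength,latency as in [sizeTuning()].
#' @return data.frame with columns `speed`, `edge`, `amplitude`.
#' @export
speedTuning <- function(traces, speeds, windowLength = 0.15, latency = 0.05) {
  .assert(length(traces) == length(speeds), "one trace per speed required")
  do.call(rbind, lapply(seq_along(traces), function(i) {
    data.frame(speed = speeds[i],
               edge = c("leading", "trailing"),
               amplitude = c(
                 .edgeAmplitude(traces[[i]], "leading_edge", windowLength,
                                latency),
                 .edgeAmplitude(traces[[i]], "trailing_edge", windowLength,
                                latency)))
  }))
}
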
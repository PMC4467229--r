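## ON/OFF temporal-filter recovery from Gaussian white-noise runs:
## response-weighted stimulus ensemble, principal-component sign splitting,
## and filter metrics (peak time, biphasic index, frequency tuning).

#' Response-weighted stimulus ensemble
#'
#' For every frame `t >= lagFrames`, the preceding `lagFrames`-frame stimulus
#' window (lag 0 = the frame simultaneous with the response, increasing lag
#' reaching into the past) is weighted by the baseline-subtracted response of
#' that frame.  The response trace is resampled to frame bins (mean within
#' each frame); its baseline is the mean over the trace's baseline window, or
#' the run mean if that window is empty.  Windows overlap (one per frame).
#'
#' @param stim stimulus intensity per frame: a numeric vector or a white-noise
#'   [StimulusClip-class] (its per-frame region intensity is used).  Converted
#'   to contrast by subtracting the mean.
#' @param response an [EpochedTrace-class] (sampled modality) covering the
#'   stimulus, or a numeric vector already on the frame base.
#' @param lagFrames window length in frames (>= 5; default 15, i.e. 500 ms at
#'   30 Hz).
#' @param refreshHz stimulus refresh rate (taken from the clip if given).
#' @return list with `segments` (weighted windows, one row per frame),
#'   `weights`, `globalAverage` (mean weighted window), `lagFrames`,
#'   `refreshHz`.
#' @export
responseWeightedEnsemble <- function(stim, response, lagFrames = 15,
                                     refreshHz = 30) {
  .assert(lagFrames >= 5, "lagFrames must be at least 5")
  if (methods::is(stim, "StimulusClip")) {
    refreshHz <- stim@params$refreshHz %||% frameRate(stim)
    s <- stim@params$values
    if (is.null(s)) {                    # uniform-region clips: use the time
      m <- matrix(frames(stim), nrow = nFrames(stim))   # course of the most
      v <- colMeans(m^2) - colMeans(m)^2                # modulated pixel
      s <- m[, which.max(v)]
    }
  } else s <- as.numeric(stim)
  s <- s - mean(s)

  if (methods::is(response, "EpochedTrace")) {
    w <- .binToFrames(traceSamples(response), traceRate(response), refreshHz)
    bw <- baselineWindow(response)
    base <- if (bw[2] > bw[1]) .windowMean(response, bw[1], bw[2]) else mean(w)
  } else {
    w <- as.numeric(response)
    base <- mean(w)
  }
  n <- min(length(s), length(w))
  s <- s[seq_len(n)]; w <- w[seq_len(n)] - base
  .assert(n > lagFrames, "stimulus shorter than the filter window")
  .assert(any(w != 0), "all response weights are zero")

  idx <- lagFrames:n
  seg <- vapply(seq_len(lagFrames) - 1L, function(lag) s[idx - lag],
                numeric(length(idx)))       # rows = windows, cols = lags
  seg <- seg * w[idx]
  list(segments = seg, weights = w[idx],
       globalAverage = colMeans(seg),
       lagFrames = lagFrames, refreshHz = refreshHz)
}

#' Split a response-weighted ensemble into ON and OFF filters
#'
#' Principal-components analysis of the weighted stimulus windows identifies
#' the dimension of highest variance (on the mean-centered windows by
#' default, since variance is defined about the mean; `center = FALSE` runs
#' the PCA on the raw second moment, in which the weighted mean — the global
#' average — also carries signal); windows are
#' partitioned by the sign of their projection onto this first component and
#' each group is averaged into a filter.  The group whose average has a
#' positive dominant extremum is labeled ON.  Both filters are rescaled by one
#' common factor so that `sum(on) + sum(off)` equals the sum of the global
#' response-weighted average (the scaling contract, asserted by the class
#' validity of the result).
#'
#' @param ensemble output of [responseWeightedEnsemble()] (>= 100 windows).
#' @param center mean-center the windows before the PCA (default `TRUE`).
#' @return a [FilterPair-class].
#' @export
splitOnOff <- function(ensemble, center = TRUE) {
  seg <- ensemble$segments
  .assert(nrow(seg) >= 100, "at least 100 stimulus windows required")
  m <- if (center) scale(seg, center = TRUE, scale = FALSE) else seg
  .assert(sum(apply(m, 2, stats::var)) > 0,
          "degenerate ensemble: all windows identical")
  pc1 <- svd(m, nu = 0, nv = 1)$v[, 1]
  proj <- as.vector(seg %*% pc1)     # raw projections carry the ON/OFF sign

  gPos <- if (any(proj >= 0)) colMeans(seg[proj >= 0, , drop = FALSE])
          else numeric(ensemble$lagFrames)
  gNeg <- if (any(proj < 0)) colMeans(seg[proj < 0, , drop = FALSE])
          else numeric(ensemble$lagFrames)

  ## common rescaling (the scaling contract), then label the groups: the
  ## group whose scaled average has a positive dominant extremum is ON
  tot <- sum(gPos) + sum(gNeg)
  target <- sum(ensemble$globalAverage)
  .assert(abs(tot) > .Machine$double.eps * 100,
          "cannot scale filters: sum(on) + sum(off) is zero")
  sc <- target / tot
  gPos <- gPos * sc; gNeg <- gNeg * sc
  domPositive <- function(f) any(f != 0) && f[which.max(abs(f))] > 0
  if (!domPositive(gPos) && domPositive(gNeg)) {
    on <- gNeg; off <- gPos
  } else {
    on <- gPos; off <- gNeg          # "positive = ON" tie-break
  }
  new("FilterPair", onFilter = on, offFilter = off,
      refreshHz = ensemble$refreshHz, globalAverage = ensemble$globalAverage,
      scaleChecksum = sum(on) + sum(off))
}

#' Recover ON and OFF temporal filters from a white-noise run
#'
#' Convenience wrapper: [responseWeightedEnsemble()] followed by
#' [splitOnOff()].
#'
#' @inheritParams responseWeightedEnsemble
#' @inheritParams splitOnOff
#' @return a [FilterPair-class].
#' @export
recoverFilters <- function(stim, response, lagFrames = 15, refreshHz = 30,
                           center = TRUE) {
  splitOnOff(responseWeightedEnsemble(stim, response, lagFrames, refreshHz),
             center = center)
}

## One-sided amplitude spectrum: A_k = 2 |X_k| / n (A_0 = |X_0| / n).
.amplitudeSpectrum <- function(f, rate) {
  n <- length(f)
  X <- stats::fft(f)
  k <- 0:(floor(n / 2))
  amp <- Mod(X[k + 1]) / n * ifelse(k == 0, 1, 2)
  data.frame(hz = k * rate / n, amplitude = amp)
}

#' Filter metrics: peak time, biphasic index, frequency tuning
#'
#' Peak time is the lag of the dominant extremum of each filter.  The
#' biphasic index follows the ON/OFF conventions: for a filter whose dominant
#' lobe is positive (ON-type), `|trough| / peak`; for a dominant negative lobe
#' (OFF-type), `peak / |trough|` — a monophasic filter scores 0.  Frequency
#' tuning is the one-sided Fourier amplitude spectrum of each filter.
#'
#' @param pair a [FilterPair-class] with nonzero filters.
#' @return list with `peakTime_s`, `biphasicIndex` (named `on`/`off` vectors)
#'   and `frequencyTuning` (data.frame `hz`, `onAmplitude`, `offAmplitude`).
#' @export
filterMetrics <- function(pair) {
  one <- function(f) {
    .assert(any(f != 0), "zero filter")
    i <- which.max(abs(f))
    peakTime <- (i - 1) / pair@refreshHz
    if (f[i] > 0) {
      trough <- min(f, 0)
      bi <- abs(trough) / f[i]
    } else {
      peak <- max(f, 0)
      bi <- peak / abs(f[i])
    }
    c(peakTime = peakTime, biphasic = bi)
  }
  mOn <- one(pair@onFilter); mOff <- one(pair@offFilter)
  spOn <- .amplitudeSpectrum(pair@onFilter, pair@refreshHz)
  spOff <- .amplitudeSpectrum(pair@offFilter, pair@refreshHz)
  list(peakTime_s = c(on = unname(mOn["peakTime"]),
                      off = unname(mOff["peakTime"])),
       biphasicIndex = c(on = unname(mOn["biphasic"]),
                         off = unname(mOff["biphasic"])),
       frequencyTuning = data.frame(hz = spOn$hz,
                                    onAmplitude = spOn$amplitude,
                                    offAmplitude = spOff$amplitude))
}
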
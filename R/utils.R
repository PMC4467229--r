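## Internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Build a StimulusClip from a (t, y, x) array, clamping away numerical fuzz.
.newClip <- function(frames, frameRate, pixelPitch, meanIntensity, events,
                     stimClass, params = list()) {
  frames[frames < 0] <- 0
  frames[frames > 1] <- 1
  ev <- events[order(events$start_s), , drop = FALSE]
  rownames(ev) <- NULL
  new("StimulusClip", frames = frames, frameRate = frameRate,
      pixelPitch = pixelPitch, meanIntensity = meanIntensity,
      events = ev, stimClass = stimClass, params = params)
}

## Pixel-center coordinate grids (um), origin at the field center.
.pixelGrid <- function(fieldSize, pitch) {
  n <- round(fieldSize / pitch)
  coord <- (seq_len(n) - (n + 1) / 2) * pitch
  list(n = n, x = coord, y = coord)
}

## Sample index range for a time window [start, end) at a given rate.
.windowIdx <- function(start_s, end_s, rate, n) {
  i0 <- max(1L, floor(start_s * rate) + 1L)
  i1 <- min(n, ceiling(end_s * rate))
  .assert(i0 <= i1, "time window [%g, %g] s lies outside the trace", start_s, end_s)
  i0:i1
}

## Mean of a uniformly sampled trace within each stimulus frame (handles
## non-integer samples-per-frame ratios).
.binToFrames <- function(samples, rate, frameRate) {
  n <- length(samples)
  frame <- floor((seq_len(n) - 0.5) / rate * frameRate) + 1L
  nfr <- floor(n / rate * frameRate)
  keep <- frame <= nfr
  as.vector(rowsum(samples[keep], frame[keep])) /
    tabulate(frame[keep], nbins = nfr)
}

## Run `fn()` under a fixed RNG seed, restoring global RNG state afterwards.
.withSeed <- function(seed, fn) {
  if (is.null(seed) || is.na(seed)) return(fn())
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

## Causal FIR convolution along rows of a (units x time) matrix:
## out[, t] = sum_k kernel[k] * x[, t - k + 1]   (kernel index 1 = lag 0)
.causalFilter <- function(x, kernel) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  nt <- ncol(x)
  out <- matrix(0, nrow(x), nt)
  for (k in seq_along(kernel)) {
    if (kernel[k] == 0) next
    out[, k:nt] <- out[, k:nt] + kernel[k] * x[, 1:(nt - k + 1), drop = FALSE]
  }
  out
}

## Piecewise-linear resampling of a signal from rate r1 to rate r2
## (sample i sits at time (i - 0.5) / rate).
.resample <- function(x, r1, r2) {
  n2 <- round(length(x) / r1 * r2)
  t1 <- (seq_along(x) - 0.5) / r1
  t2 <- (seq_len(n2) - 0.5) / r2
  stats::approx(t1, x, xout = t2, rule = 2)$y
}

## Sliding-window means of width w (samples); returns vector of length n-w+1.
.slidingMean <- function(x, w) {
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}
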
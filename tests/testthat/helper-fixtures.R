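# Shared fixtures, all built in code.  Expensive clips are memoized so the
# suite builds each at most once.

.cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .cache)) assign(key, build(), envir = .cache)
  get(key, envir = .cache)
}

# Texture-motion clips at the standard geometry (one per segment)
textureClips <- function() memo("texture", function() {
  segs <- c("global", "diff_center", "diff_surround")
  cl <- lapply(segs, function(s) makeTextureMotion(segment = s))
  names(cl) <- segs
  cl
})

# A small, fast geometry for tests that only exercise plumbing
smallGeom <- list(fieldSize = 480, pixelPitch = 8, frameRate = 30)

# Uniform full-field clip with an arbitrary per-frame modulation (contrast
# units, added to mean 0.5); used to probe the subunit layer directly.
uniformClip <- function(modulation, frameRate = 30, fieldSize = 160,
                        pixelPitch = 8) {
  n <- round(fieldSize / pixelPitch)
  fr <- array(0.5, dim = c(length(modulation), n, n)) +
    array(rep(modulation, n * n), dim = c(length(modulation), n, n))
  fr[fr < 0] <- 0; fr[fr > 1] <- 1
  new("StimulusClip", frames = fr, frameRate = frameRate,
      pixelPitch = pixelPitch, meanIntensity = 0.5,
      events = data.frame(label = "mod", start_s = 0,
                          end_s = length(modulation) / frameRate),
      stimClass = "uniform", params = list())
}

# Noise-free circuit parameters for deterministic checks
quietParams <- function(...) circuitParams(noiseSd = 0, ...)

# Linear filtering helper matching the circuit's causal convolution
causalConv <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_along(k)) out[i:n] <- out[i:n] + k[i] * x[1:(n - i + 1)]
  out
}
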
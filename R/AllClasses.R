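## S4 data containers used throughout the package.

#' @include AllGenerics.R
NULL

#' StimulusClip: a discretized space-time visual stimulus
#'
#' A `StimulusClip` holds a stimulus movie as a 3D intensity array with
#' dimensions (time, y, x), unitless intensity in \[0, 1\] (mid-gray = mean
#' intensity), together with its frame rate, pixel pitch and a machine-readable
#' epoch/event table.  Event tables carry all timing used downstream: epoch
#' extraction never relies on hidden stimulus state.
#'
#' @slot frames 3D numeric array `(t, y, x)`, intensities in \[0, 1\].
#' @slot frameRate frames per second (Hz).
#' @slot pixelPitch micrometres per pixel.
#' @slot meanIntensity the background/mean intensity (default 0.5).
#' @slot events `data.frame` with columns `label`, `start_s`, `end_s`; sorted
#'   by onset and non-overlapping within a label.
#' @slot stimClass character tag naming the generator that produced the clip.
#' @slot params list of generator parameters (provenance; not interpreted).
#'
#' @seealso [makeSpotSeries()], [makeSplitField()], [makeTextureMotion()],
#'   [makeMovingBar()], [makeWhiteNoise()]
#' @export
setClass("StimulusClip",
  representation(
    frames = "array",
    frameRate = "numeric",
    pixelPitch = "numeric",
    meanIntensity = "numeric",
    events = "data.frame",
    stimClass = "character",
    params = "list"
  ),
  prototype(
    frameRate = 30, pixelPitch = 4, meanIntensity = 0.5,
    events = data.frame(label = character(), start_s = numeric(),
                        end_s = numeric()),
    stimClass = "clip", params = list()
  )
)

setValidity("StimulusClip", function(object) {
  msg <- character()
  if (length(dim(object@frames)) != 3L)
    msg <- c(msg, "frames must be a 3D (t, y, x) array")
  rng <- suppressWarnings(range(object@frames))
  if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
    msg <- c(msg, "intensities must lie in [0, 1]")
  if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
  if (object@pixelPitch <= 0) msg <- c(msg, "pixelPitch must be positive")
  ev <- object@events
  if (!all(c("label", "start_s", "end_s") %in% names(ev)))
    msg <- c(msg, "events needs columns label, start_s, end_s")
  else if (nrow(ev) > 1) {
    if (is.unsorted(ev$start_s)) msg <- c(msg, "events must be sorted by start_s")
    for (lb in unique(ev$label)) {
      e <- ev[ev$label == lb, , drop = FALSE]
      if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)] - 1e-9))
        msg <- c(msg, sprintf("events overlap within label '%s'", lb))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("frames", "StimulusClip", function(x) x@frames)
#' @rdname accessors
#' @export
setMethod("frameRate", "StimulusClip", function(x) x@frameRate)
#' @rdname accessors
#' @export
setMethod("pixelPitch", "StimulusClip", function(x) x@pixelPitch)
#' @rdname accessors
#' @export
setMethod("meanIntensity", "StimulusClip", function(x) x@meanIntensity)
#' @rdname accessors
#' @export
setMethod("events", "StimulusClip", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("nFrames", "StimulusClip", function(x) dim(x@frames)[1])
#' @rdname accessors
#' @export
setMethod("duration", "StimulusClip", function(x) dim(x@frames)[1] / x@frameRate)

setMethod("show", "StimulusClip", function(object) {
  d <- dim(object@frames)
  cat(sprintf("StimulusClip '%s': %d frames of %d x %d px (%.0f x %.0f um), %g Hz\n",
              object@stimClass, d[1], d[2], d[3],
              d[2] * object@pixelPitch, d[3] * object@pixelPitch,
              object@frameRate))
  cat(sprintf("  mean intensity %.3g; %d event(s)\n",
              object@meanIntensity, nrow(object@events)))
})

#' EpochedTrace: a uniformly sampled (or spike-time) response trace
#'
#' Response of a simulated or recorded cell, annotated with the epoch table of
#' the stimulus that elicited it and a baseline window used for
#' baseline-subtracted amplitude measures.  For `modality = "spike_times_s"`,
#' `samples` holds strictly increasing spike times in seconds rather than a
#' uniformly sampled signal.
#'
#' @slot samples numeric vector: the signal (or spike times).
#' @slot rate sampling rate in Hz (10 kHz default; ignored for spike times).
#' @slot modality one of `voltage_mV`, `current_pA`, `conductance_nS`,
#'   `spike_rate_Hz`, `spike_times_s`.
#' @slot baselineWindow `(start_s, end_s)` of the baseline epoch.
#' @slot events epoch table copied from the stimulus.
#' @slot duration_s trace duration in seconds (needed for spike-time traces).
#' @export
setClass("EpochedTrace",
  representation(
    samples = "numeric",
    rate = "numeric",
    modality = "character",
    baselineWindow = "numeric",
    events = "data.frame",
    duration_s = "numeric"
  ),
  prototype(rate = 1e4, modality = "voltage_mV",
            baselineWindow = c(0, 0), duration_s = 0,
            events = data.frame(label = character(), start_s = numeric(),
                                end_s = numeric()))
)

.modalities <- c("voltage_mV", "current_pA", "conductance_nS",
                 "spike_rate_Hz", "spike_times_s")

setValidity("EpochedTrace", function(object) {
  msg <- character()
  if (!(object@modality %in% .modalities))
    msg <- c(msg, paste("modality must be one of:",
                        paste(.modalities, collapse = ", ")))
  if (object@rate <= 0) msg <- c(msg, "rate must be positive")
  dur <- if (object@modality == "spike_times_s") object@duration_s
         else length(object@samples) / object@rate
  bw <- object@baselineWindow
  if (length(bw) != 2 || bw[1] > bw[2] || bw[1] < -1e-9 || bw[2] > dur + 1e-9)
    msg <- c(msg, "baselineWindow must lie inside the trace")
  if (object@modality == "spike_times_s" &&
      length(object@samples) > 1 &&
      any(diff(object@samples) <= 0))
    msg <- c(msg, "spike times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("traceSamples", "EpochedTrace", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("traceRate", "EpochedTrace", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("modality", "EpochedTrace", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("baselineWindow", "EpochedTrace", function(x) x@baselineWindow)
#' @rdname accessors
#' @export
setMethod("events", "EpochedTrace", function(x) x@events)
#' @rdname accessors
#' @export
setMethod("duration", "EpochedTrace", function(x) {
  if (x@modality == "spike_times_s") x@duration_s
  else length(x@samples) / x@rate
})

setMethod("show", "EpochedTrace", function(object) {
  if (object@modality == "spike_times_s")
    cat(sprintf("EpochedTrace [%s]: %d spikes over %.3g s\n",
                object@modality, length(object@samples), duration(object)))
  else
    cat(sprintf("EpochedTrace [%s]: %d samples at %g Hz (%.3g s)\n",
                object@modality, length(object@samples), object@rate,
                duration(object)))
  cat(sprintf("  baseline [%.3g, %.3g] s; %d event(s)\n",
              object@baselineWindow[1], object@baselineWindow[2],
              nrow(object@events)))
})

#' Constructor for [EpochedTrace-class]
#'
#' @param samples numeric samples (or spike times for `spike_times_s`).
#' @param rate sampling rate, Hz.
#' @param modality signal modality string.
#' @param baselineWindow `(start_s, end_s)` baseline epoch.
#' @param events epoch table (`label`, `start_s`, `end_s`).
#' @param duration_s total duration (required for spike-time traces).
#' @return an [EpochedTrace-class].
#' @export
epochedTrace <- function(samples, rate = 1e4, modality = "voltage_mV",
                         baselineWindow = c(0, 0),
                         events = data.frame(label = character(),
                                             start_s = numeric(),
                                             end_s = numeric()),
                         duration_s = length(samples) / rate) {
  new("EpochedTrace", samples = as.numeric(samples), rate = rate,
      modality = modality, baselineWindow = as.numeric(baselineWindow),
      events = events, duration_s = duration_s)
}

#' AreaResponseCurve: ON/OFF response amplitude vs spot radius
#'
#' Signed ON and OFF response amplitudes measured at a series of spot radii
#' (the spatial sensitivity profile fitted by [fitDoG()] / [fitGaussian()]).
#'
#' @slot radii spot radii, micrometres, strictly increasing (>= 5 for fitting).
#' @slot onAmp,offAmp signed amplitudes per radius.
#' @slot modality response modality the amplitudes were measured from.
#' @export
setClass("AreaResponseCurve",
  representation(radii = "numeric", onAmp = "numeric", offAmp = "numeric",
                 modality = "character"),
  prototype(modality = "voltage_mV")
)

setValidity("AreaResponseCurve", function(object) {
  msg <- character()
  if (is.unsorted(object@radii, strictly = TRUE))
    msg <- c(msg, "radii must be strictly increasing")
  if (length(object@onAmp) != length(object@radii) ||
      length(object@offAmp) != length(object@radii))
    msg <- c(msg, "one ON and one OFF amplitude per radius required")
  if (length(msg)) msg else TRUE
})

#' Constructor for [AreaResponseCurve-class]
#'
#' @param radii,onAmp,offAmp,modality see [AreaResponseCurve-class].
#' @return an [AreaResponseCurve-class].
#' @export
areaResponseCurve <- function(radii, onAmp, offAmp = onAmp,
                              modality = "voltage_mV") {
  new("AreaResponseCurve", radii = as.numeric(radii),
      onAmp = as.numeric(onAmp), offAmp = as.numeric(offAmp),
      modality = modality)
}

setMethod("show", "AreaResponseCurve", function(object) {
  cat(sprintf("AreaResponseCurve [%s]: %d radii from %g to %g um\n",
              object@modality, length(object@radii), min(object@radii),
              max(object@radii)))
})

#' DoGFit: disc-integrated Difference-of-Gaussians fit of an area-response curve
#'
#' Parameters of the model
#' \deqn{R(r) = k_c (1 - e^{-r^2 / 2\sigma_c^2}) - k_s (1 - e^{-r^2/2\sigma_s^2})}
#' fitted to response amplitude vs spot radius, or its single-Gaussian
#' restriction (`model = "gaussian"`, `kSurround = 0`).
#'
#' @slot kCenter,kSurround non-negative amplitudes of the center/surround terms.
#' @slot sigmaCenter,sigmaSurround Gaussian SDs in micrometres
#'   (surround > center for the DoG model).
#' @slot rss residual sum of squares of the fit.
#' @slot model `"dog"` or `"gaussian"`.
#' @slot polarity `"on"` or `"off"`.
#' @slot radii,fitted the fitted curve (for plotting/diagnostics).
#' @export
setClass("DoGFit",
  representation(
    kCenter = "numeric", kSurround = "numeric",
    sigmaCenter = "numeric", sigmaSurround = "numeric",
    rss = "numeric", model = "character", polarity = "character",
    radii = "numeric", fitted = "numeric"
  ),
  prototype(model = "dog", polarity = "on", kSurround = 0,
            sigmaSurround = Inf)
)

setValidity("DoGFit", function(object) {
  msg <- character()
  if (object@sigmaCenter <= 0) msg <- c(msg, "sigmaCenter must be > 0")
  if (object@model == "dog" && object@sigmaSurround <= object@sigmaCenter)
    msg <- c(msg, "sigmaSurround must exceed sigmaCenter")
  if (object@kCenter < 0 || object@kSurround < 0)
    msg <- c(msg, "amplitudes must be non-negative")
  if (!(object@model %in% c("dog", "gaussian")))
    msg <- c(msg, "model must be 'dog' or 'gaussian'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DoGFit", function(object) {
  cat(sprintf("DoGFit (%s, %s): k_c=%.4g sigma_c=%.4g um", object@model,
              object@polarity, object@kCenter, object@sigmaCenter))
  if (object@model == "dog")
    cat(sprintf("  k_s=%.4g sigma_s=%.4g um", object@kSurround,
                object@sigmaSurround))
  cat(sprintf("  (rss %.4g)\n", object@rss))
})

#' FilterPair: ON and OFF temporal filters recovered from white noise
#'
#' Linear temporal filters on the stimulus refresh time base, lag 0 being the
#' frame simultaneous with the response and increasing lag reaching further
#' into the past.  Both filters are scaled by one common factor so that
#' `sum(on) + sum(off)` equals the sum of the global response-weighted
#' stimulus average (the scaling contract; recorded in `scaleChecksum`).
#'
#' @slot onFilter,offFilter numeric filters over lag frames (equal length).
#' @slot refreshHz stimulus refresh rate, Hz.
#' @slot globalAverage the global response-weighted stimulus average.
#' @slot scaleChecksum `sum(onFilter) + sum(offFilter)`.
#' @export
setClass("FilterPair",
  representation(
    onFilter = "numeric", offFilter = "numeric", refreshHz = "numeric",
    globalAverage = "numeric", scaleChecksum = "numeric"
  )
)

setValidity("FilterPair", function(object) {
  msg <- character()
  if (length(object@onFilter) != length(object@offFilter))
    msg <- c(msg, "ON and OFF filters must have equal length")
  if (object@refreshHz <= 0) msg <- c(msg, "refreshHz must be positive")
  chk <- sum(object@onFilter) + sum(object@offFilter)
  if (!isTRUE(all.equal(chk, object@scaleChecksum, tolerance = 1e-8)))
    msg <- c(msg, "scaleChecksum does not match sum(on)+sum(off)")
  if (length(object@globalAverage) &&
      abs(chk - sum(object@globalAverage)) >
        1e-8 * max(1, abs(sum(object@globalAverage))))
    msg <- c(msg, "scaling contract violated: sum(on)+sum(off) != sum(global average)")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("onFilter", "FilterPair", function(x) x@onFilter)
#' @rdname accessors
#' @export
setMethod("offFilter", "FilterPair", function(x) x@offFilter)
#' @rdname accessors
#' @export
setMethod("frameRate", "FilterPair", function(x) x@refreshHz)

setMethod("show", "FilterPair", function(object) {
  cat(sprintf("FilterPair: %d lags at %g Hz (%.3g s support)\n",
              length(object@onFilter), object@refreshHz,
              length(object@onFilter) / object@refreshHz))
})

#' PointMosaic: a 2D soma mosaic in a rectangular region
#'
#' @slot points n x 2 matrix of (x, y) positions in micrometres.
#' @slot region named numeric `(xmin, xmax, ymin, ymax)` in micrometres.
#' @export
setClass("PointMosaic",
  representation(points = "matrix", region = "numeric")
)

setValidity("PointMosaic", function(object) {
  msg <- character()
  r <- object@region
  if (length(r) != 4 || r[2] <= r[1] || r[4] <= r[3])
    msg <- c(msg, "region must be (xmin, xmax, ymin, ymax) with positive extent")
  p <- object@points
  if (ncol(p) != 2) msg <- c(msg, "points must be an n x 2 matrix")
  else if (nrow(p) > 0 &&
           (any(p[, 1] < r[1] - 1e-9) || any(p[, 1] > r[2] + 1e-9) ||
            any(p[, 2] < r[3] - 1e-9) || any(p[, 2] > r[4] + 1e-9)))
    msg <- c(msg, "all points must lie inside the region")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("mosaicPoints", "PointMosaic", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("mosaicDensity", "PointMosaic", function(x) {
  r <- x@region
  area_mm2 <- (r[2] - r[1]) * (r[4] - r[3]) / 1e6
  nrow(x@points) / area_mm2
})

setMethod("show", "PointMosaic", function(object) {
  r <- object@region
  cat(sprintf("PointMosaic: %d points in %.0f x %.0f um (%.0f points/mm^2)\n",
              nrow(object@points), r[2] - r[1], r[4] - r[3],
              mosaicDensity(object)))
})

#' DRProfile: density recovery profile of a point mosaic
#'
#' Neighbor density as a function of distance around each point, with the
#' effective radius of the central exclusion zone derived from the density
#' deficit of the contiguous central dip (see [drp()]).
#'
#' @slot binEdges annulus edges, micrometres.
#' @slot annulusDensity points/mm^2 per annulus.
#' @slot meanDensity overall mosaic density, points/mm^2.
#' @slot effectiveRadius micrometres.
#' @export
setClass("DRProfile",
  representation(binEdges = "numeric", annulusDensity = "numeric",
                 meanDensity = "numeric", effectiveRadius = "numeric")
)

setValidity("DRProfile", function(object) {
  msg <- character()
  if (length(object@annulusDensity) != length(object@binEdges) - 1)
    msg <- c(msg, "annulusDensity must have one value per bin")
  if (any(object@annulusDensity < 0)) msg <- c(msg, "densities must be >= 0")
  if (object@effectiveRadius < 0) msg <- c(msg, "effectiveRadius must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("effectiveRadius", "DRProfile", function(x) x@effectiveRadius)

setMethod("show", "DRProfile", function(object) {
  cat(sprintf("DRProfile: %d bins to %.0f um; mean density %.0f /mm^2; effective radius %.2f um\n",
              length(object@annulusDensity), max(object@binEdges),
              object@meanDensity, object@effectiveRadius))
})

#' NeuriteScene: a 3D neurite mask with synaptic puncta
#'
#' Binary voxel mask of neurites plus puncta centroids in physical
#' (micrometre) coordinates, with anisotropic voxel size and the z-range of
#' the synaptic layer used for Monte Carlo randomization.  Voxel `(i, j, k)`
#' of the mask is centered at `((i - 0.5) vx, (j - 0.5) vy, (k - 0.5) vz)`.
#'
#' @slot mask 3D logical array `(x, y, z)`.
#' @slot voxelSize `(vx, vy, vz)` micrometres.
#' @slot puncta n x 3 matrix of centroid positions, micrometres.
#' @slot layerBounds z-range `(zmin, zmax)` of the synaptic layer, micrometres.
#' @export
setClass("NeuriteScene",
  representation(mask = "array", voxelSize = "numeric",
                 puncta = "matrix", layerBounds = "numeric")
)

setValidity("NeuriteScene", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3 || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3D logical array")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive values")
  if (ncol(object@puncta) != 3)
    msg <- c(msg, "puncta must be an n x 3 matrix")
  else {
    ext <- dim(object@mask) * object@voxelSize
    p <- object@puncta
    if (nrow(p) > 0 && (any(p < -1e-9) || any(sweep(p, 2, ext) > 1e-9)))
      msg <- c(msg, "puncta must lie within the imaged volume")
  }
  if (length(object@layerBounds) != 2 ||
      object@layerBounds[1] >= object@layerBounds[2])
    msg <- c(msg, "layerBounds must be (zmin, zmax) with zmin < zmax")
  if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("puncta", "NeuriteScene", function(x) x@puncta)
#' @rdname accessors
#' @export
setMethod("voxelSize", "NeuriteScene", function(x) x@voxelSize)

setMethod("show", "NeuriteScene", function(object) {
  d <- dim(object@mask)
  cat(sprintf("NeuriteScene: %d x %d x %d voxels (%.2f x %.2f x %.2f um), %d puncta\n",
              d[1], d[2], d[3], d[1] * object@voxelSize[1],
              d[2] * object@voxelSize[2], d[3] * object@voxelSize[3],
              nrow(object@puncta)))
  cat(sprintf("  %.3g%% of voxels in mask; synaptic layer z = [%.2f, %.2f] um\n",
              100 * mean(object@mask), object@layerBounds[1],
              object@layerBounds[2]))
})
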
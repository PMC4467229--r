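## Receptive-field estimation from area-response (spot-size) curves:
## disc-integrated Difference-of-Gaussians and single-Gaussian fits, 1-SD
## diameters, and population coverage.

#' Forward area-response models
#'
#' Predicted response to a spot of radius `r` under the disc-integrated
#' (cumulative) Difference-of-Gaussians model
#' \deqn{R(r) = k_c (1 - e^{-r^2/2\sigma_c^2}) - k_s (1 - e^{-r^2/2\sigma_s^2})}
#' (`form = "integrated"`; the natural model when the abscissa is spot radius)
#' or the point-spread form
#' \eqn{R(r) = k_c e^{-r^2/2\sigma_c^2} - k_s e^{-r^2/2\sigma_s^2}}.
#' With `kS = 0` both reduce to the single-Gaussian model used for inhibition.
#'
#' @param r spot radii, micrometres.
#' @param kC,sigmaC center amplitude and SD (um).
#' @param kS,sigmaS surround amplitude and SD (um).
#' @param form `"integrated"` (default) or `"point"`.
#' @return predicted responses at `r`.
#' @export
dogAreaResponse <- function(r, kC, sigmaC, kS = 0, sigmaS = Inf,
                            form = c("integrated", "point")) {
  form <- match.arg(form)
  if (form == "integrated")
    kC * (1 - exp(-r^2 / (2 * sigmaC^2))) - kS * (1 - exp(-r^2 / (2 * sigmaS^2)))
  else
    kC * exp(-r^2 / (2 * sigmaC^2)) - kS * exp(-r^2 / (2 * sigmaS^2))
}

## One bounded Levenberg-Marquardt start; surround SD parametrized as
## sigmaC + dSigma to keep sigmaS > sigmaC.  Returns NULL on failure.
.dogFitOnce <- function(r, y, start, fixSurround, form) {
  resid <- function(p) {
    if (fixSurround)
      y - dogAreaResponse(r, p[1], p[2], form = form)
    else
      y - dogAreaResponse(r, p[1], p[3], p[2], p[3] + p[4], form = form)
  }
  lower <- if (fixSurround) c(0, 1) else c(0, 0, 1, 0.5)
  upper <- if (fixSurround) c(Inf, 2000) else c(Inf, Inf, 2000, 5000)
  out <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  list(par = out$par, rss = sum(out$fvec^2), info = out$info)
}

.fitAreaModel <- function(radii, amp, model, polarity, form) {
  .assert(length(radii) >= 5, "at least 5 radii required for fitting")
  .assert(stats::sd(amp) > 0, "degenerate curve: all amplitudes equal")
  scale <- max(abs(amp))
  fixSurround <- model == "gaussian"
  sigmaCGrid <- c(15, 30, 60)
  sigmaSGrid <- c(75, 150, 300)
  starts <- if (fixSurround) {
    lapply(c(sigmaCGrid, sigmaSGrid), function(sc) c(scale, sc))
  } else {
    do.call(c, lapply(sigmaCGrid, function(sc)
      lapply(sigmaSGrid, function(ss)
        c(1.5 * scale, 0.75 * scale, sc, max(ss - sc, 1)))))
  }
  fits <- Filter(Negate(is.null),
                 lapply(starts, .dogFitOnce, r = radii, y = amp,
                        fixSurround = fixSurround, form = form))
  if (!length(fits))
    stop(sprintf(
      "area-response fit failed to converge from all %d starts (model=%s, polarity=%s, n=%d radii)",
      length(starts), model, polarity, length(radii)), call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
  p <- best$par
  if (fixSurround)
    new("DoGFit", kCenter = p[1], kSurround = 0, sigmaCenter = p[2],
        sigmaSurround = Inf, rss = best$rss, model = "gaussian",
        polarity = polarity, radii = radii,
        fitted = dogAreaResponse(radii, p[1], p[2], form = form))
  else
    new("DoGFit", kCenter = p[1], kSurround = p[2], sigmaCenter = p[3],
        sigmaSurround = p[3] + p[4], rss = best$rss, model = "dog",
        polarity = polarity, radii = radii,
        fitted = dogAreaResponse(radii, p[1], p[3], p[2], p[3] + p[4],
                                 form = form))
}

#' Fit a Difference-of-Gaussians model to an area-response curve
#'
#' Bounded multi-start Levenberg-Marquardt least squares of the
#' disc-integrated DoG model (see [dogAreaResponse()]); the start grid covers
#' center SDs of 15/30/60 um crossed with surround SDs of 75/150/300 um.
#' Voltage and excitation curves take the DoG; inhibition, which rises
#' monotonically with spot size, takes the nested single-Gaussian model
#' ([fitGaussian()]).
#'
#' @param curve an [AreaResponseCurve-class].
#' @param polarity `"on"` or `"off"` — which amplitude column to fit.
#' @param form `"integrated"` (default) or `"point"`; see [dogAreaResponse()].
#' @return a [DoGFit-class].
#' @export
fitDoG <- function(curve, polarity = c("on", "off"),
                   form = c("integrated", "point")) {
  polarity <- match.arg(polarity)
  form <- match.arg(form)
  amp <- if (polarity == "on") curve@onAmp else curve@offAmp
  .fitAreaModel(curve@radii, amp, "dog", polarity, form)
}

#' @rdname fitDoG
#' @export
fitGaussian <- function(curve, polarity = c("on", "off"),
                        form = c("integrated", "point")) {
  polarity <- match.arg(polarity)
  form <- match.arg(form)
  amp <- if (polarity == "on") curve@onAmp else curve@offAmp
  .fitAreaModel(curve@radii, amp, "gaussian", polarity, form)
}

#' Receptive-field diameter at 1 SD
#'
#' Diameter of the fitted center or surround Gaussian at 1 SD, i.e.
#' `2 * sigma`.
#'
#' @param fit a [DoGFit-class].
#' @param component `"center"` or `"surround"`.
#' @return diameter in micrometres.
#' @export
rfDiameter <- function(fit, component = c("center", "surround")) {
  component <- match.arg(component)
  .assert(!(component == "surround" && fit@model == "gaussian"),
          "a single-Gaussian fit has no surround component")
  2 * if (component == "center") fit@sigmaCenter else fit@sigmaSurround
}

#' Population coverage factor
#'
#' `density x territory`, the number of times a cell population tiles the
#' retina (898 cells/mm^2 x 7662 um^2 gives 6.88).
#'
#' @param density_mm2 cell density, cells per mm^2.
#' @param territory_um2 single-cell territory, um^2.
#' @return unitless coverage factor.
#' @export
coverageFactor <- function(density_mm2, territory_um2) {
  .assert(density_mm2 > 0 && territory_um2 > 0,
          "density and territory must be positive")
  density_mm2 * territory_um2 / 1e6
}

#' Measure an area-response curve from simulated spot responses
#'
#' Peak baseline-subtracted amplitudes within each ON and each OFF epoch
#' (averaged over modulation periods) of one response trace per spot radius.
#'
#' @param traces list of [EpochedTrace-class], one per radius, with `on`/`off`
#'   epochs in their event tables.
#' @param radii spot radii (um), parallel to `traces`; must be sorted.
#' @param modality stored in the returned curve (taken from the first trace
#'   when `NULL`).
#' @param windowLength,lag_s passed to [segmentAmplitude()].
#' @return an [AreaResponseCurve-class].
#' @export
measureAreaResponse <- function(traces, radii, modality = NULL,
                                windowLength = 0.15, lag_s = 0.2) {
  .assert(length(traces) == length(radii), "one trace per radius required")
  if (is.null(modality)) modality <- modality(traces[[1]])
  epochMean <- function(tr, lab) {
    ev <- events(tr)
    ev <- ev[ev$label == lab, , drop = FALSE]
    .assert(nrow(ev) > 0, "trace lacks '%s' epochs", lab)
    mean(vapply(seq_len(nrow(ev)), function(i)
      segmentAmplitude(tr, ev$start_s[i], ev$end_s[i],
                       windowLength = windowLength, lag_s = lag_s),
      numeric(1)))
  }
  areaResponseCurve(
    radii,
    onAmp = vapply(traces, epochMean, numeric(1), lab = "on"),
    offAmp = vapply(traces, epochMean, numeric(1), lab = "off"),
    modality = modality)
}
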
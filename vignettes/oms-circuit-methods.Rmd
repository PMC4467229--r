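---
title: "Modeling and measuring object motion sensitivity in the inner retina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and measuring object motion sensitivity in the inner retina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(omsretina)
```

This vignette explains the science implemented by `omsretina`: the
rectified-subunit circuit model of the VG3 amacrine cell / W3 ganglion cell
object-motion pathway, the stimulus battery it is probed with, the analysis
methods applied to the simulated (or any compatible) recordings, and the
anatomical statistics.  It also records the design choices made where the
underlying experimental literature leaves the implementation open.

## The scientific problem

W3 retinal ganglion cells — the most abundant ganglion cell type in the mouse
retina — spike selectively for small moving objects: they respond when a
textured patch over their receptive-field center moves at a different time
than the background, and they fall silent during global image motion, such as
that produced by eye movements.  VG3 amacrine cells are glutamatergic
interneurons presynaptic to W3 cells that already express this selectivity in
their graded membrane potential.  Three receptive-field mechanisms jointly
produce it:

1. **Rectified subunits.**  Excitation is carried by transient ON and OFF
   bipolar cells, each pooling a small region (~25 µm scale) and releasing
   transmitter only for its preferred contrast sign.  Rectification before
   spatial summation makes the cell sensitive to pattern motion even when the
   mean luminance over its receptive field never changes — the signature is a
   frequency-doubled (F2-dominant) response to counterphase or evenly split
   stimuli.
2. **Center–surround antagonism.**  Spot responses grow with stimulus size up
   to the excitatory center (1-SD diameters of order 40–140 µm, OFF smaller
   than ON) and are suppressed beyond it.
3. **Spiking wide-field inhibition.**  Surround suppression is carried by
   spiking (TTX-sensitive) wide-field amacrine cells driven by the same kind
   of rectified subunits.  Inhibition acts both presynaptically — on bipolar
   terminals, before release rectification — and postsynaptically as a
   conductance.

The package provides a synthetic but mechanistically faithful version of this
circuit so that every analysis stage of an object-motion study (receptive
field fitting, harmonic analysis, motion/size/speed tuning, temporal-filter
recovery, mosaic and apposition statistics) can be exercised end to end with
known ground truth.

## The circuit model

`circuitParams()` collects every tunable constant.  The signal path of
`simulateVG3()` is:

* **Stimulus contrast.** A `StimulusClip` holds intensities in [0, 1] with
  mean 0.5; contrast is intensity minus mean.
* **Bipolar subunit lattices** (`bipolarLayer()`).  Two lattices (ON, OFF) of
  subunits spaced 25 µm apart pool contrast with a Gaussian of σ = 12.5 µm,
  convolve it with a temporal kernel, and half-wave rectify.  The OFF lattice
  uses sign-inverted contrast, its own kernel, and a gain of 1.5 relative to
  ON (OFF responses exceed ON responses throughout this circuit).  The
  spacing/σ defaults put the transition of the surround's F2 response between
  25-µm and 50-µm counterphase bars, where it is observed.  A diagnostic
  switch (`rectifySubunits = FALSE`) makes the subunits linear; it exists to
  demonstrate that frequency doubling requires rectification.
* **Temporal kernels.**  `biphasicKernel()` builds difference-of-gamma-lobe
  kernels on the 30-Hz stimulus refresh base (15 taps = 500 ms, peak ~80 ms).
  The circuit defaults are *DC-balanced* (the kernel integrates to zero): the
  cells are fully transient and static patterns produce no sustained drive,
  which keeps pre-motion baselines clean.  The ON kernel rebounds faster than
  the OFF kernel, making ON filters more biphasic.
* **Wide-field inhibition** (`wideFieldAC()`).  A lattice of spiking
  wide-field units (50 µm spacing) each takes a local Gaussian-weighted
  (σ = 75 µm) mean of subunit activity in the *surround* — subunits within
  `wacInnerRadius` (150 µm, matching the texture-stimulus center) are
  excluded — and fires only above a hard threshold.  The cell-level
  inhibitory drive is the Gaussian-weighted mean of unit outputs, with the
  weight σ's tied to the measured 1-SD inhibition diameters (ON 258 µm → 129,
  OFF 148.2 µm → 74.1).  A *population* of locally thresholded units, rather
  than one globally pooled unit, is essential: a single global pool dilutes
  the activity of one moving edge ~50-fold relative to full-surround motion
  and cannot produce both texture-surround suppression and the suppression of
  tall-bar edge responses.  `ttx = TRUE` silences the population, mimicking
  bath-applied tetrodotoxin.
* **VG3 conductances and voltage.**  Excitation is the center-Gaussian pool
  of subunit activity (σ from the 1-SD excitation diameters: ON 137 µm →
  68.5, OFF 83.1 µm → 41.5) minus presynaptic inhibition
  (`presynWeight` × wide-field drive), floored at zero; postsynaptic
  inhibition is a conductance (`inhGain` × drive).  Voltage is the
  quasi-static mix of leak (resting −38 mV), excitatory (0 mV) and inhibitory
  (−60 mV) conductances relaxed by a first-order membrane filter
  (τ = 20 ms).  EPSCs and IPSCs are computed at the standard holding
  potentials (−60 mV and 0 mV) with additive, seeded Gaussian conductance
  noise (SD 0.05 nS).
* **W3 ganglion cell** (`simulateW3()`).  Excitation is the sum of (i)
  thresholded VG3 glutamate release (rectified voltage above −38 mV,
  0.7 nS/mV), delayed by 10 ms, weighted `w3Vg3Weight` (0.5), and (ii) a
  direct bipolar center pool weighted `w3DirectWeight` (0.5).  The release
  gain is calibrated so the two arms contribute comparably during
  differential center motion, making the VG3 arm carry approximately half of
  the peak excitation — `vglut3Ko = TRUE` zeroes that arm.  Spikes are an
  inhomogeneous Poisson process on the rectified net drive with a 2-ms
  absolute refractory period.
* **Rates.**  The front end runs on the stimulus frame base (30 Hz default),
  conductances are upsampled to a 1-kHz simulation grid, and output traces
  are resampled to 10 kHz, the standard acquisition rate.

### What the generator emulates — and what it does not

The generator reproduces, qualitatively and with the measured spatial scales:
OFF-dominant transient ON–OFF responses; center–surround antagonism with the
published 1-SD diameters entering as pooling σ's; F2-dominant responses to
even split fields and counterphase gratings; depolarization confined to
differential center motion with hyperpolarization for global and
differential-surround motion; abolition of all surround suppression by TTX;
edge responses across 100–800 µm/s that are suppressed for bars taller than
~200 µm; and the ~50% VG3 share of W3 excitation removed by the knockout.

It does **not** model: biophysically detailed membranes or dendrites (one
point per cell); direction selectivity (the model is isotropic by
construction, matching the measured absence of direction selectivity);
adaptation, photoreceptor dynamics or photon noise; pattern-dependent spatial
correlations in the noise (noise is additive white Gaussian on conductances);
or the detailed tuning of W3 *currents* — in the model W3's direct bipolar
pool is not itself surround-suppressed (only the spike generator sees
inhibition), so W3 EPSC motion selectivity is weaker than the recorded one
while W3 *spiking* selectivity is preserved.  Passing tests therefore
demonstrate the correctness of the analysis chain and the qualitative circuit
logic, not quantitative agreement with any particular recorded cell.

## The stimulus battery

All generators return `StimulusClip` objects (frames in [0, 1], event table
with every epoch used downstream).  Defaults: 800 × 800 µm field, 4 µm/pixel,
30 Hz — fine enough that the 12.5-µm subunits are well sampled while a full
battery simulates in seconds; all three are arguments.  The battery covers
spots of varying radius (square-wave modulated, 2 s ON / 2 s OFF, 96%
Michelson contrast, pseudorandom order with the first stimulus repeated at
the end as a stability check), split fields (anti-phase sinusoids, 2 Hz; the
area bias is a parameter), counterphase annulus gratings (bar widths 25/50
µm), differential texture motion (50-µm square-wave gratings over center and
surround separated by a 25-µm gray annulus; `global`, `diff_center`,
`diff_surround` segments), moving bars (width 800 µm along the motion axis,
heights 50–600 µm across it, speeds 100–800 µm/s, dark or light), drifting
sine gratings (eight directions, 2 Hz) and Gaussian white noise (uniform disc
or annulus, 30 Hz refresh, 40% RMS contrast, 10 min; values clipped to [0, 1]
with the clipped fraction logged in `params$clipFraction`).

Two timing conventions for spots coexist in the source literature (0.125 Hz
square-wave modulation vs 2 s ON / 2 s OFF); the package defaults to 2 s ON /
2 s OFF and exposes `period_s`.

Luminance neutrality is enforced *by construction*: split fields and
counterphase annuli cancel exactly by mirror symmetry (bar-boundary pixel
columns are left unmodulated; a bar wider than the annulus is treated as a
single region), and texture/drifting gratings are balanced to zero mean over
each region per frame, since partial grating periods inside a disc or annulus
would otherwise modulate the mean by a few percent.  Texture gratings default
to 90% contrast so the balancing offset never clips.  The moving-bar "height"
is the extent *perpendicular* to motion — that is the dimension that controls
how much wide-field surround an edge recruits — while the 800-µm width lies
along the motion axis, so the trailing edge crosses the center `width/speed`
seconds after the leading edge.

## Analysis methods

* **Epoch amplitudes** (`epochAmplitude()`, `segmentAmplitude()`):
  baseline-subtracted means in 100–200 ms windows (default 150 ms).  Within a
  stimulus segment the window is placed at the response peak (largest
  |baseline-subtracted mean|, signed), searched over the segment plus a 300-ms
  latency allowance.  The baseline is the last 0.5 s of the pre-stimulus
  lead-in, clear of any clip-onset transient.  Hyperpolarizations and
  suppressions are negative.  Edge-response windows are centered on the
  center-crossing times from the stimulus event table plus a configurable
  latency (default 50 ms).
* **Conductance extraction** (`currentToConductance()`):
  `g = I / (V_hold − E_rev)`; EPSCs recorded at the inhibitory reversal
  (−60 mV), IPSCs at the excitatory reversal (0 mV).
* **Harmonics** (`harmonicAmplitudes()`): discrete Fourier amplitudes at the
  stimulus frequency (F1) and its double (F2), after truncating to whole
  fundamental periods (the discarded tail is reported) and removing the mean.
  A pure tone `A sin` has F1 = A; a half-wave-rectified unit sine has
  F1 = 1/2 and F2 = 2/(3π); the sum of two anti-phase half-wave-rectified
  sines (= |sin|) has F1 = 0 and F2 = 4/(3π).  Squared amplitudes are
  returned alongside for users who work in power.
* **Tuning** (`motionSelectivity()`, `sizeTuning()`, `speedTuning()`,
  `dsi()`): per-segment signed amplitudes; the size-suppression index is
  `1 − amp(600)/amp(200)` on leading-edge responses; the direction
  selectivity index is `|Σ F1(θ) e^{iθ}| / Σ F1(θ)`.
* **Receptive fields** (`fitDoG()`, `fitGaussian()`): area-response curves
  are fit with the *disc-integrated* Difference-of-Gaussians
  `R(r) = k_c (1 − e^{−r²/2σ_c²}) − k_s (1 − e^{−r²/2σ_s²})` — the natural
  form when the abscissa is spot radius — by bounded Levenberg–Marquardt
  least squares from a 3 × 3 multi-start grid (σ_c ∈ {15, 30, 60} µm,
  σ_s ∈ {75, 150, 300} µm), with the surround parametrized as
  σ_s = σ_c + Δσ, Δσ ≥ 0.5 µm, so the surround always exceeds the center.
  The point-spread form is available behind `form = "point"`.  Inhibition,
  which rises monotonically with spot size, takes the nested single-Gaussian
  model.  Receptive-field diameters are reported at 1 SD (`2σ`).
  `coverageFactor()` is density × territory with the mm²→µm² conversion.
* **Temporal filters** (`responseWeightedEnsemble()`, `splitOnOff()`):
  responses are binned to stimulus frames, baseline-subtracted, and used to
  weight the preceding 15-frame stimulus window (overlapping windows, lag 0 =
  simultaneous frame).  The first principal component of the weighted windows
  is computed on mean-centered windows ("the dimension of highest variance";
  `center = FALSE` gives the raw-second-moment variant), windows are split by
  the sign of their raw projection (positive = ON), group averages form the
  two filters, and both are rescaled by one common factor so that
  `sum(on) + sum(off)` equals the sum of the global response-weighted
  average.  The rescaling is applied before the ON/OFF labels are assigned,
  because a negative common factor would otherwise flip already-labeled
  filters.  For a purely linear cell all windows project to one side, so the
  method returns one kernel-shaped filter and one empty one.  Filters
  recovered from simulated *voltage* converge to the kernel as smoothed by
  the membrane chain; `effectiveKernel()` computes that ground truth, and
  conductance traces (where the chain is nearly the identity) recover the raw
  kernels.  Metrics: peak time (lag of the dominant extremum), biphasic index
  (ON: |trough|/peak; OFF: peak/|trough|), and one-sided Fourier amplitude
  spectra.
* **Anatomy** (`simulateMosaic()`, `drp()`, `territoryArea()`,
  `appositionFraction()`, `randomizedNull()`): soma mosaics are
  sequential-inhibition (RSA) hard-core processes; the density recovery
  profile uses 5-µm annuli by default with a border-buffer edge correction
  (only points ≥ max radius from the border serve as reference points — an
  unbiased and simpler alternative to exact annulus–rectangle intersection
  areas).  The effective exclusion radius converts the density deficit of the
  contiguous central dip into the radius of an equivalent fully empty disc:
  `r_eff = sqrt(Σ_dip (D̄ − D_b)·A_b / (π D̄))`, which recovers a perfect
  hard core exactly.  Neurite territories are convex-hull areas of
  z-projected arbors.  Apposition fractions use exact anisotropic Euclidean
  distances from puncta to the nearest mask voxel (voxel size defaults
  0.103/0.103/0.3 µm; threshold 0.5 µm, sweep 0.25–1 µm).  The Monte Carlo
  null repositions puncta uniformly in the synaptic-layer slab; to keep the
  comparison exchangeable it classifies both observed and null puncta on a
  precomputed voxel-lattice dilation (within half a voxel of the exact rule),
  and reports `p = P(null ≥ observed)`.

## Numerical choices and degenerate inputs

Windows are `[start, end)` half-open on the sample grid with samples at
`(i − ½)/rate`.  Harmonic analysis errors below one fundamental period.
Fits error with diagnostics if no start converges; degenerate (constant)
curves, all-zero response weights, identical ensemble windows, all-zero DSI
inputs, empty puncta sets and collinear territories all raise explicit
errors; an empty neurite mask yields fraction 0 with a warning.  All
stochastic stages (noise, spikes, mosaics, nulls, presentation order) are
seeded; `childSeed()` fans a master seed out to named stages so any stage can
be rerun in isolation.  Clip round trips through RDS are bit-exact; the
conductance/current conversion inverts to one floating-point rounding.

## Problem sizes

The test-suite and acceptance computations use the standard geometry (800-µm
field at 4 µm/pixel, 30 Hz), 10-minute white-noise runs (18,000 frames) for
filter recovery, 1-mm² mosaics (~900 somata) with 20 seeds for the density
recovery profiles, and 12 × 12 × 6 µm confocal-scale scenes with 100–200
puncta, 199–999 Monte Carlo iterations and 200 scenes for the apposition
calibration — sizes at which every stage completes in seconds on one core
while estimator variance stays well inside the asserted tolerances.

## Known limitations

The wide-field inhibition model, while biologically motivated, compresses a
diverse population of spiking amacrine cells into one thresholded lattice
with a hard inner exclusion radius; real surround inhibition tapers smoothly
into the center.  The W3 EPSC tuning caveat above applies.  The texture
stimulus drifts smoothly at constant speed; jittering trajectories are not
modeled.  The DoG fits assume radially symmetric receptive fields centered on
the soma.  Filter recovery degrades gracefully but measurably when ON and
OFF kernels are near mirror images and the response is a compressive
function of the conductances (voltage recordings); conductance inputs are
preferred for kernel-level ground-truth comparisons.
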
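---
title: "Quantifying motor-driven protein clearance on DNA curtains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motor-driven protein clearance on DNA curtains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoclear)
```

## The measurement

In a single-stranded DNA curtain experiment, long ssDNA molecules are
tethered at one end (the 5' biotin at a chromium barrier) and, for
double-tethered imaging, at a pedestal 13 µm downstream. The molecule is
uniformly coated with a fluorescent ssDNA-binding protein (RPA-GFP, the
"green" channel). A translocating motor protein loads at an internal site
and strips the coating protein as it moves 3'→5'. The growing
protein-free gap is visualized either by a complementary fluorescent oligo
that hybridizes into the gap (Atto647N, "magenta" channel, RPA assay) or by
influx of a low concentration of RPA-GFP into gaps cut into an unlabelled
RAD51 filament (green gain, RAD51 assay).

For every molecule and frame, the pixel rows spanning the molecule
(3 rows, matching the diffraction-limited width) are summed into a 1-D
intensity profile, background-subtracted using rows ≥ 5 px outside the
molecule, and the gap signal is fit with either a Gaussian or a two-edge
step ("Heaviside" boxcar) model. The full width at half maximum (FWHM) of
the fit, converted to nucleotides, measures the cleared extent; its growth
over time gives the motor's **velocity** (nt/s) and its terminal plateau
the **processivity** (knt). Population summaries are the median and
interquartile range (linear-interpolation quartiles), the conventional
statistics for these strongly right-skewed single-molecule distributions.

## From fitted FWHM to cleared extent

The cleared region is a top-hat in coverage, observed through a Gaussian
PSF (σ ≈ 1.3 px, so a diffraction-limited spot spans ~3 px). The FWHM of a
Gaussian fit to such a blurred top-hat is a *biased* reading of the top-hat
width: sub-resolution gaps are inflated toward the diffraction limit
(~3 px), while wide top-hats are under-read by about 14% because the
Gaussian's tails cannot follow sharp edges. Quadrature subtraction of the
PSF FWHM over-corrects mid-width gaps. Because the forward operator
(true width → fitted FWHM, given the PSF and the fit model) is fully
deterministic, `extent_calibration()` tabulates it on noiseless synthetic
profiles and inverts it; `build_trace()` reports both the raw fitted FWHM
and the calibrated extent. The calibration puts the Gaussian and Heaviside
estimators on the same physical scale, which is why the two can be
substituted without changing downstream population medians (checked to
within 15% in the test suite).

## Segmenting the active phase

`segment_active_phase()` fits a flat–rising–flat piecewise-linear model to
extent-versus-time by exhaustive search over changepoint pairs on the frame
grid, followed by continuous refinement (motors start and stop between
camera exposures). Three less-obvious choices matter at realistic
signal-to-noise (≈ 5 per profile column at the RPA condition):

* **Pre-detection frames are censored observations, not gaps.** A gap
  smaller than the detection limit produces no converged fit, so leading
  "missing" frames actually constrain the extent from above. The detection
  limit is computed per molecule from the amplitude gate (3× residual SD)
  and the blurred-top-hat amplitude response, and the model is penalized
  wherever it predicts a detectable extent at a dark frame. The leading
  plateau is anchored at zero extent — physically, nothing is cleared
  before the motor starts.
* **Resolution-limited rises are lower bounds.** When the first detected
  frame is already at the plateau (no detected sample sits significantly
  below it before it is reached, and the plateau is reached within ≤ 2
  frames of the last dark frame), the rise completed between exposures.
  The velocity is then reported as plateau/elapsed-dark-gap — a lower
  bound, flagged as such — rather than a noise-fit slope.
* **Flicker plateaus are unmeasurable.** If the plateau is within ~2× the
  detection limit, the whole trace rides the detection boundary and any
  apparent rise is indistinguishable from flicker; the velocity is
  reported as missing. Processivity (a plateau mean) is still reported.

Velocity is the ramp slope of the segmented fit; processivity is the mean
calibrated extent over the terminal plateau. Motors still translocating at
the movie end are right-censored: their last extent is a lower bound on
processivity, and such events are excluded from processivity medians but
retained for velocity (velocity is not an endpoint quantity). Shortening a
movie can therefore only lower, never raise, a processivity median.

Polarity is classified from the two gap edges (Heaviside edges, or
center ± extent/2 for the Gaussian model): the early-rise edge positions
are compared with the terminal-plateau positions, an edge "moves" when its
displacement exceeds 2 standard errors, and the moving edge must dominate
(≥ 75% of the total displacement). Barrier-side-only movement is 3'→5'.
Motors whose rise is entirely sub-frame carry no directional information
and are reported ambiguous.

## What the simulator emulates

`render_kymograph()` is a forward model of the assay: per frame, green
coverage is the coated fraction of each pixel (1 − union of motor-cleared
intervals, merged so overlapping motors are never double-counted)
attenuated by single-exponential photobleaching; magenta coverage is the
cleared-interval indicator (oligo hybridization is effectively
instantaneous behind the motor). Each channel is gain × coverage spread
across rows and convolved along columns with the Gaussian PSF, plus a
constant background, Poisson shot noise, and Gaussian read noise — the
standard EMCCD approximation. In `rad51` mode the green channel carries
the gap signal instead and is not bleach-attenuated, because the reporting
RPA exchanges with the solution pool; the green gain is 3× the RPA-assay
value in the packaged presets, mirroring the ~3× stronger 488-nm
excitation used for that assay (40 mW versus 14 mW).

Motor velocities and processivities are log-normal, parameterized by the
population median and IQR. With the median pinned
(`meanlog = log(median)`), a two-parameter log-normal cannot match both
quartiles of an asymmetric IQR exactly, so the scale parameter is solved
(numerically, from the quartile function) to match the interquartile
*range*; the empirical quartiles of large draws reproduce the configured
median to ~1% and the IQR width to a few percent. Initiation positions are
uniform along the molecule, and the cleared interval is clipped at the 5'
tether. By default draws are *stratified*: each variable's quantiles are
balanced (then independently permuted), which leaves the marginal
distributions unchanged but removes most of the sampling noise in the
empirical median — at N ≈ 50–90 and these dispersions the drawn median
would otherwise wander by ±20–25% between seeds, swamping any estimate of
pipeline bias. Plain i.i.d. draws remain available (`stratified = FALSE`).

Default geometry: 25 knt of coated ssDNA spanning 13 µm (122 px), i.e.
~0.5 nm per nucleotide — the extension of protein-coated ssDNA under
flow — giving ~205 nt/px; 15-s frames; PSF σ 1.3 px; gain 120 photons per
unit coverage per column, background 50, read noise 5 (profile SNR ≈ 5).
The standard recovery simulations use 80 frames (RPA condition, 91
molecules, ~1 min of compute) and 150 frames (RAD51 condition, 53
molecules; longer movies keep censoring of the slow motors below ~5%).

Features of real data the simulator does **not** emulate: stage drift,
molecule-to-molecule length heterogeneity beyond the configured length,
transverse molecule motion, RAD51 filament dynamics, motor pausing
(each motor moves at constant velocity until its drawn processivity is
exhausted — per-molecule pause statistics are not represented), and
non-uniform illumination. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated noise model, not robustness
to every instrumental artifact.

## Foci, intensity, tracking, binding

* `detect_foci()` finds local maxima above 5 robust (MAD-based) SDs with
  3-px non-maximum suppression (ties toward the lower column). The 5σ
  default keeps the Monte-Carlo false-positive rate well under one focus
  per molecule; counts are reported per µm (or per knt) of tethered length.
  Counts scale linearly with planted density until spot separation
  approaches twice the PSF width, where they saturate.
* `intensity_trace()` integrates the background-subtracted ROI per frame,
  divides by tethered length (correcting length heterogeneity), and
  normalizes to a reference frame; condition aggregation is mean ± SEM
  across molecules, never across frames.
* `focus_intensity_3x3()` is the 3×3-pixel average minus background used
  for single-focus brightness comparisons.
* `tether_lifetime()` wraps a Kaplan–Meier estimate (via the survival
  package) of bridge persistence after a challenge, right-censored at the
  movie end; the bridged/unbridged call per frame is an input annotation.
* `link_foci()` links foci frame-to-frame by accepting candidate links in
  global distance order (each focus used once, links capped at
  `max_disp_px` per frame, gaps up to `max_gap_frames` re-joined), a
  nearest-neighbour scheme whose default displacement cap should be ~2×
  the expected per-frame motion.
* `fit_hyperbolic()` fits the one-site isotherm f = Bmax·[P]/(Kd+[P]) to
  replicate means, Bmax free. The fit is unweighted by default: with three
  replicates the per-point SEM estimates are noisy enough that 1/SEM²
  weighting inflates the Kd variance by ~60% (SEM weighting remains
  available as an option).
  When the lower 95% bound on Kd exceeds the highest tested concentration
  the fit reports "Kd > bound" instead of a point estimate — the honest
  statement for a titration that never approaches saturation. No Hill
  coefficient and no ligand-depletion correction are offered; the input is
  assumed to be a classical gel-shift titration with trace labelled DNA.

## Numerical notes and limitations

* Profile fits never throw on data: failures and sub-threshold amplitudes
  return `converged = FALSE` and propagate as missing frames; traces with
  more than half their frames missing are flagged unusable.
* A fitted Gaussian wider than 90% of its fit window is rejected as a
  baseline artifact; isolated single-frame detections more than 2 frames
  before the first sustained run are pruned as noise blips (single-frame
  gaps at onset are kept — detection flicker at the limit is real signal).
* After two consecutive failed fits the adaptive window (recentered on the
  previous center, width max(21 px, 3× previous FWHM)) resets to the full
  molecule, so a spurious detection cannot capture the tracker.
* The velocity median of a 91-molecule RPA-condition simulation at profile
  SNR 5 still varies by roughly ±10% between seeds — individual rises span
  only ~4 frames — whereas the processivity median is stable to ~±5%.
  Tolerances in the recovery tests (±15% and ±20%) reflect that.
* Quartiles use R's default type-7 (linear interpolation) convention.
* The titration design with a true Kd near the top tested concentration
  (e.g. 390 nM versus a 512 nM maximum) is weakly identified by
  construction; roughly half of such fits land above 370 nM and a subset
  are censored outright. The *median* reported value across seeds tracks
  the true value; an individual fit should be read through its reported
  confidence bound.
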
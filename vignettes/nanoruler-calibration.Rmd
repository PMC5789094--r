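---
title: "Methods: traceable nanoruler distance calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: traceable nanoruler distance calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement and its model

A DNA origami nanoruler places two fluorescent marks — each a small grid of
DNA-PAINT docking sites — at a designed separation. A localization
microscope measures the 2D projection of the centre-to-centre distance.
`nanocal` treats one ruler's projected distance as

\[ a_{proj} = P\,\bigl(d + \textstyle\sum_j \delta d_j\bigr), \]

where \(P\) is the object-space pixel size (nm/pixel), \(d\) the fitted
distance in pixels, and the \(\delta d_j\) are corrections with expectation
zero but finite standard uncertainty: per-structure fit error
(\(\delta d_{fit,k}\), random), residual imperfection of the fit model
(\(\delta d_{model}\)), simultaneous-emitter merging driven by the blinking
kinetics (\(\delta d_{blink}\)), environmental influences such as salt and
temperature-driven drift (\(\delta d_{env}\)), and false-positive structure
picking (\(\delta d_{fp}\)) — the last four systematic. For the ensemble
mean over \(n\) structures, first-order propagation with independent inputs
gives

\[ u^2(a_{proj}) = u^2(P)\,\bigl(d + \textstyle\sum_j \delta d_j\bigr)^2
   + P^2\bigl(u^2(d) + \textstyle\sum_j u^2(\delta d_j)\bigr), \]

random contributions carrying an extra \(1/\sqrt{n}\). The expanded
uncertainty is \(U = k\,u\) with \(k = 2\) (a ~95 % coverage interval), the
convention throughout. Because the correction expectations are zero, the
sensitivity of the pixel-size term is the mean distance itself; `nanocal`
therefore uses \(\bar d\) in that product. Corrections and their
uncertainties are carried in pixel units and contributions reported in nm;
contributions are displayed at two decimals and \(U\) at one, but every
combination uses unrounded values.

Out of scope by design: correlated input quantities,
effective-degrees-of-freedom coverage calculus, 3D distances, and any
correction of field distortion (it enters as an uncertainty instead, see
below).

## What the simulator emulates

`sim_config()` fixes the study conditions; `generate_nanoruler_field()`
produces localization tables with per-localization ground-truth labels.

* **Kinetics.** Each docking site is an independent two-state renewal
  process with exponential dark and bright dwells (means `t_off`, `t_on`).
  Defaults `t_on = 0.5 s`, `t_off = 500 s` give a duty cycle just below
  \(10^{-3}\) — transient imager binding, not photophysics, so no
  photobleaching is modelled.
* **Camera.** `frame_time = 0.1 s`, `n_frames = 12000` (a typical 20-minute
  acquisition). A site ON for a fraction \(f\) of a frame yields
  `Poisson(photons_per_frame * f)` photons (default mean 5000); frames
  below `min_photons = 50` are discarded, mirroring the detection threshold
  of localization software.
* **Localization noise.** Isotropic Gaussian with
  \(\sigma = \sigma_{PSF}/\sqrt{N}\) (`sigma_psf = 130 nm`), the simplest
  model consistent with photon-limited localization; background and
  pixelation excess noise are deliberately omitted (the config leaves room
  for a background hook).
* **Merging.** Emitters simultaneously ON and closer than `merge_radius`
  (default \(2.5\,\sigma_{PSF}\), a diffraction-limited footprint) are
  detected as one event at their photon-weighted centroid. This is the
  mechanism that shortens distances at high `t_on/t_off`:
  `estimate_blink_bias()` sweeps that ratio with all else fixed and scales
  the acquisition length so the expected binding events per site stay
  constant — the merging probability depends on the duty cycle, not on how
  long one records.
* **Marks and labeling.** Each mark is a 3 × 3 site grid at 3 nm pitch
  (the inter-helix spacing of the origami; nine protrusions per mark), each
  site present with probability `site_activity_prob = 0.8`. The designed
  distance follows from 0.34 nm per nucleotide along the helix and 3 nm
  across helices (`design_distance()`).
* **Inhomogeneous broadening.** Per-ruler true distances are drawn from
  `Normal(true_distance_mean, true_distance_sd)`; `sd = 0` isolates the
  purely statistical scatter of the pipeline, nonzero `sd` adds in
  variance, which the test suite verifies as
  \(SD^2 \approx sd^2 + SD_0^2\).
* **Placement.** Rulers sit on a shuffled jittered grid (cell
  `2 * min_spacing`, jitter `±min_spacing/2`) rather than pure uniform
  rejection sampling: the minimum spacing is guaranteed deterministically
  and per-ruler seed substreams (fixed offsets from the master seed) keep
  existing rulers identical when `n_rulers` grows. Orientations are
  uniform.

Not emulated: EMCCD gain/readout noise, raw-movie rendering, dye
photophysics beyond the two-state kinetics, axial (z) structure, spectral
cross-talk. Passing tests therefore demonstrate the *analysis chain* under
controlled statistics, not camera-level realism.

## Structure picking

`cluster_localizations()` is a DBSCAN (grid-bucketed, neighbourhood radius
`radius_nm`, core threshold `min_neighbors` including the point itself).
The default radius is 1.5 × the nominal distance so both marks of one
ruler join a single cluster. Border points join their *nearest* core
neighbour, which makes the partition independent of row order. The filter
cascade runs in a fixed order — localization count, radius of gyration,
bimodality, field edge — and records the first failure; the bimodality
statistic is the ratio of the two principal variances (default threshold
3), standing in for the unpublished "looks like a nanoruler" rules of
commercial software. A second, stricter configuration models manual
picking: `estimate_fp_uncertainty()` reports the absolute difference of
the two arms' ensemble means as the standard-uncertainty surrogate for
picking bias; true interactive picking is out of scope.

## Distance fitting

`fit_two_marks()` projects a candidate's localizations onto the principal
axis (2D second moments) and fits a two-component equal-variance Gaussian
mixture to the 1D projections by EM. This 1D projection fit is the
package's documented distance model, kept behind one interface so a
different model (e.g. a full 2D mixture) can replace it without touching
the pipeline. Numerical choices:

* EM runs in log space (stable even for point-mass clouds), starts from
  the 25 %/75 % projection quantiles, iterates to a relative log-likelihood
  change below \(10^{-12}\) (max 500 iterations), and floors \(\sigma\) at
  \(10^{-6}\) nm;
* components are ordered \(\mu_1 < \mu_2\) and the axis angle reported in
  \([0, \pi)\) — the tie-break that makes results unique under rotation;
* \(u_{fit}\) comes from the observed-information matrix of the mixture
  likelihood (numerical Hessian over \(\mu_1, \mu_2, \log\sigma,
  \mathrm{logit}\,\pi\)); if that matrix is not invertible (degenerate,
  e.g. noise-free clouds) a moment-based fallback
  \(\sigma\sqrt{1/n_1 + 1/n_2}\) is used;
* localizations farther than \(3\sigma\) from both components are removed
  once and the fit repeated — this also strips cross-mark merged events,
  which sit near the midpoint;
* clouds that collapse to a point, or fits that do not converge, return a
  failure marker and are excluded from the ensemble.

`ensemble_stats()` reports mean, SD (0 with a flag for a single
structure), SE = SD/√n, and a histogram on half-open bins with the left
edge at 0 (default 2 nm).

## Pixel-size calibration

`generate_micrometre_image()` renders a grating of wide dark lines
(nominal 10 µm pitch) with Gaussian edge blur, optional noise, and an
optional linear magnification gradient. `locate_lines()` averages a row
band into a profile and takes each line centre as the midpoint of the two
half-depth edge crossings (linear interpolation on the flanks). A 3-point
parabola through the valley minimum was considered and rejected: these
lines are many blur-widths wide, the valley bottom is flat, and a parabola
there is ill-posed — the crossing midpoint is the standard practice for
wide, weakly defined lines.

`calibrate_pixel_size()` computes per-interval pixel sizes
\(P_i = L_{ref,i}/\Delta c_i\) and reports their mean with three
uncertainty components combined in quadrature: (a) the reference pitches
(expanded \(U(k{=}2)\) values halved to standard, independent across
intervals, averaged), (b) the scatter of the \(P_i\) taken at *full* value
as the field-variation/distortion term — distortion is deliberately not
corrected, it does not average out — and (c) the line-location
uncertainty propagated from the profile noise. The small correlation
between adjacent intervals sharing a centre is neglected in (c).

## Registration and benchmarks

The green-to-red channel map is the six-coefficient linear transform
\(x_r = a x_g + b y_g + c\), \(y_r = d x_g + e y_g + f\): exactly solved
for three non-collinear beads, least squares for more (the overdetermined
behaviour is this package's choice). The correlation image is the
element-wise product of equally 10 nm-binned channel images built from
localization *counts* (not 8-bit rendered intensities — a dialect choice);
the correlation density sums it over non-overlapping 1.6 × 1.6 µm² tiles
anchored at the origin (partial edge tiles dropped), normalizes to the
maximum, and uses the coefficient of variation of the tile sums as the
uniformity statistic. The counting-noise reference for that CV is computed
in the tests by randomly placing the per-structure correlation masses over
the tiles; a mis-registration announces itself as a gradient of the tile
map.

Drift correction is a windowed structure-residual tracker: each clustered
structure's localizations are referenced to their mark centres
(deterministic 1D two-means along the principal axis), and the pooled mean
residual per window (default 500 frames) gives the drift at the window
midpoint, linearly interpolated between midpoints and linearly
extrapolated beyond the outermost ones. Tracking residuals instead of raw
centroids matters for blinking structures, whose bursts come from single
marks half a separation off-centre; because drift-smeared anchors shrink a
single pass slightly, the estimate-correct cycle iterates (three times or
until the update is below 0.05 nm), which also makes the correction
idempotent. Window length trades bias against noise: short windows follow
fast drift but carry more counting noise. Fiducial-marker tracking is the
experimental alternative; this scheme is the package's substitute and is
labelled as such.

`cross_section_fwhm()` samples a rendered image along a segment with
perpendicular averaging, detects peaks above background (prominence
fraction 0.3, minimum separation 10 nm), fits one Gaussian
(amplitude, centre, \(\sigma\), offset) per peak by Nelder–Mead least
squares, and reports \(FWHM = 2\sqrt{2\ln 2}\,\sigma\) from the fitted
\(\sigma\), not from half-maximum crossings.

## Problem sizes and tolerances in the shipped tests

The test suite sizes its simulations for statistical resolution:
1000 rulers for the precision-recovery check (mean within ±0.5 nm of
truth), 400 rulers per point of a five-point `t_on/t_off` grid spanning
\(10^{-4}\)–\(10^{-1}\) (monotonicity within two combined standard
errors), 400 rulers per arm for the variance-addition check (±3 standard
errors of a variance difference), 240 rulers for the two-color
correlation-density field, five rulers over a simulated six-hour
drift-free acquisition for the sub-20 nm spot-width benchmark, and
20 000-sample Monte-Carlo oracles for the uncertainty propagation. Exact
contracts (the worked budget, transform recovery, unit identities) are
tested at printed precision or \(10^{-9}\).

## Known limitations

* The equal-variance 1D mixture is a stand-in for more elaborate distance
  models; strongly unequal mark intensities or bent rulers violate its
  assumptions (the fit-model imperfection is exactly what the
  \(\delta d_{model}\) budget term absorbs).
* The localization-precision model has no background term, so simulated
  precisions are optimistic at low photon counts.
* The picking-bias estimate depends on the chosen pair of configurations;
  it is a surrogate, not a bound.
* Drift correction assumes stationary structures and lateral drift only.
* All distances are 2D projections; tilt and bending shorten them relative
  to the design, which is a property of the measurand, not an error of the
  pipeline.
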
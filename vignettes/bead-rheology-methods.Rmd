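---
title: "Passive bead rheology on multiwell plates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive bead rheology on multiwell plates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadRheo)
```

# The measurement

Fibronectin-coated fluorescent microbeads (2 µm) bound to the surface of
adherent cells move under thermal and motor-driven forces. Imaged at
video rate (33 fps for 60 s per field of view), each bead's trajectory
yields a time-averaged mean squared displacement (MSD) curve,

$$\mathrm{msd}(\tau_k) = \frac{1}{n-k}\sum_{i=1}^{n-k}
  \lVert \mathbf{r}_{i+k} - \mathbf{r}_i \rVert^2 ,
  \qquad \tau_k = k\,\Delta t,$$

whose magnitude at a reference lag (τ = 1 s here) is a relative measure
of the compliance of the cell cortex under the bead: softer, more
invasive cells let their beads wander farther. beadRheo implements the
full in-silico counterpart of such a screen — generators for every raw
input, tracking, audit-preserving video compression, MSD model
selection, AFM cross-validation, and plate-stratified statistics — so
that each analysis stage can be validated against known ground truth.

# Motion models and their generators

Four canonical bead behaviours are modelled, each with an explicit
generator and an MSD form used for fitting (all MSDs include a noise
offset $c$ so that localization error cannot masquerade as confinement):

| model | behaviour | generator | MSD form |
|---|---|---|---|
| N  | stuck bead (elastic) | fixed point + i.i.d. jitter | $c$ |
| D  | free Brownian | Gaussian increments, $\sigma^2 = 2D\Delta t$ per axis | $4D\tau + c$ |
| DR | confined | reflected Brownian motion in a square corral of side $L$ | $L_f^2(1-e^{-4D\tau/L_f^2}) + c$ |
| DA | anomalous subdiffusion | fractional Brownian motion, $H=\alpha/2$ | $4D_\alpha\tau^\alpha + c$ |

The DA generator is exact: per axis, fractional Gaussian noise is drawn
by Cholesky factorization of its Toeplitz covariance (the factor is
cached per $(\alpha, n, \Delta t)$, so large ensembles cost one
factorization plus matrix products). The physical origin of anomalous
bead motion on cells is not modelled — fBm is a standard stand-in with
the right second-order statistics, nothing more. Two caveats on the DR
model: reflection in a square corral is the simplest confinement
mechanism with an MSD plateau (the plateau of the generator is $L^2/3$,
while the fitted $L_f^2$ is the plateau itself, so $L_f$ is an effective
confinement scale, not the corral side); and no active-motor force model
is included anywhere.

Localization noise is added post hoc, i.i.d. Gaussian per coordinate
(default 20 nm, matching the centroid precision of a bright bead;
the plate power study below uses 10 nm, see its section). Rendering
draws each bead as a 2-D Gaussian (default σ = 2 px, a 2 µm bead at
0.25 µm/px through a reduced-NA 0.45 objective) on a constant
background (100 counts) with Gaussian read noise (2 counts, 16-bit);
there is no photobleaching, no shot noise, no motion blur, and no
optics-accurate (Airy/aberration) PSF. Passing tests therefore
demonstrate correctness of the analysis chain under this image model,
not robustness to every artefact of real video.

# Autofocus and calibration

The liquid-lens objectives focus by electrowetting: the plane of focus
does not move until the drive exceeds 30 V RMS and then approaches the
objective monotonically, with a small magnification change. Calibration
tables (voltage → focal displacement, voltage → µm/px) are interpolated
linearly, return the zero-voltage value exactly at or below 30 V, and
refuse to extrapolate. Because the lens is hysteretic, focus must
always be approached from the low-voltage side; `selectFocus()`
documents this contract and the simulated acquisition loop enforces
ascending-voltage traversal.

The autofocus score is `(q0.995 − median) / median` of the frame — the
brightest-spot-over-background statistic that a sparse bead field
maximizes at focus. The exact metric used on the original instrument is
not published; this form is a documented stand-in, validated against
rendered through-focus stacks (≥ 95% correct slice at default noise). A
stack whose best score does not stand above the bulk of slice scores
(by 5 robust sds) has no focal plane and is an error, so all-noise
stacks are rejected rather than silently "focused".

Pixel scale is estimated from 100 commanded 3 µm stage steps in random
directions (`knownStep / mean(|displacement|)`), optionally refined by a
corner-to-corner span; per-channel calibration curves are replaced by
their mean only when the cross-channel spread is below 5%.

# Tracking

Spots are strict-ish local maxima (8-neighbourhood, plateau-tolerant
because integer quantization ties peak pixels) above
`background + 5σ`, refined by an intensity-weighted centroid in a
window of radius 3σ_psf. The noise scale σ is the sd of pixels below
the 99.5th percentile — the MAD is not used because on integer-rounded
counts it collapses to 1.48 regardless of the true noise. Linking is
greedy nearest-neighbour with a per-frame displacement cap, no gap
closing (a conservative choice that keeps MSD lags honest), ties broken
toward the lower spot index, and tracks shorter than half the video
discarded by default. Round-trip accuracy (simulate → render → track)
is ≤ 0.15 px RMSE at default noise; the residual tracker noise (~0.01
px ≈ 2.5 nm) is far below the 10–20 nm localization noise the
generators model.

# Audit-preserving compression

Raw plate runs produce terabytes of video while the trajectories
themselves are tiny; the archive keeps just enough pixels to *re-track*.
Motion regions are pixels whose temporal standard deviation exceeds 5×
the noise floor (median of the sd map); connected components are
dilated by a margin (default 24 px = 3 bead diameters, so centroid
windows never touch reconstructed pixels) and overlapping boxes merged.
Each ROI's pixel stream is stored losslessly — byte-plane-separated
16-bit little-endian raw, gzip-compressed — with an md5 checksum of the
uncompressed stream; everything outside the ROIs is replaced by the
per-pixel temporal mean rounded to the source bit depth. The design
contract is bit-exact reconstruction inside ROIs (checksum-verified),
not any particular codec.

Two consequences are tested rather than assumed: tracking the
reconstruction with the same absolute detection threshold reproduces
raw-video positions exactly (the threshold estimated from a
reconstruction would differ, because its background is noiseless — the
archive therefore records the source noise floor in its metadata); and
on the sparse default field (three beads in 512×512 px × 1980 frames)
the archive is ≥ 99% smaller than the raw stack. The ratio is driven by
ROI area and by the entropy of the read noise (~3 bits/pixel here), so
denser fields or noisier cameras compress less; the ratio is monotone
non-increasing in total ROI area.

# Bayesian trajectory classification

Beads stuck to the substrate (N) or diffusing freely in the medium (D)
carry no information about the cell and must be removed; analysis is
restricted to trajectories classified anomalous (DA) with posterior
above 0.5. All four models are fit to each MSD curve and compared by an
evidence approximation, posterior ∝ exp(−BIC/2) under equal priors,
ties toward the simpler model.

Two statistical properties of time-averaged MSDs shape the likelihood
the BIC is built on. First, adjacent lags of an overlapping-window MSD
are strongly correlated; a likelihood that treats all lags as
independent overcounts information by orders of magnitude and always
prefers the most flexible model. The classifier therefore evaluates
fits on an octave-spaced lag subset (1, 2, 4, … frames up to 25% of the
track), which approximately decorrelates residuals. Second, the
sampling variance of the estimator grows with lag,
$\mathrm{Var}[\mathrm{msd}_k] \approx \mathrm{msd}_k^2\,4k/(3n)$, so
the likelihood is a generalized-least-squares χ² with these variances
(pair-count weights would overweight the long, noisy lags). The
evidence is then $\chi^2 + k_{\mathrm{par}}\log n_{\mathrm{frames}}$.
With well-separated populations (1980-frame tracks at default noise)
this selects the true model in ≈ 100% of cases for all four classes.
Because DR and DA nest the Brownian model, a correct posterior for a
true-D track is often 0.7–0.9 rather than ≈ 1 — genuine
χ²(1)-sized fit improvements of the richer models keep a calibrated
posterior away from certainty; the selection itself is what the
pipeline relies on.

Parameter *estimation* (as opposed to selection) uses the same
calibrated weighting: the anomalous exponent from the classifier's DA
fit recovers α ∈ {0.3, 0.5, 0.8} with median error ≤ 0.04 on single
1980-frame tracks, whereas the naive pair-count fit errs by 0.1–0.25.
`fitMotionModel()` retains the conventional pair-count weighting as its
default (exact on noiseless curves; appropriate when the caller
supplies its own curve and weights). Nonlinear fits (DR, DA) are
profile-linear: for a fixed confinement time or exponent the remaining
parameters are linear (with non-negativity enforced by boundary
refits), and the 1-D profile is minimized by golden-section search over
a wide bounded range (α ∈ (0.01, 1.4], letting Brownian tracks land at
α ≈ 1 where the simpler D model then wins). This is deterministic and
cannot fail to converge.

Whether the τ = 1 s summaries should pool displacements or use per-bead
curves is ambiguous in general; per-bead medians are used (each bead
contributes one MSD value at the lag nearest τ, within Δt/2), with the
RMS displacement reported as $\sqrt{\mathrm{median\ MSD}}$ in nm.

# The viscosity benchmark

As an absolute sanity check, the full simulate → render → track → MSD
chain is run on freely diffusing 200 nm beads in "water" (η = 0.932
mPa·s at 23 °C, D = k_BT/6πηr = 2.33 µm²/s) at 50 ms frame intervals.
The ensemble MSD (pooled across beads, pair-count-weighted) is fit with
$4D\tau + c$ using only lags up to 2% of the track — long lags of a
time-averaged MSD carry little independent information and would
inflate the estimator variance — and inverted through Stokes–Einstein.
Twelve tracked beads (six 256×256 px videos of 600 frames) recover η
within a few percent, comfortably inside the 10% acceptance band; the
study size was chosen so the Monte-Carlo error of the estimate sits
well below that band. Motion blur during exposure is not modelled; at
these displacement-per-frame levels (≈ 2 px) blur would bias short-lag
MSDs slightly low in real data.

# AFM force curves

The AFM branch analyses approach curves of a 5 µm beaded cantilever
(R = 2.5 µm, nominal k = 0.02 N/m, trigger 1 nN on-nucleus / 0.5 nN
off-nucleus): force from Hooke's law F = kΔd, indentation
δ = Δz_piezo − Δd, and the spherical Hertz model

$$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},
  \qquad \nu = 0.5,$$

which is linear in E given δ. The contact point is found by exhaustive
scan: every sample index is tried as the breakpoint of a piecewise
(free line before, Hertz after) fit, residuals of both segments are
combined in force units with equal per-sample weight, and the minimum
total RMS wins. The pre-contact line has free slope and intercept to
capture drift. Two guards reject curves that never touch the cell: a
minimum at either end of the scan range, and a best piecewise fit that
is not at least 5% better than a single global line. Retract segments
are not analysed, and no thin-sample (bottom-effect) or viscoelastic
corrections are applied. Compliance is reported as 1000/E (kPa⁻¹ for E
in Pa): E = 500 Pa ↔ 2 kPa⁻¹, E = 250 Pa ↔ 4 kPa⁻¹. Batch reduction is
median-of-medians: curves → cell, cells → group, so cells are the
experimental unit entering the rank statistics.

On noiseless synthetic curves the contact index is recovered within ±1
sample and E to relative 1e-6; at 0.02 nN force noise the contact
height is recovered within a few nm (median) and E with < 2% median
bias over 100 curves.

# Stratified statistics

Plate screens are blocked: each objective/camera pair (stratum) views
every condition, so comparisons must respect strata. Van Elteren's test
combines per-stratum Wilcoxon rank-sum statistics,

$$T \;=\; \frac{\sum_s w_s\,(W_s - \mathrm{E}[W_s])}
  {\sqrt{\sum_s w_s^2\,\mathrm{Var}[W_s]}},
  \qquad w_s = \frac{1}{n_{As}+n_{Bs}+1},$$

with tie-corrected variances, referred two-sided to the normal
distribution. Strata missing a group are dropped with a warning. With a
single stratum the function delegates to the plain rank-sum test, so
the reduction is exact to machine precision; with several strata no
continuity correction is applied (bead-level n is large; the null
rejection rate at α = 0.05 is 0.049 over 10⁴ simulated plates). The
rank-sum test itself uses the exact null distribution for small untied
samples (both n ≤ 10) and the tie- and continuity-corrected normal
approximation otherwise. Family-wise error is controlled by Bonferroni
over the comparisons actually made — by default each condition against
the control, per assay, with the family size recorded in the output —
and significance is star-coded at 0.05/0.01/0.001. Two-sided tests
throughout.

# The in-silico plate experiment

`runExperiment()` chains everything deterministically from one seed:
balanced layout (every condition under every stratum; the plate is
traversed in 8 steps of 12 wells, the step count being configurable
because different descriptions of the instrument give 7 or 8), Poisson
bead counts (mean 3/FOV), per-bead MSD, classification, DA filter
(threshold 0.5), τ = 1 s summaries, van Elteren vs control, Bonferroni,
star table, and a manifest carrying the seed, versions and parameters.
Optionally each FOV is rendered to video and re-tracked
(`render = TRUE`), exercising the imaging path end to end.

The power study mirrors a two-condition screen at the compliance scale
of interest: control-like beads at a measured median MSD(1 s) of
2.9×10⁻³ µm² (RMS 54 nm) versus 4.9×10⁻³ µm² (RMS 70 nm), i.e. a
built-in ~30% RMS gap, at ~480 beads per condition across 8 strata
(16 wells × 10 FOV × Poisson(3) per condition). Generator parameters:
α = 0.5, D_α = 6.25×10⁻⁴ and 1.125×10⁻³ µm²/s^α, localization noise 10
nm per coordinate — 10 nm (not the 20 nm default) because a screen's
static-bead noise floor (RMS 20 nm) must sit well below the control
signal for the DA filter to retain the population, and indeed > 99% of
trajectories are then retained as DA with confined selections below 1%.
Across seeded repeats the van Elteren comparison rejects at
p_adj < 0.001 in every run, with the realized median RMS ratio at the
designed 1.30. Twelve repeats are used in the automated suite; the
failure criterion (≥ 95% of repeats) then demands 12/12.

# Numerical choices and degenerate inputs

* MSD requires uniform sampling (consecutive frame gaps equal) and at
  least 2 frames; model fits need ≥ 5 lags; classification subsets to
  octave lags only when ≥ 16 lags are available.
* Exact fits (RSS → 0) are handled by flooring the χ² at a tiny value;
  a fully degenerate all-zero curve ties all models and the tie rule
  returns the simplest (N).
* All non-negativity constraints (D, L², D_α, c ≥ 0) are enforced by
  boundary refits rather than clipping, so the reported RSS always
  belongs to the reported parameters.
* Static videos produce zero ROIs; whole-frame motion degenerates to a
  single full-frame ROI (logged). Zero-noise videos make the noise
  floor 0 and any temporal variation an ROI.
* Seeds: every generator takes an explicit seed (or inherits the
  caller's RNG state when seed = NULL); seeded runs are bit-identical,
  including rendered pixels.
* Simulation-study sizes in the automated tests (60 tracks per model
  and per exponent, 12 plate repeats, 2000-replicate null calibration,
  six-video viscosity benchmark) were chosen once so that Monte-Carlo
  error is small against each test's acceptance band.

# Known limitations

* The image model omits shot noise, bleaching, blur, aberrations and
  cell autofluorescence; compression ratios and tracking accuracy on
  real video will differ.
* fBm is a phenomenological stand-in for anomalous bead motion; no
  active/passive decomposition (e.g. ATP-depletion contrast) is
  attempted, and MSDs are not converted to absolute moduli
  G*(ω) — the pipeline reports *relative* compliance only.
* Greedy linking without gap closing splits tracks at missed
  detections and cannot resolve crossing beads; dense fields need a
  multi-hypothesis tracker.
* The evidence approximation ignores residual correlation between
  octave-spaced lags; posteriors are approximately, not exactly,
  calibrated (selection accuracy, not posterior sharpness, is the
  validated quantity).
* Hertz analysis assumes an elastic half-space: no bottom-effect
  correction for thin lamellae, no viscoelastic model, approach curves
  only.
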
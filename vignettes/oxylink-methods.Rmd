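---
title: "Frequency-specific effective connectivity from fNIRS signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-specific effective connectivity from fNIRS signals: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxylink)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics through source-detector optode pairs on the scalp. The
concentration signals carry oscillations of distinct physiological
origin, conventionally separated into four frequency intervals:

| band | range (Hz)   | attributed origin |
|------|--------------|-------------------|
| I    | 0.6–2        | cardiac           |
| II   | 0.145–0.6    | respiratory       |
| III  | 0.052–0.145  | myogenic          |
| IV   | 0.021–0.052  | neurogenic        |

`oxylink` estimates *effective* (directed) connectivity between
channels — and, aggregated, between six cortical regions (left/right
prefrontal, motor, occipital) — separately per interval, by modelling
each channel pair as two coupled phase oscillators and inferring the
coupling terms of their phase dynamics. Undirected correlation methods
cannot distinguish "A drives B" from "B drives A"; the phase-dynamics
model can, within the identifiability limits discussed below.

## Pipeline and models

### Preprocessing

Raw optical-density changes are converted per channel with the modified
Beer–Lambert law, `dOD(lambda) = d · DPF(lambda) · (eps · dc)`, solved
in least squares over the available wavelengths (exactly determined at
two wavelengths, overdetermined at three). The differential pathlength
factor defaults to 6.0 at all wavelengths and the extinction table to
standard tabulated hemoglobin spectra; both are plain config entries
because instruments differ. Cleaning is a 3-s centred moving average
(31 samples at 10 Hz; the even 30-sample window is forced odd so the
filter is symmetric and phase-neutral), moving-SD artifact detection
(1-s window; a sample is flagged when its windowed SD exceeds the mean
plus 3 SD of the windowed-SD series — the detection threshold is a
design choice, stated here because only "a threshold" is conventionally
reported) with cubic-spline repair over flagged runs padded by one
sample, and a 6th-order Butterworth band-pass of 0.021–2 Hz.

The band-pass is applied forward–backward (zero phase). A causal filter
would add a frequency-dependent phase lag, which is fatal for an
analysis whose entire content is relative phase; the cost is that the
effective magnitude order doubles. The series is demeaned and
reflection-padded before filtering because the 0.021-Hz pole pair rings
for minutes and would otherwise contaminate a large fraction of a 10-min
record.

### Phase extraction

The continuous wavelet transform uses the analytic Morlet wavelet
(centre frequency `omega0 = 6`, the standard time–frequency trade-off)
on a logarithmic grid of 16 voices per octave, computed by
frequency-domain convolution; scale and frequency are related by
`s = omega0 / (2 pi f)`. One phase per band per channel is obtained by
averaging the complex coefficients across in-band frequencies with
amplitude weights, then taking the four-quadrant angle and unwrapping.
Averaging coefficients (rather than following a ridge) is robust for
broadband physiological oscillations whose instantaneous frequency
wanders across the interval; a ridge tracker can jump between competing
maxima and create spurious phase slips. Samples inside the
cone of influence (within `sqrt(2) s` of either record edge, with `s`
the largest in-band scale) are excluded from all coupling fits, because
edge effects bias phase derivatives badly at very low frequencies.

For the pairwise connectivity sweep the band phase is evaluated at a
decimated rate — the largest stride that keeps at least 12 samples per
cycle of the band's upper edge — since a 0.03-Hz phase sampled at 10 Hz
carries no extra information between samples. The decimation is
implemented in the frequency domain (folding the windowed spectrum), so
it is exact for in-band content, and midpoint evaluation in the
inference keeps the finite-difference error second order in the step.

### Coupled phase-oscillator model and inference

Each ordered channel pair in each band is modelled as

$$\dot\varphi_i = \omega_i + q_i(\varphi_i, \varphi_j) + \xi_i(t), \qquad i \ne j,$$

with Gaussian white phase noise $\xi_i$. The deterministic part is
expanded on Fourier base functions
$\{1, \sin(k_1\varphi_1 + k_2\varphi_2), \cos(k_1\varphi_1 + k_2\varphi_2)\}$
over the lattice $\max(|k_1|,|k_2|) \le K$ with one representative per
$\pm(k_1,k_2)$ class (25 members per equation at the default K = 2).
Both equations are inferred jointly by recursive Bayesian estimation:
within a window, forward-difference phase velocities regress on base
functions evaluated at midpoints, iterating coefficients and the 2×2
noise matrix to a fixed point, with the stochastic-calculus drift
correction `-(h/2) \sum dPhi/dphi` removing the bias that arises
because the midpoint already contains half of the noise increment.
Across windows the posterior becomes the next prior with diffusive
covariance inflation `diag(p_w c)^2`, `p_w = 0.2`. The default is a
single window per 10-min condition — one coupling strength per state,
which is the granularity at which results are reported — and the
windowed mode exists for tracking non-stationary coupling.

Directed coupling strength is the Euclidean norm of the target
equation's coefficients on members that depend on the source phase
(`k_source != 0`, mixed terms included — the literal reading of
"parameters from the phase dynamics of j in equation i"), averaged over
windows; the direction index is the normalised difference
`(s_ji - s_ij) / (s_ji + s_ij)`.

With a flat prior, one window and a fixed small noise matrix the
estimator reduces exactly to ordinary least squares — this limit is the
main correctness oracle in the test suite, checked to 1e-6 relative.

### Surrogate significance

Coupling-strength estimates have a positive noise floor, so raw values
are screened against amplitude-adjusted Fourier transform (AAFT)
surrogates: Gaussianise by normal scores, randomise Fourier phases
under conjugate symmetry, rank-remap back onto the original values.
Sorted surrogate values equal sorted original values exactly, the
spectrum is approximately preserved, and all cross-channel phase
relations are destroyed. Both channels of a pair are surrogated
independently — the conservative null that removes every cross
relation while preserving each marginal spectrum — and each surrogate
pair passes through the identical phase-extraction and inference chain.
A value is significant when it exceeds the surrogate mean by two
surrogate standard deviations; the surrogate mean is also reported as
the "zero level" for reading effect sizes. Production default is 100
surrogates; screening and tests use 19 for speed, and the calibration
test shows the false-positive rate of the rule at 19 surrogates stays
at or below the nominal level on independent oscillators.

### Region aggregation and maps

Significant channel-pair strengths are averaged over all channel pairs
spanning each ordered region pair (source channel in source region,
target channel in target region), giving the 30 directed inter-regional
connectivities of a 6-region network. Non-significant pairs are
*excluded* from the mean rather than zero-filled — the literal reading
of "significant coupling parameters were averaged" — and each cell
carries the count of contributing pairs, so the zero-filled alternative
is reconstructible. Within-region channel pairs are excluded
everywhere. Activation maps average each channel's concentration change
over a condition and interpolate channel-midpoint values by inverse
distance weighting (power 2, all channels); the interpolant is exact at
channel midpoints.

### Group statistics

Region-level coupling strengths enter a two-way mixed-design ANOVA
(group between subjects, condition within), followed by Bonferroni
pairwise contrasts: three condition contrasts at alpha = 0.05/3 =
0.0167 and two patient-vs-control contrasts at 0.05/2 = 0.025. No
sphericity correction is applied by default (none is conventionally
reported for this design); Kolmogorov–Smirnov and Brown–Forsythe
screening is available but advisory only. The implementation is
deliberately thin — `stats::aov` with a subject error stratum and
`t.test` — since these are standard methods.

## The synthetic-data generator

No subject recordings accompany this method, so every stage is
validated against a generator with known ground truth. A synthetic
study mirrors the experimental design: three groups (control, R-H, L-H)
× three conditions (resting, task_S1, task_S2), 24-channel recordings
of 10 min at 10 Hz. Each channel carries one stochastic phase
oscillator per band (Euler–Maruyama integration with at least 20
internal steps per cycle of the fastest oscillator, noise discretised
as `sqrt(2 D h) N(0,1)`), mapped to hemodynamics as
`sum_b A_b cos(phi_b)` plus linear drift and white measurement noise,
with HHb an anti-phase scaled copy; spike/step motion artifacts are
injected at Poisson times with an exact ground-truth mask.

Defaults, chosen once to represent plausible recordings: band centre
frequencies 1.1 / 0.25 / 0.10 / 0.033 Hz with a ±25 % uniform
per-channel scatter, oscillation amplitudes 0.06–0.10 µM, phase-noise
intensity 0.05 rad²/s, measurement noise 0.03 µM, drift 0.2 µM per
record, artifacts 0.5/min at 8 SD. The frequency scatter matters: with
near-identical natural frequencies, any planted coupling hard-locks the
pair deterministically, a degenerate regime (see limitations) that
real vasomotor rhythms — which differ across cortical sites — do not
occupy. The default study plants interval-IV motor→prefrontal coupling
in patient groups only (RMC→RPFC for R-H, LMC→LPFC for L-H), 0.4 rad/s
during both task sessions and 0.1 rad/s at rest, giving the downstream
statistics a known directed, band-specific, group-specific effect.

What the generator does *not* emulate: superficial-layer (scalp/skull)
physiology and short-separation contamination, heterogeneous DPF,
non-sinusoidal oscillator waveforms, inter-subject amplitude
variability, and any hemodynamic forward model (no balloon model).
Passing the recovery benchmarks therefore shows the *inference chain*
is correct and calibrated on signals with the right spectral and
coupling structure — not that real recordings satisfy the model.

## Numerical choices

* Fixed-point iteration: tolerance 1e-5 relative on coefficients,
  maximum 100 iterations, non-converged windows flagged.
* The noise matrix estimate is floored at `1e-12 I` so noise-free
  deterministic inputs (used by tests) remain solvable.
* Singular designs (e.g. constant phases making all trig members
  constant) raise an error naming the degenerate members.
* FFT lengths are padded to 5-smooth integers.
* AAFT requires ≥ 32 samples and non-constant input; ties are broken
  by first-occurrence ranks, keeping the value multiset identical.
* Decimation stride: `floor(fs / (12 f_hi))`, so a band's phase always
  keeps ≥ 12 samples per cycle of its upper edge.
* IDW interpolation returns the exact channel mean within 1e-12 mm² of
  a midpoint, avoiding 0/0.

## Problem sizes used in the shipped checks

The packaged validation runs at desk scale, chosen as the smallest
sizes at which the checks are statistically meaningful: coupling
recovery over 20 seeds of 10-min pairs; surrogate-rule calibration over
50 independent pairs with 19 surrogates; and an end-to-end benchmark of
20 synthetic studies with 8 subjects per group, one task condition,
evaluated on the planted region cells in interval IV. A full study at
production settings (all 552 ordered pairs × 4 bands × 3 conditions ×
100 surrogates) is the same code with different arguments.

## Known limitations

* **Locked-pair direction blindness.** At interval IV the Morlet
  envelope spans ~29 s at 0.033 Hz, so band phases are smooth on the
  timescale of the phase noise that identifies the dynamics. For a
  strongly coupled (synchronised) pair the phase difference is nearly
  constant, the (k, −k) Fourier members become collinear with the
  constant, and the Euclidean norm of the fitted coefficients inflates
  in *both* directions. Genuine coupling is still detected reliably —
  surrogates share neither the lock nor the inflation — but which
  direction dominates is essentially not recoverable from a 10-min
  record. The recovery benchmark therefore validates directionality on
  raw simulated phases (where it holds in ≥ 90 % of runs at matched
  expansion order), and the study-level benchmark scores detection of
  the planted directed cell without requiring the reverse cell to be
  smaller; both directions of a synchronised region pair are typically
  co-elevated, and the reported direction comparison makes this
  visible.
* **Heavy-tailed strength estimates.** For synchronised pairs the
  inflation varies over an order of magnitude between subjects, so the
  benchmark's group contrast uses a rank-sum test; the package's stats
  module keeps the conventional t/ANOVA scheme for real analyses.
* **K = 2 under-identification.** The 25-member expansion is the
  method's reporting convention, but for locked pairs only a few
  directions of the design are informative. The matched-order K = 1
  fit recovers a planted first-order coupling amplitude within 20 %;
  the K = 2 fit does not, and no amount of windowing rescues it at
  this record length.
* Surrogate counts below ~50 make the mean + 2 SD threshold itself
  noisy; 19 is adequate for calibration tests but production analyses
  should use 100.
* SNIRF (HDF5) input is not supported in this build; the CSV dialect
  plus sidecar JSON is the interchange format.
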
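---
title: "Personalised tremor profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalised tremor profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorprofile)
```

This vignette documents the scientific model behind `tremorprofile`, the
tunable parameters and their defaults, the numerical choices made where the
design was genuinely open, and what the synthetic-data validation does and
does not demonstrate.

## The problem and the model

Sensor-based tremor amplitude measurements are precise but poorly
repeatable within a patient: the symptom itself fluctuates, and a
one-size-fits-all change score cannot tell fluctuation from progression.
The package's premise is that each patient's tremor has a recognisable
*blend* across joints which persists even while its overall size varies.
Formally, each task execution yields a measurement vector of per-parameter
log-amplitudes; the per-parameter mean of a subject's valid measurements is
their characteristic vector `a_c` (their profile). Change between two
measurements is decomposed into the component parallel to `a_c` (scale
change `d_S`, a resizing of the usual tremor) and the perpendicular
magnitude (profile change `d_P`, a change of blend). The squared-profile
variant `d_S2` boosts the weight of the dominant joints; the mean
difference `d_M` is the conventional unprofiled comparator. Working in log
amplitude makes "scale" multiplicative in physical units, which matches how
tremor severity is perceived.

Because `d_S` and `d_P` are an orthogonal decomposition of the difference
vector, `d_S^2 + d_P^2 = ||a_B - a_A||^2` holds exactly on null-free
vectors; the test suite property-checks this, together with antisymmetry,
invariance to positive rescaling of `a_c`, the equivalence of `d_P` with
the 2-D/3-D cross-product formula, and the degeneration of `d_S` to `d_M`
at a single parameter.

### Intrinsic-variability control

The clinically interesting quantity is not the raw between-visit change but
its size relative to the subject's own short-term variability. With two
instances per day on each of two days,

```
d'_X = mean( d_X(a_p1, a_q1), d_X(a_p2, a_q2) ) /
       mean( |d_X(a_p1, a_p2)|, |d_X(a_q1, a_q2)| )
```

The denominator uses *absolute* same-day differences by default. For signed
metrics the same-day differences are zero-mean noise; averaged with sign
they can cancel (or go negative), making the ratio meaningless as a
variability scale, while the numerator keeps its sign so the direction of
change survives. Both conventions are implemented
(`variability_adjust(..., denominator = "signed")`) since the choice is an
interpretation; `"absolute"` is the default for the reason above. The
coarse clinical scales themselves cannot be adjusted this way — their
same-day differences are typically exactly zero.

### Nulls

A missing amplitude (all repetitions rejected) is a first-class value:
`NA` end-to-end, never zero, since zero is a legal amplitude. Vector
metrics exclude a parameter from *all* vectors involved before
renormalising `a_c`; CSV output writes nulls as empty fields.

## Amplitude extraction

**Welch PSD** (`welch_psd()`): rectangular window, 1-s segments, 50%
overlap, zero-padded to a grid no coarser than 0.0625 Hz. Tapering is
deliberately avoided: the analysed clinical segments can be as short as
1.5 s and a taper would discard most of the usable signal. The fixed 1-s
segment makes the spectral line shape of a sinusoid independent of segment
duration and sampling rate, which the amplitude calibration exploits.

**ATA** (`ata()`): the square-root PSD summed over the tremor band
`[max(2, f_T - 1), min(10, f_T + 1)]` around the in-band PSD maximum
`f_T`, scaled to return the peak-to-peak amplitude of a pure sinusoid.
The published form of this estimator fixes its constant only up to the PSD
convention; the sinusoid calibration is the operative contract, so the
package derives the constant analytically from the rectangular-window line
shape: `ATA = kappa * df * sum(sqrt(X))` with
`kappa = 2 * sqrt(2 * T_w) / I`, where `I` integrates `|sinc((f - f_T) T_w)|`
over the band offsets. Because `I` is a function of the band geometry only,
the calibration stays exact when the band is clamped at the 2 or 10 Hz
edge; it is never fitted to data. Measured accuracy on pure sinusoids is
within 2% across 2.5–9 Hz, 50–200 Hz sampling and 1.5–10 s durations, and
linearity in amplitude is exact.

**Rejection heuristics** (`reject_estimate()`): estimates are discarded
when (1) the window is shorter than 1.5 s; (2) the tremor band — bounded by
the PSD local minima nearest the peak within 1.5 Hz either side — carries
mean power below the median of the remaining 2–10 Hz comparison band; or
(3) the tremor band's power range fails to stand out from the comparison
band's fluctuations (less than twice the 70th percentile of the absolute
differences between consecutive local extrema, or less than their mean plus
three standard deviations). Local extrema are defined by strict sign change
of first differences with plateaus collapsing to their left edge; extrema
are collected per contiguous run of the comparison band so that no
artificial extremum spans the gap left by the tremor band; percentiles use
linear interpolation. When the comparison band has fewer than three extrema
the fluctuation statistics are undefined and the estimate is accepted with
a logged `sparse_comparison_band` note — failing open preserves data while
the note preserves auditability.

One behaviour of these published rules deserves emphasis: because the
tremor band is centred on the spectrum's own maximum, a featureless noise
spectrum presents its largest fluctuation *as* the candidate peak, and in
roughly a third of white-noise draws that fluctuation clears the
comparison-band thresholds. The suite measures ~60–70% rejection of pure
white noise (confirmed against an independent implementation), while
unambiguous sinusoidal tremor is accepted in ≥ 95% of draws and acceptance
is monotone in signal-to-noise ratio. In the intended workflow the
remaining noise acceptances are further diluted by log-averaging across
three repetitions and by the profile weighting itself.

**Per-instance aggregation** (`instance_amplitude()`): the natural log of
ATA is averaged over the repetitions that survive rejection (natural log is
a free choice — any base is order-preserving); no survivors yield a null.

## Kinematics

Band-pass filtering uses a 4th-order Butterworth applied forward and
backward (zero phase), with mean removal and odd-reflection padding to
suppress end transients on short segments; the squared response gives
> 20 dB attenuation at 1 Hz and at 14 Hz. Dominant tremor axes come from
PCA (covariance eigendecomposition) of the band-passed triaxial signal,
with the sign fixed so the first nonzero loading is positive — PCA sign is
arbitrary and a fixed rule makes outputs reproducible. Hand displacement is
obtained from acceleration in the frequency domain, dividing by
`-(2*pi*f)^2` inside 2–10 Hz only; restricting to the band sidesteps the
drift that time-domain double integration accumulates, and sub-2 Hz content
is outside the analysis by construction. Window times in seconds map to
samples as `[round(start*fs), round(end*fs))`.

## Statistical evaluation

Correlations are squared Spearman rank coefficients (tie-corrected,
asymptotic t p-values — the standard library behaviour), immune to
monotone transforms and outliers. The joint-movement metrics form a family
over the number of retained joints `N` (default 2–15, ranked by the
characteristic vector, nulls last, ties broken by canonical parameter
order); each (metric, reference) family is Benjamini–Hochberg adjusted, and
the adjusted `pFDR` is read as a conservative p-value replacement.
Univariate hand metrics and the maximum-amplitude joint are judged
individually and are not family-adjusted. Exactly ranked inputs short-cut
to `rho = ±1` so that a perfect monotone relationship reports 1 rather
than `1 - 1e-16`.

The two discretisation experiments quantify why coarse 0–4 scales are
insensitive to change: rounding a continuous scale to two levels drops the
squared Spearman correlation with the underlying values to 0.75
(`discretization_experiment_abs()`), and on an integer 0–4 scale the
correlation between true changes and discretised changes collapses when
changes are smaller than the scale interval
(`discretization_experiment_change()`). The change experiment rounds
without clipping by default: saturating at the 0–4 bounds caps the
achievable correlation at large change sizes (≈ 0.65 at σ = 10) and is
available as `clip_bounds = TRUE` for modelling a truly bounded scale.

The heterogeneous hand pair (displacement in mm, rotation in deg/s) is
z-scored before combination using the sample convention (n − 1); the
statistics used are returned alongside the result so externally supplied
cohort statistics can reproduce a normalisation exactly. Homogeneous joint
sets are deliberately not z-scored — that would inflate joints that barely
tremble.

## The synthetic cohort generator

`simulate_cohort_vectors()` encodes the generative structure the metrics
assume: a fixed non-negative profile per subject; a log-normal per-day
scale factor (`scale_sd = 0.5`, giving a median between-day severity ratio
of about 1.6 — drift large enough to matter, consistent with the strong
test–retest variability reported clinically); a day-level additive profile
wobble (`profile_noise_sd = 0.1`) and per-instance noise
(`within_day_sd = 0.15`), both expressed relative to the profile norm; and
optional dropout for nulls. The default cohort shape (24 subjects, 15
joints, 2 days × 2 instances) mirrors the clinical study design.
`simulate_recordings()` renders amplitudes into raw signals — a sinusoid at
a subject-stable frequency in 3–6 Hz plus white noise and a 0.3 Hz
voluntary-movement drift — and `simulate_observer_scores()` discretises the
latent severity into a saturating single 0–4 item (A) and finer-grained
item sums (B, C) via log-normally perturbed per-item gains, so a zero
latent maps to zero on every item.

What passing tests on this cohort show: the pipeline recovers known
amplitudes through the full spectral chain (within the ATA calibration
tolerance); the variability-adjusted scale2 change tracks the true
between-day log-scale drift (mean ρ² ≈ 0.87 at the stated noise regime,
30 subjects, 20 seeds); and scale2's correlation varies less across
`N = 2…15` than the mean difference's, reproducing the qualitative
N-robustness claim. What they do not show: performance on real MS tremor,
whose "tremor" is less periodic, mixes with ataxia, and violates the
stationary-sinusoid signal model; nor observer behaviour beyond the simple
latent-plus-discretisation score model. Headline clinical correlation
values depend on the original sensor recordings and manual windowing and
are not reproducible from synthetic data; the synthetic results are
structural validation, not clinical replication.

## Problem sizes and determinism

All simulations take explicit seeds and are bit-reproducible. The test
suite uses 100-seed Monte-Carlo runs for rejection rates (with common
random numbers across the SNR ladder, so monotonicity is tested without
seed noise), 20-seed × 30-subject cohorts for parameter recovery, 200
permutation-style replicates for null false-discovery calibration, and
100,000 samples for the discretisation experiments — sizes at which the
Monte-Carlo error is comfortably inside the asserted tolerances.

## Known limitations

- The rejection heuristics' white-noise specificity is intrinsically
  limited (see above); they are a guard against ambiguous spectra, not a
  tremor detector.
- The characteristic vector uses amplitude only; relative phase and
  frequency across joints are discarded.
- Tremor is not distinguished from ataxia; both can inflate amplitudes.
- The acceleration-to-displacement step assumes the hand sensor's frame is
  approximately inertial over the analysed window; orientation estimation
  from raw IMU data is out of scope (recordings are consumed after sensor
  fusion).
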
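---
title: "Methods: thalamocortical dynamics at behavioral arousal transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thalamocortical dynamics at behavioral arousal transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Fast fMRI (repetition times of 0.2–0.4 s) can resolve sub-second timing
differences between brain regions. `arousalseq` implements an analysis
pipeline for a specific use of that capability: measuring *when* each
thalamic nucleus and cortical region activates or deactivates around a
spontaneous **behavioral arousal** — the moment a drowsy subject, asked to
press a button with every breath, resumes pressing after a long silence.

The pipeline runs from raw inputs (per-ROI BOLD tables, button-press logs,
motion parameters, cardiac/respiratory waveforms, optionally EEG) to the
derived quantities a study of this design reports: arousal-locked mean
responses and 20%-of-maximum latencies with bootstrap confidence intervals,
a cross-nucleus lag sequence, model-based activation onset times, a
breathhold-based vascular control, and the occipital alpha-power change
that confirms the behavioral transition is an electrophysiological one.

# Definitions and decision rules

**Behavioral arousal.** The first button-press after at least 20 s of
unresponsiveness (`detect_arousals()`, `min_gap = 20`). Three rules make
this operational on real logs:

* silence from the run start counts toward the gap — unresponsiveness, not
  a previous press, is the defining condition;
* the triggering press counts as response #1 of the arousal's response
  train;
* the response train ends at the next silence of 20 s or more, which makes
  the response-counting window self-consistent with the arousal definition
  itself.

Arousals with **5 or more** responses are *sustained*, **2 or fewer**
*transient*; counts of 3–4 form an *intermediate* band excluded from the
two-class comparison.

**Motion exclusion.** Framewise displacement is the Power-style scalar:
sum of absolute backward differences of the translations plus 50 mm times
that of the rotations (the conventional 50 mm head radius). An arousal is
excluded when FD exceeds 0.3 mm anywhere in its −10…+20 s window. The FD
formula is a config-visible choice — any monotone alternative would change
exclusions — so it is fixed and documented rather than implicit.

**20% latency.** Event-locked means are baseline-centered on −10…−7 s.
The latency is the earliest time after the baseline window at which the
deviation from baseline, on the side of the window's extremum, reaches 20%
of that extremum's magnitude. The search scans forward with no persistence
requirement at the crossing — the simplest reading of "the time at which
the signal reached 20%" — and the crossing is not constrained to lie on
the rising limb toward the global extremum; the rule is recorded in the
output provenance. For regions whose activation (not deactivation) is the
quantity of interest, `polarity = "positive"` uses the maximum positive
deviation instead of the absolute one.

# Signal processing choices

**Upsampling.** BOLD series are linearly interpolated to 4× the sampling
rate (e.g. 247 ms → 61.75 ms) before event alignment, so that windows can
be locked to the sample nearest each press. Original samples are preserved
exactly; upsampling followed by reading back the original grid is the
identity.

**Physiological noise regression.** Cardiac and respiratory fluctuations
appear in fast-TR BOLD as quasi-periodic components whose frequency *and*
amplitude drift over a scan. `dynamic_retroicor()` regresses, in sliding
windows of 1000 s stepped by 400 s, the BOLD trace on sines and cosines of
the first and second harmonics of the cardiac and respiratory phases
(eight regressors), assigns the betas to window centers, interpolates them
linearly to every sample (held constant beyond the first/last center), and
subtracts only the reconstructed harmonic component. Each window's design
also contains an intercept and a linear drift column — not subtracted, but
present so that slow trends cannot leak into the harmonic betas; this is
disable-able (`drift = FALSE`) since whether the original analysis
included such terms is not documented. A series shorter than one window
falls back to a single full-length fit with a message.

Cardiac phase comes from bandpass filtering (0.2–10 Hz), peak detection
with a 0.4 s minimum inter-peak distance (150 bpm ceiling) and a threshold
at half the 99th-percentile amplitude, then mapping each interbeat
interval linearly onto 0…2π. Respiratory phase is the angle of the
analytic signal after a linear-phase FIR bandpass (0.16–0.4 Hz,
Hamming-window design; the filter is applied by symmetric convolution,
which is exactly zero-phase for a linear-phase FIR). The analytic signal
is built by the standard FFT half-spectrum construction.

**Cross-correlation lags.** `xcorr_lag()` computes the Pearson correlation
over the *overlapping* samples at every integer-step shift within ±10 s
and returns the maximizing shift. Overlap-only correlation (no zero
padding) avoids biasing lags toward zero on 30 s windows; per-shift
Pearson normalization (rather than one global normalization) is used and
logged. Ties are broken toward the smallest absolute lag, then negative
before positive. The ±10 s bound exceeds any physiologically plausible
sequence while excluding window-edge artifacts. The reference ("whole
thalamus" or "whole cortex") is the equal-weight average of the region
means and is rebuilt from the same resampled events inside every bootstrap
iteration, preserving the dependence between a region and the reference
that contains it. Within sustained-only or transient-only analyses the
search is restricted to positive correlations, since positive coupling
between thalamic regions is established before the split.

One property of self-inclusive composite references is worth knowing when
interpreting single-region lags: each region's own noise also enters the
reference, which adds a small correlation excess exactly at zero lag. For
a region whose true offset from the reference center is well under the
correlation profile's resolution this can pin the estimate at zero. Lag
*orderings* and *ranges* — the quantities of scientific interest — are
insensitive to this, but simulation studies that check confidence-interval
coverage should use configurations in which the estimator's population
value is well-defined (see "Validation design" below).

**Bootstrap uncertainty.** Event-level: arousals are resampled with
replacement 1000 times; the statistic (latency or lag) is recomputed on
each resampled mean; the CI is the 2.5/97.5 percentile pair. Subject-level
(hierarchical): subjects are resampled with replacement, then arousals
within each drawn subject, accumulating until the total event count
reaches the observed total; this propagates both between-subject and
between-event variability. All resampling requires an explicit seed and is
deterministic given it.

**Breathhold control.** A breathhold task (27 s free breathing, three
paced 3 s-in/3 s-out breaths, 15 s hold, repeated 8 times per run) evokes
a purely vascular response; windows of −20…+20 s around each release are
processed by the same ensemble and cross-correlation machinery, and each
region's average breathhold lag is subtracted from its arousal lag
(`hemodynamic_correct()`) to remove the hemodynamic component of the
sequence. Regions with degenerate breathhold responses are excluded from
the corrected sequence with a logged list.

**HRF model and onset.** The event-locked mean of a small, noisy region is
summarized by a smooth model: two unit-height Gaussians plus their
temporal derivatives,
$$ f(t) = a_1 G(t;\mu_1,\sigma_1) + a_2 G(t;\mu_2,\sigma_2)
        + d_1 G'(t;\mu_1,\sigma_1) + d_2 G'(t;\mu_2,\sigma_2). $$
Fitting minimizes RMSE by Nelder–Mead simplex over the four shape
parameters $(\mu_1,\mu_2,\sigma_1,\sigma_2)$ with 8 jittered restarts;
the four amplitude coefficients enter the model linearly and are profiled
out by least squares at every objective evaluation, which makes the search
low-dimensional and well-conditioned. Shape parameters are solved jointly
with the derivative terms, not post hoc. Widths are constrained to
0.5–10 s and centers to the data window (via logistic transforms), which
prevents degenerate spike or runaway fits. **Onset** is the earliest time
the fitted curve reaches 10% of its positive maximum — positive, because
onset quantifies activation. Fits explaining less than 20% of variance are
flagged `low_confidence`.

**Multitaper alpha power.** EEG power uses Slepian (DPSS) tapers computed
from the symmetric tridiagonal eigenproblem — 3 tapers on 2 s windows
stepped by 1 s, time-bandwidth product 2 (the value that yields three
well-concentrated tapers on a 2 s window). Alpha is 8–13 Hz by default
with the band configurable (a 7–12 Hz convention also exists). The
arousal effect is tested by a two-sided paired t-test of mean alpha power
in the 10 s before versus 10 s after each arousal.

**Statistical testing.** Time-binned tests average each event's signal in
1 s bins and apply two-sided one-sample (vs zero) or paired t-tests per
bin, Bonferroni-corrected for the number of bins times the number of
regions in the family — for a 30 s window and 30 cortical regions, a
family of 900. Degenerate bins (zero variance) are handled exactly: zero
mean difference gives p = 1, nonzero gives p = 0.

# The synthetic-data generator

`make_session()` produces complete sessions with recorded ground truth for
every quantity the pipeline later estimates, which is what makes each
stage testable by parameter recovery. Each ROI trace is the sum of:

* **arousal responses** — the same double-Gaussian family the fitter uses
  (positive Gaussian of width 2 s peaking 6 s after the effective onset,
  i.e. near the arousal for thalamus-type regions), shifted by the
  region's true lag and scaled by its amplitude; generator and fitter
  sharing one curve family is what makes parameter recovery well-posed;
* **cortical deactivation** — cortex-type regions carry a slight early
  rise followed by a delayed negative Gaussian (default 5 s delay), since
  the qualitative shape (post-arousal deactivation) is known but no
  generative model is established;
* **slow drift** — two slow sinusoids (600 s and 210 s periods, 0.1 a.u.);
* **physiological contamination** — first and second harmonics of
  integrated cardiac (0.9–1.3 Hz) and respiratory (0.2–0.3 Hz) frequency
  trajectories, synthesized directly on the BOLD grid (the fast TR
  resolves them, so no aliasing model is needed), with amplitude slowly
  modulated ±30% over ~20-minute periods — real physiological artifacts
  are non-stationary in amplitude as well as frequency, and this slow
  modulation is precisely the regime a sliding-window regression addresses
  and a static fit cannot;
* **noise** — Gaussian with AR(1) correlation (coefficient 0.4 by
  default) mimicking BOLD autocorrelation. The marginal noise SD defines
  SNR as amplitude/SD. No empirical noise magnitudes are established for
  arousal-locked nuclear traces; the defaults (SNR 5 at the single-event
  level) are chosen for estimator-recovery testing, not claimed realism.

Button logs press at twice the breathing rate during responsive periods;
sustained arousals emit ≥ 5 presses, transient ≤ 2, intermediate 3–4, with
class probabilities 0.46/0.35/0.19 (matching the observed mix of arousal
types in studies of this design). Motion traces are slow wander plus
occasional 0.5 mm spikes. The optional EEG-like channel is broadband noise
with a 10 Hz component whose amplitude triples for 10 s at each arousal.
One global seed feeds per-component child seeds, so any subset of a
session is independently reproducible, and identical configurations are
bit-identical.

What the generator does **not** emulate: voxel-level structure, real EEG
sleep architecture, scanner artifacts, and non-separable interactions
between physiology and neural response. Passing recovery tests on these
sessions therefore demonstrates the estimators' correctness under the
stated signal model, not performance on arbitrary real data.

# Validation design and problem sizes

The test suite validates each stage against independent oracles:
brute-force O(n²) re-implementations (arousal rule, motion exclusion,
shift-and-correlate), closed forms (20% crossing of a ramp, Gaussian 10%
onset at $-\sigma\sqrt{2\ln 10}$), finite differences (derivative terms),
dense-grid root searches (onset), and eigen-decompositions (SVD variance
fractions). End-to-end checks use cohort-scale synthetic sessions: 9
nuclei with true lags spanning 2.1 s, ~40 events at SNR 5 on the 61.75 ms
grid, requiring exact order recovery and median lag error below 0.15 s;
100-replicate coverage studies for flat and hierarchical bootstrap CIs
(≥ 90% at nominal 95%); 100 HRF recoveries (median onset error < 0.3 s);
and 500 null simulations of the binned test (family-wise error at or
below the corrected nominal rate). These sizes keep the full suite within
a few minutes while leaving Monte-Carlo slack well below the margins
tested.

The coverage study uses a symmetric lag set ({−0.6, 0, +0.6} s): with an
asymmetric set the composite reference shifts all lags by a common
alignment constant and the central region's estimand falls within the
zero-lag noise spike discussed above, making "coverage of the configured
lag" ill-posed rather than the bootstrap miscalibrated.

# Known limitations

* Lag estimates are quantized to the upsampled grid (61.75 ms at TR
  247 ms); CIs narrower than one step collapse to zero width.
* The positive-correlation restriction can fail on regions anticorrelated
  with the reference; this raises an explicit error rather than returning
  a sign-flipped lag.
* The hierarchical bootstrap requires at least two subjects; with one it
  falls back to the flat bootstrap with a warning.
* Baseline choice is exposed (`baseline` window) but alternative baseline
  definitions are not systematically compared.
* Voxelwise maps, traveling-wave models, and EEG artifact removal are out
  of scope; the pipeline consumes ROI-level traces and cleaned EEG.

# A minimal worked run

```{r, eval = FALSE}
library(arousalseq)
s <- make_session(tr = 0.247, duration = 1800, seed = 1)
res <- run_pipeline(s, pipeline_params(n_boot = 200))
res$latency$thalamus   # 20% latency with bootstrap CI
res$sequence$order     # nuclei ordered by lag (leaders first)
res$sequence$range     # lag range in seconds
res$hrf$onsets         # per-nucleus 10% onset times
```
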
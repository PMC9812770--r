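---
title: "Methods: NREMS oscillation coupling and manifold dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NREMS oscillation coupling and manifold dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Sleep staging

The averaged LFP of one area (M1 by default; the area is configurable) is
segmented into non-overlapping 6 s epochs; a trailing partial epoch is
discarded. Per epoch we estimate the power spectral density with a single
Hann-tapered periodogram — one 6 s segment per epoch is the minimal
estimator consistent with epoch-wise classification, and its band averages
are what the classifier consumes — and average it over the slow-wave band
(0.1–4 Hz) and the gamma band (30–60 Hz). A 2-means classifier on the
standardized (delta, gamma) features separates NREMS from everything else;
REM and wake are deliberately not distinguished. Two conventions deserve
note, because no external standard fixes them: features are standardized
per dimension before clustering (otherwise delta power, typically orders of
magnitude larger, dominates the distance), and the cluster with the higher
mean delta power is NREMS, which also makes the labels invariant to the
solver's arbitrary cluster indexing. k-means uses k-means++ with 10
restarts under a fixed seed. Adjacent NREMS epochs merge into bouts; bouts
shorter than 30 s are discarded, with exactly 30 s retained (the exclusion
rule is "less than 30 s").

## Oscillation detection

All detection runs on NREMS samples of averaged traces. Artifact samples
(beyond 10 channel-s.d.) are masked, not deleted, so indices stay aligned
to the session clock; masked samples are linearly interpolated before
filtering, which keeps detection invariant to the masking of a single
sample. SO detection averages raw channels; spindle and SWR detection
z-score each channel first so channels with different gains contribute
equal variance; SWR detection uses the three designated dorsal-CA1
channels from the session manifest.

Band-passing applies two independent zero-phase (forward–backward)
Butterworth filters, high-pass then low-pass: SO 0.1 Hz (order 2) / 4 Hz
(order 5); spindle 10 Hz (6) / 15 Hz (8); ripple 150 Hz (8) / 250 Hz (10).

The SO detector enumerates positive-to-negative zero crossings with their
preceding peak, following trough and surrounding negative-to-positive
crossings. Percentile thresholds are computed per sleep block over all
NREMS candidate waves — block-level pooling gives stable percentiles where
per-epoch pooling would not — with "top 15 percentile of peaks" read as the
85th percentile of the peak-value distribution and "bottom 40 percentile of
troughs" as the 40th percentile ascending; threshold comparisons are
strict. A wave is an SO when its trough is below the trough threshold, the
preceding peak above the peak threshold, and the peak→trough duration in
[150, 500] ms (closed).

Envelope events use the magnitude of the analytic signal (FFT Hilbert
construction), computed separately within each NREMS bout — no analytic
signal across gaps — and smoothed with a Gaussian window (200 ms spindles,
20 ms SWRs). The configured window length is read as the full width at two
kernel s.d. (σ = width/2), truncated at ±3σ; the convention is logged in
the configuration since the width alone does not fix it. Thresholds are
μ + 2.5σ / μ + 1.5σ (spindle) and μ + 4σ / μ + 1σ (SWR) of the pooled NREMS
envelope; an event is a maximal run above the lower threshold containing at
least one sample above the upper threshold and lasting ≥ 500 ms (spindle)
or ≥ 50 ms (SWR). Onset/end are the lower-threshold crossings, the peak is
the envelope argmax. Whether μ and σ should be pooled per block or per
bout is not externally fixed; both are available, block-level pooling is
the default.

## Event coupling and null models

Lags follow lag = target − reference; equidistant ties link to the earlier
reference. Windows are closed at both endpoints — at microsecond timestamp
precision the distinction is immaterial, but it is fixed and documented.
Coupling values are percentages of target events; sessions with no targets
yield a flagged undefined value rather than zero, and callers are expected
to treat fewer than 10 events per train as unreliable.

The shuffle null rotates the entire target train by a single uniform
offset modulo the total NREMS duration *in gap-excised (concatenated)
time*, so shuffled events remain inside NREMS and the inter-event-interval
multiset is preserved; 1,000 rotations are averaged. The mean of this null
equals the window-coverage fraction of the fixed train — the package
computes that coverage analytically (`window_coverage`), both as a test
oracle and as the chance-coincidence rate c against which coupling
estimates should be read: an injected coupling probability p yields an
expected estimate p + (1 − p)·c, not p. The subsampling control redraws a
fixed number (100) of reference events without replacement, 1,000 times.

SWR⁺SO⁺ labels require an M1 SO up-state in the half-open second following
the SWR onset; SWR⁻ epochs are uniform 1 s epochs whose full extent lies
inside NREMS, one per SWR; they may overlap each other.

## Across-day transition dynamics

Session items (trials, or sleep events) are split by time into three
contiguous tertiles, remainder to the last (31 → 10/10/11), and the metric
recomputed per tertile; 13 days give 39 samples. Series are padded at each
end with that end's 2-day (6-tertile) mean, convolved with a Gaussian
kernel spanning 9 tertiles (3 days; kernel σ = (9−1)/5 tertiles, the
standard Gaussian-window convention), and min-max normalized to [0, 1].
ΔSO–SWR coupling enters this machinery as raw percentage-point differences
per animal, mirroring every other metric; a constant series flags
normalization as undefined.

The sigmoid L + (U − L)/(1 + exp(−k(x − x_mid))) is fitted by
Levenberg–Marquardt least squares with box constraints (L, U ∈ [−0.5, 1.5]
on the normalized scale, x_mid within the data range, |k| ≤ 20) and a
multi-start grid over x_mid at 1-day spacing with two slope signs; the
best-SSE start wins. Fits focus on days 3–11 (M1) or 3–13 (PFC) where
configured. A fit is flagged "no transition" when the slope is ~0, R² is
below 0.1, or the fitted amplitude |U − L| is smaller than four residual
standard deviations — the last criterion is what actually catches
flat-plus-noise series, where a spurious small-amplitude sigmoid can
otherwise fit with nonzero k.

The moving-window transition scan measures OLS slopes in windows of 3–7
days. The baseline distribution is the slopes of windows lying entirely
within days 1–4; when the window is too wide for that, the first window's
slope alone. A transition is the end day of the first window whose slope
strictly exceeds baseline mean + 2 s.d. (threshold configurable); the
reported day is the modal day across window sizes, flagged on
disagreement. Piecewise fits are independent per-segment OLS, with the
final segment optionally truncated at the series argmax to isolate the
rising phase. The change point minimizes the summed SSE about two segment
means by exhaustive search; ties break to the earliest index. Success-rate
change subtracts the mean of the two preceding days, with the two days
before day 1 taken as zero. Stage labels (I before, II after the
grand-midpoint, the per-animal median of the coupling rise and drop
midpoints) feed a standard logistic regression; perfect separation is
flagged, not hidden.

## GPFA, alignment, fidelity

Spike counts in 15 ms bins within the reach window (−200 to +400 ms from
reach onset by default; PFC windows are expanded by 100 ms at both ends)
are z-transformed per unit using concatenated-across-trials statistics;
silent units and units below 0.5 Hz in-window are excluded to avoid
degenerate z-scores. The observation model is y_t = C z_t + d + ε with
diagonal private noise; each latent follows a zero-mean GP over bins with
a squared-exponential kernel and a fixed innovation-noise fraction of
1e−3. EM uses the exact joint posterior over each trial's latent path
(block-structured precision, Cholesky solves); (C, d) and the private
variances update in closed form, and each timescale by a bounded 1-D
search that never accepts a worse value, so the marginal log-likelihood is
non-decreasing by construction — the test suite asserts this on every
fit. Initialization is PCA on the concatenated z-scored counts with
100 ms initial timescales; convergence at relative log-likelihood change
below 1e−6 or 500 iterations. Factors are ordered by explained shared
variance (squared loading norm); shared-over-total variance is
tr(CC′)/tr(CC′ + R).

Dimensionality selection is leave-neuron-out prediction error — each unit
predicted from latents inferred from the remaining units — computed on
held-out trials (2-fold trial-level cross-validation). Without the trial
split the error keeps creeping down past the true dimensionality, because
extra latents can fit chance noise correlations in the fitted trials.

Daily manifolds are aligned to the mean manifold of the final three days
by Procrustes transformation including scaling (the cited standard routine
scales by default; a flag disables it). The GPFA correlation resamples
trajectory and template to 100 points per factor, centers each factor and
correlates the concatenated factors — per-factor centering makes the
statistic exactly invariant to a simultaneous rotation of both, which the
plain concatenated Pearson correlation is not. One correlation per trial
(concatenation, not per-factor averaging) is the default, with per-factor
averaging available. Fidelity is mean over s.d. of these correlations
across all trials of a tertile, successful and failed alike. The optimal
template averages the three best-performance days' trajectories, ranked by
success rate, using all trials (success-only as an option).

## Reactivation and the communication subspace

Sleep spikes around SWR onsets are binned at 15 ms, z-scored with the
*awake* per-unit parameters — so templates and reactivations share the
units' scales; sleep-local z-scoring is available as an option — and
projected onto the orthonormalized top-3 awake loadings. The reach
template is built by pushing each awake trial's z-scored counts through
the same projection and averaging: template and reactivation must live in
the same coordinates, since the statistic is not invariant to the
invertible mixing that separates posterior latents from basis projections.
The compression/lag search spans window sizes 75–405 ms in 2-bin (30 ms)
steps and lags in 1-bin (15 ms) steps with lag + size ≤ 405 ms;
projections are linearly resampled to the template length (the resampling
rule for length mismatch is a package choice). The fixed comparison window
is 195 ms at zero lag. The null shuffles each unit's binned counts
circularly within −200 to +400 ms around the onset, independently per unit
and event.

CCA concatenates 1 s post-SWR windows across events, mean-subtracts, and
retains only the top canonical variable. The implementation delegates to
the standard QR-based solution; when a within-area covariance is
rank-deficient a ridge of 1e−6 times the mean diagonal is added and
reported. Condition-wise cross-area R projects each condition's bins on
weights fitted once on all SWR⁺ data (per-condition refitting is exposed
as an option; shared weights are the more stable default), and
ΔCross-area R = R(SWR⁺SO⁺) − R(SWR⁺SO⁻).

## The synthetic generator

The generator is a pure function of (configuration, seed) and records
every scheduled truth. Defaults are the study conditions: 1018 samples/s
LFP; sleep blocks of 45 min alternating NREMS bouts (60–120 s) with wake
(20–60 s), giving roughly 30 NREMS minutes; ~10 SOs, ~5 SWRs and ~2
spindles per NREMS minute (rat NREMS scale); PFC–M1 SO coupling rising
sigmoidally across days with midpoint day 6 and post-sleep SO–SWR coupling
dropping with midpoint day 8 against a constant pre-sleep baseline of
0.25; 30-unit populations driven by 3 shared latents through exp-linear
Poisson rates (10 Hz baseline); 40 trials/day; 30% of post-sleep SWRs
carrying replay at 0.5× compression. Event trains are refractory Poisson
processes whose draw rate is inflated to first order so the realized rate
matches the configured one after thinning; per-trial latent noise is
Gaussian-smoothed white noise rescaled so its marginal s.d. equals the
configured level (otherwise smoothing would silently attenuate the noise
schedule ~10-fold and the fidelity ladder would measure Poisson noise, not
the schedule).

The LFP level emulates what the detectors assume and little more: pink
1/f background per channel, extra sub-1.2 Hz power in NREMS and extra
gamma in wake for the staging contrast, raised-cosine biphasic SO waves
(down-peak then up-trough, 150–500 ms peak→trough), amplitude-modulated
12.5 Hz spindle bursts and 200 Hz ripple bursts injected coherently across
channels. It does *not* model volume conduction, state-dependent spectra
beyond the delta/gamma contrast, REM, electrode drift, or unit turnover —
so passing tests show the pipeline recovers its own generative structure
at realistic SNR, not that it is robust to every artifact of real chronic
recordings.

Multi-day studies are generated at the event/spike level by default; full
LFP synthesis is exercised per block. Thirteen days of multichannel LFP at
1018 Hz is not a desk-scale object, and the across-day questions — sigmoid
midpoints, change points, stage ordering — are functions of event-time
statistics that the detectors are separately shown to recover.

## Problem sizes and validation scales

The validation suite and `scripts/acceptance.R` use these scales, chosen
so each check is statistically meaningful yet the whole run stays in the
minutes range on one CPU: detector recovery on one ~30 min NREMS block
(~250 SOs, ~140 SWRs, ~60 spindles); coupling calibration at p ∈ {0.2,
0.5, 0.8} with 500 target events × 200 replicates; shuffle nulls at 1,000
rotations; sigmoid recovery at noise σ = 0.1 × 200 replicates; 50
simulated 13-day studies for rise-before-drop ordering; GPFA subspace
recovery at 30 units × 100 trials and dimensionality selection over 20
replicates of 20 units × 30 trials; a 5-level fidelity ladder at 60
trials; reactivation power over 50 replicates of 200 SWRs with 40-shuffle
nulls; and 40 CCA condition-contrast replicates.

## Known limitations

Percentile-based SO thresholds tie the detected count to the candidate-wave
count: the detector cannot find more SOs than the configured percentile
tail admits, so extreme mismatches between true event rate and background
wave rate bias recall — a property of the detection rule itself, visible
in the generator when the background slow-wave rate is reduced.
Staging is two-class by design; REM epochs with high delta would be
misfiled. The GPFA implementation assumes equal trial lengths within a
session. The reactivation statistic compares a partial window against the
full template when replay is compressed; this lowers absolute R without
harming the SWR⁺/SWR⁻ contrast. Change-point analysis finds exactly one
mean shift. Hypothesis-testing machinery (LME, ANOVA, post-hoc tests) is
out of scope: the pipeline emits the per-session summary values such tests
consume.
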
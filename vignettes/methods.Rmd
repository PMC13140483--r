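---
title: "Models and methods behind hemowave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hemowave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowave)
```

`hemowave` analyses the haemodynamic battery of a two-group (young healthy
vs. middle-aged with cardiometabolic risk), three-time (baseline, 30 min,
60 min) acute-challenge study: pressure-waveform calibration, large-artery
stiffness and impedance, wave separation, transcranial and carotid Doppler
indices, breath-hold cerebrovascular reactivity, and the group-by-time
repeated-measures analysis. Because raw recordings of such studies are
rarely shareable, the package pairs every analysis stage with a synthetic
generator of known ground truth; this vignette documents the models,
parameter choices, numerical details, and what the verification does and
does not establish.

## Signal containers and beat processing

All waveforms are uniformly sampled tibbles (`time_s`, `value`) carrying
their sampling rate and units. Ingest from CSV validates a monotone uniform
time grid to 1 ppm; gaps are an error rather than silently interpolated.

Beat detection anchors either on R waves (5–25 Hz zero-phase Butterworth
band-pass, local maxima with greedy suppression at the minimum physiologic
period of 0.33 s) or on pressure feet (maxima of the lightly smoothed first
derivative). Implied beat periods are constrained to 0.33–2.0 s, so an
ectopic extra spike shortening a beat below 0.33 s drops that anchor.

Ensemble averaging segments half-open beats `[onset_i, onset_{i+1})` —
half-open so no boundary sample is counted twice — that are complete within
the averaging epoch (default 20 s, the standard tonometry epoch). Beats are
time-normalized to the *median* beat length by linear resampling before
pointwise averaging; averaging raw unequal-length beats would smear the
late-cycle waveform, and the median is insensitive to one aberrant beat.
Two quality-control rules are ours, since acquisition protocols are
typically silent on artifact handling:

- a beat whose peak-to-foot amplitude deviates more than 3 robust standard
  deviations (1.4826·MAD) from the epoch median amplitude is dropped and
  reported. The MAD scale is used rather than the sample SD because a
  single corrupted beat inflates the SD enough to mask itself;
- an ensemble with fewer than 7 beats warns (ensemble sets are expected to
  contain 7–10 beats) but never hard-fails.

## Pressure calibration

Brachial calibration is the affine map sending the raw waveform minimum and
maximum to diastolic and systolic cuff pressure; carotid calibration
anchors the minimum at brachial diastolic and the *mean* at brachial MAP
(the standard tonometric transfer, since diastolic and mean pressure are
far more stable along the arterial tree than systolic). Carotid systolic
pressure is therefore an output. Both maps are exactly affine, so waveform
shape (correlation with the raw trace) is preserved at 1, and the carotid
beat's time average equals brachial MAP by construction.

MAP itself is the time average of the calibrated brachial waveform over the
full cycle. We read "derived from the pressure waveform" as integration;
the cruder `diastolic + pulse pressure / 3` form factor is available as
`derive_map(..., method = "form_factor")`. Duplicate cuff readings must
agree within 5 mmHg and are averaged, mirroring screening practice.

## Stiffness and wave mechanics

**Foot detection.** The intersecting-tangents construction: the foot is the
intersection of the horizontal line through the pre-upstroke minimum with
the tangent at the point of maximum upstroke slope. This is the consensus
definition for foot-to-foot transit timing. Numerically, the waveform is
smoothed with a 20 ms edge-padded moving average before differentiation and
the slope maximum is restricted to the interior (edge samples see the
padding); the construction remains exact on piecewise-linear upstrokes and
holds foot jitter below 2 ms at 40 dB SNR. Sub-sample precision comes from
the tangent intersection, not the sample grid.

**cfPWV.** Per R-wave-gated beat, Δt = femoral foot − carotid foot; the
per-beat Δt are aggregated by the median (robust to isolated
mis-detections; the aggregation rule is a package choice), and
cfPWV = path distance / median Δt, with at least 5 usable beats required
and a non-positive median Δt treated as a site-ordering error. Path
distance is taken as measured (direct), not a subtracted distance.

**β-stiffness.** `ln(Ps/Pd) / ((Ds − Dd)/Dd)`, with domain checks and an
explicit zero-strain error.

**Characteristic impedance.** Time-domain estimate
`Zc = max(dP/dt)/max(dQ/dt)`, both maxima over the full cycle, derivatives
by centered differences. See *Known limitations* for the bias this
estimator carries on Windkessel-generated waves.

**Wave separation.** Time-domain linear split on pulsatile components:
`ΔP = P − min(P)`; `ΔQ` references flow to its value at the *pressure
foot*, not the cycle minimum, so venous-like negative diastolic dips do not
bias the reference. `Pf = (ΔP + Zc·ΔQ)/2`, `Pb = (ΔP − Zc·ΔQ)/2`;
`Pf + Pb = ΔP` holds identically, and the test suite asserts it to
10⁻⁹ mmHg on noisy inputs. Amplitudes are peak minus foot value of each
separated wave (peak-to-peak is the plausible alternative; peak-to-foot was
chosen because both separated waves share the foot as a common, noise-robust
reference), and `RIx = Pb/Pf`. Values above 1 warn rather than error.

## Doppler indices

Site plans follow the acquisition protocol: MCA metrics from eight 7 s
epochs spread evenly across a 2 min window; carotid metrics from two 12 s
epochs. Within an epoch, systolic and diastolic velocity are the means of
per-beat extrema (not the global extremum — robust to single-beat spikes;
the per-beat rule is a package choice), and mean velocity is the time
average. `PI = (Vs − Vd)/Vm`. The resistive index is the Pourcelot form
`RI = (Vs − Vd)/Vs`; the validating evidence for that choice is that it
reproduces the published RI table cells from the published velocity cells
within rounding (106/45 → 0.58, 91/39 → 0.57), which the acceptance script
recomputes. Note the identity `RI = PI·Vm/Vs`, asserted property-style in
the tests. Conductance is `Vm/MAP`. Subject-level indices are means of
per-epoch ratios; a ratio of group means would differ and is not used.

## Breath-hold reactivity

The protocol: 8 paced breaths at 16 breaths/min (30 s), a 20 s hold,
then recovery; repeated 4 times. End-tidal values are the plateau maxima
within each scheduled breath window, extracted from the continuous CO₂
trace (the generator deliberately emits the continuous trace, not
pre-picked end-tidal points, so the extraction path is exercised).
`ΔETCO₂` = post-hold peak − mean of the last two paced end-tidals. The
response window for both the CO₂ peak and the velocity response is the hold
plus 15 s, and the velocity response uses a 3 s moving average; the ΔMCAv
construction deliberately mirrors the stated ΔETCO₂ rule (baseline from the
last two paced breaths) since no explicit windowing rule exists for the
velocity side. CVR is the mean of per-repeat ratios (not a regression
across repeats, and not a ratio of means — with four repeats the mean of
ratios is the simplest unbiased summary and keeps failed repeats
excludable); repeats with `ΔETCO₂ ≤ 0` (failed holds) are excluded and
reported, never silently. Relative CVR uses each repeat's own paced-breath
baseline. The identity `cvr_rel·baseline/100 = cvr_abs` per repeat is
asserted in the tests.

## Statistics

The normality gate runs Shapiro–Wilk on within-cell residuals for each
group × time cell; if any cell rejects at α = 0.05 the outcome is
natural-log transformed (positivity enforced, offending rows listed) and
re-tested, and the decision is recorded. Constant cells are flagged
untestable.

The 2 × 3 mixed repeated-measures ANOVA uses the classical partition:
group against subject-within-group; time and group × time against the
subject × time residual. Partial η² = SS_effect/(SS_effect + SS_error of
that stratum). Complete cases (subjects with all three times) are selected
per outcome, since dropout can differ by outcome. Sphericity is not
assumed silently: the Greenhouse–Geisser ε is estimated from the pooled
within-group covariance of the three repeated measures and a corrected p
value is reported alongside the uncorrected one (the uncorrected p is the
primary value, matching common practice when sphericity is not discussed).
The implementation fits `stats::aov` with an `Error(subject)` stratum; the
test suite verifies F, p and η² against an independent brute-force
sums-of-squares decomposition (sequential least-squares projections) to
10⁻⁸ on 100 random datasets, and the 2000-replicate null simulation checks
the interaction's type-I error at α = 0.05.

Post hoc families are explicit because the family size m is a reporting
choice: `time_within_group` (3 paired contrasts per group, m = 3),
`group_within_time` (Welch t at each time, m = 3), `time_overall` (m = 3);
Bonferroni adjustment is `min(1, m·p)`. Group descriptives use Welch
(unequal-variance) t tests — the safer default when only "independent
t-tests" is specified — and χ² without continuity correction (the classical
statistic whose closed form the tests check directly).

## Synthetic generators: what they emulate

- **Windkessel** (`simulate_windkessel`): three-element model
  `P = p_wk + Zc·Q`, `C·dp_wk/dt = Q − p_wk/R`, half-sinusoid ejection
  integrating to the stroke volume. Integrated by the classical fixed-step
  RK4 scheme at the signal rate (for this linear ODE the RK4 step reduces
  to a linear recurrence, evaluated exactly by a recursive filter, so the
  integration is vectorized without changing the scheme); 20 warm-up beats
  are discarded, and emitted beats are periodic to 10⁻⁶ of the pulse
  pressure. Ejection occupies 0.3 of the cycle by default — a resting
  left-ventricular ejection time of ~0.3 s at 60 beats/min. The flow shape
  is a deliberate simplification with a well-defined peak derivative and is
  swappable in principle.
- **Delayed pair** (`simulate_delayed_pair`): sub-sample shift by linear
  interpolation; delays longer than one cycle error (foot pairing would be
  ambiguous).
- **Doppler envelope** (`simulate_doppler_envelope`): raised-cosine
  upstroke of fixed width (15% of the cycle) plus a raised-cosine decay
  whose width is solved so the beat mean hits the target — since a
  raised-cosine limb has mean exactly half its width, the solution is
  closed-form. Triples outside the systolic-dominant feasible band are
  rejected with the violated constraint named, never clipped.
- **Breath-hold session** (`simulate_breath_hold_session`): continuous
  capnograph-like CO₂ trace (per-breath plateaus, apnoeic floor, post-hold
  peak, decaying recovery breaths) and a velocity trace whose response
  plateau is wider than the 3 s smoothing window, so the programmed CVR is
  recoverable exactly at zero noise.
- **Cohort** (`simulate_cohort`): compound symmetry via a per-subject
  shared deviate weighted `sqrt(ρ)·SD` plus independent residuals weighted
  `sqrt(1−ρ)·SD` — cell means and SDs are matched exactly in expectation,
  any two times within a subject correlate at ρ even with unequal cell
  SDs, and this is precisely the covariance structure under which the
  repeated-measures F tests are exact.
- **Visit/study** (`simulate_visit`, `simulate_study`): group-by-time true
  values follow the published group means of the emulated study design
  (MAP, heart rate, cfPWV, β, diameters, MCA and carotid velocities,
  glucose/insulin), with per-subject Gaussian offsets at table-like SDs and
  0.5% relative waveform noise.

Acquisition sampling rates are package decisions, since study protocols
rarely state them: 500 Hz for tonometry/ECG, 200 Hz for Doppler envelopes,
50 Hz for CO₂/velocity trend traces — typical for the respective
instruments.

What passing recovery tests shows: the analysis operators invert the
generative models they were designed for, at the stated tolerances, and
the full pipeline is deterministic end to end. What it does not show:
robustness to real-world failure modes absent from the generators —
probe repositioning drifts, spectral-envelope dropouts, arrhythmia,
breathing artifacts in tonometry, or calibration error in the cuff itself.

## Numerical choices

- Derivatives: centered differences scaled by the sampling rate, one-sided
  at the ends; exact on linear segments.
- Foot search: 20 ms moving-average smoothing, interior-restricted argmax,
  tangent intersection for sub-sample precision.
- Ensemble time base: median beat length; linear resampling.
- Ties/degenerate inputs: flat signals error at beat detection; flat beats
  error at calibration; zero strain errors in β; non-positive `ΔETCO₂`
  repeats are excluded with a message; constant Shapiro cells are flagged.
- Waveform CSVs are written with 17 significant digits so write→read
  round-trips are bit-exact.
- Problem sizes in the verification suite: 100-beat reconstruction checks,
  a 3 × 3 Zc grid, 9-session CVR grid, 100-dataset ANOVA oracle
  comparison, 2000-replicate null simulation at n = 20/group, and a
  41-subject × 3-time full-study determinism run.

## Known limitations

**Peak-derivative Zc on Windkessel waves is biased.** With
`P = p_wk + Zc·Q`, the pressure derivative is `Zc·dQ/dt + (Q − p_wk/R)/C`.
The full-cycle maximum of that sum falls slightly after the flow-derivative
maximum, where the compliance term is positive and non-negligible, so the
estimator `max(dP/dt)/max(dQ/dt)` systematically overestimates Zc. The
relative bias scales like `1/(Zc·C·ω)` (ω the ejection angular frequency):
it is worst at low Zc, low heart rate and long ejection. At a physiological
ejection fraction (0.3 of the cycle) the acceptance suite measures up to
~58% relative error at the grid's hardest point (Zc = 0.05 mmHg·s/mL,
50 beats/min) — far outside a 5% recovery band — and no physiologically
defensible ejection shape or timing removes the bias (its validity
condition `Zc·C·ω ≫ 1` would require ~50 ms ejections). This is a property
of the estimator/model pair, not an implementation defect: on proportional
waves (`P = Zc·Q + const`) the estimator is exact to machine precision,
which the unit tests assert. In practice the estimator is used
*comparatively* (within-subject change), where a common multiplicative
bias largely cancels; absolute Zc values from this method should not be
compared against frequency-domain estimates.

**Other limitations.** The beat template family for Doppler envelopes only
reaches systolic-dominant means (normalized mean below 0.5), which covers
arterial velocimetry but not venous-like waveforms. The QRS detector is a
band-pass-and-threshold scheme adequate for clean single-lead traces, not
a clinical-grade delineator. The rm-ANOVA covers exactly the 2 × 3 mixed
design; unbalanced *time* structures (missed visits) are handled only by
complete-case exclusion, not by mixed-effects modelling.
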
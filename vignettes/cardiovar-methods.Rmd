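---
title: "Methods: signal processing and statistics in cardiovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal processing and statistics in cardiovar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiovar)
```

`cardiovar` analyses beat-to-beat cardiovascular recordings from acute
exercise crossover sessions: an initial supine rest, one exercise bout, and
re-evaluations 10, 20 and 30 minutes into recovery. This vignette documents
the models and conventions behind each stage, the tunable parameters and
their defaults, the synthetic-data generators that give every stage a known
ground truth, and the numerical choices that were genuinely open.

## Beat streams and preprocessing

The common currency is the `beat_series`: strictly increasing beat times,
RR intervals in ms, and optional beat-to-beat pressures. RR and beat-time
differences must agree within 1 ms for unedited beats — editing operations
restore this invariant after they modify the stream.

**Ectopy flagging** (`flag_ectopics`). A beat is flagged when its RR differs
from the median of its 11-beat neighbourhood (5 on each side, the beat
excluded) by more than `dev_frac` (default 0.2) of that median. A premature
ectopic at 0.6× the local RR and its 1.4× compensatory pause both clear a
20 % gate, so the pair is caught while respiratory-scale variation (a few
percent of the mean RR) is untouched. Artifact editing in practice is
semi-automated; a fully reproducible rule is required here, so the threshold
is an exposed knob rather than an operator judgment.

**Bridging** (`remove_and_bridge`). Flagged beats are deleted. The RR of
each surviving beat whose predecessor was removed spans the gap and is
therefore re-estimated from a natural cubic spline through the trustworthy
(time, RR) points; beat times are then recomputed as cumulative RR sums.
More than 20 % flagged beats aborts the window — a usability guard in the
spirit of standard HRV task-force practice, also configurable. Bridging a
single beat from a constant series reproduces the constant exactly, and on
noiseless generator output a second flag–bridge pass flags nothing
(idempotence), both enforced by tests.

**Resampling** (`resample_window`). RR-versus-*beat-time* (not beat index)
is interpolated with a natural cubic spline and evaluated on a uniform grid.
Interpolating against time is the standard choice for spectral HRV, because
the frequency axis is then in Hz rather than cycles/beat; this is an
interpretation the package fixes and documents. The default rate is 4 Hz:
the Nyquist frequency (2 Hz) sits far above the 0.4 Hz upper HF edge, and
480 samples per 2-minute window is dyadic-friendly for the wavelet stage.
Windows with an internal gap exceeding 3 s are refused. Session windows are
the 120 s ending at each protocol mark (rest, 10, 20, 30 min).

## Time-domain HRV

`hrv_time_domain` works on the edited NN intervals themselves, never on the
resampled signal: SDNN is the (n−1)-divisor standard deviation, RMSSD the
root mean square of successive differences, pNN50 the percentage of the
n−1 successive differences exceeding 50 ms. Natural-log transforms are
attached because downstream statistics are usually run on ln-indices. The
default usability guard is 30 unflagged beats per window, relaxable
(`min_beats`) for short diagnostic segments.

## Wavelet band powers

The spectral stage uses a shift-invariant (maximal-overlap) discrete wavelet
transform with Daubechies filters. "Daubechies-12" is ambiguous between 12
taps and 12 vanishing moments; the package reads it as the filter commonly
labelled *db12* (12 vanishing moments, 24 taps) and exposes the order as a
knob (`wavelet = "db6"`, …) — tests require alternative orders to pass the
same tolerances, so nothing hinges on the naming. Filters are generated at
run time by spectral factorization of the binomial half-band polynomial
(`daubechies_filter`), and their orthonormality and vanishing moments are
property-tested rather than asserted against tabulated constants.

**Band mapping.** A dyadic level j nominally covers [fs/2^{j+1}, fs/2^j].
The LF/HF edges (0.04, 0.15, 0.4 Hz) do not fall on dyadic boundaries at
any sampling rate, and a plain "level variance × fractional overlap"
aggregation has a sharper problem: a tone at a dyadic edge (0.25 Hz at
fs = 4) is split 50/50 between the adjacent levels by the quadrature-mirror
identity |H(1/4)|² = ½ — this holds for *every* orthonormal wavelet, so no
filter choice fixes it — and the overlap weights then discard ~30 % of its
power. `modwt_band_power` therefore refines the tree adaptively: any node
whose band straddles a target band edge is split further (sequency-ordered
wavelet packet), and fractional overlap is applied only to terminal nodes.
A 30 ms tone at 0.25 Hz is then recovered at ~449 ms² against the A²/2 =
450 ms² truth (the tests enforce 15 %, and 20 % agreement with the Welch
periodogram oracle in `fft_band_power`).

**Boundary handling.** The detrended window is reflected to twice its
length and filtering is circular. Coefficients whose filter support reaches
back across the reflection junction are excluded from variances when the
level still leaves interior coefficients; at depths where the support
exceeds the window, all coefficients are kept — with reflection padding they
are not garbage, merely correlated with the mirrored segment. Packet depth
is capped where the cumulative support exceeds twice the reflected length
(depth 6 for db12 on 480-sample windows); a window too short even for depth
3 is refused outright.

**Normalized units** are defined as LF/(LF+HF)·100. No very-low-frequency
band is reported, and detrending is mean-removal only — a polynomial detrend
would silently move power out of LF.

## Sequence-method baroreflex sensitivity

Ramps are maximal runs of ≥ 3 beats whose per-beat SBP changes all exceed
1 mmHg in the same direction; the paired RR segment, offset by `lag` beats
(default 1 — the classical convention for the sinoatrial latency), must show
same-direction per-beat changes > 4 ms. The sequence slope is the
least-squares regression of RR on SBP, retained when r² ≥ 0.85 — the
conventional validity gate that suppresses noise slopes; both thresholds and
the minimum sequence count (default 3) are arguments. The estimate is the
plain mean of valid slopes; the baroreflex effectiveness index is the
fraction of ramps that produced a valid sequence. The error paths
distinguish "no ramps at all" (flat pressure) from "ramps without an RR
response" (threshold or coupling failure), because the two mean different
things physiologically.

Against the generator, estimates recover prescribed gains of 5, 10 and
20 ms/mmHg within 10 % at 1 ms RR noise over 300 beats, and up-only versus
down-only estimates agree within 20 % on symmetric input.

## Pulse wave velocity and pressures

`detect_feet` segments cycles at mid-amplitude rising crossings, takes the
diastolic minimum of each cycle, and places the foot at the intersection of
the horizontal through that minimum with the tangent at the maximal-upstroke
point; the derivative peak is refined to sub-sample precision by a local
quadratic fit. The intersecting-tangent definition is the consensus for
carotid–femoral devices; a maximum-of-second-derivative alternative was
considered and rejected as noisier on sampled data at the rates involved.
Proximal and distal feet are matched by rank order within the common span —
no cross-correlation fallback, so a mismatch fails loudly rather than
silently shifting by a beat.

Transit time is the mean per-beat foot difference; PWV is the corrected
distance over transit time, with the 0.8 path-length correction applied to
the carotid–femoral site only (a test pins that cf and cr pipelines differ
by exactly that factor on identical inputs). Fewer than 10 matched beats
yields a result flagged invalid rather than an error; a non-positive mean
transit (reversed sites, or zero delay) is an error.

`calibrate_carotid` solves the two-point linear map sending the waveform
minimum to DBP and the time average to MAP; central systolic pressure is the
mean of per-beat maxima over a ≥ 15 s window. Which device MAP comes from is
deliberately outside the function: it takes MAP as an explicit argument.

## Calorimetry

The Weir form used is `kcal/day = 1.44·(3.94·VO₂ + 1.11·VCO₂)` (mL/min, no
urinary-nitrogen term). Steady-state search slides 5-minute windows across
minutes 5–15 (the first five minutes of an REE measurement are discarded),
requires CV(VO₂) and CV(VCO₂) ≤ 10 % — CV computed as sd/mean of the five
1-minute bins — and a mean RER in [0.7, 1.0], and among valid windows takes
the lowest-REE one; a single window, not an average of disjoint candidates,
which is the stricter reading of the lowest-REE rule. Session energy sums
per-minute Weir energy (TEE), pro-rates REE over the phase duration, and
computes `AEE = TEE − (REE_session + 0.1·TEE)`; the identity
`AEE + 0.1·TEE + REE_session = TEE` is enforced to machine precision in
tests. METs use the participant's measured resting VO₂ rather than the
3.5 mL/kg/min convention, because a measured REE is available by
construction. VO₂peak adjudication uses 220 − age for the age-predicted
maximal heart rate — the most widely used formula, chosen since none is
named in the source conventions — and accepts a test when at least two of
the five criteria hold.

## Crossover statistics

`fit_crossover_model` fits `outcome ~ condition × timepoint × group +
(1 | participant)` by REML and reports Satterthwaite-denominator F tests per
term. On the balanced crossover this reproduces the classical
repeated-measures ANOVA exactly (a test checks term-by-term agreement with
`aov` + `Error(participant)`), so the mixed model's value is robustness to
unbalanced, real-world tables. A singular random-intercept fit downgrades,
with a warning, to a fixed-effects `lm` — on balanced data the sequential
ANOVA there coincides with partial tests.

Effect sizes: `ω² = df₁(F−1)/(df₁(F−1)+df₁+df₂+1)` and
`η²ₚ = F·df₁/(F·df₁+df₂)` with Cohen-style labels (small < 0.05,
medium < 0.25, large above). Both are reported because both appear in
practice and they answer different questions (population variance explained
versus sample partial association); ω² may be negative below F = 1 and is
returned as computed. Tukey post hocs come from `emmeans` with
studentized-range adjustment; adjusted p never falls below the unadjusted p.
Group characteristics use Welch's t with a Shapiro-Wilk-gated Mann-Whitney
companion. `power_f_test` is a documented generic F-test planning utility,
not a pipeline stage.

## Synthetic generators: what they do and do not show

Every generator takes a validated spec carrying its own integer seed
(`withr::with_seed`; no global RNG state), and records its ground truth in
the output metadata:

* `generate_rr` — RR(t) as mean + LF/HF sinusoids + Gaussian noise, beat
  times as cumulative sums; ectopics as isolated 0.6×/1.4× pairs. Default
  ectopic burden 1/min, a plausible supine figure. Instantaneous RR ≤
  200 ms is rejected as non-physiological.
* `generate_baro_beats` — alternating SBP ramps (default 1.5 mmHg steps,
  4-beat ramps) with RR = gain·ΔSBP at a configurable lag plus noise.
* `generate_wave_pair` — a fixed analytic beat template (two log-normal
  bumps on a diastolic baseline) and its delayed copy. Physiological realism
  is a non-goal; a detectable foot is the requirement.
* `generate_gas_trace` — 1-minute bins whose realized CV equals `cv_inside`
  in the embedded segment; outside bins deviate by at least
  max(`cv_outside`, 0.25) with alternating sign, large enough that *any*
  5-minute window touching them fails the 10 % CV gate — this is what makes
  "the detector returns a window inside the embedded segment" a theorem
  about the construction, not a hope.
* `generate_trial_table` — balanced 2-group × 4-condition × 4-timepoint
  layout, participant intercepts (SD 5), residual SD 5, n = 12 per group by
  default, matching the scale of a realistic crossover of this design; cell
  shifts via an explicit effect map.

Passing tests on these inputs shows the *algorithms* recover known
structure; it does not show robustness to respiration drift, measurement
trends, missing beats in bursts, device-specific artifacts, or non-Gaussian
outcome tails — none of which the generators emulate.

## Problem sizes and numerical conventions

The test-suite simulations use 2-minute windows at 4 Hz (480 samples),
300–3600-beat pressure streams, 25 seeds per tone for spectral recovery, 25
replicates for post hoc power, and 1000 replicates for the null calibration
of the interaction F test (rejection rate required within 5 % ± 1.5 %);
`scripts/acceptance.R` uses 400 replicates for the same quantity. Ties and
degenerate inputs follow explicit rules: sub-threshold constructions yield
empty detections (not errors); zero transit delay errors in the PWV stage,
not the generator; equal-REE steady windows resolve to the first-found
lowest; zero-variance Welch comparisons return p = 1 on equal means.

## Limitations

Ectopy editing assumes isolated ectopics — runs of consecutive artifacts
longer than the interpolation can bridge trip the 20 % guard instead. The
wavelet band estimator's terminal-node overlap weighting still assumes
roughly flat spectra within the finest boxes (~0.03 Hz), adequate for HRV
bands but not for line spectra at band edges beyond the refinement depth.
Foot detection requires a clear diastolic minimum per cycle and will refuse
heavily damped or flat traces. The statistics stage models a single outcome
at a time and applies no multiplicity control across outcomes.
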
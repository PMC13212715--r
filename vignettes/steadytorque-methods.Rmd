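---
title: "Methods: analysing fixed-end torque-reduction contractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing fixed-end torque-reduction contractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steadytorque)
```

## The problem

During a fixed-end (isometric joint) contraction, the muscle fascicles are
not isometric: as force rises they shorten against the stretching in-series
elastic tissue (tendon and aponeurosis), and when the person deliberately
reduces their torque output the elastic tissue recoils and the fascicles
are lengthened while still active. `steadytorque` implements the complete
analysis chain for experiments that exploit this mechanism in the human
tibialis anterior (TA): participants track a displayed trapezoidal torque
trace — ramp up to a high "test" plateau (Hold 1), descend at a controlled
rate or amplitude, then hold a lower plateau (Hold 2) that matches a
constant-torque reference condition — while net ankle joint torque and
crank-arm angle (2 kHz), surface EMG (2 kHz) and ultrasound-tracked
fascicle length (~34 frames/s) are recorded. The scientific questions are
whether fascicle lengthening during the activity reduction changes the
subsequent steady-state EMG amplitude at matched torque, and whether it
degrades torque steadiness.

The package has two halves: the analysis pipeline (signal conditioning,
designed-trace generation, validity gating, hold-phase metrics, statistics)
and a mechanistic simulator that generates synthetic datasets with the
structure the analysis assumes, so that every stage is testable without any
human data.

## Signal conditioning

All filters are Butterworth filters applied once forward and once backward
(dual-pass), which doubles the attenuation and cancels the phase. Because a
cascade of `p` passes of an order-`n` filter attenuates more than 3 dB at
the single-pass cut-off, each pass is designed at the corrected frequency

$$f_\text{design} = f_\text{desired} / C, \qquad
  C = \left(2^{1/p} - 1\right)^{1/(2n)},$$

so the composite −3 dB point lands on the desired cut-off
(`corrected_cutoff()`; for the usual dual-pass second-order case
C ≈ 0.8022). For high-pass edges the correction multiplies instead of
divides, moving the design edge down. The per-channel defaults are 20 Hz
(torque), 6 Hz (crank angle) and, for EMG, band-pass 20–400 Hz followed by
mean-bias subtraction, full-wave rectification and 10 Hz low-pass
smoothing, in exactly that stage order. Applying the cut-off correction to
the band-pass edges is an assumption (the correction is only stated for
the low-pass stages); it is exposed so it can be changed.

Numerical choices: filtering uses odd-reflection padding whose length is
the larger of the conventional minimum (3 × order × passes, 1% of the
signal) and the filter's own settling length computed from its largest pole
radius; the signal mean is removed before filtering and restored through
the filter DC gain, so constants pass through exactly. Signals too short
for the padding raise an error rather than being truncated. A zero-phase
low-pass of a rectified signal can undershoot zero, so the envelope is not
clamped; no sample-wise non-negativity is promised.

Baseline torque is the mean filtered torque over 1 s before contraction
onset (0.5 s / 0.25 s for MVC trials of Experiments 1 / 2), active torque
is filtered torque minus baseline, and both torque and EMG are expressed
relative to the MVC trial with the highest active torque as the mean over
a 0.5-s window centred on the maximum of the already-filtered signal. A
centred window that would extend past the trial bounds is an error, never
a clamp.

## Protocols and trial validity

The condition library holds both experiments: Experiment 1 ramps at
20 %MVT/s to 60 %MVT and descends to 40 %MVT over 0.25/0.5/1/2 s
(reference: a single ramp to 40 %MVT), all traces lasting 13.5 s;
Experiment 2 ramps to 85 %MVT and descends at 20 %MVT/s to 15/30/45 %MVT
(reference: ramps to the same levels), lasting 15 s with Hold 2 durations
of 5/5.75/6.5 s.

Two closures were genuinely open and are package design choices:

* **Experiment 1 hold durations** are not printed. With ascend fixed at
  3 s and the total at 13.5 s, splitting the remainder equally between the
  two holds (`hold1 = hold2 = (13.5 − 3 − descend)/2`) reproduces the
  printed Hold 2 range "4.25 s to 5.1 s" exactly (4.25 s for the 2-s
  descend, 5.125 s for the 0.25-s descend) and is consistent with the
  published representative analysis windows. No other single-parameter
  closure does this.
* **Reference-condition hold boundaries** have no ramp corners to define
  them. Experiment 2 references borrow the boundaries of their
  torque-matched test condition; Experiment 1's single reference takes the
  intersection of the four test conditions' hold spans (3–7.25 s and
  9.25–13.5 s from onset).

Contraction onset is the first time normalized active torque exceeds
1 %MVT for at least 100 ms (both parameters exposed; the returned time is
the threshold crossing, which for a 20 %MVT/s ramp sits ~50 ms after the
commanded departure from zero). Torque-matching error is the maximum
absolute deviation between active torque and the displayed band's midline
from onset to the end of Hold 2. A trial is invalid if that error exceeds
10 %MVT (strict `>`; exact equality is kept but warned about, following
the analysis-section wording over the stricter protocol-section wording)
or if the active torque between Hold 1 and Hold 2 undershoots the Hold 2
mean by more than 0.8 Nm (Experiment 1) or 2 Nm (Experiment 2) — both
thresholds being pilot mean + 2 SD, reproduced by
`dip_threshold_from_pilot()`.

Hold-phase metrics are computed over the solved hold spans trimmed by a
0.25-s guard at **both** ends. The leading guard keeps ramp transients out;
the trailing guard keeps onset-detection jitter (~50 ms) from pulling the
window into the following ramp or release. The published representative
windows, which are similarly interior, are available as presets.

## Per-trial metrics

Hold means of normalized torque, EMG envelope and absolute fascicle length;
fascicle shortening amplitude (range over [onset − 0.5 s, Hold 2 start] —
"maximum difference" is read as the range, matching the "peak-to-peak"
wording used for lengthening); lengthening amplitude (range over
[Hold 1 end, Hold 2 start], also as % of the length at Hold 1 end — the
instantaneous pre-lengthening length, another flagged reading); maximum
lengthening speed (central differences on the length trace after dual-pass
5-Hz smoothing at the ~34 Hz frame rate, because raw frame differences
amplify tracking jitter; the cut-off is exposed and smoothing can be
disabled); and torque steadiness as the coefficient of variation (sample
SD / mean × 100) of active torque during Hold 2. Fascicle data stay on
their native frame grid; nothing is upsampled. Condition summaries average
all valid trials; a condition with zero valid trials raises a
`condition_excluded` signal and the pipeline logs it, mirroring
participant exclusion in practice.

## Statistics

* `rmcorr()` — repeated-measures correlation via ANCOVA with subject as a
  factor and a common slope, computed in closed form on within-subject
  centred data; error df = N − n_subjects − 1, p from F(1, df), CI by
  Fisher z with SE = 1/√(df − 1) (standard rmcorr practice; the method
  name is recorded in the result).
* `rm_anova()` — one- or two-way within-subject ANOVA by
  sums-of-squares partitioning, each effect tested against its own
  subject-interaction error. Mauchly's test runs per effect on the
  orthonormal-contrast covariance (with Box's second-order chi-square
  correction; the base-R implementation differs microscopically in that
  term's dimension constant), and a rejection at α = .05 triggers the
  Greenhouse–Geisser epsilon on both dfs. "Mixed-effects analysis" in the
  Prism sense is implemented as complete-case RM-ANOVA: subjects with
  missing cells are dropped with a warning and a count; Prism's
  missing-cell denominator dfs are not reproduced (documented divergence).
* `holm_sidak()` / `pairwise_holm_sidak()` — step-down Šidák adjustment
  with enforced monotonicity; pairwise paired t statistics use the pooled
  ANOVA error variance when sphericity holds and per-pair difference-score
  variances otherwise.
* `paired_power()` / `min_sample_size()` — exact noncentral-t power for
  the two-tailed paired design (ncp = d_z √n, df = n − 1); the planning
  numbers n = 10 (80% power) and n = 13 (90% power) at d_z = 1 fall out.

## The simulator

`simulate_trial()` runs a two-element muscle-tendon model in closed loop.
The contractile element has a Gaussian force–length curve (width 0.45–0.5
of optimum; the operating region sits near the plateau) and a hyperbolic
force–velocity curve; the series-elastic element has a quadratic toe
stiffening into a linear region, `F = f_max(0.85 x² + 0.15 x)` with
`x = stretch / d_max` and 13 mm of stretch at maximal force (5% strain of
a 260-mm tendon-aponeurosis). The MTU length is constant, so fascicle
length is the length constant minus SEE length; pennation is absorbed into
the constant (TA pennation is small and the mechanism under test does not
depend on it). With default parameters the model lands near the printed
anchors — MVT ≈ 43 Nm, fascicle ≈ 83 mm at 40 %MVT, lengthening
amplitudes ≈ 7.4/5.2/3.5 mm for the 85→15/30/45 drops — treated as
realism checks, never equality tests.

A PI controller with predictive feedforward (the quasi-static activation
inverse evaluated ~30 ms ahead) drives first-order activation
(τ_up 15 ms, τ_down 50 ms) so the model torque tracks the designed trace;
noise-free matching error stays below 2 %MVT in every condition. The
integrator relaxes the SEE stretch toward its force-balance equilibrium at
a rate capped by the force-velocity curve — a semi-implicit step that
cannot overshoot equilibrium, keeping the stiff low-force region stable at
any analysis sampling rate (results agree across 200 Hz–2 kHz). Sustained
tracking error above 20 %MVT for 0.5 s raises a simulation-failure error.

Observation models, chosen to exercise each pipeline stage:

* **Torque**: clean model torque + constant passive baseline (2 Nm) +
  signal-dependent noise — unit-variance low-pass-filtered (10 Hz) white
  noise scaled by CV × instantaneous torque, plus a small sensor floor.
  Putting the noise below the 20-Hz analysis cut-off makes the injected CV
  equal the measured CV by construction; it is observation noise, not fed
  back to the controller, so the measured hold-phase CV runs only a few
  percent above the injected value (controller wobble adds in quadrature).
  The default CV of 1.5% sits in the reported 1–4% range; per-condition
  `steadiness_effect` adds CV in Hold 2 of designated conditions (defaults
  +0.3% for the 0.25-s drop; +1.5% and +0.7% for the 85−15 and 85−30
  drops, the reported condition differences).
* **EMG**: a synthetic raw interference signal — 20–400 Hz band-limited
  Gaussian carrier amplitude-modulated by activation with multiplicative
  low-frequency noise and an additive floor, scaled so the envelope
  pipeline reads back activation (the mean of rectified unit-variance
  Gaussian noise is √(2/π)). The linear activation→amplitude map is a
  stated modelling choice; the true mapping is unknown.
* **Fascicle**: the model trajectory subsampled to ~34 frames/s with
  Gaussian tracking jitter (0.1 mm) and an optional drift ramp from onset
  (0 by default), emulating optical-flow tracking drift. Drift is only
  flagged, never corrected, matching the analysis's stated limitation.

The MVC generator drives activation open-loop to 1 with a 1% mid-plateau
"tent": human maximal effort peaks mid-hold, and a perfectly flat plateau
would put the filtered-signal maximum on the release corner's zero-phase
ringing, biasing the MVT reference low by ~3%.

`generate_dataset()` jitters per-subject parameters log-normally (defaults:
20% CV on strength, 8% on optimal length, 15% on tendon strain),
randomizes condition order within blocks, and emits trial CSVs with JSON
sidecars plus scalar ground truth, standing in for the study's deposited
raw data.

### What a green test does and does not establish

The generator reproduces the mechanistic structure (series-elastic recoil,
amplitude/rate orderings, signal-dependent steadiness noise, EMG nulls at
matched torque) but not: motor-unit discharge statistics or common-drive
structure in either torque fluctuations or EMG; antagonist co-contraction
and cross-talk; pennation or curvature of real fascicle geometry;
nonstationary tracking errors beyond a linear drift; or any history
dependence of muscle force (residual force enhancement/depression) — the
phenomena whose absence of signature the original experiments tested for.
Green pipeline tests therefore establish that the code measures what it
claims on data with known ground truth, not that the physiology behaves
this way.

## Degenerate inputs and tie-breaks

Zero-length descends are valid traces (Hold 1 flows into Hold 2); traces
whose solved hold durations go negative are infeasible-protocol errors.
An all-quiet trial has no onset (error, not 0). CV with non-positive mean
torque is an error, not NaN. Identical ANOVA cells give F = 0. Mauchly's
test needs more subjects than contrast dimensions; otherwise its p is NA
and no correction is applied (a singular contrast covariance counts as a
violation). The matching-error bound uses strict `>` with a warning at
exact equality.

## Test and acceptance budget

The unit suite runs in seconds at reduced simulator rates (explicit
`sim_config` fields, not hidden switches). The acceptance suite runs the
two Monte-Carlo calibrations at stated scale — 100 seeded datasets of
n = 14 for recovery of the +1.5% CV effect, 50 seeded datasets for the
null EMG rejection rate (α ± 2 Monte-Carlo SE) — in about six minutes on
one CPU.
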
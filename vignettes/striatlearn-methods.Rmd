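---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistics it implements:
what each model assumes, which parameters matter, how the synthetic-data
generator works and what passing tests do and do not establish about real
recordings.

```{r setup, message = FALSE}
library(striatlearn)
```

## The task and the data model

A session is a sequence of trials repeated every 20 s: an instruction tone
(high = 10 kHz or low = 2 kHz), lever insertion 3 s later, a press (right
is correct for high, left for low), and — on correct trials — a reward
sound after a 0.5 ± 0.2 s delay followed by licking. A `session_bundle`
stores trials, licks, per-unit spike times, mean waveform templates and
sorter-supplied quality metrics as five plain TSV tables. Timestamps are
seconds from recording start with 1 µs precision in files — ample for
20 kHz acquisition — and every binning operation in the package uses
half-open `[start, end)` intervals so no spike is counted twice at a bin
edge.

Omission trials (no press within the response window) keep their cue and
lever-insertion times but have no press, outcome credit, reward sound or
licks; they are retained because omission and success rates need them in
their denominators.

## Behavioral metrics and strategy scores

Success rate divides correct trials by *completed* (non-omission) trials.
Response bias is `(n_right − n_left) / (n_right + n_left)` over completed
trials and response time the mean press latency from lever insertion;
neither quantity has a single canonical definition in the field, so the
package uses these simplest forms and documents them here.

The strategy scores formalize two modes of control. Win-shift-win requires
`correct(t−1) ∧ cue(t) ≠ cue(t−1) ∧ press(t) ≠ press(t−1) ∧ correct(t)`:
the animal tracked the shifted cue, which only stimulus-response control
explains. Lose-shift-lose requires the same shift pattern bracketed by two
errors: the animal abandoned an unrewarded lever regardless of the cue,
the signature of response-outcome control. Both predicates need the
previous *and* current trial completed — against an omission, "pressed the
opposite lever" is undefined — so trials adjacent to an omission are
excluded from the counts (their completed neighbors still enter the
denominator, which is all completed trials of the session).

## The learning curve and stage windows

Daily success rates are fit with the four-parameter logistic
`f(x) = γ + (λ − γ) / (1 + exp(−β(x − α)))`, γ the lower asymptote
(chance ≈ 0.5 in a two-alternative task), λ the upper asymptote, α the
inflection day and β the slope in 1/day. The fit is bounded nonlinear
least squares (`0 ≤ γ < λ ≤ 1`, `β > 0`, α within the observed days ± 5)
via L-BFGS-B. The RSS surface is multimodal in (α, β), and no canonical
initialization exists, so the optimizer restarts from a deterministic 3 × 3
grid — α at the day quartiles, β ∈ {0.3, 1, 3} — and keeps the best
solution; on noiseless curves this recovers all four parameters to better
than 1e−3. A session set with identical rates leaves β unidentifiable; the
fit is then flagged `degenerate` rather than raising an error, and
crossing days are refused.

The crossing day for a fraction `p` of the rise solves
`f(t) = γ + p(λ − γ)` analytically, `t_p = α − ln((1−p)/p)/β`, and is
reported as `ceiling(t_p)` — the first whole day at or above the
threshold, which is what "the day the success rate reached p" means for
daily data. A 1e−6 guard inside the ceiling keeps fit noise from pushing
an exactly-integer crossing to the next day. Stage windows are then:
middle = {t20 − 1, t20, t20 + 1}; late = {t90 − 2, t90 − 1, t90}; early =
the three consecutive days immediately before the middle window, clamped
at day 1 (and shorter if clamped). "Up to 3 days before the middle stage"
could in principle be any earlier window; the immediately-preceding
reading is adopted as the only parameter-free choice. When a fast learner
collapses the two windows (t90 ≤ t20 + 2), the late stage keeps the
contested days and the middle stage retains only its non-overlapping
remainder.

## Unit quality and cell-type classification

The quality gate consumes the sorter's metrics — L-ratio < 0.05, isolation
distance > 15, ISI index < 0.2, strict inequalities so boundary values
fail — and never recomputes them: they require the sorter's feature space,
which the bundle deliberately does not carry.

Classification uses three measurements. Trough-to-peak width of the mean
template (global trough to the subsequent maximum) splits wide cells
(> 0.6 ms: MSNs and TANs) from narrow ones (FSIs and UIs). The long-ISI
proportion — the summed duration of ISIs longer than 2 s divided by total
recording time — splits FSIs (< 0.4) from UIs. Post-spike suppression
splits TANs (< 40 ms) from MSNs. Boundary values resolve by the strict
inequalities: exactly 0.6 ms is narrow, exactly 40 ms an MSN, exactly 0.4
a UI.

The autocorrelogram that feeds the suppression measure is estimated in
1-ms bins to 900 ms and normalized to a conditional rate,
`pairs(lag) / (n_spikes × bin width)` (Hz), so "the rate of the neuron is
equal to or greater than its averaged rate" is dimensionally meaningful;
the zero-lag self term is excluded by construction and the scan starts at
the first 1-ms bin. Its baseline is the mean over the 600–900 ms lags, and
the suppression is the length of the initial run of bins strictly below
that baseline. A silent 600–900 ms tail makes the baseline zero and the
measure undefined; this is raised as an explicit error rather than
returning 900 ms. No standard estimator convention exists for the ACG's
edge handling; pairs are simply truncated at the recording end, which
biases nothing at the recording lengths used here (≥ 600 s).

## Event-related detection

Completed trials are typed HR/LL/HL/LR by cue × press. For one unit and
one trial type, per-trial spike counts in a peri-event window are compared
with per-trial pre-cue baseline counts by the Wilcoxon rank-sum test at
p < 0.01, requiring at least 3 trials (fewer yields a `skipped` marker,
not an error). The four event windows are cue onset [0, +1000) ms, choice
response [−700, +300) ms, reward sound [−300, +300) ms and first licking
[0, +1000) ms. Two baseline windows exist, [−1500, −500) and
[−1100, −500) ms before cue onset; the package pairs the 600-ms baseline
with the 600-ms reward-sound window and the 1000-ms baseline with the
three 1000-ms windows so counts are length-matched (configurable through
`event_windows()`). Counts are converted to rates before testing — the
rank test is scale-invariant within a comparison, but rates keep
cross-window comparisons interpretable — and the response direction is the
sign of the median rate difference, consistent with the rank statistic.
Baseline counts come from the same trials being tested, not pooled across
types, so a type-specific baseline shift cannot masquerade as an event
response. `stats::wilcox.test` supplies exact small-sample p-values when
samples are small and untied and the tie-corrected normal approximation
otherwise.

Trials whose baseline or event window would extend beyond the recording
edges are dropped before counting. This matters: a truncated window
yields a systematically low count, and because the truncation pattern is
shared by every unit recorded in the session, it induces a *correlated*
bias that inflates across-unit tests well above their nominal level.

Sustained post-reward activity is measured on the trial-averaged 50-ms
PSTH for 5 s after the first lick: the count of bins strictly above the
baseline mean + 3 s.d., where mean and s.d. are taken across the pooled
single-trial 50-ms baseline bins of the same trials (taking the s.d.
across trial-averaged bins instead would shrink it by √n_trials and
flag noise; the pooled convention is the conservative reading). The
spike–lick correlation is a per-trial Pearson correlation of spike and
lick counts in the same 5-s window, after removing trials with zero
spikes; fewer than 3 retained trials or zero variance yields an undefined
marker.

## Population statistics

`auroc(a, b)` is `P(X_a > X_b) + 0.5 P(X_a = X_b)`, computed from midranks
(`U/(n_a n_b)`), hence exact under ties and invariant to monotone
transforms of the counts. The coding profile computes it per unit in
200-ms bins between a target and a comparison trial type; per bin, the
across-unit distribution is tested against 0.5. A two-sample rank-sum test
against the constant 0.5 is ill-posed, so the standard construction — the
one-sample Wilcoxon signed-rank of (auROC − 0.5) at p < 0.05 — is used.
Per-bin firing-rate contrasts between a target type and each other type
use the paired signed-rank across units at 50-ms resolution and are
suppressed below 6 paired units.

Matched-trial resampling equalizes power across stages: units with fewer
than 20 trials of the type are removed; for each remaining unit 20 trials
are drawn without replacement ("randomly selected" is read as without
replacement — resampling the same trial twice has no experimental
meaning); detection is re-run; and the percentage of responsive units
among *eligible* units (the internally consistent denominator, since
removed units were never tested) is recorded. Thirty repeats give a
distribution; repeats and units draw from sub-seeds derived
deterministically from one master seed, so a distribution is reproducible
in isolation. Stage distributions are compared by Kruskal–Wallis, with
pairwise Tukey–Kramer-style contrasts on rank means using the studentized
range distribution — the post hoc that matches the omnibus test's rank
scale.

## The synthetic-data generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth. Behavior: cues are balanced within each
4-trial block; each trial is an omission with probability `omission_prob`;
otherwise, after an error, the animal presses the lever opposite its
previous press with probability `lose_shift_prob` (the lose-shift habit),
and otherwise follows the stimulus rule with probability `f(day)` from the
same 4PL used in fitting. Correct trials get a reward sound at press +
U(0.3, 0.7) s and a ~7-Hz lick burst (regular with small Gaussian jitter
rather than Poisson — licking is stereotyped, and a regular burst gives
stable first-lick times) starting 0.1–0.3 s later. Defaults are chosen
once as realistic task conditions: 14 daily sessions of 180 trials (a
60-min session at one trial per 20 s), γ = 0.5 (chance), λ = 0.95,
α = 7 days, β = 0.8/day, 5% omissions, 20% lose-shift.

Spike trains are inhomogeneous Poisson: a baseline rate plus event-locked
kernels (boxcar or alpha-shaped, per event, per trial-type mask),
simulated by thinning a homogeneous process at the rate ceiling, then
silencing quiescent pauses, then enforcing an absolute dead time
sequentially. Thinning with an absolute dead time makes the imposed
post-spike suppression analytically known — the ACG is exactly zero below
the dead time — which is what lets the tests demand the suppression
estimate within ±2 ms of ground truth. The long-ISI proportion is
controlled by a two-state rate switch: pause onsets arrive as a Poisson
process and silence the train for a fixed duration, so the expected
quiescent fraction is `1 − exp(−rate × duration)` without touching the
waveform. Per-class presets place every metric at least twofold beyond its
threshold (MSN: 1.2 ms width, 3 Hz, 80 ms dead time; TAN: 1.3 ms, 5 Hz,
12 ms; FSI: 0.25 ms, 15 Hz; UI: 0.3 ms, 2 Hz, ~80% quiescence from 10-s
pauses). The paper-scale literature gives no canonical per-class baseline
rates, so these are field-plausible values, fixed once. Waveform templates
are piecewise-linear with sample-exact trough and peak positions —
adequate for testing the width measure, deliberately not realistic enough
for spike sorting.

All randomness descends from one master seed through a fixed integer
recurrence (`child_seed`), so any sub-generator (a day, a unit, a
resampling repeat) can be reproduced alone.

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: spike-sorting artifacts and drift (quality
metrics are written as given, not computed), inter-neuron correlations
(units are conditionally independent given the task events), history
effects in firing beyond the imposed dead time, session-to-session
non-stationarity, and waveform noise. Conclusions from the pipeline on
real recordings inherit the usual caveats of those phenomena.

## Problem sizes and numerical tolerances

The test-suite and acceptance scales are the package's own choices,
balancing statistical resolution against desk-scale runtimes: 2,000 null
units (30 trials each) bound the detector's type-I error within
[0.005, 0.02] at p < 0.01; 30 null cohorts of 30 units calibrate the
per-bin auROC and signed-rank flags to their nominal 5% (accepted within
±50% relative); 100 binomial replicates (100 trials/day, 14 days) require
t20/t90 recovery within ±1 day in ≥ 90%; 1,000 random count pairs (n ≤ 12)
must match exhaustive auROC enumeration exactly; and the staged end-to-end
run uses 30 units per stage with planted 20/50/80% cue responders, whose
resampled-proportion medians must increase monotonically. Matched-trial
subsampling deliberately trades power for comparability, so recovered
proportions sit somewhat below the planted fractions when effects are
near the detection margin; the planted-fraction recovery check therefore
uses strong effects where detection power is ≈ 1.

## Known limitations

Response bias and response time are pragmatic definitions, not literature
standards. The ACG estimator ignores edge truncation (negligible at
≥ 600 s but not for very short recordings). The signed-rank against 0.5
relies on the asymptotic approximation once auROC values tie heavily;
with very low counts per bin its level can drift within a few per cent of
nominal. L-ratio, isolation distance and ISI index are trusted as
provided. Group-level repeated-measures ANOVA across animals is out of
scope, as is any model of pharmacological manipulation.
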
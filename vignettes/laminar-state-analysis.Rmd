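---
title: "Laminar and state-modulation analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laminar and state-modulation analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamstate)
```

This vignette documents the scientific model behind each pipeline stage, the
parameters that matter and their defaults, what the synthetic-session
generator does and does not emulate, and the design decisions taken where
reasonable alternatives existed.

## The experimental design being analyzed

A head-fixed mouse on a spherical treadmill hears 600 ms white-noise (WN)
bursts at 80 dB with a 1 s inter-stimulus interval, randomly interleaved
with 600 ms silent blanks; each is presented with and without an 800 ms
laser pulse activating ChR2-expressing VIP interneurons, the pulse starting
50 ms before sound onset and ending 150 ms after sound offset, with at
least 30 repeats per stimulus-by-laser combination. A linear silicon probe
(25 µm site spacing) spans the cortical layers; running speed and
(optionally) pupil size are recorded alongside. The analysis asks how
locomotion and VIP activation each modulate spontaneous and sound-evoked
firing, whether those modulations differ by cortical layer and cell class,
and — the headline question — whether their combined effect equals the sum
of the effects measured separately, as expected if the two act through
independent circuits.

## Behavioral state

The running trace is smoothed with a 200 ms centered moving median
(`smooth_running`), which removes single-sample optical-tracker artifacts
without smearing bout edges. A trial is *running* when its mean smoothed
speed over the 600 ms stimulus window exceeds 5% of the session's maximum
smoothed speed (strict inequality, matching "above 5% of maximum"); a
session enters running/sitting contrasts only with ≥ 7 running trials.
Design choices made here, since the verbal description admits variants:

* "moving median average" is read as a moving **median** filter — the
  artifact-suppression purpose and the colloquial "median average" both
  point there;
* the maximum speed is taken from the **smoothed** trace so that threshold
  and trial means live on a single trace;
* only the stimulus window defines the trial's state — the analysis is
  trial-locked, not movement-onset-locked.

The caveat that follows from the ratio rule: in a session with no running
at all, baseline jitter makes "5% of max" a meaningless floor. The
inclusion rule (≥ 7 running trials, and in practice a sanity check on
`max_speed`) is what protects downstream analyses. The pupil-based arousal
gate flags samples above 60% of the maximum recorded pupil size; a
perfectly flat pupil trace carries no arousal modulation and yields an
empty mask.

## Laminar assignment from the evoked CSD

The LFP is band-passed 1–300 Hz with a zero-phase (forward–backward)
Butterworth filter — zero-phase because the *latency* of the sink is part
of its identification — and the CSD is the discrete second spatial
derivative across channels, `(v[j−1] + v[j+1] − 2 v[j]) / h²`. The
trial-averaged CSD over WN laser-off trials is searched 0–50 ms post onset
for its most negative value (the sink). A sink is accepted only when its
magnitude exceeds `k = 3` standard deviations of the trial-averaged
pre-stimulus CSD; this depth-of-modulation criterion is the package's
operationalization of a "robust" sink (no published quantitative rule
exists), and sessions failing it are excluded from laminar analyses while
remaining in everything else. The sink channel is anchored at 400 µm (the
L3/L4 boundary), each unit's depth is
`400 + (peak_channel − sink_channel) × 25 µm` using the channel with
maximal waveform amplitude, and layers follow the boundary table L1 0–128,
L2/3 129–380, L4 381–525, L5 526–805, L6 806–1200 µm (half-open intervals
at the integer boundaries so every depth maps to one layer). Layer L1,
essentially never populated in these recordings, is reported but excluded
from layer-group statistics by default.

## Cell classes from waveforms

Width is the time from the waveform's global trough to the subsequent
positive peak — the extracellular trough-to-peak convention; the source
description ("distance from the peak to the trough") does not fix an order,
so the convention is explicit and configurable. Narrow-spiking (NS) means
width < 0.5 ms *and* negative end-slope; width ≥ 0.5 ms is regular-spiking
(RS); sub-threshold width with nonnegative end-slope matches neither rule
and is left `unclassified` rather than forced. The end-slope epoch is the
final 0.2 ms of the template (least-squares slope) — the epoch length is a
package decision, checked to be insensitive for templates whose tails decay
monotonically. All features are amplitude-scale invariant.

## Responses and modulation indices

Firing rates are spike counts in half-open windows `[t0, t1)` divided by
window length, so boundary spikes count exactly once. Onset responses use
0–100 ms after stimulus onset, offset responses the 100 ms after stimulus
offset, and spontaneous rates the full 600 ms stimulus-equivalent window on
the interleaved blanks. Sound-responsiveness is a two-sided rank-sum test
between onset-window rates on WN trials and the *matched* 100 ms window on
blanks (sitting laser-off, p < 0.01), and only increases qualify — which is
what bounds the sitting laser-off MI to [0, 1]. The MI itself contrasts the
onset-window evoked rate with the full-window blank spontaneous rate; the
internal consistency check is that the published population means reproduce
the published laser-off MI under exactly this pairing. Response latency is
the first post-onset time where the 15 ms-smoothed 5 ms-bin PSTH crosses
half its post-onset peak (halfway between 0 Hz and the peak, not between
spontaneous and peak), linearly interpolated between bins, with the first
crossing as tie-break; a zero peak leaves latency undefined.

Trial-count floors: each condition MI requires ≥ 7 WN and ≥ 7 blank trials
(the same floor as the running-trial inclusion rule, symmetric evidence on
both sides of the contrast; configurable). An MI whose rates are both zero
is undefined and excluded pairwise, never imputed.

## The additivity test

Per unit, the running effect, VIP effect, predicted combined effect (their
sum) and observed combined effect are the four differences defined in the
README. `additivity_test` reports the Spearman rank correlation between
predicted and observed — rank-based to match the nonparametric statistics
used throughout, and because the population of effects is heavy-tailed —
plus the OLS fit of observed on predicted (slope, intercept, r²) and
single-predictor comparison fits. The matched-subsampling utility redraws
`n_running` sitting trials without replacement 100 times and recomputes the
population sitting MI each time, with a paired signed-rank test against the
running MI per repeat; its RNG stream is independent of the generator's, so
the same analysis seed reproduces on any input.

Two quantitative facts about this test, established with the package's own
generator and worth knowing before interpreting ρ on real data:

* with additive *rate* increments, additivity in **MI** space is only
  approximate — MI is a ratio, and its curvature leaves a small systematic
  super-additive residual (mean observed − predicted ≈ +0.05 to +0.1 for
  effect spreads like those here) even with unlimited data;
* the attainable ρ is noise-limited by the scarce running trials. At a 13%
  running fraction and 100 trials per stimulus-by-laser combination, ~13
  running trials per condition put ≈ 0.16 SD of estimation noise on each
  per-unit effect whose true spread is ≈ 0.3–0.4 SD, capping ρ near 0.8 —
  the same order as values reported from comparable recordings. Longer
  sessions or higher running occupancy move ρ toward its curvature-limited
  ceiling (≈ 0.97).

An injected multiplicative interaction (generator option
`interaction_scale < 1`) produces the sub-additive signature robustly: the
observed-on-predicted slope falls far below 1 (≈ 0.3 at scale 0.4).

## Population–speed coupling timescale

`distance_correlation` implements the classical (biased) sample estimator:
double-centered pairwise Euclidean distance matrices, dCov² as the mean
elementwise product, dCor = dCov/√(dVarX·dVarY), defined as 0 when either
variable is constant. It accepts the n_units × n_bins rate matrix against
univariate speed directly. `dcor_sweep` bins both signals on a ladder
doubling from 50 ms, subtracts the mean over shuffled speed vectors, and
reports a permutation p-value in steps of 1/n_shuffles (default 50
shuffles). Choices: speed is bin-averaged (not subsampled) so coarse bins
conserve bout energy; the shuffle permutes the *binned* speed vector; the
ladder ceiling is configurable (methods descriptions of such sweeps quote
both 40 s and 12.8 s ceilings — the cap only matters if the recording is
long enough to supply ≥ 4 bins). Full permutation destroys all temporal
structure and therefore overstates significance for autocorrelated signals;
a circular-shift option is provided as the conservative alternative, with
permutation kept as the default for fidelity to the standard shuffle
control. A useful implementation identity: double centering commutes with
permuting samples, so shuffles reuse the centered matrices.

## Group statistics

Effect sizes use r = z/√N with z the Wilcoxon statistic on the normal scale
(midranks, tie correction, continuity correction — implemented directly
since `wilcox.test` does not expose z) and N the total number of cases,
i.e. twice the sample size for paired comparisons. Layer contrasts use
Kruskal–Wallis followed, when significant, by pairwise rank-sum tests at
the Bonferroni-corrected threshold alpha / n_pairs exactly.

## The synthetic-session generator

`generate_session` emulates: the interleaved four-combination schedule at
1.6 s period; bout-structured running (exponential dwell times, mean bouts
5 s running / 33 s sitting giving ≈ 13% running trials, per-bout speeds
≈ 7 cm/s with 200 ms raised-cosine ramps, 0.02 cm/s stationary baseline);
Poisson spiking with additive condition increments (spontaneous baseline
Γ(1, 4.87) Hz; onset/offset evoked gains; running increments +1.27 Hz RS /
+2.70 Hz NS spontaneous and ≈ −3.5 Hz evoked; laser increments +1.5 Hz on
both, all with across-unit spreads matching published SEM·√N values;
evoked gains are divided by the fraction of the 100 ms window following the
mean 15 ms latency so that *measured* window rates hit the calibration
targets); NS/RS waveform templates with class-separated widths and
exponential amplitude decay across channels (length constant 60 µm); a
stimulus-evoked LFP dipole centered at the channel nearest 400 µm
(alpha-function time course peaking ≈ 12 ms, Gaussian spatial profile of
35 µm, 100 µV amplitude) over spatially smooth temporally correlated noise
(75 µV); and a pupil trace elevated around running bouts. One master seed
drives labelled sub-streams (schedule, running, units, spikes, waveforms,
LFP, pupil), so identical parameters give byte-identical sessions, and
analysis seeds are scoped separately. Rates clipped at zero are flagged per
unit in the ground truth so recovery tests can exclude saturated units.

What it deliberately does **not** emulate: refractoriness or spike-history
structure (all downstream statistics are rate-based), biophysical LFP
generation beyond the single evoked dipole, waveform realism beyond
width/end-slope/amplitude-decay, and slow nonstationarities (drift,
adaptation). Passing recovery tests therefore demonstrates correctness of
the estimators under Poisson variability and the stated effect structure —
not robustness to drift or non-Poisson dispersion in real recordings.

`generate_coupled_population` targets one analysis specifically: a latent
Ornstein–Uhlenbeck state with configurable correlation time drives both the
(rectified) speed trace and every unit's log-linear rate gain, so the only
structure shared between speed and spiking lives at that timescale; with
zero gain it is the exact null.

## Validation problem sizes

The shipped tests exercise: exact closed forms (MI bounds and effect
ranges by grid search; CSD on linear profiles, unit bumps and
superpositions; distance correlation against an independent naive
double-centering oracle on 100 random instances up to n = 200); recovery
(sink localization within ±1 channel over 100 noisy seeds; layer labels on
a 120-unit session; NS/RS classes across the width range at three
amplitude scales; additivity on 100 units × 100 trials/combination with and
without an injected interaction; the 0.4 s coupling timescale over 20 seeds
of 20 units × 240 s); and calibration (null rejection rate of the
layer-group test over 1000 replicates; population rate targets at 235
units). These sizes were chosen as the smallest at which the respective
statistics are stable.

## Known limitations

* The MI-space additivity test has the curvature ceiling and
  running-trial noise floor described above; raw-rate additivity (evoked
  and spontaneous separately) is less affected because the spontaneous
  estimate uses the full blank window.
* The 5%-of-max running rule is scale-free and therefore degenerate on
  sessions without genuine running; rely on the inclusion flag.
* Permutation-based dcor significance is anticonservative under strong
  autocorrelation at coarse bins; use the circular-shift option when that
  matters.
* The CSD sink criterion assumes a single dominant short-latency sink;
  sessions with ambiguous laminar CSD are meant to be excluded, not forced.
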
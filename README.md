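# lamstate

Laminar and behavioral-state analysis of extracellular recordings from
auditory cortex.

Movement changes how sensory cortex responds to stimuli: in auditory cortex,
locomotion raises spontaneous firing but suppresses sound-evoked firing, so
the neural contrast between sound and silence shrinks while the animal runs.
Optogenetic activation of VIP (vasoactive intestinal peptide-expressing)
disinhibitory interneurons also reshapes firing. A central question is
whether these two modulations share a mechanism. `lamstate` implements the
complete analysis by which that question is answered with linear-probe
recordings: laminar depth assignment from the stimulus-evoked current source
density (CSD), running/sitting trial classification from a speed trace,
narrow-/regular-spiking cell classification from spike waveforms, sound
modulation indices under the four state-by-laser conditions, an additivity
(interaction) test between the running and laser effects, and a
shuffle-corrected distance-correlation analysis of the timescale on which
running couples to population firing. A calibrated synthetic-session
generator with full ground truth backs every stage with recovery tests.

It is intended for systems neuroscientists analyzing trial-based awake
ephys sessions (sorted spikes + trial table + behavior traces + optional
LFP), and for anyone who needs the individual statistics (distance
correlation, Wilcoxon effect sizes, CSD) as tested building blocks.

## The core quantities

For each unit and condition (state ∈ {sitting, running} × laser ∈ {off, on}),
with E the mean firing rate 0–100 ms after white-noise onset and S the mean
rate during interleaved silent blanks:

    sound MI = (E − S) / (E + S)            ∈ [−1, 1]

Units enter the analysis only if they respond to sound with a significant
rate *increase* (rank-sum p < 0.01, sitting laser-off), so MI_sit,off ∈ [0, 1].
The effect decomposition is

    running effect    = MI(run, off) − MI(sit, off)          ∈ [−2, 2]
    VIP effect        = MI(sit, on)  − MI(sit, off)          ∈ [−2, 2]
    predicted combined = running effect + VIP effect         ∈ [−4, 4]
    observed combined  = MI(run, on)  − MI(sit, off)

If running and VIP activation act through independent mechanisms, observed ≈
predicted (linear additivity, the epistasis logic); a sub-additive
interaction drives the regression slope of observed on predicted below 1.

Depths come from the evoked CSD, `csd[j] = (v[j−1] + v[j+1] − 2 v[j]) / h²`
on 25 µm-spaced channels after zero-phase 1–300 Hz filtering: the
short-latency sink marks the layer-3/4 boundary and is anchored at 400 µm
(layers: L1 0–128, L2/3 129–380, L4 381–525, L5 526–805, L6 806–1200 µm).
Population–speed coupling is the distance correlation between the
n_units × n_bins rate matrix and binned running speed, minus its mean over
shuffled speed vectors, swept across bin sizes doubling from 50 ms.

## Worked example

```r
library(lamstate)

g <- generate_session(generator_params(n_units = 40, n_trials_per_combo = 100,
                                       seed = 108))
s <- g$session

lab <- label_trials(s$trials, smooth_running(s$running))
cat(sprintf("running trials: %d of %d (max speed %.1f cm/s)\n",
            lab$n_running, nrow(s$trials), lab$max_speed))
s$trials <- lab$trials

sink <- locate_sink(compute_csd(s$lfp), s$trials)
cat(sprintf("evoked CSD sink: channel %d, latency %.0f ms\n",
            sink$sink_channel, 1000 * sink$sink_latency_s))
s$units <- assign_depths(s$units, sink, spacing_um = s$lfp$spacing_um)
s <- classify_cells(s)

mods <- modulation_set(s)
cat(sprintf("sound-responsive units: %d; MI sitting %.2f, running %.2f\n",
            nrow(mods), mean(mods$mi_sit_off, na.rm = TRUE),
            mean(mods$mi_run_off, na.rm = TRUE)))
at <- additivity_test(mods)
cat(sprintf("additivity: rho = %.2f (p = %.2g), slope = %.2f, r2 = %.2f, n = %d\n",
            at$rho, at$p, at$slope, at$r2, at$n))
```

Output:

```
running trials: 43 of 400 (max speed 9.2 cm/s)
evoked CSD sink: channel 11, latency 14 ms
sound-responsive units: 34; MI sitting 0.63, running 0.26
additivity: rho = 0.81 (p = 5.3e-07), slope = 0.44, r2 = 0.39, n = 33
```

Reading: the mouse ran on ~11% of trials; the sink lands on the channel the
generator placed at 400 µm; sound modulation drops during running (0.63 →
0.26) as the spontaneous rate rises and the evoked rate falls; and the
observed combined running+laser effect is strongly rank-correlated with the
arithmetic sum of the two effects measured separately — the additive
(independent-mechanism) signature. `run_pipeline(s)` performs all of the
above plus subsampling, the distance-correlation sweep and layer statistics,
and returns a machine-readable report.

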
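---
title: "Methods: canine TMR sleep analysis in caninetmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canine TMR sleep analysis in caninetmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninetmr)
```

`caninetmr` implements the computational pipeline of a targeted-memory-
reactivation (TMR) sleep study in family dogs: sleep-macrostructure scoring
variables, stage-restricted EEG spectra, adaptive sleep-spindle detection,
non-REM-gated cue scheduling, and latency-based behavioral learning
statistics, together with a synthetic-data generator that gives every stage
a known ground truth. This vignette explains the models and procedures, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic validation does and does not show.

## Sleep macrostructure

Canine polysomnography is scored in 20-s epochs over four stages: wake,
drowsiness, non-REM and REM. Drowsiness is a real transitional stage in
carnivores — it carries features of both quiet wakefulness and light
non-REM sleep — so sleep onset is genuinely ambiguous, and the package
exports *two* latencies and *two* WASO (wakefulness after sleep onset)
variables: anchored at the first drowsiness epoch and at the first non-REM
epoch. `macrostructure()` returns nine variables: sleep efficiency,
relative wake, both latencies, both WASOs, and relative drowsiness, non-REM
and REM durations.

Two conventions needed fixing:

- **Drowsiness counts as sleep** in the efficiency numerator by default.
  With a typical 2-h nap containing roughly 25 min drowsiness, 58 min
  non-REM and 12 min REM, only this convention reproduces efficiencies
  near 79 %; counting drowsiness as wake would put it near 59 %. The
  switch `drowsiness_is_sleep = FALSE` selects the stricter convention.
- **WASO counts WAKE epochs only.** Drowsiness after sleep onset is a
  scored sleep stage here, not wakefulness.

A stage that never occurs yields `NA` for its latency and WASO — short
daytime naps can lack REM entirely, and a sentinel zero would be wrong in
both directions.

## Stage-restricted spectra

`stage_psd()` computes Welch-style average periodograms from 4-s windows
with 50 % overlap, per-window mean removal and a Hann taper, using only
windows that lie wholly inside a contiguous run of same-stage epochs and
touch no artifact-flagged time. Artifact intervals are snapped outward to
the 4-s subepoch grid on which manual rejection is performed. A 4-s window
gives exactly 0.25 Hz resolution, so a "0.25 Hz bin" is a single FFT
coefficient; the analysis grid is 1.00–30.00 Hz inclusive, 117 bins.
Relative power divides each bin by the sum over the grid, which removes
amplifier gain and electrode impedance scale: the result is invariant to
any positive rescaling of the signal. No wake spectrum is computed — wake
EEG in unrestrained dogs is dominated by muscle artifact.

Band summaries use half-open bands delta [1, 4), theta [4, 8),
alpha [8, 12) and beta [12, 30], so the bands partition the grid and a
shared endpoint such as 4.00 Hz belongs to the higher band.

**Taper leakage.** A Hann taper spreads even a perfectly on-grid sinusoid
over a three-coefficient mainlobe with amplitude weights 1/4, 1/2, 1/4:
exactly 2/3 of a spectral line's power lands in its own coefficient and
1/6 in each neighbour. Localization checks in the tests therefore assert
that more than 99 % of a 10 Hz tone's power falls within 10 ± 0.25 Hz and
that the 10.00 Hz bin is the maximum — not that a single coefficient holds
99 % of the power, which no cosine taper can achieve.

## Adaptive spindle detection

Sleep spindles are transient sigma-band bursts in non-REM EEG lasting at
least 0.5 s. The detector is an adaptive amplitude–frequency algorithm:

1. Band-pass 9–16 Hz (4th-order zero-phase Butterworth) and form an RMS
   envelope over a 0.125-s sliding window. Only samples inside non-REM
   epochs and outside artifact intervals are eligible; envelope statistics
   are computed over exactly these samples.
2. **Initial detections**: maximal envelope runs above mean + 2 SD lasting
   ≥ 0.5 s (after merging runs separated by < 0.1 s).
3. **Refit**: event amplitude (peak envelope) and event frequency
   (reciprocal of twice the mean zero-crossing half-period, measured over
   the event core where the envelope is at least half its peak) are fitted
   with maximum-likelihood Gaussians — sample means and SDs of independent
   univariate normals, fitted separately for the slow (< 13 Hz) and fast
   (≥ 13 Hz) populations present among the current detections.
4. **Re-detect**: candidate events are envelope runs above a *lower*
   boundary threshold (mean + 0.25 SD, ≥ 0.5 s); a candidate is accepted
   when its amplitude and frequency both fall inside either subtype's
   fitted mean ± 2 SD window.
5. Iterate 3–4 until the overlap-matched symmetric difference between
   successive event sets falls below 1 % of the current count, or 10
   iterations.

Detected events are classified slow (< 13 Hz) or fast (≥ 13 Hz, boundary
inclusive). Density is events per artifact-free non-REM minute;
`averaged_density()` gives the within-subject mean across recordings — the
trait estimate that correlates better with cognition than any single
recording's density.

Four numerical choices deserve comment:

- **Per-subtype acceptance windows.** Slow and fast spindles form a
  bimodal frequency distribution; a single Gaussian fitted over the
  mixture centres on whichever subtype dominates and its acceptance
  window then extinguishes the rarer one entirely (in synthetic runs with
  ten fast among forty slow events, every fast event was rejected).
  Fitting the windows per subtype and accepting candidates that match
  either mirrors the slow/fast separation the field's detectors apply.

- **Two thresholds.** A Hann-shaped burst of nominal duration 0.5 s spends
  well under 0.5 s above a mean + 2 SD envelope threshold, so measuring
  duration at the strict detection threshold silently discards the
  shortest legitimate spindles. The strict threshold decides *that* an
  event population exists (and on spindle-free noise it fires essentially
  never, so noise recordings yield empty event lists); the low boundary
  threshold measures each event's true extent, with false candidates
  removed by the fitted amplitude/frequency acceptance window rather than
  by raw amplitude.
- **Acceptance-width floors.** When the detected population is homogeneous
  the fitted SDs can collapse below the intrinsic jitter of per-event
  estimates (zero-crossing frequency jitters by a few tenths of a Hz), and
  a literal ± 2 SD window would then reject valid events. The frequency
  half-width is floored at 1 Hz and the amplitude half-width at 25 % of
  the fitted mean.
- **Core-based frequency.** Zero crossings are counted where the envelope
  is ≥ half the event peak; the low-amplitude tails of an event are
  background-dominated and bias frequency estimates toward the band
  centre, which matters at the 13 Hz classification boundary.

The defaults (threshold 2 SD, acceptance 2 SD, 9–16 Hz, 0.125-s envelope)
are a documented reconstruction of this detector family, not a replication
of any specific prior implementation, and all are exposed in
`detector_params()`.

## Cue scheduling

The online TMR rule is replayed deterministically over a stream of 30-s
stage estimates: once two consecutive non-REM epochs have elapsed, a bout
starts at the next epoch and the cue fires every 5 s on a grid anchored at
bout start (first cue at t + 0 — "every 5 s" leaves the phase free, and
anchoring at onset is the simplest deterministic reading). Any non-NREM
epoch aborts the bout instantly; no cue is emitted in that epoch. New bouts
may start when the criterion is re-met (configurable, since the protocol's
manual interruption leaves resumption unspecified), and scheduling stops
permanently once cumulative stimulation reaches 300 s — the "~5 min" of
stimulation is modelled as a hard, testable cap, with each cue accounting
for one 5-s inter-cue interval. The online stream is deliberately
independent of the offline 20-s hypnogram; `validate_schedule()` audits a
schedule against the offline scoring and reports any cue falling in a
non-NREM offline epoch.

## Behavioral statistics

Each dog contributes 15 baseline and 15 post-sleep test trials; each trial
records the baited location, the cue class, correctness and response
latency.

- **Cueing benefit** = proportion correct among cued test trials −
  proportion correct among cued baseline trials. Both cued sides are
  pooled; the definition names no side split.
- **Latency reduction** (per correctness class) = mean baseline latency /
  mean test latency. The ratio of per-class means is used rather than a
  mean of per-trial ratios because baseline and test trials are unpaired.
  Values above 1 mean faster post-sleep responses.
- **Relative latency reduction** = latency reduction of correct trials /
  latency reduction of incorrect trials. A value above 1 says responses
  that end correctly sped up more than responses that end incorrectly — a
  learning signature robust to any global rescaling of latencies (timing
  equipment, dog size). Dogs lacking a correctness class in either phase
  have no defined value and are excluded from correlations, with a count
  reported.

With ~7 trials per correctness class and phase, the relative latency
reduction is a ratio of ratios of small-sample means: it is median-unbiased
for the generative ratio, but its *mean* carries a positive Jensen bias
(about +0.10 at a generative value of 1.6 under the synthetic latency
model). Group summaries of this statistic should prefer medians or
log-scale means.

**Bin-by-bin scans and the Rüger procedure.** `binwise_scan()` correlates a
per-subject outcome with relative power at each of the 117 bins (Pearson r,
two-sided p from the t transform on n − 2 degrees of freedom, missing
subjects dropped bin-wise with per-bin n recorded). Because neighbouring
bins are strongly dependent, per-bin correction would be both too harsh and
wrongly targeted; instead contiguous runs of conventionally significant
bins (p < 0.05) form *Rüger areas* that are accepted or rejected as a
whole: an area is significant iff at least half of its member p-values are
below α/2 **and** at least one third are below α/3. Fractions are compared
exactly (a 3-bin area needs 2 of 3 below α/2, since 2 ≥ 1.5) with strict
inequalities at the thresholds, and "its members" means all bins of the
area — they are all below α by construction. Grid edges count as area
boundaries.

## The synthetic-data generator

The generator emulates the study design the pipeline targets, with every
default chosen once as a realistic study condition:

- **Hypnogram**: a semi-Markov chain on 20-s epochs starting in wake, with
  geometric dwell times (means: wake 4, drowsiness 5, non-REM 12, REM
  3.5 min) and an embedded transition matrix in which wake always enters
  drowsiness and drowsiness enters non-REM with probability 0.85. The
  implied stationary occupancy (embedded stationary distribution weighted
  by dwell means, `stationary_occupancy()`) is roughly 9 % wake, 23 %
  drowsiness, 60 % non-REM, 8 % REM — a sleepy afternoon nap, biased
  toward wake early in finite recordings because they start awake.
- **EEG**: per channel, 1/f-amplitude-shaped Gaussian background (20 µV
  RMS) plus a stage oscillation as an amplitude-modulated sinusoid
  (drowsiness 7 Hz, non-REM 1.5 Hz delta, REM weak 6 Hz). Spindle bursts
  are Hann-windowed sinusoids with per-event frequency drawn from the
  subtype Gaussian (slow 11 ± 0.4 Hz, fast 14.5 ± 0.4 Hz — means clear of
  the 13 Hz boundary so ground-truth subtypes are unambiguous), peak
  amplitude 3× the background RMS, and duration uniform on 0.5–1.5 s.
  Bursts are placed wholly inside single non-REM epochs, clear of each
  other and of artifacts; the injected count is density × artifact-free
  non-REM minutes, so the injected density is exactly recoverable.
  Artifact subepochs (2 % of the 4-s grid) receive a large low-frequency
  transient. Samples are quantized to float32 at generation so written
  signal files round-trip bit-exactly.
- **Behavior**: baited locations cycle the fixed semirandom block order
  (ABC, ACB, CAB, CBA, BAC), so each location is baited exactly five times
  per 15-trial phase and never twice in a row. One side is the cued side,
  counterbalanced by dog-index parity. Correctness is Bernoulli on a
  configurable logit (default: chance-ish accuracy with no cued shift —
  the difficulty regime where latency, not accuracy, carries the learning
  signal); latencies are lognormal (median 5 s, σ_log 0.45) with
  post-sleep latencies divided by a correct-trial factor (2.0) and an
  incorrect-trial factor (1.25), floored at 0.3 s for physical
  plausibility.
- **Between-dog traits**: each dog's trait fast-spindle density and
  correct-trial latency factor are lognormal around the shared defaults
  (σ_log 0.6 and 0.5), optionally correlated on the latent Gaussian scale
  (`density_effect_corr`). Dogs vary enormously in spindle density —
  reference samples show coefficients of variation well above 1 — so
  these spreads are conservative, and they keep between-dog signal above
  within-dog measurement noise, which is what gives recovery analyses
  their power.

All randomness flows through seeded generators; per-dog sub-seeds are
derived deterministically, and the full bundle is a pure function of
(parameters, seed).

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
hand-enumerated macrostructure examples; a brute-force window counter for
the spectral pipeline; ground-truth injection records for the detector; a
brute-force run-finder and counter for the Rüger procedure (1,000 random
117-bin p-vectors); direct enumeration for the cue scheduler; and exact
arithmetic identities for the behavioral statistics.

The end-to-end check generates 200 replicate studies of 16 dogs under
`recovery_sim_params()` — 6-min recordings at 128 Hz on one channel, a
nap structure that reaches non-REM within a minute or two, and a latent
density–effect correlation of 0.6 — runs the full pipeline (detection →
density → trait averaging → behavioral statistics → correlation), and
requires the recovered correlation to be positive in at least 95 % of
replicates. The reduced recording length and sampling rate keep hundreds
of replicates tractable while exercising every pipeline stage at realistic
signal-to-noise; detection behaves identically at 1,024 Hz. The
measurement chain attenuates the latent 0.6 to a recovered mean near
0.4 — attenuation is expected whenever noisy estimates stand in for true
traits, and the sign, not the magnitude, is the recovery target. The
bin-scan's type-I error is checked at 1,000 null studies (nominal 0.05
± 0.02).

What passing these tests shows: the implementations compute their defined
quantities correctly, the detector recovers known injected densities
within ±20 % with ≥95 % subtype accuracy at the default signal-to-noise,
and the pipeline propagates a real association through all its stages.
What they do not show: performance on real canine EEG, whose spindles are
not Hann-windowed sinusoids, whose artifacts are not confined to a 4-s
grid, and whose stage transitions are not semi-Markov. The generator's
amplitude distributions are placeholders, not calibrated claims about dog
physiology.

## Known limitations

- The detector's defaults are a reconstruction; on real data the sigma
  band, thresholds and envelope window should be revisited per montage.
- Density denominators use artifact-free non-REM minutes; with heavy
  artifact load this differs from total non-REM time.
- Mixed-model analyses of accuracy and latency are deliberately out of
  scope: the package exports tidy per-trial and per-dog tables for any
  external GLMM tool.
- EDF input/output is not provided; signals use a float32 + JSON header
  pair, and any EDF source should be converted upstream.
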
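# caninetmr

Analysis tools for canine targeted-memory-reactivation (TMR) sleep studies.

Family dogs are an emerging noninvasive model for sleep-dependent memory
consolidation: they sleep readily in afternoon polysomnography sessions, and
their sleep spindles and EEG spectra track learning much as in humans. In a
TMR protocol a dog learns verbal commands tied to locations, then naps while
one of the learned commands is replayed during non-REM sleep, and is tested
again after waking. `caninetmr` implements the complete computational
pipeline such a study needs:

- **Hypnogram macrostructure** — the nine standard variables from 20-s-epoch
  scoring over wake / drowsiness / non-REM / REM: sleep efficiency, relative
  wake, two sleep latencies and two WASO variants (anchored at first
  drowsiness and first non-REM, because canine sleep onset passes through a
  scored drowsiness stage), and relative stage durations.
- **Stage-restricted spectra** — Welch-style power spectral densities on the
  Fz–Cz derivation from 4-s Hann-tapered windows with 50 % overlap, wholly
  inside one sleep stage and artifact-free, expressed as relative power on
  the 1–30 Hz grid at 0.25 Hz (117 bins) with delta/theta/alpha/beta band
  summaries.
- **Adaptive spindle detection** — sigma-band (9–16 Hz) amplitude–frequency
  detection restricted to non-REM: an initial envelope threshold
  (mean + 2 SD, events ≥ 0.5 s) seeds maximum-likelihood Gaussian fits of
  event amplitude and frequency, which define an acceptance window for
  iterative re-detection; events are split into slow (< 13 Hz) and fast
  (≥ 13 Hz) spindles, with densities per artifact-free non-REM minute and
  within-subject averaged (trait) densities.
- **Cue scheduling** — a deterministic replay of the online cueing rule: a
  bout starts after two consecutive 30-s non-REM epochs, cues fire every
  5 s, any non-NREM epoch aborts the bout, and cumulative stimulation is
  capped at ~5 min; plus an offline audit against the scored hypnogram.
- **Behavioral statistics** — cueing benefit (post-sleep − baseline accuracy
  of cued trials), latency reduction (pre/post latency ratio per correctness
  class), relative latency reduction (correct/incorrect ratio of those
  ratios), bin-by-bin Pearson scans of spectra against outcomes, and the
  Rüger-area multiple-comparison correction: maximal runs of p < 0.05 bins
  accepted as a whole iff at least half their p-values are < α/2 and at
  least a third are < α/3.
- **Synthetic data with ground truth** — a generator for semi-Markov
  hypnograms, 1/f EEG with stage oscillations and injected spindle bursts at
  known density, artifact intervals, cue logs, and per-dog behavior with
  configurable post-sleep latency effects, so every stage of the pipeline is
  testable without animal data.

All user-facing functions take data frames first and return tibbles, so the
pieces chain with the pipe; result objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(caninetmr)

# a scored nap: 9 epochs of 20 s
macrostructure(c("W", "W", "D", "N", "N", "R", "N", "W", "W"))
#> # A tibble: 1 × 9
#>   sleep_efficiency relative_wake sleep_latency1_min sleep_latency2_min ...
#> 1             55.6          44.4              0.667                  1
```

Sleep efficiency is 55.6 % (5 of 9 epochs asleep, drowsiness included),
sleep latency is 0.667 min to first drowsiness and 1 min to first non-REM,
and 0.667 min of wake follows sleep onset.

A full synthetic study, end to end:

```r
p  <- recovery_sim_params()          # 16 dogs, known ground truth
st <- gen_study(p, seed = 1)

# detect spindles on every recording and average within dogs
traits <- study_spindle_densities(st)$traits

# behavioral statistics per dog
beh <- behavior_summary(st$trials)

# does trait fast-spindle density track the latency-based learning measure?
cor(traits$trait_density_fast, beh$relative_latency_reduction,
    use = "complete.obs")
#> [1] 0.751   (one replicate; the injected latent correlation is 0.6)
```

The cue scheduler on the canonical stream — one wake epoch, one drowsiness
epoch, then ten non-REM epochs of 30 s:

```r
s <- schedule_cues(c("W", "D", rep("N", 10)))
glance(s)
#> # A tibble: 1 × 5
#>   n_cues n_bouts total_stim_s first_cue_s last_cue_s
#> 1     48       1          240         120        355
```

Cueing begins 120 s in (after two full non-REM epochs) and fires every 5 s
until non-REM ends at 360 s: 48 cues.

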
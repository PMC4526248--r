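# runsync

Simulation and analysis of **spontaneous entrainment of running cadence to
music tempo**.

Runners listening to music whose tempo sits close to their step rate tend to
fall into step with the beat without being told to — and without noticing,
provided the tempo manipulation stays below the ~4 % detection threshold.
`runsync` packages the whole experimental logic of such a study as testable
code, for movement scientists and auditory–motor coupling researchers who
want to prototype protocols, validate analysis pipelines, or study the
entrainment basin in simulation:

* a **117-song stimulus library** (id, artist, title, label, year, tempo in
  BPM) with BMRI-2 motivational scoring and tempo-window song selection;
* the **four-lap protocol**: a silent lap, a lap of cadence-matched music,
  then two laps in which the tempo ramps to one of eleven shifts
  (−3.00 … +3.00 % in the set {±3, ±2.5, ±2, ±1.5, ±1, 0}), with unique
  per-participant condition orders;
* a **circle-map runner simulator**: the next inter-step interval is
  corrected by the phase error between the last footfall and the nearest
  beat, `I_{n+1} = T_c − (K·T_b/2π)·sin(2πφ_n) + ε`, which phase-locks
  exactly when the relative detuning is below `K/2π` (the entrainment-basin
  half-width) — plus synthesis of 100 Hz tri-axial accelerometer traces;
* **step detection** (band-pass 1–5 Hz, adaptive-threshold peak picking,
  refractory period) and cadence estimation;
* the two outcome measures: **cadence adaptation**
  `avg(SPM_TCL)/avg(SPM_TML)` with the 5 s head / 20 s tail trimming rule,
  and the **tempo-entrainment score** (percentage of steps within 1 % of the
  concurrent BPM);
* the **statistical battery**: Lilliefors-corrected KS normality check,
  one-way repeated-measures ANOVA with a linear trend contrast, Friedman
  test, paired Wilcoxon comparisons of every condition against the 0 %
  control at a Bonferroni-corrected α = .005, Mann–Whitney gender and
  training comparisons, and a Spearman correlation of entrainment with
  perceived exertion (Borg RPE 6–20).

Everything is tibble-first and pipe-friendly; test results carry
`tidy()`/`glance()` methods and result objects have plot functions
(`plot_basin()`, `plot_adaptation()`, `plot_timeline()`).

## Worked example

```r
library(runsync)

run <- run_experiment(list(seed = 1))
#> stage simulate    192 records    19.14 s
#> stage score       176 records    14.08 s
#> stage analyze       8 records     0.07 s
#> stage export        5 records     0.35 s

print(run$report)
#> == entrainment report ==
#> <sync_test> Lilliefors (KS) normality test: D = 0.06282, df = 176, p = 0.08708
#> <sync_test> RM-ANOVA condition effect: F = 36.21, df = 10, p = 3.9e-35
#> <sync_test> RM-ANOVA linear contrast: F = 44.65, df = 1, p = 7.329e-06, r^2 = 0.749
#> <sync_test> Friedman rank test: chi-squared = 55.19, df = 10, p = 2.904e-08
#> <basin_result> entrainment_pct vs control, Bonferroni alpha = 0.005
#> flagged conditions: +2.5% +3.0%
#> <sync_test> Mann-Whitney U test: U = 2, Z = 3.070, p = 0.002143, r^2 = 0.589
#> <sync_test> Spearman rank correlation: rho = -0.0354, p = 0.6409
```

Reading these numbers: the simulated cohort's cadence adaptation follows the
tempo shift (a strong condition effect with a dominant linear trend), the
per-condition entrainment scores differ (Friedman), and the paired Wilcoxon
follow-ups flag the **+2.5 % and +3.0 % conditions as significantly less
entrained than the 0 % control** at the corrected .005 level — the
entrainment basin's edge. The more strongly coupled female runners entrain
more than the male runners (Mann–Whitney p ≈ .002), and entrainment is
unrelated to perceived exertion (ρ ≈ −.04). `run$metrics` holds the tidy
16 × 11 participant-by-condition table behind all of this, and
`plot_basin(run$report$basin)` draws the basin.

Lower-level pieces compose the same way:

```r
lib <- read_stimulus_library()            # 117 songs, one flagged out-of-range
tl  <- tempo_timeline(+2, reference_bpm = 160, lap_durations = rep(72, 4))
st  <- simulate_steps(list(preferred_cadence = 160, coupling = 0.16,
                           motor_noise_sd = 0.01), tl, seed = 1)
tr  <- synth_accel(st, seed = 2)
det <- detect_steps(tr)
entrainment_score(det, tl, trim_tcl_window(144, 288))
```

A thin CLI over the same functions lives at `inst/cli/runsync.R`
(`simulate`, `detect`, `score`, `analyze`, `run-all` subcommands).

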
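# qeegr

Quantitative EEG analysis of early post-resuscitation recovery.

After resuscitation from cardiac arrest, cortical activity recovers through a
stereotyped sequence — isoelectric (flat) EEG, then burst suppression, then
continuous background activity. The speed of that progression, the frequency
of bursts while suppression lasts, and the spectral makeup of the restored
background carry prognostic information about hypoxic-ischemic brain injury,
especially in experiments on therapeutic hypothermia. `qeegr` implements this
analysis for two-channel rodent EEG (300 Hz, microvolts, time origin at the
return of spontaneous circulation):

* **Burst detection** — rectified amplitude > 10 µV required on *both*
  channels, events merged when separated by less than 0.5 s of sub-threshold
  signal (the interburst-interval rule).
* **Epoch classification** — nonoverlapping 60 s epochs labeled
  `isoelectric`, `burst_suppression` or `continuous`.
* **Recovery metrics** — burst onset time, burst-frequency time course, and
  the time of recovery of continuous background activity (persistence rule).
* **Spectral entropy** — per epoch, a Welch averaged periodogram (10 s
  segments, 50% overlap, linear detrend, Hanning window) is integrated over
  the delta (0.5–4 Hz), theta (4–8 Hz), alpha (8–13 Hz) and beta (13–30 Hz)
  bands; with X_i the band powers,

      p_i = X_i / sum_j X_j,      SE = -sum_i p_i log2(p_i) / log2(N),  N = 4

  so SE = 1 means power spread evenly across bands and SE = 0 means a single
  dominant band. SE is averaged over the left and right channels.
* **Outcome statistics** — neurologic deficit score (NDS, 0 = no deficit to
  500 = brain death) validation and totals, Welch t tests from raw samples
  *or* printed mean/SD/n summaries, Fisher's exact test, two-way ANOVA with
  per-time post hoc tests, Kaplan–Meier + log-rank survival analysis,
  Spearman correlation, and single-predictor logistic regression for
  survival.
* **Synthetic generator** — two-channel records with the three-stage
  recovery structure (inhomogeneous-Poisson bursts, band-mixture continuous
  background) and a two-arm cohort with NDS and survival outcomes, every
  generating parameter logged so the analysis can be validated by parameter
  recovery.
* **I/O and pipeline** — EDF and CSV signal formats, cohort/metrics/entropy
  CSVs, a YAML-configurable end-to-end pipeline (`run_pipeline()`) and a thin
  command-line wrapper (`inst/scripts/qeeg-pipeline.R`).

## Worked example

```r
library(qeegr)

# a synthetic record: flat for 60 s, burst suppression until 240 s with the
# burst rate ramping 8 -> 16 bursts/min, then continuous background activity
prof <- stage_profile(isoelectric_end = 60, bs_end = 240,
                      burst_rate = data.frame(t_min = c(0, 3), rate = c(8, 16)))
rec <- generate_recording(prof, continuous_spec(total_rms = 30),
                          fs = 300, duration = 360, seed = 42)

fit <- qeeg(rec)   # condition -> detect bursts -> classify -> metrics -> entropy
summary(fit)
#> Quantitative EEG summary
#>   epochs: 6  |  bursts: 43
#>
#>       isoelectric burst_suppression        continuous
#>                 1                 3                 2
#>   burst onset:        1.1 min
#>   recovery time:      4 min
#>   mean SE (continuous epochs): 0.822
```

The record's six 60 s epochs split into one isoelectric, three
burst-suppression and two continuous epochs; the first burst is detected
1.1 min after ROSC (the stage nominally ends at 1 min — the first burst event
is the observable boundary), continuous activity is recovered at 4 min
(true boundary 240 s), and the flat-spectrum background sits at the
theoretical flat-PSD entropy 0.824 (measured 0.822).

Group comparisons work from raw samples or from published summary
statistics:

```r
welch_t_summary(15.1, 1.9, 10, 21.5, 6.0, 10)   # burst onset, treated vs control
#> 	Welch two-sample t test (from summaries)
#> t = -3.2157, df = 10.787, p-value = 0.008419

fisher_exact_2x2(6, 4, 0, 10)$p.value           # 96 h survival 6/10 vs 0/10
#> [1] 0.01083591
```

A full synthetic study — 2 × 10 animals, per-animal EEG analysis, group
statistics, survival analysis, output files and a reproducibility manifest —
is one call:

```r
res <- run_pipeline(pipeline_config(cohort_spec(seed = 1), out_dir = "out"))
print(res)
```

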
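# neurocultr

Quantification of neuronal network development and morphology in cultured
cortical neurons, built for two-genotype comparisons such as wild-type versus
haploinsufficient (e.g. *Setd5*⁺/⁻) primary cultures. The package is aimed at
cellular neurophysiology labs that record multielectrode-array (MEA)
activity, calcium imaging and immunofluorescence from the same cultures and
want one reproducible, tested pipeline from raw signals to group statistics.

It implements:

- **MEA activity** — spike detection at |V| ≥ 6σ with σ = MAD/0.6745,
  active electrodes at ≥ 5 spikes·min⁻¹, weighted mean firing rate
  (spikes on active electrodes / *n*<sub>active</sub>·*T*), network bursts
  (≥ 5 electrodes co-firing in 25 ms bins, gaps < 100 ms merged), and a
  chance-corrected synchrony index
  SI = (C − n₁n₂·2w/T) / (√(n₁n₂) − n₁n₂·2w/T) averaged over electrode
  pairs, clipped to [0, 1].
- **LFP spectra** — zero-phase 500 Hz low-pass, Welch PSD (2 s Hann
  segments, 50% overlap, density-normalized), band power over 1–10 Hz and
  100–150 Hz, and the per-day development curve
  log₁₀(P<sub>day</sub>/P<sub>first day</sub>).
- **Calcium imaging** — running-percentile ΔF/F, transient detection, and a
  correlated-firing response ratio: the fraction of active cells whose
  correlation with the population mean exceeds the 95th percentile of their
  circular-shift surrogates.
- **Morphometry** — SWC I/O, Sholl intersections at 10 µm circle steps,
  total outgrowth and soma area, Laplacian-of-Gaussian puncta detection, and
  pre/post colocalization density in puncta per 50 µm of neurite.
- **Group statistics** — pooled or Welch two-sample *t* from raw data *or*
  printed mean/SEM/n summaries, two-way ANOVA (genotype × DIV), exact
  Mann–Whitney *U*, and Benjamini–Hochberg FDR.
- **A synthetic cohort generator** with known ground truth (spike trains
  with controllable burst breadth and synchrony, raw voltage, calcium
  traces, morphologies, puncta fields), so every stage is testable without
  recordings.

Results come back as tibbles; fitted objects have `tidy()`/`glance()`
methods and result types have `autoplot()`/`plot_*()` methods.

## Worked example

Simulate one well for 10 minutes and summarize its network activity:

```r
library(neurocultr)

sim <- simulate_spike_trains(sim_profile(duration_s = 600, seed = 1))
activity_summary(sim$spikes)
#> # A tibble: 1 × 6
#>   wmfr_hz n_active burst_freq_per_min burst_freq_normalized mean_burst_breadth
#>     <dbl>    <int>              <dbl> <lgl>                              <dbl>
#> 1    3.17        8                5.5 FALSE                               7.98
#> # ℹ 1 more variable: synchrony_index <dbl>
```

All eight electrodes are active, firing at 3.2 Hz on average; the detector
recovers the generator's ~6 bursts/min recruiting essentially the whole
array (mean breadth 8.0 of 8 electrodes).

Two groups described only by published summary statistics can be compared
directly — here soma areas of 257.7 ± 16.2 µm² (n = 39) versus
216.2 ± 11.19 µm² (n = 33):

```r
wt  <- group_summary(257.7, 16.2, 39, "wt")
het <- group_summary(216.2, 11.19, 33, "het")
pooled_t(wt, het)
#> Two-sample t (pooled): t = 2.033, df = 70, p = 0.0458
```

The smaller group differs by 41.5 µm² and the difference is significant at
α = 0.05. `recompute_published_stats()` runs this for all six bundled
endpoints and reports each recomputed *t* beside the printed value (all
agree within 0.15%).

A full synthetic cohort — simulation, all analysis stages, and the
genotype × DIV statistics table — is one call:

```r
res <- run_pipeline(cohort_config(n_animals = 6, seed = 1))
res$stats
```

or from a shell, `Rscript inst/scripts/run_pipeline.R --out results/ --seed 1`
(optionally with a YAML cohort config).

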
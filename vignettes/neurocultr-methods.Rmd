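---
title: "Methods: quantifying network development in cultured cortical neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying network development in cultured cortical neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocultr)
```

neurocultr quantifies how a neuronal network matures in vitro, and how that
maturation differs between two genotypes — the typical use case being a
wild-type versus haploinsufficient (e.g. *Setd5*^+/-^) comparison of primary
cortical cultures. It covers five assays (multielectrode-array spiking, LFP
spectra, calcium imaging, single-neuron morphometry, synaptic puncta), the
statistics used to compare groups, and a synthetic-data generator that stands
in for recordings so every stage can be tested against known ground truth.
This vignette explains each model, the tunable parameters and why their
defaults are what they are, the numerical choices, and what passing tests do
and do not establish about real data.

## MEA spike and network-burst analysis

Recordings are modeled as 8 electrodes per well sampled for 30 minutes, the
standard serial-recording protocol for these cultures. The analysis chain
applies three criteria:

* **Spike detection** — a sample is a spike candidate when its absolute
  voltage reaches 6 sigma above noise. The noise sigma is estimated as
  `MAD / 0.6745` (`estimate_noise_sigma()`); a robust estimator is essential
  because the spikes themselves would inflate a plain SD. Detection uses both
  polarities (extracellular fields are biphasic) and collapses crossings
  within a 1 ms refractory window to the largest-amplitude sample.
* **Active electrodes** — at least 5 spikes/min over the whole recording,
  inclusive at the boundary. Whether the criterion should be evaluated over
  sliding windows is not standardized; we evaluate over the full recording.
* **Network bursts** — spikes from active electrodes are binned at 25 ms; a
  bin with at least 5 distinct electrodes firing is a burst bin, and runs of
  burst bins separated by less than 100 ms merge into one burst. Breadth is
  the number of distinct electrodes firing inside the burst interval. The
  binned detector reproduces the ">= 5 electrodes" set criterion
  deterministically; commercial MEA software implements proprietary variants
  of the same idea.

**Weighted mean firing rate** is the total spike count on active electrodes
divided by (number of active electrodes x duration), i.e. the mean
per-electrode rate over active electrodes only — silent electrodes affect
neither numerator nor denominator. **Normalized burst frequency** is
reported as bursts/min per well; division by the active-electrode count is
available (`normalize_burst_freq = TRUE`) and flagged in the output, since
the normalization conventions differ between acquisition systems.

**Synchrony index.** Vendor synchrony metrics are unpublished, so the package
defines its own chance-corrected coincidence index. For electrodes *i*, *j*
with spike counts *n~i~*, *n~j~* over duration *T*, coincidences *C* are
spike pairs within ±20 ms, the chance expectation is *E = n~i~n~j~·2w/T*, and
the pair score is *(C − E)/(√(n~i~n~j~) − E)*, clipped to [0, 1] and averaged
over pairs. Identical trains score exactly 1, independent Poisson trains
score ≈ 0, and the score decreases as spike-time jitter grows past the
window. Because the definition is ours, its validation is by these
properties, not by comparison with vendor numbers; absolute values should not
be compared across software.

## LFP band-power ratio timecourse

The LFP is the raw signal low-pass filtered at 500 Hz with a zero-phase
(forward–backward) 4th-order Butterworth filter; filter family and order are
a package choice, recorded in output metadata. Spectra are Welch averages of
Hann-tapered, demeaned 2 s segments with 50% overlap, normalized as a
one-sided density so that the integral over frequency equals signal variance
(verified by a Parseval check in the tests). Band power integrates the
density over 1–10 Hz (network-depolarization transients) or 100–150 Hz
(broadband/high-gamma, an index of aggregate local firing) by the
trapezoidal rule with interpolated band edges.

Development is summarized as `log10(P_day / P_first)` per band, with the
first recorded day — 8 DIV by convention in the pipeline defaults — exactly 0.
The ratio is invariant to any common gain (amplifier units cancel), which is
the point of baselining. Whether published curves averaged electrodes, wells
or animals before the ratio is ambiguous; the pipeline averages band power
over electrodes within a well first (one curve per well/animal) and retains
the electrode-level powers.

## Calcium correlated-firing ratio

Traces are normalized to ΔF/F with a running 10th-percentile baseline
(30 s window). The baseline percentile is evaluated every quarter-window and
interpolated, which is indistinguishable from a dense scan for baselines that
drift on the window timescale. Transients are runs above 3 robust SDs lasting
at least 0.5 s; cells with at least one transient are "active".

The **correlated firing response ratio** — the fraction of active cells
participating in network-correlated activity — is not given a formula in the
literature that reports it, so the package defines one explicitly: each
active cell's statistic is the zero-lag Pearson correlation with the mean
trace of the other active cells; its null distribution is obtained from
circular time-shift surrogates of that cell (random rotations preserve the
trace's autocorrelation while destroying alignment); the cell is correlated
when its statistic exceeds the (1 − α) surrogate quantile, α = 0.05. The
ratio is flagged undefined below two active cells. Correlation is computed on
ΔF/F rather than binarized events for robustness at low event counts. The
implementation computes all rotations at once via FFT cross-correlation,
which is algebraically identical to correlating the rotated series.

This definition is validated by calibration: on independent cells the ratio
concentrates near α (the test uses 20 seeds of 50 cells), on fully coupled
noiseless cells it is exactly 1, and it is monotone in the generator's
coupling. Published absolute ratios (e.g. 0.292 vs 0.053) come from
unreleased recordings under an unpublished definition and are deliberately
not acceptance targets.

## Morphometry

Reconstructions are SWC node tables with a single soma root; the reader
rejects cycles and forward parent references with line numbers. **Sholl
analysis** counts neurite segments whose endpoint distances from the soma
centroid straddle each circle of radius 10, 20, ... um; a crossing exactly at
a radius counts once (upper-inclusive). Distances are in-plane by default
because tracings of cultured neurons are two-dimensional projections; a 3-D
flag exists. **Outgrowth** sums neurite segment lengths; **soma area** is
πr² from the root radius. All three are invariant under rigid motions
(tested).

**Puncta.** Pre/post channels are detected with a scale-normalized
Laplacian-of-Gaussian (sigma matched to the punctum PSF, 3x3 local maxima,
sub-pixel quadratic refinement; plateau ties broken by scan order so a spot
centered between pixels yields one detection). Colocalization is one-to-one
greedy nearest-neighbor matching under a 0.5 um center distance — a typical
synapse-scale tolerance; no published value exists for these data, so the
radius is a config value logged with results. Density is pairs per 50 um of
neurite, the customary reporting unit.

## Group statistics

* `pooled_t()` is the pooled-variance two-sample t (df = n1 + n2 − 2), which
  is the variant that reproduces published t statistics recomputed from
  printed mean/SEM/n (all six bundled endpoints agree within 0.15%; the
  residual is SEM rounding). Welch's form is a flag. Groups can be raw
  vectors or `group_summary(mean, sem, n)` objects interchangeably.
* `two_way_anova()` fits the crossed fixed-effects model with interaction
  when replicated. Balanced designs use sequential (Type I) sums of squares,
  which partition the total exactly; unbalanced designs fall back to Type II
  with a warning (the designs this package mirrors are balanced). In
  degenerate zero-residual fits, zero-SS terms get F = 0 and true effects
  F = ∞ instead of unstable 0/0 ratios.
* `mann_whitney_u()` uses midrank ties; p values are exact by enumerating all
  rank splits for n1 + n2 ≤ 20 (valid under ties, unlike the classical no-tie
  exact distribution) and the tie-corrected normal approximation with
  continuity correction beyond that. The enumeration cap keeps the worst case
  at choose(20, 10) = 184,756 splits.
* `bh_fdr()` applies the Benjamini–Hochberg step-up rule and reports standard
  monotone adjusted values, so a flag is equivalent to `adjusted <= q`.

## The synthetic cohort generator

The generator's defaults are the study conditions the analyses were designed
for, chosen once:

| Parameter | Default | Rationale |
|---|---|---|
| electrodes / duration | 8 / 1800 s | one MEA well, 30 min protocol |
| background rate | 1 Hz | sparse spontaneous firing of mature cultures |
| burst rate / duration | 6 min⁻¹ / 0.5 s | typical culture network-burst statistics |
| within-burst rate | 50 Hz | dense burst firing; keeps bursts contiguous at 25 ms binning |
| synchrony coupling | 0.8 | strongly but imperfectly synchronized mature network |
| calcium: 50 cells, 10 Hz, tau 0.2/1.5 s | — | Fluo-4-like indicator kinetics at imaging frame rates |
| morphology target | 848 um, 3 trunks, soma r 9.06 um | wild-type means (848.1 um outgrowth, 257.7 um² soma, 3.3 neurites) |
| puncta | 0.37/um, colocalization 0.6 | ≈ 11 colocalized puncta per 50 um, wild-type density |

Burst onsets are a homogeneous Poisson process; each burst recruits a uniform
electrode subset of size `participation x n_electrodes`; within-burst spikes
are a shared mother train thinned per electrode with probability
`synchrony_coupling` plus an independent complement at
`(1 − coupling) x rate`, so coupling moves synchrony without changing the
expected in-burst rate. A recruited electrode that drew no spike receives one
uniform spike so the returned ground truth is always consistent with the
data. Raw voltage renders each spike as a 2 ms biphasic template at
`amp_sigma x noise SD`, plus optional sinusoids and noise synthesized in the
frequency domain with PSD ∝ 1/f^χ (χ = 1 matches the broadband character of
culture spectra; χ = 0 gives white noise for detector calibration). Calcium
traces convolve shared-drive and private events with a unit-peak difference
of exponentials. Morphologies grow gamma-length segments with angular drift
and bifurcation probability per segment, stopping exactly at the target
length. All generators are deterministic in their seed.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: electrode crosstalk and drift, spike waveform diversity
and overlapping units, non-Poisson burst initiation dynamics, calcium
indicator saturation and bleaching, photon shot noise, neurite fasciculation
and z-projection artifacts, and any genuine genotype effect size. Tests
establish that the estimators recover known structure under controlled
conditions, not that the biological effect sizes are reproduced.

## Pipeline

`run_pipeline()` takes a `cohort_config()` (per-genotype generator profiles,
animals per genotype, recording days, master seed) and runs the stages per
animal and day, then compares genotypes: pooled t across per-animal endpoints
and genotype x DIV two-way ANOVA for longitudinal metrics, with one
well/animal as the replicate unit (per-neuron analysis is available by
operating on the per-row tables directly). Activity metrics run on the
simulated spike trains; synthesized voltage feeds the LFP stage. Spike
detection from voltage is validated separately — this stage separation keeps
cohort runs at desk scale while every link of the raw-voltage chain is still
tested. Per-animal failures are logged and skipped, never fatal. Every output
row carries a manifest hash computed from the scientific configuration (not
the output path), and rerunning the same configuration reproduces tables
byte-for-byte.

Seeds for every animal/day/stage derive deterministically from the master
seed via hashing, truncated to stay within R's 32-bit integer range.

## Problem sizes

The bundled tests and the acceptance script use 600 s recordings for detector
validation (8 electrodes at 5 kHz), 300–1500 s calcium simulations at 10 Hz,
20-seed calibration ensembles, and 10⁴ null simulations for type-I error —
sizes chosen so the full suite completes in a couple of minutes on a single
core while keeping Monte Carlo error well inside the asserted tolerances.

## Known limitations

* The synchrony index and correlated-firing ratio are package-defined
  substitutes for unpublished vendor/ad hoc metrics; compare trends, not
  absolute values, against other software.
* The LFP stage assumes stationarity within a recording; no time–frequency
  analysis is provided.
* Sholl is 2-D by default; genuinely 3-D reconstructions should set
  `use_3d = TRUE`.
* ROI segmentation, spike sorting and neurite tracing from images are out of
  scope; the package starts from traces, spike times/voltage, and SWC files.
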
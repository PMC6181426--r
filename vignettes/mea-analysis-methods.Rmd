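---
title: "Methods: multi-well MEA spike-train analysis with meaplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-well MEA spike-train analysis with meaplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaplate)
library(dplyr)
```

## The problem

A multi-well microelectrode array (MEA) plate carries dozens of culture
wells, each with a grid of extracellular electrodes (typically 16,
positions 11–44). Cultured neuronal networks fire spontaneously; after
spike detection (done upstream — this package never sees voltage traces)
each electrode contributes a *spike train*, a sorted vector of action
potential timestamps. An experiment records the same plate repeatedly over
days in vitro (DIV), and wells carry *treatment* labels — genotype, drug,
concentration — that we want to compare statistically.

`meaplate` turns these spike lists into a catalogue of well-level activity
features, at four levels of organization:

1. **Spikes** — firing rates, inter-spike intervals, activity gating.
2. **Bursts** — short periods of elevated firing on one electrode.
3. **Network spikes (NS)** — ~10 ms volleys of coincident firing across a
   well.
4. **Network bursts (NB)** — long (hundreds of ms to seconds)
   synchronized bursting intervals across a well.

plus pairwise synchrony metrics (spike time tiling coefficient, mutual
information, entropy), empirical distributions of burst features, and a
permutation-based statistical layer for comparing treatments across
recordings.

## Data model and activity gating

A recording is a tibble of spikes (`time`, `electrode`, `amplitude`) plus
an electrode table mapping electrodes to wells and within-well positions,
bundled by `mea_recording()`. Electrode names are parsed as
`"<well>_<rowcol>"` by default; the regex is configurable for other
vendors. When the file carries no duration, the recording end defaults to
`ceiling(last spike time)`. Amplitudes are parsed but unused — no feature
in the catalogue consumes them.

An electrode is **active** when its mean firing rate reaches
`min_rate` (default 5 spikes/min, a common MEA convention; the activity
criterion itself is a free design choice and is exposed as a parameter).
Activity gates everything downstream: well statistics are computed over
active electrodes, and wells need a minimum number of active electrodes
(default 4, i.e. 25% of a 16-electrode well) to survive multi-recording
filtering.

## The feature catalogue

The aggregated inventory is **70 features**: 8 spike, 19 burst, 10 NS and
33 NB (11 per smoothing window × 3 windows). Alongside, the per-recording
spiking table reports **11 well-level spiking statistics** — the 8 spike
features plus the three synchrony means (STTC, mutual information,
normalized entropy), which are reported as statistics but not aggregated.
The exact composition of the 8/11/19/10/33 lists is this package's own
enumeration (`spike_feature_names()` and friends); the counts are fixed,
the names are documented reconstructions.

### Bursts

Two detectors with identical downstream features:

* **Maximum Interval** (`detect_bursts_max_interval()`), NeuroExplorer
  semantics with defaults 0.1 s (max begin ISI), 0.25 s (max end ISI),
  0.8 s (min inter-burst interval for merging), 0.05 s (min duration), 6
  (min spikes). The defaults are conventional, not canonical — all five
  are parameters.
* **Poisson Surprise** (`detect_bursts_poisson_surprise()`): the surprise
  of a run of `n` spikes spanning `d` seconds is
  `S = -log10 P(X >= n | X ~ Poisson(rate * d))` with the electrode's mean
  rate; seeds (stretches of ISIs below half the mean ISI) are greedily
  extended and trimmed while `S` increases, runs with `S >= 5` are kept,
  and overlaps resolve toward higher `S` (ties toward the longer burst).

Well burst features average over *bursting* electrodes only (electrodes
with zero bursts contribute missing values, not zeros); whether to
average over all electrodes instead is a genuinely open choice — we chose
bursting-only so that sparse wells do not dilute burst shape statistics.

### Network spikes

Spike times are binned into tumbling 10 ms windows and the number of
distinct electrodes firing per bin is counted; a contiguous run of bins at
or above the threshold (default `max(4, 25%)` electrodes) is one NS, its
peak the maximum bin (earliest on ties). A sliding window would be the
alternative reading; tumbling bins are the default because they make the
event extent and the "separated by a sub-threshold bin" rule unambiguous.
Spikes "in" an NS are those inside the above-threshold run — the event
extent is otherwise undefined. The around-peak profile counts distinct
electrodes in 100 ms bins spanning ±1 s of each peak, averaged over
events; note the central 100 ms bin can only count *more* electrodes than
the 10 ms peak bin, so the profile dominates the peak count rather than
equalling it.

### Network bursts

Following the smoothing-and-threshold scheme: each electrode train is
binned at 2 ms (fine enough that a bin almost never holds two spikes;
collisions collapse to one with a warning), convolved with a Gaussian
kernel, and standardized to max 1. The standardized electrode signals are
averaged, re-smoothed with the same kernel, and re-standardized — in that
order; standardizing before combination weights every active electrode
equally regardless of its rate. Otsu's method (256-level histogram,
between-class variance maximization; ties break toward the middle of the
maximal plateau so the threshold centers in an empty gap) then marks
above-threshold intervals as NBs.

Two choices here are ours, documented because the scheme leaves them
open:

* The kernel's σ equals the window size converted to bins (windows 10,
  20, 50 ms by default), truncated at ±3σ and normalized to unit sum.
* Candidate intervals with fewer than `max(4, 25%)` participating
  electrodes are discarded. Otsu always splits its input; on a sparse
  asynchronous well the "high" class would otherwise be the set of
  isolated single-electrode bumps, yielding spurious NBs. The
  participation filter reuses the plate's own activity convention.

### Synchrony metrics

* **STTC** (`sttc()`): with `P_A` the proportion of A's spikes within ±Δt
  of a B spike and `T_A` the tiled fraction of the recording,
  `STTC = ½[(P_A − T_B)/(1 − P_A T_B) + (P_B − T_A)/(1 − P_B T_A)]`.
  Δt defaults to 0.05 s; tiles are clipped at the recording boundaries.
  The well statistic is the unweighted mean over all N(N−1)/2
  active-electrode pairs — any distance dependence of correlation is
  deliberately ignored.
* **Entropy** (`spike_entropy()`): Shannon entropy of the per-bin spike
  mass function (0.1 s bins), base 2; normalized by `log2(n_bins)`.
  Base 2 is used for both entropy and MI for consistency.
* **Mutual information** (`pairwise_mutual_information()`): bin counts
  are binarized at the electrode's 75th percentile (linear-interpolation
  quantile, strict `>`, so ties at the percentile map to 0 — a bin is a
  "burst member" only when clearly above typical counts), and MI is
  computed on the resulting 2×2 joint distribution. The well feature is
  the mean over pairs; the full pair distribution is retained
  (`well_mutual_information()`) for treatment-level tests.

### Burst-feature distributions

Five features — IBI, ISI within bursts, spikes per burst, burst duration,
spike frequency within bursts — get per-electrode normalized histograms
on fixed grids (30 bins; maxima 20 s, 0.5 s, 200, 3 s, 300 Hz; the
duration and frequency caps are user-facing conventions, the others are
package defaults), values above the cap clipped into the last bin, and
electrodes with fewer than 5 bursts excluded. Histograms are averaged
(unweighted, renormalized) by well and then by treatment. Distances
between treatments: 1-D earth mover's distance (area between CDFs, in
bin-width × probability units) and maximum CDF distance; p-values by
shuffling well treatment labels while each well's electrode histograms
stay intact, `p = P(permuted distance >= observed)` with no smoothing (p
may be exactly 0). Single-recording comparisons use the two-sample K-S
test on pooled raw values (pooling raw values rather than histogram means
is our reading of "comparing probability distributions" for a single
recording).

## Multi-recording statistics

`aggregate_features()` builds one wells × recordings table per feature;
`filter_wells()` removes wells active (≥ `min_ae` electrodes) in *no more
than* half the recordings (strict inequality). `mw_permutation_test()`
then pools each well's values across recordings into its treatment's
sample, runs a two-sided Mann–Whitney test (normal approximation with
continuity correction — group sizes here are far beyond exact-test
territory), and permutes well labels (whole wells move; within-well time
series stay intact, preserving temporal correlation) to get
`p_perm = P(permuted MW p <= observed MW p)`. Label shuffles are simple
resampling without enforcing distinctness. No multiple-testing correction
is applied across the 70 features by default — the permutation p is
reported per feature; a Benjamini–Hochberg adjustment can be added by the
user with `p.adjust()` on the `glance()` output.

## The synthetic-data generator

`simulate_recording()` produces plates with known ground truth: per
electrode a homogeneous Poisson background (default 1 Hz), electrode-level
bursts as fixed-ISI packets (10 ms ISI, 6–20 spikes, 3/min), and NB
events that place coincident packets on a sampled electrode subset
(default 80% participation, 2/min, onsets jittered ≤ 20 ms to exercise
the smoothing windows). Treatment multipliers scale rates per well.
These defaults are meant as a plausible active cortical culture; the
packet model is deliberately simple.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: refractory periods, rate nonstationarity
across the recording, electrode-to-electrode rate heterogeneity within a
well, bursts with decelerating ISIs, partial/propagating network events,
or amplitude structure. The statistical calibration results (below) are
about the testing machinery, not about biological effect sizes.

`simulate_mfr_table()` is a count-level shortcut for calibration studies:
it draws per-electrode Poisson spike counts directly, which for the MFR
feature is distributionally identical to measuring full simulated trains
at a small fraction of the cost.

## Numerical choices and problem sizes

* Signals are convolved via FFT (`stats::convolve`); negative round-off
  is clamped to zero before standardization.
* Degenerate inputs: empty trains give empty burst lists and `NA`
  statistics (never zeros); constant synchronization signals are
  degenerate for Otsu and yield zero NBs; constant binary vectors give
  MI = 0; wells with < 2 active electrodes give `NA` synchrony means.
* STTC terms with a zero denominator (`P·T = 1`) contribute 0.
* Validation problem sizes, chosen to keep the full suite at desk scale:
  the end-to-end scenario uses three recordings (40, 60, 60 s) of a
  48-well, 16-electrode plate with 100 permutations; NB recovery uses 20
  seeds × 120 s single-well recordings; null calibration uses 200
  replicates of a 12-vs-11-well, 8-recording design at 50 permutations;
  power uses 100 replicates at 100 permutations.

## Known limitations

* The 8/11/19/10/33 feature name lists are reconstructions; other
  implementations may enumerate differently while keeping the same counts.
* The Poisson Surprise search is greedy (seeded, extend-and-trim); it is
  validated against an exhaustive scan on small trains but is not
  guaranteed globally optimal on pathological inputs.
* EMD/MD operate on a shared fixed grid; features with heavy tails beyond
  the grid cap are compared only through their clipped mass.
* Permutation p-values are unsmoothed proportions: with `n_perm = 100`
  the smallest attainable p is 0, and granularity is 0.01.
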
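---
title: "Noise-responsive fasciculation detection and voluntary-activity exclusion in grid surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise-responsive fasciculation detection and voluntary-activity exclusion in grid surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasctools)
```

## The problem and the model

Surface EMG of a relaxed muscle records two kinds of motor-unit discharge.
Fasciculation potentials arise from the random, spontaneous firing of single
motor units; their firing is well modelled as a homogeneous Poisson process,
so their inter-spike intervals are exponential except for a sharp deficit at
very short intervals caused by the absolute refractory period, and for
occasional multiplet discharges (paired firings at < 50 ms). Voluntary
motor-unit firing, by contrast, is *regular*: at low force, units fire at
roughly 4–12 Hz, concentrating inter-spike intervals in the 84–250 ms band.
Counting fasciculations therefore requires two exclusions: epochs too noisy
to threshold reliably, and epochs of voluntary firing whose regular trains
would otherwise inflate the count dramatically.

The pipeline quantifies a recording in four stages, each exposed as a
documented function and each validated against the synthetic generator's
ground truth.

### Detection

An amplitude screen keeps, per channel, only the most extreme samples — the
positive threshold sits at the $1 - f/2$ amplitude quantile and the negative
at the $f/2$ quantile with $f = 0.02$, so strictly supra-threshold samples
occupy less than 2% of the channel (type-1 quantiles make the bound exact).
These extremes are the peaks and troughs of motor-unit potentials. Crossing
runs are padded by 10 ms and merged within a channel; concurrent events
across channels are then collapsed into single potentials on a
*super-channel*, each sourced from the channel with the greatest peak–trough
amplitude.

Each potential's local noise level is its *noise band*: the mean positive
amplitude minus the mean negative amplitude over the one-second windows
flanking its span (other potentials' spans are masked out; an empty sign
class contributes zero, which keeps the statistic defined on rectified-like
segments; a fully masked window leaves the noise band undefined and the
potential excluded). For pure Gaussian noise of standard deviation
$\sigma$ the noise band has expectation $2\sigma\sqrt{2/\pi}$ — the
half-normal mean on each side — which the test suite verifies by Monte
Carlo to within 2%.

Inclusion is noise-responsive: a potential is kept iff its peak–trough
amplitude reaches $8\times$ its noise band. Whole 5 s blocks are discarded
as noise when the inclusion threshold exceeded 100 μV for more than half of
the block's potentials, or exceeded 200 μV even once; an excluded block
forfeits its duration and its potentials. The recording's noise readout is
the *median* of all per-potential noise bands — the median, not the mean,
because occasional large positive outliers would dominate a mean.

### Voluntary-activity exclusion

A voluntary train is defined operationally: at least 4 potentials whose
consecutive inter-spike intervals are all strictly below 250 ms. The
threshold corresponds to the lowest recruitment firing rate (≈ 4 Hz), and
deliberately does not exclude sub-50 ms multiplet pairs from
consideration. The recording is tiled into blocks and a block is flagged
when its own potentials contain a train; trains are evaluated strictly
within blocks, never stitched across boundaries — this is exactly why long
blocks are sensitive (a 10 s block almost always captures a full train) and
short blocks specific (a 1 s block rarely contains 4 spikes by chance).

Four strategies are offered: `0` disables exclusion; `1A` excludes every
flagged 10 s block; `2` excludes flagged 1 s blocks; and `1B` applies a
classifier to each block flagged by `1A`, returning predicted false
positives to the analysable pool. The classifier is a bagged ensemble of 30
decision trees (bootstrap aggregation with all features available at every
split, i.e. no feature subsampling and no dimensionality reduction) over
eight interval statistics per block: median, mean, mode, standard deviation,
inter-quartile range and per-minute frequency of the full interval set, plus
the Pearson kurtosis of, and the proportion of intervals inside, the
84–250 ms voluntary band. Stratified 5-fold cross-validation reports
accuracy, PPV and NPV. With high background fasciculation rates, chance
runs of four sub-250 ms intervals flag blocks spuriously; the interval
statistics of such blocks differ systematically from genuine regular firing,
which is what the classifier exploits.

### Summary metrics

The fasciculation frequency is the number of included potentials divided by
the analysable time (recording duration minus noise-excluded minus
voluntary-excluded time), reported per minute. Time accounting is exact by
construction — voluntary excluded time is counted net of overlap with
already-excluded noisy blocks — and the identity
`analysed + noise + voluntary = duration` is asserted on every synthetic
fixture in the test suite. Block-level detection quality against ground
truth is summarised as a confusion matrix with sensitivity, specificity,
PPV and NPV; evaluation percentages are computed per recording and
summarised by their median across recordings (a pooled confusion matrix is
also returned). Ordinary least squares provides the coefficient of
determination between frequency and the data-quality readouts.

## Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `bandpass_low_hz`, `bandpass_high_hz` | 20, 500 | Hz | analysis band |
| `notch_hz` | 50 | Hz | mains interference |
| `extreme_occupancy_fraction` | 0.02 | — | screen occupancy budget |
| `at_inc_noise_factor` | 8 | — | inclusion threshold = 8 × noise band |
| `at_exc_uv` | 100 | μV | noisy-block exclusion threshold |
| `noise_block_s` | 5 | s | noisy-block tiling |
| `train_min_potentials`, `train_max_isi_ms` | 4, 250 | —, ms | voluntary-train definition |
| `avid_block_sensitive_s`, `avid_block_specific_s` | 10, 1 | s | strategy block sizes |
| `feature_band_ms` | 84–250 | ms | 4–12 Hz interval band |
| `n_trees`, `cv_folds` | 30, 5 | — | classifier ensemble and validation |
| `rng_seed` | 1 | — | governs bagging and simulation; echoed in summaries |

The occupancy budget is split 1% positive + 1% negative
(`occupancy_split = 0.5`); the split is configurable because only the total
is physiologically motivated.

## Design choices where the design was open

* **Filter realisation.** The band edges name no design, so the band-pass is
  realised as 4th-order Butterworth high- and low-pass sections applied
  forward–backward (zero phase, so spike times are not shifted), plus a
  biquad notch of quality factor 30. Passband behaviour, ≥ 10× notch
  attenuation and < 10% drift leakage are asserted by tone tests.
* **Super-channel assembly.** Events are merged through a *dominant seed*:
  the unclaimed event with the largest peak–trough amplitude claims every
  event whose padded span overlaps its quarter-amplitude core, and claimed
  events are consumed. Two degenerate behaviours motivated this. First,
  transitive padded merging is unusable when few genuine spikes are present:
  the extreme-amplitude quantiles then sit inside the noise floor of every
  channel, ~2% of samples cross per channel, and transitive chaining across
  36 independent channels coalesces essentially the whole recording into one
  pseudo-potential. Second, zero-phase filtering keeps a large discharge
  supra-threshold for ~100–200 ms on low-threshold channels, so anchoring
  claims on the full run would swallow a separate neighbouring discharge,
  while refusing to merge long tail events would duplicate each spike once
  per channel. Seeding on the quarter-amplitude core consumes the tails
  without concatenating them, resolves discharges down to a few tens of
  milliseconds, and is order-independent (ties break by time, then channel).
  The generator-based tests verify one included potential per simulated
  spike with ≥ 95% recall at ±10 ms on clean recordings.
* **Channel quality control** runs on the *unfiltered* signal (switchable
  via `qc_before_filtering`), so baseline drift and line contamination
  remain visible to the spectral metric; the FFT area-under-curve is summed
  over the 20–500 Hz analysis band. The 95% interval is a single-pass
  mean ± 1.96 SD across non-null channels per metric — the simplest reading
  of an across-channel confidence band — and drift screening is subsumed by
  the spectral metric rather than added as a third statistic. A channel that
  is extreme on both metrics is reported as a range outlier (null >
  range > spectrum priority). Null means SD < 0.01 μV.
* **Noise bands on the source channel.** The flanking windows are evaluated
  on the potential's own source channel (the channel that defined its
  amplitude), which is the natural reading of a per-potential "local" noise
  level; computing them on a composite trace would mix channels with
  different noise floors.
* **Interval mode and degenerate kurtosis.** The mode of continuous
  intervals is the centre of the maximal 10 ms bin, ties broken toward the
  shorter interval; band kurtosis with fewer than 4 in-band intervals (or
  with numerically zero spread) is recorded as the Gaussian reference value
  3. A block with fewer than two potentials has undefined features and is
  treated as non-voluntary without classification — such a block can never
  be flagged anyway, since a train needs four.
* **Stage order.** Noisy-block exclusion runs *before* voluntary labelling,
  so artefact bursts cannot masquerade as trains; the voluntary stage sees
  only surviving potentials. The classifier's probability threshold for
  "truly voluntary" is 0.5, the ensemble's majority vote.
* **Strategy recommendation** is advisory by design: the decision whether a
  100–200 ms interval peak exists (operationalised as any bin exceeding 3×
  the median 250–400 ms bin) and the escalation points between strategies
  are declared heuristics, and the interface requires the caller to confirm
  the strategy explicitly.
* **Ingestion.** Recordings arrive either as a documented open matrix format
  (single-line JSON header — sampling rate, grid geometry, units, channel
  map — followed by a tab-separated body, lossless at double precision) or
  as continuous 16-bit EDF, for which a minimal reader/writer is included;
  EDF round-trips are exact only to the 16-bit quantisation step, as with
  acquisition hardware. Proprietary vendor formats are out of scope.

## The synthetic generator

`generate_recording()` emulates the features the pipeline must survive:
Poisson fasciculations (refractory-thinned, so intervals beyond the
refractory period stay exactly exponential — verified by Kolmogorov–Smirnov
tests across seeds), voluntary units firing inside declared epochs with
multiplicative ISI jitter (CV 0.12, keeping 5–10 Hz trains inside the
84–250 ms band so interval histograms develop the characteristic voluntary
peak), multiplets reusing their parent's waveform at a 30 ms gap, Gaussian
noise, common-phase 50 Hz line interference, slow sinusoidal drift and
zeroed dead channels. Spikes are ~15 ms triphasic Hanning-windowed
polynomial templates, scaled across the grid by exponential decay from a
random epicentre with the quarter-amplitude radius set to 3 electrode
pitches, which guarantees the ≥ 10-channel footprint that makes multi-channel
identification meaningful on an 8×8 grid.

Defaults were chosen once to represent a realistic recording: 2048 Hz, 8×8
grid, 40 fasciculations/min (a typical patient-scale rate), 300 μV spikes
with log-normal amplitude scatter (sdlog 0.3; no amplitude distribution is
established for fasciculations, so a right-skewed positive family is a
modelling choice), noise SD 2 μV — which by the half-normal identity yields
noise bands near 3 μV, the magnitude seen in practice — and voluntary rates
of 8 Hz. What the generator does *not* model: volume-conduction physics,
motor-unit recruitment and force modulation, waveform variability within a
unit, electrode motion artefacts, and non-stationary noise. Passing tests
therefore demonstrate that the pipeline implements its stated rules
correctly and recovers known ground truth under those rules; they do not
certify performance on real patient data.

## Problem sizes and numerical notes

Test fixtures are 20–60 s recordings (64 channels at 2048 Hz for end-to-end
runs; timing-only checks drop the sampling rate to 128–512 Hz, where only
spike times matter). The block-sensitivity simulation uses 20 one-minute
recordings with one voluntary unit at 6–10 Hz over a 15–25 s epoch plus
20/min background fasciculations — enough voluntary blocks per recording
(typically 2–3 of 6) for a meaningful per-recording sensitivity, and enough
recordings for a stable median. Intervals derived from spike-time
subtraction are rounded at the sub-nanosecond digit before binning and
thresholding so that float jitter cannot move an interval across a bin edge
or the 250 ms cutoff. All sample spans are half-open `[start, end)`,
sample indices are 1-based inside R, timestamps are seconds from recording
start, and the single `rng_seed` governs classifier bagging and any
simulation launched from a configuration.

## Known limitations

Discharges closer than a few tens of milliseconds (notably multiplet
partners at the default 30 ms gap) usually merge into one detected
potential, so multiplets are under-counted — consistent with treating them
as future work rather than a readout. The classifier is only as good as its
labels; `simulate_training_blocks()` provides generator-labelled training
data, but for real recordings manually labelled blocks should be preferred.
EDF support covers the continuous, equal-rate case sufficient for grid
recordings, not the full annotation-bearing EDF+ specification.
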
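---
title: "Methods: from raw tetrode traces to E/I ratios and differential abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw tetrode traces to E/I ratios and differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aonpipe)
```

`aonpipe` re-implements, as tested and reusable functions, the computational
chain behind a class of awake head-fixed olfactory experiments: extracellular
tetrode recordings from the anterior olfactory nucleus (AON) during
pseudo-randomized odor presentation, scored for odor-excited and
odor-inhibited single-unit responses and summarized as an
excitation/inhibition (E/I) ratio; together with the molecular companions of
such studies - reference-gene-normalized digital expression counts and a
SWATH-style proteomics differential-abundance chain. Because raw recordings
of this kind are rarely deposited, the package ships ground-truthed synthetic
generators for every input, so each stage can be validated at desk scale
against planted truth.

## The synthetic session generator

`generate_session()` draws one session from a generative model chosen to
match the experimental design: 7 odorants, each delivered 30 times in a
pseudo-randomized order with at most 3 consecutive repeats (rejection
sampling of permuted trial lists), 500 ms stimulus, 10 s inter-trial
interval. Trial onsets are therefore spaced by stimulus + ITI; the first
onset is placed at 10 s so a full 2 s pre-odor baseline always exists.

Each unit fires as an inhomogeneous Poisson process: a constant baseline
rate, drawn log-normal across units (default mean 5 Hz, SD 3 Hz, a plausible
range for AON single units), multiplied by `excited_gain` (default 3) or
`inhibited_gain` (default 0.1) inside the response window of odors for which
the cell-odor pair carries that ground-truth label. Labels are independent
per pair with probabilities `p_excited` / `p_inhibited`; the alternative
`balanced_labels` mode plants exact label counts so the population E/I ratio
is exact by construction (used by the recovery experiments below). The
response window defaults to 2 s after onset: odor responses in olfactory
cortex commonly outlast a 500 ms stimulus, and the published designs do not
state response-duration statistics, so this is an explicit, configurable
assumption. Excitation is implemented by superposing an extra Poisson
process at rate `baseline * (gain - 1)` inside the window, inhibition by
thinning (each baseline spike kept with probability `gain`), both exact for
piecewise-constant intensities.

What the generator deliberately does **not** model: biophysical spike
shapes or refractoriness in the point process, sniff-locked dynamics,
rate drift, bursting, or correlated noise across units. Passing tests
therefore demonstrate that the analysis chain is correct *given* its
statistical assumptions, not that those assumptions exhaust real AON data.

`render_traces()` turns spike trains into raw voltage: each unit's biphasic
template (1 ms, sharp negative trough at 30 kHz) is placed at its spike
times on the four channels of its tetrode with a fixed amplitude fall-off
across channels, superposing linearly, plus iid Gaussian noise. Traces
travel as little-endian int16 flat binary with a JSON sidecar
(`write_traces()` / `read_traces()`).

## Spike detection

`reference_and_filter()` subtracts the per-sample median across all
channels of the array (common-median reference) and applies a 4th-order
Butterworth band-pass, 300-5000 Hz. Filtering is zero-phase
(forward-backward): the analysis is offline, and zero-phase filtering keeps
detected peak times aligned with the raw waveform.

`compute_threshold()` sets the per-channel threshold at 7.5 times the
median absolute deviation of the filtered trace. The MAD is used *raw*
(median of absolute deviations from the median), not divided by 0.6745:
the procedure being emulated specifies the median absolute deviation
itself, not a Gaussian SD estimate. A `scaled` flag provides the
SD-calibrated variant; for Gaussian noise the raw-MAD threshold at k = 7.5
corresponds to about 5.1 noise SDs.

`detect_events()` finds local maxima of the inverted trace (negative-going
peaks, the extracellular convention; a rectified mode exists because the
emulated procedure does not state polarity) above threshold, pools
candidates across the four channels of a tetrode, and prunes by height to a
minimum separation of 1 ms: candidates are accepted in decreasing amplitude
order, and anything within 1 ms of an accepted event is discarded. This
single pass both removes multiple detections of one multiphasic spike and
merges cross-channel detections, keeping the timestamp of the highest peak
(pruning after merging; the alternative order is not distinguishable from
the published description). Waveforms are cut -10..+21 samples around the
peak (32 samples); events too close to the trace edges are dropped.

## Unit quality control

Three criteria gate a unit into the response analysis
(`unit_qc()` / `apply_inclusion()`):

* baseline rate >= 0.5 Hz, measured over the 2 s pre-odor baseline windows
  (not the whole session, which would mix in evoked activity);
* end-to-end stability: the session is cut into 10 equal blocks and the
  absolute rate change from first to last block, relative to the first,
  must stay below 10%;
* intermittent stability: the largest block deviation from the session
  mean rate must stay below 20%.

"Beginning to end" and "intermittent fluctuations" are not operationally
defined in the published descriptions; first-vs-last of 10 equal blocks and
max-block-deviation are this package's explicit operationalizations, and
both the block count and the thresholds are arguments. One caveat worth
knowing: for a stationary Poisson unit near 1 Hz in a ~30 min session, the
10% end-to-end criterion sits at the Poisson noise floor (a 180 s block rate
estimate has relative SE ~ `sqrt(1/(180 r))` ~ 7.5%), so slow units fail it
stochastically. `refractory_contamination()` (fraction of inter-spike
intervals below 5 ms) is reported alongside but is not part of the default
inclusion rule, matching its published role as a sorting-quality metric.

## PSTHs, z-scores and response classification

`build_psth()` bins spikes in 100 ms bins over [-2, +4] s around onset.
`zscore_psth()` subtracts the baseline mean rate (2 s before onset) from
each bin's trial-averaged rate and divides by a baseline SD. The emulated
description - "the baseline standard deviation computed across all trials" -
admits several readings, which differ materially in calibration. The
package's default (`sd_mode = "sem"`) pools the single-trial baseline bin
rates across all trials and baseline bins and divides their SD by
`sqrt(n_trials)`: this is the standard error of a trial-averaged bin rate,
so under stationary firing the per-bin z is calibrated and the +/-1.96
cutoff used for significance calls is an honest ~5% test. A Monte-Carlo
check (stationary 10 Hz pairs, 30 trials) puts the per-bin exceedance rate
at ~0.055 - slightly above 0.05 because sigma is estimated and counts are
discrete. The literal per-trial-baseline-rate SD (`"trial"`) yields ~0.028
(conservative ~0.7 sigma-units too wide), and the per-bin SD of the mean
PSTH (`"bins"`) ~0.072; both are available.

`classify_response()` calls a pair excited if *any* bin in the response
window ([0, 2] s by default) exceeds +1.96, else inhibited if any bin falls
below -1.96, ties resolved by the larger |z|. The any-bin rule over 20 bins
implies a substantial per-pair family-wise false-positive rate (~0.3 per
side under the null); this is inherent to the published classification
style, matters for interpreting absolute responsive fractions, and is why
the recovery analyses below are framed around *ratios and rank order*, not
absolute counts. A peak-bin-only variant is a one-argument change
(`response_window` narrowed) and the threshold is an argument. As the
signal-to-noise summary of a response, the extremal response-window z
(`peak_z`) is the default and the mean response-window z (`mean_z`) is
reported alongside - published descriptions do not distinguish the two.

`peak_metrics()` reports the baseline-subtracted peak (subtraction window
1 s before onset) and its full width at half extremum, measured on the
unsmoothed 100 ms PSTH with linear interpolation between bin centers; a
flat PSTH yields peak 0 and undefined width. `summarize_session()`
aggregates: fraction of responsive units, tuning broadness, excited and
inhibited pair counts, their E/I ratio (undefined when no pair is
inhibited), and mean baseline firing over all and over excited units.

## E/I parameter recovery

`ei_genotype_profiles()` fixes three session configurations whose planted
population E/I ratios are 2.0 (control: p_excited 0.35, p_inhibited 0.175),
5.0 (SH-WT-like: 0.40 / 0.08) and 1.4 (SH-RX-like: 0.245 / 0.175), with
strong gains and 220 units per session (the size of the largest cohort in
the emulated study; equal sizes isolate the E/I contrast). Response
probabilities are enriched relative to cortex so that desk-scale sessions
carry enough labeled pairs; `balanced_labels` makes the planted ratio exact
rather than binomial-in-expectation - a pilot variance decomposition showed
that label-sampling noise otherwise contributes over half the variance of
the recovered log-ratio margins, i.e. the experiment would mostly be
measuring its own label lottery. Because any-bin false positives load both
the numerator and denominator, detected ratios are compressed toward 1
relative to the planted 2.0 / 5.0 / 1.4 (typically ~2.1 / ~3.5 / ~1.7);
the recovery claim made and tested is *rank order* - SH-WT above control
above SH-RX - across 100 independently simulated triplets.

## Group statistics

`welch_anova()` (via `stats::oneway.test`) is the default omnibus test
between genotypes, with the classical equal-variance ANOVA as an option;
firing-rate-like quantities can be natural-log transformed first
(non-positive values raise, they are never silently offset).
`dunnett_test()` implements the many-to-one post-test against the control
group: pooled-variance contrast t statistics, and family-wise two-sided
adjusted p from the joint multivariate-t distribution of the contrasts,
evaluated by seeded quasi-Monte-Carlo integration (`mvtnorm::pmvt`,
absolute tolerance ~5e-4; deterministic for a fixed seed; with one
treatment group it reduces exactly to the pooled t-test). `bh_fdr()` wraps
the Benjamini-Hochberg step-up with the significance set at FDR < 0.05.

## Codeset counts and fold changes

`genorm_stability()` computes the reference-gene stability measure M (mean
SD of pairwise log2 ratios across samples) and per-sample normalization
factors as the geometric mean of the reference genes, rescaled to
geometric mean 1. Iterative worst-gene elimination is implemented but off
by default - the emulated study retained its full six-gene panel.
`normalize_counts()` chains an optional positive-control stage (per-sample
geometric mean of positive-control probes scaled to the cohort mean, the
vendor convention; exact background-correction settings of the vendor
software are not published, so this stage is an explicit approximation and
can be bypassed), the geNorm factors, and finally scales each gene by its
control-group mean so the control mean is exactly 1. `fold_change()`
reproduces worked-example arithmetic with an explicit aggregation
(mean of per-line ratios, or pooled sums) and rounding mode.

## Proteomics differential abundance

The SWATH-style chain (`proteomics_pipeline()`):

1. `filter_peptides()`: a peptide is kept iff at most one sample *per
   group* (independently per group) has identification Q-value above 1e-3 -
   the stringent threshold with a one-outlier allowance; missing Q-values
   count as failures.
2. `cyclic_loess_normalize()`: intensity-dependent normalization of log2
   peptide areas (around `limma::normalizeCyclicLoess`, the function used
   in the emulated workflow), cycled until the largest per-sample median
   change drops below 1e-3 or 3 cycles. The default `"fast"` variant
   (loess against the sample mean) is used because with ~30 samples the
   all-pairs variant is an order of magnitude slower and converges to the
   same normalization; `"pairs"` is available.
3. `rollup_proteins()`: protein abundance = *sum* of linear-scale
   normalized peptide areas (summation keeps single-peptide proteins and is
   the published roll-up rule). Normalization happens at the peptide level,
   before the roll-up; a protein-level normalization is possible by calling
   the normalizer on the rolled-up matrix instead.
4. `moderated_t()`: per-protein pooled variances are shrunk toward a prior
   fitted across proteins by method-of-moments on the log variances
   (scaled inverse-chi-square model; hyperparameters d0, s02 via a Newton
   trigamma inverse). The moderated t has d + d0 degrees of freedom;
   d0 = 0 recovers the ordinary t and d0 = Inf the fully pooled limit, and
   both limits plus agreement with the reference empirical-Bayes
   implementation are covered by tests. Contrasts are fitted pairwise,
   each transgenic-like group against the control (the published analysis
   does not state whether a joint three-group fit was used; pairwise is
   the default here).
5. `median_cv()`: per-group median of per-protein CVs (SD/mean, linear
   scale), the quantification-precision summary. The generator's default
   peptide noise (log2 SD 0.25, ~3 peptides/protein) lands protein-level
   median CVs near the 10-13% range typical of cross-run-normalized SWATH
   data.

## Problem sizes and numerical choices

The shipped checks run at desk scale by design: 60 s of 4-channel 30 kHz
trace for the detection benchmark (SNR 8, the lower edge of the regime
where >= 95% recall and precision are claimed); 1000 stationary cell-odor
pairs for z calibration; 100 session triplets of 220 units for E/I rank
recovery; 500 null replicates for the Dunnett family-wise error; 50
replicates of 2000-protein tables (7 vs 14 samples, 10% planted DE at
2-fold) for the differential-abundance recovery. Tolerances: quantization
of written traces is 0.195 uV/bit; the Dunnett quasi-Monte-Carlo tolerance
is ~5e-4 on each adjusted p; loess convergence is 1e-3 on per-sample
medians; the trigamma-inverse Newton iterates to 1e-8 relative. Degenerate
inputs fail loudly and early: constant traces (MAD 0), silent baselines
(sigma_b 0 -> unclassifiable pair), zero-variance groups, empty control
groups, zero denominators, and non-positive values under a log transform
all raise or flag rather than returning numbers silently.

## Known limitations

Spike sorting is out of scope - unit identities come from ground truth (or
an external sorter); the detection chain stops at merged tetrode events
with waveforms. The E/I machinery assumes the trial design (balanced odor
schedule, long ITI, stationary baseline); sniff-locked analysis, decoding,
and drift handling are not attempted. The proteomics chain starts from
exported peptide areas with Q-values: spectral-library search,
retention-time alignment and protein inference are upstream of this
package.
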
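---
title: "Graph-theoretical analysis of rodent resting-state functional connectivity"
author: "fcgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical analysis of rodent resting-state functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcgraph)
```

# The problem

In rodent models of absence epilepsy, spontaneous spike-and-wave
discharges (SWDs, fundamental ~6 Hz) sweep through a cortico-thalamo-
cortical circuit. Resting-state fMRI lets one ask how the *whole-brain*
functional network is organized before and during seizures: pairwise
correlations between regional BOLD time courses define a weighted graph
over ~72 atlas regions, and graph metrics summarize its integration
(path length), segregation (clustering, communities) and the role of
individual regions (degree, strength, betweenness, hub scores).
`fcgraph` implements this analysis chain as tested, seeded, reusable
functions, together with a synthetic-data generator so that each stage
can be validated against known ground truth without animal data.

# Pipeline and model

## Preprocessing

The temporal pipeline operates on a T x R matrix of regional signals
(`RoiTimeSeries`, TR in seconds):

1. **Stable-epoch selection** (`selectStableEpoch`): the earliest
   contiguous window of the requested length whose per-axis peak-to-peak
   motion stays strictly below 0.2 mm (translations) and 0.3 degrees
   (rotations). Peak-to-peak is the strictest simple window statistic;
   thresholds are per axis. If the run starts stable, the first window is
   used unchanged. No qualifying window yields `NULL`, so callers can
   drop the run rather than crash.
2. **In-plane Gaussian smoothing** (`smoothImage`): 3 x 3 pixel kernel,
   FWHM 0.6 mm evaluated on the physical pixel grid, zero-padded
   boundaries (total intensity is conserved up to edge truncation).
3. **Fourier low-pass at 0.1 Hz** (`lowpassFourier`): a hard spectral
   mask — bins strictly above the cutoff are zeroed, the DC bin is kept,
   so the filter is linear, idempotent and mean-preserving. A hard mask
   can ring near sharp transients; that is accepted as the price of an
   exactly defined pass band.
4. **ROI extraction** (`extractRoiTimeseries`): per volume, the mean of
   voxels carrying each atlas label. Atlas-to-brain registration is out
   of scope; a label map must be supplied.
5. **Global-signal regression** (`regressGlobalSignal`): residuals after
   least squares on an intercept plus the across-region mean signal;
   residuals are exactly orthogonal to the global mean. Regression is
   applied to ROI series rather than voxels; because ROI extraction is a
   label mean, the two orders are equivalent for the extracted series,
   and the ROI-level form is directly testable.

Quality assurance uses the temporal SNR (`temporalSNR`): mean over
masked voxels of temporal mean / temporal SD, excluding (and counting)
zero-SD voxels.

## Connectivity

`correlationMatrix` computes all pairwise Pearson correlations and keeps
only positive coefficients (negatives are zeroed at construction — the
most literal reading of a positive-weights-only network). The diagonal
is stored as zero. Group matrices are built by Fisher averaging
(`fisherAverage`): z = atanh(r), arithmetic mean, back-transform. When
several runs per animal exist, average per animal first, then across
animals. Edge significance (`fdrSignificanceMask`) converts r to a
two-sided p through the t transform with T - 2 degrees of freedom and
applies Benjamini-Hochberg across all R(R-1)/2 unique edges of the
matrix (the FDR family is per matrix). The nominal post-filtering T is
used as the degrees-of-freedom basis; no temporal-autocorrelation
correction is applied, and the documentation states so explicitly.

## Thresholding and graph metrics

`thresholdToDensity` keeps exactly `floor(R * k / 2)` strongest edges
(k = 10 on 72 regions gives 360 edges); ties at the cutoff break by
lexicographic node order so results are reproducible. All binary metrics
(clustering, path length, betweenness, component count) are computed on
the binarized graph; strength is the only weighted node metric, matching
its definition as a weight sum.

`globalMetrics` normalizes the clustering coefficient C and the
characteristic path length L (mean shortest-path hop count over ordered
pairs) against the means of `nNull` uniform random graphs with identical
node and edge counts — Erdos-Renyi G(n, m), the literal "same number of
nodes and edges" null; degree-preserving rewiring is available as an
option. Disconnected null draws are resampled and counted, which keeps
the hop-count definition of L uniform instead of switching to harmonic
means. gamma = C/C_rand, lambda = L/L_rand, sigma = gamma/lambda; sigma
> 1 marks small-world organization. If the input graph itself is
disconnected, L is computed on the largest component and flagged — a
guarded fallback, since analyses are run at densities where networks are
connected.

The hub score is the equal-weight mean of the within-network z-scores of
degree, betweenness and negated average path length. The cited composite
has no published closed form, so the formula is recorded in the result's
`"formula"` attribute to keep alternative composites comparable. Metrics
with zero variance across nodes (e.g. every node of a regular lattice)
contribute zero, with a tolerance guard so that floating-point-level
spread in analytically equal values is not standardized into spurious
±1 z-scores.

## Communities

`detectCommunities` runs Louvain-style modularity optimization (via
igraph) on the weighted thresholded graph — weights are retained because
community structure is interpreted on weighted networks — with
best-of-10 seeded restarts; a single greedy run depends on sweep order,
and restarts make the reported partition stable and deterministic given
the master seed. The resolution parameter defaults to 1.0.
`modularityScore` is an independent implementation of weighted
modularity (used for the reported Q and cross-checked against igraph in
the tests). Community ids are dense integers from 1.

## Network-based statistics

`nbsTest` compares two groups of connectivity matrices edge by edge with
homoscedastic two-sample t-tests in the Fisher z domain. The primary
threshold keeps edges whose BH-adjusted p falls below alpha — an
FDR-thresholded variant of NBS; the classic uncorrected threshold is
available via `primary = "uncorrected"`. Supra-threshold edges are split
by contrast direction and their connected components extracted. The
permutation null relabels subjects (unpaired), recomputes the full
thresholding rule per permutation (preserving exchangeability; the
alternative of freezing the observed edge family is deliberately not the
default), and records the maximal component edge count over both
directions, so the familywise error of the direction-split report is
controlled. Component probability is (1 + #(null >= observed)) /
(nPerm + 1), which cannot reach zero. Component size is measured in
edges, with node counts reported alongside.

## Group statistics

`compareZDistributions` applies the Mann-Whitney rank-sum test to the
nonzero edge z-values of two group-average matrices (the group-average
edge set, not pooled per-subject edges; both readings are defensible and
the function accepts any pair of matrices). `anovaLocalParams` fits the
two-factor fixed-effects model metric ~ group * region with Type-II sums
of squares — identical to the classic decomposition when balanced, and
well-defined for unequal group sizes such as 9/8/7 animals. With one
region it collapses to the two-sample t-test (F = t²).
`posthocTTests` runs per-region homoscedastic unpaired t-tests and
reports raw p-values (the convention for descriptive post-hoc maps) with
a BH-adjusted column always alongside.

## SWD detection

`powerSpectrum` is a Welch estimate: Hann-windowed, mean-removed
segments, one-sided, scaled so the spectral integral matches the
time-domain variance up to the windowing constant. `classifyBrainState`
computes per 2-s sliding window (50% overlap) the fraction of DC-free
power in the 4-8 Hz band, labels windows above the threshold as SWD,
accounts each hit window by its central half so segment edges track
burst edges to about a quarter window, merges, and drops segments of
1 s or less. The default threshold 0.45 was calibrated once on the
generator: pure-background traces produce essentially no false segments
(about 0.1% of windows exceed it) while windows inside default-preset
bursts lie well above (2nd percentile ≈ 0.49). The window length of 2 s
resolves the 6 Hz fundamental (0.5 Hz bins place a bin exactly at 6.0)
while still tracking epochs of a few seconds. A visual-identification
protocol cannot be reconstructed from a paper; this detector is a
defined, reproducible stand-in whose thresholds are all exposed as
parameters.

# The synthetic generator: what it emulates, and what not

`generateAtlas` builds 72 bilateral regions — per hemisphere 8
sensorimotor, 6 association-cortex, 9 limbic, 8 thalamic and 5
basal-ganglia regions — with mirrored `_L`/`_R` abbreviations.

`communitySpec` defines the population correlation matrix from which
subjects are drawn. Defaults (chosen once as the study conditions; the
underlying experiments report no empirical per-group correlation
magnitudes, so these are calibration choices):

| parameter | default | role |
|---|---|---|
| withinBlock | 0.45 | within functional-group coupling |
| betweenBlock | 0.15 | global baseline between groups |
| thalamusBridge | 0.25 | thalamo-cortical connector coupling |
| homotopic | 0.70 | left-right pairs of the same region |
| jitterSD | 0.12 | fixed per-edge heterogeneity |
| ar | 0.3 | AR(1) hemodynamic-like smoothing |
| nTimepoints | 900 | 15 min at TR = 1 s |
| nSubjects | 9 | largest group size of the emulated design |

The homotopic value reflects the strong interhemispheric coupling that
appears as matrix diagonals in real group matrices; the thalamic bridge
encodes the cortico-thalamo-cortical connector role of the thalamus; the
per-edge jitter (a fixed, seed-determined realization that is part of
the specification, not per-subject noise) gives the weight distribution
the smooth heterogeneous profile of real connectivity data — without it
the thresholded graph would split into blocks, whereas real networks at
k = 10 are connected. Targets are repaired to positive semi-definiteness
by eigenvalue clipping at 1e-8 and renormalization to unit diagonal
(`psdRepair`), deterministic with the maximum entry adjustment reported.
Subjects are T x R draws coloured by the symmetric matrix square root of
the repaired target; AR(1) filtering applied identically to every region
preserves the contemporaneous correlation structure. Group effects add a
delta to named block-pair edge sets before repair, giving group
contrasts exact ground truth.

Deliberately **not** emulated: hemodynamic forward modelling, scanner
artifacts beyond AR(1), anesthesia effects, and between-subject
variability of the correlation targets — every subject shares one
population matrix, so between-subject variance is sampling noise only.
Group-comparison power on synthetic data is therefore optimistic
relative to real animals; passing tests demonstrate correctness of the
machinery, not field-realistic effect sizes.

`generateCaTrace` emulates the optical Ca²⁺ readout: 1/f-power
background (spectrally shaped white noise, unit SD) plus bursts of an
asymmetric sawtooth at the SWD fundamental (6 Hz default) with a
second-harmonic spike component at relative amplitude 0.3 and overall
amplitude 5 background SDs, laid out on a 20-s cycle with seeded onset
jitter so bursts alternate with rest. Only the 6 Hz fundamental is
anchored in the emulated recordings; waveform details are free choices.
Ground-truth burst intervals are returned for validation.

# Numerical choices and degenerate inputs

- Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state (`withr::with_seed`); identical seeds give
  bit-identical output.
- Constant region series yield undefined correlations; such regions are
  flagged and their edges zeroed. r = 1 off-diagonal is clipped to
  1 - 1e-7 before atanh.
- Thresholding ties break lexicographically; insufficient positive edges
  raise an error reporting the maximum achievable density.
- Zero pooled variance in an edge t-test gives t = 0 (flagged), p = 1.
- A constant global signal degrades regression to mean-centering, with a
  warning.
- Disconnected graphs: component count is always reported; L falls back
  to the largest component with a flag; hub scores require connectivity.

# Problem sizes

The test suite and the benchmark script run at desk scale by design:
72-region networks, 200-900 time points, 100-500 permutations or null
networks, 10-20 replicate seeds per property. These sizes were chosen so
that the full validation battery executes in well under half an hour on
a single core while leaving every statistical check enough resolution
(e.g. permutation p floors of ~1/100, binomial bounds on 20 replicates).

# Known limitations

- The FDR-thresholded NBS variant is nonstandard (classic NBS uses an
  uncorrected t threshold); both are provided, the FDR form is default.
- Degrees of freedom for edge significance ignore temporal
  autocorrelation introduced by low-pass filtering; with 0.1 Hz cutoff
  at TR = 1 s the nominal T overstates the effective sample size, so
  absolute edge p-values are liberal. Group contrasts (NBS, ANOVA) are
  unaffected because they operate across subjects.
- Community counts from single Louvain runs on real data are
  resolution-dependent; reproducing a specific published count requires
  the original data and settings.
- The SWD detector is a calibrated band-ratio stand-in for visual state
  identification, not a reconstruction of it.
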
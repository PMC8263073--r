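# fcgraph

Graph-theoretical analysis of resting-state fMRI functional connectivity
for rodent absence-epilepsy studies.

In absence epilepsy, ~6 Hz spike-and-wave discharges (SWDs) engage a
cortico-thalamo-cortical circuit, and whole-brain network organization
shifts between the preseizure and seizure states. `fcgraph` implements
the full analysis chain used to characterize such networks from
resting-state fMRI, for researchers analyzing ROI-level rodent (or other
small-animal) connectivity data:

- **Preprocessing** — motion-stable epoch selection (peak-to-peak
  < 0.2 mm / 0.3°), in-plane Gaussian smoothing, hard Fourier low-pass
  at 0.1 Hz, ROI extraction from a label map, global-signal regression,
  temporal-SNR QA.
- **Connectivity** — pairwise Pearson correlation with positive-only
  weights, Fisher-z group averaging
  (r̄ = tanh(mean(atanh r))), FDR (Benjamini–Hochberg) edge
  significance from the t transform of r.
- **Graph metrics** — density thresholding to mean degree *k* (k = 10
  on 72 regions keeps the strongest 360 edges), component counting, and
  small-world metrics normalized against random networks with matched
  node and edge counts: γ = C/C_rand, λ = L/L_rand, σ = γ/λ.
- **Communities & hubs** — seeded Louvain modularity partitions;
  composite hub score = mean of z(degree), z(betweenness),
  z(−path length).
- **Network-based statistics (NBS)** — edge-wise homoscedastic t-tests
  in the z domain, FDR primary threshold, supra-threshold component
  extraction split by direction, permutation null of the maximal
  component size.
- **Group statistics** — Mann–Whitney comparison of edge-weight
  distributions, two-factor ANOVA (group × region, Type-II SS) with
  region-wise post-hoc t-tests.
- **Brain-state readout** — Welch power spectra of optical Ca²⁺ traces
  and a band-ratio SWD detector (4–8 Hz).
- **Synthetic data** — a seeded generator for the whole study design:
  a 72-region bilateral atlas in 5 functional groups, multi-subject
  time series with planted community structure, homotopic coupling and
  group effects, and Ca²⁺ traces with ground-truth SWD bursts — so
  every stage is testable against known truth.

## Worked example

```r
library(fcgraph)

atlas <- generateAtlas()                       # 72 bilateral regions
spec  <- communitySpec(atlas)                  # planted structure
tsl   <- generateGroupTimeseries(atlas, spec, nSubjects = 9,
                                 nTimepoints = 900, seed = 1)
mats  <- lapply(tsl, correlationMatrix)        # positive-only Pearson
gmat  <- fisherAverage(mats)                   # group matrix (z-average)
net   <- thresholdToDensity(gmat, k = 10)      # strongest 360 edges
net
#> ThresholdedNetwork: 72 nodes, 360 edges (target mean degree k = 10 )
countComponents(net)
#> [1] 1

gm <- globalMetrics(net, nNull = 200, seed = 2)
sprintf("C=%.3f L=%.3f gamma=%.2f lambda=%.2f sigma=%.2f",
        gm$C, gm$L, gm$gamma, gm$lambda, gm$sigma)
#> [1] "C=0.547 L=2.667 gamma=3.90 lambda=1.29 sigma=3.02"

detectCommunities(net, seed = 3)
#> Partition: 5 communities over 72 nodes, Q = 0.6754 (resolution 1 )

head(sort(hubScores(nodeMetrics(net)), decreasing = TRUE), 5)
#> thal5_L  lim4_L  smc5_L thal2_L thal3_R
#>    3.21    2.14    1.50    1.29    1.19

tr <- generateCaTrace(900, burstDuty = 0.5, seed = 4)  # seizure preset
peakFrequency(powerSpectrum(tr))
#> [1] 6
classifyBrainState(tr)$state
#> [1] "seizure"
```

Reading the output: the group-average synthetic network at k = 10 is
fully connected (1 component) and strongly small-world (σ ≈ 3: much
more clustered than a matched random graph, at nearly random path
length). The partition recovers the five planted functional-group
communities (Q ≈ 0.68), thalamic regions carry the top hub scores (they
are the planted connector block), and the seizure-preset calcium trace
shows its dominant spectral peak at exactly 6 Hz.

For two-group comparisons, `nbsTest(groupA, groupB)` returns the
significantly different subnetwork components with permutation
probabilities, and `anovaLocalParams()` / `posthocTTests()` handle
node-level metrics. See the vignette in `vignettes/fcgraph-methods.Rmd`
for the statistical model, parameter defaults, and the design choices
behind each stage.

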
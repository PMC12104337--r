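---
title: "Consensus subtyping of cortical tau and atrophy maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus subtyping of cortical tau and atrophy maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticlust)
```

## The problem and the model

Alzheimer's-spectrum patients differ systematically in *where* tau pathology
accumulates and *where* the cortex thins. corticlust implements a
similarity-based subtyping workflow that finds such groups from vertex-wise
imaging maps, one modality at a time:

1. **Normalisation.** Each patient map is converted to abnormality z-scores
   against a cognitively normal (HC) reference,
   $z_v = (x_v - \bar{x}_v^{HC}) / \sigma_v^{HC}$, per vertex $v$.
2. **Similarity graph.** Subjects become nodes of a weighted graph whose edge
   weights are correlations between their z-score vectors. Two patients with
   the same spatial pattern of abnormality — regardless of overall severity —
   correlate highly.
3. **Community detection.** The graph is partitioned by maximising weighted
   Newman–Girvan modularity with a resolution parameter $\gamma$,
   $$Q = \frac{1}{2m}\sum_{i \ne j}\left[w_{ij} - \gamma\frac{k_i k_j}{2m}\right]
   \delta(c_i, c_j),$$
   using greedy Louvain local moves plus graph aggregation. Larger $\gamma$
   yields more, smaller communities.
4. **Consensus.** Louvain is stochastic (node visit order), so a single run is
   a sample from a basin of local optima. We run it `n_iterations` times
   (default 1,000), form the co-assignment matrix of pairwise same-cluster
   fractions, zero entries below `coassignment_threshold` (default 0.5), and
   re-cluster the thresholded matrix, iterating until the co-assignment matrix
   is binary block-structured. Run on the full cohort this yields the
   *Consensus Initial Partition* (CIP).
5. **Resolution selection.** `gamma_search()` scans an ascending grid and
   returns the smallest $\gamma$ whose consensus partition has the target
   cluster count — the "smallest resolution for the target k" rule. The
   default grid step of 0.02 matches the precision at which per-modality
   resolutions are conventionally reported (1.2 tau, 1.32 atrophy for a
   four-cluster solution in the cohort this workflow reproduces).
6. **Stability.** `loo_stability()` drops a small random subset of patients,
   rebuilds the similarity matrix from the remaining z-rows, re-runs consensus
   at the unchanged $\gamma$, and scores the Rand Index against the CIP
   restricted to retained subjects. The HC reference is deliberately left
   untouched: removal perturbs the graph, not the normalisation.
7. **Cross-modal comparison and longitudinal rates.** Cluster allocations are
   compared by a hand-computed Pearson chi-square; cluster ROI profiles by
   Spearman correlation (cortical volume/thickness multiplied by −1 first, so
   positive $\rho$ means coupled abnormality), Bonferroni-corrected over the
   cells; contrast maps by max-statistic permutation tests; annual regional
   change rates by per-subject slopes standardised against HC slopes and
   compared with Kruskal–Wallis + Benjamini–Hochberg across the 34-region
   family, with Bonferroni-corrected pairwise rank-sum tests inside
   significant regions.

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| `gamma` | 1.2 (tau), 1.32 (atrophy) | published per-modality resolutions for a 4-cluster solution; search available |
| `n_iterations` | 1000 | restart count at which consensus was reported stable |
| `coassignment_threshold` | 0.5 | majority co-assignment; the consensus literature leaves this open, so it is configurable |
| `negative_weight_policy` | clip to zero | modularity needs non-negative weights; clipped fraction is recorded. A pass-through "signed" variant exists but is experimental |
| SD estimator | sample (n−1) | unstated in the source; configurable to population |
| positivity cut-offs | CSF ratio < 0.075, AV45 > 1.11, FBB > 1.08, tau meta-ROI > 1.37 | published values; all strict inequalities, boundary = negative |
| centiloid | AV45 196.9·SUVr − 196.03; FBB 159.08·SUVr − 151.65 | published tracer calibrations |
| CTV:HV | cortical ÷ hippocampal | the label and the direction of published group differences imply this orientation even though the methods sentence reads inverted; `invert = TRUE` gives the other reading |

## What the synthetic generator emulates — and what it does not

`cohort_spec()` defaults state the world the analysis assumes: 154 controls,
166 patients in clusters of 57/53/36/20, two modalities on a shared
2,000-vertex grid (1,000 per hemisphere), 34 parcels per hemisphere, a 3-SD
mean abnormality shift at pattern vertices over unit vertex noise, tau
baseline 1.2 (SUVr-like) and thickness baseline 2.5 (mm-like) so that tau
elevation and cortical thinning both map to positive abnormality downstream,
and three visits spaced 0.925 y with Uniform(0.5, 1.5) per-subject jitter so
the median within-subject follow-up is ~1.85 y.

Each cluster's abnormality is `effect_size` times an *amplitude field*: a
linear taper with mean exactly 1 over the cluster's core mask (a random
contiguous vertex block from `build_patterns()`), plus a small
pattern-specific per-parcel background, Uniform(0, 0.3) of the effect, off
the core. The taper keeps the mean shift at core vertices equal to
`effect_size`; the background gives each subtype the graded, widespread
topography real subtype maps show. This graded structure is what makes
cross-modal profile coupling recoverable: with flat disjoint 0/1 shifts the
cluster ROI profiles are binary, and one can show from rank-group means that
the matched-pair Spearman correlation then cannot exceed ≈0.58 at 25% pattern
coverage, no matter how strong the effect. When the two modalities share
patterns (`independent_patterns = FALSE`) they share the amplitude fields;
with independent patterns and full `crossmodal_discordance` the profile
coupling vanishes, which the tests verify.

The generator does **not** emulate: cortical mesh geometry or smoothing
(patterns are index blocks; nothing downstream uses geometry beyond the
parcel lookup), scanner or site noise (site labels exist but carry no effect,
so adjustment code is testable against a known null), covariate effects
(hooks default to zero), missing data, or dropout. A green recovery test
therefore establishes that the machinery recovers structure *of the planted
kind*, not that real cohorts contain four clusters.

Longitudinal slopes are applied in raw measurement units per year on the
pattern's core parcels (a parcel is core when at least half its vertices are
in the mask); with unit vertex noise this coincides with the HC-SD z scale.
Defaults 0.30/0.25/0.20/0.15 per cluster are in the range reported for
regional tau accumulation in impaired cohorts; volumes decline at the same
rate.

## Numerical choices

* **Modularity convention.** Self-weights are excluded from the edge term;
  the diagonal of the null term is kept (so an all-singleton partition has
  $Q = -\gamma\sum_i (k_i/2m)^2$). Aggregated-level self-loops carry internal
  weight double-counted, keeping node strength and $2m$ invariant across
  levels.
* **Louvain moves.** Strict first-improvement over the current community with
  an explicit move-to-empty-community option (gain 0), shuffled visit order
  per pass, ties keep the earlier community — all deterministic given the
  seed. Restart seeds are derived in double precision to avoid 32-bit
  overflow.
* **Consensus convergence.** A co-assignment matrix counts as converged when
  every entry is 0/1 within 1e-12 and the 1-blocks are transitive; an
  all-zero thresholded matrix yields the all-singleton partition rather than
  an error. Labels are canonicalised by descending cluster size.
* **Degenerate features.** Vertices with HC SD below 1e-8 are flagged,
  excluded from z-matrices (and hence clustering), and counted. ROIs with
  degenerate HC slope SD are likewise dropped from change-z tables.
* **Permutation p-values** use the add-one estimator $(1 + \#\{\text{null} \ge
  \text{obs}\})/(B + 1)$, so the smallest attainable p is $1/(B+1)$.
* **Mixed-model slopes** are BLUPs (fixed + random) from `lme4` with singular
  fits tolerated; noiseless recovery is exact to 1e-9 for the OLS route and
  to ~1e-6 for the mixed route (REML convergence tolerance), which the tests
  reflect.
* **MMSE log transform** errors on MMSE ≤ 0 rather than applying a silent
  offset, since no offset is specified anywhere.

## Design decisions taken where the design was open

* **TFCE replaced by max-statistic FWE.** The original surface analysis used
  threshold-free cluster enhancement, which needs mesh adjacency. This
  package substitutes the max-statistic permutation procedure, exact under
  exchangeability and geometry-free; calibration is verified by simulation
  (family-wise error within [0.03, 0.07] at nominal 0.05).
* **Consensus variant.** "Correction of individual-level modular
  decomposition" is read as the Lancichinetti–Fortunato consensus-matrix
  iteration (threshold, re-cluster, repeat). Other readings exist; threshold
  and round limits are configurable.
* **Oracle-equivalence ensemble.** Exhaustive-enumeration checks of the
  consensus modularity run on small weighted *planted-partition* graphs. On
  structureless dense random graphs the consensus partition tracks the
  majority Louvain basin, which can sit below the global enumeration maximum
  even though some restart attains it (reference implementations behave
  identically); the package documents this rather than papering over it, and
  separately asserts that no Louvain run ever exceeds the enumerated maximum
  on either ensemble.
* **Cross-modal ROI set.** Cluster-mean profiles over all cortical
  Desikan–Killiany regions of both hemispheres (68 by default), configurable,
  since the source analysis does not state the count.
* **Chi-square** is computed without continuity correction; expected counts
  below 5 raise a warning, not an automatic exact test.
* **Config format.** The pipeline reads JSON configs (YAML too when the yaml
  package is present); unknown keys are rejected before any compute.

## Known limitations

* Vertex grids are abstract index ranges; GIFTI/MGH surface import is out of
  scope in this version (TSV matrices are the interchange format).
* The signed-modularity path passes negative weights through the standard
  gain formula; it is exposed for experimentation, not validated theory.
* Exact label reproduction of any real cohort's clusters is not attainable:
  the original per-iteration partitions and seeds are not archived, and the
  underlying data are access-controlled.
* Stability medians reported for the real cohort (~0.6 tau, ~0.71 atrophy)
  are cohort-specific observations, not package targets; the synthetic
  high-SNR world yields higher medians by construction.
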
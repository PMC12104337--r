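# corticlust

Similarity-based consensus clustering of cortical tau-PET and atrophy maps,
for researchers who subtype Alzheimer's-spectrum cohorts from vertex-wise
imaging data.

## What it does

Patients with the same *spatial pattern* of pathology — posterior, limbic,
medial-temporal-sparing, left-temporal tau binding; hippocampal-sparing,
diffuse, minimal or limbic-predominant atrophy — form data-driven clusters.
corticlust finds them:

1. **Z-score** every patient map against a cognitively normal reference,
   per vertex: *z* = (*x* − x̄<sub>HC</sub>) / σ<sub>HC</sub>.
2. **Correlate** subjects' z-vectors into a weighted similarity graph.
3. **Cluster** the graph by Louvain maximisation of weighted modularity

   *Q* = (1/2*m*) Σ<sub>i≠j</sub> [*w*<sub>ij</sub> − γ *k*<sub>i</sub>*k*<sub>j</sub>/2*m*] δ(*c*<sub>i</sub>, *c*<sub>j</sub>),

   stabilised by **consensus clustering** over 1,000 stochastic restarts
   (co-assignment matrix, threshold, re-cluster until binary-blocked).
   `gamma_search()` finds the smallest resolution γ giving a target cluster
   count (γ = 1.2 tau / 1.32 atrophy reproduce a four-cluster solution in
   the cohort this workflow follows).
4. **Stability**: leave-one-out Rand-Index evaluation against the
   full-cohort Consensus Initial Partition.
5. **Compare modalities**: allocation chi-square, Spearman coupling of
   cluster ROI profiles (volume flipped by −1 so positive ρ = coupled
   abnormality), max-statistic permutation contrast maps (geometry-free FWE
   control).
6. **Longitudinal**: per-subject annual ROI change rates (OLS or lme4 mixed
   model), standardised against HC slopes, compared across clusters with
   Kruskal–Wallis + Benjamini–Hochberg over the 34-region family.

Biomarker utilities include centiloid conversion (AV45: 196.9·SUVr − 196.03;
FBB: 159.08·SUVr − 151.65), strict amyloid/tau positivity cut-offs
(CSF Aβ42/40 < 0.075, AV45 > 1.11, FBB > 1.08, tau meta-ROI > 1.37), cohort
inclusion filtering, and the cortex-to-hippocampus volume ratio.

A synthetic cohort generator (`cohort_spec()`, `generate_cohort()`,
`generate_visits()`) plants four ground-truth patterns in both modalities —
with configurable effect size, noise, cross-modal discordance and
longitudinal slopes — so every stage is testable end to end.

## Worked example

```r
library(corticlust)

spec   <- cohort_spec(seed = 42)          # 154 HC + 166 ADS, 4 planted clusters
cohort <- generate_cohort(spec)
print(cohort)
#> Synthetic cohort: 154 HC + 166 ADS, 2000 vertices, clusters 57/53/36/20

hc  <- cohort$metadata$group == "HC"
ref <- fit_reference(cohort$tau[hc, ])
z   <- vertex_zscores(cohort$tau[!hc, ], ref, modality = "tau")
S   <- similarity_matrix(z)

part <- consensus_cluster(S, clustering_config(gamma = 1.2,
                                               n_iterations = 1000, seed = 1))
print(part)
#> Consensus partition: k = 4 (gamma = 1.2, 1000 iterations, 1 round(s))
#> cluster
#>  1  2  3  4
#> 57 53 36 20

adjusted_rand_index(part$labels, cohort$truth$tau_cluster)
#> [1] 1
```

The consensus solution recovers the planted 57/53/36/20 partition exactly
(ARI = 1: chance-corrected pair agreement at its maximum). Stability under
leave-one-out, scored against this partition as reference:

```r
stab <- loo_stability(z, gamma = 1.2,
                      stability_config(removal_sizes = c(1, 5, 10),
                                       reps_per_size = 5, master_seed = 1),
                      clustering_config(n_iterations = 100, seed = 1))
print(stab)
#> LOO stability over 3 removal size(s); overall median RI = 1
#>  size median_ri
#>     1         1
#>     5         1
#>    10         1
```

Median Rand Index 1 at every removal size: at this signal-to-noise the
partition is insensitive to subject removal. The full pipeline (both
modalities, cross-modal comparison, longitudinal rates, report files) runs
from one config: `run_pipeline(pipeline_config(...))` or, from a shell,
`inst/cli/corticlust run-all --config cfg.json --seed 1 --out report/`.

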
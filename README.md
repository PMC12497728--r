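# ClonalKinetics

Longitudinal B-cell receptor (BCR) repertoire analysis: clonal lineage
clustering and detection of stimulus-induced lineage expansion across
timepoints, for annotated AIRR-style rearrangement tables.

## The problem

Innate-immune stimulants such as TLR7/8 agonists perturb the antibody
repertoire within days, but unlike an antigen they elicit no single dominant
specificity — the response is spread over many B-cell lineages. Detecting it
therefore requires tracking every clonal lineage through time and asking
which ones expand beyond resampling noise. This package implements that
pipeline for repertoires sampled at 0, 8, 24, 48, 72 and 168 h (one week):

1. **Clonotypes** — unique (V gene, J gene, CDR3 amino-acid sequence)
   combinations, counted per sample; heavy chains (IGH) and pooled light
   chains (IGK + IGL, "IgKL") form separate frequency denominators.
2. **Lineages** — clonotypes sharing V, J and CDR3 length whose CDR3s are
   connected under single linkage with hamming distance ≤ 1, clustered per
   animal with all timepoints pooled. Per timepoint, each lineage gets three
   indices: cumulative frequency, unique CDR3 count, and pooled somatic
   hypermutation (SHM) rate `100·(Σvᵢ+Σjᵢ)/(ΣVᵢ+ΣJᵢ)`.
3. **Dynamics** — per index, `log₂FC = log₂(value_t / value_0h)`; a lineage
   is *increased* on an index when log₂FC > 1, *decreased* when FC < 0.5,
   and *expanded* when at 48 h or 72 h it passes a chain-specific criterion
   pair (fold-change threshold AND absolute threshold; e.g. IgKL frequency
   log₂FC > 3 with frequency > 0.001%).
4. **Characterisation** — repertoire diversity (Shannon −Σpᵢ ln pᵢ, Gini,
   top-N cumulative frequency), Morisita–Horn and overlap-coefficient
   similarity, κ/λ ratio, mutation/isotype class partitions (naive-like
   IgM/D non-mutated vs memory/effector-like IgA/G/E mutated), origin
   tracing of expanded lineages back to their 0 h members, matched control
   sampling, and Neighbor-Joining lineage trees built from fixed-length
   V-tail + CDR3 + J-region subsequences.

A seeded synthetic cohort generator (`generateCohort`) produces longitudinal
cohorts with power-law lineage abundances, a three-peak SHM mixture,
isotypes conditional on mutation class, and planted expanded lineages with
ground truth, so the full pipeline is testable end to end without any data
download.

## Worked example

```r
library(ClonalKinetics)

cfg <- cohortConfig(nAnimals = 2, sequencesPerSample = 5000,
                    nBaselineLineages = 400, nPlanted = 8, seed = 42)
gen <- generateCohort(cfg)
gen$repertoire
#> Repertoire with 16808 records, 120,000 sequences
#>   animals:    AGM02, IRM01
#>   timepoints: 0, 8, 24, 48, 72, 168 hr
#>   chains:     IGH, IGK, IGL

res <- analyzeCohort(gen$repertoire)   # clonotypes -> lineages -> calls
table(res$calls$status)
#> decreased  expanded increased unchanged
#>       720         8       175       698

ev <- evaluateRecovery(res$calls, res$lineages, gen$truth)
#> recall 1.00, precision 1.00 over 8 planted lineages
```

All 8 lineages planted by the generator are recovered as expanded, with no
false positives among the 1,601 clustered lineages. The expanded set shows
the λ-chain bias the generator plants (80% of planted light-chain lineages
are assigned to IGL):

```r
kl <- kappaLambdaOfLineages(res$lineages,
        res$calls[status == "expanded" & chain_group == "IgKL", lineage_id])
#> kappa/lambda of expanded lineages at 72 hr: 0.252
```

against a baseline κ/λ of about 2. Diversity, similarity and mutation-class
tables come from `diversityTable()`, `timepointOverlapMatrix()`,
`morisitaHorn()` and `mutationClassProportions()`; NJ trees for individual
expanded lineages from `lineageTree()` and `writeNewickAnnotated()`.

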
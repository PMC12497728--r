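---
title: "Detecting stimulus-induced clonal lineage expansion in longitudinal BCR repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stimulus-induced clonal lineage expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

ClonalKinetics analyses annotated immunoglobulin rearrangement tables from a
longitudinal design: several animals, each sampled at 0, 8, 24, 48, 72 and
168 hours around an immuno-stimulatory intervention. The package starts from
error-corrected, V/J-annotated sequences (upstream read processing, V/J
alignment and CDR3 calling are assumed done) and asks which clonal lineages
expand beyond what resampling noise explains.

The analysis chain is:

* **Clonotype**: unique (chain, V gene, J gene, CDR3 amino acid sequence).
  Counts are sequence (duplicate-count) weighted. Heavy chains form one
  frequency denominator; IGK and IGL are pooled into a joint light-chain
  ("IgKL") denominator because the κ/λ ratio and light-chain diversity are
  properties of the joint light-chain repertoire.
* **Lineage**: clonotypes of one animal (all timepoints pooled) with the
  same V, J and CDR3 length, connected under single linkage with CDR3
  hamming distance ≤ 1. Single linkage means two CDR3s two mismatches apart
  co-cluster when an intermediate links them; this matches the idea that a
  lineage is the closure of stepwise somatic variants of one ancestral
  rearrangement. Allele suffixes (`*01`) are stripped before matching, since
  allele-level calls are unstable at these read lengths.
* **Per-lineage, per-timepoint indices**: cumulative frequency, number of
  unique CDR3s, and the pooled somatic hypermutation rate
  $100\,(\sum_i v_i + \sum_i j_i)/(\sum_i V_i + \sum_i J_i)$ over member
  sequences (mismatches over aligned lengths, duplicate-weighted). The
  pooled form — rather than the mean of per-sequence rates — was chosen
  because it is additive under pooling and robust to short aligned segments.
* **Dynamics**: for each index, $\log_2 FC = \log_2(\text{value}_t /
  \text{value}_{0h})$. *Increased* on an index: $\log_2 FC > 1$.
  *Decreased*: $FC < 0.5$, i.e. $\log_2 FC < -1$ — the fold-scale mirror of
  the increased rule. A literal variant of the decreased cut
  ($\log_2 FC < 0.5$) is available via `literalDecreased = TRUE`, but it
  would label mild increases as decreases, so the symmetric rule is the
  default.
* **Expanded**: at 48 h or 72 h, at least one chain-specific criterion pair
  holds — fold change above threshold AND the post-stimulation value above
  an absolute floor, both at the same timepoint. Defaults
  (`defaultThresholds()`): IgKL — frequency $\log_2 FC > 3$ with frequency
  $> 0.001\%$; unique CDR3 $\log_2 FC > 2$ with count $> 5$; mutation rate
  $\log_2 FC > 1.3$ with rate $> 6\%$. IGH — frequency $\log_2 FC > 3$ with
  frequency $> 0.001\%$; mutation rate $\log_2 FC > 1.5$ with rate $> 5\%$.
  Criteria combine with OR; `criteria_met` records which fired. All
  thresholds are strict inequalities; boundary values do not qualify.

### Definedness of fold changes

A fold change is defined only when baseline and post values are both present
and positive. A lineage absent at 0 h cannot be classified (it is excluded
and counted, not treated as infinite fold change): expansion calls are
anchored to a baseline state, and origin tracing needs 0 h members. A
lineage present at 0 h but absent at a later timepoint likewise yields an
undefined fold change at that timepoint rather than a "decrease to zero".
Besides keeping log arithmetic total, this preserves an exact symmetry: in
a cohort with no intervention effect, the 0 h and t h samples of a lineage
are exchangeable draws, so conditional on both being positive the fold
change and its reciprocal are equidistributed — increased and decreased
counts are balanced in expectation, which is the homeostasis null the
calibration tests check.

## Supporting metrics

* **Diversity**: Shannon index $-\sum p_i \ln p_i$ (natural log), Gini index
  in the mean-absolute-difference form
  $\sum_{ij}|x_i-x_j| / (2n\sum_j x_j)$ (identical to the Lorenz-curve
  form), top-N cumulative frequency (default N = 100, descending sort with
  deterministic tie-break by label). Lineage-level diversity substitutes
  lineage cumulative frequencies for clonotype frequencies.
* **Similarity**: Morisita–Horn on clonotype counts
  ($2\sum x_i y_i / [(\sum x_i^2/X^2 + \sum y_i^2/Y^2) X Y]$); the
  timepoint overlap index is the overlap coefficient
  $|A\cap B|/\min(|A|,|B|)$, chosen over Jaccard (available via `method =
  "jaccard"`) because the expanded-lineage pool is orders of magnitude
  smaller than the full pool and Jaccard would be dominated by that size
  asymmetry; inter-individual gene-usage similarity uses Spearman's rank
  correlation on the gene-label union.
* **Subsampling**: diversity comparisons across samples of unequal depth use
  multivariate-hypergeometric subsampling (draws without replacement from
  the count-expanded multiset), defaulting to 400k heavy / 500k light
  sequences; depth and seed are explicit arguments.
* **Mutation classes**: heavy chain — IgM/IgD with rate < 0.5%
  ("IgMD_nonmutated", naive-like), IgA/G/E with rate > 3% ("IgAGE_mutated",
  memory/effector-like), IgM with rate > 3% ("IgM_mutated",
  IgM-memory-like), remainder "other"; light chain — < 0.5% non-mutated,
  > 4% mutated, otherwise intermediate.
* **Statistics**: two-sided Wilcoxon signed-rank for paired comparisons
  (exact distribution for ≤ 25 non-zero differences without ties, otherwise
  normal approximation with continuity correction), Benjamini–Hochberg FDR,
  Spearman correlation. Pairs fed to the signed-rank test should be
  independent units — in the calibration tests, animals, not
  (animal × timepoint) strata, because all post-baseline timepoints share
  one 0 h sample and that correlation inflates the test otherwise.

## Lineage phylogenies

Lineage trees use a fixed-length subsequence per sequence: the 10 nt of
V region immediately 5′ of the CDR3, the CDR3 nucleotides, and the J-region
nucleotides. Members of one lineage share V, J and CDR3 length, so these
subsequences align without gaps and no multiple alignment is needed.
Distances are uncorrected p-distances (Jukes–Cantor behind a flag; at
within-lineage divergences the correction is negligible). Trees are built
by Saitou–Nei Neighbor-Joining implemented in the package: ties in the
Q-criterion break deterministically on the lowest (row, column) pair,
negative branch lengths are clamped to zero and counted, and duplicate
subsequences are collapsed to one taxon with a multiplicity annotation
(NJ degenerates on zero-distance pairs). On additive matrices the
implementation reproduces the generating topology and branch lengths to
machine precision, which the test suite verifies against independently
generated random trees and against `ape::nj`.

## The synthetic cohort generator

`generateCohort(cohortConfig(...))` emulates the study design the analysis
assumes: animals of two species (IRM/AGM), six timepoints, heavy and pooled
light chains, fixed sequencing depth per sample. Its defaults are the
package's reference conditions and were chosen once:

* **Depth** 200,000 sequences per chain-group sample and **4,000** baseline
  lineages per animal and chain-group — deep enough that each sample holds
  tens of thousands of unique clonotypes, proportionally similar to
  real repertoire sequencing after depth normalisation.
* **Power-law abundances** with exponent 0.8 (lineage weight ∝ rank^−0.8):
  keeps the largest lineage near a few percent of the repertoire, typical of
  healthy steady-state repertoires, while leaving a long sampled tail.
* **Mutation mixture** with weights (0.4, 0.3, 0.3) and per-lineage rates
  log-normally jittered around peaks at 0.2%, 2% and 7%, clamped inside
  class windows: reproduces the three-peak per-sequence SHM histogram
  (naive-like below 0.5%, intermediate, memory-like above the 4%/3%
  mutated-class cuts). Mismatch counts are binomial draws over aligned
  lengths (240–300 nt V, 30–45 nt J) — the data model the pooled SHM
  formula assumes. A clone's mismatch profile and isotype are drawn once
  and held fixed across timepoints: a sequence's mutation content is a
  property of the clone, so lineage-level rate changes arise from
  composition shifts, not per-timepoint redrawing.
* **Isotypes conditional on class** (heavy chain only): naive-like mostly
  IgM with some IgD; memory-like dominated by IgA/IgG with an IgM-memory
  component; light chains carry no isotype.
* **Baseline κ:λ = 2**, the conventional healthy light-chain balance.
* **Planted expansions**: 50 light-chain lineages (heavy-chain planting off
  by default, configurable), drawn from lineages with expected baseline
  counts of 15–60 so the baseline is solid but the lineage is far from
  dominant. Mechanisms per lineage: frequency (weight × 2^4), CDR3
  diversification (variant count × 2^3, added as new single-mismatch
  CDR3s, which also raises lineage mass as real clonal expansion does), and
  mutation-rate boost (× 2^2.3, capped at 45%), each applied with
  probability 0.7 and at least one active; a naive-origin lineage never
  carries the mutation mechanism alone, since low-mutation cells cannot
  present a > 6% SHM rate within days. The targets sit ≥ 1 log₂ unit above
  the calling thresholds. λ-bias 0.8, persistence to one week 0.6,
  memory-like origin 0.8.

Everything is a deterministic function of the configuration including its
mandatory seed; regenerating with the same seed gives byte-identical files.

### What passing tests do and do not show

The generator reproduces the *structure* the detector relies on — power-law
abundances, multinomial resampling noise, the three-peak SHM mixture,
class-conditional isotypes, baseline-anchored expansions — but not PCR or
sequencing error, primer bias, germline allele diversity, indels in CDR3s,
biased SHM targeting, or selection. Planted expansions are strong and
concentrated by design (detectability with margin), so the cohort-level
diversity response differs from a broad physiological response: planting
concentrates mass and lowers Shannon diversity at trigger timepoints,
whereas a diffuse many-lineage response raises it. Recovery results on this
generator therefore demonstrate correctness of the pipeline's bookkeeping
and thresholds under the assumed noise model, not performance on raw
sequencer output.

## Numerical and implementation choices

* Clustering finds hamming-1 edges with a masked-position hash (two
  equal-length strings are ≤ 1 mismatch apart iff they agree after masking
  one position), giving O(nL) edge discovery and union-find components; the
  test suite checks exact equality against a brute-force all-pairs oracle.
  Lineage IDs are deterministic:
  `animal|chain_group|V|J|length|smallest member CDR3`.
* Frequencies are fractions in [0, 1] throughout; thresholds quoted in
  percent are converted internally (0.001% = 1e-5).
* Frequency-matched control draws stratify over 10 log10-spaced bins
  spanning the pool's nonzero frequency range, with nearest-stratum
  fallback (warned) when a bin is exhausted — expanded lineages concentrate
  in the top bins where the pool is thin.
* Degenerate inputs error early and explicitly: all-zero Gini input, zero
  total Morisita–Horn counts, zero aligned length in the SHM rate, zero IGL
  counts in the κ/λ ratio, non-symmetric NJ input, unequal sequence lengths
  in p-distances.

## Problem sizes used by the test suite

Unit tests run on hand-built fixtures and tiny cohorts (2 animals × 5,000
sequences). The end-to-end recovery check runs the full default cohort
(6 animals × 6 timepoints × 200,000 sequences per chain-group). Replicated
calibration checks use 20 seeded cohorts of 6 animals × 12,000 sequences
(null) and 2 animals × 20,000 sequences (planted directions) — sizes chosen
to give stable counts for the directional comparisons while keeping the
suite quick to run.

## Known limitations

* Lineage clustering tolerates no CDR3 indels; length-variant members of a
  true biological lineage form separate lineages here.
* Lineages absent at baseline are excluded from dynamics; a genuinely novel
  lineage appearing only post-stimulation is invisible to the expanded
  caller by construction.
* The κ/λ ratio and light-chain pooling assume both light loci were
  captured with comparable efficiency.
* NJ trees are unrooted and carry no support values; they visualise
  within-lineage structure rather than test evolutionary hypotheses.
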
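---
title: "Detecting miRNA-gene enrichment in de novo CNVs: model and methods"
author: "cnvMir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting miRNA-gene enrichment in de novo CNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvMir)
```

## The question and the data model

Copy number variants (CNVs) delete or duplicate genomic segments from
roughly a kilobase up to several megabases; microRNA genes (miRBase
`miRNA_primary_transcript` loci) are tiny by comparison, typically
78–110 bp. When a cohort of patients carries de novo CNVs, some miRNA
loci will fall inside them merely because the CNVs are large; the
analytically interesting situation is a chromosome where the CNVs cover
*more* miRNA loci than their sizes alone explain. `cnvMir` formalises
this per chromosome and per CNV type (Gain or Loss).

All coordinates are 1-based and inclusive on both ends, so a locus size
is `end - start + 1` — the convention used by miRBase GRCh37 tables,
which the reader validates (BED input is shifted at the boundary; a
leading `chr` in chromosome labels is stripped). CNV calls identical in
(chromosome, start, end, type) across patients are collapsed to one
record that retains the patient list, so the unit of analysis is the
distinct CNV event, not the carrier; `keepDuplicates = TRUE` disables
this for sensitivity analyses.

## The observed statistic

For each (chromosome, type) combination with at least one CNV,
`summarizeCnvMirna()` reports

* `L1`, `R1 = L1/G`: summed miRNA gene length and its fraction of the
  chromosome length `G`;
* `L2`, `R2 = L2/G`: the union length of the CNVs — overlapping CNV
  regions counted once, via sort-and-sweep interval merging — and its
  fraction of `G`;
* `hits`: the sum over CNVs of the number of miRNA genes each overlaps.
  A gene inside two distinct CNVs contributes two hits; `unique` counts
  distinct genes, so `unique <= hits`;
* combinations with no CNVs are kept as explicit no-data rows (written
  as `N/A` by the tabular writers) rather than dropped, so downstream
  multiple-testing families are unambiguous.

Overlap is closed-interval intersection: a CNV and a gene overlap when
they share at least one base; mere adjacency does not count. Because
CNVs are at least an order of magnitude longer than miRNA loci,
intersection and full containment almost always agree; both predicates
are implemented (`overlapMode = "any"` or `"containment"`) and the
choice is threaded through every stage, including the null. Strand is
recorded but ignored — CNVs are unstranded dosage events.

## The randomization null

The null hypothesis is that CNV placement is uniform over the
chromosome. One realization keeps every CNV's length `L` fixed and
redraws its start uniformly from `{1, ..., G - L + 1}` (the CNV stays
wholly inside the chromosome), independently across CNVs — simulated
CNVs may therefore overlap one another. All CNVs of one type on one
chromosome are re-placed jointly per realization, and the hits statistic
is recomputed. After `N` realizations (default `1e6`), the empirical
upper-tail p-value of the observed value `H` is the plain proportion

$$p = \frac{\#\{\text{realizations with hits} \ge H\}}{N},$$

the area of the null histogram at and beyond `H`. The plain proportion
can be exactly zero when `H` exceeds every simulated value; users who
need guaranteed-positive p-values can request the `(r+1)/(N+1)` variant
(`correction = "add-one"`), which is not the default because the tail
area above is the definition the rest of the analysis is built on.

Two design choices deserve emphasis. First, *independent* placement is
what makes an analytic check possible: the exact distribution of the
total hits statistic is then the convolution of per-CNV hit
distributions. `exactHitDistribution()` derives each per-CNV pmf by an
event-point sweep — each gene contributes a window of start positions
that produce a hit, and the hit count as a function of the start is a
step function whose segment widths give the pmf — with a brute-force
enumeration of every legal start as a second, independent
implementation; `convolvePmfs()` combines them sparsely. On real-scale
data the dependence between CNVs that a non-overlapping placement model
would introduce is negligible because CNVs cover at most ~a quarter of
any chromosome, but the choice matters in principle and is stated here
rather than hidden. Second, the Monte Carlo sampler evaluates the same
step functions at sampled starts, so sampler and exact path share the
hit *definition* but not the distributional computation; the test suite
holds them against each other (total-variation distance shrinking like
$N^{-1/2}$, tail probabilities within binomial standard errors) and
against a literal place-and-count loop.

## Multiple testing, correlation, candidates

Raw p-values are adjusted with the Benjamini–Hochberg step-up procedure
(via `stats::p.adjust`; an independently coded sort-and-cummin reference
guards it in the tests). Adjustment is applied separately within the
Gain family and within the Loss family, over combinations that have
data: the two CNV classes are biologically distinct dosage events and
each column of the per-type analysis forms its own family. A
`fdrFamily = "joint"` option adjusts across both at once for users who
prefer a single family. Significance is the strict inequality
`p_fdr < alpha` with `alpha = 0.05` by default.

`correlateHitsCoverage()` quantifies the baseline expectation that hits
grow with coverage: Pearson's r between per-chromosome `hits` and `R2`,
with the least-squares line of hits on R2, separately per type and
excluding no-data rows (at least three points are required; zero
variance is an error, not an `NA`). Chromosomes far above the line are
the natural enrichment suspects, but the randomization test — not the
regression residual — is what confers significance.

Candidates are the distinct miRNA genes overlapped by at least one CNV
on a significant combination (`enrichedCandidates()`), annotated with
the implicating CNV types and the number of distinct carriers.
`populationFilter()` marks each candidate as population-seen when it
overlaps any CNV from a population catalogue (Gains and Losses pooled,
same overlap predicate); the remaining study-specific candidates are the
strongest nominations.

## The synthetic-data generator

`simulateDataset()` produces the datasets the test suite and the
calibration/power experiments run on. Defaults, chosen once as a
realistic miniature of the intended data:

| parameter | default | rationale |
| --- | --- | --- |
| `chromLengths` | one 10-Mb chromosome | large enough that 10 CNVs of kb–Mb scale cover a few percent, the coverage regime of real per-chromosome data, while keeping expected null hits near 1 |
| `nGenes` | 10 | a plausible per-chromosome miRNA count at 1:25 scale |
| `geneLengthRange` | 80–110 bp | the empirical size range of annotated hairpin loci |
| `nCnvs` | 10 per type | cohort-scale per-chromosome CNV counts |
| `cnvLengthRange` | 1 kb – 1 Mb, log-uniform | CNV lengths span orders of magnitude; log-uniform reproduces that spread |
| `enrichment` (q) | 0 | the null regime |

Genes are placed uniformly without mutual overlap (real miRNA clusters
can be nearly adjacent; clustering is a stress-test variant users can
build, not the default). With enrichment `q`, `round(q * nCnvs)` CNVs
per type are *forced* hits: a gene is chosen uniformly and the CNV start
is drawn uniformly among the starts whose interval contains the whole
gene, clamped to the chromosome (a CNV shorter than the gene falls back
to any overlapping placement). The remaining CNVs are placed uniformly —
exactly the null model of `simulateNull()`, which is what makes `q = 0`
datasets a valid calibration instrument. The generator is a pure
function of its arguments and the seed, and its files round-trip through
the package readers byte-identically.

What the generator does *not* emulate: chromosome-specific gene
clustering, aCGH platform resolution and breakpoint uncertainty,
recurrent CNV hotspots, and inter-patient dependence. Passing
calibration and power checks on these fixtures therefore demonstrates
the correctness of the statistical machinery under its own null, not the
adequacy of the uniform-placement null for any particular real genome.

## Numerical choices and degenerate inputs

* Hit counting for observed data uses a dense pairwise comparison
  (chromosome-level counts are small); the simulation path uses the
  step-function evaluation, and the two are cross-checked.
* Exact pmfs are stored sparsely (support → probability), keeping the
  convolution quadratic in support size rather than linear in `G`.
* A CNV longer than its chromosome is an error naming the record; a CNV
  exactly the chromosome length has a single legal placement.
* Empty gene lists are valid: the null concentrates at zero and every
  observed value has p = 1 at `H = 0`.
* `empiricalPvalue` is non-increasing in the observed value by
  construction; `p_fdr >= p_raw` always.
* Monte Carlo reproducibility: `testEnrichment(seed =)` seeds one RNG
  stream consumed in a fixed chromosome/type order, so a run is a pure
  function of (data, parameters, seed).

## Problem sizes used in the shipped experiments

The package's own experiments are sized for a desk run: calibration uses
200 regenerated null datasets at `1e4` realizations each; power uses 100
planted datasets (`q = 0.8`, 10 genes, 10 CNVs) at `1e4` realizations;
sampler-vs-exact agreement uses a 10-kb toy chromosome with 5 genes and
3 CNVs at `1e5` realizations. The default `1e6` realizations per
chromosome remains the recommendation for real analyses, where the
smallest resolvable p-value (`1/N`) should sit well below the
Bonferroni-scale thresholds of interest.

## Known limitations

* The uniform-placement null ignores assembly gaps, segmental
  duplications and CNV formation hotspots; enrichment against a
  GC-/gap-aware null is out of scope.
* Hits weight every gene equally; no dosage or gene-length weighting.
* The population filter is presence/absence against the supplied
  catalogue; it does not model population CNV frequency.
* Annotation-snapshot drift changes mapped-gene counts by a few units
  between miRBase releases; analyses should record the snapshot used
  (the output headers record version, seed and parameters for this
  reason).
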
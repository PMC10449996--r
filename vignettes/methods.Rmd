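---
title: "Methods: cross-phenotype CNV gene overlap and developmental constraint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-phenotype CNV gene overlap and developmental constraint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvconstraint)
```

## The problem

Neurodevelopmental disorders (NDD) and congenital anomalies (CA) are
phenotypically distinct but co-occur often, and several genomic disorders
(22q11.2, 15q13.3, 1p36) present with either phenotype. When two clinical
cohorts — one ascertained for NDD, one for CA — both carry rare copy
number variants (CNVs) over the same genes, those genes are candidates
for a shared developmental etiology, particularly when they are
*constraint* genes: intolerant of loss of function and highly expressed
in the developing brain.

`cnvconstraint` implements that analysis as a reusable pipeline. It
consumes already-called, already-classified CNV tables (segmentation and
ACMG classification are upstream), a CDS-level gene annotation, a control
CNV cohort, per-gene pLI scores, an exon-by-brain-sample RPKM matrix with
developmental-stage metadata, a per-exon rare-mutation burden vector, and
a GMT pathway collection.

## The pipeline, stage by stage

**CNV filtering.** Calls outside the 10 kb to 10 Mb window are excluded.
The bounds are inclusive: the source criterion states what is *excluded*
(smaller than 10 kb, larger than 10 Mb), so a call of exactly 10 kb is
kept. Filtering is idempotent and monotone in the window; per-filter
exclusion counts are logged and conserved (excluded + retained = input).

**Gene extraction.** A gene is impacted by a CNV iff the CNV overlaps at
least one base pair of at least one of its CDS intervals (closed
1-based intervals; `GenomicRanges::findOverlaps` does the interval
work). Intronic-only overlap does not count; UTR-only exons are not
modeled, since gene assignment is by unique CDS ids with exact-duplicate
intervals collapsed.

**Control filtering.** A gene's control frequency is the fraction of
control samples carrying at least one CNV hitting it (a sample hit twice
counts once). Genes with frequency strictly above 0.001 are removed —
strict, following the wording "frequency > 0.001". Deletions and
duplications are pooled in the control count by default (conservative
removal); `control_type_match` restricts to type-matched hits.

**Overlap statistics.** For each stratum in {male, female, pooled} x
{pathogenic, VUS} x {deletion, duplication} x {all, de novo}, the two
cohorts' post-filter gene sets are tested with a one-sided Fisher's
exact test: `p = P(X >= a)` for hypergeometric `X`, i.e. enrichment of
the intersection against a finite universe. One-sided matches the
default of the GeneOverlap-style testing this reproduces. The odds ratio
is the sample cross-product `(a*d)/(b*c)` with conventions 0 (`a = 0`)
and infinite (`b*c = 0, a > 0`) — the convention that naturally produces
the exact 0 and "infinite" values such analyses report; a
conditional-MLE variant is exposed via `or_method = "cmle"`. The
universe defaults to the number of genes with at least one CDS interval
in the loaded annotation, because no universe is canonical for clinical
CNV data; it is configurable. P-values below double underflow are
formatted as `< 1e-300`. No multiple-testing correction is applied
across strata at this stage.

**Constraint gate.** An exon is *critical* in a brain sample iff its
expression is strictly above the sample's 75th percentile (over exons)
and its rare (frequency < 0.01) non-synonymous mutation burden is
strictly below the 75th percentile of burden over all exons. Percentiles
use linear interpolation between order statistics (`quantile` type 7),
the common scientific-computing default; the type is configurable. The
expression threshold is per sample because criticality is declared per
sample; a global-matrix alternative is exposed
(`expr_threshold_scope = "global"`) since "compared to the entire
dataset" is ambiguous. A gene is a critical-exon (CE) gene iff a single
exon is critical in at least 50 brain samples — per exon, never pooled
across exons. The 50 is kept absolute (not rescaled as a fraction of the
matrix width) with a config override, since the criterion was stated as
an absolute sample count. The constraint gate retains a gene iff it is a
CE gene **or** has pLI >= 0.9 (inclusive). A missing pLI fails the pLI
arm: absence of evidence never passes a constraint filter. The source
mixes "pLI > 0.90" and "pLI >= 0.9" in different places; the single
inclusive threshold is used throughout.

**Expression profiles.** Gene-level expression is the unweighted mean of
exon RPKM (median available). Stage summaries report per-gene means for
prenatal, early-childhood and adult samples and per-stage quartiles with
IQR whiskers (Q1 - IQR, Q3 + IQR). Stage comparisons use a two-sided
Mann-Whitney U test — exact for groups of at most 8 without ties, normal
approximation with tie correction otherwise, without continuity
correction so identical distributions give p = 1. The test is a design
choice: the compared RPKM distributions are non-normal and no test was
named in the source analysis. All three pairwise stage comparisons are
reported, since the original figure does not say which pair its p-value
compares. Multi-tissue proteome/transcriptome summaries rank tissues by
median with alphabetical tie-break, and the expression call on exon-array
data is log2 intensity >= 6 with a gene expressed iff any exon is.

**Pathway enrichment.** Pathways with more than 50 and fewer than 1000
members (strict bounds) are tested with the same hypergeometric core as
the overlap test; Benjamini-Hochberg FDR is computed across tested
pathways (`stats::p.adjust`). A pathway passes iff p < 0.05, FDR < 0.01
and at least 5 query genes overlap it — the dual p/FDR gate is applied
exactly as stated even though the FDR gate dominates. KEGG/GO are
consumed as user-supplied GMT snapshots, never fetched live, so results
are reproducible against a fixed database version. The network export
draws an undirected edge between passing pathways when the overlap
coefficient of their overlap-gene sets is at least 0.5 (EnrichmentMap
convention; Jaccard available), and writes Cytoscape-readable node/edge
tables and SIF.

**Candidate ranking.** For each constraint-overlap gene, the pipeline
counts distinct case CNVs of at most 1 Mb hitting its CDS (CNV-level:
two qualifying CNVs in one sample both count), orders by descending
count with alphabetical tie-break, flags genes with at least two
gene-specific CNVs as candidates, and emits the non-OMIM sublist
separately. OMIM membership is a boolean input column, not a live
query.

## The synthetic study and what it shows

The clinical cohorts behind this design are not deposited, so the
package ships a seeded generator (`simulate_study()`) that emulates
their statistical structure with planted ground truth. The desk-scale
preset — chosen once as a realistic, fast configuration — is:

* 500 genes with 2–10 CDS intervals each, spread over chromosomes 1–22
  and X with wide intergenic gaps;
* 300 NDD, 150 CA, 400 control samples;
* 30 genes shared between cohorts via pathogenic de novo deletions and
  12 via duplications (penetrance 1), 10 private genes per cohort, 25
  control-common genes at 5% carrier recurrence, plus background noise
  CNVs of mixed pathogenicity in 10% of samples;
* 60 brain expression samples (20 per stage, 16 region labels);
  log-normal RPKM with a 2-SD log-mean shift for constraint-gene exons
  plus a prenatal boost (0.75, with 40% of it in adults) so the planted
  stage ordering is prenatal > adult > early childhood; Poisson burden
  (rate 8 background, 1 for constraint exons); pLI U(0.9, 1) for
  constraint genes, U(0, 0.89) otherwise;
* 100 pathways of 60–200 genes, one overloaded with every planted
  constraint gene.

Background noise CNVs never hit planted case genes. That is ground-truth
semantics, not tuning: the planted categories assert those genes are
rare in every cohort but their own, and at 400 controls a single stray
carrier (frequency 1/400) would already exceed the 0.001 control filter
and contradict the category. This is also where the scaled-down study
differs most from the real one: with 9,692 controls the 0.001 threshold
tolerates up to 9 carriers, so the filter is far less brittle at full
scale.

The generator is deterministic under its seed (all randomness flows
through one seed; the RNG state of the caller is preserved), and the
files it writes round-trip through every reader.

What passing tests on this generator demonstrate: the interval
arithmetic, counting rules, thresholds and statistics implement the
stated procedure exactly (oracle equivalence against brute-force
re-implementations), the overlap test is calibrated, and the pipeline
recovers planted structure end to end. What they do not demonstrate:
performance on real aCGH calls — the generator does not mimic probe
noise, CNV hotspots, segmental-duplication artifacts, batch effects
between case and control platforms, or correlated expression between
neighbouring exons.

## Numerical choices and degenerate inputs

* Percentile convention: `quantile` type 7 everywhere, configurable.
* Strict vs inclusive comparisons follow the stated wording verbatim:
  size window inclusive, control frequency strictly `>`, expression
  strictly `>`, burden strictly `<`, pLI `>=`, pathway size strictly
  between, expression call `>=` 6.
* Percentages round half away from zero (so 31/170 prints 18 and 19/48
  prints 40) and always retain numerator and denominator.
* A stratum with an empty gene set on either side is reported with
  `a = 0` and a degenerate flag, never as an error; an empty CA cohort
  completes the run. Fewer than 3 constraint genes skips the stage
  tests (the rank test needs 3 per group). A critical-exon matrix needs
  at least 2 exons for its percentiles to be defined.
* Enum tokens are matched case-insensitively with clinical synonyms
  (`loss`/`gain`, `denovo`, `m`/`f`); unknown tokens are rejected, not
  guessed.
* Tie-breaks are deterministic and documented: tissue ranking and
  candidate ranking break ties alphabetically.

## Validation design

The test suite pairs every non-trivial computation with an independent
oracle: explicit `choose()`-sum tail enumeration for the hypergeometric
test (every table with universe <= 25), a per-basepair membership loop
for CNV-gene intersection, a double-loop re-implementation of the
critical-exon classifier, full permutation enumeration for the
Mann-Whitney test at small n, and a hand-computed Benjamini-Hochberg
example. Calibration of the overlap test is checked at universe 1000
with |A| = |B| = 400 — a configuration chosen by exact computation
(before simulating) so the discrete test's attainable size, 0.0499, is
close enough to the nominal 0.05 for the +/- 2 SE band over 2,000
replicates to be informative; discrete exact tests are conservative at
most configurations, which would make the nominal-rate property
vacuous. The null pathway pass rate is measured pooled across seeded
replicates of null-only collections, where the FDR < 0.01 gate keeps it
far below 1%.

## Known limitations

* No reciprocal-overlap merging of CNVs across samples, breakpoint
  refinement, liftover, VCF support, or probe-level segmentation.
* The control filter depends on the control cohort size; at small n the
  strict 0.001 threshold means any carrier removes a gene.
* Overlapping (non-identical) CDS intervals of one gene can double-count
  overlapped base pairs in the hit table; gene membership is unaffected.
* Burden is an input vector; the package does not recompute it from
  population VCFs.
* The annotation release supplying CDS ids is the user's choice; results
  are only comparable across runs sharing an annotation.
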
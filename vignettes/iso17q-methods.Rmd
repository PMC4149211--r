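---
title: "Methods: dosage-aware expression analysis and replicate-concordant variant filtering in i17q medulloblastoma"
author: "iso17q authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{iso17q methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iso17q)
```

## The scientific problem

Isodicentric chromosome 17 — i17q, formally idic(17)(p11.2) — is the most
common chromosomal abnormality in medulloblastoma. Its formation by
non-allelic homologous recombination at the 17p11.2 low-copy repeats leaves
the tumor with **one** copy of 17p telomeric to the breakpoint and **three**
copies of everything centromeric of it plus all of 17q. Two consequences
follow for expression data: genes on distal 17p should drop to roughly
0.5-fold expression (hemizygous dosage), and genes on 17q should rise to
roughly 1.5-fold (duplication dosage). The analytic question this package
answers is whether a focal gene — TP53, the canonical 17p tumor suppressor —
is suppressed *beyond* what its compartment's dosage background predicts,
which would mark the rearrangement as a targeted p53-pathway lesion rather
than a passenger-scale copy-number effect.

Around that core test the package implements the rest of the analysis chain
such a study needs: stringent filtering of amplicon variant calls from FFPE
tissue, mutation-table summaries, probe-normalized expression comparisons
across the WNT/SHH/group3/group4 molecular subgroups, and Kaplan–Meier /
log-rank survival stratification with a combined molecular-risk rule
(mutation **or** i17q).

## Variant filtering model

FFPE DNA accumulates crosslinking and cytosine-deamination damage, and
microfluidic amplification can "jackpot" an early-cycle artifact to a high
allele fraction in a single replicate. The retention procedure therefore
uses three independent lines of evidence:

1. **Caller thresholds** (on the calls made from the *compiled* alignments
   of all replicates): call quality ≥ 30, mapping quality ≥ 30, alternate
   allele fraction ≥ 0.20. All three are minima, so a call at exactly the
   bound is retained.
2. **Annotation filters**: synonymous and intronic (non-splice-site)
   changes are removed, as are variants documented at a population allele
   frequency strictly above 1% in any of dbSNP, 1000 genomes or the 6500
   exomes set. The *maximum* frequency across the three databases is used,
   and a variant absent from all of them is treated as novel and retained.
3. **Replicate concordance**: a pooled call survives only if at least one
   *individual* amplification replicate of the same sample shows the same
   chrom/pos/ref/alt at an allele fraction strictly greater than 5%. The
   pooled run itself never counts as the supporting replicate; a replicate
   at exactly 5% does not qualify. The deliberate asymmetry — inclusive
   caller minima, exclusive concordance bound — follows the wording of the
   two rules and is unit-tested at both boundaries.

Variant identity is always the tuple (chromosome, 1-based position, ref,
alt). Damage-predictor tallies (AV_SIFT/PolyPhen/LRT/MutationTaster) are
annotation *inputs* carried through to the mutation table, never computed.

Sensitivity and specificity are defined against a truth table: retained
true variants / all true variants, and rejected artifacts / all artifacts.
When a denominator is empty the rate is reported as undefined rather than
silently coerced.

## The dosage-excess test

`computeFoldChanges()` expresses every feature as the ratio of class
geometric means, `2^(mean log2 i17q-positive − mean log2 i17q-negative)`.
Geometric (log-scale) means were chosen over arithmetic means because
microarray log2 intensities are the natural symmetric scale; the fold of a
pure hemizygous effect is then exactly 0.5 regardless of a gene's baseline.

`partitionByBreakpoint()` splits chromosome 17 at a configurable breakpoint
coordinate (default 20,000,000, a 1-based coordinate inside 17p11.2; the
breakpoint region is defined cytogenetically by the REPA/REPB repeats, so
any coordinate within the repeat region is equally defensible and the exact
value is a tunable). Features strictly below the breakpoint are
`hemizygous`, at or above it `duplicated`, off chromosome 17 `other`.

`focalExcessTest()` then asks whether the focal gene is an outlier within
its own compartment:

* the **background** is the set of per-feature folds of all hemizygous
  features except the focal gene (at least 10 required, since a smaller
  background gives an unstable SD);
* `focalZ` standardizes the focal fold against the background mean and SD
  on the **linear fold** scale, with an explicit indicator for `focalZ <
  -2` ("more than 2 SD below the average hemizygous gene");
* a Welch t-test compares the focal gene's per-i17q-sample normalized
  log2 values (each positive sample minus the negative-class mean) against
  the background per-feature log2 folds, and the raw p is Bonferroni
  multiplied by the number of hemizygous-compartment features.

Two genuinely open choices are worth recording. First, the *units* of the
focal-vs-background comparison: per-sample values against per-feature folds
(default) or per-sample values against pooled per-sample background values
(`mode = "per-feature"`). Both are implemented; neither is claimed to
reproduce any externally printed p-value, which would require the original
103-tumor microarray data. Second, the **Bonferroni factor**: the count of
hemizygous-compartment features (default) rather than all chromosome 17
features, because only hemizygous features are candidate comparisons; the
factor is overridable and always reported. The t-test is run on the log2
scale to avoid the Jensen bias that linear per-sample folds carry under
log-normal noise; the z-score stays on the linear fold scale where the
2-SD remark is defined.

`pathwayPanelProfile()` applies the same fold + Welch machinery to an
explicit gene panel (core TP53/WIP1, chIP-seq p53 targets, signal
transducers — panel membership is an input, not discovered), Bonferroni
corrected by panel size with `*`/`**` at corrected p < 0.05 / < 0.01.

## Subgroup and two-group comparisons

`probeNormalize()` divides each feature by its probe count so genes
represented by different probe numbers are directly comparable.
`subgroupAnova()` is a fixed-effects one-way ANOVA over the four molecular
subgroups (subgroups with fewer than 2 samples are excluded with a
warning); `twoGroupTest()` is a Welch t-test by default (pooled-variance
optional) over any binary grouping — i17q status, sex, or i17q within
group 4 only. Constant input is handled explicitly: equal constant groups
give statistic 0 and p 1 instead of an error. Single-gene p-values are
reported unadjusted, matching the single-gene reporting convention of the
analyses they implement; multi-gene screens can correct externally.

## Survival stratification

The product-limit estimator and the two-group log-rank test are implemented
from their defining formulas (risk sets at each distinct time; observed
minus hypergeometric-expected events with the usual variance, no continuity
correction, chi-square with 1 df). At tied times events are processed
before censorings — the standard convention. The test suite cross-checks
both against the survival package to 1e-12 on random cohorts, keeping the
implementation and its oracle on separate routes.

The combined molecular-risk rule labels a patient high-risk when they carry
a retained chromatin-remodeling-gene mutation **or** are i17q-positive.
`runSurvivalAnalysis()` emits the full reporting grid: {OS, DFS} ×
{standard-risk only, all patients} × {mutation, i17q, combined}. Published
per-patient survival times for the original cohort are not redistributable,
so the package validates this chain by simulation instead: null calibration
(hazard ratio 1 → rejection rate at the nominal level, uniform p-values)
and power (hazard ratio 5 at n = 60 → median p well below 0.01).

## What the synthetic cohorts emulate

`simulateVariantReplicates()` draws true somatic variants per sample
(Poisson, default 0.25/sample against a 4-gene panel) that appear in
*every* replicate at allele fraction 0.2–0.6, and artifacts independently
per replicate (Poisson, default 5/replicate over 20,000 panel positions)
with transitions biased toward C>T/G>A and allele fractions
`0.3 × Beta(1, 3)` — right-skewed, bounded below 0.3, so most artifacts
fail the pooled 0.20 threshold but a minority jackpot past it. Per-site
read depths are lognormal (median 500, sdlog 1), echoing the highly skewed
coverage of microfluidic amplicon panels; pooled allele fractions are
depth-weighted means with absent replicates contributing depth at AF 0.
Site-level annotation (functional class, population frequency) is a fixed
property of the site. Under these defaults true variants are retained with
sensitivity exactly 1 — by construction they satisfy every filter — which
is precisely the qualitative behavior the filter was designed for, and
artifact co-occurrence across replicates follows the closed form
(rate/sites)² per position, which the tests verify by counting.

`simulateExpressionCohort()` writes log2 expression as gene baseline +
dosage term + focal excess + Gaussian noise (default SD 0.25 log2 units).
Half the chromosome 17 features sit below the breakpoint (with TP53 fixed
at 7,571,720 and GPS2 at 7,217,225), half above (with PPM1D/WIP1 at
58,711,000). i17q-positive samples are labeled group 4 with probability
0.85, group 3 otherwise; negatives spread over all four subgroups; the
male fraction is 0.84 among i17q-positive samples. What the generator does
*not* model: probe-level microarray physics, baseline correlation between
co-regulated genes, heavy-tailed noise, and partial tumor purity. Passing
calibration on these cohorts therefore shows the procedures are correct
under their stated assumptions, not that real microarray data meet those
assumptions.

`simulateSurvivalCohort()` draws exponential death and relapse times with
equal per-stratum hazards (defaults 0.01/month low, 0.05/month high) and
administrative censoring at 60 months, so DFS ≤ OS holds by construction.

## Problem sizes and numerical choices

The validation suite uses cohorts of 57–100 samples for filter checks
(500 for the specificity estimate), 60 samples × 1,010 features (500
hemizygous background genes) for the dosage test with 200–500 simulation
seeds, and 100–500 seeds for the survival calibrations — sizes chosen to
put binomial standard errors comfortably inside the asserted margins.
Fixed seeds make every generator bit-reproducible. Degenerate inputs are
defined rather than left to error: zero-variance t-tests return 0/1 (equal
means) or ±Inf/0, a zero-SD background with a focal gene at the mean gives
z = 0, and `censorTime = 0` yields an all-censored cohort.

## Known limitations

* The externally printed p-values of the original analyses (subgroup
  ANOVA, i17q t-tests, the corrected focal-gene p, the survival log-rank
  p-values) depend on the original 103-tumor expression matrix and
  per-patient clinical tables, which are not shipped; the package
  reproduces the printed *summary* statistics of the packaged mutation
  table and the pooled sex ratio, and validates everything else by
  simulation.
* The concordance rule's reading — an individual replicate must support
  the pooled call — is one of two defensible interpretations; the other
  (letting the pooled run itself count) would only loosen the filter.
* Whether the 18% mutated-patient fraction uses the pre- or post-QC
  cohort denominator is not derivable from the summaries; the cohort size
  is an explicit argument.
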
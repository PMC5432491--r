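---
title: "Dissecting breeding histories with pedscan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting breeding histories with pedscan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscan)
```

## The problem

Modern oilseed rape (*Brassica napus*, an allotetraploid with an A
subgenome from *B. rapa* and a C subgenome from *B. oleracea*) was bred
through a small number of documented crosses.  When the cultivars
involved are fully homozygous inbred lines genotyped at tens of
thousands of biallelic SNPs, the breeding history is legible in the
genomes themselves: long runs of identical genotype calls between two
lines mark haplotype blocks identical by descent (IBD) from a common
ancestor; depressions in within-pedigree diversity mark loci that
breeders selected; and the rate at which linkage disequilibrium (LD)
decays with physical distance bounds the size of the haplotype "cargo"
that travels with any selected gene.

`pedscan` implements this dissection as a pipeline of small, separately
testable stages, plus a forward simulator that generates pedigrees with
exact founder-origin bookkeeping so that every stage can be validated
against known truth.

## IBD detection in homozygous material

General-purpose IBD software models haplotype frequencies and phase
uncertainty.  For fully homozygous doubled-haploid (DH) or inbred lines
both complications vanish: each line *is* a haplotype, and IBD
manifests directly as a maximal run of concordant calls.  `pairwise_ibd()`
therefore scans each chromosome for maximal concordance runs under
three explicit rules:

* **Missingness.** A missing call in either line neither extends nor
  breaks a run; more than `max_missing_gap_markers` (default 50)
  consecutive missing markers break it.  This rule also makes the
  all-missing C subgenome of a diploid *B. rapa* ancestor (such as
  Chengduai) fall out naturally: the chromosome is skipped rather than
  the line excluded.
* **Mismatch tolerance.** A discordant call is absorbed only while the
  running mismatch fraction stays at or below `max_mismatch_fraction`
  (default 0.02), which accommodates residual array genotyping error.
  When a mismatch could either end one run or start the next, the left
  run is extended greedily; segment boundaries are always concordant
  markers.  With error-free data the matched setting is a tolerance of
  zero — any positive tolerance lets the detector bridge two adjacent
  true segments across a short non-IBD gap whose markers happen to
  agree by state.
* **Minimum evidence.** Runs with fewer than `min_markers` (default 20)
  compared markers, or spanning less than `min_length_mb` (default
  1 Mb), are discarded.  Segment length is `end_bp - start_bp` (not
  `+ 1`), the usual convention for physical spans.

The defaults are exposed rather than fixed because segment-level minima
are a reporting choice, not a property of the data.  Validation against
the simulator (error rate 0) gives marker-level precision and recall
above 0.99 for parent/offspring pairs, with detected boundaries within
one inter-marker interval of the identity-by-state envelope of the true
segment.  Boundary error is scored against that envelope deliberately:
when the markers flanking a true breakpoint agree by state, no method
can place the boundary more precisely than the first discordant marker.

## Direct and indirect transfer

The pedigree is a directed acyclic graph of crosses.  Transfer from an
ancestor to a descendant is **direct** when a single parent-to-offspring
edge connects them — even if additional, longer routes exist — and
**indirect** when only a path of two or more crosses does.  This
labelling matches how breeding records attribute material: a
grandparent's blocks arrive "through" the intermediate cross.
`aggregate_transfer()` attaches these labels to per-pair IBD summaries
and sums counts and sizes per final cultivar and path type; pairs
absent from the pedigree are flagged and left out of subtotals.

The theoretical contribution of an ancestor is the Mendelian
expectation `expected_contribution()`: each cross halves the expected
fraction, summed over all directed paths, so a parent contributes 0.5
and a grandparent reachable by one path 0.25.  This ignores selection
and any undocumented parents, and is reported as such: in the real
Tapidor pedigree, for example, substantial genome fractions came from
cultivars (Turret, SI8879) that are not in the documented graph, so
realized IBD totals can fall well short of the expectation.

## Sliding-window selection scan

Within each pedigree, the panel is the final cultivar plus its
documented ancestors (five lines in each of the two built-in panels).
`sliding_scan()` moves a window of 15 consecutive usable loci (a locus
is usable when at least two panel lines are called; monomorphic loci
are retained) along each chromosome, one locus per step, assigning each
window's values to its midpoint (the 8th locus).  Chromosomes are
scanned independently and chromosomes with fewer than 15 usable loci
are skipped.

Per window the scan reports:

* **S** — segregating sites;
* **pi** — the mean over all line pairs of their discordant-site
  counts (each homozygous line counts once; sites missing in either
  member of a pair are excluded for that pair);
* **Tajima's D** — `(pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the
  standard constants computed from the panel size; D is reported as
  undefined when the panel has fewer than three lines, when S = 0, or
  when the variance term vanishes;
* **Hs** — Nei's gene diversity, the mean over loci of
  `1 - q^2 - (1-q)^2` (equivalently `2q(1-q)`);
* **PIC** — the biallelic Botstein polymorphism information content,
  `1 - (p^2 + q^2) - 2 p^2 q^2`, bounded by 0.375.  The PIC formula is
  the standard biallelic form; the original analysis software does not
  print its formula, so the conventional definition is used.

With n = 5 lines the window statistics are coarse; they are descriptive
screens, not significance tests, and no coalescent null is attached to
D (a non-goal of the package).

### Selection-timing quadrants

Crossing the sign of D with gene diversity against a 0.3 threshold
gives four selection-timing calls via `classify_selection()`: under the
default `"main_text"` convention, D < 0 with Hs < 0.3 suggests
selection in earlier breeding cycles, D < 0 with Hs > 0.3 a later
round, D > 0 with Hs < 0.3 selection predating the documented pedigree,
and D > 0 with Hs > 0.3 no strong evidence of selection.  The source
analyses state the two D < 0 quadrants inconsistently between their
running text and their figure legend; because the contradiction cannot
be resolved from the description alone, both conventions are
implemented behind the `convention` switch (`"figure_legend"` swaps the
early/late assignment) and the main-text form is the default.  Exact
boundary values (D = 0 or Hs = 0.3) are reported as `no_selection` with
a boundary flag rather than silently assigned to a side.

## LD decay and gene clusters

For homozygous lines, two-marker LD needs no phasing:
`r2 = (pAB - pA*pB)^2 / (pA(1-pA) pB(1-pB))` over the lines called at
both markers, computed within chromosomes up to a maximum separation
(default 10 Mb, a bound on pair counts rather than a biological claim).
An optional windowed accounting (default 50 markers advancing by half a
window) mirrors the pair-selection rule of common LD software; both the
all-pair and windowed means are available because summaries differ
between the two accountings.

The decay curve is the one-parameter hyperbola `r2(d) = 1/(1 + beta*d)`,
chosen because it satisfies the anchor r2(0) = 1 exactly with a single
parameter; the fit minimizes least squares over `log10(beta)` by
golden-section search, which is robust for this smooth one-dimensional
problem.  The decay distance at threshold t is `(1/t - 1)/beta` — `4/beta`
at the conventional t = 0.2.  On generative data the decay distance is
recovered within 5%.

Genes lying within one decay distance of each other tend to be
inherited as one haplotype block, so `call_clusters()` groups genes per
chromosome by single linkage with an inter-gene gap at most `gap_mb`
(default 0.7 Mb, or the fitted decay distance in the pipeline),
flagging singletons and multi-trait clusters.

## QTL-by-IBD overlap and candidate genes

`intersect_qtl_ibd()` counts a QTL as "in IBD" when at least one base
pair overlaps any segment — no minimum overlap is imposed because the
consolidated QTL intervals are themselves uncertain.  Candidate genes
require full containment in the overlap by default (a flag relaxes
this), which avoids inflating counts with boundary-straddling genes.
Each candidate is annotated with the donor lineage: the IBD pair member
that is a pedigree ancestor of the other, with every directed path
rendered as a transfer chain such as
`Shengliyoucai>Chuanyou2>Ningyou7`.  `selection_annotate()` then
attaches the quadrant of the nearest scan-window midpoint (ties broken
toward the lower coordinate).

## The synthetic-pedigree generator

`simulate_pedigree()` forward-simulates any pedigree DAG of inbred
lines:

* **Founders.** Per-marker alternate-allele frequencies are drawn
  uniformly from `founder_maf_range` (default 0.1–0.9, reflecting array
  markers ascertained to be common); each founder is an independent
  homozygous draw.
* **Map.** Default 4 chromosomes (half named A.., half C.., so both
  subgenomes are represented) of 20 Mb carrying 920 markers each — the
  46 markers/Mb density of the array survey the simulator emulates,
  scaled down from 19 chromosomes so that full runs complete in
  seconds.
* **Crosses.** Each cross draws one recombinant gamete per chromosome
  from the F1 — crossover count Poisson with mean the chromosome's
  genetic length (uniform 2 cM/Mb by default), breakpoints uniform in
  genetic distance — and fixes it to homozygosity, the doubled-haploid
  endpoint used in the real material.  Uniform recombination keeps
  truth extraction exact; no interference or mutation is modelled.
* **Selection.** Directional selection is implemented by gamete
  rejection: at each target locus, whenever a parent carries the
  favored founder's allele copy, the cross is redrawn until the
  offspring carries it.  This mirrors deterministic breeder mass
  selection rather than a fitness-weight model.
* **Observation.** Genotyping error flips calls at
  `genotyping_error_rate`, missingness is applied last, and lines
  tagged as diploid A-genome species get all-missing C-subgenome
  columns.

Every allele of every line is tracked to the founder copy it descends
from and through the immediate parent that transmitted it, so
`true_ibd_segments()` can emit exact ground truth in two senses:
*lineage* truth (markers whose transmission chain passes through a
given ancestor) and *shared-founder* truth (markers where two lines
carry the same founder's copy — the pairwise notion a detector can hope
to see).  Realized ancestor fractions computed from these tracks
converge to `expected_contribution()` over replicates (0.5 parent,
0.25 grandparent).

What the simulator does **not** emulate: ascertainment bias of array
content, population structure beyond the documented pedigree,
homoeologous exchange between subgenomes, and undocumented extra
parents.  Passing validation on synthetic data therefore demonstrates
correctness of the algorithms under the stated model, not robustness
to every artefact of real array data.

### The selection-footprint study

The diversity footprint of selection is validated on a small breeding
program (two cross cycles ending in four sibling DH lines) with the
panel taken as the five post-selection descendants.  This design is
used because a panel containing the founders themselves dilutes the
footprint almost entirely: selection cannot change founder genotypes,
so forcing two descendants to carry one founder's copy shifts the
expected per-locus Hs by only ~0.02 — far below window noise.  With a
descendant panel the target locus is monomorphic (per-locus Hs exactly
0) and windows over the target show depressed Hs relative to the
genome in essentially every replicate (50-replicate studies in the
test suite and acceptance script; chromosomes of 150 markers keep each
study under half a minute).

## Numerical choices and degenerate inputs

* Marker positions are 1-based bp; exported BED is 0-based half-open.
* Heterozygous VCF calls in nominally inbred lines become missing and
  are counted in a QC summary, not rejected: residual heterozygosity is
  expected in array data.
* Tajima's D windows with S = 0, panels smaller than 3, or a vanishing
  variance term return `NA` with a reason code; quadrant calls are
  suppressed for undefined D.
* `fit_decay()` refuses fewer than 10 pairs or all-equal distances, and
  reports an infinite decay distance when the fitted beta is
  numerically zero (the curve never reaches the threshold).
* Pipeline reruns with the same configuration are byte-identical;
  per-stage seeds are derived from the global seed and the stage name,
  so adding a stage never perturbs an earlier one.

## Problem sizes

The test suite and acceptance script run scaled-down studies chosen to
exercise every code path while completing quickly: oracle checks on
windows of 15 loci and chromosomes of up to 200 markers, detector
validation on 4x500-marker genomes (5 replicates), ancestor-fraction
convergence on 4x80-marker genomes (200 replicates), and
selection-footprint studies on 2x150-marker genomes (50 replicates).
These sizes are the package's own validation choices; all scale
linearly if larger studies are wanted.
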
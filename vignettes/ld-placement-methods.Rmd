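---
title: "LD-based placement of unmapped markers: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-based placement of unmapped markers: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodemap)
```

## The statistical model

`lodemap` treats linkage disequilibrium between two biallelic SNPs as the
squared Pearson correlation of their 0/1/2 genotype allele counts,
estimated without phasing. For diploid data this genotype-count r² is a
consistent estimator of the haplotype-frequency r² as sample size grows;
for polyploids genotyped under a pseudo-diploid model (all heterozygote
dosage classes collapsed to the single code 1) it is a proxy rather than a
dosage-aware LD estimate. That proxy status is a deliberate modelling
choice: dosage-aware polyploid LD models require known ploidy per locus,
which aneuploid crops cannot supply, and the placement algorithm only
needs the *ranking and rough magnitude* of associations, not calibrated
haplotype frequencies.

Placement of a candidate marker is two steps:

1. **Assignment.** Restrict to mapped anchors with r² strictly greater
   than the threshold $t$. If fewer than two remain, the candidate is
   unplaced (reasons `no_anchor_above_threshold` or
   `single_anchor_only`). Otherwise take the two anchors with the
   highest r²; if they share a linkage group the candidate is assigned
   there, else unplaced (`top_two_disagree`). Requiring agreement of two
   independent associations is what protects against spurious long-range
   LD: chance r² between unlinked markers is of order $1/n$ and rarely
   exceeds 0.1 once, let alone twice on the same chromosome.
2. **Positioning.** The estimate is the r²-weighted mean position of
   *all* supra-threshold anchors on the assigned group,
   $\hat p = \sum_i r^2_i p_i / \sum_i r^2_i$. Using every
   supra-threshold anchor (a multi-point estimate) rather than only the
   top two averages out single-pair noise; it also means $\hat p$ is a
   convex combination of anchor positions, so estimates can never leave
   the anchors' span — a property the test suite asserts.

Key assumptions: the anchor map itself is correct (the method refines
nothing about it); LD in the population is dominated by linkage, not by
admixture or strong family structure; and the candidate's MAF is high
enough (above `maf_min`) for r² to carry signal.

## Parameters that matter

| parameter | default | units | why this value |
|---|---|---|---|
| `threshold` | 0.1 | r² | the conventional floor for a meaningful pairwise association; the threshold-sweep machinery exists precisely to examine this choice per dataset. The comparison is strict (`>`), and exposed so users can flip boundary behaviour. |
| `maf_min` | 0.01 | frequency | below this a marker's genotype vector is nearly constant and r² against it is noise; the comparison is strict (`maf > maf_min`). Populations filtered more aggressively upstream can raise it (0.1 is common for diversity panels). |
| `call_rate_min` | 0.9 | fraction | standard array-QC floor; compared with `>=`. |
| `min_complete` | 10 | samples | minimum pairwise-complete observations for r² to be defined; with fewer, a single shared haplotype produces spuriously perfect correlation. |
| `k` (folds) | 20 | — | masks 5% of anchors per fold, small enough not to thin the anchor backbone, large enough for stable fold means. |
| `max_distance` | 100 | cM | decay profiling only; pairs further apart carry no linkage signal and would dilute the smoother. |
| `span` | 0.5 | — | LOESS span for the decay curve; the decay shape is smooth and monotone at this scale, so the fit is insensitive to spans in 0.3–0.7. A binned-mean smoother (`smoother = "bin"`, 1 cM bins) is provided as a nonparametric cross-check. |

## The synthetic population

`simulate_population()` is a forward-in-time simulator, not a coalescent:
`n_founders` diploid founders (default 8) carry haplotypes drawn
independently per marker from allele frequencies uniform on
`founder_allele_freq_range`; each of `n_generations` (default 5)
generations samples two parents per offspring uniformly with replacement
and recombines haplotypes with crossover probability between adjacent
markers given by the Haldane map function $c = (1 - e^{-2d/100})/2$ — no
crossover interference, the simplest closed form, and an acceptable
simplification because the simulator only shapes the test fixture, not
the method under test.

What this emulates: the LD regime of an elite breeding population — a
narrow founder base makes the final generation a mosaic of few founder
haplotypes, so markers close on the map share mosaic blocks and show
elevated r², decaying smoothly with cM distance, while inter-chromosomal
r² stays at the $1/n$ sampling floor. The defaults (3 linkage groups ×
100 cM × 200 markers, 500 samples) keep every test and the acceptance
script within interactive runtimes while leaving ~1.8 anchors/cM, a
density comparable to a usable sparse map.

Free parameters not pinned down by the study design were fixed once:
`founder_allele_freq_range = (0.1, 0.9)` (segregating, non-extreme
founder frequencies, as expected after array ascertainment) and
`missing_rate = 0.02` (typical residual missingness after a >90%
call-rate filter). Missing calls are injected uniformly at random.

What it does **not** emulate — and hence what passing tests cannot show
about real data: population structure and admixture (which create
long-range LD and would erode assignment accuracy), selection, dosage
variation and aneuploidy (real pseudo-diploid calls in a high polyploid
are a coarser summary than a true diploid genotype), genotyping error
beyond missingness, and map error in the anchor backbone. Results on the
simulator are therefore an upper bound on, not a forecast of, real-data
performance.

## Numerical and degenerate-case choices

- r² is computed from sums over pairwise-complete observations via
  crossproducts, giving exact per-pair complete counts; a restricted
  vector with zero variance yields `NA` (undefined), never an error or a
  warning. Computed r² is clamped to `[0, 1]` against last-bit overshoot.
- Monomorphic markers (all non-missing calls identical — including the
  all-heterozygous case, whose genotype variance is zero even though its
  allele frequency is 0.5) are always excluded: r² against them is
  undefined.
- Tie-break for equal r² at the second-highest slot: prefer the anchor
  agreeing with the top anchor's linkage group, then the
  lexicographically smallest marker id; at the top slot, smallest id.
  This makes placement fully deterministic.
- Candidates are placed independently; a placed candidate never becomes
  an anchor within the same run, so output is invariant to candidate
  order and to the composition of the candidate set.
- The decay distance is operationalized as the smoothed curve's first
  grid point at or below the threshold (grid of 256 points spanning the
  observed distance range). An alternative reading — the mean distance of
  pairs whose r² sits near the threshold — was considered and rejected as
  less stable under the skewed r² distribution. When the curve never
  reaches the threshold the distance is flagged undefined rather than
  extrapolated. The percentile of the threshold is computed over all
  intra-chromosomal pairs pooled (not per chromosome).
- Fold partitions are true partitions with sizes differing by at most
  one. For a 4502-marker map and 20 folds this gives 225–226 markers per
  fold; workflows that want fixed-size test sets can mask explicit id
  sets via `mask_map(ids = ...)`.
- Cross-validation metrics: accuracy is computed over placed markers
  only; the distance and correlation metrics are computed over
  placed-and-correct markers, because a cM difference between positions
  on different chromosomes is meaningless. Wrong-chromosome placements
  therefore lower accuracy but do not contaminate the precision
  statistics. A fold with no placements reports efficiency 0 and
  accuracy `NA` (flagged, not zero). Aggregates are unweighted fold
  means, fold sizes being near-equal.
- Serialized map positions carry six decimals, enough for bit-stable
  read/write round-trips of any position that is itself a six-decimal
  value.

## Open design decisions, resolved

- **Anchor set for the weighted mean**: all supra-threshold anchors on
  the assigned group, not just the top two. A multi-point average is less
  sensitive to a single inflated r²; the two-anchor rule is still what
  gates assignment.
- **Strict vs inclusive threshold**: strict `>` in both steps, uniformly;
  boundary candidates are rare in continuous data, but a uniform rule
  keeps the threshold-monotonicity property exact (the placed set at a
  higher threshold is always a subset of the placed set at a lower one).
- **Partition vs repeated subsampling for CV**: a true partition, so each
  mapped marker is scored exactly once per run and fold metrics are
  independent across folds given the partition.

## Problem sizes and limitations

The test suite and the acceptance script run everything on the default
600-marker, 500-sample simulation (plus smaller populations for property
loops); these sizes were chosen so the full suite completes in well under
a minute of compute per scenario while keeping ~40+ masked markers per
evaluation, enough for stable percentages. The quantities the acceptance
script reports (masking efficiency, accuracy, mean absolute placement
error, known-vs-estimated Pearson correlation, threshold response, decay
summary) are recomputed from scratch at run time; the vignette
deliberately quotes none of them.

Known limitations: placement interpolates — a candidate whose true
position lies outside its anchors' span (e.g. at a chromosome end beyond
the last anchor) is pulled inward; accuracy degrades when a linkage
group's anchors are sparse relative to the population's LD decay
distance; and in populations whose LD is structure-driven rather than
linkage-driven the two-anchor agreement rule loses its protective value.
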
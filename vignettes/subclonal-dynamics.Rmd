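---
title: "Inferring subclonal diversity dynamics from paired tumor samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring subclonal diversity dynamics from paired tumor samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subclonedyn)
```

## The question

When a tumor is biopsied at diagnosis, treated (for example with immune
checkpoint inhibition), and later resected, the two samples give two
snapshots of the same clonal population. Comparing the somatic variant
allele frequency (VAF) spectra of the two samples asks: which subclones
were depleted by therapy ("lost"), which were enriched or newly apparent
("gained"), and how diverse did the residual tumor remain?

This package implements that comparison for paired biopsy/resection
somatic calls, together with a seeded clonal-evolution simulator that
provides ground truth for every inferential step.

## Model and assumptions

**One mutation, one subclone.** Every nonlethal somatic mutation during
tumor development founds a new subclone, so each somatic variant is used
as the representative of the subclone that originates in it, and variant
counts are proportional to subclone counts under a shared mutation rate.
This deliberately ignores that several mutations can arise in one cell
division; relative comparisons across patients survive that
simplification, absolute subclone numbers do not.

**Purity on the allele scale.** Without copy-number variation, a somatic
variant's VAF cannot exceed the tumor purity: in a sample with tumor cell
content `rho` and copy-neutral heterozygous variants, the maximal
attainable VAF is `rho / 2`. Throughout this package *purity means that
maximal attainable VAF* (the allele scale). The simulator, the
estimators, and the purity adjustment all use this one convention, so no
factor-of-two conversions appear anywhere. When the estimated maximal VAF
is compared with pathologist estimates, the comparison is therefore
literal; a pathologist's cell-fraction estimate of 0.8 corresponds to an
allele-scale purity near 0.4 under diploidy. We keep the literal
comparison because the reconciliation rule (below) is a consistency
check, not a calibration.

**Purity-adjusted VAF.** `adjust_vaf(f, purity) = min(1, f / purity)`
approximates the cellular prevalence of a variant among tumor cells and
is the quantity thresholded everywhere.

## Purity estimation

For the resection sample, the upper edge of the somatic VAF distribution
estimates purity. Isolated read-sampling and copy-number outliers can
exceed the edge, so `robust_max_vaf()` operationalizes "the highest VAF,
or a threshold beyond which higher VAFs are explicable by noise" as a
high quantile (default 0.98, standard linear-interpolation convention)
of the somatic VAF distribution, restricted to variants with somatic
posterior at least 0.95 and depth at least 30 (defaults, both
configurable). A quantile with a depth floor is deterministic and robust
to single inflated outliers, which visual inspection of plotted
distributions — the manual alternative — handles implicitly.

The estimate `v` is reported as the purity only when it is consistent
with the two pathologist estimates, `p1 <= v <= p2`, and the
pathologists agree to a sufficient degree, `p2 - p1 <= 0.2`
(`resolve_resection_purity()`). Otherwise the purity is *unknown* and
the patient is excluded from subclone dynamics — silently wrong purity
would corrupt every downstream threshold.

For the biopsy there are no pathologist priors; the biopsy VAF
distribution is scaled to match the resection distribution. With at
least 10 variants observed in both samples, the scaling factor `s` is
the median of per-variant resection/biopsy VAF ratios (exact under
shared clonal structure). With fewer shared variants, `s` minimizes the
1-Wasserstein distance between the scaled biopsy VAFs and the resection
VAFs over a grid `s in [0.1, 10]` (step 0.05). The biopsy purity is then
`purity_resection / s`, clipped to `(0, 1]`. The Wasserstein distance is
computed as the mean absolute difference of empirical quantile functions
on a fixed 512-point grid; its resolution error is far below the grid
step of the `s` search. The median-ratio path is exactly equivariant
under rescaling of the biopsy VAFs; the grid path is equivariant up to
the grid step.

## Counting lost and gained subclones

A variant *qualifies* as a countable subclone when all of the following
hold:

1. somatic posterior `>= 0.95`;
2. purity-adjusted VAF `>= 0.1` in at least one sample;
3. from each sample where (2) holds, the variant would be expected to be
   represented by at least 2 reads in the *other* sample if it occurred
   there at the same cellular frequency:
   `f_adj * purity_other * depth_other >= 2` (inclusive bound).

Among qualifying variants, *lost* means zero alt reads in the resection
with adjusted biopsy VAF `>= 0.1`; *gained* is the mirror image; the
remainder is *retained*. Three readings of the rules were genuinely
open, and the package resolves them as follows:

- **"Adjusted VAF >= 0.1" applies to at least one sample.** Requiring it
  in both samples would contradict the lost/gained definitions, which
  demand VAF 0.0 in one sample.
- **"VAF = 0.0" means zero observed alt reads**, not "below threshold".
  A variant with a handful of reads in one sample and adjusted VAF 0.05
  there is retained, not lost — it is still present.
- **Fractions share one denominator**, the total qualifying count across
  both samples, so lost, gained and retained partition the total and
  `fraction_lost + fraction_gained <= 1` by construction. A
  resection-only qualifying count is reported alongside
  (`n_resection`) for users who prefer that denominator for the total
  subclone number of the residual tumor.

Patients in which no variant qualifies in either sample are excluded
(reason `empty_qualifying_set`), as are patients with unknown purity.
Because a pretreatment biopsy need not represent the whole tumor, a
"gain" is indistinguishable from spatial enrichment of a variant the
biopsy missed; the simulator models exactly this ambiguity
(`spatial_miss_prob`), and no attempt is made to resolve it at
inference time.

## Mutational spectrum curves

`spectrum_curve()` counts somatic variants with VAF at least `t` for each
threshold `t` on a grid, per substitution class, divided by the targeted
footprint in megabases. Single-base substitutions are collapsed to the
pyrimidine-reference convention (six classes `C>A` … `T>G`); equal-length
multi-base substitutions are `MNV`; everything else — including indels,
for which no class exists in this scheme — is `complex`. The footprint
default of 1.94 Mb is a typical coding footprint of a 500-gene panel;
it is a pure scaling constant, recorded in every output, and should be
set to the actual design footprint of the assay.

## Prioritizing candidate resistance variants

`filter_reportable()` applies the conjunction: nonsynonymous
consequence; pathogenicity (REVEL-style) score above 0.5 *when a score
is available* (missense-only scores make "if available" semantics
necessary — absence passes); population allele frequency below 0.2
(absent treated as 0); not labelled benign/likely benign; and membership
of a user-supplied cancer-gene list. A stricter reporting policy raises
the score threshold to 0.7. Every rejection is tallied by the first
failing clause.

Two transparent evidence models replace opaque caller probabilities:

- `prob_absent_in_normal()`: the posterior weight, under equal priors,
  of alt reads in the matched normal arising from sequencing noise
  (`Binomial(depth, 0.001)`) versus germline heterozygosity
  (`Binomial(depth, 0.5)`), computed in log space. Depth 0 returns the
  uninformative 0.5.
- `prob_vaf_changed()`: independent Jeffreys-prior (`Beta(0.5, 0.5)`)
  posteriors on each sample's VAF, divided by the respective purity, and
  the Monte-Carlo probability (default 20,000 seeded draws) that the two
  cellular frequencies differ by more than `delta = 0.05`. The statistic
  is symmetric in the two samples and invariant under joint rescaling of
  both purities with `delta` rescaled accordingly. Note that at shallow
  depth the posteriors are wide, so even identical observed counts give
  a probability well above zero — `delta` is a cellular-frequency
  difference, not a significance level, and no reporting threshold is
  baked in; raw probabilities are reported.

## The simulator

`simulate_case()` generates what the inference assumes:

- a clone tree by random parent attachment (or `star` / `chain`
  topologies for designed experiments);
- tree-consistent cellular prevalences by recursive stick-breaking: each
  clone's mass is partitioned among its children and itself with a
  symmetric Dirichlet (concentration 1 by default), so a child's
  prevalence never exceeds its parent's — the simplest scheme honoring
  the one-mutation-one-subclone proxy. A deterministic geometric profile
  (`prevalence_decay`) is available for experiments that need every
  clone above a detection threshold;
- therapy as per-clone survival multipliers of exclusive masses, with a
  killed clone taking its whole subtree (descendant cells carry the
  ancestor's mutations), followed by renormalization;
- spatial biopsy sampling: each non-truncal subtree is absent from the
  biopsy with probability `spatial_miss_prob`;
- reads: per-variant depth `~ Poisson(mean_depth)` and alt count
  `~ Binomial(depth, prevalence x purity)` — so expected somatic VAF
  never exceeds purity, the bound the purity estimator relies on;
- germline heterozygous contaminants at expected VAF 0.5 with somatic
  posterior below 0.95, exercising the posterior filter;
- pathologist priors `p1, p2` as the true resection purity minus/plus
  independent `Uniform(0, p_error)` noise.

Defaults describe one realistic deep-coverage paired design, chosen once:
8 clones, Poisson(15) mutations per clone, 300x mean depth in both
samples, allele-scale purity 0.4, spatial-miss probability 0.05, a
quarter of non-truncal clones killed by therapy, pathologist noise
width 0.1, and 10 germline contaminants. No copy-number events are
generated by default, matching the no-CNV assumption of the purity
bound; CNV-like outliers can be emulated by appending high-VAF records
when stress-testing `robust_max_vaf()`.

Determinism: `simulate_case()` is bit-reproducible given its seed;
`simulate_cohort()` derives one sub-seed per patient from a master seed,
so cohorts are reproducible and patients are independent streams.

## What the tests do and do not show

The test and acceptance studies run at deliberately chosen problem
sizes: purity recovery uses 200 replicates of ~300 variants at 600x
(deep FFPE panel-like coverage, clonal cluster present, true purity in
[0.2, 0.5]); selection recovery uses a 10-clone chain with geometric
prevalences (ratio 0.85) so that every clone sits well above the 0.1
adjusted-VAF threshold, killing the subtree that carries 20/50/80% of
qualifying mutations over 100 replicates at 300x; the null control runs
200 replicates against an independent brute-force read-noise oracle.
Classification tests inject the simulator's true purities (the
`simulated_truth` method of `purity_estimate()`), separating the
counting rules from purity-estimation error, which has its own recovery
study.

Passing these studies shows the implementation is faithful to its own
generative model. It does not show robustness to what the simulator
omits: copy-number change under therapy, FFPE damage artifacts,
sequencing batch effects between biopsy and resection, mutation-rate
heterogeneity across clones, or subclonal structure violating the
infinite-sites-like one-variant-one-clone proxy. On real data the purity
quantile, depth floor and `region_mb` should be revisited against the
assay design.

## Known limitations

- The purity estimator is upward-biased by roughly one to two VAF
  standard errors at the clonal cluster (it reports an upper-edge
  quantile); at 600x and ~300 variants this is ~0.02-0.03 purity units,
  within the ±0.05 recovery target, but it grows at shallow depth.
- The detectability filter uses expected reads, not a sampling-aware
  probability of detection; variants near the boundary are handled
  deterministically (inclusive at exactly 2 expected reads).
- Gains cannot be separated from spatially missed biopsy variants, by
  design.
- The VAF-change probability treats the two samples' VAFs as
  independent Beta posteriors; it does not model shared copy-number or
  mapping artifacts.
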
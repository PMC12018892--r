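---
title: "Kinship and breeding-habit reconstruction from hatchling SNP data"
author: "nestkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship and breeding-habit reconstruction from hatchling SNP data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sea turtle nesting populations are usually censused indirectly: beach
surveys count nests, and maternally inherited mtDNA haplotypes group nests
into matrilines. Neither distinguishes two females that share a haplotype,
and neither says anything about males. When dead hatchlings can be sampled
from nests, genome-wide SNP genotypes make a direct reconstruction
possible: hatchlings from one nest share a mother; full siblings share both
parents; half siblings share exactly one. From kinship among hatchlings
alone one can therefore count mothers, fathers and mating events, detect
multiple paternity and sperm storage, and — with nest dates and coordinates
— describe remigration intervals, internesting intervals and nest-site
fidelity.

`nestkin` implements this analysis end to end, together with a synthetic
pedigree generator that provides ground truth for every stage.

## The normalized-IBS statistic

For two samples, per biallelic site the identity-by-state (IBS) score is 1
when the genotypes are identical (including het vs het), 0.5 when they
share one allele (het vs either homozygote), and 0 for opposite
homozygotes. The raw pairwise IBS is the mean score over the sites called
in both samples (pairwise-complete; the per-pair overlap is reported so
missingness can be audited).

Raw IBS between unrelated members of one gene pool is far from zero — it
is the level of allele sharing expected by chance. To remove it, values
are rescaled by a dataset-specific baseline:

```
normalized IBS = (IBS − av.min) / (1 − av.min)
```

where `av.min` is the average raw IBS between all members of the two least
related groups (families or nests) in the dataset. Identity maps to 1, the
unrelated baseline to 0; values below the baseline come out negative and
are deliberately not clipped — their spread around zero is informative.
Because the baseline is recomputed per dataset, the same pair can get
slightly different normalized values in different dataset contexts;
`av_min` can be frozen explicitly (`normalized_ibs(gm, av_min = ...)`) when
comparisons across contexts are needed.

### Choosing the baseline groups

`baseline_av_min()` scans every unordered pair of groups and takes the pair
with the smallest cross-group mean (ties broken lexicographically and
logged). With many single-hatchling nests this minimum is dominated by
pair-level sampling noise: a single cross-pair mean at 2,000 SNPs has a
standard error of roughly 0.007 on the raw scale, and minimizing over
thousands of such means selects values several standard errors below the
true unrelated level, which inflates every normalized value by up to ~0.1.
`reconstruct_parentage()` therefore restricts the baseline search to nests
with at least `baseline_min_group = 2` sampled hatchlings (falling back to
all nests when fewer than two qualify). In datasets with no unrelated
groups at all — e.g. two nests known to share a parent — the baseline must
be supplied explicitly.

### Analytic expectations

Under Hardy–Weinberg proportions, with `p` the site allele frequency and
`q = 1 − p`, the per-site conditional expectations are

* `E[IBS | 2 alleles IBD] = 1`
* `E[IBS | 1 allele IBD] = 1 − pq`
* `E[IBS | 0 alleles IBD] = 0.5 (1 + (1 − 2pq)^2)`

Taking the baseline as the unrelated expectation, a relationship with
Cotterman coefficients `(k0, k1, k2)` has expected normalized IBS
`k2 + k1 · n̄₁` with

```
n̄₁ = Σ pq (1 − 2pq) / Σ 2pq (1 − pq)
```

summed over sites. `expected_normalized_ibs()` implements the closed form;
the test suite verifies the three conditional expectations against an
exhaustive enumeration of all nine genotype-pair combinations at every
`p ∈ {0.05, …, 0.5}` to 1e-12, and the full closed form against an
enumeration-only oracle. At a single site with `p = 0.5`, parent–offspring
gives 1/3 and full siblings 0.25 + 0.5/3 ≈ 0.4167. The exact band means
observed in real data depend on the realized allele-frequency spectrum and
on founder relatedness, so they are not universal constants; the
reproducible surface is the unrelated mean of 0 and the ordering
full-sib > half-sib > distant kin > unrelated.

### Classification bands

`kinship_bands()` defaults to full-sib ≥ 0.38, half-sib [0.15, 0.38),
distant kin [0.05, 0.15), unrelated < 0.05. These sit between the band
means observed in a calibration dataset of known families (full siblings
near 0.45–0.50, half siblings near 0.21–0.28, unrelated near 0.00). There
is no universal threshold — band positions drift with parental relatedness
— so all cut points are configuration, and values within ±0.03 of a
boundary are flagged ambiguous.

## Significance by permutation

Pairwise kinship values are not independent, so within-group means are
tested by permutation (`permutation_ci()`): sample labels are randomly
reassigned to groups of the same sizes, the pooled within-group mean is
recomputed for each of `n_perm = 1000` permutations, and the empirical
2.5/97.5 percentiles form the 95% interval. The suite checks calibration:
under a null of randomly assigned groups the observed mean falls inside
the interval in 95% ± 2% of 500 replicates.

## Reconstruction rules

`cluster_full_sibs()` draws an edge between every pair at or above the
full-sib threshold and takes connected components as candidate full-sib
groups. A component containing a within-pair below the threshold is
refined by average-linkage clustering cut at the threshold: a group is
split only where the cross-cluster *mean* falls below the full-sib bound.
The alternative — splitting on any single below-threshold pair — would let
one noisy pair (a few per dataset are expected at 2,000 SNPs) break up a
cohesive family; group-mean evidence outweighs single-pair noise, and the
offending pairs are flagged in `flagged_pairs` instead. Half-sib links are
recorded between groups whose cross-group mean lies in the half-sib band.

`assign_parents()` then applies, in order:

* **R1** — all hatchlings in one nest share the mother (one female per
  nest; violations surface as integrity errors, never silent splits).
* **R2** — a full-sib group spanning nests implies the same mother *and*
  father for those nests (the same female returning; sperm storage).
  Full siblings must share the matriline, so a group spanning different
  barcodes is an integrity error.
* **R3** — a half-sib link within a nest: same mother, different fathers
  (multiple paternity).
* **R4** — a half-sib link across nests with identical barcodes and dates
  compatible with one female (same season: nests within
  `same_season_max_days = 30` days, i.e. internesting range; different
  seasons: any gap, remigration) is read maternally — one female with
  multiple mates — because a nesting survey counts such cases as one
  female. The paternal alternative cannot be excluded, so the link is
  flagged in the audit trail. If the dates rule the maternal reading out,
  the link is read as a shared father, also flagged. Missing dates leave
  the maternal default in place, flagged.
* **R5** — a half-sib link across nests with *different* barcodes can only
  be paternal: the two full-sib groups share a father across matrilines.

Mothers are the equivalence classes of nests under R2/R4 merges; fathers
are the equivalence classes of full-sib groups under R5 merges (fathers
are never observed, so their identifiers `M01…` are synthetic labels);
mating events are the distinct (mother, father) pairs. The enumeration is
minimal: no two mother or father classes can be merged without either
claiming sibship the kinship matrix places below the half-sib band or
collapsing two fathers of one mother (the suite checks this exhaustively
on small instances).

## The synthetic-data generator

The generator is first-class, tested code; every downstream stage is
validated against its ground truth.

`sim_config()` draws per-site minor allele frequencies from U(0.05, 0.5)
by default — the post-filter spectrum of a reduced-representation SNP
panel — and founders as mutually unrelated Hardy–Weinberg draws.
Hatchlings are exact Mendelian transmissions from their assigned parents;
missingness (default 5%) and a Gaussian read-depth model (mean 40×, SD 17,
matching a typical ddRAD coverage profile) are applied after transmission.

The default `"nesting"` scenario fixes the population structure at the
scale of a two-decade Mediterranean hatchling survey: 35 mothers in five
matrilines (19/3/5/7 across the common barcodes 6-8-8-4, 6-8-9-4, 6-9-6-4,
8-7-7-4, plus one female with a private barcode), 84 nests, 60 mating
events, 59 fathers with exactly one father shared across two matrilines,
18 nests with more than five sampled hatchlings of which a third are
multi-paternal (10 multi-paternal nests overall), internesting intervals
drawn from 8–23 days, remigration intervals of 3–4 years, philopatric nest
placement (Gaussian, 2 km SD) with rare (3%) 60–90 km displacements along
the coast. Counts are allocated deterministically; seeded randomness
enters through genotypes, nest sizes, years, dates and coordinates.
Multi-paternity seasons are capped at two clutches so that every
same-season nest pair of one female stays within a single internesting
interval. Clutches per season default to 1–4: surveys report three to five
clutches per female per season, but only a fraction are sampled, so the
*sampled* clutch count is lower.

A `"random"` scenario drives structure from rates instead (polyandry
probability per clutch, clutch and clutch-size ranges) for distributional
checks, and a `"plan"` scenario takes an explicit nest plan —
`breeding_stock_config()` uses it to build the two-family calibration
scenario (11 full siblings; 10 hatchlings split 5 + 5 between two
fathers).

What the generator deliberately does not emulate: founder relatedness or
historical inbreeding (founders are exactly unrelated, which keeps the
analytic oracles exact), linkage between sites, mtDNA mutation between
generations, genotyping error beyond missingness, or sequence reads.
Passing recovery tests therefore demonstrate correctness of the method
under its own assumptions, not robustness to background relatedness — on
real data the bands must be re-calibrated from known siblings, exactly as
a nesting survey would use its breeding-stock families.

## Numerical choices

* Depth bounds are inclusive ([10, 120]) and are applied first per
  genotype (masking), then per site mean, then presence/missingness, then
  minor allele frequency on the remaining calls — the order matters and is
  fixed; filtering is idempotent.
* The locus-presence rule (≥ 60% of individuals in at least one
  population) reduces to a plain 60% presence rule with a single
  population.
* MAF is the minor allele's frequency regardless of ref/alt orientation;
  multi-allelic and non-SNP records are dropped (with a logged count), not
  split.
* Pairs with fewer than `min_overlap = 100` jointly called sites raise an
  error (or are masked `NA` in matrix mode, with a warning).
* Exact peak-height ties in mtSTR heteroplasmy calling are ambiguity
  errors, never broken silently; the heteroplasmy noise floor defaults to
  0.2× the major peak. AT-repeat loci are found as the four maximal
  AT-dimer runs of ≥ 3 repeats in sequence order on the forward strand —
  with real amplicons, users should verify locus boundaries against their
  reference alignment.
* Great-circle distances use the haversine on a 6371 km sphere; at ≤ 90 km
  the spherical approximation to WGS84 is negligible. A season is a
  calendar year; remigration gaps use year arithmetic.
* Baseline ties are broken lexicographically and logged; `av.min ≥ 1` is a
  degenerate-baseline error.

## Problem sizes

The default SNP panel size is 12,795 sites, the size of a typical
breeding-stock dataset; the simulation-based tests and the acceptance
script run at 500–2,000 sites, which keeps full-sib/half-sib band
separation at several pair-level standard errors while completing the
whole validation suite in about a minute. Band-mean checks use a
conservative standard error (effective n = distinct individuals rather
than pairs, plus a baseline-uncertainty term) because pairwise values
share parents and baseline.

## Limitations

* Fathers are inferred equivalence classes; two fathers that never
  co-occur in a detectable half-sib configuration cannot be
  distinguished from one father mated twice if the kinship signal is
  ambiguous — such cases are flagged rather than guessed.
* Same-barcode cross-nest half siblings are intrinsically ambiguous
  (maternal vs paternal); the maternal default matches survey convention
  but the audit trail must be consulted before citing father counts.
* The minimum-female census is a lower bound: unsampled nests and
  haplotypes add unseen females.
* Likelihood-based pedigree inference, genotype-error modelling and
  fractional paternity are out of scope.
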
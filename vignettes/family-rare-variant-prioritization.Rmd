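---
title: "Methods: family-based rare-variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based rare-variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(famrvar)
```

# The problem

Multiplex families — pedigrees with several affected relatives —
concentrate rare risk alleles that case/control designs are underpowered
to see. `famrvar` implements a two-pronged prioritization for such
cohorts: (i) rare (< 5 %) damaging variants shared across multiple
families under suggestive linkage peaks, and (ii) very rare (< 0.5 %)
damaging variants shared by most affected members of at least one large
family, backed by segregation checks against unaffected relatives,
gene-dropping enrichment tests, case/control replication and a gene-level
burden test. This vignette records the model choices, defaults, and the
numerical conventions the implementation commits to.

# Quality control

*Genotype level.* A call fails on GQ < 30, on alternate depth < 3 for
carriers, or — for heterozygotes — when a continuity-corrected χ² test of
(ref, alt) depths against 1:1 gives p < 0.001. The allele-balance test is
checked before the depth floor, so a grossly skewed het (e.g. 20:1) is
reported as an allele-balance failure rather than a depth failure; the
masked result is the same either way. Calls with absent quality fields
are "unevaluable" and pass by default (`missing_quality = "fail"`
reverses this). Failing genotypes are set missing before variant-level
QC, so they depress call rate rather than distort HWE.

*Variant level.* Call rate ≥ 0.75, HWE χ² (1 df, against expectations at
the sample allele frequency; monomorphic sites pass with p = 1) with
p ≥ 5×10⁻⁸, and VQSR truth tranche ≤ 99.5 % (SNPs) / 99.0 % (indels).
All failing reasons are reported, not just the first.

*Kinship.* Expected kinship is computed by the standard pedigree
recursion (founders unrelated and non-inbred). Coefficient bins follow
the usual cut points with lower-inclusive boundaries going downward, so
φ = 0.354 is first-degree, not duplicate: the printed ranges touch, and a
deterministic partition requires choosing a side.

*Ancestry.* A Gaussian is fitted to the first five PCs after iterated
outlier trimming: points with Mahalanobis d² above the χ²₅ quantile at
1−10⁻³ are dropped and the fit repeated to convergence. The published
procedure says only that multivariate outliers were removed; the iterated
trim is this package's concrete choice and the tail probability is
config-exposed. Membership uses the χ² quantile of the requested coverage
(0.90 by default), and proximal controls are ranked by Mahalanobis
distance with id-ordered tie-breaks. Sex thresholds on X homozygosity
(female ≤ 0.8, male ≥ 0.9) are defaults, not published values.

# Damaging variants and allele frequencies

A variant is damaging if it is frameshift, start-loss, stop-gain or a
splice acceptor/donor, or a missense with a damaging CAROL call *and*
CADD ≥ 20. Missense with a missing CAROL or CADD is conservatively not
damaging.

Control AF is the maximum over the available AJ-exome, NFE and
proximal-AJ panels; a missing panel is absent, never zero, because a
silent zero would pass the rarity filter unnoticed. A variant absent from
*all* panels gets AF 0 with an `af_unknown` flag and is excluded from
AF-thresholded filters. In the gene-dropping context only, a missing
AJ-exome AF is substituted by the AJ whole-genome AF before the maximum.
Rarity tiers are strict as printed (< 0.005, < 0.05, > 0.05); the
undefined boundary points 0.005 and 0.05 are assigned to `rare`. The
deciding panel for minor-allele orientation (proximal-AJ, then AJ, then
NFE) is likewise unspecified in print and is this package's convention;
an AF of exactly 0.5 does not flip.

# Linkage support

LOD curves and per-family LOD scores are consumed as input — multipoint
NPL machinery is deliberately out of scope; the synthetic module emits
toy tables with the right qualitative structure. The package implements
everything around it: 0.3 cM windows anchored at each chromosome's first
mapped SNP (fixed grid, chosen over sliding windows for determinism),
max-heterozygosity SNP retention with lowest-MAF then smallest-position
tie-breaks, PLINK-style greedy LD pruning (within a violating pair the
lower-MAF SNP is removed), linear genetic-map interpolation with flat
ends, maximal runs with LOD ≥ 1.5 as loci, and the contributing-family
rule: mean per-family LOD strictly > 0 over the locus extent (the locus
itself, not a wider window — the published text does not say which; the
locus is the reproducible reading). "Seen in at least two affected family
members" counts sequenced affecteds with dosage ≥ 1.

# Family-based prioritization and segregation

An lfam for phenotype P has ≥ 4 sequenced P-affected members; CD counts
toward the composite IBD phenotype, and IBD-U individuals count toward
IBD but (by default) not CD — the published analysis does not state the
CD-specific handling, so it is a config switch. Sharing requires ≥ 75 %
of evaluable affecteds (missing genotypes leave the denominator, flagged)
and the boundary is inclusive: 6/8 passes.

Segregation counts sequenced unaffected siblings or offspring of
affecteds, excluding parents of any affected as potential obligate
carriers, and requires carriers ≤ 1/3 of them. The methods text says
"less than one-third" but the results and table legend say "≤ 1/3" and
printed rows sit exactly at 3/9 and 1/3; the inclusive rule is adopted.

The conditional probability of the unaffected genotypes given the
affected ones assumes the variant entered the pedigree as a single copy
in exactly one heterozygous founder, with a uniform prior over founders
consistent with the observed affected genotypes (the prior is
config-relevant only when several founders are consistent; the published
text is silent, and uniformity is the symmetric choice). The probability
is computed by exhaustive enumeration over founder assignments and
Mendelian transmission events — exact, and feasible because eligible
families have at most a dozen meioses. A family "has power" at level α
only when the most extreme outcome (no unaffected carries the variant)
has conditional probability below α; with ≤ 5 eligible unaffecteds and
shared ancestry this rarely drops below 2⁻⁵ ≈ 0.03, which is why
realistic families almost never reach α = 0.05.

# Gene dropping

Founders draw genotypes from Binomial(2, control AF); each child receives
one allele per parent with heterozygous parents transmitting either
allele with probability ½ (vectorized across replicates; equivalent to
the depth-first traversal description, one start per founder couple). The
cohort AF per replicate is measured over the sequenced phenotype cases
outside the index family — the same individuals the observed AF uses, so
the comparison is like-for-like; whether the published denominator
included unsequenced affecteds is not stated, and sequenced-only is the
defensible default. The empirical p uses (k+1)/(n+1) with inclusive ties,
so 100,000 all-miss replicates report p < 10⁻⁵, never 0. Power for a
hypothesized cohort AF treats the count of sub-threshold simulated AFs as
Binomial(n, q) and applies the Normal approximation, with the degenerate
q ∈ {0, 1} cases returned analytically.

# Replication and correction

Fisher's exact test is two-sided by the standard summation convention
(all tables with probability ≤ the observed one); this matters because
mid-p variants visibly shift power curves. The implementation sums
hypergeometric densities directly; `stats::fisher.test` serves as the
independent oracle in the test suite. Odds ratios are sample
cross-products, with a 0.5 continuity correction (flagged) only when a
cell is zero.

Power simulation derives the case AF from the control AF and OR on the
odds scale, draws Binomial allele counts for both arms and counts
replicates with p < α. "Sampled log odds ratios" in the published
description is ambiguous; the default is a fixed OR per power point (the
reproducible reading) with an optional `log_or_sd` to draw log-OR ~
Normal per replicate. The smallest OR reaching 80 % power is found by
bisection with common random numbers (the same substream per evaluation),
reported to one decimal.

Effective dataset counts: phenotype datasets whose p-values over shared
variants correlate (Spearman, pair p < 0.05 — the published analysis
reports pair p-values but no explicit threshold) are merged into
connected components; the Bonferroni budget is
`linkage variants × effective case/control datasets + family variants ×
(effective case/control + effective gene-drop datasets)`, and
α = 0.05 / total. With the published counts (11, 413, 2, 1) this is
0.05/1261 = 3.97×10⁻⁵.

The CMC burden test collapses damaging variants into two carrier
indicators (panel AF < 0.01, and 0.01–0.05, AJ-first with NFE then
proximal-AJ fallback) and compares logistic models with and without the
indicators, both containing five PC covariates; the LLR is χ² with one
degree of freedom per non-empty bin. Complete separation triggers a
Firth-penalized fit (Jeffreys prior), flagged in the result.

# The synthetic-data generator

The generator emulates the *structure* the analysis assumes: multiplex
families ascertained for ≥ 2 sequenced affecteds (designated lfams for
≥ 4, via a liability boost plus rejection — rejection is legitimate here
because ascertainment *is* conditioning), sporadic cases and controls as
singletons, founder AFs log-uniform over 0.0005–0.05, affection from a
logistic liability model (baseline prevalence 1 %, shared familial term
sd 1.5, subtype split CD 0.55 / UC 0.35 / IBD-U 0.10 reflecting the
CD-heavy composition of such cohorts), and GQ/AD fields from Poisson
depth (mean 40) with dosage-conditional Binomial alt reads. Replication
cohorts default to the published sizes (IBD 1867/3616, CD 1286/3035,
UC 544/3035; only the control range 3035–3616 is printed, so per-cohort
values are config).

Planted variants are written directly as heterozygous carriers into a
fraction (default 0.8) of each target lfam's sequenced affecteds rather
than coupled through an infinite odds ratio in the liability model: the
direct construction makes the intended sharing pattern certain and keeps
the planted truth independent of the phenotype model. Consequently a
green end-to-end test establishes that the pipeline *recovers a planted
signal of the stated shape* — it does not establish calibration of the
liability model itself, which is exercised separately (founder-AF
recovery, HWE among founders, null phenotype independence).

What the generator does *not* emulate: realistic LD beyond what the
pruning tests need, sequence-level error processes, locus-specific
genetic maps (the toy map is 1 cM/Mb), and real NPL statistics (per-family
LOD means are drawn from separated Gaussians around the known
carrier-sharing truth). Results that depend on those features — e.g. the
published cohort's exact variant counts (413, 51/30/11) — are therefore
out of reach by design, and the acceptance tests instead pin the
self-contained published numbers (the 3.97×10⁻⁵ threshold, the
3-significant-variant count from printed p-values, the nine printed
segregation proportions, the ~1.7 required OR) plus distributional
properties.

# Numerical conventions and degenerate inputs

- Pedigrees are validated as acyclic with both-or-neither parents;
  referenced-but-absent parents are synthesized as unknown founders
  (recruited pedigrees routinely have unsequenced connectors). A single
  listed parent is an error naming the individual.
- Topological order sorts each generation layer by id, making every
  stochastic traversal invariant to input row order.
- Monomorphic SNPs have undefined r² and are dropped from LD pruning
  with a flag; monomorphic HWE is p = 1.
- Empirical p-values are never 0 ((k+1)/(n+1)); ties count as extreme.
- The OR bisection brackets upward from 1 by doubling and reports
  `unreachable` above a cap instead of extrapolating.
- Seeds: every simulation entry point takes an explicit seed; internal
  substreams derive via a fixed LCG-style hash kept below 2³¹.

# Known limitations

- Gene dropping is autosomal only; X-linked transmission is out of scope.
- The conditional segregation probability assumes a single carrier
  founder and heterozygous carriers — appropriate for very rare variants,
  wrong for common ones (which the AF filter removes upstream).
- The burden test inherits logistic-regression small-count behaviour;
  published use was supplementary for the same reason (observed
  inflation).
- `read_vcf` targets well-formed VCF v4.2 with GT/GQ/AD; exotic FORMAT
  layouts fall back to flagged, unevaluable quality fields.
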
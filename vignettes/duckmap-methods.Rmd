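---
title: "Mapping a two-locus epistatic plumage trait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a two-locus epistatic plumage trait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duckmap)
```

## The genetic model

White plumage in the Liancheng-type duck segregates as a classic two-locus
system in crosses with the Pekin-type duck. The beak locus (`Bb`) gates
melanin synthesis: `B` is dominant and enabling, and `bb` birds are white
feathered with a yellow beak regardless of everything else (recessive
epistasis). On a `B_` background, the feather locus (`Rr`) shows incomplete
dominance over melanin deposition in the feather: `RR` birds are black
feathered, `Rr` grey, `rr` white, all with black beaks. The cross is
`BBrr x bbRR`: both parent lines are white feathered for opposite reasons,
every F1 is `BbRr` and grey, and the F2 segregates

| class | genotype | probability |
|-------|----------|-------------|
| BF (black feather, black beak)  | `B_RR`  | 3/16 |
| GF (grey feather, black beak)   | `B_Rr`  | 6/16 |
| WB (white feather, black beak)  | `B_rr`  | 3/16 |
| WY (white feather, yellow beak) | `bb__`  | 4/16 |

`segregation_model()` encodes the genotype-to-phenotype map,
`enumerate_f2_ratio()` derives these probabilities exactly from the 16
equiprobable dihybrid gamete combinations, and `chisq_gof()` tests observed
class counts against them.

```{r}
m <- segregation_model()
enumerate_f2_ratio(m)
chisq_gof(c(BF = 235, GF = 452, WB = 234, WY = 360), enumerate_f2_ratio(m))
```

Three numerical choices deserve a note.

* **Expected counts.** The chi-squared statistic always uses the real-valued
  expectations `n * p_k`. The integer presentation from `expected_counts()`
  rounds half-away-from-zero and then repairs the class with the largest
  remainder so the integers sum to `n`; at `n = 1281` this yields
  240/481/240/320.
* **Degrees of freedom** are `k - 1` with no estimated parameter: the ratio
  is fixed a priori by the model, not fitted.
* **WY is one class.** Under `bb` epistasis the feather genotype is
  unobservable, so `bb RR`, `bb Rr` and `bb rr` are pooled.

Published segregation tables for this cross report a smaller chi-squared
value (3.322) than Pearson's statistic computed from the same observed
counts and the same 3:6:3:4 expectation (about 6.88, `p` about 0.076 at 3
df). The package reports the standard Pearson value and makes no attempt to
reverse-engineer the discrepancy.

## The synthetic intercross

Because the analysis layer should be testable without any sequencing data,
`breed_cross()` simulates the whole study design: two founder breeds, an F1,
and an F2 with recombination, planted causal loci, genome-wide neutral SNPs
and optional read-depth data.

What the generator emulates, and the defaults of `sim_study_config()`:

* **Genome**: five 50-Mb autosomes at 1 cM/Mb, about 1,040 SNPs per
  chromosome (roughly 5,200 genome wide). This scales the real 1.29-Gb,
  multi-million-SNP problem down to desk size while keeping tens of
  expected crossovers per meiosis genome wide and a realistic marker
  density per map unit.
* **Causal loci**: the beak locus mid-chromosome 2 and the feather locus at
  position 5,300,000 of chromosome 5 (an echo of the real feather-locus
  region near 5.3 Mb of a microchromosome), each fixed for opposite alleles
  in the two founder breeds.
* **Founder allele frequencies**: neutral SNPs are drawn per breed from
  Beta(0.8, 0.8) truncated to [0.05, 0.95] — a U-shaped spectrum typical of
  diverged breeds — and a fraction (10% by default) are
  ancestry-informative markers at 0.02 vs 0.98, so that delta-AF > 0.8
  screens have realistic numbers of hits.
* **Cohort sizes**: 30 founders per breed, 60 F1, 320 F2 — scaled down from
  the real resequencing panel (117 + 59 founders, about 150 intercross
  birds genotyped, 1,281 F2 phenotyped) so a full scan runs in seconds.
* **Recombination**: Haldane's model — crossover counts Poisson in the map
  length, positions uniform, no interference. No published linkage map
  exists for this cross; this is the simplest defensible choice, and the
  breakpoint logic downstream never relies on interference.
* **Missingness**: i.i.d. per genotype at 2% by default. Real missingness
  is clustered by sample and by region; only a per-SNP cap matters to the
  filters, so the i.i.d. model is adequate here.
* **Sex**: Bernoulli(0.5), carried only as a covariate — the trait is
  autosomal and shows no sex pattern, but the fixed effect belongs in the
  model regardless.
* **Phenotype**: assigned deterministically from the true causal diplotypes
  through the segregation model. There is no phenotyping error; tests that
  pass under this generator therefore validate the statistical machinery,
  not robustness to misclassified birds.

Every simulated cohort carries its ground truth (causal diplotypes,
crossover positions, the founder-haplotype origin of every transmitted
allele), which is what the planted-truth tests check against. A fixed seed
reproduces a cohort exactly.

What the generator does **not** emulate: linkage disequilibrium within
founder breeds (founder haplotypes are drawn site-independently),
genotyping error, clustered missingness, allele-frequency correlation along
the chromosome, and sequence-level artefacts. Results on real data will be
noisier than the noise-free recovery rates reported by the test suite.

## Variant filtering

`apply_filters()` applies the resequencing-style SNP filters in a fixed
order — biallelic only, then per-variant missing fraction, then MAF — with
strict inequalities exactly as conventionally printed: MAF > 0.05 keeps a
variant, missing fraction < 0.7 keeps a variant. Boundary cases therefore
fail the MAF rule and fail a missing fraction of exactly 0.7. MAF is
computed over all samples in the file. Indels are parsed and kept in the
variant table (the causative screen needs to see and exclude them) but are
excluded from the association scan input by `gwas_inputs()`.

## The mixed-model scan

The association model is `y = Xb + g + e` with `Var(g) = sigma_g2 * G` for
a genomic relationship matrix `G` and `Var(e) = sigma_e2 * I`.

* `grm()` builds `G` with mean imputation and `2p(1-p)` standardization.
* `pca_covariates()` supplies the top-3 kinship PCs (with a deterministic
  sign convention) as stratification covariates; `X` is intercept + sex +
  PCs.
* `fit_null_lmm()` estimates the variance components once, EMMA-style: a
  single eigendecomposition of `G`, then 1-D profiled REML over
  `log10(delta)` in [-5, 5] (`delta = sigma_e2/sigma_g2`), a 100-point grid
  followed by bounded refinement. The grid bounds cover heritabilities from
  essentially 0 to essentially 1; the grid step is far finer than the
  likelihood's curvature at either end.
* `assoc_scan()` fixes those components for every marker (the EMMAX
  approximation) and tests each variant by GLS on rotated, whitened data.

The per-marker test statistic is a t-statistic with the residual variance
re-estimated per marker (`df = n - p - 1`). With an identity kinship this
reduces *exactly* to ordinary linear regression, which is both a useful
invariant and what the widely used EMMAX implementation reports; a Wald
chi-squared(1) version using the null fit's variance is available as
`test = "wald"`. p-values are floored at 1e-300 to keep the `-log10` scale
finite. An identity-kinship fit is degenerate in the variance split (only
the total is identified); the fit reports the ridge edge case rather than
failing.

**Phenotype coding.** The scan needs a numeric phenotype and the source
analysis does not state one. The default is the ordinal melanin dose
`WY = 0, WB = 1, GF = 2, BF = 3`: it is monotone in melanin load and gives
both loci a marginal effect (the beak locus acts dominantly on it, the
feather locus additively within `B_`). A `feather` coding restricted to
black-beaked birds (`WB = 0, GF = 1, BF = 2`) is available for feather-locus
fine scans. Neither is asserted to be the original study's coding.

**Removing the major signal.** `conditional_scan()` implements signal
exclusion as covariate conditioning: the beak-locus genotype joins the
fixed effects and the scan re-runs, which is the standard conditional-GWAS
mechanism. On simulated cohorts this leaves exactly one significant region,
at the feather locus.

The genome-wide threshold is Bonferroni, `-log10(alpha/N)`; at
`alpha = 0.01` and `N = 8,887,194` SNPs it evaluates to 8.95 (2 dp).

## Divergence statistics

`divergence_table()` reports per-SNP delta-AF and FST for a two-population
contrast. The FST estimator is Hudson's (with the standard finite-sample
correction), chosen because it is robust to unequal sample sizes and has no
within-population weighting ambiguity; Weir-Cockerham is available behind
`estimator = "wc"`. Negative per-SNP estimates are kept as computed.
`window_fst()` averages in fixed 10-kb windows tiled from coordinate 1,
half-open, using the ratio-of-averages (sum of numerators over sum of
denominators), which is the recommended way to combine FST across sites;
empty windows are omitted. The window origin is a convention — no offset
was stated for the published windows — and none of the conclusions depend
on it.

The delta-AF > 0.8 and FST >= 0.8 screens are both implemented; which one
feeds fine-mapping is the caller's choice, since published descriptions use
the two interchangeably for the founder contrast.

## Fine-mapping by ancestry painting

Within a candidate region, `informative_snps()` keeps founder-contrast
markers with delta-AF above 0.8. `infer_ancestry()` paints each individual
at those markers with the count of founder-1-major alleles: `HOM_P1`,
`HET`, `HOM_P2`, or `UNKNOWN` for missing. An optional 3-SNP majority
smoother exists for noisy data and is off by default.

`find_breakpoints()` reports every change between consecutive known states
as an *interval* between the two flanking informative SNPs, never a point:
genotype data cannot localize a crossover more finely, and downstream logic
treats the interval as the unit. `UNKNOWN` states are skipped with the last
known state carried forward.

`partition_blocks()` cuts the region at the union of all individuals'
breakpoint intervals (a gap between adjacent informative SNPs is cut if any
breakpoint interval covers it), so `k` distinct cut gaps give `k + 1`
blocks. How a population of individual breakpoints should collapse into
region-level blocks is not specified anywhere; the union rule is the most
conservative choice (it never merges two blocks that any individual
separates). Per-individual block states are the consensus of member-SNP
states, requiring 80% agreement — below that the block state is `UNKNOWN`
rather than a guess.

`block_concordance()` scores each block by the fraction of black-beaked
individuals whose block state matches the state implied by their feather
phenotype (BF implies homozygous founder-2 ancestry, GF heterozygous, WB
homozygous founder-1). Blocks scoring exactly 1 are flagged as the
candidate interval. A cohort with no recombinant in the region is
degenerate — every block scores 1 — and the flag is only meaningful once
breakpoints exist.

## The causative-mutation screen

`causative_screen()` reproduces the three-step cross-breed logic. Indels
are excluded first and reported separately. Step 1 keeps variants with
founder-contrast FST at or above 0.8 (the published rule excludes below
0.8, so the boundary is inclusive). Step 2 operationalizes "highest FST
shared with every black breed" as the intersection of the per-contrast top
decile (the decile is configurable; no numeric rule was published). Step 3
demands complete genotype-phenotype concordance in the validation
populations: the observed genotype-to-phenotype relation must be one-to-one
with zero exceptions. Survivors are nested by construction, and final
candidates in complete LD (`ld_r2()` = 1) are reported as a single LD
group, mirroring the published outcome of two fully linked SNPs.

## Copy-number classification

`normalize_depth()` turns windowed read counts into depth ratios: each
sample is scaled by its library-size factor, then each window is divided by
the reference-group median (median, not mean, for robustness to outlier
reference samples; windows with zero reference median are masked).
`classify_cn()` maps the ratio to the copy-number classes 0, 0.5, 1, 1.5, 2
— homozygous loss, loss of heterozygosity, diploid, heterozygous
duplication, homozygous duplication — with boundaries at the midpoints
(0.25, 0.75, 1.25, 1.75), ties rounding up, and ratios above 2.25 called
COMPLEX. The class list is the published convention; the midpoint
boundaries are this package's choice, since only the class centres were
stated.

## Expression utilities

`cpm()` is plain counts-per-million. `group_log2fc()` uses a pseudocount of
1 on both group means (no published pseudocount rule; 1 is the common
default and keeps zero-expression genes finite). `ddct_fold()` implements
2^-ddCt with technical replicates averaged before differencing, matching
triplicate qPCR practice.

## Problem sizes used in validation

The test suite exercises: a 440-duck, ~5,200-SNP full scan with
conditioning (one replicate); a 200-sample, 2,000-SNP null calibration; a
10,000-duck F2 segregation check; 50 replicate fine-mapping cohorts of 300
F2 at 36 informative markers; and a 33-variant engineered screen fixture.
These sizes were chosen so the whole suite runs in well under a minute per
component while keeping every statistical check comfortably powered.

## Known limitations

* Founder haplotypes have no within-breed LD, so the simulator cannot probe
  LD-based follow-up analyses (e.g. locus-zoom patterns around a hit).
* Ancestry painting is deterministic; there is no HMM posterior decoding,
  so heavily missing or error-prone regions should use the smoothing option
  with care rather than expect probabilistic robustness.
* The CNV module reimplements only the stated ratio-and-classification
  mapping, not a full CNV caller (no GC correction, no population
  genotyping of CNV alleles).
* Differential-expression testing is out of scope; the expression module
  stops at CPM, fold changes and qPCR quantification.
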
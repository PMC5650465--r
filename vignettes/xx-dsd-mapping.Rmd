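---
title: "Mapping a recessive insertion for canine XX DSD: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive insertion for canine XX DSD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

Canine XX DSD is a disorder of sex development in which SRY-negative dogs
with an XX karyotype develop testicular tissue, from small foci in an
ovotestis up to bilateral testes. The trait behaves as an autosomal
recessive with breed-background-dependent penetrance: in a mixed
cocker-spaniel-by-beagle (ACS x BGL) model pedigree most affected dogs are
homozygous for a candidate guanine insertion, while in purebred pet dogs
most affected animals are heterozygous and homozygotes are rare —
breeding experiments on a susceptible (German shorthaired pointer, GSHP)
background produce no homozygous offspring at all, indicating embryonic
lethality of the homozygote on that background.

`xxdsdmap` implements the statistical chain that localizes such a
variant. This vignette records the models, the tunable parameters and the
package's own design decisions where the underlying procedure left a
choice open.

```{r setup}
library(xxdsdmap)
```

# Data model

Genotypes live in a `genotype_matrix`: samples x biallelic sites, calls
coded as alternate-allele dosage 0/1/2 with `NA` for missing. All
coordinates are **1-based inclusive**, matching VCF and browser-style
printed intervals; the BED-like writers emit this dialect by default and
true BED (0-based half-open) behind `bed_strict = TRUE`. Missing
genotypes are never silently imputed: the GRM and PCA mean-impute
explicitly (documented below), every other stage either excludes or
rejects missing calls.

PLINK text PED/MAP files carry no reference-allele designation, so
`read_plink_text()` takes the first allele seen at a site as reference
unless a reference map is supplied — round trips therefore require
passing the original reference alleles.

A third allele at the focal locus (a CT SNP segregates at the insertion
site in some breeds) is kept as a separate tally. For allele frequencies,
`third_allele_policy = "exclude"` (default) leaves those dogs out of
numerator and denominator; `"as_noncarrier"` counts them as two
non-insertion alleles in the denominator, which is the arithmetic that
reproduces the published cohort frequencies (0.405 / 0.292 / 0.175).

# Segregation-pattern filtering and the enrichment scan

Under the recessive hypothesis the reference animals must show, at the
causal site and anything tightly linked to it: affected dogs
`hom_alt`, the obligate carrier `het`, the unrelated control `hom_ref`.
`segregation_pattern_filter()` retains exactly the sites where every
patterned sample matches. The default `missing_policy = "fail_match"` is
conservative: a missing call cannot *confirm* a pattern, so the site is
rejected; `"ignore_sample"` drops the sample from the comparison instead.
The filter is monotone — adding a required sample can only shrink the
retained set.

`enrichment_scan()` slides fixed windows (default **1 Mb width, 100 kb
step**) over the retained sites. A window's fold enrichment is the
density ratio `(k/w)/(K/G)` with `K` the genome-wide retained count and
`G` the effective genome length (a configuration constant: 2.392e9 for a
CanFam3.1-scale run; the simulator supplies its own 6e8). Overlapping
windows at or above `fold_threshold` (default 5) merge into maximal
segments. How the final segment boundary is drawn was left open by the
source procedure (only the final ~1.9 Mb segment is reported there), so
the package adopts an explicit rule: within a merged segment the retained
variants are split into runs at inter-variant gaps larger than
`trim_gap_bp` (default = the step size, 100 kb) and the reported interval
spans the run with the most variants. This makes the segment cover the
dense cluster itself rather than isolated stragglers caught by a flanking
window, and it is deterministic. Segments are ranked by variant count,
then fold — ranking by per-bp density alone would let a degenerate
one-variant "segment" (width 1 bp) outrank any real cluster. Window ties
break by (chromosome, start).

`homozygosity_blocks()` finds maximal runs of consecutive sites where all
cases are `hom_alt` and all controls `hom_ref`; runs shorter than
`min_sites` are dropped, and per-site qualification is strict by default
(`max_violations = 0`). `breed_sharing_table()` counts, per breed, the
affected dogs homozygous-alternate across an entire block; a breed
"segregates" with one such dog.

# Cohort association

`genotype_count_table()` tallies genotype classes per cohort (missing
excluded; an empty cohort is flagged, not fatal).
`genetic_model_collapse()` builds the test table: dominant (carriers vs
non-carriers), recessive (homozygotes vs rest), allelic (2 per homozygote
+ 1 per het), genotypic (2x3). `contingency_chisq()` wraps the Pearson
test; the Yates continuity correction applies only at df = 1. p-values
come from the continuous chi-squared distribution — with the tiny cell
counts typical of a rare-disease cohort an exact test could be
substituted, but the published analyses used the chi-squared, and the
package follows them. Multiple testing mirrors the study design:
Bonferroni (`alpha/m`) for the fixed-size custom-array stage, BH step-up
for genome-wide p-value lists.

"Thinning every 10th SNP" is ambiguous; the package reads it as
*keeping* one in ten (`thin = "keep"`), consistent with "leaving less
than 2,000 SNPs" from a ~20k post-filter pool, and offers
`thin = "drop"` for the other reading. The prefilter order is missing →
MAF → thinning, the order in which the steps are described.

# The logistic mixed model

The null model is `logit P(y_i = 1) = x_i'beta + b_i` with
`b ~ N(0, tau K)`; `K` is the GEMMA-style centered GRM `ZZ'/p` over
column-mean-centered dosages. Five genotype principal components enter as
fixed effects, computed — exactly as in the source design — on a
*differently* filtered site set than the scan (PCA: MAF >= 0.01 kept,
every 100th site; scan: MAF >= 0.3, every 10th). The phrase "filtered
for MAF < 0.01" is read as *removing* sites below 0.01.

Fitting is penalized quasi-likelihood: iterate the logistic working
response `ytil = eta + (y - mu)/w`, `w = mu(1 - mu)`, solve the GLS
normal equations under `V = W^{-1} + tau K`, and update `tau` by an
average-information step with a fixed-point fallback, floored at zero.
Convergence is a relative parameter change below **1e-6**, capped at
**200 iterations**; a non-converged fit is returned with
`converged = FALSE` rather than raising. Working weights are floored at
1e-6, which bounds the coefficients under quasi-separation (common with
a handful of cases). With `tau` fixed at 0 the fit reduces exactly to
iteratively reweighted logistic regression, which the tests exploit as an
oracle.

The per-variant score test uses `U = g'(y - mu_hat)` and `V = g'Pg`,
`P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}` evaluated at the null
fit, referred to chi-squared with 1 df. Missing dosages are replaced by
the site mean, which zeroes those samples' contribution to the score;
monomorphic sites report p = 1 with a flag. No saddlepoint correction
for case-control imbalance is applied — at pedigree-scale n it would be
the natural next extension.

# Segregation distortion and lethality

`mendelian_expected()` returns `n` times the Punnett class probabilities,
restricted to possible classes (probabilities always sum to 1, verified
against exhaustive gamete enumeration). `gof_chisq()` is the plain
goodness-of-fit statistic with the Yates continuity correction
(`(|O - E| - 0.5)^2/E`) when df = 1 — the base `chisq.test()` offers no
continuity correction for goodness-of-fit tests, hence the hand-written
statistic. A zero expected class is an error advising a class merge.

`lethality_screen()` pools observed and expected counts class-wise across
crosses (per-cross results are reported alongside) and flags a class as
lethality-consistent only when all three hold: never observed, pooled
expectation at least `min_expected = 5` (the standard chi-squared
validity guard — the source is silent here), and pooled test significant
at `alpha` (default 0.01). The screen never flags a class that is
Mendelian-impossible in every cross, and an observed impossible class is
an error.

# Stringent differential expression

The stringent-DE gate retains a gene (per age group) iff `q <= 0.05`,
`|log2FC| >= 1` and the larger comparison-arm mean FPKM is `>= 4`. The
FPKM condition is read as applying to the two comparison arms of that age
group (the plausible alternative — any group at any age — is noted but
not adopted). A pseudocount of 0.1 FPKM guards `log2FC` when a group mean
is zero. The verbal fold categories carry no numeric definition in the
source; the package fixes documented cut points on |log2FC| — `">2-fold"`
at >= 1 (closed boundary: an exactly 2-fold change qualifies),
`"~2-fold"` in [0.9, 1), `"<2-fold"` in [0.4, 0.9), `"<<2-fold"` below
0.4 — configurable and echoed in report headers. Binning assigns genes by
start coordinate to `floor((start - 1)/1e7)` bins; argmax ties break
lexicographically.

The DE statistic itself (cuffdiff's) is out of scope: q-values are
inputs. The simulator supplies a documented stand-in (Welch t-test on
log2(FPKM + 0.1), BH within age group) solely so the stage can be
exercised end to end.

# What the simulator emulates — and what it does not

`sim_config()` defaults are the study conditions, scaled to a genome a
desk machine can iterate on:

* **Genome**: 10 chromosomes x 60 Mb (G = 6e8), 19,750 background
  variants plus a 250-site linked block in chr9:5.0-7.0 Mb containing the
  causal insertion at chr9:6048201 — preserving the ~250-variants-in-2-Mb
  cluster geometry of the real candidate region at about a quarter of the
  genome length.
* **Pedigree**: 2 ACS founder sires carrying the insertion on both
  haplotypes, 6 BGL founder dams, 3 generations mixing founder
  backcrosses (probability 0.3) and intercrosses, 4 offspring per mating
  — the backcross/intercross structure of the model pedigree.
* **Transmission**: background variants segregate independently from
  per-breed allele-frequency profiles (uniform on [0.05, 0.95]); the
  causal block is transmitted whole, reflecting the short ancestral
  haplotype premise. An optional per-meiosis block-edge recombination
  probability exists and defaults to 0.
* **Penetrance**: the source states only directionality (penetrance
  falls as BGL background rises), so the functional form is the
  package's choice, kept in configuration rather than code:
  `P(affected | hom_alt, b) = clamp(pi_hom_max - c(1 - b), 0, 1)` and
  `P(affected | het, b) = pi_het * b`, with `b` the expected causal-breed
  fraction from the pedigree. Defaults `pi_hom_max = 0.9`, `c = 0.5`,
  `pi_het = 0.1`; the het penetrance is a free parameter (a few affected
  heterozygotes exist in the real pedigree, but no rate is quantified).
  Only SRY-negative animals are eligible for the affected phenotype.
* **Lethality**: `{hom_alt, GSHP background >= 0.5, survive = 0}`,
  applied to conceptuses before birth. Litters are modeled only as
  cross-level groupings; no maternal effects, no sex-limited viability.
* **Cohorts**: 63/65/60 dogs at insertion allele frequencies
  0.405/0.292/0.175 under Hardy-Weinberg — the published cohort sizes
  and frequencies.
* **Expression**: 10,000 genes, lognormal FPKM (baseline meanlog
  `log 2`, sdlog 1.5; within-group sigma 0.25), 6 affected vs 6 control
  samples per age group, two age groups, 300 planted genes at 4-fold
  down with baselines floored at 10 FPKM so the expression gate is
  reachable.

Every stochastic operation draws from a named substream of the single
top-level seed (`substream()`), so whole studies reproduce bit-for-bit
and stages can be regenerated independently.

The simulator deliberately omits: linkage disequilibrium beyond the one
causal block (so scan specificity on real, LD-rich genomes will be
somewhat worse than on simulated ones), sequence-level realism, X
chromosome dosage, genotyping error, and cuffdiff's dispersion modeling.
Passing tests therefore demonstrate the *inference machinery* —
filtering, scanning, testing, calibration — not robustness to every
artifact of real data.

# Problem sizes used by the test suite

The suite exercises the stages at study scale while staying quick on one
CPU: the pattern-filter/scan checks run on the full default 20,000-site
genome; mixed-model calibration uses n = 500 unrelated samples and
10,000 null score tests; variance-component recovery uses n = 400 in 20
family blocks over 10 seeds; lethality power/specificity use 100 and 200
replicate cross sets; DE recovery uses the default 10,000-gene table.
These sizes are the package's chosen trade-off between statistical
resolution and iteration speed.

# Known limitations

* PQL variance components for binary traits are biased toward zero at
  small block counts; the test suite asserts recovery within 50%
  relative error at its simulated design, not unbiasedness.
* The score-test scan assumes the null-model `P` matrix applies to every
  site; per-site missingness is handled by mean imputation rather than
  per-site refitting.
* The association stage offers no exact small-cell tests beyond the
  chi-squared (Fisher's exact would be a natural flag to add).
* Sample re-assignment by expression PCA clustering (a QC step in the
  source workflow) is recorded here but not automated.
* `run_pipeline()`'s `--resume` equivalent skips work only when the full
  configuration hash and all output hashes are unchanged — it does not
  track per-stage input lineage at finer grain.
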
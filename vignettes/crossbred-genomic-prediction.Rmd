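---
title: "Predicting crossbred pig performance from SNP genotypes: models and design"
author: "crossgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting crossbred pig performance from SNP genotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgp)
```

## The problem

Pig production relies on three-way crossbred (CB) animals — a terminal sire
line mated to F1 sows from two maternal lines — while selection happens in
purebred (PB) nucleus lines on PB records. When the genetic correlation
between PB and CB expression of a trait (rPB,CB) is below one, gains made in
the nucleus transfer imperfectly to the commercial tier; literature averages
for pig feed efficiency and growth put rPB,CB around 0.66. `crossgp`
implements a complete, testable pipeline for asking how well crossbred feed
efficiency (residual feed intake, RFI) and growth (average daily gain, ADG)
can be predicted from SNP genotypes under different sources of training
information: individual PB records (trn1), per-sire averages of CB progeny
(trn2), and individual CB records (trn3), each evaluated on held-out PB
records (tst1) or sire averages (tst2).

Because commercial datasets of this kind are proprietary, the package ships
a pedigree-aware simulator whose output has the statistical structure the
analysis assumes; every stage of the pipeline is exercised end to end on
simulated data.

## Phenotype preparation

Raw performance-test records go through a fixed sequence:

1. **Test-window filter.** Only records with age at start in [50, 105] days
   and test duration in [60, 120] days are kept. The bounds are treated as
   inclusive ("between" is ambiguous; inclusivity is the package's reading).
2. **Multivariate outliers.** Within farm-by-batch (PB) or
   farm-by-batch-by-sex (CB) groups, records whose squared Mahalanobis
   distance on (ADG, daily feed intake, backfat, metabolic weight) exceeds
   12 are removed. Groups with fewer than 6 records are skipped — a 4x4
   covariance estimated from fewer rows is meaningless — and a singular
   covariance falls back to the pseudo-inverse.
3. **RFI derivation.** RFI is the residual of an ordinary least squares
   regression of daily feed intake on ADG, backfat and metabolic weight
   MW = ((Wstart + Wend)/2)^0.75 (kg^0.75), fitted separately within each
   data subset.
4. **Pre-adjustment.** RFI and ADG are adjusted for age at start and test
   duration (covariates), farm-by-batch, and sex (CB subsets only), after
   dropping farm-by-batch levels with fewer than 10 records. The adjusted
   value keeps the fitted intercept (residual + intercept), so trait means
   stay on their natural scale; rank-based evaluation is unaffected by this
   choice, and the operation is exactly idempotent.
5. **Sire averaging.** For the sire-average subset, adjusted CB records are
   averaged per PB sire.

## Genotype quality control and feature pruning

The QC cascade runs in a fixed order: SNPs with call rate < 0.90 or minor
allele frequency < 0.05 (strict inequality: a SNP at exactly 0.05 stays) are
removed; then samples with call rate < 0.90; then parent-offspring pairs
whose opposite-homozygote rate over jointly typed loci exceeds a tolerance
(default 0.01) have the offspring removed — the parent may anchor other
pairs, so removing the offspring is the safer default. Per data
subset, near-zero-variance SNPs (most-common/second-most-common genotype
count ratio above 95/5) are dropped and greedy correlation pruning removes,
while any absolute pairwise correlation exceeds 0.8, the member of the worst
pair with the larger mean absolute correlation (ties: lower column index).
The crossbred panel is then restricted to the SNPs retained for the PB
sires, in the same column order, so every predictor segregates in the sire
line. Missing doses are mean-imputed before correlation work and GRM
construction; the post-QC missing rate is low, so nothing fancier is
warranted.

## Learners

**Support vector regression.** The epsilon-insensitive SVR dual with
Gaussian kernel exp(-gamma ||u-v||^2) is solved by a sequential minimal
optimization solver written for this package (C++), using the standard
2n-variable expansion and maximal-violating-pair working-set selection.
Features and target are standardized on training statistics, so the tube
half-width epsilon is expressed in target standard deviations. The tube
half-width has no canonical value for genomic data, so the common
toolchain default epsilon = 0.1 is used; it is an exposed parameter. Hyper-parameters are tuned by exhaustive
grid search over C in {0.001, 0.1, 1, 5, 10} and gamma in
{0.005, 0.05, 0.5, 5}, scored by mean squared error over an inner 6-fold
cross-validation (MSE is the standard regression tuning criterion and is
exposed as a setting). Ties break toward smaller C, then
smaller gamma. The solver is validated in the test suite against a generic
quadratic-programming oracle to 1e-6 on the dual objective, and
Karush-Kuhn-Tucker complementarity is asserted point by point.

**GBLUP.** The benchmark learner solves the mixed-model equations for
y = 1 mu + g + e with g ~ N(0, G sigma2_g), where G is the VanRaden genomic
relationship matrix ZZ'/(2 sum p(1-p)) built from all post-QC SNPs over all
animals in the scenario (training and testing together, with frequencies
from the combined matrix). Test animals carry no records; their breeding
values come through genomic relationships. Variance components default to
EM-REML in the eigenbasis of G (deterministic and fast: a coarse profile
scan picks the starting point, EM iterates until the restricted-likelihood
gradient norm is below 1e-6 or 500 iterations, estimates clamped at zero).
A single-site Gibbs sampler with long-chain defaults (250,000
iterations, 25,000 burn-in, thinning 10) is available behind
`method = "gibbs"` for fidelity runs; its priors (scaled inverse chi-squared,
nu0 = 4, scale var(y)/2, flat mean) are weakly informative and the
cross-method agreement test shows REML and Gibbs within 0.05 on h2.
GBLUP deliberately uses all SNPs (no feature selection): subset GBLUP is a
stated non-goal.

## Evaluation design

`run_scenario()` executes the nested design: outer folds (10-fold for
trn1-tst1/trn1-tst2; 5-fold repeated 5 times for trn2-tst2 and trn3-tst2,
which have less data), and within each outer training set feature
standardization, Spearman-rank SNP ranking, subset selection (50-2,000
SNPs, including 1,000), inner-6-fold tuning, fitting, and prediction of the
fold's testing units. Ranking uses |rho| because SVR can exploit either
direction of association. Individual-record testing sets are standardized
with training statistics; sire-average testing sets use their own
statistics, because their scale (a mean of progeny records) differs from
the training records'. For trn3-tst2 the folds are blocked
by sire family so no test sire has progeny records in the training side.
trn1-tst2 reports IN- and OUT-of-training sires separately, where IN means
the sire's own PB record sat in that fold's training data. Accuracy is the
Spearman correlation (SC) between observed and predicted values per fold,
summarized by the median and interquartile range across folds; the
single-split generational scenarios (OLD generations train, youngest two
generations test) get their spread from 500 bootstrap resamples of the
test pairs instead. Constant predictions score SC = 0 with a degenerate
flag rather than erroring mid-pipeline.

Two design details deserve emphasis. First, everything the model touches —
standardization parameters, SNP ranks, hyper-parameters — is computed from
training data only; the test suite includes a pure-noise null (median SC
compatible with zero) and a deliberately leaky variant (`rank_on = "all"`)
that reproduces the optimistic bias of pre-CV feature selection. Second,
variance components for GBLUP are estimated once per scenario from all of
that scenario's records before per-fold BLUP (the standard two-stage
workflow of dedicated BLUP tooling); this is a mild departure from strict
fold hygiene, which is why the leakage null is run with the SVR branch.

## The synthetic world

`sim_config()` defaults describe a desk-scale analogue of a commercial
three-way crossbreeding scheme:

* three founder lines of 100 animals, four discrete terminal-line
  generations of random mating (nucleus selection histories are
  proprietary, so none is imposed), 120 F1 sows, 50 CB-mated sires with 10
  offspring each (a typical median progeny-group size for sire-average
  records);
* 1,200 SNPs with founder MAF uniform on [0.05, 0.5] and founder-haplotype
  LD generated per 8-SNP blocks with latent AR(1) correlation 0.99 — chosen
  so correlation pruning has realistic work (tens of percent of SNPs
  removed, echoing the heavy pruning a dense chip needs);
* 150 QTL shared by the traits, additive effects N(0,1), dominance scaled
  to mean |d/a| = 0.2, and line-context deviations whose SD controls
  rPB,CB. The PB-context genotypic value is sum a(x-1) + d 1{x=1}; the CB
  context replaces a by a + b. With deviations off the two contexts
  coincide and rPB,CB = 1 exactly; `calibrate_line_context()` solves
  sigma_g / sqrt(sigma_g^2 + s^2 sigma_d^2) = target for s, and the
  realized correlation lands within about 0.1 of a 0.66 target across
  seeds;
* phenotypes in Table-1-like units (ADG around 1,100 g/day PB and 880 g/day
  CB; RFI-scale SD 160 g/day; heritability targets 0.35 for RFI and 0.30
  for ADG, typical of pig literature), with age-at-start and duration
  covariate effects, two farms by four two-month-style batches with
  N(0, 25 g/day) shifts, a sex effect expressed in the mixed-sex CB tier,
  and daily feed intake built as a planted linear function of ADG, backfat
  and metabolic weight plus an independent true-RFI component — so the RFI
  regression has a known answer;
* corruption: 1% missing cells and 0.1% per-locus Mendelian errors planted
  as opposite homozygotes of a genotyped parent, with a defect log so QC
  detection can be asserted exactly. Missingness is applied before error
  planting so every planted defect stays observable.

What the generator does not emulate: genetic maps and recombination-based
LD decay (transmission is locus-independent gene dropping), selection in
the nucleus, maternal and litter environment, repeated daily feed-intake
curves, and genotype-by-environment interaction beyond additive
farm-by-batch shifts. A green test therefore establishes that the pipeline
computes what it claims on data with the assumed structure — not that any
particular accuracy level would be attained on commercial data. In this
synthetic world the sire-average and individual-CB subsets coincide apart
from the response used (all CB are genotyped offspring of genotyped sires),
whereas the real datasets overlapped only partially.

## Numerical choices

* SMO stops when the maximal KKT violation drops below 1e-6 (1e-4 inside
  the scenario loop, 1e-3 during grid tuning, where fit quality is scored
  by validation error anyway); the iteration cap is 1e7 pair updates.
* EM-REML clamps variance estimates at 1e-10 of the phenotypic variance;
  the profile-scan start avoids the slow EM crawl near the boundary.
* A rank-deficient relationship matrix is bent on its eigenvalue floor
  (1e-8 of the largest eigenvalue, logged); a singular mixed-model
  coefficient matrix gets one 1e-8 ridge attempt before failing.
* Fold assignment shuffles ids and deals them round-robin; family-blocked
  plans assign whole families greedily to the currently smallest fold.
  All randomness flows through integer seeds recorded in the run manifest;
  reruns are byte-identical.
* Quantiles (IQR) use R's default linear interpolation (type 7).

## Limitations

The scenario orderings observed on simulations (for example, CB-reference
training beating OUT-of-training purebred transfer when rPB,CB is 0.66,
with the gap shrinking as rPB,CB approaches 1) are properties of the stated
synthetic world at desk scale; effect sizes will differ at commercial scale
and under real LD. Published accuracy values for this prediction problem
come from proprietary commercial data and are deliberately not
reproduction targets of this package.
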
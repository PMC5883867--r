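---
title: "Joint-population genomic prediction of ordinal hip scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-population genomic prediction of ordinal hip scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointgp)
```

## The problem

Canine hip dysplasia is scored radiographically: the Norberg angle of each
hip, a measure of joint laxity, maps to an ordinal 0–6 score in the UK
(BVA/KC) scheme, with 0 for healthy hips (angle above 105°) and 6 for the
most severe (angle below 79°). The trait is moderately heritable, which
makes genomic selection attractive, but single-country reference panels of
genotyped, scored dogs are small. The question this package is built
around is whether pooling two diverged populations of the same breed —
e.g. a large UK panel and a smaller US panel — into one joint training set
improves genomic prediction, and what limits it: relatedness between the
panels, consistency of linkage disequilibrium (LD), the information content
of GWAS-preselected marker subsets, and their genome coverage.

Because real per-dog records for such cohorts are not generally
redistributable, the package ships a synthetic-cohort generator that
reproduces the statistical structure the analysis assumes, and every
method is exercised and validated on cohorts from that generator.

## The GBLUP model

The workhorse is genomic best linear unbiased prediction:

$$ y = W\alpha + u + e, \qquad
   u \sim \mathcal{N}(0, G\,\sigma_g^2), \quad
   e \sim \mathcal{N}(0, I\,\sigma_e^2), $$

with $y$ the mean left/right Norberg-angle score, $W$ the fixed-effect
design (intercept, sex, origin; the origin column is dropped automatically
when a training set is single-origin, where it is aliased with the
intercept), and $G$ the VanRaden Method 1 genomic relationship matrix

$$ G = \frac{ZZ'}{2\sum_i p_i(1-p_i)}, $$

where $Z$ is the dosage matrix centered by $2p_i$ per SNP. Missing
dosages are mean-imputed at GRM construction only; the raw matrix keeps
them. A ridge of 0.01 is added to the diagonal before any inversion, and
in cross-validation the allele frequencies are computed once from the full
joint cohort so every fold's sub-block refers to the same centering.

### AI-REML

`fit_aireml()` maximizes the restricted likelihood with average-information
(Newton-type) updates. Internals follow standard practice: starting values
$\sigma_g^2 = \sigma_e^2 = \mathrm{Var}(y)/2$; step-halving whenever an AI
step would decrease the restricted log-likelihood; a single EM step
whenever the AI proposal leaves the parameter space; a component floor of
$10^{-8}\mathrm{Var}(y)$. Convergence is declared when the components,
normalized by their sum, change by less than $10^{-5}$ in maximum absolute
difference. Two numerical guards matter in practice:

* *Degenerate phenotypes.* When $y$ lies in the span of $W$, the
  restricted likelihood increases without bound as the overall variance
  scale shrinks, while the sum-normalized components stabilize — the
  convergence metric alone would declare success far from the floor. After
  convergence the fit therefore tests a ten-fold scale contraction; if it
  improves the likelihood, both components are clamped to the floor and
  the `boundary` flag is set.
* *Identifiability.* If the final AI matrix is near-singular (condition
  number above $10^{10}$), the fit is flagged `boundary` as well; this is
  the regime that produces heritability estimates of 1 with flat
  likelihood profiles on very small training groups.

The inverse of the final AI matrix is reported as the sampling covariance
of $(\hat\sigma_g^2, \hat\sigma_e^2)$, and heritability
$h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$ gets a delta-method standard
error with partials $\partial h^2/\partial\sigma_g^2 = \sigma_e^2/s^2$ and
$\partial h^2/\partial\sigma_e^2 = -\sigma_g^2/s^2$, $s$ the component sum.

### Prediction

Validation individuals are predicted by the conditional-expectation form
$\hat u_{val} = G_{vt} G_{tt}^{-1} \hat u_{t}$ plus the fixed-effect part
for their covariates. This is algebraically equivalent to solving
Henderson's equations with the validation records treated as missing, and
to ridge regression on centered marker dosages with
$\lambda = c\,\sigma_e^2/\sigma_g^2$ (where $c$ is the VanRaden
denominator); both equivalences are asserted in the test suite rather than
offered as user options. Prediction quality is summarized by the Pearson
correlation $\rho$, the mean squared error, and the slope of the
regression of observed on predicted scores (1 = unbiased; above 1 means
the predictions under-disperse). The accuracy of selection is
$\rho/\sqrt{h^2}$.

## Cross-validation designs

`make_folds()` assigns 5 folds stratified within origin (larger blocks
first, so 1,179 dogs split 236/236/236/236/235 and 242 split
49/49/48/48/48), and `run_cv()` re-estimates the variance components
within every training set — per-fold heritabilities are part of the
report. Training schemes: `joint` (both origins' non-held-out folds),
`pop1-only`, `pop2-only`, and `balanced-subset` (equal random draws per
origin). Aggregation is mean over folds within replicate, then mean and
min–max over replicates. Folds whose REML fit fails to converge are
excluded and counted, never imputed. Replicate $r$ derives its fold split
from `seed + r`, so reports are reproducible.

`split_by_pc()` + `pca_group_experiment()` implement the no-CV design:
rank samples on a principal component of the variance-standardized
genotype matrix (PLINK-style per-SNP standardization, the default for
stratification; the VanRaden-scaled GRM spectrum is also available and
spans the same subspace), cut into contiguous near-equal groups, train on
one group, validate on each excluded group.

## GWAS preselection without leakage

`fit_lmm_gwas()` scans SNPs one at a time in
$y = W\alpha + x_i\beta_i + u + e$. The training-block GRM is
eigendecomposed once; in the eigenbasis the model is weighted least
squares with weights $(\lambda d_j + 1)^{-1}$ at the variance ratio
$\lambda = \sigma_g^2/\sigma_e^2$ estimated on the null (no-SNP) model.
$\beta_i$ is tested as a fixed effect with the Wald statistic
$(\hat\beta/\mathrm{se})^2$ against $\chi^2_1$. Fixing $\lambda$ across
SNPs is a deliberate score-test-like approximation: the scan's only role
in the pipeline is ranking SNPs for subset selection, and ranking is
insensitive to per-SNP re-optimization at these scales; a
`per_snp_lambda = TRUE` switch re-profiles the ratio per SNP for users who
want the full treatment. At $\lambda = 0$ the scan reduces exactly to OLS,
which the tests exploit as an oracle.

`subset_prediction_experiment()` nests everything inside cross-validation:
for each fold, the GWAS ranking, the subset GRM (joint-cohort allele
frequencies restricted to the subset), the REML refit and the prediction
all use the training records only — ranking on data that includes the
validation fold would leak association signal into the measured accuracy.
GWAS effect sizes are never used for prediction, only for ranking; subset
SNP effects are re-estimated jointly by GBLUP. Random subsets are
replicated (default 20).

## Haplotype blocks and genome coverage

`estimate_blocks()` implements a simplified Gabriel-style algorithm: for
SNP pairs within 200 kb, two-SNP haplotype frequencies are estimated from
unphased genotypes by EM (the double heterozygote is the only ambiguous
class), and a confidence interval for $|D'|$ comes from profiling the
multinomial likelihood over $|D'|$ with allele frequencies held at their
estimates. Pairs are classified strong-LD (CI within [0.70, 1] reaching
0.98) or strong-recombination (upper CI below 0.90); candidate spans whose
outermost pair is strong and whose informative pairs are ≥95% strong-LD
are accepted greedily, longest first, leftmost on ties, without overlap.
All thresholds are arguments. `coverage_fraction()` then reports the
fraction of the total block span (not chromosome length) covered by
blocks containing at least one subset SNP — the statistic that
distinguishes the genome coverage of random versus preselected subsets.

## The synthetic-cohort generator

`simulate_cohort()` emulates the joint-cohort structure:

* **Founder LD.** A small founder set (30 haplotypes, allele frequencies
  drawn in (0.1, 0.9)) is expanded through 20 generations of random mating
  with crossovers at 1 cM/Mb over 38 chromosomes, building LD that decays
  with distance.
* **Divergence.** Two populations drift independently for 6 Wright–Fisher
  generations at effective size 100; expected
  $F_{ST} \approx 1-(1-1/(2N_e))^g \approx 0.03$, matching an
  intra-breed, cross-country split. Binomial resampling was chosen
  precisely because it admits this closed form for calibration.
* **Trait.** `n_qtl` markers get Gaussian effects (QTL are markers, so the
  GBLUP model is correctly specified; a `hidden_qtl` flag drops them from
  the panel to emulate imperfect LD). Liability maps to Norberg angles
  with *larger* genetic liability giving *smaller* angles and larger
  scores. The residual splits into a dog-level and a hip-level part so
  that the left/right score correlation is 0.6 and the heritability of the
  mean left/right phenotype **on the angle (liability) scale** equals
  `target_h2` (default 0.3). Under those two constraints the per-hip
  heritability works out to $h^2(1+\rho_{LR})/2 \approx 0.24$. The
  ordinal 0–6 binning of the angle costs a little information: the
  heritability recoverable from the mean *score* is attenuated to roughly
  0.26 when the angle-scale target is 0.3, which is why the
  parameter-recovery checks analyze the mean angle. Angle mean and sd
  default to 104° and 9°, which places the bulk of simulated dogs at
  scores of 2 or below, with sex and origin shifting the liability by 0.1
  score units each.
* **Determinism.** One top-level seed; every stage (founders, drift,
  trait) derives its own sub-stream deterministically, so identical
  configurations give bit-identical cohorts.

Desk-scale defaults (600 + 150 dogs, 2,000 SNPs) stand in for the
full-size design (1,179 + 242 dogs, ~10⁵ SNPs) because REML costs
$O(n^3)$ per iteration; all sizes are configuration, not constants. The
test suite runs cohorts between 180 and 500 dogs and 250–2,000 SNPs.

What the generator does *not* emulate: pedigree structure and family
clusters within population (real within-population relationship spectra
are long-tailed; ours come from a homogeneous drifting pool), genotyping
error and missingness patterns, selection during the drift phase, X-linked
inheritance, and any real LD map. Passing tests therefore demonstrate
that the estimators recover the structure this generator creates — drift
divergence, distance-decaying LD, a polygenic ordinal trait — not that
real cohorts would yield any particular accuracy.

## Numerical and design choices worth knowing

* Score-scale breakpoints: the public scheme pins only the endpoints
  (0 above 105°, 6 below 79°). The default scale places six strictly
  decreasing thresholds evenly from 105 to 79 and assigns an angle the
  count of thresholds strictly above it, so an angle exactly on a
  threshold takes the lower (healthier) score. Users holding the original
  conversion table can supply their own breakpoints.
* Merging joins on (chromosome, position), harmonizes swapped allele
  labels by flipping dosages, and drops irreconcilable or strand-ambiguous
  (A/T, C/G) SNPs with a message — positions, not names, are the stable
  key across chips.
* `maf_filter()` uses a strict inequality (`min(p, 1-p) > threshold`,
  default 0.01) and always recomputes frequencies on the current sample
  set.
* The Weir–Cockerham $F_{ST}$ aggregates as ratio-of-averages
  $\sum a / \sum(a+b+c)$, the PLINK convention; per-SNP $\theta$ is also
  reported.
* LD consistency between populations correlates *signed* dosage
  correlations $r$ (not $r^2$) over shared intra-chromosome pairs within
  1 Mb passing MAF 0.05 in both populations, with allele orientation
  harmonized first; window and floor are arguments since published
  protocols vary.
* GWAS ties in p-value rank break by ascending genome order; preselected
  subsets are therefore deterministic and nested across fractions.
* In the calibration checks, single-scan Kolmogorov–Smirnov uniformity
  tests on LD-correlated p-values are noisy by construction, so the suite
  judges the median KS p-value over twelve permutation scans and pools the
  scans for the type-I error rate.

## Limitations

Univariate only: the cross-population genetic correlation (a bivariate
REML quantity) is out of scope. Dense linear algebra assumes desk-scale
$n \le 5{,}000$. The Dennis conversion table's intermediate angle bands
are approximated by even spacing. Haplotype-phase statistics beyond
two-SNP EM (multi-locus phasing) are not implemented.
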
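---
title: "Methods: pathway-centred case-control association and patient stratification"
author: "slepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway-centred case-control association and patient stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slepath)
```

# Scope

`slepath` implements a gene-centred case-control analysis for targeted
sequencing studies of immune-mediated disease, moving from single variants
to immunological pathways: aggregate pathway and gene association testing
with a sequential-elimination scheme for independent signals, per-patient
pathway polygenic risk scores (PRS) with control-percentile positivity
calls, hierarchical patient stratification with clinical group
comparisons, and rare/case-only variant cataloguing. Because cohort-level
genotype data of this kind are typically not publicly deposited, the
package ships a synthetic-cohort generator that reproduces the statistical
structure every downstream stage assumes, so the whole stack is testable
end to end.

# The aggregate association test

For a set of $m$ variants with minor-allele dosage matrix $G$
(individuals $\times$ variants), case-control status $y_i \in \{0,1\}$
and a null logistic model with fitted means $\mu_i$ (intercept-only by
default; covariates are accepted), define per-variant scores
$s_j = \sum_i w_j G_{ij}(y_i - \mu_i)$ with weights
$w_j = \mathrm{Beta}(\hat f_j; a, b)$ evaluated at the sample MAF
($a=1, b=25$ by default, up-weighting rare variants; `"flat"` weights are
available and preferable when common variants carry the signal). The
family of statistics

$$Q_\rho = (1-\rho)\sum_j s_j^2 \;+\; \rho\Big(\sum_j s_j\Big)^2,
  \qquad \rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\},$$

interpolates between the weighted variance-component statistic
($\rho = 0$) and the squared weighted burden ($\rho = 1$). Each $Q_\rho$
is asymptotically a mixture $\sum_k \lambda_k \chi^2_1$ with $\lambda$
the eigenvalues of $R_\rho^{1/2}\,\Phi\,R_\rho^{1/2}$, where
$\Phi = G_w' P G_w$ is the score covariance under the null projection
$P$ and $R_\rho$ the exchangeable mixing matrix. The reported p-value is
the adjusted p of $T = \min_\rho p_\rho$.

## Numerical construction

* Mixture survival functions are evaluated by characteristic-function
  inversion (Imhof's formula) on composite 8-point Gauss-Legendre panels
  sized to resolve both the arctangent phase structure and the
  oscillation, closed by a two-term integration-by-parts tail expansion.
  Accuracy is about $10^{-7}$ absolute; below $p \approx 10^{-6}$ the
  evaluator hands over to modified-Liu moment matching, which is smooth
  and monotone in the deep tail (what matters there is ordering, not the
  sixth digit).
* For sets with at most 64 variants the adjusted p of $T$ is computed
  **exactly** (up to quadrature): conditional on the burden-direction
  score, every $Q_\rho$ is that score plus a common noncentral quadratic
  form in the orthogonal complement, so the joint tail reduces to a
  one-dimensional Gaussian integral over a noncentral-Imhof CDF. The
  integrand is a narrow step in the burden score (the conditional mean
  cancels the threshold's quadratic term), so the quadrature window is
  located analytically first. The usual independence approximation
  between the burden factor and the remainder errs by 0.01-0.03 in
  mid-range p, which is visible against a $10^5$-permutation oracle;
  the exact route removes that error.
* For larger sets the classic moment-matched construction is used; at
  those dimensions it is accurate and the exact route would be slow.
* $\rho = 1$ is nudged to 0.999 inside the combination integral, as in
  the method's standard construction.

## Small samples and discrete genotypes

With a binary trait, the permutation null of the scores is a lattice.
Two consequences are handled explicitly:

* **Small-sample moment correction.** When a set has $\le 64$ variants
  and any meaningfully weighted variant has a minor-allele count below
  40, the per-$\rho$ null maps are moment-matched to cumulants of the
  exact permutation null (2000 internal permutations, seed-controlled,
  the caller's RNG stream is preserved), and borderline p-values
  (0.001-0.15) are refined by a 20000-permutation mid-p estimate.
  Without the correction the analytic test is conservative at
  $n = 400$ with rare-variant weights (null rejection $\approx 0.028$
  at $\alpha = 0.05$); with it the size is $\approx 0.044$.
* **Mid-p convention.** A continuous approximation targets the mid-p of
  a discrete null (ties between the observed and resampled statistics
  count half). `pvalue_method = "permutation"` therefore reports both
  the standard inclusive estimate (`p_value`, a valid conservative
  test) and the mid-p variant (`p_value_mid`), and analytic/permutation
  comparisons are made against the latter. At very small samples
  (tens of individuals) the permutation atoms are 1-5% of probability
  mass; no continuous approximation can agree more closely than that,
  which bounds what such comparisons can show.

## Choice of p-value route

`set_test_config(pvalue_method = "permutation")` gives the fully
empirical min-p permutation test (per-$\rho$ p-values are permutation
ranks for observed and permuted statistics alike); it is exact but its
resolution is $1/(B+1)$. The analytic route has no resolution floor and
is the default.

# Pathway polygenic risk scores

Weights are the signed natural-log odds ratios of the minor allele from
single-variant logistic fits (allelic 2x2 fallback with
Haldane-Anscombe correction when expected cells drop below 5), for
variants that pass LD pruning (greedy by ascending p, retaining a
variant iff its dosage $r^2$ with every retained variant within 500 kb
on the same chromosome is below 0.2) and are nominally significant
($p < 0.05$). A variant maps to every pathway containing its gene. The
score of individual $i$ for pathway $P$ is
$\sum_{v \in P} \hat\beta_v \, G_{iv}$, with missing dosages imputed to
the cohort mean. Positivity is a score strictly above the
linear-interpolation 97.5th percentile of the control distribution
(at least 20 controls are required). Protective minor alleles keep
their negative weights by default; a risk-allele orientation
(`orientation = "risk"`) recodes them instead — both readings of the
formula are available because the source description is ambiguous.

In-sample weighting (scoring the same cohort the weights were fitted
on) is supported, with a warning: selected variants are winner's-cursed
and the training controls' score distribution sits below that of fresh
controls, so fresh-sample positivity exceeds 2.5%. The split-sample
design (weights from one cohort, thresholds from held-out controls) is
the one under which the 2.5% control-positivity property holds, and is
what the package's validation studies use.

# Stratification

Scores are standardised per pathway against the control mean and
standard deviation (zero-variance pathways are dropped with a warning).
Cases are clustered by Ward linkage (`hclust` method `ward.D2`) on
Euclidean distances and the tree is cut at `k = 4` by default — the
linkage, metric and `k` are parameters recorded in the output, since
the underlying study design does not pin them. Labels are renumbered by
descending cluster size for reproducible reporting. Clinical contrasts
use Mann-Whitney (two groups) or Kruskal-Wallis (more) for
ordinal/continuous variables — suited to an ordinal damage index — and
chi-square (Fisher when any expected cell is below 5) for categorical
flags, with the family-wise Bonferroni threshold $0.05/|family|$
reported alongside raw p-values; a 35-pathway family gives 0.00143.

# Rare and case-only variants

The per-individual burden counts rare (MAF < 0.01) non-synonymous
variants (missense, stop-gained/lost, start-lost, frameshift,
splice-region — splice-region is included because recurrent catalogues
of this kind list splice-region variants) with dosage $\ge 1$; allele
counting (homozygotes twice) is an option because "variants per
individual" is ambiguous between the two. The case-only catalogue keeps
variants with at least one case carrier, zero in-study control carriers
(missing control genotypes are not evidence of presence; per-variant
control missingness is reported), and absence from every supplied
external panel flag, where presence at any allele count excludes the
variant. The recurrent view filters to two or more carriers. The
homozygous-rare screen lists (case, variant) pairs with dosage 2 at
rare non-synonymous sites in a gene list of interest (e.g. monogenic
lupus genes); an empty result is a valid outcome.

# The synthetic cohort generator

The generator emulates the structure the analysis assumes, not any real
cohort: a Beta-shaped MAF spectrum (default
$0.5\,\mathrm{Beta}(0.3, 1.4)$ truncated to $[0.002, 0.5]$, a
sequencing-like rare-heavy spectrum), per-gene variant blocks with
optional LD from a one-factor Gaussian copula whose latent correlation
is calibrated by numerically inverting the bivariate-normal orthant
probability to the target allele correlation, consequence labels
assigned so the expected rare non-synonymous count per gene matches a
configurable rate, and external-panel presence flags sampled from the
probability that a variant of that frequency is seen at least once in a
panel of the given size. Case status comes from either a
liability-threshold model (standard-normal polygenic liability plus the
planted genetic load; cases are the top quantile matching the requested
case fraction — a case-enriched ascertainment design without a fixed
prevalence) or a logistic model with the genetic load centred at its
expectation so the intercept keeps its baseline meaning; the logistic
route refills case/control quotas over bounded resampling rounds.
Clinical outcomes follow a Poisson log-link damage index (non-negative
integers, matching damage-score semantics) and a logistic autoantibody
flag, both driven by the standardised true genetic burden, which is
stored for recovery tests. Case-only variants are injected as
singleton/doubleton heterozygous carriers among cases, absent from all
panels. Every variant is re-oriented after sampling so the written ALT
allele is the minor allele on the realised sample (frequency ties broken
lexicographically), which makes the VCF round trip exact.

What the generator does **not** emulate: realistic human haplotype
structure (the copula LD is exchangeable within blocks), population
stratification, genotyping batch effects, or linkage between clinical
covariates beyond the single burden channel. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to those real-data complications.

The default configuration is desk-scale (hundreds of samples, tens of
genes) so examples run in seconds; the published reference scale
(958 cases / 1026 controls, ~287k SNVs over 1832 genes, 35 pathways) is
reachable through the same configuration fields.

# Validation studies and their design choices

The acceptance studies (reproducible via `scripts/acceptance.R`) were
designed as follows; sizes are the package's own choices.

* **Null calibration**: 500 replicate 20-variant sets at $n = 400$
  under the null generator; the rejection rate at $\alpha = 0.05$ must
  sit inside the exact binomial 95% interval.
* **Permutation agreement**: 20 fixtures of 2000 individuals and 6-10
  common variants (MAF 0.25-0.5) under Madsen-Browning-type
  Beta(0.5, 0.5) weights — continuous per-variant weights densify the
  permutation lattice of the burden component, whose integer
  flat-weight version has a parity structure with atoms above the
  Monte-Carlo noise scale. Fixtures whose min-p statistic exceeds 0.9
  are skipped a priori because at the support boundary both estimates
  pin near 1 and the normalised comparison degenerates. Agreement with
  the $10^5$-permutation mid-p is assessed as consistency with
  Monte-Carlo noise at the 3-standard-error scale: at least 90% of
  fixtures inside 3 SEs and none far outside (two *identical*
  estimators would breach an all-fixtures-within-3-SE band in about 5%
  of runs, so a literal all-must-pass rule cannot distinguish a correct
  method from noise).
* **Sequential elimination**: six disjoint pathways
  (30/20/15/15/15/15 genes x 12 SNVs), per-SNV ln-OR 0.3 on causal
  fractions 0.25 and 0.15 of the two causal pathways (mean 0.20;
  identical fractions would leave "stronger first" undefined),
  n = 1000/1000 under the logistic model, flat test weights (effects
  are planted across the full MAF spectrum, and rare-upweighting would
  discard the informative common signal). Success means the first two
  selections are the planted pathways in strength order, in at least
  90 of 100 replicates. A paired construction with fully shared causal
  genes must collapse to a single selection.
* **Positivity**: split-sample design (weights from a 400/600 cohort,
  thresholds from 2000 held-out controls, rate measured on 400 fresh
  controls per replicate, 5 pathways x 10 replicates) with the pooled
  rate inside the exact binomial interval around 2.5%.
* **Stratification**: four subgroups, each elevated by +3 control-SD
  on its own pair of 8 pathways (cluster signatures in the style of
  pathway-PRS heat maps; minimum between-centre distance 4.24 SD).
  A literal pairwise centre distance of 3 SD is below the
  Bayes-optimal ARI 0.8 threshold and is not a meaningful target.
* **Effect recovery**: ln(1.5) planted at one common SNV, 4000
  chromosomes, logistic Wald 95% CI coverage at least 90/100 (case-
  control sampling preserves the logistic slope, so the estimate is
  consistent under ascertainment).

# Worked example

```{r example, eval = FALSE}
library(slepath)

cfg <- sim_config(n_cases = 300, n_controls = 300, n_genes = 30,
                  n_pathways = 5, variants_per_gene = 10,
                  causal_pathways = list(causal_pathway("P1", 0.35, 0.3)),
                  disease_model = "logistic", seed = 42)
pipe <- pipeline_config(outdir = "slepath_demo", simulate = cfg,
                        set_test = set_test_config(weight_scheme = "flat"),
                        seed = 42)
manifest <- run_full_pipeline(pipe)
```

This writes the fixture bundle, the single-variant and aggregate
association tables, the sequential-elimination trace, PRS weights,
scores and positivity calls, cluster assignments with clinical
contrasts, and the rare/case-only reports, plus a manifest with md5
hashes and the seed.

# Known limitations

* Covariate adjustment is supported in the association engine but the
  permutation route assumes exchangeability and warns when covariates
  are present.
* The exact min-p construction is quadrature-exact for the Gaussian
  score limit; genuine finite-sample lattice effects remain at very
  small n (quantified above) and are only fully captured by the
  permutation route.
* The copula LD model is exchangeable within blocks and is meant to
  exercise pruning logic, not to mimic human LD decay.
* P-values below about $10^{-12}$ are combined by the Bonferroni rule
  across the rho grid; they are reported for ordering, not for their
  absolute magnitude.
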
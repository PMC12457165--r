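---
title: "Genomic selection indices for working-dog breeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection indices for working-dog breeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selindex)
```

## The problem

Guide-dog schools breed from small, closed colonies and must decide, long
before a dog finishes training, which animals to keep as breeders. The
decision rests on many traits at once: behavioral scores assigned by trainers
(trainability, distraction, pace, pull strength, neck control, soundness, an
overall handler rating), a set of mostly low-prevalence health diagnoses
(dental, ocular, dermatological, musculoskeletal and other conditions), and
ultimately a binary outcome — did the dog succeed as a guide? `selindex`
implements a complete genomic-evaluation workflow for this setting: SNP
quality control, a genomic relationship matrix (GRM), REML/GBLUP breeding
values with fixed effects, correlation-weighted multi-trait selection
indices, and cross-validated predictive evaluation. Because colony data of
this kind are access-restricted, the package also ships a population
simulator that reproduces the statistical structure of such a dataset, so
every stage is testable end to end without any external download.

## The mixed model

For each trait the package fits the standard GBLUP model

$$ y = X\beta + u + e, \qquad u \sim N(0, \sigma^2_g G), \qquad
   e \sim N(0, \sigma^2_e I), $$

where $G$ is the additive genomic relationship matrix and $X$ holds the
fixed effects — by default an intercept, birth year as categorical
indicators (first level dropped), and the first three principal components
of $G$; index scores or parental scores can be appended. Variance components
are estimated by restricted maximum likelihood (REML): the GRM is
eigendecomposed once, the model is rotated to the eigenbasis where the
covariance is diagonal, and the restricted log-likelihood — profiled so that
only the heritability ratio $h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$
remains free — is maximized over $[0,1]$ with Brent's method (tolerance
1e-8). Boundary solutions are allowed and flagged. The estimated ratio is
reported as the trait's *pseudo-heritability*. On the rotated scale the
profiled definition coincides with the raw $\sigma^2_g/(\sigma^2_g+\sigma^2_e)$
for this single-random-effect model, so no further choice is required.

Binary and ordinal traits are fitted on their observed 0/1/k numeric scale —
a linear mixed model, no threshold link. This mirrors the analysis style the
package reproduces, whose continuous predicted phenotypes are thresholded
only afterwards for classification metrics. Fixed-effect solutions are
generalized least squares under $V = \sigma^2_g G + \sigma^2_e I$, and
breeding values are $\hat u = \sigma^2_g G V^{-1}(y - X\hat\beta)$.

Held-out individuals are predicted by the conditional expectation
$\hat u_{\text{test}} = G_{\text{test,train}} G_{\text{train,train}}^{-1}
\hat u_{\text{train}}$ (ridge-stabilized solve), which for this model equals
the prediction from a joint mixed-model equation system with missing
responses but is simpler to validate against a dense conditional-normal
oracle; predicted phenotypes add $X_{\text{test}}\hat\beta$. Index-score
fixed effects (behavior score, total score) are observed phenotypic values
and are therefore available for test-fold individuals; parental-score fixed
effects restrict the analysis to the trio subset with both parents scored.

## The GRM

`compute_grm()` uses VanRaden's first method: per-SNP mean imputation of
missing dosages, centering by twice the sample allele frequency, and
$G = MM^\top / \sum_j 2 p_j (1 - p_j)$ over polymorphic SNPs. Allele
frequencies come from the analyzed sample itself, the appropriate choice for
a single closed population. A per-SNP-standardized variant is available via
`method = "standardized"` because the exact construction used by commercial
software cannot be pinned down; the two differ only in how low-frequency
SNPs are weighted. Principal components are eigenvectors scaled by the
square root of their eigenvalues with a deterministic sign convention
(largest-magnitude loading positive), so repeated runs are bit-identical;
any affine rescaling would be absorbed by the fixed-effect coefficients.

## Quality control

`run_qc()` applies, in the conventional order: variant call rate, sample
call rate, an exact Hardy–Weinberg test, and minor allele frequency. The
defaults (call rates below 0.90 removed on either axis, HWE $p < 10^{-5}$,
MAF $< 0.01$) reproduce the thresholds used for the reference dataset, each
applied as a strict inequality on the failing side, matching the wording
"less than" / "below" of the original pipeline. The HWE test is the plain
two-sided exact test conditional on allele counts (the PLINK default; the
mid-$p$ variant is deliberately not used), computed on all samples because
the original analysis did not restrict to founders. Filters are idempotent,
and every removed variant or sample is accounted for in the report.

## Selection indices

Trainer-assigned behavior categories are first condensed to ordinal scores
(`standardization_map()`): pace, pull and neck to a 0/1/2
low/average/high scale, distraction to binary, soundness to 0/1/2, rating
retains its eight levels (0–7). Each standardized score $X$ is then
normalized by its relationship with success:

* negative-direction traits (neck, distraction, rating):
  $|X_{\max} - X| / X_{\max}$,
* positive-direction traits (soundness, trainability): $X / X_{\max}$,
* optimum-intermediate traits (pace, pull): $1 - |X - 1|$.

The Behavior Score is the weighted sum of the normalized values; the Health
Score is the sum of binary diagnosis indicators times each condition's
(negative) correlation with success; the Total Score is
$w_{\text{health}} \cdot \text{health} + w_{\text{behavior}} \cdot
\text{behavior}$. Two defaults deserve explanation:

* **Weight signs.** The normalizations already orient every behavior trait
  so that 1 is best. Multiplying an inverted negative-direction trait by its
  *negative* correlation would penalize good dogs again, so the default
  weight is the absolute correlation; `raw_sign_weights = TRUE` restores the
  literal signed product for comparison.
* **Total Score weights.** No values for $w_{\text{health}}$ and
  $w_{\text{behavior}}$ are published; the defaults are the absolute
  correlations of the two composite scores with success (0.02 and 0.324),
  configurable via `default_index_weights()`-shaped lists.

Condition counts (Dental/Ocular/Dermal/Health) tally diagnoses per category;
every diagnosed condition adds one point to the overall Health Count,
including the neurological, congenital and infectious conditions that belong
to no named sub-count. The trainability scale's range is program-internal
and not published; its $X_{\max}$ defaults to 10 and must be set to match
the user's data. Missing trait values are an error, not imputed — the
reference analysis excluded incomplete dogs, and silent imputation would
change the indices.

## The simulator

`simulate_population()` generates founders in Hardy–Weinberg equilibrium at
allele frequencies drawn uniformly from `maf_range`, then gene-drops
offspring by transmitting one uniformly chosen allele per parent per SNP.
Loci are unlinked: the downstream analysis uses only genome-wide
relationships, never linkage, so omitting a recombination map leaves every
GRM expectation unchanged. Traits follow a liability-threshold model — the
generative model is a package choice; only observed heritabilities and
category frequencies are published — with causal effects drawn for
`n_causal_per_trait` SNPs, the genetic value standardized to variance
exactly $h^2$, and independent $N(0, 1-h^2)$ environmental noise. Binary
traits threshold the liability at the normal $(1-\text{prevalence})$
quantile; ordinal traits cut at the quantiles of the observed cumulative
category frequencies; continuous traits are the liability itself.

Success is a weighted sum of trait liabilities plus noise, dichotomized at
the configured success rate (default 0.5; the real split is unpublished).
The liability-scale weights are the target phenotypic correlations inflated
by the binormal point-biserial factor $\sqrt{q(1-q)}/\phi(z_q)$, so the
realized correlation of the binary outcome with a continuous trait
approaches its target (e.g. trainability 0.531); correlations with ordinal
phenotypes are attenuated further by categorization, which the generator
reports rather than corrects. Default trait parameters reproduce the
published population: 844 dogs (200 founders + 644 offspring, of which 172
form the trio subset with fully phenotyped parents), ordinal category
frequencies from the published standardization table, pseudo-heritabilities
from the published per-trait estimates (values printed as "<0.000" enter as
0), health-condition prevalence 0.05 (low-prevalence incidental findings;
per-trait prevalences are unpublished), and a 2% missing-call rate.
Environmental residuals are independent across traits by default
(`residual_trait_cor` exposes a shared component) because no residual trait
covariances are published.

What the simulator does *not* emulate: linkage disequilibrium, litter
structure and multi-generation selection, X-linked inheritance, genotyping
batch effects, and rater drift in behavior scoring. Tests that pass on
simulated data therefore validate the estimation machinery — not the claim
that any particular real trait is predictable.

## Cross-validated evaluation

`evaluate_trait()` runs seeded k-fold cross-validation (default five folds,
sizes differing by at most one, unstratified by default with an optional
stratify flag): fit on four folds, predict the fifth, so every individual is
predicted exactly once out of fold. Metrics follow the trait type — MCC and
AUROC for binary traits, Kendall's tau-b and Spearman's rho for ordinal
traits, Pearson's R and NMSE for continuous traits — reported pooled over
all out-of-fold predictions and per fold (the per-fold values feed the
violin plots; whether published tables pooled or averaged folds is unstated,
so both are available). Numerical conventions:

* **MCC** returns 0 whenever a denominator factor is zero — the convention
  under which a constant one-class prediction on an unbalanced trait scores
  exactly 0, reproducing the characteristic `0.000` pattern of
  low-prevalence traits under a linear predictor.
* **Classification thresholds** are unpublished; the package uses the
  simplest rule consistent with that pattern — 0.5 for binary predictions,
  nearest-class rounding with clipping for ordinal — and exposes the
  threshold as an option.
* **AUROC** is the rank (Mann–Whitney) form with ties credited one half.
* **NMSE** divides by the population (divide-by-$n$) variance of the
  observations so a constant mean predictor scores exactly 1.

One property of pooled out-of-fold predictions is worth knowing: each
training fold estimates its own intercept, so for a null trait the pooled
predictions are slightly *anti*-correlated with the held-out labels (a fold
whose test set is case-rich trains on a case-poor complement). Null AUROC
therefore sits just below 0.5 rather than exactly at it; the package reports
what the procedure actually produces.

## Problem sizes used by the test suite

The package's acceptance-style checks replicate simulations at sizes chosen
to make the sampling distributions of the checked statistics narrow enough
for their stated tolerances: heritability recovery uses 50 replicates of a
1,000-dog (500 founders + 500 offspring) population with 10,000 SNPs —
family structure matters here, since REML heritability from a GRM of
unrelated individuals is several times noisier than from a pedigreed
population of the same size; the AUROC-versus-$h^2$ ordering uses 50
replicates of 800 dogs with 5,000 SNPs; the behavior-score uplift comparison
uses 20 paired replicates of 400 dogs with 2,000 SNPs. Where a published
condition fixes a size (sample counts, fold counts, replicate counts), the
tests use it; SNP counts not fixed anywhere were chosen once at
GRM-resolving density and kept.

## A worked example

```{r example, eval = FALSE}
library(selindex)

pop <- simulate_population(sim_config(n_snps = 5000, seed = 1))
qc <- run_qc(pop$geno)
grm <- compute_grm(qc$geno)
pcs <- compute_pcs(grm, 3)
scored <- add_parent_scores(score_dogs(pop$pheno))

success <- evaluate_success(scored, grm, extra_fixed = "behavior_score",
                            pcs = pcs, k = 5, seed = 1)
glance(success)
autoplot(success)
```

## Known limitations

* The linear (non-threshold) treatment of binary and ordinal responses is
  faithful to the reproduced analysis but biases variance components on the
  observed scale; liability-scale heritabilities would need a threshold
  model.
* Holdout prediction conditions on training breeding values, not a joint
  refit; the two coincide for this model class but would not for models with
  multiple random effects.
* The simulator's unlinked loci make LD-based phenomena (marker density
  effects, imputation accuracy) out of reach by design.
* Pedigrees are one generation deep; multi-generation gene dropping would
  be needed to study long-term selection response.
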
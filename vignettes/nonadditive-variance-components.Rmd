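---
title: "Partitioning additive, dominance and epistatic genetic variance with genomic relationship matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning additive, dominance and epistatic genetic variance with genomic relationship matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(epigblup)
library(dplyr)
```

## The model

epigblup fits animal models of the form

$$\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{f}b + \mathbf{Z}\mathbf{a}
 + \mathbf{Z}\mathbf{d} + \mathbf{Z}\mathbf{e}_{aa} + \mathbf{Z}\mathbf{e}_{ad}
 + \mathbf{Z}\mathbf{e}_{dd} + \mathbf{Z}\mathbf{pe} + \boldsymbol\epsilon,$$

where $\mathbf{y}$ holds one or more records per animal, $\mathbf{X}\boldsymbol\beta$
the fixed effects, $\mathbf{f}b$ an optional regression of the phenotype on the
inbreeding coefficient (inbreeding depression), and the random terms are the
additive ($\mathbf{a}$), dominance ($\mathbf{d}$), epistatic
($\mathbf{e}_{aa}, \mathbf{e}_{ad}, \mathbf{e}_{dd}$) and permanent
environmental ($\mathbf{pe}$) effects, each with covariance
$\mathbf{G}_k\sigma^2_k$ (identity for $\mathbf{pe}$ and the residual).

The covariance structures come from SNP genotypes:

* $\mathbf{G}_A = \mathbf{M}\mathbf{M}'/(2\sum_i p_i q_i)$ (VanRaden), with
  $\mathbf{M}$ the allele dosage centred at $2p_i$;
* $\mathbf{G}_D = \mathbf{W}\mathbf{W}'/(4\sum_i p_i^2 q_i^2)$ (Vitezica),
  with $\mathbf{W}$ the heterozygosity coding $(-2q_i^2,\,2p_iq_i,\,-2p_i^2)$
  that is orthogonal to the dosage under Hardy–Weinberg proportions;
* $\mathbf{G}_{AA} = (\mathbf{G}_A \odot \mathbf{G}_A)\,/\,
  (\mathrm{tr}(\mathbf{G}_A \odot \mathbf{G}_A)/n)$, and analogously
  $\mathbf{G}_{AD}$ and $\mathbf{G}_{DD}$: Hadamard products rescaled so
  their trace equals the number of animals, which puts every component on a
  comparable per-animal scale.

Sixteen named model variants (`MA` … `MAIDE3`, and the repeatability set
`MAIpe` … `MAIDEpe`) are catalogued in `model_catalogue()`; any other
combination can be declared with `model_spec()`.

## A worked run

```{r example}
ped <- simulate_pedigree(50, 2, matings_per_generation = 50,
                         offspring_per_mating = 2, seed = 1)
geno <- simulate_genotypes(ped, 1000, mode = "gene_drop", seed = 2)
geno <- apply_qc(geno, snp_call_rate_min = 0.9, maf_min = 0.01,
                 hwe_p_min = 1e-5)$genotypes
truth <- simulation_truth(additive = 0.3, dominance = 0.1, aa = 0.2,
                          residual = 0.4)
grms <- build_grms(geno, kinds = c("A", "D", "AA"))
sim <- simulate_phenotypes(geno, truth, grms = grms, seed = 3)

fit <- fit_reml(build_design(sim$phenotypes, model_spec("MADE1"), grms))
tidy(fit)
variance_ratios(fit)
```

## Estimation: AI-REML with EM fallback

`fit_reml()` maximises the restricted log-likelihood
$-\tfrac12(\log|\mathbf{V}| + \log|\mathbf{X}'\mathbf{V}^{-1}\mathbf{X}| +
\mathbf{y}'\mathbf{P}\mathbf{y})$ by average-information updates. Design
choices that matter in practice:

* **Start values.** The phenotypic variance is split equally across all
  components. This is deterministic and scale-free; no tuning is exposed.
* **Boundary handling.** Components are bounded below by
  $10^{-8}\times\widehat{\sigma}^2_p$. An average-information step that
  violates the bound pins the offending components there and re-solves the
  reduced system (an active-set step); if no improving AI step exists the
  update falls back to the monotone expectation–maximisation form
  $\sigma^{2\,(t+1)}_k = \sigma^{2\,(t)}_k + (\sigma^{2\,(t)}_k)^2
  (\mathbf{y}'\mathbf{P}\mathbf{V}_k\mathbf{P}\mathbf{y} -
  \mathrm{tr}(\mathbf{P}\mathbf{V}_k))/q_k$. Estimates reported at the
  boundary print at the $10^{-8}$ scale and carry an `at_boundary` flag —
  null components are visible rather than silently removed.
* **Convergence.** Relative log-likelihood change below $10^{-8}$ with
  parameters stable to $10^{-7}$, capped at 200 iterations. These values
  make the engine agree with a derivative-free maximiser of the same
  likelihood to better than $10^{-4}$ on small problems, which the test
  suite checks directly. Non-convergence is reported, not raised: a model
  battery keeps running when one overparameterised variant stalls.
* **Standard errors** come from the inverse average-information matrix at
  the optimum; variance-ratio standard errors use the delta method on that
  covariance.

REML log-likelihoods omit constant terms, so likelihoods, AIC
($-2\log L + 2t$, $t$ = number of variance parameters) and likelihood-ratio
tests are only ever compared between models with the same fixed structure;
`likelihood_ratio_test()` enforces this, which in particular separates the
models with and without the inbreeding covariate. The LRT refers the
statistic to $\chi^2_{\Delta k}$. When the tested component lies on the
boundary of its parameter space this reference is conservative; the test
suite measures the empirical size under the null at roughly 2–3% for a
nominal 5%, and the package documents rather than "corrects" this, matching
common practice in variance-component model comparison.

## What the simulator emulates — and what it does not

`simulate_phenotypes()` draws every genetic vector from
$N(\mathbf{0}, \mathbf{G}_k\sigma^2_k)$ using an eigendecomposition of
$\mathbf{G}_k$ with negative eigenvalues clipped at zero (Hadamard products
are only numerically semidefinite). Effects are thus generated from the
model's *own* covariance structures rather than from per-SNP effect draws.
This makes the fitted model correctly specified by construction, which is
the clean surface for parameter-recovery testing: estimation error then
reflects the estimator alone, not model misspecification. The flip side is
that passing recovery tests says nothing about how the model behaves when
real genetic architecture (finite loci, directional dominance, LD between
causal and marker loci) violates those assumptions.

Genotypes come either from independent Hardy–Weinberg draws or from
gene-dropping founder alleles through a simulated pedigree. Gene-dropping
creates identity-by-descent consistent with pedigree inbreeding, so genomic
and pedigree inbreeding coefficients correlate as they do in real livestock
data. The simulator does not model linkage disequilibrium beyond this
pedigree-induced covariance, selection across generations, or
sequence-level mutation.

The allele-frequency sampler defaults to Uniform(0.05, 0.5) so that
simulated SNPs survive the standard MAF filter; genotype QC
(`apply_qc()`) applies, in a fixed single pass, individual call rate, then
SNP call rate, minor allele frequency and a 1-df Hardy–Weinberg chi-square
screen evaluated on the surviving individuals. Monomorphic SNPs are always
removed because they contribute nothing to any relationship-matrix
denominator and break the dominance coding. Remaining missing calls are
imputed at the dosage expectation $2p_i$ (additive coding) and at the
Hardy–Weinberg expectation of the dominance code (zero), which preserves
allele frequencies and adds no spurious covariance.

## Study designs used in the replicated checks

The replicated experiments (parameter recovery, LR calibration, null LRT
size) simulate **family-structured samples**: two generations of random
mating gene-dropped from 40–100 founders, giving 200–500 animals in
full-sib/half-sib families, with 250–2,000 polymorphic SNPs. The family
structure is a scientific necessity, not a convenience: for a sample of
unrelated individuals the off-diagonals of $\mathbf{G}_A$ are $O(m^{-1/2})$
noise, so $\mathbf{G}_{AA}$ is numerically close to the identity and
$\sigma^2_{aa}$ is barely separable from the residual — and masked animals
in cross-validation would have no informative genomic ties to the training
set. Related samples, which is what genomic evaluation programmes actually
analyse, identify these components. Parameter recovery uses 20 replicates
at truth $(\sigma^2_a, \sigma^2_d, \sigma^2_{aa}, \sigma^2_\epsilon) =
(0.3, 0.1, 0.2, 0.4)$; the LR calibration uses 20 replicates of 10-fold
cross-validation at $h^2_a = 0.3$; the null LRT size uses 200 replicates.
These sizes keep the full suite within a few minutes on a single core
while leaving each check adequately powered for its direction.

## Predictive ability: the LR method

`cross_validate()` implements the Linear Regression (LR) comparison of
partial and whole predictions. Animals are partitioned into $k$ folds
(default 10, matching the usual "10% of records missing" design); each
partial fit removes *all* records of the fold's animals, so repeated
records can never leak information about a masked animal, and
variance components are re-estimated in every partial fit — the
conservative reading of "fit the same model to the partial data". The
statistics are computed over the masked animals only:

* bias $\mu_{wp} = \overline{\hat u_p} - \overline{\hat u_w}$ (0 is ideal),
* dispersion $b_{w,p} = \mathrm{cov}(\hat u_p, \hat u_w)/
  \mathrm{var}(\hat u_p)$ (1 is ideal),
* accuracy $acc_p = \sqrt{\mathrm{cov}(\hat u_p, \hat u_w)/
  ((1-\bar F)\widehat{\sigma}^2_a)}$, with $\widehat{\sigma}^2_a$ from the
  whole-data fit and $\bar F$ the mean inbreeding of the masked animals.

A negative partial/whole covariance leaves the accuracy undefined; it is
reported as missing with a log message rather than silently clipped.

## Model comparison

`comparison_report()` collates AIC, likelihood-ratio tests against a
reference model (usually `MA`), Spearman rank correlations between GEBV
vectors (average ranks for ties), and the percentage of commonly selected
animals in the top 1/5/10/20% of each ranking. Selection size is
$\lceil \text{fraction} \times n \rceil$ with ties broken by stable animal
id, a deterministic convention. GEBVs used for ranking are the BLUP
solutions of the additive term from whole-data fits.

## Known limitations

* Dense double-precision matrices throughout: comfortable to a few
  thousand animals, not designed for national-evaluation scale.
* Single-trait models only; no thresholds/link functions for categorical
  scores, no marker-effect (SNP-BLUP) reformulation, no single-step
  pedigree–genomic blending.
* The chi-square LRT reference is conservative for boundary components
  (documented above); no 50:50 mixture correction is applied.
* Weighted residuals (e.g. for progeny-mean traits) are not modelled.
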
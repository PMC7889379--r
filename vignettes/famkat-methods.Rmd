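---
title: "Multivariate-trait region tests for family data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate-trait region tests for family data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famkat)
```

famkat tests whether a region of `p` genetic variants is associated
with `K` correlated phenotypes in samples of related individuals.  This
vignette lays out the model, the statistics, the numerical choices, and
what the simulation machinery does and does not emulate.

## The null model

For family $i$ with $n_i$ subjects, the $n_i K$-vector $y_i$ stacks the
$K$ trait blocks (trait-major).  Under the null hypothesis of no
genetic effect the mean follows a generalized linear model
$\mu_i = g(X_i\alpha)$ with $X_i = I_K \otimes x_i$ (so each trait has
its own coefficient vector over the same $q+1$ covariates, intercept
included).  Two links are supported: identity with Gaussian variance
(continuous traits) and logit with Bernoulli variance (binary traits);
mixing the two kinds in one model is not supported, because the
quasi-likelihood scale and the variance functions are incompatible
across blocks.

Dependence is modeled through a working covariance in Kronecker form,

$$ V_i \;=\; A_i^{1/2}\,\bigl(R_K(\gamma) \otimes R_{n_i}(\varphi)\bigr)\,A_i^{1/2}\,\phi, $$

where $A_i$ holds the variance-function values, $R_{n_i}$ is the
within-cluster (between-subject) working correlation, and $R_K$ the
multivariate-response (between-trait) working correlation.  Each factor
may be independence, exchangeable, or unstructured; unstructured
$R_{n_i}$ requires a constant cluster size, since its entries are
position-wise.  As in any GEE, $V_i$ need not be correctly specified
for the tests to be valid — it only shapes efficiency.  One deliberate
example of working misspecification: the simulation model has
cross-subject cross-trait correlation 0.1, while the Kronecker form can
only represent it as $\gamma\rho \approx 0.06$.  We leave this as is;
it is exactly the kind of misspecification GEE is designed to tolerate.

**Estimation.**  $\alpha$ starts at trait-wise GLM estimates and is
updated by Fisher scoring of the GEE estimating equation
$\sum_i D_i^\top V_i^{-1}(y_i - \mu_i) = 0$; correlation parameters and
the scale $\phi$ are moment estimators on Pearson residuals,
re-evaluated each iteration.  The loop stops when the max-norm of the
$\alpha$ update falls below `tol` ($10^{-6}$ by default; trio-sized
clusters converge in a handful of iterations, `max_iter = 50` is a
generous cap).  $\phi$ is estimated for continuous traits and fixed at
1 for binary traits, standard GEE practice.  Non-convergence flags the
fit rather than silently returning; correlation matrices are nudged to
positive definiteness by shrinking toward the identity only when a
Cholesky factorization fails.  When every cluster has the same size the
per-family algebra is reorganized into whole-sample matrix operations
(the Kronecker inverse is shared), which is what makes the
simulation-scale studies cheap; unequal cluster sizes fall back to a
per-family loop with identical results.

## The test statistics

Let $S_i = \hat V_i^{-1}(y_i - \hat\mu_i)$ be the standardized
residuals and $Z_{lk} = \sum_i g_{il}^\top \hat\Delta_{ik}\hat
A_{ik} S_{ik}$ the score of variant $l$ on trait $k$ (for the two
canonical links $\Delta \equiv 1$).  The tests treat genotypes as
random conditional on phenotypes (a *retrospective* view), so their
null variances rest on genotype moments only:

* $m_l$: minor allele frequency, estimated among **founders** by
  default so that transmitted alleles are not double-counted
  (configurable);
* $H$: the $p \times p$ Pearson correlation of dosages, computed over
  **all** individuals — it describes the genotype scores themselves,
  and relatedness enters separately;
* $\Omega_i$: the genetic-correlation matrix (twice the kinship
  matrix), from the pedigree recursion, or from standardized dosage
  products when the pedigree is unknown.

The residual-kinship quadratic forms
$C_{Ho} = \sum_i u_i^\top \Omega_i u_i$ (with
$u_i = \sum_k \hat\Delta_{ik}\hat A_{ik}S_{ik}$) and
$C_{He}[k,k'] = \sum_i u_{ik}^\top \Omega_i u_{ik'}$ scale those
variances; $C_{Ho} = \sum_{k,k'} C_{He}[k,k']$ identically, which the
code asserts.

* **HoK** (homogeneous kernel): $\kappa_{Ho} = \sum_l w_l (\sum_k
  Z_{lk})^2$, powerful when variants act on all traits alike.
* **HeK** (heterogeneous kernel): $\kappa_{He} = \sum_{l,k} w_{lk}
  Z_{lk}^2$, powerful for trait-specific effects, at the price of a
  null distribution with roughly $K$ times the degrees of freedom.
* **BT** (burden): the squared pooled score of the weighted dosage sum,
  against a 1-df chi-square; best when effects are concentrated and
  sign-aligned.
* **HoO / HeO**: Cauchy combinations $-\tfrac12\{\tan\pi(p_a-\tfrac12)
  + \tan\pi(p_b-\tfrac12)\}$ of the kernel and burden p-values, valid
  under arbitrary dependence of the two components.  Inputs are clipped
  to $[10^{-15}, 1-10^{-15}]$ before the tangent; the induced bias is
  negligible against the overflow it prevents.

**Weight placement.**  The kernel statistics are written as sums of
squared *weighted* scores $\tilde Z_l = \sqrt{w_l}\,Z_l$, so the null
covariance carries $\sqrt{w_l w_{l'}}$.  This is forced by internal
consistency: the chi-square-mixture representation requires the
covariance of exactly the quantities being squared and summed.  With
$w_l \equiv 1$ (the unweighted analysis) the distinction vanishes.

## Mixture chi-square p-values

Kernel statistics are mixtures $\sum_l \lambda_l \chi^2_{l,1}$, with
$\lambda$ the nonzero eigenvalues of the null covariance
(eigenvalues below $10^{-10}\lambda_{max}$ are dropped; materially
negative eigenvalues abort, as they indicate an upstream bug).  Tail
probabilities use the Lugannani–Rice saddlepoint on the cumulant
generating function $K(t) = -\tfrac12\sum\log(1-2\lambda_l t)$; the
saddlepoint is a bracketed root of $K'(t) = q$ on
$(-\infty, 1/2\lambda_{max})$, the singular point $q = \sum\lambda$ is
crossed by local interpolation, and root failure falls back to
Satterthwaite moment matching with the result flagged.  Two exact
shortcuts: $q \le 0$ returns 1, and equal eigenvalues are evaluated as
a scaled chi-square (the mixture *is* one) — this also makes the
single-variant identity between HoK and BT exact rather than
approximate.  P-values are floored at $10^{-300}$.

**Known accuracy limits.**  Against exact numerical inversion, the
first-order saddlepoint for a small mixture such as
$\lambda = (2, 1, 0.5)$ carries a relative error of roughly 1–3% for
$p \in [10^{-3}, 10^{-1}]$ (and grows slowly further into the tail);
accuracy improves quickly with the number of components, and regions of
20+ variants — the intended use — sit well below 1%.  No second-order
or renormalized variant we evaluated improves this uniformly for
mixtures, so the plain first-order form is kept.

## The simulation machinery

The generator emulates the package's study conditions: two haplotype
pools ("EUR-like" and "AA-like") sharing sites, with per-site base MAFs
from a two-component spectrum (60% of sites log-uniform on
[0.002, 0.03], the rest uniform on [0.03, 0.5]) and pool-specific
frequencies perturbed by a Balding–Nichols beta draw with
differentiation 0.05; nuclear trios gene-dropped from a pool (two
haplotypes per parent, one transmitted per parent, no recombination
within the short region); covariates (intercept; Bernoulli(0.5);
cluster-correlated normal with mean 0.5, variance 1, covariance 0.1);
and phenotypes with covariate effects $(0.01, 0.1, 0.1)$ per trait
(continuous) or $(-1.4, 0.1, 0.1)$ (binary, giving prevalence around
0.2).  Error/outcome correlations target 0.2 within trait across
subjects, 0.3 across traits within subject, and 0.1 across both.
Causal variants under the alternative are a random 35% of variants with
MAF < 0.03, with effect $0.095\,|\log_{10} m_l|$ (risk) or
$0.095\,\log_{10} m_l$ (protective); heterogeneous scenarios silence
trait 2 entirely.

Binary phenotypes are dichotomized multivariate normals.  The latent
pairwise correlations are solved from the bivariate-normal orthant
equation so that the **binary-scale** correlations hit the targets at
each pair's marginal prevalences; the orthant probability uses the
one-dimensional integral identity
$\Phi_2(a,b,\rho) = \Phi(a)\Phi(b) + \int_0^\rho \phi_2(a,b,r)\,dr$,
and the solved latent correlations are cached on a prevalence lattice
and bilinearly interpolated (interpolation error $\sim 10^{-4}$, far
below Monte-Carlo resolution).  Targets outside the Fréchet bounds at
the realized prevalences raise an error rather than being clipped.

**What the generator does not emulate:** linkage disequilibrium (sites
are independent given their frequencies; an LD-free pool is the
cleanest setting for verifying the statistics, whose inputs are only
MAFs, dosage correlations and kinship), demographic realism beyond the
frequency spectrum, ascertainment, genotyping error, missingness, and
admixture within families (each family draws all haplotypes from one
pool).  Passing tests therefore validate the statistics and their
calibration — not robustness to LD structure or sampling artifacts in
real cohorts.

## Study sizes used by the test suite and acceptance script

Type-I-error studies run at a desk-scale profile of 300 families
(170/130 across the two pools, preserving the full design's 4:3 ratio)
with 2,000 null replicates — 5,000 where a rate at the 0.01 level is
reported — which resolves a 0.05-level rate to a standard error of
about 0.005.  The full-scale profile (1,400 families, 50,000
replicates) is supported by configuration but is a cluster-scale
computation.  Power-ordering studies run at 700 families (400/300) with
500 replicates: at 300 families *all* methods' power sits at the
nominal level itself, so no ordering is identifiable; 700 families is
the smallest scale at which the weighted analyses separate cleanly
(power 0.10–0.36).  Kernel-ordering conclusions are asserted on the
Beta(1, 25)-weighted analyses for the same reason — unweighted power
on rare-causal scenarios is statistically indistinguishable from the
null at any desk scale.  Each replicate derives its own seed from the
master seed and its index, so any single replicate can be reproduced in
isolation.

## Numerical and design choices, in brief

* Trio composition is father + mother + one child; founders (the
  parents) supply allele-frequency estimates.
* Unknown parents make an individual a founder with kinship 0 to
  everyone but itself; the kinship recursion handles inbreeding
  (diagonal above 1) even though the simulator never produces it.
* Pedigree-based $\Omega$ is the default (trio structure is known);
  the genomic estimator is available when structure is not trusted.
* The JGEE update schedule (correlations re-estimated between each
  $\alpha$ step) is one of several fixed-point schedules that satisfy
  the convergence contract; with trio-sized clusters the choice is
  immaterial.
* Working-correlation parameters are clamped to valid ranges and the
  assembled matrices checked for positive definiteness; the ridge used
  on a singular normal-equations matrix is $10^{-8} I$.
* Desk-scale binary analyses show mildly elevated kernel rejection
  rates (e.g. 0.06 at nominal 0.05 with 300 families) that vanish at
  full scale — small-sample behavior of GEE-based score tests with
  binary outcomes, not an implementation artifact.

## Limitations

Continuous and binary traits cannot be mixed in one model.  The
X chromosome is not handled.  P-values far into the extreme tail
inherit the saddlepoint's slowly growing relative error.  Large
pedigrees with many traits make the unstructured working correlations
expensive to estimate reliably; exchangeable structures and unweighted
tests are the robust default when the data cannot support more.
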
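---
title: "Genomic prediction under genotype-by-environment interaction: models and design choices"
author: "gxepredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction under genotype-by-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxepredict)
```

## The problem

Water-saving irrigation such as alternate wetting and drying (AWD) changes
the environment a rice crop experiences relative to conventional continuous
flooding (CF). When genotypes rank differently across the two systems —
genotype-by-environment interaction (G×E) — a breeding programme must decide
whether to select directly under the new system, indirectly under the old
one, or jointly with models that share information between systems.
`gxepredict` implements the statistical chain that supports this decision
for a two-system, two-year, replicated trial:

1. mixed-model adjustment of plot data per system (REML), with broad-sense
   heritability, conditional R², genetic correlation between systems and
   the correlated-response ratio;
2. genotypic response variables (relative-performance index and
   joint-regression slope);
3. marker-based genomic prediction with linear (GBLUP) and Gaussian (RKHS)
   kernels, in single-environment and three multi-environment forms, fitted
   by Gibbs sampling;
4. the validation designs that quantify what each modelling choice buys:
   random 80/20 cross-validation (single-environment, M1, M2),
   across-generation prediction (S1/S2/S3 with CDmean training-set
   optimization), and a factorial ANOVA on Fisher-Z-transformed abilities.

A synthetic trial generator with the same structure makes every stage
testable without access to the original field data.

## Phenotype adjustment

For each water system $m$ the plot model is
$$Y_{ijkm} = \mu_m + y_{im} + g_{jm} + (gy)_{jim} + \varepsilon_{ijkm},$$
with year fixed, genotype and genotype-by-year random (a
replicate-within-year fixed term is added for block designs). Estimation is
REML via `lme4::lmer`; variance components are constrained non-negative by
the optimizer's parameterization, and boundary estimates are reported as 0.
Adjusted means are $\hat Y_{jm} = \hat\mu_m + \hat g_{jm}$ — the system mean
plus the genotype BLUP, without the year-interaction deviation — and are the
unit of analysis for everything downstream.

Broad-sense heritability on an entry-mean basis is
$$H^2 = \frac{\sigma_g^2}{\sigma_g^2 + \sigma_{gy}^2/n_y + \sigma_e^2/n_r},$$
with $n_y$ and $n_r$ the harmonic means of the numbers of years and plots
per genotype (2 and 6 for a complete two-year, three-replicate design).
Its standard error uses the delta method on a finite-difference covariance
of the REML components and is flagged approximate. The conditional R² is
$(\mathrm{Var}_{fixed} + \sigma_g^2 + \sigma_{gy}^2)/\mathrm{Var}_{total}$;
the fixed-effect contribution is defined as the population variance of the
fitted fixed-effect linear predictor across plots, the convention that
reproduces published summary tables of this design at their printed
precision.

The genotype-by-system variance is tested by a restricted likelihood-ratio
test against the model without the $g{\times}m$ term, with the p-value from
the 50:50 mixture of $\chi^2_0$ and $\chi^2_1$ appropriate for a variance
component on the boundary. The influence screen is deliberately simple —
standardized conditional residuals beyond a threshold (default 4 SD),
removal opt-in and logged — rather than a full likelihood-displacement
diagnostic, which is out of scope.

## Response variables

Two per-genotype summaries of the response to AWD are computed from adjusted
means: the relative-performance index
$I_j = (\hat Y_{j,AWD} - \hat Y_{j,CF})/\hat Y_{j,CF}$ (negative = loss
under the water-saving system), and the joint-regression slope $\beta_j$
from $\hat Y_{jm} = \mu_j + \beta_j \theta_m + \varepsilon_{jm}$, where
$\theta_m$ is the mean of all genotypes in system $m$, left uncentred
because the intercept absorbs location. With two environments the fit is
exact and the mean slope is 1 by construction — both facts are asserted in
the test suite. The same index at population level measures stress
intensity. Genetic correlations between systems carry Fisher-transform
confidence intervals, $\hat Z \pm u_{1-\alpha/2}/\sqrt{N_P-3}$,
back-transformed with $\tanh$; the correlated-response ratio is
$r_G\sqrt{H^2_{CF}/H^2_{AWD}}$.

## Kernels and prediction models

The linear kernel is $K = XX'$ on column-centred $\{-1,0,1\}$ codes, not
rescaled by marker count (the model's variance parameter absorbs scale).
The Gaussian kernel is $K(x_i,x_j) = \exp(-h\lVert x_i - x_j\rVert^2)$ on
the same centred codes; an optional flag divides squared distances by their
off-diagonal mean (common practice) and is applied consistently to both
bandwidth estimation and kernel construction. The bandwidth is the mode of
the marginal posterior of $h$: the restricted likelihood profiled over the
genetic/residual variance ratio on a log grid, plus a gamma prior with
shape 3 and scale 1.5 (mode $2 \times 1.5 = 3$; a rate parameterization of
the same prior appears in parts of the literature). When the data carry no
genetic signal the profile is flat in $h$ and the estimate falls back to
the prior mode — a property the tests exercise directly.

Four Bayesian models share one Gibbs engine, sampling in the eigenbasis of
each kernel so genetic-effect updates are diagonal:

* **single-environment** $y = \mu + u + \varepsilon$, $u \sim N(0,
  \sigma_u^2 K)$, for GBLUP or RKHS kernels;
* **extended GBLUP / RKHS-1** $y_{je} = \mu_e + u_{0j} + u_{Ej,e} +
  \varepsilon$: a main marker effect shared across environments plus an
  independent environment-specific effect, with linear or Gaussian kernels;
* **RKHS-2** $y = \mu + u + f + \varepsilon$ with $u \sim N(0, \Sigma_u
  \otimes K)$ — an explicit $m \times m$ genetic covariance between
  environments — and $f \sim N(0, \Sigma_f \otimes I)$ catching genetic
  effects the markers miss.

Numerical choices: variance priors are scaled-inverse-chi-square with 5
degrees of freedom and scale set so the prior mode equals an equal split of
the sample phenotypic variance across the model's random terms; the
covariance priors in RKHS-2 are inverse-Wishart with $m+2$ degrees of
freedom and identity scale. These are declared defaults, chosen as weakly
informative, not values inferred from data. The intercept update in the
single-environment sampler is collapsed (drawn with the genetic effect
integrated out), which removes the strong intercept–genetic-value
autocorrelation; posterior means of genetic values are Rao-Blackwellized.
Missing cells are handled by sampling the missing responses each sweep,
which leaves the posterior over parameters identical to the observed-data
likelihood and keeps all updates conjugate. Kernels are accepted when their
minimum eigenvalue is above $-10^{-8}\,\mathrm{tr}(K)/N$; smaller negative
eigenvalues are an error, and near-zero eigencomponents are fixed at zero.
Default chains are 35,000 iterations with 5,000 burn-in and thinning 10
(3,000 retained samples); convergence is assessed by the Gelman-Rubin
potential scale reduction factor over $\geq 2$ chains (seed offset by chain
index), with a single chain yielding an explicit "diagnostics unavailable"
report.

One identifiability caution, visible in the test suite's design: with one
adjusted mean per genotype and environment, the $f$ term and the residual
in RKHS-2 are confounded (both are i.i.d. per cell), and the
environment-specific genetic signal is separated from noise only through
the kernel structure. The posterior for the environment correlation is
therefore ridge-like and sensitive to the residual prior at small $N$; at
the package's reference scale ($N \approx 300$) recovery is within the
tolerances asserted in the tests.

## Validation designs

`make_partitions` draws 80/20 training/validation splits (227/57 at
$N = 284$). Under M1 the validation genotypes are unobserved everywhere;
under M2 each keeps exactly one observed environment, assigned at random
and balanced within each replicate (the balancing is this package's choice;
it avoids confounding environment with replicate). The same partitions are
reused across models so comparisons are paired. Predictive ability is the
Pearson correlation between predictions and observed adjusted means in the
validation set, per environment; abilities are averaged arithmetically over
replicates (with their SE), and the Fisher Z transform is used only as the
response of the factorial ANOVA stage, which reports the classic table plus
R², CV, RMSE and back-transformed level means.

Across-generation validation trains on S1 (parents only), S2 (a CDmean-
optimized subset, default 100) or S3 (the full reference) and predicts all
progeny. CDmean maximizes the mean coefficient of determination
$CD_i = K_{i,T} M K_{T,i}/K_{ii}$ of predicting non-selected individuals,
with $M$ the mean-adjusted inverse of $K_{T,T} + \lambda I$, by
accept-only-improving single swaps, so the objective trace is
non-decreasing; $\lambda$ defaults to $(1-h^2)/h^2$ at $h^2 = 0.5$ when no
REML estimate is supplied.

## The synthetic generator

The generator emulates the structure the models assume: unlinked biallelic
loci with minor allele frequencies drawn from a configurable range,
genotypes sampled under Hardy-Weinberg proportions generalized by an
inbreeding coefficient (default $F = 0.98$; advanced inbred lines are
nearly homozygous, which is also what keeps simulated panels inside the
heterozygosity < 5% filter), the standard panel filters (MAF > 5%,
heterozygosity < 5%), and phenotypes built from i.i.d. Gaussian marker
effects scaled so the main and environment-specific genetic variances hit
their configured values in expectation. The implied cross-environment
genetic correlation is $\rho = \sigma^2_{main}/(\sigma^2_{main} +
\sigma^2_{env})$. Defaults are 284 genotypes, 2,000 markers, two years,
three replicates, $\rho = 0.8$, and variances on the scale of days-to-
flowering in the reference trial (genetic 57.6, genotype-by-year 10.9,
residual 11.3, year variance about 44), giving entry-mean heritability
near 0.89 — inside the published 0.56–0.94 range for this design.

What the generator does **not** emulate, and what that means for the tests:
there is no linkage disequilibrium, no pedigree structure and no missing
genotypes. Without LD, the effective number of independent markers equals
the marker count, so absolute predictive abilities at desk scale
($n \approx 100$–300 genotypes, a few hundred markers) are substantially
lower than published values from real rice panels — roughly
$\sqrt{h^2\,n/(n+p)}$ for the single-environment baseline. Passing tests
therefore demonstrate the *orderings* and *contracts* (M2 > single ≈ M1,
reductions, calibration of closed-form statistics), not the absolute
ability levels of the original data, which are unreachable without the
real genotypes. The year effect is fixed, mirroring the trial models; the
genotype-by-year deviation is drawn independently per environment, so a
combined-model analysis attributes it mostly to the three-way interaction,
which is consistent with how the per-system models treat it.

## Problem sizes used by the tests and scripts

The test suite runs the closed-form checks instantly; the oracle
equivalences use a 30-genotype instance at full chain length (35,000
iterations); structural reductions use 100 genotypes with 3,000-iteration
chains; parameter recovery uses 10 replicates at $N = 300$ with
5,000-iteration chains; the prediction-gain ordering uses 30 partition
replicates at $N = 120$. The analysis scripts run the full $N = 284$ panel
with 10 partition replicates and 3,000-iteration chains. These sizes are
the package's own desk-scale choices; raising replicate counts and chain
lengths to the full protocol changes runtimes, not code paths.

## Known limitations

* The restricted-likelihood-distance influence diagnostic of the original
  two-stage workflow is replaced by the simple residual screen.
* The RKHS-2 sampler supports two environments (the design it was built
  for); the other models accept any number.
* `heritability()` standard errors are delta-method approximations and
  inherit the usual fragility of variance-component covariances near
  boundaries.
* Genotype imputation is intentionally minimal (rounded marker-mean fill
  after filtering); panels with substantial missingness should be imputed
  upstream.
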
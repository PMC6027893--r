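# gxepredict

Statistical tools for breeding under genotype-by-environment interaction
(G×E) in two-environment trials, built around the water-management contrast
in rice: conventional continuous flooding (CF) versus the water-saving
alternate wetting and drying (AWD) system. The package is aimed at
quantitative geneticists and breeders who need to decide, with data from a
replicated multi-year trial and genome-wide markers, whether selection for
the new environment can ride on phenotyping in the old one — and how much
multi-environment genomic prediction models buy over single-environment
ones.

## What it computes

**Phenotype adjustment.** Per-system REML mixed models
(`Y = µ + year + g + g×year + ε`, year fixed, genotype terms random) give
adjusted means `Ŷ_jm = µ̂_m + ĝ_jm`, variance components, entry-mean
broad-sense heritability

    H² = σ²_g / (σ²_g + σ²_gy/n_y + σ²_e/n_r)

(`n_y`, `n_r` harmonic means of years and plots per genotype), conditional
R², the genetic correlation between systems with a Fisher-transform
confidence interval, and the correlated-response ratio
`CR_CF/DR_AWD = r_G √(H²_CF/H²_AWD)`. A combined two-system model tests the
G×E variance with a boundary-corrected (50:50 χ² mixture)
likelihood-ratio test.

**Response variables.** Per genotype: the relative-performance index
`I_j = (Ŷ_AWD − Ŷ_CF)/Ŷ_CF` and the joint-regression slope β_j of the
genotype's means on the environment indices (mean slope is 1 by
construction). At population level the index measures stress intensity.

**Genomic prediction.** Bayesian kernel regression by Gibbs sampling, with
the linear kernel `K = XX'` (GBLUP) or the Gaussian kernel
`K(x_i,x_j) = exp(−h‖x_i−x_j‖²)` (RKHS; bandwidth `h` estimated as an
empirical-Bayes posterior mode under a gamma(shape 3, scale 1.5) prior).
Multi-environment extensions: a shared-plus-environment-specific marker
effect model (extended GBLUP / RKHS-1) and an explicit environment
covariance model (RKHS-2, `u ~ N(0, Σ_u ⊗ K)`). Default chains: 35,000
iterations, 5,000 burn-in, thinning 10; Gelman-Rubin diagnostics over
multiple chains.

**Validation.** Random 80/20 partitions (227/57 at N = 284) in three
designs — single-environment, M1 (validation genotypes unobserved
everywhere) and M2 (observed in exactly one system) — with Pearson
predictive ability per system, a factorial ANOVA on Fisher-Z-transformed
abilities, and across-generation scenarios S1/S2/S3 (parents only / CDmean-
optimized 100 / full reference panel).

A synthetic trial generator (`sim_config`, `simulate_genotypes`,
`simulate_trial`) reproduces this structure — inbred panels, MAF and
heterozygosity filters, controllable cross-environment genetic correlation
ρ and heritability — so the whole chain is testable without the original
field data.

## Worked example

```r
library(gxepredict)

cfg  <- sim_config(n_genotypes = 120, n_markers = 500, seed = 42)
geno <- simulate_genotypes(cfg)
obs  <- simulate_trial(geno, cfg, trait = "FL")

fit_awd <- fit_single_system(obs, "FL", "AWD")
fit_cf  <- fit_single_system(obs, "FL", "CF")
print(fit_awd$vc)
#> variance components: g = 48.86, g x y = 13.59, residual = 10.35, fixed = 41.1 (total 113.9)
#>   harmonic means: n_y = 2 years, n_r = 6 plots

round(heritability(fit_awd$vc), 2)   #> 0.85
round(conditional_r2(fit_awd$vc), 2) #> 0.91

means   <- rbind(fit_awd$means, fit_cf$means)
profile <- response_profile(means,
                            h2_control = heritability(fit_cf$vc),
                            h2_stress  = heritability(fit_awd$vc))
print(profile)
#> response profile over 120 genotypes
#>   stress intensity: +7.4%
#>   rG = 0.704 [0.600; 0.784]; Spearman rho = 0.700
#>   CR/DR ratio = 0.73

print(fit_combined(obs, "FL"))
#> combined two-system mixed model (REML)
#>   variance components:
#>        g       gm       gy      gmy residual
#>  43.2428  12.1349   1.6663   9.7597  10.8052
#>   genotype x system LRT: statistic = 37.317, p = 5.021e-10 (50:50 chi-square mixture)
```

The simulated panel was configured with ρ = 0.8 and heritability near 0.89;
the fitted heritabilities (0.85, 0.90), the interaction test and the
genetic correlation of the adjusted means (0.70 — attenuated from ρ by the
entry-mean error) recover that structure. Prediction and cross-validation
continue from the adjusted means:

```r
Y <- cbind(CF  = fit_cf$means$value[match(geno$genotype_ids,
                                          fit_cf$means$genotype_id)],
           AWD = fit_awd$means$value[match(geno$genotype_ids,
                                           fit_awd$means$genotype_id)])
rownames(Y) <- geno$genotype_ids
ks  <- kernel_set(geno, phenotype = Y[, "CF"], scale_dist = TRUE)
rec <- run_cv_experiment(Y, ks, models = c("GBLUP", "GBLUP-GxE"),
                         schemes = c("single", "M1", "M2"), n_reps = 10)
summarise_ability(rec)
```

## The analysis workflow

`analysis/` contains the numbered drivers that chain the stages over a
full-size synthetic trial, writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_trial.R` | reference (N = 284) and progeny (N = 97) panels, plot phenotypes, CSV/VCF output |
| `02_adjust_phenotypes.R` | per-system REML, outlier screen, variance-component table, combined-model G×E test |
| `03_response_variables.R` | index, slope, stress intensity, rG with CI |
| `04_crossval_prediction.R` | kernels, single vs M1/M2 cross-validation, Z-ANOVA |
| `05_progeny_validation.R` | S1/S2/S3 scenarios with CDmean training-set optimization |

On the default synthetic trial, stage 4 shows the headline pattern: M2
designs (one system observed) lift predictive ability far above the
single-environment baseline (gains ≈ +0.46 to +0.49 here), while M1
performs on par with it.

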
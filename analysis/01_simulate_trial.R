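#!/usr/bin/env Rscript

# Stage 1 — simulate the two-population, two-system trial.
#
# Generates a reference panel of 284 inbred genotypes and a progeny-style
# panel of 97 genotypes on a common marker set, then plot-level phenotypes
# for two years x three replicates under continuous flooding (CF) and
# alternate wetting and drying (AWD), with a cross-environment genetic
# correlation of 0.8 and entry-mean heritability near 0.89.
#
# Outputs (results/): genotype CSV + VCF, long-format phenotype CSVs,
# and run manifests.

suppressPackageStartupMessages(library(gxepredict))
dir.create("results", showWarnings = FALSE)

seed <- 20260301L

# reference-like panel
cfg_ref <- sim_config(n_genotypes = 284, n_markers = 2000, seed = seed)
geno_ref <- simulate_genotypes(cfg_ref)
obs_ref <- simulate_trial(geno_ref, cfg_ref, trait = "FL")
cat(sprintf("reference panel: %d genotypes x %d markers after filtering\n",
            nrow(geno_ref$codes), ncol(geno_ref$codes)))
cat(sprintf("  plot records: %d; true cross-environment rG: %.3f\n",
            nrow(obs_ref),
            cor(attr(obs_ref, "true_values")[, 1],
                attr(obs_ref, "true_values")[, 2])))

write_genotypes(geno_ref, "results/reference_genotypes.csv", format = "csv")
write_genotypes(geno_ref, "results/reference_genotypes.vcf", format = "vcf")
write_phenotypes(obs_ref, "results/reference_phenotypes.csv")
write_manifest("results/reference_phenotypes.csv",
               list(seed = seed, config = unclass(cfg_ref)))

# progeny-style panel (smaller, same marker density), phenotyped separately
cfg_pp <- sim_config(n_genotypes = 97, n_markers = 2000,
                     var_main = 28, var_env_specific = 7,
                     var_gy = 8, var_residual = 10,
                     env_means = c(CF = 92.9, AWD = 102.8),
                     seed = seed + 1L)
geno_pp <- simulate_genotypes(cfg_pp)
obs_pp <- simulate_trial(geno_pp, cfg_pp, trait = "FL")
cat(sprintf("progeny panel: %d genotypes x %d markers\n",
            nrow(geno_pp$codes), ncol(geno_pp$codes)))

write_genotypes(geno_pp, "results/progeny_genotypes.csv", format = "csv")
write_phenotypes(obs_pp, "results/progeny_phenotypes.csv")
write_manifest("results/progeny_phenotypes.csv",
               list(seed = seed + 1L, config = unclass(cfg_pp)))

cat("stage 1 done: genotypes and phenotypes under results/\n")
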
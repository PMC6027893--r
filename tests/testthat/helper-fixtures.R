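# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small two-environment trial with genotypes, observations, adjusted means
# per system and kernels
small_trial <- function() fixture("small_trial", function() {
  cfg <- sim_config(n_genotypes = 60, n_markers = 300, seed = 11)
  geno <- simulate_genotypes(cfg)
  obs <- simulate_trial(geno, cfg)
  fa <- fit_single_system(obs, "trait", "AWD")
  fc <- fit_single_system(obs, "trait", "CF")
  means <- rbind(fa$means, fc$means)
  tg <- attr(obs, "true_values")
  Y <- cbind(CF = fc$means$value[match(rownames(tg), fc$means$genotype_id)],
             AWD = fa$means$value[match(rownames(tg), fa$means$genotype_id)])
  rownames(Y) <- rownames(tg)
  list(cfg = cfg, geno = geno, obs = obs, fit_awd = fa, fit_cf = fc,
       means = means, Y = Y, true_g = tg, K = linear_kernel(geno))
})

# short-chain sampler spec for unit tests
quick_spec <- function(model = "GBLUP", seed = 1, n_chains = 1)
  model_spec(model, chain = 2000, burnin = 500, thin = 5, seed = seed,
             n_chains = n_chains)

# long-format adjusted-means data frame from a genotype x system matrix
means_df <- function(Y, trait = "trait") {
  if (is.null(rownames(Y))) rownames(Y) <- paste0("G", seq_len(nrow(Y)))
  data.frame(genotype_id = rep(rownames(Y), ncol(Y)),
             system = rep(colnames(Y), each = nrow(Y)),
             trait = trait, value = as.vector(Y),
             stringsAsFactors = FALSE)
}
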
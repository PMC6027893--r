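# Validation designs: partitions, predictive ability, Z-ANOVA, CDmean and
# progeny scenarios.

test_that("partitions have the declared sizes, disjointness and M2 semantics", {
  pop <- paste0("G", 1:284)
  plans <- make_partitions(pop, fraction = 0.8, n_reps = 5, scheme = "M2",
                           environments = c("CF", "AWD"), seed = 4)
  p <- plans[[1]]
  expect_length(p$training, 227)
  expect_length(p$validation, 57)
  expect_length(intersect(p$training, p$validation), 0)
  expect_setequal(c(p$training, p$validation), pop)
  # every validation genotype observed in exactly one environment, balanced
  expect_setequal(names(p$observed_env), p$validation)
  tab <- table(p$observed_env)
  expect_lte(abs(tab[["CF"]] - tab[["AWD"]]), 1)

  plans2 <- make_partitions(pop, fraction = 0.8, n_reps = 5, scheme = "M2",
                            environments = c("CF", "AWD"), seed = 4)
  expect_identical(plans[[3]]$training, plans2[[3]]$training)

  expect_error(make_partitions(pop, fraction = 1.2), "fraction")
  expect_error(make_partitions(pop[1:3]), "small")
})

test_that("predictive ability matches the textbook Pearson formula", {
  expect_equal(predictive_ability(1:5, 1:5)$r, 1)
  expect_equal(predictive_ability(1:5, -(1:5))$r, -1)

  p <- c(1.2, 0.7, 2.5, 3.1, 2.0)
  o <- c(0.8, 1.1, 2.2, 2.9, 1.4)
  manual <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  expect_equal(predictive_ability(p, o)$r, manual)

  expect_warning(r0 <- predictive_ability(rep(1, 5), o)$r, "zero variance")
  expect_true(is.na(r0))
  strat <- predictive_ability(c(p, p), c(o, rev(o)),
                              strata = rep(c("a", "b"), each = 5))
  expect_identical(nrow(strat), 2L)
  expect_equal(strat$r[strat$stratum == "a"], manual)
})

test_that("Z-ANOVA reproduces a hand-computed one-factor decomposition", {
  z <- c(1.0, 1.2, 0.8, 1.1, 2.0, 2.2, 1.8, 2.1)
  d <- data.frame(Z = z, model = rep(c("A", "B"), each = 4))
  an <- zstat_anova(d, "model")
  # hand computation: SS_model = n/2 * sum((group mean - grand mean)^2) * 2
  gm <- mean(z)
  ss_model <- 4 * sum((tapply(z, d$model, mean) - gm)^2)
  ss_tot <- sum((z - gm)^2)
  tab <- an$table
  expect_equal(tab$SS[tab$Source == "model"], ss_model)
  expect_equal(an$r2 + tab$SS[tab$Source == "Residuals"] / ss_tot, 1)
  expect_equal(unname(an$level_means$model),
               unname(tanh(tapply(z, d$model, mean))))

  # identical response: all factor SS vanish
  d0 <- data.frame(Z = rep(1.5, 8), model = rep(c("A", "B"), each = 4))
  an0 <- suppressWarnings(zstat_anova(d0, "model"))  # perfect-fit ANOVA
  expect_lt(an0$table$SS[an0$table$Source == "model"], 1e-20)

  expect_error(zstat_anova(data.frame(Z = 1:4, f = "x"), "f"), "levels")
})

test_that("CDmean exchange optimization is monotone and beats random sets", {
  set.seed(8)
  X <- matrix(sample(c(-1, 0, 1), 150 * 200, TRUE), 150, 200)
  K <- linear_kernel(X)
  rownames(K) <- colnames(K) <- paste0("G", 1:150)
  K <- K / mean(diag(K))

  sel <- cdmean_select(K, target_size = 40, n_iter = 300, seed = 2)
  expect_length(sel, 40)
  trace <- attr(sel, "trace")
  expect_true(all(diff(trace) >= 0))

  # Monte-Carlo baseline: 200 random same-size sets
  lambda <- 1    # (1 - 0.5) / 0.5, the selector's default
  cd_of <- function(ids) {
    A <- K[ids, ids] + lambda * diag(length(ids))
    Ai <- solve(A)
    a1 <- rowSums(Ai)
    M <- Ai - outer(a1, a1) / sum(a1)
    out <- setdiff(rownames(K), ids)
    Kot <- K[out, ids]
    mean(rowSums((Kot %*% M) * Kot) / diag(K)[out])
  }
  expect_equal(cd_of(sel), attr(sel, "cdmean"), tolerance = 1e-10)
  set.seed(99)
  rand <- replicate(200, cd_of(sample(rownames(K), 40)))
  expect_gte(attr(sel, "cdmean"), quantile(rand, 0.95))

  expect_warning(all_sel <- cdmean_select(K, target_size = 150), "full set")
  expect_length(all_sel, 150)
})

test_that("cross-validation records are paired across models and counted", {
  tr <- small_trial()
  ks <- kernel_set(tr$geno, h = 0.002)
  rec <- run_cv_experiment(tr$Y, ks, models = c("GBLUP", "GBLUP-GxE"),
                           schemes = c("single", "M2"), n_reps = 2,
                           spec = model_spec(chain = 600, burnin = 100,
                                             thin = 5), seed = 3)
  # single scheme: GBLUP + GBLUP-GxE, 2 envs each; M2: GBLUP-GxE only
  expect_setequal(unique(rec$model), c("GBLUP", "GBLUP-GxE"))
  expect_true(all(rec$r >= -1 & rec$r <= 1))
  expect_equal(rec$Z, atanh(rec$r))
  # pairing: same replicate ids appear for every model within a scheme
  sub <- rec[rec$scheme == "single", ]
  expect_identical(sort(unique(sub$replicate[sub$model == "GBLUP"])),
                   sort(unique(sub$replicate[sub$model == "GBLUP-GxE"])))
  sm <- summarise_ability(rec)
  expect_true(all(c("mean_r", "se_r", "n") %in% names(sm)))
})

test_that("progeny scenarios control training composition and relatedness drives accuracy", {
  cfg <- sim_config(n_genotypes = 80, n_markers = 250, seed = 17)
  geno <- simulate_genotypes(cfg)
  obs <- simulate_trial(geno, cfg)
  fa <- fit_single_system(obs, "trait", "AWD")$means
  fc <- fit_single_system(obs, "trait", "CF")$means
  Y <- cbind(CF = fc$value[match(geno$genotype_ids, fc$genotype_id)],
             AWD = fa$value[match(geno$genotype_ids, fa$genotype_id)])
  rownames(Y) <- geno$genotype_ids

  # "progeny" = relabelled subset of the reference (perfect relatedness)
  prog_ids <- geno$genotype_ids[61:80]
  ref_ids <- geno$genotype_ids[1:60]
  Y_ref <- Y[ref_ids, ]
  Y_prog <- Y[prog_ids, ]
  ks <- kernel_set(geno, h = 0.002)
  sp <- model_spec(chain = 1500, burnin = 300, thin = 5, seed = 5)

  r3 <- run_progeny_validation(Y_ref, Y_prog, ks, scenario = "S3",
                               models = "GBLUP", spec = sp)
  expect_identical(unique(r3$n_train), 60L)
  expect_gt(mean(r3$r), 0.3)

  r2 <- run_progeny_validation(Y_ref, Y_prog, ks, scenario = "S2",
                               models = "GBLUP", spec = sp, s2_size = 30)
  expect_identical(unique(r2$n_train), 30L)

  # unrelated "parents": scrambling marker columns destroys relatedness
  set.seed(18)
  scrambled <- apply(geno$codes[ref_ids[1:20], ], 2, sample)
  codes_all <- rbind(scrambled, geno$codes[prog_ids, ])
  rownames(codes_all) <- c(paste0("P", 1:20), prog_ids)
  ks_u <- kernel_set(genotype_matrix(codes_all), h = 0.002)
  Y_ref_u <- Y[ref_ids[1:20], ]
  rownames(Y_ref_u) <- paste0("P", 1:20)
  r1 <- run_progeny_validation(Y_ref_u, Y_prog, ks_u, scenario = "S1",
                               parents = paste0("P", 1:20),
                               models = "GBLUP", spec = sp)
  expect_identical(unique(r1$n_train), 20L)
  expect_lt(mean(abs(r1$r)), 0.35)
})
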
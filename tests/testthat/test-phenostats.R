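# Mixed-model adjustment: REML components, adjusted means, heritability,
# conditional R2, the genotype-by-system test and the outlier screen.

test_that("noise-free balanced data is fitted exactly", {
  set.seed(2)
  n_g <- 12
  g <- rnorm(n_g, 0, 3)
  d <- expand.grid(genotype_id = paste0("g", seq_len(n_g)),
                   environment = "E1", year = c("Y1", "Y2"),
                   replicate = 1:3, stringsAsFactors = FALSE)
  d$trait <- "t"
  d$value <- 50 + ifelse(d$year == "Y2", 2, 0) +
    g[match(d$genotype_id, paste0("g", seq_len(n_g)))] +
    rnorm(nrow(d), 0, 1e-5)
  class(d) <- c("trial_observations", "data.frame")
  fit <- suppressWarnings(fit_single_system(d, "t", "E1"))  # near-zero residual
  expect_lt(fit$vc$sigma2_e, 1e-6)
  truth <- 51 + g   # system mean (years averaged) plus genotype value
  est <- fit$means$value[match(paste0("g", seq_len(n_g)),
                               fit$means$genotype_id)]
  expect_equal(est, truth, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("REML solution matches a brute-force restricted-likelihood grid", {
  d <- make_toy_obs(5, years = 2, reps = 2, sg = 2, sgy = 1, se = 0.7,
                    seed = 4)
  d$genotype_id <- factor(d$genotype_id); d$year <- factor(d$year)
  fit <- fit_single_system(d, "t", "E1")
  est <- c(fit$vc$sigma2_g, fit$vc$sigma2_gy, fit$vc$sigma2_e)
  expect_equal(est, reml_grid_argmax(d, est), tolerance = 1e-3)
})

test_that("REML recovers components simulated at the reference-trial scale", {
  set.seed(31)
  truth <- c(g = 57.68, gy = 10.90, e = 11.28)
  n_g <- 284
  g <- rnorm(n_g, 0, sqrt(truth["g"]))
  d <- expand.grid(genotype_id = paste0("g", seq_len(n_g)),
                   environment = "AWD", year = c("Y1", "Y2"),
                   replicate = 1:3, stringsAsFactors = FALSE)
  gy <- matrix(rnorm(n_g * 2, 0, sqrt(truth["gy"])), n_g, 2)
  gi <- match(d$genotype_id, paste0("g", seq_len(n_g)))
  yi <- as.integer(d$year == "Y2") + 1L
  d$trait <- "t"
  d$value <- 100 + c(-6.6, 6.6)[yi] + g[gi] + gy[cbind(gi, yi)] +
    rnorm(nrow(d), 0, sqrt(truth["e"]))
  class(d) <- c("trial_observations", "data.frame")
  fit <- fit_single_system(d, "t", "AWD")
  expect_equal(fit$vc$sigma2_g, 57.68, tolerance = 0.15)
  expect_equal(fit$vc$sigma2_gy, 10.90, tolerance = 0.15)
  expect_equal(fit$vc$sigma2_e, 11.28, tolerance = 0.15)
  expect_equal(fit$vc$n_y, 2)
  expect_equal(fit$vc$n_r, 6)
})

test_that("heritability and conditional R2 reproduce published-scale arithmetic", {
  vc1 <- variance_components(57.68, 10.90, 11.28, fixed_var = 44.12,
                             n_y = 2, n_r = 6)
  expect_equal(round(heritability(vc1), 2), 0.89)
  expect_equal(round(conditional_r2(vc1), 2), 0.91)

  vc2 <- variance_components(4.12, 0.70, 3.72, n_y = 2, n_r = 6)
  expect_equal(round(heritability(vc2), 4), 0.8094)

  vc3 <- variance_components(27.97 + 0, 23.20, 7.38)  # smoke for total
  expect_error(heritability(variance_components(0, 0, 0)), "undefined")
  expect_equal(heritability(variance_components(3, 0, 0)), 1)
  expect_equal(conditional_r2(variance_components(5, 2, 0, fixed_var = 1)), 1)
})

test_that("conditional R2 reproduces the progeny continuous-flooding value", {
  vc <- variance_components(23.20, 7.38, 2.27, fixed_var = 27.97,
                            n_y = 2, n_r = 6)
  expect_equal(round(conditional_r2(vc), 2), 0.96)
})

test_that("REML components are invariant to a constant phenotype shift", {
  d <- make_toy_obs(15, seed = 6)
  f1 <- fit_single_system(d, "t", "E1")
  d2 <- d; d2$value <- d2$value + 1000
  f2 <- fit_single_system(d2, "t", "E1")
  expect_equal(f1$vc$sigma2_g, f2$vc$sigma2_g, tolerance = 1e-5)
  expect_equal(f1$vc$sigma2_e, f2$vc$sigma2_e, tolerance = 1e-5)
  expect_equal(f2$mu - f1$mu, 1000, tolerance = 1e-5)
})

test_that("BLUP shrinkage keeps the regression of means on truth at most 1", {
  tr <- small_trial()
  truth <- tr$true_g[, "AWD"]
  est <- tr$fit_awd$means$value[match(names(truth),
                                      tr$fit_awd$means$genotype_id)]
  slope <- coef(lm(est ~ truth))[2]
  expect_lte(slope, 1 + 0.05)
  expect_gt(slope, 0.7)    # high heritability: little shrinkage
})

test_that("duplicating one system as the other gives exactly zero gxm variance", {
  d <- make_toy_obs(10, seed = 8)
  d2 <- d; d2$environment <- "E2"
  both <- rbind(d, d2)
  class(both) <- c("trial_observations", "data.frame")
  fit <- fit_combined(both, "t")
  expect_lt(fit$vc["gm"], 1e-8)
  expect_gt(fit$lrt["p_value"], 0.5)
})

test_that("the gxm likelihood-ratio test detects interaction when present and not otherwise", {
  pvals_null <- vapply(1:10, function(r) {
    cfg <- sim_config(n_genotypes = 40, n_markers = 150, var_main = 60,
                      var_env_specific = 0, seed = 300 + r)
    obs <- simulate_trial(simulate_genotypes(cfg), cfg)
    fit_combined(obs, "trait")$lrt[["p_value"]]
  }, numeric(1))
  pvals_alt <- vapply(1:10, function(r) {
    cfg <- sim_config(n_genotypes = 40, n_markers = 150, var_main = 40,
                      var_env_specific = 20, seed = 200 + r)
    obs <- simulate_trial(simulate_genotypes(cfg), cfg)
    fit_combined(obs, "trait")$lrt[["p_value"]]
  }, numeric(1))
  expect_gte(mean(pvals_null > 0.05), 0.9)
  expect_gte(mean(pvals_alt < 0.05), 0.9)
})

test_that("the outlier screen flags a spiked record and nothing on clean data", {
  tr <- small_trial()
  obs <- tr$obs
  flagged <- screen_outliers(obs, "trait", threshold = 4)
  expect_lt(mean(flagged$outlier), 0.005)

  spiked <- obs
  sd_tot <- sd(spiked$value)
  spiked$value[17] <- spiked$value[17] + 10 * sd_tot
  out <- screen_outliers(spiked, "trait", threshold = 4)
  expect_true(out$outlier[17])

  inf <- screen_outliers(spiked, "trait", threshold = Inf, remove = TRUE)
  expect_identical(nrow(inf), nrow(spiked))
})
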
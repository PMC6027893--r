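# Gibbs samplers: chain contract, oracle equivalences at reduced scale,
# structural degeneracies, invariances and convergence diagnostics.

test_that("the chain/burn-in/thin contract is honoured exactly", {
  sp <- model_spec("GBLUP")
  expect_equal(sp$retained, 3000L)
  expect_error(model_spec(chain = 100, burnin = 200), "chain > burnin")

  tr <- small_trial()
  y <- tr$Y[, "AWD"]
  f <- fit_single_env(tr$K, y, model_spec("GBLUP", chain = 230, burnin = 30,
                                          thin = 10, seed = 2))
  expect_identical(nrow(f$samples[[1]]), 20L)
})

test_that("constant phenotypes and non-PSD kernels are rejected", {
  tr <- small_trial()
  expect_error(fit_single_env(tr$K, rep(1, nrow(tr$K)), quick_spec()),
               "variance")
  bad <- tr$K
  bad[1, 2] <- bad[1, 2] + 100   # break symmetry
  expect_error(fit_single_env(bad, tr$Y[, "AWD"], quick_spec()),
               "symmetric")
  n <- nrow(tr$K)
  notpsd <- diag(n); notpsd[1, 2] <- notpsd[2, 1] <- 2
  dimnames(notpsd) <- dimnames(tr$K)
  expect_error(fit_single_env(notpsd, tr$Y[, "AWD"], quick_spec()),
               "positive semi-definite")
})

test_that("with fixed variances the posterior mean matches closed-form BLUP", {
  tr <- small_trial()
  n <- 30
  K <- tr$K[1:n, 1:n]
  y <- tr$Y[1:n, "AWD"]
  su2 <- 40; se2 <- 10
  f <- fit_single_env(K, y, model_spec("GBLUP", chain = 6000, burnin = 1000,
                                       thin = 5, seed = 3),
                      fix = list(sigma2_u = su2, sigma2_e = se2))
  # mixed-model oracle with the same variances, intercept profiled by GLS
  V <- su2 * K + se2 * diag(n)
  Vi <- solve(V)
  mu <- drop(crossprod(rep(1, n), Vi %*% y) / sum(Vi))
  u_blup <- drop(su2 * K %*% Vi %*% (y - mu))
  expect_lt(max(abs(f$u_mean - u_blup)), 0.05 * sd(y))
})

test_that("phenotype shifts move intercepts, not genetic values", {
  tr <- small_trial()
  y <- tr$Y[, "AWD"]
  sp <- quick_spec(seed = 5)
  f1 <- fit_single_env(tr$K, y, sp)
  f2 <- fit_single_env(tr$K, y + 500, sp)
  expect_equal(f2$components$mu - f1$components$mu, 500, tolerance = 1e-6)
  expect_equal(f1$u_mean, f2$u_mean, tolerance = 1e-6)
})

test_that("unobserved genotypes are predicted like the closed-form mixed model", {
  tr <- small_trial()
  y <- tr$Y[, "AWD"]
  y[1:12] <- NA
  f <- fit_single_env(tr$K, y, quick_spec(seed = 7))
  pr <- f$predictions
  expect_identical(sum(!pr$observed), 12L)

  # oracle: BLUP from the observed subset at the sampler's posterior-mean
  # variances; the Gibbs predictions must track it closely
  su2 <- f$components$sigma2_u; se2 <- f$components$sigma2_e
  o <- !is.na(y)
  V <- su2 * tr$K[o, o] + se2 * diag(sum(o))
  Vi <- solve(V)
  mu <- drop(crossprod(rep(1, sum(o)), Vi %*% y[o]) / sum(Vi))
  blup_all <- drop(su2 * tr$K[, o] %*% Vi %*% (y[o] - mu))
  expect_gt(cor(pr$pred[1:12], mu + blup_all[1:12]), 0.98)
  expect_lt(mean(abs(pr$pred[1:12] - (mu + blup_all[1:12]))),
            0.1 * sd(y, na.rm = TRUE))
  # and carries real signal on this high-heritability trait
  expect_gt(cor(pr$pred[1:12], tr$Y[1:12, "AWD"]), 0)
})

test_that("GxE model reductions behave structurally", {
  tr <- small_trial()
  Y <- tr$Y
  sp <- quick_spec(seed = 11)
  # no environment-specific term: identical rankings across environments
  f0 <- fit_gblup_gxe(tr$K, Y, sp, fix = list(sigma2_uE = 0))
  P <- matrix(f0$predictions$pred, nrow(Y), 2)
  centred <- sweep(P, 2, colMeans(P))
  expect_equal(centred[, 1], centred[, 2], tolerance = 1e-8)
  expect_equal(f0$components$sigma2_uE, c(0, 0), ignore_attr = TRUE)

  # no shared term: per-environment predictions match independent fits
  f1 <- fit_gblup_gxe(tr$K, Y, quick_spec(seed = 12),
                      fix = list(sigma2_u0 = 0))
  P1 <- matrix(f1$predictions$pred, nrow(Y), 2,
               dimnames = list(rownames(Y), colnames(Y)))
  for (e in colnames(Y)) {
    fe <- fit_single_env(tr$K, Y[, e], quick_spec(seed = 12))
    expect_gt(cor(P1[, e], fe$predictions$pred), 0.98)
    expect_lt(mean(abs(P1[, e] - fe$predictions$pred)), 0.1 * sd(Y[, e]))
  }
})

test_that("an environment without observations fails by name", {
  tr <- small_trial()
  Y <- tr$Y
  Y[, "AWD"] <- NA
  expect_error(fit_gblup_gxe(tr$K, Y, quick_spec()), "AWD")
})

test_that("duplicate environments drive the environment-specific variance to zero", {
  tr <- small_trial()
  Y <- cbind(E1 = tr$Y[, "CF"], E2 = tr$Y[, "CF"])
  f <- fit_rkhs1(tr$K / mean(diag(tr$K)), Y, quick_spec(seed = 13))
  expect_lt(mean(f$components$sigma2_uE), f$components$sigma2_u0 * 0.2)
})

test_that("with all genetic variances fixed at zero predictions are the intercepts", {
  tr <- small_trial()
  f <- fit_gblup_gxe(tr$K, tr$Y, quick_spec(seed = 14),
                     fix = list(sigma2_u0 = 0, sigma2_uE = 0))
  P <- matrix(f$predictions$pred, nrow(tr$Y), 2)
  expect_equal(P[, 1], rep(f$components$mu[1], nrow(P)),
               tolerance = 0.02 * sd(tr$Y), ignore_attr = TRUE)
  expect_equal(P[, 2], rep(f$components$mu[2], nrow(P)),
               tolerance = 0.02 * sd(tr$Y), ignore_attr = TRUE)
})

test_that("the environment-covariance model recovers exchanged environments", {
  tr <- small_trial()
  K <- tr$K / mean(diag(tr$K))
  sp <- model_spec("RKHS-2", chain = 3000, burnin = 500, thin = 5, seed = 15)
  f12 <- fit_rkhs2(K, tr$Y, sp)
  f21 <- fit_rkhs2(K, tr$Y[, c("AWD", "CF")], sp)
  P12 <- matrix(f12$predictions$pred, nrow(tr$Y), 2)
  P21 <- matrix(f21$predictions$pred, nrow(tr$Y), 2)
  expect_equal(P12[, 1], P21[, 2], tolerance = 0.05)
  expect_equal(P12[, 2], P21[, 1], tolerance = 0.05)
  expect_equal(f12$components$env_correlation[1, 2],
               f21$components$env_correlation[1, 2], tolerance = 0.1)
})

test_that("a diagonal environment covariance matches independent fits", {
  tr <- small_trial()
  K <- tr$K / mean(diag(tr$K))
  f <- fit_rkhs2(K, tr$Y, model_spec("RKHS-2", chain = 3000, burnin = 500,
                                     thin = 5, seed = 16),
                 constrain = "diagonal")
  P <- matrix(f$predictions$pred, nrow(tr$Y), 2,
              dimnames = list(rownames(tr$Y), colnames(tr$Y)))
  for (e in colnames(tr$Y)) {
    fe <- fit_single_env(K, tr$Y[, e], quick_spec(seed = 16))
    expect_gt(cor(P[, e], fe$predictions$pred), 0.97)
  }
})

test_that("Gelman-Rubin diagnostics behave across chain regimes", {
  tr <- small_trial()
  y <- tr$Y[, "AWD"]

  f1 <- fit_single_env(tr$K, y, quick_spec(seed = 1, n_chains = 1))
  rep1 <- check_convergence(f1)
  expect_false(rep1$available)
  expect_match(rep1$message, "unavailable")

  # identical chains (same seed): PSRF is 1 up to the finite-sample factor
  f_same <- fit_single_env(tr$K, y, quick_spec(seed = 2, n_chains = 1))
  f_same2 <- f_same
  f_same2$samples <- c(f_same$samples, f_same$samples)
  rep_same <- check_convergence(f_same2)
  # identical chains: PSRF = sqrt((n-1)/n), i.e. 1 up to the finite-sample
  # factor of the retained-sample count
  expect_true(all(abs(rep_same$psrf - 1) < 1 / rep_same$n_retained))

  # well-mixed chains: all PSRF < 1.1
  f2 <- fit_single_env(tr$K, y, model_spec("GBLUP", chain = 7000,
                                           burnin = 1000, thin = 2,
                                           seed = 3, n_chains = 2))
  rep2 <- check_convergence(f2)
  expect_true(rep2$available)
  expect_true(all(rep2$psrf < 1.1))
  expect_length(rep2$flagged, 0)
  # cross-check the PSRF computation against coda on the same chains
  ml <- coda::mcmc.list(lapply(f2$samples, coda::mcmc))
  gd <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)
  expect_equal(unname(rep2$psrf), unname(gd$psrf[, 1]), tolerance = 0.02)

  # deliberately short chains on a weakly identified posterior: flagged
  f3 <- fit_rkhs2(tr$K[1:30, 1:30] / mean(diag(tr$K)), tr$Y[1:30, ],
                  model_spec("RKHS-2", chain = 100, burnin = 10, thin = 1,
                             seed = 1, n_chains = 2))
  rep3 <- check_convergence(f3)
  expect_gt(max(rep3$psrf, na.rm = TRUE), 1.1)
  expect_gt(length(rep3$flagged), 0)
})
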
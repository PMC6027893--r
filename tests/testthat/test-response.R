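# Response variables: index, stress intensity, joint regression, Fisher
# intervals and correlated-response ratios.

test_that("relative-performance index follows its definition", {
  Y <- cbind(CF = c(100, 50, 80), AWD = c(90, 50, 100))
  rownames(Y) <- c("a", "b", "c")
  idx <- response_index(means_df(Y))
  expect_equal(idx$index[idx$genotype_id == "a"], -0.10)
  expect_equal(idx$index[idx$genotype_id == "b"], 0)
  expect_equal(idx$index[idx$genotype_id == "c"], 0.25)
})

test_that("near-zero control means are excluded with a warning", {
  Y <- cbind(CF = c(100, 1e-12, 90), AWD = c(90, 5, 80))
  rownames(Y) <- c("a", "b", "c")
  expect_warning(idx <- response_index(means_df(Y)), "near-zero")
  expect_identical(nrow(idx), 2L)
})

test_that("population stress intensity reproduces the flowering-time case", {
  # population means 100.3 under AWD vs 93.4 under CF: +7.4%
  Y <- cbind(CF = c(93.4, 93.4), AWD = c(100.3, 100.3))
  rownames(Y) <- c("a", "b")
  expect_equal(round(100 * population_stress_intensity(means_df(Y)), 1), 7.4)
  expect_equal(population_stress_intensity(means_df(cbind(
    CF = c(10, 20), AWD = c(10, 20)))), 0)
})

test_that("a simulated 20% depression is recovered at population level", {
  cfg <- sim_config(n_genotypes = 200, n_markers = 150,
                    env_means = c(CF = 100, AWD = 80), seed = 21)
  obs <- simulate_trial(simulate_genotypes(cfg), cfg)
  fa <- fit_single_system(obs, "trait", "AWD")
  fc <- fit_single_system(obs, "trait", "CF")
  I <- population_stress_intensity(rbind(fa$means, fc$means))
  expect_equal(I, -0.20, tolerance = 0.05)
})

test_that("joint regression is definitional with two environments and mean slope 1", {
  tr <- small_trial()
  jr <- joint_regression(tr$means)
  expect_equal(mean(jr$slope), 1, tolerance = 1e-10)

  theta <- attr(jr, "theta")
  # two-point formula equals a generic least-squares fit per genotype
  set.seed(3)
  pick <- sample(jr$genotype_id, 10)
  for (g in pick) {
    yv <- tr$Y[g, names(theta)]
    ls <- coef(lm(yv ~ theta))
    expect_equal(jr$slope[jr$genotype_id == g], unname(ls[2]),
                 tolerance = 1e-10)
    expect_equal(jr$intercept[jr$genotype_id == g], unname(ls[1]),
                 tolerance = 1e-8)
  }
  # residuals are exactly zero with two environments
  g1 <- jr$genotype_id[1]
  fitv <- jr$intercept[1] + jr$slope[1] * theta
  expect_equal(unname(fitv), unname(tr$Y[g1, names(theta)]),
               tolerance = 1e-10)
})

test_that("slope degenerate cases behave as defined", {
  Y <- cbind(CF = c(10, 20, 15), AWD = c(12, 22, 17))
  rownames(Y) <- c("a", "b", "c")
  # a genotype equal to the environment means (adding the mean row leaves
  # the environment indices unchanged) has slope exactly 1
  Ym <- rbind(Y, d = colMeans(Y))
  jr <- joint_regression(means_df(Ym))
  expect_equal(jr$slope[jr$genotype_id == "d"], 1, tolerance = 1e-10)
  # constant genotype: slope 0
  Yc <- rbind(Y, e = c(15, 15))
  jr2 <- joint_regression(means_df(Yc))
  expect_equal(jr2$slope[jr2$genotype_id == "e"], 0, tolerance = 1e-10)
  # identical environment indices: failure
  Yeq <- cbind(CF = c(10, 20), AWD = c(12, 18))
  rownames(Yeq) <- c("a", "b")
  expect_error(joint_regression(means_df(Yeq)), "identical")
})

test_that("Fisher intervals reproduce published reference and progeny bounds", {
  ci1 <- fisher_ci(0.955, 284)
  expect_equal(round(unname(ci1["lower"]), 3), 0.943)
  expect_equal(round(unname(ci1["upper"]), 3), 0.964)

  ci2 <- fisher_ci(0.731, 97)
  expect_equal(round(unname(ci2["lower"]), 3), 0.622)
  expect_equal(round(unname(ci2["upper"]), 3), 0.812)

  ci0 <- fisher_ci(0, 50)
  expect_equal(unname(ci0["lower"]), -unname(ci0["upper"]))
  expect_error(fisher_ci(1, 50), "degenerate")
  expect_error(fisher_ci(0.5, 3), "n > 3")
})

test_that("genetic correlation CI wraps the adjusted means and contains rG", {
  tr <- small_trial()
  ci <- genetic_correlation_ci(tr$means)
  expect_true(ci["lower"] < ci["r"] && ci["r"] < ci["upper"])
  expect_true(all(abs(ci) < 1))
  expect_equal(attr(ci, "n"), nrow(tr$Y))
})

test_that("correlated-response ratios match published arithmetic", {
  expect_equal(round(correlated_response_ratio(0.773, 0.85, 0.76), 2), 0.82)
  expect_equal(round(correlated_response_ratio(0.848, 0.90, 0.88), 2), 0.86)
  expect_equal(correlated_response_ratio(1, 0.8, 0.8), 1)
  expect_error(correlated_response_ratio(0.5, 0.8, 0), "> 0")
})

test_that("the assembled response profile is internally consistent", {
  tr <- small_trial()
  rp <- response_profile(tr$means, h2_control = 0.9, h2_stress = 0.87)
  expect_equal(mean(rp$per_genotype$slope), 1, tolerance = 1e-10)
  expect_equal(rp$rG[["r"]],
               cor(tr$Y[, "AWD"], tr$Y[, "CF"]), tolerance = 1e-10)
  expect_equal(rp$cr_dr,
               rp$rG[["r"]] * sqrt(0.9 / 0.87), tolerance = 1e-10)
  # with two environments the slope is a linear function of the AWD-CF gap
  gap <- tr$Y[rp$per_genotype$genotype_id, "AWD"] -
    tr$Y[rp$per_genotype$genotype_id, "CF"]
  expect_equal(abs(cor(rp$per_genotype$slope, gap)), 1, tolerance = 1e-10)
})
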
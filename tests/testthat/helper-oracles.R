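# Independent oracles shared across test files.

# Restricted log-likelihood of the per-system model, computed densely from
# the full covariance matrix (independent of the package's REML engine).
reml_oracle_loglik <- function(d, sg2, sgy2, se2) {
  X <- model.matrix(~ year, d)
  Zg <- model.matrix(~ 0 + genotype_id, d)
  Zgy <- model.matrix(~ 0 + genotype_id:year, d)
  V <- sg2 * tcrossprod(Zg) + sgy2 * tcrossprod(Zgy) + se2 * diag(nrow(d))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% d$value)
  r <- d$value - X %*% beta
  -0.5 * (determinant(V)$modulus[1] + determinant(XtViX)$modulus[1] +
            drop(t(r) %*% Vi %*% r))
}

# nested grid maximization of the restricted likelihood around a start point
reml_grid_argmax <- function(d, start, stages = 5, points = 9) {
  centre <- pmax(start, 0.05)
  width <- 1
  for (stage in seq_len(stages)) {
    grid <- expand.grid(
      sg2 = centre[1] * seq(1 - width, 1 + width, length.out = points),
      sgy2 = centre[2] * seq(1 - width, 1 + width, length.out = points),
      se2 = centre[3] * seq(1 - width, 1 + width, length.out = points))
    grid <- grid[grid$sg2 > 0 & grid$sgy2 > 0 & grid$se2 > 0, ]
    ll <- mapply(function(a, b, c) reml_oracle_loglik(d, a, b, c),
                 grid$sg2, grid$sgy2, grid$se2)
    centre <- unlist(grid[which.max(ll), ])
    width <- width / 4
  }
  unname(centre)
}

# balanced single-system toy trial with known variance components
make_toy_obs <- function(n_g, years = 2, reps = 2, sg = 2, sgy = 1, se = 0.7,
                         seed = 1) {
  set.seed(seed)
  g <- rnorm(n_g, 0, sg)
  d <- expand.grid(genotype_id = paste0("g", seq_len(n_g)),
                   environment = "E1", year = paste0("Y", seq_len(years)),
                   replicate = seq_len(reps), stringsAsFactors = FALSE)
  gy <- matrix(rnorm(n_g * years, 0, sgy), n_g, years)
  gi <- match(d$genotype_id, paste0("g", seq_len(n_g)))
  yi <- match(d$year, paste0("Y", seq_len(years)))
  d$trait <- "t"
  d$value <- 10 + c(0, 1.5)[yi] + g[gi] + gy[cbind(gi, yi)] +
    rnorm(nrow(d), 0, se)
  structure(d, class = c("trial_observations", "data.frame"),
            true_g = g)
}
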
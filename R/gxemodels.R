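# Bayesian kernel regression by Gibbs sampling: single-environment GBLUP /
# RKHS and three multi-environment extensions (shared + environment-specific
# genetic effects with linear or Gaussian kernels, and an
# environment-covariance model). Sampling is done in the eigenbasis of each
# kernel so every genetic-effect update is diagonal (or a small m x m solve).

#' Sampler specification for the Gibbs models
#'
#' Defaults follow the long-chain convention used for this class of models:
#' 35,000 iterations, 5,000 burn-in, thinning 10, retaining 3,000 samples.
#'
#' @param model One of `"GBLUP"`, `"RKHS"`, `"GBLUP-GxE"`, `"RKHS-1"`,
#'   `"RKHS-2"`.
#' @param chain Total Gibbs iterations.
#' @param burnin Discarded initial iterations.
#' @param thin Keep one sample in `thin` after burn-in.
#' @param seed Integer seed; chain `k` uses `seed + k - 1`.
#' @param n_chains Number of chains (>= 2 enables Gelman-Rubin diagnostics).
#' @param prior_df Degrees of freedom of the scaled-inverse-chi-square
#'   variance priors (default 5); prior scales are set so the prior mode
#'   equals an equal split of the sample phenotypic variance across the
#'   model's random terms.
#' @return A `model_spec` object; `retained` gives the per-chain retained
#'   sample count.
#' @export
model_spec <- function(model = "GBLUP", chain = 35000L, burnin = 5000L,
                       thin = 10L, seed = 1L, n_chains = 1L, prior_df = 5) {
  model <- match.arg(model,
                     c("GBLUP", "RKHS", "GBLUP-GxE", "RKHS-1", "RKHS-2"))
  stopifnot(chain > burnin, thin >= 1, n_chains >= 1, prior_df > 0)
  retained <- (chain - burnin) %/% thin
  if (retained < 1) stop("no retained samples under these chain settings")
  structure(list(model = model, chain = as.integer(chain),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), n_chains = as.integer(n_chains),
                 prior_df = prior_df, retained = as.integer(retained)),
            class = "model_spec")
}

# eigendecomposition with a PSD check calibrated to the matrix scale
eigen_kernel <- function(K, tol_factor = 1e-8) {
  if (!isSymmetric(unname(K), tol = 1e-8)) stop("kernel must be symmetric")
  E <- eigen(K, symmetric = TRUE)
  tolv <- tol_factor * max(sum(abs(E$values)), 1) / nrow(K)
  if (min(E$values) < -tolv)
    stop("kernel is not positive semi-definite beyond tolerance")
  lam <- pmax(E$values, 0)
  pos <- lam > max(lam) * 1e-12
  list(V = E$vectors, lam = lam, pos = pos)
}

# scaled-inverse-chi-square draw and the prior scale giving a chosen mode
rscinvchisq <- function(df, scale) df * scale / stats::rchisq(1L, df)
scale_for_mode <- function(mode, df) mode * (df + 2) / df

# draw from an inverse-Wishart(nu, S) via base R's Wishart sampler
riwish <- function(nu, S) {
  W <- stats::rWishart(1L, nu, solve(S))[, , 1L]
  solve(W)
}

new_gxe_fit <- function(model, spec, predictions, components, samples,
                        extra = list()) {
  structure(c(list(model = model, spec = spec, predictions = predictions,
                   components = components, samples = samples), extra),
            class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("gxe_fit: %s (%d chain(s), %d retained samples each)\n",
              x$model, length(x$samples), x$spec$retained))
  comp <- vapply(x$components, function(v)
    if (is.matrix(v)) NA_real_ else mean(v), numeric(1))
  comp <- comp[!is.na(comp)]
  cat("  posterior means:",
      paste(sprintf("%s = %.4g", names(comp), comp), collapse = ", "), "\n")
  invisible(x)
}

# online accumulator for posterior means / sds of large vectors
acc_new <- function(dim) list(n = 0, mean = array(0, dim), m2 = array(0, dim))
acc_add <- function(a, x) {
  a$n <- a$n + 1
  d <- x - a$mean
  a$mean <- a$mean + d / a$n
  a$m2 <- a$m2 + d * (x - a$mean)
  a
}
acc_sd <- function(a) if (a$n > 1) sqrt(a$m2 / (a$n - 1)) else a$m2 * NA

#' Single-environment Bayesian kernel regression (GBLUP / RKHS)
#'
#' Gibbs sampler for \eqn{y = \mu + u + \varepsilon}, \eqn{u \sim N(0,
#' \sigma_u^2 K)}, \eqn{\varepsilon \sim N(0, \sigma_e^2 I)}. Genotypes with
#' `NA` phenotypes stay in the genetic term and are predicted from it
#' (their missing responses are augmented each sweep, which leaves the
#' parameter posterior identical to the observed-data-likelihood model).
#'
#' @param kernel N x N relationship kernel (rownames = genotype ids).
#' @param y Phenotype vector aligned with the kernel; `NA` marks genotypes to
#'   predict.
#' @param spec A [model_spec()].
#' @param fix Optional list fixing variances, e.g.
#'   `list(sigma2_u = 2, sigma2_e = 1)` (used for closed-form BLUP checks).
#' @return A `gxe_fit` with `predictions` (data frame `genotype_id,
#'   environment, pred, sd`), posterior summaries of `u`, component means,
#'   and per-chain retained samples of the scalar parameters.
#' @export
fit_single_env <- function(kernel, y, spec = model_spec("GBLUP"),
                           fix = NULL) {
  n <- nrow(kernel)
  y <- as.numeric(y)
  if (length(y) != n) stop("phenotype not aligned with kernel")
  obs <- !is.na(y)
  if (!any(obs)) stop("no observed phenotypes")
  if (stats::var(y[obs]) <= 0) stop("zero phenotypic variance")
  E <- eigen_kernel(kernel)
  V <- E$V; lam <- E$lam; pos <- E$pos; npos <- sum(pos)
  lamp <- lam[pos]
  vy <- stats::var(y[obs])
  df0 <- spec$prior_df
  S0u <- scale_for_mode(vy / 2 / mean(lamp), df0)  # on the u scale via K
  S0e <- scale_for_mode(vy / 2, df0)
  fixed_u <- !is.null(fix$sigma2_u); fixed_e <- !is.null(fix$sigma2_e)

  u_acc <- acc_new(n)
  urb_acc <- acc_new(n)
  chains <- vector("list", spec$n_chains)
  mu_hat <- 0
  for (ch in seq_len(spec$n_chains)) {
    set.seed(spec$seed + ch - 1L)
    mu <- mean(y[obs])
    su2 <- if (fixed_u) fix$sigma2_u else vy / 2
    se2 <- if (fixed_e) fix$sigma2_e else vy / 2
    u <- numeric(n)
    yf <- y; yf[!obs] <- mu
    keep <- matrix(NA_real_, spec$retained,
                   3, dimnames = list(NULL, c("mu", "sigma2_u", "sigma2_e")))
    k <- 0L
    delta <- numeric(npos)
    Vp <- V[, pos, drop = FALSE]
    Ut1 <- drop(crossprod(Vp, rep(1, n)))
    r1 <- rep(1, n) - drop(Vp %*% Ut1)    # component of 1 outside span(K)
    n_out <- sum(r1^2)
    for (it in seq_len(spec$chain)) {
      if (any(!obs))
        yf[!obs] <- mu + u[!obs] + stats::rnorm(sum(!obs), 0, sqrt(se2))
      zf <- drop(crossprod(Vp, yf))
      y_out <- sum(r1 * yf)
      # blocked update: mu drawn with u integrated out (collapsed Gibbs),
      # then delta | mu; avoids the strong mu-u autocorrelation
      w <- su2 * lamp + se2
      prec <- sum(Ut1^2 / w) + n_out / se2
      mu <- stats::rnorm(1L, (sum(Ut1 * zf / w) + y_out / se2) / prec,
                         sqrt(1 / prec))
      z <- zf - mu * Ut1
      cc <- su2 * lamp / (su2 * lamp + se2)
      delta <- stats::rnorm(npos, cc * z, sqrt(cc * se2))
      u <- drop(Vp %*% delta)
      if (!fixed_u)
        su2 <- rscinvchisq(df0 + npos,
                           (df0 * S0u + sum(delta^2 / lamp)) / (df0 + npos))
      if (!fixed_e)
        se2 <- rscinvchisq(df0 + n,
                           (df0 * S0e + sum((yf - mu - u)^2)) / (df0 + n))
      if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
        k <- k + 1L
        keep[k, ] <- c(mu, su2, se2)
        u_acc <- acc_add(u_acc, u)
        # Rao-Blackwellized mean: conditional expectation of u given the
        # current variances and intercept (lower Monte-Carlo error)
        urb_acc <- acc_add(urb_acc,
                           drop(V[, pos, drop = FALSE] %*% (cc * z)))
      }
    }
    chains[[ch]] <- keep
    mu_hat <- mu_hat + mean(keep[, "mu"]) / spec$n_chains
  }
  ids <- rownames(kernel)
  if (is.null(ids)) ids <- paste0("G", seq_len(n))
  u_mean <- urb_acc$mean; u_sd <- acc_sd(u_acc)
  pred <- data.frame(genotype_id = ids, environment = NA_character_,
                     pred = mu_hat + u_mean, sd = u_sd,
                     observed = obs, stringsAsFactors = FALSE)
  comp <- list(mu = mu_hat,
               sigma2_u = mean(unlist(lapply(chains, function(m)
                 mean(m[, "sigma2_u"])))),
               sigma2_e = mean(unlist(lapply(chains, function(m)
                 mean(m[, "sigma2_e"])))))
  new_gxe_fit(spec$model, spec, pred, comp, chains,
              list(u_mean = u_mean, u_sd = u_sd))
}

# Shared engine for the "main + environment-specific effects" models:
# y_e = mu_e + u0 + uE_e + eps, u0 ~ N(0, s2_u0 K0), uE_e ~ N(0, s2_uE_e K_e).
fit_main_plus_env <- function(K0, KE, Y, spec, fix = NULL, model_name) {
  Y <- as.matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  if (m < 2L) stop("multi-environment model needs >= 2 environments")
  envs <- colnames(Y)
  if (is.null(envs)) envs <- paste0("E", seq_len(m))
  none <- colSums(!is.na(Y)) == 0L
  if (any(none))
    stop("environment(s) with no observations: ",
         paste(envs[none], collapse = ", "))
  if (!is.list(KE)) KE <- rep(list(KE), m)
  E0 <- eigen_kernel(K0)
  EE <- lapply(KE, eigen_kernel)
  obs <- !is.na(Y)
  vy <- stats::var(Y[obs])
  df0 <- spec$prior_df
  use_u0 <- is.null(fix$sigma2_u0) || fix$sigma2_u0 > 0
  use_uE <- is.null(fix$sigma2_uE) || any(fix$sigma2_uE > 0)
  nterms <- 1 + use_u0 + use_uE
  S0_0 <- scale_for_mode(vy / nterms / mean(E0$lam[E0$pos]), df0)
  S0_E <- vapply(EE, function(e)
    scale_for_mode(vy / nterms / mean(e$lam[e$pos]), df0), numeric(1))
  S0_e <- scale_for_mode(vy / nterms, df0)

  u0_acc <- acc_new(n); uE_acc <- acc_new(c(n, m)); pr_acc <- acc_new(c(n, m))
  chains <- vector("list", spec$n_chains)
  scal_names <- c(paste0("mu_", envs), "sigma2_u0",
                  paste0("sigma2_uE_", envs), "sigma2_e")
  for (ch in seq_len(spec$n_chains)) {
    set.seed(spec$seed + ch - 1L)
    mu <- colMeans(Y, na.rm = TRUE)
    su0 <- if (use_u0) vy / nterms else 0
    suE <- rep(if (use_uE) vy / nterms else 0, m)
    se2 <- vy / nterms
    u0 <- numeric(n); uE <- matrix(0, n, m)
    Yf <- Y
    for (e in seq_len(m)) Yf[!obs[, e], e] <- mu[e]
    keep <- matrix(NA_real_, spec$retained, length(scal_names),
                   dimnames = list(NULL, scal_names))
    k <- 0L
    for (it in seq_len(spec$chain)) {
      for (e in seq_len(m)) {
        miss <- !obs[, e]
        if (any(miss))
          Yf[miss, e] <- mu[e] + u0[miss] + uE[miss, e] +
            stats::rnorm(sum(miss), 0, sqrt(se2))
        mu[e] <- stats::rnorm(1L, mean(Yf[, e] - u0 - uE[, e]),
                              sqrt(se2 / n))
      }
      if (use_u0) {
        rbar <- rowMeans(sweep(Yf, 2, mu) - uE)
        Vp <- E0$V[, E0$pos, drop = FALSE]; lp <- E0$lam[E0$pos]
        z <- drop(crossprod(Vp, rbar))
        vpost <- 1 / (1 / (su0 * lp) + m / se2)
        d0 <- stats::rnorm(length(z), vpost * z * m / se2, sqrt(vpost))
        u0 <- drop(Vp %*% d0)
        su0 <- if (is.null(fix$sigma2_u0))
          rscinvchisq(df0 + length(d0),
                      (df0 * S0_0 + sum(d0^2 / lp)) / (df0 + length(d0)))
          else fix$sigma2_u0
      }
      if (use_uE) {
        for (e in seq_len(m)) {
          Vp <- EE[[e]]$V[, EE[[e]]$pos, drop = FALSE]
          lp <- EE[[e]]$lam[EE[[e]]$pos]
          r <- Yf[, e] - mu[e] - u0
          z <- drop(crossprod(Vp, r))
          cc <- suE[e] * lp / (suE[e] * lp + se2)
          dE <- stats::rnorm(length(z), cc * z, sqrt(cc * se2))
          uE[, e] <- drop(Vp %*% dE)
          suE[e] <- if (is.null(fix$sigma2_uE))
            rscinvchisq(df0 + length(dE),
                        (df0 * S0_E[e] + sum(dE^2 / lp)) / (df0 + length(dE)))
            else fix$sigma2_uE[min(e, length(fix$sigma2_uE))]
        }
      }
      resid <- sweep(Yf, 2, mu) - u0 - uE
      if (is.null(fix$sigma2_e))
        se2 <- rscinvchisq(df0 + n * m,
                           (df0 * S0_e + sum(resid^2)) / (df0 + n * m))
      else se2 <- fix$sigma2_e
      if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
        k <- k + 1L
        keep[k, ] <- c(mu, su0, suE, se2)
        u0_acc <- acc_add(u0_acc, u0)
        uE_acc <- acc_add(uE_acc, uE)
        pr_acc <- acc_add(pr_acc, sweep(matrix(u0, n, m) + uE, 2, mu, "+"))
      }
    }
    chains[[ch]] <- keep
  }
  ids <- rownames(Y); if (is.null(ids)) ids <- paste0("G", seq_len(n))
  pred_mean <- pr_acc$mean; pred_sd <- acc_sd(pr_acc)
  pred <- data.frame(genotype_id = rep(ids, m),
                     environment = rep(envs, each = n),
                     pred = as.vector(pred_mean), sd = as.vector(pred_sd),
                     observed = as.vector(obs), stringsAsFactors = FALSE)
  msamp <- do.call(rbind, chains)
  comp <- list(mu = colMeans(msamp[, paste0("mu_", envs), drop = FALSE]),
               sigma2_u0 = mean(msamp[, "sigma2_u0"]),
               sigma2_uE = colMeans(msamp[, paste0("sigma2_uE_", envs),
                                          drop = FALSE]),
               sigma2_e = mean(msamp[, "sigma2_e"]))
  new_gxe_fit(model_name, spec, pred, comp, chains,
              list(u0_mean = u0_acc$mean, uE_mean = uE_acc$mean,
                   environments = envs))
}

#' Multi-environment extended GBLUP (main + environment-specific effects)
#'
#' \eqn{y_{je} = \mu_e + u_{0j} + u_{Ej,e} + \varepsilon}: marker effects are
#' split into a component shared by all environments (\eqn{u_0 \sim N(0,
#' \sigma_{u0}^2 K)}) and an independent component per environment. Missing
#' cells are allowed and predicted.
#'
#' @param kernel Linear relationship kernel over all genotypes.
#' @param Y N x m matrix of phenotypes (adjusted means), genotypes in rows,
#'   environments in columns; `NA` marks cells to predict.
#' @param spec A [model_spec()].
#' @param fix Optional list fixing variances (`sigma2_u0`, `sigma2_uE`,
#'   `sigma2_e`); a value of 0 removes the term.
#' @return A `gxe_fit` with per-(genotype, environment) predictions.
#' @export
fit_gblup_gxe <- function(kernel, Y, spec = model_spec("GBLUP-GxE"),
                          fix = NULL) {
  fit_main_plus_env(kernel, kernel, Y, spec, fix, "GBLUP-GxE")
}

#' Multi-environment Gaussian-kernel model (main + environment-specific)
#'
#' Same structure as [fit_gblup_gxe()] with Gaussian kernels: a shared kernel
#' for the across-environment component and (optionally environment-specific)
#' kernels for the environment components. With linear kernels supplied it
#' reduces exactly to the extended GBLUP.
#'
#' @param K0 Shared Gaussian kernel.
#' @param KE A kernel or list of per-environment kernels (default `K0`).
#' @inheritParams fit_gblup_gxe
#' @return A `gxe_fit`.
#' @export
fit_rkhs1 <- function(K0, Y, spec = model_spec("RKHS-1"), KE = K0,
                      fix = NULL) {
  fit_main_plus_env(K0, KE, Y, spec, fix, "RKHS-1")
}

# vectorized bivariate-normal posterior draws for the environment-covariance
# model: for each index i, prior N(0, lam_i * Sigma), likelihood z_i = x_i +
# e, e ~ N(0, diag(se2)); returns draws (length(lam) x 2)
draw_bivariate <- function(Z, lam, Sigma_inv, se2) {
  r1 <- 1 / se2[1]; r2 <- 1 / se2[2]
  p11 <- Sigma_inv[1, 1] / lam + r1
  p12 <- Sigma_inv[1, 2] / lam
  p22 <- Sigma_inv[2, 2] / lam + r2
  det <- p11 * p22 - p12^2
  c11 <- p22 / det; c12 <- -p12 / det; c22 <- p11 / det
  m1 <- c11 * r1 * Z[, 1] + c12 * r2 * Z[, 2]
  m2 <- c12 * r1 * Z[, 1] + c22 * r2 * Z[, 2]
  l11 <- sqrt(c11); l21 <- c12 / l11
  l22 <- sqrt(pmax(c22 - l21^2, 0))
  e1 <- stats::rnorm(length(lam)); e2 <- stats::rnorm(length(lam))
  cbind(m1 + l11 * e1, m2 + l21 * e1 + l22 * e2)
}

#' Environment-covariance kernel model (RKHS-2 style)
#'
#' \eqn{y = \mu + u + f + \varepsilon} with per-environment intercepts, a
#' genetic term with covariance \eqn{\Sigma_u \otimes K} (an m x m
#' environment covariance crossed with the marker kernel), an
#' individual-level term \eqn{f} with covariance \eqn{\Sigma_f \otimes I}
#' catching genetic effects the markers miss, and independent per-environment
#' residual variances. Returns the posterior mean environment correlation
#' matrix alongside predictions.
#'
#' @param kernel Shared (typically Gaussian) kernel.
#' @param Y N x m phenotype matrix with `NA` for cells to predict.
#' @param spec A [model_spec()].
#' @param constrain `"none"` (full covariances) or `"diagonal"`
#'   (independent environments; reduction check).
#' @param include_f Include the individual-level `f` term (default `TRUE`).
#' @return A `gxe_fit`; `components$env_correlation` holds the posterior mean
#'   genetic correlation between environments.
#' @export
fit_rkhs2 <- function(kernel, Y, spec = model_spec("RKHS-2"),
                      constrain = c("none", "diagonal"), include_f = TRUE) {
  constrain <- match.arg(constrain)
  Y <- as.matrix(Y)
  n <- nrow(Y); m <- ncol(Y)
  if (m == 1L) return(fit_single_env(kernel, Y[, 1], spec))
  if (m > 2L)
    stop("the environment-covariance sampler currently supports m = 2")
  envs <- colnames(Y); if (is.null(envs)) envs <- paste0("E", seq_len(m))
  E <- eigen_kernel(kernel)
  Vp <- E$V[, E$pos, drop = FALSE]; lp <- E$lam[E$pos]; npos <- length(lp)
  obs <- !is.na(Y)
  if (any(colSums(obs) == 0L)) stop("an environment has no observations")
  vy <- stats::var(Y[obs])
  df0 <- spec$prior_df
  nterms <- if (include_f) 3 else 2
  # inverse-Wishart priors: df = m + 2, identity scale (weakly informative)
  df_iw <- m + 2
  S_iw <- diag(m)
  S0_e <- scale_for_mode(vy / nterms, df0)

  pr_acc <- acc_new(c(n, m)); u_acc <- acc_new(c(n, m))
  cor_acc <- acc_new(c(m, m))
  chains <- vector("list", spec$n_chains)
  scal_names <- c(paste0("mu_", envs),
                  paste0("Sigma_u_", c("11", "22", "12")),
                  paste0("Sigma_f_", c("11", "22"))[seq_len(if (include_f) 2 else 0)],
                  paste0("sigma2_e_", envs))
  for (ch in seq_len(spec$n_chains)) {
    set.seed(spec$seed + ch - 1L)
    mu <- colMeans(Y, na.rm = TRUE)
    Su <- diag(vy / nterms / mean(lp), m)
    Sf <- diag(vy / nterms, m)
    se2 <- rep(vy / nterms, m)
    eta <- matrix(0, npos, m)
    U <- matrix(0, n, m)
    f <- matrix(0, n, m)
    Yf <- Y
    for (e in seq_len(m)) Yf[!obs[, e], e] <- mu[e]
    keep <- matrix(NA_real_, spec$retained, length(scal_names),
                   dimnames = list(NULL, scal_names))
    k <- 0L
    for (it in seq_len(spec$chain)) {
      for (e in seq_len(m)) {
        miss <- !obs[, e]
        if (any(miss))
          Yf[miss, e] <- mu[e] + U[miss, e] + f[miss, e] +
            stats::rnorm(sum(miss), 0, sqrt(se2[e]))
        mu[e] <- stats::rnorm(1L, mean(Yf[, e] - U[, e] - f[, e]),
                              sqrt(se2[e] / n))
      }
      # genetic term in the kernel eigenbasis
      R <- sweep(Yf, 2, mu) - f
      Z <- crossprod(Vp, R)
      Su_inv <- solve(Su)
      if (m == 2L) {
        eta <- draw_bivariate(Z, lp, Su_inv, se2)
      } else {
        Rinv <- diag(1 / se2)
        for (i in seq_len(npos)) {
          P <- Su_inv / lp[i] + Rinv
          Cp <- solve(P)
          mn <- drop(Cp %*% (Z[i, ] / se2))
          eta[i, ] <- mn + drop(chol(Cp) %*% stats::rnorm(m))
        }
      }
      U <- Vp %*% eta
      # individual-level term (identity kernel): one posterior covariance
      if (include_f) {
        Rf <- sweep(Yf, 2, mu) - U
        P <- solve(Sf) + diag(1 / se2)
        Cp <- solve(P)
        Mn <- Rf %*% t(Cp %*% diag(1 / se2))
        f <- Mn + matrix(stats::rnorm(n * m), n, m) %*% chol(Cp)
      }
      # covariances
      Ssc <- crossprod(eta / sqrt(lp))      # sum_i eta_i eta_i' / lam_i
      if (constrain == "diagonal") {
        Su <- diag(vapply(seq_len(m), function(e)
          rscinvchisq(df0 + npos,
                      (df0 * scale_for_mode(vy / nterms / mean(lp), df0) +
                         Ssc[e, e]) / (df0 + npos)), numeric(1)), m)
      } else {
        Su <- riwish(df_iw + npos, S_iw + Ssc)
      }
      if (include_f) {
        if (constrain == "diagonal") {
          Sf <- diag(vapply(seq_len(m), function(e)
            rscinvchisq(df0 + n,
                        (df0 * scale_for_mode(vy / nterms, df0) +
                           sum(f[, e]^2)) / (df0 + n)), numeric(1)), m)
        } else {
          Sf <- riwish(df_iw + n, S_iw + crossprod(f))
        }
      }
      resid <- sweep(Yf, 2, mu) - U - f
      for (e in seq_len(m))
        se2[e] <- rscinvchisq(df0 + n,
                              (df0 * S0_e + sum(resid[, e]^2)) / (df0 + n))
      if (it > spec$burnin && (it - spec$burnin) %% spec$thin == 0L) {
        k <- k + 1L
        Guse <- Su   # genetic environment covariance (marker term)
        keep[k, ] <- c(mu, Su[1, 1], Su[2, 2], Su[1, 2],
                       if (include_f) c(Sf[1, 1], Sf[2, 2]), se2)
        u_acc <- acc_add(u_acc, U + f)
        pr_acc <- acc_add(pr_acc, sweep(U + f, 2, mu, "+"))
        cor_acc <- acc_add(cor_acc, stats::cov2cor(Guse))
      }
    }
    chains[[ch]] <- keep
  }
  ids <- rownames(Y); if (is.null(ids)) ids <- paste0("G", seq_len(n))
  pred <- data.frame(genotype_id = rep(ids, m),
                     environment = rep(envs, each = n),
                     pred = as.vector(pr_acc$mean),
                     sd = as.vector(acc_sd(pr_acc)),
                     observed = as.vector(obs), stringsAsFactors = FALSE)
  msamp <- do.call(rbind, chains)
  comp <- list(mu = colMeans(msamp[, paste0("mu_", envs), drop = FALSE]),
               Sigma_u = matrix(c(mean(msamp[, "Sigma_u_11"]),
                                  mean(msamp[, "Sigma_u_12"]),
                                  mean(msamp[, "Sigma_u_12"]),
                                  mean(msamp[, "Sigma_u_22"])), 2, 2),
               sigma2_e = colMeans(msamp[, paste0("sigma2_e_", envs),
                                         drop = FALSE]),
               env_correlation = cor_acc$mean)
  new_gxe_fit("RKHS-2", spec, pred, comp, chains,
              list(u_mean = u_acc$mean, environments = envs))
}

#' Gelman-Rubin convergence report for a fitted model
#'
#' Computes the potential scale reduction factor (PSRF) for every monitored
#' scalar parameter across the chains of a `gxe_fit`, flagging parameters
#' with PSRF > `threshold`. With a single chain an explicit
#' "diagnostics unavailable" report is returned rather than a silent pass.
#'
#' @param fit A `gxe_fit`.
#' @param threshold PSRF flag threshold (default 1.1).
#' @return A `convergence_report`: `available`, `psrf` (named vector),
#'   `flagged`.
#' @export
check_convergence <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "gxe_fit"))
  if (length(fit$samples) < 2L)
    return(structure(list(available = FALSE, psrf = NULL,
                          flagged = character(),
                          message = "diagnostics unavailable: need >= 2 chains"),
                     class = "convergence_report"))
  keep <- Reduce(`|`, lapply(fit$samples, function(s)
    apply(s, 2, stats::sd) > 0))
  pars <- colnames(fit$samples[[1]])[keep]
  n <- nrow(fit$samples[[1]])
  psrf <- vapply(pars, function(p) {
    draws <- vapply(fit$samples, function(s) s[, p], numeric(n))
    W <- mean(apply(draws, 2, stats::var))
    B_n <- stats::var(colMeans(draws))      # B/n
    if (W <= 0) return(NA_real_)
    sqrt((n - 1) / n + B_n / W)
  }, numeric(1))
  structure(list(available = TRUE, psrf = psrf,
                 flagged = names(psrf)[!is.na(psrf) & psrf > threshold],
                 threshold = threshold, n_retained = n),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  if (!x$available) {
    cat("convergence diagnostics:", x$message, "\n")
    return(invisible(x))
  }
  cat("Gelman-Rubin PSRF per parameter:\n")
  print(round(x$psrf, 3))
  if (length(x$flagged))
    cat("  flagged (PSRF >", x$threshold, "):",
        paste(x$flagged, collapse = ", "), "\n")
  else cat("  no parameter flagged (threshold", x$threshold, ")\n")
  invisible(x)
}
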
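# Per-system and combined mixed models: REML variance components, adjusted
# means, broad-sense heritability, conditional R2, and the genotype-by-system
# interaction test.

#' Variance components of a per-system mixed model
#'
#' @param sigma2_g Genotype variance.
#' @param sigma2_gy Genotype-by-year interaction variance.
#' @param sigma2_e Residual variance.
#' @param fixed_var Variance accounted for by the fixed effects (population
#'   variance of the fitted fixed-effect linear predictor across plots).
#' @param n_y Harmonic mean number of years per genotype.
#' @param n_r Harmonic mean number of plots (across years) per genotype.
#' @param vcov Optional 3x3 covariance matrix of
#'   `(sigma2_g, sigma2_gy, sigma2_e)` for delta-method standard errors.
#' @return A `variance_components` object with `total` = `fixed_var` +
#'   random components.
#' @export
variance_components <- function(sigma2_g, sigma2_gy, sigma2_e,
                                fixed_var = 0, n_y = 1, n_r = 1, vcov = NULL) {
  comps <- c(sigma2_g = sigma2_g, sigma2_gy = sigma2_gy, sigma2_e = sigma2_e,
             fixed_var = fixed_var)
  if (any(comps < 0)) stop("variance components must be >= 0")
  if (n_y < 1 || n_r < 1) stop("n_y and n_r must be >= 1")
  structure(list(sigma2_g = sigma2_g, sigma2_gy = sigma2_gy,
                 sigma2_e = sigma2_e, fixed_var = fixed_var,
                 total = fixed_var + sigma2_g + sigma2_gy + sigma2_e,
                 n_y = n_y, n_r = n_r, vcov = vcov),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(paste0("variance components: g = %.4g, g x y = %.4g, ",
                     "residual = %.4g, fixed = %.4g (total %.4g)\n"),
              x$sigma2_g, x$sigma2_gy, x$sigma2_e, x$fixed_var, x$total))
  cat(sprintf("  harmonic means: n_y = %.3g years, n_r = %.3g plots\n",
              x$n_y, x$n_r))
  invisible(x)
}

harmonic_mean <- function(x) length(x) / sum(1 / x)

# harmonic means of the per-genotype numbers of years and plots
replication_harmonic_means <- function(obs) {
  yrs <- tapply(obs$year, obs$genotype_id, function(y) length(unique(y)))
  plots <- tapply(obs$value, obs$genotype_id, length)
  list(n_y = harmonic_mean(yrs), n_r = harmonic_mean(plots))
}

#' Fit the per-system mixed model and extract adjusted means
#'
#' Fits, by REML, the single-environment model
#' \deqn{y = \mu + year + g + g{\times}year + \varepsilon}
#' with genotype and genotype-by-year random, year fixed (and, for the
#' replicated-block progeny design, replicate-within-year fixed), then
#' returns the adjusted mean per genotype
#' \eqn{\hat Y_j = \hat\mu + \hat g_j} (system mean plus genotype BLUP)
#' together with the REML variance components.
#'
#' @param obs A `trial_observations` data frame.
#' @param trait Trait to analyse.
#' @param system Environment (water-management system) to subset to.
#' @param rep_in_year Add replicate-within-year fixed effects (block design).
#' @param se Compute an approximate covariance matrix of the variance
#'   components by finite-differencing the restricted log-likelihood (used
#'   for delta-method heritability standard errors). Costs a dense solve per
#'   evaluation; intended for moderate data sizes.
#' @return A list with elements `means` (data frame `genotype_id, system,
#'   trait, value`), `vc` (a [variance_components()]), `fit` (the underlying
#'   `lmerMod`), and `dropped` (names of terms dropped for estimability).
#' @export
fit_single_system <- function(obs, trait, system, rep_in_year = FALSE,
                              se = FALSE) {
  d <- obs[obs$trait == trait & obs$environment == system, , drop = FALSE]
  if (nrow(d) == 0L) stop("no records for trait ", trait, " in ", system)
  if (length(unique(d$genotype_id)) < 2L)
    stop("need >= 2 genotypes with records in system ", system)
  d$genotype_id <- factor(d$genotype_id)
  d$year <- factor(d$year)
  d$replicate <- factor(d$replicate)

  dropped <- character()
  one_year <- nlevels(d$year) < 2L
  fixed <- if (one_year) "value ~ 1" else "value ~ year"
  if (rep_in_year && !one_year) fixed <- paste(fixed, "+ year:replicate")
  if (rep_in_year && one_year) fixed <- paste(fixed, "+ replicate")
  terms <- "(1 | genotype_id)"
  if (!one_year) terms <- c(terms, "(1 | genotype_id:year)")
  else dropped <- c(dropped, "genotype:year")
  form <- stats::as.formula(paste(fixed, "+", paste(terms, collapse = " + ")))
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))

  vcs <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) {
    v <- vcs$vcov[vcs$grp == g]
    if (length(v)) v else 0
  }
  fx <- drop(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  fixed_var <- mean((fx - mean(fx))^2)
  hm <- replication_harmonic_means(d)
  comp <- c(pick("genotype_id"), pick("genotype_id:year"), pick("Residual"))
  V <- if (se) reml_vcov(d, comp, rep_in_year = rep_in_year) else NULL
  vc <- variance_components(comp[1], comp[2], comp[3], fixed_var = fixed_var,
                            n_y = hm$n_y, n_r = hm$n_r, vcov = V)

  blup <- lme4::ranef(fit)$genotype_id
  mu <- mean(fx)
  means <- data.frame(genotype_id = rownames(blup), system = system,
                      trait = trait, value = mu + blup[[1]],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(means = means, vc = vc, fit = fit, dropped = dropped, mu = mu)
}

# Restricted log-likelihood of the per-system model at given components
# (sigma2_g, sigma2_gy, sigma2_e), evaluated densely. Used for the
# finite-difference covariance of the REML estimates.
reml_loglik_direct <- function(d, comp, rep_in_year = FALSE) {
  fixed <- if (nlevels(d$year) > 1) "value ~ year" else "value ~ 1"
  if (rep_in_year && nlevels(d$year) > 1) fixed <- paste(fixed, "+ year:replicate")
  X <- stats::model.matrix(stats::as.formula(fixed), d)
  Zg <- stats::model.matrix(~ 0 + genotype_id, d)
  Zgy <- if (nlevels(d$year) > 1)
    stats::model.matrix(~ 0 + genotype_id:year, d) else NULL
  n <- nrow(d)
  V <- comp[1] * tcrossprod(Zg) + comp[3] * diag(n)
  if (!is.null(Zgy)) V <- V + comp[2] * tcrossprod(Zgy)
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), d$value))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(Vi_X, d$value))
  r <- d$value - drop(X %*% beta)
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  -0.5 * (2 * sum(log(diag(ch))) + determinant(XtViX)$modulus[1] +
            sum(r * Vi_r))
}

reml_vcov <- function(d, comp, rep_in_year = FALSE, rel_step = 1e-4) {
  f <- function(th) reml_loglik_direct(d, th, rep_in_year = rep_in_year)
  h <- pmax(abs(comp), 1e-3) * sqrt(rel_step)
  H <- matrix(NA_real_, 3, 3)
  f0 <- f(comp)
  for (i in 1:3) for (j in i:3) {
    ei <- ej <- c(0, 0, 0); ei[i] <- h[i]; ej[j] <- h[j]
    if (i == j) {
      H[i, i] <- (f(pmax(comp + ei, 0)) - 2 * f0 + f(pmax(comp - ei, 0))) /
        h[i]^2
    } else {
      H[i, j] <- H[j, i] <-
        (f(pmax(comp + ei + ej, 0)) - f(pmax(comp + ei - ej, 0)) -
           f(pmax(comp - ei + ej, 0)) + f(pmax(comp - ei - ej, 0))) /
        (4 * h[i] * h[j])
    }
  }
  out <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 3, 3))
  dimnames(out) <- list(c("sigma2_g", "sigma2_gy", "sigma2_e"),
                        c("sigma2_g", "sigma2_gy", "sigma2_e"))
  out
}

#' Broad-sense heritability on an entry-mean basis
#'
#' \deqn{H^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_{gy}^2 / n_y +
#'   \sigma_e^2 / n_r)}
#' with \eqn{n_y} and \eqn{n_r} the harmonic means of the numbers of years
#' and plots per genotype.
#'
#' @param vc A [variance_components()] object.
#' @param se If `TRUE` and `vc$vcov` is available, attach an approximate
#'   delta-method standard error as `attr(, "se")`.
#' @return Heritability in `[0, 1]`.
#' @examples
#' vc <- variance_components(57.68, 10.90, 11.28, n_y = 2, n_r = 6)
#' heritability(vc)  # 0.887...
#' @export
heritability <- function(vc, se = FALSE) {
  stopifnot(inherits(vc, "variance_components"))
  denom <- vc$sigma2_g + vc$sigma2_gy / vc$n_y + vc$sigma2_e / vc$n_r
  if (denom <= 0) stop("heritability undefined: all components zero")
  h2 <- vc$sigma2_g / denom
  if (se) {
    if (is.null(vc$vcov) || anyNA(vc$vcov)) {
      warning("no component covariance available; SE not computed")
    } else {
      # gradient of H2 wrt (sigma2_g, sigma2_gy, sigma2_e)
      grad <- c((denom - vc$sigma2_g) / denom^2,
                -vc$sigma2_g / (vc$n_y * denom^2),
                -vc$sigma2_g / (vc$n_r * denom^2))
      attr(h2, "se") <- sqrt(drop(t(grad) %*% vc$vcov %*% grad))
      attr(h2, "se_method") <- "delta (approximate)"
    }
  }
  h2
}

#' Conditional coefficient of determination of the per-system model
#'
#' Proportion of phenotypic variance captured by fixed effects plus genotype
#' and genotype-by-year random effects:
#' \eqn{(fixed\_var + \sigma_g^2 + \sigma_{gy}^2) / total}.
#'
#' @param vc A [variance_components()] object with `fixed_var` set.
#' @return Value in `[0, 1]`.
#' @examples
#' conditional_r2(variance_components(57.68, 10.90, 11.28, fixed_var = 44.12,
#'                                    n_y = 2, n_r = 6))  # 0.909
#' @export
conditional_r2 <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  if (vc$total <= 0) stop("conditional R2 undefined: total variance is zero")
  (vc$fixed_var + vc$sigma2_g + vc$sigma2_gy) / vc$total
}

#' Fit the combined two-system model and test the genotype-by-system term
#'
#' Fits, by REML,
#' \deqn{y = \mu + m + y + my + g + gm + gy + gmy + \varepsilon}
#' with system (m), year and their interaction fixed, and genotype (g) and
#' its interactions with system and year random. The genotype-by-system
#' variance is tested by a restricted likelihood-ratio test against the model
#' without `gm`, with the p-value from the 50:50 mixture of chi-square(0) and
#' chi-square(1) appropriate for a variance on its boundary.
#'
#' @param obs A `trial_observations` data frame.
#' @param trait Trait to analyse.
#' @param rep_in_year Add replicate-within-(system, year) fixed effects.
#' @return A `combined_model_fit` list: `vc` (named vector of the five
#'   variance components), `lrt` (statistic, p-value), `fit`, `dropped`.
#' @export
fit_combined <- function(obs, trait, rep_in_year = FALSE) {
  d <- obs[obs$trait == trait, , drop = FALSE]
  if (length(unique(d$environment)) < 2L)
    stop("combined model needs both systems present")
  d$genotype_id <- factor(d$genotype_id)
  d$year <- factor(d$year)
  d$system <- factor(d$environment)
  d$replicate <- factor(d$replicate)

  fixed <- "value ~ system * year"
  if (rep_in_year) fixed <- paste(fixed, "+ system:year:replicate")
  full_terms <- c("(1 | genotype_id)", "(1 | genotype_id:system)",
                  "(1 | genotype_id:year)", "(1 | genotype_id:system:year)")
  mk <- function(terms) stats::as.formula(
    paste(fixed, "+", paste(terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore")
  dropped <- character()
  fit <- tryCatch(lme4::lmer(mk(full_terms), data = d, REML = TRUE,
                             control = ctrl),
                  error = function(e) NULL)
  if (is.null(fit)) {       # inestimable three-way term: drop gmy
    dropped <- "genotype:system:year"
    full_terms <- full_terms[1:3]
    fit <- lme4::lmer(mk(full_terms), data = d, REML = TRUE, control = ctrl)
  }
  red <- lme4::lmer(mk(setdiff(full_terms, "(1 | genotype_id:system)")),
                    data = d, REML = TRUE, control = ctrl)
  stat <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                        as.numeric(stats::logLik(red))))
  p <- if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)

  vcs <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) { v <- vcs$vcov[vcs$grp == g]; if (length(v)) v else 0 }
  vc <- c(g = pick("genotype_id"), gm = pick("genotype_id:system"),
          gy = pick("genotype_id:year"),
          gmy = pick("genotype_id:system:year"), residual = pick("Residual"))
  structure(list(vc = vc, lrt = c(statistic = stat, p_value = p),
                 fit = fit, fit_reduced = red, dropped = dropped),
            class = "combined_model_fit")
}

#' @export
print.combined_model_fit <- function(x, ...) {
  cat("combined two-system mixed model (REML)\n  variance components:\n")
  print(round(x$vc, 4))
  cat(sprintf("  genotype x system LRT: statistic = %.3f, p = %.4g %s\n",
              x$lrt["statistic"], x$lrt["p_value"],
              "(50:50 chi-square mixture)"))
  if (length(x$dropped))
    cat("  dropped for estimability:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Flag outlying plot records by standardized conditional residuals
#'
#' Fits the per-system model for each system present and flags records whose
#' absolute standardized conditional residual exceeds `threshold`. A light
#' screen standing in for more elaborate influence diagnostics; removal is
#' opt-in.
#'
#' @param obs A `trial_observations` data frame.
#' @param trait Trait to screen.
#' @param threshold Flagging threshold in residual standard deviations
#'   (default 4).
#' @param remove If `TRUE`, return `obs` with flagged records removed
#'   (flags logged in `attr(, "outlier_log")`); otherwise return `obs` with a
#'   logical `outlier` column added.
#' @param rep_in_year Passed to [fit_single_system()].
#' @return `trial_observations`, flagged or filtered.
#' @export
screen_outliers <- function(obs, trait, threshold = 4, remove = FALSE,
                            rep_in_year = FALSE) {
  flag <- rep(FALSE, nrow(obs))
  sel_all <- obs$trait == trait
  for (sys in unique(obs$environment[sel_all])) {
    sel <- which(sel_all & obs$environment == sys)
    fit <- fit_single_system(obs, trait, sys, rep_in_year = rep_in_year)$fit
    r <- stats::residuals(fit) / stats::sigma(fit)
    flag[sel] <- abs(r) > threshold
  }
  if (!remove) {
    obs$outlier <- flag
    return(obs)
  }
  out <- obs[!flag, , drop = FALSE]
  attr(out, "outlier_log") <- obs[flag, , drop = FALSE]
  attr(out, "true_values") <- attr(obs, "true_values")
  class(out) <- class(obs)
  out
}
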
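# Genotypic response to the contrasting environment: relative-performance
# index, joint-regression slope, genetic correlation with Fisher CI, and the
# correlated-response ratio.

# adjusted means (long: genotype_id, system, trait, value) -> genotype x
# system matrix for one trait
means_matrix <- function(means, trait = NULL) {
  if (!is.null(trait)) means <- means[means$trait == trait, , drop = FALSE]
  ids <- unique(means$genotype_id)
  sys <- unique(means$system)
  m <- matrix(NA_real_, length(ids), length(sys), dimnames = list(ids, sys))
  m[cbind(match(means$genotype_id, ids), match(means$system, sys))] <-
    means$value
  m
}

#' Per-genotype relative-performance index
#'
#' \deqn{I_j = (\hat Y_{j,stress} - \hat Y_{j,control}) / \hat Y_{j,control}}
#' Negative values mean performance loss under the stress system.
#'
#' @param means Adjusted-means data frame (`genotype_id, system, trait,
#'   value`).
#' @param stress,control System labels for numerator difference and
#'   denominator.
#' @param trait Optional trait filter.
#' @param tol Genotypes with `|control mean| < tol * sd(control means)` are
#'   excluded with a warning (near-zero denominator).
#' @return Data frame `genotype_id, index`.
#' @examples
#' m <- data.frame(genotype_id = c("a", "a"), system = c("AWD", "CF"),
#'                 trait = "t", value = c(90, 100))
#' response_index(m)$index  # -0.1
#' @export
response_index <- function(means, stress = "AWD", control = "CF",
                           trait = NULL, tol = 1e-6) {
  m <- means_matrix(means, trait)
  if (!all(c(stress, control) %in% colnames(m)))
    stop("both systems must be present in the adjusted means")
  ok <- stats::complete.cases(m[, c(stress, control)])
  denom_scale <- max(stats::sd(m[ok, control]), 1)
  bad <- ok & abs(m[, control]) < tol * denom_scale
  if (any(bad)) {
    warning(sum(bad), " genotype(s) excluded: near-zero control-system mean")
    ok <- ok & !bad
  }
  data.frame(genotype_id = rownames(m)[ok],
             index = (m[ok, stress] - m[ok, control]) / m[ok, control],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Population-level stress intensity
#'
#' The relative-performance index applied to population means:
#' \eqn{I = (\bar Y_{stress} - \bar Y_{control}) / \bar Y_{control}}, a
#' measure of the intensity of the stress the second system imposes.
#'
#' @inheritParams response_index
#' @return A single proportion (e.g. 0.074 for a 7.4% increase).
#' @export
population_stress_intensity <- function(means, stress = "AWD",
                                        control = "CF", trait = NULL) {
  m <- means_matrix(means, trait)
  if (!all(c(stress, control) %in% colnames(m)))
    stop("both systems must be present in the adjusted means")
  mc <- mean(m[, control], na.rm = TRUE)
  if (abs(mc) < .Machine$double.eps) stop("control-system mean is zero")
  (mean(m[, stress], na.rm = TRUE) - mc) / mc
}

#' Joint-regression (stability) coefficients per genotype
#'
#' Regresses each genotype's adjusted means on the environmental indices
#' \eqn{\theta_m} (the mean of all genotypes in system \eqn{m}):
#' \eqn{\hat Y_{jm} = \mu_j + \beta_j \theta_m + \varepsilon_{jm}}.
#' With exactly two environments the least-squares fit is exact and
#' \eqn{\beta_j = (\hat Y_{j2} - \hat Y_{j1}) / (\theta_2 - \theta_1)}.
#' By construction the mean of \eqn{\beta_j} over genotypes is 1.
#'
#' @inheritParams response_index
#' @return Data frame `genotype_id, intercept, slope`, with the environment
#'   indices in `attr(, "theta")`.
#' @export
joint_regression <- function(means, trait = NULL) {
  m <- means_matrix(means, trait)
  if (ncol(m) < 2L) stop("joint regression needs >= 2 environments")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  theta <- colMeans(m)
  if (max(theta) - min(theta) < .Machine$double.eps^0.5)
    stop("environment indices are identical; slope undefined")
  tc <- theta - mean(theta)
  beta <- drop(m %*% tc) / sum(tc^2)
  mu <- rowMeans(m) - beta * mean(theta)
  out <- data.frame(genotype_id = rownames(m), intercept = mu, slope = beta,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "theta") <- theta
  out
}

#' Fisher-transform confidence interval for a correlation
#'
#' \eqn{\hat Z = \tanh^{-1}(r)}, bounds \eqn{\hat Z \pm u_{1-\alpha/2} /
#' \sqrt{n - 3}}, back-transformed with \eqn{\tanh}.
#'
#' @param r Correlation in (-1, 1).
#' @param n Number of pairs (> 3).
#' @param alpha Two-sided error rate (default 0.05).
#' @return Named vector `c(r, lower, upper)`.
#' @examples
#' fisher_ci(0.955, 284)  # lower 0.943, upper 0.964
#' @export
fisher_ci <- function(r, n, alpha = 0.05) {
  if (n <= 3) stop("Fisher interval needs n > 3")
  if (abs(r) >= 1) stop("degenerate correlation |r| = 1")
  z <- atanh(r)
  hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  c(r = r, lower = tanh(z - hw), upper = tanh(z + hw))
}

#' Genetic correlation between systems with Fisher confidence interval
#'
#' Pearson correlation between per-genotype adjusted means under the two
#' systems, with the Fisher-transform interval of [fisher_ci()].
#'
#' @inheritParams response_index
#' @param n Number of genotypes used for the interval; defaults to the number
#'   of complete pairs.
#' @param alpha Two-sided error rate.
#' @return Named vector `c(r, lower, upper)` with `attr(, "n")`.
#' @export
genetic_correlation_ci <- function(means, stress = "AWD", control = "CF",
                                   trait = NULL, n = NULL, alpha = 0.05) {
  m <- means_matrix(means, trait)
  m <- m[stats::complete.cases(m[, c(stress, control)]), , drop = FALSE]
  if (is.null(n)) n <- nrow(m)
  r <- stats::cor(m[, stress], m[, control])
  out <- fisher_ci(r, n, alpha)
  attr(out, "n") <- n
  out
}

#' Spearman rank correlation of genotype means between systems
#'
#' Rank stability of genotypes across the two systems (ties mid-ranked).
#'
#' @inheritParams genetic_correlation_ci
#' @return Spearman's rho.
#' @export
system_rank_correlation <- function(means, stress = "AWD", control = "CF",
                                    trait = NULL) {
  m <- means_matrix(means, trait)
  m <- m[stats::complete.cases(m[, c(stress, control)]), , drop = FALSE]
  stats::cor(m[, stress], m[, control], method = "spearman")
}

#' Ratio of correlated to direct response to selection
#'
#' Expected response in the stress system from selecting in the control
#' system, relative to direct selection under stress:
#' \deqn{CR/DR = r_G \sqrt{H^2_{control} / H^2_{stress}}}
#'
#' @param rG Genetic correlation between the systems.
#' @param h2_control Broad-sense heritability under the control (selection)
#'   system.
#' @param h2_stress Broad-sense heritability under the stress (target)
#'   system.
#' @return The CR/DR ratio.
#' @examples
#' correlated_response_ratio(0.773, 0.85, 0.76)  # 0.817...
#' @export
correlated_response_ratio <- function(rG, h2_control, h2_stress) {
  if (h2_stress <= 0) stop("stress-system heritability must be > 0")
  if (h2_control < 0) stop("heritabilities must be >= 0")
  rG * sqrt(h2_control / h2_stress)
}

#' Assemble the full genotypic response profile
#'
#' Convenience wrapper combining [response_index()], [joint_regression()],
#' [population_stress_intensity()], [genetic_correlation_ci()] and
#' [system_rank_correlation()]; if the two heritabilities are supplied the
#' [correlated_response_ratio()] is added.
#'
#' @inheritParams genetic_correlation_ci
#' @param h2_control,h2_stress Optional heritabilities for the CR/DR ratio.
#' @return A `response_profile` list: `per_genotype` (index, intercept,
#'   slope), `stress_intensity`, `rG` (with CI), `spearman`, `cr_dr`.
#' @export
response_profile <- function(means, stress = "AWD", control = "CF",
                             trait = NULL, n = NULL, alpha = 0.05,
                             h2_control = NULL, h2_stress = NULL) {
  idx <- response_index(means, stress, control, trait)
  jr <- joint_regression(means, trait)
  per <- merge(idx, jr, by = "genotype_id")
  rg <- genetic_correlation_ci(means, stress, control, trait, n, alpha)
  cr <- if (!is.null(h2_control) && !is.null(h2_stress))
    correlated_response_ratio(rg["r"], h2_control, h2_stress) else NA_real_
  structure(list(
    per_genotype = per,
    stress_intensity = population_stress_intensity(means, stress, control,
                                                   trait),
    rG = rg,
    spearman = system_rank_correlation(means, stress, control, trait),
    cr_dr = unname(cr), theta = attr(jr, "theta")),
    class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf("response profile over %d genotypes\n", nrow(x$per_genotype)))
  cat(sprintf("  stress intensity: %+.1f%%\n", 100 * x$stress_intensity))
  cat(sprintf("  rG = %.3f [%.3f; %.3f]; Spearman rho = %.3f\n",
              x$rG["r"], x$rG["lower"], x$rG["upper"], x$spearman))
  if (!is.na(x$cr_dr)) cat(sprintf("  CR/DR ratio = %.2f\n", x$cr_dr))
  invisible(x)
}
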
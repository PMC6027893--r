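# Synthetic two-environment trial generator: genotypes for an inbred rice-like
# panel and replicated plot-level phenotypes with a controllable
# cross-environment genetic correlation.

#' Simulation configuration for a two-environment breeding trial
#'
#' Bundles the design and variance parameters used by [simulate_genotypes()]
#' and [simulate_trial()]. Defaults emulate the reference-panel conditions the
#' package is designed around: 284 inbred genotypes phenotyped for two years
#' with three replicates under two contrasting water-management systems
#' (continuous flooding, CF, and alternate wetting and drying, AWD), with a
#' genetic variance split giving a cross-environment genetic correlation of
#' 0.8 and an entry-mean heritability near 0.89.
#'
#' The genotypic value of genotype \eqn{j} in environment \eqn{e} is
#' \eqn{g_{je} = g_j + s_{je}}, where the main effect \eqn{g_j} is shared
#' across environments (variance `var_main`) and \eqn{s_{je}} is
#' environment-specific (variance `var_env_specific`). The implied
#' cross-environment genetic correlation is
#' \eqn{\rho = var\_main / (var\_main + var\_env\_specific)}.
#'
#' @param n_genotypes Number of genotypes (>= 2).
#' @param n_markers Number of biallelic SNPs simulated before filtering.
#' @param maf_range Length-2 numeric in (0, 0.5]: range of minor allele
#'   frequencies loci are drawn from.
#' @param n_environments Number of environments (default 2).
#' @param n_years Number of years (fixed effects).
#' @param n_reps Number of replicates per year.
#' @param var_main Variance of the cross-environment (main) genetic effect.
#' @param var_env_specific Variance of the environment-specific genetic effect.
#' @param var_gy Genotype-by-year interaction variance.
#' @param var_residual Plot residual variance.
#' @param env_means Named numeric vector of per-environment intercepts; names
#'   become the environment labels.
#' @param year_effects Numeric vector of per-year fixed shifts.
#' @param inbreeding Inbreeding coefficient F used when drawing genotypes;
#'   heterozygote frequency is 2p(1-p)(1-F). Advanced inbred lines are close
#'   to F = 1; the default 0.98 keeps heterozygosity below the 5% filter.
#' @param seed Integer seed making all generation reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genotypes = 50, n_markers = 200, seed = 1)
#' cfg$rho   # implied cross-environment genetic correlation
#' @export
sim_config <- function(n_genotypes = 284, n_markers = 2000,
                       maf_range = c(0.05, 0.5), n_environments = 2,
                       n_years = 2, n_reps = 3,
                       var_main = 46.1, var_env_specific = 11.5,
                       var_gy = 10.9, var_residual = 11.3,
                       env_means = c(CF = 93.4, AWD = 100.3),
                       year_effects = c(-6.6, 6.6),
                       inbreeding = 0.98, seed = 1L) {
  stopifnot(n_genotypes >= 2, n_markers >= 1, n_environments >= 1,
            n_years >= 1, n_reps >= 1)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]")
  vars <- c(var_main = var_main, var_env_specific = var_env_specific,
            var_gy = var_gy, var_residual = var_residual)
  if (any(vars < 0)) stop("all variance components must be >= 0")
  if (length(env_means) != n_environments)
    stop("env_means must have one entry per environment")
  if (is.null(names(env_means)))
    names(env_means) <- paste0("E", seq_len(n_environments))
  if (length(year_effects) != n_years)
    stop("year_effects must have one entry per year")
  if (inbreeding < 0 || inbreeding > 1) stop("inbreeding must be in [0,1]")
  rho <- if (var_main + var_env_specific > 0)
    var_main / (var_main + var_env_specific) else NA_real_
  structure(list(
    n_genotypes = as.integer(n_genotypes), n_markers = as.integer(n_markers),
    maf_range = maf_range, n_environments = as.integer(n_environments),
    n_years = as.integer(n_years), n_reps = as.integer(n_reps),
    var_main = var_main, var_env_specific = var_env_specific,
    var_gy = var_gy, var_residual = var_residual,
    env_means = env_means, year_effects = year_effects,
    inbreeding = inbreeding, seed = as.integer(seed), rho = rho),
    class = "sim_config")
}

# Run code with a private RNG stream; the caller's RNG state is untouched.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Construct a genotype matrix object
#'
#' @param codes Integer matrix in \{-1, 0, 1\} (minor-allele dosage centred at
#'   the heterozygote: -1 major homozygote, 0 heterozygote, 1 minor
#'   homozygote), genotypes in rows.
#' @param marker_ids,genotype_ids Optional dimension names.
#' @param report Optional filter report list.
#' @return A `genotype_matrix` object with per-marker `maf` and `het_rate`.
#' @export
genotype_matrix <- function(codes, marker_ids = colnames(codes),
                            genotype_ids = rownames(codes), report = NULL) {
  codes <- as.matrix(codes)
  if (!all(codes %in% c(-1L, 0L, 1L)))
    stop("genotype codes must be in {-1, 0, 1}")
  if (is.null(genotype_ids)) genotype_ids <- paste0("G", seq_len(nrow(codes)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(codes)))
  storage.mode(codes) <- "integer"
  dimnames(codes) <- list(genotype_ids, marker_ids)
  maf <- colMeans(codes + 1) / 2           # minor allele frequency
  het <- colMeans(codes == 0L)
  structure(list(codes = codes, marker_ids = marker_ids,
                 genotype_ids = genotype_ids, maf = maf, het_rate = het,
                 report = report),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d genotypes x %d markers\n",
              nrow(x$codes), ncol(x$codes)))
  cat(sprintf("  MAF range [%.3f, %.3f]; heterozygote rate range [%.3f, %.3f]\n",
              min(x$maf), max(x$maf), min(x$het_rate), max(x$het_rate)))
  if (!is.null(x$report))
    cat(sprintf("  filter report: %s\n",
                paste(names(x$report), unlist(x$report), sep = "=",
                      collapse = ", ")))
  invisible(x)
}

# Apply the standard marker filters (MAF > maf_min, heterozygosity < het_max)
# and return the filtered object plus a count report. Errors if nothing
# survives, naming the responsible filter.
filter_markers <- function(geno, maf_min = 0.05, het_max = 0.05) {
  keep_maf <- geno$maf > maf_min
  keep_het <- geno$het_rate < het_max
  keep <- keep_maf & keep_het
  if (!any(keep)) {
    culprit <- if (!any(keep_maf)) sprintf("MAF > %g", maf_min)
               else sprintf("heterozygosity < %g", het_max)
    stop("no markers retained after filtering (failing filter: ", culprit, ")")
  }
  report <- list(n_input = length(keep),
                 dropped_maf = sum(!keep_maf),
                 dropped_het = sum(!keep_het & keep_maf),
                 n_retained = sum(keep))
  genotype_matrix(geno$codes[, keep, drop = FALSE], report = report)
}

#' Simulate filtered biallelic genotypes for an inbred panel
#'
#' Draws unlinked loci with minor allele frequencies uniform in
#' `config$maf_range`, samples genotypes under Hardy-Weinberg proportions
#' generalised for inbreeding coefficient `config$inbreeding`, codes them as
#' minor-allele dosage \{-1, 0, 1\}, and applies the standard panel filters
#' (MAF > 5%, heterozygosity < 5%).
#'
#' @param config A [sim_config()].
#' @param maf_min,het_max Filter thresholds.
#' @return A `genotype_matrix` with a filter report.
#' @examples
#' g <- simulate_genotypes(sim_config(n_genotypes = 60, n_markers = 300))
#' all(g$maf > 0.05)
#' @export
simulate_genotypes <- function(config, maf_min = 0.05, het_max = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_genotypes; p <- config$n_markers
    f <- runif(p, config$maf_range[1], config$maf_range[2])
    Fc <- config$inbreeding
    # genotype frequencies with inbreeding: P(het) = 2p(1-p)(1-F)
    p_het <- 2 * f * (1 - f) * (1 - Fc)
    p_min <- f^2 + f * (1 - f) * Fc        # minor homozygote
    u <- matrix(runif(n * p), n, p)
    codes <- matrix(-1L, n, p)
    codes[u < rep(p_het, each = n)] <- 0L
    codes[u >= rep(p_het, each = n) &
          u < rep(p_het + p_min, each = n)] <- 1L
    # recode: -1 should be the MAJOR homozygote; swap where sampling made the
    # "minor" allele the more frequent one in the realised matrix
    geno <- genotype_matrix(codes)
    flip <- geno$maf > 0.5
    if (any(flip)) {
      codes[, flip] <- -codes[, flip]
      geno <- genotype_matrix(codes)
    }
    filter_markers(geno, maf_min = maf_min, het_max = het_max)
  })
}

#' Simulate plot-level phenotypes for a multi-environment trial
#'
#' Builds true genotypic values from marker effects and generates plot
#' phenotypes
#' \deqn{y = \mu_e + year_y + g_j + s_{je} + (gy)_{jye} + \varepsilon}
#' where the main genetic value \eqn{g_j = X a} and environment-specific
#' deviation \eqn{s_{je} = X b_e} come from i.i.d. Gaussian marker effects
#' scaled so the realised genetic variances match `var_main` and
#' `var_env_specific` in expectation, giving an expected cross-environment
#' genetic correlation of `config$rho`.
#'
#' @param genotypes A `genotype_matrix`.
#' @param config The [sim_config()] used (variances, design sizes, seed).
#' @param trait Trait label recorded in the output.
#' @return A `trial_observations` data frame with columns
#'   `genotype_id, environment, year, replicate, trait, value`, carrying the
#'   true genotypic values per environment in `attr(, "true_values")`.
#' @examples
#' cfg <- sim_config(n_genotypes = 40, n_markers = 200, seed = 2)
#' obs <- simulate_trial(simulate_genotypes(cfg), cfg)
#' head(obs)
#' @export
simulate_trial <- function(genotypes, config, trait = "trait") {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  n <- nrow(genotypes$codes)
  if (n != config$n_genotypes)
    stop("genotype matrix size does not match config$n_genotypes")
  with_seed(config$seed + 1L, {
    Xc <- scale(genotypes$codes, center = TRUE, scale = FALSE)
    p <- ncol(Xc)
    trK <- sum(Xc^2)                       # tr(Xc Xc')
    # effect-size variance so that the sample variance of X a has expectation
    # var_main (and likewise for the environment-specific term)
    tau_main <- if (trK > 0) sqrt(config$var_main * (n - 1) / trK) else 0
    tau_env  <- if (trK > 0) sqrt(config$var_env_specific * (n - 1) / trK) else 0
    g_main <- drop(Xc %*% rnorm(p, 0, tau_main))
    envs <- names(config$env_means)
    true_g <- sapply(envs, function(e)
      g_main + drop(Xc %*% rnorm(p, 0, tau_env)))
    rownames(true_g) <- genotypes$genotype_ids

    years <- paste0("Y", seq_len(config$n_years))
    grid <- expand.grid(genotype_id = genotypes$genotype_ids,
                        environment = envs, year = years,
                        replicate = seq_len(config$n_reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gy <- array(rnorm(n * length(envs) * config$n_years, 0,
                      sqrt(config$var_gy)),
                dim = c(n, length(envs), config$n_years),
                dimnames = list(genotypes$genotype_ids, envs, years))
    gi <- match(grid$genotype_id, genotypes$genotype_ids)
    ei <- match(grid$environment, envs)
    yi <- match(grid$year, years)
    grid$trait <- trait
    grid$value <- config$env_means[ei] + config$year_effects[yi] +
      true_g[cbind(gi, ei)] + gy[cbind(gi, ei, yi)] +
      rnorm(nrow(grid), 0, sqrt(config$var_residual))
    obs <- structure(grid, class = c("trial_observations", "data.frame"))
    attr(obs, "true_values") <- true_g
    attr(obs, "config") <- config
    obs
  })
}

#' Mask observations to emulate prediction designs
#'
#' Removes the plot records of the named genotypes in the named environments,
#' e.g. all environments (the M1 cross-validation situation: validation
#' genotypes unobserved everywhere) or a single environment (M2: the genotype
#' remains observed elsewhere).
#'
#' @param obs A `trial_observations` data frame.
#' @param genotypes Character vector of genotype ids to mask.
#' @param environments Character vector of environments in which to mask them;
#'   default all environments present.
#' @return The masked `trial_observations`; the removed cells are recorded in
#'   `attr(, "masking_log")`.
#' @export
mask_observations <- function(obs, genotypes = character(),
                              environments = unique(obs$environment)) {
  stopifnot(is.data.frame(obs))
  drop <- obs$genotype_id %in% genotypes & obs$environment %in% environments
  out <- obs[!drop, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("masking removed every observation; no training data left")
  log_new <- if (any(drop))
    unique(obs[drop, c("genotype_id", "environment")]) else
    obs[0, c("genotype_id", "environment")]
  prev <- attr(obs, "masking_log")
  attr(out, "masking_log") <- rbind(prev, log_new)
  attr(out, "true_values") <- attr(obs, "true_values")
  attr(out, "config") <- attr(obs, "config")
  class(out) <- class(obs)
  out
}
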
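# Validation designs: random 80/20 partitions (single-environment, M1, M2),
# cross-validation runner, predictive ability, Z-transformed factorial
# analysis, CDmean training-set optimization and progeny validation.

#' Random training/validation partitions for cross-validation
#'
#' Draws `n_reps` uniformly random splits of the population into a training
#' fraction and a validation remainder. Scheme semantics:
#' * `"single"` / `"M1"`: validation genotypes are unobserved in every
#'   environment;
#' * `"M2"`: each validation genotype keeps its phenotype in exactly one
#'   environment (assigned at random, balanced across environments within
#'   each replicate) and is predicted in the other(s).
#'
#' @param population Character vector of genotype ids.
#' @param fraction Training fraction in (0, 1); 0.8 gives the 227/57 split
#'   at N = 284.
#' @param n_reps Number of random partitions (default 100).
#' @param scheme `"single"`, `"M1"` or `"M2"`.
#' @param environments Environment labels (required for `"M2"`).
#' @param seed Integer seed.
#' @return A list of `partition_plan` objects (`replicate`, `training`,
#'   `validation`, `scheme`, and for M2 `observed_env`, a named vector giving
#'   each validation genotype's observed environment).
#' @export
make_partitions <- function(population, fraction = 0.8, n_reps = 100L,
                            scheme = c("single", "M1", "M2"),
                            environments = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  N <- length(population)
  if (N < 5L) stop("population too small to partition")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  if (scheme == "M2" && length(environments) < 2L)
    stop("M2 needs >= 2 environment labels")
  n_train <- round(fraction * N)
  with_seed(seed, lapply(seq_len(n_reps), function(r) {
    train <- sample(population, n_train)
    valid <- setdiff(population, train)
    obs_env <- NULL
    if (scheme == "M2") {
      # balanced assignment of the single observed environment
      envs <- rep(environments, length.out = length(valid))
      obs_env <- stats::setNames(sample(envs), valid)
    }
    structure(list(replicate = r, training = train, validation = valid,
                   scheme = scheme, observed_env = obs_env, seed = seed),
              class = "partition_plan")
  }))
}

# apply a partition plan to a genotype x environment phenotype matrix,
# masking the cells the scheme declares unobserved
mask_phenotype_matrix <- function(Y, plan) {
  Ym <- Y
  if (plan$scheme %in% c("single", "M1")) {
    Ym[plan$validation, ] <- NA
  } else {
    for (g in plan$validation)
      Ym[g, setdiff(colnames(Y), plan$observed_env[[g]])] <- NA
  }
  Ym
}

#' Predictive ability: Pearson correlation by stratum
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @param strata Optional factor splitting the pairs (e.g. environment);
#'   `NULL` computes one overall correlation.
#' @return Data frame `stratum, r, n`; strata with < 3 complete pairs or
#'   zero variance give `NA` with a warning.
#' @export
predictive_ability <- function(predicted, observed, strata = NULL) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (is.null(strata)) strata <- rep("all", length(predicted))
  out <- lapply(split(seq_along(predicted), strata), function(i) {
    ok <- stats::complete.cases(predicted[i], observed[i])
    if (sum(ok) < 3L) {
      warning("fewer than 3 complete pairs in a stratum; r undefined")
      return(NA_real_)
    }
    p <- predicted[i][ok]; o <- observed[i][ok]
    if (stats::sd(p) == 0 || stats::sd(o) == 0) {
      warning("zero variance in a stratum; r undefined")
      return(NA_real_)
    }
    stats::cor(p, o)
  })
  data.frame(stratum = names(out), r = unlist(out),
             n = as.vector(table(strata)[names(out)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher Z-transform of a correlation
#' @param r Correlation in (-1, 1).
#' @return `0.5 * (log(1 + r) - log(1 - r))`.
#' @export
fisher_z <- function(r) atanh(r)

# fit one model on a masked phenotype matrix and return predictions as a
# genotype x environment matrix
fit_and_predict <- function(model, kernels, Ym, spec) {
  envs <- colnames(Ym)
  K <- switch(model,
              "GBLUP" = , "GBLUP-GxE" = kernels$K_linear,
              kernels$K_gauss)
  spec$model <- model
  if (model %in% c("GBLUP", "RKHS")) {
    P <- matrix(NA_real_, nrow(Ym), ncol(Ym), dimnames = dimnames(Ym))
    for (e in envs) {
      fit <- fit_single_env(K, Ym[, e], spec)
      P[, e] <- fit$predictions$pred
    }
    return(P)
  }
  fit <- switch(model,
                "GBLUP-GxE" = fit_gblup_gxe(K, Ym, spec),
                "RKHS-1" = fit_rkhs1(K, Ym, spec),
                "RKHS-2" = fit_rkhs2(K, Ym, spec))
  pr <- fit$predictions
  P <- matrix(NA_real_, nrow(Ym), ncol(Ym), dimnames = dimnames(Ym))
  P[cbind(match(pr$genotype_id, rownames(Ym)),
          match(pr$environment, envs))] <- pr$pred
  P
}

#' Run a cross-validation prediction experiment
#'
#' For each random partition and each model, masks the validation phenotypes
#' according to the scheme, fits the model on the training data, predicts the
#' validation genotypes, and records the per-environment predictive ability.
#' The same partitions are reused across models so comparisons are paired.
#'
#' @param Y Genotype x environment matrix of phenotypes (adjusted means).
#' @param kernels A [kernel_set()] over the same genotypes.
#' @param models Character vector of model names (see [model_spec()]).
#' @param schemes Character vector of partition schemes (`"single"`, `"M1"`,
#'   `"M2"`); single-environment models are only meaningful with genotype-out
#'   masking and are fitted per environment.
#' @param n_reps Number of partitions.
#' @param fraction Training fraction.
#' @param spec Base [model_spec()] (chain settings shared by all fits).
#' @param trait Trait label stored in the records.
#' @param seed Seed for the partitions.
#' @return Data frame of ability records: `replicate, trait, model, scheme,
#'   environment, r, Z`, with failed fits logged in `attr(, "failures")`.
#' @export
run_cv_experiment <- function(Y, kernels, models = "GBLUP",
                              schemes = c("single", "M1", "M2"),
                              n_reps = 10L, fraction = 0.8,
                              spec = model_spec(), trait = "trait",
                              seed = 1L) {
  Y <- as.matrix(Y)
  envs <- colnames(Y)
  plans <- make_partitions(rownames(Y), fraction = fraction, n_reps = n_reps,
                           scheme = "M2", environments = envs, seed = seed)
  records <- list(); failures <- list()
  for (plan in plans) {
    for (scheme in schemes) {
      plan2 <- plan; plan2$scheme <- scheme
      Ym <- mask_phenotype_matrix(Y, plan2)
      for (model in models) {
        single <- model %in% c("GBLUP", "RKHS")
        if (single && scheme == "M2") next   # no masked cell to predict from
        fit_spec <- spec
        fit_spec$seed <- spec$seed + plan$replicate
        P <- tryCatch(fit_and_predict(model, kernels, Ym, fit_spec),
                      error = function(e) e)
        if (inherits(P, "error")) {
          failures[[length(failures) + 1L]] <-
            data.frame(replicate = plan$replicate, model = model,
                       scheme = scheme, message = conditionMessage(P))
          next
        }
        for (e in envs) {
          vg <- if (scheme == "M2")
            plan2$validation[plan2$observed_env[plan2$validation] != e]
          else plan2$validation
          if (length(vg) < 3L) next
          r <- predictive_ability(P[vg, e], Y[vg, e])$r
          records[[length(records) + 1L]] <-
            data.frame(replicate = plan$replicate, trait = trait,
                       model = model, scheme = scheme, environment = e,
                       r = r, Z = fisher_z(r), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, records)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
  out
}

#' Summarise ability records: mean and standard error per group
#'
#' @param records Output of [run_cv_experiment()] or
#'   [run_progeny_validation()].
#' @param by Grouping columns (default model, scheme, environment).
#' @return Data frame with `mean_r`, `se_r`, `n` per group.
#' @export
summarise_ability <- function(records,
                              by = c("model", "scheme", "environment")) {
  by <- intersect(by, names(records))
  agg <- stats::aggregate(records$r, records[by], function(x)
    c(mean = mean(x, na.rm = TRUE),
      se = stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))),
      n = sum(!is.na(x))))
  out <- cbind(agg[by], as.data.frame(agg$x))
  names(out)[(ncol(out) - 2):ncol(out)] <- c("mean_r", "se_r", "n")
  out
}

#' Factorial ANOVA on Z-transformed predictive abilities
#'
#' Fits a fixed-effects ANOVA of the Fisher-Z-transformed ability on the
#' named factors (main effects, optionally all first-order interactions) and
#' reports the classic table (DF, SS, MS, F, p) together with the model
#' coefficient of determination, coefficient of variation, RMSE, overall
#' mean of Z, and back-transformed (tanh) means per factor level.
#'
#' @param records Ability record data frame with a `Z` column.
#' @param factors Character vector of factor column names.
#' @param interactions Include all first-order interactions.
#' @return A `z_anova` list: `table`, `r2`, `cv`, `rmse`, `mean_z`,
#'   `level_means` (back-transformed to the r scale).
#' @export
zstat_anova <- function(records, factors, interactions = FALSE) {
  stopifnot(all(factors %in% names(records)), "Z" %in% names(records))
  d <- records[stats::complete.cases(records[c(factors, "Z")]), ]
  for (f in factors) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) < 2L) stop("factor ", f, " has < 2 levels")
  }
  rhs <- if (interactions && length(factors) > 1L)
    paste0("(", paste(factors, collapse = " + "), ")^2")
  else paste(factors, collapse = " + ")
  form <- stats::as.formula(paste("Z ~", rhs))
  fit <- stats::aov(form, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("aliased factors: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  an <- stats::anova(fit)
  tab <- data.frame(Source = rownames(an), DF = an$Df, SS = an$`Sum Sq`,
                    MS = an$`Mean Sq`, FValue = an$`F value`,
                    ProbF = an$`Pr(>F)`, row.names = NULL)
  ss_err <- tab$SS[tab$Source == "Residuals"]
  ss_tot <- sum(tab$SS)
  mse <- tab$MS[tab$Source == "Residuals"]
  level_means <- lapply(stats::setNames(factors, factors), function(f)
    tanh(tapply(d$Z, d[[f]], mean)))
  structure(list(table = tab, r2 = 1 - ss_err / ss_tot,
                 cv = 100 * sqrt(mse) / mean(d$Z), rmse = sqrt(mse),
                 mean_z = mean(d$Z), level_means = level_means, fit = fit),
            class = "z_anova")
}

#' @export
print.z_anova <- function(x, ...) {
  cat(sprintf("ANOVA on Z-transformed ability: R2 = %.3f, CV = %.2f%%, RMSE = %.3f, mean Z = %.3f\n",
              x$r2, x$cv, x$rmse, x$mean_z))
  print(x$table, digits = 4)
  invisible(x)
}

#' CDmean training-set optimization by greedy exchange
#'
#' Selects a training set maximising the mean coefficient of determination
#' of predicting the non-selected candidates under the kernel mixed model:
#' for candidate \eqn{i} outside the training set \eqn{T},
#' \deqn{CD_i = K_{i,T} M K_{T,i} / K_{ii}, \quad
#'   M = A^{-1} - A^{-1} 1 (1' A^{-1} 1)^{-1} 1' A^{-1},
#'   \quad A = K_{T,T} + \lambda I,}
#' with \eqn{\lambda = \sigma_e^2 / \sigma_g^2}. Random single swaps between
#' the selected and unselected sets are proposed and accepted only when the
#' objective improves, so the objective trace is non-decreasing.
#'
#' @param K Relationship kernel over all candidates (rownames = ids).
#' @param candidates Ids to select from (default all rows of `K`).
#' @param target_size Training-set size (e.g. 100).
#' @param lambda Variance ratio; default `(1 - h2) / h2` with `h2`.
#' @param h2 Heritability used for the default `lambda` (default 0.5).
#' @param n_iter Number of exchange proposals.
#' @param seed Integer seed.
#' @return Character vector of selected ids with attributes `cdmean` (final
#'   objective) and `trace` (objective after each accepted state).
#' @export
cdmean_select <- function(K, candidates = rownames(K), target_size = 100L,
                          lambda = NULL, h2 = 0.5, n_iter = 500L, seed = 1L) {
  if (is.null(lambda)) lambda <- (1 - h2) / h2
  if (is.null(candidates)) candidates <- as.character(seq_len(nrow(K)))
  if (is.null(rownames(K)))
    dimnames(K) <- list(candidates, candidates)
  n <- length(candidates)
  if (target_size >= n) {
    warning("target_size covers all candidates; returning the full set")
    out <- candidates
    attr(out, "cdmean") <- NA_real_
    attr(out, "trace") <- numeric()
    return(out)
  }
  Kc <- K[candidates, candidates]
  objective <- function(sel) {
    A <- Kc[sel, sel] + lambda * diag(length(sel))
    Ai <- tryCatch(solve(A), error = function(e)
      solve(A + 1e-8 * mean(diag(A)) * diag(length(sel))))
    a1 <- rowSums(Ai)
    M <- Ai - outer(a1, a1) / sum(a1)
    out_ids <- setdiff(seq_len(n), sel)
    Kot <- Kc[out_ids, sel, drop = FALSE]
    cd <- rowSums((Kot %*% M) * Kot) / diag(Kc)[out_ids]
    mean(cd)
  }
  with_seed(seed, {
    sel <- sample(n, target_size)
    best <- objective(sel)
    trace <- best
    for (i in seq_len(n_iter)) {
      cand <- sel
      cand[sample.int(target_size, 1L)] <-
        sample(setdiff(seq_len(n), sel), 1L)
      val <- objective(cand)
      if (val > best) {
        sel <- cand; best <- val
      }
      trace <- c(trace, best)
    }
    out <- candidates[sel]
    attr(out, "cdmean") <- best
    attr(out, "trace") <- trace
    out
  })
}

#' Progeny validation across populations
#'
#' Trains on a scenario-defined subset of the reference population and
#' predicts all progeny genotypes:
#' * `"S1"`: only the parental lines;
#' * `"S2"`: a CDmean-optimised subset of the reference (default size 100);
#' * `"S3"`: the whole reference population.
#'
#' @param Y_ref Reference genotype x environment phenotype matrix.
#' @param Y_prog Progeny genotype x environment phenotype matrix (observed
#'   values used only for validation).
#' @param kernels A [kernel_set()] over reference and progeny genotypes
#'   jointly (common marker set).
#' @param scenario `"S1"`, `"S2"` or `"S3"`.
#' @param parents Character vector of parental ids (required for S1).
#' @param models Models to fit (single-environment models are fitted per
#'   environment).
#' @param spec Base [model_spec()].
#' @param s2_size CDmean training-set size for S2.
#' @param trait Trait label for the records.
#' @param seed Seed (CDmean and sampler).
#' @return Ability records `trait, model, scenario, environment, r, n_train`.
#' @export
run_progeny_validation <- function(Y_ref, Y_prog, kernels,
                                   scenario = c("S1", "S2", "S3"),
                                   parents = NULL, models = "GBLUP",
                                   spec = model_spec(), s2_size = 100L,
                                   trait = "trait", seed = 1L) {
  scenario <- match.arg(scenario)
  ref_ids <- rownames(Y_ref); prog_ids <- rownames(Y_prog)
  all_ids <- kernels$genotype_ids
  if (!all(c(ref_ids, prog_ids) %in% all_ids))
    stop("kernel must cover all reference and progeny genotypes")
  training <- switch(scenario,
    S1 = {
      if (is.null(parents)) stop("S1 needs the parental ids")
      intersect(parents, ref_ids)
    },
    S2 = cdmean_select(kernels$K_linear[ref_ids, ref_ids],
                       candidates = ref_ids, target_size = s2_size,
                       seed = seed),
    S3 = ref_ids)
  envs <- colnames(Y_ref)
  Y_all <- matrix(NA_real_, length(all_ids), length(envs),
                  dimnames = list(all_ids, envs))
  Y_all[training, ] <- Y_ref[training, envs]
  records <- list()
  for (model in models) {
    fit_spec <- spec; fit_spec$seed <- spec$seed + seed
    P <- fit_and_predict(model, kernels, Y_all, fit_spec)
    for (e in envs) {
      r <- predictive_ability(P[prog_ids, e], Y_prog[, e])$r
      records[[length(records) + 1L]] <-
        data.frame(trait = trait, model = model, scenario = scenario,
                   environment = e, r = r, Z = fisher_z(r),
                   n_train = length(training), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, records)
}
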
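# Marker-based relationship kernels: linear (GBLUP) and Gaussian (RKHS),
# plus empirical-Bayes estimation of the Gaussian bandwidth.

geno_codes <- function(geno) {
  if (inherits(geno, "genotype_matrix")) geno$codes else as.matrix(geno)
}

#' Linear (GBLUP) relationship kernel
#'
#' \eqn{K = X X'} with `X` the column-centred genotype matrix coded
#' (-1, 0, 1). Not rescaled by marker count by default: the scale is absorbed
#' by the model's genetic variance parameter.
#'
#' @param geno A `genotype_matrix` or a numeric genotype matrix (genotypes in
#'   rows).
#' @param center Centre marker columns first (default `TRUE`).
#' @param scale_mean_diag Divide by the mean diagonal so the average
#'   self-relationship is 1 (off by default).
#' @return A symmetric positive semi-definite N x N matrix.
#' @export
linear_kernel <- function(geno, center = TRUE, scale_mean_diag = FALSE) {
  X <- geno_codes(geno)
  if (nrow(X) < 2L) stop("need >= 2 genotypes")
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  K <- tcrossprod(X)
  if (scale_mean_diag) {
    md <- mean(diag(K))
    if (md > 0) K <- K / md
  }
  K
}

# squared Euclidean distance matrix between genotype rows
squared_distances <- function(X) {
  d2 <- as.matrix(stats::dist(X))^2
  diag(d2) <- 0
  d2
}

#' Gaussian (RKHS) relationship kernel
#'
#' \eqn{K(x_i, x_j) = \exp(-h \lVert x_i - x_j \rVert^2)} on centred marker
#' codes. Entries lie in (0, 1] with a unit diagonal, and decrease
#' monotonically in the bandwidth `h` off the diagonal.
#'
#' @param geno A `genotype_matrix` or numeric matrix (genotypes in rows).
#' @param h Positive bandwidth.
#' @param center Centre marker columns before computing distances.
#' @param scale_dist Divide squared distances by their off-diagonal mean
#'   before exponentiating (common practice; off by default, matching the
#'   plain formula).
#' @return A symmetric N x N matrix with unit diagonal.
#' @export
gaussian_kernel <- function(geno, h, center = TRUE, scale_dist = FALSE) {
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("bandwidth h must be a positive scalar")
  X <- geno_codes(geno)
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  d2 <- squared_distances(X)
  if (scale_dist) {
    m <- mean(d2[upper.tri(d2)])
    if (m > 0) d2 <- d2 / m
  }
  exp(-h * d2)
}

# Restricted log-likelihood of y = 1*mu + u + e, u ~ N(0, su2*K),
# profiled over mu and the residual variance, as a function of the
# variance ratio phi = su2/se2, given the eigendecomposition of K.
profile_reml_gauss <- function(ev, Uty, Ut1, phi) {
  w <- phi * ev + 1
  xwx <- sum(Ut1^2 / w)
  beta <- sum(Ut1 * Uty / w) / xwx
  r <- Uty - beta * Ut1
  rss <- sum(r^2 / w)
  n1 <- length(Uty) - 1
  s2 <- rss / n1
  -0.5 * (n1 * log(s2) + sum(log(w)) + log(xwx) + n1)
}

#' Empirical-Bayes bandwidth for the Gaussian kernel
#'
#' Chooses the bandwidth `h` maximising the restricted marginal
#' log-likelihood of the Gaussian-kernel mixed model
#' \eqn{y = \mu + u + \varepsilon}, \eqn{u \sim N(0, \sigma_u^2 K(h))},
#' profiled over the genetic/residual variance ratio on a log grid, plus a
#' gamma log-prior on `h` (shape/scale parameterization; the default shape 3,
#' scale 1.5 puts the prior mode at \eqn{(3-1)\times 1.5 = 3}). The posterior
#' mode is located on a log-spaced grid and refined by golden-section
#' search; when the data carry no genetic signal the likelihood is flat in
#' `h` and the estimate falls back towards the prior mode.
#'
#' @param geno A `genotype_matrix` or numeric matrix.
#' @param phenotype Numeric vector aligned with the genotype rows.
#' @param prior_shape,prior_scale Gamma prior hyperparameters for `h`.
#' @param h_grid Positive grid of candidate bandwidths (default 40 log-spaced
#'   points spanning the prior mode).
#' @param ratio_grid Log grid for the profiled variance ratio.
#' @param center,scale_dist Passed to the distance computation (see
#'   [gaussian_kernel()]).
#' @return The estimated bandwidth, with the objective trace in
#'   `attr(, "objective")`.
#' @export
estimate_bandwidth <- function(geno, phenotype, prior_shape = 3,
                               prior_scale = 1.5,
                               h_grid = exp(seq(log(0.005), log(30),
                                                length.out = 40)),
                               ratio_grid = exp(seq(log(1e-4), log(1e4),
                                                    length.out = 41)),
                               center = TRUE, scale_dist = FALSE) {
  X <- geno_codes(geno)
  y <- as.numeric(phenotype)
  if (length(y) != nrow(X)) stop("phenotype not aligned with genotypes")
  if (any(h_grid <= 0)) stop("h_grid must be positive")
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  d2 <- squared_distances(X)
  if (scale_dist) d2 <- d2 / mean(d2[upper.tri(d2)])
  ones <- rep(1, length(y))

  objective <- function(h) {
    E <- eigen(exp(-h * d2), symmetric = TRUE)
    Uty <- drop(crossprod(E$vectors, y))
    Ut1 <- drop(crossprod(E$vectors, ones))
    ll <- max(vapply(ratio_grid, function(phi)
      profile_reml_gauss(pmax(E$values, 0), Uty, Ut1, phi), numeric(1)))
    ll + stats::dgamma(h, shape = prior_shape, scale = prior_scale,
                       log = TRUE)
  }
  obj <- vapply(h_grid, objective, numeric(1))
  if (max(obj) - min(obj) < 1e-10) {
    warning("flat bandwidth objective; returning the prior mode")
    h <- (prior_shape - 1) * prior_scale
    attr(h, "objective") <- data.frame(h = h_grid, objective = obj)
    return(h)
  }
  i <- which.max(obj)
  lo <- h_grid[max(1L, i - 1L)]
  hi <- h_grid[min(length(h_grid), i + 1L)]
  opt <- stats::optimize(objective, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-4 * (hi - lo))
  h <- if (opt$objective >= obj[i]) opt$maximum else h_grid[i]
  attr(h, "objective") <- data.frame(h = h_grid, objective = obj)
  h
}

#' Build the kernel set used by the prediction models
#'
#' Computes the linear kernel, the Gaussian-kernel bandwidth (from the
#' supplied phenotype) and the Gaussian kernel, and keeps the centred marker
#' matrix and squared-distance matrix alongside.
#'
#' @param geno A `genotype_matrix` or numeric matrix.
#' @param phenotype Phenotype vector used for bandwidth estimation; if
#'   `NULL`, `h` must be supplied.
#' @param h Optional fixed bandwidth (skips estimation).
#' @param scale_dist Divide squared distances by their off-diagonal mean;
#'   applied consistently to both the bandwidth estimation and the Gaussian
#'   kernel, so `h` is always on the metric the kernel uses.
#' @param ... Passed to [estimate_bandwidth()].
#' @return A `kernel_set` list: `K_linear`, `K_gauss`, `h`, `X` (centred),
#'   `D2` (on the metric used), `genotype_ids`.
#' @export
kernel_set <- function(geno, phenotype = NULL, h = NULL, scale_dist = FALSE,
                       ...) {
  X <- geno_codes(geno)
  ids <- rownames(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  d2 <- squared_distances(Xc)
  if (scale_dist) d2 <- d2 / mean(d2[upper.tri(d2)])
  if (is.null(h)) {
    if (is.null(phenotype)) stop("supply a phenotype or a fixed bandwidth h")
    h <- estimate_bandwidth(geno, phenotype, scale_dist = scale_dist, ...)
  }
  Kg <- exp(-as.numeric(h) * d2)
  dimnames(Kg) <- list(ids, ids)
  structure(list(K_linear = tcrossprod(Xc), K_gauss = Kg,
                 h = as.numeric(h), X = Xc, D2 = d2,
                 genotype_ids = ids),
            class = "kernel_set")
}

#' Write / read a kernel as a square CSV with genotype-id headers
#'
#' @param K Square matrix with genotype ids as dimnames.
#' @param path File path.
#' @return `read_kernel` returns the matrix.
#' @export
write_kernel <- function(K, path) {
  utils::write.csv(as.data.frame(K), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}
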
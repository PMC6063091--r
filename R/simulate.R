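#' Simulation design
#'
#' Bundles the parameters of a simulation study: dimensions, the uniform
#' MAF law on `[maf_low, maf_high]`, true parameters `psi0` and `theta0`,
#' the causal-subset size `k`, the replicate structure (I causal sets by J
#' phenotype replicates), a seed, and an optional genotype-error rate.
#' Defaults follow the study conditions used throughout: MAF uniform on
#' [0.05, 0.5], theta0 = 1, and a desk-scale design of n = 500, p = 2000,
#' I = 50, J = 100 for the causal-subset study.
#'
#' @param n individuals; @param p SNPs.
#' @param psi0 true heritability in [0, 1).
#' @param theta0 true noise precision (> 0).
#' @param k number of causal SNPs (defaults to p: fully causal).
#' @param n_causal_sets,n_reps causal-set count I and replicate count J.
#' @param maf_low,maf_high MAF range, 0 < maf_low <= maf_high <= 0.5.
#' @param genotype_error_pi per-entry genotype error probability.
#' @param seed integer seed making every generated object reproducible.
#' @return Object of class `sim_design`.
#' @export
sim_design <- function(n = 500L, p = 2000L, psi0 = 0.5, theta0 = 1,
                       k = p, n_causal_sets = 50L, n_reps = 100L,
                       maf_low = 0.05, maf_high = 0.5,
                       genotype_error_pi = 0, seed = 1L) {
  stopifnot(n >= 2L, p >= 1L, k >= 1L, k <= p,
            psi0 >= 0, psi0 < 1, theta0 > 0,
            maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
            genotype_error_pi >= 0, genotype_error_pi <= 1)
  structure(
    list(n = as.integer(n), p = as.integer(p), psi0 = psi0, theta0 = theta0,
         k = as.integer(k), n_causal_sets = as.integer(n_causal_sets),
         n_reps = as.integer(n_reps), maf_low = maf_low, maf_high = maf_high,
         genotype_error_pi = genotype_error_pi, seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' Generate binomial genotypes
#'
#' Draws per-site minor allele frequencies uniformly on
#' `[maf_low, maf_high]`, then assigns each individual at each site a
#' Binomial(2, MAF) minor-allele count, and normalizes each column to mean 0
#' and variance 1. A column constant by chance is resampled once; a second
#' failure is an error.
#'
#' @param design a `sim_design`.
#' @param seed overrides `design$seed` when given.
#' @return A `genotype_matrix` (per-column normalization) with attributes
#'   `maf` (the site frequencies) on the object.
#' @export
gen_genotypes <- function(design, seed = design$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- design$n
  p <- design$p
  maf <- runif(p, design$maf_low, design$maf_high)
  raw <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  const <- which(apply(raw, 2L, function(x) all(x == x[1L])))
  if (length(const) > 0L) {
    for (j in const) raw[, j] <- rbinom(n, 2L, maf[j])
    still <- which(apply(raw[, const, drop = FALSE], 2L,
                         function(x) all(x == x[1L])))
    if (length(still) > 0L) {
      stop(sprintf("column %d constant even after resampling; increase n or maf_low", const[still[1L]]))
    }
  }
  G <- normalize_genotypes(raw, "per_column")
  G$maf <- maf
  G
}

#' Generate a phenotype from the random-effects model
#'
#' Full model (`eta = NULL`): effect sizes u i.i.d.
#' \eqn{N(0, \phi_0/(p\theta_0))}, noise \eqn{N(0, 1/\theta_0)},
#' y = Z u + eps. Causal model (`eta` a subset of size k): u is supported on
#' eta, drawn i.i.d. normal and rescaled so the sum of squares equals
#' \eqn{\sigma_g^2 = \psi_0/(\theta_0(1-\psi_0))} exactly, with noise
#' variance \eqn{\sigma_e^2 = \sigma_g^2(1-\psi_0)/\psi_0 = 1/\theta_0}.
#'
#' @param G a `genotype_matrix`.
#' @param design a `sim_design` (supplies psi0, theta0).
#' @param eta optional integer vector of causal SNP indices.
#' @param seed optional seed.
#' @return List: `y`, `u`, `eps`.
#' @export
gen_trait <- function(G, design, eta = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- G$n
  p <- G$p
  psi0 <- design$psi0
  theta0 <- design$theta0
  if (is.null(eta)) {
    phi0 <- psi0 / (1 - psi0)
    u <- rnorm(p, sd = sqrt(phi0 / (p * theta0)))
  } else {
    if (psi0 <= 0) stop("causal model requires psi0 > 0")
    k <- length(eta)
    if (k < 1L) stop("eta must be nonempty in the causal model")
    sigma_g2 <- psi0 / (theta0 * (1 - psi0))
    u <- numeric(p)
    raw_u <- rnorm(k)
    u[eta] <- raw_u * sqrt(sigma_g2 / sum(raw_u^2))
  }
  eps <- rnorm(n, sd = sqrt(1 / theta0))
  list(y = drop(G$Z %*% u) + eps, u = u, eps = eps)
}

#' Generate rotated observations directly from a spectrum
#'
#' The fast genotype-free simulation path: draws
#' \eqn{z_i \sim N\big(0, (1-\psi_0+\psi_0 t_i)/(\theta_0(1-\psi_0))\big)}
#' independently, the exact distribution of the rotated phenotype under the
#' model. Statistically indistinguishable from the full genotype path at a
#' matched spectrum.
#'
#' @param spec a `grm_spectrum` or eigenvalue vector.
#' @param psi0 true heritability in [0, 1).
#' @param theta0 true noise precision.
#' @param seed optional seed.
#' @return A `rotated_data`.
#' @export
gen_rotated <- function(spec, psi0, theta0 = 1, seed = NULL) {
  rotated_data(gen_rotated_reps(spec, psi0, theta0, reps = 1L, seed = seed)[, 1L])
}

#' @rdname gen_rotated
#' @param reps number of replicate draws.
#' @return For `gen_rotated_reps`, an n x reps matrix of independent
#'   replicate z vectors.
#' @export
gen_rotated_reps <- function(spec, psi0, theta0 = 1, reps = 1L, seed = NULL) {
  if (psi0 < 0 || psi0 >= 1) stop("psi0 must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  t_vals <- spec_t(spec)
  n <- length(t_vals)
  sd_i <- sqrt((1 - psi0 + psi0 * t_vals) / (theta0 * (1 - psi0)))
  matrix(rnorm(n * reps), n, reps) * sd_i
}

#' Deterministic Marcenko-Pastur quantile spectrum
#'
#' Eigenvalues placed at the MP inverse CDF evaluated at (i - 1/2)/n,
#' a variance-reduced deterministic stand-in for a sampled independent-
#' setting spectrum. The CDF is tabulated by trapezoidal integration of
#' [mp_density()] on a fine grid and inverted by interpolation.
#'
#' @param n number of eigenvalues.
#' @param mu aspect ratio in (0, 1]; the implied p is `round(n/mu)`.
#' @param cdf_points tabulation grid size.
#' @return A `grm_spectrum` with `p = round(n/mu)`.
#' @export
mp_quantile_spectrum <- function(n, mu, cdf_points = 8192L) {
  supp <- mp_support(mu)
  grid <- seq(supp[1L], supp[2L], length.out = cdf_points)
  dens <- mp_density(grid, mu)
  h <- diff(grid)
  cdf <- c(0, cumsum((dens[-1] + dens[-cdf_points]) / 2 * h))
  cdf <- cdf / cdf[cdf_points]
  q <- (seq_len(n) - 0.5) / n
  t_vals <- stats::approx(cdf, grid, xout = q, ties = "ordered")$y
  spectrum_from_eigenvalues(t_vals, p = round(n / mu))
}

#' Inject independent genotype errors
#'
#' Each raw count is independently replaced, with probability `pi`, by a
#' fresh Binomial(2, MAF) draw at that site's frequency; the matrix is then
#' renormalized with the original mode. Resampling from the site frequency
#' (rather than flipping alleles) keeps entries in 0/1/2 and models
#' independent misidentification.
#'
#' @param G a `genotype_matrix` (with a `maf` attribute from
#'   [gen_genotypes()], else frequencies estimated from the column means).
#' @param pi per-entry error probability in [0, 1].
#' @param seed optional seed.
#' @return A new `genotype_matrix`.
#' @export
inject_genotype_errors <- function(G, pi, seed = NULL) {
  if (pi < 0 || pi > 1) stop("pi must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  raw <- G$raw
  if (pi == 0) return(G)
  maf <- if (!is.null(G$maf)) G$maf else pmin(pmax(colMeans(raw) / 2, 1e-3), 0.5)
  n <- nrow(raw)
  hit <- matrix(runif(length(raw)) < pi, n)
  repl <- matrix(rbinom(length(raw), 2L, rep(maf, each = n)), n)
  raw[hit] <- repl[hit]
  out <- normalize_genotypes(raw, G$normalization_mode)
  out$maf <- maf
  out
}

#' Balanced one-way variance decomposition
#'
#' Method-of-moments decomposition of an I x J matrix of estimates into
#' between-row and within-row variance components:
#' `var_within = MSW`, `var_between = max(0, (MSB - MSW)/J)`. For balanced
#' designs with MSB >= MSW this coincides with the REML estimates of the
#' one-way Gaussian random-effects model.
#'
#' @param psi_hat_matrix numeric I x J matrix (rows = groups).
#' @return Object of class `decomposition_result`: `var_between`,
#'   `var_within`, `grand_mean`, `I`, `J`, `msb`, `msw`, and `se_between`
#'   (large-sample standard error of `var_between` under normality).
#' @export
variance_decompose <- function(psi_hat_matrix) {
  m <- as.matrix(psi_hat_matrix)
  I <- nrow(m)
  J <- ncol(m)
  if (I < 2L || J < 2L) stop("need at least 2 causal sets and 2 replicates")
  if (anyNA(m)) stop("psi_hat matrix contains NA; exclude failed fits upstream")
  row_means <- rowMeans(m)
  msb <- J * sum((row_means - mean(m))^2) / (I - 1)
  msw <- sum((m - row_means)^2) / (I * (J - 1))
  vb <- max(0, (msb - msw) / J)
  se_vb <- sqrt(2 / J^2 * (msb^2 / (I - 1) + msw^2 / (I * (J - 1))))
  structure(
    list(var_between = vb, var_within = msw, grand_mean = mean(m),
         I = I, J = J, msb = msb, msw = msw, se_between = se_vb),
    class = "decomposition_result"
  )
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("One-way decomposition (%d sets x %d replicates):\n", x$I, x$J))
  cat(sprintf("  var_between = %.4g (SE %.2g), var_within = %.4g, grand mean = %.5g\n",
              x$var_between, x$se_between, x$var_within, x$grand_mean))
  invisible(x)
}

#' Causal-subset simulation study
#'
#' Replicates the restricted-causality experiment: simulate one genotype
#' matrix, draw I random causal sets of size k, generate J phenotypes per
#' set, estimate heritability for each, and decompose the I x J estimate
#' matrix into between-set variance (the fingerprint of the random bias
#' \eqn{\psi_* - \psi_0}) and within-set variance. Phenotypes are generated
#' directly in rotated coordinates,
#' \eqn{z = \sqrt{p}\, s \circ (V_\eta^\top u) + \tilde\varepsilon},
#' which is exact and avoids J matrix products per set. The theoretical
#' between-set variance \eqn{(\tau_1^2\psi_0^2/k)\,\mathrm{Var}(\hat\psi)}
#' is attached, with \eqn{\mathrm{Var}(\hat\psi)} evaluated on the realized
#' spectrum.
#'
#' @param design a `sim_design` with `k < p`.
#' @param G optional pre-generated `genotype_matrix` (so several k values
#'   can share one matrix).
#' @return Object of class `causal_study`: `psi_hat` (I x J), `psi_star`
#'   (length I, from [causal_fixed_point()]), `decomposition`,
#'   `theory_var_between`, `var_psi_hat_theory`, `tau1`, `design`,
#'   `n_failed`.
#' @export
causal_study <- function(design, G = NULL) {
  set.seed(design$seed)
  if (is.null(G)) G <- gen_genotypes(design, seed = design$seed)
  n <- G$n
  p <- G$p
  k <- design$k
  psi0 <- design$psi0
  theta0 <- design$theta0
  I <- design$n_causal_sets
  J <- design$n_reps

  spec <- grm_spectrum(G)
  s <- sqrt(spec$t)
  sigma_g2 <- psi0 / (theta0 * (1 - psi0))
  sigma_e <- sqrt(1 / theta0)
  prep <- prepare_fit_grid(spec)

  pos <- spec$t > 1e-12 * max(spec$t)
  psi_hat <- matrix(NA_real_, I, J)
  psi_star <- numeric(I)
  for (i in seq_len(I)) {
    eta <- sample.int(p, k)
    Vh <- spec$V[eta, , drop = FALSE]          # k x n, NA on null columns
    Vh[, !pos] <- 0                            # null coordinates get no genetic signal
    gamma <- p * colSums(Vh^2) - k
    psi_star[i] <- tryCatch(
      causal_fixed_point(spec, gamma, psi0, k)$psi_star,
      error = function(e) NA_real_
    )
    U <- matrix(rnorm(k * J), k, J)
    U <- sweep(U, 2L, sqrt(colSums(U^2) / sigma_g2), "/")   # sum of squares = sigma_g2
    zmat <- sqrt(p) * s * (crossprod(Vh, U)) +
      matrix(rnorm(n * J, sd = sigma_e), n, J)
    psi_hat[i, ] <- greml_fit_many(prep, zmat)
  }
  n_failed <- sum(is.na(psi_hat))
  dec <- variance_decompose(psi_hat)
  tm <- tau_moments(spec, psi0)
  v_hat <- variance_approx(tm, psi0, n)
  structure(
    list(psi_hat = psi_hat, psi_star = psi_star, decomposition = dec,
         var_psi_hat_theory = v_hat,
         theory_var_between = tm$tau[1L]^2 * psi0^2 / k * v_hat,
         tau1 = tm$tau[1L], design = design, n_failed = n_failed,
         spectrum = spec),
    class = "causal_study"
  )
}

#' @export
print.causal_study <- function(x, ...) {
  d <- x$design
  cat(sprintf("Causal-subset study: n = %d, p = %d, k = %d, psi0 = %.3g, %d sets x %d reps\n",
              d$n, d$p, d$k, d$psi0, d$n_causal_sets, d$n_reps))
  cat(sprintf("  between-set variance: empirical %.4g (SE %.2g), theory %.4g\n",
              x$decomposition$var_between, x$decomposition$se_between,
              x$theory_var_between))
  cat(sprintf("  grand mean psi_hat = %.4f (psi0 = %.3g)\n",
              x$decomposition$grand_mean, d$psi0))
  invisible(x)
}
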
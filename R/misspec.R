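#' Causal-subset projection deviations
#'
#' For a causal subset eta of the p SNPs, computes
#' \eqn{\gamma_i = p \sum_{j\in\eta} V_{ji}^2 - k}, the deviation from
#' expectation of the squared projection of the causal indicator onto the
#' i-th right singular vector. Over a uniformly random eta of size k each
#' \eqn{\gamma_i} has mean zero, is identically zero when k = p, and for
#' k << p the variable \eqn{\gamma_i + k} is distributed approximately
#' chi-squared with k degrees of freedom.
#'
#' @param V p x n matrix of right singular vectors of the normalized
#'   genotype matrix divided by sqrt(p) (as stored by [grm_spectrum()]), or a
#'   `grm_spectrum` carrying `V`. Columns corresponding to zero singular
#'   values (where V is undefined) yield NA.
#' @param eta integer vector of causal SNP indices in 1..p.
#' @return Numeric vector gamma of length n, paired with the eigenvalues.
#' @export
gamma_projections <- function(V, eta) {
  if (inherits(V, "grm_spectrum")) {
    if (is.null(V$V)) stop("spectrum carries no right singular vectors")
    V <- V$V
  }
  eta <- as.integer(eta)
  if (length(eta) == 0L) stop("eta must contain at least one causal SNP")
  p <- nrow(V)
  if (any(eta < 1L | eta > p)) stop("eta indices outside 1..p")
  k <- length(eta)
  p * colSums(V[eta, , drop = FALSE]^2) - k
}

# Smooth form of the fixed-eta stationarity condition. The defining
# condition Cov(w(x), w(x)/w(psi0)) + [psi0/(1-psi0)] * (1-x)/(k x) *
# [Cov(w(x), gamma) - Cov(w(x), gamma w(x))] = 0 factors as x * h(x) with
#   h(x) = Var(wt(x)) [x - psi0(1-x)/(1-psi0)]
#          - [psi0 (1-x) / ((1-psi0) k)] Cov(wt(x), gamma * wt(x)),
# using w = 1 - x*wt. h is continuous through x = 0 and has the same roots
# away from the spurious factor x = 0; h(psi0) = 0 exactly when gamma == 0.
causal_score <- function(x, t_vals, gamma, psi0, k) {
  d <- 1 - x + x * t_vals
  wt <- t_vals / d
  emp_var(wt) * (x - psi0 * (1 - x) / (1 - psi0)) -
    psi0 * (1 - x) / ((1 - psi0) * k) * emp_cov(wt, gamma * wt)
}

#' Asymptotic heritability estimate under a fixed causal subset
#'
#' When only the k SNPs in a fixed subset eta are causal, the MLE converges
#' (over a large number of independent phenotype draws) not to the true
#' \eqn{\psi_0} but to the Kullback-Leibler closest value \eqn{\psi_*},
#' the root of the stationarity condition
#' \deqn{0 = \mathrm{Cov}\!\big(w(\psi_*), w(\psi_*)/w(\psi_0)\big)
#'  + \frac{\psi_0/(1-\psi_0)}{k\,\psi_*/(1-\psi_*)}
#'  \big[\mathrm{Cov}(w(\psi_*),\gamma) - \mathrm{Cov}(w(\psi_*),\gamma\,w(\psi_*))\big].}
#' The root is located by the same bracketed grid scan as the MLE, on an
#' algebraically equivalent form that is smooth through \eqn{\psi_* = 0};
#' if several roots exist the one closest to `psi0` is returned.
#'
#' @param spec a `grm_spectrum` or eigenvalue vector.
#' @param gamma projection deviations from [gamma_projections()] (use
#'   `gamma = rep(0, n)` for the fully causal case, which returns `psi0`).
#' @param psi0 true heritability in (0, 1).
#' @param k number of causal SNPs.
#' @return List: `psi_star`, `eps_star` = (psi_star - psi0)/(psi0(1-psi0)),
#'   `n_roots`.
#' @export
causal_fixed_point <- function(spec, gamma, psi0, k) {
  t_vals <- spec_t(spec)
  if (length(gamma) != length(t_vals)) stop("gamma must pair with the eigenvalues")
  if (anyNA(gamma)) stop("gamma contains NA (zero singular value coordinates); drop them consistently")
  if (k < 1L) stop("k must be at least 1")
  if (psi0 <= 0 || psi0 >= 1) stop("psi0 must be in (0, 1)")
  if (emp_var(t_vals) == 0) stop("degenerate spectrum: tau_2 = 0")
  adm <- admissible_interval(t_vals)
  eps <- 1e-10
  lo <- if (adm$bounded_below) adm$psi_min + eps * max(1, abs(adm$psi_min)) else -1e3
  grid <- psi_grid(lo, 1 - eps, 96L)
  f <- function(x) causal_score(x, t_vals, gamma, psi0, k)
  fv <- vapply(grid, f, numeric(1))
  flips <- which(fv[-1] * fv[-length(fv)] <= 0 & fv[-1] != fv[-length(fv)])
  roots <- numeric(0)
  for (i in flips) {
    r <- tryCatch(stats::uniroot(f, lower = grid[i], upper = grid[i + 1L],
                                 tol = 1e-12)$root,
                  error = function(e) NULL)
    if (!is.null(r)) roots <- c(roots, r)
  }
  if (length(roots) == 0L) {
    stop(sprintf("no root of the causal stationarity condition in (%g, 1)", lo))
  }
  psi_star <- roots[which.min(abs(roots - psi0))]
  list(psi_star = psi_star,
       eps_star = (psi_star - psi0) / (psi0 * (1 - psi0)),
       n_roots = length(roots))
}

#' Error inflation under random causal subsets
#'
#' Treating the causal subset as a uniform random sample of k SNPs, the
#' asymptotic estimate \eqn{\psi_*} is approximately unbiased,
#' \eqn{E[\psi_*] \approx \psi_0}, and its between-subset variance inflates
#' the total estimation error by the factor
#' \deqn{\frac{\mathrm{Var}(\psi_*)}{\mathrm{Var}(\hat\psi)} \approx
#'   \frac{\tau_1^2\,\psi_0^2}{k}.}
#' The inflation is negligible once the phenotype is influenced by several
#' tens of SNPs. The derivation assumes \eqn{\tau_4 \ll \tau_2}; a warning
#' is issued when that fails.
#'
#' @param tm a `tau_moments` object evaluated at `psi0` (kmax >= 4).
#' @param psi0 true heritability.
#' @param k number of causal SNPs.
#' @param n sample size.
#' @return List: `mean_psi_star` (= psi0), `var_ratio`, `var_psi_star`
#'   (= var_ratio times the [variance_approx()] value), `sd_psi_star`.
#' @export
rcs_error_inflation <- function(tm, psi0 = tm$psi, k, n = tm$n) {
  if (k < 1L) stop("k must be at least 1")
  tau2 <- get_tau(tm, 2L)
  tau4 <- get_tau(tm, 4L)
  if (tau4 > 0.5 * tau2) {
    warning("tau_4 is not small relative to tau_2; the random-causal-subset approximation may be inaccurate")
  }
  ratio <- get_tau(tm, 1L)^2 * psi0^2 / k
  v_hat <- variance_approx(tm, psi0, n)
  list(mean_psi_star = psi0, var_ratio = ratio,
       var_psi_star = ratio * v_hat, sd_psi_star = sqrt(ratio * v_hat))
}

#' Bias from untagged causal variation
#'
#' When the k causal SNPs are not observed but are linearly tagged by the
#' observed panel, \eqn{Z_c = Z_o B + \delta} with per-column residual
#' variances averaging \eqn{\sigma_\delta^2}, the asymptotic estimate
#' acquires a deterministic negative bias \eqn{-2\sigma_\delta^2\psi_0^2}
#' plus a random component \eqn{(\sigma_\gamma/\tau_2) X} with X
#' approximately standard normal over permutations of the causal columns and
#' \deqn{\sigma_\gamma^2 = \frac{2\psi_0^2(1-\psi_0)^2}{n k}
#'  (\tau_2\tau_1^2 + 2\tau_3\tau_1 + \tau_4)\cdot
#'  \overline{\sigma_{(\ell)}^4}.}
#' With \eqn{\sigma_\delta = 0} and B a 0/1 copy matrix this reduces exactly
#' to the random-causal-subset standard deviation of
#' [rcs_error_inflation()] when \eqn{2\tau_3\tau_1 + \tau_4 \ll \tau_2\tau_1^2}.
#' Splitting each causal SNP's tagging weight across several observed SNPs
#' lowers \eqn{\overline{\sigma_{(\ell)}^4}} and hence the random component.
#'
#' @param tm a `tau_moments` at `psi0` with kmax >= 4.
#' @param psi0 true heritability.
#' @param n sample size.
#' @param k number of causal SNPs.
#' @param sigma_delta2 mean residual tagging variance (small).
#' @param mean_sigma_l4 mean over causal columns of the squared column sums
#'   of squares of B (1 for a 0/1 copy matrix).
#' @return List: `deterministic_bias`, `sigma_gamma2`, `sigma_gamma`,
#'   `random_sd` (= sigma_gamma / tau_2).
#' @export
untagged_bias <- function(tm, psi0 = tm$psi, n = tm$n, k,
                          sigma_delta2 = 0, mean_sigma_l4 = 1) {
  if (sigma_delta2 < 0) stop("sigma_delta2 must be nonnegative")
  tau1 <- get_tau(tm, 1L)
  tau2 <- get_tau(tm, 2L)
  tau3 <- get_tau(tm, 3L)
  tau4 <- get_tau(tm, 4L)
  sg2 <- 2 * psi0^2 * (1 - psi0)^2 / (n * k) *
    (tau2 * tau1^2 + 2 * tau3 * tau1 + tau4) * mean_sigma_l4
  sg2 <- max(sg2, 0)
  list(deterministic_bias = -2 * sigma_delta2 * psi0^2,
       sigma_gamma2 = sg2, sigma_gamma = sqrt(sg2),
       random_sd = sqrt(sg2) / tau2)
}

#' GRM inversion symmetry map
#'
#' Replacing the phenotype y by \eqn{A^{-1/2} y} yields a sample from the
#' same model family with the GRM inverted, \eqn{\psi} replaced by
#' \eqn{1-\psi} and \eqn{\theta} by \eqn{\theta(1/\psi - 1)}. In rotated
#' coordinates the map is \eqn{t \mapsto 1/t}, \eqn{z_i \mapsto z_i/\sqrt{t_i}};
#' it is an involution, and the MLE is exactly equivariant under it:
#' fitting the mapped data returns \eqn{1-\hat\psi} and
#' \eqn{\hat\theta(1/\hat\psi - 1)}.
#'
#' @param spec a `grm_spectrum` or eigenvalue vector with all t > 0.
#' @param rot a `rotated_data` or numeric z paired with `spec`.
#' @param psi,theta optional parameter values to map along.
#' @return List: `spec` (inverted spectrum, ascending, re-paired), `rot`,
#'   and when parameters were given, `psi` = 1 - psi and
#'   `theta` = theta (1/psi - 1).
#' @export
symmetry_map <- function(spec, rot, psi = NULL, theta = NULL) {
  t_vals <- spec_t(spec)
  z <- rot_z(rot)
  if (any(t_vals <= 0)) {
    stop("spectrum contains a zero eigenvalue: the GRM is not invertible and the symmetry map is undefined")
  }
  new_t <- 1 / t_vals
  new_z <- z / sqrt(t_vals)
  ord <- order(new_t)
  p <- if (inherits(spec, "grm_spectrum")) spec$p else length(t_vals)
  out <- list(
    spec = spectrum_from_eigenvalues(new_t[ord], p = p),
    rot = rotated_data(new_z[ord])
  )
  if (!is.null(psi)) {
    out$psi <- 1 - psi
    if (!is.null(theta)) out$theta <- theta * (1 / psi - 1)
  }
  out
}

#' Equivalent parameters under phenotype measurement error
#'
#' Additive independent measurement error on the phenotype with variance
#' `sigma_m2` only inflates the noise channel, so the model is equivalent to
#' one with the genetic variance \eqn{g = \psi/(\theta(1-\psi))} unchanged,
#' \eqn{\theta_{eff} = 1/(1/\theta + \sigma_m^2)} and
#' \eqn{\psi_{eff} = g/(g + 1/\theta + \sigma_m^2) \le \psi}.
#'
#' @param psi,theta model parameters.
#' @param sigma_m2 measurement-error variance (>= 0).
#' @return List: `psi_eff`, `theta_eff`, `genetic_variance`.
#' @export
phenotype_error_equiv <- function(psi, theta, sigma_m2) {
  if (sigma_m2 < 0) stop("sigma_m2 must be nonnegative")
  g <- psi / (theta * (1 - psi))
  noise <- 1 / theta + sigma_m2
  list(psi_eff = g / (g + noise), theta_eff = 1 / noise, genetic_variance = g)
}

#' Predicted attenuation from genotype misidentification
#'
#' Independent sparse genotype errors (each entry wrong with probability pi)
#' act approximately like extra phenotype noise of variance
#' \eqn{c\,p\,\sigma_u^2\,\pi}, where c depends on the error distribution
#' and \eqn{\sigma_u^2} is the per-SNP effect variance; the correlation
#' terms neglected by this equivalence are small only when `p * pi` is
#' large, which is flagged in the result. The constant c has no closed form
#' for count resampling errors and is calibrated empirically on simulated
#' data (see [inject_genotype_errors()]).
#'
#' @param psi,theta model parameters.
#' @param pi per-entry error probability in [0, 1].
#' @param p number of SNPs.
#' @param sigma_u2 per-SNP effect variance (default `psi/(theta (1-psi) p)`,
#'   the fully causal model value).
#' @param c calibration constant (default 1).
#' @return List from [phenotype_error_equiv()] plus `noise_inflation` and
#'   `valid` (TRUE when p * pi >= 30).
#' @export
genotype_error_equiv <- function(psi, theta, pi, p,
                                 sigma_u2 = psi / (theta * (1 - psi) * p), c = 1) {
  if (pi < 0 || pi > 1) stop("pi must be in [0, 1]")
  infl <- c * p * sigma_u2 * pi
  out <- phenotype_error_equiv(psi, theta, infl)
  out$noise_inflation <- infl
  out$valid <- (p * pi >= 30) || pi == 0
  out
}
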
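# Extract (t, z) pairs from the container types; used by every likelihood
# routine. z may be omitted for weight-only computations.
spec_t <- function(spec) if (inherits(spec, "grm_spectrum")) spec$t else as.numeric(spec)
rot_z <- function(rot) if (inherits(rot, "rotated_data")) rot$z else as.numeric(rot)

#' Admissible heritability interval for a spectrum
#'
#' The rotated log likelihood is defined for trial \eqn{\psi} in the open
#' interval \eqn{(-1/(\max_i t_i - 1),\, 1)} (unbounded below when
#' \eqn{\max t \le 1}). As the largest eigenvalue grows, the interval
#' shrinks toward \eqn{[0, 1)}.
#'
#' @param spec a `grm_spectrum` or eigenvalue vector.
#' @return List with `psi_min`, `psi_max = 1`, and `bounded_below`.
#' @export
admissible_interval <- function(spec) {
  t_max <- max(spec_t(spec))
  if (t_max > 1) {
    list(psi_min = -1 / (t_max - 1), psi_max = 1, bounded_below = TRUE)
  } else {
    list(psi_min = -Inf, psi_max = 1, bounded_below = FALSE)
  }
}

#' Rotated-coordinate log likelihood
#'
#' The log likelihood of the rotated observations z under the two-parameter
#' model: independent centered normals with variances
#' \eqn{(1-\psi+\psi t_i)/(\theta(1-\psi))},
#' \deqn{\ell(\theta,\psi) = \frac{n}{2}\log\theta(1-\psi)
#'  - \frac12\sum_i \log(1-\psi+\psi t_i)
#'  - \frac{\theta}{2}\sum_i \frac{(1-\psi) z_i^2}{1-\psi+\psi t_i}.}
#' The \eqn{-(n/2)\log 2\pi} density constant is included by default so the
#' value matches the multivariate normal density of the unrotated phenotype;
#' set `constant = FALSE` for the constant-free display.
#'
#' @param theta precision (reciprocal variance) of the non-genetic noise, > 0.
#' @param psi trial heritability, inside the admissible interval.
#' @param spec a `grm_spectrum` or eigenvalue vector.
#' @param rot a `rotated_data` or numeric vector z.
#' @param constant include the `-(n/2) log(2 pi)` term? Default `TRUE`.
#' @return Scalar log likelihood.
#' @export
greml_loglik <- function(theta, psi, spec, rot, constant = TRUE) {
  if (theta <= 0) stop("theta must be positive")
  t_vals <- spec_t(spec)
  z <- rot_z(rot)
  if (length(z) != length(t_vals)) stop("dimension mismatch between spectrum and rotated data")
  d <- 1 - psi + psi * t_vals
  if (any(d <= 0) || psi >= 1) {
    stop(sprintf("psi = %g outside the admissible interval", psi))
  }
  n <- length(t_vals)
  val <- n / 2 * log(theta * (1 - psi)) - sum(log(d)) / 2 -
    theta / 2 * sum((1 - psi) * z^2 / d)
  if (constant) val <- val - n / 2 * log(2 * pi)
  val
}

#' One-parameter profile log likelihood
#'
#' The log likelihood maximized analytically over the noise precision
#' \eqn{\theta}, with maximizer \eqn{\hat\theta(\psi) = n / \sum_i w_i z_i^2}:
#' \deqn{\ell_p(\psi) = -\frac{n}{2}\log\Big(\sum_i w_i(\psi) z_i^2\Big)
#'   + \frac12\sum_i \log w_i(\psi) + \frac{n}{2}(\log n - 1).}
#' With a zero eigenvalue in the spectrum it tends to \eqn{-\infty} at both
#' ends of the admissible interval, so an interior maximum exists.
#'
#' @inheritParams greml_loglik
#' @param constant include the `-(n/2) log(2 pi)` density constant (so that
#'   the value equals `max_theta greml_loglik(...)`)? Default `FALSE`,
#'   matching the usual constant-free display.
#' @return Scalar profile log likelihood.
#' @export
profile_loglik <- function(psi, spec, rot, constant = FALSE) {
  t_vals <- spec_t(spec)
  z <- rot_z(rot)
  d <- 1 - psi + psi * t_vals
  if (any(d <= 0) || psi >= 1) {
    stop(sprintf("psi = %g outside the admissible interval", psi))
  }
  n <- length(t_vals)
  w <- (1 - psi) / d
  S <- sum(w * z^2)
  if (S <= 0) stop("sum of w_i z_i^2 is zero; degenerate rotated data")
  val <- -n / 2 * log(S) + sum(log(w)) / 2 + n / 2 * (log(n) - 1)
  if (constant) val <- val - n / 2 * log(2 * pi)
  val
}

#' Score function of the profile likelihood
#'
#' The stationarity condition for the heritability MLE is that the empirical
#' covariance over coordinates of \eqn{w_i(\psi)} and
#' \eqn{v_i(\psi) = w_i(\psi) z_i^2} vanishes. Because
#' \eqn{w_i = 1 - \psi \tilde w_i}, that covariance equals
#' \eqn{-\psi\,\mathrm{Cov}(\tilde w, v)} and is trivially zero at
#' \eqn{\psi = 0}; the implemented score is therefore the continuous form
#' \deqn{U(\psi) = \mathrm{Cov}(\tilde w(\psi), v(\psi)),}
#' which is a positive multiple of the derivative of the profile log
#' likelihood: \eqn{\ell_p'(\psi) = n\, U(\psi) / (2 (1-\psi) \bar v)}.
#' Roots of the score are stationary points of the profile likelihood.
#'
#' @inheritParams greml_loglik
#' @return Scalar score value (0 with a warning for a degenerate spectrum
#'   with all eigenvalues equal, where heritability is not identifiable).
#' @export
greml_score <- function(psi, spec, rot) {
  t_vals <- spec_t(spec)
  z <- rot_z(rot)
  d <- 1 - psi + psi * t_vals
  if (any(d <= 0) || psi >= 1) {
    stop(sprintf("psi = %g outside the admissible interval", psi))
  }
  if (emp_var(t_vals) == 0) {
    warning("all eigenvalues equal: heritability is not identifiable, score is identically 0")
    return(0)
  }
  wt <- t_vals / d
  v <- (1 - psi) * z^2 / d
  emp_cov(wt, v)
}

# Logit-spaced psi grid on (lo, hi), denser near both endpoints.
psi_grid <- function(lo, hi, n_points = 64L, spread = 16) {
  if (!is.finite(lo)) lo <- -1e3
  lo + (hi - lo) * stats::plogis(seq(-spread, spread, length.out = n_points))
}

#' Maximum likelihood fit of heritability from a spectrum
#'
#' Locates the MLE \eqn{(\hat\psi, \hat\theta)} by scanning the score
#' [greml_score()] on a logit-spaced grid over the open admissible interval,
#' polishing every sign change with a bracketed root finder, and keeping the
#' root with the highest profile likelihood. Negative \eqn{\hat\psi} is
#' returned as-is: the estimate distribution is never truncated at zero.
#' If the score has no interior sign change (possible only without a zero
#' eigenvalue) the fit falls back to bounded maximization of the profile
#' likelihood and flags it.
#'
#' @param spec a `grm_spectrum` or eigenvalue vector.
#' @param rot a `rotated_data` or numeric vector z.
#' @param kmax tau order used for the attached bias/SE approximations.
#' @param grid_points,tol root-scan grid size and root tolerance on psi.
#' @return Object of class `greml_fit`: `psi_hat`, `theta_hat`, `phi_hat`,
#'   `profile_loglik`, `score_at_opt`, `admissible`, `se_approx`,
#'   `bias_approx`, `n_roots`, `converged`, `fallback`.
#' @export
greml_fit <- function(spec, rot, kmax = 8L, grid_points = 64L, tol = 1e-12) {
  t_vals <- spec_t(spec)
  z <- rot_z(rot)
  if (length(z) != length(t_vals)) stop("dimension mismatch between spectrum and rotated data")
  if (emp_var(t_vals) == 0) {
    stop("degenerate spectrum (all eigenvalues equal): heritability is not identifiable")
  }
  adm <- admissible_interval(t_vals)
  n <- length(t_vals)
  z2 <- z^2

  score_f <- function(psi) {
    d <- 1 - psi + psi * t_vals
    wt <- t_vals / d
    v <- (1 - psi) * z2 / d
    mean(wt * v) - mean(wt) * mean(v)
  }
  prof_f <- function(psi) {
    d <- 1 - psi + psi * t_vals
    w <- (1 - psi) / d
    -n / 2 * log(sum(w * z2)) + sum(log(w)) / 2
  }

  eps <- 1e-10
  lo <- if (adm$bounded_below) adm$psi_min + eps * max(1, abs(adm$psi_min)) else -1e3
  hi <- 1 - eps
  grid <- psi_grid(lo, hi, grid_points)
  sv <- vapply(grid, score_f, numeric(1))
  flips <- which(sv[-1] * sv[-length(sv)] <= 0 & sv[-1] != sv[-length(sv)])

  roots <- numeric(0)
  for (i in flips) {
    r <- tryCatch(
      stats::uniroot(score_f, lower = grid[i], upper = grid[i + 1L], tol = tol),
      error = function(e) NULL
    )
    if (!is.null(r)) roots <- c(roots, r$root)
  }
  fallback <- length(roots) == 0L
  if (fallback) {
    opt <- stats::optimize(prof_f, interval = c(lo, hi), maximum = TRUE, tol = tol)
    psi_hat <- opt$maximum
  } else {
    ll <- vapply(roots, prof_f, numeric(1))
    psi_hat <- roots[which.max(ll)]
  }

  wp <- greml_weights(t_vals, psi_hat)
  v_bar <- mean(wp$w * z2)
  theta_hat <- 1 / v_bar
  tm <- tau_moments(t_vals, psi_hat, kmax = kmax)
  se <- if (tm$degenerate) NA_real_ else sqrt(variance_approx(tm, psi_hat, n))
  bias <- if (tm$degenerate) NA_real_ else bias_approx(tm, psi_hat, n)

  structure(
    list(psi_hat = psi_hat, theta_hat = theta_hat,
         phi_hat = psi_hat / (1 - psi_hat),
         profile_loglik = prof_f(psi_hat) + n / 2 * (log(n) - 1),
         score_at_opt = score_f(psi_hat),
         admissible = adm,
         se_approx = se, bias_approx = bias,
         tau = tm$tau, n = n,
         n_roots = length(roots),
         converged = fallback || abs(score_f(psi_hat)) <= 1e-6,
         fallback = fallback),
    class = "greml_fit"
  )
}

#' @export
print.greml_fit <- function(x, ...) {
  cat("GREML profile-likelihood fit\n")
  cat(sprintf("  psi_hat   = %.6f  (approx SE %.4f, approx bias %.2e)\n",
              x$psi_hat, x$se_approx, x$bias_approx))
  cat(sprintf("  theta_hat = %.6f  (phi_hat = %.6f)\n", x$theta_hat, x$phi_hat))
  cat(sprintf("  profile log likelihood = %.4f, |score| = %.2e\n",
              x$profile_loglik, abs(x$score_at_opt)))
  cat(sprintf("  admissible psi interval: (%s, 1); %d score root(s)%s\n",
              ifelse(x$admissible$bounded_below,
                     sprintf("%.4f", x$admissible$psi_min), "-Inf"),
              x$n_roots,
              ifelse(x$fallback, " [fallback maximization]", "")))
  invisible(x)
}

#' Fit heritability directly from genotypes and a phenotype
#'
#' Convenience wrapper: normalizes the genotype counts, extracts the GRM
#' spectrum, rotates the phenotype, and calls [greml_fit()]. The likelihood
#' depends on the genotypes only through their singular values, so this is
#' exactly equivalent to the spectrum-level fit.
#'
#' @param raw genotype count matrix (n x p) or a `genotype_matrix`.
#' @param y phenotype vector of length n.
#' @param mode normalization mode passed to [normalize_genotypes()].
#' @param ... passed on to [greml_fit()].
#' @return A `greml_fit`.
#' @export
greml_fit_genotypes <- function(raw, y, mode = c("global", "per_column"), ...) {
  G <- if (inherits(raw, "genotype_matrix")) raw else normalize_genotypes(raw, match.arg(mode))
  spec <- grm_spectrum(G)
  rot <- rotate_phenotype(spec, y)
  greml_fit(spec, rot, ...)
}

# --- batch fitting over many replicate z vectors on one fixed spectrum ----

#' Precompute the score grid for repeated fits on one spectrum
#'
#' Monte Carlo studies fit thousands of replicate phenotypes against a single
#' spectrum. This precomputes the grid weight matrices so each replicate fit
#' reduces to two matrix-vector products plus a local root polish.
#'
#' @param spec a `grm_spectrum` or eigenvalue vector.
#' @param grid_points grid resolution.
#' @return Opaque prepared-grid object for [greml_fit_many()].
#' @export
prepare_fit_grid <- function(spec, grid_points = 64L) {
  t_vals <- spec_t(spec)
  adm <- admissible_interval(t_vals)
  eps <- 1e-10
  lo <- if (adm$bounded_below) adm$psi_min + eps * max(1, abs(adm$psi_min)) else -1e3
  grid <- psi_grid(lo, 1 - eps, grid_points)
  n <- length(t_vals)
  D <- outer(t_vals, grid, function(t, p) 1 - p + p * t)
  Wt <- t_vals / D                              # n x G matrix of w_tilde
  W <- sweep(1 / D, 2L, 1 - grid, "*")          # n x G matrix of w
  list(t = t_vals, n = n, grid = grid, adm = adm,
       WtW = Wt * W, W = W, m_wt = colMeans(Wt))
}

#' Fit many replicates against one spectrum
#'
#' @param prep output of [prepare_fit_grid()] (or a spectrum, prepared
#'   internally).
#' @param zmat n x R matrix whose columns are replicate rotated observations.
#' @param tol psi tolerance of the root polish.
#' @return Numeric vector of length R of heritability estimates `psi_hat`
#'   with attribute `theta_hat`.
#' @export
greml_fit_many <- function(prep, zmat, tol = 1e-10) {
  if (inherits(prep, "grm_spectrum") || is.numeric(prep)) prep <- prepare_fit_grid(prep)
  zmat <- as.matrix(zmat)
  if (nrow(zmat) != prep$n) stop("zmat rows must match spectrum length")
  R <- ncol(zmat)
  Z2 <- zmat^2
  n <- prep$n
  t_vals <- prep$t
  # score on the grid for all replicates: G x R
  S <- (crossprod(prep$WtW, Z2) - prep$m_wt * crossprod(prep$W, Z2)) / n
  grid <- prep$grid
  G <- length(grid)

  psi_hat <- numeric(R)
  theta_hat <- numeric(R)
  for (r in seq_len(R)) {
    z2 <- Z2[, r]
    score_f <- function(psi) {
      d <- 1 - psi + psi * t_vals
      wt <- t_vals / d
      v <- (1 - psi) * z2 / d
      mean(wt * v) - mean(wt) * mean(v)
    }
    sv <- S[, r]
    flips <- which(sv[-1] * sv[-G] <= 0 & sv[-1] != sv[-G])
    best_psi <- NA_real_
    best_ll <- -Inf
    for (i in flips) {
      rt <- tryCatch(
        stats::uniroot(score_f, lower = grid[i], upper = grid[i + 1L], tol = tol)$root,
        error = function(e) NA_real_
      )
      if (is.na(rt)) next
      d <- 1 - rt + rt * t_vals
      w <- (1 - rt) / d
      ll <- -n / 2 * log(sum(w * z2)) + sum(log(w)) / 2
      if (ll > best_ll) {
        best_ll <- ll
        best_psi <- rt
      }
    }
    if (is.na(best_psi)) {
      prof_f <- function(psi) {
        d <- 1 - psi + psi * t_vals
        w <- (1 - psi) / d
        -n / 2 * log(sum(w * z2)) + sum(log(w)) / 2
      }
      best_psi <- stats::optimize(prof_f, interval = range(grid), maximum = TRUE)$maximum
    }
    psi_hat[r] <- best_psi
    d <- 1 - best_psi + best_psi * t_vals
    theta_hat[r] <- 1 / mean((1 - best_psi) * z2 / d)
  }
  attr(psi_hat, "theta_hat") <- theta_hat
  psi_hat
}
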
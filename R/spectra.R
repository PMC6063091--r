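# Empirical (population, 1/n) moments. All tau-moment identities in the
# package assume the 1/n convention, so that mean(t) = 1 holds exactly for
# globally normalized genotypes.
emp_var <- function(x) mean((x - mean(x))^2)
emp_cov <- function(x, y) mean(x * y) - mean(x) * mean(y)
central_moment <- function(x, k) mean((x - mean(x))^k)

#' Normalize a genotype count matrix
#'
#' Centers each column of the raw allele-count matrix to mean zero and then
#' scales it so that either the mean square over the whole matrix equals 1
#' (`mode = "global"`) or every column has unit variance
#' (`mode = "per_column"`, which implies the global condition). The
#' population (1/n) variance convention is used throughout, so the global
#' normalization makes the mean GRM eigenvalue exactly 1.
#'
#' @param raw numeric matrix, n individuals by p SNPs; typically minor-allele
#'   counts in 0/1/2, but any real entries are accepted.
#' @param mode `"global"` (default) or `"per_column"`.
#' @return An object of class `genotype_matrix` with elements `Z` (the
#'   normalized matrix), `raw`, `n`, `p` and `normalization_mode`.
#' @export
normalize_genotypes <- function(raw, mode = c("global", "per_column")) {
  mode <- match.arg(mode)
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("genotype matrix must be numeric")
  if (anyNA(raw) || any(!is.finite(raw))) {
    stop("genotype matrix contains NA or non-finite entries; missing genotypes are not supported")
  }
  n <- nrow(raw)
  p <- ncol(raw)
  if (n < 2L) stop("need at least 2 individuals")
  if (p < 1L) stop("need at least 1 SNP")
  Z <- sweep(raw, 2L, colMeans(raw), "-")
  if (mode == "per_column") {
    cv <- colMeans(Z^2)          # population column variances after centering
    bad <- which(cv <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("column %d has zero variance; cannot normalize per column", bad[1L]))
    }
    Z <- sweep(Z, 2L, sqrt(cv), "/")
  } else {
    msq <- mean(Z^2)             # post-centering global mean square
    if (msq <= 0) stop("genotype matrix is constant; cannot normalize")
    Z <- Z / sqrt(msq)
  }
  structure(
    list(Z = Z, raw = raw, n = n, p = p, normalization_mode = mode),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Normalized genotype matrix: %d individuals x %d SNPs (%s normalization)\n",
              x$n, x$p, x$normalization_mode))
  invisible(x)
}

#' Eigenvalue spectrum of the genetic relatedness matrix
#'
#' Computes the n squared singular values of \eqn{Z/\sqrt{p}}, i.e. the
#' eigenvalues of the GRM \eqn{A = ZZ^*/p}, from the n x n Gram matrix
#' (cheap when p > n). Column centering of Z forces at least one exact zero
#' eigenvalue; tiny negative eigenvalues from roundoff are clipped at zero.
#'
#' @param G a `genotype_matrix`, or a plain numeric matrix assumed already
#'   normalized.
#' @param keep_vectors keep the left singular vectors `U` (needed to rotate
#'   phenotypes) and the right singular vectors `V` (needed for causal-subset
#'   projections)? Default `TRUE`.
#' @return An object of class `grm_spectrum`: `t` (eigenvalues sorted
#'   ascending), `n`, `p`, `mu = n/p`, and optionally `U` (n x n) and
#'   `V` (p x n) aligned with `t`.
#' @export
grm_spectrum <- function(G, keep_vectors = TRUE) {
  if (inherits(G, "genotype_matrix")) {
    Z <- G$Z
  } else {
    Z <- as.matrix(G)
  }
  n <- nrow(Z)
  p <- ncol(Z)
  A <- tcrossprod(Z) / p
  eig <- eigen(A, symmetric = TRUE)
  t_vals <- eig$values
  if (any(!is.finite(t_vals))) stop("non-finite GRM eigenvalues")
  t_vals[t_vals < 0 & t_vals > -1e-10 * max(abs(t_vals))] <- 0
  if (any(t_vals < 0)) stop("substantially negative GRM eigenvalues; input not a valid Gram matrix")
  ord <- order(t_vals)
  out <- list(t = t_vals[ord], n = n, p = p, mu = n / p)
  if (keep_vectors) {
    out$U <- eig$vectors[, ord, drop = FALSE]
    # right singular vectors of Z/sqrt(p): V = (Z/sqrt(p))' U diag(1/s), only
    # defined for nonzero singular values; zero-eigenvalue columns are left NA.
    s <- sqrt(out$t)
    V <- matrix(NA_real_, p, n)
    pos <- s > 1e-12 * max(s)
    if (any(pos)) {
      V[, pos] <- crossprod(Z / sqrt(p), out$U[, pos, drop = FALSE]) %*%
        diag(1 / s[pos], sum(pos))
    }
    out$V <- V
  }
  structure(out, class = "grm_spectrum")
}

#' Construct a spectrum object directly from eigenvalues
#'
#' Wraps a vector of GRM eigenvalues (squared singular values) together with
#' the dimensions n and p into the container used by the likelihood and
#' moment machinery, e.g. for spectrum-level simulation without genotypes.
#'
#' @param t nonnegative eigenvalues (any order; stored ascending).
#' @param p number of SNPs; defaults to `length(t)` (mu = 1).
#' @return A `grm_spectrum` (without singular vectors).
#' @export
spectrum_from_eigenvalues <- function(t, p = length(t)) {
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0)) stop("eigenvalues must be finite and nonnegative")
  structure(list(t = sort(t), n = length(t), p = p, mu = length(t) / p),
            class = "grm_spectrum")
}

#' @export
print.grm_spectrum <- function(x, ...) {
  cat(sprintf("GRM spectrum: n = %d, p = %d, mu = %.4g; mean(t) = %.6g, range [%.4g, %.4g]\n",
              x$n, x$p, x$mu, mean(x$t), min(x$t), max(x$t)))
  invisible(x)
}

#' Rotate a phenotype vector into the singular-vector basis
#'
#' Computes \eqn{z = U^* y}, the coordinates of the phenotype in the basis of
#' left singular vectors of the normalized genotype matrix. In this basis the
#' model coordinates are independent centered normals with variances
#' \eqn{(1-\psi+\psi t_i)/(\theta(1-\psi))}, paired with the eigenvalues
#' `spec$t`.
#'
#' @param spec a `grm_spectrum` carrying the left singular vectors `U`.
#' @param y phenotype vector of length n.
#' @return Object of class `rotated_data` with elements `z` and `n`.
#' @export
rotate_phenotype <- function(spec, y) {
  if (is.null(spec$U)) stop("spectrum was computed without singular vectors; rerun grm_spectrum(keep_vectors = TRUE)")
  y <- as.numeric(y)
  if (length(y) != spec$n) {
    stop(sprintf("phenotype length %d does not match n = %d", length(y), spec$n))
  }
  rotated_data(drop(crossprod(spec$U, y)))
}

#' Bundle rotated observations
#'
#' @param z numeric vector of rotated observations, paired coordinate-wise
#'   with the eigenvalues of the spectrum they were computed against.
#' @return Object of class `rotated_data`.
#' @export
rotated_data <- function(z) {
  z <- as.numeric(z)
  structure(list(z = z, n = length(z)), class = "rotated_data")
}

#' Spectral weights at a trial heritability
#'
#' Computes the deterministic weights
#' \eqn{w_i(\psi) = (1-\psi)/(1-\psi+\psi t_i)} and the companion transform
#' \eqn{\tilde w_i(\psi) = t_i/(1-\psi+\psi t_i)}, which satisfy the identity
#' \eqn{\psi \tilde w_i = 1 - w_i}. These weights drive the profile
#' likelihood, its score, and all tau-moment formulas.
#'
#' @param spec a `grm_spectrum` (or plain eigenvalue vector).
#' @param psi trial heritability, inside the admissible interval
#'   (all denominators \eqn{1-\psi+\psi t_i} must be positive).
#' @return Object of class `weight_profile` with `psi`, `w`, `w_tilde`.
#' @export
greml_weights <- function(spec, psi) {
  t_vals <- if (inherits(spec, "grm_spectrum")) spec$t else as.numeric(spec)
  d <- 1 - psi + psi * t_vals
  if (any(d <= 0)) {
    stop(sprintf("psi = %g outside the admissible interval: denominator 1-psi+psi*t nonpositive", psi))
  }
  structure(list(psi = psi, w = (1 - psi) / d, w_tilde = t_vals / d, t = t_vals),
            class = "weight_profile")
}

#' Randomized weight diagnostics v_i
#'
#' Computes \eqn{v_i(\psi) = w_i(\psi) z_i^2}. Under the model at the true
#' parameters, \eqn{\theta_0 v_i(\psi_0)} has expectation 1 for every i.
#'
#' @param wp a `weight_profile` from [greml_weights()].
#' @param rot a `rotated_data` (or plain numeric vector z).
#' @return The `weight_profile` with component `v` filled in.
#' @export
v_values <- function(wp, rot) {
  z <- if (inherits(rot, "rotated_data")) rot$z else as.numeric(rot)
  if (length(z) != length(wp$w)) stop("dimension mismatch between weights and rotated data")
  wp$v <- wp$w * z^2
  wp
}

#' Rescaled central moments of the spectral weights
#'
#' Computes \eqn{\bar w}, the tau-moments
#' \eqn{\tau_k(\psi) = \psi^{-k} n^{-1}\sum_i (w_i - \bar w)^k} for k >= 2
#' and \eqn{\tau_1 = \psi^{-1}(1-\bar w)}, evaluated through the transform
#' \eqn{\tilde w_i} so that everything is well defined at \eqn{\psi = 0}
#' (where \eqn{\tilde w_i = t_i}), together with the error scale
#' \eqn{\nu = 1/\sqrt{n \tau_2}}. These moments are the currency of all bias
#' and variance approximations: bias is controlled by \eqn{1-\tau_1} and
#' variance by \eqn{\tau_2}.
#'
#' @param spec a `grm_spectrum` or eigenvalue vector.
#' @param psi trial heritability (admissible).
#' @param kmax highest tau order to compute (default 8).
#' @return Object of class `tau_moments`: `psi`, `w_bar`, `tau` (length
#'   `kmax`, `tau[k]` = \eqn{\tau_k}), `nu`, `n`, `degenerate` flag.
#' @export
tau_moments <- function(spec, psi, kmax = 8L) {
  if (kmax < 2L) stop("kmax must be at least 2")
  wp <- greml_weights(spec, psi)
  n <- length(wp$w)
  tau <- numeric(kmax)
  tau[1L] <- mean(wp$w_tilde)
  for (k in 2:kmax) tau[k] <- central_moment(wp$w_tilde, k)
  degenerate <- tau[2L] <= 0
  if (degenerate) {
    warning("degenerate spectrum: tau_2 = 0, error scale nu is infinite")
  }
  structure(
    list(psi = psi, w_bar = mean(wp$w), tau = tau,
         nu = if (degenerate) Inf else 1 / sqrt(n * tau[2L]),
         n = n, degenerate = degenerate),
    class = "tau_moments"
  )
}

# Internal constructor for tau moments obtained analytically (theoretical
# eigenvalue laws); n is carried only for nu / bias / variance evaluation.
make_tau_moments <- function(psi, tau, w_bar, n = NA_integer_) {
  degenerate <- tau[2L] <= 0
  structure(
    list(psi = psi, w_bar = w_bar, tau = tau,
         nu = if (degenerate || is.na(n)) NA_real_ else 1 / sqrt(n * tau[2L]),
         n = n, degenerate = degenerate),
    class = "tau_moments"
  )
}

#' @export
print.tau_moments <- function(x, ...) {
  cat(sprintf("tau moments at psi = %.4g (n = %s):\n", x$psi,
              ifelse(is.na(x$n), "?", format(x$n))))
  cat(sprintf("  w_bar = %.6g, tau_1 = %.6g, tau_2 = %.6g\n",
              x$w_bar, x$tau[1L], x$tau[2L]))
  if (length(x$tau) >= 4L) {
    cat(sprintf("  tau_3 = %.4g, tau_4 = %.4g\n", x$tau[3L], x$tau[4L]))
  }
  if (!is.na(x$nu)) cat(sprintf("  nu = %.4g\n", x$nu))
  invisible(x)
}
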
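# Shared helpers: small random spectra and instances used across test files.

# A random nonnegative spectrum with mean 1 and (optionally) a zero
# eigenvalue, mimicking the spectrum of a column-centered genotype matrix.
random_spectrum <- function(n, include_zero = TRUE) {
  t <- rexp(if (include_zero) n - 1L else n) + runif(1, 0.05, 0.4)
  if (include_zero) t <- c(0, t)
  t * (length(t) / sum(t))   # mean exactly 1
}

# A random (spectrum, z) instance drawn from the model at random parameters.
random_instance <- function(n = 40, psi0 = runif(1, 0.1, 0.7),
                            theta0 = runif(1, 0.5, 2), include_zero = TRUE) {
  t <- random_spectrum(n, include_zero)
  z <- gen_rotated(t, psi0, theta0)$z
  list(t = t, z = z, psi0 = psi0, theta0 = theta0)
}

# Central numeric derivative.
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Absolute-tolerance closeness (expect_equal's tolerance is relative, which
# is the wrong scale for small moment values and Monte-Carlo bounds).
expect_close <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y)), tol)
}

extdata <- function(...) {
  system.file("extdata", ..., package = "gremlspectra", mustWork = TRUE)
}
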
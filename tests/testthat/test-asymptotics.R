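test_that("MP quadrature moments match the printed small-mu series", {
  for (mu in c(0.01, 0.05)) {
    for (psi in c(0, 0.25, 0.5)) {
      tm <- mp_weight_moments(psi, mu, kmax = 4L)
      s <- mp_series_moments(psi, mu)
      budget <- 5 * mu^3            # order of the first omitted series term
      expect_close(tm$w_bar, s$w_bar, budget)
      expect_close(tm$tau[1], s$tau1, budget)
      expect_close(tm$tau[2], s$tau2, budget)
      expect_close(tm$tau[3], s$tau3, budget)
      expect_close(tm$tau[4], s$tau4, budget)
    }
  }
  # at psi = 0 the weight variance is the eigenvalue variance mu, exactly
  expect_close(mp_weight_moments(0, 0.25, 2L)$tau[2], 0.25, 1e-8)
  # tau_3 loses its mu^2 term at psi = 1/3
  expect_identical(mp_series_moments(1 / 3, 0.05)$tau3, 0)
})

test_that("MP eigenvalue and reciprocal moments match their closed forms", {
  for (mu in c(0.1, 0.2, 0.25)) {
    em <- mp_eigen_moments(mu)
    expect_close(em$var, mu, 1e-8)
    expect_close(em$third, mu^2, 1e-8)
    expect_close(em$fourth, 2 * mu^2 + mu^3, 1e-8)
    expect_close(em$recip_mean, 1 / (1 - mu), 1e-8)
    expect_close(em$recip_var, mu / (1 - mu)^3, 1e-8)
    expect_close(em$recip_third, 2 * mu^2 / (1 - mu)^5, 1e-7)
  }
  expect_close(mp_eigen_moments(0.2)$recip_var, 0.390625, 1e-8)
  expect_close(mp_eigen_moments(0.25)$recip_mean, 4 / 3, 1e-8)
  expect_error(mp_eigen_moments(1), "mu")
})

test_that("Stieltjes transform has the documented limits and series", {
  # zeta M(zeta) -> mu at infinity
  expect_close(1e6 * mp_stieltjes(1e6, 0.3)$M, 0.3, 1e-5)
  # small-mu limit: point mass at 1, M/mu -> 1/(zeta - 1)
  expect_close(mp_stieltjes(-1, 1e-4)$M / 1e-4, -0.5, 1e-3)
  # truncated series at mu = 0.1, zeta = -1, within its O(mu^3) budget
  zeta <- -1
  mu <- 0.1
  ser <- mu * (-1 / (1 - zeta) - mu / (1 - zeta)^3 +
                 mu^2 / (1 - zeta)^4 - 2 * mu^2 / (1 - zeta)^5)
  expect_close(mp_stieltjes(zeta, mu)$M, ser, 5 * mu^3)
  expect_error(mp_stieltjes(1, 0.25), "inside")
  # derivative matches numeric differentiation
  d_num <- (mp_stieltjes(-0.95, 0.1)$M - mp_stieltjes(-1.05, 0.1)$M) / 0.1
  expect_close(mp_stieltjes(-1, 0.1)$dM, d_num, 1e-3)
})

test_that("paired point-mass moments match closed forms and hand values", {
  pm <- paired_moments(2, 0.5)
  expect_close(pm$tau[1], 8 / 9, 1e-12)
  expect_close(pm$tau[2], 8 / 81, 1e-12)
  expect_equal(paired_moments(3, 0.2)$eigen_var, 1)   # (3-1)^2/(3+1)
  # closed forms agree with the direct two-point central moments everywhere
  set.seed(20)
  for (i in 1:10) {
    beta <- runif(1, 1.01, 50)
    psi <- runif(1, 0.02, 0.95)
    pm <- paired_moments(beta, psi)
    expect_close(1 - pm$tau[1], pm$closed_form$one_minus_tau1,
                 1e-12 * max(1, pm$closed_form$one_minus_tau1))
    expect_close(pm$tau[2], pm$closed_form$tau2, 1e-12)
  }
  expect_equal(paired_moments(1, 0.4)$tau[2], 0)      # degenerate point mass
  expect_error(paired_moments(0.5, 0.4), "beta")
})

test_that("dosage mixture interpolates between MP and paired laws", {
  a0 <- dosage_moments(0, 7, 0.04, 0.25)
  mp <- mp_weight_moments(0.25, 0.04)
  expect_close(a0$tau[1:4], mp$tau[1:4], 1e-10)
  expect_close(a0$w_bar, mp$w_bar, 1e-10)
  a1 <- dosage_moments(1, 7, 0.04, 0.25)
  pm <- paired_moments(7, 0.25)
  expect_close(a1$tau[1:4], pm$tau[1:4], 1e-12)
})

test_that("a small dosage of stratification cuts the SE by less than 25%", {
  red <- dosage_se_reduction(0.01, 1 / 25, 0.25)
  expect_gt(red$max_reduction_pct, 0)
  expect_lt(red$max_reduction_pct, 25)
})

test_that("lognormal moments match sampling and rise-fall in gamma", {
  expect_equal(lognormal_moments(0, 0.3)$tau[2], 0)
  set.seed(21)
  gam <- 2
  psi <- 0.4
  s2 <- log(1 + gam)
  x <- exp(rnorm(1e6, -s2 / 2, sqrt(s2)))
  wt <- x / (1 - psi + psi * x)
  tm <- lognormal_moments(gam, psi)
  mc_se <- stats::sd((wt - mean(wt))^2) / sqrt(1e6)
  expect_close(tm$tau[2], mean((wt - mean(wt))^2), 3 * mc_se)
  expect_close(tm$w_bar, mean(1 - psi * wt), 3 * psi * stats::sd(wt) / sqrt(1e6))
  # tau_2 over a log grid in gamma rises to a single maximum then falls
  grid <- exp(seq(log(0.01), log(1000), length.out = 30))
  t2 <- vapply(grid, function(g) lognormal_moments(g, psi, 2L)$tau[2], numeric(1))
  runs <- rle(sign(diff(t2)))$values
  expect_identical(runs, c(1, -1))
})

test_that("bias, variance and their ratio follow the tau-moment formulas", {
  set.seed(22)
  t <- random_spectrum(200)
  for (psi0 in c(0.2, 0.5, 0.8)) {
    tm <- tau_moments(t, psi0)
    b <- bias_approx(tm, psi0, 1000)
    v <- variance_approx(tm, psi0, 1000)
    expect_equal(b, -2 * (1 - psi0) * (1 - tm$tau[1]) / (1000 * tm$tau[2]))
    expect_equal(v, 2 * (1 - psi0)^2 / (1000 * tm$tau[2]))
    expect_lte(b, 0)
    expect_close(bias_se_ratio(tm, 1000), b / sqrt(v), 1e-14)
    # internal consistency: ratio^2 * n tau_2 = 2 (1 - tau_1)^2
    expect_close(bias_se_ratio(tm, 1000)^2 * 1000 * tm$tau[2],
                 2 * (1 - tm$tau[1])^2, 1e-12)
  }
  # bias vanishes at psi0 = 0 for unit-mean spectra (tau_1 = 1 there)
  tm0 <- tau_moments(t, 0)
  expect_close(bias_approx(tm0, 0, 1000), 0, 1e-12)
  expect_close(bias_se_ratio(tm0, 1000), 0, 1e-12)
  # variance decreases in tau_2 at fixed psi0 and n
  tm5 <- tau_moments(t, 0.5)
  expect_gt(variance_approx(tm5, 0.5, 100),
            2 * (1 - 0.5)^2 / (100 * (tm5$tau[2] * 2)))
  degen <- structure(list(psi = 0.3, tau = c(1, 0), n = 10),
                     class = "tau_moments")
  expect_error(bias_approx(degen, 0.3, 10), "tau_2")
})

test_that("delta-method approximations and their implied bias are correct", {
  d0 <- delta_method_moments(0, 0.4)
  expect_equal(d0$one_minus_tau1, 0)
  expect_equal(d0$tau2, 0)
  expect_equal(d0$implied_bias_times_n, -0.8)
  # var_t = mu matches the leading terms of the MP expansions
  mu <- 0.01
  psi0 <- 0.3
  d <- delta_method_moments(mu, psi0)
  s <- mp_series_moments(psi0, mu)
  expect_close(d$one_minus_tau1, 1 - s$tau1, 2 * mu^2)
  expect_close(d$tau2, s$tau2, 2 * mu^2)
})

test_that("independent-setting closed forms reproduce the headline numbers", {
  acc <- independent_bias_variance(0.25, 1e4, 0.01)
  expect_equal(round(acc$se, 2), 0.14)
  expect_equal(independent_bias_variance(0.5, 1e4, 0.1)$bias, -9.75e-5)
  expect_equal(independent_bias_variance(0, 500, 0.2)$bias, 0)
  # consistent with plugging MP quadrature moments into the tau formulas
  for (mu in c(0.01, 0.05)) {
    psi0 <- 0.35
    n <- 5000
    tm <- mp_weight_moments(psi0, mu)
    acc <- independent_bias_variance(psi0, n, mu)
    expect_close(bias_approx(tm, psi0, n), acc$bias, 20 * mu^2 * abs(acc$bias))
    expect_close(variance_approx(tm, psi0, n), acc$variance,
                 20 * mu^2 * acc$variance)
  }
})

test_that("paired-model accuracy approaches the stated large-beta limits", {
  n <- 1e4
  psi0 <- 0.4
  for (beta in c(200, 2000)) {
    pm <- paired_moments(beta, psi0, n = n)
    b <- bias_approx(pm, psi0, n)
    v <- variance_approx(pm, psi0, n)
    expect_close(b, -(2 * beta / n) * psi0^2 * (1 - psi0), 30 / beta * abs(b))
    expect_close(v, (2 * beta / n) * psi0^2 * (1 - psi0)^2, 30 / beta * v)
  }
  # variance grows with beta (stratified spread erodes accuracy)
  v1 <- variance_approx(paired_moments(50, psi0), psi0, n)
  v2 <- variance_approx(paired_moments(500, psi0), psi0, n)
  expect_gt(v2 / v1, 5)
})
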
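# Shared small genotype instance for the causal-subset tests.
misspec_instance <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- sim_design(n = 200, p = 800, psi0 = 0.5, seed = 404)
      G <- gen_genotypes(d)
      spec <- grm_spectrum(G)
      pos <- spec$t > 1e-12 * max(spec$t)
      cache <<- list(design = d, G = G, spec = spec, pos = pos)
    }
    cache
  }
})

test_that("gamma projections have zero mean, vanish at k = p, and are chi-square-like", {
  inst <- misspec_instance()
  spec <- inst$spec
  p <- spec$p
  pos <- inst$pos
  # k = p: the projection of the full index set is exact, gamma identically 0
  g_all <- gamma_projections(spec, seq_len(p))[pos]
  expect_equal(g_all, rep(0, sum(pos)), tolerance = 1e-6)
  expect_error(gamma_projections(spec, integer(0)), "at least one")

  set.seed(30)
  k <- 5
  draws <- replicate(1500, {
    g <- gamma_projections(spec, sample.int(p, k))
    g[!pos] <- 0
    g
  })
  # expectation zero over random eta, coordinate-wise and overall
  overall_mean <- mean(draws[pos, ])
  expect_lt(abs(overall_mean), 3 * stats::sd(draws[pos, ]) / sqrt(length(draws[pos, ])) * 5)
  # gamma_i + k approximately chi-squared with k df (loose goodness of fit)
  i <- which(pos)[100]
  ks <- stats::ks.test(draws[i, ] + k, stats::pchisq, df = k)
  expect_gt(ks$p.value, 0.001)
})

test_that("the causal fixed point solves both defining stationarity equations", {
  inst <- misspec_instance()
  spec <- inst$spec
  t <- spec$t
  n <- spec$n
  psi0 <- 0.5
  k <- 8
  # gamma == 0 recovers psi0 exactly
  expect_equal(causal_fixed_point(spec, rep(0, n), psi0, k)$psi_star, psi0,
               tolerance = 1e-9)

  set.seed(31)
  eta <- sample.int(spec$p, k)
  gam <- gamma_projections(spec, eta)
  gam[!inst$pos] <- 0
  cfp <- causal_fixed_point(spec, gam, psi0, k)
  ps <- cfp$psi_star
  expect_true(ps > admissible_interval(t)$psi_min && ps < 1)

  # literal stationarity residual (covariance form) vanishes at the root
  w_at <- function(x) (1 - x) / (1 - x + x * t)
  emp_cov <- function(a, b) mean(a * b) - mean(a) * mean(b)
  ws <- w_at(ps)
  w0 <- w_at(psi0)
  resid12 <- emp_cov(ws, ws / w0) +
    (psi0 / (1 - psi0)) / (k * ps / (1 - ps)) *
      (emp_cov(ws, gam) - emp_cov(ws, gam * ws))
  expect_equal(resid12, 0, tolerance = 1e-10)

  # independent oracle: stationarity against the model-implied E[z^2],
  # E[z_i^2] = sigma_g^2 t_i (1 + gamma_i/k) + sigma_e^2
  sigma_g2 <- psi0 / (1 - psi0)
  Ez2 <- sigma_g2 * t * (1 + gam / k) + 1
  resid10 <- emp_cov(ws, Ez2 * ws)
  expect_equal(resid10, 0, tolerance = 1e-10)
})

test_that("psi_star equals the long-run mean of the MLE at a fixed causal set", {
  inst <- misspec_instance()
  spec <- inst$spec
  pos <- inst$pos
  p <- spec$p
  n <- spec$n
  psi0 <- 0.5
  k <- 10
  set.seed(32)
  eta <- sample.int(p, k)
  gam <- gamma_projections(spec, eta)
  gam[!pos] <- 0
  ps <- causal_fixed_point(spec, gam, psi0, k)$psi_star

  # long-run simulation: many phenotype replicates at this fixed eta
  J <- 1500
  s <- sqrt(spec$t)
  Vh <- spec$V[eta, , drop = FALSE]
  Vh[, !pos] <- 0
  U <- matrix(rnorm(k * J), k)
  sigma_g2 <- psi0 / (1 - psi0)
  U <- sweep(U, 2, sqrt(colSums(U^2) / sigma_g2), "/")
  zm <- sqrt(p) * s * crossprod(Vh, U) + matrix(rnorm(n * J), n)
  ph <- greml_fit_many(prepare_fit_grid(spec), zm)
  expect_close(mean(ph), ps, 3 * stats::sd(ph) / sqrt(J))
})

test_that("averaging psi_star over random causal sets recovers psi0", {
  inst <- misspec_instance()
  spec <- inst$spec
  pos <- inst$pos
  psi0 <- 0.5
  k <- 10
  set.seed(33)
  ps <- replicate(250, {
    g <- gamma_projections(spec, sample.int(spec$p, k))
    g[!pos] <- 0
    causal_fixed_point(spec, g, psi0, k)$psi_star
  })
  expect_close(mean(ps), psi0, 3 * stats::sd(ps) / sqrt(250))
  # between-set variance decreases roughly like 1/k
  ps2 <- replicate(250, {
    g <- gamma_projections(spec, sample.int(spec$p, 40))
    g[!pos] <- 0
    causal_fixed_point(spec, g, psi0, 40)$psi_star
  })
  expect_gt(stats::var(ps) / stats::var(ps2), 2)
})

test_that("random-causal-subset inflation follows the tau formula", {
  tm <- mp_weight_moments(0.5, 0.01, n = 1e4)
  r <- rcs_error_inflation(tm, 0.5, k = 25)
  expect_equal(r$var_ratio, tm$tau[1]^2 * 0.25 / 25, tolerance = 1e-12)
  expect_close(r$var_ratio, 0.01, 2e-4)    # tau_1 near 1
  expect_equal(r$mean_psi_star, 0.5)
  expect_lt(rcs_error_inflation(tm, 0.5, k = 1e6)$var_ratio, 1e-6)
  expect_equal(r$var_psi_star, r$var_ratio * variance_approx(tm, 0.5, 1e4))
  # the tau_4 << tau_2 assumption is checked
  tm_bad <- paired_moments(500, 0.5, n = 1e4)
  expect_warning(rcs_error_inflation(tm_bad, 0.5, k = 10), "tau_4")
})

test_that("untagged-variation bias has the documented structure", {
  tm <- mp_weight_moments(0.4, 0.02, n = 2e3)
  psi0 <- 0.4
  k <- 20
  # sigma_delta = 0 with a copy matrix reduces to the RCS standard deviation
  ub <- untagged_bias(tm, psi0, 2e3, k, sigma_delta2 = 0, mean_sigma_l4 = 1)
  expect_identical(ub$deterministic_bias, 0)
  rcs <- rcs_error_inflation(tm, psi0, k)
  tau <- tm$tau
  extra <- (2 * tau[3] * tau[1] + tau[4]) / (tau[2] * tau[1]^2)
  expect_lt(abs(extra), 0.05)                       # higher taus negligible here
  expect_close(ub$random_sd, rcs$sd_psi_star, abs(extra) * rcs$sd_psi_star)
  # deterministic bias is -2 sigma_delta^2 psi0^2, strictly negative
  ub2 <- untagged_bias(tm, psi0, 2e3, k, sigma_delta2 = 0.05)
  expect_equal(ub2$deterministic_bias, -2 * 0.05 * psi0^2)
  expect_equal(untagged_bias(tm, psi0, 2e3, k, 0.1)$deterministic_bias /
                 ub2$deterministic_bias, 2)
  # splitting tagging weight across m observed SNPs shrinks the random part
  ub_split <- untagged_bias(tm, psi0, 2e3, k, 0, mean_sigma_l4 = 1 / 4)
  expect_equal(ub_split$sigma_gamma, ub$sigma_gamma / 2, tolerance = 1e-12)
})

test_that("the GRM inversion map is an involution with exact MLE equivariance", {
  set.seed(34)
  t <- rexp(50) + 0.3
  t <- t / mean(t)
  z <- gen_rotated(t, 0.35, 1.5)$z
  m <- symmetry_map(t, z, psi = 0.35, theta = 1.5)
  expect_equal(m$psi, 0.65)
  expect_equal(m$theta, 1.5 * (1 / 0.35 - 1))
  expect_equal(symmetry_map(0.5, 1, psi = 0.5)$psi, 0.5)   # fixed point
  # double application restores the configuration
  m2 <- symmetry_map(m$spec, m$rot)
  expect_equal(m2$spec$t, sort(t), tolerance = 1e-12)
  expect_equal(sort(abs(m2$rot$z)), sort(abs(z)), tolerance = 1e-12)
  expect_error(symmetry_map(c(0, 1), c(1, 1)), "not invertible")

  f <- greml_fit(t, z)
  fm <- greml_fit(m$spec, m$rot)
  expect_equal(fm$psi_hat, 1 - f$psi_hat, tolerance = 1e-8)
  expect_equal(fm$theta_hat, f$theta_hat * (1 / f$psi_hat - 1), tolerance = 1e-6)
  # the map conjugates the score: score'(1 - psi) = -(psi/(1-psi))^2 score(psi)
  s1 <- greml_score(0.4, t, z)
  s2 <- greml_score(0.6, m$spec, m$rot)
  expect_lt(s1 * s2, 0)
  expect_close(s2, -s1 * (0.4 / 0.6)^2, 1e-10 * max(1, abs(s1)))
})

test_that("phenotype measurement error lowers heritability, not genetic variance", {
  e0 <- phenotype_error_equiv(0.5, 1, 0)
  expect_equal(e0$psi_eff, 0.5)
  expect_equal(e0$theta_eff, 1)
  e <- phenotype_error_equiv(0.5, 1, 1)
  expect_equal(e$psi_eff, 1 / 3)
  expect_equal(e$genetic_variance, 1)
  expect_lt(phenotype_error_equiv(0.5, 1, 100)$psi_eff, 0.01)
  set.seed(35)
  for (i in 1:10) {
    psi <- runif(1, 0.05, 0.9)
    th <- runif(1, 0.5, 3)
    s2 <- rexp(1)
    eq <- phenotype_error_equiv(psi, th, s2)
    expect_lte(eq$psi_eff, psi)
    expect_equal(eq$psi_eff / (eq$theta_eff * (1 - eq$psi_eff)),
                 psi / (th * (1 - psi)), tolerance = 1e-12)
  }
})

test_that("genotype error maps to a noise inflation decreasing in pi", {
  id <- genotype_error_equiv(0.4, 1, 0, 1000)
  expect_equal(id$psi_eff, 0.4)
  expect_true(id$valid)
  pis <- c(0.001, 0.01, 0.05, 0.2)
  eff <- vapply(pis, function(pp) genotype_error_equiv(0.4, 1, pp, 1000)$psi_eff,
                numeric(1))
  expect_true(all(diff(eff) < 0))
  expect_false(genotype_error_equiv(0.4, 1, 0.001, 1000)$valid)  # p*pi small
})
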
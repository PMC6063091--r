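---
title: "Spectral analysis of GREML heritability estimates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral analysis of GREML heritability estimates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gremlspectra)
```

## The model

GREML-type heritability analysis fits the random-effects model

$$ y = Z u + \varepsilon, \qquad
   u_j \sim N\!\big(0, \tfrac{\phi_0}{p\,\theta_0}\big), \qquad
   \varepsilon_i \sim N\!\big(0, \tfrac{1}{\theta_0}\big), $$

where $Z$ is the $n \times p$ matrix of column-centered, normalized
genotypes, $\theta$ is the precision of the non-genetic noise, $\psi$ is the
heritability (the fraction of phenotypic variance that is additive-genetic)
and $\phi = \psi/(1-\psi)$. Conditional on $Z$, the phenotype is multivariate
normal with covariance $\theta^{-1}(\phi A + I_n)$ where $A = ZZ^*/p$ is the
genetic relatedness matrix (GRM). Everything the likelihood can learn about
$(\theta, \psi)$ passes through the eigenvalues $t_1 \le \dots \le t_n$ of
$A$ — the squared singular values of $Z/\sqrt p$ — and the rotated
observations $z = U^* y$, where $U$ holds the left singular vectors. In the
rotated basis the coordinates are independent centered normals with
variances $(1-\psi+\psi t_i)/(\theta(1-\psi))$.

Two normalization conventions are supported. The default (`global`) centers
every column and scales the whole matrix so its mean square is 1, which
makes $\mathrm{mean}(t) = 1$ exactly; `per_column` additionally gives every
column unit variance (and implies the global condition). Both appear in
practice; the simulation generator uses `per_column`, matching the usual
treatment of simulated binomial genotypes, while file-based fits default to
`global`. Column centering always forces one exact zero eigenvalue, whose
rotated coordinate absorbs the phenotype mean.

## Profile likelihood, score, and the estimator

Maximizing the two-parameter log likelihood over $\theta$ analytically, with
$w_i(\psi) = (1-\psi)/(1-\psi+\psi t_i)$ and maximizer
$\hat\theta(\psi) = n / \sum_i w_i z_i^2$, leaves the one-parameter profile

$$ \ell_p(\psi) = -\tfrac n2 \log\Big(\sum_i w_i(\psi) z_i^2\Big)
   + \tfrac12 \sum_i \log w_i(\psi) + \tfrac n2(\log n - 1), $$

defined on the open interval $(-1/(\max_i t_i - 1),\, 1)$. Negative trial
values — and negative estimates — are meaningful within the model and are
never truncated. With a zero eigenvalue present and $\max t > 1$ the profile
tends to $-\infty$ at both ends, so an interior maximum exists.

The stationarity condition is that the empirical covariance over
coordinates of $w_i(\hat\psi)$ and $v_i(\hat\psi) = w_i(\hat\psi) z_i^2$
vanishes. Because $w_i = 1 - \psi\tilde w_i$ with
$\tilde w_i = t_i/(1-\psi+\psi t_i)$, that covariance equals
$-\psi\,\mathrm{Cov}(\tilde w, v)$ and degenerates at $\psi = 0$; the
implemented score is the continuous factor
$U(\psi) = \mathrm{Cov}(\tilde w(\psi), v(\psi))$, which satisfies

$$ \ell_p'(\psi) = \frac{n}{2(1-\psi)\bar v}\, U(\psi), $$

a positive multiple, so roots of $U$ are exactly the stationary points. The
proportionality is verified against numeric differentiation in the test
suite. `greml_fit()` scans $U$ on a 64-point logit-spaced grid (denser near
both endpoints), polishes every sign change with `uniroot` at tolerance
$10^{-12}$, and keeps the root with the highest profile value; if no sign
change exists (possible only without a zero eigenvalue) it falls back to
bounded maximization of $\ell_p$ and flags the fit. Nothing in the theory
rules out multiple roots, so global selection over all roots is used.

## Tau moments and accuracy approximations

All accuracy formulas are driven by rescaled central moments of the
transformed spectrum: $\tau_1 = \mathrm{mean}(\tilde w)$,
$\tau_k = \psi^{-k}\,n^{-1}\sum_i (w_i - \bar w)^k$ for $k \ge 2$ (computed
through $\tilde w$, hence well defined at $\psi = 0$), and the error scale
$\nu = (n\tau_2)^{-1/2}$. Empirical moments use the $1/n$ convention
throughout so that $\mathrm{mean}(t) = 1$ holds exactly under global
normalization. Moments are computed to order `kmax = 8` by default; the
highest order any implemented formula needs is $\tau_4$.

To leading order in $\nu$,

$$ \mathrm{Bias}(\hat\psi) \approx -\frac{2(1-\psi_0)(1-\tau_1)}{n\,\tau_2},
 \qquad \mathrm{Var}(\hat\psi) \approx \frac{2(1-\psi_0)^2}{n\,\tau_2}, $$

with bias/SE ratio $-\sqrt2\,(1-\tau_1)/\sqrt{n\tau_2}$, nonpositive by
Jensen's inequality and exactly zero at $\psi_0 = 0$ for unit-mean spectra.
The remainder is of order $\nu^3$; our Monte Carlo runs at $n = 2000$,
$\mu = 0.25$ (where $\nu \approx 0.09$) put the residual bias gap at about
$2 \times 10^{-4}$, i.e. well below the Monte-Carlo resolution of a
5000-replicate study, which is why those study sizes are used in the tests.

Four theoretical eigenvalue laws supply analytic $\tau$ moments:

* **Marcenko–Pastur** (`mp_weight_moments`): the independent-setting limit
  with aspect ratio $\mu = n/p$, density
  $\sqrt{(b-t)(t-a)}/(2\pi\mu t)$ on $[(1-\sqrt\mu)^2, (1+\sqrt\mu)^2]$.
  Moment functionals (and the Stieltjes transform `mp_stieltjes`) are
  computed by adaptive quadrature against this density — the primary route,
  because the quadratic closed form for $M(\zeta)$ is easy to mis-transcribe
  while the limiting measure is unambiguous — and cross-checked against the
  order-$\mu^2$ series, exposed separately in `mp_series_moments()` so that
  truncation error is distinguishable from implementation error. The series
  route yields the closed forms in `independent_bias_variance()`: at
  $n = 10^4$, $\mu = 0.01$, $\psi_0 = 0.25$ the SE is 0.14 — large standard
  errors, not bias, are the practical limitation in the independent setting.
* **Paired point mass** (`paired_moments`): mass $\beta/(\beta+1)$ at
  $1/\beta$ and $1/(\beta+1)$ at $\beta$, a stylized deeply stratified
  spectrum with eigenvalue variance $(\beta-1)^2/(\beta+1)$. Two-point
  moments are exact; the printed closed forms for $1-\tau_1$ and $\tau_2$
  are carried alongside and tested to $10^{-12}$. Exact $\tau$'s are used in
  the bias/variance formulas; the large-$\beta$ display forms
  ($-2\beta\psi_0^2(1-\psi_0)/n$ and $2\beta\psi_0^2(1-\psi_0)^2/n$) are
  asserted as limits only.
* **Dosage mixture** (`dosage_moments`): a fraction $\alpha$ paired-mass,
  the rest MP. Raw weight moments are mixed (so the between-component mean
  gap feeds $\tau_2$), then centralized. A 1% dosage at $\mu = 1/25$,
  $\psi = 1/4$ cuts the SE by at most about 18% over all $\beta$ — under the
  25% ceiling one expects from this model.
* **Lognormal** (`lognormal_moments`): eigenvalue variance $\gamma$ with the
  unit-mean constraint (underlying normal variance $\log(1+\gamma)$, mean
  $-\tfrac12\log(1+\gamma)$); the weights are logit-normal with no closed
  moments, so everything is quadrature on the underlying normal scale,
  validated against large Monte Carlo samples. $\tau_2$ rises to a single
  maximum in $\gamma$ and then decays: moderate stratification helps,
  extreme stratification hurts.

Quadrature uses `stats::integrate` at $10^{-10}$ absolute / $10^{-8}$
relative tolerance.

## Misspecification analyses

**Restricted causal subsets.** If only a fixed subset $\eta$ of $k$ SNPs is
causal, the estimator converges (over phenotype replicates) to the
Kullback–Leibler-closest $\psi_*$, determined by the projection deviations
$\gamma_i = p\sum_{j\in\eta} V_{ji}^2 - k$. The defining stationarity
equation

$$ 0 = \mathrm{Cov}\!\big(w(\psi_*), \tfrac{w(\psi_*)}{w(\psi_0)}\big)
  + \frac{\psi_0/(1-\psi_0)}{k\,\psi_*/(1-\psi_*)}
    \big[\mathrm{Cov}(w(\psi_*), \gamma) -
         \mathrm{Cov}(w(\psi_*), \gamma\, w(\psi_*))\big] $$

factors, after substituting $w = 1 - \psi\tilde w$, as $\psi_*$ times the
smooth function

$$ h(\psi) = \mathrm{Var}(\tilde w(\psi))
   \Big[\psi - \frac{\psi_0(1-\psi)}{1-\psi_0}\Big]
   - \frac{\psi_0(1-\psi)}{(1-\psi_0)\,k}\,
     \mathrm{Cov}\big(\tilde w(\psi), \gamma\,\tilde w(\psi)\big), $$

which `causal_fixed_point()` solves by the same bracketed scan as the MLE
(root nearest $\psi_0$ when several exist). The factored form avoids both
the spurious root at $\psi = 0$ and the $1/\psi$ prefactor; tests verify
that the literal covariance form, and the equivalent condition
$\mathrm{Cov}(w, E[z^2] w) = 0$ with the model-implied
$E[z_i^2] = \sigma_g^2 t_i (1 + \gamma_i/k) + \sigma_e^2$, both vanish at
the returned root, and that $\psi_*$ matches the long-run mean of the MLE
over thousands of phenotype replicates at a fixed $\eta$.

Averaged over uniformly random causal sets, $E[\psi_*] \approx \psi_0$ and

$$ \frac{\mathrm{Var}(\psi_*)}{\mathrm{Var}(\hat\psi)}
   \approx \frac{\tau_1^2 \psi_0^2}{k} $$

(`rcs_error_inflation`), derived by treating $\gamma_i + k$ as independent
$\chi^2_k$ variables across coordinates. A caveat that our own simulations
expose: the independence step degrades as $\mu = n/p$ grows. Measuring
$\mathrm{Var}_\eta(\mathrm{Cov}(\tilde w, \gamma\tilde w))$ against the
iid-$\chi^2$ prediction on simulated genotype matrices gives ratios of
about 0.88 at $\mu = 0.02$, 0.73 at $\mu = 0.1$, and 0.48 at $\mu = 0.25$,
with per-coordinate $\mathrm{Var}(\gamma_i) \approx 2k$ intact throughout —
the deficit is cross-coordinate dependence of the singular-vector
projections, not the marginal law, and it is a property of the
approximation, not of the fixed-point computation (feeding synthetic iid
$\chi^2_k$ deviations through the same code reproduces the predicted
variance within Monte-Carlo error). At the desk-scale study size used in
the test suite ($n = 500$, $p = 2000$, hence $\mu = 0.25$) the formula
therefore overpredicts the between-set variance by roughly a factor of two
for small $k$, and the corresponding acceptance check fails its 3-SE
comparison for the small-$k$ cells; at ratios $\mu \lesssim 0.1$, where the
approximation is intended to operate, the agreement is good.

**Untagged causal variants.** When the $k$ causal SNPs are only linearly
tagged by the panel, $Z_c = Z_o B + \delta$ with residual variances
averaging $\sigma_\delta^2$ and column sums of squares
$\sigma_{(\ell)}^2$, the asymptotic estimate decomposes into a
deterministic bias $-2\sigma_\delta^2\psi_0^2$ plus a random component
$(\sigma_\gamma/\tau_2) X$, $X$ approximately standard normal, with

$$ \sigma_\gamma^2 = \frac{2\psi_0^2(1-\psi_0)^2}{nk}
   \big(\tau_2\tau_1^2 + 2\tau_3\tau_1 + \tau_4\big)\,
   \overline{\sigma_{(\ell)}^4}. $$

This reading of the decomposition was fixed by a consistency requirement
that is itself part of the test suite: with $\sigma_\delta = 0$ and a 0/1
copy matrix ($\overline{\sigma_{(\ell)}^4} = 1$) it must reduce exactly to
the random-causal-subset standard deviation above, which it does.
Splitting each causal SNP's tagging weight across $m$ observed SNPs
divides $\overline{\sigma_{(\ell)}^4}$ by $m$ and so shrinks the random
component.

**Measurement error.** Additive phenotype error of variance $\sigma_m^2$
leaves the genetic variance $g = \psi/(\theta(1-\psi))$ untouched and
rescales $(\psi, \theta)$ to $\psi_{\mathrm{eff}} = g/(g + 1/\theta +
\sigma_m^2)$, $\theta_{\mathrm{eff}} = 1/(1/\theta + \sigma_m^2)$. Sparse
independent genotype errors (probability $\pi$ per entry) act like extra
phenotype noise $c\,p\,\sigma_u^2\pi$; the constant $c$ depends on the
error distribution and has no closed form for count resampling, so it is
left as a calibration parameter and the qualitative prediction — estimates
decreasing in $\pi$ — is validated by simulation with coupled (nested)
error masks across $\pi$ values for variance reduction.

**Inversion symmetry.** Replacing $y$ by $A^{-1/2}y$ maps the model to
itself with $t \to 1/t$, $z \to z/\sqrt t$, $\psi \to 1-\psi$,
$\theta \to \theta(1/\psi - 1)$. The MLE is exactly equivariant under this
involution whenever both optima are interior, which the tests verify to
$10^{-8}$; a fit with $\hat\psi \le 0$ maps to a parameter outside the
admissible interval of the inverted spectrum, so such draws are excluded
from the equivariance check by design, not by tolerance.

## The simulation generators

`gen_genotypes()` draws MAFs uniformly on $[0.05, 0.5]$, allele counts
Binomial(2, MAF), and normalizes columns to mean 0, variance 1 — exactly
the distributional structure the model assumes: no linkage, no relatedness,
no shared environment. What passing Monte-Carlo tests show is therefore
internal consistency of the formulas under the model, not robustness to
the LD structure, ascertainment, or confounding of real cohorts.
`gen_rotated()` samples the rotated coordinates directly from their exact
normal law, the fast genotype-free path; the two paths give statistically
indistinguishable estimator distributions (tested by Kolmogorov–Smirnov),
which validates the diagonalization end to end. `mp_quantile_spectrum()`
places eigenvalues at the MP inverse CDF at $(i-\tfrac12)/n$, a
deterministic variance-reduced stand-in for a sampled spectrum.

Causal phenotypes condition the effect vector on its sum of squares:
i.i.d. normal draws rescaled so $\sum u_j^2 = \sigma_g^2$ exactly, with
$\sigma_e^2 = \sigma_g^2(1-\psi_0)/\psi_0$; with $\theta_0 = 1$ this makes
the noise variance 1. The noise scale of the published study conditions is
not fully determined, so $\theta_0 = 1$ is the recorded default everywhere.

`causal_study()` runs the restricted-causality experiment at desk scale —
defaults $n = 500$, $p = 2000$, $I = 50$ causal sets, $J = 100$ replicates
per set, versus $p = 10^5$, $I = 100$, $J = 1000$ at full scale — chosen so
that the complete study runs in seconds while keeping the identical
statistical structure (the $\mu$-dependence caveat above is the one
structural difference that scale introduces). Replicates are generated in
rotated coordinates, $z = \sqrt p\, s \circ (V_\eta^\top u) +
\tilde\varepsilon$, and fitted with a shared precomputed score grid
(`prepare_fit_grid()` / `greml_fit_many()`), which makes ~30,000 fits per
study cheap. The per-set/within-set variance split uses the balanced
one-way method-of-moments decomposition, $\widehat{\mathrm{Var}}(\psi_*) =
\max(0, (\mathrm{MSB} - \mathrm{MSW})/J)$ — identical to the REML answer
for balanced designs whenever $\mathrm{MSB} \ge \mathrm{MSW}$, without a
mixed-model dependency.

All generators are pure functions of (design, seed), and every CLI run
writes a manifest with the full parameter set, so outputs are bitwise
reproducible.

## Numerical choices and degenerate inputs

* Centering before scaling, so the zero singular value is exact; population
  ($1/n$) variances everywhere.
* Spectrum from the $n \times n$ Gram matrix (never the $p \times p$ one);
  roundoff-negative eigenvalues clipped at zero below
  $10^{-10}\max t$.
* A spectrum with all eigenvalues equal makes $\psi$ non-identifiable:
  `greml_score` returns 0 with a warning, `greml_fit` refuses, and
  `tau_moments` flags $\nu = \infty$.
* $\psi = 0$ is handled by continuity through the $\tilde w$
  parameterization; $\psi$ outside the admissible interval is an error, not
  a clamp.
* The density constant $-(n/2)\log 2\pi$ is included in `greml_loglik` by
  default (so it matches a multivariate-normal oracle) and omitted from
  `profile_loglik` by default (the conventional display); both have flags.

## Known limitations

The package analyzes the model in which it lives: independent entries or
stylized stratified spectra, fully observed genotypes, no fixed-effect
covariates, no LD-aware tagging beyond the linear model above, and no
shared-environment confounding (which enters only through the discussion of
spectral spread: related samples raise $\tau_2$ and cut the variance, at
the price of confounding risk that the model cannot see). The
random-causal-subset variance formula should be trusted only for
$\mu \lesssim 0.1$, per the measurements above. The probabilistic model in
which causal sites are an unobserved random subsample of a larger panel
admits no analytic treatment here and is available only as a simulation
exercise via the generators.
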
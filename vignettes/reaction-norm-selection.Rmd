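---
title: "Estimating nonlinear selection on reaction norms"
author: "rnselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nonlinear selection on reaction norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

A labile trait — a behaviour, a hormone titre, a clutch size — is
expressed many times over an individual's life, and its expression is
structured by the individual's **reaction norm (RN)**: the expected trait
value in the reference environment (intercept $\mu_0 + \mu_{0j}$), the
change per unit of an environmental covariate (slope
$\beta_x + \beta_{xj}$, plasticity), and the magnitude of stochastic
variation around that expectation (residual parameter
$\sigma_0 + \sigma_{0j}$, the inverse of predictability).  These three
individual-level parameters are plausible direct targets of selection, but
they are never observed: each individual contributes a handful of noisy
phenotype measurements, from which the parameters must be inferred.

The statistical danger is well known.  If individual RN parameters are
first estimated (individual means, per-individual regressions, BLUPs) and
then regressed on fitness, the uncertainty of the first stage is ignored;
selection estimates become anticonservative and, for nonlinear selection,
can be biased in either direction.  `rnselect` avoids this by fitting one
joint model in which the latent parameters appear simultaneously in the
phenotype likelihood and in the fitness likelihood — the
errors-in-variables (latent-variable) approach.  The latent deviations are
never plugged in as point estimates anywhere in the pipeline.

## The joint model

Phenotype measure $t$ of individual $j$ in environment $x_{jt}$:

$$z_{jt} \sim \mathrm{Normal}(\mu_{jt}, \sigma_j), \qquad
\mu_{jt} = \mu_0 + \mu_{0j} + (\beta_x + \beta_{xj}) x_{jt}, \qquad
\log \sigma_j^2 = \sigma_0 + \sigma_{0j}.$$

The dispersion is modelled on the log-variance scale throughout, so a
linear predictor $\eta$ corresponds to an SD of $\sqrt{e^{\eta}}$; with
$\sigma_0 = \log 2$ the within-individual SD is $\sqrt 2 \approx 1.41$.
A log-SD convention would silently halve all residual effect sizes, which
is why the package fixes one convention and exposes it through
`dispersion_sd()`.  The triplet of individual deviations
$u_j = (\mu_{0j}, \beta_{xj}, \sigma_{0j})$ is multivariate normal with
covariance $P$ (SDs times a correlation matrix), making the model a
double-hierarchical Gaussian mixed model.

Fitness measures of the same individuals get a second response model,

$$W_{jt} \sim \mathrm{Normal}(\theta_j, \delta), \qquad
\theta_j = W_0 + W_{0j} + b^\top u_j + u_j^\top Q u_j,$$

with directional coefficients $b$ and the symmetric quadratic matrix $Q$
assembled from six coefficients by `make_Q()`: squared terms on the
diagonal, cross-coefficients halved off the diagonal so
$u^\top Q u$ reproduces the polynomial exactly (the classic factor-of-two
pitfall in quadratic selection analysis).  The individual fitness effect
$W_{0j} \sim \mathrm{Normal}(0, sd_{W0})$ absorbs repeatable fitness
differences not caused by the modelled RN parameters.  When every
individual has a single fitness measure, $sd_{W0}$ and $\delta$ enter the
likelihood only through their sum of squares and cannot be separated, so
`rn_selection()` drops $W_{0j}$ in that case and refuses a request to
force it in.

## From coefficients to selection gradients

$b$ and $Q$ live on the scale of the fitness model and are not themselves
selection gradients.  The package defines gradients as population-averaged
derivatives of **relative expected fitness**: with
$w(u) = E[W\mid u] / \bar W$ and $u \sim \mathrm{MVN}(0, P)$,

$$\beta_k = E\!\left[\partial w / \partial u_k\right], \qquad
\gamma_{kl} = E\!\left[\partial^2 w / \partial u_k \partial u_l\right].$$

This is the Lande–Arnold-consistent estimand for latent traits; for
Gaussian fitness with identity link it has the closed form
$\bar W = W_0 + \mathrm{tr}(QP)$, $\beta = b / \bar W$,
$\gamma = 2Q / \bar W$ (`analytic_gradients_gaussian()`).  For other
fitness links no closed form is assumed: `mc_average_gradients()` draws
deviations from $\mathrm{MVN}(0, P)$, evaluates expected fitness on the
observed scale (for a log link,
$\exp(\theta(u) + \tfrac12 sd_{W0}^2 + \tfrac12 \delta^2)$), and averages
central finite-difference first and second derivatives.  Defaults:
$n_{mc} = 20{,}000$ deviations per evaluation ($2{,}000$ when iterating
over thousands of posterior draws), step $h = 10^{-3}$, common random
numbers across posterior draws so that draw-to-draw differences reflect
the parameters rather than Monte-Carlo noise.  The two routes agree to
better than $0.01$ per entry at $n_{mc} = 10^5$ on identity-link test
cases, which the test suite checks.

`posterior_selection_gradients()` applies the transformation to every
posterior draw of $(b, Q, W_0, P)$.  Because the analytic form is the
exact limit of the Monte-Carlo evaluator for identity-link Gaussian
fitness, it is used by default there; `method = "mc"` forces the numeric
route for any link.  Rarely, an early or extreme posterior draw implies
$\bar W \le 0$, where relative fitness is undefined; the default is to
fail naming the draw, and validation runs use `on_invalid = "drop"`,
which excludes such draws and records how many.  Gradients are
variance-standardized as $\beta^*_k = \beta_k \,\mathrm{sd}_k$ and
$\gamma^*_{kl} = \gamma_{kl}\,\mathrm{sd}_k \mathrm{sd}_l$ with
$\mathrm{sd}_k = \sqrt{P_{kk}}$; mean standardization is not offered
separately because the gradients are already relative-fitness based.

Latent-scale repeatability is reported by `latent_repeatability()`: the
share of each RN parameter's variance in the total latent plus residual
phenotypic variance.  Under the validation regime (variances $1,1,1$,
residual variance $2$) each parameter has $R = 0.2$.

## Priors and sampling

Priors follow the regularization principle: zero-centred unit-scale
normals on $(\mu_0, \beta_x, \sigma_0, W_0, b, q)$, half-normal(1) on all
SDs, and LKJ($\eta$) on the among-individual correlation matrix —
$\eta = 2$ by default, $\eta = 5$ for the validation regime where
correlations were generated weakly concentrated near zero.  These scales
assume data on roughly unit scale; rescale gross phenotypes before
fitting.

Sampling is MCMC via JAGS.  Two implementation details matter:

* **Exact LKJ prior.**  JAGS has no built-in LKJ distribution.  The
  correlation matrix is parameterized through its C-vine partial
  correlations — for dimension 3, two first-tree correlations with
  shifted-Beta$(\eta + \tfrac12, \eta + \tfrac12)$ priors and one
  second-tree partial correlation with shifted-Beta$(\eta, \eta)$ — whose
  implied joint density is exactly $\propto \det(R)^{\eta - 1}$ and whose
  reconstruction is always positive definite.  The simulator's
  `rlkj_corr()` uses the same construction, and the test suite checks the
  sampled correlations against the known Beta marginal.

* **Non-centred latent field.**  Deviations are expressed as
  standard-normal innovations scaled by $\mathrm{diag}(sds)$ times the
  Cholesky factor of the correlation matrix, which removes the
  scale–location funnel between $sds$ and the deviations.

`rn_sampler()` defaults to 4 chains of 1000 warmup (half adaptation, half
burn-in) plus 1000 retained iterations.  Scaled-down runs (validation
studies, quick checks) use 2 chains of 500 + 500.  Chain seeds derive
deterministically from one integer seed, so any fit is bit-reproducible.
`check_convergence()` reports split R-hat (computed in the package, each
chain split in half) and effective sample sizes (spectral estimator from
`coda`), flagging parameters above 1.01.  Short-chain runs routinely show
R-hat up to ~1.1 and effective sizes of a few dozen; they are adequate
for posterior medians aggregated across many datasets, not for precise
tail quantiles of a single analysis.

## The simulator and the validation study

`sim_config()` fixes a study design and the generative parameters.
Defaults reproduce the validation regime: unit among-individual SDs,
LKJ(5) correlations, $\sigma_0 = \log 2$ (residual phenotypic variance 2,
hence $R = 0.2$ per parameter), $sd_{W0} = 1$, $\delta = 1$, environments
$x \sim \mathrm{Normal}(0,1)$ i.i.d. across observations (randomized
exposure), Gaussian phenotype and fitness.  $\delta = 1$ is the package's
choice where the generative description left the fitness residual scale
open.  The population means $\mu_0, \beta_x$ default to zero; they do not
enter the gradients.

The simulator is parameterized directly by **target standardized
gradients** rather than raw coefficients: given targets
$(\beta^*, \gamma^*)$ it sets $b_k = \beta^*_k / \mathrm{sd}_k$,
$Q_{kl} = \gamma^*_{kl} \bar W / (2\, \mathrm{sd}_k \mathrm{sd}_l)$ and
normalizes mean fitness to 1 by $W_0 = 1 - \mathrm{tr}(QP)$, so the
estimand of every simulated dataset is exact by construction (the package
inverts its own gradient map; the tests confirm the round trip).  Study
conditions for validation runs are sampled integer-uniformly:
$N \sim U\{100..1000\}$, $t_z \sim U\{3..7\}$, $t_w \sim U\{1..5\}$, and
all nine gradient targets $\sim U(0.1, 0.5)$ — all positive, so the
posterior probability of positive selection ($p_+$) acts as a power
metric.  Correlational gradient targets are drawn from the same range as
the diagonal ones.

`run_validation_study()` executes draw–simulate–fit–transform–score per
condition and reports, per dataset and gradient component on the
standardized scale: bias (truth minus posterior median), RMSD (root mean
squared deviation of the posterior draws from the truth, i.e. computed
across the posterior, not across datasets), and $p_+$.  The mean absolute
among-individual correlation accompanies each row as a condition
covariate.  Dataset-level failures are recorded and excluded rather than
fatal.  `polynomial_trend_summary()` fits the second-order polynomial
used to summarize metric-versus-condition trends.

What the simulator does *not* emulate: non-Gaussian phenotypes or
fitness, unbalanced or missing repeats, within-individual environmental
centering, autocorrelated environments, and fluctuating
(environment-specific) selection.  Passing validation therefore shows the
estimator is correct under its own assumptions, not that field data meet
them.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run scaled-down versions of the
validation study chosen to finish in minutes: 8 datasets at $N = 200$,
$t_z = 5$, $t_w = 2$ with 2 chains of 500 + 500 for the bias check
(mean directional bias within $\pm 0.05$ of zero); 6 null-selection
datasets at $N = 150$ for calibration of $p_+$ around 0.5; 20 replicates
at $N = 100$, $t_z = 3$, $t_w = 1$ for 90% interval coverage (expected in
the 80–98% Monte-Carlo band).  `scripts/extended_checks.R` runs the
full condition grid (40+ datasets, $N$ up to 1000) and verifies the
qualitative trends — RMSD falling and $p_+$ rising with $N$, $p_+$ rising
with effect size, quadratic gradients less accurate and less powerful
than directional ones — at a cost of roughly an hour.

## Numerical choices and degenerate inputs

* Cross-coefficients are halved when building $Q$; `q_from_Q` inverts it.
* $\bar W \le 0$ at a posterior draw is treated as described above; for a
  single `gradient_estimate` it is always an error.
* The repeatability denominator must be positive; zero total variance is
  an input error rather than `NaN`.
* `sample_validation_conditions()` samples integer ranges inclusively and
  handles degenerate (fixed) ranges exactly.
* The finite-difference step $h = 10^{-3}$ balances truncation against
  round-off for second derivatives of smooth links; halving $h$ moves
  entries by less than $10^{-3}$ in the shipped tests.
* All randomness flows from integer seeds through a deterministic
  splitter (`derive_seed`), keeping every derived seed within 32-bit
  range.

## Known limitations

Only Gaussian phenotype (identity mean link) and Gaussian fitness
(identity link) are implemented in the sampler; the gradient machinery
already accepts a log fitness link, and other links are an extension
point, not a tested path.  JAGS's componentwise samplers mix slowly on
the latent quadratic fitness geometry compared with Hamiltonian Monte
Carlo: at the scaled-down settings effective sample sizes of a few dozen
per parameter are typical, and posterior medians of weakly informed
components (slope and residual gradients at small $N$, $t_z$) shrink
a few hundredths toward zero under the regularizing priors — visible as
a small positive mean bias in scaled-down runs, well inside the
validation tolerance and vanishing with longer chains and larger $N$.
Spline reaction norms, additional distributional parameters, multi-trait
and multi-fitness-component models, and fluctuating selection terms are
out of scope.
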
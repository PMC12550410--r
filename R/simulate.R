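## ---- random-number helpers ------------------------------------------------

## deterministic 32-bit seed derivation (global seed + stream offset)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 69621) %%
               2147483647)
}

## multivariate normal draws via Cholesky (n x d)
rmvn <- function(n, Sigma) {
  d <- ncol(Sigma)
  L <- chol(Sigma)
  matrix(stats::rnorm(n * d), n, d) %*% L
}

#' Draw random 3x3 correlation matrices from the LKJ distribution
#'
#' Uses the C-vine construction: the partial correlations of the vine are
#' independent shifted-Beta variates, which for dimension 3 means the two
#' first-tree correlations have Beta(eta + 1/2, eta + 1/2) on (-1, 1) and
#' the second-tree partial correlation has Beta(eta, eta).  The implied
#' joint density over the correlation matrix is proportional to
#' `det(R)^(eta - 1)` and the result is always positive definite.
#'
#' @param n Number of matrices.
#' @param eta Concentration parameter (> 0); larger values concentrate the
#'   correlations near zero.
#' @return If `n == 1`, a 3x3 correlation matrix; otherwise a list of them.
#' @examples
#' set.seed(1)
#' rlkj_corr(1, eta = 5)
#' @export
rlkj_corr <- function(n = 1, eta = 1) {
  stopifnot(n >= 1, eta > 0)
  one <- function() {
    a1 <- eta + 0.5
    r12 <- 2 * stats::rbeta(1, a1, a1) - 1
    r13 <- 2 * stats::rbeta(1, a1, a1) - 1
    p23 <- 2 * stats::rbeta(1, eta, eta) - 1
    r23 <- p23 * sqrt((1 - r12^2) * (1 - r13^2)) + r12 * r13
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- r12
    R[1, 3] <- R[3, 1] <- r13
    R[2, 3] <- R[3, 2] <- r23
    R
  }
  if (n == 1) one() else replicate(n, one(), simplify = FALSE)
}

## ---- simulation configuration --------------------------------------------

#' Configuration of one simulated study
#'
#' Fixes the sampling design (subjects and repeats), the target
#' variance-standardized selection gradients, and the population parameters
#' used to generate a dataset.  Defaults follow the validation-study regime:
#' unit among-individual SDs, LKJ(5) correlations, residual phenotypic
#' variance 2 (`sigma0 = log 2`), unexplained-selection SD 1 and fitness
#' residual SD 1.
#'
#' @param N Number of subjects (>= 2).
#' @param t_z Phenotype repeats per subject (>= 1).
#' @param t_w Fitness repeats per subject (>= 1).
#' @param target_beta Length-3 vector of standardized directional gradients.
#' @param target_gamma Length-6 vector of standardized quadratic gradients:
#'   three diagonal (stabilizing/disruptive) then three correlational
#'   components, order (1,2), (1,3), (2,3).
#' @param sds Among-individual SDs of the reaction-norm deviations.
#' @param lkj_eta LKJ concentration for the among-individual correlations.
#' @param mu0,beta_x Population mean intercept and slope.
#' @param sigma0 Population residual parameter (log-variance scale).
#' @param sd_W0 SD of the individual fitness random effect.
#' @param delta Fitness residual SD.
#' @param seed Integer seed controlling all draws for this dataset.
#' @return An object of class `"sim_config"`.
#' @examples
#' sim_config(N = 100, t_z = 3, t_w = 1, seed = 1)
#' @export
sim_config <- function(N = 200, t_z = 5, t_w = 2,
                       target_beta = c(0.3, 0.3, 0.3),
                       target_gamma = rep(0.3, 6),
                       sds = c(1, 1, 1), lkj_eta = 5,
                       mu0 = 0, beta_x = 0, sigma0 = log(2),
                       sd_W0 = 1, delta = 1, seed = 1L) {
  stopifnot(N >= 2, t_z >= 1, t_w >= 1,
            length(target_beta) == 3, length(target_gamma) == 6,
            length(sds) == 3, all(sds > 0), lkj_eta > 0,
            sd_W0 >= 0, delta > 0)
  structure(list(N = as.integer(N), t_z = as.integer(t_z),
                 t_w = as.integer(t_w),
                 target_beta = as.numeric(target_beta),
                 target_gamma = as.numeric(target_gamma),
                 sds = as.numeric(sds), lkj_eta = lkj_eta,
                 mu0 = mu0, beta_x = beta_x, sigma0 = sigma0,
                 sd_W0 = sd_W0, delta = delta, seed = as.integer(seed)),
            class = "sim_config")
}

## ---- generative draws -----------------------------------------------------

#' Draw the generative truth of one simulated dataset
#'
#' Draws the among-individual correlation matrix from LKJ(`lkj_eta`),
#' assembles `P`, and sets the fitness-model coefficients so that the
#' analytic variance-standardized gradients equal the configured targets.
#' Mean fitness is normalized to 1 by setting `W0 = 1 - trace(Q P)`, so for
#' Gaussian fitness with identity link the raw coefficient-to-gradient map
#' inverts exactly: `b_k = beta*_k / sd_k`, `Q_kl = gamma*_kl / (2 sd_k
#' sd_l)`.  Individual deviations are drawn MVN(0, P) and the fitness random
#' effects N(0, sd_W0).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `"sim_truth"`: `pop` ([population_rn()]),
#'   `coefs` ([selection_coefs()]), `deviations` (N x 3), `w0` (length N),
#'   `true_beta` (standardized, length 3), `true_gamma` (standardized,
#'   symmetric 3x3), `mean_abs_corr`, and the originating `config`.
#' @examples
#' tr <- draw_truth(sim_config(N = 50, seed = 1))
#' tr$true_beta
#' @export
draw_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  corr <- rlkj_corr(1, config$lkj_eta)
  sds <- config$sds
  P <- assemble_P(sds, corr)

  ## invert the gradient map at mean fitness 1
  b <- config$target_beta / sds
  tg <- config$target_gamma             # gamma matrix: diag and off-diagonal
  Gamma <- diag(tg[1:3])                # entries are the targets themselves
  Gamma[1, 2] <- Gamma[2, 1] <- tg[4]
  Gamma[1, 3] <- Gamma[3, 1] <- tg[5]
  Gamma[2, 3] <- Gamma[3, 2] <- tg[6]
  Q <- Gamma / 2 / outer(sds, sds)
  W0 <- 1 - sum(diag(Q %*% P))
  coefs <- selection_coefs(b = b, q = q_from_Q(Q), W0 = W0,
                           sd_W0 = config$sd_W0, delta = config$delta)

  deviations <- rmvn(config$N, P)
  colnames(deviations) <- c("mu0j", "beta_xj", "sigma0j")
  w0 <- stats::rnorm(config$N, 0, config$sd_W0)

  grad <- standardize_gradients(analytic_gradients_gaussian(coefs, P), P)
  structure(list(pop = population_rn(config$mu0, config$beta_x,
                                     config$sigma0, sds, corr),
                 coefs = coefs, P = P,
                 deviations = deviations, w0 = w0,
                 true_beta = grad$beta, true_gamma = grad$gamma,
                 mean_abs_corr = mean(abs(corr[upper.tri(corr)])),
                 config = config),
            class = "sim_truth")
}

#' Simulate a phenotype/fitness dataset from a generative truth
#'
#' Environmental states are i.i.d. standard normal across observations
#' (randomized exposure); phenotypes are Gaussian around each individual's
#' reaction norm with individual-specific SD; fitness measures are Gaussian
#' around the quadratic fitness predictor (identity link).
#'
#' @param truth A [sim_truth][draw_truth()] object.
#' @param config Optional [sim_config()]; defaults to `truth$config`.
#' @return An object of class `"rn_data"`: list with data frames
#'   `phenotype` (`individual_id`, `rep`, `x`, `z`) and `fitness`
#'   (`individual_id`, `rep`, `W`).
#' @examples
#' tr <- draw_truth(sim_config(N = 50, t_z = 3, t_w = 1, seed = 1))
#' d <- simulate_dataset(tr)
#' nrow(d$phenotype)  # 150
#' @export
simulate_dataset <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  N <- config$N; t_z <- config$t_z; t_w <- config$t_w
  u <- truth$deviations
  pop <- truth$pop

  id_z <- rep(seq_len(N), each = t_z)
  x <- stats::rnorm(N * t_z)
  mu <- pop$mu0 + u[id_z, 1] + (pop$beta_x + u[id_z, 2]) * x
  sd_j <- dispersion_sd(pop$sigma0 + u[id_z, 3])
  z <- stats::rnorm(N * t_z, mu, sd_j)

  theta <- truth$coefs$W0 + truth$w0 +
    as.numeric(u %*% truth$coefs$b) +
    rowSums((u %*% truth$coefs$Q) * u)
  id_w <- rep(seq_len(N), each = t_w)
  W <- stats::rnorm(N * t_w, theta[id_w], config$delta)

  rn_data(phenotype = data.frame(individual_id = id_z,
                                 rep = rep(seq_len(t_z), N),
                                 x = x, z = z),
          fitness = data.frame(individual_id = id_w,
                               rep = rep(seq_len(t_w), N),
                               W = W))
}

#' Sample study conditions for a validation run
#'
#' Draws `n_datasets` independent study conditions: subjects
#' `N ~ U{100..1000}`, phenotype repeats `t_z ~ U{3..7}`, fitness repeats
#' `t_w ~ U{1..5}` (all integer-uniform, inclusive), and all nine
#' standardized gradient targets `~ U(0.1, 0.5)`.  Remaining parameters are
#' fixed to the defaults of [sim_config()].
#'
#' @param n_datasets Number of conditions (>= 1).
#' @param seed Integer seed.
#' @param N_range,t_z_range,t_w_range Inclusive integer ranges.
#' @param effect_range Range of the uniform gradient targets.
#' @param ... Further arguments passed to [sim_config()] (e.g. fixed `N`).
#' @return List of [sim_config()] objects with per-dataset derived seeds.
#' @examples
#' conds <- sample_validation_conditions(3, seed = 7)
#' sapply(conds, `[[`, "N")
#' @export
sample_validation_conditions <- function(n_datasets, seed = 1L,
                                         N_range = c(100L, 1000L),
                                         t_z_range = c(3L, 7L),
                                         t_w_range = c(1L, 5L),
                                         effect_range = c(0.1, 0.5),
                                         ...) {
  stopifnot(n_datasets >= 1)
  set.seed(derive_seed(seed, 3L))
  ## integer-uniform on [lo, hi]; avoids sample()'s scalar expansion
  runifint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  lapply(seq_len(n_datasets), function(i) {
    sim_config(N = runifint(N_range[1], N_range[2]),
               t_z = runifint(t_z_range[1], t_z_range[2]),
               t_w = runifint(t_w_range[1], t_w_range[2]),
               target_beta = stats::runif(3, effect_range[1], effect_range[2]),
               target_gamma = stats::runif(6, effect_range[1], effect_range[2]),
               seed = derive_seed(seed, 100L + i),
               ...)
  })
}
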
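#' Population-level reaction-norm parameters
#'
#' Describes the population distribution of individual reaction norms: the
#' average intercept, environmental slope and residual (log-variance)
#' parameter, together with the among-individual covariance structure of
#' individual deviations from those averages.
#'
#' @param mu0 Population mean intercept (link scale).
#' @param beta_x Population mean environmental slope (link scale).
#' @param sigma0 Population mean residual parameter (log-variance scale);
#'   `sigma0 = log(2)` corresponds to a within-individual SD of
#'   `sqrt(2) = 1.41`.
#' @param sds Length-3 vector of positive SDs of the individual deviations
#'   (intercept, slope, residual).
#' @param corr 3x3 correlation matrix of the deviations.
#' @return An object of class `"population_rn"`.
#' @examples
#' population_rn(0, 0, log(2), sds = c(1, 1, 1), corr = diag(3))
#' @export
population_rn <- function(mu0 = 0, beta_x = 0, sigma0 = log(2),
                          sds = c(1, 1, 1), corr = diag(3)) {
  stopifnot(length(mu0) == 1, length(beta_x) == 1, length(sigma0) == 1,
            is.finite(mu0), is.finite(beta_x), is.finite(sigma0))
  if (length(sds) != 3 || any(!is.finite(sds)) || any(sds <= 0))
    stop("'sds' must be 3 positive finite values", call. = FALSE)
  corr <- validate_corr(corr)
  structure(list(mu0 = mu0, beta_x = beta_x, sigma0 = sigma0,
                 sds = as.numeric(sds), corr = corr),
            class = "population_rn")
}

validate_corr <- function(corr) {
  corr <- as.matrix(corr)
  if (!all(dim(corr) == c(3, 3)))
    stop("'corr' must be a 3x3 matrix", call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("'corr' must be symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("'corr' must have unit diagonal", call. = FALSE)
  ev <- eigen((corr + t(corr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("'corr' must be positive semi-definite", call. = FALSE)
  (corr + t(corr)) / 2
}

#' Assemble the among-individual covariance matrix P
#'
#' `P = diag(sds) %*% corr %*% diag(sds)`.
#'
#' @param sds Length-3 vector of positive SDs.
#' @param corr 3x3 correlation matrix.
#' @return 3x3 covariance matrix.
#' @export
assemble_P <- function(sds, corr) {
  corr <- validate_corr(corr)
  diag(sds) %*% corr %*% diag(sds)
}

#' Selection coefficients of the quadratic fitness model
#'
#' The fitness linear predictor for individual j is
#' `W0 + w0j + b' u_j + u_j' Q u_j`, where `u_j` holds the individual's
#' reaction-norm deviations (intercept, slope, residual) and `Q` is the
#' symmetric matrix built from the six quadratic coefficients by [make_Q()].
#'
#' @param b Length-3 vector of directional coefficients.
#' @param q Length-6 vector of quadratic coefficients: three squared terms
#'   (intercept, slope, residual) then three cross terms
#'   (intercept:slope, intercept:residual, slope:residual).
#' @param W0 Intercept of the fitness model (link scale).
#' @param sd_W0 SD of the individual fitness random effect (>= 0).
#' @param delta Residual dispersion of fitness (> 0; an SD for Gaussian
#'   fitness).
#' @return An object of class `"selection_coefs"` with elements `b`, `q`,
#'   `Q` (the symmetric matrix), `W0`, `sd_W0`, `delta`.
#' @examples
#' selection_coefs(b = c(0.3, 0.1, 0.2), q = rep(0, 6), W0 = 1)
#' @export
selection_coefs <- function(b = c(0, 0, 0), q = rep(0, 6), W0 = 1,
                            sd_W0 = 0, delta = 1) {
  if (length(b) != 3 || any(!is.finite(b)))
    stop("'b' must be 3 finite values", call. = FALSE)
  if (length(sd_W0) != 1 || !is.finite(sd_W0) || sd_W0 < 0)
    stop("'sd_W0' must be a nonnegative number", call. = FALSE)
  if (length(delta) != 1 || !is.finite(delta) || delta <= 0)
    stop("'delta' must be a positive number", call. = FALSE)
  Q <- make_Q(q)
  structure(list(b = as.numeric(b), q = as.numeric(q), Q = Q,
                 W0 = as.numeric(W0), sd_W0 = as.numeric(sd_W0),
                 delta = as.numeric(delta)),
            class = "selection_coefs")
}

#' Build the symmetric quadratic-form matrix from six coefficients
#'
#' Given the six quadratic selection coefficients, returns the symmetric
#' 3x3 matrix `Q` such that `u' Q u` reproduces the fitness polynomial
#' `q1*u1^2 + q2*u2^2 + q3*u3^2 + q4*u1*u2 + q5*u1*u3 + q6*u2*u3`.
#' Cross coefficients are halved on the off-diagonals because each appears
#' twice in the quadratic form; this is the usual pitfall when relating
#' regression coefficients to quadratic selection matrices.
#'
#' @param q Length-6 numeric: `(q1, q2, q3, q4, q5, q6)`.
#' @return Symmetric 3x3 matrix.
#' @examples
#' make_Q(c(1, 1, 1, 0, 0, 0))   # identity
#' make_Q(c(0, 0, 0, 0.4, 0, 0)) # 0.2 on the (1,2) off-diagonal
#' @export
make_Q <- function(q) {
  if (length(q) != 6 || any(!is.finite(q)))
    stop("'q' must be 6 finite values", call. = FALSE)
  Q <- diag(q[1:3])
  Q[1, 2] <- Q[2, 1] <- q[4] / 2
  Q[1, 3] <- Q[3, 1] <- q[5] / 2
  Q[2, 3] <- Q[3, 2] <- q[6] / 2
  Q
}

## inverse of make_Q
q_from_Q <- function(Q) {
  c(diag(Q), 2 * Q[1, 2], 2 * Q[1, 3], 2 * Q[2, 3])
}

#' Predicted phenotype mean and SD for one individual and environment
#'
#' Evaluates the reaction norm of an individual at environmental state `x`:
#' the mean linear predictor is `mu0 + u[1] + (beta_x + u[2]) * x`, passed
#' through the inverse mean link, and the within-individual SD is
#' `sqrt(exp(sigma0 + u[3]))`.
#'
#' @param pop A [population_rn()] object.
#' @param u Length-3 vector of individual deviations
#'   (intercept, slope, residual), link scale.
#' @param x Environmental covariate value(s).
#' @param links An [rn_links()] object.
#' @return List with `mean` (same length as `x`) and `sd` (scalar).
#' @examples
#' pop <- population_rn(1, 0.5, log(2))
#' phenotype_predict(pop, u = c(0.2, -0.1, 0), x = 2)
#' @export
phenotype_predict <- function(pop, u, x, links = rn_links()) {
  stopifnot(inherits(pop, "population_rn"))
  if (length(u) != 3 || any(!is.finite(u)))
    stop("'u' must be 3 finite values", call. = FALSE)
  if (any(!is.finite(x)))
    stop("'x' must be finite", call. = FALSE)
  eta <- pop$mu0 + u[1] + (pop$beta_x + u[2]) * x
  list(mean = inv_link_fun(links$mean)(eta),
       sd = dispersion_sd(pop$sigma0 + u[3]))
}

#' Fitness linear predictor for one individual
#'
#' Evaluates `W0 + w0j + b' u + u' Q u` on the fitness link scale.
#'
#' @param coefs A [selection_coefs()] object.
#' @param u Length-3 vector of individual reaction-norm deviations.
#' @param w0j Individual fitness random effect (default 0).
#' @return Scalar linear predictor (link scale).
#' @examples
#' cf <- selection_coefs(b = c(1, 0, 0), q = c(0, 0, 0, 0.5, 0, 0), W0 = 0)
#' fitness_predict(cf, u = c(1, 1, 0))  # 1.5
#' @export
fitness_predict <- function(coefs, u, w0j = 0) {
  stopifnot(inherits(coefs, "selection_coefs"))
  if (length(u) != 3 || any(!is.finite(u)))
    stop("'u' must be 3 finite values", call. = FALSE)
  if (!is.finite(w0j))
    stop("'w0j' must be finite", call. = FALSE)
  as.numeric(coefs$W0 + w0j + sum(coefs$b * u) + t(u) %*% coefs$Q %*% u)
}

#' Latent-scale repeatability of reaction-norm parameters
#'
#' Fraction of the total latent phenotypic variance attributable to each
#' reaction-norm parameter: `R_k = var_k / (var_mu0 + var_beta + var_sigma0
#' + resid_var)`.  With the three among-individual variances at 1 and a
#' residual variance of 2 each parameter has modest repeatability
#' `R = 0.2`.
#'
#' @param var_mu0,var_beta,var_sigma0 Among-individual variances (>= 0) of
#'   intercepts, slopes and residual parameters.
#' @param resid_var Residual (within-individual) phenotypic variance (>= 0).
#' @return Length-3 vector of repeatabilities in `[0, 1]`.
#' @examples
#' latent_repeatability(1, 1, 1, 2)  # 0.2 0.2 0.2
#' @export
latent_repeatability <- function(var_mu0, var_beta, var_sigma0, resid_var) {
  v <- c(var_mu0, var_beta, var_sigma0, resid_var)
  if (length(v) != 4 || any(!is.finite(v)) || any(v < 0))
    stop("variances must be nonnegative finite numbers", call. = FALSE)
  denom <- sum(v)
  if (denom <= 0)
    stop("total variance must be positive", call. = FALSE)
  v[1:3] / denom
}
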
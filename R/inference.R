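#' Prior specification for the joint model
#'
#' Regularizing defaults: zero-centered normal priors of unit scale on the
#' fixed effects and the selection coefficients, half-normal unit-scale
#' priors on all SD parameters, and an LKJ(2) prior on the among-individual
#' correlation matrix (use `lkj_eta = 5` to match the validation-study
#' generative regime).  These place low probability on extreme effect
#' sizes without being informative about direction.
#'
#' @param scale_fixed Prior SD for `mu0`, `beta_x`, `sigma0`, `W0`.
#' @param scale_coefs Prior SD for the selection coefficients `b`, `q`.
#' @param scale_sd Scale of the half-normal priors on SD parameters.
#' @param lkj_eta LKJ concentration for the correlation prior.
#' @return An object of class `"rn_priors"`.
#' @export
rn_priors <- function(scale_fixed = 1, scale_coefs = 1, scale_sd = 1,
                      lkj_eta = 2) {
  stopifnot(scale_fixed > 0, scale_coefs > 0, scale_sd > 0, lkj_eta > 0)
  structure(list(scale_fixed = scale_fixed, scale_coefs = scale_coefs,
                 scale_sd = scale_sd, lkj_eta = lkj_eta),
            class = "rn_priors")
}

#' MCMC sampler settings
#'
#' @param chains Number of chains (>= 2 so convergence can be diagnosed).
#' @param warmup Adaptation/burn-in iterations per chain.
#' @param iter Retained sampling iterations per chain.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain seeds are derived deterministically.
#' @return An object of class `"rn_sampler"`.
#' @export
rn_sampler <- function(chains = 4, warmup = 1000, iter = 1000, thin = 1,
                       seed = 1L) {
  stopifnot(chains >= 2, warmup >= 1, iter >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "rn_sampler")
}

## JAGS model code for the joint phenotype + fitness model.
##
## The among-individual correlation matrix gets an exact LKJ prior through
## its C-vine partial correlations (independent shifted-Beta variates), and
## the latent deviations are non-centered: standard-normal innovations
## scaled by the Cholesky factor of P.  The individual fitness random
## effect w0 is included only when repeated fitness measures make its SD
## identifiable.
build_jags_model <- function(priors, include_w0) {
  prec_fixed <- 1 / priors$scale_fixed^2
  prec_coefs <- 1 / priors$scale_coefs^2
  prec_sd <- 1 / priors$scale_sd^2
  a1 <- priors$lkj_eta + 0.5
  a2 <- priors$lkj_eta
  w0_prior <- if (include_w0)
    sprintf("  sd_W0 ~ dnorm(0, %g) T(0,)", prec_sd) else ""
  w0_j <- if (include_w0)
    "w0[j] ~ dnorm(0, pow(sd_W0, -2))" else "w0[j] <- 0"
  sprintf("
model {
  mu0 ~ dnorm(0, %1$g)
  beta_x ~ dnorm(0, %1$g)
  sigma0 ~ dnorm(0, %1$g)
  W0 ~ dnorm(0, %1$g)
  for (k in 1:3) { b[k] ~ dnorm(0, %2$g) }
  for (k in 1:6) { q[k] ~ dnorm(0, %2$g) }
  for (k in 1:3) { sds[k] ~ dnorm(0, %3$g) T(0,) }
  delta ~ dnorm(0, %3$g) T(0,)
%4$s
  # LKJ(eta) over the correlation matrix via C-vine partial correlations
  pb12 ~ dbeta(%5$g, %5$g); r12 <- 2 * pb12 - 1
  pb13 ~ dbeta(%5$g, %5$g); r13 <- 2 * pb13 - 1
  pb23 ~ dbeta(%6$g, %6$g); p23 <- 2 * pb23 - 1
  r23 <- p23 * sqrt((1 - r12^2) * (1 - r13^2)) + r12 * r13
  L21 <- r12
  L22 <- sqrt(1 - r12^2)
  L31 <- r13
  L32 <- (r23 - r12 * r13) / L22
  L33 <- sqrt(max(1 - L31^2 - L32^2, 1e-12))
  for (j in 1:N) {
    for (k in 1:3) { zr[j, k] ~ dnorm(0, 1) }
    u[j, 1] <- sds[1] * zr[j, 1]
    u[j, 2] <- sds[2] * (L21 * zr[j, 1] + L22 * zr[j, 2])
    u[j, 3] <- sds[3] * (L31 * zr[j, 1] + L32 * zr[j, 2] + L33 * zr[j, 3])
    %7$s
    theta[j] <- W0 + w0[j] + b[1] * u[j, 1] + b[2] * u[j, 2] + b[3] * u[j, 3]
              + q[1] * u[j, 1]^2 + q[2] * u[j, 2]^2 + q[3] * u[j, 3]^2
              + q[4] * u[j, 1] * u[j, 2] + q[5] * u[j, 1] * u[j, 3]
              + q[6] * u[j, 2] * u[j, 3]
  }
  for (i in 1:nz) {
    muz[i] <- mu0 + u[idz[i], 1] + (beta_x + u[idz[i], 2]) * x[i]
    z[i] ~ dnorm(muz[i], exp(-(sigma0 + u[idz[i], 3])))
  }
  tauw <- pow(delta, -2)
  for (i in 1:nw) { W[i] ~ dnorm(theta[idw[i]], tauw) }
}
", prec_fixed, prec_coefs, prec_sd, w0_prior, a1, a2, w0_j)
}

#' Fit the joint reaction-norm and selection model
#'
#' Jointly estimates, by MCMC, the double-hierarchical phenotype model
#' (individual intercepts, environmental slopes and residual log-variances,
#' MVN-distributed with covariance `P`) and the quadratic fitness model on
#' the same latent individual deviations.  Estimating the deviations
#' jointly with their fitness effects is what makes the selection inference
#' an errors-in-variables analysis: plugging in point estimates of
#' reaction-norm parameters leads to anticonservative inference.
#'
#' Gaussian phenotype (identity mean link, log-variance dispersion link)
#' and Gaussian fitness (identity link) are supported.  When every
#' individual has exactly one fitness measure, the individual fitness
#' random effect `w0j` is dropped: its SD cannot be separated from the
#' fitness residual dispersion.
#'
#' @param data An [rn_data()] object (or a list with `phenotype` and
#'   `fitness` data frames).
#' @param priors An [rn_priors()] object.
#' @param control An [rn_sampler()] object.
#' @param include_w0 Logical; default (`NULL`) includes the individual
#'   fitness random effect exactly when some individual has more than one
#'   fitness row.  Forcing `TRUE` with single fitness measures is an
#'   identifiability error.
#' @param monitor_deviations If `TRUE`, posterior draws of all latent
#'   individual deviations are retained (3 N extra parameters).
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `"rn_selection"`: posterior draws (a
#'   [coda::mcmc.list]), the model code, data summaries and settings.
#'   Methods: `print`, `summary`, `coef`, `as.matrix`.
#' @seealso [posterior_selection_gradients()], [check_convergence()]
#' @export
rn_selection <- function(data, priors = rn_priors(), control = rn_sampler(),
                         include_w0 = NULL, monitor_deviations = FALSE,
                         quiet = TRUE) {
  if (!inherits(data, "rn_data")) data <- rn_data(data$phenotype, data$fitness)
  stopifnot(inherits(priors, "rn_priors"), inherits(control, "rn_sampler"))

  ids <- sort(unique(data$phenotype$individual_id))
  idx <- match(data$phenotype$individual_id, ids)
  idw <- match(data$fitness$individual_id, ids)
  n_w_per <- table(idw)
  repeated_w <- any(n_w_per > 1)
  if (is.null(include_w0)) include_w0 <- repeated_w
  if (include_w0 && !repeated_w)
    stop(paste("individual fitness random effect requested but every",
               "individual has a single fitness measure: sd_W0 cannot be",
               "identified separately from the fitness residual dispersion;",
               "set include_w0 = FALSE"), call. = FALSE)

  model_code <- build_jags_model(priors, include_w0)
  jdata <- list(N = length(ids), nz = nrow(data$phenotype),
                nw = nrow(data$fitness),
                idz = idx, idw = idw,
                x = data$phenotype$x, z = data$phenotype$z,
                W = data$fitness$W)
  inits <- lapply(seq_len(control$chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(control$seed, 1000L + ch)))
  monitors <- c("mu0", "beta_x", "sigma0", "sds", "r12", "r13", "r23",
                "b", "q", "W0", "delta",
                if (include_w0) "sd_W0",
                if (monitor_deviations) "u")

  n_adapt <- ceiling(control$warmup / 2)
  model <- tryCatch(
    withCallingHandlers(
      rjags::jags.model(textConnection(model_code), data = jdata,
                        inits = inits, n.chains = control$chains,
                        n.adapt = n_adapt, quiet = quiet),
      warning = function(w) {
        ## short exploratory fits routinely leave sampler tuning unfinished
        if (grepl("Adaptation incomplete", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }),
    error = function(e)
      stop("MCMC initialization failed (seed ", control$seed, "): ",
           conditionMessage(e), call. = FALSE))
  if (control$warmup > n_adapt)
    stats::update(model, control$warmup - n_adapt)
  draws <- tryCatch(
    rjags::coda.samples(model, monitors,
                        n.iter = control$iter * control$thin,
                        thin = control$thin,
                        progress.bar = if (quiet) "none" else "text"),
    error = function(e)
      stop("MCMC sampling failed (seed ", control$seed, "): ",
           conditionMessage(e), call. = FALSE))

  structure(list(draws = draws, model_code = model_code,
                 include_w0 = include_w0, priors = priors,
                 control = control,
                 individuals = ids,
                 n_phenotype = nrow(data$phenotype),
                 n_fitness = nrow(data$fitness)),
            class = "rn_selection")
}

#' @export
as.matrix.rn_selection <- function(x, ...) {
  as.matrix(x$draws)
}

#' @export
print.rn_selection <- function(x, ...) {
  cat("Joint reaction-norm selection model (MCMC)\n")
  cat(sprintf("  %d individuals; %d phenotype rows; %d fitness rows\n",
              length(x$individuals), x$n_phenotype, x$n_fitness))
  cat(sprintf("  %d chains x %d iterations (warmup %d); w0 random effect: %s\n",
              x$control$chains, x$control$iter, x$control$warmup,
              if (x$include_w0) "included" else "omitted"))
  invisible(x)
}

#' @param object An `rn_selection` fit.
#' @param prob Credible-interval mass.
#' @param ... Unused.
#' @rdname rn_selection
#' @export
summary.rn_selection <- function(object, prob = 0.9, ...) {
  m <- as.matrix(object)
  keep <- !startsWith(colnames(m), "u[")
  m <- m[, keep, drop = FALSE]
  a <- (1 - prob) / 2
  diag <- check_convergence(object)
  out <- data.frame(parameter = colnames(m),
                    median = apply(m, 2, stats::median),
                    lower = apply(m, 2, stats::quantile, probs = a),
                    upper = apply(m, 2, stats::quantile, probs = 1 - a),
                    row.names = NULL)
  merge(out, diag, by = "parameter", sort = FALSE)
}

#' @export
coef.rn_selection <- function(object, ...) {
  m <- as.matrix(object)
  keep <- !startsWith(colnames(m), "u[")
  apply(m[, keep, drop = FALSE], 2, stats::median)
}
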
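## Selection gradients on reaction-norm parameters.
##
## A gradient here is the population average of the first (directional) or
## second (quadratic) derivative of relative expected fitness
## E[W | u] / Wbar with respect to the latent reaction-norm deviations u,
## taken over the population distribution u ~ MVN(0, P).  For Gaussian
## fitness with identity link this has a closed form; for other links a
## Monte-Carlo finite-difference evaluator is provided.

new_gradient_estimate <- function(beta, gamma, mean_fitness) {
  names(beta) <- rn_par_names()
  dimnames(gamma) <- list(rn_par_names(), rn_par_names())
  structure(list(beta = beta, gamma = (gamma + t(gamma)) / 2,
                 mean_fitness = mean_fitness),
            class = "gradient_estimate")
}

rn_par_names <- function() c("mu0", "beta_x", "sigma0")

#' @export
print.gradient_estimate <- function(x, digits = 3, ...) {
  cat("Selection gradients (mean fitness ",
      format(x$mean_fitness, digits = digits), ")\n", sep = "")
  cat("directional:\n"); print(round(x$beta, digits))
  cat("quadratic:\n"); print(round(x$gamma, digits))
  invisible(x)
}

#' Closed-form selection gradients for identity-link Gaussian fitness
#'
#' For expected fitness `E[W|u] = W0 + b'u + u'Qu` and `u ~ MVN(0, P)`,
#' mean fitness is `Wbar = W0 + trace(QP)`, the directional gradient is
#' `beta = b / Wbar` and the quadratic gradient is `gamma = 2Q / Wbar`.
#'
#' @param coefs A [selection_coefs()] object.
#' @param P 3x3 among-individual covariance matrix.
#' @return A `gradient_estimate`: list with `beta` (length 3), `gamma`
#'   (symmetric 3x3) and `mean_fitness`.
#' @examples
#' cf <- selection_coefs(b = c(0.3, 0.1, 0.2), W0 = 1)
#' analytic_gradients_gaussian(cf, diag(3))
#' @export
analytic_gradients_gaussian <- function(coefs, P) {
  stopifnot(inherits(coefs, "selection_coefs"))
  P <- as.matrix(P)
  wbar <- coefs$W0 + sum(diag(coefs$Q %*% P))
  if (!is.finite(wbar) || wbar <= 0)
    stop("mean fitness is not positive; relative fitness undefined",
         call. = FALSE)
  new_gradient_estimate(coefs$b / wbar, 2 * coefs$Q / wbar, wbar)
}

## expected fitness on the observed scale as a function of u (n x 3 matrix)
expected_fitness_fun <- function(coefs, links) {
  theta <- function(U)
    coefs$W0 + as.numeric(U %*% coefs$b) + rowSums((U %*% coefs$Q) * U)
  switch(links$fitness,
         identity = theta,
         log = function(U)
           exp(theta(U) + 0.5 * coefs$sd_W0^2 + 0.5 * coefs$delta^2),
         stop("unsupported fitness link: ", links$fitness, call. = FALSE))
}

#' Monte-Carlo average selection gradients by finite differences
#'
#' Draws `n_mc` deviations from MVN(0, P), computes expected fitness on the
#' observed scale at perturbed deviations, and averages central
#' finite-difference first and second derivatives of relative expected
#' fitness.  For identity-link Gaussian fitness this converges to
#' [analytic_gradients_gaussian()] as `n_mc` grows.
#'
#' @param coefs A [selection_coefs()] object.
#' @param P 3x3 among-individual covariance matrix.
#' @param links An [rn_links()] object (fitness link used).
#' @param n_mc Number of Monte-Carlo deviations (>= 1000).
#' @param h Finite-difference step (> 0).
#' @param seed Integer seed; the same seed reproduces the same estimate.
#' @param u Optional pre-drawn n x 3 deviation matrix (overrides `n_mc` and
#'   `seed`); used internally for common random numbers across posterior
#'   draws.
#' @return A `gradient_estimate` (see [analytic_gradients_gaussian()]).
#' @examples
#' cf <- selection_coefs(b = c(0.3, 0.1, 0.2), W0 = 1)
#' mc_average_gradients(cf, diag(3), n_mc = 10000, seed = 1)
#' @export
mc_average_gradients <- function(coefs, P, links = rn_links(),
                                 n_mc = 20000, h = 1e-3, seed = 1L,
                                 u = NULL) {
  stopifnot(inherits(coefs, "selection_coefs"), h > 0)
  P <- as.matrix(P)
  if (is.null(u)) {
    if (n_mc < 1000) stop("'n_mc' must be at least 1000", call. = FALSE)
    set.seed(seed)
    u <- rmvn(n_mc, P)
  }
  f <- expected_fitness_fun(coefs, links)
  shift <- function(k, s) {
    U <- u; U[, k] <- U[, k] + s * h; U
  }
  f0 <- f(u)
  wbar <- mean(f0)
  if (!is.finite(wbar) || wbar <= 0)
    stop("mean fitness is not positive; relative fitness undefined",
         call. = FALSE)
  beta <- numeric(3)
  gamma <- matrix(0, 3, 3)
  fp <- fm <- vector("list", 3)
  for (k in 1:3) {
    fp[[k]] <- f(shift(k, 1))
    fm[[k]] <- f(shift(k, -1))
    d1 <- (fp[[k]] - fm[[k]]) / (2 * h)
    d2 <- (fp[[k]] - 2 * f0 + fm[[k]]) / h^2
    if (any(!is.finite(d1)) || any(!is.finite(d2)))
      stop("non-finite derivative at Monte-Carlo draw ",
           which(!is.finite(d1 + d2))[1], call. = FALSE)
    beta[k] <- mean(d1)
    gamma[k, k] <- mean(d2)
  }
  for (k in 1:2) for (l in (k + 1):3) {
    Upp <- u; Upp[, k] <- Upp[, k] + h; Upp[, l] <- Upp[, l] + h
    Upm <- u; Upm[, k] <- Upm[, k] + h; Upm[, l] <- Upm[, l] - h
    Ump <- u; Ump[, k] <- Ump[, k] - h; Ump[, l] <- Ump[, l] + h
    Umm <- u; Umm[, k] <- Umm[, k] - h; Umm[, l] <- Umm[, l] - h
    d2 <- (f(Upp) - f(Upm) - f(Ump) + f(Umm)) / (4 * h^2)
    if (any(!is.finite(d2)))
      stop("non-finite derivative at Monte-Carlo draw ",
           which(!is.finite(d2))[1], call. = FALSE)
    gamma[k, l] <- gamma[l, k] <- mean(d2)
  }
  new_gradient_estimate(beta / wbar, gamma / wbar, wbar)
}

#' Variance-standardize selection gradients
#'
#' Multiplies directional gradients by the trait SDs and quadratic
#' gradients by the SD products: `beta*_k = beta_k sd_k`,
#' `gamma*_kl = gamma_kl sd_k sd_l` with `sd_k = sqrt(P_kk)`.  With unit
#' SDs the gradients are unchanged.
#'
#' @param est A `gradient_estimate`.
#' @param P 3x3 among-individual covariance matrix.
#' @return A `gradient_estimate` on the standardized scale.
#' @export
standardize_gradients <- function(est, P) {
  stopifnot(inherits(est, "gradient_estimate"))
  sds <- sqrt(diag(as.matrix(P)))
  new_gradient_estimate(est$beta * sds, est$gamma * outer(sds, sds),
                        est$mean_fitness)
}

gradient_component_names <- function() {
  p <- rn_par_names()
  c(paste0("beta_", p),
    paste0("gamma_", p),
    paste0("gamma_", c("mu0.beta_x", "mu0.sigma0", "beta_x.sigma0")))
}

## flatten a gradient_estimate into the 9 named components
## (3 directional, 3 diagonal quadratic, 3 correlational)
flatten_gradients <- function(est) {
  g <- est$gamma
  stats::setNames(c(est$beta, diag(g), g[1, 2], g[1, 3], g[2, 3]),
                  gradient_component_names())
}

#' Posterior draws of selection gradients
#'
#' Transforms each posterior draw of the fitness-model coefficients and the
#' among-individual covariance into directional and quadratic selection
#' gradients, raw and variance-standardized.  With identity-link Gaussian
#' fitness the exact closed form is used (`method = "analytic"`); the
#' Monte-Carlo finite-difference route (`method = "mc"`) is available for
#' any link and uses common random numbers across draws.
#'
#' @param fit An [rn_selection()] fit.
#' @param links An [rn_links()] object.
#' @param method `"analytic"` (identity-link closed form) or `"mc"`.
#' @param n_mc,h,seed Monte-Carlo settings for `method = "mc"`; `n_mc`
#'   deviations are shared across draws.
#' @param on_invalid What to do with a draw whose implied mean fitness is
#'   not positive (relative fitness undefined there): `"error"` (default)
#'   fails naming the draw; `"drop"` excludes such draws and records their
#'   count in the `n_dropped` attribute.
#' @return An object of class `"gradient_draws"`: matrices `raw` and
#'   `standardized` (draws x 9 named gradient components),
#'   `mean_fitness` (per draw), and `components`.
#' @export
posterior_selection_gradients <- function(fit, links = rn_links(),
                                          method = c("analytic", "mc"),
                                          n_mc = 2000, h = 1e-3,
                                          seed = 1L,
                                          on_invalid = c("error", "drop")) {
  method <- match.arg(method)
  on_invalid <- match.arg(on_invalid)
  stopifnot(inherits(fit, "rn_selection"))
  if (method == "analytic" && links$fitness != "identity")
    stop("analytic gradients require the identity fitness link; use method = \"mc\"",
         call. = FALSE)
  m <- as.matrix(fit)
  ndraw <- nrow(m)
  Z <- NULL
  if (method == "mc") {
    set.seed(seed)
    Z <- matrix(stats::rnorm(n_mc * 3), n_mc, 3)
  }
  raw <- std <- matrix(NA_real_, ndraw, 9,
                       dimnames = list(NULL, gradient_component_names()))
  wbar <- rep(NA_real_, ndraw)
  for (i in seq_len(ndraw)) {
    coefs_i <- selection_coefs(b = m[i, paste0("b[", 1:3, "]")],
                               q = m[i, paste0("q[", 1:6, "]")],
                               W0 = m[i, "W0"],
                               sd_W0 = if ("sd_W0" %in% colnames(m))
                                 m[i, "sd_W0"] else 0,
                               delta = m[i, "delta"])
    sds_i <- m[i, paste0("sds[", 1:3, "]")]
    corr_i <- diag(3)
    corr_i[1, 2] <- corr_i[2, 1] <- m[i, "r12"]
    corr_i[1, 3] <- corr_i[3, 1] <- m[i, "r13"]
    corr_i[2, 3] <- corr_i[3, 2] <- m[i, "r23"]
    P_i <- assemble_P(sds_i, corr_i)
    est <- tryCatch(
      if (method == "analytic") analytic_gradients_gaussian(coefs_i, P_i)
      else mc_average_gradients(coefs_i, P_i, links, h = h,
                                u = Z %*% chol(P_i)),
      error = function(e) {
        if (on_invalid == "drop") return(NULL)
        stop("gradient transformation failed at draw ", i, ": ",
             conditionMessage(e), call. = FALSE)
      })
    if (is.null(est)) next
    raw[i, ] <- flatten_gradients(est)
    std[i, ] <- flatten_gradients(standardize_gradients(est, P_i))
    wbar[i] <- est$mean_fitness
  }
  keep <- !is.na(wbar)
  structure(list(raw = raw[keep, , drop = FALSE],
                 standardized = std[keep, , drop = FALSE],
                 mean_fitness = wbar[keep],
                 components = gradient_component_names()),
            class = "gradient_draws")
}

#' @export
print.gradient_draws <- function(x, ...) {
  cat("Posterior selection-gradient draws:", nrow(x$standardized),
      "draws x", ncol(x$standardized), "components\n")
  print(summary(x))
  invisible(x)
}

#' Plot posterior selection gradients
#'
#' Posterior medians and credible intervals for the nine gradient
#' components, with a reference line at zero.
#'
#' @param x A `gradient_draws` object.
#' @param scale,prob Passed to [summary.gradient_draws()].
#' @param ... Further arguments to [graphics::plot()].
#' @return The summary data frame, invisibly.
#' @export
plot.gradient_draws <- function(x, scale = "standardized", prob = 0.9,
                                ...) {
  s <- summary(x, scale = scale, prob = prob)
  n <- nrow(s)
  old <- graphics::par(mar = c(4, 10, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(s$median, n:1, xlim = range(s$lower, s$upper, 0),
                 ylim = c(0.5, n + 0.5), yaxt = "n", pch = 16,
                 xlab = paste(scale, "selection gradient"), ylab = "", ...)
  graphics::segments(s$lower, n:1, s$upper, n:1)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  graphics::axis(2, at = n:1, labels = s$component, las = 1, cex.axis = 0.8)
  invisible(s)
}

#' Summarize posterior gradient draws
#'
#' @param object A `gradient_draws` object.
#' @param scale `"standardized"` (default) or `"raw"`.
#' @param prob Credible-interval mass (default 0.9).
#' @param ... Unused.
#' @return Data frame with one row per gradient component: posterior
#'   `median`, interval bounds, and `p_pos`, the posterior probability that
#'   the gradient is positive.
#' @export
summary.gradient_draws <- function(object, scale = c("standardized", "raw"),
                                   prob = 0.9, ...) {
  scale <- match.arg(scale)
  m <- object[[scale]]
  a <- (1 - prob) / 2
  data.frame(component = colnames(m),
             median = apply(m, 2, stats::median),
             lower = apply(m, 2, stats::quantile, probs = a),
             upper = apply(m, 2, stats::quantile, probs = 1 - a),
             p_pos = colMeans(m > 0),
             row.names = NULL)
}
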
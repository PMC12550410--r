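#' Split R-hat for one parameter
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain trends are detected as well as between-chain
#' disagreement.  Values near 1 indicate the chains are mixing over the
#' same distribution.
#'
#' @param x Matrix of draws, iterations x chains (or a vector for a single
#'   chain, which is split in two).
#' @return Scalar split R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 iterations", call. = FALSE)
  half <- floor(n / 2)
  splits <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics for a fitted model
#'
#' Split R-hat and effective sample size for every population-level
#' parameter, with a flag when any R-hat exceeds 1.01.  Effective sample
#' sizes use the spectral estimator from \pkg{coda}.
#'
#' @param fit An [rn_selection()] fit or a [coda::mcmc.list].
#' @param rhat_threshold Flag threshold (default 1.01).
#' @return Data frame (`parameter`, `rhat`, `ess`) with attributes
#'   `flagged` (parameter names exceeding the threshold) and `ok`.
#' @export
check_convergence <- function(fit, rhat_threshold = 1.01) {
  draws <- if (inherits(fit, "rn_selection")) fit$draws else fit
  if (!inherits(draws, "mcmc.list")) {
    if (is.list(draws) && length(draws) && all(sapply(draws, is.matrix)))
      draws <- coda::mcmc.list(lapply(draws, coda::mcmc))
    else stop("'fit' must be an rn_selection fit or an mcmc.list",
              call. = FALSE)
  }
  if (length(draws) < 1 || nrow(draws[[1]]) == 0)
    stop("empty draws", call. = FALSE)
  pars <- colnames(draws[[1]])
  pars <- pars[!startsWith(pars, "u[")]
  rhat <- vapply(pars, function(p)
    split_rhat(sapply(draws, function(ch) as.numeric(ch[, p]))),
    numeric(1))
  ess <- vapply(pars, function(p)
    as.numeric(coda::effectiveSize(
      coda::mcmc.list(lapply(draws, function(ch) coda::mcmc(ch[, p]))))),
    numeric(1))
  out <- data.frame(parameter = pars, rhat = rhat, ess = ess,
                    row.names = NULL)
  flagged <- pars[rhat > rhat_threshold]
  attr(out, "flagged") <- flagged
  attr(out, "ok") <- length(flagged) == 0
  out
}
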
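#' Link specification for the reaction-norm selection model
#'
#' Bundles the link functions used by the phenotype and fitness submodels.
#' The mean of the phenotype and the expectation of fitness are modelled on
#' a link scale chosen here; the within-individual dispersion is always
#' modelled as a log-variance, so that a linear predictor \eqn{\eta} maps to
#' a standard deviation \eqn{\sqrt{\exp(\eta)}}.  Fixing the dispersion link
#' avoids the classic log-SD versus log-variance scale confusion.
#'
#' @param mean One of `"identity"`, `"log"`, `"logit"` for the phenotype
#'   mean.
#' @param fitness One of `"identity"`, `"log"` for expected fitness.
#' @return An object of class `"rn_links"`: a list with elements `mean`,
#'   `fitness` and `dispersion` (always `"logvar"`).
#' @examples
#' rn_links()
#' rn_links(mean = "log", fitness = "log")
#' @export
rn_links <- function(mean = c("identity", "log", "logit"),
                     fitness = c("identity", "log")) {
  mean <- match.arg(mean)
  fitness <- match.arg(fitness)
  structure(list(mean = mean, fitness = fitness, dispersion = "logvar"),
            class = "rn_links")
}

## apply a named link / inverse link to a numeric vector
link_fun <- function(name) {
  switch(name,
         identity = identity,
         log = log,
         logit = function(p) log(p / (1 - p)),
         stop("unknown link: ", name, call. = FALSE))
}

inv_link_fun <- function(name) {
  switch(name,
         identity = identity,
         log = exp,
         logit = function(eta) 1 / (1 + exp(-eta)),
         stop("unknown link: ", name, call. = FALSE))
}

#' Inverse dispersion link: linear predictor to standard deviation
#'
#' Maps the log-variance linear predictor of the phenotype model to the
#' within-individual standard deviation, `sqrt(exp(eta))`.  The output is
#' strictly positive for any finite input.
#'
#' @param eta Numeric vector on the log-variance scale.
#' @return Standard deviations, same length as `eta`.
#' @examples
#' dispersion_sd(log(2))  # 1.41
#' @export
dispersion_sd <- function(eta) {
  if (!is.numeric(eta) || any(!is.finite(eta)))
    stop("'eta' must be finite numeric", call. = FALSE)
  sqrt(exp(eta))
}
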
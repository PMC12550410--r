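#' Score posterior gradient draws against the generative truth
#'
#' For each of the nine gradient components (three directional, three
#' stabilizing/disruptive, three correlational) computes, on the
#' variance-standardized scale:
#' bias (true value minus posterior median), RMSD (root mean squared
#' deviation of the posterior draws from the true value), and `p_pos`
#' (posterior probability the gradient is positive).
#'
#' @param gdraws A [gradient_draws][posterior_selection_gradients()]
#'   object.
#' @param truth A [sim_truth][draw_truth()] object.
#' @return Data frame with one row per gradient component: `gradient_name`,
#'   `true_value`, `bias`, `rmsd`, `p_pos`, plus the study conditions
#'   (`N`, `t_z`, `t_w`, `mean_abs_corr`).
#' @examples
#' \donttest{
#' tr <- draw_truth(sim_config(N = 60, t_z = 3, t_w = 1, seed = 1))
#' fit <- rn_selection(simulate_dataset(tr),
#'                     control = rn_sampler(2, 200, 200, seed = 1))
#' score_gradients(posterior_selection_gradients(fit), tr)
#' }
#' @export
score_gradients <- function(gdraws, truth) {
  stopifnot(inherits(gdraws, "gradient_draws"), inherits(truth, "sim_truth"))
  true_est <- new_gradient_estimate(truth$true_beta, truth$true_gamma, 1)
  tv <- flatten_gradients(true_est)
  m <- gdraws$standardized
  if (!nrow(m)) stop("no gradient draws", call. = FALSE)
  if (!all(colnames(m) %in% names(tv)))
    stop("missing truth component", call. = FALSE)
  cfg <- truth$config
  data.frame(gradient_name = colnames(m),
             true_value = as.numeric(tv[colnames(m)]),
             bias = as.numeric(tv[colnames(m)] -
                               apply(m, 2, stats::median)),
             rmsd = sqrt(colMeans((matrix(tv[colnames(m)], nrow(m), 9,
                                          byrow = TRUE) - m)^2)),
             p_pos = colMeans(m > 0),
             N = cfg$N, t_z = cfg$t_z, t_w = cfg$t_w,
             mean_abs_corr = truth$mean_abs_corr,
             row.names = NULL)
}

#' Run a simulation-based validation study
#'
#' For each study condition: draw a generative truth, simulate a dataset,
#' fit the joint model, transform the posterior to standardized selection
#' gradients, and score bias, RMSD and `p_pos` against the truth.
#' Per-dataset failures (sampler errors) are recorded and excluded rather
#' than aborting the study.
#'
#' @param n_datasets Number of datasets (ignored when `conditions` given).
#' @param seed Integer seed for condition sampling.
#' @param control An [rn_sampler()] object used for every fit.
#' @param conditions Optional list of [sim_config()] objects; default
#'   conditions are drawn by [sample_validation_conditions()].
#' @param priors An [rn_priors()] object.
#' @param gradient_method Passed to [posterior_selection_gradients()].
#' @param progress Print one line per dataset.
#' @return Data frame of scored gradients (9 rows per successful dataset,
#'   with a `dataset_id` column), with attribute `failures` (named list of
#'   error messages for failed datasets).
#' @export
run_validation_study <- function(n_datasets, seed = 1L,
                                 control = rn_sampler(chains = 2,
                                                      warmup = 500,
                                                      iter = 500),
                                 conditions = NULL,
                                 priors = rn_priors(lkj_eta = 5),
                                 gradient_method = "analytic",
                                 progress = FALSE) {
  if (is.null(conditions))
    conditions <- sample_validation_conditions(n_datasets, seed)
  out <- vector("list", length(conditions))
  failures <- list()
  for (i in seq_along(conditions)) {
    cfg <- conditions[[i]]
    res <- tryCatch({
      truth <- draw_truth(cfg)
      dat <- simulate_dataset(truth, cfg)
      ctrl <- control
      ctrl$seed <- derive_seed(cfg$seed, 7L)
      fit <- rn_selection(dat, priors = priors, control = ctrl)
      gd <- posterior_selection_gradients(fit, method = gradient_method,
                                          seed = derive_seed(cfg$seed, 8L),
                                          on_invalid = "drop")
      cbind(dataset_id = i, score_gradients(gd, truth))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
    } else {
      out[[i]] <- res
    }
    if (progress)
      cat(sprintf("dataset %d/%d %s\n", i, length(conditions),
                  if (inherits(res, "error")) "FAILED" else "ok"))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  attr(res, "failures") <- failures
  res
}

#' Second-order polynomial trend across study conditions
#'
#' Ordinary least-squares fit of a metric on a condition covariate and its
#' square, the summary used to describe how bias, RMSD and `p_pos` change
#' across simulated conditions.
#'
#' @param metrics Data frame of scored gradients (or any data frame).
#' @param predictor,response Column names.
#' @return Named numeric vector `(intercept, linear, quadratic)`.
#' @examples
#' d <- data.frame(x = 1:10, y = 1 + 2 * (1:10) + 3 * (1:10)^2)
#' polynomial_trend_summary(d, "x", "y")
#' @export
polynomial_trend_summary <- function(metrics, predictor, response) {
  x <- metrics[[predictor]]
  y <- metrics[[response]]
  if (is.null(x) || is.null(y))
    stop("unknown column(s): ", predictor, " / ", response, call. = FALSE)
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct predictor values", call. = FALSE)
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  if (any(is.na(cf))) stop("rank-deficient polynomial fit", call. = FALSE)
  stats::setNames(as.numeric(cf), c("intercept", "linear", "quadratic"))
}
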
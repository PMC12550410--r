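## Shared fixtures: one small simulated dataset and a short fitted model,
## built once per test run and reused across test files.

fixture_env <- new.env(parent = emptyenv())

small_truth <- function() {
  if (is.null(fixture_env$truth))
    fixture_env$truth <- draw_truth(
      sim_config(N = 60, t_z = 3, t_w = 2,
                 target_beta = c(0.2, 0.3, 0.4),
                 target_gamma = c(0.3, 0.2, 0.1, 0.2, 0.3, 0.2),
                 seed = 11L))
  fixture_env$truth
}

small_data <- function() {
  if (is.null(fixture_env$data))
    fixture_env$data <- simulate_dataset(small_truth())
  fixture_env$data
}

small_fit <- function() {
  if (is.null(fixture_env$fit))
    fixture_env$fit <- rn_selection(
      small_data(),
      control = rn_sampler(chains = 2, warmup = 200, iter = 200, seed = 7L))
  fixture_env$fit
}

## a fit-shaped object holding exactly one posterior draw with known values,
## for checking the posterior gradient transformation against closed forms
single_draw_fit <- function(b = c(0.3, 0.1, 0.2), q = rep(0, 6), W0 = 1,
                            sds = c(1, 1, 1), r = c(0, 0, 0),
                            sd_W0 = 1, delta = 1) {
  m <- matrix(c(b, q, W0, sds, r, sd_W0, delta, 0, 0, log(2)), nrow = 1)
  colnames(m) <- c(paste0("b[", 1:3, "]"), paste0("q[", 1:6, "]"), "W0",
                   paste0("sds[", 1:3, "]"), "r12", "r13", "r23",
                   "sd_W0", "delta", "mu0", "beta_x", "sigma0")
  m <- m[c(1, 1), , drop = FALSE]  # two identical draws
  structure(list(draws = coda::mcmc.list(coda::mcmc(m)),
                 include_w0 = TRUE, individuals = integer(0),
                 n_phenotype = 0L, n_fitness = 0L,
                 control = rn_sampler(chains = 2, warmup = 1, iter = 2)),
            class = "rn_selection")
}

## uniform gradient targets on the validation-study range, seeded
runif_targets <- function(k, seed) {
  set.seed(seed)
  runif(k, 0.1, 0.5)
}
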
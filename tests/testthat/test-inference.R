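test_that("the joint fit is seeded, structured, and shares the latent field", {
  fit <- small_fit()
  m <- as.matrix(fit)
  expect_equal(nrow(m), 400)  # 2 chains x 200 iterations
  need <- c("mu0", "beta_x", "sigma0", paste0("sds[", 1:3, "]"),
            "r12", "r13", "r23", paste0("b[", 1:3, "]"),
            paste0("q[", 1:6, "]"), "W0", "delta", "sd_W0")
  expect_true(all(need %in% colnames(m)))
  expect_true(all(m[, paste0("sds[", 1:3, "]")] > 0))
  expect_true(all(m[, "delta"] > 0))
  expect_true(all(abs(m[, c("r12", "r13", "r23")]) < 1))

  ## same data, same seed, same settings: bit-identical draws
  refit <- rn_selection(small_data(),
                        control = rn_sampler(chains = 2, warmup = 200,
                                             iter = 200, seed = 7L))
  expect_identical(as.matrix(refit), m)

  ## coef/summary methods expose population-level parameters
  cf <- coef(fit)
  expect_true(all(need %in% names(cf)))
  s <- summary(fit)
  expect_true(all(c("median", "lower", "upper", "rhat", "ess") %in% names(s)))
})

test_that("latent deviations can be monitored and are per-individual", {
  fit <- rn_selection(small_data(),
                      control = rn_sampler(chains = 2, warmup = 100,
                                           iter = 50, seed = 3L),
                      monitor_deviations = TRUE)
  m <- as.matrix(fit)
  expect_true(all(paste0("u[", 1:60, ",1]") %in% colnames(m)))
  ## coef drops the latent field
  expect_false(any(startsWith(names(coef(fit)), "u[")))
})

test_that("the individual fitness effect obeys the identifiability rule", {
  tr <- draw_truth(sim_config(N = 40, t_z = 3, t_w = 1, seed = 21))
  d <- simulate_dataset(tr)
  fit <- rn_selection(d, control = rn_sampler(chains = 2, warmup = 100,
                                              iter = 50, seed = 1L))
  expect_false(fit$include_w0)
  expect_false("sd_W0" %in% colnames(as.matrix(fit)))
  expect_error(rn_selection(d, include_w0 = TRUE), "identified separately")
  ## repeated fitness measures include it by default
  expect_true(small_fit()$include_w0)
})

test_that("posterior medians recover generative selection coefficients", {
  ## stronger design than the shared fixture: directional selection only
  cfg <- sim_config(N = 250, t_z = 5, t_w = 2,
                    target_beta = c(0.5, 0.5, 0.5),
                    target_gamma = rep(0, 6), seed = 41)
  tr <- draw_truth(cfg)
  d <- simulate_dataset(tr)
  fit <- rn_selection(d, priors = rn_priors(lkj_eta = 5),
                      control = rn_sampler(chains = 2, warmup = 400,
                                           iter = 400, seed = 2L))
  s <- summary(fit)
  b_rows <- match(paste0("b[", 1:3, "]"), s$parameter)
  ## each 90% interval covers the true coefficient and the medians are
  ## closer to 0.5 than to 0
  expect_true(all(s$lower[b_rows] < 0.5 & s$upper[b_rows] > 0.15))
  expect_true(all(s$median[b_rows] > 0.25))
})

test_that("split R-hat flags shifted chains and passes stationary ones", {
  set.seed(8)
  chains <- cbind(rnorm(1000), rnorm(1000))
  r <- split_rhat(chains)
  expect_gt(r, 0.99)
  expect_lt(r, 1.01)

  shifted <- cbind(rnorm(1000), rnorm(1000) + 10)
  expect_gt(split_rhat(shifted), 1.1)

  ## a within-chain trend is caught by the split
  trended <- cbind(seq(0, 5, length.out = 1000) + rnorm(1000),
                   seq(0, 5, length.out = 1000) + rnorm(1000))
  expect_gt(split_rhat(trended), 1.1)
})

test_that("convergence checking reports and flags per parameter", {
  set.seed(9)
  good <- list(cbind(a = rnorm(500), b = rnorm(500)),
               cbind(a = rnorm(500), b = rnorm(500)))
  diag <- check_convergence(good)
  expect_equal(diag$parameter, c("a", "b"))
  expect_true(attr(diag, "ok"))

  bad <- list(cbind(a = rnorm(500), b = rnorm(500)),
              cbind(a = rnorm(500) + 10, b = rnorm(500)))
  diag2 <- check_convergence(bad)
  expect_false(attr(diag2, "ok"))
  expect_true("a" %in% attr(diag2, "flagged"))
  expect_false("b" %in% attr(diag2, "flagged"))

  expect_error(check_convergence(list()), "rn_selection|empty")
  expect_error(check_convergence(coda::mcmc.list(coda::mcmc(
    matrix(numeric(0), 0, 1)))), "empty")
})
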
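test_that("LKJ correlation draws match the known marginal distribution", {
  ## for 3x3 LKJ(eta) every pairwise correlation is marginally
  ## 2*Beta(eta + 1/2, eta + 1/2) - 1
  eta <- 5
  set.seed(20)
  rs <- replicate(4000, {
    R <- rlkj_corr(1, eta)
    R[upper.tri(R)]
  })
  frac_big <- mean(abs(rs) > 0.5)
  oracle <- 2 * stats::pbeta(0.25, eta + 0.5, eta + 0.5)  # P(|r| > 0.5)
  expect_lt(frac_big, 0.1)
  expect_lt(abs(frac_big - oracle), 0.02)
  ## mean near zero, matrices valid
  expect_lt(abs(mean(rs)), 0.02)
  R <- rlkj_corr(1, eta)
  expect_equal(diag(R), rep(1, 3))
  expect_true(min(eigen(R, symmetric = TRUE)$values) > 0)
})

test_that("drawing the truth is seeded and hits the configured targets", {
  cfg <- sim_config(N = 100, seed = 5)
  t1 <- draw_truth(cfg)
  t2 <- draw_truth(cfg)
  expect_identical(t1$deviations, t2$deviations)
  expect_identical(t1$pop$corr, t2$pop$corr)

  expect_equal(diag(t1$P), c(1, 1, 1))
  ## truth gradients are the analytic standardized gradients of the coefs
  expect_equal(unname(t1$true_beta), cfg$target_beta)
  expect_equal(unname(diag(t1$true_gamma)), cfg$target_gamma[1:3])
  expect_equal(unname(t1$true_gamma[upper.tri(t1$true_gamma)]),
               cfg$target_gamma[c(4, 5, 6)][c(1, 2, 3)])
  ## mean fitness normalized to 1
  expect_equal(analytic_gradients_gaussian(t1$coefs, t1$P)$mean_fitness, 1)
})

test_that("non-unit SDs still reproduce the standardized targets", {
  cfg <- sim_config(N = 50, sds = c(2, 0.5, 1),
                    target_beta = c(0.1, 0.2, 0.3),
                    target_gamma = c(0.4, 0.3, 0.2, 0.1, 0.2, 0.3),
                    seed = 9)
  tr <- draw_truth(cfg)
  expect_equal(unname(tr$true_beta), cfg$target_beta, tolerance = 1e-10)
  expect_equal(unname(diag(tr$true_gamma)), cfg$target_gamma[1:3],
               tolerance = 1e-10)
})

test_that("simulated tables have the configured shape", {
  cfg <- sim_config(N = 100, t_z = 3, t_w = 1, seed = 2)
  d <- simulate_dataset(draw_truth(cfg))
  expect_equal(nrow(d$phenotype), 300)
  expect_equal(nrow(d$fitness), 100)
  expect_equal(as.numeric(table(d$fitness$individual_id)), rep(1, 100))
  expect_true(all(is.finite(d$phenotype$z)))
  expect_identical(simulate_dataset(draw_truth(cfg)), d)
})

test_that("large-sample moments match the generative parameters", {
  cfg <- sim_config(N = 5000, t_z = 2, t_w = 1, seed = 31)
  tr <- draw_truth(cfg)
  ## deviations variance: law of large numbers, within 5% of 1
  v <- apply(tr$deviations, 2, var)
  expect_lt(max(abs(v - 1)), 0.05)
  ## empirical covariance matches P within 3 Monte-Carlo standard errors
  emp <- cov(tr$deviations)
  se <- sqrt((1 + tr$P^2) / cfg$N)  # SE of a covariance entry under MVN
  expect_true(all(abs(emp - tr$P) <= 3 * se))

  ## phenotype residual SD: individual SD is sqrt(exp(sigma0 + u3)), so
  ## with tiny residual-parameter variance the pooled residual SD is
  ## sqrt(exp(sigma0)); with unit variance it is inflated by exp(var/2)
  cfg0 <- sim_config(N = 5000, t_z = 2, t_w = 1, sds = c(1, 1, 1e-6),
                     seed = 32)
  tr0 <- draw_truth(cfg0)
  d0 <- simulate_dataset(tr0)
  id <- d0$phenotype$individual_id
  mu <- tr0$pop$mu0 + tr0$deviations[id, 1] +
    (tr0$pop$beta_x + tr0$deviations[id, 2]) * d0$phenotype$x
  expect_lt(abs(sd(d0$phenotype$z - mu) / sqrt(exp(cfg0$sigma0)) - 1), 0.02)

  d1 <- simulate_dataset(tr)
  id <- d1$phenotype$individual_id
  mu <- tr$pop$mu0 + tr$deviations[id, 1] +
    (tr$pop$beta_x + tr$deviations[id, 2]) * d1$phenotype$x
  expect_lt(abs(sd(d1$phenotype$z - mu) /
                  sqrt(exp(cfg$sigma0 + 0.5)) - 1), 0.03)
})

test_that("validation conditions sample the documented ranges", {
  conds <- sample_validation_conditions(500, seed = 7)
  expect_length(conds, 500)
  Ns <- sapply(conds, `[[`, "N")
  tzs <- sapply(conds, `[[`, "t_z")
  tws <- sapply(conds, `[[`, "t_w")
  expect_true(all(Ns >= 100 & Ns <= 1000))
  expect_true(all(tzs %in% 3:7))
  expect_true(all(tws %in% 1:5))
  effs <- unlist(lapply(conds, function(cf) c(cf$target_beta,
                                              cf$target_gamma)))
  expect_true(all(effs >= 0.1 & effs <= 0.5))
  expect_identical(sample_validation_conditions(5, seed = 3),
                   sample_validation_conditions(5, seed = 3))

  ## degenerate ranges pin the condition exactly
  fixed <- sample_validation_conditions(4, seed = 2,
                                        N_range = c(200L, 200L),
                                        t_z_range = c(5L, 5L),
                                        t_w_range = c(2L, 2L))
  expect_true(all(sapply(fixed, `[[`, "N") == 200L))
  expect_true(all(sapply(fixed, `[[`, "t_z") == 5L))
  expect_true(all(sapply(fixed, `[[`, "t_w") == 2L))
})
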
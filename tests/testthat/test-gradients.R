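test_that("analytic gradients match hand-derived closed forms", {
  ## flat fitness surface
  est <- analytic_gradients_gaussian(selection_coefs(W0 = 1), diag(3))
  expect_equal(unname(est$beta), c(0, 0, 0))
  expect_equal(unname(est$gamma), matrix(0, 3, 3))
  expect_equal(est$mean_fitness, 1)

  ## pure directional: E[grad(b'u + u'Qu)] = b
  est <- analytic_gradients_gaussian(
    selection_coefs(b = c(0.3, 0.1, 0.2), W0 = 1), diag(3))
  expect_equal(unname(est$beta), c(0.3, 0.1, 0.2))
  expect_equal(unname(est$gamma), matrix(0, 3, 3))

  ## quadratic lifts mean fitness through trace(QP)
  est <- analytic_gradients_gaussian(
    selection_coefs(q = c(0.2, 0, 0, 0, 0, 0), W0 = 1), diag(3))
  expect_equal(est$mean_fitness, 1.2)
  expect_equal(est$gamma[1, 1], 2 * 0.2 / 1.2)
  expect_equal(est$gamma[1, 1], 1 / 3, tolerance = 1e-12)

  expect_error(analytic_gradients_gaussian(
    selection_coefs(W0 = -2), diag(3)), "positive")
})

test_that("Monte-Carlo gradients agree with the analytic oracle", {
  cases <- list(
    list(b = c(0.3, 0.1, 0.2), q = rep(0, 6), W0 = 1),
    list(b = rep(0, 3), q = c(0.2, 0, 0, 0, 0, 0), W0 = 1),
    list(b = c(0.2, -0.3, 0.1), q = c(0.1, -0.2, 0.3, 0.15, -0.1, 0.2),
         W0 = 1.5))
  P <- matrix(c(1, 0.3, -0.2, 0.3, 1, 0.1, -0.2, 0.1, 1), 3, 3)
  for (cs in cases) {
    cf <- selection_coefs(b = cs$b, q = cs$q, W0 = cs$W0)
    a <- analytic_gradients_gaussian(cf, P)
    m <- mc_average_gradients(cf, P, n_mc = 1e5, seed = 42)
    expect_lt(max(abs(m$beta - a$beta)), 0.01)
    expect_lt(max(abs(m$gamma - a$gamma)), 0.01)
    expect_lt(abs(m$mean_fitness - a$mean_fitness), 0.01)
  }
})

test_that("Monte-Carlo gradients are exact for a flat surface and seeded", {
  cf <- selection_coefs(W0 = 1)
  est <- mc_average_gradients(cf, diag(3), n_mc = 1000, seed = 1)
  expect_equal(unname(est$beta), c(0, 0, 0))
  expect_equal(unname(est$gamma), matrix(0, 3, 3))

  cf <- selection_coefs(b = c(0.2, 0.1, 0), q = c(0.1, 0, 0, 0.2, 0, 0),
                        W0 = 1)
  e1 <- mc_average_gradients(cf, diag(3), n_mc = 2000, seed = 9)
  e2 <- mc_average_gradients(cf, diag(3), n_mc = 2000, seed = 9)
  expect_identical(e1, e2)
  expect_error(mc_average_gradients(cf, diag(3), n_mc = 10), "1000")
})

test_that("halving the step changes smooth-link gradients only at second order", {
  cf <- selection_coefs(b = c(0.2, -0.1, 0.3),
                        q = c(0.1, 0.2, -0.1, 0.1, 0, 0.2),
                        W0 = 1, sd_W0 = 0.5, delta = 0.3)
  links <- rn_links(fitness = "log")
  e1 <- mc_average_gradients(cf, diag(3), links, n_mc = 5000, h = 2e-3,
                             seed = 4)
  e2 <- mc_average_gradients(cf, diag(3), links, n_mc = 5000, h = 1e-3,
                             seed = 4)
  expect_lt(max(abs(e1$beta - e2$beta)), 1e-4)
  expect_lt(max(abs(e1$gamma - e2$gamma)), 1e-3)
  ## returned gamma is exactly symmetric
  expect_identical(e1$gamma, t(e1$gamma))
})

test_that("variance standardization scales by trait SDs", {
  est <- analytic_gradients_gaussian(
    selection_coefs(b = c(0.3, 0, 0), W0 = 1), diag(3))
  expect_equal(standardize_gradients(est, diag(3)), est)

  P <- diag(c(4, 1, 1))  # sds (2,1,1)
  s <- standardize_gradients(est, P)
  expect_equal(unname(s$beta[1]), 0.6)

  est2 <- analytic_gradients_gaussian(
    selection_coefs(q = c(0, 0, 0, 0.1, 0, 0), W0 = 1), diag(3))
  ## gamma12 = 0.1 (= q4); standardization by sds (2,3,1)
  P2 <- diag(c(4, 9, 1))
  s2 <- standardize_gradients(est2, P2)
  expect_equal(s2$gamma[1, 2], est2$gamma[1, 2] * 6)
  expect_identical(s2$gamma, t(s2$gamma))
})

test_that("posterior gradient draws reproduce the closed form draw by draw", {
  fit <- single_draw_fit(b = c(0.3, 0.1, 0.2), q = rep(0, 6), W0 = 1)
  gd <- posterior_selection_gradients(fit)
  expect_equal(nrow(gd$standardized), 2)  # draw count in = draw count out
  expect_equal(unname(gd$raw[1, 1:3]), c(0.3, 0.1, 0.2))
  expect_equal(unname(gd$raw[1, 4:9]), rep(0, 6))
  ## unit SDs: standardized equals raw
  expect_equal(gd$standardized, gd$raw)

  ## mc route agrees with analytic route on the same single draw
  gm <- posterior_selection_gradients(fit, method = "mc", n_mc = 50000,
                                      seed = 2)
  expect_lt(max(abs(gm$standardized - gd$standardized)), 0.01)

  ## all-positive draws give p_pos 1 downstream
  s <- summary(gd)
  expect_equal(s$p_pos[1:3], rep(1, 3))
})

test_that("non-unit posterior SDs separate raw and standardized scales", {
  fit <- single_draw_fit(b = c(0.4, 0, 0), sds = c(2, 1, 1))
  gd <- posterior_selection_gradients(fit)
  expect_equal(unname(gd$raw[1, "beta_mu0"]), 0.4)
  expect_equal(unname(gd$standardized[1, "beta_mu0"]), 0.8)
})
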
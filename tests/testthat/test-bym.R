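zero_state <- function(n, k = 0, tau_u = 1, tau_v = 1) {
  list(alpha = 0, u = rep(0, n), v = rep(0, n), beta = rep(0, k),
       tau_u = tau_u, tau_v = tau_v)
}

test_that("log posterior matches hand evaluation and symbolic re-derivation", {
  adj <- adjacency(c("a", "b"), list(2L, 1L))
  md <- model_data(c(1, 1), c(1, 1), adj)
  cfg <- bym_config(n_iter = 100, fix_tau = list(tau_u = 1, tau_v = 1))
  # all effects zero, O = E = 1: Poisson term sums to -2, all priors vanish
  expect_equal(log_posterior(zero_state(2), md, cfg), -2)

  # independent re-derivation on a 3-unit path (constants cancel in
  # differences between states)
  adj3 <- path3_adjacency()
  md3 <- model_data(c(4, 0, 7), c(2, 3, 5), adj3)
  cfg3 <- bym_config(n_iter = 100, hyper_shape = 0.5, hyper_rate = 0.0005,
                     alpha_prior_sd = 10, beta_prior_sd = 10)
  oracle <- function(s) {
    eta <- s$alpha + s$u + s$v
    sum(dpois(md3$observed, md3$expected * exp(eta), log = TRUE)) +
      sum(lfactorial(md3$observed)) +
      sum(dnorm(s$u, 0, 1 / sqrt(s$tau_u), log = TRUE)) +
      (3 / 2) * log(2 * pi) +
      (2 / 2) * log(s$tau_v) -
      s$tau_v / 2 * ((s$v[1] - s$v[2])^2 + (s$v[2] - s$v[3])^2) +
      dgamma(s$tau_u, 0.5, rate = 0.0005, log = TRUE) -
      (0.5 * log(0.0005) - lgamma(0.5)) +
      dgamma(s$tau_v, 0.5, rate = 0.0005, log = TRUE) -
      (0.5 * log(0.0005) - lgamma(0.5)) +
      dnorm(s$alpha, 0, 10, log = TRUE) + log(10) + 0.5 * log(2 * pi)
  }
  set.seed(9)
  for (i in 1:5) {
    s1 <- list(alpha = rnorm(1), u = rnorm(3, 0, 0.5),
               v = rnorm(3, 0, 0.5), beta = numeric(0),
               tau_u = rgamma(1, 3, 1), tau_v = rgamma(1, 3, 1))
    s2 <- list(alpha = rnorm(1), u = rnorm(3, 0, 0.5),
               v = rnorm(3, 0, 0.5), beta = numeric(0),
               tau_u = rgamma(1, 3, 1), tau_v = rgamma(1, 3, 1))
    expect_equal(log_posterior(s1, md3, cfg3) - log_posterior(s2, md3, cfg3),
                 oracle(s1) - oracle(s2), tolerance = 1e-10)
  }
})

test_that("shifting level between alpha and u leaves the likelihood unchanged", {
  adj3 <- path3_adjacency()
  md3 <- model_data(c(4, 0, 7), c(2, 3, 5), adj3)
  cfg <- bym_config(n_iter = 100, alpha_prior_sd = 2, beta_prior_sd = 2,
                    fix_tau = list(tau_u = 3, tau_v = 1))
  s <- zero_state(3, tau_u = 3, tau_v = 1)
  s$alpha <- 0.4; s$u <- c(0.1, -0.2, 0.3)
  cc <- 0.25
  s2 <- s; s2$alpha <- s$alpha + cc; s2$u <- s$u - cc
  # difference is purely the prior terms
  prior_diff <- (-(s2$alpha^2 - s$alpha^2) / (2 * 4)) -
    3 / 2 * (sum(s2$u^2) - sum(s$u^2))
  expect_equal(log_posterior(s2, md3, cfg) - log_posterior(s, md3, cfg),
               prior_diff, tolerance = 1e-12)
})

test_that("CAR full conditional averages neighbors", {
  adj3 <- path3_adjacency()
  fc <- car_full_conditional(c(1, 0, 3), adj3, 2, tau_v = 1)
  expect_equal(fc$mean, 2)
  expect_equal(fc$variance, 0.5)
  fc1 <- car_full_conditional(c(0.5, 0, 0), adj3, 1, tau_v = 2)
  expect_equal(fc1$mean, 0)
  expect_equal(fc1$variance, 0.5)
  a22 <- build_lattice_adjacency(2, 2)
  fc0 <- car_full_conditional(c(1, 2, 3, 4), a22, 1, tau_v = 1)
  expect_equal(fc0$mean, 2.5)
  expect_equal(fc0$variance, 1 / 2)
  iso <- adjacency(c("a", "b", "c"),
                   list(2L, 1L, integer(0)))
  expect_error(car_full_conditional(c(0, 0, 0), iso, 3, 1), "no neighbors")
})

test_that("precision Gibbs draws match their conjugate gamma laws", {
  adj <- build_lattice_adjacency(2, 2)
  md <- model_data(c(1, 1, 1, 1), c(1, 1, 1, 1), adj)
  cfg <- bym_config(n_iter = 100, hyper_shape = 0.5, hyper_rate = 0.0005)
  s <- zero_state(4)
  s$u <- c(0.5, -0.3, 0.2, -0.1)
  s$v <- c(0.2, -0.2, 0.1, -0.1)
  set.seed(42)
  draws_u <- replicate(20000, gibbs_update_precisions(s, md, cfg)$tau_u)
  a_u <- 0.5 + 2; b_u <- 0.0005 + sum(s$u^2) / 2
  probs <- seq(0.1, 0.9, 0.1)
  expect_equal(unname(quantile(draws_u, probs)),
               qgamma(probs, a_u, rate = b_u), tolerance = 0.05)

  # constant v on a connected graph: pairwise sum 0
  s$v <- rep(0.7, 4) - 0.7  # sum-to-zero constant field is 0
  set.seed(43)
  draws_v <- replicate(5000, gibbs_update_precisions(s, md, cfg)$tau_v)
  a_v <- 0.5 + 3 / 2; b_v <- 0.0005
  expect_equal(mean(draws_v), a_v / b_v, tolerance = 0.05)
})

test_that("with the likelihood switched off, Metropolis samples the prior", {
  adj <- adjacency(c("a", "b"), list(2L, 1L))
  md <- model_data(c(0, 0), c(1e-8, 1e-8), adj)
  cfg <- bym_config(n_iter = 100, spatial = FALSE,
                    fix_tau = list(tau_u = 4, tau_v = 1))
  scales <- list(alpha = 0.5, beta = numeric(0), u = c(1, 1), v = c(1, 1))
  s <- zero_state(2, tau_u = 4)
  set.seed(7)
  n_sweep <- 8000
  u1 <- numeric(n_sweep)
  for (i in seq_len(n_sweep)) {
    s <- metropolis_update_effects(s, md, cfg, scales)$state
    u1[i] <- s$u[1]
  }
  expect_equal(var(u1), 1 / 4, tolerance = 0.15)
  expect_equal(mean(u1), 0, tolerance = 0.05)
})

test_that("the spatial field is recentred to sum to zero every sweep", {
  adj <- build_lattice_adjacency(3, 3)
  set.seed(5)
  md <- model_data(rpois(9, 8), rep(8, 9), adj)
  cfg <- bym_config(n_iter = 100)
  scales <- list(alpha = 0.2, beta = numeric(0),
                 u = rep(0.3, 9), v = rep(0.3, 9))
  s <- zero_state(9, tau_u = 10, tau_v = 10)
  for (i in 1:50) {
    out <- metropolis_update_effects(s, md, cfg, scales)
    s <- out$state
    expect_lt(abs(sum(s$v)), 1e-8)
    s <- gibbs_update_precisions(s, md, cfg)
  }
})

test_that("burn-in adaptation lands acceptance rates in the working band", {
  adj <- build_lattice_adjacency(4, 4)
  set.seed(21)
  md <- model_data(rpois(16, 20), rep(20, 16), adj)
  f <- fit_bym(md, bym_config(n_iter = 2000, n_burnin = 2000, seed = 3))
  acc <- f$diagnostics$accept
  expect_true(acc$alpha > 0.2 && acc$alpha < 0.6)
  expect_true(all(acc$u > 0.2 & acc$u < 0.6))
  expect_true(all(acc$v > 0.2 & acc$v < 0.6))
})

test_that("degenerate zero proposal scale leaves the chain in place", {
  adj <- adjacency(c("a", "b"), list(2L, 1L))
  md <- model_data(c(2, 3), c(2, 2), adj)
  cfg <- bym_config(n_iter = 10, fix_tau = list(tau_u = 1, tau_v = 1))
  scales <- list(alpha = 0, beta = numeric(0), u = c(0, 0), v = c(0, 0))
  s <- zero_state(2)
  out <- metropolis_update_effects(s, md, cfg, scales)
  expect_equal(out$state$alpha, s$alpha)
  expect_equal(out$state$u, s$u)
})

test_that("large-count null data give smoothed SIRs pinned to 1", {
  adj <- build_lattice_adjacency(3, 3)
  md <- model_data(rep(1e4, 9), rep(1e4, 9), adj)
  f <- fit_bym(md, bym_config(n_iter = 1500, n_burnin = 500, seed = 11))
  expect_true(all(abs(f$summary$smoothed_sir - 1) < 0.02))
})

test_that("compiled and reference engines agree with each other", {
  adj <- build_lattice_adjacency(2, 2)
  md <- model_data(c(8, 3, 5, 6), rep(5, 4), adj)
  f_cpp <- fit_bym(md, bym_config(n_iter = 8000, n_burnin = 1000, seed = 1,
                                  fix_tau = list(tau_u = 4, tau_v = 4)))
  f_r <- fit_bym(md, bym_config(n_iter = 8000, n_burnin = 1000, seed = 2,
                                fix_tau = list(tau_u = 4, tau_v = 4),
                                engine = "R"))
  mcse <- function(f, j) {
    x <- f$chains$theta[, j]
    sd(x) / sqrt(ess_for_test(x))
  }
  for (j in 1:4) {
    tol <- 3 * (mcse(f_cpp, j) + mcse(f_r, j))
    expect_lt(abs(f_cpp$summary$smoothed_sir[j] - f_r$summary$smoothed_sir[j]),
              tol)
  }
})

test_that("a fixed seed reproduces the fit bit-for-bit", {
  reg <- simulate_region(generator_spec(n_rows = 4, n_cols = 4,
                                        mean_pop = 5000, seed = 2))
  f1 <- fit_registry(reg, n_iter = 500, n_burnin = 200, seed = 99)
  f2 <- fit_registry(reg, n_iter = 500, n_burnin = 200, seed = 99)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("islands are rejected unless explicitly allowed", {
  iso <- adjacency(c("a", "b", "c"), list(2L, 1L, integer(0)))
  md <- model_data(c(2, 3, 1), c(2, 2, 2), iso)
  expect_error(fit_bym(md, bym_config(n_iter = 200, n_burnin = 50)),
               "island")
  f <- fit_bym(md, bym_config(n_iter = 500, n_burnin = 200, seed = 4,
                              allow_islands = TRUE))
  expect_equal(nrow(f$summary), 3)
})
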
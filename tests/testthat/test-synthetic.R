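test_that("CAR field draws satisfy the constraint and the 2-node variance", {
  adj2 <- adjacency(c("a", "b"), list(2L, 1L))
  set.seed(10)
  draws <- replicate(20000, simulate_car_field(adj2, sigma_v = 1))
  expect_true(all(abs(colSums(draws)) < 1e-10))
  # single non-null Laplacian eigenvalue lambda = 2:
  # Var(v_1) = sigma_v^2 * pinv(D - W)[1,1] = 1/4
  expect_equal(var(draws[1, ]), 0.25, tolerance = 0.05)
})

test_that("empirical CAR covariance matches the Laplacian pseudo-inverse", {
  adj <- build_lattice_adjacency(3, 3)
  n <- 9
  W <- matrix(0, n, n)
  for (i in 1:n) W[i, adj$neighbors[[i]]] <- 1
  pinv <- MASS::ginv(diag(rowSums(W)) - W)
  set.seed(11)
  draws <- t(replicate(12000, simulate_car_field(adj, sigma_v = 1)))
  emp <- cov(draws)
  expect_lt(max(abs(emp - pinv)), 0.05 * max(abs(pinv)) + 0.01)
  # marginal variances scale as sigma_v^2
  set.seed(12)
  d2 <- t(replicate(6000, simulate_car_field(adj, sigma_v = 2)))
  expect_equal(mean(diag(cov(d2))) / mean(diag(emp)), 4, tolerance = 0.15)
})

test_that("disconnected graphs need the per-component flag", {
  pairs <- adjacency(c("a", "b", "c", "d"), list(2L, 1L, 4L, 3L))
  expect_error(simulate_car_field(pairs, 1), "disconnected")
  v <- simulate_car_field(pairs, 1, per_component = TRUE)
  expect_lt(abs(sum(v[1:2])), 1e-12)
  expect_lt(abs(sum(v[3:4])), 1e-12)
})

test_that("a fixed seed reproduces the registry bit-for-bit", {
  r1 <- simulate_region(generator_spec(n_rows = 4, n_cols = 4,
                                       mean_pop = 3000, seed = 77))
  r2 <- simulate_region(generator_spec(n_rows = 4, n_cols = 4,
                                       mean_pop = 3000, seed = 77))
  expect_identical(r1$population, r2$population)
  expect_identical(r1$cases, r2$cases)
  expect_identical(r1$ground_truth, r2$ground_truth)
})

test_that("generator hits its population and incidence calibration", {
  pops <- numeric(0)
  for (s in 1:10) {
    reg <- simulate_region(generator_spec(seed = 500 + s, sigma_u = 0,
                                          sigma_v = 0,
                                          deprivation_risk_link = "none"))
    pops <- c(pops, tapply(reg$population$population,
                           reg$population$unit_id, sum))
  }
  expect_equal(mean(pops), 23725, tolerance = 0.05)

  # null model: pooled crude rate estimates the programmed 163 pmi target
  reg <- simulate_region(generator_spec(sigma_u = 0, sigma_v = 0,
                                        deprivation_risk_link = "none",
                                        alpha = 0, seed = 123))
  pop_total <- sum(reg$population$population)
  n_cases <- nrow(reg$cases)
  rate <- crude_rate(n_cases, pop_total, 7)
  se <- crude_rate(sqrt(n_cases), pop_total, 7)
  expect_lt(abs(rate - 163), 3 * se)
})

test_that("realized case totals track their Poisson expectation", {
  for (s in 1:3) {
    spec <- generator_spec(n_rows = 6, n_cols = 6, mean_pop = 8000,
                           seed = 600 + s)
    reg <- simulate_region(spec)
    gt <- reg$ground_truth
    mu <- with(reg$population,
               7 * population *
                 gt$stratum_rates$rate[match(paste(sex, age_band),
                                             paste(gt$stratum_rates$sex,
                                                   gt$stratum_rates$age_band))] *
                 gt$theta[match(unit_id, reg$adjacency$unit_ids)])
    total_mu <- sum(mu)
    expect_lt(abs(sum(reg$population$cases) - total_mu), 4 * sqrt(total_mu))
  }
})

test_that("case records are consistent with the stratified counts", {
  reg <- simulate_region(generator_spec(n_rows = 5, n_cols = 5,
                                        mean_pop = 10000, seed = 9))
  expect_equal(nrow(reg$cases), sum(reg$population$cases))
  by_unit_strat <- table(paste(reg$cases$unit_id, reg$cases$sex,
                               reg$cases$age_band))
  tab <- reg$population[reg$population$cases > 0, ]
  key <- paste(tab$unit_id, tab$sex, tab$age_band)
  expect_equal(as.integer(by_unit_strat[key]), tab$cases)
  expect_true(all(reg$cases$egfr > 0))
  expect_true(all(reg$cases$cause %in% c("diabetic", "vascular", "other")))
})

test_that("programmed cause shares are recovered from the records", {
  reg <- simulate_region(generator_spec(seed = 321))
  p <- cause_proportions(reg$cases$unit_id, reg$cases$cause, "diabetic",
                         units = reg$adjacency$unit_ids)
  n <- nrow(reg$cases)
  pooled <- 100 * sum(reg$cases$cause == "diabetic") / n
  se <- 100 * sqrt(0.275 * 0.725 / n)
  expect_lt(abs(pooled - 27.5), 4 * se)
  expect_true(all(is.na(p$value) | (p$value >= 0 & p$value <= 100)))
})

test_that("ground-truth report recomposes theta exactly", {
  reg <- simulate_region(generator_spec(n_rows = 5, n_cols = 5,
                                        mean_pop = 5000, seed = 14))
  gt <- ground_truth_report(reg)
  expect_equal(nrow(gt), 25)
  X <- quintile_dummies(reg$townsend)
  recomposed <- unname(exp(attr(gt, "alpha") + gt$u + gt$v +
                             drop(X %*% attr(gt, "beta"))))
  expect_identical(recomposed, gt$theta)
})
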
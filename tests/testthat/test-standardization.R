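test_that("crude rate arithmetic and argument checks", {
  expect_equal(round(crude_rate(4597, 4033000, 7)), 163)
  expect_equal(crude_rate(0, 1e6, 7), 0)
  expect_equal(crude_rate(7, 1e6, 7), 1)
  expect_error(crude_rate(1, 0, 7), "population")
  expect_error(crude_rate(1, 100, 0), "years")
  # linear in cases, inverse-linear in person-years
  expect_equal(crude_rate(30, 5e5, 4), 3 * crude_rate(10, 5e5, 4))
  expect_equal(crude_rate(10, 5e5, 8), crude_rate(10, 5e5, 4) / 2)
})

test_that("internal reference rates pool strata over units", {
  one <- data.frame(unit_id = "a", sex = "M", age_band = "0-4",
                    population = 1e6, cases = 70)
  r <- internal_reference_rates(one, 7)
  expect_equal(r$rate, 1e-5)  # 10 per million person-years

  zero <- data.frame(unit_id = "a", sex = "F", age_band = "0-4",
                     population = 100, cases = 0)
  expect_equal(internal_reference_rates(zero, 7)$rate, 0)

  tab <- toy_stratified()
  r2 <- internal_reference_rates(tab, 7)
  # pooled by hand: stratum 0-4 has 3 cases / 1600 persons, 5-9 has 8 / 1600
  expect_equal(sort(r2$rate), sort(c(3 / (7 * 1600), 8 / (7 * 1600))))

  bad <- data.frame(unit_id = "a", sex = "M", age_band = "0-4",
                    population = 0, cases = 2)
  expect_error(internal_reference_rates(bad, 7), "zero regional population")
})

test_that("expected counts follow indirect standardization", {
  tab <- toy_stratified()
  r <- internal_reference_rates(tab, 7)
  E <- expected_counts(tab, r, 7)
  # hand computation with pooled rates
  r04 <- 3 / (7 * 1600); r59 <- 8 / (7 * 1600)
  expect_equal(unname(E),
               7 * c(1000 * r04 + 200 * r59,
                     500 * r04 + 500 * r59,
                     100 * r04 + 900 * r59))
  # conservation: sum(E) = sum(O) to machine precision
  expect_equal(sum(E), sum(tab$cases))

  # proportionality under a uniform rate
  uni <- data.frame(unit_id = c("a", "b"), sex = "M", age_band = "0-4",
                    population = c(100, 300), cases = c(0, 0))
  Eu <- expected_counts(uni, data.frame(sex = "M", age_band = "0-4",
                                        rate = 0.01), 2)
  expect_equal(unname(Eu[2] / Eu[1]), 3)

  expect_error(
    expected_counts(tab, data.frame(sex = "M", age_band = "0-4",
                                    rate = 0.1), 7),
    "missing reference rate")
})

test_that("conservation and pooled SIR hold on generated registries", {
  for (s in 1:3) {
    reg <- simulate_region(generator_spec(n_rows = 5, n_cols = 5,
                                          mean_pop = 4000, seed = s))
    r <- internal_reference_rates(reg$population, 7)
    E <- expected_counts(reg$population, r, 7)
    O <- observed_counts(reg$population)
    expect_equal(sum(E), sum(O), tolerance = 1e-12)
    expect_equal(sum(O) / sum(E), 1, tolerance = 1e-12)
  }
})

test_that("direct standardization is a weighted mean of stratum rates", {
  expect_equal(direct_standardized_rate(c(5, 5, 5), c(1, 7, 2)), 5)
  expect_equal(direct_standardized_rate(c(10, 30), c(1, 1)), 20)
  expect_equal(direct_standardized_rate(c(10, 30), c(3, 1)), 15)
  expect_error(direct_standardized_rate(c(1, 2), c(0, 0)), "weights")
})

test_that("SIR table exposes exact Poisson intervals", {
  t1 <- sir_table(10, 10)
  expect_equal(t1$sir, 1)
  expect_true(t1$ci_low < 1 && t1$ci_high > 1)

  t0 <- sir_table(0, 5)
  expect_equal(t0$sir, 0)
  expect_equal(t0$ci_low, 0)

  t2 <- sir_table(10, 5)
  expect_equal(t2$sir, 2)
  oracle <- poisson_ci_oracle(10, 5)
  expect_equal(t2$ci_low, oracle[1], tolerance = 1e-6)
  expect_equal(t2$ci_high, oracle[2], tolerance = 1e-6)

  expect_error(sir_table(3, 0), "zero expected")
  flagged <- sir_table(0, 0)
  expect_false(flagged$estimable)
  expect_true(is.na(flagged$sir))
})

test_that("gamma-quantile bounds match the tail-sum oracle on a grid", {
  # spot grid here; the full O in 0..50 sweep runs in the acceptance suite
  for (o in c(0, 1, 7, 25)) for (e in c(0.5, 5, 20)) {
    tab <- sir_table(o, e)
    oracle <- poisson_ci_oracle(o, e)
    expect_equal(tab$ci_low, oracle[1], tolerance = 1e-6)
    expect_equal(tab$ci_high, oracle[2], tolerance = 1e-6)
  }
})
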
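# small builders shared across test files

toy_stratified <- function() {
  # 3 units x 2 strata with unequal age structures
  data.frame(
    unit_id = rep(c("a", "b", "c"), each = 2),
    sex = rep("M", 6),
    age_band = rep(c("0-4", "5-9"), 3),
    population = c(1000, 200, 500, 500, 100, 900),
    cases = c(2, 1, 1, 3, 0, 4),
    stringsAsFactors = FALSE)
}

toy_census <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(
    unit_id = sprintf("u%02d", seq_len(n)),
    pct_non_owner = runif(n, 10, 80),
    pct_unemployed = runif(n, 2, 30),
    pct_overcrowded = runif(n, 1, 20),
    pct_no_car = runif(n, 5, 50),
    stringsAsFactors = FALSE)
}

write_gal <- function(lines) {
  path <- tempfile(fileext = ".gal")
  writeLines(lines, path)
  path
}

path3_adjacency <- function() {
  adjacency(c("A", "B", "C"), list(2L, c(1L, 3L), 2L))
}

# exact Poisson interval bounds by direct tail-probability search,
# independent of the gamma-quantile identity used in sir_table()
poisson_ci_oracle <- function(o, e, level = 0.95) {
  a <- 1 - level
  upper <- max(10, 10 * (o + 1) / e)
  lo <- if (o == 0) 0 else
    uniroot(function(s) ppois(o - 1, s * e, lower.tail = FALSE) - a / 2,
            c(1e-12, upper), tol = 1e-12)$root
  hi <- uniroot(function(s) ppois(o, s * e) - a / 2,
                c(1e-12, upper), tol = 1e-12)$root
  c(lo, hi)
}

# crude ESS used only to set Monte-Carlo tolerances in tests
ess_for_test <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 500), plot = FALSE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r < 0.01) break
    s <- s + r
  }
  max(1, n / (1 + 2 * s))
}

# small standardization + fit pipeline used by several tests
fit_registry <- function(reg, n_iter = 2000, n_burnin = 500, seed = 1,
                         covariates = TRUE, ...) {
  rates <- internal_reference_rates(reg$population, reg$spec$years)
  E <- expected_counts(reg$population, rates, reg$spec$years)
  O <- observed_counts(reg$population)
  X <- if (covariates) quintile_dummies(reg$townsend) else NULL
  md <- model_data(O, E, reg$adjacency, X)
  fit_bym(md, bym_config(n_iter = n_iter, n_burnin = n_burnin,
                         seed = seed, ...))
}
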
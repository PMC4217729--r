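default_age_bands <- function() {
  c(paste(seq(0, 85, 5), seq(4, 89, 5), sep = "-"), "90+")
}

# plausible western-European age pyramid (shares normalized at use)
default_age_shares <- function() {
  c(6.2, 6.1, 6.2, 6.5, 6.3, 6.3, 6.4, 6.9, 7.0, 6.9,
    6.6, 6.4, 5.9, 4.2, 3.7, 3.2, 2.5, 1.7, 1.0)
}

# relative incidence by age band: ESRD incidence rises steeply with age
# and plateaus in the very old
default_age_rate_shape <- function() {
  c(0.08, 0.08, 0.12, 0.2, 0.3, 0.45, 0.65, 0.95, 1.4, 2.2,
    3.4, 5.2, 7.5, 10.0, 13.0, 15.0, 15.5, 13.0, 9.0)
}

#' Specification of a synthetic ESRD registry
#'
#' Defaults emulate a ~170-canton region observed for 7 years: a 13 x 13
#' lattice (169 units), mean unit population 23,725 with lognormal
#' dispersion, an age-sex-structured population with steeply age-increasing
#' incidence calibrated to an overall crude rate of 163 cases per million
#' person-years, a spatially correlated true log-risk field (heterogeneity
#' sd `sigma_u`, intrinsic-CAR sd `sigma_v`), and a deprivation gradient
#' whose quintiles multiply risk by `exp(beta_true)` =
#' (1.18, 1.28, 1.30, 1.44) relative to the least-deprived quintile.
#' Case attributes (cause shares, eGFR at initiation, nephrologist visits)
#' follow registry-typical values.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param mean_pop mean unit population.
#' @param pop_sdlog lognormal sd of unit population sizes.
#' @param years study duration in years.
#' @param target_crude_pmi overall crude incidence target, cases per million
#'   person-years.
#' @param sex_male_share male share of the population.
#' @param age_shares relative population shares of the 5-year age bands
#'   0-4 .. 90+ (normalized internally).
#' @param age_rate_shape relative incidence by age band.
#' @param male_rate_ratio male/female incidence ratio.
#' @param sigma_u,sigma_v true random-effect standard deviations.
#' @param beta_true log relative risks of deprivation quintiles Q2..Q5
#'   (vs Q1).
#' @param deprivation_risk_link `"quintile"` (risk follows the Townsend
#'   quintile dummies; the fitted model is correctly specified),
#'   `"continuous"` (risk follows the latent deprivation axis linearly; a
#'   misspecification toggle) or `"none"`.
#' @param alpha overall log-risk level; `NULL` (default) calibrates it so
#'   the population-weighted mean relative risk is 1, keeping the realized
#'   overall crude rate at its target.
#' @param cause_shares named probabilities of primary kidney disease labels.
#' @param egfr_mean,egfr_sd eGFR at initiation (ml/min/1.73m^2), truncated
#'   positive normal.
#' @param visits_lambda Poisson mean of nephrologist visits in the year
#'   before treatment.
#' @param seed RNG seed; fixed seed gives bit-identical registries.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_rows = 13, n_cols = 13,
                           mean_pop = 23725, pop_sdlog = 0.6,
                           years = 7, target_crude_pmi = 163,
                           sex_male_share = 0.49,
                           age_shares = default_age_shares(),
                           age_rate_shape = default_age_rate_shape(),
                           male_rate_ratio = 1.43,
                           sigma_u = 0.1, sigma_v = 0.2,
                           beta_true = log(c(1.18, 1.28, 1.30, 1.44)),
                           deprivation_risk_link = c("quintile",
                                                     "continuous", "none"),
                           alpha = NULL,
                           cause_shares = c(diabetic = 0.275,
                                            vascular = 0.244,
                                            other = 0.481),
                           egfr_mean = 9.05, egfr_sd = 1.46,
                           visits_lambda = 3,
                           seed = NULL) {
  deprivation_risk_link <- match.arg(deprivation_risk_link)
  bands <- default_age_bands()
  if (length(age_shares) != length(bands) ||
      length(age_rate_shape) != length(bands))
    stop("age_shares and age_rate_shape must have ", length(bands),
         " entries (5-year bands 0-4 .. 90+)", call. = FALSE)
  if (any(age_shares < 0) || sum(age_shares) <= 0)
    stop("age_shares must be non-negative with a positive sum", call. = FALSE)
  if (any(age_rate_shape < 0)) stop("age_rate_shape must be >= 0",
                                    call. = FALSE)
  if (mean_pop <= 0 || pop_sdlog <= 0 || years <= 0 || target_crude_pmi <= 0)
    stop("scale parameters must be positive", call. = FALSE)
  if (sigma_u < 0 || sigma_v < 0)
    stop("sigma_u and sigma_v must be >= 0", call. = FALSE)
  if (abs(sum(cause_shares) - 1) > 1e-8 || any(cause_shares < 0))
    stop("cause_shares must be non-negative and sum to 1", call. = FALSE)
  if (deprivation_risk_link == "quintile" && length(beta_true) != 4)
    stop("beta_true must have 4 entries (Q2..Q5)", call. = FALSE)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, mean_pop = mean_pop,
         pop_sdlog = pop_sdlog, years = years,
         target_crude_pmi = target_crude_pmi,
         sex_male_share = sex_male_share,
         age_bands = bands,
         age_shares = age_shares / sum(age_shares),
         age_rate_shape = age_rate_shape,
         male_rate_ratio = male_rate_ratio,
         sigma_u = sigma_u, sigma_v = sigma_v, beta_true = beta_true,
         deprivation_risk_link = deprivation_risk_link,
         alpha = alpha, cause_shares = cause_shares,
         egfr_mean = egfr_mean, egfr_sd = egfr_sd,
         visits_lambda = visits_lambda, seed = seed),
    class = "generator_spec")
}

#' Exact draw from the intrinsic CAR distribution
#'
#' Samples the zero-mean Gaussian Markov random field whose precision is
#' `(1/sigma_v^2) (D - W)` restricted to the sum-to-zero subspace, by
#' eigen-decomposition of the graph Laplacian: independent normals with
#' variance `sigma_v^2 / lambda_k` on the non-null eigenvectors. The draw
#' sums to zero by construction.
#'
#' @param adj an [adjacency()] object; must be connected unless
#'   `per_component = TRUE` (then the constraint holds per component).
#' @param sigma_v marginal scale of the field (conditional sd is
#'   `sigma_v / sqrt(n_i)`).
#' @param per_component allow disconnected graphs, constraining each
#'   component separately.
#' @return Numeric vector `v` with `sum(v) == 0` (exactly, after removing
#'   numerical round-off).
#' @export
simulate_car_field <- function(adj, sigma_v, per_component = FALSE) {
  rep_adj <- validate_adjacency(adj)
  n <- rep_adj$n_units
  if (rep_adj$n_components > 1 && !per_component)
    stop("adjacency graph is disconnected; set per_component = TRUE",
         call. = FALSE)
  if (sigma_v == 0) return(numeric(n))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, adj$neighbors[[i]]] <- 1
  L <- diag(rowSums(W)) - W
  eg <- eigen(L, symmetric = TRUE)
  keep <- eg$values > 1e-9 * max(eg$values)
  z <- stats::rnorm(sum(keep))
  v <- drop(eg$vectors[, keep, drop = FALSE] %*%
              (z * sigma_v / sqrt(eg$values[keep])))
  # remove numerical round-off so the constraint holds exactly
  for (k in seq_len(rep_adj$n_components)) {
    m <- rep_adj$component == k
    v[m] <- v[m] - mean(v[m])
  }
  v
}

rnorm_trunc_pos <- function(n, mean, sd) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] <= 0]
  }
  out
}

#' Generate a synthetic ESRD registry with known ground truth
#'
#' Builds the full data-generating process the mapping pipeline assumes:
#' lattice adjacency, lognormal unit populations stratified by sex and
#' 5-year age band, census deprivation components driven by a latent axis,
#' true log-risks `log theta_i = alpha + u_i + v_i + x_i' beta`, Poisson
#' stratum case counts with mean `years * pop * rate * theta_i`, and
#' per-case attributes (cause, eGFR at initiation, nephrologist visits).
#'
#' @param spec a [generator_spec()].
#' @return An object of class `synthetic_registry`: list with `population`
#'   (stratified table), `cases` (one row per case), `census`, `adjacency`,
#'   `centroids`, `townsend` (scores/quintiles used for the risk link), and
#'   `ground_truth` (`alpha`, `u`, `v`, `beta`, `theta`, sds, latent axis).
#' @export
simulate_region <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  adj <- build_lattice_adjacency(spec$n_rows, spec$n_cols)
  n <- length(adj$unit_ids)
  pop <- pmax(100, round(stats::rlnorm(
    n, log(spec$mean_pop) - spec$pop_sdlog^2 / 2, spec$pop_sdlog)))

  # stratum shares (age x sex) and per-stratum annual rates calibrated to
  # the overall crude target
  shares <- c(spec$age_shares * spec$sex_male_share,
              spec$age_shares * (1 - spec$sex_male_share))
  sexes <- rep(c("M", "F"), each = length(spec$age_bands))
  bands <- rep(spec$age_bands, 2)
  shape <- rep(spec$age_rate_shape, 2) *
    ifelse(sexes == "M", spec$male_rate_ratio, 1)
  scale <- (spec$target_crude_pmi * 1e-6) / sum(shares * shape)
  rates <- shape * scale   # cases per person-year by stratum

  strat_pop <- vapply(seq_len(n), function(i)
    drop(stats::rmultinom(1, pop[i], shares)), numeric(length(shares)))

  # latent deprivation axis -> census components
  d <- stats::rnorm(n)
  clip <- function(x) pmin(100, pmax(0, x))
  census <- data.frame(
    unit_id = adj$unit_ids,
    pct_non_owner = clip(40 + 12 * d + stats::rnorm(n, 0, 4)),
    pct_unemployed = clip(12 + 4 * d + stats::rnorm(n, 0, 1.5)),
    pct_overcrowded = clip(8 + 3 * d + stats::rnorm(n, 0, 1.2)),
    pct_no_car = clip(20 + 8 * d + stats::rnorm(n, 0, 3)),
    stringsAsFactors = FALSE)

  townsend <- assign_quintiles(townsend_score(census))
  risk <- numeric(n)
  X <- NULL
  beta <- numeric(0)
  if (spec$deprivation_risk_link == "quintile") {
    X <- quintile_dummies(townsend)
    beta <- spec$beta_true
    risk <- drop(X %*% beta)
  } else if (spec$deprivation_risk_link == "continuous") {
    beta <- spec$beta_true[1]
    risk <- beta * d
  }

  u <- if (spec$sigma_u > 0) stats::rnorm(n, 0, spec$sigma_u) else numeric(n)
  v <- simulate_car_field(adj, spec$sigma_v)
  alpha <- if (is.null(spec$alpha))
    -log(sum(pop * exp(u + v + risk)) / sum(pop)) else spec$alpha
  theta <- exp(alpha + u + v + risk)

  # stratum case counts and case records
  mu <- spec$years * strat_pop * outer(rates, theta)    # strata x units
  cases_sa <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
  population <- data.frame(
    unit_id = rep(adj$unit_ids, each = length(shares)),
    sex = rep(sexes, n),
    age_band = rep(bands, n),
    population = as.vector(strat_pop),
    cases = as.vector(cases_sa),
    stringsAsFactors = FALSE)

  n_cases <- sum(cases_sa)
  idx <- rep(seq_along(cases_sa), as.vector(cases_sa))
  s_ix <- (idx - 1) %% length(shares) + 1
  u_ix <- (idx - 1) %/% length(shares) + 1
  cases <- data.frame(
    unit_id = adj$unit_ids[u_ix],
    sex = sexes[s_ix],
    age_band = bands[s_ix],
    cause = sample(names(spec$cause_shares), n_cases, replace = TRUE,
                   prob = spec$cause_shares),
    egfr = rnorm_trunc_pos(n_cases, spec$egfr_mean, spec$egfr_sd),
    visits = stats::rpois(n_cases, spec$visits_lambda),
    stringsAsFactors = FALSE)
  cases$townsend <- townsend$score[match(cases$unit_id, townsend$unit_id)]

  rc <- (seq_len(n) - 1) %/% spec$n_cols
  cc <- (seq_len(n) - 1) %% spec$n_cols
  centroids <- data.frame(unit_id = adj$unit_ids, name = adj$unit_ids,
                          lon = 3 + cc * 0.05, lat = 50 + rc * 0.05,
                          stringsAsFactors = FALSE)

  structure(
    list(population = population, cases = cases, census = census,
         adjacency = adj, centroids = centroids, townsend = townsend,
         ground_truth = list(alpha = alpha, u = u, v = v, beta = beta,
                             theta = theta, sigma_u = spec$sigma_u,
                             sigma_v = spec$sigma_v, latent_axis = d,
                             stratum_rates = data.frame(
                               sex = sexes, age_band = bands, rate = rates,
                               stringsAsFactors = FALSE)),
         spec = spec),
    class = "synthetic_registry")
}

#' @export
print.synthetic_registry <- function(x, ...) {
  cat("Synthetic registry:", length(x$adjacency$unit_ids), "units,",
      nrow(x$cases), "cases over", x$spec$years, "years\n")
  cat("  overall crude rate:",
      round(crude_rate(nrow(x$cases), sum(x$population$population),
                       x$spec$years)), "per million person-years\n")
  invisible(x)
}

#' Ground-truth parameter report
#'
#' Emits the generator's true per-unit parameters for recovery scoring:
#' `theta_i` recomposed from its parts must match the stored value exactly.
#'
#' @param registry a [simulate_region()] result.
#' @return Data frame with one row per unit (`unit_id`, `u`, `v`,
#'   `log_theta`, `theta`, `quintile`) and the global parameters as
#'   attributes `alpha`, `beta`, `sigma_u`, `sigma_v`.
#' @export
ground_truth_report <- function(registry) {
  stopifnot(inherits(registry, "synthetic_registry"))
  gt <- registry$ground_truth
  df <- data.frame(unit_id = registry$adjacency$unit_ids,
                   u = gt$u, v = gt$v,
                   log_theta = log(gt$theta), theta = gt$theta,
                   quintile = registry$townsend$quintile,
                   stringsAsFactors = FALSE)
  attr(df, "alpha") <- gt$alpha
  attr(df, "beta") <- gt$beta
  attr(df, "sigma_u") <- gt$sigma_u
  attr(df, "sigma_v") <- gt$sigma_v
  df
}

#' Write a synthetic registry to the pipeline's input formats
#'
#' @param registry a [simulate_region()] result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "synthetic_registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    population = file.path(dir, "population.csv"),
    cases = file.path(dir, "cases.csv"),
    census = file.path(dir, "census.csv"),
    adjacency = file.path(dir, "adjacency.gal"),
    centroids = file.path(dir, "centroids.csv"),
    ground_truth = file.path(dir, "ground_truth.csv"))
  utils::write.csv(registry$population, paths["population"],
                   row.names = FALSE)
  utils::write.csv(registry$cases, paths["cases"], row.names = FALSE)
  utils::write.csv(registry$census, paths["census"], row.names = FALSE)
  write_neighbor_list(registry$adjacency, paths["adjacency"])
  utils::write.csv(registry$centroids, paths["centroids"], row.names = FALSE)
  gt <- ground_truth_report(registry)
  utils::write.csv(gt, paths["ground_truth"], row.names = FALSE)
  paths
}
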
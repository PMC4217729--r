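#' Crude incidence rate
#'
#' Number of new cases divided by person-time at risk, expressed per `scale`
#' persons per year. With `scale = 1e6` this is the conventional "per million
#' inhabitants per year" (pmi) figure.
#'
#' @param cases number of incident cases (>= 0).
#' @param population population at risk, assumed constant over the period.
#' @param years study duration in years.
#' @param scale reporting scale in persons (default `1e6`).
#' @return Rate per `scale` persons per year.
#' @export
crude_rate <- function(cases, population, years, scale = 1e6) {
  if (any(population <= 0)) stop("population must be positive", call. = FALSE)
  if (any(years <= 0)) stop("years must be positive", call. = FALSE)
  if (any(cases < 0)) stop("cases must be non-negative", call. = FALSE)
  cases / (population * years) * scale
}

check_stratified <- function(table) {
  need <- c("unit_id", "sex", "age_band", "population", "cases")
  if (!all(need %in% names(table)))
    stop("stratified table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$population < 0) || any(table$cases < 0))
    stop("population and cases must be non-negative", call. = FALSE)
  table$unit_id <- as.character(table$unit_id)
  table$stratum <- paste(table$sex, table$age_band, sep = "|")
  table
}

#' Internal (regional) reference rates by stratum
#'
#' Pools cases and person-years over all units to give the region-wide rate
#' for every sex x age-band stratum, the engine of indirect standardization.
#' Strata with zero regional population get rate 0 (and must have no cases).
#'
#' @param table stratified data frame with columns `unit_id`, `sex`,
#'   `age_band`, `population`, `cases`.
#' @param years study duration in years.
#' @return Data frame with columns `sex`, `age_band`, `rate` (cases per
#'   person-year).
#' @export
internal_reference_rates <- function(table, years) {
  if (years <= 0) stop("years must be positive", call. = FALSE)
  table <- check_stratified(table)
  pop <- tapply(table$population, table$stratum, sum)
  cas <- tapply(table$cases, table$stratum, sum)
  if (any(cas > 0 & pop == 0))
    stop("stratum with cases but zero regional population", call. = FALSE)
  rate <- ifelse(pop > 0, cas / (years * pop), 0)
  parts <- strsplit(names(pop), "|", fixed = TRUE)
  data.frame(sex = vapply(parts, `[`, "", 1),
             age_band = vapply(parts, `[`, "", 2),
             rate = as.numeric(rate),
             stringsAsFactors = FALSE)
}

#' Expected case counts by indirect standardization
#'
#' Applies stratum-specific reference rates to each unit's population:
#' `E_i = years * sum_s population(i,s) * rate(s)`. With rates from
#' [internal_reference_rates()], `sum(E_i)` equals the total observed count
#' exactly and the pooled SIR of the region is 1.
#'
#' @param table stratified data frame (see [internal_reference_rates()]).
#' @param rates reference rate data frame with columns `sex`, `age_band`,
#'   `rate`.
#' @param years study duration in years.
#' @return Named numeric vector of `E_i` per unit (names are unit ids, in
#'   first-appearance order).
#' @export
expected_counts <- function(table, rates, years) {
  table <- check_stratified(table)
  rates$stratum <- paste(rates$sex, rates$age_band, sep = "|")
  m <- match(table$stratum, rates$stratum)
  if (anyNA(m))
    stop("missing reference rate for stratum ",
         paste(unique(table$stratum[is.na(m)]), collapse = ", "),
         call. = FALSE)
  contrib <- years * table$population * rates$rate[m]
  units <- unique(table$unit_id)
  e <- tapply(contrib, factor(table$unit_id, levels = units), sum)
  out <- as.numeric(e)
  names(out) <- units
  out
}

#' Observed case counts per unit
#'
#' @param table stratified data frame (see [internal_reference_rates()]).
#' @return Named integer-valued vector of `O_i` per unit.
#' @export
observed_counts <- function(table) {
  table <- check_stratified(table)
  units <- unique(table$unit_id)
  o <- tapply(table$cases, factor(table$unit_id, levels = units), sum)
  out <- as.numeric(o)
  names(out) <- units
  out
}

#' Directly standardized rate
#'
#' Weighted average of stratum-specific rates with weights proportional to a
#' reference population.
#'
#' @param stratum_rates numeric vector of rates per stratum.
#' @param reference_pop non-negative weights of the same length, not all zero.
#' @return The standardized rate (same units as `stratum_rates`).
#' @export
direct_standardized_rate <- function(stratum_rates, reference_pop) {
  if (length(stratum_rates) != length(reference_pop))
    stop("rates and weights must have the same length", call. = FALSE)
  if (any(reference_pop < 0) || sum(reference_pop) <= 0)
    stop("weights must be non-negative with a positive sum", call. = FALSE)
  sum(stratum_rates * reference_pop) / sum(reference_pop)
}

#' Raw standardized incidence ratios with exact Poisson intervals
#'
#' `SIR_i = O_i / E_i` with equal-tailed exact Poisson interval bounds from
#' the gamma-quantile formulation: `low = qgamma(a/2, O_i) / E_i` (0 when
#' `O_i = 0`) and `high = qgamma(1 - a/2, O_i + 1) / E_i`, `a = 1 - level`.
#'
#' @param observed per-unit observed counts `O_i` (optionally named).
#' @param expected per-unit expected counts `E_i`.
#' @param level interval coverage, default 0.95.
#' @return Data frame `unit_id`, `observed`, `expected`, `sir`, `ci_low`,
#'   `ci_high`, `estimable`. Units with `E_i = 0` and `O_i = 0` are flagged
#'   not estimable (`sir = NA`); `E_i = 0` with `O_i > 0` is an error.
#' @export
sir_table <- function(observed, expected, level = 0.95) {
  if (length(observed) != length(expected))
    stop("observed and expected must have the same length", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  if (any(expected < 0)) stop("expected counts must be >= 0", call. = FALSE)
  if (any(expected == 0 & observed > 0))
    stop("unit with observed cases but zero expected count", call. = FALSE)
  ids <- names(observed)
  if (is.null(ids)) ids <- as.character(seq_along(observed))
  a <- 1 - level
  estimable <- expected > 0
  sir <- ifelse(estimable, observed / expected, NA_real_)
  lo <- ifelse(observed > 0, stats::qgamma(a / 2, shape = observed), 0)
  hi <- stats::qgamma(1 - a / 2, shape = observed + 1)
  data.frame(unit_id = ids,
             observed = as.numeric(observed),
             expected = as.numeric(expected),
             sir = sir,
             ci_low = ifelse(estimable, lo / expected, NA_real_),
             ci_high = ifelse(estimable, hi / expected, NA_real_),
             estimable = estimable,
             stringsAsFactors = FALSE)
}
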
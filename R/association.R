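#' Per-unit median of a case-level attribute
#'
#' Aggregates a per-case numeric attribute (e.g. eGFR at dialysis
#' initiation) to its median within each spatial unit; even counts use the
#' midpoint of the central pair. Units with no non-missing value are
#' returned as `NA` (to be excluded downstream).
#'
#' @param unit_id character vector of the unit of each case.
#' @param value numeric attribute per case (NAs allowed).
#' @param units optional character vector fixing the output units/order;
#'   defaults to the units present.
#' @return Data frame `unit_id`, `value` (the median, NA when no data).
#' @export
area_median <- function(unit_id, value, units = NULL) {
  unit_id <- as.character(unit_id)
  if (length(unit_id) != length(value))
    stop("unit_id and value must have the same length", call. = FALSE)
  if (is.null(units)) units <- unique(unit_id)
  keep <- !is.na(value)
  med <- tapply(value[keep], factor(unit_id[keep], levels = units),
                stats::median)
  data.frame(unit_id = units, value = as.numeric(med),
             stringsAsFactors = FALSE)
}

#' Pearson correlation of log-SIR with an area covariate
#'
#' Correlates the logarithm of the (typically smoothed) SIR with an
#' area-level covariate such as the canton median eGFR; `p` comes from the
#' t transform with `n - 2` degrees of freedom. Units with a missing
#' covariate or non-positive SIR are dropped.
#'
#' @param sir per-unit SIRs (> 0 where used).
#' @param covariate per-unit covariate values, same length/order.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_log_sir <- function(sir, covariate) {
  if (length(sir) != length(covariate))
    stop("sir and covariate must have the same length", call. = FALSE)
  keep <- !is.na(sir) & !is.na(covariate) & sir > 0
  x <- log(sir[keep]); y <- covariate[keep]
  if (length(x) < 3)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero-variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-unit cause-of-disease proportions
#'
#' Percentage of cases in each unit whose primary kidney disease carries the
#' named label (e.g. diabetic or vascular nephropathy). Units without cases
#' are returned as `NA`.
#'
#' @param unit_id character vector of the unit of each case.
#' @param cause character vector of cause labels per case (an explicit
#'   `"unknown"` is a label like any other).
#' @param label the cause to tally.
#' @param units optional character vector fixing the output units/order.
#' @return Data frame `unit_id`, `value` (percentage in `[0, 100]`).
#' @export
cause_proportions <- function(unit_id, cause, label, units = NULL) {
  unit_id <- as.character(unit_id)
  if (length(unit_id) != length(cause))
    stop("unit_id and cause must have the same length", call. = FALSE)
  if (anyNA(cause))
    stop("every case needs a cause label (use an explicit 'unknown')",
         call. = FALSE)
  if (is.null(units)) units <- unique(unit_id)
  f <- factor(unit_id, levels = units)
  tot <- tapply(rep(1, length(unit_id)), f, sum)
  hit <- tapply(as.numeric(cause == label), f, sum)
  data.frame(unit_id = units,
             value = as.numeric(100 * hit / tot),
             stringsAsFactors = FALSE)
}

#' Deprivation vs late-referral association
#'
#' Correlates the residential deprivation score attributed to each case with
#' the number of nephrologist visits in the year preceding treatment (a
#' late-referral proxy). Spearman by default (visit counts are discrete and
#' skewed); Pearson available by flag.
#'
#' @param townsend per-case residential deprivation score.
#' @param visits per-case nephrologist visit count.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List with `statistic` (the correlation), `p`, `n`, `method`.
#' @export
late_referral_association <- function(townsend, visits,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- !is.na(townsend) & !is.na(visits)
  x <- townsend[keep]; y <- visits[keep]
  if (length(x) < 10)
    stop("need at least 10 complete cases", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant column", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(statistic = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}
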
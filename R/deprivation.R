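#' Townsend deprivation scores
#'
#' Builds the Townsend material-deprivation index for each spatial unit as
#' the sum of four z-standardized census components: % households not
#' owner-occupied, % unemployment, % household overcrowding, and % households
#' without access to a motor vehicle. Under the classical transform,
#' unemployment and overcrowding are `log(x + 1)`-transformed before
#' z-scoring; z-scores use the population (n-denominator) standard deviation
#' across the supplied units, so the mean score is exactly 0.
#'
#' @param census data frame with columns `unit_id`, `pct_non_owner`,
#'   `pct_unemployed`, `pct_overcrowded`, `pct_no_car`; all percentages in
#'   `[0, 100]`.
#' @param transform `"townsend1988"` (default; log-transform the unemployment
#'   and overcrowding components) or `"none"`.
#' @return Data frame `unit_id`, `score`, `quintile` (NA until
#'   [assign_quintiles()] is applied).
#' @export
townsend_score <- function(census, transform = c("townsend1988", "none")) {
  transform <- match.arg(transform)
  comp <- c("pct_non_owner", "pct_unemployed", "pct_overcrowded", "pct_no_car")
  if (!all(c("unit_id", comp) %in% names(census)))
    stop("census table needs columns unit_id, ", paste(comp, collapse = ", "),
         call. = FALSE)
  if (nrow(census) < 2)
    stop("at least 2 units are required", call. = FALSE)
  x <- as.matrix(census[, comp])
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100))
    stop("census components must be finite percentages in [0, 100]",
         call. = FALSE)
  if (transform == "townsend1988") {
    x[, "pct_unemployed"] <- log(x[, "pct_unemployed"] + 1)
    x[, "pct_overcrowded"] <- log(x[, "pct_overcrowded"] + 1)
  }
  n <- nrow(x)
  mu <- colMeans(x)
  sd_pop <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sd_pop == 0))
    stop("degenerate variance: component constant across units (",
         paste(comp[sd_pop == 0], collapse = ", "), ")", call. = FALSE)
  z <- sweep(sweep(x, 2, mu), 2, sd_pop, "/")
  data.frame(unit_id = as.character(census$unit_id),
             score = rowSums(z),
             quintile = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Assign deprivation quintiles
#'
#' Rank-based classification into quintiles Q1 (least deprived) .. Q5 (most
#' deprived): units are sorted by score ascending (ties broken by `unit_id`),
#' then split into 5 contiguous groups whose sizes differ by at most one,
#' with any remainder allocated to the lowest quintiles.
#'
#' @param scores data frame from [townsend_score()] (columns `unit_id`,
#'   `score`); at least 5 units.
#' @return The input with the `quintile` column filled (integer 1..5), rows
#'   in the original order.
#' @export
assign_quintiles <- function(scores) {
  n <- nrow(scores)
  if (n < 5) stop("at least 5 units are required for quintiles", call. = FALSE)
  sizes <- rep(n %/% 5L, 5L)
  rem <- n %% 5L
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ord <- order(scores$score, scores$unit_id)
  q <- rep.int(1:5, times = sizes)
  scores$quintile[ord] <- q
  scores
}

#' Quintile dummy covariates
#'
#' Indicator columns for quintiles 2..5, the first quintile being the
#' reference level (all-zero row), for use as the covariate matrix of the
#' ecological regression.
#'
#' @param scores data frame with `quintile` assigned
#'   (see [assign_quintiles()]).
#' @return Numeric matrix `n x 4` with columns `Q2`..`Q5`; row names are unit
#'   ids.
#' @export
quintile_dummies <- function(scores) {
  if (any(is.na(scores$quintile)))
    stop("quintiles not assigned; call assign_quintiles() first",
         call. = FALSE)
  x <- vapply(2:5, function(q) as.numeric(scores$quintile == q),
              numeric(nrow(scores)))
  dimnames(x) <- list(scores$unit_id, paste0("Q", 2:5))
  x
}
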
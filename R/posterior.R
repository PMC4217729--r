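#' Summaries of kept MCMC draws
#'
#' Computes, for each unit, the smoothed SIR (posterior mean of `theta_i`),
#' the posterior median, equal-tailed 95% credible bounds, the exceedance
#' probability `P(theta_i > 1 | data)` and a significance flag (interval
#' excludes 1); for each covariate coefficient, the relative risk
#' `exp(posterior mean of beta_k)` with exponentiated quantile bounds (and
#' the posterior mean of `exp(beta_k)`); and posterior summaries of the two
#' random-effect variances.
#'
#' @param theta matrix of kept draws of `theta_i` (draws x units); at least
#'   100 rows.
#' @param beta optional matrix of kept coefficient draws (draws x k).
#' @param tau_u,tau_v optional vectors of kept precision draws.
#' @param unit_ids optional unit identifiers.
#' @param beta_names optional coefficient names.
#' @param level credible level, default 0.95.
#' @return List with data frames `units`, `coefficients` (NULL without
#'   covariates) and `hyper`.
#' @export
posterior_summaries <- function(theta, beta = NULL, tau_u = NULL,
                                tau_v = NULL, unit_ids = NULL,
                                beta_names = NULL, level = 0.95) {
  theta <- as.matrix(theta)
  if (nrow(theta) < 100)
    stop("at least 100 kept draws are required", call. = FALSE)
  a <- (1 - level) / 2
  qs <- apply(theta, 2, stats::quantile, probs = c(a, 0.5, 1 - a),
              names = FALSE)
  if (is.null(unit_ids)) unit_ids <- as.character(seq_len(ncol(theta)))
  units <- data.frame(
    unit_id = unit_ids,
    smoothed_sir = colMeans(theta),
    median = qs[2, ],
    ci_low = qs[1, ],
    ci_high = qs[3, ],
    exceed_prob = colMeans(theta > 1),
    stringsAsFactors = FALSE)
  units$significant <- units$ci_low > 1 | units$ci_high < 1
  coefficients <- NULL
  if (!is.null(beta)) {
    beta <- as.matrix(beta)
    bq <- apply(beta, 2, stats::quantile, probs = c(a, 0.5, 1 - a),
                names = FALSE)
    if (is.null(beta_names)) beta_names <- paste0("x", seq_len(ncol(beta)))
    coefficients <- data.frame(
      term = beta_names,
      beta_mean = colMeans(beta),
      beta_low = bq[1, ], beta_high = bq[3, ],
      rr = exp(colMeans(beta)),
      rr_low = exp(bq[1, ]), rr_high = exp(bq[3, ]),
      rr_mean_exp = colMeans(exp(beta)),
      stringsAsFactors = FALSE)
    coefficients$significant <-
      coefficients$rr_low > 1 | coefficients$rr_high < 1
  }
  hyper <- NULL
  summ_var <- function(tau, nm) {
    s2 <- 1 / tau
    data.frame(parameter = nm, mean = mean(s2), median = stats::median(s2),
               ci_low = unname(stats::quantile(s2, a)),
               ci_high = unname(stats::quantile(s2, 1 - a)),
               stringsAsFactors = FALSE)
  }
  if (!is.null(tau_u)) hyper <- summ_var(tau_u, "sigma_u2")
  if (!is.null(tau_v)) hyper <- rbind(hyper, summ_var(tau_v, "sigma_v2"))
  list(units = units, coefficients = coefficients, hyper = hyper)
}

ess_one <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  # Geyer initial positive sequence on paired sums
  npair <- length(rho) %/% 2
  s <- 0
  for (m in seq_len(npair)) {
    pair <- rho[2 * m - 1] + rho[2 * m]
    if (pair < 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

#' MCMC convergence diagnostics
#'
#' Effective sample size per parameter from the initial-positive-sequence
#' autocorrelation estimator, and a Geweke z-score comparing the mean of the
#' first 10% of the chain with the mean of the last 50% (standard errors
#' computed from segment-wise effective sample sizes).
#'
#' @param chains numeric matrix of kept draws (draws x parameters), at least
#'   200 rows; a vector is treated as one parameter.
#' @return Data frame with `parameter`, `ess`, `geweke_z`.
#' @export
convergence_diagnostics <- function(chains) {
  chains <- as.matrix(chains)
  n <- nrow(chains)
  if (n < 200)
    stop("at least 200 kept draws are required for diagnostics",
         call. = FALSE)
  nms <- colnames(chains)
  if (is.null(nms)) nms <- paste0("par", seq_len(ncol(chains)))
  out <- lapply(seq_len(ncol(chains)), function(j) {
    x <- chains[, j]
    ess <- ess_one(x)
    a <- x[seq_len(max(2, floor(0.1 * n)))]
    b <- x[seq.int(floor(0.5 * n) + 1L, n)]
    se2 <- stats::var(a) / ess_one(a) + stats::var(b) / ess_one(b)
    z <- if (se2 > 0) (mean(a) - mean(b)) / sqrt(se2) else 0
    data.frame(parameter = nms[j], ess = ess, geweke_z = z,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
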
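#' Assemble data for the BYM model
#'
#' Bundles per-unit observed counts, fixed expected counts, an optional
#' area-level covariate matrix and the adjacency graph, validating that the
#' pieces refer to the same units.
#'
#' @param observed per-unit observed counts `O_i`.
#' @param expected per-unit expected counts `E_i`, all positive (they enter
#'   the Poisson mean `E_i * theta_i` as fixed constants).
#' @param adjacency an [adjacency()] object covering exactly these units, in
#'   the same order.
#' @param covariates optional numeric matrix `n x k` of area covariates
#'   (e.g. deprivation quintile dummies from [quintile_dummies()]).
#' @return An object of class `model_data`.
#' @export
model_data <- function(observed, expected, adjacency, covariates = NULL) {
  stopifnot(inherits(adjacency, "adjacency"))
  n <- length(adjacency$unit_ids)
  if (length(observed) != n || length(expected) != n)
    stop("observed/expected length must match the adjacency unit count",
         call. = FALSE)
  if (any(expected <= 0))
    stop("all expected counts must be positive", call. = FALSE)
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed counts must be non-negative integers", call. = FALSE)
  if (!is.null(names(observed)) &&
      !identical(unname(names(observed)), unname(adjacency$unit_ids)) &&
      !setequal(names(observed), adjacency$unit_ids))
    stop("observed names do not match adjacency unit ids", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariate matrix must have one row per unit", call. = FALSE)
    if (any(!is.finite(covariates)))
      stop("covariates must be finite", call. = FALSE)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  }
  structure(
    list(observed = as.numeric(observed),
         expected = as.numeric(expected),
         covariates = covariates,
         adjacency = adjacency),
    class = "model_data")
}

#' MCMC configuration for the BYM sampler
#'
#' @param n_iter kept iterations after burn-in (default 25000).
#' @param n_burnin discarded warm-up iterations (default 5000), during which
#'   proposal scales adapt if `adapt = TRUE`.
#' @param hyper_shape,hyper_rate gamma hyperprior parameters shared by the
#'   two random-effect precisions (default `Gamma(0.5, 0.0005)`, a weakly
#'   informative choice in the Bernardinelli tradition).
#' @param alpha_prior_sd,beta_prior_sd standard deviations of the vague
#'   normal priors on the intercept and covariate coefficients
#'   (default 1000).
#' @param seed RNG seed (`set.seed()` is called when non-NULL); a fixed seed
#'   makes the fit bit-reproducible.
#' @param adapt adapt random-walk proposal scales during burn-in (frozen
#'   afterwards, preserving detailed balance for the kept draws).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param spatial include the CAR component `v` (default TRUE); with FALSE
#'   the model is heterogeneity-only.
#' @param fix_tau optional list `list(tau_u =, tau_v =)` fixing the
#'   precisions (no hyperprior layer); used by oracle comparisons.
#' @param allow_islands give zero-neighbour units `v_i = 0` (heterogeneity
#'   only) instead of raising an error.
#' @param engine `"cpp"` (compiled sampler, default) or `"R"` (pure-R
#'   reference sweeps; identical model, slower).
#' @param keep_chains retain raw kept draws in the fit object.
#' @return An object of class `bym_config`.
#' @export
bym_config <- function(n_iter = 25000, n_burnin = 5000,
                       hyper_shape = 0.5, hyper_rate = 0.0005,
                       alpha_prior_sd = 1000, beta_prior_sd = 1000,
                       seed = NULL, adapt = TRUE, thin = 1,
                       spatial = TRUE, fix_tau = NULL,
                       allow_islands = FALSE,
                       engine = c("cpp", "R"), keep_chains = TRUE) {
  engine <- match.arg(engine)
  if (n_iter <= 0 || n_burnin < 0 || thin < 1)
    stop("n_iter > 0, n_burnin >= 0 and thin >= 1 required", call. = FALSE)
  if (hyper_shape <= 0 || hyper_rate <= 0)
    stop("gamma hyperprior parameters must be positive", call. = FALSE)
  if (!is.null(fix_tau)) {
    if (!all(c("tau_u", "tau_v") %in% names(fix_tau)) ||
        fix_tau$tau_u <= 0 || fix_tau$tau_v <= 0)
      stop("fix_tau must supply positive tau_u and tau_v", call. = FALSE)
  }
  structure(
    list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
         hyper_shape = hyper_shape, hyper_rate = hyper_rate,
         alpha_prior_sd = alpha_prior_sd, beta_prior_sd = beta_prior_sd,
         seed = seed, adapt = isTRUE(adapt), thin = as.integer(thin),
         spatial = isTRUE(spatial), fix_tau = fix_tau,
         allow_islands = isTRUE(allow_islands),
         engine = engine, keep_chains = isTRUE(keep_chains)),
    class = "bym_config")
}

new_mcmc_state <- function(data, config) {
  n <- length(data$observed)
  k <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  list(alpha = log((sum(data$observed) + 0.5) / sum(data$expected)),
       u = rep(0, n),
       v = rep(0, n),
       beta = rep(0, k),
       tau_u = if (is.null(config$fix_tau)) 10 else config$fix_tau$tau_u,
       tau_v = if (is.null(config$fix_tau)) 10 else config$fix_tau$tau_v)
}

edge_list <- function(adj) {
  n <- length(adj$unit_ids)
  ei <- integer(0); ej <- integer(0)
  for (i in seq_len(n)) {
    js <- adj$neighbors[[i]]
    js <- js[js > i]
    ei <- c(ei, rep.int(i, length(js)))
    ej <- c(ej, js)
  }
  cbind(i = ei, j = ej)
}

linear_predictor <- function(state, data) {
  eta <- state$alpha + state$u + state$v
  if (!is.null(data$covariates) && length(state$beta))
    eta <- eta + drop(data$covariates %*% state$beta)
  eta
}

#' Unnormalized log posterior of the BYM model
#'
#' Sum of the Poisson log-likelihood
#' `sum_i O_i (log E_i + eta_i) - E_i exp(eta_i)` with
#' `eta_i = alpha + u_i + v_i + x_i' beta`, the normal log-density of the
#' heterogeneity effects `u`, the intrinsic-CAR pairwise-difference form
#' `-(tau_v/2) sum_{i~j} (v_i - v_j)^2` (with the rank-adjusted
#' `((n - n_components)/2) log tau_v` normalizer), gamma log-priors on the
#' precisions, and vague normal log-priors on `alpha` and `beta`. Constant
#' terms not involving parameters are dropped consistently.
#'
#' @param state list with `alpha`, `u`, `v`, `beta`, `tau_u`, `tau_v`.
#' @param data a [model_data()] object.
#' @param config a [bym_config()] object.
#' @return Scalar log-density (unnormalized).
#' @export
log_posterior <- function(state, data, config) {
  n <- length(data$observed)
  if (length(state$u) != n || length(state$v) != n)
    stop("state dimensions do not match data", call. = FALSE)
  k <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  if (length(state$beta) != k)
    stop("beta length does not match covariate count", call. = FALSE)
  eta <- linear_predictor(state, data)
  lp <- sum(data$observed * (log(data$expected) + eta) -
              data$expected * exp(eta))
  # u ~ N(0, 1/tau_u)
  lp <- lp + n / 2 * log(state$tau_u) - state$tau_u / 2 * sum(state$u^2)
  if (config$spatial) {
    rep_adj <- validate_adjacency(data$adjacency)
    ed <- edge_list(data$adjacency)
    pair_ss <- if (nrow(ed)) sum((state$v[ed[, 1]] - state$v[ed[, 2]])^2) else 0
    rank_v <- n - rep_adj$n_components
    lp <- lp + rank_v / 2 * log(state$tau_v) - state$tau_v / 2 * pair_ss
  }
  if (is.null(config$fix_tau)) {
    lp <- lp + (config$hyper_shape - 1) * log(state$tau_u) -
      config$hyper_rate * state$tau_u
    if (config$spatial)
      lp <- lp + (config$hyper_shape - 1) * log(state$tau_v) -
        config$hyper_rate * state$tau_v
  }
  lp <- lp - state$alpha^2 / (2 * config$alpha_prior_sd^2)
  if (k) lp <- lp - sum(state$beta^2) / (2 * config$beta_prior_sd^2)
  if (!is.finite(lp)) stop("non-finite log posterior", call. = FALSE)
  lp
}

#' CAR full conditional of one spatial effect
#'
#' Under the intrinsic CAR prior, `v_i | v_{-i}` is normal with mean the
#' average of the neighbouring effects and variance `1 / (tau_v * n_i)`.
#'
#' @param v numeric vector of spatial effects.
#' @param adj an [adjacency()] object.
#' @param i unit index.
#' @param tau_v CAR precision.
#' @return List with `mean` and `variance`.
#' @export
car_full_conditional <- function(v, adj, i, tau_v) {
  nb <- adj$neighbors[[i]]
  ni <- length(nb)
  if (ni == 0)
    stop("unit ", adj$unit_ids[i],
         " has no neighbors: CAR conditional undefined", call. = FALSE)
  list(mean = mean(v[nb]), variance = 1 / (tau_v * ni))
}

#' Gibbs draw of the random-effect precisions
#'
#' Conjugate updates: `tau_u ~ Gamma(shape + n/2, rate + sum(u^2)/2)` and
#' `tau_v ~ Gamma(shape + (n - n_components)/2, rate + pairsum/2)` where
#' `pairsum = sum_{i~j} (v_i - v_j)^2` over unordered adjacent pairs and the
#' shape reflects the intrinsic-CAR rank deficiency (one per connected
#' component).
#'
#' @inheritParams log_posterior
#' @return The state with fresh `tau_u` (and `tau_v` if spatial).
#' @export
gibbs_update_precisions <- function(state, data, config) {
  if (!is.null(config$fix_tau)) return(state)
  n <- length(data$observed)
  state$tau_u <- stats::rgamma(1, shape = config$hyper_shape + n / 2,
                               rate = config$hyper_rate + sum(state$u^2) / 2)
  if (config$spatial) {
    rep_adj <- validate_adjacency(data$adjacency)
    ed <- edge_list(data$adjacency)
    pair_ss <- if (nrow(ed)) sum((state$v[ed[, 1]] - state$v[ed[, 2]])^2) else 0
    state$tau_v <- stats::rgamma(
      1, shape = config$hyper_shape + (n - rep_adj$n_components) / 2,
      rate = config$hyper_rate + pair_ss / 2)
  }
  state
}

#' One Metropolis sweep over all location parameters (reference engine)
#'
#' Univariate random-walk Metropolis updates for `alpha`, each `beta_k`,
#' each `u_i` and each `v_i` against the joint posterior; after the full `v`
#' sweep, `v` is recentred to sum to zero with the removed mean absorbed
#' into `alpha` (the intrinsic-CAR identifiability constraint, which leaves
#' the likelihood unchanged).
#'
#' @inheritParams log_posterior
#' @param scales list of proposal standard deviations: `alpha` (scalar),
#'   `beta` (vector), `u` (vector), `v` (vector).
#' @return List with the updated `state` and 0/1 acceptance indicators per
#'   block (`accept`).
#' @export
metropolis_update_effects <- function(state, data, config, scales) {
  O <- data$observed; E <- data$expected
  X <- data$covariates
  k <- length(state$beta)
  acc <- list(alpha = 0, beta = numeric(k),
              u = numeric(length(O)), v = numeric(length(O)))
  eta <- linear_predictor(state, data)

  # alpha: likelihood over all units + vague normal prior
  prop <- state$alpha + stats::rnorm(1, 0, scales$alpha)
  d <- prop - state$alpha
  lr <- sum(O * d - E * (exp(eta + d) - exp(eta))) -
    (prop^2 - state$alpha^2) / (2 * config$alpha_prior_sd^2)
  if (log(stats::runif(1)) < lr) {
    state$alpha <- prop; eta <- eta + d; acc$alpha <- 1
  }

  if (k) for (j in seq_len(k)) {
    xj <- X[, j]
    act <- which(xj != 0)
    prop <- state$beta[j] + stats::rnorm(1, 0, scales$beta[j])
    d <- (prop - state$beta[j]) * xj[act]
    lr <- sum(O[act] * d - E[act] * (exp(eta[act] + d) - exp(eta[act]))) -
      (prop^2 - state$beta[j]^2) / (2 * config$beta_prior_sd^2)
    if (log(stats::runif(1)) < lr) {
      eta[act] <- eta[act] + d
      state$beta[j] <- prop; acc$beta[j] <- 1
    }
  }

  for (i in seq_along(O)) {
    prop <- state$u[i] + stats::rnorm(1, 0, scales$u[i])
    d <- prop - state$u[i]
    lr <- O[i] * d - E[i] * (exp(eta[i] + d) - exp(eta[i])) -
      state$tau_u / 2 * (prop^2 - state$u[i]^2)
    if (log(stats::runif(1)) < lr) {
      state$u[i] <- prop; eta[i] <- eta[i] + d; acc$u[i] <- 1
    }
  }

  if (config$spatial) {
    free <- which(data$adjacency$n_neighbors > 0)
    for (i in free) {
      fc <- car_full_conditional(state$v, data$adjacency, i, state$tau_v)
      prop <- state$v[i] + stats::rnorm(1, 0, scales$v[i])
      d <- prop - state$v[i]
      lr <- O[i] * d - E[i] * (exp(eta[i] + d) - exp(eta[i])) -
        ((prop - fc$mean)^2 - (state$v[i] - fc$mean)^2) / (2 * fc$variance)
      if (log(stats::runif(1)) < lr) {
        state$v[i] <- prop; eta[i] <- eta[i] + d; acc$v[i] <- 1
      }
    }
    m <- mean(state$v[free])
    state$v[free] <- state$v[free] - m
    state$alpha <- state$alpha + m
  }
  list(state = state, accept = acc)
}

fit_bym_R <- function(data, config) {
  n <- length(data$observed)
  k <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
  state <- new_mcmc_state(data, config)
  scales <- list(alpha = 0.1, beta = rep(0.1, k),
                 u = rep(0.3, n), v = rep(0.3, n))
  n_total <- config$n_burnin + config$n_iter
  n_kept <- config$n_iter %/% config$thin
  theta <- matrix(NA_real_, n_kept, n)
  alpha_c <- numeric(n_kept)
  beta_c <- matrix(NA_real_, n_kept, max(k, 1))
  tau_u_c <- numeric(n_kept); tau_v_c <- numeric(n_kept)
  acc_tot <- list(alpha = 0, beta = numeric(k), u = numeric(n), v = numeric(n))
  win <- list(alpha = 0, beta = numeric(k), u = numeric(n), v = numeric(n))
  win_len <- 50L
  kept <- 0L
  for (it in seq_len(n_total)) {
    res <- metropolis_update_effects(state, data, config, scales)
    state <- res$state
    state <- gibbs_update_precisions(state, data, config)
    for (nm in names(win)) win[[nm]] <- win[[nm]] + res$accept[[nm]]
    if (config$adapt && it <= config$n_burnin && it %% win_len == 0L) {
      tune <- function(sc, a) sc * exp(a / win_len - 0.44)
      scales$alpha <- tune(scales$alpha, win$alpha)
      if (k) scales$beta <- tune(scales$beta, win$beta)
      scales$u <- tune(scales$u, win$u)
      scales$v <- tune(scales$v, win$v)
      win <- list(alpha = 0, beta = numeric(k),
                  u = numeric(n), v = numeric(n))
    }
    if (it > config$n_burnin) {
      for (nm in names(acc_tot)) acc_tot[[nm]] <- acc_tot[[nm]] + res$accept[[nm]]
      if ((it - config$n_burnin) %% config$thin == 0L) {
        kept <- kept + 1L
        theta[kept, ] <- exp(linear_predictor(state, data))
        alpha_c[kept] <- state$alpha
        if (k) beta_c[kept, seq_len(k)] <- state$beta
        tau_u_c[kept] <- state$tau_u
        tau_v_c[kept] <- state$tau_v
      }
    }
  }
  list(theta = theta[seq_len(kept), , drop = FALSE],
       alpha = alpha_c[seq_len(kept)],
       beta = if (k) beta_c[seq_len(kept), seq_len(k), drop = FALSE] else NULL,
       tau_u = tau_u_c[seq_len(kept)],
       tau_v = tau_v_c[seq_len(kept)],
       accept = lapply(acc_tot, function(a) a / config$n_iter),
       scales = scales)
}

#' Fit the BYM model by Metropolis-within-Gibbs MCMC
#'
#' Area relative risks follow a Poisson log-linear model
#' `O_i ~ Poisson(E_i * theta_i)`,
#' `log theta_i = alpha + u_i + v_i + x_i' beta`, with i.i.d. normal
#' heterogeneity `u`, an intrinsic CAR spatial effect `v` constrained to sum
#' to zero, gamma hyperpriors on the two precisions, and vague normal priors
#' on `alpha` and `beta`. Each sweep performs univariate random-walk
#' Metropolis updates of all location parameters followed by conjugate Gibbs
#' draws of the precisions; proposal scales adapt during burn-in only.
#'
#' @param data a [model_data()] object.
#' @param config a [bym_config()] object.
#' @return An object of class `bym_fit` with components `summary` (per-unit
#'   smoothed SIRs, 95% credible intervals, exceedance probabilities and
#'   significance flags), `coefficients` (per-covariate relative risks with
#'   exponentiated quantile intervals), `hyper` (posterior summaries of the
#'   random-effect variances), `diagnostics` (acceptance rates, effective
#'   sample sizes, Geweke z-scores), and, when `keep_chains`, `chains`.
#' @export
fit_bym <- function(data, config = bym_config()) {
  stopifnot(inherits(data, "model_data"), inherits(config, "bym_config"))
  rep_adj <- validate_adjacency(data$adjacency)
  if (config$spatial && rep_adj$n_islands > 0 && !config$allow_islands)
    stop("adjacency has islands (", paste(rep_adj$islands, collapse = ", "),
         "); set allow_islands = TRUE for heterogeneity-only risk there",
         call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  chains <- if (config$engine == "cpp") {
    k <- if (is.null(data$covariates)) 0L else ncol(data$covariates)
    X <- if (k) data$covariates else matrix(0, length(data$observed), 0)
    nb0 <- lapply(data$adjacency$neighbors, function(x) as.integer(x - 1L))
    out <- bym_mcmc_cpp(
      data$observed, data$expected, X, nb0,
      as.integer(rep_adj$n_components),
      config$n_iter, config$n_burnin, config$thin,
      config$hyper_shape, config$hyper_rate,
      config$alpha_prior_sd, config$beta_prior_sd,
      config$adapt, config$spatial,
      !is.null(config$fix_tau),
      if (is.null(config$fix_tau)) 0 else config$fix_tau$tau_u,
      if (is.null(config$fix_tau)) 0 else config$fix_tau$tau_v)
    if (k == 0L) out$beta <- NULL
    out
  } else {
    fit_bym_R(data, config)
  }
  summ <- posterior_summaries(
    theta = chains$theta, beta = chains$beta,
    tau_u = chains$tau_u, tau_v = chains$tau_v,
    unit_ids = data$adjacency$unit_ids,
    beta_names = if (!is.null(data$covariates)) colnames(data$covariates))
  diag_pars <- cbind(alpha = chains$alpha,
                     if (!is.null(chains$beta)) chains$beta,
                     tau_u = chains$tau_u,
                     if (config$spatial) cbind(tau_v = chains$tau_v))
  diagnostics <- convergence_diagnostics(diag_pars)
  structure(
    list(summary = summ$units,
         coefficients = summ$coefficients,
         hyper = summ$hyper,
         diagnostics = list(parameters = diagnostics,
                            accept = chains$accept),
         chains = if (config$keep_chains) chains,
         config = config,
         n_kept = length(chains$alpha),
         n_units = length(data$observed)),
    class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("BYM fit:", x$n_units, "units,", x$n_kept, "kept draws\n")
  cat("Smoothed SIR range:",
      sprintf("%.2f-%.2f", min(x$summary$smoothed_sir),
              max(x$summary$smoothed_sir)), "\n")
  if (!is.null(x$coefficients)) {
    cat("Covariate relative risks:\n")
    print(x$coefficients[, c("term", "rr", "rr_low", "rr_high")],
          row.names = FALSE, digits = 3)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
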
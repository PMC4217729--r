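#' Brute-force posterior means by grid quadrature (test oracle)
#'
#' For instances with at most 3 units and fixed precisions (no hyperprior
#' layer), computes the posterior mean of each `theta_i = exp(alpha + u_i +
#' v_i)` by dense numerical integration: the heterogeneity effects `u_i` are
#' integrated out unit-by-unit on a 1-D grid, and the remaining low-
#' dimensional integral over `alpha` and the intrinsic-CAR sum-to-zero
#' subspace (spectral coordinates of the graph Laplacian) is evaluated on a
#' tensor grid. Intended purely as an independent check of the MCMC sampler.
#'
#' @param observed,expected per-unit counts (length <= 3).
#' @param tau_u fixed heterogeneity precision.
#' @param adjacency optional [adjacency()] object; when supplied (with
#'   `tau_v`) the CAR component is included.
#' @param tau_v fixed CAR precision (required with `adjacency`).
#' @param alpha_prior_sd normal prior sd on the intercept.
#' @param n_alpha,n_z,n_c,n_u grid resolutions (outer alpha, outer spectral
#'   coordinates, inner linear-predictor grid, inner `u` grid).
#' @return Numeric vector of posterior means of `theta_i`.
#' @export
quadrature_oracle <- function(observed, expected, tau_u,
                              adjacency = NULL, tau_v = NULL,
                              alpha_prior_sd = 1000,
                              n_alpha = 161, n_z = 81,
                              n_c = 601, n_u = 601) {
  n <- length(observed)
  if (n > 3)
    stop("quadrature oracle refuses more than 3 units (cost)", call. = FALSE)
  if (length(expected) != n || any(expected <= 0))
    stop("expected must be positive and match observed", call. = FALSE)
  spatial <- !is.null(adjacency)
  if (spatial && is.null(tau_v))
    stop("tau_v required with an adjacency", call. = FALSE)

  # spectral basis of the intrinsic CAR on the sum-to-zero subspace
  basis <- NULL; lam <- NULL
  if (spatial && n > 1) {
    W <- matrix(0, n, n)
    for (i in seq_len(n)) W[i, adjacency$neighbors[[i]]] <- 1
    L <- diag(rowSums(W)) - W
    eg <- eigen(L, symmetric = TRUE)
    keep <- eg$values > 1e-9
    if (sum(!keep) > 1)
      stop("disconnected adjacency not supported by the oracle",
           call. = FALSE)
    lam <- eg$values[keep]
    basis <- eg$vectors[, keep, drop = FALSE]
  }
  nz <- if (is.null(basis)) 0L else ncol(basis)

  # outer alpha grid centred on the mode of prior x profile likelihood
  # (u = v = 0), wide enough for the u-level to shift the posterior
  f_a <- function(a) -a^2 / (2 * alpha_prior_sd^2) +
    sum(observed * a - expected * exp(a))
  a0 <- stats::optimize(f_a, c(-40, 40), maximum = TRUE)$maximum
  curv <- 1 / alpha_prior_sd^2 + sum(expected * exp(a0))
  wa <- 8 / sqrt(curv) + 8 / sqrt(n * tau_u) + 0.5
  alpha_g <- seq(a0 - wa, a0 + wa, length.out = n_alpha)
  z_grids <- lapply(seq_len(nz), function(k) {
    sdk <- 1 / sqrt(tau_v * lam[k])
    seq(-6 * sdk, 6 * sdk, length.out = n_z)
  })

  # per-unit inner integral over u on a grid of c = alpha + v_i:
  # g(c) = int lik_i(c + u) N(u; 0, 1/tau_u) du,  r(c) = E[exp(c+u) | ...]
  vmax <- if (nz) sum(vapply(seq_len(nz), function(k)
    max(abs(basis[, k])) * max(abs(z_grids[[k]])), numeric(1))) else 0
  c_lo <- min(alpha_g) - vmax; c_hi <- max(alpha_g) + vmax
  c_grid <- seq(c_lo, c_hi, length.out = n_c)
  sd_u <- 1 / sqrt(tau_u)
  unit_tabs <- lapply(seq_len(n), function(i) {
    ohat <- log((observed[i] + 0.5) / expected[i])
    u_lo <- min(-8 * sd_u, ohat - c_hi - 8 / sqrt(observed[i] + 0.5))
    u_hi <- max(8 * sd_u, ohat - c_lo + 8 / sqrt(observed[i] + 0.5))
    u_g <- seq(u_lo, u_hi, length.out = n_u)
    du <- u_g[2] - u_g[1]
    eta <- outer(c_grid, u_g, "+")                      # n_c x n_u
    loglik <- observed[i] * eta - expected[i] * exp(eta)
    logw <- sweep(loglik, 2, u_g^2 / (2 * sd_u^2))
    mx <- apply(logw, 1, max)
    w <- exp(logw - mx)
    g <- rowSums(w) * du
    m <- rowSums(w * exp(eta)) * du
    list(log_g = log(g) + mx, r = m / g)
  })

  # tensor grid over (alpha, z_1..z_nz)
  grids <- c(list(alpha_g), z_grids)
  pts <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  logw <- -pts[, 1]^2 / (2 * alpha_prior_sd^2)
  if (nz) for (k in seq_len(nz))
    logw <- logw - pts[, k + 1]^2 * tau_v * lam[k] / 2
  r_mat <- matrix(NA_real_, nrow(pts), n)
  for (i in seq_len(n)) {
    ci <- pts[, 1]
    if (nz) for (k in seq_len(nz)) ci <- ci + basis[i, k] * pts[, k + 1]
    logw <- logw + stats::approx(c_grid, unit_tabs[[i]]$log_g, ci)$y
    r_mat[, i] <- stats::approx(c_grid, unit_tabs[[i]]$r, ci)$y
  }
  mx <- max(logw)
  w <- exp(logw - mx)
  colSums(w * r_mat) / sum(w)
}
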
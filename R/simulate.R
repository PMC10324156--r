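#' Simulate cluster-period mean outcomes from the trial model
#'
#' Draws replicate trials from the linear mixed model underlying the
#' design calculations: outcome = overall mean + fixed period effect +
#' treatment effect + cluster(-period) random effect + individual error.
#' Under the exchangeable structure the cluster effect is a single
#' `N(0, tau^2)` draw shared across periods; under discrete-time decay
#' (or block-exchangeable) it is a `T`-variate normal with covariance
#' `tau^2 R`. Individual errors are `N(0, sigma_eps^2)`, averaged over the
#' `m` subjects per observed cell, so the function returns cluster-period
#' means directly. Unobserved cells are `NA`.
#'
#' Intended for Monte-Carlo verification of the analytic design variance
#' and for generating example data; not an analysis tool.
#'
#' @param design An [sw_design()].
#' @param config An [sw_config()] (its `effect_size` is the simulated
#'   treatment effect; 0 when unset).
#' @param n_rep Number of replicate trials.
#' @param mu Overall mean in period 1 (default 0).
#' @param beta Fixed period effects, length `T` with first element 0
#'   (default all zero).
#' @return A 3-d array `n_rep x K x T` of cluster-period means, `NA` in
#'   unobserved cells.
#' @export
sw_simulate <- function(design, config, n_rep, mu = 0, beta = NULL) {
  stopifnot(inherits(design, "sw_design"), inherits(config, "sw_config"))
  K <- design$K; T <- design$T
  if (is.null(beta)) beta <- numeric(T)
  if (length(beta) != T || beta[1L] != 0)
    stop("`beta` must have length T with first element 0", call. = FALSE)
  theta <- if (is.na(config$effect_size)) 0 else config$effect_size
  R <- sw_corr_matrix(T, config$r, config$structure)
  L <- t(chol(config$tau2 * R + 1e-14 * diag(T)))  # jitter for the rank-1 exchangeable R
  sd_mean <- sqrt(config$sigma2_eps / config$m)

  fixed <- matrix(rep(mu + beta, each = K), K, T) + theta * design$X
  out <- array(NA_real_, c(n_rep, K, T))
  for (rep in seq_len(n_rep)) {
    gamma <- t(L %*% matrix(stats::rnorm(T * K), T, K))   # K x T cluster effects
    eps <- matrix(stats::rnorm(K * T, sd = sd_mean), K, T)
    y <- fixed + gamma + eps
    y[!design$observed] <- NA_real_
    out[rep, , ] <- y
  }
  out
}

#' GLS fit of the treatment effect from cluster-period means
#'
#' Stacks the observed cluster-period means of one replicate and solves
#' the generalised least squares normal equations for the model with one
#' fixed mean per period and a single treatment effect, using the known
#' covariance of cluster-period means. This is an independent estimation
#' route (a stacked design-matrix solve rather than the per-cluster
#' Schur-complement form) used to verify the analytic variance by
#' simulation.
#'
#' @param y `K x T` matrix of cluster-period means with `NA` in
#'   unobserved cells.
#' @param design The [sw_design()] that generated `y`.
#' @param config An [sw_config()].
#' @return Named list: `theta` (point estimate) and `se` (model-based
#'   standard error).
#' @export
sw_gls_fit <- function(y, design, config) {
  K <- design$K; T <- design$T
  V <- sw_cov_matrix(config)
  op <- which(colSums(design$observed) > 0L)
  # design matrix: one column per observed-anywhere period, plus treatment
  WtW <- matrix(0, length(op) + 1L, length(op) + 1L)
  Wty <- numeric(length(op) + 1L)
  for (k in seq_len(K)) {
    p <- which(design$observed[k, ])
    if (length(p) == 0L) next
    yk <- y[k, p]
    W <- cbind(outer(p, op, `==`) * 1, design$X[k, p])
    Vi_W <- solve(V[p, p, drop = FALSE], W)
    WtW <- WtW + crossprod(W, Vi_W)
    Wty <- Wty + crossprod(Vi_W, yk)
  }
  coef <- solve(WtW, Wty)
  cov_last <- solve(WtW)[length(coef), length(coef)]
  list(theta = coef[length(coef)], se = sqrt(cov_last))
}
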
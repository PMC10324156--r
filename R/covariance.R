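#' Within-cluster correlation matrix of cluster-period random effects
#'
#' Builds the `T x T` correlation matrix `R` of the cluster-period random
#' effects. Under the discrete-time decay structure the `(j, s)` element is
#' `r^|j - s|`; the exchangeable structure (r = 1) gives a matrix of ones;
#' the block-exchangeable structure has a unit diagonal with all
#' off-diagonal elements equal to `r`.
#'
#' @param T Number of periods.
#' @param r Cluster autocorrelation, in `(0, 1]`.
#' @param structure One of `"exchangeable"`, `"block_exchangeable"`,
#'   `"discrete_time_decay"`.
#' @return A symmetric `T x T` matrix with unit diagonal.
#' @export
sw_corr_matrix <- function(T, r = 1,
                           structure = c("exchangeable", "block_exchangeable",
                                         "discrete_time_decay")) {
  structure <- match.arg(structure)
  if (r <= 0 || r > 1) stop("`r` must lie in (0, 1]", call. = FALSE)
  T <- as.integer(T)
  switch(structure,
    exchangeable = matrix(1, T, T),
    block_exchangeable = { R <- matrix(r, T, T); diag(R) <- 1; R },
    discrete_time_decay = outer(seq_len(T), seq_len(T),
                                function(j, s) r^abs(j - s))
  )
}

#' Covariance matrix of a cluster's period means
#'
#' For `m` subjects per cluster-period, the vector of cluster-period mean
#' outcomes has covariance `V = (sigma_eps^2 / m) I + tau^2 R`, common to
#' all clusters of a complete design. Under the standardised-outcome
#' convention used throughout the package, `tau^2 = rho` and
#' `sigma_eps^2 = 1 - rho`.
#'
#' @param config An [sw_config()], or a list with elements `tau2`,
#'   `sigma2_eps`, `r`, `structure`, `m` and `T` (the latter two may be
#'   supplied separately).
#' @param m,T Optional overrides for the cluster-period size and period
#'   count in `config`.
#' @return A symmetric positive-definite `T x T` matrix.
#' @examples
#' cfg <- sw_config(5, m = 90, rho = 0.14, structure = "exchangeable")
#' V <- sw_cov_matrix(cfg)
#' V[1, 1]  # 0.14 + 0.86 / 90
#' @export
sw_cov_matrix <- function(config, m = config$m, T = config$T) {
  R <- sw_corr_matrix(T, config$r, config$structure)
  V <- (config$sigma2_eps / m) * diag(T) + config$tau2 * R
  # eigenvalues are bounded below by sigma2_eps/m > 0, so V is PD
  V
}

#' Restrict a covariance matrix to a cluster's observed periods
#'
#' `sw_selector()` builds the `T_k x T` selection matrix `Z_k`: an identity
#' matrix with the rows of unobserved periods deleted.
#' `sw_restrict_cov()` extracts the `T_k x T_k` covariance block
#' `V_k = Z_k V Z_k'` of the observed periods.
#'
#' @param observed_periods Strictly increasing 1-based period indices in
#'   which the cluster is measured; must be nonempty (a cluster observing
#'   no periods is simply excluded from all sums by the caller).
#' @param T Total number of periods.
#' @param V A `T x T` covariance matrix.
#' @return `sw_selector()`: a `T_k x T` 0/1 matrix with one 1 per row;
#'   `sw_restrict_cov()`: the `T_k x T_k` submatrix of `V`.
#' @rdname restrict
#' @export
sw_selector <- function(observed_periods, T) {
  p <- as.integer(observed_periods)
  if (length(p) == 0L || any(diff(p) <= 0L) || p[1L] < 1L || p[length(p)] > T)
    stop("`observed_periods` must be nonempty, strictly increasing, within 1..T",
         call. = FALSE)
  diag(T)[p, , drop = FALSE]
}

#' @rdname restrict
#' @export
sw_restrict_cov <- function(V, observed_periods) {
  p <- as.integer(observed_periods)
  if (length(p) == 0L || any(diff(p) <= 0L) || p[1L] < 1L || p[length(p)] > nrow(V))
    stop("`observed_periods` must be nonempty, strictly increasing, within 1..T",
         call. = FALSE)
  V[p, p, drop = FALSE]
}
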
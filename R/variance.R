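#' Variance of the GLS treatment effect estimator
#'
#' Computes `var(theta-hat)` for a stepped wedge design under a known
#' correlation structure, as used at the design stage for power and sample
#' size calculations. The model has a fixed categorical effect for each
#' period and a single treatment effect; cluster-period means are the
#' working observations, with within-cluster covariance given by
#' [sw_cov_matrix()].
#'
#' For a design in which some cluster-period cells are unobserved, each
#' cluster `k` contributes only its observed periods: with `Z_k` the
#' period-selection matrix, `V_k` the covariance block of the observed
#' periods and `X_k` the treatment indicators over those periods,
#'
#' \deqn{var(\hat\theta) = \{ \sum_k X_k' V_k^{-1} X_k -
#'   (\sum_k Z_k' V_k^{-1} X_k)' (\sum_k Z_k' V_k^{-1} Z_k)^{-1}
#'   (\sum_k Z_k' V_k^{-1} X_k) \}^{-1}.}
#'
#' Periods observed by no cluster carry no period-effect parameter and are
#' dropped from the middle inverse. The treatment effect is estimable only
#' if the remaining period-effect information matrix is nonsingular and the
#' bracketed scalar is positive; a necessary design condition is that at
#' least one period contains both an observed control cell and an observed
#' intervention cell. Non-estimability is reported as a value
#' (`estimable = FALSE`, infinite variance), not an error, because the
#' removal algorithm probes many non-estimable candidate designs.
#'
#' @param design An [sw_design()] with a centrosymmetric mask and at least
#'   one observed cell.
#' @param config An [sw_config()] supplying the covariance model.
#' @return An object of class `sw_variance`: list with `variance` (Inf when
#'   not estimable), `information` (`1/variance`, 0 when not estimable) and
#'   `estimable` (logical).
#' @seealso [sw_vartheta_complete()] for the closed form restricted to
#'   complete designs.
#' @export
sw_vartheta <- function(design, config) {
  stopifnot(inherits(design, "sw_design"))
  if (design$T != config$T)
    stop("design and config disagree on the number of periods", call. = FALSE)
  V <- sw_cov_matrix(config)
  sw_vartheta_V(design, V)
}

# Workhorse: general (incomplete-design) variance given the common T x T
# covariance matrix V of cluster-period means. Accumulates
#   A = sum_k X_k' V_k^-1 X_k            (scalar)
#   B = sum_k Z_k' V_k^-1 X_k            (T-vector)
#   C = sum_k Z_k' V_k^-1 Z_k            (T x T)
# then inverts the Schur complement A - B' C^-1 B on the periods that are
# observed at least once.
sw_vartheta_V <- function(design, V) {
  K <- design$K; T <- design$T
  A <- 0
  B <- numeric(T)
  C <- matrix(0, T, T)
  for (k in seq_len(K)) {
    p <- which(design$observed[k, ])
    if (length(p) == 0L) next
    Vk <- V[p, p, drop = FALSE]
    Xk <- as.numeric(design$X[k, p])
    Vk_inv <- chol2inv(chol(Vk))
    ViX <- Vk_inv %*% Xk
    A <- A + sum(Xk * ViX)
    B[p] <- B[p] + ViX
    C[p, p] <- C[p, p] + Vk_inv
  }
  op <- which(colSums(design$observed) > 0L)
  if (length(op) == 0L) return(new_sw_variance(Inf, FALSE))
  Co <- C[op, op, drop = FALSE]
  Bo <- B[op]
  # near-singular period-effect information => treatment effect not estimable
  if (rcond(Co) < 1e-12) return(new_sw_variance(Inf, FALSE))
  den <- A - sum(Bo * solve(Co, Bo))
  if (!is.finite(den) || den <= 1e-12 * max(A, 1))
    return(new_sw_variance(Inf, FALSE))
  new_sw_variance(1 / den, TRUE)
}

new_sw_variance <- function(variance, estimable) {
  structure(list(variance = variance,
                 information = if (estimable) 1 / variance else 0,
                 estimable = estimable),
            class = "sw_variance")
}

#' Treatment effect variance for a complete design
#'
#' Closed form for a complete design, in which every cluster shares the
#' same covariance matrix `V` of its period means:
#' \deqn{var(\hat\theta) = \{ \sum_k X_k' V^{-1} X_k -
#'   (1/K)\, (\sum_k X_k)' V^{-1} (\sum_k X_k) \}^{-1}.}
#' The general expression in [sw_vartheta()] reduces to this when all cells
#' are observed.
#'
#' @param design A complete [sw_design()] (every cell observed).
#' @param V The `T x T` covariance matrix of cluster-period means, e.g.
#'   from [sw_cov_matrix()].
#' @return An `sw_variance` object.
#' @export
sw_vartheta_complete <- function(design, V) {
  stopifnot(inherits(design, "sw_design"))
  if (!all(design$observed))
    stop("`design` must be complete; use sw_vartheta() for incomplete designs",
         call. = FALSE)
  K <- design$K
  V_inv <- chol2inv(chol(V))
  A <- 0
  for (k in seq_len(K)) {
    Xk <- as.numeric(design$X[k, ])
    A <- A + sum(Xk * (V_inv %*% Xk))
  }
  S <- as.numeric(colSums(design$X))
  den <- A - sum(S * (V_inv %*% S)) / K
  if (!is.finite(den) || den <= 1e-12 * max(A, 1))
    return(new_sw_variance(Inf, FALSE))
  new_sw_variance(1 / den, TRUE)
}

#' Is the treatment effect estimable for a design?
#'
#' TRUE when [sw_vartheta()] yields a finite positive variance. A design
#' admitting estimation must have at least one period with both an observed
#' control and an observed intervention cell; this necessary condition is
#' implied by the variance computation.
#'
#' @inheritParams sw_vartheta
#' @return Logical scalar.
#' @export
sw_estimable <- function(design, config) {
  sw_vartheta(design, config)$estimable
}

#' @export
print.sw_variance <- function(x, ...) {
  if (x$estimable)
    cat(sprintf("var(theta-hat) = %.8g  (information %.8g)\n",
                x$variance, x$information))
  else
    cat("treatment effect not estimable (infinite variance)\n")
  invisible(x)
}
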
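#' Trial configuration for a standard stepped wedge design
#'
#' Bundles the parameters that determine a stepped wedge trial design and
#' the covariance model of its cluster-period means. One cluster is
#' randomised to each treatment sequence, so the number of clusters is
#' fixed at `K = T - 1`.
#'
#' The within-cluster correlation model is parameterised by the
#' within-period intracluster correlation `rho` (the correlation between
#' two subjects measured in the same cluster and the same period) and the
#' cluster autocorrelation `r` (the proportionate reduction in correlation
#' per period of separation). `structure = "exchangeable"` forces `r = 1`;
#' `"discrete_time_decay"` gives correlation `rho * r^|j - s|` between
#' periods `j` and `s`; `"block_exchangeable"` gives `rho * r` between any
#' two distinct periods.
#'
#' Outcomes are taken on the standardised scale: the total outcome variance
#' `tau^2 + sigma_eps^2` is fixed at 1, so the cluster-level variance
#' component is `tau^2 = rho` and the individual-level error variance is
#' `sigma_eps^2 = 1 - rho`. `effect_size` is then the treatment effect in
#' total-standard-deviation units.
#'
#' @param periods Integer number of periods `T` (at least 2).
#' @param m Integer number of subjects measured per observed cluster-period
#'   (at least 1).
#' @param rho Within-period intracluster correlation, in `[0, 1)`.
#' @param r Cluster autocorrelation (CAC), in `(0, 1]`. Must be 1 when
#'   `structure = "exchangeable"`.
#' @param structure Correlation structure: `"exchangeable"`,
#'   `"block_exchangeable"` or `"discrete_time_decay"`.
#' @param effect_size Standardised treatment effect used for power
#'   calculations.
#' @param alpha Two-sided significance level, in `(0, 1)`.
#'
#' @return An object of class `sw_config`: a list with elements `T`, `K`,
#'   `m`, `rho`, `r`, `structure`, `effect_size`, `alpha`, `tau2` and
#'   `sigma2_eps`.
#'
#' @examples
#' cfg <- sw_config(periods = 5, m = 90, rho = 0.14,
#'                  structure = "exchangeable", effect_size = 0.25)
#' cfg$K   # 4 clusters, one per sequence
#' @export
sw_config <- function(periods, m, rho, r = 1,
                      structure = c("exchangeable", "block_exchangeable",
                                    "discrete_time_decay"),
                      effect_size = NA_real_, alpha = 0.05) {
  structure <- match.arg(structure)
  if (!is.numeric(periods) || length(periods) != 1L || periods != round(periods) ||
      periods < 2)
    stop("`periods` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < 1)
    stop("`m` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("`rho` must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    stop("`r` must lie in (0, 1]", call. = FALSE)
  if (structure == "exchangeable" && r != 1)
    stop("the exchangeable structure requires r = 1", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (!is.na(effect_size) &&
      (!is.numeric(effect_size) || length(effect_size) != 1L))
    stop("`effect_size` must be a single number", call. = FALSE)

  structure(
    list(T = as.integer(periods), K = as.integer(periods) - 1L,
         m = as.integer(m), rho = as.numeric(rho), r = as.numeric(r),
         structure = structure, effect_size = as.numeric(effect_size),
         alpha = as.numeric(alpha),
         tau2 = as.numeric(rho), sigma2_eps = 1 - as.numeric(rho)),
    class = "sw_config"
  )
}

#' @export
print.sw_config <- function(x, ...) {
  cat(sprintf("Stepped wedge configuration: T = %d periods, K = %d clusters\n",
              x$T, x$K))
  cat(sprintf("  m = %d subjects per cluster-period\n", x$m))
  cat(sprintf("  correlation: %s, rho = %g, r = %g\n",
              x$structure, x$rho, x$r))
  if (!is.na(x$effect_size))
    cat(sprintf("  effect size = %g, alpha = %g (two-sided)\n",
                x$effect_size, x$alpha))
  invisible(x)
}
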
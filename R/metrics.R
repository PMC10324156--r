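#' Precision loss of a reduced design
#'
#' The precision of a design is the reciprocal of the treatment-effect
#' variance. Precision loss of a reduced design relative to the complete
#' design is the relative drop in precision, reported as a percentage:
#' `100 * (1 - var_complete / var_reduced)`. It is 0% for the complete
#' design itself, increases strictly with the reduced-design variance, and
#' is bounded above by 100%.
#'
#' @param var_complete Treatment-effect variance of the complete design.
#' @param var_reduced Treatment-effect variances of reduced designs
#'   (vectorised); each must be at least `var_complete` (removing data
#'   cannot gain precision).
#' @return Precision loss in percent, one value per element of
#'   `var_reduced`.
#' @export
precision_loss <- function(var_complete, var_reduced) {
  if (length(var_complete) != 1L || !is.finite(var_complete) ||
      var_complete <= 0)
    stop("`var_complete` must be a single finite positive value",
         call. = FALSE)
  if (any(!is.finite(var_reduced) | var_reduced <= 0))
    stop("`var_reduced` must be finite and positive", call. = FALSE)
  if (any(var_reduced < var_complete * (1 - 1e-9)))
    stop("`var_reduced` is smaller than `var_complete`; variances are inconsistent",
         call. = FALSE)
  100 * (1 - var_complete / var_reduced)
}

#' Power of the two-sided Wald test for the treatment effect
#'
#' Normal-approximation power for detecting a standardised effect size
#' `theta` given the design variance of the GLS estimator:
#' `100 * Phi(|theta| / sqrt(var) - z_{1 - alpha/2})`. The opposite-tail
#' rejection mass is negligible at conventional powers and is omitted. No
#' degrees-of-freedom correction is applied, consistent with treating the
#' correlation parameters as known at the design stage.
#'
#' @param variance Treatment-effect variance `var(theta-hat)`; may be an
#'   `sw_variance` object.
#' @param effect_size Standardised treatment effect.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in percent.
#' @examples
#' cfg <- sw_config(5, 90, rho = 0.14, structure = "exchangeable",
#'                  effect_size = 0.25)
#' v <- sw_vartheta(sw_design_complete(cfg), cfg)
#' sw_power(v, 0.25)  # 88.23
#' @export
sw_power <- function(variance, effect_size, alpha = 0.05) {
  if (inherits(variance, "sw_variance")) variance <- variance$variance
  if (!is.numeric(variance) || any(variance <= 0))
    stop("`variance` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  100 * stats::pnorm(abs(effect_size) / sqrt(variance) -
                       stats::qnorm(1 - alpha / 2))
}
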
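# Shared trial configurations used across tests.

cfg_hill_exch <- function()
  sw_config(5, 90, rho = 0.14, structure = "exchangeable",
            effect_size = 0.25)

cfg_hill_decay <- function()
  sw_config(5, 90, rho = 0.15, r = 0.95,
            structure = "discrete_time_decay", effect_size = 0.35)

cfg_large_decay <- function()
  sw_config(10, 50, rho = 0.05, r = 0.95,
            structure = "discrete_time_decay", effect_size = 0.2)

# Hussey-Hughes closed-form variance of the treatment effect for a complete
# stepped wedge under the exchangeable structure, written directly from the
# published formula as an oracle independent of sw_vartheta():
#   var = K sigma^2 (sigma^2 + T tau^2) /
#         [(KU - W) sigma^2 + (U^2 + KTU - TW - KV) tau^2]
# with sigma^2 the variance of a cluster-period mean error (sigma_eps^2/m),
# U = sum_kj X_kj, W = sum_j (sum_k X_kj)^2, V = sum_k (sum_j X_kj)^2.
hh_variance <- function(T, m, rho) {
  K <- T - 1
  X <- sw_design_complete(T)$X
  sigma2 <- (1 - rho) / m
  tau2 <- rho
  U <- sum(X)
  W <- sum(colSums(X)^2)
  V <- sum(rowSums(X)^2)
  K * sigma2 * (sigma2 + T * tau2) /
    ((K * U - W) * sigma2 + (U^2 + K * T * U - T * W - K * V) * tau2)
}
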
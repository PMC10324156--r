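test_that("complete-design variance matches the Hussey-Hughes closed form", {
  for (T in c(3, 5, 8, 12)) for (m in c(10, 90)) for (rho in c(0.01, 0.14, 0.3)) {
    cfg <- sw_config(T, m, rho = rho, structure = "exchangeable")
    d <- sw_design_complete(cfg)
    v <- sw_vartheta_complete(d, sw_cov_matrix(cfg))
    expect_true(v$estimable)
    expect_equal(v$variance, hh_variance(T, m, rho), tolerance = 1e-10)
  }
})

test_that("general variance reduces to the complete-design form", {
  grid <- expand.grid(T = c(3, 5, 10), m = c(10, 50),
                      rho = c(0.05, 0.15), r = c(1, 0.95, 0.8))
  for (i in seq_len(nrow(grid))) {
    st <- if (grid$r[i] == 1) "exchangeable" else "discrete_time_decay"
    cfg <- sw_config(grid$T[i], grid$m[i], grid$rho[i], grid$r[i], st)
    d <- sw_design_complete(cfg)
    v3 <- sw_vartheta_complete(d, sw_cov_matrix(cfg))
    v4 <- sw_vartheta(d, cfg)
    expect_equal(v4$variance, v3$variance, tolerance = 1e-10)
  }
})

test_that("variance is invariant to relabelling clusters", {
  cfg <- cfg_hill_decay()
  d <- remove_pair(remove_pair(sw_design_complete(cfg), c(1, 4)), c(2, 1))
  v <- sw_vartheta(d, cfg)$variance
  perm <- c(3, 1, 4, 2)
  dp <- sw_design(d$X[perm, ], d$observed[perm, ])
  # a permuted mask is generally not centrosymmetric, but the variance
  # computation only uses per-cluster blocks
  expect_equal(swreduce:::sw_vartheta_V(dp, sw_cov_matrix(cfg))$variance, v,
               tolerance = 1e-12)
})

test_that("estimability requires a period with both arms observed", {
  cfg <- cfg_hill_exch()
  expect_true(sw_estimable(sw_design_complete(cfg), cfg))

  # all-control observed cells: theta not identified
  d <- sw_design_complete(cfg)
  d$observed <- d$X == 0L
  expect_false(swreduce:::sw_vartheta_V(d, sw_cov_matrix(cfg))$estimable)

  # six-cell staircase: estimable; its middle pair can be removed once,
  # after which no further pair removal keeps the effect estimable
  d6 <- sw_design_complete(cfg)
  for (cell in list(c(1, 1), c(1, 3), c(1, 4), c(2, 1), c(2, 4), c(2, 5), c(1, 5)))
    d6 <- remove_pair(d6, cell)
  expect_equal(sum(d6$observed), 6L)
  expect_true(sw_estimable(d6, cfg))
  d4 <- remove_pair(d6, c(2, 3))
  expect_true(sw_estimable(d4, cfg))
  for (p in sw_pairs(d4))
    expect_false(sw_estimable(remove_pair(d4, p), cfg))
})

test_that("clusters with no observed periods drop out of the sums", {
  cfg <- sw_config(4, 20, rho = 0.1, r = 0.9,
                   structure = "discrete_time_decay")
  d <- sw_design_complete(cfg)
  # blank out cluster 2 and its centrosymmetric partner cluster 2 of K=3...
  # remove the full middle row pairwise: cluster 2 pairs with itself only at
  # T odd; here K=3, partner of (2, j) is (2, 5-j), so removing (2,1),(2,2)
  # empties row 2
  d <- remove_pair(d, c(2, 1))
  d <- remove_pair(d, c(2, 2))
  expect_equal(sum(d$observed[2, ]), 0L)
  v <- sw_vartheta(d, cfg)
  expect_true(v$estimable)
  # identical to computing on the design without that cluster (period
  # effects for all periods still estimable from remaining clusters)
  dsub <- sw_design(d$X[-2, ], d$observed[-2, ])
  expect_equal(swreduce:::sw_vartheta_V(dsub, sw_cov_matrix(cfg))$variance, v$variance,
               tolerance = 1e-12)
})

test_that("Monte-Carlo GLS variance agrees with the analytic expression", {
  set.seed(1405)
  cfg <- sw_config(4, 5, rho = 0.1, r = 0.9,
                   structure = "discrete_time_decay", effect_size = 0.3)
  d <- remove_pair(sw_design_complete(cfg), c(1, 4))
  analytic <- sw_vartheta(d, cfg)$variance

  n_rep <- 20000
  y <- sw_simulate(d, cfg, n_rep)
  theta_hat <- vapply(seq_len(n_rep), function(i)
    sw_gls_fit(y[i, , ], d, cfg)$theta, numeric(1))
  emp <- stats::var(theta_hat)
  # sampling SE of the empirical variance of a normal estimator
  se <- analytic * sqrt(2 / (n_rep - 1))
  expect_lt(abs(emp - analytic), 3 * se)
  # estimator is unbiased for the simulated effect
  expect_lt(abs(mean(theta_hat) - 0.3), 4 * sqrt(analytic / n_rep))
})
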
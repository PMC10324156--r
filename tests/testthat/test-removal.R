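test_that("minimum-IC selection breaks ties toward the top-left cell", {
  mk <- function(...) lapply(list(...), function(a)
    list(a = a, b = centro_partner(a, 4, 5)))
  pairs <- mk(c(2, 2), c(1, 3), c(1, 2))

  # strict minimum wins regardless of position
  expect_equal(select_min_pair(pairs, c(1.2, 1.1, 1.3)), 2L)
  # exact ties: cluster-major lexicographic order of the smaller member
  expect_equal(select_min_pair(pairs, c(1.2, 1.2, 1.2)), 3L)
  # ICs within relative 1e-9 are tied, so position decides ...
  expect_equal(select_min_pair(pairs, c(1.3, 1.2 * (1 + 1e-12), 1.2)), 3L)
  expect_equal(select_min_pair(pairs, c(1.2 * (1 + 1e-12), 1.2, 1.3)), 2L)
  # ... but a genuinely smaller IC beats a better-placed pair
  expect_equal(select_min_pair(pairs, c(1.3, 1.2, 1.2 * (1 + 1e-6))), 2L)
  # single finite IC
  expect_equal(select_min_pair(pairs, c(Inf, 1.5, Inf)), 2L)
  # all infinite signals termination
  expect_null(select_min_pair(pairs, c(Inf, Inf, Inf)))
})

test_that("greedy removal of the 4x5 exchangeable design reaches the 4-cell staircase", {
  tr <- sw_reduce(cfg_hill_exch())

  expect_equal(length(tr$removed), 8L)
  expect_equal(tr$n_cells, seq(20L, 4L, by = -2L))
  # removal order, frozen from the first full run and consistent with the
  # published 50%-removed power/precision figures
  order_removed <- t(vapply(tr$removed, function(p) p$a, integer(2)))
  expect_equal(order_removed,
               rbind(c(1L, 4L), c(2L, 1L), c(2L, 5L), c(2L, 4L),
                     c(1L, 3L), c(1L, 1L), c(1L, 5L), c(2L, 3L)))

  # minimally viable design: two mixed periods around the switches
  final <- tr$designs[[9]]
  expect_equal(which(final$observed, arr.ind = TRUE, useNames = FALSE),
               cbind(c(1L, 2L, 3L, 4L), c(2L, 2L, 4L, 4L)))
  # no further pair is removable
  for (p in sw_pairs(final))
    expect_false(sw_estimable(remove_pair(final, p), tr$config))
})

test_that("each removed pair is the brute-force minimum at its iteration", {
  cfg <- cfg_hill_decay()
  tr <- sw_reduce(cfg)
  for (i in seq_along(tr$removed)) {
    d <- tr$designs[[i]]
    base <- tr$variances[i]
    ics <- vapply(sw_pairs(d), function(p) {
      v <- sw_vartheta(remove_pair(d, p), cfg)
      if (v$estimable) v$variance / base else Inf
    }, numeric(1))
    sel_ic <- tr$variances[i + 1] / base
    expect_equal(sel_ic, min(ics), tolerance = 1e-9)
  }
})

test_that("traces are deterministic with monotone variance and precision loss", {
  cfg <- cfg_hill_decay()
  tr1 <- sw_reduce(cfg)
  tr2 <- sw_reduce(cfg)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))

  expect_true(all(diff(tr1$variances) >= -1e-15))
  expect_true(all(diff(tr1$precision_loss) >= -1e-12))
  expect_true(all(diff(tr1$power) <= 1e-12))
  expect_lte(length(tr1$removed), 5 * 4 / 2)
  for (d in tr1$designs) {
    expect_true(is_centrosymmetric(d))
    expect_true(is_skew_symmetric(d))
  }
})

test_that("degenerate and minimal wedges behave sensibly", {
  # T = 2 means a single cluster: the treatment indicator coincides with
  # the period-2 effect, so even the complete design is non-estimable
  cfg2 <- sw_config(2, 10, rho = 0.1)
  expect_false(sw_estimable(sw_design_complete(cfg2), cfg2))
  expect_error(sw_reduce(cfg2), "not estimable")

  # T = 3 is the smallest wedge with a removal path; it terminates at a
  # single mixed-period pair
  cfg3 <- sw_config(3, 10, rho = 0.1)
  tr <- sw_reduce(cfg3)
  final <- tr$designs[[length(tr$designs)]]
  expect_equal(sum(final$observed), 2L)
  expect_true(sw_estimable(final, cfg3))
  expect_equal(tr$precision_loss[1], 0)
})

test_that("the 10-period decay path matches the published staircase checkpoint", {
  cfg <- cfg_large_decay()
  tr <- sw_reduce(cfg, max_removals = 23, keep_ic_maps = FALSE)
  expect_equal(tr$pct_removed[24], 100 * 46 / 90, tolerance = 1e-12)
  d <- tr$designs[[24]]
  # staircase-like: every cluster retains its switch-adjacent cells
  for (k in 1:9) {
    expect_true(d$observed[k, k])       # last control period
    expect_true(d$observed[k, k + 1])   # first intervention period
  }
  # with some additional measurements in the first and final periods
  expect_gt(sum(d$observed[, 1]) + sum(d$observed[, 10]), 2)
})

test_that("trace exports round-trip through CSV and JSON", {
  tr <- sw_reduce(cfg_hill_exch())
  csv <- file.path(tempdir(), "trace.csv")
  write_trace_csv(tr, csv)
  df <- utils::read.csv(csv)
  expect_equal(nrow(df), 9L)
  expect_equal(df$variance, tr$variances, tolerance = 1e-12)

  js <- file.path(tempdir(), "trace.json")
  write_trace_json(tr, js)
  bundle <- jsonlite::read_json(js)
  expect_length(bundle$iterations, 9L)
  expect_equal(bundle$iterations[[1]]$variance, tr$variances[1],
               tolerance = 1e-12)
  expect_equal(unlist(bundle$iterations[[2]]$removed_pair$a), c(1L, 4L))
})
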
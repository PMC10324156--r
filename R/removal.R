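#' Iteratively remove low-information cell pairs from a stepped wedge design
#'
#' Starting from the complete design, repeatedly (1) computes the
#' information content of every remaining centrosymmetric cell pair,
#' (2) removes the pair with the lowest IC, breaking ties in favour of the
#' pair containing the cell with the smallest cluster and period index
#' (the cell closest to the top-left corner of the schematic), and
#' (3) records the variance, precision loss and power of the reduced
#' design. Iteration stops when no pair can be removed without losing
#' estimability of the treatment effect: the final recorded design is the
#' minimally viable design. The whole procedure is deterministic.
#'
#' @param config An [sw_config()]. `effect_size` and `alpha` are used for
#'   the power column; power is `NA` when no effect size is set.
#' @param max_removals Optional cap on the number of pair removals
#'   (default: run to the minimally viable design). At most
#'   `T(T-1)/2 - 1` removals are ever possible.
#' @param keep_ic_maps Keep the full IC map of each visited design in the
#'   trace (default TRUE; memory is trivial at typical sizes).
#' @return An object of class `sw_trace`: list with
#'   \describe{
#'     \item{config}{the configuration.}
#'     \item{designs}{list of `sw_design`s, element 1 the complete design.}
#'     \item{removed}{list of removed pairs, one per iteration.}
#'     \item{variances}{numeric vector, `variances[l + 1]` the variance
#'       after `l` removals; non-decreasing.}
#'     \item{ic_maps}{list of `sw_icmap`s (when `keep_ic_maps`).}
#'     \item{precision_loss, power, n_cells, pct_removed}{per-design
#'       metric vectors aligned with `designs`.}
#'   }
#' @examples
#' cfg <- sw_config(5, 90, rho = 0.14, structure = "exchangeable",
#'                  effect_size = 0.25)
#' tr <- sw_reduce(cfg)
#' as.data.frame(tr)
#' @export
sw_reduce <- function(config, max_removals = Inf, keep_ic_maps = TRUE) {
  stopifnot(inherits(config, "sw_config"))
  design <- sw_design_complete(config)
  v0 <- sw_vartheta(design, config)
  if (!v0$estimable)
    stop(paste0("treatment effect is not estimable for the complete design",
                if (config$T == 2L)
                  " (with a single cluster it is confounded with the period effects)"),
         call. = FALSE)

  designs <- list(design)
  variances <- v0$variance
  removed <- list()
  ic_maps <- list()

  repeat {
    if (length(removed) >= max_removals) break
    current <- designs[[length(designs)]]
    vcur <- variances[length(variances)]
    pairs <- sw_pairs(current)
    if (length(pairs) == 0L) break
    ics <- vapply(pairs, function(p)
      sw_pair_ic(current, p, config, base_variance = vcur), numeric(1L))
    if (keep_ic_maps) {
      values <- matrix(NA_real_, current$K, current$T)
      for (i in seq_along(pairs)) {
        pairs[[i]]$ic <- ics[i]
        a <- pairs[[i]]$a; b <- pairs[[i]]$b
        values[a[1L], a[2L]] <- ics[i]
        values[b[1L], b[2L]] <- ics[i]
      }
      ic_maps[[length(ic_maps) + 1L]] <-
        structure(list(values = values, base_variance = vcur, pairs = pairs),
                  class = "sw_icmap")
    }
    sel <- select_min_pair(pairs, ics)
    if (is.null(sel)) break  # every removal destroys estimability
    reduced <- remove_pair(current, pairs[[sel]])
    stopifnot(is_centrosymmetric(reduced), is_skew_symmetric(reduced))
    v <- sw_vartheta(reduced, config)
    designs[[length(designs) + 1L]] <- reduced
    removed[[length(removed) + 1L]] <- pairs[[sel]]
    variances <- c(variances, v$variance)
  }

  n_cells <- vapply(designs, function(d) sum(d$observed), integer(1L))
  total <- config$K * config$T
  pl <- precision_loss(variances[1L], variances)
  pw <- if (is.na(config$effect_size)) rep(NA_real_, length(variances))
        else sw_power(variances, config$effect_size, config$alpha)

  structure(list(config = config, designs = designs, removed = removed,
                 variances = variances, ic_maps = ic_maps,
                 precision_loss = pl, power = pw, n_cells = n_cells,
                 pct_removed = 100 * (total - n_cells) / total),
            class = "sw_trace")
}

#' Select the pair with minimum information content
#'
#' Returns the index of the pair minimising IC among pairs with finite IC.
#' ICs within a relative tolerance of `1e-9` are treated as tied (the
#' exchangeable structure produces exact mathematical ties that differ
#' only in floating-point rounding); among tied pairs the one whose
#' smaller member cell comes first in (cluster, period) lexicographic
#' order is chosen, so exactly one pair is removed per iteration.
#'
#' @param pairs List of pairs as from [sw_pairs()].
#' @param ics Numeric vector of IC values aligned with `pairs`.
#' @return Integer index into `pairs`, or `NULL` when every IC is
#'   infinite (signalling termination of the removal algorithm).
#' @export
select_min_pair <- function(pairs, ics) {
  finite <- is.finite(ics)
  if (!any(finite)) return(NULL)
  mn <- min(ics[finite])
  tied <- which(finite & ics <= mn * (1 + 1e-9))
  ks <- vapply(pairs[tied], function(p) as.numeric(p$a[1L]), numeric(1L))
  js <- vapply(pairs[tied], function(p) as.numeric(p$a[2L]), numeric(1L))
  tied[order(ks, js)][1L]
}

#' @export
print.sw_trace <- function(x, ...) {
  cat(sprintf("Removal trace: %d periods, %d clusters, %s structure\n",
              x$config$T, x$config$K, x$config$structure))
  cat(sprintf("  %d pair removals, %d -> %d observed cells\n",
              length(x$removed), x$n_cells[1L],
              x$n_cells[length(x$n_cells)]))
  cat("Minimally viable design:\n")
  cat(sw_schematic(x$designs[[length(x$designs)]]), sep = "\n")
  invisible(x)
}

#' Per-iteration summary of a removal trace
#'
#' One row per visited design (row 1 = complete design): the removed pair
#' that produced it, cells remaining, percent removed, variance, precision
#' loss and power.
#'
#' @param x An `sw_trace`.
#' @param row.names,optional,... Passed through for the S3 generic.
#' @export
as.data.frame.sw_trace <- function(x, row.names = NULL, optional = FALSE, ...) {
  n <- length(x$designs)
  rem <- function(i, el) if (i == 1L) NA_integer_ else x$removed[[i - 1L]][[el]]
  data.frame(
    iteration = seq_len(n) - 1L,
    removed_cluster = vapply(seq_len(n), function(i)
      if (i == 1L) NA_integer_ else x$removed[[i - 1L]]$a[1L], integer(1L)),
    removed_period = vapply(seq_len(n), function(i)
      if (i == 1L) NA_integer_ else x$removed[[i - 1L]]$a[2L], integer(1L)),
    partner_cluster = vapply(seq_len(n), function(i)
      if (i == 1L) NA_integer_ else x$removed[[i - 1L]]$b[1L], integer(1L)),
    partner_period = vapply(seq_len(n), function(i)
      if (i == 1L) NA_integer_ else x$removed[[i - 1L]]$b[2L], integer(1L)),
    n_cells_remaining = x$n_cells,
    pct_removed = x$pct_removed,
    variance = x$variances,
    precision_loss_pct = x$precision_loss,
    power_pct = x$power
  )
}

#' Export a removal trace
#'
#' `write_trace_csv()` writes the per-iteration summary (see
#' [as.data.frame.sw_trace()]) as CSV. `write_trace_json()` writes a JSON
#' bundle holding the configuration, every intermediate design, the
#' removed pairs, and (when retained) the IC map values per iteration.
#'
#' @param trace An `sw_trace`.
#' @param path Output file path.
#' @rdname trace-export
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname trace-export
#' @export
write_trace_json <- function(trace, path) {
  cfg <- trace$config
  bundle <- list(
    config = list(T = cfg$T, K = cfg$K, m = cfg$m, rho = cfg$rho, r = cfg$r,
                  structure = cfg$structure, effect_size = cfg$effect_size,
                  alpha = cfg$alpha),
    iterations = lapply(seq_along(trace$designs), function(i) {
      d <- trace$designs[[i]]
      list(iteration = i - 1L,
           X = unclass(d$X), observed = unclass(d$observed),
           removed_pair = if (i == 1L) NULL else
             list(a = trace$removed[[i - 1L]]$a, b = trace$removed[[i - 1L]]$b),
           variance = trace$variances[i],
           precision_loss_pct = trace$precision_loss[i],
           power_pct = trace$power[i],
           ic = if (length(trace$ic_maps) >= i)
             unclass(trace$ic_maps[[i]]$values) else NULL)
    })
  )
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Plot precision loss and power along a removal trace
#'
#' Two stacked panels against the percentage of cluster-period cells
#' removed: precision loss (top) and power (bottom, when an effect size is
#' configured).
#'
#' @param x An `sw_trace`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.sw_trace <- function(x, ...) {
  has_power <- !all(is.na(x$power))
  op <- graphics::par(mfrow = c(if (has_power) 2L else 1L, 1L),
                      mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$pct_removed, x$precision_loss, type = "b", pch = 16,
                 xlab = "% of cluster-period cells removed",
                 ylab = "precision loss (%)", ...)
  if (has_power)
    graphics::plot(x$pct_removed, x$power, type = "b", pch = 16,
                   xlab = "% of cluster-period cells removed",
                   ylab = "power (%)", ...)
  invisible(x)
}
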
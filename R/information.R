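#' Information content of a centrosymmetric cell pair
#'
#' The information content (IC) of a pair of centrosymmetric cells `A`
#' within a design `D` is the ratio of treatment-effect variances
#' `IC_D(A) = var_{D[A]}(theta-hat) / var_D(theta-hat)`, where `D[A]` is
#' the design with both cells of `A` removed. IC is at least 1 (removing
#' data can never increase precision); large values flag information-rich
#' cells. `Inf` means removing the pair makes the treatment effect
#' non-estimable.
#'
#' The ratio is computed by direct re-evaluation of the general variance
#' expression on the reduced design; no incremental update is used, so
#' every IC is an independent from-scratch computation.
#'
#' @param design An estimable [sw_design()].
#' @param pair A pair from [sw_pairs()], or `c(k, j)` naming either member.
#' @param config An [sw_config()].
#' @param base_variance Optional precomputed `var_D(theta-hat)` of
#'   `design`, to avoid recomputation in loops.
#' @return A single numeric IC value, possibly `Inf`.
#' @export
sw_pair_ic <- function(design, pair, config, base_variance = NULL) {
  if (is.null(base_variance)) {
    base <- sw_vartheta(design, config)
    if (!base$estimable)
      stop("base design is not estimable; IC is undefined", call. = FALSE)
    base_variance <- base$variance
  }
  reduced <- remove_pair(design, pair)
  v <- sw_vartheta(reduced, config)
  if (!v$estimable) return(Inf)
  v$variance / base_variance
}

#' Information-content map of a design
#'
#' Evaluates [sw_pair_ic()] for every observed centrosymmetric pair and
#' fills both member cells with the shared value. Cells of unobserved
#' pairs are `NA`. The map is centrosymmetric by construction:
#' `values[k, j] == values[K+1-k, T+1-j]` wherever defined.
#'
#' @inheritParams sw_pair_ic
#' @return An object of class `sw_icmap`: list with `values` (`K x T`
#'   numeric matrix), `base_variance`, and `pairs` (the enumerated pairs,
#'   each with its `ic`).
#' @export
sw_ic_map <- function(design, config) {
  base <- sw_vartheta(design, config)
  if (!base$estimable)
    stop("design is not estimable; IC map is undefined", call. = FALSE)
  pairs <- sw_pairs(design)
  values <- matrix(NA_real_, design$K, design$T)
  for (i in seq_along(pairs)) {
    ic <- sw_pair_ic(design, pairs[[i]], config,
                     base_variance = base$variance)
    pairs[[i]]$ic <- ic
    a <- pairs[[i]]$a; b <- pairs[[i]]$b
    values[a[1L], a[2L]] <- ic
    values[b[1L], b[2L]] <- ic
  }
  structure(list(values = values, base_variance = base$variance,
                 pairs = pairs),
            class = "sw_icmap")
}

#' @export
print.sw_icmap <- function(x, digits = 3, ...) {
  cat(sprintf("Information content map (%d pairs, base variance %.6g)\n",
              length(x$pairs), x$base_variance))
  print(round(x$values, digits))
  invisible(x)
}

#' Export an information-content map as a data frame or CSV
#'
#' `as.data.frame()` gives the long format: one row per cluster-period
#' cell with its cluster, period, treatment indicator, observation status
#' and IC value. `write_ic_csv()` writes either this long format or the
#' `K x T` wide matrix (empty strings for unobserved cells).
#'
#' @param x An `sw_icmap`.
#' @param design The `sw_design` the map was computed from.
#' @param row.names,optional,... Passed through for the S3 generic.
#' @rdname icmap-export
#' @export
as.data.frame.sw_icmap <- function(x, row.names = NULL, optional = FALSE,
                                   design = NULL, ...) {
  K <- nrow(x$values); T <- ncol(x$values)
  df <- data.frame(
    cluster = rep(seq_len(K), times = T),
    period = rep(seq_len(T), each = K),
    ic = as.vector(x$values)
  )
  if (!is.null(design)) {
    df$treatment <- as.vector(design$X)
    df$observed <- as.vector(design$observed)
  }
  df
}

#' @param path File path for the CSV output.
#' @param format `"long"` (one row per cell) or `"wide"` (`K x T` matrix,
#'   empty string for unobserved cells).
#' @rdname icmap-export
#' @export
write_ic_csv <- function(x, path, design = NULL, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "long") {
    utils::write.csv(as.data.frame(x, design = design), path,
                     row.names = FALSE)
  } else {
    ch <- matrix("", nrow(x$values), ncol(x$values))
    def <- !is.na(x$values)
    ch[def] <- format(x$values[def], digits = 10)
    utils::write.table(ch, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
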
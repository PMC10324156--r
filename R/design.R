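#' Stepped wedge design objects
#'
#' An `sw_design` holds the treatment-indicator matrix `X` (clusters in
#' rows, periods in columns, 0 = control, 1 = intervention) together with a
#' logical `observed` mask of the same dimension marking the cluster-period
#' cells in which measurements are taken. Complete designs observe every
#' cell; incomplete designs produced by this package remove cells only in
#' centrosymmetric pairs, so the mask is always centrosymmetric and the
#' observed part of `X` is skew-symmetric: wherever both members of a pair
#' are observed, their treatment labels are complementary.
#'
#' @param X Integer or numeric matrix of 0/1 treatment indicators,
#'   `K` rows by `T` columns.
#' @param observed Logical matrix of the same dimension; defaults to all
#'   cells observed.
#' @return An object of class `sw_design` with elements `X`, `observed`,
#'   `K` and `T`.
#' @seealso [sw_design_complete()], [remove_pair()], [sw_pairs()]
#' @export
sw_design <- function(X, observed = NULL) {
  X <- as.matrix(X)
  if (!all(X %in% c(0, 1)))
    stop("`X` must contain only 0/1 treatment indicators", call. = FALSE)
  storage.mode(X) <- "integer"
  if (is.null(observed)) observed <- matrix(TRUE, nrow(X), ncol(X))
  observed <- as.matrix(observed)
  if (!is.logical(observed) || !identical(dim(observed), dim(X)))
    stop("`observed` must be a logical matrix with the dimensions of `X`",
         call. = FALSE)
  structure(list(X = X, observed = observed,
                 K = nrow(X), T = ncol(X)),
            class = "sw_design")
}

#' Complete standard stepped wedge design
#'
#' Builds the complete design with `T` periods and `K = T - 1` clusters,
#' one cluster per sequence: cluster `k` spends its first `k` periods in
#' control and switches to intervention at period `k + 1`. Every
#' cluster-period cell is observed.
#'
#' @param periods Number of periods `T` (>= 2), or an [sw_config()] from
#'   which `T` is taken.
#' @return An `sw_design` with all cells observed.
#' @examples
#' d <- sw_design_complete(5)
#' d$X[1, ]  # cluster 1: control in period 1, intervention thereafter
#' @export
sw_design_complete <- function(periods) {
  if (inherits(periods, "sw_config")) periods <- periods$T
  if (!is.numeric(periods) || length(periods) != 1L ||
      periods != round(periods) || periods < 2)
    stop("`periods` must be a single integer >= 2", call. = FALSE)
  T <- as.integer(periods)
  K <- T - 1L
  X <- matrix(0L, K, T)
  for (k in seq_len(K)) X[k, (k + 1L):T] <- 1L
  sw_design(X)
}

#' Centrosymmetric partner of a cluster-period cell
#'
#' Reflecting a design schematic through its centre maps the cell in
#' cluster `k`, period `j` onto the cell in cluster `K + 1 - k`, period
#' `T + 1 - j`. These two cells form a centrosymmetric pair; for a
#' skew-symmetric stepped wedge they carry complementary treatment labels
#' and contribute equal information about the treatment effect, so the
#' package always removes them together. The map is an involution, and with
#' `K = T - 1` no cell is its own partner.
#'
#' @param cell Integer vector `c(k, j)`: 1-based cluster and period index.
#' @param K Number of clusters.
#' @param T Number of periods.
#' @return Integer vector `c(k', j')` of the partner cell.
#' @examples
#' centro_partner(c(1, 1), K = 4, T = 5)  # c(4, 5)
#' @export
centro_partner <- function(cell, K, T) {
  if (length(cell) != 2L || any(cell != round(cell)))
    stop("`cell` must be an integer pair c(k, j)", call. = FALSE)
  k <- as.integer(cell[1L]); j <- as.integer(cell[2L])
  if (k < 1L || k > K || j < 1L || j > T)
    stop(sprintf("cell (%d, %d) outside the %d x %d design", k, j, K, T),
         call. = FALSE)
  c(K + 1L - k, T + 1L - j)
}

#' Enumerate observed centrosymmetric cell pairs
#'
#' Lists every centrosymmetric pair whose two member cells are both
#' currently observed. Each pair appears once, keyed by its
#' lexicographically smallest member (cluster-major), which is also the
#' order used to break ties during removal. A complete design has
#' `T(T-1)/2` pairs.
#'
#' @param design An `sw_design` whose mask is centrosymmetric.
#' @return A list of pairs; each element is a list with integer cells
#'   `a = c(k, j)` and `b = c(K+1-k, T+1-j)`.
#' @export
sw_pairs <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  if (!is_centrosymmetric(design))
    stop("design mask is not centrosymmetric", call. = FALSE)
  K <- design$K; T <- design$T
  out <- vector("list", sum(design$observed) %/% 2L)
  n <- 0L
  for (k in seq_len(K)) for (j in seq_len(T)) {
    p <- c(K + 1L - k, T + 1L - j)
    if (design$observed[k, j] && design$observed[p[1L], p[2L]] &&
        (k < p[1L] || (k == p[1L] && j < p[2L]))) {
      n <- n + 1L
      out[[n]] <- list(a = c(k, j), b = p)
    }
  }
  out[seq_len(n)]
}

#' Remove a centrosymmetric pair of cells from a design
#'
#' Returns a new design in which both member cells of `pair` are
#' unobserved; the input design is not modified. Removing cells only in
#' centrosymmetric pairs preserves the centrosymmetry of the mask and the
#' skew-symmetry of the observed design.
#'
#' @param design An `sw_design`.
#' @param pair A pair as returned by [sw_pairs()], or an integer vector
#'   `c(k, j)` naming either member cell.
#' @return The reduced `sw_design`.
#' @export
remove_pair <- function(design, pair) {
  stopifnot(inherits(design, "sw_design"))
  a <- if (is.list(pair)) as.integer(pair$a) else as.integer(pair)
  b <- centro_partner(a, design$K, design$T)
  if (!design$observed[a[1L], a[2L]] || !design$observed[b[1L], b[2L]])
    stop(sprintf("pair {(%d,%d), (%d,%d)} is not fully observed",
                 a[1L], a[2L], b[1L], b[2L]), call. = FALSE)
  design$observed[a[1L], a[2L]] <- FALSE
  design$observed[b[1L], b[2L]] <- FALSE
  design
}

#' Structural checks on a design
#'
#' `is_centrosymmetric()` checks that the observation mask maps onto itself
#' under the centre reflection. `is_skew_symmetric()` checks that wherever
#' both members of a centrosymmetric pair are observed their treatment
#' labels are complementary (`X[k, j] = 1 - X[K+1-k, T+1-j]`).
#'
#' @param design An `sw_design`.
#' @return Logical scalar.
#' @rdname design-checks
#' @export
is_centrosymmetric <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  o <- design$observed
  identical(o, o[design$K:1L, design$T:1L, drop = FALSE])
}

#' @rdname design-checks
#' @export
is_skew_symmetric <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  o <- design$observed
  flip <- design$X[design$K:1L, design$T:1L, drop = FALSE]
  both <- o & o[design$K:1L, design$T:1L, drop = FALSE]
  all(design$X[both] == 1L - flip[both])
}

#' Render a design schematic as text
#'
#' One row per cluster, one column per period; `0` marks an observed
#' control cell, `1` an observed intervention cell, and `.` a cell in which
#' no measurements are taken.
#'
#' @param design An `sw_design`.
#' @return A character vector, one element per cluster row.
#' @export
sw_schematic <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  ch <- matrix(".", design$K, design$T)
  ch[design$observed] <- as.character(design$X[design$observed])
  apply(ch, 1L, paste, collapse = " ")
}

#' @export
print.sw_design <- function(x, ...) {
  cat(sprintf("Stepped wedge design: %d clusters x %d periods, %d of %d cells observed\n",
              x$K, x$T, sum(x$observed), x$K * x$T))
  cat(sw_schematic(x), sep = "\n")
  invisible(x)
}

#' Serialise a design to and from JSON
#'
#' The JSON form records `T`, `K`, the 0/1 treatment matrix `X` and the
#' logical `observed` mask, all row-major.
#'
#' @param design An `sw_design`.
#' @return `sw_design_to_json()` returns a JSON string;
#'   `sw_design_from_json()` returns an `sw_design`.
#' @rdname design-json
#' @export
sw_design_to_json <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  jsonlite::toJSON(
    list(T = design$T, K = design$K,
         X = unclass(design$X), observed = unclass(design$observed)),
    auto_unbox = TRUE
  )
}

#' @param json JSON string produced by `sw_design_to_json()`.
#' @rdname design-json
#' @export
sw_design_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  sw_design(obj$X, matrix(as.logical(obj$observed),
                          nrow(obj$observed), ncol(obj$observed)))
}
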
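# Lattice geometry, exclusion rules and admissibility for two-type
# configurations on an L x L square grid.
#
# Conventions used throughout the package:
#  * A configuration is an L x L integer matrix with entries 0 (empty),
#    1 (tumor cell) and 2 (normal cell); matrix[row, col] with 1-based
#    indices in R code. Snapshot files on disk use 0-based coordinates
#    (see read_snapshot/write_snapshot).
#  * Distances are graph (L1/Manhattan) distances: the minimal number of
#    unit lattice edges between two vertices.
#  * Border vertices (row or col equal to 1 or L) are kept permanently
#    empty to suppress boundary effects.

#' Exclusion rule between cell types
#'
#' Builds the symmetric table of minimal allowed graph distances between
#' cells: a pair of cells of types `i` and `j` must sit at graph distance
#' at least `D(i, j)`. `D(i, i)` is the self-exclusion diameter of type `i`
#' and quantifies its degree of contact inhibition: larger values force
#' sparser single-type packings.
#'
#' @param d11 Minimal distance between two tumor (type 1) cells.
#' @param d12 Minimal distance between a tumor and a normal cell
#'   (symmetric, so also `D(2, 1)`).
#' @param d22 Minimal distance between two normal (type 2) cells.
#' @return An object of class `exclusion_rule`: a symmetric 2x2 integer
#'   matrix `D` with `D[i, j]` the minimal allowed distance.
#' @examples
#' rule <- exclusion_rule(1, 3, 2)  # default co-culture parameterization
#' rule$D
#' @export
exclusion_rule <- function(d11 = 1L, d12 = 3L, d22 = 2L) {
  d <- c(d11, d12, d22)
  if (any(d < 1) || any(d != round(d))) {
    stop("exclusion distances must be positive integers")
  }
  D <- matrix(as.integer(c(d11, d12, d12, d22)), 2, 2)
  structure(list(D = D), class = "exclusion_rule")
}

#' @export
print.exclusion_rule <- function(x, ...) {
  cat("Exclusion rule (minimal allowed graph distances):\n")
  cat(sprintf("  D(1,1)=%d  D(1,2)=D(2,1)=%d  D(2,2)=%d\n",
              x$D[1, 1], x$D[1, 2], x$D[2, 2]))
  invisible(x)
}

#' Lattice configuration of two cell types
#'
#' Wraps an `L x L` occupancy matrix (0 empty, 1 tumor, 2 normal) together
#' with the exclusion rule it is expected to satisfy. Construction
#' validates entries, the empty-border invariant and (by default)
#' admissibility under the rule.
#'
#' @param state Integer matrix with entries in `{0, 1, 2}`.
#' @param rule An [exclusion_rule()].
#' @param validate If `TRUE` (default) check borders and admissibility.
#' @return An object of class `lattice_config` with fields `L`, `state`
#'   and `rule`.
#' @export
lattice_config <- function(state, rule = exclusion_rule(), validate = TRUE) {
  state <- as.matrix(state)
  if (nrow(state) != ncol(state)) stop("state must be a square matrix")
  storage.mode(state) <- "integer"
  if (!all(state %in% c(0L, 1L, 2L))) {
    stop("state entries must be 0 (empty), 1 (tumor) or 2 (normal)")
  }
  cfg <- structure(list(L = nrow(state), state = state, rule = rule),
                   class = "lattice_config")
  if (validate) {
    if (!borders_empty(cfg)) stop("border vertices must be empty")
    if (!is_admissible(cfg, rule)) {
      stop("configuration violates the exclusion rule")
    }
  }
  cfg
}

#' @export
print.lattice_config <- function(x, ...) {
  n1 <- sum(x$state == 1L)
  n2 <- sum(x$state == 2L)
  cat(sprintf("lattice_config: %d x %d grid, %d tumor + %d normal cells (densities %.4f / %.4f)\n",
              x$L, x$L, n1, n2, n1 / x$L^2, n2 / x$L^2))
  invisible(x)
}

borders_empty <- function(config) {
  s <- config$state
  L <- config$L
  all(s[1, ] == 0L) && all(s[L, ] == 0L) &&
    all(s[, 1] == 0L) && all(s[, L] == 0L)
}

#' Graph distance between two lattice vertices
#'
#' The minimal number of unit lattice edges connecting two vertices of the
#' square grid, i.e. the L1 (Manhattan) distance
#' `|r1 - r2| + |c1 - c2|`.
#'
#' @param a,b Sites as length-2 integer vectors `c(row, col)`.
#' @return Nonnegative integer distance.
#' @examples
#' graph_distance(c(3, 6), c(5, 5))  # 3
#' @export
graph_distance <- function(a, b) {
  abs(a[[1]] - b[[1]]) + abs(a[[2]] - b[[2]])
}

#' Sites on the ring at a given graph distance
#'
#' All grid vertices at graph distance exactly `d` from `x` (the "diamond
#' shell"); an interior site far from the edges has `4 d` of them, the set
#' is truncated near the grid boundary.
#'
#' @param x Site `c(row, col)` (1-based).
#' @param d Positive integer distance.
#' @param L Grid side length.
#' @return Integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
ring_sites <- function(x, d, L) {
  if (d < 1) stop("d must be >= 1")
  dr <- seq.int(-d, d)
  rem <- d - abs(dr)
  rows <- c(x[[1]] + dr, x[[1]] + dr[rem > 0])
  cols <- c(x[[2]] + rem, x[[2]] - rem[rem > 0])
  keep <- rows >= 1 & rows <= L & cols >= 1 & cols <= L
  cbind(row = rows[keep], col = cols[keep])
}

# Offsets (dr, dc) with 1 <= |dr|+|dc| <= radius, precomputed per radius.
.diamond_offsets <- local({
  cache <- list()
  function(radius) {
    key <- as.character(radius)
    if (is.null(cache[[key]])) {
      g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
      g <- g[abs(g$dr) + abs(g$dc) >= 1 & abs(g$dr) + abs(g$dc) <= radius, ]
      cache[[key]] <<- cbind(dr = g$dr, dc = g$dc,
                             dist = abs(g$dr) + abs(g$dc))
    }
    cache[[key]]
  }
})

#' Check whether a configuration is admissible
#'
#' A configuration is admissible when every pair of cells of types `i` and
#' `j` sits at graph distance at least `D(i, j)` and all border vertices
#' are empty. The check is an all-pairs scan and is intended for
#' validation and testing; the simulation kernel maintains admissibility
#' incrementally.
#'
#' @param config A [lattice_config()] (or a bare state matrix).
#' @param rule An [exclusion_rule()]; defaults to the one attached to
#'   `config`.
#' @return `TRUE` or `FALSE`.
#' @export
is_admissible <- function(config, rule = NULL) {
  if (is.matrix(config)) config <- lattice_config(config, validate = FALSE)
  if (is.null(rule)) rule <- config$rule
  if (!borders_empty(config)) return(FALSE)
  occ <- which(config$state != 0L, arr.ind = TRUE)
  if (nrow(occ) < 2) return(TRUE)
  if (nrow(occ) > 2000) {
    # large configurations: local-scan check in compiled code (equivalent,
    # since any violating pair lies within max(D) - 1 of each other)
    return(kernel_is_admissible(config$state, rule$D))
  }
  types <- config$state[occ]
  # all-pairs L1 distances; configurations checked this way are small
  dr <- outer(occ[, 1], occ[, 1], "-")
  dc <- outer(occ[, 2], occ[, 2], "-")
  dd <- abs(dr) + abs(dc)
  need <- rule$D[cbind(rep(types, each = length(types)),
                       rep(types, times = length(types)))]
  need <- matrix(need, length(types), length(types), byrow = TRUE)
  all(dd[upper.tri(dd)] >= need[upper.tri(need)])
}

#' Can a cell of a given type be placed at a vertex?
#'
#' The placement indicator of the update rule: `TRUE` when putting a
#' type-`i` cell at `x` keeps the configuration admissible. Border
#' vertices can never be occupied. When `ignore` names an occupied site
#' (the would-be migrating cell), that cell is disregarded during the
#' check.
#'
#' @param config A [lattice_config()].
#' @param x Site `c(row, col)` (1-based); must be empty or equal `ignore`.
#' @param type Cell type, 1 or 2.
#' @param rule Exclusion rule; defaults to the configuration's.
#' @param ignore Optional occupied site to disregard.
#' @return `TRUE` or `FALSE`.
#' @export
can_place <- function(config, x, type, rule = NULL, ignore = NULL) {
  if (is.null(rule)) rule <- config$rule
  L <- config$L
  s <- config$state
  r <- x[[1]]; c <- x[[2]]
  if (s[r, c] != 0L &&
      !(length(ignore) && r == ignore[[1]] && c == ignore[[2]])) {
    stop("can_place: site x is occupied and is not the ignored site")
  }
  if (r == 1L || r == L || c == 1L || c == L) return(FALSE)
  radius <- max(rule$D[type, ]) - 1L
  if (radius < 1L) return(TRUE)   # D(i, .) all 1: only double occupancy forbidden
  off <- .diamond_offsets(radius)
  rr <- r + off[, "dr"]; cc <- c + off[, "dc"]
  keep <- rr >= 1 & rr <= L & cc >= 1 & cc <= L
  rr <- rr[keep]; cc <- cc[keep]; dd <- off[keep, "dist"]
  if (length(ignore)) {
    drop <- rr == ignore[[1]] & cc == ignore[[2]]
    rr <- rr[!drop]; cc <- cc[!drop]; dd <- dd[!drop]
  }
  occ <- s[cbind(rr, cc)]
  here <- occ != 0L
  if (!any(here)) return(TRUE)
  all(dd[here] >= rule$D[type, occ[here]])
}

#' Count donor cells for an empty vertex
#'
#' The number of type-`i` cells on the ring at graph distance exactly
#' `D(i, i)` from the empty vertex `x` -- its nearest allowed same-type
#' neighbors, each a potential parent (division) or migrant (migration).
#'
#' @inheritParams can_place
#' @return Nonnegative integer count.
#' @export
count_donors <- function(config, x, type, rule = NULL) {
  if (is.null(rule)) rule <- config$rule
  if (config$state[x[[1]], x[[2]]] != 0L) stop("count_donors: x must be empty")
  ring <- ring_sites(x, rule$D[type, type], config$L)
  if (nrow(ring) == 0) return(0L)
  sum(config$state[ring] == type)
}

#' Empty receiver sites for a migrating cell
#'
#' For a cell of type `i` at `x`, the empty vertices on the ring at
#' distance `D(i, i)` that can receive it without violating admissibility
#' (the migrating cell itself is disregarded during the check).
#'
#' @inheritParams can_place
#' @param x Site occupied by a cell of type `type`.
#' @return A list with `count` and `sites` (matrix of rows `row,col`).
#' @export
count_empty_receivers <- function(config, x, type, rule = NULL) {
  if (is.null(rule)) rule <- config$rule
  if (config$state[x[[1]], x[[2]]] != type) {
    stop("count_empty_receivers: x must hold a cell of the stated type")
  }
  ring <- ring_sites(x, rule$D[type, type], config$L)
  ok <- logical(nrow(ring))
  for (k in seq_len(nrow(ring))) {
    y <- ring[k, ]
    ok[k] <- config$state[y[1], y[2]] == 0L &&
      can_place(config, y, type, rule, ignore = x)
  }
  list(count = sum(ok), sites = ring[ok, , drop = FALSE])
}

#' Per-type cell densities of a configuration
#'
#' Fraction of grid vertices occupied by each type. By default the
#' denominator is the full `L^2` vertex count (border included); with
#' `interior = TRUE` only the `(L-2)^2` interior vertices are counted.
#'
#' @param config A [lattice_config()] or state matrix.
#' @param interior Use interior vertices only as denominator.
#' @return Named numeric vector `c(density1, density2)`.
#' @export
cell_densities <- function(config, interior = FALSE) {
  s <- if (is.matrix(config)) config else config$state
  L <- nrow(s)
  if (interior) {
    s <- s[2:(L - 1), 2:(L - 1), drop = FALSE]
    denom <- (L - 2)^2
  } else {
    denom <- L^2
  }
  c(density1 = sum(s == 1L) / denom, density2 = sum(s == 2L) / denom)
}
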
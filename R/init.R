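# Admissible initial configurations: uniform random sequential insertion
# with rejection, and the densest single-type packings.

# Analytic interior capacity (cell count) of a single type under its
# self-exclusion distance: full interior for D = 1, the parity
# checkerboard for D = 2.
single_type_capacity <- function(L, d_self) {
  interior <- (L - 2L)^2
  if (d_self == 1L) return(interior)
  if (d_self == 2L) return(ceiling(interior / 2))
  # coarse bound for larger exclusion: one cell per diamond of radius
  # floor(d/2); only used for the feasibility guard
  floor(interior / (d_self^2 / 2))
}

#' Random admissible initial configuration
#'
#' Places exact per-type cell counts (`round(density * L^2)`, half-up) at
#' uniformly random interior vertices by sequential insertion with
#' admissibility rejection. The species with the larger self-exclusion
#' distance is placed first by default, which improves feasibility at
#' higher target densities. Deterministic given the RNG state (call
#' `set.seed()` first, or go through [run_simulation()] which seeds).
#'
#' Targets above 90% of the analytic single-type packing capacity are
#' refused outright rather than attempted: random sequential insertion
#' jams well below the ordered-packing density.
#'
#' @param L Grid side length.
#' @param rule An [exclusion_rule()].
#' @param densities Length-2 numeric, target occupied fraction of the
#'   `L^2` vertices for types 1 and 2.
#' @param order Placement order of the types (default: larger
#'   self-exclusion first).
#' @param max_attempts Random placement attempts allowed per cell before
#'   declaring a jam.
#' @return An admissible [lattice_config()].
#' @export
random_admissible_init <- function(L, rule = exclusion_rule(),
                                   densities = c(0.01, 0.09),
                                   order = NULL,
                                   max_attempts = 500L) {
  stopifnot(length(densities) == 2, all(densities >= 0), sum(densities) <= 1)
  counts <- floor(densities * L^2 + 0.5)   # round half-up
  for (i in 1:2) {
    cap <- single_type_capacity(L, rule$D[i, i])
    if (counts[i] > 0.9 * cap) {
      stop(sprintf(
        "type %d target count %d exceeds 90%% of its packing capacity (%d)",
        i, counts[i], cap))
    }
  }
  if (is.null(order)) order <- order(diag(rule$D), decreasing = TRUE)
  state <- matrix(0L, L, L)
  cfg <- lattice_config(state, rule, validate = FALSE)
  for (i in order) {
    placed <- 0L
    attempts <- 0L
    while (placed < counts[i]) {
      r <- sample.int(L - 2L, 1L) + 1L
      c <- sample.int(L - 2L, 1L) + 1L
      if (cfg$state[r, c] == 0L && can_place(cfg, c(r, c), i, rule)) {
        cfg$state[r, c] <- as.integer(i)
        placed <- placed + 1L
        attempts <- 0L
      } else {
        attempts <- attempts + 1L
        if (attempts >= max_attempts) {
          stop(sprintf(
            "could not place cell %d of %d for type %d after %d attempts (jammed)",
            placed + 1L, counts[i], i, max_attempts))
        }
      }
    }
  }
  cfg
}

#' Densest single-type packing
#'
#' The maximal admissible arrangement of a single cell type on the
#' interior of the grid: for self-exclusion distance 1, every interior
#' vertex is occupied; for distance 2, the even-parity checkerboard of
#' the interior (interior density 1/2 up to parity rounding). These are
#' the packings against which the capacity of each type is understood:
#' density is inversely related to the self-exclusion distance.
#'
#' @param type Cell type (1 or 2).
#' @param L Grid side length.
#' @param rule An [exclusion_rule()].
#' @return An admissible [lattice_config()].
#' @export
dense_packing <- function(type, L, rule = exclusion_rule()) {
  d <- rule$D[type, type]
  state <- matrix(0L, L, L)
  idx <- 2:(L - 1)
  if (d == 1L) {
    state[idx, idx] <- as.integer(type)
  } else if (d == 2L) {
    for (r in idx) for (c in idx) {
      if ((r + c) %% 2 == 0) state[r, c] <- as.integer(type)
    }
  } else {
    stop("dense_packing is defined for self-exclusion distances 1 and 2 only")
  }
  lattice_config(state, rule, validate = FALSE)
}
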
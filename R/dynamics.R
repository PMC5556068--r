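# Discrete-time Markov chain on admissible configurations.
#
# One step: pick a vertex uniformly over all L^2 vertices. At an occupied
# vertex the cell is quiescent, dies, or migrates to an admissible empty
# ring site; at an empty vertex nothing happens, or a cell of type i is
# born from / migrates in from one of its nearest allowed neighbors,
# subject to the placement indicator. The analytic per-vertex outcome
# distributions here are the reference; the compiled kernel in src/
# implements the same rule for long runs and is cross-checked against
# them in the test suite.

#' Per-type event rates
#'
#' Division, migration and death weights per cell type. These are
#' dimensionless weights entering the per-vertex outcome distributions,
#' not rates per unit physical time.
#'
#' @param division Length-2 numeric, division weight `alpha_i` per type.
#' @param migration Length-2 numeric, migration weight `delta_i`.
#' @param death Length-2 numeric, death weight `rho_i`.
#' @return An object of class `rate_set`.
#' @examples
#' rate_set()  # the default co-culture parameterization
#' @export
rate_set <- function(division = c(0.1, 0.1),
                     migration = c(0.001, 0.001),
                     death = c(0.01, 0.01)) {
  stopifnot(length(division) == 2, length(migration) == 2, length(death) == 2)
  if (any(c(division, migration, death) < 0)) stop("rates must be nonnegative")
  if (any(division + death == 0)) {
    stop("each type needs division or death positive (normalizers vanish otherwise)")
  }
  structure(list(division = as.numeric(division),
                 migration = as.numeric(migration),
                 death = as.numeric(death)),
            class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("rates: division (%g, %g)  migration (%g, %g)  death (%g, %g)\n",
              x$division[1], x$division[2], x$migration[1], x$migration[2],
              x$death[1], x$death[2]))
  invisible(x)
}

#' Simulation parameter bundle
#'
#' @param L Grid side length (vertices); must satisfy
#'   `L >= 2 * max(D) + 2` so the interior is nonempty at every exclusion
#'   radius.
#' @param rule An [exclusion_rule()].
#' @param rates A [rate_set()].
#' @param seed Integer RNG seed for the run.
#' @param n_steps Total vertex-selection steps.
#' @param record_every Recording stride for the density trajectory.
#' @param init_density Length-2 target occupied fractions (type 1, type 2)
#'   for the random initial configuration.
#' @param density_interior If `TRUE`, densities are reported over the
#'   `(L-2)^2` interior vertices instead of all `L^2`.
#' @return An object of class `model_params`.
#' @export
model_params <- function(L = 200L, rule = exclusion_rule(),
                         rates = rate_set(), seed = 1L,
                         n_steps = 1e5, record_every = max(1, floor(n_steps / 200)),
                         init_density = c(0.01, 0.09),
                         density_interior = FALSE) {
  L <- as.integer(L)
  if (L < 2L * max(rule$D) + 2L) stop("L too small for the exclusion distances")
  if (n_steps < 0) stop("n_steps must be >= 0")
  structure(list(L = L, rule = rule, rates = rates, seed = as.integer(seed),
                 n_steps = n_steps, record_every = record_every,
                 init_density = init_density,
                 density_interior = isTRUE(density_interior)),
            class = "model_params")
}

#' Parameterization of the default in-silico co-culture experiment
#'
#' The reference parameter set: a 200 x 200 grid with empty borders,
#' exclusion distances `D(1,1)=1, D(1,2)=3, D(2,2)=2`, rates
#' `alpha = 0.1`, `rho = 0.01`, `delta = 0.001` for both types, and
#' initial densities 0.01 (tumor) and 0.09 (normal). Scale arguments let
#' the same experiment be run desk-size.
#'
#' @param L Grid side (default 200).
#' @param n_steps Steps (default 1e5).
#' @param seed RNG seed.
#' @param ... Passed on to [model_params()].
#' @return A [model_params()] object.
#' @export
coculture_params <- function(L = 200L, n_steps = 1e5, seed = 1L, ...) {
  model_params(L = L, rule = exclusion_rule(1L, 3L, 2L),
               rates = rate_set(division = c(0.1, 0.1),
                                migration = c(0.001, 0.001),
                                death = c(0.01, 0.01)),
               seed = seed, n_steps = n_steps,
               init_density = c(0.01, 0.09), ...)
}

.new_update_distribution <- function(outcomes, normalizer) {
  stopifnot(abs(sum(outcomes$prob) - 1) < 1e-12)
  structure(list(outcomes = outcomes, normalizer = normalizer),
            class = "update_distribution")
}

#' @export
print.update_distribution <- function(x, ...) {
  cat(sprintf("update distribution (normalizer %.6g):\n", x$normalizer))
  print(x$outcomes, row.names = FALSE)
  invisible(x)
}

#' Outcome distribution at an occupied vertex
#'
#' For a vertex holding a cell of type `i` with rates
#' `(alpha_i, delta_i, rho_i)` and `n_e` admissible empty receiver sites
#' on the ring at distance `D(i, i)`, the normalizer is
#' `Q = alpha_i + n_e * delta_i + rho_i` and the outcomes are quiescence
#' with probability `alpha_i / Q`, death with `rho_i / Q`, and migration
#' to each receiver with `delta_i / Q` (destination uniform among the
#' `n_e` receivers).
#'
#' @param config A [lattice_config()].
#' @param x Occupied site `c(row, col)`.
#' @param params A [model_params()].
#' @return An `update_distribution` whose `outcomes` data frame has
#'   columns `event`, `type`, `row`, `col`, `prob`.
#' @export
occupied_update_distribution <- function(config, x, params) {
  i <- config$state[x[[1]], x[[2]]]
  if (i == 0L) stop("occupied_update_distribution: vertex is empty")
  a <- params$rates$division[i]
  d <- params$rates$migration[i]
  r <- params$rates$death[i]
  recv <- count_empty_receivers(config, x, i, params$rule)
  Q <- a + recv$count * d + r
  if (Q == 0) stop("degenerate occupied-vertex distribution: Q = 0")
  out <- data.frame(event = c("quiescence", "death"),
                    type = c(i, i), row = NA_integer_, col = NA_integer_,
                    prob = c(a / Q, r / Q))
  if (recv$count > 0 && d > 0) {
    out <- rbind(out, data.frame(event = "migrate_out", type = i,
                                 row = recv$sites[, 1], col = recv$sites[, 2],
                                 prob = rep(d / Q, recv$count)))
  }
  out <- out[out$prob > 0 | out$event %in% c("quiescence", "death"), ]
  .new_update_distribution(out, Q)
}

#' Outcome distribution at an empty vertex
#'
#' For an empty vertex `x`, with `n_i` type-`i` donors on the ring at
#' distance `D(i, i)` and placement indicator `I(i)` (1 when a type-`i`
#' cell may occupy `x` admissibly, always 0 on the border), the
#' normalizer is
#' `R = rho_1 + rho_2 + sum_i n_i (alpha_i + delta_i) I(i)`. The vertex
#' stays empty with probability `(rho_1 + rho_2) / R`; a type-`i` cell is
#' born there with `n_i alpha_i I(i) / R` (the parent remains in place);
#' a type-`i` cell migrates in from each donor with `delta_i I(i) / R`
#' (source uniform among the `n_i` donors, vacated on arrival). When
#' `R = rho_1 + rho_2` the vertex remains empty with probability 1.
#'
#' @inheritParams occupied_update_distribution
#' @param x Empty site.
#' @return An `update_distribution`.
#' @export
empty_update_distribution <- function(config, x, params) {
  if (config$state[x[[1]], x[[2]]] != 0L) {
    stop("empty_update_distribution: vertex is occupied")
  }
  rule <- params$rule
  rho <- params$rates$death
  R <- sum(rho)
  rows <- data.frame(event = "stay_empty", type = NA_integer_,
                     row = NA_integer_, col = NA_integer_, prob = sum(rho))
  for (i in 1:2) {
    ring <- ring_sites(x, rule$D[i, i], config$L)
    donors <- ring[config$state[ring] == i, , drop = FALSE]
    n_i <- nrow(donors)
    if (n_i == 0) next
    I_i <- can_place(config, x, i, rule)
    if (!I_i) next
    a <- params$rates$division[i]
    d <- params$rates$migration[i]
    R <- R + n_i * (a + d)
    if (a > 0) {
      rows <- rbind(rows, data.frame(event = "birth", type = i,
                                     row = NA_integer_, col = NA_integer_,
                                     prob = n_i * a))
    }
    if (d > 0) {
      rows <- rbind(rows, data.frame(event = "migrate_in", type = i,
                                     row = donors[, 1], col = donors[, 2],
                                     prob = rep(d, n_i)))
    }
  }
  if (R == sum(rho)) {
    rows <- data.frame(event = "stay_empty", type = NA_integer_,
                       row = NA_integer_, col = NA_integer_, prob = 1)
    return(.new_update_distribution(rows, R))
  }
  rows$prob <- rows$prob / R
  .new_update_distribution(rows, R)
}

#' One Markov-chain step (reference implementation)
#'
#' Selects a vertex uniformly over all `L^2` vertices (border included;
#' border selections always resolve to stay-empty), samples the
#' appropriate per-vertex outcome distribution with R's RNG, and applies
#' the event. This pure-R path mirrors the compiled kernel and is used
#' for small-scale testing; long runs go through [run_simulation()].
#'
#' @param config A [lattice_config()].
#' @param params A [model_params()].
#' @return A list with `config` (updated) and `event` (a one-row data
#'   frame: site, event, type, target site).
#' @export
step_chain <- function(config, params) {
  L <- config$L
  v <- sample.int(L * L, 1L) - 1L
  x <- c(v %% L + 1L, v %/% L + 1L)
  state_x <- config$state[x[1], x[2]]
  dist <- if (state_x == 0L) {
    empty_update_distribution(config, x, params)
  } else {
    occupied_update_distribution(config, x, params)
  }
  k <- sample.int(nrow(dist$outcomes), 1L, prob = dist$outcomes$prob)
  ev <- dist$outcomes[k, ]
  config <- apply_event(config, x, ev)
  list(config = config,
       event = data.frame(row = x[1], col = x[2], event = ev$event,
                          type = ev$type, target_row = ev$row,
                          target_col = ev$col))
}

apply_event <- function(config, x, ev) {
  s <- config$state
  switch(ev$event,
         quiescence = , stay_empty = NULL,
         death = { s[x[1], x[2]] <- 0L },
         migrate_out = {
           s[ev$row, ev$col] <- s[x[1], x[2]]
           s[x[1], x[2]] <- 0L
         },
         birth = { s[x[1], x[2]] <- as.integer(ev$type) },
         migrate_in = {
           s[ev$row, ev$col] <- 0L
           s[x[1], x[2]] <- as.integer(ev$type)
         },
         stop("unknown event: ", ev$event))
  config$state <- s
  config
}

#' Run a seeded simulation
#'
#' Builds (or accepts) an admissible initial configuration, iterates the
#' chain `n_steps` times through the compiled kernel, and records per-type
#' densities every `record_every` steps plus the initial and final state.
#' Fully reproducible given the seed and parameters.
#'
#' @param params A [model_params()].
#' @param init Optional [lattice_config()] to start from (defaults to
#'   [random_admissible_init()] at `params$init_density`).
#' @param snapshot_steps Numeric vector of step indices at which to store
#'   full configuration snapshots (0 = initial state).
#' @param validate Admissibility checking during the run: `"none"`
#'   (default), `"local"` (re-check the changed neighborhood after every
#'   event), or `"full"` (additionally run the all-pairs check every
#'   `validate_full_every` steps). Any violation aborts with an error.
#' @param validate_full_every Stride for the full check (with
#'   `validate = "full"`).
#' @return An object of class `sim_run`: list with `trajectory` (data
#'   frame `step, density1, density2, ratio`), `snapshots` (named list of
#'   [lattice_config()]s), `final_config`, and `params`. The ratio is
#'   `density2 / density1`, `NA` where the denominator is 0.
#' @export
run_simulation <- function(params, init = NULL, snapshot_steps = numeric(0),
                           validate = c("none", "local", "full"),
                           validate_full_every = 1e4) {
  validate <- match.arg(validate)
  set.seed(params$seed)
  if (is.null(init)) {
    init <- random_admissible_init(params$L, params$rule, params$init_density)
  } else {
    stopifnot(inherits(init, "lattice_config"), init$L == params$L)
    if (!is_admissible(init, params$rule)) stop("initial configuration inadmissible")
  }
  res <- kernel_run(init$state, params$rule$D,
                    params$rates$division, params$rates$migration,
                    params$rates$death,
                    as.numeric(params$n_steps), as.numeric(params$record_every),
                    as.numeric(sort(unique(snapshot_steps))),
                    validate != "none",
                    if (validate == "full") as.numeric(validate_full_every) else 0)
  denom <- if (params$density_interior) (params$L - 2)^2 else params$L^2
  d1 <- res$count1 / denom
  d2 <- res$count2 / denom
  traj <- data.frame(step = res$steps, density1 = d1, density2 = d2,
                     ratio = ifelse(d1 > 0, d2 / d1, NA_real_))
  snaps <- lapply(res$snapshots, function(s) {
    lattice_config(s, params$rule, validate = FALSE)
  })
  names(snaps) <- as.character(res$snapshot_steps)
  structure(list(trajectory = traj, snapshots = snaps,
                 final_config = lattice_config(res$state, params$rule,
                                               validate = FALSE),
                 params = params),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  n <- nrow(x$trajectory)
  cat(sprintf("sim_run: L=%d, %s steps, %d records, final densities %.4f / %.4f\n",
              x$params$L, format(x$params$n_steps, big.mark = ","), n,
              x$trajectory$density1[n], x$trajectory$density2[n]))
  invisible(x)
}

#' Robustness sweep over the division-rate ratio
#'
#' Re-runs the co-culture experiment for a range of division-rate ratios
#' `alpha_2 / alpha_1` (with `alpha_1` fixed), `n_reps` independent
#' repetitions each, and reports the repetition mean and standard
#' deviation of the final per-type densities. Each repetition uses a seed
#' derived deterministically from `base_params$seed`, the ratio index and
#' the repetition index, so results are independent of evaluation order.
#'
#' @param base_params A [model_params()]; its `rates$division[1]` is the
#'   fixed `alpha_1`.
#' @param ratios Numeric vector of `alpha_2 / alpha_1` values (default
#'   `1:10`).
#' @param n_reps Repetitions per ratio.
#' @param n_steps Steps per run (defaults to `base_params$n_steps`).
#' @return A data frame with one row per ratio: `ratio`, `mean1`, `sd1`,
#'   `mean2`, `sd2`, `n_reps`. With `n_reps = 1` the sd columns are `NA`.
#' @export
sweep_alpha_ratio <- function(base_params, ratios = 1:10, n_reps = 10,
                              n_steps = base_params$n_steps) {
  res <- vector("list", length(ratios))
  for (k in seq_along(ratios)) {
    fin <- matrix(NA_real_, n_reps, 2)
    for (j in seq_len(n_reps)) {
      p <- base_params
      p$rates$division[2] <- p$rates$division[1] * ratios[k]
      p$n_steps <- n_steps
      p$record_every <- n_steps   # only initial + final needed
      p$seed <- derive_seed(base_params$seed, k, j)
      run <- run_simulation(p)
      n <- nrow(run$trajectory)
      fin[j, ] <- c(run$trajectory$density1[n], run$trajectory$density2[n])
    }
    res[[k]] <- data.frame(ratio = ratios[k],
                           mean1 = mean(fin[, 1]),
                           sd1 = if (n_reps > 1) stats::sd(fin[, 1]) else NA_real_,
                           mean2 = mean(fin[, 2]),
                           sd2 = if (n_reps > 1) stats::sd(fin[, 2]) else NA_real_,
                           n_reps = n_reps)
  }
  do.call(rbind, res)
}

# Deterministic per-repetition seed, kept within the 32-bit integer range.
derive_seed <- function(seed, ratio_index, rep_index) {
  as.integer((as.numeric(seed) * 7919 + ratio_index * 613 + rep_index * 31 + 17) %%
               2147483647)
}

#' Crossing summaries of a robustness sweep
#'
#' Two summaries of a [sweep_alpha_ratio()] table: the ratio whose
#' repetition-mean final densities are closest to equal
#' (`crossing_ratio`), and the smallest ratio at which the mean type-2
#' density strictly exceeds the type-1 density (`first_type2_prevails`,
#' `NA` when type 2 never prevails in the sweep range).
#'
#' @param sweep Output of [sweep_alpha_ratio()].
#' @return Named list with `crossing_ratio` and `first_type2_prevails`.
#' @export
sweep_crossing <- function(sweep) {
  gap <- abs(sweep$mean2 - sweep$mean1)
  prevails <- sweep$ratio[sweep$mean2 > sweep$mean1]
  list(crossing_ratio = sweep$ratio[which.min(gap)],
       first_type2_prevails = if (length(prevails)) min(prevails) else NA_real_)
}
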
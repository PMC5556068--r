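# Per-vertex update distributions and the chain itself.

paper_rates <- function() {
  rate_set(division = c(0.1, 0.1), migration = c(0.001, 0.001),
           death = c(0.01, 0.01))
}

test_that("rate sets reject configurations with vanishing normalizers", {
  expect_error(rate_set(division = c(0, 0.1), death = c(0, 0.01)),
               "division or death")
  expect_error(rate_set(division = c(-0.1, 0.1)), "nonnegative")
  expect_s3_class(rate_set(division = c(0, 0.1), death = c(0.01, 0)),
                  "rate_set")
})

test_that("occupied-vertex distribution matches the Q-normalized weights", {
  params <- model_params(L = 11, rates = paper_rates(), n_steps = 1)
  # a lone tumor cell: all 4 ring sites receive, Q = 0.1 + 4*0.001 + 0.01
  s <- matrix(0L, 11, 11); s[6, 6] <- 1L
  cfg <- lattice_config(s, params$rule)
  d <- occupied_update_distribution(cfg, c(6, 6), params)
  expect_equal(d$normalizer, 0.114)
  probs <- stats::setNames(d$outcomes$prob, d$outcomes$event)
  expect_equal(unname(probs["quiescence"]), 0.1 / 0.114, tolerance = 1e-12)
  expect_equal(unname(probs["death"]), 0.01 / 0.114, tolerance = 1e-12)
  expect_equal(sum(d$outcomes$event == "migrate_out"), 4)
  expect_equal(d$outcomes$prob[d$outcomes$event == "migrate_out"],
               rep(0.001 / 0.114, 4))
  expect_equal(sum(d$outcomes$prob), 1, tolerance = 1e-12)

  # enclosed cell: no receivers, Q = 0.11
  full <- dense_packing(1, 11, params$rule)
  d0 <- occupied_update_distribution(full, c(6, 6), params)
  expect_equal(d0$normalizer, 0.11)
  expect_equal(d0$outcomes$prob[d0$outcomes$event == "quiescence"],
               0.1 / 0.11, tolerance = 1e-12)
  expect_equal(d0$outcomes$prob[d0$outcomes$event == "death"],
               0.01 / 0.11, tolerance = 1e-12)
  expect_false("migrate_out" %in% d0$outcomes$event)

  expect_error(occupied_update_distribution(cfg, c(2, 2), params), "empty")
})

test_that("empty-vertex distribution matches the R-normalized weights", {
  params <- model_params(L = 11, rates = paper_rates(), n_steps = 1)
  # isolated empty vertex: stays empty with probability 1
  empty <- lattice_config(matrix(0L, 11, 11), params$rule)
  d <- empty_update_distribution(empty, c(6, 6), params)
  expect_equal(d$outcomes$event, "stay_empty")
  expect_equal(d$outcomes$prob, 1)

  # three tumor donors at distance 1, placement allowed:
  # R = 0.02 + 3 * 0.101 = 0.323
  s <- matrix(0L, 11, 11)
  s[5, 6] <- 1L; s[7, 6] <- 1L; s[6, 5] <- 1L
  cfg <- lattice_config(s, params$rule)
  d3 <- empty_update_distribution(cfg, c(6, 6), params)
  expect_equal(d3$normalizer, 0.323)
  probs <- d3$outcomes
  expect_equal(probs$prob[probs$event == "stay_empty"], 0.02 / 0.323,
               tolerance = 1e-12)
  expect_equal(probs$prob[probs$event == "birth"], 3 * 0.1 / 0.323,
               tolerance = 1e-12)
  mig <- probs[probs$event == "migrate_in", ]
  expect_equal(nrow(mig), 3)
  expect_equal(mig$prob, rep(0.001 / 0.323, 3))
  expect_equal(sum(probs$prob), 1, tolerance = 1e-12)

  # a vertex shadowed by normal cells: no tumor events despite donors
  s <- matrix(0L, 11, 11)
  s[4, 6] <- 1L          # tumor donor at distance 1 from (5, 6)
  s[7, 6] <- 2L          # normal cell at distance 2 from (5, 6)
  cfg <- lattice_config(s, params$rule)
  dsh <- empty_update_distribution(cfg, c(5, 6), params)
  expect_false(any(dsh$outcomes$type %in% 1))
  expect_equal(dsh$outcomes$event, "stay_empty")  # type 2 blocked by the donor

  expect_error(empty_update_distribution(cfg, c(4, 6), params), "occupied")

  # border vertices always stay empty
  db <- empty_update_distribution(cfg, c(1, 6), params)
  expect_equal(db$outcomes$event, "stay_empty")
  expect_equal(db$outcomes$prob, 1)
})

test_that("update distributions normalize at random vertices", {
  set.seed(5)
  params <- model_params(L = 12, rates = paper_rates(), n_steps = 1)
  for (k in 1:15) {
    s <- random_admissible_state(12, params$rule)
    cfg <- lattice_config(s, params$rule, validate = FALSE)
    for (j in 1:10) {
      x <- c(sample.int(12, 1), sample.int(12, 1))
      d <- if (s[x[1], x[2]] == 0L) {
        empty_update_distribution(cfg, x, params)
      } else {
        occupied_update_distribution(cfg, x, params)
      }
      expect_equal(sum(d$outcomes$prob), 1, tolerance = 1e-12)
      expect_true(all(d$outcomes$prob >= 0))
    }
  }
})

test_that("kernel sampling agrees with the analytic distributions", {
  cfg <- fixture_9x9()
  params <- model_params(L = 9, rates = paper_rates(), n_steps = 1)
  n <- 2e4
  set.seed(42)
  for (x in list(c(3, 3), c(7, 7), c(6, 6))) {
    freq <- kernel_frequencies(cfg, x, params, n)
    probs <- analytic_probs(cfg, x, params)
    expect_frequencies_match(freq, probs, n)
  }
})

test_that("single steps preserve admissibility and change counts by <= 1", {
  set.seed(9)
  params <- model_params(L = 12, rates = paper_rates(), n_steps = 1)
  cfg <- lattice_config(random_admissible_state(12, params$rule),
                        params$rule, validate = FALSE)
  for (k in 1:300) {
    before <- c(sum(cfg$state == 1L), sum(cfg$state == 2L))
    res <- step_chain(cfg, params)
    cfg <- res$config
    after <- c(sum(cfg$state == 1L), sum(cfg$state == 2L))
    expect_true(all(abs(after - before) <= 1))
    expect_true(bf_admissible(cfg$state, params$rule$D))
  }
})

test_that("all-empty grid is a fixed point of the step", {
  set.seed(3)
  params <- model_params(L = 10, rates = paper_rates(), n_steps = 1)
  cfg <- lattice_config(matrix(0L, 10, 10), params$rule)
  for (k in 1:50) {
    res <- step_chain(cfg, params)
    expect_true(all(res$config$state == 0L))
    cfg <- res$config
  }
})

test_that("death-free chains never lose cells; death-only chains empty out", {
  # delta = rho = 0: counts are non-decreasing
  p <- model_params(L = 20, rates = rate_set(division = c(0.1, 0.1),
                                             migration = c(0, 0),
                                             death = c(0, 0)),
                    seed = 4, n_steps = 1e5, record_every = 1e3)
  run <- run_simulation(p)
  tot <- run$trajectory$density1 + run$trajectory$density2
  expect_true(all(diff(run$trajectory$density1) >= 0))
  expect_true(all(diff(run$trajectory$density2) >= 0))
  expect_gt(tot[length(tot)], tot[1])

  # alpha = delta = 0, rho > 0: absorbing at the empty configuration
  p2 <- model_params(L = 20, rates = rate_set(division = c(0, 0),
                                              migration = c(0, 0),
                                              death = c(0.05, 0.05)),
                     seed = 5, n_steps = 3e5, record_every = 1e4,
                     init_density = c(0.05, 0.1))
  run2 <- run_simulation(p2)
  n <- nrow(run2$trajectory)
  expect_equal(run2$trajectory$density1[n], 0)
  expect_equal(run2$trajectory$density2[n], 0)
})

test_that("runs are reproducible and respect trajectory invariants", {
  p <- coculture_params(L = 40, n_steps = 2e5, seed = 77)
  r1 <- run_simulation(p, snapshot_steps = c(0, 1e5))
  r2 <- run_simulation(p, snapshot_steps = c(0, 1e5))
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_config$state, r2$final_config$state)
  tr <- r1$trajectory
  expect_true(all(diff(tr$step) > 0))
  expect_true(all(tr$density1 >= 0 & tr$density1 <= 1))
  expect_true(all(tr$density2 >= 0 & tr$density2 <= 1))
  expect_true(all(tr$density1 + tr$density2 <= 1))
  expect_named(r1$snapshots, c("0", "1e+05"))
  expect_true(is_admissible(r1$snapshots[[1]]))
  expect_true(is_admissible(r1$final_config))
  # n_steps = 0: trajectory holds only the initial densities
  p0 <- coculture_params(L = 40, n_steps = 0, seed = 77)
  p0$record_every <- 1
  r0 <- run_simulation(p0)
  expect_equal(nrow(r0$trajectory), 1)
  expect_equal(r0$trajectory$step, 0)
})

test_that("equal rates with unequal self-exclusion favor the tumor share", {
  # with identical rates and D(1,1) < D(2,2), the repetition-mean tumor
  # share of the population rises over the run
  share <- sapply(1:20, function(s) {
    p <- coculture_params(L = 40, n_steps = 1e6, seed = 700 + s)
    p$record_every <- 2.5e5
    tr <- run_simulation(p)$trajectory
    tr$density1 / (tr$density1 + tr$density2)
  })
  mean_share <- rowMeans(share)
  expect_equal(mean_share[1], 0.1, tolerance = 1e-12)  # 0.01 of 0.10
  expect_true(all(diff(mean_share) > 0))
})

test_that("swapping type labels and parameters swaps the outcome", {
  # relabeling symmetry at reduced scale: same exclusion for both type
  # orderings, mirrored rates, mirrored initial densities
  run_once <- function(swapped, seed) {
    rule <- if (!swapped) exclusion_rule(1, 3, 2) else exclusion_rule(2, 3, 1)
    init <- if (!swapped) c(0.02, 0.06) else c(0.06, 0.02)
    p <- model_params(L = 30, rule = rule, rates = paper_rates(), seed = seed,
                      n_steps = 4e5, record_every = 4e5, init_density = init)
    tr <- run_simulation(p)$trajectory
    n <- nrow(tr)
    c(tr$density1[n], tr$density2[n])
  }
  base <- rowMeans(sapply(1:8, function(s) run_once(FALSE, s)))
  swap <- rowMeans(sapply(1:8, function(s) run_once(TRUE, 100 + s)))
  # swapped means agree after exchanging the labels, within MC error
  expect_lt(max(abs(base - rev(swap))), 0.15)
})

test_that("sweep table reports means, sds and derived seeds correctly", {
  p <- coculture_params(L = 30, n_steps = 5e4, seed = 10)
  sw <- sweep_alpha_ratio(p, ratios = c(1, 5), n_reps = 3, n_steps = 5e4)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$ratio, c(1, 5))
  expect_true(all(is.finite(sw$mean1)))
  expect_true(all(sw$n_reps == 3))
  # single repetition: sd is the NA sentinel
  sw1 <- sweep_alpha_ratio(p, ratios = 1, n_reps = 1, n_steps = 2e4)
  expect_true(is.na(sw1$sd1) && is.na(sw1$sd2))
  # derived seeds are distinct across repetitions and ratios
  seeds <- c(sapply(1:10, function(k) sapply(1:10, function(j)
    exclusim:::derive_seed(10, k, j))))
  expect_equal(anyDuplicated(seeds), 0)
  # crossing summaries on a synthetic table
  tab <- data.frame(ratio = 1:4, mean1 = c(0.8, 0.5, 0.2, 0.1),
                    mean2 = c(0.1, 0.3, 0.25, 0.4))
  cr <- sweep_crossing(tab)
  expect_equal(cr$crossing_ratio, 3)
  expect_equal(cr$first_type2_prevails, 3)
})
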
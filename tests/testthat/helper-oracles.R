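# Independent brute-force oracles and small hand-built configurations.
# These deliberately avoid the package's own fast paths: admissibility by
# an all-pairs double loop, region properties by flood fill.

# All-pairs admissibility check by explicit double loop over occupied
# sites (plus the empty-border rule).
bf_admissible <- function(state, D) {
  L <- nrow(state)
  if (any(state[c(1, L), ] != 0) || any(state[, c(1, L)] != 0)) return(FALSE)
  occ <- which(state != 0, arr.ind = TRUE)
  if (nrow(occ) < 2) return(TRUE)
  for (a in seq_len(nrow(occ) - 1)) {
    for (b in (a + 1):nrow(occ)) {
      dd <- abs(occ[a, 1] - occ[b, 1]) + abs(occ[a, 2] - occ[b, 2])
      if (dd < D[state[occ[a, 1], occ[a, 2]], state[occ[b, 1], occ[b, 2]]]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Random (not necessarily admissible) state matrix with empty borders.
random_state <- function(L, p_occupied = 0.2) {
  s <- matrix(sample(0:2, L * L, replace = TRUE,
                     prob = c(1 - p_occupied, p_occupied / 2, p_occupied / 2)),
              L, L)
  s[c(1, L), ] <- 0L
  s[, c(1, L)] <- 0L
  storage.mode(s) <- "integer"
  s
}

# Random admissible configuration built by rejection over random states
# of decreasing density (small grids only).
random_admissible_state <- function(L, rule, target = 0.15) {
  repeat {
    s <- random_state(L, target)
    occ <- which(s != 0, arr.ind = TRUE)
    # greedy repair: drop cells that violate the rule
    keep <- rep(TRUE, nrow(occ))
    for (a in seq_len(nrow(occ))) {
      if (!keep[a]) next
      for (b in seq_len(nrow(occ))) {
        if (a == b || !keep[b]) next
        dd <- abs(occ[a, 1] - occ[b, 1]) + abs(occ[a, 2] - occ[b, 2])
        if (dd < rule$D[s[occ[a, 1], occ[a, 2]], s[occ[b, 1], occ[b, 2]]]) {
          keep[b] <- FALSE
        }
      }
    }
    drop <- occ[!keep, , drop = FALSE]
    s[drop] <- 0L
    if (bf_admissible(s, rule$D)) return(s)
  }
}

# Flood-fill region labelling oracle (recursive stack, 4- or 8-conn).
bf_label <- function(bin, connectivity = 8) {
  n <- nrow(bin); m <- ncol(bin)
  lab <- matrix(0L, n, m)
  cur <- 0L
  offs <- if (connectivity == 8) {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
         c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  } else {
    list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  }
  for (r0 in 1:n) for (c0 in 1:m) {
    if (!bin[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        rr <- p[1] + o[1]; cc <- p[2] + o[2]
        if (rr >= 1 && rr <= n && cc >= 1 && cc <= m &&
            bin[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Pixel-walk area and boundary-edge perimeter of one labelled region.
bf_region_area_perimeter <- function(lab, id) {
  n <- nrow(lab); m <- ncol(lab)
  area <- 0L; per <- 0L
  for (r in 1:n) for (c in 1:m) {
    if (lab[r, c] != id) next
    area <- area + 1L
    for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr < 1 || rr > n || cc < 1 || cc > m || lab[rr, cc] != id) {
        per <- per + 1L
      }
    }
  }
  c(area = area, perimeter = per)
}

# Hand-built 9x9 configuration containing both types, used for the
# kernel-vs-analytic checks. Default exclusion distances (1, 3, 2):
# a type-1 pair in the north-west, a type-2 pair in the south-east.
fixture_9x9 <- function() {
  s <- matrix(0L, 9, 9)
  s[3, 3] <- 1L
  s[3, 4] <- 1L
  s[7, 7] <- 2L
  s[7, 5] <- 2L
  lattice_config(s, exclusion_rule(), validate = TRUE)
}

# Empirical outcome frequencies from the compiled kernel at one vertex.
kernel_frequencies <- function(config, x, params, n) {
  res <- exclusim:::kernel_sample_vertex(
    config$state, params$rule$D, params$rates$division,
    params$rates$migration, params$rates$death, x[1], x[2], n)
  res$counts / res$n
}

# Analytic outcome probabilities keyed like kernel_sample_vertex().
analytic_probs <- function(config, x, params) {
  occupied <- config$state[x[1], x[2]] != 0L
  dist <- if (occupied) {
    occupied_update_distribution(config, x, params)
  } else {
    empty_update_distribution(config, x, params)
  }
  out <- dist$outcomes
  key <- character(nrow(out))
  for (k in seq_len(nrow(out))) {
    key[k] <- switch(out$event[k],
      quiescence = "quiescence",
      death = "death",
      stay_empty = "stay_empty",
      migrate_out = sprintf("migrate_out_%d_%d", out$row[k], out$col[k]),
      birth = sprintf("birth_%d", out$type[k]),
      migrate_in = sprintf("migrate_in_%d_%d_%d", out$type[k], out$row[k],
                           out$col[k]))
  }
  stats::setNames(out$prob, key)
}

# Assert empirical frequencies match probabilities within k Monte-Carlo
# standard errors for every outcome (missing empirical keys count as 0).
expect_frequencies_match <- function(freq, probs, n, k = 4) {
  expect_true(all(names(freq) %in% names(probs)),
              label = "no unexpected outcomes sampled")
  for (key in names(probs)) {
    p <- probs[[key]]
    f <- if (key %in% names(freq)) freq[[key]] else 0
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(f - p), max(k * se, 1e-12),
              label = sprintf("outcome %s: |%.5f - %.5f|", key, f, p))
  }
}
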
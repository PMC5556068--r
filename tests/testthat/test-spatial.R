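# Heatmaps, cluster labeling, shape descriptors, distance analyses.

test_that("occupancy heatmaps average the type indicator over the window", {
  s1 <- matrix(0L, 6, 6); s1[3, 3] <- 1L; s1[4, 4] <- 2L
  s2 <- matrix(0L, 6, 6); s2[3, 3] <- 1L
  h1 <- occupancy_heatmap(list(s1), type = 1)
  expect_equal(unclass(h1)[3, 3], 1)
  expect_equal(sum(unclass(h1)), 1)
  # static window: identical regardless of length
  hs <- occupancy_heatmap(list(s1, s1, s1), type = 1)
  expect_equal(unclass(hs), unclass(h1), ignore_attr = TRUE)
  # mixed window: fractional occupancy
  hm <- occupancy_heatmap(list(s1, s2), type = 2)
  expect_equal(unclass(hm)[4, 4], 0.5)
  expect_true(all(unclass(hm) >= 0 & unclass(hm) <= 1))
  expect_error(occupancy_heatmap(list()), "empty")
})

test_that("cluster labeling follows the stated connectivity", {
  m <- matrix(0, 7, 7)
  m[2:3, 2:3] <- 1   # square A
  m[2:3, 6:7] <- 1   # square B, separated by an empty column
  lab <- label_clusters(m)
  expect_equal(max(lab), 2)
  expect_equal(max(label_clusters(matrix(0, 5, 5))), 0)
  # diagonal touch: one cluster under 8-connectivity, two under 4
  d <- matrix(0, 6, 6)
  d[2:3, 2:3] <- 1; d[4:5, 4:5] <- 1
  expect_equal(max(label_clusters(d, connectivity = 8)), 1)
  expect_equal(max(label_clusters(d, connectivity = 4)), 2)
  # min_size filtering drops single pixels by default
  sp <- matrix(0, 5, 5); sp[3, 3] <- 1
  expect_equal(max(label_clusters(sp)), 0)
  expect_equal(max(label_clusters(sp, min_size = 1)), 1)
  # agreement with the flood-fill oracle on random maps
  set.seed(12)
  for (k in 1:20) {
    bin <- matrix(stats::runif(100) < 0.4, 10, 10)
    for (conn in c(4, 8)) {
      got <- label_clusters(bin, connectivity = conn, min_size = 1)
      want <- bf_label(bin, conn)
      # same partition: one-to-one label correspondence
      expect_equal(max(got), max(want))
      if (max(want) > 0) {
        expect_equal(length(unique(paste(got[bin], want[bin]))), max(want))
      }
    }
  }
})

test_that("cluster features reproduce closed-form shapes", {
  m <- matrix(0, 9, 9)
  m[3:5, 3:5] <- 1   # 3x3 solid square
  f <- cluster_features(label_clusters(m), pixel_to_um = 10)
  expect_equal(nrow(f), 1)
  expect_equal(f$area_px2, 9)
  expect_equal(f$perimeter_px, 12)
  expect_equal(f$convex_hull_ratio, 1)
  expect_equal(f$aspect_ratio, 1)
  expect_equal(f$area_um2, 900)
  expect_equal(f$perimeter_um, 120)

  # 1x5 row: moments-ellipse aspect ratio of a discrete pixel row
  r <- matrix(0, 7, 9); r[4, 2:6] <- 1
  fr <- cluster_features(label_clusters(r))
  expect_equal(fr$area_px2, 5)
  expect_equal(fr$perimeter_px, 12)
  # population variance along the row is (5^2 - 1)/12; adding the 1/12
  # pixel term gives axis ratio sqrt((25/12) / (1/12)) = 5
  expect_equal(fr$aspect_ratio, 5, tolerance = 1e-12)
  expect_equal(fr$convex_hull_ratio, 1)

  # single-pixel cluster: degenerate conventions
  sp <- matrix(0, 5, 5); sp[3, 3] <- 1
  fs <- cluster_features(label_clusters(sp, min_size = 1))
  expect_equal(fs$aspect_ratio, 1)
  expect_equal(fs$convex_hull_ratio, 1)
  expect_equal(fs$perimeter_px, 4)

  # defining inequalities on random shapes
  set.seed(4)
  for (k in 1:10) {
    bin <- matrix(stats::runif(144) < 0.45, 12, 12)
    f <- cluster_features(label_clusters(bin, min_size = 1))
    expect_true(all(f$convex_hull_ratio > 0 & f$convex_hull_ratio <= 1 + 1e-12))
    expect_true(all(f$aspect_ratio >= 1 - 1e-12))
    expect_true(all(f$area_px2 > 0))
  }
})

test_that("area and perimeter agree with the pixel-walk oracle", {
  set.seed(99)
  for (k in 1:25) {
    bin <- matrix(stats::runif(400) < stats::runif(1, 0.2, 0.6), 20, 20)
    lab <- label_clusters(bin, min_size = 1)
    f <- cluster_features(lab)
    for (j in seq_len(nrow(f))) {
      ap <- bf_region_area_perimeter(lab, j)
      expect_equal(f$area_px2[j], unname(ap["area"]))
      expect_equal(f$perimeter_px[j], unname(ap["perimeter"]))
    }
  }
})

test_that("unit conversion is consistent with the area calibration", {
  scale <- sqrt(93)    # 1 px^2 ~ 93 um^2, so 1 px ~ 9.64 um
  expect_equal(scale, 9.643651, tolerance = 1e-6)
  m <- matrix(0, 8, 8); m[3:5, 3:6] <- 1
  f <- cluster_features(label_clusters(m), pixel_to_um = scale)
  expect_equal(f$area_um2, f$area_px2 * 93)
  expect_equal(f$perimeter_um, f$perimeter_px * scale)
})

test_that("distance distributions histogram all same-type pairs", {
  pts <- data.frame(x_um = c(0, 10, 20), y_um = 0, type = 1L)
  dd <- distance_distribution(pts, 1, bin_width = 5)
  # pair distances {10, 10, 20}: mode at the bin centred on 10
  expect_equal(dd$mode, 10)
  expect_equal(dd$n_pairs, 3)
  expect_equal(sum(dd$rel_freq), 1, tolerance = 1e-12)
  expect_equal(dd$rel_freq[dd$bin_center == 10], 2 / 3)
  expect_equal(dd$rel_freq[dd$bin_center == 20], 1 / 3)
  # two points: a single-pair histogram
  two <- data.frame(x_um = c(0, 7), y_um = 0, type = 2L)
  d2 <- distance_distribution(two, 2, bin_width = 5)
  expect_equal(d2$n_pairs, 1)
  expect_equal(d2$mode, 5)   # 7 falls in the bin centred on 5
  # mode ties resolve to the smallest bin
  tie <- data.frame(x_um = c(0, 5, 15), y_um = 0, type = 1L)
  dt <- distance_distribution(tie, 1, bin_width = 5)
  expect_equal(dt$mode, 5)   # distances {5, 10, 15}: all singleton bins
  expect_error(distance_distribution(pts, 2), "at least 2")
})

test_that("density-by-band recovers an exact exponential profile", {
  # 150x150 um field, 3x3 quadrats of 50 um; a single tumor point at the
  # centre of quadrat (1,1); per-band type-2 counts exactly on the curve
  lambda <- log(2) / 50
  counts_per_band <- c(16, 8, 4)   # at midpoints 25, 75, 125
  qpos <- expand.grid(x = c(25, 75, 125), y = c(25, 75, 125))
  d <- sqrt((qpos$x - 25)^2 + (qpos$y - 25)^2)
  band <- cut(d, c(0, 50, 100, 150), include.lowest = TRUE)
  pts <- data.frame(x_um = 25, y_um = 25, type = 1L)
  set.seed(6)
  for (q in seq_len(nrow(qpos))) {
    nb <- counts_per_band[as.integer(band[q])]
    pts <- rbind(pts, data.frame(
      x_um = qpos$x[q] + stats::runif(nb, -20, 20),
      y_um = qpos$y[q] + stats::runif(nb, -20, 20), type = 2L))
  }
  pat <- structure(list(points = pts, field_um = 150, seed = 6),
                   class = "point_pattern")
  bp <- density_by_distance_band(pat, bands = c(0, 50, 100, 150),
                                 quadrat_um = 50)
  expect_equal(bp$summary$mean, counts_per_band)
  expect_equal(bp$fit$lambda, lambda, tolerance = 1e-6)
  expect_equal(bp$fit$A, 16 * exp(lambda * 25), tolerance = 1e-6)

  # uniform background: flat profile, lambda ~ 0
  set.seed(13)
  u <- data.frame(x_um = stats::runif(900, 0, 150),
                  y_um = stats::runif(900, 0, 150), type = 2L)
  upat <- structure(list(points = rbind(pts[1, ], u), field_um = 150,
                         seed = 13), class = "point_pattern")
  bu <- density_by_distance_band(upat)
  expect_lt(abs(bu$fit$lambda), 0.01)

  # bands beyond the field: every band empty
  expect_error(density_by_distance_band(pat, bands = c(400, 500)),
               "empty")
})

test_that("simulated tumor clusters are ringed by empty separating layers", {
  p <- coculture_params(L = 60, n_steps = 3e6, seed = 15)
  run <- run_simulation(p, snapshot_steps = 3e6)
  snap <- run$snapshots[["3e+06"]]
  h1 <- occupancy_heatmap(list(snap), type = 1)
  lab <- label_clusters(h1, min_size = 2)
  expect_gte(max(lab), 1)
  # admissibility (cross distance >= 3) forbids any 8-adjacency between
  # the two types: no normal cell may touch a tumor cell even diagonally
  t1 <- which(snap$state == 1L, arr.ind = TRUE)
  t2 <- which(snap$state == 2L, arr.ind = TRUE)
  if (nrow(t1) && nrow(t2)) {
    cheb <- outer(t1[, 1], t2[, 1], function(a, b) abs(a - b))
    cheb2 <- outer(t1[, 2], t2[, 2], function(a, b) abs(a - b))
    expect_gt(min(pmax(cheb, cheb2)), 1)
  }
})
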
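# Synthetic data generators: typed centroid point patterns emulating
# co-culture micrograph fields (dense tumor clusters surrounded by a
# spaced normal-cell background) and logistic growth tables. These stand
# in for experimental measurements, which are not distributed with the
# package, and are labelled synthetic throughout.

#' Specification of a synthetic co-culture point pattern
#'
#' Parameters of the generator that emulates a post-confluence co-culture
#' field: dense circular clusters of tumor (type 1) centroids surrounded
#' by a hard-core background of normal (type 2) centroids. Defaults
#' describe a 400 x 400 micrometre field of view (roughly one 20x
#' objective field) holding two clusters packed close to the hard-core
#' jamming density, so the all-pairs distance histogram of the tumor type
#' has a dominant peak just above its 6 um spacing, well below the modal
#' normal-normal distance -- the configuration in which the two types'
#' cell-to-cell distance distributions separate.
#'
#' @param field_um Side of the square field (micrometres).
#' @param n_clusters Number of tumor clusters.
#' @param cluster_radius_um Cluster disc radius.
#' @param cluster_n Tumor centroids per cluster.
#' @param type1_spacing_um Minimal tumor-tumor centroid distance.
#' @param n_background Normal centroids in the background.
#' @param type2_spacing_um Minimal normal-normal centroid distance.
#' @param buffer_um Width of the empty annulus between a cluster disc and
#'   the normal background.
#' @param seed RNG seed.
#' @return A list of class `pattern_spec`.
#' @export
pattern_spec <- function(field_um = 400, n_clusters = 2,
                         cluster_radius_um = 35, cluster_n = 65,
                         type1_spacing_um = 6,
                         n_background = 250, type2_spacing_um = 15,
                         buffer_um = 12, seed = 1L) {
  stopifnot(field_um > 0, n_clusters >= 0, cluster_radius_um > 0,
            type1_spacing_um >= 0, type2_spacing_um >= 0, buffer_um >= 0)
  structure(as.list(environment()), class = "pattern_spec")
}

# Hard-core random sequential placement of n points inside the region
# accepted by `accept(x, y)`, with minimal spacing among themselves and
# against `against` (2-col matrix).
.rsa_points <- function(n, field, spacing, accept, against = NULL,
                        max_attempts = 20000L) {
  pts <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(pts) < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    p <- stats::runif(2, 0, field)
    if (!accept(p[1], p[2])) next
    ok <- TRUE
    if (nrow(pts) > 0 && spacing > 0) {
      if (min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) < spacing^2) ok <- FALSE
    }
    if (ok && !is.null(against) && nrow(against) > 0 && spacing > 0) {
      if (min((against[, 1] - p[1])^2 + (against[, 2] - p[2])^2) < spacing^2)
        ok <- FALSE
    }
    if (ok) {
      pts <- rbind(pts, p)
      attempts <- 0L
    }
  }
  pts
}

#' Generate a synthetic typed point pattern
#'
#' Draws tumor (type 1) centroids inside randomly located cluster discs
#' with a short hard-core spacing, and normal (type 2) centroids as a
#' hard-core background outside the buffered cluster discs. The
#' construction reproduces the post-confluence distance-distribution
#' signature: the modal tumor-tumor centroid distance is shorter than the
#' modal normal-normal distance.
#'
#' @param spec A [pattern_spec()].
#' @return A `point_pattern`: list with `points` (data frame
#'   `x_um, y_um, type`), `field_um` and `seed`.
#' @export
synthetic_point_pattern <- function(spec = pattern_spec()) {
  set.seed(spec$seed)
  f <- spec$field_um
  R <- spec$cluster_radius_um
  # cluster centres, kept inside the field and apart from each other
  centers <- .rsa_points(spec$n_clusters, f, 2.5 * R,
                         accept = function(x, y) {
                           x > R & x < f - R & y > R & y < f - R
                         })
  pts1 <- matrix(numeric(0), 0, 2)
  for (k in seq_len(nrow(centers))) {
    in_disc <- function(x, y) {
      (x - centers[k, 1])^2 + (y - centers[k, 2])^2 <= R^2
    }
    pk <- .rsa_points(spec$cluster_n, f, spec$type1_spacing_um, in_disc,
                      against = pts1)
    pts1 <- rbind(pts1, pk)
  }
  outside_all <- function(x, y) {
    if (nrow(centers) == 0) return(TRUE)
    all((x - centers[, 1])^2 + (y - centers[, 2])^2 >
          (R + spec$buffer_um)^2)
  }
  pts2 <- .rsa_points(spec$n_background, f, spec$type2_spacing_um,
                      outside_all)
  points <- rbind(
    if (nrow(pts1)) data.frame(x_um = pts1[, 1], y_um = pts1[, 2], type = 1L),
    if (nrow(pts2)) data.frame(x_um = pts2[, 1], y_um = pts2[, 2], type = 2L))
  if (is.null(points)) {
    points <- data.frame(x_um = numeric(0), y_um = numeric(0),
                         type = integer(0))
  }
  structure(list(points = points, field_um = f, seed = spec$seed),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points (%d type 1, %d type 2) in a %g um field\n",
              nrow(x$points), sum(x$points$type == 1L),
              sum(x$points$type == 2L), x$field_um))
  invisible(x)
}

#' Synthetic logistic growth table
#'
#' Evaluates the three-parameter logistic growth curve
#' `N(t) = K / (1 + exp(-r (t - tau)))` -- carrying capacity `K`, growth
#' rate `r` per unit time, half-capacity time `tau` (so `N(tau) = K/2`) --
#' at the given times and adds Gaussian noise.
#'
#' @param K Carrying capacity (> 0).
#' @param r Growth rate (> 0).
#' @param tau Half-capacity time.
#' @param times Numeric vector of observation times.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return Data frame with columns `time` and `value`.
#' @export
synthetic_growth_curve <- function(K, r, tau, times = 0:8, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(K > 0, r > 0, noise_sd >= 0)
  value <- K / (1 + exp(-r * (times - tau)))
  if (noise_sd > 0) {
    set.seed(seed)
    value <- value + stats::rnorm(length(times), 0, noise_sd)
  }
  data.frame(time = times, value = value)
}
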
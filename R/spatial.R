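# Pattern quantification: occupancy heatmaps, cluster labeling and shape
# descriptors with pixel-to-micrometre conversion, same-type pairwise
# distance distributions, and density-by-distance-band profiles.

#' Occupancy heatmap over a window of snapshots
#'
#' Per-vertex mean of the type-occupancy indicator over a set of recorded
#' configuration snapshots: entry `(r, c)` is the fraction of snapshots in
#' which vertex `(r, c)` holds a cell of the requested type.
#'
#' @param snapshots A list of [lattice_config()]s (or state matrices), all
#'   of the same size.
#' @param type Cell type (1 or 2).
#' @return An object of class `heatmap_grid`: the `L x L` frequency
#'   matrix with attributes `type` and `n_snapshots`.
#' @export
occupancy_heatmap <- function(snapshots, type = 1L) {
  if (length(snapshots) == 0) stop("occupancy_heatmap: empty snapshot window")
  mats <- lapply(snapshots, function(s) if (is.matrix(s)) s else s$state)
  L <- nrow(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == c(L, L)), logical(1)))) {
    stop("snapshots differ in size")
  }
  acc <- Reduce(`+`, lapply(mats, function(m) (m == type) + 0))
  h <- acc / length(mats)
  structure(h, class = c("heatmap_grid", "matrix"),
            type = as.integer(type), n_snapshots = length(mats))
}

#' Label connected clusters in a binary map
#'
#' Thresholds a heatmap (or accepts a binary/logical matrix directly) and
#' labels its connected components. Components smaller than `min_size`
#' pixels are discarded. Connectivity 8 (edges and diagonals, the
#' default) or 4 (edges only).
#'
#' @param map A `heatmap_grid`, numeric matrix (thresholded at
#'   `threshold`) or logical matrix.
#' @param connectivity 8 (default) or 4.
#' @param threshold Binarization level for numeric input (default 0.5:
#'   a pixel belongs to the foreground when its occupancy frequency is at
#'   least the threshold).
#' @param min_size Minimum pixel count of a retained cluster.
#' @return Integer matrix of the same size: 0 background, 1..k cluster
#'   labels (labels are contiguous, ordered by first pixel).
#' @export
label_clusters <- function(map, connectivity = 8L, threshold = 0.5,
                           min_size = 2L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  bin <- if (is.logical(map)) map else unclass(map) >= threshold
  n <- nrow(bin); m <- ncol(bin)
  labels <- matrix(0L, n, m)
  pix <- which(bin)
  if (length(pix) == 0) return(labels)
  r <- (pix - 1L) %% n + 1L
  c <- (pix - 1L) %/% n + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- integer(0); to <- integer(0)
  pos <- matrix(FALSE, n, m); pos[pix] <- TRUE
  id <- matrix(0L, n, m); id[pix] <- seq_along(pix)
  for (o in offs) {
    rr <- r + o[1]; cc <- c + o[2]
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
    ok[ok] <- pos[cbind(rr[ok], cc[ok])]
    from <- c(from, id[cbind(r[ok], c[ok])])
    to <- c(to, id[cbind(rr[ok], cc[ok])])
  }
  g <- igraph::make_graph(edges = as.vector(rbind(from, to)),
                          n = length(pix), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(pix)]
  sizes <- table(comp)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  comp[!(comp %in% keep)] <- NA
  relab <- match(comp, sort(unique(stats::na.omit(comp))))
  labels[pix] <- ifelse(is.na(relab), 0L, relab)
  labels
}

# Shoelace area of a polygon given as a 2-column matrix of vertices.
.polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Shape descriptors of labeled clusters
#'
#' Computes, for every labeled cluster, the shape descriptors used for
#' tumor-cluster morphometrics, in pixel units and converted to
#' micrometres through the stated length scale:
#' \itemize{
#'   \item area: pixel count (`um^2` via `scale^2`);
#'   \item perimeter: number of unit pixel edges between the cluster and
#'     anything that is not this cluster, including the map boundary
#'     (`um` via `scale`);
#'   \item convex hull ratio: `Area / ConvexArea`, with the convex area
#'     taken over the corners of the pixel squares so that the ratio is
#'     at most 1 even for degenerate (collinear) clusters;
#'   \item aspect ratio: major/minor axis length of the
#'     second-central-moment ellipse of the pixel centres (each pixel
#'     contributing the 1/12 variance of its unit square), at least 1; a
#'     single-pixel cluster has aspect ratio 1 and hull ratio 1.
#' }
#'
#' The default length scale is `sqrt(93) ~ 9.64` micrometres per pixel,
#' the calibration at which simulated heatmap clusters and experimental
#' micrograph clusters share an area scale (1 px^2 ~ 93 um^2).
#'
#' @param labels Labeled matrix from [label_clusters()].
#' @param pixel_to_um Length of one pixel side in micrometres.
#' @return A data frame of class `cluster_features` with one row per
#'   cluster: `cluster_id`, `area_px2`, `area_um2`, `perimeter_px`,
#'   `perimeter_um`, `convex_hull_ratio`, `aspect_ratio`,
#'   `centroid_row`, `centroid_col`.
#' @export
cluster_features <- function(labels, pixel_to_um = sqrt(93)) {
  ids <- sort(unique(labels[labels > 0]))
  out <- vector("list", length(ids))
  n <- nrow(labels); m <- ncol(labels)
  for (k in seq_along(ids)) {
    id <- ids[k]
    pix <- which(labels == id, arr.ind = TRUE)
    area <- nrow(pix)
    # perimeter: 4-neighbour edges to non-cluster (or off-map)
    per <- 0L
    for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      rr <- pix[, 1] + o[1]; cc <- pix[, 2] + o[2]
      inside <- rr >= 1 & rr <= n & cc >= 1 & cc <= m
      same <- logical(area)
      same[inside] <- labels[cbind(rr[inside], cc[inside])] == id
      per <- per + sum(!same)
    }
    # convex hull of the pixel squares' corners
    corners <- rbind(cbind(pix[, 1] - 0.5, pix[, 2] - 0.5),
                     cbind(pix[, 1] - 0.5, pix[, 2] + 0.5),
                     cbind(pix[, 1] + 0.5, pix[, 2] - 0.5),
                     cbind(pix[, 1] + 0.5, pix[, 2] + 0.5))
    hull <- grDevices::chull(corners)
    hull_area <- .polygon_area(corners[hull, , drop = FALSE])
    # second-central-moment ellipse of the pixel centres (+ 1/12 per pixel)
    if (area == 1) {
      aspect <- 1
    } else {
      cv <- stats::cov(pix) * (area - 1) / area + diag(1 / 12, 2)
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      aspect <- sqrt(max(ev) / min(ev))
    }
    out[[k]] <- data.frame(
      cluster_id = k, area_px2 = area, area_um2 = area * pixel_to_um^2,
      perimeter_px = per, perimeter_um = per * pixel_to_um,
      convex_hull_ratio = area / hull_area, aspect_ratio = aspect,
      centroid_row = mean(pix[, 1]), centroid_col = mean(pix[, 2]))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cluster_id = integer(0), area_px2 = numeric(0),
               area_um2 = numeric(0), perimeter_px = numeric(0),
               perimeter_um = numeric(0), convex_hull_ratio = numeric(0),
               aspect_ratio = numeric(0), centroid_row = numeric(0),
               centroid_col = numeric(0))
  class(res) <- c("cluster_features", "data.frame")
  res
}

#' Same-type pairwise distance distribution
#'
#' Histograms all unordered pairwise Euclidean centroid distances among
#' points of one type and reports the modal distance -- the bin centre of
#' maximal relative frequency (smallest such bin on ties). The mode of
#' this distribution operationalizes the minimal allowed distance between
#' cells of a type, i.e. its degree of contact inhibition.
#'
#' @param pattern A `point_pattern` (see [synthetic_point_pattern()]), or
#'   a data frame with columns `x_um`, `y_um`, `type`.
#' @param type Cell type whose distances are measured.
#' @param bin_width Histogram bin width in the coordinate units
#'   (default 5, suited to micrometre patterns; use 1 for lattice
#'   coordinates).
#' @return A list of class `distance_distribution`: `breaks`,
#'   `bin_center`, `rel_freq` (summing to 1), `mode`, `n_pairs`.
#' @export
distance_distribution <- function(pattern, type, bin_width = 5) {
  pts <- if (is.data.frame(pattern)) pattern else pattern$points
  pts <- pts[pts$type == type, , drop = FALSE]
  if (nrow(pts) < 2) stop("distance_distribution: need at least 2 points of the type")
  dd <- as.numeric(stats::dist(pts[, c("x_um", "y_um")]))
  # bins centred on multiples of bin_width (centres 0, w, 2w, ...)
  breaks <- seq(-bin_width / 2,
                (max(dd) %/% bin_width + 1.5) * bin_width, by = bin_width)
  h <- graphics::hist(dd, breaks = breaks, plot = FALSE)
  rel <- h$counts / sum(h$counts)
  structure(list(breaks = breaks, bin_center = h$mids, rel_freq = rel,
                 mode = h$mids[which.max(rel)], n_pairs = length(dd)),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("distance_distribution: %d pairs, mode %.3g (bin width %.3g)\n",
              x$n_pairs, x$mode, diff(x$bin_center[1:2])))
  invisible(x)
}

#' Normal-cell density by distance band from the tumor compartment
#'
#' Partitions the field into square quadrats (default 50 x 50 um), assigns
#' each quadrat to a distance band according to the Euclidean distance
#' from its centre to the nearest tumor (type 1) centroid, counts normal
#' (type 2) centroids per quadrat, summarizes each band (median and IQR),
#' and fits the exponential decay `count(d) = A * exp(-lambda * d)` by
#' least squares to the per-band mean counts at the band midpoints.
#' Bands with no quadrats are dropped from the fit with a warning.
#'
#' @param pattern A `point_pattern` or data frame (`x_um`, `y_um`,
#'   `type`); must contain at least one type-1 point.
#' @param bands Numeric vector of band edges in micrometres (default
#'   `c(0, 50, 100, 150)`, i.e. bands 0-50, 50-100, 100-150). Quadrats
#'   farther than the last edge are ignored.
#' @param quadrat_um Quadrat side length.
#' @return A list of class `band_profile`: `quadrats` (data frame with
#'   per-quadrat centre, distance, band, count), `summary` (per band:
#'   midpoint, n quadrats, median, q25, q75, mean), and `fit`
#'   (`A`, `lambda`, `fitted`).
#' @export
density_by_distance_band <- function(pattern, bands = c(0, 50, 100, 150),
                                     quadrat_um = 50) {
  pts <- if (is.data.frame(pattern)) pattern else pattern$points
  field <- if (is.data.frame(pattern)) max(pts$x_um, pts$y_um) else pattern$field_um
  if (is.unsorted(bands, strictly = TRUE)) stop("bands must be strictly increasing")
  p1 <- pts[pts$type == 1L, , drop = FALSE]
  p2 <- pts[pts$type == 2L, , drop = FALSE]
  if (nrow(p1) == 0) stop("density_by_distance_band: no type-1 points to measure from")
  nq <- floor(field / quadrat_um)
  if (nq < 1) stop("field smaller than one quadrat")
  qx <- (seq_len(nq) - 0.5) * quadrat_um
  centers <- expand.grid(x = qx, y = qx)
  # distance from each quadrat centre to the nearest type-1 centroid
  d <- apply(centers, 1, function(p) {
    sqrt(min((p1$x_um - p[1])^2 + (p1$y_um - p[2])^2))
  })
  band <- cut(d, breaks = bands, include.lowest = TRUE, right = TRUE)
  cnt <- mapply(function(x, y) {
    sum(p2$x_um > x - quadrat_um / 2 & p2$x_um <= x + quadrat_um / 2 &
          p2$y_um > y - quadrat_um / 2 & p2$y_um <= y + quadrat_um / 2)
  }, centers$x, centers$y)
  quad <- data.frame(x = centers$x, y = centers$y, dist = d, band = band,
                     count = cnt)
  mids <- (bands[-1] + bands[-length(bands)]) / 2
  lv <- levels(band)
  summ <- do.call(rbind, lapply(seq_along(lv), function(k) {
    v <- cnt[!is.na(band) & band == lv[k]]
    data.frame(band = lv[k], midpoint = mids[k], n_quadrats = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               q25 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               q75 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
               mean = if (length(v)) mean(v) else NA_real_)
  }))
  use <- summ$n_quadrats > 0
  if (!any(use)) stop("density_by_distance_band: all bands are empty")
  if (!all(use)) {
    warning("empty distance band(s) excluded from the decay fit: ",
            paste(summ$band[!use], collapse = ", "))
  }
  fit <- fit_exponential_decay(summ$midpoint[use], summ$mean[use])
  structure(list(quadrats = quad, summary = summ, fit = fit),
            class = "band_profile")
}

# Least-squares fit of y = A * exp(-lambda * d). Log-linear start (on the
# positive values), refined by Levenberg-Marquardt least squares.
fit_exponential_decay <- function(d, y) {
  stopifnot(length(d) == length(y), length(d) >= 2)
  pos <- y > 0
  if (sum(pos) >= 2) {
    sl <- stats::lm(log(y[pos]) ~ d[pos])
    A0 <- unname(exp(stats::coef(sl)[1])); l0 <- unname(-stats::coef(sl)[2])
  } else {
    A0 <- max(y, 1e-8); l0 <- 0.01
  }
  fit <- try(minpack.lm::nlsLM(y ~ A * exp(-lambda * d),
                               start = list(A = A0, lambda = l0),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    list(A = unname(A0), lambda = unname(l0), fitted = A0 * exp(-l0 * d),
         converged = FALSE)
  } else {
    co <- stats::coef(fit)
    list(A = unname(co["A"]), lambda = unname(co["lambda"]),
         fitted = stats::fitted(fit), converged = TRUE)
  }
}
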
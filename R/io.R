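# Plain-text readers and writers for the package's data products.
#
# All formats are line-oriented delimited text with `#`-prefixed header
# lines. Snapshot and point-pattern files use 0-based coordinates on
# disk; the R-side objects are 1-based matrices.

#' Write a configuration snapshot
#'
#' Site-list text format: header comment lines
#' `# L=<int>`, `# D=<d11,d12,d22>`, `# seed=<int>`, `# step=<int>`,
#' then one `row,col,type` line per occupied vertex with 0-based
#' coordinates (empty vertices are implicit).
#'
#' @param config A [lattice_config()].
#' @param path Output file path.
#' @param seed,step Metadata recorded in the header.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(config, path, seed = NA_integer_,
                           step = NA_integer_) {
  occ <- which(config$state != 0L, arr.ind = TRUE)
  D <- config$rule$D
  hdr <- c(sprintf("# L=%d", config$L),
           sprintf("# D=%d,%d,%d", D[1, 1], D[1, 2], D[2, 2]),
           sprintf("# seed=%s", ifelse(is.na(seed), "NA", seed)),
           sprintf("# step=%s", ifelse(is.na(step), "NA", step)),
           "row,col,type")
  body <- if (nrow(occ)) {
    ord <- order(occ[, 1], occ[, 2])
    occ <- occ[ord, , drop = FALSE]
    sprintf("%d,%d,%d", occ[, 1] - 1L, occ[, 2] - 1L, config$state[occ])
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

.header_value <- function(lines, key) {
  hit <- grep(sprintf("^#\\s*%s=", key), lines, value = TRUE)
  if (!length(hit)) stop("missing header line: # ", key, "=")
  sub(sprintf("^#\\s*%s=", key), "", hit[1])
}

#' Read a configuration snapshot
#'
#' Parses the format of [write_snapshot()], validates that all sites are
#' within the declared grid, that no vertex is doubly occupied, that
#' borders are empty, and that the configuration is admissible under the
#' declared exclusion distances.
#'
#' @param path Snapshot file.
#' @return A [lattice_config()] with attributes `seed` and `step`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  L <- as.integer(.header_value(lines, "L"))
  D <- as.integer(strsplit(.header_value(lines, "D"), ",")[[1]])
  if (length(D) != 3 || any(is.na(D))) stop("malformed # D= header")
  seed <- suppressWarnings(as.integer(.header_value(lines, "seed")))
  step <- suppressWarnings(as.numeric(.header_value(lines, "step")))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) && grepl("^row", body[1])) body <- body[-1]
  state <- matrix(0L, L, L)
  if (length(body)) {
    parts <- utils::read.csv(text = body, header = FALSE,
                             col.names = c("row", "col", "type"))
    bad <- which(parts$row < 0 | parts$row >= L | parts$col < 0 |
                   parts$col >= L | !(parts$type %in% 1:2))
    if (length(bad)) {
      stop("snapshot site out of range or invalid type at data line ", bad[1])
    }
    idx <- cbind(parts$row + 1L, parts$col + 1L)
    if (any(state[idx] != 0L) || anyDuplicated(idx)) {
      stop("snapshot declares a doubly-occupied vertex")
    }
    state[idx] <- as.integer(parts$type)
  }
  cfg <- lattice_config(state, exclusion_rule(D[1], D[2], D[3]),
                        validate = TRUE)
  attr(cfg, "seed") <- seed
  attr(cfg, "step") <- step
  cfg
}

#' Write / read a density trajectory
#'
#' Delimited text `step,density1,density2,ratio` with `#` metadata header
#' lines echoing the run parameters.
#'
#' @param run A `sim_run` from [run_simulation()] (or a trajectory data
#'   frame).
#' @param path File path.
#' @return `path` (write) / the trajectory data frame (read).
#' @export
write_trajectory <- function(run, path) {
  traj <- if (is.data.frame(run)) run else run$trajectory
  hdr <- character(0)
  if (!is.data.frame(run)) {
    p <- run$params
    hdr <- c(sprintf("# L=%d", p$L),
             sprintf("# D=%d,%d,%d", p$rule$D[1, 1], p$rule$D[1, 2],
                     p$rule$D[2, 2]),
             sprintf("# alpha=%g,%g", p$rates$division[1], p$rates$division[2]),
             sprintf("# delta=%g,%g", p$rates$migration[1], p$rates$migration[2]),
             sprintf("# rho=%g,%g", p$rates$death[1], p$rates$death[2]),
             sprintf("# seed=%d", p$seed),
             sprintf("# n_steps=%s", format(p$n_steps, scientific = FALSE)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("step,density1,density2,ratio", con)
  writeLines(sprintf("%s,%.10g,%.10g,%s",
                     format(traj$step, scientific = FALSE, trim = TRUE),
                     traj$density1, traj$density2,
                     ifelse(is.na(traj$ratio), "NA",
                            sprintf("%.10g", traj$ratio))), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write / read a typed point pattern
#'
#' Delimited text `x_um,y_um,type` with a header line
#' `# field_um=<float> seed=<int>`.
#'
#' @param pattern A `point_pattern`.
#' @param path File path.
#' @return `path` (write) / a `point_pattern` (read).
#' @export
write_point_pattern <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# field_um=%g seed=%s", pattern$field_um,
                     ifelse(is.null(pattern$seed), "NA", pattern$seed)), con)
  writeLines("x_um,y_um,type", con)
  writeLines(sprintf("%.6f,%.6f,%d", pattern$points$x_um,
                     pattern$points$y_um, pattern$points$type), con)
  invisible(path)
}

#' @rdname write_point_pattern
#' @export
read_point_pattern <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)[1]
  field <- as.numeric(sub(".*field_um=([0-9.eE+-]+).*", "\\1", hdr))
  seed <- suppressWarnings(as.integer(sub(".*seed=([0-9-]+).*", "\\1", hdr)))
  pts <- utils::read.csv(path, comment.char = "#")
  if (!all(c("x_um", "y_um", "type") %in% names(pts))) {
    stop("point pattern file must have columns x_um,y_um,type")
  }
  if (any(!pts$type %in% 1:2)) stop("point types must be 1 or 2")
  if (is.finite(field) &&
      any(pts$x_um < 0 | pts$x_um > field | pts$y_um < 0 | pts$y_um > field)) {
    stop("point coordinates exceed the declared field extent")
  }
  structure(list(points = pts, field_um = field, seed = seed),
            class = "point_pattern")
}

#' Read a simulation configuration file
#'
#' YAML (or plain `key: value`) configuration with keys `L`, `D`
#' (list/vector `d11, d12, d22`), `alpha`, `delta`, `rho` (length-2
#' each), `seed`, `n_steps`, `record_every`, `init_density` (length 2)
#' and optional `density_interior`. Missing rate keys are an error;
#' other keys fall back to [model_params()] defaults.
#'
#' @param path YAML file.
#' @param overrides Named list applied on top of the file's values.
#' @return A [model_params()].
#' @export
read_sim_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  for (key in c("alpha", "delta", "rho")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("config validation: missing required key '%s' in %s",
                   key, path))
    }
    if (length(cfg[[key]]) == 1) cfg[[key]] <- rep(cfg[[key]], 2)
  }
  D <- cfg$D %||% c(1, 3, 2)
  if (length(D) != 3) stop("config validation: key 'D' must have 3 entries (d11,d12,d22)")
  out <- model_params(
    L = cfg$L %||% 200L,
    rule = exclusion_rule(D[1], D[2], D[3]),
    rates = rate_set(cfg$alpha, cfg$delta, cfg$rho),
    seed = cfg$seed %||% 1L,
    n_steps = cfg$n_steps %||% 1e5,
    record_every = cfg$record_every %||% max(1, floor((cfg$n_steps %||% 1e5) / 200)),
    init_density = cfg$init_density %||% c(0.01, 0.09),
    density_interior = cfg$density_interior %||% FALSE)
  # snapshot steps are a run-command concern; carried as an attribute
  attr(out, "snapshot_steps") <- as.numeric(cfg$snapshot_steps %||% numeric(0))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' JSON record of a command invocation: the command, resolved parameters,
#' seeds, input/output paths, package version and wall time -- sufficient
#' to re-run the command.
#'
#' @param command Command name.
#' @param params Named list of resolved parameters.
#' @param paths Named list of input/output paths.
#' @param out_dir Directory to write `manifest.json` into.
#' @param wall_time_s Elapsed seconds.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(command, params, paths, out_dir,
                           wall_time_s = NA_real_) {
  manifest <- list(command = command, params = params, paths = paths,
                   package_version = as.character(utils::packageVersion("exclusim")),
                   wall_time_s = wall_time_s)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
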
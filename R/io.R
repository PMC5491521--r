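# File I/O: tracks and force-distance curves as CSV, configurations as JSON,
# and a run manifest for reproducibility. All readers raise typed format
# errors rather than silently coercing.

#' Read / write a position track (CSV)
#'
#' Tracks are CSV files with header `time_s,x_nm,y_nm`; a `z_nm` column (as
#' written for simulated trajectories) is carried along when present. Frame
#' spacing must be uniform within 1e-6 s. Round-trips are lossless beyond 6
#' significant digits.
#'
#' @param path File path.
#' @return `read_track()`: a track tibble.
#' @export
read_track <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_format(paste("cannot parse CSV:", conditionMessage(e))))
  need <- c("time_s", "x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    abort_format("track CSV must have columns time_s, x_nm, y_nm")
  }
  keep <- intersect(c("time_s", "x_nm", "y_nm", "z_nm", "n_bound"), names(df))
  as_track(as_tibble(df[keep]))
}

#' @rdname read_track
#' @param track Track data frame to write.
#' @return `write_track()`: the path, invisibly.
#' @export
write_track <- function(track, path) {
  track <- as_track(track)
  readr::write_csv(as_tibble(as.data.frame(track)), path)
  invisible(path)
}

#' Read / write a force-distance curve (CSV)
#'
#' Curves are CSV files with header `separation_nm,force_nN,segment`,
#' `segment` being `approach` or `retract`.
#'
#' @param path File path.
#' @return `read_fd_curve()`: an fd-curve tibble.
#' @export
read_fd_curve <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort_format(paste("cannot parse CSV:", conditionMessage(e))))
  need <- c("separation_nm", "force_nN", "segment")
  if (!all(need %in% names(df))) {
    abort_format("curve CSV must have columns separation_nm, force_nN, segment")
  }
  as_fd_curve(as_tibble(df[need]))
}

#' @rdname read_fd_curve
#' @param curve Curve data frame to write.
#' @return `write_fd_curve()`: the path, invisibly.
#' @export
write_fd_curve <- function(curve, path) {
  curve <- as_fd_curve(curve)
  readr::write_csv(as_tibble(as.data.frame(curve)), path)
  invisible(path)
}

#' Read / write a simulation configuration (JSON)
#'
#' Flat JSON with keys named as in [sim_config()], SI units. `Inf` adhesion
#' force is stored as the string `"Inf"`.
#'
#' @param path File path.
#' @return `read_config()`: a validated `sim_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort_format(paste("bad JSON:", conditionMessage(e))))
  if (!is.null(raw$tether_adhesion_force) &&
      identical(raw$tether_adhesion_force, "Inf")) {
    raw$tether_adhesion_force <- Inf
  }
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort_format(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  do.call(sim_config, raw)
}

#' @rdname read_config
#' @param config A `sim_config` to write.
#' @return `write_config()`: the path, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_sim_config(config)
  out <- unclass(config)
  if (is.infinite(out$tether_adhesion_force)) out$tether_adhesion_force <- "Inf"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-identically: the config
#' snapshot, seed, package version, input/output paths, wall-clock start, and
#' MD5 hashes of the outputs.
#'
#' @param path Manifest path (JSON).
#' @param config The `sim_config` (or any named list) used.
#' @param seed Seed actually used.
#' @param inputs,outputs Character vectors of file paths.
#' @param started Wall-clock start time.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(),
                           outputs = character(), started = Sys.time()) {
  cfg <- unclass(config)
  if (is.numeric(cfg$tether_adhesion_force) &&
      is.infinite(cfg$tether_adhesion_force)) {
    cfg$tether_adhesion_force <- "Inf"
  }
  man <- list(
    package = "retether",
    version = as.character(utils::packageVersion("retether")),
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfg,
    inputs = as.list(inputs),
    outputs = lapply(outputs, function(p) {
      list(path = p,
           md5 = if (file.exists(p)) unname(tools::md5sum(p)) else NA)
    })
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}
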
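# Configuration loading (JSON/YAML), time-series persistence (CSV) and
# run manifests (JSON).  Units in files: angles deg, forces N, torques
# N m, actuator displacements and moment arms mm.

#' Load and validate a configuration file
#'
#' Reads a JSON or YAML configuration with (optional) top-level
#' sections `plant`, `controller`, `trajectory`, `seed` and
#' `muscle_table` (a CSV path, resolved relative to the config file;
#' defaults to the bundled table).  Every section is passed through the
#' corresponding constructor, so all invariants are enforced and
#' defaults filled.  Unknown keys are rejected with a field-level
#' message.
#'
#' @param path Path to a `.json`, `.yaml`/`.yml` file.
#' @return A list: `plant` (a `plant_config`), `controller` (a
#'   [controller_config()]), `trajectory` (a [trajectory_spec()]),
#'   `muscles` (a `muscle_table`), `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- c("plant", "controller", "trajectory", "muscle_table", "seed",
             "version", "timestamp", "outputs")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  }
  muscles <- if (!is.null(raw$muscle_table)) {
    p <- raw$muscle_table
    if (!file.exists(p)) p <- file.path(dirname(path), raw$muscle_table)
    read_muscle_table(p)
  } else {
    wrist_muscles()
  }
  plant <- build_from_keys(raw$plant, plant_config, "plant")
  controller <- build_controller_cfg(raw$controller, plant, "controller")
  check_f0_fmax(controller, muscles)
  trajectory <- build_from_keys(raw$trajectory, trajectory_spec, "trajectory")
  list(plant = plant, controller = controller, trajectory = trajectory,
       muscles = muscles,
       seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}

check_f0_fmax <- function(cc, muscles) {
  fmax <- resolved_fmax(cc, muscles)
  if (cc$f0 >= min(fmax)) {
    stop("controller invariant violated: f0 (", cc$f0,
         ") must be < min(f_max) (", min(fmax), ")")
  }
  invisible(cc)
}

# Call `constructor` with exactly the keys given, rejecting unknowns.
build_from_keys <- function(keys, constructor, section) {
  if (is.null(keys)) return(constructor())
  ok <- names(formals(constructor))
  bad <- setdiff(names(keys), ok)
  if (length(bad)) {
    stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
  }
  if (!is.null(keys$joint_limits)) keys$joint_limits <-
      lapply(keys$joint_limits, as.numeric)
  do.call(constructor, keys)
}

build_controller_cfg <- function(keys, plant, section) {
  if (is.null(keys)) {
    return(default_controller("hybrid", plant_cfg = plant))
  }
  ok <- c(names(formals(controller_config)), "torque_gains")
  bad <- setdiff(names(keys), ok)
  if (length(bad)) {
    stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
  }
  gset <- default_gains()
  strategy <- if (is.null(keys$strategy)) "hybrid" else keys$strategy
  gains_from <- function(x, fallback) {
    if (is.null(x)) fallback else build_from_keys(x, pid_gains, section)
  }
  ag <- if (strategy == "cascade") {
    tg <- if (is.null(keys$torque_gains)) keys$axis_gains else keys$torque_gains
    list(fe = gains_from(tg$fe, gset$torque_fe),
         rud = gains_from(tg$rud, gset$torque_rud))
  } else {
    list(fe = gains_from(keys$axis_gains$fe, gset$fe),
         rud = gains_from(keys$axis_gains$rud, gset$rud))
  }
  args <- keys[setdiff(names(keys), c("axis_gains", "torque_gains",
                                      "force_gains", "strategy"))]
  args$strategy <- strategy
  args$axis_gains <- ag
  args$force_gains <- gains_from(keys$force_gains, gset$force)
  if (is.null(args$ff_inertia)) {
    args$ff_inertia <- c(fe = plant$inertia_fe, rud = plant$inertia_rud)
  } else {
    args$ff_inertia <- stats::setNames(as.numeric(args$ff_inertia),
                                       c("fe", "rud"))
  }
  do.call(controller_config, args)
}

#' Write / read a simulation time series as CSV
#'
#' Fixed dialect: comma separated, header row, `.` decimal separator,
#' UTF-8, full double precision (round trips are lossless to well
#' below 1e-9).
#'
#' @param result A `wrist_sim` or a plain data.frame of its `series`.
#' @param path Output file path.
#' @return `write_timeseries`: the path, invisibly.
#' @export
write_timeseries <- function(result, path) {
  df <- if (inherits(result, "wrist_sim")) result$series else result
  stopifnot(is.data.frame(df))
  txt <- vapply(seq_len(nrow(df)), function(i) {
    paste(vapply(df[i, ], function(v) {
      if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1)), collapse = ",")
  }, character(1))
  writeLines(c(paste(names(df), collapse = ","), txt), path,
             useBytes = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @return `read_timeseries`: the series as a data.frame (possibly with
#'   zero rows).
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("time series file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty time series file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(lines) == 1L) {
    df <- as.data.frame(stats::setNames(rep(list(numeric(0)),
                                            length(header)), header))
    return(df)
  }
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  nfield <- lengths(rows)
  bad <- which(nfield != length(header))
  if (length(bad)) {
    stop("malformed time series at line ", bad[1] + 1L, ": expected ",
         length(header), " fields, got ", nfield[bad[1]])
  }
  raw <- matrix(unlist(rows), ncol = length(header), byrow = TRUE)
  vals <- suppressWarnings(
    matrix(as.numeric(raw), ncol = length(header)))
  bad_rows <- which(rowSums(is.na(vals) & !(raw %in% c("NA", "NaN"))) > 0)
  if (length(bad_rows)) {
    stop("malformed time series at line ", bad_rows[1] + 1L,
         ": non-numeric field")
  }
  stats::setNames(as.data.frame(vals), header)
}

#' Write a run manifest
#'
#' A manifest snapshots everything needed to reproduce a run: the full
#' configuration, the seed, the package version and the output paths.
#' Re-running a manifest (`wristsim_cli(c("simulate", "--manifest",
#' path))`) reproduces the outputs bit-identically.
#'
#' @param cfgs A configuration bundle as from [load_config()].
#' @param seed The seed used.
#' @param outputs Named character vector of output paths.
#' @param path Manifest destination (JSON).
#' @return The path, invisibly.
#' @export
write_manifest <- function(cfgs, seed, outputs, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.function, logical(1))]
  }
  cc <- strip(cfgs$controller)
  cc$force_profiles <- NULL
  man <- list(
    version = as.character(utils::packageVersion("wristsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    plant = strip(cfgs$plant),
    controller = lapply(cc, function(x) if (inherits(x, "pid_gains") ||
                                            is.list(x)) lapply(x, unclass) else x),
    trajectory = strip(cfgs$trajectory),
    outputs = as.list(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
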
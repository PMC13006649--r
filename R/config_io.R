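#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration file, applies documented defaults,
#' and validates it. Recognized sections: `seed` (integer), `generator`
#' (arguments of [do_gen_params()]), `model` (arguments of [mlp_config()]),
#' `training` (arguments of [training_config()]), `smoother` (arguments of
#' [sg_smoother()]), `controller` with subsections `growth` and `induction`
#' (arguments of [controller_params()]; the induction subsection holds
#' overrides), `plant` (arguments of [plant_params()]), and `paths`
#' (`model`, `out`). Unknown keys are rejected with their dotted location so
#' typos cannot silently fall back to defaults.
#'
#' @param path configuration file path.
#' @param quiet suppress the effective-configuration message.
#' @return an object of class `run_config`: list with `seed`, `generator`,
#'   `model`, `training`, `smoother`, `phase_params`, `plant`, `paths`, and
#'   `hash` (md5 of the effective configuration).
#' @export
load_run_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("seed", "generator", "model", "training", "smoother",
             "controller", "plant", "paths")
  check_keys(raw, known, "")
  seed <- as.integer(raw$seed %||% 1L)

  generator <- build_section(raw$generator, do_gen_params, "generator")
  model_cfg <- build_section(raw$model, mlp_config, "model")
  training <- build_section(raw$training, training_config, "training")
  smoother <- build_section(raw$smoother, sg_smoother, "smoother")
  plant <- build_section(raw$plant, plant_params, "plant")

  ctrl <- raw$controller %||% list()
  check_keys(ctrl, c("growth", "induction"), "controller")
  growth <- build_section(ctrl$growth, controller_params, "controller.growth")
  ind_over <- ctrl$induction %||%
    list(baseline_increase = 5, threshold_increase = 10, v_glc = 7)
  check_keys(ind_over, names(formals(controller_params)),
             "controller.induction")
  phase <- tryCatch(
    phase_param_set(growth, induction_overrides = ind_over),
    error = function(e) stop("controller.induction: ", conditionMessage(e),
                             call. = FALSE))

  paths <- raw$paths %||% list()
  check_keys(paths, c("model", "out"), "paths")

  cfg <- list(seed = seed, generator = generator, model = model_cfg,
              training = training, smoother = smoother,
              phase_params = phase, plant = plant, paths = paths)
  cfg$hash <- config_hash(cfg)
  if (!quiet)
    message("effective configuration loaded (seed ", seed, ", md5 ",
            cfg$hash, ")")
  structure(cfg, class = "run_config")
}

check_keys <- function(x, known, where) {
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste0(if (nzchar(where)) paste0(where, ".") else "", unknown,
                collapse = ", "),
         call. = FALSE)
  invisible(x)
}

build_section <- function(given, constructor, where) {
  given <- given %||% list()
  check_keys(given, names(formals(constructor)), where)
  tryCatch(do.call(constructor, given),
           error = function(e) stop(where, ": ", conditionMessage(e),
                                    call. = FALSE))
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(rapply(cfg, unclass, how = "replace"), tf)
  unname(tools::md5sum(tf))
}

#' Read a DO time series from CSV
#'
#' Expects a header with at least `time_s` and `do_percent` columns. An
#' empty file yields an empty data frame; rows with non-numeric values are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @return `data.frame` with numeric columns `time_s`, `do_percent`.
#' @export
read_do_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0)
    return(data.frame(time_s = numeric(0), do_percent = numeric(0)))
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  need <- c("time_s", "do_percent")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- data.frame(time_s = suppressWarnings(as.numeric(df$time_s)),
                    do_percent = suppressWarnings(as.numeric(df$do_percent)))
  bad <- which(!stats::complete.cases(out))
  if (length(bad) > 0)
    stop("non-numeric value(s) in ", path, " at data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (header is line 1)", call. = FALSE)
  out
}

#' Write a closed-loop trajectory (and event log) to disk
#'
#' The trajectory is written as CSV at full double precision (round-trips to
#' well below 1e-9); the event log, if given, as JSON lines next to it.
#'
#' @param traj a trajectory `data.frame` (e.g. from [run_closed_loop()]) or
#'   a `neurostat_run`.
#' @param path output CSV path.
#' @param events optional event-log `data.frame`; taken from the run object
#'   automatically when `traj` is a `neurostat_run`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, events = NULL) {
  if (inherits(traj, "neurostat_run")) {
    if (is.null(events)) events <- traj$events
    traj <- traj$trajectory
  }
  df <- as.data.frame(lapply(traj, function(col) {
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE,
                                scientific = FALSE)
    else col
  }), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(events)) write_events(events, paste0(path, ".events.jsonl"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
write_events <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events)))
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"),
               con)
  invisible(path)
}
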
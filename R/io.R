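#' Read and write waveform files
#'
#' The waveform file dialect is comma-delimited text with header
#' `time_s,paw_cmh2o,flow_lps` and an optional `phase` column; one row per
#' sample, values written with 9 significant digits. Unknown extra columns
#' are preserved in the record's `meta$extra_columns`.
#'
#' @param path File path.
#' @param record A [waveform_record()] (writer).
#' @return A `waveform_record` (reader) or `path` invisibly (writer).
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) {
    aprv_error(paste0("waveform file not found: ", path), "aprv_io_error")
  }
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "paw_cmh2o", "flow_lps")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    aprv_error(paste0("waveform file missing mandatory column(s): ",
                      paste(miss, collapse = ", ")), "aprv_parse_error")
  }
  extra <- setdiff(names(df), c(need, "phase"))
  meta <- list(source = path)
  if (length(extra)) meta$extra_columns <- df[extra]
  rec <- tryCatch(
    waveform_record(time = df$time_s, pressure = df$paw_cmh2o,
                    flow = df$flow_lps,
                    phase = if ("phase" %in% names(df)) df$phase,
                    meta = meta),
    aprv_nonuniform_time = function(e) {
      aprv_error(paste0("non-uniform time column in ", path, ": ",
                        conditionMessage(e)), "aprv_nonuniform_time")
    })
  rec
}

#' @rdname read_waveform
#' @export
write_waveform <- function(record, path) {
  validate_waveform_record(record)
  cols <- list(time_s = record$time, paw_cmh2o = record$pressure,
               flow_lps = record$flow)
  if (!is.null(record$phase)) cols$phase <- record$phase
  num <- vapply(cols, is.numeric, logical(1))
  body <- do.call(paste, c(lapply(seq_along(cols), function(i) {
    if (num[i]) sprintf("%.9g", cols[[i]]) else cols[[i]]
  }), sep = ","))
  atomic_write_lines(c(paste(names(cols), collapse = ","), body), path)
  invisible(path)
}

#' Read and write simulation scenario configurations
#'
#' JSON mirroring the [simulation_config()] structure: top-level keys
#' `settings`, `lung`, `recruitment`, `n_cycles`, `dt`,
#' `noise_sd_pressure`, `noise_sd_flow`, `seed`.
#'
#' @param path File path.
#' @param config A [simulation_config()] (writer).
#' @return A `simulation_config` (reader) or `path` invisibly (writer).
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) {
    aprv_error(paste0("scenario config not found: ", path), "aprv_io_error")
  }
  raw <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) aprv_error(
                    paste0("cannot parse scenario config: ", conditionMessage(e)),
                    "aprv_parse_error"))
  grab <- function(block, field, default = NULL) {
    v <- raw[[block]][[field]]
    if (is.null(v)) {
      if (is.null(default)) {
        aprv_error(sprintf("scenario config missing field '%s.%s'", block, field),
                   "aprv_config_error")
      }
      default
    } else v
  }
  settings <- ventilator_settings(
    p_high = grab("settings", "p_high"), t_high = grab("settings", "t_high"),
    p_low = grab("settings", "p_low", 0), t_low = grab("settings", "t_low", 0.5),
    rise_time_constant = grab("settings", "rise_time_constant", 0.05))
  lung <- lung_model(
    r1 = grab("lung", "r1"), r2 = grab("lung", "r2"),
    e1 = grab("lung", "e1"), e2 = grab("lung", "e2"),
    p0 = grab("lung", "p0", 0))
  rdef <- recruitment_model()
  recruitment <- if (is.null(raw$recruitment)) rdef else recruitment_model(
    enabled = grab("recruitment", "enabled", FALSE),
    p_crit = grab("recruitment", "p_crit", rdef$p_crit),
    k = grab("recruitment", "k", rdef$k),
    tau_open = grab("recruitment", "tau_open", rdef$tau_open),
    tau_close = grab("recruitment", "tau_close", rdef$tau_close),
    r_min = grab("recruitment", "r_min", rdef$r_min))
  top <- function(field, default = NULL) {
    v <- raw[[field]]
    if (is.null(v)) default else v
  }
  simulation_config(settings = settings, lung = lung,
                    recruitment = recruitment,
                    n_cycles = top("n_cycles", 3),
                    dt = top("dt", 0.001),
                    noise_sd_pressure = top("noise_sd_pressure", 0),
                    noise_sd_flow = top("noise_sd_flow", 0),
                    seed = top("seed", 1))
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  payload <- list(settings = unclass(config$settings),
                  lung = unclass(config$lung),
                  recruitment = unclass(config$recruitment),
                  n_cycles = config$n_cycles, dt = config$dt,
                  noise_sd_pressure = config$noise_sd_pressure,
                  noise_sd_flow = config$noise_sd_flow,
                  seed = config$seed)
  atomic_write_lines(
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    path)
  invisible(path)
}

# Sidecar carrying the simulator's configured ground truth next to a
# written waveform.
write_truth_sidecar <- function(config, path) {
  payload <- list(truth = unclass(config$lung),
                  settings = unclass(config$settings),
                  recruitment = unclass(config$recruitment),
                  dt = config$dt, n_cycles = config$n_cycles,
                  noise_sd_pressure = config$noise_sd_pressure,
                  noise_sd_flow = config$noise_sd_flow,
                  seed = config$seed,
                  software_version = as.character(utils::packageVersion("aprvtitrate")))
  atomic_write_lines(
    jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    path)
  invisible(path)
}

# Machine-readable manifest written alongside every CLI run's outputs.
write_run_manifest <- function(path, subcommand, args, inputs = character(0),
                               outputs = character(0), seed = NA) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else list()
  payload <- list(
    software = "aprvtitrate",
    software_version = as.character(utils::packageVersion("aprvtitrate")),
    subcommand = subcommand,
    arguments = as.list(args),
    seed = seed,
    input_digests = digests,
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  atomic_write_lines(
    jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE, na = "null"),
    path)
  invisible(path)
}
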
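#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish configuration errors,
# rank deficiency, and analysis aborts programmatically.
aprv_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "aprv_error", "error", "condition")))
}

aprv_warn <- function(msg, class = "aprv_warning") {
  warning(warningCondition(msg, class = c(class, "aprv_warning", "warning", "condition")))
}

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the logging verbosity
#'
#' Messages at or above this level are written to standard error by the
#' package's pipeline functions and command-line interface.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("aprvtitrate.log_level", "info")
  options(aprvtitrate.log_level = level)
  invisible(old)
}

aprv_log <- function(level, ...) {
  threshold <- getOption("aprvtitrate.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[threshold]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# Write text atomically: temp file in the same directory, then rename.
atomic_write_lines <- function(lines, path) {
  dir <- dirname(path)
  tmp <- tempfile(pattern = ".aprv_tmp_", tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && abs(x - round(x)) < 1e-9

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
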
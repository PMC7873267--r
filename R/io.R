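#' Load controller and plant configuration from a YAML or JSON file
#'
#' The file may contain a \code{controller:} and a \code{plant:} section
#' (either may be omitted), whose keys mirror the argument names of
#' \code{\link{controller_params}} and \code{\link{plant_params}} exactly.
#' Missing keys take the package defaults; every invariant is enforced at
#' load time with field-level messages.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A list with validated \code{controller} and \code{plant}
#'   parameter objects.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  known <- c("controller", "plant")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ctl_args <- if (is.null(cfg$controller)) list() else as.list(cfg$controller)
  pl_args <- if (is.null(cfg$plant)) list() else as.list(cfg$plant)
  ok_ctl <- names(formals(controller_params))
  bad <- setdiff(names(ctl_args), ok_ctl)
  if (length(bad)) {
    stop("unknown controller field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  list(controller = do.call(controller_params, ctl_args),
       plant = do.call(plant_params, pl_args))
}

#' Save a configuration bundle as YAML
#'
#' @param config A list with \code{controller} and/or \code{plant} parameter
#'   objects (as returned by \code{\link{load_config}}).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x$preset <- NULL
    x
  }
  out <- list()
  if (!is.null(config$controller)) out$controller <- strip(config$controller)
  if (!is.null(config$plant)) out$plant <- strip(config$plant)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a trial record to CSV
#'
#' One row per 20-ms control step, columns \code{time_s},
#' \code{pressure_cmH2O}, \code{infused_mL}, \code{voided_mL},
#' \code{residual_mL}, per-channel amplitude/frequency/gate, and
#' \code{epoch_index}. Values are written with 15 significant digits so the
#' write/read round trip is lossless at double precision.
#'
#' @param trial An \code{"isms_trial"} or a trial-record data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trial_record <- function(trial, path) {
  record <- if (inherits(trial, "isms_trial")) trial$record else trial
  stopifnot(is.data.frame(record))
  fmt <- record
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial record CSV
#'
#' Validates the dialect written by \code{\link{write_trial_record}}: the
#' mandatory columns must be present and numeric, the record non-empty, and
#' the time grid uniform. Malformed rows are reported with their line
#' numbers.
#'
#' @param path Input path.
#' @param tol Relative tolerance on time-grid uniformity.
#' @return The record data frame.
#' @export
read_trial_record <- function(path, tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(rec) == 0) stop("empty trial record: ", path, call. = FALSE)
  need <- c("time_s", "pressure_cmH2O", "residual_mL", "epoch_index")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop("trial record lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(record_colnames, names(rec))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(rec[[col]]))))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    rec[[col]] <- as.numeric(rec[[col]])
  }
  dt <- diff(rec$time_s)
  if (any(dt <= 0)) {
    stop("time column is not strictly increasing at line(s) ",
         paste(utils::head(which(dt <= 0) + 2L, 5), collapse = ", "),
         call. = FALSE)
  }
  if ((max(dt) - min(dt)) > tol * stats::median(dt)) {
    stop("non-uniform time grid (step varies from ",
         format(min(dt)), " to ", format(max(dt)),
         " s); resample before analysis", call. = FALSE)
  }
  rec
}

#' Resample an externally recorded trial to a uniform grid
#'
#' Linear interpolation of every numeric column onto a uniform time grid;
#' gate and epoch-index columns are carried with constant (last value
#' forward) interpolation. A message notes that resampling occurred.
#'
#' @param record Data frame with at least \code{time_s}.
#' @param dt Target sampling step in seconds.
#' @return The resampled record.
#' @export
resample_trial_record <- function(record, dt = 0.02) {
  stopifnot(is.data.frame(record), "time_s" %in% names(record))
  grid <- seq(record$time_s[1], record$time_s[nrow(record)], by = dt)
  out <- data.frame(time_s = grid)
  step_cols <- c("ch1_gate", "ch2_gate", "epoch_index",
                 "ch1_amp_uA", "ch1_freq_Hz", "ch2_amp_uA", "ch2_freq_Hz")
  for (col in setdiff(names(record), "time_s")) {
    method <- if (col %in% step_cols) "constant" else "linear"
    out[[col]] <- stats::approx(record$time_s, record[[col]], xout = grid,
                                method = method, rule = 2)$y
  }
  message("resampled trial record to a uniform ", dt, "-s grid (",
          nrow(out), " samples)")
  out
}

#' Write per-epoch and per-trial metric tables as CSV
#'
#' @param metrics A list as returned by \code{\link{trial_metrics}}.
#' @param per_epoch_path,trial_path Output paths (either may be NULL).
#' @return Invisibly, the paths written.
#' @export
write_metrics_csv <- function(metrics, per_epoch_path = NULL,
                              trial_path = NULL) {
  if (!is.null(per_epoch_path)) {
    utils::write.csv(metrics$per_epoch, per_epoch_path, row.names = FALSE)
  }
  if (!is.null(trial_path)) {
    utils::write.csv(metrics$trial, trial_path, row.names = FALSE)
  }
  invisible(c(per_epoch_path, trial_path))
}

#' Write a run manifest
#'
#' Records the package version, R version, seed, timestamp and the full
#' parameter set of a run as JSON, for reproducibility audits.
#'
#' @param path Output path.
#' @param seed The seed used.
#' @param config Optional list of parameter objects to embed.
#' @param extra Optional named list of additional fields.
#' @return The path, invisibly.
#' @export
run_manifest <- function(path, seed = NULL, config = NULL, extra = NULL) {
  obj <- list(
    package = "ismsloop",
    version = as.character(utils::packageVersion("ismsloop")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed)
  if (!is.null(config)) obj$config <- lapply(config, unclass)
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @export
print.isms_trial <- function(x, ...) {
  cat("Closed-loop ISMS voiding trial\n")
  cat(sprintf("  epochs: %d  termination: %s\n", x$n_epochs,
              x$termination_reason))
  cat(sprintf("  fill: %.3f mL  voided: %.3f mL  residual: %.3f mL\n",
              x$fill_target_mL, x$UVR_mL, x$RV_mL))
  cat(sprintf("  voiding efficiency: %.1f%%  stimulation time: %.0f s\n",
              x$VE_percent, x$stimulation_time_s))
  invisible(x)
}
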
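#' Voiding efficiency from voided and residual volume
#'
#' \code{VE = 100 * UVR / (RV + UVR)}, where UVR is the urine voided volume
#' and RV the residual volume left in the bladder.
#'
#' @param UVR_mL Voided volume (mL, >= 0).
#' @param RV_mL Residual volume (mL, >= 0).
#' @return Voiding efficiency in percent (0-100). Both volumes zero is
#'   undefined and raises an error rather than returning 0.
#' @examples
#' voiding_efficiency(3, 1)  # 75
#' @export
voiding_efficiency <- function(UVR_mL, RV_mL) {
  if (any(UVR_mL < 0) || any(RV_mL < 0)) {
    stop("volumes must be non-negative", call. = FALSE)
  }
  tot <- UVR_mL + RV_mL
  if (any(tot <= 0)) {
    stop("voiding efficiency is undefined when both UVR and RV are zero",
         call. = FALSE)
  }
  100 * UVR_mL / tot
}

# Coerce an isms_trial or a trial-record data frame to the record df and
# check the columns the metric functions need.
as_trial_record <- function(record) {
  if (inherits(record, "isms_trial")) record <- record$record
  need <- c("time_s", "pressure_cmH2O", "residual_mL", "epoch_index")
  miss <- setdiff(need, names(record))
  if (length(miss)) {
    stop("trial record lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  record
}

# Row indices of an epoch's analysis window. "on_plus_off" spans the whole
# epoch period (post-stimulus spurts during OFF are part of the epoch);
# "on_only" stops at the last sample for which any channel gate is high.
epoch_window_idx <- function(record, epoch, window = c("on_plus_off", "on_only")) {
  window <- match.arg(window)
  idx <- which(record$epoch_index == epoch)
  if (!length(idx)) stop("epoch ", epoch, " not present in record", call. = FALSE)
  if (window == "on_only") {
    g <- rep(0, length(idx))
    if ("ch1_gate" %in% names(record)) g <- g + record$ch1_gate[idx]
    if ("ch2_gate" %in% names(record)) g <- g + record$ch2_gate[idx]
    last_on <- if (any(g > 0)) max(which(g > 0)) else length(idx)
    idx <- idx[seq_len(last_on)]
  }
  idx
}

# Mean pressure over the 1 s preceding the epoch's first sample.
epoch_baseline <- function(record, epoch) {
  idx <- which(record$epoch_index == epoch)
  first <- idx[1]
  if (first <= 1) stop("epoch ", epoch, " has no pre-onset history", call. = FALSE)
  dt <- stats::median(diff(record$time_s))
  n_base <- max(1L, as.integer(round(1 / dt)))
  if (first - n_base < 1) {
    stop("epoch ", epoch, " has less than 1 s of pre-onset history",
         call. = FALSE)
  }
  mean(record$pressure_cmH2O[(first - n_base):(first - 1)])
}

#' Peak intravesical pressure of one stimulation epoch
#'
#' Maximum recorded pressure over the epoch window. By default the window is
#' the full ON + OFF period, so pressure carried by the post-stimulus spurt
#' is included; \code{window = "on_only"} restricts it to the ON span.
#'
#' @param record An \code{"isms_trial"} or its record data frame.
#' @param epoch Epoch number (>= 1).
#' @param window \code{"on_plus_off"} (default) or \code{"on_only"}.
#' @return Peak pressure in cmH2O.
#' @export
peak_pressure <- function(record, epoch, window = c("on_plus_off", "on_only")) {
  record <- as_trial_record(record)
  idx <- epoch_window_idx(record, epoch, window)
  max(record$pressure_cmH2O[idx])
}

#' Pressure change of one stimulation epoch over its pre-onset baseline
#'
#' The baseline is the mean pressure over the 1-s window before the epoch
#' onset (for epoch 1, the final second of the fill/rest phase); the change
#' is the epoch's peak pressure minus that baseline.
#'
#' @inheritParams peak_pressure
#' @return Pressure change in cmH2O.
#' @export
delta_p <- function(record, epoch, window = c("on_plus_off", "on_only")) {
  record <- as_trial_record(record)
  peak_pressure(record, epoch, window) - epoch_baseline(record, epoch)
}

#' Residual volume at the end of an epoch, as a percentage
#'
#' Expressed relative to the mean bladder volume over the 1 s prior to the
#' first stimulation epoch.
#'
#' @inheritParams peak_pressure
#' @return Residual volume in percent of the pre-first-epoch volume.
#' @export
residual_percent <- function(record, epoch) {
  record <- as_trial_record(record)
  idx1 <- which(record$epoch_index == 1)
  if (!length(idx1)) stop("record has no stimulation epochs", call. = FALSE)
  first <- idx1[1]
  dt <- stats::median(diff(record$time_s))
  n_base <- max(1L, as.integer(round(1 / dt)))
  if (first - n_base < 1) {
    stop("first epoch has less than 1 s of pre-onset history", call. = FALSE)
  }
  ref <- mean(record$residual_mL[(first - n_base):(first - 1)])
  if (ref <= 0) stop("pre-first-epoch reference volume is zero", call. = FALSE)
  idx <- which(record$epoch_index == epoch)
  if (!length(idx)) stop("epoch ", epoch, " not present in record", call. = FALSE)
  100 * record$residual_mL[idx[length(idx)]] / ref
}

#' Per-epoch and per-trial cystometry metrics of a trial
#'
#' @param trial An \code{"isms_trial"} or a trial-record data frame.
#' @param window Epoch window for peak pressure and delta-P.
#' @return A list with \code{per_epoch} (one row per epoch: peak pressure,
#'   delta-P, residual in mL and percent, voided volume) and \code{trial}
#'   (one row: UVR, RV, VE, number of epochs, stimulation time).
#' @export
trial_metrics <- function(trial, window = c("on_plus_off", "on_only")) {
  window <- match.arg(window)
  record <- as_trial_record(trial)
  eps <- sort(unique(record$epoch_index[record$epoch_index > 0]))
  per <- do.call(rbind, lapply(eps, function(e) {
    idx <- which(record$epoch_index == e)
    data.frame(
      epoch = e,
      peak_pressure_cmH2O = peak_pressure(record, e, window),
      delta_p_cmH2O = delta_p(record, e, window),
      residual_mL = record$residual_mL[idx[length(idx)]],
      residual_percent = residual_percent(record, e),
      voided_epoch_mL = if ("voided_mL" %in% names(record))
        diff(range(record$voided_mL[idx])) else NA_real_)
  }))
  if ("voided_mL" %in% names(record)) {
    uvr <- record$voided_mL[nrow(record)]
  } else if (inherits(trial, "isms_trial")) {
    uvr <- trial$UVR_mL
  } else {
    uvr <- NA_real_
  }
  rv <- record$residual_mL[nrow(record)]
  dt <- stats::median(diff(record$time_s))
  stim_time <- sum(record$epoch_index > 0) * dt
  list(per_epoch = per,
       trial = data.frame(
         UVR_mL = uvr, RV_mL = rv,
         VE_percent = voiding_efficiency(uvr, rv),
         n_epochs = length(eps),
         stimulation_time_s = stim_time))
}

#' Summarise per-trial metrics across conditions
#'
#' Computes mean, sample standard deviation (n - 1 denominator) and n of the
#' requested value columns within each group. No hypothesis tests are
#' performed.
#'
#' @param trials Data frame with one row per trial.
#' @param by Character vector of grouping column names.
#' @param vars Character vector of numeric columns to summarise.
#' @return Data frame with one row per group and columns
#'   \code{<var>_mean}, \code{<var>_sd} for each variable, plus \code{n}.
#' @examples
#' d <- data.frame(mode = c("a", "a"), VE = c(80, 100))
#' summarize_trials(d, by = "mode", vars = "VE")  # 90 +/- 14.14, n = 2
#' @export
summarize_trials <- function(trials, by, vars = "VE_percent") {
  stopifnot(is.data.frame(trials))
  miss <- setdiff(c(by, vars), names(trials))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(trials) == 0) stop("no trials to summarise", call. = FALSE)
  key <- interaction(trials[by], drop = TRUE, lex.order = TRUE)
  groups <- split(trials, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    row <- g[1, by, drop = FALSE]
    for (v in vars) {
      row[[paste0(v, "_mean")]] <- mean(g[[v]])
      row[[paste0(v, "_sd")]] <- if (nrow(g) > 1) stats::sd(g[[v]]) else 0
    }
    row$n <- nrow(g)
    row
  }))
  rownames(out) <- NULL
  out
}
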
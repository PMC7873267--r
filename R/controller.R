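#' Closed-loop controller parameters
#'
#' Constants of the finite-state controller that steps pulse amplitude and,
#' in hybrid mode, pulse frequency from epoch to epoch based on
#' residual-volume feedback.
#'
#' @param I_start Initial current amplitude (uA) at \code{f_start}.
#' @param I_th Initial amplitude (uA) used when the frequency is raised; the
#'   default re-uses \code{I_start}.
#' @param I_max Maximum allowable amplitude (uA).
#' @param f_start Initial stimulation frequency (Hz).
#' @param f_max Maximum allowable frequency (Hz).
#' @param dI Amplitude increment per epoch (uA, > 0).
#' @param df Frequency increment (Hz, > 0).
#' @param modulation \code{"hybrid"} (amplitude then frequency stepping),
#'   \code{"PAM"} (amplitude only) or \code{"constant"}.
#' @param electrode_mode \code{"two_asynchronous"}, \code{"two_synchronous"}
#'   or \code{"single"}.
#' @param duty Duty-cycle preset, \code{"33"} (2 s ON, 4 s OFF) or
#'   \code{"50"} (2 s ON, 2 s OFF).
#' @param fill_fraction Fraction of V_th to fill before the first epoch.
#' @param fill_rate_mL_h Pre-trial infusion rate (mL/h).
#' @param rest_s Simulated rest between fill and the first epoch (s); must
#'   be >= 1 s so the baseline window of the cystometry metrics exists.
#' @param zero_tol_frac Residual at or below this fraction of the
#'   pre-first-epoch volume counts as "residual reached zero".
#' @param max_epochs Hard guard on the epoch count.
#' @param terminate_at_f_max If \code{TRUE} the loop stops as soon as the
#'   frequency reaches \code{f_max}; the default runs one full amplitude
#'   ramp at \code{f_max} before giving up.
#' @return An \code{"isms_controller_params"} list.
#' @export
controller_params <- function(I_start = 40, I_th = I_start, I_max = 150,
                              f_start = 20, f_max = 30, dI = 10, df = 10,
                              modulation = c("hybrid", "PAM", "constant"),
                              electrode_mode = c("two_asynchronous",
                                                 "two_synchronous", "single"),
                              duty = c("33", "50"),
                              fill_fraction = 0.9, fill_rate_mL_h = 20,
                              rest_s = 2, zero_tol_frac = 0.01,
                              max_epochs = 200, terminate_at_f_max = FALSE) {
  modulation <- match.arg(modulation)
  electrode_mode <- match.arg(electrode_mode)
  duty <- as.character(duty)[1]
  duty <- match.arg(duty, c("33", "50"))
  p <- list(I_start = I_start, I_th = I_th, I_max = I_max,
            f_start = f_start, f_max = f_max, dI = dI, df = df,
            modulation = modulation, electrode_mode = electrode_mode,
            duty = duty, fill_fraction = fill_fraction,
            fill_rate_mL_h = fill_rate_mL_h, rest_s = rest_s,
            zero_tol_frac = zero_tol_frac, max_epochs = max_epochs,
            terminate_at_f_max = terminate_at_f_max)
  validate_controller_params(p)
  structure(p, class = "isms_controller_params")
}

validate_controller_params <- function(p) {
  if (p$I_start > p$I_max) {
    stop("'I_start' (", p$I_start, ") must not exceed 'I_max' (", p$I_max, ")",
         call. = FALSE)
  }
  if (p$I_th > p$I_max) {
    stop("'I_th' (", p$I_th, ") must not exceed 'I_max' (", p$I_max, ")",
         call. = FALSE)
  }
  if (p$f_start > p$f_max) {
    stop("'f_start' (", p$f_start, ") must not exceed 'f_max' (", p$f_max, ")",
         call. = FALSE)
  }
  if (p$dI <= 0) stop("'dI' must be > 0", call. = FALSE)
  if (p$df <= 0) stop("'df' must be > 0", call. = FALSE)
  if (p$I_start <= 0 || p$f_start <= 0) {
    stop("'I_start' and 'f_start' must be positive", call. = FALSE)
  }
  if (p$fill_fraction <= 0 || p$fill_fraction > 1) {
    stop("'fill_fraction' must be in (0, 1]", call. = FALSE)
  }
  if (p$rest_s < 1) stop("'rest_s' must be >= 1 s", call. = FALSE)
  if (p$zero_tol_frac < 0) stop("'zero_tol_frac' must be >= 0", call. = FALSE)
  if (p$max_epochs < 1) stop("'max_epochs' must be >= 1", call. = FALSE)
  invisible(p)
}

controller_init <- function(params) {
  structure(
    list(epoch_index = 0L,
         amplitude = params$I_start,
         frequency = params$f_start,
         terminated = FALSE,
         reason = NA_character_),
    class = "isms_controller_state")
}

#' Initialise a closed-loop voiding trial
#'
#' @param V_th Threshold volume of the subject (mL, > 0).
#' @param params An \code{"isms_controller_params"} object.
#' @return A list with \code{state} (controller at \code{I_start},
#'   \code{f_start}, epoch 0) and \code{fill_target_mL}
#'   (\code{fill_fraction * V_th}).
#' @export
init_trial <- function(V_th, params = controller_params()) {
  if (!is.numeric(V_th) || length(V_th) != 1 || !is.finite(V_th) || V_th <= 0) {
    stop("'V_th' must be a single positive volume in mL", call. = FALSE)
  }
  list(state = controller_init(params),
       fill_target_mL = params$fill_fraction * V_th)
}

#' Advance the controller one epoch from residual-volume feedback
#'
#' Implements the controller's decision tree. If the residual is at or below
#' the zero tolerance the loop terminates (\code{residual_zero}). Otherwise,
#' under PAM or hybrid modulation the amplitude steps up by \code{dI} until
#' \code{I_max}; under hybrid modulation, once \code{I_max} is reached the
#' frequency steps up by \code{df} and the amplitude restarts at
#' \code{I_th}; when amplitude and frequency are both exhausted the loop
#' terminates (\code{f_max_exhausted}). Constant modulation never changes
#' the parameters; PAM holds at \code{I_max}.
#'
#' @param state An \code{"isms_controller_state"} (not terminated).
#' @param residual_mL Residual volume measured at the end of the epoch's OFF
#'   period (mL).
#' @param params An \code{"isms_controller_params"} object.
#' @param tol Zero-residual tolerance in mL.
#' @return The updated controller state.
#' @export
next_epoch_params <- function(state, residual_mL, params, tol = 0) {
  stopifnot(inherits(state, "isms_controller_state"))
  if (state$terminated) {
    stop("next_epoch_params() called on a terminated controller state",
         call. = FALSE)
  }
  if (residual_mL <= tol) {
    state$terminated <- TRUE
    state$reason <- "residual_zero"
    return(state)
  }
  if (params$modulation == "constant") return(state)
  if (state$amplitude < params$I_max) {
    state$amplitude <- min(state$amplitude + params$dI, params$I_max)
    return(state)
  }
  # amplitude saturated at I_max
  if (params$modulation == "PAM") return(state)
  if (state$frequency < params$f_max) {
    state$frequency <- min(state$frequency + params$df, params$f_max)
    state$amplitude <- params$I_th
    if (params$terminate_at_f_max && state$frequency >= params$f_max) {
      state$terminated <- TRUE
      state$reason <- "f_max_exhausted"
    }
    return(state)
  }
  state$terminated <- TRUE
  state$reason <- "f_max_exhausted"
  state
}

#' Analytic bound on the closed-loop epoch count
#'
#' For hybrid modulation the controller can run at most one amplitude ramp
#' from \code{I_start} to \code{I_max} at \code{f_start} plus, for each
#' frequency step up to \code{f_max}, one ramp from \code{I_th} to
#' \code{I_max}. PAM and constant modulation have no exhaustion branch, so
#' their bound is the \code{max_epochs} guard.
#'
#' @param params An \code{"isms_controller_params"} object.
#' @return Maximum possible epoch count.
#' @export
n_max_epochs <- function(params) {
  if (params$modulation != "hybrid") return(params$max_epochs)
  n1 <- floor((params$I_max - params$I_start) / params$dI) + 1
  nf <- floor((params$f_max - params$f_start) / params$df)
  n2 <- floor((params$I_max - params$I_th) / params$dI) + 1
  if (params$terminate_at_f_max && nf > 0) {
    bound <- n1 + (nf - 1) * n2
  } else {
    bound <- n1 + nf * n2
  }
  min(bound, params$max_epochs)
}

# Per-step channel gates over one epoch period. Returns list(g1, g2, n).
epoch_gates <- function(schedule, electrode_mode, dt) {
  n <- as.integer(round(schedule$period_s / dt))
  n_on <- as.integer(round(schedule$on_s / dt))
  g1 <- c(rep(1, n_on), rep(0, n - n_on))
  if (electrode_mode == "single") {
    g2 <- numeric(n)
  } else if (electrode_mode == "two_synchronous") {
    g2 <- g1
  } else {
    off <- interleave_offset(if (isTRUE(all.equal(schedule$duty_cycle, 1 / 3)))
      "33" else "50", "asynchronous")
    k0 <- as.integer(round(off / dt))
    g2 <- numeric(n)
    g2[(k0 + 1):(k0 + n_on)] <- 1
  }
  list(g1 = g1, g2 = g2, n = n)
}

record_colnames <- c("time_s", "pressure_cmH2O", "infused_mL", "voided_mL",
                     "residual_mL", "ch1_amp_uA", "ch1_freq_Hz", "ch1_gate",
                     "ch2_amp_uA", "ch2_freq_Hz", "ch2_gate", "epoch_index")

# Shared fill + rest preamble. Returns list(state, block, ref_volume).
trial_preamble <- function(plant, fill_target, fill_rate, rest_s) {
  st <- manual_empty(plant_init(plant))
  st <- plant_fill(st, plant, fill_target, fill_rate)
  n_rest <- as.integer(round(rest_s / plant$dt))
  seg <- plant_segment(st, plant, n_rest, g1 = numeric(n_rest), epoch = 0L)
  list(state = seg$state, block = seg$record,
       ref_volume = seg$state$volume_mL)
}

finish_trial <- function(plant, control_like, blocks, epochs, state,
                         reason, ref_volume, fill_target, schedule) {
  rec <- as.data.frame(do.call(rbind, blocks))
  names(rec) <- record_colnames
  epochs <- do.call(rbind, epochs)
  uvr <- state$voided_mL
  rv <- state$volume_mL
  n_ep <- if (is.null(epochs)) 0L else nrow(epochs)
  structure(
    list(record = rec, epochs = epochs, plant = plant,
         control = control_like, termination_reason = reason,
         n_epochs = n_ep, fill_target_mL = fill_target,
         ref_volume_mL = ref_volume, UVR_mL = uvr, RV_mL = rv,
         VE_percent = if (uvr + rv > 0) 100 * uvr / (uvr + rv) else NA_real_,
         stimulation_time_s = n_ep * schedule$period_s),
    class = "isms_trial")
}

#' Run one closed-loop voiding trial against the synthetic plant
#'
#' Executes the full protocol: manual emptying, fill to
#' \code{fill_fraction * V_th} at \code{fill_rate_mL_h}, a short rest, then
#' repeated stimulation epochs. Each epoch compiles one duty-cycled ON/OFF
#' period for the configured electrode mode, advances the plant at the 20-ms
#' control step, measures the residual volume at the end of the OFF period
#' and updates the controller, until the controller terminates or the
#' epoch guard trips.
#'
#' @param plant An \code{"isms_plant_params"} object.
#' @param control An \code{"isms_controller_params"} object.
#' @param seed Optional integer seed for the observation-noise stream.
#' @return An \code{"isms_trial"} object: the sampled \code{record} data
#'   frame (20-ms grid), a per-epoch table (\code{epoch},
#'   \code{amplitude_uA}, \code{frequency_Hz}, \code{residual_mL},
#'   \code{voided_epoch_mL}, \code{peak_pressure_cmH2O}), the termination
#'   reason, and the per-trial volumes and voiding efficiency.
#' @export
run_closed_loop <- function(plant = plant_params(),
                            control = controller_params(), seed = NULL) {
  stopifnot(inherits(plant, "isms_plant_params"),
            inherits(control, "isms_controller_params"))
  if (!is.null(seed)) set.seed(seed)
  schedule <- duty_preset(control$duty)
  fill_target <- control$fill_fraction * plant$V_th
  pre <- trial_preamble(plant, fill_target, control$fill_rate_mL_h,
                        control$rest_s)
  st <- pre$state
  tol <- control$zero_tol_frac * pre$ref_volume
  gates <- epoch_gates(schedule, control$electrode_mode, plant$dt)
  cs <- controller_init(control)
  blocks <- list(pre$block)
  epochs <- list()
  reason <- "max_epochs_guard"
  e <- 0L
  repeat {
    e <- e + 1L
    voided_before <- st$voided_mL
    two <- control$electrode_mode != "single"
    seg <- plant_segment(st, plant, gates$n, gates$g1, gates$g2,
                         I1 = cs$amplitude, f1 = cs$frequency,
                         I2 = if (two) cs$amplitude else 0,
                         f2 = if (two) cs$frequency else 0,
                         epoch = e)
    st <- seg$state
    blocks[[length(blocks) + 1L]] <- seg$record
    epochs[[e]] <- data.frame(
      epoch = e, amplitude_uA = cs$amplitude, frequency_Hz = cs$frequency,
      residual_mL = st$volume_mL,
      voided_epoch_mL = st$voided_mL - voided_before,
      peak_pressure_cmH2O = max(seg$record[, 2]))
    cs$epoch_index <- e
    cs <- next_epoch_params(cs, st$volume_mL, control, tol)
    if (cs$terminated) { reason <- cs$reason; break }
    if (e >= control$max_epochs) break
  }
  finish_trial(plant, control, blocks, epochs, st, reason,
               pre$ref_volume, fill_target, schedule)
}

#' Run an open-loop stimulation trial with fixed per-epoch parameters
#'
#' Same fill/rest/epoch machinery as \code{\link{run_closed_loop}}, but the
#' per-epoch amplitude and frequency sequences are given up front instead of
#' being chosen by the controller. Used by the calibration ramp and the
#' pattern experiments.
#'
#' @param plant An \code{"isms_plant_params"} object.
#' @param amplitudes_uA Per-epoch amplitudes (uA).
#' @param frequencies_Hz Per-epoch frequencies (Hz); recycled if scalar.
#' @param duty Duty preset, \code{"33"} or \code{"50"}.
#' @param electrode_mode \code{"single"}, \code{"two_synchronous"} or
#'   \code{"two_asynchronous"}.
#' @param fill_fraction,fill_rate_mL_h,rest_s Fill protocol (see
#'   \code{\link{controller_params}}).
#' @param seed Optional integer seed.
#' @return An \code{"isms_trial"} object.
#' @export
run_open_loop <- function(plant, amplitudes_uA, frequencies_Hz = 20,
                          duty = "33", electrode_mode = "single",
                          fill_fraction = 0.9, fill_rate_mL_h = 20,
                          rest_s = 2, seed = NULL) {
  stopifnot(inherits(plant, "isms_plant_params"))
  if (!is.null(seed)) set.seed(seed)
  schedule <- duty_preset(duty)
  n_ep <- length(amplitudes_uA)
  frequencies_Hz <- rep_len(frequencies_Hz, n_ep)
  fill_target <- fill_fraction * plant$V_th
  pre <- trial_preamble(plant, fill_target, fill_rate_mL_h, rest_s)
  st <- pre$state
  gates <- epoch_gates(schedule, electrode_mode, plant$dt)
  blocks <- list(pre$block)
  epochs <- list()
  two <- electrode_mode != "single"
  for (e in seq_len(n_ep)) {
    voided_before <- st$voided_mL
    seg <- plant_segment(st, plant, gates$n, gates$g1, gates$g2,
                         I1 = amplitudes_uA[e], f1 = frequencies_Hz[e],
                         I2 = if (two) amplitudes_uA[e] else 0,
                         f2 = if (two) frequencies_Hz[e] else 0,
                         epoch = e)
    st <- seg$state
    blocks[[e + 1L]] <- seg$record
    epochs[[e]] <- data.frame(
      epoch = e, amplitude_uA = amplitudes_uA[e],
      frequency_Hz = frequencies_Hz[e], residual_mL = st$volume_mL,
      voided_epoch_mL = st$voided_mL - voided_before,
      peak_pressure_cmH2O = max(seg$record[, 2]))
  }
  finish_trial(plant, list(duty = duty, electrode_mode = electrode_mode),
               blocks, epochs, st, "open_loop_complete",
               pre$ref_volume, fill_target, schedule)
}

#' Calibrate the initial current amplitude by an amplitude ramp
#'
#' Replays the amplitude-ramp calibration protocol: the bladder is filled to
#' 90% of V_th, then open-loop epochs are delivered starting at
#' \code{ramp_start} uA and stepping by \code{dI} up to \code{I_max}. Across
#' seeded replicate trials, the selected \code{I_start} is the lowest
#' amplitude whose voided-volume change from the previous epoch exceeds a
#' significance surrogate: \code{signif_mult} times the replicate standard
#' deviation of that change, with a floor of \code{min_frac} of the fill
#' volume (which decides in the fully deterministic case).
#'
#' @param plant An \code{"isms_plant_params"} object.
#' @param frequency_Hz Stimulation frequency during the ramp (Hz).
#' @param dI Amplitude step (uA).
#' @param ramp_start First ramp amplitude (uA).
#' @param I_max Last ramp amplitude (uA).
#' @param duty Duty preset.
#' @param replicates Number of replicate ramp trials.
#' @param signif_mult Multiple of the replicate SD the mean increment must
#'   exceed.
#' @param min_frac Floor on the required increment, as a fraction of the
#'   fill volume.
#' @param jitter_cv Coefficient of variation of the per-replicate plant
#'   jitter (0 disables it).
#' @param seed Integer seed.
#' @return An \code{"isms_calibration"} list: \code{I_start} (uA, or
#'   \code{NA} if no amplitude qualifies), \code{qualified}, and the full
#'   ramp \code{table} (amplitude, mean voided volume, mean and SD of the
#'   consecutive increment, qualification flag).
#' @export
calibrate_I_start <- function(plant, frequency_Hz = 20, dI = 10,
                              ramp_start = 10, I_max = 150, duty = "33",
                              replicates = 5, signif_mult = 2,
                              min_frac = 0.02, jitter_cv = 0.05,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amps <- seq(ramp_start, I_max, by = dI)
  v <- matrix(0, replicates, length(amps))
  fill_target <- 0.9 * plant$V_th
  for (r in seq_len(replicates)) {
    pj <- jitter_plant(plant, jitter_cv,
                       fields = c("detrusor_gain", "urethral_resistance"))
    tr <- run_open_loop(pj, amps, frequency_Hz, duty = duty)
    v[r, ] <- tr$epochs$voided_epoch_mL
  }
  incr <- cbind(v[, 1, drop = FALSE], t(apply(v, 1, diff)))
  mean_incr <- colMeans(incr)
  sd_incr <- apply(incr, 2, stats::sd)
  if (replicates == 1) sd_incr[] <- 0
  need <- pmax(signif_mult * sd_incr, min_frac * fill_target)
  qual <- mean_incr > need
  tab <- data.frame(amplitude_uA = amps,
                    mean_voided_mL = colMeans(v),
                    mean_increment_mL = mean_incr,
                    sd_increment_mL = sd_incr,
                    required_mL = need,
                    qualifies = qual)
  i <- which(qual)[1]
  structure(
    list(I_start = if (is.na(i)) NA_real_ else amps[i],
         qualified = !is.na(i), table = tab,
         replicates = replicates, frequency_Hz = frequency_Hz),
    class = "isms_calibration")
}

#' @export
print.isms_calibration <- function(x, ...) {
  if (x$qualified) {
    cat("I_start calibration at", x$frequency_Hz, "Hz:", x$I_start, "uA\n")
  } else {
    cat("I_start calibration at", x$frequency_Hz,
        "Hz failed: no amplitude produced a significant voiding increase\n")
  }
  print(x$table, digits = 4)
  invisible(x)
}

#' Isovolumetric frequency sweep
#'
#' With outflow blocked and the bladder held at a low volume (default
#' 0.25 V_th), each frequency is applied for \code{stim_s} seconds of
#' continuous single-channel stimulation followed by \code{rest_s} seconds
#' of rest, and the pressure rise over the 1-s pre-stimulation baseline is
#' reported.
#'
#' @param plant An \code{"isms_plant_params"} object.
#' @param frequencies_Hz Frequencies to test (Hz, > 0).
#' @param amplitude_uA Stimulation amplitude (uA).
#' @param volume_fraction Held volume as a fraction of V_th.
#' @param stim_s Stimulation duration per frequency (s).
#' @param rest_s Inter-stimulation interval (s).
#' @param seed Optional integer seed.
#' @return Data frame with \code{frequency_Hz}, \code{delta_p_cmH2O},
#'   \code{peak_pressure_cmH2O} and \code{baseline_cmH2O}.
#' @export
frequency_sweep_isovolumetric <- function(plant,
                                          frequencies_Hz = c(10, 20, 30, 40, 50),
                                          amplitude_uA = 80,
                                          volume_fraction = 0.25,
                                          stim_s = 10, rest_s = 20,
                                          seed = NULL) {
  stopifnot(inherits(plant, "isms_plant_params"))
  if (any(frequencies_Hz <= 0)) {
    stop("frequencies must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  dt <- plant$dt
  st <- manual_empty(plant_init(plant))
  st <- plant_fill(st, plant, volume_fraction * plant$V_th)
  st <- set_isovolumetric(st, TRUE)
  n_pre <- as.integer(round(2 / dt))
  n_stim <- as.integer(round(stim_s / dt))
  n_rest <- as.integer(round(rest_s / dt))
  n_base <- as.integer(round(1 / dt))
  seg <- plant_segment(st, plant, n_pre, g1 = numeric(n_pre))
  st <- seg$state
  tail_p <- seg$record[(n_pre - n_base + 1):n_pre, 2]
  out <- data.frame(frequency_Hz = frequencies_Hz, delta_p_cmH2O = NA_real_,
                    peak_pressure_cmH2O = NA_real_, baseline_cmH2O = NA_real_)
  for (i in seq_along(frequencies_Hz)) {
    base <- mean(tail_p)
    seg <- plant_segment(st, plant, n_stim, g1 = rep(1, n_stim),
                         I1 = amplitude_uA, f1 = frequencies_Hz[i])
    st <- seg$state
    pk <- max(seg$record[, 2])
    out$baseline_cmH2O[i] <- base
    out$peak_pressure_cmH2O[i] <- pk
    out$delta_p_cmH2O[i] <- pk - base
    seg <- plant_segment(st, plant, n_rest, g1 = numeric(n_rest))
    st <- seg$state
    tail_p <- seg$record[(n_rest - n_base + 1):n_rest, 2]
  }
  out
}
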
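# Per-replicate seeds derived from a base seed; kept small so downstream
# set.seed() calls stay within 32-bit integer range.
replicate_seeds <- function(seed, n) {
  if (is.null(seed)) seed <- 1L
  as.integer(seed) + seq_len(n) - 1L
}

# One jittered replicate trial of a closed-loop arm.
run_arm_replicate <- function(plant, control, seed, jitter_cv) {
  set.seed(seed)
  pj <- jitter_plant(plant, jitter_cv)
  run_closed_loop(pj, control)
}

#' Amplitude-ramp experiment
#'
#' Open-loop single-electrode trial in which the amplitude starts low and
#' steps up by \code{dI} each epoch to \code{I_max}, at fixed frequency and
#' duty cycle. Reports per-epoch amplitude, peak pressure, delta-P and
#' voided volume.
#'
#' @param plant An \code{"isms_plant_params"} object.
#' @param amp_start First epoch amplitude (uA).
#' @param dI Amplitude step (uA).
#' @param I_max Last amplitude (uA).
#' @param frequency_Hz Stimulation frequency (Hz).
#' @param duty Duty preset.
#' @param seed Optional integer seed.
#' @return A list with \code{per_epoch} (the ramp table) and \code{trial}
#'   (the underlying \code{"isms_trial"}).
#' @export
amplitude_ramp_experiment <- function(plant = plant_params(), amp_start = 10,
                                      dI = 10, I_max = 150,
                                      frequency_Hz = 20, duty = "33",
                                      seed = NULL) {
  amps <- seq(amp_start, I_max, by = dI)
  tr <- run_open_loop(plant, amps, frequency_Hz, duty = duty,
                      electrode_mode = "single", seed = seed)
  m <- trial_metrics(tr)
  per <- merge(tr$epochs[, c("epoch", "amplitude_uA", "frequency_Hz")],
               m$per_epoch, by = "epoch")
  list(per_epoch = per, trial = tr)
}

#' Fixed-amplitude versus stepped-amplitude pattern comparison
#'
#' Runs two open-loop arms over the same schedule and plant: a fixed
#' amplitude (default 80 uA) and a step pattern starting at
#' \code{step_start} (default 40 uA) incrementing \code{dI} per epoch. With
#' the defaults the two arms inject exactly equal total charge after nine
#' epochs. Reports per-epoch cumulative voiding efficiency for both arms and
#' a cumulative-charge audit.
#'
#' @param plant An \code{"isms_plant_params"} object.
#' @param n_epochs Number of epochs per arm.
#' @param fixed_amp Fixed-arm amplitude (uA).
#' @param step_start First amplitude of the step arm (uA).
#' @param dI Step increment (uA).
#' @param frequency_Hz Stimulation frequency (Hz).
#' @param duty Duty preset.
#' @param pulse Pulse descriptor used for the charge audit.
#' @param seed Optional integer seed (same seed is used for both arms).
#' @return A list with \code{per_epoch} (epoch, per-arm amplitude,
#'   cumulative VE and cumulative charge), \code{summary} (final VE and
#'   total charge per arm) and the two \code{"isms_trial"} objects.
#' @export
pattern_comparison_experiment <- function(plant = plant_params(),
                                          n_epochs = 9, fixed_amp = 80,
                                          step_start = 40, dI = 10,
                                          frequency_Hz = 20, duty = "33",
                                          pulse = pulse_descriptor(0),
                                          seed = NULL) {
  amps_fixed <- rep(fixed_amp, n_epochs)
  amps_step <- seq(step_start, by = dI, length.out = n_epochs)
  tr_fixed <- run_open_loop(plant, amps_fixed, frequency_Hz, duty = duty,
                            seed = seed)
  tr_step <- run_open_loop(plant, amps_step, frequency_Hz, duty = duty,
                           seed = seed)
  cum_ve <- function(tr) {
    cumv <- cumsum(tr$epochs$voided_epoch_mL)
    100 * cumv / (cumv + tr$epochs$residual_mL)
  }
  charge <- function(amps) {
    tl <- compile_timelines(duty_preset(duty), "single", amps, frequency_Hz)
    cumsum(vapply(seq_along(amps), function(k)
      cumulative_charge(compile_timelines(duty_preset(duty), "single",
                                          amps[k], frequency_Hz), pulse),
      numeric(1)))
  }
  per <- data.frame(epoch = seq_len(n_epochs),
                    fixed_amplitude_uA = amps_fixed,
                    step_amplitude_uA = amps_step,
                    fixed_cum_VE_percent = cum_ve(tr_fixed),
                    step_cum_VE_percent = cum_ve(tr_step),
                    fixed_cum_charge_nC = charge(amps_fixed),
                    step_cum_charge_nC = charge(amps_step))
  list(per_epoch = per,
       summary = data.frame(
         pattern = c("fixed", "step"),
         VE_percent = c(tr_fixed$VE_percent, tr_step$VE_percent),
         total_charge_nC = c(per$fixed_cum_charge_nC[n_epochs],
                             per$step_cum_charge_nC[n_epochs])),
       fixed_trial = tr_fixed, step_trial = tr_step)
}

#' Electrode-mode comparison under closed-loop pulse-amplitude modulation
#'
#' Runs replicate closed-loop trials for each combination of electrode mode
#' and duty cycle, with per-replicate plant jitter, and summarises voiding
#' efficiency per arm.
#'
#' @param plant An \code{"isms_plant_params"} object.
#' @param modes Electrode modes to compare.
#' @param duties Duty presets to compare.
#' @param modulation Modulation strategy (default PAM).
#' @param replicates Replicate trials per arm.
#' @param jitter_cv Coefficient of variation of per-replicate plant jitter.
#' @param seed Integer base seed; replicate r of every arm uses seed + r - 1
#'   so arms share their plant-jitter schedule.
#' @param control Template controller parameters; modulation, mode and duty
#'   are overridden per arm.
#' @return A list with \code{trials} (one row per trial) and \code{summary}
#'   (mean, sd, n of VE per mode x duty).
#' @export
mode_comparison_experiment <- function(plant = plant_params(),
                                       modes = c("single", "two_synchronous",
                                                 "two_asynchronous"),
                                       duties = c("33", "50"),
                                       modulation = "PAM",
                                       replicates = 6, jitter_cv = 0.05,
                                       seed = 1,
                                       control = controller_params()) {
  seeds <- replicate_seeds(seed, replicates)
  rows <- list()
  for (duty in duties) {
    for (mode in modes) {
      ctrl <- control
      ctrl$modulation <- modulation
      ctrl$electrode_mode <- mode
      ctrl$duty <- duty
      validate_controller_params(ctrl)
      for (r in seq_len(replicates)) {
        tr <- run_arm_replicate(plant, ctrl, seeds[r], jitter_cv)
        rows[[length(rows) + 1L]] <- data.frame(
          electrode_mode = mode, duty = duty, modulation = modulation,
          replicate = r, seed = seeds[r],
          VE_percent = tr$VE_percent, n_epochs = tr$n_epochs,
          stimulation_time_s = tr$stimulation_time_s,
          termination = tr$termination_reason)
      }
    }
  }
  trials <- do.call(rbind, rows)
  list(trials = trials,
       summary = summarize_trials(trials, by = c("electrode_mode", "duty"),
                                  vars = c("VE_percent",
                                           "stimulation_time_s")))
}

#' Single- versus two-electrode hybrid closed-loop comparison
#'
#' Replicate closed-loop trials under hybrid amplitude-frequency modulation
#' for single-electrode and two-electrode asynchronous stimulation at 33%
#' duty cycle, reporting voiding efficiency and total stimulation time.
#'
#' @inheritParams mode_comparison_experiment
#' @param duty Duty preset (the hybrid protocol uses 33%).
#' @return A list with \code{trials} and \code{summary} (VE and stimulation
#'   time per mode).
#' @export
hybrid_comparison_experiment <- function(plant = plant_params(),
                                         modes = c("single",
                                                   "two_asynchronous"),
                                         duty = "33", replicates = 6,
                                         jitter_cv = 0.05, seed = 1,
                                         control = controller_params()) {
  out <- mode_comparison_experiment(plant, modes = modes, duties = duty,
                                    modulation = "hybrid",
                                    replicates = replicates,
                                    jitter_cv = jitter_cv, seed = seed,
                                    control = control)
  out
}
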
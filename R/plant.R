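#' Parameters of the synthetic bladder-urethra plant
#'
#' A lumped-parameter model of the bladder detrusor, external urethral
#' sphincter (EUS) and urethral outflow, designed to close the control loop
#' in silico. It reproduces the qualitative dose-response structure expected
#' of sacral ISMS: intravesical peak pressure monotone in pulse amplitude, a
#' band-pass frequency response with its maximum at 30 Hz, pressure decline
#' under repeated constant-amplitude epochs (fatigue), fast sphincter versus
#' slow detrusor relaxation during OFF periods (post-stimulus voiding in
#' spurts), a sphincter co-activation penalty when both electrodes fire
#' simultaneously, sphincter inhibition from the dorsal-gray-commissure
#' channel, and a distension-evoked contraction at the threshold volume.
#' It is a demonstration calibration, not a validated physiological model.
#'
#' @param preset One of \code{"rat-default"} (calibrated demonstration
#'   parameters), \code{"never-voids"} (urethral opening pressure too high
#'   for any stimulus), \code{"voids-at-10uA"} (recruitment threshold below
#'   the first ramp step) or \code{"threshold-at-40uA"} (first clear voiding
#'   at the 40-uA ramp step).
#' @param ... Named overrides of individual fields (see Details).
#'
#' @details Fields (units in parentheses):
#' \describe{
#'   \item{V_th (mL)}{Volume at which distension-evoked contraction fires.}
#'   \item{compliance (mL/cmH2O)}{Passive bladder compliance.}
#'   \item{basal_pressure (cmH2O)}{Pressure of the empty, quiescent bladder.}
#'   \item{detrusor_gain (cmH2O)}{Pressure generated at full detrusor
#'     activation and volume (scaled by the length-tension factor below).}
#'   \item{vol_half (mL)}{Half-saturation volume of the detrusor
#'     length-tension factor V / (V + vol_half): an emptier bladder
#'     generates less active pressure.}
#'   \item{amp_I50, amp_slope (uA)}{Midpoint and slope of the sigmoidal
#'     amplitude-recruitment curve (rectified so zero amplitude gives zero
#'     drive).}
#'   \item{amp_lin (1/uA)}{Small linear recruitment component added to the
#'     sigmoid so drive keeps growing past the shoulder.}
#'   \item{act_sat}{Soft-saturation coefficient of total detrusor drive,
#'     u / (1 + act_sat * u); bounds the benefit of summing two channels.}
#'   \item{freq_peak_Hz, freq_sigma}{Mode and log-width of the log-normal
#'     shaped frequency-response curve (unit gain at the mode).}
#'   \item{fatigue_rate (1/s), fatigue_cap, fatigue_recovery_tau (s)}{Drive-
#'     dependent fatigue accumulation, its saturation level and recovery
#'     time constant.}
#'   \item{detrusor_rise_tau, detrusor_relax_tau (s)}{Detrusor activation
#'     time constants; relaxation is slow.}
#'   \item{sphincter_rise_tau, sphincter_relax_tau (s)}{EUS tone time
#'     constants; relaxation is faster than the detrusor's, which is what
#'     lets the bladder empty in spurts during OFF periods.}
#'   \item{coactivation_rise_tau, coactivation_relax_tau (s)}{Time
#'     constants of the slow sphincter after-contraction driven by
#'     synchronous two-channel overlap.}
#'   \item{urethral_opening_pressure (cmH2O)}{Pressure the detrusor must
#'     exceed, scaled by sphincter tone, before flow starts.}
#'   \item{urethral_resistance (cmH2O per mL/s)}{Outflow resistance.}
#'   \item{sphincter_spill_gain}{EUS co-activation caused by the S2
#'     ventral-horn channel itself (current spillover).}
#'   \item{sphincter_coactivation_gain}{Magnitude of the slow EUS
#'     after-contraction recruited while both channels' ON windows overlap
#'     (synchronous field summation activating pudendal motoneurons).}
#'   \item{dgc_inhibition_gain}{EUS tone reduction while the S1
#'     dorsal-gray-commissure channel is ON.}
#'   \item{dgc_detrusor_gain}{Fraction of the DGC channel's drive that also
#'     excites the detrusor.}
#'   \item{distension_drive, distension_tau (s)}{Size and decay constant of
#'     the transient detrusor activation fired when volume crosses V_th.}
#'   \item{noise_sd (cmH2O)}{SD of additive Gaussian observation noise on
#'     recorded pressure; the process itself is deterministic.}
#'   \item{dt (s)}{Integration and control-update step (explicit Euler).}
#' }
#' @return An \code{"isms_plant_params"} list.
#' @export
plant_params <- function(preset = c("rat-default", "never-voids",
                                    "voids-at-10uA", "threshold-at-40uA"),
                         ...) {
  preset <- match.arg(preset)
  p <- list(
    V_th = 1.0,
    compliance = 0.3,
    basal_pressure = 8,
    detrusor_gain = 60,
    vol_half = 0.15,
    amp_I50 = 80,
    amp_slope = 22,
    amp_lin = 0.0035,
    act_sat = 0.3,
    freq_peak_Hz = 30,
    freq_sigma = 0.55,
    fatigue_rate = 0.04,
    fatigue_cap = 0.3,
    fatigue_recovery_tau = 20,
    detrusor_rise_tau = 0.5,
    detrusor_relax_tau = 6,
    sphincter_rise_tau = 0.2,
    sphincter_relax_tau = 2.6,
    coactivation_rise_tau = 1,
    coactivation_relax_tau = 10,
    urethral_opening_pressure = 21.5,
    urethral_resistance = 90,
    sphincter_spill_gain = 0.7,
    sphincter_coactivation_gain = 0.35,
    dgc_inhibition_gain = 0.25,
    dgc_detrusor_gain = 0.6,
    distension_drive = 0.8,
    distension_tau = 3,
    noise_sd = 0.5,
    dt = 0.02)
  if (preset == "never-voids") {
    p$urethral_opening_pressure <- 200
  } else if (preset == "voids-at-10uA") {
    p$amp_I50 <- 4
    p$amp_slope <- 2
    p$amp_lin <- 0
  } else if (preset == "threshold-at-40uA") {
    p$amp_I50 <- 34
    p$amp_slope <- 2.5
    p$amp_lin <- 0
    p$urethral_opening_pressure <- 18
  }
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown plant parameter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p[names(ov)] <- ov
  p$preset <- preset
  validate_plant_params(p)
  structure(p, class = "isms_plant_params")
}

validate_plant_params <- function(p) {
  pos <- c("V_th", "compliance", "detrusor_gain", "vol_half", "amp_slope",
           "freq_peak_Hz",
           "freq_sigma", "fatigue_cap", "fatigue_recovery_tau",
           "detrusor_rise_tau", "detrusor_relax_tau", "sphincter_rise_tau",
           "sphincter_relax_tau", "coactivation_rise_tau",
           "coactivation_relax_tau", "urethral_opening_pressure",
           "urethral_resistance", "distension_tau", "dt")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || !is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("plant parameter '", f, "' must be a positive number", call. = FALSE)
    }
  }
  nonneg <- c("basal_pressure", "fatigue_rate", "sphincter_spill_gain",
              "sphincter_coactivation_gain", "dgc_inhibition_gain",
              "dgc_detrusor_gain", "distension_drive", "noise_sd",
              "amp_lin", "act_sat")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || !is.finite(p[[f]]) || p[[f]] < 0) {
      stop("plant parameter '", f, "' must be non-negative", call. = FALSE)
    }
  }
  if (p$sphincter_relax_tau >= p$detrusor_relax_tau) {
    stop("'sphincter_relax_tau' must be smaller than 'detrusor_relax_tau' ",
         "(the sphincter relaxes faster than the detrusor)", call. = FALSE)
  }
  invisible(p)
}

#' Initial plant state
#'
#' @param params An \code{"isms_plant_params"} object.
#' @param volume_mL Initial bladder volume (mL, >= 0).
#' @return An \code{"isms_plant_state"} list with fields \code{volume_mL},
#'   \code{activation} (detrusor, 0 at rest), \code{sphincter_tone} (1 at
#'   rest), \code{fatigue}, \code{distension}, \code{voided_mL},
#'   \code{infused_mL}, \code{time_s} and \code{isovolumetric}.
#' @export
plant_init <- function(params, volume_mL = 0) {
  stopifnot(inherits(params, "isms_plant_params"), volume_mL >= 0)
  structure(
    list(volume_mL = volume_mL, activation = 0, sphincter_tone = 1,
         coactivation = 0, fatigue = 0, distension = 0, voided_mL = 0,
         infused_mL = volume_mL, time_s = 0, isovolumetric = FALSE),
    class = "isms_plant_state")
}

# Rectified sigmoidal amplitude recruitment (0 at I = 0) plus a small
# linear component so recruitment keeps growing past the sigmoid shoulder.
amp_activation <- function(I_uA, p) {
  if (I_uA <= 0) return(0)
  s0 <- stats::plogis((0 - p$amp_I50) / p$amp_slope)
  sig <- (stats::plogis((I_uA - p$amp_I50) / p$amp_slope) - s0) / (1 - s0)
  max(0, sig) + p$amp_lin * I_uA
}

# Band-pass frequency gain, unit at the mode, log-normal shaped.
freq_gain <- function(f_Hz, p) {
  if (f_Hz <= 0) return(0)
  exp(-log(f_Hz / p$freq_peak_Hz)^2 / (2 * p$freq_sigma^2))
}

#' Process pressure of a plant state
#' @param state An \code{"isms_plant_state"}.
#' @param params The matching \code{"isms_plant_params"}.
#' @return Intravesical pressure in cmH2O (noise-free).
#' @export
plant_pressure <- function(state, params) {
  params$basal_pressure + state$volume_mL / params$compliance +
    params$detrusor_gain * state$activation *
      state$volume_mL / (state$volume_mL + params$vol_half)
}

# Advance the plant over n steps under per-step channel gates.
#
# g1, g2: numeric 0/1 gate vectors of length n (channel 1 = S2 ventral horn,
# channel 2 = S1 dorsal gray commissure). I*, f*: amplitudes (uA) and
# frequencies (Hz) held constant over the segment. infusion: mL/s.
# Returns list(state, record) where record is an n x 12 matrix (or NULL).
plant_segment <- function(state, p, n, g1, g2 = NULL, I1 = 0, f1 = 0,
                          I2 = 0, f2 = 0, infusion = 0, epoch = 0L,
                          record = TRUE) {
  dt <- p$dt
  if (is.null(g2)) g2 <- numeric(n)
  stopifnot(length(g1) == n, length(g2) == n)
  a1 <- amp_activation(I1, p); a2 <- amp_activation(I2, p)
  d1 <- a1 * freq_gain(f1, p); d2 <- a2 * freq_gain(f2, p)
  vol <- state$volume_mL; act <- state$activation
  sph <- state$sphincter_tone; coa <- state$coactivation
  fat <- state$fatigue
  dist <- state$distension; voided <- state$voided_mL
  infused <- state$infused_mL; tim <- state$time_s
  iso <- state$isovolumetric
  eps <- if (record && p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd)
         else numeric(n)
  rec <- if (record) matrix(0, n, 12) else NULL
  for (k in seq_len(n)) {
    u <- d1 * g1[k] + p$dgc_detrusor_gain * d2 * g2[k] + dist
    fat <- fat + dt * (p$fatigue_rate * u * (1 - fat / p$fatigue_cap) -
                         fat / p$fatigue_recovery_tau)
    if (fat < 0) fat <- 0
    ueff <- u * (1 - fat)
    ueff <- ueff / (1 + p$act_sat * ueff)
    tau_a <- if (ueff >= act) p$detrusor_rise_tau else p$detrusor_relax_tau
    act <- act + dt * (ueff - act) / tau_a
    s_t <- 1 + p$sphincter_spill_gain * a1 * g1[k] -
      p$dgc_inhibition_gain * a2 * g2[k]
    if (s_t < 0) s_t <- 0
    tau_s <- if (s_t >= sph) p$sphincter_rise_tau else p$sphincter_relax_tau
    sph <- sph + dt * (s_t - sph) / tau_s
    c_t <- p$sphincter_coactivation_gain * (g1[k] * g2[k]) *
      min(a1, a2)
    tau_c <- if (c_t >= coa) p$coactivation_rise_tau else p$coactivation_relax_tau
    coa <- coa + dt * (c_t - coa) / tau_c
    dist <- dist - dt * dist / p$distension_tau
    P <- p$basal_pressure + vol / p$compliance +
      p$detrusor_gain * act * vol / (vol + p$vol_half)
    if (!is.finite(P) || !is.finite(vol)) {
      stop("plant diverged: non-finite pressure or volume at t = ",
           format(tim, digits = 6), " s", call. = FALSE)
    }
    if (iso) {
      q <- 0
    } else {
      q <- (P - p$urethral_opening_pressure * (sph + coa)) / p$urethral_resistance
      if (q < 0) q <- 0
      if (q * dt > vol) q <- vol / dt
    }
    newvol <- vol + dt * (infusion - q)
    if (vol < p$V_th && newvol >= p$V_th) dist <- p$distension_drive
    vol <- newvol
    voided <- voided + dt * q
    infused <- infused + dt * infusion
    tim <- tim + dt
    if (record) {
      rec[k, 1] <- tim; rec[k, 2] <- P + eps[k]; rec[k, 3] <- infused
      rec[k, 4] <- voided; rec[k, 5] <- vol
      rec[k, 6] <- I1 * g1[k]; rec[k, 7] <- f1 * g1[k]; rec[k, 8] <- g1[k]
      rec[k, 9] <- I2 * g2[k]; rec[k, 10] <- f2 * g2[k]; rec[k, 11] <- g2[k]
      rec[k, 12] <- epoch
    }
  }
  state$volume_mL <- vol; state$activation <- act
  state$sphincter_tone <- sph; state$coactivation <- coa
  state$fatigue <- fat
  state$distension <- dist; state$voided_mL <- voided
  state$infused_mL <- infused; state$time_s <- tim
  list(state = state, record = rec)
}

#' Fill the bladder to a target volume
#'
#' Filling is analytic: the volume is set to the target and the infused
#' total and clock advance by \code{(target - volume) / rate}. If the target
#' reaches \code{V_th}, the distension-evoked contraction is armed.
#'
#' @param state An \code{"isms_plant_state"}.
#' @param params The matching \code{"isms_plant_params"}.
#' @param target_mL Target volume (mL, >= current volume).
#' @param rate_mL_h Infusion rate in mL/h (> 0); 20 mL/h is the standard
#'   pre-trial fill, 3-6 mL/h the slow fill used to find V_th.
#' @param allow_above_threshold Permit targets above \code{V_th} (outside
#'   the closed-loop protocol, e.g. when determining V_th itself).
#' @return The updated state.
#' @export
plant_fill <- function(state, params, target_mL, rate_mL_h = 20,
                       allow_above_threshold = FALSE) {
  stopifnot(inherits(state, "isms_plant_state"),
            inherits(params, "isms_plant_params"))
  if (!is.numeric(rate_mL_h) || rate_mL_h <= 0) {
    stop("'rate_mL_h' must be > 0", call. = FALSE)
  }
  if (target_mL < state$volume_mL) {
    stop("fill target below current volume", call. = FALSE)
  }
  if (!allow_above_threshold && target_mL > params$V_th) {
    stop("fill target exceeds V_th; closed-loop trials fill to 90% of V_th",
         call. = FALSE)
  }
  dv <- target_mL - state$volume_mL
  if (dv == 0) return(state)
  if (state$volume_mL < params$V_th && target_mL >= params$V_th) {
    state$distension <- params$distension_drive
  }
  state$volume_mL <- target_mL
  state$infused_mL <- state$infused_mL + dv
  state$time_s <- state$time_s + dv / rate_mL_h * 3600
  state
}

#' Block or restore urethral outflow (isovolumetric condition)
#' @param state An \code{"isms_plant_state"}.
#' @param blocked Logical; \code{TRUE} forces flow to zero.
#' @return The updated state.
#' @export
set_isovolumetric <- function(state, blocked = TRUE) {
  stopifnot(inherits(state, "isms_plant_state"))
  state$isovolumetric <- isTRUE(blocked)
  state
}

#' Manually empty the bladder and reset for a new trial
#'
#' Models syringe emptying followed by the inter-trial rest: volume and the
#' infused/voided totals are zeroed and the dynamic state (detrusor
#' activation, sphincter tone, fatigue, distension, clock) returns to rest,
#' so pressure returns to basal. Idempotent.
#'
#' @param state An \code{"isms_plant_state"}.
#' @return The reset state (isovolumetric flag preserved).
#' @export
manual_empty <- function(state) {
  stopifnot(inherits(state, "isms_plant_state"))
  state$volume_mL <- 0; state$activation <- 0; state$sphincter_tone <- 1
  state$coactivation <- 0; state$fatigue <- 0; state$distension <- 0
  state$voided_mL <- 0; state$infused_mL <- 0; state$time_s <- 0
  state
}

# Multiplicative lognormal jitter emulating biological variability. The
# experiment runners jitter recruitment and outflow parameters
# (inter-animal variability); within-session replicates, e.g. during
# I_start calibration, keep the recruitment midpoint fixed because the
# electrode and its recruitment geometry do not change between trials of
# one session. Draws from the current RNG stream; each jittered plant is
# still fully deterministic given its parameters.
jitter_plant <- function(params, cv = 0.05,
                         fields = c("detrusor_gain", "urethral_resistance",
                                    "amp_I50")) {
  if (cv <= 0) return(params)
  for (f in fields) {
    params[[f]] <- params[[f]] * exp(stats::rnorm(1, 0, cv))
  }
  params
}
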
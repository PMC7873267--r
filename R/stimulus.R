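# Default electrode contact area (cm^2). Chosen so that the maximum charge per
# phase delivered by the default pulse (150 uA x 80 us = 12 nC) corresponds to
# a charge density of ~363 uC/cm^2, at the upper end of the commonly quoted
# safe range for microelectrode stimulation. Overridable everywhere it is used.
DEFAULT_CONTACT_AREA_CM2 <- 3.306e-5

#' Describe one charge-balanced biphasic stimulus pulse
#'
#' A stimulus pulse is cathodic-first, symmetric and biphasic: a cathodic
#' phase of \code{phase_width_us} at \code{-amplitude_uA}, an interphase
#' delay, then an anodic phase of the same width and magnitude. Symmetry
#' makes the pulse charge-balanced by construction.
#'
#' @param amplitude_uA Current amplitude in microamperes (>= 0).
#' @param phase_width_us Width of each phase in microseconds (> 0).
#' @param interphase_delay_us Delay between the two phases in microseconds
#'   (>= 0).
#' @param polarity Only \code{"cathodic_first"} is supported.
#' @return An object of class \code{"isms_pulse"}: a list with the fields
#'   above plus \code{charge_balanced = TRUE}.
#' @examples
#' p <- pulse_descriptor(40)
#' pulse_net_charge(p)   # exactly 0
#' @export
pulse_descriptor <- function(amplitude_uA, phase_width_us = 80,
                             interphase_delay_us = 100,
                             polarity = "cathodic_first") {
  polarity <- match.arg(polarity)
  if (!is.numeric(amplitude_uA) || length(amplitude_uA) != 1 ||
      !is.finite(amplitude_uA) || amplitude_uA < 0) {
    stop("'amplitude_uA' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(phase_width_us) || phase_width_us <= 0) {
    stop("'phase_width_us' must be > 0", call. = FALSE)
  }
  if (!is.numeric(interphase_delay_us) || interphase_delay_us < 0) {
    stop("'interphase_delay_us' must be >= 0", call. = FALSE)
  }
  structure(
    list(amplitude_uA = amplitude_uA,
         phase_width_us = phase_width_us,
         interphase_delay_us = interphase_delay_us,
         polarity = polarity,
         charge_balanced = TRUE),
    class = "isms_pulse")
}

#' Net charge of a biphasic pulse
#'
#' Computed as the sum of the (signed) charges of the cathodic and anodic
#' phases; exactly zero for the symmetric pulses built by
#' \code{\link{pulse_descriptor}}.
#'
#' @param pulse An \code{"isms_pulse"} object.
#' @return Net charge in nC (0 for charge-balanced pulses).
#' @export
pulse_net_charge <- function(pulse) {
  stopifnot(inherits(pulse, "isms_pulse"))
  q <- charge_per_phase(pulse$amplitude_uA, pulse$phase_width_us)
  (-q) + q
}

#' Total duration of one pulse in seconds
#' @param pulse An \code{"isms_pulse"} object.
#' @return Duration (both phases plus interphase delay) in seconds.
#' @export
pulse_duration_s <- function(pulse) {
  stopifnot(inherits(pulse, "isms_pulse"))
  (2 * pulse$phase_width_us + pulse$interphase_delay_us) * 1e-6
}

#' Charge injected per pulse phase
#'
#' @param amplitude_uA Current amplitude in uA (>= 0, vectorised).
#' @param phase_width_us Phase width in us (> 0).
#' @return Charge per phase in nC (uA x us = 1e-3 nC).
#' @examples
#' charge_per_phase(150, 80)  # 12 nC, the upper end of the default range
#' charge_per_phase(40, 80)   # 3.2 nC, the lower end at I_start
#' @export
charge_per_phase <- function(amplitude_uA, phase_width_us = 80) {
  if (any(!is.finite(amplitude_uA)) || any(amplitude_uA < 0)) {
    stop("'amplitude_uA' must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(phase_width_us)) || any(phase_width_us <= 0)) {
    stop("'phase_width_us' must be positive", call. = FALSE)
  }
  amplitude_uA * phase_width_us * 1e-3
}

#' Charge density per phase at the electrode contact
#'
#' @param charge_nC Charge per phase in nC (>= 0).
#' @param contact_area_cm2 Geometric contact area of the electrode in cm^2
#'   (> 0). The default corresponds to the ~3-um conical tungsten tip used
#'   for intraspinal microstimulation (see package vignette).
#' @return Charge density in uC/cm^2 per phase.
#' @examples
#' charge_density(12)  # ~363 uC/cm^2 at the default contact area
#' @export
charge_density <- function(charge_nC, contact_area_cm2 = DEFAULT_CONTACT_AREA_CM2) {
  if (any(!is.finite(charge_nC)) || any(charge_nC < 0)) {
    stop("'charge_nC' must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(contact_area_cm2)) || any(contact_area_cm2 <= 0)) {
    stop("'contact_area_cm2' must be positive", call. = FALSE)
  }
  (charge_nC * 1e-3) / contact_area_cm2
}

#' Duty-cycled ON/OFF epoch schedule
#'
#' One stimulation epoch is an ON window (pulses delivered) followed by an
#' OFF window. The two presets used throughout the package are 33% duty
#' cycle (2 s ON, 4 s OFF) and 50% duty cycle (2 s ON, 2 s OFF).
#'
#' @param on_s ON duration in seconds (> 0).
#' @param off_s OFF duration in seconds (>= 0).
#' @return An \code{"isms_schedule"} list with \code{on_s}, \code{off_s},
#'   \code{period_s} and \code{duty_cycle}.
#' @seealso \code{\link{duty_preset}}
#' @export
epoch_schedule <- function(on_s = 2, off_s = 4) {
  if (!is.numeric(on_s) || on_s <= 0) stop("'on_s' must be > 0", call. = FALSE)
  if (!is.numeric(off_s) || off_s < 0) stop("'off_s' must be >= 0", call. = FALSE)
  structure(
    list(on_s = on_s, off_s = off_s,
         period_s = on_s + off_s,
         duty_cycle = on_s / (on_s + off_s)),
    class = "isms_schedule")
}

#' Epoch schedule for a named duty-cycle preset
#'
#' @param duty \code{"33"} (2 s ON, 4 s OFF) or \code{"50"} (2 s ON, 2 s OFF).
#' @return An \code{"isms_schedule"} object.
#' @export
duty_preset <- function(duty = c("33", "50")) {
  duty <- as.character(duty)[1]
  duty <- match.arg(duty)
  switch(duty, "33" = epoch_schedule(2, 4), "50" = epoch_schedule(2, 2))
}

#' Interleave offset between the two stimulation channels
#'
#' In synchronous two-electrode mode both channels fire together (offset 0).
#' In asynchronous mode channel 2 is delayed so its ON window falls inside
#' channel 1's OFF window: 3 s for the 33% preset and 2 s for the 50% preset.
#'
#' @param duty Duty preset, \code{"33"} or \code{"50"}.
#' @param mode \code{"synchronous"} or \code{"asynchronous"}.
#' @return Offset of channel 2 onsets relative to channel 1, in seconds.
#' @export
interleave_offset <- function(duty = c("33", "50"),
                              mode = c("synchronous", "asynchronous")) {
  duty <- as.character(duty)[1]
  duty <- match.arg(duty)
  mode <- match.arg(mode)
  if (mode == "synchronous") return(0)
  switch(duty, "33" = 3, "50" = 2)
}

#' Number of complete pulses in one ON window
#'
#' Pulse onsets are placed at regular 1/f intervals starting at the ON-window
#' start; a pulse counts only if it completes (both phases plus the
#' interphase delay) inside the window.
#'
#' @param on_s ON duration in seconds (>= 0).
#' @param frequency_Hz Pulse rate in Hz (>= 0).
#' @param pulse An \code{"isms_pulse"}; only its duration matters.
#' @return Integer pulse count.
#' @examples
#' count_pulses(2, 20)  # 40
#' count_pulses(2, 30)  # 60
#' @export
count_pulses <- function(on_s, frequency_Hz, pulse = pulse_descriptor(0)) {
  if (!is.numeric(on_s) || on_s < 0) stop("'on_s' must be >= 0", call. = FALSE)
  if (!is.numeric(frequency_Hz) || frequency_Hz < 0) {
    stop("'frequency_Hz' must be >= 0", call. = FALSE)
  }
  dur <- pulse_duration_s(pulse)
  if (frequency_Hz == 0 || on_s < dur) return(0L)
  as.integer(floor((on_s - dur) * frequency_Hz) + 1L)
}

channel_sites <- c("S2_lateral_ventral_horn", "S1_dorsal_gray_commissure")

#' Compile per-channel stimulation timelines
#'
#' Lays out epoch onsets for one or two channels under a duty-cycled
#' schedule. Channel 1 onsets sit at k * (on + off); channel 2 onsets are
#' shifted by \code{\link{interleave_offset}}. ON windows are half-open
#' intervals \code{[onset, onset + on_s)}, so boundary-touching windows (the
#' 50% asynchronous preset) do not overlap.
#'
#' @param schedule An \code{"isms_schedule"} or a duty preset string.
#' @param mode \code{"single"}, \code{"two_synchronous"} or
#'   \code{"two_asynchronous"}.
#' @param amplitudes_uA Per-epoch amplitude sequence (uA).
#' @param frequencies_Hz Per-epoch frequency sequence (Hz); recycled to the
#'   length of \code{amplitudes_uA} if scalar.
#' @param onset_s Time of the first channel-1 epoch onset (s).
#' @return A list of class \code{"isms_timelines"}; one data frame per
#'   channel with columns \code{epoch}, \code{onset_s}, \code{amplitude_uA},
#'   \code{frequency_Hz}, plus attributes \code{schedule}, \code{mode},
#'   \code{channel_id} and \code{site} on each element.
#' @export
compile_timelines <- function(schedule = duty_preset("33"),
                              mode = c("single", "two_synchronous",
                                       "two_asynchronous"),
                              amplitudes_uA, frequencies_Hz = 20,
                              onset_s = 0) {
  if (is.character(schedule) || is.numeric(schedule)) {
    schedule <- duty_preset(as.character(schedule))
  }
  stopifnot(inherits(schedule, "isms_schedule"))
  mode <- match.arg(mode)
  n <- length(amplitudes_uA)
  if (n < 1) stop("need at least one epoch", call. = FALSE)
  frequencies_Hz <- rep_len(frequencies_Hz, n)
  if (any(amplitudes_uA < 0) || any(frequencies_Hz < 0)) {
    stop("amplitudes and frequencies must be non-negative", call. = FALSE)
  }
  duty <- if (isTRUE(all.equal(schedule$duty_cycle, 1 / 3))) "33"
          else if (isTRUE(all.equal(schedule$duty_cycle, 1 / 2))) "50"
          else NA_character_
  n_channels <- if (mode == "single") 1L else 2L
  offs <- 0
  if (n_channels == 2L) {
    if (is.na(duty)) stop("two-channel modes require a 33% or 50% preset schedule",
                          call. = FALSE)
    offs <- interleave_offset(duty, if (mode == "two_asynchronous")
      "asynchronous" else "synchronous")
  }
  base <- onset_s + (seq_len(n) - 1) * schedule$period_s
  tl <- vector("list", n_channels)
  for (ch in seq_len(n_channels)) {
    d <- data.frame(epoch = seq_len(n),
                    onset_s = base + if (ch == 2L) offs else 0,
                    amplitude_uA = amplitudes_uA,
                    frequency_Hz = frequencies_Hz)
    attr(d, "schedule") <- schedule
    attr(d, "mode") <- mode
    attr(d, "channel_id") <- ch
    attr(d, "site") <- channel_sites[ch]
    tl[[ch]] <- d
  }
  out <- structure(tl, class = "isms_timelines",
                   schedule = schedule, mode = mode)
  if (mode == "two_asynchronous" && timeline_overlap(out) > 0) {
    stop("internal error: asynchronous ON windows overlap", call. = FALSE)
  }
  out
}

# Total ON-window overlap (s) between the two channels of a timeline set.
# Half-open [onset, onset + on) windows; 0 for single-channel sets.
timeline_overlap <- function(timelines) {
  if (length(timelines) < 2) return(0)
  sch <- attr(timelines, "schedule")
  a <- timelines[[1]]$onset_s; b <- timelines[[2]]$onset_s
  tot <- 0
  for (x in a) {
    lo <- pmax(x, b); hi <- pmin(x + sch$on_s, b + sch$on_s)
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}

#' Total injected charge of a compiled timeline set
#'
#' Sums, over channels and epochs, the number of complete pulses per ON
#' window times both phases' charge magnitude (2 x charge per phase).
#'
#' @param timelines An \code{"isms_timelines"} object (or a single channel
#'   data frame from one).
#' @param pulse Pulse descriptor supplying phase width and duration.
#' @return Total delivered charge magnitude in nC.
#' @export
cumulative_charge <- function(timelines, pulse = pulse_descriptor(0)) {
  if (is.data.frame(timelines)) timelines <- list(timelines)
  tot <- 0
  for (d in timelines) {
    if (nrow(d) == 0) next
    sch <- attr(d, "schedule")
    np <- vapply(d$frequency_Hz, function(f)
      as.numeric(count_pulses(sch$on_s, f, pulse)), numeric(1))
    tot <- tot + sum(np * 2 * charge_per_phase(d$amplitude_uA, pulse$phase_width_us))
  }
  tot
}

#' Gate-transition event table for a timeline set
#'
#' @param timelines An \code{"isms_timelines"} object.
#' @return Data frame with columns \code{time_s}, \code{channel},
#'   \code{amplitude_uA}, \code{frequency_Hz}, \code{gate}; one row per
#'   ON (gate 1) and OFF (gate 0) transition, ordered by time.
#' @export
timeline_events <- function(timelines) {
  stopifnot(inherits(timelines, "isms_timelines"))
  sch <- attr(timelines, "schedule")
  rows <- lapply(timelines, function(d) {
    ch <- attr(d, "channel_id")
    rbind(
      data.frame(time_s = d$onset_s, channel = ch,
                 amplitude_uA = d$amplitude_uA,
                 frequency_Hz = d$frequency_Hz, gate = 1L),
      data.frame(time_s = d$onset_s + sch$on_s, channel = ch,
                 amplitude_uA = d$amplitude_uA,
                 frequency_Hz = d$frequency_Hz, gate = 0L))
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$time_s, ev$channel, -ev$gate), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write a timeline event table as CSV
#' @param timelines An \code{"isms_timelines"} object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_timeline_csv <- function(timelines, path) {
  utils::write.csv(timeline_events(timelines), path, row.names = FALSE)
  invisible(path)
}

#' Export a compiled schedule as JSON
#' @param timelines An \code{"isms_timelines"} object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_schedule_json <- function(timelines, path) {
  sch <- attr(timelines, "schedule")
  obj <- list(
    mode = attr(timelines, "mode"),
    schedule = list(on_s = sch$on_s, off_s = sch$off_s,
                    duty_cycle = sch$duty_cycle),
    channels = lapply(timelines, function(d) {
      list(channel_id = attr(d, "channel_id"), site = attr(d, "site"),
           epoch = d$epoch, onset_s = d$onset_s,
           amplitude_uA = d$amplitude_uA, frequency_Hz = d$frequency_Hz)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
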
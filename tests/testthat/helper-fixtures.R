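# Noise-free default plant used whenever a test needs deterministic dynamics.
quiet_plant <- function(...) plant_params(noise_sd = 0, ...)

# Plant that voids completely during the 60-uA epoch of a default hybrid
# ramp (steep recruitment between 50 and 60 uA, low outflow impedance).
voids_at_60_plant <- function() {
  plant_params("threshold-at-40uA", amp_I50 = 56, amp_slope = 2,
               urethral_resistance = 15, urethral_opening_pressure = 12,
               vol_half = 0.02, noise_sd = 0)
}

# Plant that empties within the very first closed-loop epoch.
voids_first_epoch_plant <- function() {
  plant_params("voids-at-10uA", urethral_resistance = 15,
               urethral_opening_pressure = 12, vol_half = 0.02,
               noise_sd = 0)
}

# Hand-built trial record: constant baseline, one triangular pressure peak
# inside epoch 1. dt in seconds; rest_s of pre-epoch history.
triangle_record <- function(baseline = 10, peak = 35, rest_s = 2,
                            on_s = 2, off_s = 4, dt = 0.02) {
  n_rest <- round(rest_s / dt); n_ep <- round((on_s + off_s) / dt)
  tt <- seq_len(n_rest + n_ep) * dt
  p <- rep(baseline, n_rest + n_ep)
  ramp <- seq(0, 1, length.out = 50)
  tri <- c(ramp, rev(ramp)[-1]) * (peak - baseline) + baseline
  i0 <- n_rest + 30
  p[i0:(i0 + length(tri) - 1)] <- tri
  data.frame(time_s = tt, pressure_cmH2O = p,
             infused_mL = 0.9, voided_mL = 0,
             residual_mL = 0.9,
             ch1_gate = c(rep(0, n_rest), rep(1, round(on_s / dt)),
                          rep(0, n_ep - round(on_s / dt))),
             epoch_index = c(rep(0, n_rest), rep(1, n_ep)))
}
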
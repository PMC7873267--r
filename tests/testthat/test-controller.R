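test_that("trial initialisation sets I_start, f_start and the 90% fill target", {
  tr <- init_trial(1.0)
  expect_equal(tr$fill_target_mL, 0.9)
  expect_equal(tr$state$amplitude, 40)
  expect_equal(tr$state$frequency, 20)
  expect_equal(tr$state$epoch_index, 0L)
  expect_false(tr$state$terminated)
  expect_equal(init_trial(2.0)$fill_target_mL, 1.8)
  expect_error(init_trial(0), "positive")
  expect_error(init_trial(-1), "positive")
})

test_that("controller parameter invariants are enforced", {
  expect_error(controller_params(I_start = 200), "I_start.*I_max")
  expect_error(controller_params(I_th = 160), "I_th.*I_max")
  expect_error(controller_params(f_start = 40), "f_start.*f_max")
  expect_error(controller_params(dI = 0), "dI")
  expect_error(controller_params(df = -5), "df")
})

test_that("controller transitions agree exactly with the decision branch table", {
  params <- controller_params()  # 40/150 uA, 20/30 Hz, steps 10
  amp_grid <- seq(params$I_start, params$I_max, by = params$dI)
  freq_grid <- seq(params$f_start, params$f_max, by = params$df)
  for (amp in amp_grid) {
    for (f in freq_grid) {
      for (res in c(0, 0.5)) {
        st <- ismsloop:::controller_init(params)
        st$amplitude <- amp
        st$frequency <- f
        out <- next_epoch_params(st, res, params, tol = 0)
        # Branch table, written from the control flowchart:
        #   residual == 0            -> stop (residual_zero)
        #   amp < 150                -> amp + 10, same frequency
        #   amp == 150, f < 30       -> f + 10, amp back to I_th
        #   amp == 150, f == 30      -> stop (f_max_exhausted)
        if (res == 0) {
          exp_term <- TRUE; exp_reason <- "residual_zero"
          exp_amp <- amp; exp_f <- f
        } else if (amp < 150) {
          exp_term <- FALSE; exp_reason <- NA_character_
          exp_amp <- amp + 10; exp_f <- f
        } else if (f < 30) {
          exp_term <- FALSE; exp_reason <- NA_character_
          exp_amp <- params$I_th; exp_f <- f + 10
        } else {
          exp_term <- TRUE; exp_reason <- "f_max_exhausted"
          exp_amp <- amp; exp_f <- f
        }
        expect_equal(out$terminated, exp_term)
        expect_equal(out$reason, exp_reason)
        expect_equal(out$amplitude, exp_amp)
        expect_equal(out$frequency, exp_f)
      }
    }
  }
})

test_that("PAM holds at I_max and constant modulation never changes parameters", {
  pam <- controller_params(modulation = "PAM")
  st <- ismsloop:::controller_init(pam)
  out <- next_epoch_params(st, 0.5, pam)
  expect_equal(out$amplitude, 50)
  st$amplitude <- 150
  out <- next_epoch_params(st, 0.5, pam)
  expect_equal(out$amplitude, 150)
  expect_false(out$terminated)
  expect_equal(out$frequency, 20)

  cst <- controller_params(modulation = "constant", I_start = 80)
  st <- ismsloop:::controller_init(cst)
  out <- next_epoch_params(st, 0.5, cst)
  expect_equal(out$amplitude, 80)
  expect_equal(out$frequency, 20)
  expect_false(out$terminated)
})

test_that("advancing a terminated controller state is a contract violation", {
  params <- controller_params()
  st <- ismsloop:::controller_init(params)
  st <- next_epoch_params(st, 0, params)
  expect_true(st$terminated)
  expect_error(next_epoch_params(st, 0.5, params), "terminated")
})

test_that("closed loop on a plant that voids fully at 60 uA stops after three amplitude steps", {
  tr <- run_closed_loop(voids_at_60_plant(), controller_params(), seed = 1)
  expect_equal(tr$termination_reason, "residual_zero")
  expect_equal(tr$n_epochs, 3L)
  expect_equal(tr$epochs$amplitude_uA, c(40, 50, 60))
  expect_gte(tr$VE_percent, 99)
})

test_that("closed loop on a never-voiding plant exhausts the controller at N_max", {
  params <- controller_params()
  tr <- run_closed_loop(plant_params("never-voids", noise_sd = 0), params,
                        seed = 1)
  expect_equal(tr$termination_reason, "f_max_exhausted")
  expect_equal(tr$n_epochs, n_max_epochs(params))
  expect_equal(n_max_epochs(params), 24L)  # 12 amplitudes at 20 Hz + 12 at 30 Hz
  expect_equal(tr$stimulation_time_s, 24 * 6)
})

test_that("residual below tolerance at the first measurement ends the trial in one epoch", {
  tr <- run_closed_loop(voids_first_epoch_plant(), controller_params(),
                        seed = 1)
  expect_equal(tr$n_epochs, 1L)
  expect_equal(tr$termination_reason, "residual_zero")
})

test_that("epoch count never exceeds the analytic bound for randomized plants", {
  set.seed(42)
  params <- controller_params()
  for (k in 1:8) {
    pp <- plant_params(
      noise_sd = 0,
      detrusor_gain = runif(1, 20, 90),
      urethral_opening_pressure = runif(1, 15, 60),
      urethral_resistance = runif(1, 30, 300),
      amp_I50 = runif(1, 40, 120))
    tr <- run_closed_loop(pp, params, seed = k)
    expect_lte(tr$n_epochs, n_max_epochs(params))
  }
})

test_that("amplitude ramps by exactly dI within a frequency level and resets to I_th", {
  tr <- run_closed_loop(plant_params("never-voids", noise_sd = 0),
                        controller_params(I_th = 60), seed = 1)
  ep <- tr$epochs
  expect_true(all(diff(ep$frequency_Hz) >= 0))
  for (f in unique(ep$frequency_Hz)) {
    amps <- ep$amplitude_uA[ep$frequency_Hz == f]
    expect_true(all(diff(amps) == 10))
  }
  first30 <- ep$amplitude_uA[match(30, ep$frequency_Hz)]
  expect_equal(first30, 60)
})

test_that("optional termination on reaching f_max skips the final amplitude ramp", {
  params <- controller_params(terminate_at_f_max = TRUE)
  tr <- run_closed_loop(plant_params("never-voids", noise_sd = 0), params,
                        seed = 1)
  expect_equal(tr$termination_reason, "f_max_exhausted")
  expect_equal(tr$n_epochs, 12L)
  expect_equal(n_max_epochs(params), 12L)
})

test_that("I_start calibration finds the first significant voiding step", {
  cal <- calibrate_I_start(plant_params("threshold-at-40uA"), seed = 2)
  expect_true(cal$qualified)
  expect_equal(cal$I_start, 40)
  expect_false(any(cal$table$qualifies[cal$table$amplitude_uA < 40]))

  cal10 <- calibrate_I_start(plant_params("voids-at-10uA"), seed = 2)
  expect_equal(cal10$I_start, 10)

  calnv <- calibrate_I_start(plant_params("never-voids"), seed = 2)
  expect_false(calnv$qualified)
  expect_true(is.na(calnv$I_start))
  expect_equal(nrow(calnv$table), length(seq(10, 150, 10)))
})

test_that("isovolumetric frequency sweep peaks at 30 Hz with 20 Hz above 10 Hz", {
  sw <- frequency_sweep_isovolumetric(quiet_plant())
  expect_equal(sw$frequency_Hz[which.max(sw$delta_p_cmH2O)], 30)
  dp <- setNames(sw$delta_p_cmH2O, sw$frequency_Hz)
  expect_gt(dp[["20"]], dp[["10"]])
  expect_gt(dp[["30"]], dp[["40"]])
  expect_gt(dp[["30"]], dp[["50"]])
  # zero amplitude drives nothing
  sw0 <- frequency_sweep_isovolumetric(quiet_plant(), amplitude_uA = 0)
  expect_equal(sw0$delta_p_cmH2O, rep(0, 5), tolerance = 1e-10)
  expect_error(frequency_sweep_isovolumetric(quiet_plant(),
                                             frequencies_Hz = c(10, -5)),
               "positive")
})
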
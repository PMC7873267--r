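test_that("plant parameter invariants are enforced", {
  expect_error(plant_params(compliance = 0), "positive")
  expect_error(plant_params(sphincter_relax_tau = 10, detrusor_relax_tau = 5),
               "faster")
  expect_error(plant_params(noise_sd = -1), "non-negative")
  expect_error(plant_params(bogus = 1), "unknown")
})

test_that("quiescent plant sits at basal plus volume/compliance pressure", {
  pp <- quiet_plant()
  st <- plant_init(pp, volume_mL = 0.6)
  seg <- ismsloop:::plant_segment(st, pp, 200, g1 = numeric(200))
  expect_equal(tail(seg$record[, 2], 1),
               pp$basal_pressure + 0.6 / pp$compliance, tolerance = 1e-9)
  # no outflow below opening pressure
  expect_equal(seg$state$voided_mL, 0)
  expect_equal(seg$state$volume_mL, 0.6)
})

test_that("zero-amplitude stimulation never voids", {
  pp <- quiet_plant()
  st <- plant_init(pp, volume_mL = 0.9)
  n <- 500
  seg <- ismsloop:::plant_segment(st, pp, n, g1 = rep(1, n), I1 = 0, f1 = 20)
  expect_equal(seg$state$voided_mL, 0)
})

test_that("mass is conserved under randomized stimulation programs", {
  set.seed(7)
  pp <- quiet_plant()
  for (k in 1:5) {
    st <- plant_init(pp, volume_mL = runif(1, 0.3, 0.9))
    v0 <- st$volume_mL
    n_min <- 3000  # one simulated minute at 20 ms
    g1 <- as.numeric(runif(n_min) < 0.4)
    g2 <- as.numeric(runif(n_min) < 0.4)
    inf_rate <- runif(1, 0, 20) / 3600
    seg <- ismsloop:::plant_segment(st, pp, n_min, g1, g2,
                                    I1 = runif(1, 20, 150), f1 = 20,
                                    I2 = runif(1, 20, 150), f2 = 20,
                                    infusion = inf_rate)
    s <- seg$state
    expect_equal(s$infused_mL - v0, (s$volume_mL - v0) + s$voided_mL,
                 tolerance = 1e-6)
  }
})

test_that("peak pressure is non-decreasing in amplitude, all else fixed", {
  pp <- quiet_plant()
  peaks <- vapply(seq(20, 150, 10), function(amp) {
    st <- set_isovolumetric(plant_init(pp, volume_mL = 0.9))
    n <- 100
    seg <- ismsloop:::plant_segment(st, pp, n, g1 = rep(1, n), I1 = amp,
                                    f1 = 20)
    max(seg$record[, 2])
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("amplitude-ramp trial peaks rise monotonically despite voiding", {
  ramp <- amplitude_ramp_experiment(quiet_plant(), seed = 1)
  expect_true(all(diff(ramp$per_epoch$peak_pressure_cmH2O) >= 0))
  expect_gt(ramp$trial$UVR_mL, 0)
})

test_that("stronger pressure rise at 30 Hz than at 10 Hz for identical drive", {
  pp <- quiet_plant()
  rise <- vapply(c(10, 30), function(f) {
    st <- set_isovolumetric(plant_init(pp, volume_mL = 0.25))
    n <- 250
    seg <- ismsloop:::plant_segment(st, pp, n, g1 = rep(1, n), I1 = 80,
                                    f1 = f)
    max(seg$record[, 2]) - seg$record[1, 2]
  }, numeric(1))
  expect_gt(rise[2], rise[1])
})

test_that("repeated constant-amplitude epochs fatigue the detrusor", {
  tr <- run_open_loop(quiet_plant(), rep(80, 9), 20)
  pk <- tr$epochs$peak_pressure_cmH2O
  expect_true(all(diff(pk[2:9]) <= 0))
  expect_lt(pk[9], max(pk[1:2]))
})

test_that("sphincter tone recovers faster than detrusor activation after OFF", {
  pp <- quiet_plant()
  st <- plant_init(pp, volume_mL = 0.9)
  st <- set_isovolumetric(st, TRUE)
  n_on <- 100
  seg <- ismsloop:::plant_segment(st, pp, n_on, g1 = rep(1, n_on), I1 = 120,
                                  f1 = 20)
  st <- seg$state
  s0 <- st$sphincter_tone; a0 <- st$activation
  stopifnot(s0 > 1, a0 > 0)
  t_s <- NA; t_a <- NA
  for (k in 1:1000) {
    seg <- ismsloop:::plant_segment(st, pp, 1, g1 = 0, record = FALSE)
    st <- seg$state
    if (is.na(t_s) && (st$sphincter_tone - 1) <= (s0 - 1) * exp(-1)) {
      t_s <- k * pp$dt
    }
    if (is.na(t_a) && st$activation <= a0 * exp(-1)) t_a <- k * pp$dt
    if (!is.na(t_s) && !is.na(t_a)) break
  }
  expect_lt(t_s, t_a)
})

test_that("synchronous two-channel voiding never exceeds asynchronous", {
  amps <- seq(40, 150, 10)
  sync <- run_open_loop(quiet_plant(), amps, 20,
                        electrode_mode = "two_synchronous")
  async <- run_open_loop(quiet_plant(), amps, 20,
                         electrode_mode = "two_asynchronous")
  expect_lte(sync$UVR_mL, async$UVR_mL)
})

test_that("fill is analytic, respects V_th and arms the distension contraction", {
  pp <- quiet_plant()
  st <- plant_init(pp)
  st <- plant_fill(st, pp, 0.9, rate_mL_h = 20)
  expect_equal(st$volume_mL, 0.9)
  expect_equal(st$infused_mL, 0.9)
  expect_equal(st$time_s, 0.9 / 20 * 3600)  # 162 s = 0.045 h
  expect_equal(st$distension, 0)
  # no-op at the current volume
  st2 <- plant_fill(st, pp, 0.9)
  expect_identical(st2, st)
  expect_error(plant_fill(st, pp, 1.2), "V_th")
  # slow fill to V_th triggers the distension drive exactly at threshold
  st3 <- plant_fill(plant_init(pp), pp, pp$V_th, rate_mL_h = 3)
  expect_equal(st3$distension, pp$distension_drive)
})

test_that("distension-evoked contraction raises pressure at threshold volume", {
  pp <- quiet_plant()
  st <- set_isovolumetric(plant_fill(plant_init(pp), pp, pp$V_th,
                                     rate_mL_h = 3))
  seg <- ismsloop:::plant_segment(st, pp, 100, g1 = numeric(100))
  passive <- pp$basal_pressure + pp$V_th / pp$compliance
  expect_gt(max(seg$record[, 2]), passive + 1)
})

test_that("isovolumetric blocking freezes volume under strong stimulation", {
  pp <- quiet_plant()
  st <- set_isovolumetric(plant_init(pp, 0.9), TRUE)
  n <- 300
  seg <- ismsloop:::plant_segment(st, pp, n, g1 = rep(1, n), I1 = 150,
                                  f1 = 30)
  expect_equal(seg$state$voided_mL, 0)
  expect_equal(seg$state$volume_mL, 0.9)
  expect_gt(max(seg$record[, 2]), 30)
  # unblocking restores the flow law
  st2 <- set_isovolumetric(seg$state, FALSE)
  seg2 <- ismsloop:::plant_segment(st2, pp, n, g1 = numeric(n))
  expect_gt(seg2$state$voided_mL, 0)
})

test_that("manual emptying resets the trial and is idempotent", {
  pp <- quiet_plant()
  tr <- run_closed_loop(pp, controller_params(), seed = 1)
  st <- plant_init(pp, 0.5)
  st$activation <- 0.4; st$voided_mL <- 0.2; st$fatigue <- 0.1
  class(st) <- "isms_plant_state"
  e1 <- manual_empty(st)
  expect_equal(e1$volume_mL, 0)
  expect_equal(e1$voided_mL, 0)
  expect_equal(e1$infused_mL, 0)
  expect_equal(plant_pressure(e1, pp), pp$basal_pressure)
  expect_identical(manual_empty(e1), e1)
})

test_that("noise-free trajectories are bit-reproducible, noisy ones seed-reproducible", {
  pp <- quiet_plant()
  a <- run_closed_loop(pp, controller_params(), seed = 5)
  b <- run_closed_loop(pp, controller_params(), seed = 99)
  expect_identical(a$record, b$record)  # process independent of seed at sd 0
  pn <- plant_params()  # default observation noise
  c1 <- run_closed_loop(pn, controller_params(), seed = 5)
  c2 <- run_closed_loop(pn, controller_params(), seed = 5)
  expect_identical(c1$record, c2$record)
  c3 <- run_closed_loop(pn, controller_params(), seed = 6)
  expect_false(identical(c3$record$pressure_cmH2O, c1$record$pressure_cmH2O))
  # observation noise does not alter the voiding trajectory
  expect_identical(c1$record$voided_mL, c3$record$voided_mL)
})

test_that("diverging dynamics abort with a diagnostic", {
  pp <- quiet_plant()
  st <- plant_init(pp, 0.9)
  st$activation <- Inf
  expect_error(ismsloop:::plant_segment(st, pp, 5, g1 = numeric(5)),
               "diverged")
})
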
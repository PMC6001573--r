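test_that("step currents measure the last two-thirds correctly", {
  # ohmic, no transient: exact Ohm's law at every step
  sp <- sweep_spec(leak_conductance_nS = 1, leak_reversal_mV = 0,
                   cap_gain_pA_per_mV = 0, noise_sd_pA = 0)
  iv <- measure_step_currents(generate_sweepset(sp))
  expect_equal(iv$i_pA, iv$v_mV)
  # with a tau = 10 ms transient: matches the closed-form discrete window
  # mean (geometric-series oracle) to near machine precision
  sp2 <- sweep_spec(leak_conductance_nS = 2, leak_reversal_mV = -40,
                    capacitance_tau_ms = 10, cap_gain_pA_per_mV = 3,
                    noise_sd_pA = 0)
  iv2 <- measure_step_currents(generate_sweepset(sp2))
  vs <- iv2$v_mV
  fs <- 10000; D <- 0.250; tau <- 0.010
  tt <- (seq_len(round(D * fs)) - 1) / fs
  k0 <- sum(tt < D / 3)                  # samples excluded at the start
  n_all <- length(tt); n_win <- n_all - k0
  rho <- exp(-1 / (fs * tau))
  geom_mean_exp <- (rho^k0 - rho^n_all) / ((1 - rho) * n_win)
  oracle <- 2 * (vs + 40) + 3 * (vs + 20) * geom_mean_exp
  expect_lt(max(abs(iv2$i_pA - oracle) / pmax(abs(oracle), 1)), 1e-9)
  # missing one trace -> protocol mismatch
  ss <- generate_sweepset(sp)
  ss$traces <- ss$traces[-3]
  expect_error(measure_step_currents(ss), class = "protocol_mismatch")
  # trace shorter than the step -> protocol mismatch
  ss2 <- generate_sweepset(sp)
  ss2$traces[[1]] <- current_trace(ss2$traces[[1]]$samples[1:100], 10000)
  expect_error(measure_step_currents(ss2), class = "protocol_mismatch")
})

test_that("window measurement is robust to fast capacitive transients", {
  # tau at most one tenth of the excluded first third changes the
  # measurement by far less than 1%
  base <- sweep_spec(leak_conductance_nS = 2, leak_reversal_mV = -40,
                     cap_gain_pA_per_mV = 0, noise_sd_pA = 0)
  with_tr <- sweep_spec(leak_conductance_nS = 2, leak_reversal_mV = -40,
                        capacitance_tau_ms = 250 / 3 / 10,
                        cap_gain_pA_per_mV = 5, noise_sd_pA = 0)
  iv_a <- measure_step_currents(generate_sweepset(base))
  iv_b <- measure_step_currents(generate_sweepset(with_tr))
  rel <- abs(iv_b$i_pA - iv_a$i_pA) / pmax(abs(iv_a$i_pA), 1)
  expect_lt(max(rel), 0.01)
})

test_that("difference curves recover the added conductance exactly", {
  before_spec <- sweep_spec(leak_conductance_nS = 1, leak_reversal_mV = 0,
                            cap_gain_pA_per_mV = 0, noise_sd_pA = 0)
  after_spec <- sweep_spec(leak_conductance_nS = 1, leak_reversal_mV = 0,
                           added_conductance_nS = 0.5,
                           added_reversal_mV = 15,
                           cap_gain_pA_per_mV = 0, noise_sd_pA = 0)
  before <- measure_step_currents(generate_sweepset(before_spec))
  after <- measure_step_currents(generate_sweepset(after_spec))
  dc <- difference_curve(after, before)
  expect_equal(dc$i_pA, 0.5 * (dc$v_mV - 15))
  expect_equal(difference_curve(before, before)$i_pA, rep(0, 11))
  # mismatched grids error
  sub <- iv_curve(before$v_mV[-1], before$i_pA[-1])
  expect_error(difference_curve(sub, before), class = "grid_mismatch")
})

test_that("reversal potential interpolation and error paths", {
  # ohmic line sampled on a 20 mV grid reverses exactly at -10 mV
  v <- seq(-140, 60, by = 20)
  expect_equal(estimate_reversal_potential(iv_curve(v, 2 * (v + 10))), -10,
               ignore_attr = TRUE)
  # all-positive curve -> no-reversal error
  expect_error(estimate_reversal_potential(iv_curve(v, v - (-160))),
               class = "no_reversal")
  # planted rectifying difference current: estimate within +/- 2 mV
  before <- measure_step_currents(generate_sweepset(
    sweep_spec(noise_sd_pA = 0, cap_gain_pA_per_mV = 0)))
  after <- measure_step_currents(generate_sweepset(
    sweep_spec(added_conductance_nS = 0.8, added_reversal_mV = 12,
               rectification = "outward", rect_gain = 1.3,
               noise_sd_pA = 0, cap_gain_pA_per_mV = 0)))
  est <- estimate_reversal_potential(difference_curve(after, before))
  expect_lt(abs(est - 12), 2)
  # multiple crossings: nearest zero wins and the ambiguity is flagged
  wob <- iv_curve(v, c(1, -1, rep(-1, 5), 1, 1, 1, 1) * abs(v + 5))
  expect_warning(e2 <- estimate_reversal_potential(wob), "sign changes")
  expect_true(attr(e2, "ambiguous"))
})

test_that("series-resistance QC applies the 25% rule", {
  expect_true(check_rs_stability(c(10, 11))$pass)          # 10% change
  expect_false(check_rs_stability(c(10, 13))$pass)         # 30% change
  expect_true(check_rs_stability(rep(12, 5))$pass)
  expect_false(check_rs_stability(c(10, 10.5, 13.1, 11))$pass)
  expect_error(check_rs_stability(c(10, -1)), class = "invalid_qc")
  expect_error(check_rs_stability(10), class = "invalid_qc")
})

test_that("linearity: measured difference equals the closed-form added I/V", {
  # measure(A+B) - measure(A) recovers B's line to < 1% at every voltage
  g_add <- 0.7; e_add <- -5
  a <- measure_step_currents(generate_sweepset(
    sweep_spec(leak_conductance_nS = 2.5, leak_reversal_mV = -35,
               cap_gain_pA_per_mV = 4, noise_sd_pA = 0)))
  ab <- measure_step_currents(generate_sweepset(
    sweep_spec(leak_conductance_nS = 2.5, leak_reversal_mV = -35,
               added_conductance_nS = g_add, added_reversal_mV = e_add,
               cap_gain_pA_per_mV = 4, noise_sd_pA = 0)))
  dc <- difference_curve(ab, a)
  closed <- g_add * (dc$v_mV - e_add)
  rel <- abs(dc$i_pA - closed) / pmax(abs(closed), 1)
  expect_lt(max(rel), 0.01)
})
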
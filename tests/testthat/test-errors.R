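test_that("conversion error is one injection quantum per window", {
  cfg <- cdc_config()
  # code 1 (500 nA), 3.125 ns clock, 500 fC decay charge -> 0.3125%
  e <- conversion_error(1, 1, cfg, q1 = 30e-12, q2 = 500e-15)
  expect_equal(e$eps2, 0.003125)

  # linear in T_clk: doubling the clock halves both terms
  cfg2 <- cdc_config(f_clk = 640e6)
  e2 <- conversion_error(1, 1, cfg2, q1 = 30e-12, q2 = 500e-15)
  expect_equal(e2$eps_total, e$eps_total / 2)

  # proportional to the code
  e3 <- conversion_error(3, 3, cfg, q1 = 30e-12, q2 = 500e-15)
  expect_equal(e3$eps1 / e$eps1, 3)

  expect_error(conversion_error(1, 1, cfg, q1 = 0, q2 = 1e-12), "positive")
})

test_that("comparator offset error matches the capacitive charge model", {
  expect_equal(offset_charge_error(3e-12, 25e-3), 75e-15)
  expect_equal(offset_charge_error(3e-12, 0), 0)
  expect_equal(offset_charge_error(6e-12, 25e-3), 150e-15)

  expect_equal(offset_current_error(75e-15, 1e-6), 75e-9)
  expect_equal(offset_current_error(75e-15, 2e-6), 37.5e-9)
  expect_equal(offset_current_error(0, 1e-6), 0)
})

test_that("offset shifts the counted window charge by C_total * dV_off", {
  cfg0 <- ideal_cfg()
  cfg1 <- cdc_config(comparator = comparator_params(offset = 25e-3,
                                                    noise_rms = 0))
  wf <- constant_waveform(1e-6, 31e-6)
  sch <- single_window_schedule(30e-6, 3, cfg0)
  dq <- run_conversion(wf, sch, cfg0)$q1_hat -
    run_conversion(wf, sch, cfg1)$q1_hat
  eps_q <- offset_charge_error(cfg0$c_total, 25e-3)
  expect_lt(abs(dq - eps_q), quantum(3, cfg0))
})

test_that("error versus clock frequency reproduces the operating point", {
  grid <- c(80e6, 160e6, 320e6, 640e6)
  ana <- error_vs_fclk_sweep(grid, mode = "analytic")
  sim <- error_vs_fclk_sweep(grid, mode = "loop_sim")

  # analytic error strictly decreasing in clock frequency
  expect_true(all(diff(ana$eps_total) < 0))
  # eps2 dominates: the decay window holds far less charge than T1
  expect_true(all(ana$eps2 / ana$eps1 >= 30e-6 / 1e-6 / ana$code1))
  # loop simulation agrees with the one-quantum model within a factor of 2
  ratio <- sim$eps_total / ana$eps_total
  expect_true(all(ratio < 2 & ratio > 0.5))
  # 320 MHz operating point sits below the 0.5% design target
  expect_lt(ana$eps_total[ana$f_clk_Hz == 320e6], 0.005)
  expect_lt(sim$eps_total[sim$f_clk_Hz == 320e6], 0.005)
})

test_that("resolution and dynamic range derive from count extremes", {
  cfg <- cdc_config()
  r <- resolution_and_dr(10, 10000, cfg, window_s = 30e-6, code = 1)
  expect_equal(r$resolution, 500e-9 * 3.125e-9 / 30e-6)  # 52.08 pA/cnt
  expect_equal(r$dr, 60)
  expect_equal(resolution_and_dr(7, 7, cfg, 30e-6)$dr, 0)
  expect_error(resolution_and_dr(0, 10, cfg, 30e-6), "undefined")
  # DR is a pure count ratio: independent of the code
  expect_equal(resolution_and_dr(10, 10000, cfg, 30e-6, code = 5)$dr, 60)
})

test_that("the decision-probability sweep recovers the injected noise", {
  target <- 0.28e-3
  sw <- comparator_noise_sweep(comparator_params(noise_rms = target),
                               n_trials = 1000, seed = 4)
  expect_equal(nrow(sw), 31)
  sigma <- fit_comparator_noise(sw)
  expect_lt(abs(sigma - target) / target, 0.10)
})

test_that("zero-mean kickback leaves no net charge error", {
  kick <- 2e-15  # ~1.3 quanta of code-3 charge per decision
  wf <- constant_waveform(1e-6, 31e-6)
  errs <- sapply(1:40, function(s) {
    cfg <- cdc_config(comparator = comparator_params(
      offset = 0, noise_rms = 0, kickback_charge_rms = kick))
    r <- run_conversion(wf, single_window_schedule(30e-6, 3, cfg), cfg,
                        seed = s)
    r$q1_hat - r$q_in1
  })
  se <- stats::sd(errs) / sqrt(length(errs))
  expect_gt(stats::sd(errs), 0)
  expect_lt(abs(mean(errs)), 3 * se)
})

test_that("cell rotation averages out I-DAC mismatch", {
  set.seed(12)
  mm <- stats::rnorm(15, 0, 0.05)
  mm <- mm - mean(mm)  # gain referenced to the array average
  wf <- constant_waveform(1e-6, 31e-6)
  err <- sapply(c(TRUE, FALSE), function(dem) {
    cfg <- ideal_cfg(dem_enabled = dem, cell_mismatch = mm)
    r <- run_conversion(wf, single_window_schedule(30e-6, 3, cfg), cfg)
    abs(r$q1_hat - r$q_in1) / r$q_in1
  })
  expect_lt(err[1], err[2])          # DEM beats the frozen subset
  expect_lt(err[1], 2 * quantum(3, ideal_cfg()) / 30e-12)
})
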
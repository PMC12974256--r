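test_that("comparator decisions follow the offset-shifted threshold", {
  cfg <- cdc_config()
  ideal <- ideal_comparator()
  expect_equal(comparator_decide(cfg$v_ref - 1e-6, ideal, cfg), 1L)
  expect_equal(comparator_decide(cfg$v_ref + 1e-6, ideal, cfg), 0L)

  # far from threshold the decision is certain even with noise on
  noisy <- comparator_params(offset = 0, noise_rms = 0.28e-3)
  v <- rep(cfg$v_ref - 10 * noisy$noise_rms, 500)
  expect_equal(mean(comparator_decide(v, noisy, cfg, seed = 1)), 1)

  # at the offset-shifted threshold the decision is a fair coin
  at_thr <- comparator_params(offset = 25e-3, noise_rms = 0.28e-3)
  v <- rep(cfg$v_ref - at_thr$offset, 20000)
  p <- mean(comparator_decide(v, at_thr, cfg, seed = 2))
  expect_equal(p, 0.5, tolerance = 0.02)
})

test_that("I-DAC steps select rotating thermometer cells", {
  cfg <- cdc_config()
  s0 <- idac_step(0, 0, cfg)
  expect_equal(s0$current, 0)
  expect_equal(s0$next_dem_state, 1)

  expect_equal(idac_step(15, 0, cfg)$current, 7.5e-6)
  expect_error(idac_step(16, 0, cfg), "code")

  # code 1, 15 steps: every cell used exactly once
  st <- 0; used <- integer(0)
  for (i in 1:15) {
    s <- idac_step(1, st, cfg)
    used <- c(used, s$cells)
    st <- s$next_dem_state
  }
  expect_equal(sort(used), 1:15)

  # DEM off: the pointer (and hence the cell subset) never moves
  cfg_off <- cdc_config(dem_enabled = FALSE)
  expect_equal(idac_step(3, 7, cfg_off)$next_dem_state, 7)

  # mismatch sums over the activated cells
  mm <- rep(0, 15); mm[1:2] <- c(0.05, -0.05)
  cfgm <- cdc_config(cell_mismatch = mm)
  expect_equal(idac_step(2, 0, cfgm)$current, 2 * 500e-9)
  expect_equal(idac_step(1, 0, cfgm)$current, 500e-9 * 1.05)
})

test_that("node update conserves charge on the integration capacitance", {
  cfg <- cdc_config()  # C_total = 3.2 pF
  expect_equal(node_step(0.8, 1e-6, 0, 4, cfg, 3.125e-9) - 0.8,
               -0.0009765625)
  expect_equal(node_step(0.8, 0, 0, 4, cfg), 0.8)
  # balanced: injected code current equals input current
  expect_equal(node_step(0.8, 2e-6, 1, 4, cfg), 0.8)
})

test_that("charge balance digitizes a constant current to one count", {
  cfg <- ideal_cfg()
  wf <- constant_waveform(1e-6, 31e-6)
  r <- run_conversion(wf, single_window_schedule(30e-6, 4, cfg), cfg)
  expect_equal(r$cnt1, 4800, tolerance = 1 / 4800)  # 30 pC / 6.25 fC
  expect_lt(abs(r$q1_hat - r$q_in1), 2 * quantum(4, cfg))

  # zero input: nothing to balance
  r0 <- run_conversion(constant_waveform(0, 31e-6),
                       single_window_schedule(30e-6, 4, cfg), cfg)
  expect_equal(r0$cnt1, 0)
})

test_that("film conversion reconstructs both window charges", {
  cfg <- ideal_cfg()
  fm <- film_params()
  exc <- excitation_profile()
  resp <- film_response(0, fm, exc, mode = "exact")
  r <- run_conversion(film_waveform_factory(0, fm, exc)(),
                      film_schedule(exc, 3, 1), cfg)
  expect_lt(abs(r$q1_hat - resp$a1), 2 * quantum(3, cfg))
  expect_lt(abs(r$q2_hat - resp$a2), 2 * quantum(1, cfg))
  expect_equal(r$lr_hat, resp$lr, tolerance = 0.01)
})

test_that("per-window charge conservation holds to machine precision", {
  # counted injections + node state account for every coulomb of input
  set.seed(101)
  for (i in 1:25) {
    f <- stats::runif(1, 50e6, 640e6)
    cur <- 10^stats::runif(1, -7, -5.2)
    cfg <- ideal_cfg(f_clk = f)
    code <- covering_code(cur, cfg)
    w <- stats::runif(1, 5e-6, 40e-6)
    wf <- constant_waveform(cur, w + 2 / f)
    r <- run_conversion(wf, single_window_schedule(w, code, cfg), cfg,
                        trace = TRUE)
    tr <- r$vpd_trace
    v_end <- tr$v_pd_V[max(which(tr$window == 1))]
    residual <- r$q_act1 - r$q_in1 - cfg$c_total * (v_end - cfg$v_ref)
    expect_lt(abs(residual), 1e-3 * quantum(code, cfg))
    expect_lt(abs(r$q1_hat - r$q_in1), 2 * quantum(code, cfg))
  }
})

test_that("counts are monotone in the input current at fixed code", {
  cfg <- ideal_cfg()
  cnts <- sapply(seq(0.2e-6, 3e-6, length.out = 10), function(cur) {
    run_conversion(constant_waveform(cur, 31e-6),
                   single_window_schedule(30e-6, 8, cfg), cfg)$cnt1
  })
  expect_true(all(diff(cnts) >= 0))
})

test_that("counter overflow and injection overload are reported", {
  cfg <- ideal_cfg(counter_bits = 8)  # overflows at 256 counts
  wf <- constant_waveform(2e-6, 31e-6)
  expect_error(run_conversion(wf, single_window_schedule(30e-6, 5, cfg), cfg),
               "overflow.*Count1")

  # code current below the input: duty saturates and the flag is raised
  cfg16 <- ideal_cfg()
  r <- run_conversion(constant_waveform(1e-6, 31e-6),
                      single_window_schedule(30e-6, 1, cfg16), cfg16)
  expect_true(r$saturation_warning[["count1"]])
  expect_lt(r$q1_hat, r$q_in1)
})

test_that("DEM keeps cell usage uniform across the array", {
  cfg <- ideal_cfg()
  r <- run_conversion(constant_waveform(1e-6, 31e-6),
                      single_window_schedule(30e-6, 3, cfg), cfg)
  # rotation by one per injection: usage deviates from the mean by less
  # than the arc length (the final partial rotation)
  expect_lt(max(abs(r$cell_use - mean(r$cell_use))), 3)
  expect_equal(sum(r$cell_use), 3 * (r$cnt1 + r$cnt2))
})

test_that("count arithmetic recovers the photocurrent ratio", {
  expect_equal(intensity_ratio_from_counts(19200, 320, 30e-6, 1e-6), 1)
  # fully quenched: count ratio equals t1/tau_ref
  expect_equal(intensity_ratio_from_counts(3000, 100, 30e-6, 1e-6), 0)
  expect_error(intensity_ratio_from_counts(100, 0, 30e-6, 1e-6), "cnt2")
  expect_warning(out <- intensity_ratio_from_counts(0, 10, 30e-6, 1e-6),
                 "degenerate")
  expect_equal(out, -1)
})
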
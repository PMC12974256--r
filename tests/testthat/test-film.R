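test_that("luminophore intensities follow Stern-Volmer quenching", {
  exc <- excitation_profile()
  # unquenched: i_sen = i_ext * s_sen
  fm <- film_params()
  iv0 <- luminophore_intensities(0, fm, exc)
  expect_equal(iv0$i_sen, exc$i_ext * fm$s_sen)

  # 1.5 uA unquenched current, K_SV = 0.05 /mmHg, 40 mmHg -> 0.5 uA
  fm2 <- film_params(k_sv = 0.05, s_sen = 1.5e-6)
  expect_equal(luminophore_intensities(40, fm2, exc)$i_sen, 0.5e-6)

  # reference channel independent of CO2
  fm3 <- film_params(s_ref = 0.6e-6)
  iref <- luminophore_intensities(c(0, 10, 200), fm3, exc)$i_ref
  expect_equal(iref, rep(0.6e-6, 3))

  # Stern-Volmer identity: i_sen0/i_sen - 1 = k_sv * pco2
  p <- c(0, 1, 5, 40, 120, 500)
  iv <- luminophore_intensities(p, fm, exc)
  expect_equal(iv0$i_sen / iv$i_sen - 1, fm$k_sv * p)

  expect_error(luminophore_intensities(-1, fm, exc), "non-negative")
})

test_that("constructors enforce the physical invariants", {
  expect_error(film_params(tau_sen = 2e-6, tau_ref = 1e-6), "tau_sen")
  expect_error(film_params(k_sv = -0.1), "positive")
  expect_error(excitation_profile(i_ext = 0), "positive")
  expect_error(excitation_profile(t_d_sen = 7e-6, t_d_ref = 6e-6),
               "t_d_sen")
})

test_that("photocurrent waveform rises, plateaus and decays continuously", {
  fm <- film_params()
  exc <- excitation_profile()
  t_off <- exc$t_stabilize + exc$t1
  iv <- luminophore_intensities(0, fm, exc)
  plateau <- iv$i_sen + iv$i_ref

  # stabilized plateau well after many reference lifetimes
  expect_equal(photocurrent_waveform(t_off - 1e-9, 0, fm, exc), plateau,
               tolerance = 1e-6)
  # continuity at LED turn-off
  expect_equal(photocurrent_waveform(t_off, 0, fm, exc),
               photocurrent_waveform(t_off + 1e-12, 0, fm, exc),
               tolerance = 1e-3)
  # one reference lifetime into the decay: only the slow term survives
  expect_equal(photocurrent_waveform(t_off + fm$tau_ref, 0, fm, exc),
               iv$i_ref * exp(-1), tolerance = 1e-4)
  expect_error(photocurrent_waveform(t_off + exc$t_d_ref + 1e-6, 0, fm, exc),
               "outside")
})

test_that("window areas match their closed forms", {
  exc <- excitation_profile(t1 = 30e-6, t_d_sen = 50e-9, t_d_ref = 6e-6)
  fm <- film_params(tau_ref = 1e-6)
  resp <- list(i_sen = 0.5e-6, i_ref = 0.5e-6)
  expect_equal(area_a1(resp, exc), 30e-12)
  expect_equal(area_a1(list(i_sen = 0, i_ref = 0.5e-6), exc),
               0.5e-6 * exc$t1)

  expect_equal(area_a2(resp, fm, exc, "approximate"), 0.5e-12)
  # closed-form window integral, sensitive term removed
  resp0 <- list(i_sen = 0, i_ref = 0.5e-6)
  expect_equal(area_a2(resp0, fm, exc, "exact"),
               0.5e-12 * (exp(-0.05) - exp(-6)), tolerance = 1e-12)
  # exact -> approximate as the window opens up
  wide <- excitation_profile(t_d_sen = 0, t_d_ref = 100e-6)
  expect_equal(area_a2(resp0, fm, wide, "exact"),
               area_a2(resp0, fm, wide, "approximate"), tolerance = 1e-9)
  expect_error(area_a2(resp, fm, excitation_profile(), mode = "exact")
               , NA)
})

test_that("luminescence ratio cancels excitation and decreases with CO2", {
  fm <- film_params(s_sen = 500e-9, s_ref = 500e-9, k_sv = 0.05,
                    tau_ref = 1e-6)
  exc <- excitation_profile(t1 = 30e-6)
  # s_sen/s_ref = 1, pco2 = 0, T1/tau_ref = 30 -> LR = 60
  expect_equal(luminescence_ratio(0, fm, exc), 60)
  # fully quenched limit -> T1/tau_ref
  expect_equal(luminescence_ratio(1e9, fm, exc), 30, tolerance = 1e-6)

  # excitation invariance to machine precision at several scales
  p <- seq(0, 300, length.out = 7)
  for (alpha in c(0.1, 2, 17)) {
    exc2 <- excitation_profile(i_ext = alpha * exc$i_ext, t1 = exc$t1)
    expect_equal(luminescence_ratio(p, fm, exc),
                 luminescence_ratio(p, fm, exc2), tolerance = 1e-14)
  }

  # strict monotone decrease, both area models
  for (m in c("approximate", "exact")) {
    lr <- luminescence_ratio(seq(0, 500, length.out = 101), fm, exc,
                             mode = m)
    expect_true(all(diff(lr) < 0))
  }
})

test_that("CO2 inversion round-trips and rejects unphysical ratios", {
  fm <- film_params()
  exc <- excitation_profile()
  p <- seq(0, 500, length.out = 201)
  for (m in c("approximate", "exact")) {
    back <- pco2_from_lr(luminescence_ratio(p, fm, exc, mode = m),
                         fm, exc, mode = m)
    expect_equal(back, p, tolerance = 1e-9)
  }

  # hand inversion: ratio 1, K_SV 0.05, T1/tau = 30, lr = 50 -> 10 mmHg
  expect_equal(pco2_from_lr(50, fm, exc), 10, tolerance = 1e-12)

  hi <- luminescence_ratio(0, fm, exc)
  lo <- exc$t1 / fm$tau_ref
  expect_error(pco2_from_lr(hi * 1.01, fm, exc), "physical range")
  expect_error(pco2_from_lr(lo, fm, exc), "physical range")
})
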
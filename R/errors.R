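#' Per-window conversion (quantization) error
#'
#' The charge-balancing loop resolves each window's charge to one injection
#' quantum `I_DAC(code) * T_clk`, so the relative conversion error of a
#' window is one quantum over the window charge. Larger codes and slower
#' clocks increase it; the scaling controller reduces the code for small
#' photocurrents precisely to shrink this quantum.
#'
#' @param code1,code2 DAC codes of the two windows.
#' @param config A [cdc_config()].
#' @param q1,q2 Window charges, coulombs (positive).
#' @return List with `eps1`, `eps2`, `eps_total` (fractions).
#' @examples
#' conversion_error(1, 1, cdc_config(), q1 = 30e-12, q2 = 500e-15)
#' @export
conversion_error <- function(code1, code2, config = cdc_config(), q1, q2) {
  if (any(c(q1, q2) <= 0))
    stop("window charges must be positive: conversion error undefined",
         call. = FALSE)
  eps1 <- idac_current(code1, config) * config$t_clk / q1
  eps2 <- idac_current(code2, config) * config$t_clk / q2
  list(eps1 = eps1, eps2 = eps2, eps_total = eps1 + eps2)
}

#' Comparator-offset charge error
#'
#' A static comparator offset shifts the threshold the node settles to,
#' adding `eps_Q = C_total * delta_v_off` to the integrated charge of a
#' window entered from the idle preset.
#'
#' @param c_total Integration capacitance, farads.
#' @param delta_v_off Comparator input offset, volts.
#' @return Charge error, coulombs.
#' @examples
#' offset_charge_error(3e-12, 25e-3)  # 75 fC
#' @export
offset_charge_error <- function(c_total, delta_v_off) {
  if (c_total <= 0) stop("c_total must be positive", call. = FALSE)
  c_total * delta_v_off
}

#' Offset charge error referred to the decay-phase current
#'
#' Spread over the decay time constant, the offset charge error corresponds
#' to an equivalent current `eps_I = eps_Q / tau`, which is why the offset
#' matters most for sub-microampere photocurrents.
#'
#' @param eps_q Charge error, coulombs.
#' @param tau Decay time constant, seconds.
#' @return Current error, amperes.
#' @examples
#' offset_current_error(75e-15, 1e-6)  # 75 nA
#' @export
offset_current_error <- function(eps_q, tau) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  eps_q / tau
}

#' Total conversion error versus clock frequency
#'
#' Sweeps the clock and reports the total conversion error `eps1 + eps2`
#' for the dual-window measurement, with per-window minimal covering codes
#' (scaling-controller rule applied to the known mean window currents).
#' `analytic` mode evaluates the one-quantum-per-window model of
#' [conversion_error()]; `loop_sim` runs the full clock-cycle loop with an
#' ideal comparator and reports `|Q1_hat - Q1|/Q1 + |Q2_hat - Q2|/Q2`
#' against the closed-form window charges.
#'
#' Defaults reproduce the behavioral operating-point study: both
#' photocurrents 500 nA, reference lifetime 1 us, excitation window 30 us,
#' I-DAC LSB 500 nA.
#'
#' @param f_grid Clock frequencies, Hz.
#' @param film A [film_params()].
#' @param excitation An [excitation_profile()].
#' @param config Template [cdc_config()] (its `f_clk` is overridden).
#' @param scaling A [scaling_config()] (provides the code headroom).
#' @param mode `"analytic"`, `"loop_sim"`, or both.
#' @param pco2 Operating CO2 level for the film waveform, mmHg.
#' @return `data.frame` with columns `f_clk_Hz`, `eps1`, `eps2`,
#'   `eps_total`, `code1`, `code2`, `mode`.
#' @examples
#' error_vs_fclk_sweep(c(160e6, 320e6), mode = "analytic")
#' @export
error_vs_fclk_sweep <- function(f_grid,
                                film = film_params(),
                                excitation = excitation_profile(),
                                config = cdc_config(comparator = ideal_comparator()),
                                scaling = scaling_config(),
                                mode = c("analytic", "loop_sim"),
                                pco2 = 0) {
  mode <- match.arg(mode, several.ok = TRUE)
  resp <- film_response(pco2, film, excitation, mode = "exact")
  q1 <- resp$a1
  q2 <- resp$a2
  w1 <- excitation$t1
  w2 <- excitation$t_d_ref - excitation$t_d_sen
  rows <- list()
  for (f in f_grid) {
    cfg <- cdc_config(f_clk = f, c_pd = config$c_pd,
                      c_parasitic = config$c_parasitic, v_ref = config$v_ref,
                      i_dac_lsb = config$i_dac_lsb,
                      n_dac_bits = config$n_dac_bits,
                      counter_bits = config$counter_bits,
                      comparator = config$comparator,
                      dem_enabled = config$dem_enabled,
                      cell_mismatch = config$cell_mismatch,
                      switch_injection_charge = config$switch_injection_charge)
    code1 <- min(max(ceiling(scaling$headroom * (q1 / w1) / cfg$i_dac_lsb),
                     1), cfg$code_max)
    code2 <- min(max(ceiling(scaling$headroom * (q2 / w2) / cfg$i_dac_lsb),
                     1), cfg$code_max)
    for (m in mode) {
      if (m == "analytic") {
        e <- conversion_error(code1, code2, cfg, q1, q2)
        eps1 <- e$eps1; eps2 <- e$eps2
      } else {
        wf <- film_waveform_factory(pco2, film, excitation)()
        r <- run_conversion(wf, film_schedule(excitation, code1, code2), cfg)
        eps1 <- abs(r$q1_hat - q1) / q1
        eps2 <- abs(r$q2_hat - q2) / q2
      }
      rows[[length(rows) + 1]] <- data.frame(
        f_clk_Hz = f, eps1 = eps1, eps2 = eps2, eps_total = eps1 + eps2,
        code1 = code1, code2 = code2, mode = m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Resolution and dynamic range from count extremes
#'
#' Resolution is the input current corresponding to one count,
#' `I_DAC(code) * T_clk / window`; dynamic range is the dB ratio of the
#' counts at the largest and smallest reliably measured currents,
#' `20 * log10(cnt_max/cnt_min)`.
#'
#' @param cnt_min,cnt_max Counts at the detection extremes
#'   (`0 < cnt_min <= cnt_max`).
#' @param config A [cdc_config()].
#' @param window_s Counted window, seconds.
#' @param code DAC code at which the resolution is quoted (default 1).
#' @return List with `resolution` (A per count) and `dr` (dB).
#' @examples
#' resolution_and_dr(10, 10000, cdc_config(), 30e-6)
#' @export
resolution_and_dr <- function(cnt_min, cnt_max, config = cdc_config(),
                              window_s, code = 1) {
  if (cnt_min <= 0) stop("cnt_min = 0: dynamic range undefined", call. = FALSE)
  if (cnt_min > cnt_max) stop("cnt_min must be <= cnt_max", call. = FALSE)
  list(resolution = idac_current(code, config) * config$t_clk / window_s,
       dr = 20 * log10(cnt_max / cnt_min))
}

#' Comparator decision-probability sweep
#'
#' The input-referred noise characterization procedure: a small differential
#' `dv` is applied to the comparator input (node held at `v_ref + dv`,
#' offset removed) and the probability of the output being high is recorded
#' over `n_trials` decisions at each grid point. The probability curve is a
#' Gaussian CDF whose standard deviation is the input-referred noise.
#'
#' @param params A [comparator_params()] carrying the noise to be recovered.
#' @param config A [cdc_config()].
#' @param dv_grid Differential grid, volts (default -1.5 to 1.5 mV, 31
#'   points).
#' @param n_trials Decisions per grid point (default 1000).
#' @param seed Optional integer seed.
#' @return `data.frame` with `dv_V`, `n`, `k_high`, `p_high`.
#' @seealso [fit_comparator_noise()]
#' @export
comparator_noise_sweep <- function(params, config = cdc_config(),
                                   dv_grid = seq(-1.5e-3, 1.5e-3,
                                                 length.out = 31),
                                   n_trials = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probe <- comparator_params(offset = 0, noise_rms = params$noise_rms)
  k <- vapply(dv_grid, function(dv) {
    sum(comparator_decide(rep(config$v_ref + dv, n_trials), probe, config))
  }, numeric(1))
  data.frame(dv_V = dv_grid, n = n_trials, k_high = k, p_high = k / n_trials)
}

#' Recover the input-referred noise sigma from a decision sweep
#'
#' Fits a probit model `P(high) = Phi(-(dv)/sigma)` to the output of
#' [comparator_noise_sweep()] and returns the recovered noise standard
#' deviation.
#'
#' @param sweep Output of [comparator_noise_sweep()].
#' @return Estimated noise RMS, volts.
#' @examples
#' sw <- comparator_noise_sweep(comparator_params(noise_rms = 0.28e-3),
#'                              n_trials = 200, seed = 1)
#' fit_comparator_noise(sw)
#' @export
fit_comparator_noise <- function(sweep) {
  fit <- stats::glm(cbind(k_high, n - k_high) ~ dv_V,
                    family = stats::binomial(link = "probit"), data = sweep)
  slope <- stats::coef(fit)[["dv_V"]]
  if (slope >= 0)
    stop("decision probability does not decrease with dv: no noise to fit",
         call. = FALSE)
  -1 / slope
}
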
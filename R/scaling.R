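#' Current-scaling controller configuration
#'
#' Parameters of the I-DAC current-scaling algorithm: after one full-scale
#' scaling cycle the controller selects per-window DAC codes from the
#' counter outputs and holds them for `n_average_cycles` measurement cycles,
#' whose counts are averaged into one luminescence-ratio estimate.
#'
#' @param n_average_cycles Cycles per held-code measurement (default 100).
#' @param headroom Code-selection margin >= 1: the selected code current
#'   must exceed `headroom` times the estimated mean input current.
#' @param lut_mode `"per_window"` (independent codes for Count1/Count2) or
#'   `"shared"` (one code, the larger of the two, for both windows).
#' @param duty_cycle Active fraction of the measurement timeline.
#' @param quantization_target Design target for the relative LR error
#'   (default 0.005, i.e. 0.5 percent).
#' @return Object of class `scaling_config`.
#' @export
scaling_config <- function(n_average_cycles = 100L, headroom = 1.25,
                           lut_mode = c("per_window", "shared"),
                           duty_cycle = 0.01, quantization_target = 0.005) {
  lut_mode <- match.arg(lut_mode)
  if (n_average_cycles < 1) stop("n_average_cycles must be >= 1", call. = FALSE)
  if (headroom < 1) stop("headroom must be >= 1", call. = FALSE)
  if (duty_cycle <= 0 || duty_cycle > 1)
    stop("duty_cycle must be in (0, 1]", call. = FALSE)
  structure(list(n_average_cycles = as.integer(n_average_cycles),
                 headroom = headroom, lut_mode = lut_mode,
                 duty_cycle = duty_cycle,
                 quantization_target = quantization_target),
            class = "scaling_config")
}

#' Select a DAC code from a full-scale count
#'
#' Implements the look-up rule behind the scaling table: the full-scale
#' count estimates the mean window current `I_hat = cnt_prime *
#' I_DAC(full) * T_clk / window`, and the smallest code whose current covers
#' `headroom * I_hat` is returned, clipped to `[1, code_max]`. The headroom
#' keeps the loop balanced while minimizing the per-count charge quantum,
#' which drives the conversion error.
#'
#' @param cnt_prime Count obtained at full scale during the scaling cycle.
#' @param window_s Counted window duration, seconds.
#' @param config A [cdc_config()].
#' @param scaling A [scaling_config()].
#' @return Integer DAC code in `[1, code_max]`.
#' @examples
#' # 1 uA estimated current, 1.25 headroom, 500 nA LSB -> code 3
#' cfg <- cdc_config()
#' cnt <- 1e-6 * 30e-6 / (idac_current(15, cfg) * cfg$t_clk)
#' select_dac_code(cnt, 30e-6, cfg)
#' @export
select_dac_code <- function(cnt_prime, window_s, config = cdc_config(),
                            scaling = scaling_config()) {
  stopifnot(cnt_prime >= 0, window_s > 0)
  i_hat <- cnt_prime * idac_current(config$code_max, config) *
    config$t_clk / window_s
  code <- ceiling(scaling$headroom * i_hat / config$i_dac_lsb)
  as.integer(min(max(code, 1), config$code_max))
}

#' Scaled, averaged luminescence-ratio measurement
#'
#' The full measurement procedure: one scaling cycle at full scale yields
#' `CNT1'`/`CNT2'`, the controller selects the held codes, then
#' `n_average_cycles` conversions run with those codes (never changed
#' mid-hold) and their counts are averaged. The returned `lr` is the
#' reconstructed-charge ratio (equal to the mean count ratio when the two
#' windows share one code); `count_ratio` is `cnt1_mean/cnt2_mean`.
#'
#' @param waveform_factory Zero-argument function yielding one cycle's
#'   `cdc_waveform` per call (see [constant_current_factory()],
#'   [film_waveform_factory()]).
#' @param schedule_fn Function `(code1, code2) -> conversion_schedule`
#'   fixing the window timing; see [film_schedule()], [bench_schedule()].
#' @param config A [cdc_config()].
#' @param scaling A [scaling_config()].
#' @param scaling_enabled If `FALSE`, the held cycles also run at full
#'   scale (the no-scaling reference mode).
#' @param seed Optional integer seed (consumed once; all cycles draw from
#'   the resulting stream).
#' @param keep_cycles Keep the per-cycle `conversion_result` list?
#' @return Object of class `lr_measurement`.
#' @examples
#' fac <- constant_current_factory(test_current_spec(list(c(30e-6, 5e-6))))
#' sch <- function(c1, c2) bench_schedule(25e-6, 5e-6, c1, c2)
#' cfg <- cdc_config(comparator = ideal_comparator())
#' measure_lr(fac, sch, cfg, scaling_config(n_average_cycles = 5))
#' @export
measure_lr <- function(waveform_factory, schedule_fn,
                       config = cdc_config(), scaling = scaling_config(),
                       scaling_enabled = TRUE, seed = NULL,
                       keep_cycles = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  full <- config$code_max

  # scaling cycle: both windows at full scale
  sc <- run_conversion(waveform_factory(), schedule_fn(full, full), config)
  cnt1p <- sc$cnt1
  cnt2p <- sc$cnt2
  sch_probe <- schedule_fn(full, full)
  if (scaling_enabled) {
    code1 <- select_dac_code(cnt1p, sch_probe$count1_s, config, scaling)
    code2 <- select_dac_code(cnt2p, sch_probe$count2_s, config, scaling)
    if (scaling$lut_mode == "shared") code1 <- code2 <- max(code1, code2)
  } else {
    code1 <- code2 <- full
  }

  held <- schedule_fn(code1, code2)
  cycles <- vector("list", scaling$n_average_cycles)
  cnt1 <- cnt2 <- numeric(scaling$n_average_cycles)
  for (i in seq_len(scaling$n_average_cycles)) {
    r <- run_conversion(waveform_factory(), held, config)
    cnt1[i] <- r$cnt1
    cnt2[i] <- r$cnt2
    if (keep_cycles) cycles[[i]] <- r
  }
  cnt1_mean <- mean(cnt1)
  cnt2_mean <- mean(cnt2)
  q1 <- cnt1_mean * idac_current(code1, config) * config$t_clk
  q2 <- cnt2_mean * idac_current(code2, config) * config$t_clk
  structure(list(cnt1_mean = cnt1_mean, cnt2_mean = cnt2_mean,
                 lr = q1 / q2, count_ratio = cnt1_mean / cnt2_mean,
                 dacbit = c(code1 = code1, code2 = code2),
                 cnt1_prime = cnt1p, cnt2_prime = cnt2p,
                 scaling_enabled = scaling_enabled,
                 cycle_counts = data.frame(cycle = seq_along(cnt1),
                                           cnt1 = cnt1, cnt2 = cnt2),
                 cycle_results = if (keep_cycles) cycles else NULL,
                 seed = seed),
            class = "lr_measurement")
}

#' @export
print.lr_measurement <- function(x, ...) {
  cat("LR measurement\n")
  cat(sprintf("  scaling cycle: CNT1' = %d, CNT2' = %d -> codes (%d, %d)%s\n",
              as.integer(x$cnt1_prime), as.integer(x$cnt2_prime),
              x$dacbit[["code1"]], x$dacbit[["code2"]],
              if (x$scaling_enabled) "" else " [scaling off]"))
  cat(sprintf("  %d-cycle hold: CNT1 = %.2f, CNT2 = %.2f\n",
              nrow(x$cycle_counts), x$cnt1_mean, x$cnt2_mean))
  cat(sprintf("  LR = %.5g (count ratio %.5g)\n", x$lr, x$count_ratio))
  invisible(x)
}

#' Duty-cycle schedule bookkeeping
#'
#' Pure bookkeeping of the duty-cycled timeline: the active time per
#' measurement cycle is the LED-on interval plus the decay window; the idle
#' period is stretched so the active fraction equals the configured duty
#' cycle. No power model is implied.
#'
#' @param scaling A [scaling_config()] (provides `duty_cycle`).
#' @param excitation An [excitation_profile()].
#' @param n_samples Number of measurement cycles in the timeline.
#' @param period_s Optional externally imposed cycle period; if the implied
#'   duty exceeds the configured one the schedule is infeasible and an
#'   error is raised.
#' @return List with `active_s`, `period_s`, `duty`, `n_samples`,
#'   `total_s`.
#' @examples
#' schedule_summary(scaling_config(), excitation_profile(), 100)
#' @export
schedule_summary <- function(scaling = scaling_config(),
                             excitation = excitation_profile(),
                             n_samples = 100L, period_s = NULL) {
  active <- excitation$t_stabilize + excitation$t1 + excitation$t_d_ref
  if (is.null(period_s)) {
    period_s <- active / scaling$duty_cycle
    duty <- scaling$duty_cycle
  } else {
    duty <- active / period_s
    if (duty > scaling$duty_cycle + 1e-12)
      stop(sprintf(
        "infeasible schedule: active %g us in a %g us period is a %.3g%% duty, config demands %.3g%%",
        active * 1e6, period_s * 1e6, 100 * duty,
        100 * scaling$duty_cycle), call. = FALSE)
  }
  list(active_s = active, period_s = period_s, duty = duty,
       n_samples = as.integer(n_samples),
       total_s = n_samples * period_s)
}
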
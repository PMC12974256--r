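#' Latch comparator nonidealities
#'
#' Behavioral parameters of the clocked regenerative comparator: a static
#' input offset, Gaussian input-referred noise redrawn at every decision,
#' and a zero-mean kickback charge coupled onto the integration node at each
#' decision instant. Defaults are the post-layout characterization values
#' (25 mV offset, 0.28 mVrms noise); use [ideal_comparator()] for analyses
#' that isolate quantization.
#'
#' @param offset Input offset, volts.
#' @param noise_rms Input-referred noise, volts RMS (>= 0).
#' @param kickback_charge_rms Zero-mean per-decision charge perturbation,
#'   coulombs RMS.
#' @return Object of class `comparator_params`.
#' @export
comparator_params <- function(offset = 25e-3, noise_rms = 0.28e-3,
                              kickback_charge_rms = 0) {
  if (noise_rms < 0) stop("noise_rms must be >= 0", call. = FALSE)
  if (kickback_charge_rms < 0)
    stop("kickback_charge_rms must be >= 0", call. = FALSE)
  structure(list(offset = offset, noise_rms = noise_rms,
                 kickback_charge_rms = kickback_charge_rms),
            class = "comparator_params")
}

#' @rdname comparator_params
#' @export
ideal_comparator <- function() {
  comparator_params(offset = 0, noise_rms = 0, kickback_charge_rms = 0)
}

#' Converter hardware configuration
#'
#' All parameters of the direct current-to-digital converter: clock,
#' integration capacitance (photodiode junction plus board parasitics),
#' comparator threshold, I-DAC unit cell and width, counter width, dynamic
#' element matching, per-cell mismatch, and the residual switch
#' charge-injection per I-DAC turn-off (after dummy-transistor
#' cancellation).
#'
#' @param f_clk Clock frequency, Hz (default 320 MHz).
#' @param c_pd Photodiode junction capacitance, farads (default 3 pF).
#' @param c_parasitic Board/wire-bond parasitic capacitance, farads
#'   (default 0.2 pF); the integration node sees `c_pd + c_parasitic`.
#' @param v_ref Comparator reference (node preset) voltage, volts.
#' @param i_dac_lsb Unit-cell current, amperes (default 500 nA).
#' @param n_dac_bits DAC code width; codes run 0..2^n - 1 (default 4).
#' @param counter_bits Counter width; reaching 2^bits is an overflow error.
#' @param comparator A [comparator_params()] object.
#' @param dem_enabled Rotate the thermometer cells (barrel shifter)?
#' @param cell_mismatch Relative unit-cell current errors, length
#'   `2^n_dac_bits - 1`.
#' @param switch_injection_charge Residual charge injected on each I-DAC
#'   turn-off event, coulombs (default 0).
#' @return Object of class `cdc_config`.
#' @examples
#' cdc_config(comparator = ideal_comparator())
#' @export
cdc_config <- function(f_clk = 320e6, c_pd = 3e-12, c_parasitic = 0.2e-12,
                       v_ref = 0.8, i_dac_lsb = 500e-9, n_dac_bits = 4L,
                       counter_bits = 16L,
                       comparator = comparator_params(),
                       dem_enabled = TRUE,
                       cell_mismatch = NULL,
                       switch_injection_charge = 0) {
  if (f_clk <= 0) stop("f_clk must be positive", call. = FALSE)
  if (c_pd <= 0 || c_parasitic < 0)
    stop("capacitances must be positive", call. = FALSE)
  if (i_dac_lsb <= 0) stop("i_dac_lsb must be positive", call. = FALSE)
  stopifnot(inherits(comparator, "comparator_params"))
  ncell <- 2L^as.integer(n_dac_bits) - 1L
  if (is.null(cell_mismatch)) cell_mismatch <- numeric(ncell)
  if (length(cell_mismatch) != ncell)
    stop(sprintf("cell_mismatch must have length %d", ncell), call. = FALSE)
  structure(list(f_clk = f_clk, t_clk = 1 / f_clk, c_pd = c_pd,
                 c_parasitic = c_parasitic, c_total = c_pd + c_parasitic,
                 v_ref = v_ref, i_dac_lsb = i_dac_lsb,
                 n_dac_bits = as.integer(n_dac_bits),
                 code_max = ncell, counter_bits = as.integer(counter_bits),
                 comparator = comparator, dem_enabled = isTRUE(dem_enabled),
                 cell_mismatch = as.numeric(cell_mismatch),
                 switch_injection_charge = switch_injection_charge),
            class = "cdc_config")
}

#' @export
print.cdc_config <- function(x, ...) {
  cat("CDC configuration\n")
  cat(sprintf("  f_clk   : %g MHz (T_clk = %.4g ns)\n",
              x$f_clk / 1e6, x$t_clk * 1e9))
  cat(sprintf("  C_total : %g pF (C_pd %g + parasitic %g)\n",
              x$c_total * 1e12, x$c_pd * 1e12, x$c_parasitic * 1e12))
  cat(sprintf("  I-DAC   : %d-bit, LSB %g nA, DEM %s\n", x$n_dac_bits,
              x$i_dac_lsb * 1e9, if (x$dem_enabled) "on" else "off"))
  cat(sprintf("  comparator: offset %g mV, noise %g mVrms\n",
              x$comparator$offset * 1e3, x$comparator$noise_rms * 1e3))
  invisible(x)
}

#' Nominal I-DAC current for a code
#' @param code DAC code (0..`code_max`).
#' @param config A [cdc_config()].
#' @return Current, amperes.
#' @export
idac_current <- function(code, config) {
  if (any(code < 0 | code > config$code_max))
    stop(sprintf("DAC code must be in [0, %d]", config$code_max),
         call. = FALSE)
  code * config$i_dac_lsb
}

#' Single comparator decision
#'
#' Returns 1 (schedule an injection for the next clock period) iff
#' `v_pd + offset + noise < v_ref` with `noise ~ N(0, noise_rms)`.
#' Vectorized over `v_pd` (independent noise draws).
#'
#' @param v_pd Node voltage(s), volts.
#' @param params A [comparator_params()].
#' @param config A [cdc_config()] (provides `v_ref`).
#' @param seed Optional seed; required implicitly (an R RNG must be
#'   available) when `noise_rms > 0`.
#' @return Integer 0/1 vector.
#' @export
comparator_decide <- function(v_pd, params = comparator_params(),
                              config = cdc_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  noise <- if (params$noise_rms > 0)
    stats::rnorm(length(v_pd), 0, params$noise_rms) else 0
  as.integer(v_pd + params$offset + noise < config$v_ref)
}

#' One I-DAC step with barrel-shifter dynamic element matching
#'
#' Activates `code` consecutive unit cells starting at the rotation pointer
#' (wrapping modulo the cell count), sums their mismatched currents, and
#' advances the pointer by one when DEM is enabled.
#'
#' @param code DAC code, 0..`code_max`.
#' @param dem_state Rotation pointer, 0-based.
#' @param config A [cdc_config()].
#' @return List with `current` (amperes), `next_dem_state`, and `cells`
#'   (1-based indices of the activated cells).
#' @examples
#' idac_step(15, 0, cdc_config())$current  # 7.5 uA with no mismatch
#' @export
idac_step <- function(code, dem_state, config = cdc_config()) {
  if (length(code) != 1 || code < 0 || code > config$code_max)
    stop(sprintf("DAC code must be a scalar in [0, %d]", config$code_max),
         call. = FALSE)
  ncell <- config$code_max
  cells <- if (code > 0) ((dem_state + seq_len(code) - 1) %% ncell) + 1
           else integer(0)
  current <- sum(config$i_dac_lsb * (1 + config$cell_mismatch[cells]))
  next_state <- if (config$dem_enabled) (dem_state + 1) %% ncell else dem_state
  list(current = current, next_dem_state = next_state, cells = cells)
}

#' One clock period of the integration node
#'
#' Charge conservation on the photodiode node: the photocurrent discharges
#' it, the I-DAC (at its nominal code current) recharges it when an
#' injection is gated.
#'
#' @param v_pd Node voltage, volts.
#' @param i_in Input (photo)current, amperes.
#' @param inject 0/1 injection gate.
#' @param code Active DAC code.
#' @param config A [cdc_config()].
#' @param dt Period, seconds (one clock period).
#' @return Updated node voltage, volts.
#' @export
node_step <- function(v_pd, i_in, inject, code, config = cdc_config(),
                      dt = config$t_clk) {
  v_pd + (inject * idac_current(code, config) - i_in) * dt / config$c_total
}

#' State-machine timing for one conversion
#'
#' Defines the active portion of a measurement cycle relative to the input
#' waveform's time origin: a wake-up interval (loop running, counter gated
#' off), the Count1 window, an uncounted gap (e.g. the skipped start of the
#' decay), and the Count2 window. Before `t_start` the node is held at the
#' Idle preset `v_ref`.
#'
#' @param count1_s,count2_s Counted window durations, seconds.
#' @param code1,code2 DAC codes used during (wake-up + Count1 + gap) and
#'   Count2 respectively.
#' @param wakeup_s Comparator-on, counter-off interval before Count1.
#' @param gap_s Uncounted interval between the windows.
#' @param t_start Waveform time at which the loop wakes, seconds.
#' @return Object of class `conversion_schedule`.
#' @export
conversion_schedule <- function(count1_s, count2_s, code1, code2,
                                wakeup_s = 0.5e-6, gap_s = 0, t_start = 0) {
  stopifnot(count1_s > 0, count2_s > 0, wakeup_s >= 0, gap_s >= 0,
            t_start >= 0)
  structure(list(wakeup_s = wakeup_s, count1_s = count1_s, gap_s = gap_s,
                 count2_s = count2_s, code1 = as.integer(code1),
                 code2 = as.integer(code2), t_start = t_start),
            class = "conversion_schedule")
}

#' Schedule matching a film excitation profile
#'
#' Count1 spans the post-stabilization excitation window `t1`; the gap skips
#' `[LED-off, LED-off + t_d_sen]`; Count2 spans the decay window. The loop
#' wakes `wakeup_s` before Count1 (clipped to the available stabilization
#' time), modeling the start-up at the tail of the LED-on state.
#'
#' @param excitation An [excitation_profile()].
#' @inheritParams conversion_schedule
#' @return A [conversion_schedule()].
#' @export
film_schedule <- function(excitation, code1, code2, wakeup_s = 0.5e-6) {
  wake <- min(wakeup_s, excitation$t_stabilize)
  conversion_schedule(count1_s = excitation$t1,
                      count2_s = excitation$t_d_ref - excitation$t_d_sen,
                      code1 = code1, code2 = code2,
                      wakeup_s = wake, gap_s = excitation$t_d_sen,
                      t_start = excitation$t_stabilize - wake)
}

#' Schedule for the bench characterization protocol
#'
#' Two counted windows applied back-to-back to a test current, as in the
#' constant-current characterization where the Count1:Count2 duration ratio
#' sets the expected count ratio. The wake-up interval defaults to zero: a
#' constant bench current has no settling transient to ride out.
#'
#' @inheritParams conversion_schedule
#' @return A [conversion_schedule()].
#' @export
bench_schedule <- function(count1_s, count2_s, code1, code2,
                           wakeup_s = 0, gap_s = 0) {
  conversion_schedule(count1_s, count2_s, code1, code2,
                      wakeup_s = wakeup_s, gap_s = gap_s, t_start = 0)
}

#' Run one clock-cycle-accurate conversion
#'
#' Simulates the charge-balancing loop over one measurement cycle: at every
#' clock edge the comparator compares the node voltage against `v_ref`, and
#' its latched decision gates the I-DAC during the following period; the
#' counter accumulates injections inside each counted window. The input
#' charge per period is taken from the waveform's closed-form integral, so
#' the update is exact at any clock frequency.
#'
#' Reconstructed charges use the count identity `Q_hat = CNT * I_DAC(code) *
#' T_clk`. `lr_hat` is the reconstructed-charge ratio `q1_hat/q2_hat`, which
#' equals the raw count ratio `cnt1/cnt2` whenever both windows share one
#' code; both are reported.
#'
#' @param waveform A `cdc_waveform` (see [constant_current_factory()],
#'   [film_waveform_factory()]).
#' @param schedule A [conversion_schedule()].
#' @param config A [cdc_config()].
#' @param seed Optional integer seed for the stochastic comparator elements.
#' @param preset_windows Re-bias the node to `v_ref` (dropping the pending
#'   latched decision) at the start of each counted window, so a window's
#'   charge balance is independent of the loop state carried over from the
#'   preceding phase. `FALSE` keeps the node state continuous across phase
#'   boundaries.
#' @param trace Keep the per-period node voltage / injection trace?
#' @return Object of class `conversion_result` with counts, reconstructed
#'   charges, `lr_hat`, `count_ratio`, codes, per-window true input charge
#'   (`q_in1`, `q_in2`), overload (saturation) fractions and warnings, DEM
#'   cell activation counts, and (optionally) the trace.
#' @examples
#' wf <- constant_current_factory(test_current_spec(list(c(30e-6, 1e-6))))()
#' sch <- bench_schedule(30e-6, 1e-6, code1 = 4, code2 = 4, wakeup_s = 0)
#' run_conversion(wf, sch, cdc_config(comparator = ideal_comparator()))
#' @export
run_conversion <- function(waveform, schedule, config = cdc_config(),
                           seed = NULL, preset_windows = TRUE,
                           trace = FALSE) {
  stopifnot(inherits(waveform, "cdc_waveform"),
            inherits(schedule, "conversion_schedule"),
            inherits(config, "cdc_config"))
  if (!is.null(seed)) set.seed(seed)
  dt <- config$t_clk
  n_wake <- round(schedule$wakeup_s / dt)
  n1 <- round(schedule$count1_s / dt)
  n_gap <- round(schedule$gap_s / dt)
  n2 <- round(schedule$count2_s / dt)
  if (n1 < 1 || n2 < 1)
    stop("counted windows must span at least one clock period", call. = FALSE)
  n <- n_wake + n1 + n_gap + n2
  if (schedule$t_start + n * dt > waveform$span + dt / 2)
    stop(sprintf(
      "schedule runs to %g us but the waveform spans only %g us",
      (schedule$t_start + n * dt) * 1e6, waveform$span * 1e6),
      call. = FALSE)
  window <- c(rep.int(0L, n_wake), rep.int(1L, n1),
              rep.int(0L, n_gap), rep.int(2L, n2))
  code <- c(rep.int(schedule$code1, n_wake + n1 + n_gap),
            rep.int(schedule$code2, n2))
  edges <- schedule$t_start + dt * (0:n)
  q_in <- waveform_charge(waveform, edges[-(n + 1)], edges[-1])

  cmp <- config$comparator
  k <- cdc_kernel(q_in, window, code, dt, config$c_total, config$v_ref,
                  config$v_ref, cmp$offset, cmp$noise_rms,
                  cmp$kickback_charge_rms, config$switch_injection_charge,
                  config$i_dac_lsb, config$cell_mismatch,
                  config$dem_enabled, 0L, config$counter_bits,
                  isTRUE(preset_windows), trace)
  if (k$overflow_window > 0)
    stop(sprintf("counter overflow (>= 2^%d) in Count%d window",
                 config$counter_bits, k$overflow_window), call. = FALSE)

  q1_hat <- k$cnt1 * idac_current(schedule$code1, config) * dt
  q2_hat <- k$cnt2 * idac_current(schedule$code2, config) * dt
  i1 <- n_wake + 1
  q_in1 <- sum(q_in[seq.int(i1, i1 + n1 - 1)])
  i2 <- n_wake + n1 + n_gap + 1
  q_in2 <- sum(q_in[seq.int(i2, i2 + n2 - 1)])

  res <- structure(list(
    cnt1 = k$cnt1, cnt2 = k$cnt2,
    q1_hat = q1_hat, q2_hat = q2_hat,
    lr_hat = if (k$cnt2 > 0) q1_hat / q2_hat else NA_real_,
    count_ratio = if (k$cnt2 > 0) k$cnt1 / k$cnt2 else NA_real_,
    code_used = c(code1 = schedule$code1, code2 = schedule$code2),
    q_in1 = q_in1, q_in2 = q_in2,
    q_act1 = k$q_act1, q_act2 = k$q_act2,
    saturation = c(count1 = k$sat1, count2 = k$sat2),
    saturation_warning = c(count1 = k$sat1 > 0.1, count2 = k$sat2 > 0.1),
    v_end = k$v_end, cell_use = k$cell_use,
    n_periods = c(wakeup = n_wake, count1 = n1, gap = n_gap, count2 = n2),
    seed = seed), class = "conversion_result")
  if (trace) {
    res$vpd_trace <- data.frame(
      time_s = schedule$t_start + dt * seq_len(n),
      v_pd_V = k$v_trace, inject = k$inj_trace,
      window = window)
  }
  res
}

#' @export
print.conversion_result <- function(x, ...) {
  cat("Conversion result\n")
  cat(sprintf("  CNT1 = %d (code %d), CNT2 = %d (code %d)\n",
              as.integer(x$cnt1), x$code_used[["code1"]],
              as.integer(x$cnt2), x$code_used[["code2"]]))
  cat(sprintf("  Q1_hat = %.6g pC (true %.6g), Q2_hat = %.6g pC (true %.6g)\n",
              x$q1_hat * 1e12, x$q_in1 * 1e12,
              x$q2_hat * 1e12, x$q_in2 * 1e12))
  cat(sprintf("  LR_hat = %.5g (count ratio %.5g)\n",
              x$lr_hat, x$count_ratio))
  if (any(x$saturation_warning))
    cat(sprintf("  warning: injection overload in %s\n",
                paste(names(x$saturation_warning)[x$saturation_warning],
                      collapse = ", ")))
  invisible(x)
}

#' Recover the sensitive/reference photocurrent ratio from counts
#'
#' Inverts the count identity of the ratiometric measurement:
#' `I_sen/I_ref = (cnt1/cnt2) * tau_ref / t1 - 1`.
#'
#' @param cnt1,cnt2 Window counts (same DAC code assumed).
#' @param t1 Excitation window, seconds.
#' @param tau_ref Reference lifetime, seconds.
#' @return Dimensionless photocurrent ratio; `-1` (with a warning) when
#'   `cnt1 = 0`.
#' @export
intensity_ratio_from_counts <- function(cnt1, cnt2, t1, tau_ref) {
  if (any(cnt2 == 0))
    stop("cnt2 = 0: decay charge unmeasurable, ratio undefined",
         call. = FALSE)
  out <- (cnt1 / cnt2) * (tau_ref / t1) - 1
  if (any(cnt1 == 0))
    warning("cnt1 = 0: degenerate measurement, ratio pinned at -1")
  out
}
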
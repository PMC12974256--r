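# Shared fixtures: an ideal-comparator converter at the nominal operating
# point, and small builders used across the test files.

ideal_cfg <- function(...) {
  cdc_config(comparator = ideal_comparator(), ...)
}

# single counted window of a constant current; token Count2 of one period
single_window_schedule <- function(window_s, code, config) {
  conversion_schedule(count1_s = window_s, count2_s = config$t_clk,
                      code1 = code, code2 = code, wakeup_s = 0)
}

constant_waveform <- function(current_A, span_s, dark = 0) {
  constant_current_factory(
    test_current_spec(list(c(span_s, current_A)), dark_current = dark))()
}

quantum <- function(code, config) code * config$i_dac_lsb * config$t_clk

# minimal covering code with the default 1.25 headroom
covering_code <- function(current_A, config, headroom = 1.25) {
  min(max(ceiling(headroom * current_A / config$i_dac_lsb), 1),
      config$code_max)
}
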
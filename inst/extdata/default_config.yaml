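# Default simulator configuration. All photophysical constants are a
# synthetic calibration (the commercial film's Stern-Volmer constant is not
# public); converter parameters are the characterized hardware values.
film:
  k_sv: 0.05          # 1/mmHg, synthetic
  tau_sen: 100 ns
  tau_ref: 1 us
  s_sen: 500 nA       # photocurrent per excitation unit
  s_ref: 500 nA
excitation:
  i_ext: 1
  t_stabilize: 10 us
  t1: 30 us
  t_d_sen: 50 ns
  t_d_ref: 6 us
cdc:
  f_clk: 320 MHz
  c_pd: 3 pF
  c_parasitic: 0.2 pF
  v_ref: 800 mV
  i_dac_lsb: 500 nA
  n_dac_bits: 4
  counter_bits: 16
  dem_enabled: true
  switch_injection_charge: 0 C
comparator:
  offset: 25 mV
  noise_rms: 0.28 mV
  kickback_charge_rms: 0 C
scaling:
  n_average_cycles: 100
  headroom: 1.25
  lut_mode: per_window
  duty_cycle: 0.01
  quantization_target: 0.005
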
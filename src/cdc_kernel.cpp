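#include <Rcpp.h>
using namespace Rcpp;

// Clock-cycle core of the charge-balancing conversion loop.
//
// One iteration per clock period. The comparator samples the node voltage at
// the period's leading edge; its decision gates the I-DAC during the *next*
// period (latched comparator, one-period loop delay). The counter increments
// on every injection that falls inside a counted window.
//
// q_in[k]   input (photocurrent) charge drained from the node in period k [C]
// window[k] 0 = active but not counted, 1 = Count1, 2 = Count2
// code[k]   DAC code active in period k (0..2^nbits-1)
//
// The thermometer cells are rotated by the barrel shifter one position per
// injection event, so consecutive injections walk the array and cell
// mismatch averages toward the array mean.
//
// Uses R's RNG (GetRNGstate handled by Rcpp attributes); draws are consumed
// only when noise_rms/kick_rms are non-zero, so ideal runs are deterministic.
// [[Rcpp::export]]
List cdc_kernel(NumericVector q_in, IntegerVector window, IntegerVector code,
                double dt, double c_total, double v_ref, double v_start,
                double offset, double noise_rms, double kick_rms,
                double q_switch, double lsb, NumericVector mismatch,
                bool dem, int dem_start, int counter_bits,
                bool preset_windows, bool trace) {
  const int n = q_in.size();
  const int ncell = mismatch.size();
  const long cnt_max = (1L << counter_bits);

  long cnt[3] = {0, 0, 0};
  long nwin[3] = {0, 0, 0};
  long nsat[3] = {0, 0, 0};
  double q_act[3] = {0.0, 0.0, 0.0};

  IntegerVector cell_use(ncell);
  NumericVector v_trace(trace ? n : 0);
  IntegerVector inj_trace(trace ? n : 0);

  double v = v_start;
  int ptr = dem_start % ncell;
  int inj_next = 0;   // injection scheduled for the current period
  int inj_prev = 0;   // injection state of the previous period
  int overflow_window = 0;

  for (int k = 0; k < n; ++k) {
    const int w = window[k];
    const int c = code[k];

    // re-bias the node at each counted-window start; the pending latched
    // decision is dropped so the window opens with a clean loop state
    if (preset_windows && w > 0 && k > 0 && window[k - 1] != w) {
      v = v_ref;
      inj_next = 0;
      inj_prev = 0;
    }

    // comparator decision at edge k (gates period k+1)
    double noise = (noise_rms > 0.0) ? R::rnorm(0.0, noise_rms) : 0.0;
    const int dec = (v + offset + noise < v_ref) ? 1 : 0;

    const int inj = inj_next;
    double q_dac = 0.0;
    if (inj && c > 0) {
      double cur = 0.0;
      for (int j = 0; j < c; ++j) {
        const int cell = (ptr + j) % ncell;
        cur += lsb * (1.0 + mismatch[cell]);
        cell_use[cell]++;
      }
      if (dem) ptr = (ptr + 1) % ncell;
      q_dac = cur * dt;
    }

    // switch charge injection on I-DAC turn-off (residual after dummy cancel)
    if (inj_prev == 1 && inj == 0 && q_switch != 0.0) v += q_switch / c_total;

    v += (q_dac - q_in[k]) / c_total;
    if (kick_rms > 0.0) v += R::rnorm(0.0, kick_rms) / c_total;

    if (w > 0) {
      nwin[w]++;
      if (inj) {
        cnt[w]++;
        q_act[w] += q_dac;
        if (cnt[w] >= cnt_max) { overflow_window = w; break; }
      }
      // overload: node more than one injection quantum below threshold
      const double quantum_v = (c > 0 ? c : 1) * lsb * dt / c_total;
      if (v < v_ref - offset - quantum_v) nsat[w]++;
    }

    if (trace) { v_trace[k] = v; inj_trace[k] = inj; }
    inj_prev = inj;
    inj_next = dec;
  }

  return List::create(
    _["cnt1"] = (double)cnt[1], _["cnt2"] = (double)cnt[2],
    _["n1"] = (double)nwin[1], _["n2"] = (double)nwin[2],
    _["sat1"] = nwin[1] > 0 ? (double)nsat[1] / nwin[1] : 0.0,
    _["sat2"] = nwin[2] > 0 ? (double)nsat[2] / nwin[2] : 0.0,
    _["q_act1"] = q_act[1], _["q_act2"] = q_act[2],
    _["v_end"] = v, _["dem_ptr"] = ptr,
    _["cell_use"] = cell_use,
    _["overflow_window"] = overflow_window,
    _["v_trace"] = v_trace, _["inj_trace"] = inj_trace);
}
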
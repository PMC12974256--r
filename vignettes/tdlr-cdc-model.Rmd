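---
title: "Modeling a t-DLR luminescence readout and its current-to-digital converter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling a t-DLR luminescence readout and its current-to-digital converter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumicdc)
```

## The measurement problem

Transcutaneous CO2 monitoring with a luminescent sensing film reads out the
partial pressure of CO2 from the emission of two co-immobilized
luminophores. A CO2-sensitive fluorophore is quenched according to the
Stern-Volmer relation,

$$ \frac{I_{SEN,0}}{I_{SEN}} = 1 + K_{SV}\,p_{CO_2}, $$

while a phosphorescent reference with a much longer lifetime
($\tau_{REF}$ in microseconds versus $\tau_{SEN}$ in nanoseconds) is
CO2-insensitive. Time-domain dual lifetime referencing (t-DLR) exploits
the lifetime gap: while the excitation LED is on, both luminophores emit;
a few sensitive lifetimes after it turns off, only the reference remains.
Integrating the photocurrent over an excitation window $T_1$ and over a
decay window yields two charges $Q_1 = (I_{SEN} + I_{REF})\,T_1$ and
$Q_2 \approx I_{REF}\,\tau_{REF}$, and their ratio — the luminescence
ratio

$$ LR = \left(\frac{S_{SEN}/S_{REF}}{1 + K_{SV}\,p_{CO_2}} + 1\right)
        \frac{T_1}{\tau_{REF}} $$

is independent of the excitation intensity, which cancels between
numerator and denominator. `luminescence_ratio()` and `pco2_from_lr()`
implement this model and its closed-form inverse.

The converter digitizes the two charges directly: the photodiode's
junction capacitance integrates the photocurrent, a clocked latch
comparator watches the node against a reference voltage, and its decision
gates a thermometer-coded current DAC that injects one quantum
$I_{DAC}\,T_{CLK}$ of charge per clock period. A 16-bit counter
accumulates injections per window, so $Q_k = CNT_k \cdot I_{DAC}\,T_{CLK}$
with no transimpedance amplifier in the path. `run_conversion()`
simulates this loop clock cycle by clock cycle.

## Model structure and key assumptions

**Intensities are photocurrents.** Optical collection efficiency and
photodiode responsivity are folded into the responsivities
$S_{SEN}, S_{REF}$, so film "intensities" carry ampere units throughout.

**Rise dynamics.** During LED-on each luminophore approaches its steady
photocurrent as a first-order exponential with its own lifetime. This is
the simplest model consistent with the stated lifetimes and with a film
response that stabilizes within 10–15 µs; the default profile waits
`t_stabilize = 10 µs` before the counted window opens. A consequence is
that the plateau is reached only to about $e^{-t_{stab}/\tau_{REF}}$
(~$10^{-4}$ relative), so the closed-form areas and the waveform window
integrals agree to ~$10^{-4}$, not machine precision; tests account for
this residual explicitly and the exact window integrals are available via
`waveform_charge()`.

**Exact per-period input charge.** The loop update uses the waveform's
closed-form integral over each clock period rather than sub-stepping, so
results are exact at any clock frequency with no time-step convergence
concerns.

**Latched comparator.** The decision sampled at clock edge $k$ gates the
injection during period $k+1$ — one period of loop delay, the inherently
stable first-order behavior of a latch-based modulator. Behavioral
nonidealities are a static offset (default 25 mV, the post-layout
characterization value), Gaussian input-referred noise (0.28 mVrms)
redrawn per decision, and an optional zero-mean kickback charge per
decision. Residual switch charge injection (after dummy-transistor
cancellation) is a per-turn-off charge parameter, default 0.

**Node preset at window starts.** The idle state biases the node to
$V_{REF}$. In this simulator the node is additionally re-biased to
$V_{REF}$ at the start of *each counted window* (and the pending latched
decision is dropped). The reason is numerical hygiene of the per-window
codes: without it, the Count2 window inherits the voltage limit-cycle
state of the preceding larger-code phase, which is worth several
small-code quanta and would make the window error depend on an
uncontrolled phase relationship. With the preset, each window's
reconstruction error is bounded by roughly two of its own quanta, the
charge-balance ledger closes exactly, and the comparator-offset charge
error $C_{tot}\,\Delta V_{off}$ appears in every counted window, matching
the analytic model. The physical, carry-over behavior remains available
via `run_conversion(preset_windows = FALSE)`.

**Dynamic element matching.** The barrel shifter rotates the active arc
of unit cells by one position per injection event, so consecutive
injections walk the array and cell mismatch averages toward the array
mean. Per-cell usage is uniform within one activation over complete
rotations; mid-rotation the spread is bounded by the arc length (the
code). Note that the converter's gain is referenced to the array-average
cell current: a mismatch vector with non-zero mean is a gain error that
no rotation can remove.

## Error budget

The loop resolves each window to one injection quantum, so the relative
conversion errors are

$$ \epsilon_1 = \frac{I_{DAC}(c_1)\,T_{CLK}}{Q_1}, \qquad
   \epsilon_2 = \frac{I_{DAC}(c_2)\,T_{CLK}}{Q_2}, $$

with $\epsilon_2$ dominant because $Q_2 \ll Q_1$ (microseconds of decay
versus tens of microseconds of excitation). `error_vs_fclk_sweep()`
evaluates this analytic model and, in `loop_sim` mode, the full simulator;
the two agree within a factor of two across 80–640 MHz, and at the
320 MHz operating clock the total error is ≈0.31%, inside the 0.5%
design target that motivates that clock choice. Because the latched loop
can end a window one quantum above threshold plus a partial-period drain,
the simulated error can slightly exceed one quantum; the package
documents (and tests) a two-quantum reconstruction bound, while the
conservation form of the charge balance — counted injected charge minus
input charge minus $C_{tot}\,\Delta V$ — closes to machine precision.

The comparator offset contributes a charge error
$\epsilon_Q = C_{tot}\,\Delta V_{off}$ (75 fC at 3 pF and 25 mV), best
read as an equivalent decay-phase current $\epsilon_I = \epsilon_Q/\tau$
(75 nA at 1 µs) — which is why the offset matters most for
sub-microampere photocurrents. It is a DC error, removable in
post-processing. Input-referred noise is recovered by the
decision-probability sweep procedure (`comparator_noise_sweep()` plus a
probit fit); kickback is zero-mean and leaves no net charge error over an
integration window.

## The current-scaling controller

A measurement starts with one scaling cycle at full DAC scale; the
resulting counts estimate each window's mean current, and
`select_dac_code()` picks the smallest code whose current covers 1.25×
that estimate (the headroom default). The code is held for 100 cycles
(`n_average_cycles`), whose counts are averaged. Smaller codes mean
smaller quanta, hence smaller $\epsilon_k$, at low photocurrents — the
reason scaling extends the usable dynamic range downward. The look-up
table of the hardware is not public; the minimal-covering-with-headroom
rule guarantees loop balance while minimizing the quantum, and the
headroom absorbs the one-count truncation of the full-scale estimate.

Two open choices were resolved as follows. Codes are selected *per
window* by default (`lut_mode = "per_window"`), since the two windows'
errors are independent and the decay window benefits most from a small
code; a `"shared"` mode is available. The decay-window length is not
printed by the hardware description; the default spans 50 ns to
6 µs ($6\,\tau_{REF}$) after LED-off, late enough to skip the fast
residual, long enough to capture ≈99.5% of the reference decay.

During a Count2 window opened with a small code, the early decay current
can exceed the code current; the integrator remembers the deficit and the
loop catches up as the decay falls, so the count total is still correct.
The per-window overload fraction is reported, with a warning flag when
the node spends more than 10% of a window more than one quantum below
threshold.

`lr_hat` is defined as the reconstructed-charge ratio
$\hat Q_1/\hat Q_2$, which equals the raw count ratio whenever both
windows share a code (the bench protocol); with per-window codes the raw
count ratio alone is not the luminescence ratio, so both are reported.

## CO2 inversion for measured ratios

Counting over a *finite* decay window measures
$Q_2 = I_{REF}\tau_{REF}(e^{-T_{dsen}/\tau_{REF}} -
e^{-T_{dref}/\tau_{REF}}) + (\text{sensitive residual})$, about 4–5%
below the idealized $I_{REF}\,\tau_{REF}$. Inverting a measured LR
through the idealized model would bias the CO2 estimate by tens of mmHg
at the top of the range, so `luminescence_ratio()`/`pco2_from_lr()` offer
an `"exact"` mode using the window integrals; the LR is then a Möbius
function of $1/(1+K_{SV}p)$ and inverts in closed form. The CO2 sweep
driver uses the exact mode and lands within one bench grid step
(3.8 mmHg) of truth at every point with an ideal comparator.

## Synthetic study conditions

No external data exist for this simulator; the fixtures module generates
the two signal classes the bench used. The defaults are the study
conditions: both photocurrents 500 nA at zero CO2 ($S_{SEN} = S_{REF} =$
500 nA per excitation unit), $\tau_{SEN} = 100$ ns, $\tau_{REF} = 1$ µs,
$T_1 = 30$ µs, 500 nA DAC LSB, 320 MHz clock, 3 pF + 0.2 pF node
capacitance, 25 mV / 0.28 mVrms comparator, 100-cycle holds, 1% duty
cycle, 10 pA dark current, CO2 from 0 to 76 mmHg in 3.8 mmHg steps.
$K_{SV}$ is proprietary to the commercial film and never printed; the
synthetic calibration uses 0.05 /mmHg, a mid-range optode value, and is
labeled synthetic wherever it appears. The LED-intensity jitter fixture
(uniform ±10% per cycle) emulates excitation fluctuation; it rescales a
cycle's waveform uniformly, which is exactly the perturbation t-DLR
cancels. What passing tests consequently do *not* show: robustness to
photobleaching drift, temperature/humidity sensitivity of the
responsivities, ambient-light leakage, or any real film's deviation from
single-exponential kinetics — none of which are modeled.

## Numerical choices and problem sizes

Window durations are rounded to whole clock periods. Ideal-comparator
runs consume no random numbers and are bit-reproducible; stochastic
elements draw from R's RNG, seeded per call, and waveform factories carry
private RNG streams so interleaved factories with equal seeds generate
identical cycle sequences. The test suite exercises one full conversion
(~10⁴ clock periods) per case, 100-cycle averaged measurements where the
averaging procedure itself is under test, 100 randomized charge-balance
configurations, and a 31-point × 1000-trial noise-recovery sweep; the
CO2 sweep tests use a coarse 5-point grid with 2 excitation levels.
These sizes were chosen so every statistical check has comfortable margin
while a full run of the suite stays in the tens of seconds.

## Known limitations

The simulator is behavioral: no transistor-level effects (metastability,
finite regeneration, cascode headroom), no VCO phase noise (the clock is
ideal), no power model (the duty-cycle report is bookkeeping only), and
the input range tops out at the 7.5 µA full-scale DAC current — the
hardware extends range by retuning the unit-cell bias, which is
abstracted into `i_dac_lsb`. Hardware-measured figures (power, die area,
measured resolution and dynamic range) are outside what a behavioral
model can reproduce; the package computes the same *metrics* for its own
configurations instead.
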
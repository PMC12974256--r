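# lumicdc

Clock-cycle-accurate behavioral simulation of a luminescence-based
transcutaneous CO2 readout: the time-domain dual-lifetime-referencing
(t-DLR) photophysics of a dual-luminophore sensing film, and the direct
current-to-digital converter (CDC) that digitizes its photocurrent without
a transimpedance amplifier.

The package is for mixed-signal and biomedical-instrumentation engineers
who want to exercise the architecture's accuracy claims on synthetic
signals: quantization versus clock frequency, comparator offset/noise
budgets, dynamic-element-matched current-DAC behavior, and the current
scaling algorithm that preserves accuracy at sub-microampere
photocurrents.

## The model in brief

A CO2-sensitive fluorophore is quenched per Stern-Volmer,
`I_SEN = I_EXT S_SEN / (1 + K_SV p)`, while a long-lifetime phosphorescent
reference is CO2-independent. Integrating the film photocurrent over the
excitation window `T1` and over a decay window after LED turn-off gives
charges `Q1 = (I_SEN + I_REF) T1` and `Q2 ≈ I_REF τ_REF`, whose ratio

    LR = (S_SEN/S_REF · 1/(1 + K_SV·p) + 1) · T1/τ_REF

cancels the excitation intensity and inverts in closed form to the CO2
partial pressure.

The converter balances the photocurrent on the photodiode's own junction
capacitance: a latched comparator watches the node against `V_REF` and
gates a thermometer-coded current DAC, one charge quantum
`I_DAC · T_CLK` per clock period; a 16-bit counter accumulates injections
per window so `Q_k = CNT_k · I_DAC · T_CLK`. A scaling controller runs one
full-scale cycle, picks the smallest DAC code covering each window's
current with 1.25× headroom, and averages counts over a 100-cycle hold.
The per-window conversion error is one injection quantum relative to the
window charge — `ε_k = I_DAC(c_k)·T_CLK / Q_k` — plus a comparator offset
charge `ε_Q = C_tot·ΔV_off` (75 fC at 3 pF, 25 mV), equivalent to
`ε_I = ε_Q/τ` = 75 nA of decay-phase current at τ = 1 µs.

## Worked example

Measure a film at 40 mmHg CO2 through the full pipeline — scaling cycle,
code selection, 100-cycle averaged conversion, CO2 inversion:

```r
library(lumicdc)
cfg <- cdc_config(comparator = ideal_comparator())
fm  <- film_params()          # synthetic calibration, K_SV = 0.05 /mmHg
exc <- excitation_profile()   # T1 = 30 us, decay window 50 ns - 6 us

m <- measure_lr(film_waveform_factory(40, fm, exc),
                function(c1, c2) film_schedule(exc, c1, c2),
                cfg, scaling_config())
print(m)
#> LR measurement
#>   scaling cycle: CNT1' = 854, CNT2' = 22 -> codes (2, 1)
#>   100-cycle hold: CNT1 = 6400.00, CNT2 = 311.00
#>   LR = 41.158 (count ratio 20.579)

pco2_from_lr(m$lr, fm, exc, mode = "exact")
#> [1] 40.78554
```

The scaling cycle's full-scale counts (854 and 22) estimate the mean
window currents; the controller drops the DAC codes to 2 and 1, shrinking
the charge quantum 7.5× and 15×. The averaged counts reconstruct the
window charges, whose ratio (41.16) inverts to 40.8 mmHg — within a
single count quantum of the true 40 mmHg setting. The
`vignettes/tdlr-cdc-model.Rmd` vignette documents the model, its
assumptions, and every default.

A command-line harness over the same functions ships in
`inst/cli/lumicdc.R` (subcommands `simulate`, `sweep-current`,
`sweep-lr-error`, `sweep-fclk`, `sweep-pco2`, `error-budget`,
`schedule`), e.g.:

    Rscript "$(Rscript -e 'cat(system.file("cli/lumicdc.R", package="lumicdc"))')" \
        sweep-pco2 --seed 1 --out results/

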
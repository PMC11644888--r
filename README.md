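# capblink

Blink detection and fatigue scoring from capacitive eyewear recordings.

An electrode glued to an eyeglass frame forms a capacitor with the head as
the opposite plate. Placed in an RLC tank, its capacitance is read out as a
resonance frequency

f<sub>x</sub> = 1 / (2π √(L (C + C<sub>x</sub>))),

and because the eyelid (relative permittivity near 100, like any water-rich
tissue) raises the sensed capacitance C<sub>x</sub> when it slides in front
of the electrode, every blink appears as a transient dip in f<sub>x</sub>.
Unlike camera-based drowsiness monitoring this works in the dark and
records no images. `capblink` implements the full processing chain for
such recordings, with a physics-based synthetic generator standing in for
the hardware so the chain is testable end to end:

1. **Forward model** — closed-form open/closed-eye capacitance of the
   air / eyelid / tissue dielectric stack and the tank resonance frequency.
2. **Synthesis** — labelled recordings with raised-cosine lid kinematics,
   white noise, baseline drift and sampling jitter; labelled per-window
   feature datasets.
3. **Pre-processing** — Gaussian-weight interpolation of jittered samples
   onto a uniform grid, then a zero-phase Butterworth band-pass to the
   human blink band [2.0, 5.5] Hz (order 128, realized as second-order
   sections).
4. **Detection** — robust-rescaled derivative, threshold 4.0 with fused
   amplitude/duration confidence, per-event closing and opening phase
   durations, 40 s / 2 s sliding-window features (closing, opening, idle
   time).
5. **Fatigue scoring** — FSAS questionnaire totals (10–50), and a 3-5-1
   backpropagation network mapping blink features to the fatigue scale,
   evaluated by 100% minus mean absolute relative error.

Everything is tibble-in / tibble-out and pipe-friendly, with `autoplot()`,
`tidy()` and `glance()` methods for the result types.

## Worked example

Simulate the benchmark scenario — ten blinks in 40 s under the "bench"
noise preset — and run the whole chain:

```r
library(capblink)

report <- run_pipeline(default_config())
report
#> <capblink_report>
#>   simulate     4000 samples, 10 scheduled blinks, noise 'bench'
#>   interpolate  grid period 0.01 s, 4000 points
#>   bandpass     order 128, band [2, 5.5] Hz
#>   detect       10 events above threshold 4
#>   features     1 windows of 40 s
#>   fatigue      hold-out accuracy 96.16%

report$events
#> # A tibble: 10 x 4
#>   onset_s closing_s opening_s confidence
#>     <dbl>     <dbl>     <dbl>      <dbl>
#> 1    2.02     0.130     0.240       5.02
#> 2    6.02     0.120     0.250       5.13
#> 3   10.0      0.120     0.250       5.18
#> # i 7 more rows
```

All ten scheduled blinks (onsets 2, 6, ..., 38 s) are recovered within a
few hundredths of a second, with phase durations close to the scheduled
0.15 s closing / 0.25 s opening. Per-window features and the fatigue scale
predicted by the trained network:

```r
report$features
#> # A tibble: 1 x 5
#>   window_start_s closing_s opening_s idle_s count
#>            <dbl>     <dbl>     <dbl>  <dbl> <int>
#> 1              0     0.125     0.248   3.63    10

report$fatigue$per_window
#> # A tibble: 1 x 2
#>   window_start_s scale
#>            <dbl> <dbl>
#> 1              0  20.0
```

A scale of 20 on the 10–50 FSAS range is mildly fatigued — consistent with
short blinks and a ~3.6 s inter-blink interval. The physics underneath:

```r
m <- eye_model()
c(closed = capacitance_closed(m), open = capacitance_open(m),
  ratio = capacitance_ratio(m))
#>       closed         open        ratio
#> 3.212986e-13 2.723624e-13 1.179673e+00
```

Closing the eye raises the sensed capacitance by ~18%, which with the
default 18 µH / 33 pF tank lowers the ~6.5 MHz resonance by ~4.8 kHz — the
dip the detector looks for.

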
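---
title: "Methods: capacitive blink detection and fatigue scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: capacitive blink detection and fatigue scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capblink)
```

## The sensing physics

An eyewear-mounted copper-foil electrode close to the eye forms one plate of
a capacitor whose other plate is the effective ground through the head. That
capacitance sits in an RLC tank, so the quantity actually measured is the
tank's resonance frequency

$$f_x = \frac{1}{2\pi\sqrt{L\,(C + C_x)}},$$

which decreases monotonically in the sensed capacitance $C_x$. The dielectric
between the plates is modelled as a stack of parallel layers in series. With
the eye closed the stack is air gap / eyelid / remaining tissue:

$$C_x = \frac{S}{4\pi k\left(\frac{d_1}{\epsilon_1} + \frac{d_2}{\epsilon_2} +
\frac{d_3}{\epsilon_3}\right)},$$

and with the eye open the eyelid leaves the gap, its position filled by air:

$$C_x' = \frac{S}{4\pi k\left(\frac{d_1 + d_2}{\epsilon_1} +
\frac{d_3}{\epsilon_3}\right)}.$$

Because water-rich tissue has a relative permittivity near 100 while air has
1, $C_x > C_x'$ whenever the lid is present, so every blink is a transient
*dip* in the resonance frequency. `capacitance_closed()`,
`capacitance_open()`, `capacitance_ratio()` and `resonance_frequency()`
implement these closed forms; the test suite checks them against the
independent route of combining per-layer capacitors in series, at relative
tolerance $10^{-12}$ over a thousand random stacks.

Units are SI throughout, with $k = 8.99\times 10^9\,\mathrm{N\,m^2/C^2}$.
The eyelid permittivity defaults to 100. The default geometry
($d_1 = 5$ mm air gap, $d_2 = 1$ mm lid, $d_3 = 50$ mm tissue,
$S = 25\,\mathrm{mm}\times 8\,\mathrm{mm}$) is a plausible eyewear
configuration, not a measured one, and every element is configurable. With
the default 18 µH / 33 pF tank it puts the carrier near 6.5 MHz with a blink
dip of roughly 4.8 kHz — the physics fixes only the *ratio* of open to closed
frequency, and the pipeline never depends on the absolute carrier scale.

## The synthetic-data generator

`generate_recording()` is the package's ground-truth instrument. Lid motion
is modelled per scheduled blink as a raised-cosine descent (closing), a hold
at full closure, and a raised-cosine ascent (opening); the frequency trace
interpolates between the open- and closed-eye resonance frequencies of the
configured physics. Raised cosines were chosen because lid kinematics are
smooth; square edges would inject broadband energy that no real lid
produces. Default kinematics are 0.15 s closing, 0.08 s hold, 0.25 s
opening, inside the 0.2–0.4 s range of normal human blinks, and the default
sampling rate is 100 Hz, which resolves the fastest phase with about 15
samples while keeping the 5.5 Hz band edge far below Nyquist.

Noise has three components, parameterized relative to the blink dip
amplitude because the absolute carrier scale is hardware-dependent: white
Gaussian noise, a slow sinusoidal baseline drift, and Gaussian
sampling-time jitter (truncated at ±0.45 samples so timestamps stay
strictly increasing). The presets are fixed operating points: `"bench"`
(0.5% white, 2% drift over 10 s, 1 ms jitter) for a still subject,
`"driving"` (1%, 10% over 5 s) and `"walking"` (2%, 20% over 2 s) for
progressively shakier eyewear. `"none"` is exactly noiseless and is the
regime in which detector recall, precision and phase-duration recovery are
required to be perfect.

What the generator does *not* emulate: saccades, partial blinks,
hand-touch artifacts, electrode repositioning, and 1/f electronics noise.
Tests passing on this generator therefore demonstrate correctness of the
processing chain under the stated noise model, not field performance on
human subjects.

`generate_feature_dataset()` plays the same role one level up: it draws
per-window blink features from uniform ranges and labels them through a
monotone linear map (defaults: $10 + 60\,t_{close} + 40\,t_{open} -
2\,t_{idle}$, clamped to the 10–50 questionnaire range) plus Gaussian label
noise of 1.5 scale points, emulating the noisy pairing of instrumented
windows with self-assessed fatigue.

## Interpolation onto a uniform grid

Acquisition timestamps jitter, and the filter needs uniform sampling.
`gaussian_interpolate()` computes each grid value at $t = nT$ as a
Gaussian-weighted combination of samples within $\pm 3T$, with kernel
$f(t) = \tfrac{1}{\sqrt{2\pi}}\exp\!\left(-\tfrac{(t-nT)^2}{2\sigma^2}\right)$
and $\sigma = T$ by default. Two choices deserve note:

* **Weight renormalization (default on).** The plain weighted sum makes the
  output amplitude depend on how many samples happen to fall near each grid
  point, which breaks the elementary requirement that a constant signal
  interpolate to itself. Weights are therefore renormalized to sum to one
  per grid point; `normalize = FALSE` restores the plain sum for
  comparison.
* **Grid placement.** The grid keeps every point within half a period of
  the sampled span, so edge jitter cannot shave off a boundary point and
  silently shorten a 40 s recording below the 40 s window length.

Grid points with an empty truncated neighbourhood (a data gap) come back as
`NA` with a warning, and the filter refuses `NA`s rather than inventing
data.

## Band-pass filtering

Human blinks occupy roughly 2.5–5 Hz, so the pipeline's filter is a
Butterworth band-pass with passband [2.0, 5.5] Hz and order 128 by default.
A direct recursive realization of such a filter is numerically hopeless;
`butter_bandpass_sos()` therefore factors the design into second-order
sections: analog Butterworth prototype, low-pass→band-pass transform,
bilinear transform with prewarping, then pole–zero pairing (poles processed
from closest to the unit circle, each pair given the nearest available
zeros from the $z = \pm 1$ pools), sections ordered by ascending pole
radius, and each section scaled to unit gain at the band centre. Each
biquad is individually stable, and the cascade's response matches an
independent low-order design from the `signal` package to $10^{-8}$.
`bandpass()` applies the cascade forward and backward (zero phase, so
detected event times are not delayed) with odd-symmetric reflection padding
of 30 samples per section to control edge transients.

The single-pass design meets, and the test suite asserts: gain at 3.5 Hz
within [0.9, 1.1]; at least 40 dB attenuation at 0.1 Hz and 20 Hz; and
stopband gain at 1 Hz strictly decreasing over orders 4, 8, 16. A
first-order RC band-pass magnitude (`first_order_band_response()`) is
included as an analytical reference only.

One consequence of a 128th-order band-pass worth knowing: its impulse
response rings for about a second either side of each blink. The ringing is
what the refractory merge and the robust threshold (below) are designed
around.

## Blink detection

`differentiate()` takes central differences (one-sided at the edges). The
printed detection threshold of 4.0 comes with no units, and raw Hz/s would
tie it to one hardware gain; the derivative is therefore rescaled by a
robust local scale — 1.4826 × the rolling median absolute deviation over a
10 s baseline — making the threshold "4 robust scales" and transferable.
Two guards matter in practice: the rolling MAD is floored by the global
robust scale of the derivative, because running medians shrink toward zero
at the series edges and would otherwise manufacture huge spurious edge
events; and an exactly noiseless derivative (global MAD zero) falls back to
a tiny positive floor so the rescaling never divides by zero.
`rescale = FALSE` exposes raw Hz/s for instruments with a calibrated gain.

`detect_blinks()` thresholds frame by frame: maximal runs with
$|d| > \theta$ are merged across gaps shorter than the refractory, and each
candidate gets the fused confidence

$$\mathrm{conf} = \sqrt{c_{amp}\, c_{dur}}, \qquad
c_{amp} = \frac{\max|d|}{\theta}, \qquad
c_{dur} = \frac{\text{run length}}{t_{min}},$$

with $t_{min} = 0.05$ s; an event is emitted when the confidence exceeds 1.
The geometric mean is symmetric in its two factors and reduces to the bare
threshold rule when $c_{dur} = 1$ — a single marginal sample cannot fire the
detector, but either a strong or a sustained excursion can. The refractory
default is 0.35 s: a blink excites the threshold twice (closing edge,
opening edge), and for the slowest modelled kinematics (0.2 s close, 0.1 s
hold, 0.3 s open) the quiet stretch between those excursions approaches
0.31 s, while physiological inter-blink intervals are seconds long, so
0.35 s merges one blink without ever bridging two.

Phases are read off the derivative's sign structure: closing is the
contiguous negative lobe containing the candidate's most negative sample
(the frequency *falls* as the lid covers the electrode), opening is the
positive lobe that follows, and the onset is the start of the closing lobe.
Central differences smear a lobe's support one sample outward on each side,
so durations subtract one sample from the first-to-last span; on noiseless
recordings this recovers scheduled phase durations to within ±1 sample,
which the acceptance suite verifies over 100 random schedules.

`extract_features()` aggregates events per window: mean closing and opening
time, and idle time defined as the mean gap from the end of one event's
opening phase to the next event's onset. Windows with no events report
(0, 0, window length); a single-event window reports the window length
minus the event's duration, since no inter-blink gap exists. Whether idle
time should be a per-pair or per-window quantity is genuinely open; the
per-pair mean is used because it is what the inter-blink interval means
physiologically. `sliding_windows()` tiles a recording with 40 s windows
advancing 2 s (the step read as seconds: a ~260 s session then yields 111
windows per recording, the right order of magnitude for thousands of
windows over a multi-subject study).

## Fatigue scoring

The fatigue self-assessment scale (FSAS) has ten statements answered
1–5, summed to a total in [10, 50]. `score_fsas()` sums all ten
responses in the same direction by default — the source scoring rule —
although items 4 and 10 are positively worded; `reverse_items = TRUE`
applies the usual psychometric reversal and is off by default for fidelity.

`fit_fatigue_network()` is a deliberately classic backpropagation network:
3 inputs (closing, opening, idle time), one hidden layer of 5 sigmoid
neurons, one linear output neuron, trained by full-batch gradient descent
with momentum on the mean-squared error. Activations and training scheme
are not dictated by the problem, so the choices are the textbook ones for a
small "BP network": sigmoid hidden layer, z-scored features, targets mapped
to [0, 1], learning rate 0.5 with momentum 0.9, 2000 iterations (the loss
plateaus by roughly 1500 on datasets of this size). Training is
deterministic given a seed, and full-batch gradients make the fit invariant
to sample order up to floating-point round-off. Predictions are clamped to
[10, 50]; `predict()`, `tidy()`, `glance()` and `autoplot()` follow the
usual modelling-package conventions.

Accuracy is reported as 100% minus the mean absolute relative error:

$$r = \left(1 - \frac{1}{n}\sum_{i=1}^{n}
\frac{|n_i - f_i|}{f_i}\right)\times 100\%.$$

The absolute value is a deliberate choice: without it, over- and
under-predictions cancel and a biased predictor can look perfect;
`signed = TRUE` reproduces the cancelling variant for comparison. The
measure is invariant to common positive rescaling of predictions and
truths, and can be negative for very poor predictors.

`evaluate_fatigue()` shuffles samples with a seeded permutation into an
80/20 train/test split. The split ignores any subject structure — on real
multi-subject data a subject-respecting split would be the honest design,
and this is a known limitation of the synthetic evaluation.

## Reproducibility and problem sizes

Every random quantity flows from explicit seeds; `run_pipeline()` fans a
single master seed into independent per-stage sub-seeds so that skipping or
re-ordering stages cannot silently shift another stage's random stream.

The test suite exercises: a thousand random dielectric stacks for the
physics equivalence; 40 s, 100 Hz recordings (4 000 samples) for the
detection chain; 100 random noiseless schedules for detector
recall/precision and ±1-sample phase recovery; 20 schedules for
offset/drift invariance of the event count; a 5-point white-noise grid for
monotone recall degradation; and 8 343-window feature datasets with an
80/20 split for network evaluation, where held-out relative-error accuracy
exceeds 93.6%. `scripts/acceptance.R` recomputes the two headline numbers
(ten detected blinks on the benchmark recording; mean held-out accuracy
over five seeds) from scratch against the installed package.

## Known limitations

* The generator's noise model is stationary and Gaussian; real eyewear
  noise is not, and nothing here certifies performance on human subjects.
* The detector assumes one dominant signal channel; two-electrode fusion is
  not modelled.
* Idle time for a single-event window is a convention, not a measurement.
* The network evaluation's random split ignores subject identity.
* The sharp 128th-order filter trades ringing for selectivity; onset timing
  under heavy noise inherits that trade-off.
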
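---
title: "Frequency-division-multiplexed FLIM flow cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-division-multiplexed FLIM flow cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimflow)
```

## The measurement model

A frequency-division-multiplexed FLIM flow cytometer excites a flowing
object with an array of `n` beam spots, the k-th modulated at frequency
`f_k`. The spots are generated by interfering two acousto-optically
deflected tone combs, one of them offset by a frequency shifter; the beat
between tone `a_k` and the *reversed-order* tone `b_{n-1-k}` gives

```
f_k = a_k + f_shift - b_{n-1-k},
```

which is simultaneously what makes the second beam array spatially
inverted and what makes beams `k` and `n-1-k` a *complementary pair*:
`f_k + f_{n-1-k} = 2 f_center` with `f_center = (f_1 + f_n)/2`. With the
published tone combs (207.12890625–307.6171875 MHz and
293.26171875–393.75 MHz at 2.05078125 MHz spacing, shifter
207.6171875 MHz) the modulation frequencies run from 20.99609375 to
221.97265625 MHz in steps of 4.1015625 MHz; every constant is a dyadic
rational, so `build_modulation_plan()` reproduces them exactly in double
precision. The beam spacing equals the line acquisition rate: one image
line is acquired per period of the frequency spacing.

A fluorophore with decay components `(alpha_l, tau_l)` (weights summing
to 1) responds to excitation at angular frequency `w` with the
single-frequency response

```
D = sum_l alpha_l / (1 + w^2 tau_l^2)
N = sum_l alpha_l * w * tau_l / (1 + w^2 tau_l^2)
phase delay     theta = atan2(N, D)      (emission lags excitation)
demodulation    m     = sqrt(N^2 + D^2)
```

implemented in `fluorophore_response()`. We fix the sign convention so
that the phase delay is non-negative and reduces to `atan(w tau)` for a
mono-exponential emitter, consistent with the phase-lifetime readout
`tau = tan(theta) / (2 pi f_center)`; any constant offset in the
detection chain is absorbed by the calibration described below.

## The forward simulator

`simulate_event()` synthesizes the four detector traces of one triggered
acquisition. Excitation is a unit-depth raised cosine `0.5 (1 + cos)`.
At sample time `t` the beam line illuminates phantom row
`start_row + floor(t v / p)` (flow speed `v`, pixel pitch `p`); array A's
beam `k` excites phantom column `k`, while in the spatially inverted
array B the beam at `f_k` excites column `n - 1 - k`. The transmitted
channel carries the per-pixel transmittance, and the reference channel
the zero-phase excitation baseline. Noise is additive white Gaussian
(`noise_sd`, trace units), optionally scaled with the square root of the
instantaneous signal as a shot-noise approximation.

Choices worth knowing:

- **Flow scanning is nearest-row**: the line period (244 ns at the full
  plan) is far shorter than a pixel transit, so within-line motion blur is
  ignored. With the default pitch (0.8 µm) and flow speed (3.28125 m/s,
  inside the instrument's 1–3.5 m/s range) exactly one phantom row passes
  per line, so simulated envelopes step at line boundaries.
- **Trigger statistics**: `simulate_stream()` draws candidate arrivals as
  a homogeneous Poisson process and discards candidates within the
  non-paralyzable dead time (default: the 20.48 µs event length) of the
  last accepted event. An envelope-threshold trigger (`detect_trigger()`)
  is exposed separately as a stand-in for the hardware trigger, whose
  exact envelope is not modelled.
- **Determinism**: one seed in `acquisition_config()` governs the
  arrival process; each event's noise uses a substream derived from the
  seed and the event counter, so any event can be regenerated alone.
- **Phantoms**: `make_bead_phantom()` builds uniform mono-exponential
  disks (the polymer-bead standards at 1.72/2.71/5.54 ns);
  `make_cell_phantom()` builds a cell body visible in transmission with a
  stained nucleus whose lifetime varies linearly in normalized
  edge-to-center distance. The linear coefficient is calibrated against
  the package's own ring-binning code so that the four-ring gradient
  statistic of the noiseless map equals the requested `gradient_percent`
  exactly, with the whole-nucleus mean preserved.

The generator emulates frequency multiplexing, complementary-pair phase
structure, flow scanning, trigger statistics and brightness variation; it
does **not** emulate optical point-spread functions, photon-counting
statistics, detector nonlinearity, or spectral bleed-through. Passing
tests therefore validate the signal-processing chain, not those optical
effects.

## Reconstruction chain

`reconstruct_event()` runs the full chain per event:

1. **Demultiplexing** (`demultiplex_lines()`). The trace is Fourier
   transformed; for each beam the band `[f_k - s/2, f_k + s/2)` (spacing
   `s`) is shifted to baseband, components with `|f| > 0.45 s` are zeroed
   (the ~10% high-frequency cut that suppresses interference crosstalk
   while keeping spatial resolution), and the inverse transform at the
   band length yields exactly one complex sample per line. Two numerical
   refinements matter here:
   - *Line-center sampling.* A half-line phase ramp makes the
     one-sample-per-line decimation read each line at its center rather
     than at the transition between lines — the matched filter for a
     constant line. Without it, edge lines of an object are sampled
     exactly on their amplitude step.
   - *Interference cleanup.* The raised-cosine excitation puts half of
     each beam's power into an unmodulated baseband lump and a quarter
     into the negative-frequency mirror carrier. Both have spectral
     sidelobes wherever the envelope changes quickly (object edges), and
     those sidelobes land in other beams' bands. The demultiplexer first
     subtracts the baseband lump, estimated per line from the sub-carrier
     spectrum (which contains no beam signal); it then iterates twice: a
     signal model built from the current line estimates — every mirror
     carrier plus every *other* beam's sideband — is subtracted and each
     band re-read together with its own modeled sideband. Each iteration
     suppresses the crosstalk by roughly an order of magnitude; two
     iterations bring noise-free bead recovery from several percent to
     about 0.1%. Set `cleanup_iterations = 0` to see the raw behavior.
2. **Calibration** (`derive_calibration()`). For each beam and channel,
   the amplitude-weighted circular mean of (fluorescence phase − reference
   phase) over all lines of a lifetime standard, minus `atan(2 pi f_k
   tau_std)`, gives the instrument's excess phase. Rhodamine B in ethanol
   (mono-exponential, 2.69 ns) is the canonical standard. A beam without
   signal raises an error naming the beam.
3. **Image-pair assembly** (`assemble_image_pair()`). Amplitude = modulus;
   phase = raw argument − reference phase − calibration phase, wrapped to
   (−π, π]; near-zero-amplitude pixels get NA phases. Channel B stays in
   demultiplexing order (spatially mirrored); its per-column frequency map
   after the flip is the reverse of channel A's.
4. **Registration** (`register_image_pair()`). Channel B's amplitude is
   flipped left-right, both amplitudes are up-sampled 2× by bilinear
   interpolation, and the offset is the argmax of the zero-mean normalized
   cross-correlation over integer offsets of the doubled grid (half-pixel
   resolution in native units), ties broken toward the smallest offset.
   On a featureless field (uniform phantom) registration is ill-posed —
   the only amplitude structure is the opposing demodulation-factor
   gradients of the two arrays — so aligned-by-construction fixtures
   should pass the known offset directly to `superpose_pair()`.
5. **Superposition** (`superpose_pair()`). Interpolation acts on the
   complex image `A e^{i theta}` (bilinear on real and imaginary parts),
   avoiding phase-wrap artifacts; amplitude and phase are then
   re-extracted, and the optional 3×3 median filter (default on) is
   applied to the phase images before superposition. The fluorescence
   image is the mean of the aligned amplitudes. For the phase, each
   aligned pixel has a complementary pair `theta_L` at `f_L` and
   `theta_H` at `f_H`; assuming two equal-weight lifetime components, the
   two phase conditions reduce — via `s = tau_a + tau_b`,
   `p = tau_a tau_b` — to a cubic in `s` solved in closed form
   (`polyroot`), and the fitted model is evaluated at `f_center`. The fit
   fixes the weights at 1/2 because two phases cannot determine three
   parameters; this regularization is ours, the underlying
   parameterization being left open by the instrument description.
   Solutions must be real, non-negative, reproduce both phases to 1e-6
   rad, and give a center phase between `theta_L` and `theta_H`; among
   several admissible roots the most nearly mono-exponential one is
   taken. If no solution passes (e.g. `theta_H < theta_L`, impossible for
   positive lifetimes), the pixel falls back to the simple average of the
   two single-frequency phase lifetimes, converted back to a phase at the
   center frequency, and is flagged. Pixels covered by only one channel
   use that channel's mono-exponential transfer and carry their own flag.
6. **Lifetime conversion** (`phase_to_lifetime()`):
   `tau = tan(theta) / (2 pi f_center)` in ns; phases outside [0, π/2)
   are unresolvable at this frequency and map to NA rather than erroring.

Segmentation thresholds images at `max / divisor` with the instrument's
preset divisors 2.5, 3.5 and 4.5 (`segment_image()`); an all-zero image
yields an empty mask rather than a full one.

## Downstream statistics

- **Object features** (`extract_objects()`): cells are segmented on the
  bright-field image (objects attenuate transmission, so the cell mask is
  the dark region), nuclei on fluorescence with one 3×3 binary closing.
  Eccentricity comes from the mask's second central moments, compactness
  from `perimeter^2 / (4 pi area)` with a boundary-face perimeter count —
  standard region properties, since the reference analysis delegates to a
  general-purpose tool without printing formulas. With several nuclei in
  one cell, the roundest (smallest eccentricity) represents nucleus
  morphology and `n_nuclei` is recorded.
- **Ring lifetime gradient** (`ring_lifetime_gradient()`): normalized
  edge-to-center distance (Euclidean distance transform rescaled to [0,1])
  is cut into 4 equal intervals; each ring's fractional value is its mean
  lifetime over the whole-nucleus mean (so a uniform nucleus gives exactly
  1 per ring and gradient 0 — the reason this normalization was chosen
  among the unspecified alternatives); an ordinary least-squares line
  through the 4 fractional values at ring centers
  {0.125, 0.375, 0.625, 0.875} gives
  `gradient = (fit(innermost) - fit(outermost)) × 100` percent. Masks too
  small to form 4 distinct distance levels return a flagged undefined
  result, not an error.
- **Effect sizes** (`cohens_d()`): pooled-SD Cohen's d and the standard
  error `sqrt(((n-1)/(n-3)) (4/n) (1 + d^2/8))`, `n = n_1 + n_2`.
- **Event rates** (`event_rate_stats()`): the actual rate counts only
  images with at least one recognizable object (eccentricity below the
  gate; presets 0.6 for beads, 0.72 for cells), each image at most once;
  instantaneous rates cover consecutive 100-event blocks; the
  inter-arrival histogram above the dead time is fitted with an
  exponential by least absolute residuals (Nelder–Mead on log
  parameters).
- **Data rate** (`data_generation_rate()`): effective event time =
  flow-direction pixels / line rate; bytes per event = floor(time ×
  sampling rate) at 1 byte/sample; MB = 2^20 bytes. These conventions
  (floor, binary MB) are required to reproduce the instrument's worked
  examples (2.6819 µs, 3352 byte/event, 108.3 and 198.9 MB/s) and are
  therefore fixed.
- **Display standardization** (`standardize_lifetime_image()`): a linear
  trend of in-mask lifetime versus image column is removed (our concrete
  reading of "compensating the lifetime slope across the field of view",
  which is named but not specified upstream), a 3×3 median filter is
  applied, and the display range is median ± 1.6 IQR of in-mask pixels.
- **Multinucleate fraction** (`multinucleate_fraction()`): Wilson score
  interval for the 95% CI — chosen over Wald for its behavior at 0% and
  100%; the upstream description does not name its interval.

## Problem sizes and parameters used by the test suite

Tests run on reduced plans built from subsets of the published tone combs
(first *n* tones of set A against the last *n* of set B), which preserve
the beat arithmetic: the reduced plan's frequencies are the lowest *n* of
the full plan. The suite uses 8-beam plans at 156.25 MS/s (and 24 beams
at 312.5 MS/s for gradient studies) with the standard 20.48 µs event
length — 84 lines per event, 3200–6400 samples per trace. Bead studies
use 6-pixel beads over 20 events per lifetime; the robustness study uses
200 events with ±30% per-object brightness jitter and the default trace
noise (`noise_sd = 0.01`, roughly 2.5% of a single beam's demodulated
amplitude); gradient studies use 20-pixel cells with 16-pixel nuclei
(16 µm and 12.8 µm at the 0.8 µm pitch) and gradients of ±12%; stream
statistics use 10,000+ accepted arrivals. These sizes were chosen to keep
the geometry realistic for the cells and beads the instrument measures
while remaining desk-scale.

## Known limitations

- The 3×3 median filter mixes phases across columns that carry different
  modulation frequencies; at the two outermost image columns the
  neighborhood is asymmetric and biases the phase there by a few percent.
  Parameter-recovery invariants are therefore checked with the filter
  off; in object-centric use the bias is negligible because objects sit
  inside the field.
- Interpolated (odd-index) pixels of the doubled grid hold the circular
  midpoint of two phases, which differs from the phase at the midpoint
  frequency by the curvature of `theta(w)`; beam-position pixels are
  exact, interpolated ones carry a small (< 0.5%) bias.
- The interference cleanup is mildly nonlinear, so lifetime images are
  gauge-invariant under a common instrument/calibration phase only up to
  the cleanup residual (well below 1% per pixel).
- The two-component feasibility boundary can flip individual pixels
  between the fit and the fallback under ulp-level input changes; all
  statistics treating images as distributions are insensitive to this.
- Absolute phase lifetimes of multi-exponential dyes are frequency-pair
  summaries, not component estimates; no attempt is made to match them to
  time-correlated single-photon-counting values.
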
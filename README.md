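# flimflow

Simulation, image reconstruction and statistical analysis for
frequency-division-multiplexed, frequency-domain **fluorescence-lifetime
imaging (FLIM) flow cytometry**.

## The problem

Conventional FLIM is too slow for flow cytometry: scanning one laser spot
over each passing cell caps throughput at tens of events per second. A
frequency-division-multiplexed instrument instead illuminates the flow
channel with an array of beam spots, each intensity-modulated at its own
radio frequency f_1 … f_n. A single-pixel avalanche photodetector collects
all spots at once; digital demodulation separates them again by frequency
band, so each triggered acquisition yields bright-field, fluorescence
intensity, and fluorescence *lifetime* images of a cell moving at meters
per second — at event rates beyond 10,000 per second.

The lifetime information lives in the phase of the emission. A fluorophore
with decay components (α_l, τ_l) excited at angular frequency ω responds
with a phase lag

    θ = atan2( Σ_l α_l ωτ_l / (1 + ω²τ_l²),  Σ_l α_l / (1 + ω²τ_l²) )

and the phase lifetime is τ = tan(θ) / (2π f). Because the phase lifetime
of a multi-exponential emitter depends on f, a single beam array would
report different lifetimes in different image columns. The instrument's
key trick is a second, *spatially inverted* beam array: every point is
interrogated by a complementary frequency pair (f_low, f_high) with
f_low + f_high = 2 f_center, and a per-pixel two-component phase fit
transfers both measurements to the common center frequency
(≈ 121.5 MHz for the full 50-beam plan).

This package implements, in one coherent toolchain:

- **frequency plan** — the dual beam-array modulation layout derived from
  the acousto-optic drive tones (`build_modulation_plan()`,
  `complementary_pair_map()`, `snr_gain()`);
- **simulator** — a forward model producing the four sampled detector
  traces (transmitted, two fluorescence channels, reference) for flowing
  phantom beads and cells, with Poisson trigger statistics and dead time
  (`make_bead_phantom()`, `make_cell_phantom()`, `simulate_event()`,
  `simulate_stream()`);
- **reconstruction** — sub-band demultiplexing with interference cleanup,
  phase calibration against a lifetime standard (Rhodamine B, 2.69 ns),
  image-pair registration by flipped 2-D cross-correlation,
  complementary-pair superposition and phase-to-lifetime conversion
  (`demultiplex_lines()`, `derive_calibration()`, `reconstruct_event()`);
- **analysis** — per-object morphology and pixel statistics, the nuclear
  periphery-to-center ring lifetime gradient, Cohen's d effect sizes,
  event-rate and data-generation-rate accounting (`extract_objects()`,
  `ring_lifetime_gradient()`, `cohens_d()`, `event_rate_stats()`,
  `data_generation_rate()`).

## Worked example

Build the instrument's frequency plan, simulate one bead event on a
reduced 8-beam plan, reconstruct it, and extract features:

```r
library(flimflow)

plan <- build_modulation_plan(
  tone_set(207.12890625e6, 2.05078125e6, 50),
  tone_set(293.26171875e6, 2.05078125e6, 50),
  207.6171875e6)
plan
#> <flim_plan> 50 beams, modulation 20.9960938-221.9726562 MHz
#>   line rate 4.1015625 MHz, center frequency 121.4843750 MHz

plan8 <- build_modulation_plan(            # reduced plan for a quick demo
  tone_set(207.12890625e6, 2.05078125e6, 8),
  tone_set(293.26171875e6 + 42 * 2.05078125e6, 2.05078125e6, 8),
  207.6171875e6)
cfg  <- acquisition_config(sampling_rate_hz = 156.25e6, noise_sd = 0.01, seed = 1)
bead <- make_bead_phantom(6, 2.71e-9, field = c(84, 8))
event <- simulate_event(bead, plan8, cfg)

flim <- reconstruct_event(event, plan8, zero_calibration(plan8))
flim
#> <flim_event> 'bead d=6 tau=2.71ns' 168 x 16 px, offset (0, 0)
#>   in-object lifetime 2.703 ns (mean of 145 px)

extract_objects(flim)[, c("area", "mean_lifetime_ns", "cv_lifetime_pixels", "n_nuclei")]
#>   area mean_lifetime_ns cv_lifetime_pixels n_nuclei
#> 1  105           2.7126             3.8826        1
```

The reconstructed in-object lifetime (2.71 ns) matches the phantom's
ground truth to a fraction of a percent despite the trace noise; the
registration offset (0, 0) confirms the two spatially inverted images
aligned. Throughput accounting reproduces the instrument's arithmetic:

```r
data_generation_rate(11297, 11)
#> $effective_event_time_s  2.681905e-06
#> $bytes_per_event         3352
#> $data_rate_mb_s          108.3399
```

A command-line pipeline (`simulate | calibrate | reconstruct | analyze |
pipeline`) is installed under `inst/cli/flimflow`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/flimflow", package="flimflow"))')" \
  pipeline --config demo.yaml --out out/ --n-events 10 --seed 7
```

## Limitations

The simulator models analog detector traces with additive (optionally
signal-scaled) Gaussian noise; it does not model photon counting, optical
point-spread functions, or beam-pointing errors. Lifetime estimation is
phase-based only — modulation-depth lifetimes are not available from
single-pixel detection. See the methods vignette
(`vignettes/flim-flow-methods.Rmd`) for the full model description,
parameter choices and numerical design decisions.
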
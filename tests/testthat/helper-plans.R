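# Shared fixtures: reduced beam plans built from subsets of the full
# instrument tone sets (first n tones of set A with the last n of set B keep
# the beat arithmetic, so the reduced plan's modulation frequencies are the
# lowest n of the full plan), plus matched acquisition settings with a
# sampling rate scaled to the reduced bandwidth.

TONE_A_START <- 207.12890625e6
TONE_B_START <- 293.26171875e6
TONE_SPACING <- 2.05078125e6
SHIFT_HZ <- 207.6171875e6

full_plan <- function() {
  build_modulation_plan(tone_set(TONE_A_START, TONE_SPACING, 50),
                        tone_set(TONE_B_START, TONE_SPACING, 50), SHIFT_HZ)
}

reduced_plan <- function(n_beams = 8L) {
  build_modulation_plan(
    tone_set(TONE_A_START, TONE_SPACING, n_beams),
    tone_set(TONE_B_START + (50L - n_beams) * TONE_SPACING, TONE_SPACING, n_beams),
    SHIFT_HZ)
}

reduced_fs <- function(n_beams = 8L) {
  # smallest power-of-two division of 1.25 GS/s satisfying Nyquist
  f_max <- 20.99609375e6 + n_beams * 4.1015625e6
  fs <- 1.25e9
  while (fs / 2 > 2.2 * f_max && fs > 78.125e6) fs <- fs / 2
  fs
}

test_config <- function(n_beams = 8L, noise_sd = 0, seed = 1L, ...) {
  acquisition_config(sampling_rate_hz = reduced_fs(n_beams),
                     noise_sd = noise_sd, seed = seed, ...)
}

# full-field uniform mono-exponential phantom (calibration standard analogue)
uniform_phantom <- function(tau_s, n_beams = 8L, n_rows = 84L, brightness = 1) {
  flim_phantom(matrix(brightness, n_rows, n_beams),
               matrix(0.3, n_rows, n_beams),
               matrix(tau_s, n_rows, n_beams),
               label = "uniform standard")
}

# uniform bi-exponential phantom (equal-weight two components)
biexp_phantom <- function(tau1_s, tau2_s, n_beams = 8L, n_rows = 84L) {
  flim_phantom(matrix(1, n_rows, n_beams), matrix(0.3, n_rows, n_beams),
               array(rep(c(tau1_s, tau2_s), each = n_rows * n_beams),
                     c(n_rows, n_beams, 2L)),
               array(0.5, c(n_rows, n_beams, 2L)),
               label = "uniform bi-exponential")
}

# bare image pair for registration fixtures (flat phases, linear freq maps)
fake_pair <- function(amp_a, amp_b, f_lo = 20e6, f_hi = 48e6) {
  n <- ncol(amp_a)
  f <- seq(f_lo, f_hi, length.out = n)
  structure(list(amplitude_a = amp_a, phase_a = amp_a * 0,
                 amplitude_b = amp_b, phase_b = amp_b * 0,
                 frequency_map_a = f, frequency_map_b = rev(f),
                 center_frequency_hz = (f_lo + f_hi) / 2),
            class = "flim_image_pair")
}

# minimal reconstructed event for feature-extraction fixtures
fake_flim_event <- function(bf, fl, lt) {
  structure(list(bright_field = bf, fluorescence = fl, lifetime_ns = lt,
                 registration_offset = c(0L, 0L),
                 flags = matrix(0L, nrow(bf), ncol(bf)), empty = FALSE,
                 pair = NULL, center_frequency_hz = NA_real_,
                 options = reconstruct_options(), timestamp_s = 0,
                 label = "fixture"),
            class = "flim_event")
}

disk <- function(nr, nc, center_r, center_c, diameter) {
  r <- matrix(seq_len(nr), nr, nc) - center_r
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center_c
  sqrt(r^2 + c^2) <= diameter / 2
}

segment_nucleus <- function(fl, divisor = 3.5) {
  m <- segment_image(fl, divisor)
  as.matrix(EBImage::closing(matrix(as.numeric(m), nrow(m), ncol(m)),
                             EBImage::makeBrush(3, "box"))) > 0
}
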
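# Dual beam-array modulation-frequency plan.
#
# Each acousto-optic deflector is driven by a multi-tone signal; interfering
# the two deflected beam sets (one of them frequency-shifted) produces one
# intensity-modulated beam per tone pair, with the set-B tones consumed in
# reversed order. That reversed pairing is what creates both the spatial
# inversion of the second array and the complementary-frequency structure
# f_k + f_{n-1-k} = 2 f_center.

#' Acousto-optic drive tone set
#'
#' An arithmetic comb of drive tones: `start + k * spacing` for
#' `k = 0 .. count - 1`.
#'
#' @param start_hz first tone frequency in Hz.
#' @param spacing_hz tone spacing in Hz (> 0).
#' @param count number of tones (>= 1).
#' @return an object of class `flim_tone_set`.
#' @examples
#' tone_set(207.12890625e6, 2.05078125e6, 50)
#' @export
tone_set <- function(start_hz, spacing_hz, count) {
  stopifnot(is.numeric(start_hz), length(start_hz) == 1L,
            is.numeric(spacing_hz), length(spacing_hz) == 1L,
            is.numeric(count), length(count) == 1L)
  if (spacing_hz <= 0) stop("tone spacing must be > 0")
  if (count < 1 || count != round(count)) stop("tone count must be a positive integer")
  structure(list(start_hz = as.numeric(start_hz),
                 spacing_hz = as.numeric(spacing_hz),
                 count = as.integer(count)),
            class = "flim_tone_set")
}

#' @export
print.flim_tone_set <- function(x, ...) {
  cat(sprintf("<flim_tone_set> %d tones, %.8f-%.8f MHz, spacing %.8f MHz\n",
              x$count, x$start_hz / 1e6,
              (x$start_hz + (x$count - 1) * x$spacing_hz) / 1e6,
              x$spacing_hz / 1e6))
  invisible(x)
}

tone_frequencies <- function(ts) ts$start_hz + (seq_len(ts$count) - 1) * ts$spacing_hz

#' Build the dual beam-array modulation plan
#'
#' Derives per-beam intensity-modulation frequencies from the two drive tone
#' sets and the frequency-shifter offset. The k-th beam (array-A spatial
#' order) is modulated at `tone_a[k] + shift - tone_b[count - 1 - k]`; the
#' reversed consumption of set-B tones yields strictly increasing,
#' uniformly spaced modulation frequencies whose spacing is the line
#' acquisition rate, and makes beam k complementary to beam n - 1 - k
#' about the center frequency `(f_1 + f_n) / 2`.
#'
#' @param tone_set_a,tone_set_b [tone_set()] objects with equal counts.
#' @param shift_frequency_hz frequency-shifter offset in Hz.
#' @return an object of class `flim_plan` with elements
#'   `n_beams`, `modulation_frequencies_hz` (array-A spatial order),
#'   `shift_frequency_hz`, `line_rate_hz`, `center_frequency_hz`,
#'   `complementary_pairs` (two-column matrix of 1-based indices) and
#'   `array_b_spatial_map` (array-A index -> array-B spatial index).
#' @examples
#' plan <- build_modulation_plan(
#'   tone_set(207.12890625e6, 2.05078125e6, 50),
#'   tone_set(293.26171875e6, 2.05078125e6, 50),
#'   207.6171875e6)
#' range(plan$modulation_frequencies_hz) / 1e6  # 20.996..., 221.972... MHz
#' @export
build_modulation_plan <- function(tone_set_a, tone_set_b, shift_frequency_hz) {
  stopifnot(inherits(tone_set_a, "flim_tone_set"),
            inherits(tone_set_b, "flim_tone_set"))
  if (tone_set_a$count != tone_set_b$count) {
    stop("configuration error: tone sets must have equal counts (",
         tone_set_a$count, " vs ", tone_set_b$count, ")")
  }
  n <- tone_set_a$count
  fa <- tone_frequencies(tone_set_a)
  fb <- tone_frequencies(tone_set_b)
  f_mod <- fa + shift_frequency_hz - rev(fb)
  if (any(f_mod <= 0)) {
    stop("configuration error: beat relation yields non-positive modulation frequency")
  }
  if (n > 1L && any(diff(f_mod) <= 0)) {
    stop("configuration error: modulation frequencies are not strictly increasing")
  }
  line_rate <- if (n > 1L) f_mod[2] - f_mod[1] else tone_set_a$spacing_hz + tone_set_b$spacing_hz
  center <- (f_mod[1] + f_mod[n]) / 2
  pairs <- cbind(seq_len(n), n + 1L - seq_len(n))
  pairs <- pairs[pairs[, 1] <= pairs[, 2], , drop = FALSE]
  structure(list(
    n_beams = n,
    modulation_frequencies_hz = f_mod,
    shift_frequency_hz = as.numeric(shift_frequency_hz),
    line_rate_hz = line_rate,
    center_frequency_hz = center,
    complementary_pairs = pairs,
    array_b_spatial_map = n + 1L - seq_len(n),
    tone_set_a = tone_set_a,
    tone_set_b = tone_set_b
  ), class = "flim_plan")
}

#' @export
print.flim_plan <- function(x, ...) {
  f <- x$modulation_frequencies_hz / 1e6
  cat(sprintf("<flim_plan> %d beams, modulation %.7f-%.7f MHz\n",
              x$n_beams, min(f), max(f)))
  cat(sprintf("  line rate %.7f MHz, center frequency %.7f MHz\n",
              x$line_rate_hz / 1e6, x$center_frequency_hz / 1e6))
  invisible(x)
}

#' Complementary modulation-frequency pairs
#'
#' Beam k and beam n - 1 - k (0-based) interrogate the same spatial point
#' from the two spatially inverted arrays; their frequency sum is constant
#' at twice the center frequency. For odd beam counts the middle beam is
#' its own partner.
#'
#' @param plan a [build_modulation_plan()] result.
#' @return two-column integer matrix of 1-based beam index pairs.
#' @export
complementary_pair_map <- function(plan) {
  stopifnot(inherits(plan, "flim_plan"))
  plan$complementary_pairs
}

#' Multiplexing SNR gain
#'
#' Signal-to-noise improvement factor of multiplexed acquisition relative to
#' a single-spot scan with the same line rate: pixel dwell time grows by the
#' number of beam spots `n_spots`, while superposed shot noise from the
#' `n_flu` simultaneously excited fluorescent spots costs `sqrt(n_flu)`,
#' giving `sqrt(n_spots) / sqrt(n_flu)`.
#'
#' @param n_spots total beam spots per line.
#' @param n_flu beam spots exciting fluorophores per line (1 <= n_flu <= n_spots).
#' @return dimensionless gain factor.
#' @examples
#' snr_gain(50, 2)  # 5
#' @export
snr_gain <- function(n_spots, n_flu) {
  if (n_spots < 1 || n_flu < 1) stop("domain error: counts must be positive")
  if (n_flu > n_spots) stop("domain error: n_flu cannot exceed n_spots")
  sqrt(n_spots) / sqrt(n_flu)
}

#' Serialize a modulation plan to YAML
#'
#' Writes the generating configuration (tone sets in MHz plus the shifter
#' frequency) under a `modulation_plan:` block; [plan_from_yaml()] rebuilds
#' the identical plan.
#'
#' @param plan a `flim_plan`.
#' @param path optional file path; when NULL the YAML text is returned.
#' @return YAML string (invisibly when written to a file).
#' @export
plan_to_yaml <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "flim_plan"))
  obj <- list(modulation_plan = list(
    tone_set_a = list(start_mhz = plan$tone_set_a$start_hz / 1e6,
                      spacing_mhz = plan$tone_set_a$spacing_hz / 1e6,
                      count = plan$tone_set_a$count),
    tone_set_b = list(start_mhz = plan$tone_set_b$start_hz / 1e6,
                      spacing_mhz = plan$tone_set_b$spacing_hz / 1e6,
                      count = plan$tone_set_b$count),
    shift_mhz = plan$shift_frequency_hz / 1e6
  ))
  txt <- yaml::as.yaml(obj, precision = 15L)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Rebuild a modulation plan from YAML
#'
#' @param x YAML text or a file path containing a `modulation_plan:` block.
#' @return a `flim_plan`.
#' @export
plan_from_yaml <- function(x) {
  obj <- if (length(x) == 1L && file.exists(x)) yaml::read_yaml(x) else yaml::yaml.load(paste(x, collapse = "\n"))
  mp <- obj$modulation_plan
  if (is.null(mp)) stop("format error: no 'modulation_plan' block")
  need <- c("tone_set_a", "tone_set_b", "shift_mhz")
  miss <- setdiff(need, names(mp))
  if (length(miss)) stop("format error: modulation_plan missing key(s): ", paste(miss, collapse = ", "))
  mk <- function(tsb) tone_set(tsb$start_mhz * 1e6, tsb$spacing_mhz * 1e6, tsb$count)
  build_modulation_plan(mk(mp$tone_set_a), mk(mp$tone_set_b), mp$shift_mhz * 1e6)
}
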
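# Forward model: flowing phantoms -> four sampled detector traces.
#
# Each beam k contributes a unit-depth raised cosine 0.5 * (1 + cos(w_k t)).
# A fluorophore with multi-exponential decay responds with demodulation
# factor m and phase lag phi given by the single-frequency response of the
# decay, so the fluorescence channel carries
#   sum_k B(r, c) * m * 0.5 * (1 + cos(w_k t - phi))
# with the flow sweeping phantom rows past the beam line.

#' Acquisition configuration
#'
#' @param sampling_rate_hz digitizer sampling rate (default 1.25 GS/s).
#' @param event_duration_s data length of one triggered event (default
#'   20.48 us); `sampling_rate_hz * event_duration_s` must be an integer.
#' @param dead_time_s non-paralyzable dead time after each trigger; must be
#'   >= the event duration (default: equal to it).
#' @param noise_sd additive Gaussian noise SD per sample, in trace units.
#' @param signal_dependent_noise when TRUE the noise SD scales with the
#'   square root of the instantaneous signal (shot-noise approximation).
#' @param trigger_threshold envelope threshold for [detect_trigger()].
#' @param seed integer seed for all randomness derived from this
#'   configuration; per-event substreams are derived by counter.
#' @param instrument_phase_a,instrument_phase_b optional per-beam excess
#'   instrument phases (radians) injected into the fluorescence channels;
#'   recovered by [derive_calibration()].
#' @return object of class `flim_config`.
#' @export
acquisition_config <- function(sampling_rate_hz = 1.25e9,
                               event_duration_s = 20.48e-6,
                               dead_time_s = event_duration_s,
                               noise_sd = 0.01,
                               signal_dependent_noise = FALSE,
                               trigger_threshold = 0.1,
                               seed = 1L,
                               instrument_phase_a = 0,
                               instrument_phase_b = 0) {
  n_samples <- sampling_rate_hz * event_duration_s
  if (abs(n_samples - round(n_samples)) > 1e-6) {
    stop("sampling_rate * event_duration must be an integer sample count")
  }
  if (dead_time_s < event_duration_s) stop("dead_time must be >= event_duration")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 event_duration_s = event_duration_s,
                 dead_time_s = dead_time_s,
                 noise_sd = noise_sd,
                 signal_dependent_noise = isTRUE(signal_dependent_noise),
                 trigger_threshold = trigger_threshold,
                 seed = as.integer(seed),
                 instrument_phase_a = instrument_phase_a,
                 instrument_phase_b = instrument_phase_b,
                 n_samples = as.integer(round(n_samples))),
            class = "flim_config")
}

#' @export
print.flim_config <- function(x, ...) {
  cat(sprintf("<flim_config> %.4g GS/s, event %.4g us (%d samples), dead time %.4g us, noise sd %g\n",
              x$sampling_rate_hz / 1e9, x$event_duration_s * 1e6, x$n_samples,
              x$dead_time_s * 1e6, x$noise_sd))
  invisible(x)
}

#' Single-frequency response of a multi-exponential emitter
#'
#' For excitation modulated at angular frequency `omega`, an emitter with
#' components (alpha_l, tau_l) responds with complex factor
#' `sum_l alpha_l / (1 + i omega tau_l)`; the phase delay is the positive
#' lag of emission behind excitation, `atan2(N, D)` with
#' `D = sum alpha / (1 + w^2 tau^2)` and `N = sum alpha w tau / (1 + w^2 tau^2)`,
#' and the demodulation factor is `sqrt(N^2 + D^2)`. For a mono-exponential
#' emitter these reduce to `atan(w tau)` and `1 / sqrt(1 + (w tau)^2)`.
#'
#' @param omega angular modulation frequency in rad/s (>= 0).
#' @param components a [lifetime_components()] object.
#' @return list with `modulation_factor` (in (0, 1\]) and `phase_delay`
#'   (radians, in \[0, pi/2)).
#' @examples
#' fluorophore_response(2 * pi * 121.484375e6, lifetime_components(1, 2.69e-9))
#' @export
fluorophore_response <- function(omega, components) {
  stopifnot(inherits(components, "flim_lifetime_components"))
  if (omega < 0) stop("domain error: omega must be >= 0")
  den <- 1 + (omega * components$tau)^2
  D <- sum(components$alpha / den)
  N <- sum(components$alpha * omega * components$tau / den)
  list(modulation_factor = sqrt(N^2 + D^2), phase_delay = atan2(N, D))
}

# rows x L matrix slice of a rows x cols x L array at one column
col_slice <- function(arr, k) matrix(arr[, k, ], nrow = dim(arr)[1])

# vectorized response for one column of a phantom: alpha/tau are n_rows x L
response_rows <- function(omega, alpha, tau) {
  den <- 1 + (omega * tau)^2
  D <- rowSums(alpha / den)
  N <- rowSums(alpha * omega * tau / den)
  list(m = sqrt(N^2 + D^2), phi = atan2(N, D))
}

#' Simulate one triggered acquisition
#'
#' Generates the four sampled detector traces (transmitted, fluorescence
#' from array A, fluorescence from array B, reference) for one event. The
#' phantom moves at its flow speed, so sample time t sees phantom row
#' `start_row + floor(t * flow_speed / pixel_pitch)` (rows outside the
#' phantom are background: zero emission, full transmittance). Array-A
#' beam k excites phantom column k; in the spatially inverted array B the
#' beam modulated at f_k excites column `n_beams - k + 1`. The reference
#' channel carries the zero-phase excitation baseline.
#'
#' @param phantom a [flim_phantom()]; its width must be >= `plan$n_beams`.
#' @param plan a [build_modulation_plan()] result.
#' @param config an [acquisition_config()].
#' @param start_row phantom row swept at t = 0 (may be negative to delay
#'   entry of the object into the event window).
#' @param event_index counter used to derive the per-event noise substream
#'   from `config$seed`, making every event independently reproducible.
#' @param timestamp_s acquisition timestamp stored in the event.
#' @return object of class `flim_raw_event` with the four traces.
#' @export
simulate_event <- function(phantom, plan, config, start_row = 1L,
                           event_index = 0L, timestamp_s = 0) {
  stopifnot(inherits(phantom, "flim_phantom"), inherits(plan, "flim_plan"),
            inherits(config, "flim_config"))
  n <- plan$n_beams
  if (ncol(phantom$brightness) < n) {
    stop("shape error: phantom narrower (", ncol(phantom$brightness),
         ") than beam count (", n, ")")
  }
  if (max(plan$modulation_frequencies_hz) + plan$line_rate_hz / 2 >=
      config$sampling_rate_hz / 2) {
    stop("configuration error: sampling rate violates Nyquist for this plan")
  }
  N <- config$n_samples
  t <- (seq_len(N) - 1) / config$sampling_rate_hz
  row_at <- start_row + floor(t * phantom$flow_speed_m_s / phantom$pixel_pitch_m)
  nr <- nrow(phantom$brightness)
  valid <- row_at >= 1L & row_at <= nr
  # lookup index: 1 = background, r + 1 = phantom row r
  lk <- ifelse(valid, row_at + 1L, 1L)

  psi_a <- rep_len(config$instrument_phase_a, n)
  psi_b <- rep_len(config$instrument_phase_b, n)
  s_a <- numeric(N); s_b <- numeric(N); s_t <- numeric(N); s_r <- numeric(N)
  for (k in seq_len(n)) {
    w <- 2 * pi * plan$modulation_frequencies_hz[k]
    wt <- w * t
    # array A: beam k -> column k
    ra <- response_rows(w, col_slice(phantom$alpha, k), col_slice(phantom$tau, k))
    amp_a <- c(0, phantom$brightness[, k] * ra$m)[lk]
    phi_a <- c(0, ra$phi)[lk]
    s_a <- s_a + amp_a * 0.5 * (1 + cos(wt - phi_a - psi_a[k]))
    # array B: beam at f_k -> column n - k + 1
    cb <- n - k + 1L
    rb <- response_rows(w, col_slice(phantom$alpha, cb), col_slice(phantom$tau, cb))
    amp_b <- c(0, phantom$brightness[, cb] * rb$m)[lk]
    phi_b <- c(0, rb$phi)[lk]
    s_b <- s_b + amp_b * 0.5 * (1 + cos(wt - phi_b - psi_b[k]))
    # transmitted and reference
    tr <- c(1, phantom$transmittance[, k])[lk]
    s_t <- s_t + tr * 0.5 * (1 + cos(wt))
    s_r <- s_r + 0.5 * (1 + cos(wt))
  }
  if (config$noise_sd > 0) {
    sub_seed <- (config$seed + 1000003 * (event_index %% 2048L)) %% 2147483647
    noisy <- with_seed(sub_seed, {
      addn <- function(s) {
        sdv <- if (config$signal_dependent_noise) {
          config$noise_sd * sqrt(pmax(s, 0))
        } else config$noise_sd
        s + rnorm(length(s), sd = sdv)
      }
      list(addn(s_t), addn(s_a), addn(s_b), addn(s_r))
    })
    s_t <- noisy[[1]]; s_a <- noisy[[2]]; s_b <- noisy[[3]]; s_r <- noisy[[4]]
  }
  structure(list(transmitted = s_t, fluorescence_a = s_a, fluorescence_b = s_b,
                 reference = s_r, timestamp_s = timestamp_s,
                 start_row = start_row, n_beams = n,
                 sampling_rate_hz = config$sampling_rate_hz,
                 event_duration_s = config$event_duration_s,
                 label = phantom$label),
            class = "flim_raw_event")
}

#' @export
print.flim_raw_event <- function(x, ...) {
  cat(sprintf("<flim_raw_event> '%s' %d samples @ %.4g GS/s, t = %.6f s\n",
              x$label, length(x$transmitted), x$sampling_rate_hz / 1e9,
              x$timestamp_s))
  invisible(x)
}

#' Poisson arrivals with non-paralyzable dead time
#'
#' Candidate arrivals are a homogeneous Poisson process at `mean_rate`;
#' candidates within `dead_time_s` of the previously accepted arrival are
#' discarded. Inter-arrival gaps of the accepted process therefore never
#' fall below the dead time, and gaps above it remain exponential.
#'
#' @param mean_rate_eps candidate event rate in events/s.
#' @param duration_s observation window in seconds.
#' @param dead_time_s dead time in seconds.
#' @param seed integer seed.
#' @return numeric vector of accepted arrival times (s); attribute
#'   `"n_candidates"` carries the total candidate count.
#' @export
simulate_arrivals <- function(mean_rate_eps, duration_s, dead_time_s, seed = 1L) {
  if (mean_rate_eps <= 0) {
    out <- numeric(0); attr(out, "n_candidates") <- 0L
    return(out)
  }
  with_seed(seed, {
    # draw gaps in blocks until past the window
    times <- numeric(0); t_end <- 0
    while (t_end < duration_s) {
      gaps <- rexp(max(1000L, ceiling(mean_rate_eps * duration_s / 4)),
                   rate = mean_rate_eps)
      times <- c(times, t_end + cumsum(gaps))
      t_end <- times[length(times)]
    }
    cand <- times[times <= duration_s]
    acc <- numeric(0); last <- -Inf
    for (tt in cand) {
      if (tt - last >= dead_time_s) {
        acc <- c(acc, tt); last <- tt
      }
    }
    attr(acc, "n_candidates") <- length(cand)
    acc
  })
}

#' Simulate a stream of triggered events
#'
#' Draws arrival times with [simulate_arrivals()] and generates one raw
#' event per accepted arrival from `phantom_factory(i)`.
#'
#' @param phantom_factory function of the event index returning a
#'   [flim_phantom()]; ignored when `traces = FALSE`.
#' @param mean_rate_eps candidate Poisson rate (events/s).
#' @param duration_s observation window (s).
#' @inheritParams simulate_event
#' @param traces when FALSE only arrival statistics are generated (cheap
#'   large-n stream timing studies).
#' @return object of class `flim_event_stream` with `events` (list of raw
#'   events), `arrival_times`, `n_candidates` and `total_duration_s`.
#' @export
simulate_stream <- function(phantom_factory, mean_rate_eps, duration_s,
                            plan, config, start_row = 1L, traces = TRUE) {
  at <- simulate_arrivals(mean_rate_eps, duration_s, config$dead_time_s,
                          seed = config$seed)
  events <- list()
  if (traces && length(at)) {
    events <- lapply(seq_along(at), function(i) {
      simulate_event(phantom_factory(i), plan, config, start_row = start_row,
                     event_index = i, timestamp_s = at[i])
    })
  }
  structure(list(events = events, arrival_times = as.numeric(at),
                 n_candidates = attr(at, "n_candidates"),
                 total_duration_s = duration_s,
                 plan = plan, config = config),
            class = "flim_event_stream")
}

#' @export
print.flim_event_stream <- function(x, ...) {
  cat(sprintf("<flim_event_stream> %d accepted arrivals in %.4g s (%s raw events)\n",
              length(x$arrival_times), x$total_duration_s,
              if (length(x$events)) length(x$events) else "no"))
  invisible(x)
}

#' Envelope trigger detection
#'
#' Stand-in for the hardware trigger: the fluorescence trace is rectified
#' about its baseline, smoothed with a moving average much longer than the
#' carrier period, and the first crossing of `config$trigger_threshold`
#' is reported.
#'
#' @param trace sampled fluorescence trace.
#' @param config an [acquisition_config()].
#' @param window_samples smoothing window (default: 2 line periods).
#' @return index of the first threshold crossing, or NA if none.
#' @export
detect_trigger <- function(trace, config, window_samples = NULL) {
  if (is.null(window_samples)) {
    window_samples <- max(8L, as.integer(length(trace) / 40L))
  }
  env <- abs(trace - median(trace))
  ker <- rep(1 / window_samples, window_samples)
  sm <- stats::filter(env, ker, sides = 1)
  idx <- which(!is.na(sm) & sm >= config$trigger_threshold)
  if (length(idx)) idx[1] else NA_integer_
}
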
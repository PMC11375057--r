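# Signal-processing chain: raw multiplexed traces -> BF / FL / LT images.
#
# Each beam occupies its own frequency band of width equal to the beam
# spacing (= line rate). Demultiplexing extracts that band from the full
# event spectrum, removes the outer ~10% of the baseband (crosstalk from
# undesired beam-pair interference), and inverse-transforms at the band
# length, which lands exactly one complex sample per line -- the matched
# decimation for a constant line. Phases are referenced to the reference
# channel and corrected with the calibration table, the two spatially
# inverted images are registered on a 2x-interpolated grid and superposed,
# and the superposed phase at the center frequency is converted to a phase
# lifetime tau = tan(theta) / (2 pi f_center).

#' Demultiplex a trace into per-beam complex line profiles
#'
#' @param trace sampled detector trace.
#' @param plan a [build_modulation_plan()] result.
#' @param sampling_rate_hz digitizer rate in Hz.
#' @param subband_cut half-width of the retained baseband as a fraction of
#'   the beam spacing; the default 0.45 discards the outer ~10% of the
#'   band's frequency components.
#' @param remove_baseband subtract the baseband lump (the excitation DC
#'   offset tracked line by line, estimated from the sub-carrier spectrum)
#'   before transforming. The raised-cosine excitation puts half of every
#'   beam's power into an unmodulated baseband lump whose spectral
#'   sidelobes leak into the carrier bands whenever the envelope changes
#'   quickly (object edges).
#' @param cleanup_iterations iterative interference cleanup: from the
#'   current line estimates, synthesize every beam's lower-sideband
#'   (mirror) carrier and every other beam's upper sideband, subtract this
#'   interference model from the trace, and demodulate again (each beam
#'   re-reading its own modeled upper sideband plus the residual).
#'   Suppresses the crosstalk produced by undesired interference pairs of
#'   beam spots by roughly an order of magnitude per iteration at object
#'   edges; 0 disables.
#' @param channel label stored with the result.
#' @return object of class `flim_line_set`: a complex matrix (lines x
#'   beams) whose modulus is the demodulated amplitude and whose argument
#'   is the raw phase lag of each beam, with attributes `line_rate_hz` and
#'   `channel`.
#' @export
demultiplex_lines <- function(trace, plan, sampling_rate_hz,
                              subband_cut = 0.45, remove_baseband = TRUE,
                              cleanup_iterations = 2L, channel = "") {
  stopifnot(inherits(plan, "flim_plan"))
  N <- length(trace)
  duration <- N / sampling_rate_hz
  spacing <- plan$line_rate_hz
  f_k <- plan$modulation_frequencies_hz
  if (max(f_k) + spacing / 2 >= sampling_rate_hz / 2) {
    stop("configuration error: Nyquist violated for the highest beam frequency")
  }
  M <- floor(duration * spacing)          # lines per event = bins per band
  if (M < 1L) stop("configuration error: trace shorter than one line period")
  line_of <- pmin(floor((seq_len(N) - 1) / sampling_rate_hz * spacing), M - 1L)

  m_seq <- seq.int(-floor(M / 2), ceiling(M / 2) - 1L)
  keep <- abs(m_seq) <= subband_cut * M   # low-pass in the baseband
  # sample each line at its center, not at the transition between lines:
  # the half-line advance makes the one-sample-per-line decimation act as
  # the matched filter for a constant line
  center <- exp(1i * pi * m_seq / M)
  band_k <- function(X, k) {
    ck <- round(f_k[k] * duration)
    Y <- complex(length.out = M)
    Y[(m_seq %% M) + 1L] <- X[((ck + m_seq) %% N) + 1L] * keep * center
    # conjugate so that a trace cos(w t - phi) yields argument +phi
    Conj(fft(Y, inverse = TRUE)) / N
  }
  demux_all <- function(x) {
    X <- fft(x)
    vapply(seq_along(f_k), function(k) band_k(X, k),
           complex(M))
  }

  work <- trace
  if (remove_baseband) {
    # estimate the baseband lump from the sub-carrier spectrum (which holds
    # no beam signal), then rebuild it as a per-line step so that its
    # spectral sidelobes inside the carrier bands are subtracted too
    Xl <- fft(work)
    b_lo <- max(1L, floor((min(f_k) - spacing / 2) * duration))
    keep_lo <- rep(FALSE, N)
    keep_lo[seq_len(b_lo)] <- TRUE                 # bins 0 .. b_lo - 1
    keep_lo[N - seq_len(b_lo - 1L) + 1L] <- TRUE   # negative-frequency mirror
    lump <- Re(fft(Xl * keep_lo, inverse = TRUE)) / N
    work <- work - ave(lump, line_of)
  }
  out <- demux_all(work)
  if (cleanup_iterations > 0L) {
    t <- (seq_len(N) - 1) / sampling_rate_hz
    for (it in seq_len(cleanup_iterations)) {
      # per-beam signal model from the current line envelopes D: upper
      # sideband conj(D) e^{+iwt} plus its mirror D e^{-iwt}
      model <- numeric(N)
      upper <- vector("list", length(f_k))
      for (k in seq_along(f_k)) {
        Dk <- out[line_of + 1L, k]
        upper[[k]] <- Conj(Dk) * exp((0 + 2i) * pi * f_k[k] * t)
        model <- model + 2 * Re(upper[[k]])
      }
      X_res <- fft(work - model)
      for (k in seq_along(f_k)) {
        # each beam reads the residual plus its own modeled upper sideband:
        # every other beam's sideband and all mirror carriers are gone
        out[, k] <- band_k(X_res, k) + band_k(fft(upper[[k]]), k)
      }
    }
  }
  structure(out, line_rate_hz = spacing, channel = channel,
            frequencies_hz = f_k,
            class = c("flim_line_set", "matrix", "array"))
}

#' Derive the per-beam calibration table from a lifetime standard
#'
#' Records, for every beam and both fluorescence channels, the excess
#' instrument phase: the amplitude-weighted circular mean of the raw
#' fluorescence-minus-reference phase over all lines and events, minus the
#' phase `atan(2 pi f_k tau)` expected from the standard's known
#' mono-exponential lifetime (Rhodamine B in ethanol, 2.69 ns, is the
#' canonical standard).
#'
#' @param standard_events list of [simulate_event()] raw events measuring
#'   the standard (or a single event).
#' @param standard_tau_s known lifetime of the standard in seconds.
#' @param plan the modulation plan.
#' @param sampling_rate_hz digitizer rate.
#' @param subband_cut see [demultiplex_lines()].
#' @return object of class `flim_calibration` with per-beam `phases_a`,
#'   `phases_b` (radians), the standard lifetime and the plan frequencies.
#' @export
derive_calibration <- function(standard_events, standard_tau_s, plan,
                               sampling_rate_hz, subband_cut = 0.45) {
  if (inherits(standard_events, "flim_raw_event")) standard_events <- list(standard_events)
  n <- plan$n_beams
  acc_a <- acc_b <- complex(length.out = n)
  amp_a <- amp_b <- numeric(n)
  for (ev in standard_events) {
    la <- demultiplex_lines(ev$fluorescence_a, plan, sampling_rate_hz, subband_cut, channel = "fluorescence_a")
    lb <- demultiplex_lines(ev$fluorescence_b, plan, sampling_rate_hz, subband_cut, channel = "fluorescence_b")
    lr <- demultiplex_lines(ev$reference, plan, sampling_rate_hz, subband_cut, channel = "reference")
    ref_unit <- lr / pmax(Mod(lr), .Machine$double.xmin)
    acc_a <- acc_a + colSums(la * Conj(ref_unit))
    acc_b <- acc_b + colSums(lb * Conj(ref_unit))
    amp_a <- amp_a + colMeans(Mod(la))
    amp_b <- amp_b + colMeans(Mod(lb))
  }
  thr <- 0.01 * max(amp_a, amp_b)
  for (k in seq_len(n)) {
    if (amp_a[k] < thr) stop("calibration error: beam ", k, " has no signal in channel A")
    if (amp_b[k] < thr) stop("calibration error: beam ", k, " has no signal in channel B")
  }
  expected <- atan(2 * pi * plan$modulation_frequencies_hz * standard_tau_s)
  structure(list(phases_a = wrap_phase(Arg(acc_a) - expected),
                 phases_b = wrap_phase(Arg(acc_b) - expected),
                 standard_tau_s = standard_tau_s,
                 frequencies_hz = plan$modulation_frequencies_hz,
                 center_frequency_hz = plan$center_frequency_hz,
                 n_beams = n),
            class = "flim_calibration")
}

#' @export
print.flim_calibration <- function(x, ...) {
  cat(sprintf("<flim_calibration> %d beams, standard tau %.3f ns, |phase| max %.2e rad\n",
              x$n_beams, x$standard_tau_s * 1e9,
              max(abs(c(x$phases_a, x$phases_b)))))
  invisible(x)
}

#' Zero calibration table
#'
#' All calibration phases zero -- appropriate for an ideal simulator with no
#' instrument phase.
#' @param plan the modulation plan.
#' @return a `flim_calibration`.
#' @export
zero_calibration <- function(plan) {
  structure(list(phases_a = numeric(plan$n_beams),
                 phases_b = numeric(plan$n_beams),
                 standard_tau_s = 0,
                 frequencies_hz = plan$modulation_frequencies_hz,
                 center_frequency_hz = plan$center_frequency_hz,
                 n_beams = plan$n_beams),
            class = "flim_calibration")
}

#' Assemble the amplitude and phase image pair
#'
#' Rows are successive lines (flow direction), columns beam positions.
#' Per pixel: amplitude = modulus of the complex line sample; phase = raw
#' argument minus reference phase minus calibration phase, wrapped to
#' (-pi, pi]. Channel-B images are kept in demultiplexing (frequency)
#' order, i.e. spatially mirrored; `frequency_map_b` gives the per-column
#' frequency after the left-right flip applied during registration, and is
#' the reverse of `frequency_map_a`.
#'
#' @param lines_a,lines_b,reference_lines [demultiplex_lines()] outputs of
#'   the two fluorescence channels and the reference channel.
#' @param calibration a [derive_calibration()] or [zero_calibration()] table.
#' @return object of class `flim_image_pair`.
#' @export
assemble_image_pair <- function(lines_a, lines_b, reference_lines, calibration) {
  if (!all(dim(lines_a) == dim(lines_b)) ||
      !all(dim(lines_a) == dim(reference_lines))) {
    stop("shape error: line sets must share dimensions")
  }
  n <- ncol(lines_a)
  if (calibration$n_beams != n) stop("shape error: calibration beam count mismatch")
  one_channel <- function(lines, cal) {
    amp <- Mod(lines)
    ph <- wrap_phase(Arg(lines * Conj(reference_lines)) -
                       matrix(cal, nrow(lines), n, byrow = TRUE))
    thr <- 1e-9 * max(amp, 0)
    ph[amp <= thr] <- NA_real_
    list(amp = amp, ph = ph)
  }
  a <- one_channel(lines_a, calibration$phases_a)
  b <- one_channel(lines_b, calibration$phases_b)
  structure(list(amplitude_a = a$amp, phase_a = a$ph,
                 amplitude_b = b$amp, phase_b = b$ph,
                 frequency_map_a = calibration$frequencies_hz,
                 frequency_map_b = rev(calibration$frequencies_hz),
                 center_frequency_hz = calibration$center_frequency_hz),
            class = "flim_image_pair")
}

#' @export
print.flim_image_pair <- function(x, ...) {
  cat(sprintf("<flim_image_pair> %d lines x %d beams, center %.4f MHz\n",
              nrow(x$amplitude_a), ncol(x$amplitude_a),
              x$center_frequency_hz / 1e6))
  invisible(x)
}

#' Register the amplitude image pair
#'
#' Flips the channel-B amplitude image left-right (undoing the spatial
#' inversion), up-samples both amplitudes 2x by bilinear interpolation, and
#' locates the maximum of the zero-mean normalized 2-D cross-correlation
#' over integer offsets of the doubled grid (half-pixel resolution in
#' native units). Ties are broken toward the smallest offset magnitude.
#'
#' @param pair a [assemble_image_pair()] result.
#' @param max_shift integer c(rows, cols) search radius on the doubled
#'   grid; defaults to a quarter of each image dimension.
#' @return integer c(offset_rows, offset_cols) on the doubled grid such
#'   that shifting the flipped, interpolated B image by this amount aligns
#'   it with A.
#' @export
register_image_pair <- function(pair, max_shift = NULL) {
  a2 <- interp2x(pair$amplitude_a)
  b2 <- interp2x(pair$amplitude_b[, ncol(pair$amplitude_b):1, drop = FALSE])
  if (max(a2) <= 0 || max(b2) <= 0) stop("registration error: all-zero amplitude image")
  if (is.null(max_shift)) {
    max_shift <- c(max(1L, nrow(a2) %/% 4L), max(1L, ncol(a2) %/% 4L))
  }
  best <- -Inf; best_off <- c(0L, 0L); best_rank <- Inf
  for (dr in seq.int(-max_shift[1], max_shift[1])) {
    for (dc in seq.int(-max_shift[2], max_shift[2])) {
      bs <- shift_image(b2, dr, dc)
      ok <- !is.na(bs)
      if (sum(ok) < 4L) next
      av <- a2[ok]; bv <- bs[ok]
      av <- av - mean(av); bv <- bv - mean(bv)
      den <- sqrt(sum(av^2) * sum(bv^2))
      if (den == 0) next
      score <- sum(av * bv) / den
      rank <- abs(dr) + abs(dc)
      if (score > best + 1e-12 ||
          (score > best - 1e-12 && rank < best_rank)) {
        best <- max(score, best); best_off <- c(dr, dc); best_rank <- rank
      }
    }
  }
  as.integer(best_off)
}

# phase of an equal-weight two-component decay at angular frequency w
biexp_phase <- function(w, ta, tb) {
  da <- 1 + (w * ta)^2; db <- 1 + (w * tb)^2
  atan2(0.5 * (w * ta / da + w * tb / db), 0.5 * (1 / da + 1 / db))
}

#' Two-component phase superposition at the center frequency
#'
#' Solves for an equal-weight pair of lifetime components (tau_a, tau_b)
#' whose phase matches `theta_l` at `f_l` and `theta_h` at `f_h`, then
#' evaluates that model's phase at the center frequency. In terms of
#' s = tau_a + tau_b and p = tau_a tau_b the two phase conditions reduce to
#' a cubic in s (p is rationally eliminated), solved in closed form.
#' Feasibility requires theta_l <= theta_h (for f_l <= f_h) and a real
#' non-negative component pair; otherwise the fallback is the simple
#' average of the two single-frequency phase lifetimes, converted back to a
#' phase at the center frequency.
#'
#' @param theta_l,theta_h phases (radians) at the lower and higher
#'   frequency of the complementary pair.
#' @param f_l,f_h the pair frequencies in Hz.
#' @param f_center center frequency in Hz.
#' @return list: `theta_c` (phase at the center frequency), `feasible`
#'   (TRUE when the two-component solve succeeded), `tau_s` (the component
#'   pair in seconds, NA on the fallback path).
#' @export
superpose_phase_pair <- function(theta_l, theta_h, f_l, f_h, f_center) {
  wl <- 2 * pi * f_l; wh <- 2 * pi * f_h; wc <- 2 * pi * f_center
  fallback <- function() {
    tau_bar <- 0.5 * (tan(theta_l) / wl + tan(theta_h) / wh)
    list(theta_c = atan(wc * tau_bar), feasible = FALSE,
         tau_s = c(NA_real_, NA_real_))
  }
  if (!is.finite(theta_l) || !is.finite(theta_h) ||
      theta_l < 0 || theta_h < 0 || theta_l >= pi / 2 || theta_h >= pi / 2) {
    return(fallback())
  }
  if (theta_l < 1e-12 && theta_h < 1e-12) {
    return(list(theta_c = 0, feasible = TRUE, tau_s = c(0, 0)))
  }
  if (f_l == f_h) {
    # degenerate middle column: both phases sample the same frequency
    th <- (theta_l + theta_h) / 2
    tau <- tan(th) / wl
    return(list(theta_c = atan(wc * tau), feasible = TRUE, tau_s = c(tau, tau)))
  }
  if (theta_h < theta_l - 1e-9) return(fallback())
  TL <- tan(theta_l); TH <- tan(theta_h)
  # cubic in s from equating the rational expressions for p at both bands
  lc <- c(2 * TH * 2 * TL,
          2 * TH * (-wl) + 2 * TL * wh,
          2 * TH * TL * wl^2 + (-wl) * wh,
          TL * wl^2 * wh) * wh^2
  rc <- c(2 * TL * 2 * TH,
          2 * TL * (-wh) + 2 * TH * wl,
          2 * TL * TH * wh^2 + (-wh) * wl,
          TH * wh^2 * wl) * wl^2
  co <- lc - rc
  if (all(abs(co) < 1e-300)) return(fallback())
  roots <- polyroot(co)
  cand <- NULL
  for (z in roots) {
    s <- Re(z)
    if (abs(Im(z)) > 1e-8 * (1 + abs(s)) || s < -1e-15) next
    s <- max(s, 0)
    p <- (TL * wl^2 * s^2 - wl * s + 2 * TL) / (wl^2 * (wl * s + 2 * TL))
    if (!is.finite(p)) next
    disc <- s^2 - 4 * p
    if (p < -1e-12 * (1 + s^2) || disc < -1e-10 * (1 + s^2)) next
    root <- sqrt(max(disc, 0))
    ta <- max((s - root) / 2, 0); tb <- max((s + root) / 2, 0)
    # accept only solutions that actually reproduce both phases
    err <- max(abs(biexp_phase(wl, ta, tb) - theta_l),
               abs(biexp_phase(wh, ta, tb) - theta_h))
    if (err > 1e-6) next
    th_c <- biexp_phase(wc, ta, tb)
    if (th_c < min(theta_l, theta_h) - 1e-9 ||
        th_c > max(theta_l, theta_h) + 1e-9) next
    if (is.null(cand) || err < cand$err ||
        (err == cand$err && abs(tb - ta) < abs(cand$tau_s[2] - cand$tau_s[1]))) {
      cand <- list(theta_c = th_c, err = err, tau_s = c(ta, tb))
    }
  }
  if (is.null(cand)) return(fallback())
  list(theta_c = cand$theta_c, feasible = TRUE, tau_s = cand$tau_s)
}

#' Superpose a registered image pair
#'
#' Flips channel B, up-samples both complex images (amplitude times
#' exp(i phase)) 2x by bilinear interpolation, optionally median-filters
#' the phase images (3x3), translates B by the registration offset, and
#' superposes: fluorescence = mean of the aligned amplitudes; phase = the
#' two-component phase at the center frequency from each aligned pixel's
#' complementary phase pair ([superpose_phase_pair()]).
#'
#' @param pair a [assemble_image_pair()] result.
#' @param offset integer c(rows, cols) from [register_image_pair()] (doubled
#'   grid).
#' @param assume_two_components attempt the equal-weight two-component fit;
#'   when FALSE every pixel takes the lifetime-averaging fallback.
#' @param median_filter apply the 3x3 median filter to the interpolated
#'   phase images before superposition.
#' @return list with `fluorescence` and `phase_at_center` matrices on the
#'   doubled grid, integer `flags` (0 = two-component fit, 1 = fallback
#'   average, 2 = single-channel pixel, 3 = undefined) and
#'   `center_frequency_hz`.
#' @export
superpose_pair <- function(pair, offset, assume_two_components = TRUE,
                           median_filter = FALSE) {
  n <- ncol(pair$amplitude_a)
  flipc <- function(m) m[, n:1, drop = FALSE]
  to_complex <- function(amp, ph) {
    ph0 <- ph; ph0[is.na(ph0)] <- 0
    amp * exp(1i * ph0)
  }
  extract <- function(cplx) {
    amp <- Mod(cplx); ph <- Arg(cplx)
    ph[amp <= 1e-9 * max(amp, 0)] <- NA_real_
    list(amp = amp, ph = ph)
  }
  A <- extract(interp2x(to_complex(pair$amplitude_a, pair$phase_a)))
  B <- extract(interp2x(to_complex(flipc(pair$amplitude_b), flipc(pair$phase_b))))
  if (median_filter) {
    A$ph <- median_filter3(A$ph)
    B$ph <- median_filter3(B$ph)
  }
  amp_b <- shift_image(B$amp, offset[1], offset[2])
  ph_b <- shift_image(B$ph, offset[1], offset[2])

  # per-column frequencies on the doubled grid (linear in position, so the
  # complementary sum stays 2 f_center at interpolated columns too)
  x <- pmin((seq_len(2L * n) - 1) / 2, n - 1L)
  fa <- approx(0:(n - 1L), pair$frequency_map_a, xout = x)$y
  fb0 <- approx(0:(n - 1L), pair$frequency_map_b, xout = x)$y
  fb <- if (offset[2] == 0) fb0 else {
    out <- rep(NA_real_, length(fb0))
    src <- seq_along(fb0) - offset[2]
    ok <- src >= 1L & src <= length(fb0)
    out[ok] <- fb0[src[ok]]
    out
  }
  fc <- pair$center_frequency_hz

  nr <- nrow(A$amp); nc2 <- ncol(A$amp)
  fluor <- matrix(NA_real_, nr, nc2)
  phase_c <- matrix(NA_real_, nr, nc2)
  flags <- matrix(3L, nr, nc2)
  both <- is.finite(A$amp) & is.finite(amp_b)
  fluor[both] <- (A$amp[both] + amp_b[both]) / 2
  only_a <- is.finite(A$amp) & !both
  fluor[only_a] <- A$amp[only_a]
  for (j in seq_len(nc2)) {
    f1 <- fa[j]; f2 <- fb[j]
    for (i in seq_len(nr)) {
      th_a <- A$ph[i, j]; th_b <- ph_b[i, j]
      if (is.finite(th_a) && is.finite(th_b) && is.finite(f2)) {
        if (f1 <= f2) {
          r <- superpose_phase_pair(th_a, th_b, f1, f2, fc)
        } else {
          r <- superpose_phase_pair(th_b, th_a, f2, f1, fc)
        }
        if (!assume_two_components) {
          r <- local({
            wl <- 2 * pi * min(f1, f2); wh <- 2 * pi * max(f1, f2)
            tl <- if (f1 <= f2) th_a else th_b
            th <- if (f1 <= f2) th_b else th_a
            tau_bar <- 0.5 * (tan(tl) / wl + tan(th) / wh)
            list(theta_c = atan(2 * pi * fc * tau_bar), feasible = FALSE)
          })
        }
        phase_c[i, j] <- r$theta_c
        flags[i, j] <- if (isTRUE(r$feasible)) 0L else 1L
      } else if (is.finite(th_a)) {
        tau <- tan(th_a) / (2 * pi * f1)
        phase_c[i, j] <- atan(2 * pi * fc * tau)
        flags[i, j] <- 2L
      } else if (is.finite(th_b) && is.finite(f2)) {
        tau <- tan(th_b) / (2 * pi * f2)
        phase_c[i, j] <- atan(2 * pi * fc * tau)
        flags[i, j] <- 2L
      }
    }
  }
  list(fluorescence = fluor, phase_at_center = phase_c, flags = flags,
       center_frequency_hz = fc)
}

#' Convert phase to phase lifetime
#'
#' `tau = tan(theta) / (2 pi f_center)`. Phases outside \[0, pi/2) are
#' unresolvable at this frequency and map to NA rather than raising an
#' error.
#'
#' @param phase phase(s) in radians.
#' @param center_frequency_hz modulation frequency in Hz.
#' @return lifetime(s) in seconds, NA where the phase is out of range.
#' @examples
#' phase_to_lifetime(pi / 4, 121.484375e6) * 1e9  # ~1.31 ns
#' @export
phase_to_lifetime <- function(phase, center_frequency_hz) {
  out <- tan(phase) / (2 * pi * center_frequency_hz)
  out[!is.finite(phase) | phase < 0 | phase >= pi / 2] <- NA_real_
  out
}

#' Threshold segmentation relative to the image maximum
#'
#' `mask = intensity >= max(intensity) / divisor`; the instrument's presets
#' are divisors 2.5, 3.5 and 4.5. An all-zero image yields an empty mask.
#'
#' @param intensity 2-D image.
#' @param divisor threshold divisor (> 1).
#' @return logical mask of the same shape.
#' @export
segment_image <- function(intensity, divisor = 2.5) {
  if (divisor <= 1) stop("divisor must be > 1")
  mx <- suppressWarnings(max(intensity, na.rm = TRUE))
  if (!is.finite(mx) || mx <= 0) {
    return(matrix(FALSE, nrow(intensity), ncol(intensity)))
  }
  m <- !is.na(intensity) & intensity >= mx / divisor
  m
}

#' Reconstruction options
#'
#' @param median_filter 3x3 median filter on interpolated phase images.
#' @param two_component equal-weight two-component phase superposition
#'   (fallback averaging where infeasible).
#' @param subband_cut baseband low-pass fraction, see [demultiplex_lines()].
#' @param max_shift registration search radius (doubled grid), or NULL for
#'   the default.
#' @param segmentation_divisor divisor used for the "empty event" check.
#' @return list of class `flim_recon_options`.
#' @export
reconstruct_options <- function(median_filter = TRUE, two_component = TRUE,
                                subband_cut = 0.45, max_shift = NULL,
                                segmentation_divisor = 2.5) {
  structure(list(median_filter = isTRUE(median_filter),
                 two_component = isTRUE(two_component),
                 subband_cut = subband_cut, max_shift = max_shift,
                 segmentation_divisor = segmentation_divisor),
            class = "flim_recon_options")
}

#' Reconstruct one event into BF / FL / LT images
#'
#' Full chain: demultiplex all four channels; bright-field = concatenated
#' moduli of the transmitted-channel lines (2x up-sampled to share the
#' output grid); assemble the calibrated fluorescence image pair; register;
#' superpose with the two-component phase model; convert the superposed
#' phase to lifetime in ns.
#'
#' @param event a [simulate_event()] raw event (or one read back from disk).
#' @param plan the modulation plan.
#' @param calibration a calibration table.
#' @param options a [reconstruct_options()] list.
#' @return object of class `flim_event` with `bright_field`,
#'   `fluorescence`, `lifetime_ns` (all on the doubled grid),
#'   `registration_offset`, per-pixel `flags` (see [superpose_pair()]),
#'   `empty` flag and the native-resolution `pair` for diagnostics.
#' @export
reconstruct_event <- function(event, plan, calibration,
                              options = reconstruct_options()) {
  stopifnot(inherits(event, "flim_raw_event"), inherits(plan, "flim_plan"))
  fs <- event$sampling_rate_hz
  lt_tr <- demultiplex_lines(event$transmitted, plan, fs, options$subband_cut, channel = "transmitted")
  la <- demultiplex_lines(event$fluorescence_a, plan, fs, options$subband_cut, channel = "fluorescence_a")
  lb <- demultiplex_lines(event$fluorescence_b, plan, fs, options$subband_cut, channel = "fluorescence_b")
  lr <- demultiplex_lines(event$reference, plan, fs, options$subband_cut, channel = "reference")
  bright <- interp2x(Mod(unclass(lt_tr)))
  pair <- assemble_image_pair(la, lb, lr, calibration)
  offset <- if (max(pair$amplitude_a) <= 0 || max(pair$amplitude_b) <= 0) {
    c(0L, 0L)   # nothing to register in an empty event
  } else {
    register_image_pair(pair, options$max_shift)
  }
  sup <- superpose_pair(pair, offset,
                        assume_two_components = options$two_component,
                        median_filter = options$median_filter)
  lifetime_ns <- phase_to_lifetime(sup$phase_at_center,
                                   sup$center_frequency_hz) * 1e9
  mask <- segment_image(sup$fluorescence, options$segmentation_divisor)
  structure(list(bright_field = bright,
                 fluorescence = sup$fluorescence,
                 lifetime_ns = lifetime_ns,
                 registration_offset = offset,
                 flags = sup$flags,
                 empty = !any(mask),
                 pair = pair,
                 center_frequency_hz = sup$center_frequency_hz,
                 options = options,
                 timestamp_s = event$timestamp_s,
                 label = event$label),
            class = "flim_event")
}

#' @export
print.flim_event <- function(x, ...) {
  cat(sprintf("<flim_event> '%s' %d x %d px, offset (%d, %d)%s\n",
              x$label, nrow(x$lifetime_ns), ncol(x$lifetime_ns),
              x$registration_offset[1], x$registration_offset[2],
              if (x$empty) ", EMPTY" else ""))
  lt <- x$lifetime_ns[segment_image(x$fluorescence, x$options$segmentation_divisor)]
  if (length(lt) && any(is.finite(lt))) {
    cat(sprintf("  in-object lifetime %.3f ns (mean of %d px)\n",
                mean(lt, na.rm = TRUE), sum(is.finite(lt))))
  }
  invisible(x)
}

#' @export
plot.flim_event <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  show <- function(m, main, col) {
    m[is.na(m)] <- min(m, na.rm = TRUE)
    image(t(m)[, nrow(m):1, drop = FALSE], axes = FALSE, col = col, main = main)
  }
  show(x$bright_field, "BF", gray.colors(64))
  show(x$fluorescence, "FL", hcl.colors(64, "viridis"))
  show(x$lifetime_ns, "LT [ns]", hcl.colors(64, "plasma"))
  invisible(x)
}

#' Batch reconstruction of an event stream
#'
#' Per-event failures are logged as warnings and skipped.
#'
#' @param stream a [simulate_stream()] result (or list of raw events).
#' @inheritParams reconstruct_event
#' @return list of `flim_event` objects.
#' @export
reconstruct_stream <- function(stream, plan, calibration,
                               options = reconstruct_options()) {
  events <- if (inherits(stream, "flim_event_stream")) stream$events else stream
  out <- list()
  for (i in seq_along(events)) {
    r <- tryCatch(reconstruct_event(events[[i]], plan, calibration, options),
                  error = function(e) {
                    warning("event ", i, " skipped: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(r)) out[[length(out) + 1L]] <- r
  }
  out
}

#' Single-array phase lifetime image
#'
#' Lifetime computed per column from one channel's phase at that column's
#' own modulation frequency (native resolution, no superposition). For
#' non-mono-exponential emitters this estimate varies across the field of
#' view with the column frequency -- the disparity the complementary-pair
#' superposition removes.
#'
#' @param pair a [assemble_image_pair()] result.
#' @param which `"a"` or `"b"`.
#' @return lifetime image in ns (native grid).
#' @export
single_array_lifetime <- function(pair, which = c("a", "b")) {
  which <- match.arg(which)
  ph <- if (which == "a") pair$phase_a else pair$phase_b
  # channel B is stored in frequency order, so its stored column k is
  # modulated at frequency_map_a[k] for both channels
  f <- matrix(pair$frequency_map_a, nrow(ph), ncol(ph), byrow = TRUE)
  tau <- tan(ph) / (2 * pi * f)
  tau[!is.finite(ph) | ph < 0 | ph >= pi / 2] <- NA_real_
  tau * 1e9
}
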
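# Phantom objects: 2-D models of beads and cells carried past the beam line
# by the flow. Columns map one-to-one to beam positions (0.8 um pitch by
# default); rows are swept by the flow, one row per line period when
# flow_speed = pixel_pitch * line_rate (3.28125 m/s at the default plan,
# within the instrument's 1-3.5 m/s operating range).

#' Multi-exponential lifetime components
#'
#' @param alpha intensity-weighted fractions (>= 0, summing to 1).
#' @param tau lifetimes in seconds (>= 0), same length as `alpha`.
#' @return object of class `flim_lifetime_components`.
#' @examples
#' lifetime_components(c(0.5, 0.5), c(1e-9, 4e-9))
#' @export
lifetime_components <- function(alpha, tau) {
  stopifnot(length(alpha) == length(tau), length(alpha) >= 1L)
  if (any(alpha < 0) || any(tau < 0)) stop("alpha and tau must be non-negative")
  if (abs(sum(alpha) - 1) > 1e-9) stop("alpha fractions must sum to 1")
  structure(list(alpha = as.numeric(alpha), tau = as.numeric(tau)),
            class = "flim_lifetime_components")
}

#' Construct a phantom
#'
#' Low-level constructor; most users call [make_bead_phantom()] or
#' [make_cell_phantom()]. The per-pixel decay model is stored as fraction
#' and lifetime arrays of shape rows x cols x n_components.
#'
#' @param brightness non-negative matrix of fluorophore emission strength.
#' @param transmittance matrix in \[0, 1\] for the bright-field channel.
#' @param tau per-pixel lifetimes: a matrix (mono-exponential) or an array
#'   rows x cols x L.
#' @param alpha per-pixel fractions matching `tau`; defaults to a single
#'   component of weight 1 when `tau` is a matrix.
#' @param pixel_pitch_m pixel pitch in meters (beam-spot spacing).
#' @param flow_speed_m_s flow speed in m/s (> 0).
#' @param label free-text label.
#' @return object of class `flim_phantom`.
#' @export
flim_phantom <- function(brightness, transmittance, tau, alpha = NULL,
                         pixel_pitch_m = 0.8e-6, flow_speed_m_s = 3.28125,
                         label = "phantom") {
  brightness <- as.matrix(brightness)
  transmittance <- as.matrix(transmittance)
  if (is.matrix(tau)) tau <- array(tau, c(dim(tau), 1L))
  if (is.null(alpha)) alpha <- array(1, dim(tau))
  if (is.matrix(alpha)) alpha <- array(alpha, c(dim(alpha), 1L))
  if (!all(dim(brightness) == dim(transmittance)) ||
      !all(dim(brightness) == dim(tau)[1:2]) ||
      !all(dim(tau) == dim(alpha))) {
    stop("shape error: brightness, transmittance and lifetime grids must agree")
  }
  if (any(brightness < 0)) stop("brightness must be non-negative")
  if (any(transmittance < 0 | transmittance > 1)) stop("transmittance must lie in [0, 1]")
  if (flow_speed_m_s <= 0) stop("flow_speed must be > 0")
  asum <- apply(alpha, c(1, 2), sum)
  if (any(abs(asum - 1) > 1e-9)) stop("per-pixel alpha fractions must sum to 1")
  structure(list(brightness = brightness, transmittance = transmittance,
                 tau = tau, alpha = alpha,
                 pixel_pitch_m = pixel_pitch_m,
                 flow_speed_m_s = flow_speed_m_s, label = label),
            class = "flim_phantom")
}

#' @export
print.flim_phantom <- function(x, ...) {
  cat(sprintf("<flim_phantom> '%s' %d x %d px, %d lifetime component(s), flow %.3f m/s\n",
              x$label, nrow(x$brightness), ncol(x$brightness), dim(x$tau)[3],
              x$flow_speed_m_s))
  invisible(x)
}

disk_mask <- function(nr, nc, center, diameter) {
  r <- matrix(seq_len(nr), nr, nc) - center[1]
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  sqrt(r^2 + c^2) <= diameter / 2
}

#' Uniform-lifetime bead phantom
#'
#' A disk of uniform mono-exponential lifetime, emulating the polymer
#' calibration beads (nominal lifetimes 1.72, 2.71 and 5.54 ns).
#'
#' @param diameter_pixels bead diameter in pixels.
#' @param tau_s mono-exponential lifetime in seconds.
#' @param brightness in-disk emission strength (arbitrary units).
#' @param field c(rows, cols) grid size; defaults to 84 rows (one event at
#'   the default line rate) by `diameter_pixels + 4` columns.
#' @param transmittance_object in-disk transmittance (beads attenuate the
#'   transmitted beam; background is fully transmitting).
#' @param seed unused placeholder for API symmetry (the bead is
#'   deterministic); kept so stream factories can thread a seed through.
#' @inheritParams flim_phantom
#' @return a `flim_phantom`.
#' @export
make_bead_phantom <- function(diameter_pixels, tau_s, brightness = 1,
                              field = c(84L, diameter_pixels + 4L),
                              transmittance_object = 0.3,
                              pixel_pitch_m = 0.8e-6,
                              flow_speed_m_s = 3.28125, seed = NULL) {
  if (diameter_pixels < 1) stop("shape error: diameter must be >= 1 pixel")
  if (any(field < diameter_pixels)) stop("shape error: field smaller than bead")
  nr <- field[1]; nc <- field[2]
  m <- disk_mask(nr, nc, c((nr + 1) / 2, (nc + 1) / 2), diameter_pixels)
  flim_phantom(brightness = ifelse(m, brightness, 0),
               transmittance = ifelse(m, transmittance_object, 1),
               tau = matrix(ifelse(m, tau_s, 0), nr, nc),
               pixel_pitch_m = pixel_pitch_m, flow_speed_m_s = flow_speed_m_s,
               label = sprintf("bead d=%g tau=%.3gns", diameter_pixels, tau_s * 1e9))
}

#' Cell phantom with a prescribed nuclear lifetime gradient
#'
#' A cell body (visible in the bright-field channel) containing a stained
#' nucleus whose lifetime varies linearly with the normalized edge-to-center
#' distance. The linear coefficient is chosen so that the four-ring
#' fractional-lifetime gradient statistic ([ring_lifetime_gradient()]) of
#' the noiseless lifetime map equals `gradient_percent` exactly by
#' construction; `gradient_percent = 0` gives a uniform nucleus.
#'
#' @param cell_diameter,nucleus_diameter diameters in pixels; the nucleus
#'   must fit inside the cell.
#' @param nucleus_tau_s mean nuclear lifetime in seconds (the whole-nucleus
#'   mean is preserved for any gradient).
#' @param gradient_percent target periphery-to-center lifetime gradient in
#'   percent (positive = longer lifetime at the center).
#' @param brightness in-nucleus emission strength.
#' @param field c(rows, cols) grid size.
#' @param transmittance_cell in-cell transmittance for the bright-field
#'   channel.
#' @param seed unused placeholder (deterministic geometry), as in
#'   [make_bead_phantom()].
#' @inheritParams flim_phantom
#' @return a `flim_phantom`.
#' @export
make_cell_phantom <- function(cell_diameter, nucleus_diameter,
                              nucleus_tau_s = 3e-9, gradient_percent = 0,
                              brightness = 1,
                              field = c(84L, cell_diameter + 4L),
                              transmittance_cell = 0.3,
                              pixel_pitch_m = 0.8e-6,
                              flow_speed_m_s = 3.28125, seed = NULL) {
  if (nucleus_diameter > cell_diameter) {
    stop("shape error: nucleus must fit inside the cell")
  }
  if (any(field < cell_diameter)) stop("shape error: field smaller than cell")
  nr <- field[1]; nc <- field[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  cell <- disk_mask(nr, nc, ctr, cell_diameter)
  nuc <- disk_mask(nr, nc, ctr, nucleus_diameter)
  tau <- matrix(0, nr, nc)
  if (gradient_percent == 0) {
    tau[nuc] <- nucleus_tau_s
  } else {
    dn <- edge_distance_norm(nuc)
    if (isTRUE(attr(dn, "degenerate"))) {
      stop("shape error: nucleus too small to carry a radial gradient")
    }
    dpix <- dn[nuc]
    ring <- ring_index(dpix, 4L)
    m_i <- tapply(dpix, ring, mean)
    if (length(m_i) < 4L || any(is.na(m_i))) {
      stop("shape error: nucleus too small to form 4 rings")
    }
    x <- ring_centers(4L)
    beta <- sum((x - mean(x)) * (m_i - mean(m_i))) / sum((x - mean(x))^2)
    a <- (gradient_percent / 100) / ((x[4] - x[1]) * beta)
    tau[nuc] <- nucleus_tau_s * (1 + a * (dpix - mean(dpix)))
    if (any(tau[nuc] <= 0)) {
      stop("gradient too steep: constructed lifetimes become non-positive")
    }
  }
  flim_phantom(brightness = ifelse(nuc, brightness, 0),
               transmittance = ifelse(cell, transmittance_cell, 1),
               tau = tau,
               pixel_pitch_m = pixel_pitch_m, flow_speed_m_s = flow_speed_m_s,
               label = sprintf("cell d=%g nucleus d=%g grad=%g%%",
                               cell_diameter, nucleus_diameter, gradient_percent))
}

# ring index 1 (outermost) .. n (innermost) from normalized distance in [0,1]
ring_index <- function(dnorm, n_rings = 4L) {
  idx <- pmin(floor(dnorm * n_rings) + 1L, n_rings)
  as.integer(idx)
}

ring_centers <- function(n_rings = 4L) (seq_len(n_rings) - 0.5) / n_rings
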
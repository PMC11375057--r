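# Downstream statistics: per-object features, the nuclear ring lifetime
# gradient, effect sizes, event-rate and data-rate accounting.

#' Extract per-object features from a reconstructed event
#'
#' Cells are segmented on the bright-field image (objects attenuate the
#' transmitted beam, so the cell mask is the region darker than
#' `max / cell_divisor`); nuclei on the fluorescence-intensity image
#' (brighter than `max / nucleus_divisor`, followed by one binary closing
#' with a 3x3 element). Connected components are labelled; when several
#' nuclei fall inside one cell, `n_nuclei` is recorded and the nucleus with
#' the smaller eccentricity is used for nucleus morphology. Means and
#' pixel CVs are computed over in-mask pixels; undefined lifetime pixels
#' are excluded.
#'
#' @param flim_event a [reconstruct_event()] result.
#' @param cell_divisor bright-field threshold divisor.
#' @param nucleus_divisor fluorescence threshold divisor (preset 3.5).
#' @return data frame, one row per cell, with morphology, intensity,
#'   lifetime, pixel-CV, ring-gradient and nucleus-count columns. Empty
#'   events yield a zero-row frame.
#' @export
extract_objects <- function(flim_event, cell_divisor = 2.5,
                            nucleus_divisor = 3.5) {
  stopifnot(inherits(flim_event, "flim_event"))
  bf <- flim_event$bright_field
  fl <- flim_event$fluorescence
  lt <- flim_event$lifetime_ns
  cols <- c("object_id", "area", "eccentricity", "compactness",
            "mean_transmitted", "mean_fluorescence", "mean_lifetime_ns",
            "cv_fluorescence_pixels", "cv_lifetime_pixels",
            "lifetime_gradient_percent", "n_nuclei",
            "nucleus_area", "nucleus_eccentricity", "nucleus_compactness")
  empty <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  mx_bf <- suppressWarnings(max(bf, na.rm = TRUE))
  if (!is.finite(mx_bf) || mx_bf <= 0) return(empty)
  cell_mask <- !is.na(bf) & bf <= mx_bf / cell_divisor
  nuc_mask <- segment_image(fl, nucleus_divisor)
  nuc_mask <- as.matrix(EBImage::closing(
    matrix(as.numeric(nuc_mask), nrow(nuc_mask), ncol(nuc_mask)),
    EBImage::makeBrush(3, "box"))) > 0
  if (!any(cell_mask)) return(empty)
  cell_lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(cell_mask), nrow(cell_mask), ncol(cell_mask))))
  nuc_lab <- as.matrix(EBImage::bwlabel(matrix(as.numeric(nuc_mask), nrow(nuc_mask), ncol(nuc_mask))))
  rows <- list()
  for (id in seq_len(max(cell_lab))) {
    cm <- cell_lab == id
    shp <- mask_shape(cm)
    nuc_ids <- setdiff(unique(nuc_lab[cm & nuc_lab > 0]), 0)
    n_nuc <- length(nuc_ids)
    nshp <- list(area = NA_real_, eccentricity = NA_real_, compactness = NA_real_)
    grad <- NA_real_
    cvf <- cvl <- mlt <- mfl <- NA_real_
    if (n_nuc > 0) {
      shapes <- lapply(nuc_ids, function(nid) mask_shape(nuc_lab == nid))
      eccs <- vapply(shapes, `[[`, numeric(1), "eccentricity")
      pick <- which.min(eccs)
      nshp <- shapes[[pick]]
      nm <- nuc_lab == nuc_ids[pick]
      flv <- fl[nm]; ltv <- lt[nm]
      mfl <- mean(flv[is.finite(flv)])
      mlt <- mean(ltv[is.finite(ltv)])
      cvf <- cv_percent(flv)
      cvl <- cv_percent(ltv)
      gr <- ring_lifetime_gradient(lt, nm)
      grad <- gr$gradient_percent
    }
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = id, area = shp$area, eccentricity = shp$eccentricity,
      compactness = shp$compactness,
      mean_transmitted = mean(bf[cm], na.rm = TRUE),
      mean_fluorescence = mfl, mean_lifetime_ns = mlt,
      cv_fluorescence_pixels = cvf, cv_lifetime_pixels = cvl,
      lifetime_gradient_percent = grad, n_nuclei = n_nuc,
      nucleus_area = as.numeric(nshp$area),
      nucleus_eccentricity = nshp$eccentricity,
      nucleus_compactness = nshp$compactness)
  }
  do.call(rbind, rows)
}

#' Ring lifetime gradient from nuclear periphery to center
#'
#' The nucleus is divided into 4 ring-shaped regions of equal normalized
#' edge-to-center distance (ring 1 = outermost). The fractional value of
#' each ring is its mean lifetime divided by the whole-nucleus mean; a
#' least-squares line through the 4 fractional values at the ring centers
#' (normalized distances 0.125, 0.375, 0.625, 0.875) gives the gradient:
#' (fitted value at the innermost center minus fitted value at the
#' outermost center) x 100, in percent. Positive gradients mean the
#' nucleus center has a longer lifetime than its periphery.
#'
#' @param lifetime_image lifetime image (any positive scaling; the
#'   fractional normalization removes global scale).
#' @param nucleus_mask logical mask of the nucleus.
#' @param n_rings number of rings (4 in the standard analysis).
#' @return object of class `flim_gradient`: list with `fractional_values`
#'   (outermost to innermost), `fit_slope`, `fit_intercept`,
#'   `gradient_percent` and `defined` (FALSE when the mask cannot form the
#'   rings, in which case the numeric fields are NA).
#' @export
ring_lifetime_gradient <- function(lifetime_image, nucleus_mask, n_rings = 4L) {
  nucleus_mask <- nucleus_mask != 0
  undefined <- structure(list(fractional_values = rep(NA_real_, n_rings),
                              fit_slope = NA_real_, fit_intercept = NA_real_,
                              gradient_percent = NA_real_, defined = FALSE),
                         class = "flim_gradient")
  if (!any(nucleus_mask)) return(undefined)
  dn <- edge_distance_norm(nucleus_mask)
  if (isTRUE(attr(dn, "degenerate"))) return(undefined)
  vals <- lifetime_image[nucleus_mask != 0]
  dv <- dn[nucleus_mask != 0]
  ok <- is.finite(vals) & is.finite(dv)
  vals <- vals[ok]; dv <- dv[ok]
  if (length(unique(round(dv, 12))) < n_rings) return(undefined)
  ring <- ring_index(dv, n_rings)
  if (length(unique(ring)) < n_rings) return(undefined)
  overall <- mean(vals)
  if (overall == 0) return(undefined)
  frac <- as.numeric(tapply(vals, factor(ring, levels = seq_len(n_rings)), mean)) / overall
  x <- ring_centers(n_rings)
  sl <- sum((x - mean(x)) * (frac - mean(frac))) / sum((x - mean(x))^2)
  ic <- mean(frac) - sl * mean(x)
  structure(list(fractional_values = frac, fit_slope = sl, fit_intercept = ic,
                 gradient_percent = sl * (x[n_rings] - x[1]) * 100,
                 defined = TRUE),
            class = "flim_gradient")
}

#' @export
print.flim_gradient <- function(x, ...) {
  if (!x$defined) {
    cat("<flim_gradient> undefined (mask too small)\n")
  } else {
    cat(sprintf("<flim_gradient> %+.2f%% (fractional values: %s)\n",
                x$gradient_percent,
                paste(sprintf("%.4f", x$fractional_values), collapse = ", ")))
  }
  invisible(x)
}

#' Cohen's d with its standard error
#'
#' Pooled-SD standardized mean difference
#' `d = (M_1 - M_2) / sqrt(((n_1 - 1) SD_1^2 + (n_2 - 1) SD_2^2) / (n_1 + n_2 - 2))`
#' and its standard error
#' `se = sqrt(((n - 1) / (n - 3)) * (4 / n) * (1 + d^2 / 8))` with
#' `n = n_1 + n_2`.
#'
#' @param sample_1,sample_2 numeric vectors (each of length >= 2).
#' @return object of class `flim_effect_size`: list with `d`, `se`, means,
#'   SDs and sample sizes; `d` is NA (flagged undefined) when the pooled
#'   SD is zero.
#' @examples
#' cohens_d(c(0, 2), c(-1, 1))$d  # 1 / sqrt(2)
#' @export
cohens_d <- function(sample_1, sample_2) {
  sample_1 <- sample_1[is.finite(sample_1)]
  sample_2 <- sample_2[is.finite(sample_2)]
  n1 <- length(sample_1); n2 <- length(sample_2)
  if (n1 < 2L || n2 < 2L) stop("each sample needs >= 2 finite values")
  m1 <- mean(sample_1); m2 <- mean(sample_2)
  s1 <- sd(sample_1); s2 <- sd(sample_2)
  pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  d <- if (pooled == 0) NA_real_ else (m1 - m2) / pooled
  n <- n1 + n2
  se <- if (is.na(d) || n <= 3L) NA_real_ else
    sqrt(((n - 1) / (n - 3)) * (4 / n) * (1 + d^2 / 8))
  structure(list(d = d, se = se, n_1 = n1, n_2 = n2,
                 M_1 = m1, M_2 = m2, SD_1 = s1, SD_2 = s2),
            class = "flim_effect_size")
}

#' @export
print.flim_effect_size <- function(x, ...) {
  cat(sprintf("<flim_effect_size> d = %.4f (se %.4f), n = %d vs %d\n",
              x$d, x$se, x$n_1, x$n_2))
  invisible(x)
}

#' Event-rate statistics of a triggered stream
#'
#' The event rate proper counts only images containing at least one
#' recognizable object (eccentricity below the gate: presets 0.6 for beads,
#' 0.72 for cells), each image at most once; the mean rate counts all
#' triggers. Instantaneous rates cover consecutive blocks of 100 events.
#' The inter-arrival histogram above the dead time is fitted with an
#' exponential by least absolute residuals.
#'
#' @param arrival_times trigger times in seconds (strictly increasing).
#' @param recognizable logical per event: does its image contain a
#'   recognizable object? (See [is_recognizable()].)
#' @param total_duration_s elapsed acquisition time; defaults to the last
#'   arrival time.
#' @param window events per instantaneous-rate block.
#' @param bin_width_s histogram bin width for the exponential fit (5 us as
#'   in the instrument characterization).
#' @param dead_time_s gaps below this are excluded from the fit.
#' @return object of class `flim_rate_report`.
#' @export
event_rate_stats <- function(arrival_times, recognizable,
                             total_duration_s = NULL, window = 100L,
                             bin_width_s = 5e-6, dead_time_s = 0) {
  n <- length(arrival_times)
  if (n == 0L) stop("empty stream")
  stopifnot(length(recognizable) == n)
  if (is.null(total_duration_s)) total_duration_s <- arrival_times[n]
  if (total_duration_s <= 0) stop("zero elapsed time")
  inst <- numeric(0)
  if (n >= window) {
    starts <- seq.int(1L, n - window + 1L, by = window)
    inst <- vapply(starts, function(s) {
      span <- arrival_times[s + window - 1L] - arrival_times[s]
      if (span > 0) window / span else NA_real_
    }, numeric(1))
  }
  gaps <- diff(arrival_times)
  fit <- list(rate = NA_real_, amplitude = NA_real_, residual = NA_real_)
  g <- gaps[gaps >= dead_time_s]
  if (length(g) >= 20L) {
    br <- seq(dead_time_s, max(g) + bin_width_s, by = bin_width_s)
    cnt <- tabulate(findInterval(g, br), nbins = length(br) - 1L)
    mid <- head(br, -1L) + bin_width_s / 2
    use <- cnt > 0
    if (sum(use) >= 3L) {
      l1 <- function(par) sum(abs(cnt[use] - exp(par[1]) * exp(-exp(par[2]) * (mid[use] - dead_time_s))))
      init <- c(log(max(cnt)), log(1 / max(mean(g - dead_time_s), 1e-9)))
      op <- optim(init, l1)
      fit <- list(rate = exp(op$par[2]), amplitude = exp(op$par[1]),
                  residual = op$value)
    }
  }
  structure(list(actual_rate_eps = sum(recognizable) / total_duration_s,
                 mean_rate_eps = n / total_duration_s,
                 instantaneous_rates_eps = inst,
                 n_events = n, n_recognizable = sum(recognizable),
                 inter_arrival_fit = fit,
                 total_duration_s = total_duration_s),
            class = "flim_rate_report")
}

#' @export
print.flim_rate_report <- function(x, ...) {
  cat(sprintf("<flim_rate_report> %d events in %.4g s: mean %.1f eps, actual %.1f eps\n",
              x$n_events, x$total_duration_s, x$mean_rate_eps, x$actual_rate_eps))
  invisible(x)
}

#' Recognizability of an event's objects
#'
#' @param features an [extract_objects()] frame for one event.
#' @param eccentricity_gate maximum eccentricity (presets: 0.6 beads, 0.72
#'   cells).
#' @return TRUE when at least one object passes the gate.
#' @export
is_recognizable <- function(features, eccentricity_gate = 0.6) {
  nrow(features) > 0 && any(is.finite(features$eccentricity) &
                              features$eccentricity < eccentricity_gate)
}

#' Digital data-generation rate
#'
#' The effective acquisition time of one event is the flow-direction pixel
#' count divided by the line rate; at 1 byte per sample (8-bit digitizer)
#' this gives `floor(effective_time * sampling_rate)` bytes per event and
#' channel, and the data rate is
#' `event_rate x bytes_per_event x n_channels / 2^20` MB/s.
#'
#' @param event_rate_eps event rate in events/s.
#' @param pixels_flow flow-direction pixels per event image.
#' @param line_rate_hz line acquisition rate (default: the instrument's
#'   4.1015625 MHz).
#' @param sampling_rate_hz digitizer rate (default 1.25 GS/s).
#' @param n_channels image channels (default 3: BF, FL, LT).
#' @return list with `effective_event_time_s`, `bytes_per_event` and
#'   `data_rate_mb_s` (MB = 2^20 bytes).
#' @examples
#' data_generation_rate(11297, 11)$data_rate_mb_s  # ~108.3
#' @export
data_generation_rate <- function(event_rate_eps, pixels_flow,
                                 line_rate_hz = 4.1015625e6,
                                 sampling_rate_hz = 1.25e9, n_channels = 3L) {
  if (pixels_flow <= 0 || line_rate_hz <= 0 || sampling_rate_hz <= 0 ||
      n_channels <= 0 || event_rate_eps < 0) {
    stop("all inputs must be positive (event rate >= 0)")
  }
  t_eff <- pixels_flow / line_rate_hz
  bytes <- floor(t_eff * sampling_rate_hz)
  list(effective_event_time_s = t_eff,
       bytes_per_event = bytes,
       data_rate_mb_s = event_rate_eps * bytes * n_channels / 2^20)
}

#' Standardized lifetime display image
#'
#' Compensates the lifetime slope across the field of view by fitting and
#' removing a linear trend of in-mask lifetime versus column index (the
#' in-mask mean is preserved), applies a 3x3 median filter, and returns the
#' display bounds median +/- 1.6 IQR of the in-mask pixels.
#'
#' @param lifetime_image lifetime image (ns).
#' @param nucleus_mask logical mask.
#' @return list with `image` (slope-compensated, median-filtered),
#'   `scale_low`, `scale_high`, `slope_per_column` and `degenerate` (TRUE
#'   when the in-mask IQR is zero and the bounds collapse to the median).
#' @export
standardize_lifetime_image <- function(lifetime_image, nucleus_mask) {
  nucleus_mask <- nucleus_mask != 0
  if (!any(nucleus_mask)) stop("degenerate mask: no in-mask pixels")
  idx <- which(nucleus_mask != 0, arr.ind = TRUE)
  vals <- lifetime_image[nucleus_mask != 0]
  ok <- is.finite(vals)
  if (sum(ok) < 2L) stop("degenerate mask: fewer than 2 finite lifetime pixels")
  colc <- idx[ok, 2]
  slope <- if (length(unique(colc)) > 1L) {
    unname(coef(lm(vals[ok] ~ colc))[2])
  } else 0
  cols <- matrix(seq_len(ncol(lifetime_image)), nrow(lifetime_image),
                 ncol(lifetime_image), byrow = TRUE)
  comp <- lifetime_image - slope * (cols - mean(colc))
  comp <- median_filter3(comp)
  v <- comp[nucleus_mask != 0]
  v <- v[is.finite(v)]
  md <- median(v); iqr <- unname(quantile(v, 0.75) - quantile(v, 0.25))
  list(image = comp, scale_low = md - 1.6 * iqr, scale_high = md + 1.6 * iqr,
       slope_per_column = slope, degenerate = iqr == 0)
}

#' Percentage of multinucleate cells with Wilson 95% CI
#'
#' @param features an [extract_objects()] frame (or any frame with an
#'   `n_nuclei` column), one row per cell.
#' @return list with `percent`, `ci_low`, `ci_high` (Wilson score interval,
#'   all in percent) and `n`.
#' @export
multinucleate_fraction <- function(features) {
  n <- nrow(features)
  if (is.null(n) || n == 0L) stop("empty feature list")
  x <- sum(features$n_nuclei >= 2, na.rm = TRUE)
  p <- x / n
  z <- qnorm(0.975)
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(percent = 100 * p, ci_low = 100 * max(ctr - half, 0),
       ci_high = 100 * min(ctr + half, 1), n = n)
}
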
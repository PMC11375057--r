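# On-disk formats: raw-event container, image output, run configuration.

#' Write a raw-event stream to disk
#'
#' The container mirrors the acquisition layout: one group per event with
#' the four channel traces plus timestamp/rate attributes, the modulation
#' plan serialized as its YAML configuration, and the acquisition-config
#' snapshot. Stored via R-native serialization; [read_raw_events()] is the
#' bit-exact inverse.
#'
#' @param stream a [simulate_stream()] result.
#' @param path output file path.
#' @param plan plan override (defaults to `stream$plan`).
#' @return `path`, invisibly.
#' @export
write_raw_events <- function(stream, path, plan = stream$plan) {
  stopifnot(inherits(stream, "flim_event_stream"))
  events <- lapply(stream$events, function(ev) {
    list(transmitted = ev$transmitted, fluorescence_a = ev$fluorescence_a,
         fluorescence_b = ev$fluorescence_b, reference = ev$reference,
         timestamp_s = ev$timestamp_s, sampling_rate_hz = ev$sampling_rate_hz,
         event_duration_s = ev$event_duration_s, start_row = ev$start_row,
         n_beams = ev$n_beams, label = ev$label)
  })
  obj <- list(format = "flimflow-raw-events-v1",
              events = events,
              arrival_times = stream$arrival_times,
              total_duration_s = stream$total_duration_s,
              plan = plan_to_yaml(plan),
              config = unclass(stream$config))
  saveRDS(obj, path)
  invisible(path)
}

#' Read a raw-event stream from disk
#'
#' @param path file written by [write_raw_events()].
#' @return a `flim_event_stream`.
#' @export
read_raw_events <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "flimflow-raw-events-v1")) {
    stop("format error: ", path, " is not a raw-event container")
  }
  for (key in c("events", "plan", "config")) {
    if (is.null(obj[[key]])) stop("format error: ", path, " missing '", key, "'")
  }
  chans <- c("transmitted", "fluorescence_a", "fluorescence_b", "reference")
  events <- lapply(seq_along(obj$events), function(i) {
    ev <- obj$events[[i]]
    miss <- chans[!vapply(chans, function(ch) is.numeric(ev[[ch]]), logical(1))]
    if (length(miss)) {
      stop("format error: event ", i, " missing channel(s): ",
           paste(miss, collapse = ", "))
    }
    if (length(unique(vapply(chans, function(ch) length(ev[[ch]]), integer(1)))) != 1L) {
      stop("format error: event ", i, " channel lengths differ")
    }
    structure(ev, class = "flim_raw_event")
  })
  cfg <- structure(obj$config, class = "flim_config")
  structure(list(events = events, arrival_times = obj$arrival_times,
                 n_candidates = NA_integer_,
                 total_duration_s = obj$total_duration_s,
                 plan = plan_from_yaml(obj$plan), config = cfg),
            class = "flim_event_stream")
}

#' Write reconstructed images as multi-page TIFF
#'
#' One 3-page float TIFF per event (pages BF, FL, LT), or a single tiled
#' montage with one-pixel separator gutters when `montage = c(rows, cols)`
#' is given. TIFF float storage is defined on \[0, 1\], so each channel is
#' scaled by a fixed factor recorded in the JSON manifest
#' (`lt_scale_ns` for the lifetime page: stored value x scale = ns).
#'
#' @param events list of [reconstruct_event()] results.
#' @param path output directory (created if needed).
#' @param format `"tiff"` or `"ome-tiff"` (both written as plain multi-page
#'   TIFF by the installed writer; the manifest records the request).
#' @param montage NULL for per-event files, or c(rows, cols) to tile the
#'   lifetime images of `rows * cols` events into one image per channel.
#' @param bf_scale,fl_scale,lt_scale_ns channel scale factors.
#' @return the manifest (also written as `manifest.json` in `path`),
#'   invisibly.
#' @export
write_flim_images <- function(events, path, format = c("tiff", "ome-tiff"),
                              montage = NULL, bf_scale = NULL,
                              fl_scale = NULL, lt_scale_ns = 25) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(format = format, files = list(),
                   scales = list(lt_scale_ns = lt_scale_ns))
  if (length(events)) {
    if (is.null(bf_scale)) {
      bf_scale <- max(vapply(events, function(e) max(e$bright_field, 0, na.rm = TRUE), numeric(1)), 1e-12)
    }
    if (is.null(fl_scale)) {
      fl_scale <- max(vapply(events, function(e) max(e$fluorescence, 0, na.rm = TRUE), numeric(1)), 1e-12)
    }
    manifest$scales$bf_scale <- bf_scale
    manifest$scales$fl_scale <- fl_scale
    norm <- function(m, s) {
      m[!is.finite(m)] <- 0
      pmin(pmax(m / s, 0), 1)
    }
    if (is.null(montage)) {
      for (i in seq_along(events)) {
        ev <- events[[i]]
        fn <- file.path(path, sprintf("event_%04d.tif", i))
        tiff::writeTIFF(list(norm(ev$bright_field, bf_scale),
                             norm(ev$fluorescence, fl_scale),
                             norm(ev$lifetime_ns, lt_scale_ns)),
                        fn, bits.per.sample = 32L)
        manifest$files[[length(manifest$files) + 1L]] <-
          list(file = basename(fn), event = i, empty = ev$empty,
               offset = as.integer(ev$registration_offset))
      }
    } else {
      stopifnot(length(montage) == 2L)
      n_tiles <- montage[1] * montage[2]
      use <- events[seq_len(min(n_tiles, length(events)))]
      dims <- dim(use[[1]]$lifetime_ns)
      gut <- 1L
      big_nr <- montage[1] * dims[1] + (montage[1] - 1L) * gut
      big_nc <- montage[2] * dims[2] + (montage[2] - 1L) * gut
      pages <- list(bf = matrix(0, big_nr, big_nc),
                    fl = matrix(0, big_nr, big_nc),
                    lt = matrix(0, big_nr, big_nc))
      for (i in seq_along(use)) {
        tr <- (i - 1L) %/% montage[2]; tc <- (i - 1L) %% montage[2]
        rr <- tr * (dims[1] + gut) + seq_len(dims[1])
        cc <- tc * (dims[2] + gut) + seq_len(dims[2])
        pages$bf[rr, cc] <- norm(use[[i]]$bright_field, bf_scale)
        pages$fl[rr, cc] <- norm(use[[i]]$fluorescence, fl_scale)
        pages$lt[rr, cc] <- norm(use[[i]]$lifetime_ns, lt_scale_ns)
      }
      fn <- file.path(path, "montage.tif")
      tiff::writeTIFF(unname(pages), fn, bits.per.sample = 32L)
      manifest$files[[1L]] <- list(file = basename(fn),
                                   tiles = length(use),
                                   tile_rows = montage[1], tile_cols = montage[2],
                                   tile_dim = as.integer(dims))
    }
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a run configuration
#'
#' YAML with blocks `modulation_plan`, `acquisition`, `reconstruction`,
#' `analysis`, plus `seed`; unit-suffixed keys (`*_mhz`, `*_us`, `*_ns`)
#' are converted to SI on load. Unknown keys are rejected so that typos
#' fail loudly before any computation.
#'
#' @param path YAML file.
#' @return list of class `flim_run_config` with elements `plan`, `config`
#'   (acquisition), `recon_options`, `analysis` and `seed`.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  known_top <- c("modulation_plan", "acquisition", "reconstruction",
                 "analysis", "seed")
  unknown <- setdiff(names(obj), known_top)
  if (length(unknown)) stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(obj$modulation_plan)) stop("config error: missing key: modulation_plan")
  plan <- plan_from_yaml(yaml::as.yaml(obj["modulation_plan"], precision = 15L))
  acq <- obj$acquisition
  known_acq <- c("sampling_rate_gsps", "event_duration_us", "dead_time_us",
                 "noise_sd", "signal_dependent_noise", "trigger_threshold")
  unknown <- setdiff(names(acq), known_acq)
  if (length(unknown)) stop("config error: unknown acquisition key(s): ", paste(unknown, collapse = ", "))
  seed <- if (is.null(obj$seed)) 1L else as.integer(obj$seed)
  dur <- if (is.null(acq$event_duration_us)) 20.48 else acq$event_duration_us
  cfg <- acquisition_config(
    sampling_rate_hz = if (is.null(acq$sampling_rate_gsps)) 1.25e9 else acq$sampling_rate_gsps * 1e9,
    event_duration_s = dur * 1e-6,
    dead_time_s = if (is.null(acq$dead_time_us)) dur * 1e-6 else acq$dead_time_us * 1e-6,
    noise_sd = if (is.null(acq$noise_sd)) 0.01 else acq$noise_sd,
    signal_dependent_noise = isTRUE(acq$signal_dependent_noise),
    trigger_threshold = if (is.null(acq$trigger_threshold)) 0.1 else acq$trigger_threshold,
    seed = seed)
  rec <- obj$reconstruction
  known_rec <- c("median_filter", "two_component", "subband_cut_fraction")
  unknown <- setdiff(names(rec), known_rec)
  if (length(unknown)) stop("config error: unknown reconstruction key(s): ", paste(unknown, collapse = ", "))
  ropt <- reconstruct_options(
    median_filter = if (is.null(rec$median_filter)) TRUE else isTRUE(rec$median_filter),
    two_component = if (is.null(rec$two_component)) TRUE else isTRUE(rec$two_component),
    subband_cut = if (is.null(rec$subband_cut_fraction)) 0.45 else rec$subband_cut_fraction)
  ana <- obj$analysis
  known_ana <- c("cell_divisor", "nucleus_divisor", "eccentricity_gate")
  unknown <- setdiff(names(ana), known_ana)
  if (length(unknown)) stop("config error: unknown analysis key(s): ", paste(unknown, collapse = ", "))
  analysis <- list(
    cell_divisor = if (is.null(ana$cell_divisor)) 2.5 else ana$cell_divisor,
    nucleus_divisor = if (is.null(ana$nucleus_divisor)) 3.5 else ana$nucleus_divisor,
    eccentricity_gate = if (is.null(ana$eccentricity_gate)) 0.72 else ana$eccentricity_gate)
  structure(list(plan = plan, config = cfg, recon_options = ropt,
                 analysis = analysis, seed = seed),
            class = "flim_run_config")
}
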
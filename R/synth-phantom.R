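#' Acquisition configuration for the synthetic phantom simulator
#'
#' Describes one simulated acquisition campaign: a Gaussian-modulated UWB
#' pulse traverses a breast phantom from a transmit to a receive antenna;
#' a tumor of a given size at a given location adds a delayed, attenuated
#' echo. The defaults follow the measurement protocol the pipeline was
#' designed around: 1632 samples per signal, five tumor sizes (2-6 mm),
#' 27 tumor locations, 50 repetitions per placement (6750 tumor signals)
#' plus 750 tumor-free signals, pulse content centered at 4.3 GHz.
#'
#' The echo model is a declared stand-in, not electromagnetics: its
#' amplitude scales with the square of the tumor diameter (cross-section
#' -like scaling) damped exponentially with the extra path length, and its
#' delay is the Euclidean detour via the tumor divided by a fixed
#' propagation speed. Baseline drift is a deterministic low-frequency
#' (0.1-period) sinusoid across the window; measurement noise is additive
#' white Gaussian.
#'
#' @param n_points samples per signal (default 1632).
#' @param window_ns acquisition window in nanoseconds. The default 16.32 ns
#'   (100 GS/s) keeps the 4.3 GHz carrier far below Nyquist.
#' @param center_freq_ghz pulse carrier frequency in GHz.
#' @param tumor_sizes_mm tumor diameters in millimetres (all > 0).
#' @param locations_cm matrix (rows = locations) or data.frame with columns
#'   x, y, z in centimetres. Default: the 3 x 3 x 3 subgrid of the printed
#'   placement coordinates (x, y in {0.25, 3.25, 6.25}, z in {3, 4, 5}),
#'   i.e. 27 locations.
#' @param reps_per_point repeated acquisitions per (size, location).
#' @param n_tumor_free number of tumor-free records appended to the set.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   the same amplitude units as the pulse (peak 1).
#' @param drift_amplitude amplitude of the baseline-drift sinusoid.
#' @param rng_seed integer seed making the generated set reproducible.
#' @param pulse_sigma_ns Gaussian envelope width of the pulse.
#' @param pulse_center_ns envelope center of the transmitted pulse.
#' @param direct_delay_ns propagation delay of the direct (no-echo) path.
#' @param direct_atten amplitude attenuation of the direct path.
#' @param echo_gain echo amplitude per mm^2 of tumor diameter squared.
#' @param echo_atten_cm e-folding length of echo damping with path detour.
#' @param prop_speed_cm_ns propagation speed inside the phantom (cm/ns).
#' @param tx_cm,rx_cm transmit/receive antenna positions (x, y, z in cm).
#'
#' @return An object of class `acquisition_config`.
#' @export
#' @examples
#' cfg <- acquisition_config(tumor_sizes_mm = c(2, 6), reps_per_point = 2,
#'                           locations_cm = cbind(x = 3.25, y = 3.25, z = 4),
#'                           n_tumor_free = 2, n_points = 256, window_ns = 2.56)
#' ds <- generate_dataset(cfg)
#' nrow(ds$amplitude)  # 2 sizes x 1 location x 2 reps + 2 tumor-free = 6
acquisition_config <- function(n_points = 1632L,
                               window_ns = 16.32,
                               center_freq_ghz = 4.3,
                               tumor_sizes_mm = c(2, 3, 4, 5, 6),
                               locations_cm = default_locations(),
                               reps_per_point = 50L,
                               n_tumor_free = 750L,
                               noise_sd = 0.02,
                               drift_amplitude = 0.05,
                               rng_seed = 1L,
                               pulse_sigma_ns = 0.25,
                               pulse_center_ns = 2,
                               direct_delay_ns = 1,
                               direct_atten = 0.6,
                               echo_gain = 0.01,
                               echo_atten_cm = 5,
                               prop_speed_cm_ns = 11.3,
                               tx_cm = c(-0.5, 3.25, 4),
                               rx_cm = c(7.0, 3.25, 4)) {
  locations_cm <- as.matrix(locations_cm)
  if (ncol(locations_cm) != 3L) stopf("locations_cm must have 3 columns (x, y, z)")
  colnames(locations_cm) <- c("x", "y", "z")
  cfg <- list(n_points = as.integer(n_points), window_ns = window_ns,
              center_freq_ghz = center_freq_ghz,
              tumor_sizes_mm = as.numeric(tumor_sizes_mm),
              locations_cm = locations_cm,
              reps_per_point = as.integer(reps_per_point),
              n_tumor_free = as.integer(n_tumor_free),
              noise_sd = noise_sd, drift_amplitude = drift_amplitude,
              rng_seed = as.integer(rng_seed),
              pulse_sigma_ns = pulse_sigma_ns, pulse_center_ns = pulse_center_ns,
              direct_delay_ns = direct_delay_ns, direct_atten = direct_atten,
              echo_gain = echo_gain, echo_atten_cm = echo_atten_cm,
              prop_speed_cm_ns = prop_speed_cm_ns,
              tx_cm = as.numeric(tx_cm), rx_cm = as.numeric(rx_cm))
  class(cfg) <- "acquisition_config"
  validate_config(cfg)
  cfg
}

#' Default tumor placement grid
#'
#' The 27 default placements: a 3 x 3 x 3 subgrid of the printed
#' placement coordinates (x, y in 0.25/3.25/6.25 cm, z in 3/4/5 cm).
#'
#' @return 27 x 3 matrix with columns x, y, z (cm).
#' @export
default_locations <- function() {
  g <- expand.grid(x = c(0.25, 3.25, 6.25), y = c(0.25, 3.25, 6.25),
                   z = c(3, 4, 5))
  as.matrix(g)
}

validate_config <- function(config) {
  if (!inherits(config, "acquisition_config")) stopf("not an acquisition_config")
  if (config$n_points < 8L) stopf("n_points must be >= 8")
  if (!(config$window_ns > 0)) stopf("window_ns must be positive")
  if (config$reps_per_point < 1L) stopf("reps_per_point must be >= 1")
  if (any(config$tumor_sizes_mm <= 0)) stopf("all tumor sizes must be > 0")
  if (config$noise_sd < 0 || config$drift_amplitude < 0) {
    stopf("noise_sd and drift_amplitude must be non-negative")
  }
  invisible(config)
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat("<acquisition_config>\n")
  cat(sprintf("  %d points / %.4g ns, carrier %.3g GHz\n",
              x$n_points, x$window_ns, x$center_freq_ghz))
  cat(sprintf("  %d sizes x %d locations x %d reps + %d tumor-free = %d records\n",
              length(x$tumor_sizes_mm), nrow(x$locations_cm), x$reps_per_point,
              x$n_tumor_free, protocol_record_count(x)))
  cat(sprintf("  noise_sd %.3g, drift %.3g, seed %d\n",
              x$noise_sd, x$drift_amplitude, x$rng_seed))
  invisible(x)
}

# Record count implied by the acquisition protocol.
protocol_record_count <- function(config) {
  length(config$tumor_sizes_mm) * nrow(config$locations_cm) *
    config$reps_per_point + config$n_tumor_free
}

#' Time axis of a configured acquisition, in nanoseconds
#' @param config an [acquisition_config()].
#' @return numeric vector of length `n_points`.
#' @export
time_axis_ns <- function(config) {
  validate_config(config)
  seq(0, config$window_ns, length.out = config$n_points)
}

# Analytic transmitted pulse evaluated at arbitrary times (ns):
# Gaussian envelope modulating a cosine at the carrier frequency.
pulse_eval <- function(t_ns, config) {
  tc <- t_ns - config$pulse_center_ns
  exp(-tc^2 / (2 * config$pulse_sigma_ns^2)) *
    cos(2 * pi * config$center_freq_ghz * tc)
}

#' Transmitted UWB pulse
#'
#' Gaussian-modulated sinusoid sampled at `n_points` over `window_ns`,
#' whose magnitude-spectrum peak lies at `center_freq_ghz`. Deterministic
#' for a given configuration.
#'
#' @param config an [acquisition_config()].
#' @return numeric vector of length `config$n_points`.
#' @export
generate_pulse <- function(config) {
  validate_config(config)
  pulse_eval(time_axis_ns(config), config)
}

# Deterministic baseline drift: 0.1-period sinusoid across the window.
drift_term <- function(config) {
  config$drift_amplitude * sin(2 * pi * 0.1 * time_axis_ns(config) / config$window_ns)
}

# Extra path length (cm) of the scattering detour via `location_cm`.
path_detour_cm <- function(config, location_cm) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  d(config$tx_cm, location_cm) + d(location_cm, config$rx_cm) -
    d(config$tx_cm, config$rx_cm)
}

# Noise-free, drift-free received waveform for one placement.
received_clean <- function(config, size_mm, location_cm) {
  t_ns <- time_axis_ns(config)
  v <- config$direct_atten * pulse_eval(t_ns - config$direct_delay_ns, config)
  if (size_mm > 0) {
    detour <- path_detour_cm(config, location_cm)
    amp <- config$echo_gain * size_mm^2 * exp(-detour / config$echo_atten_cm)
    delay <- config$direct_delay_ns + detour / config$prop_speed_cm_ns
    v <- v + amp * pulse_eval(t_ns - delay, config)
  }
  v
}

#' Simulate one received forward-scattered signal
#'
#' The received record is an attenuated, delayed copy of the transmitted
#' pulse, plus (for `size_mm > 0`) a tumor echo whose amplitude increases
#' strictly with tumor size and whose delay is monotone in the path detour
#' implied by the location, plus additive Gaussian noise and the
#' deterministic baseline drift. Noise is drawn from the current RNG
#' stream; seed it (or use [generate_dataset()]) for reproducibility.
#'
#' @param config an [acquisition_config()].
#' @param size_mm tumor diameter in mm; 0 encodes tumor-free (no echo).
#' @param location_cm numeric (x, y, z) in cm; may be `NULL` for tumor-free.
#' @param rep repetition index stored in the record metadata.
#' @return A `signal_record`: list with `amplitude` (length `n_points`),
#'   `size_mm`, `location_cm` (or `NULL`), `rep`.
#' @export
generate_received <- function(config, size_mm, location_cm = NULL, rep = 1L) {
  validate_config(config)
  if (!(size_mm == 0 || size_mm %in% config$tumor_sizes_mm)) {
    stopf("unknown tumor size %s (must be 0 or one of the configured sizes)",
          format(size_mm))
  }
  if (size_mm > 0 && is.null(location_cm)) stopf("tumor records need a location")
  v <- received_clean(config, size_mm, location_cm) + drift_term(config)
  if (config$noise_sd > 0) v <- v + rnorm(config$n_points, sd = config$noise_sd)
  structure(list(amplitude = v, size_mm = size_mm,
                 location_cm = if (size_mm > 0) location_cm else NULL,
                 rep = as.integer(rep)),
            class = "signal_record")
}

#' Generate a full synthetic signal set under the acquisition protocol
#'
#' Iterates sizes (ascending) x locations (config order) x repetitions,
#' then appends `n_tumor_free` tumor-free records (the location loop is
#' reused for generation but the location is marked absent in the output).
#' Fully reproducible from `config$rng_seed`.
#'
#' @param config an [acquisition_config()].
#' @return A `signal_set`: list with `amplitude` (records x n_points
#'   matrix), `meta` (data.frame: size_mm, x, y, z, rep) and `config`.
#' @export
generate_dataset <- function(config) {
  validate_config(config)
  n_loc <- nrow(config$locations_cm)
  n_rec <- protocol_record_count(config)
  amp <- matrix(0, n_rec, config$n_points)
  meta <- data.frame(size_mm = numeric(n_rec), x = NA_real_, y = NA_real_,
                     z = NA_real_, rep = integer(n_rec))
  with_seed(config$rng_seed, {
    i <- 0L
    for (size in sort(config$tumor_sizes_mm)) {
      for (l in seq_len(n_loc)) {
        loc <- config$locations_cm[l, ]
        clean <- received_clean(config, size, loc) + drift_term(config)
        for (r in seq_len(config$reps_per_point)) {
          i <- i + 1L
          v <- clean
          if (config$noise_sd > 0) {
            v <- v + rnorm(config$n_points, sd = config$noise_sd)
          }
          amp[i, ] <- v
          meta$size_mm[i] <- size
          meta[i, c("x", "y", "z")] <- loc
          meta$rep[i] <- r
        }
      }
    }
    if (config$n_tumor_free > 0L) {
      clean0 <- received_clean(config, 0, NULL) + drift_term(config)
      for (j in seq_len(config$n_tumor_free)) {
        i <- i + 1L
        v <- clean0
        if (config$noise_sd > 0) {
          v <- v + rnorm(config$n_points, sd = config$noise_sd)
        }
        amp[i, ] <- v
        meta$size_mm[i] <- 0
        meta$rep[i] <- (j - 1L) %/% n_loc + 1L
      }
    }
  })
  structure(list(amplitude = amp, meta = meta, config = config),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> %d records x %d points (%d tumor, %d tumor-free)\n",
              nrow(x$amplitude), ncol(x$amplitude), sum(x$meta$size_mm > 0),
              sum(x$meta$size_mm == 0)))
  invisible(x)
}

#' Class labels of a signal set
#'
#' @param set a `signal_set`.
#' @return factor with levels `none`, `<size>mm` ... in ascending size order.
#' @export
signal_labels <- function(set) {
  size_factor(set$meta$size_mm, set$config$tumor_sizes_mm)
}

#' Write / read a signal set as a wide CSV
#'
#' One row per record: metadata columns (`size_mm`, `x`, `y`, `z`, `rep`)
#' followed by one column per amplitude sample (`a1` ... `a<n_points>`).
#' The round trip is lossless for metadata and within double precision for
#' amplitudes. The acquisition config is stored alongside as
#' `<path>.config.json`.
#'
#' @param set a `signal_set`.
#' @param path output CSV path.
#' @return `write_signal_set`: `path`, invisibly. `read_signal_set`: a
#'   `signal_set`.
#' @export
write_signal_set <- function(set, path) {
  amp <- set$amplitude
  colnames(amp) <- paste0("a", seq_len(ncol(amp)))
  dt <- data.table::data.table(set$meta, amp)
  data.table::fwrite(dt, path)
  cfg <- set$config
  cfg$locations_cm <- as.data.frame(cfg$locations_cm)
  jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signal_set
#' @export
read_signal_set <- function(path) {
  dt <- data.table::fread(path)
  meta_cols <- c("size_mm", "x", "y", "z", "rep")
  meta <- as.data.frame(dt[, meta_cols, with = FALSE])
  amp <- as.matrix(dt[, setdiff(names(dt), meta_cols), with = FALSE])
  dimnames(amp) <- NULL
  cfg_path <- paste0(path, ".config.json")
  config <- NULL
  if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    raw$locations_cm <- as.matrix(raw$locations_cm)
    config <- do.call(acquisition_config, raw[names(raw) %in%
                                                names(formals(acquisition_config))])
  }
  structure(list(amplitude = amp, meta = meta, config = config),
            class = "signal_set")
}
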
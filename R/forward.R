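#' Concave-arc transducer array geometry
#'
#' Defaults reproduce the acquisition hardware modelled throughout the
#' package: a 128-element concave array spanning a 180 degree half-arc of
#' 50 mm radius, 5 MHz centre frequency, 50 MHz sampling, homogeneous
#' speed of sound 1500 m/s, and a 0.7 fractional receive bandwidth.
#'
#' @param n_elements number of elements (>= 2).
#' @param arc_span_deg angular span of the arc, degrees.
#' @param arc_radius_mm arc radius, mm.
#' @param center_frequency_mhz transducer centre frequency, MHz.
#' @param sampling_rate_mhz sampling frequency, MHz; must exceed twice the
#'   upper band edge.
#' @param c_mps speed of sound, m/s.
#' @param fractional_bandwidth FWHM bandwidth / centre frequency.
#' @param arc_start_deg angle of the first element, degrees (arc spans
#'   counter-clockwise from here; default 0 so the arc covers the upper
#'   half-plane).
#' @return object of class `array_geometry`.
#' @export
array_geometry <- function(n_elements = 128, arc_span_deg = 180,
                           arc_radius_mm = 50, center_frequency_mhz = 5,
                           sampling_rate_mhz = 50, c_mps = 1500,
                           fractional_bandwidth = 0.7, arc_start_deg = 0) {
  stopifnot(n_elements >= 2, arc_radius_mm > 0, arc_span_deg > 0,
            fractional_bandwidth > 0)
  if (sampling_rate_mhz <= 2 * center_frequency_mhz * (1 + fractional_bandwidth / 2))
    stop("sampling rate must exceed twice the upper band edge")
  structure(list(n_elements = as.integer(n_elements),
                 arc_span_deg = arc_span_deg,
                 arc_radius_mm = arc_radius_mm,
                 center_frequency_mhz = center_frequency_mhz,
                 sampling_rate_mhz = sampling_rate_mhz,
                 c_mps = c_mps,
                 fractional_bandwidth = fractional_bandwidth,
                 arc_start_deg = arc_start_deg),
            class = "array_geometry")
}

#' Element positions on the arc
#'
#' Elements are spaced uniformly in angle over the arc span (endpoints
#' included), all at `arc_radius_mm` from the array focus at the origin.
#'
#' @param geometry an [array_geometry()].
#' @return data.frame with `x_mm`, `y_mm`, `angle_deg`.
#' @export
element_positions <- function(geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  ang <- geometry$arc_start_deg +
    geometry$arc_span_deg * seq(0, 1, length.out = geometry$n_elements)
  th <- ang * pi / 180
  data.frame(x_mm = geometry$arc_radius_mm * cos(th),
             y_mm = geometry$arc_radius_mm * sin(th),
             angle_deg = ang)
}

# Electro-mechanical impulse response: derivative of a Gaussian-windowed
# sinusoid at the centre frequency. The Gaussian's FWHM in frequency is
# fractional_bandwidth * f0. Returned with its centre index so
# convolution can be aligned to zero delay.
impulse_response <- function(geometry) {
  f0 <- geometry$center_frequency_mhz          # MHz = cycles/us
  fs <- geometry$sampling_rate_mhz
  sigma_f <- geometry$fractional_bandwidth * f0 / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)            # us
  half <- ceiling(4 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * sin(2 * pi * f0 * t)
  h <- c(0, diff(w)) * fs                      # d/dt, per us
  list(h = h, center = half + 1L)
}

# Ideal (broadband, noiseless) traces: each pixel contributes its initial
# pressure times pixel area over 2 pi distance (2-D cylindrical spreading)
# at its time of flight, deposited into the two neighbouring time bins by
# linear fractional binning.
ideal_traces <- function(p0map, geometry, nt) {
  pos <- element_positions(geometry)
  s <- p0map$spacing_mm
  dims <- dim(p0map$p0)
  nz <- which(p0map$p0 != 0)
  dt <- 1 / geometry$sampling_rate_mhz         # us
  c_mmus <- geometry$c_mps / 1000              # mm/us
  out <- matrix(0, nrow = geometry$n_elements, ncol = nt)
  if (length(nz) == 0) return(out)
  xy <- raster_coords(dims, s, p0map$origin_mm)
  px <- xy$x[nz]; py <- xy$y[nz]
  if (any(sqrt(px^2 + py^2) >= geometry$arc_radius_mm))
    stop("geometry error: source pixel outside the detection arc")
  amp_base <- p0map$p0[nz] * s^2
  for (k in seq_len(geometry$n_elements)) {
    d <- sqrt((px - pos$x_mm[k])^2 + (py - pos$y_mm[k])^2)
    tof <- d / c_mmus / dt                     # in samples
    i0 <- floor(tof)
    frac <- tof - i0
    w <- amp_base / (2 * pi * d)
    idx <- c(i0 + 1L, i0 + 2L)
    val <- c(w * (1 - frac), w * frac)
    keep <- idx >= 1 & idx <= nt
    acc <- rowsum(val[keep], idx[keep])
    out[k, as.integer(rownames(acc))] <- out[k, as.integer(rownames(acc))] + acc[, 1]
  }
  out
}

#' Simulate band-limited photoacoustic signals
#'
#' Forward model: every nonzero pixel of the initial-pressure map radiates
#' a delta at its time of flight, weighted by pixel area over 2 pi
#' distance (2-D cylindrical spreading); the broadband trace is then
#' convolved with the transducer impulse response (derivative of a
#' Gaussian-windowed tone at the centre frequency). White Gaussian noise
#' of `noise_sd` per frame is added and `n_averages` frames are averaged;
#' the deterministic component is frame-invariant, so averaging is applied
#' as a single noise draw with sd `noise_sd / sqrt(n_averages)` — exactly
#' the distribution of the frame mean.
#'
#' @param p0map a `pressure_map` (see [initial_pressure()]).
#' @param geometry an [array_geometry()].
#' @param n_averages frames averaged (>= 1); default 10.
#' @param noise_sd per-frame white-noise sd, signal units (>= 0).
#' @param seed RNG seed for the noise.
#' @param extra_time_us extra time-axis coverage beyond the raster's own
#'   maximal time of flight, microseconds.
#' @return object of class `sinogram`: list(signals [elements x samples],
#'   time_us, wavelength_nm, n_averages, noise_sd, geometry, seed).
#' @export
simulate_signals <- function(p0map, geometry = array_geometry(),
                             n_averages = 10, noise_sd = 0, seed = 1,
                             extra_time_us = 5) {
  stopifnot(inherits(p0map, "pressure_map"), n_averages >= 1, noise_sd >= 0)
  dims <- dim(p0map$p0)
  xy <- raster_coords(dims, p0map$spacing_mm, p0map$origin_mm)
  pos <- element_positions(geometry)
  c_mmus <- geometry$c_mps / 1000
  dt <- 1 / geometry$sampling_rate_mhz
  # pad the time axis so reconstruction grids somewhat larger than the
  # source raster are still covered
  dmax <- max(sqrt(xy$x^2 + xy$y^2)) + geometry$arc_radius_mm
  ir <- impulse_response(geometry)
  nt <- ceiling((dmax / c_mmus + extra_time_us) / dt) + length(ir$h) + 2L

  g <- ideal_traces(p0map, geometry, nt)
  # zero-delay band-limiting convolution per element (FFT-free; nt is small)
  sig <- t(apply(g, 1, function(row) {
    full <- stats::convolve(row, rev(ir$h), type = "open")
    full[ir$center:(ir$center + nt - 1L)] / geometry$sampling_rate_mhz
  }))
  if (noise_sd > 0) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    sig <- sig + matrix(stats::rnorm(length(sig),
                                     sd = noise_sd / sqrt(n_averages)),
                        nrow = nrow(sig))
  }
  structure(list(signals = sig,
                 time_us = (seq_len(nt) - 1L) * dt,
                 wavelength_nm = p0map$wavelength_nm,
                 n_averages = as.integer(n_averages),
                 noise_sd = noise_sd,
                 geometry = geometry,
                 seed = as.integer(seed)),
            class = "sinogram")
}

#' Acquire a multiwavelength sinogram set from a chromophore map
#'
#' Runs the optics chain (absorption, initial pressure) and the acoustic
#' forward model once per wavelength under one shared geometry and noise
#' model; per-wavelength noise seeds derive from `seed` via [seed_for()].
#'
#' @param map a `chromophore_map`.
#' @param geometry an [array_geometry()].
#' @param wavelengths nm, all present in `table`.
#' @param table an [extinction_table()].
#' @param n_averages,noise_sd,seed see [simulate_signals()].
#' @param fluence,gamma see [initial_pressure()].
#' @return named list of `sinogram`s (one per wavelength).
#' @export
acquire_multiwavelength <- function(map, geometry = array_geometry(),
                                    wavelengths = WAVELENGTHS_NM,
                                    table = extinction_table(),
                                    n_averages = 10, noise_sd = 0, seed = 1,
                                    fluence = fluence_uniform(), gamma = 1) {
  out <- lapply(seq_along(wavelengths), function(i) {
    wl <- wavelengths[i]
    mu <- absorption_map(map, wl, table)
    p0 <- initial_pressure(mu, map, fluence = fluence, gamma = gamma,
                           wavelength = wl)
    simulate_signals(p0, geometry, n_averages = n_averages,
                     noise_sd = noise_sd, seed = seed_for(seed, i))
  })
  names(out) <- paste0(wavelengths, "nm")
  out
}

#' Write / read a sinogram (TSV + JSON sidecar)
#'
#' Signals go to a tab-separated matrix at full precision; the time axis,
#' wavelength, averaging, noise and geometry metadata go to a JSON sidecar
#' (`<path>.json`). The pair round-trips losslessly through
#' [read_sinogram()].
#'
#' @param sino a `sinogram`.
#' @param path TSV file path.
#' @return `write_sinogram`: the path, invisibly. `read_sinogram`: a
#'   `sinogram`.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  utils::write.table(format(sino$signals, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- sino[setdiff(names(sino), "signals")]
  meta$geometry <- unclass(meta$geometry)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  sig <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(sig) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geo <- do.call(array_geometry, meta$geometry)
  structure(list(signals = sig, time_us = meta$time_us,
                 wavelength_nm = meta$wavelength_nm,
                 n_averages = as.integer(meta$n_averages),
                 noise_sd = meta$noise_sd, geometry = geo,
                 seed = as.integer(meta$seed)),
            class = "sinogram")
}
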
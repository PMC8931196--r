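#' Reconstruction grid specification
#'
#' @param n pixels per side (square grid).
#' @param spacing_mm pixel size, mm.
#' @param center_mm grid centre, mm (default the array focus at the
#'   origin).
#' @return list(n, spacing_mm, origin_mm) where `origin_mm` is the centre
#'   of pixel [1,1].
#' @export
recon_grid <- function(n = 256, spacing_mm = 0.05, center_mm = c(0, 0)) {
  stopifnot(n >= 2, spacing_mm > 0)
  origin <- center_mm - (n - 1) * spacing_mm / 2
  list(n = as.integer(n), spacing_mm = spacing_mm, origin_mm = origin)
}

#' Universal back-projection reconstruction
#'
#' Reconstructs the initial-pressure image from an arc sinogram with the
#' universal back-projection filter: each pixel accumulates
#' `g_k(t) - t * dg_k/dt(t)` evaluated at its time of flight
#' `t = |x - r_k| / c`, averaged over elements (uniform angular weights
#' summing to 1). The time derivative uses central differences on the
#' sampled trace; the time lookup is linearly interpolated. Linear in the
#' sinogram.
#'
#' @param sino a `sinogram`.
#' @param grid a [recon_grid()].
#' @return object of class `recon_image`: list(pixels [n x n], spacing_mm,
#'   origin_mm, wavelength_nm).
#' @export
backproject <- function(sino, grid = recon_grid()) {
  stopifnot(inherits(sino, "sinogram"))
  geo <- sino$geometry
  pos <- element_positions(geo)
  c_mmus <- geo$c_mps / 1000
  dt <- sino$time_us[2] - sino$time_us[1]
  nt <- length(sino$time_us)

  xy <- raster_coords(c(grid$n, grid$n), grid$spacing_mm, grid$origin_mm)
  img <- numeric(grid$n * grid$n)
  tmax_needed <- 0
  for (k in seq_len(geo$n_elements)) {
    d <- sqrt((xy$x - pos$x_mm[k])^2 + (xy$y - pos$y_mm[k])^2)
    tof <- d / c_mmus
    tmax_needed <- max(tmax_needed, max(tof))
    g <- sino$signals[k, ]
    dg <- c(0, (g[-c(1, 2)] - g[-c(nt - 1, nt)]) / (2 * dt), 0)
    filt <- g - sino$time_us * dg
    # linear interpolation at t = tof
    s <- tof / dt
    i0 <- pmin(pmax(floor(s), 0), nt - 2)
    fr <- s - i0
    img <- img + (1 - fr) * filt[i0 + 1L] + fr * filt[i0 + 2L]
  }
  if (tmax_needed > max(sino$time_us))
    stop("coverage error: sinogram time axis does not cover the grid")
  structure(list(pixels = matrix(img / geo$n_elements, nrow = grid$n),
                 spacing_mm = grid$spacing_mm,
                 origin_mm = grid$origin_mm,
                 wavelength_nm = sino$wavelength_nm),
            class = "recon_image")
}

#' Envelope (non-negative magnitude)
#'
#' For a numeric vector: magnitude of the analytic signal (FFT-based
#' Hilbert transform). For a matrix or `recon_image`: pointwise absolute
#' value (band-limited reconstructions are bipolar; downstream
#' segmentation operates on the magnitude image).
#'
#' @param x numeric vector, matrix, or `recon_image`.
#' @return same shape as `x`, non-negative; for a `recon_image`, a
#'   `recon_image` with magnitude pixels.
#' @export
envelope <- function(x) {
  if (inherits(x, "recon_image")) {
    x$pixels <- abs(x$pixels)
    return(x)
  }
  if (is.matrix(x)) return(abs(x))
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Profile through (pi, pj) along one axis of a matrix.
half_max_width <- function(profile, coords, peak_idx) {
  half <- profile[peak_idx] / 2
  n <- length(profile)
  # walk left
  li <- peak_idx
  while (li > 1 && profile[li] > half) li <- li - 1
  if (profile[li] > half) return(NA_real_)
  xl <- coords[li] + (coords[li + 1] - coords[li]) *
    (half - profile[li]) / (profile[li + 1] - profile[li])
  ri <- peak_idx
  while (ri < n && profile[ri] > half) ri <- ri + 1
  if (profile[ri] > half) return(NA_real_)
  xr <- coords[ri - 1] + (coords[ri] - coords[ri - 1]) *
    (half - profile[ri - 1]) / (profile[ri] - profile[ri - 1])
  xr - xl
}

#' Point-spread-function width (FWHM)
#'
#' Measures the full width at half maximum of the envelope peak along both
#' grid axes, with sub-pixel localisation of the half-maximum crossings by
#' linear interpolation.
#'
#' @param image a `recon_image` (envelope is taken internally).
#' @param background_factor peak must exceed `background_factor` times the
#'   image median, else a detection error is raised.
#' @return list(fwhm_x_um, fwhm_y_um).
#' @export
psf_fwhm <- function(image, background_factor = 5) {
  stopifnot(inherits(image, "recon_image"))
  env <- abs(image$pixels)
  pk <- which(env == max(env), arr.ind = TRUE)[1, ]
  if (max(env) <= background_factor * (stats::median(env) + .Machine$double.eps))
    stop("detection error: no peak above background")
  s <- image$spacing_mm
  coords_row <- seq_len(nrow(env)) * s
  coords_col <- seq_len(ncol(env)) * s
  fw_y <- half_max_width(env[, pk[2]], coords_row, pk[1])  # along rows = y
  fw_x <- half_max_width(env[pk[1], ], coords_col, pk[2])  # along cols = x
  list(fwhm_x_um = fw_x * 1000, fwhm_y_um = fw_y * 1000)
}
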
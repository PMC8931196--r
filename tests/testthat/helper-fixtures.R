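# Shared in-code fixtures for the test suite.

# A pressure map holding a single bright pixel at (x_mm, y_mm).
single_pixel_p0 <- function(x_mm = 0, y_mm = 0, value = 1, n = 11,
                            spacing = 0.05, wavelength = 760) {
  m <- matrix(0, n, n)
  mid <- (n + 1) %/% 2
  m[mid, mid] <- value
  structure(list(p0 = m, spacing_mm = spacing,
                 origin_mm = c(x_mm - (mid - 1) * spacing,
                               y_mm - (mid - 1) * spacing),
                 wavelength_nm = wavelength),
            class = "pressure_map")
}

# A sharp (not band-limited) annulus rendered as a recon_image.
annulus_image <- function(r_in = 2, r_out = 3, n = 256, spacing = 0.05) {
  origin <- c(-(n - 1) * spacing / 2, -(n - 1) * spacing / 2)
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  x <- origin[1] + (j - 1) * spacing
  y <- origin[2] + (i - 1) * spacing
  d <- sqrt(x^2 + y^2)
  px <- matrix(as.numeric(d >= r_in & d <= r_out), nrow = n)
  structure(list(pixels = px, spacing_mm = spacing, origin_mm = origin,
                 wavelength_nm = NA_real_),
            class = "recon_image")
}

# A constant-spectrum stack of fake recon images (one per wavelength) with
# pixel spectrum y (length = n wavelengths).
constant_stack <- function(y, wavelengths = WAVELENGTHS_NM, n = 4) {
  stacks <- lapply(seq_along(wavelengths), function(k)
    structure(list(pixels = matrix(y[k], n, n), spacing_mm = 0.05,
                   origin_mm = c(0, 0), wavelength_nm = wavelengths[k]),
              class = "recon_image"))
  names(stacks) <- paste0(wavelengths, "nm")
  stacks
}

# Cached single-wavelength pipeline measurement used by several tests.
quick_measure <- function(phantom, seed = 1, noise_sd = DEFAULT_NOISE_SD,
                          observer = observer_params()) {
  res <- pipeline_morphometry(phantom, seed = seed, wavelengths = 760,
                              noise_sd = noise_sd,
                              observers = list(observer))
  res[[1]]
}
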
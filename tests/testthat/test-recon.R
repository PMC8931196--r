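test_that("a point source reconstructs at its true position", {
  geo <- array_geometry()
  grid <- recon_grid(n = 129, spacing_mm = 0.05)   # odd: centres on the grid
  p0 <- single_pixel_p0(0.5, 1.0)
  img <- backproject(simulate_signals(p0, geo, noise_sd = 0), grid)
  pk <- which(abs(img$pixels) == max(abs(img$pixels)), arr.ind = TRUE)[1, ]
  x_pk <- img$origin_mm[1] + (pk[2] - 1) * grid$spacing_mm
  y_pk <- img$origin_mm[2] + (pk[1] - 1) * grid$spacing_mm
  expect_lte(abs(x_pk - 0.5), grid$spacing_mm)
  expect_lte(abs(y_pk - 1.0), grid$spacing_mm)
})

test_that("back-projection is linear in the sinogram", {
  geo <- array_geometry()
  grid <- recon_grid(n = 64, spacing_mm = 0.05)
  sa <- simulate_signals(single_pixel_p0(0.3, 0.1, n = 21), geo, noise_sd = 0)
  sb <- simulate_signals(single_pixel_p0(-0.4, -0.2, n = 21), geo, noise_sd = 0)
  # pad to common length for summation
  nt <- min(length(sa$time_us), length(sb$time_us))
  sa$signals <- sa$signals[, 1:nt]; sa$time_us <- sa$time_us[1:nt]
  sb$signals <- sb$signals[, 1:nt]; sb$time_us <- sb$time_us[1:nt]
  ssum <- sa; ssum$signals <- sa$signals + sb$signals
  ia <- backproject(sa, grid); ib <- backproject(sb, grid)
  isum <- backproject(ssum, grid)
  expect_lt(max(abs(isum$pixels - ia$pixels - ib$pixels)), 1e-9)
  zero <- sa; zero$signals <- sa$signals * 0
  expect_true(all(backproject(zero, grid)$pixels == 0))
})

test_that("insufficient time coverage raises a coverage error", {
  sino <- simulate_signals(single_pixel_p0(0, 0), noise_sd = 0,
                           extra_time_us = 0)
  keep <- sino$time_us < 30           # cut before the 33.3 us arrival
  sino$signals <- sino$signals[, keep]
  sino$time_us <- sino$time_us[keep]
  expect_error(backproject(sino, recon_grid(n = 64)), "coverage")
})

test_that("the arc's open side blurs tangentially relative to the covered side", {
  # the aperture's convex hull covers the upper half-plane; a point below
  # the chord reconstructs with a tangentially broadened spot compared to
  # its mirror point inside the covered side
  geo <- array_geometry()
  grid <- recon_grid(n = 65, spacing_mm = 0.05, center_mm = c(0, 4.5))
  grid_m <- recon_grid(n = 65, spacing_mm = 0.05, center_mm = c(0, -4.5))
  up <- backproject(simulate_signals(single_pixel_p0(0, 4.5, n = 21),
                                     geo, noise_sd = 0), grid)
  dn <- backproject(simulate_signals(single_pixel_p0(0, -4.5, n = 21),
                                     geo, noise_sd = 0), grid_m)
  fw_up <- psf_fwhm(envelope(up))
  fw_dn <- psf_fwhm(envelope(dn))
  expect_gt(fw_dn$fwhm_x_um / fw_up$fwhm_x_um, 1)
})

test_that("envelope of a pure tone is its amplitude", {
  t <- seq(0, 10, by = 0.01)
  x <- 2.5 * sin(2 * pi * 3 * t)
  env <- envelope(x)
  core <- env[100:900]
  expect_true(all(abs(core - 2.5) / 2.5 < 0.02))
  expect_identical(envelope(numeric(16)), numeric(16))
  expect_equal(envelope(3 * x), 3 * envelope(x), tolerance = 1e-12)
})

test_that("PSF width of a Gaussian bump matches the closed form", {
  n <- 101; s <- 0.05
  xy <- expand.grid(i = 1:n, j = 1:n)
  sig <- 0.1
  px <- matrix(exp(-(((xy$i - 51) * s)^2 + ((xy$j - 51) * s)^2) / (2 * sig^2)),
               nrow = n)
  img <- structure(list(pixels = px, spacing_mm = s,
                        origin_mm = c(-2.5, -2.5), wavelength_nm = NA),
                   class = "recon_image")
  fw <- psf_fwhm(img)
  expect_lt(abs(fw$fwhm_x_um - 2.355 * sig * 1000), s * 1000)
  expect_lt(abs(fw$fwhm_y_um - 2.355 * sig * 1000), s * 1000)
  img10 <- img; img10$pixels <- 10 * img$pixels
  expect_equal(psf_fwhm(img10)$fwhm_x_um, fw$fwhm_x_um)
  blank <- img; blank$pixels <- img$pixels * 0 + 1
  expect_error(psf_fwhm(blank), "detection error")
})

test_that("reconstructed point-target width shrinks with bandwidth", {
  fw <- vapply(c(0.3, 0.6, 0.9), function(bw) {
    geo <- array_geometry(fractional_bandwidth = bw)
    grid <- recon_grid(n = 96, spacing_mm = 0.025)
    img <- backproject(simulate_signals(single_pixel_p0(0, 0, spacing = 0.025),
                                        geo, noise_sd = 0), grid)
    fwhm <- psf_fwhm(envelope(img))
    min(fwhm$fwhm_x_um, fwhm$fwhm_y_um)
  }, numeric(1))
  expect_true(all(diff(fw) < 0))
})

test_that("reconstructed images round-trip through float TIFF", {
  img <- annulus_image(n = 64)
  img$pixels <- img$pixels * 3.7 - 0.5
  path <- tempfile(fileext = ".tif")
  write_recon_tiff(img, path)
  rt <- read_recon_tiff(path)
  expect_equal(rt$pixels, img$pixels, tolerance = 1e-6)
  expect_equal(rt$spacing_mm, img$spacing_mm)
  expect_equal(rt$origin_mm, img$origin_mm)
})
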
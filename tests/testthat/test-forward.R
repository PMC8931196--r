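test_that("element positions lie on the stated arc", {
  geo <- array_geometry()
  pos <- element_positions(geo)
  expect_equal(nrow(pos), 128)
  expect_equal(sqrt(pos$x_mm^2 + pos$y_mm^2), rep(50, 128))
  # 180 degree span: first and last elements diametrically opposite
  expect_equal(pos$x_mm[1] + pos$x_mm[128], 0, tolerance = 1e-9)
  expect_equal(pos$y_mm[1] + pos$y_mm[128], 0, tolerance = 1e-9)
  two <- element_positions(array_geometry(n_elements = 2, arc_span_deg = 90))
  expect_equal(diff(two$angle_deg), 90)
})

test_that("geometry invariants are enforced", {
  expect_error(array_geometry(sampling_rate_mhz = 8), "sampling rate")
  expect_error(array_geometry(n_elements = 1), "n_elements")
})

test_that("a source at the focus arrives at distance over sound speed", {
  p0 <- single_pixel_p0(0, 0)
  sino <- simulate_signals(p0, array_geometry(), noise_sd = 0)
  dt <- sino$time_us[2] - sino$time_us[1]
  for (k in c(1, 40, 128)) {
    env <- envelope(sino$signals[k, ])
    expect_lt(abs(sino$time_us[which.max(env)] - 50 / 1.5), dt + 1e-12)
  }
})

test_that("the forward model is linear and superposes", {
  geo <- array_geometry()
  pa <- single_pixel_p0(0.4, 0.2, n = 21)
  pb <- single_pixel_p0(0.4, 0.2, n = 21)
  pb$p0 <- pb$p0 * 0                     # same raster, different pixel
  pb$p0[5, 17] <- 1
  psum <- pa; psum$p0 <- pa$p0 + pb$p0
  sa <- simulate_signals(pa, geo, noise_sd = 0)
  sb <- simulate_signals(pb, geo, noise_sd = 0)
  ss <- simulate_signals(psum, geo, noise_sd = 0)
  expect_lt(max(abs(ss$signals - sa$signals - sb$signals)), 1e-9)
  p2 <- pa; p2$p0 <- 2 * pa$p0
  s2 <- simulate_signals(p2, geo, noise_sd = 0)
  expect_equal(s2$signals, 2 * sa$signals, tolerance = 1e-12)
})

test_that("10-frame averaging attenuates noise by about sqrt(10)", {
  p0 <- single_pixel_p0(0, 0, value = 0)   # pure-noise sinogram
  s1 <- simulate_signals(p0, noise_sd = 1, n_averages = 1, seed = 7)
  s10 <- simulate_signals(p0, noise_sd = 1, n_averages = 10, seed = 8)
  expect_gt(length(s1$signals), 1e5)
  ratio <- sd(s10$signals) / sd(s1$signals)
  expect_lt(abs(ratio - 1 / sqrt(10)), 0.1 / sqrt(10))
  expect_lt(abs(mean(s10$signals)), 3 / sqrt(length(s10$signals) / 10))
  # deterministic component unchanged by averaging
  pd <- single_pixel_p0(0, 0)
  d1 <- simulate_signals(pd, noise_sd = 0, n_averages = 1)
  d10 <- simulate_signals(pd, noise_sd = 0, n_averages = 10)
  expect_equal(d1$signals, d10$signals)
})

test_that("noise is reproducible per seed", {
  p0 <- single_pixel_p0(0, 0)
  a <- simulate_signals(p0, noise_sd = 1e-6, seed = 5)
  b <- simulate_signals(p0, noise_sd = 1e-6, seed = 5)
  c <- simulate_signals(p0, noise_sd = 1e-6, seed = 6)
  expect_identical(a$signals, b$signals)
  expect_false(identical(a$signals, c$signals))
})

test_that("sources outside the arc are rejected", {
  p0 <- single_pixel_p0(60, 0)
  expect_error(simulate_signals(p0), "outside the detection arc")
})

test_that("multiwavelength acquisition shares one time axis and geometry", {
  ph <- make_phantom(default_group_specs()$A, 1)
  cmap <- rasterize(ph, fov_mm = 8, spacing_mm = 0.1)
  sinos <- acquire_multiwavelength(cmap, noise_sd = 0, seed = 1)
  expect_length(sinos, 3)
  expect_identical(sinos[[1]]$time_us, sinos[[3]]$time_us)
  expect_identical(sinos[[1]]$geometry, sinos[[2]]$geometry)
})

test_that("a flat-spectrum absorber gives wavelength-invariant signals", {
  flat <- data.frame(
    chromophore = rep(CHROMOPHORES, each = 2),
    wavelength_nm = rep(c(760, 840), 4),
    epsilon = rep(c(1, 0.5, 0.2, 0.3), each = 2))
  class(flat) <- c("extinction_table", "data.frame")
  ph <- make_phantom(group_spec("A", 0.8, 0, 16, 0, vessel_density = 0), 1)
  cmap <- rasterize(ph, fov_mm = 8, spacing_mm = 0.1)
  sinos <- acquire_multiwavelength(cmap, wavelengths = c(760, 840),
                                   table = flat, noise_sd = 0, seed = 1)
  expect_equal(sinos[[1]]$signals, sinos[[2]]$signals, tolerance = 1e-12)
})

test_that("an empty chromophore map yields zero-mean all-noise sinograms", {
  empty <- structure(list(
    conc = setNames(lapply(CHROMOPHORES, function(ch) matrix(0, 8, 8)),
                    CHROMOPHORES),
    spacing_mm = 0.1, origin_mm = c(-0.35, -0.35),
    lumen_frac = matrix(0, 8, 8)), class = "chromophore_map")
  sinos <- acquire_multiwavelength(empty, noise_sd = 1, seed = 3)
  expect_lt(abs(mean(sinos[[1]]$signals)),
            3 / sqrt(length(sinos[[1]]$signals) * 10))
})

test_that("sinograms round-trip through TSV + JSON", {
  p0 <- single_pixel_p0(0.2, -0.3)
  sino <- simulate_signals(p0, noise_sd = 1e-6, seed = 4)
  path <- tempfile(fileext = ".tsv")
  write_sinogram(sino, path)
  rt <- read_sinogram(path)
  expect_equal(rt$signals, sino$signals, tolerance = 1e-15)
  expect_equal(rt$time_us, sino$time_us)
  expect_equal(rt$geometry, sino$geometry)
  expect_identical(rt$n_averages, sino$n_averages)
})
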
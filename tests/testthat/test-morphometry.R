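test_that("an ideal annulus is segmented and measured analytically", {
  img <- annulus_image(r_in = 2, r_out = 3)
  # ideal sharp image: linear thresholding (log compression targets the
  # dynamic range of band-limited envelopes)
  obs <- observer_params(boundary_method = "mask", log_k = 0)
  seg <- segment_lumen(img, obs)
  # lumen mask area vs analytic disk
  area <- sum(seg$lumen_mask) * seg$spacing_mm^2
  expect_lt(abs(area - pi * 4) / (pi * 4), 0.02)
  res <- measure(seg, reference_csa = REFERENCE_CSA_MM2)
  expect_lt(abs(res$twt_mm - 1), 2 * img$spacing_mm)
  expect_lt(abs(res$csa_mm2 - pi * 4) / (pi * 4), 0.02)
  # determinism
  expect_identical(seg$inner_r_mm, segment_lumen(img, obs)$inner_r_mm)
})

test_that("blank images raise a segmentation failure", {
  blank <- annulus_image()
  blank$pixels <- blank$pixels * 0
  expect_error(segment_lumen(blank), "segmentation failure")
})

test_that("stenosis rate follows the area-ratio closed form", {
  mk_seg <- function(r, twt) {
    ang <- 2 * pi * (0:63) / 64
    structure(list(angles_rad = ang, inner_r_mm = rep(r, 64),
                   outer_r_mm = rep(r + twt, 64), centroid_mm = c(0, 0),
                   lumen_mask = matrix(TRUE, 2, 2),
                   wall_mask = matrix(TRUE, 2, 2),
                   spacing_mm = 0.05, origin_mm = c(0, 0),
                   observer_id = "synthetic"), class = "segmentation")
  }
  res <- measure(mk_seg(sqrt(8 / pi), 0.5), reference_csa = 16)
  expect_equal(res$csa_mm2, 8, tolerance = 1e-12)
  expect_equal(res$sr_pct, 50, tolerance = 1e-10)
  res0 <- measure(mk_seg(1.5, 0.4))
  expect_true(is.na(res0$sr_pct))
  resr <- measure(mk_seg(1.5, 0.4), reference_csa = measure(mk_seg(1.5, 0.4))$csa_mm2)
  expect_equal(resr$sr_pct, 0, tolerance = 1e-12)
  expect_equal(resr$sr_pct, (1 - resr$csa_mm2 / resr$csa_mm2) * 100,
               tolerance = 1e-12)
})

test_that("degenerate contours are rejected", {
  ang <- 2 * pi * (0:63) / 64
  bad <- structure(list(angles_rad = ang, inner_r_mm = rep(2, 64),
                        outer_r_mm = rep(1.5, 64), centroid_mm = c(0, 0),
                        lumen_mask = matrix(TRUE, 2, 2),
                        wall_mask = matrix(TRUE, 2, 2),
                        spacing_mm = 0.05, origin_mm = c(0, 0),
                        observer_id = "x"), class = "segmentation")
  expect_error(measure(bad), "geometry error")
})

test_that("estimated wall thickness tracks true wall thickness", {
  twts <- seq(0.7, 1.9, length.out = 10)
  est <- vapply(seq_along(twts), function(i) {
    sp <- group_spec("A", twt_mean = twts[i], twt_sd = 0,
                     csa_mean = 14, csa_sd = 0, vessel_density = 0)
    quick_measure(make_phantom(sp, 100 + i), seed = 100 + i)$twt_mm
  }, numeric(1))
  expect_gt(cor(est, twts, method = "spearman"), 0.9)
})

test_that("two observers with identical parameters agree exactly; jittered ones nearly", {
  ph <- make_phantom(default_group_specs()$A, 3)
  res <- pipeline_morphometry(ph, seed = 3, wavelengths = 760,
                              observers = list(observer_params(id = "x"),
                                               observer_params(id = "y")))
  expect_equal(res[["x"]]$twt_mm, res[["y"]]$twt_mm)
  expect_equal(res[["x"]]$csa_mm2, res[["y"]]$csa_mm2)

  obs <- default_observers()
  resj <- pipeline_morphometry(ph, seed = 3, wavelengths = 760,
                               observers = obs)
  d_ab <- resj[[1]]$twt_mm - resj[[2]]$twt_mm
  resj2 <- pipeline_morphometry(ph, seed = 3, wavelengths = 760,
                                observers = rev(obs))
  d_ba <- resj2[[1]]$twt_mm - resj2[[2]]$twt_mm
  expect_equal(d_ab, -d_ba)           # order swap flips the bias sign
  expect_lt(abs(d_ab), 0.2)           # jittered observers stay close
})

test_that("a static phantom shows no respiratory modulation beyond noise", {
  ph <- make_phantom(default_group_specs()$A, 6)
  imgs <- lapply(1:4, function(i) {
    cmap <- rasterize(ph)
    sinos <- acquire_multiwavelength(cmap, wavelengths = 760,
                                     noise_sd = DEFAULT_NOISE_SD,
                                     seed = seed_for(6, i))
    compound_envelope(reconstruct_stack(sinos))
  })
  ts <- csa_timeseries(imgs, phases = 2 * pi * (0:3) / 4)
  expect_lt(ts$modulation_depth, 0.05)
})

test_that("segmentation failures propagate with the frame index", {
  good <- annulus_image()
  blank <- annulus_image(); blank$pixels <- blank$pixels * 0
  expect_error(
    csa_timeseries(list(good, blank, good, good), phases = c(0, 1, 2, 3),
                   params = observer_params(boundary_method = "mask")),
    "frame 2")
})
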
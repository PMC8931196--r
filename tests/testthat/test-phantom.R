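specs <- default_group_specs()

test_that("phantom draws follow the group morphometry distributions", {
  coh <- sample_cohort(specs$A, 50, seed = 11)
  twt <- vapply(coh, `[[`, numeric(1), "wall_thickness_mm")
  csa <- vapply(coh, `[[`, numeric(1), "true_csa_mm2")
  expect_lt(abs(mean(twt) - specs$A$twt_mean), 3 * specs$A$twt_sd / sqrt(50))
  expect_lt(abs(mean(csa) - specs$A$csa_mean), 3 * specs$A$csa_sd / sqrt(50))
  # lumen radius consistent with drawn area
  expect_equal(pi * coh[[1]]$lumen_radius_mm^2, coh[[1]]$true_csa_mm2,
               tolerance = 1e-9)
})

test_that("zero-variance specs are deterministic and exact", {
  s0 <- group_spec("A", twt_mean = 0.9, twt_sd = 0, csa_mean = 16, csa_sd = 0)
  ph <- make_phantom(s0, seed = 3)
  expect_identical(ph$wall_thickness_mm, 0.9)
  expect_equal(ph$true_csa_mm2, 16)
})

test_that("identical (spec, seed) give bitwise-identical phantoms", {
  expect_identical(make_phantom(specs$C, 5), make_phantom(specs$C, 5))
  expect_false(identical(make_phantom(specs$C, 5), make_phantom(specs$C, 6)))
})

test_that("degenerate truncated-normal specs raise after bounded retries", {
  expect_error(tracheapat:::rtruncnorm_pos(-100, 1), "degenerate")
  expect_error(tracheapat:::rtruncnorm_pos(-1, 0), "degenerate")
})

test_that("respiration follows the closed-form CSA cycle", {
  ph <- make_phantom(specs$A, 2)
  a <- 0.15
  expect_equal(apply_respiration(ph, 0, a)$true_csa_mm2, ph$true_csa_mm2)
  expect_equal(apply_respiration(ph, pi, a)$true_csa_mm2,
               ph$true_csa_mm2 * (1 + a))
  phases <- seq(0, pi, length.out = 8)
  csa <- vapply(phases, function(p) apply_respiration(ph, p, a)$true_csa_mm2,
                numeric(1))
  expect_true(all(diff(csa) > 0))
  expect_error(apply_respiration(ph, 0, a = 1.2), "modulation depth")
  expect_error(apply_respiration(ph, 7, a), "phase")
})

test_that("respiration conserves wall cross-sectional area", {
  ph <- make_phantom(specs$B, 9)
  wall_area <- function(p) {
    ro <- p$lumen_radius_mm + p$wall_thickness_mm
    pi * (ro^2 - p$lumen_radius_mm^2)
  }
  for (phase in c(0.5, pi, 5)) {
    m <- apply_respiration(ph, phase)
    expect_equal(wall_area(m), wall_area(ph), tolerance = 1e-6)
  }
})

test_that("rasterized lumen area matches the analytic disk area", {
  s0 <- group_spec("A", twt_mean = 0.82, twt_sd = 0, csa_mean = 16.28,
                   csa_sd = 0, vessel_density = 0)
  ph <- make_phantom(s0, 1)
  errs <- vapply(c(0.2, 0.1, 0.05), function(sp) {
    cmap <- rasterize(ph, spacing_mm = sp)
    abs(rasterized_lumen_area(cmap) - ph$true_csa_mm2)
  }, numeric(1))
  expect_lt(errs[3], 2 * 0.05^2)      # within 2 pixel areas at 0.05 mm
  expect_true(all(diff(errs) < 0))    # refinement reduces the error
})

test_that("rasterization respects the air lumen and chromophore sparsity", {
  ph <- make_phantom(specs$C, 4)
  cmap <- rasterize(ph)
  ctr <- round((ph$center_mm - cmap$origin_mm) / cmap$spacing_mm) + 1
  for (ch in CHROMOPHORES)
    expect_identical(cmap$conc[[ch]][ctr[2], ctr[1]], 0)
  n_active <- Reduce(`+`, lapply(cmap$conc, function(m) m > 0))
  expect_lte(max(n_active), 3)
  expect_true(all(vapply(cmap$conc, function(m) all(m >= 0), logical(1))))
})

test_that("phantoms exceeding the field of view are rejected", {
  big <- group_spec("A", twt_mean = 2, twt_sd = 0, csa_mean = 150, csa_sd = 0)
  expect_error(rasterize(make_phantom(big, 1), fov_mm = 12.8), "field of view")
})

test_that("cohorts are reproducible, distinct, and seed-sensitive", {
  c1 <- sample_cohort(specs$B, 3, seed = 21)
  c2 <- sample_cohort(specs$B, 3, seed = 21)
  c3 <- sample_cohort(specs$B, 3, seed = 22)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
  expect_false(identical(c1[[1]], c1[[2]]))
  expect_error(sample_cohort(specs$B, 0, seed = 1), "n")
})

test_that("generator self-consistency over 200 phantoms", {
  coh <- sample_cohort(specs$B, 200, seed = 31)
  twt <- vapply(coh, `[[`, numeric(1), "wall_thickness_mm")
  csa <- vapply(coh, `[[`, numeric(1), "true_csa_mm2")
  expect_lt(abs(mean(twt) - specs$B$twt_mean), 3 * specs$B$twt_sd / sqrt(200))
  expect_lt(abs(sd(twt) - specs$B$twt_sd),
            4 * specs$B$twt_sd / sqrt(2 * 200))
  expect_lt(abs(mean(csa) - specs$B$csa_mean), 3 * specs$B$csa_sd / sqrt(200))
})

test_that("phantom ground truth serializes losslessly to JSON", {
  ph <- make_phantom(specs$C, 8)
  path <- tempfile(fileext = ".json")
  write_phantom_json(ph, path)
  rt <- read_phantom_json(path)
  expect_equal(rt$lumen_radius_mm, ph$lumen_radius_mm)
  expect_equal(rt$true_csa_mm2, ph$true_csa_mm2)
  expect_equal(as.data.frame(rt$inclusions), as.data.frame(ph$inclusions))
  expect_equal(rt$spec$twt_mean, ph$spec$twt_mean)
})
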
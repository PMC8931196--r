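#' Group specification for phantom generation
#'
#' Describes one experimental group as a distribution over tracheal
#' morphometry plus the group's chromophore signature. Groups follow the
#' four-arm stenosis study design: A normal control; B mucosal edema
#' (elevated water, mild wall thickening); C granulomatous hyperplasia
#' (extra blood vessels, greatest thickening, smallest lumen); D
#' cicatricial scar (elevated collagen).
#'
#' @param group_label one of "A","B","C","D".
#' @param twt_mean,twt_sd wall-thickness distribution, mm.
#' @param csa_mean,csa_sd lumen cross-sectional-area distribution, mm^2.
#' @param edema_water_boost multiplicative water boost (>= 1).
#' @param vessel_density number of discrete vessel inclusions per phantom.
#' @param collagen_boost multiplicative collagen boost (>= 1).
#' @return object of class `group_spec`.
#' @export
group_spec <- function(group_label, twt_mean, twt_sd, csa_mean, csa_sd,
                       edema_water_boost = 1, vessel_density = 2,
                       collagen_boost = 1) {
  stopifnot(group_label %in% c("A", "B", "C", "D"),
            twt_mean > 0, csa_mean > 0, twt_sd >= 0, csa_sd >= 0,
            edema_water_boost >= 1, collagen_boost >= 1,
            vessel_density >= 0)
  structure(list(group_label = group_label,
                 twt_mean = twt_mean, twt_sd = twt_sd,
                 csa_mean = csa_mean, csa_sd = csa_sd,
                 edema_water_boost = edema_water_boost,
                 vessel_density = as.integer(vessel_density),
                 collagen_boost = collagen_boost),
            class = "group_spec")
}

#' Default group specifications
#'
#' Morphometry distributions (mean +/- SD of wall thickness and lumen
#' cross-sectional area) for the four study groups, with the group
#' chromophore signatures: B carries a 1.5x water boost (edema), C carries
#' extra vessel inclusions (granulomatous hypervascularity), D a 2x
#' collagen boost (scar). Cross-sectional areas are in mm^2 throughout.
#'
#' @return named list of [group_spec()] objects ("A".."D").
#' @export
default_group_specs <- function() {
  list(
    A = group_spec("A", twt_mean = 0.82, twt_sd = 0.02,
                   csa_mean = 16.28, csa_sd = 0.33),
    B = group_spec("B", twt_mean = 1.14, twt_sd = 0.04,
                   csa_mean = 12.37, csa_sd = 0.30,
                   edema_water_boost = 1.5),
    C = group_spec("C", twt_mean = 1.50, twt_sd = 0.30,
                   csa_mean = 8.78, csa_sd = 0.92,
                   vessel_density = 6),
    D = group_spec("D", twt_mean = 1.17, twt_sd = 0.11,
                   csa_mean = 12.47, csa_sd = 0.27,
                   collagen_boost = 2)
  )
}

#' Reference lumen area for stenosis-rate ground truth (mm^2): the control
#' group mean.
#' @export
REFERENCE_CSA_MM2 <- 16.28

# One positive truncated-normal draw; the retry cap surfaces degenerate
# specs (e.g. mean << 0) instead of looping forever.
rtruncnorm_pos <- function(mean, sd, retries = 100) {
  if (sd == 0) {
    if (mean <= 0) stop("degenerate spec: non-positive deterministic value")
    return(mean)
  }
  for (i in seq_len(retries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x > 0) return(x)
  }
  stop("degenerate spec: no positive draw after ", retries, " retries")
}

#' Generate one digital trachea phantom
#'
#' The phantom is a concentric-disk cross-section: an air-filled lumen of
#' radius r (drawn so that pi r^2 follows the group's CSA distribution,
#' truncated positive), a tissue wall annulus of drawn thickness, and
#' `vessel_density` circular blood-vessel inclusions embedded in the wall.
#' Ground-truth morphometry (TWT, CSA, SR relative to
#' [REFERENCE_CSA_MM2]) is stored on the object. Identical (spec, seed)
#' yield identical phantoms.
#'
#' @param spec a [group_spec()].
#' @param seed integer RNG seed.
#' @param center_mm phantom centre in image coordinates, mm.
#' @return object of class `phantom`.
#' @export
make_phantom <- function(spec, seed, center_mm = c(0, 0)) {
  stopifnot(inherits(spec, "group_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  csa <- rtruncnorm_pos(spec$csa_mean, spec$csa_sd)
  twt <- rtruncnorm_pos(spec$twt_mean, spec$twt_sd)
  r_in <- sqrt(csa / pi)
  r_out <- r_in + twt

  vessels <- NULL
  if (spec$vessel_density > 0) {
    vr <- 0.18                       # vessel radius, mm (mucosal arteriole)
    theta <- stats::runif(spec$vessel_density, 0, 2 * pi)
    # embed fully inside the wall annulus (never overlapping the lumen)
    lo <- r_in + vr
    hi <- max(r_out - vr, lo)
    rad <- stats::runif(spec$vessel_density, lo, hi)
    vessels <- data.frame(
      x = center_mm[1] + rad * cos(theta),
      y = center_mm[2] + rad * sin(theta),
      radius = vr,
      frac_depth = (rad - r_in) / twt   # radial position, wall-relative
    )
  }

  structure(list(lumen_radius_mm = r_in,
                 wall_thickness_mm = twt,
                 center_mm = center_mm,
                 inclusions = vessels,
                 group_label = spec$group_label,
                 spec = spec,
                 true_csa_mm2 = csa,
                 true_twt_mm = twt,
                 true_sr_pct = (1 - csa / REFERENCE_CSA_MM2) * 100,
                 seed = as.integer(seed)),
            class = "phantom")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Trachea phantom, group %s: lumen r = %.3f mm, TWT = %.3f mm, CSA = %.2f mm^2, SR = %.1f%%, %d vessel(s)\n",
              x$group_label, x$lumen_radius_mm, x$wall_thickness_mm,
              x$true_csa_mm2, x$true_sr_pct,
              if (is.null(x$inclusions)) 0L else nrow(x$inclusions)))
  invisible(x)
}

#' Apply respiratory modulation to a phantom
#'
#' Scales the lumen so the cross-sectional area follows
#' CSA(phase) = CSA0 * (1 + a (1 - cos phase)/2): minimal at phase 0
#' (end-exhalation) and maximal at phase pi (end-inhalation), matching the
#' respiratory cycle seen in real-time airway imaging. The wall
#' cross-sectional area is conserved (tissue is incompressible in-plane):
#' the outer radius is recomputed from the new lumen radius, and vessel
#' inclusions keep their wall-relative radial position.
#'
#' @param phantom a [make_phantom()] result.
#' @param phase radians in [0, 2 pi).
#' @param a modulation depth (0 <= a < 1), default 0.15.
#' @return modulated `phantom` (true_csa/true_twt updated).
#' @export
apply_respiration <- function(phantom, phase, a = 0.15) {
  stopifnot(inherits(phantom, "phantom"))
  if (a < 0 || a >= 1) stop("modulation depth a must be in [0, 1)")
  if (phase < 0 || phase >= 2 * pi) stop("phase must be in [0, 2*pi)")
  scale2 <- 1 + a * (1 - cos(phase)) / 2          # CSA scale factor
  r_in0 <- phantom$lumen_radius_mm
  r_out0 <- r_in0 + phantom$wall_thickness_mm
  wall_area <- pi * (r_out0^2 - r_in0^2)
  r_in <- r_in0 * sqrt(scale2)
  r_out <- sqrt(r_in^2 + wall_area / pi)
  out <- phantom
  out$lumen_radius_mm <- r_in
  out$wall_thickness_mm <- r_out - r_in
  out$true_csa_mm2 <- phantom$true_csa_mm2 * scale2
  out$true_twt_mm <- r_out - r_in
  out$true_sr_pct <- (1 - out$true_csa_mm2 / REFERENCE_CSA_MM2) * 100
  if (!is.null(out$inclusions)) {
    v <- out$inclusions
    rad <- r_in + v$frac_depth * (r_out - r_in)
    theta <- atan2(v$y - phantom$center_mm[2], v$x - phantom$center_mm[1])
    v$x <- phantom$center_mm[1] + rad * cos(theta)
    v$y <- phantom$center_mm[2] + rad * sin(theta)
    out$inclusions <- v
  }
  out
}

#' Sample a cohort of phantoms
#'
#' @param spec a [group_spec()].
#' @param n cohort size (>= 1).
#' @param seed master seed; phantom i uses sub-seed `seed_for(seed, i)`.
#' @return list of `phantom` objects.
#' @export
sample_cohort <- function(spec, n, seed) {
  if (n < 1) stop("cohort size n must be >= 1")
  lapply(seq_len(n), function(i) make_phantom(spec, seed_for(seed, i)))
}

# Baseline chromophore concentrations (arbitrary units). The tissue wall
# carries water + collagen + a diffuse oxygenated-blood background; vessel
# inclusions carry whole blood (HbO2/HbR at 60% saturation). At most 3
# chromophores are nonzero at any pixel, keeping every pixel's 3-wavelength
# unmixing subproblem full-rank.
WALL_CONC <- c(HbO2 = 0.10, HbR = 0, collagen = 1.0, water = 1.0)
VESSEL_CONC <- c(HbO2 = 0.45, HbR = 0.30, collagen = 0, water = 0)

# Fractional pixel coverage of a disk of radius r: smooth one-pixel-wide
# edge ramp so rasterized areas converge to pi r^2 (error ~ spacing^2).
disk_coverage <- function(dist, r, spacing) {
  pmin(pmax(0.5 + (r - dist) / spacing, 0), 1)
}

#' Rasterize a phantom into per-chromophore concentration maps
#'
#' Renders the phantom on a square raster of pixel size `spacing_mm`
#' covering `fov_mm` x `fov_mm` centred on `origin_center`. The wall
#' annulus gets the wall background (water, collagen, diffuse HbO2) with
#' the group's water/collagen boosts applied; vessel inclusions get whole
#' blood (HbO2 + HbR); the air-filled lumen is zero in all chromophores.
#' Annulus edges are anti-aliased (fractional coverage); vessel disks are
#' binary so no pixel mixes more than 3 chromophores.
#'
#' @param phantom a `phantom`.
#' @param spacing_mm pixel size, mm (default 0.05).
#' @param fov_mm field-of-view width, mm (default 12.8).
#' @param origin_center centre of the raster in mm (default the phantom
#'   centre).
#' @return object of class `chromophore_map`: list with `conc` (named list
#'   of matrices), `spacing_mm`, `origin_mm` (centre of pixel [1,1]),
#'   `lumen_frac` (fractional lumen coverage per pixel), `phantom`.
#' @export
rasterize <- function(phantom, spacing_mm = 0.05, fov_mm = 12.8,
                      origin_center = phantom$center_mm) {
  stopifnot(inherits(phantom, "phantom"), spacing_mm > 0)
  r_in <- phantom$lumen_radius_mm
  r_out <- r_in + phantom$wall_thickness_mm
  reach <- sqrt(sum((phantom$center_mm - origin_center)^2)) + r_out
  if (reach > fov_mm / 2)
    stop("geometry error: phantom exceeds the field of view")

  n <- round(fov_mm / spacing_mm)
  origin_mm <- origin_center - fov_mm / 2 + spacing_mm / 2
  xy <- raster_coords(c(n, n), spacing_mm, origin_mm)
  dx <- xy$x - phantom$center_mm[1]
  dy <- xy$y - phantom$center_mm[2]
  dist <- sqrt(dx^2 + dy^2)

  cov_out <- disk_coverage(dist, r_out, spacing_mm)
  cov_in <- disk_coverage(dist, r_in, spacing_mm)
  wall_frac <- cov_out - cov_in

  spec <- phantom$spec
  wall <- WALL_CONC
  wall["water"] <- wall["water"] * spec$edema_water_boost
  wall["collagen"] <- wall["collagen"] * spec$collagen_boost

  conc <- lapply(CHROMOPHORES, function(ch)
    matrix(wall[[ch]] * wall_frac, nrow = n))
  names(conc) <- CHROMOPHORES

  if (!is.null(phantom$inclusions)) {
    for (k in seq_len(nrow(phantom$inclusions))) {
      v <- phantom$inclusions[k, ]
      inside <- matrix(sqrt((xy$x - v$x)^2 + (xy$y - v$y)^2) < v$radius,
                       nrow = n)
      for (ch in CHROMOPHORES)
        conc[[ch]][inside] <- VESSEL_CONC[[ch]]
    }
  }

  structure(list(conc = conc, spacing_mm = spacing_mm,
                 origin_mm = origin_mm,
                 lumen_frac = matrix(cov_in, nrow = n),
                 phantom = phantom),
            class = "chromophore_map")
}

#' Rasterized lumen area (mm^2)
#'
#' Sum of fractional lumen pixel coverage times pixel area; converges to
#' the analytic pi r^2 as spacing shrinks.
#'
#' @param map a `chromophore_map`.
#' @return area in mm^2.
#' @export
rasterized_lumen_area <- function(map) {
  sum(map$lumen_frac) * map$spacing_mm^2
}
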
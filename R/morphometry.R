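#' Observer parameter set for automated segmentation
#'
#' Human observers are replaced by a parameterised automatic segmenter;
#' inter-observer variability is modelled as jitter of these
#' hyperparameters (threshold factor, smoothing width).
#'
#' @param id observer label.
#' @param threshold_factor multiplies the Otsu threshold (default 1).
#' @param smooth_sigma_px Gaussian smoothing sigma in pixels before
#'   thresholding.
#' @param close_radius_px radius of the morphological closing disc,
#'   pixels (bridges the band-limited intensity dip inside thick walls).
#' @param n_spokes radial spokes for boundary extraction.
#' @param max_wall_mm maximal plausible wall extent, mm: along each spoke
#'   the wall is taken to span from the first thresholded run to the last
#'   run starting within this distance (merges unbridged double rims).
#' @param log_k logarithmic compression strength applied to the
#'   normalised envelope before thresholding (`log1p(k x)/log1p(k)`;
#'   0 disables). Compression makes the Otsu threshold robust to small
#'   very-bright structures (vessels) that would otherwise dominate the
#'   histogram; being monotone, it does not move the rim peaks used for
#'   boundary placement.
#' @param boundary_method how spoke boundary radii are localised:
#'   `"peak"` places each boundary at the sub-pixel envelope ridge maximum
#'   of the wall rim (band-limited interfaces reconstruct as ridges
#'   centred on the physical boundary), `"halfmax"` at the half-maximum
#'   crossing of the rim, `"mask"` at the raw threshold-mask edge.
#' @return object of class `observer_params`.
#' @export
observer_params <- function(id = "observer", threshold_factor = 1,
                            smooth_sigma_px = 1.5, close_radius_px = 8,
                            n_spokes = 64, boundary_method = "peak",
                            max_wall_mm = 3, log_k = 50) {
  stopifnot(threshold_factor > 0, smooth_sigma_px >= 0, n_spokes >= 8,
            boundary_method %in% c("peak", "halfmax", "mask"),
            max_wall_mm > 0, log_k >= 0)
  structure(list(id = id, threshold_factor = threshold_factor,
                 smooth_sigma_px = smooth_sigma_px,
                 close_radius_px = as.integer(close_radius_px),
                 n_spokes = as.integer(n_spokes),
                 boundary_method = boundary_method,
                 max_wall_mm = max_wall_mm, log_k = log_k),
            class = "observer_params")
}

#' Default paired observers
#'
#' Two observer parameter sets differing by `jitter` in threshold factor
#' and 10% of `jitter` relative in smoothing, emulating two trained
#' readers.
#'
#' @param jitter fractional threshold jitter (default 0.03, i.e. +/- 3%).
#' @return list of two [observer_params()].
#' @export
default_observers <- function(jitter = 0.03) {
  list(observer_params("obs_a", threshold_factor = 1 - jitter,
                       smooth_sigma_px = 1.5),
       observer_params("obs_b", threshold_factor = 1 + jitter,
                       smooth_sigma_px = 1.5 * (1 + jitter / 3)))
}

# Bilinear interpolation of matrix `m` at physical points (x, y) given the
# raster spacing/origin (centre of pixel [1,1]); row index <-> y.
interp_bilinear <- function(m, x, y, spacing, origin) {
  cj <- (x - origin[1]) / spacing + 1
  ri <- (y - origin[2]) / spacing + 1
  ri <- pmin(pmax(ri, 1), nrow(m) - 1e-9)
  cj <- pmin(pmax(cj, 1), ncol(m) - 1e-9)
  i0 <- floor(ri); j0 <- floor(cj)
  fi <- ri - i0; fj <- cj - j0
  i1 <- pmin(i0 + 1, nrow(m)); j1 <- pmin(j0 + 1, ncol(m))
  m[cbind(i0, j0)] * (1 - fi) * (1 - fj) + m[cbind(i1, j0)] * fi * (1 - fj) +
    m[cbind(i0, j1)] * (1 - fi) * fj + m[cbind(i1, j1)] * fi * fj
}

# Sub-pixel maximum location by quadratic fit around discrete max.
refine_peak <- function(r, v, idx) {
  if (idx <= 1 || idx >= length(v)) return(r[idx])
  denom <- v[idx - 1] - 2 * v[idx] + v[idx + 1]
  if (denom >= 0) return(r[idx])
  r[idx] + 0.5 * (v[idx - 1] - v[idx + 1]) / denom * (r[2] - r[1])
}

#' Segment the tracheal lumen and wall from an envelope image
#'
#' The wall is the bright annulus: the envelope image is normalised
#' robustly (99.9th percentile), Gaussian-smoothed, thresholded at the
#' observer-scaled Otsu level and morphologically closed; the lumen is the
#' largest enclosed (non-border-touching) background component. Inner and
#' outer wall boundaries are then extracted along `n_spokes` radial spokes
#' from the lumen centroid and localised sub-pixel according to the
#' observer's `boundary_method`. Deterministic for fixed (image, params).
#'
#' @param image a `recon_image` (envelope is taken internally).
#' @param params an [observer_params()].
#' @return object of class `segmentation`: list with `angles_rad`,
#'   `inner_r_mm`, `outer_r_mm` (per spoke), `centroid_mm`, `lumen_mask`,
#'   `wall_mask`, `spacing_mm`, `origin_mm`, `observer_id`.
#' @export
segment_lumen <- function(image, params = observer_params()) {
  stopifnot(inherits(image, "recon_image"), inherits(params, "observer_params"))
  env <- abs(image$pixels)
  top <- stats::quantile(env, 0.999, names = FALSE)
  if (top <= 0) stop("segmentation failure: blank image")
  env_n <- pmin(env / top, 1)
  if (params$log_k > 0)
    env_n <- log1p(params$log_k * env_n) / log1p(params$log_k)
  sm <- if (params$smooth_sigma_px > 0)
    as.matrix(EBImage::gblur(EBImage::Image(env_n), params$smooth_sigma_px))
  else env_n

  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1)) *
    params$threshold_factor
  wall_raw <- sm > thr
  # Morphological closing bridges the band-limited intensity dip inside a
  # thick wall and the weak lateral rims of the limited-view arc. The
  # radius is adapted upward (topology only; boundary placement below is
  # independent of the mask's exact edges) until a closed annulus appears.
  lumen <- NULL
  for (mult in c(1, 1.5, 2, 3)) {
    rad <- ceiling(params$close_radius_px * mult)
    wall <- wall_raw
    if (rad > 0) {
      brush <- EBImage::makeBrush(2 * rad + 1, "disc")
      wall <- as.matrix(EBImage::closing(EBImage::Image(wall * 1), brush)) > 0.5
    }
    lumen <- find_lumen(wall)
    if (!is.null(lumen)) break
  }
  if (is.null(lumen))
    stop("segmentation failure: no closed annulus found")

  s <- image$spacing_mm
  idx <- which(lumen, arr.ind = TRUE)
  cx <- image$origin_mm[1] + (mean(idx[, 2]) - 1) * s
  cy <- image$origin_mm[2] + (mean(idx[, 1]) - 1) * s

  n_sp <- params$n_spokes
  angles <- 2 * pi * (seq_len(n_sp) - 1) / n_sp
  rmax <- (min(dim(env)) / 2 - 2) * s
  rr <- seq(s, rmax, by = s / 2)
  inner_r <- outer_r <- rep(NA_real_, n_sp)
  for (a in seq_len(n_sp)) {
    px <- cx + rr * cos(angles[a])
    py <- cy + rr * sin(angles[a])
    wall_prof <- interp_bilinear(wall * 1, px, py, s, image$origin_mm) > 0.5
    env_prof <- interp_bilinear(sm, px, py, s, image$origin_mm)
    runs <- rle(wall_prof)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    hit <- which(runs$values)
    if (length(hit) == 0) next
    # The wall spans from the first TRUE run outward: band-limited
    # reconstruction renders thick walls as two rims with a dip between,
    # so merge all runs starting within max_wall_mm of the first one.
    k0 <- hit[1]
    kmax <- hit[rr[starts[hit]] - rr[starts[k0]] <= params$max_wall_mm]
    i_in <- starts[k0]; i_out <- ends[kmax[length(kmax)]]
    if (params$boundary_method == "mask") {
      inner_r[a] <- rr[i_in]; outer_r[a] <- rr[i_out]
      next
    }
    # rim search windows around the mask edges
    win <- max(3L, round(0.35 / (s / 2)))
    in_lo <- max(1L, i_in - win); in_hi <- min(length(rr), i_in + win)
    out_lo <- max(1L, i_out - win); out_hi <- min(length(rr), i_out + win)
    ip <- in_lo - 1L + which.max(env_prof[in_lo:in_hi])
    op <- out_lo - 1L + which.max(env_prof[out_lo:out_hi])
    if (params$boundary_method == "peak") {
      inner_r[a] <- refine_peak(rr, env_prof, ip)
      outer_r[a] <- refine_peak(rr, env_prof, op)
    } else {                              # halfmax
      half_i <- env_prof[ip] / 2
      j <- ip
      while (j > 1 && env_prof[j] > half_i) j <- j - 1
      inner_r[a] <- if (env_prof[j] > half_i) rr[j] else
        rr[j] + (rr[j + 1] - rr[j]) * (half_i - env_prof[j]) /
          (env_prof[j + 1] - env_prof[j])
      half_o <- env_prof[op] / 2
      j <- op
      while (j < length(rr) && env_prof[j] > half_o) j <- j + 1
      outer_r[a] <- if (env_prof[j] > half_o) rr[j] else
        rr[j - 1] + (rr[j] - rr[j - 1]) * (half_o - env_prof[j - 1]) /
          (env_prof[j] - env_prof[j - 1])
    }
  }
  # reject spokes that latched onto artifacts: deviation from the local
  # circular median marks the crossing invalid (filled in by measure())
  inner_r <- reject_radial_outliers(inner_r, tol_mm = 0.4)
  outer_r <- reject_radial_outliers(outer_r, tol_mm = 0.5)
  if (mean(is.na(inner_r)) > 0.25)
    stop("segmentation failure: too many spokes without a wall crossing")

  structure(list(angles_rad = angles, inner_r_mm = inner_r,
                 outer_r_mm = outer_r, centroid_mm = c(cx, cy),
                 lumen_mask = lumen, wall_mask = wall,
                 spacing_mm = s, origin_mm = image$origin_mm,
                 observer_id = params$id),
            class = "segmentation")
}

# The lumen is the largest *compact* enclosed background component: a
# disk, not the enclosed dark ring that the intensity dip inside a thick
# wall can form (compactness = area / circumscribed-circle area about the
# component centroid rejects rings). NULL when no usable component exists.
find_lumen <- function(wall) {
  labm <- as.matrix(EBImage::bwlabel(EBImage::Image((!wall) * 1)))
  border_labels <- unique(c(labm[1, ], labm[nrow(labm), ],
                            labm[, 1], labm[, ncol(labm)]))
  inner_labels <- setdiff(setdiff(unique(as.vector(labm)), border_labels), 0)
  if (length(inner_labels) == 0) return(NULL)
  feat <- vapply(inner_labels, function(l) {
    px <- which(labm == l, arr.ind = TRUE)
    ctr <- colMeans(px)
    rmax <- sqrt(max((px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2))
    c(size = nrow(px), compact = nrow(px) / (pi * rmax^2 + 1))
  }, numeric(2))
  cand <- which(feat["compact", ] >= 0.5 & feat["size", ] >= 20)
  if (length(cand) == 0) return(NULL)
  lumen_lab <- inner_labels[cand[which.max(feat["size", cand])]]
  labm == lumen_lab
}

# Mark entries deviating more than tol_mm from the local circular median
# (window of 9 spokes) as NA.
reject_radial_outliers <- function(r, tol_mm, window = 9) {
  n <- length(r)
  if (n < window) return(r)
  half <- window %/% 2
  med <- vapply(seq_len(n), function(i) {
    idx <- ((i - half - 1):(i + half - 1)) %% n + 1
    stats::median(r[idx], na.rm = TRUE)
  }, numeric(1))
  r[!is.na(r) & abs(r - med) > tol_mm] <- NA_real_
  r
}

# Fill NA entries of a circular sequence by linear interpolation between
# the nearest valid neighbours (wrapping around).
fill_circular <- function(r) {
  ok <- which(!is.na(r))
  if (length(ok) == length(r)) return(r)
  n <- length(r)
  x3 <- c(ok - n, ok, ok + n)
  y3 <- rep(r[ok], 3)
  r[is.na(r)] <- stats::approx(x3, y3, xout = which(is.na(r)))$y
  r
}

#' Morphometric measurement from a segmentation
#'
#' Computes lumen cross-sectional area (CSA) as the area of the polygon
#' spanned by the per-spoke inner-boundary radii (shoelace formula with
#' the inscribed-polygon curvature correction, exact for circles), wall
#' thickness (TWT) as the circumferential mean of outer minus inner spoke
#' radii, and, when a reference area is supplied, the stenosis rate
#' SR = (1 - CSA / reference) * 100 (Myer-Cotton-style area ratio).
#'
#' @param seg a [segment_lumen()] result.
#' @param reference_csa reference lumen area, mm^2 (optional).
#' @return object of class `morphometry_result`: list(twt_mm, csa_mm2,
#'   sr_pct or NA, inner_contour_mm, outer_contour_mm, observer_id).
#' @export
measure <- function(seg, reference_csa = NULL) {
  stopifnot(inherits(seg, "segmentation"))
  ok <- !is.na(seg$inner_r_mm) & !is.na(seg$outer_r_mm) &
    seg$outer_r_mm > seg$inner_r_mm
  if (mean(ok) < 0.75)
    stop("geometry error: spokes failing to cross both contours")
  ang <- seg$angles_rad
  # circular interpolation across the few spokes without a valid crossing
  ri <- fill_circular(ifelse(ok, seg$inner_r_mm, NA_real_))
  ro <- fill_circular(ifelse(ok, seg$outer_r_mm, NA_real_))
  dth <- 2 * pi / length(ang)
  # shoelace over consecutive spokes; dth/sin(dth) corrects polygon inscription
  csa <- sum(0.5 * ri * c(ri[-1], ri[1]) * sin(dth)) * (dth / sin(dth))
  twt <- mean(ro - ri)
  sr <- if (!is.null(reference_csa)) (1 - csa / reference_csa) * 100 else NA_real_
  inner_xy <- cbind(seg$centroid_mm[1] + ri * cos(ang),
                    seg$centroid_mm[2] + ri * sin(ang))
  outer_xy <- cbind(seg$centroid_mm[1] + ro * cos(ang),
                    seg$centroid_mm[2] + ro * sin(ang))
  structure(list(twt_mm = twt, csa_mm2 = csa, sr_pct = sr,
                 inner_contour_mm = inner_xy, outer_contour_mm = outer_xy,
                 observer_id = seg$observer_id),
            class = "morphometry_result")
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(sprintf("Morphometry [%s]: TWT = %.3f mm, CSA = %.2f mm^2, SR = %s\n",
              x$observer_id, x$twt_mm, x$csa_mm2,
              if (is.na(x$sr_pct)) "-" else sprintf("%.1f%%", x$sr_pct)))
  invisible(x)
}

#' Respiratory CSA time series
#'
#' Segments and measures every frame of a respiratory sequence and
#' summarises the cycle: per-frame CSA, the phases of minimal and maximal
#' area, and the modulation depth (max - min) / min.
#'
#' @param images list of `recon_image`s (>= 4 frames spanning a cycle).
#' @param phases numeric vector of respiratory phases (radians), one per
#'   frame.
#' @param params an [observer_params()].
#' @return list(trace = data.frame(phase, csa_mm2), min_phase, max_phase,
#'   modulation_depth).
#' @export
csa_timeseries <- function(images, phases, params = observer_params()) {
  stopifnot(length(images) == length(phases), length(images) >= 4)
  csa <- vapply(seq_along(images), function(i) {
    res <- tryCatch(measure(segment_lumen(images[[i]], params)),
                    error = function(e)
                      stop(sprintf("frame %d: %s", i, conditionMessage(e)),
                           call. = FALSE))
    res$csa_mm2
  }, numeric(1))
  list(trace = data.frame(phase = phases, csa_mm2 = csa),
       min_phase = phases[which.min(csa)],
       max_phase = phases[which.max(csa)],
       modulation_depth = (max(csa) - min(csa)) / min(csa))
}

#' Run two observers on one image
#'
#' @param image a `recon_image`.
#' @param params_a,params_b [observer_params()] for the two observers.
#' @param reference_csa optional reference area for SR.
#' @return list of two `morphometry_result`s named by observer id.
#' @export
two_observer_run <- function(image, params_a, params_b, reference_csa = NULL) {
  res <- list(measure(segment_lumen(image, params_a), reference_csa),
              measure(segment_lumen(image, params_b), reference_csa))
  names(res) <- c(params_a$id, params_b$id)
  res
}
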
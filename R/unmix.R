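#' Per-pixel non-negative spectral unmixing
#'
#' Decomposes a co-registered multiwavelength stack of envelope
#' reconstructions into chromophore concentration maps by solving, at
#' every pixel, the non-negative least-squares problem
#' `c = argmin || E c - y ||^2, c >= 0` where `y` is the pixel's spectrum
#' across wavelengths and `E` the extinction matrix. With three
#' wavelengths and four chromophores the global problem is
#' underdetermined; recovery relies on at most three chromophores being
#' active per pixel (as the phantoms guarantee), which makes each pixel's
#' active submatrix full-rank. NNLS returns the canonical non-negative
#' solution either way. Pixels whose spectral norm is below
#' `min_norm_frac` times the stack maximum are skipped (left zero) for
#' speed; the residual map stores `|| E c - y ||`.
#'
#' @param stack named list of `recon_image`s, one per wavelength, on one
#'   grid; names like "760nm" (as from [acquire_multiwavelength()] +
#'   [backproject()]).
#' @param E extinction matrix from [extinction_matrix()]; rows must match
#'   the stack wavelengths in order.
#' @param min_norm_frac skip threshold as a fraction of the maximum pixel
#'   spectral norm (default 1e-3).
#' @return object of class `unmixed_maps`: list with `conc` (named list of
#'   matrices per chromophore), `hbt`, `so2` (masked with NA, see
#'   [oxygen_saturation()]), `residual`, `spacing_mm`, `origin_mm`.
#' @export
unmix <- function(stack, E = extinction_matrix(), min_norm_frac = 1e-3) {
  stopifnot(length(stack) == nrow(E))
  wl_stack <- vapply(stack, function(im) im$wavelength_nm, numeric(1))
  wl_E <- as.numeric(sub("nm$", "", rownames(E)))
  if (!isTRUE(all.equal(unname(wl_stack), wl_E)))
    stop("configuration error: stack wavelengths do not match extinction matrix rows")
  dims <- dim(stack[[1]]$pixels)
  Y <- vapply(stack, function(im) {
    stopifnot(all(dim(im$pixels) == dims))
    as.vector(abs(im$pixels))
  }, numeric(prod(dims)))                     # pixels x wavelengths

  nchrom <- ncol(E)
  C <- matrix(0, nrow = nrow(Y), ncol = nchrom)
  resid <- numeric(nrow(Y))
  norms <- sqrt(rowSums(Y^2))
  active <- which(norms > min_norm_frac * max(norms))
  for (p in active) {
    fit <- pracma::lsqnonneg(E, Y[p, ])
    C[p, ] <- fit$x
    resid[p] <- sqrt(fit$resid.norm)
  }
  conc <- lapply(seq_len(nchrom), function(i) matrix(C[, i], nrow = dims[1]))
  names(conc) <- colnames(E)
  hbt <- conc$HbO2 + conc$HbR
  maps <- structure(list(conc = conc, hbt = hbt, so2 = NULL,
                         residual = matrix(resid, nrow = dims[1]),
                         spacing_mm = stack[[1]]$spacing_mm,
                         origin_mm = stack[[1]]$origin_mm),
                    class = "unmixed_maps")
  maps$so2 <- oxygen_saturation(maps)
  maps
}

#' Blood oxygen saturation map
#'
#' SO2 = HbO2 / (HbO2 + HbR), masked (NA) wherever total hemoglobin falls
#' below `mask_threshold`. The default threshold is 5% of the 99th
#' percentile of the HbT map, which suppresses noise-driven saturation
#' speckle outside perfused tissue.
#'
#' @param maps an `unmixed_maps`.
#' @param mask_threshold absolute HbT threshold (>= 0); default as above.
#' @return matrix of SO2 in [0, 1] with NA where masked.
#' @export
oxygen_saturation <- function(maps, mask_threshold = NULL) {
  stopifnot(inherits(maps, "unmixed_maps"))
  hbt <- maps$hbt
  if (is.null(mask_threshold))
    mask_threshold <- 0.05 * stats::quantile(hbt, 0.99, names = FALSE)
  if (mask_threshold < 0) stop("mask threshold must be >= 0")
  so2 <- maps$conc$HbO2 / hbt
  so2[hbt < mask_threshold | hbt == 0] <- NA_real_
  so2
}

#' Between-group chromophore contrast within a region
#'
#' Compares two unmixed map sets over one region mask: mean concentration
#' per chromophore in each, and their ratio (first / second). Used to
#' check the expected qualitative group orderings (e.g. scar tissue shows
#' more collagen than edematous tissue; edema shows more water).
#'
#' @param maps_1,maps_2 `unmixed_maps` on the same grid.
#' @param mask logical matrix selecting the region (same dims).
#' @return data.frame: chromophore, mean_1, mean_2, ratio.
#' @export
group_contrast <- function(maps_1, maps_2, mask) {
  stopifnot(inherits(maps_1, "unmixed_maps"), inherits(maps_2, "unmixed_maps"),
            is.logical(mask))
  if (!any(mask)) stop("region error: empty mask")
  stopifnot(all(dim(maps_1$conc[[1]]) == dim(mask)),
            all(dim(maps_2$conc[[1]]) == dim(mask)))
  chs <- names(maps_1$conc)
  m1 <- vapply(chs, function(ch) mean(maps_1$conc[[ch]][mask]), numeric(1))
  m2 <- vapply(chs, function(ch) mean(maps_2$conc[[ch]][mask]), numeric(1))
  data.frame(chromophore = chs, mean_1 = m1, mean_2 = m2,
             ratio = ifelse(m1 == m2, 1, m1 / m2),
             row.names = NULL, stringsAsFactors = FALSE)
}
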
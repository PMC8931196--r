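#' Write / read a reconstructed image as 32-bit float TIFF
#'
#' Pixel data go to a float TIFF; spacing, origin and wavelength go to a
#' JSON sidecar (`<path>.json`). Pixels are stored scaled into [0, 1]
#' (TIFF float range accepted by the writer) with the scale factor
#' recorded in the sidecar, so the round trip is lossless up to float
#' precision.
#'
#' @param image a `recon_image`.
#' @param path TIFF path.
#' @return `write_recon_tiff`: the path, invisibly; `read_recon_tiff`: a
#'   `recon_image`.
#' @export
write_recon_tiff <- function(image, path) {
  stopifnot(inherits(image, "recon_image"))
  lo <- min(image$pixels); hi <- max(image$pixels)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((image$pixels - lo) / scale, path, bits.per.sample = 32)
  jsonlite::write_json(list(spacing_mm = image$spacing_mm,
                            origin_mm = image$origin_mm,
                            wavelength_nm = image$wavelength_nm,
                            offset = lo, scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recon_tiff
#' @export
read_recon_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$scale + meta$offset
  structure(list(pixels = px, spacing_mm = meta$spacing_mm,
                 origin_mm = meta$origin_mm,
                 wavelength_nm = if (is.null(meta$wavelength_nm))
                   NA_real_ else meta$wavelength_nm),
            class = "recon_image")
}

#' Write / read a chromophore map as multi-page float TIFF
#'
#' One page per chromophore (page order in the JSON sidecar along with
#' spacing, origin and per-page scaling).
#'
#' @param map a `chromophore_map` or `unmixed_maps` (its `conc` list is
#'   written).
#' @param path TIFF path.
#' @return write: path invisibly; read: list(conc, spacing_mm, origin_mm).
#' @export
write_maps_tiff <- function(map, path) {
  conc <- map$conc
  scales <- vapply(conc, function(m) max(m, 1e-300), numeric(1))
  pages <- lapply(seq_along(conc), function(i) conc[[i]] / scales[i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  jsonlite::write_json(list(pages = names(conc), scales = scales,
                            spacing_mm = map$spacing_mm,
                            origin_mm = map$origin_mm),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maps_tiff
#' @export
read_maps_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  conc <- lapply(seq_along(pages), function(i) pages[[i]] * meta$scales[i])
  names(conc) <- meta$pages
  list(conc = conc, spacing_mm = meta$spacing_mm, origin_mm = meta$origin_mm)
}

#' Serialize a phantom to JSON
#'
#' Ground truth (geometry, morphometry, group, seed) round-trips through
#' `read_phantom_json()`.
#'
#' @param phantom a `phantom`.
#' @param path JSON path.
#' @return write: path invisibly; read: a `phantom`.
#' @export
write_phantom_json <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  x <- unclass(phantom)
  x$spec <- unclass(x$spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_phantom_json
#' @export
read_phantom_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$spec <- do.call(group_spec, x$spec)
  if (!is.null(x$inclusions) && length(x$inclusions) > 0)
    x$inclusions <- as.data.frame(x$inclusions)
  else x$inclusions <- NULL
  structure(x, class = "phantom")
}

#' Write a morphometry results table as CSV
#'
#' One row per image per observer (group, phantom index, observer,
#' TWT/CSA/SR and ground truth), as produced by [recover_cohort()].
#'
#' @param results data.frame.
#' @param path CSV path.
#' @return path, invisibly.
#' @export
write_morphometry_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
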
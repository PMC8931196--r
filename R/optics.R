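#' Chromophores modelled by the package
#' @export
CHROMOPHORES <- c("HbO2", "HbR", "collagen", "water")

#' Acquisition wavelengths (nm)
#'
#' The three near-infrared wavelengths at which multispectral images are
#' acquired.
#' @export
WAVELENGTHS_NM <- c(760, 840, 910)

#' Load an extinction-coefficient table
#'
#' Reads a CSV with columns `chromophore`, `wavelength_nm`, `epsilon`
#' (cm^-1 per concentration unit). With no argument, the table bundled
#' with the package is loaded; it covers HbO2, HbR, collagen and water at
#' 760, 840 and 910 nm. Values are read verbatim: no spectral
#' interpolation is performed, and requesting a wavelength absent from the
#' table is an error.
#'
#' @param path CSV path; default the bundled table.
#' @return data.frame of class `extinction_table`.
#' @export
extinction_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "extinction_coefficients.csv",
                        package = "tracheapat")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("chromophore", "wavelength_nm", "epsilon") %in% names(tab)))
  if (any(tab$epsilon < 0)) stop("extinction coefficients must be >= 0")
  class(tab) <- c("extinction_table", "data.frame")
  tab
}

ext_lookup <- function(table, chromophore, wavelength) {
  hit <- table$epsilon[table$chromophore == chromophore &
                         table$wavelength_nm == wavelength]
  if (length(hit) != 1)
    stop(sprintf("no extinction entry for %s at %g nm (no interpolation is done)",
                 chromophore, wavelength))
  hit
}

#' Extinction matrix for unmixing
#'
#' Builds the n_wavelength x n_chromophore matrix E with
#' `E[j, i] = epsilon_i(lambda_j)`. Rows are ordered as `wavelengths`,
#' columns as `chromophores`; dimnames record both so the ordering is
#' stable and self-describing.
#'
#' @param table an [extinction_table()].
#' @param wavelengths numeric, nm.
#' @param chromophores character.
#' @return matrix (wavelengths x chromophores).
#' @export
extinction_matrix <- function(table = extinction_table(),
                              wavelengths = WAVELENGTHS_NM,
                              chromophores = CHROMOPHORES) {
  E <- vapply(chromophores, function(ch)
    vapply(wavelengths, function(wl) ext_lookup(table, ch, wl), numeric(1)),
    numeric(length(wavelengths)))
  E <- matrix(E, nrow = length(wavelengths),
              dimnames = list(paste0(wavelengths, "nm"), chromophores))
  E
}

#' Absorption coefficient map at one wavelength
#'
#' Linear spectral mixing: mu_a(lambda) = sum_i epsilon_i(lambda) c_i,
#' evaluated pixelwise over a chromophore map.
#'
#' @param map a `chromophore_map` (see [rasterize()]).
#' @param wavelength nm; must be present in `table`.
#' @param table an [extinction_table()].
#' @return matrix of absorption coefficients (cm^-1), same raster as `map`.
#' @export
absorption_map <- function(map, wavelength, table = extinction_table()) {
  stopifnot(inherits(map, "chromophore_map"))
  mu <- 0
  for (ch in CHROMOPHORES)
    mu <- mu + ext_lookup(table, ch, wavelength) * map$conc[[ch]]
  mu
}

#' Fluence models
#'
#' `fluence_uniform()` returns the constant-fluence model (the default:
#' unmixing then operates on Grueneisen-and-fluence-scaled relative
#' concentrations, as clinical multispectral optoacoustic systems report).
#' `fluence_exponential(mu_eff, surface_y_mm)` attenuates exponentially
#' with depth below a surface plane, for robustness experiments.
#'
#' @param mu_eff effective attenuation, cm^-1 (>= 0).
#' @param surface_y_mm y-coordinate (mm) of the illuminated surface; depth
#'   is measured downward from it (zero above it).
#' @return function(x_mm, y_mm) -> fluence (dimensionless, > 0).
#' @export
fluence_uniform <- function() function(x_mm, y_mm) rep(1, length(x_mm))

#' @rdname fluence_uniform
#' @export
fluence_exponential <- function(mu_eff, surface_y_mm = 10) {
  if (mu_eff < 0) stop("mu_eff must be >= 0")
  function(x_mm, y_mm) {
    depth_cm <- pmax(surface_y_mm - y_mm, 0) / 10
    exp(-mu_eff * depth_cm)
  }
}

#' Initial pressure map
#'
#' Photoacoustic generation: p0 = Gamma * mu_a * Phi, with Grueneisen
#' parameter Gamma (thermoacoustic efficiency) and fluence Phi. With the
#' default uniform fluence and Gamma = 1, p0 is proportional to mu_a.
#'
#' @param mu_a absorption matrix from [absorption_map()].
#' @param map the originating `chromophore_map` (provides the raster).
#' @param fluence a fluence model function; default [fluence_uniform()].
#' @param gamma Grueneisen parameter, > 0.
#' @param wavelength nm, recorded as metadata.
#' @return object of class `pressure_map`: list(p0, spacing_mm, origin_mm,
#'   wavelength_nm).
#' @export
initial_pressure <- function(mu_a, map, fluence = fluence_uniform(),
                             gamma = 1, wavelength = NA_real_) {
  if (gamma <= 0) stop("Grueneisen parameter must be > 0")
  xy <- raster_coords(dim(mu_a), map$spacing_mm, map$origin_mm)
  phi <- matrix(fluence(xy$x, xy$y), nrow = nrow(mu_a))
  if (any(phi < 0)) stop("fluence must be non-negative")
  structure(list(p0 = gamma * mu_a * phi,
                 spacing_mm = map$spacing_mm,
                 origin_mm = map$origin_mm,
                 wavelength_nm = wavelength),
            class = "pressure_map")
}

# Physical coordinates (mm) of every pixel centre of a raster.
# Column j -> x, row i -> y; origin_mm is the centre of pixel [1,1].
raster_coords <- function(dims, spacing_mm, origin_mm) {
  i <- rep(seq_len(dims[1]), times = dims[2])
  j <- rep(seq_len(dims[2]), each = dims[1])
  list(x = origin_mm[1] + (j - 1) * spacing_mm,
       y = origin_mm[2] + (i - 1) * spacing_mm)
}
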
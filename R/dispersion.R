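#' Tabulated complex refractive index of a material
#'
#' A dispersion table holds the real index n and extinction coefficient k of
#' a material on a strictly increasing wavelength grid (nm).  Queries between
#' grid points are linearly interpolated; queries outside the tabulated range
#' raise an error unless `extrapolate = TRUE`, in which case the end value is
#' held constant and the result is flagged.
#'
#' @param material_id character scalar naming the material.
#' @param wavelength_nm strictly increasing numeric vector (nm).
#' @param n real refractive index per grid point, all > 0.
#' @param k extinction coefficient per grid point, all >= 0.
#' @return An object of class `dispersion_table`.
#' @export
dispersion_table <- function(material_id, wavelength_nm, n, k = rep(0, length(n))) {
  stopifnot(is.character(material_id), length(material_id) == 1L)
  wavelength_nm <- as.numeric(wavelength_nm)
  n <- as.numeric(n); k <- as.numeric(k)
  if (length(wavelength_nm) < 2L || any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing with >= 2 points")
  if (length(n) != length(wavelength_nm) || length(k) != length(wavelength_nm))
    stop("n and k must match the wavelength grid length")
  if (any(!is.finite(n)) || any(n <= 0)) stop("n must be finite and > 0 everywhere")
  if (any(!is.finite(k)) || any(k < 0)) stop("k must be finite and >= 0 everywhere")
  structure(list(material_id = material_id, wavelength_nm = wavelength_nm,
                 n = n, k = k),
            class = "dispersion_table")
}

#' @export
print.dispersion_table <- function(x, ...) {
  cat(sprintf("<dispersion_table> %s: %d points, %.0f-%.0f nm, n in [%.3f, %.3f], max k %.3g\n",
              x$material_id, length(x$wavelength_nm), min(x$wavelength_nm),
              max(x$wavelength_nm), min(x$n), max(x$n), max(x$k)))
  invisible(x)
}

#' Complex refractive index at given wavelengths
#'
#' Returns the complex index n + i*k (time convention `exp(-i*omega*t)`, so
#' k >= 0 corresponds to absorption) by linear interpolation in wavelength.
#'
#' @param table a `dispersion_table`.
#' @param wavelength_nm numeric vector of query wavelengths (nm).
#' @param extrapolate if `TRUE`, out-of-range queries return the boundary
#'   value instead of erroring.
#' @return complex vector of the same length as `wavelength_nm`.
#' @export
refractive_index <- function(table, wavelength_nm, extrapolate = FALSE) {
  stopifnot(inherits(table, "dispersion_table"))
  wl <- as.numeric(wavelength_nm)
  rng <- range(table$wavelength_nm)
  out_of_range <- wl < rng[1] | wl > rng[2]
  if (any(out_of_range) && !extrapolate)
    stop(sprintf("dispersion table '%s' does not cover %.1f nm (tabulated %.0f-%.0f nm)",
                 table$material_id, wl[which(out_of_range)[1]], rng[1], rng[2]))
  n <- stats::approx(table$wavelength_nm, table$n, xout = wl, rule = 2)$y
  k <- stats::approx(table$wavelength_nm, table$k, xout = wl, rule = 2)$y
  complex(real = n, imaginary = k)
}

# constant-index media used in examples and as incident medium
.const_material <- function(id, n, k = 0) {
  dispersion_table(id, c(1, 1e7), c(n, n), c(k, k))
}

#' Built-in materials
#'
#' `material()` returns a bundled dispersion table by name.  `"air"` and
#' `"vacuum"` are constant n = 1; `"glass"` is constant n = 1.5 (convenience
#' for textbook interfaces).  All other materials (si, sio2, si3n4, ito,
#' tio2, zro2, polysi, isdp) are loaded from the synthetic tables bundled
#' under `extdata/dispersion_synthetic/`, which are smooth model curves
#' anchored to standard optical-constant compilations -- synthetic stand-ins,
#' not measurements of a specific device.
#'
#' @param id material name (case-insensitive).
#' @return a `dispersion_table`.
#' @export
material <- function(id) {
  id <- tolower(id)
  if (id %in% c("air", "vacuum")) return(.const_material(id, 1))
  if (id == "glass") return(.const_material(id, 1.5))
  dir <- system.file("extdata", "dispersion_synthetic", package = "etalonsim")
  nf <- file.path(dir, paste0(id, "_n.tsv"))
  kf <- file.path(dir, paste0(id, "_k.tsv"))
  if (!file.exists(nf))
    stop(sprintf("unknown material '%s'; bundled: %s", id,
                 paste(sort(sub("_n\\.tsv$", "", basename(Sys.glob(file.path(dir, "*_n.tsv"))))),
                       collapse = ", ")))
  nt <- utils::read.delim(nf)
  kt <- utils::read.delim(kf)
  dispersion_table(id, nt$wavelength_nm, nt$n, kt$k)
}

#' Names of the bundled materials
#' @return character vector of material ids accepted by [material()].
#' @export
list_materials <- function() {
  dir <- system.file("extdata", "dispersion_synthetic", package = "etalonsim")
  c("air", "vacuum", "glass",
    sort(sub("_n\\.tsv$", "", basename(Sys.glob(file.path(dir, "*_n.tsv"))))))
}
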
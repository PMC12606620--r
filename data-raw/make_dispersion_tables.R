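# Generates the synthetic dispersion tables bundled under
# inst/extdata/dispersion_synthetic/.  The tables are smooth interpolations of
# anchor values assembled from standard optical-constant compilations
# (Sellmeier-type behaviour for the dielectrics, band-edge absorption for
# silicon, free-carrier absorption for the doped/conductive films).  They are
# synthetic stand-ins, not measured data for any specific device: fringe
# amplitudes computed from them are realistic in structure but not traceable
# to a particular CCD.
#
# Run from the package root:  Rscript data-raw/make_dispersion_tables.R

grid <- seq(600, 1300, by = 2)  # nm

spline_at <- function(x, y, grid) stats::spline(x, y, xout = grid, method = "natural")$y

# anchors: wavelength_nm, n ; k from absorption coefficient alpha (cm^-1)
anchors <- list(
  si = list(
    n = list(x = c(600, 700, 785, 900, 1000, 1100, 1200, 1300),
             y = c(3.939, 3.774, 3.696, 3.620, 3.575, 3.545, 3.525, 3.510)),
    alpha = list(x = c(600, 700, 785, 900, 1000, 1100, 1200, 1300),
                 y = c(4170, 1900, 1000, 306, 64, 3.5, 0.02, 1e-4))
  ),
  sio2 = list(
    n = list(x = c(600, 785, 1000, 1300), y = c(1.458, 1.454, 1.450, 1.446)),
    alpha = NULL
  ),
  si3n4 = list(
    n = list(x = c(600, 785, 1000, 1300), y = c(2.027, 2.007, 1.995, 1.985)),
    alpha = NULL
  ),
  ito = list(
    n = list(x = c(600, 700, 785, 900, 1000, 1100, 1200, 1300),
             y = c(1.93, 1.86, 1.80, 1.72, 1.65, 1.57, 1.49, 1.41)),
    k = list(x = c(600, 785, 900, 1000, 1100, 1200, 1300),
             y = c(0.005, 0.010, 0.020, 0.034, 0.055, 0.085, 0.120))
  ),
  tio2 = list(
    n = list(x = c(600, 785, 1000, 1300), y = c(2.437, 2.364, 2.320, 2.290)),
    alpha = NULL
  ),
  zro2 = list(
    n = list(x = c(600, 785, 1000, 1300), y = c(2.160, 2.131, 2.113, 2.100)),
    alpha = NULL
  ),
  # polysilicon: crystalline-silicon index with defect-enhanced absorption
  polysi = list(
    n = list(x = c(600, 700, 785, 900, 1000, 1100, 1200, 1300),
             y = c(3.960, 3.790, 3.710, 3.632, 3.586, 3.556, 3.536, 3.520)),
    alpha = list(x = c(600, 700, 785, 900, 1000, 1100, 1200, 1300),
                 y = c(6000, 2900, 1600, 520, 130, 20, 2, 0.5))
  ),
  # ISDP (in-situ doped polysilicon): polysilicon with free-carrier absorption
  isdp = list(
    n = list(x = c(600, 700, 785, 900, 1000, 1100, 1200, 1300),
             y = c(3.950, 3.782, 3.703, 3.626, 3.581, 3.552, 3.533, 3.518)),
    alpha = list(x = c(600, 700, 785, 900, 1000, 1100, 1200, 1300),
                 y = c(7000, 3800, 2400, 1100, 600, 420, 380, 370))
  )
)

out_dir <- file.path("inst", "extdata", "dispersion_synthetic")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

for (mat in names(anchors)) {
  a <- anchors[[mat]]
  n <- spline_at(a$n$x, a$n$y, grid)
  if (!is.null(a$k)) {
    k <- pmax(spline_at(a$k$x, a$k$y, grid), 0)
  } else if (!is.null(a$alpha)) {
    # interpolate log10(alpha) for smooth band-edge decay, k = alpha*lambda/(4*pi)
    la <- spline_at(a$alpha$x, log10(a$alpha$y), grid)
    k <- pmax(10^la * (grid * 1e-7) / (4 * pi), 0)
  } else {
    k <- rep(0, length(grid))
  }
  write.table(data.frame(wavelength_nm = grid, n = sprintf("%.6f", n)),
              file.path(out_dir, paste0(mat, "_n.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(wavelength_nm = grid, k = sprintf("%.6e", k)),
              file.path(out_dir, paste0(mat, "_k.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
cat("wrote", length(anchors) * 2, "tables to", out_dir, "\n")
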
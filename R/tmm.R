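#' Planar layer of a multilayer stack
#'
#' @param material a `dispersion_table` (or a material name passed to
#'   [material()]).
#' @param thickness_nm layer thickness in nm, finite and > 0.
#' @return an object of class `tmm_layer`.
#' @export
layer <- function(material, thickness_nm) {
  if (is.character(material)) material <- material(material)
  stopifnot(inherits(material, "dispersion_table"))
  if (!is.numeric(thickness_nm) || length(thickness_nm) != 1L ||
      !is.finite(thickness_nm) || thickness_nm < 0)
    stop_etalon("etalonsim_invalid_argument", "layer thickness must be finite and >= 0")
  structure(list(material = material, thickness_nm = thickness_nm), class = "tmm_layer")
}

#' Multilayer stack bounded by semi-infinite media
#'
#' Layers are ordered incidence-side first.  The incident medium is assumed
#' lossless for the energy bookkeeping; the substrate is the semi-infinite
#' exit medium.
#'
#' @param layers list of [layer()] objects (may be empty).
#' @param incident incident-medium `dispersion_table` (default air).
#' @param substrate exit-medium `dispersion_table` (default air).
#' @return an object of class `tmm_stack`.
#' @export
optical_stack <- function(layers = list(), incident = material("air"),
                          substrate = material("air")) {
  if (is.character(incident)) incident <- material(incident)
  if (is.character(substrate)) substrate <- material(substrate)
  if (inherits(layers, "tmm_layer")) layers <- list(layers)
  stopifnot(all(vapply(layers, inherits, logical(1), "tmm_layer")),
            inherits(incident, "dispersion_table"),
            inherits(substrate, "dispersion_table"))
  structure(list(incident = incident, layers = layers, substrate = substrate),
            class = "tmm_stack")
}

#' @export
print.tmm_stack <- function(x, ...) {
  cat(sprintf("<tmm_stack> %s | %s | %s\n", x$incident$material_id,
              if (length(x$layers) == 0) "(no layers)" else
                paste(vapply(x$layers, function(l)
                  sprintf("%s %.5g nm", l$material$material_id, l$thickness_nm),
                  character(1)), collapse = " | "),
              x$substrate$material_id))
  invisible(x)
}

#' Plane-wave context: wavelength, incidence angle and polarization
#'
#' @param wavelength_nm wavelength in nm, > 0.
#' @param angle incidence angle in radians, in `[0, pi/2)`.
#' @param pol `"s"` or `"p"`.
#' @return an object of class `plane_wave`.
#' @export
plane_wave <- function(wavelength_nm, angle = 0, pol = c("s", "p")) {
  pol <- match.arg(pol)
  if (!is.numeric(wavelength_nm) || any(wavelength_nm <= 0))
    stop_etalon("etalonsim_invalid_argument", "wavelength must be > 0")
  if (angle < 0 || angle >= pi / 2)
    stop_etalon("etalonsim_invalid_argument", "incidence angle must be in [0, pi/2)")
  structure(list(wavelength_nm = wavelength_nm, angle = angle, pol = pol),
            class = "plane_wave")
}

#' Axial wavevector in a medium
#'
#' `k_z = 2 pi n cos(theta) / lambda` with complex index `n = n' + i k`
#' (time convention `exp(-i omega t)`, so `Im(k_z) >= 0` gives forward decay).
#'
#' @param n complex refractive index.
#' @param wavelength_nm wavelength in nm, > 0.
#' @param cos_theta (complex) cosine of the propagation angle in the medium.
#' @return complex wavevector in nm^-1.
#' @export
axial_wavevector <- function(n, wavelength_nm, cos_theta = 1) {
  if (any(!is.finite(wavelength_nm)) || any(wavelength_nm <= 0))
    stop_etalon("etalonsim_invalid_argument", "wavelength must be positive")
  2 * pi * n * cos_theta / wavelength_nm
}

# complex cos(theta_j) from Snell's law, branch chosen so Im(n_j cos_j) >= 0
.snell_cos <- function(n_j, sin0_times_n0) {
  ct <- sqrt(1 - (sin0_times_n0 / n_j)^2)
  flip <- Im(n_j * ct) < 0
  ct[flip] <- -ct[flip]
  ct
}

#' Propagation-angle cosines through a stack (Snell chain)
#'
#' Returns the complex `cos(theta_j)` for the incident medium, every layer,
#' and the substrate, satisfying `n_0 sin(theta_0) = n_j sin(theta_j)` with
#' the branch chosen for forward decay (`Im(n_j cos_j) >= 0`).
#'
#' @param stack a `tmm_stack`.
#' @param context a `plane_wave` (single wavelength).
#' @return complex vector of length `length(layers) + 2`.
#' @export
snell_chain <- function(stack, context) {
  stopifnot(inherits(stack, "tmm_stack"), inherits(context, "plane_wave"))
  wl <- context$wavelength_nm[1]
  media <- c(list(stack$incident), lapply(stack$layers, `[[`, "material"),
             list(stack$substrate))
  nm <- vapply(media, refractive_index, complex(1), wavelength_nm = wl)
  s0 <- nm[1] * sin(context$angle)
  .snell_cos(nm, s0)
}

#' Fresnel amplitude coefficients at a single interface
#'
#' s-polarization: `r = (n1 c1 - n2 c2)/(n1 c1 + n2 c2)`,
#' `t = 2 n1 c1/(n1 c1 + n2 c2)`; p-polarization by the standard analogous
#' forms.  The s-pol identities `t = 1 + r` and `r(1->2) = -r(2->1)` hold.
#'
#' @param pol `"s"` or `"p"`.
#' @param n1,n2 complex indices of the two media (nonzero).
#' @param cos1,cos2 complex propagation-angle cosines.
#' @return list with complex elements `r` and `t` (vectorized).
#' @export
fresnel <- function(pol, n1, cos1, n2, cos2) {
  if (any(n1 == 0) || any(n2 == 0))
    stop_etalon("etalonsim_invalid_argument", "refractive indices must be nonzero")
  if (pol == "s") {
    den <- n1 * cos1 + n2 * cos2
    if (any(abs(den) < 1e-300))
      stop_etalon("etalonsim_degenerate_interface", "vanishing s-pol Fresnel denominator")
    list(r = as.complex((n1 * cos1 - n2 * cos2) / den),
         t = as.complex(2 * n1 * cos1 / den))
  } else if (pol == "p") {
    den <- n2 * cos1 + n1 * cos2
    if (any(abs(den) < 1e-300))
      stop_etalon("etalonsim_degenerate_interface", "vanishing p-pol Fresnel denominator")
    list(r = as.complex((n2 * cos1 - n1 * cos2) / den),
         t = as.complex(2 * n1 * cos1 / den))
  } else stop_etalon("etalonsim_invalid_argument", "pol must be 's' or 'p'")
}

# phase clamp: beyond this imaginary phase the layer is numerically opaque
.delta_im_max <- 700

#' Single-layer transfer matrix
#'
#' `(1/t) * [[e^{-i d}, r e^{-i d}], [r e^{i d}, e^{i d}]]`: propagation by
#' phase `delta` followed by the interface to the next medium with Fresnel
#' coefficients `(r, t)`.  `Im(delta)` is clamped at 700 so that thick
#' absorbing layers do not overflow; transmission underflows to 0 beyond it.
#'
#' @param delta complex phase `k_z d`.
#' @param r_next,t_next Fresnel coefficients of the trailing interface.
#' @return 2x2 complex matrix.
#' @export
layer_matrix <- function(delta, r_next, t_next) {
  if (abs(t_next) == 0)
    stop_etalon("etalonsim_degenerate_interface", "total-reflection interface: t = 0")
  if (Im(delta) > .delta_im_max)
    delta <- complex(real = Re(delta), imaginary = .delta_im_max)
  em <- exp(-1i * delta); ep <- exp(1i * delta)
  matrix(c(em, r_next * ep, r_next * em, ep), 2, 2) / t_next
}

# vectorized-over-wavelength core: returns r, t, and the boundary-medium
# quantities needed for R/T; single code path shared by stack_matrix and
# tmm_response
.tmm_core <- function(stack, wavelength_nm, angle, pol, keep_matrix = FALSE) {
  media <- c(list(stack$incident), lapply(stack$layers, `[[`, "material"),
             list(stack$substrate))
  nmed <- length(media)
  nl <- length(wavelength_nm)
  nm <- matrix(complex(1), nmed, nl)
  for (j in seq_len(nmed)) nm[j, ] <- refractive_index(media[[j]], wavelength_nm)
  s0 <- nm[1, ] * sin(angle)
  cosm <- matrix(complex(1), nmed, nl)
  for (j in seq_len(nmed)) cosm[j, ] <- .snell_cos(nm[j, ], s0)

  # interface j -> j+1 Fresnel coefficients
  fr <- lapply(seq_len(nmed - 1), function(j)
    fresnel(pol, nm[j, ], cosm[j, ], nm[j + 1, ], cosm[j + 1, ]))

  # M = M0 M1 ... M_{N-1}; M0 is the incident interface (no propagation)
  m11 <- 1 / fr[[1]]$t; m12 <- fr[[1]]$r / fr[[1]]$t
  m21 <- m12;           m22 <- m11
  for (j in seq_along(stack$layers)) {
    d <- stack$layers[[j]]$thickness_nm
    delta <- axial_wavevector(nm[j + 1, ], wavelength_nm, cosm[j + 1, ]) * d
    im <- Im(delta)
    clip <- im > .delta_im_max
    if (any(clip)) delta[clip] <- complex(real = Re(delta[clip]),
                                          imaginary = .delta_im_max)
    em <- exp(-1i * delta); ep <- exp(1i * delta)
    r <- fr[[j + 1]]$r; t <- fr[[j + 1]]$t
    l11 <- em / t; l12 <- r * em / t
    l21 <- r * ep / t; l22 <- ep / t
    n11 <- m11 * l11 + m12 * l21; n12 <- m11 * l12 + m12 * l22
    n21 <- m21 * l11 + m22 * l21; n22 <- m21 * l12 + m22 * l22
    m11 <- n11; m12 <- n12; m21 <- n21; m22 <- n22
  }
  if (any(m11 == 0))
    stop_etalon("etalonsim_singular_stack", "singular stack matrix (M11 = 0)")
  out <- list(r = m21 / m11, t = 1 / m11,
              n0c0 = nm[1, ] * cosm[1, ], nsc = nm[nmed, ] * cosm[nmed, ])
  if (keep_matrix) out$M <- list(m11 = m11, m12 = m12, m21 = m21, m22 = m22)
  out
}

#' Total transfer matrix of a stack at one wavelength
#'
#' Product of the incident-interface matrix and one [layer_matrix()] per
#' layer, ordered from the incident medium toward the substrate.  The
#' substrate boundary condition (unit incident amplitude, no backward wave)
#' is applied by [amplitudes()].
#'
#' @param stack a `tmm_stack`.
#' @param context a `plane_wave` with a single wavelength.
#' @return 2x2 complex matrix.
#' @export
stack_matrix <- function(stack, context) {
  stopifnot(inherits(stack, "tmm_stack"), inherits(context, "plane_wave"))
  core <- .tmm_core(stack, context$wavelength_nm[1], context$angle, context$pol,
                    keep_matrix = TRUE)
  with(core$M, matrix(c(m11, m21, m12, m22), 2, 2))
}

#' Reflection and transmission amplitudes from a stack matrix
#'
#' `r = M21/M11`, `t = 1/M11`.
#'
#' @param M 2x2 complex matrix from [stack_matrix()].
#' @return list with complex elements `r` and `t`.
#' @export
amplitudes <- function(M) {
  if (M[1, 1] == 0)
    stop_etalon("etalonsim_singular_stack", "singular stack matrix (M11 = 0)")
  list(r = M[2, 1] / M[1, 1], t = 1 / M[1, 1])
}

#' Reflectance, transmittance and absorbance spectra of a stack
#'
#' Runs the transfer-matrix sweep over a wavelength grid.
#' `R = |r|^2`, `T = |t|^2 Re(n_sub cos_sub)/Re(n_0 cos_0)`, `A = 1 - R - T`.
#' All three lie in `[0, 1]` for passive stacks and sum to 1 by construction.
#'
#' @param stack a `tmm_stack`.
#' @param wavelength_nm strictly increasing wavelength grid (nm); every
#'   material must cover it.
#' @param angle incidence angle (radians), default normal incidence.
#' @param pol polarization, `"s"` (default) or `"p"`.
#' @return an `optical_response`: list with `wavelength_nm`, `R`, `T`, `A`
#'   and the complex amplitudes `r`, `t`.
#' @export
tmm_response <- function(stack, wavelength_nm, angle = 0, pol = c("s", "p")) {
  pol <- match.arg(pol)
  stopifnot(inherits(stack, "tmm_stack"))
  wavelength_nm <- as.numeric(wavelength_nm)
  if (length(wavelength_nm) < 1 || any(diff(wavelength_nm) <= 0))
    stop_etalon("etalonsim_invalid_argument", "wavelength grid must be strictly increasing")
  core <- .tmm_core(stack, wavelength_nm, angle, pol)
  R <- Mod(core$r)^2
  T <- Mod(core$t)^2 * Re(core$nsc) / Re(core$n0c0)
  structure(list(wavelength_nm = wavelength_nm, R = R, T = T, A = 1 - R - T,
                 r = core$r, t = core$t, angle = angle, pol = pol),
            class = "optical_response")
}

#' @export
print.optical_response <- function(x, ...) {
  cat(sprintf("<optical_response> %d points %.0f-%.0f nm; R in [%.3f, %.3f], mean A %.3f\n",
              length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
              min(x$R), max(x$R), mean(x$A)))
  invisible(x)
}

#' Median etalon fringe period of a reflectance spectrum
#'
#' Locates local maxima of R and reports the median spacing of adjacent
#' maxima on the absolute wavenumber axis (`1/lambda`, cm^-1).  For a single
#' dominant film of index n and thickness d at normal incidence this is
#' `1/(2 n d)` within a few percent.
#'
#' @param response an `optical_response`.
#' @return fringe period in cm^-1.
#' @export
fringe_period <- function(response) {
  stopifnot(inherits(response, "optical_response"))
  peaks <- local_maxima(response$R)
  if (length(peaks) < 3)
    stop_etalon("etalonsim_insufficient_fringes",
                "fewer than 3 reflectance maxima: no measurable fringes")
  wn <- 1e7 / response$wavelength_nm  # cm^-1, decreasing with wavelength
  stats::median(abs(diff(wn[peaks])))
}
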
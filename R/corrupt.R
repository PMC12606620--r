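#' Map a Raman shift to absolute wavelength
#'
#' `lambda = 1 / (1/lambda0 - shift)` with the excitation wavelength
#' `lambda0`; monotone increasing in the shift.  Shift 0 maps to the
#' excitation wavelength (e.g. 3648 cm^-1 at 785 nm excitation maps to
#' ~1100 nm).
#'
#' @param shift_cm1 Raman shift (cm^-1), >= 0.
#' @param excitation_nm excitation wavelength (nm), > 0.
#' @return wavelength in nm (vectorized).
#' @export
shift_to_wavelength <- function(shift_cm1, excitation_nm) {
  if (any(shift_cm1 < 0)) stop_etalon("etalonsim_invalid_argument", "shift must be >= 0")
  if (excitation_nm <= 0) stop_etalon("etalonsim_invalid_argument", "excitation must be > 0")
  wn0 <- 1e7 / excitation_nm  # absolute wavenumber of the laser, cm^-1
  if (any(shift_cm1 >= wn0))
    stop_etalon("etalonsim_domain", "shift beyond the excitation wavenumber pole")
  1e7 / (wn0 - shift_cm1)
}

#' Settings for random fluorescence baselines
#'
#' @param degree_range polynomial degree range (default 3-5; degree 0 gives
#'   a flat baseline).
#' @param scale_range baseline maximum as a multiple of the reference
#'   intensity (default 0.5-5).
#' @return named list of settings.
#' @export
baseline_config <- function(degree_range = c(3L, 5L), scale_range = c(0.5, 5)) {
  list(degree_range = as.integer(degree_range), scale_range = scale_range)
}

#' Draw a smooth non-negative polynomial fluorescence baseline
#'
#' A random polynomial of seeded degree is shifted to its minimum (so the
#' baseline is non-negative by construction) and rescaled so its maximum is
#' a seeded multiple of `ref_intensity`.  Degenerate (constant) draws are
#' resampled up to `max_retry` times.
#'
#' @param axis Raman-shift grid (cm^-1).
#' @param seed integer seed.
#' @param config a [baseline_config()].
#' @param ref_intensity reference intensity the scale range multiplies.
#' @param max_retry resample limit for degenerate draws.
#' @return numeric baseline of `length(axis)` with the sampled coefficients
#'   in attribute `"coefficients"`.
#' @export
fluorescence_baseline <- function(axis, seed, config = baseline_config(),
                                  ref_intensity = 1, max_retry = 100) {
  set.seed(as.integer(seed))
  deg <- if (config$degree_range[1] == config$degree_range[2])
    config$degree_range[1] else
      sample(config$degree_range[1]:config$degree_range[2], 1)
  scale <- stats::runif(1, config$scale_range[1], config$scale_range[2]) * ref_intensity
  if (deg == 0) {
    y <- rep(scale, length(axis))
    attr(y, "coefficients") <- scale
    return(y)
  }
  x <- (axis - min(axis)) / (max(axis) - min(axis))
  for (try in seq_len(max_retry)) {
    cf <- stats::rnorm(deg + 1)
    y <- drop(outer(x, 0:deg, `^`) %*% cf)
    y <- y - min(y)
    if (max(y) > 1e-9) {
      y <- y / max(y) * scale
      attr(y, "coefficients") <- cf
      return(y)
    }
  }
  stop_etalon("etalonsim_config", "could not draw a non-degenerate baseline")
}

#' Gaussian-smoothed quantum-efficiency envelope of an absorbance curve
#'
#' Convolves A with a Gaussian of standard deviation `sigma` grid points,
#' renormalizing the kernel at the boundaries so that a constant input is
#' returned exactly.
#'
#' @param A absorbance values on a uniform grid.
#' @param sigma Gaussian standard deviation in grid points, > 0.
#' @return smoothed values, same length as `A`.
#' @export
qe_from_absorbance <- function(A, sigma) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop_etalon("etalonsim_invalid_argument", "sigma must be > 0")
  n <- length(A)
  m <- ceiling(4 * sigma)
  w <- stats::dnorm(-m:m, 0, sigma)
  sm <- as.numeric(stats::filter(c(rep(0, m), A, rep(0, m)), w, sides = 2))[(m + 1):(m + n)]
  wt <- as.numeric(stats::filter(c(rep(0, m), rep(1, n), rep(0, m)), w, sides = 2))[(m + 1):(m + n)]
  sm / wt
}

#' Etalon fringe profile of a CCD design on a Raman-shift axis
#'
#' Resamples the simulated absorbance A(lambda) onto the spectrum's
#' Raman-shift axis via [shift_to_wavelength()], extracts the smooth
#' quantum-efficiency envelope QE as the Gaussian-smoothed absorbance, and
#' isolates the relative etaloning effect `E = A - QE`, a high-pass fringe
#' residual oscillating about 0 (so `E + 1` oscillates about 1).
#'
#' @param response an `optical_response` covering the mapped wavelength
#'   range of `axis`.
#' @param excitation_nm excitation wavelength (nm).
#' @param axis Raman-shift grid (cm^-1).
#' @param sigma Gaussian sigma in grid points for the QE envelope; default
#'   3x the dominant fringe period so QE tracks the envelope, not the
#'   fringes (falls back to 5% of the axis length if the response has no
#'   measurable fringes).
#' @return an `etalon_profile`: list with `shift_cm1`, `A`, `QE`, `E`.
#' @export
etalon_profile <- function(response, excitation_nm, axis, sigma = NULL) {
  stopifnot(inherits(response, "optical_response"))
  wl <- shift_to_wavelength(axis, excitation_nm)
  rng <- range(response$wavelength_nm)
  if (min(wl) < rng[1] || max(wl) > rng[2])
    stop_etalon("etalonsim_coverage",
                "response covers %.1f-%.1f nm but the axis maps to %.1f-%.1f nm",
                rng[1], rng[2], min(wl), max(wl))
  A <- stats::approx(response$wavelength_nm, response$A, xout = wl)$y
  if (is.null(sigma)) {
    step <- axis[2] - axis[1]  # shift step equals the absolute-wavenumber step
    sigma <- tryCatch(3 * fringe_period(response) / step,
                      error = function(e) length(axis) / 20)
    sigma <- max(sigma, 2)
  }
  QE <- qe_from_absorbance(A, sigma)
  structure(list(shift_cm1 = axis, A = A, QE = QE, E = A - QE,
                 excitation_nm = excitation_nm, sigma = sigma),
            class = "etalon_profile")
}

.profile_ids <- function(ids) {
  # profile names may carry a variant suffix ("7_v3"); the design id is the
  # leading integer
  as.integer(sub("^([0-9]+).*$", "\\1", ids))
}

.check_axis <- function(a, b) {
  if (length(a) != length(b) || max(abs(a - b)) > 1e-9)
    stop_etalon("etalonsim_alignment", "axes do not match")
}

#' Corrupt a clean spectrum with baseline and absorbance fringes
#'
#' Simulated-data forward model: add the fluorescence baseline, then
#' multiply by the absorbance curve A (which carries both the QE envelope
#' and the fringes): `corrupted = (clean + baseline) * A`.  The E-only
#' variant `(clean + baseline) * (E + 1)` is recorded alongside.
#'
#' @param clean a `raman_spectrum` (the ground truth).
#' @param baseline numeric baseline on the same axis.
#' @param profile an `etalon_profile` on the same axis.
#' @return a `corruption_pair`: list with `clean`, `corrupted` (both
#'   `raman_spectrum`), `corrupted_E` (intensities of the E-only variant),
#'   `recipe = "A_times"`, `baseline` and the profile.
#' @export
corrupt_simulated <- function(clean, baseline, profile) {
  stopifnot(inherits(clean, "raman_spectrum"), inherits(profile, "etalon_profile"))
  .check_axis(clean$shift_cm1, profile$shift_cm1)
  if (length(baseline) != length(clean$intensity))
    stop_etalon("etalonsim_alignment", "baseline length does not match the axis")
  lifted <- clean$intensity + baseline
  corrupted <- raman_spectrum(clean$shift_cm1, lifted * profile$A,
                              clean$excitation_nm,
                              metadata = list(recipe = "A_times"))
  structure(list(clean = clean, corrupted = corrupted,
                 corrupted_E = lifted * (profile$E + 1),
                 recipe = "A_times", baseline = baseline,
                 dark_current = 0, profile = profile),
            class = "corruption_pair")
}

#' Prepare an experimental-like spectrum: dark current and fringe injection
#'
#' Experimental-data forward model: subtract the fixed dark-current offset
#' (floored at 0), then multiply by `E + 1` to imprint fringes while leaving
#' the fluorescence baseline and QE envelope in place:
#' `corrupted = (raw - dark) * (E + 1)`.  The dark-corrected spectrum is the
#' ground truth of the pair.
#'
#' @param raw a `raman_spectrum` containing signal + baseline (+ dark).
#' @param profile an `etalon_profile` on the same axis.
#' @param dark_current fixed offset in arbitrary units (default 600).
#' @return a `corruption_pair` with `recipe = "E_plus_one"`.
#' @export
prepare_experimental <- function(raw, profile, dark_current = 600) {
  stopifnot(inherits(raw, "raman_spectrum"), inherits(profile, "etalon_profile"))
  .check_axis(raw$shift_cm1, profile$shift_cm1)
  working <- pmax(raw$intensity - dark_current, 0)
  clean <- raman_spectrum(raw$shift_cm1, working, raw$excitation_nm,
                          metadata = list(dark_current = dark_current))
  corrupted <- raman_spectrum(raw$shift_cm1, working * (profile$E + 1),
                              raw$excitation_nm,
                              metadata = list(recipe = "E_plus_one"))
  structure(list(clean = clean, corrupted = corrupted, corrupted_E = NULL,
                 recipe = "E_plus_one", baseline = NULL,
                 dark_current = dark_current, profile = profile),
            class = "corruption_pair")
}

# ---- training-set builders -------------------------------------------------

#' Etalon profiles for a set of designs
#'
#' @param designs list of `ccd_design` objects.
#' @param axis Raman-shift grid (cm^-1).
#' @param excitation_nm excitation wavelength.
#' @param wavelength_step sweep step of the underlying optical simulation (nm).
#' @return named list of `etalon_profile`s keyed by design id.
#' @export
design_profiles <- function(designs, axis = default_axis(), excitation_nm = 785,
                            wavelength_step = 1) {
  wl_max <- shift_to_wavelength(max(axis), excitation_nm)
  grid <- seq(floor(excitation_nm) - 1, ceiling(wl_max) + 1, by = wavelength_step)
  out <- lapply(designs, function(d)
    etalon_profile(tmm_response(d$stack, grid), excitation_nm, axis))
  names(out) <- vapply(designs, function(d) as.character(d$design_id), character(1))
  out
}

#' Silicon-thickness-variant profiles of an interpolation design
#'
#' Interpolation designs explore etaloning patterns by varying the silicon
#' bulk thickness within 14,000-18,000 nm.  This draws `n` seeded
#' thicknesses, rebuilds the stack with [vary_silicon()] and returns the
#' fringe profile of each variant (named `<id>_v<k>`).
#'
#' @param design an interpolation `ccd_design`.
#' @param n number of variants.
#' @param axis Raman-shift grid (cm^-1).
#' @param seed integer seed.
#' @param thickness_range sampled thickness range (nm).
#' @param excitation_nm excitation wavelength.
#' @return named list of `etalon_profile`s.
#' @export
vary_profiles <- function(design, n, axis, seed,
                          thickness_range = c(14000, 18000),
                          excitation_nm = 785) {
  set.seed(derive_seed(seed, paste0("vary", design$design_id)))
  ths <- stats::runif(n, thickness_range[1], thickness_range[2])
  out <- lapply(ths, function(th)
    design_profiles(list(vary_silicon(design, th)), axis, excitation_nm)[[1]])
  names(out) <- paste0(design$design_id, "_v", seq_len(n))
  out
}

#' Build a supervised set of simulated corruption pairs
#'
#' For each clean corpus spectrum a design is drawn (seeded) from
#' `profiles`, a fluorescence baseline is added, and the A-times forward
#' model applied.  The ground truth is the clean spectrum.
#'
#' @param corpus a `raman_corpus` of clean spectra.
#' @param profiles named list of `etalon_profile`s from [design_profiles()].
#' @param seed integer seed.
#' @param baseline_cfg a [baseline_config()].
#' @return a `pair_set`: list with `axis`, matrices `clean` and `corrupted`
#'   (rows are spectra), `design_id`, `recipe`.
#' @export
make_simulated_pairs <- function(corpus, profiles, seed = 1,
                                 baseline_cfg = baseline_config()) {
  n <- nrow(corpus$intensity)
  set.seed(derive_seed(seed, "assign_sim"))
  ids <- sample(names(profiles), n, replace = TRUE)
  corrupted <- matrix(0, n, length(corpus$axis))
  for (i in seq_len(n)) {
    cl <- corpus$intensity[i, ]
    bl <- fluorescence_baseline(corpus$axis, derive_seed(seed, paste0("bl", i)),
                                baseline_cfg,
                                ref_intensity = max(stats::median(cl), 1e-12))
    corrupted[i, ] <- (cl + bl) * profiles[[ids[i]]]$A
  }
  structure(list(axis = corpus$axis, clean = corpus$intensity,
                 corrupted = corrupted, design_id = .profile_ids(ids),
                 recipe = "A_times", seed = seed),
            class = "pair_set")
}

#' Build a supervised set of experimental-like corruption pairs
#'
#' Emulates the structure of real fine-tuning data: each clean spectrum is
#' lifted by a fluorescence baseline, scaled to a detector-counts level
#' (log-uniform over `scale_range`), offset by the dark current, then passed
#' through [prepare_experimental()] so the ground truth keeps its baseline
#' and only the fringes differ.
#'
#' @param corpus a `raman_corpus` of clean spectra.
#' @param profiles named list of `etalon_profile`s.
#' @param seed integer seed.
#' @param dark_current fixed offset (default 600 a.u.).
#' @param scale_range detector-counts scale range.
#' @param baseline_cfg a [baseline_config()].
#' @return a `pair_set` with `recipe = "E_plus_one"`.
#' @export
make_experimental_pairs <- function(corpus, profiles, seed = 1,
                                    dark_current = 600,
                                    scale_range = c(1000, 10000),
                                    baseline_cfg = baseline_config()) {
  n <- nrow(corpus$intensity)
  set.seed(derive_seed(seed, "assign_exp"))
  ids <- sample(names(profiles), n, replace = TRUE)
  scales <- exp(stats::runif(n, log(scale_range[1]), log(scale_range[2])))
  clean <- corrupted <- matrix(0, n, length(corpus$axis))
  for (i in seq_len(n)) {
    cl <- corpus$intensity[i, ]
    bl <- fluorescence_baseline(corpus$axis, derive_seed(seed, paste0("ebl", i)),
                                baseline_cfg,
                                ref_intensity = max(stats::median(cl), 1e-12))
    raw <- raman_spectrum(corpus$axis, (cl + bl) * scales[i] + dark_current,
                          corpus$excitation_nm)
    pair <- prepare_experimental(raw, profiles[[ids[i]]], dark_current)
    clean[i, ] <- pair$clean$intensity
    corrupted[i, ] <- pair$corrupted$intensity
  }
  structure(list(axis = corpus$axis, clean = clean, corrupted = corrupted,
                 design_id = .profile_ids(ids), recipe = "E_plus_one",
                 dark_current = dark_current, seed = seed),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set> %d pairs, %d points, recipe %s, designs {%s}\n",
              nrow(x$clean), ncol(x$clean), x$recipe,
              paste(sort(unique(x$design_id)), collapse = ",")))
  invisible(x)
}

#' Subset a pair set by index
#' @param x a `pair_set`.
#' @param idx integer row indices.
#' @return the subset `pair_set`.
#' @export
pair_subset <- function(x, idx) {
  x$clean <- x$clean[idx, , drop = FALSE]
  x$corrupted <- x$corrupted[idx, , drop = FALSE]
  x$design_id <- x$design_id[idx]
  x
}
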
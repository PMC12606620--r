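#' Raman spectrum container
#'
#' A spectrum is an intensity vector on a uniform, increasing Raman-shift
#' axis (cm^-1), with the excitation wavelength and free-form provenance
#' metadata attached.
#'
#' @param shift_cm1 uniform increasing axis (cm^-1).
#' @param intensity non-negative intensities (clean spectra), same length.
#' @param excitation_nm excitation wavelength (nm), default 785.
#' @param metadata named list of provenance entries.
#' @return an object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(shift_cm1, intensity, excitation_nm = 785,
                           metadata = list()) {
  shift_cm1 <- as.numeric(shift_cm1); intensity <- as.numeric(intensity)
  if (length(shift_cm1) != length(intensity))
    stop_etalon("etalonsim_invalid_argument", "axis and intensity lengths differ")
  d <- diff(shift_cm1)
  if (any(d <= 0) || (length(d) > 1 && max(abs(d - d[1])) > 1e-6 * d[1]))
    stop_etalon("etalonsim_invalid_argument", "shift axis must be uniform and increasing")
  structure(list(shift_cm1 = shift_cm1, intensity = intensity,
                 excitation_nm = excitation_nm, metadata = metadata),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points %.0f-%.0f cm-1, excitation %.0f nm, max %.4g\n",
              length(x$shift_cm1), min(x$shift_cm1), max(x$shift_cm1),
              x$excitation_nm, max(x$intensity)))
  invisible(x)
}

#' Default Raman-shift axis
#'
#' The canonical axis spans 0-3700 cm^-1.  `n` controls the resolution
#' (default 3701 points, i.e. 1 cm^-1 steps); training-scale corpora use a
#' coarser axis.
#'
#' @param n number of points.
#' @return numeric axis (cm^-1).
#' @export
default_axis <- function(n = 3701) seq(0, 3700, length.out = n)

#' Generator settings for random peak lists
#'
#' Defaults: 5-40 peaks, positions uniform on the axis, peak heights
#' log-uniform over `intensity_range`, Lorentzian half-widths gamma uniform
#' in `[3, 40]` cm^-1 (fwhm 6-80 cm^-1), one width per peak.
#'
#' @param n_peaks_range integer range of the peak count.
#' @param position_range allowed peak positions (cm^-1).
#' @param intensity_range log-uniform peak height range.
#' @param gamma_range Lorentzian half-width range (cm^-1).
#' @return named list of generator settings.
#' @export
peaklist_config <- function(n_peaks_range = c(5L, 40L),
                            position_range = c(100, 3600),
                            intensity_range = c(0.05, 1),
                            gamma_range = c(3, 40)) {
  if (n_peaks_range[1] > n_peaks_range[2] ||
      position_range[1] > position_range[2] ||
      intensity_range[1] > intensity_range[2] ||
      gamma_range[1] > gamma_range[2])
    stop_etalon("etalonsim_config", "empty range in peak-list config")
  list(n_peaks_range = as.integer(n_peaks_range), position_range = position_range,
       intensity_range = intensity_range, gamma_range = gamma_range)
}

#' Draw a random Raman peak list
#'
#' Reproducible for a given seed.  Stands in for quantum-chemical line
#' lists: positions, heights and Lorentzian widths are drawn from the
#' documented distributions in `config`.
#'
#' @param seed integer seed.
#' @param config a [peaklist_config()].
#' @return a `peak_list`: data.frame with columns `position`, `intensity`,
#'   `gamma` (half-width at half-maximum, cm^-1).
#' @export
sample_peaklist <- function(seed, config = peaklist_config()) {
  set.seed(as.integer(seed))
  np <- if (config$n_peaks_range[1] == config$n_peaks_range[2])
    config$n_peaks_range[1] else
      sample(config$n_peaks_range[1]:config$n_peaks_range[2], 1)
  pl <- data.frame(
    position = stats::runif(np, config$position_range[1], config$position_range[2]),
    intensity = exp(stats::runif(np, log(config$intensity_range[1]),
                                 log(config$intensity_range[2]))),
    gamma = stats::runif(np, config$gamma_range[1], config$gamma_range[2]))
  class(pl) <- c("peak_list", "data.frame")
  pl
}

#' Broaden a peak list with Lorentzian line profiles
#'
#' Amplitude-normalized Lorentzians (default): the summed intensity at an
#' isolated peak position equals the listed peak height,
#' `I(v) = sum_i I_i * g_i^2 / ((v - v_i)^2 + g_i^2)`.  With
#' `normalization = "area"` each profile integrates to `I_i` instead.
#'
#' @param peaks a `peak_list`.
#' @param axis Raman-shift grid covering all peak positions (cm^-1).
#' @param excitation_nm excitation wavelength recorded in the result.
#' @param normalization `"amplitude"` (default) or `"area"`.
#' @return a `raman_spectrum`.
#' @export
broaden <- function(peaks, axis = default_axis(), excitation_nm = 785,
                    normalization = c("amplitude", "area")) {
  normalization <- match.arg(normalization)
  if (nrow(peaks) > 0 &&
      (min(peaks$position) < min(axis) || max(peaks$position) > max(axis)))
    stop_etalon("etalonsim_coverage", "peak position outside the spectral axis")
  y <- rep(0, length(axis))
  for (i in seq_len(nrow(peaks))) {
    g2 <- peaks$gamma[i]^2
    lor <- g2 / ((axis - peaks$position[i])^2 + g2)
    if (normalization == "area") lor <- lor / (pi * peaks$gamma[i])
    y <- y + peaks$intensity[i] * lor
  }
  raman_spectrum(axis, y, excitation_nm,
                 metadata = list(n_peaks = nrow(peaks), normalization = normalization))
}

#' Augmentation settings
#'
#' Defaults chosen as realistic desk-scale values (the underlying protocol
#' states the kinds of perturbation -- noise, peak shifts, silent regions --
#' but not their magnitudes): additive Gaussian noise with sd equal to
#' `noise_sd_frac` of the spectrum maximum, a global axis shift uniform in
#' `+/- shift_max_cm1`, and with probability `silent_prob` one zeroed window
#' of width drawn from `silent_width_range`.
#'
#' @param noise_sd_frac noise sd as a fraction of max intensity.
#' @param shift_max_cm1 maximum global peak shift (cm^-1).
#' @param silent_prob probability of inserting a silent region.
#' @param silent_width_range width range of the silent window (cm^-1).
#' @return named list of augmentation settings.
#' @export
augment_config <- function(noise_sd_frac = 0.01, shift_max_cm1 = 4,
                           silent_prob = 0.3, silent_width_range = c(200, 600)) {
  list(noise_sd_frac = noise_sd_frac, shift_max_cm1 = shift_max_cm1,
       silent_prob = silent_prob, silent_width_range = silent_width_range)
}

#' Augment a clean spectrum with noise, shift and silent regions
#'
#' Applies, in order: a global axis shift (linear re-interpolation, edges
#' held at 0), a zeroed silent window, and additive Gaussian noise clipped
#' at 0 so the result stays non-negative.  The input intensities are kept in
#' `metadata$clean`.
#'
#' @param spectrum a `raman_spectrum`.
#' @param seed integer seed.
#' @param config an [augment_config()].
#' @return an augmented `raman_spectrum`.
#' @export
augment <- function(spectrum, seed, config = augment_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  set.seed(as.integer(seed))
  ax <- spectrum$shift_cm1
  y <- spectrum$intensity
  if (config$shift_max_cm1 > 0) {
    sh <- stats::runif(1, -config$shift_max_cm1, config$shift_max_cm1)
    y <- stats::approx(ax + sh, y, xout = ax, rule = 1)$y
    y[is.na(y)] <- 0
  } else sh <- 0
  silent <- NULL
  if (config$silent_prob > 0 && stats::runif(1) < config$silent_prob) {
    w <- stats::runif(1, config$silent_width_range[1], config$silent_width_range[2])
    lo <- stats::runif(1, min(ax), max(ax) - w)
    silent <- c(lo, lo + w)
    y[ax >= lo & ax <= lo + w] <- 0
  }
  if (config$noise_sd_frac > 0) {
    sd <- config$noise_sd_frac * max(spectrum$intensity)
    y <- pmax(y + stats::rnorm(length(y), 0, sd), 0)
  }
  raman_spectrum(ax, y, spectrum$excitation_nm,
                 metadata = c(spectrum$metadata,
                              list(clean = spectrum$intensity, shift_cm1 = sh,
                                   silent_window = silent, augment_seed = seed)))
}

#' Convolve a spectrum with a Gaussian instrument response
#'
#' Emulates the finite resolution of the spectrograph (and guards the
#' sampled axis against sub-sample lines: the generator's narrowest
#' Lorentzians are sharper than a coarse axis step, so features should be
#' broadened to at least ~2 grid points before corruption and training).
#' The Gaussian kernel is renormalized at the boundaries, so constants are
#' preserved exactly.
#'
#' @param spectrum a `raman_spectrum`, or a `raman_corpus` (all rows).
#' @param fwhm_cm1 instrument full width at half maximum (cm^-1).
#' @return the smoothed object, same class as the input.
#' @export
apply_instrument <- function(spectrum, fwhm_cm1) {
  if (fwhm_cm1 <= 0) return(spectrum)
  if (inherits(spectrum, "raman_corpus")) {
    sigma <- fwhm_cm1 / 2.355 / (spectrum$axis[2] - spectrum$axis[1])
    for (i in seq_len(nrow(spectrum$intensity)))
      spectrum$intensity[i, ] <- qe_from_absorbance(spectrum$intensity[i, ], sigma)
    return(spectrum)
  }
  stopifnot(inherits(spectrum, "raman_spectrum"))
  sigma <- fwhm_cm1 / 2.355 / (spectrum$shift_cm1[2] - spectrum$shift_cm1[1])
  raman_spectrum(spectrum$shift_cm1,
                 qe_from_absorbance(spectrum$intensity, sigma),
                 spectrum$excitation_nm,
                 metadata = c(spectrum$metadata, list(instrument_fwhm = fwhm_cm1)))
}

#' Generate a corpus of clean synthetic Raman spectra
#'
#' Reproducible for a given seed; spectrum i uses the child seed derived
#' from `(seed, "peaks", i)` / `(seed, "augment", i)`.
#'
#' @param n number of spectra.
#' @param seed master seed.
#' @param axis shift axis (cm^-1).
#' @param peak_config a [peaklist_config()].
#' @param aug_config an [augment_config()]; set `NULL` to skip augmentation.
#' @param excitation_nm excitation wavelength.
#' @return a `raman_corpus`: list with `axis` and an `n x length(axis)`
#'   intensity matrix `intensity`.
#' @export
raman_corpus <- function(n, seed = 1, axis = default_axis(),
                         peak_config = peaklist_config(),
                         aug_config = augment_config(), excitation_nm = 785) {
  X <- matrix(0, n, length(axis))
  for (i in seq_len(n)) {
    pk <- sample_peaklist(derive_seed(seed, paste0("peaks", i)), peak_config)
    sp <- broaden(pk, axis, excitation_nm)
    if (!is.null(aug_config))
      sp <- augment(sp, derive_seed(seed, paste0("augment", i)), aug_config)
    X[i, ] <- sp$intensity
  }
  structure(list(axis = axis, intensity = X, excitation_nm = excitation_nm,
                 seed = seed),
            class = "raman_corpus")
}
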
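.as_intensity <- function(x) {
  if (inherits(x, "raman_spectrum")) x$intensity else as.numeric(x)
}

#' Spectral angle mapper
#'
#' Angle (radians) between two spectra viewed as vectors:
#' `arccos(<a,b> / (|a| |b|))`, clamped to `[0, pi]`.  Scale-invariant.
#' Intensities are clipped at 0 first so negative lobes cannot inflate the
#' angle.
#'
#' @param a,b equal-length numeric vectors or `raman_spectrum`s.
#' @return angle in radians.
#' @export
sam <- function(a, b) {
  a <- pmax(.as_intensity(a), 0); b <- pmax(.as_intensity(b), 0)
  if (length(a) != length(b))
    stop_etalon("etalonsim_alignment", "spectra lengths differ")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop_etalon("etalonsim_undefined_angle", "zero-norm spectrum has no angle")
  acos(min(1, max(-1, sum(a * b) / (na * nb))))
}

#' Root-mean-square error between two spectra
#' @param a,b equal-length numeric vectors or `raman_spectrum`s.
#' @return RMSE in intensity units.
#' @export
rmse <- function(a, b) {
  a <- .as_intensity(a); b <- .as_intensity(b)
  if (length(a) != length(b))
    stop_etalon("etalonsim_alignment", "spectra lengths differ")
  sqrt(mean((a - b)^2))
}

#' Mean absolute error between two spectra
#' @param a,b equal-length numeric vectors or `raman_spectrum`s.
#' @return MAE in intensity units.
#' @export
mae <- function(a, b) {
  a <- .as_intensity(a); b <- .as_intensity(b)
  if (length(a) != length(b))
    stop_etalon("etalonsim_alignment", "spectra lengths differ")
  mean(abs(a - b))
}

#' Unit-normalized Euclidean distance
#'
#' `| a/|a| - b/|b| |`: the Euclidean distance between the two spectra
#' after scaling each to unit norm.  Scale-invariant, bounded by `[0, 2]`.
#' (The metric name follows the evaluation protocol; its formula is this
#' package's documented reconstruction and can be swapped out.)
#'
#' @param a,b equal-length numeric vectors or `raman_spectrum`s with
#'   nonzero norms.
#' @return dimensionless distance in `[0, 2]`.
#' @export
uned <- function(a, b) {
  a <- .as_intensity(a); b <- .as_intensity(b)
  if (length(a) != length(b))
    stop_etalon("etalonsim_alignment", "spectra lengths differ")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop_etalon("etalonsim_undefined_angle", "zero-norm spectrum")
  sqrt(sum((a / na - b / nb)^2))
}

#' Percentage improvement of a metric after correction
#'
#' `100 * (uncorrected - corrected) / uncorrected`; negative values denote
#' degradation.
#'
#' @param metric_uncorrected baseline metric value, > 0.
#' @param metric_corrected metric value after correction.
#' @return percent improvement.
#' @export
improvement_pct <- function(metric_uncorrected, metric_corrected) {
  if (any(metric_uncorrected <= 0))
    stop_etalon("etalonsim_undefined_improvement",
                "improvement undefined for zero baseline metric")
  100 * (metric_uncorrected - metric_corrected) / metric_uncorrected
}

#' Savitzky-Golay smoothing baseline
#'
#' Classical fixed-window polynomial smoothing used as the non-physics
#' reference method for fringe removal.
#'
#' @param spectrum a `raman_spectrum` or numeric vector.
#' @param window odd filter length, > `polyorder`.
#' @param polyorder polynomial order (default 3).
#' @return filtered spectrum of the same type as the input.
#' @export
sg_baseline <- function(spectrum, window, polyorder = 3) {
  if (window %% 2 == 0 || window <= polyorder)
    stop_etalon("etalonsim_invalid_argument",
                "window must be odd and greater than polyorder")
  y <- .as_intensity(spectrum)
  if (window > length(y))
    stop_etalon("etalonsim_invalid_argument", "window longer than the spectrum")
  out <- signal::sgolayfilt(y, p = polyorder, n = window)
  if (inherits(spectrum, "raman_spectrum"))
    raman_spectrum(spectrum$shift_cm1, pmax(out, 0), spectrum$excitation_nm,
                   metadata = list(sg_window = window, sg_polyorder = polyorder))
  else out
}

#' Best-case Savitzky-Golay RMSE over a window grid
#'
#' Applies [sg_baseline()] at every odd window in `windows` to all rows of
#' `corrupted` and returns, for the best single window (oracle-chosen
#' against the truth), the mean RMSE.
#'
#' @param corrupted,clean matrices with one spectrum per row.
#' @param windows odd window grid (default `seq(5, 101, by = 4)`).
#' @param polyorder polynomial order.
#' @return list with `best_window`, `best_rmse`, and the per-window mean
#'   RMSE vector `rmse_by_window`.
#' @export
sg_best_rmse <- function(corrupted, clean, windows = seq(5, 101, by = 4),
                         polyorder = 3) {
  windows <- windows[windows <= ncol(corrupted) & windows > polyorder &
                       windows %% 2 == 1]
  if (length(windows) == 0)
    stop_etalon("etalonsim_invalid_argument", "no admissible SG window in the grid")
  rms <- vapply(windows, function(w) {
    mean(vapply(seq_len(nrow(corrupted)), function(i)
      rmse(signal::sgolayfilt(corrupted[i, ], p = polyorder, n = w), clean[i, ]),
      numeric(1)))
  }, numeric(1))
  list(best_window = windows[which.min(rms)], best_rmse = min(rms),
       rmse_by_window = stats::setNames(rms, windows))
}
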
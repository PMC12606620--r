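# Synthetic Raman generator: peak lists, Lorentzian broadening, augmentation.

test_that("peak lists are reproducible and respect their configured ranges", {
  expect_equal(sample_peaklist(42), sample_peaklist(42))
  pl10 <- sample_peaklist(1, peaklist_config(n_peaks_range = c(10, 10)))
  expect_equal(nrow(pl10), 10)
  # distribution check over many draws
  gam <- unlist(lapply(1:300, function(s) sample_peaklist(s)$gamma))
  expect_true(all(gam >= 3 & gam <= 40))
  pos <- unlist(lapply(1:300, function(s) sample_peaklist(s)$position))
  expect_true(all(pos >= 0 & pos <= 3700))
  expect_error(peaklist_config(n_peaks_range = c(5, 2)),
               class = "etalonsim_config")
})

test_that("Lorentzian broadening matches the closed form", {
  axis <- default_axis()
  pk <- data.frame(position = 1000, intensity = 1, gamma = 10)
  class(pk) <- c("peak_list", "data.frame")
  sp <- broaden(pk, axis)
  expect_equal(sp$intensity[axis == 1000], 1, tolerance = 1e-12)
  expect_equal(sp$intensity[axis == 1010], 0.5, tolerance = 1e-12)  # half max at +gamma
  expect_equal(sp$intensity[axis == 990], 0.5, tolerance = 1e-12)
  # measured fwhm = 2*gamma within one grid step
  above <- range(which(sp$intensity >= 0.5))
  expect_equal(diff(axis[above]), 20, tolerance = 1)
  # empty list -> zero spectrum; symmetric twin peaks have equal maxima
  empty <- pk[0, ]
  expect_true(all(broaden(empty, axis)$intensity == 0))
  two <- data.frame(position = c(800, 2800), intensity = 1, gamma = 8)
  class(two) <- c("peak_list", "data.frame")
  y <- broaden(two, axis)$intensity
  expect_equal(max(y[axis < 1800]), max(y[axis >= 1800]), tolerance = 1e-6)
  # coverage error
  out <- data.frame(position = 4000, intensity = 1, gamma = 5)
  class(out) <- c("peak_list", "data.frame")
  expect_error(broaden(out, axis), class = "etalonsim_coverage")
})

test_that("augmentation: identity config, silent windows, calibrated noise", {
  sp <- broaden(sample_peaklist(3))
  idcfg <- augment_config(noise_sd_frac = 0, shift_max_cm1 = 0, silent_prob = 0)
  expect_equal(augment(sp, 1, idcfg)$intensity, sp$intensity)
  # forced silent window zeroes exactly that range
  scfg <- augment_config(noise_sd_frac = 0, shift_max_cm1 = 0, silent_prob = 1,
                         silent_width_range = c(800, 800))
  aug <- augment(sp, 5, scfg)
  w <- aug$metadata$silent_window
  expect_equal(diff(w), 800, tolerance = 1e-6)
  expect_true(all(aug$intensity[sp$shift_cm1 >= w[1] & sp$shift_cm1 <= w[2]] == 0))
  # Monte-Carlo noise calibration (clipping at 0 biases slightly; 20% band)
  ncfg <- augment_config(noise_sd_frac = 0.01, shift_max_cm1 = 0, silent_prob = 0)
  sds <- vapply(1:100, function(s)
    stats::sd(augment(sp, s, ncfg)$intensity - sp$intensity), numeric(1))
  expect_equal(mean(sds), 0.01 * max(sp$intensity), tolerance = 0.2)
  # non-negativity always
  expect_true(all(augment(sp, 9, augment_config())$intensity >= 0))
})

test_that("corpus generation scales and shows a broad variability envelope", {
  # full-axis generation at a rate consistent with a 30,000-spectrum
  # pretraining corpus completing at desk scale (< ~10 min)
  t0 <- Sys.time()
  corp <- raman_corpus(400, 21)
  rate <- as.numeric(Sys.time() - t0, units = "secs") / 400
  expect_lt(rate * 30000, 600)
  m <- colMeans(corp$intensity)
  s <- apply(corp$intensity, 2, stats::sd)
  interior <- corp$axis > 200 & corp$axis < 3500
  # mean spectrum positive across the interior with a wide spread band
  expect_true(all(m[interior] > 0))
  expect_gt(stats::median(s[interior] / m[interior]), 0.5)
})

test_that("corpus generation is seed-stable and non-negative", {
  axis <- default_axis(256)
  c1 <- raman_corpus(8, 11, axis)
  c2 <- raman_corpus(8, 11, axis)
  expect_identical(c1$intensity, c2$intensity)
  expect_true(all(c1$intensity >= 0))
  expect_false(identical(c1$intensity, raman_corpus(8, 12, axis)$intensity))
})
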
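# Forward corruption: wavelength mapping, baselines, QE envelope, recipes.

test_that("shift-to-wavelength mapping matches the published axis pairings", {
  expect_equal(shift_to_wavelength(0, 785), 785)
  expect_equal(shift_to_wavelength(3648, 785), 1100, tolerance = 1e-3)  # ~1100 nm
  expect_equal(shift_to_wavelength(3098, 785), 1037, tolerance = 1e-3)  # ~1037 nm
  expect_equal(shift_to_wavelength(350, 800), 1e7 / (1e7 / 800 - 350))
  # monotone increasing
  wl <- shift_to_wavelength(seq(0, 3600, 100), 785)
  expect_true(all(diff(wl) > 0))
  expect_error(shift_to_wavelength(13000, 785), class = "etalonsim_domain")
  expect_error(shift_to_wavelength(-1, 785), class = "etalonsim_invalid_argument")
})

test_that("fluorescence baselines are smooth, non-negative, reproducible", {
  axis <- default_axis(512)
  b1 <- fluorescence_baseline(axis, 7)
  expect_identical(b1, fluorescence_baseline(axis, 7))
  # flat baseline from degree-0 config with pinned scale
  flat <- fluorescence_baseline(axis, 3,
                                baseline_config(degree_range = c(0, 0),
                                                scale_range = c(2.5, 2.5)))
  expect_equal(unclass(flat), rep(2.5, 512), ignore_attr = TRUE)
  # 1000 draws all non-negative and within the scale band
  for (s in 1:1000) {
    b <- fluorescence_baseline(axis, s)
    expect_true(all(b >= 0))
    expect_lte(max(b), 5 + 1e-9)
  }
})

test_that("QE extraction is exact on constants and attenuates sinusoids", {
  expect_equal(qe_from_absorbance(rep(0.7, 300), 5), rep(0.7, 300))
  expect_error(qe_from_absorbance(rep(1, 10), 0),
               class = "etalonsim_invalid_argument")
  # sigma -> large approaches the global mean
  x <- seq(0, 1, length.out = 200)
  A <- 0.5 + 0.3 * x
  q <- qe_from_absorbance(A, 1000)
  expect_equal(mean(abs(q - mean(A))), 0, tolerance = 0.02)
  # Gaussian transfer function on a sinusoid of period p points
  p <- 40; n <- 2000; sigma <- 20
  A <- 0.5 + 0.2 * sin(2 * pi * seq_len(n) / p)
  q <- qe_from_absorbance(A, sigma)
  gain <- exp(-2 * pi^2 * sigma^2 / p^2)
  interior <- 200:(n - 200)
  expect_equal(max(abs(q[interior] - 0.5)), 0.2 * gain, tolerance = 0.05)
})

test_that("etalon profiles isolate a zero-mean fringe residual", {
  axis <- default_axis(512)
  # constant-A response -> E identically 0
  flat <- tmm_response(optical_stack(substrate = const_mat(1.5)),
                       seq(780, 1108, 1))
  pf <- etalon_profile(flat, 785, axis)
  expect_lt(max(abs(pf$E)), 1e-12)
  expect_equal(pf$QE, pf$A, tolerance = 1e-12)
  # Design 7: E is a high-pass residual with near-zero mean
  p7 <- design_profiles(list(get_design(7)), axis)[[1]]
  expect_lt(abs(mean(p7$E)), 0.005)
  expect_lt(abs(mean(p7$E + 1) - 1), 0.01)
  expect_gt(stats::sd(p7$E), 0.005)  # fringes are actually present
  # coverage error names the gap
  narrow <- tmm_response(optical_stack(substrate = const_mat(1.5)), 800:900)
  expect_error(etalon_profile(narrow, 785, axis), class = "etalonsim_coverage")
})

test_that("E+1 curves have near-unit mean for every suite design", {
  axis <- default_axis(256)
  profs <- design_profiles(design_suite(1), axis)
  for (p in profs) expect_lt(abs(mean(p$E + 1) - 1), 0.01)
})

test_that("simulated corruption: identities and the pointwise-ratio oracle", {
  axis <- default_axis(256)
  clean <- broaden(sample_peaklist(5), axis)
  prof <- design_profiles(list(get_design(7)), axis)[[1]]
  # A == 1, baseline == 0 -> identity
  unit <- prof; unit$A <- rep(1, length(axis)); unit$QE <- unit$A; unit$E <- unit$A * 0
  pr <- corrupt_simulated(clean, rep(0, length(axis)), unit)
  expect_equal(pr$corrupted$intensity, clean$intensity)
  # scalar A halves everything
  half <- unit; half$A <- rep(0.5, length(axis))
  bl <- fluorescence_baseline(axis, 2, ref_intensity = max(clean$intensity))
  pr <- corrupt_simulated(clean, bl, half)
  expect_equal(pr$corrupted$intensity, as.numeric(0.5 * (clean$intensity + bl)),
               tolerance = 1e-15)
  # fringed A: corrupted / (clean + baseline) reproduces A pointwise
  pr <- corrupt_simulated(clean, bl, prof)
  lifted <- clean$intensity + bl
  expect_lt(max(abs(pr$corrupted$intensity / lifted - prof$A)), 1e-12)
  # round-trip well-posedness: dividing by A recovers clean + baseline
  expect_lt(max(abs(pr$corrupted$intensity / prof$A - lifted)), 1e-10)
  # axis mismatch is an alignment error
  short <- raman_spectrum(axis[1:128], clean$intensity[1:128])
  expect_error(corrupt_simulated(short, bl[1:128], prof),
               class = "etalonsim_alignment")
})

test_that("experimental preparation: dark current and E+1 ratio oracle", {
  axis <- default_axis(256)
  clean <- broaden(sample_peaklist(6), axis)
  prof <- design_profiles(list(get_design(7)), axis)[[1]]
  # dark = 0 and E == 0 -> identity
  unit <- prof; unit$E <- rep(0, length(axis))
  raw <- raman_spectrum(axis, clean$intensity * 3000 + 600)
  pr0 <- prepare_experimental(raw, unit, dark_current = 0)
  expect_equal(pr0$corrupted$intensity, raw$intensity)
  # raw identically 600 with dark 600 -> working identically 0
  r600 <- raman_spectrum(axis, rep(600, length(axis)))
  expect_true(all(prepare_experimental(r600, prof)$clean$intensity == 0))
  # fringes: corrupted / working = E + 1 wherever working > 0
  pr <- prepare_experimental(raw, prof)
  w <- pr$clean$intensity
  ok <- w > 0
  expect_lt(max(abs(pr$corrupted$intensity[ok] / w[ok] - (prof$E[ok] + 1))), 1e-12)
  expect_equal(pr$recipe, "E_plus_one")
  expect_equal(pr$dark_current, 600)
})

test_that("pair-set builders are deterministic and record provenance", {
  axis <- default_axis(128)
  profs <- design_profiles(design_suite(1)[c(7, 1)], axis)
  corpus <- raman_corpus(6, 3, axis)
  p1 <- make_simulated_pairs(corpus, profs, seed = 9)
  p2 <- make_simulated_pairs(corpus, profs, seed = 9)
  expect_identical(p1, p2)
  expect_equal(p1$recipe, "A_times")
  expect_true(all(p1$design_id %in% c(7L, 1L)))
  e1 <- make_experimental_pairs(corpus, profs, seed = 9)
  expect_equal(e1$recipe, "E_plus_one")
  expect_identical(e1, make_experimental_pairs(corpus, profs, seed = 9))
})
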
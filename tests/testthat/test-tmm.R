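# Transfer-matrix optics: closed forms, Airy oracle, energy conservation.

test_that("axial wavevector matches its closed form", {
  expect_equal(Re(axial_wavevector(1, 785)), 2 * pi / 785, tolerance = 1e-12)
  expect_equal(Re(axial_wavevector(1.5, 600)), 0.015707963, tolerance = 1e-6)
  k <- axial_wavevector(complex(real = 3.6, imaginary = 0.002), 900)
  expect_equal(k, 2 * pi * (3.6 + 0.002i) / 900, tolerance = 1e-12)
  expect_gt(Im(k), 0)  # absorbing medium decays forward
  expect_error(axial_wavevector(1.5, -5), class = "etalonsim_invalid_argument")
})

test_that("Snell chain conserves n sin(theta) with forward-decay branch", {
  st <- optical_stack(list(layer(const_mat(1.5, 0, "glass"), 100),
                           layer(const_mat(3.6, 0.01, "si"), 100)),
                      substrate = const_mat(2, 0, "sub"))
  # normal incidence: all cosines are exactly 1
  expect_equal(snell_chain(st, plane_wave(800, 0)), rep(1 + 0i, 4))
  # oblique: invariant holds to 1e-12, including the absorbing layer
  ct <- snell_chain(st, plane_wave(800, pi / 6))
  nm <- c(1, 1.5, 3.6 + 0.01i, 2)
  sines <- sqrt(1 - ct^2)
  expect_lt(max(Mod(nm * sines - nm[1] * sin(pi / 6))), 1e-12)
  expect_true(all(Im(nm * ct) >= -1e-15))
  # air -> glass textbook angle
  ct2 <- snell_chain(optical_stack(substrate = const_mat(1.5)),
                     plane_wave(600, pi / 6))
  expect_equal(Re(ct2[2]), sqrt(1 - (0.5 / 1.5)^2), tolerance = 1e-12)
})

test_that("Fresnel coefficients reproduce closed forms and identities", {
  fr <- fresnel("s", 1, 1, 1.5, 1)
  expect_equal(fr$r, -0.2 + 0i, tolerance = 1e-15)
  expect_equal(fr$t, 0.8 + 0i, tolerance = 1e-15)
  # identity interface
  id <- fresnel("s", 1.7, 1, 1.7, 1)
  expect_equal(id$r, 0 + 0i)
  expect_equal(id$t, 1 + 0i)
  # t = 1 + r and antisymmetry (s-pol)
  set.seed(11)
  for (i in 1:20) {
    n1 <- runif(1, 1, 4); n2 <- runif(1, 1, 4); th <- runif(1, 0, 1.2)
    c1 <- cos(th); s1 <- sin(th)
    c2 <- sqrt(1 - (n1 * s1 / n2)^2 + 0i)
    a <- fresnel("s", n1, c1, n2, c2)
    b <- fresnel("s", n2, c2, n1, c1)
    expect_equal(a$t, 1 + a$r, tolerance = 1e-12)
    expect_equal(a$r, -b$r, tolerance = 1e-12)
    # Stokes relation for lossless media
    expect_equal(Re(a$t * b$t + a$r^2), 1, tolerance = 1e-12)
  }
  # Brewster angle: p-pol reflection vanishes
  thb <- atan(1.5)
  c2 <- sqrt(1 - (sin(thb) / 1.5)^2 + 0i)
  expect_lt(Mod(fresnel("p", 1, cos(thb), 1.5, c2)$r), 1e-12)
})

test_that("layer matrix has the propagation-interface structure", {
  expect_equal(layer_matrix(0, 0, 1), diag(2) + 0i, tolerance = 1e-15)
  expect_equal(layer_matrix(pi, 0, 1), diag(c(-1, -1)) + 0i, tolerance = 1e-12)
  # a pure interface matrix round-trips through amplitude extraction
  a <- amplitudes(layer_matrix(0, -0.2, 0.8))
  expect_equal(a$r, -0.2 + 0i, tolerance = 1e-14)
  expect_equal(a$t, 0.8 + 0i, tolerance = 1e-14)
  expect_error(layer_matrix(0, 1, 0), class = "etalonsim_degenerate_interface")
})

test_that("stack matrix: vacuum, single interface, and the Airy oracle", {
  vac <- optical_stack()
  a <- amplitudes(stack_matrix(vac, plane_wave(700)))
  expect_equal(a$r, 0 + 0i)
  expect_equal(a$t, 1 + 0i)
  ag <- amplitudes(stack_matrix(optical_stack(substrate = const_mat(1.5)),
                                plane_wave(700)))
  expect_equal(ag$r, -0.2 + 0i, tolerance = 1e-14)
  # 1000 random lossless and absorbing films vs the Airy series
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    n1 <- complex(real = runif(1, 1.2, 4),
                  imaginary = if (i %% 2) 0 else runif(1, 0, 0.05))
    n2 <- runif(1, 1, 2)
    d <- runif(1, 30, 20000); wl <- runif(1, 500, 1100)
    st <- single_film_stack(n1, d, n2 = n2, k1 = Im(n1))
    got <- amplitudes(stack_matrix(st, plane_wave(wl)))
    want <- airy_film(1 + 0i, n1, n2 + 0i, d, wl)
    worst <- max(worst, Mod(got$r - want$r), Mod(got$t - want$t))
    if (i <= 100) expect_lte(Mod(got$r), 1 + 1e-12)
  }
  expect_lt(worst, 1e-10)
})

test_that("response obeys energy conservation and the lossless limit", {
  # bare air/glass: R = 0.04, T = 0.96, A = 0
  r <- tmm_response(optical_stack(substrate = const_mat(1.5)), 500:520)
  expect_equal(r$R, rep(0.04, 21), tolerance = 1e-12)
  expect_equal(r$T, rep(0.96, 21), tolerance = 1e-12)
  expect_lt(max(abs(r$A)), 1e-12)
  # lossless film: |A| at machine level
  rf <- tmm_response(single_film_stack(2.3, 1200, n2 = 1.5), seq(600, 900, 2))
  expect_lt(max(abs(rf$A)), 1e-8)
  # random passive stacks at normal and oblique incidence, both pols
  set.seed(21)
  for (i in 1:25) {
    nl <- sample(1:4, 1)
    lys <- lapply(seq_len(nl), function(j)
      layer(const_mat(runif(1, 1.2, 4), runif(1, 0, 0.02), paste0("m", j)),
            runif(1, 20, 5000)))
    st <- optical_stack(lys, substrate = const_mat(runif(1, 1, 3), 0, "sub"))
    for (pol in c("s", "p")) {
      rr <- tmm_response(st, seq(600, 1100, 25), angle = runif(1, 0, 1), pol = pol)
      expect_lt(max(abs(rr$R + rr$T + rr$A - 1)), 1e-10)
      expect_true(all(rr$R >= -1e-12 & rr$R <= 1 + 1e-12))
      expect_true(all(rr$T >= -1e-12 & rr$T <= 1 + 1e-12))
      expect_true(all(rr$A >= -1e-8))
    }
  }
})

test_that("s and p polarization agree at normal incidence", {
  st <- optical_stack(list(layer(const_mat(2.6, 0.01, "a"), 300),
                           layer(const_mat(1.46, 0, "b"), 800)),
                      substrate = const_mat(3.5, 0.005, "sub"))
  rs <- tmm_response(st, seq(600, 1100, 10), pol = "s")
  rp <- tmm_response(st, seq(600, 1100, 10), pol = "p")
  expect_lt(max(abs(rs$R - rp$R)), 1e-12)
  expect_lt(max(abs(rs$T - rp$T)), 1e-12)
})

test_that("degenerate layers are no-ops", {
  base <- tmm_response(optical_stack(substrate = const_mat(1.5)), 600:650)
  # zero-thickness layer between identical media
  z <- tmm_response(optical_stack(list(layer(const_mat(2.8, 0, "z"), 0)),
                                  substrate = const_mat(1.5)), 600:650)
  expect_lt(max(abs(z$R - base$R)), 1e-12)
  # index-matched layer (same as incident medium)
  m <- tmm_response(optical_stack(list(layer(const_mat(1, 0, "airlike"), 500)),
                                  substrate = const_mat(1.5)), 600:650)
  expect_lt(max(abs(m$R - base$R)), 1e-12)
  expect_lt(max(abs(m$T - base$T)), 1e-12)
})

test_that("fringe period follows 1/(2nd) and shrinks with thickness", {
  wl <- seq(785, 1099, by = 0.25)
  per <- fringe_period(tmm_response(single_film_stack(3.6, 16000), wl))
  expect_equal(per, 1 / (2 * 3.6 * 16000 * 1e-7), tolerance = 0.05)
  per2 <- fringe_period(tmm_response(single_film_stack(3.6, 32000), wl))
  expect_equal(per2 / per, 0.5, tolerance = 0.05)
  pers <- vapply(c(10000, 14000, 18000, 22000), function(d)
    fringe_period(tmm_response(single_film_stack(3.6, d), wl)), numeric(1))
  expect_true(all(diff(pers) < 0))
  # flat response: no fringes to measure
  flat <- tmm_response(optical_stack(substrate = const_mat(1.5)), 600:700)
  expect_error(fringe_period(flat), class = "etalonsim_insufficient_fringes")
})

test_that("dispersion coverage gaps raise a named error", {
  tab <- dispersion_table("narrow", c(700, 800), c(2, 2), c(0, 0))
  st <- optical_stack(list(layer(tab, 100)), substrate = const_mat(1.5))
  err <- tryCatch(tmm_response(st, 600:900), error = identity)
  expect_match(conditionMessage(err), "narrow")
  expect_match(conditionMessage(err), "600")
})
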
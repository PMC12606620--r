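# CCD design library: published stacks, silicon variation, suite properties.

test_that("published designs match their layer tables", {
  d7 <- get_design(7)
  expect_length(d7$stack$layers, 7)
  mats <- vapply(d7$stack$layers, function(l) l$material$material_id, character(1))
  expect_equal(mats, c("ito", "sio2", "isdp", "si", "sio2", "si3n4", "si"))
  expect_equal(vapply(d7$stack$layers, `[[`, numeric(1), "thickness_nm"),
               c(80, 55, 10, 16000, 80, 240, 500))
  expect_equal(d7$scenario, "interpolation")

  d4 <- get_design(4)
  expect_length(d4$stack$layers, 8)
  expect_equal(d4$stack$layers[[1]]$material$material_id, "tio2")
  expect_equal(d4$stack$layers[[1]]$thickness_nm, 57)
  expect_equal(vapply(d4$stack$layers, `[[`, numeric(1), "thickness_nm"),
               c(57, 132, 32, 50, 50, 300, 2000, 2e5))
  expect_equal(d4$scenario, "extrapolation")

  expect_error(get_design(9), class = "etalonsim_invalid_design")
  expect_error(get_design(0), class = "etalonsim_invalid_design")
})

test_that("vary_silicon changes only the silicon bulk layer, within range", {
  d7 <- get_design(7)
  v <- vary_silicon(d7, 14000)
  expect_equal(v$silicon_thickness, 14000)
  expect_equal(v$stack$layers[[4]]$thickness_nm, 14000)
  for (i in c(1:3, 5:7))
    expect_equal(v$stack$layers[[i]]$thickness_nm,
                 d7$stack$layers[[i]]$thickness_nm)
  # identity at the published thickness
  expect_equal(vary_silicon(d7, 16000), d7)
  expect_error(vary_silicon(d7, 20000), class = "etalonsim_range")
  expect_error(vary_silicon(get_design(4), 15000),
               class = "etalonsim_invalid_design")
})

test_that("the suite is deterministic per seed and spans both scenarios", {
  s1 <- design_suite(5); s2 <- design_suite(5); s3 <- design_suite(6)
  expect_equal(vapply(s1, `[[`, integer(1), "design_id"), 1:8)
  expect_equal(s1, s2)
  # different seed changes extrapolation thicknesses but not the exact designs
  expect_false(isTRUE(all.equal(s1[[1]], s3[[1]])))
  expect_equal(s1[[4]], s3[[4]])
  expect_equal(s1[[7]], s3[[7]])
  # interpolation designs differ only in silicon thickness
  for (i in c(6, 8)) {
    expect_equal(s1[[i]]$stack$layers[-4], s1[[7]]$stack$layers[-4])
    expect_true(s1[[i]]$silicon_thickness %in% c(14000, 18000))
  }
})

test_that("every suite design fringes over the sweep window", {
  wl <- 785:1099
  pers <- numeric(0)
  for (d in design_suite(1)) {
    r <- tmm_response(d$stack, wl)
    expect_lt(max(abs(r$R + r$T + r$A - 1)), 1e-10)
    p <- fringe_period(r)  # errors if < 3 maxima
    if (d$design_id %in% 6:8) pers[as.character(d$design_id)] <- p
  }
  # interpolation fringe period decreases with silicon thickness (14/16/18 um)
  expect_true(pers["6"] > pers["7"] && pers["7"] > pers["8"])
})

test_that("design-5-style AR stack suppresses fringes at high shifts", {
  axis <- default_axis(512)
  prof <- design_profiles(list(get_design(5)), axis)[[1]]
  half <- axis < 1850
  expect_gt(stats::sd(prof$E[half]), 2 * stats::sd(prof$E[!half]))
})
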
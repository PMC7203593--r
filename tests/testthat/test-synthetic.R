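test_that("the generator is deterministic in the seed", {
  a <- make_synthetic_fsu(synth_config(seed = 5))
  b <- make_synthetic_fsu(synth_config(seed = 5))
  c <- make_synthetic_fsu(synth_config(seed = 6))
  expect_identical(a, b)
  expect_false(identical(a, c))
  s1 <- make_synthetic_spine(synth_config(seed = 5))
  s2 <- make_synthetic_spine(synth_config(seed = 5))
  expect_identical(s1, s2)
})

test_that("bilateral structures are exactly mirror-symmetric across the sagittal plane", {
  geom <- make_synthetic_fsu(synth_config(seed = 3))
  pts <- geom$caudal$points
  expect_equal(pts$CL_left * c(-1, 1, 1), pts$CL_right)
  expect_equal(pts$ITL_left * c(-1, 1, 1), pts$ITL_right)
  # mirrored facet surfaces: the odd-in-x cubic coefficient flips sign
  expect_equal(geom$facets$left$coef$p30, -geom$facets$right$coef$p30,
               tolerance = 1e-9)
  expect_equal(geom$facets$left$coef$p00, geom$facets$right$coef$p00,
               tolerance = 1e-9)
})

test_that("generated facet landmarks support a stable surface fit", {
  geom <- make_synthetic_fsu(synth_config(seed = 4))
  for (side in c("left", "right")) {
    expect_lt(attr(geom$facets[[side]], "rms_sup"), 0.5)
    expect_lt(attr(geom$facets[[side]], "rms_inf"), 0.5)
  }
})

test_that("a noise-free table equals the forward simulation exactly", {
  eds1 <- fx_eds1()
  sim <- run_stepwise_forward(fx_chars(), fx_geom())
  expect_equal(eds1$rom_mean_deg, sim$rom_deg, tolerance = 1e-9)
  half <- eds1$rom_max_deg - eds1$rom_mean_deg
  expect_true(all(half[eds1$torque_nm > 0] >= 0.1 - 1e-12))
})

test_that("noise and ranges are seeded and shaped as configured", {
  geom <- tiny_segment()
  geom$ligaments <- list()
  # a disk-only table is cheap enough to simulate twice
  cfg <- synth_config(seed = 8, noise_rom_deg = 0.25,
                      range_halfwidth_frac = 0.2)
  t1 <- simulate_eds1(geom, fx_chars(), cfg)
  t2 <- simulate_eds1(geom, fx_chars(), cfg)
  expect_identical(t1, t2)
  t3 <- simulate_eds1(geom, fx_chars(), synth_config(seed = 9,
                                                     noise_rom_deg = 0.25))
  expect_false(identical(t1$rom_mean_deg, t3$rom_mean_deg))
  loaded <- t1[t1$torque_nm > 0, ]
  expect_equal(loaded$rom_max_deg - loaded$rom_mean_deg,
               pmax(0.1, 0.2 * abs(loaded$rom_mean_deg)))
})

test_that("the intradiscal-pressure table reflects cable compression ordering", {
  eds2 <- fx_eds2()
  expect_equal(nrow(eds2), 49)
  neutral <- eds2[eds2$load_case == "neutral", ]
  base <- neutral$idp_mean_mpa[neutral$muscle_config == "none"]
  all_on <- neutral$idp_mean_mpa[neutral$muscle_config == "all"]
  expect_gt(all_on, base)
  # every caudally pulling pair compresses the disk
  for (g in setdiff(muscle_groups(), "multifidus_cranial")) {
    expect_gt(neutral$idp_mean_mpa[neutral$muscle_config == g], base)
  }
  # cranial traction unloads it
  expect_lt(neutral$idp_mean_mpa[neutral$muscle_config ==
                                   "multifidus_cranial"], base)
  expect_true(all(eds2$idp_sd_mpa >= 0.02 - 1e-12))
})

test_that("symmetric chains mirror lateral and axial pressures", {
  eds2 <- fx_eds2()
  for (cfg in unique(eds2$muscle_config)) {
    sub <- eds2[eds2$muscle_config == cfg, ]
    lp <- sub$idp_mean_mpa[sub$load_case == "lateral_pos"]
    ln <- sub$idp_mean_mpa[sub$load_case == "lateral_neg"]
    if (is.na(lp) || is.na(ln)) next
    expect_equal(lp, ln, tolerance = 1e-3)
  }
})

test_that("a model compared against its own noise-free table has no outliers", {
  eds2 <- fx_eds2()
  mv <- tibble::tibble(muscle_config = eds2$muscle_config,
                       load_case = eds2$load_case,
                       idp_mpa = eds2$idp_mean_mpa)
  expect_equal(count_outliers(mv, eds2, "sd")$count, 0)
})
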
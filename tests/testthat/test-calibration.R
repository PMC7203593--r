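test_that("disk point extraction reproduces the disk-only stage records", {
  eds1 <- fx_eds1()
  pts <- extract_disk_points(eds1)
  for (d in c("flexion", "extension", "lateral", "axial")) {
    sub <- dplyr::filter(pts, direction == d)
    expect_equal(nrow(sub), 6)   # five torques plus the origin
    expect_true(any(sub$phi_rad == 0 & sub$torque_nm == 0))
  }
  # round trip: the noise-free points lie exactly on the generating curves
  rows <- fx_chars()$disk$rot
  loaded <- dplyr::filter(pts, torque_nm > 0)
  for (i in seq_len(nrow(loaded))) {
    p <- rows[[loaded$direction[i]]]
    tq <- p$p1 * tanh(loaded$phi_rad[i]^3 / p$p2) + p$p3 * loaded$phi_rad[i]
    expect_equal(tq, loaded$torque_nm[i], tolerance = 1e-6)
  }
  expect_error(extract_disk_points(dplyr::filter(eds1,
                                                 stage != "wo_ALL")),
               "wo_ALL")
})

test_that("tanh-cubic fits recover generating parameters from noiseless samples", {
  rows <- fx_chars()$disk$rot
  phi <- seq(0.002, 0.3, length.out = 50)
  for (d in c("flexion", "axial")) {
    p <- rows[[d]]
    pts <- tibble::tibble(phi_rad = phi,
                          torque_nm = p$p1 * tanh(phi^3 / p$p2) +
                            p$p3 * phi)
    fit <- fit_disk_characteristic(pts, d)
    expect_equal(signif(fit$p1, 4), signif(p$p1, 4))
    expect_equal(signif(fit$p2, 4), signif(p$p2, 4))
    expect_equal(signif(fit$p3, 4), signif(p$p3, 4))
    expect_lt(fit$rmse, 1e-8)
  }
})

test_that("tanh-cubic fit degenerates gracefully to a straight line", {
  phi <- seq(0, 0.3, length.out = 30)
  fit <- fit_disk_characteristic(tibble::tibble(phi_rad = phi,
                                                torque_nm = 3 * phi))
  pred <- fit$p1 * tanh(phi^3 / fit$p2) + fit$p3 * phi
  expect_lt(sqrt(mean((pred - 3 * phi)^2)), 1e-6)
  expect_error(fit_disk_characteristic(
    tibble::tibble(phi_rad = c(0, 0, 0.1), torque_nm = c(0, 0, 1))),
    "distinct")
})

test_that("softplus fit recovers the anterior-longitudinal row from a perturbed start", {
  row <- fx_chars()$ligaments$ALL
  eps <- seq(0, 20, length.out = 100)
  pts <- tibble::tibble(
    strain_pct = eps,
    force_n = row$a * log1p(exp((eps + row$b) / row$d)) + row$c)
  fit <- fit_ligament_characteristic(
    pts, start = 1.1 * c(row$a, row$b, row$c, row$d))
  expect_equal(signif(fit$a, 4), 173.5)
  expect_lt(fit$rmse, 1e-6)
})

test_that("softplus fit handles straight-line and degenerate point sets", {
  eps <- seq(0, 20, length.out = 40)
  lin <- fit_ligament_characteristic(tibble::tibble(strain_pct = eps,
                                                    force_n = 2 * eps))
  expect_lt(lin$rmse, 1e-3)
  expect_warning(
    zero <- fit_ligament_characteristic(tibble::tibble(strain_pct = eps,
                                                       force_n = 0 * eps)),
    "zero")
  expect_equal(ligament_force(zero$char, 30), 0)
  expect_error(fit_ligament_characteristic(
    tibble::tibble(strain_pct = c(0, 1, 2, 3, 4), force_n = 1:5)), "span")
  expect_error(fit_ligament_characteristic(
    tibble::tibble(strain_pct = c(0, 10), force_n = c(0, 1))), ">= 5")
})

test_that("facet stiffness is recovered from the capsule-free stage", {
  eds1 <- fx_eds1()
  chars <- fx_chars()
  known <- chars
  known$ligaments <- list(ALL = chars$ligaments$ALL,
                          PLL = chars$ligaments$PLL,
                          ITL = zero_ligament_characteristic())
  fac <- extract_facet_stiffness(eds1, fx_geom(), known)
  expect_equal(fac$stiffness, 12000, tolerance = 0.02)
  expect_gt(nrow(fac$samples), 0)
  # the returned stiffness is the least-squares scalar over its samples
  expect_equal(fac$stiffness,
               sum(fac$samples$deficit_nm * fac$samples$arm) /
                 sum(fac$samples$arm^2), tolerance = 1e-9)
  expect_error(extract_facet_stiffness(
    dplyr::filter(eds1, stage != "wo_CL"), fx_geom(), known), "wo_CL")
})

test_that("ligament point extraction reproduces the generating curve", {
  eds1 <- fx_eds1()
  chars <- fx_chars()
  known <- chars
  known$ligaments <- list(ITL = zero_ligament_characteristic())
  known$facets$stiffness <- 0
  ex <- suppressWarnings(
    extract_ligament_points(eds1, "wo_PLL", "ALL", fx_geom(), known))
  big_arm <- ex$points[ex$points$arm_m > 0.01, ]
  truth <- ligament_force(chars$ligaments$ALL, big_arm$strain_pct)
  expect_lt(max(abs(big_arm$force_n - truth)), 1.5)
  expect_gte(nrow(big_arm), 5)
})

test_that("a missing stage aborts the calibration naming the stage", {
  eds1 <- fx_eds1()
  expect_error(
    run_backward_calibration(dplyr::filter(eds1, stage != "wo_FL"),
                             fx_geom()),
    "wo_FL")
})

test_that("identical consecutive stages yield a near-zero element", {
  eds1 <- fx_eds1()
  doctored <- eds1
  src <- dplyr::filter(eds1, stage == "wo_SSL")
  idx <- which(doctored$stage == "intact")
  key <- paste(doctored$direction[idx], doctored$torque_nm[idx])
  src_key <- paste(src$direction, src$torque_nm)
  doctored$rom_mean_deg[idx] <- src$rom_mean_deg[match(key, src_key)]
  chars <- fx_chars()
  known <- chars
  known$ligaments[["SSL"]] <- NULL
  known$ligaments$ITL <- zero_ligament_characteristic()
  ex <- suppressWarnings(
    extract_ligament_points(doctored, "intact", "SSL", fx_geom(), known,
                            max_outer = 3))
  forces <- ligament_force(if (is.null(ex$fit))
    zero_ligament_characteristic() else ex$fit$char,
    seq(-20, 5, length.out = 50))
  expect_lt(max(forces), 2)
})
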
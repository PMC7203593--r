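test_that("the protocol grids enumerate the full experimental designs", {
  rom <- rom_protocol_grid()
  expect_equal(nrow(rom), 192)
  expect_equal(sum(rom$torque_nm > 0), 160)
  expect_equal(length(unique(rom$stage)), 8)
  expect_equal(sort(unique(rom$torque_nm)), c(0, 1, 2.5, 5, 7.5, 10))
  idp <- idp_protocol_grid()
  expect_equal(nrow(idp), 49)
  expect_equal(length(unique(idp$muscle_config)), 7)
  expect_equal(length(unique(idp$load_case)), 7)
  expect_true(all(idp$torque_nm[idp$load_case != "neutral"] == 3.75))
})

make_ref <- function() {
  tibble::tibble(
    stage = "intact", direction = rep(c("flexion", "extension"), each = 3),
    torque_nm = rep(c(0, 5, 10), 2),
    rom_mean_deg = c(0, 4, 6, 0, 3, 5),
    rom_min_deg = c(NA, 3.5, 5.5, NA, 2.5, 4.5),
    rom_max_deg = c(NA, 4.5, 6.5, NA, 3.5, 5.5))
}

test_that("range-mode outlier counting honours the closed interval and skips 0 Nm", {
  ref <- make_ref()
  inside <- dplyr::mutate(ref, rom_deg = rom_mean_deg)
  expect_equal(count_outliers(inside, ref, "range")$count, 0)
  # exactly at the boundary is inside
  edge <- dplyr::mutate(ref, rom_deg = rom_max_deg)
  edge$rom_deg[is.na(edge$rom_deg)] <- 0
  expect_equal(count_outliers(edge, ref, "range")$count, 0)
  # three planted exceedances are found; a wild 0 Nm value is ignored
  bad <- inside
  bad$rom_deg[c(2, 3, 6)] <- bad$rom_max_deg[c(2, 3, 6)] + 1
  bad$rom_deg[1] <- 99
  out <- count_outliers(bad, ref, "range")
  expect_equal(out$count, 3)
  expect_setequal(out$outliers$torque_nm, c(5, 10))
})

test_that("outlier counting is invariant under row permutation and strict on keys", {
  ref <- make_ref()
  mv <- dplyr::mutate(ref, rom_deg = rom_mean_deg)
  mv$rom_deg[3] <- 100
  shuffled <- mv[sample(nrow(mv)), ]
  expect_equal(count_outliers(mv, ref, "range")$count,
               count_outliers(shuffled, ref, "range")$count)
  alien <- dplyr::mutate(mv, stage = "wo_SSL")
  expect_error(count_outliers(alien, ref, "range"), "missing")
})

test_that("sd-mode outlier counting flags one-sigma exceedances", {
  ref <- tibble::tibble(
    muscle_config = c("none", "all"), load_case = c("neutral", "flexion"),
    idp_mean_mpa = c(0.3, 0.5), idp_sd_mpa = c(0.05, 0.1))
  ok <- tibble::tibble(muscle_config = ref$muscle_config,
                       load_case = ref$load_case,
                       idp_mpa = c(0.34, 0.41))
  expect_equal(count_outliers(ok, ref, "sd")$count, 0)
  bad <- dplyr::mutate(ok, idp_mpa = c(0.36, 0.39))
  expect_equal(count_outliers(bad, ref, "sd")$count, 2)
})

test_that("the five muscle groups cover the experimental cable pairs", {
  expect_equal(length(muscle_groups()), 5)
  expect_true(all(c("multifidus_caudal", "multifidus_cranial") %in%
                    muscle_groups()))
})

test_that("the forward stepwise sweep has the protocol shape", {
  eds1 <- fx_eds1()   # built through run_stepwise_forward
  expect_equal(nrow(eds1), 192)
  expect_equal(sum(eds1$torque_nm > 0), 160)
  expect_true(all(is.na(eds1$rom_min_deg[eds1$torque_nm == 0])))
  expect_true(all(eds1$rom_min_deg[eds1$torque_nm > 0] <=
                    eds1$rom_mean_deg[eds1$torque_nm > 0]))
  # ROM grows with torque within every stage and direction
  grp <- dplyr::group_by(dplyr::filter(eds1, torque_nm > 0),
                         stage, direction)
  mono <- dplyr::summarise(grp,
                           ok = all(diff(rom_mean_deg[order(torque_nm)]) >
                                      -1e-6), .groups = "drop")
  expect_true(all(mono$ok))
})
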
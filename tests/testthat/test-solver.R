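test_that("a purely linear torsional model equilibrates exactly at M/k", {
  geom <- tiny_segment(prestrain = 0)
  geom$ligaments <- list()
  k <- 20   # Nm/rad
  lin <- disk_characteristic(rot = list(
    flexion = list(p1 = 0, p2 = 1, p3 = k),
    extension = list(p1 = 0, p2 = 1, p3 = k),
    lateral = list(p1 = 0, p2 = 1, p3 = k),
    axial = list(p1 = 0, p2 = 1, p3 = k)))
  chars <- fx_chars()
  chars$disk <- lin
  model <- build_model(geom, chars, stage = "wo_ALL")
  res <- solve_equilibrium(model, load_case("flexion", 5))
  expect_true(res$converged)
  expect_equal(res$rom_deg, (5 / k) * 180 / pi, tolerance = 1e-6)
})

test_that("disk-only equilibria match the scalar torque-inversion oracle", {
  model <- build_model(fx_geom(), fx_chars(), stage = "wo_ALL")
  rows <- fx_chars()$disk$rot
  cases <- list(c("flexion", 1), c("flexion", 10), c("extension", 7.5),
                c("lateral", 5), c("axial", 10))
  for (cs in cases) {
    d <- cs[[1]]
    tq <- as.numeric(cs[[2]])
    res <- solve_equilibrium(model, load_case(d, tq))
    row <- rows[[if (d %in% c("lateral", "axial")) d else d]]
    oracle <- invert_disk_row(row, tq)
    ax <- if (d == "flexion" || d == "extension") 1 else
      if (d == "lateral") 2 else 3
    sign <- if (d == "extension") -1 else 1
    phi <- res$state[3 + ax] * sign
    expect_lt(abs(phi - oracle), 1e-4)
  }
})

test_that("the neutral load case self-equilibrates with prestrained ligaments", {
  model <- build_model(fx_geom(), fx_chars(), stage = "intact")
  res <- solve_equilibrium(model, load_case("neutral"))
  expect_true(res$converged)
  expect_lt(res$residual_norm[["force"]], 1e-6)
  expect_lt(res$residual_norm[["torque"]], 1e-8)
  expect_lt(max(abs(res$state[1:3])), 1e-3)   # translations stay sub-mm
})

test_that("lateral bending of a sagittally symmetric segment mirrors in sign", {
  model <- build_model(fx_geom(), fx_chars(), stage = "intact")
  n <- solve_equilibrium(model, load_case("neutral"))
  pl <- solve_equilibrium(model, load_case("lateral", 5), init = n$state)
  mn <- solve_equilibrium(model, load_case("lateral_neg", 5),
                          init = n$state)
  expect_equal(rom_from_result(pl, model, 1, 2),
               -rom_from_result(mn, model, 1, 2), tolerance = 1e-6)
})

test_that("two identical disk-only segments in series compose rotations additively", {
  lin <- fx_chars()
  bodies <- list(rigid_body("A", c(0, 0, 0.08)),
                 rigid_body("B", c(0, 0, 0.04)),
                 rigid_body("C", c(0, 0, 0)))
  seg1 <- segment_geometry(bodies[[1]], bodies[[2]], c(0, 0, 0.06),
                           csa = 1.8e-3)
  seg2 <- segment_geometry(bodies[[2]], bodies[[3]], c(0, 0, 0.02),
                           csa = 1.8e-3)
  chain <- spine_geometry(bodies, list(seg1, seg2))
  model <- build_model(chain, lin, stage = "wo_ALL")
  res <- solve_equilibrium(model, load_case("axial", 5))
  expect_true(res$converged)
  single <- build_model(seg2, lin, stage = "wo_ALL")
  r1 <- solve_equilibrium(single, load_case("axial", 5))
  # a pure moment transmits undiminished down the chain
  expect_equal(res$rom_deg[1], r1$rom_deg[1], tolerance = 1e-4)
  expect_equal(res$rom_deg[2], r1$rom_deg[1], tolerance = 1e-4)
  # top-to-bottom rotation is the sum of the segment rotations
  top <- spinewise:::matrix_to_rotvec(
    spinewise:::rotvec_to_matrix(res$poses$A$rot))[3] * 180 / pi
  expect_equal(top, sum(res$rom_deg), tolerance = 1e-3)
})

test_that("removing passive elements does not reduce ROM along the reduction order", {
  # removal monotonicity holds exactly for the absolute end-range rotation;
  # table ROM is referenced to each stage's own 0 Nm pose, so prestressed
  # elements (their removal shifts the neutral) can reduce *referenced* ROM
  # by a fraction of a degree, and the concave flaval row by more (its
  # removal step is exempt). Spot-check the absolute-angle property first.
  geom <- fx_geom()
  chars <- fx_chars()
  phis <- vapply(c("wo_FL", "wo_CL", "wo_VA"), function(st) {
    m <- build_model(geom, chars, stage = st)
    solve_equilibrium(m, load_case("flexion", 5))$state[4]
  }, numeric(1))
  expect_true(all(diff(phis) > -1e-6))

  eds1 <- fx_eds1()
  wide <- tidyr::pivot_wider(
    dplyr::filter(eds1, torque_nm > 0),
    id_cols = c("direction", "torque_nm"),
    names_from = "stage", values_from = "rom_mean_deg")
  transitions <- list(c("intact", "wo_SSL"), c("wo_SSL", "wo_ISL"),
                      c("wo_FL", "wo_CL"), c("wo_CL", "wo_VA"),
                      c("wo_VA", "wo_PLL"))
  for (tr in transitions) {
    expect_true(all(wide[[tr[2]]] - wide[[tr[1]]] > -0.3),
                info = paste(tr, collapse = " -> "))
  }
})

test_that("equilibria are independent of damping coefficients", {
  chars <- fx_chars()
  chars$disk$d_damp_tra <- 1
  chars$disk$d_damp_rot <- 1
  chars$ligaments <- lapply(chars$ligaments, function(l) {
    l$damping_factor <- 0
    l
  })
  m1 <- build_model(fx_geom(), fx_chars(), stage = "intact")
  m2 <- build_model(fx_geom(), chars, stage = "intact")
  r1 <- solve_equilibrium(m1, load_case("flexion", 7.5))
  r2 <- solve_equilibrium(m2, load_case("flexion", 7.5))
  expect_equal(r1$state, r2$state, tolerance = 1e-6)
})

test_that("rom_from_result converts relative rotation to degrees", {
  model <- build_model(fx_geom(), fx_chars(), stage = "wo_ALL")
  res <- solve_equilibrium(model, load_case("neutral"))
  res$state[4] <- 0.1
  expect_equal(rom_from_result(res, model, 1, 1), 0.1 * 180 / pi,
               tolerance = 1e-9)
})

test_that("a load beyond the saturating flexion row has no equilibrium and errors", {
  # the flexion tanh-cubic row saturates near 10 Nm, so 50 Nm cannot be
  # balanced by the disk alone
  model <- build_model(fx_geom(), fx_chars(), stage = "wo_ALL")
  expect_error(
    solve_equilibrium(model, load_case("flexion", 50),
                      control = list(max_iter = 15, relax_steps = 5)),
    "no convergence")
})
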
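test_that("disk translational spring matches the compression polynomial and is tension-free", {
  ch <- fx_chars()$disk
  expect_equal(disk_force(ch, c(0, 0, 0)), c(0, 0, 0))
  f <- disk_force(ch, c(0, 0, 0.001))
  expect_equal(f[3], 690234060 * 1e-6 + 659748 * 1e-3, tolerance = 1e-10)
  expect_equal(disk_force(ch, c(0, 0, -0.001))[3], 0)
  # linear shear
  expect_equal(disk_force(ch, c(1e-4, 0, 0))[1], -ch$shear_stiffness * 1e-4)
})

test_that("disk torque follows the tanh-cubic law with per-sign sagittal rows", {
  ch <- fx_chars()$disk
  expect_equal(disk_torque(ch, c(0, 0, 0)), c(0, 0, 0))
  p <- ch$rot$flexion
  expected <- p$p1 * tanh(0.3^3 / p$p2) + p$p3 * 0.3
  expect_equal(disk_torque(ch, c(0.3, 0, 0))[1], -expected,
               tolerance = 1e-12)
  expect_equal(signif(expected, 4), 10.16)
  pe <- ch$rot$extension
  expect_equal(disk_torque(ch, c(-0.2, 0, 0))[1],
               pe$p1 * tanh(0.2^3 / pe$p2) + pe$p3 * 0.2, tolerance = 1e-12)
})

test_that("lateral and axial disk torque are odd in the rotation angle", {
  ch <- fx_chars()$disk
  for (theta in c(0.02, 0.1, 0.25)) {
    expect_equal(disk_torque(ch, c(0, theta, 0))[2],
                 -disk_torque(ch, c(0, -theta, 0))[2], tolerance = 1e-12)
    expect_equal(disk_torque(ch, c(0, 0, theta))[3],
                 -disk_torque(ch, c(0, 0, -theta))[3], tolerance = 1e-12)
  }
})

test_that("torque rows are monotone where the protocol operates", {
  ch <- fx_chars()$disk
  phi <- seq(0.05, 0.35, by = 1e-3)
  for (d in c("extension", "lateral", "axial")) {
    p <- ch$rot[[d]]
    tq <- p$p1 * tanh(phi^3 / p$p2) + p$p3 * phi
    expect_true(all(diff(tq) > 0))
  }
  # the flexion row is increasing over the mid range but saturates near the
  # top protocol torque: its maximum (~10.2 Nm) sits near 0.25 rad, beyond
  # which the negative linear coefficient wins
  p <- ch$rot$flexion
  mid <- seq(0.05, 0.23, by = 1e-3)
  tq <- p$p1 * tanh(mid^3 / p$p2) + p$p3 * mid
  expect_true(all(diff(tq) > 0))
  expect_lt(max(p$p1 * tanh(phi^3 / p$p2) + p$p3 * phi), 10.2)
  # and it has a shallow non-monotone toe below ~0.03 rad whose magnitude
  # never exceeds a few hundredths of a Nm
  toe <- seq(0, 0.031, by = 1e-4)
  expect_lt(max(abs(p$p1 * tanh(toe^3 / p$p2) + p$p3 * toe)), 0.03)
})

test_that("ligament softplus law reproduces the packaged rows and their limits", {
  ch <- fx_chars()
  isl <- ch$ligaments$ISL
  expected <- isl$a * log1p(exp((5 + isl$b) / isl$d)) + isl$c
  expect_equal(ligament_force(isl, 5), expected, tolerance = 1e-9)
  expect_equal(signif(expected, 3), 28.0)
  # softplus lower limit: force tends to c, clamped at zero
  all_row <- ch$ligaments$ALL
  expect_equal(ligament_force(all_row, -80), 0)
  # cables cannot push even where the raw curve is negative
  expect_true(all(ligament_force(all_row, seq(-30, 0, by = 1)) >= 0))
})

test_that("supraspinous negative-strain branch joins continuously at zero strain", {
  ssl <- fx_chars()$ligaments$SSL
  pos <- spinewise:::softplus_force(0, ssl$a, ssl$b, ssl$c, ssl$d)
  nb <- ssl$neg_branch
  neg <- spinewise:::softplus_force(0, nb$a, nb$b, nb$c, nb$d)
  expect_lt(abs(pos - neg), 0.1)
  # a discontinuous branch pair is rejected at construction
  expect_error(
    ligament_characteristic(1.218, -22.97, 0, 1.369,
                            neg_branch = list(a = 10, b = 0, c = 5, d = 1)),
    "zero strain")
})

test_that("softplus slope saturates at a/d and vanishes for deep slack", {
  for (row in fx_chars()$ligaments[c("ALL", "PLL", "ISL", "SSL")]) {
    h <- 1e-4
    num <- function(e) {
      (spinewise:::softplus_force(e + h, row$a, row$b, row$c, row$d) -
         spinewise:::softplus_force(e - h, row$a, row$b, row$c, row$d)) /
        (2 * h)
    }
    ana <- function(e) spinewise:::softplus_slope(e, row$a, row$b, row$d)
    for (e in c(-10, 0, 15, 40)) {
      expect_equal(num(e), ana(e), tolerance = 1e-4)
    }
    high <- row$b + 40 * abs(row$d) + 40
    expect_equal(num(high), row$a / row$d, tolerance = 1e-3)
    low <- row$b - 40 * abs(row$d) - 40
    expect_equal(num(low), 0, tolerance = 1e-6)
  }
})

test_that("facet probe contact follows the penalty spring law", {
  frame <- list(origin = c(0, 0, 0), axes = diag(3))
  flat <- facet_surface_def(list(p30 = 0, p03 = 0, p20 = 0, p02 = 0,
                                 p00 = 5),
                            frame = frame, stiffness = 12000, damping = 0,
                            probe_points = matrix(c(0, 0, 0.004), nrow = 1))
  res <- facet_force(flat, pose())
  expect_equal(res$force, c(0, 0, 12), tolerance = 1e-9)
  # separated probe: no wrench
  clear <- facet_surface_def(flat$coef, frame, 12000, 0,
                             probe_points = matrix(c(0, 0, 0.006), nrow = 1))
  expect_equal(facet_force(clear, pose())$force, c(0, 0, 0))
  # linearity in penetration depth
  deep <- facet_surface_def(flat$coef, frame, 12000, 0,
                            probe_points = matrix(c(0, 0, 0.003), nrow = 1))
  expect_equal(facet_force(deep, pose())$force[3], 24, tolerance = 1e-9)
})

test_that("muscle cables transmit pose-independent constant traction", {
  m0 <- muscle_cable("L2", c(0, 0, 0.01), c(0, 0, -1), force = 40)
  w0 <- muscle_wrench(m0, pose())
  expect_equal(w0$force, c(0, 0, -40))
  expect_equal(w0$torque, c(0, 0, 0))
  m1 <- muscle_cable("L2", c(0, 0.03, 0), c(0, 0, -1), force = 40)
  # a 40 N caudal pull offset 0.03 m dorsally: 1.2 Nm about x (extension
  # sense, hence negative in this frame)
  expect_equal(muscle_wrench(m1, pose())$torque, c(-1.2, 0, 0),
               tolerance = 1e-12)
  # mirrored pair cancels the axial torque
  mr <- muscle_cable("L2", c(0.02, 0.03, 0), c(0, 0.1, -0.99), force = 40)
  ml <- muscle_cable("L2", c(-0.02, 0.03, 0), c(0, 0.1, -0.99), force = 40)
  net <- muscle_wrench(mr, pose())$torque + muscle_wrench(ml, pose())$torque
  expect_equal(net[3], 0, tolerance = 1e-12)
  # force magnitude unchanged under rotation of the body
  w_rot <- muscle_wrench(m1, pose(rot = c(0.2, 0, 0)))
  expect_equal(w_rot$force, c(0, 0, -40))
})

test_that("intradiscal pressure conversion is the 1.68 stress ratio", {
  expect_equal(idp_from_force(500, 5e-4), 1.68e6)
  expect_equal(idp_from_force(0, 5e-4), 0)
  expect_equal(idp_from_force(1000, 5e-4), 2 * idp_from_force(500, 5e-4))
  expect_error(idp_from_force(500, 0), "csa")
  expect_error(idp_from_force(-1, 1e-3), "compressive")
})

test_that("a prestrain-free model at the identity pose transmits almost nothing", {
  geom <- fx_geom()
  geom$ligaments <- lapply(geom$ligaments, function(l) {
    l$prestrain <- 0
    l
  })
  chars <- fx_chars()
  # the flaval row is the one characteristic with a large force offset at
  # zero strain (its concave law never vanishes); with it excluded the only
  # residual at rest is the capsular row's ~0.05 N offset at zero strain
  chars$ligaments$FL <- zero_ligament_characteristic()
  model <- build_model(geom, chars, stage = "intact")
  r <- residual_wrench(model, pose())
  expect_lt(max(abs(unlist(r[, -1]))), 0.1)
})
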
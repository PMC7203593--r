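test_that("facet surface fit recovers the packaged coefficient sets from noiseless landmarks", {
  ch <- fx_chars()
  for (side in c("left", "right")) {
    coef <- ch$facets[[side]]
    fit <- fit_facet_surface(landmarks_on(coef), landmarks_on(coef))
    for (term in names(coef)) {
      expect_equal(signif(fit$coef[[term]], 4), signif(coef[[term]], 4))
    }
    expect_lt(attr(fit, "rms_sup"), 1e-9)
  }
})

test_that("facet surface fit is exact for arbitrary coefficients and handles flat planes", {
  set.seed(7)
  for (i in 1:5) {
    coef <- list(p30 = stats::rnorm(1, 0, 0.01), p03 = stats::rnorm(1, 0, 0.01),
                 p20 = stats::rnorm(1, 0, 0.2), p02 = stats::rnorm(1, 0, 0.2),
                 p00 = stats::rnorm(1, 45, 5))
    fit <- fit_facet_surface(landmarks_on(coef), landmarks_on(coef))
    expect_equal(unlist(fit$coef), unlist(coef), tolerance = 1e-9)
  }
  flat <- list(p30 = 0, p03 = 0, p20 = 0, p02 = 0, p00 = 5)
  fit <- fit_facet_surface(landmarks_on(flat), landmarks_on(flat))
  expect_equal(unlist(fit$coef), c(p30 = 0, p03 = 0, p20 = 0, p02 = 0,
                                   p00 = 5), tolerance = 1e-10)
})

test_that("the mean regression surface is the coefficient-wise mean of the two fits", {
  coef <- list(p30 = -0.008, p03 = -0.004, p20 = -0.18, p02 = -0.17,
               p00 = 47)
  offset <- utils::modifyList(coef, list(p00 = coef$p00 + 2))
  fit <- fit_facet_surface(landmarks_on(coef), landmarks_on(offset))
  expect_equal(fit$coef$p00, coef$p00 + 1, tolerance = 1e-9)
  expect_equal(fit$coef$p20, coef$p20, tolerance = 1e-9)
})

test_that("degenerate or frame-mismatched landmark sets are rejected", {
  collinear <- facet_landmarks(cbind(seq_len(9), seq_len(9) * 2, 1))
  good <- landmarks_on(list(p30 = 0, p03 = 0, p20 = -0.1, p02 = -0.1,
                            p00 = 40))
  expect_error(fit_facet_surface(collinear, collinear), "degenerate")
  f1 <- list(origin = c(0, 0, 0), axes = diag(3))
  f2 <- list(origin = c(0, 0, 0.01), axes = diag(3))
  a <- landmarks_on(list(p30 = 0, p03 = 0, p20 = -0.1, p02 = -0.1,
                         p00 = 40), frame = f1)
  b <- landmarks_on(list(p30 = 0, p03 = 0, p20 = -0.1, p02 = -0.1,
                         p00 = 40), frame = f2)
  expect_error(fit_facet_surface(a, b), "frames")
  expect_error(facet_landmarks(matrix(0, 8, 3)), "9 points")
})

test_that("strain at the identity pose equals the declared prestrain", {
  for (seed in c(1, 2, 9)) {
    geom <- make_synthetic_fsu(synth_config(seed = seed))
    for (lig in geom$ligaments) {
      k <- ligament_kinematics(geom, lig, pose())
      expect_equal(k$strain, lig$prestrain, tolerance = 1e-10)
    }
  }
})

test_that("uniaxial stretch of a vertical cord gives the textbook strain", {
  geom <- tiny_segment(prestrain = 0)
  k <- ligament_kinematics(geom, geom$ligaments[[1]],
                           pose(trans = c(0, 0, 0.002)))
  expect_equal(k$strain, 10, tolerance = 1e-9)
  expect_equal(k$length, 0.022, tolerance = 1e-12)
})

test_that("a midline ligament in the x-z plane has zero lateral moment arm", {
  geom <- fx_geom()
  mid <- Filter(function(l) l$side == "midline", geom$ligaments)
  for (lig in mid) {
    k <- ligament_kinematics(geom, lig, pose())
    expect_equal(unname(k$moment_arm[["y"]]), 0, tolerance = 1e-12)
  }
})

test_that("moment arms agree with the finite-difference length gradient", {
  geom <- fx_geom()
  set.seed(11)
  h <- 1e-6
  for (rep in 1:4) {
    base <- pose(rot = stats::runif(3, -0.1, 0.1),
                 trans = stats::runif(3, -1e-3, 1e-3))
    lig <- geom$ligaments[[sample(length(geom$ligaments), 1)]]
    k <- ligament_kinematics(geom, lig, base)
    for (axis in 1:3) {
      # incremental rotation about the disk centre: compose the rotation and
      # move the centre of mass so the disk centre stays put
      bump <- function(s) {
        e <- c(0, 0, 0)
        e[axis] <- s * h
        Rd <- spinewise:::rotvec_to_matrix(e)
        R0 <- spinewise:::rotvec_to_matrix(base$rot)
        R1 <- Rd %*% R0
        com <- geom$cranial$com
        c_w <- spinewise:::transform_point(geom$disk_centre, R0, com,
                                           base$trans)
        # translation such that the (body-frame) disk centre maps to
        # Rd (c_w - c) + c
        c_new <- as.numeric(Rd %*% (c_w - geom$disk_centre)) +
          geom$disk_centre
        t1 <- c_new - as.numeric(R1 %*% (geom$disk_centre - com)) - com
        ligament_kinematics(geom, lig, pose(rot = spinewise:::matrix_to_rotvec(R1),
                                            trans = t1))$length
      }
      dl_dphi <- (bump(1) - bump(-1)) / (2 * h)
      expect_equal(dl_dphi, -unname(k$moment_arm[[axis]]),
                   tolerance = 1e-5)
    }
  }
})

test_that("mirror-symmetric bilateral ligaments strain equally in pure sagittal poses", {
  geom <- fx_geom()
  cl <- Filter(function(l) l$name == "CL", geom$ligaments)
  for (phi in c(0.05, -0.08)) {
    ks <- lapply(cl, function(l) {
      ligament_kinematics(geom, l, pose(rot = c(phi, 0, 0)))
    })
    expect_equal(ks[[1]]$strain, ks[[2]]$strain, tolerance = 1e-10)
  }
})

test_that("geometry constructors enforce their invariants", {
  expect_error(segment_geometry(rigid_body("a", c(0, 0, 0.04)),
                                rigid_body("b", c(0, 0, 0)),
                                disk_centre = c(0, 0, 0.02), csa = 0),
               "csa")
  expect_error(segment_geometry(rigid_body("a", c(0, 0, 0.04)),
                                rigid_body("b", c(0, 0, 0)),
                                disk_centre = c(0, 0, 0.1)),
               "between")
  expect_error(ligament_def("ALL", "midline", c("a", "P"), c("b", "P"),
                            prestrain = 30), "prestrain")
  expect_error(rigid_body("a", c(0, 0, 0),
                          points = list(P = c(0, 0, 0), P = c(1, 0, 0))),
               "unique")
  expect_error(pose(rot = c(pi, 0, 0)), "pi")
})

test_that("coincident ligament endpoints raise a geometry error", {
  cr <- rigid_body("up", com = c(0, 0, 0.04), points = list(P = c(0, 0, 0.02)))
  ca <- rigid_body("dn", com = c(0, 0, 0), points = list(P = c(0, 0, 0.02)))
  geom <- segment_geometry(cr, ca, c(0, 0, 0.02),
                           ligaments = list(ligament_def("ALL", "midline",
                                                         c("up", "P"),
                                                         c("dn", "P"))))
  expect_error(ligament_kinematics(geom, geom$ligaments[[1]], pose()),
               "zero-length")
})
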
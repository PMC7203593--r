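#' Configuration of the synthetic-data generator
#'
#' Controls the non-anatomical but mechanically plausible geometries and the
#' experiment-shaped tables the generator emits. Defaults are the study
#' conditions of the emulated protocols: the six-torque pure-moment set with
#' noise-free mean ROM, experimental ranges at +/- 15 percent of the mean
#' (floored at 0.1 deg), and intradiscal-pressure standard deviations of 10
#' percent of the mean (floored at 0.02 MPa).
#'
#' @param seed integer seed; every random draw of the generator derives from
#'   it, so equal seeds give identical geometries and tables.
#' @param noise_rom_deg standard deviation (deg) of Gaussian noise added to
#'   simulated mean ROM values.
#' @param range_halfwidth_frac fractional half-width of the min/max range
#'   around the mean ROM.
#' @param disk_height disk-centre to centre-of-mass spacing scale (m); the
#'   centres of mass of adjacent vertebrae sit `2 * disk_height` apart.
#' @param jitter_mm uniform insertion-point jitter amplitude (mm); bilateral
#'   structures stay exactly mirror-symmetric.
#' @param facet_gap_mm neutral-pose clearance between facet probe points and
#'   the opposing surface (mm).
#' @param csa disk cross-sectional area (m^2).
#' @param noise_idp_mpa standard deviation (MPa) of noise on simulated mean
#'   IDP.
#' @param idp_sd_frac,idp_sd_floor_mpa reported IDP standard deviation:
#'   `max(idp_sd_floor_mpa, idp_sd_frac * mean)`.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, noise_rom_deg = 0,
                         range_halfwidth_frac = 0.15,
                         disk_height = 0.02, jitter_mm = 0.5,
                         facet_gap_mm = 0.5, csa = 1.8e-3,
                         noise_idp_mpa = 0, idp_sd_frac = 0.10,
                         idp_sd_floor_mpa = 0.02) {
  stopifnot(noise_rom_deg >= 0, range_halfwidth_frac >= 0, csa > 0,
            disk_height > 0)
  structure(list(seed = as.integer(seed), noise_rom_deg = noise_rom_deg,
                 range_halfwidth_frac = range_halfwidth_frac,
                 disk_height = disk_height, jitter_mm = jitter_mm,
                 facet_gap_mm = facet_gap_mm, csa = csa,
                 noise_idp_mpa = noise_idp_mpa, idp_sd_frac = idp_sd_frac,
                 idp_sd_floor_mpa = idp_sd_floor_mpa),
            class = "synth_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample nine facet landmarks from a convex ellipsoid-like patch (mm) plus a
# small antisymmetric cubic term so the cubic coefficients are exercised
synth_facet_landmarks <- function(jitter_sd_mm = 0.08) {
  g <- expand.grid(x = c(-3, 0, 3), y = c(-2.5, 0, 2.5))
  f <- -0.16 * g$x^2 - 0.19 * g$y^2 - 0.006 * g$x^3 - 0.004 * g$y^3 +
    stats::rnorm(9, sd = jitter_sd_mm)
  cbind(g$x, g$y, f)
}

# one synthetic motion segment spanning z0 .. z0 + 4*h/2 (caudal com at z0)
synth_segment <- function(cfg, cranial_name, caudal_name, z0) {
  h <- cfg$disk_height
  j <- cfg$jitter_mm / 1000
  jit <- function() stats::runif(1, -j, j)
  dc <- c(0, 0, z0 + h)

  # midline insertion layout (y positive = dorsal); per-ligament jitter is
  # shared by the two insertions so cords stay near-vertical
  mid <- list(ALL = c(-0.025, 0.010), PLL = c(0.020, 0.010),
              FL = c(0.035, 0.010), ISL = c(0.055, 0.008),
              SSL = c(0.070, 0.008))
  pts_cr <- list()
  pts_ca <- list()
  for (nm in names(mid)) {
    dy <- jit(); dz <- jit()
    y <- mid[[nm]][1] + dy
    zoff <- mid[[nm]][2] + dz
    pts_cr[[nm]] <- c(0, y, z0 + 2 * h - zoff)   # mirrored about the disk centre
    pts_ca[[nm]] <- c(0, y, z0 + zoff)
  }
  # bilateral pairs, exactly mirrored in x
  bil <- list(CL = c(0.025, 0.030, 0.012), ITL = c(0.040, 0.015, 0.010))
  for (nm in names(bil)) {
    dy <- jit(); dz <- jit()
    xo <- bil[[nm]][1]
    y <- bil[[nm]][2] + dy
    zoff <- bil[[nm]][3] + dz
    for (side in c("left", "right")) {
      sx <- if (side == "left") xo else -xo
      pts_cr[[paste(nm, side, sep = "_")]] <- c(sx, y, z0 + 2 * h - zoff)
      pts_ca[[paste(nm, side, sep = "_")]] <- c(sx, y, z0 + zoff)
    }
  }

  prestrains <- c(ALL = 8, PLL = 10, FL = 10, ITL = 10, CL = 10, ISL = 4,
                  SSL = -6)
  ligs <- list()
  for (nm in c("ALL", "PLL", "FL", "ISL", "SSL")) {
    ligs[[length(ligs) + 1L]] <- ligament_def(
      nm, "midline", c(cranial_name, nm), c(caudal_name, nm),
      prestrain = prestrains[[nm]])
  }
  for (nm in c("CL", "ITL")) {
    for (side in c("left", "right")) {
      lab <- paste(nm, side, sep = "_")
      ligs[[length(ligs) + 1L]] <- ligament_def(
        nm, side, c(cranial_name, lab), c(caudal_name, lab),
        prestrain = prestrains[[nm]])
    }
  }

  # facet joints: origin lateral-dorsal at disk-centre height; the local
  # normal (third frame axis) mixes lateral and cranial components so that
  # extension, lateral bending and axial rotation all produce contact
  # one landmark draw, mirrored exactly onto the right side so the segment is
  # sagittally symmetric (the mirror flips the local x coordinate, hence the
  # sign of the fitted p30 coefficient)
  sup_pts <- synth_facet_landmarks()
  inf_pts <- synth_facet_landmarks()
  facets <- list()
  for (side in c("left", "right")) {
    sx <- if (side == "left") 1 else -1
    origin <- c(sx * 0.022, 0.032, z0 + h)
    e3 <- c(sx * 0.8, 0, 0.6)                # outward-cranial surface normal
    e1 <- c(0.6, 0, -0.8 * sx)               # in-plane, x-z
    e2 <- cross3(e3, e1)
    E <- cbind(e1, e2, e3)
    mirror_x <- function(p) if (sx == 1) p else p * c(-1, 1, 1)
    sup <- facet_landmarks(t(apply(sup_pts, 1, mirror_x)),
                           frame = list(origin = origin, axes = E))
    inf <- facet_landmarks(t(apply(inf_pts, 1, mirror_x)),
                           frame = list(origin = origin, axes = E))
    fs <- fit_facet_surface(sup, inf, stiffness = 12000, damping = 4000)
    # probe points on the cranial (inferior) process, offset by the neutral
    # clearance along the local normal direction
    pxy <- rbind(c(0, 0), c(1.5, 1.0), c(-1.5, -1.0))
    probes <- t(apply(pxy, 1, function(p) {
      p <- if (sx == 1) p else c(-p[1], p[2])
      zloc <- eval_facet_poly(fs$coef, p[1], p[2]) + cfg$facet_gap_mm
      origin + as.numeric(E %*% (c(p[1], p[2], zloc) / 1000))
    }))
    fs$probe_points <- probes
    facets[[side]] <- fs
  }

  cranial <- rigid_body(cranial_name, com = c(0, 0, z0 + 2 * h),
                        points = pts_cr)
  caudal <- rigid_body(caudal_name, com = c(0, 0, z0), points = pts_ca)
  segment_geometry(cranial, caudal, disk_centre = dc, ligaments = ligs,
                   facets = facets, csa = cfg$csa)
}

#' Generate a synthetic functional spinal unit
#'
#' Builds a non-anatomical but scale-plausible two-vertebra motion segment:
#' midline and bilateral ligament insertions around a 20 mm disk, facet
#' surfaces fitted to landmarks sampled from a convex ellipsoid-like patch,
#' and standard prestrains. Deterministic given the seed; bilateral
#' structures are exactly mirror-symmetric across the sagittal plane.
#'
#' @param cfg a [synth_config()].
#' @param cranial_name,caudal_name body labels.
#' @return A [segment_geometry()].
#' @export
make_synthetic_fsu <- function(cfg = synth_config(), cranial_name = "L4",
                               caudal_name = "L5") {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, synth_segment(cfg, cranial_name, caudal_name, z0 = 0))
}

#' Muscle group labels of the intradiscal-pressure protocol
#'
#' @return Character vector of the five cable-pair groups.
#' @export
muscle_groups <- function() {
  c("multifidus_caudal", "iliocostalis_longissimus", "psoas_corpus",
    "psoas_transversus", "multifidus_cranial")
}

#' Generate a synthetic lumbar spine chain
#'
#' Stacks four synthetic motion segments (L2 to S1, sacrum fixed) and attaches
#' five mirror-symmetric muscle cable pairs (40 N per cable) to the topmost
#' vertebra. Cable directions are fixed unit vectors approximating the
#' emulated experimental groups (caudal/cranial multifidus, erector spinae,
#' two psoas lines); they are explicitly non-anatomical placeholders.
#'
#' @param cfg a [synth_config()].
#' @return A [spine_geometry()].
#' @export
make_synthetic_spine <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  names <- c("L2", "L3", "L4", "L5", "S1")
  h2 <- 2 * cfg$disk_height
  segments <- list()
  for (i in 1:4) {
    seg_cfg <- cfg
    segments[[i]] <- with_seed(
      cfg$seed * 10L + i,
      synth_segment(seg_cfg, names[i], names[i + 1], z0 = h2 * (4 - i)))
  }
  bodies <- c(lapply(1:4, function(i) segments[[i]]$cranial),
              list(segments[[4]]$caudal))
  coms <- lapply(bodies, `[[`, "com")
  names(coms) <- names
  unit <- function(v) v / sqrt(sum(v^2))
  # Placeholder cable geometry (the emulated experiment guides its wire
  # cables along the spine, so the 80 N pairs act like follower loads and
  # never buckle the specimen): attachments are spread over the lumbar
  # vertebrae, near each vertebra's caudal end, which keeps the dead-load
  # destabilising stiffness of every disk below its lateral restoring
  # stiffness. All groups still load the L4-L5 disk.
  defs <- list(
    multifidus_caudal = list(body = "L4", p = c(0.020, 0.045, -0.020),
                             d = unit(c(0, 0.2, -0.98))),
    iliocostalis_longissimus = list(body = "L3", p = c(0.030, 0.035, -0.020),
                                    d = unit(c(0, 0.1, -0.995))),
    psoas_corpus = list(body = "L4", p = c(0.015, -0.020, -0.020),
                        d = unit(c(0, -0.15, -0.99))),
    psoas_transversus = list(body = "L4", p = c(0.035, 0.010, -0.020),
                             d = unit(c(0, -0.1, -0.99))),
    multifidus_cranial = list(body = "L4", p = c(0.020, 0.045, -0.020),
                              d = unit(c(0, 0.2, 0.98)))
  )
  muscles <- list()
  for (g in names(defs)) {
    for (s in c(1, -1)) {
      p <- defs[[g]]$p
      muscles[[length(muscles) + 1L]] <- muscle_cable(
        body = defs[[g]]$body,
        point = coms[[defs[[g]]$body]] + c(s * p[1], p[2], p[3]),
        direction = defs[[g]]$d, force = 40, group = g)
    }
  }
  spine_geometry(bodies, segments, muscles)
}

#' Simulate a stepwise-reduction ROM table from a ground-truth model
#'
#' Runs the full forward stepwise-reduction protocol on the ground-truth
#' characteristics, then shapes the result like the experimental data set:
#' seeded Gaussian noise on the mean ROM (SD `cfg$noise_rom_deg`) and a
#' min-to-max range of half-width `max(0.1 deg, range_halfwidth_frac * mean)`;
#' 0 Nm rows carry no range.
#'
#' @param geom a [segment_geometry()].
#' @param ground_truth a characteristic set (e.g.
#'   [default_characteristics()]).
#' @param cfg a [synth_config()].
#' @return A ROM table tibble: `stage`, `direction`, `torque_nm`,
#'   `rom_mean_deg`, `rom_min_deg`, `rom_max_deg`.
#' @export
simulate_eds1 <- function(geom, ground_truth = default_characteristics(),
                          cfg = synth_config()) {
  sim <- run_stepwise_forward(ground_truth, geom)
  if (any(!sim$converged)) {
    bad <- sim[!sim$converged, ]
    stop(sprintf("simulate_eds1(): %d scenarios failed to converge (first: %s %s %.3g Nm)",
                 nrow(bad), bad$stage[1], bad$direction[1], bad$torque_nm[1]),
         call. = FALSE)
  }
  with_seed(cfg$seed + 1000L, {
    noise <- stats::rnorm(nrow(sim), sd = cfg$noise_rom_deg)
    mean_rom <- sim$rom_deg + ifelse(sim$torque_nm > 0, noise, 0)
    half <- pmax(0.1, cfg$range_halfwidth_frac * abs(mean_rom))
    tibble::tibble(
      stage = sim$stage, direction = sim$direction,
      torque_nm = sim$torque_nm,
      rom_mean_deg = mean_rom,
      rom_min_deg = ifelse(sim$torque_nm > 0, mean_rom - half, NA_real_),
      rom_max_deg = ifelse(sim$torque_nm > 0, mean_rom + half, NA_real_))
  })
}

#' Simulate an intradiscal-pressure table from a ground-truth model
#'
#' Runs the 49-scenario IDP protocol on the ground-truth characteristics and
#' shapes the result like the experimental table: per-record mean (plus
#' optional seeded noise) and standard deviation
#' `max(idp_sd_floor_mpa, idp_sd_frac * mean)`.
#'
#' @param spine a [spine_geometry()].
#' @param ground_truth a characteristic set.
#' @param cfg a [synth_config()].
#' @return An IDP table tibble: `muscle_config`, `load_case`, `idp_mean_mpa`,
#'   `idp_sd_mpa`.
#' @export
simulate_eds2 <- function(spine, ground_truth = default_characteristics(),
                          cfg = synth_config()) {
  sim <- run_idp_protocol(spine, ground_truth)
  with_seed(cfg$seed + 2000L, {
    noise <- stats::rnorm(nrow(sim), sd = cfg$noise_idp_mpa)
    m <- sim$idp_mpa + noise
    tibble::tibble(
      muscle_config = sim$muscle_config, load_case = sim$load_case,
      idp_mean_mpa = m,
      idp_sd_mpa = pmax(cfg$idp_sd_floor_mpa, cfg$idp_sd_frac * abs(m)))
  })
}
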
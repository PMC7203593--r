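# Backward stepwise-reduction calibration.
#
# The reduction experiment is rolled backward: the most-reduced stage (disk
# only) yields the disk torque-angle points directly; every later stage adds
# exactly one element on top of an already-calibrated partial model, and the
# torque that the known elements cannot supply at the measured ROM (the
# deficit) is attributed to the new element. Because the new element also
# changes the stage's neutral pose and the free degrees of freedom, its
# current characteristic estimate is included in all equilibrium solves and
# the extract-fit cycle is iterated to a fixed point.

#' Extract disk torque-angle points from the disk-only stage
#'
#' In the most-reduced stage only the disk transmits moments, so each record
#' directly yields the point (rotation = mean ROM in radians, torque =
#' applied torque). Flexion and extension are kept as separate point sets;
#' lateral flexion and axial rotation are pooled over both signs by oddness
#' of their characteristic. The origin (0, 0) is appended to every set.
#'
#' @param rom ROM table ([simulate_eds1()] layout) containing the `wo_ALL`
#'   stage.
#' @return Tibble with columns `direction`, `phi_rad`, `torque_nm`, `stage`.
#' @export
extract_disk_points <- function(rom) {
  if (!("wo_ALL" %in% rom$stage)) {
    stop("extract_disk_points(): ROM table lacks the disk-only stage 'wo_ALL'",
         call. = FALSE)
  }
  sub <- dplyr::filter(rom, .data$stage == "wo_ALL", .data$torque_nm > 0)
  pts <- tibble::tibble(direction = sub$direction,
                        phi_rad = abs(sub$rom_mean_deg) * pi / 180,
                        torque_nm = sub$torque_nm, stage = "wo_ALL")
  origin <- tidyr::expand_grid(direction = unique(pts$direction),
                               phi_rad = 0, torque_nm = 0, stage = "wo_ALL")
  dplyr::arrange(dplyr::bind_rows(pts, origin), .data$direction,
                 .data$phi_rad)
}

#' Fit the tanh-cubic disk torque-angle law to points
#'
#' Least-squares fit of `T(phi) = p1 tanh(phi^3 / p2) + p3 phi` by
#' Levenberg-Marquardt with a multi-start over initializations
#' (`p1 in {1, 5, 20}`, `p2 in {1e-3, 1e-2}`, `p3 in {-5, 1, 20}`); the best
#' residual wins.
#'
#' @param points tibble with `phi_rad`, `torque_nm` (>= 4 points, distinct
#'   abscissae).
#' @param direction direction label carried into the result.
#' @param start optional single start `c(p1, p2, p3)` replacing the
#'   multi-start grid.
#' @return Object of class `"disk_fit"`: `p1`, `p2`, `p3`, `rmse` (Nm), `n`.
#' @export
fit_disk_characteristic <- function(points, direction = "flexion",
                                    start = NULL) {
  phi <- points$phi_rad
  tq <- points$torque_nm
  if (length(unique(phi)) < 4) {
    stop("fit_disk_characteristic(): need >= 4 points with distinct angles",
         call. = FALSE)
  }
  resid <- function(p) {
    if (p[2] == 0 || !all(is.finite(p))) return(rep(1e6, length(phi)))
    tq - (p[1] * tanh(phi^3 / p[2]) + p[3] * phi)
  }
  starts <- if (!is.null(start)) list(start) else {
    g <- expand.grid(p1 = c(1, 5, 20), p2 = c(1e-3, 1e-2), p3 = c(-5, 1, 20))
    lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(resid(fit$par)^2))
    if (is.null(best) || rmse < best$rmse) {
      best <- list(par = fit$par, rmse = rmse)
    }
  }
  if (is.null(best)) {
    stop("fit_disk_characteristic(): all starts failed", call. = FALSE)
  }
  # canonical sign convention: (p1, p2) and (-p1, -p2) describe the same
  # curve because tanh is odd; report the positive-p2 representative
  if (best$par[2] < 0) best$par[1:2] <- -best$par[1:2]
  structure(list(direction = direction, p1 = best$par[1], p2 = best$par[2],
                 p3 = best$par[3], rmse = best$rmse, n = length(phi)),
            class = "disk_fit")
}

#' @export
print.disk_fit <- function(x, ...) {
  cat(sprintf("<disk_fit> %s: p1 = %.4g, p2 = %.4g, p3 = %.4g (rmse %.3g Nm, n = %d)\n",
              x$direction, signif(x$p1, 4), signif(x$p2, 4), signif(x$p3, 4),
              x$rmse, x$n))
  invisible(x)
}

#' Fit the softplus ligament force-strain law to points
#'
#' Levenberg-Marquardt least squares of
#' `F = a ln(exp((eps + b)/d) + 1) + c` with a multi-start over
#' initializations including negative-`d` starts (required for concave
#' characteristics). When two starts tie within 1e-6 N RMSE but disagree in
#' parameters, the smaller-`|b|` solution is reported. Point sets whose
#' forces never exceed 0.5 N yield the zero-force curve with a warning.
#'
#' @param points tibble with `strain_pct`, `force_n`; at least 5 points
#'   spanning at least 5 percent strain.
#' @param start optional single start `c(a, b, c, d)` replacing the grid.
#' @param weights optional per-point weights (e.g. moment-arm magnitudes
#'   during calibration, where small arms amplify pose error into force
#'   error); normalised internally.
#' @param extra_starts optional list of additional start vectors appended to
#'   the grid.
#' @return Object of class `"ligament_fit"`: `a`, `b`, `c`, `d`, `rmse` (N),
#'   `n`, and `char` (a [ligament_characteristic()]).
#' @export
fit_ligament_characteristic <- function(points, start = NULL, weights = NULL,
                                        extra_starts = NULL) {
  eps <- points$strain_pct
  ff <- points$force_n
  w <- if (is.null(weights)) rep(1, length(eps)) else weights / max(weights)
  if (length(eps) < 5) {
    stop("fit_ligament_characteristic(): need >= 5 points", call. = FALSE)
  }
  if (diff(range(eps)) < 5) {
    stop("fit_ligament_characteristic(): points span < 5 percent strain",
         call. = FALSE)
  }
  if (max(abs(ff)) < 0.5) {
    warning("fit_ligament_characteristic(): all forces near zero; returning the zero curve",
            call. = FALSE)
    return(structure(list(a = 0, b = 0, c = 0, d = 1, rmse = sqrt(mean(ff^2)),
                          n = length(eps),
                          char = zero_ligament_characteristic()),
                     class = "ligament_fit"))
  }
  resid <- function(p) {
    if (p[4] == 0 || !all(is.finite(p))) return(rep(1e6, length(eps)))
    w * (ff - softplus_force(eps, p[1], p[2], p[3], p[4]))
  }
  starts <- if (!is.null(start)) list(start) else {
    fmax <- max(ff)
    slope <- (max(ff) - min(ff)) / diff(range(eps))
    g <- expand.grid(a = c(fmax, 10 * slope, 1),
                     b = c(-stats::median(eps), 0, 10),
                     c = c(0, min(ff)),
                     d = c(0.05, 1, 10, -10))
    c(lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ])),
      extra_starts)
  }
  fits <- list()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit) || fit$par[4] == 0) next
    fits[[length(fits) + 1L]] <- list(
      par = fit$par, rmse = sqrt(sum(resid(fit$par)^2) / sum(w^2)))
  }
  if (length(fits) == 0) {
    stop("fit_ligament_characteristic(): all starts failed", call. = FALSE)
  }
  rmses <- vapply(fits, `[[`, numeric(1), "rmse")
  near <- fits[rmses <= min(rmses) + 1e-6]
  pick <- near[[which.min(vapply(near, function(f) abs(f$par[2]),
                                 numeric(1)))]]
  p <- pick$par
  structure(list(a = p[1], b = p[2], c = p[3], d = p[4], rmse = pick$rmse,
                 n = length(eps),
                 char = ligament_characteristic(p[1], p[2], p[3], p[4])),
            class = "ligament_fit")
}

#' @export
print.ligament_fit <- function(x, ...) {
  cat(sprintf("<ligament_fit> a = %.4g, b = %.4g, c = %.4g, d = %.4g (rmse %.3g N, n = %d)\n",
              signif(x$a, 4), signif(x$b, 4), signif(x$c, 4), signif(x$d, 4),
              x$rmse, x$n))
  invisible(x)
}

# ---- constrained stage equilibria -------------------------------------------

# Solve the stage equilibrium with the loading-axis rotation of the mobile
# vertebra clamped to `target` (rad); remaining five DOFs equilibrate freely.
constrained_solve <- function(model, load, axis, target, x0,
                              ctl = solver_control()) {
  fix <- stats::setNames(target, as.character(3L + axis))
  res <- solve_state(model, load, x0, fix = fix, ctl = ctl)
  if (!res$converged) {
    # retry from the undeformed state with only the clamped DOF set
    res <- solve_state(model, load, numeric(model$n_dof), fix = fix,
                       ctl = ctl)
  }
  if (!res$converged) {
    stop(sprintf(
      "constrained stage solve failed (%s, %.3g Nm, target %.4g rad)",
      load$direction, load$torque_nm, target), call. = FALSE)
  }
  res
}

record_targets <- function(rom, stage) {
  sub <- dplyr::filter(rom, .data$stage == !!stage, .data$torque_nm > 0)
  if (nrow(sub) == 0) {
    stop(sprintf("ROM table has no loaded records for stage '%s'", stage),
         call. = FALSE)
  }
  dplyr::arrange(sub, .data$direction, .data$torque_nm)
}

stage_neutral <- function(model, x0 = NULL, ctl = solver_control(),
                          fix = NULL) {
  res <- solve_state(model, load_case("neutral"),
                     if (is.null(x0)) numeric(model$n_dof) else x0,
                     fix = fix, ctl = ctl)
  if (!res$converged) {
    stop(sprintf("neutral solve failed at stage %s", model$stage),
         call. = FALSE)
  }
  res$x
}

# Sagittal side on which a ligament goes slack: the sign of its sagittal
# moment arm at the identity pose (a tension torque +x resists extension,
# hence the cord slackens in flexion, and vice versa).
slack_sign_of <- function(geom, defs) {
  arms <- vapply(defs, function(l) {
    ligament_kinematics(geom, l, pose())$moment_arm[["x"]]
  }, numeric(1))
  if (mean(arms) >= 0) 1 else -1
}

# Anchor the stage's sagittal neutral angle on the records in which the new
# element is slack: there the stage model (known elements plus the current
# estimate of the new element, which contributes little on its slack side)
# must reproduce the recorded ROM, so each unconstrained equilibrium yields
# an estimate of the absolute neutral angle. Torque-weighted mean, because
# high-torque records are deepest into the slack region and therefore least
# sensitive to the current estimate.
estimate_neutral_offset <- function(model, recs, slack_sign,
                                    ctl = solver_control()) {
  dir <- if (slack_sign > 0) "flexion" else "extension"
  sub <- recs[recs$direction == dir, , drop = FALSE]
  if (nrow(sub) == 0) return(0)
  deltas <- numeric(0)
  wts <- numeric(0)
  x <- numeric(model$n_dof)
  for (i in order(sub$torque_nm)) {
    res <- tryCatch(
      solve_equilibrium(model, load_case(dir, sub$torque_nm[i]), init = x,
                        control = ctl),
      error = function(e) NULL)
    if (is.null(res)) next
    x <- res$state
    deltas <- c(deltas, x[4] - slack_sign * sub$rom_mean_deg[i] * pi / 180)
    wts <- c(wts, sub$torque_nm[i])
  }
  if (length(deltas) == 0) return(0)
  # median across records: robust against the occasional record that lands
  # near the flexion row's torque saturation, where the angle is extremely
  # sensitive to noise in the fitted disk row. Clamped to a physiological
  # window (single-segment neutral tilts beyond ~11 degrees would mean a
  # runaway intermediate estimate, not anatomy).
  max(-0.2, min(0.2, stats::median(deltas)))
}

#' Extract facet contact stiffness from the capsule-free stage
#'
#' In the stage where the capsular ligaments have just been removed, the
#' partial model (disk, anterior/posterior longitudinal ligaments) plus bony
#' facet contact carries the load. For every record in which the facets
#' engage, the mobile vertebra is clamped at the measured ROM, the free
#' degrees of freedom are equilibrated, and the deficit moment about the
#' loading axis is attributed to facet contact; dividing by the facet moment
#' per unit stiffness at that pose gives a per-record stiffness sample. The
#' returned stiffness is the least-squares scalar over all engaging samples.
#' Because the contact state feeds back on the free-DOF equilibria, the
#' estimate is iterated to a fixed point.
#'
#' @param rom ROM table containing the `wo_CL` stage.
#' @param geom the segment geometry.
#' @param chars partial characteristic set with calibrated disk and
#'   longitudinal ligaments.
#' @param control solver control overrides.
#' @return List with `stiffness` (N/m), `samples` (tibble: direction, torque,
#'   per-record stiffness sample) and `iterations`.
#' @export
extract_facet_stiffness <- function(rom, geom, chars, control = list()) {
  if (!("wo_CL" %in% rom$stage)) {
    stop("extract_facet_stiffness(): ROM table lacks stage 'wo_CL'",
         call. = FALSE)
  }
  ctl <- solver_control(control)
  recs <- record_targets(rom, "wo_CL")
  k_est <- 0
  samples <- NULL
  delta <- NULL
  for (iter in 1:5) {
    ch <- chars
    ch$facets$stiffness <- k_est
    model <- build_model(geom, ch, stage = "wo_CL")
    ch1 <- chars
    ch1$facets$stiffness <- 1
    model_unit <- build_model(geom, ch1, stage = "wo_CL")
    # facet contact disengages in flexion; anchor the sagittal neutral there,
    # then refine it by the scalar-stiffness misfit (the contact geometry is
    # sensitive to the neutral at the fraction-of-a-millimetre level, so the
    # anchor alone is not accurate enough on noisy tables)
    d0 <- estimate_neutral_offset(model, recs, 1, ctl)
    if (is.null(delta) || abs(d0 - delta) > 1e-3 || iter <= 2) {
      cost <- function(dd) {
        sw <- tryCatch(
          facet_sweep(model, model_unit, recs, dd, ctl),
          error = function(e) NULL)
        if (is.null(sw)) return(1e6)
        eng <- sw[sw$engaged, , drop = FALSE]
        # non-contact records (flexion opens the joint) must balance with
        # the known elements alone: their deficits pin the neutral angle
        # independently of the stiffness scale, breaking the
        # neutral/stiffness ridge
        free <- sw[!sw$engaged, , drop = FALSE]
        pen <- if (nrow(free) > 0) sum(free$deficit_nm^2) else 0
        if (nrow(eng) < 3) return(1e3 + pen)
        k <- sum(eng$deficit_nm * eng$arm) / sum(eng$arm^2)
        sum((eng$deficit_nm - k * eng$arm)^2) + pen +
          if (k < 0) k^2 else 0
      }
      opt <- stats::optimize(cost, interval = c(d0 - 0.03, d0 + 0.03),
                             tol = 1e-4)
      delta <- if (cost(d0) <= opt$objective) d0 else opt$minimum
    }
    samples <- facet_sweep(model, model_unit, recs, delta, ctl)
    samples <- samples[samples$engaged, , drop = FALSE]
    if (nrow(samples) == 0) {
      warning("extract_facet_stiffness(): facets never engage; stiffness 0",
              call. = FALSE)
      return(list(stiffness = 0, samples = samples, iterations = iter))
    }
    k_new <- sum(samples$deficit_nm * samples$arm) / sum(samples$arm^2)
    done <- abs(k_new - k_est) < 1e-3 * max(abs(k_new), 1)
    k_est <- k_new
    if (done) break
  }
  list(stiffness = k_est, samples = samples, iterations = iter,
       neutral_rad = delta)
}

# constrained sweep of the capsule-free stage at a given sagittal neutral:
# per engaging record, the deficit moment and the facet moment per unit
# stiffness at the clamped pose
facet_sweep <- function(model, model_unit, recs, delta, ctl) {
  x_n <- stage_neutral(model, {
    x0 <- numeric(model$n_dof); x0[4] <- delta; x0
  }, ctl = ctl, fix = stats::setNames(delta, "4"))
  rows <- list()
  x_warm <- x_n
  last_dir <- ""
  for (i in seq_len(nrow(recs))) {
    d <- recs$direction[i]
    ax <- load_axis(d)
    if (d != last_dir) { x_warm <- x_n; last_dir <- d }
    target <- x_n[3L + ax$axis] + ax$sign * recs$rom_mean_deg[i] * pi / 180
    load <- load_case(d, recs$torque_nm[i])
    sol <- tryCatch(
      constrained_solve(model, load, ax$axis, target, x_warm, ctl),
      error = function(e) NULL)
    if (is.null(sol)) next
    x_warm <- sol$x
    r_wo <- residual_fun(model, sol$x, load, about = "joint",
                         exclude = list(type = "facets", segment = 1L))
    tau_needed <- -r_wo[3L + ax$axis]
    r_u1 <- residual_fun(model_unit, sol$x, load, about = "joint")
    r_u0 <- residual_fun(model_unit, sol$x, load, about = "joint",
                         exclude = list(type = "facets", segment = 1L))
    m1 <- (r_u1 - r_u0)[3L + ax$axis]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      direction = d, torque_nm = recs$torque_nm[i],
      deficit_nm = tau_needed, arm = m1,
      sample = if (abs(m1) > 1e-6) tau_needed / m1 else NA_real_,
      engaged = abs(m1) > 1e-6)
  }
  dplyr::bind_rows(rows)
}

#' Extract force-strain points for one ligament from its first stage
#'
#' For each loaded record of the stage in which `ligament` first appears, the
#' loading-axis rotation is clamped at the measured ROM (relative to the
#' stage's sagittal neutral angle), the free degrees of freedom are
#' equilibrated with all known elements plus the current estimate of the new
#' ligament, and the deficit moment about the loading axis (taken about the
#' disk centre) is converted to a ligament tension through the moment arm
#' from [ligament_kinematics()]. Bilateral pairs split a symmetric-load
#' deficit equally; in lateral/axial loading the strained side receives it.
#' Records with a moment arm below 1 mm or a negative required tension are
#' skipped.
#'
#' The stage's sagittal neutral angle is not observable directly (ROM is
#' recorded relative to it), so it is estimated in two steps: records on the
#' ligament's slack side anchor it (there the partial model alone must
#' reproduce the ROM), and a one-dimensional refinement then minimises the
#' arm-weighted misfit of the softplus family, which also covers
#' characteristics that never go slack. The extract-fit cycle is iterated to
#' a fixed point.
#'
#' @param rom ROM table.
#' @param stage the first stage containing the ligament.
#' @param ligament ligament name.
#' @param geom segment geometry.
#' @param chars partial characteristic set covering all other elements of the
#'   stage.
#' @param control solver control overrides.
#' @param max_outer maximum extract-fit iterations.
#' @return List with `points` (tibble: `strain_pct`, `force_n`, `side`,
#'   `arm_m`, `direction`, `torque_nm`, `stage`), `fit` (a `"ligament_fit"`
#'   or `NULL`), `neutral_rad` (estimated sagittal neutral angle),
#'   `iterations`.
#' @export
extract_ligament_points <- function(rom, stage, ligament, geom, chars,
                                    control = list(), max_outer = 10L) {
  ctl <- solver_control(control)
  recs <- record_targets(rom, stage)
  defs <- Filter(function(l) l$name == ligament, geom$ligaments)
  if (length(defs) == 0) {
    stop(sprintf("geometry has no ligament '%s'", ligament), call. = FALSE)
  }
  slack_sign <- slack_sign_of(geom, defs)
  char_est <- zero_ligament_characteristic()
  fit <- NULL
  pts <- NULL
  delta <- NULL
  sag_recs <- recs[recs$direction %in% c("flexion", "extension"), ,
                   drop = FALSE]
  for (iter in seq_len(max_outer)) {
    ch <- chars
    ch$ligaments[[ligament]] <- char_est
    model <- build_model(geom, ch, stage = stage)
    # anchor the sagittal neutral on the slack-side records ...
    d0 <- estimate_neutral_offset(model, recs, slack_sign, ctl)
    # ... then refine it against the sagittal records: the neutral and the
    # curve trade off almost freely for characteristics that never go
    # slack, and the refinement resolves the trade-off through the known
    # elements' nonlinearity
    refine <- is.null(delta) || abs(d0 - delta) > 1e-3 || iter <= 4
    if (refine) {
      cost <- function(dd) {
        sw <- tryCatch(
          sweep_stage_points(model, sag_recs, geom, defs, ligament, dd,
                             ctl),
          error = function(e) NULL)
        if (is.null(sw)) return(1e6)
        stage_misfit(sw, char_est)
      }
      opt <- stats::optimize(cost, interval = c(d0 - 0.03, d0 + 0.03),
                             tol = 1e-4)
      delta <- if (cost(d0) <= opt$objective) d0 else opt$minimum
    }
    sw <- sweep_stage_points(model, recs, geom, defs, ligament, delta, ctl)
    pts <- sw$points[sw$points$kept, , drop = FALSE]
    if (nrow(pts) == 0) {
      stop(sprintf(
        "extract_ligament_points(): ligament %s is slack in every record of stage %s",
        ligament, stage), call. = FALSE)
    }
    prev <- if (is.null(fit)) NULL else
      list(c(fit$a, fit$b, fit$c, fit$d))
    fit_new <- tryCatch(
      fit_ligament_characteristic(pts, weights = pts$arm_m,
                                  extra_starts = prev),
      error = function(e) NULL)
    if (is.null(fit_new)) {
      # not enough span yet to fit; keep the current estimate
      break
    }
    delta_f <- max(abs(ligament_spring_force(fit_new$char, pts$strain_pct) -
                         ligament_spring_force(char_est, pts$strain_pct)))
    char_est <- fit_new$char
    fit <- fit_new
    if (delta_f < 0.02) break
  }
  list(points = pts[, setdiff(names(pts), "kept")], fit = fit,
       neutral_rad = delta, iterations = iter)
}

# One full sweep of the stage records at a given sagittal neutral angle:
# constrained solves, deficit attribution, per-side strain/arm bookkeeping.
# Negative-force records are returned with kept = FALSE so the neutral
# refinement can penalise them.
sweep_stage_points <- function(model, recs, geom, defs, ligament, delta,
                               ctl) {
  x_n <- stage_neutral(model, {
    x0 <- numeric(model$n_dof); x0[4] <- delta; x0
  }, ctl = ctl, fix = stats::setNames(delta, "4"))
  stage <- model$stage
  rows <- list()
  x_warm <- x_n
  last_dir <- ""
  for (i in seq_len(nrow(recs))) {
    d <- recs$direction[i]
    ax <- load_axis(d)
    if (d != last_dir) { x_warm <- x_n; last_dir <- d }
    target <- x_n[3L + ax$axis] + ax$sign * recs$rom_mean_deg[i] * pi / 180
    load <- load_case(d, recs$torque_nm[i])
    sol <- tryCatch(
      constrained_solve(model, load, ax$axis, target, x_warm, ctl),
      error = function(e) NULL)
    if (is.null(sol)) next   # record skipped; logged via the point count
    x_warm <- sol$x
    r_wo <- residual_fun(model, sol$x, load, about = "joint",
                         exclude = list(type = "ligament", segment = 1L,
                                        name = ligament))
    tau_needed <- -r_wo[3L + ax$axis]
    ps <- pose(rot = sol$x[4:6], trans = sol$x[1:3])
    kins <- lapply(defs, function(l) ligament_kinematics(geom, l, ps))
    arms <- vapply(kins, function(k) k$moment_arm[[ax$axis]], numeric(1))
    strains <- vapply(kins, `[[`, numeric(1), "strain")
    usable <- abs(arms) >= 1e-3
    if (!any(usable)) next
    emit <- function(s, f) {
      # fit only points whose arm can resolve the deficit: a ~0.1 Nm
      # deficit uncertainty over less than ~8 mm amplifies to tens of
      # newtons of force error (the 1 mm rule below is the hard skip)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        strain_pct = strains[s], force_n = f, side = defs[[s]]$side,
        arm_m = abs(arms[s]), direction = d,
        torque_nm = recs$torque_nm[i], stage = stage,
        kept = f >= 0 && abs(arms[s]) >= 8e-3)
    }
    if (length(defs) == 1L) {
      if (usable[1]) emit(1L, tau_needed / arms[1])
    } else if (ax$axis == 1L) {
      # symmetric sagittal loading: equal split between engaged sides
      for (s in which(usable)) emit(s, (tau_needed / 2) / arms[s])
    } else {
      # asymmetric loading: the strained side receives the deficit
      f_all <- ifelse(usable, tau_needed / arms, NA_real_)
      cand <- which(usable & f_all > 0)
      if (length(cand) > 0) {
        s <- cand[which.max(strains[cand])]
        emit(s, f_all[s])
      } else {
        s <- which(usable)[which.max(strains[usable])]
        emit(s, f_all[s])
      }
    }
  }
  list(points = dplyr::bind_rows(rows))
}

# Arm-weighted misfit of a stage sweep against the softplus family: the best
# multi-start refit residual over the kept points plus a penalty for records
# that would need the cord to push. A single warm start is not enough here:
# on noisy points it can stall on a bad fit and poison the neutral-angle
# search.
stage_misfit <- function(sw, char_est) {
  pts <- sw$points
  kept <- pts[pts$kept, , drop = FALSE]
  neg <- pts[pts$force_n < 0, , drop = FALSE]
  pen <- if (nrow(neg) > 0) sum((neg$arm_m * neg$force_n)^2) else 0
  if (nrow(kept) < 5 || diff(range(kept$strain_pct)) < 5) {
    return(1e3 + pen)
  }
  fit <- tryCatch(
    suppressWarnings(fit_ligament_characteristic(
      kept, weights = kept$arm_m,
      extra_starts = list(c(char_est$a, char_est$b, char_est$c,
                            char_est$d)))),
    error = function(e) NULL)
  if (is.null(fit)) return(1e3 + pen)
  resid <- kept$force_n -
    softplus_force(kept$strain_pct, fit$a, fit$b, fit$c, fit$d)
  sum((kept$arm_m * resid)^2) + pen
}

#' Run the complete backward stepwise-reduction calibration
#'
#' Rolls the reduction experiment backward, from the most-reduced stage to
#' the intact segment: the disk torque-angle law is fitted to the disk-only
#' stage, then the anterior and posterior longitudinal ligaments, the facet
#' contact stiffness, and the capsular, flaval, interspinous and supraspinous
#' ligaments are extracted one per stage, each step refitting and freezing
#' its element before the next. The intertransverse ligament is carried with
#' its prestrain but excluded from calibration (zero-force default) because
#' the reduction protocol never isolates it.
#'
#' @param rom ROM table covering all eight stages.
#' @param geom segment geometry.
#' @param prestrains optional named numeric (percent) overriding the
#'   geometry's ligament prestrains.
#' @param base characteristic set supplying everything the ROM data cannot
#'   identify: the disk's translational springs and damping, ligament damping
#'   factors, facet damping. Defaults to [default_characteristics()].
#' @param control solver control overrides.
#' @return Object of class `c("calibrated_model", "characteristic_set")`:
#'   a characteristic set usable directly in [build_model()], with a
#'   `diagnostics` element carrying per-step points, fits and RMSE.
#' @export
run_backward_calibration <- function(rom, geom, prestrains = NULL,
                                     base = default_characteristics(),
                                     control = list()) {
  missing <- setdiff(rom_stages(), unique(rom$stage))
  if (length(missing) > 0) {
    stop(sprintf("run_backward_calibration(): ROM table lacks stage(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(prestrains)) {
    geom$ligaments <- lapply(geom$ligaments, function(l) {
      if (l$name %in% names(prestrains)) l$prestrain <- prestrains[[l$name]]
      l
    })
  }
  # step 1: disk rotational characteristics from the disk-only stage
  disk_pts <- extract_disk_points(rom)
  disk_fits <- lapply(c("flexion", "extension", "lateral", "axial"),
                      function(d) {
                        fit_disk_characteristic(
                          dplyr::filter(disk_pts, .data$direction == d), d)
                      })
  names(disk_fits) <- c("flexion", "extension", "lateral", "axial")
  chars <- base
  chars$disk <- disk_characteristic(
    rot = lapply(disk_fits, function(f) list(p1 = f$p1, p2 = f$p2,
                                             p3 = f$p3)),
    axial_quad = base$disk$axial_quad, axial_lin = base$disk$axial_lin,
    shear_stiffness = base$disk$shear_stiffness,
    d_damp_tra = base$disk$d_damp_tra, d_damp_rot = base$disk$d_damp_rot)
  chars$ligaments <- list(ITL = base$ligaments$ITL %||%
                            zero_ligament_characteristic())
  chars$facets$stiffness <- 0
  diagnostics <- list(disk_points = disk_pts, disk_fits = disk_fits,
                      ligaments = list(), facet = NULL)

  steps <- list(list(elem = "ALL", stage = "wo_PLL"),
                list(elem = "PLL", stage = "wo_VA"),
                list(elem = "facet", stage = "wo_CL"),
                list(elem = "CL", stage = "wo_FL"),
                list(elem = "FL", stage = "wo_ISL"),
                list(elem = "ISL", stage = "wo_SSL"),
                list(elem = "SSL", stage = "intact"))
  for (st in steps) {
    if (st$elem == "facet") {
      fac <- tryCatch(
        extract_facet_stiffness(rom, geom, chars, control),
        error = function(e) {
          stop(sprintf("calibration failed at stage %s (facets): %s",
                       st$stage, conditionMessage(e)), call. = FALSE)
        })
      chars$facets$stiffness <- fac$stiffness
      diagnostics$facet <- fac
    } else {
      ex <- tryCatch(
        extract_ligament_points(rom, st$stage, st$elem, geom, chars,
                                control),
        error = function(e) {
          stop(sprintf("calibration failed at stage %s (%s): %s",
                       st$stage, st$elem, conditionMessage(e)),
               call. = FALSE)
        })
      chars$ligaments[[st$elem]] <- if (is.null(ex$fit)) {
        zero_ligament_characteristic()
      } else ex$fit$char
      diagnostics$ligaments[[st$elem]] <- ex
    }
  }
  chars$prestrains <- stats::setNames(
    vapply(geom$ligaments, `[[`, numeric(1), "prestrain"),
    vapply(geom$ligaments, `[[`, "", "name"))
  chars$diagnostics <- diagnostics
  class(chars) <- c("calibrated_model", "characteristic_set")
  chars
}

#' @export
print.calibrated_model <- function(x, ...) {
  cat("<calibrated_model>\n")
  print(x$disk)
  cat(sprintf("  facet stiffness %.4g N/m (from %d samples)\n",
              x$facets$stiffness,
              if (!is.null(x$diagnostics$facet)) nrow(x$diagnostics$facet$samples)
              else 0L))
  for (nm in names(x$diagnostics$ligaments)) {
    f <- x$diagnostics$ligaments[[nm]]$fit
    if (is.null(f)) next
    cat(sprintf("  %-4s a = %8.4g  b = %8.4g  c = %8.4g  d = %8.4g  (rmse %.3g N)\n",
                nm, signif(f$a, 4), signif(f$b, 4), signif(f$c, 4),
                signif(f$d, 4), f$rmse))
  }
  invisible(x)
}
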
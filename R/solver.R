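# Quasi-static equilibrium solver: damped Newton with backtracking line
# search and central-difference Jacobian; Levenberg-damped fallback
# (minpack.lm) and kinetic-energy dynamic relaxation on stagnation. Central
# differences matter because the compression-only disk axial spring has a
# one-sided zero-stiffness branch at the contact boundary.

solver_control <- function(control = list()) {
  utils::modifyList(list(
    tol_force = 1e-6,      # N
    tol_torque = 1e-8,     # Nm
    max_iter = 80,
    fd_step = 1e-7,        # rad / m
    max_ramp = 5,
    relax_steps = 5000
  ), control)
}

fd_jacobian <- function(f, x, free, h) {
  r0 <- f(x)
  J <- matrix(0, nrow = length(free), ncol = length(free))
  for (j in seq_along(free)) {
    xp <- x; xm <- x
    xp[free[j]] <- xp[free[j]] + h
    xm[free[j]] <- xm[free[j]] - h
    J[, j] <- (f(xp)[free] - f(xm)[free]) / (2 * h)
  }
  list(J = J, r0 = r0)
}

residual_converged <- function(r, free, ctl) {
  dof_type <- rep(rep(c("t", "r"), each = 3), length.out = length(r))
  ft <- abs(r[free][dof_type[free] == "t"])
  tq <- abs(r[free][dof_type[free] == "r"])
  (length(ft) == 0 || max(ft) < ctl$tol_force) &&
    (length(tq) == 0 || max(tq) < ctl$tol_torque)
}

# weights making N and Nm residual components comparable in norms (the
# convergence tolerances are 1e-6 N and 1e-8 Nm)
residual_weights <- function(n) {
  rep(rep(c(1, 100), each = 3), length.out = n)
}

newton_solve <- function(f, x0, free, ctl) {
  w <- residual_weights(length(x0))[free]
  x <- x0
  r <- f(x)
  if (residual_converged(r, free, ctl)) {
    return(list(x = x, r = r, converged = TRUE, iters = 0L))
  }
  best_norm <- sqrt(sum((w * r[free])^2))
  stall <- 0L
  J <- NULL
  j_age <- 0L
  for (it in seq_len(ctl$max_iter)) {
    # finite-difference Jacobian, reused with Broyden rank-one updates for a
    # few steps (the Jacobian is the dominant cost for chain models)
    if (is.null(J) || j_age >= 5L) {
      J <- fd_jacobian(f, x, free, ctl$fd_step)$J
      j_age <- 0L
    }
    jac <- list(J = J, r0 = r)
    dx <- tryCatch(solve(jac$J, -jac$r0[free]), error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx))) {
      # Marquardt-scaled damped step for (near-)singular Jacobians: the
      # damping is relative to each column's own scale so that soft
      # (rotational) degrees of freedom keep moving
      Jw <- w * jac$J
      JtJ <- crossprod(Jw)
      dg <- pmax(diag(JtJ), 1e-8 * max(diag(JtJ), 1e-300))
      dx <- tryCatch(
        solve(JtJ + 1e-6 * diag(dg, nrow = length(dg)),
              -crossprod(Jw, w * jac$r0[free])),
        error = function(e) NULL)
      if (is.null(dx)) break
      dx <- as.numeric(dx)
    }
    # trust cap: 10 mm / 0.1 rad per iteration keeps the iterate from
    # drifting along zero-stiffness directions (e.g. the tension-free axial
    # branch of the disk, where any separation is force-free)
    dof_type <- rep(rep(c("t", "r"), each = 3), length.out = length(x))[free]
    cap <- max(max(abs(dx[dof_type == "t"]), 0) / 0.01,
               max(abs(dx[dof_type == "r"]), 0) / 0.1, 1)
    dx <- dx / cap
    # backtracking line search on the residual norm
    alpha <- 1
    accepted <- FALSE
    for (ls in 1:30) {
      xt <- x
      xt[free] <- xt[free] + alpha * dx
      rt <- tryCatch(f(xt), error = function(e) NULL)
      if (!is.null(rt) && all(is.finite(rt))) {
        nt <- sqrt(sum((w * rt[free])^2))
        if (nt < best_norm * (1 - 1e-4 * alpha) || nt < 1e-14) {
          s <- alpha * dx
          y <- rt[free] - r[free]
          # Broyden update keeps the reused Jacobian honest between refreshes
          J <- J + ((y - J %*% s) %*% t(s)) / sum(s^2)
          j_age <- if (alpha < 0.5) 5L else j_age + 1L
          x <- xt; r <- rt
          stall <- if (nt > 0.9 * best_norm) stall + 1L else 0L
          best_norm <- nt
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha / 2
    }
    if (!accepted) {
      if (j_age > 0L) { J <- NULL; next }   # retry once with a fresh Jacobian
      break
    }
    if (residual_converged(r, free, ctl)) {
      return(list(x = x, r = r, converged = TRUE, iters = it))
    }
    if (stall >= 15L) break
  }
  list(x = x, r = r, converged = FALSE, iters = ctl$max_iter)
}

lm_polish <- function(f, x0, free, ctl) {
  w <- residual_weights(length(x0))[free]
  fn <- function(xf) {
    x <- x0
    x[free] <- xf
    w * f(x)[free]
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = x0[free], fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 400, ftol = 1e-15, ptol = 1e-15,
                         gtol = 0)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  x <- x0
  x[free] <- fit$par
  list(x = x, r = f(x))
}

# Explicit damped integration of the equations of motion until the kinetic
# energy drops below 1e-9 J; used only when Newton and the Levenberg fallback
# both stagnate (e.g. a start far outside the basin of attraction).
dynamic_relaxation <- function(f, x0, free, ctl) {
  m_tr <- 1          # kg
  m_rot <- 1e-3      # kg m^2
  mass <- rep(rep(c(m_tr, m_rot), each = 3), length.out = length(x0))[free]
  x <- x0
  v <- numeric(length(free))
  # crude stiffness scale from a diagonal probe to pick dt and damping
  kdiag <- vapply(seq_along(free), function(j) {
    xp <- x; xp[free[j]] <- xp[free[j]] + 1e-6
    abs((f(xp)[free[j]] - f(x)[free[j]]) / 1e-6)
  }, numeric(1))
  kmax <- max(kdiag / mass, 1)
  dt <- 0.5 / sqrt(kmax)
  damp <- 2 * sqrt(pmax(kdiag, 1) * mass)
  for (step in seq_len(ctl$relax_steps)) {
    r <- f(x)[free]
    acc <- (r - damp * v) / mass
    v <- v + dt * acc
    x[free] <- x[free] + dt * v
    ke <- 0.5 * sum(mass * v^2)
    if (ke < 1e-9 && max(abs(r)) < 1e3 * ctl$tol_force) break
  }
  x
}

solve_state <- function(model, load, x0, fix = NULL, about = "com",
                        ctl = solver_control()) {
  f <- function(x) residual_fun(model, x, load, about = about)
  free <- seq_len(model$n_dof)
  x <- x0
  if (!is.null(fix)) {
    idx <- as.integer(names(fix))
    x[idx] <- as.numeric(fix)
    free <- setdiff(free, idx)
  }
  res <- newton_solve(f, x, free, ctl)
  if (!res$converged) {
    # homotopy: (i) a small axial tension stiffness regularizes the
    # force-free separation branch of the disk, whose solution manifold
    # stalls Newton; (ii) a smoothed ligament slack clamp removes the
    # slack/taut derivative kink. The smoothed solution then seeds an
    # active-set stage that freezes every piecewise element on its current
    # branch (making the residual smooth), solves, and re-checks branch
    # consistency.
    x_h <- x
    for (mu in c(1e-2, 1e-4)) {
      f_reg <- function(x) residual_fun(model, x, load, about = about,
                                        tension_reg = 1e4, smooth_mu = mu)
      x_h <- newton_solve(f_reg, x_h, free, ctl)$x
    }
    res_h <- active_set_solve(model, load, x_h, free, about, ctl, f)
    if (res_h$converged) {
      res <- res_h
    } else {
      pol <- lm_polish(f, res$x, free, ctl)
      if (!is.null(pol) && residual_converged(pol$r, free, ctl)) {
        res <- list(x = pol$x, r = pol$r, converged = TRUE)
      } else {
        xr <- dynamic_relaxation(f, if (is.null(pol)) res$x else pol$x, free,
                                 ctl)
        res2 <- newton_solve(f, xr, free, ctl)
        if (!res2$converged) {
          pol2 <- lm_polish(f, res2$x, free, ctl)
          if (!is.null(pol2) && residual_converged(pol2$r, free, ctl)) {
            res2 <- list(x = pol2$x, r = pol2$r, converged = TRUE)
          }
        }
        if (res2$converged ||
            sqrt(sum(res2$r[free]^2)) < sqrt(sum(res_h$r[free]^2))) {
          res <- res2
        } else {
          res <- res_h
        }
      }
    }
  }
  res$free <- free
  res
}

# Active-set stage: freeze every piecewise element on its current branch,
# solve the resulting smooth system, and iterate on the branch assignment.
# A branch-consistent solution of the frozen system whose exact residual
# passes the tolerances is an exact equilibrium of the true piecewise model.
active_set_solve <- function(model, load, x, free, about, ctl, f_exact) {
  for (k in 1:6) {
    br <- compute_branches(model, x)
    f_br <- function(x) residual_fun(model, x, load, about = about,
                                     branches = br)
    sol <- newton_solve(f_br, x, free, ctl)
    x <- sol$x
    if (identical(br, compute_branches(model, x))) break
  }
  r <- f_exact(x)
  if (!residual_converged(r, free, ctl)) {
    # branch assignment can cycle when the iterate sits between sagittal
    # basins (the flexion row's shallow negative toe slope makes the
    # zero-rotation point unstable); kick the sagittal rotations into each
    # basin and retry the exact solve
    sag_idx <- intersect(free, 6L * (seq_along(model$mobile) - 1L) + 4L)
    for (kick in c(0.05, -0.05)) {
      x_k <- x
      x_k[sag_idx] <- x_k[sag_idx] + kick
      sol_k <- newton_solve(f_exact, x_k, free, ctl)
      if (sol_k$converged) {
        return(list(x = sol_k$x, r = sol_k$r, converged = TRUE))
      }
    }
  }
  list(x = x, r = r, converged = residual_converged(r, free, ctl))
}

#' Solve the quasi-static equilibrium of a model under a pure moment
#'
#' Finds the pose(s) at which the residual wrench on every mobile body
#' vanishes. The applied moment is ramped in at most five increments with
#' warm starts; each increment is solved by damped Newton iteration with a
#' finite-difference Jacobian, falling back to a Levenberg-damped step and to
#' dynamic relaxation (explicit damped integration until the kinetic energy
#' falls below 1e-9 J) on stagnation. Convergence requires the residual to be
#' below 1e-6 N and 1e-8 Nm per component.
#'
#' @param model an [build_model()] result.
#' @param load a [load_case()].
#' @param init optional initial state: a list of [pose()]s per mobile body or
#'   a bare state vector (warm start). Defaults to the neutral state.
#' @param control optional list overriding solver tolerances
#'   (`tol_force`, `tol_torque`, `max_iter`, `fd_step`, `max_ramp`).
#' @return Object of class `"equilibrium_result"`: `poses` (named list of
#'   [pose()]), `state` (bare vector), `residual_norm` (named: force N,
#'   torque Nm), `converged`, `rom_deg` (per-segment rotation about the
#'   loading axis, degrees, relative to the neutral configuration of the
#'   bodies, not load-referenced), `element_state` tibble.
#' @export
solve_equilibrium <- function(model, load = load_case(), init = NULL,
                              control = list()) {
  stopifnot(inherits(model, "mbs_model"), inherits(load, "load_case"))
  ctl <- solver_control(control)
  x0 <- if (is.null(init)) numeric(model$n_dof) else
    poses_to_state(model, init)
  tmag <- load$torque_nm
  attempt <- function(x, n_ramp) {
    res <- NULL
    for (fr in seq_len(n_ramp) / n_ramp) {
      lc <- load
      lc$moment <- load$moment * fr
      lc$torque_nm <- load$torque_nm * fr
      res <- solve_state(model, lc, x, ctl = ctl)
      x <- res$x
    }
    res
  }
  n_ramp <- if (tmag <= 1 || !is.null(init)) 1L else
    min(ctl$max_ramp, ceiling(tmag / 2.5))
  res <- attempt(x0, n_ramp)
  if (!res$converged && ctl$max_ramp > n_ramp) {
    # retry with a fine warm-started ramp, then from the undeformed state
    res <- attempt(x0, ctl$max_ramp)
    if (!res$converged && !is.null(init)) {
      res <- attempt(numeric(model$n_dof), ctl$max_ramp)
    }
  }
  if (!res$converged) {
    rn <- residual_norms(res$r, model)
    stop(sprintf(
      "solve_equilibrium(): no convergence (stage %s, %s %.3g Nm); residual %.3g N / %.3g Nm",
      model$stage, load$direction, load$torque_nm, rn["force"], rn["torque"]),
      call. = FALSE)
  }
  finalize_result(model, res, load)
}

residual_norms <- function(r, model) {
  m <- matrix(r, nrow = 6)
  c(force = max(abs(m[1:3, , drop = FALSE])),
    torque = max(abs(m[4:6, , drop = FALSE])))
}

finalize_result <- function(model, res, load) {
  rom <- vapply(seq_along(model$segments), function(si) {
    segment_rotation_deg(model, res$x, si, load_axis(load$direction)$axis)
  }, numeric(1))
  structure(list(
    poses = state_to_pose_list(model, res$x),
    state = res$x,
    residual_norm = residual_norms(res$r, model),
    converged = res$converged,
    load = load,
    rom_deg = rom,
    element_state = NULL), class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("<equilibrium_result> %s %.3g Nm | converged: %s | residual %.2g N / %.2g Nm\n",
              x$load$direction, x$load$torque_nm, x$converged,
              x$residual_norm["force"], x$residual_norm["torque"]))
  cat("  segment rotation about loading axis (deg):",
      signif(x$rom_deg, 4), "\n")
  invisible(x)
}

# relative rotation (deg) of a segment's cranial vs caudal body about an axis
segment_rotation_deg <- function(model, x, segment, axis) {
  poses <- state_to_poses(model, x)
  sg <- model$segments[[segment]]
  phi <- matrix_to_rotvec(crossprod(poses[[sg$body_b]]$R,
                                    poses[[sg$body_a]]$R))
  phi[axis] * 180 / pi
}

#' Range of motion of a segment from an equilibrium result
#'
#' Relative rotation of the segment's cranial versus caudal body about the
#' requested axis, in degrees. Protocol drivers subtract the solved 0 Nm
#' (neutral) value of the same stage to obtain the reported ROM.
#'
#' @param res an [solve_equilibrium()] result.
#' @param model the model it was solved on.
#' @param segment segment index (1 = topmost).
#' @param axis 1 (x, flexion/extension), 2 (y, lateral) or 3 (z, axial).
#' @return Rotation in degrees (signed).
#' @export
rom_from_result <- function(res, model, segment = 1L, axis = 1L) {
  stopifnot(inherits(res, "equilibrium_result"))
  segment_rotation_deg(model, res$state, segment, axis)
}
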
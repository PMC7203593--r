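#' Stepwise-reduction stages
#'
#' The eight experimental stages of the stepwise reduction protocol, from the
#' intact segment to the disk-only state, in removal order: supraspinous
#' ligament, interspinous ligament, flaval ligament, capsular ligament,
#' vertebral arches (which eliminates facet contact and the intertransverse
#' ligament), posterior longitudinal ligament, anterior longitudinal ligament.
#'
#' @return Character vector of stage labels, intact first.
#' @export
rom_stages <- function() {
  c("intact", "wo_SSL", "wo_ISL", "wo_FL", "wo_CL", "wo_VA", "wo_PLL",
    "wo_ALL")
}

#' Elements active at a reduction stage
#'
#' @param stage one of [rom_stages()].
#' @return List with `ligaments` (character vector of active ligament names)
#'   and `facets` (logical: is bony facet contact present).
#' @export
stage_elements <- function(stage) {
  stages <- rom_stages()
  stage <- match.arg(stage, stages)
  k <- match(stage, stages)   # 1 = intact ... 8 = wo_ALL
  ligs <- c("ALL", "PLL", "FL", "ITL", "CL", "ISL", "SSL")
  removed <- character(0)
  if (k >= 2) removed <- c(removed, "SSL")
  if (k >= 3) removed <- c(removed, "ISL")
  if (k >= 4) removed <- c(removed, "FL")
  if (k >= 5) removed <- c(removed, "CL")
  if (k >= 6) removed <- c(removed, "ITL")   # arches carry the ITL
  if (k >= 7) removed <- c(removed, "PLL")
  if (k >= 8) removed <- c(removed, "ALL")
  list(ligaments = setdiff(ligs, removed), facets = k < 6)
}

#' Pure-moment load case
#'
#' Spine-tester loading: a pure moment applied to the designated loaded body
#' (the cranial vertebra of a single segment, the topmost vertebra of a
#' chain), with no applied force. Directions map to global axes as flexion =
#' +x, extension = -x, lateral = +y (`lateral_neg` = -y), axial = +z
#' (`axial_neg` = -z).
#'
#' @param direction one of `"neutral"`, `"flexion"`, `"extension"`,
#'   `"lateral"`, `"lateral_neg"`, `"axial"`, `"axial_neg"`.
#' @param torque_nm applied moment magnitude, Nm (>= 0).
#' @param muscles character vector of active muscle group labels.
#' @return Object of class `"load_case"` with the moment vector in `moment`.
#' @export
load_case <- function(direction = "neutral", torque_nm = 0,
                      muscles = character(0)) {
  direction <- match.arg(direction, c("neutral", "flexion", "extension",
                                      "lateral", "lateral_neg", "axial",
                                      "axial_neg"))
  stopifnot(torque_nm >= 0)
  ax <- load_axis(direction)
  moment <- c(0, 0, 0)
  if (direction != "neutral") moment[ax$axis] <- ax$sign * torque_nm
  structure(list(direction = direction, torque_nm = torque_nm,
                 moment = moment, muscles = muscles),
            class = "load_case")
}

load_axis <- function(direction) {
  switch(direction,
         neutral = list(axis = 1L, sign = 1),
         flexion = list(axis = 1L, sign = 1),
         extension = list(axis = 1L, sign = -1),
         lateral = list(axis = 2L, sign = 1),
         lateral_neg = list(axis = 2L, sign = -1),
         axial = list(axis = 3L, sign = 1),
         axial_neg = list(axis = 3L, sign = -1))
}

#' Assemble a solvable multi-body model
#'
#' Compiles a [segment_geometry()] or [spine_geometry()] together with a
#' characteristic set into the element lists the equilibrium solver operates
#' on. The reduction `stage` selects which passive elements are present;
#' `muscle_groups` selects active cables. The caudal-most body is fixed, all
#' others are mobile; the applied moment acts on the topmost body.
#'
#' @param geom a [segment_geometry()] or [spine_geometry()].
#' @param chars a characteristic set as returned by
#'   [default_characteristics()] or [read_characteristics()]; ligament
#'   characteristics are matched to ligaments by name. Facet stiffness and
#'   damping from `chars$facets` override the values stored in the geometry.
#' @param stage one of [rom_stages()].
#' @param muscle_groups character vector of active muscle groups (chain
#'   models).
#' @return Object of class `"mbs_model"`.
#' @export
build_model <- function(geom, chars, stage = "intact",
                        muscle_groups = character(0)) {
  stopifnot(inherits(chars, "characteristic_set") || is.list(chars))
  segs_in <- if (inherits(geom, "segment_geometry")) list(geom)
             else geom$segments
  bodies_in <- if (inherits(geom, "segment_geometry")) {
    list(geom$cranial, geom$caudal)
  } else geom$bodies
  act <- stage_elements(stage)

  bodies <- lapply(bodies_in, function(b) {
    list(name = b$name, com = b$com, points = b$points)
  })
  n <- length(bodies)
  body_idx <- stats::setNames(seq_len(n), vapply(bodies, `[[`, "", "name"))
  fixed <- c(rep(FALSE, n - 1), TRUE)   # caudal-most body is fixed
  mobile <- which(!fixed)

  segments <- lapply(segs_in, function(sg) {
    a <- body_idx[[sg$cranial$name]]
    b <- body_idx[[sg$caudal$name]]
    ligs <- list()
    for (ld in sg$ligaments) {
      if (!(ld$name %in% act$ligaments)) next
      ch <- chars$ligaments[[ld$name]]
      if (is.null(ch)) {
        stop(sprintf("build_model(): no characteristic for ligament %s",
                     ld$name), call. = FALSE)
      }
      cr <- resolve_segment_point(sg, ld$cranial_point)
      ca <- resolve_segment_point(sg, ld$caudal_point)
      l_neutral <- sqrt(sum((cr$point - ca$point)^2))
      ligs[[length(ligs) + 1L]] <- list(
        name = ld$name, side = ld$side,
        body_a = a, p_a = cr$point,     # cranial attachment
        body_b = b, p_b = ca$point,     # caudal attachment
        prestrain = ld$prestrain,
        l0 = l_neutral / (1 + ld$prestrain / 100),
        char = ch)
    }
    facets <- NULL
    if (act$facets && !is.null(sg$facets)) {
      facets <- lapply(sg$facets, function(fs) {
        fs$stiffness <- chars$facets$stiffness %||% fs$stiffness
        fs$damping <- chars$facets$damping %||% fs$damping
        fs
      })
    }
    list(body_a = a, body_b = b, disk_centre = sg$disk_centre, csa = sg$csa,
         disk_char = chars$disk, ligaments = ligs, facets = facets)
  })

  muscles <- list()
  if (!inherits(geom, "segment_geometry")) {
    for (mc in geom$muscles) {
      if (!(mc$group %in% muscle_groups)) next
      p <- if (is.numeric(mc$point)) as.numeric(mc$point)
           else bodies[[body_idx[[mc$body]]]]$points[[mc$point]]
      muscles[[length(muscles) + 1L]] <- list(
        body = body_idx[[mc$body]], point = p,
        direction = mc$direction, force = mc$force, group = mc$group)
    }
  }

  structure(list(bodies = bodies, fixed = fixed, mobile = mobile,
                 segments = segments, muscles = muscles,
                 loaded_body = 1L, stage = stage,
                 n_dof = 6L * length(mobile)),
            class = "mbs_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mbs_model <- function(x, ...) {
  cat(sprintf("<mbs_model> stage %s | %d bodies (%d mobile) | %d segments | %d cables\n",
              x$stage, length(x$bodies), length(x$mobile), length(x$segments),
              length(x$muscles)))
  invisible(x)
}

# ---- state vector helpers ---------------------------------------------------

state_to_poses <- function(model, x) {
  poses <- vector("list", length(model$bodies))
  for (b in seq_along(model$bodies)) {
    if (model$fixed[b]) {
      poses[[b]] <- list(R = diag(3), t = c(0, 0, 0), rot = c(0, 0, 0))
    } else {
      m <- match(b, model$mobile)
      i <- (m - 1L) * 6L
      tr <- x[i + 1:3]
      ro <- x[i + 4:6]
      poses[[b]] <- list(R = rotvec_to_matrix(ro), t = tr, rot = ro)
    }
  }
  poses
}

world_point <- function(model, poses, b, p) {
  ps <- poses[[b]]
  as.numeric(ps$R %*% (p - model$bodies[[b]]$com)) + model$bodies[[b]]$com +
    ps$t
}

# reference points about which body wrenches are accumulated
reference_points <- function(model, poses, about = c("com", "joint")) {
  about <- match.arg(about)
  refs <- vector("list", length(model$bodies))
  for (b in seq_along(model$bodies)) {
    refs[[b]] <- model$bodies[[b]]$com + poses[[b]]$t
  }
  if (about == "joint") {
    # supporting disk centre (as carried by the caudal body of that segment)
    for (sg in model$segments) {
      refs[[sg$body_a]] <- world_point(model, poses, sg$body_b, sg$disk_centre)
    }
  }
  refs
}

# Core wrench assembly. Returns a 6 x n_bodies matrix (rows Fx Fy Fz Tx Ty Tz)
# of the total element + applied wrench on every body, about the given
# reference points. `exclude` drops one element from the sum:
#   list(type = "ligament", segment = i, name = "ALL") (all sides) or
#   list(type = "facets", segment = i).
assemble_wrenches <- function(model, poses, load = NULL, refs = NULL,
                              exclude = NULL, facet_scale = 1,
                              tension_reg = 0, smooth_mu = 0,
                              branches = NULL) {
  nb <- length(model$bodies)
  if (is.null(refs)) refs <- reference_points(model, poses, "com")
  W <- matrix(0, nrow = 6, ncol = nb)
  add <- function(b, f, p_app) {
    W[1:3, b] <<- W[1:3, b] + f
    W[4:6, b] <<- W[4:6, b] + cross3(p_app - refs[[b]], f)
  }
  add_torque <- function(b, tau) W[4:6, b] <<- W[4:6, b] + tau

  for (si in seq_along(model$segments)) {
    sg <- model$segments[[si]]
    a <- sg$body_a; b <- sg$body_b
    Ra <- poses[[a]]$R; Rb <- poses[[b]]$R
    x_ca <- world_point(model, poses, a, sg$disk_centre)
    x_cb <- world_point(model, poses, b, sg$disk_centre)
    # disk bushing
    r_local <- as.numeric(crossprod(Rb, x_ca - x_cb))
    q <- -r_local[3]                       # compression depth, m
    f_local <- disk_force(sg$disk_char, c(r_local[1], r_local[2], q))
    # optional continuation stiffness on the tension-free axial branch; used
    # only as a solver homotopy, zero in every reported equilibrium
    if (q < 0 && tension_reg > 0) f_local[3] <- tension_reg * q
    if (!is.null(branches)) {
      # active-set solve: the axial branch is frozen, making the residual
      # smooth; consistency is re-checked by the caller
      f_local[3] <- if (branches$disk[si])
        sg$disk_char$axial_quad * q^2 * sign(q) + sg$disk_char$axial_lin * q
      else 0
    }
    phi_rel <- matrix_to_rotvec(crossprod(Rb, Ra))
    tau_local <- disk_torque(sg$disk_char, phi_rel)
    if (!is.null(branches)) {
      # frozen sagittal row: removes the flexion/extension slope kink at
      # zero rotation (both rows are odd, hence smooth through the origin)
      p <- if (branches$sag[si]) sg$disk_char$rot$flexion
           else sg$disk_char$rot$extension
      tau_local[1] <- -tanh_cubic(phi_rel[1], p$p1, p$p2, p$p3)
    }
    f_w <- as.numeric(Rb %*% f_local)
    tau_w <- as.numeric(Rb %*% tau_local)
    add(a, f_w, x_cb); add_torque(a, tau_w)
    add(b, -f_w, x_cb); add_torque(b, -tau_w)
    # ligaments
    for (li in seq_along(sg$ligaments)) {
      lg <- sg$ligaments[[li]]
      if (!is.null(exclude) && identical(exclude$type, "ligament") &&
          exclude$segment == si && identical(exclude$name, lg$name)) next
      p_a <- world_point(model, poses, a, lg$p_a)
      p_b <- world_point(model, poses, b, lg$p_b)
      dvec <- p_b - p_a
      len <- sqrt(sum(dvec^2))
      eps <- 100 * (len - lg$l0) / lg$l0
      f <- if (!is.null(branches)) {
        # frozen slack/taut branch: taut keeps the raw (unclamped) spring law
        if (branches$lig[[si]][li]) spring_force_scalar(lg$char, eps) else 0
      } else if (smooth_mu > 0) {
        # smoothed non-negativity clamp (solver homotopy only): keeps the
        # residual C1 across the slack/taut boundary
        fr <- spring_force_scalar(lg$char, eps) / smooth_mu
        smooth_mu * (if (fr > 30) fr else log1p(exp(fr)))
      } else {
        max(spring_force_scalar(lg$char, eps), 0)
      }
      if (f != 0) {
        u <- dvec / len
        add(a, f * u, p_a)
        add(b, -f * u, p_b)
      }
    }
    # facet contact: surfaces on the caudal body, probes on the cranial one
    if (!is.null(sg$facets) &&
        !(!is.null(exclude) && identical(exclude$type, "facets") &&
          exclude$segment == si)) {
      for (fi in seq_along(sg$facets)) {
        fs <- sg$facets[[fi]]
        if (is.null(fs$probe_points)) next
        E <- fs$frame$axes
        o_w <- world_point(model, poses, b, fs$frame$origin)
        probes <- as.matrix(fs$probe_points)
        for (i in seq_len(nrow(probes))) {
          p_w <- world_point(model, poses, a, probes[i, ])
          xi <- as.numeric(crossprod(E, crossprod(Rb, p_w - o_w))) * 1000
          pen <- facet_penetration(fs, matrix(xi, nrow = 1))[[1]]
          active <- if (!is.null(branches)) branches$fac[[si]][[fi]][i]
                    else pen$depth > 0
          if (active) {
            fn <- facet_scale * fs$stiffness * pen$depth
            n_w <- as.numeric(Rb %*% (E %*% pen$normal))
            add(a, fn * n_w, p_w)
            add(b, -fn * n_w, p_w)
          }
        }
      }
    }
  }
  for (mu in model$muscles) {
    p_w <- world_point(model, poses, mu$body, mu$point)
    add(mu$body, mu$force * mu$direction, p_w)
  }
  if (!is.null(load) && load$direction != "neutral") {
    add_torque(model$loaded_body, load$moment)
  }
  W
}

# Residual vector over the mobile bodies' degrees of freedom, ordered
# [t_x t_y t_z r_x r_y r_z] per mobile body; zero iff static equilibrium.
residual_fun <- function(model, x, load = NULL, about = "com",
                         exclude = NULL, tension_reg = 0, smooth_mu = 0,
                         branches = NULL) {
  poses <- state_to_poses(model, x)
  refs <- reference_points(model, poses, about)
  W <- assemble_wrenches(model, poses, load, refs, exclude,
                         tension_reg = tension_reg, smooth_mu = smooth_mu,
                         branches = branches)
  if (any(!is.finite(W))) {
    stop("residual evaluation produced non-finite element forces",
         call. = FALSE)
  }
  as.numeric(W[, model$mobile, drop = FALSE])
}

#' Generalized residual wrench of a model state
#'
#' Sums disk, ligament, facet and muscle wrenches plus the applied moment
#' about each mobile body's (posed) centre of mass. The result is the zero
#' vector exactly at static equilibrium.
#'
#' @param model an [build_model()] result.
#' @param poses list of [pose()] objects, one per mobile body (cranial to
#'   caudal), or a bare state vector.
#' @param load a [load_case()].
#' @return A tibble with one row per mobile body and columns `body`,
#'   `fx`, `fy`, `fz` (N), `tx`, `ty`, `tz` (Nm).
#' @export
residual_wrench <- function(model, poses, load = load_case()) {
  stopifnot(inherits(model, "mbs_model"))
  x <- poses_to_state(model, poses)
  r <- residual_fun(model, x, load)
  m <- matrix(r, nrow = 6)
  tibble::tibble(
    body = vapply(model$mobile, function(b) model$bodies[[b]]$name, ""),
    fx = m[1, ], fy = m[2, ], fz = m[3, ],
    tx = m[4, ], ty = m[5, ], tz = m[6, ])
}

poses_to_state <- function(model, poses) {
  if (is.numeric(poses)) {
    stopifnot(length(poses) == model$n_dof)
    return(as.numeric(poses))
  }
  if (is_pose(poses)) poses <- list(poses)
  stopifnot(length(poses) == length(model$mobile))
  as.numeric(unlist(lapply(poses, function(p) c(p$trans, p$rot))))
}

state_to_pose_list <- function(model, x) {
  out <- list()
  for (m in seq_along(model$mobile)) {
    i <- (m - 1L) * 6L
    out[[model$bodies[[model$mobile[m]]]$name]] <-
      pose(rot = x[i + 4:6], trans = x[i + 1:3])
  }
  out
}

#' Per-element state at a model configuration
#'
#' @param model an [build_model()] result.
#' @param poses poses or state vector as in [residual_wrench()].
#' @return Tibble with columns `segment`, `type`, `name`, `side`, `strain_pct`
#'   (ligaments), `force_n` and `value` (disk: axial compressive force; facet:
#'   total normal force).
#' @export
element_state <- function(model, poses) {
  x <- poses_to_state(model, poses)
  poses <- state_to_poses(model, x)
  rows <- list()
  for (si in seq_along(model$segments)) {
    sg <- model$segments[[si]]
    a <- sg$body_a; b <- sg$body_b
    Rb <- poses[[b]]$R
    x_ca <- world_point(model, poses, a, sg$disk_centre)
    x_cb <- world_point(model, poses, b, sg$disk_centre)
    q <- -as.numeric(crossprod(Rb, x_ca - x_cb))[3]
    f_ax <- if (q > 0) sg$disk_char$axial_quad * q^2 +
      sg$disk_char$axial_lin * q else 0
    rows[[length(rows) + 1L]] <- tibble::tibble(
      segment = si, type = "disk", name = "disk", side = "midline",
      strain_pct = NA_real_, force_n = f_ax)
    for (lg in sg$ligaments) {
      p_a <- world_point(model, poses, a, lg$p_a)
      p_b <- world_point(model, poses, b, lg$p_b)
      len <- sqrt(sum((p_b - p_a)^2))
      eps <- 100 * (len - lg$l0) / lg$l0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        segment = si, type = "ligament", name = lg$name, side = lg$side,
        strain_pct = eps, force_n = ligament_force(lg$char, eps))
    }
    if (!is.null(sg$facets)) {
      for (side in names(sg$facets)) {
        fs <- sg$facets[[side]]
        if (is.null(fs$probe_points)) next
        E <- fs$frame$axes
        o_w <- world_point(model, poses, b, fs$frame$origin)
        tot <- 0
        for (i in seq_len(nrow(as.matrix(fs$probe_points)))) {
          p_w <- world_point(model, poses, a,
                             as.matrix(fs$probe_points)[i, ])
          xi <- as.numeric(crossprod(E, crossprod(Rb, p_w - o_w))) * 1000
          pen <- facet_penetration(fs, matrix(xi, nrow = 1))[[1]]
          if (pen$depth > 0) tot <- tot + fs$stiffness * pen$depth
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          segment = si, type = "facet", name = "facet", side = side,
          strain_pct = NA_real_, force_n = tot)
      }
    }
  }
  dplyr::bind_rows(rows)
}

# Branch state of every piecewise-defined element (disk axial
# compression/separation, ligament taut/slack, facet probe contact/clear) at
# a configuration; used by the active-set stage of the solver.
compute_branches <- function(model, x) {
  poses <- state_to_poses(model, x)
  disk <- logical(length(model$segments))
  sag <- logical(length(model$segments))
  lig <- vector("list", length(model$segments))
  fac <- vector("list", length(model$segments))
  for (si in seq_along(model$segments)) {
    sg <- model$segments[[si]]
    a <- sg$body_a; b <- sg$body_b
    Rb <- poses[[b]]$R
    x_ca <- world_point(model, poses, a, sg$disk_centre)
    x_cb <- world_point(model, poses, b, sg$disk_centre)
    disk[si] <- -as.numeric(crossprod(Rb, x_ca - x_cb))[3] > 0
    sag[si] <- matrix_to_rotvec(crossprod(Rb, poses[[a]]$R))[1] > 0
    lig[[si]] <- vapply(sg$ligaments, function(lg) {
      p_a <- world_point(model, poses, a, lg$p_a)
      p_b <- world_point(model, poses, b, lg$p_b)
      eps <- 100 * (sqrt(sum((p_b - p_a)^2)) - lg$l0) / lg$l0
      ligament_spring_force(lg$char, eps) > 0
    }, logical(1))
    fac[[si]] <- lapply(sg$facets %||% list(), function(fs) {
      if (is.null(fs$probe_points)) return(logical(0))
      E <- fs$frame$axes
      o_w <- world_point(model, poses, b, fs$frame$origin)
      probes <- as.matrix(fs$probe_points)
      vapply(seq_len(nrow(probes)), function(i) {
        p_w <- world_point(model, poses, a, probes[i, ])
        xi <- as.numeric(crossprod(E, crossprod(Rb, p_w - o_w))) * 1000
        facet_penetration(fs, matrix(xi, nrow = 1))[[1]]$depth > 0
      }, logical(1))
    })
  }
  list(disk = disk, sag = sag, lig = lig, fac = fac)
}

# axial compressive disk spring force (N) of one segment at a state
disk_axial_force <- function(model, x, segment = 1L) {
  poses <- state_to_poses(model, x)
  sg <- model$segments[[segment]]
  Rb <- poses[[sg$body_b]]$R
  x_ca <- world_point(model, poses, sg$body_a, sg$disk_centre)
  x_cb <- world_point(model, poses, sg$body_b, sg$disk_centre)
  q <- -as.numeric(crossprod(Rb, x_ca - x_cb))[3]
  if (q > 0) sg$disk_char$axial_quad * q^2 + sg$disk_char$axial_lin * q else 0
}
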
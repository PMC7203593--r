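#' Rigid vertebra definition
#'
#' A vertebra is a rigid body with a centre of mass and a dictionary of named
#' attachment points (ligament insertions, facet anchors, muscle attachments,
#' disk centre). Points are given in the body frame, which coincides with the
#' global frame in the neutral configuration; all coordinates in metres.
#'
#' @param name body label, e.g. `"L4"`.
#' @param com centre of mass, length-3 numeric (m, global frame at neutral).
#' @param points named list of length-3 numerics (m, body frame).
#' @return Object of class `"rigid_body"`.
#' @export
rigid_body <- function(name, com, points = list()) {
  stopifnot(is.character(name), length(com) == 3)
  if (length(points) > 0 && anyDuplicated(names(points))) {
    stop("rigid_body(): point labels must be unique within a body",
         call. = FALSE)
  }
  structure(list(name = name, com = as.numeric(com),
                 points = lapply(points, as.numeric)),
            class = "rigid_body")
}

#' Ligament definition
#'
#' Anchors a ligament between a point on the cranial and a point on the caudal
#' vertebra of a segment. Prestrain is the strain present at the neutral pose
#' (percent; negative prestrain means the ligament is slack at neutral); the
#' rest length is derived from the neutral length via
#' `L0 = L_neutral / (1 + prestrain/100)` so that neutral-pose strain equals
#' the declared prestrain by construction.
#'
#' @param name ligament label; one of ALL, PLL, FL, ITL, CL, ISL, SSL.
#' @param side `"midline"`, `"left"` or `"right"`.
#' @param cranial_point,caudal_point character vectors `c(body, point_label)`.
#' @param prestrain percent, within \[-20, 20\].
#' @return Object of class `"ligament_def"`.
#' @export
ligament_def <- function(name, side = "midline", cranial_point, caudal_point,
                         prestrain = 0) {
  name <- match.arg(name, c("ALL", "PLL", "FL", "ITL", "CL", "ISL", "SSL"))
  side <- match.arg(side, c("midline", "left", "right"))
  stopifnot(length(cranial_point) == 2, length(caudal_point) == 2)
  if (prestrain < -20 || prestrain > 20) {
    stop("ligament_def(): prestrain must lie in [-20, 20] percent",
         call. = FALSE)
  }
  structure(list(name = name, side = side,
                 cranial_point = as.character(cranial_point),
                 caudal_point = as.character(caudal_point),
                 prestrain = as.numeric(prestrain)),
            class = "ligament_def")
}

#' Facet landmark set
#'
#' Nine landmarks sampled on one articular process, expressed in the shared
#' facet-local frame in millimetres (columns x, y, f).
#'
#' @param points 9 x 3 numeric matrix (mm).
#' @param frame optional facet-local frame (list with `origin`, `axes`) used to
#'   detect mismatched frames when two sets are fitted together.
#' @return Object of class `"facet_landmarks"`.
#' @export
facet_landmarks <- function(points, frame = NULL) {
  points <- as.matrix(points)
  if (nrow(points) != 9 || ncol(points) != 3) {
    stop("facet_landmarks(): exactly 9 points with 3 coordinates required",
         call. = FALSE)
  }
  structure(list(points = points, frame = frame), class = "facet_landmarks")
}

facet_design_matrix <- function(x, y) {
  cbind(x^3, y^3, x^2, y^2, 1)
}

eval_facet_poly <- function(coef, x, y) {
  coef$p30 * x^3 + coef$p03 * y^3 + coef$p20 * x^2 + coef$p02 * y^2 + coef$p00
}

# outward gradient of f; surface normal in facet-local coordinates
facet_normal_local <- function(coef, x, y) {
  fx <- 3 * coef$p30 * x^2 + 2 * coef$p20 * x
  fy <- 3 * coef$p03 * y^2 + 2 * coef$p02 * y
  n <- c(-fx, -fy, 1)
  n / sqrt(sum(n^2))
}

#' Facet contact surface definition
#'
#' Convex cubic regression surface `f(x, y) = p30 x^3 + p03 y^3 + p20 x^2 +
#' p02 y^2 + p00` in the facet-local frame (millimetres), together with the
#' penalty-contact stiffness and damping and the probe points on the opposing
#' articular process used for contact detection.
#'
#' @param coef named list `p30`, `p03`, `p20`, `p02`, `p00` (mm units).
#' @param frame facet-local frame: list with `origin` (length-3, m, caudal body
#'   frame) and `axes` (3 x 3 matrix whose columns are the local x, y, f axes).
#' @param stiffness contact stiffness, N/m (> 0).
#' @param damping contact damping, Ns/m (>= 0).
#' @param probe_points matrix (k x 3) of probe points on the opposing (cranial)
#'   process, metres, cranial body frame.
#' @param xy_domain optional 2 x 2 matrix of fitted (x, y) ranges (mm) used to
#'   warn on extrapolation.
#' @return Object of class `"facet_surface_def"`.
#' @export
facet_surface_def <- function(coef, frame, stiffness = 12000, damping = 4000,
                              probe_points = NULL, xy_domain = NULL) {
  stopifnot(all(c("p30", "p03", "p20", "p02", "p00") %in% names(coef)))
  if (stiffness <= 0) stop("facet_surface_def(): stiffness must be > 0",
                           call. = FALSE)
  if (damping < 0) stop("facet_surface_def(): damping must be >= 0",
                        call. = FALSE)
  structure(list(coef = lapply(coef, as.numeric), frame = frame,
                 stiffness = stiffness, damping = damping,
                 probe_points = probe_points, xy_domain = xy_domain),
            class = "facet_surface_def")
}

#' Fit the mean facet regression surface to two landmark sets
#'
#' Fits the convex cubic surface polynomial separately to the nine landmarks on
#' the superior and on the inferior articular process by linear least squares,
#' then returns the component-wise mean of the two coefficient quintuples as
#' the single contact surface of the joint. The residual RMS of each fit is
#' reported in the result.
#'
#' @param landmarks_sup,landmarks_inf [facet_landmarks()] in the same
#'   facet-local frame (mm).
#' @param frame,stiffness,damping,probe_points passed to
#'   [facet_surface_def()]; the frame defaults to the landmarks' frame.
#' @return A [facet_surface_def()] with attributes `rms_sup`, `rms_inf` (mm)
#'   and `fits` (the two per-process coefficient sets).
#' @examples
#' cf <- list(p30 = 0, p03 = 0, p20 = 0, p02 = 0, p00 = 5)
#' g <- expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2))
#' lm <- facet_landmarks(cbind(g$x, g$y, 5))
#' fit_facet_surface(lm, lm)$coef$p00   # 5
#' @export
fit_facet_surface <- function(landmarks_sup, landmarks_inf, frame = NULL,
                              stiffness = 12000, damping = 4000,
                              probe_points = NULL) {
  stopifnot(inherits(landmarks_sup, "facet_landmarks"),
            inherits(landmarks_inf, "facet_landmarks"))
  fs <- landmarks_sup$frame
  fi <- landmarks_inf$frame
  if (!is.null(fs) && !is.null(fi)) {
    if (max(abs(unlist(fs$origin) - unlist(fi$origin)),
            abs(unlist(fs$axes) - unlist(fi$axes))) > 1e-9) {
      stop("fit_facet_surface(): landmark sets are expressed in different frames",
           call. = FALSE)
    }
  }
  fit_one <- function(lm) {
    X <- facet_design_matrix(lm$points[, 1], lm$points[, 2])
    if (qr(X)$rank < ncol(X)) {
      stop("fit_facet_surface(): degenerate landmarks (rank-deficient design matrix)",
           call. = FALSE)
    }
    beta <- qr.solve(X, lm$points[, 3])
    rms <- sqrt(mean((X %*% beta - lm$points[, 3])^2))
    list(coef = stats::setNames(as.list(beta),
                                c("p30", "p03", "p20", "p02", "p00")),
         rms = rms)
  }
  sup <- fit_one(landmarks_sup)
  inf <- fit_one(landmarks_inf)
  mean_coef <- purrr::map2(sup$coef, inf$coef, ~ (.x + .y) / 2)
  xy <- rbind(landmarks_sup$points[, 1:2], landmarks_inf$points[, 1:2])
  out <- facet_surface_def(
    coef = mean_coef,
    frame = if (is.null(frame)) fs else frame,
    stiffness = stiffness, damping = damping, probe_points = probe_points,
    xy_domain = apply(xy, 2, range))
  attr(out, "rms_sup") <- sup$rms
  attr(out, "rms_inf") <- inf$rms
  attr(out, "fits") <- list(superior = sup$coef, inferior = inf$coef)
  out
}

#' @rdname fit_facet_surface
#' @param x a fitted facet surface.
#' @param ... unused.
#' @export
tidy.facet_surface_def <- function(x, ...) {
  tibble::tibble(term = names(x$coef), estimate = unlist(x$coef))
}

#' Motion-segment geometry
#'
#' Two adjacent vertebrae with their connecting disk, ligaments and facet
#' joints. The disk centre must lie between the two centres of mass along the
#' cranio-caudal (z) axis; the cross-sectional area feeds the intradiscal
#' pressure conversion.
#'
#' @param cranial,caudal [rigid_body()] objects (cranial is the mobile one in
#'   single-segment experiments).
#' @param disk_centre length-3 numeric, metres, global frame at neutral.
#' @param ligaments list of [ligament_def()].
#' @param facets list with elements `left` and `right`, each a
#'   [facet_surface_def()] (may be `NULL` for a facet-free segment).
#' @param csa disk cross-sectional area, m^2 (> 0).
#' @return Object of class `"segment_geometry"`.
#' @export
segment_geometry <- function(cranial, caudal, disk_centre, ligaments = list(),
                             facets = NULL, csa = 1.8e-3) {
  stopifnot(inherits(cranial, "rigid_body"), inherits(caudal, "rigid_body"))
  if (csa <= 0) stop("segment_geometry(): csa must be positive", call. = FALSE)
  zs <- sort(c(cranial$com[3], caudal$com[3]))
  if (disk_centre[3] < zs[1] || disk_centre[3] > zs[2]) {
    stop("segment_geometry(): disk_centre must lie between the centres of mass along z",
         call. = FALSE)
  }
  structure(list(cranial = cranial, caudal = caudal,
                 disk_centre = as.numeric(disk_centre),
                 ligaments = ligaments, facets = facets, csa = csa),
            class = "segment_geometry")
}

#' @export
print.segment_geometry <- function(x, ...) {
  cat(sprintf("<segment_geometry> %s over %s | %d ligaments | facets: %s | csa %.3g m^2\n",
              x$cranial$name, x$caudal$name, length(x$ligaments),
              if (is.null(x$facets)) "none" else "left/right", x$csa))
  invisible(x)
}

#' Multi-segment spine geometry
#'
#' An ordered chain of vertebrae (topmost first, the caudal-most body is
#' fixed) with one motion segment per adjacent pair and muscle cables.
#'
#' @param bodies ordered list of [rigid_body()], cranial to caudal.
#' @param segments list of [segment_geometry()], one per adjacent pair,
#'   ordered the same way.
#' @param muscles list of muscle cable definitions (see [muscle_cable()]).
#' @return Object of class `"spine_geometry"`.
#' @export
spine_geometry <- function(bodies, segments, muscles = list()) {
  if (length(segments) != length(bodies) - 1) {
    stop("spine_geometry(): need exactly one segment per adjacent body pair",
         call. = FALSE)
  }
  structure(list(bodies = bodies, segments = segments, muscles = muscles),
            class = "spine_geometry")
}

#' @export
print.spine_geometry <- function(x, ...) {
  cat(sprintf("<spine_geometry> %s | %d segments | %d muscle cables\n",
              paste(vapply(x$bodies, `[[`, "", "name"), collapse = "-"),
              length(x$segments), length(x$muscles)))
  invisible(x)
}

resolve_segment_point <- function(geom, ref) {
  body <- ref[1]
  label <- ref[2]
  b <- if (identical(geom$cranial$name, body)) geom$cranial
       else if (identical(geom$caudal$name, body)) geom$caudal
       else stop(sprintf("unknown body '%s' in ligament endpoint", body),
                 call. = FALSE)
  p <- b$points[[label]]
  if (is.null(p)) {
    stop(sprintf("unknown point '%s' on body '%s'", label, body), call. = FALSE)
  }
  list(body = b, point = p, mobile = identical(geom$cranial$name, body))
}

#' Ligament length, strain, line of action and moment arms under a pose
#'
#' Poses the cranial vertebra of the segment (rotation about its centre of
#' mass plus translation), resolves the ligament's two endpoints in the world
#' frame, and returns current length, engineering strain relative to the
#' prestrain-derived rest length, the unit line of action of the tension force
#' acting on the mobile vertebra, and the moment arm of that force about each
#' axis through the disk centre (`(attachment_on_mobile - disk_centre) x
#' line_of_action`, metres: the torque per newton of tension).
#'
#' @param geom a [segment_geometry()].
#' @param lig a [ligament_def()] belonging to `geom`.
#' @param pose a [pose()] of the cranial vertebra.
#' @return A list with `length` (m), `strain` (percent), `line_of_action`
#'   (unit vector, world frame, direction of the force on the mobile body) and
#'   `moment_arm` (named numeric, m, axes x/y/z).
#' @examples
#' geom <- make_synthetic_fsu(synth_config(seed = 1))
#' lig <- geom$ligaments[[1]]
#' ligament_kinematics(geom, lig, pose())$strain  # equals lig$prestrain
#' @export
ligament_kinematics <- function(geom, lig, pose) {
  stopifnot(inherits(geom, "segment_geometry"), inherits(lig, "ligament_def"),
            is_pose(pose))
  cr <- resolve_segment_point(geom, lig$cranial_point)
  ca <- resolve_segment_point(geom, lig$caudal_point)
  R <- rotvec_to_matrix(pose$rot)
  place <- function(ep) {
    if (ep$mobile) transform_point(ep$point, R, geom$cranial$com, pose$trans)
    else ep$point
  }
  p_cr <- place(cr)
  p_ca <- place(ca)
  l_neutral <- sqrt(sum((cr$point - ca$point)^2))
  if (l_neutral < 1e-9) {
    stop("ligament_kinematics(): zero-length ligament", call. = FALSE)
  }
  l0 <- l_neutral / (1 + lig$prestrain / 100)
  len <- sqrt(sum((p_cr - p_ca)^2))
  if (len < 1e-9) {
    stop("ligament_kinematics(): ligament endpoints coincide", call. = FALSE)
  }
  # the cranial body is mobile in a single-segment experiment
  p_mob <- if (cr$mobile) p_cr else p_ca
  p_fix <- if (cr$mobile) p_ca else p_cr
  u <- (p_fix - p_mob) / len
  arm <- cross3(p_mob - geom$disk_centre, u)
  list(length = len,
       strain = 100 * (len - l0) / l0,
       line_of_action = u,
       moment_arm = stats::setNames(arm, c("x", "y", "z")))
}
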
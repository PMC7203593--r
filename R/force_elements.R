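#' Muscle cable definition
#'
#' A one-dimensional, length-independent force element: a wire cable attached
#' to one vertebra that transmits a constant traction along a fixed global
#' direction, emulating the symmetric cable pairs (80 N per pair, i.e. 40 N
#' per cable) used to represent active lumbar muscles in spine-tester
#' experiments.
#'
#' @param body name of the body holding the attachment.
#' @param point attachment point: a point label on that body, or a length-3
#'   numeric (m, body frame).
#' @param direction length-3 numeric, global frame; normalised internally.
#' @param force cable tension, N (>= 0).
#' @param group muscle group label, e.g. `"multifidus_caudal"`; used to switch
#'   configurations in the intradiscal-pressure protocol.
#' @return Object of class `"muscle_cable"`.
#' @export
muscle_cable <- function(body, point, direction, force = 40,
                         group = "muscle") {
  direction <- as.numeric(direction)
  nd <- sqrt(sum(direction^2))
  if (nd < 1e-12) stop("muscle_cable(): zero direction vector", call. = FALSE)
  if (force < 0) stop("muscle_cable(): force must be >= 0", call. = FALSE)
  structure(list(body = body, point = point, direction = direction / nd,
                 force = as.numeric(force), group = group),
            class = "muscle_cable")
}

#' Wrench exerted by a muscle cable on its body
#'
#' The cable force has constant magnitude and constant global direction; only
#' its point of application moves with the body. The wrench is accumulated
#' about the body's (posed) centre of mass.
#'
#' @param m a [muscle_cable()] whose `point` is a length-3 numeric (body
#'   frame, m).
#' @param pose the body's [pose()].
#' @param com the body's centre of mass (m, body frame).
#' @return List with `force` (N, length 3) and `torque` (Nm, length 3, about
#'   the posed centre of mass).
#' @examples
#' m <- muscle_cable("L2", c(0, 0.03, 0), c(0, 0, -1), force = 40)
#' muscle_wrench(m, pose())$torque   # 1.2 Nm about x
#' @export
muscle_wrench <- function(m, pose, com = c(0, 0, 0)) {
  stopifnot(inherits(m, "muscle_cable"), is_pose(pose), is.numeric(m$point))
  R <- rotvec_to_matrix(pose$rot)
  p_w <- transform_point(as.numeric(m$point), R, com, pose$trans)
  f <- m$force * m$direction
  list(force = f, torque = cross3(p_w - (com + pose$trans), f))
}

# facet penetration of a set of probe points (facet-local mm coordinates)
# against the mean regression surface; returns per-probe depth (m, >0 when
# penetrating) and the local surface normal
facet_penetration <- function(fs, xi) {
  # xi: k x 3 matrix of probe coordinates, facet-local, mm
  k <- nrow(xi)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    h <- eval_facet_poly(fs$coef, xi[i, 1], xi[i, 2])
    n <- facet_normal_local(fs$coef, xi[i, 1], xi[i, 2])
    gap_vert <- xi[i, 3] - h                    # mm, positive when separated
    depth <- -gap_vert * n[3] / 1000            # m, along the surface normal
    extrap <- FALSE
    if (!is.null(fs$xy_domain)) {
      extrap <- xi[i, 1] < fs$xy_domain[1, 1] || xi[i, 1] > fs$xy_domain[2, 1] ||
        xi[i, 2] < fs$xy_domain[1, 2] || xi[i, 2] > fs$xy_domain[2, 2]
    }
    out[[i]] <- list(depth = depth, normal = n, extrapolated = extrap)
  }
  out
}

#' Facet contact wrench on the mobile vertebra
#'
#' Penalty contact of the probe points (attached to the mobile, cranial
#' vertebra) against the mean regression surface (attached to the fixed,
#' caudal vertebra). Each penetrating probe contributes a normal force
#' `stiffness * depth` along the local surface normal, applied at the probe
#' point; separated probes contribute nothing. The wrench is accumulated about
#' the mobile body's posed centre of mass. Probes outside the fitted (x, y)
#' domain trigger an extrapolation warning but the force is still computed.
#'
#' @param fs a [facet_surface_def()] with probe points.
#' @param pose the mobile body's [pose()].
#' @param com the mobile body's centre of mass (m, body frame).
#' @return List with `force` (N), `torque` (Nm, about the posed com) and
#'   `contacts` (tibble: probe index, penetration depth m, normal force N).
#' @export
facet_force <- function(fs, pose, com = c(0, 0, 0)) {
  stopifnot(inherits(fs, "facet_surface_def"), is_pose(pose))
  if (is.null(fs$probe_points)) {
    stop("facet_force(): probe points undefined", call. = FALSE)
  }
  R <- rotvec_to_matrix(pose$rot)
  E <- fs$frame$axes
  o <- fs$frame$origin
  probes <- as.matrix(fs$probe_points)
  force <- c(0, 0, 0)
  torque <- c(0, 0, 0)
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    p_w <- transform_point(probes[i, ], R, com, pose$trans)
    xi <- as.numeric(crossprod(E, p_w - o)) * 1000   # caudal body fixed
    pen <- facet_penetration(fs, matrix(xi, nrow = 1))[[1]]
    fn <- 0
    if (pen$depth > 0) {
      if (pen$extrapolated) {
        warning("facet_force(): probe point outside the fitted surface domain; extrapolating",
                call. = FALSE)
      }
      fn <- fs$stiffness * pen$depth
      n_w <- as.numeric(E %*% pen$normal)
      force <- force + fn * n_w
      torque <- torque + cross3(p_w - (com + pose$trans), fn * n_w)
    }
    rows[[i]] <- tibble::tibble(probe = i, depth_m = max(pen$depth, 0),
                                force_n = fn)
  }
  list(force = force, torque = torque, contacts = dplyr::bind_rows(rows))
}
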
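#' Six degree-of-freedom pose of a mobile vertebra
#'
#' A pose is the relative placement of a mobile rigid body with respect to its
#' neutral configuration: a rotation vector `rot` (radians; axis-angle, applied
#' about the body's centre of mass) and a translation `trans` (metres) of the
#' centre of mass. The axis convention is right-handed with x = medio-lateral
#' (flexion/extension axis; positive rotation = flexion), y = antero-posterior
#' (lateral-flexion axis; positive y points dorsally) and z = cranio-caudal
#' (axial-rotation axis; positive z points cranially).
#'
#' @param rot numeric length-3 rotation vector in radians; `norm(rot)` must be
#'   below `pi`.
#' @param trans numeric length-3 translation in metres.
#' @return An object of class `"pose"`.
#' @examples
#' pose()                      # identity
#' pose(rot = c(0.1, 0, 0))    # 0.1 rad flexion
#' @export
pose <- function(rot = c(0, 0, 0), trans = c(0, 0, 0)) {
  rot <- as.numeric(rot)
  trans <- as.numeric(trans)
  stopifnot(length(rot) == 3, length(trans) == 3,
            all(is.finite(rot)), all(is.finite(trans)))
  if (sqrt(sum(rot^2)) >= pi) {
    stop("pose(): rotation vector magnitude must be < pi", call. = FALSE)
  }
  structure(list(rot = rot, trans = trans), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("<pose> rot (rad):", signif(x$rot, 4),
      "| trans (m):", signif(x$trans, 4), "\n")
  invisible(x)
}

is_pose <- function(x) inherits(x, "pose")

#' Rotation vector to rotation matrix (Rodrigues formula)
#' @noRd
rotvec_to_matrix <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) {
    # second-order expansion keeps the map smooth through the origin
    K <- skew(r)
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  k <- r / th
  K <- skew(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to rotation vector
#' @noRd
matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-9) {
    # first-order: R ~ I + skew(r)
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  th * ax
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), nrow = 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Transform a body-frame point to the world frame under a pose
#'
#' Points are stored in the body frame, which coincides with the world frame in
#' the neutral configuration. The pose rotates the body about its centre of
#' mass `com` and translates the centre of mass.
#' @noRd
transform_point <- function(p, pose_rotmat, com, trans) {
  as.numeric(pose_rotmat %*% (p - com)) + com + trans
}
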
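#' Intervertebral-disk characteristic
#'
#' The disk acts as a six degree-of-freedom spring-damper bushing. Rotations
#' follow the odd tanh-cubic torque-angle law
#' \deqn{T(\varphi) = p_1 \tanh(\varphi^3 / p_2) + p_3 \varphi}
#' with angles in radians and torques in Nm; flexion (positive rotation about
#' x) and extension (negative) use separate parameter rows, lateral flexion
#' (y) and axial rotation (z) are each captured by a single odd curve. The
#' axial translational spring is a compression-only quadratic polynomial
#' `axial_quad * r^2 + axial_lin * r` (r = compression depth in metres, force
#' in N); the disk transmits no axial traction. Shear is linear.
#'
#' @param rot named list of directions `flexion`, `extension`, `lateral`,
#'   `axial`, each a list/vector with elements `p1` (Nm), `p2` (rad^3),
#'   `p3` (Nm/rad).
#' @param axial_quad,axial_lin compression polynomial coefficients (N/m^2, N/m).
#' @param shear_stiffness linear shear stiffness, N/m.
#' @param d_damp_tra,d_damp_rot translational (Ns/m) and rotational (Nm s)
#'   damping coefficients; irrelevant at equilibrium.
#' @return Object of class `"disk_characteristic"`.
#' @seealso [disk_force()], [disk_torque()], [default_characteristics()]
#' @export
disk_characteristic <- function(rot,
                                axial_quad = 690234060,
                                axial_lin = 659748,
                                shear_stiffness = 260000,
                                d_damp_tra = 400000,
                                d_damp_rot = 100) {
  dirs <- c("flexion", "extension", "lateral", "axial")
  stopifnot(all(dirs %in% names(rot)))
  rot <- lapply(rot[dirs], function(p) {
    p <- as.list(p)
    stopifnot(all(c("p1", "p2", "p3") %in% names(p)))
    p <- lapply(p[c("p1", "p2", "p3")], as.numeric)
    if (p$p2 == 0) stop("disk_characteristic(): p2 must be nonzero", call. = FALSE)
    p
  })
  stopifnot(axial_quad >= 0, axial_lin >= 0, shear_stiffness >= 0)
  structure(list(rot = rot, axial_quad = axial_quad, axial_lin = axial_lin,
                 shear_stiffness = shear_stiffness,
                 d_damp_tra = d_damp_tra, d_damp_rot = d_damp_rot),
            class = "disk_characteristic")
}

#' @export
print.disk_characteristic <- function(x, ...) {
  cat("<disk_characteristic>\n")
  for (d in names(x$rot)) {
    p <- x$rot[[d]]
    cat(sprintf("  %-9s p1 = %-9.4g p2 = %-9.4g p3 = %-9.4g\n",
                d, p$p1, p$p2, p$p3))
  }
  cat(sprintf("  axial %.6g r^2 + %.6g r (compression only); shear %.4g N/m\n",
              x$axial_quad, x$axial_lin, x$shear_stiffness))
  invisible(x)
}

#' Ligament force-strain characteristic
#'
#' Ligaments follow the smooth softplus force-strain law
#' \deqn{F(\varepsilon) = a \ln(e^{(\varepsilon + b)/d} + 1) + c}
#' with strain in percent and force in N, reproducing the nonlinear toe zone
#' and quasi-linear region of connective tissue. An optional negative-strain
#' branch (`neg_branch`) takes over for strains below zero; where present it
#' must join the positive branch continuously at zero strain (gap below
#' 0.1 N). The damping term is force-proportional,
#' `damping_factor * F_spring * deps` with the strain rate `deps` expressed as
#' a fraction per second; it vanishes at equilibrium. Total force is clamped
#' non-negative: a ligament cannot push.
#'
#' @param a,b,c,d softplus parameters (N, percent, N, percent). `d` must be
#'   nonzero; negative `d` yields a decreasing (concave) curve.
#' @param neg_branch optional list with elements `a`, `b`, `c`, `d` used for
#'   negative strains.
#' @param damping_factor dimensionless force-proportional damping factor.
#' @return Object of class `"ligament_characteristic"`.
#' @seealso [ligament_force()], [default_characteristics()]
#' @export
ligament_characteristic <- function(a, b, c, d, neg_branch = NULL,
                                    damping_factor = 10) {
  if (d == 0) stop("ligament_characteristic(): d must be nonzero", call. = FALSE)
  obj <- structure(list(a = as.numeric(a), b = as.numeric(b),
                        c = as.numeric(c), d = as.numeric(d),
                        neg_branch = neg_branch,
                        damping_factor = as.numeric(damping_factor)),
                   class = "ligament_characteristic")
  if (!is.null(neg_branch)) {
    nb <- lapply(neg_branch[c("a", "b", "c", "d")], as.numeric)
    if (nb$d == 0) stop("neg_branch d must be nonzero", call. = FALSE)
    obj$neg_branch <- nb
    gap <- abs(softplus_force(0, a, b, c, d) -
                 softplus_force(0, nb$a, nb$b, nb$c, nb$d))
    if (gap >= 0.1) {
      stop(sprintf(
        "ligament_characteristic(): branches disagree at zero strain by %.3g N",
        gap), call. = FALSE)
    }
  }
  obj
}

#' Zero-force ligament characteristic
#'
#' Used for ligaments carried in the model whose characteristic cannot be
#' calibrated (the intertransverse ligament): the element exists but transmits
#' no force unless the user supplies a characteristic.
#' @return A `"ligament_characteristic"` evaluating to 0 N at every strain.
#' @export
zero_ligament_characteristic <- function() {
  ligament_characteristic(a = 0, b = 0, c = 0, d = 1, damping_factor = 0)
}

#' @export
print.ligament_characteristic <- function(x, ...) {
  cat(sprintf("<ligament_characteristic> a = %.4g, b = %.4g, c = %.4g, d = %.4g%s\n",
              x$a, x$b, x$c, x$d,
              if (!is.null(x$neg_branch)) " (+ negative-strain branch)" else ""))
  invisible(x)
}

# numerically stable a*softplus((eps+b)/d) + c
softplus_force <- function(eps, a, b, c, d) {
  x <- (eps + b) / d
  sp <- ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  a * sp + c
}

# analytic slope dF/deps of the softplus law (N per percent strain)
softplus_slope <- function(eps, a, b, d) {
  x <- (eps + b) / d
  (a / d) * stats::plogis(x)
}

# scalar fast path for the solver's inner loop (no damping, no clamp)
spring_force_scalar <- function(char, eps) {
  if (eps < 0 && !is.null(char$neg_branch)) {
    nb <- char$neg_branch
    x <- (eps + nb$b) / nb$d
    return(nb$a * (if (x > 30) x else log1p(exp(x))) + nb$c)
  }
  x <- (eps + char$b) / char$d
  char$a * (if (x > 30) x else log1p(exp(x))) + char$c
}

ligament_spring_force <- function(char, eps) {
  use_neg <- !is.null(char$neg_branch) & eps < 0
  f <- softplus_force(eps, char$a, char$b, char$c, char$d)
  if (any(use_neg)) {
    nb <- char$neg_branch
    f[use_neg] <- softplus_force(eps[use_neg], nb$a, nb$b, nb$c, nb$d)
  }
  f
}

#' Ligament tension from strain and strain rate
#'
#' Evaluates the softplus spring law (negative-strain branch if present and
#' strain is negative) plus the force-proportional damping term, clamping the
#' total at zero from below (a cable cannot push).
#'
#' @param char a [ligament_characteristic()].
#' @param eps strain in percent (may be a vector).
#' @param deps strain rate in percent per second on the strain scale; it is
#'   converted to fraction per second internally so that the damping term
#'   `damping_factor * F_spring * deps/100` carries units of N.
#' @return Tension in N (non-negative), same length as `eps`.
#' @examples
#' isl <- default_characteristics()$ligaments$ISL
#' ligament_force(isl, eps = 5)   # ~28 N
#' @export
ligament_force <- function(char, eps, deps = 0) {
  stopifnot(inherits(char, "ligament_characteristic"))
  f <- ligament_spring_force(char, eps)
  f <- f + char$damping_factor * f * (deps / 100)
  pmax(f, 0)
}

# signed odd tanh-cubic torque law for one direction row
tanh_cubic <- function(phi, p1, p2, p3) {
  p1 * tanh(phi^3 / p2) + p3 * phi
}

disk_rot_torque_axis <- function(char, phi, axis) {
  # axis: 1 = x (flexion/extension asymmetric), 2 = y (lateral), 3 = z (axial)
  if (axis == 1L) {
    p <- if (phi >= 0) char$rot$flexion else char$rot$extension
    sign(phi) * tanh_cubic(abs(phi), p$p1, p$p2, p$p3)
  } else {
    p <- if (axis == 2L) char$rot$lateral else char$rot$axial
    tanh_cubic(phi, p$p1, p$p2, p$p3)
  }
}

#' Disk restoring force from translational deformation
#'
#' `r` is the displacement of the cranial vertebra relative to the caudal one
#' in the caudal disk frame, metres; its z component is taken positive in
#' compression. The axial spring is the compression-only quadratic polynomial;
#' in axial tension the spring force is zero (the disk cannot transmit
#' traction). Shear (x, y) is linear. Damping acts per axis on `dr`.
#'
#' @param char a [disk_characteristic()].
#' @param r numeric length-3 displacement (m), z positive in compression.
#' @param dr numeric length-3 velocity (m/s).
#' @return Length-3 restoring force (N) acting on the cranial vertebra,
#'   expressed in the same frame as `r` (z positive = pushing the cranial
#'   vertebra cranially, i.e. resisting compression).
#' @examples
#' ch <- default_characteristics()$disk
#' disk_force(ch, c(0, 0, 0.001))  # ~1350 N axial
#' @export
disk_force <- function(char, r, dr = c(0, 0, 0)) {
  stopifnot(inherits(char, "disk_characteristic"), length(r) == 3)
  fz <- if (r[3] > 0) char$axial_quad * r[3]^2 + char$axial_lin * r[3] else 0
  f <- c(-char$shear_stiffness * r[1], -char$shear_stiffness * r[2], fz)
  f - char$d_damp_tra * dr
}

#' Disk restoring torque from relative rotation
#'
#' Evaluates the tanh-cubic law per axis (radians in, Nm out) and returns the
#' restoring torque opposing the rotation; about x the flexion row is used for
#' positive angles and the extension row for negative angles, about y and z a
#' single odd characteristic serves both signs.
#'
#' @param char a [disk_characteristic()].
#' @param phi numeric length-3 relative rotation vector (rad) of the cranial
#'   relative to the caudal vertebra.
#' @param dphi numeric length-3 rotation rate (rad/s).
#' @return Length-3 restoring torque (Nm) acting on the cranial vertebra.
#' @examples
#' ch <- default_characteristics()$disk
#' disk_torque(ch, c(0.3, 0, 0))   # ~ -10.16 Nm resisting 0.3 rad flexion
#' @export
disk_torque <- function(char, phi, dphi = c(0, 0, 0)) {
  stopifnot(inherits(char, "disk_characteristic"), length(phi) == 3)
  t_spring <- vapply(1:3, function(ax) disk_rot_torque_axis(char, phi[ax], ax),
                     numeric(1))
  -t_spring - char$d_damp_rot * dphi
}

#' Intradiscal pressure from axial compressive force
#'
#' Converts the disk's axial compressive force to intradiscal pressure via the
#' empirical relation IDP = 1.68 F / CSA, which relates nucleus pressure to
#' mean axial stress over the cross-sectional area.
#'
#' @param force axial compressive force, N (non-negative).
#' @param csa cross-sectional area, m^2 (positive).
#' @return Pressure in Pa.
#' @examples
#' idp_from_force(500, 5e-4)   # 1.68e6 Pa = 1.68 MPa
#' @export
idp_from_force <- function(force, csa) {
  if (any(csa <= 0)) stop("idp_from_force(): csa must be positive", call. = FALSE)
  if (any(force < 0)) stop("idp_from_force(): force must be compressive (>= 0)",
                           call. = FALSE)
  1.68 * force / csa
}

#' Packaged default characteristic set
#'
#' The calibrated disk, facet and ligament parameter set shipped with the
#' package: tanh-cubic disk rows for flexion/extension/lateral/axial, the
#' axial compression polynomial, facet contact stiffness/damping and the
#' left/right facet surface coefficient sets, softplus rows for the six
#' calibrated ligaments (plus the negative-strain branch of the supraspinous
#' ligament and a zero-force intertransverse placeholder), and the standard
#' prestrain assignment.
#'
#' @return A list of class `"characteristic_set"` with elements `disk`
#'   ([disk_characteristic()]), `ligaments` (named list of
#'   [ligament_characteristic()]), `facets` (list with `stiffness`, `damping`,
#'   `left`/`right` coefficient lists) and `prestrains` (named numeric,
#'   percent).
#' @export
default_characteristics <- function() {
  disk <- disk_characteristic(rot = list(
    flexion   = list(p1 = 10.67, p2 = 0.005913, p3 = -1.685),
    extension = list(p1 = 5.196, p2 = 0.008417, p3 = 24.50),
    lateral   = list(p1 = 6.929, p2 = 0.001482, p3 = 19.76),
    axial     = list(p1 = 4.399, p2 = 0.001141, p3 = 42.38)
  ))
  ligaments <- list(
    ALL = ligament_characteristic(173.5, -10.06, -26.82, 5.625),
    PLL = ligament_characteristic(48.12, -43.97, -2.500, 15.00),
    FL  = ligament_characteristic(47.11, 4.210, 54.85, -11.25),
    CL  = ligament_characteristic(98.94, 18.97, -82.20, 73.33),
    ISL = ligament_characteristic(0.4517, -3.502, 0, 0.02414),
    SSL = ligament_characteristic(1.218, -22.97, 0, 1.369,
                                  neg_branch = list(a = -50.49, b = -36.00,
                                                    c = -0.02453, d = 4.718)),
    ITL = zero_ligament_characteristic()
  )
  facets <- list(
    stiffness = 12000, damping = 4000,
    left  = list(p30 = -0.007975, p03 = -0.004237, p20 = -0.1823,
                 p02 = -0.1734, p00 = 47.31),
    right = list(p30 = 0.01011, p03 = -0.008587, p20 = -0.1236,
                 p02 = -0.2915, p00 = 44.26)
  )
  prestrains <- c(ALL = 8, PLL = 10, FL = 10, ITL = 10, CL = 10,
                  ISL = 4, SSL = -6)
  structure(list(disk = disk, ligaments = ligaments, facets = facets,
                 prestrains = prestrains),
            class = "characteristic_set")
}

#' @export
print.characteristic_set <- function(x, ...) {
  cat("<characteristic_set>\n  disk directions:",
      paste(names(x$disk$rot), collapse = ", "), "\n  ligaments:",
      paste(names(x$ligaments), collapse = ", "),
      sprintf("\n  facet stiffness %.4g N/m\n", x$facets$stiffness))
  invisible(x)
}
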
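# Internal rotation utilities. Angles in degrees at the API surface,
# radians internally; all matrices proper orthogonal (det = +1).

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

rot_x <- function(deg) {
  a <- deg * .deg2rad
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * .deg2rad
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

rot_z <- function(deg) {
  a <- deg * .deg2rad
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Compose a rotation from anatomical elevation/yaw/roll angles
#'
#' Builds the relative rotation of the neurocranium in fish-frame axes
#' (X anteroposterior positive caudal, Y dorsoventral positive dorsal,
#' Z mediolateral, right-handed) from the three anatomical angles, applied
#' in the fixed order elevation (about Z), then yaw (about Y), then roll
#' (about X). Sign conventions: positive elevation lifts the snout
#' dorsally, positive yaw turns the head to the fish's left, positive roll
#' is clockwise seen from anterior. With the snout pointing along -X these
#' are the negatives of the raw right-handed Euler angles, which is why the
#' composition negates them.
#'
#' @param elevation,yaw,roll angles in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
compose_eyr <- function(elevation, yaw = 0, roll = 0) {
  rot_z(-elevation) %*% rot_y(-yaw) %*% rot_x(-roll)
}

#' Decompose a relative rotation into elevation/yaw/roll
#'
#' Inverse of [compose_eyr()]: extracts the Z-Y-X Euler angles of `R` and
#' maps them to the anatomical sign conventions. Emits a gimbal flag when
#' the middle (yaw) angle is within `gimbal_guard_deg` of 90 degrees,
#' where the decomposition loses a degree of freedom.
#'
#' @param R 3x3 proper rotation matrix.
#' @param gimbal_guard_deg proximity to 90 deg yaw that triggers the flag.
#' @return list with `elevation`, `yaw`, `roll` (degrees) and `gimbal`
#'   (logical).
#' @keywords internal
decompose_eyr <- function(R, gimbal_guard_deg = 1) {
  # R = Rz(a) %*% Ry(b) %*% Rx(c); a = -elevation, b = -yaw, c = -roll
  sb <- -R[3, 1]
  sb <- min(1, max(-1, sb))
  b <- asin(sb)
  gimbal <- (90 - abs(b) * .rad2deg) < gimbal_guard_deg
  if (gimbal) {
    # at b = +/-90 only (a - sign(b)*c) is determined; fix c = 0
    a <- atan2(-R[1, 2], R[2, 2])
    c <- 0
  } else {
    a <- atan2(R[2, 1], R[1, 1])
    c <- atan2(R[3, 2], R[3, 3])
  }
  list(elevation = -a * .rad2deg, yaw = -b * .rad2deg, roll = -c * .rad2deg,
       gimbal = gimbal)
}

# rotation about an arbitrary unit axis through the origin
rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg * .deg2rad
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}
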
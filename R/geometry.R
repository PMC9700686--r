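# Spherical geometry and quaternion algebra for head-free gaze.
#
# Conventions (asserted in I/O validation):
#   * world frame: x right, y up, z forward; unit gaze vectors;
#   * azimuth  = atan2(x, z) in degrees (positive rightwards, yaw about +y);
#   * elevation = asin(y) in degrees (positive upwards);
#   * quaternions (w, x, y, z), Hamilton convention, rotating head-frame
#     vectors into the world frame (world <- head).

DEG <- pi / 180

#' Convert azimuth/elevation angles to unit direction vectors
#'
#' @param az_deg,el_deg numeric vectors of azimuth and elevation in degrees.
#' @return numeric matrix with columns `x`, `y`, `z`.
#' @export
angles_to_dir <- function(az_deg, el_deg) {
  az <- az_deg * DEG
  el <- el_deg * DEG
  cbind(x = cos(el) * sin(az), y = sin(el), z = cos(el) * cos(az))
}

#' Convert unit direction vectors to azimuth/elevation angles
#'
#' @param v numeric matrix with columns x, y, z (rows need not be exactly
#'   unit length; they are normalized first).
#' @return data.frame with columns `az_deg`, `el_deg`.
#' @export
dir_to_angles <- function(v) {
  v <- as_dir_matrix(v)
  n <- sqrt(rowSums(v^2))
  if (any(n < 1e-12)) {
    stop_vrgaze("zero-norm direction vector", class = "vrgaze_geometry_error")
  }
  v <- v / n
  data.frame(az_deg = atan2(v[, 1], v[, 3]) / DEG,
             el_deg = asin(pmin(1, pmax(-1, v[, 2]))) / DEG)
}

as_dir_matrix <- function(v) {
  if (is.null(dim(v))) matrix(v, ncol = 3) else as.matrix(v)
}

#' Great-circle (angular) distance between unit directions
#'
#' Uses the chord-length form, which is numerically stable for small angles.
#'
#' @param v1,v2 matrices of unit direction vectors (rows paired).
#' @return angular distance in degrees.
#' @export
gc_dist_deg <- function(v1, v2) {
  v1 <- as_dir_matrix(v1)
  v2 <- as_dir_matrix(v2)
  if (nrow(v1) == 1L && nrow(v2) > 1L) v1 <- v1[rep(1L, nrow(v2)), , drop = FALSE]
  if (nrow(v2) == 1L && nrow(v1) > 1L) v2 <- v2[rep(1L, nrow(v1)), , drop = FALSE]
  chord <- sqrt(rowSums((v1 - v2)^2))
  2 * asin(pmin(1, chord / 2)) / DEG
}

#' Destination on the sphere given start, bearing and angular distance
#'
#' Bearing 0 deg moves towards increasing elevation; 90 deg towards
#' increasing azimuth.
#'
#' @param az_deg,el_deg start position (degrees), vectors.
#' @param bearing_deg initial bearing (degrees), vector.
#' @param dist_deg angular distance (degrees), vector.
#' @return data.frame with `az_deg`, `el_deg` of the destination.
#' @export
gc_dest <- function(az_deg, el_deg, bearing_deg, dist_deg) {
  out <- gc_dest_num(az_deg, el_deg, bearing_deg, dist_deg)
  data.frame(az_deg = out[[1]], el_deg = out[[2]])
}

# numeric-core destination (list of az, el vectors); avoids data.frame
# overhead in per-event loops
gc_dest_num <- function(az_deg, el_deg, bearing_deg, dist_deg) {
  el1 <- el_deg * DEG
  brg <- bearing_deg * DEG
  d <- dist_deg * DEG
  sin_el2 <- sin(el1) * cos(d) + cos(el1) * sin(d) * cos(brg)
  sin_el2 <- pmin(1, pmax(-1, sin_el2))
  el2 <- asin(sin_el2)
  daz <- atan2(sin(brg) * sin(d) * cos(el1), cos(d) - sin(el1) * sin_el2)
  az2 <- az_deg * DEG + daz
  list(((az2 / DEG + 180) %% 360) - 180, el2 / DEG)
}

# --- quaternions -----------------------------------------------------------

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) matrix(q, ncol = 4) else as.matrix(q)
}

#' Quaternion from axis and angle
#'
#' @param axis length-3 unit axis (a common choice is `c(0, 1, 0)` for yaw).
#' @param angle_deg rotation angles in degrees (vectorized).
#' @return matrix with columns w, x, y, z.
#' @export
quat_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * DEG / 2
  cbind(w = cos(half), x = sin(half) * axis[1],
        y = sin(half) * axis[2], z = sin(half) * axis[3])
}

#' Hamilton product of quaternions (rowwise)
#'
#' @param q1,q2 quaternion matrices (columns w, x, y, z); rows recycled if
#'   one input has a single row.
#' @return quaternion matrix `q1 * q2`.
#' @export
quat_mul <- function(q1, q2) {
  q1 <- as_quat_matrix(q1); q2 <- as_quat_matrix(q2)
  if (nrow(q1) == 1L && nrow(q2) > 1L) q1 <- q1[rep(1L, nrow(q2)), , drop = FALSE]
  if (nrow(q2) == 1L && nrow(q1) > 1L) q2 <- q2[rep(1L, nrow(q1)), , drop = FALSE]
  w1 <- q1[, 1]; x1 <- q1[, 2]; y1 <- q1[, 3]; z1 <- q1[, 4]
  w2 <- q2[, 1]; x2 <- q2[, 2]; y2 <- q2[, 3]; z2 <- q2[, 4]
  cbind(w = w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        x = w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        y = w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        z = w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' Quaternion conjugate
#' @param q quaternion matrix.
#' @return conjugated quaternion matrix.
#' @export
quat_conj <- function(q) {
  q <- as_quat_matrix(q)
  cbind(w = q[, 1], x = -q[, 2], y = -q[, 3], z = -q[, 4])
}

#' Rotate vectors by unit quaternions (rowwise)
#'
#' Computes `q v q*` for each row; `q` must be (approximately) unit norm.
#'
#' @param q quaternion matrix (columns w, x, y, z), one row or one per vector.
#' @param v matrix of 3-vectors (columns x, y, z).
#' @return rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat_matrix(q); v <- as_dir_matrix(v)
  if (nrow(q) == 1L && nrow(v) > 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
  qn <- rowSums(q^2)
  if (any(qn < 1e-12)) {
    stop_vrgaze("zero-norm quaternion", class = "vrgaze_geometry_error")
  }
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  # v' = v + 2 u x (u x v + w v), exact for unit quaternions
  cross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  t1 <- cross(u, v) + w * v
  out <- v + 2 * cross(u, t1)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Geodesic angle between successive quaternions
#'
#' Angle of the relative rotation `q1^-1 q2`, in degrees; used for
#' head-rotation metrics.
#'
#' @param q1,q2 quaternion matrices (rows paired).
#' @return rotation angles in degrees.
#' @export
quat_angle_deg <- function(q1, q2) {
  q1 <- as_quat_matrix(q1); q2 <- as_quat_matrix(q2)
  dot <- abs(rowSums(q1 * q2))
  2 * acos(pmin(1, dot)) / DEG
}

#' Spherical linear interpolation between two unit directions
#'
#' @param u,v unit 3-vectors (single rows) delimiting the arc.
#' @param f interpolation fractions in `[0, 1]` (vectorized).
#' @return matrix of interpolated unit vectors.
#' @export
slerp_dir <- function(u, v, f) {
  u <- as.numeric(u); v <- as.numeric(v)
  dot <- max(-1, min(1, sum(u * v)))
  omega <- acos(dot)
  if (omega < 1e-9) {
    out <- outer(rep(1, length(f)), u)
  } else {
    a <- sin((1 - f) * omega) / sin(omega)
    b <- sin(f * omega) / sin(omega)
    out <- outer(a, u) + outer(b, v)
  }
  colnames(out) <- c("x", "y", "z")
  out
}
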
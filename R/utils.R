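`%||%` <- function(a, b) if (is.null(a)) b else a

#' Homogeneous translation matrix
#' @param v length-3 translation (mm)
#' @return 4x4 matrix
#' @keywords internal
translation_matrix <- function(v) {
  M <- diag(4)
  M[1:3, 4] <- v
  M
}

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Compose a rotation matrix from extrinsic x-y-z Euler angles
#'
#' Convention: R = Rz(rz) Ry(ry) Rx(rx), angles in radians, matching the
#' column order of FSL-style 6-parameter motion files (rx, ry, rz).
#' @param angles length-3 numeric (radians)
#' @return 3x3 rotation matrix
#' @export
euler_to_rotation <- function(angles) {
  rot_z(angles[3]) %*% rot_y(angles[2]) %*% rot_x(angles[1])
}

#' Decompose a rotation matrix into extrinsic x-y-z Euler angles
#'
#' Inverse of [euler_to_rotation()]; gimbal lock (|ry| = pi/2) resolves with
#' rz = 0.
#' @param R 3x3 rotation matrix
#' @return length-3 numeric (rx, ry, rz) in radians
#' @export
rotation_to_euler <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ry <- asin(sy)
  if (abs(abs(sy) - 1) < 1e-12) {
    # gimbal lock: only rx +- rz determined
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  } else {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  }
  c(rx, ry, rz)
}

#' Check that a 4x4 homogeneous matrix is a rigid-body transform
#' @param M 4x4 matrix
#' @param tol orthonormality tolerance
#' @keywords internal
is_rigid_matrix <- function(M, tol = 1e-8) {
  if (!is.matrix(M) || any(dim(M) != 4)) return(FALSE)
  R <- M[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol) return(FALSE)
  if (abs(det(R) - 1) > 1e-6) return(FALSE)
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > tol) return(FALSE)
  TRUE
}

#' World coordinates of voxels
#'
#' Converts 1-based array indices to world coordinates (mm) through a
#' NIfTI-style affine (which maps 0-based voxel indices to world space).
#' @param idx integer matrix (n x 3) of 1-based voxel indices
#' @param affine 4x4 voxel-to-world matrix
#' @return n x 3 matrix of world coordinates
#' @keywords internal
voxel_to_world_coords <- function(idx, affine) {
  h <- cbind(idx - 1, 1)
  h %*% t(affine[1:3, , drop = FALSE])
}

# deterministic integer sub-seeds derived from one master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

stop_rdi <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_rdi <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
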
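# shared fixture builders; everything is generated in code at test time

# homogeneous translation
tmat <- function(v) {
  M <- diag(4)
  M[1:3, 4] <- v
  M
}

# rotation by `angle` about `axis` through point `center`
rmat <- function(axis, angle, center = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  M <- diag(4)
  M[1:3, 1:3] <- R
  tmat(center) %*% M %*% tmat(-center)
}

# random rigid transform with bounded rotation/translation
random_rigid <- function(max_angle = 0.05, max_trans = 1) {
  ax <- stats::rnorm(3)
  rmat(ax, stats::runif(1, -max_angle, max_angle),
       center = stats::runif(3, -10, 10)) %*%
    tmat(stats::runif(3, -max_trans, max_trans))
}

# rigid series from a list of matrices, identity injected at the reference
series_from <- function(mats, affine = diag(4), ref = NULL) {
  n <- length(mats)
  ref <- ref %||% ((n + 1L) %/% 2L)
  mats[[ref]] <- diag(4)
  rigid_motion_series(mats, affine, ref)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# cube mask with a world affine whose origin is at the grid centre
cube_mask <- function(n = 8, voxel = 2) {
  affine <- diag(c(rep(voxel, 3), 1))
  affine[1:3, 4] <- -voxel * (n - 1) / 2
  list(mask = array(TRUE, c(n, n, n)), affine = affine)
}

# brute-force voxel-wise displacement derivative via explicit homogeneous
# coordinate multiplication (the independent oracle)
brute_displacement <- function(series, mask) {
  idx <- which(mask, arr.ind = TRUE)
  Tn <- series$n_frames
  D <- matrix(0, nrow(idx), Tn)
  d_prev <- numeric(nrow(idx))
  for (t in seq_len(Tn)) {
    Minv <- solve(series$transforms[[t]])
    d <- numeric(nrow(idx))
    for (v in seq_len(nrow(idx))) {
      x <- series$voxel_to_world %*% c(idx[v, ] - 1, 1)
      y <- Minv %*% x
      d[v] <- sqrt(sum((y[1:3] - x[1:3])^2))
    }
    if (t > 1) D[, t] <- abs(d - d_prev)
    d_prev <- d
  }
  D
}

# small random label atlas over a mask (contiguous ids, all non-empty)
random_labels <- function(mask, n_regions, seed = 1) {
  set.seed(seed)
  lab <- array(0L, dim(mask))
  v <- which(mask)
  lab[v] <- as.integer(sample(rep_len(seq_len(n_regions), length(v))))
  lab
}

# tiny cohort spec used by the fast end-to-end tests
tiny_spec <- function(...) {
  cohort_spec(n_per_group = c(8, 8), n_frames = 60, grid = c(16, 16, 16),
              n_regions = 8, ...)
}
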
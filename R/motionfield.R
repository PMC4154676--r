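#' Rigid motion series
#'
#' Container for the per-frame rigid-body realignment transforms of one
#' subject, expressed about the world-coordinate origin, with the transform
#' at the reference frame equal to the identity.
#'
#' @param transforms list of 4x4 homogeneous rigid-body matrices (mm, world
#'   coordinates), one per retained frame
#' @param voxel_to_world 4x4 affine of the image grid
#' @param reference_index index of the realignment target frame; default
#'   mid-series
#' @param tol tolerance for the rigidity and identity checks
#' @return object of class `rigid_motion_series`
#' @export
rigid_motion_series <- function(transforms, voxel_to_world,
                                reference_index = NULL, tol = 1e-8) {
  n <- length(transforms)
  if (n < 2) stop_rdi("a rigid motion series needs at least 2 frames")
  reference_index <- reference_index %||% ((n + 1L) %/% 2L)
  for (i in seq_len(n)) {
    if (!is_rigid_matrix(transforms[[i]], tol))
      stop_rdi("invalid transform: matrix %d is not rigid", i)
  }
  Mref <- transforms[[reference_index]]
  if (max(abs(Mref - diag(4))) > tol)
    stop_rdi("transform at reference_index %d is not the identity",
             reference_index)
  structure(list(transforms = transforms,
                 reference_index = reference_index,
                 voxel_to_world = voxel_to_world,
                 n_frames = n),
            class = "rigid_motion_series")
}

#' @export
print.rigid_motion_series <- function(x, ...) {
  cat("Rigid motion series:", x$n_frames, "frames, reference at frame",
      x$reference_index, "\n")
  p <- motion_parameters(x)
  cat(sprintf("  max |translation| %.4f mm, max |rotation| %.5f rad\n",
              max(abs(p[, 4:6])), max(abs(p[, 1:3]))))
  invisible(x)
}

#' Load rigid-body realignment transforms
#'
#' Reads a set of MCFLIRT-style `.mat` files (one 4x4 whitespace-separated
#' text matrix per frame) or a single 6-column `.par` file (rx, ry, rz in
#' radians, tx, ty, tz in mm), re-expresses the transforms about the
#' world-coordinate origin, and normalises the series so the transform at
#' the reference frame is the identity.
#'
#' A transform file written about a different origin (for example the image
#' centre) represents the mapping x -> R (x - c) + c + t; supplying that
#' origin `c` through `origin` rewrites it as a single homogeneous matrix
#' about the world origin, which maps every world point identically.
#'
#' @param paths character vector of `.mat` file paths (ordered by frame), or
#'   a single `.par` path
#' @param voxel_to_world 4x4 affine of the image grid
#' @param reference_index realignment target frame (default mid-series)
#' @param origin length-3 world point the file transforms are expressed
#'   about (default the world origin, i.e. matrices are used as-is)
#' @param n_frames_expected optional frame count of the matching image; a
#'   mismatch is an error
#' @param drop number of leading frames to discard (T1 equilibration);
#'   default 0
#' @return [rigid_motion_series()]
#' @export
load_rigid_transforms <- function(paths, voxel_to_world,
                                  reference_index = NULL,
                                  origin = c(0, 0, 0),
                                  n_frames_expected = NULL,
                                  drop = 0L) {
  if (length(paths) == 1L && grepl("\\.par$", paths)) {
    pars <- as.matrix(utils::read.table(paths))
    mats <- lapply(seq_len(nrow(pars)), function(i) {
      M <- diag(4)
      M[1:3, 1:3] <- euler_to_rotation(pars[i, 1:3])
      M[1:3, 4] <- pars[i, 4:6]
      M
    })
  } else {
    mats <- lapply(paths, function(p) {
      v <- scan(p, quiet = TRUE)
      if (length(v) != 16)
        stop_rdi("invalid transform: %s does not parse to a 4x4 matrix", p)
      matrix(v, 4, 4, byrow = TRUE)
    })
  }
  if (!is.null(n_frames_expected) && length(mats) != n_frames_expected + drop &&
      length(mats) != n_frames_expected)
    stop_rdi("length mismatch: %d transforms for %d image frames",
             length(mats), n_frames_expected)
  if (drop > 0) mats <- mats[-seq_len(drop)]
  if (any(abs(origin) > 0)) {
    To <- translation_matrix(origin)
    Ti <- translation_matrix(-origin)
    mats <- lapply(mats, function(M) To %*% M %*% Ti)
  }
  for (i in seq_along(mats)) {
    if (!is_rigid_matrix(mats[[i]], 1e-6))
      stop_rdi("invalid transform: matrix %d is not rigid", i)
  }
  n <- length(mats)
  reference_index <- reference_index %||% ((n + 1L) %/% 2L)
  Mref_inv <- solve(mats[[reference_index]])
  mats <- lapply(mats, function(M) M %*% Mref_inv)
  mats[[reference_index]] <- diag(4) # exact identity, not just numerical
  rigid_motion_series(mats, voxel_to_world, reference_index, tol = 1e-6)
}

#' Six rigid-body motion parameters per frame
#'
#' Decomposes each transform into 3 rotations (radians, extrinsic x-y-z)
#' and 3 translations (mm), FSL column order (rx, ry, rz, tx, ty, tz).
#' @param series [rigid_motion_series()]
#' @return n_frames x 6 matrix
#' @export
motion_parameters <- function(series) {
  out <- t(vapply(series$transforms, function(M) {
    c(rotation_to_euler(M[1:3, 1:3]), M[1:3, 4])
  }, numeric(6)))
  colnames(out) <- c("rx", "ry", "rz", "tx", "ty", "tz")
  out
}

#' Voxel-wise displacement derivative field
#'
#' For every voxel in the mask with world position x, the per-frame
#' displacement relative to the reference frame is
#' d_t(x) = ||inv(T_t) x - x||, i.e. the position change experienced by the
#' tissue at x when the realignment transform of frame t is undone. The
#' stored field is the first temporal derivative of that local displacement
#' time series, D_t(x) = |d_t(x) - d_{t-1}(x)|, with D at the first frame
#' defined as 0 (no predecessor).
#'
#' @param series [rigid_motion_series()]
#' @param mask 3-D logical array on the series' grid
#' @param norm `"euclidean"` (default) takes the Euclidean norm of the
#'   3-vector position change; `"rms"` divides by sqrt(3) (per-coordinate
#'   root mean square)
#' @param signed keep the sign of the derivative instead of its absolute
#'   value (diagnostic use)
#' @param frame_to_frame use ||inv(T_t) x - inv(T_{t-1}) x|| directly as the
#'   frame-to-frame displacement instead of differentiating the
#'   distance-to-reference series
#' @return object of class `displacement_field` with elements `deriv`
#'   (n_voxel x n_frame matrix, mm/frame), `mask`, `vox` (voxel indices),
#'   `affine`, `n_frames`
#' @export
voxelwise_displacement <- function(series, mask,
                                   norm = c("euclidean", "rms"),
                                   signed = FALSE,
                                   frame_to_frame = FALSE) {
  norm <- match.arg(norm)
  if (!any(mask)) stop_rdi("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  XW <- cbind(voxel_to_world_coords(idx, series$voxel_to_world), 1)
  Tn <- series$n_frames
  V <- nrow(XW)
  scale <- if (norm == "rms") 1 / sqrt(3) else 1
  # one block multiply for all frames: rows 3t-2..3t hold inv(T_t) - I
  Ball <- do.call(rbind, lapply(series$transforms, function(M) {
    B <- solve(M) - diag(4)
    B[1:3, , drop = FALSE]
  }))
  P2 <- (XW %*% t(Ball))^2                     # V x 3T squared components
  i1 <- seq(1, 3 * Tn, by = 3)
  dmat <- sqrt(P2[, i1, drop = FALSE] + P2[, i1 + 1, drop = FALSE] +
                 P2[, i1 + 2, drop = FALSE]) * scale           # d_t(x)
  if (frame_to_frame) {
    # ||inv(T_t) x - inv(T_{t-1}) x||: consecutive position differences
    Pos <- XW %*% t(Ball)
    D <- matrix(0, V, Tn)
    for (t in 2:Tn) {
      s3 <- Pos[, (3 * t - 2):(3 * t)] - Pos[, (3 * t - 5):(3 * t - 3)]
      D[, t] <- sqrt(rowSums(s3^2)) * scale
    }
  } else {
    D <- cbind(0, dmat[, -1, drop = FALSE] - dmat[, -Tn, drop = FALSE])
    if (!signed) D <- abs(D)
  }
  structure(list(deriv = D, mask = mask, vox = idx,
                 affine = series$voxel_to_world, n_frames = Tn),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat("Displacement derivative field:", nrow(x$deriv), "voxels x",
      x$n_frames, "frames\n")
  cat(sprintf("  mean FD %.4f mm/frame\n", mean(frame_displacement(x))))
  invisible(x)
}

#' Expand a displacement field to a 4-D array
#' @param field [voxelwise_displacement()] result
#' @return 4-D numeric array (grid x frames), zero outside the mask
#' @export
field_as_array <- function(field) {
  dm <- dim(field$mask)
  out <- array(0, c(dm, field$n_frames))
  flat <- (field$vox[, 3] - 1) * dm[1] * dm[2] +
    (field$vox[, 2] - 1) * dm[1] + field$vox[, 1]
  step <- prod(dm)
  for (t in seq_len(field$n_frames))
    out[flat + (t - 1) * step] <- field$deriv[, t]
  out
}

#' Frame-wise displacement (FD)
#'
#' Spatial mean of the voxel-wise displacement derivative over the brain
#' mask, per frame.
#' @param field [voxelwise_displacement()] result
#' @return numeric vector (mm/frame), first element 0
#' @export
frame_displacement <- function(field) {
  colMeans(field$deriv)
}

# labels of the field's mask voxels under an atlas (same grid)
field_labels <- function(field, atlas) {
  lab <- if (is.array(atlas)) atlas else atlas$labels
  if (!all(dim(lab) == dim(field$mask)))
    stop_rdi("atlas grid does not match the displacement field grid")
  lab[field$vox]
}

#' Regional displacement (RD) time courses
#'
#' Mean voxel-wise displacement derivative over each labelled region, per
#' frame. Regions are taken from the atlas restricted to the field's mask;
#' a region with no masked voxels is an error.
#' @param field [voxelwise_displacement()] result
#' @param atlas [label_atlas()] or 3-D integer label array (0 = background)
#' @return region x frame matrix with region ids as rownames
#' @export
regional_displacement <- function(field, atlas) {
  lab <- field_labels(field, atlas)
  ids <- if (is.array(atlas)) sort(unique(lab[lab > 0L])) else atlas$table$id
  keep <- lab > 0L
  missing <- setdiff(ids, unique(lab[keep]))
  if (length(missing))
    stop_rdi("empty region: %s has no voxels inside the mask",
             paste(missing, collapse = ", "))
  sums <- rowsum(field$deriv[keep, , drop = FALSE], lab[keep])
  counts <- as.vector(table(factor(lab[keep], levels = rownames(sums))))
  rd <- sums / counts
  rd[as.character(ids), , drop = FALSE]
}

#' Differential regional displacement (deltaRD)
#'
#' Temporal average of RD minus FD per region: the per-region scalar motion
#' covariate entering the RDI second-level model. Frames are the retained
#' frames (leading volumes already discarded upstream).
#' @param rd region x frame RD matrix
#' @param fd per-frame FD vector
#' @return named numeric vector, one value per region (mm)
#' @export
delta_rd <- function(rd, fd) {
  if (ncol(rd) != length(fd))
    stop_rdi("length mismatch: RD has %d frames, FD has %d",
             ncol(rd), length(fd))
  rowMeans(sweep(rd, 2, fd))
}

#' Motion summary of one subject
#'
#' Bundles FD, RD, deltaRD, mean FD and the temporally averaged voxel-wise
#' displacement map (the per-subject map whose group means enter the
#' rho_groups spatial correlation).
#' @param field [voxelwise_displacement()] result
#' @param atlas optional [label_atlas()] for the regional measures
#' @return object of class `motion_summary`
#' @export
motion_summary <- function(field, atlas = NULL) {
  fd <- frame_displacement(field)
  rd <- if (!is.null(atlas)) regional_displacement(field, atlas) else NULL
  structure(list(fd = fd,
                 rd = rd,
                 delta_rd = if (!is.null(rd)) delta_rd(rd, fd) else NULL,
                 mean_fd = mean(fd),
                 mean_voxel_map = rowMeans(field$deriv),
                 vox = field$vox,
                 mask_dim = dim(field$mask)),
            class = "motion_summary")
}

#' @export
print.motion_summary <- function(x, ...) {
  cat(sprintf("Motion summary: mean FD %.4f mm over %d frames\n",
              x$mean_fd, length(x$fd)))
  if (!is.null(x$rd))
    cat(sprintf("  %d regions, deltaRD range [%.5f, %.5f] mm\n",
                nrow(x$rd), min(x$delta_rd), max(x$delta_rd)))
  invisible(x)
}
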
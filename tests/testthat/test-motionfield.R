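test_that("rigid transform loading handles identities, translations and re-origin", {
  dir <- withr::local_tempdir()
  write_m <- function(M, i) {
    f <- file.path(dir, sprintf("MAT_%04d", i))
    writeLines(apply(M, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), f)
    f
  }
  paths <- vapply(1:5, function(i) write_m(diag(4), i), character(1))
  s <- load_rigid_transforms(paths, diag(4))
  expect_equal(s$n_frames, 5)
  for (M in s$transforms) expect_equal(M, diag(4))

  paths2 <- c(write_m(diag(4), 10), write_m(tmat(c(3, 0, 0)), 11),
              write_m(diag(4), 12))
  s2 <- load_rigid_transforms(paths2, diag(4), reference_index = 1)
  expect_equal(s2$transforms[[2]][1:3, 4], c(3, 0, 0))

  # rotation written about the image centre, re-expressed about the world
  # origin: both forms must map any world point identically
  ctr <- c(12, -5, 7)
  Rc <- rmat(c(0, 0, 1), 0.03)            # as stored in the file (about ctr)
  paths3 <- c(write_m(diag(4), 20), write_m(Rc, 21))
  s3 <- load_rigid_transforms(paths3, diag(4), reference_index = 1,
                              origin = ctr)
  for (k in 1:20) {
    x <- c(stats::runif(3, -40, 40), 1)
    expect_equal(as.vector(s3$transforms[[2]] %*% x),
                 as.vector(tmat(ctr) %*% Rc %*% tmat(-ctr) %*% x),
                 tolerance = 1e-12)
  }
})

test_that("non-rigid input and frame-count mismatch are rejected", {
  dir <- withr::local_tempdir()
  bad <- diag(4); bad[1, 1] <- 2
  f <- file.path(dir, "MAT_0000"); write(t(bad), f, ncolumns = 4)
  g <- file.path(dir, "MAT_0001"); write(t(diag(4)), g, ncolumns = 4)
  expect_error(load_rigid_transforms(c(f, g), diag(4)), "invalid transform")
  expect_error(
    load_rigid_transforms(c(g, g, g), diag(4), n_frames_expected = 7),
    "length mismatch")
})

test_that(".par files reproduce the matrices they encode", {
  dir <- withr::local_tempdir()
  pars <- rbind(c(0, 0, 0, 0, 0, 0),
                c(0.01, -0.02, 0.005, 1.5, -0.3, 0.8),
                c(0, 0, 0, 0, 0, 0))
  f <- file.path(dir, "mc.par")
  write.table(pars, f, row.names = FALSE, col.names = FALSE)
  s <- load_rigid_transforms(f, diag(4), reference_index = 1)
  M <- s$transforms[[2]]
  expect_equal(M[1:3, 1:3], euler_to_rotation(pars[2, 1:3]), tolerance = 1e-10)
  expect_equal(M[1:3, 4], pars[2, 4:6], tolerance = 1e-10)
})

test_that("voxel-wise displacement matches closed forms and the brute-force oracle", {
  cm <- cube_mask(6, 2)
  # identity series -> zero field
  s0 <- series_from(replicate(4, diag(4), simplify = FALSE), cm$affine)
  f0 <- voxelwise_displacement(s0, cm$mask)
  expect_true(all(f0$deriv == 0))

  # pure translation at frame 3 (prev identity): spatially constant 3 mm
  mats <- replicate(4, diag(4), simplify = FALSE)
  mats[[3]] <- tmat(c(3, 0, 0))
  st <- series_from(mats, cm$affine, ref = 1)
  ft <- voxelwise_displacement(st, cm$mask)
  expect_equal(ft$deriv[, 3], rep(3, nrow(ft$deriv)), tolerance = 1e-12)
  expect_equal(ft$deriv[, 4], rep(3, nrow(ft$deriv)), tolerance = 1e-12)

  # rotation 0.02 rad about z through the origin: chord length at radius r
  # is 2 r sin(theta/2); check the voxel at world (50, 0, 0)
  aff <- diag(4); aff[1:3, 4] <- c(50, 0, 0)  # single voxel at (50,0,0)
  mask1 <- array(TRUE, c(1, 1, 1))
  mats <- list(diag(4), rmat(c(0, 0, 1), 0.02))
  sr <- series_from(mats, aff, ref = 1)
  fr <- voxelwise_displacement(sr, mask1)
  expect_equal(fr$deriv[1, 2], 2 * 50 * sin(0.01), tolerance = 1e-10)

  # random rigid series vs explicit homogeneous-coordinate oracle
  set.seed(42)
  mats <- c(list(diag(4)), replicate(3, random_rigid(), simplify = FALSE))
  sx <- series_from(mats, cm$affine, ref = 1)
  fx <- voxelwise_displacement(sx, cm$mask)
  expect_equal(fx$deriv, brute_displacement(sx, cm$mask), tolerance = 1e-10)

  expect_error(voxelwise_displacement(sx, array(FALSE, c(6, 6, 6))),
               "empty mask")
})

test_that("rotation fields scale linearly with distance from the axis", {
  cm <- cube_mask(10, 4)
  th <- 0.05
  mats <- list(diag(4), rmat(c(0, 0, 1), th))
  s <- series_from(mats, cm$affine, ref = 1)
  f <- voxelwise_displacement(s, cm$mask)
  w <- cbind(f$vox - 1, 1) %*% t(cm$affine[1:3, ])
  r_axis <- sqrt(w[, 1]^2 + w[, 2]^2)
  expect_equal(f$deriv[, 2], 2 * sin(th / 2) * r_axis, tolerance = 1e-8)
})

test_that("norm, sign and frame-to-frame options behave as documented", {
  cm <- cube_mask(5, 3)
  set.seed(7)
  mats <- c(list(diag(4)), replicate(4, random_rigid(), simplify = FALSE))
  s <- series_from(mats, cm$affine, ref = 1)
  f_eu <- voxelwise_displacement(s, cm$mask)
  f_rms <- voxelwise_displacement(s, cm$mask, norm = "rms")
  expect_equal(f_rms$deriv, f_eu$deriv / sqrt(3), tolerance = 1e-12)
  f_sgn <- voxelwise_displacement(s, cm$mask, signed = TRUE)
  expect_equal(abs(f_sgn$deriv), f_eu$deriv, tolerance = 1e-12)
  expect_true(any(f_sgn$deriv < 0))
  # frame-to-frame distance upper-bounds the derivative of the distance
  f_ftf <- voxelwise_displacement(s, cm$mask, frame_to_frame = TRUE)
  expect_true(all(f_ftf$deriv >= f_eu$deriv - 1e-12))
})

test_that("FD, RD and deltaRD match brute-force aggregation", {
  cm <- cube_mask(6, 2)
  set.seed(3)
  mats <- c(list(diag(4)), replicate(5, random_rigid(), simplify = FALSE))
  s <- series_from(mats, cm$affine, ref = 2)
  f <- voxelwise_displacement(s, cm$mask)
  fd <- frame_displacement(f)
  expect_equal(fd, apply(f$deriv, 2, mean), tolerance = 1e-12)
  expect_equal(fd[1], 0)

  lab <- random_labels(cm$mask, 5, seed = 9)
  rd <- regional_displacement(f, lab)
  labv <- lab[f$vox]
  for (r in 1:5)
    expect_equal(rd[r, ], colMeans(f$deriv[labv == r, , drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)

  # whole-mask region: RD == FD and deltaRD == 0
  whole <- array(1L, dim(cm$mask))
  rd1 <- regional_displacement(f, whole)
  expect_equal(as.vector(rd1[1, ]), fd, tolerance = 1e-10)
  expect_equal(unname(delta_rd(rd1, fd)), 0, tolerance = 1e-10)

  # single-voxel region equals that voxel's series
  lab1 <- array(0L, dim(cm$mask)); lab1[2, 3, 4] <- 1L
  rds <- regional_displacement(f, lab1)
  v <- which(f$vox[, 1] == 2 & f$vox[, 2] == 3 & f$vox[, 3] == 4)
  expect_equal(as.vector(rds[1, ]), f$deriv[v, ], tolerance = 1e-12)

  # deltaRD: brute force and the constant-offset case
  drd <- delta_rd(rd, fd)
  for (r in 1:5)
    expect_equal(drd[[r]], mean(rd[r, ] - fd), tolerance = 1e-12)
  rd_off <- sweep(matrix(fd, 3, length(fd), byrow = TRUE), 1, c(0.01, 0, -0.02), `+`)
  expect_equal(unname(delta_rd(rd_off, fd)), c(0.01, 0, -0.02), tolerance = 1e-12)
  expect_error(delta_rd(rd[, -1], fd), "length mismatch")

  # voxel-count weighting: weighted mean of RD rows is FD, weighted deltaRD sums to 0
  cnt <- as.vector(table(labv))
  expect_equal(colSums(rd * cnt) / sum(cnt), fd, tolerance = 1e-10)
  expect_equal(sum(drd * cnt) / sum(cnt), 0, tolerance = 1e-10)

  # empty region error: all of region 2's voxels fall outside the mask
  mask2 <- cm$mask; mask2[lab == 2L] <- FALSE
  f2 <- voxelwise_displacement(s, mask2)
  expect_error(regional_displacement(f2, label_atlas(lab)), "empty region")
})

test_that("motion summary bundles the per-subject measures coherently", {
  cm <- cube_mask(6, 2)
  set.seed(5)
  mats <- c(list(diag(4)), replicate(3, random_rigid(), simplify = FALSE))
  s <- series_from(mats, cm$affine, ref = 1)
  f <- voxelwise_displacement(s, cm$mask)
  ms <- motion_summary(f, random_labels(cm$mask, 3, seed = 2))
  expect_equal(ms$mean_fd, mean(ms$fd))
  expect_equal(ms$mean_voxel_map, rowMeans(f$deriv))
  expect_equal(ms$delta_rd, delta_rd(ms$rd, ms$fd))
})
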
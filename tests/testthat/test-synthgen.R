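test_that("simulated motion matches the AR(1) closed form and is seed-deterministic", {
  # sigma = 0 -> identity series
  s0 <- simulate_motion(motion_phenotype(sigma = 0), 10, seed = 1)
  for (M in s0$transforms) expect_equal(M, diag(4), tolerance = 1e-12)

  # fixed seed -> bit-identical series
  ph <- motion_phenotype()
  s1 <- simulate_motion(ph, 50, seed = 3)
  s2 <- simulate_motion(ph, 50, seed = 3)
  expect_identical(s1$transforms, s2$transforms)
  expect_equal(s1$reference_index, 25)

  # stationary variance of the parameter series: sigma^2 / (1 - phi^2)
  phi <- 0.8; s_inn <- 0.01
  x <- rdiconn:::ar1_series(10000, phi, s_inn)
  expect_equal(var(x), s_inn^2 / (1 - phi^2), tolerance = 0.1)

  expect_error(motion_phenotype(sigma = -1), "nonnegative")
  expect_error(motion_phenotype(phi = 1), "phi")
})

test_that("the phantom partitions an ellipsoid into contiguous parcels", {
  ph <- make_phantom(grid = c(16, 16, 16), n_regions = 6, seed = 2)
  lab <- ph$atlas$labels
  # parcels partition the shell: counts sum to labelled voxels
  expect_equal(sum(ph$atlas$table$n_voxels), sum(lab > 0))
  # parcels, wm and csf are disjoint and inside the mask
  expect_true(all(ph$mask[lab > 0]))
  expect_false(any(ph$wm & ph$csf))
  expect_false(any(ph$wm[lab > 0] | ph$csf[lab > 0]))

  # contiguity oracle: flood fill each parcel from one seed voxel
  connected <- function(region) {
    vox <- which(lab == region, arr.ind = TRUE)
    n <- nrow(vox)
    key <- function(v) paste(v[, 1], v[, 2], v[, 3])
    all_keys <- key(vox)
    seen <- structure(rep(FALSE, n), names = all_keys)
    queue <- all_keys[1]; seen[queue] <- TRUE
    shifts <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
    while (length(queue)) {
      v <- as.integer(strsplit(queue[1], " ")[[1]]); queue <- queue[-1]
      nb <- key(sweep(shifts, 2, v, `+`))
      hit <- nb[nb %in% all_keys & !seen[nb]]
      seen[hit] <- TRUE
      queue <- c(queue, hit)
    }
    all(seen)
  }
  for (r in ph$atlas$table$id) expect_true(connected(r), label = paste("region", r))

  # single-region phantom covers the whole shell
  ph1 <- make_phantom(grid = c(12, 12, 12), n_regions = 1, seed = 3)
  expect_equal(nrow(ph1$atlas$table), 1)
  expect_error(make_phantom(grid = c(3, 3, 3)), "degenerate grid")
})

test_that("latent correlations are reproduced exactly in the noise-free limit", {
  ph <- make_phantom(grid = c(14, 14, 14), n_regions = 6, seed = 4)
  S <- rdiconn:::default_latent_corr(ph$centers)
  mats <- c(list(diag(4)),
            replicate(499, random_rigid(0.002, 0.02), simplify = FALSE))
  ser <- series_from(mats, ph$affine, ref = 1)
  f <- voxelwise_displacement(ser, ph$mask)
  sim <- simulate_bold(f, ph, S, gamma = 0, noise_sd = 0, tr = 2, seed = 5)
  got <- cor(t(sim$roi$data))
  expect_equal(got[upper.tri(got)], S[upper.tri(S)], tolerance = 0.05)
  # seed determinism
  sim2 <- simulate_bold(f, ph, S, gamma = 0, noise_sd = 0, tr = 2, seed = 5)
  expect_identical(sim$roi$data, sim2$roi$data)
})

test_that("ROI fast path equals ROI-averaging of the voxel model exactly", {
  ph <- make_phantom(grid = c(14, 14, 14), n_regions = 5, seed = 6)
  set.seed(7)
  mats <- c(list(diag(4)),
            replicate(29, random_rigid(0.01, 0.1), simplify = FALSE))
  ser <- series_from(mats, ph$affine, ref = 1)
  f <- voxelwise_displacement(ser, ph$mask)
  S <- rdiconn:::default_latent_corr(ph$centers)
  sim <- simulate_bold(f, ph, S, gamma = 8, noise_sd = 0, tr = 2,
                       voxels = TRUE, baseline = 0, seed = 8)
  roi_from_vox <- roi_timecourses(sim$img, ph$atlas, tr = 2)
  expect_equal(roi_from_vox$data, sim$roi$data, tolerance = 1e-12)
})

test_that("the artifact shifts connectivity in the direction of the deltaRD product", {
  # off-centre rotations create regions with high vs low displacement; a
  # positive displacement-coupled artifact adds shared variance to region
  # pairs in proportion to their displacement, so Fisher-Z between
  # high-displacement pairs rises relative to the gamma = 0 case
  ph <- make_phantom(grid = c(16, 16, 16), n_regions = 8, seed = 9)
  set.seed(10)
  ser <- simulate_motion(motion_phenotype(sigma = 2,
                                          rotation_center = c(0, 0, 35)),
                         150, ph$affine, seed = 11)
  f <- voxelwise_displacement(ser, ph$mask)
  S <- diag(8)                                 # independent latents
  z_at <- function(g) {
    sim <- simulate_bold(f, ph, S, gamma = g, noise_sd = 0, tr = 2, seed = 12)
    atanh(cor(t(sim$roi$data)))
  }
  z0 <- z_at(0); z1 <- z_at(12)
  rd <- regional_displacement(f, ph$atlas)
  drd <- delta_rd(rd, frame_displacement(f))
  hi <- order(drd, decreasing = TRUE)[1:2]     # most-displaced pair
  expect_gt(z1[hi[1], hi[2]], z0[hi[1], hi[2]])
})

test_that("cohort generation is deterministic, validated, and phenotype-sensitive", {
  expect_error(cohort_spec(n_per_group = c(0, 5)), "nonempty")
  expect_error(cohort_spec(n_frames = 10), "at least 20")

  sp <- tiny_spec(seed = 13)
  c1 <- generate_cohort(sp)
  c2 <- generate_cohort(sp)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$subjects[[3]]$bold$data, c2$subjects[[3]]$bold$data)
  expect_identical(c1$pheno, c2$pheno)

  # matched phenotypes: group-mean displacement maps nearly parallel
  rho_of <- function(coh) {
    maps <- cohort_mean_maps(coh)
    g <- coh$pheno$group
    cor(colMeans(maps[g == 0, ]), colMeans(maps[g == 1, ]))
  }
  # group-mean map similarity needs the full-size averaging (2 x 30); the
  # distinct-centre condition flips the spatial pattern entirely
  rho_matched <- vapply(1:3, function(i)
    rho_of(generate_cohort(cohort_spec(seed = 50 + i))), numeric(1))
  rho_distinct <- vapply(1:3, function(i)
    rho_of(generate_cohort(cohort_spec(
      phenotype1 = motion_phenotype(rotation_center = c(0, 0, 40)),
      phenotype2 = motion_phenotype(rotation_center = c(0, 0, -40)),
      seed = 50 + i))), numeric(1))
  # with per-subject rotation-centre heterogeneity, matched random splits
  # land in the high-similarity regime (the range real random splits show)
  # while opposed mean centres flip the pattern outright
  expect_gt(median(rho_matched), 0.8)
  expect_lt(median(rho_distinct), 0)
})

test_that("planted group effects appear in the group-2 latent correlations", {
  eff <- data.frame(A = c("1", "2"), B = c("3", "4"))
  sp <- tiny_spec(effect_edges = eff, effect_size = 0.3, seed = 60)
  coh <- generate_cohort(sp)
  S1 <- coh$latent$group1; S2 <- coh$latent$group2
  expect_equal(atanh(S2[1, 3]) - atanh(S1[1, 3]), 0.3, tolerance = 0.02)
  expect_equal(atanh(S2[2, 4]) - atanh(S1[2, 4]), 0.3, tolerance = 0.02)
  # untouched edges stay put
  expect_equal(S2[5, 6], S1[5, 6], tolerance = 0.02)
  expect_gte(min(eigen(S2, symmetric = TRUE)$values), 0)
})
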
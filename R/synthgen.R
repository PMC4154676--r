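#' Motion phenotype of a simulated subject group
#'
#' Describes in-scanner head motion as a trait: the amplitude multiplier
#' scales all six rigid-body parameter processes, `phi` is the AR(1)
#' coefficient of each parameter series (motion is slow and persistent,
#' not white), and `rotation_center` places the axis the simulated
#' rotations act about, which is what makes the voxel-wise displacement
#' field spatially structured. Scales are innovation SDs per parameter
#' (rotations in radians, translations in mm).
#'
#' @param sigma nonnegative amplitude multiplier (1 = typical mover)
#' @param phi AR(1) coefficient in [0, 1)
#' @param rotation_center mean world point (mm) the group's rotations act
#'   about
#' @param center_scatter per-subject SD (mm, per axis) of the rotation
#'   centre around the group mean; groups emulating random splits of one
#'   heterogeneous population keep the default scatter, so within-group
#'   displacement patterns vary as they do across real subjects
#' @param scales named length-6 vector of innovation SDs
#'   (rx, ry, rz in rad; tx, ty, tz in mm)
#' @return object of class `motion_phenotype`
#' @export
motion_phenotype <- function(sigma = 1, phi = 0.95,
                             rotation_center = c(0, 0, 0),
                             center_scatter = 12,
                             scales = c(rx = 2e-3, ry = 2e-3, rz = 2e-3,
                                        tx = 0.07, ty = 0.07, tz = 0.07)) {
  if (sigma < 0) stop_rdi("sigma must be nonnegative")
  if (phi < 0 || phi >= 1) stop_rdi("phi must be in [0, 1)")
  if (center_scatter < 0) stop_rdi("center_scatter must be nonnegative")
  structure(list(sigma = sigma, phi = phi,
                 rotation_center = rotation_center,
                 center_scatter = center_scatter, scales = scales),
            class = "motion_phenotype")
}

# AR(1) series of length n, innovation sd s, started from stationarity
ar1_series <- function(n, phi, s) {
  if (s == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, s / sqrt(1 - phi^2))
  innov <- stats::rnorm(n - 1, 0, s)
  for (t in 2:n) x[t] <- phi * x[t - 1] + innov[t - 1]
  x
}

#' Simulate a rigid motion series
#'
#' Draws six AR(1) rigid-body parameter series, composes each frame's
#' rotation about the phenotype's rotation centre plus translation, and
#' re-references the series so the mid-series frame is the identity
#' (realignment-target convention).
#'
#' @param phenotype [motion_phenotype()]
#' @param n_frames number of frames (>= 2)
#' @param voxel_to_world grid affine carried on the series
#' @param seed RNG seed
#' @return [rigid_motion_series()]
#' @export
simulate_motion <- function(phenotype, n_frames, voxel_to_world = diag(4),
                            seed = 1) {
  if (n_frames < 2) stop_rdi("need at least 2 frames")
  set.seed(seed)
  s <- phenotype$scales * phenotype$sigma
  par6 <- vapply(seq_len(6),
                 function(k) ar1_series(n_frames, phenotype$phi, s[k]),
                 numeric(n_frames))
  colnames(par6) <- names(phenotype$scales)
  cc <- phenotype$rotation_center
  To <- translation_matrix(cc)
  Ti <- translation_matrix(-cc)
  mats <- lapply(seq_len(n_frames), function(t) {
    M <- diag(4)
    M[1:3, 1:3] <- euler_to_rotation(par6[t, 1:3])
    M <- To %*% M %*% Ti
    M[1:3, 4] <- M[1:3, 4] + par6[t, 4:6]
    M
  })
  ref <- (n_frames + 1L) %/% 2L
  Mref_inv <- solve(mats[[ref]])
  mats <- lapply(mats, function(M) M %*% Mref_inv)
  mats[[ref]] <- diag(4)
  rigid_motion_series(mats, voxel_to_world, ref, tol = 1e-6)
}

#' Build an ellipsoidal brain phantom with parcellated cortex
#'
#' The brain mask is an ellipsoid on the grid; an inner core provides CSF
#' (innermost) and white-matter stand-ins, and the outer shell is
#' partitioned into `n_regions` contiguous parcels by k-means on voxel
#' world coordinates (Voronoi cells). World origin sits at the volume
#' centre so rotation centres are specified in mm about the head centre.
#'
#' @param grid length-3 integer grid shape
#' @param n_regions number of cortical parcels
#' @param voxel_size isotropic voxel edge (mm)
#' @param seed RNG seed (k-means initialisation)
#' @return list with `atlas` ([label_atlas()] of the parcels), `mask`,
#'   `wm`, `csf` (3-D logical arrays), `affine`, `centers` (region x 3
#'   world coordinates)
#' @export
make_phantom <- function(grid = c(24, 24, 24), n_regions = 20,
                         voxel_size = 3, seed = 1) {
  if (any(grid < 4)) stop_rdi("degenerate grid")
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- -voxel_size * (grid - 1) / 2
  idx <- as.matrix(expand.grid(i = seq_len(grid[1]), j = seq_len(grid[2]),
                               k = seq_len(grid[3])))
  w <- voxel_to_world_coords(idx, affine)
  semi <- 0.45 * voxel_size * grid
  rfrac <- sqrt(rowSums(sweep(w, 2, rep(0, 3))^2 / rep(semi^2, each = nrow(w))))
  mask <- array(rfrac <= 1, grid)
  csf <- array(rfrac <= 0.35, grid)
  wm <- array(rfrac > 0.35 & rfrac <= 0.6, grid)
  shell <- rfrac > 0.6 & rfrac <= 1
  if (sum(shell) < n_regions * 8) stop_rdi("grid too small for %d parcels",
                                           n_regions)
  set.seed(seed)
  km <- stats::kmeans(w[shell, ], centers = n_regions, nstart = 5,
                      iter.max = 100)
  lab <- integer(nrow(w))
  lab[shell] <- km$cluster
  atlas <- label_atlas(array(lab, grid), affine = affine)
  list(atlas = atlas, mask = mask, wm = wm, csf = csf, affine = affine,
       centers = km$centers)
}

# default latent correlation: distance-dependent exponential kernel over
# parcel centres (positive definite), unit diagonal
default_latent_corr <- function(centers, range_mm = 60, base = 0.85) {
  d <- as.matrix(stats::dist(centers))
  S <- base * exp(-d / range_mm)
  diag(S) <- 1
  S
}

# shift Fisher-Z of selected edges of a correlation matrix, then repair to
# the nearest PD correlation matrix if the shift breaks positive
# definiteness (eigenvalue floor + rescale to unit diagonal)
plant_effect <- function(corr, edges, effect_z) {
  S <- corr
  for (k in seq_len(nrow(edges))) {
    i <- edges$Ai[k]; j <- edges$Bi[k]
    r <- tanh(atanh(S[i, j]) + effect_z)
    S[i, j] <- r; S[j, i] <- r
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    vals <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% (vals * t(ev$vectors))
    Dh <- 1 / sqrt(diag(S))
    S <- S * outer(Dh, Dh)
  }
  S
}

#' Specification of a synthetic two-group cohort
#'
#' Defaults describe the study conditions the package's validation runs
#' use: 2 x 30 subjects, 150 frames at TR = 2 s on a 24^3 grid of 3 mm
#' voxels with 20 cortical parcels; distance-dependent latent
#' connectivity; displacement-coupled BOLD artifact with coupling `gamma`
#' (BOLD a.u. per mm/frame) and iid voxel noise. Subject motion amplitude
#' is a lognormal trait around the group phenotype.
#'
#' @param n_per_group length-2 integer
#' @param n_frames frames per subject (>= 20, after leading-volume
#'   discard)
#' @param tr repetition time (s)
#' @param grid,voxel_size,n_regions phantom geometry
#' @param phenotype1,phenotype2 group [motion_phenotype()]s
#' @param latent_corr M x M positive-definite latent correlation matrix
#'   (default distance-dependent)
#' @param gamma artifact coupling, BOLD a.u. per mm/frame of local
#'   displacement derivative
#' @param noise_sd voxel-level iid noise SD (BOLD a.u.); ROI-level noise
#'   scales as noise_sd / sqrt(region size)
#' @param effect_edges data frame (`A`, `B` region ids) of edges carrying
#'   a planted group difference, or NULL
#' @param effect_size planted difference in Fisher-Z units (applied to
#'   group 2)
#' @param trait_sdlog lognormal SD of the per-subject amplitude trait
#' @param sign_mode `"positive"` (artifact adds with one sign everywhere)
#'   or `"voxel"` (random +-1 per voxel)
#' @param voxels also synthesise full 4-D voxel images (needed for the
#'   WMCSF/GSREG/COMPCOR/SAT36 strategies and NIfTI export)
#' @param seed master seed; all randomness derives from it
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group = c(30, 30), n_frames = 150, tr = 2,
                        grid = c(24, 24, 24), voxel_size = 3,
                        n_regions = 20,
                        phenotype1 = motion_phenotype(),
                        phenotype2 = motion_phenotype(),
                        latent_corr = NULL, gamma = 8, noise_sd = 7,
                        effect_edges = NULL, effect_size = 0,
                        trait_sdlog = 0.35,
                        sign_mode = c("positive", "voxel"),
                        voxels = FALSE, seed = 1) {
  sign_mode <- match.arg(sign_mode)
  if (any(n_per_group < 1)) stop_rdi("both groups must be nonempty")
  if (n_frames < 20) stop_rdi("need at least 20 frames")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Simulate regional (and optionally voxel) BOLD for one subject
#'
#' Latent regional signals are drawn band-limited to the connectivity band
#' (0.01-0.1 Hz) with their empirical correlation matrix equal to
#' `latent_corr` exactly (QR-orthonormalised filtered noise mixed through
#' the Cholesky factor); the motion artifact adds
#' gamma * s(x) * D_t(x) at each voxel, where D is the subject's
#' voxel-wise displacement derivative and s(x) the artifact sign field;
#' iid Gaussian noise completes the voxel model. Regional time courses
#' are the exact ROI means of that voxel model, formed analytically
#' (regional noise SD = noise_sd / sqrt(region size)) unless `voxels` is
#' TRUE, in which case the full 4-D image is synthesised too.
#'
#' @param field [voxelwise_displacement()] of the subject
#' @param phantom [make_phantom()] output
#' @param latent_corr M x M latent correlation
#' @param gamma,noise_sd,sign_mode see [cohort_spec()]
#' @param tr repetition time (s)
#' @param voxels synthesise the 4-D image as well
#' @param baseline mean voxel intensity (a.u.) for the voxel image
#' @param csf_noise_factor extra temporal noise in CSF voxels (makes the
#'   tSNR-based CompCor noise ROI meaningful)
#' @param seed RNG seed
#' @return list: `roi` ([bold_roi()], raw region means), `latent` (frame x
#'   region matrix), `img` (4-D array or NULL), `truth` (generative
#'   record)
#' @export
simulate_bold <- function(field, phantom, latent_corr, gamma = 8,
                          noise_sd = 7, sign_mode = "positive", tr = 2,
                          voxels = FALSE, baseline = 1000,
                          csf_noise_factor = 3, seed = 1) {
  set.seed(seed)
  M <- nrow(latent_corr)
  Tn <- field$n_frames
  flt <- signal::butter(4, c(0.01, 0.1) * 2 * tr, type = "pass")
  E <- matrix(stats::rnorm(Tn * M), Tn, M)
  F1 <- apply(E, 2, bp_filtfilt, flt = flt, order = 4)
  F1 <- sweep(F1, 2, colMeans(F1))
  Q <- qr.Q(qr(F1)) * sqrt(Tn - 1)
  latent <- Q %*% chol(latent_corr)
  lab <- field_labels(field, phantom$atlas)
  inreg <- lab > 0L
  signs <- if (sign_mode == "voxel")
    sample(c(-1, 1), nrow(field$deriv), replace = TRUE) else
    rep(1, nrow(field$deriv))
  wsum <- rowsum(field$deriv[inreg, , drop = FALSE] * signs[inreg], lab[inreg])
  counts <- as.vector(table(factor(lab[inreg], levels = rownames(wsum))))
  art <- t(wsum / counts)                    # frames x regions
  roi_noise <- sweep(matrix(stats::rnorm(Tn * M), Tn, M), 2,
                     noise_sd / sqrt(counts), `*`)
  img <- NULL
  if (voxels) {
    V <- nrow(field$deriv)
    base_v <- baseline * stats::runif(V, 0.9, 1.1)
    nf <- ifelse(phantom$csf[field$vox], csf_noise_factor, 1)
    vox_mat <- latent[, ifelse(inreg, lab, 1), drop = FALSE]
    vox_mat[, !inreg] <- 0
    vox_mat <- t(vox_mat) + gamma * signs * field$deriv +
      matrix(stats::rnorm(V * Tn), V, Tn) * (noise_sd * nf) + base_v
    dm <- dim(field$mask)
    img <- array(0, c(dm, Tn))
    flat <- (field$vox[, 3] - 1) * dm[1] * dm[2] +
      (field$vox[, 2] - 1) * dm[1] + field$vox[, 1]
    step <- prod(dm)
    for (t in seq_len(Tn)) img[flat + (t - 1) * step] <- vox_mat[, t]
  }
  roi <- bold_roi(t(latent + gamma * art + roi_noise) + baseline,
                  region_ids = rownames(wsum), tr = tr)
  list(roi = roi, latent = latent, img = img,
       truth = list(latent_corr = latent_corr, gamma = gamma,
                    noise_sd = noise_sd, sign_mode = sign_mode, seed = seed))
}

#' Generate a synthetic two-group cohort
#'
#' Builds the shared phantom, then per subject: draws the amplitude trait,
#' simulates the rigid motion series about the group's rotation centre,
#' derives the voxel-wise displacement field and FD/RD/deltaRD, and
#' synthesises regional BOLD with the displacement-coupled artifact.
#' Phenotypes (age ~ U(7, 35), IQ ~ N(110, 15), gender ~ Bernoulli(0.5))
#' emulate a developmental cohort. Every random draw derives from the
#' spec seed; the manifest records all sub-seeds.
#'
#' @param spec [cohort_spec()]
#' @return object of class `synthetic_cohort`: `subjects` (list with
#'   `bold`, `fd`, `rd`, `delta_rd`, `mean_fd`, `mean_map`, `series`,
#'   `img`), `pheno` ([phenotype_table()]), `phantom`, `latent`,
#'   (per-group correlation matrices), `spec`, `manifest`
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(spec$seed, 4 + sum(spec$n_per_group) * 2)
  phantom <- make_phantom(spec$grid, spec$n_regions, spec$voxel_size,
                          seed = seeds[1])
  M <- spec$n_regions
  S1 <- spec$latent_corr %||% default_latent_corr(phantom$centers)
  ids <- phantom$atlas$table$id
  S2 <- S1
  eff <- NULL
  if (!is.null(spec$effect_edges) && spec$effect_size != 0) {
    eff <- spec$effect_edges
    eff$Ai <- match(eff$A, ids)
    eff$Bi <- match(eff$B, ids)
    S2 <- plant_effect(S1, eff, spec$effect_size)
  }
  n <- sum(spec$n_per_group)
  group <- rep(0:1, spec$n_per_group)
  set.seed(seeds[2])
  age <- stats::runif(n, 7, 35)
  iq <- stats::rnorm(n, 110, 15)
  gender <- stats::rbinom(n, 1, 0.5)
  set.seed(seeds[3])
  trait <- exp(stats::rnorm(n, 0, spec$trait_sdlog))
  subjects <- vector("list", n)
  sid <- sprintf("sub%03d", seq_len(n))
  set.seed(seeds[4])
  centers <- matrix(stats::rnorm(3 * n), n)
  for (i in seq_len(n)) {
    ph0 <- if (group[i] == 0) spec$phenotype1 else spec$phenotype2
    ph <- motion_phenotype(ph0$sigma * trait[i], ph0$phi,
                           ph0$rotation_center +
                             (ph0$center_scatter %||% 0) * centers[i, ],
                           center_scatter = 0, scales = ph0$scales)
    series <- simulate_motion(ph, spec$n_frames, phantom$affine,
                              seed = seeds[3 + i])
    field <- voxelwise_displacement(series, phantom$mask)
    fd <- frame_displacement(field)
    rd <- regional_displacement(field, phantom$atlas)
    sim <- simulate_bold(field, phantom, if (group[i] == 0) S1 else S2,
                         gamma = spec$gamma, noise_sd = spec$noise_sd,
                         sign_mode = spec$sign_mode, tr = spec$tr,
                         voxels = spec$voxels,
                         seed = seeds[3 + n + i])
    subjects[[i]] <- list(id = sid[i], bold = sim$roi, fd = fd, rd = rd,
                          delta_rd = delta_rd(rd, fd), mean_fd = mean(fd),
                          mean_map = rowMeans(field$deriv),
                          series = series, img = sim$img)
  }
  pheno <- phenotype_table(sid, group, age, iq, gender,
                           vapply(subjects, `[[`, numeric(1), "mean_fd"))
  manifest <- list(seed = spec$seed, sub_seeds = seeds,
                   n_per_group = spec$n_per_group,
                   n_frames = spec$n_frames, tr = spec$tr,
                   grid = spec$grid, n_regions = spec$n_regions,
                   gamma = spec$gamma, noise_sd = spec$noise_sd,
                   effect_size = spec$effect_size)
  structure(list(subjects = subjects, pheno = pheno, phantom = phantom,
                 latent = list(group1 = S1, group2 = S2),
                 effect_edges = eff, spec = spec, manifest = manifest),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d + %d subjects, %d regions, %d frames\n",
              x$spec$n_per_group[1], x$spec$n_per_group[2],
              x$spec$n_regions, x$spec$n_frames))
  cat(sprintf("  gamma %.2g, noise SD %.2g, planted effect %.2g Z on %d edges\n",
              x$spec$gamma, x$spec$noise_sd, x$spec$effect_size,
              if (is.null(x$effect_edges)) 0L else nrow(x$effect_edges)))
  invisible(x)
}

#' Subject x region deltaRD matrix of a cohort
#' @param cohort [generate_cohort()] output
#' @return matrix with subject ids as rownames, region ids as colnames
#' @export
cohort_delta_rd <- function(cohort) {
  m <- t(vapply(cohort$subjects, `[[`,
                numeric(cohort$spec$n_regions), "delta_rd"))
  rownames(m) <- cohort$pheno$subject
  colnames(m) <- as.character(cohort$phantom$atlas$table$id)
  m
}

#' Subject x voxel matrix of temporally averaged displacement maps
#' @param cohort [generate_cohort()] output
#' @return matrix (subjects x mask voxels)
#' @export
cohort_mean_maps <- function(cohort) {
  m <- do.call(rbind, lapply(cohort$subjects, `[[`, "mean_map"))
  rownames(m) <- cohort$pheno$subject
  m
}
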
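#' @rdname nuisance_design
#' @export
NUISANCE_STRATEGIES <- c("NOREG", "WMCSF", "GSREG", "COMPCOR",
                         "NOREG+M6", "WMCSF+M6", "GSREG+M6", "COMPCOR+M6",
                         "SAT36")

# expected regressor column counts per strategy (intercept excluded)
strategy_ncol <- c(NOREG = 0L, WMCSF = 2L, GSREG = 1L, COMPCOR = 5L,
                   `NOREG+M6` = 6L, `WMCSF+M6` = 8L, `GSREG+M6` = 7L,
                   `COMPCOR+M6` = 11L, SAT36 = 36L)

# one-iteration 6-connectivity erosion of a 3-D logical mask
erode_mask <- function(mask) {
  dm <- dim(mask)
  out <- mask
  pad <- function(sh) {
    a <- array(FALSE, dm)
    src <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    dst <- src
    ax <- which(sh != 0)
    s <- sh[ax]
    if (s > 0) { dst[[ax]] <- (1 + s):dm[ax]; src[[ax]] <- 1:(dm[ax] - s) }
    else       { dst[[ax]] <- 1:(dm[ax] + s); src[[ax]] <- (1 - s):dm[ax] }
    a[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    a
  }
  for (sh in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
    out <- out & pad(sh)
  out
}

mask_mean_series <- function(img, mask) {
  colMeans(flatten_func(img, mask))
}

#' White-matter and CSF mean-signal regressors
#'
#' Per-frame mean BOLD over the one-voxel-eroded (6-connectivity) WM and
#' CSF masks.
#' @param img 4-D array
#' @param wm_mask,csf_mask 3-D logical arrays
#' @return frame x 2 matrix, columns `wm`, `csf`
#' @export
build_wmcsf <- function(img, wm_mask, csf_mask) {
  wm <- erode_mask(wm_mask)
  csf <- erode_mask(csf_mask)
  if (!any(wm) || !any(csf)) stop_rdi("erosion emptied mask")
  cbind(wm = mask_mean_series(img, wm), csf = mask_mean_series(img, csf))
}

#' Global-signal regressor
#' @param img 4-D array
#' @param brain_mask 3-D logical array
#' @return frame x 1 matrix, column `gs`
#' @export
build_gsr <- function(img, brain_mask) {
  if (!any(brain_mask)) stop_rdi("empty mask")
  cbind(gs = mask_mean_series(img, brain_mask))
}

#' CompCor principal-component regressors
#'
#' Defines a noise ROI as the voxels in the lowest `noise_fraction`
#' quantile of temporal signal-to-noise ratio (voxel temporal mean over
#' temporal SD) inside the brain mask, then returns the leading principal
#' components of the demeaned, variance-normalised noise-ROI voxel time
#' courses. Components are unit-norm and mutually orthogonal.
#'
#' @param img 4-D array
#' @param brain_mask 3-D logical array
#' @param n_components number of components (default 5)
#' @param noise_fraction tSNR quantile defining the noise ROI (default
#'   0.02)
#' @return frame x n_components matrix, columns `cc1..`
#' @export
build_compcor <- function(img, brain_mask, n_components = 5,
                          noise_fraction = 0.02) {
  m <- flatten_func(img, brain_mask)
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  tsnr <- ifelse(sdv > 0, mu / sdv, Inf)
  cut <- stats::quantile(tsnr, noise_fraction, names = FALSE)
  noise <- which(tsnr <= cut)
  if (length(noise) < n_components)
    stop_rdi("noise ROI has %d voxels; cannot support %d components",
             length(noise), n_components)
  X <- t(m[noise, , drop = FALSE])             # frames x voxels
  X <- scale(X)                                 # demean + unit variance
  X[, !is.finite(colSums(X))] <- 0
  sv <- svd(X, nu = min(n_components, ncol(X)), nv = 0)
  rank <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (rank < n_components)
    stop_rdi("noise-ROI covariance supports only %d components; %d requested",
             rank, n_components)
  comps <- sv$u[, seq_len(n_components), drop = FALSE]
  colnames(comps) <- paste0("cc", seq_len(n_components))
  comps
}

#' Six motion-parameter regressors
#'
#' Three translations (mm) and three rotations (radians, extrinsic x-y-z)
#' per frame, decomposed from the rigid motion series.
#' @param series [rigid_motion_series()]
#' @return frame x 6 matrix (`tx,ty,tz,rx,ry,rz`)
#' @export
build_motion6 <- function(series) {
  p <- motion_parameters(series)
  out <- p[, c("tx", "ty", "tz", "rx", "ry", "rz")]
  if (all(out == 0))
    warn_rdi("identity motion series: all six motion regressors are zero")
  out
}

#' 36-parameter nuisance expansion
#'
#' Expands a 9-column core (6 motion parameters + WM + CSF + global
#' signal) into 36 regressors: the core, its first backward differences
#' (first row 0), and the squares of both sets.
#' @param core9 frame x 9 matrix
#' @return frame x 36 matrix
#' @export
build_sat36 <- function(core9) {
  core9 <- as.matrix(core9)
  if (ncol(core9) != 9)
    stop_rdi("SAT36 needs a 9-column core (6 motion + WM + CSF + GS); got %d",
             ncol(core9))
  d <- rbind(0, diff(core9))
  out <- cbind(core9, d, core9^2, d^2)
  colnames(out) <- c(colnames(core9, do.NULL = FALSE, prefix = "c"),
                     paste0("d_", colnames(core9, do.NULL = FALSE, prefix = "c")),
                     paste0("sq_", colnames(core9, do.NULL = FALSE, prefix = "c")),
                     paste0("sqd_", colnames(core9, do.NULL = FALSE, prefix = "c")))
  out
}

#' Assemble a nuisance design for one of the nine strategies
#'
#' @param strategy one of `NUISANCE_STRATEGIES`
#' @param img 4-D array (needed for WMCSF/GSREG/COMPCOR/SAT36 variants)
#' @param brain_mask,wm_mask,csf_mask 3-D logical arrays as required
#' @param series [rigid_motion_series()] (needed for +M6 and SAT36)
#' @param n_components,noise_fraction CompCor settings
#' @return object of class `nuisance_design`: list with `x` (frame x k
#'   matrix, possibly 0 columns), `strategy`
#' @export
nuisance_design <- function(strategy, img = NULL, brain_mask = NULL,
                            wm_mask = NULL, csf_mask = NULL, series = NULL,
                            n_components = 5, noise_fraction = 0.02) {
  strategy <- match.arg(strategy, NUISANCE_STRATEGIES)
  base <- sub("\\+M6$", "", strategy)
  m6 <- grepl("\\+M6$", strategy)
  x <- switch(base,
    NOREG = NULL,
    WMCSF = build_wmcsf(img, wm_mask, csf_mask),
    GSREG = build_gsr(img, brain_mask),
    COMPCOR = build_compcor(img, brain_mask, n_components, noise_fraction),
    SAT36 = {
      core <- cbind(build_motion6(series),
                    build_wmcsf(img, wm_mask, csf_mask),
                    build_gsr(img, brain_mask))
      build_sat36(core)
    })
  if (m6) x <- cbind(x, build_motion6(series))
  nframes <- if (is.null(x)) {
    if (!is.null(series)) series$n_frames else dim(img)[4]
  } else nrow(x)
  x <- x %||% matrix(numeric(0), nframes, 0)
  if (ncol(x) != strategy_ncol[[strategy]])
    stop_rdi("strategy %s should have %d columns, got %d",
             strategy, strategy_ncol[[strategy]], ncol(x))
  structure(list(x = x, strategy = strategy), class = "nuisance_design")
}

#' Regress nuisance signals out of regional time courses
#'
#' Ordinary least squares of each regional time course on the design plus
#' an intercept; the residuals (orthogonal to every design column and
#' demeaned) replace the data. Constant-zero columns are dropped with a
#' warning; collinear columns are dropped via the QR pivoting with a
#' warning.
#'
#' @param bold [bold_roi()]
#' @param design [nuisance_design()] or a frame x k matrix (may have 0
#'   columns: demeaning only)
#' @return residual [bold_roi()]
#' @export
regress_out <- function(bold, design) {
  x <- if (inherits(design, "nuisance_design")) design$x else as.matrix(design)
  if (nrow(x) != ncol(bold$data) && ncol(x) > 0)
    stop_rdi("design has %d frames but BOLD has %d", nrow(x), ncol(bold$data))
  if (ncol(x) > 0) {
    zero <- apply(x, 2, function(v) all(v == 0))
    if (any(zero)) {
      warn_rdi("dropping %d constant-zero design column(s)", sum(zero))
      x <- x[, !zero, drop = FALSE]
    }
  }
  X <- cbind(`(Intercept)` = 1, x)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[seq(qrX$rank + 1, ncol(X))]
    warn_rdi("rank-deficient design: dropping collinear column(s) %s",
             paste(colnames(X)[drop_idx], collapse = ", "))
    X <- X[, -drop_idx, drop = FALSE]
    qrX <- qr(X)
  }
  res <- qr.resid(qrX, t(bold$data))
  bold_roi(t(res), region_ids = bold$region_ids, tr = bold$tr)
}

# zero-phase Butterworth with odd-reflection padding at both ends, so the
# forward-backward pass does not ring against the series boundaries
bp_filtfilt <- function(v, flt, order) {
  n <- length(v)
  p <- min(3L * (2L * order + 1L), n - 1L)
  ext <- c(2 * v[1] - v[(p + 1):2], v, 2 * v[n] - v[(n - 1):(n - p)])
  y <- signal::filtfilt(flt, ext)
  y[(p + 1):(p + n)]
}

#' Temporal band-pass filter for regional time courses
#'
#' Fourth-order (by default) Butterworth band-pass applied forward and
#' backward (zero phase), retaining frequencies between `low` and `high`.
#' The temporal mean is removed before filtering and any residual numeric
#' DC after it (the passband excludes 0 Hz, so the output has no mean
#' component by construction).
#' @param bold [bold_roi()]
#' @param low,high band edges in Hz (defaults 0.01 and 0.1)
#' @param order filter order (default 4; the two-pass application doubles
#'   the effective roll-off)
#' @return filtered [bold_roi()], same length
#' @export
bandpass <- function(bold, low = 0.01, high = 0.1, order = 4) {
  nyq <- 1 / (2 * bold$tr)
  if (!(low > 0 && low < high && high < nyq))
    stop_rdi("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
             low, high, nyq)
  flt <- signal::butter(order, c(low, high) / nyq, type = "pass")
  out <- t(apply(bold$data, 1, function(v) {
    y <- bp_filtfilt(v - mean(v), flt, order)
    y - mean(y)
  }))
  bold_roi(out, region_ids = bold$region_ids, tr = bold$tr)
}
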
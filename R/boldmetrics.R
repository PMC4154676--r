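#' Regional BOLD time-course container
#'
#' @param data region x frame matrix of ROI-mean BOLD intensities
#' @param region_ids region identifiers (default rownames or 1..M)
#' @param tr frame period in seconds
#' @return object of class `bold_roi`
#' @export
bold_roi <- function(data, region_ids = NULL, tr = 2) {
  data <- as.matrix(data)
  if (ncol(data) < 2) stop_rdi("a BOLD series needs at least 2 frames")
  if (!all(is.finite(data))) stop_rdi("non-finite BOLD values")
  if (tr <= 0) stop_rdi("TR must be positive")
  region_ids <- region_ids %||% rownames(data) %||% as.character(seq_len(nrow(data)))
  rownames(data) <- region_ids
  structure(list(data = data, region_ids = region_ids, tr = tr),
            class = "bold_roi")
}

#' @export
print.bold_roi <- function(x, ...) {
  cat("Regional BOLD series:", nrow(x$data), "regions x", ncol(x$data),
      sprintf("frames (TR = %g s)\n", x$tr))
  invisible(x)
}

# flatten a 4-D image + 3-D mask into a voxel x frame matrix
flatten_func <- function(img, mask) {
  dm <- dim(img)
  if (!all(dim(mask) == dm[1:3])) stop_rdi("mask grid does not match image")
  m <- matrix(img, prod(dm[1:3]), dm[4])
  m[as.vector(mask), , drop = FALSE]
}

#' Extract ROI-mean time courses from a 4-D image
#' @param img 4-D array
#' @param atlas [label_atlas()] or 3-D integer label array
#' @param tr frame period (s)
#' @return [bold_roi()]
#' @export
roi_timecourses <- function(img, atlas, tr = 2) {
  lab <- if (is.array(atlas)) atlas else atlas$labels
  dm <- dim(img)
  lv <- as.vector(lab)
  keep <- lv > 0L
  m <- matrix(img, prod(dm[1:3]), dm[4])[keep, , drop = FALSE]
  sums <- rowsum(m, lv[keep])
  counts <- as.vector(table(factor(lv[keep], levels = rownames(sums))))
  bold_roi(sums / counts, region_ids = rownames(sums), tr = tr)
}

#' DVARS: global rate of BOLD intensity change
#'
#' Root mean square over mask voxels of the frame-to-frame intensity
#' difference; the first frame has no predecessor and is set to 0. Computed
#' on realigned data prior to confound regression and filtering.
#' @param img 4-D array or voxel x frame matrix
#' @param mask 3-D logical array (required when `img` is 4-D)
#' @return per-frame numeric vector
#' @export
dvars <- function(img, mask = NULL) {
  m <- if (length(dim(img)) == 4) {
    if (is.null(mask)) stop_rdi("mask required for a 4-D image")
    if (!any(mask)) stop_rdi("empty mask")
    flatten_func(img, mask)
  } else as.matrix(img)
  Tn <- ncol(m)
  dd <- m[, -1, drop = FALSE] - m[, -Tn, drop = FALSE]
  c(0, sqrt(colMeans(dd^2)))
}

#' Regional DVARS (RDVARS)
#'
#' Per-region root mean square of frame-to-frame voxel intensity
#' differences; first frame 0.
#' @param img 4-D array
#' @param atlas [label_atlas()] or 3-D integer label array
#' @return region x frame matrix
#' @export
rdvars <- function(img, atlas) {
  lab <- if (is.array(atlas)) atlas else atlas$labels
  dm <- dim(img)
  lv <- as.vector(lab)
  keep <- lv > 0L
  if (!any(keep)) stop_rdi("empty region")
  m <- matrix(img, prod(dm[1:3]), dm[4])[keep, , drop = FALSE]
  Tn <- ncol(m)
  dd2 <- (m[, -1, drop = FALSE] - m[, -Tn, drop = FALSE])^2
  sums <- rowsum(dd2, lv[keep])
  counts <- as.vector(table(factor(lv[keep], levels = rownames(sums))))
  cbind(0, sqrt(sums / counts))
}

#' Residual regional measures
#'
#' Subtracts the global measure from the regional ones:
#' rRD_r(t) = RD_r(t) - FD(t) and rRDVARS_r(t) = RDVARS_r(t) - DVARS(t),
#' isolating the spatially varying component of motion and of the BOLD
#' change rate.
#' @param rd region x frame RD matrix
#' @param fd FD vector
#' @param rdvars_mat region x frame RDVARS matrix
#' @param dvars_vec DVARS vector
#' @return list with elements `rrd` and `rrdvars`
#' @export
residual_measures <- function(rd, fd, rdvars_mat, dvars_vec) {
  if (!all(dim(rd) == dim(rdvars_mat)) || ncol(rd) != length(fd) ||
      length(fd) != length(dvars_vec))
    stop_rdi("shape mismatch between displacement and DVARS inputs")
  list(rrd = sweep(rd, 2, fd),
       rrdvars = sweep(rdvars_mat, 2, dvars_vec))
}

#' Motion-BOLD coupling analysis
#'
#' For each subject, correlates FD with DVARS (global coupling) and the
#' residual RD with the residual RDVARS pooled over all regions and frames
#' 2..T (regional coupling); then correlates the two coupling coefficients
#' across subjects. The first frame of every difference series is excluded.
#'
#' @param subjects list; each element a list with `fd`, `dvars`, `rrd`,
#'   `rrdvars` (as returned by the metric functions)
#' @param method correlation type, `"pearson"` (default) or `"spearman"`
#' @param per_region average per-region correlations instead of pooling
#'   regions and frames into one vector
#' @return object of class `motion_bold_coupling`: per-subject data frame
#'   (`r_global`, `r_residual`) plus `across_r`, the across-subject
#'   correlation of the two
#' @export
coupling_analysis <- function(subjects, method = c("pearson", "spearman"),
                              per_region = FALSE) {
  method <- match.arg(method)
  safe_cor <- function(a, b) {
    if (length(a) < 3 || anyNA(a) || anyNA(b)) return(NA_real_)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warn_rdi("zero-variance input: coupling correlation undefined")
      return(NA_real_)
    }
    stats::cor(a, b, method = method)
  }
  rows <- lapply(subjects, function(s) {
    Tn <- length(s$fd)
    use <- 2:Tn
    rg <- safe_cor(s$fd[use], s$dvars[use])
    rr <- if (per_region) {
      mean(vapply(seq_len(nrow(s$rrd)), function(r)
        safe_cor(s$rrd[r, use], s$rrdvars[r, use]), numeric(1)), na.rm = TRUE)
    } else {
      safe_cor(as.vector(s$rrd[, use]), as.vector(s$rrdvars[, use]))
    }
    c(r_global = rg, r_residual = rr)
  })
  tab <- as.data.frame(do.call(rbind, rows))
  across <- if (nrow(tab) >= 3) {
    ok <- stats::complete.cases(tab)
    safe_cor(tab$r_residual[ok], tab$r_global[ok])
  } else NA_real_
  structure(list(subjects = tab, across_r = across, method = method),
            class = "motion_bold_coupling")
}

#' @export
print.motion_bold_coupling <- function(x, ...) {
  cat("Motion-BOLD coupling over", nrow(x$subjects), "subjects\n")
  cat(sprintf("  median r(FD, DVARS)        %.3f\n",
              stats::median(x$subjects$r_global, na.rm = TRUE)))
  cat(sprintf("  median r(rRD, rRDVARS)     %.3f\n",
              stats::median(x$subjects$r_residual, na.rm = TRUE)))
  cat(sprintf("  across-subject correlation %.3f\n", x$across_r))
  invisible(x)
}
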
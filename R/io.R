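# File-format plumbing: NIfTI images via RNifti, MCFLIRT-style .mat
# directories, TSV metric tables.

#' Read a 4-D NIfTI image as a plain array plus affine
#' @param path NIfTI file
#' @return list with `data` (array) and `affine` (4x4 voxel-to-world)
#' @export
read_func_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = unclass(img)[drop = FALSE],
       affine = structure(RNifti::xform(img), class = NULL))
}

#' Write an array as NIfTI with a given affine
#' @param data 3-D or 4-D array
#' @param affine 4x4 voxel-to-world matrix
#' @param path output file (.nii or .nii.gz)
#' @param pixdim voxel sizes; fourth entry is the TR for 4-D data
#' @export
write_func_nifti <- function(data, affine, path, pixdim = NULL) {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  if (!is.null(pixdim)) RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a rigid motion series as an MCFLIRT-style .mat directory
#'
#' One text file per frame (`MAT_0000`, `MAT_0001`, ...), each a 4x4
#' whitespace-separated matrix.
#' @param series [rigid_motion_series()]
#' @param dir output directory (created)
#' @return the directory path
#' @export
write_mat_dir <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(series$n_frames)) {
    f <- file.path(dir, sprintf("MAT_%04d", i - 1))
    writeLines(apply(series$transforms[[i]], 1,
                     function(r) paste(sprintf("%.17g", r), collapse = "  ")),
               f)
  }
  invisible(dir)
}

#' Read an MCFLIRT-style .mat directory
#' @param dir directory of per-frame matrix files (sorted by name)
#' @param ... passed to [load_rigid_transforms()]
#' @export
read_mat_dir <- function(dir, ...) {
  paths <- sort(list.files(dir, full.names = TRUE))
  load_rigid_transforms(paths, ...)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write FD / RD / deltaRD metric tables as TSV
#' @param summary [motion_summary()]
#' @param dir output directory
#' @return vector of written paths
#' @export
write_motion_tsv <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("fd.tsv", "rd.tsv", "delta_rd.tsv"))
  write_tsv(data.frame(frame = seq_along(summary$fd), fd = summary$fd),
            paths[1])
  if (!is.null(summary$rd)) {
    rd <- data.frame(region = rownames(summary$rd), summary$rd,
                     check.names = FALSE)
    write_tsv(rd, paths[2])
    write_tsv(data.frame(region = names(summary$delta_rd),
                         delta_rd = summary$delta_rd), paths[3])
  }
  invisible(paths)
}

#' Export a synthetic cohort to disk in standard formats
#'
#' Writes, per subject, the 4-D functional NIfTI (when the cohort was
#' generated with `voxels = TRUE`), the MCFLIRT-style .mat directory and
#' the motion metric TSVs; plus the cohort phenotype TSV and the atlas
#' label NIfTI and region table, so the synthetic cohort is
#' format-compatible with a real one.
#' @param cohort [generate_cohort()] output
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- cohort$phantom
  write_func_nifti(ph$atlas$labels, ph$affine, file.path(dir, "atlas.nii.gz"))
  write_tsv(ph$atlas$table, file.path(dir, "regions.tsv"))
  write_tsv(cohort$pheno, file.path(dir, "phenotype.tsv"))
  for (s in cohort$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_mat_dir(s$series, file.path(sd, "func.mat"))
    write_motion_tsv(motion_summary_from_subject(s), sd)
    if (!is.null(s$img))
      write_func_nifti(s$img, ph$affine, file.path(sd, "func.nii.gz"),
                       pixdim = c(rep(cohort$spec$voxel_size, 3),
                                  cohort$spec$tr))
  }
  invisible(dir)
}

motion_summary_from_subject <- function(s) {
  structure(list(fd = s$fd, rd = s$rd,
                 delta_rd = delta_rd(s$rd, s$fd),
                 mean_fd = s$mean_fd, mean_voxel_map = s$mean_map),
            class = "motion_summary")
}
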
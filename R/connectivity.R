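#' Fisher-Z connectivity matrix
#'
#' Pearson product-moment correlations between all pairs of regional time
#' courses, Fisher-Z transformed (atanh). Correlations are clipped to
#' +-(1 - clip) before the transform so degenerate pairs stay finite; with
#' `clip_mode = "drop"` such edges are set to NA instead. The diagonal is
#' stored as NA (undefined). Zero-variance regions get all their edges set
#' to NA with a warning.
#'
#' @param bold [bold_roi()] of denoised time courses (>= 3 frames)
#' @param subject,strategy identifying tags carried on the object
#' @param clip clipping constant (default 1e-7)
#' @param clip_mode `"clip"` (default) or `"drop"`
#' @return object of class `connectivity_matrix`: `z` (M x M symmetric),
#'   `region_ids`, `subject`, `strategy`
#' @export
fisher_z_matrix <- function(bold, subject = NA_character_,
                            strategy = NA_character_,
                            clip = 1e-7, clip_mode = c("clip", "drop")) {
  clip_mode <- match.arg(clip_mode)
  if (ncol(bold$data) < 3) stop_rdi("need at least 3 frames for correlation")
  sds <- apply(bold$data, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(bold$data)))
  if (any(sds == 0)) {
    warn_rdi("zero-variance region(s) %s: their edges are set to NA",
             paste(bold$region_ids[sds == 0], collapse = ", "))
    r[sds == 0, ] <- NA
    r[, sds == 0] <- NA
  }
  at_bound <- !is.na(r) & abs(r) > 1 - clip
  if (clip_mode == "drop") {
    r[at_bound] <- NA
  } else {
    r[at_bound] <- sign(r[at_bound]) * (1 - clip)
  }
  z <- atanh(r)
  diag(z) <- NA
  dimnames(z) <- list(bold$region_ids, bold$region_ids)
  structure(list(z = z, region_ids = bold$region_ids,
                 subject = subject, strategy = strategy),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  m <- length(x$region_ids)
  cat(sprintf("Connectivity matrix: %d x %d Fisher-Z (subject %s, %s)\n",
              m, m, x$subject, x$strategy))
  off <- x$z[upper.tri(x$z)]
  cat(sprintf("  %d edges, mean Z %.3f\n", length(off), mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Long-format edge table from connectivity matrices
#'
#' One row per subject per unordered region pair (A < B): M(M-1)/2 rows
#' per subject.
#' @param matrices list of [fisher_z_matrix()] results sharing a region set
#' @return data frame with columns `subject`, `A`, `B`, `z`
#' @export
edge_table <- function(matrices) {
  ids <- matrices[[1]]$region_ids
  ut <- which(upper.tri(matrices[[1]]$z), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  rows <- lapply(matrices, function(cm) {
    if (!identical(cm$region_ids, ids))
      stop_rdi("region mismatch between connectivity matrices")
    data.frame(subject = cm$subject,
               A = ids[ut[, 1]], B = ids[ut[, 2]],
               z = cm$z[ut], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rebuild a connectivity matrix from a one-subject edge table
#' @param edges data frame with `A`, `B`, `z` for a single subject
#' @param region_ids region identifiers in order
#' @return [fisher_z_matrix()]-style object
#' @export
edges_to_matrix <- function(edges, region_ids) {
  m <- length(region_ids)
  z <- matrix(NA_real_, m, m, dimnames = list(region_ids, region_ids))
  i <- match(edges$A, region_ids)
  j <- match(edges$B, region_ids)
  z[cbind(i, j)] <- edges$z
  z[cbind(j, i)] <- edges$z
  structure(list(z = z, region_ids = region_ids,
                 subject = edges$subject[1], strategy = NA_character_),
            class = "connectivity_matrix")
}

#' Write a connectivity matrix as dense TSV
#' @param cm [fisher_z_matrix()] result
#' @param path output file
#' @export
write_connectivity_tsv <- function(cm, path) {
  utils::write.table(cm$z, path, sep = "\t", quote = FALSE,
                     col.names = NA, na = "")
  invisible(path)
}
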
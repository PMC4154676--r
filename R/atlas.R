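#' Labelled ROI atlas
#'
#' @param labels 3-D integer array; 0 = background, regions are a contiguous
#'   positive integer range
#' @param table data frame with at least `id`; optional `long_name`,
#'   `short_name`, `hemisphere`, `merged_from`; `n_voxels` and `volume_mm3`
#'   are (re)computed
#' @param affine 4x4 voxel-to-world matrix (used for volumes)
#' @return object of class `label_atlas`
#' @export
label_atlas <- function(labels, table = NULL, affine = diag(4)) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0L]
  if (length(ids) && !identical(ids, seq_len(length(ids))))
    stop_rdi("labels must form a contiguous range 1..M (got %s)",
             paste(utils::head(ids, 5), collapse = ","))
  if (is.null(table)) table <- data.frame(id = ids)
  table <- table[match(ids, table$id), , drop = FALSE]
  counts <- tabulate(labels[labels > 0L], nbins = length(ids))
  if (any(counts == 0L)) stop_rdi("every region must have at least 1 voxel")
  table$n_voxels <- counts
  table$volume_mm3 <- counts * abs(det(affine[1:3, 1:3]))
  rownames(table) <- NULL
  structure(list(labels = labels, table = table, affine = affine),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("Label atlas:", nrow(x$table), "regions,",
      sum(x$table$n_voxels), "labelled voxels\n")
  invisible(x)
}

#' Threshold probabilistic maps into a label atlas
#'
#' Each voxel is assigned to the region with the highest probability among
#' regions whose probability strictly exceeds the threshold; voxels where
#' no region exceeds it remain background. Equal-probability ties go to the
#' lower region id (deterministic).
#'
#' @param prob_maps 4-D array (grid x region) of probabilities, or a list
#'   of 3-D arrays sharing a grid
#' @param threshold retention probability threshold, strict inequality;
#'   default 0.25
#' @param table optional region table passed to [label_atlas()]
#' @param affine voxel-to-world matrix
#' @return [label_atlas()]; regions that receive no voxel are dropped with
#'   a warning (candidates for merging)
#' @export
threshold_probabilistic <- function(prob_maps, threshold = 0.25,
                                    table = NULL, affine = diag(4)) {
  if (is.list(prob_maps)) {
    dm <- dim(prob_maps[[1]])
    prob_maps <- array(unlist(prob_maps), c(dm, length(prob_maps)))
  }
  if (threshold <= 0 || threshold >= 1) stop_rdi("threshold must be in (0,1)")
  dm <- dim(prob_maps)
  nreg <- dm[4]
  P <- matrix(prob_maps, prod(dm[1:3]), nreg)
  # argmax with lower-id tie-break: max.col(ties.method = "first")
  best <- max.col(P, ties.method = "first")
  pbest <- P[cbind(seq_len(nrow(P)), best)]
  lab <- ifelse(pbest > threshold, best, 0L)
  present <- sort(unique(lab[lab > 0L]))
  missing <- setdiff(seq_len(nreg), present)
  if (length(missing)) {
    warn_rdi("no voxel survives thresholding for region(s) %s; dropped (merge candidates)",
             paste(missing, collapse = ", "))
    lab <- match(lab, present, nomatch = 0L) # relabel contiguously
    if (!is.null(table)) table <- transform(table[present, , drop = FALSE],
                                            id = seq_along(present))
  }
  label_atlas(array(as.integer(lab), dm[1:3]), table, affine)
}

# counts of face-adjacent (6-connectivity) voxel pairs between labels;
# returns a data.frame(a, b, n) with a < b
boundary_counts <- function(labels) {
  dm <- dim(labels)
  pairs <- list()
  shift_pairs <- function(a, b) {
    keep <- a != b & a > 0L & b > 0L
    if (!any(keep)) return(NULL)
    cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  }
  p1 <- shift_pairs(labels[-dm[1], , , drop = FALSE], labels[-1, , , drop = FALSE])
  p2 <- shift_pairs(labels[, -dm[2], , drop = FALSE], labels[, -1, , drop = FALSE])
  p3 <- shift_pairs(labels[, , -dm[3], drop = FALSE], labels[, , -1, drop = FALSE])
  ab <- rbind(p1, p2, p3)
  if (is.null(ab) || nrow(ab) == 0)
    return(data.frame(a = integer(), b = integer(), n = integer()))
  key <- paste(ab[, 1], ab[, 2])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(a = as.integer(parts[, 1]), b = as.integer(parts[, 2]),
             n = as.integer(tab))
}

#' Merge small atlas regions into their neighbours
#'
#' Regions below the volume threshold are absorbed, one at a time (smallest
#' first), by the face-adjacent neighbour sharing the largest boundary
#' surface. Boundary ties go to the larger neighbour, then to the lower id.
#' Merging iterates until no region is under-volume; an under-volume region
#' with no neighbour is left unmerged with a warning. Merge provenance is
#' recorded in the region table (`merged_from`).
#'
#' @param atlas [label_atlas()]
#' @param min_volume volume threshold (strictly-less-than regions merge)
#' @param unit `"vox"` (default) or `"mm3"`
#' @return [label_atlas()] with contiguously relabelled regions
#' @export
merge_small_regions <- function(atlas, min_volume = 30, unit = c("vox", "mm3")) {
  unit <- match.arg(unit)
  if (min_volume <= 0) stop_rdi("min_volume must be positive")
  lab <- atlas$labels
  tab <- atlas$table
  vox_mm3 <- abs(det(atlas$affine[1:3, 1:3]))
  name_of <- function(i) {
    if (!is.null(tab$short_name)) as.character(tab$short_name[i]) else as.character(tab$id[i])
  }
  merged_from <- as.list(tab$merged_from %||% rep("", nrow(tab)))
  active <- rep(TRUE, nrow(tab))
  volume <- function(counts) if (unit == "vox") counts else counts * vox_mm3
  unmergeable <- integer()
  repeat {
    counts <- tabulate(lab[lab > 0L], nbins = nrow(tab))
    small <- which(active & volume(counts) < min_volume)
    small <- setdiff(small, unmergeable)
    if (!length(small)) break
    i <- small[which.min(counts[small])]
    bc <- boundary_counts(lab)
    nb <- bc[bc$a == i | bc$b == i, , drop = FALSE]
    if (!nrow(nb)) {
      warn_rdi("region %s is under-volume but has no neighbour; left unmerged",
               name_of(i))
      unmergeable <- c(unmergeable, i)
      next
    }
    nb$other <- ifelse(nb$a == i, nb$b, nb$a)
    # largest shared surface; ties -> larger neighbour, then lower id
    ord <- order(-nb$n, -counts[nb$other], nb$other)
    target <- nb$other[ord[1]]
    lab[lab == i] <- as.integer(target)
    prov <- c(merged_from[[target]], name_of(i),
              strsplit(merged_from[[i]], ";\\s*")[[1]])
    merged_from[[target]] <- paste(prov[nzchar(prov)], collapse = "; ")
    active[i] <- FALSE
  }
  keep <- which(active)
  lab <- array(match(lab, keep, nomatch = 0L), dim(lab))
  newtab <- tab[keep, setdiff(names(tab), c("n_voxels", "volume_mm3")),
                drop = FALSE]
  newtab$id <- seq_along(keep)
  newtab$merged_from <- vapply(merged_from[keep], identity, character(1))
  label_atlas(lab, newtab, atlas$affine)
}
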
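#' Exclude high-motion subjects
#'
#' Removes subjects whose mean FD strictly exceeds the threshold (default
#' 0.7 mm); a subject at exactly the threshold is retained.
#' @param mean_fd named numeric vector of per-subject mean FD (mm)
#' @param threshold exclusion threshold in mm
#' @return list with `retained` (names), `excluded` (names) and a printed
#'   exclusion log
#' @export
exclude_high_motion <- function(mean_fd, threshold = 0.7) {
  if (is.null(names(mean_fd))) names(mean_fd) <- as.character(seq_along(mean_fd))
  out <- mean_fd > threshold
  if (all(out)) stop_rdi("all subjects exceed the FD threshold")
  structure(list(retained = names(mean_fd)[!out],
                 excluded = names(mean_fd)[out],
                 threshold = threshold,
                 mean_fd = mean_fd),
            class = "fd_exclusion")
}

#' @export
print.fd_exclusion <- function(x, ...) {
  cat(sprintf("FD exclusion at > %g mm: %d retained, %d excluded\n",
              x$threshold, length(x$retained), length(x$excluded)))
  for (s in x$excluded)
    cat(sprintf("  excluded %s (mean FD %.3f mm)\n", s, x$mean_fd[s]))
  invisible(x)
}

# spatial correlation of the two group-mean displacement maps
rho_groups <- function(maps, idx1, idx2) {
  stats::cor(colMeans(maps[idx1, , drop = FALSE]),
             colMeans(maps[idx2, , drop = FALSE]))
}

#' Random group-pair permutations with displacement-map similarity
#'
#' Randomly halves the cohort `n_perm` times; for each split the spatial
#' Pearson correlation between the two groups' mean temporally-averaged
#' voxel-wise displacement maps (rho_groups) is recorded. An odd cohort
#' puts the extra subject into group 1. Fully reproducible from `seed`.
#'
#' @param maps subject x voxel matrix of temporally averaged voxel-wise
#'   displacement (brain-mask voxels only; no standardisation)
#' @param n_perm number of random splits
#' @param seed RNG seed
#' @return object of class `group_permutations`: data frame `rho` per
#'   permutation plus the group-1 index sets
#' @export
permute_group_pairs <- function(maps, n_perm = 5000, seed = 1) {
  n <- nrow(maps)
  if (n < 4) stop_rdi("need at least 4 subjects")
  if (n_perm < 1) stop_rdi("n_perm must be >= 1")
  set.seed(seed)
  n1 <- ceiling(n / 2)
  g1 <- vector("list", n_perm)
  rho <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    g1[[i]] <- sort(sample.int(n, n1))
    rho[i] <- rho_groups(maps, g1[[i]], setdiff(seq_len(n), g1[[i]]))
  }
  structure(list(rho = rho, group1 = g1, n = n, seed = seed),
            class = "group_permutations")
}

#' @export
print.group_permutations <- function(x, ...) {
  cat(sprintf("Group permutations: %d splits of %d subjects\n",
              length(x$rho), x$n))
  cat(sprintf("  rho_groups range [%.3f, %.3f], median %.3f\n",
              min(x$rho), max(x$rho), stats::median(x$rho)))
  invisible(x)
}

#' Select group pairs nearest to target rho values
#'
#' For each target, returns the permutation whose rho_groups is nearest
#' (ties: first encountered).
#' @param perms [permute_group_pairs()] result
#' @param targets numeric vector of rho targets
#' @return data frame with `target`, `achieved_rho`, `perm_index`, plus a
#'   `pairs` attribute (list of group-1/group-2 index sets)
#' @export
select_pairs_at <- function(perms, targets) {
  if (!length(perms$rho)) stop_rdi("no permutations available")
  if (length(perms$rho) == 1 && length(targets) > 1)
    warn_rdi("a single pair is available; it is returned for every target")
  idx <- vapply(targets, function(tg) which.min(abs(perms$rho - tg)),
                integer(1))
  pairs <- lapply(idx, function(i) {
    g1 <- perms$group1[[i]]
    list(group1 = g1, group2 = setdiff(seq_len(perms$n), g1))
  })
  out <- data.frame(target = targets, achieved_rho = perms$rho[idx],
                    perm_index = idx)
  attr(out, "pairs") <- pairs
  out
}

#' Permutation test for equal group mean FD
#'
#' Two-sided test of the group difference in mean FD under random label
#' permutation, p = (#\{|diff_perm| >= |diff_obs|\} + 1) / (n_perm + 1).
#' With `exact = TRUE` all distinct splits of the pooled subjects into
#' groups of the observed sizes are enumerated and
#' p = #\{|diff| >= |diff_obs|\} / n_splits.
#'
#' @param fd1,fd2 per-subject mean FD of the two groups
#' @param n_perm number of random permutations (ignored when exact)
#' @param seed RNG seed
#' @param exact enumerate all splits (feasible for small groups)
#' @return p-value
#' @export
fd_permutation_test <- function(fd1, fd2, n_perm = 5000, seed = 1,
                                exact = FALSE) {
  if (!length(fd1) || !length(fd2)) stop_rdi("both groups must be nonempty")
  pooled <- c(fd1, fd2)
  n1 <- length(fd1)
  obs <- abs(mean(fd1) - mean(fd2))
  diff_for <- function(idx1) {
    abs(mean(pooled[idx1]) - mean(pooled[-idx1]))
  }
  if (exact) {
    splits <- utils::combn(length(pooled), n1)
    d <- apply(splits, 2, diff_for)
    return(mean(d >= obs - 1e-12))
  }
  set.seed(seed)
  d <- replicate(n_perm, diff_for(sample.int(length(pooled), n1)))
  (sum(d >= obs - 1e-12) + 1) / (n_perm + 1)
}
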
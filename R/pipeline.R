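#' Per-subject connectivity matrices for a cohort under one strategy
#'
#' For every subject: assembles the nuisance design of the requested
#' strategy, regresses it out of the regional time courses, band-pass
#' filters the residuals, and computes the Fisher-Z connectivity matrix.
#' The voxel-based strategies (WMCSF, GSREG, COMPCOR, SAT36 and their +M6
#' variants) need a cohort generated with `voxels = TRUE`.
#'
#' @param cohort [generate_cohort()] output
#' @param strategy one of `NUISANCE_STRATEGIES`
#' @param low,high,order band-pass settings
#' @param noise_fraction CompCor tSNR quantile
#' @return list of [fisher_z_matrix()] objects
#' @export
cohort_connectivity <- function(cohort, strategy = "NOREG",
                                low = 0.01, high = 0.1, order = 4,
                                noise_fraction = 0.02) {
  strategy <- match.arg(strategy, NUISANCE_STRATEGIES)
  needs_vox <- !(strategy %in% c("NOREG", "NOREG+M6"))
  ph <- cohort$phantom
  lapply(cohort$subjects, function(s) {
    if (needs_vox && is.null(s$img))
      stop_rdi("strategy %s needs voxel data; regenerate with voxels = TRUE",
               strategy)
    design <- nuisance_design(strategy, img = s$img, brain_mask = ph$mask,
                              wm_mask = ph$wm, csf_mask = ph$csf,
                              series = s$series,
                              noise_fraction = noise_fraction)
    clean <- suppressWarnings(regress_out(s$bold, design))
    filt <- bandpass(clean, low, high, order)
    fisher_z_matrix(filt, subject = s$id, strategy = strategy)
  })
}

#' Two-group comparison of a cohort under STD and STD+RDI
#'
#' Runs the first-level denoising and connectivity for one strategy, then
#' fits the edge-wise STD and STD+RDI models and counts significant group
#' differences at the uncorrected and FDR thresholds.
#'
#' @param cohort [generate_cohort()] output
#' @param strategy nuisance strategy tag
#' @param alpha uncorrected significance threshold (default 0.01)
#' @param q FDR level (default 0.05)
#' @param ... band-pass settings forwarded to [cohort_connectivity()]
#' @return list with the two [edge_glm()] fits and a `counts` data frame
#'   (model, p_count, q_count)
#' @export
compare_groups <- function(cohort, strategy = "NOREG", alpha = 0.01,
                           q = 0.05, ...) {
  mats <- cohort_connectivity(cohort, strategy, ...)
  edges <- edge_table(mats)
  drd <- cohort_delta_rd(cohort)
  fit_std <- edge_glm(edges, cohort$pheno, "std")
  fit_rdi <- edge_glm(edges, cohort$pheno, "std_rdi", delta_rd = drd)
  counts <- data.frame(
    model = c("STD", "STD+RDI"),
    p_count = c(sum(fit_std$results$p < alpha, na.rm = TRUE),
                sum(fit_rdi$results$p < alpha, na.rm = TRUE)),
    q_count = c(sum(fdr_control(fit_std$results$p, q)$significant),
                sum(fdr_control(fit_rdi$results$p, q)$significant)))
  list(std = fit_std, rdi = fit_rdi, counts = counts, edges = edges,
       strategy = strategy, alpha = alpha, q = q)
}

validate_config <- function(config) {
  defaults <- list(strategies = "NOREG", models = c("std", "std_rdi"),
                   alpha = 0.01, q = 0.05, fd_exclusion = 0.7,
                   low = 0.01, high = 0.1, order = 4, seed = 1,
                   cohort = list())
  config <- utils::modifyList(defaults, config)
  bad <- setdiff(config$strategies, NUISANCE_STRATEGIES)
  if (length(bad))
    stop_rdi("unknown strategy tag(s): %s", paste(bad, collapse = ", "))
  if (config$alpha <= 0 || config$alpha >= 1 || config$q <= 0 || config$q >= 1)
    stop_rdi("thresholds must be in (0,1)")
  config
}

#' Run the full synthetic-cohort pipeline
#'
#' Sequences the stages (motion simulation, displacement metrics,
#' denoising, connectivity, group GLMs, SPN thresholding) for every
#' requested nuisance strategy and writes the per-strategy edge-result
#' TSVs plus a summary table of significant-edge counts per strategy and
#' model, a manifest recording the seed and configuration hash, and the
#' cohort phenotype table. Rerunning the same configuration reproduces the
#' outputs byte for byte.
#'
#' @param config list (or path to a YAML file) with entries `cohort`
#'   (arguments to [cohort_spec()]), `strategies`, `alpha`, `q`,
#'   `fd_exclusion`, `low`/`high`/`order`, `seed`
#' @param out_dir output directory
#' @return the summary data frame, invisibly; files under `out_dir`
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- do.call(cohort_spec, utils::modifyList(list(seed = config$seed),
                                                 config$cohort))
  cohort <- generate_cohort(spec)
  keep <- exclude_high_motion(stats::setNames(cohort$pheno$mean_fd,
                                              cohort$pheno$subject),
                              config$fd_exclusion)
  if (length(keep$excluded)) {
    sel <- cohort$pheno$subject %in% keep$retained
    cohort$subjects <- cohort$subjects[sel]
    cohort$pheno <- cohort$pheno[sel, ]
  }
  summary_rows <- list()
  for (strat in config$strategies) {
    cmp <- compare_groups(cohort, strat, config$alpha, config$q,
                          low = config$low, high = config$high,
                          order = config$order)
    tag <- gsub("[^A-Za-z0-9]", "_", strat)
    for (mn in intersect(config$models, c("std", "std_rdi"))) {
      fit <- if (mn == "std") cmp$std else cmp$rdi
      res <- fit$results
      res$q <- fdr_control(res$p, config$q)$qvalue
      write_tsv(format(res, digits = 10),
                file.path(out_dir, sprintf("edges_%s_%s.tsv", tag, mn)))
      spn <- build_spn(fit, "p", config$alpha)
      write_spn_tsv(spn, file.path(out_dir,
                                   sprintf("spn_%s_%s.tsv", tag, mn)))
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        strategy = strat, model = toupper(sub("_", "+", mn)),
        p_count = sum(res$p < config$alpha, na.rm = TRUE),
        q_count = sum(fdr_control(res$p, config$q)$significant))
    }
  }
  summary <- do.call(rbind, summary_rows)
  write_tsv(summary, file.path(out_dir, "summary.tsv"))
  write_tsv(cohort$pheno, file.path(out_dir, "phenotype.tsv"))
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   n_subjects = nrow(cohort$pheno),
                   excluded = keep$excluded,
                   generated = cohort$manifest)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Summarise a pipeline results directory
#'
#' Reads back the summary table and manifest written by [run_pipeline()]
#' and prints the per-strategy significant-edge counts.
#' @param dir results directory
#' @return list with `summary` and `manifest`
#' @export
report_summary <- function(dir) {
  sf <- file.path(dir, "summary.tsv")
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(sf) || !file.exists(mf))
    stop_rdi("results directory %s is incomplete", dir)
  summary <- utils::read.delim(sf)
  manifest <- jsonlite::read_json(mf)
  cat(sprintf("Pipeline results (%d subjects, seed %s)\n",
              manifest$n_subjects, manifest$seed))
  print(summary, row.names = FALSE)
  invisible(list(summary = summary, manifest = manifest))
}
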
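# Validation experiments: the scripted studies the package runs on its own
# synthetic cohorts. These back both the test suite and scripts/acceptance.R.

#' Motion-phenotype group-difference experiment
#'
#' Generates cohorts with identical latent connectivity in which the two
#' groups either share a motion phenotype (`condition = "matched"`) or
#' rotate about centres offset to opposite ends of the head
#' (`"distinct"`, +-40 mm along z), runs the first-level pipeline and the
#' STD / STD+RDI second-level models, and records the number of
#' significant group-difference edges per cohort. Any such edge is
#' artifactual by construction.
#'
#' @param n_cohorts cohorts per call
#' @param condition `"distinct"` or `"matched"` motion phenotypes
#' @param seed master seed (cohort seeds derive from it)
#' @param strategy first-level nuisance strategy
#' @param alpha,q significance thresholds
#' @param ... overrides forwarded to [cohort_spec()]
#' @return data frame with one row per cohort: `std_p`, `rdi_p` (edge
#'   counts at p < alpha), `std_q`, `rdi_q` (edge counts at FDR q)
#' @export
motion_group_experiment <- function(n_cohorts = 50,
                                    condition = c("distinct", "matched"),
                                    seed = 1, strategy = "NOREG",
                                    alpha = 0.01, q = 0.05, ...) {
  condition <- match.arg(condition)
  seeds <- derive_seeds(seed, n_cohorts)
  phen <- if (condition == "distinct") {
    list(motion_phenotype(rotation_center = c(0, 0, 40)),
         motion_phenotype(rotation_center = c(0, 0, -40)))
  } else {
    list(motion_phenotype(), motion_phenotype())
  }
  rows <- lapply(seq_len(n_cohorts), function(i) {
    spec <- cohort_spec(phenotype1 = phen[[1]], phenotype2 = phen[[2]],
                        seed = seeds[i], ...)
    cmp <- compare_groups(generate_cohort(spec), strategy, alpha, q)
    data.frame(cohort = i, condition = condition,
               std_p = cmp$counts$p_count[1], rdi_p = cmp$counts$p_count[2],
               std_q = cmp$counts$q_count[1], rdi_q = cmp$counts$q_count[2])
  })
  do.call(rbind, rows)
}

#' Planted-effect preservation experiment
#'
#' Generates matched-motion cohorts in which 10 disjoint edges carry a
#' true group difference of `effect_size` Fisher-Z units, fits STD and
#' STD+RDI, and measures the fraction of STD's planted-edge detections
#' (p < alpha) that STD+RDI retains.
#'
#' @param n_cohorts number of cohorts
#' @param effect_size planted difference (Z units)
#' @param seed master seed
#' @param alpha detection threshold
#' @param ... overrides forwarded to [cohort_spec()]
#' @return data frame per cohort: `std_detected` (of the 10 planted),
#'   `retained` (detected by both), `retention` (their ratio, NA when STD
#'   detects none)
#' @export
preservation_experiment <- function(n_cohorts = 20, effect_size = 0.3,
                                    seed = 1, alpha = 0.01, ...) {
  seeds <- derive_seeds(seed + 1L, n_cohorts)
  planted <- data.frame(A = as.character(seq(1, 19, by = 2)),
                        B = as.character(seq(2, 20, by = 2)))
  rows <- lapply(seq_len(n_cohorts), function(i) {
    spec <- cohort_spec(effect_edges = planted, effect_size = effect_size,
                        seed = seeds[i], ...)
    cmp <- compare_groups(generate_cohort(spec), "NOREG", alpha)
    key <- function(r) paste(r$A, r$B)
    pk <- key(planted)
    std_hit <- key(cmp$std$results) %in% pk & cmp$std$results$p < alpha
    rdi_hit <- key(cmp$rdi$results) %in% pk & cmp$rdi$results$p < alpha
    nstd <- sum(std_hit)
    data.frame(cohort = i, std_detected = nstd,
               retained = sum(std_hit & rdi_hit),
               retention = if (nstd > 0) sum(std_hit & rdi_hit) / nstd
                           else NA_real_)
  })
  do.call(rbind, rows)
}

#' Null calibration of the edge-wise group test
#'
#' Simulates Gaussian null responses on a fixed STD design and measures
#' the type-I error of the group t-test plus the uniformity of the t and
#' RDI-F p-value distributions.
#'
#' @param n subjects
#' @param n_sims null simulations for the rejection rate
#' @param n_ks null simulations for the uniformity checks
#' @param alpha nominal level
#' @param seed RNG seed
#' @return list: `rate` (empirical type-I error), `t_pvalues`,
#'   `f_pvalues`, `ks_t`, `ks_f` (Kolmogorov-Smirnov p-values against the
#'   uniform)
#' @export
glm_null_calibration <- function(n = 60, n_sims = 5000, n_ks = 2000,
                                 alpha = 0.05, seed = 1) {
  set.seed(seed)
  pheno <- phenotype_table(sprintf("s%03d", 1:n), rep(0:1, length.out = n),
                           stats::runif(n, 7, 35), stats::rnorm(n, 110, 15),
                           stats::rbinom(n, 1, 0.5),
                           abs(stats::rnorm(n, 0.07, 0.03)) + 0.01)
  X0 <- cbind(1, grp = pheno$group, pheno$age, pheno$iq, pheno$gender,
              pheno$mean_fd)
  drdA <- stats::rnorm(n); drdB <- stats::rnorm(n)
  X1 <- cbind(X0, drdA, drdB, drdA * drdB)
  qr0 <- qr(X0); qr1 <- qr(X1)
  # vectorised group-effect t-test under the null
  Y <- matrix(stats::rnorm(n * n_sims), n)
  B <- qr.coef(qr0, Y)
  rss <- colSums(qr.resid(qr0, Y)^2)
  df0 <- n - ncol(X0)
  se <- sqrt(rss / df0 * diag(chol2inv(qr.R(qr0)))[2])
  tp <- 2 * stats::pt(abs(B[2, ] / se), df0, lower.tail = FALSE)
  # vectorised nested F-test under the null
  Yk <- matrix(stats::rnorm(n * n_ks), n)
  r0 <- colSums(qr.resid(qr0, Yk)^2)
  r1 <- colSums(qr.resid(qr1, Yk)^2)
  df1 <- n - ncol(X1)
  Fv <- ((r0 - r1) / 3) / (r1 / df1)
  fp <- stats::pf(Fv, 3, df1, lower.tail = FALSE)
  list(rate = mean(tp < alpha),
       t_pvalues = tp, f_pvalues = fp,
       ks_t = suppressWarnings(stats::ks.test(tp, "punif"))$p.value,
       ks_f = suppressWarnings(stats::ks.test(fp, "punif"))$p.value)
}

#' RDI interaction parameter-recovery simulation
#'
#' Simulates the RDI-extended edge model with a known interaction
#' coefficient on standardised covariates and checks estimation bias and
#' the power of the nested F-test. Covariates (including the deltaRD
#' pair) are drawn standard normal so the stated noise SD and effect size
#' are in comparable units.
#'
#' @param n subjects per replicate
#' @param beta_int true interaction coefficient
#' @param sigma residual SD
#' @param reps replicates
#' @param alpha F-test level for the power estimate
#' @param seed RNG seed
#' @return list: `mean_estimate`, `bias`, `power`, `estimates`
#' @export
rdi_recovery_sim <- function(n = 200, beta_int = 0.4, sigma = 0.2,
                             reps = 500, alpha = 0.05, seed = 1) {
  set.seed(seed)
  est <- numeric(reps)
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    grp <- rep(0:1, length.out = n)
    covs <- matrix(stats::rnorm(n * 4), n)     # age, iq, gender-like, fd
    dA <- stats::rnorm(n); dB <- stats::rnorm(n)
    y <- 0.1 * grp + 0.05 * covs[, 1] + beta_int * dA * dB +
      stats::rnorm(n, 0, sigma)
    X1 <- cbind(1, grp, covs, dA, dB, dA * dB)
    X0 <- cbind(1, grp, covs)
    f1 <- stats::lm.fit(X1, y)
    f0 <- stats::lm.fit(X0, y)
    est[r] <- f1$coefficients[9]
    r1 <- sum(f1$residuals^2); r0 <- sum(f0$residuals^2)
    Fv <- ((r0 - r1) / 3) / (r1 / (n - ncol(X1)))
    rej[r] <- stats::pf(Fv, 3, n - ncol(X1), lower.tail = FALSE) < alpha
  }
  list(mean_estimate = mean(est), bias = mean(est) - beta_int,
       power = mean(rej), estimates = est)
}
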
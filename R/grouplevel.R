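#' Phenotype table for second-level models
#'
#' Validates the per-subject covariates of the edge-wise GLMs: a two-level
#' group indicator (dummy coded, 0 = control), age in years, full-scale IQ,
#' gender coded 0/1, and mean FD in mm.
#'
#' @param subject subject identifiers
#' @param group 0/1 group dummy (or a 2-level factor)
#' @param age,iq,gender,mean_fd numeric covariates
#' @return data frame of class `phenotype_table`
#' @export
phenotype_table <- function(subject, group, age, iq, gender, mean_fd) {
  if (is.factor(group) || is.character(group)) {
    lev <- unique(as.character(group))
    if (length(lev) != 2) stop_rdi("group must have exactly 2 levels")
    group <- as.integer(as.character(group) == lev[2])
  }
  tab <- data.frame(subject = as.character(subject), group = group,
                    age = age, iq = iq, gender = gender, mean_fd = mean_fd,
                    stringsAsFactors = FALSE)
  if (anyNA(tab)) stop_rdi("phenotype covariates must have no missing values")
  if (length(unique(tab$group)) != 2)
    stop_rdi("group must have exactly 2 levels")
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

EDGE_MODELS <- c("std", "std_rdi", "std_nogrp", "std_rdi_nogrp")

# base (non-RDI) design matrix for a model
base_design <- function(pheno, model) {
  X <- cbind(`(Intercept)` = 1, grp = pheno$group, age = pheno$age,
             iq = pheno$iq, gender = pheno$gender, mean_fd = pheno$mean_fd)
  if (grepl("nogrp", model)) X <- X[, colnames(X) != "grp", drop = FALSE]
  X
}

check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop_rdi("rank-deficient design: collinear column(s) %s",
             paste(bad, collapse = ", "))
  }
  qrX
}

# single OLS fit returning the pieces the edge models need
ols_pieces <- function(X, y, qrX = NULL) {
  qrX <- qrX %||% qr(X)
  beta <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  rss <- sum(res^2)
  df <- length(y) - ncol(X)
  xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  sigma2 <- rss / df
  list(beta = beta, rss = rss, df = df, se = sqrt(sigma2 * xtx_inv_diag))
}

#' Fit the edge-wise second-level GLMs
#'
#' Fits, for every edge (region pair), a Gaussian GLM of connectivity
#' strength on the phenotype covariates. The `std` model regresses
#' Fisher-Z on group, age, IQ, gender and mean FD; `std_rdi` appends the
#' Regional Displacement Interaction covariates of the edge's two endpoint
#' regions: deltaRD_A, deltaRD_B, and their product. The `*_nogrp`
#' variants drop the group term (used for characterising the interaction
#' itself and for the nested F-test). For a Gaussian family the IWLS fit
#' reduces to ordinary least squares, solved here by QR.
#'
#' The effect of interest is the group coefficient (`std`, `std_rdi`) or
#' the RDI interaction coefficient (`*_nogrp` models); its t-score is the
#' coefficient over its standard error, with a two-sided p-value on the
#' residual degrees of freedom. The variance inflation factor of the
#' effect-of-interest column against the remaining non-intercept columns
#' is reported per edge.
#'
#' @param edges long edge table (`subject`, `A`, `B`, `z`) from
#'   [edge_table()]
#' @param pheno [phenotype_table()]
#' @param model one of `"std"`, `"std_rdi"`, `"std_nogrp"`,
#'   `"std_rdi_nogrp"`
#' @param delta_rd subject x region matrix of deltaRD values (dimnames:
#'   subject ids, region ids); required for the RDI models
#' @return object of class `edge_glm`; `results` holds one row per edge
#'   (`A`, `B`, `beta`, `se`, `t`, `p`, `rss`, `df`, `vif`, `degenerate`)
#' @export
edge_glm <- function(edges, pheno, model = c("std", "std_rdi",
                                             "std_nogrp", "std_rdi_nogrp"),
                     delta_rd = NULL) {
  model <- match.arg(model)
  rdi <- grepl("rdi", model)
  if (rdi && is.null(delta_rd))
    stop_rdi("model %s needs the delta_rd matrix", model)
  subjects <- pheno$subject
  n <- length(subjects)
  key <- paste(edges$A, edges$B, sep = "\r")
  keys <- unique(key)
  Y <- matrix(NA_real_, n, length(keys))
  Y[cbind(match(edges$subject, subjects), match(key, keys))] <- edges$z
  AB <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  Xbase <- base_design(pheno, model)
  interest <- if (rdi && grepl("nogrp", model)) "rdi_ab"
              else if (grepl("nogrp", model)) "rdi_ab"
              else "grp"
  if (grepl("nogrp", model) && !rdi)
    stop_rdi("std_nogrp has no effect of interest on its own; use ftest_rdi()")
  if (n <= ncol(Xbase) + if (rdi) 3 else 0)
    stop_rdi("n = %d subjects is not enough for %d parameters", n,
             ncol(Xbase) + if (rdi) 3 else 0)
  ne <- length(keys)
  out <- data.frame(A = AB[, 1], B = AB[, 2], beta = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, rss = NA_real_,
                    df = NA_integer_, vif = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  coefs <- NULL
  if (!rdi) {
    qrX <- check_full_rank(Xbase)
    ok <- !apply(Y, 2, anyNA)
    B <- qr.coef(qrX, Y[, ok, drop = FALSE])
    R <- qr.resid(qrX, Y[, ok, drop = FALSE])
    rss <- colSums(R^2)
    df <- n - ncol(Xbase)
    xtx_inv_diag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
    j <- match(interest, colnames(Xbase))
    se <- sqrt(rss / df * xtx_inv_diag[j])
    vif <- vif_of_interest(Xbase, interest)
    out$beta[ok] <- B[j, ]
    out$se[ok] <- se
    out$rss[ok] <- rss
    out$df[ok] <- df
    out$vif[ok] <- vif
    coefs <- matrix(NA_real_, ne, nrow(B),
                    dimnames = list(NULL, rownames(B)))
    coefs[ok, ] <- t(B)
  } else {
    drd <- delta_rd[match(subjects, rownames(delta_rd)), , drop = FALSE]
    if (anyNA(drd)) stop_rdi("delta_rd is missing for some subjects")
    for (e in seq_len(ne)) {
      y <- Y[, e]
      if (anyNA(y)) next
      dA <- drd[, AB[e, 1]]
      dB <- drd[, AB[e, 2]]
      X <- cbind(Xbase, rdi_a = dA, rdi_b = dB, rdi_ab = dA * dB)
      qrX <- check_full_rank(X)
      f <- ols_pieces(X, y, qrX)
      j <- match(interest, colnames(X))
      out$beta[e] <- f$beta[j]
      out$se[e] <- f$se[j]
      out$rss[e] <- f$rss
      out$df[e] <- f$df
      out$vif[e] <- vif_of_interest(X, interest)
      if (is.null(coefs))
        coefs <- matrix(NA_real_, ne, ncol(X),
                        dimnames = list(NULL, colnames(X)))
      coefs[e, ] <- f$beta
    }
  }
  out$degenerate <- !is.na(out$rss) & out$rss < .Machine$double.eps * n
  out$t <- out$beta / out$se
  out$p <- 2 * stats::pt(abs(out$t), out$df, lower.tail = FALSE)
  out$p[out$degenerate] <- 0
  structure(list(results = out, coefficients = coefs, model = model,
                 effect = interest, n = n,
                 terms = colnames(coefs)),
            class = "edge_glm")
}

#' @export
print.edge_glm <- function(x, ...) {
  cat(sprintf("Edge-wise GLM (%s), effect of interest: %s\n",
              toupper(sub("_", "+", sub("_nogrp", " (no group)", x$model))),
              x$effect))
  cat(sprintf("  %d edges, %d subjects, residual df %d\n",
              nrow(x$results), x$n, x$results$df[1]))
  sig <- sum(x$results$p < 0.01, na.rm = TRUE)
  cat(sprintf("  %d edges with p < 0.01\n", sig))
  invisible(x)
}

#' @export
summary.edge_glm <- function(object, alpha = 0.01, q = 0.05, ...) {
  r <- object$results
  qv <- fdr_control(r$p, q)
  structure(list(model = object$model, effect = object$effect,
                 n = object$n, n_edges = nrow(r),
                 n_p = sum(r$p < alpha, na.rm = TRUE),
                 n_q = sum(qv$significant, na.rm = TRUE),
                 alpha = alpha, q = q,
                 max_vif = suppressWarnings(max(r$vif, na.rm = TRUE))),
            class = "summary.edge_glm")
}

#' @export
print.summary.edge_glm <- function(x, ...) {
  cat(sprintf("Edge-wise GLM summary (%s): %d subjects, %d edges\n",
              x$model, x$n, x$n_edges))
  cat(sprintf("  p < %g: %d edges;  FDR q < %g: %d edges;  max VIF %.2f\n",
              x$alpha, x$n_p, x$q, x$n_q, x$max_vif))
  invisible(x)
}

#' @export
coef.edge_glm <- function(object, ...) object$coefficients

#' Nested F-test of the RDI covariates
#'
#' Compares the model without and with the RDI covariate set on identical
#' subject rows, per edge:
#' F = ((RSS_std - RSS_rdi)/3) / (RSS_rdi / (n - p_rdi)), with a p-value
#' from the F(3, n - p_rdi) distribution. By default the group term is
#' excluded from both models (the interaction-characterisation setting);
#' set `include_group = TRUE` to keep it.
#'
#' @param edges long edge table
#' @param pheno [phenotype_table()]
#' @param delta_rd subject x region deltaRD matrix
#' @param include_group keep the group dummy in both nested models
#' @return data frame (`A`, `B`, `F`, `p`, `df1`, `df2`, `degenerate`)
#' @export
ftest_rdi <- function(edges, pheno, delta_rd, include_group = FALSE) {
  m0 <- if (include_group) "std" else "std_nogrp"
  m1 <- if (include_group) "std_rdi" else "std_rdi_nogrp"
  fit0 <- if (include_group) edge_glm(edges, pheno, m0)
          else edge_glm_rss(edges, pheno, m0, NULL)
  fit1 <- edge_glm(edges, pheno, m1, delta_rd)
  r0 <- if (is.data.frame(fit0)) fit0 else fit0$results
  r1 <- fit1$results
  stopifnot(identical(r0$A, r1$A), identical(r0$B, r1$B))
  df2 <- r1$df
  Fv <- ((r0$rss - r1$rss) / 3) / (r1$rss / df2)
  degenerate <- r1$rss < .Machine$double.eps * fit1$n
  p <- stats::pf(Fv, 3, df2, lower.tail = FALSE)
  p[degenerate] <- 0
  data.frame(A = r1$A, B = r1$B, F = Fv, p = p, df1 = 3, df2 = df2,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

# internal: RSS-only fit for models without an effect of interest
edge_glm_rss <- function(edges, pheno, model, delta_rd) {
  subjects <- pheno$subject
  key <- paste(edges$A, edges$B, sep = "\r")
  keys <- unique(key)
  Y <- matrix(NA_real_, length(subjects), length(keys))
  Y[cbind(match(edges$subject, subjects), match(key, keys))] <- edges$z
  AB <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  X <- base_design(pheno, model)
  qrX <- check_full_rank(X)
  ok <- !apply(Y, 2, anyNA)
  rss <- rep(NA_real_, length(keys))
  rss[ok] <- colSums(qr.resid(qrX, Y[, ok, drop = FALSE])^2)
  data.frame(A = AB[, 1], B = AB[, 2], rss = rss,
             df = length(subjects) - ncol(X), stringsAsFactors = FALSE)
}

#' Pooled RDI model over all edges
#'
#' Concatenates the dependent and independent variables of the
#' no-group RDI model over every edge of every subject and fits one GLM to
#' all of them; the effect of interest is the RDI interaction term. Used
#' to characterise the overall direction of the interaction and to
#' produce the predicted-connectivity surface over a deltaRD_A x deltaRD_B
#' lattice (other covariates held at their means).
#'
#' @param edges long edge table
#' @param pheno [phenotype_table()]
#' @param delta_rd subject x region deltaRD matrix
#' @param row_cap refuse to build a design larger than this many rows
#'   (memory guard); subsample edges to stay below it
#' @return object of class `pooled_rdi` with `coefficients` table,
#'   `interaction` (beta, se, t, p), `n_rows`
#' @export
pooled_rdi <- function(edges, pheno, delta_rd, row_cap = 2e6) {
  i <- match(edges$subject, pheno$subject)
  if (anyNA(i)) stop_rdi("edge table contains subjects missing from pheno")
  if (nrow(edges) > row_cap)
    stop_rdi("pooled design would have %d rows (cap %g); subsample edges",
             nrow(edges), row_cap)
  si <- match(edges$subject, rownames(delta_rd))
  dA <- delta_rd[cbind(si, match(edges$A, colnames(delta_rd)))]
  dB <- delta_rd[cbind(si, match(edges$B, colnames(delta_rd)))]
  X <- cbind(`(Intercept)` = 1, age = pheno$age[i], iq = pheno$iq[i],
             gender = pheno$gender[i], mean_fd = pheno$mean_fd[i],
             rdi_a = dA, rdi_b = dB, rdi_ab = dA * dB)
  ok <- !is.na(edges$z)
  f <- ols_pieces(X[ok, , drop = FALSE], edges$z[ok])
  tv <- f$beta / f$se
  pv <- 2 * stats::pt(abs(tv), f$df, lower.tail = FALSE)
  ctab <- data.frame(term = colnames(X), beta = f$beta, se = f$se,
                     t = tv, p = pv, row.names = NULL)
  means <- colMeans(X[ok, , drop = FALSE])
  structure(list(coefficients = ctab,
                 interaction = ctab[ctab$term == "rdi_ab", ],
                 covariate_means = means, n_rows = sum(ok), df = f$df),
            class = "pooled_rdi")
}

#' @export
print.pooled_rdi <- function(x, ...) {
  cat(sprintf("Pooled RDI model: %d stacked rows, residual df %d\n",
              x$n_rows, x$df))
  with(x$interaction,
       cat(sprintf("  interaction: beta %.4g, t = %.2f, p = %.3g\n",
                   beta, t, p)))
  invisible(x)
}

#' Predicted connectivity surface of the pooled RDI model
#'
#' Evaluates the pooled model over a deltaRD_A x deltaRD_B lattice with
#' the remaining covariates at their means.
#' @param object [pooled_rdi()] fit
#' @param grid_a,grid_b lattice values; default 41 points spanning
#'   +-2 SD-equivalents of the fitted deltaRD columns
#' @param ... unused
#' @return list with `a`, `b`, `z` (matrix length(a) x length(b)), usable
#'   directly with [graphics::filled.contour()]
#' @export
predict.pooled_rdi <- function(object, grid_a = NULL, grid_b = NULL, ...) {
  b <- object$coefficients$beta
  names(b) <- object$coefficients$term
  mu <- object$covariate_means
  rng <- max(abs(mu[c("rdi_a", "rdi_b")])) + 3 * abs(mu["rdi_ab"])^(1/2)
  grid_a <- grid_a %||% seq(-rng, rng, length.out = 41)
  grid_b <- grid_b %||% seq(-rng, rng, length.out = 41)
  zhat <- outer(grid_a, grid_b, function(a, bb) {
    b["(Intercept)"] + b["age"] * mu["age"] + b["iq"] * mu["iq"] +
      b["gender"] * mu["gender"] + b["mean_fd"] * mu["mean_fd"] +
      b["rdi_a"] * a + b["rdi_b"] * bb + b["rdi_ab"] * a * bb
  })
  list(a = grid_a, b = grid_b, z = zhat)
}

#' @export
plot.pooled_rdi <- function(x, ...) {
  s <- predict(x)
  graphics::filled.contour(s$a, s$b, s$z,
                           xlab = "deltaRD A (mm)", ylab = "deltaRD B (mm)",
                           main = "Predicted connectivity (Fisher-Z)", ...)
  invisible(x)
}

#' Variance inflation factor of the effect-of-interest column
#'
#' VIF = 1 / (1 - R^2) where R^2 comes from regressing the column of
#' interest on the remaining non-intercept columns (with intercept).
#' Perfect collinearity is reported as `Inf`.
#' @param X design matrix including an intercept column
#' @param interest column name or index of the effect of interest
#' @return scalar VIF
#' @export
vif_of_interest <- function(X, interest) {
  j <- if (is.character(interest)) match(interest, colnames(X)) else interest
  icept <- which(colnames(X) %in% "(Intercept)")
  others <- setdiff(seq_len(ncol(X)), c(j, icept))
  if (length(others) < 1) stop_rdi("need at least 2 non-intercept columns")
  y <- X[, j]
  Z <- cbind(1, X[, others, drop = FALSE])
  res <- qr.resid(qr(Z), y)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  if (r2 > 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

#' Benjamini-Hochberg false-discovery-rate control
#' @param p p-value vector (NAs tolerated)
#' @param q FDR level (default 0.05)
#' @return list with `qvalue` and logical `significant` (`qvalue < q`)
#' @export
fdr_control <- function(p, q = 0.05) {
  if (!length(p)) stop_rdi("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_rdi("p-values must be in [0,1]")
  qv <- stats::p.adjust(p, method = "BH")
  list(qvalue = qv, significant = !is.na(qv) & qv < q)
}

#' Threshold edge-wise statistics into a statistical parametric network
#'
#' @param fit [edge_glm()] result (or a data frame with `A`, `B`, `t`,
#'   `p`)
#' @param rule `"p"` (uncorrected p < alpha) or `"q"` (BH FDR q < alpha)
#' @param alpha threshold level (default 0.01 for `"p"`, use 0.05 for
#'   `"q"`)
#' @return object of class `spn`: surviving `edges` (with `t`, `p`, `q`,
#'   `sign`), `n_edges`, `rule`, `alpha`
#' @export
build_spn <- function(fit, rule = c("p", "q"), alpha = 0.01) {
  rule <- match.arg(rule)
  r <- if (inherits(fit, "edge_glm")) fit$results else fit
  qv <- fdr_control(r$p, if (rule == "q") alpha else 0.05)
  r$q <- qv$qvalue
  keep <- if (rule == "p") !is.na(r$p) & (r$p < alpha | alpha >= 1)
          else qv$significant
  edges <- r[keep, , drop = FALSE]
  edges$sign <- sign(edges$t)
  structure(list(edges = edges, n_edges = sum(keep), rule = rule,
                 alpha = alpha, n_total = nrow(r)),
            class = "spn")
}

#' @export
print.spn <- function(x, ...) {
  cat(sprintf("SPN: %d of %d edges survive %s < %g\n",
              x$n_edges, x$n_total, if (x$rule == "p") "p" else "FDR q",
              x$alpha))
  invisible(x)
}

#' Write an SPN edge list as TSV
#' @param spn [build_spn()] result
#' @param path output file
#' @export
write_spn_tsv <- function(spn, path) {
  utils::write.table(spn$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param coords optional region x 2 matrix of node positions (rownames =
#'   region ids) for a simple node-edge sketch
#' @rdname build_spn
#' @export
plot.spn <- function(x, coords = NULL, ...) {
  if (is.null(coords)) stop_rdi("node coordinates required for plotting")
  graphics::plot(coords, pch = 16, col = "grey40", asp = 1,
                 xlab = "", ylab = "", main = sprintf(
                   "SPN (%s < %g): %d edges", x$rule, x$alpha, x$n_edges), ...)
  for (i in seq_len(nrow(x$edges))) {
    a <- coords[as.character(x$edges$A[i]), ]
    b <- coords[as.character(x$edges$B[i]), ]
    graphics::segments(a[1], a[2], b[1], b[2],
                       col = if (x$edges$sign[i] > 0) "firebrick" else "navy")
  }
  invisible(x)
}
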
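#' Per-subject wide table for the path model
#'
#' Restricts to one group, averages hemispheres, and spreads T2
#' heterogeneity and ICV-corrected volume across subfield columns
#' (`sigma_<subfield>`, `vol_<subfield>`), with pooled-cohort `age_z` and
#' the standardized PAL outcomes. Use a table Z-scored with the
#' `hc_by_subfield` reference so every structural measure is 0 +/- 1 in HC
#' and between-subfield level differences are removed.
#'
#' @param tab cohort table from [zscore_by_reference].
#' @param group `"HC"` (default) or `"MCI"`.
#' @param sigma_col,vol_col metric columns to use.
#' @return wide data.frame, complete cases only.
#' @export
make_path_data <- function(tab, group = "HC", sigma_col = "t2_sigma_z",
                           vol_col = "icv_ratio_z") {
  d <- tab[tab$group == group, ]
  hs <- .hemi_average(d, sigma_col)
  hv <- .hemi_average(d, vol_col)
  ws <- stats::reshape(hs[, c("subject_id", "subfield", sigma_col)],
                       idvar = "subject_id", timevar = "subfield",
                       direction = "wide")
  names(ws) <- sub(paste0(sigma_col, "\\."), "sigma_", names(ws))
  wv <- stats::reshape(hv[, c("subject_id", "subfield", vol_col)],
                       idvar = "subject_id", timevar = "subfield",
                       direction = "wide")
  names(wv) <- sub(paste0(vol_col, "\\."), "vol_", names(wv))
  first <- hs[!duplicated(hs$subject_id),
              c("subject_id", "age_z", "pal_accuracy", "pal_rt")]
  out <- merge(merge(first, ws, by = "subject_id"), wv, by = "subject_id")
  out[stats::complete.cases(out), ]
}

# standardized recursive OLS system; returns named vector of direct +
# indirect path estimates. X columns already standardized by caller.
.estimate_paths <- function(X, subfields, outcome_col) {
  sd0 <- apply(X, 2, stats::sd)
  if (any(sd0 == 0)) return(NULL)
  Z <- scale(X)
  age <- Z[, "age_z"]
  one <- rep(1, nrow(Z))
  est <- c()
  a <- b <- avl <- cvl <- svl <- stats::setNames(numeric(length(subfields)),
                                                 subfields)
  for (sf in subfields) {
    sig <- Z[, paste0("sigma_", sf)]
    vol <- Z[, paste0("vol_", sf)]
    a[sf] <- stats::.lm.fit(cbind(one, age), sig)$coefficients[2]
    cf <- stats::.lm.fit(cbind(one, age, sig), vol)$coefficients
    avl[sf] <- cf[2]; b[sf] <- cf[3]
  }
  Xo <- cbind(one, age,
              Z[, paste0("sigma_", subfields), drop = FALSE],
              Z[, paste0("vol_", subfields), drop = FALSE])
  co <- stats::.lm.fit(Xo, Z[, outcome_col])$coefficients
  age_out <- co[2]
  svl <- stats::setNames(co[3:(2 + length(subfields))], subfields)
  cvl <- stats::setNames(co[(3 + length(subfields)):length(co)], subfields)
  for (sf in subfields) {
    est[paste0("age->sigma_", sf)] <- a[sf]
    est[paste0("age->vol_", sf)] <- avl[sf]
    est[paste0("sigma_", sf, "->vol_", sf)] <- b[sf]
    est[paste0("sigma_", sf, "->PAL")] <- svl[sf]
    est[paste0("vol_", sf, "->PAL")] <- cvl[sf]
  }
  est["age->PAL"] <- age_out
  for (sf in subfields) {
    est[paste0("age->sigma_", sf, "->vol_", sf)] <- a[sf] * b[sf]
    est[paste0("sigma_", sf, "->vol_", sf, "->PAL")] <- b[sf] * cvl[sf]
    est[paste0("age->sigma_", sf, "->vol_", sf, "->PAL")] <-
      a[sf] * b[sf] * cvl[sf]
  }
  est["age->sigma->vol->PAL(total)"] <- sum(a * b * cvl)
  est
}

# analytic (normal-theory) p-values: OLS t for directs, multivariate
# delta method for products of coefficients
.analytic_paths_p <- function(X, subfields, outcome_col, est) {
  Z <- scale(X)
  n <- nrow(Z)
  age <- Z[, "age_z"]
  se <- p <- stats::setNames(rep(NA_real_, length(est)), names(est))
  ols <- function(xm, y) {
    fit <- stats::lm.fit(xm, y)
    s2 <- sum(fit$residuals^2) / fit$df.residual
    list(b = fit$coefficients, se = sqrt(diag(chol2inv(chol(crossprod(xm))) * s2)),
         df = fit$df.residual)
  }
  one <- rep(1, n)
  A <- B <- list()
  for (sf in subfields) {
    sig <- Z[, paste0("sigma_", sf)]
    vol <- Z[, paste0("vol_", sf)]
    fa <- ols(cbind(one, age), sig)
    fv <- ols(cbind(one, age, sig), vol)
    A[[sf]] <- c(fa$b[2], fa$se[2], fa$df)
    B[[sf]] <- c(fv$b[3], fv$se[3], fv$df)
    p[paste0("age->sigma_", sf)] <-
      2 * stats::pt(-abs(fa$b[2] / fa$se[2]), fa$df)
    p[paste0("age->vol_", sf)] <- 2 * stats::pt(-abs(fv$b[2] / fv$se[2]), fv$df)
    p[paste0("sigma_", sf, "->vol_", sf)] <-
      2 * stats::pt(-abs(fv$b[3] / fv$se[3]), fv$df)
  }
  Xo <- cbind(one, age, Z[, paste0("sigma_", subfields), drop = FALSE],
              Z[, paste0("vol_", subfields), drop = FALSE])
  fo <- ols(Xo, Z[, outcome_col])
  p["age->PAL"] <- 2 * stats::pt(-abs(fo$b[2] / fo$se[2]), fo$df)
  Cvl <- list()
  for (i in seq_along(subfields)) {
    sf <- subfields[i]
    js <- 2 + i; jv <- 2 + length(subfields) + i
    p[paste0("sigma_", sf, "->PAL")] <-
      2 * stats::pt(-abs(fo$b[js] / fo$se[js]), fo$df)
    p[paste0("vol_", sf, "->PAL")] <-
      2 * stats::pt(-abs(fo$b[jv] / fo$se[jv]), fo$df)
    Cvl[[sf]] <- c(fo$b[jv], fo$se[jv], fo$df)
  }
  sobel <- function(terms) {
    bs <- vapply(terms, `[`, numeric(1), 1)
    ses <- vapply(terms, `[`, numeric(1), 2)
    prod_b <- prod(bs)
    v <- sum((prod_b / bs)^2 * ses^2)
    z <- prod_b / sqrt(v)
    2 * stats::pnorm(-abs(z))
  }
  for (sf in subfields) {
    p[paste0("age->sigma_", sf, "->vol_", sf)] <- sobel(list(A[[sf]], B[[sf]]))
    p[paste0("sigma_", sf, "->vol_", sf, "->PAL")] <-
      sobel(list(B[[sf]], Cvl[[sf]]))
    p[paste0("age->sigma_", sf, "->vol_", sf, "->PAL")] <-
      sobel(list(A[[sf]], B[[sf]], Cvl[[sf]]))
  }
  # total over subfields: delta-method variance of sum of triple products,
  # treating per-subfield estimates as independent across equations
  vtot <- 0
  for (sf in subfields) {
    aa <- A[[sf]]; bb <- B[[sf]]; cc <- Cvl[[sf]]
    vtot <- vtot + (bb[1] * cc[1])^2 * aa[2]^2 +
      (aa[1] * cc[1])^2 * bb[2]^2 + (aa[1] * bb[1])^2 * cc[2]^2
  }
  p["age->sigma->vol->PAL(total)"] <-
    2 * stats::pnorm(-abs(est["age->sigma->vol->PAL(total)"] / sqrt(vtot)))
  p
}

#' Regression-based path model of age, T2 heterogeneity, volume and memory
#'
#' Estimates a recursive system of standardized OLS equations under the
#' theory-driven direction constraints: T2 heterogeneity may not be
#' predicted by volume, memory predicts nothing, nothing predicts age.
#' The equations are: each subfield's sigma on age; each subfield's
#' volume on age and its own sigma; the PAL outcome on age, all sigmas
#' and all volumes. Indirect effects are products of the constituent
#' direct estimates. Inference is by bias-corrected percentile bootstrap
#' over subjects (`n_boot >= 200` recommended) or, with `n_boot = 0`, by
#' normal-theory OLS t-tests with delta-method (Sobel) p-values for
#' products. Benjamini-Hochberg FDR is applied across all paths.
#'
#' @param data wide table from [make_path_data].
#' @param outcome `"pal_accuracy"` or `"pal_rt"`.
#' @param subfields subfields in the model.
#' @param n_boot bootstrap resamples (0 = analytic inference).
#' @param seed RNG seed for the bootstrap.
#' @param conf CI level.
#' @param fdr_alpha significance threshold on FDR-adjusted p.
#' @return object of class `path_model_result`: data.frame `paths` with
#'   estimate, ci_lo, ci_hi, p, p_fdr, significant, type; plus `n`,
#'   `n_boot`, `seed`, `unstable` (TRUE if > 1% of resamples produced
#'   non-finite estimates).
#' @export
path_model <- function(data, outcome = c("pal_accuracy", "pal_rt"),
                       subfields = analysis_subfields(), n_boot = 2000,
                       seed = 1L, conf = 0.95, fdr_alpha = 0.05) {
  outcome <- match.arg(outcome)
  need <- c("age_z", outcome, paste0("sigma_", subfields),
            paste0("vol_", subfields))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  X <- as.matrix(data[, need])
  est <- .estimate_paths(X, subfields, outcome)
  if (is.null(est)) stop("degenerate data: a variable has zero variance",
                         call. = FALSE)
  n <- nrow(X)
  unstable <- FALSE
  if (n_boot > 0) {
    if (n_boot < 200)
      warning("n_boot < 200; bootstrap inference will be unstable",
              call. = FALSE)
    set.seed(seed)
    boots <- matrix(NA_real_, n_boot, length(est))
    for (bi in seq_len(n_boot)) {
      e <- .estimate_paths(X[sample.int(n, n, replace = TRUE), , drop = FALSE],
                           subfields, outcome)
      if (!is.null(e)) boots[bi, ] <- e
    }
    bad <- rowSums(!is.finite(boots)) > 0
    unstable <- mean(bad) > 0.01
    boots <- boots[!bad, , drop = FALSE]
    zc <- stats::qnorm(c((1 - conf) / 2, 1 - (1 - conf) / 2))
    ci <- matrix(NA_real_, length(est), 2)
    pv <- numeric(length(est))
    for (j in seq_along(est)) {
      bj <- boots[, j]
      z0 <- stats::qnorm(pmin(pmax(mean(bj < est[j]), 1 / length(bj)),
                              1 - 1 / length(bj)))
      ci[j, ] <- stats::quantile(bj, stats::pnorm(2 * z0 + zc),
                                 names = FALSE, type = 6)
      p0 <- pmin(pmax(mean(bj <= 0), 1 / length(bj)), 1 - 1 / length(bj))
      alpha0 <- stats::pnorm(stats::qnorm(p0) - 2 * z0)
      pv[j] <- 2 * min(alpha0, 1 - alpha0)
    }
  } else {
    pv <- .analytic_paths_p(X, subfields, outcome, est)
    ci <- matrix(NA_real_, length(est), 2)
  }
  typ <- ifelse(grepl("->.*->", names(est)), "indirect", "direct")
  pf <- fdr_bh(pv)
  res <- data.frame(path = names(est), type = typ, estimate = unname(est),
                    ci_lo = ci[, 1], ci_hi = ci[, 2], p = unname(pv),
                    p_fdr = unname(pf), significant = unname(pf) < fdr_alpha,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(list(paths = res, outcome = outcome, n = n, n_boot = n_boot,
                 seed = seed, unstable = unstable),
            class = "path_model_result")
}

#' @export
print.path_model_result <- function(x, ...) {
  cat(sprintf("path model (outcome %s), n = %d, %s inference%s\n",
              x$outcome, x$n,
              if (x$n_boot > 0) sprintf("bootstrap (%d)", x$n_boot)
              else "analytic",
              if (x$unstable) " [UNSTABLE RESAMPLES]" else ""))
  sig <- x$paths[x$paths$significant, ]
  cat(sprintf("  %d/%d paths FDR-significant\n", nrow(sig), nrow(x$paths)))
  for (i in seq_len(nrow(sig)))
    cat(sprintf("  %-38s %+.3f (p_fdr = %.4f)\n", sig$path[i],
                sig$estimate[i], sig$p_fdr[i]))
  invisible(x)
}
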
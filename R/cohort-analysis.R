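#' Benjamini-Hochberg and Bonferroni p-value adjustment
#'
#' `fdr_bh` implements the Benjamini-Hochberg step-up procedure: sorted
#' ascending, `p_(i) * m / i`, enforced monotone from the largest p down,
#' capped at 1. `bonferroni` is `min(1, m * p)`.
#'
#' @param p p-values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return adjusted p-values in the original order.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

#' @rdname fdr_bh
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, m * p)
}

#' Pool studies by reference-stratum Z-scoring
#'
#' Converts raw per-subfield metrics to Z-scores separately within each
#' study so that studies acquired with different scanners/scales can be
#' pooled. Three reference conventions are supported:
#' \describe{
#'   \item{`left_dg_hc`}{one reference stratum per study and metric: the
#'     left DG of healthy controls. Group, subfield and hemisphere
#'     differences are preserved within each study (default; used for the
#'     group/age battery).}
#'   \item{`hc_by_subfield`}{per study, subfield and metric, referenced to
#'     HC, so every subfield's HC distribution is 0 +/- 1 and between-
#'     subfield differences are removed (used by the path model).}
#'   \item{`mci_by_subfield`}{as above but referenced to the MCI
#'     population (used for decline prediction).}
#' }
#' A pooled-cohort `age_z` column and per-study HC-referenced cognition
#' Z-scores are added.
#'
#' @param metrics long data.frame: subject_id, subfield, hemisphere and
#'   metric columns.
#' @param meta subject metadata (subject_id, study, group, age,
#'   cognition_baseline, cognition_followup, pal_accuracy, pal_rt).
#' @param reference reference convention, see above.
#' @param metric_cols columns of `metrics` to Z-score.
#' @return long cohort table: metrics joined to metadata with `<col>_z`
#'   columns and `age_z`.
#' @export
zscore_by_reference <- function(metrics, meta,
                                reference = c("left_dg_hc", "hc_by_subfield",
                                              "mci_by_subfield"),
                                metric_cols = c("t2_sigma", "t2_mu",
                                                "volume_mm3", "icv_ratio")) {
  reference <- match.arg(reference)
  metric_cols <- intersect(metric_cols, names(metrics))
  tab <- merge(metrics, meta, by = "subject_id", sort = FALSE)
  if (any(is.na(tab$group)) || any(is.na(tab$age)))
    stop("every row needs group and age", call. = FALSE)

  zcol <- function(x, ref_sel, strata, what) {
    out <- rep(NA_real_, length(x))
    for (s in unique(strata)) {
      in_s <- strata == s
      ref <- x[in_s & ref_sel]
      ref <- ref[is.finite(ref)]
      if (length(ref) < 2 || stats::sd(ref) == 0)
        stop(sprintf("empty/degenerate reference stratum: study %s, %s",
                     s, what), call. = FALSE)
      out[in_s] <- (x[in_s] - mean(ref)) / stats::sd(ref)
    }
    out
  }

  for (cc in metric_cols) {
    if (reference == "left_dg_hc") {
      sel <- tab$subfield == "DG" & tab$hemisphere == "L" & tab$group == "HC"
      tab[[paste0(cc, "_z")]] <- zcol(tab[[cc]], sel, tab$study, cc)
    } else {
      grp <- if (reference == "hc_by_subfield") "HC" else "MCI"
      strata <- paste(tab$study, tab$subfield)
      tab[[paste0(cc, "_z")]] <- zcol(tab[[cc]], tab$group == grp, strata, cc)
    }
  }
  tab$age_z <- (tab$age - mean(meta$age)) / stats::sd(meta$age)
  ref_grp <- if (reference == "mci_by_subfield") "MCI" else "HC"
  for (cc in intersect(c("cognition_baseline", "cognition_followup"),
                       names(tab))) {
    ok <- is.finite(tab[[cc]])
    z <- rep(NA_real_, nrow(tab))
    for (s in unique(tab$study)) {
      sel <- tab$study == s & ok
      ref <- tab[[cc]][sel & tab$group == ref_grp]
      if (length(unique(tab$subject_id[sel & tab$group == ref_grp])) >= 2 &&
          stats::sd(ref) > 0)
        z[sel] <- (tab[[cc]][sel] - mean(ref)) / stats::sd(ref)
    }
    tab[[paste0(cc, "_z")]] <- z
  }
  tab
}

# hemisphere-averaged wide-ish table: one row per subject x subfield
.hemi_average <- function(tab, metric) {
  agg <- stats::aggregate(tab[[metric]],
                          by = list(subject_id = tab$subject_id,
                                    subfield = tab$subfield),
                          FUN = mean, na.rm = TRUE)
  names(agg)[3] <- metric
  subj_cols <- intersect(
    c("subject_id", "study", "group", "age", "age_z", "sex", "education",
      "cognition_baseline", "cognition_followup", "cognition_baseline_z",
      "cognition_followup_z", "pal_accuracy", "pal_rt", "icv"),
    names(tab))
  merge(agg, tab[!duplicated(tab$subject_id), subj_cols],
        by = "subject_id", sort = FALSE)
}

#' Age-adjusted group contrasts per subfield
#'
#' Hemispheres are averaged per subject and subfield, then the group
#' contrast (MCI minus HC) is estimated corrected for age. Two
#' age-correction modes:
#' \describe{
#'   \item{`ancova`}{(default) `metric ~ age_z + group`; the group effect
#'     is adjusted for age without the age term absorbing any of it.
#'     Cohen's d = group coefficient / residual SD.}
#'   \item{`residualize`}{metric residualized on age alone (pooled OLS),
#'     then a two-sample t-test on residuals with pooled-SD d.}
#' }
#' Bonferroni correction is applied over subfields.
#'
#' @param tab cohort table from [zscore_by_reference].
#' @param metric column to test (e.g. `"t2_sigma_z"`).
#' @param subfields which subfields to test.
#' @param adjust age-correction mode, see above.
#' @return data.frame per subfield: t, df, p, p_bonf, cohens_d, direction.
#' @export
adjusted_group_stats <- function(tab, metric = "t2_sigma_z",
                                 subfields = analysis_subfields(),
                                 adjust = c("ancova", "residualize")) {
  adjust <- match.arg(adjust)
  h <- .hemi_average(tab, metric)
  rows <- lapply(subfields, function(sf) {
    d <- h[h$subfield == sf & is.finite(h[[metric]]), ]
    if (length(unique(d$group)) < 2) {
      warning("subfield ", sf, ": a group is empty, skipped", call. = FALSE)
      return(NULL)
    }
    g <- as.numeric(d$group == "MCI")
    if (adjust == "ancova") {
      fit <- stats::lm(d[[metric]] ~ d$age_z + g)
      sm <- summary(fit)
      beta <- stats::coef(fit)[["g"]]
      tval <- sm$coefficients["g", "t value"]
      p <- sm$coefficients["g", "Pr(>|t|)"]
      df <- fit$df.residual
      dd <- beta / sm$sigma
    } else {
      r <- stats::resid(stats::lm(d[[metric]] ~ d$age_z))
      tt <- stats::t.test(r[g == 1], r[g == 0], var.equal = TRUE)
      tval <- unname(tt$statistic); p <- tt$p.value; df <- unname(tt$parameter)
      n1 <- sum(g == 1); n0 <- sum(g == 0)
      sp <- sqrt(((n1 - 1) * stats::var(r[g == 1]) +
                  (n0 - 1) * stats::var(r[g == 0])) / (n1 + n0 - 2))
      dd <- (mean(r[g == 1]) - mean(r[g == 0])) / sp
    }
    data.frame(subfield = sf, t = tval, df = df, p = p, cohens_d = dd,
               direction = "MCI-HC", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out$p_bonf <- bonferroni(out$p, m = length(subfields))
  rownames(out) <- NULL
  out[, c("subfield", "t", "df", "p", "p_bonf", "cohens_d", "direction")]
}

#' Per-subfield age association
#'
#' Simple linear regression of the hemisphere-averaged metric on age per
#' subfield; R^2 is the squared correlation. Bonferroni over subfields.
#'
#' @inheritParams adjusted_group_stats
#' @return data.frame per subfield: r_squared, f, df1, df2, p, p_bonf.
#' @export
age_association <- function(tab, metric = "t2_sigma_z",
                            subfields = analysis_subfields()) {
  h <- .hemi_average(tab, metric)
  if (stats::sd(h$age) == 0) stop("zero age variance", call. = FALSE)
  rows <- lapply(subfields, function(sf) {
    d <- h[h$subfield == sf & is.finite(h[[metric]]), ]
    if (nrow(d) < 3) stop("need >= 3 subjects", call. = FALSE)
    fit <- stats::lm(d[[metric]] ~ d$age)
    sm <- summary(fit)
    f <- unname(sm$fstatistic)
    data.frame(subfield = sf, r_squared = sm$r.squared,
               f = f[1], df1 = f[2], df2 = f[3],
               p = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- bonferroni(out$p, m = length(subfields))
  rownames(out) <- NULL
  out
}

#' Wide per-subject predictor table for decline prediction
#'
#' Restricts to MCI subjects with follow-up cognition, averages
#' hemispheres, and spreads one metric across subfield columns. A
#' whole-hippocampus column `Hipp` (mean of the DG, CA and SUB Z-scores)
#' is added as a candidate.
#'
#' @param tab cohort table, Z-scored with `mci_by_subfield` reference.
#' @param metric metric column (typically `"t2_sigma_z"`).
#' @return data.frame: one row per subject with followup, baseline, age_z
#'   and one column per candidate.
#' @export
make_stepwise_data <- function(tab, metric = "t2_sigma_z") {
  h <- .hemi_average(tab[tab$group == "MCI", ], metric)
  h <- h[is.finite(h$cognition_followup_z), ]
  wide <- stats::reshape(
    h[, c("subject_id", "subfield", metric)],
    idvar = "subject_id", timevar = "subfield", direction = "wide")
  names(wide) <- sub(paste0(metric, "\\."), "", names(wide))
  wide$Hipp <- rowMeans(wide[, intersect(c("DG", "CA", "SUB"), names(wide))])
  first <- h[!duplicated(h$subject_id),
             c("subject_id", "age_z", "cognition_baseline_z",
               "cognition_followup_z")]
  merge(first, wide, by = "subject_id", sort = FALSE)
}

#' Forward stepwise regression with forced covariates
#'
#' Starts from the forced-covariate model and iteratively adds the
#' candidate with the smallest partial-F p-value while that p-value is
#' below `alpha`; forced covariates are never removed. Ties are broken by
#' larger partial F, then alphabetically. Deterministic for fixed data.
#'
#' @param data data.frame containing all columns.
#' @param outcome outcome column name.
#' @param forced character vector of forced covariate columns.
#' @param candidates character vector of candidate columns.
#' @param alpha entry threshold on the partial-F p-value.
#' @return object of class `stepwise_result`: `entered` (data.frame of
#'   entry order, coefficient at entry, F, p), `coefficients` of the
#'   final model, `r_squared`, `aic`, `base_r_squared`, `base_aic`, `n`.
#' @export
stepwise_forward <- function(data, outcome, forced, candidates,
                             alpha = 0.05) {
  data <- data[stats::complete.cases(data[, c(outcome, forced, candidates)]), ]
  n <- nrow(data)
  fit_with <- function(vars) {
    X <- as.matrix(cbind(`(Intercept)` = 1, data[, vars, drop = FALSE]))
    if (qr(X)$rank < ncol(X))
      stop("singular design; collinear columns among: ",
           paste(vars, collapse = ", "), call. = FALSE)
    stats::lm(stats::reformulate(vars, response = outcome), data = data)
  }
  current <- forced
  fit <- fit_with(current)
  base_r2 <- summary(fit)$r.squared
  base_aic <- stats::AIC(fit)
  entered <- data.frame(variable = character(0), beta = numeric(0),
                        f = numeric(0), p = numeric(0),
                        stringsAsFactors = FALSE)
  pool <- sort(candidates)
  repeat {
    if (!length(pool) || n <= length(current) + 2) break
    rss0 <- sum(stats::resid(fit)^2)
    stats_c <- lapply(pool, function(v) {
      f1 <- fit_with(c(current, v))
      rss1 <- sum(stats::resid(f1)^2)
      df2 <- f1$df.residual
      Fv <- (rss0 - rss1) / (rss1 / df2)
      list(v = v, fit = f1, F = Fv,
           p = stats::pf(Fv, 1, df2, lower.tail = FALSE))
    })
    ps <- vapply(stats_c, `[[`, numeric(1), "p")
    Fs <- vapply(stats_c, `[[`, numeric(1), "F")
    best <- order(ps, -Fs)[1]
    if (ps[best] >= alpha) break
    ch <- stats_c[[best]]
    current <- c(current, ch$v)
    fit <- ch$fit
    entered <- rbind(entered, data.frame(
      variable = ch$v, beta = stats::coef(fit)[[ch$v]], f = ch$F, p = ch$p,
      stringsAsFactors = FALSE))
    pool <- setdiff(pool, ch$v)
  }
  structure(list(entered = entered, coefficients = stats::coef(fit),
                 r_squared = summary(fit)$r.squared, aic = stats::AIC(fit),
                 base_r_squared = base_r2, base_aic = base_aic, n = n,
                 forced = forced),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("stepwise forward regression, n = %d\n", x$n))
  cat(sprintf("  base model (%s): R^2 = %.3f, AIC = %.1f\n",
              paste(x$forced, collapse = " + "), x$base_r_squared, x$base_aic))
  if (nrow(x$entered) == 0) cat("  no candidate entered\n")
  else for (i in seq_len(nrow(x$entered)))
    cat(sprintf("  + %s (beta = %.3f, F = %.2f, p = %.4f)\n",
                x$entered$variable[i], x$entered$beta[i], x$entered$f[i],
                x$entered$p[i]))
  cat(sprintf("  final: R^2 = %.3f, AIC = %.1f\n", x$r_squared, x$aic))
  invisible(x)
}

#' Partial correlation of volume and T2 heterogeneity controlling age
#'
#' Correlation between the OLS residuals of x and y after regressing each
#' on age, per subfield (hemisphere-averaged), typically in healthy
#' controls with the *uncorrected* absolute volume.
#'
#' @param tab cohort table (restrict rows to the desired group first).
#' @param x,y metric columns.
#' @param subfields subfields to test.
#' @return data.frame per subfield: r, df, p.
#' @export
partial_correlation <- function(tab, x = "volume_mm3", y = "t2_sigma",
                                subfields = analysis_subfields()) {
  hx <- .hemi_average(tab, x)
  hy <- .hemi_average(tab, y)
  rows <- lapply(subfields, function(sf) {
    dx <- hx[hx$subfield == sf, ]
    dy <- hy[hy$subfield == sf, ]
    m <- merge(dx[, c("subject_id", x)],
               dy[, c("subject_id", y, "age")], by = "subject_id")
    m <- m[stats::complete.cases(m), ]
    if (nrow(m) < 4) stop("need >= 4 subjects", call. = FALSE)
    rx <- stats::resid(stats::lm(m[[x]] ~ m$age))
    ry <- stats::resid(stats::lm(m[[y]] ~ m$age))
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
      stop("zero residual variance in subfield ", sf, call. = FALSE)
    r <- stats::cor(rx, ry)
    df <- nrow(m) - 3
    tt <- r * sqrt(df / (1 - r^2))
    data.frame(subfield = sf, r = r, df = df,
               p = 2 * stats::pt(-abs(tt), df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
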
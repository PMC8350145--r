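test_that("BH and Bonferroni adjustments match hand calculation and stats oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_bh(0.03), 0.03)                 # single p unchanged
  expect_equal(fdr_bh(rep(0.2, 5)), rep(0.2, 5))   # ties stay equal
  set.seed(1)
  for (i in 1:5) {
    p <- stats::runif(20)
    expect_equal(fdr_bh(p), stats::p.adjust(p, "BH"))
    expect_equal(bonferroni(p), stats::p.adjust(p, "bonferroni"))
  }
  expect_equal(bonferroni(0.03, m = 5), 0.15)
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(-0.1), "\\[0, 1\\]")
})

# small deterministic metrics/meta pair used by the Z-scoring tests
mini_cohort <- function(seed = 2, n_hc = 30, n_mci = 15) {
  p <- cohort_preset(n_hc = n_hc, n_mci = n_mci)
  gen_cohort(p, "summary", seed = seed)
}

test_that("reference-stratum Z-scoring is exact on its own stratum", {
  co <- mini_cohort()
  tab <- zscore_by_reference(co$metrics, co$meta)
  for (s in unique(tab$study)) {
    ref <- tab$t2_sigma_z[tab$study == s & tab$subfield == "DG" &
                          tab$hemisphere == "L" & tab$group == "HC"]
    expect_equal(mean(ref), 0, tolerance = 1e-12)
    expect_equal(stats::sd(ref), 1, tolerance = 1e-12)
  }
  # a raw value equal to the reference mean maps to z = 0 (for a row
  # outside the reference stratum, so the stratum itself is unchanged)
  ref_raw <- tab$t2_sigma[tab$study == 1 & tab$subfield == "DG" &
                          tab$hemisphere == "L" & tab$group == "HC"]
  pick <- which(tab$study == 1 & tab$subfield == "EC" &
                tab$hemisphere == "R")[1]
  key <- tab[pick, c("subject_id", "subfield", "hemisphere")]
  m2 <- co$metrics
  j <- which(m2$subject_id == key$subject_id & m2$subfield == key$subfield &
             m2$hemisphere == key$hemisphere)
  m2$t2_sigma[j] <- mean(ref_raw)
  tab2 <- zscore_by_reference(m2, co$meta)
  j2 <- which(tab2$subject_id == key$subject_id &
              tab2$subfield == key$subfield &
              tab2$hemisphere == key$hemisphere)
  expect_equal(tab2$t2_sigma_z[j2], 0)
  # HC-by-subfield mode: every subfield's HC stratum is 0 +/- 1
  tabh <- zscore_by_reference(co$metrics, co$meta, "hc_by_subfield")
  for (sf in analysis_subfields()) {
    ref <- tabh$t2_sigma_z[tabh$study == 1 & tabh$subfield == sf &
                           tabh$group == "HC"]
    expect_equal(mean(ref), 0, tolerance = 1e-12)
    expect_equal(stats::sd(ref), 1, tolerance = 1e-12)
  }
})

test_that("pooled effect sizes are invariant to per-study affine rescaling", {
  co <- mini_cohort(seed = 6, n_hc = 60, n_mci = 30)
  tab1 <- zscore_by_reference(co$metrics, co$meta)
  d1 <- adjusted_group_stats(tab1, "t2_sigma_z")$cohens_d
  m2 <- co$metrics
  s2 <- co$meta$study[match(m2$subject_id, co$meta$subject_id)] == 2
  m2$t2_sigma[s2] <- 3.7 * m2$t2_sigma[s2] + 0.5
  d2 <- adjusted_group_stats(zscore_by_reference(m2, co$meta),
                             "t2_sigma_z")$cohens_d
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("Z-scoring rejects rows without group/age and empty reference strata", {
  co <- mini_cohort()
  meta_bad <- co$meta; meta_bad$age[1] <- NA
  expect_error(zscore_by_reference(co$metrics, meta_bad), "group and age")
  meta_hcless <- co$meta
  meta_hcless$group[meta_hcless$study == 1 & meta_hcless$group == "HC"] <- "MCI"
  expect_error(zscore_by_reference(co$metrics, meta_hcless),
               "reference stratum")
})

test_that("age-adjusted group stats agree with explicit normal-equation algebra", {
  co <- mini_cohort(seed = 12, n_hc = 20, n_mci = 12)
  tab <- zscore_by_reference(co$metrics, co$meta)
  gs <- adjusted_group_stats(tab, "t2_sigma_z", subfields = "EC")
  # independent route: solve the EC ANCOVA by hand on hemisphere means
  h <- stats::aggregate(t2_sigma_z ~ subject_id, tab[tab$subfield == "EC", ],
                        mean)
  h <- merge(h, unique(tab[, c("subject_id", "age_z", "group")]))
  X <- cbind(1, h$age_z, h$group == "MCI")
  beta <- solve(crossprod(X), crossprod(X, h$t2_sigma_z))
  res <- h$t2_sigma_z - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - 3)
  se <- sqrt(s2 * solve(crossprod(X))[3, 3])
  expect_equal(gs$t, beta[3] / se, tolerance = 1e-10)
  expect_equal(gs$cohens_d, beta[3] / sqrt(s2), tolerance = 1e-10)
  expect_equal(gs$df, nrow(X) - 3)
  expect_equal(gs$p_bonf, min(1, gs$p))  # single subfield tested
})

test_that("residualize mode gives a pooled t-test on age residuals", {
  co <- mini_cohort(seed = 13)
  tab <- zscore_by_reference(co$metrics, co$meta)
  gs <- adjusted_group_stats(tab, "t2_sigma_z", adjust = "residualize")
  expect_equal(nrow(gs), 5)
  expect_true(all(is.finite(gs$t)))
  # both adjustments see the same strong effects at matched sign
  gs2 <- adjusted_group_stats(tab, "t2_sigma_z")
  expect_true(all(sign(gs$cohens_d) == sign(gs2$cohens_d)))
})

test_that("age associations: self-regression gives R^2 = 1; shuffled ages give null", {
  co <- mini_cohort(seed = 3, n_hc = 80, n_mci = 40)
  tab <- zscore_by_reference(co$metrics, co$meta)
  tab$age_copy <- tab$age
  aa <- suppressWarnings(age_association(tab, "age_copy", subfields = "DG"))
  # (suppressed: lm warns about the essentially perfect self-fit)
  expect_equal(aa$r_squared, 1, tolerance = 1e-12)
  set.seed(4)
  perm <- sample(unique(tab$subject_id))
  tab$age <- tab$age[match(perm[match(tab$subject_id, unique(tab$subject_id))],
                           tab$subject_id)]
  aa2 <- age_association(tab, "t2_sigma_z")
  expect_lt(mean(aa2$r_squared), 0.06)
  expect_equal(aa2$df1[1], 1)
  expect_equal(aa2$df2[1], length(unique(tab$subject_id)) - 2)
})

test_that("generator age slope reproduces the target population R^2", {
  a <- sqrt(0.20)
  p <- null_preset(age_sigma = c(DG = a, CA = a, SUB = a, EC = a, BA35 = a),
                   hemi_jitter = 0)
  set.seed(15)
  r2 <- replicate(30, {
    co <- gen_cohort(p, "summary", seed = sample.int(2^30, 1))
    tab <- zscore_by_reference(co$metrics, co$meta)
    age_association(tab, "t2_sigma_z")$r_squared[2]  # CA
  })
  expect_lt(abs(mean(r2) - 0.20), 0.03)
})

test_that("partial correlation equals the closed-form three-variable formula", {
  set.seed(8)
  co <- mini_cohort(seed = 8, n_hc = 40, n_mci = 20)
  tab <- zscore_by_reference(co$metrics, co$meta)
  hc <- tab[tab$group == "HC", ]
  pc <- partial_correlation(hc, "volume_mm3", "t2_sigma", subfields = "CA")
  h <- stats::aggregate(cbind(volume_mm3, t2_sigma) ~ subject_id,
                        hc[hc$subfield == "CA", ], mean)
  h <- merge(h, unique(hc[, c("subject_id", "age")]))
  rxy <- stats::cor(h$volume_mm3, h$t2_sigma)
  rxa <- stats::cor(h$volume_mm3, h$age)
  rya <- stats::cor(h$t2_sigma, h$age)
  expect_equal(pc$r, (rxy - rxa * rya) / sqrt((1 - rxa^2) * (1 - rya^2)),
               tolerance = 1e-10)
  # y = x gives r = 1
  hc2 <- hc; hc2$t2_sigma <- hc2$volume_mm3
  expect_equal(partial_correlation(hc2, subfields = "CA")$r, 1,
               tolerance = 1e-12)
})
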
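test_that("forward signal model is the closed-form exponential", {
  t2t <- array(80, c(2, 2, 1))
  vol <- gen_multiecho_volume(t2t, 100, c(24, 48, 72), 0,
                              exclude_first_echo = FALSE)
  expect_equal(vol$signal[1, 1, 1, ], 100 * exp(-c(24, 48, 72) / 80))
  expect_equal(round(vol$signal[1, 1, 1, ], 2), c(74.08, 54.88, 40.66))
  # noiseless generation and log-linear fitting are exact inverses
  tm <- compute_t2_map(vol)
  expect_equal(tm$t2[1, 1, 1], 80, tolerance = 1e-12)
  expect_error(gen_multiecho_volume(t2t, 100, c(48, 24), 0), "increasing")
})

test_that("noisy generation is centred on truth, matching an NLS oracle", {
  set.seed(14)
  te <- seq(12, 120, 12)
  t2t <- array(80, c(40, 25, 2))  # 2000 voxels
  vol <- gen_multiecho_volume(t2t, 400, te, noise_sd = 4, seed = 14,
                              exclude_first_echo = FALSE)
  tm <- compute_t2_map(vol)
  expect_equal(mean(tm$t2[tm$valid]), 80, tolerance = 0.01)  # ~1% bias cap
  # oracle: nonlinear LS on a subsample of the same series
  m <- matrix(vol$signal, 2000, 10)
  nls_fit <- apply(m[1:150, ], 1, function(s) {
    stats::coef(stats::nls(s ~ A * exp(-te / T2),
                           data.frame(s = s, te = te),
                           start = list(A = 400, T2 = 80)))[["T2"]]
  })
  ll_fit <- apply(m[1:150, ], 1, function(s) fit_t2_voxel(s, te)$t2)
  expect_lt(abs(mean(ll_fit) - mean(nls_fit)), 0.5)
})

test_that("rician option and zero-noise reproducibility behave", {
  t2t <- array(90, c(10, 10, 1))
  v1 <- gen_multiecho_volume(t2t, 300, c(20, 40), 2, seed = 3,
                             noise_model = "rician")
  v2 <- gen_multiecho_volume(t2t, 300, c(20, 40), 2, seed = 3,
                             noise_model = "rician")
  expect_identical(v1$signal, v2$signal)
  expect_true(all(v1$signal[t2t > 0] > 0))  # magnitude noise is positive
})

test_that("gen_subject draws voxel T2 from the subject's log-logistic truth", {
  p <- cohort_preset(n_hc = 2, n_mci = 2, mask_scale = 0.15)
  truth <- data.frame(subject_id = "S1",
                      subfield = rep(c("DG", "CA"), each = 2),
                      hemisphere = rep(c("L", "R"), 2),
                      sigma_true = c(0.001, 0.001, 0.1, 0.2),
                      mu_true = log(80), volume_mm3 = 120,
                      stringsAsFactors = FALSE)
  s <- gen_subject(p, truth, seed = 8)
  # near-degenerate sigma: all voxel T2 collapse to the median exp(mu)
  tm <- compute_t2_map(s$L$volume)
  dg <- tm$t2[s$L$mask$labels == 3L & tm$valid]
  expect_equal(stats::median(dg), 80, tolerance = 0.02)
  expect_lt(stats::IQR(log(dg)), 0.05)
  # doubling sigma doubles the log-IQR (quantile formula of the distribution)
  ca_l <- log(tm$t2[s$L$mask$labels == subfield_codes()[["CA"]] & tm$valid])
  tm_r <- compute_t2_map(s$R$volume)
  ca_r <- log(tm_r$t2[s$R$mask$labels == subfield_codes()[["CA"]] & tm_r$valid])
  expect_equal(stats::IQR(ca_r) / stats::IQR(ca_l), 2, tolerance = 0.35)
  # determinism and validation
  s2 <- gen_subject(p, truth, seed = 8)
  expect_identical(s$L$volume$signal, s2$L$volume$signal)
  expect_identical(s$L$mask$labels, s2$L$mask$labels)
  truth$sigma_true[1] <- -0.1
  expect_error(gen_subject(p, truth, seed = 8), "sigma")
})

test_that("summary cohorts have faithful structure: medians, nulls, determinism", {
  p0 <- null_preset(seed = 21)
  co <- gen_cohort(p0, "summary")
  co2 <- gen_cohort(p0, "summary")
  expect_identical(co$metrics, co2$metrics)
  expect_error(gen_cohort(p0, "imagine"), "arg")
  expect_equal(co$metrics$median_ms, exp(co$metrics$t2_mu))
  # null preset: estimated group d near zero in every subfield
  set.seed(31)
  dbar <- rowMeans(replicate(20, {
    cc <- gen_cohort(p0, "summary", seed = sample.int(2^30, 1))
    tab <- zscore_by_reference(cc$metrics, cc$meta)
    adjusted_group_stats(tab, "t2_sigma_z")$cohens_d
  }))
  expect_true(all(abs(dbar) < 0.12))
})

test_that("summary-mode path structure matches closed-form OLS expectations", {
  # age->sigma = 0.5, sigma->vol = -0.4 for every subfield; large n
  p <- null_preset(n_hc = 5000, n_mci = 2, hemi_jitter = 0,
                   age_sigma = c(DG = .5, CA = .5, SUB = .5, EC = .5, BA35 = .5),
                   sigma_vol = c(DG = -.4, CA = -.4, SUB = -.4, EC = -.4,
                                 BA35 = -.4),
                   n_studies = 1, study_frac = 1, seed = 9)
  co <- gen_cohort(p, "summary")
  tab <- zscore_by_reference(co$metrics, co$meta, reference = "hc_by_subfield")
  pm <- path_model(make_path_data(tab), "pal_rt", n_boot = 0)
  a <- pm$paths$estimate[pm$paths$path == "age->sigma_CA"]
  b <- pm$paths$estimate[pm$paths$path == "sigma_CA->vol_CA"]
  expect_equal(a, 0.5, tolerance = 0.06)  # |err| < 0.03 absolute
  expect_lt(abs(a - 0.5), 0.03)
  expect_lt(abs(b + 0.4), 0.03)
  expect_lt(abs(pm$paths$estimate[pm$paths$path == "age->sigma_CA->vol_CA"] -
                  a * b), 1e-12)
})

test_that("preset validation rejects inconsistent parameter sets", {
  expect_error(cohort_preset(n_hc = 1), "n >= 2")
  expect_error(cohort_preset(sd_sigma = 0), "> 0")
  expect_error(cohort_preset(age_sigma = c(DG = 1.2, CA = .4, SUB = .4,
                                           EC = .4, BA35 = .4)), "< 1")
  expect_error(cohort_preset(study_frac = c(0.5, 0.4)), "sum to 1")
  expect_error(cohort_preset(d_sigma = c(DG = Inf, CA = 0, SUB = 0, EC = 0,
                                         BA35 = 0)), "finite")
})
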
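#' Cohort generating preset
#'
#' The parameter set from which synthetic cohorts are generated. Defaults
#' encode the study conditions this package is designed around: 99 healthy
#' controls (HC) aged 69.2 +/- 8.55 y and 49 mild-cognitive-impairment
#' (MCI) subjects aged 72.2 +/- 9.03 y, pooled from two studies; per-
#' subfield T2-heterogeneity group effects (Cohen's d on the age-adjusted
#' scale) of DG 0.62, CA 0.63, SUB 0.92, EC 1.07, BA35 0.95; standardized
#' age -> sigma slopes equal to the square roots of the reported
#' age-association R^2 values; and sigma -> volume path coefficients chosen
#' so that the product age->sigma->volume reproduces the reported
#' standardized indirect effects (DG -0.063, CA -0.074, SUB -0.062,
#' EC -0.072, BA35 -0.076).
#'
#' Generation order is age -> sigma -> volume -> PAL with independent
#' Gaussian disturbances; all standardized coefficients are coefficients
#' of the generating linear equations after standardization. Group shifts
#' are applied on the age-conditional scale, so the configured `d_sigma`
#' is the age-adjusted Cohen's d the pipeline estimates.
#'
#' @param n_hc,n_mci group sizes.
#' @param age_hc,age_mci c(mean, sd) in years.
#' @param subfields analysis subfield names.
#' @param sigma0,mu0 per-subfield baseline heterogeneity (dimensionless)
#'   and midpoint (log-ms) for HC at mean age.
#' @param sd_sigma,sd_mu between-subject SDs of sigma and mu.
#' @param d_sigma,d_mu,d_vol per-subfield group effects (MCI - HC,
#'   standardized, age-conditional scale).
#' @param age_sigma,age_mu standardized age slopes on sigma and mu.
#' @param sigma_vol sigma -> volume standardized path per subfield.
#' @param age_vol direct age -> volume standardized path per subfield.
#' @param vol_pal_acc,vol_pal_rt volume -> PAL paths per subfield.
#' @param age_pal_acc,age_pal_rt direct age -> PAL paths.
#' @param vol0_mm3 per-hemisphere baseline subfield volumes, mm^3.
#' @param cv_vol coefficient of variation of volume.
#' @param sigma_cor,vol_cor equicorrelation of subfield disturbances
#'   within a modality (subfields covary within, never between,
#'   modalities).
#' @param hemi_jitter SD of per-hemisphere deviation, standardized units.
#' @param cog coefficients of the follow-up cognition equation (MCI):
#'   baseline, age, sigma_CA and residual SD.
#' @param n_followup number of MCI subjects with follow-up cognition.
#' @param n_studies,study_frac study pooling structure; studies apply
#'   different affine raw scales (exercised by Z-pooling).
#' @param s0,noise_sd,echo_times,exclude_first_echo,voxel_dims imaging-
#'   mode acquisition parameters (defaults: CPMG-style, 10 echoes at
#'   12-120 ms, first echo excluded from fitting, proton-density SNR
#'   s0/noise_sd = 100, typical of high-resolution hippocampal TSE).
#' @param mask_scale multiplier on default region sizes (imaging mode).
#' @param mask_voxels optional fixed pre-erosion voxel count per subfield
#'   for shared-mask phantoms (overrides the volume-proportional sizing;
#'   used to run replicate studies at the minimum region size a stable
#'   distribution fit needs).
#' @param shared_mask reuse one mask geometry for all subjects (imaging
#'   mode; volumes then carry no between-subject variation).
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param seed default seed.
#' @return object of class `cohort_preset`.
#' @export
cohort_preset <- function(
    n_hc = 99L, n_mci = 49L,
    age_hc = c(69.2, 8.55), age_mci = c(72.2, 9.03),
    subfields = analysis_subfields(),
    sigma0 = c(DG = 0.115, CA = 0.120, SUB = 0.125, EC = 0.130, BA35 = 0.125),
    mu0 = log(c(DG = 83, CA = 88, SUB = 78, EC = 85, BA35 = 90)),
    sd_sigma = 0.030, sd_mu = 0.020,
    d_sigma = c(DG = 0.62, CA = 0.63, SUB = 0.92, EC = 1.07, BA35 = 0.95),
    d_mu = c(DG = 0, CA = 0, SUB = -1.47, EC = -0.82, BA35 = 0),
    d_vol = c(DG = -0.6, CA = -0.6, SUB = -0.6, EC = -0.6, BA35 = -0.6),
    age_sigma = sqrt(c(DG = 0.159, CA = 0.163, SUB = 0.146, EC = 0.168,
                       BA35 = 0.206)),
    age_mu = c(DG = 0, CA = 0, SUB = 0, EC = 0, BA35 = 0),
    sigma_vol = c(DG = -0.063, CA = -0.074, SUB = -0.062, EC = -0.072,
                  BA35 = -0.076) /
      sqrt(c(DG = 0.159, CA = 0.163, SUB = 0.146, EC = 0.168, BA35 = 0.206)),
    age_vol = c(DG = -0.25, CA = -0.25, SUB = 0, EC = 0, BA35 = 0),
    vol_pal_acc = c(DG = 0, CA = 0, SUB = 0, EC = 0, BA35 = 0.32),
    vol_pal_rt = c(DG = 0, CA = -0.55, SUB = 0, EC = 0, BA35 = 0),
    age_pal_acc = -0.30, age_pal_rt = 0.30,
    vol0_mm3 = c(DG = 800, CA = 1100, SUB = 450, EC = 600, BA35 = 500),
    cv_vol = 0.10,
    sigma_cor = 0.5, vol_cor = 0.5,
    hemi_jitter = 0.15,
    cog = c(baseline = 0.25, age = -0.15, sigma_ca = -0.605, resid = 0.70),
    n_followup = 20L,
    n_studies = 2L, study_frac = c(0.55, 0.45),
    s0 = 400, noise_sd = 4,
    echo_times = seq(12, 120, by = 12), exclude_first_echo = TRUE,
    voxel_dims = c(0.34, 0.34, 1.7),
    mask_scale = 1, mask_voxels = NULL, shared_mask = FALSE,
    noise_model = c("gaussian", "rician"),
    seed = 1L) {
  noise_model <- match.arg(noise_model)
  per_sf <- function(x, what) {
    if (is.null(names(x))) names(x) <- subfields
    if (!all(subfields %in% names(x)))
      stop(sprintf("`%s` must be named for every subfield", what), call. = FALSE)
    x[subfields]
  }
  p <- list(
    n_hc = as.integer(n_hc), n_mci = as.integer(n_mci),
    age_hc = age_hc, age_mci = age_mci, subfields = subfields,
    sigma0 = per_sf(sigma0, "sigma0"), mu0 = per_sf(mu0, "mu0"),
    sd_sigma = sd_sigma, sd_mu = sd_mu,
    d_sigma = per_sf(d_sigma, "d_sigma"), d_mu = per_sf(d_mu, "d_mu"),
    d_vol = per_sf(d_vol, "d_vol"),
    age_sigma = per_sf(age_sigma, "age_sigma"),
    age_mu = per_sf(age_mu, "age_mu"),
    sigma_vol = per_sf(sigma_vol, "sigma_vol"),
    age_vol = per_sf(age_vol, "age_vol"),
    vol_pal_acc = per_sf(vol_pal_acc, "vol_pal_acc"),
    vol_pal_rt = per_sf(vol_pal_rt, "vol_pal_rt"),
    age_pal_acc = age_pal_acc, age_pal_rt = age_pal_rt,
    vol0_mm3 = per_sf(vol0_mm3, "vol0_mm3"), cv_vol = cv_vol,
    sigma_cor = sigma_cor, vol_cor = vol_cor, hemi_jitter = hemi_jitter,
    cog = cog, n_followup = as.integer(n_followup),
    n_studies = as.integer(n_studies), study_frac = study_frac,
    s0 = s0, noise_sd = noise_sd, echo_times = as.numeric(echo_times),
    exclude_first_echo = exclude_first_echo,
    voxel_dims = as.numeric(voxel_dims),
    mask_scale = mask_scale,
    mask_voxels = if (!is.null(mask_voxels)) as.integer(mask_voxels),
    shared_mask = isTRUE(shared_mask),
    noise_model = noise_model, seed = as.integer(seed))
  validate_preset(structure(p, class = "cohort_preset"))
}

#' @rdname cohort_preset
#' @param preset object to validate.
#' @export
validate_preset <- function(preset) {
  stopifnot(inherits(preset, "cohort_preset"))
  with(preset, {
    if (n_hc < 2 || n_mci < 2) stop("need n >= 2 per group", call. = FALSE)
    if (any(sigma0 <= 0) || sd_sigma <= 0 || sd_mu <= 0)
      stop("sigma0 and SDs must be > 0", call. = FALSE)
    if (age_hc[2] <= 0 || age_mci[2] <= 0)
      stop("age SDs must be > 0", call. = FALSE)
    if (any(!is.finite(c(d_sigma, d_mu, d_vol, age_sigma, sigma_vol))))
      stop("effect sizes must be finite", call. = FALSE)
    if (any(abs(age_sigma) >= 1))
      stop("standardized |age_sigma| must be < 1", call. = FALSE)
    if (sigma_cor < 0 || sigma_cor >= 1 || vol_cor < 0 || vol_cor >= 1)
      stop("disturbance correlations must be in [0, 1)", call. = FALSE)
    if (length(study_frac) != n_studies || abs(sum(study_frac) - 1) > 1e-8)
      stop("study_frac must sum to 1 with one entry per study", call. = FALSE)
  })
  preset
}

# equicorrelated standard-normal matrix: n rows, k columns, correlation rho
.equicor_noise <- function(n, k, rho) {
  shared <- stats::rnorm(n)
  uniq <- matrix(stats::rnorm(n * k), n, k)
  sqrt(rho) * shared + sqrt(1 - rho) * uniq
}

# Subject-level truths: meta (1 row/subject) + truth (subject x subfield x
# hemisphere) + subject-level standardized latents used by summary mode.
.gen_truth <- function(preset, seed) {
  set.seed(seed)
  p <- preset
  n <- p$n_hc + p$n_mci
  k <- length(p$subfields)
  group <- c(rep("HC", p$n_hc), rep("MCI", p$n_mci))
  g <- as.numeric(group == "MCI")
  age <- c(stats::rnorm(p$n_hc, p$age_hc[1], p$age_hc[2]),
           stats::rnorm(p$n_mci, p$age_mci[1], p$age_mci[2]))
  # theoretical pooled age moments of the preset (not the sample), so the
  # standardization is part of the stated world, not data-dependent
  w <- c(p$n_hc, p$n_mci) / n
  m_age <- w[1] * p$age_hc[1] + w[2] * p$age_mci[1]
  v_age <- w[1] * (p$age_hc[2]^2 + (p$age_hc[1] - m_age)^2) +
    w[2] * (p$age_mci[2]^2 + (p$age_mci[1] - m_age)^2)
  z <- (age - m_age) / sqrt(v_age)

  a <- p$age_sigma
  eps_s <- .equicor_noise(n, k, p$sigma_cor)
  s_lat <- sweep(eps_s + outer(g, p$d_sigma), 2, sqrt(1 - a^2), `*`) +
    outer(z, a)                                   # n x k, ~ standardized

  am <- p$age_mu
  eps_m <- .equicor_noise(n, k, p$sigma_cor)
  m_lat <- sweep(eps_m + outer(g, p$d_mu), 2, sqrt(1 - am^2), `*`) +
    outer(z, am)

  b <- p$sigma_vol; av <- p$age_vol
  resv2 <- 1 - (av^2 + b^2 + 2 * av * b * a)
  resv <- sqrt(pmax(resv2, 0.05))
  eps_v <- .equicor_noise(n, k, p$vol_cor)
  v_lat <- outer(z, av) + sweep(s_lat, 2, b, `*`) +
    sweep(eps_v + outer(g, p$d_vol), 2, resv, `*`)

  pal_part <- function(age_c, vc) {
    lin <- p[[age_c]] * z + as.vector(v_lat %*% p[[vc]])
    res <- sqrt(max(0.1, 1 - stats::var(lin)))
    lin + res * stats::rnorm(n)
  }
  pal_acc_z <- pal_part("age_pal_acc", "vol_pal_acc")
  pal_rt_z <- pal_part("age_pal_rt", "vol_pal_rt")

  split_counts <- function(m) diff(round(m * cumsum(c(0, p$study_frac))))
  study <- c(rep(seq_len(p$n_studies), times = split_counts(p$n_hc)),
             rep(seq_len(p$n_studies), times = split_counts(p$n_mci)))
  cog_bl_z <- stats::rnorm(n)
  cog_bl <- ifelse(group == "HC", cog_bl_z, -3.75 + 2.42 * cog_bl_z)
  ca_i <- match("CA", p$subfields)
  cog_fu_z <- p$cog["baseline"] * cog_bl_z + p$cog["age"] * z +
    p$cog["sigma_ca"] * s_lat[, ca_i] + p$cog["resid"] * stats::rnorm(n)
  mci_idx <- which(group == "MCI")
  fu_keep <- mci_idx[seq_len(min(p$n_followup, length(mci_idx)))]
  cog_fu <- rep(NA_real_, n)
  cog_fu[fu_keep] <- cog_fu_z[fu_keep]

  meta <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)), study = study, group = group,
    age = age,
    sex = sample(c("M", "F"), n, replace = TRUE),
    education = round(stats::rnorm(n, ifelse(group == "HC", 15.8, 14.2),
                                   ifelse(group == "HC", 3.13, 2.81))),
    cognition_baseline = cog_bl, cognition_followup = cog_fu,
    pal_accuracy = 20 + 3 * pal_acc_z, pal_rt = 2500 + 400 * pal_rt_z,
    icv = stats::rnorm(n, 1.4e6, 1.2e5),
    stringsAsFactors = FALSE)

  hj <- p$hemi_jitter
  truth <- do.call(rbind, lapply(c("L", "R"), function(h) {
    eta_s <- matrix(stats::rnorm(n * k), n, k)
    eta_m <- matrix(stats::rnorm(n * k), n, k)
    eta_v <- matrix(stats::rnorm(n * k), n, k)
    sig <- sweep(s_lat + hj * eta_s, 2, p$sd_sigma * rep(1, k), `*`)
    sig <- sweep(sig, 2, p$sigma0, `+`)
    mu <- sweep(m_lat + hj * eta_m, 2, p$sd_mu * rep(1, k), `*`)
    mu <- sweep(mu, 2, p$mu0, `+`)
    # v_lat lives on the ICV-corrected scale (the scale the path model
    # analyses); raw volume additionally carries head-size variance
    vol <- sweep(1 + p$cv_vol * (v_lat + hj * eta_v), 2, p$vol0_mm3, `*`) *
      (meta$icv / 1.4e6)
    data.frame(
      subject_id = rep(meta$subject_id, k),
      subfield = rep(p$subfields, each = n),
      hemisphere = h,
      sigma_true = pmax(as.vector(sig), 0.02),
      mu_true = as.vector(mu),
      volume_mm3 = pmax(as.vector(vol), 30),
      stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(meta = meta, truth = truth)
}

#' Generate a multi-echo phantom from a T2 truth map
#'
#' Forward model of the mono-exponential decay: voxel signal at echo time
#' t is `s0 * exp(-t / T2)` plus noise (zero-mean Gaussian by default, or
#' Rician magnitude noise). Voxels with T2 truth 0 (background) have zero
#' mean signal. Noiseless when `noise_sd = 0`.
#'
#' @param t2_truth 3-D array of true T2 (ms); 0 marks background.
#' @param s0 proton-density signal amplitude (scalar or array).
#' @param echo_times strictly increasing echo times, ms.
#' @param noise_sd noise SD in signal units.
#' @param seed integer seed; NULL to use the current RNG stream.
#' @param voxel_dims mm.
#' @param exclude_first_echo flag carried into the returned volume.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @return a [multi_echo_volume].
#' @export
gen_multiecho_volume <- function(t2_truth, s0 = 400,
                                 echo_times = seq(12, 120, by = 12),
                                 noise_sd = 0, seed = NULL,
                                 voxel_dims = c(0.34, 0.34, 1.7),
                                 exclude_first_echo = TRUE,
                                 noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  t2_truth <- as.array(t2_truth)
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("`echo_times` must be positive and strictly increasing", call. = FALSE)
  if (any(t2_truth < 0)) stop("negative T2 truth", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- dim(t2_truth)
  ne <- length(echo_times)
  inside <- which(t2_truth > 0)
  # simulate only tissue voxels; background stays exactly 0 and is flagged
  # invalid by the fitter (air carries no decay information)
  clean <- exp(outer(-1 / t2_truth[inside], echo_times)) *
    (if (length(s0) > 1) s0[inside] else s0)
  if (noise_sd > 0) {
    if (noise_model == "gaussian") {
      sig_in <- clean + stats::rnorm(length(clean), 0, noise_sd)
      sig_in[sig_in < 1e-12] <- 1e-12  # log-space fit needs positive values
    } else {
      sig_in <- sqrt((clean + stats::rnorm(length(clean), 0, noise_sd))^2 +
                     stats::rnorm(length(clean), 0, noise_sd)^2)
    }
  } else sig_in <- clean
  sig <- numeric(prod(d) * ne)
  dim(sig) <- c(prod(d), ne)
  sig[inside, ] <- sig_in
  dim(sig) <- c(d, ne)
  multi_echo_volume(sig, echo_times, voxel_dims, exclude_first_echo)
}

#' Generate one synthetic subject (imaging level)
#'
#' Realizes one subject's truths as per-hemisphere phantom data: a
#' subfield label mask (region sizes scaled to the subject's true
#' volumes) and a multi-echo volume whose voxelwise T2 inside each
#' subfield is drawn i.i.d. from the subject's log-logistic(mu, sigma)
#' truth for that subfield and hemisphere.
#'
#' @param preset a [cohort_preset].
#' @param truth data.frame of that subject's rows (subfield x hemisphere)
#'   as produced inside [gen_cohort].
#' @param seed integer seed.
#' @param masks optional named list (L, R) of pre-built un-eroded
#'   [label_mask] objects to reuse (shared-mask mode).
#' @return list with elements `L` and `R`, each `list(volume, mask)`, plus
#'   `truth`.
#' @export
gen_subject <- function(preset, truth, seed = 1L, masks = NULL) {
  stopifnot(inherits(preset, "cohort_preset"))
  if (any(truth$sigma_true <= 0)) stop("sigma truth must be > 0", call. = FALSE)
  set.seed(seed)
  out <- list()
  for (h in c("L", "R")) {
    th <- truth[truth$hemisphere == h, ]
    if (!nrow(th)) next
    if (is.null(masks)) {
      vv <- prod(preset$voxel_dims)
      specs <- lapply(seq_len(nrow(th)), function(i) {
        sf <- th$subfield[i]
        n_tgt <- max(64L, as.integer(round(
          th$volume_mm3[i] / vv * preset$mask_scale)))
        fam <- if (sf %in% c("CA", "SUB")) "ribbon" else "blob"
        subfield_spec(sf, n_tgt, fam,
                      thickness_voxels = if (fam == "ribbon") 9L else 8L)
      })
      mask <- gen_subfield_mask(NULL, specs,
                                seed = stats::runif(1, 1, 2^30),
                                voxel_dims = preset$voxel_dims,
                                erosion_band = NULL)
    } else mask <- masks[[h]]
    t2t <- array(0, dim(mask$labels))
    for (i in seq_len(nrow(th))) {
      sel <- mask$labels == label_code(mask, th$subfield[i])
      t2t[sel] <- rloglogis(sum(sel), th$mu_true[i], th$sigma_true[i])
    }
    vol <- gen_multiecho_volume(t2t, preset$s0, preset$echo_times,
                                preset$noise_sd, seed = NULL,
                                voxel_dims = preset$voxel_dims,
                                exclude_first_echo = preset$exclude_first_echo,
                                noise_model = preset$noise_model)
    out[[h]] <- list(volume = vol, mask = mask)
  }
  out$truth <- truth
  out
}

#' Generate a synthetic cohort
#'
#' In `summary` mode, returns subject-level metric tables generated
#' directly from the linear path structure (no imaging): per subject x
#' subfield x hemisphere raw T2 sigma, T2 mu and volume, plus metadata.
#' Raw scales differ between studies (each study applies its own affine
#' transform), which downstream Z-pooling must undo. In `imaging` mode,
#' subject truths are realized as phantoms via [gen_subject]; subjects are
#' exposed through a `get_subject(i)` closure so that large cohorts never
#' sit in memory at once.
#'
#' @param preset a [cohort_preset].
#' @param mode `"summary"` or `"imaging"`.
#' @param seed overrides `preset$seed`.
#' @return `summary`: list(metrics, meta, truth). `imaging`: list(n,
#'   get_subject, meta, truth, masks) of class `imaging_cohort`.
#' @export
gen_cohort <- function(preset, mode = c("summary", "imaging"), seed = NULL) {
  stopifnot(inherits(preset, "cohort_preset"))
  mode <- match.arg(mode)
  seed <- if (is.null(seed)) preset$seed else as.integer(seed)
  tr <- .gen_truth(preset, seed)
  study_of <- tr$meta$study[match(tr$truth$subject_id, tr$meta$subject_id)]
  if (mode == "summary") {
    # per-study raw-scale affine transforms (undone by Z-pooling)
    sc_sigma <- c(1, 1.12, 0.95)[seq_len(preset$n_studies)]
    sh_mu <- c(0, 0.03, -0.02)[seq_len(preset$n_studies)]
    sc_vol <- c(1, 1.06, 0.97)[seq_len(preset$n_studies)]
    metrics <- data.frame(
      subject_id = tr$truth$subject_id, subfield = tr$truth$subfield,
      hemisphere = tr$truth$hemisphere,
      t2_sigma = tr$truth$sigma_true * sc_sigma[study_of],
      t2_mu = tr$truth$mu_true + sh_mu[study_of],
      median_ms = exp(tr$truth$mu_true + sh_mu[study_of]),
      volume_mm3 = tr$truth$volume_mm3 * sc_vol[study_of],
      n_voxels = NA_integer_, converged = TRUE,
      stringsAsFactors = FALSE)
    metrics$icv_ratio <- metrics$volume_mm3 /
      tr$meta$icv[match(metrics$subject_id, tr$meta$subject_id)]
    return(list(metrics = metrics, meta = tr$meta, truth = tr$truth))
  }
  masks <- NULL
  if (preset$shared_mask) {
    vv <- prod(preset$voxel_dims)
    specs <- lapply(preset$subfields, function(sf) {
      fam <- if (sf %in% c("CA", "SUB")) "ribbon" else "blob"
      n_tgt <- if (!is.null(preset$mask_voxels)) preset$mask_voxels
        else max(64L, as.integer(round(
          preset$vol0_mm3[[sf]] / vv * preset$mask_scale)))
      subfield_spec(sf, n_tgt, fam,
                    thickness_voxels = if (fam == "ribbon") 9L else 8L)
    })
    masks <- list(
      L = gen_subfield_mask(NULL, specs, seed = seed + 11L,
                            voxel_dims = preset$voxel_dims,
                            erosion_band = NULL),
      R = gen_subfield_mask(NULL, specs, seed = seed + 12L,
                            voxel_dims = preset$voxel_dims,
                            erosion_band = NULL))
  }
  ids <- tr$meta$subject_id
  get_subject <- function(i) {
    stopifnot(i >= 1, i <= length(ids))
    gen_subject(preset, tr$truth[tr$truth$subject_id == ids[i], ],
                seed = (seed + 7919L * i) %% 2147483629L, masks = masks)
  }
  structure(list(n = length(ids), get_subject = get_subject,
                 meta = tr$meta, truth = tr$truth, masks = masks),
            class = "imaging_cohort")
}
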
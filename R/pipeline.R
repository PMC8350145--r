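#' Pipeline run configuration
#'
#' Bundles the stage settings of a full run: acquisition convention,
#' erosion connectivity, distribution-fit thresholds and statistics
#' options. Serializable to/from JSON (and YAML if the `yaml` package is
#' available); every run emits the resolved configuration verbatim in its
#' manifest.
#'
#' @param echo_times ms; acquisition preset.
#' @param exclude_first_echo drop echo 1 from T2 fits (CPMG convention).
#' @param voxel_dims mm.
#' @param t2_min,t2_max T2 validity bounds, ms.
#' @param connectivity erosion connectivity, `"3d"` or `"2d"`.
#' @param n_min minimum voxels per subfield distribution fit.
#' @param n_boot bootstrap resamples for the path model.
#' @param group_adjust age-correction mode for group contrasts.
#' @param seed integer seed recorded with every run.
#' @return list of class `run_config`.
#' @export
run_config <- function(echo_times = seq(12, 120, by = 12),
                       exclude_first_echo = TRUE,
                       voxel_dims = c(0.34, 0.34, 1.7),
                       t2_min = 1, t2_max = 2000,
                       connectivity = "3d", n_min = 50,
                       n_boot = 2000, group_adjust = "ancova",
                       seed = 1L) {
  structure(list(echo_times = as.numeric(echo_times),
                 exclude_first_echo = isTRUE(exclude_first_echo),
                 voxel_dims = as.numeric(voxel_dims),
                 t2_min = t2_min, t2_max = t2_max,
                 connectivity = connectivity, n_min = as.integer(n_min),
                 n_boot = as.integer(n_boot), group_adjust = group_adjust,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path file to read/write (`.json`, or `.yaml`/`.yml` when the
#'   yaml package is installed).
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

# small stable FNV-1a hash of the serialized config, for manifests
.config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the subject-level pipeline on one subject
#'
#' Deterministic composition of the subject-level stages: T2 mapping
#' ([compute_t2_map]), CA pooling ([pool_ca]), one-voxel erosion
#' ([erode_labels]), per-subfield sample extraction
#' ([extract_subfield_sample]), log-logistic fitting and row assembly
#' ([summarize_subject]). Volumes come from the un-eroded pooled mask;
#' T2 samples from the eroded one. Misc and BA36 are excluded.
#'
#' @param subject list with elements `L` and/or `R`, each
#'   `list(volume = multi_echo_volume, mask = label_mask)` (the shape
#'   returned by [gen_subject]).
#' @param config a [run_config].
#' @param subject_id id copied into the rows.
#' @param icv optional intracranial volume, mm^3.
#' @param subfields subfields to report.
#' @param mask_cache optional per-hemisphere list of
#'   `list(pooled, eroded)` masks, reused when all subjects share mask
#'   geometry (avoids re-eroding per subject).
#' @return metric rows as from [summarize_subject], one per subfield x
#'   hemisphere.
#' @export
run_subject <- function(subject, config = run_config(),
                        subject_id = NA_character_, icv = NULL,
                        subfields = analysis_subfields(),
                        mask_cache = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  rows <- list()
  for (h in intersect(c("L", "R"), names(subject))) {
    vol <- subject[[h]]$volume
    mask <- subject[[h]]$mask
    if (!identical(dim(vol$signal)[1:3], dim(mask$labels)))
      stop(sprintf("[grid] hemisphere %s: volume and mask grids differ", h),
           call. = FALSE)
    t2map <- stage("fit-t2", compute_t2_map(
      vol, t2_fit_config(config$t2_min, config$t2_max)))
    if (!is.null(mask_cache) && !is.null(mask_cache[[h]])) {
      pooled <- mask_cache[[h]]$pooled
      eroded <- mask_cache[[h]]$eroded
    } else {
      pooled <- stage("pool-ca", if (all(c("CA1", "CA2", "CA3", "CA") %in%
                                         names(mask$label_table)))
        pool_ca(mask) else mask)
      eroded <- stage("erode", suppressWarnings(
        erode_labels(pooled, connectivity = config$connectivity)))
    }
    present <- intersect(subfields, names(pooled$label_table))
    nb_cache <- if (!is.null(mask_cache)) mask_cache[[h]]$n_before else NULL
    samples <- list(); volumes <- c()
    for (sf in present) {
      n_before <- if (!is.null(nb_cache)) nb_cache[[sf]]
        else sum(pooled$labels == label_code(pooled, sf))
      if (n_before == 0) next
      samples[[paste(sf, h)]] <- stage("extract", extract_subfield_sample(
        t2map, eroded, sf, h, n_before = n_before))
      volumes[paste(sf, h, sep = "_")] <- n_before * prod(pooled$voxel_dims)
    }
    rows[[h]] <- stage("fit-dist", summarize_subject(
      samples, volumes, subject_id = subject_id, icv = icv,
      n_min = config$n_min))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full cohort pipeline
#'
#' Applies [run_subject] to every subject of an imaging cohort (or takes
#' a summary-mode metrics table as-is), pools studies by Z-scoring, and
#' runs the statistical battery: age-adjusted group contrasts for T2
#' heterogeneity, T2 midpoint and volume; per-subfield age associations;
#' and, when requested, the decline-prediction stepwise model and the
#' path models. Per-subject failures are recorded and excluded; the
#' manifest lists exclusions, seeds and the configuration hash.
#'
#' @param cohort an `imaging_cohort` from [gen_cohort] (or a list with
#'   `metrics` + `meta` from summary mode).
#' @param config a [run_config].
#' @param analyses subset of `c("group", "age", "stepwise", "path")`.
#' @return list: `metrics`, `table` (Z-pooled), `group_stats` (per
#'   metric), `age_assoc`, `stepwise`, `path` (per PAL outcome),
#'   `manifest`.
#' @export
run_cohort <- function(cohort, config = run_config(),
                       analyses = c("group", "age")) {
  if (inherits(cohort, "imaging_cohort")) {
    mask_cache <- NULL
    if (!is.null(cohort$masks)) {
      mask_cache <- lapply(cohort$masks, function(m) {
        pooled <- if (all(c("CA1", "CA2", "CA3", "CA") %in%
                          names(m$label_table))) pool_ca(m) else m
        nb <- vapply(analysis_subfields(), function(sf)
          if (sf %in% names(pooled$label_table))
            sum(pooled$labels == label_code(pooled, sf)) else 0L,
          numeric(1))
        list(pooled = pooled,
             eroded = suppressWarnings(
               erode_labels(pooled, connectivity = config$connectivity)),
             n_before = nb)
      })
    }
    metrics <- list(); excluded <- character(0)
    for (i in seq_len(cohort$n)) {
      id <- cohort$meta$subject_id[i]
      res <- tryCatch(
        run_subject(cohort$get_subject(i), config, subject_id = id,
                    icv = cohort$meta$icv[i], mask_cache = mask_cache),
        error = function(e) e)
      if (inherits(res, "error")) {
        excluded <- c(excluded, sprintf("%s: %s", id, conditionMessage(res)))
      } else metrics[[i]] <- res
    }
    metrics <- do.call(rbind, metrics)
  } else {
    metrics <- cohort$metrics
    excluded <- character(0)
  }
  meta <- cohort$meta[cohort$meta$subject_id %in% metrics$subject_id, ]
  # metrics without variation (e.g. volumes under shared-mask phantoms)
  # cannot be Z-pooled and are dropped from the battery
  mcols <- intersect(c("t2_sigma", "t2_mu", "volume_mm3", "icv_ratio"),
                     names(metrics))
  mcols <- mcols[vapply(mcols, function(cc) {
    s <- tapply(metrics[[cc]],
                interaction(metrics$subfield, metrics$hemisphere),
                stats::sd, na.rm = TRUE)
    any(s > 1e-9, na.rm = TRUE)  # between-subject variation required
  }, logical(1))]
  tab <- zscore_by_reference(metrics, meta, reference = "left_dg_hc",
                             metric_cols = mcols)
  out <- list(metrics = metrics, table = tab)
  if ("group" %in% analyses) {
    out$group_stats <- lapply(
      stats::setNames(nm = intersect(c("t2_sigma_z", "t2_mu_z", "volume_mm3_z"),
                                     names(tab))),
      function(m) adjusted_group_stats(tab, m, adjust = config$group_adjust))
  }
  if ("age" %in% analyses) out$age_assoc <- age_association(tab, "t2_sigma_z")
  if ("stepwise" %in% analyses) {
    mtab <- zscore_by_reference(metrics, meta, reference = "mci_by_subfield",
                                metric_cols = mcols)
    sw <- make_stepwise_data(mtab, "t2_sigma_z")
    out$stepwise <- stepwise_forward(
      sw, "cognition_followup_z", c("age_z", "cognition_baseline_z"),
      intersect(c(analysis_subfields(), "Hipp"), names(sw)))
  }
  if ("path" %in% analyses) {
    ptab <- zscore_by_reference(metrics, meta, reference = "hc_by_subfield",
                                metric_cols = mcols)
    pdat <- make_path_data(ptab, group = "HC")
    out$path <- list(
      pal_accuracy = path_model(pdat, "pal_accuracy", n_boot = config$n_boot,
                                seed = config$seed),
      pal_rt = path_model(pdat, "pal_rt", n_boot = config$n_boot,
                          seed = config$seed + 1L))
  }
  out$manifest <- list(
    package_version = as.character(utils::packageVersion("t2het")),
    n_subjects = length(unique(metrics$subject_id)),
    excluded = excluded, seed = config$seed,
    config = unclass(config), config_hash = .config_hash(config))
  out
}
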
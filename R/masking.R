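#' Default subfield label codes
#'
#' ASHS-style integer codes for MTL subfield labels. CA1-CA3 are pooled
#' into a single CA label (code 99) before analysis; Misc and BA36 are
#' carried through I/O but excluded from all statistics by default.
#' @return named integer vector, name = subfield, value = label code.
#' @export
subfield_codes <- function() {
  c(CA1 = 1L, CA2 = 2L, DG = 3L, CA3 = 4L, MISC = 7L, SUB = 8L,
    EC = 10L, BA35 = 11L, BA36 = 12L, CA = 99L)
}

#' Subfields entering statistical analyses
#' @return character vector: DG, CA, SUB, EC, BA35.
#' @export
analysis_subfields <- function() c("DG", "CA", "SUB", "EC", "BA35")

#' Subfield label mask
#'
#' 3-D integer label image on the same grid as the T2 map (0 =
#' background), with a code-to-name label table and voxel dimensions.
#'
#' @param labels 3-D integer array.
#' @param label_table named integer vector mapping subfield name -> code;
#'   must cover every nonzero code present in `labels`.
#' @param voxel_dims mm, length 3.
#' @param eroded logical; TRUE for masks produced by [erode_labels].
#' @param erosion_fractions optional named numeric vector (per label name)
#'   recorded by [erode_labels].
#' @return object of class `label_mask`.
#' @export
label_mask <- function(labels, label_table = subfield_codes(),
                       voxel_dims = c(0.34, 0.34, 1.7), eroded = FALSE,
                       erosion_fractions = NULL) {
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (length(dim(labels)) != 3)
    stop("`labels` must be a 3-D array", call. = FALSE)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, unname(label_table))
  if (length(unknown))
    stop("codes present in mask but missing from label table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(labels = labels, label_table = label_table,
                 voxel_dims = as.numeric(voxel_dims), eroded = isTRUE(eroded),
                 erosion_fractions = erosion_fractions),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  counts <- table(factor(x$labels[x$labels > 0],
                         levels = unname(x$label_table),
                         labels = names(x$label_table)))
  counts <- counts[counts > 0]
  cat(sprintf("label mask %s%s: %s\n",
              paste(dim(x$labels), collapse = "x"),
              if (x$eroded) " (eroded)" else "",
              paste(sprintf("%s=%d", names(counts), counts), collapse = " ")))
  invisible(x)
}

label_code <- function(mask, subfield) {
  if (!subfield %in% names(mask$label_table))
    stop(sprintf("subfield '%s' not in label table", subfield), call. = FALSE)
  unname(mask$label_table[subfield])
}

#' Pool CA1, CA2 and CA3 into a single CA label
#'
#' CA2 and CA3 are too small for stable distribution fits on their own, so
#' the three cornu ammonis labels are rewritten to one pooled CA code
#' before erosion and sampling. Idempotent; all other labels untouched.
#'
#' @param mask an un-eroded [label_mask] whose table contains CA1, CA2,
#'   CA3 and CA.
#' @return a [label_mask] with the pooled CA label.
#' @export
pool_ca <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  if (mask$eroded)
    stop("pool_ca() must run before erosion", call. = FALSE)
  need <- c("CA1", "CA2", "CA3", "CA")
  if (!all(need %in% names(mask$label_table)))
    stop("label table must contain CA1, CA2, CA3 and CA to pool",
         call. = FALSE)
  lab <- mask$labels
  ca_codes <- unname(mask$label_table[c("CA1", "CA2", "CA3")])
  lab[lab %in% ca_codes] <- unname(mask$label_table["CA"])
  label_mask(lab, mask$label_table, mask$voxel_dims, eroded = FALSE)
}

# face-neighbour (6-connected) shift logic shared by erosion
.shift_pad <- function(a, axis, dir, pad) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx
  if (dir > 0) src[[axis]] <- c(1L, seq_len(d[axis] - 1L))
  else src[[axis]] <- c(seq_len(d[axis] - 1L) + 1L, d[axis])
  out <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  edge <- idx
  edge[[axis]] <- if (dir > 0) 1L else d[axis]
  out <- array(out, d)
  do.call(`[<-`, c(list(out), edge, list(value = pad)))
}

#' One-voxel morphological erosion of each label
#'
#' Removes, independently for every label, all voxels with at least one
#' face-adjacent (6-connected) neighbour not carrying that label.
#' Neighbouring voxels of *other* labels count as outside, so erosion also
#' strips voxels at subfield-subfield interfaces, targeting between-
#' subfield as well as tissue-CSF partial voluming. Grid boundary counts
#' as outside. With `connectivity = "2d"` only the 4 in-plane neighbours
#' are considered (an option for strongly anisotropic slices).
#'
#' @param mask a [label_mask].
#' @param connectivity `"3d"` (6 face neighbours, default) or `"2d"`
#'   (4 in-plane neighbours).
#' @return eroded [label_mask]; `erosion_fractions` holds the fraction of
#'   voxels removed per label name. Labels eroded to zero voxels trigger a
#'   warning.
#' @examples
#' a <- array(0L, c(12, 12, 12)); a[2:11, 2:11, 2:11] <- 3L
#' m <- erode_labels(label_mask(a))
#' sum(m$labels == 3L)  # 8^3 = 512
#' @export
erode_labels <- function(mask, connectivity = c("3d", "2d")) {
  stopifnot(inherits(mask, "label_mask"))
  connectivity <- match.arg(connectivity)
  lab <- mask$labels
  axes <- if (connectivity == "3d") 1:3 else 1:2
  keep <- array(TRUE, dim(lab))
  for (ax in axes) for (dir in c(-1L, 1L)) {
    keep <- keep & (.shift_pad(lab, ax, dir, pad = 0L) == lab)
  }
  out <- lab
  out[!keep] <- 0L

  present <- setdiff(unique(as.vector(lab)), 0L)
  fr <- vapply(present, function(code) {
    n0 <- sum(lab == code)
    1 - sum(out == code) / n0
  }, numeric(1))
  code2name <- names(mask$label_table)[match(present, mask$label_table)]
  names(fr) <- code2name
  empty <- code2name[vapply(present, function(code) sum(out == code) == 0,
                            logical(1))]
  if (length(empty))
    warning("label(s) fully removed by erosion: ",
            paste(empty, collapse = ", "), call. = FALSE)
  label_mask(out, mask$label_table, mask$voxel_dims, eroded = TRUE,
             erosion_fractions = fr)
}

#' Extract the voxelwise T2 sample of one subfield
#'
#' Overlays an eroded label mask on a T2 map and collects all valid-fit T2
#' values under the given subfield label. Invalid voxels are dropped and
#' counted.
#'
#' @param t2map a [t2_map].
#' @param eroded_mask an eroded [label_mask] on the identical grid.
#' @param subfield subfield name (must be in the label table).
#' @param hemisphere `"L"` or `"R"` (metadata tag on the sample).
#' @param n_before optional voxel count of the un-eroded label, for
#'   provenance.
#' @return object of class `subfield_sample`: `t2_values` (ms),
#'   `n_voxels_before_erosion`, `n_voxels_after_erosion`, `n_invalid`.
#' @export
extract_subfield_sample <- function(t2map, eroded_mask, subfield,
                                    hemisphere = "L",
                                    n_before = NA_integer_) {
  stopifnot(inherits(t2map, "t2_map"), inherits(eroded_mask, "label_mask"),
            hemisphere %in% c("L", "R"))
  if (!identical(dim(t2map$t2), dim(eroded_mask$labels)))
    stop("T2 map and mask grids differ", call. = FALSE)
  sel <- eroded_mask$labels == label_code(eroded_mask, subfield)
  vals <- t2map$t2[sel]
  keep <- t2map$valid[sel] & !is.na(vals)
  n_invalid <- sum(!keep)
  vals <- vals[keep]
  if (sum(sel) > 0 && length(vals) == 0)
    warning(sprintf("subfield %s/%s: no valid T2 voxels", subfield, hemisphere),
            call. = FALSE)
  structure(list(subfield = subfield, hemisphere = hemisphere,
                 t2_values = as.numeric(vals),
                 n_voxels_before_erosion = as.integer(n_before),
                 n_voxels_after_erosion = as.integer(sum(sel)),
                 n_invalid = as.integer(n_invalid)),
            class = "subfield_sample")
}

#' Subfield volume from the un-eroded mask
#'
#' Volume = voxel count x voxel volume. By convention (and matching the
#' analysis this package implements) volumes are measured on the
#' *un-eroded* mask while T2 samples come from the eroded mask.
#'
#' @param mask an un-eroded [label_mask].
#' @param subfield subfield name.
#' @param icv intracranial volume, mm^3; if given the ICV ratio is also
#'   returned.
#' @return named list `volume_mm3` and (if `icv` given) `icv_ratio`.
#' @export
subfield_volume <- function(mask, subfield, icv = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (mask$eroded)
    warning("volume computed on an eroded mask; convention is un-eroded",
            call. = FALSE)
  n <- sum(mask$labels == label_code(mask, subfield))
  v <- n * prod(mask$voxel_dims)
  out <- list(volume_mm3 = v)
  if (!is.null(icv)) {
    if (icv <= 0) stop("`icv` must be > 0", call. = FALSE)
    out$icv_ratio <- v / icv
  }
  out
}
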
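#' Minimal NIfTI-1 volume I/O
#'
#' Self-contained reader/writer for uncompressed or gzipped single-file
#' NIfTI-1 (`.nii` / `.nii.gz`), covering what this pipeline needs: 3-D
#' and 4-D volumes, float32/float64/int16/int32/uint8 datatypes, voxel
#' dimensions in `pixdim`, and scl_slope/scl_inter scaling on read. World
#' affines are preserved as an identity-with-scaling sform only; all
#' statistics in this package operate on voxel grids, and map/mask pairs
#' must share a grid (resampling is out of scope; mismatches are hard
#' errors downstream).
#'
#' @param img 3-D or 4-D array (numeric or integer).
#' @param path file path; gzip compression inferred from a `.gz` suffix.
#' @param voxel_dims voxel size, mm (first 3 pixdims).
#' @param datatype `"auto"` (float32 for doubles, int32 for integers),
#'   or one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`, `"float64"`.
#' @return `write_nifti` returns `path` invisibly. `read_nifti` returns a
#'   list: `data` (array), `voxel_dims`, `dim`.
#' @export
write_nifti <- function(img, path, voxel_dims = c(1, 1, 1),
                        datatype = "auto") {
  img <- as.array(img)
  nd <- length(dim(img))
  if (!nd %in% c(3, 4)) stop("only 3-D/4-D volumes supported", call. = FALSE)
  if (datatype == "auto")
    datatype <- if (is.integer(img)) "int32" else "float32"
  dt <- switch(datatype,
    uint8 = list(code = 2L, bitpix = 8L, what = "integer", size = 1L),
    int16 = list(code = 4L, bitpix = 16L, what = "integer", size = 2L),
    int32 = list(code = 8L, bitpix = 32L, what = "integer", size = 4L),
    float32 = list(code = 16L, bitpix = 32L, what = "double", size = 4L),
    float64 = list(code = 64L, bitpix = 64L, what = "double", size = 8L),
    stop("unsupported datatype ", datatype, call. = FALSE))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size,
                                        endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  dims <- c(nd, dim(img), rep(1L, 7 - nd))
  wi(348L)                       # sizeof_hdr
  writeBin(raw(36), con)         # data_type, db_name, extents, session, regular, dim_info
  wi(dims, size = 2L)            # dim[8]
  wf(rep(0, 3))                  # intent_p1..3
  wi(c(0L, dt$code, dt$bitpix, 0L), size = 2L)  # intent_code, datatype, bitpix, slice_start
  wf(c(0, voxel_dims[1], voxel_dims[2], voxel_dims[3],
       if (nd == 4) 1 else 0, 0, 0, 0))  # pixdim[8], qfac = 0
  wf(352)                        # vox_offset
  wf(1); wf(0)                   # scl_slope, scl_inter
  wi(0L, size = 2L); writeBin(raw(2), con)  # slice_end, slice_code+xyzt_units
  wf(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L))                  # glmax, glmin
  writeBin(raw(104), con)        # descrip(80) + aux_file(24)
  wi(c(0L, 1L), size = 2L)       # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                  # quatern b,c,d + qoffset x,y,z
  wf(c(voxel_dims[1], 0, 0, 0))  # srow_x
  wf(c(0, voxel_dims[2], 0, 0))  # srow_y
  wf(c(0, 0, voxel_dims[3], 0))  # srow_z
  writeBin(raw(16), con)         # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)          # extension flag
  if (dt$what == "integer")
    writeBin(as.integer(img), con, size = dt$size, endian = "little")
  else
    writeBin(as.double(img), con, size = dt$size, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  ri <- function(off, n, size, what = "integer", signed = TRUE, endian) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (ri(0, 1, 4, endian = "little") != 348L) {
    if (ri(0, 1, 4, endian = "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic)", call. = FALSE)
  dims <- ri(40, 8, 2, endian = endian)
  nd <- dims[1]
  shape <- dims[2:(1 + nd)]
  datatype <- ri(70, 1, 2, endian = endian)
  pixdim <- ri(76, 8, 4, what = "double", endian = endian)
  vox_offset <- ri(108, 1, 4, what = "double", endian = endian)
  slope <- ri(112, 1, 4, what = "double", endian = endian)
  inter <- ri(116, 1, 4, what = "double", endian = endian)
  n <- prod(shape)
  spec <- switch(as.character(datatype),
    "2" = list(what = "integer", size = 1, signed = FALSE),
    "4" = list(what = "integer", size = 2, signed = TRUE),
    "8" = list(what = "integer", size = 4, signed = TRUE),
    "16" = list(what = "double", size = 4, signed = TRUE),
    "64" = list(what = "double", size = 8, signed = TRUE),
    "512" = list(what = "integer", size = 2, signed = FALSE),
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (slope != 0 && !(slope == 1 && inter == 0))
    data <- data * slope + inter
  list(data = array(data, shape), voxel_dims = pixdim[2:4], dim = shape)
}

#' Read/write a multi-echo volume as NIfTI + JSON sidecar
#'
#' The 4-D signal goes to `<path>.nii(.gz)`; echo times (ms) and the
#' first-echo-exclusion flag go to a JSON sidecar `<path>.json`.
#'
#' @param vol a [multi_echo_volume].
#' @param path base path, with or without `.nii` / `.nii.gz` suffix.
#' @return `write_multiecho` the image path invisibly; `read_multiecho`
#'   a [multi_echo_volume].
#' @export
write_multiecho <- function(vol, path) {
  stopifnot(inherits(vol, "multi_echo_volume"))
  base <- sub("\\.nii(\\.gz)?$", "", path)
  img_path <- if (grepl("\\.nii(\\.gz)?$", path)) path else paste0(path, ".nii.gz")
  write_nifti(vol$signal, img_path, vol$voxel_dims)
  jsonlite::write_json(
    list(echo_times_ms = vol$echo_times,
         exclude_first_echo = vol$exclude_first_echo),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(img_path)
}

#' @rdname write_multiecho
#' @export
read_multiecho <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  img_path <- if (grepl("\\.nii(\\.gz)?$", path)) path
    else if (file.exists(paste0(path, ".nii.gz"))) paste0(path, ".nii.gz")
    else paste0(path, ".nii")
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  nii <- read_nifti(img_path)
  multi_echo_volume(nii$data, side$echo_times_ms, nii$voxel_dims,
                    isTRUE(side$exclude_first_echo))
}

#' Read/write a label mask as NIfTI + JSON label table
#'
#' @param mask a [label_mask].
#' @param path base path (suffix handling as in [write_multiecho]).
#' @return `write_label_mask` the image path invisibly; `read_label_mask`
#'   a [label_mask].
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  base <- sub("\\.nii(\\.gz)?$", "", path)
  img_path <- if (grepl("\\.nii(\\.gz)?$", path)) path else paste0(path, ".nii.gz")
  write_nifti(mask$labels, img_path, mask$voxel_dims, datatype = "int16")
  jsonlite::write_json(
    list(label_table = as.list(mask$label_table), eroded = mask$eroded),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(img_path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  img_path <- if (grepl("\\.nii(\\.gz)?$", path)) path
    else if (file.exists(paste0(path, ".nii.gz"))) paste0(path, ".nii.gz")
    else paste0(path, ".nii")
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  nii <- read_nifti(img_path)
  label_mask(nii$data, unlist(side$label_table), nii$voxel_dims,
             eroded = isTRUE(side$eroded))
}
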
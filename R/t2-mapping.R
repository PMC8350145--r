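#' Multi-echo MR volume
#'
#' Container for a 4-D multi-echo acquisition: signal indexed (x, y, z,
#' echo) with one echo time (TE, ms) per echo. `exclude_first_echo`
#' records whether the first echo is dropped from T2 fitting (standard for
#' CPMG-style trains, where the first echo is contaminated by stimulated
#' echoes; FALSE for sparse TSE-style acquisitions).
#'
#' @param signal 4-D numeric array, arbitrary scanner units, non-negative.
#' @param echo_times strictly increasing positive echo times, ms; length
#'   must equal `dim(signal)[4]`.
#' @param voxel_dims voxel size, mm, length 3.
#' @param exclude_first_echo logical flag (see above).
#' @return object of class `multi_echo_volume`.
#' @export
multi_echo_volume <- function(signal, echo_times,
                              voxel_dims = c(0.34, 0.34, 1.7),
                              exclude_first_echo = FALSE) {
  signal <- as.array(signal)
  if (length(dim(signal)) == 3) dim(signal) <- c(dim(signal), 1L)
  if (length(dim(signal)) != 4)
    stop("`signal` must be a 4-D array (x, y, z, echo)", call. = FALSE)
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) != dim(signal)[4])
    stop(sprintf("echo count mismatch: %d echoes in signal, %d echo times",
                 dim(signal)[4], length(echo_times)), call. = FALSE)
  if (any(echo_times <= 0) || any(diff(echo_times) <= 0))
    stop("`echo_times` must be positive and strictly increasing", call. = FALSE)
  n_usable <- length(echo_times) - as.integer(exclude_first_echo)
  if (n_usable < 1)
    stop("need at least 1 usable echo after first-echo exclusion", call. = FALSE)
  structure(list(signal = signal, echo_times = echo_times,
                 voxel_dims = as.numeric(voxel_dims),
                 exclude_first_echo = isTRUE(exclude_first_echo)),
            class = "multi_echo_volume")
}

#' @export
print.multi_echo_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("multi-echo volume %dx%dx%d, %d echoes (TE %s ms)%s\n",
              d[1], d[2], d[3], d[4],
              paste(format(x$echo_times, trim = TRUE), collapse = ", "),
              if (x$exclude_first_echo) ", first echo excluded from fits" else ""))
  invisible(x)
}

#' T2 fit configuration
#'
#' @param t2_min,t2_max validity bounds, ms. Fits outside the bounds are
#'   flagged invalid (not clipped) so they never enter subfield histograms.
#' @return list of class `t2_fit_config`.
#' @export
t2_fit_config <- function(t2_min = 1, t2_max = 2000) {
  stopifnot(t2_min > 0, t2_max > t2_min)
  structure(list(t2_min = t2_min, t2_max = t2_max), class = "t2_fit_config")
}

#' Voxelwise mono-exponential T2 fit
#'
#' Ordinary least squares of `log(signal)` on echo time for one voxel
#' series: the mono-exponential model `S(TE) = S0 * exp(-TE / T2)` is
#' linear in log space with slope `-1/T2` and intercept `log(S0)`. A voxel
#' is invalid (not an error) when any usable signal is <= 0, the slope is
#' >= 0 (no decay), or the fitted T2 falls outside the configured bounds.
#'
#' @param signal per-echo signal values for one voxel.
#' @param echo_times ms, same length as `signal`.
#' @param config a [t2_fit_config].
#' @param exclude_first_echo drop the first echo before fitting.
#' @return list with `t2` (ms), `s0`, `r_squared`, `valid`.
#' @examples
#' fit_t2_voxel(100 * exp(-c(24, 48, 72) / 80), c(24, 48, 72))
#' @export
fit_t2_voxel <- function(signal, echo_times, config = t2_fit_config(),
                         exclude_first_echo = FALSE) {
  if (exclude_first_echo) {
    signal <- signal[-1]
    echo_times <- echo_times[-1]
  }
  if (length(signal) != length(echo_times) || length(signal) < 2)
    stop("need >= 2 usable echoes with matching echo times", call. = FALSE)
  bad <- list(t2 = NA_real_, s0 = NA_real_, r_squared = NA_real_, valid = FALSE)
  if (any(signal <= 0) || any(!is.finite(signal))) return(bad)
  y <- base::log(signal)
  t <- echo_times - mean(echo_times)
  b <- sum(t * y) / sum(t * t)
  a0 <- mean(y) - b * mean(echo_times)  # intercept at TE = 0
  ss_res <- sum((y - mean(y) - b * t)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (b >= 0) return(bad)
  t2 <- -1 / b
  valid <- t2 > config$t2_min && t2 < config$t2_max
  list(t2 = if (valid) t2 else NA_real_, s0 = exp(a0),
       r_squared = r2, valid = valid)
}

#' Compute a T2 map from a multi-echo volume
#'
#' Applies the log-linear mono-exponential fit of [fit_t2_voxel]
#' independently at every voxel (vectorized over the whole grid). The
#' first echo is dropped if the volume's `exclude_first_echo` flag is set.
#'
#' @param vol a [multi_echo_volume].
#' @param config a [t2_fit_config].
#' @return object of class `t2_map`: 3-D arrays `t2` (ms; NA where
#'   invalid), `s0`, `r_squared`, logical `valid`, plus `voxel_dims`.
#' @export
compute_t2_map <- function(vol, config = t2_fit_config()) {
  stopifnot(inherits(vol, "multi_echo_volume"))
  sig <- vol$signal
  te <- vol$echo_times
  echo_cols <- seq_along(te)
  if (vol$exclude_first_echo) {
    echo_cols <- echo_cols[-1]
    te <- te[-1]
  }
  if (length(te) < 2)
    stop("T2 fitting needs >= 2 usable echoes", call. = FALSE)
  ne <- length(te)
  d4 <- dim(sig)
  nvox <- prod(d4[1:3])

  # gather only candidate voxels (first usable echo > 0): background stays
  # untouched and the full grid is never copied
  ok <- sig[(echo_cols[1] - 1) * nvox + seq_len(nvox)] > 0
  cand <- which(ok)
  mc <- NULL
  if (length(cand)) {
    mc <- matrix(sig[rep(cand, ne) +
                     rep((echo_cols - 1) * nvox, each = length(cand))],
                 length(cand), ne)
    good <- rowSums(mc > 0 & is.finite(mc)) == ne
    ok[cand] <- good
    mc <- mc[good, , drop = FALSE]
  }
  t2 <- s0 <- r2 <- rep(NA_real_, nvox)
  valid <- rep(FALSE, nvox)
  if (any(ok)) {
    y <- base::log(mc)
    tc <- te - mean(te)
    stt <- sum(tc * tc)
    b <- as.vector(y %*% tc) / stt
    ybar <- rowMeans(y)
    a0 <- ybar - b * mean(te)
    fitted_dev <- outer(b, tc)                 # b_i * tc_j
    ss_res <- rowSums((y - ybar - fitted_dev)^2)
    ss_tot <- rowSums((y - ybar)^2)
    r2ok <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
    t2ok <- ifelse(b < 0, -1 / b, NA_real_)
    vok <- !is.na(t2ok) & t2ok > config$t2_min & t2ok < config$t2_max
    t2[ok] <- ifelse(vok, t2ok, NA_real_)
    s0[ok] <- exp(a0)
    r2[ok] <- r2ok
    valid[ok] <- vok
  }
  shape <- d4[1:3]
  structure(list(t2 = array(t2, shape), s0 = array(s0, shape),
                 r_squared = array(r2, shape), valid = array(valid, shape),
                 voxel_dims = vol$voxel_dims),
            class = "t2_map")
}

#' @export
print.t2_map <- function(x, ...) {
  d <- dim(x$t2)
  cat(sprintf("T2 map %dx%dx%d: %d/%d valid voxels, median T2 %.1f ms\n",
              d[1], d[2], d[3], sum(x$valid), prod(d),
              stats::median(x$t2[x$valid])))
  invisible(x)
}

#' Sum-of-echoes image
#'
#' Voxelwise sum of the signal over the echo dimension, a high-SNR
#' T2-weighted structural image used for segmentation and visual QC. All
#' echoes are summed, including any echo excluded from T2 fitting.
#'
#' @param vol a [multi_echo_volume].
#' @return 3-D numeric array.
#' @export
sum_of_echoes <- function(vol) {
  stopifnot(inherits(vol, "multi_echo_volume"))
  d <- dim(vol$signal)
  array(rowSums(matrix(vol$signal, nrow = prod(d[1:3]), ncol = d[4])), d[1:3])
}
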
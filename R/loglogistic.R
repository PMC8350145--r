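#' Log-logistic distribution in (mu, sigma) parameterization
#'
#' Density, distribution function, quantile function and random generation
#' for the log-logistic distribution parameterized by its log-median `mu`
#' (the "midpoint"; `exp(mu)` is the median, in ms when applied to T2
#' values) and shape `sigma` (the "heterogeneity"). With
#' `z = (log(x) - mu) / sigma` the density is
#' \deqn{f(x \mid \mu, \sigma) = \frac{1}{\sigma}\,\frac{1}{x}\,
#'       \frac{e^z}{(1 + e^z)^2}.}
#' Equivalently, `log(X)` follows a logistic distribution with location
#' `mu` and scale `sigma`; these parameters play the role that median and
#' median absolute deviation play for a normal distribution.
#'
#' @param x,q vector of quantiles (> 0).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param mu log-median (midpoint), dimensionless log-ms.
#' @param sigma shape (heterogeneity), > 0.
#' @param log,log.p logical; return log-density / log-probability.
#' @param lower.tail logical; if TRUE (default), probabilities are P(X <= x).
#' @return `dloglogis` density per unit of `x`; `ploglogis` probabilities;
#'   `qloglogis` quantiles `exp(mu) * (p/(1-p))^sigma`; `rloglogis` draws.
#' @examples
#' dloglogis(80, log(80), 0.1)   # at the median: 1 / (4 * 0.1 * 80)
#' qloglogis(0.5, log(80), 0.2)  # median is exp(mu) for any sigma
#' @export
dloglogis <- function(x, mu, sigma, log = FALSE) {
  if (any(sigma <= 0)) stop("`sigma` must be > 0", call. = FALSE)
  if (any(x <= 0)) stop("`x` must be > 0", call. = FALSE)
  ld <- stats::dlogis(base::log(x), location = mu, scale = sigma, log = TRUE) -
    base::log(x)
  if (log) ld else exp(ld)
}

#' @rdname dloglogis
#' @export
ploglogis <- function(q, mu, sigma, lower.tail = TRUE, log.p = FALSE) {
  if (any(sigma <= 0)) stop("`sigma` must be > 0", call. = FALSE)
  if (any(q <= 0)) stop("`q` must be > 0", call. = FALSE)
  stats::plogis(base::log(q), location = mu, scale = sigma,
                lower.tail = lower.tail, log.p = log.p)
}

#' @rdname dloglogis
#' @export
qloglogis <- function(p, mu, sigma) {
  if (any(sigma <= 0)) stop("`sigma` must be > 0", call. = FALSE)
  exp(stats::qlogis(p, location = mu, scale = sigma))
}

#' @rdname dloglogis
#' @export
rloglogis <- function(n, mu, sigma) {
  if (any(sigma <= 0)) stop("`sigma` must be > 0", call. = FALSE)
  exp(stats::rlogis(n, location = mu, scale = sigma))
}

#' Maximum-likelihood fit of the log-logistic distribution
#'
#' Fits (`mu`, `sigma`) to a sample of positive values (typically voxelwise
#' T2 within an eroded subfield mask) by maximum likelihood. Estimation is
#' performed as a logistic MLE on the log-transformed values, which is the
#' same likelihood reparameterized. Initialization uses the log sample
#' median for `mu` and `IQR(log(x)) / (2 * log(3))` for `sigma` (the
#' logistic inter-quartile width is `2 * sigma * log(3)`).
#'
#' @param x numeric vector of positive values, or a [subfield_sample].
#' @param n_min minimum sample size; smaller samples are refused with an
#'   error so that unstable fits never enter downstream tables.
#' @param sigma_floor lower bound for `sigma` during optimization, keeping
#'   the likelihood finite on near-degenerate samples. A fit at the floor is
#'   flagged `degenerate`.
#' @param tol parameter convergence tolerance passed to the optimizer.
#' @return an object of class `loglogistic_fit`: list with `mu`, `sigma`,
#'   `median_ms = exp(mu)`, `n`, `log_likelihood`, `converged`, `degenerate`.
#' @examples
#' set.seed(1)
#' fit_loglogistic(rloglogis(500, log(80), 0.12))
#' @export
fit_loglogistic <- function(x, n_min = 50, sigma_floor = 1e-4, tol = 1e-8) {
  if (inherits(x, "subfield_sample")) x <- x$t2_values
  x <- as.numeric(x)
  if (length(x) < n_min) {
    stop(sprintf("sample size %d below n_min = %d; refusing to fit",
                 length(x), n_min), call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("all values must be finite and > 0", call. = FALSE)
  }
  lx <- base::log(x)
  mu0 <- stats::median(lx)
  s0 <- stats::IQR(lx) / (2 * base::log(3))
  s0 <- max(s0, sigma_floor)

  # negative log-likelihood of logistic(mu, exp(ls)) on log values;
  # sigma optimized on the log scale so positivity is unconstrained
  nll <- function(par) {
    if (any(!is.finite(par)) || par[2] > 50 || par[2] < -50) return(1e10)
    s <- exp(par[2])
    v <- -sum(stats::dlogis(lx, location = par[1], scale = s, log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  grad <- function(par) {
    s <- exp(par[2])
    z <- (lx - par[1]) / s
    ez <- stats::plogis(z)            # e^z / (1 + e^z)
    dmu <- sum(1 - 2 * ez) / s
    dls <- sum(1 - z * (2 * ez - 1))  # d(-ll)/d log s
    c(dmu, dls)
  }
  opt <- stats::optim(c(mu0, base::log(s0)), nll, gr = grad, method = "BFGS",
                      control = list(reltol = tol, maxit = 500))
  sigma <- max(exp(opt$par[2]), sigma_floor)
  structure(list(
    mu = opt$par[1],
    sigma = sigma,
    median_ms = exp(opt$par[1]),
    n = length(x),
    log_likelihood = -nll(c(opt$par[1], base::log(sigma))),
    converged = opt$convergence == 0,
    degenerate = sigma <= sigma_floor * (1 + 1e-9)
  ), class = "loglogistic_fit")
}

#' @export
print.loglogistic_fit <- function(x, ...) {
  cat(sprintf(
    "log-logistic fit: mu = %.4f (median %.2f ms), sigma = %.4f, n = %d%s\n",
    x$mu, x$median_ms, x$sigma, x$n,
    if (!x$converged) " [NOT CONVERGED]" else if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Per-subject subfield metric table
#'
#' Collapses a list of [subfield_sample] objects (plus matching volumes)
#' into one tidy row per subfield x hemisphere: the log-logistic fit
#' parameters, median T2, volume and optional ICV ratio, with voxel-count
#' provenance. Samples below `n_min` voxels yield no row (reported missing,
#' not imputed).
#'
#' @param samples list of [subfield_sample] objects.
#' @param volumes named numeric vector of un-eroded volumes in mm^3, names
#'   `"<subfield>_<hemisphere>"` (e.g. `"DG_L"`); optional.
#' @param subject_id identifier copied into every row.
#' @param icv intracranial volume in mm^3; if given, an `icv_ratio` column
#'   is added.
#' @param n_min minimum voxels for a distribution fit (see
#'   [fit_loglogistic]).
#' @return data.frame with columns subject_id, subfield, hemisphere,
#'   n_voxels, n_voxels_before_erosion, t2_mu, t2_sigma, median_ms,
#'   volume_mm3, icv_ratio, converged.
#' @export
summarize_subject <- function(samples, volumes = NULL, subject_id = NA_character_,
                              icv = NULL, n_min = 50) {
  keep <- vapply(samples, function(s) {
    stopifnot(inherits(s, "subfield_sample"))
    length(s$t2_values) >= n_min
  }, logical(1))
  samples <- samples[keep]
  if (!length(samples)) return(data.frame())
  fits <- lapply(samples, fit_loglogistic, n_min = n_min)
  keys <- vapply(samples, function(s)
    paste(s$subfield, s$hemisphere, sep = "_"), character(1))
  vol <- if (is.null(volumes)) rep(NA_real_, length(keys))
    else unname(volumes[keys])
  out <- data.frame(
    subject_id = subject_id,
    subfield = vapply(samples, `[[`, character(1), "subfield"),
    hemisphere = vapply(samples, `[[`, character(1), "hemisphere"),
    n_voxels = vapply(samples, function(s) length(s$t2_values), integer(1)),
    n_voxels_before_erosion = vapply(samples, `[[`, integer(1),
                                     "n_voxels_before_erosion"),
    t2_mu = vapply(fits, `[[`, numeric(1), "mu"),
    t2_sigma = vapply(fits, `[[`, numeric(1), "sigma"),
    median_ms = vapply(fits, `[[`, numeric(1), "median_ms"),
    volume_mm3 = vol,
    icv_ratio = if (!is.null(icv)) vol / icv else NA_real_,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
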
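test_that("density has the closed-form value at the median and integrates to 1", {
  # z = 0 at x = exp(mu) forces e^z/(1+e^z)^2 = 1/4, so f = 1/(4 sigma x)
  expect_equal(dloglogis(80, log(80), 0.1), 1 / (4 * 0.1 * 80))
  expect_equal(dloglogis(exp(2), 2, 0.37), 1 / (4 * 0.37 * exp(2)))
  for (par in list(c(log(80), 0.12), c(log(5), 0.4), c(0, 0.05))) {
    q <- stats::integrate(dloglogis, 0, Inf, mu = par[1], sigma = par[2],
                          rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
})

test_that("density is symmetric in log space and quantiles follow Q(p) = exp(mu) (p/(1-p))^sigma", {
  mu <- log(60); s <- 0.2
  for (a in c(0.1, 0.5, 1.5)) {
    expect_equal(dloglogis(exp(mu + a), mu, s) * exp(mu + a),
                 dloglogis(exp(mu - a), mu, s) * exp(mu - a))
  }
  p <- c(0.1, 0.25, 0.5, 0.9)
  expect_equal(qloglogis(p, mu, s), exp(mu) * (p / (1 - p))^s)
  expect_equal(ploglogis(qloglogis(p, mu, s), mu, s), p)
})

test_that("domain violations error", {
  expect_error(dloglogis(-1, 0, 1), "x")
  expect_error(dloglogis(1, 0, -1), "sigma")
  expect_error(qloglogis(0.5, 0, 0), "sigma")
})

test_that("MLE is consistent and matches the logistic-on-log oracle", {
  set.seed(42)
  x <- rloglogis(2e4, log(80), 0.12)
  fit <- fit_loglogistic(x)
  expect_true(fit$converged)
  expect_equal(fit$mu, log(80), tolerance = 0.02)
  expect_equal(fit$sigma, 0.12, tolerance = 0.1)  # relative
  expect_equal(fit$median_ms, exp(fit$mu))
  if (requireNamespace("MASS", quietly = TRUE)) {
    # (MASS explores negative scales during optimisation; warnings are its own)
    ref <- suppressWarnings(MASS::fitdistr(log(x), "logistic"))
    expect_equal(unname(fit$mu), unname(ref$estimate["location"]),
                 tolerance = 1e-4)
    expect_equal(unname(fit$sigma), unname(ref$estimate["scale"]),
                 tolerance = 1e-3)
  }
})

test_that("MLE attains the grid-search oracle maximum on small samples", {
  set.seed(7)
  for (i in 1:6) {
    x <- rloglogis(60, log(stats::runif(1, 40, 120)), stats::runif(1, 0.05, 0.3))
    fit <- fit_loglogistic(x)
    orc <- oracle_grid_loglik(x)
    expect_gte(fit$log_likelihood, orc$loglik - 1e-3)
  }
})

test_that("scale law: multiplying values by k shifts mu by log k, sigma unchanged", {
  set.seed(3)
  x <- rloglogis(400, log(70), 0.15)
  f1 <- fit_loglogistic(x)
  f2 <- fit_loglogistic(3.5 * x)
  expect_equal(f2$mu, f1$mu + log(3.5), tolerance = 1e-5)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-5)
})

test_that("degenerate and undersized samples are handled explicitly", {
  x <- 80 * (1 + stats::runif(100, -1e-9, 1e-9))
  fit <- fit_loglogistic(x)
  expect_true(fit$degenerate)
  expect_equal(fit$mu, log(80), tolerance = 1e-6)
  expect_error(fit_loglogistic(rloglogis(10, 4, 0.1)), "n_min")
  expect_error(fit_loglogistic(c(rep(80, 60), -1), n_min = 10), "> 0")
})

test_that("sigma recovery error shrinks with n and is < 15% at n = 500", {
  set.seed(11)
  for (s in c(0.05, 0.2, 0.4)) {
    err <- sapply(c(100, 500), function(n) {
      stats::median(abs(replicate(15, fit_loglogistic(
        rloglogis(n, log(80), s))$sigma) - s))
    })
    expect_lt(err[2], 0.15 * s)
    expect_lt(err[2], err[1] + 0.02 * s)  # non-increasing up to MC noise
  }
})

test_that("summarize_subject produces one row per subfield x hemisphere with provenance", {
  set.seed(5)
  samples <- list()
  for (sf in c("DG", "CA")) for (h in c("L", "R")) {
    samples[[paste(sf, h)]] <- structure(
      list(subfield = sf, hemisphere = h,
           t2_values = rloglogis(120, log(80), 0.1),
           n_voxels_before_erosion = 200L, n_voxels_after_erosion = 120L,
           n_invalid = 0L), class = "subfield_sample")
  }
  vols <- c(DG_L = 100, DG_R = 110, CA_L = 200, CA_R = 210)
  out <- summarize_subject(samples, vols, "S1", icv = 1.4e6)
  expect_equal(nrow(out), 4)
  expect_setequal(out$subfield, c("DG", "CA"))
  expect_equal(out$volume_mm3[out$subfield == "CA" & out$hemisphere == "R"], 210)
  expect_equal(out$icv_ratio, out$volume_mm3 / 1.4e6)
  # undersized samples are reported missing, not imputed
  samples$`DG L`$t2_values <- samples$`DG L`$t2_values[1:20]
  out2 <- summarize_subject(samples, vols, "S1")
  expect_equal(nrow(out2), 3)
})
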
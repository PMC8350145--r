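# independent oracles and small fixture builders shared across tests

# brute-force 2-D grid search maximizing the log-logistic log-likelihood;
# coarse grid refined twice around the incumbent (final step ~2e-4)
oracle_grid_loglik <- function(x, mu_span = NULL, sigma_span = NULL) {
  lx <- log(x)
  ll <- function(mu, s) sum(stats::dlogis(lx, mu, s, log = TRUE))
  mu_c <- stats::median(lx)
  s_c <- max(stats::IQR(lx) / (2 * log(3)), 1e-3)
  half_mu <- 4 * s_c / sqrt(length(x)) + 0.1
  half_s <- 0.8 * s_c + 0.05
  best <- c(mu_c, s_c)
  for (step in c(1, 0.1, 0.01)) {
    mus <- seq(best[1] - half_mu * step, best[1] + half_mu * step,
               length.out = 41)
    ss <- seq(max(best[2] - half_s * step, 1e-4),
              best[2] + half_s * step, length.out = 41)
    grid <- expand.grid(mu = mus, s = ss)
    vals <- mapply(ll, grid$mu, grid$s)
    best <- unlist(grid[which.max(vals), ])
  }
  list(mu = best[1], sigma = best[2], loglik = ll(best[1], best[2]))
}

# 6-connected flood fill; returns number of voxels reachable from `start`
# within the set of voxels carrying `code`
flood_fill_count <- function(labels, code, start) {
  d <- dim(labels)
  sel <- labels == code
  visited <- array(FALSE, d)
  queue <- matrix(start, ncol = 3)
  visited[start[1], start[2], start[3]] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  count <- 0
  while (nrow(queue) > 0) {
    count <- count + nrow(queue)
    nxt <- do.call(rbind, lapply(seq_len(6), function(k)
      sweep(queue, 2, shifts[k, ], `+`)))
    ok <- nxt[, 1] >= 1 & nxt[, 1] <= d[1] & nxt[, 2] >= 1 &
      nxt[, 2] <= d[2] & nxt[, 3] >= 1 & nxt[, 3] <= d[3]
    nxt <- nxt[ok, , drop = FALSE]
    idx <- nxt[, 1] + d[1] * (nxt[, 2] - 1) + d[1] * d[2] * (nxt[, 3] - 1)
    keep <- sel[idx] & !visited[idx]
    idx_keep <- unique(idx[keep])
    if (!length(idx_keep)) break
    visited[idx_keep] <- TRUE
    queue <- arrayInd(idx_keep, d)
  }
  count
}

# tiny single-subfield imaging subject used by pipeline tests
tiny_subject <- function(seed = 1, sigma = 0.12, mu = log(80),
                         n_target = 600, noise_sd = 4) {
  set.seed(seed)
  spec <- list(subfield_spec("DG", n_target, "blob"))
  out <- list()
  for (h in c("L", "R")) {
    mask <- gen_subfield_mask(NULL, spec, seed = seed + match(h, c("L", "R")),
                              erosion_band = NULL)
    t2t <- array(0, dim(mask$labels))
    sel <- mask$labels == subfield_codes()[["DG"]]
    t2t[sel] <- rloglogis(sum(sel), mu, sigma)
    vol <- gen_multiecho_volume(t2t, 400, seq(12, 120, 12), noise_sd,
                                exclude_first_echo = TRUE)
    out[[h]] <- list(volume = vol, mask = mask)
  }
  out
}

# null cohort preset: every effect switched off; overrides win
null_preset <- function(...) {
  z5 <- c(DG = 0, CA = 0, SUB = 0, EC = 0, BA35 = 0)
  args <- list(d_sigma = z5, d_mu = z5, d_vol = z5, age_sigma = z5,
               age_mu = z5, sigma_vol = z5, age_vol = z5,
               vol_pal_acc = z5, vol_pal_rt = z5,
               age_pal_acc = 0, age_pal_rt = 0,
               cog = c(baseline = 0, age = 0, sigma_ca = 0, resid = 1))
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(cohort_preset, args)
}
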
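# Independent oracles used by both the module tests and the acceptance
# suite. These deliberately re-derive quantities by the dumbest possible
# route (explicit loops, scalar recursions) and never call the vectorized
# implementation they check.

loop_mape <- function(pred, truth, mask, eps = 1.0) {
  tot <- 0; cnt <- 0
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(ncol(truth))) {
      if (mask[i, j]) {
        tot <- tot + abs(pred[i, j] - truth[i, j]) / max(truth[i, j], eps)
        cnt <- cnt + 1
      }
    }
  }
  100 * tot / cnt
}

loop_rmse <- function(pred, truth, mask) {
  tot <- 0; cnt <- 0
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(ncol(truth))) {
      if (mask[i, j]) {
        tot <- tot + (pred[i, j] - truth[i, j])^2
        cnt <- cnt + 1
      }
    }
  }
  sqrt(tot / cnt)
}

random_panel_pair <- function(seed, n = 20, tt = 50) {
  set.seed(seed)
  stamps <- hourly_stamps(tt)
  truth <- matrix(runif(n * tt, 0, 400), n, tt,
                  dimnames = list(sprintf("s%02d", 1:n), NULL))
  mask <- matrix(runif(n * tt) < 0.7, n, tt)
  tv <- truth; tv[!mask] <- NA
  pred <- truth + matrix(rnorm(n * tt, 0, 25), n, tt)
  pv <- pred; pvalid <- matrix(runif(n * tt) < 0.9, n, tt); pv[!pvalid] <- NA
  list(truth = readings_panel(tv, stamps, mask = mask),
       pred = readings_panel(pv, stamps, mask = pvalid, bounds = NULL),
       both = mask & pvalid)
}

# Scalar Kalman filter for the univariate AR(1) + noise state-space model.
scalar_kalman_loglik <- function(y, phi, q, r, P0) {
  x <- 0; P <- P0; ll <- 0
  for (t in seq_along(y)) {
    if (t > 1) { x <- phi * x; P <- phi^2 * P + q }
    if (!is.na(y[t])) {
      S <- P + r
      e <- y[t] - x
      ll <- ll - 0.5 * (log(2 * pi * S) + e^2 / S)
      K <- P / S
      x <- x + K * e
      P <- (1 - K) * P
    }
  }
  ll
}

make_sthm_fit <- function(site, phi, q, r, mean_level, tz = "UTC") {
  structure(list(
    sites = site, tier = "all",
    dist = matrix(0, 1, 1, dimnames = list(site, site)), tz = tz,
    phi = phi, rho = 5, sigma_sp = sqrt(q), sigma_eps = c(all = sqrt(r)),
    a_site = stats::setNames(mean_level, site), s_hour = rep(0, 24),
    Sigma0 = matrix(q / (1 - phi^2), 1, 1), mean_structure = TRUE
  ), class = "sthm_fit")
}
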
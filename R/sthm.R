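# Spatio-Temporal Hierarchical Model: a linear-Gaussian hierarchical
# state-space model in the descriptive-geostatistics tradition.
#
#   y_{v,t} = a_v + s_{hour(t)} + z_{v,t} + eps_{v,t},   eps ~ N(0, sigma_eps(tier)^2)
#   z_t     = phi z_{t-1} + eta_t,                       eta ~ N(0, sigma_sp^2 exp(-d/rho))
#
# fit by EM: the E-step runs a Kalman filter + RTS smoother over the latent
# field with missing observation rows simply omitted at each hour; the
# M-step has closed-form updates for the mean structure, phi, sigma_sp and
# the noise sds, and profiles rho over a fixed log-spaced grid. The initial
# state covariance is a free parameter (updated to the smoothed second
# moment), and the current rho is always among the profile candidates, so
# every EM step is a true ascent of the observed-data log-likelihood.

sthm_config_defaults <- function() {
  list(max_iter = 30, tol = 1e-4,
       rho_grid = exp(seq(log(0.5), log(50), length.out = 15)),
       phi_init = 0.5, mean_structure = TRUE, var_floor = 1e-8)
}

# Kalman filter with per-hour observation subsets.
# yc: centered observations (n x T, NA where missing); Q, Sigma0: n x n;
# rvar: per-site observation variances. Returns filtered moments, one-step
# predictive moments, and the exact log-likelihood.
sthm_kfilter <- function(yc, phi, Q, Sigma0, rvar, keep_pred = TRUE) {
  n <- nrow(yc); tt <- ncol(yc)
  xf <- matrix(0, n, tt)
  Pf <- array(0, c(n, n, tt))
  xp <- if (keep_pred) matrix(0, n, tt) else NULL
  Pp <- if (keep_pred) array(0, c(n, n, tt)) else NULL
  ll <- 0
  x <- rep(0, n); P <- Sigma0
  for (t in seq_len(tt)) {
    if (t > 1) {
      x <- phi * x
      P <- phi^2 * P + Q
    }
    if (keep_pred) { xp[, t] <- x; Pp[, , t] <- P }
    o <- which(!is.na(yc[, t]))
    if (length(o)) {
      e <- yc[o, t] - x[o]
      S <- P[o, o, drop = FALSE] + diag(rvar[o], length(o))
      cS <- tryCatch(chol(S), error = function(err)
        chol(S + diag(1e-10, length(o))))
      Sinv_e <- backsolve(cS, forwardsolve(t(cS), e))
      ll <- ll - 0.5 * (length(o) * log(2 * pi) + 2 * sum(log(diag(cS))) +
                          sum(e * Sinv_e))
      PHt <- P[, o, drop = FALSE]
      K <- t(backsolve(cS, forwardsolve(t(cS), t(PHt))))
      x <- x + drop(K %*% e)
      P <- P - K %*% t(PHt)
      P <- (P + t(P)) / 2
    }
    xf[, t] <- x
    Pf[, , t] <- P
  }
  list(xf = xf, Pf = Pf, xp = xp, Pp = Pp, loglik = ll)
}

# RTS smoother; also returns lag-one smoothed cross-covariances
# Cov(z_t, z_{t-1} | Y) = P_{t|T} J_{t-1}'.
sthm_ksmoother <- function(kf, phi) {
  n <- nrow(kf$xf); tt <- ncol(kf$xf)
  xs <- kf$xf
  Ps <- kf$Pf
  Plag <- array(0, c(n, n, tt))  # Plag[,,t] = Cov(z_t, z_{t-1}|Y), t >= 2
  if (tt > 1) {
    for (t in (tt - 1):1) {
      Ppn <- kf$Pp[, , t + 1]
      J <- phi * t(solve(Ppn + diag(1e-12, n), kf$Pf[, , t]))
      xs[, t] <- kf$xf[, t] + drop(J %*% (xs[, t + 1] - kf$xp[, t + 1]))
      Ps[, , t] <- kf$Pf[, , t] + J %*% (Ps[, , t + 1] - Ppn) %*% t(J)
      Ps[, , t] <- (Ps[, , t] + t(Ps[, , t])) / 2
      Plag[, , t + 1] <- Ps[, , t + 1] %*% t(J)
    }
  }
  list(xs = xs, Ps = Ps, Plag = Plag)
}

sthm_mean_matrix <- function(a_site, s_hour, hod) {
  outer(a_site, rep(1, length(hod))) +
    outer(rep(1, length(a_site)), s_hour[hod + 1])
}

#' Fit the spatio-temporal hierarchical model by EM
#'
#' @param panel a [readings_panel]; missing cells are handled exactly by the
#'   Kalman machinery (their observation rows are omitted).
#' @param sites optional site table with `site_id` and `tier` (per-tier
#'   observation noise) and coordinates; if omitted, a single shared noise
#'   variance is used and distances must be supplied via `dist`.
#' @param dist optional precomputed km distance matrix (site order must
#'   match the panel); computed from `sites` otherwise.
#' @param config list overriding any of: `max_iter` (30), `tol` (1e-4,
#'   relative log-likelihood change), `rho_grid` (15 log-spaced points,
#'   0.5-50 km), `phi_init` (0.5), `mean_structure` (TRUE: site intercept +
#'   24 shared hour-of-day offsets).
#' @return an `sthm_fit`: estimated parameters (`phi`, `rho`, `sigma_sp`,
#'   `sigma_eps` per tier), mean structure (`a_site`, `s_hour`), smoothed
#'   latent states and their variances over the training panel, the
#'   log-likelihood trace (non-decreasing), and a convergence flag.
#' @export
fit_sthm <- function(panel, sites = NULL, dist = NULL, config = list()) {
  cfg <- utils::modifyList(sthm_config_defaults(), config)
  obs_per_site <- rowSums(panel$mask)
  if (sum(obs_per_site) == 0) stopf("fit_sthm: all cells missing")
  if (sum(obs_per_site) < 48) stopf("fit_sthm: need >= 48 observed hours overall")
  drop <- obs_per_site == 0
  if (any(drop)) {
    warnf("fit_sthm: dropping site(s) with no observations: %s",
          paste(panel$sites[drop], collapse = ", "))
    panel <- subset_panel(panel, sites = which(!drop))
  }
  n <- length(panel$sites); tt <- length(panel$timestamps)

  if (is.null(dist)) {
    if (is.null(sites)) stopf("fit_sthm: need `sites` (with coordinates) or `dist`")
    geom <- build_geometry(sites[match(panel$sites, sites$site_id), , drop = FALSE])
    dist <- geom$dist
  } else {
    dist <- dist[panel$sites, panel$sites, drop = FALSE]
  }
  tier <- if (!is.null(sites) && "tier" %in% names(sites)) {
    sites$tier[match(panel$sites, sites$site_id)]
  } else rep("all", n)
  tz <- attr(panel$timestamps, "tzone") %||% ""
  hod <- hour_of_day(panel$timestamps, tz)

  y <- panel$values
  y[!panel$mask] <- NA_real_

  # --- deterministic initialization (documented method-of-moments) ---
  a_site <- rowMeans(y, na.rm = TRUE)
  s_hour <- rep(0, 24)
  if (cfg$mean_structure) {
    r0 <- y - a_site
    for (h in 0:23) {
      v <- r0[, hod == h, drop = FALSE]
      s_hour[h + 1] <- mean(v, na.rm = TRUE)
    }
    s_hour[!is.finite(s_hour)] <- 0
    s_hour <- s_hour - mean(s_hour)
  }
  resid0 <- y - sthm_mean_matrix(a_site, s_hour, hod)
  v0 <- stats::var(resid0[panel$mask])
  if (!is.finite(v0) || v0 <= 0) v0 <- 1
  phi <- cfg$phi_init
  rho <- max(dist) / 4
  if (!is.finite(rho) || rho <= 0) rho <- 1
  sigma_sp2 <- 0.5 * v0 * (1 - phi^2)
  rvar_tier <- stats::setNames(rep(0.5 * v0, length(unique(tier))), unique(tier))

  Rcor <- function(r) exp(-dist / r)
  ll_trace <- numeric(0)
  converged <- FALSE
  Sigma0 <- sigma_sp2 / (1 - phi^2) * Rcor(rho)
  sm <- NULL

  for (iter in seq_len(cfg$max_iter)) {
    mu <- sthm_mean_matrix(a_site, s_hour, hod)
    rvar <- pmax(rvar_tier[tier], cfg$var_floor)
    kf <- sthm_kfilter(y - mu, phi, sigma_sp2 * Rcor(rho), Sigma0, rvar)
    ll_trace <- c(ll_trace, kf$loglik)
    if (iter > 1) {
      dll <- kf$loglik - ll_trace[iter - 1]
      if (abs(dll) < cfg$tol * (abs(ll_trace[iter - 1]) + 1)) {
        converged <- TRUE
        sm <- sthm_ksmoother(kf, phi)
        break
      }
    }
    sm <- sthm_ksmoother(kf, phi)

    # --- M-step ---
    # sufficient statistics of the process term
    S11 <- matrix(0, n, n); S10 <- matrix(0, n, n); S00 <- matrix(0, n, n)
    if (tt > 1) {
      for (t in 2:tt) {
        S11 <- S11 + sm$Ps[, , t] + tcrossprod(sm$xs[, t])
        S10 <- S10 + sm$Plag[, , t] + tcrossprod(sm$xs[, t], sm$xs[, t - 1])
        S00 <- S00 + sm$Ps[, , t - 1] + tcrossprod(sm$xs[, t - 1])
      }
    }
    # profile over rho (current value always a candidate -> monotone EM)
    if (tt > 1) {
      best <- NULL
      for (r in unique(c(cfg$rho_grid, rho))) {
        R <- Rcor(r)
        cR <- chol(R + diag(1e-10, n))
        Rinv <- chol2inv(cR)
        den <- sum(Rinv * S00)
        ph <- if (den > 0) max(min(sum(Rinv * S10) / den, 0.999), -0.999) else 0
        Cm <- S11 - ph * (S10 + t(S10)) + ph^2 * S00
        s2 <- max(sum(Rinv * Cm) / (n * (tt - 1)), cfg$var_floor)
        qv <- -0.5 * ((tt - 1) * (n * log(s2) + 2 * sum(log(diag(cR)))) +
                        sum(Rinv * Cm) / s2)
        if (is.null(best) || qv > best$qv) best <- list(rho = r, phi = ph, s2 = s2, qv = qv)
      }
      rho <- best$rho; phi <- best$phi; sigma_sp2 <- best$s2
    }
    Sigma0 <- sm$Ps[, , 1] + tcrossprod(sm$xs[, 1])

    # mean structure: weighted coordinate ascent (weights = 1/noise var per tier)
    if (cfg$mean_structure) {
      w <- 1 / pmax(rvar_tier[tier], cfg$var_floor)
      rr <- y - sm$xs
      for (sweep in 1:3) {
        adj <- rr - outer(rep(1, n), s_hour[hod + 1])
        a_site <- rowMeans(adj, na.rm = TRUE)  # same weight within a site
        adj <- rr - a_site
        for (h in 0:23) {
          cols <- hod == h
          vals <- adj[, cols, drop = FALSE]
          ww <- matrix(w, n, sum(cols))
          ww[is.na(vals)] <- 0
          s_hour[h + 1] <- if (sum(ww) > 0) sum(vals * ww, na.rm = TRUE) / sum(ww) else 0
        }
        ctr <- mean(s_hour)
        s_hour <- s_hour - ctr
        a_site <- a_site + ctr
      }
    } else {
      rr <- y - sm$xs
      a_site <- rowMeans(rr, na.rm = TRUE)
      a_site[!is.finite(a_site)] <- 0
    }

    # observation noise per tier
    mu <- sthm_mean_matrix(a_site, s_hour, hod)
    sq <- (y - mu - sm$xs)^2
    tot <- sq + matrix(apply(sm$Ps, 3, diag), n, tt)
    for (tr in names(rvar_tier)) {
      cells <- panel$mask & (tier == tr)
      rvar_tier[tr] <- max(mean(tot[cells]), cfg$var_floor)
    }
  }

  fit <- structure(list(
    sites = panel$sites, tier = tier, dist = dist, tz = tz,
    phi = phi, rho = rho, sigma_sp = sqrt(sigma_sp2),
    sigma_eps = sqrt(rvar_tier),
    a_site = stats::setNames(a_site, panel$sites), s_hour = s_hour,
    Sigma0 = Sigma0,
    smoothed = sm$xs, smoothed_var = matrix(apply(sm$Ps, 3, diag), n, tt),
    loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
    n_iter = length(ll_trace), converged = converged,
    mean_structure = cfg$mean_structure, config = cfg
  ), class = "sthm_fit")
  if (!converged) {
    fit$converged <- FALSE
  }
  fit
}

#' @export
print.sthm_fit <- function(x, ...) {
  cat(sprintf("<sthm_fit> %d sites  phi=%.3f  rho=%.2f km  sigma_sp=%.2f\n",
              length(x$sites), x$phi, x$rho, x$sigma_sp))
  cat(sprintf("  sigma_eps: %s\n",
              paste(sprintf("%s=%.2f", names(x$sigma_eps), x$sigma_eps),
                    collapse = "  ")))
  cat(sprintf("  loglik %.2f after %d EM iterations (%sconverged)\n",
              x$loglik, x$n_iter, if (x$converged) "" else "not "))
  invisible(x)
}

sthm_panel_inputs <- function(fit, panel) {
  i <- match(panel$sites, fit$sites)
  if (anyNA(i)) {
    stopf("sthm: fit does not cover site(s): %s",
          paste(panel$sites[is.na(i)], collapse = ", "))
  }
  hod <- hour_of_day(panel$timestamps, fit$tz)
  mu <- sthm_mean_matrix(fit$a_site[i], fit$s_hour, hod)
  y <- panel$values
  y[!panel$mask] <- NA_real_
  list(idx = i, mu = mu, yc = y - mu,
       Q = fit$sigma_sp^2 * exp(-fit$dist[i, i, drop = FALSE] / fit$rho),
       Sigma0 = fit$Sigma0[i, i, drop = FALSE],
       rvar = pmax(fit$sigma_eps[fit$tier[i]]^2, 1e-8))
}

#' Log-likelihood of a panel under a fitted model
#'
#' Evaluates the exact marginal Gaussian log-likelihood via the Kalman
#' filter (missing cells omitted).
#'
#' @param fit an `sthm_fit`.
#' @param panel a [readings_panel] whose sites the fit covers.
#' @return log-likelihood (scalar).
#' @export
sthm_loglik <- function(fit, panel) {
  inp <- sthm_panel_inputs(fit, panel)
  sthm_kfilter(inp$yc, fit$phi, inp$Q, inp$Sigma0, inp$rvar, keep_pred = FALSE)$loglik
}

#' Fill gaps with the smoothed posterior mean
#'
#' Unobserved cells are replaced by `mean structure + smoothed latent
#' state`, clipped to \[0, 1000\]; observed cells are untouched. The result
#' is fully observed, with the provenance recorded in the `"imputed"`
#' attribute (a logical matrix marking filled cells).
#'
#' @param fit an `sthm_fit`.
#' @param panel a [readings_panel] whose sites the fit covers.
#' @return a fully observed [readings_panel] with attribute `"imputed"`.
#' @export
sthm_impute <- function(fit, panel) {
  if (!any(!panel$mask)) {
    out <- panel
    attr(out, "imputed") <- !panel$mask
    return(out)
  }
  inp <- sthm_panel_inputs(fit, panel)
  kf <- sthm_kfilter(inp$yc, fit$phi, inp$Q, inp$Sigma0, inp$rvar)
  sm <- sthm_ksmoother(kf, fit$phi)
  filled <- clip_pm(inp$mu + sm$xs)
  vals <- panel$values
  vals[!panel$mask] <- filled[!panel$mask]
  out <- readings_panel(vals, panel$timestamps, sites = panel$sites)
  attr(out, "imputed") <- !panel$mask
  out
}

#' One-step-ahead forecasts from the state-space model
#'
#' For each hour t the prediction is `mean structure at t + phi * filtered
#' state at t-1`, i.e. the exact one-step-ahead predictive mean given all
#' observations up to t-1. The first hour carries no prediction.
#'
#' @param fit an `sthm_fit`.
#' @param panel a [readings_panel] supplying the observation history.
#' @return an unbounded [readings_panel] of predictions (first column
#'   invalid).
#' @export
predict_sthm <- function(fit, panel) {
  inp <- sthm_panel_inputs(fit, panel)
  kf <- sthm_kfilter(inp$yc, fit$phi, inp$Q, inp$Sigma0, inp$rvar)
  tt <- length(panel$timestamps)
  pred <- inp$mu + kf$xp
  valid <- matrix(TRUE, length(panel$sites), tt)
  valid[, 1] <- FALSE
  pred[!valid] <- NA_real_
  readings_panel(pred, panel$timestamps, sites = panel$sites,
                 mask = valid, bounds = NULL)
}
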
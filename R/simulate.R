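#' Synthetic-city simulation configuration
#'
#' Parameters of the seeded synthetic sensor network generator. Defaults
#' emulate a dense urban PM2.5 network: a ~30 km extent, city-mean
#' concentration near 130 ug/m3, a three-regime diurnal baseline (rising to
#' 8am, falling to 4pm, rising to midnight), strongly persistent and
#' spatially correlated short-term dynamics, and two sensor tiers -- quiet,
#' highly available reference monitors and noisier low-cost sensors with
#' ~30% availability and blocky outages. The desk-scale default of 20 sites
#' and 120 days keeps every downstream model trainable in minutes.
#'
#' @param n_sites number of monitors.
#' @param extent_km side of the square urban extent (km).
#' @param n_days simulated days (hourly resolution).
#' @param mean_level city-mean PM2.5 (ug/m3).
#' @param amplitude diurnal peak-to-mean swing (ug/m3): the baseline rises to
#'   `mean_level + amplitude` at 8am and falls to `mean_level - amplitude`
#'   at 4pm.
#' @param site_level_sd sd of per-site offsets to `mean_level` (ug/m3).
#' @param site_amp_jitter relative jitter of per-site amplitude (uniform
#'   in `1 +/- site_amp_jitter`).
#' @param ar_coefficient hourly AR(1) coefficient of the residual field,
#'   abs value < 1.
#' @param spatial_range_km e-folding range of the exponential spatial
#'   correlation of residual innovations (km).
#' @param innovation_sd sd of residual-field innovations (ug/m3).
#' @param noise_sd_reference,noise_sd_low_cost measurement noise sd per tier.
#' @param avail_reference,avail_low_cost target availability per tier, in
#'   (0, 1].
#' @param outage_mean_hours mean length of a down run (blocky outages).
#' @param frac_reference fraction of sites on the reference tier.
#' @param blocky_outages if `FALSE`, use i.i.d. Bernoulli missingness
#'   instead of geometric up/down runs.
#' @param seasonal,seasonal_amplitude optional slow annual sinusoidal
#'   modulation of the city mean (off by default: the generator's scope is
#'   sub-seasonal).
#' @param start first hour of the simulation (local time).
#' @param tz timezone of the panel.
#' @param seed master integer seed; every random stream derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_sites = 20, extent_km = 30, n_days = 120,
                       mean_level = 130, amplitude = 60,
                       site_level_sd = 15, site_amp_jitter = 0.2,
                       ar_coefficient = 0.9, spatial_range_km = 10,
                       innovation_sd = 15,
                       noise_sd_reference = 5, noise_sd_low_cost = 15,
                       avail_reference = 0.9, avail_low_cost = 0.3,
                       outage_mean_hours = 12, frac_reference = 0.5,
                       blocky_outages = TRUE,
                       seasonal = FALSE, seasonal_amplitude = 40,
                       start = "2018-05-01 00:00:00", tz = "Asia/Kolkata",
                       seed = 1) {
  cfg <- list(
    n_sites = as.integer(n_sites), extent_km = extent_km, n_days = n_days,
    mean_level = mean_level, amplitude = amplitude,
    site_level_sd = site_level_sd, site_amp_jitter = site_amp_jitter,
    ar_coefficient = ar_coefficient, spatial_range_km = spatial_range_km,
    innovation_sd = innovation_sd,
    noise_sd_reference = noise_sd_reference,
    noise_sd_low_cost = noise_sd_low_cost,
    avail_reference = avail_reference, avail_low_cost = avail_low_cost,
    outage_mean_hours = outage_mean_hours, frac_reference = frac_reference,
    blocky_outages = blocky_outages,
    seasonal = isTRUE(seasonal), seasonal_amplitude = seasonal_amplitude,
    start = start, tz = tz, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_sites < 1) stopf("sim_config: n_sites must be >= 1")
    if (abs(ar_coefficient) >= 1) stopf("sim_config: |ar_coefficient| must be < 1")
    if (any(c(innovation_sd, noise_sd_reference, noise_sd_low_cost,
              site_level_sd) < 0)) stopf("sim_config: sds must be >= 0")
    for (a in c(avail_reference, avail_low_cost)) {
      if (a <= 0 || a > 1) stopf("sim_config: availability must lie in (0, 1]")
    }
    if (spatial_range_km <= 0) stopf("sim_config: spatial_range_km must be > 0")
  })
  invisible(cfg)
}

#' Diurnal baseline curve
#'
#' The smooth 24-h periodic baseline: piecewise-cubic over the three 8-hour
#' slots, built from Hermite segments with zero slope at the slot knots
#' 0h/8h/16h/24h. With positive amplitude it rises monotonically from
#' `mean_level` at midnight to `mean_level + amplitude` at 8am, falls to
#' `mean_level - amplitude` at 4pm, and rises back by midnight. Each slot
#' restriction is exactly a cubic polynomial in within-slot time, and the
#' day-mean equals `mean_level`.
#'
#' @param hour numeric hour(s) of day in \[0, 24).
#' @param mean_level,amplitude curve parameters (ug/m3).
#' @return baseline values, same length as `hour`.
#' @export
diurnal_baseline <- function(hour, mean_level = 130, amplitude = 60) {
  h <- as.numeric(hour)
  if (any(h < 0 | h >= 24)) stopf("diurnal_baseline: hour must lie in [0, 24)")
  knot_vals <- c(mean_level, mean_level + amplitude, mean_level - amplitude,
                 mean_level)
  slot <- pmin(floor(h / 8), 2)
  s <- (h - 8 * slot) / 8
  va <- knot_vals[slot + 1]
  vb <- knot_vals[slot + 2]
  va + (vb - va) * (3 * s^2 - 2 * s^3)
}

#' Spatially correlated AR(1) residual field
#'
#' Simulates `z_t = phi z_(t-1) + eta_t` with innovations
#' `eta_t ~ N(0, sigma_sp^2 exp(-d/rho))` over the site network, started
#' from its stationary marginal `sigma_sp^2/(1-phi^2) exp(-d/rho)`.
#'
#' @param dist symmetric km distance matrix (sites as rows/cols).
#' @param n_hours series length.
#' @param phi AR(1) coefficient, abs value < 1.
#' @param sigma_sp innovation sd (ug/m3).
#' @param rho spatial e-folding range (km).
#' @param seed integer seed; same seed gives an identical field.
#' @return numeric matrix sites x hours.
#' @export
simulate_residual_field <- function(dist, n_hours, phi, sigma_sp, rho, seed) {
  n <- nrow(dist)
  if (abs(phi) >= 1) stopf("simulate_residual_field: |phi| must be < 1")
  if (rho <= 0) stopf("simulate_residual_field: rho must be > 0")
  z <- matrix(0, n, n_hours, dimnames = list(rownames(dist), NULL))
  if (sigma_sp == 0 || n_hours == 0) return(z)
  R <- exp(-dist / rho)
  L <- tryCatch(t(chol(R + diag(1e-10, n))),
                error = function(e) stopf(
                  "simulate_residual_field: spatial covariance not positive definite"))
  with_seed(seed, {
    z0 <- (sigma_sp / sqrt(1 - phi^2)) * (L %*% stats::rnorm(n))
    eta <- sigma_sp * (L %*% matrix(stats::rnorm(n * n_hours), n, n_hours))
    prev <- z0
    for (t in seq_len(n_hours)) {
      prev <- phi * prev + eta[, t]
      z[, t] <- prev
    }
  })
  z
}

# Geometric-run up/down mask for one site: stationary alternating renewal
# with mean up run u and mean down run d, so long-run availability u/(u+d).
renewal_mask <- function(n_hours, avail, outage_mean_hours) {
  if (avail >= 1) return(rep(TRUE, n_hours))
  d <- max(outage_mean_hours, 1)
  u <- avail / (1 - avail) * d
  state <- stats::runif(1) < avail
  out <- logical(n_hours)
  i <- 1L
  while (i <= n_hours) {
    len <- stats::rgeom(1, prob = 1 / if (state) u else d) + 1L
    j <- min(i + len - 1L, n_hours)
    out[i:j] <- state
    state <- !state
    i <- j + 1L
  }
  out
}

#' Degrade a panel with tier-dependent missingness
#'
#' Marks cells unobserved according to a per-site alternating renewal
#' process (geometric up/down run lengths) whose long-run availability
#' matches the tier target; values at surviving cells are untouched. With
#' `blocky = FALSE`, uses i.i.d. Bernoulli missingness instead.
#'
#' @param panel a fully or partially observed [readings_panel].
#' @param availability numeric vector of per-site target availabilities in
#'   (0, 1] (recycled if length 1).
#' @param outage_mean_hours mean down-run length.
#' @param seed integer seed (per-site substreams derive from it).
#' @param blocky geometric runs (default) vs Bernoulli missingness.
#' @return a [readings_panel] with the degraded mask.
#' @export
apply_missingness <- function(panel, availability, outage_mean_hours = 12,
                              seed = 1, blocky = TRUE) {
  n <- length(panel$sites); tt <- length(panel$timestamps)
  availability <- rep_len(availability, n)
  if (any(availability <= 0 | availability > 1)) {
    stopf("apply_missingness: availability must lie in (0, 1]")
  }
  mask <- panel$mask
  for (i in seq_len(n)) {
    if (availability[i] >= 1) next
    keep <- with_seed(substream_seed(seed, 5L, i), {
      if (blocky) renewal_mask(tt, availability[i], outage_mean_hours)
      else stats::runif(tt) < availability[i]
    })
    mask[i, ] <- mask[i, ] & keep
  }
  vals <- panel$values
  vals[!mask] <- NA_real_
  readings_panel(vals, panel$timestamps, sites = panel$sites, mask = mask)
}

#' Simulate a synthetic sensor city
#'
#' Generates ground truth and degraded observations over a square urban
#' extent: per-site diurnal baselines plus a spatially correlated AR(1)
#' residual field, clipped to \[0, 1000\]; observations add tier-dependent
#' Gaussian noise (re-clipped) and tier-dependent blocky missingness. The
#' whole product is a deterministic function of `config$seed`, and each site
#' draws from its own counter-derived random stream, so enlarging the
#' network leaves existing sites' streams unchanged (except through the
#' jointly drawn residual field).
#'
#' @param config a [sim_config()].
#' @return list with `truth` (fully observed [readings_panel]), `observed`
#'   (noisy, gappy panel), `sites` (data.frame `site_id`, `x_km`, `y_km`,
#'   `tier`), and `config`.
#' @export
simulate_city <- function(config = sim_config()) {
  validate_sim_config(config)
  n <- config$n_sites
  tt <- as.integer(round(config$n_days * 24))
  ids <- sprintf("S%03d", seq_len(n))
  t0 <- as.POSIXct(config$start, tz = config$tz)
  stamps <- seq(t0, by = 3600, length.out = tt)

  n_ref <- round(config$frac_reference * n)
  tier <- c(rep("reference", n_ref), rep("low_cost", n - n_ref))

  xy <- t(vapply(seq_len(n), function(i) {
    with_seed(substream_seed(config$seed, 1L, i),
              stats::runif(2, 0, config$extent_km))
  }, numeric(2)))
  sites <- data.frame(site_id = ids, x_km = xy[, 1], y_km = xy[, 2],
                      tier = tier, stringsAsFactors = FALSE)

  site_mean <- numeric(n); site_amp <- numeric(n)
  for (i in seq_len(n)) {
    with_seed(substream_seed(config$seed, 2L, i), {
      site_mean[i] <- config$mean_level + stats::rnorm(1, 0, config$site_level_sd)
      site_amp[i] <- config$amplitude *
        stats::runif(1, 1 - config$site_amp_jitter, 1 + config$site_amp_jitter)
    })
  }

  hod <- hour_of_day(stamps, config$tz)
  base <- matrix(0, n, tt, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    base[i, ] <- diurnal_baseline(hod, site_mean[i], site_amp[i])
  }
  if (config$seasonal && tt > 0) {
    day_frac <- (as.numeric(stamps) - as.numeric(t0)) / 86400
    base <- base + rep(config$seasonal_amplitude * sin(2 * pi * day_frac / 365.25),
                       each = n)
  }

  geom <- build_geometry(sites)
  z <- simulate_residual_field(geom$dist, tt, config$ar_coefficient,
                               config$innovation_sd, config$spatial_range_km,
                               seed = substream_seed(config$seed, 3L))
  truth_vals <- clip_pm(base + z)
  truth <- readings_panel(truth_vals, stamps, sites = ids)

  noise_sd <- ifelse(tier == "reference", config$noise_sd_reference,
                     config$noise_sd_low_cost)
  obs_vals <- truth_vals
  for (i in seq_len(n)) {
    if (noise_sd[i] > 0) {
      eps <- with_seed(substream_seed(config$seed, 4L, i),
                       stats::rnorm(tt, 0, noise_sd[i]))
      obs_vals[i, ] <- clip_pm(truth_vals[i, ] + eps)
    }
  }
  observed <- readings_panel(obs_vals, stamps, sites = ids)
  avail <- ifelse(tier == "reference", config$avail_reference,
                  config$avail_low_cost)
  observed <- apply_missingness(observed, avail, config$outage_mean_hours,
                                seed = config$seed,
                                blocky = config$blocky_outages)

  list(truth = truth, observed = observed, sites = sites, config = config)
}
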
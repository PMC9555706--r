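#' Project site coordinates and compute the pairwise distance matrix
#'
#' Maps latitude/longitude to a local planar frame via an equirectangular
#' projection about the mean latitude (1 deg lat = 111.32 km, 1 deg lon =
#' 111.32 * cos(mean lat) km) and computes all pairwise Euclidean distances
#' in km. Valid for a single metropolitan extent; refuses spans over 200 km
#' where the planar approximation degrades. If the site table already carries
#' `x_km`/`y_km` (e.g. simulator output), those are used as-is.
#'
#' @param sites data.frame with `site_id` and either `latitude`/`longitude`
#'   or `x_km`/`y_km` columns; a `tier` column is carried through.
#' @return list with `sites` (input plus `x_km`, `y_km`) and `dist`
#'   (symmetric km matrix with site ids as dimnames, zero diagonal).
#' @export
build_geometry <- function(sites) {
  stopifnot(is.data.frame(sites), "site_id" %in% names(sites))
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id)) stopf("build_geometry: duplicate site_id")
  if (!all(c("x_km", "y_km") %in% names(sites))) {
    if (!all(c("latitude", "longitude") %in% names(sites))) {
      stopf("build_geometry: need latitude/longitude or x_km/y_km columns")
    }
    lat <- sites$latitude; lon <- sites$longitude
    if (any(!is.finite(lat)) || any(abs(lat) > 90)) stopf("invalid latitude")
    if (any(!is.finite(lon)) || any(abs(lon) > 180)) stopf("invalid longitude")
    lat0 <- mean(lat)
    sites$x_km <- (lon - mean(lon)) * 111.32 * cos(lat0 * pi / 180)
    sites$y_km <- (lat - lat0) * 111.32
  }
  if (any(!is.finite(sites$x_km)) || any(!is.finite(sites$y_km))) {
    stopf("build_geometry: non-finite planar coordinates")
  }
  d <- as.matrix(stats::dist(cbind(sites$x_km, sites$y_km)))
  dimnames(d) <- list(sites$site_id, sites$site_id)
  if (nrow(sites) > 1 && max(d) > 200) {
    stopf("build_geometry: network span %.1f km exceeds 200 km; local planar projection invalid",
          max(d))
  }
  list(sites = sites, dist = d)
}

#' Diurnal slot of an hour
#'
#' The day is partitioned into three behavioural regimes of 8 hours each:
#' slot 1 = midnight-8am, slot 2 = 8am-4pm, slot 3 = 4pm-midnight, evaluated
#' in local time. Slot boundaries are half-open, so 08:00 belongs to slot 2.
#'
#' @param t `POSIXct` instants, or integer hours of day in 0..23.
#' @param tz timezone in which the local hour is taken; defaults to the
#'   `tzone` attribute of `t`.
#' @return integer vector of slots in {1, 2, 3}.
#' @export
hour_slot <- function(t, tz = NULL) {
  h <- hour_of_day(t, tz)
  h %/% 8L + 1L
}

hour_of_day <- function(t, tz = NULL) {
  if (inherits(t, "POSIXt")) {
    tz <- tz %||% attr(t, "tzone") %||% ""
    h <- as.integer(format(t, "%H", tz = tz))
  } else {
    h <- as.integer(t)
  }
  if (any(h < 0L | h > 23L)) stopf("hour_slot: hour of day outside 0..23")
  h
}

#' Chronological train/test split
#'
#' Splits a panel at a time boundary with no shuffling: the training panel
#' ends strictly before the test panel begins. A fractional boundary is
#' resolved to the nearest hour.
#'
#' @param panel a [readings_panel].
#' @param boundary either a fraction in (0, 1) of the panel's columns that go
#'   to training, or a `POSIXct` instant (first test hour).
#' @return list with `train` and `test` panels.
#' @export
split_train_test <- function(panel, boundary) {
  tt <- length(panel$timestamps)
  if (tt < 2) stopf("split_train_test: panel too short to split")
  if (inherits(boundary, "POSIXt")) {
    n_train <- sum(panel$timestamps < boundary)
  } else {
    b <- as.numeric(boundary)
    if (!is.finite(b) || b <= 0 || b >= 1) {
      stopf("split_train_test: fractional boundary must lie strictly in (0, 1)")
    }
    n_train <- round(b * tt)
  }
  if (n_train < 1 || n_train >= tt) {
    stopf("split_train_test: boundary must leave nonempty train and test sets")
  }
  list(
    train = subset_panel(panel, time_idx = seq_len(n_train)),
    test = subset_panel(panel, time_idx = (n_train + 1L):tt)
  )
}
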
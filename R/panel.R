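#' Hourly readings panel
#'
#' The central container of the package: an hourly PM2.5 matrix over a sensor
#' network, sites in rows and timestamps in columns, with an explicit
#' missingness mask. Unobserved cells hold `NA` in `values` and `FALSE` in
#' `mask`; observed cells are finite and lie in \[0, 1000\] ug/m3.
#'
#' @param values numeric matrix, sites x hours; `NA` where unobserved.
#' @param timestamps `POSIXct` vector of column instants, strictly increasing
#'   and spaced exactly one hour.
#' @param sites character vector of site ids (row order); defaults to
#'   `rownames(values)`.
#' @param mask logical matrix of the same shape; defaults to `!is.na(values)`.
#' @param validate check invariants (disable only in hot internal paths).
#' @param bounds admissible value range for observed cells, default
#'   `c(0, 1000)` ug/m3; `NULL` for unbounded panels (e.g. residuals).
#' @return an object of class `readings_panel`: a list with fields `sites`,
#'   `timestamps`, `values`, `mask`.
#' @export
readings_panel <- function(values, timestamps, sites = rownames(values),
                           mask = NULL, validate = TRUE,
                           bounds = c(0, PM_MAX)) {
  values <- as.matrix(values)
  if (is.null(sites)) stopf("readings_panel: site ids required (rownames or `sites`)")
  sites <- as.character(sites)
  rownames(values) <- sites
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  dimnames(mask) <- dimnames(values)
  x <- structure(
    list(sites = sites, timestamps = timestamps, values = values, mask = mask),
    class = "readings_panel", bounds = bounds
  )
  if (validate) validate_panel(x)
  x
}

validate_panel <- function(x) {
  stopifnot(inherits(x, "readings_panel"))
  n <- length(x$sites); tt <- length(x$timestamps)
  if (anyDuplicated(x$sites)) stopf("panel: duplicate site ids")
  if (!all(dim(x$values) == c(n, tt)) || !all(dim(x$mask) == c(n, tt))) {
    stopf("panel: values/mask must be %d x %d", n, tt)
  }
  if (tt > 1) {
    dt <- diff(as.numeric(x$timestamps))
    if (any(dt != 3600)) stopf("panel: timestamps must be strictly hourly")
  }
  obs <- x$values[x$mask]
  if (length(obs)) {
    if (any(!is.finite(obs))) stopf("panel: non-finite observed value")
    b <- attr(x, "bounds")
    if (!is.null(b) && (any(obs < b[1]) || any(obs > b[2]))) {
      stopf("panel: observed values outside [%g, %g] ug/m3", b[1], b[2])
    }
  }
  invisible(x)
}

#' @export
print.readings_panel <- function(x, ...) {
  n <- length(x$sites); tt <- length(x$timestamps)
  avail <- if (n * tt > 0) mean(x$mask) else NA_real_
  cat(sprintf("<readings_panel> %d sites x %d hours", n, tt))
  if (tt > 0) {
    cat(sprintf("  [%s .. %s]",
                format(x$timestamps[1], "%Y-%m-%d %H:%M %Z"),
                format(x$timestamps[tt], "%Y-%m-%d %H:%M %Z")))
  }
  cat("\n")
  if (!is.na(avail)) {
    cat(sprintf("  observed: %.1f%%  mean: %.1f ug/m3\n", 100 * avail,
                mean(x$values[x$mask])))
  }
  invisible(x)
}

#' @export
dim.readings_panel <- function(x) c(length(x$sites), length(x$timestamps))

#' Subset a panel by sites and/or time columns
#'
#' @param panel a `readings_panel`.
#' @param sites character site ids or integer row indices (order preserved).
#' @param time_idx integer column indices (must stay contiguous so the hourly
#'   grid remains valid).
#' @return a `readings_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, time_idx = NULL) {
  i <- seq_along(panel$sites)
  if (!is.null(sites)) {
    i <- if (is.character(sites)) match(sites, panel$sites) else as.integer(sites)
    if (anyNA(i)) stopf("subset_panel: unknown site id(s): %s",
                        paste(setdiff(sites, panel$sites), collapse = ", "))
  }
  j <- if (is.null(time_idx)) seq_along(panel$timestamps) else as.integer(time_idx)
  readings_panel(panel$values[i, j, drop = FALSE], panel$timestamps[j],
                 sites = panel$sites[i],
                 mask = panel$mask[i, j, drop = FALSE],
                 bounds = attr(panel, "bounds"))
}

# Floor to the start of the LOCAL hour (zones at fractional UTC offsets,
# e.g. +05:30, have hour boundaries off the whole UTC hour).
floor_hour <- function(t) {
  tz <- attr(t, "tzone") %||% ""
  lt <- as.POSIXlt(t, tz = tz)
  lt$min <- 0L; lt$sec <- 0
  as.POSIXct(lt)
}

hour_grid <- function(from, to, tz) {
  if (from > to) stopf("hour_grid: empty range")
  seq(from, to, by = 3600)
}

parse_iso8601 <- function(x, tz) {
  x <- trimws(as.character(x))
  x2 <- sub("T", " ", x, fixed = TRUE)
  # strip a trailing Z or +hh:mm colon so %z can parse it
  x2 <- sub("Z$", " +0000", x2)
  x2 <- sub("([+-][0-9]{2}):([0-9]{2})$", " \\1\\2", x2)
  has_off <- grepl("[+-][0-9]{4}$", x2)
  out <- rep(as.POSIXct(NA), length(x))
  if (any(has_off)) {
    out[has_off] <- as.POSIXct(x2[has_off], format = "%Y-%m-%d %H:%M:%S %z", tz = tz)
  }
  if (any(!has_off)) {
    # offset-free timestamps are taken in the panel's declared timezone
    out[!has_off] <- as.POSIXct(x2[!has_off], tz = tz,
                                tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  }
  if (anyNA(out)) {
    stopf("unparseable timestamp(s), e.g. %s", x[which(is.na(out))[1]])
  }
  attr(out, "tzone") <- tz
  out
}

#' Load a readings + sites dataset from CSV
#'
#' Reads long-format hourly (or sub-hourly) PM2.5 records and a site table,
#' aligns them on a common hourly grid spanning the min..max record hour, and
#' averages sub-hourly records within each hour. Hours with no record are
#' unobserved. Every sensor appearing in the readings must be declared in the
#' site table; negative PM values and exact-duplicate records with conflicting
#' values are rejected.
#'
#' @param readings_path CSV with header `sensor_id,timestamp,pm25`
#'   (ISO-8601 timestamps, offset optional).
#' @param sites_path CSV with header `sensor_id,latitude,longitude,tier`,
#'   tier in `low_cost`/`reference`.
#' @param tz timezone governing the hourly grid and diurnal slot logic.
#'   Defaults to Indian Standard Time, the network the defaults emulate.
#' @return list with `panel` (a [readings_panel], rows in site-table order)
#'   and `sites` (data.frame `site_id`, `latitude`, `longitude`, `tier`).
#' @export
load_dataset <- function(readings_path, sites_path, tz = "Asia/Kolkata") {
  sites <- utils::read.csv(sites_path, stringsAsFactors = FALSE)
  need <- c("sensor_id", "latitude", "longitude", "tier")
  if (!all(need %in% names(sites))) {
    stopf("sites file must have columns %s", paste(need, collapse = ", "))
  }
  sites$sensor_id <- as.character(sites$sensor_id)
  if (anyDuplicated(sites$sensor_id)) stopf("duplicate sensor_id in sites file")
  bad_tier <- setdiff(unique(sites$tier), c("low_cost", "reference"))
  if (length(bad_tier)) stopf("unknown tier value(s): %s", paste(bad_tier, collapse = ", "))

  rd <- utils::read.csv(readings_path, stringsAsFactors = FALSE)
  need <- c("sensor_id", "timestamp", "pm25")
  if (!all(need %in% names(rd))) {
    stopf("readings file must have columns %s", paste(need, collapse = ", "))
  }
  rd$sensor_id <- as.character(rd$sensor_id)

  unknown <- setdiff(unique(rd$sensor_id), sites$sensor_id)
  if (length(unknown)) {
    stopf("readings mention sensor(s) absent from sites table: %s",
          paste(unknown, collapse = ", "))
  }

  site_ids <- sites$sensor_id
  out_sites <- data.frame(site_id = site_ids, latitude = sites$latitude,
                          longitude = sites$longitude, tier = sites$tier,
                          stringsAsFactors = FALSE)

  if (nrow(rd) == 0) {
    vals <- matrix(NA_real_, length(site_ids), 0, dimnames = list(site_ids, NULL))
    ts0 <- as.POSIXct(character(), tz = tz)
    return(list(panel = readings_panel(vals, ts0, sites = site_ids), sites = out_sites))
  }

  if (any(!is.finite(rd$pm25))) stopf("non-finite PM value in readings")
  if (any(rd$pm25 < 0)) {
    k <- which(rd$pm25 < 0)[1]
    stopf("negative PM value for sensor %s at %s", rd$sensor_id[k], rd$timestamp[k])
  }

  ts <- parse_iso8601(rd$timestamp, tz)
  key <- paste(rd$sensor_id, format(ts, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  dup <- duplicated(key)
  if (any(dup)) {
    for (k in unique(key[dup])) {
      v <- rd$pm25[key == k]
      if (max(v) - min(v) > 1e-9) {
        stopf("conflicting duplicate records for (sensor, instant) %s", k)
      }
    }
    rd <- rd[!dup, ]; ts <- ts[!dup]
  }

  hr <- floor_hour(ts)
  grid <- hour_grid(min(hr), max(hr), tz)
  jj <- as.integer(round((as.numeric(hr) - as.numeric(grid[1])) / 3600)) + 1L
  ii <- match(rd$sensor_id, site_ids)

  cell <- (jj - 1L) * length(site_ids) + ii
  sums <- rowsum(rd$pm25, cell)
  cnts <- rowsum(rep(1, length(cell)), cell)
  vals <- matrix(NA_real_, length(site_ids), length(grid),
                 dimnames = list(site_ids, NULL))
  vals[as.integer(rownames(sums))] <- sums / cnts

  list(panel = readings_panel(vals, grid, sites = site_ids), sites = out_sites)
}

#' Write a panel back to long-format CSV
#'
#' Emits only observed cells, in the same `sensor_id,timestamp,pm25` dialect
#' that [load_dataset()] reads, with fixed numeric formatting so that a
#' write/load/write round trip is byte-stable.
#'
#' @param panel a [readings_panel].
#' @param path output CSV path.
#' @export
write_panel <- function(panel, path) {
  idx <- which(panel$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(
    sensor_id = panel$sites[idx[, 1]],
    timestamp = format(panel$timestamps[idx[, 2]], "%Y-%m-%dT%H:%M:%S%z"),
    pm25 = sprintf("%.12g", panel$values[idx]),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
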
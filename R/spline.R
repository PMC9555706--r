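#' Piecewise-cubic diurnal baseline model
#'
#' Fits, per sensor (or for the network-average series), one cubic
#' polynomial per 8-hour slot of the day -- slot 1 midnight-8am, slot 2
#' 8am-4pm, slot 3 4pm-midnight -- by ordinary least squares against all
#' observed values pooled across days. Within-slot time is re-zeroed per
#' slot (t in \[0, 8)), and no continuity is imposed between slots: the
#' three cubics are fit independently, so the composite "average day" curve
#' may jump at slot boundaries. The fitted quadruple per (site, slot) is
#' (alpha, beta, kappa, nu) for `alpha t^3 + beta t^2 + kappa t + nu`.
#'
#' @param panel a [readings_panel] (raw PM or residuals).
#' @param scope `"per_site"` for one model per sensor, `"average"` for a
#'   single model fit to the per-hour cross-site mean series and applied to
#'   every site.
#' @param fallback_to_average if `TRUE`, a (site, slot) with too few
#'   distinct within-slot hours (< 4; cubic identifiability) falls back to
#'   the average-scope coefficients instead of erroring.
#' @param tz timezone for the hour-of-day; defaults to the panel's.
#' @return a `spline_model`: list with `scope`, `sites`, 3-d coefficient
#'   array `coef` (site x slot x alpha/beta/kappa/nu), and `tz`.
#' @export
fit_spline <- function(panel, scope = c("per_site", "average"),
                       fallback_to_average = FALSE, tz = NULL) {
  scope <- match.arg(scope)
  tz <- tz %||% attr(panel$timestamps, "tzone") %||% ""
  hod <- hour_of_day(panel$timestamps, tz)
  slot <- hod %/% 8L + 1L
  tins <- hod - 8 * (slot - 1L)  # within-slot hour, 0..7

  fit_one_series <- function(y, obs, label) {
    coefs <- matrix(NA_real_, 3, 4,
                    dimnames = list(NULL, c("alpha", "beta", "kappa", "nu")))
    for (p in 1:3) {
      sel <- obs & slot == p
      if (length(unique(tins[sel])) < 4) {
        return(structure(coefs, failed = sprintf("%s/slot %d", label, p)))
      }
      t1 <- tins[sel]
      X <- cbind(t1^3, t1^2, t1, 1)
      coefs[p, ] <- stats::lm.fit(X, y[sel])$coefficients
    }
    coefs
  }

  if (scope == "average") {
    n_obs <- colSums(panel$mask)
    vals <- panel$values
    vals[!panel$mask] <- 0
    ybar <- ifelse(n_obs > 0, colSums(vals) / pmax(n_obs, 1), NA_real_)
    cf <- fit_one_series(ybar, n_obs > 0, "network average")
    if (!is.null(attr(cf, "failed"))) {
      stopf("fit_spline: too few distinct within-slot hours for %s", attr(cf, "failed"))
    }
    coef <- array(cf, dim = c(1, 3, 4),
                  dimnames = list("average", NULL, colnames(cf)))
    model <- list(scope = "average", sites = NULL, coef = coef, tz = tz)
  } else {
    avg <- NULL
    n <- length(panel$sites)
    coef <- array(NA_real_, dim = c(n, 3, 4),
                  dimnames = list(panel$sites, NULL,
                                  c("alpha", "beta", "kappa", "nu")))
    failed <- character()
    for (i in seq_len(n)) {
      cf <- fit_one_series(panel$values[i, ], panel$mask[i, ], panel$sites[i])
      if (!is.null(attr(cf, "failed"))) {
        if (fallback_to_average) {
          if (is.null(avg)) avg <- fit_spline(panel, "average", tz = tz)
          cf <- avg$coef[1, , ]
        } else {
          failed <- c(failed, attr(cf, "failed"))
          next
        }
      }
      coef[i, , ] <- cf
    }
    if (length(failed)) {
      stopf("fit_spline: too few distinct within-slot hours for %s",
            paste(failed, collapse = "; "))
    }
    model <- list(scope = "per_site", sites = panel$sites, coef = coef, tz = tz)
  }
  class(model) <- "spline_model"
  model
}

#' @export
print.spline_model <- function(x, ...) {
  cat(sprintf("<spline_model> scope=%s, %d site(s) x 3 slots\n", x$scope,
              dim(x$coef)[1]))
  invisible(x)
}

spline_site_row <- function(model, site_id) {
  if (model$scope == "average") return(1L)
  i <- match(site_id, model$sites)
  if (is.na(i)) stopf("eval_spline: site %s not covered by per-site model", site_id)
  i
}

#' Evaluate a diurnal baseline at given instants
#'
#' Each timestamp is routed to exactly one slot cubic (slots are half-open,
#' so a boundary hour like 08:00 uses the new slot's cubic) and evaluated at
#' its within-slot time.
#'
#' @param model a `spline_model` from [fit_spline()].
#' @param site_id site to evaluate (ignored under average scope).
#' @param timestamps `POSIXct` vector (or numeric hours of day).
#' @return baseline values (ug/m3), same length as `timestamps`.
#' @export
eval_spline <- function(model, site_id, timestamps) {
  i <- spline_site_row(model, site_id)
  hod <- hour_of_day(timestamps, model$tz)
  slot <- hod %/% 8L + 1L
  t1 <- hod - 8 * (slot - 1L)
  cf <- model$coef[i, slot, , drop = FALSE]
  dim(cf) <- c(length(slot), 4)
  cf[, 1] * t1^3 + cf[, 2] * t1^2 + cf[, 3] * t1 + cf[, 4]
}

# Baseline matrix for all panel sites (sites x hours).
eval_spline_matrix <- function(model, sites, timestamps) {
  out <- matrix(NA_real_, length(sites), length(timestamps),
                dimnames = list(sites, NULL))
  if (model$scope == "average") {
    row <- eval_spline(model, NULL, timestamps)
    out[] <- rep(row, each = length(sites))
  } else {
    for (i in seq_along(sites)) out[i, ] <- eval_spline(model, sites[i], timestamps)
  }
  out
}

#' Residuals of a panel over its diurnal baseline
#'
#' Subtracts the slot-cubic baseline at every observed cell; the mask is
#' unchanged, and adding the baseline back reconstructs the panel exactly.
#'
#' @param panel a [readings_panel].
#' @param model a `spline_model` covering the panel's sites.
#' @return an unbounded [readings_panel] of residuals.
#' @export
spline_residuals <- function(panel, model) {
  base <- eval_spline_matrix(model, panel$sites, panel$timestamps)
  vals <- panel$values - base
  vals[!panel$mask] <- NA_real_
  readings_panel(vals, panel$timestamps, sites = panel$sites,
                 mask = panel$mask, bounds = NULL)
}

#' Serialize / restore a spline model as JSON
#'
#' @param model a `spline_model`.
#' @param path JSON file path.
#' @return `spline_from_json` returns a `spline_model`.
#' @export
spline_to_json <- function(model, path) {
  ids <- if (model$scope == "average") "average" else model$sites
  obj <- list(
    scope = model$scope, tz = model$tz,
    coefficients = lapply(seq_along(ids), function(i) {
      list(site_id = ids[i],
           slots = lapply(1:3, function(p) as.list(stats::setNames(
             model$coef[i, p, ], c("alpha", "beta", "kappa", "nu")))))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname spline_to_json
#' @export
spline_from_json <- function(path) {
  obj <- jsonlite::read_json(path)
  ids <- vapply(obj$coefficients, function(x) x$site_id, "")
  coef <- array(NA_real_, dim = c(length(ids), 3, 4),
                dimnames = list(ids, NULL, c("alpha", "beta", "kappa", "nu")))
  for (i in seq_along(ids)) {
    for (p in 1:3) coef[i, p, ] <- as.numeric(unlist(obj$coefficients[[i]]$slots[[p]]))
  }
  model <- list(scope = obj$scope,
                sites = if (obj$scope == "average") NULL else ids,
                coef = coef, tz = obj$tz)
  class(model) <- "spline_model"
  model
}
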
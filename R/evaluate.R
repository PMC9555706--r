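# Evaluation: masked error metrics, per-sensor reports, hazard-exceedance
# detection, network-size ablation, and co-location diagnostics.

eval_cells <- function(predictions, truth, mask = NULL) {
  pv <- if (inherits(predictions, "readings_panel")) predictions$values else as.matrix(predictions)
  pm <- if (inherits(predictions, "readings_panel")) predictions$mask else is.finite(pv)
  tv <- if (inherits(truth, "readings_panel")) truth$values else as.matrix(truth)
  tm <- if (inherits(truth, "readings_panel")) truth$mask else is.finite(tv)
  if (!all(dim(pv) == dim(tv))) stopf("predictions/truth shapes differ")
  m <- pm & tm
  if (!is.null(mask)) m <- m & mask
  list(pred = pv, truth = tv, mask = m)
}

#' Mean absolute percentage error (%)
#'
#' `100 * mean(|yhat - y| / max(y, eps))` over cells that are observed in
#' the truth AND valid in the predictions. The denominator floor `eps`
#' (1 ug/m3) guards against division by near-zero readings.
#'
#' @param predictions,truth [readings_panel]s or matrices of equal shape.
#' @param mask optional additional logical matrix restricting evaluation.
#' @param eps denominator floor (ug/m3).
#' @return MAPE in percent.
#' @export
mape <- function(predictions, truth, mask = NULL, eps = 1.0) {
  e <- eval_cells(predictions, truth, mask)
  if (!any(e$mask)) stopf("mape: no cells to evaluate")
  y <- e$truth[e$mask]; yh <- e$pred[e$mask]
  100 * mean(abs(yh - y) / pmax(y, eps))
}

#' Root mean squared error (ug/m3)
#'
#' Conventional `sqrt(mean((yhat - y)^2))` over evaluated cells.
#'
#' @inheritParams mape
#' @return RMSE in ug/m3.
#' @export
rmse <- function(predictions, truth, mask = NULL) {
  e <- eval_cells(predictions, truth, mask)
  if (!any(e$mask)) stopf("rmse: no cells to evaluate")
  sqrt(mean((e$pred[e$mask] - e$truth[e$mask])^2))
}

#' Per-sensor error report
#'
#' Computes RMSE and MAPE per site, network aggregates (mean, median, best,
#' worst), tier-stratified aggregates when a site table with `tier` is
#' given, and the cumulative distribution of per-site MAPE.
#'
#' @param predictions,truth [readings_panel]s of equal shape.
#' @param sites optional data.frame with `site_id` and `tier`.
#' @param eps MAPE denominator floor.
#' @return a `metrics_report`: list with `per_site` (data.frame),
#'   `aggregate`, `tiers`, `mape_cdf`, `n_cells`.
#' @export
per_sensor_report <- function(predictions, truth, sites = NULL, eps = 1.0) {
  e <- eval_cells(predictions, truth)
  ids <- if (inherits(truth, "readings_panel")) truth$sites else rownames(e$truth)
  n_cells <- rowSums(e$mask)
  keep <- n_cells > 0
  if (!any(keep)) stopf("per_sensor_report: no cells to evaluate")
  if (any(!keep)) {
    warnf("per_sensor_report: excluding site(s) with no evaluated cells: %s",
          paste(ids[!keep], collapse = ", "))
  }
  per <- data.frame(site_id = ids[keep],
                    n_cells = n_cells[keep],
                    rmse = NA_real_, mape = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(per))) {
    i <- which(ids == per$site_id[k])
    m <- e$mask[i, ]
    y <- e$truth[i, m]; yh <- e$pred[i, m]
    per$rmse[k] <- sqrt(mean((yh - y)^2))
    per$mape[k] <- 100 * mean(abs(yh - y) / pmax(y, eps))
  }
  agg <- function(x) c(mean = mean(x), median = stats::median(x),
                       best = min(x), worst = max(x))
  tiers <- NULL
  if (!is.null(sites) && "tier" %in% names(sites)) {
    per$tier <- sites$tier[match(per$site_id, sites$site_id)]
    tiers <- lapply(split(per, per$tier), function(d) {
      list(rmse = agg(d$rmse), mape = agg(d$mape), n_sites = nrow(d))
    })
    tiers$combined <- list(rmse = agg(per$rmse), mape = agg(per$mape),
                           n_sites = nrow(per))
  }
  srt <- sort(per$mape)
  cdf <- data.frame(mape = srt, cum_fraction = seq_along(srt) / length(srt))
  structure(list(per_site = per,
                 aggregate = list(rmse = agg(per$rmse), mape = agg(per$mape)),
                 tiers = tiers, mape_cdf = cdf, n_cells = sum(n_cells[keep])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<metrics_report> %d sites, %d cells\n", nrow(x$per_site), x$n_cells))
  cat(sprintf("  RMSE (ug/m3): mean %.2f  median %.2f  best %.2f  worst %.2f\n",
              a$rmse["mean"], a$rmse["median"], a$rmse["best"], a$rmse["worst"]))
  cat(sprintf("  MAPE (%%):     mean %.2f  median %.2f  best %.2f  worst %.2f\n",
              a$mape["mean"], a$mape["median"], a$mape["best"], a$mape["worst"]))
  invisible(x)
}

#' Hazard-exceedance detection quality
#'
#' Classifies site-days as exceeding a daily PM2.5 standard by the
#' daily-mean truth vs the daily-mean prediction, and reports pooled
#' precision and recall. Default threshold is the Indian daily standard of
#' 60 ug/m3. Only days with at least `min_hours` of the 24 hours evaluated
#' (observed truth and valid prediction) enter; daily means are taken over
#' the evaluated hours.
#'
#' @param predictions,truth [readings_panel]s of equal shape.
#' @param threshold daily-mean exceedance threshold (ug/m3).
#' @param min_hours day-completeness rule (default 18 of 24).
#' @param tz timezone defining the day; defaults to the truth panel's.
#' @return list with `precision`, `recall`, `counts` (tp/fp/fn/tn) and the
#'   per-site-day classification table.
#' @export
hazard_detection <- function(predictions, truth, threshold = 60,
                             min_hours = 18, tz = NULL) {
  e <- eval_cells(predictions, truth)
  stamps <- truth$timestamps
  tz <- tz %||% attr(stamps, "tzone") %||% ""
  day <- format(stamps, "%Y-%m-%d", tz = tz)
  ids <- truth$sites
  rows <- list()
  for (i in seq_along(ids)) {
    m <- e$mask[i, ]
    if (!any(m)) next
    for (d in unique(day[m])) {
      sel <- m & day == d
      if (sum(sel) < min_hours) next
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = ids[i], day = d, n_hours = sum(sel),
        truth_mean = mean(e$truth[i, sel]),
        pred_mean = mean(e$pred[i, sel]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    stopf("hazard_detection: no site-day with >= %d evaluated hours", min_hours)
  }
  tab <- do.call(rbind, rows)
  tab$truth_exceeds <- tab$truth_mean > threshold
  tab$pred_exceeds <- tab$pred_mean > threshold
  tp <- sum(tab$truth_exceeds & tab$pred_exceeds)
  fp <- sum(!tab$truth_exceeds & tab$pred_exceeds)
  fn <- sum(tab$truth_exceeds & !tab$pred_exceeds)
  tn <- sum(!tab$truth_exceeds & !tab$pred_exceeds)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
       days = tab)
}

#' Temporal correlation of low-cost sites with their nearest reference site
#'
#' For each low-cost site, finds the nearest reference-tier site and
#' computes the Pearson correlation of the two series over co-observed
#' hours. Pairs with fewer than `min_hours` co-observed hours are flagged
#' and excluded from the network mean.
#'
#' @param panel a [readings_panel].
#' @param sites data.frame with `site_id`, `tier` and planar coordinates
#'   (`x_km`, `y_km`) or `latitude`/`longitude`.
#' @param min_hours minimum co-observed hours per pair.
#' @return list with `table` (one row per low-cost site: nearest reference,
#'   distance, n co-observed hours, r, flagged) and `mean_r`.
#' @export
colocated_correlation <- function(panel, sites, min_hours = 30) {
  geom <- build_geometry(sites)
  d <- geom$dist
  lc <- sites$site_id[sites$tier == "low_cost"]
  rf <- sites$site_id[sites$tier == "reference"]
  if (!length(rf)) stopf("colocated_correlation: no reference sites")
  if (!length(lc)) stopf("colocated_correlation: no low-cost sites")
  rows <- lapply(lc, function(s) {
    dd <- d[s, rf]
    nearest <- rf[which.min(dd)]
    i <- match(s, panel$sites); j <- match(nearest, panel$sites)
    co <- panel$mask[i, ] & panel$mask[j, ]
    r <- if (sum(co) >= 2) {
      stats::cor(panel$values[i, co], panel$values[j, co])
    } else NA_real_
    data.frame(site_id = s, nearest_reference = nearest,
               distance_km = min(dd), n_hours = sum(co), r = r,
               flagged = sum(co) < min_hours, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$flagged & is.finite(tab$r)
  list(table = tab, mean_r = if (any(ok)) mean(tab$r[ok]) else NA_real_)
}

#' Prediction error versus network size
#'
#' Re-fits a pipeline on seeded random subnetworks of increasing size and
#' evaluates it at a fixed set of held-out target locations, quantifying how
#' much spatial context the predictor needs. `build_fn` is called as
#' `build_fn(observed_subpanel, sites_subset, seed)` and must return a
#' prediction panel covering the final `1 - split` fraction of the panel's
#' columns (the test span) for at least the target sites. A companion
#' training-length ablation truncates the training span instead.
#'
#' @param build_fn pipeline builder (see [pipeline_builder()]).
#' @param observed observed [readings_panel] over the full span.
#' @param truth reference panel to score against (synthetic ground truth, or
#'   the observed panel itself).
#' @param sites site table covering the panel.
#' @param sizes total network sizes to try (each >= `n_targets`; sizes < 2
#'   are skipped with a note since message passing needs a neighbor).
#' @param repeats independent subnetwork draws per size.
#' @param n_targets number of fixed target sites (drawn once from `seed`).
#' @param split training fraction passed through to the builder's contract.
#' @param seed master seed for target choice, subnetwork draws, and builder.
#' @return data.frame with size, repeat, and test MAPE at the targets, plus
#'   per-size mean/sd.
#' @export
ablate_network_size <- function(build_fn, observed, truth, sites,
                                sizes, repeats = 1, n_targets = 2,
                                split = 0.75, seed = 1) {
  ids <- sites$site_id
  n <- length(ids)
  stopifnot(all(sizes <= n), repeats >= 1, n_targets >= 1)
  targets <- with_seed(substream_seed(seed, 11L), sample(ids, n_targets))
  pool <- setdiff(ids, targets)
  tt <- length(observed$timestamps)
  n_train <- round(split * tt)
  test_idx <- (n_train + 1L):tt
  truth_test <- subset_panel(truth, time_idx = test_idx)

  out <- list()
  for (s in sizes) {
    if (s < 2) {
      message(sprintf("ablate_network_size: skipping size %d (message passing needs a neighbor)", s))
      next
    }
    for (r in seq_len(repeats)) {
      extra <- if (s > n_targets) {
        with_seed(substream_seed(seed, 12L, s, r), sample(pool, s - n_targets))
      } else character()
      sub_ids <- ids[ids %in% c(targets, extra)]  # preserve panel order
      sub_obs <- subset_panel(observed, sites = sub_ids)
      sub_sites <- sites[match(sub_ids, sites$site_id), , drop = FALSE]
      pred <- build_fn(sub_obs, sub_sites, substream_seed(seed, 13L, s, r))
      pred_t <- subset_panel(pred, sites = targets)
      truth_t <- subset_panel(truth_test, sites = targets)
      out[[length(out) + 1L]] <- data.frame(
        size = s, rep = r,
        mape = mape(pred_t, truth_t), rmse = rmse(pred_t, truth_t))
    }
  }
  tab <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(split(tab, tab$size), function(d) {
    data.frame(size = d$size[1], mean_mape = mean(d$mape),
               sd_mape = stats::sd(d$mape), n = nrow(d))
  }))
  list(runs = tab, summary = summ[order(summ$size), ], targets = targets)
}
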
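test_that("mape matches hand arithmetic and the identity case", {
  truth <- matrix(c(100, 200), 1, 2, dimnames = list("a", NULL))
  pred <- matrix(c(110, 180), 1, 2)
  expect_equal(mape(pred, truth), 10.0)
  expect_equal(mape(truth, truth), 0)
  expect_equal(rmse(matrix(c(103, 196), 1, 2), truth), sqrt((9 + 16) / 2))
  expect_equal(rmse(truth, truth), 0)
  expect_error(mape(pred, truth, mask = matrix(FALSE, 1, 2)), "no cells")
})

test_that("vectorized metrics equal the double-loop oracles on random panels", {
  for (seed in 1:50) {
    pp <- random_panel_pair(seed)
    expect_lt(abs(mape(pp$pred, pp$truth) -
                    loop_mape(pp$pred$values, pp$truth$values, pp$both)), 1e-12)
    expect_lt(abs(rmse(pp$pred, pp$truth) -
                    loop_rmse(pp$pred$values, pp$truth$values, pp$both)), 1e-12)
  }
})

test_that("cells invalid in either panel never enter the metrics", {
  pp <- random_panel_pair(1)
  m0 <- mape(pp$pred, pp$truth); r0 <- rmse(pp$pred, pp$truth)
  poisoned <- pp$pred
  poisoned$values[!poisoned$mask] <- 9e5   # sentinel garbage
  poisoned_truth <- pp$truth
  poisoned_truth$values[!poisoned_truth$mask] <- -9e5
  expect_identical(mape(poisoned, poisoned_truth), m0)
  expect_identical(rmse(poisoned, poisoned_truth), r0)
})

test_that("per-sensor report aggregates and CDF behave", {
  stamps <- hourly_stamps(10)
  truth <- readings_panel(matrix(100, 2, 10, dimnames = list(c("a", "b"), NULL)),
                          stamps)
  pred <- readings_panel(rbind(a = rep(105, 10), b = rep(115, 10)), stamps,
                         bounds = NULL)
  rep1 <- per_sensor_report(pred, truth,
                            sites = data.frame(site_id = c("a", "b"),
                                               tier = c("reference", "low_cost")))
  expect_equal(rep1$aggregate$mape[["median"]], 10)
  expect_equal(rep1$aggregate$mape[["best"]], 5)
  expect_equal(rep1$aggregate$mape[["worst"]], 15)
  expect_equal(rep1$tiers$reference$mape[["mean"]], 5)
  cdf <- rep1$mape_cdf
  expect_true(all(diff(cdf$cum_fraction) >= 0))
  expect_equal(cdf$cum_fraction[nrow(cdf)], 1)

  # single site: aggregates collapse to that site's metrics
  rep2 <- per_sensor_report(subset_panel(pred, sites = "a"),
                            subset_panel(truth, sites = "a"))
  expect_equal(rep2$aggregate$mape[["mean"]], rep2$per_site$mape[1])

  # a site with no evaluated cells is excluded with a warning
  truth2 <- truth; truth2$mask[2, ] <- FALSE; truth2$values[2, ] <- NA
  expect_warning(rep3 <- per_sensor_report(pred, truth2), "b")
  expect_equal(rep3$per_site$site_id, "a")
})

test_that("hazard detection matches hand enumeration", {
  stamps <- hourly_stamps(72)
  truth_daily <- c(70, 50, 65)
  pred_daily <- c(72, 55, 58)
  truth <- readings_panel(matrix(rep(truth_daily, each = 24), 1, 72,
                                 dimnames = list("a", NULL)), stamps)
  pred <- readings_panel(matrix(rep(pred_daily, each = 24), 1, 72,
                                dimnames = list("a", NULL)), stamps,
                         bounds = NULL)
  hz <- hazard_detection(pred, truth)   # default threshold 60 (daily standard)
  expect_equal(unname(hz$counts), c(1, 0, 1, 1))
  expect_equal(hz$precision, 1.0)
  expect_equal(hz$recall, 0.5)

  hz2 <- hazard_detection(truth, truth)
  expect_equal(hz2$precision, 1)
  expect_equal(hz2$recall, 1)
})

test_that("pooled hazard counts equal the sum of per-site confusion matrices", {
  city <- toy_city()
  truth <- subset_panel(city$truth, time_idx = 1:480)
  set.seed(5)
  noisy <- truth$values + matrix(rnorm(length(truth$values), 0, 20),
                                 nrow(truth$values))
  pred <- readings_panel(noisy, truth$timestamps, sites = truth$sites,
                         bounds = NULL)
  pooled <- hazard_detection(pred, truth, threshold = 130)
  per_site <- Reduce(`+`, lapply(truth$sites, function(s) {
    hazard_detection(subset_panel(pred, sites = s),
                     subset_panel(truth, sites = s), threshold = 130)$counts
  }))
  expect_equal(pooled$counts, per_site)
})

test_that("day completeness rule excludes fragmentary days", {
  stamps <- hourly_stamps(48)
  truth <- readings_panel(matrix(100, 1, 48, dimnames = list("a", NULL)), stamps)
  pred_vals <- matrix(100, 1, 48)
  valid <- matrix(FALSE, 1, 48)
  valid[1, 1:10] <- TRUE   # only 10 evaluated hours on day 1
  pred <- readings_panel(pred_vals, stamps, sites = "a", mask = valid,
                         bounds = NULL)
  expect_error(hazard_detection(pred, truth), "18")
})

test_that("colocated correlation finds nearest reference pairs", {
  stamps <- hourly_stamps(1000)
  sites <- data.frame(site_id = c("ref1", "ref2", "lc1", "lc2"),
                      x_km = c(0, 20, 0.5, 19), y_km = 0,
                      tier = c("reference", "reference", "low_cost", "low_cost"))
  set.seed(6)
  base <- 130 + as.numeric(stats::filter(rnorm(1000, 0, 10), 0.9,
                                         method = "recursive"))
  vals <- rbind(ref1 = base, ref2 = rev(base),
                lc1 = base,                      # exact copy of ref1
                lc2 = runif(1000, 50, 210))      # independent noise
  pan <- readings_panel(pmin(pmax(vals, 0), 1000), stamps)
  cc <- colocated_correlation(pan, sites)
  t1 <- cc$table[cc$table$site_id == "lc1", ]
  expect_equal(t1$nearest_reference, "ref1")
  expect_equal(t1$r, 1, tolerance = 1e-9)
  t2 <- cc$table[cc$table$site_id == "lc2", ]
  expect_lt(abs(t2$r), 0.1)

  no_ref <- sites[sites$tier == "low_cost", ]
  expect_error(colocated_correlation(pan, no_ref), "reference")
})

test_that("co-moving city sites correlate more when closer", {
  city <- toy_city()
  cc <- colocated_correlation(city$observed, city$sites)
  ok <- !cc$table$flagged
  expect_true(any(ok))
  expect_gt(cc$mean_r, 0)
  # nearest pairs beat the farthest pairing for the same sites
  far <- vapply(cc$table$site_id[ok], function(s) {
    rf <- city$sites$site_id[city$sites$tier == "reference"]
    d <- build_geometry(city$sites)$dist[s, rf]
    fr <- rf[which.max(d)]
    i <- match(s, city$observed$sites); j <- match(fr, city$observed$sites)
    co <- city$observed$mask[i, ] & city$observed$mask[j, ]
    cor(city$observed$values[i, co], city$observed$values[j, co])
  }, numeric(1))
  expect_gt(mean(cc$table$r[ok]), mean(far))
})
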
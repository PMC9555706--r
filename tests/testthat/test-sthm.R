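test_that("single-site log-likelihood matches the scalar Kalman oracle", {
  set.seed(21)
  phi <- 0.7; q <- 9; r <- 4; n <- 400
  z <- numeric(n); z[1] <- rnorm(1, 0, sqrt(q / (1 - phi^2)))
  for (t in 2:n) z[t] <- phi * z[t - 1] + rnorm(1, 0, sqrt(q))
  y <- pmax(60 + z + rnorm(n, 0, sqrt(r)), 0)
  y[sample(n, 80)] <- NA
  pan <- readings_panel(matrix(y, 1, n, dimnames = list("solo", NULL)),
                        hourly_stamps(n))
  fit <- make_sthm_fit("solo", phi, q, r, 60)
  ll_oracle <- scalar_kalman_loglik(pan$values[1, ] - 60, phi, q, r,
                                    q / (1 - phi^2))
  expect_lt(abs(sthm_loglik(fit, pan) - ll_oracle), 1e-8)
})

test_that("EM log-likelihood trace is non-decreasing", {
  city <- toy_city()
  pan <- subset_panel(city$observed, time_idx = 1:400)
  fit <- fit_sthm(pan, sites = city$sites, config = list(max_iter = 8))
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) > -1e-8 * (abs(tr[-length(tr)]) + 1)))
})

test_that("a constant noiseless panel degenerates gracefully", {
  pan <- readings_panel(matrix(77, 3, 120,
                               dimnames = list(c("a", "b", "c"), NULL)),
                        hourly_stamps(120))
  s <- data.frame(site_id = c("a", "b", "c"), x_km = c(0, 2, 5),
                  y_km = c(0, 1, 2), tier = "reference")
  fit <- suppressWarnings(fit_sthm(pan, sites = s,
                                   config = list(max_iter = 10)))
  mu <- fit$a_site + 0  # hour offsets are centred
  expect_lt(max(abs(mu - 77)), 0.5)
  expect_lt(fit$sigma_eps[["reference"]], 0.5)
  expect_lt(fit$sigma_sp, 1)
})

test_that("fit_sthm validates its inputs and drops empty sites", {
  stamps <- hourly_stamps(100)
  vals <- matrix(NA_real_, 2, 100, dimnames = list(c("a", "b"), NULL))
  pan <- readings_panel(vals, stamps)
  s <- data.frame(site_id = c("a", "b"), x_km = 0:1, y_km = 0, tier = "reference")
  expect_error(fit_sthm(pan, sites = s), "missing")

  vals["a", ] <- 80
  pan2 <- readings_panel(vals, stamps)
  expect_warning(fit2 <- fit_sthm(pan2, sites = s, config = list(max_iter = 3)),
                 "dropping")
  expect_equal(fit2$sites, "a")
})

test_that("imputation fills only missing cells and respects bounds", {
  city <- toy_city()
  pan <- subset_panel(city$observed, time_idx = 1:300)
  fit <- fit_sthm(pan, sites = city$sites, config = list(max_iter = 6))
  imp <- sthm_impute(fit, pan)
  expect_true(all(imp$mask))
  expect_identical(imp$values[pan$mask], pan$values[pan$mask])
  expect_true(all(imp$values >= 0 & imp$values <= 1000))
  expect_identical(attr(imp, "imputed"), !pan$mask)

  full <- readings_panel(matrix(80, 2, 60, dimnames = list(c("a", "b"), NULL)),
                         hourly_stamps(60))
  fitc <- make_sthm_fit("a", 0.5, 1, 1, 80)
  fitc$sites <- c("a", "b"); fitc$tier <- c("all", "all")
  fitc$dist <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  fitc$a_site <- c(a = 80, b = 80); fitc$Sigma0 <- diag(2)
  imp2 <- sthm_impute(fitc, full)
  expect_identical(imp2$values, full$values)
})

test_that("a single missing cell is imputed between its neighbors", {
  # near-noiseless AR(1): the smoothed value at the gap must sit in the
  # band spanned by the flanking observations
  set.seed(22)
  n <- 200
  z <- stats::filter(rnorm(n, 0, 2), 0.9, method = "recursive")
  y <- 100 + as.numeric(z)
  pan_vals <- matrix(y, 1, n, dimnames = list("a", NULL))
  pan_vals[1, 100] <- NA
  pan <- readings_panel(pan_vals, hourly_stamps(n))
  fit <- make_sthm_fit("a", 0.9, 4, 0.01, 100)
  imp <- sthm_impute(fit, pan)
  lo <- min(y[99], y[101]) - 3 * 2
  hi <- max(y[99], y[101]) + 3 * 2
  expect_gt(imp$values[1, 100], lo)
  expect_lt(imp$values[1, 100], hi)
})

test_that("one-step forecasts follow the closed-form state recursion", {
  pan <- readings_panel(matrix(c(80, 130, 80, 80), 1, 4,
                               dimnames = list("a", NULL)),
                        hourly_stamps(4))
  # phi = 0: forecast reverts to the fitted mean structure
  fit0 <- make_sthm_fit("a", 0, 9, 1e-6, 80)
  p0 <- predict_sthm(fit0, pan)
  expect_false(p0$mask[1, 1])
  expect_lt(max(abs(p0$values[1, 2:4] - 80)), 1e-6)

  # phi near 1 with negligible noise: forecast ~ mean + phi * (y - mean)
  fit1 <- make_sthm_fit("a", 0.95, 9, 1e-8, 80)
  p1 <- predict_sthm(fit1, pan)
  expect_lt(abs(p1$values[1, 3] - (80 + 0.95 * 50)), 0.5)
})

test_that("state-space forecasts beat persistence on model-simulated data", {
  set.seed(23)
  sites <- toy_sites(5)
  d <- toy_dist(sites)
  n <- 800
  z <- simulate_residual_field(d, n, 0.8, 10, 5, seed = 3)
  y <- pmin(pmax(100 + z + matrix(rnorm(5 * n, 0, 3), 5, n), 0), 1000)
  rownames(y) <- sites$site_id
  pan <- readings_panel(y, hourly_stamps(n))
  fit <- fit_sthm(pan, sites = sites, config = list(max_iter = 10))
  pred <- predict_sthm(fit, pan)
  pers <- persistence_predict(pan)
  truth <- subset_panel(pan, time_idx = 401:800)
  expect_lte(rmse(subset_panel(pred, time_idx = 401:800), truth),
             rmse(subset_panel(pers, time_idx = 401:800), truth))
})
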
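test_that("noiseless per-slot cubics are recovered exactly", {
  fx <- cubic_panel(n_sites = 2, n_days = 10)
  m <- fit_spline(fx$panel, "per_site")
  expect_lt(max(abs(m$coef["s01", , c("alpha", "beta", "kappa")] -
                      fx$coef[, 1:3])), 1e-8)
  expect_lt(max(abs(m$coef["s01", , "nu"] - fx$coef[, 4])), 1e-8)
  # second site differs only by its intercept
  expect_lt(max(abs(m$coef["s02", , "nu"] - (fx$coef[, 4] + 7))), 1e-8)
})

test_that("a constant panel yields the constant in every slot", {
  pan <- readings_panel(matrix(42, 2, 72, dimnames = list(c("a", "b"), NULL)),
                        hourly_stamps(72))
  m <- fit_spline(pan, "per_site")
  expect_lt(max(abs(m$coef[, , c("alpha", "beta", "kappa")])), 1e-10)
  expect_lt(max(abs(m$coef[, , "nu"] - 42)), 1e-10)
})

test_that("noisy cubic recovery: fitted curve is close to the truth", {
  fx <- cubic_panel(n_sites = 1, n_days = 200)
  set.seed(8)
  noisy <- fx$panel$values + matrix(rnorm(length(fx$panel$values), 0, 10),
                                    nrow = 1)
  pan <- readings_panel(noisy, fx$panel$timestamps, bounds = NULL)
  m <- fit_spline(pan, "per_site")
  fitted_curve <- eval_spline(m, "s01", fx$panel$timestamps)
  # OLS sd of the fitted cubic at n = 1600 points/slot keeps curve RMSE
  # well under 2 ug/m3 (noise sd 10 / sqrt(n/p))
  expect_lt(sqrt(mean((fitted_curve - fx$panel$values[1, ])^2)), 2)
})

test_that("evaluation follows the half-open slot convention", {
  cf <- array(0, dim = c(1, 3, 4),
              dimnames = list("x", NULL, c("alpha", "beta", "kappa", "nu")))
  cf[1, , "nu"] <- c(10, 20, 30)
  cf[1, 1, "kappa"] <- 1
  m <- structure(list(scope = "per_site", sites = "x", coef = cf, tz = "UTC"),
                 class = "spline_model")
  # linear cubic: value 3 at the 4th hour of slot 1 (within-slot t = 3)
  expect_equal(eval_spline(m, "x", 3L), 13)
  # boundary hours use the NEW slot's cubic
  expect_equal(eval_spline(m, "x", 8L), 20)
  expect_equal(eval_spline(m, "x", 16L), 30)
  expect_equal(eval_spline(m, "x", 0L), 10)
})

test_that("residuals reconstruct the panel and are centred per site-slot", {
  fx <- cubic_panel(n_sites = 2, n_days = 15)
  set.seed(9)
  vals <- fx$panel$values + matrix(rnorm(length(fx$panel$values), 0, 5), 2)
  pan <- readings_panel(vals, fx$panel$timestamps, bounds = NULL)
  m <- fit_spline(pan, "per_site")
  r <- spline_residuals(pan, m)
  base_mat <- do.call(rbind, lapply(pan$sites, function(s)
    eval_spline(m, s, pan$timestamps)))
  expect_lt(max(abs((r$values + base_mat) - vals)), 1e-12)
  # OLS normal equations include the intercept: per (site, slot) mean ~ 0
  for (i in 1:2) for (p in 1:3) {
    expect_lt(abs(mean(r$values[i, fx$slot == p])), 1e-8)
  }
})

test_that("fitted coefficients are an SSR minimum", {
  fx <- cubic_panel(n_sites = 1, n_days = 30)
  set.seed(10)
  vals <- fx$panel$values + matrix(rnorm(length(fx$panel$values), 0, 8), 1)
  pan <- readings_panel(vals, fx$panel$timestamps, bounds = NULL)
  m <- fit_spline(pan, "per_site")
  ssr <- function(mod) {
    sum(spline_residuals(pan, mod)$values^2)
  }
  base_ssr <- ssr(m)
  for (p in 1:3) for (k in 1:4) for (dd in c(-1e-3, 1e-3)) {
    m2 <- m
    m2$coef[1, p, k] <- m2$coef[1, p, k] + dd
    expect_gte(ssr(m2), base_ssr)
  }
})

test_that("average scope is shared across sites and agrees on identical data", {
  fx <- cubic_panel(n_sites = 1, n_days = 10)
  vals <- rbind(s1 = fx$panel$values[1, ], s2 = fx$panel$values[1, ])
  pan <- readings_panel(vals, fx$panel$timestamps, bounds = NULL)
  avg <- fit_spline(pan, "average")
  per <- fit_spline(pan, "per_site")
  expect_equal(eval_spline(avg, "s1", pan$timestamps),
               eval_spline(avg, "s2", pan$timestamps))
  expect_lt(max(abs(per$coef[1, , ] - avg$coef[1, , ])), 1e-8)
  expect_lt(max(abs(per$coef[2, , ] - avg$coef[1, , ])), 1e-8)
})

test_that("identifiability failures name the site and slot", {
  fx <- cubic_panel(n_sites = 2, n_days = 5)
  pan <- fx$panel
  # leave site s02 with too few distinct within-slot hours in slot 2
  kill <- fx$slot == 2 & !(fx$tin %in% c(0, 1, 2))
  pan$mask[2, kill] <- FALSE
  pan$values[2, kill] <- NA
  expect_error(fit_spline(pan, "per_site"), "s02/slot 2")
  m <- fit_spline(pan, "per_site", fallback_to_average = TRUE)
  expect_true(all(is.finite(m$coef)))
})

test_that("spline models survive a JSON round trip", {
  fx <- cubic_panel(n_sites = 2, n_days = 10)
  m <- fit_spline(fx$panel, "per_site")
  f <- tempfile(fileext = ".json")
  spline_to_json(m, f)
  m2 <- spline_from_json(f)
  expect_equal(m2$coef, m$coef, tolerance = 1e-12)
  expect_equal(m2$scope, m$scope)
})
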
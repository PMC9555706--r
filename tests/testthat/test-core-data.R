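test_that("load_dataset averages sub-hourly records onto the hourly grid", {
  rd <- tempfile(fileext = ".csv"); st <- tempfile(fileext = ".csv")
  writeLines(c("sensor_id,timestamp,pm25",
               "A,2020-01-01T03:10:00+05:30,10",
               "A,2020-01-01T03:40:00+05:30,20",
               "B,2020-01-01T04:00:00+05:30,55"), rd)
  writeLines(c("sensor_id,latitude,longitude,tier",
               "A,28.60,77.20,low_cost",
               "B,28.65,77.25,reference"), st)
  ds <- load_dataset(rd, st)
  expect_equal(dim(ds$panel), c(2L, 2L))
  expect_equal(unname(ds$panel$values["A", 1]), 15)  # mean of 10 and 20
  expect_false(ds$panel$mask["A", 2])
  expect_equal(unname(ds$panel$values["B", 2]), 55)
})

test_that("load_dataset enforces referential integrity and value sanity", {
  st <- tempfile(fileext = ".csv")
  writeLines(c("sensor_id,latitude,longitude,tier",
               "A,28.6,77.2,low_cost"), st)

  rd <- tempfile(fileext = ".csv")
  writeLines(c("sensor_id,timestamp,pm25",
               "X9,2020-01-01T03:00:00+05:30,10"), rd)
  expect_error(load_dataset(rd, st), "X9")

  writeLines(c("sensor_id,timestamp,pm25",
               "A,2020-01-01T03:00:00+05:30,-4"), rd)
  expect_error(load_dataset(rd, st), "negative")

  writeLines(c("sensor_id,timestamp,pm25",
               "A,2020-01-01T03:00:00+05:30,10",
               "A,2020-01-01T03:00:00+05:30,12"), rd)
  expect_error(load_dataset(rd, st), "conflicting")

  # empty readings: panel with rows for all sites and zero columns
  writeLines("sensor_id,timestamp,pm25", rd)
  ds <- load_dataset(rd, st)
  expect_equal(dim(ds$panel), c(1L, 0L))
})

test_that("write/load round trip is value-exact and byte-stable", {
  city <- toy_city()
  pan <- subset_panel(city$observed, time_idx = 1:48)
  f1 <- tempfile(fileext = ".csv")
  write_panel(pan, f1)
  st <- tempfile(fileext = ".csv")
  write.csv(data.frame(sensor_id = city$sites$site_id,
                       latitude = 28.5 + city$sites$y_km / 111.32,
                       longitude = 77.0 + city$sites$x_km / 103.0,
                       tier = city$sites$tier),
            st, row.names = FALSE, quote = FALSE)
  ds <- load_dataset(f1, st, tz = "Asia/Kolkata")
  expect_equal(ds$panel$mask, pan$mask, ignore_attr = TRUE)
  expect_lt(max(abs(ds$panel$values[pan$mask] - pan$values[pan$mask])), 1e-9)
  f2 <- tempfile(fileext = ".csv")
  write_panel(ds$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("build_geometry computes planar Euclidean distances", {
  s <- data.frame(site_id = c("a", "b"), x_km = c(0, 3), y_km = c(0, 4))
  g <- build_geometry(s)
  expect_equal(g$dist["a", "b"], 5)

  s1 <- data.frame(site_id = "solo", x_km = 0, y_km = 0)
  expect_equal(build_geometry(s1)$dist, matrix(0, 1, 1, dimnames = list("solo", "solo")))

  s3 <- data.frame(site_id = c("a", "b", "c"), x_km = c(0, 1, 2), y_km = 0)
  g3 <- build_geometry(s3)
  expect_equal(g3$dist["a", "c"], g3$dist["a", "b"] + g3$dist["b", "c"])
})

test_that("projection is translation-invariant and rejects continental spans", {
  s <- data.frame(site_id = letters[1:4],
                  latitude = c(28.50, 28.55, 28.61, 28.70),
                  longitude = c(77.10, 77.25, 77.18, 77.05))
  d1 <- build_geometry(s)$dist
  # longitude shifts leave the local frame exactly unchanged
  s2 <- s; s2$longitude <- s2$longitude + 0.05
  expect_lt(max(abs(build_geometry(s2)$dist - d1)), 1e-9)
  # small latitude shifts move the reference latitude: sub-metre effect
  s3 <- s; s3$latitude <- s3$latitude + 0.01; s3$longitude <- s3$longitude + 0.01
  expect_lt(max(abs(build_geometry(s3)$dist - d1)), 5e-3)

  far <- data.frame(site_id = c("a", "b"), latitude = c(28, 31),
                    longitude = c(77, 77))
  expect_error(build_geometry(far), "200 km")
})

test_that("hour_slot partitions the day into the three 8-hour regimes", {
  expect_equal(hour_slot(7L), 1L)
  expect_equal(hour_slot(8L), 2L)
  expect_equal(hour_slot(23L), 3L)
  # each day contributes exactly 8 hours per slot, in any timezone
  for (tz in c("UTC", "Asia/Kolkata")) {
    day <- hourly_stamps(24, "2020-06-01 00:00:00", tz = tz)
    expect_equal(as.vector(table(hour_slot(day))), c(8, 8, 8))
  }
})

test_that("split_train_test is chronological and validates its boundary", {
  pan <- readings_panel(matrix(100, 2, 100,
                               dimnames = list(c("a", "b"), NULL)),
                        hourly_stamps(100))
  sp <- split_train_test(pan, 0.5)
  expect_equal(length(sp$train$timestamps), 50L)
  expect_lt(max(as.numeric(sp$train$timestamps)),
            min(as.numeric(sp$test$timestamps)))

  sp75 <- split_train_test(pan, 0.75)
  expect_equal(length(sp75$train$timestamps), 75L)

  expect_error(split_train_test(pan, 1.0), "boundary")
  expect_error(split_train_test(pan, pan$timestamps[1] - 3600), "boundary")

  spb <- split_train_test(pan, pan$timestamps[61])
  expect_equal(length(spb$train$timestamps), 60L)
})
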
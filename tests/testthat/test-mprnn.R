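ns <- asNamespace("pmcast")

tiny_model <- function(n = 3, H = 4, seed = 5) {
  sites <- toy_sites(n)
  init_mprnn(sites$site_id, toy_dist(sites), hidden = H, seed = seed)
}

test_that("initialization is deterministic, shaped, and guarded", {
  m1 <- tiny_model(seed = 11)
  m2 <- tiny_model(seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- tiny_model(seed = 12)
  expect_false(identical(m1$params, m3$params))

  m <- tiny_model(n = 3, H = 8)
  expect_equal(dim(m$params$Wr), c(3L, 8L))
  expect_length(m$params$br, 3L)
  st <- ns$mprnn_init_state(m, 1L, seed = 1)
  expect_equal(dim(st$h), c(3L, 8L))

  sites <- toy_sites(3)
  dflt <- init_mprnn(sites$site_id, toy_dist(sites), seed = 1)
  expect_equal(dflt$H, 256L)

  expect_error(init_mprnn("only", matrix(0, 1, 1, dimnames = list("only", "only"))),
               "neighbor")
})

test_that("message aggregation equals an explicit pairwise loop", {
  for (n in c(3, 5)) {
    m <- tiny_model(n = n, H = 4, seed = 7)
    st <- ns$mprnn_init_state(m, 1L, seed = 8)
    set.seed(9)
    yin <- matrix(rnorm(n), 1, n)
    obs <- matrix(1, 1, n)
    idx <- ns$mprnn_pair_index(m, 1L)
    pp <- ns$mprnn_prep_params(m$params, m)
    fw <- ns$mprnn_cell_forward(pp, m, idx, st, yin, obs, want_cache = TRUE)
    hob <- fw$cache$hobs
    p <- m$params
    H <- m$H
    magg <- matrix(0, n, H)
    for (v in seq_len(n)) {
      for (u in setdiff(seq_len(n), v)) {
        pin <- c(hob[v, ], hob[u, ], m$dist_scaled[v, u])
        magg[v, ] <- magg[v, ] + pmax(drop(pin %*% p$Wm) + p$bm, 0)
      }
      expect_length(setdiff(seq_len(n), v), n - 1L)  # sum over V - v
    }
    expect_lt(max(abs(magg - fw$cache$rounds[[1]]$Magg)), 1e-6)
  }
})

test_that("zeroed message parameters silence the spatial pathway", {
  m <- tiny_model(n = 4, H = 4, seed = 3)
  m$params$Wm[] <- 0; m$params$bm[] <- 0
  st <- ns$mprnn_init_state(m, 1L, seed = 2)
  idx <- ns$mprnn_pair_index(m, 1L)
  pp <- ns$mprnn_prep_params(m$params, m)
  fw <- ns$mprnn_cell_forward(pp, m, idx, st, matrix(rnorm(4), 1, 4),
                              matrix(1, 1, 4), want_cache = TRUE)
  expect_equal(max(abs(fw$cache$rounds[[1]]$Magg)), 0)
})

test_that("distances enter the message embedding", {
  m <- tiny_model(n = 3, H = 4, seed = 3)
  st <- ns$mprnn_init_state(m, 1L, seed = 2)
  y <- matrix(rnorm(3), 1, 3); o <- matrix(1, 1, 3)
  r1 <- mprnn_step(m, st, drop(y), rep(TRUE, 3))
  m2 <- m
  m2$dist_scaled <- m$dist_scaled * 0.5
  r2 <- mprnn_step(m2, st, drop(y), rep(TRUE, 3))
  expect_false(isTRUE(all.equal(r1$predictions, r2$predictions)))
})

test_that("analytic gradients match central finite differences", {
  n <- 3; H <- 4; B <- 2; K <- 3
  m <- tiny_model(n = n, H = H, seed = 5)
  m$norm <- list(in_mean = 10, in_sd = 4, out_mean = 10, out_sd = 4)
  idx <- ns$mprnn_pair_index(m, B)
  set.seed(2)
  yin <- array(rnorm(B * n * K), c(B, n, K))
  obs <- array(rbinom(B * n * K, 1, 0.8), c(B, n, K))
  targets <- data.frame(b = c(1, 2, 2, 1), v = c(2, 1, 3, 3),
                        k = c(3, 2, 3, 1), y = c(12, 9, 11, 10))
  h0 <- ns$mprnn_init_state(m, B, seed = 99)
  for (loss in c("mse", "mape")) {
    res <- ns$mprnn_window_loss(m$params, m, idx, yin, obs, targets, h0,
                                loss = loss)
    flat <- ns$flatten_params(m$params)
    gflat <- ns$flatten_params(res$grad)
    set.seed(3)
    pick <- sample(length(flat), 40)
    eps <- 1e-5
    num <- vapply(pick, function(i) {
      fp <- flat; fp[i] <- fp[i] + eps
      lp <- ns$mprnn_window_loss(ns$unflatten_params(fp, m$params), m, idx,
                                 yin, obs, targets, h0, loss = loss,
                                 want_grad = FALSE)$loss
      fm <- flat; fm[i] <- fm[i] - eps
      lm <- ns$mprnn_window_loss(ns$unflatten_params(fm, m$params), m, idx,
                                 yin, obs, targets, h0, loss = loss,
                                 want_grad = FALSE)$loss
      (lp - lm) / (2 * eps)
    }, numeric(1))
    an <- gflat[pick]
    rel <- abs(an - num) / pmax(abs(an) + abs(num), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training learns a constant panel to within 1%", {
  stamps <- hourly_stamps(300)
  pan <- readings_panel(matrix(100, 3, 300,
                               dimnames = list(c("a", "b", "c"), NULL)),
                        stamps)
  d <- build_geometry(data.frame(site_id = c("a", "b", "c"),
                                 x_km = c(0, 1, 2), y_km = c(0, 0, 1)))$dist
  m <- init_mprnn(c("a", "b", "c"), d, hidden = 32, seed = 1)
  m <- train_mprnn(m, pan, epochs = 30, seed = 2)
  expect_length(m$loss_history, 30L)
  expect_lt(m$loss_history[30], m$loss_history[1] + 1e-12)
  pred <- predict_mprnn(m, pan, from = 100, to = 200, seed = 3)
  expect_lt(max(abs(pred$values[pred$mask] - 100) / 100), 0.01)
})

test_that("training is bit-reproducible under a fixed seed", {
  city <- toy_city()
  pan <- subset_panel(city$observed, time_idx = 1:200)
  d <- toy_dist(city$sites)
  m0 <- init_mprnn(city$sites$site_id, d, hidden = 8, seed = 4)
  m1 <- train_mprnn(m0, pan, epochs = 2, stride = 4, seed = 17)
  m2 <- train_mprnn(m0, pan, epochs = 2, stride = 4, seed = 17)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("predictions never consume the target site's own readings", {
  city <- toy_city()
  pan <- subset_panel(city$observed, time_idx = 1:240)
  d <- toy_dist(city$sites)
  m <- init_mprnn(city$sites$site_id, d, hidden = 8, seed = 4)
  m <- train_mprnn(m, pan, epochs = 1, stride = 6, seed = 5)
  tgt <- city$sites$site_id[2]
  p1 <- predict_mprnn(m, pan, target_sites = tgt, from = 100, to = 160, seed = 6)

  # blank the target's own column entirely: predictions must not move
  pan2 <- pan
  pan2$mask[2, ] <- FALSE
  pan2$values[2, ] <- NA
  p2 <- predict_mprnn(m, pan2, target_sites = tgt, from = 100, to = 160, seed = 6)
  expect_identical(p1$values, p2$values)
  expect_true(all(is.finite(p2$values[p2$mask])))  # virtual-site mode
})

test_that("node relabeling permutes predictions consistently", {
  city <- toy_city()
  pan <- subset_panel(city$observed, time_idx = 1:160)
  d <- toy_dist(city$sites)
  ids <- city$sites$site_id
  m <- init_mprnn(ids, d, hidden = 8, seed = 4)
  m <- train_mprnn(m, pan, epochs = 1, stride = 8, seed = 5)

  perm <- c(3, 1, 2, 5, 4, 6, 8, 7)
  pan_p <- subset_panel(pan, sites = ids[perm])
  m_p <- m
  m_p$sites <- ids[perm]
  m_p$dist_scaled <- m$dist_scaled[perm, perm]
  for (nm in c("bo", "bl", "Wr")) m_p$params[[nm]] <- m$params[[nm]][perm, , drop = FALSE]
  m_p$params$br <- m$params$br[perm]
  for (nm in c("Wo", "Wx", "Wh")) m_p$params[[nm]] <- m$params[[nm]][perm, , , drop = FALSE]

  st1 <- mprnn_state(m, seed = 31)
  st2 <- list(h = st1$h[perm, , drop = FALSE], c = st1$c[perm, , drop = FALSE])
  y <- pan$values[, 50]; y[is.na(y)] <- 100
  r1 <- mprnn_step(m, st1, y, pan$mask[, 50])
  r2 <- mprnn_step(m_p, st2, y[perm], pan$mask[perm, 50])
  expect_equal(r2$predictions, r1$predictions[perm], tolerance = 1e-10)
})

test_that("insufficient warm-up history is rejected", {
  city <- toy_city()
  pan <- subset_panel(city$observed, time_idx = 1:60)
  m <- init_mprnn(city$sites$site_id, toy_dist(city$sites), hidden = 8, seed = 1)
  expect_error(predict_mprnn(m, pan, from = 5), "warm-up")
})
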
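# Comparison predictors: the k-nearest-neighbor spatial recurrent network
# (per-target LSTM consuming the K nearest neighbors' readings; no
# all-pairs message passing) and the persistence carry-forward floor.

#' K nearest neighbors per site
#'
#' For each site, the K nearest *other* sites by Euclidean distance;
#' deterministic tie-break by lexicographic site id. K is clamped to
#' `n_sites - 1` with a warning when larger.
#'
#' @param sites site table (or character ids matching `dist`).
#' @param dist symmetric km distance matrix.
#' @param K neighbor count, >= 1.
#' @return named list: site id -> character vector of K neighbor ids.
#' @export
knn_neighbors <- function(sites, dist, K) {
  ids <- if (is.data.frame(sites)) as.character(sites$site_id) else as.character(sites)
  if (K < 1) stopf("knn_neighbors: K must be >= 1")
  if (K >= length(ids)) {
    warnf("knn_neighbors: K = %d >= n_sites; clamped to %d", K, length(ids) - 1L)
    K <- length(ids) - 1L
  }
  out <- lapply(ids, function(s) {
    others <- setdiff(ids, s)
    d <- dist[s, others]
    others[order(d, others)][seq_len(K)]
  })
  stats::setNames(out, ids)
}

# --- single-series LSTM used per k-NN target --------------------------------

knn_init_params <- function(D, H, seed) {
  with_seed(seed, list(
    Wx = matrix(stats::rnorm(D * 4 * H, 0, 1 / sqrt(D)), D, 4 * H),
    Wh = matrix(stats::rnorm(H * 4 * H, 0, 1 / sqrt(H)), H, 4 * H),
    b = c(rep(0, H), rep(1, H), rep(0, 2 * H)),
    Wr = stats::rnorm(H, 0, 1 / sqrt(H)),
    br = 0
  ))
}

# Forward over a window; emits a readout at every step (step k's readout
# predicts window hour k+1). yhat: B x K.
lstm_seq_forward <- function(p, x_seq, h0, c0, want_cache = FALSE) {
  K <- dim(x_seq)[3]; H <- ncol(h0)
  h <- h0; cc <- c0
  caches <- if (want_cache) vector("list", K) else NULL
  yhat <- matrix(0, nrow(h0), K)
  hs <- if (want_cache) vector("list", K) else NULL
  for (k in seq_len(K)) {
    x <- matrix(x_seq[, , k], nrow(h0), dim(x_seq)[2])
    G <- x %*% p$Wx + h %*% p$Wh
    G <- G + rep(p$b, each = nrow(h0))
    gi <- sigmoid(G[, 1:H, drop = FALSE])
    gf <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    go <- sigmoid(G[, (2 * H + 1):(3 * H), drop = FALSE])
    gg <- tanh(G[, (3 * H + 1):(4 * H), drop = FALSE])
    cn <- gf * cc + gi * gg
    tc <- tanh(cn)
    hn <- go * tc
    if (want_cache) {
      caches[[k]] <- list(x = x, h_prev = h, c_prev = cc, gi = gi, gf = gf,
                          go = go, gg = gg, tc = tc)
      hs[[k]] <- hn
    }
    h <- hn; cc <- cn
    yhat[, k] <- drop(hn %*% p$Wr) + p$br
  }
  list(h = h, c = cc, yhat = yhat, caches = caches, hs = hs)
}

# dyhat: B x K matrix of per-step readout gradients.
lstm_seq_backward <- function(p, fw, dyhat) {
  H <- length(p$Wr)
  g <- list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0, Wr = p$Wr * 0, br = 0)
  dh <- matrix(0, nrow(dyhat), H)
  dc <- dh
  for (k in rev(seq_along(fw$caches))) {
    dyk <- dyhat[, k]
    if (any(dyk != 0)) {
      g$Wr <- g$Wr + drop(crossprod(fw$hs[[k]], dyk))
      g$br <- g$br + sum(dyk)
      dh <- dh + outer(dyk, p$Wr)
    }
    cc <- fw$caches[[k]]
    dcv <- dc + dh * cc$go * (1 - cc$tc^2)
    dG <- cbind((dcv * cc$gg) * cc$gi * (1 - cc$gi),
                (dcv * cc$c_prev) * cc$gf * (1 - cc$gf),
                (dh * cc$tc) * cc$go * (1 - cc$go),
                (dcv * cc$gi) * (1 - cc$gg^2))
    g$Wx <- g$Wx + crossprod(cc$x, dG)
    g$Wh <- g$Wh + crossprod(cc$h_prev, dG)
    g$b <- g$b + colSums(dG)
    dh <- dG %*% t(p$Wh)
    dc <- dcv * cc$gf
  }
  g
}

#' Train the k-NN spatial recurrent baseline
#'
#' One LSTM per target site, consuming at each hour the standardized
#' readings (and observed flags) of the target's K nearest neighbors --
#' never the target itself -- under the same windowing, loss, optimizer and
#' chronology contracts as [train_mprnn()].
#'
#' @param targets_panel panel gating and supplying the prediction targets.
#' @param inputs_panel panel supplying neighbor readings (default: targets).
#' @param sites site table with coordinates.
#' @param dist optional precomputed distance matrix.
#' @param K neighbor count (default 5).
#' @param hidden LSTM hidden size.
#' @param target_sites sites to train predictors for (default: all).
#' @inheritParams train_mprnn
#' @return a `knn_model` with per-target parameters and loss histories.
#' @export
train_knn_rnn <- function(targets_panel, inputs_panel = NULL, sites, dist = NULL,
                          K = 5, hidden = 32, target_sites = NULL,
                          lr = 1e-3, epochs = 30, batch_size = 64,
                          window = 8, stride = 1, loss = c("mape", "mse", "mae"),
                          eps = 1.0, loss_burn = 3, denom_panel = NULL,
                          seed = 1) {
  loss <- match.arg(loss)
  if (is.null(inputs_panel)) inputs_panel <- targets_panel
  if (is.null(dist)) dist <- build_geometry(sites)$dist
  ids <- targets_panel$sites
  target_sites <- target_sites %||% ids
  nbrs <- knn_neighbors(sites, dist, K)
  H <- as.integer(hidden)
  tt <- length(inputs_panel$timestamps)
  if (tt < window + 1) stopf("train_knn_rnn: panel shorter than window + 1 hours")

  inorm <- panel_norm(inputs_panel)
  onorm <- panel_norm(targets_panel)
  yin_all <- (inputs_panel$values - inorm$mean) / inorm$sd
  yin_all[!inputs_panel$mask] <- 0
  obs_all <- inputs_panel$mask * 1
  starts <- seq(1L, tt - window, by = stride)

  loss_steps <- (loss_burn + 1L):window
  models <- list()
  for (s in target_sites) {
    nb_idx <- match(nbrs[[s]], ids)
    v <- match(s, ids)
    ok <- starts[colSums(matrix(targets_panel$mask[v, outer(loss_steps, starts, "+")],
                                length(loss_steps))) > 0]
    if (!length(ok)) stopf("train_knn_rnn: no observed target cells for site %s", s)
    D <- 2L * length(nb_idx)
    p <- knn_init_params(D, H, substream_seed(seed, 41L, v))
    theta <- unlist(p, use.names = FALSE)
    ad <- adam_state(length(theta))
    tmpl <- p
    hist_ep <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- with_seed(substream_seed(seed, 42L, v, ep), sample(length(ok)))
      ep_loss <- 0; ep_n <- 0
      for (b0 in seq(1L, length(ord), by = batch_size)) {
        selw <- ok[ord[b0:min(b0 + batch_size - 1L, length(ord))]]
        B <- length(selw)
        x_seq <- array(0, c(B, D, window))
        ymat <- matrix(NA_real_, B, window)
        dmat <- matrix(NA_real_, B, window)
        for (bi in seq_len(B)) {
          cols <- selw[bi]:(selw[bi] + window - 1L)
          x_seq[bi, , ] <- rbind(yin_all[nb_idx, cols, drop = FALSE],
                                 obs_all[nb_idx, cols, drop = FALSE])
          tcols <- selw[bi] + loss_steps
          obs_t <- targets_panel$mask[v, tcols]
          ymat[bi, loss_steps[obs_t]] <- targets_panel$values[v, tcols[obs_t]]
          if (!is.null(denom_panel)) {
            dmat[bi, loss_steps[obs_t]] <- denom_panel$values[v, tcols[obs_t]]
          }
        }
        if (is.null(denom_panel)) dmat <- ymat
        lmask <- !is.na(ymat)
        p <- utils::relist(theta, tmpl)
        h0 <- with_seed(substream_seed(seed, 43L, v, ep, b0),
                        matrix(stats::rnorm(B * H), B, H))
        fw <- lstm_seq_forward(p, x_seq, h0, matrix(0, B, H), want_cache = TRUE)
        yhat_raw <- onorm$mean + onorm$sd * fw$yhat
        err <- yhat_raw - ymat
        nL <- sum(lmask)
        dyhat <- matrix(0, B, window)
        if (loss == "mape") {
          den <- pmax(dmat, eps)
          L <- mean((abs(err) / den)[lmask])
          dyhat[lmask] <- (sign(err) / den)[lmask] / nL * onorm$sd
        } else if (loss == "mae") {
          L <- mean(abs(err[lmask]))
          dyhat[lmask] <- sign(err[lmask]) / nL * onorm$sd
        } else {
          L <- mean(err[lmask]^2)
          dyhat[lmask] <- 2 * err[lmask] / nL * onorm$sd
        }
        gr <- lstm_seq_backward(p, fw, dyhat)
        up <- adam_update(theta, unlist(gr, use.names = FALSE), ad, lr = lr)
        theta <- up$theta; ad <- up$state
        ep_loss <- ep_loss + L * nL; ep_n <- ep_n + nL
      }
      hist_ep[ep] <- ep_loss / max(ep_n, 1)
    }
    models[[s]] <- list(params = utils::relist(theta, tmpl),
                        neighbors = nbrs[[s]], loss_history = hist_ep)
  }
  structure(list(K = K, hidden = H, sites = ids, models = models,
                 norm = list(in_mean = inorm$mean, in_sd = inorm$sd,
                             out_mean = onorm$mean, out_sd = onorm$sd),
                 window = window, seed = seed),
            class = "knn_model")
}

#' Rolling predictions from the k-NN recurrent baseline
#'
#' @param model a `knn_model` from [train_knn_rnn()].
#' @param inputs_panel panel supplying neighbor readings.
#' @param target_sites sites to predict at (must have trained predictors).
#' @param from,to first/last predicted column (index or `POSIXct`).
#' @param window warm-up hours.
#' @param seed seed for hidden-state draws.
#' @return an unbounded [readings_panel] of predictions.
#' @export
predict_knn_rnn <- function(model, inputs_panel, target_sites = NULL,
                            from, to = NULL, window = 8, seed = 1) {
  ids <- inputs_panel$sites
  target_sites <- target_sites %||% names(model$models)
  tt <- length(inputs_panel$timestamps)
  f <- if (inherits(from, "POSIXt")) match(TRUE, inputs_panel$timestamps >= from) else as.integer(from)
  t_end <- if (is.null(to)) tt else as.integer(to)
  if (is.na(f) || f - window < 1) stopf("predict_knn_rnn: insufficient warm-up history")
  yin_all <- (inputs_panel$values - model$norm$in_mean) / model$norm$in_sd
  yin_all[!inputs_panel$mask] <- 0
  obs_all <- inputs_panel$mask * 1

  pred <- matrix(NA_real_, length(target_sites), tt,
                 dimnames = list(target_sites, NULL))
  valid <- matrix(FALSE, length(target_sites), tt)
  H <- model$hidden
  for (si in seq_along(target_sites)) {
    s <- target_sites[si]
    mm <- model$models[[s]]
    if (is.null(mm)) stopf("predict_knn_rnn: no trained predictor for site %s", s)
    nb_idx <- match(mm$neighbors, ids)
    h <- with_seed(substream_seed(seed, 44L, si), matrix(stats::rnorm(H), 1, H))
    cc <- matrix(0, 1, H)
    p <- mm$params
    for (t in (f - window):(t_end - 1L)) {
      x <- array(c(yin_all[nb_idx, t], obs_all[nb_idx, t]),
                 c(1, 2L * length(nb_idx), 1))
      fw <- lstm_seq_forward(p, x, h, cc)
      h <- fw$h; cc <- fw$c
      if (t + 1L >= f) {
        pred[si, t + 1L] <- model$norm$out_mean + model$norm$out_sd * fw$yhat[1, 1]
        valid[si, t + 1L] <- TRUE
      }
    }
  }
  readings_panel(pred, inputs_panel$timestamps, sites = target_sites,
                 mask = valid, bounds = NULL)
}

#' Persistence baseline
#'
#' Carries the last observed reading forward: the prediction for hour t+1
#' at a site is that site's most recent observed value at or before t.
#' Hours with no prior observation carry no prediction.
#'
#' @param panel a [readings_panel].
#' @return an unbounded [readings_panel] of predictions.
#' @export
persistence_predict <- function(panel) {
  n <- length(panel$sites); tt <- length(panel$timestamps)
  pred <- matrix(NA_real_, n, tt, dimnames = list(panel$sites, NULL))
  for (i in seq_len(n)) {
    last <- NA_real_
    for (t in seq_len(tt)) {
      pred[i, t] <- last
      if (panel$mask[i, t]) last <- panel$values[i, t]
    }
  }
  readings_panel(pred, panel$timestamps, sites = panel$sites,
                 mask = is.finite(pred), bounds = NULL)
}
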
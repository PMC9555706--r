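# Message-passing recurrent neural network over the complete sensor graph.
#
# Each node (sensor) carries a hidden state of size H. One time step runs
# five phases: a per-node observation encoder O_v (affine + ReLU over
# [previous hidden, reading, observed flag], with a learned placeholder
# vector added when the reading is masked), one or more rounds of a shared
# message operator M (affine + ReLU over [h_v, h_n, scaled distance],
# summed over all other nodes) and shared update operator U (affine + ReLU
# over [h_v, m_v]), a per-node LSTM cell T_v, and a per-node affine readout
# R_v producing the next-hour prediction. Forward and backward passes are
# authored here directly (no autodiff): activations are cached per step and
# gradients are accumulated analytically through all five phases and
# through time.

mprnn_param_shapes <- function(n, H) {
  list(
    Wo = c(n, H, H + 2L), bo = c(n, H), placeholder = H,
    Wm = c(2L * H + 1L, H), bm = H,
    Wu = c(2L * H, H), bu = H,
    Wx = c(n, H, 4L * H), Wh = c(n, H, 4L * H), bl = c(n, 4L * H),
    Wr = c(n, H), br = n
  )
}

mprnn_init_params <- function(n, H, seed) {
  shapes <- mprnn_param_shapes(n, H)
  with_seed(seed, {
    p <- list()
    sc <- function(fan_in) 1 / sqrt(fan_in)
    p$Wo <- array(stats::rnorm(prod(shapes$Wo), 0, sc(H + 2)), shapes$Wo)
    p$bo <- array(0, shapes$bo)
    p$placeholder <- stats::rnorm(H, 0, 0.1)
    p$Wm <- array(stats::rnorm(prod(shapes$Wm), 0, sc(2 * H + 1)), shapes$Wm)
    p$bm <- rep(0, H)
    p$Wu <- array(stats::rnorm(prod(shapes$Wu), 0, sc(2 * H)), shapes$Wu)
    p$bu <- rep(0, H)
    p$Wx <- array(stats::rnorm(prod(shapes$Wx), 0, sc(H)), shapes$Wx)
    p$Wh <- array(stats::rnorm(prod(shapes$Wh), 0, sc(H)), shapes$Wh)
    p$bl <- array(0, shapes$bl)
    p$bl[, (H + 1):(2 * H)] <- 1  # forget-gate bias
    p$Wr <- array(stats::rnorm(prod(shapes$Wr), 0, sc(H)), shapes$Wr)
    p$br <- rep(0, n)
    p
  })
}

params_zero_like <- function(p) lapply(p, function(x) x * 0)

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, template) {
  out <- template
  pos <- 1L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    v <- flat[pos:(pos + len - 1L)]
    if (!is.null(dim(template[[nm]]))) dim(v) <- dim(template[[nm]])
    out[[nm]] <- v
    pos <- pos + len
  }
  out
}

#' Initialize a message-passing recurrent network
#'
#' Parameters are drawn deterministically from `seed` (scaled-normal
#' weights, zero biases, forget-gate bias 1). The observation, LSTM and
#' readout operators are per node; the message and update operators are
#' shared across the graph. Distances enter the message embedding scaled by
#' the network's maximum pairwise distance.
#'
#' @param sites character site ids, or a site table with `site_id` (node
#'   order; fixed for the model's lifetime).
#' @param dist symmetric km distance matrix over those sites.
#' @param hidden hidden/embedding size H (default 256).
#' @param rounds message-passing rounds per hour (default 1).
#' @param hidden_init `"normal"`: hidden states drawn N(0,1) at every
#'   sequence start; `"zeros"` for variance-reduction experiments.
#' @param seed integer seed for parameter initialization.
#' @return an `mprnn_model`.
#' @export
init_mprnn <- function(sites, dist, hidden = 256, rounds = 1,
                       hidden_init = c("normal", "zeros"), seed = 1) {
  ids <- if (is.data.frame(sites)) as.character(sites$site_id) else as.character(sites)
  n <- length(ids)
  if (n < 2) stopf("init_mprnn: need >= 2 sites (messages need a neighbor)")
  hidden_init <- match.arg(hidden_init)
  dist <- dist[ids, ids, drop = FALSE]
  dmax <- max(dist)
  structure(list(
    sites = ids, n = n, H = as.integer(hidden), rounds = as.integer(rounds),
    dist_scaled = if (dmax > 0) dist / dmax else dist, dist_max = dmax,
    params = mprnn_init_params(n, as.integer(hidden), seed),
    norm = list(in_mean = 0, in_sd = 1, out_mean = 0, out_sd = 1),
    hidden_init = hidden_init, seed = as.integer(seed)
  ), class = "mprnn_model")
}

#' @export
print.mprnn_model <- function(x, ...) {
  cat(sprintf("<mprnn_model> %d nodes  H=%d  rounds=%d  (%d parameters)\n",
              x$n, x$H, x$rounds, length(flatten_params(x$params))))
  invisible(x)
}

# Precomputed pair/row indexing for a batch size B.
mprnn_pair_index <- function(model, B) {
  n <- model$n
  pv <- rep(seq_len(n), each = n - 1L)
  pu <- unlist(lapply(seq_len(n), function(v) setdiff(seq_len(n), v)))
  ivrows <- rep((pv - 1L) * B, each = B) + rep(seq_len(B), length(pv))
  iurows <- rep((pu - 1L) * B, each = B) + rep(seq_len(B), length(pu))
  dvec <- rep(model$dist_scaled[cbind(pv, pu)], each = B)
  list(B = B, ivrows = ivrows, iurows = iurows, dvec = dvec)
}

mprnn_init_state <- function(model, B, seed = NULL) {
  nB <- model$n * B
  h <- if (model$hidden_init == "normal") {
    if (is.null(seed)) {
      matrix(stats::rnorm(nB * model$H), nB, model$H)
    } else {
      with_seed(seed, matrix(stats::rnorm(nB * model$H), nB, model$H))
    }
  } else {
    matrix(0, nB, model$H)
  }
  list(h = h, c = matrix(0, nB, model$H))
}

# Pre-slice the parameter arrays into per-node matrices (and the
# transposes the backward pass needs) once per batch; the hot per-step
# loops then avoid all array-slice copying.
mprnn_prep_params <- function(p, model) {
  n <- model$n; H <- model$H
  pp <- list(n = n, H = H,
             bo = p$bo, placeholder = p$placeholder,
             Wm1 = p$Wm[1:H, , drop = FALSE],
             Wm2 = p$Wm[(H + 1):(2 * H), , drop = FALSE],
             wmd = p$Wm[2 * H + 1, ], bm = p$bm,
             Wu1 = p$Wu[1:H, , drop = FALSE],
             Wu2 = p$Wu[(H + 1):(2 * H), , drop = FALSE], bu = p$bu,
             bl = p$bl, Wr = p$Wr, br = p$br)
  pp$Wm1_t <- t(pp$Wm1); pp$Wm2_t <- t(pp$Wm2)
  pp$Wu1_t <- t(pp$Wu1); pp$Wu2_t <- t(pp$Wu2)
  pp$Wo_t <- vector("list", n); pp$Wo_h1 <- vector("list", n)
  pp$Wx <- vector("list", n); pp$Wx_t <- vector("list", n)
  pp$Wh <- vector("list", n); pp$Wh_t <- vector("list", n)
  for (v in seq_len(n)) {
    Wo_v <- matrix(p$Wo[v, , ], H, H + 2L)
    pp$Wo_t[[v]] <- t(Wo_v)
    pp$Wo_h1[[v]] <- Wo_v[, 1:H, drop = FALSE]
    pp$Wx[[v]] <- matrix(p$Wx[v, , ], H, 4L * H)
    pp$Wx_t[[v]] <- t(pp$Wx[[v]])
    pp$Wh[[v]] <- matrix(p$Wh[v, , ], H, 4L * H)
    pp$Wh_t[[v]] <- t(pp$Wh[[v]])
  }
  pp
}

# One forward step in standardized units.
# st: list(h, c) each (n*B) x H, row (v-1)*B + b.
# yin, obs: B x n (standardized reading; observed/visible flag in {0,1}).
mprnn_cell_forward <- function(pp, model, idx, st, yin, obs, want_cache = FALSE) {
  n <- model$n; H <- model$H; B <- idx$B
  nB <- n * B
  yin <- yin * obs  # a masked reading never enters, by construction
  hobs <- matrix(0, nB, H)
  for (v in seq_len(n)) {
    rows <- ((v - 1L) * B + 1L):(v * B)
    X <- cbind(st$h[rows, , drop = FALSE], yin[, v], obs[, v])
    A <- X %*% pp$Wo_t[[v]]
    A <- A + rep(pp$bo[v, ], each = B)
    A <- A + outer(1 - obs[, v], pp$placeholder)
    hobs[rows, ] <- A
  }
  hobs <- relu(hobs)

  # The message operator is affine before its ReLU, so the per-pair design
  # matrix never needs materializing: project hidden states through the
  # "own"/"neighbor" weight blocks once per node, then gather rows per pair.
  hcur <- hobs
  rounds <- vector("list", model$rounds)
  if (is.null(pp$dbias)) {
    pp$dbias <- outer(idx$dvec, pp$wmd) + rep(pp$bm, each = length(idx$dvec))
  }
  for (r in seq_len(model$rounds)) {
    hv_lin <- hcur %*% pp$Wm1
    hu_lin <- hcur %*% pp$Wm2
    pre <- hv_lin[idx$ivrows, , drop = FALSE] +
      hu_lin[idx$iurows, , drop = FALSE] + pp$dbias
    Mact <- pre > 0
    pre[!Mact] <- 0
    Magg <- rowsum(pre, idx$ivrows)
    hupd <- relu(hcur %*% pp$Wu1 + Magg %*% pp$Wu2 + rep(pp$bu, each = nB))
    rounds[[r]] <- list(hin = hcur, Mact = Mact, Magg = Magg, hupd = hupd)
    hcur <- hupd
  }

  hnew <- matrix(0, nB, H); cnew <- matrix(0, nB, H)
  gates <- if (want_cache) vector("list", n) else NULL
  yhat <- matrix(0, B, n)
  for (v in seq_len(n)) {
    rows <- ((v - 1L) * B + 1L):(v * B)
    G <- hcur[rows, , drop = FALSE] %*% pp$Wx[[v]] +
      st$h[rows, , drop = FALSE] %*% pp$Wh[[v]]
    G <- G + rep(pp$bl[v, ], each = B)
    gi <- sigmoid(G[, 1:H, drop = FALSE])
    gf <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    go <- sigmoid(G[, (2 * H + 1):(3 * H), drop = FALSE])
    gg <- tanh(G[, (3 * H + 1):(4 * H), drop = FALSE])
    cv <- gf * st$c[rows, , drop = FALSE] + gi * gg
    tc <- tanh(cv)
    hv <- go * tc
    hnew[rows, ] <- hv
    cnew[rows, ] <- cv
    if (want_cache) gates[[v]] <- list(gi = gi, gf = gf, go = go, gg = gg, tc = tc)
    yhat[, v] <- hv %*% pp$Wr[v, ] + pp$br[v]
  }

  out <- list(state = list(h = hnew, c = cnew), yhat = yhat)
  if (want_cache) {
    out$cache <- list(h_prev = st$h, c_prev = st$c, yin = yin, obs = obs,
                      hobs = hobs, rounds = rounds, hlstm_in = hcur,
                      gates = gates, hnew = hnew, cnew = cnew)
  }
  out
}

# Gradient accumulators matching the prepared-parameter layout.
mprnn_acc_new <- function(model) {
  n <- model$n; H <- model$H
  acc <- new.env(parent = emptyenv())
  acc$Wo <- lapply(seq_len(n), function(v) matrix(0, H, H + 2L))
  acc$bo <- matrix(0, n, H)
  acc$placeholder <- numeric(H)
  acc$Wm1 <- matrix(0, H, H); acc$Wm2 <- matrix(0, H, H)
  acc$wmd <- numeric(H); acc$bm <- numeric(H)
  acc$Wu1 <- matrix(0, H, H); acc$Wu2 <- matrix(0, H, H); acc$bu <- numeric(H)
  acc$Wx <- lapply(seq_len(n), function(v) matrix(0, H, 4L * H))
  acc$Wh <- lapply(seq_len(n), function(v) matrix(0, H, 4L * H))
  acc$bl <- matrix(0, n, 4L * H)
  acc$Wr <- matrix(0, n, H); acc$br <- numeric(n)
  acc
}

mprnn_acc_to_grad <- function(acc, params, model) {
  n <- model$n; H <- model$H
  grad <- params_zero_like(params)
  for (v in seq_len(n)) {
    grad$Wo[v, , ] <- acc$Wo[[v]]
    grad$Wx[v, , ] <- acc$Wx[[v]]
    grad$Wh[v, , ] <- acc$Wh[[v]]
  }
  grad$bo <- acc$bo; grad$placeholder <- acc$placeholder
  grad$Wm <- rbind(acc$Wm1, acc$Wm2, acc$wmd); grad$bm <- acc$bm
  grad$Wu <- rbind(acc$Wu1, acc$Wu2); grad$bu <- acc$bu
  grad$bl <- acc$bl; grad$Wr <- acc$Wr; grad$br <- acc$br
  grad
}

# Backward through one step. dyhat: B x n; dh_next/dc_next: (nB) x H
# gradients flowing into this step's output state. Parameter gradients are
# accumulated into the environment `acc`; returns the gradients w.r.t. the
# previous state.
mprnn_cell_backward <- function(pp, model, idx, cache, dyhat, dh_next, dc_next, acc) {
  n <- model$n; H <- model$H; B <- idx$B
  dh_prev <- matrix(0, n * B, H)
  dc_prev <- matrix(0, n * B, H)
  dhlstm_in <- matrix(0, n * B, H)

  for (v in seq_len(n)) {
    rows <- ((v - 1L) * B + 1L):(v * B)
    g <- cache$gates[[v]]
    hv_rows <- cache$hnew[rows, , drop = FALSE]
    dhv <- dh_next[rows, , drop = FALSE] + outer(dyhat[, v], pp$Wr[v, ])
    acc$Wr[v, ] <- acc$Wr[v, ] + drop(crossprod(hv_rows, dyhat[, v]))
    acc$br[v] <- acc$br[v] + sum(dyhat[, v])

    dcv <- dc_next[rows, , drop = FALSE] + dhv * g$go * (1 - g$tc^2)
    dgo <- dhv * g$tc
    dgi <- dcv * g$gg
    dgf <- dcv * cache$c_prev[rows, , drop = FALSE]
    dgg <- dcv * g$gi
    dc_prev[rows, ] <- dcv * g$gf
    dG <- cbind(dgi * g$gi * (1 - g$gi),
                dgf * g$gf * (1 - g$gf),
                dgo * g$go * (1 - g$go),
                dgg * (1 - g$gg^2))
    x_v <- cache$hlstm_in[rows, , drop = FALSE]
    hp_v <- cache$h_prev[rows, , drop = FALSE]
    acc$Wx[[v]] <- acc$Wx[[v]] + crossprod(x_v, dG)
    acc$Wh[[v]] <- acc$Wh[[v]] + crossprod(hp_v, dG)
    acc$bl[v, ] <- acc$bl[v, ] + colSums(dG)
    dhlstm_in[rows, ] <- dG %*% pp$Wx_t[[v]]
    dh_prev[rows, ] <- dh_prev[rows, ] + dG %*% pp$Wh_t[[v]]
  }

  dhcur <- dhlstm_in
  for (r in rev(seq_len(model$rounds))) {
    rc <- cache$rounds[[r]]
    dpre_u <- dhcur * (rc$hupd > 0)
    acc$Wu1 <- acc$Wu1 + crossprod(rc$hin, dpre_u)
    acc$Wu2 <- acc$Wu2 + crossprod(rc$Magg, dpre_u)
    acc$bu <- acc$bu + colSums(dpre_u)
    dhin <- dpre_u %*% pp$Wu1_t
    dMagg <- dpre_u %*% pp$Wu2_t

    # per-pair gradient, factorized the same way as the forward pass
    dpre_m <- dMagg[idx$ivrows, , drop = FALSE]
    dpre_m[!rc$Mact] <- 0
    rs_v <- rowsum(dpre_m, idx$ivrows)
    rs_u <- rowsum(dpre_m, idx$iurows)
    acc$Wm1 <- acc$Wm1 + crossprod(rc$hin, rs_v)
    acc$Wm2 <- acc$Wm2 + crossprod(rc$hin, rs_u)
    acc$wmd <- acc$wmd + drop(crossprod(dpre_m, idx$dvec))
    acc$bm <- acc$bm + colSums(rs_v)
    dhin <- dhin + rs_v %*% pp$Wm1_t + rs_u %*% pp$Wm2_t
    dhcur <- dhin
  }

  dpre_o <- dhcur * (cache$hobs > 0)
  for (v in seq_len(n)) {
    rows <- ((v - 1L) * B + 1L):(v * B)
    dpo <- dpre_o[rows, , drop = FALSE]
    X <- cbind(cache$h_prev[rows, , drop = FALSE], cache$yin[, v], cache$obs[, v])
    acc$Wo[[v]] <- acc$Wo[[v]] + crossprod(dpo, X)
    acc$bo[v, ] <- acc$bo[v, ] + colSums(dpo)
    acc$placeholder <- acc$placeholder +
      drop(crossprod(dpo, 1 - cache$obs[, v]))
    dh_prev[rows, ] <- dh_prev[rows, ] + dpo %*% pp$Wo_h1[[v]]
  }

  list(dh_prev = dh_prev, dc_prev = dc_prev)
}

# Loss and (optionally) analytic gradient over one batch of windows.
# yin/obs: B x n x K arrays (standardized inputs and visibility flags);
# targets: data.frame(b, v, k, y) with raw-unit targets: row (b, v, k, y)
# scores the prediction emitted at step k (for window hour k+1) at node v
# of window b. h0: initial state list(h, c). Pure function of `params` --
# used both by the trainer and by the finite-difference gradient check.
mprnn_window_loss <- function(params, model, idx, yin, obs, targets, h0,
                              loss = c("mape", "mse", "mae"), eps = 1.0,
                              want_grad = TRUE) {
  loss <- match.arg(loss)
  K <- dim(yin)[3]
  B <- idx$B
  pp <- mprnn_prep_params(params, model)
  pp$dbias <- outer(idx$dvec, pp$wmd) + rep(pp$bm, each = length(idx$dvec))
  st <- h0
  caches <- if (want_grad) vector("list", K) else NULL
  yhats <- vector("list", K)
  for (k in seq_len(K)) {
    fw <- mprnn_cell_forward(pp, model, idx, st,
                             matrix(yin[, , k], B, model$n),
                             matrix(obs[, , k], B, model$n),
                             want_cache = want_grad)
    if (want_grad) caches[[k]] <- fw$cache
    yhats[[k]] <- fw$yhat
    st <- fw$state
  }
  om <- model$norm$out_mean; osd <- model$norm$out_sd
  yhat_raw <- vapply(seq_len(nrow(targets)), function(r) {
    om + osd * yhats[[targets$k[r]]][targets$b[r], targets$v[r]]
  }, numeric(1))
  err <- yhat_raw - targets$y
  nT <- nrow(targets)
  if (loss == "mape") {
    # percentage denominator: the raw level when given (residual stages:
    # |residual error| / level is exactly the final prediction's MAPE
    # under an additive baseline), else the target itself
    den <- pmax(targets$den %||% targets$y, eps)
    L <- mean(abs(err) / den)
    dl_raw <- sign(err) / den / nT
  } else if (loss == "mae") {
    L <- mean(abs(err))
    dl_raw <- sign(err) / nT
  } else {
    L <- mean(err^2)
    dl_raw <- 2 * err / nT
  }
  if (!want_grad) return(list(loss = L))

  acc <- mprnn_acc_new(model)
  dy_steps <- vector("list", K)
  for (k in unique(targets$k)) {
    dy <- matrix(0, B, model$n)
    rows <- targets$k == k
    dy[cbind(targets$b[rows], targets$v[rows])] <- dl_raw[rows] * osd
    dy_steps[[k]] <- dy
  }
  zero_dy <- matrix(0, B, model$n)
  dh <- matrix(0, model$n * B, model$H)
  dc <- matrix(0, model$n * B, model$H)
  for (k in rev(seq_len(K))) {
    dyhat <- dy_steps[[k]] %||% zero_dy
    bk <- mprnn_cell_backward(pp, model, idx, caches[[k]], dyhat, dh, dc, acc)
    dh <- bk$dh_prev
    dc <- bk$dc_prev
  }
  list(loss = L, grad = mprnn_acc_to_grad(acc, params, model))
}

adam_state <- function(n_par) list(m = numeric(n_par), v = numeric(n_par), t = 0L)

adam_update <- function(theta, g, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

panel_norm <- function(panel, floor_sd = 1e-8) {
  v <- panel$values[panel$mask]
  m <- if (length(v)) mean(v) else 0
  s <- if (length(v) > 1) stats::sd(v) else 1
  if (!is.finite(s) || s < floor_sd) s <- 1
  list(mean = m, sd = s)
}

#' Train the message-passing recurrent network
#'
#' Truncated backpropagation through time over sliding windows of `window`
#' input hours predicting the following hour, with the Adam optimizer
#' (defaults: learning rate 0.001, 30 epochs, shuffled windows). Per
#' window, a seeded subset of nodes is designated as prediction targets;
#' their own readings are masked (learned placeholder + flag) throughout
#' the window, so a prediction at a node never consumes that node's
#' readings, and the loss is taken at those nodes at the window's final
#' hour. The loss is only evaluated at cells observed in the *target*
#' panel; imputed inputs may feed the network but never the loss.
#'
#' @param model an [init_mprnn()] model.
#' @param targets_panel panel of prediction targets (raw PM or residuals);
#'   its mask gates the loss.
#' @param inputs_panel panel feeding the network (possibly imputed);
#'   defaults to `targets_panel`.
#' @param lr,epochs,batch_size,window Adam learning rate, epochs, windows
#'   per batch, input hours per window.
#' @param stride step between window starts (1 = every sliding window).
#' @param target_frac fraction of nodes masked as targets per window.
#' @param loss `"mape"` (masked absolute percentage with denominator floor
#'   `eps`) or `"mse"`.
#' @param eps MAPE denominator floor (ug/m3).
#' @param loss_burn hidden-state burn-in: the loss is taken at every window
#'   step after the first `loss_burn` hours (each step's readout predicts
#'   the following hour), not just at the window's last hour.
#' @param seed seed for window shuffling, target sampling and hidden-state
#'   draws.
#' @return the trained model, with `loss_history` (one mean loss per epoch).
#' @export
train_mprnn <- function(model, targets_panel, inputs_panel = NULL,
                        lr = 1e-3, epochs = 30, batch_size = 64,
                        window = 8, stride = 1, target_frac = 0.25,
                        loss = c("mape", "mse", "mae"), eps = 1.0, loss_burn = 3,
                        denom_panel = NULL, seed = 1) {
  loss <- match.arg(loss)
  if (is.null(inputs_panel)) inputs_panel <- targets_panel
  stopifnot(identical(inputs_panel$sites, model$sites),
            identical(targets_panel$sites, model$sites))
  tt <- length(inputs_panel$timestamps)
  if (tt < window + 1) stopf("train_mprnn: panel shorter than window + 1 hours")
  n <- model$n
  inorm <- panel_norm(inputs_panel)
  onorm <- panel_norm(targets_panel)
  model$norm <- list(in_mean = inorm$mean, in_sd = inorm$sd,
                     out_mean = onorm$mean, out_sd = onorm$sd)

  yin_all <- (inputs_panel$values - inorm$mean) / inorm$sd
  yin_all[!inputs_panel$mask] <- 0
  obs_all <- inputs_panel$mask * 1

  starts <- seq(1L, tt - window, by = stride)
  loss_steps <- (loss_burn + 1L):window
  n_mask <- max(1L, ceiling(target_frac * n))
  tmask <- with_seed(substream_seed(seed, 21L), {
    do.call(rbind, lapply(starts, function(s) sample(n, n_mask)))
  })
  has_target <- vapply(seq_along(starts), function(k) {
    any(targets_panel$mask[tmask[k, ], starts[k] + loss_steps])
  }, logical(1))
  if (!any(has_target)) stopf("train_mprnn: no observed target cells in any window")
  starts <- starts[has_target]
  tmask <- tmask[has_target, , drop = FALSE]

  theta <- flatten_params(model$params)
  ad <- adam_state(length(theta))
  loss_history <- numeric(epochs)
  idx_cache <- new.env(parent = emptyenv())

  for (ep in seq_len(epochs)) {
    ord <- with_seed(substream_seed(seed, 22L, ep), sample(length(starts)))
    ep_loss <- 0; ep_n <- 0
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      sel <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      B <- length(sel)
      key <- as.character(B)
      if (is.null(idx_cache[[key]])) idx_cache[[key]] <- mprnn_pair_index(model, B)
      idx <- idx_cache[[key]]

      yin <- array(0, c(B, n, window))
      obs <- array(0, c(B, n, window))
      tb <- integer(0); tv <- integer(0); tk <- integer(0); ty <- numeric(0)
      td <- numeric(0)
      for (bi in seq_len(B)) {
        k <- sel[bi]
        cols <- starts[k]:(starts[k] + window - 1L)
        yin[bi, , ] <- yin_all[, cols]
        ob <- obs_all[, cols]
        ob[tmask[k, ], ] <- 0
        obs[bi, , ] <- ob
        for (kk in loss_steps) {
          tcol <- starts[k] + kk
          for (v in tmask[k, ]) {
            if (targets_panel$mask[v, tcol]) {
              tb <- c(tb, bi); tv <- c(tv, v); tk <- c(tk, kk)
              ty <- c(ty, targets_panel$values[v, tcol])
              if (!is.null(denom_panel)) td <- c(td, denom_panel$values[v, tcol])
            }
          }
        }
      }
      if (!length(tb)) next
      tg <- data.frame(b = tb, v = tv, k = tk, y = ty)
      if (!is.null(denom_panel)) tg$den <- td
      params <- unflatten_params(theta, model$params)
      h0 <- mprnn_init_state(model, B, seed = substream_seed(seed, 23L, ep, b0))
      res <- mprnn_window_loss(params, model, idx, yin, obs, tg, h0,
                               loss = loss, eps = eps)
      up <- adam_update(theta, flatten_params(res$grad), ad, lr = lr)
      theta <- up$theta; ad <- up$state
      ep_loss <- ep_loss + res$loss * length(tb)
      ep_n <- ep_n + length(tb)
    }
    loss_history[ep] <- ep_loss / max(ep_n, 1)
  }
  model$params <- unflatten_params(theta, model$params)
  model$loss_history <- loss_history
  model$trained <- TRUE
  model
}

#' One forward step of the network (user-facing)
#'
#' Consumes one hour of observations and returns the advanced hidden state
#' and the raw-unit prediction for the next hour at every node. Nodes in
#' `targets` have their own reading masked (they never consume it); missing
#' observations are masked the same way.
#'
#' @param model a trained or freshly initialized `mprnn_model`.
#' @param state state from [mprnn_state()] or a previous step.
#' @param y named (or model-ordered) numeric vector of readings at this hour.
#' @param observed logical vector: which readings are present.
#' @param targets site ids treated as prediction targets (self-masked).
#' @return list with `state` and `predictions` (named, raw units).
#' @export
mprnn_step <- function(model, state, y, observed = !is.na(y), targets = character()) {
  n <- model$n
  yv <- as.numeric(y)[seq_len(n)]
  obsv <- as.numeric(observed)[seq_len(n)]
  obsv[model$sites %in% targets] <- 0
  yv[obsv == 0 | is.na(yv)] <- model$norm$in_mean
  yin <- matrix((yv - model$norm$in_mean) / model$norm$in_sd, 1, n)
  obs <- matrix(obsv, 1, n)
  idx <- mprnn_pair_index(model, 1L)
  pp <- mprnn_prep_params(model$params, model)
  fw <- mprnn_cell_forward(pp, model, idx, state, yin, obs)
  pred <- model$norm$out_mean + model$norm$out_sd * drop(fw$yhat)
  list(state = fw$state,
       predictions = stats::setNames(pred, model$sites))
}

#' Fresh hidden state for a rolling pass
#'
#' @param model an `mprnn_model`.
#' @param seed seed for the N(0,1) hidden-state draw (under the model's
#'   `"normal"` initialization rule).
#' @return a state list for [mprnn_step()].
#' @export
mprnn_state <- function(model, seed = NULL) {
  mprnn_init_state(model, 1L, seed = seed)
}

#' Rolling one-step-ahead predictions
#'
#' Re-initializes hidden states per the model's stored rule, warms up on
#' `window` hours of history, then rolls across the requested span
#' predicting each hour from the previous hours' readings. Each target site
#' is handled by its own copy of the network state in which that site's
#' readings are masked throughout, so predictions never consume the target
#' site's own readings -- which also permits predicting at sites with no
#' observations at all (virtual-site mode).
#'
#' @param model a trained `mprnn_model`.
#' @param inputs_panel panel supplying neighbor readings (its sites must
#'   match the model's node order).
#' @param target_sites sites to predict at (subset of model sites).
#' @param from first predicted column: integer index or `POSIXct`.
#' @param to last predicted column (default: end of panel).
#' @param window warm-up hours required before `from`.
#' @param seed seed for the hidden-state draw.
#' @return an unbounded [readings_panel] of predictions over the full panel
#'   grid, valid on `from..to` for `target_sites`.
#' @export
predict_mprnn <- function(model, inputs_panel, target_sites = model$sites,
                          from, to = NULL, window = 8, seed = 1) {
  stopifnot(identical(inputs_panel$sites, model$sites))
  tt <- length(inputs_panel$timestamps)
  f <- if (inherits(from, "POSIXt")) match(TRUE, inputs_panel$timestamps >= from) else as.integer(from)
  t_end <- if (is.null(to)) tt else if (inherits(to, "POSIXt")) max(which(inputs_panel$timestamps <= to)) else as.integer(to)
  if (is.na(f) || f - window < 1) {
    stopf("predict_mprnn: need %d hours of warm-up history before the first predicted hour", window)
  }
  bad <- setdiff(target_sites, model$sites)
  if (length(bad)) stopf("predict_mprnn: unknown target site(s): %s", paste(bad, collapse = ", "))
  n <- model$n
  B <- length(target_sites)
  tnode <- match(target_sites, model$sites)
  idx <- mprnn_pair_index(model, B)

  yin_all <- (inputs_panel$values - model$norm$in_mean) / model$norm$in_sd
  yin_all[!inputs_panel$mask] <- 0
  obs_all <- inputs_panel$mask * 1

  st <- mprnn_init_state(model, B, seed = substream_seed(seed, 31L))
  pp <- mprnn_prep_params(model$params, model)
  pp$dbias <- outer(idx$dvec, pp$wmd) + rep(pp$bm, each = length(idx$dvec))
  pred <- matrix(NA_real_, B, tt, dimnames = list(target_sites, NULL))
  valid <- matrix(FALSE, B, tt)
  for (t in (f - window):(t_end - 1L)) {
    yin <- matrix(rep(yin_all[, t], each = B), B, n)
    obs <- matrix(rep(obs_all[, t], each = B), B, n)
    obs[cbind(seq_len(B), tnode)] <- 0
    yin[obs == 0] <- 0
    fw <- mprnn_cell_forward(pp, model, idx, st, yin, obs)
    st <- fw$state
    if (t + 1L >= f) {
      pred[, t + 1L] <- model$norm$out_mean +
        model$norm$out_sd * fw$yhat[cbind(seq_len(B), tnode)]
      valid[, t + 1L] <- TRUE
    }
  }
  readings_panel(pred, inputs_panel$timestamps, sites = target_sites,
                 mask = valid, bounds = NULL)
}
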
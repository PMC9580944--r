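# Minimal batched neural-network engine: dense, 1-D/2-D convolution and
# (bidirectional) LSTM layers with hand-written backpropagation, Adam, and
# binary cross-entropy on logits. Matrix multiplications go through BLAS;
# shapes follow the conventions
#   dense:   N x F matrices
#   conv1d:  (N, L, C) arrays
#   conv2d:  (N, n, n, C) arrays
#   lstm:    (N, L, C) arrays
# Models output logits; the sigmoid is fused into the loss for stability.

glorot <- function(fin, fout) {
  matrix(stats::runif(fin * fout, -1, 1) * sqrt(6 / (fin + fout)), fin, fout)
}

nn_dense <- function(n_in, n_out, act = c("linear", "relu")) {
  list(type = "dense", act = match.arg(act),
       params = list(W = glorot(n_in, n_out), b = numeric(n_out)))
}

nn_conv1d <- function(in_ch, out_ch, width) {
  list(type = "conv1d", width = width,
       params = list(W = glorot(width * in_ch, out_ch), b = numeric(out_ch)))
}

nn_maxpool1d <- function() list(type = "maxpool1d", params = list())

nn_lstm_bi <- function(in_ch, hidden) {
  mk <- function() list(Wx = glorot(in_ch, 4L * hidden),
                        Wh = glorot(hidden, 4L * hidden),
                        b = rep(c(0, 1, 0, 0), each = hidden)) # forget bias 1
  p <- c(stats::setNames(mk(), c("Wx_f", "Wh_f", "b_f")),
         stats::setNames(mk(), c("Wx_b", "Wh_b", "b_b")))
  list(type = "lstm_bi", hidden = hidden, params = p)
}

nn_conv2d <- function(in_ch, out_ch, ksize = 3L, act = c("linear", "relu")) {
  off <- if (ksize == 1L) cbind(0L, 0L) else
    as.matrix(expand.grid(di = -1:1, dj = -1:1))
  W <- lapply(seq_len(nrow(off)), function(k) glorot(in_ch, out_ch) / nrow(off))
  names(W) <- paste0("W", seq_len(nrow(off)))
  list(type = "conv2d", off = off, act = match.arg(act),
       params = c(W, list(b = numeric(out_ch))))
}

# residual block: relu(conv3x3) -> conv3x3 + skip -> relu
nn_res2d <- function(ch) {
  c1 <- nn_conv2d(ch, ch); c2 <- nn_conv2d(ch, ch)
  list(type = "res2d", off = c1$off,
       params = c(stats::setNames(c1$params, paste0(names(c1$params), "_1")),
                  stats::setNames(c2$params, paste0(names(c2$params), "_2"))))
}

# 2-D BLSTM block: bidirectional LSTM along rows and along columns, outputs
# concatenated (4 * hidden channels)
nn_bilstm2d <- function(in_ch, hidden) {
  r <- nn_lstm_bi(in_ch, hidden); cl <- nn_lstm_bi(in_ch, hidden)
  list(type = "bilstm2d", hidden = hidden,
       params = c(stats::setNames(r$params, paste0(names(r$params), "_r")),
                  stats::setNames(cl$params, paste0(names(cl$params), "_c"))))
}

new_nn_model <- function(layers, spec = NULL) {
  m <- new.env(parent = emptyenv())
  m$layers <- layers
  m$spec <- spec
  m$adam <- NULL
  class(m) <- "synfold_nn"
  m
}

#' Number of trainable parameters of a model
#' @param model a fitted or unfitted model handle.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l)
    sum(vapply(l$params, length, 0L)), 0))
}

# ---- forward / backward ----

shift2 <- function(x, di, dj) {
  d <- dim(x); n <- d[2L]
  out <- array(0, d)
  i1 <- max(1L, 1L - di); i2 <- min(n, n - di)
  j1 <- max(1L, 1L - dj); j2 <- min(n, n - dj)
  if (i1 <= i2 && j1 <= j2)
    out[, i1:i2, j1:j2, ] <-
      x[, (i1 + di):(i2 + di), (j1 + dj):(j2 + dj), , drop = FALSE]
  out
}

# forward returns the shifted input matrices so backward need not recompute
conv2d_fwd <- function(x, params, off, keep_cols = TRUE) {
  d <- dim(x); nm <- d[1L] * d[2L] * d[3L]
  K <- length(params$b)
  out <- matrix(rep(params$b, each = nm), nm, K)
  cols <- if (keep_cols) vector("list", nrow(off)) else NULL
  for (k in seq_len(nrow(off))) {
    xs <- if (off[k, 1L] == 0L && off[k, 2L] == 0L) matrix(x, nm, d[4L])
          else matrix(shift2(x, off[k, 1L], off[k, 2L]), nm, d[4L])
    if (keep_cols) cols[[k]] <- xs
    out <- out + xs %*% params[[k]]
  }
  list(z = array(out, c(d[1L], d[2L], d[3L], K)), cols = cols, d = d)
}

conv2d_bwd <- function(dout, fwd, params, off) {
  d <- fwd$d; nm <- d[1L] * d[2L] * d[3L]
  K <- length(params$b)
  dom <- matrix(dout, nm, K)
  grads <- list()
  dx <- array(0, d)
  for (k in seq_len(nrow(off))) {
    grads[[names(params)[k]]] <- crossprod(fwd$cols[[k]], dom)
    dxk <- array(dom %*% t(params[[k]]), d)
    dx <- dx + if (off[k, 1L] == 0L && off[k, 2L] == 0L) dxk
               else shift2(dxk, -off[k, 1L], -off[k, 2L])
  }
  grads$b <- colSums(dom)
  list(dx = dx, grads = grads)
}

sigm <- function(x) 1 / (1 + exp(-x))

lstm_dir <- function(x, Wx, Wh, b, reverse = FALSE) {
  d <- dim(x); N <- d[1L]; L <- d[2L]; H <- nrow(Wh)
  ts <- if (reverse) L:1 else 1:L
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  hs <- array(0, c(N, L, H))
  cache <- vector("list", L)
  for (t in ts) {
    xt <- matrix(x[, t, ], N, d[3L])
    z <- xt %*% Wx + h %*% Wh + matrix(rep(b, each = N), N)
    i <- sigm(z[, 1:H, drop = FALSE])
    f <- sigm(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigm(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    hs[, t, ] <- h
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c = cc, tc = tc, c_prev = c_prev, h_prev = h_prev)
  }
  list(h = hs, cache = cache, ts = ts)
}

lstm_dir_bwd <- function(dh_seq, fw, Wx, Wh) {
  ts <- rev(fw$ts)
  L <- length(ts)
  ex <- fw$cache[[fw$ts[1L]]]$xt
  N <- nrow(ex); H <- nrow(Wh); C <- ncol(ex)
  dWx <- matrix(0, C, 4L * H); dWh <- matrix(0, H, 4L * H); db <- numeric(4L * H)
  dh_next <- matrix(0, N, H); dc_next <- matrix(0, N, H)
  dx <- array(0, c(N, L, C))
  for (t in ts) {
    cc <- fw$cache[[t]]
    dh <- matrix(dh_seq[, t, ], N, H) + dh_next
    do <- dh * cc$tc * cc$o * (1 - cc$o)
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g * cc$i * (1 - cc$i)
    df <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dc * cc$i * (1 - cc$g^2)
    dz <- cbind(di, df, dg, do)
    dWx <- dWx + crossprod(cc$xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(Wx)
    dh_next <- dz %*% t(Wh)
    dc_next <- dc * cc$f
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

layer_forward <- function(layer, x, train = FALSE) {
  p <- layer$params
  switch(layer$type,
    dense = {
      xdim <- dim(x)
      if (length(xdim) == 3L) # per-position head on sequence output
        x <- matrix(x, xdim[1L] * xdim[2L], xdim[3L])
      z <- x %*% p$W + matrix(rep(p$b, each = nrow(x)), nrow(x))
      out <- if (layer$act == "relu") pmax(z, 0) else z
      list(out = out, cache = list(x = x, z = z, xdim = xdim))
    },
    conv1d = {
      d <- dim(x); N <- d[1L]; L <- d[2L]; C <- d[3L]; w <- layer$width
      Lo <- L - w + 1L
      col <- matrix(0, N * Lo, w * C) # im2col over valid positions
      for (o in seq_len(w))
        col[, ((o - 1L) * C + 1L):(o * C)] <-
          matrix(x[, o:(o + Lo - 1L), , drop = FALSE], N * Lo, C)
      z <- col %*% p$W + matrix(rep(p$b, each = N * Lo), N * Lo)
      out <- array(pmax(z, 0), c(N, Lo, ncol(z)))
      list(out = out, cache = list(col = col, z = z, d = d, Lo = Lo))
    },
    maxpool1d = {
      d <- dim(x); N <- d[1L]; L <- d[2L]; K <- d[3L]
      xm <- matrix(aperm(x, c(2L, 1L, 3L)), L) # L x (N*K)
      idx <- max.col(t(xm), ties.method = "first")
      out <- matrix(xm[cbind(idx, seq_along(idx))], N, K)
      list(out = out, cache = list(idx = idx, d = d))
    },
    lstm_bi = {
      f <- lstm_dir(x, p$Wx_f, p$Wh_f, p$b_f, FALSE)
      b <- lstm_dir(x, p$Wx_b, p$Wh_b, p$b_b, TRUE)
      d <- dim(x); H <- layer$hidden
      out <- array(0, c(d[1L], d[2L], 2L * H))
      out[, , 1:H] <- f$h
      out[, , (H + 1):(2 * H)] <- b$h
      list(out = out, cache = list(f = f, b = b))
    },
    conv2d = {
      f <- conv2d_fwd(x, p, layer$off, keep_cols = train)
      out <- if (layer$act == "relu") pmax(f$z, 0) else f$z
      list(out = out, cache = list(f = f))
    },
    res2d = {
      p1 <- list(p$W1_1, p$W2_1, p$W3_1, p$W4_1, p$W5_1, p$W6_1, p$W7_1,
                 p$W8_1, p$W9_1, b = p$b_1)
      names(p1)[1:9] <- paste0("W", 1:9)
      p2 <- list(p$W1_2, p$W2_2, p$W3_2, p$W4_2, p$W5_2, p$W6_2, p$W7_2,
                 p$W8_2, p$W9_2, b = p$b_2)
      names(p2)[1:9] <- paste0("W", 1:9)
      f1 <- conv2d_fwd(x, p1, layer$off, keep_cols = train)
      h <- pmax(f1$z, 0)
      f2 <- conv2d_fwd(h, p2, layer$off, keep_cols = train)
      z2 <- f2$z + x
      out <- pmax(z2, 0)
      list(out = out, cache = list(f1 = f1, f2 = f2, z2 = z2,
                                   p1 = p1, p2 = p2))
    },
    bilstm2d = {
      d <- dim(x); N <- d[1L]; n <- d[2L]; C <- d[4L]; H <- layer$hidden
      pr <- list(Wx_f = p$Wx_f_r, Wh_f = p$Wh_f_r, b_f = p$b_f_r,
                 Wx_b = p$Wx_b_r, Wh_b = p$Wh_b_r, b_b = p$b_b_r)
      pc <- list(Wx_f = p$Wx_f_c, Wh_f = p$Wh_f_c, b_f = p$b_f_c,
                 Wx_b = p$Wx_b_c, Wh_b = p$Wh_b_c, b_b = p$b_b_c)
      lr <- list(type = "lstm_bi", hidden = H, params = pr)
      lc <- list(type = "lstm_bi", hidden = H, params = pc)
      # rows: batch (N*n) sequences of length n over channels C
      xr <- array(x, c(N * n, n, C))
      fr <- layer_forward(lr, xr, train)
      # columns: transpose the two spatial dims
      xc <- array(aperm(x, c(1L, 3L, 2L, 4L)), c(N * n, n, C))
      fc <- layer_forward(lc, xc, train)
      out <- array(0, c(N, n, n, 4L * H))
      out[, , , 1:(2 * H)] <- array(fr$out, c(N, n, n, 2L * H))
      out[, , , (2 * H + 1):(4 * H)] <-
        aperm(array(fc$out, c(N, n, n, 2L * H)), c(1L, 3L, 2L, 4L))
      list(out = out, cache = list(fr = fr, fc = fc, lr = lr, lc = lc, d = d))
    },
    stop("unknown layer type ", layer$type))
}

layer_backward <- function(layer, dout, cache) {
  p <- layer$params
  switch(layer$type,
    dense = {
      dz <- if (layer$act == "relu") dout * (cache$z > 0) else dout
      dx <- dz %*% t(p$W)
      if (length(cache$xdim) == 3L) dx <- array(dx, cache$xdim)
      list(dx = dx,
           grads = list(W = crossprod(cache$x, dz), b = colSums(dz)))
    },
    conv1d = {
      d <- cache$d; N <- d[1L]; C <- d[3L]; w <- layer$width; Lo <- cache$Lo
      K <- length(p$b)
      dz <- matrix(dout, N * Lo, K) * (cache$z > 0)
      dcol <- dz %*% t(p$W)
      dx <- array(0, d)
      for (o in seq_len(w))
        dx[, o:(o + Lo - 1L), ] <- dx[, o:(o + Lo - 1L), , drop = FALSE] +
          array(dcol[, ((o - 1L) * C + 1L):(o * C)], c(N, Lo, C))
      list(dx = dx,
           grads = list(W = crossprod(cache$col, dz), b = colSums(dz)))
    },
    maxpool1d = {
      d <- cache$d
      dxm <- matrix(0, d[2L], d[1L] * d[3L])
      dxm[cbind(cache$idx, seq_along(cache$idx))] <- as.vector(dout)
      list(dx = aperm(array(dxm, c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L)),
           grads = list())
    },
    lstm_bi = {
      H <- layer$hidden
      bf <- lstm_dir_bwd(dout[, , 1:H, drop = FALSE], cache$f, p$Wx_f, p$Wh_f)
      bb <- lstm_dir_bwd(dout[, , (H + 1):(2 * H), drop = FALSE], cache$b,
                         p$Wx_b, p$Wh_b)
      list(dx = bf$dx + bb$dx,
           grads = list(Wx_f = bf$dWx, Wh_f = bf$dWh, b_f = bf$db,
                        Wx_b = bb$dWx, Wh_b = bb$dWh, b_b = bb$db))
    },
    conv2d = {
      dz <- if (layer$act == "relu") dout * (cache$f$z > 0) else dout
      conv2d_bwd(dz, cache$f, p, layer$off)
    },
    res2d = {
      dz2 <- dout * (cache$z2 > 0)
      b2 <- conv2d_bwd(dz2, cache$f2, cache$p2, layer$off)
      dz1 <- b2$dx * (cache$f1$z > 0)
      b1 <- conv2d_bwd(dz1, cache$f1, cache$p1, layer$off)
      g <- c(stats::setNames(b1$grads, paste0(names(b1$grads), "_1")),
             stats::setNames(b2$grads, paste0(names(b2$grads), "_2")))
      list(dx = b1$dx + dz2, grads = g)
    },
    bilstm2d = {
      d <- cache$d; N <- d[1L]; n <- d[2L]; H <- layer$hidden
      dr <- array(dout[, , , 1:(2 * H), drop = FALSE], c(N * n, n, 2L * H))
      dc <- array(aperm(dout[, , , (2 * H + 1):(4 * H), drop = FALSE],
                        c(1L, 3L, 2L, 4L)), c(N * n, n, 2L * H))
      br <- layer_backward(cache$lr, dr, cache$fr$cache)
      bc <- layer_backward(cache$lc, dc, cache$fc$cache)
      dxr <- array(br$dx, c(N, n, n, d[4L]))
      dxc <- aperm(array(bc$dx, c(N, n, n, d[4L])), c(1L, 3L, 2L, 4L))
      g <- c(stats::setNames(br$grads, paste0(names(br$grads), "_r")),
             stats::setNames(bc$grads, paste0(names(bc$grads), "_c")))
      list(dx = dxr + dxc, grads = g)
    },
    stop("unknown layer type ", layer$type))
}

forward_model <- function(model, x, train = FALSE) {
  caches <- vector("list", length(model$layers))
  for (k in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[k]], x, train)
    x <- r$out
    caches[[k]] <- r$cache
  }
  list(out = x, caches = caches)
}

backward_model <- function(model, dout, caches) {
  grads <- vector("list", length(model$layers))
  for (k in rev(seq_along(model$layers))) {
    r <- layer_backward(model$layers[[k]], dout, caches[[k]])
    dout <- r$dx
    grads[[k]] <- r$grads
  }
  grads
}

# ---- loss and optimizer ----

# numerically stable binary cross-entropy on logits; returns loss and dlogits.
# pos_weight rescales the positive class (NA = auto-balance to the batch's
# negative/positive ratio), the standard remedy for the sparse-pair imbalance
# of base-pair matrices.
bce_logits <- function(z, y, pos_weight = 1) {
  if (is.na(pos_weight)) {
    npos <- sum(y)
    pos_weight <- if (npos > 0 && npos < length(y))
      (length(y) - npos) / npos else 1
  }
  w <- ifelse(y == 1, pos_weight, 1)
  sw <- sum(w)
  loss <- sum(w * (pmax(z, 0) - z * y + log1p(exp(-abs(z))))) / sw
  dz <- w * (sigm(z) - y) / sw
  list(loss = loss, dz = dz)
}

adam_init <- function(model) {
  model$adam <- lapply(model$layers, function(l)
    lapply(l$params, function(p) list(m = p * 0, v = p * 0)))
  model$adam_t <- 0L
  invisible(model)
}

adam_step <- function(model, grads, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  model$adam_t <- model$adam_t + 1L
  t <- model$adam_t
  for (k in seq_along(model$layers)) {
    for (nm in names(grads[[k]])) {
      g <- grads[[k]][[nm]]
      st <- model$adam[[k]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      model$adam[[k]][[nm]] <- st
      model$layers[[k]]$params[[nm]] <-
        model$layers[[k]]$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(model)
}

get_params <- function(model) lapply(model$layers, `[[`, "params")
set_params <- function(model, params) {
  for (k in seq_along(params)) model$layers[[k]]$params <- params[[k]]
  invisible(model)
}
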
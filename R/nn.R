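# Minimal neural-network engine: GRU / LSTM / vanilla-RNN sequence
# classifiers and a small CNN, with hand-derived reverse-mode gradients and
# an Adam optimizer. All heavy operations are dense matrix products, so the
# engine rides on BLAS; sequences are processed as lists of per-timestep
# B x F matrices. Deterministic given the R RNG state.

sigmoid <- function(x) 1 / (1 + exp(-x))

# add a bias row-vector to every row of M (column-major recycling trick)
add_bias <- function(M, b) M + rep(b, each = nrow(M))

glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

## ---- parameter initialization ----

init_recurrent_params <- function(variant, input_dim, layers, units) {
  p <- list()
  din <- input_dim
  gates <- switch(variant,
                  GRU = c("z", "r", "c"),
                  LSTM = c("i", "f", "o", "g"),
                  RNN = c(""))
  for (l in seq_len(layers)) {
    for (g in gates) {
      p[[sprintf("l%d.W%s", l, g)]] <- glorot(din, units)
      p[[sprintf("l%d.U%s", l, g)]] <- glorot(units, units)
      b <- numeric(units)
      if (variant == "LSTM" && g == "f") b[] <- 1  # standard forget-gate bias
      p[[sprintf("l%d.b%s", l, g)]] <- b
    }
    din <- units
  }
  p
}

init_cnn_params <- function(input_shape, filters = c(32L, 64L)) {
  # two 3x3 conv blocks with 2x2 max-pooling on the 1-channel feature image
  H <- input_shape[1L]; W <- input_shape[2L]
  if (H < 4L || W < 2L)
    stop("CNN variant needs an input of at least 4 x 2; got ", H, " x ", W)
  p <- list()
  p[["conv1.W"]] <- array(stats::runif(9 * 1 * filters[1L],
                                       -sqrt(6 / (9 + filters[1L])),
                                       sqrt(6 / (9 + filters[1L]))),
                          c(3L, 3L, 1L, filters[1L]))
  p[["conv1.b"]] <- numeric(filters[1L])
  p[["conv2.W"]] <- array(stats::runif(9 * filters[1L] * filters[2L],
                                       -sqrt(6 / (9 * filters[1L] + filters[2L])),
                                       sqrt(6 / (9 * filters[1L] + filters[2L]))),
                          c(3L, 3L, filters[1L], filters[2L]))
  p[["conv2.b"]] <- numeric(filters[2L])
  p
}

## ---- recurrent layer forward/backward ----

rnn_layer_forward <- function(p, l, xs) {
  W <- p[[sprintf("l%d.W", l)]]; U <- p[[sprintf("l%d.U", l)]]
  b <- p[[sprintf("l%d.b", l)]]
  Tn <- length(xs); B <- nrow(xs[[1L]]); H <- ncol(U)
  h <- matrix(0, B, H)
  hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    h <- tanh(add_bias(xs[[t]] %*% W + h %*% U, b))
    hs[[t]] <- h
  }
  list(hs = hs)
}

rnn_layer_backward <- function(p, l, xs, fwd, dhs, need_dx) {
  W <- p[[sprintf("l%d.W", l)]]; U <- p[[sprintf("l%d.U", l)]]
  hs <- fwd$hs
  Tn <- length(xs); B <- nrow(xs[[1L]]); H <- ncol(U)
  dW <- W * 0; dU <- U * 0; db <- numeric(H)
  dxs <- if (need_dx) vector("list", Tn) else NULL
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    dh <- dh_next
    if (!is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    da <- dh * (1 - hs[[t]]^2)
    hprev <- if (t > 1L) hs[[t - 1L]] else matrix(0, B, H)
    dW <- dW + crossprod(xs[[t]], da)
    dU <- dU + crossprod(hprev, da)
    db <- db + colSums(da)
    if (need_dx) dxs[[t]] <- tcrossprod(da, W)
    dh_next <- tcrossprod(da, U)
  }
  g <- list(); g[[sprintf("l%d.W", l)]] <- dW
  g[[sprintf("l%d.U", l)]] <- dU; g[[sprintf("l%d.b", l)]] <- db
  list(grads = g, dxs = dxs)
}

gru_layer_forward <- function(p, l, xs) {
  nm <- function(s) p[[sprintf("l%d.%s", l, s)]]
  Wz <- nm("Wz"); Uz <- nm("Uz"); bz <- nm("bz")
  Wr <- nm("Wr"); Ur <- nm("Ur"); br <- nm("br")
  Wc <- nm("Wc"); Uc <- nm("Uc"); bc <- nm("bc")
  Tn <- length(xs); B <- nrow(xs[[1L]]); H <- ncol(Uz)
  h <- matrix(0, B, H)
  hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- xs[[t]]
    z <- sigmoid(add_bias(x %*% Wz + h %*% Uz, bz))
    r <- sigmoid(add_bias(x %*% Wr + h %*% Ur, br))
    cc <- tanh(add_bias(x %*% Wc + (r * h) %*% Uc, bc))
    cache[[t]] <- list(z = z, r = r, cc = cc, hprev = h)
    h <- (1 - z) * h + z * cc
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

gru_layer_backward <- function(p, l, xs, fwd, dhs, need_dx) {
  nm <- function(s) p[[sprintf("l%d.%s", l, s)]]
  Wz <- nm("Wz"); Uz <- nm("Uz"); Wr <- nm("Wr"); Ur <- nm("Ur")
  Wc <- nm("Wc"); Uc <- nm("Uc")
  Tn <- length(xs); B <- nrow(xs[[1L]]); H <- ncol(Uz)
  dWz <- Wz * 0; dUz <- Uz * 0; dbz <- numeric(H)
  dWr <- Wr * 0; dUr <- Ur * 0; dbr <- numeric(H)
  dWc <- Wc * 0; dUc <- Uc * 0; dbc <- numeric(H)
  dxs <- if (need_dx) vector("list", Tn) else NULL
  dh_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    ch <- fwd$cache[[t]]
    z <- ch$z; r <- ch$r; cc <- ch$cc; hprev <- ch$hprev
    dh <- dh_next
    if (!is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    dz <- dh * (cc - hprev)
    dcc <- dh * z
    dhprev <- dh * (1 - z)
    dac <- dcc * (1 - cc^2)
    dWc <- dWc + crossprod(xs[[t]], dac)
    dUc <- dUc + crossprod(r * hprev, dac)
    dbc <- dbc + colSums(dac)
    drh <- tcrossprod(dac, Uc)
    dr <- drh * hprev
    dhprev <- dhprev + drh * r
    daz <- dz * z * (1 - z)
    dar <- dr * r * (1 - r)
    dWz <- dWz + crossprod(xs[[t]], daz)
    dUz <- dUz + crossprod(hprev, daz)
    dbz <- dbz + colSums(daz)
    dWr <- dWr + crossprod(xs[[t]], dar)
    dUr <- dUr + crossprod(hprev, dar)
    dbr <- dbr + colSums(dar)
    if (need_dx)
      dxs[[t]] <- tcrossprod(daz, Wz) + tcrossprod(dar, Wr) +
        tcrossprod(dac, Wc)
    dh_next <- dhprev + tcrossprod(daz, Uz) + tcrossprod(dar, Ur)
  }
  g <- list()
  g[[sprintf("l%d.Wz", l)]] <- dWz; g[[sprintf("l%d.Uz", l)]] <- dUz
  g[[sprintf("l%d.bz", l)]] <- dbz
  g[[sprintf("l%d.Wr", l)]] <- dWr; g[[sprintf("l%d.Ur", l)]] <- dUr
  g[[sprintf("l%d.br", l)]] <- dbr
  g[[sprintf("l%d.Wc", l)]] <- dWc; g[[sprintf("l%d.Uc", l)]] <- dUc
  g[[sprintf("l%d.bc", l)]] <- dbc
  list(grads = g, dxs = dxs)
}

lstm_layer_forward <- function(p, l, xs) {
  nm <- function(s) p[[sprintf("l%d.%s", l, s)]]
  Tn <- length(xs); B <- nrow(xs[[1L]]); H <- ncol(nm("Ui"))
  h <- matrix(0, B, H); cs <- matrix(0, B, H)
  hs <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- xs[[t]]
    i <- sigmoid(add_bias(x %*% nm("Wi") + h %*% nm("Ui"), nm("bi")))
    f <- sigmoid(add_bias(x %*% nm("Wf") + h %*% nm("Uf"), nm("bf")))
    o <- sigmoid(add_bias(x %*% nm("Wo") + h %*% nm("Uo"), nm("bo")))
    g <- tanh(add_bias(x %*% nm("Wg") + h %*% nm("Ug"), nm("bg")))
    csn <- f * cs + i * g
    tc <- tanh(csn)
    cache[[t]] <- list(i = i, f = f, o = o, g = g, cprev = cs, tc = tc,
                       hprev = h)
    cs <- csn
    h <- o * tc
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

lstm_layer_backward <- function(p, l, xs, fwd, dhs, need_dx) {
  nm <- function(s) p[[sprintf("l%d.%s", l, s)]]
  Tn <- length(xs); B <- nrow(xs[[1L]]); H <- ncol(nm("Ui"))
  gnames <- c("i", "f", "o", "g")
  dW <- list(); dU <- list(); db <- list()
  for (g in gnames) {
    dW[[g]] <- nm(paste0("W", g)) * 0
    dU[[g]] <- nm(paste0("U", g)) * 0
    db[[g]] <- numeric(H)
  }
  dxs <- if (need_dx) vector("list", Tn) else NULL
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    ch <- fwd$cache[[t]]
    dh <- dh_next
    if (!is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    do_ <- dh * ch$tc
    dc <- dc_next + dh * ch$o * (1 - ch$tc^2)
    di <- dc * ch$g
    dg <- dc * ch$i
    df <- dc * ch$cprev
    dc_next <- dc * ch$f
    da <- list(i = di * ch$i * (1 - ch$i),
               f = df * ch$f * (1 - ch$f),
               o = do_ * ch$o * (1 - ch$o),
               g = dg * (1 - ch$g^2))
    dx <- NULL
    dh_next <- matrix(0, B, H)
    for (g in gnames) {
      dW[[g]] <- dW[[g]] + crossprod(xs[[t]], da[[g]])
      dU[[g]] <- dU[[g]] + crossprod(ch$hprev, da[[g]])
      db[[g]] <- db[[g]] + colSums(da[[g]])
      if (need_dx) {
        dd <- tcrossprod(da[[g]], nm(paste0("W", g)))
        dx <- if (is.null(dx)) dd else dx + dd
      }
      dh_next <- dh_next + tcrossprod(da[[g]], nm(paste0("U", g)))
    }
    if (need_dx) dxs[[t]] <- dx
  }
  gl <- list()
  for (g in gnames) {
    gl[[sprintf("l%d.W%s", l, g)]] <- dW[[g]]
    gl[[sprintf("l%d.U%s", l, g)]] <- dU[[g]]
    gl[[sprintf("l%d.b%s", l, g)]] <- db[[g]]
  }
  list(grads = gl, dxs = dxs)
}

recurrent_layer_forward <- function(variant, p, l, xs) {
  switch(variant,
         GRU = gru_layer_forward(p, l, xs),
         LSTM = lstm_layer_forward(p, l, xs),
         RNN = rnn_layer_forward(p, l, xs))
}

recurrent_layer_backward <- function(variant, p, l, xs, fwd, dhs, need_dx) {
  switch(variant,
         GRU = gru_layer_backward(p, l, xs, fwd, dhs, need_dx),
         LSTM = lstm_layer_backward(p, l, xs, fwd, dhs, need_dx),
         RNN = rnn_layer_backward(p, l, xs, fwd, dhs, need_dx))
}

## ---- CNN layers ----

conv2d_forward <- function(X, W, b) {
  # X: B x H x Wd x Cin; W: 3 x 3 x Cin x Cout; zero ("same") padding
  d <- dim(X); B <- d[1L]; H <- d[2L]; Wd <- d[3L]; Cin <- d[4L]
  Cout <- dim(W)[4L]
  out <- array(0, c(B, H, Wd, Cout))
  for (di in -1:1) for (dj in -1:1) {
    io <- max(1L, 1L - di):min(H, H - di)
    jo <- max(1L, 1L - dj):min(Wd, Wd - dj)
    ii <- io + di; jj <- jo + dj
    M <- matrix(X[, ii, jj, , drop = FALSE], ncol = Cin)
    Wm <- matrix(W[di + 2L, dj + 2L, , ], Cin, Cout)
    out[, io, jo, ] <- out[, io, jo, , drop = FALSE] +
      array(M %*% Wm, c(B, length(io), length(jo), Cout))
  }
  sweep(out, 4L, b, "+")
}

conv2d_backward <- function(X, W, dOut) {
  d <- dim(X); B <- d[1L]; H <- d[2L]; Wd <- d[3L]; Cin <- d[4L]
  Cout <- dim(W)[4L]
  dX <- array(0, dim(X))
  dW <- array(0, dim(W))
  for (di in -1:1) for (dj in -1:1) {
    io <- max(1L, 1L - di):min(H, H - di)
    jo <- max(1L, 1L - dj):min(Wd, Wd - dj)
    ii <- io + di; jj <- jo + dj
    M <- matrix(X[, ii, jj, , drop = FALSE], ncol = Cin)
    dM <- matrix(dOut[, io, jo, , drop = FALSE], ncol = Cout)
    Wm <- matrix(W[di + 2L, dj + 2L, , ], Cin, Cout)
    dW[di + 2L, dj + 2L, , ] <- crossprod(M, dM)
    dX[, ii, jj, ] <- dX[, ii, jj, , drop = FALSE] +
      array(tcrossprod(dM, Wm), c(B, length(ii), length(jj), Cin))
  }
  db <- apply(dOut, 4L, sum)
  list(dX = dX, dW = dW, db = db)
}

maxpool2_forward <- function(X) {
  # 2x2/stride-2 max pooling; odd extents are padded with -Inf so the last
  # window degenerates to size 1 (output dims are ceiling(dim / 2))
  d0 <- dim(X)
  Hp <- d0[2L] + d0[2L] %% 2L
  Wp <- d0[3L] + d0[3L] %% 2L
  if (Hp != d0[2L] || Wp != d0[3L]) {
    Xp <- array(-Inf, c(d0[1L], Hp, Wp, d0[4L]))
    Xp[, seq_len(d0[2L]), seq_len(d0[3L]), ] <- X
    X <- Xp
  }
  d <- dim(X); B <- d[1L]; H <- d[2L]; Wd <- d[3L]; C <- d[4L]
  i1 <- seq(1L, H, 2L); i2 <- i1 + 1L
  j1 <- seq(1L, Wd, 2L); j2 <- j1 + 1L
  A <- list(X[, i1, j1, , drop = FALSE], X[, i1, j2, , drop = FALSE],
            X[, i2, j1, , drop = FALSE], X[, i2, j2, , drop = FALSE])
  # argmax over the 2x2 window: first index attaining the max
  which_max <- array(1L, dim(A[[1L]]))
  best <- A[[1L]]
  for (k in 2:4) {
    upd <- A[[k]] > best
    which_max[upd] <- k
    best[upd] <- A[[k]][upd]
  }
  list(out = best, which_max = which_max, in_dim = d, orig_dim = d0)
}

maxpool2_backward <- function(pool, dOut) {
  d <- pool$in_dim
  dX <- array(0, d)
  i1 <- seq(1L, d[2L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[3L], 2L); j2 <- j1 + 1L
  sel <- list(list(i1, j1), list(i1, j2), list(i2, j1), list(i2, j2))
  for (k in 1:4) {
    mask <- pool$which_max == k
    g <- dOut * mask
    dX[, sel[[k]][[1L]], sel[[k]][[2L]], ] <-
      dX[, sel[[k]][[1L]], sel[[k]][[2L]], , drop = FALSE] + g
  }
  o <- pool$orig_dim
  dX[, seq_len(o[2L]), seq_len(o[3L]), , drop = FALSE]
}

## ---- full-model forward / backward ----

# xs: list of T matrices (B x F). Returns logits and cache.
nn_forward <- function(params, cfg, xs, train = FALSE, dropout_mask = NULL) {
  cache <- list(xs = xs)
  if (cfg$variant == "CNN") {
    Tn <- length(xs); B <- nrow(xs[[1L]]); Fd <- ncol(xs[[1L]])
    X <- array(0, c(B, Tn, Fd, 1L))
    for (t in seq_len(Tn)) X[, t, , 1L] <- xs[[t]]
    Z1 <- conv2d_forward(X, params[["conv1.W"]], params[["conv1.b"]])
    A1 <- pmax(Z1, 0)
    P1 <- maxpool2_forward(A1)
    Z2 <- conv2d_forward(P1$out, params[["conv2.W"]], params[["conv2.b"]])
    A2 <- pmax(Z2, 0)
    P2 <- maxpool2_forward(A2)
    hfinal <- matrix(P2$out, B, prod(dim(P2$out)[-1L]))
    cache$cnn <- list(X = X, Z1 = Z1, A1 = A1, P1 = P1, Z2 = Z2, A2 = A2,
                      P2 = P2)
  } else {
    layer_in <- xs
    fwd <- vector("list", cfg$recurrent_layers)
    ins <- vector("list", cfg$recurrent_layers)
    for (l in seq_len(cfg$recurrent_layers)) {
      ins[[l]] <- layer_in
      fwd[[l]] <- recurrent_layer_forward(cfg$variant, params, l, layer_in)
      layer_in <- fwd[[l]]$hs
    }
    # second (last) layer returns only its final state
    hfinal <- fwd[[cfg$recurrent_layers]]$hs[[length(xs)]]
    cache$fwd <- fwd
    cache$ins <- ins
  }
  if (train && cfg$dropout > 0) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(stats::rbinom(length(hfinal), 1L,
                                           1 - cfg$dropout) /
                               (1 - cfg$dropout),
                             nrow(hfinal), ncol(hfinal))
    hfinal <- hfinal * dropout_mask
    cache$dropout_mask <- dropout_mask
  }
  A <- pmax(add_bias(hfinal %*% params[["fc.W"]], params[["fc.b"]]), 0)
  logits <- add_bias(A %*% params[["out.W"]], params[["out.b"]])
  cache$hfinal <- hfinal
  cache$A <- A
  list(logits = logits, cache = cache)
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# y: integer vector in 1..K. Returns loss (mean NLL) and dlogits.
softmax_xent <- function(logits, y) {
  p <- softmax_rows(logits)
  B <- nrow(p)
  idx <- cbind(seq_len(B), y)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / B, probs = p)
}

nn_backward <- function(params, cfg, fw, dlogits) {
  cache <- fw$cache
  grads <- list()
  grads[["out.W"]] <- crossprod(cache$A, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  dA <- tcrossprod(dlogits, params[["out.W"]])
  dA <- dA * (cache$A > 0)
  grads[["fc.W"]] <- crossprod(cache$hfinal, dA)
  grads[["fc.b"]] <- colSums(dA)
  dh <- tcrossprod(dA, params[["fc.W"]])
  if (!is.null(cache$dropout_mask)) dh <- dh * cache$dropout_mask

  if (cfg$variant == "CNN") {
    cn <- cache$cnn
    dP2 <- array(dh, dim(cn$P2$out))
    dA2 <- maxpool2_backward(cn$P2, dP2)
    dZ2 <- dA2 * (cn$Z2 > 0)
    bk2 <- conv2d_backward(cn$P1$out, params[["conv2.W"]], dZ2)
    grads[["conv2.W"]] <- bk2$dW
    grads[["conv2.b"]] <- bk2$db
    dA1 <- maxpool2_backward(cn$P1, bk2$dX)
    dZ1 <- dA1 * (cn$Z1 > 0)
    bk1 <- conv2d_backward(cn$X, params[["conv1.W"]], dZ1)
    grads[["conv1.W"]] <- bk1$dW
    grads[["conv1.b"]] <- bk1$db
  } else {
    Tn <- length(cache$xs)
    L <- cfg$recurrent_layers
    dhs <- vector("list", Tn)
    dhs[[Tn]] <- dh
    for (l in rev(seq_len(L))) {
      bk <- recurrent_layer_backward(cfg$variant, params, l, cache$ins[[l]],
                                     cache$fwd[[l]], dhs, need_dx = l > 1L)
      grads <- c(grads, bk$grads)
      if (l > 1L) dhs <- bk$dxs
    }
  }
  grads
}

## ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
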
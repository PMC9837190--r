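# Minimal neural-network engine for the presence decoders: LSTM and CNN
# forward/backward passes, batch normalization, Adam, and the DNK-masked
# KL-divergence loss head. Everything operates on batches; matrices go
# through BLAS. Layouts: batch is always the first array dimension; an
# array (B, H, W, C) flattens to a (B, H*W*C) matrix by column-major
# reshape, so reshapes are free.

sigm <- function(x) 1 / (1 + exp(-x))
lrelu <- function(x) pmax(x, 0.01 * x)
dlrelu <- function(x) ifelse(x > 0, 1, 0.01)

# ---- batch normalization (per feature column) ----

bn_forward <- function(x, gamma, beta, run, training, momentum = 0.1,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, invstd, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       run = run)
}

bn_backward <- function(dy, cache) {
  xhat <- cache$xhat
  n <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, `*`)
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), n, ncol(dy),
                              byrow = TRUE),
              2, cache$invstd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- LSTM layer (input B x T x N array) ----

lstm_forward_layer <- function(X, Wx, Wh, b) {
  B <- dim(X)[1]; TT <- dim(X)[2]; N <- dim(X)[3]
  H <- nrow(Wh)
  XW <- matrix(X, B * TT, N) %*% Wx            # (B*T) x 4H, rows b-fastest
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hs <- array(0, c(B, TT, H))
  cache <- vector("list", TT)
  bmat <- matrix(b, B, 4 * H, byrow = TRUE)
  ii <- seq_len(H)
  for (t in seq_len(TT)) {
    Z <- XW[(t - 1) * B + seq_len(B), , drop = FALSE] + h %*% Wh + bmat
    i <- sigm(Z[, ii]); f <- sigm(Z[, H + ii])
    g <- tanh(Z[, 2 * H + ii]); o <- sigm(Z[, 3 * H + ii])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = cc, tc = tc,
                       h_prev = h)
    h <- o * tc
    cc <- c_new
    Hs[, t, ] <- h
  }
  list(Hs = Hs, cache = cache)
}

lstm_backward_layer <- function(X, fwd, Wx, Wh, dHs) {
  B <- dim(X)[1]; TT <- dim(X)[2]; N <- dim(X)[3]
  H <- nrow(Wh)
  dZ_all <- matrix(0, B * TT, 4 * H)
  dWh <- matrix(0, H, 4 * H)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  ii <- seq_len(H)
  for (t in rev(seq_len(TT))) {
    cc <- fwd$cache[[t]]
    dh <- dHs[, t, ] + dh_next
    if (is.null(dim(dh))) dh <- matrix(dh, B, H)
    do <- dh * cc$tc * cc$o * (1 - cc$o)
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g * cc$i * (1 - cc$i)
    dg <- dc * cc$i * (1 - cc$g^2)
    df <- dc * cc$c_prev * cc$f * (1 - cc$f)
    dc_next <- dc * cc$f
    dZ <- cbind(di, df, dg, do)
    dZ_all[(t - 1) * B + seq_len(B), ] <- dZ
    dWh <- dWh + crossprod(cc$h_prev, dZ)
    dh_next <- dZ %*% t(Wh)
  }
  Xmat <- matrix(X, B * TT, N)
  dWx <- crossprod(Xmat, dZ_all)
  db <- colSums(dZ_all)
  dX <- array(dZ_all %*% t(Wx), c(B, TT, N))
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# ---- 3x3 valid convolution ----
# The kernel is stored as a (9*Cin) x Cout matrix; rows for tap (dy, dx)
# and input channel cin sit at (cin-1)*9 + (dx-1)*3 + dy. The convolution
# is computed as nine accumulated shifted matrix products, which avoids
# materialising an im2col patch tensor.

conv3_tap_rows <- function(dy, dx, Cin) {
  (seq_len(Cin) - 1) * 9 + (dx - 1) * 3 + dy
}

conv3_slice <- function(X, dy, dx, H2, W2) {
  sl <- X[, dy:(dy + H2 - 1), dx:(dx + W2 - 1), , drop = FALSE]
  dim(sl) <- c(dim(X)[1] * H2 * W2, dim(X)[4])
  sl
}

conv3_forward <- function(X, W, b) {
  d <- dim(X)
  H2 <- d[2] - 2; W2 <- d[3] - 2
  Ym <- matrix(b, d[1] * H2 * W2, ncol(W), byrow = TRUE)
  for (dx in 1:3) for (dy in 1:3) {
    rows <- conv3_tap_rows(dy, dx, d[4])
    Ym <- Ym + conv3_slice(X, dy, dx, H2, W2) %*% W[rows, , drop = FALSE]
  }
  list(Y = array(Ym, c(d[1], H2, W2, ncol(W))), X = X, dimX = d)
}

conv3_backward <- function(dY, cache, W) {
  d <- cache$dimX
  H2 <- d[2] - 2; W2 <- d[3] - 2
  dYm <- matrix(dY, d[1] * H2 * W2)
  dW <- matrix(0, nrow(W), ncol(W))
  dX <- array(0, d)
  for (dx in 1:3) for (dy in 1:3) {
    rows <- conv3_tap_rows(dy, dx, d[4])
    sl <- conv3_slice(cache$X, dy, dx, H2, W2)
    dW[rows, ] <- crossprod(sl, dYm)
    dsl <- dYm %*% t(W[rows, , drop = FALSE])
    dim(dsl) <- c(d[1], H2, W2, d[4])
    dX[, dy:(dy + H2 - 1), dx:(dx + W2 - 1), ] <-
      dX[, dy:(dy + H2 - 1), dx:(dx + W2 - 1), , drop = FALSE] + dsl
  }
  list(dW = dW, db = colSums(dYm), dX = dX)
}

maxpool2_forward <- function(X) {
  d <- dim(X)
  H2 <- d[2] %/% 2; W2 <- d[3] %/% 2
  oy <- seq(1, 2 * H2, 2); ox <- seq(1, 2 * W2, 2)
  a <- X[, oy, ox, , drop = FALSE]; b <- X[, oy + 1, ox, , drop = FALSE]
  cc <- X[, oy, ox + 1, , drop = FALSE]; dd <- X[, oy + 1, ox + 1,
                                                 , drop = FALSE]
  Y <- pmax(a, b, cc, dd)
  list(Y = Y, parts = list(a, b, cc, dd), dimX = d, H2 = H2, W2 = W2)
}

maxpool2_backward <- function(dY, cache) {
  d <- cache$dimX
  H2 <- cache$H2; W2 <- cache$W2
  oy <- seq(1, 2 * H2, 2); ox <- seq(1, 2 * W2, 2)
  Y <- pmax(cache$parts[[1]], cache$parts[[2]], cache$parts[[3]],
            cache$parts[[4]])
  dX <- array(0, d)
  taken <- array(FALSE, dim(Y))
  offs <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (k in 1:4) {
    m <- (cache$parts[[k]] == Y) & !taken
    taken <- taken | m
    dX[, oy + offs[[k]][1], ox + offs[[k]][2], ] <- dY * m
  }
  dX
}

# ---- DNK-masked KLD loss head ----

# logits: B x (n_char * 3), column (c-1)*3 + l for character c, label l
# (1 = YES, 2 = NO, 3 = DNK). Row-wise softmax per character block.
softmax_blocks <- function(logits, n_char) {
  P <- logits
  for (c in seq_len(n_char)) {
    cols <- (c - 1) * 3 + 1:3
    blk <- logits[, cols, drop = FALSE]
    blk <- exp(blk - apply(blk, 1, max))
    P[, cols] <- blk / rowSums(blk)
  }
  P
}

# Mean over characters of KL(one-hot truth || prediction); a character with
# a DNK truth contributes zero. Returns the batch-mean loss and the
# gradient with respect to the logits.
masked_kld_loss <- function(logits, y, n_char, eps = 1e-8) {
  B <- nrow(logits)
  P <- softmax_blocks(logits, n_char)
  dlogits <- matrix(0, B, ncol(logits))
  loss <- 0
  for (c in seq_len(n_char)) {
    cols <- (c - 1) * 3 + 1:3
    truth <- y[, c]
    live <- truth != LBL_DNK
    if (!any(live)) next
    p_true <- P[cbind(seq_len(B), cols[1] + truth - 1)]
    loss <- loss + sum(-log(pmax(p_true[live], eps)))
    onehot <- matrix(0, B, 3)
    onehot[cbind(seq_len(B), truth)] <- 1
    g <- (P[, cols, drop = FALSE] - onehot) * live
    dlogits[, cols] <- g / (n_char * B)
  }
  list(loss = loss / (n_char * B), dlogits = dlogits, P = P)
}

# Per-sample, per-character loss vector (no gradient); DNK entries are 0.
kld_per_character <- function(P, y, n_char, eps = 1e-8) {
  B <- nrow(P)
  out <- matrix(0, B, n_char)
  for (c in seq_len(n_char)) {
    cols <- (c - 1) * 3 + 1:3
    live <- y[, c] != LBL_DNK
    p_true <- P[cbind(seq_len(B), cols[1] + y[, c] - 1)]
    out[live, c] <- -log(pmax(p_true[live], eps))
  }
  out
}

# ---- Adam ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  for (k in names(params)) {
    g <- grads[[k]]
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g^2
    mhat <- st$m[[k]] / (1 - b1^st$t)
    vhat <- st$v[[k]] / (1 - b2^st$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, st = st)
}

# ---- weight initialisation ----

init_uniform <- function(nr, nc, fan_in) {
  a <- sqrt(1 / fan_in)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

init_gauss <- function(nr, nc, sd = 0.1) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}
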
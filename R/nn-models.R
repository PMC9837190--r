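# LSTM and CNN decoder architectures assembled from the nn-core pieces.
# Both map a (batch, 60, n_units) rate window to a (n_char x 3) score
# matrix with a per-character softmax.

nn_init <- function(arch = c("lstm", "cnn"), n_units, steps = 60,
                    n_char = 4, hidden = 128, fc_dim = 128,
                    channels = c(16, 32, 64), seed = 1L) {
  arch <- match.arg(arch)
  with_seed(seed, {
    out_dim <- n_char * 3
    if (arch == "lstm") {
      params <- list(
        l1_Wx = init_uniform(n_units, 4 * hidden, hidden),
        l1_Wh = init_uniform(hidden, 4 * hidden, hidden),
        l1_b = rep(0, 4 * hidden),
        l2_Wx = init_uniform(hidden, 4 * hidden, hidden),
        l2_Wh = init_uniform(hidden, 4 * hidden, hidden),
        l2_b = rep(0, 4 * hidden),
        fc1_W = init_uniform(hidden, fc_dim, hidden),
        fc1_b = rep(0, fc_dim),
        bn1_gamma = rep(1, fc_dim), bn1_beta = rep(0, fc_dim),
        fc2_W = init_uniform(fc_dim, out_dim, fc_dim),
        fc2_b = rep(0, out_dim))
      # a positive forget-gate bias helps early training
      params$l1_b[hidden + seq_len(hidden)] <- 1
      params$l2_b[hidden + seq_len(hidden)] <- 1
      run <- list(bn1 = list(mean = rep(0, fc_dim), var = rep(1, fc_dim)))
    } else {
      c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
      h3 <- steps - 6; w3 <- n_units - 6
      if (w3 < 2 || h3 < 2) stop_cfg("input too small for the CNN stack")
      flat <- (h3 %/% 2) * (w3 %/% 2) * c3
      params <- list(
        cv1_W = init_gauss(9, c1), cv1_b = rep(0, c1),
        bnc1_gamma = rep(1, c1), bnc1_beta = rep(0, c1),
        cv2_W = init_gauss(9 * c1, c2), cv2_b = rep(0, c2),
        bnc2_gamma = rep(1, c2), bnc2_beta = rep(0, c2),
        cv3_W = init_gauss(9 * c2, c3), cv3_b = rep(0, c3),
        bnc3_gamma = rep(1, c3), bnc3_beta = rep(0, c3),
        fc1_W = init_uniform(flat, fc_dim, flat),
        fc1_b = rep(0, fc_dim),
        bn1_gamma = rep(1, fc_dim), bn1_beta = rep(0, fc_dim),
        fc2_W = init_uniform(fc_dim, out_dim, fc_dim),
        fc2_b = rep(0, out_dim))
      run <- list(
        bnc1 = list(mean = rep(0, c1), var = rep(1, c1)),
        bnc2 = list(mean = rep(0, c2), var = rep(1, c2)),
        bnc3 = list(mean = rep(0, c3), var = rep(1, c3)),
        bn1 = list(mean = rep(0, fc_dim), var = rep(1, fc_dim)))
    }
    list(arch = arch, params = params, run = run, n_units = n_units,
         steps = steps, n_char = n_char, hidden = hidden, fc_dim = fc_dim,
         channels = channels)
  })
}

addb <- function(x, b) sweep(x, 2, b, `+`)

net_forward <- function(net, X, training = FALSE) {
  p <- net$params
  run <- net$run
  B <- dim(X)[1]
  if (net$arch == "lstm") {
    l1 <- lstm_forward_layer(X, p$l1_Wx, p$l1_Wh, p$l1_b)
    l2 <- lstm_forward_layer(l1$Hs, p$l2_Wx, p$l2_Wh, p$l2_b)
    hT <- matrix(l2$Hs[, dim(X)[2], ], B)
    z1 <- addb(hT %*% p$fc1_W, p$fc1_b)
    bn <- bn_forward(z1, p$bn1_gamma, p$bn1_beta, run$bn1, training)
    run$bn1 <- bn$run
    a1 <- lrelu(bn$y)
    logits <- addb(a1 %*% p$fc2_W, p$fc2_b)
    cache <- list(X = X, l1 = l1, l2 = l2, hT = hT, bn = bn, a1 = a1,
                  bn_y = bn$y)
  } else {
    X4 <- array(X, c(dim(X), 1))
    cv1 <- conv3_forward(X4, p$cv1_W, p$cv1_b)
    d1 <- dim(cv1$Y)
    b1 <- bn_forward(matrix(cv1$Y, prod(d1[1:3])), p$bnc1_gamma,
                     p$bnc1_beta, run$bnc1, training)
    run$bnc1 <- b1$run
    a1c <- array(lrelu(b1$y), d1)
    cv2 <- conv3_forward(a1c, p$cv2_W, p$cv2_b)
    d2 <- dim(cv2$Y)
    b2 <- bn_forward(matrix(cv2$Y, prod(d2[1:3])), p$bnc2_gamma,
                     p$bnc2_beta, run$bnc2, training)
    run$bnc2 <- b2$run
    a2c <- array(lrelu(b2$y), d2)
    cv3 <- conv3_forward(a2c, p$cv3_W, p$cv3_b)
    d3 <- dim(cv3$Y)
    b3 <- bn_forward(matrix(cv3$Y, prod(d3[1:3])), p$bnc3_gamma,
                     p$bnc3_beta, run$bnc3, training)
    run$bnc3 <- b3$run
    a3c <- array(lrelu(b3$y), d3)
    mp <- maxpool2_forward(a3c)
    flat <- matrix(mp$Y, B)
    z1 <- addb(flat %*% p$fc1_W, p$fc1_b)
    bn <- bn_forward(z1, p$bn1_gamma, p$bn1_beta, run$bn1, training)
    run$bn1 <- bn$run
    a1 <- lrelu(bn$y)
    logits <- addb(a1 %*% p$fc2_W, p$fc2_b)
    cache <- list(X4 = X4, cv1 = cv1, b1 = b1, a1c = a1c, d1 = d1,
                  cv2 = cv2, b2 = b2, a2c = a2c, d2 = d2,
                  cv3 = cv3, b3 = b3, a3c = a3c, d3 = d3,
                  mp = mp, flat = flat, bn = bn, a1 = a1, bn_y = bn$y)
  }
  list(logits = logits, cache = cache, run = run)
}

net_backward <- function(net, cache, dlogits) {
  p <- net$params
  g <- list()
  g$fc2_W <- crossprod(cache$a1, dlogits)
  g$fc2_b <- colSums(dlogits)
  da1 <- dlogits %*% t(p$fc2_W)
  dbn_y <- da1 * dlrelu(cache$bn_y)
  bnb <- bn_backward(dbn_y, cache$bn$cache)
  g$bn1_gamma <- bnb$dgamma
  g$bn1_beta <- bnb$dbeta
  dz1 <- bnb$dx
  if (net$arch == "lstm") {
    g$fc1_W <- crossprod(cache$hT, dz1)
    g$fc1_b <- colSums(dz1)
    dhT <- dz1 %*% t(p$fc1_W)
    TT <- dim(cache$X)[2]
    dHs2 <- array(0, dim(cache$l2$Hs))
    dHs2[, TT, ] <- dhT
    bk2 <- lstm_backward_layer(cache$l1$Hs, cache$l2, p$l2_Wx, p$l2_Wh,
                               dHs2)
    g$l2_Wx <- bk2$dWx; g$l2_Wh <- bk2$dWh; g$l2_b <- bk2$db
    bk1 <- lstm_backward_layer(cache$X, cache$l1, p$l1_Wx, p$l1_Wh,
                               bk2$dX)
    g$l1_Wx <- bk1$dWx; g$l1_Wh <- bk1$dWh; g$l1_b <- bk1$db
  } else {
    g$fc1_W <- crossprod(cache$flat, dz1)
    g$fc1_b <- colSums(dz1)
    dflat <- dz1 %*% t(p$fc1_W)
    dmp <- array(dflat, dim(cache$mp$Y))
    da3c <- maxpool2_backward(dmp, cache$mp)
    db3y <- matrix(da3c, prod(cache$d3[1:3])) *
      dlrelu(cache$b3$y)
    b3b <- bn_backward(db3y, cache$b3$cache)
    g$bnc3_gamma <- b3b$dgamma; g$bnc3_beta <- b3b$dbeta
    c3b <- conv3_backward(array(b3b$dx, cache$d3), cache$cv3, p$cv3_W)
    g$cv3_W <- c3b$dW; g$cv3_b <- c3b$db
    db2y <- matrix(c3b$dX, prod(cache$d2[1:3])) * dlrelu(cache$b2$y)
    b2b <- bn_backward(db2y, cache$b2$cache)
    g$bnc2_gamma <- b2b$dgamma; g$bnc2_beta <- b2b$dbeta
    c2b <- conv3_backward(array(b2b$dx, cache$d2), cache$cv2, p$cv2_W)
    g$cv2_W <- c2b$dW; g$cv2_b <- c2b$db
    db1y <- matrix(c2b$dX, prod(cache$d1[1:3])) * dlrelu(cache$b1$y)
    b1b <- bn_backward(db1y, cache$b1$cache)
    g$bnc1_gamma <- b1b$dgamma; g$bnc1_beta <- b1b$dbeta
    c1b <- conv3_backward(array(b1b$dx, cache$d1), cache$cv1, p$cv1_W)
    g$cv1_W <- c1b$dW; g$cv1_b <- c1b$db
  }
  g
}

# Predicted per-character label distributions for samples `idx`, in eval
# mode, batched. Returns an n x (n_char*3) probability matrix.
net_predict <- function(net, ws, idx, knock_units = NULL,
                        knock_values = NULL, batch_size = 256) {
  out <- matrix(0, length(idx), net$n_char * 3)
  at <- 1
  while (at <= length(idx)) {
    ids <- idx[at:min(at + batch_size - 1, length(idx))]
    X <- window_batch(ws, ids, knock_units, knock_values)
    fwd <- net_forward(net, X, training = FALSE)
    out[at:(at + length(ids) - 1), ] <-
      softmax_blocks(fwd$logits, net$n_char)
    at <- at + length(ids)
  }
  out
}

# Macro-averaged F1 of binarized YES activations against YES truth,
# DNK pairs excluded. P is an n x (n_char*3) probability matrix.
macro_f1 <- function(P, y, n_char) {
  f1s <- vapply(seq_len(n_char), function(c) {
    act <- P[, (c - 1) * 3 + 1]
    live <- y[, c] != LBL_DNK
    pred <- act[live] > 0.5
    truth <- y[live, c] == LBL_YES
    tp <- sum(pred & truth)
    if (tp == 0) return(0)
    prec <- tp / sum(pred)
    rec <- tp / sum(truth)
    2 / (1 / rec + 1 / prec)
  }, 0)
  mean(f1s)
}

# Core training loop: Adam on the DNK-masked KLD loss, epoch-wise model
# selection by validation macro F1.
nn_train_core <- function(net, ws, train_idx, val_idx, epochs = 100,
                          batch_size = 64, lr = 1e-3, seed = 1L,
                          patience = Inf, verbose = FALSE) {
  with_seed(seed, {
    adam <- adam_init(net$params)
    best <- list(f1 = -Inf, params = net$params, run = net$run, epoch = 0)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_f1 = numeric(0))
    stale <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample(train_idx)
      tot_loss <- 0; n_seen <- 0
      for (at in seq(1, length(ord), by = batch_size)) {
        ids <- ord[at:min(at + batch_size - 1, length(ord))]
        if (length(ids) < 2) next   # batch norm needs > 1 sample
        X <- window_batch(ws, ids)
        y <- ws$labels[ids, , drop = FALSE]
        fwd <- net_forward(net, X, training = TRUE)
        net$run <- fwd$run
        lg <- masked_kld_loss(fwd$logits, y, net$n_char)
        grads <- net_backward(net, fwd$cache, lg$dlogits)
        upd <- adam_step(net$params, grads, adam, lr)
        net$params <- upd$params
        adam <- upd$st
        tot_loss <- tot_loss + lg$loss * length(ids)
        n_seen <- n_seen + length(ids)
      }
      P_val <- net_predict(net, ws, val_idx)
      f1 <- macro_f1(P_val, ws$labels[val_idx, , drop = FALSE], net$n_char)
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = tot_loss / n_seen,
                                           val_f1 = f1))
      if (verbose) {
        message(sprintf("epoch %d loss %.4f val F1 %.3f", ep,
                        tot_loss / n_seen, f1))
      }
      if (f1 > best$f1) {
        best <- list(f1 = f1, params = net$params, run = net$run,
                     epoch = ep)
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= patience) break
      }
    }
    net$params <- best$params
    net$run <- best$run
    net$best_epoch <- best$epoch
    net$val_f1 <- best$f1
    net$history <- history
    net
  })
}
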
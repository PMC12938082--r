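# Minimal neural-network machinery: Adam, a softmax head, and a
# bidirectional LSTM classifier with hand-written backpropagation. Sizes
# here are desk-scale (hundreds of samples, 9-step sequences), so plain R
# matrix algebra is fast enough.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(p, y_onehot) {
  -mean(rowSums(y_onehot * log(pmax(p, 1e-12))))
}

onehot <- function(y, K) {
  m <- matrix(0, length(y), K)
  m[cbind(seq_along(y), y)] <- 1
  m
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mh <- state$m[[k]] / (1 - beta1^state$t)
    vh <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

# ---- softmax head (multinomial logistic regression on frozen features) ----

softmax_head_model <- function(d, K, l2 = 0) {
  list(
    init = function() list(W = matrix(0, d, K), b = matrix(0, 1L, K)),
    predict = function(params, X)
      softmax_rows(X %*% params$W +
                     matrix(params$b, nrow(X), K, byrow = TRUE)),
    loss_grad = function(params, X, Y, train = TRUE) {
      p <- softmax_rows(X %*% params$W +
                          matrix(params$b, nrow(X), K, byrow = TRUE))
      loss <- cross_entropy(p, Y) +
        if (l2 > 0) l2 * sum(params$W^2) else 0
      dlogit <- (p - Y) / nrow(X)
      list(loss = loss,
           grads = list(W = crossprod(X, dlogit) + 2 * l2 * params$W,
                        b = matrix(colSums(dlogit), 1L)))
    })
}

# ---- bidirectional LSTM classifier ----
# input: n x T x D array; BiLSTM(H) -> concat final states (2H) ->
# FC(fc_units, ReLU, dropout, L2) -> softmax(K).

lstm_init_dir <- function(D, H) {
  s <- sqrt(1 / (D + H))
  W <- matrix(rnorm(4 * H * (D + H), sd = s), 4L * H, D + H)
  b <- matrix(0, 4L * H, 1L)
  b[(H + 1L):(2L * H), 1L] <- 1  # forget-gate bias init
  list(W = W, b = b)
}

bilstm_model <- function(D, K, H = 256L, fc_units = 512L, l2 = 1e-4,
                         dropout = 0.5) {
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2L * H + idx_i
  idx_o <- 3L * H + idx_i

  fwd_dir <- function(W, b, xs) {
    Tn <- length(xs); nb <- ncol(xs[[1L]])
    h <- matrix(0, H, nb); cc <- matrix(0, H, nb)
    cache <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      inp <- rbind(xs[[t]], h)
      z <- W %*% inp + matrix(b, 4L * H, nb)
      i <- sigmoid(z[idx_i, , drop = FALSE])
      f <- sigmoid(z[idx_f, , drop = FALSE])
      g <- tanh(z[idx_g, , drop = FALSE])
      o <- sigmoid(z[idx_o, , drop = FALSE])
      c_prev <- cc
      cc <- f * c_prev + i * g
      tc <- tanh(cc)
      h_new <- o * tc
      cache[[t]] <- list(inp = inp, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, tc = tc)
      h <- h_new
    }
    list(h = h, cache = cache)
  }

  bwd_dir <- function(W, dh_T, cache) {
    Tn <- length(cache); nb <- ncol(dh_T)
    dW <- W * 0; db <- matrix(0, 4L * H, 1L)
    dh <- dh_T; dc <- matrix(0, H, nb)
    for (t in rev(seq_len(Tn))) {
      cv <- cache[[t]]
      do_ <- dh * cv$tc
      dc <- dc + dh * cv$o * (1 - cv$tc^2)
      di <- dc * cv$g
      dg <- dc * cv$i
      df <- dc * cv$c_prev
      dc <- dc * cv$f
      dz <- rbind(di * cv$i * (1 - cv$i),
                  df * cv$f * (1 - cv$f),
                  dg * (1 - cv$g^2),
                  do_ * cv$o * (1 - cv$o))
      dW <- dW + dz %*% t(cv$inp)
      db <- db + rowSums(dz)
      dh <- t(W[, (D + 1L):(D + H), drop = FALSE]) %*% dz
    }
    list(dW = dW, db = db)
  }

  to_steps <- function(X, reverse = FALSE) {
    # X: nb x T x D -> list of T matrices D x nb
    Tn <- dim(X)[2]
    ord <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
    lapply(ord, function(t) t(X[, t, , drop = TRUE]))
  }

  forward_full <- function(params, X, train = TRUE) {
    nb <- dim(X)[1]
    ff <- fwd_dir(params$Wf, params$bf, to_steps(X, FALSE))
    fb <- fwd_dir(params$Wb, params$bb, to_steps(X, TRUE))
    z <- rbind(ff$h, fb$h)                       # 2H x nb
    a1 <- params$W1 %*% z + matrix(params$b1, fc_units, nb)
    r1 <- pmax(a1, 0)
    if (train && dropout > 0) {
      mask <- matrix(stats::rbinom(fc_units * nb, 1L, 1 - dropout),
                     fc_units, nb) / (1 - dropout)
      r1d <- r1 * mask
    } else {
      mask <- NULL
      r1d <- r1
    }
    logits <- params$W2 %*% r1d + matrix(params$b2, K, nb)
    list(ff = ff, fb = fb, z = z, a1 = a1, r1 = r1, mask = mask, r1d = r1d,
         logits = logits)
  }

  list(
    init = function() {
      df <- lstm_init_dir(D, H); db_ <- lstm_init_dir(D, H)
      s1 <- sqrt(2 / (2 * H))
      list(Wf = df$W, bf = df$b, Wb = db_$W, bb = db_$b,
           W1 = matrix(rnorm(fc_units * 2 * H, sd = s1), fc_units, 2L * H),
           b1 = matrix(0, fc_units, 1L),
           W2 = matrix(rnorm(K * fc_units, sd = sqrt(2 / fc_units)),
                       K, fc_units),
           b2 = matrix(0, K, 1L))
    },
    predict = function(params, X) {
      fw <- forward_full(params, X, train = FALSE)
      softmax_rows(t(fw$logits))  # nb x K
    },
    loss_grad = function(params, X, Y, train = TRUE) {
      nb <- dim(X)[1]
      fw <- forward_full(params, X, train = train)
      p <- t(softmax_rows(t(fw$logits)))         # K x nb
      loss <- cross_entropy(t(p), Y) +
        l2 * (sum(params$W1^2) + sum(params$W2^2))
      dlogit <- (p - t(Y)) / nb                  # K x nb
      gW2 <- dlogit %*% t(fw$r1d) + 2 * l2 * params$W2
      gb2 <- matrix(rowSums(dlogit), K, 1L)
      dr1d <- t(params$W2) %*% dlogit
      dr1 <- if (is.null(fw$mask)) dr1d else dr1d * fw$mask
      da1 <- dr1 * (fw$a1 > 0)
      gW1 <- da1 %*% t(fw$z) + 2 * l2 * params$W1
      gb1 <- matrix(rowSums(da1), fc_units, 1L)
      dz <- t(params$W1) %*% da1                 # 2H x nb
      gf <- bwd_dir(params$Wf, dz[seq_len(H), , drop = FALSE], fw$ff$cache)
      gb_ <- bwd_dir(params$Wb, dz[(H + 1L):(2L * H), , drop = FALSE],
                     fw$fb$cache)
      list(loss = loss,
           grads = list(Wf = gf$dW, bf = gf$db, Wb = gb_$dW, bb = gb_$db,
                        W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2))
    })
}

# ---- generic epoch loop with early stopping and reduce-on-plateau ----

subset_inputs <- function(X, idx) {
  if (is.matrix(X)) X[idx, , drop = FALSE] else X[idx, , , drop = FALSE]
}

train_nn <- function(model, X, y, Xval, yval, K, config) {
  Y <- onehot(y, K)
  Yval <- onehot(yval, K)
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  params <- model$init()
  opt <- adam_init(params)
  lr <- config$learning_rate
  best <- list(loss = Inf, params = params, epoch = 0L)
  since_best <- 0L; since_lr <- 0L
  history <- data.frame()
  lr_events <- data.frame(epoch = integer(0), lr = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    for (b0 in seq(1L, n, by = config$batch_size)) {
      bi <- idx[b0:min(b0 + config$batch_size - 1L, n)]
      lg <- model$loss_grad(params, subset_inputs(X, bi),
                            Y[bi, , drop = FALSE], train = TRUE)
      st <- adam_step(params, lg$grads, opt, lr)
      params <- st$params; opt <- st$state
    }
    ptr <- model$predict(params, X)
    pv <- model$predict(params, Xval)
    tr_loss <- cross_entropy(ptr, Y)
    va_loss <- cross_entropy(pv, Yval)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr,
      train_loss = tr_loss,
      train_acc = mean(max.col(ptr) == y),
      val_loss = va_loss,
      val_acc = mean(max.col(pv) == yval)))
    if (va_loss < best$loss - 1e-9) {
      best <- list(loss = va_loss, params = params, epoch = epoch)
      since_best <- 0L; since_lr <- 0L
    } else {
      since_best <- since_best + 1L
      since_lr <- since_lr + 1L
      if (since_lr >= config$lr_patience && lr > config$lr_min) {
        lr <- max(lr * config$lr_factor, config$lr_min)
        lr_events <- rbind(lr_events, data.frame(epoch = epoch, lr = lr))
        since_lr <- 0L
      }
      if (since_best >= config$patience) break
    }
  }
  list(params = best$params, best_epoch = best$epoch,
       best_val_loss = best$loss, history = history, lr_events = lr_events)
}
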
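# Minimal batched recurrent-network engine used by the baseline regressor and
# the methylation classifier. Dense linear algebra only (BLAS-backed); all
# randomness goes through R's RNG so seeded fits are reproducible.
#
# Conventions: batches are arrays [B, T, C] (batch, time, channel). A GRU cell
# holds Wx (3H x C), Wh (3H x H), bx, bh (3H), gate order r, z, n:
#   r_t = sigmoid(Wx_r x_t + bx_r + Wh_r h_{t-1} + bh_r)
#   z_t = sigmoid(Wx_z x_t + bx_z + Wh_z h_{t-1} + bh_z)
#   n_t = tanh(Wx_n x_t + bx_n + r_t * (Wh_n h_{t-1} + bh_n))
#   h_t = (1 - z_t) * n_t + z_t * h_{t-1}

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform(-k, k), k = 1/sqrt(hidden) -- the standard GRU init
nn_gru_cell_init <- function(input_dim, hidden) {
  k <- 1 / sqrt(hidden)
  list(
    Wx = matrix(stats::runif(3 * hidden * input_dim, -k, k), 3 * hidden, input_dim),
    Wh = matrix(stats::runif(3 * hidden * hidden, -k, k), 3 * hidden, hidden),
    bx = stats::runif(3 * hidden, -k, k),
    bh = stats::runif(3 * hidden, -k, k)
  )
}

nn_linear_init <- function(input_dim, output_dim) {
  k <- 1 / sqrt(input_dim)
  list(
    W = matrix(stats::runif(output_dim * input_dim, -k, k), output_dim, input_dim),
    b = stats::runif(output_dim, -k, k)
  )
}

nn_bigru_init <- function(input_dim, hidden, layers) {
  out <- vector("list", layers)
  d <- input_dim
  for (l in seq_len(layers)) {
    out[[l]] <- list(
      f = nn_gru_cell_init(d, hidden),
      b = nn_gru_cell_init(d, hidden)
    )
    d <- 2L * hidden
  }
  list(layers = out, hidden = hidden, n_layers = layers, input_dim = input_dim)
}

nn_rev_time <- function(X) {
  X[, dim(X)[2]:1, , drop = FALSE]
}

# One direction over the full sequence. Input projections for all timesteps
# are computed in a single matmul; only the recurrence loops.
nn_gru_forward <- function(cell, X) {
  dd <- dim(X)
  B <- dd[1]; Tn <- dd[2]; C <- dd[3]
  H <- ncol(cell$Wh)
  Xf <- matrix(X, B * Tn, C)
  XP <- Xf %*% t(cell$Wx)
  XP <- XP + rep(cell$bx, each = B * Tn)
  tWh <- t(cell$Wh)
  bh_add <- rep(cell$bh, each = B)
  i_r <- seq_len(H); i_z <- H + i_r; i_n <- 2L * H + i_r
  Hseq <- array(0, c(B, Tn, H))
  caches <- vector("list", Tn)
  h <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    xp <- XP[(t - 1L) * B + seq_len(B), , drop = FALSE]
    gh <- h %*% tWh
    gh <- gh + bh_add
    r <- nn_sigmoid(xp[, i_r, drop = FALSE] + gh[, i_r, drop = FALSE])
    z <- nn_sigmoid(xp[, i_z, drop = FALSE] + gh[, i_z, drop = FALSE])
    s <- gh[, i_n, drop = FALSE]
    n <- tanh(xp[, i_n, drop = FALSE] + r * s)
    hp <- h
    h <- (1 - z) * n + z * hp
    Hseq[, t, ] <- h
    caches[[t]] <- list(r = r, z = z, n = n, s = s, hp = hp)
  }
  list(H = Hseq, caches = caches, Xf = Xf, dims = c(B, Tn, C, H))
}

# Backpropagation through time. dH is [B, T, H]: the gradient of the loss
# w.r.t. every emitted hidden state (zeros where unused).
nn_gru_backward <- function(cell, fw, dH) {
  B <- fw$dims[1]; Tn <- fw$dims[2]; C <- fw$dims[3]; H <- fw$dims[4]
  dXP <- matrix(0, B * Tn, 3L * H)
  dWh <- matrix(0, 3L * H, H)
  dbh <- numeric(3L * H)
  dh <- matrix(0, B, H)
  for (t in Tn:1) {
    cc <- fw$caches[[t]]
    dh <- dh + matrix(dH[, t, ], B, H)
    dz <- dh * (cc$hp - cc$n)
    dn <- dh * (1 - cc$z)
    dhp <- dh * cc$z
    dan <- dn * (1 - cc$n^2)
    dr <- dan * cc$s
    ds <- dan * cc$r
    dar <- dr * cc$r * (1 - cc$r)
    daz <- dz * cc$z * (1 - cc$z)
    dGH <- cbind(dar, daz, ds)
    dhp <- dhp + dGH %*% cell$Wh
    dWh <- dWh + crossprod(dGH, cc$hp)
    dbh <- dbh + colSums(dGH)
    dXP[(t - 1L) * B + seq_len(B), ] <- cbind(dar, daz, dan)
    dh <- dhp
  }
  dWx <- crossprod(dXP, fw$Xf)
  dbx <- colSums(dXP)
  dX <- array(dXP %*% cell$Wx, c(B, Tn, C))
  list(grads = list(Wx = dWx, Wh = dWh, bx = dbx, bh = dbh), dX = dX)
}

# Stacked bidirectional pass. Readout = [h_fwd(T), h_bwd(1)] of the top layer.
# Inter-layer (inverted) dropout is applied only during training.
nn_bigru_forward <- function(net, X, dropout = 0, training = FALSE) {
  H <- net$hidden
  L <- net$n_layers
  B <- dim(X)[1]; Tn <- dim(X)[2]
  store <- vector("list", L)
  inp <- X
  for (l in seq_len(L)) {
    ff <- nn_gru_forward(net$layers[[l]]$f, inp)
    fb <- nn_gru_forward(net$layers[[l]]$b, nn_rev_time(inp))
    Hb <- nn_rev_time(fb$H)
    out <- array(0, c(B, Tn, 2L * H))
    out[, , seq_len(H)] <- ff$H
    out[, , H + seq_len(H)] <- Hb
    mask <- NULL
    if (l < L && training && dropout > 0) {
      mask <- array(stats::rbinom(length(out), 1L, 1 - dropout) / (1 - dropout),
                    dim(out))
      out <- out * mask
    }
    store[[l]] <- list(ff = ff, fb = fb, Hb = Hb, mask = mask)
    inp <- out
  }
  read <- cbind(matrix(store[[L]]$ff$H[, Tn, ], B, H),
                matrix(store[[L]]$Hb[, 1, ], B, H))
  list(read = read, store = store, B = B, Tn = Tn)
}

nn_bigru_backward <- function(net, fwd, dread) {
  H <- net$hidden
  L <- net$n_layers
  B <- fwd$B; Tn <- fwd$Tn
  grads <- vector("list", L)
  dout <- NULL  # gradient w.r.t. the concatenated output of the layer below
  for (l in L:1) {
    st <- fwd$store[[l]]
    dHf <- array(0, c(B, Tn, H))
    dHb <- array(0, c(B, Tn, H))
    if (l == L) {
      dHf[, Tn, ] <- dread[, seq_len(H), drop = FALSE]
      dHb[, 1, ] <- dread[, H + seq_len(H), drop = FALSE]
    }
    if (!is.null(dout)) {
      dHf <- dHf + dout[, , seq_len(H), drop = FALSE]
      dHb <- dHb + dout[, , H + seq_len(H), drop = FALSE]
    }
    gf <- nn_gru_backward(net$layers[[l]]$f, st$ff, dHf)
    gb <- nn_gru_backward(net$layers[[l]]$b, st$fb, nn_rev_time(dHb))
    dX <- gf$dX + nn_rev_time(gb$dX)
    grads[[l]] <- list(f = gf$grads, b = gb$grads)
    if (l > 1) {
      mask_below <- fwd$store[[l - 1]]$mask
      dout <- if (is.null(mask_below)) dX else dX * mask_below
    } else {
      dout <- dX
    }
  }
  list(layers = grads, dX = dout)
}

nn_linear_forward <- function(lin, x) {
  x %*% t(lin$W) + rep(lin$b, each = nrow(x))
}

nn_linear_backward <- function(lin, x, dy) {
  list(grads = list(W = crossprod(dy, x), b = colSums(dy)),
       dx = dy %*% lin$W)
}

# ---- Adam over arbitrarily nested parameter lists -------------------------

nn_adam_init <- function(params) {
  zero <- function(p) {
    if (is.list(p)) lapply(p, zero) else p * 0
  }
  list(m = zero(params), v = zero(params), t = 0L)
}

nn_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- step(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      p2 <- p - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps)
      # decoupled (AdamW-style) weight decay; biases are vectors and matrices
      # weights, so decay only the matrices
      if (weight_decay > 0 && is.matrix(p)) p2 <- p2 - lr * weight_decay * p
      list(p = p2, m = m2, v = v2)
    }
  }
  r <- step(params, grads, state$m, state$v)
  state$m <- r$m
  state$v <- r$v
  list(params = r$p, state = state)
}

# flatten parameters to one numeric vector and back (finite-difference checks)
nn_param_vec <- function(params) {
  unlist(params, use.names = FALSE)
}

nn_param_restore <- function(params, vec) {
  i <- 0L
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    n <- length(p)
    out <- vec[(i + 1L):(i + n)]
    i <<- i + n
    if (is.matrix(p)) dim(out) <- dim(p)
    out
  }
  walk(params)
}
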
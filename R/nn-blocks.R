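# Composite blocks: squeeze-and-excitation residual block, contextual
# transformer (CoT) attention block, bidirectional GRU.

# ---- squeeze-and-excitation module ---------------------------------------
#
# Squeeze: global mean over time per (record, channel).  Excitation: a
# two-layer bottleneck (reduction ratio r), ReLU then logistic, whose output
# gates each channel multiplicatively.

nn_se_module <- function(rng, c_ch, reduction = 16L) {
  ly <- nn_layer()
  hid <- max(1L, as.integer(round(c_ch / reduction)))
  ly$c <- c_ch
  ly$params <- list(W1 = he_init(rng, c_ch, c(c_ch, hid)), b1 = numeric(hid),
                    W2 = he_init(rng, hid, c(hid, c_ch)), b2 = numeric(c_ch))
  ly$grads <- lapply(ly$params, function(p) array(0, dim(p) %||% length(p)))

  ly$forward <- function(x, train = TRUE) {
    d <- dim(x); Tt <- d[1L]; B <- d[2L]
    s <- matrix(colMeans(matrix(x, Tt, B * ly$c)), B, ly$c)   # squeeze
    z1 <- s %*% ly$params$W1 + rep(ly$params$b1, each = B)
    a1 <- z1 * (z1 > 0)
    z2 <- a1 %*% ly$params$W2 + rep(ly$params$b2, each = B)
    g <- sigmoid(z2)                                          # excitation
    ly$cache <- list(x = x, s = s, z1 = z1, a1 = a1, g = g, d = d)
    x * array(rep(as.vector(g), each = Tt), d)
  }

  ly$backward <- function(dy) {
    cc <- ly$cache; d <- cc$d; Tt <- d[1L]; B <- d[2L]
    g_big <- array(rep(as.vector(cc$g), each = Tt), d)
    dx <- dy * g_big
    dg <- matrix(colSums(matrix(cc$x * dy, Tt, B * ly$c)), B, ly$c)
    dz2 <- dg * cc$g * (1 - cc$g)
    ly$grads$W2 <- ly$grads$W2 + crossprod(cc$a1, dz2)
    ly$grads$b2 <- ly$grads$b2 + colSums(dz2)
    da1 <- dz2 %*% t(ly$params$W2)
    dz1 <- da1 * (cc$z1 > 0)
    ly$grads$W1 <- ly$grads$W1 + crossprod(cc$s, dz1)
    ly$grads$b1 <- ly$grads$b1 + colSums(dz1)
    ds <- dz1 %*% t(ly$params$W1)
    dx + array(rep(as.vector(ds), each = Tt), d) / Tt
  }
  ly
}

# ---- SE residual block ---------------------------------------------------
#
# conv(k, stride) -> BN -> ReLU -> dropout -> conv(k, 1) -> BN -> SE
# -> + shortcut -> ReLU.  The shortcut is the identity when shape allows,
# otherwise a pointwise strided projection with its own BN.

nn_se_block <- function(rng, c_in, c_out, kernel = 7L, stride = 1L,
                        dropout = 0.2, se_reduction = 16L) {
  ly <- nn_layer()
  ly$conv1 <- nn_conv1d(rng, c_in, c_out, kernel, stride)
  ly$bn1 <- nn_batchnorm(c_out)
  ly$relu1 <- nn_relu()
  ly$drop <- nn_dropout(rng, dropout)
  ly$conv2 <- nn_conv1d(rng, c_out, c_out, kernel, 1L)
  ly$bn2 <- nn_batchnorm(c_out)
  ly$se <- nn_se_module(rng, c_out, se_reduction)
  ly$proj <- if (stride != 1L || c_in != c_out) {
    list(conv = nn_conv1d(rng, c_in, c_out, 1L, stride), bn = nn_batchnorm(c_out))
  } else NULL
  ly$relu_out <- nn_relu()
  ly$param_layers <- c(list(ly$conv1, ly$bn1, ly$conv2, ly$bn2, ly$se),
                   if (!is.null(ly$proj)) list(ly$proj$conv, ly$proj$bn))

  ly$forward <- function(x, train = TRUE) {
    h <- ly$conv1$forward(x, train)
    h <- ly$bn1$forward(h, train)
    h <- ly$relu1$forward(h, train)
    h <- ly$drop$forward(h, train)
    h <- ly$conv2$forward(h, train)
    h <- ly$bn2$forward(h, train)
    h <- ly$se$forward(h, train)
    sc <- if (is.null(ly$proj)) x
    else ly$proj$bn$forward(ly$proj$conv$forward(x, train), train)
    ly$relu_out$forward(h + sc, train)
  }

  ly$backward <- function(dy) {
    dsum <- ly$relu_out$backward(dy)
    dsc <- if (is.null(ly$proj)) dsum
    else ly$proj$conv$backward(ly$proj$bn$backward(dsum))
    dh <- ly$se$backward(dsum)
    dh <- ly$bn2$backward(dh)
    dh <- ly$conv2$backward(dh)
    dh <- ly$drop$backward(dh)
    dh <- ly$relu1$backward(dh)
    dh <- ly$bn1$backward(dh)
    dh <- ly$conv1$backward(dh)
    dh + dsc
  }
  ly
}

# ---- contextual transformer block ----------------------------------------
#
# For an input sequence E (with Q = E and K = E):
#   K1 = conv_k(K)                      static local context
#   V  = E W                            pointwise value embedding
#   A  = W_theta( relu( W_sigma([K1, Q]) ) )   attention map (pointwise)
#   K2 = V * A                          dynamic context (elementwise)
#   D  = proj([K1, K2])                 fused output, back to input width
# Time length and channel count are preserved, so the block is drop-in.

nn_cot_block <- function(rng, c_ch, cot_kernel = 3L) {
  stopifnot(is_odd(cot_kernel))
  ly <- nn_layer()
  ly$c <- c_ch
  ly$conv_k <- nn_conv1d(rng, c_ch, c_ch, cot_kernel, 1L)
  ly$conv_v <- nn_conv1d(rng, c_ch, c_ch, 1L, 1L)
  ly$conv_sig <- nn_conv1d(rng, 2L * c_ch, c_ch, 1L, 1L)
  ly$relu <- nn_relu()
  ly$conv_theta <- nn_conv1d(rng, c_ch, c_ch, 1L, 1L)
  ly$conv_proj <- nn_conv1d(rng, 2L * c_ch, c_ch, 1L, 1L)
  ly$param_layers <- list(ly$conv_k, ly$conv_v, ly$conv_sig, ly$conv_theta,
                      ly$conv_proj)

  ly$forward <- function(x, train = TRUE) {
    stop_if_not_finite(x, "CoT input")
    K1 <- ly$conv_k$forward(x, train)
    V <- ly$conv_v$forward(x, train)
    A <- ly$conv_theta$forward(
      ly$relu$forward(ly$conv_sig$forward(cat_channels(K1, x), train), train),
      train)
    K2 <- V * A
    ly$cache <- list(V = V, A = A)
    ly$conv_proj$forward(cat_channels(K1, K2), train)
  }

  ly$backward <- function(dy) {
    cc <- ly$cache
    dcat2 <- ly$conv_proj$backward(dy)
    parts2 <- split_channels(dcat2, ly$c)
    dK1 <- parts2[[1L]]; dK2 <- parts2[[2L]]
    dV <- dK2 * cc$A
    dA <- dK2 * cc$V
    dcat1 <- ly$conv_sig$backward(ly$relu$backward(ly$conv_theta$backward(dA)))
    parts1 <- split_channels(dcat1, ly$c)
    dK1 <- dK1 + parts1[[1L]]
    dx_q <- parts1[[2L]]
    ly$conv_k$backward(dK1) + ly$conv_v$backward(dV) + dx_q
  }
  ly
}

# ---- gated recurrent unit, one direction ---------------------------------
#
# Gate convention (r: reset, z: update, n: candidate):
#   r_t = sigma(x_t W_r + h_{t-1} U_r + b_r)
#   z_t = sigma(x_t W_z + h_{t-1} U_z + b_z)
#   n_t = tanh(x_t W_n + r_t * (h_{t-1} U_n) + b_n)
#   h_t = (1 - z_t) * n_t + z_t * h_{t-1}
# Only the final hidden state is consumed downstream.

nn_gru <- function(rng, c_in, hidden, reverse = FALSE) {
  ly <- nn_layer()
  ly$c_in <- c_in; ly$H <- as.integer(hidden); ly$reverse <- reverse
  H <- ly$H
  ly$params <- list(
    Wx = he_init(rng, c_in, c(c_in, 3L * H)),
    Wh = he_init(rng, hidden, c(H, 3L * H)),
    b = numeric(3L * H))
  ly$grads <- lapply(ly$params, function(p) array(0, dim(p) %||% length(p)))

  ly$forward <- function(x, train = TRUE) {
    d <- dim(x); Tt <- d[1L]; B <- d[2L]
    if (Tt < 1L) stop("GRU input has zero time steps")
    H <- ly$H
    steps <- if (ly$reverse) Tt:1L else 1L:Tt
    h <- matrix(0, B, H)
    cache <- vector("list", length(steps))
    ir <- seq_len(H); iz <- H + ir; inn <- 2L * H + ir
    for (s in seq_along(steps)) {
      xt <- matrix(x[steps[s], , ], B, ly$c_in)
      gx <- xt %*% ly$params$Wx + rep(ly$params$b, each = B)
      gh <- h %*% ly$params$Wh
      r <- sigmoid(gx[, ir, drop = FALSE] + gh[, ir, drop = FALSE])
      z <- sigmoid(gx[, iz, drop = FALSE] + gh[, iz, drop = FALSE])
      n <- tanh(gx[, inn, drop = FALSE] + r * gh[, inn, drop = FALSE])
      cache[[s]] <- list(xt = xt, h_prev = h, r = r, z = z, n = n,
                         ghn = gh[, inn, drop = FALSE])
      h <- (1 - z) * n + z * h
    }
    ly$cache <- cache
    ly$in_dim <- d
    h                                    # final hidden state (B x H)
  }

  ly$backward <- function(dh) {
    d <- ly$in_dim; Tt <- d[1L]; B <- d[2L]; H <- ly$H
    steps <- if (ly$reverse) Tt:1L else 1L:Tt
    dx <- array(0, d)
    for (s in rev(seq_along(steps))) {
      cc <- ly$cache[[s]]
      dz <- dh * (cc$h_prev - cc$n)
      dn <- dh * (1 - cc$z)
      dh_prev <- dh * cc$z
      dpre_n <- dn * (1 - cc$n^2)
      dr <- dpre_n * cc$ghn
      dghn <- dpre_n * cc$r
      dpre_r <- dr * cc$r * (1 - cc$r)
      dpre_z <- dz * cc$z * (1 - cc$z)
      dgx <- cbind(dpre_r, dpre_z, dpre_n)
      dgh <- cbind(dpre_r, dpre_z, dghn)
      ly$grads$Wx <- ly$grads$Wx + crossprod(cc$xt, dgx)
      ly$grads$b <- ly$grads$b + colSums(dgx)
      ly$grads$Wh <- ly$grads$Wh + crossprod(cc$h_prev, dgh)
      dx[steps[s], , ] <- dgx %*% t(ly$params$Wx)
      dh <- dh_prev + dgh %*% t(ly$params$Wh)
    }
    dx
  }
  ly
}

# ---- bidirectional GRU ---------------------------------------------------
#
# Runs a forward-direction and a backward-direction GRU over the sequence
# and concatenates their final hidden states into a 2*hidden feature vector
# per record.

nn_bigru <- function(rng, c_in, hidden) {
  ly <- nn_layer()
  ly$fwd <- nn_gru(rng, c_in, hidden, reverse = FALSE)
  ly$bwd <- nn_gru(rng, c_in, hidden, reverse = TRUE)
  ly$H <- as.integer(hidden)
  ly$param_layers <- list(ly$fwd, ly$bwd)
  ly$forward <- function(x, train = TRUE) {
    cbind(ly$fwd$forward(x, train), ly$bwd$forward(x, train))
  }
  ly$backward <- function(dh) {
    H <- ly$H
    ly$fwd$backward(dh[, seq_len(H), drop = FALSE]) +
      ly$bwd$backward(dh[, H + seq_len(H), drop = FALSE])
  }
  ly
}
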
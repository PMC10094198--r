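# Neural-network primitives.
#
# Sequence tensors are base-R arrays with dim (T, B, C): time, batch,
# channels.  Column-major layout makes (t, b) the fastest-varying pair, so a
# (T*B) x C matrix view of a tensor is a single `matrix()` call and every
# channel-wise operation is a matrix column operation.
#
# Each layer is an environment created by nn_* constructors exposing:
#   $forward(x, train)   -> output (caches what backward needs)
#   $backward(dy)        -> gradient w.r.t. input (fills $grads)
#   $params, $grads      -> named lists of arrays (same shapes)
# Parameters are updated in place by the Adam optimizer (nn_adam_step).
# Initialisation draws from the private rng stream passed to constructors,
# so a model is a deterministic function of its seed.

nn_layer <- function() {
  env <- new.env(parent = emptyenv())
  env$params <- list()
  env$grads <- list()
  env
}

he_init <- function(rng, fan_in, dims) {
  array(rng$rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- 1-D convolution (same padding, optional stride) ---------------------

nn_conv1d <- function(rng, c_in, c_out, kernel, stride = 1L) {
  stopifnot(kernel >= 1L, is_odd(kernel) || kernel == 1L)
  ly <- nn_layer()
  ly$c_in <- as.integer(c_in); ly$c_out <- as.integer(c_out)
  ly$k <- as.integer(kernel); ly$stride <- as.integer(stride)
  ly$pad <- (ly$k - 1L) %/% 2L
  ly$params <- list(W = he_init(rng, c_in * kernel, c(kernel * c_in, c_out)),
                    b = numeric(c_out))
  ly$grads <- list(W = array(0, dim(ly$params$W)), b = numeric(c_out))

  # im2col index matrix, cached per input shape
  ly$make_idx <- function(T_in, B) {
    key <- paste(T_in, B)
    if (!is.null(ly$idx_key) && ly$idx_key == key) return(invisible(NULL))
    Tp <- T_in + 2L * ly$pad
    To <- (Tp - ly$k) %/% ly$stride + 1L
    base_t <- (seq_len(To) - 1L) * ly$stride + 1L
    row0 <- rep(base_t, times = B) + rep((seq_len(B) - 1L) * Tp, each = To)
    off <- rep(0L:(ly$k - 1L), times = ly$c_in) +
      rep((seq_len(ly$c_in) - 1L) * (Tp * B), each = ly$k)
    ly$idx <- outer(row0, off, "+")
    ly$T_in <- T_in; ly$B <- B; ly$Tp <- Tp; ly$To <- To
    ly$idx_key <- key
    invisible(NULL)
  }

  ly$forward <- function(x, train = TRUE) {
    d <- dim(x)
    stopifnot(length(d) == 3L)
    if (d[3L] != ly$c_in)
      stop("conv1d: expected ", ly$c_in, " input channels, got ", d[3L])
    ly$make_idx(d[1L], d[2L])
    xp <- if (ly$pad > 0L) {
      out <- array(0, c(ly$Tp, d[2L], ly$c_in))
      out[(ly$pad + 1L):(ly$pad + d[1L]), , ] <- x
      out
    } else x
    X2 <- matrix(xp[as.vector(ly$idx)], nrow = ly$To * d[2L])
    Y2 <- X2 %*% ly$params$W
    Y2 <- Y2 + rep(ly$params$b, each = nrow(Y2))
    ly$cache_X2 <- X2
    array(Y2, c(ly$To, d[2L], ly$c_out))
  }

  ly$backward <- function(dy) {
    B <- ly$B
    dY2 <- matrix(dy, ly$To * B, ly$c_out)
    ly$grads$W <- ly$grads$W + crossprod(ly$cache_X2, dY2)
    ly$grads$b <- ly$grads$b + colSums(dY2)
    dX2 <- dY2 %*% t(ly$params$W)
    dxp <- numeric(ly$Tp * B * ly$c_in)
    # scatter-add column by column: within one im2col column every index is
    # a distinct (t, b) position, so plain indexed addition is exact
    for (c2 in seq_len(ncol(ly$idx))) {
      ii <- ly$idx[, c2]
      dxp[ii] <- dxp[ii] + dX2[, c2]
    }
    dxp <- array(dxp, c(ly$Tp, B, ly$c_in))
    if (ly$pad > 0L)
      dxp[(ly$pad + 1L):(ly$pad + ly$T_in), , , drop = FALSE]
    else dxp
  }
  ly
}

# ---- batch normalisation over (time, batch) per channel ------------------

nn_batchnorm <- function(c_ch, eps = 1e-5, momentum = 0.1) {
  ly <- nn_layer()
  ly$params <- list(gamma = rep(1, c_ch), beta = numeric(c_ch))
  ly$grads <- list(gamma = numeric(c_ch), beta = numeric(c_ch))
  ly$run_mean <- numeric(c_ch)
  ly$run_var <- rep(1, c_ch)
  ly$eps <- eps; ly$momentum <- momentum; ly$c <- c_ch

  ly$forward <- function(x, train = TRUE) {
    d <- dim(x); n <- d[1L] * d[2L]
    M <- matrix(x, n, ly$c)
    if (train) {
      mu <- colMeans(M)
      xc <- M - rep(mu, each = n)
      v <- colSums(xc * xc) / n
      ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * mu
      ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * v
    } else {
      mu <- ly$run_mean; v <- ly$run_var
      xc <- M - rep(mu, each = n)
    }
    inv_std <- 1 / sqrt(v + ly$eps)
    xhat <- xc * rep(inv_std, each = n)
    y <- xhat * rep(ly$params$gamma, each = n) + rep(ly$params$beta, each = n)
    ly$cache <- list(xhat = xhat, inv_std = inv_std, n = n, d = d, train = train)
    array(y, d)
  }

  ly$backward <- function(dy) {
    cc <- ly$cache; n <- cc$n
    dY <- matrix(dy, n, ly$c)
    ly$grads$gamma <- ly$grads$gamma + colSums(dY * cc$xhat)
    ly$grads$beta <- ly$grads$beta + colSums(dY)
    dxhat <- dY * rep(ly$params$gamma, each = n)
    if (cc$train) {
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * cc$xhat)
      dx <- (dxhat - rep(s1 / n, each = n) -
               cc$xhat * rep(s2 / n, each = n)) * rep(cc$inv_std, each = n)
    } else {
      dx <- dxhat * rep(cc$inv_std, each = n)
    }
    array(dx, cc$d)
  }
  ly
}

# ---- pointwise nonlinearity and dropout ----------------------------------

nn_relu <- function() {
  ly <- nn_layer()
  ly$forward <- function(x, train = TRUE) {
    ly$mask <- x > 0
    x * ly$mask
  }
  ly$backward <- function(dy) dy * ly$mask
  ly
}

nn_dropout <- function(rng, rate) {
  ly <- nn_layer()
  ly$rate <- rate; ly$rng <- rng
  ly$forward <- function(x, train = TRUE) {
    if (!train || ly$rate <= 0) { ly$mask <- NULL; return(x) }
    keep <- 1 - ly$rate
    ly$mask <- array((ly$rng$runif(length(x)) < keep) / keep, dim(x))
    x * ly$mask
  }
  ly$backward <- function(dy) if (is.null(ly$mask)) dy else dy * ly$mask
  ly
}

# ---- fully connected -----------------------------------------------------

nn_dense <- function(rng, d_in, d_out) {
  ly <- nn_layer()
  ly$params <- list(W = he_init(rng, d_in, c(d_in, d_out)), b = numeric(d_out))
  ly$grads <- list(W = array(0, dim(ly$params$W)), b = numeric(d_out))
  ly$forward <- function(x, train = TRUE) {
    ly$cache_x <- x
    x %*% ly$params$W + rep(ly$params$b, each = nrow(x))
  }
  ly$backward <- function(dy) {
    ly$grads$W <- ly$grads$W + crossprod(ly$cache_x, dy)
    ly$grads$b <- ly$grads$b + colSums(dy)
    dy %*% t(ly$params$W)
  }
  ly
}

# ---- channel concatenation helpers ---------------------------------------

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[1L] == db[1L], da[2L] == db[2L])
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L]))
  out[, , seq_len(da[3L])] <- a
  out[, , da[3L] + seq_len(db[3L])] <- b
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  list(x[, , seq_len(c1), drop = FALSE],
       x[, , (c1 + 1L):d[3L], drop = FALSE])
}

# ---- parameter traversal and Adam ----------------------------------------

# depth-first list of parameterised layer environments under a model object;
# composite blocks advertise their primitive sublayers via $param_layers
collect_layers <- function(x) {
  if (is.environment(x)) {
    if (!is.null(x$param_layers))
      return(do.call(c, lapply(x$param_layers, collect_layers)))
    return(list(x))
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}

nn_zero_grads <- function(layers) {
  for (ly in layers)
    for (nm in names(ly$grads)) ly$grads[[nm]][] <- 0
  invisible(NULL)
}

nn_adam_init <- function(layers) {
  lapply(layers, function(ly)
    lapply(ly$params, function(p)
      list(m = array(0, dim(p) %||% length(p)),
           v = array(0, dim(p) %||% length(p)))))
}

nn_adam_step <- function(layers, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      state[[i]][[nm]] <- st
      ly$params[[nm]] <- ly$params[[nm]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  state
}

# flat numeric view of all parameters (used by tests and coef())
nn_get_params <- function(layers) {
  unlist(lapply(layers, function(ly) lapply(ly$params, as.vector)))
}

nn_set_params <- function(layers, theta) {
  pos <- 0L
  for (ly in layers) {
    for (nm in names(ly$params)) {
      n <- length(ly$params[[nm]])
      ly$params[[nm]][] <- theta[pos + seq_len(n)]
      pos <- pos + n
    }
  }
  stopifnot(pos == length(theta))
  invisible(NULL)
}

nn_get_grads <- function(layers) {
  unlist(lapply(layers, function(ly) lapply(ly$grads, as.vector)))
}
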
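# Shared fixtures, all generated in code.

# tiny balanced synthetic dataset on the CPSC-style taxonomy
tiny_dataset <- function(n_per_class = 4L, noise_sd = 0.05, seed = 11L,
                         multilabel_rate = 0, rate = 100, duration = 3) {
  h <- cpsc_hierarchy()
  spec <- synth_spec(
    hierarchy = h,
    frequencies = stats::setNames(rep(n_per_class, length(h$fine_classes)),
                                  h$fine_classes),
    leads = 12L, rate = rate, duration = duration, noise_sd = noise_sd,
    multilabel_rate = multilabel_rate, seed = seed)
  make_dataset(spec)
}

# naive direct-summation 1-D convolution with same padding (independent of
# the package's im2col path): x (T x C), W[(tap, cin, cout)], b[cout]
naive_conv1d <- function(x, W, b, stride = 1L) {
  Tt <- nrow(x); Cin <- ncol(x)
  k <- dim(W)[1L]; Cout <- dim(W)[3L]
  pad <- (k - 1L) %/% 2L
  To <- ((Tt + 2L * pad) - k) %/% stride + 1L
  xp <- rbind(matrix(0, pad, Cin), x, matrix(0, pad, Cin))
  out <- matrix(0, To, Cout)
  for (t in seq_len(To)) {
    t0 <- (t - 1L) * stride
    for (co in seq_len(Cout)) {
      acc <- b[co]
      for (j in seq_len(k))
        for (ci in seq_len(Cin))
          acc <- acc + xp[t0 + j, ci] * W[j, ci, co]
      out[t, co] <- acc
    }
  }
  out
}

# set a conv layer's parameters from a (tap, cin, cout) array
set_conv_weights <- function(layer, W, b) {
  k <- dim(W)[1L]; Cin <- dim(W)[2L]; Cout <- dim(W)[3L]
  Wm <- matrix(0, k * Cin, Cout)
  for (ci in seq_len(Cin))
    for (j in seq_len(k))
      Wm[j + (ci - 1L) * k, ] <- W[j, ci, ]
  layer$params$W <- Wm
  layer$params$b <- b
  invisible(layer)
}
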
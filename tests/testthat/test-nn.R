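# Internal layer primitives are exercised through ecgmtnet::: ; every oracle
# below is a straight-line computation independent of the package's
# vectorised implementation.

make_rng <- ecgmtnet:::make_rng

test_that("im2col convolution matches direct summation", {
  rng <- make_rng(1)
  set.seed(1)
  for (case in list(c(k = 3, s = 1), c(k = 7, s = 1), c(k = 3, s = 2),
                    c(k = 1, s = 2))) {
    ly <- ecgmtnet:::nn_conv1d(rng, 3L, 2L, as.integer(case["k"]),
                               as.integer(case["s"]))
    W <- array(rnorm(case["k"] * 3 * 2), c(case["k"], 3, 2))
    b <- rnorm(2)
    set_conv_weights(ly, W, b)
    x <- array(rnorm(11 * 2 * 3), c(11, 2, 3))
    y <- ly$forward(x)
    for (batch in 1:2) {
      ref <- naive_conv1d(matrix(x[, batch, ], 11, 3), W, b,
                          as.integer(case["s"]))
      expect_equal(matrix(y[, batch, ], dim(y)[1], 2), ref,
                   tolerance = 1e-12)
    }
  }
})

test_that("convolution rejects a channel mismatch before computing", {
  rng <- make_rng(2)
  ly <- ecgmtnet:::nn_conv1d(rng, 4L, 2L, 3L)
  expect_error(ly$forward(array(0, c(10, 1, 3))), "channels")
})

test_that("the SE squeeze of constant channels is the constant", {
  rng <- make_rng(3)
  se <- ecgmtnet:::nn_se_module(rng, 3L, reduction = 1L)
  x <- array(0, c(8, 2, 3))
  for (ch in 1:3) x[, , ch] <- ch * 1.5
  se$forward(x)
  s <- se$cache$s
  expect_equal(s[1, ], c(1.5, 3.0, 4.5))
  expect_equal(s[2, ], c(1.5, 3.0, 4.5))
})

test_that("excitation gates forced to one make SE rescaling the identity", {
  rng <- make_rng(4)
  se <- ecgmtnet:::nn_se_module(rng, 3L, reduction = 1L)
  se$params$W1[] <- 0; se$params$b1[] <- 0
  se$params$W2[] <- 0; se$params$b2[] <- 40   # logistic(40) == 1 in doubles
  set.seed(4)
  x <- array(rnorm(8 * 2 * 3), c(8, 2, 3))
  expect_equal(se$forward(x), x, tolerance = 1e-12)
})

test_that("SE module matches a scripted mean->FC->ReLU->FC->logistic->scale", {
  rng <- make_rng(5)
  se <- ecgmtnet:::nn_se_module(rng, 2L, reduction = 1L)
  W1 <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  b1 <- c(0.05, -0.1)
  W2 <- matrix(c(-0.4, 0.6, 0.2, 0.3), 2, 2)
  b2 <- c(0.2, -0.3)
  se$params$W1 <- W1; se$params$b1 <- b1
  se$params$W2 <- W2; se$params$b2 <- b2
  set.seed(5)
  x <- array(rnorm(6 * 1 * 2), c(6, 1, 2))
  y <- se$forward(x)
  # straight-line oracle, one record
  s <- c(mean(x[, 1, 1]), mean(x[, 1, 2]))
  z1 <- as.vector(s %*% W1) + b1
  a1 <- pmax(z1, 0)
  g <- 1 / (1 + exp(-(as.vector(a1 %*% W2) + b2)))
  for (ch in 1:2)
    expect_equal(y[, 1, ch], x[, 1, ch] * g[ch], tolerance = 1e-12)
})

test_that("a CoT block with zero value embedding depends only on K1", {
  rng <- make_rng(6)
  cot <- ecgmtnet:::nn_cot_block(rng, 2L, 3L)
  cot$conv_v$params$W[] <- 0; cot$conv_v$params$b[] <- 0
  set.seed(6)
  x <- array(rnorm(8 * 1 * 2), c(8, 1, 2))
  y <- cot$forward(x)
  expect_equal(cot$cache$V, array(0, c(8, 1, 2)))
  # K2 = V*A = 0, so the output is the projection of [K1, 0]
  K1 <- cot$conv_k$forward(x)
  ref <- cot$conv_proj$forward(ecgmtnet:::cat_channels(K1, 0 * K1))
  expect_equal(y, ref, tolerance = 1e-12)
})

test_that("a zero attention map nulls the dynamic context regardless of V", {
  rng <- make_rng(7)
  cot <- ecgmtnet:::nn_cot_block(rng, 2L, 3L)
  cot$conv_theta$params$W[] <- 0; cot$conv_theta$params$b[] <- 0
  set.seed(7)
  x <- array(rnorm(8 * 1 * 2), c(8, 1, 2))
  cot$forward(x)
  expect_equal(cot$cache$A, array(0, c(8, 1, 2)))
  expect_equal(cot$cache$V * cot$cache$A, array(0, c(8, 1, 2)))
})

test_that("CoT output matches a straight-line evaluation on tiny tensors", {
  # independent oracle: naive convolutions and explicit elementwise algebra
  straight_line_cot <- function(x, cot) {
    Tt <- dim(x)[1]; C <- dim(x)[3]
    xm <- matrix(x[, 1, ], Tt, C)
    conv_as_array <- function(layer, inp) {
      k <- layer$k; Cin <- layer$c_in; Cout <- layer$c_out
      W <- array(0, c(k, Cin, Cout))
      for (ci in seq_len(Cin)) for (j in seq_len(k))
        W[j, ci, ] <- layer$params$W[j + (ci - 1) * k, ]
      naive_conv1d(inp, W, layer$params$b)
    }
    K1 <- conv_as_array(cot$conv_k, xm)
    V <- conv_as_array(cot$conv_v, xm)
    pre <- conv_as_array(cot$conv_sig, cbind(K1, xm))
    A <- conv_as_array(cot$conv_theta, pmax(pre, 0))
    K2 <- V * A
    conv_as_array(cot$conv_proj, cbind(K1, K2))
  }
  for (seed in 1:5) {
    rng <- make_rng(seed)
    C <- 1L + seed %% 3L
    cot <- ecgmtnet:::nn_cot_block(rng, C, 3L)
    set.seed(seed)
    Tt <- 4L + seed
    x <- array(rnorm(Tt * C), c(Tt, 1, C))
    y <- cot$forward(x)
    ref <- straight_line_cot(x, cot)
    expect_equal(matrix(y[, 1, ], Tt, C), ref, tolerance = 1e-6)
    expect_equal(dim(y), dim(x))  # drop-in: time and width preserved
  }
})

test_that("GRU recurrence matches a hand-unrolled three-step oracle", {
  rng <- make_rng(8)
  gru <- ecgmtnet:::nn_gru(rng, 2L, 2L)
  Wx <- matrix(seq(-0.5, 0.6, length.out = 12), 2, 6)
  Wh <- matrix(seq(0.4, -0.5, length.out = 12), 2, 6)
  b <- seq(-0.2, 0.3, length.out = 6)
  gru$params$Wx <- Wx; gru$params$Wh <- Wh; gru$params$b <- b
  x <- array(c(0.5, -1, 0.25, 1.5, -0.75, 0.1), c(3, 1, 2))
  h <- gru$forward(x)

  sig <- function(v) 1 / (1 + exp(-v))
  h_ref <- c(0, 0)
  for (t in 1:3) {
    xt <- c(x[t, 1, 1], x[t, 1, 2])
    gx <- as.vector(xt %*% Wx) + b
    gh <- as.vector(h_ref %*% Wh)
    r <- sig(gx[1:2] + gh[1:2])
    z <- sig(gx[3:4] + gh[3:4])
    n <- tanh(gx[5:6] + r * gh[5:6])
    h_ref <- (1 - z) * n + z * h_ref
  }
  expect_equal(as.vector(h), h_ref, tolerance = 1e-12)
})

test_that("on a length-one sequence both Bi-GRU directions see the same step", {
  rng <- make_rng(9)
  bg <- ecgmtnet:::nn_bigru(rng, 2L, 3L)
  # same parameters in both directions -> identical halves on length 1
  bg$bwd$params <- bg$fwd$params
  x <- array(rnorm(2), c(1, 1, 2))
  f <- bg$forward(x)
  expect_equal(f[, 1:3], f[, 4:6], tolerance = 1e-12)
  expect_error(bg$fwd$forward(array(0, c(0, 1, 2))), "zero time steps")
})

test_that("time reversal with swapped direction parameters swaps the outputs", {
  rng <- make_rng(10)
  bg <- ecgmtnet:::nn_bigru(rng, 2L, 3L)
  set.seed(10)
  x <- array(rnorm(7 * 2 * 2), c(7, 2, 2))
  f <- bg$forward(x)
  bg2 <- ecgmtnet:::nn_bigru(make_rng(99), 2L, 3L)
  bg2$fwd$params <- bg$bwd$params
  bg2$bwd$params <- bg$fwd$params
  xrev <- x[7:1, , , drop = FALSE]
  f2 <- bg2$forward(xrev)
  expect_equal(f2[, 1:3], f[, 4:6], tolerance = 1e-12)
  expect_equal(f2[, 4:6], f[, 1:3], tolerance = 1e-12)
})

test_that("analytic gradients match central differences through the whole net", {
  rng <- make_rng(42)
  cfg <- mtnet_config(in_leads = 3, n_main_classes = 4, n_aux_classes = 2,
                      block_channels = c(4, 6), block_strides = c(2, 2),
                      conv_kernel = 3, dropout = 0, se_reduction = 2,
                      cot_kernel = 3, gru_hidden = 3)
  net <- ecgmtnet:::build_network(cfg, rng)
  set.seed(7)
  x <- array(rnorm(12 * 3 * 3), c(12, 3, 3))
  tm <- matrix(rbinom(12, 1, 0.5), 3, 4)
  ta <- matrix(rbinom(6, 1, 0.5), 3, 2)
  loss_fn <- function() {
    s <- ecgmtnet:::model_forward(net, x, train = TRUE)
    0.6 * ecgmtnet:::bce_with_logits(s$main, tm) +
      0.4 * ecgmtnet:::bce_with_logits(s$aux, ta)
  }
  s <- ecgmtnet:::model_forward(net, x, train = TRUE)
  ecgmtnet:::nn_zero_grads(net$layers)
  ecgmtnet:::model_backward(net, 0.6 * ecgmtnet:::bce_grad(s$main, tm),
                            0.4 * ecgmtnet:::bce_grad(s$aux, ta))
  ga <- ecgmtnet:::nn_get_grads(net$layers)
  th0 <- ecgmtnet:::nn_get_params(net$layers)
  eps <- 1e-5
  idx <- sort(sample(length(th0), 60))
  gn <- vapply(idx, function(i) {
    th <- th0; th[i] <- th0[i] + eps
    ecgmtnet:::nn_set_params(net$layers, th); lp <- loss_fn()
    th[i] <- th0[i] - eps
    ecgmtnet:::nn_set_params(net$layers, th); lm <- loss_fn()
    ecgmtnet:::nn_set_params(net$layers, th0)
    (lp - lm) / (2 * eps)
  }, numeric(1))
  rel <- abs(gn - ga[idx]) / pmax(1e-6, abs(gn) + abs(ga[idx]))
  expect_lt(max(rel), 1e-4)
})

test_that("forward emits per-record score pairs of the two label-space sizes", {
  rng <- make_rng(12)
  cfg <- mtnet_config(in_leads = 12, n_main_classes = 9, n_aux_classes = 5,
                      block_channels = c(8, 8), block_strides = c(2, 2),
                      gru_hidden = 4, se_reduction = 4)
  net <- ecgmtnet:::build_network(cfg, rng)
  set.seed(12)
  x <- array(rnorm(64 * 3 * 12), c(64, 3, 12))
  s <- ecgmtnet:::model_forward(net, x, train = FALSE)
  expect_equal(dim(s$main), c(3L, 9L))
  expect_equal(dim(s$aux), c(3L, 5L))
  expect_true(all(is.finite(s$main)) && all(is.finite(s$aux)))
})

test_that("trunk blocks and the CoT block preserve the expected time lengths", {
  rng <- make_rng(13)
  blk <- ecgmtnet:::nn_se_block(rng, 3L, 5L, kernel = 7L, stride = 1L,
                                dropout = 0, se_reduction = 2L)
  x <- array(rnorm(20 * 2 * 3), c(20, 2, 3))
  expect_equal(dim(blk$forward(x))[1], 20L)         # stride 1: length kept
  blk2 <- ecgmtnet:::nn_se_block(rng, 3L, 5L, kernel = 7L, stride = 2L,
                                 dropout = 0, se_reduction = 2L)
  expect_equal(dim(blk2$forward(x))[1], 10L)        # stride 2: halved
  cot <- ecgmtnet:::nn_cot_block(rng, 5L, 3L)
  y <- blk$forward(x)
  expect_equal(dim(cot$forward(y)), dim(y))
})

test_that("disabling CoT and Bi-GRU reduces to the pooled SE-ResNet baseline", {
  rng <- make_rng(14)
  cfg <- mtnet_config(in_leads = 2, n_main_classes = 3, n_aux_classes = 2,
                      block_channels = 4, block_strides = 2, gru_hidden = 4,
                      se_reduction = 2, use_cot = FALSE, use_bigru = FALSE,
                      dropout = 0)
  net <- ecgmtnet:::build_network(cfg, rng)
  expect_null(net$branch_shared$cot)
  expect_null(net$branch_shared$gru)
  set.seed(14)
  x <- array(rnorm(16 * 2 * 2), c(16, 2, 2))
  s <- ecgmtnet:::model_forward(net, x, train = FALSE)
  # head input is the time-average of the trunk output
  h <- x
  for (blk in net$trunk) h <- blk$forward(h, FALSE)
  pooled <- matrix(colMeans(matrix(h, dim(h)[1], dim(h)[2] * dim(h)[3])),
                   dim(h)[2], dim(h)[3])
  ref <- net$head_main$forward(pooled)
  expect_equal(s$main, ref, tolerance = 1e-12)
})

test_that("eval-mode forward is a pure function: identical records, identical rows", {
  rng <- make_rng(15)
  cfg <- mtnet_config(in_leads = 2, n_main_classes = 3, n_aux_classes = 2,
                      block_channels = c(4, 4), block_strides = c(2, 2),
                      gru_hidden = 3, se_reduction = 2)
  net <- ecgmtnet:::build_network(cfg, rng)
  set.seed(15)
  one <- array(rnorm(16 * 2), c(16, 1, 2))
  x <- array(0, c(16, 3, 2))
  for (b in 1:3) x[, b, ] <- one[, 1, ]
  s <- ecgmtnet:::model_forward(net, x, train = FALSE)
  expect_equal(s$main[1, ], s$main[2, ])
  expect_equal(s$main[2, ], s$main[3, ])
  s2 <- ecgmtnet:::model_forward(net, x, train = FALSE)
  expect_identical(s$main, s2$main)
})

test_that("an auxiliary-only step trains the shared trunk but not the main head", {
  rng <- make_rng(16)
  cfg <- mtnet_config(in_leads = 2, n_main_classes = 3, n_aux_classes = 2,
                      block_channels = 4, block_strides = 2, gru_hidden = 3,
                      se_reduction = 2, dropout = 0)
  net <- ecgmtnet:::build_network(cfg, rng)
  set.seed(16)
  x <- array(rnorm(16 * 2 * 2), c(16, 2, 2))
  ta <- matrix(rbinom(4, 1, 0.5), 2, 2)
  s <- ecgmtnet:::model_forward(net, x, train = TRUE)
  ecgmtnet:::nn_zero_grads(net$layers)
  ecgmtnet:::model_backward(net, 0 * s$main,
                            ecgmtnet:::bce_grad(s$aux, ta))
  g_trunk <- ecgmtnet:::nn_get_grads(net$shared_layers)
  g_main_head <- ecgmtnet:::nn_get_grads(list(net$head_main))
  g_aux_head <- ecgmtnet:::nn_get_grads(list(net$head_aux))
  expect_gt(sum(abs(g_trunk)), 0)
  expect_gt(sum(abs(g_aux_head)), 0)
  expect_equal(sum(abs(g_main_head)), 0)
})
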
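# Assembly of the full multi-task network from an mtnet_config.
#
# Hard parameter sharing: one SE-ResNet trunk feeds both tasks.  By default
# the CoT block and the Bi-GRU are also shared and only the two fully
# connected heads are task-specific; with per_task_branch each task owns its
# CoT+Bi-GRU branch.

build_network <- function(cfg, rng) {
  stopifnot(inherits(cfg, "mtnet_config"))
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg

  widths <- cfg$block_channels
  ins <- c(cfg$in_leads, widths[-length(widths)])
  net$trunk <- lapply(seq_along(widths), function(i)
    nn_se_block(rng, ins[i], widths[i], cfg$conv_kernel,
                cfg$block_strides[i], cfg$dropout, cfg$se_reduction))
  c_top <- widths[length(widths)]
  feat_dim <- if (cfg$use_bigru) 2L * cfg$gru_hidden else c_top

  make_branch <- function() {
    br <- list(
      cot = if (cfg$use_cot) nn_cot_block(rng, c_top, cfg$cot_kernel),
      gru = if (cfg$use_bigru) nn_bigru(rng, c_top, cfg$gru_hidden))
    br[!vapply(br, is.null, logical(1))]
  }
  if (cfg$per_task_branch) {
    net$branch_main <- make_branch()
    net$branch_aux <- make_branch()
  } else {
    net$branch_shared <- make_branch()
  }
  net$head_main <- nn_dense(rng, feat_dim, cfg$n_main_classes)
  net$head_aux <- nn_dense(rng, feat_dim, cfg$n_aux_classes)

  net$shared_layers <- collect_layers(c(net$trunk,
                                        net$branch_shared %||% list()))
  net$main_layers <- collect_layers(c(net$branch_main %||% list(),
                                      list(net$head_main)))
  net$aux_layers <- collect_layers(c(net$branch_aux %||% list(),
                                     list(net$head_aux)))
  net$layers <- c(net$shared_layers, net$main_layers, net$aux_layers)
  net
}

branch_forward <- function(branch, x, train) {
  h <- x
  if (!is.null(branch$cot)) h <- branch$cot$forward(h, train)
  if (!is.null(branch$gru)) {
    branch$gru$forward(h, train)
  } else {
    # global average pooling over time when the Bi-GRU is ablated
    d <- dim(h)
    attr_pool <- matrix(colMeans(matrix(h, d[1L], d[2L] * d[3L])), d[2L], d[3L])
    attr(attr_pool, "pool_dim") <- d
    attr_pool
  }
}

branch_backward <- function(branch, dfeat, pooled_dim = NULL) {
  if (!is.null(branch$gru)) {
    dh <- branch$gru$backward(dfeat)
  } else {
    d <- pooled_dim
    dh <- array(rep(as.vector(dfeat), each = d[1L]), d) / d[1L]
  }
  if (!is.null(branch$cot)) dh <- branch$cot$backward(dh)
  dh
}

# x: array (T, B, leads).  Returns list(main=, aux=) of logit matrices.
model_forward <- function(net, x, train = TRUE) {
  d <- dim(x)
  if (d[3L] != net$cfg$in_leads)
    stop("expected ", net$cfg$in_leads, " leads, got ", d[3L])
  h <- x
  for (blk in net$trunk) h <- blk$forward(h, train)
  net$trunk_out_dim <- dim(h)
  if (net$cfg$per_task_branch) {
    fm <- branch_forward(net$branch_main, h, train)
    fa <- branch_forward(net$branch_aux, h, train)
  } else {
    fm <- fa <- branch_forward(net$branch_shared, h, train)
  }
  net$pool_dim_main <- attr(fm, "pool_dim")
  net$pool_dim_aux <- attr(fa, "pool_dim")
  scores <- list(main = net$head_main$forward(as.matrix(fm), train),
                 aux = net$head_aux$forward(as.matrix(fa), train))
  stop_if_not_finite(scores$main, "main-task scores")
  stop_if_not_finite(scores$aux, "aux-task scores")
  scores
}

model_backward <- function(net, d_main, d_aux) {
  dfm <- net$head_main$backward(d_main)
  dfa <- net$head_aux$backward(d_aux)
  if (net$cfg$per_task_branch) {
    dh <- branch_backward(net$branch_main, dfm, net$pool_dim_main) +
      branch_backward(net$branch_aux, dfa, net$pool_dim_aux)
  } else {
    dh <- branch_backward(net$branch_shared, dfm + dfa, net$pool_dim_main)
  }
  for (blk in rev(net$trunk)) dh <- blk$backward(dh)
  invisible(dh)
}

# binary cross-entropy with logits, mean over batch x classes
bce_with_logits <- function(logits, targets) {
  p <- sigmoid(logits)
  eps <- 1e-12
  -mean(targets * log(p + eps) + (1 - targets) * log(1 - p + eps))
}

bce_grad <- function(logits, targets) {
  g <- (sigmoid(logits) - targets) / length(logits)
  dimnames(g) <- NULL
  g
}
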
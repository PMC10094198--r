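#' Model architecture configuration
#'
#' Collects every architecture hyperparameter of the multi-task network:
#' the shared SE-ResNet trunk (block widths and strides, convolution kernel,
#' dropout, SE bottleneck reduction), the CoT attention block, the Bi-GRU
#' summary, and the two task heads.  The `use_cot` / `use_bigru` switches
#' reproduce the ablation variants; `per_task_branch` moves the CoT+Bi-GRU
#' stage from the shared stem into per-task branches (an alternative reading
#' of the architecture in which the whole classification module, not just
#' the final fully connected layer, is task-specific).
#'
#' @param in_leads number of input leads (channels); 12 for clinical ECG
#' @param n_main_classes,n_aux_classes sizes of the two label spaces
#' @param block_channels integer vector of SE-block output widths; the trunk
#'   stacks one block per entry (default `c(64, 128, 128, 256)`)
#' @param block_strides per-block time stride (default 2 per block,
#'   halving the sequence at every stage)
#' @param conv_kernel convolution kernel size inside SE blocks (odd;
#'   default 7)
#' @param dropout dropout rate inside SE blocks (default 0.2)
#' @param se_reduction SE bottleneck reduction ratio (default 16)
#' @param cot_kernel kernel of the CoT static-context convolution along
#'   time (odd; default 3)
#' @param gru_hidden hidden units per GRU direction (default 128; the head
#'   input is twice this)
#' @param use_cot,use_bigru ablation switches (default both TRUE)
#' @param per_task_branch if TRUE, each task owns its CoT+Bi-GRU branch
#' @return object of class `mtnet_config`
#' @export
mtnet_config <- function(in_leads = 12L,
                         n_main_classes,
                         n_aux_classes,
                         block_channels = c(64L, 128L, 128L, 256L),
                         block_strides = rep(2L, length(block_channels)),
                         conv_kernel = 7L,
                         dropout = 0.2,
                         se_reduction = 16L,
                         cot_kernel = 3L,
                         gru_hidden = 128L,
                         use_cot = TRUE,
                         use_bigru = TRUE,
                         per_task_branch = FALSE) {
  cfg <- list(in_leads = as.integer(in_leads),
              n_main_classes = as.integer(n_main_classes),
              n_aux_classes = as.integer(n_aux_classes),
              block_channels = as.integer(block_channels),
              block_strides = as.integer(block_strides),
              conv_kernel = as.integer(conv_kernel),
              dropout = dropout,
              se_reduction = as.integer(se_reduction),
              cot_kernel = as.integer(cot_kernel),
              gru_hidden = as.integer(gru_hidden),
              use_cot = isTRUE(use_cot),
              use_bigru = isTRUE(use_bigru),
              per_task_branch = isTRUE(per_task_branch))
  if (length(cfg$block_channels) < 1L) stop("need at least one trunk block")
  if (length(cfg$block_strides) != length(cfg$block_channels))
    stop("block_strides must match block_channels in length")
  if (!is_odd(cfg$conv_kernel)) stop("conv_kernel must be odd")
  if (!is_odd(cfg$cot_kernel)) stop("cot_kernel must be odd")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0, 1)")
  bad <- vapply(cfg[c("in_leads", "n_main_classes", "n_aux_classes",
                      "se_reduction", "gru_hidden")], function(v) v < 1L,
                logical(1))
  if (any(bad)) stop("counts must be positive: ",
                     paste(names(bad)[bad], collapse = ", "))
  structure(cfg, class = "mtnet_config")
}

#' @export
print.mtnet_config <- function(x, ...) {
  cat("mtnet architecture:\n")
  cat("  trunk: ", length(x$block_channels), " SE blocks, widths (",
      paste(x$block_channels, collapse = ", "), "), strides (",
      paste(x$block_strides, collapse = ", "), "), kernel ",
      x$conv_kernel, ", dropout ", x$dropout, "\n", sep = "")
  cat("  CoT: ", if (x$use_cot) paste0("on (kernel ", x$cot_kernel, ")") else "off",
      " | Bi-GRU: ", if (x$use_bigru) paste0("on (hidden ", x$gru_hidden, ")")
      else "off (global average pooling)", "\n", sep = "")
  cat("  heads: main ", x$n_main_classes, " classes, aux ", x$n_aux_classes,
      " classes", if (x$per_task_branch) " (per-task CoT+Bi-GRU branches)",
      "\n", sep = "")
  invisible(x)
}

#' Training protocol configuration
#'
#' Defaults reproduce the published protocol: Adam with initial learning
#' rate 5e-4, decayed by a factor of 10 every 10 epochs, batch size 32, and
#' early stopping when the monitored loss has not improved for 10
#' consecutive epochs.  `lambda` weights the joint loss
#' \eqn{L = \lambda L_{main} + (1-\lambda) L_{aux}}; it is not pinned down
#' by the protocol, so the symmetric default 0.5 is used and always logged.
#'
#' @param lambda main-task weight in \[0, 1\] (default 0.5)
#' @param lr0 initial learning rate (default 0.0005)
#' @param lr_decay_every epochs between decays (default 10)
#' @param lr_decay_factor multiplicative decay (default 0.1)
#' @param batch_size records per minibatch (default 32)
#' @param patience early-stop patience in epochs (default 10)
#' @param max_epochs hard cap on epochs (default 100)
#' @param seed integer seed controlling initialisation, shuffling, dropout
#' @return object of class `mtnet_control`
#' @export
mtnet_train_control <- function(lambda = 0.5, lr0 = 5e-4,
                                lr_decay_every = 10L, lr_decay_factor = 0.1,
                                batch_size = 32L, patience = 10L,
                                max_epochs = 100L, seed = 1L) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  structure(list(lambda = lambda, lr0 = lr0,
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "mtnet_control")
}

#' @export
print.mtnet_control <- function(x, ...) {
  cat("mtnet training protocol: Adam, lr0 ", x$lr0, " (x", x$lr_decay_factor,
      " every ", x$lr_decay_every, " epochs), batch ", x$batch_size,
      ", patience ", x$patience, ", max ", x$max_epochs,
      " epochs, lambda ", x$lambda, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
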
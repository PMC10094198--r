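#' Weighted joint loss of the two tasks
#'
#' \deqn{L_{total} = \lambda L_{main} + (1-\lambda) L_{aux}} where each task
#' loss is the mean per-class binary cross-entropy over the batch (per-class
#' sigmoid outputs: both benchmark tasks are multi-label).
#'
#' @param main_scores,aux_scores numeric matrices of per-class probabilities
#'   in (0,1) (or logits with `logits = TRUE`), records x classes
#' @param main_targets,aux_targets 0-1 matrices of matching shape
#' @param lambda main-task weight in \[0, 1\]
#' @param logits interpret scores as logits instead of probabilities
#' @return scalar loss
#' @export
joint_loss <- function(main_scores, main_targets, aux_scores, aux_targets,
                       lambda, logits = FALSE) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  stopifnot(all(dim(main_scores) == dim(main_targets)),
            all(dim(aux_scores) == dim(aux_targets)))
  bce <- function(s, t) {
    if (logits) return(bce_with_logits(s, t))
    eps <- 1e-12
    -mean(t * log(s + eps) + (1 - t) * log(1 - s + eps))
  }
  lambda * bce(main_scores, main_targets) +
    (1 - lambda) * bce(aux_scores, aux_targets)
}

#' Stepwise learning-rate schedule
#'
#' `lr0 * factor^floor(epoch / decay_every)`: the rate drops by a factor of
#' 10 every 10 epochs under the defaults.  Epochs are counted from 0.
#'
#' @param epoch epoch index, 0-based
#' @param control an `mtnet_train_control`
#' @export
lr_at_epoch <- function(epoch, control) {
  stopifnot(epoch >= 0)
  control$lr0 * control$lr_decay_factor^(epoch %/% control$lr_decay_every)
}

#' Early-stopping rule
#'
#' Training ends when the monitored loss has failed to improve on the best
#' value seen before it for `patience` consecutive epochs.
#'
#' @param loss_history numeric vector, one monitored loss per epoch so far
#' @param patience number of consecutive non-improving epochs that triggers
#'   the stop
#' @return TRUE if training should stop after the last recorded epoch
#' @export
early_stop <- function(loss_history, patience) {
  n <- length(loss_history)
  if (n == 0L) stop("loss history is empty")
  if (n <= patience) return(FALSE)
  best_before <- c(Inf, cummin(loss_history))[seq_len(n)]
  improved <- loss_history < best_before
  all(!improved[(n - patience + 1L):n])
}

#' Train / validation / test partitions
#'
#' Two schemes: `"ptbxl_recommended"` uses supplied per-record fold tags
#' 1-10 (folds 1-8 train, 9 validation, 10 test — the curated benchmark
#' partition); `"stratified_10fold"` draws a seeded label-stratified 10-fold
#' partition and assigns the same 8/1/1 roles.
#'
#' @param records list of `ecg_record` (stratification uses each record's
#'   first main label)
#' @param scheme `"ptbxl_recommended"` or `"stratified_10fold"`
#' @param fold_tags integer vector of 1-10 tags, required for
#'   `"ptbxl_recommended"`
#' @param seed seed for the stratified draw
#' @return list with integer index vectors `train`, `validation`, `test`
#'   and the per-record `fold_of` tags
#' @export
make_folds <- function(records, scheme = c("ptbxl_recommended",
                                           "stratified_10fold"),
                       fold_tags = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(records)
  if (scheme == "ptbxl_recommended") {
    if (is.null(fold_tags))
      stop("scheme ptbxl_recommended requires per-record fold tags")
    fold_of <- as.integer(fold_tags)
    stopifnot(length(fold_of) == n, all(fold_of %in% 1:10))
  } else {
    strat <- vapply(records, function(r)
      if (length(r$main_labels)) r$main_labels[1L] else "(none)", character(1))
    rng <- make_rng(seed)
    fold_of <- integer(n)
    for (cl in unique(strat)) {
      idx <- which(strat == cl)
      idx <- idx[rng$sample(length(idx))]
      fold_of[idx] <- rep_len(1:10, length(idx))
    }
  }
  list(train = which(fold_of <= 8L),
       validation = which(fold_of == 9L),
       test = which(fold_of == 10L),
       fold_of = fold_of)
}

# records -> array (T, N, leads); requires uniform shape
records_to_array <- function(records) {
  d1 <- dim(records[[1L]]$signal)
  x <- array(0, c(d1[2L], length(records), d1[1L]))
  for (i in seq_along(records)) {
    s <- records[[i]]$signal
    if (!all(dim(s) == d1))
      stop("record ", records[[i]]$record_id,
           " has shape ", nrow(s), "x", ncol(s),
           "; preprocess records to a uniform shape first")
    x[, i, ] <- t(s)
  }
  x
}

# label sets -> multi-hot matrix over a fixed class ordering
label_matrix <- function(label_sets, classes) {
  m <- matrix(0, length(label_sets), length(classes),
              dimnames = list(NULL, classes))
  for (i in seq_along(label_sets)) {
    lab <- intersect(label_sets[[i]], classes)
    m[i, lab] <- 1
  }
  m
}

#' Fit the multi-task ECG classifier
#'
#' Trains the shared-trunk multi-task network on a list of preprocessed
#' records carrying both label sets.  The main and auxiliary label spaces
#' are taken from the hierarchy: under `direction = "merge"` the main task
#' classifies fine classes and the auxiliary task their superclasses; under
#' `"split"` the main task classifies coarse classes and the auxiliary task
#' the subclasses.  Optimisation is Adam on the weighted joint
#' cross-entropy, with the stepwise learning-rate schedule, validation-loss
#' early stopping (best-epoch weights restored), and full seeding: two runs
#' with the same data, configuration and seed are identical.
#'
#' @param records list of `ecg_record`, preprocessed to a uniform shape,
#'   with `main_labels` and `aux_labels` set
#' @param hierarchy a `label_hierarchy`
#' @param direction `"merge"` (fine main task) or `"split"` (coarse main
#'   task)
#' @param config an `mtnet_config`; `in_leads`, `n_main_classes` and
#'   `n_aux_classes` are checked against the data
#' @param control an `mtnet_train_control`
#' @param scheme partition scheme, see [make_folds()]
#' @param fold_tags per-record fold tags for `"ptbxl_recommended"`
#' @param verbose print one line per epoch
#' @return an object of class `mtnet` with the fitted network, the class
#'   orderings, the partition, and a per-epoch `history` data.frame (both
#'   task losses, validation loss and validation macro F1)
#' @seealso [predict.mtnet()], [evaluate_mtnet()]
#' @export
mtnet <- function(records, hierarchy, direction = c("merge", "split"),
                  config = NULL, control = mtnet_train_control(),
                  scheme = c("stratified_10fold", "ptbxl_recommended"),
                  fold_tags = NULL, verbose = FALSE) {
  direction <- match.arg(direction)
  scheme <- match.arg(scheme)
  validate_hierarchy(hierarchy)
  if (length(records) == 0L) stop("empty training set")
  if (direction == "merge") {
    main_classes <- hierarchy$fine_classes
    aux_classes <- hierarchy$coarse_classes
  } else {
    main_classes <- hierarchy$coarse_classes
    aux_classes <- hierarchy$fine_classes
  }
  x_all <- records_to_array(records)
  y_main <- label_matrix(lapply(records, `[[`, "main_labels"), main_classes)
  y_aux <- label_matrix(lapply(records, `[[`, "aux_labels"), aux_classes)
  if (any(rowSums(y_main) == 0) || any(rowSums(y_aux) == 0))
    stop("every record needs at least one main and one aux label ",
         "within the hierarchy's label spaces")

  if (is.null(config))
    config <- mtnet_config(in_leads = dim(x_all)[3L],
                           n_main_classes = length(main_classes),
                           n_aux_classes = length(aux_classes))
  if (config$n_main_classes != length(main_classes) ||
      config$n_aux_classes != length(aux_classes))
    stop("config head sizes (", config$n_main_classes, ", ",
         config$n_aux_classes, ") do not match the label spaces (",
         length(main_classes), ", ", length(aux_classes), ")")
  if (config$in_leads != dim(x_all)[3L])
    stop("config expects ", config$in_leads, " leads, data has ",
         dim(x_all)[3L])

  folds <- make_folds(records, scheme, fold_tags = fold_tags,
                      seed = control$seed)
  if (length(folds$train) == 0L) stop("empty training partition")

  rng <- make_rng(control$seed)
  net <- build_network(config, rng)
  adam <- nn_adam_init(net$layers)
  step <- 0L
  lam <- control$lambda

  history <- data.frame()
  val_hist <- numeric(0)
  best_val <- Inf
  best_theta <- nn_get_params(net$layers)
  best_epoch <- 0L

  eval_split <- function(idx) {
    if (length(idx) == 0L) return(list(loss = NA_real_, f1 = NA_real_))
    s <- predict_scores(net, x_all[, idx, , drop = FALSE],
                        control$batch_size)
    loss <- lam * bce_with_logits(s$main, y_main[idx, , drop = FALSE]) +
      (1 - lam) * bce_with_logits(s$aux, y_aux[idx, , drop = FALSE])
    rep_main <- suppressWarnings(
      metrics_report(sigmoid(s$main), y_main[idx, , drop = FALSE]))
    list(loss = loss, f1 = rep_main$macro_f1)
  }

  for (epoch in seq_len(control$max_epochs)) {
    lr <- lr_at_epoch(epoch - 1L, control)
    order_idx <- folds$train[rng$sample(length(folds$train))]
    batches <- split(order_idx,
                     ceiling(seq_along(order_idx) / control$batch_size))
    tr_main <- tr_aux <- 0
    for (b in batches) {
      xb <- x_all[, b, , drop = FALSE]
      sm <- model_forward(net, xb, train = TRUE)
      lm <- bce_with_logits(sm$main, y_main[b, , drop = FALSE])
      la <- bce_with_logits(sm$aux, y_aux[b, , drop = FALSE])
      tr_main <- tr_main + lm * length(b)
      tr_aux <- tr_aux + la * length(b)
      nn_zero_grads(net$layers)
      model_backward(net,
                     lam * bce_grad(sm$main, y_main[b, , drop = FALSE]),
                     (1 - lam) * bce_grad(sm$aux, y_aux[b, , drop = FALSE]))
      step <- step + 1L
      adam <- nn_adam_step(net$layers, adam, lr, step)
    }
    tr_main <- tr_main / length(folds$train)
    tr_aux <- tr_aux / length(folds$train)
    val <- eval_split(folds$validation)
    val_loss <- if (is.na(val$loss)) lam * tr_main + (1 - lam) * tr_aux
    else val$loss
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss_main = tr_main,
      train_loss_aux = tr_aux,
      train_loss = lam * tr_main + (1 - lam) * tr_aux,
      val_loss = val_loss, val_macro_f1 = val$f1))
    if (verbose)
      message(sprintf(
        "epoch %3d lr %.2g train %.4f (main %.4f aux %.4f) val %.4f F1 %.3f",
        epoch, lr, history$train_loss[epoch], tr_main, tr_aux, val_loss,
        val$f1))
    val_hist <- c(val_hist, val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss
      best_theta <- nn_get_params(net$layers)
      best_epoch <- epoch
    }
    if (early_stop(val_hist, control$patience)) break
  }
  nn_set_params(net$layers, best_theta)

  structure(
    list(net = net, config = config, control = control,
         hierarchy = hierarchy, direction = direction,
         main_classes = main_classes, aux_classes = aux_classes,
         folds = folds, history = history, best_epoch = best_epoch,
         best_val_loss = best_val, n_records = length(records)),
    class = "mtnet")
}

# batched eval-mode forward over an (T, N, leads) array; returns logits
predict_scores <- function(net, x, batch_size = 32L) {
  n <- dim(x)[2L]
  chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  out_m <- NULL; out_a <- NULL
  for (ch in chunks) {
    s <- model_forward(net, x[, ch, , drop = FALSE], train = FALSE)
    out_m <- rbind(out_m, s$main)
    out_a <- rbind(out_a, s$aux)
  }
  list(main = out_m, aux = out_a)
}

#' Predict class probabilities for new records
#'
#' @param object a fitted `mtnet`
#' @param records list of `ecg_record` preprocessed to the training shape
#' @param type `"prob"` for sigmoid probabilities, `"logit"` for raw scores
#' @param ... unused
#' @return list with matrices `main` and `aux` (records x classes)
#' @export
predict.mtnet <- function(object, records, type = c("prob", "logit"), ...) {
  type <- match.arg(type)
  x <- records_to_array(records)
  s <- predict_scores(object$net, x, object$control$batch_size)
  if (type == "prob") s <- list(main = sigmoid(s$main), aux = sigmoid(s$aux))
  colnames(s$main) <- object$main_classes
  colnames(s$aux) <- object$aux_classes
  s
}

#' Evaluate a fitted model on a set of records
#'
#' @param object a fitted `mtnet`
#' @param records list of labelled `ecg_record`
#' @return list with a `metrics_report` per task (`main`, `aux`)
#' @export
evaluate_mtnet <- function(object, records) {
  p <- predict.mtnet(object, records)
  ym <- label_matrix(lapply(records, `[[`, "main_labels"), object$main_classes)
  ya <- label_matrix(lapply(records, `[[`, "aux_labels"), object$aux_classes)
  list(main = suppressWarnings(metrics_report(p$main, ym)),
       aux = suppressWarnings(metrics_report(p$aux, ya)))
}

#' @export
print.mtnet <- function(x, ...) {
  cat("Multi-task ECG classifier (", x$direction, " auxiliary task)\n",
      sep = "")
  cat("  main task: ", length(x$main_classes), " classes | aux task: ",
      length(x$aux_classes), " classes | lambda ", x$control$lambda, "\n",
      sep = "")
  cat("  trained ", nrow(x$history), " epochs on ", length(x$folds$train),
      " records (best epoch ", x$best_epoch, ", val loss ",
      signif(x$best_val_loss, 4), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.mtnet <- function(object, ...) {
  print(object)
  print(object$config)
  print(object$control)
  cat("partition: ", length(object$folds$train), " train / ",
      length(object$folds$validation), " validation / ",
      length(object$folds$test), " test\n", sep = "")
  cat("parameters: ", length(nn_get_params(object$net$layers)), "\n", sep = "")
  invisible(object)
}

#' @export
coef.mtnet <- function(object, ...) {
  nn_get_params(object$net$layers)
}

#' Training-history curves
#'
#' Plots training and validation joint loss per epoch, with the validation
#' macro F1 on a second panel.
#' @param x a fitted `mtnet`
#' @param ... passed to `matplot`
#' @export
plot.mtnet <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "joint loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::plot(h$epoch, h$val_macro_f1, type = "b", pch = 16,
                 col = "darkgreen", xlab = "epoch",
                 ylab = "validation macro F1")
  invisible(x)
}
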
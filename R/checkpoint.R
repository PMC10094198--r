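# Model checkpointing: the full configuration plus every numeric state
# (parameters and batch-norm running statistics), so a reloaded model
# reproduces eval-mode predictions bit for bit.

nn_get_state <- function(layers) {
  lapply(layers, function(ly) {
    st <- list(params = ly$params)
    if (!is.null(ly$run_mean))
      st$bn <- list(run_mean = ly$run_mean, run_var = ly$run_var)
    st
  })
}

nn_set_state <- function(layers, state) {
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    for (nm in names(state[[i]]$params)) ly$params[[nm]] <- state[[i]]$params[[nm]]
    if (!is.null(state[[i]]$bn)) {
      ly$run_mean <- state[[i]]$bn$run_mean
      ly$run_var <- state[[i]]$bn$run_var
    }
  }
  invisible(NULL)
}

#' Save / load a fitted model
#'
#' The checkpoint embeds the full architecture configuration, the training
#' control, the class orderings and all numeric state; loading rebuilds the
#' network and restores it exactly.
#'
#' @param object a fitted `mtnet`
#' @param path file path (RDS)
#' @export
save_mtnet <- function(object, path) {
  stopifnot(inherits(object, "mtnet"))
  saveRDS(list(
    config = object$config, control = object$control,
    hierarchy_pairs = data.frame(
      fine = object$hierarchy$fine_classes,
      coarse = unname(object$hierarchy$parent_of[object$hierarchy$fine_classes]),
      stringsAsFactors = FALSE),
    direction = object$direction,
    main_classes = object$main_classes, aux_classes = object$aux_classes,
    state = nn_get_state(object$net$layers),
    history = object$history, best_epoch = object$best_epoch,
    best_val_loss = object$best_val_loss, folds = object$folds,
    n_records = object$n_records), path)
  invisible(path)
}

#' @rdname save_mtnet
#' @export
load_mtnet <- function(path) {
  ck <- readRDS(path)
  rng <- make_rng(ck$control$seed)
  net <- build_network(ck$config, rng)
  nn_set_state(net$layers, ck$state)
  structure(
    list(net = net, config = ck$config, control = ck$control,
         hierarchy = build_hierarchy(ck$hierarchy_pairs),
         direction = ck$direction,
         main_classes = ck$main_classes, aux_classes = ck$aux_classes,
         folds = ck$folds, history = ck$history, best_epoch = ck$best_epoch,
         best_val_loss = ck$best_val_loss, n_records = ck$n_records),
    class = "mtnet")
}
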
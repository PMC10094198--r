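#' Desk-scale experiment configuration
#'
#' The package's standard conditions for the synthetic-data experiments: a
#' nine-class five-group taxonomy with ~600 label assignments, 12-lead
#' records of 3 s at 100 Hz with 0.1 mV noise and 10% multi-label records,
#' a small trunk (two SE blocks of 16 and 32 channels, stride 2 each), CoT
#' kernel 3, 16 GRU units per direction, and ten epochs of Adam at initial
#' learning rate 5e-3 (the corpus-scale schedule starts at 5e-4, sized for
#' thousands of updates; a ten-epoch run on ~500 training records takes
#' ~190 updates, so the desk-scale rate is scaled up one decade).
#'
#' @param n_per_class label assignments per fine class (default 67, about
#'   600 in total)
#' @param noise_sd millivolts of additive noise (default 0.1)
#' @param max_epochs training epochs (default 10)
#' @param lr0 initial learning rate (default 5e-3)
#' @return list with `spec_args`, `config_args`, `control_args`
#' @export
desk_conditions <- function(n_per_class = 67L, noise_sd = 0.1,
                            max_epochs = 10L, lr0 = 5e-3) {
  list(
    spec_args = list(leads = 12L, rate = 100, duration = 3,
                     noise_sd = noise_sd, multilabel_rate = 0.1,
                     n_per_class = as.integer(n_per_class)),
    config_args = list(block_channels = c(16L, 32L),
                       block_strides = c(2L, 2L),
                       gru_hidden = 16L, se_reduction = 4L),
    control_args = list(lr0 = lr0, max_epochs = as.integer(max_epochs),
                        batch_size = 32L))
}

# generate a desk-scale dataset and relabel its auxiliary task under an
# arbitrary grouping of the same fine classes
desk_dataset <- function(h, cond, seed) {
  freq <- stats::setNames(rep(cond$spec_args$n_per_class,
                              length(h$fine_classes)), h$fine_classes)
  sa <- cond$spec_args
  spec <- synth_spec(h, freq, leads = sa$leads, rate = sa$rate,
                     duration = sa$duration, noise_sd = sa$noise_sd,
                     multilabel_rate = sa$multilabel_rate, seed = seed)
  make_dataset(spec)
}

fit_with_aux <- function(ds, aux_h, cond, seed, config_extra = list()) {
  recs <- lapply(ds$records, function(r) {
    r$aux_labels <- derive_aux_labels(r$main_labels, aux_h)
    r
  })
  cfg <- do.call(mtnet_config, c(
    list(in_leads = cond$spec_args$leads,
         n_main_classes = length(aux_h$fine_classes),
         n_aux_classes = length(aux_h$coarse_classes)),
    cond$config_args, config_extra))
  ctl <- do.call(mtnet_train_control, c(cond$control_args, list(seed = seed)))
  fit <- mtnet(recs, aux_h, "merge", cfg, ctl,
               scheme = "ptbxl_recommended", fold_tags = ds$metadata$fold)
  list(fit = fit, records = recs,
       test_idx = which(ds$metadata$fold == 10L))
}

#' Does a meaningful auxiliary task beat a random one?
#'
#' The synthetic analogue of the random-auxiliary-task control: for each
#' seed, a hierarchical dataset is generated, and the same main task is
#' trained twice — once with the true superclasses as the auxiliary task
#' and once with a seeded random regrouping of the same classes into groups
#' of the same sizes.  Because the synthetic coarse groups carry shared
#' morphology traits, the true auxiliary task is informative and the random
#' one is not; the expectation is that the held-out main-task macro F1 with
#' the true hierarchy is at least as high on average.
#'
#' @param seeds integer vector of seeds, one dataset + model pair per seed
#' @param hierarchy the taxonomy (default CPSC-style)
#' @param conditions a [desk_conditions()] list
#' @param verbose print one line per run
#' @return object of class `mtl_benefit`: data.frame `runs` with columns
#'   `seed`, `f1_true`, `f1_random`, and the two means
#' @export
mtl_benefit_experiment <- function(seeds = 1:5, hierarchy = cpsc_hierarchy(),
                                   conditions = desk_conditions(),
                                   verbose = FALSE) {
  runs <- lapply(seeds, function(seed) {
    ds <- desk_dataset(hierarchy, conditions, seed)
    ft <- fit_with_aux(ds, hierarchy, conditions, seed)
    f1_true <- evaluate_mtnet(ft$fit, ft$records[ft$test_idx])$main$macro_f1
    rh <- random_hierarchy(hierarchy, seed)
    fr <- fit_with_aux(ds, rh, conditions, seed)
    f1_rand <- evaluate_mtnet(fr$fit, fr$records[fr$test_idx])$main$macro_f1
    if (verbose)
      message(sprintf("seed %d: true %.3f random %.3f", seed, f1_true, f1_rand))
    data.frame(seed = seed, f1_true = f1_true, f1_random = f1_rand)
  })
  runs <- do.call(rbind, runs)
  structure(list(runs = runs,
                 mean_true = mean(runs$f1_true),
                 mean_random = mean(runs$f1_random)),
            class = "mtl_benefit")
}

#' @export
print.mtl_benefit <- function(x, ...) {
  cat("Auxiliary-task benefit on synthetic hierarchical data\n")
  print(transform(x$runs, f1_true = round(f1_true, 3),
                  f1_random = round(f1_random, 3)), row.names = FALSE)
  cat(sprintf("mean held-out macro F1: true %.3f vs random %.3f (delta %+.3f)\n",
              x$mean_true, x$mean_random, x$mean_true - x$mean_random))
  invisible(x)
}

#' Ablation sweep over the architecture switches
#'
#' Runs the four study variants on one synthetic dataset: the full model,
#' the model without the CoT block, the model without the Bi-GRU (global
#' average pooling instead), and the full model with a random auxiliary
#' task.  Each variant trains under identical conditions and is evaluated
#' on the held-out test fold.
#'
#' @param seed dataset and training seed
#' @param hierarchy the taxonomy (default CPSC-style)
#' @param conditions a [desk_conditions()] list
#' @return object of class `mtnet_ablation`: named list of
#'   `metrics_report`s plus a `comparison` data.frame of macro scores
#' @export
run_ablation <- function(seed = 1L, hierarchy = cpsc_hierarchy(),
                         conditions = desk_conditions()) {
  ds <- desk_dataset(hierarchy, conditions, seed)
  variants <- list(
    full = list(aux = hierarchy, extra = list()),
    no_cot = list(aux = hierarchy, extra = list(use_cot = FALSE)),
    no_bigru = list(aux = hierarchy, extra = list(use_bigru = FALSE)),
    random_aux = list(aux = random_hierarchy(hierarchy, seed), extra = list()))
  reports <- lapply(variants, function(v) {
    ft <- fit_with_aux(ds, v$aux, conditions, seed, v$extra)
    evaluate_mtnet(ft$fit, ft$records[ft$test_idx])$main
  })
  comparison <- data.frame(
    variant = names(reports),
    macro_f1 = vapply(reports, `[[`, numeric(1), "macro_f1"),
    macro_auc = vapply(reports, `[[`, numeric(1), "macro_auc"),
    macro_accuracy = vapply(reports, `[[`, numeric(1), "macro_accuracy"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(reports = reports, comparison = comparison, seed = seed),
            class = "mtnet_ablation")
}

#' @export
print.mtnet_ablation <- function(x, ...) {
  cat("Ablation sweep (seed ", x$seed, ")\n", sep = "")
  tab <- x$comparison
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
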
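test_that("the joint loss interpolates the two task losses", {
  # lambda endpoints and midpoint arithmetic on fixed probability tensors
  sm <- matrix(c(0.9, 0.2), 1); tm <- matrix(c(1, 0), 1)
  sa <- matrix(c(0.6, 0.4), 1); ta <- matrix(c(1, 1), 1)
  l_main <- -mean(log(c(0.9, 0.8)))
  l_aux <- -mean(log(c(0.6, 0.4)))
  expect_equal(joint_loss(sm, tm, sa, ta, 1), l_main, tolerance = 1e-9)
  expect_equal(joint_loss(sm, tm, sa, ta, 0), l_aux, tolerance = 1e-9)
  expect_equal(joint_loss(sm, tm, sa, ta, 0.5), (l_main + l_aux) / 2,
               tolerance = 1e-9)
  expect_error(joint_loss(sm, tm, sa, ta, 1.2), "lambda")
})

test_that("the joint loss is linear in lambda", {
  set.seed(20)
  sm <- matrix(runif(12, 0.05, 0.95), 3); tm <- matrix(rbinom(12, 1, 0.5), 3)
  sa <- matrix(runif(6, 0.05, 0.95), 3); ta <- matrix(rbinom(6, 1, 0.5), 3)
  at <- function(l) joint_loss(sm, tm, sa, ta, l)
  lams <- seq(0, 1, by = 0.25)
  vals <- vapply(lams, at, numeric(1))
  fit <- lm(vals ~ lams)
  expect_equal(unname(fitted(fit)), vals, tolerance = 1e-12)
})

test_that("a single hand-computed record reproduces the scalar cross-entropy", {
  # one record, two classes, p = (0.8, 0.3), t = (1, 0):
  # L = -(log 0.8 + log 0.7)/2 = 0.28990
  expect_equal(joint_loss(matrix(c(0.8, 0.3), 1), matrix(c(1, 0), 1),
                          matrix(0.5, 1, 1), matrix(1, 1, 1), 1),
               -(log(0.8) + log(0.7)) / 2, tolerance = 1e-8)
})

test_that("the learning-rate schedule decays by a decade every ten epochs", {
  ctl <- mtnet_train_control()
  expect_equal(lr_at_epoch(0, ctl), 0.0005)
  expect_equal(lr_at_epoch(9, ctl), 0.0005)
  expect_equal(lr_at_epoch(10, ctl), 0.00005)
  expect_equal(lr_at_epoch(25, ctl), 0.0005 * 0.01)
  expect_error(lr_at_epoch(-1, ctl))
})

test_that("early stopping triggers exactly after the patience window", {
  expect_false(early_stop(seq(1, 0.1, by = -0.1), 10))
  hist <- c(1, 0.5, rep(0.6, 10))
  expect_true(early_stop(hist, 10))
  expect_false(early_stop(hist[1:11], 10))          # only 9 bad epochs
  hist2 <- c(1, 0.5, rep(0.6, 9), 0.4)              # improvement at the end
  expect_false(early_stop(hist2, 10))
  expect_false(early_stop(0.7, 10))
  expect_error(early_stop(numeric(0), 10), "empty")
})

test_that("the recommended partition splits fold tags 8:1:1", {
  ds <- tiny_dataset(n_per_class = 2L)
  n <- length(ds$records)
  tags <- rep_len(1:10, n)
  f <- make_folds(ds$records, "ptbxl_recommended", fold_tags = tags)
  expect_setequal(f$train, which(tags <= 8))
  expect_setequal(f$validation, which(tags == 9))
  expect_setequal(f$test, which(tags == 10))
  expect_error(make_folds(ds$records, "ptbxl_recommended"), "fold tags")
})

test_that("stratified folds are deterministic and balanced", {
  set.seed(30)
  recs <- lapply(1:100, function(i)
    ecg_record(paste0("r", i), matrix(rnorm(20), 2), 100,
               main_labels = if (i <= 50) "A" else "B",
               aux_labels = "G"))
  f1 <- make_folds(recs, "stratified_10fold", seed = 5)
  f2 <- make_folds(recs, "stratified_10fold", seed = 5)
  expect_identical(f1$fold_of, f2$fold_of)
  # 50 records per class over 10 folds: exactly 5 of each class per fold
  for (k in 1:10) {
    in_fold <- which(f1$fold_of == k)
    expect_equal(sum(in_fold <= 50), 5L)
    expect_equal(sum(in_fold > 50), 5L)
  }
})

test_that("training reduces the joint loss on separable synthetic data", {
  ds <- tiny_dataset(n_per_class = 8L, noise_sd = 0.05, seed = 31L,
                     duration = 2)
  cfg <- mtnet_config(in_leads = 12, n_main_classes = 9, n_aux_classes = 5,
                      block_channels = c(8, 16), block_strides = c(2, 2),
                      gru_hidden = 8, se_reduction = 4)
  ctl <- mtnet_train_control(lr0 = 5e-3, max_epochs = 5, seed = 1)
  fit <- mtnet(ds$records, cpsc_hierarchy(), "merge", cfg, ctl,
               scheme = "ptbxl_recommended", fold_tags = ds$metadata$fold)
  expect_lt(fit$history$train_loss[5], fit$history$train_loss[1])
  expect_s3_class(fit, "mtnet")
  expect_equal(nrow(fit$history), 5L)
})

test_that("two runs with the same seed produce identical epoch-one losses", {
  ds <- tiny_dataset(n_per_class = 4L, duration = 2)
  cfg <- mtnet_config(in_leads = 12, n_main_classes = 9, n_aux_classes = 5,
                      block_channels = 8, block_strides = 2,
                      gru_hidden = 4, se_reduction = 4)
  ctl <- mtnet_train_control(max_epochs = 1, seed = 77)
  f1 <- mtnet(ds$records, cpsc_hierarchy(), "merge", cfg, ctl,
              scheme = "ptbxl_recommended", fold_tags = ds$metadata$fold)
  f2 <- mtnet(ds$records, cpsc_hierarchy(), "merge", cfg, ctl,
              scheme = "ptbxl_recommended", fold_tags = ds$metadata$fold)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
  expect_identical(coef(f1), coef(f2))
})

test_that("lambda = 1 leaves the auxiliary head untrained", {
  ds <- tiny_dataset(n_per_class = 3L, duration = 2, seed = 32L)
  cfg <- mtnet_config(in_leads = 12, n_main_classes = 9, n_aux_classes = 5,
                      block_channels = 8, block_strides = 2,
                      gru_hidden = 4, se_reduction = 4)
  ctl <- mtnet_train_control(lambda = 1, max_epochs = 2, seed = 3)
  fit <- mtnet(ds$records, cpsc_hierarchy(), "merge", cfg, ctl,
               scheme = "ptbxl_recommended", fold_tags = ds$metadata$fold)
  rng <- ecgmtnet:::make_rng(3L)
  init <- ecgmtnet:::build_network(fit$config, rng)
  expect_equal(fit$net$head_aux$params$W, init$head_aux$params$W)
  expect_false(isTRUE(all.equal(fit$net$head_main$params$W,
                                init$head_main$params$W)))
})

test_that("empty training inputs are rejected", {
  expect_error(mtnet(list(), cpsc_hierarchy()), "empty")
})

test_that("prediction and evaluation run on held-out records", {
  ds <- tiny_dataset(n_per_class = 12L, duration = 2, seed = 33L)
  cfg <- mtnet_config(in_leads = 12, n_main_classes = 9, n_aux_classes = 5,
                      block_channels = 8, block_strides = 2,
                      gru_hidden = 4, se_reduction = 4)
  ctl <- mtnet_train_control(max_epochs = 1, seed = 2)
  fit <- mtnet(ds$records, cpsc_hierarchy(), "merge", cfg, ctl,
               scheme = "ptbxl_recommended", fold_tags = ds$metadata$fold)
  te <- ds$records[fit$folds$test]
  p <- predict(fit, te)
  expect_equal(dim(p$main), c(length(te), 9L))
  expect_true(all(p$main >= 0 & p$main <= 1))
  expect_identical(colnames(p$main), cpsc_hierarchy()$fine_classes)
  ev <- evaluate_mtnet(fit, te)
  expect_s3_class(ev$main, "metrics_report")
  expect_s3_class(ev$aux, "metrics_report")
})

test_that("checkpoints restore eval-mode predictions exactly", {
  ds <- tiny_dataset(n_per_class = 3L, duration = 2, seed = 34L)
  cfg <- mtnet_config(in_leads = 12, n_main_classes = 9, n_aux_classes = 5,
                      block_channels = 8, block_strides = 2,
                      gru_hidden = 4, se_reduction = 4)
  ctl <- mtnet_train_control(max_epochs = 1, seed = 4)
  fit <- mtnet(ds$records, cpsc_hierarchy(), "merge", cfg, ctl,
               scheme = "ptbxl_recommended", fold_tags = ds$metadata$fold)
  path <- withr::local_tempfile(fileext = ".rds")
  save_mtnet(fit, path)
  fit2 <- load_mtnet(path)
  p1 <- predict(fit, ds$records[1:5])
  p2 <- predict(fit2, ds$records[1:5])
  expect_identical(p1$main, p2$main)
  expect_identical(p1$aux, p2$aux)
})
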
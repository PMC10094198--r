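test_that("a beat is a sum of Gaussian bumps on a zero baseline", {
  flat <- make_beat(250, 0.8, amps = c(0, 0, 0, 0, 0))
  expect_true(all(flat == 0))
  lone <- make_beat(250, 0.8, amps = c(0, 0, 1, 0, 0))
  expect_equal(which.max(lone), round(0.26 * 250) + 1L, tolerance = 1)
  expect_gt(max(lone), 0.99)
  deft <- make_beat(250, 0.8)
  expect_equal(which.max(deft), round(0.26 * 250) + 1L, tolerance = 1)
  expect_error(make_beat(250, 0.8, widths = c(0.03, -0.01, 0.02, 0.01, 0.05)),
               "positive")
  expect_error(make_beat(250, 0), "positive")
})

test_that("record synthesis is deterministic given the rng state", {
  h <- cpsc_hierarchy()
  spec <- synth_spec(h, stats::setNames(rep(1L, 9), h$fine_classes),
                     leads = 4, rate = 100, duration = 2, noise_sd = 0,
                     seed = 1)
  r1 <- make_record("AF", spec, ecgmtnet:::make_rng(5))
  r2 <- make_record("AF", spec, ecgmtnet:::make_rng(5))
  expect_identical(r1$signal, r2$signal)
  expect_error(make_record("nope", spec, ecgmtnet:::make_rng(1)), "nope")
})

test_that("QRS-group records have wider QRS complexes than normal records", {
  h <- cpsc_hierarchy()
  spec <- synth_spec(h, stats::setNames(rep(1L, 9), h$fine_classes),
                     leads = 1, rate = 250, duration = 4, noise_sd = 0,
                     seed = 2)
  # width measured by threshold crossing around the tallest peak
  qrs_width <- function(r) {
    x <- r$signal[1, ]
    pk <- which.max(x)
    half <- 0.5 * x[pk]
    lo <- pk; while (lo > 1 && x[lo] > half) lo <- lo - 1
    hi <- pk; while (hi < length(x) && x[hi] > half) hi <- hi + 1
    hi - lo
  }
  rng <- ecgmtnet:::make_rng(3)
  w_wide <- mean(vapply(1:5, function(i)
    qrs_width(make_record("LBBB", spec, rng)), numeric(1)))
  w_norm <- mean(vapply(1:5, function(i)
    qrs_width(make_record("SNR", spec, rng)), numeric(1)))
  expect_gt(w_wide, w_norm)
})

test_that("the coarse groups imprint their distinguishing traits", {
  h <- cpsc_hierarchy()
  spec <- synth_spec(h, stats::setNames(rep(1L, 9), h$fine_classes),
                     leads = 1, rate = 250, duration = 8, noise_sd = 0,
                     seed = 4)
  rng <- ecgmtnet:::make_rng(8)
  rr_sd <- function(r) {
    x <- r$signal[1, ]
    pk <- which(x > 0.55 * max(x))
    pk <- pk[c(TRUE, diff(pk) > 50)]
    stats::sd(diff(pk)) / mean(diff(pk))
  }
  af <- mean(vapply(1:4, function(i) rr_sd(make_record("AF", spec, rng)),
                    numeric(1)))
  nr <- mean(vapply(1:4, function(i) rr_sd(make_record("SNR", spec, rng)),
                    numeric(1)))
  expect_gt(af, nr)                      # irregular RR intervals
  ste <- make_record("STE", spec, rng)
  std <- make_record("STD", spec, rng)
  st_level <- function(r) {
    x <- r$signal[1, ]
    pk <- which.max(x)                   # first R peak region
    mean(x[pk + round(0.07 * 250) + 0:5])
  }
  expect_gt(st_level(ste), st_level(std))  # offset sign splits the ST pair
})

test_that("datasets honour the frequency map, hierarchy and multilabel dial", {
  h <- cpsc_hierarchy()
  freq <- stats::setNames(c(5L, 7L, 3L, 2L, 6L, 4L, 4L, 3L, 2L),
                          h$fine_classes)
  spec <- synth_spec(h, freq, leads = 2, rate = 100, duration = 2,
                     noise_sd = 0.05, multilabel_rate = 0.15, seed = 6)
  ds <- make_dataset(spec)
  cs <- class_count_summary(ds$labelings, h)
  expect_identical(unname(cs$fine[names(freq)]), as.integer(freq))
  expect_equal(cs$n_fine_assignments, sum(freq))
  # every record's auxiliary labels are the parents of its fine labels
  for (r in ds$records)
    expect_setequal(r$aux_labels, derive_aux_labels(r$main_labels, h))
  # multi-label records pair classes from different coarse groups
  multi <- Filter(function(r) length(r$main_labels) == 2L, ds$records)
  expect_gt(length(multi), 0L)
  for (r in multi)
    expect_length(unique(unname(h$parent_of[r$main_labels])), 2L)
  expect_true(all(ds$metadata$fold %in% 1:10))

  spec0 <- synth_spec(h, freq, leads = 2, rate = 100, duration = 2,
                      multilabel_rate = 0, seed = 6)
  ds0 <- make_dataset(spec0, signals = FALSE)
  expect_true(all(vapply(ds0$labelings, function(tl)
    length(tl$main_labels), integer(1)) == 1L))
  expect_null(ds0$records)
})

test_that("identical spec and seed give byte-identical datasets", {
  spec <- synth_spec(cpsc_hierarchy(),
                     stats::setNames(rep(2L, 9), cpsc_hierarchy()$fine_classes),
                     leads = 3, rate = 100, duration = 2, seed = 9)
  d1 <- make_dataset(spec)
  d2 <- make_dataset(spec)
  expect_identical(lapply(d1$records, `[[`, "signal"),
                   lapply(d2$records, `[[`, "signal"))
  expect_identical(d1$metadata, d2$metadata)
})

test_that("full-scale frequency maps reproduce the corpus bookkeeping", {
  h <- cpsc_hierarchy()
  spec <- synth_spec(h, attr(h, "counts"), seed = 1)
  ds <- make_dataset(spec, signals = FALSE)
  cs <- class_count_summary(ds$labelings, h)
  expect_equal(cs$n_fine_assignments, 6877L)

  hp <- ptbxl_hierarchy()
  spec_p <- synth_spec(hp, attr(hp, "counts"), seed = 1)
  ds_p <- make_dataset(spec_p, signals = FALSE)
  cs_p <- class_count_summary(ds_p$labelings, hp)
  expect_equal(cs_p$n_fine_assignments, 30560L)
})

test_that("the noise dial moves a nearest-centroid baseline from skill to chance", {
  h <- cpsc_hierarchy()
  freq <- stats::setNames(rep(30L, 9), h$fine_classes)
  f1_at <- function(noise) {
    spec <- synth_spec(h, freq, leads = 12, rate = 100, duration = 5,
                       noise_sd = noise, multilabel_rate = 0, seed = 5)
    ds <- make_dataset(spec)
    tr <- ds$records[ds$metadata$fold <= 8]
    te <- ds$records[ds$metadata$fold > 8]
    centroid_baseline(tr, te)$macro_f1
  }
  f_lo <- f1_at(0.02); f_mid <- f1_at(0.6); f_hi <- f1_at(3.0)
  expect_gt(f_lo, 0.9)
  expect_gt(f_lo, f_mid)
  expect_gte(f_mid, f_hi - 0.05)
  expect_lt(f_hi, 0.3)
})

test_that("relabel_for_split swaps the task direction", {
  ds <- tiny_dataset(n_per_class = 1L)
  sw <- relabel_for_split(ds$records)
  expect_identical(sw[[1]]$main_labels, ds$records[[1]]$aux_labels)
  expect_identical(sw[[1]]$aux_labels, ds$records[[1]]$main_labels)
})
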
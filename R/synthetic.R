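#' Specification for a synthetic hierarchical ECG dataset
#'
#' The generator emulates the structure of the benchmark corpora: multi-lead
#' quasi-periodic signals whose classes form a two-level hierarchy, with
#' per-class frequencies, multi-label records pairing classes from different
#' superclass groups, and additive Gaussian noise.  Each coarse group
#' imprints a shared morphology trait on its members (widened QRS complex,
#' irregular RR intervals, premature beats, ST-segment offset), and each
#' fine class perturbs the waveform within that trait — so the hierarchy is
#' informative by construction, the property the random-grouping control
#' experiment manipulates.
#'
#' @param hierarchy a `label_hierarchy` (default: the nine-class five-group
#'   CPSC-style taxonomy)
#' @param frequencies named non-negative integer vector of label-assignment
#'   counts per fine class; defaults to the hierarchy's published `counts`
#'   attribute, or 40 per class when absent
#' @param leads number of leads (default 12)
#' @param rate sampling rate, Hz (default 500, the clinical acquisition
#'   rate)
#' @param duration record length, seconds (default 10)
#' @param hr_range heart-rate range, beats/minute (default 60-100)
#' @param noise_sd additive Gaussian noise, millivolts (default 0.1; the R
#'   peak is ~1 mV)
#' @param multilabel_rate fraction of records carrying two fine labels from
#'   different coarse groups (default 0.1)
#' @param seed integer seed; identical spec + seed gives an identical
#'   dataset
#' @return object of class `synth_spec`
#' @export
synth_spec <- function(hierarchy = cpsc_hierarchy(), frequencies = NULL,
                       leads = 12L, rate = 500, duration = 10,
                       hr_range = c(60, 100), noise_sd = 0.1,
                       multilabel_rate = 0.1, seed = 1L) {
  validate_hierarchy(hierarchy)
  if (is.null(frequencies)) {
    frequencies <- attr(hierarchy, "counts") %||%
      stats::setNames(rep(40L, length(hierarchy$fine_classes)),
                      hierarchy$fine_classes)
  }
  if (is.null(names(frequencies)) ||
      !all(names(frequencies) %in% hierarchy$fine_classes))
    stop("every frequency key must be a fine class of the hierarchy")
  if (any(frequencies < 0)) stop("frequencies must be non-negative")
  if (multilabel_rate < 0 || multilabel_rate > 1)
    stop("multilabel_rate must lie in [0, 1]")
  structure(list(hierarchy = hierarchy,
                 frequencies = frequencies,
                 leads = as.integer(leads), rate = rate, duration = duration,
                 hr_range = hr_range, noise_sd = noise_sd,
                 multilabel_rate = multilabel_rate, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Synthesize a single beat as a sum of Gaussian bumps
#'
#' The classic additive approximation of the PQRST complex: each wave is a
#' Gaussian bump on a zero baseline.  Generic in the number of bumps, which
#' lets class morphologies add ST-segment plateaus or secondary R waves.
#'
#' @param rate sampling rate, Hz
#' @param duration beat duration, seconds
#' @param centers bump centres, seconds from beat onset
#' @param amps bump amplitudes, millivolts
#' @param widths bump standard deviations, seconds (all > 0)
#' @return numeric waveform of `round(duration * rate)` samples
#' @export
make_beat <- function(rate, duration,
                      centers = c(0.10, 0.22, 0.26, 0.30, 0.45),
                      amps = c(0.15, -0.12, 1.0, -0.2, 0.3),
                      widths = c(0.035, 0.012, 0.018, 0.014, 0.060)) {
  if (duration <= 0) stop("beat duration must be positive")
  stopifnot(length(centers) == length(amps), length(amps) == length(widths))
  if (any(widths <= 0)) stop("bump widths must be positive")
  if (!all(is.finite(c(centers, amps, widths)))) stop("wave parameters must be finite")
  t <- (seq_len(round(duration * rate)) - 1) / rate
  y <- numeric(length(t))
  for (k in seq_along(centers))
    y <- y + amps[k] * exp(-0.5 * ((t - centers[k]) / widths[k])^2)
  y
}

# baseline morphology parameters, modified per class
base_beat_params <- function() {
  list(rr_jitter = 0.03,    # sd of RR interval, fraction of the base RR
       p_amp = 0.15, q_amp = -0.12, r_amp = 1.0, s_amp = -0.2, t_amp = 0.3,
       qrs_width = 1.0,     # multiplier on Q/R/S bump widths
       pr_stretch = 1.0,    # multiplier on the P-to-R distance
       r2_amp = 0.0,        # secondary R' bump (notched QRS)
       st_offset = 0.0,     # ST-segment plateau, millivolts
       premature_rate = 0.0)
}

# coarse-group trait palette, applied by group position in the hierarchy;
# positions cycle for taxonomies with more than five groups
apply_coarse_trait <- function(p, palette_idx, strength = 1) {
  switch(((palette_idx - 1L) %% 5L) + 1L,
         p,                                                   # normal
         { p$rr_jitter <- p$rr_jitter + 0.22 * strength       # AF-like
           p$p_amp <- p$p_amp - 0.14 * strength; p },
         { p$qrs_width <- p$qrs_width + 1.3 * strength; p },  # widened QRS
         { p$premature_rate <- p$premature_rate + 0.35 * strength; p },
         { p$st_offset <- p$st_offset + 0.22 * strength; p })
}

# fine-class perturbation within the group trait, by within-group position;
# in ST-offset groups even members flip the offset sign (depression vs
# elevation), elsewhere the archetypes tweak secondary waves
apply_fine_trait <- function(p, member_idx, palette_idx) {
  if (((palette_idx - 1L) %% 5L) + 1L == 5L && member_idx %% 2L == 0L)
    p$st_offset <- -p$st_offset
  switch(((member_idx - 1L) %% 8L) + 1L,
         p,
         { p$pr_stretch <- p$pr_stretch + 0.55; p$p_amp <- p$p_amp + 0.08; p },
         { p$s_amp <- p$s_amp - 0.35; p },
         { p$r2_amp <- p$r2_amp + 0.35; p },
         { p$t_amp <- p$t_amp - 0.22; p },
         { p$r_amp <- p$r_amp + 0.25; p },
         { p$t_amp <- p$t_amp + 0.18; p$p_amp <- p$p_amp - 0.05; p },
         { p$qrs_width <- p$qrs_width + 0.25; p })
}

# morphology parameters for one or two fine classes (multi-label overlay)
class_beat_params <- function(classes, h) {
  p <- base_beat_params()
  for (cl in classes) {
    if (!cl %in% h$fine_classes) stop("unknown class: ", cl)
    g <- unname(h$parent_of[[cl]])
    gi <- match(g, h$coarse_classes)
    mi <- match(cl, children_of(h, g))
    p <- apply_coarse_trait(p, gi)
    p <- apply_fine_trait(p, mi, gi)
  }
  p
}

beat_from_params <- function(p, rate, rr) {
  r_c <- 0.26
  centers <- c(r_c - 0.16 * p$pr_stretch, 0.22, r_c, 0.30, 0.45)
  amps <- c(p$p_amp, p$q_amp, p$r_amp, p$s_amp, p$t_amp)
  widths <- c(0.035, 0.012 * p$qrs_width, 0.018 * p$qrs_width,
              0.014 * p$qrs_width, 0.060)
  if (p$r2_amp != 0) {
    centers <- c(centers, r_c + 0.045 * p$qrs_width)
    amps <- c(amps, p$r2_amp)
    widths <- c(widths, 0.016 * p$qrs_width)
  }
  if (p$st_offset != 0) {
    centers <- c(centers, 0.37)
    amps <- c(amps, p$st_offset)
    widths <- c(widths, 0.045)
  }
  make_beat(rate, rr, centers, amps, widths)
}

# canonical relative lead gains (limb + precordial pattern)
lead_gains <- function(n) {
  std <- c(0.6, 1.0, 0.5, -0.7, 0.3, 0.8, -0.4, 0.9, 1.1, 1.0, 0.8, 0.7)
  rep_len(std, n)
}

#' Generate one synthetic labelled record
#'
#' Tiles beats with jittered RR intervals over the requested duration.  The
#' record's classes decide the morphology: the coarse group supplies the
#' shared trait, the fine class the within-group perturbation; two classes
#' (multi-label) overlay both modifications.  Leads are amplitude-scaled
#' copies of the cardiac source with independent Gaussian noise, and the
#' auxiliary labels are always the parents of the fine labels.
#'
#' @param classes one or two fine classes of `spec$hierarchy`
#' @param spec a `synth_spec`
#' @param rng a private rng stream (from the dataset seed); pass the same
#'   state to reproduce the record
#' @param record_id identifier (default "synth")
#' @return an `ecg_record`
#' @export
make_record <- function(classes, spec, rng, record_id = "synth") {
  p <- class_beat_params(classes, spec$hierarchy)
  n <- round(spec$duration * spec$rate)
  hr <- rng$runif(1, spec$hr_range[1L], spec$hr_range[2L])
  rr_base <- 60 / hr
  src <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    rr <- rr_base * (1 + rng$rnorm(1, 0, p$rr_jitter))
    premature <- p$premature_rate > 0 && rng$runif(1) < p$premature_rate
    pb <- p
    if (premature) {
      rr <- rr * 0.65
      pb$r_amp <- p$r_amp * 1.2
      pb$qrs_width <- p$qrs_width * 1.4
      pb$p_amp <- 0
    }
    rr <- max(rr, 0.35)
    beat <- beat_from_params(pb, spec$rate, rr)
    take <- min(length(beat), n - pos + 1L)
    src[pos:(pos + take - 1L)] <- src[pos:(pos + take - 1L)] + beat[seq_len(take)]
    pos <- pos + length(beat)
  }
  gains <- lead_gains(spec$leads) * (1 + rng$rnorm(spec$leads, 0, 0.07))
  sig <- outer(gains, src)
  if (spec$noise_sd > 0)
    sig <- sig + matrix(rng$rnorm(length(sig), 0, spec$noise_sd), nrow = spec$leads)
  ecg_record(record_id, sig, spec$rate,
             main_labels = classes,
             aux_labels = derive_aux_labels(classes, spec$hierarchy))
}

#' Generate a complete synthetic dataset
#'
#' Builds one label assignment per unit of the per-class frequency map,
#' pairs a `multilabel_rate` fraction of records with a second class from a
#' different coarse group, synthesizes the signals, and assigns
#' class-stratified fold tags 1-10 so the recommended-partition scheme can
#' be exercised.  Per-class label-assignment counts match the frequency map
#' exactly.
#'
#' @param spec a `synth_spec`
#' @param signals generate waveforms (default); `FALSE` returns labels and
#'   metadata only, for count bookkeeping at full corpus scale
#' @return list with `records` (list of `ecg_record`, or `NULL` when
#'   `signals = FALSE`), `metadata` (record_id, labels, aux_labels, fold),
#'   `labelings` (list of `task_labeling`), and the `hierarchy`
#' @export
make_dataset <- function(spec, signals = TRUE) {
  stopifnot(inherits(spec, "synth_spec"))
  h <- spec$hierarchy
  freq <- spec$frequencies
  total <- sum(freq)
  if (total == 0L) stop("frequency map sums to zero")
  rng <- make_rng(spec$seed)

  tokens <- rep(names(freq), times = freq)
  tokens <- tokens[rng$sample(length(tokens))]
  n_multi_target <- round(spec$multilabel_rate * total / (1 + spec$multilabel_rate))

  groups <- unname(h$parent_of[tokens])
  used <- logical(length(tokens))
  label_sets <- list()
  n_multi <- 0L
  for (i in seq_along(tokens)) {
    if (used[i]) next
    used[i] <- TRUE
    if (n_multi < n_multi_target) {
      j <- which(!used & groups != groups[i])[1L]
      if (!is.na(j)) {
        used[j] <- TRUE
        label_sets[[length(label_sets) + 1L]] <- c(tokens[i], tokens[j])
        n_multi <- n_multi + 1L
        next
      }
    }
    label_sets[[length(label_sets) + 1L]] <- tokens[i]
  }

  n_rec <- length(label_sets)
  ids <- sprintf("S%05d", seq_len(n_rec))
  labelings <- lapply(seq_len(n_rec), function(i)
    task_labeling(ids[i], label_sets[[i]],
                  derive_aux_labels(label_sets[[i]], h), "merge", h))

  # class-stratified fold tags by primary label
  fold <- integer(n_rec)
  primary <- vapply(label_sets, `[[`, character(1), 1L)
  for (cl in unique(primary)) {
    idx <- which(primary == cl)
    idx <- idx[rng$sample(length(idx))]
    fold[idx] <- rep_len(1:10, length(idx))
  }

  records <- NULL
  if (signals) {
    records <- lapply(seq_len(n_rec), function(i)
      make_record(label_sets[[i]], spec, rng, ids[i]))
  }
  meta <- data.frame(
    record_id = ids,
    labels = vapply(label_sets, paste, character(1), collapse = "|"),
    aux_labels = vapply(labelings, function(tl)
      paste(tl$aux_labels, collapse = "|"), character(1)),
    fold = fold, stringsAsFactors = FALSE)
  list(records = records, metadata = meta, labelings = labelings,
       hierarchy = h)
}

#' Swap a merge-direction dataset to the split-direction task
#'
#' Re-labels records so the coarse classes are the main task and the fine
#' classes the auxiliary task (the subclass-reuse strategy used when the
#' corpus is labelled at the coarse level and a finer labelling exists).
#'
#' @param records list of `ecg_record` with fine main labels and coarse aux
#'   labels
#' @return the records with the two label sets exchanged
#' @export
relabel_for_split <- function(records) {
  lapply(records, function(r) {
    tmp <- r$main_labels
    r$main_labels <- r$aux_labels
    r$aux_labels <- tmp
    r
  })
}

# ---- nearest-centroid reference baseline ---------------------------------

# beat-averaged waveform features: R peaks are detected on the
# highest-variance lead, fixed windows around them are averaged (phase
# invariance), downsampled, and joined with RR-interval statistics
beat_features <- function(r, n_points = 40L) {
  lead <- which.max(apply(r$signal, 1L, stats::var))
  x <- r$signal[lead, ]
  if (stats::median(x) > mean(range(x))) x <- -x
  thr <- 0.5 * max(abs(x))
  min_dist <- round(0.3 * r$rate)
  cand <- which(abs(x) > thr)
  peaks <- integer(0)
  last <- -min_dist
  for (i in cand) {
    if (i - last >= min_dist) { peaks <- c(peaks, i); last <- i }
    else if (abs(x[i]) > abs(x[peaks[length(peaks)]])) {
      peaks[length(peaks)] <- i; last <- i
    }
  }
  w_pre <- round(0.25 * r$rate); w_post <- round(0.45 * r$rate)
  ok <- peaks[peaks > w_pre & peaks + w_post <= length(x)]
  if (length(ok) == 0L) ok <- peaks[1L]
  win <- vapply(ok, function(pk)
    x[(pk - w_pre):(pk + w_post)], numeric(w_pre + w_post + 1L))
  avg <- rowMeans(as.matrix(win))
  idx <- round(seq(1L, length(avg), length.out = n_points))
  rr <- diff(peaks) / r$rate
  rr_stats <- if (length(rr) >= 2L)
    c(mean(rr), stats::sd(rr), min(rr) / stats::median(rr),
      mean(rr < 0.8 * stats::median(rr)))
  else c(mean(rr) %||% 1, 0, 1, 0)
  c(avg[idx], rr_stats * c(1, 10, 1, 1))
}

#' Nearest-centroid reference classifier on beat-averaged waveforms
#'
#' A deliberately simple baseline used to calibrate the difficulty dial of
#' the synthetic generator: class centroids of beat-averaged waveform
#' features are fit on single-label training records and test records are
#' assigned to the nearest centroid.
#'
#' @param train,test lists of `ecg_record`
#' @return list with the predicted class per test record and the main-task
#'   macro F1 over the single-label test records
#' @export
centroid_baseline <- function(train, test) {
  single <- function(rs) rs[vapply(rs, function(r)
    length(r$main_labels) == 1L, logical(1))]
  tr <- single(train); te <- single(test)
  if (length(tr) == 0L || length(te) == 0L)
    stop("need single-label records on both sides")
  ftr <- t(vapply(tr, beat_features, numeric(44L)))
  fte <- t(vapply(te, beat_features, numeric(44L)))
  ytr <- vapply(tr, function(r) r$main_labels, character(1))
  classes <- sort(unique(ytr))
  cents <- t(vapply(classes, function(cl)
    colMeans(ftr[ytr == cl, , drop = FALSE]), numeric(ncol(ftr))))
  d2 <- outer(rowSums(fte^2), rep(1, length(classes))) -
    2 * fte %*% t(cents) + outer(rep(1, nrow(fte)), rowSums(cents^2))
  pred <- classes[apply(d2, 1L, which.min)]
  yte <- vapply(te, function(r) r$main_labels, character(1))
  pm <- label_matrix(as.list(pred), classes)
  tm <- label_matrix(as.list(yte), classes)
  rep <- suppressWarnings(metrics_report(pm, tm))
  list(predictions = pred, truth = yte, macro_f1 = rep$macro_f1)
}
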
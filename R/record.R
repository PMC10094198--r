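#' Multichannel ECG records
#'
#' An `ecg_record` holds one multichannel signal (matrix of leads x samples,
#' in millivolts), its sampling rate in Hz, and the main-task and
#' auxiliary-task label sets.
#'
#' @param record_id identifier string
#' @param signal numeric matrix, leads x samples, millivolts
#' @param rate sampling rate in samples/second
#' @param main_labels,aux_labels character vectors (possibly empty)
#' @return object of class `ecg_record`
#' @export
ecg_record <- function(record_id, signal, rate,
                       main_labels = character(0), aux_labels = character(0)) {
  signal <- as.matrix(signal)
  if (nrow(signal) < 1L || ncol(signal) < 1L)
    stop("signal must have at least one lead and one sample")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  stop_if_not_finite(signal, paste0("record ", record_id, ": signal"))
  structure(
    list(record_id = as.character(record_id), signal = signal,
         rate = as.numeric(rate),
         main_labels = as.character(main_labels),
         aux_labels = as.character(aux_labels)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("ECG record ", x$record_id, ": ", nrow(x$signal), " leads x ",
      ncol(x$signal), " samples @ ", x$rate, " Hz (",
      round(ncol(x$signal) / x$rate, 2), " s)\n", sep = "")
  cat("  main labels: ", paste(x$main_labels, collapse = ", "),
      " | aux labels: ", paste(x$aux_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Anti-aliased downsampling of an ECG record
#'
#' Resamples every lead from the record's rate to `target_rate` with a
#' polyphase FIR anti-aliasing filter, the standard step that halves 500 Hz
#' clinical recordings to 250 Hz before training.  Only downsampling (or the
#' identity) is supported; the training protocol never upsamples.
#'
#' @param r an `ecg_record`
#' @param target_rate desired sampling rate, Hz; must not exceed `r$rate`
#' @return a new `ecg_record` with `round(samples * target_rate / rate)`
#'   samples per lead and the rate field updated
#' @export
resample_record <- function(r, target_rate) {
  stopifnot(inherits(r, "ecg_record"))
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("target_rate must be positive")
  if (target_rate > r$rate)
    stop("upsampling (", r$rate, " -> ", target_rate,
         " Hz) is outside the supported protocol")
  if (target_rate == r$rate) return(r)
  q <- r$rate / target_rate
  n_out <- round(ncol(r$signal) * target_rate / r$rate)
  out <- t(apply(r$signal, 1L, function(lead) {
    y <- if (abs(q - round(q)) < 1e-9) {
      # integer decimation: zero-phase IIR anti-alias filter (filtfilt),
      # so the waveform is not delayed relative to the original
      signal::decimate(lead, round(q), ftype = "iir")
    } else {
      frac <- ratio_as_integers(target_rate, r$rate)
      signal::resample(lead, p = frac[1L], q = frac[2L])
    }
    length(y) <- n_out           # trim or zero-extend the boundary sample
    y[is.na(y)] <- 0
    y
  }))
  ecg_record(r$record_id, out, target_rate, r$main_labels, r$aux_labels)
}

# smallest integer p/q with p/q == a/b
ratio_as_integers <- function(a, b, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- a * q / b
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  stop("cannot express rate ratio ", a, "/", b, " as a small integer fraction")
}

#' Crop or zero-pad a record to a fixed duration
#'
#' Batches require a uniform shape, so records are cropped (keeping the
#' initial window) or zero-padded at the end to exactly
#' `target_seconds * rate` samples.  Labels are unchanged.
#'
#' @param r an `ecg_record`
#' @param target_seconds desired duration in seconds (> 0)
#' @return a new `ecg_record` with exactly `target_seconds * rate` samples
#' @export
fix_length <- function(r, target_seconds) {
  stopifnot(inherits(r, "ecg_record"))
  if (!is.numeric(target_seconds) || target_seconds <= 0)
    stop("target_seconds must be positive")
  n_target <- round(target_seconds * r$rate)
  n <- ncol(r$signal)
  if (n == n_target) return(r)
  out <- if (n > n_target) {
    r$signal[, seq_len(n_target), drop = FALSE]
  } else {
    cbind(r$signal, matrix(0, nrow(r$signal), n_target - n))
  }
  ecg_record(r$record_id, out, r$rate, r$main_labels, r$aux_labels)
}

#' Standard preprocessing pipeline
#'
#' Downsample to `target_rate` then crop/pad to `target_seconds`; applied to
#' every record before batching.
#'
#' @param records list of `ecg_record`
#' @param target_rate Hz (default 250, half the clinical 500 Hz)
#' @param target_seconds seconds (default 60, the padded batch length used
#'   for variable-length recordings)
#' @return list of preprocessed `ecg_record`
#' @export
preprocess_records <- function(records, target_rate = 250, target_seconds = 60) {
  lapply(records, function(r) fix_length(resample_record(r, target_rate),
                                         target_seconds))
}
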
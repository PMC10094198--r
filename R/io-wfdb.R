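#' Read and write WFDB-style record pairs
#'
#' A minimal implementation of the PhysioNet waveform layout used by
#' PTB-XL-style datasets: a plain-text `.hea` header naming the record, the
#' number of signals, the sampling rate and sample count, plus one line per
#' lead (`file format gain(baseline)/units ... description`), and a binary
#' `.dat` file of interleaved little-endian 16-bit integers (format 16,
#' sample-major).  Analog millivolt values are `(digital - baseline)/gain`.
#'
#' @param r an `ecg_record`
#' @param dir directory to write into
#' @param gain ADC units per millivolt (default 1000)
#' @return `write_wfdb()`: the header path, invisibly.  `read_wfdb()`: an
#'   `ecg_record` (labels are carried in the dataset metadata table, not in
#'   the header, so they come back empty).
#' @export
write_wfdb <- function(r, dir, gain = 1000) {
  stopifnot(inherits(r, "ecg_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nsig <- nrow(r$signal); nsamp <- ncol(r$signal)
  leads <- lead_names(nsig)
  hea <- file.path(dir, paste0(r$record_id, ".hea"))
  dat <- paste0(r$record_id, ".dat")
  lines <- c(
    sprintf("%s %d %g %d", r$record_id, nsig, r$rate, nsamp),
    sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s", dat, gain, leads))
  writeLines(lines, hea)
  digital <- round(r$signal * gain)
  digital <- pmin(pmax(digital, -32768), 32767)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con))
  # sample-major interleave: all leads at sample 1, then sample 2, ...
  writeBin(as.integer(digital), con, size = 2L, endian = "little")
  invisible(hea)
}

#' @rdname write_wfdb
#' @param header path to a `.hea` file (or a record path without extension)
#' @export
read_wfdb <- function(header) {
  if (!grepl("\\.hea$", header)) header <- paste0(header, ".hea")
  if (!file.exists(header)) stop("no such header: ", header)
  lines <- readLines(header)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rec_id <- top[1L]; nsig <- as.integer(top[2L])
  rate <- as.numeric(top[3L]); nsamp <- as.integer(top[4L])
  sig_lines <- lines[1L + seq_len(nsig)]
  specs <- lapply(sig_lines, parse_wfdb_signal_line)
  fmt <- unique(vapply(specs, `[[`, numeric(1), "format"))
  if (!identical(fmt, 16)) stop("only WFDB format 16 is supported, got ", fmt)
  dat_file <- unique(vapply(specs, `[[`, character(1), "file"))
  if (length(dat_file) != 1L) stop("multi-file records are not supported")
  gains <- vapply(specs, `[[`, numeric(1), "gain")
  baselines <- vapply(specs, `[[`, numeric(1), "baseline")
  con <- file(file.path(dirname(header), dat_file), "rb")
  on.exit(close(con))
  digital <- readBin(con, integer(), n = nsig * nsamp, size = 2L,
                     signed = TRUE, endian = "little")
  m <- matrix(digital, nrow = nsig, ncol = nsamp)  # sample-major interleave
  analog <- (m - baselines) / gains
  ecg_record(rec_id, analog, rate)
}

parse_wfdb_signal_line <- function(line) {
  parts <- strsplit(trimws(line), "\\s+")[[1L]]
  gain_field <- parts[3L]
  baseline <- 0
  gain_txt <- sub("/.*$", "", gain_field)
  if (grepl("\\(", gain_txt)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", gain_txt))
    gain_txt <- sub("\\(.*$", "", gain_txt)
  }
  gain <- as.numeric(gain_txt)
  if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default gain
  list(file = parts[1L], format = as.numeric(parts[2L]),
       gain = gain, baseline = baseline)
}

lead_names <- function(n) {
  std <- c("I", "II", "III", "aVR", "aVL", "aVF",
           "V1", "V2", "V3", "V4", "V5", "V6")
  if (n <= 12L) std[seq_len(n)] else c(std, paste0("L", seq_len(n - 12L)))
}
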
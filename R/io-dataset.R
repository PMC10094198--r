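#' Write a labelled dataset in an emulated benchmark layout
#'
#' Two on-disk layouts are supported, mirroring the two public benchmark
#' distributions:
#' \describe{
#'   \item{`"wfdb"`}{PTB-XL-style: one WFDB header+signal pair per record
#'     plus `metadata.csv` with columns `record_id`, `labels`,
#'     `aux_labels` (pipe-separated sets) and `fold` (1-10).}
#'   \item{`"mat"`}{CPSC2018-style: one MAT matrix per record plus
#'     `reference.csv` with columns `record_id`, `labels`, `aux_labels`.}
#' }
#'
#' @param records list of `ecg_record`
#' @param dir output directory (created if needed)
#' @param layout `"wfdb"` or `"mat"`
#' @param folds optional integer vector of fold tags (same length as
#'   `records`); required for the `"wfdb"` layout
#' @return the metadata file path, invisibly
#' @export
write_ecg_dataset <- function(records, dir, layout = c("wfdb", "mat"),
                              folds = NULL) {
  layout <- match.arg(layout)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    record_id = vapply(records, `[[`, character(1), "record_id"),
    labels = vapply(records, function(r) paste(r$main_labels, collapse = "|"),
                    character(1)),
    aux_labels = vapply(records, function(r) paste(r$aux_labels, collapse = "|"),
                        character(1)),
    rate = vapply(records, `[[`, numeric(1), "rate"),
    stringsAsFactors = FALSE)
  if (layout == "wfdb") {
    if (is.null(folds)) stop("the wfdb layout requires fold tags")
    meta$fold <- as.integer(folds)
    for (r in records) write_wfdb(r, dir)
    path <- file.path(dir, "metadata.csv")
  } else {
    if (!is.null(folds)) meta$fold <- as.integer(folds)
    for (r in records) write_ecg_mat(r$signal, file.path(dir, paste0(r$record_id, ".mat")))
    path <- file.path(dir, "reference.csv")
  }
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset written in one of the emulated layouts
#'
#' The layout is detected from the metadata file present (`metadata.csv`
#' for WFDB-style, `reference.csv` for MAT-style).  Label sets are read
#' from the metadata table; the `fold` column, when present, is returned
#' as an attribute and inside the metadata.
#'
#' @param dir dataset directory
#' @return list with elements `records` (list of `ecg_record`) and
#'   `metadata` (data.frame)
#' @export
read_ecg_dataset <- function(dir) {
  wfdb_meta <- file.path(dir, "metadata.csv")
  mat_meta <- file.path(dir, "reference.csv")
  if (file.exists(wfdb_meta)) {
    meta <- utils::read.csv(wfdb_meta, stringsAsFactors = FALSE)
    records <- lapply(seq_len(nrow(meta)), function(i) {
      r <- read_wfdb(file.path(dir, meta$record_id[i]))
      r$main_labels <- split_labels(meta$labels[i])
      r$aux_labels <- split_labels(meta$aux_labels[i])
      r
    })
  } else if (file.exists(mat_meta)) {
    meta <- utils::read.csv(mat_meta, stringsAsFactors = FALSE)
    records <- lapply(seq_len(nrow(meta)), function(i) {
      m <- read_ecg_mat(file.path(dir, paste0(meta$record_id[i], ".mat")))
      # rate travels in the reference table; 500 Hz is the acquisition
      # convention when absent
      ecg_record(meta$record_id[i], m$data, meta$rate[i] %||% 500,
                 split_labels(meta$labels[i]), split_labels(meta$aux_labels[i]))
    })
  } else {
    stop(dir, ": neither metadata.csv (wfdb layout) nor reference.csv ",
         "(mat layout) found")
  }
  list(records = records, metadata = meta)
}

split_labels <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1L]]
}
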
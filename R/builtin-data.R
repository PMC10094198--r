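#' Built-in diagnostic taxonomies
#'
#' Two-level label hierarchies for the two public 12-lead ECG benchmark
#' datasets the package targets.
#'
#' `cpsc_hierarchy()`: the nine CPSC2018 challenge classes grouped into five
#' superclasses — NORM (normal sinus rhythm), AF (atrial fibrillation),
#' QRS (conduction abnormalities widening or delaying the QRS complex:
#' first-degree AV block, left/right bundle branch block), V (premature
#' contractions: atrial and ventricular), ST (ST-segment deviations:
#' elevation and depression).  Here the nine classes are the main task and
#' the five superclasses the merge-direction auxiliary task.
#'
#' `ptbxl_hierarchy()`: the 23 PTB-XL diagnostic subclasses nested in the
#' five superclasses NORM, CD (conduction disturbance), HYP (hypertrophy),
#' MI (myocardial infarction), STTC (ST/T changes).  Here the five
#' superclasses are the main task and the 23 subclasses the split-direction
#' auxiliary task.
#'
#' @return a `label_hierarchy` with a `counts` attribute holding the
#'   published per-fine-class record counts (label assignments for PTB-XL,
#'   where records are multi-label).
#' @export
cpsc_hierarchy <- function() {
  df <- data.frame(
    fine   = c("SNR", "AF", "IAVB", "LBBB", "RBBB", "PAC", "PVC", "STE", "STD"),
    coarse = c("NORM", "AF", "QRS", "QRS", "QRS", "V", "V", "ST", "ST"),
    stringsAsFactors = FALSE)
  h <- build_hierarchy(df)
  attr(h, "counts") <- stats::setNames(
    c(918L, 1098L, 704L, 207L, 1695L, 556L, 672L, 825L, 202L), df$fine)
  h
}

#' @rdname cpsc_hierarchy
#' @export
ptbxl_hierarchy <- function() {
  df <- data.frame(
    fine = c("NORM",
             "LAFB/LPFB", "IRBBB", "ILBBB", "CLBBB", "CRBBB", "_AVB", "IVCD", "WPW",
             "LVH", "RVH", "LAO/LAE", "RAO/RAE", "SEHYP",
             "AMI", "IMI", "LMI", "PMI",
             "ISCA", "ISCI", "ISC_", "STTC", "NST_"),
    coarse = c("NORM",
               rep("CD", 8L),
               rep("HYP", 5L),
               rep("MI", 4L),
               rep("STTC", 5L)),
    stringsAsFactors = FALSE)
  h <- build_hierarchy(df)
  attr(h, "counts") <- stats::setNames(
    c(9528L,
      1803L, 1118L, 77L, 536L, 542L, 827L, 789L, 80L,
      2137L, 126L, 427L, 99L, 30L,
      3172L, 3263L, 201L, 17L,
      1016L, 398L, 1275L, 2329L, 770L),
    df$fine)
  h
}

#' Published per-class benchmark metrics
#'
#' Reference tables of per-class AUC/accuracy/precision/recall/F1 reported
#' for this architecture on the PTB-XL and CPSC2018 test sets, including the
#' ablation variants (without the CoT block, without the Bi-GRU module) and
#' the random-auxiliary-task control.  Shipped as plain-text CSV under
#' `inst/extdata/published_benchmarks.csv`; used to check the package's
#' metric aggregation arithmetic against the printed averages.
#'
#' @param table optional: restrict to one table id (e.g. `"cpsc_full"`,
#'   `"ptbxl_no_cot"`)
#' @return data.frame with columns `table`, `class`, `auc`, `accuracy`,
#'   `precision`, `recall`, `f1` (per-class rows only; averages are
#'   recomputed, never stored)
#' @export
published_benchmarks <- function(table = NULL) {
  path <- system.file("extdata", "published_benchmarks.csv",
                      package = "ecgmtnet", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(table)) {
    df <- df[df$table %in% table, , drop = FALSE]
    if (nrow(df) == 0L) stop("unknown benchmark table: ", table)
  }
  df
}
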
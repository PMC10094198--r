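#' Two-level diagnostic label hierarchies
#'
#' A `label_hierarchy` maps each fine (subclass-level) diagnostic class to
#' exactly one coarse (superclass-level) class.  It is the backbone of
#' auxiliary-task construction: the auxiliary label set of a record is the
#' image of its main labels under the parent map (merge direction), or a
#' refinement of them (split direction).
#'
#' @param pairs a two-column object (`data.frame`, `matrix`, or list of
#'   length-2 character vectors) giving `(fine, coarse)` pairs, one row per
#'   fine class.  Ordering is preserved.
#' @return an object of class `label_hierarchy` with elements
#'   `fine_classes`, `coarse_classes` and `parent_of` (a named character
#'   vector mapping fine to coarse).
#' @examples
#' h <- build_hierarchy(data.frame(
#'   fine = c("LBBB", "RBBB", "SNR"),
#'   coarse = c("QRS", "QRS", "NORM")))
#' h$parent_of[["LBBB"]]
#' @export
build_hierarchy <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      stopifnot(length(p) == 2L)
      data.frame(fine = p[[1L]], coarse = p[[2L]], stringsAsFactors = FALSE)
    }))
  }
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!is.data.frame(pairs) || ncol(pairs) < 2L)
    stop("`pairs` must have two columns: fine class and coarse class")
  if (nrow(pairs) == 0L) stop("`pairs` is empty: a hierarchy needs at least one class")
  fine <- as.character(pairs[[1L]])
  coarse <- as.character(pairs[[2L]])
  dup <- fine[duplicated(fine)]
  if (length(dup))
    stop("duplicate fine class: ", paste(unique(dup), collapse = ", "))
  if (anyNA(fine) || anyNA(coarse) || any(fine == "") || any(coarse == ""))
    stop("class identifiers must be non-empty strings")
  parent <- stats::setNames(coarse, fine)
  h <- structure(
    list(fine_classes = fine,
         coarse_classes = unique(coarse),
         parent_of = parent),
    class = "label_hierarchy")
  validate_hierarchy(h)
  h
}

validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "label_hierarchy"))
  if (!setequal(names(h$parent_of), h$fine_classes))
    stop("parent_of must be total on fine_classes")
  if (!setequal(unique(unname(h$parent_of)), h$coarse_classes))
    stop("every coarse class must have at least one child")
  # a name may appear at both levels only when the fine class is the
  # eponymous member of that group (e.g. subclass STTC inside superclass
  # STTC, or a singleton group reusing its class name)
  clash <- intersect(h$fine_classes, h$coarse_classes)
  for (cl in clash) {
    kids <- children_unchecked(h, cl)
    if (!cl %in% kids)
      stop("identifier ", cl,
           " used at both levels but the fine class is not in that group")
  }
  invisible(h)
}

children_unchecked <- function(h, coarse) {
  h$fine_classes[unname(h$parent_of[h$fine_classes]) == coarse]
}

#' @export
print.label_hierarchy <- function(x, ...) {
  cat("Label hierarchy:", length(x$fine_classes), "fine classes in",
      length(x$coarse_classes), "groups\n")
  for (g in x$coarse_classes) {
    cat("  ", g, ": ", paste(children_of(x, g), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Fine classes belonging to a coarse class
#' @param h a `label_hierarchy`
#' @param coarse a coarse class identifier
#' @return character vector of fine classes, in hierarchy order
#' @export
children_of <- function(h, coarse) {
  stopifnot(inherits(h, "label_hierarchy"))
  if (!coarse %in% h$coarse_classes) stop("unknown coarse class: ", coarse)
  children_unchecked(h, coarse)
}

#' Derive auxiliary (superclass) labels by merging
#'
#' Maps a set of fine-class labels to the set of their parents, deduplicated:
#' a record labelled with two classes of the same group receives that group
#' once.  This is the merge-direction auxiliary-task labelling.
#'
#' @param main_labels character vector (set) of fine-class labels
#' @param h a `label_hierarchy`
#' @return character vector of coarse classes, in hierarchy group order
#' @examples
#' derive_aux_labels(c("LBBB", "RBBB"), cpsc_hierarchy())  # "QRS"
#' @export
derive_aux_labels <- function(main_labels, h) {
  validate_hierarchy(h)
  main_labels <- as.character(main_labels)
  if (length(main_labels) == 0L) return(character(0))
  unknown <- setdiff(main_labels, h$fine_classes)
  if (length(unknown))
    stop("unknown fine class: ", paste(unknown, collapse = ", "))
  out <- unique(unname(h$parent_of[main_labels]))
  h$coarse_classes[h$coarse_classes %in% out]
}

#' Random regrouping control for the auxiliary task
#'
#' Builds a hierarchy over the same fine classes with the same number of
#' groups and the same multiset of group sizes, but with membership drawn by
#' a seeded permutation.  This is the control used to show that the benefit
#' of the auxiliary task comes from a clinically meaningful grouping, not
#' from merely having a second task: randomly merged superclasses carry no
#' shared morphology.
#'
#' Algorithm: shuffle the fine-class list with the seeded RNG, then refill
#' the original groups in their original size order.
#'
#' @param h a `label_hierarchy`
#' @param seed integer seed; the result is deterministic given `seed`
#' @return a new `label_hierarchy`
#' @export
random_hierarchy <- function(h, seed) {
  validate_hierarchy(h)
  sizes <- vapply(h$coarse_classes, function(g) length(children_of(h, g)), integer(1))
  perm <- local({
    rng <- make_rng(seed)
    rng$sample(length(h$fine_classes))
  })
  shuffled <- h$fine_classes[perm]
  # groups get neutral names: a random union of classes is not the clinical
  # superclass any more, and reusing a fine-class name (e.g. AF) for a group
  # it is no longer a member of would break the level-disjointness invariant
  coarse <- rep(paste0("G", seq_along(sizes)), times = sizes)
  build_hierarchy(data.frame(fine = shuffled, coarse = coarse,
                             stringsAsFactors = FALSE))
}

#' Per-record task labelling
#'
#' Bundles a record identifier with its main-task and auxiliary-task label
#' sets and the direction the auxiliary task was built in (`"merge"`: aux
#' labels are the parents of the main labels; `"split"`: aux labels are
#' children of the main labels).
#'
#' @param record_id identifier
#' @param main_labels character vector of main-task labels
#' @param aux_labels character vector of auxiliary-task labels
#' @param direction `"merge"` or `"split"`
#' @param h optional `label_hierarchy`; when given, the labelling is
#'   validated against it
#' @return an object of class `task_labeling`
#' @export
task_labeling <- function(record_id, main_labels, aux_labels,
                          direction = c("merge", "split"), h = NULL) {
  direction <- match.arg(direction)
  tl <- structure(
    list(record_id = record_id,
         main_labels = as.character(main_labels),
         aux_labels = as.character(aux_labels),
         direction = direction),
    class = "task_labeling")
  if (!is.null(h)) {
    validate_hierarchy(h)
    if (direction == "merge") {
      expected <- derive_aux_labels(tl$main_labels, h)
      if (!setequal(tl$aux_labels, expected))
        stop("merge labelling of ", record_id,
             ": aux labels must equal the parent image of the main labels")
    } else {
      parents <- unname(h$parent_of[tl$aux_labels])
      if (anyNA(parents) || !all(parents %in% tl$main_labels))
        stop("split labelling of ", record_id,
             ": every aux label must be a child of some main label")
    }
  }
  tl
}

#' Tally label assignments per class
#'
#' Bookkeeping mirror of the per-class count columns of the dataset tables:
#' counts each fine-class and coarse-class label assignment over a list of
#' task labellings.  The fine total equals the number of fine label
#' assignments (records carrying two labels count twice).
#'
#' @param labelings list of `task_labeling` objects
#' @param h a `label_hierarchy`
#' @return a list with named integer vectors `fine` and `coarse` and scalar
#'   totals `n_fine_assignments`, `n_coarse_assignments`
#' @export
class_count_summary <- function(labelings, h) {
  validate_hierarchy(h)
  fine <- stats::setNames(integer(length(h$fine_classes)), h$fine_classes)
  coarse <- stats::setNames(integer(length(h$coarse_classes)), h$coarse_classes)
  for (tl in labelings) {
    if (tl$direction == "merge") {
      f <- tl$main_labels; c2 <- tl$aux_labels
    } else {
      f <- tl$aux_labels; c2 <- tl$main_labels
    }
    fine[f] <- fine[f] + 1L
    coarse[c2] <- coarse[c2] + 1L
  }
  list(fine = fine, coarse = coarse,
       n_fine_assignments = sum(fine),
       n_coarse_assignments = sum(coarse))
}

#' Write / read a hierarchy as a two-column CSV
#' @param h a `label_hierarchy`
#' @param path file path
#' @export
write_hierarchy_csv <- function(h, path) {
  validate_hierarchy(h)
  utils::write.csv(
    data.frame(fine = h$fine_classes,
               coarse = unname(h$parent_of[h$fine_classes]),
               stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_hierarchy_csv
#' @export
read_hierarchy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  build_hierarchy(df[, c("fine", "coarse")])
}
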
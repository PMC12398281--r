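#' Grouped training design for GSDA
#'
#' Bundles a feature matrix with hemisphere labels, group codes and subject
#' identifiers.  Labels follow the convention left = 0, right = 1; groups
#' are coded 0/1 (e.g. male = 0, female = 1).  A constant feature x0 = 1 is
#' appended implicitly at fit time; `features` holds connection values only.
#'
#' @param features m x p numeric matrix of Fisher-z connectivity values.
#' @param labels length-m vector in {0,1} (left = 0, right = 1).
#' @param groups length-m vector in {0,1}.
#' @param subject_ids length-m identifiers (character or integer).
#' @param session optional length-m session identifiers.
#' @return an object of class `grouped_design`.
#' @export
grouped_design <- function(features, labels, groups, subject_ids,
                           session = NULL) {
  features <- as.matrix(features)
  check_numeric_matrix(features, "features")
  labels <- as_binary(labels, "labels")
  groups <- as_binary(groups, "groups")
  m <- nrow(features)
  if (length(labels) != m || length(groups) != m) {
    stop_shape("labels and groups must have one entry per feature row")
  }
  if (length(subject_ids) != m) {
    stop_shape("subject_ids must have one entry per feature row")
  }
  if (!is.null(session) && length(session) != m) {
    stop_shape("session must have one entry per feature row")
  }
  structure(list(features = features, labels = labels, groups = groups,
                 subject_ids = as.character(subject_ids),
                 session = session, augmented = FALSE),
            class = "grouped_design")
}

#' @export
print.grouped_design <- function(x, ...) {
  cat("<grouped_design> ", nrow(x$features), " samples x ",
      ncol(x$features), " features; groups 0/1: ",
      sum(x$groups == 0), "/", sum(x$groups == 1), "\n", sep = "")
  invisible(x)
}

#' Subset a grouped design by row indices
#'
#' @param design a [grouped_design()].
#' @param idx integer row indices.
#' @return a `grouped_design` restricted to `idx`.
#' @export
subset_design <- function(design, idx) {
  grouped_design(design$features[idx, , drop = FALSE],
                 design$labels[idx], design$groups[idx],
                 design$subject_ids[idx],
                 if (!is.null(design$session)) design$session[idx])
}
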
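#' Hemisphere-split cross-validation partition
#'
#' Subjects are randomly divided into two halves (group-stratified by
#' default; an odd subject goes to the training half).  Training samples
#' are the left hemispheres of half A plus the right hemispheres of half B;
#' test samples are the complements.  By construction no subject
#' contributes both hemispheres to training, and the training set holds
#' exactly as many left as right hemispheres.
#'
#' @param meta data.frame with columns `subject_id`, `y` (0 = left,
#'   1 = right) and `group`; every subject must contribute exactly one left
#'   and one right sample.
#' @param seed integer seed for the subject shuffle.
#' @param stratify_by_group split 50/50 within each group (default TRUE,
#'   so both groups appear in every training set, as the dependence term
#'   requires).
#' @return `list(train = , test = )` of row indices into `meta`.
#' @export
hemisphere_split_partition <- function(meta, seed = 0L,
                                       stratify_by_group = TRUE) {
  check_partition_meta(meta)
  set.seed(seed)
  subs <- unique(meta$subject_id)
  grp_of <- meta$group[match(subs, meta$subject_id)]
  half_a <- character(0)
  strata <- if (stratify_by_group) split(subs, grp_of) else list(subs)
  for (s in strata) {
    s <- sample(s)
    half_a <- c(half_a, s[seq_len(ceiling(length(s) / 2))])
  }
  in_a <- meta$subject_id %in% half_a
  train <- which((in_a & meta$y == 0) | (!in_a & meta$y == 1))
  test <- setdiff(seq_len(nrow(meta)), train)
  list(train = train, test = test)
}

#' Subject-holdout cross-validation partition
#'
#' Holds out a fraction of subjects entirely (both hemispheres go to the
#' held-out set); the remaining subjects are partitioned with
#' [hemisphere_split_partition()].
#'
#' @inheritParams hemisphere_split_partition
#' @param holdout_fraction fraction of subjects to hold out, in (0, 1).
#' @return `list(train = , test = , heldout = )` of row indices: `test` is
#'   the hemisphere-split complement among retained subjects; `heldout`
#'   are both hemispheres of the held-out subjects.
#' @export
subject_holdout_partition <- function(meta, holdout_fraction = 0.2,
                                      seed = 0L, stratify_by_group = TRUE) {
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0, 1)", call. = FALSE)
  }
  check_partition_meta(meta)
  set.seed(seed)
  subs <- unique(meta$subject_id)
  grp_of <- meta$group[match(subs, meta$subject_id)]
  held <- character(0)
  strata <- if (stratify_by_group) split(subs, grp_of) else list(subs)
  for (s in strata) {
    s <- sample(s)
    held <- c(held, s[seq_len(floor(holdout_fraction * length(s)))])
  }
  keep <- which(!(meta$subject_id %in% held))
  inner <- hemisphere_split_partition(meta[keep, , drop = FALSE],
                                      seed = seed + 1L,
                                      stratify_by_group = stratify_by_group)
  list(train = keep[inner$train], test = keep[inner$test],
       heldout = which(meta$subject_id %in% held))
}

check_partition_meta <- function(meta) {
  req <- c("subject_id", "y", "group")
  if (!all(req %in% names(meta))) {
    stop("meta must have columns subject_id, y, group", call. = FALSE)
  }
  tab <- table(meta$subject_id, meta$y)
  if (!all(dim(tab) == c(length(unique(meta$subject_id)), 2)) ||
      !all(tab == 1)) {
    stop("every subject must contribute exactly one left and one right sample",
         call. = FALSE)
  }
  grp <- tapply(meta$group, meta$subject_id, function(g) length(unique(g)))
  if (any(grp != 1)) {
    stop("inconsistent group code within subject", call. = FALSE)
  }
  invisible(meta)
}

#' Partition scheme descriptor
#'
#' @param kind `"hemisphere_split"` or `"subject_holdout"`.
#' @param holdout_fraction used by `subject_holdout` only.
#' @param stratify_by_group stratify subject splits by group.
#' @return a `partition_scheme` object consumed by [run_first_order()].
#' @export
partition_scheme <- function(kind = c("hemisphere_split", "subject_holdout"),
                             holdout_fraction = 0.2,
                             stratify_by_group = TRUE) {
  kind <- match.arg(kind)
  if (holdout_fraction <= 0 || holdout_fraction >= 1) {
    stop("holdout_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(kind = kind, holdout_fraction = holdout_fraction,
                 stratify_by_group = isTRUE(stratify_by_group)),
            class = "partition_scheme")
}

make_partition <- function(meta, scheme, seed) {
  if (scheme$kind == "hemisphere_split") {
    hemisphere_split_partition(meta, seed, scheme$stratify_by_group)
  } else {
    subject_holdout_partition(meta, scheme$holdout_fraction, seed,
                              scheme$stratify_by_group)
  }
}
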
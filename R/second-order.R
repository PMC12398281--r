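#' Standard l2-penalized logistic regression
#'
#' Plain ridge logistic classifier used for the second-order stage:
#' unit penalty strength by default and an unpenalized intercept, matching
#' the usual default of reference implementations.  Fitted by L-BFGS from
#' zero initialization; deterministic.
#'
#' @param X n x p feature matrix.
#' @param y length-n labels in {0, 1}.
#' @param alpha l2 strength on the non-intercept weights (default 1).
#' @param max_iter,tol optimizer controls.
#' @return list with `intercept` and `weights` (length p).
#' @export
logistic_l2 <- function(X, y, alpha = 1, max_iter = 1000L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as_binary(y, "y")
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  Xa <- cbind(1, X)
  pen <- c(0, rep(alpha, ncol(X)))  # intercept unpenalized
  fn <- function(w) {
    s <- drop(Xa %*% w)
    -sum(y * log_sigmoid(s) + (1 - y) * log_sigmoid(-s)) +
      sum(pen * w^2) / 2
  }
  gr <- function(w) {
    s <- drop(Xa %*% w)
    drop(crossprod(Xa, sigmoid(s) - y)) + pen * w
  }
  res <- stats::optim(numeric(ncol(Xa)), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = tol,
                                     factr = 1e3))
  list(intercept = res$par[1], weights = res$par[-1])
}

#' Assemble the second-order design from two first-order ensembles
#'
#' Stacks first-order connection-weight vectors (bias excluded) as
#' features; the label is the model's target group (0 for rows from
#' `ensemble_male`, 1 for rows from `ensemble_female`).  The two ensembles
#' may be the same object, filtered to different target groups.
#'
#' @param ensemble_male,ensemble_female `first_order_ensemble` objects.
#' @param lam the first-order lambda whose models are compared (both
#'   ensembles must contain it at the same alpha).
#' @return list with `features` (m x p), `labels` (0/1).
#' @export
assemble_second_order_design <- function(ensemble_male, ensemble_female,
                                         lam = 5) {
  take <- function(ens, tg) {
    sel <- ens$records$lam == lam & ens$records$target_group == tg
    if (!any(sel)) {
      stop("no models with lam = ", lam, " for group ", tg, call. = FALSE)
    }
    ens$weights[sel, -1, drop = FALSE]  # bias excluded
  }
  if (ensemble_male$meta$alpha != ensemble_female$meta$alpha) {
    stop("ensembles were fitted at different alpha", call. = FALSE)
  }
  Wm <- take(ensemble_male, 0)
  Wf <- take(ensemble_female, 1)
  if (ncol(Wm) != ncol(Wf)) stop_shape("feature dimensions differ")
  list(features = rbind(Wm, Wf),
       labels = c(rep(0L, nrow(Wm)), rep(1L, nrow(Wf))))
}

#' Repeated second-order classification
#'
#' For each split: stratified 80/20 train/test sampling, a standard
#' l2 logistic fit ([logistic_l2()]) on the training side, test accuracy
#' and the fitted connection weights recorded.  Split s uses seed
#' `base_seed + s`.
#'
#' @param design output of [assemble_second_order_design()].
#' @param n_splits number of random splits.
#' @param train_fraction training fraction per split (default 0.8).
#' @param base_seed integer base seed.
#' @param alpha l2 strength of the second-order classifier (default 1).
#' @return a `second_order_result`: list with `accuracy` (length
#'   `n_splits`), `weights` (n_splits x p, intercept excluded), and
#'   `mean_weights`.
#' @export
run_second_order <- function(design, n_splits = 1000L, train_fraction = 0.8,
                             base_seed = 0L, alpha = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  y <- as_binary(design$labels, "labels")
  if (length(unique(y)) < 2) stop("both classes required", call. = FALSE)
  X <- design$features
  acc <- numeric(n_splits)
  W <- matrix(NA_real_, n_splits, ncol(X))
  for (s in seq_len(n_splits)) {
    set.seed(base_seed + s)
    train <- unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, round(train_fraction * length(idx)))
    }), use.names = FALSE)
    fit <- logistic_l2(X[train, , drop = FALSE], y[train], alpha = alpha)
    test <- setdiff(seq_along(y), train)
    score <- drop(X[test, , drop = FALSE] %*% fit$weights) + fit$intercept
    acc[s] <- mean(as.integer(score >= 0) == y[test])
    W[s, ] <- fit$weights
  }
  structure(list(accuracy = acc, weights = W, mean_weights = colMeans(W),
                 meta = list(n_splits = n_splits,
                             train_fraction = train_fraction,
                             base_seed = base_seed, alpha = alpha)),
            class = "second_order_result")
}

top_fraction_set <- function(w, top_fraction) {
  p <- length(w)
  k <- floor(top_fraction * p)
  # ties at the k-th magnitude broken by lower index
  ord <- order(-abs(w), seq_len(p))
  sort(ord[seq_len(k)]) - 1L  # 0-based connection indices
}

#' Derive a lateralization mask from two averaged weight vectors
#'
#' Selects the `floor(top_fraction * p)` largest-magnitude entries of each
#' vector (ties broken by lower index) and returns the intersection as
#' 0-based connection linear indices.
#'
#' @param avg_weights_a,avg_weights_b averaged (second-order) weight
#'   vectors of equal length, bias excluded.
#' @param top_fraction fraction of connections kept per vector
#'   (default 0.05).
#' @return a `lateralization_mask`: list with `indices` (sorted 0-based)
#'   and `provenance`.
#' @export
derive_mask <- function(avg_weights_a, avg_weights_b, top_fraction = 0.05) {
  if (length(avg_weights_a) != length(avg_weights_b)) {
    stop_shape("weight vectors differ in length")
  }
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must be in (0, 1)", call. = FALSE)
  }
  sa <- top_fraction_set(avg_weights_a, top_fraction)
  sb <- top_fraction_set(avg_weights_b, top_fraction)
  structure(list(indices = intersect(sa, sb),
                 provenance = list(top_fraction = top_fraction,
                                   p = length(avg_weights_a),
                                   k_per_side = length(sa))),
            class = "lateralization_mask")
}

#' @export
print.lateralization_mask <- function(x, ...) {
  cat("<lateralization_mask> ", length(x$indices), " connections (top ",
      100 * x$provenance$top_fraction, "% of ", x$provenance$p,
      ", intersection)\n", sep = "")
  invisible(x)
}

#' Apply a mask to an averaged first-order model
#'
#' Intersects the mask with the model's own top-fraction-by-magnitude set
#' and returns the surviving connections with their signed average
#' weights.
#'
#' @param avg_first_order_weights averaged first-order connection weights
#'   (bias excluded).
#' @param mask a [derive_mask()] result.
#' @param top_fraction fraction defining the model's own top set.
#' @return data.frame with `index` (0-based) and `weight`.
#' @export
apply_mask_to_model <- function(avg_first_order_weights, mask,
                                top_fraction = 0.05) {
  own <- top_fraction_set(avg_first_order_weights, top_fraction)
  idx <- intersect(mask$indices, own)
  data.frame(index = idx, weight = avg_first_order_weights[idx + 1])
}

#' Shared and group-"exclusive" connection partition
#'
#' Within each dataset, `shared` is the intersection of the male and
#' female selections and the exclusives are the set differences;
#' `unique_connections` deduplicates across all four selections.
#'
#' @param selections a named list of datasets, each a named list with
#'   elements `male` and `female` holding data.frames from
#'   [apply_mask_to_model()] (or plain index vectors).
#' @return list with one element per dataset (`shared`,
#'   `male_exclusive`, `female_exclusive` index vectors) plus
#'   `unique_connections` and `n_with_repetition` across datasets.
#' @export
shared_exclusive_partition <- function(selections) {
  ids <- function(x) if (is.data.frame(x)) x$index else as.integer(x)
  out <- lapply(selections, function(ds) {
    m <- ids(ds$male); f <- ids(ds$female)
    list(shared = sort(intersect(m, f)),
         male_exclusive = sort(setdiff(m, f)),
         female_exclusive = sort(setdiff(f, m)))
  })
  all_ids <- unlist(lapply(selections, function(ds)
    c(ids(ds$male), ids(ds$female))))
  out$unique_connections <- sort(unique(all_ids))
  out$n_with_repetition <- length(all_ids)
  out
}

atlas_left_lobes <- function(atlas) {
  left <- atlas[atlas$hemisphere == "L", ]
  left$lobe[order(left$homologue_index)]
}

#' Average chord degree per lobe
#'
#' For each lobe: number of chord endpoints landing on its ROIs divided by
#' its ROI count.  A chord with both endpoints in one lobe contributes two
#' endpoints to it.  Lobes are taken from the left-hemisphere rows of the
#' atlas in homologue order (the mask lives on homologue indices).
#'
#' @param mask a [derive_mask()] result (0-based connection indices).
#' @param atlas an [atlas_table()].
#' @return named numeric vector, one value per lobe.
#' @export
lobe_average_degree <- function(mask, atlas) {
  lobes <- atlas_left_lobes(atlas)
  h <- length(lobes)
  sizes <- table(lobes)
  counts <- stats::setNames(numeric(length(sizes)), names(sizes))
  if (length(mask$indices)) {
    pr <- linear_index_to_pair(mask$indices, h)
    ends <- table(c(lobes[pr[, 1] + 1], lobes[pr[, 2] + 1]))
    counts[names(ends)] <- ends
  }
  counts / as.numeric(sizes[names(counts)])
}

#' Counts of selected connections by group, lobe relation and weight sign
#'
#' Classifies each selected connection as intra-lobe (both ROIs in the
#' same lobe) or inter-lobe, and by the sign of its first-order weight
#' (zero weights counted as positive).
#'
#' @param selections named list (e.g. `male`, `female`) of data.frames
#'   with `index` and `weight` columns.
#' @param atlas an [atlas_table()].
#' @return a data.frame of counts with columns `group`, `relation`,
#'   `sign`, `count` (all combinations present, zeros included).
#' @export
interaction_sign_counts <- function(selections, atlas) {
  lobes <- atlas_left_lobes(atlas)
  h <- length(lobes)
  grid <- expand.grid(group = names(selections),
                      relation = c("intra", "inter"),
                      sign = c("positive", "negative"),
                      stringsAsFactors = FALSE)
  grid$count <- 0L
  for (g in names(selections)) {
    sel <- selections[[g]]
    if (!nrow(sel)) next
    pr <- linear_index_to_pair(sel$index, h)
    relation <- ifelse(lobes[pr[, 1] + 1] == lobes[pr[, 2] + 1],
                       "intra", "inter")
    sign <- ifelse(sel$weight >= 0, "positive", "negative")
    tab <- table(relation, sign)
    for (r in rownames(tab)) for (s in colnames(tab)) {
      row <- grid$group == g & grid$relation == r & grid$sign == s
      grid$count[row] <- tab[r, s]
    }
  }
  grid
}

#' Edge-list export of a mask
#'
#' Emits one row per chord with ROI indices, lobes and (optionally) signed
#' weights, suitable for chord-diagram tools.
#'
#' @param mask a [derive_mask()] result.
#' @param atlas an [atlas_table()].
#' @param weights optional connection weight vector (bias excluded) used
#'   to attach `weight` and `sign` columns.
#' @return data.frame with `index`, `roi_i`, `roi_j`, `lobe_i`, `lobe_j`
#'   (+ `weight`, `sign`).
#' @export
mask_edge_list <- function(mask, atlas, weights = NULL) {
  lobes <- atlas_left_lobes(atlas)
  h <- length(lobes)
  if (!length(mask$indices)) {
    return(data.frame(index = integer(0), roi_i = integer(0),
                      roi_j = integer(0), lobe_i = character(0),
                      lobe_j = character(0)))
  }
  pr <- linear_index_to_pair(mask$indices, h)
  out <- data.frame(index = mask$indices, roi_i = pr[, 1], roi_j = pr[, 2],
                    lobe_i = lobes[pr[, 1] + 1], lobe_j = lobes[pr[, 2] + 1],
                    stringsAsFactors = FALSE)
  if (!is.null(weights)) {
    out$weight <- weights[mask$indices + 1]
    out$sign <- ifelse(out$weight >= 0, "positive", "negative")
  }
  out
}
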
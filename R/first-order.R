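#' Evaluate a fitted model on grouped test samples
#'
#' Computes balanced accuracy on the target- and nontarget-group test
#' samples and the resulting [gsi()].
#'
#' @param model a `gsda_model`.
#' @param dataset a `hemisphere_dataset`.
#' @param test_idx row indices of the test samples.
#' @return a one-row data.frame with `bat`, `bant`, `gsi`, `n_target`,
#'   `n_nontarget`.
#' @export
evaluate_grouped <- function(model, dataset, test_idx) {
  meta <- dataset$meta[test_idx, , drop = FALSE]
  pred <- predict(model, dataset$features[test_idx, , drop = FALSE])
  tg <- meta$group == model$target_group
  bat <- balanced_accuracy(meta$y[tg], pred[tg])
  bant <- balanced_accuracy(meta$y[!tg], pred[!tg])
  data.frame(bat = bat, bant = bant, gsi = as.numeric(gsi(bat, bant)),
             n_target = sum(tg), n_nontarget = sum(!tg))
}

#' Repeated first-order classification sweep
#'
#' For each repetition, draws a subject-aware partition and fits one
#' GSDA-Logit model per (lambda, target group), evaluating balanced
#' accuracies and GSI on the test side.  Repetition r uses seed
#' `base_seed + r`, so the whole ensemble is reproducible from
#' `base_seed`.
#'
#' @param dataset a `hemisphere_dataset`.
#' @param scheme a [partition_scheme()].
#' @param lam_grid numeric vector of dependence strengths
#'   (default `c(0, 1, 2, 5, 8, 10)`).
#' @param alpha l2 strength (default 0.1).
#' @param target_groups groups to fit models for (default `c(0, 1)`).
#' @param n_repetitions number of random partitions.
#' @param base_seed integer base seed.
#' @param params_template a [gsda_hyperparams()] supplying optimizer
#'   settings; its `alpha`/`lam` fields are overridden per task.
#' @return a `first_order_ensemble`: list with `records` (one row per
#'   repetition x lambda x target group: `rep`, `seed`, `lam`, `alpha`,
#'   `target_group`, `bat`, `bant`, `gsi`, ...) and `weights` (matrix,
#'   rows aligned with `records`, bias in column 1).
#' @export
run_first_order <- function(dataset, scheme = partition_scheme(),
                            lam_grid = c(0, 1, 2, 5, 8, 10),
                            alpha = 0.1, target_groups = c(0, 1),
                            n_repetitions = 1L, base_seed = 0L,
                            params_template = gsda_hyperparams()) {
  if (n_repetitions < 1) stop("n_repetitions must be >= 1", call. = FALSE)
  if (any(lam_grid < 0)) stop("lambda must be >= 0", call. = FALSE)
  records <- list(); weights <- list(); k <- 0
  for (r in seq_len(n_repetitions)) {
    seed_r <- base_seed + r
    part <- make_partition(dataset$meta, scheme, seed_r)
    train <- as_grouped_design(dataset, part$train)
    for (lam in lam_grid) {
      params <- params_template
      params$alpha <- alpha; params$lam <- lam
      for (tg in target_groups) {
        model <- gsda_fit(train, tg, params, seed = seed_r)
        ev <- evaluate_grouped(model, dataset, part$test)
        k <- k + 1
        records[[k]] <- cbind(
          data.frame(rep = r, seed = seed_r, lam = lam, alpha = alpha,
                     target_group = tg), ev,
          data.frame(converged = model$converged,
                     n_iter = model$n_iter_used))
        weights[[k]] <- model$weights
      }
    }
  }
  structure(list(records = do.call(rbind, records),
                 weights = do.call(rbind, weights),
                 meta = list(scheme = scheme, lam_grid = lam_grid,
                             alpha = alpha, target_groups = target_groups,
                             n_repetitions = n_repetitions,
                             base_seed = base_seed)),
            class = "first_order_ensemble")
}

#' @export
print.first_order_ensemble <- function(x, ...) {
  cat("<first_order_ensemble> ", nrow(x$records), " models (",
      x$meta$n_repetitions, " repetitions x {",
      paste(x$meta$lam_grid, collapse = ", "), "} lambda x groups {",
      paste(x$meta$target_groups, collapse = ", "), "})\n", sep = "")
  invisible(x)
}

#' Per-lambda summary of a first-order ensemble
#'
#' Means and standard deviations of balanced accuracies and GSI per
#' (lambda, target group), with the absolute accuracy gap in percent.
#'
#' @param ensemble a `first_order_ensemble`.
#' @return a data.frame, one row per (lambda, target group).
#' @export
summarize_first_order <- function(ensemble) {
  rec <- ensemble$records
  out <- do.call(rbind, lapply(
    split(rec, list(rec$lam, rec$target_group), drop = TRUE),
    function(d) data.frame(
      lam = d$lam[1], target_group = d$target_group[1], n = nrow(d),
      bat_mean = mean(d$bat), bat_sd = stats::sd(d$bat),
      bant_mean = mean(d$bant), bant_sd = stats::sd(d$bant),
      gsi_mean = mean(d$gsi), gsi_sd = stats::sd(d$gsi),
      gap_pct = accuracy_gap(100 * mean(d$bat), 100 * mean(d$bant)))))
  rownames(out) <- NULL
  out[order(out$target_group, out$lam), ]
}

#' Average first-order weights for one (lambda, target group) task
#'
#' Elementwise arithmetic mean of signed weight vectors across
#' repetitions.
#'
#' @param ensemble a `first_order_ensemble`.
#' @param lam,target_group task selectors.
#' @param drop_bias drop the bias (column 1) from the result.
#' @return numeric vector of averaged weights.
#' @export
average_first_order_weights <- function(ensemble, lam, target_group,
                                        drop_bias = TRUE) {
  sel <- ensemble$records$lam == lam &
    ensemble$records$target_group == target_group
  if (!any(sel)) stop("no models for that (lam, target_group)", call. = FALSE)
  w <- colMeans(ensemble$weights[sel, , drop = FALSE])
  if (drop_bias) w[-1] else w
}
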
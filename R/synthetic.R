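#' Configuration of the synthetic lateralization generator
#'
#' Describes a paired left/right hemisphere connectivity world, additive in
#' Fisher-z space, with three kinds of planted structure:
#'
#' * `shared_lateralized`: connections lateralized in both groups, with a
#'   per-group scaling of the left/right offset.  Equal scalings give the
#'   group-common lateralization that makes left-vs-right classification
#'   easy for everyone; unequal scalings give shared connections that
#'   differ in lateralization *strength* between groups.
#' * `exclusive_lateralized`: connections lateralized in one group only.
#' * `group_mean`: hemisphere-symmetric connections whose mean connectivity
#'   differs between groups (group 1 gets `+delta` on both hemispheres).
#'   These carry no left/right information but give the dependence term a
#'   group-discriminative direction to exploit, mimicking documented mean
#'   connectivity differences between groups in real data.
#'
#' Defaults state a desk-scale world (h = 20 ROIs per hemisphere, 190
#' connections, 200 subjects per group) with 8 common connections, 3
#' shared-unequal, 3 + 3 exclusive and 4 group-mean connections; offsets
#' are 1.2 z-units against feature noise of sd ~0.4, echoing the strong
#' hemispheric asymmetries that make real left/right classification nearly
#' perfect.  See the methods vignette for the rationale.
#'
#' @param n_subjects_per_group subjects per group (default 200).
#' @param h ROIs per hemisphere (default 20).
#' @param lobes named integer vector of lobe sizes summing to `h`.
#' @param shared_lateralized data.frame with columns `i`, `j` (0-based ROI
#'   pair), `offset`, `scale0`, `scale1`.
#' @param exclusive_lateralized data.frame with columns `i`, `j`,
#'   `offset`, `group`.
#' @param group_mean data.frame with columns `i`, `j`, `delta`.
#' @param noise_sd per-connection, per-hemisphere white noise sd (> 0
#'   for realistic data; 0 is allowed for exactness checks).
#' @param baseline_z_sd sd of the population baseline connectivity.
#' @param subject_effect_sd sd of the per-subject random effect.
#' @param seed integer generator seed.
#' @return a `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects_per_group = 200L, h = 20L,
                             lobes = NULL,
                             shared_lateralized = NULL,
                             exclusive_lateralized = NULL,
                             group_mean = NULL,
                             noise_sd = 0.25, baseline_z_sd = 0.3,
                             subject_effect_sd = 0.15, seed = 1L) {
  if (h < 4) stop("h must be >= 4", call. = FALSE)
  if (noise_sd < 0 || baseline_z_sd < 0 || subject_effect_sd < 0) {
    stop("sd parameters must be >= 0", call. = FALSE)
  }
  if (is.null(lobes)) {
    lobes <- if (h %% 4 == 0) {
      stats::setNames(rep(h / 4, 4),
                      c("frontal", "temporal", "parietal", "occipital"))
    } else stats::setNames(h, "frontal")
  }
  if (is.null(shared_lateralized)) {
    shared_lateralized <- rbind(
      # group-common lateralization (equal scaling)
      data.frame(i = c(0, 2, 4, 7, 10, 12, 15, 17),
                 j = c(1, 3, 6, 8, 11, 13, 16, 18),
                 offset = 1.2, scale0 = 1, scale1 = 1),
      # shared but group-scaled lateralization (4:1 strength ratio)
      data.frame(i = c(0, 2, 4), j = c(5, 7, 9),
                 offset = 1.2, scale0 = 0.4, scale1 = 1.6))
  }
  if (is.null(exclusive_lateralized)) {
    exclusive_lateralized <- data.frame(
      i = c(1, 3, 10, 11, 12, 13), j = c(6, 8, 15, 16, 17, 18),
      offset = 1.2, group = c(0, 0, 0, 1, 1, 1))
  }
  if (is.null(group_mean)) {
    group_mean <- data.frame(i = 0:3, j = 10:13, delta = 0.8)
  }
  cfg <- structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                        h = as.integer(h), lobes = lobes,
                        shared_lateralized = shared_lateralized,
                        exclusive_lateralized = exclusive_lateralized,
                        group_mean = group_mean,
                        noise_sd = noise_sd, baseline_z_sd = baseline_z_sd,
                        subject_effect_sd = subject_effect_sd,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  h <- cfg$h
  chk <- function(df, cols, what) {
    if (!all(cols %in% names(df))) {
      stop(what, " needs columns: ", paste(cols, collapse = ", "),
           call. = FALSE)
    }
    if (nrow(df) && any(df$i < 0 | df$j >= h | df$i >= df$j)) {
      stop(what, ": connection out of range for h = ", h, call. = FALSE)
    }
    if (nrow(df) && any(!is.finite(as.matrix(df[setdiff(cols, "group")])))) {
      stop(what, ": non-finite values", call. = FALSE)
    }
  }
  chk(cfg$shared_lateralized, c("i", "j", "offset", "scale0", "scale1"),
      "shared_lateralized")
  chk(cfg$exclusive_lateralized, c("i", "j", "offset", "group"),
      "exclusive_lateralized")
  chk(cfg$group_mean, c("i", "j", "delta"), "group_mean")
  if (sum(cfg$lobes) != h) stop("lobe sizes must sum to h", call. = FALSE)
  invisible(cfg)
}

cfg_linear_indices <- function(df, h) {
  if (!nrow(df)) return(integer(0))
  pair_to_linear_index(df$i, df$j, h)
}

#' Ground-truth index sets of a synthetic configuration
#'
#' @param config a [synthetic_config()].
#' @return list of 0-based connection linear index vectors: `common`
#'   (equal-scaling shared), `shared_unequal`, `exclusive_male`,
#'   `exclusive_female`, `group_mean`, `sex_different` (shared_unequal +
#'   both exclusives: the connections whose lateralization differs
#'   between groups) and `group_dependent` (sex_different + group_mean:
#'   every connection whose distribution depends on group).
#' @export
synthetic_truth <- function(config) {
  h <- config$h
  sh <- config$shared_lateralized
  eq <- sh$scale0 == sh$scale1
  ex <- config$exclusive_lateralized
  truth <- list(
    common = cfg_linear_indices(sh[eq, , drop = FALSE], h),
    shared_unequal = cfg_linear_indices(sh[!eq, , drop = FALSE], h),
    exclusive_male = cfg_linear_indices(ex[ex$group == 0, , drop = FALSE], h),
    exclusive_female = cfg_linear_indices(ex[ex$group == 1, , drop = FALSE], h),
    group_mean = cfg_linear_indices(config$group_mean, h))
  truth$sex_different <- sort(unique(c(truth$shared_unequal,
                                       truth$exclusive_male,
                                       truth$exclusive_female)))
  # everything whose distribution depends on group: what the dual
  # classification is expected to flag
  truth$group_dependent <- sort(unique(c(truth$sex_different,
                                         truth$group_mean)))
  truth
}

#' Generate a paired-hemisphere synthetic dataset
#'
#' Each subject gets a latent symmetric baseline in Fisher-z space
#' (population component sd `baseline_z_sd`, drawn once per dataset, plus
#' a subject random effect sd `subject_effect_sd`, both shared by the
#' subject's two hemispheres).  Planted lateralization offsets are applied
#' as -offset/2 to the left copy and +offset/2 to the right copy (scaled
#' per group for shared connections, one group only for exclusives);
#' group-mean deltas are added to both hemispheres of group-1 subjects.
#' Independent white noise (sd `noise_sd`) is then added per hemisphere
#' and connection.  Everything is generated directly on the
#' upper-triangle feature space, so matrices are symmetric with zero
#' diagonal by construction.
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (a `hemisphere_dataset`; left samples have
#'   y = 0, right y = 1; groups 0/1), `truth` ([synthetic_truth()]
#'   record), and `config`.
#' @export
generate_synthetic <- function(config) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  h <- config$h
  p <- h * (h - 1) / 2
  n <- config$n_subjects_per_group

  offs <- function(group) {
    d <- numeric(p)
    sh <- config$shared_lateralized
    if (nrow(sh)) {
      idx <- cfg_linear_indices(sh, h) + 1
      sc <- if (group == 0) sh$scale0 else sh$scale1
      d[idx] <- d[idx] + sh$offset * sc
    }
    ex <- config$exclusive_lateralized
    ex <- ex[ex$group == group, , drop = FALSE]
    if (nrow(ex)) {
      idx <- cfg_linear_indices(ex, h) + 1
      d[idx] <- d[idx] + ex$offset
    }
    d
  }
  lat <- list(`0` = offs(0), `1` = offs(1))
  gm <- numeric(p)
  if (nrow(config$group_mean)) {
    idx <- cfg_linear_indices(config$group_mean, h) + 1
    gm[idx] <- gm[idx] + config$group_mean$delta
  }

  base_pop <- stats::rnorm(p, 0, config$baseline_z_sd)
  samples <- vector("list", 4 * n)
  k <- 0
  for (group in c(0L, 1L)) {
    d <- lat[[as.character(group)]]
    for (s in seq_len(n)) {
      base <- base_pop + stats::rnorm(p, 0, config$subject_effect_sd)
      if (group == 1L) base <- base + gm
      left <- base - d / 2 + stats::rnorm(p, 0, config$noise_sd)
      right <- base + d / 2 + stats::rnorm(p, 0, config$noise_sd)
      sid <- sprintf("g%d_s%03d", group, s)
      samples[[k + 1]] <- structure(
        list(subject_id = sid, session = 1L, y = 0L, group = group,
             features = left), class = "hemisphere_sample")
      samples[[k + 2]] <- structure(
        list(subject_id = sid, session = 1L, y = 1L, group = group,
             features = right), class = "hemisphere_sample")
      k <- k + 2
    }
  }
  list(dataset = hemisphere_dataset(samples),
       truth = synthetic_truth(config), config = config)
}

#' Recovery of planted connections
#'
#' Set-overlap metrics of a selection against a planted ground-truth index
#' set, plus (when a score vector is given) the average precision of the
#' ranking by |score|.
#'
#' @param selected selected connection indices (a `lateralization_mask`
#'   or an integer vector, 0-based).
#' @param truth planted 0-based connection indices.
#' @param scores optional full-length score vector (e.g. |second-order
#'   weights|) for the rank-based retrieval metric.
#' @return list with `precision`, `recall`, `n_selected`, `n_truth`, and
#'   `average_precision` (NA without scores).
#' @export
planted_recovery_report <- function(selected, truth, scores = NULL) {
  if (inherits(selected, "lateralization_mask")) selected <- selected$indices
  selected <- as.integer(selected)
  truth <- as.integer(truth)
  hit <- length(intersect(selected, truth))
  ap <- NA_real_
  if (!is.null(scores)) {
    ord <- order(-abs(scores), seq_along(scores)) - 1L  # 0-based ranking
    rel <- ord %in% truth
    prec_at <- cumsum(rel) / seq_along(rel)
    ap <- sum(prec_at[rel]) / length(truth)
  }
  list(precision = if (length(selected)) hit / length(selected) else 0,
       recall = if (length(truth)) hit / length(truth) else NA_real_,
       n_selected = length(selected), n_truth = length(truth),
       average_precision = ap)
}
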
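#' Atlas table
#'
#' Maps ROIs to hemispheres, homologues, lobes and gyri.  Left/right ROIs
#' pair one-to-one by `homologue_index` (0-based position within a
#' hemisphere), which is the single source of truth for hemisphere
#' reordering.
#'
#' @param df a data.frame with columns `roi_id` (0-based integer), `name`,
#'   `hemisphere` ("L"/"R"), `homologue_index` (0-based integer), `lobe`,
#'   `gyrus`.
#' @return a validated `atlas_table` (a data.frame).
#' @export
atlas_table <- function(df) {
  req <- c("roi_id", "name", "hemisphere", "homologue_index", "lobe", "gyrus")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("atlas is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[req]
  if (!all(df$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'", call. = FALSE)
  }
  nl <- sum(df$hemisphere == "L"); nr <- sum(df$hemisphere == "R")
  if (nl != nr || nl == 0) {
    stop("atlas must have equal, nonzero ROI counts per hemisphere",
         call. = FALSE)
  }
  for (h in c("L", "R")) {
    hi <- sort(df$homologue_index[df$hemisphere == h])
    if (!identical(as.integer(hi), seq_len(nl) - 1L)) {
      stop("homologue_index must be a bijection onto 0..",
           nl - 1, " within hemisphere ", h, call. = FALSE)
    }
  }
  if (anyDuplicated(df$roi_id)) stop("duplicate roi_id", call. = FALSE)
  class(df) <- c("atlas_table", "data.frame")
  df
}

#' Default interleaved atlas
#'
#' Builds a Brainnetome-style atlas of `2 * h` ROIs in which left/right
#' homologues interleave (roi_id 2k = left homologue k, 2k + 1 = right),
#' with lobes assigned in contiguous blocks of homologue indices.
#'
#' @param h ROIs per hemisphere.
#' @param lobes named integer vector of lobe sizes summing to `h`
#'   (defaults to a rough 7-lobe split for h >= 7, a single lobe otherwise).
#' @return an `atlas_table`.
#' @export
default_atlas <- function(h, lobes = NULL) {
  if (is.null(lobes)) {
    lobes <- if (h >= 7) {
      sizes <- rep(h %/% 7, 7)
      sizes[seq_len(h %% 7)] <- sizes[seq_len(h %% 7)] + 1
      stats::setNames(sizes, c("frontal", "temporal", "parietal", "insular",
                               "limbic", "occipital", "subcortical"))
    } else {
      stats::setNames(h, "frontal")
    }
  }
  if (sum(lobes) != h) stop("lobe sizes must sum to h", call. = FALSE)
  lobe_of <- rep(names(lobes), lobes)
  k <- 0:(h - 1)
  atlas_table(data.frame(
    roi_id = c(rbind(2 * k, 2 * k + 1)),
    name = c(rbind(paste0(lobe_of, "_", k, "_L"),
                   paste0(lobe_of, "_", k, "_R"))),
    hemisphere = rep(c("L", "R"), h),
    homologue_index = rep(k, each = 2),
    lobe = rep(lobe_of, each = 2),
    gyrus = rep(paste0("gyrus", (k %% 3) + 1), each = 2),
    stringsAsFactors = FALSE))
}

validate_connectivity <- function(mat, tol = 1e-10) {
  check_numeric_matrix(mat, "connectivity matrix")
  if (nrow(mat) != ncol(mat)) stop_shape("connectivity matrix must be square")
  if (max(abs(mat - t(mat))) > tol) {
    stop("connectivity matrix is not symmetric", call. = FALSE)
  }
  invisible(mat)
}

#' Fisher-z connectivity matrix from ROI time series
#'
#' Pearson correlation between ROI columns, transformed with Fisher's
#' z = atanh(r).  Correlations are clamped to +/-(1 - 1e-12) before atanh
#' so numerically perfect correlations yield large finite z, and the
#' diagonal is set to 0 (it is never extracted as a feature).
#'
#' @param timeseries T x n numeric matrix, frames in rows, ROIs in columns.
#' @return n x n symmetric matrix of z values with zero diagonal.
#' @export
correlation_fisher_z <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  check_numeric_matrix(timeseries, "timeseries")
  if (nrow(timeseries) < 3) {
    stop("need at least 3 frames", call. = FALSE)
  }
  sds <- apply(timeseries, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(colnames(timeseries))) colnames(timeseries)[bad]
          else bad - 1  # 0-based position
    stop("constant time series for ROI(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(timeseries)
  bound <- 1 - 1e-12
  r[r > bound] <- bound
  r[r < -bound] <- -bound
  z <- atanh(r)
  diag(z) <- 0
  (z + t(z)) / 2
}

#' Average connectivity matrices across runs
#'
#' Elementwise arithmetic mean in Fisher-z space.
#'
#' @param matrices a list of equally sized symmetric matrices (same ROI
#'   order).
#' @return the mean matrix.
#' @export
average_runs <- function(matrices) {
  if (!length(matrices)) stop("no matrices supplied", call. = FALSE)
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[, 1])) stop_shape("matrices differ in shape")
  lapply(matrices, validate_connectivity)
  Reduce(`+`, matrices) / length(matrices)
}

#' Split a full-brain matrix into intrahemispheric blocks
#'
#' Reorders rows/columns via the atlas so that row/column k of each output
#' is the ROI with `homologue_index` k in that hemisphere; homologous
#' connections then occupy identical positions in the two outputs.
#'
#' @param full 2h x 2h symmetric matrix, rows/cols in `roi_id` order
#'   (0-based roi_id r is row r + 1).
#' @param atlas an [atlas_table()] covering all 2h ROIs.
#' @return `list(left = , right = )` of h x h matrices in homologue order.
#' @export
split_hemispheres <- function(full, atlas) {
  validate_connectivity(full)
  if (nrow(full) != nrow(atlas)) {
    stop_shape("matrix size does not match atlas (", nrow(full),
               " vs ", nrow(atlas), " ROIs)")
  }
  pick <- function(hemi) {
    sub <- atlas[atlas$hemisphere == hemi, ]
    rows <- sub$roi_id[order(sub$homologue_index)] + 1
    full[rows, rows, drop = FALSE]
  }
  list(left = pick("L"), right = pick("R"))
}

#' Strict upper-triangle vectorization
#'
#' Row-major strict upper triangle: for h = 3 the order is (0,1), (0,2),
#' (1,2).  Length h(h-1)/2 (7,503 for h = 123).
#'
#' @param mat h x h symmetric matrix.
#' @return numeric vector of length h(h-1)/2.
#' @export
upper_triangle_vector <- function(mat) {
  validate_connectivity(mat)
  h <- nrow(mat)
  pr <- upper_pairs(h)
  mat[cbind(pr[, 1] + 1, pr[, 2] + 1)]
}

# all (i, j) with 0 <= i < j < h, row-major; 0-based
upper_pairs <- function(h) {
  i <- rep.int(0:(h - 2), (h - 1):1)
  j <- sequence((h - 1):1, from = 2:h) - 1
  cbind(i = i, j = j)
}

#' Rebuild a symmetric matrix from its upper-triangle vector
#'
#' Inverse of [upper_triangle_vector()] (diagonal set to 0).
#'
#' @param vec vector of length h(h-1)/2.
#' @param h matrix size.
#' @return h x h symmetric matrix.
#' @export
vector_to_symmetric <- function(vec, h) {
  if (length(vec) != h * (h - 1) / 2) {
    stop_shape("vector length does not match h(h-1)/2")
  }
  out <- matrix(0, h, h)
  pr <- upper_pairs(h)
  out[cbind(pr[, 1] + 1, pr[, 2] + 1)] <- vec
  out + t(out)
}

#' Map between connection linear indices and ROI pairs
#'
#' 0-based linear indices follow the row-major strict-upper-triangle order
#' of [upper_triangle_vector()]: index 0 is pair (0, 1); index
#' h(h-1)/2 - 1 is (h-2, h-1).  Vectorized over `idx` / `i`, `j`.
#'
#' @param idx 0-based linear index (0 <= idx < h(h-1)/2).
#' @param h ROIs per hemisphere.
#' @return `linear_index_to_pair`: a 2-column matrix of (i, j) with i < j;
#'   `pair_to_linear_index`: integer vector of linear indices.
#' @export
linear_index_to_pair <- function(idx, h) {
  nmax <- h * (h - 1) / 2
  if (any(idx < 0 | idx >= nmax)) stop("index out of range", call. = FALSE)
  row_start <- function(i) i * (h - 1) - i * (i - 1) / 2  # index of (i, i+1)
  # closed form from row_start(i) <= idx, then guard the float boundary
  i <- floor(((2 * h - 1) - sqrt((2 * h - 1)^2 - 8 * idx)) / 2)
  i <- pmin(pmax(i, 0), h - 2)
  low <- idx < row_start(i)
  i[low] <- i[low] - 1
  high <- i < h - 2 & idx >= row_start(i + 1)
  i[high] <- i[high] + 1
  j <- idx - row_start(i) + i + 1
  cbind(i = as.integer(i), j = as.integer(j))
}

#' @rdname linear_index_to_pair
#' @param i,j 0-based ROI indices with i < j.
#' @export
pair_to_linear_index <- function(i, j, h) {
  if (any(i < 0 | j >= h | i >= j)) {
    stop("need 0 <= i < j < h", call. = FALSE)
  }
  as.integer(i * (h - 1) - i * (i - 1) / 2 + (j - i) - 1)
}

#' Build the two hemisphere samples of one subject/session
#'
#' @param left,right h x h intrahemispheric matrices in homologue order
#'   (as produced by [split_hemispheres()]).
#' @param subject_id subject identifier.
#' @param group group code in {0, 1}.
#' @param session session identifier.
#' @return a list of two `hemisphere_sample` objects (left: y = 0,
#'   right: y = 1) each with a length h(h-1)/2 `features` vector.
#' @export
hemisphere_samples <- function(left, right, subject_id, group,
                               session = 1L) {
  mk <- function(mat, y) {
    structure(list(subject_id = as.character(subject_id),
                   session = session, y = y, group = group,
                   features = upper_triangle_vector(mat)),
              class = "hemisphere_sample")
  }
  list(mk(left, 0L), mk(right, 1L))
}

#' Assemble hemisphere samples into a dataset
#'
#' @param samples a list of `hemisphere_sample` objects.
#' @return a `hemisphere_dataset`: list with `features` matrix (one sample
#'   per row), and `meta` data.frame (`subject_id`, `session`, `y`,
#'   `group`).
#' @export
hemisphere_dataset <- function(samples) {
  feats <- do.call(rbind, lapply(samples, `[[`, "features"))
  meta <- data.frame(
    subject_id = vapply(samples, `[[`, character(1), "subject_id"),
    session = vapply(samples, function(s) as.character(s$session),
                     character(1)),
    y = vapply(samples, function(s) as.integer(s$y), integer(1)),
    group = vapply(samples, function(s) as.integer(s$group), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(features = feats, meta = meta), class = "hemisphere_dataset")
}

#' @export
print.hemisphere_dataset <- function(x, ...) {
  cat("<hemisphere_dataset> ", nrow(x$features), " hemisphere samples x ",
      ncol(x$features), " connections; subjects: ",
      length(unique(x$meta$subject_id)), "\n", sep = "")
  invisible(x)
}

#' Convert a hemisphere dataset (or a row subset) to a grouped design
#'
#' @param dataset a `hemisphere_dataset`.
#' @param idx optional row indices.
#' @return a [grouped_design()].
#' @export
as_grouped_design <- function(dataset, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(nrow(dataset$features))
  grouped_design(dataset$features[idx, , drop = FALSE],
                 dataset$meta$y[idx], dataset$meta$group[idx],
                 dataset$meta$subject_id[idx], dataset$meta$session[idx])
}
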
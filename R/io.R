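#' Read/write delimited connectivity matrices
#'
#' Matrices are stored as TSV with a `roi_id` header row and first column
#' (0-based ids in row order).
#'
#' @param mat square numeric matrix.
#' @param path file path.
#' @param roi_ids 0-based ids (default `0:(n-1)`).
#' @return `read_matrix`: the matrix with ids as dimnames.
#' @export
write_matrix <- function(mat, path, roi_ids = seq_len(nrow(mat)) - 1L) {
  df <- data.frame(roi_id = roi_ids, mat, check.names = FALSE)
  names(df) <- c("roi_id", roi_ids)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1] != "roi_id") {
    stop("matrix file ", path, ": first column must be 'roi_id'",
         call. = FALSE)
  }
  ids <- df$roi_id
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(mat) != ncol(mat)) {
    stop_shape("matrix file ", path, " is not square (", nrow(mat), " x ",
               ncol(mat), ")")
  }
  if (!identical(as.integer(ids), as.integer(colnames(mat)))) {
    stop("matrix file ", path, ": row and column roi_ids disagree",
         call. = FALSE)
  }
  dimnames(mat) <- list(ids, ids)
  mat
}

#' Read/write ROI time series
#'
#' Frames x ROIs TSV with a header row of 0-based roi_ids.
#'
#' @param ts T x n numeric matrix.
#' @param path file path.
#' @return `read_timeseries`: numeric matrix with roi_id colnames.
#' @export
write_timeseries <- function(ts, path) {
  colnames(ts) <- seq_len(ncol(ts)) - 1L
  utils::write.table(ts, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  mat <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  if (!is.numeric(mat)) {
    stop("time-series file ", path, " contains non-numeric values",
         call. = FALSE)
  }
  mat
}

#' Read/write an atlas table
#'
#' TSV with the five atlas columns (`roi_id`, `name`, `hemisphere`,
#' `homologue_index`, `lobe`, `gyrus`).
#'
#' @param atlas an [atlas_table()].
#' @param path file path.
#' @return `read_atlas`: a validated `atlas_table`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas_table(utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}

#' Read/write a dataset manifest
#'
#' A JSON array of records `{subject_id, group, session, run, path}`;
#' paths are interpreted relative to the manifest's directory.
#'
#' @param manifest data.frame with those five columns.
#' @param path file path.
#' @return `read_manifest`: a data.frame with an extra `dir` attribute.
#' @export
write_manifest <- function(manifest, path) {
  req <- c("subject_id", "group", "session", "run", "path")
  if (!all(req %in% names(manifest))) {
    stop("manifest needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  jsonlite::write_json(manifest[req], path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("subject_id", "group", "session", "run", "path")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("manifest ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$group <- as_binary(df$group, "manifest group")
  attr(df, "dir") <- dirname(path)
  df
}

#' Write a synthetic dataset in the on-disk pipeline formats
#'
#' Embeds each subject's left/right intrahemispheric matrices into a full
#' 2h x 2h matrix in interleaved atlas order (interhemispheric block set
#' to 0, which is never extracted), and writes one matrix file per
#' subject together with `atlas.tsv`, `manifest.json` and `truth.json`,
#' so the standard extract/fit pipeline runs unchanged on synthetic data.
#'
#' @param gen output of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic_dataset <- function(gen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- gen$config
  atlas <- default_atlas(cfg$h, cfg$lobes)
  write_atlas(atlas, file.path(dir, "atlas.tsv"))
  ds <- gen$dataset
  subs <- unique(ds$meta$subject_id)
  rows <- vector("list", length(subs))
  for (s in seq_along(subs)) {
    idx <- which(ds$meta$subject_id == subs[s])
    left <- vector_to_symmetric(
      ds$features[idx[ds$meta$y[idx] == 0], ], cfg$h)
    right <- vector_to_symmetric(
      ds$features[idx[ds$meta$y[idx] == 1], ], cfg$h)
    full <- matrix(0, 2 * cfg$h, 2 * cfg$h)
    lrows <- atlas$roi_id[atlas$hemisphere == "L"][
      order(atlas$homologue_index[atlas$hemisphere == "L"])] + 1
    rrows <- atlas$roi_id[atlas$hemisphere == "R"][
      order(atlas$homologue_index[atlas$hemisphere == "R"])] + 1
    full[lrows, lrows] <- left
    full[rrows, rrows] <- right
    fname <- paste0("sub_", subs[s], ".tsv")
    write_matrix(full, file.path(dir, fname))
    rows[[s]] <- data.frame(subject_id = subs[s],
                            group = ds$meta$group[idx[1]],
                            session = 1L, run = 1L, path = fname,
                            stringsAsFactors = FALSE)
  }
  write_manifest(do.call(rbind, rows), file.path(dir, "manifest.json"))
  jsonlite::write_json(gen$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}

#' Extract hemisphere samples from a manifest of connectivity data
#'
#' For each (subject, session): read the listed files (connectivity
#' matrices, or ROI time series converted via [correlation_fisher_z()]),
#' average across runs in z space, split hemispheres through the atlas
#' and vectorize the upper triangles.
#'
#' @param manifest a [read_manifest()] result (or data.frame plus `dir`
#'   attribute).
#' @param atlas an [atlas_table()].
#' @param input one of `"matrix"`, `"timeseries"`.
#' @return a `hemisphere_dataset`.
#' @export
extract_dataset <- function(manifest, atlas, input = c("matrix",
                                                       "timeseries")) {
  input <- match.arg(input)
  dir <- attr(manifest, "dir")
  if (is.null(dir)) dir <- "."
  samples <- list()
  keys <- unique(manifest[c("subject_id", "session")])
  for (r in seq_len(nrow(keys))) {
    rows <- manifest[manifest$subject_id == keys$subject_id[r] &
                       manifest$session == keys$session[r], , drop = FALSE]
    mats <- lapply(file.path(dir, rows$path), function(f) {
      if (input == "matrix") read_matrix(f)
      else correlation_fisher_z(read_timeseries(f))
    })
    avg <- average_runs(mats)
    halves <- split_hemispheres(avg, atlas)
    samples <- c(samples, hemisphere_samples(
      halves$left, halves$right, keys$subject_id[r], rows$group[1],
      keys$session[r]))
  }
  hemisphere_dataset(samples)
}

#' Read/write a hemisphere dataset
#'
#' `samples.csv` holds the metadata (one row per hemisphere sample) and
#' `features.csv` the feature matrix, both plain CSV.
#'
#' @param dataset a `hemisphere_dataset`.
#' @param dir directory.
#' @return `read_hemisphere_dataset`: a `hemisphere_dataset`.
#' @export
write_hemisphere_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$meta, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$features),
                   file.path(dir, "features.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_hemisphere_dataset
#' @export
read_hemisphere_dataset <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "samples.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character"))
  feats <- as.matrix(utils::read.csv(file.path(dir, "features.csv")))
  dimnames(feats) <- NULL
  structure(list(features = feats, meta = meta),
            class = "hemisphere_dataset")
}

#' Read/write a first-order ensemble
#'
#' `records.csv` + `weights.csv` + a `meta.json` sidecar.
#'
#' @param ensemble a `first_order_ensemble`.
#' @param dir directory.
#' @return `read_first_order_ensemble`: a `first_order_ensemble`.
#' @export
write_first_order_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ensemble$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(ensemble$weights),
                   file.path(dir, "weights.csv"), row.names = FALSE)
  meta <- ensemble$meta
  meta$scheme <- unclass(meta$scheme)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_first_order_ensemble
#' @export
read_first_order_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  meta$scheme <- structure(meta$scheme, class = "partition_scheme")
  W <- as.matrix(utils::read.csv(file.path(dir, "weights.csv")))
  dimnames(W) <- NULL
  structure(list(records = utils::read.csv(file.path(dir, "records.csv")),
                 weights = W, meta = meta),
            class = "first_order_ensemble")
}

#' Write a JSON provenance record
#'
#' @param path output path.
#' @param command command name.
#' @param config named list of parameters (seeds included).
#' @export
write_provenance <- function(path, command, config) {
  jsonlite::write_json(
    list(command = command, config = config,
         package_version = as.character(utils::packageVersion("gsda")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC")),
    path, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(path)
}
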
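#' Index a class-per-folder image dataset
#'
#' Expects one subfolder per identity under `root`, each holding the
#' images of that identity (PNG/JPEG/TIFF). Ordering is lexicographic and
#' deterministic. Empty subfolders are dropped with a warning.
#'
#' @param root dataset directory.
#' @return data.frame with columns `path`, `label`.
#' @export
load_dataset <- function(root) {
  if (!dir.exists(root)) stop("no such directory: ", root, call. = FALSE)
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = TRUE))
  if (!length(classes)) stop("no class subfolders under ", root, call. = FALSE)
  rows <- list()
  for (cl in classes) {
    files <- sort(list.files(cl, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) {
      warning("dropping empty class folder: ", basename(cl))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(path = files,
                                            label = basename(cl))
  }
  if (!length(rows)) stop("dataset is empty", call. = FALSE)
  do.call(rbind, rows)
}

#' Load the images of a dataset index
#'
#' Reads every file of a [load_dataset()] index as grayscale; unreadable
#' files are skipped with a warning reporting the count.
#'
#' @param index data.frame with `path` and `label` columns.
#' @param roi_args optional list of arguments to [extract_roi()] applied
#'   to each image (e.g. `list(bypass = TRUE, target_shape = c(32, 32))`);
#'   `NULL` loads raw images.
#' @return List with `images` and `labels`.
#' @export
load_images <- function(index, roi_args = NULL) {
  images <- list(); labels <- character(0); failed <- 0L
  for (i in seq_len(nrow(index))) {
    img <- tryCatch(read_gray(index$path[i]), error = function(e) NULL)
    if (is.null(img)) { failed <- failed + 1L; next }
    if (!is.null(roi_args))
      img <- do.call(extract_roi, c(list(image = img), roi_args))
    images[[length(images) + 1L]] <- img
    labels <- c(labels, index$label[i])
  }
  if (failed > 0L) warning(failed, " file(s) could not be read and were skipped")
  list(images = images, labels = labels)
}

#' Serialize a fitted model to JSON
#'
#' Writes the configuration, the selected per-scale orientation angles of
#' both layers, the selection weights, and the pooling geometry. The
#' filter arrays themselves are not stored: they are a deterministic
#' function of this metadata and are rebuilt on load.
#'
#' @param model a [vfdcn()] model.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_vfdcn <- function(model, path) {
  check_trained(model)
  # selected angles are members of the candidate set; store their 1-based
  # indices so the round trip is exact
  cand <- orientation_angles(model$config$Nori)
  to_idx <- function(angles) lapply(angles, function(a)
    vapply(a, function(x) which.min(abs(cand - x)), integer(1)))
  payload <- list(
    format = "vfdcn-model", version = 1L,
    config = unclass(model$config),
    per_scale_counts = model$per_scale_counts,
    ori_index_layer1 = to_idx(model$diamond$angles),
    ori_index_layer2 = to_idx(model$diamond2$angles),
    weights_layer1 = model$diamond$weights,
    block_shape = model$block_shape)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path file written by [write_vfdcn()].
#' @return A `"vfdcn"` model equivalent to the serialized one.
#' @export
read_vfdcn <- function(path) {
  p <- jsonlite::read_json(path)       # no simplification: keep list shapes
  if (!identical(p$format, "vfdcn-model"))
    stop("not a serialized vfdcn model: ", path, call. = FALSE)
  cf <- lapply(p$config, unlist)
  cfg <- lg_config(Wmin = cf$Wmin, M = cf$M, T_ang = cf$T_ang,
                   sigma_r = cf$sigma_r, Nscale = cf$Nscale,
                   Nori = cf$Nori, image_shape = cf$image_shape)
  cand <- orientation_angles(cfg$Nori)
  as_angles <- function(a) lapply(a, function(x) cand[as.integer(unlist(x))])
  a1 <- as_angles(p$ori_index_layer1)
  a2 <- as_angles(p$ori_index_layer2)
  p$weights_layer1 <- do.call(rbind, lapply(p$weights_layer1, unlist))
  p$per_scale_counts <- unlist(p$per_scale_counts)
  p$block_shape <- unlist(p$block_shape)
  bank1 <- build_bank(cfg, a1)
  bank2 <- build_bank(cfg, a2)
  cand <- orientation_angles(cfg$Nori)
  d1 <- structure(list(angles = a1, counts = lengths(a1),
                       weights = p$weights_layer1, candidate_angles = cand),
                  class = "diamond_structure")
  d2 <- structure(list(angles = a2, counts = lengths(a2),
                       weights = NULL, candidate_angles = cand),
                  class = "diamond_structure")
  block_shape <- as.integer(p$block_shape)
  B <- prod(cfg$image_shape %/% block_shape)
  structure(list(config = cfg, per_scale_counts = as.integer(p$per_scale_counts),
                 diamond = d1, diamond2 = d2, bank1 = bank1, bank2 = bank2,
                 K1 = length(bank1$filters), K2 = length(bank2$filters),
                 block_shape = block_shape, B = B,
                 feature_length = 2^length(bank2$filters) *
                   length(bank1$filters) * B),
            class = "vfdcn")
}

#' Write an evaluation report
#'
#' Emits the report as JSON (summary + per-iteration table) and the
#' threshold sweep as CSV (`threshold`, `FAR`, `FRR`).
#'
#' @param report a `"vfdcn_eval"`.
#' @param json_path,csv_path output files (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_eval <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "vfdcn_eval"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(EER = report$EER, ACC = report$ACC,
           n_iterations = report$n_iterations, seed = report$seed,
           n_genuine = report$n_genuine, n_imposter = report$n_imposter,
           per_iteration = report$per_iteration),
      json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(csv_path))
    utils::write.csv(report$roc, csv_path, row.names = FALSE)
  invisible(report)
}
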
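#' Write a dataset to disk as PNG images plus a manifest CSV
#'
#' Images and masks are written as 8-bit grayscale PNG files; the manifest
#' has columns `image_path, mask_path, bbox_x0, bbox_y0, bbox_x1, bbox_y1,
#' fold`, then one 0/1 column per class. Missing masks/boxes are written as
#' empty cells.
#'
#' @param samples List of [image_sample()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(samples, dir) {
  stopifnot(length(samples) > 0)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  class_names <- names(samples[[1]]$targets)
  rows <- lapply(samples, function(sm) {
    ip <- file.path("images", paste0(sm$id, ".png"))
    png::writePNG(sm$image, file.path(dir, ip))
    mp <- ""
    bb <- rep("", 4L)
    if (!is.null(sm$mask)) {
      mp <- file.path("masks", paste0(sm$id, "_mask.png"))
      png::writePNG(sm$mask + 0, file.path(dir, mp))  # coerce off integer storage
    }
    if (!is.null(sm$bbox)) bb <- as.character(sm$bbox)
    c(image_path = ip, mask_path = mp,
      bbox_x0 = bb[1], bbox_y0 = bb[2], bbox_x1 = bb[3], bbox_y1 = bb[4],
      fold = as.character(sm$fold),
      stats::setNames(as.character(sm$targets), class_names))
  })
  manifest <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load a dataset from a manifest CSV
#'
#' Reads the manifest layout written by [write_dataset()]: the first seven
#' columns describe paths, bounding box and fold; every remaining column is
#' a 0/1 class label. Malformed rows are reported with their line number.
#'
#' @param path Path to `manifest.csv`; image/mask paths are resolved
#'   relative to its directory.
#' @return List of [image_sample()] objects.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  fixed <- c("image_path", "mask_path", "bbox_x0", "bbox_y0",
             "bbox_x1", "bbox_y1", "fold")
  if (!all(fixed %in% names(man))) {
    stop("manifest header must contain: ", paste(fixed, collapse = ", "))
  }
  class_names <- setdiff(names(man), fixed)
  if (length(class_names) == 0L) stop("manifest has no label columns")
  root <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    line <- i + 1L  # header is line 1
    ipath <- file.path(root, row$image_path)
    if (!file.exists(ipath)) {
      stop(sprintf("line %d: image file missing: %s", line, row$image_path))
    }
    img <- png_as_gray(ipath)
    labs <- as.character(row[class_names])
    bad <- which(!labs %in% c("0", "1"))
    if (length(bad)) {
      stop(sprintf("line %d: non-binary label '%s' in column '%s'",
                   line, labs[bad[1]], class_names[bad[1]]))
    }
    targets <- stats::setNames(as.numeric(labs), class_names)
    mask <- NULL
    if (nzchar(row$mask_path)) {
      mpath <- file.path(root, row$mask_path)
      if (!file.exists(mpath)) {
        stop(sprintf("line %d: mask file missing: %s", line, row$mask_path))
      }
      mask <- png_as_gray(mpath)
      mask <- matrix(as.integer(mask > 0.5), nrow(mask), ncol(mask))
    }
    bbox <- NULL
    if (nzchar(row$bbox_x0)) {
      bbox <- as.integer(row[c("bbox_x0", "bbox_y0", "bbox_x1", "bbox_y1")])
      if (any(is.na(bbox)) || bbox[1] < 0 || bbox[2] < 0 ||
          bbox[3] > ncol(img) || bbox[4] > nrow(img) ||
          bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
        stop(sprintf("line %d: bounding box outside image or degenerate", line))
      }
    }
    image_sample(image = img, targets = targets, mask = mask, bbox = bbox,
                 fold = as.integer(row$fold),
                 id = sub("\\.png$", "", basename(row$image_path)))
  })
}

png_as_gray <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a
}

#' Write a prediction set to CSV
#'
#' Layout: an `image_id` column, then one probability column per class (the
#' header carries the class names); when targets are known, matching
#' `target_<class>` columns follow.
#'
#' @param pred A [prediction_set()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_predictions <- function(pred, path) {
  stopifnot(inherits(pred, "prediction_set"))
  df <- data.frame(image_id = pred$image_ids, check.names = FALSE)
  for (cn in pred$class_names) df[[cn]] <- pred$scores[, cn]
  if (!is.null(pred$targets)) {
    for (cn in pred$class_names) {
      df[[paste0("target_", cn)]] <- pred$targets[, cn]
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a prediction set written by [write_predictions()]
#'
#' @param path CSV path.
#' @return A [prediction_set()].
#' @export
read_predictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  tcols <- grep("^target_", names(df), value = TRUE)
  class_names <- setdiff(names(df), c("image_id", tcols))
  targets <- NULL
  if (length(tcols) == length(class_names)) {
    targets <- as.matrix(df[paste0("target_", class_names)])
  }
  prediction_set(scores = as.matrix(df[class_names]),
                 class_names = class_names,
                 image_ids = as.character(df$image_id),
                 targets = targets)
}
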
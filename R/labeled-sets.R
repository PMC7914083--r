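# Containers for labeled image sets and ordinal tabular sets, plus their
# on-disk formats (8-bit grayscale PNG; WBCD-dialect CSV with "?" for missing).

#' Labeled grayscale image set
#'
#' Bundles a list of grayscale images (numeric matrices with intensities in
#' \code{[0, 255]}), one integer class label per image (labels run from 0 to
#' \code{n_classes - 1}), and a unique string id per image.
#'
#' @param images List of numeric matrices, all the same dimensions, values in
#'   \code{[0, 255]}.
#' @param labels Integer vector of class ids, one per image, each in
#'   \code{[0, n_classes)}.
#' @param ids Character vector of unique image ids; generated as
#'   \code{"img_00001"}, ... when omitted.
#' @return An object of class \code{labeled_image_set}.
#' @export
labeled_image_set <- function(images, labels, ids = NULL) {
  if (!is.list(images) || length(images) == 0L) {
    stopf("`images` must be a nonempty list of matrices")
  }
  if (!all(vapply(images, is.matrix, logical(1)))) {
    stopf("every image must be a numeric matrix")
  }
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all images in a set must share the same dimensions")
  }
  rng <- range(vapply(images, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255) stopf("image intensities must lie in [0, 255]")
  labels <- as.integer(labels)
  if (length(labels) != length(images)) stopf("one label per image required")
  if (any(labels < 0L)) stopf("labels must be nonnegative integers")
  if (is.null(ids)) ids <- sprintf("img_%05d", seq_along(images))
  ids <- as.character(ids)
  if (length(ids) != length(images) || anyDuplicated(ids)) {
    stopf("`ids` must be unique, one per image")
  }
  structure(list(images = images, labels = labels, ids = ids),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("Labeled image set: %d images of %dx%d, %d classes\n",
              length(x$images), d[1], d[2], length(unique(x$labels))))
  print(table(label = x$labels))
  invisible(x)
}

#' @export
length.labeled_image_set <- function(x) length(x$images)

#' Subset a labeled image set
#'
#' @param x A \code{labeled_image_set}.
#' @param i Index vector of images to keep.
#' @param ... Unused.
#' @return A \code{labeled_image_set} with the selected images.
#' @export
`[.labeled_image_set` <- function(x, i, ...) {
  labeled_image_set(x$images[i], x$labels[i], x$ids[i])
}

#' Ordinal tabular set (cytology-style records)
#'
#' Rows of nine ordinal features, each an integer in \code{{1..10}} or
#' \code{NA} for a missing value, with a binary label per row
#' (0 = benign-like, 1 = malignant-like).
#'
#' @param records Data frame (or matrix) with nine integer feature columns.
#' @param labels Integer vector of 0/1 labels, one per row.
#' @param ids Optional row ids; sequential integers when omitted.
#' @return An object of class \code{tabular_set}.
#' @export
tabular_set <- function(records, labels, ids = NULL) {
  records <- as.data.frame(records)
  if (ncol(records) != 9L) stopf("`records` must have exactly 9 feature columns")
  vals <- unlist(records, use.names = FALSE)
  ok <- is.na(vals) | (vals == round(vals) & vals >= 1 & vals <= 10)
  if (!all(ok)) stopf("non-missing feature values must be integers in [1, 10]")
  labels <- as.integer(labels)
  if (length(labels) != nrow(records)) stopf("one label per row required")
  if (nrow(records) > 0L && !all(labels %in% c(0L, 1L))) stopf("labels must be binary (0/1)")
  if (is.null(ids)) ids <- seq_len(nrow(records))
  names(records) <- wbcd_feature_names()
  structure(list(records = records, labels = labels, ids = as.character(ids)),
            class = "tabular_set")
}

#' @keywords internal
#' @noRd
wbcd_feature_names <- function() {
  c("clump_thickness", "uniformity_cell_size", "uniformity_cell_shape",
    "marginal_adhesion", "single_epithelial_cell_size", "bare_nuclei",
    "bland_chromatin", "normal_nucleoli", "mitoses")
}

#' @export
print.tabular_set <- function(x, ...) {
  cat(sprintf("Tabular set: %d records, %d with missing values\n",
              nrow(x$records), sum(!stats::complete.cases(x$records))))
  print(table(label = x$labels))
  invisible(x)
}

#' Write / read a tabular set as WBCD-dialect CSV
#'
#' Columns are \code{id}, the nine feature columns, and \code{class} coded
#' 2 (benign-like, label 0) / 4 (malignant-like, label 1), with \code{"?"}
#' marking missing values — the layout of the public
#' \code{breast-cancer-wisconsin.data} file plus a header row.
#'
#' @param x A \code{tabular_set}.
#' @param path File path.
#' @return \code{write_tabular} returns \code{path} invisibly;
#'   \code{read_tabular} returns a \code{tabular_set}.
#' @export
write_tabular <- function(x, path) {
  stopifnot(inherits(x, "tabular_set"))
  out <- cbind(id = x$ids, x$records, class = ifelse(x$labels == 1L, 4L, 2L))
  utils::write.csv(out, path, row.names = FALSE, na = "?", quote = FALSE)
  invisible(path)
}

#' @rdname write_tabular
#' @export
read_tabular <- function(path) {
  df <- utils::read.csv(path, na.strings = "?", stringsAsFactors = FALSE)
  if (ncol(df) != 11L) stopf("expected 11 columns (id, 9 features, class)")
  tabular_set(df[, 2:10], as.integer(df[[11]] == 4L), ids = df[[1]])
}

#' Write / read a labeled image set as 8-bit grayscale PNG files
#'
#' Each image is written to \code{<dir>/<id>.png}; labels are stored in a
#' \code{labels.csv} manifest alongside.
#'
#' @param x A \code{labeled_image_set}.
#' @param dir Output directory (created if absent).
#' @return \code{write_image_set} returns \code{dir} invisibly;
#'   \code{read_image_set} returns a \code{labeled_image_set}.
#' @export
write_image_set <- function(x, dir) {
  stopifnot(inherits(x, "labeled_image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(x$images)) {
    png::writePNG(x$images[[i]] / 255, file.path(dir, paste0(x$ids[i], ".png")))
  }
  utils::write.csv(data.frame(id = x$ids, label = x$labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(dir) {
  man <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  imgs <- lapply(man$id, function(id) {
    px <- png::readPNG(file.path(dir, paste0(id, ".png")))
    if (length(dim(px)) == 3L) px <- px[, , 1]     # collapse RGB(A) grays
    round(px * 255)
  })
  labeled_image_set(imgs, man$label, man$id)
}
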
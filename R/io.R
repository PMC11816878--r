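# Reading and writing grayscale images and feature tables.

#' Construct a grayscale image
#'
#' A grayscale image is an integer-valued numeric matrix with intensities in
#' `[0, levels - 1]` and a `levels` attribute recording the gray-level count.
#'
#' @param mat Numeric matrix.
#' @param levels Number of gray levels (>= 2).
#' @return The matrix with a validated `levels` attribute.
#' @export
gray_image <- function(mat, levels = 256L) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop_arg("`mat` must be a numeric matrix")
  check_number(levels, "levels", lower = 2)
  if (min(mat) < 0 || max(mat) > levels - 1) {
    stop_arg("intensities must lie in [0, levels - 1]")
  }
  attr(mat, "levels") <- as.integer(levels)
  mat
}

# Gray-level count of an image, defaulting to 256 when unmarked.
image_levels <- function(image) {
  lv <- attr(image, "levels")
  if (is.null(lv)) 256L else as.integer(lv)
}

#' Read a grayscale image from PNG, TIFF, or single-slice NIfTI
#'
#' Multi-channel inputs are averaged to one channel; PNG/TIFF intensities in
#' `[0, 1]` are rescaled to 8-bit `[0, 255]`. NIfTI volumes must be a single
#' slice (one non-trivial plane); intensities are linearly rescaled to
#' `[0, 255]`.
#'
#' @param path File path; format chosen by extension (.png, .tif/.tiff,
#'   .nii/.nii.gz).
#' @return A [gray_image()] with 256 levels.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  arr <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE)) stop_arg("package `png` required")
      png::readPNG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop_arg("package `tiff` required")
      tiff::readTIFF(path)
    },
    nii = {
      if (!requireNamespace("RNifti", quietly = TRUE)) stop_arg("package `RNifti` required")
      v <- RNifti::readNifti(path)
      v <- drop(as.array(v))
      if (length(dim(v)) == 3L) {
        if (sum(dim(v) > 1L) > 2L) stop_arg("only single-slice NIfTI is supported")
        v <- drop(v)
      }
      rng <- range(v)
      if (diff(rng) > 0) v <- (v - rng[1]) / diff(rng)
      v
    },
    stop_arg("unsupported image extension: %s", ext)
  )
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
  gray_image(round(arr * 255), levels = 256L)
}

#' Write a grayscale image as PNG
#'
#' @param image A [gray_image()] (or numeric matrix; `levels` defaults to 256).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) stop_arg("package `png` required")
  lv <- image_levels(image)
  png::writePNG(unclass(image) / (lv - 1), target = path)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' Header is `feature_000..feature_NNN,label` for tables built by
#' [make_planted_feature_table()]; arbitrary feature names pass through.
#'
#' @param table Data frame with feature columns and a `label` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!("label" %in% names(table))) stop_arg("`table` must have a `label` column")
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path with a `label` column.
#' @return Data frame with numeric features and integer labels.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!("label" %in% names(tab))) stop_arg("CSV must have a `label` column")
  tab$label <- as_binary_labels(tab$label)
  tab
}
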
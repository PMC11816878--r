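# Image preprocessing: FWHM-parameterized Gaussian smoothing, resizing to the
# backend input size, optional foreground masking, and train/test splitting.

#' Convert a Gaussian FWHM in millimetres to a sigma in pixels
#'
#' Smoothing protocols in neuroimaging quote the kernel width as the full
#' width at half maximum (FWHM). For a Gaussian, FWHM = 2*sqrt(2*ln 2)*sigma,
#' so `sigma_px = fwhm_mm / (voxel_mm * 2*sqrt(2*ln 2))`.
#'
#' @param fwhm_mm Kernel full width at half maximum in mm (>= 0).
#' @param voxel_mm Pixel pitch in mm (> 0, assumed isotropic). Default 1.
#' @return Gaussian standard deviation in pixel units.
#' @examples
#' fwhm_to_sigma(4)            # the common 4 mm protocol at 1 mm voxels
#' fwhm_to_sigma(2.3548, 1)    # ~ 1 pixel
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_mm = 1) {
  check_number(fwhm_mm, "fwhm_mm", lower = 0)
  check_number(voxel_mm, "voxel_mm")
  if (voxel_mm <= 0) stop_arg("`voxel_mm` must be positive")
  fwhm_mm / (voxel_mm * 2 * sqrt(2 * log(2)))
}

# Reflect an integer index vector into [1, n] (symmetric/edge-repeat mirror,
# so out-of-range kernel mass folds back in and the total is conserved).
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  k <- (idx - 1L) %% period
  k <- ifelse(k < 0L, k + period, k)
  as.integer(ifelse(k < n, k + 1L, period - k))
}

# Row-convolution operator for a normalized Gaussian kernel with reflective
# boundary, as a dense n x n matrix; rows sum to 1 so the mean is preserved.
gaussian_band_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  offs <- (-r):r
  w <- exp(-(offs^2) / (2 * sigma^2))
  w <- w / sum(w)
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in seq_along(offs)) {
    j <- reflect_index(i + offs[k], n)
    K[cbind(i, j)] <- K[cbind(i, j)] + w[k]
  }
  K
}

#' Gaussian smoothing of a grayscale image
#'
#' Separable Gaussian convolution with reflective boundary handling. A
#' `sigma_px` of 0 returns the input unchanged. The kernel is normalized, so
#' a constant image maps to itself and the image mean is preserved exactly.
#' Output intensities are continuous (no re-quantization).
#'
#' @param image Numeric matrix of intensities.
#' @param sigma_px Gaussian standard deviation in pixels (>= 0).
#' @return Smoothed matrix of the same dimensions; the `levels` attribute, if
#'   present, is carried over.
#' @export
gaussian_smooth <- function(image, sigma_px) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_arg("`image` must be a numeric matrix")
  }
  check_number(sigma_px, "sigma_px")
  if (sigma_px < 0) stop_arg("`sigma_px` must be >= 0")
  if (sigma_px == 0) return(image)
  Kr <- gaussian_band_matrix(nrow(image), sigma_px)
  Kc <- gaussian_band_matrix(ncol(image), sigma_px)
  out <- Kr %*% image %*% t(Kc)
  attributes(out) <- attributes(image)[c("dim", "levels")]
  out
}

#' Resize a grayscale image
#'
#' Nearest-neighbor or bilinear resampling. Resizing to the input's own size
#' is the identity in both modes; bilinear output stays within the input's
#' intensity range (convex combination of neighbors).
#'
#' @param image Numeric matrix.
#' @param target_size Integer vector `c(rows, cols)` (a scalar is recycled).
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return Resized matrix, `levels` attribute preserved.
#' @export
resize_image <- function(image, target_size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_arg("`image` must be a numeric matrix")
  }
  if (nrow(image) == 0L || ncol(image) == 0L) stop_arg("`image` must be non-empty")
  if (length(target_size) == 1L) target_size <- rep(target_size, 2L)
  if (length(target_size) != 2L || any(target_size < 1)) {
    stop_arg("`target_size` must be two positive integers")
  }
  nr <- as.integer(target_size[1]); nc <- as.integer(target_size[2])
  sr <- nrow(image) / nr; sc <- ncol(image) / nc
  out <- if (method == "nearest") {
    ri <- pmin(nrow(image), pmax(1L, floor((seq_len(nr) - 0.5) * sr) + 1L))
    ci <- pmin(ncol(image), pmax(1L, floor((seq_len(nc) - 0.5) * sc) + 1L))
    image[ri, ci, drop = FALSE]
  } else {
    # center-aligned source coordinates; clamp keeps edges well-defined
    rs <- pmin(nrow(image), pmax(1, (seq_len(nr) - 0.5) * sr + 0.5))
    cs <- pmin(ncol(image), pmax(1, (seq_len(nc) - 0.5) * sc + 0.5))
    r0 <- pmin(floor(rs), nrow(image) - 1L); r0[nrow(image) == 1L] <- 1L
    c0 <- pmin(floor(cs), ncol(image) - 1L); c0[ncol(image) == 1L] <- 1L
    r1 <- pmin(r0 + 1L, nrow(image)); c1 <- pmin(c0 + 1L, ncol(image))
    fr <- rs - r0; fc <- cs - c0
    A <- image[r0, c0, drop = FALSE]; B <- image[r0, c1, drop = FALSE]
    C <- image[r1, c0, drop = FALSE]; D <- image[r1, c1, drop = FALSE]
    Wfr <- matrix(fr, nr, nc); Wfc <- matrix(fc, nr, nc, byrow = TRUE)
    (1 - Wfr) * ((1 - Wfc) * A + Wfc * B) + Wfr * ((1 - Wfc) * C + Wfc * D)
  }
  attr(out, "levels") <- attr(image, "levels")
  out
}

#' Multiply an image by a binary foreground mask
#'
#' Stands in for brain-extraction on synthetic fixtures: pixels where the
#' mask is 0 are set to 0, the rest pass through.
#'
#' @param image Numeric matrix.
#' @param mask Matrix of the same dimensions with values in \{0, 1\}.
#' @return Masked image.
#' @export
apply_mask <- function(image, mask) {
  if (!identical(dim(image), dim(mask))) stop_arg("`mask` dims must match `image`")
  if (!all(mask %in% c(0, 1))) stop_arg("`mask` must be binary")
  out <- image * mask
  attr(out, "levels") <- attr(image, "levels")
  out
}

#' Preprocessing configuration
#'
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 4).
#' @param voxel_mm Pixel pitch in mm (default 1, isotropic).
#' @param target_size Output dimensions, `c(rows, cols)` (default 224 x 224).
#' @param train_fraction Proportion of samples assigned to training (default 0.70).
#' @param seed RNG seed for the split.
#' @return A list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(fwhm_mm = 4, voxel_mm = 1,
                              target_size = c(224L, 224L),
                              train_fraction = 0.7, seed = NULL) {
  check_number(fwhm_mm, "fwhm_mm", lower = 0)
  check_number(voxel_mm, "voxel_mm")
  if (voxel_mm <= 0) stop_arg("`voxel_mm` must be positive")
  check_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_arg("`train_fraction` must lie strictly between 0 and 1")
  }
  if (length(target_size) == 1L) target_size <- rep(target_size, 2L)
  if (any(target_size < 1)) stop_arg("`target_size` must be positive")
  structure(list(fwhm_mm = fwhm_mm, voxel_mm = voxel_mm,
                 target_size = as.integer(target_size),
                 train_fraction = train_fraction, seed = seed),
            class = "preprocess_config")
}

#' Apply smoothing and resizing to one image
#'
#' Smoothing precedes resizing (recorded in the pipeline manifest).
#'
#' @param image Numeric matrix.
#' @param config A [preprocess_config()].
#' @return Preprocessed image matrix.
#' @export
preprocess_image <- function(image, config = preprocess_config()) {
  sigma <- fwhm_to_sigma(config$fwhm_mm, config$voxel_mm)
  out <- gaussian_smooth(image, sigma)
  resize_image(out, config$target_size, method = "bilinear")
}

#' Split a labeled dataset into train and test parts
#'
#' Produces a disjoint, exhaustive partition, stratified by class by default
#' so both splits preserve the class ratio within rounding. Deterministic
#' under `seed`.
#'
#' @param items List of samples. Labels are taken from `labels` if given,
#'   otherwise from each element's `$label`.
#' @param train_fraction Proportion assigned to training (default 0.7).
#' @param seed RNG seed.
#' @param stratified Preserve class proportions (default TRUE). Requires both
#'   classes present.
#' @param labels Optional explicit label vector (length of `items`).
#' @return List with `train`, `test` (sub-lists of `items`) and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_dataset <- function(items, train_fraction = 0.7, seed = NULL,
                          stratified = TRUE, labels = NULL) {
  if (length(items) < 2L) stop_arg("need at least 2 items to split")
  check_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_arg("`train_fraction` must lie strictly between 0 and 1")
  }
  check_flag(stratified, "stratified")
  if (is.null(labels)) {
    labels <- vapply(items, function(x) {
      if (is.list(x) && !is.null(x$label)) as.numeric(x$label) else NA_real_
    }, numeric(1))
  }
  n <- length(items)
  train_idx <- with_seed(seed, {
    if (stratified) {
      if (anyNA(labels)) stop_arg("stratified split requires labels on every item")
      y <- as_binary_labels(labels)
      if (length(unique(y)) < 2L) {
        stop_arg("stratified split requires both classes present")
      }
      # largest-remainder allocation: per-class counts sum to round(frac * n)
      classes <- sort(unique(y))
      sizes <- vapply(classes, function(cl) sum(y == cl), integer(1))
      quota <- train_fraction * sizes
      k <- pmax(1L, pmin(sizes - 1L, floor(quota)))
      total <- max(1L, min(n - 1L, round(train_fraction * n)))
      extra <- total - sum(k)
      if (extra > 0) {
        ord <- order(quota - floor(quota), decreasing = TRUE)
        for (ix in ord) {
          if (extra == 0) break
          if (k[ix] < sizes[ix] - 1L) { k[ix] <- k[ix] + 1L; extra <- extra - 1L }
        }
      }
      idx <- integer(0)
      for (ci in seq_along(classes)) {
        pool <- which(y == classes[ci])
        idx <- c(idx, pool[sample.int(length(pool), k[ci])])
      }
      sort(idx)
    } else {
      k <- round(train_fraction * n)
      k <- max(1L, min(n - 1L, k))
      sort(sample.int(n, k))
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = items[train_idx], test = items[test_idx],
       train_idx = train_idx, test_idx = test_idx)
}
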
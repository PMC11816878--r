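# Deep-feature backend contract and fusion with texture features.
#
# The backend abstracts the CNN stage: any object that maps a preprocessed
# image to a fixed-length real vector fits. The bundled reference backend is
# a seeded, untrained convolutional stack (random filters -> ReLU -> pooled
# moments -> fixed linear projection): deterministic, dependency-free, and
# honest about not being a trained network. A pretrained embedding can be
# plugged in through the same contract.

#' Construct the seeded convolutional feature backend
#'
#' Filters and the projection matrix are drawn once from a seeded normal
#' stream, so extraction is a pure function of (image, backend). With
#' `center = TRUE` the image mean is removed first, making features invariant
#' to constant intensity shifts.
#'
#' @param output_dim Features per image (default 20, matching the size of a
#'   deep half of a fused 40-feature set).
#' @param n_filters Number of convolution filters (default 8).
#' @param kernel_size Square filter side (default 3).
#' @param seed Seed for the filter/projection draw (default 42).
#' @param center Remove the image mean before convolution (default TRUE).
#' @return A list of class `"feature_backend"` with fields `name`,
#'   `output_dim`, `deterministic`, plus the drawn weights.
#' @export
seeded_stack_backend <- function(output_dim = 20L, n_filters = 8L,
                                 kernel_size = 3L, seed = 42L, center = TRUE) {
  check_number(output_dim, "output_dim", lower = 1)
  check_number(n_filters, "n_filters", lower = 1)
  check_number(kernel_size, "kernel_size", lower = 2)
  check_flag(center, "center")
  pooled_dim <- 2L * as.integer(n_filters)  # mean + sd per filter map
  wts <- with_seed(seed, {
    list(
      filters = lapply(seq_len(n_filters), function(i) {
        matrix(stats::rnorm(kernel_size^2), kernel_size, kernel_size)
      }),
      projection = matrix(stats::rnorm(output_dim * pooled_dim) /
                            sqrt(pooled_dim), output_dim, pooled_dim)
    )
  })
  structure(list(name = "seeded_stack", output_dim = as.integer(output_dim),
                 deterministic = TRUE, n_filters = as.integer(n_filters),
                 kernel_size = as.integer(kernel_size), seed = seed,
                 center = center, filters = wts$filters,
                 projection = wts$projection),
            class = "feature_backend")
}

# Valid 2-D convolution (correlation) of `img` with small kernel `k`.
conv2d_valid <- function(img, k) {
  kr <- nrow(k); kc <- ncol(k)
  nr <- nrow(img) - kr + 1L; nc <- ncol(img) - kc + 1L
  if (nr < 1L || nc < 1L) stop_arg("image smaller than the convolution kernel")
  out <- matrix(0, nr, nc)
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      out <- out + k[a, b] * img[a:(a + nr - 1L), b:(b + nc - 1L)]
    }
  }
  out
}

#' Extract deep features from one image
#'
#' Normalizes intensities to `[0, 1]`, optionally removes the mean, applies
#' each backend filter (valid convolution + ReLU), pools each response map to
#' its mean and standard deviation, and projects the pooled vector to
#' `output_dim` features with the backend's fixed linear map.
#'
#' @param image Grayscale image (any size larger than the kernel).
#' @param backend A [seeded_stack_backend()].
#' @return Named numeric vector of length `backend$output_dim`
#'   (`deep:f01 ...`).
#' @export
extract_deep_features <- function(image, backend = seeded_stack_backend()) {
  if (!inherits(backend, "feature_backend")) {
    stop_arg("`backend` must be a feature_backend")
  }
  x <- unclass(image) / (image_levels(image) - 1)
  if (backend$center) x <- x - mean(x)
  pooled <- numeric(0)
  for (f in backend$filters) {
    resp <- pmax(conv2d_valid(x, f), 0)
    pooled <- c(pooled, mean(resp), stats::sd(resp))
  }
  v <- as.numeric(backend$projection %*% pooled)
  names(v) <- sprintf("deep:f%02d", seq_along(v))
  v
}

#' Fuse deep and texture feature vectors
#'
#' Concatenates deep-then-texture, preserving provenance-tagged names
#' (`deep:*` then `glcm:*`). Either argument may be empty.
#'
#' @param deep Named numeric vector (finite).
#' @param texture Named numeric vector (finite).
#' @return Named numeric vector of length `length(deep) + length(texture)`.
#' @export
fuse_features <- function(deep, texture = numeric(0)) {
  if (length(deep) && any(!is.finite(deep))) stop_arg("`deep` has non-finite entries")
  if (length(texture) && any(!is.finite(texture))) {
    stop_arg("`texture` has non-finite entries")
  }
  out <- c(deep, texture)
  if (anyDuplicated(names(out))) stop_arg("fused feature names must be unique")
  out
}

#' Fit per-column standardization statistics on a training matrix
#'
#' Mean and standard deviation per column, a pure function of the training
#' split. Constant columns get sd 1 so standardization leaves them centered
#' but unscaled.
#'
#' @param x Numeric matrix (training rows x features).
#' @return List of class `"feature_standardizer"` with `mean`, `sd`.
#' @export
fit_standardizer <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  structure(list(mean = m, sd = s), class = "feature_standardizer")
}

#' Apply fitted standardization statistics to a matrix
#'
#' @param x Numeric matrix with the columns the standardizer was fit on.
#' @param stats_ A [fit_standardizer()] result.
#' @return Standardized matrix.
#' @export
apply_standardizer <- function(x, stats_) {
  if (!inherits(stats_, "feature_standardizer")) {
    stop_arg("`stats_` must come from fit_standardizer()")
  }
  sweep(sweep(x, 2, stats_$mean, "-"), 2, stats_$sd, "/")
}

#' Build a fused feature table from a labeled image dataset
#'
#' Runs preprocessing, deep extraction, and texture extraction on each image
#' and returns the fused table (unstandardized; fit a standardizer on the
#' training split downstream).
#'
#' @param dataset List of `list(image=, label=)` as from
#'   [make_image_dataset()].
#' @param backend A [seeded_stack_backend()].
#' @param glcm A [glcm_config()].
#' @param preprocess Optional [preprocess_config()]; `NULL` skips
#'   preprocessing.
#' @return Data frame of fused features plus a `label` column.
#' @export
extract_feature_table <- function(dataset, backend = seeded_stack_backend(),
                                  glcm = glcm_config(levels = 32L),
                                  preprocess = NULL) {
  rows <- lapply(dataset, function(item) {
    img <- item$image
    if (!is.null(preprocess)) img <- preprocess_image(img, preprocess)
    fuse_features(extract_deep_features(img, backend),
                  extract_texture_vector(img, glcm))
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  tab$label <- vapply(dataset, function(item) as.integer(item$label), integer(1))
  tab
}
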
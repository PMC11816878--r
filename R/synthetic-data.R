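# Synthetic fixtures: two-class textured images with controllable
# co-occurrence statistics, and feature tables with planted informative
# columns. Every generator is a pure function of (spec, seed).

#' Specification of one textured image class
#'
#' Images of a class are built by smoothing white Gaussian noise to a spatial
#' correlation length of `blob_scale` pixels, rescaling to unit spread,
#' mapping onto the gray-level range around `base_level`, adding pixel noise,
#' and quantizing. Larger `blob_scale` gives smoother texture, hence lower
#' GLCM contrast and higher homogeneity.
#'
#' @param label Binary class id (0 or 1).
#' @param base_level Mean intensity, within `[0, levels - 1]` of the images
#'   generated from the spec.
#' @param blob_scale Spatial correlation length in pixels (>= 1; `Inf` gives a
#'   flat field).
#' @param noise_sd Additive pixel noise spread in intensity units (>= 0).
#' @return A list of class `"texture_class_spec"`.
#' @export
texture_class_spec <- function(label, base_level, blob_scale, noise_sd = 0) {
  label <- as_binary_labels(label, "label")
  check_number(base_level, "base_level", lower = 0)
  check_number(blob_scale, "blob_scale", lower = 1, allow_inf = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  structure(list(label = label, base_level = base_level,
                 blob_scale = blob_scale, noise_sd = noise_sd),
            class = "texture_class_spec")
}

#' Generate one textured grayscale image
#'
#' @param spec A [texture_class_spec()].
#' @param size Image dimensions `c(rows, cols)` (scalar recycled; >= 8).
#' @param levels Gray-level count (>= 2).
#' @param seed RNG seed; the image is a pure function of (spec, size, levels,
#'   seed).
#' @return A [gray_image()] with intensities in `[0, levels - 1]`.
#' @export
make_textured_image <- function(spec, size = c(64L, 64L), levels = 32L,
                                seed = NULL) {
  if (!inherits(spec, "texture_class_spec")) {
    stop_arg("`spec` must be a texture_class_spec")
  }
  if (length(size) == 1L) size <- rep(size, 2L)
  if (length(size) != 2L || any(size < 8)) stop_arg("`size` must be >= 8 x 8")
  check_number(levels, "levels", lower = 2)
  if (spec$base_level > levels - 1) {
    stop_arg("`base_level` (%g) exceeds levels - 1 (%d)", spec$base_level, levels - 1)
  }
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  img <- with_seed(seed, {
    if (is.infinite(spec$blob_scale)) {
      field <- matrix(0, nr, nc)
    } else {
      field <- matrix(stats::rnorm(nr * nc), nr, nc)
      field <- gaussian_smooth(field, spec$blob_scale)
      s <- stats::sd(field)
      if (s > 0) field <- field / s
    }
    amp <- (levels - 1) / 5  # texture amplitude: ~±2.5 sd spans half the range
    out <- spec$base_level + amp * field
    if (spec$noise_sd > 0) {
      out <- out + stats::rnorm(nr * nc, sd = spec$noise_sd)
    }
    out
  })
  img <- pmin(pmax(round(img), 0), levels - 1)
  gray_image(img, levels = levels)
}

#' Generate a balanced two-class image dataset
#'
#' @param n_per_class Images per class (>= 1).
#' @param specs List of exactly two [texture_class_spec()]s with distinct
#'   labels.
#' @param size,levels Passed to [make_textured_image()].
#' @param seed RNG seed; the dataset is deterministic under it.
#' @return List of length `2 * n_per_class`; each element is a list with
#'   `image` and `label`.
#' @export
make_image_dataset <- function(n_per_class, specs, size = c(64L, 64L),
                               levels = 32L, seed = NULL) {
  check_number(n_per_class, "n_per_class", lower = 1)
  if (!is.list(specs) || length(specs) != 2L ||
      !all(vapply(specs, inherits, logical(1), "texture_class_spec"))) {
    stop_arg("`specs` must be a list of exactly two texture_class_spec objects")
  }
  if (specs[[1]]$label == specs[[2]]$label) {
    stop_arg("the two specs must carry distinct labels")
  }
  out <- vector("list", 2L * n_per_class)
  k <- 0L
  for (s in specs) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      out[[k]] <- list(
        image = make_textured_image(s, size = size, levels = levels,
                                    seed = derive_seed(seed, k)),
        label = s$label
      )
    }
  }
  out
}

#' Specification of a feature table with planted informative columns
#'
#' @param n_samples Number of rows (>= 2, balanced across classes).
#' @param n_features Number of feature columns (default 40, the size of a
#'   fused deep + texture set).
#' @param n_informative Number of class-informative columns
#'   (0 < n_informative <= n_features).
#' @param effect_size Standardized between-class mean shift of informative
#'   columns (unit within-class spread; >= 0).
#' @param seed RNG seed.
#' @return A list of class `"planted_table_spec"`.
#' @export
planted_table_spec <- function(n_samples, n_features = 40L, n_informative = 5L,
                               effect_size = 1, seed = NULL) {
  check_number(n_samples, "n_samples", lower = 2)
  check_number(n_features, "n_features", lower = 1)
  check_number(n_informative, "n_informative", lower = 1, upper = n_features)
  check_number(effect_size, "effect_size", lower = 0)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, seed = seed),
            class = "planted_table_spec")
}

#' Generate a feature table with a known informative subset
#'
#' Informative columns are Gaussian with class-dependent means (+/-
#' `effect_size / 2`, unit within-class spread); the remaining columns are
#' class-independent N(0, 1) noise. The identity of the planted columns is
#' recorded in the `informative` attribute for recovery tests.
#'
#' @param spec A [planted_table_spec()].
#' @return Data frame with columns `feature_000 .. feature_NNN` and `label`;
#'   attribute `informative` holds the planted column indices.
#' @export
make_planted_feature_table <- function(spec) {
  if (!inherits(spec, "planted_table_spec")) {
    stop_arg("`spec` must be a planted_table_spec")
  }
  n <- spec$n_samples; p <- spec$n_features
  y <- rep(c(0L, 1L), length.out = n)
  tab <- with_seed(spec$seed, {
    informative <- sort(sample.int(p, spec$n_informative))
    X <- matrix(stats::rnorm(n * p), n, p)
    shift <- ifelse(y == 1L, spec$effect_size / 2, -spec$effect_size / 2)
    X[, informative] <- X[, informative] + shift
    list(X = X, informative = informative)
  })
  df <- as.data.frame(tab$X)
  names(df) <- sprintf("feature_%03d", seq_len(p) - 1L)
  df$label <- y
  attr(df, "informative") <- tab$informative
  df
}
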
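# Gray-level co-occurrence matrices and their texture statistics.
#
# Angle-to-offset convention (rows increase downward):
#   0 deg -> ( 0, +d)    45 deg -> (-d, +d)
#  90 deg -> (-d,  0)   135 deg -> (-d, -d)

glcm_angles <- c(0L, 45L, 90L, 135L)

angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop_arg("`angle` must be one of 0, 45, 90, 135"))
}

#' GLCM configuration
#'
#' @param levels Gray-level count of the co-occurrence matrix (>= 2; images
#'   with more levels are uniformly re-binned). Default 256 covers the full
#'   8-bit range.
#' @param distances Pixel radii (>= 1); 1 or 2 are the usual choices.
#'   Default 1.
#' @param angles_deg Subset of \{0, 45, 90, 135\} degrees. Default all four.
#' @param symmetric Count each pixel pair in both directions (default TRUE,
#'   the dominant convention).
#' @param normalize Convert counts to probabilities (default TRUE).
#' @return A list of class `"glcm_config"`.
#' @export
glcm_config <- function(levels = 256L, distances = 1L,
                        angles_deg = c(0L, 45L, 90L, 135L),
                        symmetric = TRUE, normalize = TRUE) {
  check_number(levels, "levels", lower = 2)
  if (any(distances < 1)) stop_arg("`distances` must be >= 1")
  if (!all(angles_deg %in% glcm_angles)) {
    stop_arg("`angles_deg` must be drawn from {0, 45, 90, 135}")
  }
  check_flag(symmetric, "symmetric")
  check_flag(normalize, "normalize")
  structure(list(levels = as.integer(levels),
                 distances = as.integer(distances),
                 angles_deg = as.integer(angles_deg),
                 symmetric = symmetric, normalize = normalize),
            class = "glcm_config")
}

#' Re-bin an image to a smaller number of gray levels
#'
#' Uniform binning: level `i` of `levels_in` maps to
#' `floor(i * levels_out / levels_in)`.
#'
#' @param image Grayscale image matrix.
#' @param levels_out Target level count.
#' @param levels_in Source level count (default: the image's `levels`
#'   attribute, else 256).
#' @return A [gray_image()] with `levels_out` levels.
#' @export
quantize_image <- function(image, levels_out, levels_in = image_levels(image)) {
  check_number(levels_out, "levels_out", lower = 2)
  if (max(image) > levels_in - 1) {
    stop_arg("image intensities exceed levels_in - 1")
  }
  out <- floor(unclass(image) * levels_out / levels_in)
  out <- pmin(out, levels_out - 1)
  gray_image(out, levels = levels_out)
}

#' Compute a gray-level co-occurrence matrix for one offset
#'
#' Entry (i, j) counts ordered pixel pairs with reference level `i` and, at
#' displacement `(distance, angle)`, neighbor level `j`. With
#' `symmetric = TRUE` each pair is counted in both directions; with
#' `normalize = TRUE` counts become probabilities summing to 1.
#'
#' @param image Grayscale image with intensities in `[0, levels - 1]` (images
#'   with a larger `levels` attribute are re-binned first).
#' @param config A [glcm_config()]; its `levels`, `symmetric` and `normalize`
#'   fields are used.
#' @param distance Pixel radius of the offset (default first of
#'   `config$distances`).
#' @param angle Angle in degrees from \{0, 45, 90, 135\} (default first of
#'   `config$angles_deg`).
#' @return A `levels x levels` matrix of class `"glcm"` with attributes
#'   `distance`, `angle`, `normalized`.
#' @export
compute_glcm <- function(image, config = glcm_config(),
                         distance = config$distances[1],
                         angle = config$angles_deg[1]) {
  L <- config$levels
  if (image_levels(image) > L || max(image) > L - 1) {
    image <- quantize_image(image, L)
  }
  img <- round(unclass(image))  # continuous intensities (e.g. post-smoothing) snap to levels
  d <- as.integer(distance)
  if (d < 1) stop_arg("`distance` must be >= 1")
  off <- angle_offset(angle, d)
  dr <- off[1]; dc <- off[2]
  nr <- nrow(img); nc <- ncol(img)
  r_lo <- max(1L, 1L - dr); r_hi <- min(nr, nr - dr)
  c_lo <- max(1L, 1L - dc); c_hi <- min(nc, nc - dc)
  if (r_lo > r_hi || c_lo > c_hi) {
    stop_arg("offset (d=%d, angle=%d) exceeds the image extent", d, angle)
  }
  r <- seq.int(r_lo, r_hi)
  cc <- seq.int(c_lo, c_hi)
  ref <- img[r, cc, drop = FALSE]
  nb <- img[r + dr, cc + dc, drop = FALSE]
  counts <- tabulate(ref * L + nb + 1L, nbins = L * L)
  p <- matrix(counts, L, L, byrow = TRUE)  # row index = reference level
  if (config$symmetric) p <- p + t(p)
  if (config$normalize) p <- p / sum(p)
  structure(p, class = "glcm", distance = d, angle = as.integer(angle),
            normalized = config$normalize)
}

#' Texture statistics of a normalized GLCM
#'
#' For probabilities `p(i, j)`:
#' energy `sum p^2`; contrast `sum (i - j)^2 p`; homogeneity
#' `sum p / (1 + |i - j|)`; correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` (0 when either marginal
#' is degenerate); entropy `-sum p log2 p` with `0 log 0 = 0`.
#'
#' @param glcm A normalized matrix from [compute_glcm()].
#' @return Named list with `energy`, `contrast`, `homogeneity`,
#'   `correlation`, `entropy`.
#' @export
glcm_statistics <- function(glcm) {
  p <- unclass(glcm)
  if (!isTRUE(attr(glcm, "normalized")) &&
      abs(sum(p) - 1) > 1e-9) {
    stop_arg("`glcm` must be normalized (entries summing to 1)")
  }
  L <- nrow(p)
  idx <- seq_len(L) - 1
  I <- matrix(idx, L, L)
  J <- t(I)
  D <- abs(I - J)
  energy <- sum(p^2)
  contrast <- sum(D^2 * p)
  homogeneity <- sum(p / (1 + D))
  pi_m <- rowSums(p); pj_m <- colSums(p)
  mu_i <- sum(idx * pi_m); mu_j <- sum(idx * pj_m)
  s_i <- sqrt(sum((idx - mu_i)^2 * pi_m))
  s_j <- sqrt(sum((idx - mu_j)^2 * pj_m))
  correlation <- if (s_i > 0 && s_j > 0) {
    (sum(I * J * p) - mu_i * mu_j) / (s_i * s_j)
  } else 0  # degenerate marginal: no linear dependence to measure
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  list(energy = energy, contrast = contrast, homogeneity = homogeneity,
       correlation = correlation, entropy = entropy)
}

glcm_stat_names <- c("energy", "contrast", "homogeneity", "correlation", "entropy")

#' Extract a named GLCM texture feature vector
#'
#' Concatenates the five statistics for every (distance, angle) combination
#' of the configuration, in the fixed order: distances in config order, then
#' angles in config order, then statistics (energy, contrast, homogeneity,
#' correlation, entropy). The default configuration (d = 1, four angles)
#' yields exactly 20 named features.
#'
#' @param image Grayscale image.
#' @param config A [glcm_config()] (normalization is forced on).
#' @return Named numeric vector; names follow `glcm:d<d>_a<angle>_<stat>`.
#' @export
extract_texture_vector <- function(image, config = glcm_config()) {
  config$normalize <- TRUE
  out <- numeric(0)
  for (d in config$distances) {
    for (a in config$angles_deg) {
      st <- glcm_statistics(compute_glcm(image, config, distance = d, angle = a))
      v <- unlist(st[glcm_stat_names])
      names(v) <- sprintf("glcm:d%d_a%d_%s", d, a, glcm_stat_names)
      out <- c(out, v)
    }
  }
  out
}
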
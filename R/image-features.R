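# Image features for texture prediction: mean CIELAB colour (L*, a*, b*)
# and grey-level co-occurrence (GLCM) contrast.
#
# Colour conversion is the CIE closed form: sRGB companding -> linear RGB
# -> XYZ (D65) -> L*a*b*.  "Contrast" is the standard GLCM statistic
# sum P(i,j) (i-j)^2 over a symmetric, normalized co-occurrence matrix,
# computed on the quantized L* channel and averaged over the offsets.

#' Convert an sRGB image to CIELAB
#'
#' Per-pixel sRGB -> XYZ (D65 white point) -> CIELAB.  White maps to
#' `L* = 100, a* = b* = 0` and black to `L* = 0`.
#'
#' @param img Numeric array `[h, w, 3]` of sRGB values in `[0, 1]`.
#' @return Array `[h, w, 3]` with channels L*, a*, b*.
#' @export
rgb_to_lab <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  v <- matrix(img, ncol = 3L)
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3L, byrow = TRUE)
  xyz <- lin %*% t(m)
  # D65 reference white
  ref <- c(0.95047, 1.00000, 1.08883)
  fr <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- fr(xyz[, 1L] / ref[1L])
  fy <- fr(xyz[, 2L] / ref[2L])
  fz <- fr(xyz[, 3L] / ref[3L])
  array(c(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz)), dim = dim(img))
}

#' Mean CIELAB colour of an image
#'
#' @param lab Array `[h, w, 3]` from [rgb_to_lab()].
#' @return Named vector `c(L_star, a_star, b_star)`.
#' @export
mean_lab <- function(lab) {
  stopifnot(length(dim(lab)) == 3L, dim(lab)[3L] == 3L)
  c(L_star = mean(lab[, , 1L]),
    a_star = mean(lab[, , 2L]),
    b_star = mean(lab[, , 3L]))
}

#' Grey-level co-occurrence contrast
#'
#' Quantizes a greyscale image in `[0, 1]` to `levels` bins, accumulates a
#' symmetric normalized co-occurrence matrix per offset, and returns the
#' contrast `sum P(i,j) (i-j)^2` averaged over the offsets.  A constant
#' image has contrast 0; a one-pixel checkerboard of the extreme levels has
#' contrast `(levels - 1)^2`.
#'
#' @param gray Numeric matrix in `[0, 1]` (use `L*/100` to stay in one
#'   colour space).
#' @param levels Number of quantization bins (default 16).
#' @param offsets List of `c(drow, dcol)` displacement vectors (default
#'   horizontal and vertical neighbours).
#' @return Contrast, >= 0.
#' @export
glcm_contrast <- function(gray, levels = 16L,
                          offsets = list(c(0L, 1L), c(1L, 0L))) {
  stopifnot(is.matrix(gray))
  if (any(!is.finite(gray)) || any(gray < 0) || any(gray > 1)) {
    abort("gray values must be finite and in [0, 1]", "extrurtd_domain_error")
  }
  check_number(levels, "levels", lower = 2)
  q <- pmin(floor(gray * levels), levels - 1L)
  n <- nrow(q)
  m <- ncol(q)
  per_offset <- vapply(offsets, function(off) {
    dr <- abs(as.integer(off[1L]))
    dc <- abs(as.integer(off[2L]))
    if ((dr == 0L && dc == 0L) || dr >= n || dc >= m) {
      abort(sprintf("offset (%d, %d) does not fit a %d x %d image",
                    off[1L], off[2L], n, m), "extrurtd_domain_error")
    }
    a <- q[seq_len(n - dr), seq_len(m - dc)]
    b <- q[(1L + dr):n, (1L + dc):m]
    # (i-j)^2 is symmetric, so the symmetrized normalized matrix gives the
    # plain mean of squared level differences over the offset pairs.
    mean((a - b)^2)
  }, numeric(1))
  mean(per_offset)
}

#' Feature-extraction configuration
#'
#' @param size Working resolution `c(height, width)` passed to
#'   [load_and_standardize()]; `NULL` keeps the native resolution.
#' @param roi Optional crop `c(row, col, nrow, ncol)`.
#' @param glcm_levels Quantization levels for [glcm_contrast()].
#' @param glcm_offsets Offsets for [glcm_contrast()].
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(size = c(480, 640), roi = NULL,
                           glcm_levels = 16L,
                           glcm_offsets = list(c(0L, 1L), c(1L, 0L))) {
  structure(list(size = size, roi = roi, glcm_levels = glcm_levels,
                 glcm_offsets = glcm_offsets),
            class = "feature_config")
}

#' Extract the four image features from a photograph
#'
#' Loads and standardizes the image, converts to CIELAB, and returns the
#' mean L*, a*, b* plus GLCM contrast of the L* channel.
#'
#' @param path Image path (PNM).
#' @param config A [feature_config()].
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return One-row data frame `sample_id, L_star, a_star, b_star, contrast`.
#' @export
extract_features <- function(path, config = feature_config(),
                             sample_id = NULL) {
  stopifnot(inherits(config, "feature_config"))
  img <- load_and_standardize(path, roi = config$roi, size = config$size)
  lab <- rgb_to_lab(img)
  means <- mean_lab(lab)
  contrast <- glcm_contrast(pmax(pmin(lab[, , 1L] / 100, 1), 0),
                            levels = config$glcm_levels,
                            offsets = config$glcm_offsets)
  data.frame(
    sample_id = if (is.null(sample_id)) {
      tools::file_path_sans_ext(basename(path))
    } else {
      as.character(sample_id)
    },
    L_star = unname(means["L_star"]),
    a_star = unname(means["a_star"]),
    b_star = unname(means["b_star"]),
    contrast = contrast,
    stringsAsFactors = FALSE)
}

#' Extract features for every image in a directory
#'
#' @param dir Directory containing `.pgm`/`.ppm`/`.pnm` images.
#' @param config A [feature_config()].
#' @return Data frame with one row per image, ordered by file name.
#' @export
extract_features_dir <- function(dir, config = feature_config()) {
  files <- sort(list.files(dir, pattern = "\\.(pgm|ppm|pnm)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    abort(sprintf("no PNM images found in '%s'", dir), "extrurtd_io_error")
  }
  do.call(rbind, lapply(files, extract_features, config = config))
}
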
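# Synthetic image-feature / texture-attribute datasets and fixture images.
#
# Real data come from extrudates produced along a melt-temperature gradient:
# hotter runs brown more (L* drops, b* rises, a* stays green but creeps
# toward zero) and harden.  The generator reproduces that structure with a
# scalar "severity" latent u in [0, 1]: all four features are monotone in u
# plus measurement noise, and each texture attribute is a smooth monotone
# map of the features plus noise.  This is a test harness, not extrusion
# physics.

TEXTURE_ATTRIBUTES <- c("hardness", "stickiness", "chewiness",
                        "adhesiveness", "resilience", "cohesion",
                        "elasticity")

#' Specify a synthetic feature/texture dataset
#'
#' @param n_samples Number of samples (default 118, a realistic study
#'   size after outlier removal).
#' @param coefs Coefficients of the ground-truth map
#'   `base = alpha (100 - L*) + beta b*^2 + gamma contrast + delta a*`
#'   (named list `alpha, beta, gamma, delta`).
#' @param attr_scale,attr_offset Named vectors: each attribute equals
#'   `offset + scale * base` (+ noise), giving the seven attributes their
#'   own units and ranges.
#' @param noise_frac Attribute noise standard deviation as a fraction of
#'   each attribute's span over u in `[0, 1]` (default 0.02).
#' @param feature_noise_sd Measurement noise for `L*, a*, b*, contrast`.
#' @param seed Integer seed, or `NULL`.
#' @return An object of class `synth_dataset_spec`.
#' @export
synth_dataset_spec <- function(n_samples = 118L,
                               coefs = list(alpha = 1, beta = 0.05,
                                            gamma = 0.5, delta = 2),
                               attr_scale = c(hardness = 40, stickiness = 0.5,
                                              chewiness = 25,
                                              adhesiveness = 0.3,
                                              resilience = 0.004,
                                              cohesion = 0.005,
                                              elasticity = 0.005),
                               attr_offset = c(hardness = 1000,
                                               stickiness = 10,
                                               chewiness = 500,
                                               adhesiveness = 4,
                                               resilience = 0.1,
                                               cohesion = 0.3,
                                               elasticity = 0.4),
                               noise_frac = 0.02,
                               feature_noise_sd = c(L_star = 0.8,
                                                    a_star = 0.25,
                                                    b_star = 0.5,
                                                    contrast = 1.5),
                               seed = NULL) {
  check_number(n_samples, "n_samples", lower = 4)
  check_number(noise_frac, "noise_frac", lower = 0)
  stopifnot(all(TEXTURE_ATTRIBUTES %in% names(attr_scale)),
            all(TEXTURE_ATTRIBUTES %in% names(attr_offset)))
  structure(
    list(n_samples = as.integer(n_samples), coefs = coefs,
         attr_scale = attr_scale, attr_offset = attr_offset,
         noise_frac = noise_frac, feature_noise_sd = feature_noise_sd,
         seed = seed),
    class = "synth_dataset_spec")
}

# The ground-truth map from realized features to the dimensionless base
# response shared by all attributes.
synth_base_response <- function(spec, L, a, b, contrast) {
  with(spec$coefs,
       alpha * (100 - L) + beta * b^2 + gamma * contrast + delta * a)
}

#' Generate a synthetic feature/texture dataset
#'
#' Features are monotone in a latent severity `u ~ U(0, 1)` with small
#' measurement noise, respecting the empirical signs (`a* < 0`, `b* > 0`,
#' `L*` decreasing in severity).  Each attribute is its affine rescaling of
#' the shared nonlinear base response of the *realized* features, plus
#' Gaussian noise.  Deterministic per seed.
#'
#' @param spec A [synth_dataset_spec()].
#' @return Data frame with `sample_id`, the four features and the seven
#'   texture attributes.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_dataset_spec"))
  n <- spec$n_samples
  fsd <- spec$feature_noise_sd
  with_seed(spec$seed, {
    u <- stats::runif(n)
    L <- pmin(pmax(75 - 35 * u + stats::rnorm(n, 0, fsd[["L_star"]]), 0), 100)
    a <- pmin(-8 + 5 * u + stats::rnorm(n, 0, fsd[["a_star"]]), -0.05)
    b <- pmax(14 + 12 * u + stats::rnorm(n, 0, fsd[["b_star"]]), 0.05)
    contrast <- pmax(15 + 50 * u + stats::rnorm(n, 0, fsd[["contrast"]]), 0)
    base <- synth_base_response(spec, L, a, b, contrast)
    # span of the noiseless base response over u in [0, 1]
    span <- diff(range(synth_base_response(
      spec, c(75, 40), c(-8, -3), c(14, 26), c(15, 65))))
    out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                      L_star = L, a_star = a, b_star = b,
                      contrast = contrast, stringsAsFactors = FALSE)
    for (attr in TEXTURE_ATTRIBUTES) {
      sc <- spec$attr_scale[[attr]]
      noise_sd <- spec$noise_frac * abs(sc) * span
      out[[attr]] <- spec$attr_offset[[attr]] + sc * base +
        stats::rnorm(n, 0, noise_sd)
    }
    out
  })
}

#' Generate fixture images with analytically known features
#'
#' Writes flat-colour tiles (GLCM contrast exactly 0; mean Lab equal to
#' the tile colour's Lab) and black/white one-pixel checkerboards (contrast
#' exactly `(levels - 1)^2`; mean Lab `(50, 0, 0)`) as plain-text PPM
#' files, together with a `truth.csv` of the expected feature values.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_flat Number of flat tiles (default 6).
#' @param n_checker Number of checkerboard tiles (default 2).
#' @param tile Tile size `c(height, width)`; both even so the checkerboard
#'   is exactly half black.
#' @param glcm_levels Quantization levels assumed for the contrast truth.
#' @param seed Integer seed for the flat-tile colours.
#' @return Invisibly, the truth data frame (`sample_id`, expected
#'   `L_star, a_star, b_star, contrast`, `file`).
#' @export
generate_fixture_images <- function(out_dir, n_flat = 6L, n_checker = 2L,
                                    tile = c(64L, 64L), glcm_levels = 16L,
                                    seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stopifnot(tile[1L] %% 2L == 0L, tile[2L] %% 2L == 0L)
  h <- tile[1L]
  w <- tile[2L]
  rows <- list()
  with_seed(seed, {
    for (i in seq_len(n_flat)) {
      rgb8 <- sample(0:255, 3L, replace = TRUE)
      img <- array(rep(rgb8 / 255, each = h * w), dim = c(h, w, 3L))
      id <- sprintf("flat_%02d", i)
      file <- file.path(out_dir, paste0(id, ".ppm"))
      write_pnm(img, file)
      lab <- rgb_to_lab(array(rgb8 / 255, dim = c(1L, 1L, 3L)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, L_star = lab[1L, 1L, 1L], a_star = lab[1L, 1L, 2L],
        b_star = lab[1L, 1L, 3L], contrast = 0, file = file,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_checker)) {
      checker <- outer(seq_len(h), seq_len(w),
                       function(r, c) (r + c) %% 2L)
      img <- array(rep(checker, 3L), dim = c(h, w, 3L))
      id <- sprintf("checker_%02d", i)
      file <- file.path(out_dir, paste0(id, ".ppm"))
      write_pnm(img, file)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = id, L_star = 50, a_star = 0, b_star = 0,
        contrast = (glcm_levels - 1L)^2, file = file,
        stringsAsFactors = FALSE)
    }
  })
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(truth)
}
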
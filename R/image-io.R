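# Portable anymap (PGM/PPM) image input/output and standardization.
#
# The imaging pipeline consumes 8-bit photographs.  PNM is the supported
# container (ASCII P2/P3 and binary P5/P6, maxval <= 255): it is lossless,
# trivially diffable, and requires no external decoding library.  Images
# are represented as numeric arrays `[height, width, 3]` with values in
# [0, 1]; greyscale files are expanded to three equal channels.

#' Read a PGM/PPM image
#'
#' Supports the plain (P2/P3) and raw (P5/P6) variants with maxval up to
#' 255.  Comment lines (`#`) in the header are honoured.
#'
#' @param path Path to the image file.
#' @return Numeric array `[height, width, 3]`, values in `[0, 1]`.
#' @export
read_pnm <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read image '%s'", path), "extrurtd_io_error")
  }
  size <- file.info(path)$size
  bytes <- readBin(path, "raw", n = size)
  pos <- 1L
  ws <- as.raw(c(9L, 10L, 13L, 32L))
  next_token <- function() {
    repeat {
      while (pos <= size && bytes[pos] %in% ws) pos <<- pos + 1L
      if (pos <= size && bytes[pos] == as.raw(35L)) {
        while (pos <= size && !(bytes[pos] %in% as.raw(c(10L, 13L)))) {
          pos <<- pos + 1L
        }
      } else break
    }
    if (pos > size) abort("truncated PNM header", "extrurtd_io_error")
    start <- pos
    while (pos <= size && !(bytes[pos] %in% ws)) pos <<- pos + 1L
    rawToChar(bytes[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    abort(sprintf("'%s' is not a supported PNM file (magic '%s')",
                  path, magic), "extrurtd_io_error")
  }
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(width) || is.na(height) || width < 1L || height < 1L) {
    abort("zero-area or malformed PNM image", "extrurtd_io_error")
  }
  if (is.na(maxval) || maxval < 1L || maxval > 255L) {
    abort("only 8-bit PNM images (maxval <= 255) are supported",
          "extrurtd_io_error")
  }
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  n_vals <- width * height * channels
  vals <- if (magic %in% c("P5", "P6")) {
    pos <- pos + 1L  # single whitespace byte after maxval
    if (size - pos + 1L < n_vals) {
      abort("truncated PNM pixel data", "extrurtd_io_error")
    }
    as.integer(bytes[pos:(pos + n_vals - 1L)])
  } else {
    v <- suppressWarnings(
      scan(text = rawToChar(bytes[pos:size]), what = integer(),
           quiet = TRUE))
    if (length(v) < n_vals || anyNA(v)) {
      abort("truncated or malformed PNM pixel data", "extrurtd_io_error")
    }
    v[seq_len(n_vals)]
  }
  vals <- vals / maxval
  if (channels == 3L) {
    img <- aperm(array(vals, dim = c(3L, width, height)), c(3L, 2L, 1L))
  } else {
    gray <- t(array(vals, dim = c(width, height)))
    img <- array(rep(gray, 3L), dim = c(height, width, 3L))
  }
  img
}

#' Write an image as PPM
#'
#' @param img Numeric array `[height, width, 3]` (or matrix, written as
#'   grey RGB) with values in `[0, 1]`.
#' @param path Output path.
#' @param ascii Write the plain-text `P3` variant (default); `FALSE` writes
#'   binary `P6`.
#' @return The path, invisibly.
#' @export
write_pnm <- function(img, path, ascii = TRUE) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  if (any(!is.finite(img)) || any(img < 0) || any(img > 1)) {
    abort("image values must be finite and in [0, 1]", "extrurtd_domain_error")
  }
  h <- dim(img)[1L]
  w <- dim(img)[2L]
  vals <- as.integer(round(aperm(img, c(3L, 2L, 1L)) * 255))
  write_atomic(path, function(tmp) {
    if (ascii) {
      con <- file(tmp, "w")
      on.exit(close(con))
      writeLines(c("P3", paste(w, h), "255"), con)
      writeLines(paste(vals, collapse = " "), con)
    } else {
      con <- file(tmp, "wb")
      on.exit(close(con))
      writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
      writeBin(as.raw(vals), con)
    }
  })
}

# Nearest-neighbour resize to `h` x `w`.
resize_nearest <- function(img, h, w) {
  rows <- pmin(dim(img)[1L], floor((seq_len(h) - 0.5) * dim(img)[1L] / h) + 1L)
  cols <- pmin(dim(img)[2L], floor((seq_len(w) - 0.5) * dim(img)[2L] / w) + 1L)
  img[rows, cols, , drop = FALSE]
}

#' Load an image and standardize it for feature extraction
#'
#' Reads a PNM image, optionally crops a rectangular region of interest,
#' and resizes (nearest neighbour) to the working resolution.  Values are
#' returned in `[0, 1]`.
#'
#' @param path Image path.
#' @param roi Optional crop, `c(row, col, nrow, ncol)` (1-based).
#' @param size Target `c(height, width)` (default `c(480, 640)`), or
#'   `NULL` to keep the native resolution.
#' @return Numeric array `[height, width, 3]`.
#' @export
load_and_standardize <- function(path, roi = NULL, size = c(480, 640)) {
  img <- read_pnm(path)
  if (!is.null(roi)) {
    roi <- as.integer(roi)
    if (length(roi) != 4L || any(roi < 1L) ||
        roi[1L] + roi[3L] - 1L > dim(img)[1L] ||
        roi[2L] + roi[4L] - 1L > dim(img)[2L]) {
      abort("roi = c(row, col, nrow, ncol) must lie inside the image",
            "extrurtd_domain_error")
    }
    img <- img[roi[1L]:(roi[1L] + roi[3L] - 1L),
               roi[2L]:(roi[2L] + roi[4L] - 1L), , drop = FALSE]
  }
  if (!is.null(size)) {
    size <- as.integer(size)
    if (length(size) != 2L || any(size < 1L)) {
      abort("size must be c(height, width)", "extrurtd_domain_error")
    }
    img <- resize_nearest(img, size[1L], size[2L])
  }
  img
}
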
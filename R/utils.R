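# Internal input checks shared across the raster operations.  Images are
# plain base-R objects: an RGB image is an H x W x 3 array of intensities in
# [0, 255], a grayscale image an H x W matrix on the same scale, a binary
# mask a logical matrix, and a label map an integer matrix with 0 for
# background/ridge pixels.

assert_rgb <- function(img, arg = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    stop(sprintf("`%s` must be an H x W x 3 array (RGB image)", arg),
         call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop(sprintf("`%s` must hold intensities in [0, 255]", arg),
         call. = FALSE)
  }
  invisible(img)
}

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix (grayscale image)", arg),
         call. = FALSE)
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    stop(sprintf("`%s` must hold intensities in [0, 255]", arg),
         call. = FALSE)
  }
  invisible(img)
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask) || anyNA(mask)) {
    stop(sprintf("`%s` must be a logical matrix without NA", arg),
         call. = FALSE)
  }
  invisible(mask)
}

assert_labels <- function(labels, arg = "labels") {
  if (!is.matrix(labels) || !is.numeric(labels) || anyNA(labels) ||
      any(labels < 0) || any(labels != round(labels))) {
    stop(sprintf("`%s` must be a matrix of non-negative integers", arg),
         call. = FALSE)
  }
  invisible(labels)
}

assert_connectivity <- function(connectivity) {
  if (!connectivity %in% c(4L, 8L)) {
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  }
  as.integer(connectivity)
}

as_int_matrix <- function(img) {
  storage.mode(img) <- "integer"
  img
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)
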
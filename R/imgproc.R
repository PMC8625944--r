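#' Extract the green channel of an RGB image
#'
#' Fluorescent cells emit in the green band, so the pipeline works on the
#' green channel alone once the raw RGB capture has been loaded.
#'
#' @param img An `H x W x 3` array of intensities in `[0, 255]`.
#' @return An `H x W` matrix (the second channel), same scale.
#' @examples
#' img <- array(0, c(4, 4, 3)); img[, , 2] <- 255
#' extract_green(img)[1, 1]
#' @export
extract_green <- function(img) {
  assert_rgb(img)
  img[, , 2, drop = TRUE]
}

#' Resize an image so its longer side matches a target
#'
#' Bilinear resampling that preserves the aspect ratio to the nearest pixel.
#' Working at a fixed standard size keeps per-image quantities (percent
#' areas, pixel thresholds) comparable across captures.
#'
#' @param img RGB array or grayscale matrix, intensities in `[0, 255]`.
#' @param max_side Target length in pixels of the longer side (>= 16).
#' @return Image of the same kind with its longer side equal to `max_side`.
#' @export
resize_to_standard <- function(img, max_side = 1024) {
  if (max_side < 16) stop("`max_side` must be >= 16", call. = FALSE)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  if (max(h, w) == max_side) return(img)
  scale <- max_side / max(h, w)
  if (h >= w) {
    nh <- as.integer(max_side)
    nw <- max(1L, as.integer(round(w * scale)))
  } else {
    nw <- as.integer(max_side)
    nh <- max(1L, as.integer(round(h * scale)))
  }
  resize_plane <- function(m) {
    # map output pixel centers onto input pixel centers
    sr <- (seq_len(nh) - 0.5) * h / nh + 0.5
    sc <- (seq_len(nw) - 0.5) * w / nw + 0.5
    r0 <- pmin(pmax(floor(sr), 1), h); r1 <- pmin(r0 + 1, h)
    c0 <- pmin(pmax(floor(sc), 1), w); c1 <- pmin(c0 + 1, w)
    fr <- pmin(pmax(sr - r0, 0), 1)
    fc <- pmin(pmax(sc - c0, 0), 1)
    top <- m[r0, c0, drop = FALSE] * (1 - fc)[col(matrix(0, nh, nw))] +
      m[r0, c1, drop = FALSE] * fc[col(matrix(0, nh, nw))]
    bot <- m[r1, c0, drop = FALSE] * (1 - fc)[col(matrix(0, nh, nw))] +
      m[r1, c1, drop = FALSE] * fc[col(matrix(0, nh, nw))]
    out <- top * (1 - fr) + bot * fr
    clamp8(round(out))
  }
  if (length(d) == 3L) {
    out <- array(0, c(nh, nw, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- resize_plane(img[, , k])
    out
  } else {
    resize_plane(img)
  }
}

#' Median filter
#'
#' Rank-order denoising that removes impulse noise while keeping edges,
#' run before any contrast adjustment. Edges are handled by replicating
#' border pixels.
#'
#' @param img Grayscale matrix, intensities in `[0, 255]`.
#' @param window Odd window side length in pixels (>= 3).
#' @return Filtered grayscale matrix.
#' @export
median_filter <- function(img, window = 3) {
  assert_gray(img)
  if (window %% 2 != 1 || window < 3) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  out <- cpp_median_filter(as_int_matrix(round(img)), as.integer(window))
  storage.mode(out) <- "double"
  out
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The image is divided into a grid of tiles; each tile is histogram
#' equalized with its histogram clipped at `clip_limit` (a fraction of the
#' tile's pixel count) and the clipped excess redistributed uniformly over
#' all 256 bins, which bounds the local contrast gain and keeps background
#' noise from being amplified. Pixel mappings are blended bilinearly
#' between the four nearest tile centers.
#'
#' With a single tile and `clip_limit = 1` the operation reduces to plain
#' global histogram equalization.
#'
#' @param img Grayscale matrix, intensities in `[0, 255]`.
#' @param clip_limit Clip fraction in `[0, 1]`; small values mean gentle
#'   enhancement.
#' @param tiles Integer vector `c(rows, cols)` of the tile grid.
#' @return Equalized grayscale matrix in `[0, 255]`.
#' @export
clahe <- function(img, clip_limit = 0.01, tiles = c(8, 8)) {
  assert_gray(img)
  if (clip_limit < 0 || clip_limit > 1) {
    stop("`clip_limit` must lie in [0, 1]", call. = FALSE)
  }
  tiles <- as.integer(tiles)
  if (length(tiles) != 2L || any(tiles < 1)) {
    stop("`tiles` must be two positive integers", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  tr <- min(tiles[1], h); tc <- min(tiles[2], w)
  vals <- as_int_matrix(round(img))
  row_tile <- pmin(ceiling(seq_len(h) / (h / tr)), tr)
  col_tile <- pmin(ceiling(seq_len(w) / (w / tc)), tc)

  luts <- array(0, c(tr, tc, 256))
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (i in seq_len(tr)) centers_r[i] <- mean(which(row_tile == i))
  for (j in seq_len(tc)) centers_c[j] <- mean(which(col_tile == j))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      v <- vals[row_tile == i, col_tile == j]
      n <- length(v)
      hst <- tabulate(v + 1L, nbins = 256)
      clip <- max(1, round(clip_limit * n))
      excess <- sum(pmax(hst - clip, 0))
      hst <- pmin(hst, clip) + excess / 256
      luts[i, j, ] <- round(255 * cumsum(hst) / n)
    }
  }

  # bilinear blend of tile mappings, clamped at the border tiles
  ri <- findInterval(seq_len(h), centers_r)
  r0 <- pmin(pmax(ri, 1), tr); r1 <- pmin(r0 + 1, tr)
  fr <- ifelse(r1 > r0,
               (seq_len(h) - centers_r[r0]) / (centers_r[r1] - centers_r[r0]),
               0)
  fr <- pmin(pmax(fr, 0), 1)
  ci <- findInterval(seq_len(w), centers_c)
  c0 <- pmin(pmax(ci, 1), tc); c1 <- pmin(c0 + 1, tc)
  fc <- ifelse(c1 > c0,
               (seq_len(w) - centers_c[c0]) / (centers_c[c1] - centers_c[c0]),
               0)
  fc <- pmin(pmax(fc, 0), 1)

  vi <- vals + 1L
  gather <- function(rt, ct) {
    # LUT lookup for tile (rt[r], ct[c]) applied to every pixel
    idx <- rt[row(vi)] + (ct[col(vi)] - 1L) * tr + (vi - 1L) * (tr * tc)
    matrix(luts[idx], h, w)
  }
  top <- gather(r0, c0) * (1 - fc)[col(vi)] + gather(r0, c1) * fc[col(vi)]
  bot <- gather(r1, c0) * (1 - fc)[col(vi)] + gather(r1, c1) * fc[col(vi)]
  out <- top * (1 - fr)[row(vi)] + bot * fr[row(vi)]
  clamp8(round(out))
}

#' Otsu threshold
#'
#' Selects the threshold maximizing the between-class variance
#' \deqn{\sigma_B^2(k) = \frac{(m_G P_1(k) - m(k))^2}{P_1(k)(1 - P_1(k))}}
#' where \eqn{P_1(k)} is the cumulative probability of levels `<= k`,
#' \eqn{m(k)} the cumulative mean and \eqn{m_G} the global mean. When
#' several levels attain the maximum, the mean of the maximizing set
#' (rounded down) is returned.
#'
#' @param img Grayscale matrix with at least two distinct levels.
#' @return Integer threshold level in `[0, 255]`.
#' @export
otsu_threshold <- function(img) {
  assert_gray(img)
  vals <- as.integer(round(img))
  hst <- tabulate(vals + 1L, nbins = 256)
  n <- sum(hst)
  p <- hst / n
  if (sum(p > 0) < 2) {
    stop("image is constant: Otsu threshold undefined", call. = FALSE)
  }
  P1 <- cumsum(p)
  m <- cumsum((0:255) * p)
  mG <- m[256]
  valid <- P1 > 0 & P1 < 1
  sigma <- rep(-Inf, 256)
  sigma[valid] <- (mG * P1[valid] - m[valid])^2 / (P1[valid] * (1 - P1[valid]))
  ks <- which(sigma == max(sigma)) - 1L
  as.integer(floor(mean(ks)))
}

#' Binarize a grayscale image at a threshold
#'
#' Pixels strictly above `k` become foreground; pixels at or below it are
#' background.
#'
#' @param img Grayscale matrix.
#' @param k Threshold level in `[0, 255]`.
#' @return Logical foreground mask.
#' @export
binarize <- function(img, k) {
  assert_gray(img)
  if (k < 0 || k > 255) stop("`k` must lie in [0, 255]", call. = FALSE)
  img > k
}

#' Disk structuring element
#'
#' Odd-sized boolean stencil containing the lattice points within `radius`
#' of its center.
#'
#' @param radius Radius in pixels (>= 1).
#' @return A `(2 radius + 1)` square logical matrix.
#' @export
disk_se <- function(radius) {
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  r <- as.integer(radius)
  d <- seq(-r, r)
  outer(d, d, function(y, x) x^2 + y^2 <= radius^2)
}

#' Binary dilation and erosion
#'
#' Set-theoretic morphology on logical masks: dilation marks every
#' translation where the reflected structuring element hits the foreground,
#' erosion every translation where the element fits entirely inside it.
#' Pixels outside the raster count as background.
#'
#' @param mask Logical matrix.
#' @param se Structuring element as produced by [disk_se()] (any odd-sized
#'   logical matrix whose origin pixel is set).
#' @return Logical matrix of the same shape.
#' @export
dilate <- function(mask, se) {
  assert_mask(mask)
  assert_se(se)
  out <- cpp_dilate(mask, se)
  dimnames(out) <- NULL
  out
}

#' @rdname dilate
#' @export
erode <- function(mask, se) {
  assert_mask(mask)
  assert_se(se)
  out <- cpp_erode(mask, se)
  dimnames(out) <- NULL
  out
}

assert_se <- function(se) {
  if (!is.matrix(se) || !is.logical(se) ||
      nrow(se) %% 2 != 1 || ncol(se) %% 2 != 1) {
    stop("`se` must be an odd-sized logical matrix", call. = FALSE)
  }
  if (!se[(nrow(se) + 1) / 2, (ncol(se) + 1) / 2]) {
    stop("the origin pixel of `se` must be part of the footprint",
         call. = FALSE)
  }
  invisible(se)
}

#' Morphological opening and closing
#'
#' Opening (erosion then dilation) removes protrusions and specks smaller
#' than the structuring element; closing (dilation then erosion) fills
#' small gaps and smooths concavities. Opening is anti-extensive and
#' closing extensive: `opening(A) <= A <= closing(A)`. Closing is
#' computed on a background-padded canvas so the intermediate dilation is
#' not clipped at the raster border (the result never leaves the raster,
#' so cropping back is exact).
#'
#' @inheritParams dilate
#' @return Logical matrix of the same shape.
#' @export
opening <- function(mask, se) dilate(erode(mask, se), se)

#' @rdname opening
#' @export
closing <- function(mask, se) {
  assert_mask(mask)
  assert_se(se)
  r <- max(nrow(se), ncol(se)) %/% 2
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2 * r, W + 2 * r)
  pad[r + seq_len(H), r + seq_len(W)] <- mask
  out <- erode(dilate(pad, se), se)
  out[r + seq_len(H), r + seq_len(W), drop = FALSE]
}

#' Remove small connected components
#'
#' Foreground components with fewer than `min_area` pixels are deleted;
#' all others are untouched.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum surviving component area in pixels.
#' @param connectivity Pixel adjacency, 4 or 8.
#' @return Cleaned logical mask.
#' @export
area_open <- function(mask, min_area = 50, connectivity = 8) {
  assert_mask(mask)
  if (min_area < 1) stop("`min_area` must be >= 1", call. = FALSE)
  connectivity <- assert_connectivity(connectivity)
  lab <- cpp_label(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_area)
  out <- matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
  out
}

#' Fill small holes in a mask
#'
#' Equivalent to complementing the mask, removing small background
#' components, and complementing back: enclosed background pockets smaller
#' than `min_area` become foreground. Hole components use 4-connectivity,
#' complementary to the 8-connected foreground.
#'
#' @inheritParams area_open
#' @return Logical mask with small holes filled.
#' @export
fill_small_holes <- function(mask, min_area = 50) {
  assert_mask(mask)
  if (min_area < 1) stop("`min_area` must be >= 1", call. = FALSE)
  !area_open(!mask, min_area = min_area, connectivity = 4)
}

#' Label connected components
#'
#' Components are numbered 1, 2, ... in raster order of their first pixel.
#'
#' @inheritParams area_open
#' @return Integer label matrix; 0 marks background.
#' @export
label_components <- function(mask, connectivity = 8) {
  assert_mask(mask)
  connectivity <- assert_connectivity(connectivity)
  cpp_label(mask, connectivity)
}
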
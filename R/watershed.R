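# Marker-controlled watershed on the negated Euclidean distance transform.
#
# Surfaces are real-valued height rasters.  Before any flooding, minima
# detection or reconstruction, surfaces are quantized to 0.1 height units
# (integer decivalues) so that the ordering of near-equal floating point
# heights is reproducible across platforms.

QUANT <- 10  # surface quantization: 0.1-unit resolution

quantize_surface <- function(surface) {
  if (!is.matrix(surface) || !is.numeric(surface) || anyNA(surface)) {
    stop("`surface` must be a numeric matrix without NA", call. = FALSE)
  }
  q <- round(surface * QUANT)
  storage.mode(q) <- "integer"
  q
}

#' Euclidean distance transform
#'
#' Exact Euclidean distance from every pixel to the nearest background
#' (false) pixel of the mask. Background pixels map to 0.
#'
#' @param mask Logical matrix with at least one false pixel.
#' @return Numeric matrix of distances in pixel units.
#' @export
euclidean_distance_transform <- function(mask) {
  assert_mask(mask)
  if (all(mask)) {
    stop("mask has no background pixel: distances are undefined",
         call. = FALSE)
  }
  cpp_edt(mask)
}

#' Basin surface of a binary mask
#'
#' The negated distance transform: object interiors become catchment
#' basins whose depth equals the local half-thickness, so every blob of
#' the mask carries (at least) one regional minimum at its thickest point.
#'
#' @param mask Logical foreground mask.
#' @return Numeric surface (0 on background, negative inside objects).
#' @export
basin_surface <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  -euclidean_distance_transform(mask)
}

#' Extended minima (markers deeper than h)
#'
#' Computes the regional minima of the h-minima transform of the surface:
#' only minima whose depth relative to their lowest spill point exceeds
#' `h` survive, which suppresses the shallow minima responsible for
#' over-segmentation. Implemented by morphological reconstruction by
#' erosion of `surface + h` above `surface`.
#'
#' @param surface Numeric height matrix.
#' @param h Minima depth parameter (> 0), in surface height units.
#' @param connectivity Pixel adjacency, 4 or 8.
#' @return Logical marker mask; each connected component is one marker.
#' @export
extended_minima <- function(surface, h = 3, connectivity = 8) {
  if (h <= 0) stop("`h` must be > 0", call. = FALSE)
  connectivity <- assert_connectivity(connectivity)
  q <- quantize_surface(surface)
  qh <- as.integer(round(h * QUANT))
  hm <- cpp_reconstruct_erosion(q + qh, q, connectivity)
  inside <- matrix(TRUE, nrow(q), ncol(q))
  cpp_regional_minima(hm, connectivity, inside)
}

#' Impose minima on a surface
#'
#' Morphological reconstruction forcing the regional minima of the output
#' to be exactly the marker components; elsewhere the topography is
#' preserved up to the reconstruction. This is the step that converts the
#' watershed from an over-segmenting transform into a marker-controlled
#' one.
#'
#' @param surface Numeric height matrix.
#' @param markers Logical marker mask (non-empty).
#' @param connectivity Pixel adjacency, 4 or 8.
#' @return Numeric surface whose regional minima equal the markers.
#' @export
impose_minima <- function(surface, markers, connectivity = 8) {
  assert_mask(markers, "markers")
  if (!any(markers)) stop("`markers` must be non-empty", call. = FALSE)
  connectivity <- assert_connectivity(connectivity)
  q <- quantize_surface(surface)
  lo <- min(q) - 1L
  hi <- max(q) + 2L
  fm <- matrix(ifelse(markers, lo, hi), nrow(q), ncol(q))
  storage.mode(fm) <- "integer"
  g <- pmin(q + 1L, fm)
  storage.mode(g) <- "integer"
  out <- cpp_reconstruct_erosion(fm, g, connectivity)
  out / QUANT
}

#' Regional minima of a surface
#'
#' Connected plateaus all of whose neighbors are strictly higher.
#'
#' @inheritParams extended_minima
#' @param mask Optional logical matrix restricting the computation;
#'   pixels outside it are treated as infinitely high walls.
#' @return Logical matrix marking regional-minimum pixels.
#' @export
regional_minima <- function(surface, connectivity = 8, mask = NULL) {
  connectivity <- assert_connectivity(connectivity)
  q <- quantize_surface(surface)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(q), ncol(q))
  assert_mask(mask)
  cpp_regional_minima(q, connectivity, mask)
}

#' Watershed transform by priority flooding
#'
#' Every regional minimum of the surface seeds one catchment basin;
#' pixels flood in ascending height order (FIFO within a height level,
#' seeded in raster order, so the result is deterministic). A pixel whose
#' already-labeled neighbors belong to two or more different basins
#' becomes a watershed ridge and keeps label 0.
#'
#' @param surface Numeric height matrix, finite everywhere.
#' @param connectivity Pixel adjacency, 4 or 8.
#' @param mask Optional logical matrix; flooding is restricted to it and
#'   pixels outside keep label 0 (background).
#' @return Integer label matrix; 0 marks background and ridge pixels.
#' @export
watershed_transform <- function(surface, connectivity = 8, mask = NULL) {
  connectivity <- assert_connectivity(connectivity)
  q <- quantize_surface(surface)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(q), ncol(q))
  assert_mask(mask)
  minima <- cpp_regional_minima(q, connectivity, mask)
  seeds <- cpp_label(minima, connectivity)
  cpp_watershed(q, seeds, mask, connectivity)
}

#' Remove undersized labels
#'
#' Labels covering fewer than `min_area` pixels are set to 0; the
#' survivors are renumbered consecutively from 1 in raster order of their
#' first pixel.
#'
#' @param labels Integer label matrix.
#' @param min_area Minimum label area in pixels.
#' @return Relabeled integer matrix.
#' @export
remove_small_labels <- function(labels, min_area = 500) {
  assert_labels(labels)
  if (min_area < 1) stop("`min_area` must be >= 1", call. = FALSE)
  labels <- as_int_matrix(labels)
  mx <- max(labels)
  if (mx == 0L) return(labels)
  sizes <- tabulate(labels[labels > 0L], nbins = mx)
  keep <- sizes >= min_area
  # renumber survivors by raster order (row-major) of first occurrence
  h <- nrow(labels)
  raster <- (row(labels) - 1L) * ncol(labels) + col(labels)
  first <- rep(Inf, mx)
  pos <- labels > 0L
  first_seen <- tapply(raster[pos], labels[pos], min)
  first[as.integer(names(first_seen))] <- first_seen
  order_keep <- order(first)
  new_id <- integer(mx)
  nxt <- 0L
  for (l in order_keep) {
    if (keep[l]) {
      nxt <- nxt + 1L
      new_id[l] <- nxt
    }
  }
  out <- matrix(0L, h, ncol(labels))
  out[pos] <- new_id[labels[pos]]
  out
}
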
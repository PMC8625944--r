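# End-to-end composition: pre-processing -> mask -> marker-controlled
# watershed -> size filtering.

#' Pipeline configuration
#'
#' All stated defaults of the processing chain in one serializable record:
#' disk radius 3 for opening/closing, 50-pixel speck/hole filters, minima
#' depth 3, 8-connectivity, 500-pixel complete-cell filter and white-point
#' threshold 200.
#'
#' @param max_side Standard size of the longer image side after resizing.
#' @param median_window Median filter window (odd, >= 3).
#' @param clahe_clip CLAHE clip fraction in `[0, 1]`.
#' @param clahe_tiles CLAHE tile grid `c(rows, cols)`.
#' @param use_clahe Whether the equalized image feeds the Otsu stage
#'   (`TRUE`, default) or thresholding runs on the median-filtered green
#'   channel directly.
#' @param disk_radius Radius of the disk structuring element.
#' @param noise_area Minimum area (px) for foreground specks to survive.
#' @param hole_area Maximum hole area (px) that gets filled.
#' @param minima_depth `h` of the extended-minima transform (depth on the
#'   negated distance surface, in pixels).
#' @param connectivity Pixel adjacency, 4 or 8.
#' @param min_cell_area Minimum area (px) of an acknowledged complete cell.
#' @param white_threshold White-point intensity threshold.
#' @param criterion Ground-truth matching criterion, `"iou"` or `"exact"`.
#' @param iou_threshold IoU acceptance level.
#' @param seed Seed recorded for provenance of synthetic runs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(max_side = 1024, median_window = 3,
                            clahe_clip = 0.01, clahe_tiles = c(8, 8),
                            use_clahe = TRUE, disk_radius = 3,
                            noise_area = 50, hole_area = 50,
                            minima_depth = 3, connectivity = 8,
                            min_cell_area = 500, white_threshold = 200,
                            criterion = "iou", iou_threshold = 0.5,
                            seed = 1) {
  cfg <- list(max_side = max_side, median_window = median_window,
              clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
              use_clahe = isTRUE(use_clahe), disk_radius = disk_radius,
              noise_area = noise_area, hole_area = hole_area,
              minima_depth = minima_depth,
              connectivity = assert_connectivity(connectivity),
              min_cell_area = min_cell_area,
              white_threshold = white_threshold,
              criterion = match.arg(criterion, c("iou", "exact")),
              iou_threshold = iou_threshold, seed = as.integer(seed))
  stopifnot(cfg$max_side >= 16, cfg$median_window >= 3,
            cfg$median_window %% 2 == 1,
            cfg$clahe_clip >= 0, cfg$clahe_clip <= 1,
            length(cfg$clahe_tiles) == 2, all(cfg$clahe_tiles >= 1),
            cfg$disk_radius >= 1, cfg$noise_area >= 1, cfg$hole_area >= 1,
            cfg$minima_depth > 0, cfg$min_cell_area >= 1,
            cfg$white_threshold >= 0, cfg$white_threshold <= 255,
            cfg$iou_threshold > 0, cfg$iou_threshold <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Pre-process an RGB capture into a clean binary mask
#'
#' Applies, in order: resize to the standard size, green-channel
#' extraction, median filtering, contrast-limited adaptive histogram
#' equalization, Otsu thresholding, opening and closing with a disk,
#' removal of sub-`noise_area` specks and filling of sub-`hole_area`
#' holes. A constant (degenerate) image yields an empty mask with a
#' warning instead of an error.
#'
#' @param img RGB array (`H x W x 3`, intensities in `[0, 255]`).
#' @param config A [pipeline_config()].
#' @return List: `mask` (logical), `gray` (reference grayscale: resized,
#'   green, median-filtered — used for histograms and white points),
#'   `gray_enhanced` (after CLAHE), `threshold` (the Otsu level, or NA).
#' @export
preprocess <- function(img, config = pipeline_config()) {
  assert_rgb(img)
  img <- resize_to_standard(img, config$max_side)
  gray <- median_filter(extract_green(img), config$median_window)
  enhanced <- clahe(gray, config$clahe_clip, config$clahe_tiles)
  work <- if (config$use_clahe) enhanced else gray
  if (length(unique(as.vector(round(work)))) < 2) {
    warning("degenerate (constant) image: returning an empty mask")
    return(list(mask = matrix(FALSE, nrow(gray), ncol(gray)), gray = gray,
                gray_enhanced = enhanced, threshold = NA_integer_))
  }
  k <- otsu_threshold(work)
  se <- disk_se(config$disk_radius)
  mask <- binarize(work, k)
  mask <- closing(opening(mask, se), se)
  mask <- area_open(mask, config$noise_area, config$connectivity)
  mask <- fill_small_holes(mask, config$hole_area)
  list(mask = mask, gray = gray, gray_enhanced = enhanced, threshold = k)
}

#' Segment cells in a darkfield capture
#'
#' Full composition: pre-processing, basin surface (negated Euclidean
#' distance transform), extended-minima markers at depth `h`, minima
#' imposition, watershed flooding restricted to the foreground, and
#' removal of labels below the complete-cell area.
#'
#' @inheritParams preprocess
#' @return List: `labels` (integer label map), `mask`, `gray`,
#'   `threshold`, `n_cells`.
#' @export
segment_cells <- function(img, config = pipeline_config()) {
  pre <- preprocess(img, config)
  empty <- matrix(0L, nrow(pre$mask), ncol(pre$mask))
  if (!any(pre$mask) || all(pre$mask)) {
    if (all(pre$mask)) {
      warning("mask covers the whole raster: no background to flood from")
    }
    return(list(labels = empty, mask = pre$mask, gray = pre$gray,
                threshold = pre$threshold, n_cells = 0L))
  }
  surface <- basin_surface(pre$mask)
  markers <- extended_minima(surface, config$minima_depth,
                             config$connectivity)
  markers <- markers & pre$mask
  if (!any(markers)) {
    return(list(labels = empty, mask = pre$mask, gray = pre$gray,
                threshold = pre$threshold, n_cells = 0L))
  }
  imposed <- impose_minima(surface, markers, config$connectivity)
  labels <- watershed_transform(imposed, config$connectivity,
                                mask = pre$mask)
  labels <- remove_small_labels(labels, config$min_cell_area)
  list(labels = labels, mask = pre$mask, gray = pre$gray,
       threshold = pre$threshold, n_cells = max(labels))
}
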
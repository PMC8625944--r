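# Per-cell geometric descriptors and per-image stage quantification.
#
# Conventions (they matter for the dimensionless ratios):
#   * Perimeter is the length of the 8-connected outer boundary chain
#     through pixel centers, diagonal steps weighted sqrt(2).
#   * The convex hull (ConvexArea, ConvexPerimeter) is taken over pixel
#     corners, i.e. over the union of unit pixel squares, which guarantees
#     Area <= ConvexArea.
#   * Feret diameters (MaxDiameter, MinDiameter) are measured on pixel
#     centers: the largest pairwise distance and the minimal width over
#     supporting directions of the center hull.

# ---- boundary tracing -------------------------------------------------

# Moore-neighbor tracing of the outer boundary of a (possibly holey)
# 8-connected region given as a padded logical matrix.  Returns the closed
# chain of pixel centers (matrix with columns r, c) or NULL for a single
# pixel.  Chain length with sqrt(2)-weighted diagonals is the perimeter.
trace_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  start <- which(m)[1]
  sr <- (start - 1) %% H + 1
  sc <- (start - 1) %/% H + 1
  # clockwise Moore neighborhood starting west
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  cur <- c(sr, sc)
  dir <- 1L  # index into moves of the backtrack direction
  path_r <- integer(0); path_c <- integer(0)
  first_move <- NA_integer_
  max_steps <- 8L * H * W
  repeat {
    if (length(path_r) > max_steps) break  # safety net, never hit in practice
    found <- FALSE
    for (s in 0:7) {
      k <- (dir - 1L + s) %% 8L + 1L
      rr <- cur[1] + moves[k, 1]; cc <- cur[2] + moves[k, 2]
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && m[rr, cc]) {
        if (length(path_r) == 0L) first_move <- k
        path_r <- c(path_r, rr); path_c <- c(path_c, cc)
        cur <- c(rr, cc)
        # new backtrack: the direction pointing back toward the previous
        # pixel, advanced by one clockwise step
        dir <- (k - 1L + 5L) %% 8L + 1L
        found <- TRUE
        break
      }
    }
    if (!found) return(NULL)  # isolated pixel
    # Jacob's stopping criterion: back at start entering the same way
    if (cur[1] == sr && cur[2] == sc && length(path_r) > 1L) {
      nk <- next_move_index(m, cur, dir)
      if (!is.na(nk) && nk == first_move) break
      if (length(path_r) > 4L * (H * W)) break  # safety
    }
  }
  cbind(r = c(sr, path_r), c = c(sc, path_c))
}

next_move_index <- function(m, cur, dir) {
  H <- nrow(m); W <- ncol(m)
  moves <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
                 c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  for (s in 0:7) {
    k <- (dir - 1L + s) %% 8L + 1L
    rr <- cur[1] + moves[k, 1]; cc <- cur[2] + moves[k, 2]
    if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && m[rr, cc]) return(k)
  }
  NA_integer_
}

chain_length <- function(path) {
  if (is.null(path) || nrow(path) < 2) return(0)
  dr <- abs(diff(path[, 1])); dc <- abs(diff(path[, 2]))
  sum(ifelse(dr + dc == 2, sqrt(2), 1))
}

# ---- convex hull helpers ---------------------------------------------

polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

polygon_perimeter <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  j <- c(seq_len(n)[-1], 1)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

# max pairwise distance and minimal width of a point set (pixel centers)
feret_diameters <- function(px, py) {
  n <- length(px)
  if (n == 1) return(c(max = 0, min = 0))
  hull <- tryCatch(grDevices::chull(px, py), error = function(e) NULL)
  if (is.null(hull) || length(hull) < 3) {
    d <- 0
    for (i in seq_len(n - 1)) {
      d <- max(d, sqrt((px[i] - px[(i + 1):n])^2 + (py[i] - py[(i + 1):n])^2))
    }
    return(c(max = d, min = 0))
  }
  hx <- px[hull]; hy <- py[hull]
  m <- length(hx)
  dmax <- 0
  for (i in seq_len(m - 1)) {
    dmax <- max(dmax,
                sqrt((hx[i] - hx[(i + 1):m])^2 + (hy[i] - hy[(i + 1):m])^2))
  }
  wmin <- Inf
  j <- c(seq_len(m)[-1], 1)
  for (i in seq_len(m)) {
    ex <- hx[j[i]] - hx[i]; ey <- hy[j[i]] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    # max distance of hull points from the line through edge i
    d <- abs((hx - hx[i]) * ey - (hy - hy[i]) * ex) / len
    wmin <- min(wmin, max(d))
  }
  if (!is.finite(wmin)) wmin <- 0
  c(max = dmax, min = wmin)
}

# 8 extremal boundary points, pixel-center coordinates (rows: top-left,
# top-right, right-top, right-bottom, bottom-right, bottom-left,
# left-bottom, left-top)
extrema_points <- function(rr, cc) {
  rmin <- min(rr); rmax <- max(rr); cmin <- min(cc); cmax <- max(cc)
  p <- function(r, c) c(r, c)
  rbind(
    top_left     = p(rmin, min(cc[rr == rmin])),
    top_right    = p(rmin, max(cc[rr == rmin])),
    right_top    = p(min(rr[cc == cmax]), cmax),
    right_bottom = p(max(rr[cc == cmax]), cmax),
    bottom_right = p(rmax, max(cc[rr == rmax])),
    bottom_left  = p(rmax, min(cc[rr == rmax])),
    left_bottom  = p(max(rr[cc == cmin]), cmin),
    left_top     = p(min(rr[cc == cmin]), cmin)
  )
}

# ---- region census ----------------------------------------------------

#' Measure raw geometry of every labeled region
#'
#' One row per positive label: pixel area, hole-filled area, outer
#' boundary perimeter, convex hull area/perimeter, Feret diameters,
#' bounding-rectangle area, centroid, eccentricity of the
#' second-central-moment ellipse, and the eight boundary extrema.
#'
#' @param labels Integer label matrix (0 = background).
#' @return A data frame with one row per region, ordered by label. The
#'   eight extrema are flattened into `extrema_<name>_row`/`_col` columns.
#' @export
region_census <- function(labels) {
  assert_labels(labels)
  labels <- as_int_matrix(labels)
  mx <- max(labels)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      filled_area = numeric(0), perimeter = numeric(0),
                      convex_area = numeric(0), convex_perimeter = numeric(0),
                      max_diameter = numeric(0), min_diameter = numeric(0),
                      bbox_area = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), eccentricity = numeric(0))
  if (mx == 0L) return(empty)
  idx <- which(labels > 0L)
  H <- nrow(labels)
  rr_all <- (idx - 1L) %% H + 1L
  cc_all <- (idx - 1L) %/% H + 1L
  lab_all <- labels[idx]
  rows <- vector("list", mx)
  present <- sort(unique(lab_all))
  for (l in present) {
    sel <- lab_all == l
    rr <- rr_all[sel]; cc <- cc_all[sel]
    n <- length(rr)
    r0 <- min(rr); c0 <- min(cc)
    bh <- max(rr) - r0 + 1L; bw <- max(cc) - c0 + 1L
    # cropped mask with a 1-pixel false pad
    m <- matrix(FALSE, bh + 2L, bw + 2L)
    m[cbind(rr - r0 + 2L, cc - c0 + 2L)] <- TRUE
    # filled area: background components of the crop not touching the pad
    # border are holes
    bg <- cpp_label(!m, 4L)
    border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    holes <- bg > 0L & !(bg %in% border_ids)
    filled <- n + sum(holes)
    per <- chain_length(trace_boundary(m))
    # convex hull over pixel corners
    corners_x <- c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5)
    corners_y <- c(rr - 0.5, rr - 0.5, rr + 0.5, rr + 0.5)
    hull <- grDevices::chull(corners_x, corners_y)
    ca <- polygon_area(corners_x[hull], corners_y[hull])
    cp <- polygon_perimeter(corners_x[hull], corners_y[hull])
    fer <- feret_diameters(cc, rr)
    # second-central-moment ellipse (unit-variance pixel correction 1/12)
    mr <- mean(rr); mc <- mean(cc)
    m20 <- mean((rr - mr)^2) + 1 / 12
    m02 <- mean((cc - mc)^2) + 1 / 12
    m11 <- mean((rr - mr) * (cc - mc))
    comm <- sqrt((m20 - m02)^2 + 4 * m11^2)
    l1 <- (m20 + m02 + comm) / 2
    l2 <- (m20 + m02 - comm) / 2
    ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
    ext <- extrema_points(rr, cc)
    row <- data.frame(label = l, area = n, filled_area = filled,
                      perimeter = per, convex_area = ca,
                      convex_perimeter = cp, max_diameter = fer["max"],
                      min_diameter = fer["min"],
                      bbox_area = as.numeric(bh) * bw,
                      centroid_row = mr, centroid_col = mc,
                      eccentricity = ecc)
    for (nm in rownames(ext)) {
      row[[paste0("extrema_", nm, "_row")]] <- ext[nm, 1]
      row[[paste0("extrema_", nm, "_col")]] <- ext[nm, 2]
    }
    rows[[l]] <- row
  }
  out <- do.call(rbind, rows[present])
  rownames(out) <- NULL
  out
}

#' Dimensionless shape descriptors
#'
#' Fills the classical single-parameter shape ratios from the raw
#' measurements: form factor \eqn{4\pi A / P^2} (1 for an ideal disk),
#' roundness \eqn{4A/(\pi D_{max}^2)}, aspect ratio
#' \eqn{D_{max}/D_{min}}, solidity \eqn{A/A_{convex}}, extent
#' \eqn{A/A_{bbox}}, compactness \eqn{\sqrt{4A/\pi}/D_{max}} and
#' convexity \eqn{P_{convex}/P}. Degenerate regions (zero perimeter or
#' zero minimum diameter, e.g. single pixels or straight lines) get `NA`
#' descriptors and `degenerate = TRUE` rather than propagating NaN.
#'
#' @param rf Data frame with columns `area`, `perimeter`, `convex_area`,
#'   `convex_perimeter`, `max_diameter`, `min_diameter`, `bbox_area`
#'   (e.g. the output of [region_census()], or closed-form values).
#' @return `rf` with descriptor columns appended.
#' @export
shape_descriptors <- function(rf) {
  need <- c("area", "perimeter", "convex_area", "convex_perimeter",
            "max_diameter", "min_diameter", "bbox_area")
  miss <- setdiff(need, names(rf))
  if (length(miss) > 0) {
    stop("missing measurement columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ok_p <- rf$perimeter > 0
  ok_d <- rf$max_diameter > 0 & rf$min_diameter > 0
  ok_a <- rf$convex_area > 0 & rf$bbox_area > 0
  rf$form_factor <- ifelse(ok_p, 4 * pi * rf$area / rf$perimeter^2, NA_real_)
  rf$roundness <- ifelse(ok_d, 4 * rf$area / (pi * rf$max_diameter^2),
                         NA_real_)
  rf$aspect_ratio <- ifelse(ok_d, rf$max_diameter / rf$min_diameter,
                            NA_real_)
  rf$solidity <- ifelse(ok_a, rf$area / rf$convex_area, NA_real_)
  rf$extent <- ifelse(ok_a, rf$area / rf$bbox_area, NA_real_)
  rf$compactness <- ifelse(ok_d, sqrt(4 * rf$area / pi) / rf$max_diameter,
                           NA_real_)
  rf$convexity <- ifelse(ok_p, rf$convex_perimeter / rf$perimeter, NA_real_)
  rf$degenerate <- !(ok_p & ok_d & ok_a)
  rf
}

#' Percent of the image covered by cells
#'
#' @param labels Integer label matrix.
#' @return Percentage in `[0, 100]` of pixels with a positive label.
#' @export
percent_cell_area <- function(labels) {
  assert_labels(labels)
  100 * sum(labels > 0) / length(labels)
}

#' Percent of pixels above a white-point threshold
#'
#' Quantifies bright reflection points (e.g. from metal nanoparticles) as
#' the share of pixels strictly above `threshold`.
#'
#' @param img Grayscale matrix.
#' @param threshold Intensity level in `[0, 255]`.
#' @return Percentage in `[0, 100]`.
#' @export
white_point_fraction <- function(img, threshold = 200) {
  assert_gray(img)
  if (threshold < 0 || threshold > 255) {
    stop("`threshold` must lie in [0, 255]", call. = FALSE)
  }
  100 * sum(img > threshold) / length(img)
}

#' 256-bin intensity histogram
#'
#' @param img Grayscale matrix.
#' @return Integer vector of 256 counts; bin `i` holds the number of
#'   pixels at level `i - 1`. Counts sum to the pixel count.
#' @export
intensity_histogram <- function(img) {
  assert_gray(img)
  tabulate(as.integer(round(img)) + 1L, nbins = 256)
}

#' Assemble the per-image stage report
#'
#' Bundles everything the dose-response comparison needs for one image:
#' the stage tag, percent cell area, cell count, white-point percentage,
#' the intensity histogram of the reference grayscale, and the full
#' per-cell descriptor table.
#'
#' @param img Reference grayscale matrix (green channel after resizing and
#'   median filtering, before contrast enhancement).
#' @param labels Integer label matrix from the segmentation.
#' @param stage Stage tag: `"A"` (control), `"B"` (12.5), `"C"` (25) or
#'   `"D"` (50 ug/mL).
#' @param white_threshold White-point intensity threshold.
#' @return An object of class `stage_result` (a list).
#' @export
stage_report <- function(img, labels, stage, white_threshold = 200) {
  assert_gray(img)
  assert_labels(labels)
  if (!identical(dim(img), dim(labels))) {
    stop("`img` and `labels` must have the same shape", call. = FALSE)
  }
  if (!is.character(stage) || length(stage) != 1 ||
      !stage %in% c("A", "B", "C", "D")) {
    stop("`stage` must be one of \"A\", \"B\", \"C\", \"D\"", call. = FALSE)
  }
  regions <- shape_descriptors(region_census(labels))
  structure(list(
    stage = stage,
    percent_area = percent_cell_area(labels),
    cell_count = length(unique(labels[labels > 0])),
    percent_white_points = white_point_fraction(img, white_threshold),
    histogram = intensity_histogram(img),
    regions = regions
  ), class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat(sprintf(
    "Stage %s: %d cells, %.2f%% cell area, %.2f%% white points\n",
    x$stage, x$cell_count, x$percent_area, x$percent_white_points))
  invisible(x)
}
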
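# Seeded generator of darkfield-like fluorescent-cell images with exact
# ground truth.  Images emulate the four treatment stages: a near-black
# noisy background, bright green elliptical cells (some deliberately
# touching), a few sub-50-pixel bright white specks standing in for
# microscope artifacts (air bubbles, particulate reflections), and a cell
# density that grows with the applied dose.

STAGE_LEVELS <- c("A", "B", "C", "D")
STAGE_CELLS <- c(A = 0L, B = 12L, C = 24L, D = 40L)  # per 512 x 512 canvas

#' Specification of one synthetic darkfield capture
#'
#' @param stage Treatment stage `"A"` (control, no cells), `"B"`, `"C"` or
#'   `"D"`; determines the default cell count.
#' @param n_cells Number of cells; defaults to the stage's density scaled
#'   to the canvas area.
#' @param width,height Canvas size in pixels.
#' @param major_range,minor_range Ranges (pixels) for the ellipse
#'   semi-axes; axes are resampled until the analytic area
#'   `pi * a * b` is at least `min_axis_product * pi`, keeping every cell
#'   comfortably above the 500-pixel completeness filter.
#' @param min_axis_product Lower bound on `a * b`.
#' @param peak_range Peak green intensity range of a cell.
#' @param touching_fraction Fraction of cells placed overlapping a
#'   neighbor (so the watershed has necks to split).
#' @param n_artifacts Number of bright specks, each under 50 pixels.
#' @param background_mean,background_sd Gaussian background noise
#'   parameters (clipped to `[0, 255]`).
#' @param seed Integer seed; the single source of randomness.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(stage = "B", n_cells = NULL,
                           width = 512, height = 512,
                           major_range = c(14, 22), minor_range = c(12, 16),
                           min_axis_product = 196,
                           peak_range = c(200, 240),
                           touching_fraction = 0.15, n_artifacts = 6,
                           background_mean = 8, background_sd = 4,
                           seed = 1) {
  stage <- match.arg(stage, STAGE_LEVELS)
  if (is.null(n_cells)) {
    n_cells <- as.integer(round(STAGE_CELLS[[stage]] *
                                  (width * height) / (512 * 512)))
  }
  if (stage == "A") n_cells <- 0L
  stopifnot(n_cells >= 0, width >= 64, height >= 64,
            touching_fraction >= 0, touching_fraction <= 1,
            n_artifacts >= 0, background_sd >= 0)
  structure(list(stage = stage, n_cells = as.integer(n_cells),
                 width = as.integer(width), height = as.integer(height),
                 major_range = as.numeric(major_range),
                 minor_range = as.numeric(minor_range),
                 min_axis_product = as.numeric(min_axis_product),
                 peak_range = as.numeric(peak_range),
                 touching_fraction = as.numeric(touching_fraction),
                 n_artifacts = as.integer(n_artifacts),
                 background_mean = as.numeric(background_mean),
                 background_sd = as.numeric(background_sd),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# support radius of an ellipse (semi-axes a >= b, orientation theta) in
# direction phi: distance from center to the boundary along phi
ellipse_support <- function(a, b, theta, phi) {
  psi <- phi - theta
  sqrt((a * cos(psi))^2 + (b * sin(psi))^2)
}

rasterize_ellipse_u <- function(rr, cc, cl) {
  dr <- outer(rr - cl$cr, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - cl$cc)
  xr <- (dc * cos(cl$theta) + dr * sin(cl$theta)) / cl$a
  yr <- (-dc * sin(cl$theta) + dr * cos(cl$theta)) / cl$b
  xr^2 + yr^2
}

# A touching pair is acceptable only if the two cells overlap yet keep
# distinct thickness maxima deep enough for the watershed to split the
# clump.  The check emulates what segmentation will actually see: the
# thresholded mask is slightly fatter than the ideal ellipse union (soft
# rims) and is smoothed by a radius-3 closing, both of which widen the
# neck.  The emulated mask must give exactly two extended-minima markers
# at depth 3 (the pipeline's value) and still at depth 4 (a safety
# margin against residual rasterization differences).
touching_pair_ok <- function(c1, c2) {
  pad <- 6
  r0 <- floor(min(c1$cr - c1$a, c2$cr - c2$a)) - pad
  r1 <- ceiling(max(c1$cr + c1$a, c2$cr + c2$a)) + pad
  cl0 <- floor(min(c1$cc - c1$a, c2$cc - c2$a)) - pad
  cl1 <- ceiling(max(c1$cc + c1$a, c2$cc + c2$a)) + pad
  rr <- r0:r1; cc <- cl0:cl1
  in1 <- rasterize_ellipse_u(rr, cc, c1) <= 1
  in2 <- rasterize_ellipse_u(rr, cc, c2) <= 1
  if (!any(in1 & in2)) return(FALSE)           # must actually touch
  um <- in1 | in2
  um <- cpp_dilate(um, disk_se(1))             # soft-rim fattening
  se3 <- disk_se(3)
  um <- cpp_erode(cpp_dilate(um, se3), se3)    # pipeline's closing
  surf <- -cpp_edt(um)
  for (h in c(3, 4)) {
    markers <- extended_minima(surf, h = h)
    if (max(cpp_label(markers, 8L)) != 2L) return(FALSE)
  }
  TRUE
}

#' Generate one synthetic darkfield capture with ground truth
#'
#' Deterministic for a fixed spec (the spec's seed drives all sampling).
#' Cells are filled ellipses with a bright green interior falling off
#' radially to about 65% of the peak at the rim, plus multiplicative
#' speckle; touching pairs share boundary but keep distinct thickness
#' maxima so the distance-transform watershed can separate them.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_sample`: `image` (H x W x 3
#'   array), `truth` (list of per-cell masks as linear-index vectors with
#'   a `dim_full` attribute) and `spec`.
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  npx <- H * W

  ch_g <- matrix(clamp8(round(stats::rnorm(npx, spec$background_mean,
                                           spec$background_sd))), H, W)
  ch_r <- matrix(clamp8(round(stats::rnorm(npx, spec$background_mean * 0.75,
                                           spec$background_sd * 0.75))), H, W)
  ch_b <- matrix(clamp8(round(stats::rnorm(npx, spec$background_mean * 0.75,
                                           spec$background_sd * 0.75))), H, W)

  n <- spec$n_cells
  cells <- vector("list", n)
  truth <- vector("list", n)

  sample_axes <- function() {
    for (i in 1:100) {
      a <- stats::runif(1, spec$major_range[1], spec$major_range[2])
      b <- stats::runif(1, spec$minor_range[1], spec$minor_range[2])
      if (b > a) { tmp <- a; a <- b; b <- tmp }
      if (a * b >= spec$min_axis_product) return(c(a, b))
    }
    c(spec$major_range[2], spec$minor_range[2])
  }

  gap <- 10  # clearance between non-touching cells (closing radius 3 bridges 6)
  if (n > 0) {
    paired <- logical(n)  # cells already in a touching pair (no chains)
    for (i in seq_len(n)) {
      ax <- sample_axes()
      a <- ax[1]; b <- ax[2]
      theta <- stats::runif(1, 0, pi)
      touching <- i > 1 && stats::runif(1) < spec$touching_fraction &&
        any(!paired[seq_len(i - 1L)])
      placed <- FALSE
      for (try in seq_len(500)) {
        if (try > 300) touching <- FALSE  # fall back to isolated placement
        pj <- 0L
        if (touching) {
          free <- which(!paired[seq_len(i - 1L)])
          pj <- free[sample.int(length(free), 1)]
          partner <- cells[[pj]]
          phi <- stats::runif(1, 0, 2 * pi)
          d <- stats::runif(1, 0.78, 0.92) *
            (ellipse_support(partner$a, partner$b, partner$theta, phi) +
               ellipse_support(a, b, theta, phi + pi))
          cr <- partner$cr + d * sin(phi)
          cc <- partner$cc + d * cos(phi)
        } else {
          cr <- stats::runif(1, a + 2, H - a - 2)
          cc <- stats::runif(1, a + 2, W - a - 2)
        }
        if (cr < a + 2 || cr > H - a - 2 || cc < a + 2 || cc > W - a - 2)
          next
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          if (j == pj) next
          other <- cells[[j]]
          phi <- atan2(other$cr - cr, other$cc - cc)
          dmin <- ellipse_support(a, b, theta, phi) +
            ellipse_support(other$a, other$b, other$theta, phi + pi) + gap
          if (sqrt((other$cr - cr)^2 + (other$cc - cc)^2) < dmin) {
            ok <- FALSE
            break
          }
        }
        cand <- list(a = a, b = b, theta = theta, cr = cr, cc = cc)
        if (ok && touching) {
          ok <- touching_pair_ok(partner, cand)
        }
        if (ok) {
          cand$peak <- stats::runif(1, spec$peak_range[1],
                                    spec$peak_range[2])
          cells[[i]] <- cand
          if (touching) paired[c(i, pj)] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place all cells on the canvas; reduce `n_cells` ",
             "or enlarge the canvas", call. = FALSE)
      }
    }

    for (i in seq_len(n)) {
      cl <- cells[[i]]
      r0 <- max(1L, floor(cl$cr - cl$a - 1)); r1 <- min(H, ceiling(cl$cr + cl$a + 1))
      c0 <- max(1L, floor(cl$cc - cl$a - 1)); c1 <- min(W, ceiling(cl$cc + cl$a + 1))
      rr <- r0:r1; cc <- c0:c1
      dr <- outer(rr - cl$cr, rep(1, length(cc)))
      dc <- outer(rep(1, length(rr)), cc - cl$cc)
      xr <- (dc * cos(cl$theta) + dr * sin(cl$theta)) / cl$a
      yr <- (-dc * sin(cl$theta) + dr * cos(cl$theta)) / cl$b
      u <- xr^2 + yr^2
      inside <- u <= 1
      sel <- which(inside, arr.ind = TRUE)
      lin <- (c0 - 1L + sel[, 2] - 1L) * H + (r0 - 1L + sel[, 1])
      val <- cl$peak * (1 - 0.35 * u[inside])
      val <- val * (1 + stats::rnorm(length(val), 0, 0.05))
      val <- clamp8(round(val))
      ch_g[lin] <- pmax(ch_g[lin], val)
      ch_r[lin] <- pmax(ch_r[lin], round(0.2 * val))
      ch_b[lin] <- pmax(ch_b[lin], round(0.12 * val))
      truth[[i]] <- structure(as.integer(lin), dim_full = c(H, W))
    }
  }

  # bright white specks, each well under the 50-pixel noise filter
  if (spec$n_artifacts > 0) {
    for (k in seq_len(spec$n_artifacts)) {
      for (try in seq_len(200)) {
        ar <- stats::runif(1, 6, H - 6)
        ac <- stats::runif(1, 6, W - 6)
        clear <- TRUE
        for (cl in cells[seq_len(n)]) {
          phi <- atan2(cl$cr - ar, cl$cc - ac)
          if (sqrt((cl$cr - ar)^2 + (cl$cc - ac)^2) <
              ellipse_support(cl$a, cl$b, cl$theta, phi + pi) + 12) {
            clear <- FALSE
            break
          }
        }
        if (clear) break
      }
      rad <- sample(1:3, 1)
      lvl <- stats::runif(1, 190, 250)
      rr <- max(1, floor(ar - rad)):min(H, ceiling(ar + rad))
      cc <- max(1, floor(ac - rad)):min(W, ceiling(ac + rad))
      dr <- outer(rr - ar, rep(1, length(cc)))
      dc <- outer(rep(1, length(rr)), cc - ac)
      inside <- dr^2 + dc^2 <= rad^2
      sel <- which(inside, arr.ind = TRUE)
      lin <- (cc[1] - 1L + sel[, 2] - 1L) * H + (rr[1] - 1L + sel[, 1])
      v <- clamp8(round(lvl * (1 + stats::rnorm(length(lin), 0, 0.03))))
      ch_g[lin] <- pmax(ch_g[lin], v)
      ch_r[lin] <- pmax(ch_r[lin], v)
      ch_b[lin] <- pmax(ch_b[lin], v)
    }
  }

  img <- array(0, c(H, W, 3))
  img[, , 1] <- ch_r; img[, , 2] <- ch_g; img[, , 3] <- ch_b
  structure(list(image = img, truth = truth[seq_len(n)], spec = spec),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("synthetic stage-%s capture: %d x %d px, %d cells (seed %d)\n",
              x$spec$stage, x$spec$height, x$spec$width,
              length(x$truth), x$spec$seed))
  invisible(x)
}

#' Generate the four-stage dose series
#'
#' Four samples sharing canvas and noise parameters whose cell counts
#' increase strictly from the control stage A through the highest dose D,
#' mirroring the dose-dependent density of treated cultures.
#'
#' @param base A [synthetic_spec()] supplying canvas/noise parameters.
#' @param seed Integer seed for the series.
#' @return Named list of four `synthetic_sample` objects (A, B, C, D).
#' @export
generate_stage_series <- function(base = synthetic_spec(), seed = 1) {
  out <- vector("list", 4)
  names(out) <- STAGE_LEVELS
  for (i in seq_along(STAGE_LEVELS)) {
    st <- STAGE_LEVELS[i]
    sp <- base
    sp$stage <- st
    sp$n_cells <- as.integer(round(STAGE_CELLS[[st]] *
                                     (sp$width * sp$height) / (512 * 512)))
    sp$seed <- as.integer(seed + i)
    out[[st]] <- generate(sp)
  }
  out
}

#' Generate the 28-image validation suite
#'
#' A fixed-size suite of treated-stage captures totaling roughly 1300
#' cells (always within [1200, 1400] by construction), used for the
#' synthetic-analog accuracy run. Per-image cell counts are drawn
#' uniformly from 42..51; stages cycle through B, C, D.
#'
#' @param seed Integer seed.
#' @param n_images Number of captures (default 28).
#' @param base A [synthetic_spec()] supplying canvas/noise parameters.
#' @return List of `synthetic_sample` objects.
#' @export
validation_suite <- function(seed = 1, n_images = 28,
                             base = synthetic_spec()) {
  set.seed(seed)
  counts <- sample(42:51, n_images, replace = TRUE)
  stages <- rep(c("B", "C", "D"), length.out = n_images)
  out <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    sp <- base
    sp$stage <- stages[i]
    sp$n_cells <- counts[i]
    sp$seed <- as.integer((seed %% 10000000L) * 100L + i)
    out[[i]] <- generate(sp)
  }
  out
}
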
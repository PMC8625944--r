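test_that("region census recovers closed-form square geometry", {
  lab <- matrix(0L, 14, 14); lab[3:12, 3:12] <- 1L
  rc <- region_census(lab)
  expect_equal(rc$area, 100)
  expect_equal(rc$filled_area, 100)
  expect_equal(rc$perimeter, 36)                 # 4 sides of 9 center steps
  expect_equal(rc$bbox_area, 100)
  expect_equal(rc$max_diameter, 9 * sqrt(2))     # pixel-center diagonal
  expect_equal(rc$min_diameter, 9)
  expect_equal(rc$convex_area, 100)              # corner hull = 10 x 10
  expect_equal(rc$convex_perimeter, 40)
  expect_equal(rc$eccentricity, 0)
  expect_equal(rc$centroid_row, 7.5)
  expect_equal(rc$extrema_top_left_row, 3)
  expect_equal(rc$extrema_right_bottom_col, 12)
})

test_that("degenerate regions are flagged instead of propagating NaN", {
  lab <- matrix(0L, 3, 3); lab[2, 2] <- 1L
  rc <- region_census(lab)
  expect_equal(rc$area, 1)
  expect_equal(rc$max_diameter, rc$min_diameter)
  sd_ <- shape_descriptors(rc)
  expect_true(sd_$degenerate)
  expect_true(is.na(sd_$form_factor) && is.na(sd_$roundness))
  expect_identical(nrow(region_census(matrix(0L, 4, 4))), 0L)
})

test_that("census areas and hulls agree with brute-force counts", {
  set.seed(21)
  for (i in 1:10) {
    m <- closing(random_mask(24, 24, 0.55), disk_se(1))
    lab <- label_components(m)
    rc <- region_census(lab)
    for (k in seq_len(nrow(rc))) {
      l <- rc$label[k]
      expect_identical(as.integer(rc$area[k]), sum(lab == l))
      # the corner hull must contain every pixel square of the region
      expect_gte(rc$convex_area[k] + 1e-9, rc$area[k])
      expect_lte(rc$area[k], rc$filled_area[k])
      expect_lte(rc$filled_area[k], rc$convex_area[k] + 1e-9)
      expect_lte(rc$min_diameter[k], rc$max_diameter[k] + 1e-9)
    }
  }
  # axis-aligned rectangle: hull area/perimeter in closed form
  lab <- matrix(0L, 20, 20); lab[4:9, 3:14] <- 1L
  rc <- region_census(lab)
  expect_equal(rc$convex_area, 6 * 12)
  expect_equal(rc$convex_perimeter, 2 * (6 + 12))
})

test_that("descriptors hit the closed-form circle and square values", {
  r <- 50; a <- 100
  circle <- data.frame(area = pi * r^2, perimeter = 2 * pi * r,
                       convex_area = pi * r^2, convex_perimeter = 2 * pi * r,
                       max_diameter = 2 * r, min_diameter = 2 * r,
                       bbox_area = (2 * r)^2)
  dc <- shape_descriptors(circle)
  expect_equal(dc$form_factor, 1)
  expect_equal(dc$roundness, 1)
  expect_equal(dc$aspect_ratio, 1)
  expect_equal(dc$solidity, 1)
  expect_equal(dc$compactness, 1)
  expect_equal(dc$convexity, 1)
  expect_equal(dc$extent, pi / 4)
  square <- data.frame(area = a^2, perimeter = 4 * a,
                       convex_area = a^2, convex_perimeter = 4 * a,
                       max_diameter = a * sqrt(2), min_diameter = a,
                       bbox_area = a^2)
  ds <- shape_descriptors(square)
  expect_equal(ds$form_factor, pi / 4)
  expect_equal(ds$extent, 1)
  expect_equal(ds$solidity, 1)
  expect_equal(ds$convexity, 1)
  # diagonal Feret: roundness of the square is 2/pi by closed form
  expect_equal(ds$roundness, 2 / pi)
})

test_that("rasterized disks score near the ideal-circle descriptors", {
  m <- rasterize_disk(50)
  d <- shape_descriptors(region_census(m))
  expect_lt(abs(d$solidity - 1), 0.02)
  expect_lt(abs(d$roundness - 1), 0.02)
  expect_lt(abs(d$compactness - 1), 0.02)
  expect_lt(abs(d$aspect_ratio - 1), 0.02)
  expect_lt(abs(d$eccentricity), 0.05)
  # the sqrt(2)-weighted chain overestimates a smooth contour by ~5%,
  # so form factor and convexity sit just below 1
  expect_lt(d$form_factor, 1.02)
  expect_gt(d$form_factor, 0.85)
  expect_lt(abs(d$convexity - 1), 0.05)
})

test_that("form factor is maximized by disks among test shapes", {
  disk <- shape_descriptors(region_census(rasterize_disk(20)))
  shapes <- list()
  lab <- matrix(0L, 30, 30); lab[5:24, 10:15] <- 1L   # elongated bar
  shapes$bar <- shape_descriptors(region_census(lab))
  lab2 <- matrix(0L, 30, 30); lab2[5:24, 5:24] <- 1L  # square
  shapes$square <- shape_descriptors(region_census(lab2))
  for (s in shapes) expect_gt(disk$form_factor, s$form_factor)
})

test_that("descriptors are invariant under translation and 90-degree rotation", {
  set.seed(22)
  base <- closing(random_mask(14, 14, 0.6), disk_se(1))
  comps <- label_components(base)
  cell <- comps == which.max(tabulate(comps[comps > 0]))  # largest blob
  lab <- matrix(0L, 30, 30); lab[4:17, 4:17] <- cell * 1L
  keep_cols <- c("area", "filled_area", "perimeter", "convex_area",
                 "convex_perimeter", "max_diameter", "min_diameter",
                 "bbox_area", "eccentricity", "form_factor", "roundness",
                 "solidity", "extent", "compactness", "convexity")
  ref <- shape_descriptors(region_census(lab))[, keep_cols]
  shift <- matrix(0L, 30, 30); shift[9:22, 11:24] <- lab[4:17, 4:17]
  expect_equal(shape_descriptors(region_census(shift))[, keep_cols], ref,
               tolerance = 1e-12, ignore_attr = TRUE)
  rot <- t(lab)[, 30:1]                      # 90-degree rotation
  storage.mode(rot) <- "integer"
  expect_equal(shape_descriptors(region_census(rot))[, keep_cols], ref,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("percent areas and white points count pixels exactly", {
  expect_equal(percent_cell_area(matrix(0L, 5, 5)), 0)
  expect_equal(percent_cell_area(matrix(1L, 5, 5)), 100)
  lab <- matrix(0L, 25, 40); lab[1:10, 1:10] <- 3L
  expect_equal(percent_cell_area(lab), 100 * 100 / 1000)
  expect_equal(percent_cell_area(lab) + 100 * sum(lab == 0) / 1000, 100)
  expect_equal(white_point_fraction(matrix(0, 5, 5), 200), 0)
  expect_equal(white_point_fraction(matrix(255, 5, 5), 200), 100)
  img <- matrix(0, 20, 20); img[sample(400, 37)] <- 201
  expect_equal(white_point_fraction(img, 200), 9.25)
})

test_that("intensity histograms tally every pixel once", {
  h <- intensity_histogram(matrix(7, 4, 4))
  expect_identical(h[8], 16L)
  expect_identical(sum(h), 16L)
  set.seed(23)
  img <- matrix(sample(0:255, 300, TRUE), 15, 20)
  h2 <- intensity_histogram(img)
  expect_identical(h2, as.integer(table(factor(img, levels = 0:255))))
})

test_that("stage reports assemble counts, areas and histograms coherently", {
  img <- matrix(10, 30, 30)
  lab <- matrix(0L, 30, 30)
  rep0 <- stage_report(img, lab, "A")
  expect_identical(rep0$cell_count, 0L)
  expect_equal(rep0$percent_area, 0)
  expect_identical(rep0$histogram, intensity_histogram(img))
  lab[5:14, 5:14] <- 1L
  rep1 <- stage_report(img, lab, "C")
  expect_identical(rep1$cell_count, 1L)
  expect_equal(rep1$percent_area, 100 * 100 / 900)
  expect_identical(nrow(rep1$regions), 1L)
  expect_error(stage_report(img, lab, "E"), "stage")
  expect_error(stage_report(matrix(0, 4, 4), lab, "A"), "same shape")
})
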
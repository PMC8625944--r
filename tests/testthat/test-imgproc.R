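test_that("green-channel extraction returns exactly the second channel", {
  img <- array(0, c(4, 5, 3)); img[, , 2] <- 255
  expect_true(all(extract_green(img) == 255))
  img2 <- array(0, c(4, 5, 3)); img2[, , 1] <- 255
  expect_true(all(extract_green(img2) == 0))
  set.seed(1)
  img3 <- array(sample(0:255, 4 * 5 * 3, TRUE), c(4, 5, 3))
  expect_identical(extract_green(img3), img3[, , 2])
  expect_error(extract_green(matrix(0, 3, 3)), "H x W x 3")
})

test_that("resizing hits the target side and preserves the aspect ratio", {
  img <- array(128, c(64, 64, 3))
  expect_identical(resize_to_standard(img, 64), img)
  img2 <- array(10, c(128, 64, 3))
  expect_equal(dim(resize_to_standard(img2, 64)), c(64, 32, 3))
  set.seed(2)
  img3 <- array(sample(0:255, 100 * 60 * 3, TRUE), c(100, 60, 3))
  out <- resize_to_standard(img3, 50)
  # independent per-axis scale computation
  expect_equal(dim(out)[1:2], c(50L, round(60 * 50 / 100)))
  expect_true(min(out) >= 0 && max(out) <= 255)
  expect_error(resize_to_standard(img3, 8), ">= 16")
})

test_that("median filter matches the brute-force sorted-window median", {
  const <- matrix(77, 9, 9)
  expect_identical(median_filter(const, 3), const)
  salt <- matrix(5, 7, 7); salt[4, 4] <- 250
  expect_identical(median_filter(salt, 3), matrix(5, 7, 7))
  set.seed(3)
  img <- matrix(sample(0:255, 256, TRUE), 16, 16)
  expect_equal(median_filter(img, 3), oracle_median(img, 3))
  expect_equal(median_filter(img, 5), oracle_median(img, 5))
  expect_error(median_filter(img, 4), "odd")
})

test_that("CLAHE reduces to global equalization with one unclipped tile", {
  set.seed(4)
  img <- matrix(sample(c(40L, 180L), 400, TRUE, c(0.7, 0.3)), 20, 20)
  out <- clahe(img, clip_limit = 1, tiles = c(1, 1))
  # independent oracle: empirical-cdf mapping of each level
  ec <- stats::ecdf(as.vector(img))
  expected <- matrix(round(255 * ec(img)), 20, 20)
  expect_identical(out, expected)
})

test_that("CLAHE keeps range, handles constants, expands low contrast", {
  const <- matrix(13, 16, 16)
  out <- clahe(const)
  expect_equal(length(unique(as.vector(out))), 1L)
  ramp <- matrix(rep(100:115, each = 16), 16, 16)
  out2 <- clahe(ramp, clip_limit = 1, tiles = c(2, 2))
  expect_gte(diff(range(out2)), diff(range(ramp)))
  expect_true(min(out2) >= 0 && max(out2) <= 255)
  expect_error(clahe(ramp, clip_limit = 1.5), "clip_limit")
})

test_that("Otsu equals exhaustive between-class-variance maximization", {
  bi <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  expect_identical(otsu_threshold(bi), 104L)  # tie rule: floor-mean of ties
  set.seed(5)
  for (i in 1:100) {
    img <- matrix(sample(0:255, 64, TRUE), 8, 8)
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
  # perfectly separable classes recover the bright pixels exactly
  img2 <- matrix(0, 20, 20); img2[sample(400, 4)] <- 255
  k <- otsu_threshold(img2)
  expect_identical(binarize(img2, k), img2 == 255)
  expect_error(otsu_threshold(matrix(7, 4, 4)), "constant")
})

test_that("binarization is strict and counts levels correctly", {
  expect_false(any(binarize(matrix(0, 3, 3), 0)))
  expect_true(all(binarize(matrix(255, 3, 3), 0)))
  ramp <- matrix(0:255, 16, 16)
  expect_identical(sum(binarize(ramp, 127)), sum(0:255 > 127))
  expect_identical(sum(binarize(ramp, 127)), 128L)
})

test_that("disk structuring elements match the lattice-point count", {
  plus <- disk_se(1)
  expect_identical(sum(plus), 5L)
  expect_true(plus[1, 2] && plus[2, 1] && plus[2, 2])
  d3 <- disk_se(3)
  expect_identical(d3, t(d3))                       # symmetric
  expect_identical(d3, d3[7:1, 7:1])                # 180-degree rotation
  # brute-force lattice count x^2 + y^2 <= 9
  cnt <- sum(outer(-3:3, -3:3, function(y, x) x^2 + y^2 <= 9))
  expect_identical(sum(d3), cnt)
  expect_identical(sum(d3), 29L)
  expect_error(disk_se(0), "radius")
})

test_that("dilation and erosion satisfy their set definitions and duality", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_identical(which(dilate(m, disk_se(1))), c(8L, 12L, 13L, 14L, 18L))
  one <- matrix(TRUE, 1, 1)
  set.seed(6)
  A <- random_mask(12, 12)
  expect_identical(erode(A, one), A)
  for (i in 1:50) {
    A <- random_mask(12, 12)
    B <- disk_se(sample(1:2, 1))
    expect_identical(erode(A, B), dual_erode(A, B))  # duality, symmetric B
  }
  # sampled exhaustive small masks
  for (i in 1:150) {
    bits <- as.logical(intToBits(sample.int(2^25, 1) - 1)[1:36])
    A <- matrix(bits, 6, 6)
    expect_identical(erode(A, disk_se(1)), dual_erode(A, disk_se(1)))
  }
})

test_that("opening/closing are idempotent, ordered and increasing", {
  se <- disk_se(3)
  speck <- matrix(FALSE, 9, 9); speck[5, 5] <- TRUE
  expect_false(any(opening(speck, se)))
  sq <- matrix(FALSE, 20, 20); sq[4:17, 4:17] <- TRUE
  op <- opening(sq, se)
  expect_true(all(op[8:13, 8:13]))          # interior survives
  expect_true(all(!op | sq))                # anti-extensive
  set.seed(7)
  for (i in 1:40) {
    A <- random_mask(12, 12, 0.6)
    se2 <- disk_se(sample(1:2, 1))
    op <- opening(A, se2); cl <- closing(A, se2)
    expect_true(all(!op | A))               # open(A) subset of A
    expect_true(all(!A | cl))               # A subset of close(A)
    expect_identical(opening(op, se2), op)  # idempotence
    expect_identical(closing(cl, se2), cl)
    C <- A | random_mask(12, 12, 0.2)       # A subset of C
    expect_true(all(!opening(A, se2) | opening(C, se2)))  # increasing
  }
})

test_that("area opening keeps exactly the components above the cutoff", {
  m <- matrix(FALSE, 20, 40)
  m[2:8, 2:8] <- TRUE               # 49 px
  m[2:11, 20:24] <- TRUE            # 50 px
  out <- area_open(m, 50)
  expect_false(any(out[, 1:10]))
  expect_identical(out[, 20:24], m[, 20:24])
  expect_identical(area_open(matrix(FALSE, 5, 5), 10), matrix(FALSE, 5, 5))
  set.seed(8)
  for (i in 1:20) {
    A <- random_mask(15, 15, 0.45)
    lab <- oracle_label(A, 8)
    sizes <- tabulate(lab[lab > 0])
    expected <- A & matrix(sizes[ifelse(lab == 0, NA, lab)] >= 5, 15, 15)
    expected[is.na(expected)] <- FALSE
    expect_identical(area_open(A, 5), expected)
  }
})

test_that("hole filling equals the complement/area-open/complement pipeline", {
  ring <- matrix(FALSE, 11, 11)
  for (i in 1:11) for (j in 1:11) {
    d <- sqrt((i - 6)^2 + (j - 6)^2)
    if (d <= 4.5 && d >= 2.2) ring[i, j] <- TRUE
  }
  filled <- fill_small_holes(ring, 50)
  expect_true(all(filled[ring]))
  expect_true(filled[6, 6])                         # hole is gone
  solid <- matrix(TRUE, 6, 6)
  expect_identical(fill_small_holes(solid, 50), solid)
  set.seed(9)
  for (i in 1:20) {
    A <- random_mask(14, 14, 0.55)
    expect_identical(fill_small_holes(A, 8),
                     !area_open(!A, 8, connectivity = 4))
  }
})
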
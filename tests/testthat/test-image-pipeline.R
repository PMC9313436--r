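test_that("binarize matches an exhaustive between-class-variance sweep", {
  set.seed(1)
  # two-level image (40 vs 210): any threshold between the populations
  # separates them exactly
  img <- matrix(sample(c(40, 210), 400, replace = TRUE), 20, 20)
  mask <- binarize(img)
  expect_identical(mnaqc:::mask_matrix(mask), (img > 125) * 1L)
  t_oracle <- oracle_otsu(img / 255)
  expect_identical(mnaqc:::mask_matrix(mask),
                   (img / 255 > t_oracle) * 1L)
})

test_that("binarize is idempotent on binary input and honors invert", {
  set.seed(2)
  img <- matrix(sample(c(0, 255), 100, replace = TRUE), 10, 10)
  mask <- binarize(img)
  expect_identical(mnaqc:::mask_matrix(mask), (img == 255) * 1L)
  inv <- binarize(img, invert = TRUE)
  expect_identical(mnaqc:::mask_matrix(inv), 1L - mnaqc:::mask_matrix(mask))
  expect_error(binarize(matrix(7, 5, 5)), "degenerate histogram")
})

test_that("split_array produces one centered needle per tile", {
  arr <- clean_test_array()
  pr <- simulate_print(arr, no_artifact_params())
  tiles <- split_array(pr$mask, 10)
  expect_length(tiles, 10)
  for (tl in tiles) {
    expect_equal(dim(tl), c(150L, 150L))
    expect_equal(count_components_above_base(tl, base_strip_um = 250), 1)
    # horizontal centering within a pixel of the tile midline
    expect_lt(abs(mnaqc:::foreground_centroid_col(tl) - 75.5), 2)
  }
  expect_error(split_array(pr$mask, 12), "detected 10 needle peaks")
})

test_that("splitting conserves every needle pixel at the cut lines", {
  arr <- clean_test_array(design = mn_design(1500, 2500, 5))
  tiles <- split_array(arr, 10)
  cuts <- t(vapply(tiles, function(t) attr(t, "cut"), numeric(2)))
  # cut windows partition the needle region: contiguous, non-overlapping
  expect_true(all(cuts[-1, 1] == cuts[-10, 2] + 1))
  total_fg <- sum(vapply(tiles, sum, numeric(1)))
  covered <- sum(arr[, cuts[1, 1]:cuts[10, 2]])
  expect_equal(total_fg, covered)
  # every column outside the windows is pure base strip or margin
  expect_equal(sum(arr) - covered,
               sum(arr[, -(cuts[1, 1]:cuts[10, 2])]))
})

test_that("a single-needle array splits into one tile equal to its input", {
  d <- mn_design(1000, 2000, 5)
  arr <- render_needle_profile(d)
  tiles <- split_array(arr, 1, base_strip_um = 250)
  expect_length(tiles, 1)
  expect_equal(sum(tiles[[1]]), sum(arr))
})

test_that("alignment recovers planted shifts exactly", {
  arr <- clean_test_array()
  # embed in a wider canvas so the base strip does not touch the borders
  # (in a photo the plate never spans the full frame)
  m0 <- mnaqc:::mask_matrix(arr)
  m <- matrix(0L, nrow(m0) + 10, ncol(m0) + 20)
  m[1:nrow(m0), 11:(10 + ncol(m0))] <- m0
  cad <- binary_mask(m, scale = mnaqc:::mask_scale(arr))
  # shift up 3 and left 5
  shifted <- binary_mask(mnaqc:::shift_matrix(m, -3, -5),
                         scale = mnaqc:::mask_scale(arr))
  pair <- align_masks(shifted, cad)
  expect_equal(pair$shift, c(3, 5))
  pc <- compare_pixels(pair)
  expect_equal(pc$FP, 0)
  expect_equal(pc$FN, 0)
  # identity input: zero shift
  pair0 <- align_masks(cad, cad)
  expect_equal(pair0$shift, c(0, 0))
  # the centroid method also recovers clean planted shifts
  pairc <- align_masks(shifted, cad, method = "centroid")
  expect_equal(pairc$shift, c(3, 5))
  expect_error(align_masks(binary_mask(matrix(0L, 5, 5)), cad),
               "empty foreground")
})

test_that("compare_pixels matches the 3x3 hand-worked example", {
  cad <- binary_mask(matrix(c(0, 0, 0, 1, 1, 1, 0, 0, 0), 3, 3))  # mid column
  printed <- cad
  printed[1, 2] <- 0L   # lose top of column
  printed[3, 1] <- 1L   # gain bottom-left pixel
  pc <- compare_pixels(list(cad = cad, printed = printed))
  expect_equal(pc$TP, 2); expect_equal(pc$FN, 1)
  expect_equal(pc$FP, 1); expect_equal(pc$TN, 5)
})

test_that("compare_pixels degenerate cases and symmetry", {
  set.seed(3)
  for (i in 1:20) {
    a <- random_small_mask(); b <- random_small_mask()
    pc <- compare_pixels(list(cad = a, printed = b))
    # conservation
    expect_equal(pc$TP + pc$TN + pc$FP + pc$FN, 64)
    # swapping arguments exchanges FP and FN, fixes TP and TN
    rev <- compare_pixels(list(cad = b, printed = a))
    expect_equal(rev$TP, pc$TP); expect_equal(rev$TN, pc$TN)
    expect_equal(rev$FP, pc$FN); expect_equal(rev$FN, pc$FP)
  }
  m <- random_small_mask()
  same <- compare_pixels(list(cad = m, printed = m))
  expect_equal(same$FP + same$FN, 0)
  expect_equal(same$TP, sum(m))
  comp <- compare_pixels(list(cad = m,
                              printed = binary_mask(1L - mnaqc:::mask_matrix(m))))
  expect_equal(comp$TP, 0); expect_equal(comp$TN, 0)
  expect_error(compare_pixels(list(cad = m, printed = random_small_mask(5, 5))),
               "dimension mismatch")
})
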
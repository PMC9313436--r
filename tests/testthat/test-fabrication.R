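test_that("zero-magnitude artifacts leave the CAD mask untouched", {
  arr <- clean_test_array()
  pr <- simulate_print(arr, no_artifact_params())
  expect_identical(mnaqc:::mask_matrix(pr$mask), mnaqc:::mask_matrix(arr))
  expect_true(all(pr$ground_truth$label_print == "non-defective"))
})

test_that("guaranteed stringing bridges every gap", {
  arr <- clean_test_array()
  pr <- simulate_print(arr, print_params(p_string = 1, p_defect = 0,
                                         roughness_sigma_um = 0, seed = 3))
  st <- attr(pr$ground_truth, "strings")
  expect_length(st, 9)                      # one string per gap
  # the 10 needle components merge into a single component above the base
  expect_equal(count_components_above_base(pr$mask), 1)
  expect_true(all(pr$ground_truth$string_touch))
})

test_that("printing is bit-identical under a fixed seed", {
  arr <- clean_test_array()
  p <- print_params(seed = 11)
  pr1 <- simulate_print(arr, p)
  pr2 <- simulate_print(arr, p)
  expect_identical(mnaqc:::mask_matrix(pr1$mask),
                   mnaqc:::mask_matrix(pr2$mask))
  expect_identical(pr1$ground_truth, pr2$ground_truth)
})

test_that("zero dose is the identity and doses are validated", {
  arr <- clean_test_array()
  pr <- simulate_print(arr, print_params(seed = 5))
  et0 <- simulate_etch(pr$mask, etching_dose(5, 0))
  expect_identical(mnaqc:::mask_matrix(et0), mnaqc:::mask_matrix(pr$mask))
  expect_error(etching_dose(2, 10), "out of validated range")
  expect_error(etching_dose(25, 10), "out of validated range")
})

test_that("stronger doses erode strictly nested pixel sets", {
  arr <- clean_test_array(design = mn_design(1500, 2500, 5))
  pr <- simulate_print(arr, print_params(seed = 9))
  doses <- list(etching_dose(3, 4), etching_dose(4, 14), etching_dose(5, 18),
                etching_dose(6, 24))
  masks <- lapply(doses, function(d) simulate_etch(pr$mask, d))
  for (i in seq_len(length(masks) - 1)) {
    a <- mnaqc:::mask_matrix(masks[[i]])
    b <- mnaqc:::mask_matrix(masks[[i + 1]])
    # every foreground pixel at the stronger dose is foreground at the milder
    expect_true(all(a[b == 1L] == 1L))
  }
})

test_that("the default etch rate reproduces the reference-case base diameter", {
  # 1000 um base, 2500 um height, 5 deg draft; 5 M x 18 h
  arr <- render_array(mn_design(1000, 2500, 5))
  pr <- simulate_print(arr, print_params(seed = 1))
  et <- simulate_etch(pr$mask, etching_dose(5, 18))
  base <- mean(measure_needles(et)$base_um)
  expect_lt(abs(base - 952), 25)
})

test_that("strong doses embrittle tall designs but not short ones", {
  tall <- render_array(mn_design(1000, 3000, 5))
  short <- render_array(mn_design(1000, 2000, 0))
  broken_tall <- logical(0)
  for (s in 1:5) {
    pr <- simulate_print(tall, print_params(seed = s))
    et <- simulate_etch(pr$mask, etching_dose(6, 24))
    broken_tall <- c(broken_tall, attr(et, "broken"))
  }
  expect_gt(mean(broken_tall), 0.3)        # elevated breakage probability
  prs <- simulate_print(short, print_params(seed = 1))
  ets <- simulate_etch(prs$mask, etching_dose(6, 24))
  expect_false(any(attr(ets, "broken")))
  # mild dose never embrittles
  prm <- simulate_print(tall, print_params(seed = 1))
  etm <- simulate_etch(prm$mask, etching_dose(3, 7))
  expect_false(any(attr(etm, "broken")))
})

test_that("generate_dataset is deterministic and rejects empty input", {
  expect_error(generate_dataset(condition_grid()[0, ]), "empty condition")
  conds <- condition_grid(study_designs()[1, ], c(3, 5), c(4, 18))
  d1 <- generate_dataset(conds, print_params(seed = 2))
  d2 <- generate_dataset(conds, print_params(seed = 2))
  expect_equal(length(d1), 4)
  for (k in seq_along(d1)) {
    expect_identical(mnaqc:::mask_matrix(d1[[k]]$etched),
                     mnaqc:::mask_matrix(d2[[k]]$etched))
    expect_identical(d1[[k]]$ground_truth, d2[[k]]$ground_truth)
  }
})

test_that("dataset records carry post-etch labels and realized dimensions", {
  conds <- condition_grid(study_designs()[2, ], c(3, 6), c(4, 24))
  ds <- generate_dataset(conds, print_params(seed = 4))
  for (rec in ds) {
    gt <- rec$ground_truth
    expect_equal(nrow(gt), 10)
    expect_true(all(gt$label %in% c("defective", "non-defective")))
    expect_true(all(gt$base_um >= 0 & gt$height_um >= 0))
  }
  # the strong-dose record must not have more remaining material
  expect_lt(sum(ds[[4]]$etched), sum(ds[[1]]$etched))
})
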
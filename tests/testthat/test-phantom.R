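test_that("datasets are reproducible byte-for-byte from (params, seed)", {
  p <- coarse_params(seed = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(p, 6, 0.5, seed = 5, dir = d1)
  generate_dataset(p, 6, 0.5, seed = 5, dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  img <- setdiff(f1, "run_log.json")
  expect_identical(unname(tools::md5sum(file.path(d1, img))),
                   unname(tools::md5sum(file.path(d2, img))))
})

test_that("label allocation is deterministic, not sampled", {
  ds <- generate_dataset(coarse_params(), 100, 0.5, seed = 9)
  expect_identical(sum(ds$manifest$label == "malignant"), 50L)
  ds2 <- generate_dataset(coarse_params(), 10, 0.3, seed = 9)
  expect_identical(sum(ds2$manifest$label == "malignant"), 3L)
})

test_that("zero artifact probability yields zero artifacts", {
  p <- coarse_params(artifact_prob_deep = 0, lesion_depth_range = c(22, 28),
                     lesion_axes_range = c(2, 4))
  ds <- generate_dataset(p, 30, 0.5, seed = 2)
  expect_false(any(ds$manifest$artifact_flag))
})

test_that("deep-lesion artifact rate matches its binomial target", {
  ## every lesion deeper than 20 mm; rate 0.259 as reported for real EUS
  p <- coarse_params(lesion_depth_range = c(26, 30), lesion_axes_range = c(2, 4),
                     artifact_prob_deep = 0.259)
  ds <- generate_dataset(p, 1000, 0.5, seed = 31)
  expect_true(all(ds$manifest$tumor_depth_mm > 20))
  rate <- mean(ds$manifest$artifact_flag)
  half_width <- 1.96 * sqrt(0.259 * 0.741 / 1000)
  expect_gt(rate, 0.259 - half_width)
  expect_lt(rate, 0.259 + half_width)
})

test_that("a lesion at background stiffness has strain ratio near one", {
  p <- coarse_params(stiffness_background = 100L,
                     stiffness_benign_range = c(100L, 100L),
                     stiffness_malignant_range = c(200L, 220L))
  set.seed(4)
  cs <- generate_case(p, "benign")
  sr <- strain_ratio(cs$stiffness_truth, cs$roi,
                     select_reference_region(cs$stiffness_truth, cs$roi, size = 8L))
  expect_equal(sr$sr, 1, tolerance = 0.08)
})

test_that("EUS decodes back to the stored stiffness truth on artifact-free cases", {
  ds <- tiny_dataset(n = 8, seed = 7)
  clean <- Filter(function(cs) !cs$artifact_flag, ds$cases)
  expect_gt(length(clean), 0)
  for (cs in clean) {
    lev <- decode_pure_color(extract_pure_color(cs$eus, cs$bus), ds$bar)
    expect_identical(lev, cs$stiffness_truth)
    expect_equal(extract_pure_color(cs$eus, cs$bus), cs$pure, ignore_attr = TRUE)
  }
})

test_that("truth-derived strain ratios rank disjoint stiffness labels", {
  ds <- generate_dataset(coarse_params(artifact_prob_deep = 0), 500, 0.5, seed = 12)
  labels <- as.integer(ds$manifest$label == "malignant")
  ## the generative lesion stiffness itself ranks perfectly by construction
  drawn <- vapply(ds$cases, function(cs) {
    cs$lesion_stiffness / ds$params$stiffness_background
  }, numeric(1))
  expect_identical(auc_bruteforce(drawn, labels), 1)
  ## SR measured on the rendered truth map: the ROI bounding box dilutes the
  ## lesion mean with background pixels, so ranking is near-perfect
  sr <- vapply(ds$cases, function(cs) {
    strain_ratio(cs$stiffness_truth, cs$roi,
                 select_reference_region(cs$stiffness_truth, cs$roi, size = 6L))$sr
  }, numeric(1))
  expect_gte(auc_bruteforce(sr, labels), 0.99)
  expect_gt(auc_ci(sr, labels)$auc, 0.9)
})

test_that("attenuation artifacts corrupt the EUS but never the truth", {
  p <- coarse_params(lesion_depth_range = c(26, 30), lesion_axes_range = c(2, 4),
                     artifact_prob_deep = 0)
  set.seed(8)
  cs <- generate_case(p, "malignant")
  corrupted <- inject_attenuation_artifact(cs)
  expect_true(corrupted$artifact_flag)
  expect_identical(corrupted$stiffness_truth, cs$stiffness_truth)
  expect_false(identical(corrupted$eus, cs$eus))
  ## decoded SR from the corrupted EUS departs from the truth-derived SR
  ref <- select_reference_region(cs$stiffness_truth, cs$roi, size = 6L)
  lev_c <- decode_pure_color(extract_pure_color(corrupted$eus, corrupted$bus),
                             default_color_bar(value = p$overlay_weight))
  sr_c <- strain_ratio(lev_c, cs$roi, ref)$sr
  sr_t <- strain_ratio(cs$stiffness_truth, cs$roi, ref)$sr
  expect_false(isTRUE(all.equal(sr_c, sr_t)))
})

test_that("artifact injection is a warning no-op for shallow lesions", {
  p <- coarse_params(lesion_depth_range = c(8, 12), artifact_prob_deep = 0)
  set.seed(9)
  cs <- generate_case(p, "benign")
  expect_warning(out <- inject_attenuation_artifact(cs), "shallower")
  expect_identical(out, cs)
})

test_that("decoded tumor stiffness of corrupted deep malignant cases is biased low", {
  p <- coarse_params(lesion_depth_range = c(26, 30), lesion_axes_range = c(2, 4),
                     artifact_prob_deep = 0)
  set.seed(10)
  bar <- default_color_bar(value = p$overlay_weight)
  deltas <- replicate(12, {
    cs <- inject_attenuation_artifact(generate_case(p, "malignant"))
    lev <- decode_pure_color(extract_pure_color(cs$eus, cs$bus), bar)
    rr <- cs$roi
    rows <- (rr["row"] + 1):(rr["row"] + rr["height"])
    cols <- (rr["col"] + 1):(rr["col"] + rr["width"])
    mean(lev[rows, cols]) - mean(cs$stiffness_truth[rows, cols])
  })
  expect_lt(mean(deltas), 0)
})

test_that("depth bookkeeping follows the row-equals-depth convention", {
  ds <- tiny_dataset(n = 8, seed = 7)
  p <- ds$params
  for (cs in ds$cases) {
    expect_equal(cs$tumor_depth_mm, cs$roi["row"] * p$pixel_spacing,
                 ignore_attr = TRUE)
    expect_lte(cs$roi["row"] + cs$roi["height"], p$image_size)
    expect_lte(cs$roi["col"] + cs$roi["width"], p$image_size)
  }
})

test_that("impossible lesion geometry fails with an explicit error", {
  p <- coarse_params(lesion_depth_range = c(50, 60))  # beyond the 38.4 mm field
  set.seed(11)
  expect_error(generate_case(p, "benign"), "does not fit")
})

test_that("a dataset survives the PNG round trip exactly", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(coarse_params(), 4, 0.5, seed = 13, dir = dir)
  back <- read_dataset(dir)
  for (i in seq_along(ds$cases)) {
    expect_equal(back$cases[[i]]$bus, ds$cases[[i]]$bus, ignore_attr = TRUE)
    expect_equal(back$cases[[i]]$eus, ds$cases[[i]]$eus, ignore_attr = TRUE)
    expect_equal(matrix(back$cases[[i]]$stiffness_truth,
                        nrow = nrow(ds$cases[[i]]$stiffness_truth)),
                 matrix(ds$cases[[i]]$stiffness_truth,
                        nrow = nrow(ds$cases[[i]]$stiffness_truth)),
                 ignore_attr = TRUE)
  }
  expect_identical(unclass(back$bar), unclass(ds$bar))
})
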
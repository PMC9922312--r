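test_that("the reference region sits at tumor depth, flush to the wider margin", {
  lev <- matrix(100L, 50, 50)
  roi <- roi_box(12, 20, 10, 10)          # wider margin on the right (20 left vs 20 right: tie -> left)
  ref <- select_reference_region(lev, roi, size = 10L)
  expect_identical(unname(ref["col"]), 0L)
  expect_identical(unname(ref["row"]), 12L)
  roi2 <- roi_box(12, 5, 10, 10)          # right margin 35 > left margin 5
  ref2 <- select_reference_region(lev, roi2, size = 10L)
  expect_identical(unname(ref2["col"]), 40L)
  expect_error(select_reference_region(lev, roi, size = 30L), "smaller size")
})

test_that("reference placement never intersects the tumor box", {
  set.seed(21)
  lev <- matrix(1L, 64, 64)
  for (i in 1:100) {
    h <- sample(5:20, 1); w <- sample(5:20, 1)
    roi <- roi_box(sample(0:(64 - h), 1), sample(0:(64 - w), 1), h, w)
    ref <- tryCatch(select_reference_region(lev, roi, size = 12L),
                    error = function(e) NULL)
    if (is.null(ref)) next
    overlap <- !(roi["row"] + roi["height"] <= ref["row"] ||
                 ref["row"] + ref["height"] <= roi["row"] ||
                 roi["col"] + roi["width"] <= ref["col"] ||
                 ref["col"] + ref["width"] <= roi["col"])
    expect_false(overlap)
  }
})

test_that("strain ratio is the ratio of mean levels", {
  lev <- matrix(120L, 40, 40)
  roi <- roi_box(5, 5, 8, 8); ref <- roi_box(5, 30, 8, 8)
  expect_equal(strain_ratio(lev, roi, ref)$sr, 1)
  lev[6:13, 6:13] <- 200L
  lev[6:13, 31:38] <- 100L
  expect_equal(strain_ratio(lev, roi, ref)$sr, 2)
  expect_error(strain_ratio(lev, roi, roi_box(6, 6, 8, 8)), "overlap")
})

test_that("strain ratio from decoded EUS matches the truth within quantization", {
  ds <- tiny_dataset(n = 8, seed = 7)
  clean <- Filter(function(cs) !cs$artifact_flag, ds$cases)
  for (cs in clean[seq_len(min(4, length(clean)))]) {
    lev <- decode_pure_color(extract_pure_color(cs$eus, cs$bus), ds$bar)
    ref <- select_reference_region(lev, cs$roi, size = 12L)
    expect_equal(strain_ratio(lev, cs$roi, ref)$sr,
                 strain_ratio(cs$stiffness_truth, cs$roi, ref)$sr,
                 tolerance = 0.02)
  }
})

test_that("global SSIM matches a direct evaluation of its formula", {
  r <- matrix(c(10, 50, 90, 200), 2, 2)
  v <- matrix(c(20, 40, 100, 180), 2, 2)
  L <- 255; C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mu_r <- mean(r); mu_v <- mean(v)
  var_r <- mean((r - mu_r)^2); var_v <- mean((v - mu_v)^2)
  cov_rv <- mean((r - mu_r) * (v - mu_v))
  expected <- ((2 * mu_r * mu_v + C1) * (2 * cov_rv + C2)) /
    ((mu_r^2 + mu_v^2 + C1) * (var_r + var_v + C2))
  expect_equal(ssim_global(r, v), expected)
})

test_that("SSIM is 1 on identical images, symmetric, and never above 1", {
  set.seed(22)
  img <- random_rgb(12, 12)
  expect_identical(ssim_global(img, img), 1)
  for (i in 1:20) {
    a <- random_rgb(8, 8); b <- random_rgb(8, 8)
    expect_equal(ssim_global(a, b), ssim_global(b, a))
    expect_lte(ssim_global(a, b), 1)
  }
  ## per-pixel channel shuffling breaks structure
  shuffled <- img[, , c(2, 3, 1)]
  expect_lt(ssim_global(img, shuffled), 1)
  expect_error(ssim_global(img, random_rgb(6, 6)), "mismatch")
})

test_that("strain-ratio MAPE follows its formula and scale invariance", {
  expect_identical(sr_mape(c(1.5, 2.5), c(1.5, 2.5)), 0)
  expect_equal(sr_mape(c(2, 4), c(1, 5)), 0.375)
  set.seed(23)
  a <- runif(10, 0.5, 4); b <- runif(10, 0.5, 4)
  expect_equal(sr_mape(3.7 * a, 3.7 * b), sr_mape(a, b))
  expect_gte(sr_mape(a, b), 0)
  expect_error(sr_mape(c(1, 2), c(1, 2, 3)), "length mismatch")
  expect_error(sr_mape(c(1, -2), c(1, 2)), "positive")
})

test_that("color histogram correlation hits its limiting values", {
  set.seed(24)
  img <- random_rgb(10, 10)
  expect_equal(chc(img, img), 1)
  ## disjoint hue and saturation supports -> 0
  red <- array(rep(c(255, 0, 0), each = 100), dim = c(10, 10, 3))
  pale_green <- array(rep(c(128, 255, 128), each = 100), dim = c(10, 10, 3))
  expect_equal(chc(red, pale_green), 0)
  ## histograms are invariant to spatial shuffling
  perm <- sample(100)
  shuf <- array(apply(img, 3, function(ch) ch[perm]), dim = c(10, 10, 3))
  expect_equal(chc(img, shuf), 1)
  for (i in 1:10) {
    a <- random_rgb(6, 6); b <- random_rgb(6, 6)
    val <- chc(a, b)
    expect_gte(val, 0); expect_lte(val, 1)
  }
  expect_error(chc(img, random_rgb(6, 6)), "mismatch")
})

test_that("compare_images bundles the three metrics", {
  set.seed(25)
  a <- random_rgb(10, 10); b <- random_rgb(10, 10)
  rep <- compare_images(a, b, sr_real = c(2, 4), sr_virtual = c(1, 5))
  expect_equal(rep$ssim, ssim_global(a, b))
  expect_equal(rep$chc, chc(a, b))
  expect_equal(rep$mape, 0.375)
  expect_equal(rep$C1, (0.01 * 255)^2)
})
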
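test_that("the default generator config reproduces the published channel plan", {
  cfg <- generator_config()
  expect_identical(cfg$encoder_channels, c(64L, 128L, 256L, 512L, 512L, 512L, 512L))
  expect_identical(cfg$decoder_in_channels,
                   c(512L, 1024L, 1024L, 1024L, 512L, 256L, 128L))
  expect_identical(cfg$kernel_size, 4L)
  dcfg <- discriminator_config()
  expect_identical(dcfg$channels, c(64L, 128L, 256L, 512L, 512L, 1L))
  expect_identical(dcfg$input_channels, 4L)
})

test_that("the generator maps a 256-pixel BUS to a bounded 3-channel EUS through a 2x2 bottleneck", {
  set.seed(51)
  gen <- build_generator(generator_config())
  x <- array(runif(256 * 256, -1, 1), c(256, 256, 1))
  out <- generator_forward(gen, x, train = FALSE, return_hidden = TRUE)
  expect_identical(dim(out$output), c(256L, 256L, 3L))
  expect_true(all(out$output >= -1 & out$output <= 1))
  expect_identical(dim(out$hidden[[7]]), c(2L, 2L, 512L))
})

test_that("the tiny generator behaves identically in kind at 64 pixels", {
  set.seed(52)
  gen <- build_generator(tiny_generator_config())
  x <- array(runif(64 * 64, -1, 1), c(64, 64, 1))
  out <- generator_forward(gen, x, return_hidden = TRUE)
  expect_identical(dim(out$output), c(64L, 64L, 3L))
  expect_identical(dim(out$hidden[[4]]), c(4L, 4L, 64L))
  expect_error(generator_forward(gen, array(0, c(60, 60, 1))), "divisible")
})

test_that("the discriminator emits a spatial patch map with local receptive fields", {
  set.seed(53)
  d <- build_discriminator(tiny_discriminator_config())
  x <- array(runif(64 * 64 * 4, -1, 1), c(64, 64, 4))
  z <- discriminator_forward(d, x)
  expect_identical(dim(z)[3], 1L)
  expect_gt(dim(z)[1], 1)
  expect_error(discriminator_forward(d, array(0, c(64, 64, 3))), "4-channel")
  ## perturbing one pixel only moves patch scores within the receptive field
  x2 <- x
  x2[32, 32, 1] <- x2[32, 32, 1] + 5
  z2 <- discriminator_forward(d, x2)
  changed <- which(abs(z2 - z) > 1e-12, arr.ind = TRUE)
  expect_gt(nrow(changed), 0)
  ## receptive field of k=4 with strides 2,2,2,1: 46 pixels, radius 23;
  ## map position scale is 8 input pixels per patch at the stride-2 depth
  centers_r <- (changed[, 1] - 1) * 8 + 4
  centers_c <- (changed[, 2] - 1) * 8 + 4
  expect_true(all(abs(centers_r - 32) <= 30 & abs(centers_c - 32) <= 30))
})

test_that("rebalance weights follow the closed forms of the mixing formula", {
  ## two far-apart colors, equally frequent: uniform empirical distribution
  half <- array(rep(c(255, 0, 0, 0, 0, 255), each = 8), dim = c(4, 4, 3))
  tab <- fit_rebalance_table(half, alpha = 0.8, normalize = FALSE)
  expect_identical(tab$Q, 2L)
  expect_equal(tab$gamma, c(2, 2))            # uniform P~ -> gamma = Q
  tab0 <- fit_rebalance_table(half, alpha = 0, normalize = FALSE)
  expect_equal(tab0$gamma, rep(tab0$Q, tab0$Q))
  tab1 <- fit_rebalance_table(half, alpha = 1, normalize = FALSE)
  expect_equal(tab1$gamma, c(2, 2))           # alpha = 1, P~ = 0.5 -> 2
  expect_error(fit_rebalance_table(list()), "at least one")
})

test_that("rarer colors always get larger weights, and weights stay positive", {
  set.seed(54)
  ds <- tiny_dataset(n = 4, seed = 7)
  tab <- fit_rebalance_table(lapply(ds$cases, `[[`, "eus"), alpha = 0.8)
  expect_true(all(tab$gamma > 0))
  ord <- order(tab$p)
  expect_true(all(diff(tab$gamma[ord]) <= 1e-12))
  expect_equal(sum(tab$p * tab$gamma), 1)     # normalized expectation
  w <- rebalance_weights(tab, ds$cases[[1]]$eus)
  expect_identical(dim(w), dim(ds$cases[[1]]$bus))
  expect_true(all(w > 0))
})

test_that("loss surfaces hit their closed forms", {
  y <- array(runif(48, -1, 1), c(4, 4, 3))
  ## indistinguishable outputs at chance-level discriminators
  gl <- generator_loss(y, y, d_global_prob = 0.5, d_tumor_prob = 0.5)
  expect_equal(gl$l1, 0)
  expect_equal(gl$total, 2 * log(2), tolerance = 1e-6)
  ## perfect fool
  gl2 <- generator_loss(y, y, d_global_prob = 1, d_tumor_prob = 1)
  expect_equal(gl2$total, 0, tolerance = 1e-6)
  ## lambda scales only the L1 component
  y2 <- y + 0.1
  a <- generator_loss(y2, y, 0.5, 0.5, lambda = 100)
  b <- generator_loss(y2, y, 0.5, 0.5, lambda = 200)
  expect_equal(b$l1, 2 * a$l1)
  expect_equal(b$adv_global, a$adv_global)
  ## discriminator at probability one half, and in the correct-classification limit
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-6)
  expect_equal(discriminator_loss(1, 0), 0, tolerance = 1e-6)
  ## exchanging real/virtual with exchanged labels leaves the value unchanged
  expect_equal(discriminator_loss(0.8, 0.3), discriminator_loss(1 - 0.3, 1 - 0.8))
  expect_equal(combined_loss(1, 0.4, 0.2), 1 + 0.5 * 0.4 + 0.5 * 0.2)
})

test_that("the learning-rate schedule is flat then linear to zero", {
  cfg <- veus_train_config()
  expect_equal(learning_rate_at(1, cfg), 2e-4)
  expect_equal(learning_rate_at(100, cfg), 2e-4)
  expect_equal(learning_rate_at(150, cfg), 1e-4)
  expect_equal(learning_rate_at(200, cfg), 0)
})

test_that("a smoke-scale training run yields finite losses and a working checkpoint", {
  ds <- tiny_dataset(n = 8, seed = 7)
  cfg <- veus_train_config(epochs = 2, lr_decay_start = 1, tumor_crop_size = 32L,
                           seed = 5L)
  m <- veus_gan(ds$cases, tiny_generator_config(), tiny_discriminator_config(), cfg)
  expect_s3_class(m, "veus_gan")
  expect_true(all(is.finite(as.matrix(m$history[, c("l1", "adv_g", "d_global", "d_tumor")]))))
  out1 <- synthesize(m, ds$cases[[1]]$bus)
  expect_identical(dim(out1), c(64L, 64L, 3L))
  expect_identical(out1, synthesize(m, ds$cases[[1]]$bus))  # inference determinism
  ## checkpoint round trip reproduces the forward pass exactly
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(synthesize(m2, ds$cases[[1]]$bus), out1)
  ## training is deterministic given the seed
  m3 <- veus_gan(ds$cases, tiny_generator_config(), tiny_discriminator_config(), cfg)
  expect_identical(synthesize(m3, ds$cases[[1]]$bus), out1)
  ## off-resolution inputs are resized through the trained grid
  small <- ds$cases[[1]]$bus[1:48, 1:48]
  expect_identical(dim(synthesize(m, small)), c(48L, 48L, 3L))
  expect_error(veus_gan(list(), train_config = cfg), "empty")
})

test_that("L1-only training improves the reconstruction over epochs", {
  ds <- tiny_dataset(n = 24, seed = 19)
  cfg <- veus_train_config(epochs = 10, lr_decay_start = 5, adversarial = FALSE,
                           seed = 6L)
  m <- veus_gan(ds$cases, tiny_generator_config(), tiny_discriminator_config(), cfg)
  expect_lt(m$history$l1[nrow(m$history)], m$history$l1[1])
})

test_that("the printed-form global discriminator objective stays available", {
  ds <- tiny_dataset(n = 4, seed = 7)
  cfg <- veus_train_config(epochs = 1, lr_decay_start = 1, tumor_crop_size = 32L,
                           global_d_on_real_only = TRUE, seed = 8L)
  m <- veus_gan(ds$cases, tiny_generator_config(), tiny_discriminator_config(), cfg)
  expect_true(all(is.finite(as.matrix(m$history[, c("l1", "d_global")]))))
})
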
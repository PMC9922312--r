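## Conditional adversarial BUS -> EUS translator: U-Net generator, global
## 4-channel patch discriminator, tumor-region patch discriminator,
## color-rebalanced L1, and alternating Adam training.

## ---- configurations -----------------------------------------------------

#' Generator architecture configuration
#'
#' A U-Net encoder-decoder with stride-2 4x4 convolutions, batch
#' normalization and concatenating skip connections. The default matches
#' the full-scale model: encoder output channels
#' 64, 128, 256, 512, 512, 512, 512 (input layer + 6 blocks), so a
#' 256-pixel input reaches a 2x2 bottleneck after 7 halvings, and the
#' decoder (6 blocks + output layer) sees input widths
#' 512, 1024, 1024, 1024, 512, 256, 128 after skip concatenation. The final
#' deconvolution maps 128 channels to the 3-channel EUS through a Tanh, so
#' outputs lie in `[-1, 1]`.
#'
#' @param encoder_channels Output channels of the encoder convolutions, one
#'   per downsampling; its length sets the depth.
#' @param kernel_size Convolution kernel side (all kernels are 4x4).
#' @param input_channels,output_channels Image channel counts.
#' @return An object of class `veus_generator_config`.
#' @export
generator_config <- function(encoder_channels = c(64L, 128L, 256L, 512L, 512L, 512L, 512L),
                             kernel_size = 4L, input_channels = 1L,
                             output_channels = 3L) {
  nd <- length(encoder_channels)
  stopifnot(nd >= 2L, all(encoder_channels > 0L), kernel_size >= 2L)
  dec_out <- c(rev(encoder_channels)[-1], output_channels)
  j <- seq_len(nd - 1L) + 1L   # decoder blocks after the first
  dec_in <- c(encoder_channels[nd], dec_out[j - 1L] + encoder_channels[nd - j + 1L])
  structure(list(encoder_channels = as.integer(encoder_channels),
                 decoder_in_channels = as.integer(dec_in),
                 decoder_out_channels = as.integer(dec_out),
                 n_down = nd, kernel_size = as.integer(kernel_size),
                 input_channels = as.integer(input_channels),
                 output_channels = as.integer(output_channels)),
            class = "veus_generator_config")
}

#' Discriminator architecture configuration
#'
#' A convolutional patch classifier on the 4-channel composite
#' (1-channel BUS concatenated with 3-channel EUS): a convolution, then
#' blocks of convolution + batch norm + leaky-ReLU, and a 1-channel output
#' convolution producing a spatial map of real/fake logits. Defaults match
#' the full-scale model (channels 64, 128, 256, 512, 512, 1; strides
#' 2, 2, 2, 1, 1, 1, giving a ~70-pixel receptive field).
#'
#' @param channels Output channels per convolution; the last must be 1.
#' @param strides Stride per convolution (same length as `channels`).
#' @param input_channels Channels of the composite input (4).
#' @param kernel_size Kernel side.
#' @return An object of class `veus_discriminator_config`.
#' @export
discriminator_config <- function(channels = c(64L, 128L, 256L, 512L, 512L, 1L),
                                 strides = c(2L, 2L, 2L, 1L, 1L, 1L),
                                 input_channels = 4L, kernel_size = 4L) {
  stopifnot(length(channels) == length(strides),
            channels[length(channels)] == 1L, all(strides %in% c(1L, 2L)))
  structure(list(channels = as.integer(channels), strides = as.integer(strides),
                 input_channels = as.integer(input_channels),
                 kernel_size = as.integer(kernel_size)),
            class = "veus_discriminator_config")
}

#' Reduced configurations for CPU-scale experiments
#'
#' A 4-level, base-width-8 generator (encoder channels 8, 16, 32, 64) and a
#' matching 4-layer patch discriminator intended for 64x64 inputs: the same
#' architecture family as the full-scale model, small enough to train on
#' one CPU core in minutes.
#'
#' @return A `veus_generator_config` / `veus_discriminator_config`.
#' @export
tiny_generator_config <- function() {
  generator_config(encoder_channels = c(8L, 16L, 32L, 64L))
}

#' @rdname tiny_generator_config
#' @export
tiny_discriminator_config <- function() {
  discriminator_config(channels = c(8L, 16L, 32L, 1L),
                       strides = c(2L, 2L, 2L, 1L))
}

#' Training configuration
#'
#' Defaults follow the full-scale recipe: 200 epochs, batch size 1, Adam
#' with learning rate 2e-4 decaying linearly to zero from epoch 100, L1
#' weight `lambda = 100`, both discriminator losses weighted 0.5, color
#' rebalancing with `alpha = 0.8`, and paired random flipping.
#'
#' @param epochs Training epochs.
#' @param learning_rate Adam learning rate.
#' @param lr_decay_start Epoch after which the rate decays linearly,
#'   reaching exactly zero at `epochs`.
#' @param beta1,beta2 Adam moment coefficients.
#' @param lambda_l1 Weight of the (rebalanced) L1 term.
#' @param d_loss_weight Weight of each discriminator loss in the combined
#'   objective.
#' @param alpha Rebalance mixing weight on `[0, 1]` (see
#'   [fit_rebalance_table()]).
#' @param ab_bin_width Lab ab-plane quantization step.
#' @param rebalance Fit and apply the color-rebalance weights.
#' @param gamma_normalize Rescale gamma so its expectation under the
#'   empirical color distribution is 1 (keeps the L1 term on the same scale
#'   as plain L1); raw Eq-style weights when `FALSE`.
#' @param adversarial Include the adversarial terms; `FALSE` trains the
#'   generator with (rebalanced) L1 only.
#' @param tumor_discriminator Include the tumor-region discriminator.
#' @param tumor_crop_size Side length the tumor crop is resized to before
#'   the tumor discriminator (nearest-neighbour).
#' @param global_d_on_real_only Use the printed variant of the global
#'   discriminator objective in which both terms see the real pair (kept
#'   for fidelity experiments; it detaches the discriminator from the
#'   generator and is presumed a typo).
#' @param flip Random paired horizontal flip augmentation.
#' @param crop_pad Random-crop augmentation: images are padded by this many
#'   pixels (edge replication) and a random window of the original size is
#'   cut; 0 disables.
#' @param diffaug Differentiable-augmentation policy applied to both
#'   discriminator inputs: any of `"brightness"`, `"translation"`.
#' @param seed Integer seed for weight init, augmentation and data order.
#' @return An object of class `veus_train_config`.
#' @export
veus_train_config <- function(epochs = 200L, learning_rate = 2e-4,
                              lr_decay_start = 100L, beta1 = 0.5, beta2 = 0.999,
                              lambda_l1 = 100, d_loss_weight = 0.5,
                              alpha = 0.8, ab_bin_width = 10,
                              rebalance = TRUE, gamma_normalize = TRUE,
                              adversarial = TRUE, tumor_discriminator = TRUE,
                              tumor_crop_size = 128L,
                              global_d_on_real_only = FALSE,
                              flip = TRUE, crop_pad = 0L,
                              diffaug = character(0), seed = 1L) {
  stopifnot(epochs >= 1L, learning_rate > 0, lr_decay_start >= 1L,
            lr_decay_start <= epochs, lambda_l1 >= 0, d_loss_weight > 0,
            alpha >= 0, alpha <= 1, ab_bin_width > 0, tumor_crop_size >= 8L,
            all(diffaug %in% c("brightness", "translation")))
  structure(list(epochs = as.integer(epochs), batch_size = 1L,
                 learning_rate = learning_rate,
                 lr_decay_start = as.integer(lr_decay_start),
                 beta1 = beta1, beta2 = beta2, lambda_l1 = lambda_l1,
                 d_loss_weight = d_loss_weight, alpha = alpha,
                 ab_bin_width = ab_bin_width, rebalance = rebalance,
                 gamma_normalize = gamma_normalize, adversarial = adversarial,
                 tumor_discriminator = tumor_discriminator,
                 tumor_crop_size = as.integer(tumor_crop_size),
                 global_d_on_real_only = global_d_on_real_only,
                 flip = flip, crop_pad = as.integer(crop_pad),
                 diffaug = diffaug, seed = as.integer(seed)),
            class = "veus_train_config")
}

#' Learning rate at a given epoch
#'
#' Constant at `learning_rate` through `lr_decay_start`, then linear decay
#' reaching exactly 0 at the final epoch.
#'
#' @param epoch Epoch number (1-based).
#' @param config A [veus_train_config()].
#' @return The learning rate.
#' @export
learning_rate_at <- function(epoch, config) {
  with(config, {
    if (epoch <= lr_decay_start || epochs == lr_decay_start) return(learning_rate)
    learning_rate * max(0, 1 - (epoch - lr_decay_start) / (epochs - lr_decay_start))
  })
}

## ---- networks -----------------------------------------------------------

#' Build the U-Net generator
#'
#' @param cfg A [generator_config()].
#' @return An object of class `veus_generator`.
#' @export
build_generator <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "veus_generator_config"))
  nd <- cfg$n_down; k <- cfg$kernel_size
  enc_in <- c(cfg$input_channels, cfg$encoder_channels[-nd])
  enc_convs <- lapply(seq_len(nd), function(i) {
    new_conv(enc_in[i], cfg$encoder_channels[i], k = k, stride = 2L, pad = 1L)
  })
  enc_bns <- lapply(seq_len(nd - 1L), function(i) new_bn(cfg$encoder_channels[i + 1L]))
  dec_tconvs <- lapply(seq_len(nd), function(j) {
    new_tconv(cfg$decoder_in_channels[j], cfg$decoder_out_channels[j],
              k = k, stride = 2L, pad = 1L)
  })
  dec_bns <- lapply(seq_len(nd - 1L), function(j) new_bn(cfg$decoder_out_channels[j]))
  structure(list(cfg = cfg, enc_convs = enc_convs, enc_bns = enc_bns,
                 dec_tconvs = dec_tconvs, dec_bns = dec_bns),
            class = "veus_generator")
}

gen_layers <- function(g) c(g$enc_convs, g$enc_bns, g$dec_tconvs, g$dec_bns)

#' Run the generator forward
#'
#' @param gen A `veus_generator`.
#' @param x Input array `H x W x 1` with values on `[-1, 1]`; `H` and `W`
#'   must be divisible by `2^n_down`.
#' @param train Batch-norm mode: batch statistics (`TRUE`) or running
#'   statistics (`FALSE`, deterministic inference).
#' @param return_hidden Also return the list of encoder activations.
#' @return `H x W x 3` array on `[-1, 1]` (or a list with `output` and
#'   `hidden` when `return_hidden`).
#' @export
generator_forward <- function(gen, x, train = FALSE, return_hidden = FALSE) {
  stopifnot(inherits(gen, "veus_generator"))
  d <- dim(x); nd <- gen$cfg$n_down
  if (length(d) != 3L || d[3] != gen$cfg$input_channels) {
    stop("generator input must be H x W x ", gen$cfg$input_channels)
  }
  if (d[1] %% 2^nd != 0L || d[2] %% 2^nd != 0L) {
    stop(sprintf("input size %dx%d not divisible by 2^%d", d[1], d[2], nd))
  }
  cache <- list(x = x, enc = vector("list", nd), enc_pre = vector("list", nd),
                dec_pre = vector("list", nd), dec_cat = vector("list", nd))
  a <- conv_fw(gen$enc_convs[[1]], x)
  cache$enc[[1]] <- a
  for (i in 2:nd) {
    cache$enc_pre[[i]] <- a           # input of the block's ReLU
    r <- relu_fw(a)
    a <- bn_fw(gen$enc_bns[[i - 1L]], conv_fw(gen$enc_convs[[i]], r), train)
    cache$enc[[i]] <- a
  }
  h <- a
  for (j in seq_len(nd - 1L)) {
    cache$dec_pre[[j]] <- h
    r <- relu_fw(h)
    t <- bn_fw(gen$dec_bns[[j]], tconv_fw(gen$dec_tconvs[[j]], r), train)
    skip <- cache$enc[[nd - j]]
    cache$dec_cat[[j]] <- dim(t)[3]   # channels contributed by the decoder
    h <- array(c(t, skip), dim = c(dim(t)[1], dim(t)[2], dim(t)[3] + dim(skip)[3]))
  }
  cache$dec_pre[[nd]] <- h
  y <- tanh(tconv_fw(gen$dec_tconvs[[nd]], relu_fw(h)))
  cache$y <- y
  gen$enc_convs[[1]]$unet_cache <- cache  # stash on a stable environment
  if (return_hidden) list(output = y, hidden = cache$enc) else y
}

## backward through the generator; accumulates parameter gradients
generator_backward <- function(gen, dy) {
  nd <- gen$cfg$n_down
  cache <- gen$enc_convs[[1]]$unet_cache
  dpre <- tanh_bw(dy, cache$y)
  dh <- relu_bw(tconv_bw(gen$dec_tconvs[[nd]], dpre), cache$dec_pre[[nd]])
  denc <- vector("list", nd)          # grads flowing into encoder outputs
  for (j in rev(seq_len(nd - 1L))) {
    nt <- cache$dec_cat[[j]]
    dt <- dh[, , seq_len(nt), drop = FALSE]
    denc[[nd - j]] <- dh[, , -seq_len(nt), drop = FALSE]
    dh <- relu_bw(tconv_bw(gen$dec_tconvs[[j]], bn_bw(gen$dec_bns[[j]], dt)),
                  cache$dec_pre[[j]])
  }
  da <- dh                            # gradient at the bottleneck enc[nd]
  for (i in rev(2:nd)) {
    if (!is.null(denc[[i]])) da <- da + denc[[i]]
    da <- relu_bw(conv_bw(gen$enc_convs[[i]], bn_bw(gen$enc_bns[[i - 1L]], da)),
                  cache$enc_pre[[i]])
  }
  if (!is.null(denc[[1]])) da <- da + denc[[1]]
  conv_bw(gen$enc_convs[[1]], da)
}

#' Build a patch discriminator
#'
#' @param cfg A [discriminator_config()].
#' @return An object of class `veus_discriminator`.
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  stopifnot(inherits(cfg, "veus_discriminator_config"))
  nl <- length(cfg$channels)
  ins <- c(cfg$input_channels, cfg$channels[-nl])
  convs <- lapply(seq_len(nl), function(i) {
    new_conv(ins[i], cfg$channels[i], k = cfg$kernel_size,
             stride = cfg$strides[i], pad = 1L)
  })
  bns <- lapply(seq_len(max(0L, nl - 2L)),
                function(i) new_bn(cfg$channels[i + 1L]))
  structure(list(cfg = cfg, convs = convs, bns = bns),
            class = "veus_discriminator")
}

disc_layers <- function(d) c(d$convs, d$bns)

#' Run a discriminator forward
#'
#' @param disc A `veus_discriminator`.
#' @param x Composite input array (`H x W x 4` for the default config).
#' @param train Batch-norm mode.
#' @return A spatial map of real/fake logits (`h x w x 1`).
#' @export
discriminator_forward <- function(disc, x, train = FALSE) {
  stopifnot(inherits(disc, "veus_discriminator"))
  if (dim(x)[3] != disc$cfg$input_channels) {
    stop("discriminator expects ", disc$cfg$input_channels, "-channel input, got ",
         dim(x)[3])
  }
  nl <- length(disc$convs)
  pre <- vector("list", nl)
  a <- conv_fw(disc$convs[[1]], x)
  for (i in 2:(nl - 1L)) {
    pre[[i - 1L]] <- a
    a <- conv_fw(disc$convs[[i]], lrelu_fw(a))
    a <- bn_fw(disc$bns[[i - 1L]], a, train)
  }
  pre[[nl - 1L]] <- a
  z <- conv_fw(disc$convs[[nl]], lrelu_fw(a))
  disc$convs[[1]]$d_cache <- pre
  z
}

discriminator_backward <- function(disc, dz) {
  nl <- length(disc$convs)
  pre <- disc$convs[[1]]$d_cache
  da <- lrelu_bw(conv_bw(disc$convs[[nl]], dz), pre[[nl - 1L]])
  for (i in rev(2:(nl - 1L))) {
    da <- bn_bw(disc$bns[[i - 1L]], da)
    da <- lrelu_bw(conv_bw(disc$convs[[i]], da), pre[[i - 1L]])
  }
  conv_bw(disc$convs[[1]], da)
}

## ---- color rebalancing --------------------------------------------------

#' Fit the color-rebalance table from training EUS images
#'
#' Pixels are mapped to CIE Lab; their (a, b) chroma coordinates are
#' quantized on a grid of step `bin_width`; `Q` is the number of occupied
#' bins and `P~` the empirical distribution over them. Each bin's weight is
#' `gamma_p = (alpha * P~_p + (1 - alpha) / Q)^(-1)`,
#' so rare colors are up-weighted whenever `alpha > 0`. With
#' `normalize = TRUE` (the package default during training) gamma is
#' rescaled so that its expectation under `P~` is 1, keeping the weighted
#' L1 on the same scale as a plain L1; `normalize = FALSE` gives the raw
#' weights (magnitude about `Q`).
#'
#' @param eus_images List of RGB images (`H x W x 3`, values on
#'   `[0, 255]`), or a single image.
#' @param alpha Mixing weight between the empirical and uniform
#'   distributions, on `[0, 1]`.
#' @param bin_width ab-plane grid step.
#' @param normalize Rescale to unit expectation under `P~`.
#' @return An object of class `veus_rebalance`: list with `alpha`,
#'   `bin_width`, `Q`, `keys`, `p` (empirical distribution), `gamma`, and
#'   `normalized`.
#' @export
fit_rebalance_table <- function(eus_images, alpha = 0.8, bin_width = 10,
                                normalize = TRUE) {
  if (is.array(eus_images) || is.matrix(eus_images)) eus_images <- list(eus_images)
  if (length(eus_images) == 0L) stop("need at least one EUS image")
  stopifnot(alpha >= 0, alpha <= 1, bin_width > 0)
  keys <- unlist(lapply(eus_images, function(img) {
    check_rgb(img, "EUS image")
    ab_bin_keys(img, bin_width)
  }))
  counts <- table(keys)
  Q <- length(counts)
  p <- as.numeric(counts) / sum(counts)
  gamma <- 1 / (alpha * p + (1 - alpha) / Q)
  norm_const <- sum(p * gamma)
  if (normalize) gamma <- gamma / norm_const
  structure(list(alpha = alpha, bin_width = bin_width, Q = Q,
                 keys = names(counts), p = p, gamma = gamma,
                 normalized = normalize, norm_const = norm_const),
            class = "veus_rebalance")
}

ab_bin_keys <- function(img, bin_width) {
  px <- matrix(as.numeric(img), ncol = 3L) / 255
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  paste(floor(lab[, 2] / bin_width), floor(lab[, 3] / bin_width))
}

#' @export
print.veus_rebalance <- function(x, ...) {
  cat(sprintf("<veus_rebalance> alpha=%.2f, %d occupied ab bins (step %g), gamma in [%.3g, %.3g]%s\n",
              x$alpha, x$Q, x$bin_width, min(x$gamma), max(x$gamma),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Per-pixel rebalance weight map for a target EUS image
#'
#' Looks up each pixel's gamma from the ab bin of the real target pixel
#' (weights never depend on the generator output). Pixels falling in bins
#' unseen during fitting get the zero-frequency weight
#' `((1 - alpha)/Q)^(-1)` (capped at the table maximum when `alpha = 1`).
#'
#' @param table A `veus_rebalance`.
#' @param eus RGB image (`H x W x 3`).
#' @return An `H x W` matrix of weights.
#' @export
rebalance_weights <- function(table, eus) {
  stopifnot(inherits(table, "veus_rebalance"))
  keys <- ab_bin_keys(eus, table$bin_width)
  idx <- match(keys, table$keys)
  unseen <- if (table$alpha < 1) 1 / ((1 - table$alpha) / table$Q) else Inf
  unseen <- min(unseen, max(table$gamma * if (table$normalized) table$norm_const else 1))
  if (table$normalized) unseen <- unseen / table$norm_const
  w <- ifelse(is.na(idx), unseen, table$gamma[idx])
  matrix(w, nrow = dim(eus)[1])
}

## ---- loss surfaces ------------------------------------------------------

clamp_prob <- function(p, eps = 1e-7) clamp(p, eps, 1 - eps)

## binary cross-entropy against a constant label, on probabilities
adversarial_ce <- function(target, prob) {
  p <- clamp_prob(prob)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Generator loss (combined objective, probability form)
#'
#' `lambda * mean(gamma * |y_virtual - y_real|) + CE(1, D_global) + CE(1, D_tumor)`:
#' the color-rebalanced L1 plus the cross-entropy of each discriminator's
#' scores against the "real" label. This is the analysis-friendly surface
#' on probabilities (clamped away from 0 and 1); training itself uses the
#' numerically equivalent logit form.
#'
#' @param y_virtual,y_real Generator output and target, identical
#'   dimensions (any scale; the L1 is computed on them as given).
#' @param d_global_prob Global discriminator probabilities on the virtual
#'   pair (patch map or scalar).
#' @param d_tumor_prob Tumor discriminator probabilities on the virtual
#'   tumor crop, or `NULL` when disabled.
#' @param weight_map Optional per-pixel gamma map (see
#'   [rebalance_weights()]); 1 everywhere when `NULL`.
#' @param lambda L1 weight (default 100).
#' @return List with `total`, `l1`, `adv_global`, `adv_tumor`.
#' @export
generator_loss <- function(y_virtual, y_real, d_global_prob,
                           d_tumor_prob = NULL, weight_map = NULL,
                           lambda = 100) {
  if (!all(dim(y_virtual) == dim(y_real))) stop("y_virtual/y_real dimension mismatch")
  w <- if (is.null(weight_map)) 1 else {
    if (!all(dim(weight_map) == dim(y_virtual)[1:2])) {
      stop("weight_map must match the image grid")
    }
    as.vector(weight_map)
  }
  l1 <- lambda * mean(w * abs(y_virtual - y_real))
  adv_g <- adversarial_ce(1, d_global_prob)
  adv_t <- if (is.null(d_tumor_prob)) 0 else adversarial_ce(1, d_tumor_prob)
  list(total = l1 + adv_g + adv_t, l1 = l1, adv_global = adv_g, adv_tumor = adv_t)
}

#' Discriminator loss (probability form)
#'
#' `CE(1, prob_real) + CE(0, prob_fake)`: cross-entropy of the scores on
#' the real pair against the "real" label plus the scores on the virtual
#' pair against the "fake" label. In the combined objective each
#' discriminator's loss enters with weight 0.5.
#'
#' @param prob_real,prob_fake Discriminator probabilities (patch maps or
#'   scalars) on the real and virtual pairs.
#' @return Scalar loss.
#' @export
discriminator_loss <- function(prob_real, prob_fake) {
  adversarial_ce(1, prob_real) + adversarial_ce(0, prob_fake)
}

#' Combined objective of one training step
#'
#' `generator + 0.5 * d_global + 0.5 * d_tumor`.
#'
#' @param generator Generator loss total.
#' @param d_global,d_tumor Discriminator losses.
#' @param d_weight Weight of each discriminator term.
#' @return Scalar.
#' @export
combined_loss <- function(generator, d_global, d_tumor = 0, d_weight = 0.5) {
  generator + d_weight * d_global + d_weight * d_tumor
}

## ---- augmentation (differentiable where the generator needs it) --------

## returns list(apply, backward); same sampled parameters for every call
sample_diffaug <- function(policy, h, w) {
  if (length(policy) == 0L) {
    return(list(apply = identity, backward = identity))
  }
  shift_r <- shift_c <- 0L; bright <- 0
  if ("translation" %in% policy) {
    m <- max(1L, h %/% 8L)
    shift_r <- sample(-m:m, 1L); shift_c <- sample(-m:m, 1L)
  }
  if ("brightness" %in% policy) bright <- stats::runif(1, -0.3, 0.3)
  shift_fw <- function(x, sr, sc) {
    if (sr == 0L && sc == 0L) return(x)
    out <- array(0, dim = dim(x))
    rs <- intersect(seq_len(h), seq_len(h) - sr)
    cs <- intersect(seq_len(w), seq_len(w) - sc)
    out[rs + sr, cs + sc, ] <- x[rs, cs, , drop = FALSE]
    out
  }
  list(
    apply = function(x) shift_fw(x, shift_r, shift_c) + bright,
    backward = function(dy) shift_fw(dy, -shift_r, -shift_c)
  )
}

## random crop with edge-replicated padding, applied consistently to a
## case's images; offsets are sampled by the caller
crop_pad_apply <- function(x, pad, off_r, off_c) {
  h <- dim(x)[1]; w <- dim(x)[2]
  ri <- clamp(seq_len(h) + off_r - pad, 1L, h)
  cj <- clamp(seq_len(w) + off_c - pad, 1L, w)
  if (length(dim(x)) == 3L) x[ri, cj, , drop = FALSE] else x[ri, cj, drop = FALSE]
}

## ---- training -----------------------------------------------------------

#' Fit the BUS-to-EUS translation model
#'
#' Trains the conditional adversarial translator on paired, registered
#' BUS/EUS cases: the color-rebalance table is fitted once on the training
#' EUS images, then the global discriminator, the tumor discriminator and
#' the generator are updated alternately with Adam, batch size 1, under the
#' combined objective (rebalanced L1 weighted by `lambda`, both
#' discriminator losses weighted 0.5). Augmentations (paired flip, random
#' crop, differentiable augmentation on discriminator inputs) follow the
#' training configuration. Deterministic for a fixed
#' `train_config$seed`.
#'
#' @param data A `veus_dataset`, or a list of `veus_case` records (each
#'   needs `bus`, `eus`, `roi`).
#' @param gen_config A [generator_config()].
#' @param disc_config A [discriminator_config()] (used for both the global
#'   and, at its own input resolution, the tumor discriminator).
#' @param train_config A [veus_train_config()].
#' @param verbose Print a line per epoch.
#' @return An object of class `veus_gan`: list with `generator`,
#'   `d_global`, `d_tumor`, `rebalance`, the three configs, `history` (one
#'   row per epoch: mean L1, adversarial and discriminator losses, learning
#'   rate) and `trained_size`.
#' @export
veus_gan <- function(data, gen_config = generator_config(),
                     disc_config = discriminator_config(),
                     train_config = veus_train_config(), verbose = FALSE) {
  cases <- if (inherits(data, "veus_dataset")) data$cases else data
  if (length(cases) == 0L) stop("empty training dataset")
  cfg <- train_config
  h <- nrow(cases[[1]]$bus); w <- ncol(cases[[1]]$bus)

  model <- with_seed(cfg$seed, {
    gen <- build_generator(gen_config)
    d_g <- if (cfg$adversarial) build_discriminator(disc_config)
    d_t <- if (cfg$adversarial && cfg$tumor_discriminator) build_discriminator(disc_config)
    rebal <- if (cfg$rebalance) {
      fit_rebalance_table(lapply(cases, `[[`, "eus"), alpha = cfg$alpha,
                          bin_width = cfg$ab_bin_width,
                          normalize = cfg$gamma_normalize)
    }
    wmaps <- if (cfg$rebalance) {
      lapply(cases, function(cs) rebalance_weights(rebal, cs$eus))
    }

    g_layers <- gen_layers(gen)
    dg_layers <- if (!is.null(d_g)) disc_layers(d_g)
    dt_layers <- if (!is.null(d_t)) disc_layers(d_t)
    history <- vector("list", cfg$epochs)
    t_adam <- 0L

    for (epoch in seq_len(cfg$epochs)) {
      lr <- learning_rate_at(epoch, cfg)
      ord <- sample(length(cases))
      ep <- c(l1 = 0, adv_g = 0, adv_t = 0, d_global = 0, d_tumor = 0)
      for (ii in ord) {
        cs <- cases[[ii]]
        x <- array(cs$bus / 127.5 - 1, dim = c(h, w, 1L))
        y <- cs$eus / 127.5 - 1
        wm <- if (cfg$rebalance) wmaps[[ii]] else matrix(1, h, w)
        roi <- cs$roi
        if (cfg$crop_pad > 0L) {
          off_r <- sample.int(2L * cfg$crop_pad + 1L, 1L) - 1L
          off_c <- sample.int(2L * cfg$crop_pad + 1L, 1L) - 1L
          x <- crop_pad_apply(x, cfg$crop_pad, off_r, off_c)
          y <- crop_pad_apply(y, cfg$crop_pad, off_r, off_c)
          wm <- crop_pad_apply(wm, cfg$crop_pad, off_r, off_c)
          roi <- roi_box(clamp(roi["row"] + cfg$crop_pad - off_r, 0L, h - roi["height"]),
                         clamp(roi["col"] + cfg$crop_pad - off_c, 0L, w - roi["width"]),
                         roi["height"], roi["width"])
        }
        if (cfg$flip && stats::runif(1) < 0.5) {
          x <- x[, w:1, , drop = FALSE]
          y <- y[, w:1, , drop = FALSE]
          wm <- wm[, w:1, drop = FALSE]
          roi <- roi_box(roi["row"], w - roi["col"] - roi["width"],
                         roi["height"], roi["width"])
        }
        rr <- roi_rows(roi); rc <- roi_cols(roi)
        tcs <- cfg$tumor_crop_size
        if (lr > 0) t_adam <- t_adam + 1L

        ## generator forward (caches kept for its update below)
        yhat <- generator_forward(gen, x, train = TRUE)
        comp_fake <- array(c(x, yhat), dim = c(h, w, 4L))
        comp_real <- array(c(x, y), dim = c(h, w, 4L))

        ## ---- discriminator updates (generator output detached) ----
        if (cfg$adversarial) {
          aug <- sample_diffaug(cfg$diffaug, h, w)
          zr <- discriminator_forward(d_g, aug$apply(comp_real), train = TRUE)
          loss_r <- bce_logits(zr, 1)
          discriminator_backward(d_g, cfg$d_loss_weight * bce_logits_grad(zr, 1))
          fake_in <- if (cfg$global_d_on_real_only) comp_real else comp_fake
          zf <- discriminator_forward(d_g, aug$apply(fake_in), train = TRUE)
          loss_f <- bce_logits(zf, 0)
          discriminator_backward(d_g, cfg$d_loss_weight * bce_logits_grad(zf, 0))
          adam_step(dg_layers, lr, cfg$beta1, cfg$beta2, t = t_adam)
          zero_grads(dg_layers)
          ep["d_global"] <- ep["d_global"] + loss_r + loss_f

          if (cfg$tumor_discriminator) {
            crop_r <- resize_nearest(comp_real[rr, rc, , drop = FALSE], tcs, tcs)
            crop_f <- resize_nearest(comp_fake[rr, rc, , drop = FALSE], tcs, tcs)
            augt <- sample_diffaug(cfg$diffaug, tcs, tcs)
            ztr <- discriminator_forward(d_t, augt$apply(crop_r), train = TRUE)
            ltr <- bce_logits(ztr, 1)
            discriminator_backward(d_t, cfg$d_loss_weight * bce_logits_grad(ztr, 1))
            ztf <- discriminator_forward(d_t, augt$apply(crop_f), train = TRUE)
            ltf <- bce_logits(ztf, 0)
            discriminator_backward(d_t, cfg$d_loss_weight * bce_logits_grad(ztf, 0))
            adam_step(dt_layers, lr, cfg$beta1, cfg$beta2, t = t_adam)
            zero_grads(dt_layers)
            ep["d_tumor"] <- ep["d_tumor"] + ltr + ltf
          }
        }

        ## ---- generator update ----
        diff <- yhat - y
        wrep <- array(wm, dim = c(h, w, 3L))
        l1 <- cfg$lambda_l1 * mean(wrep * abs(diff))
        dyhat <- cfg$lambda_l1 * wrep * sign(diff) / length(diff)

        if (cfg$adversarial) {
          aug <- sample_diffaug(cfg$diffaug, h, w)
          zg <- discriminator_forward(d_g, aug$apply(comp_fake), train = TRUE)
          ep["adv_g"] <- ep["adv_g"] + bce_logits(zg, 1)
          dcomp <- aug$backward(discriminator_backward(d_g, bce_logits_grad(zg, 1)))
          dyhat <- dyhat + dcomp[, , 2:4, drop = FALSE]

          if (cfg$tumor_discriminator) {
            crop_f <- resize_nearest(comp_fake[rr, rc, , drop = FALSE], tcs, tcs)
            augt <- sample_diffaug(cfg$diffaug, tcs, tcs)
            zt <- discriminator_forward(d_t, augt$apply(crop_f), train = TRUE)
            ep["adv_t"] <- ep["adv_t"] + bce_logits(zt, 1)
            dct <- augt$backward(discriminator_backward(d_t, bce_logits_grad(zt, 1)))
            dcrop <- resize_nearest_bw(dct, length(rr), length(rc))
            dyhat[rr, rc, ] <- dyhat[rr, rc, ] + dcrop[, , 2:4, drop = FALSE]
          }
          zero_grads(c(dg_layers, dt_layers))
        }
        generator_backward(gen, dyhat)
        adam_step(g_layers, lr, cfg$beta1, cfg$beta2, t = t_adam)
        zero_grads(g_layers)
        ep["l1"] <- ep["l1"] + l1
        if (!is.finite(l1)) stop("non-finite generator loss at epoch ", epoch)
      }
      ep <- ep / length(cases)
      history[[epoch]] <- data.frame(epoch = epoch, l1 = ep["l1"],
                                     adv_g = ep["adv_g"], adv_t = ep["adv_t"],
                                     d_global = ep["d_global"],
                                     d_tumor = ep["d_tumor"], lr = lr,
                                     row.names = NULL)
      if (verbose) {
        message(sprintf("epoch %3d  L1 %.4f  advG %.3f  D_g %.3f  D_t %.3f  lr %.2e",
                        epoch, ep["l1"], ep["adv_g"], ep["d_global"],
                        ep["d_tumor"], lr))
      }
    }
    list(generator = gen, d_global = d_g, d_tumor = d_t,
         rebalance = rebal, history = do.call(rbind, history))
  })

  structure(list(generator = model$generator, d_global = model$d_global,
                 d_tumor = model$d_tumor, rebalance = model$rebalance,
                 gen_config = gen_config, disc_config = disc_config,
                 train_config = cfg, history = model$history,
                 trained_size = c(h, w)),
            class = "veus_gan")
}

## ---- inference and methods ---------------------------------------------

#' Synthesize a virtual EUS image from a BUS image
#'
#' Runs the generator in inference mode (running batch-norm statistics, so
#' the output is deterministic). Inputs whose size differs from the trained
#' resolution are resized (nearest-neighbour) for the forward pass and the
#' output resized back.
#'
#' @param model A fitted [veus_gan()] model (or loaded checkpoint).
#' @param bus Grayscale BUS image (`H x W`, values on `[0, 255]`).
#' @return RGB V-EUS image (`H x W x 3`, integers on `[0, 255]`).
#' @export
synthesize <- function(model, bus) {
  stopifnot(inherits(model, "veus_gan"))
  check_gray(bus, "bus")
  h0 <- nrow(bus); w0 <- ncol(bus)
  ts <- model$trained_size
  x <- bus
  if (h0 != ts[1] || w0 != ts[2]) x <- resize_nearest(bus, ts[1], ts[2])
  xin <- array(x / 127.5 - 1, dim = c(ts[1], ts[2], 1L))
  y <- generator_forward(model$generator, xin, train = FALSE)
  out <- round(clamp((y + 1) * 127.5, 0, 255))
  if (h0 != ts[1] || w0 != ts[2]) out <- resize_nearest(out, h0, w0)
  out
}

#' @export
predict.veus_gan <- function(object, bus, ...) synthesize(object, bus)

#' @export
print.veus_gan <- function(x, ...) {
  cat(sprintf("<veus_gan> U-Net %s, trained %d epochs at %dx%d%s\n",
              paste(x$gen_config$encoder_channels, collapse = "-"),
              nrow(x$history), x$trained_size[1], x$trained_size[2],
              if (is.null(x$d_global)) " (L1 only)" else ""))
  invisible(x)
}

#' @export
summary.veus_gan <- function(object, ...) {
  h <- object$history
  cat("BUS -> EUS conditional adversarial translator\n")
  print(object)
  cat(sprintf("  final losses: L1 %.4f, adv_G %.3f, D_global %.3f, D_tumor %.3f\n",
              h$l1[nrow(h)], h$adv_g[nrow(h)], h$d_global[nrow(h)],
              h$d_tumor[nrow(h)]))
  if (!is.null(object$rebalance)) print(object$rebalance)
  invisible(object)
}

#' @export
plot.veus_gan <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$l1, h$adv_g, h$d_global, h$d_tumor),
                    type = "l", lty = 1, xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("L1", "adv G", "D global", "D tumor"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the full fitted object (weights, optimizer-free
#' running statistics, rebalance table, configs, history); reloading
#' reproduces identical [synthesize()] output.
#'
#' @param model A `veus_gan`.
#' @param path File path.
#' @return `load_checkpoint()` returns the `veus_gan`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "veus_gan"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- tryCatch(readRDS(path), error = function(e) {
    stop("cannot read checkpoint at ", path, ": ", conditionMessage(e))
  })
  if (!inherits(model, "veus_gan")) stop("file is not a veus_gan checkpoint")
  model
}
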
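## Minimal neural-network engine: 2-D convolution and transposed
## convolution via im2col + BLAS matrix products, batch normalization,
## activations, and Adam. Layers are environments so parameters, gradients,
## optimizer state and forward caches mutate in place; every layer has a
## hand-written backward pass. Tensors are H x W x C arrays.
##
## Convolution geometry is the 4x4-kernel family used throughout the model:
## out = floor((in + 2*pad - k)/stride) + 1; transposed convolution with
## stride 2 doubles the spatial size (it is the exact adjoint of the
## corresponding stride-2 convolution).

## ---- im2col index cache -------------------------------------------------

.conv_idx_cache <- new.env(parent = emptyenv())

## Index matrix mapping (output position, patch element) -> linear index
## into the zero-padded input; patch elements ordered (dy, dx, channel).
conv_index <- function(h, w, cin, k, stride, pad) {
  key <- paste(h, w, cin, k, stride, pad, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  ph <- h + 2L * pad; pw <- w + 2L * pad
  oh <- (h + 2L * pad - k) %/% stride + 1L
  ow <- (w + 2L * pad - k) %/% stride + 1L
  if (oh < 1L || ow < 1L) stop("convolution output would be empty")
  base_r <- rep((seq_len(oh) - 1L) * stride, times = ow)
  base_c <- rep((seq_len(ow) - 1L) * stride, each = oh)
  off_r <- rep(seq_len(k), times = k * cin)
  off_c <- rep(rep(seq_len(k), each = k), times = cin)
  off_ch <- rep(seq_len(cin), each = k * k)
  idx <- outer(base_r, off_r, `+`) +
    outer(base_c, off_c - 1L, `+`) * ph +
    rep((off_ch - 1L) * ph * pw, each = oh * ow)
  storage.mode(idx) <- "integer"
  out <- list(idx = idx, oh = oh, ow = ow, ph = ph, pw = pw,
              k = k, cin = cin, pad = pad)
  .conv_idx_cache[[key]] <- out
  out
}

pad_input <- function(x, pad, ci) {
  if (pad == 0L) return(x)
  xp <- array(0, dim = c(ci$ph, ci$pw, dim(x)[3]))
  xp[(pad + 1L):(pad + dim(x)[1]), (pad + 1L):(pad + dim(x)[2]), ] <- x
  xp
}

im2col <- function(x, ci) {
  xp <- pad_input(x, ci$pad, ci)
  patches <- xp[ci$idx]
  dim(patches) <- dim(ci$idx)
  patches
}

## scatter-add of patch gradients back onto the (padded) input grid;
## inverse of im2col. Loops over the k*k spatial offsets only: within one
## offset, output positions hit pairwise-distinct input pixels, and all
## channel planes share the per-plane index.
col2im <- function(dpatches, ci, h, w) {
  cin <- ci$cin; k2 <- ci$k * ci$k
  dxp <- matrix(0, nrow = ci$ph * ci$pw, ncol = cin)
  cols0 <- (seq_len(cin) - 1L) * k2
  for (o in seq_len(k2)) {
    bi <- ci$idx[, o]
    dxp[bi, ] <- dxp[bi, ] + dpatches[, o + cols0, drop = FALSE]
  }
  dim(dxp) <- c(ci$ph, ci$pw, cin)
  p <- ci$pad
  if (p == 0L) dxp else dxp[(p + 1L):(p + h), (p + 1L):(p + w), , drop = FALSE]
}

## ---- layers -------------------------------------------------------------

new_param_layer <- function(type, W, b) {
  e <- new.env(parent = emptyenv())
  e$type <- type; e$W <- W; e$b <- b
  e$gW <- W * 0; e$gb <- b * 0
  e$mW <- W * 0; e$vW <- W * 0; e$mb <- b * 0; e$vb <- b * 0
  e
}

## weights drawn from N(0, 0.02), the usual GAN initialization
new_conv <- function(cin, cout, k = 4L, stride = 2L, pad = 1L) {
  e <- new_param_layer("conv", matrix(stats::rnorm(k * k * cin * cout, 0, 0.02),
                                      k * k * cin, cout),
                       numeric(cout))
  e$cin <- cin; e$cout <- cout; e$k <- k; e$stride <- stride; e$pad <- pad
  e
}

new_tconv <- function(cin, cout, k = 4L, stride = 2L, pad = 1L) {
  ## parameterized by the adjoint convolution big(cout) -> small(cin)
  e <- new_param_layer("tconv", matrix(stats::rnorm(k * k * cout * cin, 0, 0.02),
                                       k * k * cout, cin),
                       numeric(cout))
  e$cin <- cin; e$cout <- cout; e$k <- k; e$stride <- stride; e$pad <- pad
  e
}

new_bn <- function(c, eps = 1e-5, momentum = 0.1) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"
  e$gamma <- stats::rnorm(c, 1, 0.02); e$beta <- numeric(c)
  e$r_mean <- numeric(c); e$r_var <- rep(1, c)
  e$eps <- eps; e$momentum <- momentum
  e$ggamma <- numeric(c); e$gbeta <- numeric(c)
  e$mg <- numeric(c); e$vg <- numeric(c); e$mb <- numeric(c); e$vb <- numeric(c)
  e
}

## geometry memoized on the layer itself: shapes are constant per model
layer_conv_index <- function(L, h, w, cin) {
  ci <- L$ci
  if (is.null(ci) || L$ci_h != h || L$ci_w != w) {
    ci <- conv_index(h, w, cin, L$k, L$stride, L$pad)
    L$ci <- ci; L$ci_h <- h; L$ci_w <- w
  }
  ci
}

conv_fw <- function(L, x) {
  d <- dim(x)
  ci <- layer_conv_index(L, d[1], d[2], d[3])
  patches <- im2col(x, ci)
  out <- patches %*% L$W
  out <- out + rep(L$b, each = nrow(out))
  L$cache <- list(ci = ci, patches = patches, h = d[1], w = d[2])
  dim(out) <- c(ci$oh, ci$ow, L$cout)
  out
}

conv_bw <- function(L, dy) {
  cc <- L$cache
  dmat <- dy
  dim(dmat) <- c(cc$ci$oh * cc$ci$ow, L$cout)
  L$gW <- L$gW + crossprod(cc$patches, dmat)
  L$gb <- L$gb + colSums(dmat)
  col2im(tcrossprod(dmat, L$W), cc$ci, cc$h, cc$w)
}

tconv_fw <- function(L, x) {
  d <- dim(x)
  oh <- d[1] * L$stride; ow <- d[2] * L$stride   # stride-2, k=4, pad=1 family
  ci <- layer_conv_index(L, oh, ow, L$cout)
  stopifnot(ci$oh == d[1], ci$ow == d[2])
  xmat <- x
  dim(xmat) <- c(d[1] * d[2], d[3])
  y <- col2im(tcrossprod(xmat, L$W), ci, oh, ow)
  y <- y + rep(L$b, each = oh * ow)
  L$cache <- list(ci = ci, xmat = xmat, oh = oh, ow = ow)
  y
}

tconv_bw <- function(L, dy) {
  cc <- L$cache
  patches <- im2col(dy, cc$ci)
  L$gW <- L$gW + crossprod(patches, cc$xmat)
  dym <- dy
  dim(dym) <- c(cc$oh * cc$ow, L$cout)
  L$gb <- L$gb + colSums(dym)
  dx <- patches %*% L$W
  dim(dx) <- c(cc$ci$oh, cc$ci$ow, L$cin)
  dx
}

bn_fw <- function(L, x, train) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(n, d[3])
  if (train) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    L$r_mean <- (1 - L$momentum) * L$r_mean + L$momentum * mu
    L$r_var <- (1 - L$momentum) * L$r_var + L$momentum * v
  } else {
    mu <- L$r_mean; v <- L$r_var
    xc <- xm - rep(mu, each = n)
  }
  istd <- 1 / sqrt(v + L$eps)
  xhat <- xc * rep(istd, each = n)
  y <- xhat * rep(L$gamma, each = n) + rep(L$beta, each = n)
  L$cache <- list(xhat = xhat, istd = istd, n = n, d = d, train = train)
  array(y, dim = d)
}

bn_bw <- function(L, dy) {
  cc <- L$cache; n <- cc$n
  dym <- dy
  dim(dym) <- c(n, cc$d[3])
  L$ggamma <- L$ggamma + colSums(dym * cc$xhat)
  L$gbeta <- L$gbeta + colSums(dym)
  dxhat <- dym * rep(L$gamma, each = n)
  if (cc$train) {
    s1 <- colSums(dxhat); s2 <- colSums(dxhat * cc$xhat)
    dx <- (dxhat - rep(s1 / n, each = n) - cc$xhat * rep(s2 / n, each = n)) *
      rep(cc$istd, each = n)
  } else {
    dx <- dxhat * rep(cc$istd, each = n)
  }
  array(dx, dim = cc$d)
}

relu_fw <- function(x) pmax(x, 0)
relu_bw <- function(dy, x) dy * (x > 0)
lrelu_fw <- function(x, a = 0.2) pmax(x, 0) + a * pmin(x, 0)
lrelu_bw <- function(dy, x, a = 0.2) dy * (a + (1 - a) * (x > 0))
tanh_bw <- function(dy, y) dy * (1 - y * y)

## numerically stable binary cross-entropy on logits:
## CE(t, sigmoid(z)) = softplus(z) - t * z ; d/dz = sigmoid(z) - t
softplus <- function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30))))
sigmoid <- function(z) 1 / (1 + exp(-clamp(z, -30, 30)))
bce_logits <- function(z, target) mean(softplus(z) - target * z)
bce_logits_grad <- function(z, target) (sigmoid(z) - target) / length(z)

## ---- optimizer ----------------------------------------------------------

zero_grads <- function(layers) {
  for (L in layers) {
    if (L$type == "bn") { L$ggamma[] <- 0; L$gbeta[] <- 0 }
    else { L$gW[] <- 0; L$gb[] <- 0 }
  }
  invisible(NULL)
}

adam_step <- function(layers, lr, beta1 = 0.5, beta2 = 0.999, eps = 1e-8, t = 1) {
  if (lr <= 0) return(invisible(NULL))
  corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
  upd <- function(L, p, g, m, v) {
    L[[m]] <- beta1 * L[[m]] + (1 - beta1) * L[[g]]
    L[[v]] <- beta2 * L[[v]] + (1 - beta2) * L[[g]]^2
    L[[p]] <- L[[p]] - lr * corr * L[[m]] / (sqrt(L[[v]]) + eps)
  }
  for (L in layers) {
    if (L$type == "bn") {
      upd(L, "gamma", "ggamma", "mg", "vg")
      upd(L, "beta", "gbeta", "mb", "vb")
    } else {
      upd(L, "W", "gW", "mW", "vW")
      upd(L, "b", "gb", "mb", "vb")
    }
  }
  invisible(NULL)
}

## ---- nearest-neighbour resize (with exact adjoint) ----------------------

resize_nearest_map <- function(src, dst) {
  pmin(src, floor(((seq_len(dst) - 0.5) * src) / dst) + 1L)
}

resize_nearest <- function(x, oh, ow) {
  d <- dim(x)
  ri <- resize_nearest_map(d[1], oh)
  cj <- resize_nearest_map(d[2], ow)
  if (length(d) == 2L) x[ri, cj, drop = FALSE] else x[ri, cj, , drop = FALSE]
}

resize_nearest_bw <- function(dy, src_h, src_w) {
  d <- dim(dy)
  ri <- resize_nearest_map(src_h, d[1])
  cj <- resize_nearest_map(src_w, d[2])
  src_lin <- as.vector(outer(ri, (cj - 1L) * src_h, `+`))
  nc <- if (length(d) == 3L) d[3] else 1L
  dx <- array(0, dim = c(src_h, src_w, nc))
  for (ch in seq_len(nc)) {
    v <- if (length(d) == 3L) dy[, , ch] else dy
    acc <- rowsum(as.vector(v), group = src_lin)
    plane <- numeric(src_h * src_w)
    plane[as.integer(rownames(acc))] <- acc[, 1]
    dx[, , ch] <- plane
  }
  if (length(d) == 2L) dx[, , 1] else dx
}
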
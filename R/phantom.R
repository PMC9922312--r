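## Synthetic paired BUS/EUS phantom generator with known stiffness ground
## truth. The phantom is an idealization: first-order speckle statistics
## (multiplicative Rayleigh envelope on a smooth background), depth
## attenuation, a hypoechoic elliptical lesion whose echo intensity falls
## monotonically with its stiffness, and an additive pseudo-color overlay
## constructed so that EUS - BUS is exact 8-bit arithmetic.

#' Phantom simulation parameters
#'
#' @param image_size Pixels per side of the square image.
#' @param pixel_spacing mm per pixel; `image_size * pixel_spacing` is the
#'   field depth. The default grid spans 38.4 mm.
#' @param lesion_axes_range mm; range of the lesion's elliptical semi-axes.
#' @param lesion_depth_range mm; range of the lesion centre depth below the
#'   transducer (top edge of the image).
#' @param stiffness_background Elasticity level of normal tissue, on
#'   `[1, 256]`.
#' @param stiffness_benign_range,stiffness_malignant_range Level intervals
#'   the lesion stiffness is drawn from; the malignant interval must lie
#'   strictly above the benign one.
#' @param stiffness_noise_sd Standard deviation (levels) of the smooth
#'   spatial noise added to the stiffness map.
#' @param speckle_scale Mixing weight on `[0, 1)` of the multiplicative
#'   Rayleigh speckle envelope (0 = no speckle).
#' @param attenuation_coeff Per-mm intensity decay of the B-mode signal.
#' @param artifact_prob_deep Probability of injecting an attenuation
#'   artifact into the EUS when the lesion top edge is deeper than
#'   `artifact_depth_threshold`. The default is the rate reported for real
#'   elastography of lesions deeper than 20 mm (25.9%).
#' @param artifact_depth_threshold mm; depth beyond which artifacts occur.
#' @param overlay_weight Blending weight of pure color over BUS, on (0, 1].
#'   The BUS is pre-scaled into `[0, (1-w)*255]` and the color bar generated
#'   at HSV value `w`, so the overlay never clips and subtraction is exact.
#' @param seed Integer seed recorded with the parameters; dataset generation
#'   uses it unless an explicit seed is given.
#' @return An object of class `veus_phantom_params`.
#' @export
phantom_params <- function(image_size = 256L,
                           pixel_spacing = 38.4 / image_size,
                           lesion_axes_range = c(2.5, 6),
                           lesion_depth_range = c(7, 30),
                           stiffness_background = 64L,
                           stiffness_benign_range = c(80L, 140L),
                           stiffness_malignant_range = c(170L, 240L),
                           stiffness_noise_sd = 4,
                           speckle_scale = 0.4,
                           attenuation_coeff = 0.02,
                           artifact_prob_deep = 0.259,
                           artifact_depth_threshold = 20,
                           overlay_weight = 0.5,
                           seed = 1L) {
  p <- list(image_size = as.integer(image_size), pixel_spacing = pixel_spacing,
            lesion_axes_range = lesion_axes_range,
            lesion_depth_range = lesion_depth_range,
            stiffness_background = as.integer(stiffness_background),
            stiffness_benign_range = as.integer(stiffness_benign_range),
            stiffness_malignant_range = as.integer(stiffness_malignant_range),
            stiffness_noise_sd = stiffness_noise_sd,
            speckle_scale = speckle_scale,
            attenuation_coeff = attenuation_coeff,
            artifact_prob_deep = artifact_prob_deep,
            artifact_depth_threshold = artifact_depth_threshold,
            overlay_weight = overlay_weight, seed = as.integer(seed))
  stopifnot(p$image_size >= 16L,
            p$pixel_spacing > 0,
            diff(p$lesion_axes_range) >= 0, p$lesion_axes_range[1] > 0,
            diff(p$lesion_depth_range) >= 0,
            p$stiffness_background >= 1L, p$stiffness_background <= 256L,
            all(p$stiffness_benign_range >= 1L),
            all(p$stiffness_malignant_range <= 256L),
            p$speckle_scale >= 0, p$speckle_scale < 1,
            p$attenuation_coeff >= 0,
            p$artifact_prob_deep >= 0, p$artifact_prob_deep <= 1,
            p$overlay_weight > 0, p$overlay_weight <= 1)
  if (p$stiffness_malignant_range[1] <= p$stiffness_benign_range[2]) {
    stop("malignant stiffness interval must lie strictly above the benign interval")
  }
  structure(p, class = "veus_phantom_params")
}

#' @export
print.veus_phantom_params <- function(x, ...) {
  cat(sprintf("<veus_phantom_params> %dpx @ %.3f mm/px (%.1f mm field)\n",
              x$image_size, x$pixel_spacing, x$image_size * x$pixel_spacing))
  cat(sprintf("  stiffness: background %d, benign [%d,%d], malignant [%d,%d]\n",
              x$stiffness_background, x$stiffness_benign_range[1],
              x$stiffness_benign_range[2], x$stiffness_malignant_range[1],
              x$stiffness_malignant_range[2]))
  cat(sprintf("  artifacts: p=%.3f beyond %.0f mm; overlay weight %.2f\n",
              x$artifact_prob_deep, x$artifact_depth_threshold, x$overlay_weight))
  invisible(x)
}

## ---- low-level field helpers -------------------------------------------

gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

## separable Gaussian blur with edge replication
blur_gaussian <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  pass <- function(m) {
    p <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
    v <- stats::filter(p, k, sides = 2)
    matrix(v[(r + 1L):(r + nrow(m)), ], nrow = nrow(m))
  }
  t(pass(t(pass(m))))
}

## zero-mean, unit-sd smooth random field
smooth_field <- function(h, w, sigma) {
  f <- blur_gaussian(matrix(stats::rnorm(h * w), h, w), sigma)
  (f - mean(f)) / stats::sd(f)
}

## multiplicative speckle envelope with mean 1 (Rayleigh, lightly smoothed)
speckle_field <- function(h, w, scale) {
  if (scale <= 0) return(matrix(1, h, w))
  env <- sqrt(-2 * log(stats::runif(h * w)))    # Rayleigh(sigma = 1)
  env <- matrix(env / sqrt(pi / 2), h, w)       # mean 1
  env <- blur_gaussian(env, 0.6)
  (1 - scale) + scale * env
}

## lesion echo intensity relative to surrounding tissue: monotone
## decreasing in stiffness level (stiffer lesions are more hypoechoic)
lesion_echo_factor <- function(level) clamp(1.05 - 1.1 * level / 256, 0.12, 1)

## ---- case generation ----------------------------------------------------

#' Generate one synthetic BUS/EUS case
#'
#' Draws lesion geometry and stiffness, renders the B-mode image
#' (smooth background x depth attenuation x speckle, with the lesion as a
#' hypoechoic ellipse whose contrast is a deterministic monotone function of
#' its stiffness), builds the co-registered stiffness map, and overlays its
#' pseudo-color rendering on the BUS to form the EUS. Consumes the current
#' RNG stream; seed upstream (see [generate_dataset()]) for reproducibility.
#'
#' @param params A [phantom_params()] object.
#' @param label `"benign"` or `"malignant"`.
#' @param case_id Identifier stored in the record.
#' @return An object of class `veus_case`: a list with elements `case_id`,
#'   `bus` (pre-scaled grayscale, `H x W`), `eus` (`H x W x 3`), `pure` (the
#'   stored overlay), `stiffness_truth` (`H x W`, levels), `roi`
#'   ([roi_box()]), `label`, `tumor_depth_mm` (lesion top edge),
#'   `birads`, `artifact_flag`, `lesion_stiffness` (the drawn lesion level,
#'   ground truth for recovery checks), and `params`.
#' @export
generate_case <- function(params, label = c("benign", "malignant"),
                          case_id = "case_001") {
  stopifnot(inherits(params, "veus_phantom_params"))
  label <- match.arg(label)
  n <- params$image_size
  ps <- params$pixel_spacing
  field_mm <- n * ps

  ## sample a geometry that fits, with a bounded number of retries
  geom <- NULL
  for (try in seq_len(25L)) {
    a <- stats::runif(1, params$lesion_axes_range[1], params$lesion_axes_range[2])
    b <- stats::runif(1, params$lesion_axes_range[1], params$lesion_axes_range[2])
    dc <- stats::runif(1, params$lesion_depth_range[1], params$lesion_depth_range[2])
    margin <- ps  # one pixel
    if (dc - b < margin || dc + b > field_mm - margin) next
    if (2 * a > field_mm - 2 * margin) next
    xc <- stats::runif(1, a + margin, field_mm - a - margin)
    geom <- list(a = a, b = b, dc = dc, xc = xc)
    break
  }
  if (is.null(geom)) {
    stop("lesion does not fit in the image for the configured depth/axes ranges")
  }

  ## pixel-centre coordinates in mm (row = depth)
  depth_mm <- (seq_len(n) - 0.5) * ps
  lat_mm <- (seq_len(n) - 0.5) * ps
  rr <- matrix(depth_mm, n, n)
  cc <- matrix(lat_mm, n, n, byrow = TRUE)
  rnorm2 <- sqrt(((rr - geom$dc) / geom$b)^2 + ((cc - geom$xc) / geom$a)^2)
  member <- 1 / (1 + exp((rnorm2 - 1) / 0.06))   # soft ellipse membership

  ## stiffness truth
  lev_range <- if (label == "malignant") params$stiffness_malignant_range
               else params$stiffness_benign_range
  lesion_level <- stats::runif(1, lev_range[1], lev_range[2])
  noise <- smooth_field(n, n, sigma = n / 16) * params$stiffness_noise_sd
  truth <- round(params$stiffness_background +
                 member * (lesion_level - params$stiffness_background) + noise)
  truth <- matrix(as.integer(clamp(truth, 1L, 256L)), n, n)

  ## B-mode image
  background <- 0.72 * (1 + 0.15 * smooth_field(n, n, sigma = n / 8))
  atten <- exp(-params$attenuation_coeff * rr)
  echo <- background * ((1 - member) + member * lesion_echo_factor(lesion_level))
  busf <- clamp(echo * atten * speckle_field(n, n, params$speckle_scale), 0, 1)
  w <- params$overlay_weight
  bus <- floor(busf * 255 * (1 - w))

  ## EUS = scaled BUS + pure color from the dataset bar (exact, no clipping)
  bar <- default_color_bar(value = w)
  pure <- encode_elasticity(truth, bar)
  eus <- overlay_pure_color(bus, pure, weight = w, bus_prescaled = TRUE)

  ## ROI: bounding box of the hard ellipse, clipped to the image
  r0 <- max(0L, floor((geom$dc - geom$b) / ps))
  r1 <- min(n, ceiling((geom$dc + geom$b) / ps))
  c0 <- max(0L, floor((geom$xc - geom$a) / ps))
  c1 <- min(n, ceiling((geom$xc + geom$a) / ps))
  roi <- roi_box(r0, c0, r1 - r0, c1 - c0)

  birads_lv <- birads_levels()
  birads <- if (label == "malignant") {
    sample(birads_lv[3:6], 1, prob = c(0.15, 0.25, 0.35, 0.25))
  } else {
    sample(birads_lv[1:4], 1, prob = c(0.10, 0.50, 0.30, 0.10))
  }

  case <- structure(list(case_id = case_id, bus = bus, eus = eus, pure = pure,
                         stiffness_truth = truth, roi = roi, label = label,
                         tumor_depth_mm = r0 * ps, birads = birads,
                         artifact_flag = FALSE,
                         lesion_stiffness = lesion_level, params = params),
                    class = "veus_case")

  if (case$tumor_depth_mm > params$artifact_depth_threshold &&
      stats::runif(1) < params$artifact_prob_deep) {
    case <- inject_attenuation_artifact(case)
  }
  case
}

#' @export
print.veus_case <- function(x, ...) {
  cat(sprintf("<veus_case> %s: %s, %dx%d px, lesion top %.1f mm, BI-RADS %s%s\n",
              x$case_id, x$label, nrow(x$bus), ncol(x$bus), x$tumor_depth_mm,
              x$birads, if (x$artifact_flag) ", attenuation artifact" else ""))
  invisible(x)
}

#' Inject an attenuation artifact into a case's EUS
#'
#' Emulates signal-attenuation artifacts beneath deep lesions: within a
#' vertical band through the lesion, the pseudo-color from the lesion centre
#' downward is replaced with colors drawn from the soft (blue) end of the
#' bar, uncorrelated with the true stiffness. Only the EUS (and the stored
#' overlay) is corrupted; `stiffness_truth` is untouched. Consumes the
#' current RNG stream.
#'
#' @param case A `veus_case` whose lesion top edge is deeper than the
#'   configured `artifact_depth_threshold`; shallower cases are returned
#'   unchanged with a warning.
#' @return The corrupted `veus_case` with `artifact_flag = TRUE`.
#' @export
inject_attenuation_artifact <- function(case) {
  stopifnot(inherits(case, "veus_case"))
  p <- case$params
  if (case$tumor_depth_mm <= p$artifact_depth_threshold) {
    warning("lesion is shallower than the artifact depth threshold; no artifact injected")
    return(case)
  }
  n <- nrow(case$bus)
  roi <- case$roi
  ## band: middle two thirds of the lesion laterally, lesion centre to bottom
  band_c0 <- roi["col"] + roi["width"] %/% 6L
  band_c1 <- roi["col"] + roi["width"] - roi["width"] %/% 6L
  cols <- seq.int(band_c0 + 1L, max(band_c0 + 1L, band_c1))
  rows <- seq.int(roi["row"] + roi["height"] %/% 2L + 1L, n)

  bar <- default_color_bar(value = p$overlay_weight)
  soft <- matrix(sample(1:30, length(rows) * length(cols), replace = TRUE),
                 length(rows), length(cols))
  pure <- case$pure
  for (ch in 1:3) {
    pure[rows, cols, ch] <- matrix(unclass(bar)[cbind(as.integer(soft), ch)],
                                   length(rows), length(cols))
  }
  case$pure <- pure
  case$eus <- overlay_pure_color(case$bus, pure, weight = p$overlay_weight,
                                 bus_prescaled = TRUE)
  case$artifact_flag <- TRUE
  case
}

## ---- dataset generation and I/O ----------------------------------------

birads_levels <- function() c("2", "3", "4a", "4b", "4c", "5")

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a dataset of paired phantom cases
#'
#' Label allocation is deterministic: exactly
#' `round(malignant_fraction * n_cases)` cases are malignant, in a
#' seed-determined order. The whole dataset is reproducible byte-for-byte
#' from `(params, seed)`.
#'
#' @param params A [phantom_params()] object.
#' @param n_cases Number of cases (>= 1).
#' @param malignant_fraction Fraction of malignant cases on `[0, 1]`.
#' @param seed Integer seed; defaults to `params$seed`.
#' @param dir Optional output directory. When given, each case is written as
#'   8-bit PNGs (`*_bus.png` grayscale, `*_eus.png` RGB, `*_truth.png`
#'   storing level - 1), together with `manifest.csv`, `params.yaml` and the
#'   dataset's `bar.json`.
#' @return An object of class `veus_dataset`: list with `cases` (list of
#'   `veus_case`), `manifest` (data frame), `params`, and `bar`.
#' @export
generate_dataset <- function(params, n_cases, malignant_fraction = 0.5,
                             seed = params$seed, dir = NULL) {
  stopifnot(inherits(params, "veus_phantom_params"),
            n_cases >= 1, malignant_fraction >= 0, malignant_fraction <= 1)
  n_mal <- round(malignant_fraction * n_cases)
  cases <- with_seed(seed, {
    labels <- sample(c(rep("malignant", n_mal), rep("benign", n_cases - n_mal)))
    lapply(seq_len(n_cases), function(i) {
      generate_case(params, labels[i], case_id = sprintf("case_%04d", i))
    })
  })
  manifest <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(case_id = cs$case_id, label = cs$label,
               roi_row = cs$roi["row"], roi_col = cs$roi["col"],
               roi_height = cs$roi["height"], roi_width = cs$roi["width"],
               tumor_depth_mm = cs$tumor_depth_mm, birads = cs$birads,
               artifact_flag = cs$artifact_flag, row.names = NULL)
  }))
  ds <- structure(list(cases = cases, manifest = manifest, params = params,
                       bar = default_color_bar(value = params$overlay_weight)),
                  class = "veus_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

#' @export
print.veus_dataset <- function(x, ...) {
  cat(sprintf("<veus_dataset> %d cases (%d malignant), %dpx, %d with artifacts\n",
              nrow(x$manifest), sum(x$manifest$label == "malignant"),
              x$params$image_size, sum(x$manifest$artifact_flag)))
  invisible(x)
}

#' Write / read a phantom dataset directory
#'
#' @param ds A `veus_dataset`.
#' @param dir Directory path (created if missing).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `veus_dataset` (cases carry images and, when present, the
#'   ground-truth stiffness map).
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "veus_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  for (cs in ds$cases) {
    write_image_png(cs$bus, file.path(dir, paste0(cs$case_id, "_bus.png")))
    write_image_png(cs$eus, file.path(dir, paste0(cs$case_id, "_eus.png")))
    write_image_png(cs$stiffness_truth - 1L,
                    file.path(dir, paste0(cs$case_id, "_truth.png")))
  }
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(ds$params), file.path(dir, "params.yaml"))
  write_color_bar(ds$bar, file.path(dir, "bar.json"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              colClasses = c(birads = "character"))
  params <- do.call(phantom_params, yaml::read_yaml(file.path(dir, "params.yaml")))
  bar <- read_color_bar(file.path(dir, "bar.json"))
  cases <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    truth_path <- file.path(dir, paste0(m$case_id, "_truth.png"))
    structure(list(
      case_id = m$case_id,
      bus = read_image_png(file.path(dir, paste0(m$case_id, "_bus.png"))),
      eus = read_image_png(file.path(dir, paste0(m$case_id, "_eus.png"))),
      pure = NULL,
      stiffness_truth = if (file.exists(truth_path)) {
        tr <- read_image_png(truth_path) + 1L
        matrix(as.integer(tr), nrow = nrow(tr))
      },
      roi = roi_box(m$roi_row, m$roi_col, m$roi_height, m$roi_width),
      label = m$label, tumor_depth_mm = m$tumor_depth_mm,
      birads = as.character(m$birads), artifact_flag = m$artifact_flag,
      params = params), class = "veus_case")
  })
  structure(list(cases = cases, manifest = manifest, params = params, bar = bar),
            class = "veus_dataset")
}
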
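## Strain-ratio computation and the three image-similarity metrics used to
## compare real and virtual elastography.

#' Select the normal-tissue reference region
#'
#' Places a `size x size` box at the tumor's depth (vertically centred on
#' the ROI's row band) and laterally as far from the tumor as the image
#' allows: flush against the image edge on the side with the wider lateral
#' margin (ties go left). Deterministic; never intersects the tumor ROI.
#'
#' @param levels Elasticity map (`H x W`), only used for its dimensions.
#' @param roi Tumor [roi_box()].
#' @param size Side length of the reference box in pixels (default 25).
#' @return A [roi_box()] for the reference region.
#' @export
select_reference_region <- function(levels, roi, size = 25L) {
  check_gray(levels, "levels")
  size <- as.integer(size)
  h <- nrow(levels); w <- ncol(levels)
  check_roi_in_image(roi, c(h, w), "tumor roi")
  left_margin <- roi["col"]
  right_margin <- w - (roi["col"] + roi["width"])
  if (max(left_margin, right_margin) < size || size > h) {
    stop(sprintf(paste0("no %dx%d reference region fits beside the tumor ",
                        "(lateral margins %d and %d px); use a smaller size"),
                 size, size, left_margin, right_margin))
  }
  col <- if (left_margin >= right_margin) 0L else w - size
  row <- roi["row"] + (roi["height"] - size) %/% 2L
  row <- max(0L, min(row, h - size))
  roi_box(row, col, size, size)
}

#' Strain ratio of a decoded elasticity map
#'
#' The mean elasticity level inside the tumor ROI divided by the mean level
#' inside the reference region, so stiffer tumors give larger values and
#' larger values predict malignancy.
#'
#' @param levels Elasticity map (`H x W`, levels on `[1, 256]`).
#' @param roi Tumor [roi_box()].
#' @param ref Reference [roi_box()]; defaults to
#'   [select_reference_region()]'s placement.
#' @return An object of class `veus_strain_ratio`: list with `sr`,
#'   `tumor_mean_level`, `reference_mean_level`, `reference_box`.
#' @export
strain_ratio <- function(levels, roi, ref = select_reference_region(levels, roi)) {
  check_gray(levels, "levels")
  check_roi_in_image(roi, dim(levels), "tumor roi")
  check_roi_in_image(ref, dim(levels), "reference roi")
  if (rois_overlap(roi, ref)) stop("tumor and reference regions overlap")
  tmean <- mean(levels[roi_rows(roi), roi_cols(roi)])
  rmean <- mean(levels[roi_rows(ref), roi_cols(ref)])
  structure(list(sr = tmean / rmean, tumor_mean_level = tmean,
                 reference_mean_level = rmean, reference_box = ref),
            class = "veus_strain_ratio")
}

#' @export
print.veus_strain_ratio <- function(x, ...) {
  cat(sprintf("<veus_strain_ratio> SR = %.3f (tumor %.1f / reference %.1f)\n",
              x$sr, x$tumor_mean_level, x$reference_mean_level))
  invisible(x)
}

#' Global structural similarity (SSIM) between two images
#'
#' Single-window SSIM computed from global means, variances and covariance
#' over the whole image:
#' `(2 mu_r mu_v + C1)(2 cov_rv + C2) / ((mu_r^2 + mu_v^2 + C1)(var_r + var_v + C2))`,
#' averaged over channels for RGB input. Constants follow the usual
#' convention `C1 = (K1 L)^2`, `C2 = (K2 L)^2`.
#'
#' @param real,virtual Images of identical dimensions (matrices or
#'   `H x W x 3` arrays).
#' @param dynamic_range Value range `L` of the data (255 for 8-bit).
#' @param K1,K2 SSIM stabilization constants.
#' @return SSIM value (<= 1; 1 iff the images are identical).
#' @export
ssim_global <- function(real, virtual, dynamic_range = 255, K1 = 0.01, K2 = 0.03) {
  if (!all(dim(real) == dim(virtual))) {
    stop(sprintf("dimension mismatch: real is %s, virtual is %s",
                 paste(dim(real), collapse = "x"),
                 paste(dim(virtual), collapse = "x")))
  }
  C1 <- (K1 * dynamic_range)^2
  C2 <- (K2 * dynamic_range)^2
  one_channel <- function(r, v) {
    mu_r <- mean(r); mu_v <- mean(v)
    var_r <- mean((r - mu_r)^2); var_v <- mean((v - mu_v)^2)
    cov_rv <- mean((r - mu_r) * (v - mu_v))
    ((2 * mu_r * mu_v + C1) * (2 * cov_rv + C2)) /
      ((mu_r^2 + mu_v^2 + C1) * (var_r + var_v + C2))
  }
  if (length(dim(real)) == 3L) {
    mean(vapply(seq_len(dim(real)[3]),
                function(ch) one_channel(real[, , ch], virtual[, , ch]),
                numeric(1)))
  } else {
    one_channel(real, virtual)
  }
}

#' Mean absolute percentage error between paired strain ratios
#'
#' `(1/m) * sum(|sr_real - sr_virtual| / sr_real)` over paired cases.
#'
#' @param sr_real,sr_virtual Equal-length numeric vectors; `sr_real` must be
#'   strictly positive.
#' @return MAPE (>= 0; 0 iff the vectors are identical).
#' @export
sr_mape <- function(sr_real, sr_virtual) {
  if (length(sr_real) != length(sr_virtual)) {
    stop(sprintf("length mismatch: %d real vs %d virtual strain ratios",
                 length(sr_real), length(sr_virtual)))
  }
  if (length(sr_real) < 1L) stop("need at least one strain ratio pair")
  if (any(sr_real <= 0)) stop("all real strain ratios must be strictly positive")
  mean(abs(sr_real - sr_virtual) / sr_real)
}

#' Color histogram correlation (CHC) in hue-saturation space
#'
#' Both images are converted to HSV; per-channel histograms of hue and of
#' saturation are compared with
#' `HC = 1 - sqrt(1 - sum(sqrt(Cnt_r * Cnt_v)) / sqrt(sum(Cnt_r) * sum(Cnt_v)))`
#' (one minus Hellinger distance, via the Bhattacharyya coefficient), and
#' CHC is the mean of the hue and saturation HC values.
#'
#' @param real,virtual RGB images (`H x W x 3`, values on `[0, 255]`) of
#'   identical dimensions.
#' @param hue_bins,saturation_bins Histogram bin counts.
#' @return CHC on `[0, 1]`; 1 for identical color distributions, 0 for
#'   disjoint ones.
#' @export
chc <- function(real, virtual, hue_bins = 50L, saturation_bins = 60L) {
  check_rgb(real, "real"); check_rgb(virtual, "virtual")
  check_same_dim(real, virtual, "real", "virtual")
  hs <- function(img) {
    px <- matrix(as.numeric(img), ncol = 3L)
    grDevices::rgb2hsv(t(px), maxColorValue = 255)[1:2, , drop = FALSE]
  }
  hist_counts <- function(x, nb) tabulate(pmin(floor(x * nb) + 1L, nb), nbins = nb)
  hc <- function(cr, cv) {
    bc <- sum(sqrt(cr * cv)) / sqrt(sum(cr) * sum(cv))
    1 - sqrt(pmax(0, 1 - bc))
  }
  hr <- hs(real); hv <- hs(virtual)
  mean(c(hc(hist_counts(hr[1, ], hue_bins), hist_counts(hv[1, ], hue_bins)),
         hc(hist_counts(hr[2, ], saturation_bins), hist_counts(hv[2, ], saturation_bins))))
}

#' Similarity report between a real and a virtual EUS image
#'
#' Bundles [ssim_global()], [chc()] and, when paired strain ratios are
#' given, [sr_mape()] into one report.
#'
#' @param real,virtual RGB images of identical dimensions.
#' @param sr_real,sr_virtual Optional paired strain-ratio vectors.
#' @inheritParams ssim_global
#' @inheritParams chc
#' @return An object of class `veus_similarity`: list with `ssim`, `chc`,
#'   optionally `mape`, and the constants used.
#' @export
compare_images <- function(real, virtual, sr_real = NULL, sr_virtual = NULL,
                           dynamic_range = 255, K1 = 0.01, K2 = 0.03,
                           hue_bins = 50L, saturation_bins = 60L) {
  rep <- list(
    ssim = ssim_global(real, virtual, dynamic_range, K1, K2),
    chc = chc(real, virtual, hue_bins, saturation_bins),
    mape = if (!is.null(sr_real)) sr_mape(sr_real, sr_virtual),
    C1 = (K1 * dynamic_range)^2, C2 = (K2 * dynamic_range)^2,
    hue_bins = as.integer(hue_bins), saturation_bins = as.integer(saturation_bins))
  structure(rep, class = "veus_similarity")
}

#' @export
print.veus_similarity <- function(x, ...) {
  cat(sprintf("<veus_similarity> SSIM %.3f, CHC %.3f%s\n", x$ssim, x$chc,
              if (!is.null(x$mape)) sprintf(", MAPE %.3f", x$mape) else ""))
  invisible(x)
}
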
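## Encoding stiffness levels to pseudo-color and decoding EUS back to
## elasticity levels by nearest-color search against the bar.

#' Subtract BUS from EUS to obtain the pure color image
#'
#' Per-pixel, per-channel subtraction of the (channel-replicated) grayscale
#' BUS from the RGB EUS; negative differences are clamped to 0 so the result
#' stays in valid RGB space.
#'
#' @param eus RGB EUS image (`H x W x 3`, values on `[0, 255]`).
#' @param bus Grayscale BUS image (`H x W` matrix, same grid).
#' @return The pure color image, `H x W x 3`.
#' @export
extract_pure_color <- function(eus, bus) {
  check_rgb(eus, "eus"); check_gray(bus, "bus")
  check_same_dim(eus, bus, "eus", "bus")
  pmax(eus - gray_to_rgb(bus), 0)
}

#' Decode a pure color image to elasticity levels
#'
#' Each pixel is compared with all 256 bar entries and assigned the level
#' with the smallest Euclidean RGB distance
#' `d(c) = sqrt((R - R_c)^2 + (G - G_c)^2 + (B - B_c)^2)`.
#' The argmin is computed on exact integer squared distances (no square
#' root), and ties break to the smallest level.
#'
#' @param pure Pure color image (`H x W x 3`), e.g. from
#'   [extract_pure_color()].
#' @param bar A `veus_color_bar`.
#' @return An `H x W` integer matrix of levels on `[1, 256]`.
#' @export
decode_pure_color <- function(pure, bar) {
  check_rgb(pure, "pure")
  stopifnot(inherits(bar, "veus_color_bar"))
  h <- dim(pure)[1]; w <- dim(pure)[2]
  px <- matrix(round(as.numeric(pure)), nrow = h * w, ncol = 3L)
  b <- unclass(bar)
  ## squared distance: |p|^2 - 2 p.b + |b|^2; |p|^2 constant per row
  cross <- px %*% t(b)
  d2 <- sweep(-2 * cross, 2L, rowSums(b^2), `+`)
  lev <- max.col(-d2, ties.method = "first")
  matrix(as.integer(lev), nrow = h, ncol = w)
}

#' Encode an elasticity level map as a pure color image
#'
#' Per-pixel lookup of the color bar; the construction inverse of
#' [decode_pure_color()].
#'
#' @param levels Integer matrix of levels on `[1, 256]`.
#' @param bar A `veus_color_bar`.
#' @return Pure color image, `H x W x 3`.
#' @export
encode_elasticity <- function(levels, bar) {
  check_gray(levels, "levels")
  stopifnot(inherits(bar, "veus_color_bar"))
  bad <- which(levels < 1 | levels > 256 | levels != round(levels))
  if (length(bad)) {
    i <- bad[1]
    rc <- arrayInd(i, dim(levels))
    stop(sprintf("elasticity level %s at (row %d, col %d) outside [1, 256]",
                 format(levels[i]), rc[1], rc[2]))
  }
  b <- unclass(bar)
  array(b[cbind(as.integer(levels), rep(1:3, each = length(levels)))],
        dim = c(dim(levels), 3L))
}

#' Overlay pure color on BUS to form an EUS image
#'
#' The blend is additive: `EUS = floor((1 - weight) * BUS) + pure`, with the
#' BUS replicated to three channels. The pure color input is expected to be
#' pre-scaled into `[0, floor(255 * weight)]` (encode with a bar generated at
#' `value = weight`, see [default_color_bar()]); the function errors rather
#' than clip, so `extract_pure_color(overlay, scaled BUS)` is an exact
#' inverse.
#'
#' @param bus Grayscale BUS (`H x W`, `[0, 255]`), or an already-scaled BUS
#'   when `bus_prescaled = TRUE`.
#' @param pure Pure color image (`H x W x 3`).
#' @param weight Blending weight of the pure color, on `(0, 1]`.
#' @param bus_prescaled If `TRUE`, `bus` is already within
#'   `[0, (1 - weight) * 255]` and is used as-is.
#' @return RGB EUS image, `H x W x 3`.
#' @export
overlay_pure_color <- function(bus, pure, weight, bus_prescaled = FALSE) {
  check_gray(bus, "bus"); check_rgb(pure, "pure")
  check_same_dim(pure, bus, "pure", "bus")
  stopifnot(weight > 0, weight <= 1)
  bus_s <- if (bus_prescaled) bus else floor((1 - weight) * bus)
  eus <- gray_to_rgb(bus_s) + pure
  if (max(eus) > 255) {
    stop("overlay would clip: pure color must lie in [0, floor(255*weight)] ",
         "and BUS in [0, (1-weight)*255]")
  }
  eus
}
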
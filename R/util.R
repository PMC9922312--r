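## Shared validation helpers and the ROI box type.

#' Construct a region-of-interest box
#'
#' Boxes are 0-based and half-open: the box covers rows
#' `row .. row + height - 1` and columns `col .. col + width - 1`.
#'
#' @param row,col Top-left corner (0-based).
#' @param height,width Extent in pixels; both must be positive.
#' @return An object of class `veus_roi`, a named integer vector.
#' @export
roi_box <- function(row, col, height, width) {
  b <- c(row = as.integer(row), col = as.integer(col),
         height = as.integer(height), width = as.integer(width))
  if (anyNA(b)) stop("roi_box: all fields must be finite integers")
  if (b["height"] <= 0L || b["width"] <= 0L) stop("roi_box: height and width must be positive")
  if (b["row"] < 0L || b["col"] < 0L) stop("roi_box: row and col must be non-negative")
  structure(b, class = "veus_roi")
}

check_roi_in_image <- function(roi, dim_hw, what = "roi") {
  if (roi["row"] + roi["height"] > dim_hw[1] || roi["col"] + roi["width"] > dim_hw[2]) {
    stop(sprintf("%s (%d,%d,%d,%d) exceeds image bounds %dx%d",
                 what, roi["row"], roi["col"], roi["height"], roi["width"],
                 dim_hw[1], dim_hw[2]))
  }
  invisible(TRUE)
}

## 1-based row/col index ranges of a 0-based half-open box
roi_rows <- function(roi) seq.int(roi["row"] + 1L, roi["row"] + roi["height"])
roi_cols <- function(roi) seq.int(roi["col"] + 1L, roi["col"] + roi["width"])

rois_overlap <- function(a, b) {
  !(a["row"] + a["height"] <= b["row"] || b["row"] + b["height"] <= a["row"] ||
    a["col"] + a["width"]  <= b["col"] || b["col"] + b["width"]  <= a["col"])
}

check_gray <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) stop(name, " must be a numeric H x W matrix")
  invisible(TRUE)
}

check_rgb <- function(x, name = "image") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    stop(name, " must be a numeric H x W x 3 array")
  }
  invisible(TRUE)
}

check_same_dim <- function(a, b, na = "first image", nb = "second image") {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  if (!all(da == db)) {
    stop(sprintf("dimension mismatch: %s is %dx%d, %s is %dx%d",
                 na, da[1], da[2], nb, db[1], db[2]))
  }
  invisible(TRUE)
}

## replicate a grayscale matrix to 3 identical channels
gray_to_rgb <- function(x) array(x, dim = c(dim(x), 3L))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## 8-bit PNG helpers: values are stored as integers on [0, 255]
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  out <- round(img * 255)
  if (length(dim(out)) == 3L && dim(out)[3] == 1L) out <- out[, , 1]
  out
}

write_image_png <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, target = path)
  invisible(path)
}
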
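## The 256-level blue-to-red pseudo-color bar and its JSON serialization.

#' Construct a color bar
#'
#' A color bar is an ordered lookup of exactly 256 RGB triples mapping
#' elasticity level 1 (softest, blue end) through level 256 (hardest, red
#' end). All entries must be pairwise distinct: injectivity is what makes
#' nearest-color decoding an exact inverse of encoding.
#'
#' @param entries A 256 x 3 numeric matrix of 8-bit RGB values.
#' @return An object of class `veus_color_bar` (a 256 x 3 integer matrix with
#'   columns r, g, b).
#' @export
color_bar <- function(entries) {
  entries <- as.matrix(entries)
  if (!all(dim(entries) == c(256L, 3L))) {
    stop("a color bar needs exactly 256 RGB entries (got ",
         paste(dim(entries), collapse = "x"), ")")
  }
  storage.mode(entries) <- "integer"
  if (anyNA(entries) || any(entries < 0L) || any(entries > 255L)) {
    stop("color bar entries must be 8-bit values on [0, 255]")
  }
  if (anyDuplicated(as.data.frame(entries))) {
    stop("color bar entries must be pairwise distinct (decoding must invert encoding)")
  }
  dimnames(entries) <- list(NULL, c("r", "g", "b"))
  structure(entries, class = c("veus_color_bar", "matrix", "array"))
}

#' Default blue-to-red color bar
#'
#' A deterministic synthetic bar sweeping hue from blue (240 degrees) to red
#' (0 degrees) at full saturation. Vendors do not publish their elastography
#' colormaps; decoding only ever needs the bar that produced the image, so
#' any user-supplied 256-entry bar (see [read_color_bar()]) works equally.
#'
#' @param value HSV value (brightness) of the sweep, on (0, 1]. Bars
#'   generated at `value = w` have all channels within `[0, floor(255 w)]`,
#'   which is what the phantom's no-clipping overlay rule requires.
#' @return A `veus_color_bar`.
#' @export
#' @examples
#' bar <- default_color_bar()
#' bar[1, ]    # blue
#' bar[256, ]  # red
default_color_bar <- function(value = 1) {
  stopifnot(value > 0, value <= 1)
  k <- 0:255
  hue <- (2 / 3) * (1 - k / 255)
  rgb <- t(grDevices::col2rgb(grDevices::hsv(hue, 1, value)))
  color_bar(rgb)
}

#' Read or write a color bar as JSON
#'
#' The interchange format is `{"entries": [[r, g, b], ...]}` with 256 rows.
#'
#' @param path File path.
#' @return `read_color_bar()` returns a `veus_color_bar`; `write_color_bar()`
#'   returns `path` invisibly.
#' @export
read_color_bar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$entries)) stop("color bar JSON must have an 'entries' field")
  color_bar(obj$entries)
}

#' @rdname read_color_bar
#' @param bar A `veus_color_bar`.
#' @export
write_color_bar <- function(bar, path) {
  stopifnot(inherits(bar, "veus_color_bar"))
  jsonlite::write_json(list(entries = unclass(bar)), path,
                       dataframe = "values", matrix = "rowmajor")
  invisible(path)
}

#' @export
print.veus_color_bar <- function(x, ...) {
  cat("<veus_color_bar> 256 levels,",
      sprintf("level 1 = rgb(%d,%d,%d), level 256 = rgb(%d,%d,%d)\n",
              x[1, 1], x[1, 2], x[1, 3], x[256, 1], x[256, 2], x[256, 3]))
  invisible(x)
}
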
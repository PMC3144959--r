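#' Write a color section as PNG
#'
#' @param slice a [color_slice()] or `H x W x 3` array of 0-255 values.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_slice_png <- function(slice, path) {
  px <- if (inherits(slice, "color_slice")) slice$pixels else slice
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Read a color section from PNG
#'
#' Alpha channels are dropped; grayscale images are rejected (sections are
#' RGB).
#'
#' @param path PNG path.
#' @param order_index,section_thickness metadata for the [color_slice()].
#' @return a [color_slice()].
#' @export
read_slice_png <- function(path, order_index = 1L, section_thickness = 14) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 3 || dim(a)[3] < 3) {
    stop("expected an RGB(A) PNG: ", path, call. = FALSE)
  }
  color_slice(round(a[, , 1:3] * 255), order_index = order_index,
              section_thickness = section_thickness)
}

#' Write a binary mask as single-channel PNG (0/255)
#'
#' @param mask `H x W` logical matrix or `stain_mask`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  if (inherits(mask, "stain_mask")) mask <- mask$mask
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG path (single-channel or RGB; values > 0.5 are positive).
#' @return `H x W` logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0.5
}

#' Read a partition-line annotation file
#'
#' JSON with either a single `line` (applied to all sections) or per-slice
#' entries. Accepted shapes: `{"points": [[x,y],...], "side_convention":
#' "image_left"}` or a phantom sidecar (`phantom.json`) whose `line` element
#' has the same shape.
#'
#' @param path JSON path.
#' @return a [partition_line()].
#' @export
read_partition_annotation <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  node <- if (!is.null(j$line)) j$line else j
  if (is.null(node$points)) stop("no 'points' in annotation: ", path, call. = FALSE)
  sc <- if (!is.null(node$side_convention)) node$side_convention else "image_left"
  partition_line(as.matrix(node$points), side_convention = sc)
}
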
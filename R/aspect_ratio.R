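#' Aspect ratio of a binary shape mask
#'
#' Computes the isoperimetric aspect ratio \eqn{AR = P^2 / (4 \pi A)} of a
#' rasterized shape, where \eqn{P} is the outer-boundary perimeter and
#' \eqn{A} the foreground pixel count. A disk attains the minimum value 1;
#' elongated or limbed ("spiky") shapes score higher. Compact rounded
#' ("stubby") shapes stay close to 1.
#'
#' The perimeter is estimated by Moore-neighbour tracing of each connected
#' component's outer contour, then measuring the closed polygon through
#' every `stride`-th contour point. Resampling the digitized contour
#' removes most of the staircase bias of a raw chain-code length (which
#' overestimates smooth perimeters by about 5\%) while leaving polygonal
#' shapes essentially exact. Interior holes do not contribute.
#'
#' @param mask logical matrix; `TRUE` for foreground pixels.
#' @param stride contour resampling stride in pixels (default 4).
#' @return positive scalar aspect ratio.
#' @examples
#' disk <- raster_disk(64, 24)
#' compute_aspect_ratio(disk)  # ~1
#' @export
compute_aspect_ratio <- function(mask, stride = 4L) {
  mask <- validate_mask(mask)
  A <- sum(mask)
  P <- cpp_mask_perimeter(mask, as.integer(stride))
  P^2 / (4 * pi * A)
}

validate_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix")
  if (!any(mask)) stop("empty object")
  mask
}

#' Rasterize a disk mask
#'
#' Convenience fixture: a centered disk of given radius on a square grid.
#' Useful as the isoperimetric reference shape (aspect ratio 1).
#'
#' @param size grid side length in pixels.
#' @param radius disk radius in pixels.
#' @return logical `size x size` matrix.
#' @export
raster_disk <- function(size = 256L, radius = 60) {
  ctr <- (size + 1) / 2
  px <- seq_len(size) - ctr
  outer(px, px, function(y, x) x^2 + y^2 <= radius^2)
}
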
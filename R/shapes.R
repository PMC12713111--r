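#' Generate a synthetic object-shape mask
#'
#' Draws a random star-shaped (radially parameterized) region on a
#' 256 x 256 grid. `"stubby"` shapes are smoothly perturbed, slightly
#' stretched ellipses with aspect ratio close to 1; `"spiky"` shapes are
#' multi-armed stars whose thin limbs drive the isoperimetric aspect
#' ratio well above 3; `"median"` shapes have broad, shallow arms and land
#' between the two. The `category_style` integer nudges arm counts and
#' harmonic content so that shapes from different categories are
#' systematically (if mildly) different families.
#'
#' @param shape_class one of `"stubby"`, `"spiky"`, `"median"`.
#' @param category_style small integer style index (0-3 in practice).
#' @param seed integer seed; identical arguments give identical masks.
#' @param size grid side length in pixels.
#' @return logical `size x size` mask.
#' @export
generate_shape <- function(shape_class = c("stubby", "spiky", "median"),
                           category_style = 0L, seed = 1L, size = 256L) {
  shape_class <- match.arg(shape_class)
  set.seed(seed + 97L * as.integer(category_style))
  ctr <- (size + 1) / 2
  stretch <- runif(1, 1.0, 1.35)
  rot <- runif(1, 0, pi)
  if (shape_class == "stubby") {
    R0 <- runif(1, 52, 72)
    k <- 2:4
    amp <- runif(3, 0.02, 0.08)
    ph <- runif(3, 0, 2 * pi)
    rfun <- function(th) R0 * (1 + colSums(amp * sin(outer(k, th) + ph)))
  } else if (shape_class == "spiky") {
    arms <- 5L + (as.integer(category_style) %% 3L)
    pw <- runif(1, 2.5, 4)
    base <- runif(1, 0.18, 0.24)
    R0 <- runif(1, 95, 118)
    ph <- runif(1, 0, 2 * pi)
    rfun <- function(th)
      R0 * (base + (1 - base) * abs(cos(arms * th / 2 + ph))^pw)
  } else {
    arms <- 5L + (as.integer(category_style) %% 3L)
    base <- runif(1, 0.52, 0.62)
    R0 <- runif(1, 75, 95)
    ph <- runif(1, 0, 2 * pi)
    rfun <- function(th)
      R0 * (base + (1 - base) * abs(cos(arms * th / 2 + ph))^1.5)
  }
  px <- seq_len(size) - ctr
  X <- matrix(px, size, size, byrow = TRUE)
  Y <- matrix(px, size, size)
  # rotate, then stretch one axis (star-shapedness is preserved)
  Xr <- (cos(rot) * X + sin(rot) * Y) / stretch
  Yr <- -sin(rot) * X + cos(rot) * Y
  th <- atan2(Yr, Xr)
  rho <- sqrt(Xr^2 + Yr^2)
  rho <= matrix(rfun(as.vector(th)), size, size)
}

#' Render a stimulus image from a mask
#'
#' Silhouette rendering assigns the constant value 0.2 to every object
#' pixel on a mid-gray (0.5) background, destroying all internal detail
#' while preserving outline shape. Intact rendering fills the mask with a
#' seeded grayscale texture (a mixture of oriented gratings whose
#' frequency band depends on `category_style`), normalized so that the
#' mean foreground luminance is 0.5 for every stimulus.
#'
#' @param mask logical matrix from [generate_shape()].
#' @param rendering `"intact"` or `"silhouette"`.
#' @param seed integer seed for the intact texture.
#' @param category_style style index passed through from the stimulus set.
#' @return numeric matrix in `[0, 1]`, same dimensions as `mask`.
#' @export
render_stimulus <- function(mask, rendering = c("intact", "silhouette"),
                            seed = 1L, category_style = 0L) {
  rendering <- match.arg(rendering)
  mask <- validate_mask(mask)
  img <- matrix(0.5, nrow(mask), ncol(mask))
  if (rendering == "silhouette") {
    img[mask] <- 0.2
    return(img)
  }
  set.seed(seed + 131L * as.integer(category_style))
  n <- nrow(mask)
  px <- seq_len(n)
  X <- matrix(px, n, n, byrow = TRUE)
  Y <- matrix(px, n, n)
  tex <- matrix(0, n, n)
  fband <- 0.02 + 0.015 * (as.integer(category_style) %% 4L)
  for (g in 1:3) {
    f <- runif(1, fband, fband + 0.04)
    ang <- runif(1, 0, pi)
    phase <- runif(1, 0, 2 * pi)
    tex <- tex + runif(1, 0.5, 1) *
      sin(2 * pi * f * (X * cos(ang) + Y * sin(ang)) + phase)
  }
  fg <- tex[mask]
  fg <- (fg - mean(fg)) / max(sd(fg), 1e-12) * 0.15 + 0.5
  img[mask] <- pmin(pmax(fg, 0.02), 0.98)
  img
}
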
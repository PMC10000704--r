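#' Render a scenario to a high-resolution ground-truth image
#'
#' Rasterizes the physical scene onto a square grid spanning the full antenna
#' ring (`2 * antenna_radius`, 18 cm by default), centred at the origin.
#' Raster convention: row 1 is maximum y (north up), column 1 is minimum x.
#' Background is 0, tumor disks are filled at `tumor_value` (pixel-center
#' membership test) and the skin circle is drawn as a one-pixel-wide ring at
#' `skin_value`.
#'
#' @param scen an `mwi_scenario`.
#' @param size output side length in pixels (default 512).
#' @param tumor_value fill value for tumor pixels (default 255).
#' @param skin_value ring value for skin pixels (default 128); set to 0 to
#'   omit the skin, as used for binary tumor-only targets.
#' @return `size x size` numeric matrix with attributes `extent` (cm) and
#'   `pixel_pitch` (cm/pixel).
#' @export
render_scenario <- function(scen, size = 512, tumor_value = 255,
                            skin_value = 128) {
  cfg <- scen$cfg
  extent <- 2 * cfg$antenna_radius
  pitch <- extent / size
  # pixel-center coordinates; row i -> y decreasing, column j -> x increasing
  xs <- -extent / 2 + (seq_len(size) - 0.5) * pitch
  ys <- extent / 2 - (seq_len(size) - 0.5) * pitch
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(ys, size, size)
  img <- matrix(0, size, size)
  if (skin_value != 0) {
    rr <- sqrt(X^2 + Y^2)
    img[abs(rr - cfg$skin_radius) <= pitch / 2] <- skin_value
  }
  for (t in scen$tumors)
    img[(X - t$center_x)^2 + (Y - t$center_y)^2 <= t$radius^2] <- tumor_value
  attr(img, "extent") <- extent
  attr(img, "pixel_pitch") <- pitch
  img
}

#' Downscale an image by block averaging
#'
#' @param img square numeric matrix whose side is divisible by `target`.
#' @param target output side length (default 128).
#' @return `target x target` matrix; block means preserve the overall mean.
#' @export
downscale_image <- function(img, target = 128) {
  s <- nrow(img)
  if (s %% target != 0) stop("source size must be divisible by target size")
  b <- s %/% target
  a <- array(img, c(b, target, b, target))
  out <- matrix(colMeans(matrix(aperm(a, c(1, 3, 2, 4)), b * b)), target, target)
  ex <- attr(img, "extent")
  if (!is.null(ex)) {
    attr(out, "extent") <- ex
    attr(out, "pixel_pitch") <- ex / target
  }
  out
}

#' Binarize an image at a fraction of its maximum
#'
#' Pixels strictly above `threshold * max(img)` become 1. An all-zero image
#' stays all zero.
#'
#' @param img numeric matrix.
#' @param threshold fraction of the image maximum (default 0.5).
#' @return Matrix of 0/1 values, same shape.
#' @export
binarize_image <- function(img, threshold = 0.5) {
  stopifnot(all(is.finite(img)))
  m <- max(img)
  if (m <= 0) return(img * 0)
  (img > threshold * m) * 1
}

#' Float and binary ground-truth targets of a scenario
#'
#' The float target (0--255 with a gray skin ring) is the regression target
#' of the dense and convolutional reconstruction models; the binary target
#' (tumors only) is the segmentation target of the U-Net hybrids.
#'
#' @param scen an `mwi_scenario`.
#' @param size final image side (default 128).
#' @param hires rasterization side before block averaging (default `4 * size`).
#' @return List with matrices `float` (in `[0, 255]`) and `binary` (`{0,1}`).
#' @export
ground_truth_images <- function(scen, size = 128, hires = 4 * size) {
  fl <- downscale_image(render_scenario(scen, hires), size)
  bi <- binarize_image(
    downscale_image(render_scenario(scen, hires, skin_value = 0), size))
  list(float = fl, binary = bi)
}

#' Write a grayscale image to PNG
#'
#' @param img numeric matrix; values are scaled by `max_value` to `[0, 1]`.
#' @param path output file path.
#' @param max_value white level (default `max(img, 1)`).
#' @return The path, invisibly.
#' @export
write_image_png <- function(img, path, max_value = max(img, 1)) {
  png::writePNG(pmin(pmax(img / max_value, 0), 1), path)
  invisible(path)
}
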
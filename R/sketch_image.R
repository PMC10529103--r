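#' Raster sketch images
#'
#' A `sketch_image` wraps an H x W x 3 raster (integer values 0--255) together
#' with its background polarity and an optional integer class label. White
#' backgrounds with dark strokes are the native polarity of scanned
#' House-Tree-Person (HTP) drawings; large many-class sketch corpora typically
#' come as white strokes on black and must be inverted (see [invert_colors()])
#' before entering the model.
#'
#' @param pixels numeric array; either H x W x 3 or an H x W matrix (grayscale,
#'   promoted to 3 channels). Values in 0--255.
#' @param background `"white"` or `"black"`: the dominant canvas polarity.
#' @param label optional non-negative integer class id.
#' @param source_size optional `c(width, height)` of the original raster before
#'   any resizing (defaults to the current size).
#' @return An object of class `sketch_image` with fields `pixels`,
#'   `background`, `label`, `source_size`.
#' @examples
#' img <- sketch_image(matrix(255, 32, 32), background = "white")
#' dim(img$pixels)
#' @export
sketch_image <- function(pixels, background = c("white", "black"),
                         label = NULL, source_size = NULL) {
  background <- match.arg(background)
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3L))
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stopf("pixels must be H x W x 3 (or an H x W matrix)")
  if (d[1] < 1 || d[2] < 1) stopf("pixels must be non-empty")
  if (!all(is.finite(pixels))) stopf("pixels must be finite")
  if (min(pixels) < 0 || max(pixels) > 255) stopf("pixel values must lie in [0, 255]")
  if (!is.null(label)) {
    if (!is_count(label) || label < 0) stopf("label must be a non-negative integer")
    label <- as.integer(label)
  }
  if (is.null(source_size)) source_size <- c(d[2], d[1])
  structure(
    list(pixels = pixels, background = background, label = label,
         source_size = as.integer(source_size)),
    class = "sketch_image"
  )
}

#' @export
print.sketch_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<sketch_image %d x %d, %s background%s>\n", d[1], d[2], x$background,
              if (is.null(x$label)) "" else sprintf(", label %d", x$label)))
  invisible(x)
}

#' Read a sketch from a PNG or JPEG file
#'
#' PNG files are read natively; JPEG files require the EBImage package.
#' Grayscale images are promoted to 3 channels and values rescaled to 0--255.
#'
#' @param path file path.
#' @param background declared background polarity of the file.
#' @param label optional class label to attach.
#' @return A [sketch_image()].
#' @export
read_sketch <- function(path, background = c("white", "black"), label = NULL) {
  background <- match.arg(background)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stopf("reading '%s' requires the EBImage package (only PNG is supported natively)", ext)
    px <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(px)) >= 2) px <- aperm(px, c(2, 1, seq_along(dim(px))[-(1:2)]))
  }
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  sketch_image(round(px * 255), background = background, label = label)
}

#' Write a sketch to a PNG file
#'
#' @param image a [sketch_image()].
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_sketch <- function(image, path) {
  stopifnot(inherits(image, "sketch_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Channel-wise input normalization
#'
#' Scales pixels to `[0, 1]` and standardizes each channel with the given
#' means and standard deviations (defaults: the ImageNet constants commonly
#' assumed by pretrained convolutional stems).
#'
#' @param image a [sketch_image()] or an H x W x 3 array of 0--255 values.
#' @param mean,sd per-channel constants on the `[0, 1]` scale.
#' @return H x W x 3 numeric array of standardized values.
#' @export
normalize_pixels <- function(image, mean = c(0.485, 0.456, 0.406),
                             sd = c(0.229, 0.224, 0.225)) {
  px <- if (inherits(image, "sketch_image")) image$pixels else image
  px <- px / 255
  for (k in 1:3) px[, , k] <- (px[, , k] - mean[k]) / sd[k]
  px
}

#' Invert sketch polarity
#'
#' Pixel-wise `255 - v`, toggling the background flag. Used to convert
#' black-background/white-stroke corpora to the white-background/dark-stroke
#' polarity of HTP drawings before pre-training.
#'
#' @param image a [sketch_image()].
#' @return The inverted [sketch_image()].
#' @examples
#' img <- sketch_image(matrix(0, 8, 8), background = "black")
#' inv <- invert_colors(img)
#' inv$background
#' @export
invert_colors <- function(image) {
  stopifnot(inherits(image, "sketch_image"))
  sketch_image(255 - image$pixels,
               background = if (image$background == "white") "black" else "white",
               label = image$label, source_size = image$source_size)
}
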
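#' Overlapping local-patch geometry
#'
#' Computes the crop rectangles of the feature-enhancement stage. A square
#' sketch of side W is covered by P overlapping square patches of side
#' `floor(W * sigma)`:
#'
#' * `P = 5` (`sigma = 0.6`): four patches anchored at the image corners plus a
#'   center patch whose top-left corner is `floor(W * (1 - sigma) / 2)`. Each
#'   patch covers `sigma^2` = 36% of the image.
#' * `P = 9` (`sigma = 0.4`): a symmetric 3 x 3 grid with per-axis offsets
#'   `{0, floor((W - Wm)/2), W - Wm}`; each patch covers 16% of the image.
#'
#' Rectangles are half-open pixel intervals `[x0, x1) x [y0, y1)` in 0-based
#' pixel coordinates, so `x1 - x0` is the patch side. Fractional coordinates
#' are floored. Adjacent patches always overlap, which is what preserves the
#' hidden context between neighbouring regions of the sketch; sigma values too
#' small to produce overlap are rejected.
#'
#' @param width,height image size in pixels; the model assumes square input so
#'   `width == height` is required.
#' @param num_patches number of patches, 5 or 9.
#' @param sigma patch side as a fraction of the image side, in (0, 1). Defaults
#'   to 0.6 for 5 patches and 0.4 for 9.
#' @return An object of class `patch_layout`: list with `image_size` (W, H),
#'   `num_patches`, `sigma`, and `rects`, a `num_patches` x 4 integer matrix
#'   with columns `x0, y0, x1, y1`. Patch order is row-major with the center
#'   patch last for `P = 5`.
#' @examples
#' lay <- compute_patch_layout(1000, 1000, 5, 0.6)
#' lay$rects
#' @export
compute_patch_layout <- function(width, height, num_patches = 5, sigma = NULL) {
  if (!is_count(width) || !is_count(height) || width < 2) stopf("invalid image size")
  if (width != height) stopf("square input required")
  if (!num_patches %in% c(5L, 9L)) stopf("num_patches must be 5 or 9")
  if (is.null(sigma)) sigma <- if (num_patches == 5) 0.6 else 0.4
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0 || sigma >= 1)
    stopf("sigma must lie strictly between 0 and 1")
  W <- as.integer(width)
  side <- as.integer(floor(W * sigma))
  if (side < 1) stopf("sigma too small for this image")
  if (num_patches == 5) {
    if (2 * side <= W)
      stopf("patches must overlap: need sigma > 0.5 for the 5-patch layout")
    ctr <- as.integer(floor(W * (1 - sigma) / 2))
    off <- rbind(c(0L, 0L), c(W - side, 0L), c(0L, W - side), c(W - side, W - side),
                 c(ctr, ctr))
  } else {
    mid <- as.integer(floor((W - side) / 2))
    if (side <= mid)
      stopf("patches must overlap: sigma too small for the 9-patch layout")
    ax <- c(0L, mid, W - side)
    off <- as.matrix(expand.grid(x = ax, y = ax))[, 1:2]
    off <- off[order(off[, 2], off[, 1]), , drop = FALSE]  # row-major
  }
  rects <- cbind(x0 = off[, 1], y0 = off[, 2], x1 = off[, 1] + side, y1 = off[, 2] + side)
  rownames(rects) <- NULL
  structure(
    list(image_size = c(W, W), num_patches = as.integer(num_patches),
         sigma = sigma, side = side, rects = rects),
    class = "patch_layout"
  )
}

#' @export
print.patch_layout <- function(x, ...) {
  cat(sprintf("<patch_layout %d patches of side %d on %d x %d (sigma = %.2f)>\n",
              x$num_patches, x$side, x$image_size[1], x$image_size[2], x$sigma))
  invisible(x)
}

#' Crop and resize the local patches of a sketch
#'
#' Extracts the patches of a [compute_patch_layout()] from a white-background
#' sketch and resizes each to a common square side with bilinear
#' interpolation, in the layout's fixed order.
#'
#' @param image a [sketch_image()] with white background whose size matches
#'   `layout$image_size`.
#' @param layout a [patch_layout()].
#' @param out_side output side in pixels for every patch.
#' @return List of `num_patches` [sketch_image()] objects, each
#'   `out_side x out_side`.
#' @export
crop_patches <- function(image, layout, out_side = 224) {
  stopifnot(inherits(image, "sketch_image"), inherits(layout, "patch_layout"))
  d <- dim(image$pixels)
  if (d[1] != layout$image_size[2] || d[2] != layout$image_size[1])
    stopf("image size (%d x %d) does not match layout (%d x %d)",
          d[2], d[1], layout$image_size[1], layout$image_size[2])
  if (image$background != "white")
    stopf("white-background input required; apply invert_colors() first")
  lapply(seq_len(layout$num_patches), function(i) {
    r <- layout$rects[i, ]
    if (r["x0"] < 0 || r["y0"] < 0 || r["x1"] > d[2] || r["y1"] > d[1])
      stopf("patch rectangle falls outside the image")
    crop <- image$pixels[(r["y0"] + 1):r["y1"], (r["x0"] + 1):r["x1"], , drop = FALSE]
    px <- resize_bilinear(crop, out_side, out_side)
    sketch_image(clamp(px, 0, 255), background = "white", label = image$label,
                 source_size = image$source_size)
  })
}

# Crop + resize on an already-normalized (h, w, c) array; hot path used inside
# the model forward (normalization is per-channel affine, so it commutes with
# cropping and bilinear resampling).
crop_patches_array <- function(x, layout, out_side) {
  lapply(seq_len(layout$num_patches), function(i) {
    r <- layout$rects[i, ]
    resize_bilinear(x[(r[2] + 1):r[4], (r[1] + 1):r[3], , drop = FALSE], out_side, out_side)
  })
}
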
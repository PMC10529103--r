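#' Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping: the gradient of the target
#' class logit with respect to a convolutional activation is spatially
#' averaged per channel, used to weight the activation channels, rectified,
#' max-normalized to `[0, 1]`, and bilinearly upsampled to the model input
#' size. The default target is the bi-level fusion output (the concatenated
#' attention + global-compensation block feeding the head).
#'
#' @param model an [fbanet()] model (evaluated in inference mode).
#' @param image a [sketch_image()].
#' @param target_class class id whose logit is explained (0-based; default:
#'   the predicted class).
#' @param target_layer one of `"fusion"`, `"fw"`, `"gproj"`, `"head_conv"`,
#'   `"stem_global"`.
#' @return Object of class `fbanet_heatmap` with fields `values` (input-side
#'   square matrix in `[0, 1]`), `raw` (feature-resolution map),
#'   `target_layer`, `target_class`, `logits`.
#' @export
grad_cam <- function(model, image, target_class = NULL,
                     target_layer = "fusion") {
  stopifnot(inherits(model, "fbanet"))
  valid <- c("fusion", "fw", "gproj", "head_conv", "stem_global")
  if (config_geometry(model$config)$degenerate) valid <- setdiff(valid, "gproj")
  if (!target_layer %in% valid)
    stopf("unknown layer '%s'; valid ids: %s", target_layer, paste(valid, collapse = ", "))
  cfg <- model$config
  xg <- array(preprocess_image(image, cfg), c(cfg$input_side, cfg$input_side, 3, 1))
  fwd <- fbanet_forward(model, xg, train = FALSE, taps = target_layer)
  logits <- fwd$logits[1, ]
  if (is.null(target_class)) target_class <- which.max(logits) - 1L
  if (target_class < 0 || target_class >= cfg$num_class) stopf("target_class out of range")
  dlogits <- matrix(0, 1, cfg$num_class)
  dlogits[1, target_class + 1L] <- 1
  bwd <- fbanet_backward(model, fwd$cache, dlogits)
  A <- fwd$cache$cs$tap[[target_layer]]
  A <- array(A, dim(A)[1:3])          # single-sample batch
  G <- bwd$tap_grads[[target_layer]]
  G <- array(G, dim(G)[1:3])
  w <- apply(G, 3, mean)
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_along(w)) cam <- cam + w[k] * A[, , k]
  cam <- pmax(cam, 0)
  if (max(cam) > 0) cam <- cam / max(cam)
  up <- resize_bilinear(cam, cfg$input_side, cfg$input_side)
  up <- clamp(up, 0, 1)
  structure(list(values = up, raw = cam, target_layer = target_layer,
                 target_class = as.integer(target_class), logits = logits),
            class = "fbanet_heatmap")
}

#' @export
print.fbanet_heatmap <- function(x, ...) {
  cat(sprintf("<fbanet_heatmap %d x %d, layer '%s', class %d, range [%.3f, %.3f]>\n",
              nrow(x$values), ncol(x$values), x$target_layer, x$target_class,
              min(x$values), max(x$values)))
  invisible(x)
}

# blue -> green -> yellow -> red colormap on [0,1]; returns (n, 3) matrix.
jet_colors <- function(v) {
  ramp <- grDevices::colorRamp(c("#00007F", "#0000FF", "#00FFFF", "#FFFF00",
                                 "#FF0000", "#7F0000"))
  ramp(clamp(v, 0, 1)) / 255
}

#' Save a Grad-CAM overlay image
#'
#' Alpha-blends the colormapped heatmap over the sketch (resized to the
#' heatmap resolution) and writes a PNG.
#'
#' @param heatmap an [grad_cam()] result.
#' @param image the [sketch_image()] it explains.
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap in `[0, 1]` (0 = sketch only,
#'   1 = heatmap only).
#' @return `path`, invisibly.
#' @export
save_overlay <- function(heatmap, image, path, alpha = 0.5) {
  stopifnot(inherits(heatmap, "fbanet_heatmap"), inherits(image, "sketch_image"))
  side <- nrow(heatmap$values)
  px <- image$pixels
  if (any(dim(px)[1:2] != side)) px <- clamp(resize_bilinear(px, side, side), 0, 255)
  cmap <- jet_colors(as.vector(heatmap$values))
  out <- array(0, c(side, side, 3))
  for (k in 1:3)
    out[, , k] <- (1 - alpha) * px[, , k] / 255 + alpha * matrix(cmap[, k], side, side)
  png::writePNG(clamp(out, 0, 1), target = path)
  invisible(path)
}
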
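# Gradient-weighted class activation mapping. The heat map for a target class
# is built from the designated feature layer (the latest spatial layer before
# the classifier): gradients of the class logit w.r.t. that layer are averaged
# over the spatial dimensions to give one importance weight per channel, the
# feature maps are combined with those weights, rectified, bilinearly
# upsampled to the input image size and min-max normalized to [0, 1].

#' Per-channel importance weights from feature-layer gradients
#'
#' Averages the gradient of the target class score over the spatial
#' dimensions of each feature channel.
#'
#' @param gradients H' x W' x C' array of d(class logit)/d(feature).
#' @return Numeric vector of C' channel weights.
#' @export
channel_weights <- function(gradients) {
  d <- dim(gradients)
  if (is.null(d) || length(d) != 3 || any(d < 1))
    stop("shape error: gradients must be a nonempty H' x W' x C' array")
  if (!all(is.finite(gradients))) stop("gradients must be finite")
  apply(gradients, 3, mean)
}

#' Combine feature maps with channel weights into a coarse activation map
#'
#' Computes ReLU(sum_c weight_c * feature_c). Rectification discards spatial
#' locations that argue against the class; it can be disabled.
#'
#' @param features H' x W' x C' feature array.
#' @param weights Numeric vector of C' channel weights.
#' @param rectify Apply ReLU (default TRUE).
#' @return H' x W' matrix of (nonnegative, if rectified) reals.
#' @export
cam <- function(features, weights, rectify = TRUE) {
  d <- dim(features)
  if (is.null(d) || length(d) != 3)
    stop("shape error: features must be an H' x W' x C' array")
  if (d[3] != length(weights))
    stop("shape error: ", d[3], " channels but ", length(weights), " weights")
  m <- matrix(0, d[1], d[2])
  for (c in seq_len(d[3])) m <- m + weights[c] * features[, , c]
  if (rectify) m <- pmax(m, 0)
  m
}

#' Upsample a coarse activation map and normalize to \[0, 1\]
#'
#' Bilinear upsampling to the target size followed by min-max normalization.
#' A constant map carries no localization signal and maps to the all-zero
#' heat map.
#'
#' @param coarse H' x W' matrix.
#' @param target Integer (height, width), both >= the coarse size.
#' @param class_id,source_frame Optional metadata stored on the heat map.
#' @return A `camloc_heatmap`: list with `values` (H x W matrix in \[0,1\]),
#'   `class_id`, `source_frame`.
#' @export
upsample_normalize <- function(coarse, target, class_id = NA_integer_,
                               source_frame = NA_character_) {
  stopifnot(is.matrix(coarse))
  if (target[1] < nrow(coarse) || target[2] < ncol(coarse))
    stop("size error: target must be >= coarse map in both dimensions")
  up <- resize_bilinear(coarse, target[1], target[2])
  rng <- range(up)
  vals <- if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2])))
    matrix(0, target[1], target[2])
  else (up - rng[1]) / (rng[2] - rng[1])
  structure(list(values = vals, class_id = class_id, source_frame = source_frame),
            class = "camloc_heatmap")
}

#' Grad-CAM heat map for one class on one frame
#'
#' Composes the forward pass, the backward pass of the target class logit
#' (pre-sigmoid, so the gradient is not attenuated by sigmoid saturation),
#' [channel_weights()], [cam()] and [upsample_normalize()]. The map is
#' upsampled to the size of the supplied image.
#'
#' @param model A `camloc_model`.
#' @param image H x W x 3 array or PNG path.
#' @param class_id 0-based class index (< K).
#' @param rectify Apply ReLU before normalization (default TRUE).
#' @return A `camloc_heatmap` of the same height/width as `image`.
#' @export
grad_cam <- function(model, image, class_id, rectify = TRUE) {
  if (is.character(image)) image <- read_frame(image)
  if (class_id < 0 || class_id >= model$n_classes)
    stop("index error: class_id ", class_id, " out of range [0, ",
         model$n_classes - 1, "]")
  fw <- .model_forward_features(model, image)
  g <- fw$grad_fn(class_id)
  w <- channel_weights(g)
  coarse <- cam(fw$features, w, rectify = rectify)
  upsample_normalize(coarse, dim(image)[1:2], class_id = as.integer(class_id))
}

#' Export a heat map as grayscale or false-color overlay PNG
#'
#' @param heatmap A `camloc_heatmap`.
#' @param path Output PNG path.
#' @param frame Optional H x W x 3 frame to blend under a false-color
#'   (blue -> red) rendering of the map; omitted, a grayscale PNG is written.
#' @param blend Blend weight of the false-color layer in \[0,1\].
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path, frame = NULL, blend = 0.5) {
  v <- heatmap$values
  if (is.null(frame)) {
    png::writePNG(v, path)
  } else {
    stopifnot(identical(dim(frame)[1:2], dim(v)))
    png::writePNG(blend_heatmap(frame, v, blend), path)
  }
  invisible(path)
}

# Jet-like false-color mapping of values in [0,1]: blue (low) -> red (high).
heat_colors <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  out <- array(0, c(dim(v), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}

# Alpha-blend a false-color heat map over a frame.
blend_heatmap <- function(frame, values, blend = 0.5) {
  hc <- heat_colors(values)
  pmin(pmax((1 - blend) * frame + blend * hc, 0), 1)
}
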
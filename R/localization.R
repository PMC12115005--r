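# Heat-map -> bounding-box post-processing: Otsu binarization of the 8-bit
# quantized heat map, 8-connected contour extraction, rule-based filtering
# (instrument contours must touch a frame edge and exceed an area floor),
# tight boxes and per-class greedy non-maximum suppression.
#
# Coordinate convention throughout: x rightward, y downward, 0-based pixels,
# boxes (x_min, y_min, x_max, y_max) half-open.

#' Localization post-processing configuration
#'
#' @param edge_margin_px A contour is "edge-touching" if some pixel lies
#'   within this many pixels of any image border (default 2; tolerates
#'   anti-aliased borders).
#' @param min_area_fraction Minimum contour area as a fraction of the image
#'   area (default 0.005); suppresses speckle.
#' @param nms_iou_threshold Greedy NMS suppression threshold in (0, 1\].
#' @param presence_threshold Classifier probability above which a class is
#'   localized at all, in (0, 1).
#' @return A `localization_config` object.
#' @export
localization_config <- function(edge_margin_px = 2L, min_area_fraction = 0.005,
                                nms_iou_threshold = 0.5, presence_threshold = 0.5) {
  stopifnot(edge_margin_px >= 0, min_area_fraction >= 0, min_area_fraction < 1,
            nms_iou_threshold > 0, nms_iou_threshold <= 1,
            presence_threshold > 0, presence_threshold < 1)
  structure(list(edge_margin_px = as.integer(edge_margin_px),
                 min_area_fraction = min_area_fraction,
                 nms_iou_threshold = nms_iou_threshold,
                 presence_threshold = presence_threshold),
            class = "localization_config")
}

#' Otsu's threshold of an 8-bit image
#'
#' Returns the gray level t in 0..255 maximizing the between-class variance
#' sigma_B^2(t) = w0 w1 (mu0 - mu1)^2 of the split {<= t} / {> t}, computed
#' from the 256-bin histogram. Ties are broken toward the smallest t.
#' Foreground is defined as pixels with value > t.
#'
#' @param gray Integer matrix with values in 0..255.
#' @return The threshold (integer), or `NA_integer_` for a constant image
#'   (degenerate: no two-class split exists; callers treat the mask as empty).
#' @export
otsu_threshold <- function(gray) {
  if (length(gray) == 0) stop("nonempty grid required")
  v <- as.integer(gray)
  if (any(v < 0 | v > 255)) stop("values must be 8-bit (0..255)")
  if (min(v) == max(v)) return(NA_integer_)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levels <- 0:255
  w0 <- cumsum(p)                      # P(value <= t)
  mu <- cumsum(p * levels)             # partial mean numerator
  mu_total <- mu[256]
  w1 <- 1 - w0
  # between-class variance; undefined where a side is empty
  num <- (mu_total * w0 - mu)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)
  as.integer(which.max(sigma_b) - 1L)  # which.max takes the first (smallest t)
}

#' Extract 8-connected foreground contours from a binary mask
#'
#' Labels 8-connected foreground components and returns one contour per
#' component, ordered by the component's first pixel in row-major (top-left
#' first) scan order.
#'
#' @param mask Integer/logical H x W matrix; nonzero = foreground.
#' @return List of `camloc_contour` objects, each with `pixels` (n x 2 matrix
#'   of 0-based (x, y)), `boundary` (perimeter pixels: those with a
#'   non-component 4-neighbour or on the image border), and `area`.
#' @export
extract_contours <- function(mask) {
  stopifnot(is.matrix(mask))
  fg <- mask != 0
  h <- nrow(fg); w <- ncol(fg)
  if (!any(fg)) return(list())
  lab <- matrix(Inf, h, w)
  lab[fg] <- which(fg)        # unique provisional label per foreground pixel
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- matrix(Inf, h, w)
      ys <- max(1, 1 + s[1]):min(h, h + s[1])
      xs <- max(1, 1 + s[2]):min(w, w + s[2])
      sh[ys, xs] <- lab[ys - s[1], xs - s[2]]
      new <- pmin(new, sh)
    }
    new[!fg] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  labs <- lab[fg]
  # order components by first pixel in row-major scan (top-left-most first)
  first_rowmajor <- vapply(unique(labs), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    min((idx[, 1] - 1) * w + (idx[, 2] - 1))
  }, numeric(1))
  comp_ids <- unique(labs)[order(first_rowmajor)]
  lapply(comp_ids, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)   # (row, col) 1-based
    x <- idx[, 2] - 1L; y <- idx[, 1] - 1L
    ord <- order(y, x)
    x <- x[ord]; y <- y[ord]
    inside <- function(xx, yy) {
      ok <- xx >= 0 & xx < w & yy >= 0 & yy < h
      res <- logical(length(xx)); res[ok] <- lab[cbind(yy[ok] + 1, xx[ok] + 1)] == l
      res
    }
    on_border <- x == 0 | y == 0 | x == w - 1 | y == h - 1
    interior <- inside(x - 1, y) & inside(x + 1, y) & inside(x, y - 1) & inside(x, y + 1)
    bnd <- cbind(x = x[on_border | !interior], y = y[on_border | !interior])
    structure(list(pixels = cbind(x = x, y = y), boundary = bnd,
                   area = length(x)), class = "camloc_contour")
  })
}

#' Filter contours by the edge-touch and minimum-area rules
#'
#' A surgical instrument enters the field of view from outside, so its contour
#' must touch the frame edge; contours failing that test, or smaller than the
#' area floor, are discarded. Order is preserved.
#'
#' @param contours List of `camloc_contour`.
#' @param image_size Integer (height, width).
#' @param config A [localization_config()].
#' @return Filtered list of contours.
#' @export
filter_contours <- function(contours, image_size, config = localization_config()) {
  h <- image_size[1]; w <- image_size[2]
  m <- config$edge_margin_px
  keep <- vapply(contours, function(ct) {
    x <- ct$pixels[, 1]; y <- ct$pixels[, 2]
    touches <- any(x <= m | y <= m | x >= w - 1 - m | y >= h - 1 - m)
    touches && ct$area >= config$min_area_fraction * h * w
  }, logical(1))
  contours[keep]
}

#' Tight axis-aligned bounding box of a contour
#'
#' @param contour A `camloc_contour`.
#' @return Numeric (x_min, y_min, x_max, y_max), 0-based half-open.
#' @export
contour_to_bbox <- function(contour) {
  if (is.null(contour$pixels) || nrow(contour$pixels) == 0)
    stop("value error: empty contour")
  x <- contour$pixels[, 1]; y <- contour$pixels[, 2]
  c(x_min = min(x), y_min = min(y), x_max = max(x) + 1, y_max = max(y) + 1)
}

#' Intersection over union of two boxes
#'
#' @param a,b Boxes (x_min, y_min, x_max, y_max), half-open.
#' @return IoU in \[0, 1\].
#' @export
box_iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  area <- function(z) (z[3] - z[1]) * (z[4] - z[2])
  if (area(a) <= 0 || area(b) <= 0) stop("value error: degenerate (zero-area) box")
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  inter <- max(iw, 0) * max(ih, 0)
  inter / (area(a) + area(b) - inter)
}

#' Empty detection table
#' @return Zero-row data.frame with the detection columns.
#' @export
empty_detections <- function() {
  data.frame(class_id = integer(), confidence = numeric(), x_min = numeric(),
             y_min = numeric(), x_max = numeric(), y_max = numeric())
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-confidence remaining detection (ties broken by
#' larger box area, then input order) and discards detections whose IoU with
#' it exceeds the threshold. Input detections must share one class.
#'
#' @param detections data.frame with columns `class_id, confidence, x_min,
#'   y_min, x_max, y_max`.
#' @param iou_threshold Suppression threshold in (0, 1\].
#' @return Surviving detections, sorted by descending confidence.
#' @export
nms <- function(detections, iou_threshold = 0.5) {
  if (nrow(detections) == 0) return(detections)
  if (length(unique(detections$class_id)) > 1)
    stop("nms operates on detections of a single class")
  area <- (detections$x_max - detections$x_min) * (detections$y_max - detections$y_min)
  ord <- order(-detections$confidence, -area, seq_len(nrow(detections)))
  alive <- rep(TRUE, nrow(detections))
  keep <- integer()
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[i] <- FALSE
    for (j in ord) {
      if (!alive[j]) next
      if (box_iou(unlist(detections[i, c("x_min", "y_min", "x_max", "y_max")]),
                  unlist(detections[j, c("x_min", "y_min", "x_max", "y_max")])) >
          iou_threshold)
        alive[j] <- FALSE
    }
  }
  out <- detections[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert one heat map into class detections
#'
#' The post-processing chain of the weakly supervised localizer: 8-bit
#' quantization, Otsu thresholding (foreground > t), 8-connected contour
#' extraction, edge-touch + area filtering, tight boxes, greedy NMS. A
#' degenerate (constant) heat map yields no detections.
#'
#' @param heatmap A `camloc_heatmap` or plain H x W matrix in \[0,1\].
#' @param class_id 0-based class id recorded on the detections.
#' @param confidence Confidence assigned to every box (the classifier's
#'   presence probability for the class).
#' @param config A [localization_config()].
#' @return Detection data.frame (possibly empty).
#' @export
heatmap_to_detections <- function(heatmap, class_id = 0L, confidence = 1.0,
                                  config = localization_config()) {
  v <- if (inherits(heatmap, "camloc_heatmap")) heatmap$values else heatmap
  q <- quantize_8bit(v)
  t <- otsu_threshold(q)
  if (is.na(t)) return(empty_detections())
  mask <- (q > t) * 1L
  cts <- extract_contours(mask)
  cts <- filter_contours(cts, dim(v), config)
  if (!length(cts)) return(empty_detections())
  boxes <- t(vapply(cts, contour_to_bbox, numeric(4)))
  det <- data.frame(class_id = as.integer(class_id), confidence = unname(confidence),
                    x_min = unname(boxes[, 1]), y_min = unname(boxes[, 2]),
                    x_max = unname(boxes[, 3]), y_max = unname(boxes[, 4]))
  nms(det, config$nms_iou_threshold)
}

#' Weakly supervised tool localization for one frame
#'
#' For each class whose predicted presence probability exceeds the presence
#' threshold, computes the Grad-CAM heat map and post-processes it into
#' bounding boxes ([heatmap_to_detections()]). Each detection's confidence is
#' the class probability. Classes at or below the threshold yield no
#' detections.
#'
#' @param model A trained `camloc_model`.
#' @param image H x W x 3 array or PNG path.
#' @param config A [localization_config()].
#' @return Detection data.frame across all predicted-present classes.
#' @export
localize <- function(model, image, config = localization_config()) {
  if (is.character(image)) image <- read_frame(image)
  pred <- predict(model, image)
  out <- list()
  for (k in seq_len(model$n_classes)) {
    p <- pred$probabilities[k]
    if (p <= config$presence_threshold) next
    hm <- grad_cam(model, image, k - 1L)
    det <- heatmap_to_detections(hm, class_id = k - 1L, confidence = p,
                                 config = config)
    if (nrow(det)) out[[length(out) + 1L]] <- det
  }
  if (!length(out)) return(empty_detections())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write / read a detections CSV
#'
#' Columns: `frame_path,class_id,confidence,x_min,y_min,x_max,y_max`.
#'
#' @param detections Detection data.frame (with `frame_path`).
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_detections <- function(detections, path) {
  cols <- c("frame_path", "class_id", "confidence", "x_min", "y_min", "x_max", "y_max")
  if (nrow(detections) == 0)
    detections <- data.frame(frame_path = character(), class_id = integer(),
                             confidence = numeric(), x_min = numeric(),
                             y_min = numeric(), x_max = numeric(), y_max = numeric())
  utils::write.csv(detections[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) utils::read.csv(path)
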
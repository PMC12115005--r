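test_that("Otsu threshold separates a two-value image and handles degeneracy", {
  img <- matrix(c(rep(60L, 40), rep(200L, 60)), 10, 10)
  t <- otsu_threshold(img)
  expect_gte(t, 60L); expect_lt(t, 200L)
  expect_identical(t, oracle_otsu(img))
  expect_identical(otsu_threshold(matrix(7L, 5, 5)), NA_integer_)
  expect_error(otsu_threshold(matrix(300L, 2, 2)), "8-bit")
  expect_error(otsu_threshold(matrix(integer(), 0, 0)), "nonempty")
})

test_that("Otsu matches the exhaustive oracle on random images", {
  set.seed(41)
  for (rep in 1:60) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
  # bimodal images too
  for (rep in 1:20) {
    lo <- sample(0:100, 1); hi <- sample(150:255, 1)
    img <- matrix(sample(c(lo + sample(-5:5, 30, TRUE), hi + sample(-5:5, 34, TRUE))),
                  8, 8)
    img <- pmin(pmax(img, 0L), 255L)
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
})

test_that("contour extraction labels 8-connected components correctly", {
  mask <- matrix(0L, 8, 8)
  mask[2:4, 2:5] <- 1L                        # 3x4 rectangle
  cts <- extract_contours(mask)
  expect_length(cts, 1)
  expect_identical(cts[[1]]$area, 12L)
  expect_equal(contour_to_bbox(cts[[1]]),
               c(x_min = 1, y_min = 1, x_max = 5, y_max = 4))
  # diagonal touch merges under 8-connectivity
  mask2 <- matrix(0L, 5, 5)
  mask2[1, 1] <- 1L; mask2[2, 2] <- 1L
  expect_length(extract_contours(mask2), 1)
  # two separated blobs stay separate, ordered by row-major first pixel
  mask3 <- matrix(0L, 8, 8)
  mask3[6:7, 6:7] <- 1L; mask3[1:2, 1:2] <- 1L
  cts3 <- extract_contours(mask3)
  expect_length(cts3, 2)
  expect_identical(cts3[[1]]$pixels[1, ], c(x = 0L, y = 0L))
  expect_identical(extract_contours(matrix(0L, 4, 4)), list())
})

test_that("contour extraction matches the flood-fill oracle", {
  set.seed(42)
  for (rep in 1:15) {
    mask <- matrix(stats::rbinom(12 * 14, 1, 0.35), 12, 14)
    cts <- extract_contours(mask)
    oc <- oracle_components(mask)
    expect_length(cts, length(oc))
    key <- function(p) paste(sort(p[, 1] * 1000 + p[, 2]), collapse = ",")
    expect_setequal(vapply(cts, function(ct) key(ct$pixels), character(1)),
                    vapply(oc, key, character(1)))
    # boundary pixels are a subset of the component's pixels
    for (ct in cts)
      expect_true(all(paste(ct$boundary[, 1], ct$boundary[, 2]) %in%
                        paste(ct$pixels[, 1], ct$pixels[, 2])))
  }
})

test_that("contour filtering enforces edge contact and the area floor", {
  cfg <- localization_config(edge_margin_px = 2, min_area_fraction = 0.005)
  mask <- matrix(0L, 40, 40)
  mask[1:6, 1:6] <- 1L          # touches the border: kept
  mask[18:23, 18:23] <- 1L      # interior: removed
  mask[38, 20] <- 1L            # touches border but area 1 < 8 pixels: removed
  cts <- extract_contours(mask)
  kept <- filter_contours(cts, c(40, 40), cfg)
  expect_length(kept, 1)
  expect_equal(unname(contour_to_bbox(kept[[1]])), c(0, 0, 6, 6))
  expect_identical(filter_contours(list(), c(40, 40), cfg), list())
})

test_that("bounding boxes are tight and half-open", {
  px <- structure(list(pixels = cbind(x = 2L, y = 3L), area = 1L),
                  class = "camloc_contour")
  expect_equal(contour_to_bbox(px), c(x_min = 2, y_min = 3, x_max = 3, y_max = 4))
  many <- structure(list(pixels = cbind(x = c(0L, 9L, 4L), y = c(5L, 0L, 2L)),
                         area = 3L), class = "camloc_contour")
  expect_equal(contour_to_bbox(many), c(x_min = 0, y_min = 0, x_max = 10, y_max = 6))
  expect_error(contour_to_bbox(structure(list(pixels = NULL), class = "camloc_contour")),
               "empty")
})

test_that("box IoU matches hand calculations", {
  a <- c(0, 0, 10, 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, c(20, 20, 30, 30)), 0)
  expect_equal(box_iou(a, c(5, 0, 15, 10)), 1 / 3, tolerance = 1e-12)
  expect_equal(box_iou(a, c(0, 0, 5, 10)), 0.5)
  # symmetry
  expect_equal(box_iou(c(1, 2, 7, 9), c(3, 0, 10, 5)),
               box_iou(c(3, 0, 10, 5), c(1, 2, 7, 9)))
  expect_error(box_iou(a, c(0, 0, 0, 10)), "degenerate")
})

test_that("greedy NMS keeps the right boxes", {
  det <- data.frame(class_id = 0L,
                    confidence = c(0.9, 0.8, 0.7),
                    x_min = c(0, 1, 30), y_min = c(0, 1, 30),
                    x_max = c(10, 11, 40), y_max = c(10, 11, 40))
  out <- nms(det, 0.5)
  expect_identical(nrow(out), 2L)
  expect_equal(out$confidence, c(0.9, 0.7))
  # at exactly the threshold the box is NOT suppressed (strict >)
  det2 <- data.frame(class_id = 0L, confidence = c(0.9, 0.8),
                     x_min = c(0, 5), y_min = c(0, 0),
                     x_max = c(10, 15), y_max = c(10, 10))
  expect_identical(nrow(nms(det2, 1 / 3)), 2L)
  expect_identical(nrow(nms(det2, 0.33)), 1L)
  # confidence tie broken by larger area
  det3 <- data.frame(class_id = 0L, confidence = c(0.5, 0.5),
                     x_min = c(0, 0), y_min = c(0, 0),
                     x_max = c(5, 8), y_max = c(5, 8))
  expect_equal(nms(det3, 0.3)$x_max[1], 8)
  expect_error(nms(data.frame(class_id = c(0L, 1L), confidence = 1,
                              x_min = 0, y_min = 0, x_max = 1, y_max = 1), 0.5),
               "single class")
  expect_identical(nrow(nms(empty_detections(), 0.5)), 0L)
})

test_that("NMS matches the definitional oracle on random box sets", {
  set.seed(43)
  for (rep in 1:40) {
    det <- random_boxes(sample(1:12, 1))
    thr <- sample(c(0.3, 0.5, 0.7), 1)
    got <- nms(det, thr)
    want <- oracle_nms(det, thr)
    expect_equal(got, want)
  }
})

test_that("a planted blob heat map is recovered as a tight box", {
  h <- matrix(0, 64, 64)
  h[1:20, 5:20] <- 0.95          # y 0..19, x 4..19, touching the top edge
  h <- h + matrix(stats::runif(64 * 64, 0, 0.05), 64, 64)
  h <- pmin(h, 1)
  det <- heatmap_to_detections(h, class_id = 3L, confidence = 0.8)
  expect_identical(nrow(det), 1L)
  expect_identical(det$class_id, 3L)
  expect_equal(det$confidence, 0.8)
  iou <- box_iou(as.numeric(det[1, c("x_min", "y_min", "x_max", "y_max")]),
                 c(4, 0, 20, 20))
  expect_gte(iou, 0.9)
  # constant heat map -> no detections
  expect_identical(nrow(heatmap_to_detections(matrix(0, 32, 32))), 0L)
})

test_that("localize gates classes on the presence threshold", {
  b <- blob_image(cy = 5)   # blob clipped by the top edge -> passes edge filter
  m <- identity_model(2)
  # blob luminance pushes mean > 0 -> both identity logits positive -> p > 0.5
  det <- localize(m, b$image)
  expect_identical(sort(unique(det$class_id)), c(0L, 1L))
  expect_true(all(det$confidence > 0.5))
  h <- 64; w <- 64
  expect_true(all(det$x_min >= 0 & det$y_min >= 0 &
                    det$x_max <= w & det$y_max <= h))
  # a black frame has zero logits, p = 0.5, not above the threshold
  expect_identical(nrow(localize(m, array(0, c(32, 32, 3)))), 0L)
})

test_that("detections CSV round-trips", {
  det <- random_boxes(5)
  det$frame_path <- sprintf("frames/frame_%06d.png", seq_len(5))
  p <- file.path(tempdir(), "dets.csv")
  write_detections(det, p)
  back <- read_detections(p)
  expect_equal(back$confidence, det$confidence)
  expect_equal(back$x_min, det$x_min)
  expect_identical(back$frame_path, det$frame_path)
  header <- readLines(p, n = 1)
  expect_identical(header, "frame_path,class_id,confidence,x_min,y_min,x_max,y_max")
  write_detections(empty_detections(), p)
  expect_identical(nrow(read_detections(p)), 0L)
})
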
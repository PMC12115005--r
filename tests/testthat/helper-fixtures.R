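# Shared fixtures built once per test run: a small synthetic dataset and a
# quickly trained surrogate model (cached across test files).

.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$man)) {
    cfg <- scene_config(image_size = c(96, 96), seed = 21,
                        # boost the rare classes so a 40-frame fixture sees them
                        class_prevalences = c(0.45, 0.25, 0.45, 0.2, 0.2, 0.25, 0.25))
    .fixture_env$man <- generate_dataset(cfg, 40, 4,
                                         file.path(tempdir(), "camloc_fixture"))
  }
  .fixture_env$man
}

tiny_model <- function() {
  if (is.null(.fixture_env$model)) {
    man <- tiny_dataset()
    .fixture_env$model <- suppressWarnings(train_classifier(
      man, 0:2, config = surrogate_train_config(seed = 4, epochs = 4)))
  }
  .fixture_env$model
}

# An image with a single bright blob on black background, plus its tight box.
blob_image <- function(h = 64, w = 64, cx = 20, cy = 30, r = 8) {
  img <- array(0, c(h, w, 3))
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  m <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  for (c in 1:3) { ch <- img[, , c]; ch[m] <- 1; img[, , c] <- ch }
  idx <- which(m, arr.ind = TRUE)
  list(image = img,
       box = c(x_min = min(idx[, 2]) - 1, y_min = min(idx[, 1]) - 1,
               x_max = max(idx[, 2]), y_max = max(idx[, 1])))
}
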
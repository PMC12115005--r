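# Multi-label tool-presence classifier: class-weighted BCE-with-logits loss,
# Adam optimization with linear warmup, and a small convolutional surrogate
# backbone (conv -> ReLU -> global average pooling -> linear head) whose final
# spatial feature layer is exposed for Grad-CAM. Forward and backward passes
# are written directly in R (im2col + BLAS matrix products); the backbone is
# deliberately tiny (~5k parameters) so the full pipeline trains on a CPU in
# seconds while preserving the semantics of "the latest layer before the
# classifier".

#' Class weights for imbalanced multi-label training
#'
#' Computes CW_k = N / (K * n_k), where N is the number of training images,
#' K the number of classes and n_k the number of training images containing
#' class k. Counts must come from the training split only, so the weights
#' reflect the distribution the loss actually sees. Rare classes receive
#' proportionally larger weights, and the weights satisfy
#' sum_k CW_k * n_k = N.
#'
#' @param class_counts Integer vector of per-class positive counts (all > 0).
#' @param n_train_images Total number of training images N (> 0).
#' @return A `class_weights` object storing `weights`, `class_counts`,
#'   `n_train_images` and `n_classes`.
#' @export
compute_class_weights <- function(class_counts, n_train_images) {
  if (n_train_images <= 0) stop("n_train_images must be positive")
  bad <- which(class_counts <= 0)
  if (length(bad)) {
    nm <- if (!is.null(names(class_counts))) names(class_counts)[bad] else as.character(bad)
    stop("degenerate class count (<= 0) for class(es): ", paste(nm, collapse = ", "))
  }
  K <- length(class_counts)
  structure(list(
    weights = n_train_images / (K * as.numeric(class_counts)),
    class_counts = as.integer(class_counts),
    n_train_images = as.integer(n_train_images),
    n_classes = as.integer(K)
  ), class = "class_weights")
}

#' Class-weighted binary cross-entropy with logits (single sample)
#'
#' Numerically stable evaluation of
#' sum_i w_i * \[ -(y_i log sigma(z_i) + (1 - y_i) log(1 - sigma(z_i))) \]
#' using the max(z,0) - z*y + log1p(exp(-|z|)) form, finite for any finite
#' logits.
#'
#' @param logits Numeric vector of K logits.
#' @param targets 0/1 vector of K true labels.
#' @param weights `class_weights` object or numeric vector of K positive
#'   weights; `NULL` for unit weights.
#' @return Nonnegative scalar loss.
#' @export
weighted_bce_with_logits <- function(logits, targets, weights = NULL) {
  if (inherits(weights, "class_weights")) weights <- weights$weights
  if (is.null(weights)) weights <- rep(1, length(logits))
  if (length(logits) != length(targets) || length(logits) != length(weights))
    stop("shape error: logits, targets and weights must have equal length")
  z <- as.numeric(logits); y <- as.numeric(targets)
  per <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  sum(weights * per)
}

#' Training configuration
#'
#' Defaults mirror the published fine-tuning schedule: Adam with learning rate
#' 5e-5, batch size 32, 1000 linear warmup steps (learning rate ramps from 0
#' to its configured value, then stays constant), 8 epochs,
#' beta = (0.9, 0.999). When training the small surrogate backbone from
#' scratch, pass a larger learning rate and shorter warmup (see the package
#' vignette).
#'
#' @param learning_rate Positive learning rate.
#' @param batch_size Positive integer.
#' @param warmup_steps Nonnegative integer; linear ramp length in optimizer
#'   steps.
#' @param epochs Positive integer.
#' @param optimizer_betas Adam (beta1, beta2).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param use_class_weights Use CW_k = N/(K n_k) weights in the loss.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 5e-5, batch_size = 32L,
                         warmup_steps = 1000L, epochs = 8L,
                         optimizer_betas = c(0.9, 0.999), seed = 1L,
                         use_class_weights = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1, warmup_steps >= 0, epochs >= 1,
            length(optimizer_betas) == 2, all(optimizer_betas > 0 & optimizer_betas < 1))
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 warmup_steps = as.integer(warmup_steps), epochs = as.integer(epochs),
                 optimizer_betas = as.numeric(optimizer_betas), seed = as.integer(seed),
                 use_class_weights = isTRUE(use_class_weights)),
            class = "train_config")
}

# ---- backbone registry -----------------------------------------------------

# im2col index matrix: rows = output positions (row-major over the H'xW' grid,
# column-major within R is handled explicitly), cols = patch entries, values =
# linear indices into a flattened (h, w, 3) image.
.im2col_index <- function(input, kernel, stride) {
  n_out <- (input - kernel) %/% stride + 1L
  pos <- expand.grid(oy = seq_len(n_out) - 1L, ox = seq_len(n_out) - 1L)
  off <- expand.grid(ky = seq_len(kernel) - 1L, kx = seq_len(kernel) - 1L,
                     ch = 0:2)
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (j in seq_len(nrow(off))) {
    y <- pos$oy * stride + off$ky[j]
    x <- pos$ox * stride + off$kx[j]
    idx[, j] <- 1L + y + x * input + off$ch[j] * input * input
  }
  list(idx = idx, n_out = n_out)
}

.surrogate_spec <- function() {
  input <- 96L; kernel <- 7L; stride <- 3L; channels <- 32L
  ic <- .im2col_index(input, kernel, stride)
  list(
    name = "surrogate_small",
    input_size = input, kernel = kernel, stride = stride,
    # Head: top-quantile average pooling of the per-class score map plus a
    # fixed logit gain. Plain global average pooling dilutes the evidence of a
    # spatially small tool over all positions, so presence logits move too
    # slowly to calibrate within a short training budget; averaging the
    # strongest `pool_frac` of positions keeps the presence logit driven by
    # the tool region. The spatially averaged gradient of this head w.r.t.
    # the feature layer is identical (up to the constant gain) to the global
    # average pooling one, so Grad-CAM heat maps are unaffected.
    logit_gain = 8, pool_frac = 0.1,
    channels = channels, n_out = ic$n_out, idx = ic$idx,
    init = function(n_classes, seed) {
      with_local_seed(seed, {
        fan_in <- kernel * kernel * 3L
        list(
          Wc = matrix(stats::rnorm(fan_in * channels, sd = sqrt(2 / fan_in)),
                      fan_in, channels),
          bc = numeric(channels),
          Wl = matrix(stats::rnorm(channels * n_classes, sd = sqrt(1 / channels)),
                      channels, n_classes),
          bl = numeric(n_classes)
        )
      })
    }
  )
}

# Forward pass over a batch. `xmat`: n x (input^2*3) matrix of flattened,
# centered images. Returns logits (n x K) and, if keep_features, the post-ReLU
# feature tensor as an (n*P) x C matrix (P spatial positions per image) plus
# the top-quantile index sets used by the pooling head.
.surrogate_forward <- function(spec, params, xmat, keep_features = FALSE) {
  n <- nrow(xmat); P <- nrow(spec$idx)
  q <- max(1L, as.integer(ceiling(spec$pool_frac * P)))
  K <- ncol(params$Wl)
  # gather im2col patches: one P x fan_in block per image
  Xb <- matrix(0, n * P, ncol(spec$idx))
  flat_idx <- as.vector(spec$idx)
  for (i in seq_len(n)) {
    Xb[((i - 1) * P + 1):(i * P), ] <- matrix(xmat[i, flat_idx], P, ncol(spec$idx))
  }
  pre <- sweep(Xb %*% params$Wc, 2, params$bc, "+")
  feat <- pmax(pre, 0)
  S <- feat %*% params$Wl                       # per-position class score map
  pool <- matrix(0, n, K)
  topidx <- array(0L, c(n, q, K))               # rows (within image block)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * P + 1):(i * P)
    for (k in seq_len(K)) {
      t <- order(S[rows, k], decreasing = TRUE)[seq_len(q)]
      topidx[i, , k] <- t
      pool[i, k] <- mean(S[rows[t], k])
    }
  }
  logits <- spec$logit_gain * sweep(pool, 2, params$bl, "+")
  out <- list(logits = logits, pool = pool, q = q)
  if (keep_features) { out$feat <- feat; out$X <- Xb; out$pre <- pre; out$topidx <- topidx }
  out
}

# Flatten + center an H x W x 3 image resized to the model input.
.prep_image <- function(img, input_size) {
  if (!identical(dim(img)[1:2], c(input_size, input_size)))
    img <- resize_bilinear(img, input_size, input_size)
  as.numeric(img) - 0.5
}

#' Train the multi-label tool-presence classifier
#'
#' Optimizes the class-weighted BCE-with-logits objective with Adam and a
#' linear learning-rate warmup (constant afterwards), logging per-epoch mean
#' training loss. Deterministic given `config$seed` on the surrogate backbone.
#'
#' @param manifest A `camloc_manifest` (see [generate_dataset()] /
#'   [read_manifest()]).
#' @param train_videos Video ids forming the training split.
#' @param config A [train_config()].
#' @param backbone Backbone identifier; `"surrogate_small"` is always
#'   available.
#' @param verbose Log per-epoch loss lines.
#' @return A `camloc_model` handle exposing per-class prediction
#'   ([predict.camloc_model()]) and a designated spatial feature layer with
#'   gradient access ([grad_cam()]).
#' @export
train_classifier <- function(manifest, train_videos, config = train_config(),
                             backbone = "surrogate_small", verbose = FALSE) {
  if (!backbone %in% c("surrogate_small"))
    stop("configuration error: unknown backbone '", backbone, "'")
  recs <- manifest$records
  keep <- recs$video_id %in% train_videos
  if (!any(keep)) stop("data error: empty training split")
  recs <- recs[keep, , drop = FALSE]
  class_names <- setdiff(colnames(recs), c("frame_path", "video_id"))
  K <- length(class_names)
  Y <- as.matrix(recs[, class_names, drop = FALSE])
  N <- nrow(Y)
  spec <- .surrogate_spec()
  # image cache (flattened, centered)
  xmat <- matrix(0, N, spec$input_size^2 * 3L)
  for (i in seq_len(N))
    xmat[i, ] <- .prep_image(read_frame(file.path(manifest$root, recs$frame_path[i])),
                             spec$input_size)
  w <- rep(1, K)
  cw <- NULL
  if (config$use_class_weights) {
    counts <- colSums(Y)
    eff <- pmax(counts, 1L)  # classes absent from the split get the maximal weight
    if (any(counts == 0))
      warning("class(es) with zero training positives: ",
              paste(class_names[counts == 0], collapse = ", "),
              "; weight computed as if n_k = 1")
    cw <- compute_class_weights(eff, N)
    w <- cw$weights
  }
  params <- spec$init(K, derive_seed(config$seed, 1L))
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  b1 <- config$optimizer_betas[1]; b2 <- config$optimizer_betas[2]
  eps <- 1e-8; step <- 0L
  P <- nrow(spec$idx)
  loss_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_local_seed(derive_seed(config$seed, 1000L + ep), sample.int(N))
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1, N, by = config$batch_size)) {
      rows <- ord[start:min(start + config$batch_size - 1L, N)]
      n <- length(rows)
      fw <- .surrogate_forward(spec, params, xmat[rows, , drop = FALSE],
                               keep_features = TRUE)
      z <- fw$logits; y <- Y[rows, , drop = FALSE]
      per <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
      loss <- sum(sweep(per, 2, w, "*")) / n
      ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
      # gradients (logits carry the fixed head gain; pooling routes the
      # class-k gradient through its top-q score positions)
      dz <- spec$logit_gain * sweep(stats::plogis(z) - y, 2, w, "*") / n  # n x K
      gbl <- colSums(dz)
      q <- fw$q
      gWl <- matrix(0, spec$channels, K)
      dfeat <- matrix(0, n * P, spec$channels)
      for (i in seq_len(n)) {
        base <- (i - 1L) * P
        for (k in seq_len(K)) {
          rows <- base + fw$topidx[i, , k]
          gWl[, k] <- gWl[, k] + dz[i, k] * colMeans(fw$feat[rows, , drop = FALSE])
          dfeat[rows, ] <- dfeat[rows, ] +
            matrix(dz[i, k] / q * params$Wl[, k], q, spec$channels, byrow = TRUE)
        }
      }
      dpre <- dfeat * (fw$pre > 0)
      gWc <- t(fw$X) %*% dpre
      gbc <- colSums(dpre)
      grads <- list(Wc = gWc, bc = gbc, Wl = gWl, bl = gbl)
      step <- step + 1L
      lr <- config$learning_rate *
        if (config$warmup_steps > 0) min(1, step / config$warmup_steps) else 1
      for (nm in names(params)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * grads[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_history[ep] <- ep_loss / n_batches
    if (verbose) log_line(sprintf("epoch %d/%d mean training loss %.6f",
                                  ep, config$epochs, loss_history[ep]))
  }
  structure(list(backbone = backbone, params = params, class_names = class_names,
                 n_classes = K, input_size = spec$input_size, config = config,
                 class_weights = cw, loss_history = loss_history),
            class = "camloc_model")
}

#' Predict tool presence for one frame
#'
#' @param object A `camloc_model`.
#' @param image H x W x 3 array in \[0,1\], or a path to a PNG file. The image
#'   is resized (bilinear) to the model's square input.
#' @param ... Unused.
#' @return A `camloc_prediction`: list with `logits` and `probabilities`
#'   (sigmoid of logits), both named by class.
#' @export
predict.camloc_model <- function(object, image, ...) {
  if (is.character(image)) image <- read_frame(image)
  fw <- .model_forward_features(object, image)
  logits <- as.numeric(fw$logits)
  names(logits) <- object$class_names
  structure(list(logits = logits, probabilities = stats::plogis(logits)),
            class = "camloc_prediction")
}

# Forward pass returning logits plus the designated spatial feature layer as
# an H' x W' x C' array, and a function giving d(logit_k)/d(features).
# This is the gradient-access surface that Grad-CAM consumes.
.model_forward_features <- function(model, image) {
  if (model$backbone == "surrogate_small") {
    spec <- .surrogate_spec()
    x <- matrix(.prep_image(image, spec$input_size), 1)
    fw <- .surrogate_forward(spec, model$params, x, keep_features = TRUE)
    P <- spec$n_out^2
    # rows of fw$feat follow expand.grid(oy, ox): oy fastest => column-major
    feat <- array(fw$feat, c(spec$n_out, spec$n_out, spec$channels))
    grad_fn <- function(class_id) {
      # logit_k = gain * (mean over top-q positions of the class-k score map
      # S = F Wl) + bias  =>  dlogit/dF_c = gain * Wl[c,k] / q on the top-q
      # positions, 0 elsewhere
      g <- array(0, dim(feat))
      on <- matrix(0, spec$n_out, spec$n_out)
      on[fw$topidx[1, , class_id + 1L]] <- 1 / fw$q
      for (c in seq_len(spec$channels))
        g[, , c] <- spec$logit_gain * model$params$Wl[c, class_id + 1L] * on
      g
    }
    list(logits = fw$logits, features = feat, grad_fn = grad_fn)
  } else if (model$backbone == "identity") {
    lum <- luminance(image)
    feat <- array(lum, c(dim(lum), 1L))
    logits <- rep(20 * mean(lum), model$n_classes)
    list(logits = matrix(logits, 1), features = feat,
         grad_fn = function(class_id) array(1 / length(lum), dim(feat)))
  } else stop("configuration error: unknown backbone '", model$backbone, "'")
}

#' Diagnostic identity-backbone model
#'
#' A model whose feature layer is the input image's luminance passed through
#' unchanged and whose every class logit is proportional to mean luminance.
#' Grad-CAM on this model reproduces (a normalized version of) the input
#' brightness, which makes it a constructed oracle for the heat-map and
#' localization stages.
#'
#' @param n_classes Number of classes K.
#' @param class_names Optional class names.
#' @return A `camloc_model` with backbone `"identity"`.
#' @export
identity_model <- function(n_classes, class_names = paste0("class", seq_len(n_classes) - 1L)) {
  structure(list(backbone = "identity", params = list(), class_names = class_names,
                 n_classes = as.integer(n_classes), input_size = NA_integer_,
                 config = NULL, class_weights = NULL, loss_history = numeric()),
            class = "camloc_model")
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS file of the parameter list plus a JSON sidecar
#' recording the backbone, class order, input size, training configuration and
#' class weights.
#'
#' @param model A `camloc_model`.
#' @param path Checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(backbone = model$backbone, class_names = model$class_names,
               input_size = model$input_size,
               train_config = unclass(model$config),
               class_weights = if (!is.null(model$class_weights))
                 unclass(model$class_weights),
               loss_history = model$loss_history)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "camloc_model")) stop("not a camloc checkpoint: ", path)
  m
}
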
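# Independent brute-force oracles used to validate the algorithmic kernels.

# Otsu: exhaustive search over all 256 thresholds, maximizing between-class
# variance of the {<= t} / {> t} split; smallest argmax.
oracle_otsu <- function(values) {
  v <- as.integer(values)
  if (min(v) == max(v)) return(NA_integer_)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:255) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# Connected components by explicit flood fill (8-connectivity); returns the
# number of components and a list of 0-based (x, y) pixel sets.
oracle_components <- function(mask) {
  fg <- mask != 0
  h <- nrow(fg); w <- ncol(fg)
  seen <- matrix(FALSE, h, w)
  comps <- list()
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!fg[r, c] || seen[r, c]) next
    queue <- list(c(r, c)); seen[r, c] <- TRUE
    pix <- list()
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      pix[[length(pix) + 1]] <- p
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && fg[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    m <- do.call(rbind, pix)
    comps[[length(comps) + 1]] <- cbind(x = m[, 2] - 1L, y = m[, 1] - 1L)
  }
  comps
}

# Greedy NMS re-implemented directly from its definition.
oracle_nms <- function(det, thr) {
  area <- (det$x_max - det$x_min) * (det$y_max - det$y_min)
  ord <- order(-det$confidence, -area, seq_len(nrow(det)))
  pool <- det[ord, , drop = FALSE]
  kept <- pool[0, , drop = FALSE]
  while (nrow(pool)) {
    top <- pool[1, , drop = FALSE]
    kept <- rbind(kept, top)
    pool <- pool[-1, , drop = FALSE]
    if (nrow(pool)) {
      ious <- vapply(seq_len(nrow(pool)), function(j)
        box_iou(as.numeric(top[c("x_min", "y_min", "x_max", "y_max")]),
                as.numeric(pool[j, c("x_min", "y_min", "x_max", "y_max")])),
        numeric(1))
      pool <- pool[ious <= thr, , drop = FALSE]
    }
  }
  rownames(kept) <- NULL
  kept
}

# Non-interpolated AP recomputed rank by rank.
oracle_ap <- function(scores, labels) {
  ord <- order(-scores)
  l <- labels[ord]
  n_pos <- sum(l)
  if (n_pos == 0) return(NA_real_)
  ap <- 0; tp <- 0; prev_recall <- 0
  for (k in seq_along(l)) {
    tp <- tp + l[k]
    prec <- tp / k
    recall <- tp / n_pos
    ap <- ap + prec * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# Loop-based Grad-CAM kernel: channel weights and weighted sum, no vectorized
# shortcuts.
oracle_cam <- function(features, gradients, rectify = TRUE) {
  d <- dim(features)
  w <- numeric(d[3])
  for (c in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + gradients[i, j, c]
    w[c] <- s / (d[1] * d[2])
  }
  m <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    acc <- 0
    for (c in seq_len(d[3])) acc <- acc + w[c] * features[i, j, c]
    m[i, j] <- if (rectify) max(acc, 0) else acc
  }
  list(weights = w, map = m)
}

random_boxes <- function(n, size = 50) {
  x0 <- sample(0:(size - 10), n, replace = TRUE)
  y0 <- sample(0:(size - 10), n, replace = TRUE)
  data.frame(class_id = 0L,
             confidence = round(stats::runif(n), 3),
             x_min = x0, y_min = y0,
             x_max = x0 + sample(3:15, n, replace = TRUE),
             y_max = y0 + sample(3:15, n, replace = TRUE))
}
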
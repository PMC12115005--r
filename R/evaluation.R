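# Evaluation protocols: per-class recall/precision/F1, non-interpolated
# average precision and mAP for multi-label classification; greedy IoU
# matching of detections to ground-truth boxes with both the published
# confidence/IoU bookkeeping ("paper" mode) and the COCO convention
# ("standard" mode); and video-level (group-aware) data splitting.

#' Precision and recall from confusion counts
#'
#' Recall = TP/(TP+FN), Precision = TP/(TP+FP). A zero denominator yields 0,
#' flagged in the `undefined` field.
#'
#' @param counts List or vector with `tp`, `fp`, `fn`.
#' @return List with `precision`, `recall`, and logical `undefined`
#'   (named: precision, recall).
#' @export
precision_recall <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  und <- c(precision = tp + fp == 0, recall = tp + fn == 0)
  list(precision = if (und["precision"]) 0 else tp / (tp + fp),
       recall = if (und["recall"]) 0 else tp / (tp + fn),
       undefined = und)
}

#' Non-interpolated average precision
#'
#' Sorts by score descending (ties keep input order) and accumulates
#' AP = sum_k Precision(k) * DeltaRecall(k), where DeltaRecall(k) is the
#' recall increment at rank k (1/n_pos at each positive, else 0). No
#' interpolation is applied, so a perfect ranking gives exactly 1.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 ground-truth labels (same length).
#' @return AP in \[0, 1\], or `NA_real_` if there are no positive labels
#'   (undefined).
#' @export
average_precision <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("shape error: length mismatch")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(-scores)               # stable: ties stay in input order
  l <- labels[ord]
  tp <- cumsum(l)
  prec <- tp / seq_along(l)
  sum(prec[l == 1]) / n_pos
}

#' Mean average precision over classes
#'
#' @param per_class_ap Numeric vector of per-class AP values.
#' @param na.rm Skip undefined (NA) classes with a message instead of
#'   propagating NA.
#' @return Unweighted mean AP.
#' @export
mean_ap <- function(per_class_ap, na.rm = FALSE) {
  stopifnot(length(per_class_ap) >= 1)
  if (anyNA(per_class_ap)) {
    if (!na.rm) return(NA_real_)
    message(sum(is.na(per_class_ap)), " class(es) with undefined AP skipped")
  }
  mean(per_class_ap, na.rm = na.rm)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F1 in \[0, 1\]; 0 when both inputs are 0.
#' @export
f1_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Classification evaluation report
#'
#' Per-class recall and F1 at a fixed probability threshold, per-class AP from
#' the full score ranking, and their unweighted means, all as percentages.
#'
#' @param probabilities n x K matrix of predicted probabilities (or scores).
#' @param labels n x K 0/1 matrix of true labels, aligned frame-for-frame.
#' @param threshold Decision threshold (predicted positive when probability >
#'   threshold); default 0.5.
#' @param class_names Optional K class names.
#' @return A `camloc_eval` list: `per_class` (data.frame class, recall, f1,
#'   ap, in %), `means` (named: recall, f1, map, in %), `threshold`. Classes
#'   with no positive labels get NA AP and are skipped in the mAP mean (with a
#'   message).
#' @export
classification_report <- function(probabilities, labels, threshold = 0.5,
                                  class_names = colnames(labels)) {
  probabilities <- as.matrix(probabilities); labels <- as.matrix(labels)
  if (!all(dim(probabilities) == dim(labels)))
    stop("data error: predictions and labels are misaligned")
  K <- ncol(labels)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(K) - 1L)
  per <- data.frame(class = class_names, recall = NA_real_, f1 = NA_real_,
                    ap = NA_real_)
  for (k in seq_len(K)) {
    pred <- probabilities[, k] > threshold
    tp <- sum(pred & labels[, k] == 1)
    fp <- sum(pred & labels[, k] == 0)
    fn <- sum(!pred & labels[, k] == 1)
    pr <- precision_recall(list(tp = tp, fp = fp, fn = fn))
    per$recall[k] <- 100 * pr$recall
    per$f1[k] <- 100 * f1_score(pr$precision, pr$recall)
    ap <- average_precision(probabilities[, k], labels[, k])
    per$ap[k] <- if (is.na(ap)) NA_real_ else 100 * ap
  }
  structure(list(
    per_class = per,
    means = c(recall = mean(per$recall), f1 = mean(per$f1),
              map = mean_ap(per$ap, na.rm = TRUE)),
    threshold = threshold
  ), class = "camloc_eval")
}

#' Match detections to ground-truth boxes and accumulate confusion counts
#'
#' Greedy one-to-one matching per frame and class by descending confidence;
#' each truth is matched at most once; a match requires IoU > `iou_threshold`.
#' Two bookkeeping modes:
#' \describe{
#'   \item{paper}{TP: confident (conf > conf_threshold) and matched.
#'     FN: every unmatched confident detection, every low-confidence
#'     detection, and every unmatched truth. FP: low-confidence detections
#'     that also fail the IoU test against every truth.}
#'   \item{standard}{COCO convention: only confident detections participate;
#'     matched ones are TP, unmatched ones FP; unmatched truths are FN.}
#' }
#'
#' @param detections data.frame `frame_path (or frame id), class_id,
#'   confidence, x_min, y_min, x_max, y_max`.
#' @param truths data.frame `frame_path, class_id, x_min, y_min, x_max, y_max`.
#' @param conf_threshold,iou_threshold Thresholds in (0, 1).
#' @param mode `"paper"` or `"standard"`.
#' @param n_classes Number of classes K (rows of the output).
#' @return data.frame `class_id, tp, fp, fn, n_truth`, accumulated over
#'   frames.
#' @export
match_detections <- function(detections, truths, conf_threshold = 0.5,
                             iou_threshold = 0.5, mode = c("paper", "standard"),
                             n_classes = NULL) {
  mode <- match.arg(mode)
  if (conf_threshold <= 0 || conf_threshold >= 1 || iou_threshold <= 0 ||
      iou_threshold >= 1)
    stop("configuration error: thresholds must lie in (0, 1)")
  if (is.null(n_classes))
    n_classes <- max(c(detections$class_id, truths$class_id, -1L)) + 1L
  if (!"frame_path" %in% names(detections)) detections$frame_path <- "frame0"
  if (!"frame_path" %in% names(truths)) truths$frame_path <- "frame0"
  out <- data.frame(class_id = seq_len(n_classes) - 1L, tp = 0L, fp = 0L,
                    fn = 0L, n_truth = 0L)
  frames <- union(unique(detections$frame_path), unique(truths$frame_path))
  bx <- function(df, i) as.numeric(df[i, c("x_min", "y_min", "x_max", "y_max")])
  for (f in frames) {
    for (k in seq_len(n_classes) - 1L) {
      d <- detections[detections$frame_path == f & detections$class_id == k, ,
                      drop = FALSE]
      g <- truths[truths$frame_path == f & truths$class_id == k, , drop = FALSE]
      out$n_truth[k + 1] <- out$n_truth[k + 1] + nrow(g)
      if (mode == "standard") d <- d[d$confidence > conf_threshold, , drop = FALSE]
      d <- d[order(-d$confidence), , drop = FALSE]
      truth_used <- rep(FALSE, nrow(g))
      matched <- rep(FALSE, nrow(d))
      best_iou <- rep(0, nrow(d))
      for (i in seq_len(nrow(d))) {
        ious <- if (nrow(g)) vapply(seq_len(nrow(g)), function(j)
          box_iou(bx(d, i), bx(g, j)), numeric(1)) else numeric()
        if (length(ious)) best_iou[i] <- max(ious)
        cand <- which(!truth_used & ious > iou_threshold)
        if (length(cand)) {
          j <- cand[which.max(ious[cand])]
          truth_used[j] <- TRUE
          matched[i] <- TRUE
        }
      }
      if (mode == "standard") {
        out$tp[k + 1] <- out$tp[k + 1] + sum(matched)
        out$fp[k + 1] <- out$fp[k + 1] + sum(!matched)
        out$fn[k + 1] <- out$fn[k + 1] + sum(!truth_used)
      } else {
        conf <- d$confidence > conf_threshold
        out$tp[k + 1] <- out$tp[k + 1] + sum(conf & matched)
        out$fn[k + 1] <- out$fn[k + 1] + sum(!conf) + sum(conf & !matched) +
          sum(!truth_used)
        out$fp[k + 1] <- out$fp[k + 1] + sum(!conf & best_iou <= iou_threshold)
      }
    }
  }
  out
}

#' Localization evaluation report
#'
#' Per-class F1 (in %) from confusion counts accumulated by
#' [match_detections()], plus the unweighted mean over evaluated classes.
#' Classes with neither truths nor detections are omitted (with a message).
#'
#' @inheritParams match_detections
#' @param class_names Optional K class names.
#' @return A `camloc_loc_eval` list: `per_class` (data.frame class, tp, fp,
#'   fn, f1), `mean_f1` (in %), `mode`.
#' @export
localization_report <- function(detections, truths, conf_threshold = 0.5,
                                iou_threshold = 0.5,
                                mode = c("paper", "standard"),
                                n_classes = NULL, class_names = NULL) {
  mode <- match.arg(mode)
  counts <- match_detections(detections, truths, conf_threshold, iou_threshold,
                             mode, n_classes)
  if (is.null(class_names)) class_names <- paste0("class", counts$class_id)
  counts$class <- class_names
  active <- counts$tp + counts$fp + counts$fn > 0 | counts$n_truth > 0
  if (any(!active))
    message("class(es) with no truths and no detections omitted: ",
            paste(class_names[!active], collapse = ", "))
  counts <- counts[active, , drop = FALSE]
  counts$f1 <- vapply(seq_len(nrow(counts)), function(i) {
    pr <- precision_recall(counts[i, ])
    100 * f1_score(pr$precision, pr$recall)
  }, numeric(1))
  structure(list(per_class = counts[, c("class", "class_id", "tp", "fp", "fn",
                                        "n_truth", "f1")],
                 mean_f1 = mean(counts$f1), mode = mode),
            class = "camloc_loc_eval")
}

#' Video-level data splits
#'
#' Group-aware partitioning: every frame of a video stays on one side of every
#' split. `"kfold"` shuffles videos and partitions them into k test folds of
#' sizes differing by at most one; `"fixed_fraction"` makes one shuffled
#' train/test split with the given train fraction (0.5 on 80 videos gives the
#' conventional 40/40 split).
#'
#' @param video_ids Vector of (unique) video identifiers (>= 2).
#' @param scheme `"kfold"` or `"fixed_fraction"`.
#' @param k_or_fraction Number of folds (integer >= 2) or train fraction in
#'   (0, 1).
#' @param seed Integer seed; the plan is deterministic per seed.
#' @return A `camloc_splits` list: `folds` (list of `list(train, test)`),
#'   `scheme`, `seed`.
#' @export
make_splits <- function(video_ids, scheme = c("kfold", "fixed_fraction"),
                        k_or_fraction, seed = 1L) {
  scheme <- match.arg(scheme)
  video_ids <- unique(video_ids)
  n <- length(video_ids)
  if (n < 2) stop("configuration error: need at least 2 videos")
  shuffled <- with_local_seed(seed, sample(video_ids))
  folds <- if (scheme == "kfold") {
    k <- as.integer(k_or_fraction)
    if (k < 2 || k > n) stop("configuration error: k must lie in [2, n_videos]")
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    lapply(seq_len(k), function(i) {
      test <- shuffled[starts[i]:ends[i]]
      list(train = setdiff(shuffled, test), test = test)
    })
  } else {
    f <- k_or_fraction
    if (f <= 0 || f >= 1) stop("configuration error: fraction must lie in (0, 1)")
    n_train <- round(n * f)
    list(list(train = shuffled[seq_len(n_train)],
              test = shuffled[setdiff(seq_len(n), seq_len(n_train))]))
  }
  structure(list(folds = folds, scheme = scheme, seed = as.integer(seed)),
            class = "camloc_splits")
}

#' Persist / load a split plan as JSON
#' @param splits A `camloc_splits`.
#' @param path JSON path.
#' @return `path` (write) / `camloc_splits` (read).
#' @export
write_splits <- function(splits, path) {
  jsonlite::write_json(unclass(splits), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_splits
#' @export
read_splits <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  folds <- lapply(x$folds, function(f)
    list(train = unlist(f$train), test = unlist(f$test)))
  structure(list(folds = folds, scheme = x$scheme[[1]], seed = x$seed[[1]]),
            class = "camloc_splits")
}

#' Write an evaluation report as JSON and CSV
#'
#' The CSV mirrors the per-tool table layout (rows = tools, columns =
#' metrics, percentages to 2 decimals); the JSON keeps full precision.
#'
#' @param report A `camloc_eval` or `camloc_loc_eval`.
#' @param path_prefix Files written as `<prefix>.json` and `<prefix>.csv`.
#' @return The JSON path, invisibly.
#' @export
write_report <- function(report, path_prefix) {
  payload <- unclass(report)
  # serialize the means as a named JSON object, not an anonymous array
  if (!is.null(payload$means)) payload$means <- as.list(payload$means)
  jsonlite::write_json(payload, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  per <- report$per_class
  num <- vapply(per, is.numeric, logical(1))
  per[num] <- lapply(per[num], function(x) round(x, 2))
  utils::write.csv(per, paste0(path_prefix, ".csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(paste0(path_prefix, ".json"))
}
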
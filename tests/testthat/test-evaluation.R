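test_that("precision and recall handle hand cases and zero denominators", {
  pr <- precision_recall(list(tp = 8, fp = 2, fn = 2))
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 0.8)
  expect_false(any(pr$undefined))
  pr0 <- precision_recall(list(tp = 0, fp = 0, fn = 3))
  expect_equal(pr0$precision, 0)
  expect_true(pr0$undefined["precision"])
  expect_false(pr0$undefined["recall"])
  pr1 <- precision_recall(list(tp = 0, fp = 2, fn = 0))
  expect_true(pr1$undefined["recall"])
  expect_error(precision_recall(list(tp = -1, fp = 0, fn = 0)))
})

test_that("average precision matches hand-worked rankings", {
  # ranking (+,-,+): precisions at positives 1/1 and 2/3 -> AP = 5/6
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6,
               tolerance = 1e-12)
  # perfect ranking -> exactly 1
  expect_equal(average_precision(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  # worst ranking of 1 positive among 4
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6), c(0, 0, 0, 1)), 0.25)
  # no positives -> undefined
  expect_true(is.na(average_precision(c(0.5, 0.4), c(0, 0))))
  # score ties keep input order (stable sort)
  expect_equal(average_precision(c(0.5, 0.5), c(1, 0)), 1)
  expect_equal(average_precision(c(0.5, 0.5), c(0, 1)), 0.5)
  expect_error(average_precision(c(1, 2), 1), "shape")
})

test_that("average precision matches the rank-by-rank oracle", {
  set.seed(51)
  for (rep in 1:200) {
    n <- sample(1:40, 1)
    scores <- stats::runif(n)
    labels <- stats::rbinom(n, 1, 0.4)
    got <- average_precision(scores, labels)
    want <- oracle_ap(scores, labels)
    if (is.na(want)) expect_true(is.na(got))
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("mean AP averages per-class APs, skipping undefined classes on request", {
  # a per-tool AP table in the style of a 7-class benchmark
  aps <- c(96.85, 97.30, 99.10, 94.60, 97.75, 95.07, 97.91)
  expect_equal(mean_ap(aps), mean(aps))
  expect_true(is.na(mean_ap(c(0.9, NA))))
  expect_message(m <- mean_ap(c(0.9, NA, 0.7), na.rm = TRUE), "skipped")
  expect_equal(m, 0.8)
})

test_that("F1 is the harmonic mean with the 0/0 convention", {
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0.5, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(f1_score(0, 0), 0)
  # P == R ==> F1 == P
  for (p in c(0.1, 0.37, 0.93)) expect_equal(f1_score(p, p), p)
  expect_error(f1_score(1.2, 0.5))
})

test_that("classification report computes per-class metrics and means", {
  probs <- rbind(c(0.9, 0.2), c(0.8, 0.7), c(0.1, 0.6), c(0.3, 0.1))
  labels <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  rep <- classification_report(probs, labels, class_names = c("a", "b"))
  expect_s3_class(rep, "camloc_eval")
  # both classes perfectly ranked and thresholded
  expect_equal(rep$per_class$recall, c(100, 100))
  expect_equal(rep$per_class$f1, c(100, 100))
  expect_equal(rep$per_class$ap, c(100, 100))
  expect_equal(unname(rep$means), c(100, 100, 100))
  # an imperfect class: one miss
  probs2 <- rbind(c(0.9), c(0.2), c(0.1))
  labels2 <- rbind(1, 1, 0)
  r2 <- classification_report(probs2, labels2)
  expect_equal(r2$per_class$recall, 50)          # 1 of 2 found
  expect_equal(r2$per_class$f1, 100 * 2 / 3)     # P=1, R=0.5
  # means are definitional
  expect_equal(unname(r2$means["recall"]), mean(r2$per_class$recall))
  # a class with no positives is excluded from mAP with a message
  probs3 <- cbind(c(0.9, 0.1), c(0.5, 0.4))
  labels3 <- cbind(c(1, 0), c(0, 0))
  expect_message(r3 <- classification_report(probs3, labels3), "skipped")
  expect_true(is.na(r3$per_class$ap[2]))
  expect_equal(unname(r3$means["map"]), 100)
  expect_error(classification_report(probs, labels[1:2, ]), "misaligned")
})

test_that("match_detections follows the published bookkeeping", {
  truth <- data.frame(frame_path = "f", class_id = 0L,
                      x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  mk <- function(conf, x0) data.frame(frame_path = "f", class_id = 0L,
                                      confidence = conf, x_min = x0, y_min = 0,
                                      x_max = x0 + 10, y_max = 10)
  # confident + good overlap (IoU = 9/11 > 0.5): TP in both modes
  d <- mk(0.9, 1)
  for (m in c("paper", "standard")) {
    r <- match_detections(d, truth, mode = m, n_classes = 1)
    expect_identical(c(r$tp, r$fp, r$fn), c(1L, 0L, 0L))
  }
  # confident but poor overlap (IoU = 1/3 <= 0.5)
  d2 <- mk(0.9, 5)
  rp <- match_detections(d2, truth, mode = "paper", n_classes = 1)
  expect_identical(c(rp$tp, rp$fp, rp$fn), c(0L, 0L, 2L))  # det + truth both FN
  rs <- match_detections(d2, truth, mode = "standard", n_classes = 1)
  expect_identical(c(rs$tp, rs$fp, rs$fn), c(0L, 1L, 1L))
  # low confidence, poor overlap: paper counts it FN and FP
  d3 <- mk(0.3, 20)
  rp3 <- match_detections(d3, truth, mode = "paper", n_classes = 1)
  expect_identical(c(rp3$tp, rp3$fp, rp3$fn), c(0L, 1L, 2L))
  rs3 <- match_detections(d3, truth, mode = "standard", n_classes = 1)
  expect_identical(c(rs3$tp, rs3$fp, rs3$fn), c(0L, 0L, 1L))
  # low confidence but good overlap: paper FN only (IoU test passes)
  d4 <- mk(0.3, 1)
  rp4 <- match_detections(d4, truth, mode = "paper", n_classes = 1)
  expect_identical(c(rp4$tp, rp4$fp, rp4$fn), c(0L, 0L, 1L))
  expect_error(match_detections(d, truth, conf_threshold = 1.5), "thresholds")
})

test_that("greedy matching is one-to-one and permutation-invariant", {
  set.seed(52)
  truth <- data.frame(frame_path = "f", class_id = 0L,
                      x_min = c(0, 30), y_min = 0, x_max = c(10, 40), y_max = 10)
  det <- data.frame(frame_path = "f", class_id = 0L,
                    confidence = c(0.9, 0.8, 0.7),
                    x_min = c(1, 2, 31), y_min = 0,
                    x_max = c(11, 12, 41), y_max = 10)
  r <- match_detections(det, truth, mode = "standard", n_classes = 1)
  expect_identical(c(r$tp, r$fp, r$fn), c(2L, 1L, 0L))   # each truth used once
  # shuffling detection rows cannot change the counts (greedy is by confidence)
  for (rep in 1:5) {
    perm <- sample(nrow(det))
    r2 <- match_detections(det[perm, ], truth, mode = "standard", n_classes = 1)
    expect_identical(r2, r)
  }
  # property: tp + fn >= n_truth in both modes on random problems
  for (rep in 1:10) {
    dts <- random_boxes(sample(1:8, 1)); dts$frame_path <- "f"
    tts <- random_boxes(sample(1:5, 1))[, -2]; tts$frame_path <- "f"
    for (m in c("paper", "standard")) {
      rr <- match_detections(dts, tts, mode = m, n_classes = 1)
      expect_gte(rr$tp + rr$fn, rr$n_truth)
      expect_identical(rr$n_truth, nrow(tts))
    }
  }
})

test_that("localization report aggregates per-class F1", {
  truth <- data.frame(frame_path = c("f1", "f1", "f2"), class_id = c(0L, 1L, 0L),
                      x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  det <- truth
  det$confidence <- 0.9
  rep <- localization_report(det, truth, n_classes = 2,
                             class_names = c("a", "b"))
  expect_s3_class(rep, "camloc_loc_eval")
  expect_equal(rep$per_class$f1, c(100, 100))
  expect_equal(rep$mean_f1, 100)
  expect_identical(rep$mode, "paper")
  # a class with nothing at all is omitted with a message
  expect_message(r3 <- localization_report(det, truth, n_classes = 3,
                                           class_names = c("a", "b", "c")),
                 "omitted")
  expect_identical(nrow(r3$per_class), 2L)
})

test_that("video-level splits keep groups intact with balanced folds", {
  sp <- make_splits(0:79, "kfold", 3, seed = 7)
  sizes <- sort(vapply(sp$folds, function(f) length(f$test), integer(1)))
  expect_identical(sizes, c(26L, 27L, 27L))
  # test folds partition the videos; train/test never overlap
  all_test <- unlist(lapply(sp$folds, `[[`, "test"))
  expect_setequal(all_test, 0:79)
  expect_identical(anyDuplicated(all_test), 0L)
  for (f in sp$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 0:79)
  }
  # fixed-fraction 0.5 on 80 videos: the conventional 40/40 split
  sp2 <- make_splits(0:79, "fixed_fraction", 0.5, seed = 3)
  expect_length(sp2$folds, 1)
  expect_length(sp2$folds[[1]]$train, 40)
  expect_length(sp2$folds[[1]]$test, 40)
  # determinism per seed
  expect_identical(make_splits(0:79, "kfold", 3, seed = 7)$folds, sp$folds)
  expect_false(identical(make_splits(0:79, "kfold", 3, seed = 8)$folds, sp$folds))
  expect_error(make_splits(0:79, "kfold", 1), "k must")
  expect_error(make_splits(0L, "kfold", 2), "at least 2")
  expect_error(make_splits(0:9, "fixed_fraction", 1.2), "fraction")
})

test_that("splits and reports persist to disk and back", {
  sp <- make_splits(0:9, "kfold", 3, seed = 2)
  p <- file.path(tempdir(), "splits.json")
  write_splits(sp, p)
  sp2 <- read_splits(p)
  expect_identical(sp2$scheme, "kfold")
  expect_identical(sp2$seed, 2L)
  for (i in 1:3) {
    expect_identical(sort(sp2$folds[[i]]$test), sort(sp$folds[[i]]$test))
    expect_identical(sort(sp2$folds[[i]]$train), sort(sp$folds[[i]]$train))
  }
  probs <- rbind(c(0.9, 0.2), c(0.1, 0.8))
  labels <- rbind(c(1, 0), c(0, 1))
  rep <- classification_report(probs, labels, class_names = c("a", "b"))
  prefix <- file.path(tempdir(), "rep")
  write_report(rep, prefix)
  j <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(j$means$map, 100)
  csv <- utils::read.csv(paste0(prefix, ".csv"))
  expect_identical(csv$class, c("a", "b"))
  expect_equal(csv$f1, c(100, 100))
})
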
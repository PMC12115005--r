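# Synthetic laparoscopic-scene generator. Produces frames with elongated,
# edge-anchored tool shapes over a dark textured background, multi-hot
# presence labels, and tight ground-truth boxes, so the full weakly
# supervised pipeline is testable without any real surgical video.

#' Cholec80 tool classes, in the canonical project-wide order
#'
#' Order fixed as (grasper, bipolar, hook, scissors, clipper, irrigator,
#' specimen_bag); all label CSV columns and per-class reports follow it.
#' @export
CHOLEC80_CLASSES <- c("grasper", "bipolar", "hook", "scissors", "clipper",
                      "irrigator", "specimen_bag")

#' Tool occurrence counts in the Cholec80 benchmark
#'
#' Published per-tool occurrence frequencies over all annotated frames of the
#' Cholec80 cholecystectomy dataset (a frame may contain several tools, so the
#' counts exceed the frame count). Used to derive realistically imbalanced
#' default class prevalences for the synthetic generator: scissors and clipper
#' are heavily underrepresented relative to grasper and hook.
#' @export
cholec80_tool_counts <- c(
  grasper = 102569L, bipolar = 8876L, hook = 103099L, scissors = 3254L,
  clipper = 5986L, irrigator = 9814L, specimen_bag = 11462L
)

# Distinctive base RGB colour per tool class (bright against the dark
# tissue-like background; distinct hues make the desk-scale classification
# problem learnable by a small surrogate model).
.class_colors <- rbind(
  grasper      = c(0.85, 0.85, 0.88),  # steel gray
  bipolar      = c(0.25, 0.45, 0.95),  # blue
  hook         = c(0.95, 0.85, 0.20),  # yellow
  scissors     = c(0.90, 0.25, 0.85),  # magenta
  clipper      = c(0.20, 0.90, 0.90),  # cyan
  irrigator    = c(0.25, 0.90, 0.35),  # green
  specimen_bag = c(0.95, 0.55, 0.15)   # orange
)

#' Configuration for the synthetic scene generator
#'
#' @param image_size Integer vector (height, width) in pixels, both >= 32.
#' @param class_names Ordered character vector of K tool names.
#' @param class_prevalences Per-class probability of presence in a frame, each
#'   in \[0, 1\]. Defaults to the Cholec80 occurrence counts normalized by
#'   their total, reproducing the benchmark's imbalance regime.
#' @param max_tools_per_frame Cap on simultaneously rendered tools (>= 0).
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0); emulates the mild
#'   motion blur of endoscopic footage.
#' @param noise_level Amplitude of additive uniform pixel noise, in \[0, 1\].
#' @param distractor_prob Probability of adding one interior non-tool blob
#'   (never touches a frame edge, never labeled); exercises the edge-touch
#'   filter negatively.
#' @param seed Base integer seed; each frame derives its own stream from
#'   (seed, frame_index), so regeneration is order-independent.
#' @return A `scene_config` object (list).
#' @export
scene_config <- function(image_size = c(128L, 128L),
                         class_names = CHOLEC80_CLASSES,
                         class_prevalences = as.numeric(cholec80_tool_counts /
                                                          sum(cholec80_tool_counts)),
                         max_tools_per_frame = 3L,
                         blur_sigma = 0.8,
                         noise_level = 0.02,
                         distractor_prob = 0.25,
                         seed = 1L) {
  if (length(class_names) < 1) stop("configuration error: need >= 1 class")
  if (length(class_prevalences) != length(class_names))
    stop("configuration error: one prevalence per class required")
  if (any(class_prevalences < 0 | class_prevalences > 1))
    stop("configuration error: prevalences must lie in [0, 1]")
  if (length(image_size) != 2 || any(image_size < 32))
    stop("configuration error: image_size must be (height, width), both >= 32")
  if (max_tools_per_frame < 0) stop("configuration error: max_tools_per_frame < 0")
  if (blur_sigma < 0) stop("configuration error: blur_sigma < 0")
  if (noise_level < 0 || noise_level > 1)
    stop("configuration error: noise_level must lie in [0, 1]")
  structure(list(
    image_size = as.integer(image_size),
    class_names = as.character(class_names),
    class_prevalences = as.numeric(class_prevalences),
    max_tools_per_frame = as.integer(max_tools_per_frame),
    blur_sigma = blur_sigma,
    noise_level = noise_level,
    distractor_prob = distractor_prob,
    seed = as.integer(seed)
  ), class = "scene_config")
}

# Pixel support (logical H x W) of a capsule: points within half-width `hw`
# of the segment (x0,y0)-(x1,y1), in 0-based pixel-center coordinates.
.capsule_mask <- function(h, w, x0, y0, x1, y1, hw) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 > 0) pmin(pmax(((xs - x0) * dx + (ys - y0) * dy) / len2, 0), 1) else 0
  px <- x0 + t * dx; py <- y0 + t * dy
  (xs - px)^2 + (ys - py)^2 <= hw^2
}

.disk_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), times = w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# Tight 0-based half-open box of a logical mask; NULL if empty.
.mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(x_min = min(idx[, 2]) - 1L, y_min = min(idx[, 1]) - 1L,
    x_max = max(idx[, 2]), y_max = max(idx[, 1]))
}

# Render one edge-anchored tool capsule; returns list(mask, box). The anchor
# point sits just outside the chosen border so the clipped support always
# includes border pixels (tools enter the field of view from outside).
.render_tool <- function(h, w, class_id, img_env) {
  m <- min(h, w)
  edge <- sample.int(4L, 1L)                       # 1 top, 2 bottom, 3 left, 4 right
  u <- stats::runif(1, 0.15, 0.85)
  ang_off <- stats::runif(1, -pi / 4, pi / 4)
  len <- stats::runif(1, 0.35, 0.65) * m
  hw <- stats::runif(1, 0.05, 0.09) * m
  if (edge == 1L)      { x0 <- u * (w - 1); y0 <- -1; ang <- pi / 2 + ang_off }
  else if (edge == 2L) { x0 <- u * (w - 1); y0 <- h;  ang <- -pi / 2 + ang_off }
  else if (edge == 3L) { x0 <- -1; y0 <- u * (h - 1); ang <- 0 + ang_off }
  else                 { x0 <- w;  y0 <- u * (h - 1); ang <- pi + ang_off }
  x1 <- x0 + len * cos(ang); y1 <- y0 + len * sin(ang)
  mask <- .capsule_mask(h, w, x0, y0, x1, y1, hw)
  tip <- .disk_mask(h, w, x1, y1, 1.25 * hw)
  base_col <- .class_colors[((class_id) %% nrow(.class_colors)) + 1, ]
  inten <- stats::runif(1, 0.8, 1.0)
  jit <- stats::runif(3, -0.05, 0.05)
  col <- pmin(pmax(base_col * inten + jit, 0), 1)
  img <- img_env$img
  for (c in 1:3) {
    ch <- img[, , c]
    ch[mask] <- col[c]
    ch[tip & mask] <- min(col[c] * 1.3 + 0.05, 1)
    img[, , c] <- ch
  }
  img_env$img <- img
  list(mask = mask | (tip & mask), box = .mask_bbox(mask))
}

#' Generate one synthetic laparoscopic frame
#'
#' Renders a dark textured background plus zero or more bright elongated tool
#' shapes, each anchored on (and therefore touching) a frame edge, with an
#' optional interior distractor blob that belongs to no class. Deterministic
#' given `(config$seed, frame_index)`.
#'
#' @param config A [scene_config()].
#' @param frame_index Nonnegative integer frame index.
#' @return List with `image` (H x W x 3 array in \[0,1\]), `labels` (named 0/1
#'   vector of length K) and `boxes` (data.frame `class_id, x_min, y_min,
#'   x_max, y_max`; 0-based, half-open).
#' @export
generate_scene <- function(config, frame_index) {
  if (!inherits(config, "scene_config")) stop("configuration error: not a scene_config")
  stopifnot(frame_index >= 0)
  h <- config$image_size[1]; w <- config$image_size[2]
  K <- length(config$class_names)
  with_local_seed(derive_seed(config$seed, frame_index), {
    # tissue-like background: coarse noise grid, bilinear-upsampled, red tint
    g <- matrix(stats::runif(81, 0.05, 0.30), 9, 9)
    bg <- resize_bilinear(g, h, w)
    env <- new.env()
    env$img <- array(0, c(h, w, 3))
    env$img[, , 1] <- bg
    env$img[, , 2] <- bg * 0.55
    env$img[, , 3] <- bg * 0.50
    present <- stats::runif(K) < config$class_prevalences
    idx <- which(present)
    if (length(idx) > config$max_tools_per_frame)
      idx <- sort(sample(idx, config$max_tools_per_frame))
    labels <- integer(K); names(labels) <- config$class_names
    boxes <- list()
    for (k in idx) {
      r <- .render_tool(h, w, k - 1L, env)
      if (is.null(r$box)) next  # degenerate support; never happens at >=32 px
      labels[k] <- 1L
      boxes[[length(boxes) + 1L]] <- c(class_id = k - 1L, r$box)
    }
    # interior distractor: mid-intensity blob away from all borders
    if (stats::runif(1) < config$distractor_prob) {
      r0 <- stats::runif(1, 0.05, 0.10) * min(h, w)
      cx <- stats::runif(1, 0.3, 0.7) * (w - 1)
      cy <- stats::runif(1, 0.3, 0.7) * (h - 1)
      dm <- .disk_mask(h, w, cx, cy, r0)
      col <- c(0.50, 0.42, 0.40) * stats::runif(1, 0.85, 1.1)
      for (c in 1:3) {
        ch <- env$img[, , c]; ch[dm] <- min(col[c], 1); env$img[, , c] <- ch
      }
    }
    img <- env$img
    if (config$noise_level > 0)
      img <- img + (stats::runif(length(img)) - 0.5) * 2 * config$noise_level
    if (config$blur_sigma > 0)
      img <- EBImage::gblur(img, sigma = config$blur_sigma)
    img <- pmin(pmax(img, 0), 1)
    boxes_df <- if (length(boxes)) as.data.frame(do.call(rbind, boxes))
                else data.frame(class_id = integer(), x_min = integer(),
                                y_min = integer(), x_max = integer(), y_max = integer())
    list(image = img, labels = labels, boxes = boxes_df)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_frames` PNG frames (assigned round-robin to `n_videos` video
#' ids), a label manifest CSV and a ground-truth box CSV, and returns the
#' manifest. Rerunning with the same config/seed reproduces identical files.
#'
#' @param config A [scene_config()].
#' @param n_frames Number of frames (>= n_videos).
#' @param n_videos Number of synthetic "videos" (>= 1) for group-aware splits.
#' @param out_dir Output directory (created if missing).
#' @return A `camloc_manifest`: list with `records` (data.frame: frame_path,
#'   video_id, one 0/1 column per class), `boxes` (data.frame), `root`,
#'   `seed`, `config`.
#' @export
generate_dataset <- function(config, n_frames, n_videos, out_dir) {
  stopifnot(n_frames >= n_videos, n_videos >= 1)
  dir.create(file.path(out_dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create output directory ", out_dir)
  K <- length(config$class_names)
  labels <- matrix(0L, n_frames, K, dimnames = list(NULL, config$class_names))
  paths <- character(n_frames)
  vids <- integer(n_frames)
  all_boxes <- list()
  for (i in seq_len(n_frames)) {
    sc <- generate_scene(config, i - 1L)
    rel <- sprintf("frames/frame_%06d.png", i - 1L)
    write_frame(sc$image, file.path(out_dir, rel))
    paths[i] <- rel
    vids[i] <- (i - 1L) %% as.integer(n_videos)
    labels[i, ] <- sc$labels
    if (nrow(sc$boxes)) {
      sc$boxes$frame_path <- rel
      all_boxes[[length(all_boxes) + 1L]] <- sc$boxes
    }
  }
  records <- data.frame(frame_path = paths, video_id = vids, labels,
                        check.names = FALSE)
  boxes <- if (length(all_boxes)) do.call(rbind, all_boxes) else
    data.frame(frame_path = character(), class_id = integer(), x_min = integer(),
               y_min = integer(), x_max = integer(), y_max = integer())
  boxes <- boxes[, c("frame_path", "class_id", "x_min", "y_min", "x_max", "y_max")]
  rownames(boxes) <- NULL
  man <- structure(list(records = records, boxes = boxes, root = out_dir,
                        seed = config$seed, config = config),
                   class = "camloc_manifest")
  write_manifest(man, out_dir)
  man
}

#' Write manifest and box CSV files
#' @param manifest A `camloc_manifest`.
#' @param out_dir Directory for `manifest.csv` and `boxes.csv`.
#' @return `out_dir`, invisibly.
#' @export
write_manifest <- function(manifest, out_dir) {
  utils::write.csv(manifest$records, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(manifest$boxes, file.path(out_dir, "boxes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Read a dataset manifest written by [generate_dataset()]
#' @param dir Dataset directory containing `manifest.csv` and `boxes.csv`.
#' @param class_names Optional class order; defaults to the manifest columns.
#' @return A `camloc_manifest`.
#' @export
read_manifest <- function(dir, class_names = NULL) {
  records <- utils::read.csv(file.path(dir, "manifest.csv"), check.names = FALSE)
  boxes <- utils::read.csv(file.path(dir, "boxes.csv"))
  if (is.null(class_names))
    class_names <- setdiff(colnames(records), c("frame_path", "video_id"))
  structure(list(records = records, boxes = boxes, root = dir,
                 seed = NA_integer_, config = NULL, class_names = class_names),
            class = "camloc_manifest")
}

#' Export ground-truth boxes as COCO-style JSON
#'
#' @param manifest A `camloc_manifest`.
#' @param path Output JSON path.
#' @param class_names Class names (category labels), in class-id order.
#' @return `path`, invisibly.
#' @export
write_coco <- function(manifest, path, class_names = manifest$config$class_names) {
  recs <- manifest$records
  imgs <- data.frame(id = seq_len(nrow(recs)) - 1L, file_name = recs$frame_path)
  b <- manifest$boxes
  img_id <- match(b$frame_path, recs$frame_path) - 1L
  anns <- lapply(seq_len(nrow(b)), function(i) list(
    id = i - 1L, image_id = img_id[i], category_id = b$class_id[i],
    bbox = c(b$x_min[i], b$y_min[i], b$x_max[i] - b$x_min[i], b$y_max[i] - b$y_min[i]),
    area = (b$x_max[i] - b$x_min[i]) * (b$y_max[i] - b$y_min[i]), iscrowd = 0L))
  cats <- lapply(seq_along(class_names), function(i)
    list(id = i - 1L, name = class_names[i]))
  jsonlite::write_json(list(images = imgs, annotations = anns, categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a diagnostic heat map with planted blobs
#'
#' Builds a synthetic attention heat map containing bright, slightly smoothed
#' elongated blobs that touch a frame edge (as a real instrument's activation
#' would) plus optional interior distractor blobs that touch no edge. Used to
#' exercise the threshold/contour/filter/NMS chain with known ground truth,
#' independently of any trained model.
#'
#' @param image_size (height, width) in pixels.
#' @param n_planted Number of edge-touching blobs (each yields a truth box).
#' @param n_distractors Number of interior blobs (should yield no detection).
#' @param seed Integer seed.
#' @return List with `values` (H x W matrix in \[0,1\]), `planted_boxes`
#'   (data.frame of tight boxes of the planted supports) and
#'   `distractor_boxes`.
#' @export
planted_heatmap <- function(image_size = c(128L, 128L), n_planted = 1L,
                            n_distractors = 0L, seed = 1L) {
  h <- image_size[1]; w <- image_size[2]; m <- min(h, w)
  with_local_seed(seed, {
    vals <- matrix(stats::runif(h * w, 0, 0.08), h, w)
    planted <- list(); distract <- list()
    # Blobs that overlap merge into one connected component and are then
    # unrecoverable as individual boxes by construction, which would measure
    # the fixture, not the chain. Placements are therefore rejection-sampled
    # until each blob's box (padded so post-blur supports stay 8-disconnected)
    # is disjoint from all previously planted ones; a blob with no admissible
    # placement after 50 tries is skipped and not counted.
    pad <- 4
    separated <- function(box, others) {
      for (o in others)
        if (box[1] - pad < o[3] && o[1] - pad < box[3] &&
            box[2] - pad < o[4] && o[2] - pad < box[4]) return(FALSE)
      TRUE
    }
    all_boxes <- list()
    for (i in seq_len(n_planted)) {
      for (try in 1:50) {
        edge <- sample.int(4L, 1L); u <- stats::runif(1, 0.2, 0.8)
        ang_off <- stats::runif(1, -pi / 4, pi / 4)
        len <- stats::runif(1, 0.30, 0.55) * m
        hw <- stats::runif(1, 0.05, 0.10) * m
        if (edge == 1L)      { x0 <- u * (w - 1); y0 <- -1; ang <- pi / 2 + ang_off }
        else if (edge == 2L) { x0 <- u * (w - 1); y0 <- h;  ang <- -pi / 2 + ang_off }
        else if (edge == 3L) { x0 <- -1; y0 <- u * (h - 1); ang <- 0 + ang_off }
        else                 { x0 <- w;  y0 <- u * (h - 1); ang <- pi + ang_off }
        mask <- .capsule_mask(h, w, x0, y0, x0 + len * cos(ang), y0 + len * sin(ang), hw)
        bb <- .mask_bbox(mask)
        if (separated(bb, all_boxes)) {
          vals[mask] <- stats::runif(1, 0.85, 1.0)
          planted[[length(planted) + 1L]] <- bb
          all_boxes[[length(all_boxes) + 1L]] <- bb
          break
        }
      }
    }
    for (i in seq_len(n_distractors)) {
      for (try in 1:50) {
        r0 <- stats::runif(1, 0.04, 0.08) * m
        cx <- stats::runif(1, 0.3, 0.7) * (w - 1)
        cy <- stats::runif(1, 0.3, 0.7) * (h - 1)
        dm <- .disk_mask(h, w, cx, cy, r0)
        bb <- .mask_bbox(dm)
        if (separated(bb, all_boxes)) {
          vals[dm] <- stats::runif(1, 0.85, 1.0)
          distract[[length(distract) + 1L]] <- bb
          all_boxes[[length(all_boxes) + 1L]] <- bb
          break
        }
      }
    }
    vals <- EBImage::gblur(vals, sigma = 1.2)
    vals <- pmin(pmax(vals, 0), 1)
    to_df <- function(l) if (length(l)) as.data.frame(do.call(rbind, l)) else
      data.frame(x_min = integer(), y_min = integer(), x_max = integer(), y_max = integer())
    list(values = vals, planted_boxes = to_df(planted),
         distractor_boxes = to_df(distract))
  })
}
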
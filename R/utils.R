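# Shared internal helpers: seeded RNG streams, bilinear resizing, image I/O.

#' Derive a per-item RNG seed from a base seed and an index
#'
#' Mixes a base seed with an item index (e.g. a frame index) so that each item
#' gets an independent, order-free RNG stream. Results stay below 2^31 so they
#' are valid R integer seeds.
#'
#' @param seed Base integer seed.
#' @param index Nonnegative integer item index.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(index), length(index) == 1)
  # multiplicative hash in double precision; 2^31 - 1 is prime
  s <- (abs(as.double(seed)) * 1000003 + as.double(index) * 7919 + 12345) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Bilinear resize of a matrix or H x W x C array
#'
#' Pixel-center-aligned bilinear interpolation (the convention used by OpenCV
#' and EBImage): output pixel i samples source coordinate
#' (i + 0.5) * in/out - 0.5, clamped to the image.
#'
#' @param x Numeric matrix (H x W) or 3-d array (H x W x C).
#' @param out_h,out_w Output height and width in pixels.
#' @return Resized matrix or array of the same number of channels.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  stopifnot(out_h >= 1, out_w >= 1)
  if (length(dim(x)) == 3) {
    out <- array(0, c(out_h, out_w, dim(x)[3]))
    for (c in seq_len(dim(x)[3])) out[, , c] <- resize_bilinear(x[, , c], out_h, out_w)
    return(out)
  }
  stopifnot(is.matrix(x))
  in_h <- nrow(x); in_w <- ncol(x)
  src <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  sy <- src(out_h, in_h); sx <- src(out_w, in_w)
  y0 <- floor(sy); x0 <- floor(sx)
  y1 <- pmin(y0 + 1, in_h - 1); x1 <- pmin(x0 + 1, in_w - 1)
  wy <- sy - y0; wx <- sx - x0
  # gather the four neighbours with outer indexing (1-based)
  a <- x[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
  b <- x[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
  d <- x[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
  e <- x[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
  WY <- rep(wy, out_w); WX <- rep(wx, each = out_h)
  top <- a * (1 - WX) + b * WX
  bot <- d * (1 - WX) + e * WX
  matrix(top * (1 - WY) + bot * WY, out_h, out_w)
}

#' Read an RGB image frame from a PNG/JPEG file
#'
#' @param path Path to a PNG file (8-bit, RGB or grayscale).
#' @return Numeric H x W x 3 array with values in \[0, 1\].
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- tryCatch(png::readPNG(path), error = function(e)
    stop("failed to read image '", path, "': ", conditionMessage(e)))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image frame to a PNG file
#'
#' @param img Numeric H x W x 3 array in \[0, 1\] (clipped before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# Luminance (Rec. 601) of an H x W x 3 array.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Quantize a unit-interval raster to 8-bit gray levels
#'
#' Used when handing a real-valued heat map to Otsu thresholding.
#'
#' @param x Numeric matrix with values in \[0, 1\].
#' @return Integer matrix with values in 0..255.
#' @export
quantize_8bit <- function(x) {
  stopifnot(is.matrix(x))
  matrix(as.integer(round(255 * pmin(pmax(x, 0), 1))), nrow(x), ncol(x))
}

# Timestamped log line, optionally appended to a file.
log_line <- function(..., file = NULL) {
  msg <- paste0("[", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "] ", ...)
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE)
  invisible(msg)
}
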
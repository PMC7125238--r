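#' herbqc: staged quality control for herbarium digitisation batches
#'
#' See [herbqc_config()] for the tunable parameters, [make_batch()] for the
#' synthetic fixture generator, [run_image_processing()] and
#' [run_store_images()] for the two audit-trail phases, and the methods
#' vignette for the underlying model.
#'
#' @keywords internal
"_PACKAGE"

# ---- pixel rectangles -------------------------------------------------------
# All rectangles are 0-based, half-open: list(x0, y0, x1, y1) covering pixel
# columns x0..x1-1 and rows y0..y1-1. This is the single convention shared by
# the generator, the decoders and the exposure checks.

rect <- function(x0, y0, x1, y1) {
  stopifnot(x1 >= x0, y1 >= y0)
  list(x0 = as.integer(x0), y0 = as.integer(y0),
       x1 = as.integer(x1), y1 = as.integer(y1))
}

rect_width  <- function(r) r$x1 - r$x0
rect_height <- function(r) r$y1 - r$y0
rect_area   <- function(r) rect_width(r) * rect_height(r)

rect_inside <- function(r, width, height) {
  r$x0 >= 0 && r$y0 >= 0 && r$x1 <= width && r$y1 <= height
}

rect_intersect <- function(a, b) {
  x0 <- max(a$x0, b$x0); y0 <- max(a$y0, b$y0)
  x1 <- min(a$x1, b$x1); y1 <- min(a$y1, b$y1)
  if (x1 <= x0 || y1 <= y0) return(NULL)
  rect(x0, y0, x1, y1)
}

#' Intersection-over-union of two pixel rectangles
#'
#' Rectangles are 0-based half-open lists with elements `x0, y0, x1, y1`.
#'
#' @param a,b rectangles.
#' @return IoU in \[0, 1\].
#' @export
rect_iou <- function(a, b) {
  i <- rect_intersect(a, b)
  if (is.null(i)) return(0)
  ia <- rect_area(i)
  ia / (rect_area(a) + rect_area(b) - ia)
}

# shrink a rectangle by `frac` of its width/height on each side
rect_erode <- function(r, frac) {
  dx <- floor(rect_width(r) * frac)
  dy <- floor(rect_height(r) * frac)
  rect(r$x0 + dx, r$y0 + dy, r$x1 - dx, r$y1 - dy)
}

# 1-based row/col index vectors for an image array
rect_rows <- function(r) (r$y0 + 1L):r$y1
rect_cols <- function(r) (r$x0 + 1L):r$x1

# ---- image helpers ----------------------------------------------------------

# images are integer arrays [h, w, 3] with values 0..255
as_image <- function(arr) {
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 3L))
  storage.mode(arr) <- "integer"
  arr
}

#' Read an image file into an 8-bit array
#'
#' Reads TIFF, PNG or JPEG 2000 (the latter through the bundled Python
#' helper) into an integer array `[height, width, 3]` with values 0..255.
#'
#' @param path image file path.
#' @return integer array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path)
  } else if (ext == "png") {
    x <- png::readPNG(path)
  } else if (ext == "jp2") {
    return(read_jp2_pixels(path))
  } else {
    stop("unsupported image extension: ", ext)
  }
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[3] == 1L) x <- x[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  as_image(round(x * 255))
}

# rounded Rec.709 luma of an [h,w,3] image -> [h,w] integer matrix
luma <- function(img) {
  img <- as_image(img)
  y <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  matrix(as.integer(round(y)), nrow = dim(img)[1])
}

# nearest-neighbour resample by a scale factor (used for 450 -> 420 PPI)
resample_image <- function(img, scale) {
  img <- as_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  nh <- max(1L, as.integer(round(h * scale)))
  nw <- max(1L, as.integer(round(w * scale)))
  ri <- pmin(h, pmax(1L, as.integer(floor(((seq_len(nh) - 0.5) / scale)) + 1L)))
  ci <- pmin(w, pmax(1L, as.integer(floor(((seq_len(nw) - 0.5) / scale)) + 1L)))
  img[ri, ci, , drop = FALSE]
}

# ---- misc -------------------------------------------------------------------

file_md5 <- function(paths) {
  unname(tools::md5sum(paths))
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
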
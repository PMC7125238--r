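# Scan-line barcode decoding: locate candidate regions by transition
# density, binarise each scan line with Otsu's threshold, quantise run
# widths to modules, and map symbols through the Code 128 / UPC-A tables
# with checksum verification and multi-scan-line majority voting.

barcode_result <- function(payload = "", symbology = NA_character_,
                           checksum_valid = FALSE, region = NULL,
                           scanline_votes = 0L, detail = "") {
  structure(list(payload = payload, symbology = symbology,
                 checksum_valid = checksum_valid, region = region,
                 scanline_votes = as.integer(scanline_votes),
                 detail = detail),
            class = "barcode_result")
}

#' @export
print.barcode_result <- function(x, ...) {
  cat(sprintf("<barcode %s payload=%s checksum_valid=%s votes=%d>\n",
              x$symbology %||% "?",
              if (nzchar(x$payload)) sQuote(x$payload) else "<none>",
              x$checksum_valid, x$scanline_votes))
  invisible(x)
}

# Otsu threshold of an integer vector/matrix of 0..255 levels
otsu_threshold <- function(v) {
  h <- as.numeric(tabulate(as.integer(v) + 1L, nbins = 256L))
  n <- sum(h)
  if (n == 0) return(128)
  levels <- 0:255
  w1 <- cumsum(h)
  m1 <- cumsum(h * levels)
  mt <- m1[256]
  w2 <- n - w1
  between <- (mt * w1 - n * m1)^2 / (as.numeric(w1) * w2 * n^2)
  between[w1 == 0 | w2 == 0] <- 0
  which.max(between) - 1L
}

# round half toward the narrower bar (half-down), clip to 1..4 modules
quantise_runs <- function(runs, module) {
  w <- ceiling(runs / module - 0.5)
  pmin(4L, pmax(1L, as.integer(w)))
}

#' Decode a Code 128 scan line
#'
#' Input is the run-length sequence of a scan line (widths of alternating
#' bar/space runs, starting with the first bar; quiet zones removed). Runs
#' are grouped six per symbol, widths quantised to the 11-module symbol
#' grid, mapped through the Code 128 table (code sets A/B/C with shifts and
#' switches), and the modulo-103 checksum is verified against the check
#' symbol. The payload is returned only when the stop pattern is present.
#'
#' @param runs numeric vector of run lengths in pixels (or modules).
#' @return a `barcode_result`; on any failure `payload` is empty and
#'   `checksum_valid` is `FALSE`.
#' @export
decode_code128 <- function(runs) {
  fail <- function(msg) barcode_result(symbology = "code128", detail = msg)
  n <- length(runs)
  if (n < 19L || (n - 7L) %% 6L != 0L) return(fail("run count not a symbol grid"))
  nsym <- (n - 7L) %/% 6L            # start + data + check
  module <- sum(runs) / (11 * nsym + 13)
  if (!is.finite(module) || module <= 0) return(fail("degenerate runs"))
  w <- quantise_runs(runs, module)
  if (!identical(w[(n - 6L):n], pattern_to_widths(CODE128_STOP))) {
    return(fail("stop pattern absent"))
  }
  pats <- vapply(seq_len(nsym), function(i) {
    paste(w[((i - 1L) * 6L + 1L):(i * 6L)], collapse = "")
  }, character(1))
  values <- match(pats, CODE128_PATTERNS) - 1L
  if (anyNA(values)) return(fail("unknown symbol"))
  start <- values[1]
  if (!start %in% c(C128_START_A, C128_START_B, C128_START_C)) {
    return(fail("no start symbol"))
  }
  check_ok <- c128_checksum(values[-length(values)]) == values[length(values)]
  if (!check_ok) return(fail("checksum mismatch"))

  set <- c("A", "B", "C")[match(start, c(C128_START_A, C128_START_B, C128_START_C))]
  data <- values[-c(1L, length(values))]
  out <- character()
  shift <- NULL
  for (v in data) {
    cur <- shift %||% set
    shift <- NULL
    if (cur == "C") {
      if (v <= 99L) { out <- c(out, sprintf("%02d", v)); next }
      if (v == C128_CODE_B) { set <- "B"; next }
      if (v == C128_CODE_A) { set <- "A"; next }
      return(fail("unsupported control symbol in set C"))
    }
    if (v == C128_SHIFT) { shift <- if (cur == "A") "B" else "A"; next }
    if (v == C128_CODE_C) { set <- "C"; next }
    if (cur == "A" && v == C128_CODE_B) { set <- "B"; next }
    if (cur == "B" && v == C128_CODE_A) { set <- "A"; next }
    ch <- c128_value_to_char(v, cur)
    if (is.na(ch)) return(fail("unsupported control symbol"))
    out <- c(out, ch)
  }
  barcode_result(payload = paste(out, collapse = ""), symbology = "code128",
                 checksum_valid = TRUE, scanline_votes = 1L)
}

#' Decode a UPC-A scan line
#'
#' Parses the 95-module frame (guard 101, six left digits, centre 01010,
#' six right digits, guard 101) from a run-length sequence and verifies the
#' modulo-10 check digit.
#'
#' @inheritParams decode_code128
#' @return a `barcode_result`.
#' @export
decode_upca <- function(runs) {
  fail <- function(msg) barcode_result(symbology = "upca", detail = msg)
  if (length(runs) != 59L) return(fail("run count is not a UPC-A frame"))
  module <- sum(runs) / 95
  w <- quantise_runs(runs, module)
  if (!all(w[1:3] == 1L)) return(fail("left guard mismatch"))
  if (!all(w[28:32] == 1L)) return(fail("centre guard mismatch"))
  if (!all(w[57:59] == 1L)) return(fail("right guard mismatch"))
  digit_at <- function(k) {
    # digit groups: left at runs 4..27, right at 33..56, 4 runs each
    idx <- if (k <= 6L) 3L + (k - 1L) * 4L + 1:4 else 32L + (k - 7L) * 4L + 1:4
    g <- w[idx]
    hit <- which(apply(UPCA_RUNS, 1L, function(r) all(r == g)))
    if (length(hit) != 1L) return(NA_integer_)
    hit - 1L
  }
  d <- vapply(1:12, digit_at, integer(1))
  if (anyNA(d)) return(fail("undecodable digit"))
  payload <- paste(d, collapse = "")
  if (upca_check_digit(substr(payload, 1, 11)) != d[12]) {
    return(fail("check digit mismatch"))
  }
  barcode_result(payload = payload, symbology = "upca",
                 checksum_valid = TRUE, scanline_votes = 1L)
}

# run-length encode one scan line of luma values; returns runs starting at
# the first dark run, or NULL if fewer than 3 runs
scanline_runs <- function(line) {
  thr <- otsu_threshold(line)
  dark <- as.integer(line) <= thr
  if (!any(dark) || all(dark)) return(NULL)
  r <- rle(dark)
  if (!r$values[1]) { r$values <- r$values[-1]; r$lengths <- r$lengths[-1] }
  k <- length(r$values)
  if (k && !r$values[k]) { r$values <- r$values[-k]; r$lengths <- r$lengths[-k] }
  if (length(r$lengths) < 3L) return(NULL)
  r$lengths
}

decode_scanline <- function(line) {
  runs <- scanline_runs(line)
  if (is.null(runs)) return(barcode_result(detail = "no runs"))
  res <- decode_code128(runs)
  if (res$checksum_valid) return(res)
  res2 <- decode_upca(runs)
  if (res2$checksum_valid) return(res2)
  res
}

#' Locate candidate barcode regions in an image
#'
#' Finds axis-aligned regions with the dense bar/space alternation
#' characteristic of 1D barcodes: the image is binarised with a global
#' Otsu threshold and tiled into blocks about 1/16th of the frame width;
#' blocks whose mean per-row transition count reaches
#' `min_row_transitions` are merged into connected components and filtered
#' by aspect ratio. The statistic is scale-free: a barcode sized relative
#' to the sheet yields roughly the same per-block transition count at any
#' capture resolution, while drawings, text lines and scale-bar ticks stay
#' far below it. Candidates are ordered bottom-right first, matching the
#' placement convention for accession barcodes.
#'
#' @param image image array (`[h, w, 3]` or matrix) or a file path.
#' @param roi optional rectangle restricting the search (0-based,
#'   half-open, `list(x0, y0, x1, y1)`).
#' @param min_row_transitions candidate threshold on mean transitions per
#'   pixel row within a block.
#' @return list of candidate rectangles (possibly empty).
#' @export
locate_barcodes <- function(image, roi = NULL, min_row_transitions = 6) {
  if (is.character(image)) image <- read_image(image)
  g <- if (length(dim(image)) == 3L) luma(image) else {
    matrix(as.integer(image), nrow = nrow(image))
  }
  off_x <- 0L; off_y <- 0L
  if (!is.null(roi)) {
    roi <- rect(max(0, roi$x0), max(0, roi$y0),
                min(ncol(g), roi$x1), min(nrow(g), roi$y1))
    if (rect_area(roi) == 0L) return(list())
    g <- g[rect_rows(roi), rect_cols(roi), drop = FALSE]
    off_x <- roi$x0; off_y <- roi$y0
  }
  h <- nrow(g); w <- ncol(g)
  if (h < 8L || w < 32L) return(list())
  thr <- otsu_threshold(g)
  bw <- g <= thr
  if (!any(bw) || all(bw)) return(list())
  tr <- bw[, -1L, drop = FALSE] != bw[, -w, drop = FALSE]

  bx <- max(8L, w %/% 16L)
  by <- max(4L, h %/% 64L)
  bi <- (seq_len(h) - 1L) %/% by + 1L
  bj <- (seq_len(w - 1L) - 1L) %/% bx + 1L
  cnt <- rowsum(tr + 0L, bi)                 # transitions per (row-block, col)
  cnt <- t(rowsum(t(cnt), bj))               # then per block
  per_row <- cnt / tabulate(bi)              # mean transitions per pixel row
  cand <- per_row >= min_row_transitions

  nb_h <- nrow(cand); nb_w <- ncol(cand)
  labels <- matrix(0L, nb_h, nb_w)
  comp <- 0L
  for (s in which(cand)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      ci <- (cur - 1L) %% nb_h + 1L; cj <- (cur - 1L) %/% nb_h + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- ci + di; nj <- cj + dj
        if (ni >= 1L && ni <= nb_h && nj >= 1L && nj <= nb_w) {
          k <- (nj - 1L) * nb_h + ni
          if (cand[k] && labels[k] == 0L) { labels[k] <- comp; queue <- c(queue, k) }
        }
      }
    }
  }
  regions <- list()
  for (cc in seq_len(comp)) {
    idx <- which(labels == cc)
    ci <- (idx - 1L) %% nb_h + 1L; cj <- (idx - 1L) %/% nb_h + 1L
    x0 <- (min(cj) - 1L) * bx; x1 <- min(w, max(cj) * bx)
    y0 <- (min(ci) - 1L) * by; y1 <- min(h - 1L, max(ci) * by)
    # refine the block bbox to the extent of the actual transitions, then
    # pad ~9% (a 10-module quiet zone) on each side
    rows <- max(1L, y0 - by + 1L):min(h, y1 + by)
    cols <- max(1L, x0 - bx + 1L):min(w - 1L, x1 + bx)
    sub <- tr[rows, cols, drop = FALSE]
    chas <- which(colSums(sub) > 0)
    rhas <- which(rowSums(sub) > 0)
    if (!length(chas) || !length(rhas)) next
    px0 <- cols[min(chas)] - 1L; px1 <- cols[max(chas)] + 1L
    py0 <- rows[min(rhas)] - 1L; py1 <- rows[max(rhas)]
    pad <- as.integer(round(0.09 * (px1 - px0)))
    px0 <- max(0L, px0 - pad); px1 <- min(w, px1 + pad)
    if ((px1 - px0) < 1.2 * (py1 - py0)) next
    regions[[length(regions) + 1L]] <- rect(px0 + off_x, py0 + off_y,
                                            px1 + off_x, py1 + off_y)
  }
  if (!length(regions)) return(list())
  ord <- order(vapply(regions, function(r) r$x1 + r$y1, numeric(1)),
               decreasing = TRUE)
  regions[ord]
}

#' Read and decode all barcodes on a sheet image
#'
#' Combines [locate_barcodes()] with per-region decoding: five horizontal
#' scan lines evenly spaced over the region height are decoded
#' independently (Code 128 first, then UPC-A) and the majority payload
#' wins; a tie between distinct payloads is a failure. Regions are
#' reported bottom-right first.
#'
#' @param image image array or file path.
#' @param roi optional search rectangle.
#' @param n_scanlines scan lines per region.
#' @return list of `barcode_result`, one per candidate region.
#' @export
read_sheet_barcodes <- function(image, roi = NULL, n_scanlines = 5L) {
  if (is.character(image)) image <- read_image(image)
  g <- luma(image)
  regions <- locate_barcodes(g, roi = roi)
  out <- list()
  for (r in regions) {
    rh <- rect_height(r)
    ys <- unique(pmin(r$y1, r$y0 + pmax(1L, round(rh * seq_len(n_scanlines) /
                                                    (n_scanlines + 1L)))))
    dec <- lapply(ys, function(y) decode_scanline(g[y, rect_cols(r)]))
    good <- Filter(function(d) d$checksum_valid, dec)
    if (!length(good)) {
      res <- barcode_result(region = r, detail = "no scan line decoded")
    } else {
      payloads <- vapply(good, `[[`, character(1), "payload")
      tab <- sort(table(payloads), decreasing = TRUE)
      if (length(tab) > 1L && tab[1] == tab[2]) {
        res <- barcode_result(region = r, detail = "scan line vote tie")
      } else {
        win <- names(tab)[1]
        first <- good[[which(payloads == win)[1]]]
        res <- barcode_result(payload = win, symbology = first$symbology,
                              checksum_valid = TRUE, region = r,
                              scanline_votes = as.integer(tab[1]))
      }
    }
    out[[length(out) + 1L]] <- res
  }
  out
}
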
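# Barcode rendering: payload -> module bit sequence -> binary pixel matrix.

# Code 128 symbol values for a payload. Starts in code set C when the
# payload is all digits with even length >= 4, otherwise in B; switches to
# C mid-stream for runs of >= 6 digits (or an even all-digit tail of >= 4).
c128_encode_values <- function(payload) {
  chars <- strsplit(payload, "")[[1]]
  if (!length(chars)) stop("empty payload")
  is_digit <- chars %in% as.character(0:9)
  digits_ahead <- function(i) {
    n <- 0L
    while (i + n <= length(chars) && is_digit[i + n]) n <- n + 1L
    n
  }
  values <- integer()
  i <- 1L
  ahead <- digits_ahead(1L)
  if (ahead == length(chars) && ahead %% 2L == 0L && ahead >= 4L) {
    values <- C128_START_C; set <- "C"
  } else {
    values <- C128_START_B; set <- "B"
  }
  while (i <= length(chars)) {
    ahead <- digits_ahead(i)
    if (set == "B") {
      tail_all <- (i + ahead) > length(chars)
      if (ahead >= 6L || (tail_all && ahead >= 4L)) {
        if (ahead %% 2L == 1L) {  # encode one digit in B to even the run
          v <- c128_char_to_value(chars[i])
          values <- c(values, v); i <- i + 1L; ahead <- ahead - 1L
        }
        values <- c(values, C128_CODE_C); set <- "C"
        next
      }
      v <- c128_char_to_value(chars[i])
      if (is.na(v)) stop("character not encodable in Code 128 set B: ",
                         sQuote(chars[i]))
      values <- c(values, v); i <- i + 1L
    } else {  # set C
      if (ahead >= 2L) {
        values <- c(values, as.integer(paste0(chars[i], chars[i + 1L])))
        i <- i + 2L
      } else {
        values <- c(values, C128_CODE_B); set <- "B"
      }
    }
  }
  c(values, c128_checksum(values))
}

# module bit vector (1 = bar) for a value sequence plus stop pattern
c128_modules <- function(values) {
  widths <- unlist(lapply(CODE128_PATTERNS[values + 1L], pattern_to_widths))
  widths <- c(widths, pattern_to_widths(CODE128_STOP))
  cols <- rep(rep(c(1L, 0L), length.out = length(widths)), widths)
  cols
}

upca_modules <- function(payload) {
  if (!grepl("^[0-9]{11}$", payload)) stop("UPC-A payload must be 11 digits")
  d <- as.integer(strsplit(payload, "")[[1]])
  d <- c(d, upca_check_digit(payload))
  left  <- lapply(d[1:6], function(x) {
    rep(c(0L, 1L, 0L, 1L), UPCA_RUNS[x + 1L, ])
  })
  right <- lapply(d[7:12], function(x) {
    rep(c(1L, 0L, 1L, 0L), UPCA_RUNS[x + 1L, ])
  })
  c(1L, 0L, 1L, unlist(left), c(0L, 1L, 0L, 1L, 0L), unlist(right),
    1L, 0L, 1L)
}

#' Render a 1D barcode as a binary pixel matrix
#'
#' Encodes `payload` in the requested symbology — including start/stop
#' patterns, guard bars and the symbology checksum — and rasterises it at
#' `module_px` pixels per module with a 10-module quiet zone on each side.
#'
#' @param payload text to encode. Code 128: printable ASCII; UPC-A: exactly
#'   11 digits (the check digit is appended by the renderer).
#' @param symbology `"code128"` or `"upca"`.
#' @param module_px pixels per module (integer >= 1).
#' @param height_px bar height in pixels; default scales with width.
#' @return integer matrix `[height_px, width_px]`, 1 = bar (dark),
#'   0 = space, with attributes `payload`, `symbology` and `modules` (the
#'   module bit vector without quiet zones).
#' @examples
#' m <- render_barcode("BR0000008378064", "code128", module_px = 2)
#' dim(m)
#' @export
render_barcode <- function(payload, symbology = c("code128", "upca"),
                           module_px = 3L, height_px = NULL) {
  symbology <- match.arg(symbology)
  module_px <- as.integer(module_px)
  stopifnot(module_px >= 1L)
  mods <- switch(symbology,
    code128 = c128_modules(c128_encode_values(payload)),
    upca    = upca_modules(payload))
  quiet <- rep(0L, 10L * module_px)
  row <- c(quiet, rep(mods, each = module_px), quiet)
  if (is.null(height_px)) height_px <- max(24L, as.integer(round(length(row) * 0.18)))
  m <- matrix(rep(row, each = height_px), nrow = height_px)
  attr(m, "payload") <- payload
  attr(m, "symbology") <- symbology
  attr(m, "modules") <- mods
  m
}
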
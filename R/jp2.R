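# JPEG 2000 (JP2, ISO/IEC 15444-1) box-level validation and resolution
# metadata. The validator covers the boxes the pipeline's accept/reject
# decisions depend on: signature, ftyp brand, jp2h/ihdr, and a contiguous
# codestream starting with the SOC marker. Codestream contents beyond SOC
# are not decoded here; pixel access goes through the Python helper.

rawToUint <- function(r) {
  sum(as.numeric(r) * 256^(rev(seq_along(r)) - 1))
}

# parse the box sequence in `bytes[(from+1):to]`; returns list of
# list(type, start, content_start, content_end) with 0-based offsets
parse_jp2_boxes <- function(bytes, from = 0, to = length(bytes)) {
  boxes <- list()
  pos <- from
  while (pos + 8 <= to) {
    lbox <- rawToUint(bytes[(pos + 1):(pos + 4)])
    type <- rawToChar(bytes[(pos + 5):(pos + 8)])
    hdr <- 8
    if (lbox == 1) {
      if (pos + 16 > to) break
      lbox <- rawToUint(bytes[(pos + 9):(pos + 16)])
      hdr <- 16
    } else if (lbox == 0) {
      lbox <- to - pos
    }
    if (lbox < hdr || pos + lbox > to) {
      boxes[[length(boxes) + 1]] <- list(type = type, start = pos,
                                         content_start = NA, content_end = NA,
                                         truncated = TRUE)
      break
    }
    boxes[[length(boxes) + 1]] <- list(type = type, start = pos,
                                       content_start = pos + hdr,
                                       content_end = pos + lbox,
                                       truncated = FALSE)
    pos <- pos + lbox
  }
  boxes
}

find_box <- function(boxes, type) {
  for (b in boxes) if (b$type == type) return(b)
  NULL
}

#' Validate the structure of a JP2 file
#'
#' Verifies the 12-byte signature box, an `ftyp` box with brand `jp2 `, a
#' `jp2h` header box containing `ihdr` (height, width, components), and a
#' contiguous codestream box whose first marker is SOC (0xFF4F). Extracts
#' image dimensions and, when a capture-resolution box is present, the
#' resolution in pixels per inch.
#'
#' @param path JP2 file path.
#' @return list with `conformant`, `width`, `height`, `n_components`,
#'   `ppi` (NA when absent) and `issues`.
#' @export
validate_jp2_structure <- function(path) {
  out <- list(conformant = FALSE, width = NA_real_, height = NA_real_,
              n_components = NA_real_, ppi = NA_real_, issues = character())
  if (!file.exists(path)) { out$issues <- "io: file not found"; return(out) }
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  sig <- as.raw(c(0x00, 0x00, 0x00, 0x0C, 0x6A, 0x50, 0x20, 0x20,
                  0x0D, 0x0A, 0x87, 0x0A))
  if (length(bytes) < 12 || !identical(bytes[1:12], sig)) {
    out$issues <- "signature box absent or malformed"
    return(out)
  }
  boxes <- parse_jp2_boxes(bytes)
  if (any(vapply(boxes, function(b) isTRUE(b$truncated), logical(1)))) {
    out$issues <- c(out$issues, "truncated box")
  }
  ftyp <- if (length(boxes) >= 2) boxes[[2]] else NULL
  if (is.null(ftyp) || ftyp$type != "ftyp") {
    out$issues <- c(out$issues, "ftyp box not second")
  } else {
    brand <- rawToChar(bytes[(ftyp$content_start + 1):(ftyp$content_start + 4)])
    if (brand != "jp2 ") out$issues <- c(out$issues, "ftyp brand is not 'jp2 '")
  }
  jp2h <- find_box(boxes, "jp2h")
  if (is.null(jp2h) || isTRUE(jp2h$truncated)) {
    out$issues <- c(out$issues, "jp2h box absent")
  } else {
    inner <- parse_jp2_boxes(bytes, jp2h$content_start, jp2h$content_end)
    ihdr <- find_box(inner, "ihdr")
    if (is.null(ihdr) || isTRUE(ihdr$truncated) ||
        ihdr$content_end - ihdr$content_start < 8) {
      out$issues <- c(out$issues, "ihdr box absent")
    } else {
      s <- ihdr$content_start
      out$height <- rawToUint(bytes[(s + 1):(s + 4)])
      out$width  <- rawToUint(bytes[(s + 5):(s + 8)])
      out$n_components <- rawToUint(bytes[(s + 9):(s + 10)])
    }
    res <- find_box(inner, "res ")
    if (!is.null(res) && !isTRUE(res$truncated)) {
      rin <- parse_jp2_boxes(bytes, res$content_start, res$content_end)
      resc <- find_box(rin, "resc") %||% find_box(rin, "resd")
      if (!is.null(resc) && resc$content_end - resc$content_start >= 10) {
        s <- resc$content_start
        vn <- rawToUint(bytes[(s + 1):(s + 2)])
        vd <- rawToUint(bytes[(s + 3):(s + 4)])
        ve <- as.integer(bytes[s + 9])
        if (ve > 127) ve <- ve - 256
        ppm <- vn / vd * 10^ve
        out$ppi <- round(ppm * 0.0254, 4)
      }
    }
  }
  jp2c <- find_box(boxes, "jp2c")
  if (is.null(jp2c) || isTRUE(jp2c$truncated)) {
    out$issues <- c(out$issues, "contiguous codestream box absent")
  } else if (jp2c$content_end - jp2c$content_start < 2 ||
             !identical(bytes[(jp2c$content_start + 1):(jp2c$content_start + 2)],
                        as.raw(c(0xFF, 0x4F)))) {
    out$issues <- c(out$issues, "codestream does not start with SOC")
  }
  out$conformant <- length(out$issues) == 0L
  out
}

u16be <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "big")
u32be <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")

# Insert a capture-resolution (res/resc) box into a JP2's jp2h superbox.
# ppi is stored as the rational (ppi*50)/127 x 10^2 pixels per metre, which
# is exact for integer ppi.
jp2_set_resolution <- function(path, ppi) {
  bytes <- readBin(path, raw(), n = file.info(path)$size)
  boxes <- parse_jp2_boxes(bytes)
  jp2h <- find_box(boxes, "jp2h")
  if (is.null(jp2h)) stop("no jp2h box in ", path)
  num <- as.integer(round(ppi * 50)); den <- 127L
  resc <- c(u32be(18L), charToRaw("resc"),
            u16be(num), u16be(den), u16be(num), u16be(den),
            as.raw(2L), as.raw(2L))
  resb <- c(u32be(8L + length(resc)), charToRaw("res "), resc)
  old_len <- jp2h$content_end - jp2h$start
  new_len <- old_len + length(resb)
  out <- c(bytes[seq_len(jp2h$start)],
           u32be(new_len), charToRaw("jp2h"),
           bytes[(jp2h$content_start + 1):jp2h$content_end],
           resb,
           if (jp2h$content_end < length(bytes))
             bytes[(jp2h$content_end + 1):length(bytes)])
  writeBin(out, path)
  invisible(path)
}
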
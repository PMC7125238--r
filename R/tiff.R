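# Baseline TIFF 6.0 writing and structural validation.
#
# The writer produces deterministic, uncompressed, single-strip RGB files
# with resolution tags set in pixels/inch — the shape of an archival master.
# The validator re-implements the subset of a format characterisation tool
# that the audit trail's decisions depend on: header sanity, a walkable IFD
# chain, required baseline tags, and strip offsets that stay inside the file.

TIFF_TAGS <- c(
  ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
  Compression = 259L, PhotometricInterpretation = 262L,
  StripOffsets = 273L, SamplesPerPixel = 277L, RowsPerStrip = 278L,
  StripByteCounts = 279L, XResolution = 282L, YResolution = 283L,
  ResolutionUnit = 296L
)

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write an 8-bit RGB image as an uncompressed baseline TIFF
#'
#' Single strip, little-endian, with `XResolution`/`YResolution` set to
#' `ppi` pixels per inch. Output is byte-deterministic for identical input.
#'
#' @param img integer array `[h, w, 3]`, values 0..255.
#' @param path output path.
#' @param ppi resolution to record, pixels per inch.
#' @return `path`, invisibly.
#' @export
write_baseline_tiff <- function(img, path, ppi) {
  img <- as_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  stopifnot(h >= 1, w >= 1, dim(img)[3] == 3L)

  n_entries <- 12L
  ifd_off  <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  bps_off  <- ifd_off + ifd_size          # 3 x SHORT  (6 bytes)
  xres_off <- bps_off + 6L                # RATIONAL   (8 bytes)
  yres_off <- xres_off + 8L
  data_off <- yres_off + 8L
  nbytes   <- h * w * 3

  entry <- function(tag, type, count, value_raw) {
    if (length(value_raw) < 4L) value_raw <- c(value_raw, raw(4L - length(value_raw)))
    c(u16le(tag), u16le(type), u32le(count), value_raw[1:4])
  }
  short_val <- function(v) c(u16le(v), raw(2))

  entries <- c(
    entry(256L, 4L, 1L, u32le(w)),
    entry(257L, 4L, 1L, u32le(h)),
    entry(258L, 3L, 3L, u32le(bps_off)),
    entry(259L, 3L, 1L, short_val(1L)),       # no compression
    entry(262L, 3L, 1L, short_val(2L)),       # RGB
    entry(273L, 4L, 1L, u32le(data_off)),
    entry(277L, 3L, 1L, short_val(3L)),
    entry(278L, 4L, 1L, u32le(h)),
    entry(279L, 4L, 1L, u32le(nbytes)),
    entry(282L, 5L, 1L, u32le(xres_off)),
    entry(283L, 5L, 1L, u32le(yres_off)),
    entry(296L, 3L, 1L, short_val(2L))        # inch
  )

  res_num <- as.integer(round(ppi * 10000))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(u16le(42L), con)
  writeBin(u32le(ifd_off), con)
  writeBin(u16le(n_entries), con)
  writeBin(entries, con)
  writeBin(u32le(0L), con)                    # no next IFD
  writeBin(u16le(c(8L, 8L, 8L)), con)         # BitsPerSample
  writeBin(u32le(c(res_num, 10000L)), con)    # XResolution
  writeBin(u32le(c(res_num, 10000L)), con)    # YResolution
  # strip data: per-pixel RGB, row-major
  writeBin(as.raw(as.vector(aperm(img, c(3L, 2L, 1L)))), con)
  invisible(path)
}

# read `n` unsigned integers of `size` bytes; returns NA on short read
read_uint <- function(con, n, size, endian) {
  v <- readBin(con, integer(), n = n, size = size, endian = endian,
               signed = size >= 4)  # 4-byte reads come back signed; fixed below
  if (length(v) < n) return(rep(NA_real_, n))
  v <- as.numeric(v)
  v[v < 0] <- v[v < 0] + 4294967296
  v
}

#' Validate the structure of a TIFF file
#'
#' Checks the byte-order mark (`II`/`MM`), the magic number 42, that the IFD
#' chain is walkable without cycles, that the required baseline tags are
#' present (ImageWidth, ImageLength, BitsPerSample,
#' PhotometricInterpretation, strip offsets and byte counts), and that every
#' strip lies inside the file. Resolution tags are extracted when readable.
#'
#' @param path TIFF file path.
#' @return a list with `well_formed`, `valid`, `width`, `height`, `ppi`
#'   (NA when absent) and a character vector `issues`.
#' @export
validate_tiff_structure <- function(path) {
  out <- list(well_formed = FALSE, valid = FALSE,
              width = NA_real_, height = NA_real_, ppi = NA_real_,
              issues = character())
  fail <- function(out, msg) { out$issues <- c(out$issues, msg); out }
  if (!file.exists(path)) return(fail(out, "io: file not found"))
  fsize <- file.info(path)$size
  con <- tryCatch(file(path, "rb"), error = function(e) NULL)
  if (is.null(con)) return(fail(out, "io: cannot open"))
  on.exit(close(con))

  bom <- rawToChar(readBin(con, raw(), 2))
  endian <- switch(bom, II = "little", MM = "big", NA_character_)
  if (is.na(endian)) return(fail(out, "bad byte order mark"))
  magic <- read_uint(con, 1, 2, endian)
  if (is.na(magic) || magic != 42) return(fail(out, "bad magic number"))
  ifd_off <- read_uint(con, 1, 4, endian)
  if (is.na(ifd_off) || ifd_off < 8 || ifd_off >= fsize) {
    return(fail(out, "IFD offset out of file"))
  }

  tags <- list()
  seen <- numeric()
  n_ifd <- 0L
  while (!is.na(ifd_off) && ifd_off != 0) {
    if (ifd_off %in% seen) return(fail(out, "IFD cycle"))
    if (n_ifd >= 32L) return(fail(out, "IFD chain too long"))
    if (ifd_off + 2 > fsize) return(fail(out, "IFD offset out of file"))
    seen <- c(seen, ifd_off)
    n_ifd <- n_ifd + 1L
    seek(con, ifd_off)
    n_entries <- read_uint(con, 1, 2, endian)
    if (is.na(n_entries) || n_entries < 1 || n_entries > 4096) {
      return(fail(out, "implausible IFD entry count"))
    }
    if (ifd_off + 2 + n_entries * 12 + 4 > fsize) {
      return(fail(out, "IFD truncated"))
    }
    prev_tag <- -1
    for (i in seq_len(n_entries)) {
      seek(con, ifd_off + 2 + (i - 1) * 12)
      tag   <- read_uint(con, 1, 2, endian)
      type  <- read_uint(con, 1, 2, endian)
      count <- read_uint(con, 1, 4, endian)
      val_pos <- ifd_off + 2 + (i - 1) * 12 + 8
      if (tag <= prev_tag) out$issues <- c(out$issues, "tags not sorted")
      prev_tag <- tag
      type_size <- c(1, 1, 2, 4, 8)[type]
      if (is.na(type_size)) next  # unknown type: skip, per spec readers must
      total <- type_size * count
      if (total > 4) {
        off <- read_uint(con, 1, 4, endian)
        if (is.na(off) || off + total > fsize) {
          out$issues <- c(out$issues,
                          sprintf("tag %d value offset_out_of_file", tag))
          next
        }
        seek(con, off)
      } else {
        seek(con, val_pos)
      }
      vals <- switch(as.character(type),
        "1" = read_uint(con, count, 1, endian),
        "2" = NA_real_,
        "3" = read_uint(con, count, 2, endian),
        "4" = read_uint(con, count, 4, endian),
        "5" = {
          nd <- read_uint(con, 2 * count, 4, endian)
          nd[seq(1, 2 * count, 2)] / nd[seq(2, 2 * count, 2)]
        },
        NA_real_)
      if (n_ifd == 1L) tags[[as.character(tag)]] <- vals
    }
    seek(con, ifd_off + 2 + n_entries * 12)
    ifd_off <- read_uint(con, 1, 4, endian)
    if (is.na(ifd_off)) return(fail(out, "IFD chain truncated"))
    if (ifd_off != 0 && ifd_off >= fsize) return(fail(out, "next IFD offset out of file"))
  }
  out$well_formed <- TRUE

  tg <- function(id) tags[[as.character(id)]]
  out$width  <- (tg(256L) %||% NA_real_)[1]
  out$height <- (tg(257L) %||% NA_real_)[1]
  unit <- (tg(296L) %||% 2)[1]
  xres <- (tg(282L) %||% NA_real_)[1]
  if (!is.na(xres)) {
    out$ppi <- round(if (!is.na(unit) && unit == 3) xres * 2.54 else xres, 4)
  }

  required <- c(256L, 257L, 258L, 262L, 273L, 279L)
  missing <- required[!vapply(required, function(t) !is.null(tg(t)), logical(1))]
  if (length(missing)) {
    out$issues <- c(out$issues,
                    paste("missing required tags:", paste(missing, collapse = " ")))
  }
  offs <- tg(273L); cnts <- tg(279L)
  if (!is.null(offs) && !is.null(cnts)) {
    if (length(offs) != length(cnts)) {
      out$issues <- c(out$issues, "strip offset/count length mismatch")
    } else if (any(is.na(offs)) || any(is.na(cnts)) ||
               any(offs + cnts > fsize)) {
      out$issues <- c(out$issues, "strip data offset_out_of_file")
    }
  }
  out$valid <- out$well_formed && length(out$issues) == 0L
  out
}
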
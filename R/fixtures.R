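# Synthetic herbarium-sheet fixtures: rendered sheet images carrying the
# five required layout elements (colour chart, scale bar, labels, barcode,
# institution name), configurable defect injection, a batch manifest, and
# machine-readable ground truth. Realism is a non-goal; deterministic,
# detectable defects are the goal.

#' Specification of a synthetic herbarium sheet
#'
#' @param sheet_width_cm,sheet_height_cm physical sheet size.
#' @param ppi capture resolution in pixels per inch; rendered pixel
#'   dimensions are `round(cm / 2.54 * ppi)`.
#' @param barcode_payload accession barcode text.
#' @param barcode_symbology `"code128"` or `"upca"`.
#' @param background_tone 8-bit background level.
#' @param white_level,black_level levels rendered into the chart's white
#'   and black patches; defaults sit inside the accepted exposure bands.
#' @return list of class `sheet_spec`.
#' @export
sheet_spec <- function(sheet_width_cm = 26, sheet_height_cm = 42, ppi = 450,
                       barcode_payload = "BR0000008378064",
                       barcode_symbology = c("code128", "upca"),
                       background_tone = 235L,
                       white_level = 240L, black_level = 15L) {
  structure(list(
    sheet_width_cm = sheet_width_cm, sheet_height_cm = sheet_height_cm,
    ppi = ppi, barcode_payload = barcode_payload,
    barcode_symbology = match.arg(barcode_symbology),
    background_tone = as.integer(background_tone),
    white_level = as.integer(white_level),
    black_level = as.integer(black_level)
  ), class = "sheet_spec")
}

#' Defect injection specification
#'
#' All defects are off by default; each field enables one injected problem
#' with ground-truth bookkeeping.
#'
#' @param overexpose_white_to,underexpose_white_to optional 8-bit level
#'   forced onto the chart's white patch.
#' @param overexpose_black_to,underexpose_black_to same for the black patch.
#' @param crop_mode `"none"`, `"under_crop"` (margin-padded frame, larger
#'   file) or `"over_crop"` (frame truncated into the chart and barcode,
#'   smaller file).
#' @param corrupt_bytes number of byte flips applied after the manifest
#'   hash is recorded, so fixity checks have something to catch.
#' @param misname_as optional wrong filename for the written file.
#' @param duplicate_of optional 1-based index of another image in the same
#'   batch; the file is written as a byte-identical copy of that image.
#' @param extra_barcode_payload optional second barcode (multi-specimen
#'   sheet).
#' @return list of class `defect_spec`.
#' @export
defect_spec <- function(overexpose_white_to = NULL, underexpose_white_to = NULL,
                        overexpose_black_to = NULL, underexpose_black_to = NULL,
                        crop_mode = c("none", "under_crop", "over_crop"),
                        corrupt_bytes = 0L, misname_as = NULL,
                        duplicate_of = NULL, extra_barcode_payload = NULL) {
  structure(list(
    overexpose_white_to = overexpose_white_to,
    underexpose_white_to = underexpose_white_to,
    overexpose_black_to = overexpose_black_to,
    underexpose_black_to = underexpose_black_to,
    crop_mode = match.arg(crop_mode),
    corrupt_bytes = as.integer(corrupt_bytes),
    misname_as = misname_as,
    duplicate_of = duplicate_of,
    extra_barcode_payload = extra_barcode_payload
  ), class = "defect_spec")
}

fill_rect <- function(img, r, rgb) {
  if (is.null(rect_intersect(r, rect(0, 0, ncol(img[, , 1]), nrow(img[, , 1])))))
    return(img)
  rr <- rect_intersect(r, rect(0, 0, dim(img)[2], dim(img)[1]))
  for (ch in 1:3) img[rect_rows(rr), rect_cols(rr), ch] <- as.integer(rgb[ch])
  img
}

# reference colour patches rendered into the chart (sRGB)
CHART_COLOUR_REFS <- list(
  red    = c(175L, 54L, 60L),
  green  = c(70L, 148L, 73L),
  blue   = c(56L, 61L, 150L),
  yellow = c(231L, 199L, 31L)
)

# compute the default element layout for a w x h frame; the barcode box is
# sized from the rendered barcode matrix
default_layout <- function(w, h, bc_dim, bc2_dim = NULL) {
  fx <- function(f) as.integer(round(f * w))
  fy <- function(f) as.integer(round(f * h))
  chart <- rect(fx(0.62), fy(0.02), fx(0.95), fy(0.14))
  boxes <- list(
    institution_name = rect(fx(0.05), fy(0.02), fx(0.55), fy(0.07)),
    colour_chart = chart,
    labels = rect(fx(0.55), fy(0.70), fx(0.92), fy(0.86)),
    scale_bar = rect(fx(0.05), fy(0.90), fx(0.45), fy(0.93)),
    barcode = rect(fx(0.95) - bc_dim[2], fy(0.98) - bc_dim[1],
                   fx(0.95), fy(0.98))
  )
  if (!is.null(bc2_dim)) {
    boxes$barcode2 <- rect(fx(0.05), fy(0.98) - bc2_dim[1],
                           fx(0.05) + bc2_dim[2], fy(0.98))
  }
  # chart interior: top row white/black patches, bottom row colour patches
  inner <- rect_erode(chart, 0.06)
  midx <- (inner$x0 + inner$x1) %/% 2L
  midy <- (inner$y0 + inner$y1) %/% 2L
  cw <- (inner$x1 - inner$x0) %/% 4L
  layout <- list(
    chart = chart,
    white = rect(inner$x0, inner$y0, midx, midy),
    black = rect(midx, inner$y0, inner$x1, midy),
    colours = lapply(seq_along(CHART_COLOUR_REFS), function(i) {
      rect(inner$x0 + (i - 1L) * cw, midy, inner$x0 + i * cw, inner$y1)
    })
  )
  names(layout$colours) <- names(CHART_COLOUR_REFS)
  list(boxes = boxes, chart = layout)
}

draw_specimen <- function(img, w, h) {
  # procedural branch strokes in the central area; darkness only, so the
  # transition density stays far below barcode levels
  n_strokes <- 30L
  for (s in seq_len(n_strokes)) {
    x <- stats::runif(1, 0.10 * w, 0.50 * w)
    y <- stats::runif(1, 0.18 * h, 0.82 * h)
    ang <- stats::runif(1, 0, 2 * pi)
    len <- as.integer(stats::runif(1, 0.05, 0.25) * h)
    col <- c(60L, 90L, 45L) + as.integer(stats::runif(3, -15, 15))
    t <- seq_len(len)
    ang_t <- ang + cumsum(stats::rnorm(len, 0, 0.05))
    xs <- pmin(as.integer(0.55 * w), pmax(1L, as.integer(round(x + cumsum(cos(ang_t))))))
    ys <- pmin(as.integer(0.86 * h), pmax(1L, as.integer(round(y + cumsum(sin(ang_t))))))
    for (ch in 1:3) img[cbind(ys, xs, ch)] <- col[ch]
  }
  img
}

#' Render one synthetic herbarium sheet
#'
#' Draws the five required layout elements on a toned background, injects
#' the requested defects, writes a baseline TIFF with resolution metadata
#' set to `spec$ppi`, and returns the ground truth of what was drawn.
#' Identical `(spec, defects, seed)` yield byte-identical files.
#'
#' @param spec a [sheet_spec()].
#' @param path output TIFF path.
#' @param defects a [defect_spec()].
#' @param seed integer seed controlling the procedural specimen and noise.
#' @return invisible ground-truth record (list): filename, payloads,
#'   element boxes, chart layout, injected defects, md5 at write time,
#'   pixel dimensions and ppi.
#' @export
render_sheet <- function(spec, path, defects = defect_spec(), seed = 1L) {
  w <- as.integer(round(spec$sheet_width_cm / 2.54 * spec$ppi))
  h <- as.integer(round(spec$sheet_height_cm / 2.54 * spec$ppi))
  if (w < 64L || h < 64L) {
    stop("layout error: sheet renders to a degenerate frame (", w, "x", h, ")")
  }
  set.seed(derive_seed(seed, 0L))

  # barcode matrices first: their size fixes the barcode element box
  n_payloads <- 1L + !is.null(defects$extra_barcode_payload)
  mk_bc <- function(payload) {
    probe <- render_barcode(payload, spec$barcode_symbology, module_px = 1L)
    mpx <- max(1L, as.integer(floor(0.32 * w / ncol(probe))))
    render_barcode(payload, spec$barcode_symbology, module_px = mpx,
                   height_px = max(16L, as.integer(round(0.035 * h))))
  }
  bc <- mk_bc(spec$barcode_payload)
  bc2 <- if (n_payloads == 2L) mk_bc(defects$extra_barcode_payload)
  lay <- default_layout(w, h, dim(bc), if (!is.null(bc2)) dim(bc2))
  boxes <- lay$boxes
  for (b in boxes) {
    if (!rect_inside(b, w, h)) stop("layout error: element box outside frame")
  }
  nm <- names(boxes)
  for (i in seq_along(boxes)) {
    for (j in seq_len(i - 1L)) {
      if (!is.null(rect_intersect(boxes[[i]], boxes[[j]]))) {
        stop("layout error: overlapping element boxes ", nm[j], "/", nm[i])
      }
    }
  }

  img <- array(spec$background_tone, dim = c(h, w, 3L))
  storage.mode(img) <- "integer"
  # gentle deterministic background texture (kept off the chart patches)
  noise <- matrix(as.integer(round(stats::rnorm(h * w, 0, 2))), h, w)
  for (ch in 1:3) img[, , ch] <- pmax(0L, pmin(255L, img[, , ch] + noise))

  img <- draw_specimen(img, w, h)

  # institution name: dark band with light lettering strokes
  inb <- boxes$institution_name
  img <- fill_rect(img, inb, c(250L, 250L, 248L))
  stripe <- rect_erode(inb, 0.25)
  img <- fill_rect(img, stripe, c(40L, 40L, 60L))

  # colour chart
  ch_lay <- lay$chart
  img <- fill_rect(img, ch_lay$chart, c(120L, 120L, 120L))
  img <- fill_rect(img, ch_lay$white, rep(spec$white_level, 3L))
  img <- fill_rect(img, ch_lay$black, rep(spec$black_level, 3L))
  for (cn in names(ch_lay$colours)) {
    img <- fill_rect(img, ch_lay$colours[[cn]], CHART_COLOUR_REFS[[cn]])
  }

  # labels: paper block with solid text-line strokes
  lb <- boxes$labels
  img <- fill_rect(img, lb, c(248L, 246L, 240L))
  n_lines <- 5L
  lh <- rect_height(lb)
  for (k in seq_len(n_lines)) {
    y0 <- lb$y0 + as.integer(round(lh * (k - 0.5) / (n_lines + 0.5)))
    line_w <- as.integer(round(rect_width(lb) * stats::runif(1, 0.4, 0.8)))
    img <- fill_rect(img, rect(lb$x0 + 8L, y0, lb$x0 + 8L + line_w,
                               y0 + max(2L, lh %/% 20L)), c(30L, 30L, 30L))
  }

  # scale bar: coarse alternating blocks (10 blocks over the bar)
  sb <- boxes$scale_bar
  bw <- rect_width(sb) %/% 10L
  for (k in 0:9) {
    col <- if (k %% 2 == 0) c(20L, 20L, 20L) else c(245L, 245L, 245L)
    img <- fill_rect(img, rect(sb$x0 + k * bw, sb$y0, sb$x0 + (k + 1L) * bw,
                               sb$y1), col)
  }

  place_barcode <- function(img, m, box) {
    sub <- 255L - m * 255L  # 1 = bar -> dark
    for (ch in 1:3) img[rect_rows(box), rect_cols(box), ch] <-
        as.integer(sub[seq_len(rect_height(box)), seq_len(rect_width(box))])
    img
  }
  img <- place_barcode(img, bc, boxes$barcode)
  if (!is.null(bc2)) img <- place_barcode(img, bc2, boxes$barcode2)

  # exposure defects: force patch interiors
  force_patch <- function(img, box, level) {
    if (is.null(level)) return(img)
    fill_rect(img, box, rep(as.integer(level), 3L))
  }
  img <- force_patch(img, ch_lay$white, defects$overexpose_white_to)
  img <- force_patch(img, ch_lay$white, defects$underexpose_white_to)
  img <- force_patch(img, ch_lay$black, defects$overexpose_black_to)
  img <- force_patch(img, ch_lay$black, defects$underexpose_black_to)

  shift_rect <- function(r, dx, dy) rect(r$x0 + dx, r$y0 + dy, r$x1 + dx, r$y1 + dy)
  shift_all <- function(lst, dx, dy) lapply(lst, function(r) shift_rect(r, dx, dy))
  if (defects$crop_mode == "under_crop") {
    pad_x <- as.integer(round(0.08 * w)); pad_y <- as.integer(round(0.08 * h))
    big <- array(spec$background_tone, dim = c(h + 2L * pad_y, w + 2L * pad_x, 3L))
    storage.mode(big) <- "integer"
    big[pad_y + seq_len(h), pad_x + seq_len(w), ] <- img
    img <- big
    boxes <- shift_all(boxes, pad_x, pad_y)
    ch_lay$chart <- shift_rect(ch_lay$chart, pad_x, pad_y)
    ch_lay$white <- shift_rect(ch_lay$white, pad_x, pad_y)
    ch_lay$black <- shift_rect(ch_lay$black, pad_x, pad_y)
    ch_lay$colours <- shift_all(ch_lay$colours, pad_x, pad_y)
  } else if (defects$crop_mode == "over_crop") {
    cut_x <- as.integer(round(0.10 * w)); cut_y <- as.integer(round(0.10 * h))
    img <- img[(cut_y + 1L):(h - cut_y), (cut_x + 1L):(w - cut_x), , drop = FALSE]
    boxes <- shift_all(boxes, -cut_x, -cut_y)
    ch_lay$chart <- shift_rect(ch_lay$chart, -cut_x, -cut_y)
    ch_lay$white <- shift_rect(ch_lay$white, -cut_x, -cut_y)
    ch_lay$black <- shift_rect(ch_lay$black, -cut_x, -cut_y)
    ch_lay$colours <- shift_all(ch_lay$colours, -cut_x, -cut_y)
  }

  write_baseline_tiff(img, path, spec$ppi)
  gt <- list(
    filename = basename(path),
    payloads = c(spec$barcode_payload, defects$extra_barcode_payload),
    symbology = spec$barcode_symbology,
    element_boxes = boxes,
    chart = c(ch_lay,
              list(white_level = spec$white_level,
                   black_level = spec$black_level,
                   colour_refs = CHART_COLOUR_REFS)),
    defects = defects,
    md5 = file_md5(path),
    width_px = dim(img)[2], height_px = dim(img)[1], ppi = spec$ppi,
    seed = seed
  )
  invisible(gt)
}

#' Flip bytes in a file
#'
#' Simulates post-creation corruption: exactly `n_bytes` distinct byte
#' positions are bit-inverted in place; the file size is unchanged.
#'
#' @param path existing, non-empty file.
#' @param n_bytes number of byte positions to alter (>= 1).
#' @param seed RNG seed for position choice.
#' @return `path`, invisibly.
#' @export
corrupt_file <- function(path, n_bytes = 1L, seed = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  size <- file.info(path)$size
  if (size < 1) stop("cannot corrupt an empty file")
  if (n_bytes < 1) stop("n_bytes must be >= 1")
  n_bytes <- min(as.integer(n_bytes), size)
  set.seed(derive_seed(seed, 7L))
  pos <- sample.int(size, n_bytes)
  con <- file(path, "r+b")
  on.exit(close(con))
  for (p in pos) {
    seek(con, p - 1L)
    b <- readBin(con, raw(), 1L)
    seek(con, p - 1L, rw = "write")
    writeBin(xor(b, as.raw(0xFF)), con)
  }
  invisible(path)
}

MANIFEST_HEADER <- c("filename", "time", "operator", "batch_number", "md5", "station")

#' Write / read a batch manifest
#'
#' The manifest is the per-batch metadata file the audit trail consumes:
#' one row per master file with columns exactly
#' `filename,time,operator,batch_number,md5,station`.
#'
#' @param manifest data.frame with the manifest columns.
#' @param path CSV path.
#' @return `write_manifest`: `path` invisibly; `read_manifest`: the
#'   manifest data.frame (header is verified).
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(identical(names(manifest), MANIFEST_HEADER))
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(m), MANIFEST_HEADER)) {
    stop("manifest header must be exactly: ", paste(MANIFEST_HEADER, collapse = ","))
  }
  if (anyDuplicated(m$filename)) stop("manifest filenames are not unique")
  m
}

#' Generate a synthetic batch: images, manifest, ground truth
#'
#' Renders `n` sheets into `out_dir`, assigns sequential barcodes, injects
#' defects at the given per-class probabilities, writes the batch manifest
#' (MD5s recorded before any corruption is applied, so corruption is
#' detectable downstream) and a ground-truth JSON.
#'
#' @param out_dir batch directory (created).
#' @param n number of sheets (>= 1).
#' @param batch_number integer batch identifier.
#' @param defect_rates named list of probabilities in `[0, 1]` over the
#'   classes `overexpose_white`, `underexpose_white`, `overexpose_black`,
#'   `underexpose_black`, `under_crop`, `over_crop`, `corrupt`, `misname`,
#'   `duplicate`, `extra_barcode`.
#' @param seed master seed; every image derives its own sub-seed.
#' @param spec the [sheet_spec()] template (payload is replaced per image).
#' @return list with `dir`, `manifest`, `ground_truth`, `files`, invisibly.
#' @export
make_batch <- function(out_dir, n, batch_number = 1L,
                       defect_rates = list(), seed = 1L,
                       spec = sheet_spec()) {
  stopifnot(n >= 1)
  classes <- c("overexpose_white", "underexpose_white", "overexpose_black",
               "underexpose_black", "under_crop", "over_crop", "corrupt",
               "misname", "duplicate", "extra_barcode")
  bad <- setdiff(names(defect_rates), classes)
  if (length(bad)) stop("unknown defect classes: ", paste(bad, collapse = ", "))
  rates <- stats::setNames(rep(0, length(classes)), classes)
  rates[names(defect_rates)] <- unlist(defect_rates)
  if (any(rates < 0 | rates > 1)) stop("defect rates must be in [0, 1]")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digits <- nchar(sub("^[A-Za-z]+", "", spec$barcode_payload))
  prefix <- sub("[0-9]+$", "", spec$barcode_payload)
  payload_of <- function(i) {
    paste0(prefix, formatC(batch_number * 100000 + i, width = digits, flag = "0", format = "d"))
  }

  set.seed(derive_seed(seed, 999L))
  draws <- matrix(stats::runif(n * length(classes)), n, length(classes),
                  dimnames = list(NULL, classes))
  hit <- sweep(draws, 2L, rates, "<")
  # duplicates need a source strictly earlier in the batch
  hit[1L, "duplicate"] <- FALSE

  gt <- vector("list", n)
  rows <- vector("list", n)
  files <- character(n)
  for (i in seq_len(n)) {
    payload <- payload_of(i)
    dup_src <- if (hit[i, "duplicate"]) sample.int(i - 1L, 1L) else NULL
    def <- defect_spec(
      overexpose_white_to = if (hit[i, "overexpose_white"]) 253L,
      underexpose_white_to = if (hit[i, "underexpose_white"]) 215L,
      overexpose_black_to = if (hit[i, "overexpose_black"]) 25L,
      underexpose_black_to = if (hit[i, "underexpose_black"]) 6L,
      crop_mode = if (hit[i, "over_crop"]) "over_crop"
                  else if (hit[i, "under_crop"]) "under_crop" else "none",
      corrupt_bytes = if (hit[i, "corrupt"]) 3L else 0L,
      misname_as = if (hit[i, "misname"])
        paste0(prefix, formatC(batch_number * 100000 + 90000 + i,
                               width = digits, flag = "0", format = "d"), ".tif"),
      duplicate_of = dup_src,
      extra_barcode_payload = if (hit[i, "extra_barcode"])
        paste0(prefix, formatC(batch_number * 100000 + 80000 + i,
                               width = digits, flag = "0", format = "d"))
    )
    fname <- def$misname_as %||% paste0(payload, ".tif")
    fpath <- file.path(out_dir, fname)
    ispec <- spec
    ispec$barcode_payload <- payload
    if (!is.null(dup_src)) {
      file.copy(file.path(out_dir, files[dup_src]), fpath, overwrite = TRUE)
      g <- gt[[dup_src]]
      g$filename <- fname
      g$defects <- def
      g$md5 <- file_md5(fpath)
      gt[[i]] <- g
    } else {
      gt[[i]] <- render_sheet(ispec, fpath, def, seed = derive_seed(seed, i))
    }
    files[i] <- fname
    rows[[i]] <- data.frame(
      filename = fname,
      time = format(as.POSIXct("2026-01-05 08:00:00", tz = "UTC") + i,
                    "%Y-%m-%dT%H:%M:%SZ"),
      operator = "op1",
      batch_number = as.character(batch_number),
      md5 = gt[[i]]$md5,
      station = "st1",
      stringsAsFactors = FALSE
    )
  }
  # corruption happens after the manifest hash is recorded
  for (i in seq_len(n)) {
    if (gt[[i]]$defects$corrupt_bytes > 0L) {
      corrupt_file(file.path(out_dir, files[i]), gt[[i]]$defects$corrupt_bytes,
                   seed = derive_seed(seed, 5000L + i))
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  write_ground_truth(gt, file.path(out_dir, "groundtruth.json"))
  invisible(list(dir = out_dir, manifest = manifest, ground_truth = gt,
                 files = files))
}

#' Write / read batch ground truth
#'
#' One immutable JSON record per generated image: true payloads, element
#' boxes, injected defects, MD5 at write time, dimensions and PPI.
#'
#' @param gt list of ground-truth records from [render_sheet()].
#' @param path JSON path.
#' @export
write_ground_truth <- function(gt, path) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(lapply(gt, strip), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path)
  relist_rect <- function(r) rect(r$x0, r$y0, r$x1, r$y1)
  lapply(gt, function(g) {
    g$element_boxes <- lapply(g$element_boxes, relist_rect)
    g$chart$chart <- relist_rect(g$chart$chart)
    g$chart$white <- relist_rect(g$chart$white)
    g$chart$black <- relist_rect(g$chart$black)
    g$chart$colours <- lapply(g$chart$colours, relist_rect)
    g$defects <- do.call(defect_spec, c(
      g$defects[setdiff(names(g$defects), "crop_mode")],
      list(crop_mode = g$defects$crop_mode %||% "none")))
    g
  })
}

#' Configuration matched to a sheet specification
#'
#' Convenience for working at reduced fixture scales: derives `master_ppi`,
#' sheet dimensions and the master size window (nominal uncompressed size
#' +/- 15%) from a [sheet_spec()], leaving all QC thresholds at their
#' defaults.
#'
#' @param spec a [sheet_spec()].
#' @param ... further overrides passed to [herbqc_config()].
#' @return a `herbqc_config`.
#' @export
config_for_sheet <- function(spec, ...) {
  w <- round(spec$sheet_width_cm / 2.54 * spec$ppi)
  h <- round(spec$sheet_height_cm / 2.54 * spec$ppi)
  nominal_mb <- (w * h * 3) / 1e6
  herbqc_config(master_ppi = spec$ppi,
                derivative_ppi = spec$ppi * 420 / 450,
                sheet_width_cm = spec$sheet_width_cm,
                sheet_height_cm = spec$sheet_height_cm,
                min_master_mb = nominal_mb * 0.85,
                max_master_mb = nominal_mb * 1.15,
                ...)
}
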
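# Visual-QC criteria as computations: colour-chart patch exposure
# classification against the printed 8-bit limits, Delta E (CIE76) colour
# accuracy, layout-element presence, the two-stage inspection sampling
# schedule, and the batch accept/reject rule. Focus and contrast remain
# human-in-the-loop: the sampler emits a worklist, it does not score them.

#' Mean patch levels from the colour chart
#'
#' Computes the arithmetic mean of the rounded Rec.709 luma over the white
#' and black patch interiors, each eroded by 10% per side to avoid edge
#' bleed.
#'
#' @param image image array or file path.
#' @param layout chart layout: list with rectangles `white` and `black`
#'   (and optionally `colours` + `colour_refs`), as stored in fixture
#'   ground truth (`$chart`) or built by hand.
#' @return list of class `exposure_reading`: `white_mean`, `black_mean`,
#'   patch boxes used, `n_pixels` per patch; or a `bad_crop` finding in
#'   `$findings` when a patch falls (partly) outside the frame.
#' @export
extract_patch_means <- function(image, layout) {
  if (is.character(image)) image <- read_image(image)
  g <- luma(image)
  h <- nrow(g); w <- ncol(g)
  mean_of <- function(box) {
    inner <- rect_erode(box, 0.10)
    if (!rect_inside(inner, w, h) || rect_area(inner) < 1) return(NULL)
    list(mean = mean(g[rect_rows(inner), rect_cols(inner)]),
         n = rect_area(inner), box = inner)
  }
  wm <- mean_of(layout$white)
  bm <- mean_of(layout$black)
  if (is.null(wm) || is.null(bm)) {
    return(list(findings = finding("", "visual_qc", "bad_crop", "reject_image",
                                   "chart patch outside image frame")))
  }
  structure(list(white_mean = wm$mean, black_mean = bm$mean,
                 white_box = wm$box, black_box = bm$box,
                 n_pixels = c(white = wm$n, black = bm$n),
                 findings = no_findings()),
            class = "exposure_reading")
}

#' Classify patch exposure against the chart limits
#'
#' White patch: mean strictly above `white_over` (250) is overexposed,
#' strictly below `white_under` (225) underexposed. Black patch: strictly
#' above `black_over` (18) overexposed, strictly below `black_under` (12)
#' underexposed. The boundary values themselves pass. The image is
#' `vqc_ok` iff both patches are `ok`.
#'
#' @param reading an `exposure_reading` (or list with `white_mean`,
#'   `black_mean`).
#' @param config a [herbqc_config()].
#' @return list with `white`, `black` (each `ok`/`overexposed`/
#'   `underexposed`), `state` (`vqc_ok`/`vqc_error`) and `findings`.
#' @examples
#' classify_exposure(list(white_mean = 250, black_mean = 18))$state  # vqc_ok
#' classify_exposure(list(white_mean = 251, black_mean = 15))$state  # vqc_error
#' @export
classify_exposure <- function(reading, config = herbqc_config()) {
  cls <- function(mean, over, under) {
    if (mean > over) "overexposed" else if (mean < under) "underexposed" else "ok"
  }
  white <- cls(reading$white_mean, config$white_over, config$white_under)
  black <- cls(reading$black_mean, config$black_over, config$black_under)
  findings <- no_findings()
  add <- function(patch, class, mean) {
    finding("", "visual_qc",
            if (class == "overexposed") "overexposed" else "underexposed",
            "reject_image", sprintf("%s patch mean %.2f", patch, mean))
  }
  if (white != "ok") findings <- rbind(findings, add("white", white, reading$white_mean))
  if (black != "ok") findings <- rbind(findings, add("black", black, reading$black_mean))
  list(white = white, black = black,
       state = if (white == "ok" && black == "ok") "vqc_ok" else "vqc_error",
       findings = findings)
}

# sRGB (D50-adapted, ICC matrix) -> CIE L*a*b*
srgb_to_lab <- function(rgb8) {
  v <- rgb8 / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4360747, 0.3850649, 0.1430804,
                0.2225045, 0.7168786, 0.0606094,
                0.0139322, 0.0971045, 0.7141733), 3, 3, byrow = TRUE)
  xyz <- as.vector(m %*% lin)
  wp <- c(0.96422, 1.0, 0.82521)  # D50
  t <- xyz / wp
  d <- 6 / 29
  f <- ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  c(L = 116 * f[2] - 16, a = 500 * (f[1] - f[2]), b = 200 * (f[2] - f[3]))
}

#' Delta E (CIE76) between a measured sRGB colour and a reference Lab
#'
#' The measured 8-bit sRGB triple is linearised, converted to XYZ with the
#' D50-adapted sRGB matrix and then to CIE L*a*b* (D50 white point); the
#' returned value is the CIE76 Euclidean distance to `reference_lab`.
#' Chart-level colour accuracy passes when the mean Delta E over the
#' reference patches is below 5.
#'
#' @param measured_rgb numeric length-3, 8-bit sRGB.
#' @param reference_lab numeric length-3, CIE L*a*b*.
#' @return Delta E value (>= 0).
#' @examples
#' delta_e(c(0, 0, 0), c(100, 0, 0))  # black vs white: 100
#' @export
delta_e <- function(measured_rgb, reference_lab) {
  lab <- srgb_to_lab(as.numeric(measured_rgb))
  sqrt(sum((lab - as.numeric(reference_lab))^2))
}

#' Colour accuracy of the chart's reference patches
#'
#' Measures the mean sRGB of each coloured patch and its Delta E against
#' the layout's reference colours.
#'
#' @param image image array or path.
#' @param layout chart layout with `colours` rectangles and `colour_refs`
#'   sRGB triples (Lab references are derived from them).
#' @param max_mean_delta_e pass threshold on the mean (default 5).
#' @return list with `delta_e` (named per patch), `mean_delta_e`, `pass`.
#' @export
check_colour_accuracy <- function(image, layout, max_mean_delta_e = 5) {
  if (is.character(image)) image <- read_image(image)
  de <- vapply(names(layout$colours), function(cn) {
    box <- rect_erode(layout$colours[[cn]], 0.10)
    px <- sapply(1:3, function(ch) mean(image[rect_rows(box), rect_cols(box), ch]))
    ref <- srgb_to_lab(as.numeric(unlist(layout$colour_refs[[cn]])))
    delta_e(px, ref)
  }, numeric(1))
  list(delta_e = de, mean_delta_e = mean(de), pass = mean(de) < max_mean_delta_e)
}

REQUIRED_ELEMENTS <- c("colour_chart", "scale_bar", "labels", "barcode",
                       "institution_name")

#' Presence of the five required layout elements
#'
#' Checks one boolean per required class (colour chart, scale bar, labels,
#' barcode, institution name). Input is either a ground-truth/detection
#' list of element boxes or a character vector of present classes; a
#' combined element may be declared for several classes (e.g.
#' `"colour_chart+scale_bar"`) and counts for each constituent.
#'
#' @param elements named list of element boxes, or character vector of
#'   class names (possibly `+`-combined).
#' @return list with `present` (named logical over the five classes),
#'   `n_present`, `complete` and `findings` (flag_manual per absent class).
#' @export
check_layout_elements <- function(elements) {
  cls <- if (is.character(elements)) elements else names(elements)
  cls <- unlist(strsplit(cls, "+", fixed = TRUE))
  present <- stats::setNames(REQUIRED_ELEMENTS %in% cls, REQUIRED_ELEMENTS)
  findings <- no_findings()
  for (e in REQUIRED_ELEMENTS[!present]) {
    findings <- rbind(findings,
      finding("", "visual_qc", "bad_crop", "flag_manual",
              paste("required element absent:", e)))
  }
  list(present = present, n_present = sum(present),
       complete = all(present), findings = findings)
}

#' Visual inspection sample for a batch
#'
#' Two-stage schedule: while fewer than `clean_streak_switch` consecutive
#' problem-free batches have accrued, the last of every
#' `sample_initial_every` images (2%) is inspected; afterwards the last of
#' every `sample_steady_every` (1%). Deterministic — inspection at regular
#' intervals locates the point where a persistent fault began. A batch
#' smaller than the interval still gets its final image inspected, so no
#' batch escapes inspection.
#'
#' @param batch_size number of images (>= 1).
#' @param clean_batch_streak consecutive clean batches since the last
#'   detected problem.
#' @param config a [herbqc_config()].
#' @return strictly increasing 1-based image indices.
#' @examples
#' length(select_inspection_sample(500, 3))   # 10 (2%)
#' length(select_inspection_sample(500, 12))  # 5 (1%)
#' @export
select_inspection_sample <- function(batch_size, clean_batch_streak,
                                     config = herbqc_config()) {
  stopifnot(batch_size >= 1)
  k <- if (clean_batch_streak < config$clean_streak_switch) {
    config$sample_initial_every
  } else {
    config$sample_steady_every
  }
  idx <- seq_len(batch_size)[seq_len(batch_size) %% k == 0L]
  if (!length(idx)) idx <- batch_size
  as.integer(idx)
}

#' Batch accept/reject decision
#'
#' The batch is rejected iff the number of distinct images carrying a
#' `reject_image` finding strictly exceeds `batch_reject_pct`% of the
#' batch; exactly 5% is not "more than 5%" and is accepted. Accepted
#' batches proceed with the flagged images removed.
#'
#' @param findings findings data.frame (deduplicated per image internally).
#' @param batch_size number of images in the batch.
#' @param config a [herbqc_config()].
#' @return list with `decision` (`accept`/`reject`), `n_flagged`,
#'   `flagged` (filenames).
#' @examples
#' f <- data.frame(image = sprintf("i%03d", 1:50), sub_task = "x",
#'                 code = "duplicate", severity = "reject_image", detail = "")
#' decide_batch(f, 1000)$decision  # accept: 50/1000 is exactly 5%
#' @export
decide_batch <- function(findings, batch_size, config = herbqc_config()) {
  flagged <- unique(findings$image[findings$severity == "reject_image"])
  flagged <- flagged[nzchar(flagged)]
  n <- length(flagged)
  list(decision = if (n > config$batch_reject_pct / 100 * batch_size)
         "reject" else "accept",
       n_flagged = n, flagged = flagged)
}

#' Update the clean-batch streak
#'
#' Any detected problem (a `vqc_error` or any reject finding in the batch)
#' resets the streak to zero, returning the schedule to the 2% stage;
#' a problem-free batch increments it.
#'
#' @param streak current streak.
#' @param batch_clean logical: did the batch pass without detected
#'   problems?
#' @return updated streak.
#' @export
update_clean_streak <- function(streak, batch_clean) {
  if (isTRUE(batch_clean)) streak + 1L else 0L
}

#' Write the inspection worklist
#'
#' Emits the manual-inspection worklist CSV (index, filename, checks) for
#' the sampled images: focus, cropping, colour, contrast and barcode
#' correspondence are the human checks.
#'
#' @param indices from [select_inspection_sample()].
#' @param filenames batch filenames.
#' @param path CSV path.
#' @export
write_inspection_worklist <- function(indices, filenames, path) {
  utils::write.csv(data.frame(
    index = indices,
    filename = filenames[indices],
    checks = "focus;cropping;colour;contrast;barcode"
  ), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
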
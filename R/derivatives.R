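# Derivative generation: the lossless JPEG 2000 production image and the
# lossy JPEG publishing image derived from each master. Encoding is done by
# the bundled Pillow helper (one subprocess per batch); the JP2 capture
# resolution box is written here so the derivative records its PPI.

herbqc_python <- function() {
  p <- getOption("herbqc.python", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no 'python' found on PATH (needed for JP2/JPEG encoding)")
  p
}

# run the bundled codec helper over a list of tasks; returns list of results
python_codec <- function(tasks) {
  script <- system.file("python", "derivatives.py", package = "herbqc",
                        mustWork = TRUE)
  tf_in  <- tempfile(fileext = ".json")
  tf_out <- tempfile(fileext = ".json")
  on.exit(unlink(c(tf_in, tf_out)))
  jsonlite::write_json(tasks, tf_in, auto_unbox = TRUE)
  status <- system2(herbqc_python(), c(script, tf_in, tf_out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tf_out)) {
    stop("codec helper failed (exit ", status, ")")
  }
  jsonlite::read_json(tf_out)
}

# decode a JP2 file's pixels through the helper
read_jp2_pixels <- function(path) {
  tmp <- tempfile(fileext = ".tif")
  on.exit(unlink(tmp))
  res <- python_codec(list(list(op = "decode", src = path, out = tmp)))
  if (!isTRUE(res[[1]]$ok)) stop("JP2 decode failed: ", res[[1]]$error)
  read_image(tmp)
}

#' Generate the production derivatives for master images
#'
#' For each master, produces the lossless JPEG 2000 derivative (reversible
#' transform, capture resolution recorded as `config$derivative_ppi`) and
#' the lossy JPEG derivative (`config$jpeg_quality`, same PPI). Masters are
#' resampled from `config$master_ppi` to `config$derivative_ppi` by
#' nearest-neighbour before encoding, so the derivative's pixel grid
#' matches its recorded resolution. Filename stems are preserved.
#'
#' @param masters character vector of master TIFF paths.
#' @param out_dir directory receiving the derivatives (created if needed).
#' @param config a [herbqc_config()].
#' @return data.frame with one row per master: `master`, `jp2`, `jpg`,
#'   `jp2_ok`, `jpg_ok`, `error`.
#' @export
generate_derivatives <- function(masters, out_dir, config = herbqc_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stems <- tools::file_path_sans_ext(basename(masters))
  jp2 <- file.path(out_dir, paste0(stems, ".jp2"))
  jpg <- file.path(out_dir, paste0(stems, ".jpg"))
  scale <- config$derivative_ppi / config$master_ppi

  writable <- file.access(out_dir, 2) == 0
  tasks <- list()
  tmp_files <- character()
  prep_err <- rep(NA_character_, length(masters))
  for (i in seq_along(masters)) {
    if (!writable) { prep_err[i] <- "output directory not writable"; next }
    ok <- tryCatch({
      img <- read_image(masters[i])
      if (scale != 1) img <- resample_image(img, scale)
      tmp <- tempfile(fileext = ".tif")
      write_baseline_tiff(img, tmp, config$derivative_ppi)
      tmp_files <- c(tmp_files, tmp)
      tasks[[length(tasks) + 1]] <- list(
        op = "encode", src = tmp, jp2 = jp2[i], jpg = jpg[i],
        quality = config$jpeg_quality, ppi = config$derivative_ppi,
        index = i - 1L)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) prep_err[i] <- ok
  }
  on.exit(unlink(tmp_files))

  enc_err <- rep(NA_character_, length(masters))
  if (length(tasks)) {
    res <- python_codec(tasks)
    for (j in seq_along(res)) {
      i <- tasks[[j]]$index + 1L
      if (!isTRUE(res[[j]]$ok)) enc_err[i] <- res[[j]]$error %||% "encode failed"
    }
  }
  for (i in seq_along(masters)) {
    if (is.na(prep_err[i]) && is.na(enc_err[i]) && file.exists(jp2[i])) {
      jp2_set_resolution(jp2[i], config$derivative_ppi)
    }
  }
  err <- ifelse(!is.na(prep_err), prep_err, enc_err)
  data.frame(
    master = masters, jp2 = jp2, jpg = jpg,
    jp2_ok = is.na(err) & file.exists(jp2),
    jpg_ok = is.na(err) & file.exists(jpg),
    error = err,
    stringsAsFactors = FALSE
  )
}
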
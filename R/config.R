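#' Pipeline configuration
#'
#' Builds the configuration list consumed by every check in the audit trail.
#' Defaults reflect the operating values of the digitisation workflow the
#' package models: `BR` barcode prefix with a 13-digit zero-padded
#' identifier, 450 PPI uncompressed TIFF masters with an 88 MB size floor,
#' 420 PPI derivatives, the 250/225 (white) and 18/12 (black) 8-bit
#' exposure limits, the 2% -> 1% visual inspection schedule switching after
#' 10 clean batches, and the 5% batch rejection threshold.
#'
#' @param ... named overrides for any default listed below.
#'
#' @details Keys and defaults:
#' \describe{
#'   \item{prefix ("BR")}{two-letter filename/barcode prefix.}
#'   \item{digits (13)}{length of the zero-padded numeric identifier.}
#'   \item{extensions (tif, jp2, jpg)}{set extensions, lower case only.}
#'   \item{sheet_width_cm, sheet_height_cm (26, 42)}{nominal sheet size.}
#'   \item{master_ppi (450)}{capture resolution of the master set.}
#'   \item{derivative_ppi (420)}{resolution recorded in both derivatives.}
#'   \item{jpeg_quality (85)}{lossy derivative quality.}
#'   \item{min_master_mb (88)}{master size floor, decimal megabytes; a
#'     master passes only if strictly above this.}
#'   \item{max_master_mb (180)}{master size ceiling.}
#'   \item{dim_tolerance (0.15)}{relative window around the nominal pixel
#'     dimensions implied by sheet size and `master_ppi`.}
#'   \item{white_over (250), white_under (225)}{white patch mean limits;
#'     means strictly above/below are over/underexposed.}
#'   \item{black_over (18), black_under (12)}{black patch mean limits.}
#'   \item{sample_initial_every (50), sample_steady_every (100)}{visual
#'     inspection intervals before and after the clean-streak switch.}
#'   \item{clean_streak_switch (10)}{clean batches needed to move to the
#'     steady (1%) schedule.}
#'   \item{batch_reject_pct (5)}{batch rejected when flagged images exceed
#'     this percentage (strictly).}
#'   \item{md5_spot_every (50)}{fixity spot-check interval over the master
#'     set.}
#' }
#'
#' "MB" is decimal: `min_master_mb = 88` means 88,000,000 bytes.
#'
#' @return a list of class `herbqc_config`.
#' @examples
#' cfg <- herbqc_config()
#' cfg$white_over
#' small <- herbqc_config(master_ppi = 50, min_master_mb = 1)
#' @export
herbqc_config <- function(...) {
  cfg <- list(
    prefix              = "BR",
    digits              = 13L,
    extensions          = c("tif", "jp2", "jpg"),
    sheet_width_cm      = 26,
    sheet_height_cm     = 42,
    master_ppi          = 450,
    derivative_ppi      = 420,
    jpeg_quality        = 85L,
    min_master_mb       = 88,
    max_master_mb       = 180,
    dim_tolerance       = 0.15,
    white_over          = 250,
    white_under         = 225,
    black_over          = 18,
    black_under         = 12,
    sample_initial_every = 50L,
    sample_steady_every  = 100L,
    clean_streak_switch  = 10L,
    batch_reject_pct     = 5,
    md5_spot_every       = 50L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown or unnamed config keys: ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "herbqc_config")
}

#' Read a configuration from a YAML file
#'
#' Unknown keys are rejected; keys absent from the file keep their
#' defaults.
#'
#' @param path path to a YAML file with any subset of the keys of
#'   [herbqc_config()].
#' @return a `herbqc_config` list.
#' @export
read_herbqc_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(herbqc_config, vals)
}

#' @export
print.herbqc_config <- function(x, ...) {
  cat("<herbqc_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %-20s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  invisible(x)
}

# nominal master pixel dimensions implied by the config sheet size
config_master_dims <- function(config) {
  c(width  = round(config$sheet_width_cm / 2.54 * config$master_ppi),
    height = round(config$sheet_height_cm / 2.54 * config$master_ppi))
}
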
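# Filename grammar and filename <-> barcode correspondence.
#
# Names follow <PREFIX><D x digits>[_<a-z>].<ext>: a configurable prefix
# (default BR), a zero-padded numeric identifier (default 13 digits), an
# optional single-letter suffix for specimens with more than one image,
# and a set-consistent lower-case extension.

#' Parse an image filename against the naming grammar
#'
#' The parse is total and side-effect free: a well-formed name yields its
#' parts, a malformed one yields `NULL` plus the first violated rule in the
#' `error` attribute (also available via [check_filename()]).
#'
#' @param name filename, e.g. `"BR0000008378064.tif"`.
#' @param config a [herbqc_config()] supplying `prefix`, `digits` and
#'   `extensions`.
#' @return list with `prefix`, `digits`, `suffix` (NA if absent) and
#'   `extension`, or `NULL` if malformed.
#' @examples
#' parse_filename("BR0000008378064.tif")
#' parse_filename("BR0000008378064_a.jp2")
#' @export
parse_filename <- function(name, config = herbqc_config()) {
  res <- check_filename(name, config)
  res$parts
}

#' @rdname parse_filename
#' @return `check_filename`: list with `parts` (or NULL) and `error`
#'   (NA when well formed) naming the first violated rule.
#' @export
check_filename <- function(name, config = herbqc_config()) {
  fail <- function(rule) list(parts = NULL, error = rule)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    return(fail("empty name"))
  }
  dot <- regexpr("\\.[^.]*$", name)
  if (dot < 1) return(fail("missing extension"))
  ext <- substring(name, dot + 1L)
  stem <- substring(name, 1L, dot - 1L)
  if (!ext %in% config$extensions) {
    # lower-case-only dialect: an upper-case variant is still a name error
    return(fail(paste0("extension not in {",
                       paste(config$extensions, collapse = ","), "}")))
  }
  np <- nchar(config$prefix)
  if (substring(stem, 1L, np) != config$prefix) {
    return(fail(paste0("prefix is not ", config$prefix)))
  }
  rest <- substring(stem, np + 1L)
  suffix <- NA_character_
  us <- regexpr("_", rest, fixed = TRUE)
  if (us > 0) {
    sfx <- substring(rest, us + 1L)
    if (!grepl("^[a-z]$", sfx)) return(fail("suffix must be a single letter a-z"))
    suffix <- sfx
    rest <- substring(rest, 1L, us - 1L)
  }
  if (!grepl("^[0-9]+$", rest)) return(fail("identifier is not numeric"))
  if (nchar(rest) != config$digits) {
    return(fail(paste0("identifier must be ", config$digits, " digits")))
  }
  list(parts = list(prefix = config$prefix, digits = rest, suffix = suffix,
                    extension = ext),
       error = NA_character_)
}

#' Expected three-set filenames for a barcode
#'
#' One filename per image set (master TIFF, lossless JP2, lossy JPG), all
#' sharing the barcode stem (and suffix, if any).
#'
#' @param barcode barcode text, optionally with an `_x` suffix.
#' @param config a [herbqc_config()].
#' @return named character vector, one element per extension.
#' @examples
#' expected_set_names("BR0000008378064")
#' @export
expected_set_names <- function(barcode, config = herbqc_config()) {
  chk <- check_filename(paste0(barcode, ".", config$extensions[1]), config)
  if (!is.null(chk$error) && !is.na(chk$error)) {
    stop("invalid barcode ", sQuote(barcode), ": ", chk$error)
  }
  stats::setNames(paste0(barcode, ".", config$extensions), config$extensions)
}

finding <- function(image, sub_task, code, severity, detail = "") {
  data.frame(image = image, sub_task = sub_task, code = code,
             severity = severity, detail = detail, stringsAsFactors = FALSE)
}

no_findings <- function() {
  data.frame(image = character(), sub_task = character(), code = character(),
             severity = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Check all filenames of a batch against grammar and decoded barcodes
#'
#' Each image is assigned `names_ok` or `names_error`. A well-formed name
#' whose decoded barcode payload differs from the filename stem is a
#' `barcode_mismatch` (reject). Images carrying more than one decoded
#' barcode are flagged `manual_multi_specimen` for manual duplication and
#' are never auto-renamed. An image on which no barcode could be decoded
#' keeps `names_ok` (if the grammar passes) with an informational finding:
#' barcode correspondence then falls to the visual inspection sample.
#'
#' @param manifest batch manifest data.frame ([read_manifest()]).
#' @param decoded_barcodes named list: image filename -> character vector
#'   of decoded payloads (may be empty).
#' @param config a [herbqc_config()].
#' @return list with `states` (named character vector filename -> state)
#'   and `findings` (data.frame).
#' @export
check_batch_names <- function(manifest, decoded_barcodes,
                              config = herbqc_config()) {
  states <- stats::setNames(character(nrow(manifest)), manifest$filename)
  findings <- list()
  for (fn in manifest$filename) {
    chk <- check_filename(fn, config)
    if (is.null(chk$parts)) {
      states[fn] <- "names_error"
      findings[[length(findings) + 1L]] <-
        finding(fn, "check_name", "name_malformed", "reject_image", chk$error)
      next
    }
    payloads <- unique(unlist(decoded_barcodes[[fn]]))
    if (length(payloads) > 1L) {
      states[fn] <- "names_error"
      findings[[length(findings) + 1L]] <-
        finding(fn, "check_name", "manual_multi_specimen", "flag_manual",
                paste("decoded payloads:", paste(payloads, collapse = " ")))
      next
    }
    stem <- paste0(chk$parts$prefix, chk$parts$digits)
    if (length(payloads) == 0L) {
      states[fn] <- "names_ok"
      findings[[length(findings) + 1L]] <-
        finding(fn, "check_name", "barcode_mismatch", "info",
                "no decodable barcode; verify at visual inspection")
      next
    }
    if (payloads != stem) {
      states[fn] <- "names_error"
      findings[[length(findings) + 1L]] <-
        finding(fn, "check_name", "barcode_mismatch", "reject_image",
                paste0("filename stem ", stem, " != decoded ", payloads))
      next
    }
    states[fn] <- "names_ok"
  }
  list(states = states,
       findings = if (length(findings)) do.call(rbind, findings) else no_findings())
}

#' Duplicate a multi-specimen image, one file per barcode
#'
#' Manual remediation for sheets carrying several specimens/barcodes: the
#' image file is copied once per payload and each copy named from its
#' barcode. Requires an explicit operator confirmation token; the copies
#' are recorded as allowed duplicates by the caller's ledger.
#'
#' @param image path of the flagged image.
#' @param payloads decoded payloads (length >= 2).
#' @param operator_token non-empty string confirming the manual decision.
#' @param archive_index optional archive index (barcode -> md5,
#'   [read_archive_index()]) used to refuse payloads already archived.
#' @param config a [herbqc_config()].
#' @return list with `files` (new paths) and `findings`.
#' @export
duplicate_for_barcodes <- function(image, payloads, operator_token,
                                   archive_index = NULL,
                                   config = herbqc_config()) {
  if (length(payloads) < 2L) {
    stop("image is not multi-specimen: ", length(payloads), " payload(s)")
  }
  if (missing(operator_token) || !nzchar(operator_token)) {
    stop("operator confirmation token required")
  }
  ext <- tools::file_ext(image)
  findings <- no_findings()
  files <- character()
  for (p in payloads) {
    if (!is.null(archive_index) && p %in% names(archive_index)) {
      findings <- rbind(findings,
        finding(basename(image), "check_name", "duplicate", "reject_image",
                paste0("payload ", p, " already in archive")))
      next
    }
    newf <- file.path(dirname(image), paste0(p, ".", ext))
    file.copy(image, newf, overwrite = FALSE)
    files <- c(files, newf)
  }
  list(files = files, findings = findings)
}
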
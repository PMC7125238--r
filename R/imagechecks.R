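# File-level checks over the master set: the size/dimension heuristic
# ("large files tend to be under-cropped and small files over-cropped"),
# MD5 fixity with spot-check escalation, and duplicate detection against
# an archive index. Format structure validation lives in tiff.R / jp2.R.

#' Build an image record from a file on disk
#'
#' @param path image path.
#' @param set one of `master_tiff`, `prod_jp2`, `prod_jpg`.
#' @param md5_manifest MD5 recorded in the batch manifest (or NA).
#' @return list of class `image_record`: filename, set membership, size in
#'   bytes, pixel dimensions and ppi (from the format header), manifest and
#'   computed MD5 slots.
#' @export
image_record <- function(path, set = c("master_tiff", "prod_jp2", "prod_jpg"),
                         md5_manifest = NA_character_) {
  set <- match.arg(set)
  info <- file.info(path)
  width <- height <- ppi <- NA_real_
  if (isTRUE(info$size > 0)) {
    hdr <- switch(set,
      master_tiff = validate_tiff_structure(path),
      prod_jp2 = validate_jp2_structure(path),
      prod_jpg = NULL)
    if (!is.null(hdr)) {
      width <- hdr$width; height <- hdr$height; ppi <- hdr$ppi
    }
  }
  structure(list(
    filename = basename(path), path = path, set = set,
    size_bytes = as.numeric(info$size),
    width_px = width, height_px = height, ppi = ppi,
    md5_manifest = md5_manifest, md5_computed = NA_character_
  ), class = "image_record")
}

#' Master size / dimension / resolution heuristic
#'
#' A master passes (`fssr_ok`) iff its size is strictly above the
#' configured floor (`min_master_mb`, decimal MB — the 88 MB average
#' minimum), at or below the ceiling, and its pixel dimensions fall within
#' the window implied by the configured sheet size and `master_ppi`
#' (`dim_tolerance` relative). Undersized files carry an over-crop hint and
#' oversized files an under-crop hint. Resolution is judged in pixels;
#' the PPI tag is informational.
#'
#' @param record an [image_record()] for a master, or a list with at least
#'   `filename` and `size_bytes` (dimensions optional).
#' @param config a [herbqc_config()].
#' @return list with `state` (`fssr_ok`/`fssr_error`) and `findings`.
#' @export
check_size_resolution <- function(record, config = herbqc_config()) {
  fn <- record$filename
  findings <- no_findings()
  if (is.na(record$size_bytes) || record$size_bytes <= 0) {
    return(list(state = "fssr_error",
                findings = finding(fn, "check_size_res", "size_low",
                                   "reject_image", "unreadable or empty file")))
  }
  min_b <- config$min_master_mb * 1e6
  max_b <- config$max_master_mb * 1e6
  if (record$size_bytes <= min_b) {
    findings <- rbind(findings,
      finding(fn, "check_size_res", "size_low", "reject_image",
              sprintf("%.1f MB <= %.0f MB floor; bad_crop hint: over-cropped",
                      record$size_bytes / 1e6, config$min_master_mb)))
  }
  if (record$size_bytes > max_b) {
    findings <- rbind(findings,
      finding(fn, "check_size_res", "size_high", "reject_image",
              sprintf("%.1f MB > %.0f MB ceiling; bad_crop hint: under-cropped",
                      record$size_bytes / 1e6, config$max_master_mb)))
  }
  dims <- config_master_dims(config)
  tol <- config$dim_tolerance
  in_window <- function(x, nominal) {
    !is.na(x) && x >= nominal * (1 - tol) && x <= nominal * (1 + tol)
  }
  if (!is.null(record$width_px) && !is.na(record$width_px)) {
    if (!in_window(record$width_px, dims["width"]) ||
        !in_window(record$height_px, dims["height"])) {
      findings <- rbind(findings,
        finding(fn, "check_size_res", "dim_out_of_range", "reject_image",
                sprintf("%sx%s px outside %.0fx%.0f +/- %.0f%%",
                        record$width_px, record$height_px,
                        dims["width"], dims["height"], tol * 100)))
    }
  }
  list(state = if (nrow(findings)) "fssr_error" else "fssr_ok",
       findings = findings)
}

#' Size check over a whole batch
#'
#' Applies [check_size_resolution()] per master and additionally flags the
#' smallest and largest file of the batch for manual verification.
#'
#' @param records list of master [image_record()]s.
#' @param config a [herbqc_config()].
#' @return list with `states` (named by filename) and `findings`.
#' @export
check_batch_sizes <- function(records, config = herbqc_config()) {
  states <- character(0)
  findings <- no_findings()
  for (rec in records) {
    res <- check_size_resolution(rec, config)
    states[rec$filename] <- res$state
    findings <- rbind(findings, res$findings)
  }
  sizes <- vapply(records, function(r) r$size_bytes, numeric(1))
  if (length(records) >= 2L) {
    extremes <- unique(c(which.min(sizes), which.max(sizes)))
    for (i in extremes) {
      findings <- rbind(findings,
        finding(records[[i]]$filename, "check_size_res", "size_low",
                "flag_manual",
                sprintf("batch extreme (%s file): verify manually",
                        if (i == which.min(sizes)) "smallest" else "largest")))
    }
  }
  list(states = states, findings = findings)
}

#' Verify a file's MD5 against the manifest
#'
#' @param record an [image_record()] (uses `path` and `filename`).
#' @param manifest manifest data.frame.
#' @return list with `state` (`md5_ok`/`md5_error`), `md5_computed` and
#'   `findings`.
#' @export
verify_md5 <- function(record, manifest) {
  row <- manifest[manifest$filename == record$filename, , drop = FALSE]
  if (nrow(row) != 1L) {
    return(list(state = "md5_error", md5_computed = NA_character_,
                findings = finding(record$filename, "check_md5",
                                   "md5_mismatch", "reject_image",
                                   "no manifest row for file")))
  }
  md5 <- file_md5(record$path)
  if (is.na(md5) || md5 != row$md5) {
    return(list(state = "md5_error", md5_computed = md5,
                findings = finding(record$filename, "check_md5",
                                   "md5_mismatch", "reject_image",
                                   sprintf("manifest %s != computed %s",
                                           row$md5, md5 %||% "NA"))))
  }
  list(state = "md5_ok", md5_computed = md5, findings = no_findings())
}

#' Fixity spot check with escalation
#'
#' Verifies every `config$md5_spot_every`-th master (in manifest order)
#' against the stored hashes. If any sampled file fails, the check
#' escalates automatically to full-batch verification and lists every
#' corrupt file. Corruption confined to unsampled files escapes the spot
#' check (the documented residual risk) and is caught at archive
#' verification.
#'
#' @param records list of master [image_record()]s in manifest order.
#' @param manifest manifest data.frame.
#' @param config a [herbqc_config()].
#' @param full force full-batch verification from the start.
#' @return list with `states` (filename -> `md5_ok`/`md5_error`),
#'   `findings`, `verified` (filenames actually hashed) and `escalated`.
#' @export
spot_check_md5 <- function(records, manifest, config = herbqc_config(),
                           full = FALSE) {
  n <- length(records)
  fns <- vapply(records, function(r) r$filename, character(1))
  k <- config$md5_spot_every
  sample_idx <- if (full) seq_len(n) else seq_len(n)[seq_len(n) %% k == 0L]
  if (!full && !length(sample_idx) && n >= 1L) sample_idx <- n
  run <- function(idx) {
    st <- character(0); fd <- no_findings()
    for (i in idx) {
      res <- verify_md5(records[[i]], manifest)
      st[fns[i]] <- res$state
      fd <- rbind(fd, res$findings)
    }
    list(states = st, findings = fd)
  }
  first <- run(sample_idx)
  escalated <- FALSE
  if (!full && any(first$states == "md5_error")) {
    escalated <- TRUE
    first <- run(seq_len(n))
    sample_idx <- seq_len(n)
  }
  states <- stats::setNames(rep("md5_ok", n), fns)
  states[names(first$states)] <- first$states
  list(states = states, findings = first$findings,
       verified = fns[sample_idx], escalated = escalated)
}

#' Read / write an archive index
#'
#' The archive index is the local stand-in for the archive database of
#' previously processed specimens: a TSV `barcode<TAB>md5`, kept sorted.
#'
#' @param path TSV path.
#' @return named character vector (barcode -> md5); empty if the file does
#'   not exist.
#' @export
read_archive_index <- function(path) {
  if (!file.exists(path)) return(stats::setNames(character(), character()))
  x <- utils::read.table(path, sep = "\t", colClasses = "character",
                         col.names = c("barcode", "md5"))
  stats::setNames(x$md5, x$barcode)
}

#' @rdname read_archive_index
#' @param index named character vector (barcode -> md5).
#' @export
write_archive_index <- function(index, path) {
  index <- index[order(names(index))]
  utils::write.table(data.frame(names(index), unname(index)), path,
                     sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Find duplicate images within a batch and against the archive
#'
#' Flags (a) intra-batch repeats of a barcode without suffix
#' differentiation, (b) barcodes already present in the archive index,
#' and (c) pairs of byte-identical files (equal MD5). Suffix siblings
#' (`_a`/`_b`) of one specimen are allowed duplicates and stay `unique`.
#'
#' @param records list of master [image_record()]s (MD5s are computed if
#'   absent).
#' @param archive_index named vector barcode -> md5 ([read_archive_index()]).
#' @param config a [herbqc_config()].
#' @param allowed optional character vector of filenames operator-approved
#'   as multi-specimen duplicates.
#' @return list with `states` (filename -> `unique`/`duplicate`) and
#'   `findings`.
#' @export
find_duplicates <- function(records, archive_index = character(),
                            config = herbqc_config(), allowed = character()) {
  fns <- vapply(records, function(r) r$filename, character(1))
  states <- stats::setNames(rep("unique", length(records)), fns)
  findings <- no_findings()
  flag <- function(fn, detail) {
    states[fn] <<- "duplicate"
    findings <<- rbind(findings, finding(fn, "check_dups", "duplicate",
                                         "reject_image", detail))
  }
  stems <- vapply(fns, function(fn) {
    p <- parse_filename(fn, config)
    if (is.null(p)) fn else paste0(p$prefix, p$digits)
  }, character(1))
  # (a) repeated barcode, same (possibly absent) suffix
  full_stem <- vapply(fns, function(fn) {
    p <- parse_filename(fn, config)
    if (is.null(p)) fn
    else paste0(p$prefix, p$digits,
                if (!is.na(p$suffix)) paste0("_", p$suffix) else "")
  }, character(1))
  dup_stems <- unique(full_stem[duplicated(full_stem)])
  for (s in dup_stems) {
    for (fn in fns[full_stem == s]) flag(fn, paste0("barcode ", s, " repeated in batch"))
  }
  # (b) barcode already archived
  for (i in seq_along(fns)) {
    if (fns[i] %in% allowed) next
    if (stems[i] %in% names(archive_index)) {
      flag(fns[i], paste0("barcode ", stems[i], " already in archive"))
    }
  }
  # (c) byte-identical files
  md5s <- vapply(records, function(r) {
    if (!is.na(r$md5_computed)) r$md5_computed else file_md5(r$path)
  }, character(1))
  for (m in unique(md5s[duplicated(md5s)])) {
    grp <- fns[md5s == m]
    grp_stems <- unique(stems[md5s == m])
    if (length(grp_stems) == 1L && all(grepl("_[a-z]\\.", grp))) next
    if (all(grp %in% allowed)) next
    for (fn in grp) {
      flag(fn, paste0("identical md5 as: ",
                      paste(setdiff(grp, fn), collapse = " ")))
    }
  }
  list(states = states, findings = findings)
}
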
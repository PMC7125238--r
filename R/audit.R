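# Orchestration of the two audit-trail phases over a batch directory.
#
# Directory model: the batch directory is the buffer server. Masters live
# at its top level, derivatives under <batch>/derivatives, quarantined
# images under <batch>/quarantine. The image repository, transfer (FTP)
# staging and external archive are local directories; the external
# archive's reception is modelled by an acknowledgement JSON written when
# masters land there, which the buffer-clearing step validates before it
# deletes anything.

stem_of <- function(fn) tools::file_path_sans_ext(fn)

derivative_dir <- function(batch_dir) file.path(batch_dir, "derivatives")

# filenames (of the given set) currently in `state`
in_state <- function(ledger, state) {
  st <- ledger_states_df(ledger)
  st[!is.na(st$state) & st$state == state, , drop = FALSE]
}

set_file <- function(batch_dir, stem, set) {
  switch(set,
    master_tiff = file.path(batch_dir, paste0(stem, ".tif")),
    prod_jp2 = file.path(derivative_dir(batch_dir), paste0(stem, ".jp2")),
    prod_jpg = file.path(derivative_dir(batch_dir), paste0(stem, ".jpg")))
}

#' Run the image-processing phase over a batch
#'
#' Executes the processing sub-tasks in audit-trail order with the state
#' gating of the transition table: filename/barcode check, size and
#' dimension heuristic, derivative generation (internal mode) or
#' verification of supplied derivatives (outsourced mode), MD5 spot check
#' with escalation, duplicate detection, TIFF/JP2 structure validation,
#' visual-QC sampling with exposure classification, and the JPG name
#' check. Ends with the batch accept/reject decision.
#'
#' @param batch_dir batch (buffer) directory containing the master TIFFs
#'   and `manifest.csv`.
#' @param config a [herbqc_config()].
#' @param mode `"internal"` (derivatives generated here) or `"outsourced"`
#'   (derivatives supplied under `derivatives/`; verification only).
#' @param archive_index named vector barcode -> md5 of previously archived
#'   specimens ([read_archive_index()]).
#' @param layout chart layout for exposure checks; default `"groundtruth"`
#'   reads per-image layouts from the batch's `groundtruth.json` (fixture
#'   batches), otherwise pass a single layout list used for every image.
#' @param clean_batch_streak clean batches accrued before this one
#'   (controls the inspection schedule).
#' @param full_md5 force full-batch fixity verification.
#' @return object of class `herbqc_processing`: ledger, findings,
#'   decision, inspection sample, updated streak, manifest, config, mode.
#' @export
run_image_processing <- function(batch_dir, config = herbqc_config(),
                                 mode = c("internal", "outsourced"),
                                 archive_index = character(),
                                 layout = "groundtruth",
                                 clean_batch_streak = 0L,
                                 full_md5 = FALSE) {
  mode <- match.arg(mode)
  manifest_path <- file.path(batch_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", batch_dir, "; aborting before any state change")
  }
  manifest <- read_manifest(manifest_path)
  n <- nrow(manifest)
  ledger <- audit_ledger(as.integer(manifest$batch_number[1]))
  findings <- no_findings()
  gt <- NULL
  gt_path <- file.path(batch_dir, "groundtruth.json")
  if (identical(layout, "groundtruth") && file.exists(gt_path)) {
    gt <- read_ground_truth(gt_path)
    names(gt) <- vapply(gt, `[[`, character(1), "filename")
  }

  # -- sub-task 1: check file name (barcode decode on every master) -----------
  decoded <- list()
  for (fn in manifest$filename) {
    path <- file.path(batch_dir, fn)
    payloads <- character()
    if (file.exists(path)) {
      img <- tryCatch(read_image(path), error = function(e) NULL)
      if (!is.null(img)) {
        h <- dim(img)[1]
        res <- read_sheet_barcodes(img, roi = rect(0, floor(h * 0.82),
                                                   dim(img)[2], h))
        payloads <- vapply(Filter(function(r) r$checksum_valid, res),
                           `[[`, character(1), "payload")
      }
    }
    decoded[[fn]] <- unique(payloads)
  }
  nm <- check_batch_names(manifest, decoded, config)
  findings <- rbind(findings, nm$findings)
  for (fn in manifest$filename) {
    advance(ledger, fn, "master_tiff", "check_name",
            if (nm$states[fn] == "names_ok") "success" else "fail")
  }

  # -- sub-task 2: size / dimensions / resolution -----------------------------
  alive <- in_state(ledger, "names_ok")$image
  records <- lapply(alive, function(fn) {
    image_record(file.path(batch_dir, fn), "master_tiff",
                 md5_manifest = manifest$md5[manifest$filename == fn])
  })
  names(records) <- alive
  if (length(records)) {
    sz <- check_batch_sizes(records, config)
    findings <- rbind(findings, sz$findings)
    for (fn in alive) {
      advance(ledger, fn, "master_tiff", "check_size_res",
              if (sz$states[fn] == "fssr_ok") "success" else "fail")
    }
  }

  # -- sub-tasks 3-4: derivatives (generate or verify supplied) ---------------
  alive <- in_state(ledger, "fssr_ok")$image
  ddir <- derivative_dir(batch_dir)
  if (mode == "internal") {
    der <- if (length(alive)) {
      generate_derivatives(file.path(batch_dir, alive), ddir, config)
    } else NULL
    for (i in seq_along(alive)) {
      fn <- alive[i]; stem <- stem_of(fn)
      jp2_ok <- der$jp2_ok[i]; jpg_ok <- der$jpg_ok[i]
      advance(ledger, fn, "master_tiff", "gen_jp2",
              if (jp2_ok) "success" else "fail",
              detail = if (!jp2_ok) der$error[i] %||% "" else "")
      advance(ledger, paste0(stem, ".jp2"), "prod_jp2", "gen_jp2",
              if (jp2_ok) "success" else "fail")
      if (jp2_ok) {
        advance(ledger, fn, "master_tiff", "gen_jpg",
                if (jpg_ok) "success" else "fail")
      }
      advance(ledger, paste0(stem, ".jpg"), "prod_jpg", "gen_jpg",
              if (jpg_ok) "success" else "fail")
    }
  } else {
    for (fn in alive) {
      stem <- stem_of(fn)
      jp2 <- file.path(ddir, paste0(stem, ".jp2"))
      jpg <- file.path(ddir, paste0(stem, ".jpg"))
      jp2_ok <- file.exists(jp2) && file.info(jp2)$size > 0
      jpg_ok <- file.exists(jpg) && file.info(jpg)$size > 0
      advance(ledger, fn, "master_tiff", "gen_jp2",
              if (jp2_ok) "success" else "fail",
              detail = "supplied derivative verified")
      advance(ledger, paste0(stem, ".jp2"), "prod_jp2", "gen_jp2",
              if (jp2_ok) "success" else "fail")
      if (jp2_ok) {
        advance(ledger, fn, "master_tiff", "gen_jpg",
                if (jpg_ok) "success" else "fail")
      }
      advance(ledger, paste0(stem, ".jpg"), "prod_jpg", "gen_jpg",
              if (jpg_ok) "success" else "fail")
    }
  }

  # -- sub-task 5: MD5 fixity spot check --------------------------------------
  alive <- manifest$filename[manifest$filename %in% in_state(ledger, "jpg_gen")$image]
  if (length(alive)) {
    spot <- spot_check_md5(records[alive], manifest, config, full = full_md5)
    findings <- rbind(findings, spot$findings)
    for (fn in alive) {
      verified <- fn %in% spot$verified
      advance(ledger, fn, "master_tiff", "check_md5",
              if (spot$states[fn] == "md5_ok") "success" else "fail",
              detail = if (verified) "verified" else "spot check passed; not sampled")
    }
  }

  # -- sub-task 6: duplicates -------------------------------------------------
  alive <- in_state(ledger, "md5_ok")$image
  if (length(alive)) {
    dup <- find_duplicates(records[alive], archive_index, config)
    findings <- rbind(findings, dup$findings)
    for (fn in alive) {
      advance(ledger, fn, "master_tiff", "check_dups",
              if (dup$states[fn] == "unique") "success" else "fail")
    }
  }

  # -- sub-task 7: structure (TIFF masters, JP2 derivatives) ------------------
  for (fn in in_state(ledger, "unique")$image) {
    v <- validate_tiff_structure(file.path(batch_dir, fn))
    ok <- v$well_formed && v$valid
    if (!ok) {
      findings <- rbind(findings,
        finding(fn, "check_structure", "format_invalid", "reject_image",
                paste(v$issues, collapse = "; ")))
    }
    advance(ledger, fn, "master_tiff", "check_structure",
            if (ok) "success" else "fail")
  }
  st <- in_state(ledger, "jp2_gen")
  for (fn in st$image[st$set == "prod_jp2"]) {
    v <- validate_jp2_structure(file.path(ddir, fn))
    if (!v$conformant) {
      findings <- rbind(findings,
        finding(fn, "check_structure", "format_invalid", "reject_image",
                paste(v$issues, collapse = "; ")))
    }
    advance(ledger, fn, "prod_jp2", "check_structure",
            if (v$conformant) "success" else "fail")
  }

  # -- sub-task 8: visual QC on the inspection sample -------------------------
  sample_idx <- select_inspection_sample(n, clean_batch_streak, config)
  sampled <- manifest$filename[sample_idx]
  write_inspection_worklist(sample_idx, manifest$filename,
                            file.path(batch_dir, "inspection_worklist.csv"))
  st <- in_state(ledger, "fss_ok")
  for (fn in st$image[st$set == "master_tiff"]) {
    if (!fn %in% sampled) {
      advance(ledger, fn, "master_tiff", "visual_qc", "success",
              detail = "not in inspection sample")
      next
    }
    lay <- if (!is.null(gt)) gt[[fn]]$chart else layout
    if (identical(lay, "groundtruth") || is.null(lay)) {
      advance(ledger, fn, "master_tiff", "visual_qc", "success",
              detail = "no chart layout available; manual-only inspection")
      next
    }
    reading <- extract_patch_means(file.path(batch_dir, fn), lay)
    if (nrow(reading$findings)) {
      fd <- reading$findings; fd$image <- fn
      findings <- rbind(findings, fd)
      advance(ledger, fn, "master_tiff", "visual_qc", "fail",
              detail = "chart patch outside frame (bad crop)")
      next
    }
    cls <- classify_exposure(reading, config)
    if (nrow(cls$findings)) {
      fd <- cls$findings; fd$image <- fn
      findings <- rbind(findings, fd)
    }
    advance(ledger, fn, "master_tiff", "visual_qc",
            if (cls$state == "vqc_ok") "success" else "fail")
  }

  # -- sub-task 9: JPG set name check -----------------------------------------
  st <- in_state(ledger, "jpg_gen")
  for (fn in st$image[st$set == "prod_jpg"]) {
    chk <- check_filename(fn, config)
    ok <- !is.null(chk$parts)
    if (!ok) {
      findings <- rbind(findings,
        finding(fn, "check_name_jpg", "name_malformed", "reject_image", chk$error))
    }
    advance(ledger, fn, "prod_jpg", "check_name_jpg",
            if (ok) "success" else "fail")
  }

  decision <- decide_batch(findings, n, config)
  streak_next <- update_clean_streak(clean_batch_streak,
                                     decision$decision == "accept" &&
                                       decision$n_flagged == 0L)
  structure(list(
    batch_dir = batch_dir, ledger = ledger, findings = findings,
    decision = decision, sample = sample_idx, manifest = manifest,
    mode = mode, config = config, streak_next = streak_next
  ), class = "herbqc_processing")
}

#' @export
print.herbqc_processing <- function(x, ...) {
  cat(sprintf("<herbqc_processing batch %d: %d images, decision %s (%d flagged)>\n",
              x$ledger$batch, nrow(x$manifest), x$decision$decision,
              x$decision$n_flagged))
  invisible(x)
}

#' Remove flagged images across all three sets
#'
#' For an accepted batch, every image carrying a `reject_image` finding is
#' moved (not deleted) to the quarantine directory together with its
#' sibling files in the other sets; a re-imaging report is written for the
#' imaging team. Remaining images advance to `dup_rmv`. A flagged
#' production image whose master passed is re-validated to attribute the
#' error to derivation rather than imaging.
#'
#' @param proc a `herbqc_processing` result (accepted batch).
#' @param quarantine_dir destination; default `<batch>/quarantine`.
#' @return `proc`, updated (quarantined stems recorded), invisibly.
#' @export
remove_flagged <- function(proc, quarantine_dir = file.path(proc$batch_dir,
                                                            "quarantine")) {
  if (proc$decision$decision != "accept") {
    stop("batch was rejected; remove_flagged applies to accepted batches")
  }
  batch_dir <- proc$batch_dir
  ledger <- proc$ledger
  flagged <- proc$decision$flagged
  flagged_stems <- unique(stem_of(flagged))
  dir.create(quarantine_dir, showWarnings = FALSE, recursive = TRUE)

  # attribution per Table-11-style exception: flagged production image,
  # clean master -> re-validate the master
  for (fn in flagged[grepl("\\.jp2$", flagged)]) {
    stem <- stem_of(fn)
    master <- paste0(stem, ".tif")
    if (!master %in% flagged) {
      v <- validate_tiff_structure(file.path(batch_dir, master))
      proc$findings <- rbind(proc$findings,
        finding(fn, "remove_flagged", "format_invalid", "info",
                paste0("attribution: master ",
                       if (v$well_formed && v$valid) "valid -> derivation error"
                       else "also invalid -> imaging error")))
    }
  }

  for (stem in flagged_stems) {
    moved <- FALSE
    for (set in SET_TOKENS) {
      src <- set_file(batch_dir, stem, set)
      named_in_findings <- basename(src) %in% flagged
      if (file.exists(src)) {
        file.rename(src, file.path(quarantine_dir, basename(src)))
        moved <- TRUE
      } else if (named_in_findings) {
        stop("ledger inconsistency: flagged file already absent: ", basename(src))
      }
    }
    if (!moved) stop("ledger inconsistency: no files found for flagged stem ", stem)
  }

  start_states <- c(master_tiff = "vqc_ok", prod_jp2 = "fss_ok",
                    prod_jpg = "jpgn_ok")
  st <- ledger_states_df(ledger)
  for (set in SET_TOKENS) {
    ready <- st$image[st$set == set & st$state == start_states[[set]]]
    for (fn in ready) {
      if (stem_of(fn) %in% flagged_stems) next
      advance(ledger, fn, set, "remove_flagged", "success")
    }
  }
  utils::write.csv(
    proc$findings[proc$findings$severity == "reject_image", , drop = FALSE],
    file.path(quarantine_dir, "reimaging_report.csv"), row.names = FALSE)
  proc$quarantined <- flagged_stems
  invisible(proc)
}

#' Check that the production sets are stored
#'
#' Every expected JP2/JPG path in the repository must exist and be
#' non-empty. Unexpected extra files yield informational findings, not
#' failures.
#'
#' @param ledger the batch ledger (JP2 images in `vwrg_ok`, JPG in
#'   `stg_ok` are due for verification; already-verified images are
#'   re-checked without new events).
#' @param repo_dirs list with `jp2` and `jpg` repository directories.
#' @return list with `states`, `missing`, `findings`.
#' @export
check_production_stored <- function(ledger, repo_dirs) {
  st <- ledger_states_df(ledger)
  findings <- no_findings()
  missing <- character()
  states <- character()
  due <- rbind(
    st[st$set == "prod_jp2" & st$state %in% c("vwrg_ok", "stgv_ok", "bufc_ok"), ],
    st[st$set == "prod_jpg" & st$state %in% c("stg_ok", "stgv_ok", "bufc_ok"), ])
  expected <- character()
  for (i in seq_len(nrow(due))) {
    fn <- due$image[i]; set <- due$set[i]
    dir <- if (set == "prod_jp2") repo_dirs$jp2 else repo_dirs$jpg
    path <- file.path(dir, fn)
    expected <- c(expected, path)
    ok <- file.exists(path) && file.info(path)$size > 0
    states[fn] <- if (ok) "stgv_ok" else "stgv_err"
    if (!ok) {
      missing <- c(missing, fn)
      findings <- rbind(findings,
        finding(fn, "check_stored", "format_invalid", "reject_image",
                "expected repository file missing or empty"))
    }
    if (due$state[i] %in% c("vwrg_ok", "stg_ok")) {
      advance(ledger, fn, set, "check_stored", if (ok) "success" else "fail")
    }
  }
  for (dir in unlist(repo_dirs[c("jp2", "jpg")])) {
    extra <- setdiff(list.files(dir, full.names = TRUE, recursive = FALSE),
                     c(expected, file.path(dir, "viewers")))
    for (p in extra) {
      findings <- rbind(findings,
        finding(basename(p), "check_stored", "duplicate", "info",
                "unexpected extra file in repository"))
    }
  }
  list(states = states, missing = missing, findings = findings)
}

#' Clear the master buffer after archive acknowledgement
#'
#' Deletes the buffer copies of the master set only after the archive's
#' acknowledgement file validates: matching batch number and a complete
#' per-file MD5 list agreeing with the buffer copies. On any mismatch
#' nothing is deleted and the masters move to `bufc_err`; the copy step
#' can be retried and the check re-run. In outsourced mode a completion
#' signal file is written for the contractor.
#'
#' @param ledger the batch ledger (masters in `arc_ok`).
#' @param batch_dir buffer directory.
#' @param ack_path acknowledgement JSON:
#'   `{batch_number, files: [{filename, md5}], code}`.
#' @param mode `"internal"` or `"outsourced"`.
#' @return list with `state` (`bufc_ok`/`bufc_err`) and `detail`.
#' @export
clear_buffer <- function(ledger, batch_dir, ack_path,
                         mode = c("internal", "outsourced")) {
  mode <- match.arg(mode)
  st <- ledger_states_df(ledger)
  due <- st$image[st$set == "master_tiff" & st$state == "arc_ok"]
  if (!length(due)) return(list(state = "bufc_ok", detail = "nothing due"))
  fail_all <- function(detail) {
    for (fn in due) advance(ledger, fn, "master_tiff", "clear_buffer", "fail",
                            detail = detail)
    list(state = "bufc_err", detail = detail)
  }
  if (!file.exists(ack_path)) {
    return(fail_all("archive acknowledgement missing; nothing deleted"))
  }
  ack <- jsonlite::read_json(ack_path)
  if (!identical(as.integer(ack$batch_number), ledger$batch)) {
    return(fail_all("acknowledgement batch number mismatch; nothing deleted"))
  }
  ack_md5 <- stats::setNames(
    vapply(ack$files, `[[`, character(1), "md5"),
    vapply(ack$files, `[[`, character(1), "filename"))
  buf_paths <- file.path(batch_dir, due)
  buf_md5 <- file_md5(buf_paths)
  bad <- due[!(due %in% names(ack_md5)) | ack_md5[due] != buf_md5]
  if (length(bad) || anyNA(buf_md5)) {
    return(fail_all(paste("acknowledgement incomplete or mismatched for:",
                          paste(bad, collapse = " "), "- nothing deleted")))
  }
  unlink(buf_paths)
  for (fn in due) advance(ledger, fn, "master_tiff", "clear_buffer", "success")
  if (mode == "outsourced") {
    writeLines(sprintf("batch %d processed completely", ledger$batch),
               file.path(batch_dir, sprintf("complete_batch%d.signal",
                                            ledger$batch)))
  }
  list(state = "bufc_ok", detail = sprintf("%d buffer masters deleted",
                                           length(due)))
}

copy_step <- function(ledger, images, set, sub_task, src_dir_fn, dest_dir) {
  dir.create(dest_dir, showWarnings = FALSE, recursive = TRUE)
  for (fn in images) {
    src <- src_dir_fn(fn)
    ok <- file.exists(src) &&
      suppressWarnings(file.copy(src, file.path(dest_dir, fn),
                                 overwrite = TRUE))
    advance(ledger, fn, set, sub_task, if (ok) "success" else "fail",
            detail = if (!ok) "copy failed" else "")
  }
}

#' Run the store-images phase over a processed batch
#'
#' Executes the storage sub-tasks in audit-trail order: removal of flagged
#' images, copy of all three sets to the repository, viewer (thumbnail)
#' generation from the JP2 set, copy of masters to the transfer staging
#' directory and on to the external archive (which acknowledges reception
#' with a per-file MD5 list), verification that the production sets are
#' stored, and buffer clearing — masters only after the acknowledgement
#' validates. Images already past a step are skipped, so re-running on a
#' stored batch changes nothing and re-verifies storage.
#'
#' @param proc a `herbqc_processing` result for an accepted batch.
#' @param repo_dirs list with `tif`, `jp2`, `jpg` repository directories.
#' @param ftp_dir transfer staging directory for masters.
#' @param archive_dir external archive directory.
#' @param archive_index_path optional archive index TSV updated with the
#'   barcodes of archived masters.
#' @param skip_removal set when [remove_flagged()] was already called.
#' @return list of class `herbqc_store`: ledger, findings, storage report,
#'   ack path.
#' @export
run_store_images <- function(proc, repo_dirs, ftp_dir, archive_dir,
                             archive_index_path = NULL, skip_removal = FALSE) {
  ledger <- proc$ledger
  batch_dir <- proc$batch_dir
  config <- proc$config
  findings <- no_findings()
  ack_path <- file.path(archive_dir, sprintf("ack_batch%d.json", ledger$batch))

  st <- ledger_states_df(ledger)
  if (file.exists(ack_path) &&
      any(st$set == "master_tiff" & st$state == "dup_rmv")) {
    stop("batch ", ledger$batch, " already acknowledged by the archive; ",
         "re-submission refused")
  }

  if (!skip_removal &&
      any(st$state %in% c("vqc_ok", "fss_ok", "jpgn_ok"))) {
    proc <- remove_flagged(proc)
    ledger <- proc$ledger
    findings <- rbind(findings, proc$findings[0, ])
  }

  # copy to repository (all three sets)
  st <- ledger_states_df(ledger)
  for (set in SET_TOKENS) {
    due <- st$image[st$set == set & st$state == "dup_rmv"]
    dest <- switch(set, master_tiff = repo_dirs$tif, prod_jp2 = repo_dirs$jp2,
                   prod_jpg = repo_dirs$jpg)
    copy_step(ledger, due, set, "copy_repository",
              function(fn) set_file(batch_dir, stem_of(fn), set), dest)
  }

  # viewer generation: thumbnail per stored JP2
  st <- ledger_states_df(ledger)
  due <- st$image[st$set == "prod_jp2" & st$state == "stg_ok"]
  if (length(due)) {
    vdir <- file.path(repo_dirs$jp2, "viewers")
    dir.create(vdir, showWarnings = FALSE, recursive = TRUE)
    for (fn in due) {
      ok <- tryCatch({
        img <- read_image(file.path(repo_dirs$jp2, fn))
        thumb <- resample_image(img, 128 / dim(img)[2])
        png::writePNG(thumb / 255,
                      file.path(vdir, paste0(stem_of(fn), "_thumb.png")))
        TRUE
      }, error = function(e) FALSE)
      if (ok) advance(ledger, fn, "prod_jp2", "gen_viewers", "success")
    }
  }

  # masters: repository -> transfer staging -> external archive
  st <- ledger_states_df(ledger)
  due <- st$image[st$set == "master_tiff" & st$state == "stg_ok"]
  copy_step(ledger, due, "master_tiff", "copy_ftp",
            function(fn) file.path(repo_dirs$tif, fn), ftp_dir)
  st <- ledger_states_df(ledger)
  due <- st$image[st$set == "master_tiff" & st$state == "svrc_ok"]
  copy_step(ledger, due, "master_tiff", "copy_archive",
            function(fn) file.path(ftp_dir, fn), archive_dir)
  # the archive acknowledges what it received
  st <- ledger_states_df(ledger)
  archived <- st$image[st$set == "master_tiff" & st$state == "arc_ok"]
  if (length(archived)) {
    jsonlite::write_json(list(
      batch_number = ledger$batch,
      files = lapply(archived, function(fn) {
        list(filename = fn, md5 = file_md5(file.path(archive_dir, fn)))
      }),
      code = "ARCHIVED"
    ), ack_path, auto_unbox = TRUE)
  }

  stored <- check_production_stored(ledger, repo_dirs)
  findings <- rbind(findings, stored$findings)

  cleared <- clear_buffer(ledger, batch_dir, ack_path, mode = proc$mode)
  st <- ledger_states_df(ledger)
  for (set in c("prod_jp2", "prod_jpg")) {
    due <- st$image[st$set == set & st$state == "stgv_ok"]
    for (fn in due) {
      unlink(file.path(derivative_dir(batch_dir), fn))
      advance(ledger, fn, set, "clear_buffer", "success")
    }
  }

  if (!is.null(archive_index_path)) {
    st <- ledger_states_df(ledger)
    done <- st$image[st$set == "master_tiff" & st$state == "bufc_ok"]
    if (length(done)) {
      idx <- read_archive_index(archive_index_path)
      new <- stats::setNames(unname(file_md5(file.path(archive_dir, done))),
                             stem_of(done))
      idx[names(new)] <- new
      write_archive_index(idx, archive_index_path)
    }
  }
  structure(list(ledger = ledger, findings = findings, stored = stored,
                 cleared = cleared, ack_path = ack_path,
                 quarantined = proc$quarantined %||% character()),
            class = "herbqc_store")
}

#' Batch audit report
#'
#' Per-batch summary generated from the ledger: image counts per state and
#' set, findings per code, the batch decision, and the conservation check
#' — every manifest image is accounted for as archived, quarantined or
#' stalled in an error state; no image vanishes without a finding.
#'
#' @param ledger the batch `audit_ledger`.
#' @param findings accumulated findings data.frame (optional).
#' @param manifest batch manifest (optional; enables conservation
#'   accounting).
#' @param decision batch decision list from [decide_batch()] (optional).
#' @param quarantined character vector of quarantined stems (optional).
#' @return list of class `herbqc_report`.
#' @export
audit_report <- function(ledger, findings = NULL, manifest = NULL,
                         decision = NULL, quarantined = character()) {
  st <- ledger_states_df(ledger)
  per_state <- if (nrow(st)) {
    as.data.frame(table(set = st$set, state = st$state),
                  stringsAsFactors = FALSE)
  } else data.frame(set = character(), state = character(), Freq = integer())
  per_state <- per_state[per_state$Freq > 0, , drop = FALSE]
  per_code <- if (!is.null(findings) && nrow(findings)) {
    as.data.frame(table(code = findings$code), stringsAsFactors = FALSE)
  } else data.frame(code = character(), Freq = integer())
  conservation <- NULL
  if (!is.null(manifest)) {
    masters <- st[st$set == "master_tiff", , drop = FALSE]
    archived <- sum(masters$state == "bufc_ok")
    n_quar <- length(quarantined)
    stalled <- masters$image[!masters$state %in% "bufc_ok" &
                               !stem_of(masters$image) %in% quarantined]
    conservation <- list(
      n_manifest = nrow(manifest),
      archived = archived,
      quarantined = n_quar,
      stalled_or_error = length(stalled),
      balanced = nrow(manifest) == archived + n_quar + length(stalled)
    )
  }
  structure(list(batch = ledger$batch, n_events = length(ledger$events),
                 states = per_state, findings_per_code = per_code,
                 decision = decision, conservation = conservation),
            class = "herbqc_report")
}

#' @export
print.herbqc_report <- function(x, ...) {
  cat(sprintf("<herbqc_report batch %d: %d events>\n", x$batch, x$n_events))
  if (!is.null(x$decision)) {
    cat("  decision:", x$decision$decision,
        sprintf("(%d flagged)\n", x$decision$n_flagged))
  }
  if (!is.null(x$conservation)) {
    with(x$conservation, cat(sprintf(
      "  conservation: %d = %d archived + %d quarantined + %d stalled [%s]\n",
      n_manifest, archived, quarantined, stalled_or_error,
      if (balanced) "balanced" else "IMBALANCE")))
  }
  invisible(x)
}

#' Write the audit report
#'
#' @param report a `herbqc_report`.
#' @param json_path machine-readable JSON rendering.
#' @param csv_path operator CSV rendering (state counts).
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report$states, csv_path, row.names = FALSE)
  }
  invisible(report)
}
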
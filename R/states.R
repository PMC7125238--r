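# The audit-trail state machine: per-image, per-set state tokens and the
# legal transitions of the image-processing and store-images phases, plus
# the append-only event ledger with its two renderings (machine log and
# operator sheet) generated from one event stream.

SET_TOKENS <- c("master_tiff", "prod_jp2", "prod_jpg")

#' Legal state transitions of the audit trail
#'
#' One row per (sub-task, image set): the start state required before the
#' sub-task may run on that set, and the success/fail tokens it assigns.
#' `start = NA` marks entry sub-tasks; `fail = NA` marks sub-tasks with no
#' fail token. The master set is carried through the storage copy chain
#' (staging, transfer server, external archive) before its buffer copy may
#' be cleared.
#'
#' @return data.frame with columns `phase`, `sub_task`, `set`, `start`,
#'   `success`, `fail`.
#' @export
herbqc_transitions <- function() {
  t <- function(phase, sub_task, set, start, success, fail) {
    data.frame(phase = phase, sub_task = sub_task, set = set, start = start,
               success = success, fail = fail, stringsAsFactors = FALSE)
  }
  rbind(
    t("processing", "check_name",      "master_tiff", NA,         "names_ok", "names_error"),
    t("processing", "check_size_res",  "master_tiff", "names_ok", "fssr_ok",  "fssr_error"),
    t("processing", "gen_jp2",         "master_tiff", "fssr_ok",  "jp2_gen",  "jp2_gen_err"),
    t("processing", "gen_jp2",         "prod_jp2",    NA,         "jp2_gen",  "jp2_gen_err"),
    t("processing", "gen_jpg",         "master_tiff", "jp2_gen",  "jpg_gen",  "jpg_gen_err"),
    t("processing", "gen_jpg",         "prod_jpg",    NA,         "jpg_gen",  "jpg_gen_err"),
    t("processing", "check_md5",       "master_tiff", "jpg_gen",  "md5_ok",   "md5_error"),
    t("processing", "check_dups",      "master_tiff", "md5_ok",   "unique",   "duplicate"),
    t("processing", "check_structure", "master_tiff", "unique",   "fss_ok",   "fss_error"),
    t("processing", "check_structure", "prod_jp2",    "jp2_gen",  "fss_ok",   "fss_error"),
    t("processing", "visual_qc",       "master_tiff", "fss_ok",   "vqc_ok",   "vqc_error"),
    t("processing", "check_name_jpg",  "prod_jpg",    "jpg_gen",  "jpgn_ok",  "jpgn_error"),
    t("store",      "remove_flagged",  "master_tiff", "vqc_ok",   "dup_rmv",  NA),
    t("store",      "remove_flagged",  "prod_jp2",    "fss_ok",   "dup_rmv",  NA),
    t("store",      "remove_flagged",  "prod_jpg",    "jpgn_ok",  "dup_rmv",  NA),
    t("store",      "copy_repository", "master_tiff", "dup_rmv",  "stg_ok",   "stg_error"),
    t("store",      "copy_repository", "prod_jp2",    "dup_rmv",  "stg_ok",   "stg_error"),
    t("store",      "copy_repository", "prod_jpg",    "dup_rmv",  "stg_ok",   "stg_error"),
    t("store",      "gen_viewers",     "prod_jp2",    "stg_ok",   "vwrg_ok",  NA),
    t("store",      "copy_ftp",        "master_tiff", "stg_ok",   "svrc_ok",  "svrc_error"),
    t("store",      "copy_archive",    "master_tiff", "svrc_ok",  "arc_ok",   "arc_error"),
    t("store",      "check_stored",    "prod_jp2",    "vwrg_ok",  "stgv_ok",  "stgv_err"),
    t("store",      "check_stored",    "prod_jpg",    "stg_ok",   "stgv_ok",  "stgv_err"),
    t("store",      "clear_buffer",    "master_tiff", "arc_ok",   "bufc_ok",  "bufc_err"),
    t("store",      "clear_buffer",    "prod_jp2",    "stgv_ok",  "bufc_ok",  "bufc_err"),
    t("store",      "clear_buffer",    "prod_jpg",    "stgv_ok",  "bufc_ok",  "bufc_err")
  )
}

#' All recognised state tokens
#' @return character vector.
#' @export
herbqc_states <- function() {
  tr <- herbqc_transitions()
  unique(stats::na.omit(c(tr$success, tr$fail)))
}

#' Create an empty audit ledger
#'
#' The ledger is the single source of truth of the audit trail: an
#' append-only event stream from which both the machine log (JSONL) and
#' the operator sheet (CSV) are rendered. State is derived from events, so
#' replaying a ledger reproduces identical final states.
#'
#' @param batch_number integer batch identifier.
#' @return an `audit_ledger` (environment-backed, append-only).
#' @export
audit_ledger <- function(batch_number = 1L) {
  env <- new.env(parent = emptyenv())
  env$batch <- as.integer(batch_number)
  env$events <- list()
  env$states <- new.env(parent = emptyenv())
  class(env) <- "audit_ledger"
  env
}

state_key <- function(image, set) paste0(set, ":", image)

#' Current state of an image in a set
#' @param ledger an `audit_ledger`.
#' @param image image filename (stem + extension of that set).
#' @param set one of `master_tiff`, `prod_jp2`, `prod_jpg`.
#' @return state token, or NA if the image has no state yet.
#' @export
ledger_state <- function(ledger, image, set) {
  get0(state_key(image, set), envir = ledger$states, ifnotfound = NA_character_)
}

append_event <- function(ledger, type, image, set, sub_task, from, to,
                         outcome = NA_character_, detail = "",
                         operator = "auto") {
  ev <- list(seq = length(ledger$events) + 1L,
             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
             batch = ledger$batch, type = type, image = image, set = set,
             sub_task = sub_task, from = from, to = to, outcome = outcome,
             detail = detail, operator = operator)
  ledger$events[[length(ledger$events) + 1L]] <- ev
  assign(state_key(image, set), to, envir = ledger$states)
  invisible(ev)
}

#' Advance an image through a sub-task of the audit trail
#'
#' The single legal way to change state: the image's current state in the
#' set must equal the sub-task's start state, and the outcome selects the
#' success or fail token. Illegal transitions (wrong start state, unknown
#' sub-task/set pair, `fail` on a sub-task with no fail token) raise an
#' error and mutate nothing. Exactly one event is appended per state
#' change.
#'
#' @param ledger an [audit_ledger()].
#' @param image image filename.
#' @param set image set.
#' @param sub_task sub-task identifier (see [herbqc_transitions()]).
#' @param outcome `"success"` or `"fail"`.
#' @param detail free-text event detail.
#' @param operator operator identifier.
#' @return the new state token, invisibly.
#' @export
advance <- function(ledger, image, set, sub_task,
                    outcome = c("success", "fail"), detail = "",
                    operator = "auto") {
  outcome <- match.arg(outcome)
  tr <- herbqc_transitions()
  row <- tr[tr$sub_task == sub_task & tr$set == set, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown sub-task/set: ", sub_task, " / ", set)
  }
  cur <- ledger_state(ledger, image, set)
  if (is.na(row$start)) {
    if (!is.na(cur)) stop("illegal transition: ", sub_task, " on ", set,
                          " requires no prior state, image is in ", cur)
  } else if (is.na(cur) || cur != row$start) {
    stop("illegal transition: ", sub_task, " on ", set, " requires start ",
         row$start, ", image ", image, " is in ", cur %||% "NA")
  }
  to <- if (outcome == "success") row$success else row$fail
  if (is.na(to)) stop("sub-task ", sub_task, " has no fail state")
  append_event(ledger, "transition", image, set, sub_task,
               from = cur, to = to, outcome = outcome, detail = detail,
               operator = operator)
  invisible(to)
}

#' Log a remediation event
#'
#' An image in a fail state cannot advance until remediation is recorded;
#' this appends an explicit operator event returning the image to the
#' given state (typically the failed sub-task's start state, so it can be
#' re-run).
#'
#' @inheritParams advance
#' @param to_state state token to reset to.
#' @export
log_remediation <- function(ledger, image, set, to_state, detail = "",
                            operator = "operator") {
  if (!to_state %in% herbqc_states()) stop("unknown state token: ", to_state)
  cur <- ledger_state(ledger, image, set)
  append_event(ledger, "remediation", image, set, sub_task = "remediation",
               from = cur, to = to_state, outcome = "remediated",
               detail = detail, operator = operator)
  invisible(to_state)
}

#' Events and states of a ledger as data frames
#' @param ledger an `audit_ledger`.
#' @return `ledger_events`: one row per event; `ledger_states_df`: one row
#'   per (image, set) with the current state.
#' @export
ledger_events <- function(ledger) {
  if (!length(ledger$events)) {
    return(data.frame(seq = integer(), timestamp = character(),
                      batch = integer(), type = character(),
                      image = character(), set = character(),
                      sub_task = character(), from = character(),
                      to = character(), outcome = character(),
                      detail = character(), operator = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(ledger$events, function(e) {
    e$from <- e$from %||% NA_character_
    as.data.frame(e, stringsAsFactors = FALSE)
  }))
}

#' @rdname ledger_events
#' @export
ledger_states_df <- function(ledger) {
  keys <- ls(ledger$states)
  if (!length(keys)) {
    return(data.frame(image = character(), set = character(),
                      state = character(), stringsAsFactors = FALSE))
  }
  parts <- regmatches(keys, regexpr(":", keys), invert = TRUE)
  data.frame(
    set = vapply(parts, `[`, character(1), 1L),
    image = vapply(parts, `[`, character(1), 2L),
    state = vapply(keys, function(k) get(k, envir = ledger$states), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write / read the machine ledger (JSONL)
#'
#' One JSON object per line, append-only order preserved. Reading replays
#' the events into a fresh ledger, re-deriving identical states.
#'
#' @param ledger an `audit_ledger`.
#' @param path JSONL path.
#' @export
write_ledger <- function(ledger, path) {
  lines <- vapply(ledger$events, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE, null = "null")
  }, character(1))
  writeLines(c(sprintf("{\"batch\": %d}", ledger$batch), lines), path)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  lines <- readLines(path)
  head_obj <- jsonlite::fromJSON(lines[1])
  ledger <- audit_ledger(head_obj$batch)
  for (ln in lines[-1]) {
    e <- jsonlite::fromJSON(ln)
    ledger$events[[length(ledger$events) + 1L]] <- e
    assign(state_key(e$image, e$set), e$to, envir = ledger$states)
  }
  ledger
}

#' Render the operator sheet
#'
#' The spreadsheet view of the audit trail, generated from the same event
#' stream as the machine log (never edited independently): one row per
#' event with batch, sub-task, scope and state movement.
#'
#' @param ledger an `audit_ledger`.
#' @param path CSV path.
#' @export
write_operator_sheet <- function(ledger, path) {
  ev <- ledger_events(ledger)
  utils::write.csv(
    ev[, c("seq", "timestamp", "batch", "sub_task", "set", "image",
           "from", "to", "outcome", "operator")],
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.audit_ledger <- function(x, ...) {
  st <- ledger_states_df(x)
  cat(sprintf("<audit_ledger batch %d: %d events, %d tracked states>\n",
              x$batch, length(x$events), nrow(st)))
  if (nrow(st)) print(table(st$set, st$state))
  invisible(x)
}
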
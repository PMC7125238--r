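# Shared fixture scaffolding. Tests run at a reduced capture resolution
# (50 PPI instead of the production 450) so a sheet is ~0.5 k x 0.8 k px;
# config_for_sheet() scales the size window accordingly while every QC
# threshold keeps its default value.

test_spec <- function(ppi = 50, ...) sheet_spec(ppi = ppi, ...)
test_config <- function(ppi = 50, ...) config_for_sheet(test_spec(ppi), ...)

# one clean 12-image batch rendered once per test run and reused read-only
.clean_batch_cache <- new.env(parent = emptyenv())
clean_batch <- function() {
  if (is.null(.clean_batch_cache$batch)) {
    dir <- file.path(tempdir(), "herbqc-clean-batch")
    unlink(dir, recursive = TRUE)
    .clean_batch_cache$batch <- make_batch(dir, n = 12, batch_number = 7,
                                           seed = 101, spec = test_spec())
  }
  .clean_batch_cache$batch
}

# fresh copy of the clean batch for tests that mutate files
clean_batch_copy <- function() {
  src <- clean_batch()$dir
  dst <- tempfile("batch")
  dir.create(dst)
  file.copy(list.files(src, full.names = TRUE), dst, recursive = TRUE)
  dst
}

fresh_dirs <- function() {
  root <- tempfile("store")
  list(repo = list(tif = file.path(root, "repo", "tif"),
                   jp2 = file.path(root, "repo", "jp2"),
                   jpg = file.path(root, "repo", "jpg")),
       ftp = file.path(root, "ftp"),
       archive = file.path(root, "archive"))
}

# render a single sheet with given payload/defects into a temp file
render_one <- function(payload, defects = defect_spec(), seed = 1,
                       spec = test_spec()) {
  spec$barcode_payload <- payload
  path <- tempfile(paste0(payload, "-"), fileext = ".tif")
  gt <- render_sheet(spec, path, defects, seed = seed)
  list(path = path, gt = gt)
}

# drive an image's master-set state to a target by direct legal advances
advance_master_to <- function(ledger, image, target) {
  chain <- c("check_name", "check_size_res", "gen_jp2", "gen_jpg",
             "check_md5", "check_dups", "check_structure", "visual_qc",
             "remove_flagged", "copy_repository", "copy_ftp", "copy_archive",
             "clear_buffer")
  tr <- herbqc_transitions()
  for (stask in chain) {
    row <- tr[tr$sub_task == stask & tr$set == "master_tiff", ]
    advance(ledger, image, "master_tiff", stask, "success")
    if (row$success == target) return(invisible(ledger))
  }
  stop("target state not on master chain: ", target)
}
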
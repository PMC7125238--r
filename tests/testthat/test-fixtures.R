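# Synthetic sheet generator: determinism, ground-truth bookkeeping, and
# the defect -> detecting-check matrix.

test_that("identical (spec, defects, seed) yield byte-identical files", {
  spec <- test_spec()
  f1 <- tempfile(fileext = ".tif"); f2 <- tempfile(fileext = ".tif")
  g1 <- render_sheet(spec, f1, seed = 77)
  g2 <- render_sheet(spec, f2, seed = 77)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(g1$md5, g2$md5)
  f3 <- tempfile(fileext = ".tif")
  render_sheet(spec, f3, seed = 78)
  expect_false(tools::md5sum(f1) == tools::md5sum(f3))
})

test_that("degenerate sheet dimensions raise a layout error", {
  expect_error(render_sheet(sheet_spec(sheet_width_cm = 0, ppi = 50),
                            tempfile(fileext = ".tif")), "layout error")
})

test_that("a defect-free sheet targets the accepted exposure band", {
  b <- clean_batch()
  gt <- b$ground_truth[[3]]
  rd <- extract_patch_means(file.path(b$dir, b$files[3]), gt$chart)
  expect_gte(rd$white_mean, 225); expect_lte(rd$white_mean, 250)
  expect_gte(rd$black_mean, 12);  expect_lte(rd$black_mean, 18)
  expect_lte(abs(rd$white_mean - gt$chart$white_level), 1)
})

test_that("rendered pixel dimensions follow round(cm / 2.54 * ppi)", {
  b <- clean_batch()
  spec <- test_spec()
  gt <- b$ground_truth[[1]]
  expect_equal(gt$width_px, round(spec$sheet_width_cm / 2.54 * spec$ppi))
  expect_equal(gt$height_px, round(spec$sheet_height_cm / 2.54 * spec$ppi))
  for (box in gt$element_boxes) {
    expect_true(herbqc:::rect_inside(box, gt$width_px, gt$height_px))
  }
})

test_that("the manifest has the exact header and matches files as written", {
  b <- clean_batch()
  m <- read_manifest(file.path(b$dir, "manifest.csv"))
  expect_identical(names(m),
                   c("filename", "time", "operator", "batch_number", "md5",
                     "station"))
  expect_identical(nrow(m), 12L)
  expect_false(anyDuplicated(m$filename) > 0)
  on_disk <- unname(tools::md5sum(file.path(b$dir, m$filename)))
  expect_identical(on_disk, m$md5)
})

test_that("corrupt_file flips exactly the requested bytes in place", {
  f <- tempfile(); writeBin(as.raw(rep(7, 2048)), f)
  before <- readBin(f, raw(), 2048)
  corrupt_file(f, 5, seed = 3)
  after <- readBin(f, raw(), 2048)
  expect_identical(file.info(f)$size, 2048)
  expect_identical(sum(before != after), 5L)
  expect_error(corrupt_file(f, 0), "n_bytes")
  empty <- tempfile(); file.create(empty)
  expect_error(corrupt_file(empty, 1), "empty")
})

test_that("corrupting the TIFF header destroys well-formedness", {
  src <- clean_batch()
  f <- tempfile(fileext = ".tif")
  file.copy(file.path(src$dir, src$files[1]), f)
  con <- file(f, "r+b"); writeBin(as.raw(c(0, 0, 0, 0)), con); close(con)
  v <- validate_tiff_structure(f)
  expect_false(v$well_formed)
})

test_that("ground truth records duplicated pairs exactly", {
  dir <- tempfile("dupbatch")
  b <- make_batch(dir, n = 6, batch_number = 9, seed = 55,
                  defect_rates = list(duplicate = 0.5), spec = test_spec())
  dup_of <- vapply(b$ground_truth, function(g) {
    as.integer(g$defects$duplicate_of %||% NA_integer_)
  }, integer(1))
  expect_gte(sum(!is.na(dup_of)), 1L)
  for (i in which(!is.na(dup_of))) {
    j <- dup_of[i]
    expect_lt(j, i)  # source strictly earlier in the batch
    expect_identical(
      unname(tools::md5sum(file.path(dir, b$files[i]))),
      unname(tools::md5sum(file.path(dir, b$files[j]))))
  }
})

test_that("every injected defect class is caught by its downstream check", {
  cfg <- test_config()
  cases <- list(
    list(def = defect_spec(overexpose_white_to = 253), patch = "white",
         expect = "overexposed"),
    list(def = defect_spec(underexpose_white_to = 215), patch = "white",
         expect = "underexposed"),
    list(def = defect_spec(overexpose_black_to = 25), patch = "black",
         expect = "overexposed"),
    list(def = defect_spec(underexpose_black_to = 6), patch = "black",
         expect = "underexposed"))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    r <- render_one(sprintf("BR00000006000%02d", k), cs$def, seed = 40 + k)
    rd <- extract_patch_means(r$path, r$gt$chart)
    cls <- classify_exposure(rd, cfg)
    expect_identical(cls[[cs$patch]], cs$expect)
    expect_identical(cls$state, "vqc_error")
  }
  # crops are caught by the size heuristic
  oc <- render_one("BR0000000600090", defect_spec(crop_mode = "over_crop"),
                   seed = 51)
  uc <- render_one("BR0000000600091", defect_spec(crop_mode = "under_crop"),
                   seed = 52)
  f_oc <- check_size_resolution(image_record(oc$path, "master_tiff"), cfg)
  f_uc <- check_size_resolution(image_record(uc$path, "master_tiff"), cfg)
  expect_true("size_low" %in% f_oc$findings$code)
  expect_true("size_high" %in% f_uc$findings$code)
  # corruption is caught by fixity
  cr <- render_one("BR0000000600092", seed = 53)
  manifest <- data.frame(filename = basename(cr$path), time = "t",
                         operator = "o", batch_number = "1",
                         md5 = cr$gt$md5, station = "s",
                         stringsAsFactors = FALSE)
  corrupt_file(cr$path, 2, seed = 9)
  expect_identical(verify_md5(image_record(cr$path, "master_tiff"), manifest)$state,
                   "md5_error")
})

test_that("batch generation and ground truth survive a JSON round trip", {
  b <- clean_batch()
  gt <- read_ground_truth(file.path(b$dir, "groundtruth.json"))
  expect_length(gt, 12L)
  expect_identical(gt[[1]]$filename, b$files[1])
  expect_identical(gt[[1]]$payloads[[1]], b$ground_truth[[1]]$payloads[[1]])
  expect_identical(gt[[1]]$element_boxes$barcode,
                   b$ground_truth[[1]]$element_boxes$barcode)
})
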
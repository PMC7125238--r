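# Size heuristic, format validators, fixity and duplicate detection.

fake_record <- function(size_mb, width = NULL, height = NULL,
                        name = "BR0000000000001.tif") {
  list(filename = name, path = name, set = "master_tiff",
       size_bytes = size_mb * 1e6, width_px = width, height_px = height,
       md5_manifest = NA_character_, md5_computed = NA_character_)
}

test_that("the master size floor sits exactly at the configured 88 MB", {
  cfg <- herbqc_config()
  states <- vapply(86:91, function(mb) {
    check_size_resolution(fake_record(mb), cfg)$state
  }, character(1))
  expect_identical(states, c("fssr_error", "fssr_error", "fssr_error",
                             "fssr_ok", "fssr_ok", "fssr_ok"))
  r <- check_size_resolution(fake_record(87), cfg)
  expect_true("size_low" %in% r$findings$code)
  r2 <- check_size_resolution(fake_record(181), cfg)
  expect_true("size_high" %in% r2$findings$code)
})

test_that("growing a file never turns size_high back into fssr_ok", {
  cfg <- herbqc_config()
  sizes <- seq(80, 220, by = 5)
  states <- vapply(sizes, function(mb) {
    check_size_resolution(fake_record(mb), cfg)$state
  }, character(1))
  first_high <- match("fssr_error", states[sizes > 180])
  after_max <- states[sizes > 180]
  expect_true(all(after_max == "fssr_error"))
  # monotone: once above the ceiling it never recovers
  ok_region <- which(states == "fssr_ok")
  expect_true(all(diff(ok_region) == 1))
})

test_that("pixel dimensions outside the sheet window are flagged", {
  cfg <- test_config()
  dims <- herbqc:::config_master_dims(cfg)
  nominal_mb <- dims["width"] * dims["height"] * 3 / 1e6
  ok <- check_size_resolution(
    fake_record(nominal_mb, dims["width"], dims["height"]), cfg)
  expect_identical(ok$state, "fssr_ok")
  bad <- check_size_resolution(
    fake_record(nominal_mb, round(dims["width"] * 0.8), dims["height"]), cfg)
  expect_true("dim_out_of_range" %in% bad$findings$code)
})

test_that("batch extremes are always flagged for manual verification", {
  b <- clean_batch()
  cfg <- test_config()
  recs <- lapply(b$files, function(fn) {
    image_record(file.path(b$dir, fn), "master_tiff")
  })
  res <- check_batch_sizes(recs, cfg)
  manual <- res$findings[res$findings$severity == "flag_manual", ]
  expect_gte(nrow(manual), 1L)
  expect_true(all(grepl("batch extreme", manual$detail)))
})

test_that("the TIFF validator extracts exact fixture dimensions", {
  spec <- test_spec()
  for (seed in c(1, 2, 3, 4, 5)) {
    f <- tempfile(fileext = ".tif")
    gt <- render_sheet(spec, f, seed = seed)
    v <- validate_tiff_structure(f)
    expect_true(v$well_formed)
    expect_true(v$valid)
    expect_equal(v$width, gt$width_px)
    expect_equal(v$height, gt$height_px)
    expect_equal(v$ppi, spec$ppi)
  }
})

test_that("truncated strip data invalidates a TIFF with an offset detail", {
  b <- clean_batch()
  f <- tempfile(fileext = ".tif")
  file.copy(file.path(b$dir, b$files[1]), f)
  size <- file.info(f)$size
  raw <- readBin(f, raw(), size)
  writeBin(raw[1:(size - 5000)], f)
  v <- validate_tiff_structure(f)
  expect_false(v$valid)
  expect_true(any(grepl("offset_out_of_file", v$issues)))
})

test_that("the JP2 validator accepts encoder output and rejects imposters", {
  b <- clean_batch()
  cfg <- test_config()
  d <- generate_derivatives(file.path(b$dir, b$files[1]), tempfile("der"),
                            cfg)
  v <- validate_jp2_structure(d$jp2[1])
  expect_true(v$conformant)
  expect_gt(v$width, 0)
  # a JPEG renamed .jp2 has no signature box
  fake <- tempfile(fileext = ".jp2")
  file.copy(d$jpg[1], fake)
  v2 <- validate_jp2_structure(fake)
  expect_false(v2$conformant)
  expect_true(any(grepl("signature", v2$issues)))
})

test_that("valid boxes without an SOC marker are non-conformant", {
  # hand-built box sequence: signature + ftyp + jp2h/ihdr + jp2c w/o SOC
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "big")
  sig <- as.raw(c(0x00, 0x00, 0x00, 0x0C, 0x6A, 0x50, 0x20, 0x20,
                  0x0D, 0x0A, 0x87, 0x0A))
  ftyp <- c(u32(20), charToRaw("ftyp"), charToRaw("jp2 "), u32(0),
            charToRaw("jp2 "))
  ihdr <- c(u32(22), charToRaw("ihdr"), u32(10), u32(20),
            writeBin(3L, raw(), size = 2, endian = "big"),
            as.raw(c(7, 7, 0, 0)))
  jp2h <- c(u32(8 + length(ihdr)), charToRaw("jp2h"), ihdr)
  jp2c <- c(u32(12), charToRaw("jp2c"), as.raw(c(0x00, 0x00, 0x00, 0x00)))
  f <- tempfile(fileext = ".jp2")
  writeBin(c(sig, ftyp, jp2h, jp2c), f)
  v <- validate_jp2_structure(f)
  expect_false(v$conformant)
  expect_true(any(grepl("SOC", v$issues)))
  expect_identical(v$width, 20)
  expect_identical(v$height, 10)
})

test_that("fixity verification matches manifest hashes", {
  dir <- clean_batch_copy()
  m <- read_manifest(file.path(dir, "manifest.csv"))
  rec <- image_record(file.path(dir, m$filename[1]), "master_tiff")
  expect_identical(verify_md5(rec, m)$state, "md5_ok")
  corrupt_file(file.path(dir, m$filename[1]), 1, seed = 2)
  expect_identical(verify_md5(rec, m)$state, "md5_error")
  ghost <- rec; ghost$filename <- "BR9999999999999.tif"
  expect_identical(verify_md5(ghost, m)$state, "md5_error")
})

test_that("spot checks sample every k-th file and escalate on error", {
  dir <- clean_batch_copy()
  m <- read_manifest(file.path(dir, "manifest.csv"))
  recs <- lapply(m$filename, function(fn) {
    image_record(file.path(dir, fn), "master_tiff")
  })
  names(recs) <- m$filename
  cfg <- test_config(md5_spot_every = 4L)
  clean <- spot_check_md5(recs, m, cfg)
  expect_identical(length(clean$verified), 3L)  # floor(12 / 4)
  expect_false(clean$escalated)
  expect_true(all(clean$states == "md5_ok"))
  # corruption on a sampled index (4th) escalates to the full batch
  corrupt_file(file.path(dir, m$filename[4]), 1, seed = 5)
  corrupt_file(file.path(dir, m$filename[5]), 1, seed = 6)
  esc <- spot_check_md5(recs, m, cfg)
  expect_true(esc$escalated)
  expect_identical(length(esc$verified), 12L)
  expect_setequal(names(esc$states)[esc$states == "md5_error"],
                  m$filename[4:5])
})

test_that("corruption confined to unsampled files escapes the spot check", {
  dir <- clean_batch_copy()
  m <- read_manifest(file.path(dir, "manifest.csv"))
  recs <- lapply(m$filename, function(fn) {
    image_record(file.path(dir, fn), "master_tiff")
  })
  cfg <- test_config(md5_spot_every = 4L)
  corrupt_file(file.path(dir, m$filename[3]), 1, seed = 7)  # not sampled
  res <- spot_check_md5(recs, m, cfg)
  expect_false(res$escalated)
  expect_true(all(res$states == "md5_ok"))  # documented residual risk
  # but corruption on a sampled index is never missed
  full <- spot_check_md5(recs, m, cfg, full = TRUE)
  expect_identical(unname(full$states[3]), "md5_error")
})

test_that("duplicate detection covers batch, archive and byte-identity", {
  dir <- tempfile("dups"); dir.create(dir)
  mk <- function(name, bytes) {
    writeBin(as.raw(bytes), file.path(dir, name))
    image_record(file.path(dir, name), "master_tiff")
  }
  recs <- list(
    mk("BR0000000000001.tif", 1:50),
    mk("BR0000000000002.tif", 2:51),
    mk("BR0000000000003.tif", 1:50),      # byte-identical with 1
    mk("BR0000000000004_a.tif", 3:52),    # suffix siblings: allowed
    mk("BR0000000000004_b.tif", 4:53),
    mk("BR0000000000005.tif", 5:54))      # archived barcode
  idx <- c(BR0000000000005 = "whatever")
  res <- find_duplicates(recs, idx)
  expect_identical(unname(res$states[c("BR0000000000001.tif",
                                       "BR0000000000003.tif",
                                       "BR0000000000005.tif")]),
                   rep("duplicate", 3))
  expect_identical(unname(res$states[c("BR0000000000002.tif",
                                       "BR0000000000004_a.tif",
                                       "BR0000000000004_b.tif")]),
                   rep("unique", 3))
  pair <- res$findings[res$findings$image == "BR0000000000001.tif", ]
  expect_match(pair$detail, "BR0000000000003.tif")
  # a batch re-submitted against its own archive entries is fully flagged
  self_idx <- stats::setNames(rep("x", 6),
                              sub("\\.tif$", "", sub("_[ab]", "",
                                  vapply(recs, `[[`, character(1), "filename"))))
  res2 <- find_duplicates(recs, self_idx)
  expect_true(all(res2$states == "duplicate"))
})
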
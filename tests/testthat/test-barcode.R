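# Code 128 / UPC-A encoding and scan-line decoding.

test_that("Code 128 symbol table satisfies the structural invariants", {
  pats <- herbqc:::CODE128_PATTERNS
  expect_length(pats, 106L)
  widths <- lapply(pats, herbqc:::pattern_to_widths)
  expect_true(all(vapply(widths, length, integer(1)) == 6L))
  expect_true(all(vapply(widths, sum, numeric(1)) == 11))
  # bars (odd runs) always cover an even number of modules
  bar_mods <- vapply(widths, function(w) sum(w[c(1, 3, 5)]), numeric(1))
  expect_true(all(bar_mods %% 2 == 0))
  expect_false(anyDuplicated(pats) > 0)
  stop <- herbqc:::pattern_to_widths(herbqc:::CODE128_STOP)
  expect_identical(sum(stop), 13L)
})

test_that("UPC-A check digit matches the weighted mod-10 oracle", {
  oracle <- function(d11) {
    d <- as.integer(strsplit(d11, "")[[1]])
    as.integer((10 - (sum(d[seq(1, 11, 2)]) * 3 +
                        sum(d[seq(2, 10, 2)])) %% 10) %% 10)
  }
  expect_identical(upca_check_digit("03600029145"), oracle("03600029145"))
  expect_identical(upca_check_digit("03600029145"), 2L)
  expect_identical(upca_check_digit("00000000000"), 0L)
  set.seed(42)
  for (i in 1:25) {
    p <- paste(sample(0:9, 11, replace = TRUE), collapse = "")
    expect_identical(upca_check_digit(p), oracle(p))
  }
})

decode_matrix <- function(m) herbqc:::decode_scanline(255L - m[3, ] * 255L)

test_that("render -> decode round-trips the accession example and variants", {
  r <- decode_matrix(render_barcode("BR0000008378064", "code128"))
  expect_identical(r$payload, "BR0000008378064")
  expect_true(r$checksum_valid)
  r2 <- decode_matrix(render_barcode("00000000000", "upca"))
  expect_identical(r2$payload, "000000000000")  # check digit 0 appended
  expect_true(r2$checksum_valid)
})

test_that("round-trip holds over random payloads and module widths", {
  set.seed(11)
  pool <- c(LETTERS, letters, 0:9, " ", "-", ".", "/")
  for (i in 1:60) {
    p <- paste(sample(pool, sample(5:20, 1), replace = TRUE), collapse = "")
    r <- decode_matrix(render_barcode(p, "code128", module_px = sample(1:4, 1)))
    expect_identical(r$payload, p)
    expect_true(r$checksum_valid)
  }
  for (i in 1:60) {
    p <- paste(sample(0:9, 11, replace = TRUE), collapse = "")
    r <- decode_matrix(render_barcode(p, "upca", module_px = sample(1:4, 1)))
    expect_identical(substr(r$payload, 1, 11), p)
    expect_true(r$checksum_valid)
  }
})

test_that("non-encodable characters raise an encoding error", {
  expect_error(render_barcode("ABC€", "code128"), "not encodable")
  expect_error(render_barcode("12345", "upca"), "11 digits")
  expect_error(render_barcode("", "code128"), "empty")
})

test_that("single-module perturbations never produce a silent misread", {
  set.seed(23)
  for (i in 1:20) {
    p <- paste(sample(c(LETTERS, 0:9), 8, replace = TRUE), collapse = "")
    mods <- attr(render_barcode(p, "code128", module_px = 1L), "modules")
    runs <- rle(mods)$lengths
    j <- sample(seq_along(runs), 1)
    runs[j] <- runs[j] + 1L
    r <- decode_code128(runs)
    expect_true(identical(r$payload, p) || !r$checksum_valid)
  }
})

test_that("checksum failures are reported, not decoded", {
  # re-encode and force a mod-103 mismatch by swapping two data symbols
  vals <- herbqc:::c128_encode_values("QC12345678")
  n <- length(vals)
  swapped <- vals
  swapped[c(2, 3)] <- swapped[c(3, 2)]
  runs <- rle(herbqc:::c128_modules(swapped))$lengths
  r <- decode_code128(runs)
  expect_false(r$checksum_valid)
  expect_identical(r$payload, "")
  expect_false(decode_code128(numeric(0))$checksum_valid)
  expect_false(decode_upca(numeric(0))$checksum_valid)
  # UPC-A with a forced wrong check digit
  m <- herbqc:::upca_modules("00000000000")
  # flip the final digit's pattern to 5 (run widths 1,2,3,1)
  runs <- rle(m)$lengths
  runs[53:56] <- c(1, 2, 3, 1)
  r2 <- decode_upca(runs)
  expect_false(r2$checksum_valid)
})

test_that("barcodes are located and decoded on rendered sheets", {
  b <- clean_batch()
  gt <- b$ground_truth[[1]]
  path <- file.path(b$dir, b$files[1])
  regions <- locate_barcodes(path)
  expect_length(regions, 1L)
  expect_gt(rect_iou(regions[[1]], gt$element_boxes$barcode), 0.5)
  res <- read_sheet_barcodes(path)
  expect_length(res, 1L)
  expect_identical(res[[1]]$payload, gt$payloads[[1]])
  expect_true(res[[1]]$checksum_valid)
  expect_gte(res[[1]]$scanline_votes, 3L)
})

test_that("a blank image yields no candidates", {
  expect_length(locate_barcodes(array(255L, c(200, 320, 3))), 0L)
})

test_that("multi-specimen sheets yield two decoded barcodes", {
  two <- render_one("BR0000000700001",
                    defect_spec(extra_barcode_payload = "BR0000000800001"),
                    seed = 31)
  res <- read_sheet_barcodes(two$path)
  expect_length(res, 2L)
  expect_setequal(vapply(res, `[[`, character(1), "payload"),
                  c("BR0000000700001", "BR0000000800001"))
  expect_true(all(vapply(res, `[[`, logical(1), "checksum_valid")))
  # bottom-right ordering: primary barcode first
  expect_identical(res[[1]]$payload, "BR0000000700001")
})

test_that("an ROI restricts the search without changing a found payload", {
  b <- clean_batch()
  gt <- b$ground_truth[[2]]
  path <- file.path(b$dir, b$files[2])
  img <- read_image(path)
  h <- dim(img)[1]; w <- dim(img)[2]
  full <- read_sheet_barcodes(img)
  roi_hit <- read_sheet_barcodes(img, roi = rect(0, floor(0.8 * h), w, h))
  roi_miss <- read_sheet_barcodes(img, roi = rect(0, 0, w, floor(0.5 * h)))
  expect_identical(roi_hit[[1]]$payload, full[[1]]$payload)
  expect_length(roi_miss, 0L)
})

test_that("a truncated barcode fails safely on over-cropped sheets", {
  oc <- render_one("BR0000000700002", defect_spec(crop_mode = "over_crop"),
                   seed = 33)
  res <- read_sheet_barcodes(oc$path)
  wrong_valid <- vapply(res, function(r) {
    r$checksum_valid && r$payload != "BR0000000700002"
  }, logical(1))
  expect_false(any(wrong_valid))
})
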
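# herbqc

Staged quality control for herbarium digitisation batches.

Mass digitisation of herbarium collections produces, for every specimen
sheet, a three-image set: an uncompressed archival TIFF master (450 PPI),
a lossless JPEG 2000 production derivative (420 PPI) and a lossy JPEG for
web publishing (420 PPI). Between the camera and the long-term archive an
image is renamed, derived, copied and verified many times, and every step
can silently lose or damage a file. `herbqc` implements the audit trail
that prevents this: a per-image, per-set state machine drives each batch
through filename/barcode verification, size and crop heuristics, MD5
fixity spot checks, duplicate detection, TIFF/JP2 structural validation,
colour-chart exposure QC, derivative generation, storage and archive
verification — with an append-only event ledger rendered both as a
machine log and as an operator sheet, and a conservation guarantee that
every manifest image is accounted for as archived, quarantined or stalled
with a finding.

It is written for digitisation teams and collection informaticians who
need the quality-management logic of a mass-digitisation line —
in-house or outsourced — as tested, scriptable components, and for anyone
who needs the individual checks (a scan-line Code 128/UPC-A decoder, a
baseline TIFF validator, a JP2 box validator, CIE76 ΔE) on their own.

## The rules it enforces

* Filenames follow `<prefix><13 digits>[_a-z].<ext>` (default prefix
  `BR`), and the name must match the barcode decoded from the sheet;
  multi-specimen sheets are flagged for manual duplication.
* Master files must be strictly above 88 MB (decimal) and within a
  ±15% pixel-dimension window: small files indicate over-cropping, large
  ones under-cropping; batch extremes are always checked manually.
* Fixity: every 50th master is re-hashed against the manifest MD5; any
  failure escalates to the full batch.
* Exposure, measured on the colour chart's patches (mean Rec.709 luma,
  patch interiors eroded 10%): white mean above 250 or below 225 and
  black mean above 18 or below 12 are rejections; the boundary values
  themselves pass. Colour accuracy is mean CIE76 ΔE < 5 against the
  chart references.
* Visual inspection samples the last of every 50 images (2%) until 10
  consecutive clean batches, then the last of every 100 (1%); any problem
  resets the schedule.
* A batch is rejected only when more than 5% of its images are flagged
  (exactly 5% is accepted); flagged images are quarantined across all
  three sets and reported for re-imaging.
* Buffer copies of the masters are deleted only after the external
  archive acknowledges reception with a per-file MD5 list that validates.

A synthetic sheet generator renders ground-truthed fixtures — the five
required layout elements (colour chart, scale bar, labels, barcode,
institution name) plus injectable defects — so the whole trail runs with
no collection data. See the methods vignette
(`vignettes/herbqc-methods.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

Generate a 20-image synthetic batch, corrupt one master after its
manifest hash was recorded, and run both phases of the audit trail:

```r
library(herbqc)

spec <- sheet_spec(ppi = 50)          # reduced-scale fixtures
cfg  <- config_for_sheet(spec)        # size window scaled; QC thresholds default

b <- make_batch("demo/batch42", n = 20, batch_number = 42, seed = 7, spec = spec)
corrupt_file(file.path("demo/batch42", b$files[7]), n_bytes = 3, seed = 1)

proc <- run_image_processing("demo/batch42", cfg, full_md5 = TRUE)
print(proc)
#> <herbqc_processing batch 42: 20 images, decision accept (1 flagged)>
proc$findings[proc$findings$severity == "reject_image", c("image", "sub_task", "code")]
#>                 image  sub_task         code
#> 2 BR0000004200007.tif check_md5 md5_mismatch

res <- run_store_images(proc,
  repo_dirs = list(tif = "demo/repo/tif", jp2 = "demo/repo/jp2", jpg = "demo/repo/jpg"),
  ftp_dir = "demo/ftp", archive_dir = "demo/archive")
audit_report(res$ledger, proc$findings, proc$manifest, proc$decision, res$quarantined)
#> <herbqc_report batch 42: 503 events>
#>   decision: accept (1 flagged)
#>   conservation: 20 = 19 archived + 1 quarantined + 0 stalled [balanced]
```

The corrupted master was caught by the fixity check, quarantined together
with its JP2 and JPG siblings (one flagged image of 20 is 5% — not *more*
than 5%, so the batch proceeds), the other 19 sets were copied to the
repository, staged, archived, acknowledged, and only then cleared from
the buffer. The conservation line is the audit trail's core invariant: 20
manifest images = 19 archived + 1 quarantined + 0 stalled.

A thin command-line interface over the same functions is installed at
`inst/cli/herbqc.R` (`generate`, `decode`, `checknames`, `checkfiles`,
`vqc`, `process`, `store`, `report`; exit code 0 = accepted/complete,
2 = batch rejected, 3 = hard error).

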
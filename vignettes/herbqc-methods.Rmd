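---
title: "Methods: the herbqc audit trail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the herbqc audit trail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mass digitisation of herbarium collections produces, for every mounted
specimen sheet, a *set of three images*: an archival uncompressed TIFF
master captured at 450 PPI, a lossless JPEG 2000 production derivative at
420 PPI, and a lossy JPEG for web publishing, also at 420 PPI. At
institutional scale (thousands of sheets per week, in-house or through a
contractor), images are renamed, derived, transferred and archived many
times before publication, and each of those steps can silently lose or
damage a file. The audit trail implemented by this package is the staged
quality-management procedure that makes that impossible to miss: every
image in a batch is tracked through an explicit state machine from intake
to archive, every check appends an event to a ledger, and a batch-level
accept/reject decision gates publication.

`herbqc` implements the two phases of that procedure over local
directories:

* **Image processing** — filename grammar and barcode correspondence,
  the file-size/crop heuristic, MD5 fixity spot checks, duplicate
  detection, TIFF/JP2 structural validation, and visual-QC sampling with
  colour-chart exposure classification.
* **Store images** — removal of flagged images across all three sets,
  copies to the image repository, viewer generation, transfer staging and
  external archive, verification that the production sets are stored, and
  buffer clearing gated on an archive acknowledgement.

A synthetic sheet generator with defect injection provides ground-truthed
inputs, so the entire trail is exercisable with no collection data.

## The state machine

Each image belongs to exactly one set (`master_tiff`, `prod_jp2`,
`prod_jpg`) and carries one state token per set. `herbqc_transitions()`
enumerates the legal edges: each sub-task has a required start state and
assigns a success or fail token (e.g. the master chain
`names_ok -> fssr_ok -> jp2_gen -> jpg_gen -> md5_ok -> unique -> fss_ok
-> vqc_ok`, then through storage to `bufc_ok`). `advance()` is the only
way to change state; an illegal call errors and mutates nothing, and an
image in a fail state is parked until `log_remediation()` records an
operator intervention. The ledger is an append-only event stream; both
renderings — the machine log (JSONL) and the operator sheet (CSV) — are
generated from that one stream, so the two views of progress cannot
diverge. Replaying a written ledger re-derives identical states (event
sourcing), which the test suite asserts.

Two reconciliations of the published sub-task tables were needed. First,
the storage table starts the master set's transfer-server copy at
`stg_ok`, but no listed row produces `stg_ok` for masters; we include the
master set in the repository-copy row (`dup_rmv -> stg_ok`), which is the
evident intent. Second, the removal sub-task's fail cell repeats its
success text with a `dup_err` token that appears nowhere else; we model
removal without a fail token and instead raise a hard ledger-inconsistency
error when a flagged file is already absent, since silent continuation is
exactly what an audit trail must not do.

## Checks and their parameters

All thresholds live in `herbqc_config()`; defaults are the workflow's
operating values.

**Filename grammar** (`prefix` = `BR`, `digits` = 13): names must be
`<prefix><digits>[_a-z].<ext>` with lower-case extensions from the
three-set list. The grammar is parameterised because collections
accommodate other formats; the suffix is strictly one letter `a`–`z`.
Filename↔barcode comparison uses the decoded payload verbatim — the
barcode encodes the printed digits, so no zero-stripping is applied. An
image whose barcode cannot be decoded at all keeps `names_ok` (if the
grammar passes) with an informational finding: its name/sheet
correspondence falls to the visual inspection sample, and the other
automated checks (size, fixity) remain able to catch the underlying
defect, typically a bad crop. Multi-barcode sheets are flagged for manual
duplication (`duplicate_for_barcodes()` requires an operator token) and
never auto-renamed.

**Size/dimension heuristic** (`min_master_mb` = 88, `max_master_mb` =
180, `dim_tolerance` = 0.15): a master passes only if strictly larger
than 88 MB (decimal — 88,000,000 bytes; the unit is read as storage
vendors and digitisation guidelines use it), at or below the ceiling,
and with pixel dimensions within ±15% of the window implied by the
configured sheet size and capture PPI. Undersized files carry an
over-crop hint and oversized an under-crop hint; the smallest and largest
file of every batch are additionally flagged for manual verification.
Resolution is judged in pixels — the PPI tag is extracted but
informational, the pixel dimensions being the simpler reliable test. The
88 MB floor is an empirical constant of the source workflow's camera; it
deliberately does *not* scale with configured PPI, and
`config_for_sheet()` exists for working at reduced fixture scales.

**Fixity** (`md5_spot_every` = 50): every k-th master (manifest order) is
re-hashed against the manifest; any failure escalates automatically to
full-batch verification. Corruption confined to unsampled files can
escape the spot check — a documented residual risk, accepted for
throughput, and caught later at archive verification. The interval
defaults to the visual-QC interval since no separate value is published.

**Duplicates**: flagged when a barcode repeats within a batch without
suffix differentiation, when a barcode already exists in the archive
index (a local sorted `barcode<TAB>md5` TSV standing in for the archive
database), or when two files are byte-identical. Suffix siblings
(`_a`/`_b`) and operator-approved multi-specimen copies are allowed
duplicates.

**Structure**: the package ships its own lightweight validators for the
subset of format characterisation the pipeline's decisions depend on. For
TIFF 6.0: byte-order mark, magic 42, a walkable IFD chain without cycles,
required baseline tags, and strip offsets inside the file. For JP2
(ISO/IEC 15444-1): signature box, `ftyp` brand `jp2 `, `jp2h`/`ihdr`
(dimensions), a capture-resolution box when present, and a contiguous
codestream beginning with the SOC marker. Full JHOVE/jpylyzer parity is a
non-goal; the JPG set's integrity is deliberately not validated because
JPEGs can always be regenerated from the master or the JP2.

**Exposure** (`white_over` = 250, `white_under` = 225, `black_over` = 18,
`black_under` = 12): patch means are the arithmetic mean of rounded
Rec.709 luma over the chart patch interiors, eroded by 10% per side to
avoid edge bleed (no channel is named in the source criteria, so luma is
this package's choice). "Above" and "below" are read as strict
inequalities: a white mean of exactly 250 or 225 passes. The
classification is monotone in the mean, and the acceptance suite pins the
four boundaries by sweeping all 256 integer levels.

**Colour accuracy**: ΔE is CIE76 — Euclidean distance in CIE L\*a\*b\*
after sRGB → linear → XYZ (D50-adapted matrix) → Lab. The metric's
variant is not specified beyond "ΔE", and CIE76 is the simplest
defensible reading; chart-level accuracy passes when the mean ΔE over the
reference patches is below 5. The implementation is checked against an
independently written closed-form computation to 1e-6.

**Visual inspection schedule** (`sample_initial_every` = 50,
`sample_steady_every` = 100, `clean_streak_switch` = 10): while fewer
than 10 consecutive problem-free batches have accrued, the last of every
50 images (2%) is inspected; afterwards the last of every 100 (1%). Any
detected problem resets the streak, returning to the 2% stage. The
published rule gives "the first 10 batches" and "if the tests do not
detect a problem" as two conditions; they are combined here into one
streak counter, which reproduces both behaviours. Sampling is
deterministic at regular intervals — faults persist from their onset, so
interval inspection locates where a problem began, which random sampling
would not. Batches smaller than the interval have their final image
inspected, so no batch escapes entirely. Focus and contrast remain
human-in-the-loop: the sampler emits a worklist CSV; only exposure, crop
and barcode checks are automated.

**Batch decision** (`batch_reject_pct` = 5): a batch is rejected iff the
number of *distinct images* carrying a reject finding strictly exceeds 5%
of the batch — exactly 5% is not "more than 5%" and is accepted. Whether
the rule counts images or findings is not stated in the source; distinct
images is the reading implemented, since one bad image with three
findings is still one re-imaging job.

## Derivatives and the storage model

Derivative generation resamples the master from 450 to 420 PPI
(nearest-neighbour — reversible in the sense that the derivative's pixel
grid matches its recorded resolution) and encodes a reversible-transform
JPEG 2000 plus a quality-85 JPEG (quality is unspecified in the source;
85 is the package default). Encoding is delegated to the bundled Pillow
helper (`inst/python/derivatives.py`), one subprocess per batch; the JP2
capture-resolution box (`res`/`resc`, stored as the exact rational
`(ppi·50)/127 × 10²` pixels per metre) is written by the package so the
derivative records 420 PPI.

Servers are modelled as local directories: the batch directory is the
buffer; the repository, transfer (FTP) staging and external archive are
paths handed to `run_store_images()`. The archive "acknowledges"
reception with a JSON file carrying the batch number and a per-file MD5
list; `clear_buffer()` deletes buffer masters only after that
acknowledgement validates against the buffer copies — on any mismatch
nothing is deleted and the masters move to `bufc_err` for retry. Viewer
generation is modelled as thumbnail emission per stored JP2; tiling
services are out of scope. Extra unexpected repository files produce
informational findings, not failures, since storage verification only
requires the expected paths to be valid and non-empty. A batch number
already acknowledged by the archive is refused on re-submission.

## The synthetic generator

`render_sheet()` draws the five required layout elements — colour chart,
scale bar, labels, barcode, institution name — on a toned background with
a procedural plant silhouette (random-walk branch strokes). Realism is a
non-goal; detectability is the goal, and each injected defect class is
paired with the check that catches it:

| defect | detected by |
|---|---|
| white/black patch forced out of band | exposure classification |
| `over_crop` (frame cut 10% per side) | size floor + dimension window; chart patch outside frame |
| `under_crop` (8% margin padding) | size ceiling + dimension window |
| `corrupt_bytes` (post-manifest byte flips) | MD5 fixity |
| `misname_as` | decoded-barcode vs filename mismatch |
| `duplicate_of` (byte-identical copy) | identical-MD5 pair detection |
| `extra_barcode_payload` | multi-specimen flag at the name check |

The default sheet is 26 × 42 cm; at 450 PPI that is ≈ 4606 × 7441 px,
whose uncompressed RGB size (≈ 103 MB) naturally clears the 88 MB floor.
The chart's white and black patches are rendered at 240 and 15 — inside
the accepted bands — and patches are noise-free so measured means are
exact. Corruption is applied *after* the manifest hash is recorded, so
fixity checks have something to catch. Crop displacement follows the size
heuristic's logic: padding enlarges the file (under-crop), truncation
shrinks it (over-crop). Identical `(spec, defects, seed)` produce
byte-identical TIFFs; the writer emits deterministic single-strip
baseline TIFF with resolution tags.

What the generator does **not** emulate: focus blur, lighting gradients,
sensor noise at realistic amplitude, skewed or rotated barcodes (the
decoder is specified for axis-aligned symbols), real colour-chart
spectral behaviour, or ICC-profiled colour. Passing tests therefore
demonstrate the *logic* of every check and the integrity of the trail,
not the decoders' robustness to photographic degradation.

## The barcode decoder

Accession labels use Code 128 or UPC-A. The decoder is scan-line based:
candidate regions are found by per-block transition density (blocks about
1/16th of the frame width; the mean transitions-per-row statistic is
scale-free, so the same threshold works at fixture and capture
resolution), refined to the pixel extent of the alternation and padded by
a quiet-zone margin. Each region is decoded on 5 evenly spaced horizontal
scan lines, binarised per line with Otsu's threshold; run widths are
quantised to the symbology's module grid with ties broken toward narrower
bars. Code 128 honours code sets A/B/C with shifts and switches and
verifies the mod-103 checksum; UPC-A parses the 95-module frame and
verifies the weighted mod-10 check digit. The majority payload across
scan lines wins and ties fail — the published workflow is silent on how
scan-line disagreement was handled, so voting is this package's choice.
FNC characters and 2D symbologies are unsupported (the source workflow
chose 1D symbols deliberately). The safety property the tests enforce is
*no silent misreads*: a single-module perturbation either decodes to the
original payload or fails the checksum.

## Numerical and scale choices

Pixel rectangles are 0-based and half-open throughout. The tests run the
generator at 40–60 PPI (a sheet of ~0.5k × 0.8k px) with
`config_for_sheet()` scaling only the size window; all QC thresholds keep
their defaults, and the boundary-value acceptance checks run at the
production constants. Problem sizes used by the suite: a 12-image clean
batch shared across tests, a 100-image batch with ~5% injected defects
for the conservation property, 400 seeded payloads for the decoder
round-trip, 600 fuzz probes for state-machine legality, and 20 seeded
colour pairs for the ΔE oracle agreement.

## Known limitations

* The barcode locator assumes high-contrast, axis-aligned symbols as the
  fixtures render them; rotation beyond a degree or two, blur, or low
  contrast will reduce recall (never precision — the checksum gates every
  accepted payload).
* The TIFF/JP2 validators implement the decision-relevant subset of the
  standards, not full characterisation; exotic but legal files (tiled
  TIFFs, JPX extensions) may be reported non-conformant.
* Exposure reference values are chart-dependent in practice; per-layout
  overrides are supported via the config, but no alternative chart
  defaults are shipped.
* The MD5 spot check's residual risk (corruption on unsampled files) is
  inherent to sampling and is closed only at archive verification.
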
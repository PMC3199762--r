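---
title: "Headless pairwise synteny visualization: formats, view algebra and rendering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Headless pairwise synteny visualization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synviewr)
```

## The problem

Comparative genomics routinely asks how two genomes are arranged relative to
each other: which regions are conserved, in what order, and where the order
breaks (inversions, translocations). The inputs are usually homegrown — an
all-vs-all BLAST, a lastz run, a table from a collaborator — rather than
records in a public browser, so the toolkit here is built around
*user-supplied* data: two small tab-delimited interchange formats, converters
from common aligner outputs into them, a headless model of the browsing state
(pair selection, viewports, filters, track styling), and a deterministic
renderer that draws the classic dual-genome figure — two rulers, conserved
regions as ribbons or lines between them, and styled annotation tracks
stacked along each ruler.

Everything is scriptable: the same figure is reproducible from a synteny
file, an optional annotation file and a plain-text view configuration,
either through the R API or the bundled command-line wrapper
(`inst/scripts/synviewr`).

## Interchange formats

Both formats are UTF-8, tab-delimited, with `#` comments and a required
header line. Coordinates are **1-based and inclusive at both ends**
everywhere in the package — the same convention as GFF3, which is also why
GFF3 coordinates transfer verbatim in the converter.

The *synteny format* has six required columns, `org1 start1 end1 org2
start2 end2`, one conserved region per row. Any further header columns
declare named numeric attributes (alignment score, E-value, percent
identity, ...); these are deliberately open-ended, must be finite numbers,
and automatically become filter options. A row with start > end on either
side encodes a reverse-orientation interval — the positional convention
aligners themselves use for minus-strand hits — and is normalized on parse
to a sorted interval plus an orientation flag; serialization reverses the
transformation, so write→parse is an exact identity, which the test suite
checks field-by-field over a thousand generated datasets.

The *annotation format* has required columns `org start end track shape
color` and optional `strand`, `label` and `value`. `shape` is a closed
vocabulary — `box`, `arrow`, `line` — because those are the three glyph
families the figure draws; an unknown word is a hard error rather than a
silent fallback. `color` is `#RRGGBB` or a named color resolvable by R's
color table. Styling lives *per feature*, so a single gene can be
highlighted in a different color than the rest of its track. The `value`
column is an extension beyond the minimal format: on `line`-shaped tracks
(expression-style bars) it scales each bar's height relative to the track
maximum; without it, bars render at a fixed thin height.

Files may arrive gzip- or zip-compressed; the container is detected from
magic bytes, not the file name, and a zip archive with more than one member
is rejected as ambiguous rather than guessing.

## Converters

* **BLAST tabular (outfmt 6)** — fixed 12-column layout; query becomes side
  A, subject side B (swappable). Only the subject side can encode strand
  through coordinate order in this format, so only it is checked for
  inversion. `pident`, `length`, `evalue` and `bitscore` carry over as
  attributes.
* **lastz/BLASTZ general** — the column layout of this format is chosen by
  whoever ran lastz, so ingestion is driven by an explicit `fieldSpec`
  naming each column; `name1 start1 end1 name2 start2 end2 score` is the
  default. `strand2 == "-"` flips the side-B orientation.
* **GFF3** — nine columns, coordinates adopted verbatim (both conventions
  are 1-based inclusive; stated explicitly to prevent off-by-one drift).
  A style map assigns (track, shape, color) per feature type, with `gene`
  defaulting to blue arrows; labels come from `ID` then `Name`. A malformed
  attribute column degrades softly (warning, empty label) because upstream
  GFF3 is frequently sloppy in exactly that column, while start > end is a
  hard error because it indicates corrupt coordinates. The parser is
  intentionally small and local so these two behaviors are controllable;
  the test suite cross-checks it against `rtracklayer` on well-formed
  input.

Converters never drop rows silently: record count equals retained line
count, and anything else is an error with a line number.

## Filtering and the view algebra

Filters are inclusive range predicates `min <= value <= max` on one
attribute, combined as a conjunction and order-preserving. `length` is an
implicit attribute computed as the **maximum** of the two side lengths
(`end - start + 1`): min, mean or side-A length would all be defensible,
but the maximum is the only choice of these that is symmetric in the two
genomes while never calling a region shorter than what is drawn on either
ruler. Because attributes are total (no missing values allowed by the
format), filtering needs no NA semantics.

Viewports are integer windows `[start, end]` on one sequence.

* **zoom(factor)**: new span `= round(span / factor)` (half away from
  zero), floor 1 bp, cap at the sequence length, centered on the old
  midpoint (or an explicit center), then clamped to the sequence. Round
  half away from zero is used everywhere so that left and right edges
  behave symmetrically.
* **pan(fraction)**: shift by `round(fraction * span)`, clamped so the span
  is preserved.
* **reset**: both viewports to `[1, length]`; idempotent.

Zooming in by `k` and back out by `1/k` restores the span to within 1 bp
for factors up to 3: the reconstructed span is `round(span - d*k)` with
`|d| < 1/2` the first rounding error, so the discrepancy is `|round(d*k)|
<= 1` whenever `k <= 3`. The randomized checks therefore draw factors from
[1.25, 3], the range of single zoom steps the view is designed around;
larger factors can accumulate a 2 bp error and should be composed from
smaller steps.

A record is *visible* when it passes the filters and its interval overlaps
**either** panel's viewport. The alternative (AND) was rejected: an
integrated two-genome view must keep drawing a ribbon whose anchor on one
genome has left the window — that is precisely how one notices a
rearrangement crossing the window edge. Clipping is deferred to rendering;
visibility is a pure interval-overlap test, verified against a brute-force
double loop.

Sequence pairs collapse as unordered keys — `(A,B)` and `(B,A)` rows are
one pair — and the first-seen orientation fixes which sequence is the top
panel.

## Rendering model

The figure layout is fixed: panel-A annotation tracks stacked upward above
the A ruler, the synteny zone between the rulers, panel-B tracks stacked
downward below the B ruler. Tracks occupy one lane each in the per-panel
order; hidden tracks occupy no lane. Features within a track share a single
lane and overdraw in file order — stacked sub-lanes were deliberately left
out to keep lane height, and therefore figure height, predictable.

Coordinates map linearly: `x = margin + (pos - start) / span *
drawableWidth`, the left edge of base `pos`. Ribbon corners use the raw
interval endpoints of the record, so the corner x-values are exactly the
linear transform of the record — an invariant the tests check to 1e-6 px.
A record whose sides have opposite orientations draws with its bottom
corners swapped, producing a self-crossing (twisted) ribbon; the tests
verify with an independent segment-intersection oracle that inverted
records, and only those, self-cross. Ribbon fill opacity is fixed at 0.6 so
overlapping blocks remain readable. In lines mode each record is a single
segment joining the two interval midpoints.

Ruler tick steps come from the 1-2-5 ladder: the smallest `{1,2,5} x 10^k`
giving at most `maxTicks` ticks over the span, ticks at multiples of the
step. Labels use thousands separators and a unit (bp below 2 kb spans, kb
below 2 Mb, Mb above) chosen by the span.

Record colors default to a fixed 12-color colorblind-safe categorical
palette cycled by record index; alternatively any attribute can drive a
sequential blue colormap after min-max normalization over the drawn set
(all-equal values map to the midpoint). Both schemes are provided because
block coloring conventions differ between groups; categorical is the
default as it keeps adjacent ribbons distinguishable without implying a
quantitative reading.

## Determinism and export

A scene (the resolved glyph list) is a pure function of (dataset, view
state, canvas); no randomness, no timestamps, no locale-dependent
formatting. SVG export writes one element per glyph in z-order with all
numbers formatted to two decimals, which makes the output **byte-identical**
across runs and processes — the property the reproducibility checks hash.
PNG export rasterizes the same glyph list through the cairo device;
pixel-level identity across rasterizer versions is not promised, so SVG is
the format of record for reproducibility. The view configuration file
(`key=value`) captures pair, regions, filters, mode, track order,
visibility and style overrides, so `plot --config` reproduces a figure
byte-for-byte from the data files alone.

## The synthetic generator

`generateDataset()` emulates the *structure* a synteny browser consumes,
not sequences: for each pair of sequences it places non-nested,
non-overlapping conserved blocks in collinear order on both genomes (the
non-overlap constraint holds within each pair), inverts each block with a
configurable probability, draws attribute values from declared uniform or
log-uniform distributions, and scatters annotation features per track. The
defaults describe a small comparison a user might actually upload: three
500 kb sequences, 12 blocks of 5–30 kb per pair, a 20% inversion rate, and
BLAST-like attributes (identity 75–100%, E-values log-uniform over
1e-60–1e-3). Everything derives from one integer seed; the same seed gives
byte-identical files.

What it does **not** emulate — and what passing tests therefore do not
demonstrate about real data: overlapping or nested blocks, segmental
duplications (many-to-one mappings), inter-block attribute correlation
(real E-values correlate with block length), unequal sequence lengths
within a dataset, and coordinate pathologies of hand-edited files beyond
what the format errors catch. `demoDataset()` is a fixed-seed instance
with the stock three-track styling (genes as blue arrows, expression as
green bars, transposons as black boxes) used throughout the documentation
and the geometry checks.

The randomized suites run at deliberately modest sizes chosen to exercise
the properties densely while staying quick on one CPU: 1,000 six-block
datasets for the round trip (50 of them additionally through gzip and zip
containers), a 500-alignment BLAST file at 20% minus strand for converter
fidelity, 200 random filter sets against the brute-force oracle, 100
viewport draws for the zoom algebra and 1,000 spans for the tick ladder.

## Degenerate inputs and numerical choices

* Empty synteny file: header-only output parses to zero records; a dataset
  with no records but declared sequence lengths still renders rulers.
* 1 bp intervals and viewports are legal; zoom never shrinks below 1 bp.
* Attribute serialization uses shortest round-trip decimal formatting
  (15 significant digits, widened to 17 when needed) so doubles survive
  write→parse bit-exactly.
* Ties in zoom/pan rounding go half away from zero.
* A constant attribute under attribute coloring maps to the colormap
  midpoint rather than dividing by zero.

## Limitations

Two genomes per figure (the state model stores one pair; multi-genome
stacking is out of scope), no interactive event loop, no database-backed
sessions, single-lane tracks, and no MAF/PSL/chain converters. The lastz
converter trusts its `fieldSpec`; it cannot detect a mislabeled column
layout.
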
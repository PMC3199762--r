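# synviewr

Headless, scriptable visualization of pairwise genome synteny from
user-supplied data.

Comparative genomics asks how two genomes are arranged relative to each
other: which regions are conserved, in what order, and where that order
breaks. `synviewr` is for people whose synteny data is their own — a BLAST
or lastz run, a GFF3 of annotations — rather than a dataset pre-loaded in a
public browser. It reads two small tab-delimited interchange formats
(optionally gzip/zip-compressed), converts common aligner outputs into
them, models the browsing state (pair selection, per-genome viewports,
attribute filters, track styling) without any GUI, and renders the classic
dual-genome figure to deterministic SVG or to PNG.

## The model

A *synteny record* links an interval on genome A to an interval on genome
B, with optional numeric attributes (score, E-value, % identity, ...).
Coordinates are 1-based and inclusive; a reverse-orientation interval is
written positionally with start > end, as aligners report minus-strand
hits, and normalized internally to a sorted interval plus an orientation
flag. The rendered figure places genome A's ruler above genome B's, with
each record drawn as a quadrilateral *ribbon* whose top edge is the linear
map of `[start1, end1]` into panel A and bottom edge the map of
`[start2, end2]` into panel B:

    x(pos) = margin + (pos - viewport_start) / span * drawable_width

A record whose two sides have opposite orientations (an inversion) draws as
a self-crossing ribbon. Annotation features occupy one lane per named
track — boxes, strand-pointing arrows, or value-scaled bars — stacked
outward from each ruler. Filters are inclusive range predicates combined as
a conjunction; the implicit `length` attribute of a record is the larger of
its two side lengths. Ruler ticks follow the 1-2-5 ladder
(`{1,2,5} x 10^k`).

See `vignettes/synteny-visualization.Rmd` for the full account of the
formats, the view algebra and the rendering conventions.

## Worked example

```r
library(synviewr)

ds <- demoDataset()      # built-in deterministic 3-genome dataset
ds
#> SyntenyDataset with 36 synteny records, 108 annotation features, 3 sequences
#>   attributes: identity, evalue, score
#>   sequences: orgA (500000 bp), orgB (500000 bp), orgC (500000 bp)
#>   tracks: gene, expression, transposon

listPairs(ds)
#>   seqA seqB
#> 1 orgA orgB
#> 2 orgA orgC
#> 3 orgB orgC

## orgA vs orgB, keeping only strongly conserved regions, transposon
## track hidden on the bottom panel
st <- viewState(ds, pair = c("orgA", "orgB"),
                filters = list(filterSpec("evalue", max = 1e-30)),
                hidden = "b:transposon")
nrow(visibleRecords(ds, st))
#> [1] 9

scene <- renderFigure(ds, st)
scene
#> Scene: 118 glyphs on 1000 x 600 px canvas
#>   arrow:24 bar:24 box:12 ribbon:9 ruler:2 text:7 tick:20 tick_label:20
exportSVG(scene, "figure.svg")
```

Of the pair's 12 conserved regions, 9 pass the E-value cutoff and become
ribbons; the 24 arrows are the gene tracks of both panels, the 24 bars the
expression tracks, and the 12 boxes the transposon track of panel A only —
it is hidden on panel B. Re-running any of this produces byte-identical
SVG.

The same figure from the shell, via the thin wrapper installed at
`inst/scripts/synviewr`:

```sh
Rscript inst/scripts/synviewr simulate --out-prefix demo --demo
Rscript inst/scripts/synviewr plot --synteny demo.synteny.tsv \
    --annotation demo.annotation.tsv --pair orgA,orgB \
    --filter evalue:max=1e-30 --hide-track b:transposon --out figure.svg
```

Subcommands: `convert blast|lastz|gff3`, `validate`, `pairs`, `plot`,
`simulate` (exit codes: 0 ok, 1 usage error, 2 data error). Every plot is
reproducible from a plain-text `key=value` view configuration
(`--config`); see `?readViewConfig`.

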
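## S4 classes for the synteny viewer's central objects.

REQUIRED_RECORD_COLS <- c("seqA", "startA", "endA", "orientA",
                          "seqB", "startB", "endB", "orientB")
FEATURE_COLS <- c("seq", "start", "end", "track", "shape", "color",
                  "strand", "label", "value")

#' An in-memory synteny dataset
#'
#' Holds one user submission: the conserved-region table linking intervals on
#' two sequences, the optional styled annotation features, the display extent
#' of every named sequence, and the ordered numeric attribute names carried by
#' the synteny file.
#'
#' Coordinates are 1-based and inclusive at both ends throughout the package.
#' Intervals are stored normalized (`start <= end`) with an explicit
#' orientation flag (`"forward"` or `"reverse"`); on disk a reverse interval
#' is serialized with start > end.
#'
#' @slot records data.frame with columns `seqA, startA, endA, orientA, seqB,
#'   startB, endB, orientB` plus one numeric column per attribute.
#' @slot features data.frame with columns `seq, start, end, track, shape,
#'   color, strand, label, value` (`value` is an optional per-feature number
#'   used for bar heights; `NA` when absent).
#' @slot sequences data.frame with columns `name`, `length` (display length
#'   in bp, at least the maximum end coordinate observed for that name).
#' @slot attributeNames character, attribute column names in file order.
#'
#' @seealso [buildDataset()], [readSynteny()], [generateDataset()]
#' @export
setClass("SyntenyDataset",
  representation(
    records = "data.frame",
    features = "data.frame",
    sequences = "data.frame",
    attributeNames = "character"
  )
)

validSyntenyDataset <- function(object) {
  msgs <- character(0)
  rec <- object@records
  feat <- object@features
  seqs <- object@sequences

  if (!all(REQUIRED_RECORD_COLS %in% names(rec))) {
    return(paste("records must have columns:",
                 paste(REQUIRED_RECORD_COLS, collapse = ", ")))
  }
  if (!all(FEATURE_COLS %in% names(feat))) {
    return(paste("features must have columns:",
                 paste(FEATURE_COLS, collapse = ", ")))
  }
  if (!all(c("name", "length") %in% names(seqs))) {
    return("sequences must have columns: name, length")
  }

  if (nrow(rec) > 0) {
    if (any(rec$seqA == "") || any(rec$seqB == ""))
      msgs <- c(msgs, "empty sequence name in records")
    if (any(rec$startA < 1) || any(rec$startB < 1))
      msgs <- c(msgs, "record start positions must be >= 1")
    if (any(rec$startA > rec$endA) || any(rec$startB > rec$endB))
      msgs <- c(msgs, "record intervals must be normalized (start <= end)")
    if (!all(rec$orientA %in% c("forward", "reverse")) ||
        !all(rec$orientB %in% c("forward", "reverse")))
      msgs <- c(msgs, "orientations must be 'forward' or 'reverse'")
  }
  attrs <- object@attributeNames
  if (anyDuplicated(attrs))
    msgs <- c(msgs, "attribute names must be unique")
  if ("length" %in% attrs)
    msgs <- c(msgs, "'length' is an implicit attribute and cannot be stored")
  missingAttr <- setdiff(attrs, names(rec))
  if (length(missingAttr) > 0)
    msgs <- c(msgs, paste("attribute columns missing from records:",
                          paste(missingAttr, collapse = ", ")))
  for (a in intersect(attrs, names(rec))) {
    v <- rec[[a]]
    if (!is.numeric(v) || any(!is.finite(v)))
      msgs <- c(msgs, paste0("attribute '", a, "' must be finite numeric"))
  }

  if (nrow(feat) > 0) {
    if (any(feat$track == ""))
      msgs <- c(msgs, "empty track name in features")
    if (!all(feat$shape %in% SHAPE_VOCAB))
      msgs <- c(msgs, paste("feature shapes must be one of:",
                            paste(SHAPE_VOCAB, collapse = ", ")))
    if (!all(isValidColor(feat$color)))
      msgs <- c(msgs, "feature colors must be #RRGGBB or a known color name")
    if (!all(feat$strand %in% STRAND_VOCAB))
      msgs <- c(msgs, "feature strands must be '+', '-' or '.'")
    if (any(feat$start < 1))
      msgs <- c(msgs, "feature start positions must be >= 1")
    if (any(feat$start > feat$end))
      msgs <- c(msgs, "feature intervals must be normalized (start <= end)")
  }

  used <- unique(c(rec$seqA, rec$seqB, feat$seq))
  orphan <- setdiff(used, seqs$name)
  if (length(orphan) > 0)
    msgs <- c(msgs, paste("sequence names missing from sequences table:",
                          paste(orphan, collapse = ", ")))
  for (nm in intersect(used, seqs$name)) {
    maxEnd <- max(c(rec$endA[rec$seqA == nm], rec$endB[rec$seqB == nm],
                    feat$end[feat$seq == nm], 0))
    len <- seqs$length[match(nm, seqs$name)]
    if (len < maxEnd)
      msgs <- c(msgs, paste0("sequence '", nm, "' length (", len,
                             ") is below its maximum end coordinate (",
                             maxEnd, ")"))
  }

  if (length(msgs) == 0) TRUE else msgs
}

setValidity("SyntenyDataset", validSyntenyDataset)

#' A coordinate window on one sequence
#'
#' The currently displayed window `[start, end]` (1-based, inclusive) of one
#' named sequence.
#'
#' @slot seq sequence name.
#' @slot start,end window bounds in bp, `1 <= start <= end`.
#'
#' @seealso [genomeViewport()], [zoomViewport()], [panViewport()]
#' @export
setClass("Viewport",
  representation(seq = "character", start = "numeric", end = "numeric")
)

setValidity("Viewport", function(object) {
  if (length(object@seq) != 1 || object@seq == "")
    return("seq must be a single non-empty name")
  if (length(object@start) != 1 || length(object@end) != 1)
    return("start and end must be single positions")
  if (object@start < 1) return("start must be >= 1")
  if (object@start > object@end) return("start must be <= end")
  TRUE
})

#' Per-panel annotation track order, visibility and style overrides
#'
#' @slot orderA,orderB ordered track names for the top (A) and bottom (B)
#'   panel; tracks are stacked outward from each panel's ruler in this order.
#' @slot visibleA,visibleB named logical vectors; hidden tracks occupy no
#'   lane.
#' @slot styleOverride named list; each element is `list(shape=, color=)`
#'   (either may be NULL) applied to every feature of that track.
#'
#' @export
setClass("TrackState",
  representation(
    orderA = "character", orderB = "character",
    visibleA = "logical", visibleB = "logical",
    styleOverride = "list"
  )
)

setValidity("TrackState", function(object) {
  msgs <- character(0)
  if (anyDuplicated(object@orderA) || anyDuplicated(object@orderB))
    msgs <- c(msgs, "track order must list each track at most once")
  if (is.null(names(object@visibleA)) && length(object@visibleA) > 0)
    msgs <- c(msgs, "visibleA must be a named logical vector")
  if (is.null(names(object@visibleB)) && length(object@visibleB) > 0)
    msgs <- c(msgs, "visibleB must be a named logical vector")
  for (st in object@styleOverride) {
    if (!is.null(st$shape) && !st$shape %in% SHAPE_VOCAB)
      msgs <- c(msgs, "style override shape outside the shape vocabulary")
    if (!is.null(st$color) && !isValidColor(st$color))
      msgs <- c(msgs, "style override color not resolvable")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Complete display state of the dual-genome view
#'
#' The headless equivalent of the browser's controls: which pair of sequences
#' is shown, the viewport of each panel, the active attribute filters, the
#' annotation track state, and whether conserved regions draw as blocks
#' (ribbons) or lines.
#'
#' @slot pair character(2), the selected (top, bottom) sequence names.
#' @slot viewportA,viewportB [Viewport-class] objects for the two panels.
#' @slot filters list of filter specifications built by [filterSpec()].
#' @slot tracks a [TrackState-class] object.
#' @slot displayMode `"blocks"` or `"lines"`.
#'
#' @seealso [viewState()], [resetView()], [visibleRecords()]
#' @export
setClass("ViewState",
  representation(
    pair = "character",
    viewportA = "Viewport", viewportB = "Viewport",
    filters = "list",
    tracks = "TrackState",
    displayMode = "character"
  )
)

setValidity("ViewState", function(object) {
  msgs <- character(0)
  if (length(object@pair) != 2)
    msgs <- c(msgs, "pair must name exactly two sequences")
  if (!object@displayMode %in% c("blocks", "lines"))
    msgs <- c(msgs, "displayMode must be 'blocks' or 'lines'")
  if (length(object@pair) == 2) {
    if (object@viewportA@seq != object@pair[1])
      msgs <- c(msgs, "viewportA must reference the first pair member")
    if (object@viewportB@seq != object@pair[2])
      msgs <- c(msgs, "viewportB must reference the second pair member")
  }
  for (f in object@filters) {
    if (!is.list(f) || is.null(f$attribute))
      msgs <- c(msgs, "each filter must be built by filterSpec()")
    else if (f$min > f$max)
      msgs <- c(msgs, "filter min must be <= max")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Canvas geometry for rendering
#'
#' @slot widthPx,heightPx canvas size in pixels.
#' @slot margin margin on every side, px.
#' @slot panelGap minimum vertical gap between a ruler and the ribbon area,
#'   px.
#' @slot trackLaneHeight height of one annotation track lane, px.
#' @slot fontSize label font size, pt.
#'
#' @seealso [canvasSpec()]
#' @export
setClass("CanvasSpec",
  representation(
    widthPx = "numeric", heightPx = "numeric", margin = "numeric",
    panelGap = "numeric", trackLaneHeight = "numeric", fontSize = "numeric"
  )
)

setValidity("CanvasSpec", function(object) {
  if (object@widthPx <= 0 || object@heightPx <= 0)
    return("canvas dimensions must be positive")
  if (object@widthPx - 2 * object@margin <= 0)
    return("drawable width (widthPx - 2*margin) must be positive")
  if (object@trackLaneHeight <= 0) return("trackLaneHeight must be positive")
  TRUE
})

#' A resolved 2D scene
#'
#' The deterministic geometric output of [renderFigure()]: an ordered list of
#' glyphs (z-order = list order) on a canvas, ready for [exportSVG()] or
#' [exportPNG()]. Each glyph is a list with elements `kind` (one of ruler,
#' tick, tick_label, ribbon, segment, box, arrow, bar, text), `points` (a
#' 2-column x,y matrix in px), `fill`, `stroke`, `opacity`, `source` (the
#' originating record/feature reference) and, for text kinds, `text` and
#' `anchor`.
#'
#' @slot canvas the [CanvasSpec-class] used.
#' @slot glyphs ordered list of glyphs.
#'
#' @export
setClass("Scene",
  representation(canvas = "CanvasSpec", glyphs = "list")
)

setValidity("Scene", function(object) {
  cv <- object@canvas
  for (g in object@glyphs) {
    if (is.null(g$kind) || is.null(g$points))
      return("each glyph needs 'kind' and 'points'")
    p <- g$points
    if (any(p[, 1] < -1e-9) || any(p[, 1] > cv@widthPx + 1e-9) ||
        any(p[, 2] < -1e-9) || any(p[, 2] > cv@heightPx + 1e-9))
      return("glyph coordinates must lie within the canvas after clipping")
    if (g$kind == "ribbon" && nrow(p) != 4)
      return("ribbon glyphs must have exactly 4 corner points")
  }
  TRUE
})
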
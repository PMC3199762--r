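## The browser's state machine, headless: pair selection, attribute filters,
## per-panel viewports (zoom / pan / region / entire genome), track state.

#' Construct a viewport
#'
#' @param seq sequence name.
#' @param start,end 1-based inclusive window bounds.
#' @return a [Viewport-class].
#' @export
genomeViewport <- function(seq, start, end) {
  new("Viewport", seq = seq, start = as.numeric(start), end = as.numeric(end))
}

#' Construct an attribute filter
#'
#' A filter keeps records whose attribute value lies in `[min, max]`
#' (inclusive on both ends); multiple filters combine as a conjunction. The
#' attribute is `"length"` (implicit; the larger of the two side lengths,
#' `end - start + 1`) or any attribute declared in the synteny file.
#'
#' @param attribute attribute name.
#' @param min,max inclusive bounds; default unbounded.
#' @return a filter specification list.
#' @seealso [applyFilters()]
#' @export
filterSpec <- function(attribute, min = -Inf, max = Inf) {
  if (!is.character(attribute) || length(attribute) != 1)
    svUsageError("filter attribute must be a single name")
  if (min > max) svUsageError("filter min must be <= max")
  list(attribute = attribute, min = as.numeric(min), max = as.numeric(max))
}

#' List the sequence pairs present in a dataset
#'
#' Unique unordered pairs observed in the synteny records, ordered by first
#' occurrence; `(A,B)` and `(B,A)` rows collapse to one pair keyed by the
#' first-seen orientation, which also fixes the panel assignment (first name
#' on top).
#'
#' @param dataset a [SyntenyDataset-class].
#' @return data.frame with columns `seqA`, `seqB`, one row per pair.
#' @export
listPairs <- function(dataset) {
  rec <- syntenyRecords(dataset)
  if (nrow(rec) == 0)
    return(data.frame(seqA = character(0), seqB = character(0),
                      stringsAsFactors = FALSE))
  key <- ifelse(rec$seqA <= rec$seqB,
                paste(rec$seqA, rec$seqB, sep = "\r"),
                paste(rec$seqB, rec$seqA, sep = "\r"))
  first <- !duplicated(key)
  data.frame(seqA = rec$seqA[first], seqB = rec$seqB[first],
             stringsAsFactors = FALSE)
}

recordAttributeNames <- function(records) {
  c("length", setdiff(names(records), REQUIRED_RECORD_COLS))
}

#' Evaluate a filterable attribute on records
#'
#' `"length"` is implicit and computed as the larger of the two side lengths
#' (inclusive, `end - start + 1`), making the length filter symmetric in the
#' two genomes; any other name must be a declared attribute column.
#'
#' @param records records data.frame.
#' @param name `"length"` or a declared attribute name.
#' @return numeric vector, one value per record.
#' @export
recordAttribute <- function(records, name) {
  avail <- recordAttributeNames(records)
  if (!name %in% avail)
    svUsageError(paste0("unknown attribute '", name, "'; available: ",
                        paste(avail, collapse = ", ")))
  if (name == "length")
    pmax(records$endA - records$startA + 1, records$endB - records$startB + 1)
  else
    records[[name]]
}

#' Filter records by numeric attributes
#'
#' Keeps records with `min <= value <= max` for every filter (conjunction,
#' inclusive bounds), preserving record order.
#'
#' @param records records data.frame.
#' @param filters list of [filterSpec()] objects.
#' @return the kept subset of `records`.
#' @export
applyFilters <- function(records, filters = list()) {
  keep <- rep(TRUE, nrow(records))
  for (f in filters) {
    v <- recordAttribute(records, f$attribute)
    keep <- keep & v >= f$min & v <= f$max
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Zoom a viewport
#'
#' The new span is `round(old span / factor)` (half away from zero, minimum
#' 1 bp, capped at the sequence length), centered on `center` (default: the
#' old midpoint), then clamped to `[1, seqLength]`. Factors above 1 zoom in;
#' factors below 1 zoom out.
#'
#' @param viewport a [Viewport-class].
#' @param factor zoom factor, > 0.
#' @param center center position in bp; `NULL` keeps the old midpoint.
#' @param seqLength length of the viewport's sequence.
#' @return the new [Viewport-class].
#' @export
zoomViewport <- function(viewport, factor, center = NULL, seqLength) {
  if (factor <= 0) svUsageError("zoom factor must be > 0")
  span <- viewport@end - viewport@start + 1
  newSpan <- min(max(1, roundHalfAway(span / factor)), seqLength)
  if (is.null(center)) center <- (viewport@start + viewport@end) / 2
  newStart <- roundHalfAway(center - (newSpan - 1) / 2)
  newStart <- clampInt(newStart, 1, seqLength - newSpan + 1)
  genomeViewport(viewport@seq, newStart, newStart + newSpan - 1)
}

#' Pan a viewport
#'
#' Shifts the window by `round(fraction * span)` bp (positive = right),
#' clamped to the sequence ends so the span is preserved.
#'
#' @param viewport a [Viewport-class].
#' @param fraction signed fraction of the span to shift by.
#' @param seqLength length of the viewport's sequence.
#' @return the new [Viewport-class].
#' @export
panViewport <- function(viewport, fraction, seqLength) {
  span <- viewport@end - viewport@start + 1
  shift <- roundHalfAway(fraction * span)
  newStart <- clampInt(viewport@start + shift, 1, seqLength - span + 1)
  genomeViewport(viewport@seq, newStart, newStart + span - 1)
}

defaultTrackState <- function(dataset) {
  tracks <- unique(annotationFeatures(dataset)$track)
  vis <- rep(TRUE, length(tracks)); names(vis) <- tracks
  new("TrackState", orderA = tracks, orderB = tracks,
      visibleA = vis, visibleB = vis, styleOverride = list())
}

applyTrackOptions <- function(ts, trackOrder = NULL, hidden = character(0),
                              styles = list()) {
  known <- union(ts@orderA, ts@orderB)
  if (!is.null(trackOrder)) {
    for (panel in names(trackOrder)) {
      ord <- trackOrder[[panel]]
      bad <- setdiff(ord, known)
      if (length(bad) > 0)
        svUsageError(paste0("unknown track(s) in order: ",
                            paste(bad, collapse = ", ")))
      full <- c(ord, setdiff(if (panel == "A") ts@orderA else ts@orderB, ord))
      if (panel == "A") ts@orderA <- full else ts@orderB <- full
    }
  }
  for (h in hidden) {
    parts <- strsplit(h, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      panel <- tolower(parts[1]); track <- parts[2]
      if (!panel %in% c("a", "b"))
        svUsageError(paste0("hide panel must be 'a' or 'b': ", h))
      if (panel == "a") ts@visibleA[track] <- FALSE else ts@visibleB[track] <- FALSE
    } else {
      ts@visibleA[h] <- FALSE
      ts@visibleB[h] <- FALSE
    }
  }
  for (track in names(styles)) ts@styleOverride[[track]] <- styles[[track]]
  validObject(ts)
  ts
}

#' Construct a view state
#'
#' Builds a complete display state for a dataset: the selected pair (default:
#' the first pair listed by [listPairs()]; `(B,A)` matches a stored `(A,B)`
#' pair), full-genome viewports unless regions are given, active filters,
#' annotation track order/visibility/style, and the block/line display mode.
#'
#' @param dataset a [SyntenyDataset-class].
#' @param pair character(2) naming the (top, bottom) sequences; `NULL` picks
#'   the first pair.
#' @param regionA,regionB optional numeric `c(start, end)` restricting each
#'   panel's viewport.
#' @param filters list of [filterSpec()] objects.
#' @param displayMode `"blocks"` (ribbons) or `"lines"` (midpoint segments).
#' @param trackOrder optional list with elements `A` and/or `B`, each an
#'   ordered character vector of track names to put first.
#' @param hidden character vector of tracks to hide, either `"track"` (both
#'   panels) or `"a:track"` / `"b:track"`.
#' @param styles named list of per-track overrides, each
#'   `list(shape=, color=)`.
#' @return a [ViewState-class].
#' @export
viewState <- function(dataset, pair = NULL, regionA = NULL, regionB = NULL,
                      filters = list(), displayMode = "blocks",
                      trackOrder = NULL, hidden = character(0),
                      styles = list()) {
  pairs <- listPairs(dataset)
  if (is.null(pair)) {
    if (nrow(pairs) == 0)
      svStop("dataset has no synteny records; give an explicit pair of declared sequences")
    pair <- c(pairs$seqA[1], pairs$seqB[1])
  } else {
    hit <- which((pairs$seqA == pair[1] & pairs$seqB == pair[2]) |
                 (pairs$seqA == pair[2] & pairs$seqB == pair[1]))
    knownSeqs <- all(pair %in% sequenceInfo(dataset)$name)
    if (length(hit) == 0 && !knownSeqs)
      svStop(paste0("unknown pair '", pair[1], ",", pair[2],
                    "'; available pairs: ",
                    paste(paste(pairs$seqA, pairs$seqB, sep = ","),
                          collapse = "; ")))
  }
  lenA <- sequenceLength(dataset, pair[1])
  lenB <- sequenceLength(dataset, pair[2])
  mkVp <- function(seq, len, region) {
    if (is.null(region)) return(genomeViewport(seq, 1, len))
    if (region[1] > region[2])
      svUsageError("region start must be <= end")
    genomeViewport(seq, clampInt(region[1], 1, len),
                   clampInt(region[2], 1, len))
  }
  for (f in filters) recordAttribute(syntenyRecords(dataset), f$attribute)
  ts <- applyTrackOptions(defaultTrackState(dataset), trackOrder, hidden,
                          styles)
  st <- new("ViewState",
            pair = pair,
            viewportA = mkVp(pair[1], lenA, regionA),
            viewportB = mkVp(pair[2], lenB, regionB),
            filters = filters,
            tracks = ts,
            displayMode = displayMode)
  validObject(st)
  st
}

#' Reset both viewports to the entire genomes
#'
#' @param state a [ViewState-class].
#' @param dataset the [SyntenyDataset-class] the state belongs to.
#' @return the state with both viewports spanning `[1, length]`.
#' @export
resetView <- function(state, dataset) {
  state@viewportA <- genomeViewport(state@pair[1], 1,
                                    sequenceLength(dataset, state@pair[1]))
  state@viewportB <- genomeViewport(state@pair[2], 1,
                                    sequenceLength(dataset, state@pair[2]))
  state
}

## Records of the selected pair, oriented so side A is the top panel.
recordsForPair <- function(records, pair) {
  direct <- records$seqA == pair[1] & records$seqB == pair[2]
  flipped <- records$seqA == pair[2] & records$seqB == pair[1]
  out <- records[direct | flipped, , drop = FALSE]
  flip <- flipped[direct | flipped]
  if (any(flip)) {
    tmp <- out[flip, c("seqB", "startB", "endB", "orientB"), drop = FALSE]
    out[flip, c("seqB", "startB", "endB", "orientB")] <-
      out[flip, c("seqA", "startA", "endA", "orientA")]
    out[flip, c("seqA", "startA", "endA", "orientA")] <- tmp
  }
  rownames(out) <- NULL
  out
}

#' Records visible in the current view
#'
#' Restricts the dataset's records to the selected pair (orienting them so
#' side A is the top panel), applies the active filters, and keeps records
#' whose side-A interval overlaps viewport A OR whose side-B interval
#' overlaps viewport B (inclusive-coordinate overlap). Either-side overlap
#' keeps ribbons that leave the window on one genome — e.g. rearrangements
#' crossing the window edge — visible. Intervals are not clipped here;
#' clipping is a rendering concern.
#'
#' @param dataset a [SyntenyDataset-class].
#' @param state a [ViewState-class].
#' @return the visible subset of the pair's records, in record order.
#' @export
visibleRecords <- function(dataset, state) {
  rec <- recordsForPair(syntenyRecords(dataset), state@pair)
  rec <- applyFilters(rec, state@filters)
  vA <- state@viewportA; vB <- state@viewportB
  keep <- (rec$startA <= vA@end & rec$endA >= vA@start) |
          (rec$startB <= vB@end & rec$endB >= vB@start)
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- plain-text view configuration (key=value) --------------------------

parseRegionExpr <- function(s) {
  m <- regmatches(s, regexec("^(.+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4)
    svUsageError(paste0("bad region '", s, "'; expected SEQ:START-END"))
  list(seq = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

parseFilterExpr <- function(s) {
  i <- regexpr(":", s, fixed = TRUE)
  if (i < 0) svUsageError(paste0("bad filter '", s,
                                 "'; expected attr:min=X,max=Y"))
  attr <- substr(s, 1, i - 1)
  lo <- -Inf; hi <- Inf
  for (part in strsplit(substring(s, i + 1), ",", fixed = TRUE)[[1]]) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || !kv[1] %in% c("min", "max"))
      svUsageError(paste0("bad filter bound '", part, "' in '", s, "'"))
    v <- suppressWarnings(as.numeric(kv[2]))
    if (is.na(v)) svUsageError(paste0("bad filter value '", kv[2], "'"))
    if (kv[1] == "min") lo <- v else hi <- v
  }
  filterSpec(attr, lo, hi)
}

parseStyleExpr <- function(s) {
  i <- regexpr(":", s, fixed = TRUE)
  if (i < 0) svUsageError(paste0("bad style '", s,
                                 "'; expected track:shape=X,color=Y"))
  track <- substr(s, 1, i - 1)
  st <- list(shape = NULL, color = NULL)
  for (part in strsplit(substring(s, i + 1), ",", fixed = TRUE)[[1]]) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2 || !kv[1] %in% c("shape", "color"))
      svUsageError(paste0("bad style item '", part, "' in '", s, "'"))
    st[[kv[1]]] <- kv[2]
  }
  stats::setNames(list(st), track)
}

#' Read / write a view configuration file
#'
#' A plain-text `key=value` format capturing everything needed to reproduce
#' a plot: `pair=A,B`, optional `region_a=SEQ:START-END` / `region_b=...`,
#' repeatable `filter=attr:min=X,max=Y`, `mode=blocks|lines`, optional
#' `track_order_a=` / `track_order_b=` (comma-separated), repeatable
#' `hide=track` or `hide=a:track` / `hide=b:track`, and repeatable
#' `style=track:shape=X,color=Y`. Lines starting with `#` are comments.
#'
#' @param path configuration file path.
#' @return `readViewConfig`: a named list of view options suitable for
#'   [viewStateFromOptions()].
#' @export
readViewConfig <- function(path) {
  lines <- openMaybeCompressed(path)
  opts <- list(filters = list(), hidden = character(0), styles = list(),
               trackOrder = NULL)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    i <- regexpr("=", s, fixed = TRUE)
    if (i < 0) svFormatError(paste0("config line ", ln, ": expected key=value"))
    key <- substr(s, 1, i - 1); val <- substring(s, i + 1)
    switch(key,
      pair = { opts$pair <- strsplit(val, ",", fixed = TRUE)[[1]] },
      region_a = { opts$regionA <- parseRegionExpr(val) },
      region_b = { opts$regionB <- parseRegionExpr(val) },
      filter = { opts$filters <- c(opts$filters, list(parseFilterExpr(val))) },
      mode = { opts$mode <- val },
      track_order_a = {
        opts$trackOrder$A <- strsplit(val, ",", fixed = TRUE)[[1]]
      },
      track_order_b = {
        opts$trackOrder$B <- strsplit(val, ",", fixed = TRUE)[[1]]
      },
      hide = { opts$hidden <- c(opts$hidden, val) },
      style = { opts$styles <- c(opts$styles, parseStyleExpr(val)) },
      scheme = { opts$scheme <- val },
      svFormatError(paste0("config line ", ln, ": unknown key '", key, "'"))
    )
  }
  opts
}

#' @rdname readViewConfig
#' @param state a [ViewState-class] to serialize.
#' @param scheme optional color scheme string to record
#'   (`"categorical"` or `"attribute:<name>"`).
#' @return `writeViewConfig`: the written lines, invisibly.
#' @export
writeViewConfig <- function(state, path, scheme = NULL) {
  lines <- c(
    paste0("pair=", state@pair[1], ",", state@pair[2]),
    paste0("region_a=", state@viewportA@seq, ":",
           formatCoord(state@viewportA@start), "-",
           formatCoord(state@viewportA@end)),
    paste0("region_b=", state@viewportB@seq, ":",
           formatCoord(state@viewportB@start), "-",
           formatCoord(state@viewportB@end)),
    vapply(state@filters, function(f) {
      bounds <- c(if (is.finite(f$min)) paste0("min=", formatNumeric(f$min)),
                  if (is.finite(f$max)) paste0("max=", formatNumeric(f$max)))
      paste0("filter=", f$attribute, ":", paste(bounds, collapse = ","))
    }, character(1)),
    paste0("mode=", state@displayMode)
  )
  ts <- state@tracks
  if (length(ts@orderA) > 0)
    lines <- c(lines, paste0("track_order_a=", paste(ts@orderA, collapse = ",")),
               paste0("track_order_b=", paste(ts@orderB, collapse = ",")))
  hiddenA <- names(ts@visibleA)[!ts@visibleA]
  hiddenB <- names(ts@visibleB)[!ts@visibleB]
  both <- intersect(hiddenA, hiddenB)
  lines <- c(lines,
             vapply(both, function(t) paste0("hide=", t), character(1)),
             vapply(setdiff(hiddenA, both),
                    function(t) paste0("hide=a:", t), character(1)),
             vapply(setdiff(hiddenB, both),
                    function(t) paste0("hide=b:", t), character(1)))
  for (track in names(ts@styleOverride)) {
    st <- ts@styleOverride[[track]]
    items <- c(if (!is.null(st$shape)) paste0("shape=", st$shape),
               if (!is.null(st$color)) paste0("color=", st$color))
    lines <- c(lines, paste0("style=", track, ":",
                             paste(items, collapse = ",")))
  }
  if (!is.null(scheme)) lines <- c(lines, paste0("scheme=", scheme))
  writeLines(lines, path, sep = "\n")
  invisible(lines)
}

#' Build a view state from parsed options
#'
#' @param dataset a [SyntenyDataset-class].
#' @param opts named list as returned by [readViewConfig()].
#' @return a [ViewState-class].
#' @export
viewStateFromOptions <- function(dataset, opts) {
  pair <- opts$pair
  regionA <- NULL; regionB <- NULL
  if (!is.null(opts$regionA)) {
    regionA <- c(opts$regionA$start, opts$regionA$end)
    if (is.null(pair)) pair <- c(opts$regionA$seq, NA)
  }
  if (!is.null(opts$regionB)) regionB <- c(opts$regionB$start, opts$regionB$end)
  if (!is.null(pair) && anyNA(pair))
    svUsageError("region_a without pair cannot determine the pair")
  if (!is.null(opts$regionA) && !is.null(pair) &&
      opts$regionA$seq != pair[1])
    svUsageError("region_a sequence does not match the first pair member")
  if (!is.null(opts$regionB) && !is.null(pair) &&
      opts$regionB$seq != pair[2])
    svUsageError("region_b sequence does not match the second pair member")
  viewState(dataset, pair = pair, regionA = regionA, regionB = regionB,
            filters = opts$filters %||% list(),
            displayMode = opts$mode %||% "blocks",
            trackOrder = opts$trackOrder,
            hidden = opts$hidden %||% character(0),
            styles = opts$styles %||% list())
}
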
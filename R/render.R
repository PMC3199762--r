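## Deterministic 2D scene construction: rulers, synteny ribbons/lines,
## annotation tracks. Identical (dataset, state, canvas) input yields an
## identical glyph list.

RIBBON_OPACITY <- 0.6
TICK_LEN <- 6

## 12-color colorblind-safe categorical palette (Tol muted, extended).
PALETTE12 <- c("#332288", "#88CCEE", "#44AA99", "#117733", "#999933",
               "#DDCC77", "#CC6677", "#882255", "#AA4499", "#6699CC",
               "#661100", "#888888")

## Endpoints of the sequential colormap used for attribute coloring.
SEQ_RAMP <- c("#DEEBF7", "#08519C")

#' Construct a canvas specification
#'
#' @param widthPx,heightPx canvas size in pixels.
#' @param margin margin on every side, px.
#' @param panelGap vertical gap between each ruler and the ribbon area, px.
#' @param trackLaneHeight height of one annotation lane, px.
#' @param fontSize label font size, pt.
#' @return a [CanvasSpec-class].
#' @export
canvasSpec <- function(widthPx = 1000, heightPx = 600, margin = 60,
                       panelGap = 22, trackLaneHeight = 18, fontSize = 11) {
  cv <- new("CanvasSpec", widthPx = widthPx, heightPx = heightPx,
            margin = margin, panelGap = panelGap,
            trackLaneHeight = trackLaneHeight, fontSize = fontSize)
  validObject(cv)
  cv
}

drawableWidth <- function(canvas) canvas@widthPx - 2 * canvas@margin

#' Map a genomic position to a canvas x coordinate
#'
#' Linear map of the inclusive base interval: the left edge of base `pos`
#' lands at `margin + (pos - start) / span * drawableWidth`. Positions
#' outside the viewport extrapolate linearly; clipping happens later.
#'
#' @param pos position(s) in bp.
#' @param viewport a [Viewport-class].
#' @param canvas a [CanvasSpec-class].
#' @return x position(s) in px (real-valued).
#' @export
toCanvasX <- function(pos, viewport, canvas) {
  span <- viewport@end - viewport@start + 1
  canvas@margin + (pos - viewport@start) / span * drawableWidth(canvas)
}

#' @rdname toCanvasX
#' @param x canvas x coordinate(s) in px.
#' @return `toBp`: position(s) in bp (real-valued; the exact linear
#'   inverse of `toCanvasX`).
#' @export
toBp <- function(x, viewport, canvas) {
  span <- viewport@end - viewport@start + 1
  viewport@start + (x - canvas@margin) / drawableWidth(canvas) * span
}

#' Ruler tick positions and labels
#'
#' The tick step is the smallest value on the 1-2-5 ladder (`{1,2,5} x
#' 10^k`) that yields at most `maxTicks` ticks across the viewport; ticks
#' sit at multiples of the step inside the viewport. Labels carry thousands
#' separators and a unit suffix (bp, kb or Mb) chosen by the span.
#'
#' @param viewport a [Viewport-class].
#' @param maxTicks maximum number of ticks, >= 2.
#' @return data.frame with columns `bp` (tick position) and `label`.
#' @export
rulerTicks <- function(viewport, maxTicks = 10) {
  if (maxTicks < 2) svUsageError("maxTicks must be >= 2")
  start <- viewport@start; end <- viewport@end
  step <- NA
  for (k in 0:15) {
    for (m in c(1, 2, 5)) {
      cand <- m * 10^k
      n <- floor(end / cand) - ceiling(start / cand) + 1
      if (n <= maxTicks) { step <- cand; break }
    }
    if (!is.na(step)) break
  }
  bp <- seq(ceiling(start / step) * step, floor(end / step) * step, by = step)
  span <- end - start + 1
  if (span >= 2e6) { div <- 1e6; unit <- "Mb" }
  else if (span >= 2e3) { div <- 1e3; unit <- "kb" }
  else { div <- 1; unit <- "bp" }
  label <- vapply(bp, function(p) {
    v <- p / div
    paste0(format(v, big.mark = ",", scientific = FALSE, trim = TRUE),
           " ", unit)
  }, character(1))
  data.frame(bp = bp, label = label, stringsAsFactors = FALSE)
}

mkGlyph <- function(kind, points, fill = NA_character_,
                    stroke = NA_character_, opacity = 1, source = NULL,
                    text = NULL, anchor = "middle", strokeWidth = 1) {
  list(kind = kind, points = points, fill = fill, stroke = stroke,
       opacity = opacity, source = source, text = text, anchor = anchor,
       strokeWidth = strokeWidth)
}

## Vertical layout of the figure: lane bands, ruler baselines, ribbon zone.
sceneLayout <- function(state, canvas) {
  ts <- state@tracks
  lanesA <- ts@orderA[ts@visibleA[ts@orderA]]
  lanesB <- ts@orderB[ts@visibleB[ts@orderB]]
  lane <- canvas@trackLaneHeight
  yRulerA <- canvas@margin + length(lanesA) * lane + 8
  yRulerB <- canvas@heightPx - canvas@margin - length(lanesB) * lane - 8
  yRibbonTop <- yRulerA + canvas@panelGap
  yRibbonBot <- yRulerB - canvas@panelGap
  if (yRibbonBot - yRibbonTop < 20)
    svStop("canvas too small for the requested tracks; increase heightPx")
  ## lane i is stacked outward from each ruler
  laneBandA <- function(i) {
    bottom <- yRulerA - 8 - (i - 1) * lane
    c(top = bottom - lane + 3, bottom = bottom)
  }
  laneBandB <- function(i) {
    top <- yRulerB + 8 + (i - 1) * lane
    c(top = top, bottom = top + lane - 3)
  }
  list(lanesA = lanesA, lanesB = lanesB, yRulerA = yRulerA,
       yRulerB = yRulerB, yRibbonTop = yRibbonTop, yRibbonBot = yRibbonBot,
       laneBandA = laneBandA, laneBandB = laneBandB)
}

#' Colors for a set of drawn records
#'
#' `"categorical"` cycles a fixed 12-color colorblind-safe palette by record
#' index. `"attribute:<name>"` min-max normalizes the named attribute over
#' the drawn set and maps it through a sequential blue colormap; when all
#' values are equal every record gets the colormap midpoint.
#'
#' @param records records data.frame (the drawn set).
#' @param scheme `"categorical"` or `"attribute:<name>"`.
#' @return character vector of hex colors, one per record.
#' @export
colorFor <- function(records, scheme = "categorical") {
  n <- nrow(records)
  if (identical(scheme, "categorical"))
    return(PALETTE12[(seq_len(n) - 1) %% length(PALETTE12) + 1])
  if (!startsWith(scheme, "attribute:"))
    svUsageError(paste0("unknown color scheme '", scheme, "'"))
  attrName <- substring(scheme, nchar("attribute:") + 1)
  v <- recordAttribute(records, attrName)
  rng <- range(v)
  t <- if (rng[1] == rng[2]) rep(0.5, n) else (v - rng[1]) / (rng[2] - rng[1])
  ramp <- grDevices::colorRamp(SEQ_RAMP)
  m <- ramp(t)
  tolower(grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255))
}

clipX <- function(x, canvas) {
  pmin(pmax(x, canvas@margin), canvas@widthPx - canvas@margin)
}

#' Synteny glyphs for the drawn records
#'
#' In blocks mode each record becomes one 4-corner ribbon: the top edge is
#' its side-A interval mapped on panel A, the bottom edge its side-B
#' interval on panel B. A record whose two sides have opposite orientations
#' (an inversion) draws as a twisted ribbon: top-left joins bottom-right.
#' In lines mode each record becomes one segment joining the interval
#' midpoints. X extents are clipped to the drawable area.
#'
#' @param records drawn records (already filtered and visibility-tested).
#' @param state a [ViewState-class].
#' @param canvas a [CanvasSpec-class].
#' @param scheme color scheme passed to [colorFor()].
#' @return list of glyphs.
#' @export
layoutSynteny <- function(records, state, canvas, scheme = "categorical") {
  lay <- sceneLayout(state, canvas)
  yT <- lay$yRibbonTop; yB <- lay$yRibbonBot
  cols <- colorFor(records, scheme)
  glyphs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    xa1 <- clipX(toCanvasX(r$startA, state@viewportA, canvas), canvas)
    xa2 <- clipX(toCanvasX(r$endA, state@viewportA, canvas), canvas)
    xb1 <- clipX(toCanvasX(r$startB, state@viewportB, canvas), canvas)
    xb2 <- clipX(toCanvasX(r$endB, state@viewportB, canvas), canvas)
    inverted <- xor(r$orientA == "reverse", r$orientB == "reverse")
    if (state@displayMode == "blocks") {
      pts <- if (inverted) {
        ## twisted ribbon: top-left joins bottom-right
        rbind(c(xa1, yT), c(xa2, yT), c(xb1, yB), c(xb2, yB))
      } else {
        rbind(c(xa1, yT), c(xa2, yT), c(xb2, yB), c(xb1, yB))
      }
      glyphs[[i]] <- mkGlyph("ribbon", pts, fill = cols[i],
                             opacity = RIBBON_OPACITY,
                             source = list(type = "record", index = i,
                                           inverted = inverted))
    } else {
      pts <- rbind(c((xa1 + xa2) / 2, yT), c((xb1 + xb2) / 2, yB))
      glyphs[[i]] <- mkGlyph("segment", pts, stroke = cols[i],
                             strokeWidth = 1.5,
                             source = list(type = "record", index = i,
                                           inverted = inverted))
    }
  }
  glyphs
}

## Ruler + tick + tick-label glyphs for one panel.
rulerGlyphs <- function(viewport, canvas, y, panel, maxTicks = 10) {
  x0 <- canvas@margin; x1 <- canvas@widthPx - canvas@margin
  down <- panel == "A"        # panel A ticks point into the ribbon area
  glyphs <- list(mkGlyph("ruler", rbind(c(x0, y), c(x1, y)),
                         stroke = "#000000", strokeWidth = 1.5,
                         source = list(type = "ruler", panel = panel)))
  ticks <- rulerTicks(viewport, maxTicks)
  for (i in seq_len(nrow(ticks))) {
    tx <- toCanvasX(ticks$bp[i], viewport, canvas)
    ty <- if (down) y + TICK_LEN else y - TICK_LEN
    glyphs <- c(glyphs, list(
      mkGlyph("tick", rbind(c(tx, y), c(tx, ty)), stroke = "#000000",
              source = list(type = "tick", panel = panel, bp = ticks$bp[i])),
      mkGlyph("tick_label",
              rbind(c(tx, if (down) ty + canvas@fontSize else ty - 3)),
              fill = "#000000", text = ticks$label[i], anchor = "middle",
              source = list(type = "tick_label", panel = panel,
                            bp = ticks$bp[i]))
    ))
  }
  glyphs
}

resolveTrackStyle <- function(shape, color, override) {
  if (!is.null(override)) {
    if (!is.null(override$shape)) shape <- override$shape
    if (!is.null(override$color)) color <- override$color
  }
  list(shape = shape, color = color)
}

featureGlyph <- function(x1, x2, band, shape, colorHex, strand, value,
                         valueMax, source) {
  yT <- band["top"]; yB <- band["bottom"]
  if (shape == "arrow" && strand %in% c("+", "-")) {
    head <- min(7, x2 - x1)
    yM <- (yT + yB) / 2
    pts <- if (strand == "+") {
      rbind(c(x1, yT), c(x2 - head, yT), c(x2, yM), c(x2 - head, yB),
            c(x1, yB))
    } else {
      rbind(c(x2, yT), c(x1 + head, yT), c(x1, yM), c(x1 + head, yB),
            c(x2, yB))
    }
    return(mkGlyph("arrow", pts, fill = colorHex, source = source))
  }
  if (shape == "line") {
    h <- if (!is.na(value) && is.finite(valueMax) && valueMax > 0) {
      max(2, (yB - yT - 2) * min(1, max(0, value / valueMax)))
    } else 3
    pts <- rbind(c(x1, yB - h), c(x2, yB - h), c(x2, yB), c(x1, yB))
    return(mkGlyph("bar", pts, fill = colorHex, source = source))
  }
  ## box, and arrow with strand "."
  pts <- rbind(c(x1, yT), c(x2, yT), c(x2, yB), c(x1, yB))
  mkGlyph("box", pts, fill = colorHex, source = source)
}

#' Annotation track glyphs for one panel
#'
#' Tracks stack outward from the panel's ruler in the track order for that
#' panel (panel A above its ruler, panel B below). Hidden tracks occupy no
#' lane. Each feature draws as a box (filled rectangle), an arrow (rectangle
#' with a strand-pointing head; strand `"."` renders as a box) or a bar
#' (`line` shape; thin by default, or height-scaled by the feature's `value`
#' relative to the track's maximum). Track-level style overrides replace the
#' per-feature shape/color. Features are clipped to the viewport; features
#' wholly outside it produce no glyph.
#'
#' @param features features of the panel's sequence.
#' @param state a [ViewState-class].
#' @param panel `"A"` or `"B"`.
#' @param canvas a [CanvasSpec-class].
#' @return list of glyphs.
#' @export
layoutTracks <- function(features, state, panel = c("A", "B"), canvas) {
  panel <- match.arg(panel)
  lay <- sceneLayout(state, canvas)
  viewport <- if (panel == "A") state@viewportA else state@viewportB
  lanes <- if (panel == "A") lay$lanesA else lay$lanesB
  bandOf <- if (panel == "A") lay$laneBandA else lay$laneBandB
  glyphs <- list()
  for (i in seq_along(lanes)) {
    track <- lanes[i]
    band <- bandOf(i)
    sub <- features[features$track == track, , drop = FALSE]
    keep <- sub$start <= viewport@end & sub$end >= viewport@start
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) == 0) next
    override <- state@tracks@styleOverride[[track]]
    valueMax <- suppressWarnings(max(sub$value, na.rm = TRUE))
    for (j in seq_len(nrow(sub))) {
      f <- sub[j, ]
      st <- resolveTrackStyle(f$shape, f$color, override)
      x1 <- clipX(toCanvasX(max(f$start, viewport@start), viewport, canvas),
                  canvas)
      x2 <- clipX(toCanvasX(min(f$end, viewport@end), viewport, canvas),
                  canvas)
      glyphs <- c(glyphs, list(featureGlyph(
        x1, x2, band, st$shape, colorToHex(st$color), f$strand, f$value,
        valueMax,
        source = list(type = "feature", panel = panel, track = track,
                      label = f$label)
      )))
    }
  }
  glyphs
}

#' Render the integrated dual-genome figure
#'
#' Assembles the full scene in a fixed z-order: panel-A tracks, panel-A
#' ruler and ticks, synteny glyphs, panel-B ruler and ticks, panel-B tracks,
#' then text labels (sequence name left of each ruler, track name left of
#' each lane). The output is fully deterministic.
#'
#' @param dataset a [SyntenyDataset-class].
#' @param state a [ViewState-class].
#' @param canvas a [CanvasSpec-class].
#' @param scheme color scheme for synteny glyphs (see [colorFor()]).
#' @param maxTicks maximum ruler ticks per panel.
#' @return a [Scene-class].
#' @export
renderFigure <- function(dataset, state, canvas = canvasSpec(),
                         scheme = "categorical", maxTicks = 10) {
  lay <- sceneLayout(state, canvas)
  feat <- annotationFeatures(dataset)
  featA <- feat[feat$seq == state@pair[1], , drop = FALSE]
  featB <- feat[feat$seq == state@pair[2], , drop = FALSE]
  vis <- visibleRecords(dataset, state)

  labelGlyphs <- list()
  labelX <- max(4, canvas@margin - 6)
  addLabel <- function(text, y) {
    mkGlyph("text", rbind(c(labelX, y)), fill = "#000000", text = text,
            anchor = "end", source = list(type = "label"))
  }
  labelGlyphs <- c(
    list(addLabel(state@pair[1], lay$yRulerA - 4)),
    list(addLabel(state@pair[2], lay$yRulerB + canvas@fontSize)),
    lapply(seq_along(lay$lanesA), function(i) {
      b <- lay$laneBandA(i)
      addLabel(lay$lanesA[i], (b["top"] + b["bottom"]) / 2 + 4)
    }),
    lapply(seq_along(lay$lanesB), function(i) {
      b <- lay$laneBandB(i)
      addLabel(lay$lanesB[i], (b["top"] + b["bottom"]) / 2 + 4)
    })
  )

  glyphs <- c(
    layoutTracks(featA, state, "A", canvas),
    rulerGlyphs(state@viewportA, canvas, lay$yRulerA, "A", maxTicks),
    layoutSynteny(vis, state, canvas, scheme),
    rulerGlyphs(state@viewportB, canvas, lay$yRulerB, "B", maxTicks),
    layoutTracks(featB, state, "B", canvas),
    labelGlyphs
  )
  scene <- new("Scene", canvas = canvas, glyphs = glyphs)
  validObject(scene)
  scene
}
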
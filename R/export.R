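## Scene export: byte-deterministic SVG 1.1 and rasterized PNG.

fmt2 <- function(x) sprintf("%.2f", x)

svgColor <- function(x) if (is.na(x)) "none" else colorToHex(x)

glyphToSVG <- function(g, canvas) {
  kind <- g$kind
  p <- g$points
  if (kind %in% c("ruler", "tick", "segment")) {
    sprintf(
      '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
      fmt2(p[1, 1]), fmt2(p[1, 2]), fmt2(p[2, 1]), fmt2(p[2, 2]),
      svgColor(g$stroke), fmt2(g$strokeWidth), fmt2(g$opacity)
    )
  } else if (kind %in% c("ribbon", "box", "arrow", "bar")) {
    pts <- paste(fmt2(p[, 1]), fmt2(p[, 2]), sep = ",", collapse = " ")
    sprintf('<polygon points="%s" fill="%s" fill-opacity="%s" stroke="none"/>',
            pts, svgColor(g$fill), fmt2(g$opacity))
  } else if (kind %in% c("tick_label", "text")) {
    anchor <- switch(g$anchor, start = "start", end = "end", "middle")
    sprintf(
      '<text x="%s" y="%s" font-size="%s" font-family="Helvetica" text-anchor="%s" fill="%s">%s</text>',
      fmt2(p[1, 1]), fmt2(p[1, 2]), fmt2(canvas@fontSize), anchor,
      svgColor(g$fill), xmlEscape(g$text)
    )
  } else {
    svStop(paste0("unknown glyph kind '", kind, "'"))
  }
}

#' Export a scene as SVG
#'
#' Writes SVG 1.1 with a fixed element order (one element per glyph after a
#' fixed two-element chrome: the root and a white background rectangle),
#' fixed numeric formatting (2 decimals) and no timestamps, so identical
#' scenes produce byte-identical files across runs and processes.
#'
#' @param scene a [Scene-class].
#' @param path output path; `NULL` returns the SVG lines instead.
#' @return the SVG lines, invisibly when `path` is given.
#' @export
exportSVG <- function(scene, path = NULL) {
  cv <- sceneCanvas(scene)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%d" height="%d" viewBox="0 0 %d %d">',
      as.integer(cv@widthPx), as.integer(cv@heightPx),
      as.integer(cv@widthPx), as.integer(cv@heightPx)
    ),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
            as.integer(cv@widthPx), as.integer(cv@heightPx)),
    vapply(sceneGlyphs(scene), glyphToSVG, character(1), canvas = cv),
    "</svg>"
  )
  if (is.null(path)) return(lines)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(lines)
}

#' Export a scene as PNG
#'
#' Rasterizes the same glyph list the SVG export writes, via the cairo PNG
#' device. The image is `widthPx` x `heightPx` device pixels with the given
#' resolution stamped in the file. Byte-level determinism across rasterizer
#' versions is not promised; use [exportSVG()] where reproducibility
#' matters.
#'
#' @param scene a [Scene-class].
#' @param path output path.
#' @param dpi nominal resolution.
#' @return `path`, invisibly.
#' @export
exportPNG <- function(scene, path, dpi = 96) {
  cv <- sceneCanvas(scene)
  grDevices::png(path, width = cv@widthPx, height = cv@heightPx, res = dpi,
                 type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, cv@widthPx), ylim = c(cv@heightPx, 0))
  cex <- cv@fontSize / 12
  for (g in sceneGlyphs(scene)) {
    p <- g$points
    if (g$kind %in% c("ruler", "tick", "segment")) {
      graphics::segments(p[1, 1], p[1, 2], p[2, 1], p[2, 2],
                         col = grDevices::adjustcolor(g$stroke,
                                                      alpha.f = g$opacity),
                         lwd = g$strokeWidth)
    } else if (g$kind %in% c("ribbon", "box", "arrow", "bar")) {
      graphics::polygon(p[, 1], p[, 2],
                        col = grDevices::adjustcolor(g$fill,
                                                     alpha.f = g$opacity),
                        border = NA)
    } else {
      adj <- switch(g$anchor, start = 0, end = 1, 0.5)
      graphics::text(p[1, 1], p[1, 2], labels = g$text, adj = c(adj, 0),
                     col = g$fill, cex = cex)
    }
  }
  invisible(path)
}
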
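test_that("the bp-to-px map is linear, anchored and invertible", {
  cv <- canvasSpec(widthPx = 800, heightPx = 600, margin = 0)
  vp <- genomeViewport("s", 1, 1000)
  expect_equal(toCanvasX(1, vp, cv), 0)
  expect_equal(toCanvasX(501, vp, cv), 400)   # (501-1)/1000 * 800
  pos <- c(1, 17, 250, 999.5, 1000)
  expect_equal(toBp(toCanvasX(pos, vp, cv), vp, cv), pos)
})

test_that("ruler ticks follow the 1-2-5 ladder and respect maxTicks", {
  t1 <- rulerTicks(genomeViewport("s", 1, 1000), 11)
  expect_equal(t1$bp, seq(100, 1000, by = 100))
  expect_equal(t1$label[1], "100 bp")
  expect_equal(t1$label[10], "1,000 bp")

  t2 <- rulerTicks(genomeViewport("s", 1, 7), 10)
  expect_equal(t2$bp, 1:7)    # step 1

  set.seed(31)
  for (i in 1:200) {
    s <- sample(1e7, 1)
    e <- s + sample(1e6, 1)
    maxTicks <- sample(2:15, 1)
    ticks <- rulerTicks(genomeViewport("s", s, e), maxTicks)
    expect_lte(nrow(ticks), maxTicks)
    step <- if (nrow(ticks) > 1) diff(ticks$bp[1:2]) else NA
    want <- bruteTickStep(s, e, maxTicks)
    if (!is.na(step)) expect_equal(step, want)
    ## every tick is a multiple of the step, inside the viewport
    expect_true(all(ticks$bp >= s & ticks$bp <= e))
    expect_true(all(ticks$bp %% want == 0))
  }
})

test_that("unit suffix follows the span", {
  expect_match(rulerTicks(genomeViewport("s", 1, 5e6), 10)$label[1], "Mb$")
  expect_match(rulerTicks(genomeViewport("s", 1, 5e4), 10)$label[1], "kb$")
  expect_match(rulerTicks(genomeViewport("s", 1, 500), 10)$label[1], "bp$")
})

mkTwoRecordDs <- function() {
  rec <- data.frame(
    seqA = "A", startA = c(100, 600), endA = c(300, 800),
    orientA = "forward",
    seqB = "B", startB = c(150, 650), endB = c(350, 850),
    orientB = c("forward", "reverse"),
    stringsAsFactors = FALSE)
  buildDataset(rec, seqLengths = c(A = 1000, B = 1000))
}

test_that("ribbons map record endpoints; inversions twist", {
  ds <- mkTwoRecordDs()
  st <- viewState(ds)
  cv <- canvasSpec()
  vis <- visibleRecords(ds, st)
  glyphs <- layoutSynteny(vis, st, cv)
  expect_equal(length(glyphs), nrow(vis))

  g1 <- glyphs[[1]]   # forward
  expect_equal(g1$kind, "ribbon")
  expect_equal(nrow(g1$points), 4)
  expect_equal(g1$points[1, 1], toCanvasX(100, st@viewportA, cv))
  expect_equal(g1$points[2, 1], toCanvasX(300, st@viewportA, cv))
  expect_equal(g1$points[3, 1], toCanvasX(350, st@viewportB, cv))
  expect_equal(g1$points[4, 1], toCanvasX(150, st@viewportB, cv))
  ## side edges of a forward ribbon do not cross
  expect_false(segmentsCross(g1$points[2, ], g1$points[3, ],
                             g1$points[4, ], g1$points[1, ]))

  g2 <- glyphs[[2]]   # inverted: bottom corners swapped, edges cross
  expect_equal(g2$points[3, 1], toCanvasX(650, st@viewportB, cv))
  expect_equal(g2$points[4, 1], toCanvasX(850, st@viewportB, cv))
  expect_true(segmentsCross(g2$points[2, ], g2$points[3, ],
                            g2$points[4, ], g2$points[1, ]))
})

test_that("lines mode joins interval midpoints, one segment per record", {
  ds <- mkTwoRecordDs()
  st <- viewState(ds, displayMode = "lines")
  cv <- canvasSpec()
  glyphs <- layoutSynteny(visibleRecords(ds, st), st, cv)
  expect_equal(vapply(glyphs, `[[`, character(1), "kind"),
               c("segment", "segment"))
  expect_equal(glyphs[[1]]$points[1, 1],
               mean(toCanvasX(c(100, 300), st@viewportA, cv)))
})

test_that("record colors cycle the palette or scale with an attribute", {
  rec <- mkLengthRecords(c(10, 20))
  expect_equal(colorFor(rec), c("#332288", "#88CCEE"))

  rec3 <- mkLengthRecords(c(1, 1, 1))
  rec3$score <- c(0, 50, 100)
  cols <- colorFor(rec3, "attribute:score")
  ramp <- grDevices::colorRamp(c("#DEEBF7", "#08519C"))
  want <- tolower(grDevices::rgb(ramp(c(0, 0.5, 1)), maxColorValue = 255))
  expect_equal(cols, want)

  rec3$score <- c(7, 7, 7)
  expect_equal(unique(colorFor(rec3, "attribute:score")),
               tolower(grDevices::rgb(ramp(0.5), maxColorValue = 255)))
})

test_that("track style overrides, visibility and order drive the lanes", {
  ds <- demoDataset()
  cv <- canvasSpec()
  featA <- annotationFeatures(ds)
  featA <- featA[featA$seq == "orgA", ]

  ## genes drawn as red boxes via override instead of blue arrows
  st <- viewState(ds, styles = list(gene = list(shape = "box",
                                                color = "red")))
  glyphs <- layoutTracks(featA, st, "A", cv)
  gene <- Filter(function(g) g$source$track == "gene", glyphs)
  expect_true(all(vapply(gene, `[[`, character(1), "kind") == "box"))
  expect_true(all(vapply(gene, `[[`, character(1), "fill") == "#ff0000"))

  ## hidden track yields zero glyphs
  st2 <- viewState(ds, hidden = "a:transposon")
  glyphs2 <- layoutTracks(featA, st2, "A", cv)
  expect_false(any(vapply(glyphs2, function(g) g$source$track, "") ==
                   "transposon"))

  ## swapping two tracks exchanges their lane y-values, nothing else
  stAB <- viewState(ds, trackOrder = list(A = c("gene", "expression",
                                                "transposon")))
  stBA <- viewState(ds, trackOrder = list(A = c("expression", "gene",
                                                "transposon")))
  gAB <- layoutTracks(featA, stAB, "A", cv)
  gBA <- layoutTracks(featA, stBA, "A", cv)
  laneShift <- cv@trackLaneHeight
  for (i in seq_along(gAB)) {
    a <- gAB[[i]]
    match_ <- Filter(function(g) identical(g$source, a$source), gBA)
    expect_length(match_, 1)
    b <- match_[[1]]
    expect_equal(b$points[, 1], a$points[, 1])
    shift <- unique(b$points[, 2] - a$points[, 2])
    expect_length(shift, 1)
    if (a$source$track == "transposon") expect_equal(shift, 0)
    else expect_equal(abs(shift), laneShift)
  }
})

test_that("feature glyphs clip to the viewport and drop when outside", {
  ds <- demoDataset()
  feat <- annotationFeatures(ds)
  featA <- feat[feat$seq == "orgA", ]
  win <- c(featA$start[1], featA$start[1] + 10)
  st <- viewState(ds, pair = c("orgA", "orgB"), regionA = win)
  cv <- canvasSpec()
  glyphs <- layoutTracks(featA, st, "A", cv)
  nOverlap <- sum(featA$start <= win[2] & featA$end >= win[1])
  expect_equal(length(glyphs), nOverlap)
  for (g in glyphs) {
    expect_true(all(g$points[, 1] >= cv@margin - 1e-9))
    expect_true(all(g$points[, 1] <= cv@widthPx - cv@margin + 1e-9))
  }
})

test_that("the full figure is deterministic with additive glyph counts", {
  ds <- demoDataset()
  st <- viewState(ds, hidden = "b:transposon")
  cv <- canvasSpec()
  s1 <- renderFigure(ds, st, cv)
  s2 <- renderFigure(ds, st, cv)
  expect_identical(sceneGlyphs(s1), sceneGlyphs(s2))

  feat <- annotationFeatures(ds)
  featA <- feat[feat$seq == "orgA", ]
  featB <- feat[feat$seq == "orgB", ]
  nRulerish <- sum(vapply(sceneGlyphs(s1), function(g)
    g$source$type %in% c("ruler", "tick", "tick_label"), logical(1)))
  nLabels <- sum(vapply(sceneGlyphs(s1), function(g)
    g$source$type == "label", logical(1)))
  nExpected <- length(layoutTracks(featA, st, "A", cv)) +
    length(layoutSynteny(visibleRecords(ds, st), st, cv)) +
    length(layoutTracks(featB, st, "B", cv)) +
    nRulerish + nLabels
  expect_equal(length(sceneGlyphs(s1)), nExpected)

  ## ribbon count equals the visible record count
  kinds <- vapply(sceneGlyphs(s1), `[[`, character(1), "kind")
  expect_equal(sum(kinds == "ribbon"), nrow(visibleRecords(ds, st)))
})

test_that("an empty dataset renders rulers, ticks and labels only", {
  ds <- buildDataset(seqLengths = c(A = 1000, B = 2000))
  st <- viewState(ds, pair = c("A", "B"))
  sc <- renderFigure(ds, st)
  kinds <- vapply(sceneGlyphs(sc), `[[`, character(1), "kind")
  expect_equal(sum(kinds == "ruler"), 2)
  expect_true(all(kinds %in% c("ruler", "tick", "tick_label", "text")))
})

test_that("SVG export is byte-stable with one element per glyph", {
  ds <- demoDataset()
  sc <- renderFigure(ds, viewState(ds))
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  exportSVG(sc, f1)
  exportSVG(sc, f2)
  expect_identical(fileBytes(f1), fileBytes(f2))

  doc <- xml2::read_xml(f1)
  children <- xml2::xml_children(doc)
  expect_equal(length(children), length(sceneGlyphs(sc)) + 1)  # + background
})

test_that("PNG export matches the canvas pixel size", {
  ds <- demoDataset()
  cv <- canvasSpec(widthPx = 640, heightPx = 400)
  sc <- renderFigure(ds, viewState(ds), cv)
  f <- withr::local_tempfile(fileext = ".png")
  exportPNG(sc, f)
  img <- png::readPNG(f)
  expect_equal(dim(img)[1:2], c(400, 640))
})
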
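pairLines <- c(
  "org1\tstart1\tend1\torg2\tstart2\tend2",
  "A\t1\t100\tB\t1\t120",
  "A\t200\t300\tC\t10\t90",
  "B\t5\t50\tC\t100\t150",
  "B\t400\t450\tA\t400\t460"     # flipped duplicate of the A-B pair
)

test_that("pairs collapse by unordered identity in first-seen orientation", {
  ds <- buildDataset(parseSynteny(pairLines)$records)
  p <- listPairs(ds)
  expect_equal(nrow(p), 3)
  expect_equal(p$seqA, c("A", "A", "B"))
  expect_equal(p$seqB, c("B", "C", "C"))
})

test_that("record attributes resolve, including the implicit length", {
  rec <- parseSynteny(c(
    "org1\tstart1\tend1\torg2\tstart2\tend2\tevalue\tidentity",
    "chrA\t100\t500\tchrB\t200\t650\t1e-30\t98.5"
  ))$records
  ## length = max of the two inclusive side lengths: max(401, 451)
  expect_equal(recordAttribute(rec, "length"), 451)
  expect_equal(recordAttribute(rec, "evalue"), 1e-30)
  err <- tryCatch(recordAttribute(rec, "identty"), error = identity)
  expect_s3_class(err, "synviewr_usage_error")
  expect_match(conditionMessage(err), "length")
  expect_match(conditionMessage(err), "evalue")
  expect_match(conditionMessage(err), "identity")
})

test_that("filters are inclusive conjunctions preserving order", {
  rec <- mkLengthRecords(c(50, 150, 300))
  kept <- applyFilters(rec, list(filterSpec("length", min = 100)))
  expect_equal(kept$endA, c(150, 300))

  rec2 <- mkLengthRecords(c(10, 10))
  rec2$evalue <- c(1e-30, 1e-5)
  kept2 <- applyFilters(rec2, list(filterSpec("evalue", max = 1e-10)))
  expect_equal(nrow(kept2), 1)
  expect_equal(kept2$evalue, 1e-30)

  expect_identical(applyFilters(rec, list()), rec)
})

test_that("filtering agrees with brute force and composes as conjunction", {
  for (seed in 1:20) {
    ds <- generateDataset(smallSpec(seed))
    rec <- syntenyRecords(ds)
    set.seed(seed + 5000)
    attrs <- c("length", attributeNames(ds))
    filters <- lapply(sample(attrs, 2), function(a) {
      v <- recordAttribute(rec, a)
      filterSpec(a, min = stats::quantile(v, runif(1, 0, 0.5)),
                 max = stats::quantile(v, runif(1, 0.5, 1)))
    })
    got <- applyFilters(rec, filters)
    ## brute-force double loop
    keep <- vapply(seq_len(nrow(rec)), function(i) {
      all(vapply(filters, function(f) {
        v <- recordAttribute(rec[i, ], f$attribute)
        v >= f$min && v <= f$max
      }, logical(1)))
    }, logical(1))
    want <- rec[keep, , drop = FALSE]; rownames(want) <- NULL
    expect_identical(got, want)
    ## conjunction composability
    step <- applyFilters(applyFilters(rec, filters[1]), filters[2])
    expect_identical(got, step)
    ## anti-monotonicity: tightening a bound never adds records
    tighter <- filters
    tighter[[1]]$min <- tighter[[1]]$min +
      abs(tighter[[1]]$min) * 0.1 + 1e-9
    expect_lte(nrow(applyFilters(rec, tighter)), nrow(got))
  }
})

test_that("zoom follows the span rule with clamping at the edges", {
  vp <- genomeViewport("s", 1, 1000)
  z <- zoomViewport(vp, 2, seqLength = 1000)
  expect_equal(c(z@start, z@end), c(251, 750))
  expect_equal(zoomViewport(vp, 1, seqLength = 1000), vp)
  ## zooming out near the edge: span 101 doubles to 202, clamped right
  z2 <- zoomViewport(genomeViewport("s", 900, 1000), 0.5, seqLength = 1000)
  expect_equal(c(z2@start, z2@end), c(799, 1000))
  ## span can never exceed the sequence
  z3 <- zoomViewport(vp, 0.01, seqLength = 1000)
  expect_equal(c(z3@start, z3@end), c(1, 1000))
})

test_that("zoom in then out restores the span within 1 bp", {
  set.seed(77)
  for (i in 1:100) {
    len <- sample(1e3:1e6, 1)
    s <- sample(seq_len(len - 10), 1)
    e <- min(len, s + sample(10:5000, 1))
    vp <- genomeViewport("s", s, e)
    k <- runif(1, 1.25, 3)
    back <- zoomViewport(zoomViewport(vp, k, seqLength = len), 1 / k,
                         seqLength = len)
    expect_lte(abs((back@end - back@start) - (vp@end - vp@start)), 1)
    center <- (vp@start + vp@end) / 2
    expect_true(back@start <= center && center <= back@end)
  }
})

test_that("pan shifts by a span fraction and clamps at both ends", {
  vp <- genomeViewport("s", 101, 200)
  p <- panViewport(vp, 0.5, seqLength = 1000)
  expect_equal(c(p@start, p@end), c(151, 250))
  expect_equal(panViewport(vp, 0, seqLength = 1000), vp)
  left <- panViewport(genomeViewport("s", 1, 100), -0.5, seqLength = 1000)
  expect_equal(c(left@start, left@end), c(1, 100))
  right <- panViewport(genomeViewport("s", 901, 1000), 0.5, seqLength = 1000)
  expect_equal(c(right@start, right@end), c(901, 1000))
})

test_that("reset restores full genomes and is idempotent", {
  ds <- demoDataset()
  st <- viewState(ds)
  zoomed <- st
  zoomed@viewportA <- zoomViewport(st@viewportA, 4,
                                   seqLength = sequenceLength(ds, "orgA"))
  r1 <- resetView(zoomed, ds)
  expect_equal(c(r1@viewportA@start, r1@viewportA@end),
               c(1, sequenceLength(ds, "orgA")))
  expect_identical(resetView(r1, ds), r1)
  expect_identical(r1, st)   # reset after zoom equals the initial full view
})

test_that("visibility keeps records overlapping either viewport", {
  rec <- data.frame(seqA = "A", startA = 100, endA = 200,
                    orientA = "forward", seqB = "B", startB = 900,
                    endB = 950, orientB = "forward",
                    stringsAsFactors = FALSE)
  ds <- buildDataset(rec, seqLengths = c(A = 1000, B = 1000))
  st <- viewState(ds, regionA = c(150, 160), regionB = c(1, 50))
  expect_equal(nrow(visibleRecords(ds, st)), 1)   # A-side overlap suffices
  st2 <- viewState(ds, regionA = c(300, 400), regionB = c(1, 50))
  expect_equal(nrow(visibleRecords(ds, st2)), 0)  # outside both
  st3 <- viewState(ds)
  expect_identical(visibleRecords(ds, st3),
                   applyFilters(rec, list()))     # full view = filter output
})

test_that("visibility equals a brute-force overlap scan on random data", {
  for (seed in 1:10) {
    ds <- generateDataset(smallSpec(seed))
    lenA <- sequenceLength(ds, "seq01")
    set.seed(seed + 900)
    a1 <- sample(lenA - 100, 1); a2 <- min(lenA, a1 + sample(5000, 1))
    b1 <- sample(lenA - 100, 1); b2 <- min(lenA, b1 + sample(5000, 1))
    st <- viewState(ds, regionA = c(a1, a2), regionB = c(b1, b2))
    got <- visibleRecords(ds, st)
    rec <- syntenyRecords(ds)
    keep <- vapply(seq_len(nrow(rec)), function(i) {
      r <- rec[i, ]
      (r$startA <= a2 && r$endA >= a1) || (r$startB <= b2 && r$endB >= b1)
    }, logical(1))
    want <- rec[keep, , drop = FALSE]; rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("a view configuration file reproduces the state", {
  ds <- demoDataset()
  st <- viewState(
    ds, pair = c("orgA", "orgB"), regionA = c(1000, 250000),
    filters = list(filterSpec("evalue", max = 1e-10),
                   filterSpec("length", min = 5000)),
    displayMode = "lines",
    trackOrder = list(A = c("expression", "gene")),
    hidden = c("b:transposon"),
    styles = list(gene = list(shape = "box", color = "red"))
  )
  path <- withr::local_tempfile(fileext = ".cfg")
  writeViewConfig(st, path)
  st2 <- viewStateFromOptions(ds, readViewConfig(path))
  expect_identical(st2, st)
})

test_that("unknown pairs are rejected with the available pairs listed", {
  ds <- demoDataset()
  err <- tryCatch(viewState(ds, pair = c("orgA", "orgX")), error = identity)
  expect_s3_class(err, "synviewr_error")
  expect_match(conditionMessage(err), "orgA,orgB")
})
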
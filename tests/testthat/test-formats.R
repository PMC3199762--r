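test_that("synteny rows parse with attributes and interval normalization", {
  lines <- c(
    "# comment",
    "org1\tstart1\tend1\torg2\tstart2\tend2\tevalue\tidentity",
    "chrA\t100\t500\tchrB\t200\t650\t1e-30\t98.5",
    "chrA\t500\t100\tchrB\t200\t650\t1e-5\t80"
  )
  out <- parseSynteny(lines)
  expect_equal(out$attributeNames, c("evalue", "identity"))
  r <- out$records
  expect_equal(nrow(r), 2)
  expect_equal(r$startA[1], 100)
  expect_equal(r$endA[1], 500)
  expect_equal(r$orientA[1], "forward")
  expect_equal(r$evalue[1], 1e-30)
  expect_equal(r$identity[1], 98.5)
  ## start > end on side A normalizes to a reverse-orientation interval
  expect_equal(r$startA[2], 100)
  expect_equal(r$endA[2], 500)
  expect_equal(r$orientA[2], "reverse")
  expect_equal(r$orientB[2], "forward")
})

test_that("synteny format errors name the problem and the line", {
  hdr <- "org1\tstart1\tend1\torg2\tstart2\tend2\tscore"
  expect_error(parseSynteny(c("org1\tstart1\torg2\tstart2\tend2",
                              "a\t1\tb\t1\t2")),
               "end1", class = "synviewr_format_error")
  expect_error(parseSynteny(c(hdr, "a\t1\t10\tb\t1\t5\thigh")),
               "line 2", class = "synviewr_format_error")
  expect_error(parseSynteny(c(hdr, "a\t0\t10\tb\t1\t5\t3")),
               ">= 1", class = "synviewr_format_error")
  expect_error(parseSynteny(c(hdr, "a\t1\t10\tb\t1\t5")),
               "columns", class = "synviewr_format_error")
})

test_that("annotation rows parse with defaults and a closed shape set", {
  lines <- c(
    "org\tstart\tend\ttrack\tshape\tcolor\tstrand",
    "chrA\t10\t90\tgene\tarrow\tblue\t+",
    "chrA\t10\t90\ttransposon\tbox\tblack"
  )
  f <- parseAnnotation(lines)
  expect_equal(f$shape, c("arrow", "box"))
  expect_equal(f$color, c("blue", "black"))
  expect_equal(f$strand, c("+", "."))   # absent strand defaults to "."
  expect_equal(f$label, c("", ""))

  expect_error(
    parseAnnotation(c("org\tstart\tend\ttrack\tshape\tcolor",
                      "chrA\t10\t90\tgene\tstar\tblue")),
    "star", class = "synviewr_format_error")
  expect_error(
    parseAnnotation(c("org\tstart\tend\ttrack\tshape\tcolor",
                      "chrA\t10\t90\tgene\tbox\tnotacolor")),
    "color", class = "synviewr_format_error")
})

test_that("write -> parse is the identity for records and features", {
  for (seed in c(11, 12, 13, 14, 15)) {
    ds <- generateDataset(smallSpec(seed))
    rt <- parseSynteny(writeSynteny(syntenyRecords(ds), attributeNames(ds)))
    expect_identical(rt$records, syntenyRecords(ds))
    expect_identical(rt$attributeNames, attributeNames(ds))
    ft <- parseAnnotation(writeAnnotation(annotationFeatures(ds)))
    expect_identical(ft, annotationFeatures(ds))
  }
})

test_that("serialization encodes reverse intervals positionally", {
  rec <- data.frame(seqA = "a", startA = 100, endA = 500,
                    orientA = "reverse", seqB = "b", startB = 200,
                    endB = 650, orientB = "forward",
                    stringsAsFactors = FALSE)
  lines <- writeSynteny(rec)
  expect_match(lines[2], "^a\t500\t100\tb\t200\t650$")
  ## parsing an already-normalized serialization changes nothing
  again <- writeSynteny(parseSynteny(lines)$records)
  expect_identical(again, lines)
  ## empty record list gives a header-only file
  expect_equal(length(writeSynteny(rec[0, ])), 1)
})

test_that("compressed inputs parse identically to plain text", {
  ds <- generateDataset(smallSpec(99))
  plain <- withr::local_tempfile(fileext = ".tsv")
  writeSynteny(syntenyRecords(ds), attributeNames(ds), plain)
  gz <- writeGz(readLines(plain), withr::local_tempfile(fileext = ".gz"))
  zip <- writeZip(withr::local_tempfile(fileext = ".zip"), plain)
  expect_identical(readSynteny(gz), readSynteny(plain))
  expect_identical(readSynteny(zip), readSynteny(plain))

  other <- withr::local_tempfile(fileext = ".tsv")
  writeLines("x", other)
  twoMember <- writeZip(withr::local_tempfile(fileext = ".zip"),
                        c(plain, other))
  expect_error(openMaybeCompressed(twoMember), "ambiguous",
               class = "synviewr_format_error")
})

test_that("buildDataset infers lengths, honors declarations, flags orphans", {
  rec <- parseSynteny(c("org1\tstart1\tend1\torg2\tstart2\tend2",
                        "chrA\t100\t500\tchrB\t200\t650"))$records
  ds <- buildDataset(rec)
  expect_equal(sequenceLength(ds, "chrA"), 500)
  expect_equal(sequenceLength(ds, "chrB"), 650)

  ds2 <- buildDataset(rec, seqLengths = c(chrA = 1000))
  expect_equal(sequenceLength(ds2, "chrA"), 1000)
  expect_error(buildDataset(rec, seqLengths = c(chrA = 400)),
               "declared length", class = "synviewr_error")

  feat <- parseAnnotation(c("org\tstart\tend\ttrack\tshape\tcolor",
                            "chrZ\t1\t10\tgene\tbox\tred"))
  expect_error(buildDataset(rec[0, ], feat), "chrZ",
               class = "synviewr_error")
  ds3 <- buildDataset(rec[0, ], feat, seqLengths = c(chrZ = 100))
  expect_equal(sequenceLength(ds3, "chrZ"), 100)
})

test_that("random datasets survive the round trip under many seeds", {
  for (seed in 300:329) {
    ds <- generateDataset(smallSpec(seed))
    rt <- parseSynteny(writeSynteny(syntenyRecords(ds), attributeNames(ds)))
    expect_identical(rt$records, syntenyRecords(ds))
  }
})
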
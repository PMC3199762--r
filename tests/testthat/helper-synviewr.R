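## Shared fixtures and small independent oracles for the test suite.

## A small random dataset spec: 2 sequences, 6 blocks, 2 tracks.
smallSpec <- function(seed, inversionRate = 0.3) {
  simSpec(
    nSequences = 2, seqLength = 5e4, nBlocks = 6,
    blockLengthRange = c(500, 3000), inversionRate = inversionRate,
    attributes = list(
      identity = list(dist = "uniform", min = 70, max = 100),
      evalue = list(dist = "loguniform", min = 1e-40, max = 1e-2)
    ),
    nFeaturesPerTrack = 3,
    tracks = data.frame(name = c("gene", "expression"),
                        shape = c("arrow", "line"),
                        color = c("blue", "green"),
                        stringsAsFactors = FALSE),
    featureLengthRange = c(200, 2000),
    seed = seed
  )
}

writeGz <- function(lines, path) {
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  path
}

## No zip(1) in minimal images; the Python stdlib writes the archive.
writeZip <- function(zipPath, files) {
  script <- paste0(
    "import zipfile,sys\n",
    "z=zipfile.ZipFile(sys.argv[1],'w')\n",
    "[z.write(f,arcname=f.split('/')[-1]) for f in sys.argv[2:]]\n",
    "z.close()\n"
  )
  status <- system2("python", c("-c", shQuote(script), shQuote(zipPath),
                                vapply(files, shQuote, character(1))))
  stopifnot(status == 0)
  zipPath
}

fileBytes <- function(path) readBin(path, "raw", n = file.size(path))

## Records whose side-A spans are the given lengths (side B fixed 1 bp).
mkLengthRecords <- function(lens) {
  data.frame(seqA = "A", startA = 1, endA = lens, orientA = "forward",
             seqB = "B", startB = 1, endB = 1, orientB = "forward",
             stringsAsFactors = FALSE)
}

## Independent 1-2-5 tick-step oracle: brute force over the ladder.
bruteTickStep <- function(start, end, maxTicks) {
  cands <- sort(as.vector(outer(c(1, 2, 5), 10^(0:15))))
  for (s in cands) {
    n <- length(seq(ceiling(start / s) * s, by = s,
                    to = floor(end / s) * s))
    if (floor(end / s) < ceiling(start / s)) n <- 0
    if (n <= maxTicks) return(s)
  }
  NA
}

## Independent proper-intersection test for two segments (for ribbon
## self-crossing checks).
segmentsCross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
                         (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}
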
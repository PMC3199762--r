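## Seeded synthetic synteny/annotation generator. Produces datasets with
## controllable block structure so every other module is testable without
## external data. Coordinates only -- no nucleotide-level simulation.

drawFromSpec <- function(d, n) {
  switch(d$dist,
    uniform = runif(n, d$min, d$max),
    loguniform = exp(runif(n, log(d$min), log(d$max))),
    svUsageError(paste0("unknown attribute distribution '", d$dist, "'"))
  )
}

#' Specification for a simulated dataset
#'
#' Defaults describe a small bacterial-scale comparison: three 500 kb
#' sequences, 12 conserved blocks of 5-30 kb per pair, a 20% inversion rate,
#' and BLAST-like per-block attributes (percent identity, E-value, score).
#'
#' @param nSequences number of sequences (>= 2); every unordered pair gets
#'   synteny blocks.
#' @param seqNames optional sequence names; default `seq01, seq02, ...`.
#' @param seqLength sequence display length, bp.
#' @param nBlocks conserved blocks per pair.
#' @param blockLengthRange `c(min, max)` block length, bp.
#' @param inversionRate probability in `[0, 1]` that a block is inverted
#'   (reverse orientation on side B).
#' @param attributes named list of attribute distributions, each
#'   `list(dist = "uniform"|"loguniform", min=, max=)`.
#' @param nFeaturesPerTrack annotation features per sequence per track.
#' @param tracks data.frame with columns `name`, `shape`, `color`.
#' @param featureLengthRange `c(min, max)` feature length, bp.
#' @param seed integer RNG seed; the whole dataset is reproducible from it.
#' @return a validated spec list of class `simSpec`.
#' @export
simSpec <- function(nSequences = 3, seqNames = NULL, seqLength = 5e5,
                    nBlocks = 12, blockLengthRange = c(5e3, 3e4),
                    inversionRate = 0.2,
                    attributes = list(
                      identity = list(dist = "uniform", min = 75, max = 100),
                      evalue = list(dist = "loguniform", min = 1e-60,
                                    max = 1e-3),
                      score = list(dist = "uniform", min = 500, max = 10000)
                    ),
                    nFeaturesPerTrack = 12,
                    tracks = data.frame(
                      name = c("gene", "expression", "transposon"),
                      shape = c("arrow", "line", "box"),
                      color = c("blue", "green", "black"),
                      stringsAsFactors = FALSE
                    ),
                    featureLengthRange = c(500, 5000),
                    seed = 1) {
  if (nSequences < 2) svUsageError("nSequences must be >= 2")
  if (inversionRate < 0 || inversionRate > 1)
    svUsageError("inversionRate must be in [0, 1]")
  if (blockLengthRange[1] > blockLengthRange[2] ||
      blockLengthRange[2] > seqLength)
    svUsageError("blockLengthRange must fit within seqLength")
  if (is.null(seqNames)) seqNames <- sprintf("seq%02d", seq_len(nSequences))
  if (length(seqNames) != nSequences)
    svUsageError("seqNames must have nSequences entries")
  if (!all(tracks$shape %in% SHAPE_VOCAB))
    svUsageError("track shapes must be box, arrow or line")
  structure(
    list(nSequences = nSequences, seqNames = seqNames, seqLength = seqLength,
         nBlocks = nBlocks, blockLengthRange = blockLengthRange,
         inversionRate = inversionRate, attributes = attributes,
         nFeaturesPerTrack = nFeaturesPerTrack, tracks = tracks,
         featureLengthRange = featureLengthRange, seed = as.integer(seed)),
    class = "simSpec"
  )
}

## Place n blocks of the given lengths on [1, seqLength] without overlap,
## in left-to-right order. Gaps are drawn uniformly from the free space.
placeBlocks <- function(lens, seqLength) {
  n <- length(lens)
  free <- seqLength - sum(lens)
  if (free < 0)
    svStop(paste0("cannot place ", n, " non-overlapping blocks totalling ",
                  sum(lens), " bp on a ", seqLength,
                  " bp sequence; reduce nBlocks or blockLengthRange, or ",
                  "increase seqLength"))
  cuts <- sort(runif(n, 0, free))
  gaps <- floor(c(cuts[1], diff(cuts)))
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n])) + 1
  data.frame(start = starts, end = starts + lens - 1)
}

#' Generate a synthetic dataset
#'
#' For every unordered pair of sequences, `nBlocks` non-nested conserved
#' blocks are placed without overlap on each sequence (collinear block
#' order; the non-overlap constraint holds within each pair). Each block is
#' inverted with probability `inversionRate`; attribute values are drawn
#' from the declared distributions; annotation features are drawn per track
#' on every sequence, with `line`-shaped tracks receiving a per-feature
#' `value` in (0, 1] that drives bar heights. Everything is reproducible
#' from `spec$seed`.
#'
#' @param spec a [simSpec()].
#' @param outPrefix optional path prefix; when given,
#'   `<prefix>.synteny.tsv` and `<prefix>.annotation.tsv` are written.
#' @return a [SyntenyDataset-class].
#' @export
generateDataset <- function(spec, outPrefix = NULL) {
  stopifnot(inherits(spec, "simSpec"))
  withr::with_seed(spec$seed, {
    pairIdx <- utils::combn(spec$nSequences, 2)
    recs <- vector("list", ncol(pairIdx))
    for (p in seq_len(ncol(pairIdx))) {
      s1 <- spec$seqNames[pairIdx[1, p]]
      s2 <- spec$seqNames[pairIdx[2, p]]
      n <- spec$nBlocks
      lens1 <- round(runif(n, spec$blockLengthRange[1],
                           spec$blockLengthRange[2]))
      lens2 <- round(runif(n, spec$blockLengthRange[1],
                           spec$blockLengthRange[2]))
      posA <- placeBlocks(lens1, spec$seqLength)
      posB <- placeBlocks(lens2, spec$seqLength)
      inverted <- runif(n) < spec$inversionRate
      df <- data.frame(
        seqA = s1, startA = posA$start, endA = posA$end, orientA = "forward",
        seqB = s2, startB = posB$start, endB = posB$end,
        orientB = ifelse(inverted, "reverse", "forward"),
        stringsAsFactors = FALSE
      )
      for (a in names(spec$attributes))
        df[[a]] <- drawFromSpec(spec$attributes[[a]], n)
      recs[[p]] <- df
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL

    feats <- list()
    for (s in spec$seqNames) {
      for (t in seq_len(nrow(spec$tracks))) {
        n <- spec$nFeaturesPerTrack
        if (n == 0) next
        tr <- spec$tracks[t, ]
        lens <- round(runif(n, spec$featureLengthRange[1],
                            min(spec$featureLengthRange[2], spec$seqLength)))
        starts <- round(runif(n, 1, spec$seqLength - lens + 1))
        ord <- order(starts)
        starts <- starts[ord]; lens <- lens[ord]
        strand <- if (tr$shape == "arrow") {
          sample(c("+", "-"), n, replace = TRUE)
        } else rep(".", n)
        value <- if (tr$shape == "line") {
          round(runif(n, 0.05, 1), 4)
        } else rep(NA_real_, n)
        feats[[length(feats) + 1]] <- data.frame(
          seq = s, start = starts, end = starts + lens - 1,
          track = tr$name, shape = tr$shape, color = tr$color,
          strand = strand,
          label = sprintf("%s_%s_%02d", tr$name, s, seq_len(n)),
          value = value, stringsAsFactors = FALSE
        )
      }
    }
    features <- if (length(feats) > 0) do.call(rbind, feats) else emptyFeatures()
    rownames(features) <- NULL

    lens <- stats::setNames(rep(spec$seqLength, spec$nSequences),
                            spec$seqNames)
    ds <- buildDataset(records, features,
                       attributeNames = names(spec$attributes),
                       seqLengths = lens)
    if (!is.null(outPrefix)) {
      writeSynteny(syntenyRecords(ds), attributeNames(ds),
                   paste0(outPrefix, ".synteny.tsv"))
      writeAnnotation(annotationFeatures(ds),
                      paste0(outPrefix, ".annotation.tsv"))
    }
    ds
  })
}

#' The built-in demonstration dataset
#'
#' A deterministic three-organism dataset (all three pairs present) with the
#' stock annotation tracks: "gene" as blue arrows, "expression" as green
#' bars (line shape with per-feature values), and "transposon" as black
#' boxes.
#'
#' @return a [SyntenyDataset-class].
#' @export
demoDataset <- function() {
  generateDataset(simSpec(
    nSequences = 3, seqNames = c("orgA", "orgB", "orgC"), seed = 42L
  ))
}

#' Emit synteny records as BLAST tabular (outfmt 6) lines
#'
#' The inverse direction of [blastToSynteny()], for converter round-trip
#' testing: side A becomes the query, side B the subject; a record whose
#' sides have opposite orientations is emitted with sstart > send
#' (minus-strand subject). Percent identity, E-value and bit score are taken
#' from the `identity`, `evalue` and `bitscore` attribute columns when
#' present (defaults 100, 0, 0 otherwise); alignment length is the side-A
#' span; mismatch and gapopen are written as 0.
#'
#' @param records records data.frame.
#' @return character vector of 12-column BLAST outfmt-6 lines.
#' @export
blastTabLines <- function(records) {
  n <- nrow(records)
  if (n == 0) return(character(0))
  getAttr <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else rep(default, n)
  }
  inverted <- xor(records$orientA == "reverse", records$orientB == "reverse")
  ss <- ifelse(inverted, records$endB, records$startB)
  se <- ifelse(inverted, records$startB, records$endB)
  paste(records$seqA, records$seqB,
        formatNumeric(getAttr("identity", 100)),
        formatCoord(records$endA - records$startA + 1),
        "0", "0",
        formatCoord(records$startA), formatCoord(records$endA),
        formatCoord(ss), formatCoord(se),
        formatNumeric(getAttr("evalue", 0)),
        formatNumeric(getAttr("bitscore", 0)),
        sep = "\t")
}
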
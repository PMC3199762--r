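## Tab-delimited interchange formats: synteny and annotation files.
##
## Both formats are UTF-8, tab-delimited, "#" comment lines, a required
## header as the first non-comment line; LF or CRLF accepted, LF emitted.
## Coordinates are 1-based inclusive; a row with start > end encodes a
## reverse-orientation interval and is normalized on parse.

SYNTENY_REQUIRED <- c("org1", "start1", "end1", "org2", "start2", "end2")
ANNOTATION_REQUIRED <- c("org", "start", "end", "track", "shape", "color")
ANNOTATION_OPTIONAL <- c("strand", "label", "value")

#' Read a possibly compressed text file as lines
#'
#' Opens plain text, gzip (`.gz`) or single-member zip (`.zip`) files
#' transparently, detecting the container from magic bytes rather than the
#' file name. A zip archive with more than one member is rejected as
#' ambiguous.
#'
#' @param path path to the file.
#' @return character vector of lines.
#' @examples
#' f <- tempfile(); writeLines(c("a\tb"), f)
#' openMaybeCompressed(f)
#' @export
openMaybeCompressed <- function(path) {
  if (!file.exists(path)) svStop(paste0("file not found: ", path))
  magic <- readBin(path, "raw", n = 4)
  lines <- if (length(magic) >= 2 &&
               magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  } else if (length(magic) >= 4 && rawToChar(magic[1:2]) == "PK" &&
             magic[3] == as.raw(0x03) && magic[4] == as.raw(0x04)) {
    members <- utils::unzip(path, list = TRUE)
    if (nrow(members) != 1)
      svFormatError(paste0("ambiguous archive: zip must contain exactly one",
                           " member, found ", nrow(members)))
    con <- unz(path, members$Name[1])
    on.exit(close(con))
    readLines(con, warn = FALSE)
  } else {
    readLines(path, warn = FALSE)
  }
  bad <- !validUTF8(lines)
  if (any(bad))
    svFormatError(paste0("encoding error: line ", which(bad)[1],
                         " is not valid UTF-8"))
  lines
}

## Split raw lines into (header fields, data rows, original line numbers).
## "#" lines are comments; blank lines are skipped.
tabTable <- function(lines, what) {
  keep <- !grepl("^#", lines) & trimws(lines) != ""
  idx <- which(keep)
  if (length(idx) == 0)
    svFormatError(paste0(what, " file has no header line"))
  split1 <- function(s) strsplit(sub("\r$", "", s), "\t", fixed = TRUE)[[1]]
  header <- split1(lines[idx[1]])
  rows <- lapply(lines[idx[-1]], split1)
  list(header = trimws(header), rows = rows, lineNo = idx[-1])
}

parseRowNumber <- function(s, lineNo, col) {
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v) || !is.finite(v))
    svFormatError(paste0("line ", lineNo, ": column '", col,
                         "' value '", s, "' is not a finite number"))
  v
}

#' Parse synteny-format lines
#'
#' The synteny format has required header columns `org1, start1, end1, org2,
#' start2, end2`; any further header columns declare named numeric attributes
#' (alignment score, E-value, percent identity, ...) that characterize each
#' conserved region and become filterable. Rows with start > end on either
#' side are normalized to a sorted interval with reverse orientation.
#'
#' @param lines character vector of file lines (see [openMaybeCompressed()]).
#' @return list with `records` (normalized data.frame) and `attributeNames`
#'   (character, header order).
#' @seealso [readSynteny()], [writeSynteny()]
#' @export
parseSynteny <- function(lines) {
  tt <- tabTable(lines, "synteny")
  header <- tt$header
  missingCols <- setdiff(SYNTENY_REQUIRED, header)
  if (length(missingCols) > 0)
    svFormatError(paste0("synteny header is missing required column(s): ",
                         paste(missingCols, collapse = ", ")))
  if (anyDuplicated(header))
    svFormatError(paste0("synteny header has duplicated column(s): ",
                         paste(unique(header[duplicated(header)]),
                               collapse = ", ")))
  attrNames <- setdiff(header, SYNTENY_REQUIRED)
  if ("length" %in% attrNames)
    svFormatError("'length' is reserved for the implicit length attribute")

  n <- length(tt$rows)
  col <- function(nm) match(nm, header)
  seqA <- character(n); seqB <- character(n)
  sA <- numeric(n); eA <- numeric(n); sB <- numeric(n); eB <- numeric(n)
  attrVals <- matrix(NA_real_, nrow = n, ncol = length(attrNames),
                     dimnames = list(NULL, attrNames))
  for (i in seq_len(n)) {
    f <- tt$rows[[i]]
    ln <- tt$lineNo[i]
    if (length(f) != length(header))
      svFormatError(paste0("line ", ln, ": expected ", length(header),
                           " columns, found ", length(f)))
    seqA[i] <- f[col("org1")]; seqB[i] <- f[col("org2")]
    if (seqA[i] == "" || seqB[i] == "")
      svFormatError(paste0("line ", ln, ": empty sequence name"))
    sA[i] <- parseRowNumber(f[col("start1")], ln, "start1")
    eA[i] <- parseRowNumber(f[col("end1")], ln, "end1")
    sB[i] <- parseRowNumber(f[col("start2")], ln, "start2")
    eB[i] <- parseRowNumber(f[col("end2")], ln, "end2")
    if (min(sA[i], eA[i], sB[i], eB[i]) < 1)
      svFormatError(paste0("line ", ln, ": positions must be >= 1"))
    for (a in attrNames)
      attrVals[i, a] <- parseRowNumber(f[col(a)], ln, a)
  }

  revA <- sA > eA
  revB <- sB > eB
  records <- data.frame(
    seqA = seqA,
    startA = pmin(sA, eA), endA = pmax(sA, eA),
    orientA = ifelse(revA, "reverse", "forward"),
    seqB = seqB,
    startB = pmin(sB, eB), endB = pmax(sB, eB),
    orientB = ifelse(revB, "reverse", "forward"),
    stringsAsFactors = FALSE
  )
  for (a in attrNames) records[[a]] <- unname(attrVals[, a])
  list(records = records, attributeNames = attrNames)
}

#' Parse annotation-format lines
#'
#' The annotation format has required header columns `org, start, end, track,
#' shape, color` and optional `strand`, `label` and `value`. `shape` is drawn
#' from the closed vocabulary box/arrow/line; `color` is `#RRGGBB` or a named
#' color. A missing strand defaults to `"."`, a missing label to `""`.
#' `value` is an optional per-feature number (used e.g. for bar heights on
#' line-shaped tracks); empty cells become `NA`.
#'
#' @param lines character vector of file lines.
#' @return data.frame of features, one row per input row.
#' @seealso [readAnnotation()], [writeAnnotation()]
#' @export
parseAnnotation <- function(lines) {
  tt <- tabTable(lines, "annotation")
  header <- tt$header
  missingCols <- setdiff(ANNOTATION_REQUIRED, header)
  if (length(missingCols) > 0)
    svFormatError(paste0("annotation header is missing required column(s): ",
                         paste(missingCols, collapse = ", ")))
  unknown <- setdiff(header, c(ANNOTATION_REQUIRED, ANNOTATION_OPTIONAL))
  if (length(unknown) > 0)
    svFormatError(paste0("annotation header has unknown column(s): ",
                         paste(unknown, collapse = ", ")))
  col <- function(nm) match(nm, header)
  n <- length(tt$rows)
  out <- data.frame(
    seq = character(n), start = numeric(n), end = numeric(n),
    track = character(n), shape = character(n), color = character(n),
    strand = character(n), label = character(n), value = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    f <- tt$rows[[i]]
    ln <- tt$lineNo[i]
    if (length(f) < length(ANNOTATION_REQUIRED) || length(f) > length(header))
      svFormatError(paste0("line ", ln, ": expected ",
                           length(ANNOTATION_REQUIRED), "-", length(header),
                           " columns, found ", length(f)))
    length(f) <- length(header)          # pad trailing optionals
    f[is.na(f)] <- ""
    out$seq[i] <- f[col("org")]
    if (out$seq[i] == "")
      svFormatError(paste0("line ", ln, ": empty sequence name"))
    s <- parseRowNumber(f[col("start")], ln, "start")
    e <- parseRowNumber(f[col("end")], ln, "end")
    if (min(s, e) < 1)
      svFormatError(paste0("line ", ln, ": positions must be >= 1"))
    out$start[i] <- min(s, e); out$end[i] <- max(s, e)
    out$track[i] <- f[col("track")]
    if (out$track[i] == "")
      svFormatError(paste0("line ", ln, ": empty track name"))
    out$shape[i] <- f[col("shape")]
    if (!out$shape[i] %in% SHAPE_VOCAB)
      svFormatError(paste0("line ", ln, ": unknown shape '", out$shape[i],
                           "'; must be one of ",
                           paste(SHAPE_VOCAB, collapse = ", ")))
    out$color[i] <- f[col("color")]
    if (!isValidColor(out$color[i]))
      svFormatError(paste0("line ", ln, ": unresolvable color '",
                           out$color[i], "'"))
    strand <- if ("strand" %in% header) f[col("strand")] else ""
    if (strand == "") strand <- "."
    if (!strand %in% STRAND_VOCAB)
      svFormatError(paste0("line ", ln, ": strand must be '+', '-' or '.'"))
    out$strand[i] <- strand
    out$label[i] <- if ("label" %in% header) f[col("label")] else ""
    if ("value" %in% header && f[col("value")] != "")
      out$value[i] <- parseRowNumber(f[col("value")], ln, "value")
  }
  out
}

#' @rdname parseSynteny
#' @param path path to a synteny file (plain, `.gz` or single-member `.zip`).
#' @export
readSynteny <- function(path) parseSynteny(openMaybeCompressed(path))

#' @rdname parseAnnotation
#' @param path path to an annotation file (plain, `.gz` or `.zip`).
#' @export
readAnnotation <- function(path) parseAnnotation(openMaybeCompressed(path))

#' Serialize synteny records
#'
#' Emits the canonical header followed by one row per record. A
#' reverse-orientation interval is serialized with start > end so that
#' parse-after-write reproduces the records exactly.
#'
#' @param records normalized records data.frame (see [parseSynteny()]).
#' @param attributeNames attribute columns to emit, in order.
#' @param path optional output path; when `NULL` the lines are returned.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
writeSynteny <- function(records, attributeNames = character(0), path = NULL) {
  stopifnot(all(REQUIRED_RECORD_COLS %in% names(records)))
  missingAttr <- setdiff(attributeNames, names(records))
  if (length(missingAttr) > 0)
    svStop(paste0("records lack attribute column(s): ",
                  paste(missingAttr, collapse = ", ")))
  header <- paste(c(SYNTENY_REQUIRED, attributeNames), collapse = "\t")
  n <- nrow(records)
  lines <- character(n)
  if (n > 0) {
    revA <- records$orientA == "reverse"
    revB <- records$orientB == "reverse"
    s1 <- ifelse(revA, records$endA, records$startA)
    e1 <- ifelse(revA, records$startA, records$endA)
    s2 <- ifelse(revB, records$endB, records$startB)
    e2 <- ifelse(revB, records$startB, records$endB)
    cols <- list(records$seqA, formatCoord(s1), formatCoord(e1),
                 records$seqB, formatCoord(s2), formatCoord(e2))
    for (a in attributeNames) cols <- c(cols, list(formatNumeric(records[[a]])))
    lines <- do.call(paste, c(cols, sep = "\t"))
  }
  out <- c(header, lines)
  if (!is.null(path)) {
    writeLines(out, path, sep = "\n")
    return(invisible(out))
  }
  out
}

#' Serialize annotation features
#'
#' @param features features data.frame (see [parseAnnotation()]).
#' @param path optional output path; when `NULL` the lines are returned.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
writeAnnotation <- function(features, path = NULL) {
  stopifnot(all(setdiff(FEATURE_COLS, "value") %in% names(features)))
  hasValue <- "value" %in% names(features) && any(!is.na(features$value))
  header <- paste(c("org", "start", "end", "track", "shape", "color",
                    "strand", "label", if (hasValue) "value"),
                  collapse = "\t")
  n <- nrow(features)
  lines <- character(n)
  if (n > 0) {
    cols <- list(features$seq, formatCoord(features$start),
                 formatCoord(features$end), features$track, features$shape,
                 features$color, features$strand, features$label)
    if (hasValue) {
      v <- rep("", n)
      ok <- !is.na(features$value)
      v[ok] <- formatNumeric(features$value[ok])
      cols <- c(cols, list(v))
    }
    lines <- do.call(paste, c(cols, sep = "\t"))
  }
  out <- c(header, lines)
  if (!is.null(path)) {
    writeLines(out, path, sep = "\n")
    return(invisible(out))
  }
  out
}

emptyRecords <- function(attributeNames = character(0)) {
  df <- data.frame(
    seqA = character(0), startA = numeric(0), endA = numeric(0),
    orientA = character(0), seqB = character(0), startB = numeric(0),
    endB = numeric(0), orientB = character(0), stringsAsFactors = FALSE
  )
  for (a in attributeNames) df[[a]] <- numeric(0)
  df
}

emptyFeatures <- function() {
  data.frame(
    seq = character(0), start = numeric(0), end = numeric(0),
    track = character(0), shape = character(0), color = character(0),
    strand = character(0), label = character(0), value = numeric(0),
    stringsAsFactors = FALSE
  )
}

#' Assemble a validated dataset
#'
#' Populates the sequence table from the maximum end coordinate observed per
#' sequence name across records and features; `seqLengths` declares or
#' overrides display lengths (a declared length may exceed, but not
#' undercut, the observed extent). A feature referencing a sequence never
#' named by any record and not declared in `seqLengths` is an error.
#'
#' @param records normalized records data.frame (may be empty).
#' @param features features data.frame (may be empty).
#' @param attributeNames attribute names in file order; defaults to the
#'   non-required columns of `records`.
#' @param seqLengths optional named numeric vector of declared lengths.
#' @return a [SyntenyDataset-class].
#' @export
buildDataset <- function(records = emptyRecords(), features = emptyFeatures(),
                         attributeNames = NULL, seqLengths = NULL) {
  if (is.null(attributeNames))
    attributeNames <- setdiff(names(records), REQUIRED_RECORD_COLS)
  if (!"value" %in% names(features)) features$value <- NA_real_

  recSeqs <- unique(c(records$seqA, records$seqB))
  declared <- names(seqLengths) %||% character(0)
  orphan <- setdiff(unique(features$seq), c(recSeqs, declared))
  if (length(orphan) > 0)
    svStop(paste0("features reference sequence(s) with no synteny record ",
                  "and no declared length: ", paste(orphan, collapse = ", ")))

  allNames <- unique(c(recSeqs, unique(features$seq), declared))
  observed <- vapply(allNames, function(nm) {
    max(c(records$endA[records$seqA == nm], records$endB[records$seqB == nm],
          features$end[features$seq == nm], 0))
  }, numeric(1))
  lens <- observed
  if (length(declared) > 0) {
    short <- declared[seqLengths[declared] < observed[match(declared, allNames)]]
    short <- short[!is.na(short)]
    if (length(short) > 0)
      svStop(paste0("declared length below observed extent for: ",
                    paste(short, collapse = ", ")))
    lens[match(declared, allNames)] <- seqLengths[declared]
  }
  sequences <- data.frame(name = allNames, length = unname(lens),
                          stringsAsFactors = FALSE)
  rownames(sequences) <- NULL
  new("SyntenyDataset", records = records, features = features,
      sequences = sequences, attributeNames = attributeNames)
}

#' Read a full dataset from files
#'
#' @param synteny path to a synteny file.
#' @param annotation optional path to an annotation file.
#' @param seqLengths optional named numeric vector of declared lengths.
#' @return a [SyntenyDataset-class].
#' @export
readDataset <- function(synteny, annotation = NULL, seqLengths = NULL) {
  syn <- readSynteny(synteny)
  feat <- if (is.null(annotation)) emptyFeatures() else readAnnotation(annotation)
  buildDataset(syn$records, feat, syn$attributeNames, seqLengths)
}
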
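## Converters from common alignment/annotation outputs into the package's
## interchange formats.

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Convert BLAST tabular (outfmt 6) to synteny records
#'
#' Consumes the 12-column default BLAST tabular layout, one high-scoring
#' segment pair (HSP) per line. The query interval becomes side A and the
#' subject interval side B (swapped when `queryAs = "org2"`). A subject hit
#' reported with sstart > send is a minus-strand alignment and yields a
#' reverse-orientation interval on the subject side. Percent identity,
#' alignment length, E-value and bit score are carried over as the numeric
#' attributes `identity`, `aln_length`, `evalue`, `bitscore`.
#'
#' @param lines character vector of BLAST outfmt-6 lines ("#" comment lines
#'   tolerated and skipped).
#' @param queryAs `"org1"` (default) to place the query on side A, `"org2"`
#'   to place it on side B.
#' @return list with `records` and `attributeNames`, as [parseSynteny()].
#' @export
blastToSynteny <- function(lines, queryAs = c("org1", "org2")) {
  queryAs <- match.arg(queryAs)
  keep <- !grepl("^#", lines) & trimws(lines) != ""
  idx <- which(keep)
  n <- length(idx)
  seqQ <- character(n); seqS <- character(n)
  qs <- numeric(n); qe <- numeric(n); ss <- numeric(n); se <- numeric(n)
  ident <- numeric(n); alen <- numeric(n); eval_ <- numeric(n); bits <- numeric(n)
  for (i in seq_len(n)) {
    ln <- idx[i]
    f <- strsplit(sub("\r$", "", lines[ln]), "\t", fixed = TRUE)[[1]]
    if (length(f) != 12)
      svFormatError(paste0("line ", ln, ": expected 12 tab-delimited ",
                           "columns (BLAST outfmt 6), found ", length(f)))
    seqQ[i] <- f[1]; seqS[i] <- f[2]
    ident[i] <- parseRowNumber(f[3], ln, "pident")
    alen[i] <- parseRowNumber(f[4], ln, "length")
    qs[i] <- parseRowNumber(f[7], ln, "qstart")
    qe[i] <- parseRowNumber(f[8], ln, "qend")
    ss[i] <- parseRowNumber(f[9], ln, "sstart")
    se[i] <- parseRowNumber(f[10], ln, "send")
    eval_[i] <- parseRowNumber(f[11], ln, "evalue")
    bits[i] <- parseRowNumber(f[12], ln, "bitscore")
  }
  ## Nucleotide BLAST never reports qstart > qend; only the subject side
  ## encodes strand through coordinate order.
  query <- data.frame(
    seq = seqQ, start = pmin(qs, qe), end = pmax(qs, qe),
    orient = ifelse(qs > qe, "reverse", "forward"),
    stringsAsFactors = FALSE
  )
  subject <- data.frame(
    seq = seqS, start = pmin(ss, se), end = pmax(ss, se),
    orient = ifelse(ss > se, "reverse", "forward"),
    stringsAsFactors = FALSE
  )
  a <- if (queryAs == "org1") query else subject
  b <- if (queryAs == "org1") subject else query
  records <- data.frame(
    seqA = a$seq, startA = a$start, endA = a$end, orientA = a$orient,
    seqB = b$seq, startB = b$start, endB = b$end, orientB = b$orient,
    identity = ident, aln_length = alen, evalue = eval_, bitscore = bits,
    stringsAsFactors = FALSE
  )
  list(records = records,
       attributeNames = c("identity", "aln_length", "evalue", "bitscore"))
}

#' Convert lastz/BLASTZ "general" tabular output to synteny records
#'
#' The lastz general format is user-configurable, so the column layout is
#' supplied explicitly as `fieldSpec` (the `--format=general:...` field list
#' used when lastz was run). At minimum `name1, start1, end1, name2, start2,
#' end2` must be named; `score`, `identity` and `strand2` are understood when
#' present (`strand2 == "-"` flips the side-B orientation; a trailing "%" on
#' identity values is tolerated). Unrecognized fields are ignored.
#'
#' @param lines character vector of lastz general-format lines ("#" header
#'   lines skipped).
#' @param fieldSpec ordered character vector naming each column.
#' @return list with `records` and `attributeNames`.
#' @export
lastzToSynteny <- function(lines,
                           fieldSpec = c("name1", "start1", "end1",
                                         "name2", "start2", "end2", "score")) {
  required <- c("name1", "start1", "end1", "name2", "start2", "end2")
  missingF <- setdiff(required, fieldSpec)
  if (length(missingF) > 0)
    svUsageError(paste0("fieldSpec is missing required field(s): ",
                        paste(missingF, collapse = ", ")))
  attrNames <- intersect(c("score", "identity"), fieldSpec)
  keep <- !grepl("^#", lines) & trimws(lines) != ""
  idx <- which(keep)
  n <- length(idx)
  col <- function(nm) match(nm, fieldSpec)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- idx[i]
    f <- strsplit(sub("\r$", "", lines[ln]), "\t", fixed = TRUE)[[1]]
    if (length(f) != length(fieldSpec))
      svFormatError(paste0("line ", ln, ": expected ", length(fieldSpec),
                           " columns per fieldSpec, found ", length(f)))
    s1 <- parseRowNumber(f[col("start1")], ln, "start1")
    e1 <- parseRowNumber(f[col("end1")], ln, "end1")
    s2 <- parseRowNumber(f[col("start2")], ln, "start2")
    e2 <- parseRowNumber(f[col("end2")], ln, "end2")
    orientB <- if (s2 > e2) "reverse" else "forward"
    if ("strand2" %in% fieldSpec && f[col("strand2")] == "-")
      orientB <- "reverse"
    row <- data.frame(
      seqA = f[col("name1")], startA = min(s1, e1), endA = max(s1, e1),
      orientA = if (s1 > e1) "reverse" else "forward",
      seqB = f[col("name2")], startB = min(s2, e2), endB = max(s2, e2),
      orientB = orientB, stringsAsFactors = FALSE
    )
    for (a in attrNames)
      row[[a]] <- parseRowNumber(sub("%$", "", f[col(a)]), ln, a)
    recs[[i]] <- row
  }
  records <- if (n > 0) do.call(rbind, recs) else emptyRecords(attrNames)
  rownames(records) <- NULL
  list(records = records, attributeNames = attrNames)
}

#' Track style map for GFF3 conversion
#'
#' Maps a GFF3 feature type to a (track, shape, color) display style; types
#' absent from the map fall back to `default` with the type itself as track
#' name. The stock map styles `gene` as blue arrows.
#'
#' @param ... named arguments, each `list(track=, shape=, color=)` keyed by
#'   GFF3 feature type.
#' @param default style for unmapped types (`track = NULL` means "use the
#'   feature type as track name").
#' @return a named list usable as the `style` argument of
#'   [gff3ToAnnotation()].
#' @export
trackStyleMap <- function(...,
                          default = list(track = NULL, shape = "box",
                                         color = "gray40")) {
  entries <- list(...)
  for (st in c(entries, list(default))) {
    if (!st$shape %in% SHAPE_VOCAB)
      svUsageError(paste0("style shape '", st$shape, "' not in vocabulary"))
    if (!isValidColor(st$color))
      svUsageError(paste0("style color '", st$color, "' not resolvable"))
  }
  c(entries, list(.default = default))
}

#' @rdname trackStyleMap
#' @export
defaultTrackStyles <- function() {
  trackStyleMap(
    gene = list(track = "gene", shape = "arrow", color = "blue")
  )
}

## Parse a GFF3 column-9 attribute string; returns NA on malformed input.
gff3Attributes <- function(s) {
  if (s == "." || s == "") return(list())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  parts <- parts[trimws(parts) != ""]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) return(NA)
    out[[trimws(kv[1])]] <- utils::URLdecode(kv[2])
  }
  out
}

#' Convert GFF3 features to annotation features
#'
#' Reads the 9-column GFF3 layout (1-based inclusive, same convention as the
#' annotation format, so coordinates transfer verbatim). The feature label is
#' taken from the `ID` attribute, falling back to `Name`; a malformed
#' attribute column produces a warning and the feature is kept with an empty
#' label. A line with start > end is an error (GFF3 forbids it).
#'
#' @param lines character vector of GFF3 lines.
#' @param style a [trackStyleMap()] giving track/shape/color per feature
#'   type.
#' @param typesKeep optional character vector of feature types to retain;
#'   `NULL` keeps all types.
#' @return data.frame of features, as [parseAnnotation()].
#' @export
gff3ToAnnotation <- function(lines, style = defaultTrackStyles(),
                             typesKeep = NULL) {
  recs <- list()
  for (ln in seq_along(lines)) {
    s <- sub("\r$", "", lines[ln])
    if (startsWith(s, "##FASTA")) break
    if (grepl("^#", s) || trimws(s) == "") next
    f <- strsplit(s, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      svFormatError(paste0("line ", ln, ": GFF3 requires 9 columns, found ",
                           length(f)))
    type <- f[3]
    if (!is.null(typesKeep) && !type %in% typesKeep) next
    start <- parseRowNumber(f[4], ln, "start")
    end <- parseRowNumber(f[5], ln, "end")
    if (start > end)
      svFormatError(paste0("line ", ln, ": GFF3 start (", f[4],
                           ") exceeds end (", f[5], ")"))
    if (start < 1)
      svFormatError(paste0("line ", ln, ": positions must be >= 1"))
    strand <- if (f[7] %in% c("+", "-")) f[7] else "."
    attrs <- gff3Attributes(f[9])
    label <- ""
    if (identical(attrs, NA)) {
      warning("line ", ln, ": malformed GFF3 attribute column; ",
              "feature kept with empty label", call. = FALSE)
    } else {
      label <- attrs$ID %||% attrs$Name %||% ""
    }
    st <- style[[type]] %||% style$.default
    recs[[length(recs) + 1]] <- data.frame(
      seq = f[1], start = start, end = end,
      track = st$track %||% type, shape = st$shape, color = st$color,
      strand = strand, label = label, value = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(recs) > 0) do.call(rbind, recs) else emptyFeatures()
  rownames(out) <- NULL
  out
}
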
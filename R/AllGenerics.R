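## Generics and accessors. Slots are never reached into from user code.

#' @rdname SyntenyDataset-class
#' @param x,object a `SyntenyDataset`.
#' @export
setGeneric("syntenyRecords", function(x) standardGeneric("syntenyRecords"))

#' @rdname SyntenyDataset-class
#' @export
setGeneric("annotationFeatures",
           function(x) standardGeneric("annotationFeatures"))

#' @rdname SyntenyDataset-class
#' @export
setGeneric("sequenceInfo", function(x) standardGeneric("sequenceInfo"))

#' @rdname SyntenyDataset-class
#' @export
setGeneric("attributeNames", function(x) standardGeneric("attributeNames"))

#' @rdname Scene-class
#' @param x,object a `Scene`.
#' @export
setGeneric("sceneGlyphs", function(x) standardGeneric("sceneGlyphs"))

#' @rdname Scene-class
#' @export
setGeneric("sceneCanvas", function(x) standardGeneric("sceneCanvas"))

#' @rdname SyntenyDataset-class
#' @export
setMethod("syntenyRecords", "SyntenyDataset", function(x) x@records)

#' @rdname SyntenyDataset-class
#' @export
setMethod("annotationFeatures", "SyntenyDataset", function(x) x@features)

#' @rdname SyntenyDataset-class
#' @export
setMethod("sequenceInfo", "SyntenyDataset", function(x) x@sequences)

#' @rdname SyntenyDataset-class
#' @export
setMethod("attributeNames", "SyntenyDataset", function(x) x@attributeNames)

#' @rdname Scene-class
#' @export
setMethod("sceneGlyphs", "Scene", function(x) x@glyphs)

#' @rdname Scene-class
#' @export
setMethod("sceneCanvas", "Scene", function(x) x@canvas)

#' Length of a sequence in a dataset
#'
#' @param dataset a [SyntenyDataset-class].
#' @param name sequence name.
#' @return display length in bp.
#' @export
sequenceLength <- function(dataset, name) {
  seqs <- sequenceInfo(dataset)
  i <- match(name, seqs$name)
  if (is.na(i))
    svStop(paste0("unknown sequence '", name, "'; available: ",
                  paste(seqs$name, collapse = ", ")))
  seqs$length[i]
}

setMethod("show", "SyntenyDataset", function(object) {
  cat("SyntenyDataset with", nrow(object@records), "synteny records,",
      nrow(object@features), "annotation features,",
      nrow(object@sequences), "sequences\n")
  if (length(object@attributeNames) > 0)
    cat("  attributes:", paste(object@attributeNames, collapse = ", "), "\n")
  if (nrow(object@sequences) > 0)
    cat("  sequences:",
        paste(object@sequences$name, " (",
              format(object@sequences$length, scientific = FALSE,
                     trim = TRUE),
              " bp)", sep = "", collapse = ", "), "\n")
  if (nrow(object@features) > 0)
    cat("  tracks:",
        paste(unique(object@features$track), collapse = ", "), "\n")
})

setMethod("show", "Viewport", function(object) {
  cat(sprintf("Viewport %s:%s-%s (%s bp)\n", object@seq,
              format(object@start, scientific = FALSE),
              format(object@end, scientific = FALSE),
              format(object@end - object@start + 1, scientific = FALSE)))
})

setMethod("show", "ViewState", function(object) {
  cat("ViewState pair:", object@pair[1], "vs", object@pair[2],
      "| mode:", object@displayMode, "\n")
  cat("  viewport A: "); show(object@viewportA)
  cat("  viewport B: "); show(object@viewportB)
  if (length(object@filters) > 0) {
    for (f in object@filters)
      cat(sprintf("  filter: %s in [%g, %g]\n", f$attribute, f$min, f$max))
  }
})

setMethod("show", "Scene", function(object) {
  kinds <- vapply(object@glyphs, `[[`, character(1), "kind")
  cat("Scene:", length(object@glyphs), "glyphs on",
      object@canvas@widthPx, "x", object@canvas@heightPx, "px canvas\n")
  if (length(kinds) > 0) {
    tab <- table(kinds)
    cat(" ", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})
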
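# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats runif
NULL

## Classed conditions so callers/tests can distinguish bad files from bad usage.
svStop <- function(msg, class = "synviewr_error", call. = FALSE) {
  stop(structure(
    class = c(class, "synviewr_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

svFormatError <- function(msg) svStop(msg, class = "synviewr_format_error")
svUsageError  <- function(msg) svStop(msg, class = "synviewr_usage_error")

## Round half away from zero (base round() rounds half to even).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

clampInt <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Closed glyph shape vocabulary for annotation features.
SHAPE_VOCAB <- c("box", "arrow", "line")
STRAND_VOCAB <- c("+", "-", ".")

isHexColor <- function(x) grepl("^#[0-9A-Fa-f]{6}$", x)

## A color is valid if it is #RRGGBB or a name R's color table resolves.
isValidColor <- function(x) {
  isHexColor(x) | x %in% grDevices::colors()
}

## Resolve any accepted color to lowercase "#rrggbb".
colorToHex <- function(x) {
  m <- grDevices::col2rgb(x)
  tolower(grDevices::rgb(m[1, ], m[2, ], m[3, ], maxColorValue = 255))
}

## Shortest decimal representation that round-trips through as.numeric().
formatNumeric <- function(x) {
  s <- vapply(x, function(v) {
    if (v == floor(v) && abs(v) < 1e15) {
      sprintf("%.0f", v)
    } else {
      r <- formatC(v, digits = 15, format = "g", width = -1)
      if (as.numeric(r) != v) r <- formatC(v, digits = 17, format = "g", width = -1)
      r
    }
  }, character(1))
  s
}

formatCoord <- function(x) sprintf("%.0f", x)

## Escape text for XML content.
xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
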
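#' The xvg document model
#'
#' An `xvg_document` is the common in-memory representation of a parsed
#' Grace-dialect xvg file or a delimited (CSV/.dat/.txt) file: figure-level
#' metadata (title, axis labels) plus an ordered list of datasets.  Each
#' dataset ([xvg_dataset()]) is one x/y series with an optional legend.
#'
#' @param title,x_label,y_label Character scalars; empty string when absent.
#' @param datasets List of [xvg_dataset()] objects in reading order.
#' @param source_path Path the document was read from ("" for in-memory).
#' @param dialect Either `"xvg"` or `"delimited"`.
#' @return An object of class `xvg_document`.
#' @seealso [read_xvg()], [read_delimited()], [write_xvg()], [describe()]
#' @export
xvg_document <- function(datasets, title = "", x_label = "", y_label = "",
                         source_path = "", dialect = "xvg") {
  doc <- structure(
    list(title = as.character(title),
         x_label = as.character(x_label),
         y_label = as.character(y_label),
         datasets = datasets,
         source_path = as.character(source_path),
         dialect = match.arg(dialect, c("xvg", "delimited"))),
    class = "xvg_document")
  validate_xvg_document(doc)
}

#' One x/y data series
#'
#' @param x,y Finite numeric vectors of equal length >= 1.
#' @param legend Legend text, or `NULL` when the series has none.
#' @param set_index Zero-based position of the series within its document.
#' @return An object of class `xvg_dataset`.
#' @export
xvg_dataset <- function(x, y, legend = NULL, set_index = 0L) {
  ds <- structure(
    list(x = as.numeric(x), y = as.numeric(y),
         legend = if (is.null(legend)) NULL else as.character(legend),
         set_index = as.integer(set_index)),
    class = "xvg_dataset")
  validate_xvg_dataset(ds)
}

validate_xvg_dataset <- function(ds) {
  if (length(ds$x) != length(ds$y))
    stop("dataset x and y must have equal length", call. = FALSE)
  if (length(ds$x) < 1L)
    stop("dataset must contain at least one point", call. = FALSE)
  if (!all(is.finite(ds$x)) || !all(is.finite(ds$y)))
    stop("dataset values must all be finite", call. = FALSE)
  if (ds$set_index < 0L)
    stop("set_index must be >= 0", call. = FALSE)
  ds
}

validate_xvg_document <- function(doc) {
  if (length(doc$datasets) == 0L)
    stop("document contains no datasets", call. = FALSE)
  idx <- vapply(doc$datasets, function(d) d$set_index, integer(1))
  if (!identical(idx, seq_along(idx) - 1L))
    stop("set_index values must be 0..n-1 in order", call. = FALSE)
  doc
}

#' @export
print.xvg_document <- function(x, ...) {
  cat(describe(x), sep = "\n")
  invisible(x)
}

#' @export
print.xvg_dataset <- function(x, ...) {
  lab <- if (is.null(x$legend)) sprintf("set %d", x$set_index) else x$legend
  cat(sprintf("<xvg_dataset> %s: %d points\n", lab, length(x$x)))
  invisible(x)
}

# Field-wise equality used by round-trip tests and CLI/API comparisons;
# numeric arrays compared exactly (writer emits full double precision).
documents_equal <- function(a, b) {
  if (!identical(a$title, b$title) ||
      !identical(a$x_label, b$x_label) ||
      !identical(a$y_label, b$y_label) ||
      length(a$datasets) != length(b$datasets)) return(FALSE)
  for (i in seq_along(a$datasets)) {
    da <- a$datasets[[i]]; db <- b$datasets[[i]]
    if (!identical(da$x, db$x) || !identical(da$y, db$y)) return(FALSE)
    if (!identical(da$legend, db$legend)) return(FALSE)
  }
  TRUE
}
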
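#' Read a Grace-dialect xvg file
#'
#' Parses the plain-text xvg format emitted by the GROMACS analysis tools:
#' `#` lines are comments, `@` records carry Grace metadata, data rows are
#' whitespace-separated numeric columns (column 0 is x, every further column
#' one dataset), and a line starting with `&` closes the current block so
#' several datasets can follow one another.
#'
#' Only the metadata subset GROMACS actually writes is interpreted:
#' `@ title "..."`, `@ xaxis label "..."`, `@ yaxis label "..."` and
#' `@ s<N> legend "..."`.  Every other `@` record is ignored.  Quoted values
#' are taken between the first and last double quote on the line.  Legend
#' indices bind by `N` to the N-th dataset in reading order across all
#' blocks.  Trailing `#` comments on data rows are stripped; blank lines are
#' ignored; a trailing `&` is legal and produces no empty dataset.
#'
#' @param path Path to an xvg file.
#' @return An [xvg_document()].
#' @examples
#' f <- tempfile(fileext = ".xvg")
#' writeLines(c("@ title \"T\"", "@ s0 legend \"a\"", "0 1 2", "1 3 4"), f)
#' doc <- read_xvg(f)
#' doc$title
#' length(doc$datasets)
#' @export
read_xvg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L)
    stop("empty file: ", path, call. = FALSE)

  title <- ""; x_label <- ""; y_label <- ""
  legends <- list()          # names are "s<N>" indices as character
  blocks <- list()           # each: list(rows = list of numeric vectors, ncol)
  cur_rows <- list(); cur_ncol <- NA_integer_

  close_block <- function() {
    if (length(cur_rows) > 0L) {
      blocks[[length(blocks) + 1L]] <<- list(rows = cur_rows, ncol = cur_ncol)
    }
    cur_rows <<- list(); cur_ncol <<- NA_integer_
  }

  for (i in seq_along(lines)) {
    raw <- lines[[i]]
    line <- trimws(raw)
    if (nchar(line) == 0L) next
    first <- substr(line, 1L, 1L)
    if (first == "#") next
    if (first == "@") {
      meta <- parse_at_record(line)
      if (!is.null(meta)) {
        switch(meta$key,
               title = { title <- meta$value },
               xaxis = { x_label <- meta$value },
               yaxis = { y_label <- meta$value },
               legend = { legends[[as.character(meta$index)]] <- meta$value })
      }
      next
    }
    if (first == "&") { close_block(); next }
    # data row; strip a trailing comment first
    line <- sub("#.*$", "", line)
    line <- trimws(line)
    if (nchar(line) == 0L) next
    tokens <- strsplit(line, "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tokens))
    if (anyNA(vals) || !all(is.finite(vals)))
      stop(sprintf("non-numeric or non-finite token in %s line %d: '%s'",
                   path, i, raw), call. = FALSE)
    if (is.na(cur_ncol)) {
      cur_ncol <- length(vals)
      if (cur_ncol < 2L)
        stop(sprintf("data row with fewer than 2 columns in %s line %d",
                     path, i), call. = FALSE)
    } else if (length(vals) != cur_ncol) {
      stop(sprintf("ragged row in %s line %d: expected %d columns, got %d",
                   path, i, cur_ncol, length(vals)), call. = FALSE)
    }
    cur_rows[[length(cur_rows) + 1L]] <- vals
  }
  close_block()

  if (length(blocks) == 0L)
    stop("no data rows in file: ", path, call. = FALSE)

  datasets <- list()
  for (b in blocks) {
    m <- do.call(rbind, b$rows)
    for (j in 2:b$ncol) {
      k <- length(datasets)
      datasets[[k + 1L]] <- xvg_dataset(m[, 1], m[, j], set_index = k)
    }
  }
  # bind s<N> legends by global dataset index; out-of-range N ignored
  for (nm in names(legends)) {
    n <- as.integer(nm)
    if (n >= 0L && n < length(datasets))
      datasets[[n + 1L]]$legend <- legends[[nm]]
  }
  xvg_document(datasets, title = title, x_label = x_label, y_label = y_label,
               source_path = path, dialect = "xvg")
}

# Parse one "@" metadata record; returns NULL for unsupported records.
# Supported grammar (any run of blanks between tokens):
#   @ title "..." | @ xaxis label "..." | @ yaxis label "..."
#   @ s<N> legend "..."
parse_at_record <- function(line) {
  body <- trimws(sub("^@", "", line))
  value <- quoted_value(line)
  if (grepl("^title[[:space:]]", body) && !is.null(value))
    return(list(key = "title", value = value))
  if (grepl("^xaxis[[:space:]]+label[[:space:]]", body) && !is.null(value))
    return(list(key = "xaxis", value = value))
  if (grepl("^yaxis[[:space:]]+label[[:space:]]", body) && !is.null(value))
    return(list(key = "yaxis", value = value))
  m <- regmatches(body, regexec("^s([0-9]+)[[:space:]]+legend[[:space:]]", body))[[1]]
  if (length(m) == 2L && !is.null(value))
    return(list(key = "legend", index = as.integer(m[2]), value = value))
  NULL
}

# Text between the first and last double quote; embedded quotes kept verbatim.
quoted_value <- function(line) {
  first <- regexpr('"', line, fixed = TRUE)
  if (first < 0L) return(NULL)
  last <- max(gregexpr('"', line, fixed = TRUE)[[1]])
  if (last <= first) return(NULL)
  substr(line, first + 1L, last - 1L)
}

#' Read a delimited text file (CSV, .dat, .txt)
#'
#' Reads comma-, semicolon- or whitespace-separated numeric tables, including
#' the CSV energy reports written by OpenMM.  When `delimiter` is `NULL` it
#' is sniffed: comma, then semicolon, then whitespace — the first that yields
#' at least two columns on the first data row wins.  If the first row is not
#' fully numeric it is taken as a header: the column-0 header becomes the
#' x-axis label and the remaining headers become dataset legends; a leading
#' `#` on the header row is stripped (OpenMM dialect), as are quotes around
#' column names.
#'
#' @param path Path to the file.
#' @param delimiter Optional single-character delimiter; `NULL` to sniff.
#' @return An [xvg_document()] with `dialect = "delimited"`.
#' @export
read_delimited <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop("empty file: ", path, call. = FALSE)

  split_row <- function(line, delim) {
    if (delim == "ws") strsplit(trimws(line), "[[:space:]]+")[[1]]
    else trimws(strsplit(line, delim, fixed = TRUE)[[1]])
  }
  if (is.null(delimiter)) {
    probe <- lines[[length(lines)]]  # last row is always a data row
    delim <- NULL
    for (d in c(",", ";", "ws")) {
      if (length(split_row(probe, d)) >= 2L) { delim <- d; break }
    }
    if (is.null(delim))
      stop("cannot determine delimiter (single-column file?): ", path,
           call. = FALSE)
  } else {
    delim <- if (grepl("^[[:space:]]$", delimiter)) "ws" else delimiter
  }

  first_tokens <- split_row(sub("^#", "", lines[[1]]), delim)
  first_vals <- suppressWarnings(as.numeric(first_tokens))
  has_header <- anyNA(first_vals)
  x_label <- ""; legends <- NULL
  if (has_header) {
    hdr <- gsub('^"|"$', "", first_tokens)
    x_label <- hdr[1]
    if (length(hdr) > 1L) legends <- hdr[-1]
    lines <- lines[-1]
    if (length(lines) == 0L)
      stop("no data rows in file: ", path, call. = FALSE)
  }

  ncol <- NA_integer_
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tokens <- split_row(lines[[i]], delim)
    vals <- suppressWarnings(as.numeric(tokens))
    if (anyNA(vals) || !all(is.finite(vals)))
      stop(sprintf("non-numeric or non-finite token in %s data row %d",
                   path, i), call. = FALSE)
    if (is.na(ncol)) {
      ncol <- length(vals)
      if (ncol < 2L)
        stop("data rows have fewer than 2 columns: ", path, call. = FALSE)
    } else if (length(vals) != ncol) {
      stop(sprintf("ragged row in %s data row %d: expected %d columns, got %d",
                   path, i, ncol, length(vals)), call. = FALSE)
    }
    rows[[i]] <- vals
  }
  m <- do.call(rbind, rows)
  datasets <- lapply(seq_len(ncol - 1L), function(j) {
    xvg_dataset(m[, 1], m[, j + 1L],
                legend = if (!is.null(legends) && j <= length(legends))
                  legends[j] else NULL,
                set_index = j - 1L)
  })
  xvg_document(datasets, x_label = x_label, source_path = path,
               dialect = "delimited")
}

#' Read any supported file, dispatching on extension
#'
#' `.xvg` files go to [read_xvg()]; `.csv`, `.dat` and `.txt` to
#' [read_delimited()].  Unknown extensions are tried as xvg first, then as
#' delimited; if both fail the error reports both diagnostics.
#'
#' @param path Path to the file.
#' @return An [xvg_document()].
#' @export
read_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xvg") return(read_xvg(path))
  if (ext %in% c("csv", "dat", "txt")) return(read_delimited(path))
  xvg_err <- NULL
  doc <- tryCatch(read_xvg(path), error = function(e) { xvg_err <<- e; NULL })
  if (!is.null(doc)) return(doc)
  tryCatch(read_delimited(path), error = function(e) {
    stop(sprintf("could not parse %s as xvg (%s) nor as delimited (%s)",
                 path, conditionMessage(xvg_err), conditionMessage(e)),
         call. = FALSE)
  })
}

#' Write a document as a Grace-dialect xvg file
#'
#' Emits the title, axis-label and legend `@` records followed by the data.
#' Documents whose datasets share one x vector are written as a single
#' multi-column block; otherwise each dataset becomes its own `&`-separated
#' block.  Values are written at full double precision so that
#' `read_xvg(write_xvg(d))` reproduces `d` exactly on all modeled fields.
#'
#' @param doc An [xvg_document()].
#' @param path Output path.
#' @param layout `"auto"` (multi-column when all datasets share one x,
#'   blocks otherwise), `"columns"` (requires a shared x) or `"blocks"`.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(doc, path, layout = c("auto", "columns", "blocks")) {
  layout <- match.arg(layout)
  validate_xvg_document(doc)
  out <- character(0)
  if (nzchar(doc$title))  out <- c(out, sprintf('@    title "%s"', doc$title))
  if (nzchar(doc$x_label)) out <- c(out, sprintf('@    xaxis  label "%s"', doc$x_label))
  if (nzchar(doc$y_label)) out <- c(out, sprintf('@    yaxis  label "%s"', doc$y_label))
  for (ds in doc$datasets) {
    if (!is.null(ds$legend))
      out <- c(out, sprintf('@ s%d legend "%s"', ds$set_index, ds$legend))
  }
  fmt <- function(v) sprintf("%.17g", v)
  shared_x <- all(vapply(doc$datasets, function(d)
    identical(d$x, doc$datasets[[1]]$x), logical(1)))
  if (layout == "columns" && !shared_x)
    stop("column layout requires all datasets to share one x", call. = FALSE)
  use_columns <- switch(layout,
                        auto = shared_x && length(doc$datasets) > 1L,
                        columns = TRUE,
                        blocks = FALSE)
  if (use_columns) {
    cols <- c(list(doc$datasets[[1]]$x), lapply(doc$datasets, `[[`, "y"))
    rows <- do.call(paste, c(lapply(cols, fmt), sep = " "))
    out <- c(out, rows)
  } else {
    for (k in seq_along(doc$datasets)) {
      ds <- doc$datasets[[k]]
      out <- c(out, paste(fmt(ds$x), fmt(ds$y)))
      if (k < length(doc$datasets)) out <- c(out, "&")
    }
  }
  tryCatch(writeLines(out, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Human-readable report on a parsed document
#'
#' The report behind the command line's `-debug` flag: source path, title,
#' axis labels, and for every dataset its index, legend (or `set <index>`
#' when it has none), point count and x/y ranges.
#'
#' @param doc An [xvg_document()].
#' @return A character vector of report lines.
#' @export
describe <- function(doc) {
  validate_xvg_document(doc)
  lines <- c(
    sprintf("file:    %s",
            if (nzchar(doc$source_path)) doc$source_path else "<in memory>"),
    sprintf("dialect: %s", doc$dialect),
    sprintf("title:   %s", if (nzchar(doc$title)) doc$title else "<none>"),
    sprintf("x label: %s", if (nzchar(doc$x_label)) doc$x_label else "<none>"),
    sprintf("y label: %s", if (nzchar(doc$y_label)) doc$y_label else "<none>"),
    sprintf("datasets: %d", length(doc$datasets)))
  for (ds in doc$datasets) {
    lab <- if (is.null(ds$legend)) sprintf("set %d", ds$set_index) else ds$legend
    lines <- c(lines,
      sprintf("  [%d] %s: %d points, x in [%g, %g], y in [%g, %g]",
              ds$set_index, lab, length(ds$x),
              min(ds$x), max(ds$x), min(ds$y), max(ds$y)))
  }
  lines
}
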
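#' @import ggplot2
NULL

# Fixed qualitative 10-color cycle (matplotlib "tab10" palette values; any
# fixed, documented cycle satisfies the distinctness contract).
color_cycle <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                 "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")
linestyle_cycle <- c("-", "--", ":", "-.")
marker_cycle <- c("o", "s", "^", "v", "d", "x", "+", "*")

valid_linestyles <- c(linestyle_cycle, "None")
valid_markers <- c(".", marker_cycle, "None")

linetype_map <- c("-" = "solid", "--" = "dashed", ":" = "dotted",
                  "-." = "dotdash")
shape_map <- c("." = 20, "o" = 19, "s" = 15, "^" = 17, "v" = 6,
               "d" = 18, "x" = 4, "+" = 3, "*" = 8)

#' Assign line/marker/color styles to a set of series
#'
#' User-supplied linestyle and marker tokens are applied positionally;
#' positions beyond the user lists are filled from the default cycles, so
#' giving a single style is enough and the rest are generated automatically.
#' Colors come from a fixed 10-color qualitative cycle so every series gets
#' a distinct color.  The literal token `"None"` disables a channel; a
#' series is never left with both channels disabled — a marker from the
#' default cycle is supplied when the line is `"None"` and no marker was
#' requested.
#'
#' Valid linestyles: `-`, `--`, `:`, `-.`, `None`.  Valid markers: `.`
#' (small dots), `o`, `s`, `^`, `v`, `d`, `x`, `+`, `*`, `None`.
#'
#' @param n Number of series (>= 1).
#' @param user_linestyles,user_markers Character vectors of user tokens
#'   (possibly empty).
#' @return A list of `n` style lists with elements `color`, `linestyle`,
#'   `marker` and `marker_size`; no two share the same
#'   (color, linestyle, marker) triple.
#' @export
assign_styles <- function(n, user_linestyles = character(0),
                          user_markers = character(0)) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  bad <- setdiff(user_linestyles, valid_linestyles)
  if (length(bad))
    stop("unknown linestyle token: '", bad[1], "'", call. = FALSE)
  bad <- setdiff(user_markers, valid_markers)
  if (length(bad))
    stop("unknown marker token: '", bad[1], "'", call. = FALSE)

  styles <- vector("list", n)
  for (i in seq_len(n)) {
    ls <- if (i <= length(user_linestyles)) user_linestyles[i]
          else linestyle_cycle[(i - 1L) %% length(linestyle_cycle) + 1L]
    mk <- if (i <= length(user_markers)) user_markers[i] else "None"
    if (ls == "None" && mk == "None")
      mk <- marker_cycle[(i - 1L) %% length(marker_cycle) + 1L]
    styles[[i]] <- list(
      color = color_cycle[(i - 1L) %% length(color_cycle) + 1L],
      linestyle = ls,
      marker = mk,
      marker_size = if (identical(mk, ".")) 0.8 else 1.8)
  }
  enforce_unique_triples(styles)
}

# Bump the linestyle (or marker, for line-less series) through the default
# cycle until every (color, linestyle, marker) triple in the panel is unique.
enforce_unique_triples <- function(styles) {
  triple <- function(s) paste(s$color, s$linestyle, s$marker)
  seen <- character(0)
  for (i in seq_along(styles)) {
    k <- 0L
    while (triple(styles[[i]]) %in% seen && k < 32L) {
      s <- styles[[i]]
      if (!identical(s$linestyle, "None")) {
        j <- match(s$linestyle, linestyle_cycle)
        s$linestyle <- linestyle_cycle[j %% length(linestyle_cycle) + 1L]
      } else {
        j <- match(s$marker, marker_cycle, nomatch = 0L)
        s$marker <- marker_cycle[j %% length(marker_cycle) + 1L]
      }
      styles[[i]] <- s
      k <- k + 1L
    }
    seen <- c(seen, triple(styles[[i]]))
  }
  styles
}

#' Panel layout geometry
#'
#' With panel mode `"off"` all input files share one set of axes.  With
#' panels enabled, `"stacked"` and `"top"` place one file per row (an n-by-1
#' grid) and `"side"` one file per column (1-by-n).  Panels get consecutive
#' letter labels starting at A whenever more than one panel exists.
#'
#' @param n_files Number of input files (>= 1).
#' @param mode One of `"off"`, `"stacked"`, `"top"`, `"side"`.
#' @return A list with `nrow`, `ncol`, `labels` and `mode`.
#' @export
layout_panels <- function(n_files, mode = c("off", "stacked", "top", "side")) {
  if (n_files < 1L) stop("n_files must be >= 1", call. = FALSE)
  if (!is.character(mode) || !all(mode %in% c("off", "stacked", "top", "side")))
    stop("unknown panel mode: '", mode[1], "'", call. = FALSE)
  mode <- match.arg(mode)
  n_files <- as.integer(n_files)
  if (mode == "off" || n_files == 1L)
    return(list(nrow = 1L, ncol = 1L, labels = character(0), mode = mode))
  if (mode == "side")
    list(nrow = 1L, ncol = n_files, labels = LETTERS[seq_len(n_files)],
         mode = mode)
  else  # stacked and top are synonyms: one file per row
    list(nrow = n_files, ncol = 1L, labels = LETTERS[seq_len(n_files)],
         mode = mode)
}

#' Build a complete renderable figure description
#'
#' Turns parsed documents plus options into a `plot_spec`: the ordered list
#' of panels with styled series (or a density grid), axis labels, legend
#' texts, ranges and figure-level layout and fonts.  Transforms apply in the
#' order residual, then histogram.  With `stats` set, each legend gains an
#' "(RMSD = ..., R² = ...)" annotation computed on the raw paired data.
#' With `heatmap`/`contour`/`kde` set, all points of all datasets of all
#' files are pooled into a single density grid (Boltzmann-inverted when
#' `gibbs` is set, at `opts$temperature`).  Multiple files without panels
#' merge into one all-in-one panel.
#'
#' @param docs A list of [xvg_document()] objects (or a single document).
#' @param opts A [plot_options()] object.
#' @return An object of class `plot_spec`.
#' @export
build_plot_spec <- function(docs, opts = plot_options()) {
  if (inherits(docs, "xvg_document")) docs <- list(docs)
  if (length(docs) < 1L) stop("at least one document is required", call. = FALSE)
  lapply(docs, validate_xvg_document)
  opts <- validate_options(opts)

  density_mode <- opts$heatmap || opts$contour || opts$kde
  fonts <- list(tick = opts$tick_fontsize * opts$allfontsizes,
                label = opts$label_fontsize * opts$allfontsizes,
                legend = opts$legend_fontsize * opts$allfontsizes,
                title = opts$title_fontsize * opts$allfontsizes)

  if (density_mode) {
    panels <- list(build_density_panel(docs, opts))
    layout <- layout_panels(1L, "off")
  } else {
    if (opts$panels == "off") {
      panels <- list(build_series_panel(docs, opts, legend_offset = 0L))
    } else {
      panels <- list(); offset <- 0L
      for (d in docs) {
        panels[[length(panels) + 1L]] <-
          build_series_panel(list(d), opts, legend_offset = offset)
        offset <- offset + length(d$datasets)
      }
    }
    layout <- layout_panels(length(panels), opts$panels)
    if (length(panels) > 1L)
      for (i in seq_along(panels)) panels[[i]]$label <- layout$labels[i]
  }

  structure(
    list(panels = panels, layout = layout, fonts = fonts,
         log_y = opts$log_y, square_fig = opts$square_fig,
         share_label = opts$share_label,
         legend_placement = opts$legend_placement,
         cmap = opts$cmap, output_path = opts$output_path),
    class = "plot_spec")
}

build_series_panel <- function(docs, opts, legend_offset = 0L) {
  datasets <- list(); raw <- list()
  for (d in docs) for (ds in d$datasets) {
    raw[[length(raw) + 1L]] <- ds
    if (opts$residual) ds <- residual(ds)
    if (opts$histogram) ds <- bin_histogram(ds, opts$bins)
    datasets[[length(datasets) + 1L]] <- ds
  }
  n <- length(datasets)
  # user style lists index datasets globally across files; slice this
  # panel's window so Fig-style cross-panel style lists line up
  slice <- function(v) {
    idx <- legend_offset + seq_len(n)
    v[idx[idx <= length(v)]]
  }
  styles <- assign_styles(n, slice(opts$linestyles), slice(opts$markers))

  legends <- character(n)
  for (i in seq_len(n)) {
    gi <- legend_offset + i
    lab <- if (!is.null(opts$legends) && gi <= length(opts$legends))
      opts$legends[gi]
    else if (!is.null(datasets[[i]]$legend)) datasets[[i]]$legend
    else sprintf("set %d", datasets[[i]]$set_index)
    if (opts$stats && length(raw[[i]]$x) >= 2L)
      lab <- stats_legend_text(lab, compute_stats(raw[[i]]))
    legends[i] <- lab
  }

  first <- docs[[1]]
  xr <- range(unlist(lapply(datasets, `[[`, "x")))
  yr <- range(unlist(lapply(datasets, `[[`, "y")))
  if (opts$equal_axes) {
    lim <- range(c(xr, yr))
    xr <- lim; yr <- lim
  }
  if (!is.null(opts$x_min)) xr[1] <- opts$x_min
  if (!is.null(opts$x_max)) xr[2] <- opts$x_max
  if (!is.null(opts$y_min)) yr[1] <- opts$y_min
  if (!is.null(opts$y_max)) yr[2] <- opts$y_max

  x_label <- first$x_label
  y_label <- if (opts$histogram) "Count" else first$y_label
  if (opts$histogram && nzchar(first$y_label)) x_label <- first$y_label

  list(label = NULL,
       title = if (!is.null(opts$title)) opts$title else first$title,
       x_label = x_label, y_label = y_label,
       x_range = xr, y_range = yr,
       series = lapply(seq_len(n), function(i)
         list(data = datasets[[i]], legend = legends[i],
              style = styles[[i]])),
       grid = NULL, levels = NULL, render_as = NULL, points = NULL)
}

build_density_panel <- function(docs, opts) {
  xs <- numeric(0); ys <- numeric(0)
  for (d in docs) for (ds in d$datasets) {
    if (opts$residual) ds <- residual(ds)
    xs <- c(xs, ds$x); ys <- c(ys, ds$y)
  }
  grid <- if (opts$kde) kde_density(xs, ys, grid_size = opts$bins)
          else probability_density_2d(xs, ys, bins = opts$bins)
  if (opts$gibbs) grid <- gibbs_from_density(grid, opts$temperature)
  render_as <- if (opts$heatmap) "heatmap" else "contour"
  levels <- if (render_as == "contour")
    suppressWarnings(contour_levels(grid, opts$levels)) else NULL

  first <- docs[[1]]
  xr <- range(grid$x_edges); yr <- range(grid$y_edges)
  if (opts$equal_axes) { lim <- range(c(xr, yr)); xr <- lim; yr <- lim }
  if (!is.null(opts$x_min)) xr[1] <- opts$x_min
  if (!is.null(opts$x_max)) xr[2] <- opts$x_max
  if (!is.null(opts$y_min)) yr[1] <- opts$y_min
  if (!is.null(opts$y_max)) yr[2] <- opts$y_max

  list(label = NULL,
       title = if (!is.null(opts$title)) opts$title else first$title,
       x_label = first$x_label, y_label = first$y_label,
       x_range = xr, y_range = yr,
       series = list(), grid = grid, levels = levels, render_as = render_as,
       points = if (opts$showdots) data.frame(x = xs, y = ys) else NULL)
}

#' @export
print.plot_spec <- function(x, ...) {
  cat(sprintf("<plot_spec> %d panel(s), %dx%d layout\n",
              length(x$panels), x$layout$nrow, x$layout$ncol))
  for (p in x$panels) {
    if (!is.null(p$grid))
      cat(sprintf("  panel %s: %s of %s density grid\n",
                  if (is.null(p$label)) "-" else p$label,
                  p$render_as, p$grid$kind))
    else
      cat(sprintf("  panel %s: %d series\n",
                  if (is.null(p$label)) "-" else p$label, length(p$series)))
  }
  invisible(x)
}
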
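#' Render a plot spec to a file or to the screen
#'
#' When `opts$output_path` is set the figure is written headlessly — no
#' display is needed — as PDF or PNG selected by the file extension, and the
#' embedded PDF timestamps are fixed so repeated renders of the same spec
#' are byte-identical.  Without an output path the figure is printed to the
#' active graphics device for interactive panning/zooming.
#'
#' @param spec A `plot_spec` from [build_plot_spec()].
#' @param opts The [plot_options()] the spec was built with (supplies the
#'   output path when the spec carries none).
#' @return The assembled ggplot/patchwork object, invisibly.
#' @export
render <- function(spec, opts = plot_options()) {
  if (!inherits(spec, "plot_spec")) stop("spec must be a plot_spec", call. = FALSE)
  out <- if (!is.null(spec$output_path)) spec$output_path else opts$output_path
  fig <- assemble_figure(spec)

  if (is.null(out)) {
    print(fig)
    return(invisible(fig))
  }
  ext <- tolower(tools::file_ext(out))
  size <- figure_size(spec)
  if (ext == "pdf") {
    open_dev <- function() grDevices::pdf(out, width = size$w, height = size$h,
                                          onefile = FALSE)
  } else if (ext == "png") {
    type <- if (capabilities("cairo")) "cairo" else "Xlib"
    open_dev <- function() grDevices::png(out, width = size$w, height = size$h,
                                          units = "in", res = 150, type = type)
  } else {
    stop("unsupported output extension '.", ext, "' (use .pdf or .png)",
         call. = FALSE)
  }
  tryCatch(open_dev(),
           error = function(e) stop("cannot open output file ", out, ": ",
                                    conditionMessage(e), call. = FALSE))
  ok <- FALSE
  tryCatch({ print(fig); ok <- TRUE }, finally = grDevices::dev.off())
  if (!ok) stop("rendering to ", out, " failed", call. = FALSE)
  if (ext == "pdf") normalize_pdf_timestamps(out)
  invisible(fig)
}

figure_size <- function(spec) {
  pw <- if (spec$square_fig) 5.5 else 6.5
  ph <- if (spec$square_fig) 5.5 else 4.5
  list(w = pw * spec$layout$ncol, h = ph * spec$layout$nrow)
}

assemble_figure <- function(spec) {
  n <- length(spec$panels)
  plots <- vector("list", n)
  for (i in seq_len(n)) {
    suppress_x <- spec$share_label && spec$layout$ncol == 1L && n > 1L &&
      i < n                                # stacked: only bottom keeps x label
    suppress_y <- spec$share_label && spec$layout$nrow == 1L && n > 1L &&
      i > 1L                               # side: only leftmost keeps y label
    plots[[i]] <- panel_to_ggplot(spec$panels[[i]], spec,
                                  suppress_x = suppress_x,
                                  suppress_y = suppress_y)
  }
  if (n == 1L) return(plots[[1]])
  fig <- patchwork::wrap_plots(plots, nrow = spec$layout$nrow,
                               ncol = spec$layout$ncol)
  if (length(spec$layout$labels) > 0L)
    fig <- fig + patchwork::plot_annotation(tag_levels = "A")
  fig
}

panel_to_ggplot <- function(panel, spec, suppress_x = FALSE,
                            suppress_y = FALSE) {
  p <- if (!is.null(panel$grid)) density_layer(panel, spec)
       else series_layers(panel, spec)
  fonts <- spec$fonts
  p <- p +
    labs(title = if (nzchar(panel$title %||% "")) panel$title else NULL,
         x = if (suppress_x) NULL else
           (if (nzchar(panel$x_label %||% "")) panel$x_label else NULL),
         y = if (suppress_y) NULL else
           (if (nzchar(panel$y_label %||% "")) panel$y_label else NULL)) +
    theme_bw() +
    theme(axis.text = element_text(size = fonts$tick),
          axis.title = element_text(size = fonts$label),
          legend.text = element_text(size = fonts$legend),
          legend.title = element_blank(),
          plot.title = element_text(size = fonts$title, hjust = 0.5),
          plot.tag = element_text(size = fonts$title, face = "bold"))
  p <- p + legend_theme(spec$legend_placement)
  if (spec$log_y) p <- p + scale_y_log10()
  p <- p + coord_cartesian(xlim = panel$x_range, ylim = panel$y_range,
                           expand = TRUE)
  if (spec$square_fig) p <- p + theme(aspect.ratio = 1)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

legend_theme <- function(token) {
  corners <- c("upper left" = 1, "upper right" = 2,
               "lower left" = 3, "lower right" = 4)
  if (token %in% names(corners)) {
    pos <- switch(token,
                  "upper left" = c(0.02, 0.98), "upper right" = c(0.98, 0.98),
                  "lower left" = c(0.02, 0.02), "lower right" = c(0.98, 0.02))
    just <- switch(token,
                   "upper left" = c(0, 1), "upper right" = c(1, 1),
                   "lower left" = c(0, 0), "lower right" = c(1, 0))
    return(theme(legend.position = "inside",
                 legend.position.inside = pos, legend.justification = just))
  }
  pos <- switch(token, best = "right", right = "right", left = "left",
                top = "top", bottom = "bottom", none = "none",
                stop("unknown legend placement: '", token, "'", call. = FALSE))
  theme(legend.position = pos)
}

series_layers <- function(panel, spec) {
  series <- panel$series
  sids <- make.unique(vapply(series, `[[`, character(1), "legend"))
  frames <- lapply(seq_along(series), function(i) {
    ds <- series[[i]]$data
    data.frame(x = ds$x, y = ds$y, sid = sids[i])
  })
  df <- do.call(rbind, frames)
  df$sid <- factor(df$sid, levels = sids)

  styles <- lapply(series, `[[`, "style")
  colors <- stats::setNames(vapply(styles, `[[`, character(1), "color"), sids)
  has_line <- vapply(styles, function(s) !identical(s$linestyle, "None"),
                     logical(1))
  has_marker <- vapply(styles, function(s) !identical(s$marker, "None"),
                       logical(1))
  linetypes <- stats::setNames(
    ifelse(has_line, linetype_map[vapply(styles, `[[`, character(1),
                                         "linestyle")], "blank"), sids)
  shapes <- stats::setNames(
    ifelse(has_marker, shape_map[vapply(styles, `[[`, character(1), "marker")],
           NA_real_), sids)
  sizes <- stats::setNames(vapply(styles, `[[`, numeric(1), "marker_size"),
                           sids)

  p <- ggplot(df, aes(x = .data$x, y = .data$y))
  if (any(has_line))
    p <- p + geom_line(data = df[df$sid %in% sids[has_line], , drop = FALSE],
                       aes(colour = .data$sid, linetype = .data$sid))
  if (any(has_marker))
    p <- p + geom_point(data = df[df$sid %in% sids[has_marker], , drop = FALSE],
                        aes(colour = .data$sid, shape = .data$sid,
                            size = .data$sid))
  p <- p + scale_colour_manual(values = colors, breaks = sids)
  if (any(has_line))
    p <- p + scale_linetype_manual(values = linetypes, breaks = sids)
  if (any(has_marker))
    p <- p +
      scale_shape_manual(values = shapes, breaks = sids,
                         na.translate = FALSE) +
      scale_size_manual(values = sizes, breaks = sids) +
      guides(size = "none")
  p
}

density_layer <- function(panel, spec) {
  grid <- panel$grid
  cx <- grid_centers(grid$x_edges)
  cy <- grid_centers(grid$y_edges)
  df <- expand.grid(x = cx, y = cy)
  vals <- grid$values
  vals[grid$mask] <- NA_real_
  df$value <- as.vector(vals)
  cols <- colormap_colors(spec$cmap, 256L)
  fill_name <- switch(grid$kind,
                      energy = "G (kJ/mol)",
                      probability = "P",
                      kde = "density")
  if (panel$render_as == "heatmap") {
    p <- ggplot(df, aes(x = .data$x, y = .data$y)) +
      geom_tile(aes(fill = .data$value)) +
      scale_fill_gradientn(colours = cols, na.value = "white",
                           name = fill_name)
  } else {
    p <- ggplot(df, aes(x = .data$x, y = .data$y)) +
      geom_contour(aes(z = .data$value, colour = after_stat(level)),
                   breaks = panel$levels, na.rm = TRUE) +
      scale_colour_gradientn(colours = cols, name = fill_name)
  }
  if (!is.null(panel$points))
    p <- p + geom_point(data = panel$points, aes(x = .data$x, y = .data$y),
                        size = 0.4, alpha = 0.35, colour = "black",
                        inherit.aes = FALSE)
  p + theme(legend.title = element_text())
}

#' Resolve a colormap name to a vector of colors
#'
#' Accepts any palette known to [grDevices::hcl.colors()] (matched
#' case-insensitively; includes `"viridis"`, `"plasma"`, `"inferno"`,
#' `"magma"`, `"cividis"` and many more) plus the classic `"rainbow"`.
#'
#' @param name Colormap name; default `"viridis"`.
#' @param n Number of colors.
#' @return Character vector of `n` colors.
#' @export
colormap_colors <- function(name = "viridis", n = 256L) {
  if (tolower(name) == "rainbow") return(grDevices::rainbow(n, end = 0.85))
  pals <- grDevices::hcl.pals()
  hit <- pals[tolower(pals) == tolower(name)]
  if (length(hit) == 0L)
    stop("unknown colormap: '", name, "'", call. = FALSE)
  grDevices::hcl.colors(n, hit[1])
}

# R's pdf() device embeds creation/modification timestamps; overwrite the 14
# digits in place (same byte count, so xref offsets stay valid) to make
# repeated renders byte-identical.
normalize_pdf_timestamps <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size + 16L)
  pat <- charToRaw("Date (D:")
  fixed <- charToRaw("19700101000000")
  hits <- find_raw_pattern(r, pat)
  for (h in hits) {
    start <- h + length(pat)
    if (start + 13L <= length(r)) r[start:(start + 13L)] <- fixed
  }
  writeBin(r, path)
  invisible(path)
}

find_raw_pattern <- function(r, pat) {
  cand <- which(r == pat[1])
  cand <- cand[cand + length(pat) - 1L <= length(r)]
  cand[vapply(cand, function(i)
    identical(r[i:(i + length(pat) - 1L)], pat), logical(1))]
}
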
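#' Plot options
#'
#' The complete set of user-tunable options accepted by both the command
#' line and the programmatic API.  Defaults mirror the tool's documented
#' behavior: 50 bins, 15 contour levels, 298.15 K, viridis colormap.
#'
#' @param x_min,x_max,y_min,y_max Optional axis limits; when both ends of an
#'   axis are given the rendered range equals them exactly.
#' @param log_y Logarithmic y axis.
#' @param title Figure/panel title override.
#' @param legends Character vector of dataset legend overrides, applied
#'   positionally across all datasets in reading order.
#' @param linestyles,markers Style tokens applied positionally; the literal
#'   `"None"` disables that channel for a series.  Positions beyond the
#'   given lists are filled from the default cycles (see [assign_styles()]).
#' @param panels Panel mode: `"off"` (merge all files into one plot),
#'   `"stacked"`/`"top"` (one row per file) or `"side"` (one column per
#'   file).
#' @param equal_axes Force both axes of each panel to the same range (the
#'   union of its x and y data), as used for correlation plots.
#' @param square_fig Make each panel physically square (aspect ratio 1).
#' @param share_label Suppress repeated axis labels on inner panels.
#' @param stats Append RMSD and R-squared to each legend.
#' @param histogram Replace each series by a histogram of its y values.
#' @param residual Replace each series' y by y - x.
#' @param heatmap,contour Render a pooled 2D density as a heatmap or a
#'   contour plot (mutually exclusive).
#' @param gibbs Boltzmann-invert the density into a Gibbs free-energy
#'   landscape; requires `heatmap`, `contour` or `kde`.
#' @param kde Use a Gaussian kernel density estimate instead of binning.
#' @param showdots Overlay the raw points on the density surface.
#' @param bins Bins per axis for histograms and 2D densities (default 50).
#' @param levels Number of contour levels (default 15).
#' @param temperature Absolute temperature in kelvin for the Gibbs
#'   transform (default 298.15).
#' @param cmap Colormap name (any `grDevices::hcl.pals()` palette, plus
#'   `"rainbow"`); default `"viridis"`.
#' @param tick_fontsize,label_fontsize,legend_fontsize,title_fontsize Font
#'   sizes in points.
#' @param allfontsizes Scale factor applied to every font size.
#' @param legend_placement Legend location token: `"best"`, `"right"`,
#'   `"left"`, `"top"`, `"bottom"`, `"none"`, or `"upper left"`,
#'   `"upper right"`, `"lower left"`, `"lower right"` for in-panel placement.
#' @param output_path Output file (`.pdf` or `.png`); when set, rendering is
#'   headless, otherwise an interactive window is opened.
#' @return An object of class `plot_options`.
#' @export
plot_options <- function(x_min = NULL, x_max = NULL,
                         y_min = NULL, y_max = NULL,
                         log_y = FALSE,
                         title = NULL,
                         legends = NULL,
                         linestyles = character(0),
                         markers = character(0),
                         panels = c("off", "stacked", "top", "side"),
                         equal_axes = FALSE,
                         square_fig = FALSE,
                         share_label = FALSE,
                         stats = FALSE,
                         histogram = FALSE,
                         residual = FALSE,
                         heatmap = FALSE,
                         contour = FALSE,
                         gibbs = FALSE,
                         kde = FALSE,
                         showdots = FALSE,
                         bins = 50L,
                         levels = 15L,
                         temperature = 298.15,
                         cmap = "viridis",
                         tick_fontsize = 10,
                         label_fontsize = 12,
                         legend_fontsize = 10,
                         title_fontsize = 14,
                         allfontsizes = 1,
                         legend_placement = "best",
                         output_path = NULL) {
  opts <- structure(
    list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
         log_y = isTRUE(log_y), title = title, legends = legends,
         linestyles = as.character(linestyles), markers = as.character(markers),
         panels = match.arg(panels),
         equal_axes = isTRUE(equal_axes), square_fig = isTRUE(square_fig),
         share_label = isTRUE(share_label), stats = isTRUE(stats),
         histogram = isTRUE(histogram), residual = isTRUE(residual),
         heatmap = isTRUE(heatmap), contour = isTRUE(contour),
         gibbs = isTRUE(gibbs), kde = isTRUE(kde), showdots = isTRUE(showdots),
         bins = as.integer(bins), levels = as.integer(levels),
         temperature = as.numeric(temperature), cmap = cmap,
         tick_fontsize = as.numeric(tick_fontsize),
         label_fontsize = as.numeric(label_fontsize),
         legend_fontsize = as.numeric(legend_fontsize),
         title_fontsize = as.numeric(title_fontsize),
         allfontsizes = as.numeric(allfontsizes),
         legend_placement = legend_placement,
         output_path = output_path),
    class = "plot_options")
  validate_options(opts)
}

validate_options <- function(opts) {
  if (opts$heatmap && opts$contour)
    stop("at most one of heatmap/contour may be active", call. = FALSE)
  if (opts$gibbs && !(opts$heatmap || opts$contour || opts$kde))
    stop("gibbs requires one of heatmap, contour or kde", call. = FALSE)
  density_mode <- opts$heatmap || opts$contour || opts$kde
  if (opts$histogram && density_mode)
    stop("histogram cannot be combined with heatmap/contour/kde",
         call. = FALSE)
  if (!is.null(opts$x_min) && !is.null(opts$x_max) && opts$x_min >= opts$x_max)
    stop("x_min must be < x_max", call. = FALSE)
  if (!is.null(opts$y_min) && !is.null(opts$y_max) && opts$y_min >= opts$y_max)
    stop("y_min must be < y_max", call. = FALSE)
  if (is.na(opts$bins) || opts$bins < 1L) stop("bins must be >= 1", call. = FALSE)
  if (is.na(opts$levels) || opts$levels < 1L)
    stop("levels must be >= 1", call. = FALSE)
  if (!is.finite(opts$temperature) || opts$temperature <= 0)
    stop("temperature must be positive (kelvin)", call. = FALSE)
  if (!is.finite(opts$allfontsizes) || opts$allfontsizes <= 0)
    stop("allfontsizes must be a positive scale factor", call. = FALSE)
  if (!is.null(opts$output_path)) {
    ext <- tolower(tools::file_ext(opts$output_path))
    if (!ext %in% c("pdf", "png"))
      stop("output extension must be .pdf or .png, got: ",
           opts$output_path, call. = FALSE)
  }
  opts
}
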
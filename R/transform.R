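#' Residual transform: subtract the x values from the y values
#'
#' Converts a correlation-style dataset into a residual plot, i.e. the
#' deviation of each point from the identity line: y'_i = y_i - x_i.  The x
#' values and the legend are preserved.
#'
#' @param ds An [xvg_dataset()].
#' @return A new [xvg_dataset()] with the same x and residual y.
#' @export
residual <- function(ds) {
  validate_xvg_dataset(ds)
  xvg_dataset(ds$x, ds$y - ds$x, legend = ds$legend, set_index = ds$set_index)
}

#' Histogram of the y values of a dataset
#'
#' Bins the y values into `bins` equal-width bins spanning
#' `[min(y), max(y)]`, with the rightmost bin closed so every point is
#' counted.  Returns a dataset whose x are the bin centers and y the counts;
#' the counts always sum to the number of input points.
#'
#' @param ds An [xvg_dataset()].
#' @param bins Number of bins (>= 1); defaults to 50 to match the 2D density
#'   default.
#' @return An [xvg_dataset()] of bin centers and counts.
#' @export
bin_histogram <- function(ds, bins = 50L) {
  validate_xvg_dataset(ds)
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L) stop("bins must be >= 1", call. = FALSE)
  y <- ds$y
  lo <- min(y); hi <- max(y)
  if (lo == hi) {
    # degenerate range: one conceptual location; all mass in the middle bin
    counts <- integer(bins)
    counts[ceiling(bins / 2)] <- length(y)
    centers <- rep(lo, bins) + (seq_len(bins) - (bins + 1) / 2) * 0
    return(xvg_dataset(centers, counts, legend = ds$legend,
                       set_index = ds$set_index))
  }
  width <- (hi - lo) / bins
  idx <- pmin(floor((y - lo) / width) + 1L, bins)  # closes the rightmost bin
  counts <- tabulate(idx, nbins = bins)
  centers <- lo + (seq_len(bins) - 0.5) * width
  xvg_dataset(centers, counts, legend = ds$legend, set_index = ds$set_index)
}

#' RMSD and squared correlation for a paired series
#'
#' Treats x as the reference and y as the prediction, as in a correlation
#' plot of predicted versus reference values, and computes
#' \deqn{RMSD = \sqrt{\frac{1}{n}\sum_i (y_i - x_i)^2}}
#' together with the squared Pearson correlation
#' \eqn{R^2 = \mathrm{cor}(x, y)^2}.  When either series has zero variance
#' the correlation is undefined and `r2` is returned as `NA`; the RMSD is
#' still computed.
#'
#' @param ds An [xvg_dataset()] with at least two points.
#' @return A list of class `stats_summary` with elements `rmsd`, `r2` and
#'   `n`.
#' @examples
#' ds <- xvg_dataset(c(0, 1, 2), c(1, 2, 3))
#' compute_stats(ds)  # rmsd 1 (constant offset), r2 1 (perfect correlation)
#' @export
compute_stats <- function(ds) {
  validate_xvg_dataset(ds)
  n <- length(ds$x)
  if (n < 2L) stop("at least 2 points are required", call. = FALSE)
  rmsd <- sqrt(mean((ds$y - ds$x)^2))
  r2 <- if (stats::sd(ds$x) == 0 || stats::sd(ds$y) == 0) NA_real_
        else stats::cor(ds$x, ds$y)^2
  structure(list(rmsd = rmsd, r2 = r2, n = n), class = "stats_summary")
}

#' @export
print.stats_summary <- function(x, ...) {
  cat(sprintf("RMSD = %.6g, R² = %s, n = %d\n", x$rmsd,
              if (is.na(x$r2)) "undefined" else sprintf("%.6g", x$r2), x$n))
  invisible(x)
}

# Legend annotation used by the --stats flag:
#   "<legend> (RMSD = <3 sig. digits>, R^2 = <2 decimals>)"
stats_legend_text <- function(legend, st) {
  r2_txt <- if (is.na(st$r2)) "undefined" else sprintf("%.2f", st$r2)
  sprintf("%s (RMSD = %.3g, R² = %s)", legend, st$rmsd, r2_txt)
}
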
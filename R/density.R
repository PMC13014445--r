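#' Boltzmann's constant in GROMACS energy units
#'
#' 0.008314462618 kJ mol^-1 K^-1, used by [gibbs_from_density()].
#' @export
k_boltzmann <- 0.008314462618

#' Construct a density grid
#'
#' A `density_grid` is a 2D binned surface: bin edges on each axis plus a
#' per-bin value, which is a probability mass P (dimensionless,
#' `kind = "probability"`), a kernel density estimate (per-area density,
#' `kind = "kde"`), or a Gibbs free energy G in kJ/mol (`kind = "energy"`).
#' `mask` marks bins that are undefined (unsampled); they are rendered blank.
#'
#' @param x_edges,y_edges Strictly increasing bin-edge vectors
#'   (lengths nx+1, ny+1).
#' @param values nx-by-ny numeric matrix.
#' @param kind One of `"probability"`, `"energy"`, `"kde"`.
#' @param temperature Temperature in kelvin (energy grids only).
#' @param mask nx-by-ny logical matrix, `TRUE` = undefined bin.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(x_edges, y_edges, values,
                         kind = c("probability", "energy", "kde"),
                         temperature = NULL, mask = NULL) {
  kind <- match.arg(kind)
  x_edges <- as.numeric(x_edges); y_edges <- as.numeric(y_edges)
  if (any(diff(x_edges) <= 0) || any(diff(y_edges) <= 0))
    stop("grid edges must be strictly increasing", call. = FALSE)
  values <- as.matrix(values)
  if (nrow(values) != length(x_edges) - 1L ||
      ncol(values) != length(y_edges) - 1L)
    stop("values matrix does not match edge lengths", call. = FALSE)
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  structure(list(x_edges = x_edges, y_edges = y_edges, values = values,
                 kind = kind, temperature = temperature, mask = mask),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s, %d x %d bins, %d masked\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

grid_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Binned 2D probability density
#'
#' Bins the scatter (x, y) on a `bins`-by-`bins` equal-width grid spanning
#' the data range of each coordinate and normalizes counts by the number of
#' points, so the values are per-bin probability masses summing to 1.  The
#' rightmost edge of each axis is closed.  Zero-count bins are masked as
#' undefined rather than carrying P = 0, because the downstream Boltzmann
#' inversion is undefined there.
#'
#' @param x,y Numeric vectors of equal length >= 1.
#' @param bins Number of bins per axis (default 50).
#' @return A probability [density_grid()].
#' @export
probability_density_2d <- function(x, y, bins = 50L) {
  bins <- as.integer(bins)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 1L) stop("empty input", call. = FALSE)
  if (is.na(bins) || bins < 1L) stop("bins must be >= 1", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (length(x) > 1L && (min(x) == max(x) || min(y) == max(y)))
    stop("degenerate coordinate range: all x or all y equal", call. = FALSE)
  # a single point has no range; give it unit-width bins centred on it
  span <- function(v) if (min(v) == max(v)) c(v[1] - 0.5, v[1] + 0.5)
                      else range(v)
  xr <- span(x); yr <- span(y)
  x_edges <- seq(xr[1], xr[2], length.out = bins + 1L)
  y_edges <- seq(yr[1], yr[2], length.out = bins + 1L)
  ix <- pmin(findInterval(x, x_edges), bins)  # right-closed last bin
  iy <- pmin(findInterval(y, y_edges), bins)
  counts <- matrix(tabulate((iy - 1L) * bins + ix, nbins = bins * bins),
                   nrow = bins, ncol = bins)
  p <- counts / length(x)
  density_grid(x_edges, y_edges, p, kind = "probability", mask = counts == 0L)
}

#' Gibbs free-energy landscape by Boltzmann inversion
#'
#' Converts a probability grid into a free-energy surface via
#' \deqn{G = -k_B T \ln(P / P_0)}
#' where \eqn{P_0} is the probability of the most populated bin, which by
#' definition has G = 0.  Masked (unsampled) bins stay masked: \eqn{\ln 0}
#' is undefined and assigning a capped value would invent data.  Units are
#' kJ/mol with \eqn{k_B} = 0.008314462618 kJ/mol/K ([k_boltzmann]).
#'
#' @param grid A probability [density_grid()].
#' @param temperature Absolute temperature in kelvin (default 298.15).
#' @return An energy [density_grid()] whose minimum over unmasked bins is 0.
#' @export
gibbs_from_density <- function(grid, temperature = 298.15) {
  if (!inherits(grid, "density_grid") ||
      !grid$kind %in% c("probability", "kde"))
    stop("gibbs_from_density requires a probability (or kde) density_grid",
         call. = FALSE)
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a positive number (kelvin)", call. = FALSE)
  p <- grid$values
  p[grid$mask] <- NA_real_
  p0 <- max(p, na.rm = TRUE)
  if (!is.finite(p0) || p0 <= 0)
    stop("grid has no positive probability mass", call. = FALSE)
  g <- -k_boltzmann * temperature * log(p / p0)
  g[!is.na(g) & g == 0] <- 0  # clear IEEE negative zero at the anchor bin
  g[grid$mask] <- NA_real_
  density_grid(grid$x_edges, grid$y_edges, g, kind = "energy",
               temperature = temperature, mask = grid$mask)
}

#' 2D kernel density estimate for sparse scatter data
#'
#' Gaussian-kernel density estimate on a regular `grid_size`-by-`grid_size`
#' grid, for datasets with too few points for a stable histogram.  The
#' per-axis kernel standard deviation follows Scott's rule,
#' \eqn{h_j = \sigma_j n^{-1/6}}, unless `bandwidth` overrides it; the grid
#' spans the data range padded by one bandwidth per axis.  Values are
#' per-area densities, so their Riemann sum times the cell area is close to
#' 1 for a well-contained sample.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param grid_size Grid points per axis (>= 2); default 50.
#' @param bandwidth Optional kernel standard deviation, a scalar or a
#'   length-2 vector (x, y); `NULL` for Scott's rule.
#' @return A [density_grid()] with `kind = "kde"`.
#' @export
kde_density <- function(x, y, grid_size = 50L, bandwidth = NULL) {
  grid_size <- as.integer(grid_size)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L)
    stop("kernel density estimation needs at least 3 points; ",
         "use binned densities instead", call. = FALSE)
  if (is.na(grid_size) || grid_size < 2L)
    stop("grid_size must be >= 2", call. = FALSE)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0 || abs(stats::cor(x, y)) == 1)
    stop("singular covariance (constant or collinear points); ",
         "use binned densities instead", call. = FALSE)
  if (is.null(bandwidth)) {
    h <- c(sx, sy) * n^(-1/6)  # Scott's rule for a 2D sample
  } else {
    h <- rep_len(as.numeric(bandwidth), 2L)
    if (any(!is.finite(h)) || any(h <= 0))
      stop("bandwidth must be positive", call. = FALSE)
  }
  lims <- c(min(x) - h[1], max(x) + h[1], min(y) - h[2], max(y) + h[2])
  # MASS::kde2d's h argument is 4x the Gaussian kernel standard deviation
  k <- MASS::kde2d(x, y, h = 4 * h, n = grid_size, lims = lims)
  dx <- k$x[2] - k$x[1]; dy <- k$y[2] - k$y[1]
  x_edges <- c(k$x - dx / 2, k$x[grid_size] + dx / 2)
  y_edges <- c(k$y - dy / 2, k$y[grid_size] + dy / 2)
  density_grid(x_edges, y_edges, k$z, kind = "kde")
}

#' Evenly spaced contour levels for a density grid
#'
#' Returns `n_levels` strictly increasing values evenly spaced over the open
#' interval (min, max) of the unmasked grid values: level i is
#' `min + i (max - min) / (n_levels + 1)`.  A constant grid yields a single
#' degenerate level with a warning.
#'
#' @param grid A [density_grid()].
#' @param n_levels Number of levels (default 15).
#' @return Numeric vector of contour levels.
#' @export
contour_levels <- function(grid, n_levels = 15L) {
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 1L)
    stop("n_levels must be >= 1", call. = FALSE)
  v <- grid$values[!grid$mask]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("grid has no unmasked bins", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    warning("constant grid: returning a single degenerate level")
    return(lo)
  }
  lo + seq_len(n_levels) * (hi - lo) / (n_levels + 1L)
}
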
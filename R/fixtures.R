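# Seeded synthetic-input generators.  Each writes a file in the same
# dialects the readers accept, shaped like real simulation-analysis output
# (saturating RMSD traces, thermostat/barostat series, train/test
# correlation scatters, PCA projections).  All randomness flows from the
# explicit seed argument and the caller's RNG state is left untouched, so
# the same recipe always produces byte-identical files.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

write_fixture <- function(doc, path, dialect) {
  if (dialect == "xvg") return(write_xvg(doc, path))
  sep <- if (dialect == "csv") "," else " "
  out <- character(0)
  if (dialect == "csv") {
    # OpenMM-style header: leading '#', quoted column names
    hdr <- c(doc$x_label,
             vapply(doc$datasets, function(d)
               if (is.null(d$legend)) sprintf("set %d", d$set_index)
               else d$legend, character(1)))
    out <- c(out, paste0("#", paste(sprintf('"%s"', hdr), collapse = ",")))
  }
  fmt <- function(v) sprintf("%.17g", v)
  cols <- c(list(doc$datasets[[1]]$x), lapply(doc$datasets, `[[`, "y"))
  out <- c(out, do.call(paste, c(lapply(cols, fmt), sep = sep)))
  writeLines(out, path)
  invisible(path)
}

#' Synthetic saturating time series (RMSD-trace shape)
#'
#' A monotone-saturating mean curve `a (1 - exp(-t / tau))` — the shape of a
#' protein backbone-RMSD trace equilibrating over a few nanoseconds — plus
#' Gaussian noise, with title, axis labels and a legend populated.
#'
#' @param path Output file path.
#' @param n_points Number of points (>= 2); default 500.
#' @param seed RNG seed.
#' @param noise_sd Gaussian noise standard deviation in nm (default 0.01).
#' @param dialect One of `"xvg"`, `"csv"`, `"dat"`.
#' @return `path`, invisibly.
#' @export
make_timeseries <- function(path, n_points = 500L, seed = 1L,
                            noise_sd = 0.01, dialect = c("xvg", "csv", "dat")) {
  dialect <- match.arg(dialect)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  t <- seq(0, 10, length.out = n_points)                # ns
  mean_curve <- 0.25 * (1 - exp(-t / 1.5))              # nm, saturates ~2.5 A
  y <- with_local_seed(seed, mean_curve + stats::rnorm(n_points, 0, noise_sd))
  doc <- xvg_document(
    list(xvg_dataset(t, y, legend = "C-alpha RMSD")),
    title = "RMSD after lsq fit",
    x_label = "Time (ns)", y_label = "RMSD (nm)")
  write_fixture(doc, path, dialect)
}

#' Synthetic multi-series file (thermostat/barostat shape)
#'
#' Several series on one shared time axis — the first two shaped like a
#' system temperature fluctuating around 300 K and a pressure around 1 bar —
#' written either as one multi-column block or as `&`-separated blocks
#' encoding the same data.
#'
#' @param path Output file path.
#' @param n_series Number of series (>= 2).
#' @param n_points Points per series.
#' @param seed RNG seed.
#' @param noise_sd Noise scale (each series' own scale multiplies it).
#' @param layout `"columns"` for a shared-x multi-column block,
#'   `"blocks"` for `&`-separated blocks.
#' @return `path`, invisibly.
#' @export
make_multiseries <- function(path, n_series = 2L, n_points = 500L, seed = 2L,
                             noise_sd = 1, layout = c("columns", "blocks")) {
  layout <- match.arg(layout)
  if (n_series < 2L) stop("n_series must be >= 2", call. = FALSE)
  t <- seq(0, 10, length.out = n_points)
  levels <- rep_len(c(300, 1, 50, -120, 5), n_series)
  scales <- rep_len(c(2, 100, 5, 10, 1), n_series)
  names <- c("Temperature", "Pressure",
             sprintf("Observable %d", seq_len(max(0L, n_series - 2L)) + 2L))
  ys <- with_local_seed(seed, lapply(seq_len(n_series), function(j)
    levels[j] + stats::rnorm(n_points, 0, noise_sd * scales[j])))
  datasets <- lapply(seq_len(n_series), function(j)
    xvg_dataset(t, ys[[j]], legend = names[j], set_index = j - 1L))
  doc <- xvg_document(datasets, title = "System observables",
                      x_label = "Time (ns)", y_label = "Value")
  write_xvg(doc, path, layout = layout)
}

#' Synthetic correlation scatter with a target squared correlation
#'
#' Paired (reference, prediction) values shaped like a train/test energy
#' comparison: reference energies drawn from a normal distribution with
#' spread 10 kJ/mol and predictions equal to the reference plus Gaussian
#' noise calibrated so the sample squared correlation approaches `true_r2`
#' as n grows (`noise_sd` overrides the calibration when given).
#'
#' @param path Output file path.
#' @param n_points Number of pairs.
#' @param seed RNG seed.
#' @param true_r2 Target squared correlation in (0, 1].
#' @param noise_sd Optional explicit noise standard deviation (kJ/mol).
#' @param dialect One of `"xvg"`, `"csv"`, `"dat"`.
#' @return `path`, invisibly.
#' @export
make_scatter_correlation <- function(path, n_points = 1000L, seed = 3L,
                                     true_r2 = 0.9, noise_sd = NULL,
                                     dialect = c("xvg", "csv", "dat")) {
  dialect <- match.arg(dialect)
  if (!is.finite(true_r2) || true_r2 <= 0 || true_r2 > 1)
    stop("true_r2 must be in (0, 1]", call. = FALSE)
  sigma_x <- 10                                         # kJ/mol
  if (is.null(noise_sd)) noise_sd <- sigma_x * sqrt(1 / true_r2 - 1)
  xy <- with_local_seed(seed, {
    x <- stats::rnorm(n_points, 0, sigma_x)
    list(x = x, y = x + noise_sd * stats::rnorm(n_points))
  })
  doc <- xvg_document(
    list(xvg_dataset(xy$x, xy$y, legend = "model")),
    title = "Model vs reference energies",
    x_label = "Reference (kJ/mol)", y_label = "Model (kJ/mol)")
  write_fixture(doc, path, dialect)
}

#' Synthetic 2D projection scatter (Gaussian mixture)
#'
#' A mixture of `n_modes` isotropic Gaussian clusters with distinct,
#' strictly decreasing weights, shaped like the projection of a trajectory
#' on its first two principal components.  With the default weights the
#' most populated density bin is unambiguous, so the free-energy minimum of
#' the derived landscape sits at the heaviest mode.
#'
#' @param path Output file path.
#' @param n_points Number of points.
#' @param seed RNG seed.
#' @param n_modes Number of mixture modes (>= 1).
#' @param weights Optional mode weights (summing to 1); default
#'   proportional to `9^-(j-1)` (0.9/0.1 for two modes).
#' @param spread Per-mode isotropic standard deviation (default 0.15).
#' @param dialect One of `"xvg"`, `"csv"`, `"dat"`.
#' @return `path`, invisibly.
#' @export
make_projection_2d <- function(path, n_points = 2000L, seed = 4L,
                               n_modes = 2L, weights = NULL, spread = 0.15,
                               dialect = c("xvg", "csv", "dat")) {
  dialect <- match.arg(dialect)
  if (n_modes < 1L) stop("n_modes must be >= 1", call. = FALSE)
  if (is.null(weights)) {
    weights <- 9^-(seq_len(n_modes) - 1)
    weights <- weights / sum(weights)
  }
  if (length(weights) != n_modes || any(weights <= 0))
    stop("weights must be positive, one per mode", call. = FALSE)
  centers <- fixture_mode_centers(n_modes)
  xy <- with_local_seed(seed, {
    comp <- sample.int(n_modes, n_points, replace = TRUE, prob = weights)
    list(x = centers[comp, 1] + stats::rnorm(n_points, 0, spread),
         y = centers[comp, 2] + stats::rnorm(n_points, 0, spread))
  })
  doc <- xvg_document(
    list(xvg_dataset(xy$x, xy$y, legend = "projection")),
    title = "Projection on eigenvectors",
    x_label = "PC1 (nm)", y_label = "PC2 (nm)")
  write_fixture(doc, path, dialect)
}

# Deterministic, well-separated mode centers on a circle of radius 1.2 nm
# (origin for a single mode).
fixture_mode_centers <- function(n_modes) {
  if (n_modes == 1L) return(matrix(0, 1, 2))
  ang <- 2 * pi * (seq_len(n_modes) - 1) / n_modes
  cbind(1.2 * cos(ang), 1.2 * sin(ang))
}
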
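style_triple <- function(s) paste(s$color, s$linestyle, s$marker)

test_that("user style tokens apply positionally and cycles fill the rest", {
  st <- assign_styles(3, c("-", "None", "-"), c("None", ".", "o"))
  expect_identical(st[[1]]$linestyle, "-")
  expect_identical(st[[1]]$marker, "None")
  expect_identical(st[[2]]$linestyle, "None")
  expect_identical(st[[2]]$marker, ".")
  expect_lt(st[[2]]$marker_size, st[[3]]$marker_size)  # small dots vs dots
  expect_identical(st[[3]]$marker, "o")
  cols <- vapply(st, `[[`, character(1), "color")
  expect_length(unique(cols), 3)

  st2 <- assign_styles(3, c("-"), character(0))
  expect_identical(st2[[1]]$linestyle, "-")
  expect_false(any(vapply(st2, `[[`, character(1), "linestyle") == "None"))
  expect_length(unique(vapply(st2, `[[`, character(1), "color")), 3)

  st3 <- assign_styles(1)
  expect_true(st3[[1]]$linestyle != "None" || st3[[1]]$marker != "None")
})

test_that("a series is never left invisible and tokens are validated", {
  st <- assign_styles(2, c("None", "None"), character(0))
  for (s in st) expect_true(s$linestyle != "None" || s$marker != "None")
  expect_error(assign_styles(2, c("~"), character(0)), "~")
  expect_error(assign_styles(2, character(0), c("z")), "z")
})

test_that("style triples are unique within a panel", {
  for (n in c(1:8, 12, 25)) {
    st <- assign_styles(n)
    expect_length(unique(vapply(st, style_triple, character(1))), n)
  }
  # adversarial user lists forcing collisions
  st <- assign_styles(12, rep("-", 12), rep("o", 12))
  expect_length(unique(vapply(st, style_triple, character(1))), 12)
})

test_that("panel layouts follow the stacked/top/side grammar", {
  l <- layout_panels(2, "stacked")
  expect_identical(c(l$nrow, l$ncol), c(2L, 1L))
  expect_identical(l$labels, c("A", "B"))
  expect_identical(layout_panels(2, "top")[c("nrow", "ncol")],
                   l[c("nrow", "ncol")])  # synonym
  s <- layout_panels(2, "side")
  expect_identical(c(s$nrow, s$ncol), c(1L, 2L))
  one <- layout_panels(1, "stacked")
  expect_length(one$labels, 0)
  off <- layout_panels(5, "off")
  expect_identical(c(off$nrow, off$ncol), c(1L, 1L))
  expect_error(layout_panels(2, "diagonal"), "mode")
  for (n in 1:8)
    expect_identical(layout_panels(n, "side")$labels,
                     if (n > 1) LETTERS[seq_len(n)] else character(0))
})

make_doc <- function(seed = 1, n_sets = 1, n = 20) {
  set.seed(seed)
  xvg_document(lapply(seq_len(n_sets) - 1L, function(k)
    xvg_dataset(sort(stats::runif(n)), stats::rnorm(n),
                legend = paste("series", k), set_index = k)),
    title = "doc", x_label = "X", y_label = "Y")
}

test_that("multiple files without panels merge into one all-in-one panel", {
  spec <- build_plot_spec(list(make_doc(1), make_doc(2)), plot_options())
  expect_length(spec$panels, 1)
  expect_length(spec$panels[[1]]$series, 2)
  triples <- vapply(spec$panels[[1]]$series,
                    function(s) style_triple(s$style), character(1))
  expect_length(unique(triples), 2)
})

test_that("panel mode gives one labeled panel per file", {
  docs <- list(make_doc(1), make_doc(2), make_doc(3))
  spec <- build_plot_spec(docs, plot_options(panels = "side"))
  expect_length(spec$panels, 3)
  expect_identical(vapply(spec$panels, `[[`, character(1), "label"),
                   c("A", "B", "C"))
  expect_identical(c(spec$layout$nrow, spec$layout$ncol), c(1L, 3L))
})

test_that("stats annotations land in the legend text", {
  spec <- build_plot_spec(make_doc(4), plot_options(stats = TRUE))
  leg <- spec$panels[[1]]$series[[1]]$legend
  expect_match(leg, "RMSD = ")
  expect_match(leg, "R² = [0-9]+\\.[0-9]{2}\\)")
})

test_that("equal axes force a shared range; explicit limits are exact", {
  spec <- build_plot_spec(make_doc(5), plot_options(equal_axes = TRUE))
  p <- spec$panels[[1]]
  expect_identical(p$x_range, p$y_range)
  spec2 <- build_plot_spec(make_doc(5),
                           plot_options(x_min = -2, x_max = 7,
                                        y_min = 0, y_max = 1))
  expect_identical(spec2$panels[[1]]$x_range, c(-2, 7))
  expect_identical(spec2$panels[[1]]$y_range, c(0, 1))
})

test_that("allfontsizes scales every font in the spec", {
  base <- build_plot_spec(make_doc(6), plot_options())
  scaled <- build_plot_spec(make_doc(6), plot_options(allfontsizes = 1.5))
  for (f in names(base$fonts))
    expect_equal(scaled$fonts[[f]], 1.5 * base$fonts[[f]])
})

test_that("legend overrides apply positionally across datasets", {
  spec <- build_plot_spec(list(make_doc(1), make_doc(2)),
                          plot_options(legends = c("first", "second")))
  expect_identical(vapply(spec$panels[[1]]$series, `[[`, character(1),
                          "legend"),
                   c("first", "second"))
})

test_that("density mode pools every dataset into one grid", {
  docs <- list(make_doc(7, n = 200), make_doc(8, n = 300))
  spec <- build_plot_spec(docs, plot_options(heatmap = TRUE, bins = 10))
  expect_length(spec$panels, 1)
  grid <- spec$panels[[1]]$grid
  expect_identical(dim(grid$values), c(10L, 10L))
  expect_identical(grid$kind, "probability")
  # all 500 pooled points are in the grid
  expect_equal(sum(grid$values), 1, tolerance = 1e-9)
  spec_g <- build_plot_spec(docs, plot_options(contour = TRUE, gibbs = TRUE,
                                               bins = 10))
  expect_identical(spec_g$panels[[1]]$grid$kind, "energy")
  expect_identical(spec_g$panels[[1]]$grid$temperature, 298.15)
  expect_length(spec_g$panels[[1]]$levels, 15)
})

test_that("incompatible flag combinations are rejected", {
  expect_error(plot_options(gibbs = TRUE), "gibbs")
  expect_error(plot_options(histogram = TRUE, heatmap = TRUE), "histogram")
  expect_error(plot_options(heatmap = TRUE, contour = TRUE), "heatmap|contour")
  expect_error(plot_options(x_min = 3, x_max = 1), "x_min")
  expect_error(plot_options(output_path = "x.svg"), "extension")
})

test_that("residual and histogram transforms compose in order", {
  set.seed(2)
  x <- stats::rnorm(100); y <- x + stats::rnorm(100, 0, 0.1)
  doc <- xvg_document(list(xvg_dataset(x, y)))
  spec <- build_plot_spec(doc, plot_options(residual = TRUE,
                                            histogram = TRUE, bins = 12))
  ds <- spec$panels[[1]]$series[[1]]$data
  expect_length(ds$y, 12)
  expect_equal(sum(ds$y), 100)
  # bin centers cover the residual range, not the raw y range
  expect_true(all(ds$x > min(y - x)) && all(ds$x < max(y - x)))
})

test_that("headless rendering writes files with correct magic bytes", {
  f <- make_doc(9)
  png_path <- withr::local_tempfile(fileext = ".png")
  pdf_path <- withr::local_tempfile(fileext = ".pdf")
  spec <- build_plot_spec(f, plot_options(output_path = png_path))
  render(spec, plot_options(output_path = png_path))
  expect_gt(file.info(png_path)$size, 0)
  expect_identical(readBin(png_path, "raw", 8),
                   as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
  spec2 <- build_plot_spec(f, plot_options(output_path = pdf_path))
  render(spec2, plot_options(output_path = pdf_path))
  expect_identical(rawToChar(readBin(pdf_path, "raw", 4)), "%PDF")
  expect_error(render(build_plot_spec(f, plot_options()),
                      plot_options(output_path = "x.svg")), "extension")
})

test_that("rendering the same spec twice is byte-identical", {
  doc <- make_doc(10, n_sets = 2)
  opts <- plot_options(stats = TRUE)
  spec <- build_plot_spec(doc, opts)
  for (ext in c(".pdf", ".png")) {
    a <- withr::local_tempfile(fileext = ext)
    b <- withr::local_tempfile(fileext = ext)
    render(spec, plot_options(output_path = a, stats = TRUE))
    Sys.sleep(if (ext == ".pdf") 1.05 else 0)  # cross a timestamp second
    render(spec, plot_options(output_path = b, stats = TRUE))
    expect_identical(readBin(a, "raw", 1e7), readBin(b, "raw", 1e7))
  }
})

test_that("density figures render as heatmap and contour with overlays", {
  set.seed(30)
  doc <- xvg_document(list(xvg_dataset(stats::rnorm(500), stats::rnorm(500))))
  for (o in list(plot_options(heatmap = TRUE, gibbs = TRUE, showdots = TRUE),
                 plot_options(contour = TRUE, cmap = "plasma"),
                 plot_options(kde = TRUE, contour = TRUE, gibbs = TRUE))) {
    out <- withr::local_tempfile(fileext = ".png")
    o$output_path <- out
    spec <- build_plot_spec(doc, o)
    expect_silent(suppressMessages(render(spec, o)))
    expect_gt(file.info(out)$size, 0)
  }
})

test_that("colormap resolution accepts known names and rejects others", {
  expect_length(colormap_colors("viridis", 16), 16)
  expect_length(colormap_colors("rainbow", 8), 8)
  expect_length(colormap_colors("Plasma", 4), 4)
  expect_error(colormap_colors("not-a-map"), "colormap")
})
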
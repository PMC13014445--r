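# Shared helpers: write literal xvg content to a temp file; build randomized
# documents for round-trip property tests.

write_tmp <- function(lines, ext = ".xvg") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

rand_text <- function(n_words = 2) {
  paste(replicate(n_words,
                  paste0(sample(letters, sample(3:8, 1), TRUE), collapse = "")),
        collapse = " ")
}

# A randomized but valid document: 1-4 datasets, shared-x or per-set x,
# optional title/labels, a random subset of legends.
random_document <- function(seed) {
  set.seed(seed)
  n_sets <- sample(1:4, 1)
  shared <- runif(1) < 0.5
  len <- sample(1:25, 1)
  mk_x <- function() sort(stats::rnorm(len))
  x_shared <- mk_x()
  datasets <- lapply(seq_len(n_sets), function(k) {
    xvg_dataset(if (shared) x_shared else mk_x(),
                stats::rnorm(len),
                legend = if (runif(1) < 0.7) rand_text(1) else NULL,
                set_index = k - 1L)
  })
  xvg_document(datasets,
               title = if (runif(1) < 0.5) rand_text(2) else "",
               x_label = if (runif(1) < 0.5) rand_text(1) else "",
               y_label = if (runif(1) < 0.5) rand_text(1) else "")
}

expect_documents_equal <- function(a, b) {
  expect_identical(a$title, b$title)
  expect_identical(a$x_label, b$x_label)
  expect_identical(a$y_label, b$y_label)
  expect_equal(length(a$datasets), length(b$datasets))
  for (i in seq_along(a$datasets)) {
    expect_identical(a$datasets[[i]]$x, b$datasets[[i]]$x)
    expect_identical(a$datasets[[i]]$y, b$datasets[[i]]$y)
    expect_identical(a$datasets[[i]]$legend, b$datasets[[i]]$legend)
  }
}
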
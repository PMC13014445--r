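---
title: "Methods: from simulation output to figures and free-energy landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from simulation output to figures and free-energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xvgplot)
```

# The document model and the xvg dialect

Everything in `xvgplot` flows through one in-memory representation, the
`xvg_document`: a title, axis labels, and an ordered list of x/y datasets
with optional legends.  Two reader families populate it.

`read_xvg()` parses the Grace dialect as emitted by the GROMACS analysis
tools.  Only the metadata subset those tools actually write is
interpreted — `title`, `xaxis label`, `yaxis label` and `s<N> legend` —
with the value taken between the first and last double quote on the line;
every other `@` record (views, world coordinates, fonts, `TYPE`, ...) is
deliberately ignored, because supporting the full Grace project grammar
would buy nothing for files that originate from simulation analysis.
Data rows are whitespace-separated columns, column 0 being x and every
further column one dataset; a `&` line closes the block so further
datasets (with their own x) can follow.  Legend indices `s<N>` bind by N
to the N-th dataset in reading order across all blocks — the dialect
itself does not say whether `&` resets legend numbering, and global
binding matches the order in which GROMACS emits both.

`read_delimited()` covers comma-, semicolon- and whitespace-separated
tables, including OpenMM's CSV energy reports whose header row starts
with `#` and carries quoted column names; a non-numeric first row is
treated as a header, its first field becoming the x-axis label and the
rest dataset legends.  The delimiter is sniffed in the fixed order comma,
semicolon, whitespace — the first that splits a data row into at least
two fields — which is unambiguous for numeric tables because a numeric
field cannot contain the winning delimiter.

Both parsers are strict where it matters for downstream numerics:
non-numeric and non-finite (`nan`/`inf`) tokens are errors with a file
and line number, as are ragged rows, rather than silently dropped
observations.  `write_xvg()` emits values at full double precision
(`%.17g`), so a parse–write–parse cycle is an exact identity on every
modeled field; the test suite exercises this round trip on hundreds of
randomized documents.

# Transforms and correlation statistics

`residual()` maps y to y − x, turning a predicted-versus-reference
scatter into deviations from the identity line.  `bin_histogram()` uses
equal-width bins over the observed range with the rightmost bin closed,
so counts are conserved exactly for every input and bin choice.

`compute_stats()` reports, for paired series,
RMSD = √(Σ(yᵢ−xᵢ)²/n) and R² defined as the **squared Pearson
correlation**.  An alternative definition — the coefficient of
determination about the identity line, 1 − SSres/SStot — penalizes
systematic offsets that RMSD already captures; squared correlation keeps
the two numbers complementary, which is the usual convention for
correlation plots, and is the definition used here throughout.  When the
`stats` option is set the pair is appended to the legend as
`(RMSD = <3 significant digits>, R² = <2 decimals>)`.  Statistics are
computed on the *raw* paired data even when a residual or histogram
transform is also requested, since they describe the underlying
correlation, not its re-plotting.  Zero-variance input makes the
correlation undefined; it is reported as `NA` rather than 0 or 1, and the
RMSD is still returned.

# Densities and free-energy landscapes

`probability_density_2d()` bins a scatter on an equal-width bins × bins
grid spanning the data range (default **50**, tunable with `bins`).  The
stored value is per-bin probability *mass*, counts/N — not a per-area
density — so that Σ P = 1 holds exactly and is testable; the Boltzmann
inversion below uses only the *ratio* P/P₀, for which the distinction
cancels.  Zero-count bins are masked as undefined: ln 0 is undefined, and
capping it at some large energy would invent data where none was
sampled.  Rendering shows masked bins blank.

`gibbs_from_density()` converts probability to a Gibbs free-energy
surface by Boltzmann inversion,

$$G = -k_B T \ln(P / P_0),$$

with P₀ the maximum bin probability, so the most populated bin has
exactly G = 0 and every other bin a positive energy.  k_B is
0.008314462618 kJ·mol⁻¹·K⁻¹ (the GROMACS energy convention) and T
defaults to **298.15 K** (`temperature`).  Two consequences are worth
stating because the tests rely on them: G is antitone in P within one
grid, and G is exactly linear in T bin-wise.  The transform is also
accepted on kernel-density grids: the formula only involves the ratio to
the grid maximum, so it is well defined there too, but the result then
inherits the KDE's smoothing bias — minima get slightly broadened — which
is why binned input is the default route.

`kde_density()` serves datasets too small for stable histograms.  It
evaluates a Gaussian product kernel (via the standard 2D KDE in `MASS`)
with per-axis bandwidths from Scott's rule, hⱼ = σⱼ·n^(−1/6), on a
regular grid spanning the data range padded by one bandwidth per axis.
The padding keeps most of the edge kernels' mass on the grid, so the
Riemann sum of the grid times the cell area is close to 1 for a
well-contained sample (checked to 5% in the tests).  Collinear or
constant input makes the kernel covariance singular; the error message
directs the user to binned densities instead.

`contour_levels()` places `levels` values (default **15**) evenly inside
the open interval between the smallest and largest unmasked grid value,
so no contour coincides with the degenerate extremes.

# Figure assembly

`assign_styles()` implements the "give one style, get the rest"
behavior: user linestyle/marker tokens apply positionally, later
positions fall back to documented default cycles, and colors come from a
fixed 10-color qualitative cycle (the widely used "tab10" values — the
contract is distinctness, not specific hues).  `"None"` disables a
channel, but a series is never left with both channels off.  A final
pass guarantees that no two series in a panel share the full
(color, linestyle, marker) triple, bumping the cycled channel when user
input forces a collision.

`layout_panels()` maps the panel mode to geometry: by default panels
stack vertically (n × 1), `side` lays them out 1 × n, and `top` is
treated as a synonym of stacked — the mode names describe the axis along
which panels accumulate, and a distinct "1 × n with labels on top"
reading has no observable difference from `side` in this model.  Panels
are labeled A, B, C, ... whenever more than one exists; letters are
placed outside the panel's top-left corner by the renderer.

`build_plot_spec()` is the single code path behind both the CLI and the
API, which is what makes their equivalence testable as object identity.
Transforms apply in the order residual → histogram.  Density modes pool
every point of every dataset of every input file into one grid and one
panel — a landscape is a property of the pooled ensemble, so per-file
panels are not meaningful there.  `equal_axes` sets both axes of a panel
to the union of its x and y ranges (for correlation plots);
`square_fig` instead fixes the physical aspect ratio at 1.  Explicit
`x_min`/`x_max`/`y_min`/`y_max` override the computed ranges exactly.
`allfontsizes` is a pure multiplier on the four font sizes, applied in
the spec so it can be verified without rasterizing.

`render()` draws the spec with ggplot2 (panels combined via patchwork)
and writes PDF or PNG by extension.  Rendering is headless — no display
is required — and deterministic: PNG output is byte-stable as produced,
and the timestamps the PDF device embeds are rewritten in place (same
byte length, so the file's cross-reference offsets stay valid), making
repeated renders byte-identical and therefore diffable in pipelines.

# The synthetic-data generators

The fixture module writes the same dialects the readers accept, shaped
like the data the tool is used on, with all randomness flowing from an
explicit per-recipe seed (the caller's RNG state is saved and restored,
and identical recipes produce byte-identical files):

* `make_timeseries()`: a saturating curve 0.25·(1 − e^(−t/1.5)) nm over
  10 ns plus Gaussian noise (default σ = 0.01 nm) — the shape of a
  protein backbone-RMSD trace equilibrating; amplitude, timescale and
  noise are typical of a small soluble protein on that horizon.
* `make_multiseries()`: series fluctuating around 300 K (σ ≈ 2 K) and
  1 bar (σ ≈ 100 bar) on a shared time axis — thermostat/barostat
  output, where instantaneous pressure fluctuations of order 100 bar
  for a small box are physically realistic — writable as one
  multi-column block or as `&`-separated blocks of the same data.
* `make_scatter_correlation()`: reference values with σ = 10 kJ/mol and
  predictions offset by Gaussian noise calibrated as
  σ_noise = 10·√(1/R²_target − 1), so the sample squared correlation
  converges to the target as n grows.
* `make_projection_2d()`: a Gaussian mixture on a 1.2-nm circle with
  strictly decreasing weights (0.9/0.1 for two modes) and per-mode
  spread 0.15 nm — the shape of a trajectory projected on two principal
  components with one dominant conformational basin.

What these fixtures do **not** emulate: autocorrelation within time
series (points are independent given the mean curve), heavy-tailed or
skewed observables, drift, anisotropic or curved free-energy basins, and
file-format pathologies beyond those the parser contracts cover.  Tests
passing on them therefore validate the parsing, transformation,
inversion and rendering machinery — not the statistical subtleties of any
particular real trajectory.

# Numerical choices and limitations

* Rightmost bin edges are closed (histograms and 2D densities), so the
  maximum always lands in the last bin and counts are conserved.
* A single point has no range; it gets unit-width bins centered on it,
  while multi-point degenerate input (all x equal) is rejected.
* Free energies at exactly P = P₀ are forced to +0 to avoid IEEE
  negative zero leaking into output.
* Test problem sizes were chosen for tight statistical checks at
  interactive runtimes: 10⁴ points for correlation recovery (±0.05 on
  R²), a few thousand for landscape mode location, 200 randomized
  documents for round-trip identity; the full suite runs in well under a
  minute.
* The CLI's short flag spellings beyond `-f`, `-debug` and `-help` are
  this package's own (see `--help`); long names follow the established
  flag vocabulary.
* Out of scope: full Grace project files, EPS/SVG output, reweighting of
  biased sampling, error estimates on G, and 3D landscapes.
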
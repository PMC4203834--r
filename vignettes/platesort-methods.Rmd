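---
title: "platesort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{platesort: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platesort)
```

## The data and the problem

COPAS and BioSorter large-particle flow cytometers record, for every
object that transits the flow cell, a time of flight (TOF, a proxy for
object length), an integrated extinction (EXT, optical density) and
three integrated fluorescence channels (green, yellow, red). With a
plate sampler the instrument reads a standard 96-well microtiter plate
well by well and writes a flat, tab-delimited text file with one line
per object. Three practical problems dominate analysis of these files:
the instrument cannot tell organisms from air bubbles or precipitate;
integrated optical measures scale with object length; and long-running
plates develop positional (edge) artifacts. platesort addresses each
step of that workflow: parsing, filtering, normalization, per-well
summarization, positional statistics, and plate-grid visualization,
plus a seeded generator of synthetic plates so every step is testable
without an instrument.

## Parsing and the canonical dialect

Instrument exports differ across firmware versions, so the parser
detects a *dialect* from the header by case-insensitive synonym
matching (`Column`/`Col`, `EXT`/`Extinction`, `Status sort`/`Sort
status`, ...); users can extend the table with
`registerDialectSynonyms()`. TOF, EXT, Row and Column are required;
everything else is optional and recorded as missing when absent. Files
written by `writePlate()` use one fixed canonical header so that
write→parse is the identity on all canonical fields (integers exactly,
floats at full double precision). Malformed lines — truncated tails are
common in instrument files — are dropped and counted in a per-file
parse report rather than aborting the read. Numeric fields use a
decimal point only; well labels accept zero padding and lower case on
input and are always rendered unpadded upper case. One file is one
plate: a `Plate` column is accepted but must be constant.

## Filtering: cutoffs and the bubble classifier

Hard cutoffs keep records with `tofMin <= TOF <= tofMax` and
`extMin <= EXT <= extMax`. Both ends are inclusive because
user-specified limits naturally read as "allow this value". Cutoff
filtering is idempotent and order-independent relative to classifier
*annotation* (annotation commutes with subsetting; the command-line
tool applies cutoffs first).

The probabilistic bubble filter is a two-class support vector machine
with an RBF kernel and Platt-scaled probabilities. It is trained per
device from the two-plate protocol: a plate of organisms with the
bubble trap engaged (label 0) and an organism-free plate with the trap
disengaged (label 1). Features default to TOF, EXT, the three
fluorescence channels and the EXT/TOF ratio — bubbles separate mainly
on optical density per unit length — and are standardized with
training-set center and spread, which prediction re-applies verbatim.
Held-out accuracy is estimated on a stratified 80/20 split with a
user-settable seed stored in the classifier metadata, and the deployed
model is refitted on the full training set. Flagging uses a strict
inequality (`probability > threshold`, default 0.5), so a threshold of
1 never flags. No pretrained model ships with the package: internal
instrument parameters vary by device, so the classifier must be trained
on each machine.

## Normalization and summarization

Because the instrument integrates optical signals over the transit,
larger objects always show larger EXT and fluorescence. `normalizePlate()`
divides each of these channels by TOF per object (`norm_ext = ext/tof`,
...), so `norm_x * tof` reproduces `x` exactly wherever `TOF > 0`;
records with `TOF = 0` get missing normalized values and are counted in
the parse report.

`summarizePlate()` reduces a plate to one row per well: the population
size `n` plus, per trait, mean, median, unbiased variance (n−1
denominator, missing when `n < 2`), minimum, maximum and quantiles.
Quantiles use linear interpolation between closest order statistics
(the common "type 7" convention) — a deliberate, documented fix, since
several conventions exist and the oracle tests pin this one. The
default quantile set {10, 25, 75, 90} is configurable rather than
asserted as canonical. Log-transformed statistics use the natural log
of strictly positive values only; non-positive values are excluded
rather than shifted by a pseudo-count (which would silently distort EXT
distributions) and the per-well exclusion counts are kept in
`nlogexcl_*` columns.

Wells can be removed either by blanking their statistics (`mode =
"na"`) or by dropping their rows; `fillWells()` completes a summary to
exactly 96 row-major entries, adding missing wells with `NA` for every
population statistic so downstream plate-shaped operations stay
consistent. Strain and dose metadata attach positionally as 96-element
vectors in row-major order A1…H12 (a `well,label` CSV is also accepted
by the command-line tool). Exports write missing values as empty fields
and accept the literal `NA` on read for compatibility with R-centric
tools.

## Statistics

**Rank-sum test.** `wilcoxonRankSum()` reports W, the rank-sum of the
first sample under midranks. For tie-free samples with
`n1 + n2 <= 20` the two-sided p is exact: all `choose(N, n1)` rank
assignments are equally likely under the null, and
`p = min(1, 2 min(P(W <= w), P(W >= w)))`; the implementation indexes
the exact null distribution through the U statistic while the test
suite checks it against full combinatorial enumeration. Ties, or larger
samples, switch to the normal approximation with tie-corrected variance
and a 0.5 continuity correction; when tie correction collapses the null
variance to zero (all values identical) the p-value is 1. The
20-observation switch bounds enumeration cost while keeping the exact
branch for all plate-scale small-sample uses.

**Edge effects.** Evaporation and oxygenation gradients hit the
outermost wells hardest, so the plate is split into the outer ring (36
wells) and the 60-well center; `edgeDepth = 2` widens the edge to two
rings (64 wells) for gradients that penetrate inward. The test compares
a *per-well summary statistic* (default the well mean) between the two
populations — wells are the exchangeable units; pooling raw objects
would pseudo-replicate. Whether to test per-well summaries or raw
pooled objects was a genuinely open choice; the per-well form is the
defensible one and is what the calibration below validates. When all
traits are tested, raw p-values are reported by default (an optional
Benjamini–Hochberg flag exists) and traits with insufficient data are
marked untestable instead of failing the batch.

**Correlations.** `correlationMatrix()` computes Pearson (optionally
Spearman) correlations between summarized trait columns over wells,
pairwise-complete, with entries backed by fewer than 3 complete pairs
reported as missing. Within one plate the matrix is symmetric with unit
diagonal; between plates, trait columns are paired across wells matched
by label.

**Dose response.** With 96-element strain and dose vectors, each well
contributes one point (its per-well statistic) to its (strain, dose)
group; the group mean is the arithmetic mean of per-well values and a
group whose wells are all missing stays present with zero wells and a
missing mean. The package summarizes and plots means by dose only — no
EC50/4PL curve fitting. In dose-response figures the plotted points are
per-well values, the finer of the two readings of "one observation".

## The synthetic-plate generator

`generatePlate()` draws per-well population sizes from a Poisson
distribution (default mean 30 objects/well), organism TOF from a
lognormal (median 300 instrument units, log-SD 0.15), EXT proportional
to TOF with multiplicative lognormal noise (ratio 0.5, log-SD 0.1), and
fluorescence from gamma distributions — choices that make the TOF/EXT
scatter a monotone cloud like real organism plates. Bubbles are small,
optically thin objects (TOF ~ N(40, 10), EXT ~ N(5, 2)) interleaved at
a configurable contamination fraction. Between-well variability is an
additive shift on the well-level TOF location parameter
(SD `wellSd = 0.05` on the log scale), and the edge gradient adds
`edgeEffect * wellSd` to edge wells — parameterizing effects in SD
units of the well-mean distribution makes power experiments calibrated.
The seed fixes the full output byte stream, ground-truth bubble labels
and well parameters are returned for oracles, and
`generateTrainingPair()` emulates the two-plate SVM protocol with
seeds derived from the scenario seed.

What the generator does *not* emulate: instrument electronics, transit
peak profiles, sorting hydraulics, correlated within-well clumping, or
drift over a run. Passing tests therefore demonstrate correctness of
the computations on data with the stated statistical structure, not
robustness to every artifact a physical device can produce.

## Calibration of the edge-effect test

Two simulation experiments back the test's operating characteristics,
run both in the test suite and by `scripts/acceptance.R`: on 1000 null
plates (no gradient, 96 wells, ~10 objects/well, one trait) the
fraction of p < 0.05 must fall inside the exact binomial 99% interval
around 0.05; with a +5 SD edge gradient, p < 0.01 on at least 99% of
200 plates. The plate counts and per-well populations are the package's
chosen experiment sizes: large enough for the binomial interval around
a 5% rate to be narrow, small enough to run routinely.

## Numerical and degenerate-input choices

Missing values are skipped (never imputed) in all statistics; wells
with `n = 0` simply do not appear until `fillWells()` adds them as
all-missing rows. Variance needs two values; correlations need three
complete pairs; an empty sample is an error for the rank-sum test but a
reported "untestable" row in all-trait batches. Written floats carry 17
significant digits so round trips are lossless. Rendering is a thin,
smoke-tested layer (PNG/SVG/PDF via one code path) over pure,
fully-tested `prep*()` transformations; histogram panels share one
bin range across the plate (default 30 bins) so wells are comparable,
and box whiskers sit at 1.5 × IQR with outliers listed explicitly.

## Known limitations

One file is one plate; there is no plate stitching, no FCS-standard
flow cytometry support, and no instrument control. The bubble
classifier's reported accuracy concerns the training distributions;
real plates whose debris resembles organisms will do worse. The
edge-effect test detects a location difference between two fixed well
populations and is not a spatial autocorrelation model.
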
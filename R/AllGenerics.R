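#' @include AllClasses.R
NULL

#' Accessors for plate objects
#'
#' `observations()` returns the per-object data.frame of a [RawPlate];
#' `wellData()` the per-well data.frame of a [SummarizedPlate];
#' `wells()` the canonical well label of each record/row; `plateSource()`
#' and `plateDialect()` the provenance metadata; `parseReport()` what
#' parsing/normalization skipped; `plateTraits()` the traits carried.
#'
#' @param x A `RawPlate` or `SummarizedPlate`.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))

#' @rdname accessors
#' @export
setGeneric("wellData", function(x) standardGeneric("wellData"))

#' @rdname accessors
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))

#' @rdname accessors
#' @export
setGeneric("plateSource", function(x) standardGeneric("plateSource"))

#' @rdname accessors
#' @export
setGeneric("plateDialect", function(x) standardGeneric("plateDialect"))

#' @rdname accessors
#' @export
setGeneric("parseReport", function(x) standardGeneric("parseReport"))

#' @rdname accessors
#' @export
setGeneric("plateTraits", function(x) standardGeneric("plateTraits"))

#' Remove wells from raw or summarized plate data
#'
#' @param x A `RawPlate` or `SummarizedPlate`.
#' @param wellLabels Character vector of wells to remove (any accepted
#'   label form).
#' @param mode `"na"` blanks every trait field of the named wells but
#'   keeps their entries (a summary's `n` becomes missing); `"drop"`
#'   deletes the entries. Wells absent from the data are a warning, not
#'   an error.
#' @return An object of the same class as `x`.
#' @export
setGeneric("removeWells",
           function(x, wellLabels, mode = c("na", "drop"))
             standardGeneric("removeWells"))

#' Render a prepared figure to an image file
#'
#' A thin rendering layer over fully tested data preparation: plate-grid
#' layouts draw their 96 panels in plate geometry, correlation matrices
#' use a diverging red/green/blue scale (positive/zero/negative), and
#' dose-response tables draw per-well points with per-(strain, dose) mean
#' lines against dose. The output format follows the file extension
#' (`.png`, `.svg`, `.pdf`).
#'
#' @param x A [PlateGridLayout], [CorrelationMatrix] or
#'   [DoseResponseTable].
#' @param file Output path ending in `.png`, `.svg` or `.pdf`.
#' @param width,height Device size in inches.
#' @param ... Passed on to the underlying plot builder.
#' @return Invisibly, the output path.
#' @export
setGeneric("renderFigure",
           function(x, file, width = 10, height = 7, ...)
             standardGeneric("renderFigure"))
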
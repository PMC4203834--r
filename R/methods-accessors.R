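#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("observations", "RawPlate", function(x) x@observations)

#' @rdname accessors
#' @export
setMethod("wellData", "SummarizedPlate", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("wells", "RawPlate",
          function(x) paste0(x@observations$row, x@observations$col))

#' @rdname accessors
#' @export
setMethod("wells", "SummarizedPlate", function(x) x@data$well)

#' @rdname accessors
#' @export
setMethod("plateSource", "RawPlate", function(x) x@source)

#' @rdname accessors
#' @export
setMethod("plateSource", "SummarizedPlate", function(x) x@source)

#' @rdname accessors
#' @export
setMethod("plateDialect", "RawPlate", function(x) x@dialect)

#' @rdname accessors
#' @export
setMethod("parseReport", "RawPlate", function(x) x@parseReport)

#' @rdname accessors
#' @export
setMethod("plateTraits", "RawPlate", function(x) {
  obs <- x@observations
  present <- vapply(c(TRAIT_COLS, NORM_COLS), function(tr)
    any(!is.na(obs[[tr]])), logical(1))
  c(TRAIT_COLS, NORM_COLS)[present]
})

#' @rdname accessors
#' @export
setMethod("plateTraits", "SummarizedPlate", function(x) x@traits)

setMethod("show", "RawPlate", function(object) {
  obs <- object@observations
  cat("RawPlate:", nrow(obs), "objects in",
      length(unique(paste0(obs$row, obs$col))), "wells\n")
  cat("  source:", object@source, " dialect:", object@dialect, "\n")
  if (length(object@parseReport))
    cat("  parse report: ", object@parseReport$dataLines, " data lines, ",
        object@parseReport$dropped, " dropped\n", sep = "")
  cat("  traits:", paste(plateTraits(object), collapse = ", "), "\n")
})

setMethod("show", "SummarizedPlate", function(object) {
  cat("SummarizedPlate:", nrow(object@data), "wells, traits:",
      paste(object@traits, collapse = ", "), "\n")
  cat("  source:", object@source, "\n")
})

setMethod("show", "BubbleClassifier", function(object) {
  cat("BubbleClassifier (SVM)\n  features:",
      paste(object@features, collapse = ", "), "\n  threshold:",
      object@threshold, "\n")
  ti <- object@trainingInfo
  if (!is.null(ti$heldOutAccuracy))
    cat("  held-out accuracy:", round(ti$heldOutAccuracy, 4),
        sprintf("(%d objects, %d bubbles, seed %d)\n",
                ti$nObjects, ti$nBubbles, ti$seed))
})

setMethod("show", "RankSumResult", function(object) {
  cat(sprintf(
    "Wilcoxon rank-sum: W = %g (n1 = %d, n2 = %d), two-sided p = %.4g [%s%s]\n",
    object@wStatistic, object@n1, object@n2, object@pValue, object@method,
    if (object@tieCorrected) ", tie-corrected" else ""))
})

setMethod("show", "EdgeEffectReport", function(object) {
  cat("Edge-effect report (", length(object@edgeWells), " edge vs ",
      length(object@centerWells), " center wells, per-well ",
      object@statistic, ")\n", sep = "")
  print(object@results, row.names = FALSE)
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(object@mode, "-plate ", object@method, " correlation matrix, ",
      nrow(object@coefficients), " x ", ncol(object@coefficients),
      " traits\n", sep = "")
})

setMethod("show", "DoseResponseTable", function(object) {
  cat("Dose-response table for", object@statistic, "of", object@trait,
      ":", nrow(object@groups), "(strain, dose) groups,",
      nrow(object@points), "well points\n")
})

setMethod("show", "PlateGridLayout", function(object) {
  cat("PlateGridLayout (", object@kind, "): ", length(object@panels),
      " wells with data\n", sep = "")
})

setMethod("show", "PlateScenario", function(object) {
  cat("PlateScenario: lambda =", object@nPerWellLambda,
      ", bubble fraction =", object@bubbleFraction,
      ", wellSd =", object@wellSd,
      ", edge effect =", object@edgeEffect, "SD\n")
  cat("  empty wells:", length(object@emptyWells),
      " seed:", object@seed, "\n")
})
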
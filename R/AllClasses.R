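#' @import methods
NULL

TRAIT_COLS <- c("tof", "ext", "green", "yellow", "red")
NORM_COLS  <- c("norm_ext", "norm_green", "norm_yellow", "norm_red")
OBS_COLS   <- c("id", "row", "col", "status", TRAIT_COLS, NORM_COLS,
                "bubble_prob")

.emptyObservations <- function() {
  data.frame(id = integer(0), row = character(0), col = integer(0),
             status = integer(0), tof = numeric(0), ext = numeric(0),
             green = numeric(0), yellow = numeric(0), red = numeric(0),
             norm_ext = numeric(0), norm_green = numeric(0),
             norm_yellow = numeric(0), norm_red = numeric(0),
             bubble_prob = numeric(0), stringsAsFactors = FALSE)
}

#' RawPlate: per-object records from one plate
#'
#' One instrument record per detected object, carrying the well
#' coordinate, the instrument's sort-status code, time of flight (TOF, a
#' proxy for object length), integrated extinction (EXT, optical density)
#' and three integrated fluorescence channels (green, yellow, red).
#' Per-length normalized channels (`norm_*`) are `NA` until
#' [normalizePlate()] has run; `bubble_prob` is `NA` until
#' [classifyBubbles()] has run in annotate mode.
#'
#' @slot observations data.frame with one row per object and columns
#'   `id`, `row`, `col`, `status`, `tof`, `ext`, `green`, `yellow`,
#'   `red`, `norm_ext`, `norm_green`, `norm_yellow`, `norm_red`,
#'   `bubble_prob`.
#' @slot source Character label or file path of origin.
#' @slot dialect Name of the header dialect the source was parsed with.
#' @slot parseReport List with elements `dataLines`, `dropped`,
#'   `zeroTof` describing what parsing and normalization skipped.
#' @export
setClass("RawPlate",
  representation(observations = "data.frame", source = "character",
                 dialect = "character", parseReport = "list"),
  prototype(observations = .emptyObservations(), source = NA_character_,
            dialect = "canonical", parseReport = list()))

setValidity("RawPlate", function(object) {
  obs <- object@observations
  msgs <- character(0)
  missing_cols <- setdiff(OBS_COLS, names(obs))
  if (length(missing_cols)) {
    return(paste("observations lack columns:",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(obs)) {
    if (!all(obs$row %in% PLATE_ROWS) || !all(obs$col %in% PLATE_COLS))
      msgs <- c(msgs, "invalid well coordinates")
    if (anyDuplicated(obs$id))
      msgs <- c(msgs, "object ids are not unique within the plate")
    for (tr in c(TRAIT_COLS, NORM_COLS)) {
      v <- obs[[tr]]
      if (any(!is.na(v) & (!is.finite(v) | v < 0)))
        msgs <- c(msgs, paste0(tr, " has negative or non-finite values"))
    }
    bp <- obs$bubble_prob
    if (any(!is.na(bp) & (bp < 0 | bp > 1)))
      msgs <- c(msgs, "bubble_prob outside [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' SummarizedPlate: per-well summary statistics
#'
#' At most one row per well. `n` is the well's population size (object
#' count); per-trait columns follow the `<stat>_<trait>` convention
#' (`mean_tof`, `q25_ext`, ...). After [fillWells()] there are exactly 96
#' rows in row-major well order.
#'
#' @slot data data.frame with columns `well`, `strain`, `dose`, `n` and
#'   one column per (statistic, trait) pair.
#' @slot traits Character vector of the traits summarized.
#' @slot source Character label of the plate the summary came from.
#' @export
setClass("SummarizedPlate",
  representation(data = "data.frame", traits = "character",
                 source = "character"),
  prototype(data = data.frame(), traits = character(0),
            source = NA_character_))

setValidity("SummarizedPlate", function(object) {
  d <- object@data
  msgs <- character(0)
  for (col in c("well", "strain", "dose", "n"))
    if (!col %in% names(d)) msgs <- c(msgs, paste("missing column", col))
  if (!length(msgs) && nrow(d)) {
    ok <- grepl("^[A-H](1[0-2]|[1-9])$", d$well)
    if (!all(ok)) msgs <- c(msgs, "invalid well labels")
    if (anyDuplicated(d$well)) msgs <- c(msgs, "duplicate well entries")
    if (any(!is.na(d$n) & d$n < 0)) msgs <- c(msgs, "negative population size")
  }
  if (length(msgs)) msgs else TRUE
})

#' BubbleClassifier: trained object-vs-bubble model
#'
#' A two-class probabilistic classifier (support vector machine with
#' Platt-scaled probabilities) that scores how likely a record is an air
#' bubble rather than an organism. Feature standardization parameters
#' learned at training time are stored so that prediction applies the
#' identical scaling.
#'
#' @slot features Character vector of feature names; `"ext_tof_ratio"`
#'   denotes EXT/TOF.
#' @slot center,scale Named numeric vectors of per-feature centering and
#'   scaling constants.
#' @slot model The fitted [e1071::svm] object.
#' @slot threshold Probability above which (strictly) a record is flagged.
#' @slot trainingInfo List with `heldOutAccuracy`, `seed`, `nObjects`,
#'   `nBubbles`.
#' @export
setClass("BubbleClassifier",
  representation(features = "character", center = "numeric",
                 scale = "numeric", model = "ANY", threshold = "numeric",
                 trainingInfo = "list"))

setValidity("BubbleClassifier", function(object) {
  if (length(object@threshold) != 1L || is.na(object@threshold) ||
      object@threshold < 0 || object@threshold > 1)
    return("threshold must be a single probability in [0, 1]")
  TRUE
})

#' RankSumResult: a two-sided Wilcoxon rank-sum test result
#'
#' @slot wStatistic Rank-sum of the first sample (midranks under ties).
#' @slot n1,n2 Sample sizes after dropping missing values.
#' @slot pValue Two-sided p-value.
#' @slot method `"exact"` or `"normal-approximation"`.
#' @slot tieCorrected Logical: was the tie-corrected variance used.
#' @export
setClass("RankSumResult",
  representation(wStatistic = "numeric", n1 = "integer", n2 = "integer",
                 pValue = "numeric", method = "character",
                 tieCorrected = "logical"))

#' EdgeEffectReport: edge-vs-center rank-sum tests per trait
#'
#' @slot results data.frame with one row per tested column: `trait`,
#'   `column`, `n_edge`, `n_center`, `w`, `p`, `p_adjusted`, `method`,
#'   `testable`.
#' @slot edgeWells,centerWells The two disjoint well populations.
#' @slot statistic Which per-well statistic was compared.
#' @export
setClass("EdgeEffectReport",
  representation(results = "data.frame", edgeWells = "character",
                 centerWells = "character", statistic = "character"))

#' CorrelationMatrix: pairwise-complete trait correlations over wells
#'
#' @slot coefficients Numeric matrix of correlations (`NA` where fewer
#'   than 3 complete pairs exist).
#' @slot pairCounts Integer matrix of complete-pair counts.
#' @slot mode `"within"` or `"between"`.
#' @slot method `"pearson"` or `"spearman"`.
#' @export
setClass("CorrelationMatrix",
  representation(coefficients = "matrix", pairCounts = "matrix",
                 mode = "character", method = "character"))

#' DoseResponseTable: per-well values grouped by (strain, dose)
#'
#' @slot trait Trait summarized.
#' @slot statistic Per-well statistic used (e.g. `"mean"`).
#' @slot points data.frame of per-well values: `well`, `strain`, `dose`,
#'   `value` (wells with missing values are excluded).
#' @slot groups data.frame per (strain, dose): `strain`, `dose`, `mean`,
#'   `n_wells` (groups whose wells are all missing keep `n_wells = 0`
#'   and a missing mean).
#' @export
setClass("DoseResponseTable",
  representation(trait = "character", statistic = "character",
                 points = "data.frame", groups = "data.frame"))

#' PlateGridLayout: prepared per-well panel payloads for an 8 x 12 figure
#'
#' @slot kind One of `"scatter"`, `"histogram"`, `"heatmap"`,
#'   `"compare_box"`, `"compare_bar"`.
#' @slot panels Named list keyed by canonical well label; absent wells
#'   render as empty panels.
#' @slot meta List of layout-level metadata (trait names, shared bin
#'   edges, column name, ...).
#' @export
setClass("PlateGridLayout",
  representation(kind = "character", panels = "list", meta = "list"))

setValidity("PlateGridLayout", function(object) {
  if (!object@kind %in% c("scatter", "histogram", "heatmap",
                          "compare_box", "compare_bar"))
    return("unknown layout kind")
  if (length(object@panels) &&
      !all(names(object@panels) %in% allWells()))
    return("panel keys must be canonical well labels")
  TRUE
})

#' PlateScenario: parameters of a synthetic plate
#'
#' Describes the statistical structure of a simulated plate: per-well
#' population sizes, organism and bubble trait distributions, bubble
#' contamination fraction, between-well variability, an optional
#' edge-gradient effect, deliberately empty wells, and the seed that
#' fixes the full output.
#'
#' @slot nPerWellLambda Poisson mean of per-well population size.
#' @slot organism,bubble Named lists of trait distribution specs (see
#'   [plateScenario()]).
#' @slot bubbleFraction Fraction of records that are bubbles, in [0, 1].
#' @slot wellSd SD of the between-well shift applied to the organism TOF
#'   location parameter (the well-mean distribution).
#' @slot edgeEffect Additive shift, in units of `wellSd`, applied to edge
#'   wells' location parameter.
#' @slot emptyWells Wells that produce no records.
#' @slot seed Integer seed fixing the generated plate byte-for-byte.
#' @export
setClass("PlateScenario",
  representation(nPerWellLambda = "numeric", organism = "list",
                 bubble = "list", bubbleFraction = "numeric",
                 wellSd = "numeric", edgeEffect = "numeric",
                 emptyWells = "character", seed = "integer"))

setValidity("PlateScenario", function(object) {
  msgs <- character(0)
  if (object@nPerWellLambda < 0) msgs <- c(msgs, "negative population size")
  if (object@bubbleFraction < 0 || object@bubbleFraction > 1)
    msgs <- c(msgs, "bubbleFraction must lie in [0, 1]")
  if (object@wellSd < 0) msgs <- c(msgs, "negative wellSd")
  if (length(object@emptyWells) &&
      !all(object@emptyWells %in% allWells()))
    msgs <- c(msgs, "emptyWells contains invalid well labels")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
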
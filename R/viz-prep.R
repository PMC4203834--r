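#' @include AllClasses.R
NULL

.checkTrait <- function(plate, trait) {
  if (!trait %in% c(TRAIT_COLS, NORM_COLS))
    stop("unknown trait: ", trait, call. = FALSE)
  invisible(trait)
}

#' Prepare well-wise scatter data
#'
#' Per-well (x, y) point sets for an 8 x 12 plate-grid scatter figure
#' (e.g. TOF against EXT). Observations missing either trait are
#' dropped pairwise.
#'
#' @param plate A [RawPlate].
#' @param xTrait,yTrait Trait names.
#' @return A [PlateGridLayout] of kind `"scatter"`.
#' @export
prepTraitScatter <- function(plate, xTrait, yTrait) {
  stopifnot(is(plate, "RawPlate"))
  .checkTrait(plate, xTrait); .checkTrait(plate, yTrait)
  obs <- plate@observations
  w <- paste0(obs$row, obs$col)
  ok <- !is.na(obs[[xTrait]]) & !is.na(obs[[yTrait]])
  panels <- lapply(split(data.frame(x = obs[[xTrait]][ok],
                                    y = obs[[yTrait]][ok]),
                         w[ok]), function(d) {
    rownames(d) <- NULL
    d
  })
  new("PlateGridLayout", kind = "scatter", panels = panels,
      meta = list(xTrait = xTrait, yTrait = yTrait))
}

#' Prepare well-wise histogram data
#'
#' Per-well bin counts over a bin range common to the whole plate, so
#' panels are directly comparable. Each panel's counts sum to that
#' well's non-missing value count.
#'
#' @param plate A [RawPlate].
#' @param trait Trait name.
#' @param bins Number of bins (default 30).
#' @return A [PlateGridLayout] of kind `"histogram"`; `meta$breaks`
#'   holds the shared bin edges.
#' @export
prepTraitHistogram <- function(plate, trait, bins = 30L) {
  stopifnot(is(plate, "RawPlate"))
  .checkTrait(plate, trait)
  obs <- plate@observations
  v <- obs[[trait]]
  w <- paste0(obs$row, obs$col)
  ok <- !is.na(v)
  rng <- if (any(ok)) range(v[ok]) else c(0, 1)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  panels <- lapply(split(v[ok], w[ok]), function(x)
    graphics::hist(x, breaks = breaks, plot = FALSE,
                   include.lowest = TRUE)$counts)
  new("PlateGridLayout", kind = "histogram", panels = panels,
      meta = list(trait = trait, breaks = breaks))
}

#' Prepare a plate heatmap
#'
#' One heat value per well, taken verbatim from a column of the
#' summarized data (e.g. population size `n`, or `mean_tof`). Missing
#' values render as a distinct "no data" state.
#'
#' @param summary A [SummarizedPlate].
#' @param column Summary column name.
#' @return A [PlateGridLayout] of kind `"heatmap"`.
#' @export
prepHeatmap <- function(summary, column) {
  stopifnot(is(summary, "SummarizedPlate"))
  d <- summary@data
  if (!column %in% names(d))
    stop("unknown column: ", column, call. = FALSE)
  panels <- as.list(as.numeric(d[[column]]))
  names(panels) <- d$well
  new("PlateGridLayout", kind = "heatmap", panels = panels,
      meta = list(column = column))
}

.boxStats <- function(v, quantileType = 7) {
  v <- v[!is.na(v)]
  if (!length(v))
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                lower = NA_real_, upper = NA_real_,
                outliers = numeric(0), n = 0L))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                       type = quantileType)
  iqr <- q[3] - q[1]
  inFence <- v >= q[1] - 1.5 * iqr & v <= q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       lower = min(v[inFence]), upper = max(v[inFence]),
       outliers = sort(v[!inFence]), n = length(v))
}

#' Prepare cross-plate comparison data
#'
#' Raw plates yield per-well paired box statistics (median, quartiles,
#' whiskers at 1.5 x IQR, outliers listed); summarized plates yield
#' per-well paired bar heights. Both inputs must be the same kind.
#'
#' @param a,b Two [RawPlate]s or two [SummarizedPlate]s.
#' @param trait For raw plates a trait name; for summarized plates a
#'   summary column name.
#' @return A [PlateGridLayout] of kind `"compare_box"` or
#'   `"compare_bar"`; each panel is a list with elements `a` and `b`.
#' @export
prepCompare <- function(a, b, trait) {
  if (is(a, "RawPlate") && is(b, "RawPlate")) {
    .checkTrait(a, trait)
    grab <- function(p) {
      obs <- p@observations
      split(obs[[trait]], paste0(obs$row, obs$col))
    }
    va <- grab(a); vb <- grab(b)
    wellsUsed <- sort(unique(c(names(va), names(vb))))
    panels <- lapply(wellsUsed, function(w)
      list(a = .boxStats(va[[w]]), b = .boxStats(vb[[w]])))
    names(panels) <- wellsUsed
    new("PlateGridLayout", kind = "compare_box", panels = panels,
        meta = list(trait = trait,
                    labels = c(a@source, b@source)))
  } else if (is(a, "SummarizedPlate") && is(b, "SummarizedPlate")) {
    grab <- function(p) {
      d <- p@data
      if (!trait %in% names(d))
        stop("unknown column: ", trait, call. = FALSE)
      stats::setNames(as.numeric(d[[trait]]), d$well)
    }
    va <- grab(a); vb <- grab(b)
    wellsUsed <- sort(unique(c(names(va), names(vb))))
    panels <- lapply(wellsUsed, function(w)
      list(a = unname(va[w]), b = unname(vb[w])))
    names(panels) <- wellsUsed
    new("PlateGridLayout", kind = "compare_bar", panels = panels,
        meta = list(column = trait,
                    labels = c(a@source, b@source)))
  } else {
    stop("type mismatch: both inputs must be RawPlate or both ",
         "SummarizedPlate", call. = FALSE)
  }
}
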
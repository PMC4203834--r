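#' @include AllClasses.R stats-ranksum.R
NULL

.summaryStatColumns <- function(d) {
  setdiff(names(d), c("well", "strain", "dose"))[
    vapply(d[setdiff(names(d), c("well", "strain", "dose"))],
           is.numeric, logical(1))]
}

#' Test for plate edge effects
#'
#' Long-running plate experiments can show systematic differences caused
#' by well position (evaporation, oxygenation): the outermost wells
#' experience the greatest evaporation. This splits the plate into edge
#' wells and center wells and compares a per-well summary statistic
#' between the two populations with the two-sided Wilcoxon rank-sum
#' test, for one trait or for all. Wells are the exchangeable units:
#' pooling raw objects would pseudo-replicate.
#'
#' @param summary A [SummarizedPlate].
#' @param trait A trait name, or `"all"` to test every summarized trait
#'   (and `n`).
#' @param statistic Which per-well statistic column to compare
#'   (`"mean"`, `"median"`, ...). The trait `"n"` uses the `n` column
#'   directly.
#' @param edgeDepth 1 for the outer ring (36 wells), 2 for two rings.
#' @param adjust `"none"` (default; raw p-values) or `"BH"` for
#'   Benjamini-Hochberg across the tested traits.
#' @return An [EdgeEffectReport]. When testing all traits, traits with
#'   insufficient data are reported as untestable rather than erroring
#'   the batch.
#' @export
edgeEffectTest <- function(summary, trait = "all", statistic = "mean",
                           edgeDepth = 1L, adjust = c("none", "BH")) {
  stopifnot(is(summary, "SummarizedPlate"))
  adjust <- match.arg(adjust)
  ring <- edgeWells(edgeDepth)
  d <- summary@data
  singleTrait <- !identical(trait, "all")
  traits <- if (singleTrait) trait else c("n", summary@traits)
  columns <- vapply(traits, function(tr) {
    if (tr == "n") "n" else paste0(statistic, "_", tr)
  }, character(1))
  if (singleTrait && !columns %in% names(d))
    stop("unknown trait or statistic column: ", columns, call. = FALSE)
  have <- columns %in% names(d)
  columns <- columns[have]
  traits <- traits[have]

  isEdge <- d$well %in% ring$edge
  rows <- lapply(seq_along(columns), function(i) {
    v <- d[[columns[i]]]
    e <- v[isEdge]; ctr <- v[!isEdge]
    e <- e[!is.na(e)]; ctr <- ctr[!is.na(ctr)]
    if (length(e) == 0L || length(ctr) == 0L) {
      if (singleTrait)
        stop("insufficient data: no non-missing wells in one population ",
             "for ", columns[i], call. = FALSE)
      return(data.frame(trait = traits[i], column = columns[i],
                        n_edge = length(e), n_center = length(ctr),
                        w = NA_real_, p = NA_real_,
                        method = NA_character_, testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    res <- wilcoxonRankSum(e, ctr)
    data.frame(trait = traits[i], column = columns[i],
               n_edge = res@n1, n_center = res@n2,
               w = res@wStatistic, p = res@pValue,
               method = res@method, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$p_adjusted <- if (adjust == "BH")
    stats::p.adjust(results$p, method = "BH") else results$p
  new("EdgeEffectReport", results = results,
      edgeWells = ring$edge, centerWells = ring$center,
      statistic = statistic)
}

.pairwiseCor <- function(ma, mb, method, minPairs = 3L) {
  r <- matrix(NA_real_, ncol(ma), ncol(mb),
              dimnames = list(colnames(ma), colnames(mb)))
  counts <- matrix(0L, ncol(ma), ncol(mb),
                   dimnames = dimnames(r))
  for (i in seq_len(ncol(ma))) {
    for (j in seq_len(ncol(mb))) {
      ok <- !is.na(ma[, i]) & !is.na(mb[, j])
      counts[i, j] <- sum(ok)
      if (counts[i, j] >= minPairs)
        r[i, j] <- suppressWarnings(
          stats::cor(ma[ok, i], mb[ok, j], method = method))
    }
  }
  list(r = r, counts = counts)
}

#' Correlation matrix of traits over wells
#'
#' Pearson (or Spearman) correlation between summarized trait columns,
#' computed over wells with pairwise-complete values. Within one plate
#' the matrix is symmetric with unit diagonal; between two plates, each
#' trait column of `a` is paired with each trait column of `b` over
#' wells matched by label. Entries with fewer than 3 complete pairs are
#' missing.
#'
#' @param a A [SummarizedPlate].
#' @param b Optional second [SummarizedPlate] for between-plate mode.
#' @param traits Optional subset of summary columns to correlate;
#'   defaults to every numeric statistic column (including `n`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [CorrelationMatrix].
#' @export
correlationMatrix <- function(a, b = NULL, traits = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(a, "SummarizedPlate"))
  da <- a@data
  cols <- if (is.null(traits)) .summaryStatColumns(da) else traits
  missingCols <- setdiff(cols, names(da))
  if (length(missingCols))
    stop("unknown summary column(s): ",
         paste(missingCols, collapse = ", "), call. = FALSE)
  ma <- as.matrix(da[cols])
  rownames(ma) <- da$well
  if (is.null(b)) {
    pc <- .pairwiseCor(ma, ma, method)
    # a trait against itself is identically correlated
    diag(pc$r)[diag(pc$counts) >= 3L] <- 1
    mode <- "within"
  } else {
    stopifnot(is(b, "SummarizedPlate"))
    db <- b@data
    missingCols <- setdiff(cols, names(db))
    if (length(missingCols))
      stop("unknown summary column(s) in second plate: ",
           paste(missingCols, collapse = ", "), call. = FALSE)
    shared <- intersect(da$well, db$well)
    ma <- ma[match(shared, da$well), , drop = FALSE]
    mb <- as.matrix(db[cols])[match(shared, db$well), , drop = FALSE]
    la <- if (!is.na(a@source)) basename(a@source) else "plateA"
    lb <- if (!is.na(b@source)) basename(b@source) else "plateB"
    colnames(ma) <- paste0(cols, ".", la)
    colnames(mb) <- paste0(cols, ".", lb)
    pc <- .pairwiseCor(ma, mb, method)
    mode <- "between"
  }
  if (all(is.na(pc$r)))
    stop("insufficient data: no trait pair with >= 3 complete pairs",
         call. = FALSE)
  new("CorrelationMatrix", coefficients = pc$r, pairCounts = pc$counts,
      mode = mode, method = method)
}

#' Dose-response table by strain
#'
#' Attaches strain and dose labels (96-element vectors in row-major well
#' order) to a summarized plate, then groups wells by (strain, dose).
#' Each well contributes one point, its per-well statistic for the
#' chosen trait; wells with missing values are excluded from their
#' group, which keeps `n_wells = 0` and a missing mean if all its wells
#' are missing. The group mean is the arithmetic mean of the per-well
#' values.
#'
#' @param summary A [SummarizedPlate].
#' @param strains 96-element vector of strain labels, or `NULL` to use
#'   labels already attached at summarization.
#' @param doses 96-element numeric vector of doses, or `NULL` to use
#'   attached doses.
#' @param trait Trait name, or `"n"` for population size.
#' @param statistic Per-well statistic column prefix (default
#'   `"mean"`).
#' @return A [DoseResponseTable].
#' @export
doseResponseTable <- function(summary, strains = NULL, doses = NULL,
                              trait, statistic = "mean") {
  stopifnot(is(summary, "SummarizedPlate"))
  filled <- fillWells(summary)
  d <- filled@data
  if (!is.null(strains)) {
    if (length(strains) != 96L)
      stop("invalid metadata: strains must have exactly 96 entries",
           call. = FALSE)
    d$strain <- as.character(strains)[wellOrder(d$well)]
  }
  if (!is.null(doses)) {
    if (length(doses) != 96L)
      stop("invalid metadata: doses must have exactly 96 entries",
           call. = FALSE)
    d$dose <- as.numeric(doses)[wellOrder(d$well)]
  }
  column <- if (trait == "n") "n" else paste0(statistic, "_", trait)
  if (!column %in% names(d))
    stop("unknown trait or statistic column: ", column, call. = FALSE)
  value <- as.numeric(d[[column]])
  grouped <- !is.na(d$strain) & !is.na(d$dose)
  key <- paste(d$strain, d$dose, sep = "\r")
  groups <- unique(data.frame(strain = d$strain[grouped],
                              dose = d$dose[grouped],
                              key = key[grouped],
                              stringsAsFactors = FALSE))
  groups <- groups[order(groups$strain, groups$dose), , drop = FALSE]
  gm <- vapply(groups$key, function(k) {
    v <- value[grouped & key == k]
    v <- v[!is.na(v)]
    c(mean = if (length(v)) mean(v) else NA_real_, n = length(v))
  }, numeric(2))
  groups$mean <- gm["mean", ]
  groups$n_wells <- as.integer(gm["n", ])
  groups$key <- NULL
  rownames(groups) <- NULL
  pts <- data.frame(well = d$well, strain = d$strain, dose = d$dose,
                    value = value, stringsAsFactors = FALSE)
  pts <- pts[grouped & !is.na(pts$value), , drop = FALSE]
  rownames(pts) <- NULL
  new("DoseResponseTable", trait = trait, statistic = statistic,
      points = pts, groups = groups)
}

#' Dose-response tables for every trait
#'
#' Applies [doseResponseTable()] to each trait of the summary (plus
#' population size `n`); traits whose per-well values are entirely
#' missing are skipped with a message.
#'
#' @inheritParams doseResponseTable
#' @return Named list of [DoseResponseTable], one per testable trait.
#' @export
doseResponseAllTraits <- function(summary, strains = NULL, doses = NULL,
                                  statistic = "mean") {
  stopifnot(is(summary, "SummarizedPlate"))
  traits <- c("n", summary@traits)
  out <- list()
  for (tr in traits) {
    tab <- tryCatch(
      doseResponseTable(summary, strains, doses, trait = tr,
                        statistic = statistic),
      error = function(e) NULL)
    if (is.null(tab) || nrow(tab@points) == 0L) {
      message("doseResponseAllTraits: skipping trait ", tr,
              " (no usable values)")
      next
    }
    out[[tr]] <- tab
  }
  out
}
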
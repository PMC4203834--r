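#' @include AllClasses.R AllGenerics.R
NULL

#' Normalize optical channels by object length
#'
#' COPAS-type instruments output integrated extinction and fluorescence,
#' so larger objects always show larger values. To represent optical
#' density and fluorescence per unit length, each channel is divided by
#' the object's time of flight: `norm_ext = ext / tof`, and likewise for
#' the three fluorescence channels. Observations with `tof = 0` receive
#' missing normalized values and are counted in the parse report
#' (`zeroTof`); original fields are untouched.
#'
#' @param plate A [RawPlate].
#' @return The plate with `norm_*` columns filled.
#' @examples
#' p <- newRawPlate(well = "A1", tof = 50, ext = 100)
#' observations(normalizePlate(p))$norm_ext  # 2
#' @export
normalizePlate <- function(plate) {
  stopifnot(is(plate, "RawPlate"))
  obs <- plate@observations
  ok <- !is.na(obs$tof) & obs$tof > 0
  div <- function(x) ifelse(ok & !is.na(x), x / obs$tof, NA_real_)
  obs$norm_ext    <- div(obs$ext)
  obs$norm_green  <- div(obs$green)
  obs$norm_yellow <- div(obs$yellow)
  obs$norm_red    <- div(obs$red)
  plate@observations <- obs
  rep <- plate@parseReport
  rep$zeroTof <- sum(!is.na(obs$tof) & obs$tof == 0)
  plate@parseReport <- rep
  plate
}

.statNames <- function(quantiles) {
  c("mean", "median", "var", "min", "max", paste0("q", quantiles))
}

.traitStats <- function(v, quantiles) {
  v <- v[!is.na(v)]
  qn <- paste0("q", quantiles)
  if (length(v) == 0L) {
    out <- rep(NA_real_, 5L + length(quantiles))
  } else {
    out <- c(mean(v), stats::median(v),
             if (length(v) < 2L) NA_real_ else stats::var(v),
             min(v), max(v),
             stats::quantile(v, quantiles / 100, names = FALSE, type = 7))
  }
  names(out) <- c("mean", "median", "var", "min", "max", qn)
  out
}

#' Summarize a plate by well
#'
#' Computes, for every well with at least one observation, the population
#' size `n` and per-trait summary statistics: mean, median, unbiased
#' variance (missing when `n < 2`), minimum, maximum and the requested
#' quantiles (linear interpolation between order statistics, the "type
#' 7" convention). Missing trait values are skipped. With
#' `withLog = TRUE` the same statistics are added for the natural log of
#' each trait, computed over strictly positive values only; the per-well
#' count of excluded non-positive values is retained in
#' `nlogexcl_<trait>` columns.
#'
#' @param plate A [RawPlate] (normalization first is recommended so the
#'   `norm_*` traits are summarized too).
#' @param strains Optional 96-element vector of strain labels in
#'   row-major well order A1...H12, or `NULL`.
#' @param doses Optional 96-element numeric vector of doses in the same
#'   order, or `NULL`.
#' @param withLog Also summarize log-transformed traits?
#' @param quantiles Integer percentages, default `c(10, 25, 75, 90)`.
#' @param traits Traits to summarize; defaults to every trait with data.
#' @return A [SummarizedPlate].
#' @export
summarizePlate <- function(plate, strains = NULL, doses = NULL,
                           withLog = FALSE,
                           quantiles = c(10, 25, 75, 90),
                           traits = NULL) {
  stopifnot(is(plate, "RawPlate"))
  if (!is.null(strains) && length(strains) != 96L)
    stop("invalid metadata: strains must have exactly 96 entries",
         call. = FALSE)
  if (!is.null(doses) && length(doses) != 96L)
    stop("invalid metadata: doses must have exactly 96 entries",
         call. = FALSE)
  obs <- plate@observations
  if (is.null(traits)) traits <- plateTraits(plate)
  wl <- paste0(obs$row, obs$col)
  present <- allWells()[allWells() %in% wl]
  f <- factor(wl, levels = present)
  d <- data.frame(well = present,
                  strain = NA_character_, dose = NA_real_,
                  n = as.integer(tabulate(f, nbins = length(present))),
                  stringsAsFactors = FALSE)
  if (!is.null(strains)) d$strain <- strains[wellOrder(d$well)]
  if (!is.null(doses)) d$dose <- as.numeric(doses)[wellOrder(d$well)]

  sn <- .statNames(quantiles)
  for (tr in traits) {
    bywell <- split(obs[[tr]], f)
    m <- vapply(bywell, .traitStats, numeric(length(sn)),
                quantiles = quantiles)
    for (i in seq_along(sn)) d[[paste0(sn[i], "_", tr)]] <- m[i, ]
    if (withLog) {
      lw <- lapply(bywell, function(v) v[!is.na(v)])
      excl <- vapply(lw, function(v) sum(v <= 0), integer(1))
      lm <- vapply(lw, function(v) .traitStats(log(v[v > 0]), quantiles),
                   numeric(length(sn)))
      for (i in seq_along(sn))
        d[[paste0("log_", sn[i], "_", tr)]] <- lm[i, ]
      d[[paste0("nlogexcl_", tr)]] <- excl
    }
  }
  rownames(d) <- NULL
  new("SummarizedPlate", data = d, traits = traits,
      source = plate@source)
}

.blankTraitCols <- function(d, idx) {
  keep <- c("well", "strain", "dose")
  for (col in setdiff(names(d), keep)) d[[col]][idx] <- NA
  d
}

#' @rdname removeWells
#' @export
setMethod("removeWells", "RawPlate",
  function(x, wellLabels, mode = c("na", "drop")) {
    mode <- match.arg(mode)
    wl <- wellFromString(wellLabels)
    obs <- x@observations
    hit <- paste0(obs$row, obs$col) %in% wl
    absent <- setdiff(wl, paste0(obs$row, obs$col))
    if (length(absent))
      warning("well(s) not present in plate: ",
              paste(absent, collapse = ", "), call. = FALSE)
    if (mode == "drop") {
      obs <- obs[!hit, , drop = FALSE]
      rownames(obs) <- NULL
    } else {
      for (col in c(TRAIT_COLS, NORM_COLS, "bubble_prob"))
        obs[[col]][hit] <- NA_real_
    }
    x@observations <- obs
    x
  })

#' @rdname removeWells
#' @export
setMethod("removeWells", "SummarizedPlate",
  function(x, wellLabels, mode = c("na", "drop")) {
    mode <- match.arg(mode)
    wl <- wellFromString(wellLabels)
    d <- x@data
    hit <- d$well %in% wl
    absent <- setdiff(wl, d$well)
    if (length(absent))
      warning("well(s) not present in summary: ",
              paste(absent, collapse = ", "), call. = FALSE)
    if (mode == "drop") {
      d <- d[!hit, , drop = FALSE]
      rownames(d) <- NULL
    } else {
      d <- .blankTraitCols(d, hit)
    }
    x@data <- d
    x
  })

#' Fill missing wells of a summarized plate
#'
#' Instruments may record nothing for unused wells. This detects wells
#' absent from the summary and adds them with missing values for every
#' population statistic (including `n`), returning exactly 96 entries in
#' row-major order; existing entries are unchanged. Idempotent.
#'
#' @param summary A [SummarizedPlate] with at most 96 entries.
#' @return A [SummarizedPlate] with exactly 96 entries.
#' @export
fillWells <- function(summary) {
  stopifnot(is(summary, "SummarizedPlate"))
  d <- summary@data
  if (anyDuplicated(d$well))
    stop("corrupt summary: duplicate well entries", call. = FALSE)
  missing <- setdiff(allWells(), d$well)
  if (length(missing)) {
    add <- d[rep(NA_integer_, length(missing)), , drop = FALSE]
    add$well <- missing
    d <- rbind(d, add)
  }
  d <- d[order(wellOrder(d$well)), , drop = FALSE]
  rownames(d) <- NULL
  summary@data <- d
  summary
}

#' Export / import a summarized plate as delimited text
#'
#' One row per well with columns `well, strain, dose, n,
#' <stat>_<trait>, ...`. Missing values are written as empty fields;
#' `"NA"` is also accepted on read.
#'
#' @param summary A [SummarizedPlate].
#' @param file Destination (`.tsv`/`.txt` for tab-delimited, `.csv` for
#'   comma-separated; `sep` overrides).
#' @param sep Field separator; inferred from the extension by default.
#' @return `readSummary()` returns a [SummarizedPlate].
#' @export
writeSummary <- function(summary, file, sep = NULL) {
  stopifnot(is(summary, "SummarizedPlate"))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  utils::write.table(summary@data, file, sep = sep, na = "",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSummary
#' @export
readSummary <- function(file, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", file, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(file, sep = sep, header = TRUE,
                         na.strings = c("", "NA"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!"strain" %in% names(d)) d$strain <- NA_character_
  if (!"dose" %in% names(d)) d$dose <- NA_real_
  d$strain <- as.character(d$strain)
  statCols <- setdiff(names(d), c("well", "strain", "dose", "n"))
  traits <- unique(sub("^(log_)?(mean|median|var|min|max|q[0-9]+|nlogexcl)_",
                       "", statCols))
  new("SummarizedPlate", data = d, traits = traits,
      source = as.character(file))
}
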
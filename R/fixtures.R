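#' @include AllClasses.R io.R
NULL

#' Trait distribution specifications
#'
#' A trait spec is a named list: `list(dist = "lognormal", meanlog =,
#' sdlog =)`, `list(dist = "normal", mean =, sd =)` (truncated at 0),
#' `list(dist = "gamma", shape =, scale =)`, `list(dist = "constant",
#' value =)` or, for EXT only, `list(dist = "proportional", ratio =,
#' noiseSd =)` meaning `ext = ratio * tof * exp(N(0, noiseSd))`.
#'
#' @name traitSpecs
NULL

.drawTrait <- function(spec, n, tof = NULL, shift = 0) {
  switch(spec$dist,
    lognormal = stats::rlnorm(n, spec$meanlog + shift, spec$sdlog),
    normal = pmax(0, stats::rnorm(n, spec$mean + shift, spec$sd)),
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    constant = rep(spec$value, n),
    proportional = spec$ratio * tof *
      exp(stats::rnorm(n, 0, spec$noiseSd)),
    stop("invalid scenario: unknown distribution ", spec$dist,
         call. = FALSE))
}

.checkTraitSpec <- function(spec, name) {
  if (!is.list(spec) || is.null(spec$dist))
    stop("invalid scenario: trait spec for ", name,
         " must be a list with a 'dist' element", call. = FALSE)
  needed <- switch(spec$dist,
    lognormal = c("meanlog", "sdlog"), normal = c("mean", "sd"),
    gamma = c("shape", "scale"), constant = "value",
    proportional = c("ratio", "noiseSd"),
    stop("invalid scenario: unknown distribution ", spec$dist,
         call. = FALSE))
  missing <- setdiff(needed, names(spec))
  if (length(missing))
    stop("invalid scenario: ", name, " spec lacks ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Describe a synthetic plate
#'
#' Defaults emulate a plate of nematode-scale organisms: TOF lognormal,
#' EXT proportional to TOF with multiplicative noise (a monotone
#' TOF-vs-EXT cloud), fluorescence gamma; bubbles are small, optically
#' thin objects. Between-well variability is an additive shift on the
#' well-level TOF location parameter, and the edge gradient adds a
#' further shift (in `wellSd` units) to edge wells, enabling calibrated
#' power experiments.
#'
#' @param nPerWellLambda Poisson mean population size per well.
#' @param organism,bubble Named lists of trait specs for
#'   `tof`, `ext`, `green`, `yellow`, `red` (see [traitSpecs]).
#' @param bubbleFraction Fraction of records that are bubbles.
#' @param wellSd SD of the between-well TOF-location shift.
#' @param edgeEffect Edge-well shift in units of `wellSd`.
#' @param emptyWells Wells that yield no records.
#' @param seed Integer seed; fixes the generated plate byte-for-byte.
#' @return A [PlateScenario].
#' @export
plateScenario <- function(nPerWellLambda = 30,
                          organism = list(
                            tof = list(dist = "lognormal",
                                       meanlog = log(300), sdlog = 0.15),
                            ext = list(dist = "proportional",
                                       ratio = 0.5, noiseSd = 0.1),
                            green = list(dist = "gamma", shape = 4,
                                         scale = 10),
                            yellow = list(dist = "gamma", shape = 4,
                                          scale = 8),
                            red = list(dist = "gamma", shape = 4,
                                       scale = 6)),
                          bubble = list(
                            tof = list(dist = "normal", mean = 40,
                                       sd = 10),
                            ext = list(dist = "normal", mean = 5, sd = 2),
                            green = list(dist = "gamma", shape = 1,
                                         scale = 2),
                            yellow = list(dist = "gamma", shape = 1,
                                          scale = 2),
                            red = list(dist = "gamma", shape = 1,
                                       scale = 2)),
                          bubbleFraction = 0,
                          wellSd = 0.05,
                          edgeEffect = 0,
                          emptyWells = character(0),
                          seed = 1L) {
  for (side in list(organism = organism, bubble = bubble))
    for (tr in c("tof", "ext"))
      if (is.null(side[[tr]]))
        stop("invalid scenario: tof and ext specs are required",
             call. = FALSE)
  for (nm in names(organism)) .checkTraitSpec(organism[[nm]], nm)
  for (nm in names(bubble)) .checkTraitSpec(bubble[[nm]], nm)
  if (length(emptyWells)) emptyWells <- wellFromString(emptyWells)
  new("PlateScenario", nPerWellLambda = nPerWellLambda,
      organism = organism, bubble = bubble,
      bubbleFraction = bubbleFraction, wellSd = wellSd,
      edgeEffect = edgeEffect, emptyWells = emptyWells,
      seed = as.integer(seed))
}

.drawSide <- function(specs, n, shift = 0) {
  tof <- .drawTrait(specs$tof, n, shift = shift)
  out <- list(tof = tof)
  for (tr in c("ext", "green", "yellow", "red")) {
    out[[tr]] <- if (is.null(specs[[tr]])) rep(NA_real_, n)
      else .drawTrait(specs[[tr]], n, tof = tof)
  }
  out
}

#' Generate a synthetic plate with ground truth
#'
#' Draws per-well population sizes, interleaves bubbles at the
#' contamination fraction, applies between-well and edge-gradient shifts
#' to the organism TOF location, and returns the plate together with
#' ground-truth labels for test oracles. Output is reproducible: the
#' same scenario (same seed) yields byte-identical written files.
#'
#' @param scenario A [PlateScenario].
#' @param file Optional path; when given, the plate is also written in
#'   the canonical dialect.
#' @return A list with `plate` ([RawPlate]), `truth` (data.frame `id`,
#'   `well`, `is_bubble`) and `wellParams` (data.frame `well`, `n`,
#'   `shift`).
#' @export
generatePlate <- function(scenario, file = NULL) {
  stopifnot(is(scenario, "PlateScenario"))
  validObject(scenario)
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(scenario@seed)
  useWells <- setdiff(allWells(), scenario@emptyWells)
  edge <- edgeWells(1L)$edge
  recs <- vector("list", length(useWells))
  wp <- data.frame(well = useWells, n = 0L, shift = 0,
                   stringsAsFactors = FALSE)
  for (i in seq_along(useWells)) {
    w <- useWells[i]
    n <- stats::rpois(1, scenario@nPerWellLambda)
    shift <- stats::rnorm(1, 0, scenario@wellSd) +
      if (w %in% edge) scenario@edgeEffect * scenario@wellSd else 0
    wp$n[i] <- n; wp$shift[i] <- shift
    if (n == 0L) next
    nb <- stats::rbinom(1, n, scenario@bubbleFraction)
    no <- n - nb
    org <- if (no) .drawSide(scenario@organism, no, shift = shift)
    bub <- if (nb) .drawSide(scenario@bubble, nb)
    comb <- function(tr) c(if (no) org[[tr]], if (nb) bub[[tr]])
    recs[[i]] <- data.frame(
      well = w, is_bubble = rep(c(FALSE, TRUE), c(no, nb)),
      tof = comb("tof"), ext = comb("ext"), green = comb("green"),
      yellow = comb("yellow"), red = comb("red"),
      stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  if (is.null(recs))
    recs <- data.frame(well = character(0), is_bubble = logical(0),
                       tof = numeric(0), ext = numeric(0),
                       green = numeric(0), yellow = numeric(0),
                       red = numeric(0))
  label <- if (is.null(file)) sprintf("synthetic-seed%d", scenario@seed)
    else as.character(file)
  plate <- newRawPlate(well = recs$well, tof = recs$tof, ext = recs$ext,
                       green = recs$green, yellow = recs$yellow,
                       red = recs$red, status = 0L,
                       source = label, dialect = "canonical")
  truth <- data.frame(id = plate@observations$id, well = recs$well,
                      is_bubble = recs$is_bubble,
                      stringsAsFactors = FALSE)
  if (!is.null(file)) writePlate(plate, file)
  list(plate = plate, truth = truth, wellParams = wp)
}

#' Generate an SVM training pair of plates
#'
#' Emulates the two-plate training protocol: an object plate holding
#' only organism-distribution records and a bubble plate holding only
#' bubble-distribution records, with seeds derived from the scenario
#' seed.
#'
#' @param scenario A [PlateScenario]; its `organism` and `bubble` specs
#'   define the two classes.
#' @param n Number of records per plate (spread over the plate's
#'   non-empty wells).
#' @return A list with [RawPlate]s `objectPlate` and `bubblePlate`.
#' @export
generateTrainingPair <- function(scenario, n = 500L) {
  stopifnot(is(scenario, "PlateScenario"))
  old <- .saveRNG(); on.exit(.restoreRNG(old))
  useWells <- setdiff(allWells(), scenario@emptyWells)
  mk <- function(specs, seed, label) {
    set.seed(seed)
    side <- .drawSide(specs, n)
    if (all(vapply(specs[c("tof", "ext")],
                   function(s) s$dist == "constant", logical(1))))
      warning("insufficient variation: tof and ext are constant",
              call. = FALSE)
    newRawPlate(well = rep_len(useWells, n), tof = side$tof,
                ext = side$ext, green = side$green,
                yellow = side$yellow, red = side$red, status = 0L,
                source = label, dialect = "canonical")
  }
  list(objectPlate = mk(scenario@organism, scenario@seed + 1L,
                        "training-objects"),
       bubblePlate = mk(scenario@bubble, scenario@seed + 2L,
                        "training-bubbles"))
}

#' Read a plate scenario from a YAML or JSON file
#'
#' The file holds the arguments of [plateScenario()] by name; trait
#' specs nest as in [traitSpecs]. Lists left out keep their defaults.
#'
#' @param file Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A [PlateScenario].
#' @export
readScenario <- function(file) {
  args <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read JSON scenarios", call. = FALSE)
    jsonlite::fromJSON(file, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml is required to read YAML scenarios", call. = FALSE)
    yaml::read_yaml(file)
  }
  defaults <- formals(plateScenario)
  unknown <- setdiff(names(args), names(defaults))
  if (length(unknown))
    stop("invalid scenario: unknown field(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mergeSpecs <- function(user, default) {
    for (nm in names(user)) default[[nm]] <- user[[nm]]
    default
  }
  for (side in c("organism", "bubble"))
    if (!is.null(args[[side]]))
      args[[side]] <- mergeSpecs(args[[side]], eval(defaults[[side]]))
  do.call(plateScenario, args)
}
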
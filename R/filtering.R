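#' @include AllClasses.R
NULL

#' Size / optical-density cutoff specification
#'
#' Minimum and maximum cutoffs for object size (TOF) and optical density
#' (EXT), used to exclude records beyond the size parameters of the
#' organism being measured. All bounds are inclusive; `0`/`Inf` means
#' unbounded.
#'
#' @param tofMin,tofMax,extMin,extMax Nonnegative bounds.
#' @return A list of class `"CutoffSpec"`.
#' @examples
#' cutoffSpec(tofMin = 60, tofMax = 2000)
#' @export
cutoffSpec <- function(tofMin = 0, tofMax = Inf, extMin = 0, extMax = Inf) {
  for (v in list(tofMin, tofMax, extMin, extMax))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("invalid cutoff: bounds must be single nonnegative numbers",
           call. = FALSE)
  if (tofMin > tofMax || extMin > extMax)
    stop("invalid cutoff: minimum exceeds maximum", call. = FALSE)
  structure(list(tofMin = tofMin, tofMax = tofMax,
                 extMin = extMin, extMax = extMax),
            class = "CutoffSpec")
}

#' Apply TOF/EXT cutoffs to a plate
#'
#' Keeps exactly the observations with
#' `tofMin <= tof <= tofMax` and `extMin <= ext <= extMax` (bounds
#' inclusive), preserving record order.
#'
#' @param plate A [RawPlate].
#' @param cutoffs A [cutoffSpec()].
#' @return A list with `plate` (the filtered [RawPlate]) and
#'   `removedCount`.
#' @export
applyCutoffs <- function(plate, cutoffs) {
  stopifnot(is(plate, "RawPlate"))
  if (!inherits(cutoffs, "CutoffSpec"))
    cutoffs <- do.call(cutoffSpec, as.list(cutoffs))
  obs <- plate@observations
  keep <- !is.na(obs$tof) & !is.na(obs$ext) &
    obs$tof >= cutoffs$tofMin & obs$tof <= cutoffs$tofMax &
    obs$ext >= cutoffs$extMin & obs$ext <= cutoffs$extMax
  out <- plate
  out@observations <- obs[keep, , drop = FALSE]
  rownames(out@observations) <- NULL
  list(plate = out, removedCount = sum(!keep))
}

.ratioFeature <- "ext_tof_ratio"

.featureMatrix <- function(obs, features) {
  cols <- lapply(features, function(f) {
    if (f == .ratioFeature) {
      r <- obs$ext / obs$tof
      r[!is.finite(r)] <- NA_real_
      r
    } else {
      if (!f %in% names(obs))
        stop("feature missing from plate: ", f, call. = FALSE)
      obs[[f]]
    }
  })
  m <- do.call(cbind, cols)
  colnames(m) <- features
  bad <- colSums(!is.na(m)) == 0L
  if (any(bad))
    stop("feature missing from plate: ",
         paste(features[bad], collapse = ", "), call. = FALSE)
  m
}

#' Train a bubble classifier from a two-plate protocol
#'
#' Implements the standard training protocol: one plate run with only
#' objects of interest and the bubble trap engaged (label 0), and one
#' plate with no objects and the bubble trap disengaged, yielding bubble
#' records (label 1). Features are standardized with training-set
#' center/spread, an RBF-kernel SVM with Platt-scaled probabilities is
#' fitted, and held-out accuracy is estimated on a stratified 80/20
#' split whose seed is recorded in the classifier metadata.
#'
#' @param objectPlate [RawPlate] of organism-only records.
#' @param bubblePlate [RawPlate] of bubble-only records.
#' @param features Feature names among `tof`, `ext`, `green`, `yellow`,
#'   `red` and `"ext_tof_ratio"` (EXT/TOF). Defaults to all six; bubbles
#'   separate mainly on optical density per unit length.
#' @param threshold Probability above which (strictly) a record is
#'   flagged as a bubble.
#' @param seed Seed of the stratified holdout split.
#' @return A [BubbleClassifier].
#' @export
trainBubbleClassifier <- function(objectPlate, bubblePlate,
                                  features = c("tof", "ext", "green",
                                               "yellow", "red",
                                               .ratioFeature),
                                  threshold = 0.5, seed = 1L) {
  stopifnot(is(objectPlate, "RawPlate"), is(bubblePlate, "RawPlate"))
  if (nrow(objectPlate@observations) == 0L ||
      nrow(bubblePlate@observations) == 0L)
    stop("insufficient training data: both plates must be nonempty",
         call. = FALSE)
  # drop features with no data in either plate (e.g. fluorescence-free runs)
  keepFeat <- vapply(features, function(f) {
    ok <- function(p) {
      m <- tryCatch(.featureMatrix(p@observations, f), error = function(e) NULL)
      !is.null(m)
    }
    ok(objectPlate) && ok(bubblePlate)
  }, logical(1))
  if (!any(keepFeat))
    stop("feature missing from plate: ", paste(features, collapse = ", "),
         call. = FALSE)
  features <- features[keepFeat]

  xo <- .featureMatrix(objectPlate@observations, features)
  xb <- .featureMatrix(bubblePlate@observations, features)
  x <- rbind(xo, xb)
  y <- factor(rep(c(0L, 1L), c(nrow(xo), nrow(xb))), levels = c(0L, 1L))
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]; y <- y[complete]
  if (!all(table(y) > 0L))
    stop("insufficient training data after removing incomplete records",
         call. = FALSE)

  center <- colMeans(x)
  spread <- apply(x, 2, stats::sd)
  flat <- !is.finite(spread) | spread == 0
  if (any(flat)) {
    warning("insufficient variation in feature(s): ",
            paste(features[flat], collapse = ", "), call. = FALSE)
    spread[flat] <- 1
  }
  xs <- scale(x, center = center, scale = spread)

  old <- .saveRNG(); on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  hold <- unlist(lapply(split(seq_along(y), y), function(idx)
    sample(idx, max(1L, round(0.2 * length(idx))))))
  fit <- e1071::svm(xs[-hold, , drop = FALSE], y[-hold],
                    kernel = "radial", probability = TRUE,
                    scale = FALSE)
  pred <- stats::predict(fit, xs[hold, , drop = FALSE])
  acc <- mean(pred == y[hold])
  # refit on the full training set for the deployed model
  model <- e1071::svm(xs, y, kernel = "radial", probability = TRUE,
                      scale = FALSE)
  new("BubbleClassifier", features = features, center = center,
      scale = spread, model = model, threshold = threshold,
      trainingInfo = list(heldOutAccuracy = acc, seed = as.integer(seed),
                          nObjects = sum(y == "0"),
                          nBubbles = sum(y == "1"),
                          nHeldOut = length(hold)))
}

#' Score or drop probable bubbles in a plate
#'
#' Annotate mode fills `bubble_prob` for every observation and removes
#' nothing; drop mode removes observations whose bubble probability
#' strictly exceeds the classifier threshold.
#'
#' @param plate A [RawPlate] carrying every feature the classifier was
#'   trained on.
#' @param classifier A [BubbleClassifier].
#' @param mode `"annotate"` or `"drop"`.
#' @param threshold Optional override of the classifier's threshold.
#' @return A list with `plate` and `flaggedCount` (number of records
#'   over threshold).
#' @export
classifyBubbles <- function(plate, classifier,
                            mode = c("annotate", "drop"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(plate, "RawPlate"), is(classifier, "BubbleClassifier"))
  thr <- if (is.null(threshold)) classifier@threshold else threshold
  obs <- plate@observations
  out <- plate
  if (nrow(obs) == 0L) {
    return(list(plate = out, flaggedCount = 0L))
  }
  x <- .featureMatrix(obs, classifier@features)
  xs <- scale(x, center = classifier@center, scale = classifier@scale)
  prob <- rep(NA_real_, nrow(obs))
  complete <- stats::complete.cases(xs)
  if (any(complete)) {
    pred <- stats::predict(classifier@model, xs[complete, , drop = FALSE],
                           probability = TRUE)
    pm <- attr(pred, "probabilities")
    prob[complete] <- pm[, "1"]
  }
  obs$bubble_prob <- prob
  flagged <- !is.na(prob) & prob > thr
  if (mode == "drop") {
    obs <- obs[!flagged, , drop = FALSE]
    rownames(obs) <- NULL
  }
  out@observations <- obs
  list(plate = out, flaggedCount = sum(flagged))
}

#' Save / load a bubble classifier
#'
#' The classifier serializes to a single self-describing file holding the
#' feature list, scaling parameters, threshold, holdout seed and model.
#'
#' @param classifier A [BubbleClassifier].
#' @param file Path of the model file.
#' @return `readBubbleClassifier()` returns the [BubbleClassifier].
#' @export
saveBubbleClassifier <- function(classifier, file) {
  stopifnot(is(classifier, "BubbleClassifier"))
  saveRDS(classifier, file)
  invisible(file)
}

#' @rdname saveBubbleClassifier
#' @export
readBubbleClassifier <- function(file) {
  obj <- readRDS(file)
  if (!is(obj, "BubbleClassifier"))
    stop("file does not contain a BubbleClassifier", call. = FALSE)
  obj
}
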
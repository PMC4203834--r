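#' Well coordinates of a 96-well microtiter plate
#'
#' Plates are addressed by a row letter (A--H) and a 1-based column number
#' (1--12). The canonical string form is the unpadded uppercase label
#' (`"A1"`, `"H12"`). Parsing is case-insensitive and tolerates a
#' zero-padded column (`"a01"`); rendering always produces the canonical
#' form. Well order is row-major: A1 < A2 < ... < A12 < B1 < ... < H12.
#'
#' @param label Character vector of well labels.
#' @return `wellFromString()` returns the canonical labels;
#'   `allWells()` returns the 96 canonical labels in row-major order.
#' @examples
#' wellFromString(c("a01", "H12"))
#' allWells()[1:13]
#' @name wells
NULL

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' @rdname wells
#' @export
allWells <- function() {
  as.vector(t(outer(PLATE_ROWS, PLATE_COLS, paste0)))
}

#' @rdname wells
#' @export
wellFromString <- function(label) {
  if (length(label) == 0L) return(character(0))
  label <- as.character(label)
  m <- regmatches(label, regexec("^([A-Ha-h])(0?[1-9]|1[0-2])$", label))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("invalid well label(s): ",
         paste(sQuote(label[bad]), collapse = ", "),
         call. = FALSE)
  }
  vapply(m, function(g) paste0(toupper(g[2]), as.integer(g[3])), character(1))
}

#' @rdname wells
#' @export
wellToString <- function(label) wellFromString(label)

#' Split well labels into row letters and column numbers
#'
#' @param well Character vector of well labels (any accepted form).
#' @return A data.frame with columns `row` (letter) and `col` (integer).
#' @export
wellRowColumn <- function(well) {
  w <- wellFromString(well)
  data.frame(row = substr(w, 1, 1),
             col = as.integer(substr(w, 2, 4)),
             stringsAsFactors = FALSE)
}

#' Row-major rank of wells (A1 = 1, ..., H12 = 96)
#'
#' @inheritParams wellRowColumn
#' @return Integer vector of ranks in 1..96.
#' @export
wellOrder <- function(well) {
  rc <- wellRowColumn(well)
  (match(rc$row, PLATE_ROWS) - 1L) * 12L + rc$col
}

#' Edge and center wells of a plate
#'
#' The edge is the outermost ring of wells (rows A and H plus columns 1
#' and 12 of rows B--G; 36 wells) for `depth = 1`, or the outermost two
#' rings (64 wells) for `depth = 2`. The center is the complement.
#'
#' @param depth Integer, 1 or 2: how many rings count as edge.
#' @return A list with character vectors `edge` and `center`.
#' @export
edgeWells <- function(depth = 1L) {
  depth <- as.integer(depth)
  if (!depth %in% c(1L, 2L)) stop("edge depth must be 1 or 2", call. = FALSE)
  rc <- wellRowColumn(allWells())
  ri <- match(rc$row, PLATE_ROWS)
  on_edge <- ri <= depth | ri > 8L - depth | rc$col <= depth | rc$col > 12L - depth
  list(edge = allWells()[on_edge], center = allWells()[!on_edge])
}
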
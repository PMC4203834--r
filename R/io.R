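#' @include AllClasses.R
NULL

# Synonym table mapping canonical fields to accepted (lower-cased) header
# names. User dialects extend this via registerDialectSynonyms().
.synonyms <- new.env(parent = emptyenv())
.defaultSynonyms <- function() list(
  id     = c("id", "object", "object id"),
  row    = c("row"),
  col    = c("column", "col"),
  status = c("status", "status sort", "sort status"),
  tof    = c("tof", "time of flight"),
  ext    = c("ext", "extinction"),
  green  = c("green"),
  yellow = c("yellow"),
  red    = c("red"),
  plate  = c("plate"))

.getSynonyms <- function() {
  if (is.null(.synonyms$table)) .synonyms$table <- .defaultSynonyms()
  .synonyms$table
}

#' Extend the header synonym table
#'
#' COPAS and BioSorter exports differ across firmware versions; extra
#' header names can be mapped onto the canonical fields here.
#'
#' @param field Canonical field name (`"tof"`, `"ext"`, `"row"`, ...).
#' @param names Character vector of additional header names (matched
#'   case-insensitively).
#' @return Invisibly, the updated synonym table.
#' @export
registerDialectSynonyms <- function(field, names) {
  tab <- .getSynonyms()
  if (!field %in% names(tab))
    stop("unknown canonical field: ", field, call. = FALSE)
  tab[[field]] <- unique(c(tab[[field]], tolower(names)))
  .synonyms$table <- tab
  invisible(tab)
}

CANONICAL_HEADER <- c("Id", "Row", "Column", "Status sort", "TOF", "EXT",
                      "Green", "Yellow", "Red")

#' Detect the header dialect of an instrument file
#'
#' Maps the file's column names onto the canonical per-object fields by
#' case-insensitive synonym matching. TOF, EXT, Row and Column are
#' required; id, sort status and the fluorescence channels are optional.
#'
#' @param headerLine The first line of the file (tab-delimited header).
#' @return A list of class `"plateDialect"` with elements `name`
#'   (`"canonical"` if the header is the canonical one, else `"custom"`)
#'   and `map`, a named integer vector from canonical field to column
#'   index.
#' @examples
#' detectDialect("Row\tCol\tTOF\tExtinction")
#' @export
detectDialect <- function(headerLine) {
  cols <- strsplit(sub("\r$", "", headerLine), "\t", fixed = TRUE)[[1]]
  key <- tolower(trimws(cols))
  tab <- .getSynonyms()
  map <- integer(0)
  for (field in names(tab)) {
    hit <- which(key %in% tab[[field]])
    if (length(hit)) map[field] <- hit[1]
  }
  required <- c("tof", "ext", "row", "col")
  missing <- setdiff(required, names(map))
  if (length(missing)) {
    pretty <- c(tof = "TOF", ext = "EXT", row = "Row", col = "Column")
    stop("unrecognized instrument format: header lacks column(s) ",
         paste(pretty[missing], collapse = ", "), call. = FALSE)
  }
  name <- if (identical(cols, CANONICAL_HEADER)) "canonical" else "custom"
  structure(list(name = name, map = map, header = cols),
            class = "plateDialect")
}

.asCount <- function(x) {
  suppressWarnings(as.numeric(x))
}

#' Construct a RawPlate from vectors
#'
#' Low-level constructor used by the parser and the synthetic-data
#' generator. Missing optional fields default to `NA`.
#'
#' @param well Character vector of well labels (any accepted form).
#' @param tof,ext Numeric, required.
#' @param green,yellow,red,status,id Optional per-object fields.
#' @param source,dialect Provenance metadata.
#' @param parseReport Parse report list.
#' @return A [RawPlate].
#' @export
newRawPlate <- function(well, tof, ext, green = NA_real_,
                        yellow = NA_real_, red = NA_real_,
                        status = NA_integer_, id = NULL,
                        source = NA_character_, dialect = "canonical",
                        parseReport = list()) {
  n <- length(well)
  rc <- wellRowColumn(well)
  if (is.null(id)) id <- seq_len(n)
  obs <- data.frame(id = as.integer(id), row = rc$row, col = rc$col,
                    status = rep_len(suppressWarnings(as.integer(status)), n),
                    tof = as.numeric(tof), ext = as.numeric(ext),
                    green = rep_len(as.numeric(green), n),
                    yellow = rep_len(as.numeric(yellow), n),
                    red = rep_len(as.numeric(red), n),
                    norm_ext = NA_real_, norm_green = NA_real_,
                    norm_yellow = NA_real_, norm_red = NA_real_,
                    bubble_prob = NA_real_, stringsAsFactors = FALSE)
  if (!length(parseReport))
    parseReport <- list(dataLines = n, dropped = 0L, zeroTof = NA_integer_)
  new("RawPlate", observations = obs, source = source, dialect = dialect,
      parseReport = parseReport)
}

#' Read a tab-delimited COPAS/BioSorter plate file
#'
#' Parses one per-object record per line. Lines whose required numeric
#' fields (TOF, EXT) fail to parse, or whose well coordinate is invalid,
#' are dropped and counted in the plate's parse report rather than
#' aborting the read: instrument files commonly end with truncated lines.
#' Fluorescence fields absent from the dialect are recorded as missing.
#' If a `Plate` column is present it must be constant; one file is one
#' plate.
#'
#' @param file Path to the tab-delimited text file (LF or CRLF).
#' @param dialect Optional dialect from [detectDialect()]; detected from
#'   the header when `NULL`.
#' @return A [RawPlate]; its [parseReport()] records the data-line and
#'   dropped-line counts.
#' @seealso [writePlate()] for the inverse operation.
#' @export
readPlate <- function(file, dialect = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("empty plate: ", file,
         " has no data lines below the header", call. = FALSE)
  if (is.null(dialect)) dialect <- detectDialect(lines[1])
  map <- dialect$map
  body <- lines[-1]
  fields <- strsplit(body, "\t", fixed = TRUE)

  getCol <- function(i, field) {
    vapply(fields, function(f) {
      j <- map[[field]]
      if (!is.null(j) && j <= length(f)) f[j] else NA_character_
    }, character(1))
  }
  num <- function(field) {
    if (!field %in% names(map)) return(rep(NA_real_, length(fields)))
    v <- getCol(seq_along(fields), field)
    v[!nzchar(v) | v == "NA"] <- NA
    suppressWarnings(as.numeric(v))
  }

  rowv <- toupper(trimws(getCol(seq_along(fields), "row")))
  colraw <- getCol(seq_along(fields), "col")
  colv <- suppressWarnings(as.integer(colraw))
  tof <- num("tof"); ext <- num("ext")
  green <- num("green"); yellow <- num("yellow"); red <- num("red")
  status <- num("status"); idv <- num("id")

  if ("plate" %in% names(map)) {
    pv <- getCol(seq_along(fields), "plate")
    if (length(unique(pv[!is.na(pv) & nzchar(pv)])) > 1L)
      stop("file contains more than one plate (non-constant Plate column)",
           call. = FALSE)
  }

  ok <- rowv %in% PLATE_ROWS & !is.na(colv) & colv %in% PLATE_COLS &
    !is.na(tof) & !is.na(ext)
  dropped <- sum(!ok)
  if (!any(ok))
    stop("empty plate: no parsable data lines in ", file, call. = FALSE)

  id <- if ("id" %in% names(map) && !anyNA(idv[ok]) &&
            !anyDuplicated(idv[ok])) as.integer(idv[ok]) else seq_len(sum(ok))
  plate <- newRawPlate(
    well = paste0(rowv[ok], colv[ok]), tof = tof[ok], ext = ext[ok],
    green = green[ok], yellow = yellow[ok], red = red[ok],
    status = status[ok], id = id, source = as.character(file),
    dialect = dialect$name,
    parseReport = list(dataLines = length(body), dropped = dropped,
                       zeroTof = NA_integer_))
  if (dropped > 0L)
    message("readPlate: dropped ", dropped, " unparsable line(s) from ",
            file)
  plate
}

.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
  }, character(1))
  out
}

#' Write a RawPlate in the canonical tab-delimited dialect
#'
#' Emits the canonical nine-column header (`Id`, `Row`, `Column`,
#' `Status sort`, `TOF`, `EXT`, `Green`, `Yellow`, `Red`) and one line
#' per object, LF-terminated. Missing values are written as empty fields.
#' `readPlate(writePlate(p))` preserves integer fields exactly and
#' floating-point fields to full double precision.
#'
#' @param plate A [RawPlate].
#' @param file Destination path.
#' @return Invisibly, `file`.
#' @export
writePlate <- function(plate, file) {
  stopifnot(is(plate, "RawPlate"))
  obs <- plate@observations
  lines <- paste(CANONICAL_HEADER, collapse = "\t")
  if (nrow(obs)) {
    body <- paste(obs$id, obs$row, obs$col,
                  ifelse(is.na(obs$status), "", obs$status),
                  .fmtNum(obs$tof), .fmtNum(obs$ext), .fmtNum(obs$green),
                  .fmtNum(obs$yellow), .fmtNum(obs$red), sep = "\t")
    lines <- c(lines, body)
  }
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(file)
}
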
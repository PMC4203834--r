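#' @include AllClasses.R AllGenerics.R viz-prep.R
NULL

.gridFacets <- function(p) {
  p + ggplot2::facet_grid(
    row ~ col, drop = FALSE) +
    ggplot2::theme_bw(base_size = 8) +
    ggplot2::theme(panel.grid = ggplot2::element_blank(),
                   strip.background = ggplot2::element_blank())
}

.panelFrame <- function(wellsUsed) {
  rc <- wellRowColumn(wellsUsed)
  data.frame(well = wellsUsed,
             row = factor(rc$row, levels = PLATE_ROWS),
             col = factor(rc$col, levels = PLATE_COLS),
             stringsAsFactors = FALSE)
}

.emptyGrid <- function() {
  d <- .panelFrame(allWells())
  .gridFacets(ggplot2::ggplot(d, ggplot2::aes(x = 1, y = 1)) +
                ggplot2::geom_blank())
}

.buildGridPlot <- function(layout) {
  panels <- layout@panels
  if (!length(panels)) return(.emptyGrid())
  frame <- .panelFrame(names(panels))
  kind <- layout@kind
  if (kind == "scatter") {
    d <- do.call(rbind, lapply(seq_along(panels), function(i) {
      p <- panels[[i]]
      if (!nrow(p)) return(NULL)
      cbind(frame[rep(i, nrow(p)), ], p)
    }))
    if (is.null(d)) return(.emptyGrid())
    .gridFacets(ggplot2::ggplot(d, ggplot2::aes(x = x, y = y)) +
                  ggplot2::geom_point(size = 0.3, alpha = 0.6) +
                  ggplot2::labs(x = layout@meta$xTrait,
                                y = layout@meta$yTrait))
  } else if (kind == "histogram") {
    br <- layout@meta$breaks
    mids <- (br[-1] + br[-length(br)]) / 2
    d <- do.call(rbind, lapply(seq_along(panels), function(i)
      cbind(frame[rep(i, length(mids)), ],
            data.frame(mid = mids, count = panels[[i]]))))
    .gridFacets(ggplot2::ggplot(d, ggplot2::aes(x = mid, y = count)) +
                  ggplot2::geom_col(width = diff(br)[1]) +
                  ggplot2::labs(x = layout@meta$trait, y = "count"))
  } else if (kind == "heatmap") {
    d <- .panelFrame(allWells())
    d$value <- NA_real_
    d$value[match(names(panels), d$well)] <- unlist(panels)
    ggplot2::ggplot(d, ggplot2::aes(x = col, y = row, fill = value)) +
      ggplot2::geom_tile(color = "grey40") +
      ggplot2::scale_y_discrete(limits = rev(PLATE_ROWS)) +
      ggplot2::scale_fill_gradient(low = "lightyellow", high = "red3",
                                   na.value = "grey80") +
      ggplot2::labs(x = "column", y = "row",
                    fill = layout@meta$column) +
      ggplot2::theme_minimal(base_size = 9)
  } else if (kind == "compare_box") {
    d <- do.call(rbind, lapply(seq_along(panels), function(i) {
      pn <- panels[[i]]
      do.call(rbind, lapply(c("a", "b"), function(side) {
        s <- pn[[side]]
        if (s$n == 0L) return(NULL)
        cbind(frame[i, ],
              data.frame(plate = side, middle = s$median,
                         lower = s$q1, upper = s$q3,
                         ymin = s$lower, ymax = s$upper))
      }))
    }))
    if (is.null(d)) return(.emptyGrid())
    .gridFacets(ggplot2::ggplot(d,
        ggplot2::aes(x = plate, middle = middle, lower = lower,
                     upper = upper, ymin = ymin, ymax = ymax,
                     fill = plate)) +
        ggplot2::geom_boxplot(stat = "identity") +
        ggplot2::labs(y = layout@meta$trait))
  } else {  # compare_bar
    d <- do.call(rbind, lapply(seq_along(panels), function(i) {
      pn <- panels[[i]]
      cbind(frame[rep(i, 2), ],
            data.frame(plate = c("a", "b"),
                       value = c(pn$a, pn$b)))
    }))
    .gridFacets(ggplot2::ggplot(d,
        ggplot2::aes(x = plate, y = value, fill = plate)) +
        ggplot2::geom_col() +
        ggplot2::labs(y = layout@meta$column))
  }
}

.buildCorPlot <- function(x) {
  co <- x@coefficients
  d <- expand.grid(a = rownames(co), b = colnames(co),
                   KEEP.OUT.ATTRS = FALSE)
  d$r <- as.vector(co)
  ggplot2::ggplot(d, ggplot2::aes(x = b, y = a, fill = r)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "green3",
                                  high = "red3", midpoint = 0,
                                  limits = c(-1, 1),
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = x@method) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1))
}

.buildDosePlot <- function(x) {
  pts <- x@points
  grp <- x@groups[!is.na(x@groups$mean), , drop = FALSE]
  ggplot2::ggplot(pts, ggplot2::aes(x = dose, y = value,
                                    color = strain)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grp,
                       ggplot2::aes(x = dose, y = mean,
                                    color = strain, group = strain)) +
    ggplot2::labs(y = paste(x@statistic, x@trait, sep = "_"),
                  x = "dose") +
    ggplot2::theme_bw()
}

.writeFigure <- function(plot, file, width, height) {
  ext <- tolower(tools::file_ext(file))
  dev <- switch(ext,
    png = function() grDevices::png(file, width = width,
                                    height = height, units = "in",
                                    res = 150, type = "cairo"),
    svg = function() grDevices::svg(file, width = width,
                                    height = height),
    pdf = function() grDevices::pdf(file, width = width,
                                    height = height),
    stop("unsupported output format: .", ext, call. = FALSE))
  dev()
  ok <- FALSE
  tryCatch({ print(plot); ok <- TRUE },
           finally = grDevices::dev.off())
  if (!ok) stop("rendering failed for ", file, call. = FALSE)
  invisible(file)
}

#' @rdname renderFigure
#' @export
setMethod("renderFigure", "PlateGridLayout",
  function(x, file, width = 10, height = 7, ...)
    .writeFigure(.buildGridPlot(x), file, width, height))

#' @rdname renderFigure
#' @export
setMethod("renderFigure", "CorrelationMatrix",
  function(x, file, width = 10, height = 7, ...)
    .writeFigure(.buildCorPlot(x), file, width, height))

#' @rdname renderFigure
#' @export
setMethod("renderFigure", "DoseResponseTable",
  function(x, file, width = 10, height = 7, ...)
    .writeFigure(.buildDosePlot(x), file, width, height))
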
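## shared plotting core working on a results data.frame
.forestPlotCore <- function(tab, metameter, highlight = "blue2",
                            labelSignificant = TRUE) {
  avail <- unique(tab$metameter)
  if (!metameter %in% avail)
    stop("unknown metameter '", metameter, "'; available: ",
         paste(avail, collapse = ", "))
  d <- tab[tab$metameter == metameter &
             is.finite(tab$lower) & is.finite(tab$upper), , drop = FALSE]
  if (!nrow(d))
    stop("no plottable rows for metameter '", metameter, "'")
  d <- d[order(d$effect), , drop = FALSE]
  d$pos <- seq_len(nrow(d))
  d$sig <- isTRUE(NA) | d$significant %in% TRUE
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$effect, y = .data$pos)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper,
                   colour = .data$sig),
      height = 0, linewidth = 0.4) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sig), size = 1.1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = highlight),
                                 guide = "none") +
    ggplot2::scale_y_continuous(breaks = NULL, expand = c(0.02, 0.5)) +
    ggplot2::labs(
      x = paste0("effect (", metameter, " metameter), simultaneous ",
                 "confidence intervals"),
      y = "metabolites ordered by increasing effect") +
    ggplot2::theme_minimal()
  if (labelSignificant && any(d$sig))
    gg <- gg + ggplot2::geom_text(
      data = d[d$sig, , drop = FALSE],
      ggplot2::aes(label = .data$metabolite),
      colour = highlight, size = 2.6, hjust = -0.08, vjust = -0.6)
  gg
}

.writePlot <- function(gg, path, width = 7, height = 6) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    pdf = function() grDevices::pdf(path, width = width, height = height),
    png = function() grDevices::png(path, width = width, height = height,
                                    units = "in", res = 150),
    svg = function() grDevices::svg(path, width = width, height = height),
    stop("unsupported plot format '", ext, "' (use pdf, png or svg)"))
  dev()
  on.exit(grDevices::dev.off())
  print(gg)
  invisible(path)
}

#' @describeIn forestPlot plot one metameter panel of a scan.
#' @param metameter which metameter panel to draw (default
#'   \code{"arithmetic"}).
#' @param outPath optional file path; the format follows the extension
#'   (pdf, png or svg).
#' @param highlight colour for metabolites whose simultaneous interval
#'   excludes zero (default \code{"blue2"}).
#' @param labelSignificant label the highlighted metabolites (default TRUE).
#' @param width,height device size in inches when writing to a file.
#' @export
setMethod("forestPlot", "ScanResult",
  function(object, metameter = "arithmetic", outPath = NULL,
           highlight = "blue2", labelSignificant = TRUE,
           width = 7, height = 6) {
    gg <- .forestPlotCore(object@table, metameter, highlight,
                          labelSignificant)
    if (!is.null(outPath)) {
      .writePlot(gg, outPath, width, height)
      return(invisible(gg))
    }
    gg
  })

#' @describeIn forestPlot plot straight from a results table (e.g. a results
#'   CSV read back with \code{read.csv}), so plots can be regenerated
#'   without refitting.
#' @export
setMethod("forestPlot", "data.frame",
  function(object, metameter = "arithmetic", outPath = NULL,
           highlight = "blue2", labelSignificant = TRUE,
           width = 7, height = 6) {
    need <- c("metabolite", "metameter", "effect", "lower", "upper",
              "significant")
    missCols <- setdiff(need, colnames(object))
    if (length(missCols))
      stop("results table lacks column(s): ",
           paste(missCols, collapse = ", "))
    gg <- .forestPlotCore(object, metameter, highlight, labelSignificant)
    if (!is.null(outPath)) {
      .writePlot(gg, outPath, width, height)
      return(invisible(gg))
    }
    gg
  })

## forest plot uses the tidy-eval pronoun
#' @importFrom rlang .data
NULL
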
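#' Build the metameters of the variable of interest
#'
#' Each metabolite is modelled under every metameter of the exposure: the
#' arithmetic metameter is the raw variable, the logarithmic metameter its
#' (natural) logarithm, capturing linear and log-shaped dose-response
#' patterns respectively.  With both metameters enabled a scan of \code{p}
#' metabolites submits \code{2 * p} marginal models to the joint inference.
#' Columns are neither centered nor scaled, so effects are reported per raw
#' unit of each metameter (one year vs. one log-year for an age exposure).
#'
#' @param x numeric vector of exposure values, finite; strictly positive
#'   when \code{includeLog}.
#' @param includeLog logical, add the logarithmic metameter (default TRUE).
#' @param logBase base of the logarithm (default natural; base 2 can ease
#'   comparison with fold-change style analyses).
#' @param sourceName name of the exposure variable, e.g. \code{"age"}.
#' @param sampleIDs optional sample identifiers for error messages.
#' @return a [MetameterSet-class].
#' @examples
#' m <- makeMetameters(exp(1:3), sourceName = "age")
#' m@columns[, "logarithmic"]   # 1 2 3
#' @export
makeMetameters <- function(x, includeLog = TRUE, logBase = exp(1),
                           sourceName = "x", sampleIDs = NULL) {
  x <- as.numeric(x)
  if (any(!is.finite(x)))
    stop("exposure '", sourceName, "' must be finite")
  if (is.null(sampleIDs)) sampleIDs <- as.character(seq_along(x))
  if (includeLog && any(x <= 0)) {
    bad <- sampleIDs[x <= 0]
    stop("logarithmic metameter of '", sourceName,
         "' undefined for non-positive values in samples: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) ", ...")
  }
  cols <- cbind(arithmetic = x)
  nm <- "arithmetic"
  if (includeLog) {
    cols <- cbind(cols, logarithmic = log(x, base = logBase))
    nm <- c(nm, "logarithmic")
  }
  rownames(cols) <- sampleIDs
  new("MetameterSet", metameters = nm, columns = cols,
      sourceName = sourceName)
}

setMethod("show", "MetameterSet", function(object) {
  cat("MetameterSet of '", object@sourceName, "': ",
      paste(object@metameters, collapse = ", "), " (",
      nrow(object@columns), " samples)\n", sep = "")
})
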
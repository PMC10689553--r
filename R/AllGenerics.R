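#' Evaluate the Bernstein basis functions
#'
#' @param object a [BernsteinBasis-class].
#' @param y numeric vector of evaluation points inside the support (a small
#'   numerical slack at the edges is clamped).
#' @return numeric matrix, \code{length(y)} rows and \code{order + 1}
#'   columns; rows are non-negative and sum to one.
#' @export
setGeneric("basisEval", function(object, y) standardGeneric("basisEval"))

#' Evaluate the derivative of the Bernstein basis functions
#'
#' @inheritParams basisEval
#' @return numeric matrix of the same shape as [basisEval()], the derivative
#'   of each basis function with respect to \code{y}.
#' @export
setGeneric("basisDeriv", function(object, y) standardGeneric("basisDeriv"))

#' Evaluate the monotone transformation h and its derivative
#'
#' \code{transformEval} computes \eqn{h(y) = \sum_k \theta_k b_k(y)};
#' \code{transformDeriv} computes \eqn{h'(y)}.  With non-decreasing
#' \code{theta} the transformation is non-decreasing and interpolates
#' \code{theta[1]} and \code{theta[M+1]} at the support endpoints.
#'
#' @param object a [BernsteinBasis-class].
#' @param theta numeric, non-decreasing Bernstein coefficients.
#' @param y numeric vector of evaluation points.
#' @return numeric vector of \eqn{h(y)} (or \eqn{h'(y)}) values.
#' @export
setGeneric("transformEval",
  function(object, theta, y) standardGeneric("transformEval"))

#' @rdname transformEval
#' @export
setGeneric("transformDeriv",
  function(object, theta, y) standardGeneric("transformDeriv"))

#' Support interval of a basis or encoded response
#'
#' @param object a [BernsteinBasis-class] or [CensoredResponse-class].
#' @return numeric(2), the interval \code{(a, b)}.
#' @export
setGeneric("support", function(object) standardGeneric("support"))

#' Counts of observation kinds in an encoded response
#'
#' @param object a [CensoredResponse-class].
#' @return named integer vector with elements \code{exact}, \code{left},
#'   \code{interval}, \code{missing}; the four counts always partition the
#'   raw vector length.
#' @export
setGeneric("kindCounts", function(object) standardGeneric("kindCounts"))

#' Convert an encoded response to a survival::Surv object
#'
#' Non-missing entries are returned as an interval2-type \code{Surv} object
#' (exact values, left-censored bounds, interval endpoints), the canonical
#' censored-response container.
#'
#' @param object a [CensoredResponse-class].
#' @return a \code{survival::Surv} object of length \code{nObs(object) -
#'   kindCounts(object)["missing"]}.
#' @export
setGeneric("asSurv", function(object) standardGeneric("asSurv"))

#' Number of samples in an encoded response
#'
#' @param object a [CensoredResponse-class].
#' @return integer(1), including missing markers.
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))

#' Metabolome-wide association scan
#'
#' @param abundance samples-by-metabolites numeric matrix or data.frame with
#'   sample IDs as row names, or a \code{SummarizedExperiment} with
#'   metabolites in rows (assay columns are samples, the Bioconductor
#'   convention) and the metadata in \code{colData}.
#' @param ... passed to the workhorse; see [metaboScan,matrix-method].
#' @return a [ScanResult-class].
#' @export
setGeneric("metaboScan",
  function(abundance, ...) standardGeneric("metaboScan"))

#' Results table of a scan
#'
#' @param object a [ScanResult-class].
#' @return the results data.frame (one row per metabolite-metameter pair).
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))

#' Forest plot of simultaneous confidence intervals
#'
#' One horizontal interval per metabolite around a point marker, ordered by
#' increasing effect, with a vertical reference line at zero; metabolites
#' whose simultaneous interval excludes zero are highlighted and labelled.
#' Because every metabolite is standardized by its own most likely
#' transformation, the intervals are comparable across differently scaled
#' metabolites.
#'
#' @param object a [ScanResult-class].
#' @param ... see [forestPlot,ScanResult-method].
#' @return a ggplot object, invisibly when written to a file.
#' @export
setGeneric("forestPlot", function(object, ...) standardGeneric("forestPlot"))
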
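#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## workhorse behind the metaboScan methods
.scanCore <- function(abundance, metadata, exposure = "age",
                      adjust = character(), loqMap = NULL, order = 6L,
                      link = c("probit", "logit"), level = 0.95,
                      includeLog = TRUE, logBase = exp(1),
                      tiePolicy = c("interval", "none"),
                      supportMargin = 0.1, seed = 20230101,
                      family = c("all", "per-metameter"),
                      keepFits = FALSE) {
  link <- match.arg(link)
  tiePolicy <- match.arg(tiePolicy)
  family <- match.arg(family)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    stop("abundance must carry sample IDs as row names")
  if (is.null(colnames(abundance)))
    stop("abundance must carry metabolite names as column names")
  if (anyDuplicated(colnames(abundance)))
    stop("duplicated metabolite names: ",
         paste(unique(colnames(abundance)[duplicated(colnames(abundance))]),
               collapse = ", "))
  metadata <- as.data.frame(metadata)
  ids <- intersect(rownames(abundance), rownames(metadata))
  if (!length(ids))
    stop("no samples shared between abundance and metadata tables")
  abundance <- abundance[ids, , drop = FALSE]
  metadata <- metadata[ids, , drop = FALSE]

  if (!exposure %in% colnames(metadata))
    stop("exposure column '", exposure, "' not in metadata; available: ",
         paste(colnames(metadata), collapse = ", "))
  xvar <- metadata[[exposure]]
  if (!is.numeric(xvar)) stop("exposure '", exposure, "' must be numeric")
  mm <- makeMetameters(xvar, includeLog = includeLog, logBase = logBase,
                       sourceName = exposure, sampleIDs = ids)

  if (length(adjust)) {
    missA <- setdiff(adjust, colnames(metadata))
    if (length(missA))
      stop("adjustment covariate(s) not in metadata: ",
           paste(missA, collapse = ", "))
    Z <- as.matrix(metadata[, adjust, drop = FALSE])
    storage.mode(Z) <- "double"
  } else Z <- NULL

  mets <- colnames(abundance)
  p <- length(mets)
  fits <- list()
  rowsMeta <- list()
  skips <- data.frame(metabolite = character(), reason = character(),
                      stringsAsFactors = FALSE)
  for (met in mets) {
    resp <- tryCatch(
      encodeResponse(abundance[, met],
                     loq = if (!is.null(loqMap) && met %in% names(loqMap))
                             loqMap[[met]] else NA_real_,
                     tiePolicy = tiePolicy, supportMargin = supportMargin,
                     name = met, sampleIDs = ids),
      error = function(e) conditionMessage(e))
    if (is.character(resp)) {
      skips <- rbind(skips, data.frame(metabolite = met, reason = resp))
      next
    }
    metFits <- tryCatch({
      lapply(mm@metameters, function(mname) {
        X <- cbind(mm@columns[, mname, drop = FALSE], Z)
        colnames(X)[1] <- mname
        fitTransformModel(resp, X, link = link, order = order)
      })
    }, error = function(e) conditionMessage(e))
    if (is.character(metFits)) {
      skips <- rbind(skips, data.frame(metabolite = met, reason = metFits))
      next
    }
    cnt <- kindCounts(resp)
    for (im in seq_along(mm@metameters)) {
      lab <- paste(met, mm@metameters[im], sep = "|")
      fits[[lab]] <- metFits[[im]]
      rowsMeta[[lab]] <- list(metabolite = met,
                              metameter = mm@metameters[im],
                              n_left = cnt[["left"]],
                              n_interval = cnt[["interval"]])
    }
  }

  labs <- names(fits)
  effects <- vapply(fits, function(f) unname(f@beta[1]), 1.0)
  conv <- vapply(fits, function(f) f@converged, TRUE)
  nUsed <- vapply(fits, function(f) f@nUsed, 1L)

  lower <- upper <- pAdj <- rep(NA_real_, length(fits))
  names(lower) <- names(upper) <- names(pAdj) <- labs
  joint <- NULL
  inferOver <- function(sel) {
    V <- suppressWarnings(jointCovariance(fits[sel]))
    usable <- sel[setdiff(seq_along(sel), attr(V, "dropped"))]
    ji <- maxTInference(effects[usable], V, level = level, seed = seed,
                        labels = labs[usable])
    lower[usable] <<- ji@ciLower
    upper[usable] <<- ji@ciUpper
    pAdj[usable] <<- ji@pAdj
    ji
  }
  convIdx <- which(conv)
  if (length(convIdx)) {
    if (family == "all") {
      joint <- inferOver(convIdx)
    } else {
      joint <- lapply(mm@metameters, function(mname) {
        sel <- convIdx[vapply(rowsMeta[convIdx],
                              function(r) r$metameter == mname, TRUE)]
        if (length(sel)) inferOver(sel) else NULL
      })
      names(joint) <- mm@metameters
    }
  }

  tab <- data.frame(
    metabolite = vapply(rowsMeta, `[[`, "", "metabolite"),
    metameter = vapply(rowsMeta, `[[`, "", "metameter"),
    effect = effects, lower = lower, upper = upper, p_adj = pAdj,
    significant = ifelse(is.na(lower), NA, lower > 0 | upper < 0),
    n_used = nUsed,
    n_left = vapply(rowsMeta, function(r) as.integer(r$n_left), 1L),
    n_interval = vapply(rowsMeta, function(r) as.integer(r$n_interval), 1L),
    converged = conv, row.names = NULL, stringsAsFactors = FALSE)

  settings <- list(exposure = exposure, adjust = adjust, order = order,
                   link = link, level = level, includeLog = includeLog,
                   logBase = logBase, tiePolicy = tiePolicy,
                   supportMargin = supportMargin, seed = seed,
                   family = family, metameters = mm@metameters,
                   nSamples = length(ids), nMetabolites = p)
  new("ScanResult", table = tab, settings = settings, skips = skips,
      joint = joint, fits = if (keepFits) fits else list())
}

#' @describeIn metaboScan samples-by-metabolites matrix plus a metadata
#'   data.frame (row names are sample IDs in both; joined on the
#'   intersection of IDs, never positionally).
#' @param metadata data.frame of per-sample covariates, row names are
#'   sample IDs.
#' @param exposure name of the metadata column holding the variable of
#'   interest (must be numeric, and positive when the logarithmic metameter
#'   is enabled).
#' @param adjust character vector of metadata columns entering every model
#'   as additional linear shift terms (e.g. \code{"bmi"}); only the
#'   metameter coefficient is tested.
#' @param loqMap named numeric vector of per-metabolite limits of
#'   quantification.
#' @param order Bernstein order of the baseline transformations (default 6).
#' @param link error distribution, \code{"probit"} (default) or
#'   \code{"logit"}.
#' @param level simultaneous confidence level (default 0.95).
#' @param includeLog fit the logarithmic metameter as well (default TRUE).
#' @param logBase base of the logarithmic metameter (default natural).
#' @param tiePolicy \code{"interval"} (default) or \code{"none"}, see
#'   [encodeResponse()].
#' @param supportMargin support extension fraction, see [defaultSupport()].
#' @param seed seed for the quasi-Monte-Carlo quadrature of the joint
#'   inference; the scan is deterministic given the seed.
#' @param family \code{"all"} (default): one joint max-t family across all
#'   2p models, both metameters together; \code{"per-metameter"}: separate
#'   families per metameter.
#' @param keepFits retain the per-model [TransformationFit-class] objects in
#'   the result (default FALSE).
#' @export
setMethod("metaboScan", "matrix",
  function(abundance, metadata, exposure = "age", adjust = character(),
           loqMap = NULL, order = 6L, link = c("probit", "logit"),
           level = 0.95, includeLog = TRUE, logBase = exp(1),
           tiePolicy = c("interval", "none"), supportMargin = 0.1,
           seed = 20230101, family = c("all", "per-metameter"),
           keepFits = FALSE) {
    .scanCore(abundance, metadata, exposure = exposure, adjust = adjust,
              loqMap = loqMap, order = order, link = link, level = level,
              includeLog = includeLog, logBase = logBase,
              tiePolicy = tiePolicy, supportMargin = supportMargin,
              seed = seed, family = family, keepFits = keepFits)
  })

#' @describeIn metaboScan data.frame of abundances (converted to a matrix).
#' @export
setMethod("metaboScan", "data.frame",
  function(abundance, metadata, ...) {
    m <- as.matrix(abundance)
    storage.mode(m) <- "double"
    .scanCore(m, metadata, ...)
  })

#' @describeIn metaboScan \code{SummarizedExperiment} with metabolites in
#'   rows and samples in columns; the metadata is taken from
#'   \code{colData}.
#' @param assayName which assay to scan (default the first).
#' @export
setMethod("metaboScan", "SummarizedExperiment",
  function(abundance, exposure = "age", assayName = 1L, ...) {
    m <- t(SummarizedExperiment::assay(abundance, assayName))
    meta <- as.data.frame(SummarizedExperiment::colData(abundance))
    .scanCore(m, meta, exposure = exposure, ...)
  })

#' @rdname resultsTable
setMethod("resultsTable", "ScanResult", function(object) object@table)

#' Skipped metabolites of a scan
#'
#' @param object a [ScanResult-class].
#' @return data.frame with columns \code{metabolite} and \code{reason}; each
#'   skipped metabolite accounts for one row per metameter that was not
#'   fitted.
#' @export
scanSkips <- function(object) {
  stopifnot(is(object, "ScanResult"))
  object@skips
}

#' Write scan results to CSV
#'
#' Writes the results table with exactly the columns \code{metabolite,
#' metameter, effect, lower, upper, p_adj, significant, n_used, n_left,
#' n_interval, converged}.  Re-running the same scan configuration
#' byte-reproduces the file.
#'
#' @param object a [ScanResult-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScanResults <- function(object, path) {
  stopifnot(is(object, "ScanResult"))
  utils::write.csv(object@table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

setMethod("show", "ScanResult", function(object) {
  tab <- object@table
  cat("ScanResult:", object@settings$nMetabolites, "metabolites x",
      length(object@settings$metameters), "metameters (",
      object@settings$nSamples, "samples )\n")
  cat("  link:", object@settings$link, " order:", object@settings$order,
      " level:", object@settings$level, "\n")
  nsig <- sum(tab$significant, na.rm = TRUE)
  cat("  significant model rows:", nsig, "of", nrow(tab), "\n")
  if (nrow(object@skips))
    cat("  skipped metabolites:", nrow(object@skips), "\n")
})
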
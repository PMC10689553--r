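#' Encode a raw metabolite column as censored response data
#'
#' Implements the two encoding rules of the scan.  (1) Values at or below the
#' limit of quantification (LOQ) are not measurements but statements "at most
#' LOQ", and become left-censored observations whose likelihood contribution
#' is the CDF at the limit.  (2) Tied values -- identical recorded numbers,
#' typically produced by limited measurement precision -- are broken by
#' treating each tie as an interval observation: the recorded number is read
#' as a rounding of the truth, so the observation is placed in the interval
#' between the midpoints to the adjacent distinct observed values (the
#' outermost tied values extend outward by half the nearest inter-value gap).
#' All remaining values are exact.  Missing entries are kept as explicit
#' markers and never silently dropped.
#'
#' @param raw numeric vector with NA for missing values.
#' @param loq optional finite numeric(1); every non-missing value \code{v}
#'   with \code{v <= loq} becomes left-censored at \code{loq} ("reported at
#'   the LOQ" conventionally means at or below it).
#' @param tiePolicy \code{"interval"} (default: any duplicated non-censored
#'   value becomes an interval observation) or \code{"none"} (ties stay
#'   exact).
#' @param supportMargin fraction of the observed anchor range by which the
#'   support extends beyond the extreme anchors on each side (default 0.1);
#'   see [defaultSupport()].
#' @param name metabolite identifier used in messages.
#' @param sampleIDs optional character vector of sample identifiers.
#' @return a [CensoredResponse-class].
#' @examples
#' encodeResponse(c(1, 2, 2, 3), name = "demo")   # the 2's become (1.5, 2.5]
#' @export
encodeResponse <- function(raw, loq = NA_real_,
                           tiePolicy = c("interval", "none"),
                           supportMargin = 0.1, name = "Y",
                           sampleIDs = NULL) {
  tiePolicy <- match.arg(tiePolicy)
  raw <- as.numeric(raw)
  n <- length(raw)
  if (is.null(sampleIDs)) sampleIDs <- as.character(seq_len(n))
  stopifnot(length(sampleIDs) == n)
  miss <- !is.finite(raw)
  if (sum(!miss) < 3L)
    stop("degenerate response '", name, "': fewer than 3 non-missing values")
  if (!is.na(loq) && !is.finite(loq))
    stop("loq for '", name, "' must be finite")

  kind <- ifelse(miss, "missing", "exact")
  value <- ifelse(miss, NA_real_, raw)
  bound <- rep(NA_real_, n); lo <- rep(NA_real_, n); up <- rep(NA_real_, n)

  if (!is.na(loq)) {
    cens <- !miss & raw <= loq
    if (max(raw[!miss]) <= loq)
      stop("degenerate response '", name,
           "': all observed values are at or below the LOQ (", loq, ")")
    kind[cens] <- "left"
    bound[cens] <- loq
    value[cens] <- NA_real_
  }

  obs <- kind == "exact"
  uniq <- sort(unique(raw[obs]))
  if (length(uniq) < 2L)
    stop("degenerate response '", name,
         "': a single distinct uncensored value")

  if (tiePolicy == "interval") {
    vals <- raw[obs]
    tied <- sort(unique(vals[duplicated(vals)]))
    if (length(tied)) {
      K <- length(uniq)
      ## midpoints between adjacent distinct values; half-gap at the extremes
      loOf <- function(u) {
        k <- match(u, uniq)
        if (k > 1) (uniq[k - 1] + u) / 2 else u - (uniq[2] - uniq[1]) / 2
      }
      upOf <- function(u) {
        k <- match(u, uniq)
        if (k < K) (u + uniq[k + 1]) / 2 else u + (uniq[K] - uniq[K - 1]) / 2
      }
      for (u in tied) {
        idx <- obs & raw == u
        kind[idx] <- "interval"
        lo[idx] <- loOf(u); up[idx] <- upOf(u)
        value[idx] <- NA_real_
      }
    }
  }

  anchors <- c(value[kind == "exact"], bound[kind == "left"],
               lo[kind == "interval"], up[kind == "interval"])
  supp <- defaultSupport(anchors, margin = supportMargin)

  new("CensoredResponse", name = name, kind = kind, value = value,
      bound = bound, lower = lo, upper = up,
      loq = as.numeric(loq), support = supp, sampleIDs = sampleIDs)
}

#' Default support for a transformation basis
#'
#' The observed anchor range (exact values, censoring bounds, interval
#' endpoints) extended symmetrically by a fraction of that range, so the
#' Bernstein transformation has room beyond the extreme observations.
#'
#' @param values numeric vector of anchor points (NAs dropped).
#' @param margin non-negative fraction of the observed range added on each
#'   side (default 0.1).
#' @return numeric(2), the support \code{(a, b)} with \code{a < b}.
#' @examples
#' defaultSupport(c(10, 20))          # c(9, 21)
#' @export
defaultSupport <- function(values, margin = 0.1) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || length(unique(values)) < 2L)
    stop("need at least 2 distinct finite anchor points for a support")
  stopifnot(margin >= 0)
  r <- range(values)
  w <- diff(r)
  if (w <= 0) stop("zero range: cannot build a support")
  c(r[1] - margin * w, r[2] + margin * w)
}

#' @rdname kindCounts
setMethod("kindCounts", "CensoredResponse", function(object) {
  k <- factor(object@kind, levels = c("exact", "left", "interval", "missing"))
  cnt <- table(k)
  stats::setNames(as.integer(cnt), names(cnt))
})

#' @rdname nObs
setMethod("nObs", "CensoredResponse", function(object)
  length(object@kind))

#' @rdname support
setMethod("support", "CensoredResponse", function(object) object@support)

#' @rdname asSurv
setMethod("asSurv", "CensoredResponse", function(object) {
  keep <- object@kind != "missing"
  k <- object@kind[keep]
  t1 <- ifelse(k == "exact", object@value[keep],
        ifelse(k == "left", object@bound[keep], object@lower[keep]))
  t2 <- ifelse(k == "exact", object@value[keep],
        ifelse(k == "left", NA_real_, object@upper[keep]))
  ## interval2: (NA, b] is left-censored, [v, v] exact, (l, u] interval
  t1[k == "left"] <- NA_real_
  t2[k == "left"] <- object@bound[keep][k == "left"]
  survival::Surv(time = t1, time2 = t2, type = "interval2")
})

#' Limit of quantification of an encoded response
#'
#' @param object a [CensoredResponse-class].
#' @return numeric(1), the LOQ, or NA when none applies.
#' @export
responseLoq <- function(object) {
  stopifnot(is(object, "CensoredResponse"))
  object@loq
}

#' Observation kinds of an encoded response
#'
#' @param object a [CensoredResponse-class].
#' @return character vector, per-sample kind ("exact", "left", "interval",
#'   "missing") aligned with the sample ordering.
#' @export
responseKinds <- function(object) {
  stopifnot(is(object, "CensoredResponse"))
  stats::setNames(object@kind, object@sampleIDs)
}

setMethod("show", "CensoredResponse", function(object) {
  cnt <- kindCounts(object)
  cat("CensoredResponse '", object@name, "': ", length(object@kind),
      " samples (", cnt["exact"], " exact, ", cnt["left"],
      " left-censored, ", cnt["interval"], " interval, ", cnt["missing"],
      " missing)\n", sep = "")
  if (!is.na(object@loq)) cat("  LOQ:", object@loq, "\n")
  cat("  support: [", format(object@support[1]), ",",
      format(object@support[2]), "]\n")
})
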
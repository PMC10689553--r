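#' Construct a Bernstein basis
#'
#' @param order integer, polynomial order \code{M >= 1} (default 6, a common
#'   choice flexible enough for smooth monotone transformations while keeping
#'   the per-model parameter count small).
#' @param support numeric(2), the bounded interval \code{(a, b)} on which the
#'   transformation is defined; typically the observed range of a metabolite
#'   extended by a margin, see [defaultSupport()].
#' @return a [BernsteinBasis-class].
#' @examples
#' bb <- bernsteinBasis(3, c(0, 1))
#' basisEval(bb, 0.25)
#' @export
bernsteinBasis <- function(order = 6L, support) {
  new("BernsteinBasis", order = as.integer(order),
      support = as.numeric(support))
}

## clamp y into [a, b] within a small slack, error beyond it
.clampSupport <- function(y, support) {
  a <- support[1]; b <- support[2]
  eps <- 1e-9 * max(1, b - a)
  if (any(!is.finite(y)) || any(y < a - eps) || any(y > b + eps))
    stop("evaluation point outside the basis support [", a, ", ", b, "]")
  pmin(pmax(y, a), b)
}

#' @rdname basisEval
setMethod("basisEval", "BernsteinBasis", function(object, y) {
  M <- object@order
  y <- .clampSupport(y, object@support)
  z <- (y - object@support[1]) / diff(object@support)
  k <- 0:M
  B <- outer(z, k, function(zz, kk)
    choose(M, kk) * zz^kk * (1 - zz)^(M - kk))
  dimnames(B) <- NULL
  B
})

#' @rdname basisDeriv
setMethod("basisDeriv", "BernsteinBasis", function(object, y) {
  M <- object@order
  y <- .clampSupport(y, object@support)
  w <- diff(object@support)
  z <- (y - object@support[1]) / w
  D <- matrix(0, length(z), M + 1L)
  ## d/dy B_{k,M} = M/(b-a) * (B_{k-1,M-1} - B_{k,M-1})
  for (kk in 0:M) {
    t1 <- if (kk >= 1) choose(M - 1, kk - 1) * z^(kk - 1) * (1 - z)^(M - kk) else 0
    t2 <- if (kk <= M - 1) choose(M - 1, kk) * z^kk * (1 - z)^(M - 1 - kk) else 0
    D[, kk + 1L] <- (M / w) * (t1 - t2)
  }
  D
})

#' @rdname transformEval
setMethod("transformEval", "BernsteinBasis", function(object, theta, y) {
  stopifnot(length(theta) == object@order + 1L)
  drop(basisEval(object, y) %*% theta)
})

#' @rdname transformEval
setMethod("transformDeriv", "BernsteinBasis", function(object, theta, y) {
  stopifnot(length(theta) == object@order + 1L)
  drop(basisDeriv(object, y) %*% theta)
})

#' @rdname support
setMethod("support", "BernsteinBasis", function(object) object@support)

#' Monotone coefficient parameterization
#'
#' Non-decreasing Bernstein coefficients are parameterized by an
#' unconstrained vector via positive increments:
#' \code{theta = cumsum(c(gamma[1], exp(gamma[-1])))}.  This keeps the
#' transformation weakly monotone for every unconstrained \code{gamma}, which
#' is what the optimizer works on.
#'
#' @param gamma unconstrained numeric vector.
#' @return \code{thetaFromGamma}: the non-decreasing coefficient vector.
#' @examples
#' th <- thetaFromGamma(c(-1, 0, 0.5))
#' all.equal(gammaFromTheta(th), c(-1, 0, 0.5))
#' @export
thetaFromGamma <- function(gamma) {
  stopifnot(length(gamma) >= 1L)
  cumsum(c(gamma[1], exp(gamma[-1])))
}

#' @rdname thetaFromGamma
#' @param theta non-decreasing numeric vector with strictly positive
#'   increments (a zero increment has no finite unconstrained image).
#' @return \code{gammaFromTheta}: the unconstrained vector.
#' @export
gammaFromTheta <- function(theta) {
  d <- diff(theta)
  if (any(d <= 0))
    stop("theta must be strictly increasing to map back to gamma")
  c(theta[1], log(d))
}

setMethod("show", "BernsteinBasis", function(object) {
  cat("BernsteinBasis of order", object@order, "on [",
      format(object@support[1]), ",", format(object@support[2]), "]\n")
})
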
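#' Configure the synthetic metabolome generator
#'
#' Defaults describe a null metabolome measured on an age-like cohort:
#' exposure uniform on 18--80 years, all effects zero, identity distortions,
#' no censoring, ties or missingness, independent metabolites.  Every
#' structural feature of real metabolomics tables the scan must cope with
#' (monotone scale distortions, limit-of-quantification censoring,
#' rounding ties, correlated blocks, missing values) is switched on through
#' the corresponding argument.
#'
#' @param n,p samples and metabolites.
#' @param beta numeric(p) true latent effects on the standard-normal latent
#'   scale, per unit of the effect metameter (default all zero); recycled.
#' @param effectShape \code{"arithmetic"} (effect linear in the exposure) or
#'   \code{"logarithmic"} (linear in log exposure); recycled.
#' @param distortion monotone map from the latent scale to the reported
#'   abundance scale: \code{"identity"}, \code{"exp"}, \code{"cube"} or
#'   \code{"logistic"}; recycled.
#' @param censorFrac fraction of values reported at the per-metabolite
#'   limit of quantification (its empirical quantile), in [0, 1).
#' @param roundDecimals decimals each metabolite is rounded to (NA = no
#'   rounding; rounding creates ties); recycled.
#' @param blockSize,blockRho metabolites are grouped into consecutive
#'   blocks of \code{blockSize} whose latent errors are equicorrelated with
#'   correlation \code{blockRho}.
#' @param missingFrac fraction of cells set missing completely at random.
#' @param exposureRange uniform range of the exposure (default 18--80).
#' @param seed integer seed; generation is reproducible.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(n, p, beta = 0, effectShape = "arithmetic",
                      distortion = "identity", censorFrac = 0,
                      roundDecimals = NA_real_, blockSize = 1L,
                      blockRho = 0, missingFrac = 0,
                      exposureRange = c(18, 80), seed = 1L) {
  new("SimConfig", n = as.integer(n), p = as.integer(p),
      beta = rep_len(as.numeric(beta), p),
      effectShape = rep_len(effectShape, p),
      distortion = rep_len(distortion, p),
      censorFrac = censorFrac,
      roundDecimals = rep_len(as.numeric(roundDecimals), p),
      blockSize = as.integer(blockSize), blockRho = blockRho,
      missingFrac = missingFrac, exposureRange = as.numeric(exposureRange),
      seed = as.numeric(seed))
}

.distortionFun <- function(name) {
  switch(name,
    identity = list(g = function(z) z, inv = function(y) y),
    exp      = list(g = function(z) exp(z), inv = function(y) log(y)),
    cube     = list(g = function(z) z^3,
                    inv = function(y) sign(y) * abs(y)^(1 / 3)),
    logistic = list(g = function(z) stats::plogis(z),
                    inv = function(y) stats::qlogis(y)),
    stop("unknown distortion '", name, "'"))
}

#' Generate a synthetic metabolome dataset with known ground truth
#'
#' Draws an exposure \eqn{X \sim U(a, b)}, latent Gaussian regressions
#' \eqn{Z_i = \beta_i m_i(X) + \varepsilon_i} with block-equicorrelated
#' standard-normal errors and \eqn{m_i} the identity or the natural log,
#' then maps each latent column through a heterogeneous positive scale and
#' the configured monotone distortion, and finally applies rounding (ties),
#' limit-of-quantification truncation (values at or below the
#' \code{censorFrac} quantile are reported at it) and a missingness mask.
#' The truth record keeps everything needed to verify recovery: the true
#' effects, shapes, distortions, scales, the per-metabolite LOQs and the
#' latent matrix.
#'
#' @param config a [SimConfig-class].
#' @return list with elements \code{abundance} (samples-by-metabolites
#'   matrix with IDs), \code{metadata} (data.frame with \code{age} and an
#'   independent \code{bmi} column for adjustment exercises) and
#'   \code{truth} (list: \code{beta}, \code{effectShape}, \code{distortion},
#'   \code{scale}, \code{loq}, \code{latent}, \code{exposure}).
#' @examples
#' d <- simulateMetabolome(simConfig(n = 50, p = 3, seed = 7))
#' dim(d$abundance)
#' @export
simulateMetabolome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@n; p <- config@p
  .withSeed(config@seed, {
    x <- stats::runif(n, config@exposureRange[1], config@exposureRange[2])
    bmi <- stats::runif(n, 19, 35)
    ## block-equicorrelated standard normal errors
    blk <- rep(seq_len(ceiling(p / config@blockSize)),
               each = config@blockSize)[seq_len(p)]
    shared <- matrix(stats::rnorm(n * max(blk)), n, max(blk))
    eps <- sqrt(config@blockRho) * shared[, blk, drop = FALSE] +
      sqrt(1 - config@blockRho) * matrix(stats::rnorm(n * p), n, p)
    scl <- exp(stats::runif(p, log(0.5), log(50)))   # heterogeneous scales
    Z <- matrix(0, n, p)
    Y <- matrix(0, n, p)
    for (j in seq_len(p)) {
      m <- if (config@effectShape[j] == "arithmetic") x else log(x)
      Z[, j] <- config@beta[j] * m + eps[, j]
      Y[, j] <- scl[j] * .distortionFun(config@distortion[j])$g(Z[, j])
    }
    ids <- sprintf("S%03d", seq_len(n))
    mets <- sprintf("M%02d", seq_len(p))
    dimnames(Y) <- list(ids, mets)
    dimnames(Z) <- list(ids, mets)

    for (j in seq_len(p))
      if (is.finite(config@roundDecimals[j]))
        Y[, j] <- round(Y[, j], config@roundDecimals[j])

    loq <- stats::setNames(rep(NA_real_, p), mets)
    if (config@censorFrac > 0) {
      for (j in seq_len(p)) {
        loq[j] <- stats::quantile(Y[, j], config@censorFrac, names = FALSE)
        Y[Y[, j] <= loq[j], j] <- loq[j]    # reported at the LOQ
      }
    }
    if (config@missingFrac > 0)
      Y[matrix(stats::runif(n * p) < config@missingFrac, n, p)] <- NA_real_

    list(
      abundance = Y,
      metadata = data.frame(age = x, bmi = bmi, row.names = ids),
      truth = list(beta = stats::setNames(config@beta, mets),
                   effectShape = stats::setNames(config@effectShape, mets),
                   distortion = stats::setNames(config@distortion, mets),
                   scale = stats::setNames(scl, mets),
                   loq = loq, latent = Z, exposure = x))
  })
}

#' Invert a simulated distortion
#'
#' Maps uncensored, unrounded abundances back to the latent Gaussian scale;
#' used to verify that the configured distortions are bijective and
#' monotone on the generated range.
#'
#' @param y numeric vector of abundances of one metabolite.
#' @param distortion its distortion name.
#' @param scale its heterogeneous scale factor (\code{truth$scale}).
#' @return numeric vector on the latent scale.
#' @export
invertDistortion <- function(y, distortion, scale = 1) {
  .distortionFun(distortion)$inv(y / scale)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n, "samples x", object@p, "metabolites\n")
  cat("  non-null effects:", sum(object@beta != 0),
      " censorFrac:", object@censorFrac,
      " blockRho:", object@blockRho,
      " missingFrac:", object@missingFrac, "\n")
  cat("  exposure ~ U(", object@exposureRange[1], ",",
      object@exposureRange[2], "), seed", object@seed, "\n")
})
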
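#' @import methods
NULL

#' Bernstein polynomial basis on a bounded support
#'
#' A Bernstein basis of order \code{M} on the interval \code{[a, b]} spans the
#' polynomials of degree \code{M}; with non-decreasing coefficients it
#' parameterizes a monotone non-decreasing baseline transformation
#' \eqn{h(y) = \sum_k \theta_k b_k(y)}.  The basis dimension is \code{M + 1}.
#'
#' @slot order integer, polynomial order \code{M >= 1}.
#' @slot support numeric(2), the interval \code{(a, b)} with \code{a < b};
#'   evaluation outside the support (beyond a small numerical slack) is an
#'   error.
#'
#' @seealso [bernsteinBasis()], [basisEval()], [transformEval()]
#' @export
setClass("BernsteinBasis",
  representation(order = "integer", support = "numeric"))

setValidity("BernsteinBasis", function(object) {
  msg <- character()
  if (length(object@order) != 1L || is.na(object@order) || object@order < 1L)
    msg <- c(msg, "'order' must be a single integer >= 1")
  if (length(object@support) != 2L || anyNA(object@support) ||
      any(!is.finite(object@support)))
    msg <- c(msg, "'support' must be two finite numbers")
  else if (object@support[1] >= object@support[2])
    msg <- c(msg, "'support' must satisfy a < b")
  if (length(msg)) msg else TRUE
})

#' One metabolite's observations as exact, left-censored or interval data
#'
#' Container for a single metabolite column after encoding: every sample is
#' exactly one of exact, left-censored at the limit of quantification (LOQ),
#' interval-censored (a tie broken into the interval between the midpoints to
#' the adjacent distinct observed values), or missing.  Missing entries are
#' kept as explicit markers so that all responses of a scan stay aligned to
#' one global sample ordering.
#'
#' @slot name character(1), metabolite identifier.
#' @slot kind character vector, one of \code{"exact"}, \code{"left"},
#'   \code{"interval"}, \code{"missing"} per sample.
#' @slot value numeric, the observed value for exact entries (NA otherwise).
#' @slot bound numeric, the censoring point (the LOQ) for left entries.
#' @slot lower,upper numeric, interval endpoints (\code{lower < upper}) for
#'   interval entries.
#' @slot loq numeric(1), the limit of quantification or NA if none.
#' @slot support numeric(2), a bounded interval containing every exact value,
#'   bound and interval endpoint; passed on to the Bernstein basis.
#' @slot sampleIDs character, sample identifiers aligned with the entries.
#'
#' @seealso [encodeResponse()], [kindCounts()], [asSurv()]
#' @export
setClass("CensoredResponse",
  representation(name = "character", kind = "character", value = "numeric",
    bound = "numeric", lower = "numeric", upper = "numeric",
    loq = "numeric", support = "numeric", sampleIDs = "character"))

setValidity("CensoredResponse", function(object) {
  n <- length(object@kind)
  msg <- character()
  if (!all(object@kind %in% c("exact", "left", "interval", "missing")))
    msg <- c(msg, "unknown observation kind")
  if (length(object@value) != n || length(object@bound) != n ||
      length(object@lower) != n || length(object@upper) != n ||
      length(object@sampleIDs) != n)
    msg <- c(msg, "all per-sample slots must have equal length")
  else {
    e <- object@kind == "exact"; l <- object@kind == "left"
    iv <- object@kind == "interval"
    if (any(!is.finite(object@value[e])))
      msg <- c(msg, "exact entries need a finite value")
    if (any(!is.finite(object@bound[l])))
      msg <- c(msg, "left-censored entries need a finite bound")
    if (any(!is.finite(object@lower[iv])) || any(!is.finite(object@upper[iv])) ||
        any(object@lower[iv] >= object@upper[iv]))
      msg <- c(msg, "interval entries need finite lower < upper")
    a <- object@support[1]; b <- object@support[2]
    if (length(object@support) != 2L || !all(is.finite(object@support)) ||
        a >= b)
      msg <- c(msg, "'support' must be two finite numbers with a < b")
    else {
      anchors <- c(object@value[e], object@bound[l], object@lower[iv],
                   object@upper[iv])
      if (length(anchors) && (min(anchors) < a || max(anchors) > b))
        msg <- c(msg, "support must contain every value, bound and endpoint")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Arithmetic and logarithmic metameters of the variable of interest
#'
#' The variable of interest (e.g. age) is entered into the per-metabolite
#' models both unmodified ("arithmetic") and log-transformed ("logarithmic"),
#' so that linear and logarithmic dose-response shapes are both represented.
#' No centering or scaling is applied: effects are reported per raw unit of
#' each metameter.
#'
#' @slot metameters character, column labels (default
#'   \code{c("arithmetic", "logarithmic")}).
#' @slot columns numeric matrix, samples by metameters.
#' @slot sourceName character(1), name of the untransformed variable.
#'
#' @seealso [makeMetameters()]
#' @export
setClass("MetameterSet",
  representation(metameters = "character", columns = "matrix",
    sourceName = "character"))

setValidity("MetameterSet", function(object) {
  if (ncol(object@columns) != length(object@metameters))
    return("number of columns must match number of metameter labels")
  if (any(!is.finite(object@columns)))
    return("metameter columns must be finite")
  TRUE
})

#' Specification of one transformation regression model
#'
#' @slot link character(1), \code{"probit"} (standard normal errors, the
#'   default Box-Cox-type model) or \code{"logit"} (standard logistic errors,
#'   i.e. continuous outcome logistic regression whose shift coefficients are
#'   log-odds ratios valid at every response cutoff).
#' @slot order integer(1), Bernstein order of the baseline transformation.
#' @slot covariates character, names of the shift covariates; the first one
#'   is the metameter column whose coefficient is tested downstream.
#'
#' @seealso [modelSpec()], [fitTransformModel()]
#' @export
setClass("ModelSpec",
  representation(link = "character", order = "integer",
    covariates = "character"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (!object@link %in% c("probit", "logit"))
    msg <- c(msg, "link must be 'probit' or 'logit'")
  if (length(object@order) != 1L || object@order < 1L)
    msg <- c(msg, "order must be a single integer >= 1")
  if (length(object@covariates) < 1L)
    msg <- c(msg, "at least one shift covariate is required")
  if (length(msg)) msg else TRUE
})

#' A fitted transformation regression model
#'
#' Maximum-likelihood fit of \eqn{P(Y \le y \mid x) = F_\varepsilon(h(y) -
#' x'\beta)} with \eqn{h} parameterized in a monotone Bernstein basis.
#' Positive \eqn{\beta} means larger covariate values shift the metabolite
#' upward.  Per-observation score contributions and the observed information
#' are stored for multiple-marginal-models covariance estimation; rows of the
#' score matrix corresponding to samples not used by this model (missing
#' response or covariate) are identically zero.
#'
#' @slot basis the [BernsteinBasis-class] used for \eqn{h}.
#' @slot link character(1), error distribution ("probit" or "logit").
#' @slot gamma numeric, unconstrained transformation parameters.
#' @slot theta numeric, non-decreasing Bernstein coefficients
#'   (\code{theta = cumsum(c(gamma[1], exp(gamma[-1])))}).
#' @slot beta named numeric, shift coefficients (metameter first).
#' @slot loglik numeric(1), maximized log-likelihood.
#' @slot scores numeric matrix, per-observation gradient contributions in
#'   \code{(gamma, beta)} coordinates, one row per sample of the global
#'   ordering (zero rows for unused samples).
#' @slot info numeric matrix, observed information at the optimum.
#' @slot converged logical(1).
#' @slot nUsed integer(1), number of observations entering the likelihood.
#' @slot sampleMask logical, which samples of the global ordering were used.
#' @slot message character(1), diagnostic note for flagged fits.
#'
#' @seealso [fitTransformModel()], [scoreMatrix()], [jointCovariance()]
#' @export
setClass("TransformationFit",
  representation(basis = "BernsteinBasis", link = "character",
    gamma = "numeric", theta = "numeric", beta = "numeric",
    loglik = "numeric", scores = "matrix", info = "matrix",
    converged = "logical", nUsed = "integer", sampleMask = "logical",
    message = "character"))

#' Joint max-t inference across marginal models
#'
#' Holds the stacked effects, their sandwich standard errors, the estimated
#' correlation matrix of the tested statistics, the equicoordinate critical
#' value, simultaneous confidence intervals and single-step adjusted
#' p-values.
#'
#' @slot labels character, one label per model.
#' @slot effects,se,tstat numeric vectors, per model.
#' @slot R numeric matrix, correlation of the tested coefficients.
#' @slot crit numeric(1), the equicoordinate critical value \eqn{c_\alpha}.
#' @slot level numeric(1), simultaneous coverage level (default 0.95).
#' @slot ciLower,ciUpper numeric vectors, simultaneous limits
#'   \eqn{\hat\beta_j \pm c_\alpha \cdot se_j}.
#' @slot pAdj numeric vector, single-step adjusted p-values.
#' @slot seed numeric(1), seed of the quasi-Monte-Carlo quadrature.
#' @slot mcError numeric(1), largest reported Monte-Carlo error among the
#'   rectangle probabilities used.
#'
#' @seealso [maxTInference()]
#' @export
setClass("JointInference",
  representation(labels = "character", effects = "numeric", se = "numeric",
    tstat = "numeric", R = "matrix", crit = "numeric", level = "numeric",
    ciLower = "numeric", ciUpper = "numeric", pAdj = "numeric",
    seed = "numeric", mcError = "numeric"))

#' Result of a metabolome-wide association scan
#'
#' One row per attempted (metabolite, metameter) pair with the effect, the
#' simultaneous confidence limits, the adjusted p-value, the significance
#' flag (interval excluding zero) and the encoding bookkeeping; plus a
#' settings snapshot, a table of skipped metabolites with reasons, and the
#' underlying [JointInference-class].
#'
#' @slot table data.frame with columns \code{metabolite, metameter, effect,
#'   lower, upper, p_adj, significant, n_used, n_left, n_interval,
#'   converged}.
#' @slot settings list, full configuration snapshot (order, link, level,
#'   seed, support margin, tie policy, metameters, family).
#' @slot skips data.frame with columns \code{metabolite, reason}.
#' @slot joint the [JointInference-class] over all converged models, or NULL.
#' @slot fits list of [TransformationFit-class] objects when requested.
#'
#' @seealso [metaboScan()], [resultsTable()], [forestPlot()]
#' @export
setClass("ScanResult",
  representation(table = "data.frame", settings = "list",
    skips = "data.frame", joint = "ANY", fits = "list"))

#' Configuration of the synthetic metabolome generator
#'
#' Describes a synthetic dataset with the statistical structure the scan
#' assumes: an age-like continuous exposure, per-metabolite monotone
#' distortions of a latent Gaussian regression, block-equicorrelated errors,
#' limit-of-quantification left-censoring, rounding-induced ties and missing
#' values, with the ground truth recorded.
#'
#' @slot n,p integer, samples and metabolites.
#' @slot beta numeric(p), true latent effects (0 = null), on the standard
#'   normal latent scale per unit of the effect metameter.
#' @slot effectShape character(p), \code{"arithmetic"} or
#'   \code{"logarithmic"} dependence on the exposure.
#' @slot distortion character(p), monotone map applied to the latent scale:
#'   \code{"identity"}, \code{"exp"}, \code{"cube"} or \code{"logistic"}.
#' @slot censorFrac numeric(1) in [0,1), fraction of values reported at the
#'   limit of quantification (the per-metabolite empirical quantile).
#' @slot roundDecimals numeric(p), decimals to round each metabolite to
#'   (NA = no rounding); rounding creates ties.
#' @slot blockSize integer(1), size of equicorrelated metabolite blocks.
#' @slot blockRho numeric(1), within-block error correlation.
#' @slot missingFrac numeric(1) in [0,1).
#' @slot exposureRange numeric(2), uniform range of the exposure (age-like
#'   default 18--80 years).
#' @slot seed numeric(1).
#'
#' @seealso [simConfig()], [simulateMetabolome()]
#' @export
setClass("SimConfig",
  representation(n = "integer", p = "integer", beta = "numeric",
    effectShape = "character", distortion = "character",
    censorFrac = "numeric", roundDecimals = "numeric",
    blockSize = "integer", blockRho = "numeric", missingFrac = "numeric",
    exposureRange = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  p <- object@p
  if (p < 1L) msg <- c(msg, "p must be >= 1")
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (length(object@beta) != p || length(object@effectShape) != p ||
      length(object@distortion) != p || length(object@roundDecimals) != p)
    msg <- c(msg, "beta, effectShape, distortion, roundDecimals must have length p")
  if (!all(object@effectShape %in% c("arithmetic", "logarithmic")))
    msg <- c(msg, "effectShape must be 'arithmetic' or 'logarithmic'")
  if (!all(object@distortion %in% c("identity", "exp", "cube", "logistic")))
    msg <- c(msg, "unknown distortion")
  if (object@censorFrac < 0 || object@censorFrac >= 1)
    msg <- c(msg, "censorFrac must be in [0, 1)")
  if (object@missingFrac < 0 || object@missingFrac >= 1)
    msg <- c(msg, "missingFrac must be in [0, 1)")
  if (object@blockRho < 0 || object@blockRho >= 1)
    msg <- c(msg, "blockRho must be in [0, 1)")
  if (object@exposureRange[1] <= 0 || diff(object@exposureRange) <= 0)
    msg <- c(msg, "exposureRange must be positive and increasing")
  if (length(msg)) msg else TRUE
})
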
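#' Construct a model specification
#'
#' @param link error distribution: \code{"probit"} (standard normal, the
#'   default Box-Cox-type transformation model) or \code{"logit"} (standard
#'   logistic; continuous outcome logistic regression, whose shift
#'   coefficients are log-odds ratios valid at every response cutoff).
#' @param order Bernstein order of the baseline transformation (default 6).
#' @param covariates character, names of the shift covariates; the first is
#'   the tested (metameter) coefficient.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(link = c("probit", "logit"), order = 6L,
                      covariates = "x") {
  link <- match.arg(link)
  new("ModelSpec", link = link, order = as.integer(order),
      covariates = covariates)
}

## error-distribution primitives; all vectorized and tail-stable
.linkFuns <- function(link) {
  if (link == "probit")
    list(
      logF = function(z) stats::pnorm(z, log.p = TRUE),
      logS = function(z) stats::pnorm(z, lower.tail = FALSE, log.p = TRUE),
      logf = function(z) stats::dnorm(z, log = TRUE),
      f    = function(z) stats::dnorm(z),
      dlogf = function(z) -z,
      probit = TRUE)
  else
    list(
      logF = function(z) stats::plogis(z, log.p = TRUE),
      logS = function(z) stats::plogis(z, lower.tail = FALSE, log.p = TRUE),
      logf = function(z) stats::dlogis(z, log = TRUE),
      f    = function(z) stats::dlogis(z),
      dlogf = function(z) 1 - 2 * stats::plogis(z),
      probit = FALSE)
}

## log(exp(la) - exp(lb)) for la >= lb, stable in the tails
.logDiffExp <- function(la, lb) {
  d <- lb - la
  d[d > -1e-15] <- -1e-15
  la + log1p(-exp(d))
}

.LOGFLOOR <- -700          # -Inf-safe floor for underflowing contributions

## Assemble everything the likelihood needs once per (response, X) pair:
## basis matrices per observation kind and aligned covariate rows.
.prepareModelData <- function(response, X, basis) {
  n <- nObs(response)
  X <- as.matrix(X)
  if (nrow(X) != n)
    stop("covariate matrix rows (", nrow(X),
         ") are misaligned with the response (", n, " samples)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  used <- response@kind != "missing" & stats::complete.cases(X)
  if (!any(used)) stop("all observations missing")
  k <- response@kind
  iE <- which(used & k == "exact")
  iL <- which(used & k == "left")
  iI <- which(used & k == "interval")
  M1 <- basis@order + 1L
  emptyB <- matrix(0, 0L, M1)
  list(
    n = n, used = used, q = ncol(X), cn = colnames(X),
    iE = iE, iL = iL, iI = iI,
    Be  = if (length(iE)) basisEval(basis, response@value[iE]) else emptyB,
    De  = if (length(iE)) basisDeriv(basis, response@value[iE]) else emptyB,
    Bl  = if (length(iL)) basisEval(basis, response@bound[iL]) else emptyB,
    Biu = if (length(iI)) basisEval(basis, response@upper[iI]) else emptyB,
    Bil = if (length(iI)) basisEval(basis, response@lower[iI]) else emptyB,
    Xe  = X[iE, , drop = FALSE],
    Xl  = X[iL, , drop = FALSE],
    Xi  = X[iI, , drop = FALSE])
}

## per-observation log-likelihood contributions at (theta, beta)
.contribs <- function(pd, lk, theta, beta) {
  out <- list()
  if (length(pd$iE)) {
    z <- drop(pd$Be %*% theta) - drop(pd$Xe %*% beta)
    hp <- drop(pd$De %*% theta)
    out$e <- lk$logf(z) + log(pmax(hp, 1e-300))
  }
  if (length(pd$iL))
    out$l <- lk$logF(drop(pd$Bl %*% theta) - drop(pd$Xl %*% beta))
  if (length(pd$iI)) {
    xb <- drop(pd$Xi %*% beta)
    zu <- drop(pd$Biu %*% theta) - xb
    zl <- drop(pd$Bil %*% theta) - xb
    ## use the CDF side or the survival side, whichever is better conditioned
    lp <- ifelse(zu + zl <= 0,
                 .logDiffExp(lk$logF(zu), lk$logF(zl)),
                 .logDiffExp(lk$logS(zl), lk$logS(zu)))
    out$i <- pmax(lp, .LOGFLOOR)
  }
  out
}

## Jacobian chain rule: gradient wrt theta -> gradient wrt gamma
.thetaGradToGamma <- function(gth, gamma) {
  M1 <- length(gamma)
  cs <- rev(cumsum(rev(gth)))
  gg <- cs
  if (M1 > 1) gg[-1L] <- exp(gamma[-1L]) * cs[-1L]
  gg
}

## negative log-likelihood in (gamma, beta)
.negLoglik <- function(par, pd, lk, M1) {
  gamma <- par[seq_len(M1)]
  beta <- par[-seq_len(M1)]
  theta <- thetaFromGamma(gamma)
  if (any(!is.finite(theta))) return(1e10)
  ll <- sum(unlist(.contribs(pd, lk, theta, beta), use.names = FALSE))
  if (!is.finite(ll)) return(1e10)
  -ll
}

## summed gradient without materializing per-observation rows (hot path)
.negGrad <- function(par, pd, lk, M1) {
  gamma <- par[seq_len(M1)]
  beta <- par[-seq_len(M1)]
  theta <- thetaFromGamma(gamma)
  if (any(!is.finite(theta))) return(rep(0, M1 + pd$q))
  gth <- numeric(M1); gb <- numeric(pd$q)
  cap <- function(w) pmin(pmax(w, -1e10), 1e10)
  if (length(pd$iE)) {
    z <- drop(pd$Be %*% theta) - drop(pd$Xe %*% beta)
    hp <- pmax(drop(pd$De %*% theta), 1e-300)
    dl <- lk$dlogf(z)
    gth <- gth + drop(crossprod(pd$Be, dl)) + colSums(pd$De / hp)
    gb <- gb - drop(crossprod(pd$Xe, dl))
  }
  if (length(pd$iL)) {
    z <- drop(pd$Bl %*% theta) - drop(pd$Xl %*% beta)
    w <- cap(exp(lk$logf(z) - lk$logF(z)))
    gth <- gth + drop(crossprod(pd$Bl, w))
    gb <- gb - drop(crossprod(pd$Xl, w))
  }
  if (length(pd$iI)) {
    xb <- drop(pd$Xi %*% beta)
    zu <- drop(pd$Biu %*% theta) - xb
    zl <- drop(pd$Bil %*% theta) - xb
    lp <- pmax(ifelse(zu + zl <= 0,
                      .logDiffExp(lk$logF(zu), lk$logF(zl)),
                      .logDiffExp(lk$logS(zl), lk$logS(zu))), .LOGFLOOR)
    wu <- cap(exp(lk$logf(zu) - lp))
    wl <- cap(exp(lk$logf(zl) - lp))
    gth <- gth + drop(crossprod(pd$Biu, wu)) - drop(crossprod(pd$Bil, wl))
    gb <- gb - drop(crossprod(pd$Xi, wu - wl))
  }
  -c(.thetaGradToGamma(gth, gamma), gb)
}

## per-observation score rows in (gamma, beta); n_total x (M1 + q),
## zero rows for unused samples
.scoreRows <- function(par, pd, lk, M1) {
  gamma <- par[seq_len(M1)]
  beta <- par[-seq_len(M1)]
  theta <- thetaFromGamma(gamma)
  S <- matrix(0, pd$n, M1 + pd$q)
  cap <- function(w) pmin(pmax(w, -1e10), 1e10)
  if (length(pd$iE)) {
    z <- drop(pd$Be %*% theta) - drop(pd$Xe %*% beta)
    hp <- pmax(drop(pd$De %*% theta), 1e-300)
    dth <- lk$dlogf(z) * pd$Be + pd$De / hp
    S[pd$iE, seq_len(M1)] <- dth
    S[pd$iE, -seq_len(M1)] <- -lk$dlogf(z) * pd$Xe
  }
  if (length(pd$iL)) {
    z <- drop(pd$Bl %*% theta) - drop(pd$Xl %*% beta)
    w <- cap(exp(lk$logf(z) - lk$logF(z)))    # reverse hazard f/F
    S[pd$iL, seq_len(M1)] <- w * pd$Bl
    S[pd$iL, -seq_len(M1)] <- -w * pd$Xl
  }
  if (length(pd$iI)) {
    xb <- drop(pd$Xi %*% beta)
    zu <- drop(pd$Biu %*% theta) - xb
    zl <- drop(pd$Bil %*% theta) - xb
    lp <- ifelse(zu + zl <= 0,
                 .logDiffExp(lk$logF(zu), lk$logF(zl)),
                 .logDiffExp(lk$logS(zl), lk$logS(zu)))
    lp <- pmax(lp, .LOGFLOOR)
    wu <- cap(exp(lk$logf(zu) - lp))
    wl <- cap(exp(lk$logf(zl) - lp))
    S[pd$iI, seq_len(M1)] <- wu * pd$Biu - wl * pd$Bil
    S[pd$iI, -seq_len(M1)] <- -(wu - wl) * pd$Xi
  }
  ## chain rule on the theta block: reverse cumulative sums across columns
  if (M1 > 1) {
    A <- outer(seq_len(M1), seq_len(M1), `>=`) * 1     # A[j,k]=1 iff j>=k
    cs <- S[, seq_len(M1), drop = FALSE] %*% A
    S[, seq_len(M1)] <- cs * rep(c(1, exp(gamma[-1L])), each = nrow(S))
  }
  S
}

## analytic Hessian of the negative log-likelihood in (gamma, beta).
## Second derivatives of the contributions wrt the linear predictors are
## combined with basis/covariate outer products, then chained through the
## positive-increment reparameterization.
.negHess <- function(par, pd, lk, M1) {
  gamma <- par[seq_len(M1)]
  beta <- par[-seq_len(M1)]
  theta <- thetaFromGamma(gamma)
  q <- pd$q
  d <- M1 + q
  Htt <- matrix(0, M1, M1); Htb <- matrix(0, M1, q); Hbb <- matrix(0, q, q)
  gth <- numeric(M1)
  cap <- function(w) pmin(pmax(w, -1e10), 1e10)
  ## probit: (log f)'' = -1;  logit: (log f)'' = -2 f(z)
  d2lf <- if (lk$probit) function(z) rep(-1, length(z))
          else function(z) -2 * lk$f(z)
  fprime <- function(z) lk$f(z) * lk$dlogf(z)
  if (length(pd$iE)) {
    z <- drop(pd$Be %*% theta) - drop(pd$Xe %*% beta)
    hp <- pmax(drop(pd$De %*% theta), 1e-300)
    w2 <- d2lf(z)
    Htt <- Htt + crossprod(pd$Be, w2 * pd$Be) -
      crossprod(pd$De / hp, pd$De / hp)
    Htb <- Htb - crossprod(pd$Be, w2 * pd$Xe)
    Hbb <- Hbb + crossprod(pd$Xe, w2 * pd$Xe)
    gth <- gth + drop(crossprod(pd$Be, lk$dlogf(z))) + colSums(pd$De / hp)
  }
  if (length(pd$iL)) {
    z <- drop(pd$Bl %*% theta) - drop(pd$Xl %*% beta)
    w <- cap(exp(lk$logf(z) - lk$logF(z)))
    wp <- w * (lk$dlogf(z) - w)
    Htt <- Htt + crossprod(pd$Bl, wp * pd$Bl)
    Htb <- Htb - crossprod(pd$Bl, wp * pd$Xl)
    Hbb <- Hbb + crossprod(pd$Xl, wp * pd$Xl)
    gth <- gth + drop(crossprod(pd$Bl, w))
  }
  if (length(pd$iI)) {
    xb <- drop(pd$Xi %*% beta)
    zu <- drop(pd$Biu %*% theta) - xb
    zl <- drop(pd$Bil %*% theta) - xb
    lp <- pmax(ifelse(zu + zl <= 0,
                      .logDiffExp(lk$logF(zu), lk$logF(zl)),
                      .logDiffExp(lk$logS(zl), lk$logS(zu))), .LOGFLOOR)
    wu <- cap(exp(lk$logf(zu) - lp))
    wl <- cap(exp(lk$logf(zl) - lp))
    Auu <- cap(fprime(zu) * exp(-lp)) - wu^2
    All <- -cap(fprime(zl) * exp(-lp)) - wl^2
    Aul <- wu * wl
    Htt <- Htt + crossprod(pd$Biu, Auu * pd$Biu) +
      crossprod(pd$Bil, All * pd$Bil) +
      crossprod(pd$Biu, Aul * pd$Bil) + crossprod(pd$Bil, Aul * pd$Biu)
    Htb <- Htb - crossprod(pd$Biu, (Auu + Aul) * pd$Xi) -
      crossprod(pd$Bil, (All + Aul) * pd$Xi)
    Hbb <- Hbb + crossprod(pd$Xi, (Auu + All + 2 * Aul) * pd$Xi)
    gth <- gth + drop(crossprod(pd$Biu, wu)) - drop(crossprod(pd$Bil, wl))
  }
  ## chain rule: J = dtheta/dgamma, plus the curvature of the
  ## reparameterization itself on the diagonal
  J <- outer(seq_len(M1), seq_len(M1), `>=`) * 1
  if (M1 > 1) J[, -1L] <- J[, -1L] * rep(exp(gamma[-1L]), each = M1)
  Hgg <- t(J) %*% Htt %*% J
  if (M1 > 1) {
    cs <- rev(cumsum(rev(gth)))
    idx <- 2:M1
    diag(Hgg)[idx] <- diag(Hgg)[idx] + exp(gamma[idx]) * cs[idx]
  }
  Hgb <- t(J) %*% Htb
  H <- rbind(cbind(Hgg, Hgb), cbind(t(Hgb), Hbb))
  -(H + t(H)) / 2
}

#' Transformation-model log-likelihood
#'
#' Evaluates the log-likelihood of the monotone transformation regression
#' model \eqn{P(Y \le y \mid x) = F_\varepsilon(h(y) - x'\beta)} over a
#' censored/interval-encoded response: exact observations contribute
#' \eqn{\log f_\varepsilon(h(y) - x'\beta) + \log h'(y)}, left-censored ones
#' \eqn{\log F_\varepsilon(h(b) - x'\beta)}, and interval observations
#' \eqn{\log\{F_\varepsilon(h(u) - x'\beta) - F_\varepsilon(h(l) -
#' x'\beta)\}} (floored at a large negative value instead of \code{-Inf}
#' when a term underflows).  Missing entries are excluded.
#'
#' @param response a [CensoredResponse-class].
#' @param X covariate matrix, rows aligned with the response samples.
#' @param gamma unconstrained transformation parameters (length
#'   \code{order + 1}); \code{theta = thetaFromGamma(gamma)}.
#' @param beta shift coefficients (length \code{ncol(X)}).
#' @param link \code{"probit"} or \code{"logit"}.
#' @param basis optional [BernsteinBasis-class]; by default built on the
#'   response support with order \code{length(gamma) - 1}.
#' @return numeric(1), the log-likelihood.
#' @export
trafoLogLik <- function(response, X, gamma, beta,
                        link = c("probit", "logit"), basis = NULL) {
  link <- match.arg(link)
  if (is.null(basis))
    basis <- bernsteinBasis(length(gamma) - 1L, support(response))
  pd <- .prepareModelData(response, X, basis)
  if (length(beta) != pd$q)
    stop("beta must have one entry per covariate column")
  -.negLoglik(c(gamma, beta), pd, .linkFuns(link), basis@order + 1L)
}

## monotone ridge-stabilized start: probit/logit-transformed Winsorized
## empirical ranks regressed on the basis
.startValues <- function(response, pd, basis, lk) {
  idx <- c(pd$iE, pd$iL, pd$iI)
  pseudo <- c(response@value[pd$iE], response@bound[pd$iL],
              (response@lower[pd$iI] + response@upper[pd$iI]) / 2)
  n <- length(pseudo)
  Fh <- (rank(pseudo) - 0.5) / n
  Fh <- pmin(pmax(Fh, 1 / (2 * n)), 1 - 1 / (2 * n))
  zst <- if (identical(lk$logF, .linkFuns("logit")$logF))
    stats::qlogis(Fh) else stats::qnorm(Fh)
  B <- basisEval(basis, pseudo)
  M1 <- basis@order + 1L
  th <- drop(solve(crossprod(B) + 1e-6 * diag(M1), crossprod(B, zst)))
  th <- cummax(th)
  rng <- max(th) - min(th)
  c(th[1], log(pmax(diff(th), max(rng, 1) * 1e-3)))
}

#' Fit one transformation regression model
#'
#' Maximizes the censoring-aware likelihood over the unconstrained
#' parameters \code{(gamma, beta)} by quasi-Newton (BFGS) iteration with
#' analytic gradients.  Starting values put \code{beta = 0} and obtain the
#' transformation from a ridge-stabilized regression of the link-transformed
#' Winsorized empirical CDF on the basis.  A failed first attempt triggers
#' one deterministic jittered restart; a fit that still fails the
#' gradient-norm check is returned flagged (\code{converged = FALSE}), never
#' as an error, so that a long scan can proceed.
#'
#' @inheritParams trafoLogLik
#' @param order Bernstein order (default 6); ignored when \code{spec} given.
#' @param spec optional [ModelSpec-class] overriding \code{link}/\code{order}.
#' @param start optional numeric vector \code{c(gamma, beta)} of starting
#'   values.
#' @return a [TransformationFit-class].
#' @examples
#' set.seed(1)
#' x <- runif(80, 18, 80)
#' y <- 2 + 0.05 * x + rnorm(80)
#' f <- fitTransformModel(encodeResponse(y), cbind(age = x), order = 2)
#' f@beta
#' @export
fitTransformModel <- function(response, X, link = c("probit", "logit"),
                              order = 6L, spec = NULL, start = NULL) {
  if (!is.null(spec)) {
    link <- spec@link; order <- spec@order
  } else link <- match.arg(link)
  basis <- bernsteinBasis(order, support(response))
  pd <- .prepareModelData(response, as.matrix(X), basis)
  lk <- .linkFuns(link)
  M1 <- basis@order + 1L
  d <- M1 + pd$q
  nUsed <- length(pd$iE) + length(pd$iL) + length(pd$iI)
  if (nUsed < d + 2L)
    stop("too few usable observations (", nUsed, ") for ", d,
         " parameters in '", response@name, "'")

  if (is.null(start)) {
    g0 <- tryCatch(.startValues(response, pd, basis, lk),
                   error = function(e) c(-1, rep(log(2 / M1), M1 - 1L)))
    start <- c(g0, rep(0, pd$q))
  }
  fn <- function(p) .negLoglik(p, pd, lk, M1)
  gr <- function(p) .negGrad(p, pd, lk, M1)
  ## precondition the beta directions by the covariate scale so that BFGS
  ## sees comparably scaled parameters (a raw-unit exposure like age makes
  ## beta ~50x smaller than the transformation parameters)
  Xall <- rbind(pd$Xe, pd$Xl, pd$Xi)
  xs <- pmin(pmax(apply(Xall, 2L, stats::sd), 1e-8), 1e8)
  pscale <- c(rep(1, M1), 1 / xs)

  hs <- function(p) .negHess(p, pd, lk, M1)

  gtol <- function(v) 1e-4 * max(1, abs(v))
  gnormOf <- function(p) max(abs(gr(p) * pscale))
  ## Newton iteration (quasi-Newton safeguarded by the PORT trust region);
  ## falls back to gradient-only BFGS when the Hessian path stalls
  runNewton <- function(p0) {
    o <- tryCatch(
      stats::nlminb(p0, fn, gradient = gr, hessian = hs,
                    control = list(iter.max = 200L, eval.max = 400L,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) return(NULL)
    list(par = o$par, value = o$objective)
  }
  runBFGS <- function(p0) {
    o <- tryCatch(
      stats::optim(p0, fn, gr, method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-12,
                                  parscale = pscale)),
      error = function(e) NULL)
    if (is.null(o)) return(NULL)
    list(par = o$par, value = o$value)
  }
  best <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    if (b$value < a$value) b else a
  }

  o <- runNewton(start)
  if (is.null(o) || gnormOf(o$par) > gtol(o$value))
    o <- best(o, runBFGS(if (is.null(o)) start else o$par))
  if (is.null(o) || gnormOf(o$par) > gtol(o$value)) {
    ## one deterministic jittered restart
    jit <- start + 0.25 * sin(seq_along(start) * 7.13) * pscale
    o <- best(o, runNewton(jit))
  }
  if (is.null(o))
    stop("optimizer failed fatally for '", response@name, "'")
  msg <- ""
  gnorm <- gnormOf(o$par)
  converged <- is.finite(o$value) && gnorm <= gtol(o$value)
  if (!converged)
    msg <- paste0("gradient norm ", format(gnorm, digits = 3),
                  " above tolerance; possibly weakly identified ",
                  "(heavy censoring or ties)")

  par <- o$par
  gamma <- par[seq_len(M1)]
  beta <- stats::setNames(par[-seq_len(M1)], pd$cn)
  info <- tryCatch(hs(par), error = function(e) matrix(NA_real_, d, d))
  S <- .scoreRows(par, pd, lk, M1)

  new("TransformationFit", basis = basis, link = link, gamma = gamma,
      theta = thetaFromGamma(gamma), beta = beta, loglik = -o$value,
      scores = S, info = info, converged = converged,
      nUsed = as.integer(nUsed), sampleMask = pd$used, message = msg)
}

#' Per-observation score matrix of a fitted model
#'
#' Row i is the analytic gradient of observation i's log-likelihood
#' contribution at the maximum-likelihood estimate, in \code{(gamma, beta)}
#' coordinates; samples not used by the model (missing response or
#' covariates) have all-zero rows so that score matrices of different
#' models stay aligned on one global sample ordering.  Column sums vanish at
#' the optimum (first-order condition).
#'
#' @param fit a converged [TransformationFit-class].
#' @return numeric matrix, samples by parameters.
#' @export
scoreMatrix <- function(fit) {
  stopifnot(is(fit, "TransformationFit"))
  if (!fit@converged)
    stop("score matrix requested from a non-converged fit")
  fit@scores
}

setMethod("show", "TransformationFit", function(object) {
  cat("TransformationFit (", object@link, " link, Bernstein order ",
      object@basis@order, ")\n", sep = "")
  cat("  n used:", object@nUsed, " logLik:", format(object@loglik),
      " converged:", object@converged, "\n")
  cat("  shift coefficients:\n")
  print(object@beta)
  if (nzchar(object@message)) cat("  note:", object@message, "\n")
})
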
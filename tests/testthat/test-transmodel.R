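test_that("order-1 probit model on exact data is the Gaussian linear model", {
  g <- makeGaussian(n = 400, beta = 0.05, seed = 21)
  resp <- encodeResponse(g$y, name = "m")
  f <- fitTransformModel(resp, cbind(age = g$x), order = 1)
  expect_true(f@converged)
  ols <- lm(g$y ~ g$x)
  sigMle <- sqrt(sum(resid(ols)^2) / length(g$y))
  expect_equal(unname(f@beta[1]), unname(coef(ols)[2]) / sigMle,
               tolerance = 1e-4)
  ## maximized log-likelihood equals the Gaussian one at the MLE
  llNorm <- sum(dnorm(g$y, fitted(ols), sigMle, log = TRUE))
  expect_equal(f@loglik, llNorm, tolerance = 1e-7)
})

test_that("elementary likelihood contributions match closed forms", {
  ## single left-censored observation with h(bound) = 0 contributes log 1/2
  resp <- new("CensoredResponse", name = "m",
              kind = c("exact", "exact", "left"),
              value = c(0.5, 1.5, NA), bound = c(NA, NA, 1),
              lower = rep(NA_real_, 3), upper = rep(NA_real_, 3),
              loq = 1, support = c(0, 2), sampleIDs = as.character(1:3))
  X <- matrix(0, 3, 1, dimnames = list(NULL, "x"))
  ## M = 1, theta = (-1, 1): h(y) = y - 1, so h(1) = 0 and h' = 1
  gam <- c(-1, log(2))
  llAll <- trafoLogLik(resp, X, gam, beta = 0)
  exactPart <- dnorm(0.5 - 1, log = TRUE) + dnorm(1.5 - 1, log = TRUE)
  expect_equal(llAll - exactPart, log(0.5), tolerance = 1e-12)

  ## an interval spanning the whole support with a wide transformation
  ## carries total probability ~1, contribution ~0
  resp2 <- new("CensoredResponse", name = "m",
               kind = c("exact", "exact", "interval"),
               value = c(0.5, 1.5, NA), bound = rep(NA_real_, 3),
               lower = c(NA, NA, 1e-9), upper = c(NA, NA, 2 - 1e-9),
               loq = NA_real_, support = c(0, 2),
               sampleIDs = as.character(1:3))
  wide <- c(-10, log(20))      # theta = (-10, 10)
  llInt <- trafoLogLik(resp2, X, wide, beta = 0)
  exact2 <- sum(dnorm(c(0.5, 1.5) * 10 - 10, log = TRUE) + log(10))
  expect_equal(llInt - exact2, 0, tolerance = 1e-6)
})

test_that("likelihood errors on misaligned or all-missing input", {
  resp <- encodeResponse(c(1, 2, 3, 4), name = "m")
  expect_error(trafoLogLik(resp, matrix(0, 3, 1), c(0, 0), 0),
               "misaligned")
  respNA <- encodeResponse(c(1, 2, 3, NA), name = "m")
  X <- matrix(NA_real_, 4, 1)
  expect_error(trafoLogLik(respNA, X, c(0, 0), 0), "missing")
})

test_that("score matrix has vanishing column sums and matches finite
          differences", {
  set.seed(5)
  x <- runif(150, 18, 80)
  y <- round(1 + 0.02 * x + rnorm(150), 1)
  loq <- unname(quantile(y, 0.12))
  resp <- encodeResponse(ifelse(y <= loq, loq, y), loq = loq, name = "m")
  X <- cbind(age = x)
  f <- fitTransformModel(resp, X)
  expect_true(f@converged)
  S <- scoreMatrix(f)
  expect_lte(max(abs(colSums(S))), 1e-4 * max(1, abs(f@loglik)))
  ## zero rows exactly for unused samples
  expect_true(all(S[!f@sampleMask, ] == 0))
  ## finite-difference check of the total gradient at a non-optimal point
  par <- c(f@gamma, f@beta) * 0.9 + 0.01
  ll0 <- function(p) trafoLogLik(resp, X, p[1:7], p[8])
  gAna <- -metaboscan:::.negGrad(
    par, metaboscan:::.prepareModelData(resp, X, f@basis),
    metaboscan:::.linkFuns("probit"), 7L)
  h <- 1e-6
  for (i in c(1, 3, 7, 8)) {
    e <- rep(0, 8); e[i] <- h
    fd <- (ll0(par + e) - ll0(par - e)) / (2 * h)
    expect_lt(abs(unname(gAna[i]) - fd), 1e-4 * max(1, abs(fd)))
  }
  ## duplicating the dataset stacks the scores
  resp2 <- encodeResponse(rep(ifelse(y <= loq, loq, y), 2), loq = loq,
                          name = "m2")
  f2 <- fitTransformModel(resp2, rbind(X, X), start = c(f@gamma, f@beta))
  expect_equal(nrow(scoreMatrix(f2)), 2L * nrow(S))
  expect_error(scoreMatrix(new("TransformationFit", converged = FALSE)),
               "non-converged")
})

test_that("estimates are equivariant under rescaling of the response", {
  set.seed(8)
  x <- runif(200, 18, 80)
  y <- exp(0.02 * x + rnorm(200, 0, 0.7))
  r1 <- encodeResponse(y, name = "m")
  f1 <- fitTransformModel(r1, cbind(age = x))
  cc <- 1000
  r2 <- encodeResponse(cc * y, name = "m")
  f2 <- fitTransformModel(r2, cbind(age = x))
  expect_equal(unname(f1@beta[1]), unname(f2@beta[1]), tolerance = 1e-6)
  ## the maximized log-likelihood shifts by the density Jacobian of the
  ## rescaling, -n_exact * log(c), and is otherwise unchanged
  nE <- kindCounts(r1)[["exact"]]
  expect_equal(f2@loglik, f1@loglik - nE * log(cc), tolerance = 1e-5)
})

test_that("left-censoring the lowest decile moves the estimate by less
          than one standard error", {
  set.seed(13)
  x <- runif(300, 18, 80)
  y <- 5 + 0.04 * x + rnorm(300)
  rAll <- encodeResponse(y, name = "m")
  fAll <- fitTransformModel(rAll, cbind(age = x))
  q10 <- unname(quantile(y, 0.10))
  rCens <- encodeResponse(ifelse(y <= q10, q10, y), loq = q10, name = "m")
  fCens <- fitTransformModel(rCens, cbind(age = x))
  seAll <- sqrt(diag(jointCovariance(list(fAll))))
  expect_lt(abs(unname(fAll@beta[1]) - unname(fCens@beta[1])), seAll)
})

test_that("under the null the standardized estimate is well calibrated", {
  reps <- 150
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    d <- simulateMetabolome(simConfig(n = 200, p = 1, distortion = "exp",
                                      seed = 900 + r))
    resp <- encodeResponse(d$abundance[, 1], name = "m",
                           sampleIDs = rownames(d$abundance))
    f <- fitTransformModel(resp, cbind(age = d$metadata$age))
    se <- sqrt(drop(jointCovariance(list(f))))
    cover[r] <- abs(f@beta[1]) < 3 * se
  }
  expect_gte(mean(cover), 0.98)
})

test_that("the logit link recovers a logistic-error shift effect", {
  set.seed(31)
  x <- runif(400, 18, 80)
  y <- 2 + 0.05 * x + rlogis(400)
  resp <- encodeResponse(y, name = "m")
  f <- fitTransformModel(resp, cbind(age = x), link = "logit")
  expect_true(f@converged)
  expect_equal(unname(f@beta[1]), 0.05, tolerance = 0.25)
})

test_that("fits with too few usable observations error", {
  resp <- encodeResponse(c(1, 2, 3, 4, 5), name = "m")
  expect_error(fitTransformModel(resp, cbind(x = 1:5), order = 6),
               "too few")
})
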
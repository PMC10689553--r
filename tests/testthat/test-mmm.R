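test_that("one-dimensional rectangle probabilities are exact", {
  p <- mvnRectangle(diag(1), 1.959964)
  expect_equal(as.numeric(p), 0.95, tolerance = 1e-6)
  expect_equal(attr(p, "mcError"), 0)
})

test_that("independent and perfectly correlated cases match closed forms", {
  ## two independent tests: Sidak root of (2*pnorm(c)-1)^2 = 0.95
  p2 <- mvnRectangle(diag(2), 2.236477)
  expect_equal(as.numeric(p2), 0.95, tolerance = 1e-5)
  ## perfect correlation collapses to one dimension
  pOne <- mvnRectangle(matrix(1, 2, 2), 1.959964)
  expect_equal(as.numeric(pOne), 0.95, tolerance = 1e-4)
  pOne5 <- mvnRectangle(matrix(1, 5, 5), 1.959964)
  expect_equal(as.numeric(pOne5), 0.95, tolerance = 1e-4)
})

test_that("rectangle probabilities are deterministic given the seed and
          reject indefinite matrices", {
  R <- randomCorr(12, seed = 5)
  a <- mvnRectangle(R, 2.5, seed = 99)
  b <- mvnRectangle(R, 2.5, seed = 99)
  expect_identical(as.numeric(a), as.numeric(b))
  bad <- matrix(c(1, 0.6, -0.9, 0.6, 1, 0.6, -0.9, 0.6, 1), 3, 3)
  expect_error(mvnRectangle(bad, 2), "positive semi-definite")
  expect_error(mvnRectangle(matrix(c(1, 2, 2, 1), 2, 2) * 2, 2),
               "unit diagonal")
})

test_that("critical values fall between the unadjusted and Bonferroni
          quantiles for arbitrary correlation", {
  for (s in 1:6) {
    d <- sample(2:9, 1)
    R <- randomCorr(d, seed = 40 + s)
    ji <- maxTInference(rnorm(d), R, level = 0.95, seed = 7)
    zB <- qnorm(1 - 0.025 / d)
    expect_gte(ji@crit, 1.959964 - 1e-6)
    expect_lte(ji@crit, zB + 1e-6)
    ## nested independent families: crit grows with the family size
    jiBig <- maxTInference(rnorm(2 * d), diag(2 * d), seed = 7)
    jiSmall <- maxTInference(rnorm(d), diag(d), seed = 7)
    expect_gte(jiBig@crit + 1e-6, jiSmall@crit)
  }
})

test_that("single-model inference reduces to the Wald interval", {
  ji <- maxTInference(0.4, matrix(0.04), level = 0.95, seed = 1)
  expect_equal(ji@crit, qnorm(0.975))
  expect_equal(ji@ciLower, 0.4 - qnorm(0.975) * 0.2)
  expect_equal(ji@pAdj, 2 * pnorm(-2), tolerance = 1e-9)
})

test_that("adjusted p-values never undercut unadjusted ones and agree
          with the intervals", {
  R <- randomCorr(6, seed = 3)
  eff <- c(-0.5, 0.02, 0.3, -0.1, 0.8, 0.05)
  se <- rep(0.1, 6)
  ji <- maxTInference(eff, diag(se) %*% R %*% diag(se), seed = 11)
  pUn <- 2 * pnorm(-abs(eff / se))
  expect_true(all(ji@pAdj >= pUn - 1e-12))
  sigCI <- ji@ciLower > 0 | ji@ciUpper < 0
  sigP <- ji@pAdj < 0.05
  expect_identical(sigCI, sigP)
  expect_error(maxTInference(c(1, 2), matrix(c(1, 0, 0, 0), 2, 2)),
               "standard error")
})

test_that("joint covariance of duplicated and independent models behaves
          like correlation 1 and 0", {
  set.seed(17)
  x <- runif(300, 18, 80)
  y1 <- 1 + rnorm(300)          # independent of x and of y2
  y2 <- exp(rnorm(300))
  f1 <- fitTransformModel(encodeResponse(y1, name = "a"), cbind(age = x))
  f1b <- fitTransformModel(encodeResponse(y1, name = "a2"), cbind(age = x))
  f2 <- fitTransformModel(encodeResponse(y2, name = "b"), cbind(age = x))
  V <- jointCovariance(list(a = f1, a2 = f1b, b = f2))
  R <- cov2cor(V)
  expect_gt(R["a", "a2"], 0.999)          # same data twice
  expect_lt(abs(R["a", "b"]), 0.12)       # independent metabolites
  ## single model: its own sandwich variance
  V1 <- jointCovariance(list(f1))
  expect_equal(dim(V1), c(1L, 1L))
  expect_equal(as.numeric(V1), unname(V["a", "a"]))
})

test_that("stacked-score covariance matches a nonparametric bootstrap", {
  set.seed(23)
  n <- 300
  x <- runif(n, 18, 80)
  z <- rnorm(n)
  y1 <- 0.03 * x + z + rnorm(n, 0, 0.6)        # share the factor z
  y2 <- 0.01 * x + z + rnorm(n, 0, 0.6)
  fit2 <- function(idx) {
    fa <- fitTransformModel(encodeResponse(y1[idx], name = "a"),
                            cbind(age = x[idx]), order = 1)
    fb <- fitTransformModel(encodeResponse(y2[idx], name = "b"),
                            cbind(age = x[idx]), order = 1)
    list(fa, fb)
  }
  fits <- fit2(seq_len(n))
  Rmmm <- cov2cor(jointCovariance(fits))[1, 2]
  B <- 150
  bb <- matrix(0, B, 2)
  for (b in seq_len(B)) {
    fs <- fit2(sample.int(n, n, replace = TRUE))
    bb[b, ] <- c(fs[[1]]@beta[1], fs[[2]]@beta[1])
  }
  expect_equal(Rmmm, cor(bb)[1, 2], tolerance = 0.15)
})

test_that("non-converged fits are dropped with a warning, not an error", {
  set.seed(29)
  x <- runif(120, 18, 80)
  f <- fitTransformModel(encodeResponse(rnorm(120), name = "ok"),
                         cbind(age = x))
  brokenSlots <- f
  brokenSlots@converged <- FALSE
  expect_warning(V <- jointCovariance(list(good = f, bad = brokenSlots)),
                 "non-converged")
  expect_equal(dim(V), c(1L, 1L))
  expect_identical(attr(V, "dropped"), 2L)
})
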
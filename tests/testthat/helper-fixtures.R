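# Fixtures are generated in code so every run rebuilds them from scratch.

# A synthetic two-metabolite demo shaped like a targeted plasma panel:
# "sGUDCA" is a bile-acid-like metabolite with a strong negative age trend
# and a limit of quantification at 25 nM (values at or below 25 reported as
# 25); "sC10" is a fatty-acid-like null metabolite quantified at two
# decimals whose floor produces a large block of tied values at 0.46.
makeDemoPanel <- function(n = 301, seed = 4242) {
  set.seed(seed)
  age <- runif(n, 18, 80)
  bmi <- 22 + 0.04 * (age - 50) + rnorm(n, 0, 2.5)
  gudca <- 60 * exp(-0.022 * age + rnorm(n))
  gudca <- ifelse(gudca <= 25, 25, gudca)
  e <- rnorm(n)
  c10 <- ifelse(e < 0.36, 0.46, round(0.46 + 0.3 * (e - 0.36), 2))
  ids <- sprintf("K%03d", seq_len(n))
  list(
    abundance = matrix(c(gudca, c10), ncol = 2,
                       dimnames = list(ids, c("sGUDCA", "sC10"))),
    metadata = data.frame(age = age, bmi = bmi, row.names = ids),
    loqMap = c(sGUDCA = 25))
}

# exact-data Gaussian fixture for closed-form comparisons
makeGaussian <- function(n = 500, beta = 0.05, seed = 1) {
  set.seed(seed)
  x <- runif(n, 18, 80)
  y <- 2 + beta * x + rnorm(n)
  list(x = x, y = y)
}

# random correlation matrix via a random Gram matrix
randomCorr <- function(d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(d * (d + 2)), d + 2, d)
  stats::cov2cor(crossprod(A))
}

# fit both metameter models for every metabolite of a simulated dataset
# and return the stacked fits (used by the simulation-based checks)
fitAllModels <- function(d, order = 6L) {
  mm <- makeMetameters(d$metadata$age, sourceName = "age")
  fits <- list()
  for (met in colnames(d$abundance)) {
    resp <- encodeResponse(d$abundance[, met], name = met,
                           sampleIDs = rownames(d$abundance))
    for (mn in mm@metameters)
      fits[[paste(met, mn, sep = "|")]] <-
        fitTransformModel(resp, mm@columns[, mn, drop = FALSE],
                          order = order)
  }
  fits
}
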
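test_that("all-distinct values encode as exact observations", {
  r <- encodeResponse(c(1, 2, 3), name = "m")
  expect_equal(unname(kindCounts(r)), c(3L, 0L, 0L, 0L))
  expect_equal(r@value, c(1, 2, 3))
})

test_that("ties become intervals spanning midpoints to adjacent values", {
  r <- encodeResponse(c(1, 2, 2, 3), name = "m")
  cnt <- kindCounts(r)
  expect_equal(cnt[["interval"]], 2L)
  expect_equal(cnt[["exact"]], 2L)
  ii <- which(r@kind == "interval")
  expect_equal(unique(r@lower[ii]), 1.5)
  expect_equal(unique(r@upper[ii]), 2.5)
  ## outermost tied value extends by half the nearest gap
  r2 <- encodeResponse(c(1, 1, 2, 4), name = "m")
  i2 <- which(r2@kind == "interval")
  expect_equal(unique(r2@lower[i2]), 0.5)
  expect_equal(unique(r2@upper[i2]), 1.5)
  ## tiePolicy none keeps ties exact
  r3 <- encodeResponse(c(1, 2, 2, 3), tiePolicy = "none", name = "m")
  expect_equal(kindCounts(r3)[["exact"]], 4L)
})

test_that("values at or below the LOQ are left-censored at the LOQ", {
  raw <- c(10, 20, 25, 30, 40, 55)
  r <- encodeResponse(raw, loq = 25, name = "gudca")
  cnt <- kindCounts(r)
  expect_equal(cnt[["left"]], 3L)   # 10, 20 and the value exactly at 25
  expect_equal(cnt[["exact"]], 3L)
  expect_true(all(r@bound[r@kind == "left"] == 25))
  expect_equal(responseLoq(r), 25)
})

test_that("degenerate responses raise errors naming the metabolite", {
  expect_error(encodeResponse(c(1, 2, 3), loq = 10, name = "gudca"),
               "gudca")
  expect_error(encodeResponse(c(2, 2, 2, 2), name = "flat"), "flat")
  expect_error(encodeResponse(c(1, NA, NA, 2), name = "thin"), "thin")
})

test_that("missing values are kept as markers and counts partition n", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    raw <- round(rnorm(n, 10, 2), sample(0:2, 1))
    raw[sample(n, floor(n / 5))] <- NA
    loq <- if (rep %% 2) quantile(raw, 0.2, na.rm = TRUE) else NA
    r <- tryCatch(encodeResponse(raw, loq = loq, name = "m"),
                  error = function(e) NULL)
    if (is.null(r)) next     # degenerate draw
    cnt <- kindCounts(r)
    expect_identical(sum(cnt), length(raw))
    expect_identical(cnt[["missing"]], sum(is.na(raw)))
    ## intervals of distinct tied values are ordered and non-overlapping
    ii <- which(r@kind == "interval")
    if (length(ii)) {
      iv <- unique(cbind(r@lower[ii], r@upper[ii]))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1)
        expect_true(all(iv[-nrow(iv), 2] <= iv[-1, 1] + 1e-12))
    }
  }
})

test_that("re-encoding the exact part is idempotent in kind counts", {
  set.seed(7)
  raw <- round(rlnorm(80, 2, 0.4), 1)
  r1 <- encodeResponse(raw, name = "m")
  ## feeding back a vector with the same exact values and the same ties
  r2 <- encodeResponse(raw, name = "m")
  expect_identical(kindCounts(r1), kindCounts(r2))
})

test_that("support contains every anchor and follows the margin rule", {
  expect_equal(defaultSupport(c(10, 20), margin = 0.1), c(9, 21))
  expect_equal(defaultSupport(c(0, 1), margin = 0), c(0, 1))
  expect_error(defaultSupport(c(5, 5)), "distinct")
  r <- encodeResponse(c(1, 2, 2, 3), loq = 1, name = "m")
  s <- support(r)
  anchors <- c(r@value[r@kind == "exact"], r@bound[r@kind == "left"],
               r@lower[r@kind == "interval"], r@upper[r@kind == "interval"])
  expect_true(all(anchors >= s[1] & anchors <= s[2]))
})

test_that("asSurv round-trips the encoding into a Surv object", {
  r <- encodeResponse(c(10, 20, 25, 30, 30, 40), loq = 25, name = "m")
  s <- asSurv(r)
  expect_s3_class(s, "Surv")
  expect_equal(nrow(s), 6L)       # no missing entries here
  ## survival's interval2 coding: 2 = left, 1 = exact, 3 = interval
  expect_equal(sum(s[, "status"] == 2), 3)
  expect_equal(sum(s[, "status"] == 3), 2)
})
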
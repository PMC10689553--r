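test_that("a censored age-trending metabolite is flagged and a tied null
          metabolite is not, with and without BMI adjustment", {
  demo <- makeDemoPanel()
  res <- metaboScan(demo$abundance, demo$metadata, exposure = "age",
                    loqMap = demo$loqMap)
  tab <- resultsTable(res)
  expect_identical(nrow(tab), 4L)
  expect_identical(colnames(tab),
    c("metabolite", "metameter", "effect", "lower", "upper", "p_adj",
      "significant", "n_used", "n_left", "n_interval", "converged"))
  gud <- tab[tab$metabolite == "sGUDCA", ]
  c10 <- tab[tab$metabolite == "sC10", ]
  expect_true(all(gud$significant))
  expect_true(all(gud$effect < 0))       # declines with age
  expect_true(all(gud$n_left > 0))
  expect_false(any(c10$significant))
  expect_true(all(c10$n_interval > 100)) # the tie block is encoded
  ## BMI adjustment preserves both conclusions
  resAdj <- metaboScan(demo$abundance, demo$metadata, exposure = "age",
                       adjust = "bmi", loqMap = demo$loqMap)
  tabA <- resultsTable(resAdj)
  expect_true(all(tabA$significant[tabA$metabolite == "sGUDCA"]))
  expect_false(any(tabA$significant[tabA$metabolite == "sC10"]))
})

test_that("scans are deterministic and the results CSV byte-reproduces", {
  d <- simulateMetabolome(simConfig(n = 60, p = 3, seed = 5,
                                    distortion = "exp"))
  run <- function() metaboScan(d$abundance, d$metadata, exposure = "age",
                               order = 3, seed = 777)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeScanResults(run(), f1)
  writeScanResults(run(), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("removing a metabolite changes the joint correction but not the
          marginal estimates", {
  d <- simulateMetabolome(simConfig(n = 80, p = 4, seed = 9,
                                    beta = c(0.08, 0, 0, 0)))
  full <- resultsTable(metaboScan(d$abundance, d$metadata,
                                  exposure = "age", order = 3))
  drop1 <- resultsTable(metaboScan(d$abundance[, -1], d$metadata,
                                   exposure = "age", order = 3))
  shared <- merge(full, drop1, by = c("metabolite", "metameter"))
  expect_equal(shared$effect.x, shared$effect.y, tolerance = 1e-10)
  ## the max-t family shrank, so the simultaneous intervals must tighten
  width <- function(t) mean(t$upper - t$lower)
  expect_lt(width(drop1),
            width(full[full$metabolite != "M01", ]))
})

test_that("empty sample intersection and non-numeric exposures error", {
  d <- simulateMetabolome(simConfig(n = 30, p = 2, seed = 3))
  metaBad <- d$metadata
  rownames(metaBad) <- paste0("X", seq_len(nrow(metaBad)))
  expect_error(metaboScan(d$abundance, metaBad, exposure = "age"),
               "no samples shared")
  metaChr <- d$metadata
  metaChr$age <- as.character(metaChr$age)
  expect_error(metaboScan(d$abundance, metaChr, exposure = "age"),
               "numeric")
  expect_error(metaboScan(d$abundance, d$metadata, exposure = "height"),
               "height")
})

test_that("degenerate metabolites are skipped with reasons, never fatal", {
  d <- simulateMetabolome(simConfig(n = 50, p = 3, seed = 13))
  ab <- d$abundance
  ab[, 2] <- 7.7                      # constant column
  res <- metaboScan(ab, d$metadata, exposure = "age", order = 3)
  expect_identical(nrow(resultsTable(res)), 4L)   # 2 metabolites x 2
  sk <- scanSkips(res)
  expect_identical(sk$metabolite, "M02")
  expect_match(sk$reason, "degenerate")
  ## rows + skips x metameters = 2p
  expect_identical(nrow(resultsTable(res)) + 2L * nrow(sk), 6L)
})

test_that("per-metameter families give separate, smaller corrections", {
  d <- simulateMetabolome(simConfig(n = 70, p = 4, seed = 21))
  rAll <- metaboScan(d$abundance, d$metadata, exposure = "age", order = 3)
  rSep <- metaboScan(d$abundance, d$metadata, exposure = "age", order = 3,
                     family = "per-metameter")
  expect_identical(sort(names(rSep@joint)),
                   c("arithmetic", "logarithmic"))
  critSep <- vapply(rSep@joint, function(j) j@crit, 1.0)
  expect_true(all(critSep <= rAll@joint@crit + 1e-6))
})

test_that("a SummarizedExperiment scans identically to its matrix form", {
  d <- simulateMetabolome(simConfig(n = 50, p = 2, seed = 31))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = t(d$abundance)),
    colData = S4Vectors::DataFrame(d$metadata))
  rSE <- metaboScan(se, exposure = "age", order = 2)
  rM <- metaboScan(d$abundance, d$metadata, exposure = "age", order = 2)
  expect_equal(resultsTable(rSE), resultsTable(rM))
})

test_that("forest plots order by effect, mark zero and write files", {
  d <- simulateMetabolome(simConfig(n = 60, p = 5, seed = 41,
                                    beta = c(0.1, 0, 0, 0, 0)))
  res <- metaboScan(d$abundance, d$metadata, exposure = "age", order = 3)
  gg <- forestPlot(res, "arithmetic")
  expect_s3_class(gg, "ggplot")
  expect_true(all(diff(gg$data$effect) >= 0))
  for (ext in c("pdf", "png")) {
    f <- tempfile(fileext = paste0(".", ext))
    forestPlot(res, "logarithmic", outPath = f)
    expect_gt(file.info(f)$size, 0)
  }
  expect_error(forestPlot(res, "cubic"), "arithmetic")
  ## replotting from the written CSV needs no refit
  f <- tempfile(fileext = ".csv")
  writeScanResults(res, f)
  gg2 <- forestPlot(utils::read.csv(f), "arithmetic")
  expect_equal(gg2$data$effect, gg$data$effect)
  ## a single metabolite still renders
  res1 <- metaboScan(d$abundance[, 1, drop = FALSE], d$metadata,
                     exposure = "age", order = 3)
  expect_s3_class(forestPlot(res1, "arithmetic"), "ggplot")
})
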
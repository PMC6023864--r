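# Synthetic climate and occurrence generator.

test_that("climate generation is deterministic and honors the correlation target", {
  cfg <- scenarioConfig(gridRows = 50, gridCols = 50, seed = 7)
  s1 <- generateClimateStack(cfg)
  s2 <- generateClimateStack(cfg)
  expect_identical(gridValues(s1), gridValues(s2))

  # identity target, no autocorrelation: sample correlations near zero
  st <- correlatedStack(diag(3), n = 120, seed = 3)
  env <- allUnmaskedEnv(st)
  offDiag <- cor(env)[upper.tri(diag(3))]
  expect_true(all(abs(offDiag) < 0.1))

  # strong target recovered (oracle: direct correlation of the arrays)
  C <- rbind(c(1, 0.9), c(0.9, 1))
  st2 <- correlatedStack(C, n = 120, seed = 4)
  r <- cor(allUnmaskedEnv(st2))[1, 2]
  expect_lt(abs(r - 0.9), 0.05)
})

test_that("autocorrelation length produces spatially smoother fields", {
  rough <- generateClimateStack(scenarioConfig(gridRows = 80, gridCols = 80,
                                               autocorrLength = 0, seed = 2))
  smooth <- generateClimateStack(scenarioConfig(gridRows = 80, gridCols = 80,
                                                autocorrLength = 6, seed = 2))
  lag1 <- function(stack) {
    m <- gridValues(stack)[[1]]
    cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ]))
  }
  expect_lt(abs(lag1(rough)), 0.1)
  expect_gt(lag1(smooth), 0.8)
})

test_that("invalid correlation matrices are rejected with an explanation", {
  bad <- rbind(c(1, 0.9, -0.9), c(0.9, 1, 0.9), c(-0.9, 0.9, 1))
  expect_error(scenarioConfig(variableNames = c("a", "b", "c"),
                              crossCorrelation = bad),
               "positive semi-definite")
  expect_error(scenarioConfig(gridRows = 5, gridCols = 5), "100 cells")
})

test_that("scenario shifts apply the cellwise affine transform exactly", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 5))
  idShift <- shiftSpec(rep(0, 5), rep(1, 5))
  expect_equal(gridValues(shiftScenario(st, idShift)), gridValues(st))

  # Last Interglacial analogue: +3.8 C temperature, -16% precipitation
  sh <- shiftScenario(st, shiftSpec(c(0, 3.8, 3.8, 0, 0),
                                    c(1, 1, 1, 0.84, 0.84)), "MIS5e")
  expect_equal(mean(gridValues(sh)$bio8) - mean(gridValues(st)$bio8), 3.8)
  expect_equal(mean(gridValues(sh)$bio9) - mean(gridValues(st)$bio9), 3.8)
  expect_equal(mean(gridValues(sh)$bio18) / mean(gridValues(st)$bio18), 0.84)

  toy <- testStack(list(a = matrix(c(1, 2), 1, 2)))
  expect_equal(gridValues(shiftScenario(toy, shiftSpec(0, 2)))$a,
               matrix(c(2, 4), 1, 2))
  expect_error(shiftScenario(toy, shiftSpec(c(0, 0), c(1, 1))),
               "does not match")
})

test_that("Gaussian suitability has the closed form and its monotonicity", {
  toy <- testStack(list(a = matrix(c(10, 11, 12, 14), 1, 4)))
  niche <- nicheTruth(optimum = 10, tolerance = 1, maxPrevalence = 0.8)
  s <- gridValues(trueSuitability(toy, niche))
  expect_equal(s[1, 1], 0.8)                      # at the optimum
  expect_equal(s[1, 2], 0.8 * exp(-0.5))          # one tolerance away
  expect_true(all(diff(as.vector(s)) < 0))        # non-increasing outward
  expect_error(nicheTruth(10, 0), "strictly positive")
  expect_error(trueSuitability(toy, nicheTruth(c(1, 2), c(1, 1))),
               "dimensions")
})

test_that("occurrence sampling is suitability-weighted, distinct and seeded", {
  st <- generateClimateStack(scenarioConfig(seed = 11))
  suit <- trueSuitability(st, testNiche())
  occ <- sampleOccurrences(suit, 404, seed = 9)
  expect_equal(length(occ), 404L)
  r <- records(occ)
  expect_equal(nrow(unique(r[, c("x", "y")])), 404L)  # distinct cells
  expect_identical(records(sampleOccurrences(suit, 404, seed = 9)), r)

  # zero-suitability cells are never sampled
  vals <- matrix(0, 2, 5); vals[1, 1:3] <- 0.5
  m <- new("SuitabilityMap", values = vals, cellSize = 1, origin = c(0, 0),
           nodataMask = matrix(FALSE, 2, 5), scenarioId = "toy",
           modelId = "t")
  for (s in 1:20) {
    r <- records(sampleOccurrences(m, 3, seed = s))
    expect_true(all(r$y == 1.5))  # top row only (positive cells)
  }
  expect_error(sampleOccurrences(m, 4, seed = 1), "positive suitability")
})

test_that("uniform suitability gives uniform per-cell inclusion frequencies", {
  vals <- matrix(0.4, 2, 5)  # 10-cell toy map, uniform
  m <- new("SuitabilityMap", values = vals, cellSize = 1, origin = c(0, 0),
           nodataMask = matrix(FALSE, 2, 5), scenarioId = "toy",
           modelId = "t")
  counts <- integer(10)
  for (s in 1:500) {
    r <- records(sampleOccurrences(m, 3, seed = s))
    col <- r$x + 0.5
    row <- ifelse(r$y > 1, 1, 2)       # row 1 = top (y = 1.5)
    cell <- (col - 1) * 2 + row
    counts[cell] <- counts[cell] + 1
  }
  # chi-squared against the uniform expectation 500 * 3 / 10
  expect_gt(chisq.test(counts)$p.value, 0.01)
  # and every count within 3 binomial SDs of n/N
  expected <- 500 * 3 / 10
  sdBin <- sqrt(500 * 0.3 * 0.7)
  expect_true(all(abs(counts - expected) <= 3 * sdBin))
})
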
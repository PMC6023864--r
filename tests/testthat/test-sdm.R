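# SDM fitting, projection, evaluation, MESS.

test_that("background and pseudoabsence samples honor their contracts", {
  mask <- matrix(FALSE, 10, 10)
  mask[1, ] <- TRUE   # 90 unmasked cells
  st <- testStack(list(a = matrix(rnorm(100), 10, 10)), mask = mask)
  bg <- sampleBackground(st, fraction = 0.2, seed = 1)
  expect_equal(length(bg), 18L)  # floor(0.2 * 90)
  expect_identical(records(sampleBackground(st, 0.2, seed = 1)), records(bg))
  all1 <- sampleBackground(st, fraction = 1, seed = 2)
  expect_equal(length(all1), 90L)
  expect_equal(nrow(unique(records(all1)[, c("x", "y")])), 90L)

  pres <- testOcc(c(0.5, 1.5), c(0.5, 0.5))
  ps <- samplePseudoabsences(st, pres, n = 88, seed = 3)
  expect_equal(length(ps), 88L)
  presKey <- paste(records(pres)$x, records(pres)$y)
  expect_false(any(paste(records(ps)$x, records(ps)$y) %in% presKey))
  expect_error(samplePseudoabsences(st, pres, n = 89, seed = 3), "available")
  expect_equal(length(samplePseudoabsences(st, pres, seed = 4)), 2L)
})

test_that("weighted-background tables equalize presence and contrast mass", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 6))
  pres <- sampleOccurrences(trueSuitability(st, testNiche()), 30, seed = 1)
  bg <- sampleBackground(st, 0.5, seed = 2)
  tab <- buildTrainingTable(st, pres, bg, "background")
  d <- tab@data
  expect_equal(sum(d$weight[d$label == 1]), sum(d$weight[d$label == 0]))
  tabP <- buildTrainingTable(st, pres,
                             samplePseudoabsences(st, pres, seed = 3),
                             "pseudoabsence")
  expect_true(all(tabP@data$weight == 1))
})

test_that("the polynomial GLM recovers a known logistic slope", {
  set.seed(20)
  x <- rnorm(500)
  y <- rbinom(500, 1, plogis(2 * x))
  env <- matrix(x, dimnames = list(NULL, "bio4"))
  tab <- tableFromEnv(env, y)
  m <- fitSdmGlm(tab, degree = 1)
  slopeRaw <- m@fit$coefficients[2] / m@featureSpec$scale[["bio4_p1"]]
  expect_gt(slopeRaw, 0)
  expect_lt(abs(slopeRaw - 2), 0.5)
  # independent maximum-likelihood oracle on the same draw
  oracle <- glm(y ~ x, family = binomial)
  expect_equal(unname(slopeRaw), unname(coef(oracle)[2]), tolerance = 1e-6)
  expect_gt(fitMetric(m), 0)
})

test_that("an intercept-only GLM explains zero deviance", {
  set.seed(21)
  env <- matrix(rnorm(100), dimnames = list(NULL, "bio4"))
  tab <- tableFromEnv(env, rbinom(100, 1, 0.4))
  m <- fitSdmGlm(tab, degree = 0)
  expect_equal(unname(fitMetric(m)), 0)
})

test_that("row weights are equivalent to row duplication in the GLM", {
  set.seed(22)
  env <- matrix(rnorm(80), dimnames = list(NULL, "bio4"))
  y <- rbinom(80, 1, plogis(env[, 1]))
  dupTab <- tableFromEnv(rbind(env, env), c(y, y))
  wTab <- tableFromEnv(env, y, weight = rep(2, 80))
  expect_equal(fitSdmGlm(dupTab, 2)@fit$coefficients,
               fitSdmGlm(wTab, 2)@fit$coefficients, tolerance = 1e-8)
})

test_that("the random forest finds signal and ranks the driving variable", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 30))
  env <- allUnmaskedEnv(st)[1:500, ]
  # noiseless threshold on bio4
  y <- as.numeric(env[, "bio4"] > median(env[, "bio4"]))
  m <- fitSdmRf(tableFromEnv(env, y), nTrees = 300, seed = 1)
  expect_gt(unname(fitMetric(m)), 0.8)
  expect_equal(names(which.max(variableImportance(m))), "bio4")

  # labels independent of predictors: variance explained stays near zero
  ve <- vapply(1:10, function(s) {
    yr <- withr::with_seed(100 + s, rbinom(nrow(env), 1, 0.5))
    unname(fitMetric(fitSdmRf(tableFromEnv(env, yr), nTrees = 100, seed = s)))
  }, numeric(1))
  expect_lt(mean(ve), 0.1)

  # a constant variable has zero permutation importance
  envC <- cbind(env[, 1:2], const = 1)
  y2 <- as.numeric(env[, 1] > median(env[, 1]))
  mC <- fitSdmRf(tableFromEnv(envC, y2), nTrees = 100, seed = 2)
  expect_equal(unname(variableImportance(mC)["const"]), 0)
})

test_that("Maxent-style fit behaves at the regularization extremes", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 31))
  bgEnv <- allUnmaskedEnv(st)
  # presences drawn uniformly from the background: no discrimination
  set.seed(40)
  presEnv <- bgEnv[sample(nrow(bgEnv), 200), ]
  tab <- tableFromEnv(rbind(presEnv, bgEnv),
                      c(rep(1, 200), rep(0, nrow(bgEnv))),
                      contrastKind = "background")
  m0 <- fitSdmMaxent(tab)
  expect_lt(abs(unname(fitMetric(m0))), 0.05)

  # an overwhelming penalty forces every coefficient to exactly zero
  mBig <- fitSdmMaxent(tab, regMultiplier = 1e6)
  expect_true(all(mBig@fit$coefficients == 0))
  expect_equal(unname(fitMetric(mBig)), 0)

  # presences concentrated at high bio4: positive linear coefficient,
  # matching the sign of the presence/background mean difference
  ord <- order(bgEnv[, "bio4"], decreasing = TRUE)
  hi <- bgEnv[ord[1:100], ]
  tabHi <- tableFromEnv(rbind(hi, bgEnv),
                        c(rep(1, 100), rep(0, nrow(bgEnv))),
                        contrastKind = "background")
  mHi <- fitSdmMaxent(tabHi)
  expect_gt(mean(hi[, "bio4"]) - mean(bgEnv[, "bio4"]), 0)
  expect_gt(mHi@fit$coefficients[["bio4_lin"]], 0)
  expect_gt(unname(fitMetric(mHi)), 0.5)
})

test_that("hinge features are accepted and improve a step response", {
  st <- generateClimateStack(scenarioConfig(gridRows = 30, gridCols = 30,
                                            seed = 32))
  bgEnv <- allUnmaskedEnv(st)
  ord <- order(bgEnv[, "bio4"], decreasing = TRUE)
  tab <- tableFromEnv(rbind(bgEnv[ord[1:60], ], bgEnv),
                      c(rep(1, 60), rep(0, nrow(bgEnv))),
                      contrastKind = "background")
  mh <- fitSdmMaxent(tab, features = c("linear", "quadratic", "hinge"))
  expect_s4_class(mh, "SDMModel")
  expect_gt(unname(fitMetric(mh)), 0)
})

test_that("projection clamps out-of-range conditions to range-edge response", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 33))
  pres <- sampleOccurrences(trueSuitability(st, testNiche()), 60, seed = 1)
  # contrast covers every cell, so the training range spans the stack and
  # clamping on the training stack is a no-op
  tab <- buildTrainingTable(st, pres, sampleBackground(st, 1, seed = 2),
                            "background")
  m <- fitSdmGlm(tab)

  expect_equal(gridValues(projectModel(m, st, clamp = TRUE)),
               gridValues(projectModel(m, st, clamp = FALSE)))

  # a far-out-of-range cell predicts exactly like the range edge
  far <- st
  vars <- gridValues(far)
  sds <- apply(allUnmaskedEnv(st), 2, sd)
  for (v in names(vars)) vars[[v]][1, 1] <- variableRanges(m)["max", v] +
    10 * sds[[v]]
  edge <- st
  varsE <- gridValues(edge)
  for (v in names(varsE)) varsE[[v]][1, 1] <- variableRanges(m)["max", v]
  far@variables <- vars
  edge@variables <- varsE
  expect_equal(gridValues(projectModel(m, far, clamp = TRUE))[1, 1],
               gridValues(projectModel(m, edge, clamp = FALSE))[1, 1])

  # nodata propagates
  masked <- st
  masked@nodataMask[2, 2] <- TRUE
  expect_true(is.na(gridValues(projectModel(m, masked))[2, 2]))
  expect_error(projectModel(m, subsetVariables(st, c("bio4", "bio8"))),
               "bio9")
})

test_that("rank-based AUC equals the brute-force pairwise comparison", {
  expect_equal(aucScore(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(aucScore(c(3, 4), c(1, 2)), 1)
  expect_equal(aucScore(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(aucScore(numeric(0), 1), "non-empty")

  bruteForce <- function(pos, neg) {
    s <- 0
    for (p in pos) for (n in neg)
      s <- s + (p > n) + 0.5 * (p == n)
    s / (length(pos) * length(neg))
  }
  for (i in 1:25) {
    set.seed(i)
    pos <- round(rnorm(sample(1:120, 1)), 1)  # rounding forces ties
    neg <- round(rnorm(sample(1:80, 1)), 1)
    expect_equal(aucScore(pos, neg), bruteForce(pos, neg))
  }
})

test_that("bootstrap validation separates signal from noise and is seeded", {
  # perfectly separable data: AUC 1 for every algorithm
  set.seed(50)
  n <- 120
  x <- c(rnorm(n, 5, 0.3), rnorm(n, -5, 0.3))
  env <- cbind(bio4 = x, bio8 = rnorm(2 * n))
  tab <- tableFromEnv(env, rep(c(1, 0), each = n),
                      contrastKind = "background")
  for (alg in c("glm_poly", "random_forest", "maxent_like")) {
    ev <- suppressWarnings(
      bootstrapValidate(tab, alg, iterations = 5, seed = 1, nTrees = 50))
    expect_equal(ev@aucInternalMean, 1)
  }

  # labels shuffled against predictors: AUC near 0.5
  set.seed(51)
  env2 <- cbind(bio4 = rnorm(400), bio8 = rnorm(400))
  tab2 <- tableFromEnv(env2, sample(rep(c(1, 0), each = 200)))
  ev2 <- bootstrapValidate(tab2, "glm_poly", iterations = 20, seed = 2)
  expect_lt(abs(ev2@aucInternalMean - 0.5), 0.1)

  ev3 <- bootstrapValidate(tab2, "glm_poly", iterations = 20, seed = 2)
  expect_identical(ev2@aucInternalMean, ev3@aucInternalMean)
  expect_error(bootstrapValidate(tableFromEnv(env2[1:4, ], c(1, 1, 1, 0)),
                                 "glm_poly"), "infeasible split")
})

test_that("external validation scores maps at independent points", {
  vals <- matrix(seq(0, 1, length.out = 25), 5, 5)
  map <- new("SuitabilityMap", values = vals, cellSize = 1, origin = c(0, 0),
             nodataMask = matrix(FALSE, 5, 5), scenarioId = "s",
             modelId = "m")
  top <- which(vals >= sort(vals, decreasing = TRUE)[3], arr.ind = TRUE)
  pres <- testOcc(top[, "col"] - 0.5, 5 - top[, "row"] + 0.5, role = "fossil")
  contrast <- testOcc(rep(seq(0.5, 4.5), 5), rep(seq(0.5, 4.5), each = 5),
                      role = "background")
  expect_gt(externalValidate(map, pres, contrast), 0.9)

  flat <- map
  flat@values[] <- 0.4
  expect_equal(externalValidate(flat, pres, contrast), 0.5)
  off <- testOcc(99, 99)
  expect_error(externalValidate(map, off, contrast), "off the map")
})

test_that("MESS similarity follows the piecewise formula and flags novelty", {
  ref <- matrix(1:100, dimnames = list(NULL, "a"))
  st <- testStack(list(a = matrix(c(50.5, 30, 0.5, 101, 1, 100), 2, 3)))
  ms <- messSurface(st, ref)
  v <- messValues(ms)
  expect_equal(v[1, 1], 100)   # at the reference median
  expect_equal(v[2, 1], 58)    # f = 29 below 30 -> 2 * 29
  expect_lt(v[1, 2], 0)        # below the minimum: novel
  expect_lt(v[2, 2], 0)        # above the maximum: novel
  expect_equal(v[1, 3], 0)     # exactly at the minimum: f = 0 branch
  expect_equal(v[2, 3], 2)     # at the maximum: f = 99 -> 2 * (100 - 99)
})

test_that("MESS is negative exactly where a variable leaves its range", {
  for (s in 1:8) {
    set.seed(s)
    ref <- cbind(a = runif(40, -1, 1), b = rnorm(40))
    st <- testStack(list(a = matrix(runif(36, -2, 2), 6, 6),
                         b = matrix(rnorm(36, sd = 2), 6, 6)))
    ms <- messSurface(st, ref)
    out <- (gridValues(st)$a < min(ref[, "a"]) |
            gridValues(st)$a > max(ref[, "a"]) |
            gridValues(st)$b < min(ref[, "b"]) |
            gridValues(st)$b > max(ref[, "b"]))
    expect_equal(messValues(ms) < 0, out)
    # MoD names the minimum-similarity variable
    expect_true(all(modVariables(ms) %in% c("a", "b")))
  }
  # constant reference variable is excluded with a warning
  refC <- cbind(a = rep(1, 10), b = 1:10)
  st <- testStack(list(a = matrix(1, 2, 2), b = matrix(5, 2, 2)))
  expect_warning(ms <- messSurface(st, refC), "constant")
  expect_equal(ms@variables, "b")
})

test_that("cross-scenario projection is label-agnostic plumbing", {
  st <- generateClimateStack(scenarioConfig(gridRows = 30, gridCols = 30,
                                            seed = 60))
  sh <- shiftScenario(st, shiftSpec(c(0, 2, 2, 0, 0), c(1, 1, 1, 0.9, 0.9)),
                      "paleo")
  mk <- function(stack) {
    pres <- sampleOccurrences(trueSuitability(stack, testNiche()), 40,
                              seed = 1)
    fitSdmGlm(buildTrainingTable(
      stack, pres, samplePseudoabsences(stack, pres, seed = 2),
      "pseudoabsence"))
  }
  mA <- mk(st); mB <- mk(sh)
  abMap <- projectModel(mA, sh)
  baMap <- projectModel(mB, st)
  relabeled <- sh
  relabeled@scenarioId <- "other-name"
  expect_equal(gridValues(projectModel(mA, relabeled)), gridValues(abMap))
  expect_s4_class(baMap, "SuitabilityMap")
})
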
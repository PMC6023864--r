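# Environmental-space framework: PCA, occupancy grids, overlap and
# randomization tests, niche dynamics.

test_that("the pooled PCA is orthonormal, analytic and pooling-invariant", {
  # two variables with exact sample correlation r: top eigenvalue share
  # of the correlation matrix is (1 + r) / 2
  st <- correlatedStack(rbind(c(1, 0.6), c(0.6, 1)), n = 60, seed = 1)
  pca <- fitGlobalPCA(list(st))
  L <- pca@loadings
  expect_equal(crossprod(L), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(pca@varianceFraction[1], 0.8, tolerance = 1e-6)

  # duplicating a scenario leaves the pooled space unchanged
  pca2 <- fitGlobalPCA(list(st, st))
  expect_equal(pca2@loadings, pca@loadings)
  expect_equal(pca2@center, pca@center)
  expect_equal(pca2@varianceFraction, pca@varianceFraction)

  flat <- testStack(list(a = matrix(1, 10, 10), b = matrix(rnorm(100), 10, 10)))
  expect_error(fitGlobalPCA(list(flat)), "constant")
})

test_that("occupancy grids localize point niches and flatten uniform ones", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 2))
  bg <- allUnmaskedEnv(st)
  pca <- fitGlobalPCA(list(st))

  # all occurrences at one environment: z peaks at its grid cell
  one <- bg[rep(7, 10), , drop = FALSE]
  g1 <- buildNicheGrid(pca, one, bg, resolution = 60)
  peak <- which(occupancy(g1) == 1, arr.ind = TRUE)
  sc <- pcaScores(pca, one)[1, ]
  ax1 <- seq(gridExtent(g1)[1, 1], gridExtent(g1)[2, 1], length.out = 60)
  ax2 <- seq(gridExtent(g1)[1, 2], gridExtent(g1)[2, 2], length.out = 60)
  expect_lt(abs(ax1[peak[1, 1]] - sc[1]), diff(range(ax1)) / 10)
  expect_lt(abs(ax2[peak[1, 2]] - sc[2]), diff(range(ax2)) / 10)

  # occurrences identical to the background sample: flat occupancy
  set.seed(3)
  occ <- bg[sample(nrow(bg), 1000), ]
  g2 <- buildNicheGrid(pca, occ, occ, resolution = 60)
  zPos <- occupancy(g2)[occupancy(g2) > 0]
  expect_lt(sd(zPos) / mean(zPos), 0.15)
  expect_error(buildNicheGrid(pca, bg[1:3, ], bg), "at least 5")
})

test_that("Schoener's D hits its printed bounds and the brute-force formula", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 4))
  bg <- allUnmaskedEnv(st)
  pca <- fitGlobalPCA(list(st))
  occ <- occEnvFrom(st, testNiche(), 80, seed = 5)
  g <- buildNicheGrid(pca, occ, bg)
  expect_identical(schoenerD(g, g), 1)          # identical niches

  # disjoint supports: zero overlap
  a <- gridFromZ(rbind(c(1, 0), c(0, 0)) * 0.7)
  b <- gridFromZ(rbind(c(0, 0), c(0, 1)) * 0.3)
  expect_equal(schoenerD(a, b), 0)

  # 4-cell worked case: p_a = (.5,.5,0,0), p_b = (0,.5,.5,0) -> D = 0.5
  pa <- gridFromZ(matrix(c(0.5, 0.5, 0, 0), 2, 2))
  pb <- gridFromZ(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(schoenerD(pa, pb), 0.5)
  expect_error(schoenerD(pa, randomZGrid(3, 1)), "share extent")
})

test_that("D is symmetric, bounded and matches a direct sum on random grids", {
  for (s in 1:10) {
    R <- sample(3:10, 1)
    a <- randomZGrid(R, seed = s)
    b <- randomZGrid(R, seed = 100 + s)
    d <- schoenerD(a, b)
    expect_equal(d, schoenerD(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    pa <- occupancy(a) / sum(occupancy(a))
    pb <- occupancy(b) / sum(occupancy(b))
    direct <- 0
    for (i in seq_len(R)) for (j in seq_len(R))
      direct <- direct + abs(pa[i, j] - pb[i, j])
    expect_equal(d, 1 - direct / 2)
    expect_equal(schoenerD(a, a), 1)
  }
})

test_that("grid resolution barely moves D (stability property)", {
  st <- generateClimateStack(scenarioConfig(gridRows = 50, gridCols = 50,
                                            seed = 6))
  sh <- shiftScenario(st, shiftSpec(c(0, 2, 2, 0, 0), c(1, 1, 1, 0.9, 0.9)),
                      "p")
  pca <- fitGlobalPCA(list(st, sh))
  a <- occEnvFrom(st, testNiche(), 100, seed = 7)
  b <- occEnvFrom(sh, testNiche(), 100, seed = 8)
  bgA <- allUnmaskedEnv(st); bgB <- allUnmaskedEnv(sh)
  ext <- pooledExtent(pca, bgA, bgB)
  dAt <- function(R) {
    schoenerD(buildNicheGrid(pca, a, bgA, resolution = R, extent = ext),
              buildNicheGrid(pca, b, bgB, resolution = R, extent = ext))
  }
  expect_lt(abs(dAt(100) - dAt(200)), 0.02)
})

test_that("equivalency of a dataset with itself is never rejected", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 9))
  bg <- allUnmaskedEnv(st)
  pca <- fitGlobalPCA(list(st))
  occ <- occEnvFrom(st, testNiche(), 40, seed = 10)
  eq <- equivalencyTest(occ, occ, bg, bg, pca, replicates = 50, seed = 1)
  expect_equal(eq$observedD, 1)
  expect_equal(eq$p, 1)
  eq2 <- equivalencyTest(occ, occ, bg, bg, pca, replicates = 50, seed = 1)
  expect_identical(eq$null, eq2$null)
  expect_error(equivalencyTest(occ, occ, bg, bg, pca, replicates = 0),
               "replicates")
})

test_that("similarity detects co-located niches and is seed-stable", {
  st <- generateClimateStack(scenarioConfig(gridRows = 50, gridCols = 50,
                                            seed = 11))
  bg <- allUnmaskedEnv(st)
  pca <- fitGlobalPCA(list(st))
  # both entities concentrated at the same climate: strongly similar
  hits <- 0L
  for (i in 1:12) {
    a <- occEnvFrom(st, testNiche(), 100, seed = 500 + 2 * i)
    b <- occEnvFrom(st, testNiche(), 100, seed = 501 + 2 * i)
    gA <- buildNicheGrid(pca, a, bg)
    p <- similarityTest(gA, b, bg, pca, replicates = 100, seed = i)$p
    hits <- hits + (p <= 0.05)
  }
  expect_gte(hits, 9L)

  a <- occEnvFrom(st, testNiche(), 50, seed = 600)
  gA <- buildNicheGrid(pca, a, bg)
  b <- occEnvFrom(st, testNiche(), 50, seed = 601)
  s1 <- similarityTest(gA, b, bg, pca, replicates = 40, seed = 3)
  s2 <- similarityTest(gA, b, bg, pca, replicates = 40, seed = 3)
  expect_identical(s1$null, s2$null)
  # the centroid-shift null variant runs and returns a valid p
  s3 <- similarityTest(gA, b, bg, pca, replicates = 20, seed = 4,
                       nullModel = "shift")
  expect_gt(s3$p, 0); expect_lte(s3$p, 1)
  expect_error(similarityTest(gA, bg, bg[1:10, ], pca, seed = 1),
               "background")
})

test_that("niche dynamics honor their identities", {
  g <- randomZGrid(8, seed = 20)
  expect_equal(nicheDynamics(g, g),
               c(expansion = 0, stability = 1, unfilling = 0))

  # disjoint occupied blocks inside a shared analogue region
  a <- randomZGrid(8, seed = 21, rows = 1:3, cols = 1:3)
  b <- randomZGrid(8, seed = 22, rows = 6:8, cols = 6:8)
  dyn <- nicheDynamics(a, b)
  expect_equal(unname(dyn["expansion"]), 1)
  expect_equal(unname(dyn["stability"]), 0)
  expect_equal(unname(dyn["unfilling"]), 1)

  # expansion + stability = 1 exactly, on arbitrary pairs
  for (s in 1:10) {
    x <- randomZGrid(6, seed = 30 + s)
    y <- randomZGrid(6, seed = 60 + s)
    d <- nicheDynamics(x, y)
    expect_identical(unname(d["expansion"] + d["stability"]), 1)
  }

  empty <- gridFromZ(matrix(0.5, 4, 4))
  empty@e[] <- 0
  expect_error(nicheDynamics(empty, gridFromZ(matrix(0.5, 4, 4))),
               "analogue")
})

test_that("centroid shifts recover translations in score space", {
  st <- generateClimateStack(scenarioConfig(gridRows = 40, gridCols = 40,
                                            seed = 40))
  bg <- allUnmaskedEnv(st)
  pca <- fitGlobalPCA(list(st))
  occ <- occEnvFrom(st, testNiche(), 150, seed = 41)
  ext <- pooledExtent(pca, bg)
  ext[1, ] <- ext[1, ] - 1; ext[2, ] <- ext[2, ] + 1  # room to translate
  g <- buildNicheGrid(pca, occ, bg, extent = ext)
  expect_equal(centroidShift(g, g)$occShift, c(0, 0), tolerance = 1e-9)
  expect_equal(centroidShift(g, g)$envShift, c(0, 0), tolerance = 1e-9)

  # translate occurrences by t in PC space via the loading pseudo-inverse
  t0 <- c(0.6, -0.4)
  delta <- drop(pca@loadings %*% t0) * pca@scale
  occT <- sweep(occ, 2, delta, `+`)
  gT <- buildNicheGrid(pca, occT, bg, extent = ext,
                       bandwidthO = g@bandwidth)
  cellDiag <- (ext[2, ] - ext[1, ]) / 99
  shift <- centroidShift(g, gT)$occShift
  expect_lt(abs(shift[1] - t0[1]), cellDiag[1] * 2)
  expect_lt(abs(shift[2] - t0[2]), cellDiag[2] * 2)
  # e identical, o different: environment centroid fixed
  expect_equal(centroidShift(g, gT)$envShift, c(0, 0), tolerance = 1e-9)
})
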
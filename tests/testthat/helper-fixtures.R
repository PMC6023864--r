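# Shared fixtures: all test data are generated in code.

# Specialist Gaussian niche matching the generator's default baselines.
testNiche <- function() {
  nicheTruth(optimum = c(6300, 14, 20, 95, 320),
             tolerance = c(600, 3.5, 4, 25, 65),
             maxPrevalence = 0.9)
}

# Build a ClimateStack directly from matrices.
testStack <- function(vars, cellSize = 1, origin = c(0, 0), mask = NULL,
                      scenarioId = "test") {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(vars[[1]]), ncol(vars[[1]]))
  new("ClimateStack", variables = vars, cellSize = cellSize,
      origin = origin, nodataMask = mask, scenarioId = scenarioId)
}

# Stack whose variables have an exact target sample correlation.
correlatedStack <- function(C, n = 120, seed = 1,
                            labels = paste0("v", seq_len(nrow(C)))) {
  cfg <- scenarioConfig(gridRows = n, gridCols = n, variableNames = labels,
                        autocorrLength = 0, crossCorrelation = C,
                        baselineMean = rep(0, nrow(C)),
                        baselineSd = rep(1, nrow(C)), seed = seed)
  generateClimateStack(cfg)
}

# OccurrenceSet from bare coordinates.
testOcc <- function(x, y, role = "presence", period = "current") {
  new("OccurrenceSet",
      records = data.frame(x = x, y = y, role = role, period = period,
                           stringsAsFactors = FALSE),
      crsNote = "test")
}

# A NicheGrid built directly from an occupancy matrix (uniform e).
gridFromZ <- function(z, extent = rbind(c(0, 0), c(1, 1))) {
  R <- nrow(z)
  new("NicheGrid", resolution = as.integer(R), extent = extent,
      o = z, e = matrix(1, R, R), z = z / max(z, 1e-12),
      bandwidth = c(0.1, 0.1), entityId = "t", scenarioId = "t")
}

# Random occupancy grid with a contiguous support block.
randomZGrid <- function(R, seed, rows = seq_len(R), cols = seq_len(R)) {
  z <- matrix(0, R, R)
  set.seed(seed)
  z[rows, cols] <- matrix(runif(length(rows) * length(cols)),
                          length(rows), length(cols))
  gridFromZ(z)
}

# Training table assembled straight from data (bypasses raster lookup).
tableFromEnv <- function(env, label, weight = rep(1, length(label)),
                         contrastKind = "pseudoabsence") {
  d <- as.data.frame(env)
  d$label <- label
  d$weight <- weight
  rng <- rbind(min = apply(env, 2, min), max = apply(env, 2, max))
  deg <- rng["max", ] <= rng["min", ]
  rng["max", deg] <- rng["min", deg] + 1e-9
  new("TrainingTable", data = d, contrastKind = contrastKind,
      variableRanges = rng, variables = colnames(env))
}

# Environments of a thinned occurrence sample drawn under `niche`.
occEnvFrom <- function(stack, niche, n, seed, role = "presence") {
  occ <- sampleOccurrences(trueSuitability(stack, niche), n, seed = seed,
                           role = role)
  extractStackEnv(stack, occ)
}

# Public-surface-free accessor used across tests: environment values at
# occurrence cells, via an exported projection round trip is overkill, so
# reach the internal helper once here.
extractStackEnv <- function(stack, occ) {
  paleoniche:::extractEnv(stack, occ)
}

allUnmaskedEnv <- function(stack) paleoniche:::unmaskedEnv(stack)$env

pooledExtent <- function(pca, ...) {
  paleoniche:::scoreExtent(do.call(rbind, lapply(list(...), function(e)
    pcaScores(pca, e))))
}
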
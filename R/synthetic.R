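## Synthetic climate scenarios and species with a known Gaussian niche.
##
## The generator emulates the structure of bioclimatic raster stacks
## (spatially autocorrelated, cross-correlated fields) and of occurrence /
## fossil samples drawn from a niche-response truth, so that every
## downstream stage (thinning, SDM fitting, transferability, overlap
## tests) can be validated against a known answer.

#' Default cross-correlation among the five default bioclimatic variables
#'
#' Temperature variables (bio4, bio8, bio9) are mildly positively
#' correlated among themselves, precipitation variables (bio18, bio19)
#' likewise, with a mild negative temperature-precipitation correlation —
#' the qualitative structure of Mediterranean climate layers.
#'
#' @return 5 x 5 positive-definite correlation matrix.
#' @export
defaultCrossCorrelation <- function() {
  v <- c("bio4", "bio8", "bio9", "bio18", "bio19")
  C <- matrix(c(
    1.0,  0.3,  0.3, -0.2, -0.2,
    0.3,  1.0,  0.3, -0.2, -0.2,
    0.3,  0.3,  1.0, -0.2, -0.2,
   -0.2, -0.2, -0.2,  1.0,  0.4,
   -0.2, -0.2, -0.2,  0.4,  1.0), 5, 5, dimnames = list(v, v))
  C
}

#' Scenario configuration for the synthetic climate generator
#'
#' @param gridRows,gridCols grid shape; gridRows * gridCols must be >= 100.
#' @param variableNames variable labels; defaults to the five bioclimatic
#'   variables used throughout (temperature seasonality bio4, mean
#'   temperature of the wettest/driest quarter bio8/bio9, precipitation of
#'   the warmest/coldest quarter bio18/bio19).
#' @param autocorrLength spatial autocorrelation length in cells (Gaussian
#'   smoothing kernel SD); 0 disables smoothing.
#' @param crossCorrelation symmetric positive semi-definite correlation
#'   matrix with unit diagonal, one row/column per variable.
#' @param baselineMean,baselineSd per-variable mean and SD of the generated
#'   fields, in variable units. Defaults are Iberian-like magnitudes
#'   (bio4 in SD-of-temperature x 100 units; bio8/bio9 in degrees C;
#'   bio18/bio19 in mm).
#' @param gradient per-variable linear north-south trend added after
#'   correlation mixing (units per cell); nonzero values perturb the
#'   realized cross-correlations. Default 0.
#' @param seed integer RNG seed; generation is deterministic given it.
#' @return validated list of class used by [generateClimateStack()].
#' @export
scenarioConfig <- function(gridRows = 120L, gridCols = 120L,
                           variableNames = c("bio4", "bio8", "bio9",
                                             "bio18", "bio19"),
                           autocorrLength = 6,
                           crossCorrelation = NULL,
                           baselineMean = NULL, baselineSd = NULL,
                           gradient = NULL,
                           seed = 1L) {
  p <- length(variableNames)
  if (gridRows * gridCols < 100)
    stop("grid must have at least 100 cells")
  if (autocorrLength < 0) stop("autocorrLength must be >= 0")
  if (is.null(crossCorrelation)) {
    crossCorrelation <-
      if (p == 5 && identical(variableNames,
                              c("bio4", "bio8", "bio9", "bio18", "bio19")))
        defaultCrossCorrelation() else diag(p)
  }
  crossCorrelation <- as.matrix(crossCorrelation)
  if (!isTRUE(all.equal(crossCorrelation, t(crossCorrelation), tolerance = 1e-8)))
    stop("crossCorrelation must be symmetric")
  if (any(abs(diag(crossCorrelation) - 1) > 1e-8))
    stop("crossCorrelation must have unit diagonal")
  ev <- eigen(crossCorrelation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("crossCorrelation must be positive semi-definite; smallest ",
         "eigenvalue = ", format(min(ev)))
  if (nrow(crossCorrelation) != p)
    stop("crossCorrelation dimension must match variableNames")
  defaults <- list(
    mean = c(bio4 = 5500, bio8 = 12, bio9 = 17, bio18 = 70, bio19 = 250),
    sd   = c(bio4 = 900,  bio8 = 5,  bio9 = 6,  bio18 = 35, bio19 = 90)
  )
  if (is.null(baselineMean))
    baselineMean <- ifelse(variableNames %in% names(defaults$mean),
                           defaults$mean[variableNames], 0)
  if (is.null(baselineSd))
    baselineSd <- ifelse(variableNames %in% names(defaults$sd),
                         defaults$sd[variableNames], 1)
  if (is.null(gradient)) gradient <- numeric(p)
  stopifnot(length(baselineMean) == p, length(baselineSd) == p,
            length(gradient) == p, all(baselineSd > 0))
  structure(list(
    gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
    variableNames = variableNames, autocorrLength = autocorrLength,
    crossCorrelation = crossCorrelation,
    baselineMean = as.numeric(baselineMean),
    baselineSd = as.numeric(baselineSd),
    gradient = as.numeric(gradient),
    seed = as.integer(seed)
  ), class = "ScenarioConfig")
}

#' Gaussian niche-response truth
#'
#' Ground-truth suitability s(x) = maxPrevalence *
#' exp(-1/2 * sum_j ((x_j - optimum_j) / tolerance_j)^2).
#'
#' @param optimum per-variable niche optimum (variable units).
#' @param tolerance strictly positive per-variable niche breadth (same units).
#' @param maxPrevalence suitability at the optimum, in (0, 1].
#' @export
nicheTruth <- function(optimum, tolerance, maxPrevalence = 0.9) {
  if (length(optimum) != length(tolerance))
    stop("optimum and tolerance lengths must match")
  if (any(tolerance <= 0)) stop("tolerance must be strictly positive")
  if (maxPrevalence <= 0 || maxPrevalence > 1)
    stop("maxPrevalence must lie in (0, 1]")
  structure(list(optimum = as.numeric(optimum),
                 tolerance = as.numeric(tolerance),
                 maxPrevalence = maxPrevalence),
            class = "NicheTruth")
}

#' Scenario-to-scenario climate offset
#'
#' Cellwise transform value' = value * multiplicativeFactor + additiveOffset,
#' e.g. a Last Interglacial analogue of +3.8 degrees C on temperature and a
#' 16% precipitation decrease relative to current climate.
#'
#' @param additiveOffset per-variable additive offset (variable units).
#' @param multiplicativeFactor positive per-variable factor (dimensionless).
#' @export
shiftSpec <- function(additiveOffset, multiplicativeFactor) {
  if (length(additiveOffset) != length(multiplicativeFactor))
    stop("additiveOffset and multiplicativeFactor lengths must match")
  if (any(multiplicativeFactor <= 0))
    stop("multiplicativeFactor must be positive")
  structure(list(additiveOffset = as.numeric(additiveOffset),
                 multiplicativeFactor = as.numeric(multiplicativeFactor)),
            class = "ShiftSpec")
}

# Gaussian low-pass filter of a white-noise field via FFT (circular).
smoothField <- function(field, sdCells) {
  if (sdCells <= 0) return(field)
  nr <- nrow(field); nc <- ncol(field)
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- outer(exp(-0.5 * (dr / sdCells)^2), exp(-0.5 * (dc / sdCells)^2))
  k <- k / sum(k)
  Re(fft(fft(field) * fft(k), inverse = TRUE)) / (nr * nc)
}

#' Generate a synthetic multi-variable climate stack
#'
#' Seeded Gaussian white noise per variable is low-pass filtered to the
#' requested autocorrelation length, the fields are empirically
#' orthogonalized (QR) and linearly mixed by the Cholesky factor of the
#' cross-correlation matrix, so the sample correlations match the target
#' essentially exactly, then scaled to the per-variable baselines.
#'
#' @param config a [scenarioConfig()].
#' @param scenarioId label stored on the stack.
#' @return a \linkS4class{ClimateStack}; deterministic given config$seed.
#' @export
generateClimateStack <- function(config, scenarioId = "current") {
  stopifnot(inherits(config, "ScenarioConfig"))
  nr <- config$gridRows; nc <- config$gridCols
  p <- length(config$variableNames)
  n <- nr * nc
  fields <- withSeed(config$seed, {
    lapply(seq_len(p), function(j)
      smoothField(matrix(rnorm(n), nr, nc), config$autocorrLength))
  })
  X <- vapply(fields, as.vector, numeric(n))
  X <- scale(X, center = TRUE, scale = FALSE)
  qrX <- qr(X)
  Q <- qr.Q(qrX)
  # fix signs so decomposition (and hence output) is reproducible
  sgn <- sign(diag(qr.R(qrX)))
  sgn[sgn == 0] <- 1
  Q <- sweep(Q, 2, sgn, `*`)
  Q <- Q * sqrt(n - 1)                     # columns: mean 0, sd 1, orthogonal
  Z <- Q %*% chol(config$crossCorrelation) # sample correlation = target
  vars <- vector("list", p)
  names(vars) <- config$variableNames
  rowTrend <- (nr - seq_len(nr)) # increases southward -> northward trend sign
  for (j in seq_len(p)) {
    m <- matrix(Z[, j], nr, nc) * config$baselineSd[j] + config$baselineMean[j]
    if (config$gradient[j] != 0)
      m <- m + config$gradient[j] * rowTrend
    vars[[j]] <- m
  }
  new("ClimateStack", variables = vars, cellSize = 1,
      origin = c(0, 0), nodataMask = matrix(FALSE, nr, nc),
      scenarioId = scenarioId)
}

#' Apply a climate offset to a stack
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param spec a [shiftSpec()] with one entry per stack variable.
#' @param scenarioId label for the shifted stack.
#' @return stack with cellwise value' = value * factor + offset; geometry
#'   unchanged.
#' @export
shiftScenario <- function(stack, spec, scenarioId = paste0(scenarioId0(stack), "_shifted")) {
  stopifnot(inherits(spec, "ShiftSpec"))
  vars <- gridValues(stack)
  if (length(spec$additiveOffset) != length(vars))
    stop("shift spec length (", length(spec$additiveOffset),
         ") does not match number of variables (", length(vars), ")")
  out <- mapply(function(m, f, a) m * f + a, vars,
                spec$multiplicativeFactor, spec$additiveOffset,
                SIMPLIFY = FALSE)
  names(out) <- names(vars)
  initialize(stack, variables = out, scenarioId = scenarioId)
}

scenarioId0 <- function(stack) stack@scenarioId

#' Ground-truth suitability under a Gaussian niche
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param niche a [nicheTruth()] with dimensions matching the stack.
#' @return a \linkS4class{SuitabilityMap} with values in
#'   [0, maxPrevalence]; the maximum is attained where every variable
#'   equals its optimum.
#' @export
trueSuitability <- function(stack, niche) {
  stopifnot(inherits(niche, "NicheTruth"))
  vars <- gridValues(stack)
  if (length(niche$optimum) != length(vars))
    stop("niche dimensions do not match stack variables")
  q <- 0
  for (j in seq_along(vars))
    q <- q + ((vars[[j]] - niche$optimum[j]) / niche$tolerance[j])^2
  s <- niche$maxPrevalence * exp(-0.5 * q)
  s[nodataMask(stack)] <- NA_real_
  new("SuitabilityMap", values = s, cellSize = cellSize(stack),
      origin = gridOrigin(stack), nodataMask = nodataMask(stack),
      scenarioId = scenarioId(stack), modelId = "truth")
}

#' Sample occurrence records proportional to suitability
#'
#' Draws n distinct cells without replacement with probability
#' proportional to suitability; records are placed at cell centers.
#'
#' @param suit a \linkS4class{SuitabilityMap}.
#' @param n number of records.
#' @param seed RNG seed.
#' @param role record role label (default "presence").
#' @param period period label (default the map's scenario id).
#' @return an \linkS4class{OccurrenceSet}; deterministic given seed.
#' @export
sampleOccurrences <- function(suit, n, seed, role = "presence",
                              period = suit@scenarioId) {
  v <- gridValues(suit)
  ok <- which(!nodataMask(suit) & !is.na(v) & v > 0)
  if (length(ok) < n)
    stop("requested ", n, " records but only ", length(ok),
         " cells have positive suitability")
  pick <- withSeed(seed, safeSample(ok, n, prob = v[ok]))
  d <- dim(v)
  row <- ((pick - 1) %% d[1]) + 1L
  col <- ((pick - 1) %/% d[1]) + 1L
  newOccurrenceSet(
    x = colCenters(d[2], suit@cellSize, suit@origin)[col],
    y = rowCenters(d[1], suit@cellSize, suit@origin)[row],
    role = role, period = period)
}
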
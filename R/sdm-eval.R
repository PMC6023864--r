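## Projection with clamping, AUC evaluation (bootstrap + independent
## presences), and MESS/MoD extrapolation surfaces.

#' Bootstrap evaluation report
#'
#' @slot aucInternalMean,aucInternalSd mean and SD of test AUC over the
#'   iterative data partitions.
#' @slot aucExternal named vector of independent-presence AUCs per target
#'   scenario (may be empty until cross-scenario validation runs).
#' @slot nIterations,testFraction partitioning settings.
#' @exportClass EvalReport
setClass("EvalReport",
  representation(
    aucInternalMean = "numeric",
    aucInternalSd = "numeric",
    aucExternal = "numeric",
    nIterations = "integer",
    testFraction = "numeric",
    algorithm = "character",
    contrastKind = "character"
  )
)

setValidity("EvalReport", function(object) {
  aucs <- c(object@aucInternalMean, object@aucExternal)
  if (any(aucs < -1e-9 | aucs > 1 + 1e-9)) return("AUC values must lie in [0, 1]")
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s/%s]: internal AUC %.3f +/- %.3f (%d x %d%%-test)\n",
    object@algorithm, object@contrastKind, object@aucInternalMean,
    object@aucInternalSd, object@nIterations,
    round(100 * object@testFraction)))
  if (length(object@aucExternal))
    cat("  external AUC:",
        paste(sprintf("%s = %.3f", names(object@aucExternal),
                      object@aucExternal), collapse = ", "), "\n")
})

#' MESS / most-dissimilar-variable result
#'
#' @slot mess similarity surface (percent units; negative = novel
#'   conditions, i.e. at least one variable out of the reference range).
#' @slot mod integer grid indexing `variables`: the most dissimilar
#'   (minimum-similarity) variable per cell, ties to the first variable
#'   in stack order.
#' @exportClass MessResult
setClass("MessResult",
  representation(
    mess = "matrix",
    mod = "matrix",
    variables = "character",
    scenarioId = "character"
  )
)

setMethod("show", "MessResult", function(object) {
  novel <- sum(object@mess < 0, na.rm = TRUE)
  cat(sprintf("MessResult (%s): %d novel cell(s); MoD counts:\n",
              object@scenarioId, novel))
  print(table(factor(object@variables[object@mod],
                     levels = object@variables)))
})

## ---- prediction ----------------------------------------------------------

# Predict suitability for an environment matrix (rows = cells/points,
# columns >= model variables). With clamp = TRUE each variable is
# truncated to its training range first.
predictEnv <- function(model, env, clamp = TRUE) {
  missing <- setdiff(model@variables, colnames(env))
  if (length(missing))
    stop("environment lacks model variable(s): ",
         paste(missing, collapse = ", "))
  env <- env[, model@variables, drop = FALSE]
  if (clamp) {
    rng <- model@variableRanges
    for (j in seq_len(ncol(env)))
      env[, j] <- pmin(pmax(env[, j], rng["min", j]), rng["max", j])
  }
  switch(model@algorithm,
    glm_poly = {
      X <- polyFeatures(env, model@featureSpec)
      stats::plogis(drop(cbind(1, X) %*% model@fit$coefficients))
    },
    random_forest = {
      p <- stats::predict(model@fit, newdata = as.data.frame(env))
      pmin(pmax(p, 0), 1)
    },
    maxent_like = {
      F <- maxentFeatures(env, model@featureSpec)
      stats::plogis(drop(F %*% model@fit$coefficients))
    },
    stop("unknown algorithm"))
}

#' Project a fitted SDM onto a climate scenario
#'
#' With clamp = TRUE (the default for cross-scenario transfers) each
#' variable is truncated to its training range before prediction, so
#' conditions beyond the calibration range receive the range-edge
#' response rather than an uncontrolled extrapolation.
#'
#' @param model an \linkS4class{SDMModel}.
#' @param stack target \linkS4class{ClimateStack} containing all model
#'   variables.
#' @param clamp truncate variables to the training range (default TRUE).
#' @param modelId label for the output map.
#' @return a \linkS4class{SuitabilityMap} (nodata where the stack is masked).
#' @export
projectModel <- function(model, stack, clamp = TRUE,
                         modelId = model@algorithm) {
  u <- unmaskedEnv(stack)
  p <- predictEnv(model, u$env, clamp = clamp)
  d <- dim(nodataMask(stack))
  vals <- matrix(NA_real_, d[1], d[2])
  vals[cbind(u$row, u$col)] <- p
  new("SuitabilityMap", values = vals, cellSize = cellSize(stack),
      origin = gridOrigin(stack), nodataMask = nodataMask(stack),
      scenarioId = scenarioId(stack), modelId = modelId)
}

## ---- AUC -----------------------------------------------------------------

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random positive outscores a random negative, ties
#' counting one half; equals the normalized Mann-Whitney U statistic.
#'
#' @param posScores scores at presences.
#' @param negScores scores at contrast points.
#' @return AUC in [0, 1].
#' @export
aucScore <- function(posScores, negScores) {
  if (!length(posScores) || !length(negScores))
    stop("both score vectors must be non-empty")
  np <- length(posScores); nn <- length(negScores)
  r <- rank(c(posScores, negScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Iterative data-partitioning (bootstrap) validation
#'
#' Repeats a stratified random 40/60 (by default) test/train split of the
#' training table, refits the algorithm on the training part, and scores
#' the test part with AUC; reports the mean and SD over iterations.
#'
#' @param table a \linkS4class{TrainingTable}.
#' @param algorithm one of "glm_poly", "random_forest", "maxent_like".
#' @param iterations number of partitions (default 20).
#' @param testFraction fraction held out per iteration (default 0.4).
#' @param seed RNG seed (split sequence is deterministic given it).
#' @param ... forwarded to [fitSdm()].
#' @return an \linkS4class{EvalReport}.
#' @export
bootstrapValidate <- function(table, algorithm, iterations = 20L,
                              testFraction = 0.4, seed = 1L, ...) {
  d <- table@data
  presIdx <- which(d$label == 1)
  contIdx <- which(d$label == 0)
  nPresTest <- round(testFraction * length(presIdx))
  nContTest <- round(testFraction * length(contIdx))
  if (nPresTest < 1 || nContTest < 1 ||
      nPresTest >= length(presIdx) || nContTest >= length(contIdx))
    stop("infeasible split: each part needs >= 1 presence and >= 1 contrast")
  aucs <- withSeed(seed, vapply(seq_len(iterations), function(i) {
    testP <- safeSample(presIdx, nPresTest)
    testC <- safeSample(contIdx, nContTest)
    test <- c(testP, testC)
    trainTab <- tableFromData(d[-test, , drop = FALSE], table@variables,
                              table@contrastKind)
    m <- fitSdm(trainTab, algorithm = algorithm,
                seed = sample.int(2^30, 1), ...)
    env <- as.matrix(d[test, table@variables, drop = FALSE])
    p <- predictEnv(m, env, clamp = FALSE)
    lab <- d$label[test]
    aucScore(p[lab == 1], p[lab == 0])
  }, numeric(1)))
  new("EvalReport",
      aucInternalMean = mean(aucs), aucInternalSd = stats::sd(aucs),
      aucExternal = numeric(0), nIterations = as.integer(iterations),
      testFraction = testFraction, algorithm = algorithm,
      contrastKind = table@contrastKind)
}

#' Independent-presence (external) AUC of a projected map
#'
#' Scores the map at an independent presence set (e.g. fossil records in
#' the target scenario) against a contrast sample drawn in that scenario,
#' and returns the rank-based AUC. A constant map yields 0.5 (all ties).
#'
#' @param map a \linkS4class{SuitabilityMap}.
#' @param independentPresences presence \linkS4class{OccurrenceSet}.
#' @param contrast contrast \linkS4class{OccurrenceSet} in the target
#'   scenario.
#' @return AUC in [0, 1].
#' @export
externalValidate <- function(map, independentPresences, contrast) {
  lookup <- function(occ, what) {
    r <- records(occ)
    d <- dim(map@values)
    rc <- pointToCell(r$x, r$y, d[1], d[2], map@cellSize, map@origin)
    off <- is.na(rc$row)
    if (any(off))
      stop(what, " record(s) off the map grid: rows ",
           paste(which(off), collapse = ", "))
    v <- map@values[cbind(rc$row, rc$col)]
    if (any(is.na(v)))
      stop(what, " record(s) on masked cells: rows ",
           paste(which(is.na(v)), collapse = ", "))
    v
  }
  aucScore(lookup(independentPresences, "presence"),
           lookup(contrast, "contrast"))
}

## ---- MESS / MoD ----------------------------------------------------------

# Similarity of value v to a reference sample (percent units), given
# f = 100 * (#reference < v) / N and the reference min/max.
messSimilarity <- function(v, refSorted) {
  N <- length(refSorted)
  lo <- refSorted[1]; hi <- refSorted[N]
  cnt <- findInterval(v, refSorted, left.open = TRUE)
  # left.open counts reference values strictly below v... verify: for
  # sorted vec, findInterval(x, vec, left.open = TRUE) returns
  # #{vec[i] < x}; ties are excluded from the count.
  f <- 100 * cnt / N
  s <- numeric(length(v))
  rangeRef <- hi - lo
  iz <- f == 0
  ih <- f == 100
  im <- f > 0 & f <= 50
  iu <- f > 50 & f < 100
  s[iz] <- 100 * (v[iz] - lo) / rangeRef
  s[im] <- 2 * f[im]
  s[iu] <- 2 * (100 - f[iu])
  s[ih] <- 100 * (hi - v[ih]) / rangeRef
  s
}

#' Multivariate environmental similarity surface and MoD
#'
#' For each cell and variable, computes the similarity of the projected
#' value to the calibration reference sample; the MESS value is the
#' minimum similarity over variables and is negative exactly where at
#' least one variable falls outside its calibrated range. The MoD grid
#' records the most dissimilar (argmin) variable, ties broken by stack
#' variable order.
#'
#' @param stack projection \linkS4class{ClimateStack}.
#' @param reference a \linkS4class{TrainingTable} (its rows are the
#'   calibration sample) or a numeric matrix with the stack's variables
#'   as columns.
#' @return a \linkS4class{MessResult}.
#' @export
messSurface <- function(stack, reference) {
  refEnv <- if (is(reference, "TrainingTable"))
    as.matrix(reference@data[, reference@variables, drop = FALSE])
  else as.matrix(reference)
  vars <- intersect(variableNames(stack), colnames(refEnv))
  if (!length(vars)) stop("reference shares no variables with the stack")
  usable <- vars[vapply(vars, function(v)
    length(unique(refEnv[, v])) >= 2, logical(1))]
  skipped <- setdiff(vars, usable)
  if (length(skipped))
    warning("constant reference variable(s) excluded from MESS: ",
            paste(skipped, collapse = ", "))
  if (!length(usable)) stop("no usable (non-constant) reference variables")
  d <- dim(nodataMask(stack))
  u <- unmaskedEnv(stack)
  simMat <- vapply(usable, function(v)
    messSimilarity(u$env[, v], sort(refEnv[, v])), numeric(nrow(u$env)))
  simMat <- matrix(simMat, ncol = length(usable))
  messVal <- simMat[cbind(seq_len(nrow(simMat)), max.col(-simMat, "first"))]
  modIdx <- max.col(-simMat, ties.method = "first")
  mess <- matrix(NA_real_, d[1], d[2])
  mod <- matrix(NA_integer_, d[1], d[2])
  mess[cbind(u$row, u$col)] <- messVal
  mod[cbind(u$row, u$col)] <- modIdx
  new("MessResult", mess = mess, mod = mod, variables = usable,
      scenarioId = scenarioId(stack))
}

#' @rdname accessors
setMethod("fitMetric", "EvalReport", function(x)
  c(auc_internal_mean = x@aucInternalMean, auc_internal_sd = x@aucInternalSd))

#' MESS similarity grid of a MessResult
#' @param x a MessResult
#' @export
messValues <- function(x) x@mess

#' Most-dissimilar-variable labels of a MessResult
#' @param x a MessResult
#' @return character matrix of variable labels (NA where masked).
#' @export
modVariables <- function(x) {
  out <- matrix(NA_character_, nrow(x@mod), ncol(x@mod))
  ok <- !is.na(x@mod)
  out[ok] <- x@variables[x@mod[ok]]
  out
}
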
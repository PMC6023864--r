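#' @import methods
NULL

## Central S4 containers. All raster-like classes share the same grid
## convention: matrices are stored with row 1 = northernmost row (as in
## ESRI ASCII files); `origin` is the (x, y) of the grid's lower-left
## corner; cells are half-open, so a point exactly on a boundary belongs
## to the cell to the right/above.

#' Multi-variable climate raster stack for one scenario
#'
#' Holds one 2-D grid per bioclimatic variable on a shared geometry, plus
#' a shared nodata mask (a cell is masked if it is nodata in any layer).
#'
#' @slot variables named list of numeric matrices, one per variable.
#' @slot cellSize cell edge length in map units (> 0).
#' @slot origin numeric length-2, (x, y) of the lower-left corner.
#' @slot nodataMask logical matrix, TRUE where the cell is masked.
#' @slot scenarioId scenario label (e.g. "current", "MIS5e").
#' @exportClass ClimateStack
setClass("ClimateStack",
  representation(
    variables = "list",
    cellSize = "numeric",
    origin = "numeric",
    nodataMask = "matrix",
    scenarioId = "character"
  )
)

setValidity("ClimateStack", function(object) {
  v <- object@variables
  if (length(v) < 1L) return("at least one variable required")
  if (is.null(names(v)) || any(!nzchar(names(v))))
    return("variables must be a named list")
  dims <- vapply(v, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all variable grids must share the same shape")
  if (!identical(dim(object@nodataMask), dim(v[[1]])))
    return("nodataMask shape must match variable grids")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    return("cellSize must be a single positive number")
  if (length(object@origin) != 2L) return("origin must be length 2")
  TRUE
})

#' Point occurrence records
#'
#' @slot records data.frame with columns x, y (map units), role
#'   (one of presence, fossil, background, pseudoabsence) and period.
#' @slot crsNote free-text note on the coordinate system.
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(records = "data.frame", crsNote = "character")
)

setValidity("OccurrenceSet", function(object) {
  r <- object@records
  need <- c("x", "y", "role", "period")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  ok <- c("presence", "fossil", "background", "pseudoabsence")
  if (nrow(r) > 0 && !all(r$role %in% ok))
    return(paste("role must be one of:", paste(ok, collapse = ", ")))
  if (nrow(r) > 0 && (!all(is.finite(r$x)) || !all(is.finite(r$y))))
    return("coordinates must be finite")
  TRUE
})

#' Habitat suitability surface
#'
#' @slot values numeric matrix in [0, 1] (NA where masked).
#' @slot cellSize,origin,nodataMask geometry, as in \linkS4class{ClimateStack}.
#' @slot modelId label of the model that produced the map.
#' @exportClass SuitabilityMap
setClass("SuitabilityMap",
  representation(
    values = "matrix",
    cellSize = "numeric",
    origin = "numeric",
    nodataMask = "matrix",
    scenarioId = "character",
    modelId = "character"
  )
)

setValidity("SuitabilityMap", function(object) {
  v <- object@values[!object@nodataMask]
  v <- v[!is.na(v)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("suitability values must lie in [0, 1]")
  if (!identical(dim(object@values), dim(object@nodataMask)))
    return("values and nodataMask must share shape")
  TRUE
})

#' Presence/contrast training table for SDM fitting
#'
#' @slot data data.frame of environmental columns plus `label` (1 =
#'   presence, 0 = contrast) and `weight` (nonnegative).
#' @slot contrastKind "background" or "pseudoabsence".
#' @slot variableRanges 2 x p matrix (rows "min", "max") of per-variable
#'   ranges over all rows; used for clamping on projection.
#' @slot variables ordered predictor names.
#' @exportClass TrainingTable
setClass("TrainingTable",
  representation(
    data = "data.frame",
    contrastKind = "character",
    variableRanges = "matrix",
    variables = "character"
  )
)

setValidity("TrainingTable", function(object) {
  d <- object@data
  if (!all(c("label", "weight") %in% names(d)))
    return("data must have label and weight columns")
  if (sum(d$label == 1) < 1 || sum(d$label == 0) < 1)
    return("need at least one presence and one contrast row")
  if (any(!is.finite(d$weight)) || any(d$weight < 0))
    return("weights must be finite and nonnegative")
  if (!all(object@variables %in% names(d)))
    return("all variables must be columns of data")
  TRUE
})

#' Fitted species distribution model
#'
#' @slot algorithm "glm_poly", "random_forest" or "maxent_like".
#' @slot variables predictor names, in training order.
#' @slot fit algorithm-specific fitted object (coefficient list or
#'   randomForest ensemble).
#' @slot featureSpec feature construction details (polynomial degree,
#'   Maxent feature classes and standardization constants).
#' @slot regMultiplier Maxent-style regularization multiplier.
#' @slot variableRanges training 2 x p min/max matrix used for clamping.
#' @slot fitMetric named number: deviance_explained, variance_explained
#'   or gain.
#' @slot importance permutation importance (random forest only).
#' @exportClass SDMModel
setClass("SDMModel",
  representation(
    algorithm = "character",
    variables = "character",
    fit = "ANY",
    featureSpec = "list",
    regMultiplier = "numeric",
    variableRanges = "matrix",
    fitMetric = "numeric",
    importance = "numeric"
  )
)

setValidity("SDMModel", function(object) {
  if (!object@algorithm %in% c("glm_poly", "random_forest", "maxent_like"))
    return("unknown algorithm")
  if (length(object@fitMetric) != 1L || is.null(names(object@fitMetric)))
    return("fitMetric must be a single named number")
  rng <- object@variableRanges
  if (any(rng["max", ] <= rng["min", ]))
    return("variableRanges must be non-degenerate (max > min)")
  TRUE
})

#' Two-axis PCA of the pooled multi-scenario climate space
#'
#' @slot loadings p x 2 orthonormal loading matrix.
#' @slot center,scale pooled per-variable mean and SD used to standardize.
#' @slot varianceFraction proportion of pooled variance per axis.
#' @exportClass PCASpace
setClass("PCASpace",
  representation(
    loadings = "matrix",
    center = "numeric",
    scale = "numeric",
    varianceFraction = "numeric"
  )
)

setValidity("PCASpace", function(object) {
  L <- object@loadings
  if (ncol(L) != 2L) return("exactly two axes are used")
  if (max(abs(crossprod(L) - diag(2))) > 1e-8)
    return("loading columns must be orthonormal")
  vf <- object@varianceFraction
  if (any(vf <= 0) || sum(vf) > 1 + 1e-8 || vf[2] > vf[1] + 1e-12)
    return("variance fractions must be positive, non-increasing, sum <= 1")
  TRUE
})

#' Kernel occupancy grid in environmental (PCA) space
#'
#' R x R grids of occurrence density `o`, environment density `e` and
#' corrected occupancy `z` = (o/e where e > 0, else 0), rescaled to max 1.
#' Rows index axis 1, columns axis 2; `extent` is a 2 x 2 matrix with
#' rows (min, max) and columns the two PC axes.
#'
#' @exportClass NicheGrid
setClass("NicheGrid",
  representation(
    resolution = "integer",
    extent = "matrix",
    o = "matrix",
    e = "matrix",
    z = "matrix",
    bandwidth = "numeric",
    entityId = "character",
    scenarioId = "character"
  )
)

setValidity("NicheGrid", function(object) {
  R <- object@resolution
  if (any(dim(object@o) != c(R, R))) return("o must be R x R")
  if (any(dim(object@e) != c(R, R))) return("e must be R x R")
  if (any(dim(object@z) != c(R, R))) return("z must be R x R")
  if (min(object@o) < 0 || min(object@e) < 0) return("o and e must be >= 0")
  if (min(object@z) < -1e-12 || max(object@z) > 1 + 1e-12)
    return("z must lie in [0, 1]")
  if (!identical(dim(object@extent), c(2L, 2L)))
    return("extent must be a 2 x 2 matrix")
  if (any(object@extent[2, ] <= object@extent[1, ]))
    return("extent max must exceed min on both axes")
  TRUE
})

#' Niche-overlap comparison between two scenarios
#'
#' The machine analogue of a niche-overlap table row: Schoener's D,
#' equivalency and (two-direction) similarity p-values, and the
#' expansion/stability/unfilling dynamics indices.
#'
#' @exportClass OverlapReport
setClass("OverlapReport",
  representation(
    pair = "character",
    D = "numeric",
    equivalencyP = "numeric",
    similarityPAToB = "numeric",
    similarityPBToA = "numeric",
    expansion = "numeric",
    stability = "numeric",
    unfilling = "numeric",
    nReplicates = "integer"
  )
)

setValidity("OverlapReport", function(object) {
  if (object@D < -1e-12 || object@D > 1 + 1e-12) return("D must be in [0, 1]")
  p <- c(object@equivalencyP, object@similarityPAToB, object@similarityPBToA)
  if (any(p <= 0) || any(p > 1)) return("p-values must lie in (0, 1]")
  if (abs(object@expansion + object@stability - 1) > 1e-12)
    return("expansion + stability must equal 1")
  TRUE
})

setMethod("show", "ClimateStack", function(object) {
  d <- dim(object@nodataMask)
  cat(sprintf(
    "ClimateStack '%s': %d variable(s) [%s] on a %d x %d grid (cell %g)\n",
    object@scenarioId, length(object@variables),
    paste(names(object@variables), collapse = ", "), d[1], d[2],
    object@cellSize))
  cat(sprintf("  masked cells: %d\n", sum(object@nodataMask)))
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d record(s)\n", nrow(object@records)))
  if (nrow(object@records))
    print(table(role = object@records$role, period = object@records$period))
})

setMethod("show", "SuitabilityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("SuitabilityMap '%s' (%s): %d x %d grid, range [%.3f, %.3f]\n",
    object@modelId, object@scenarioId, d[1], d[2],
    min(object@values, na.rm = TRUE), max(object@values, na.rm = TRUE)))
})

setMethod("show", "SDMModel", function(object) {
  cat(sprintf("SDMModel [%s] on %d variable(s); %s = %.4f\n",
    object@algorithm, length(object@variables),
    names(object@fitMetric), object@fitMetric))
})

setMethod("show", "NicheGrid", function(object) {
  cat(sprintf("NicheGrid '%s' (%s): %d x %d, occupied cells (z > 0): %d\n",
    object@entityId, object@scenarioId, object@resolution,
    object@resolution, sum(object@z > 0)))
})

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf(
    "OverlapReport %s: D = %.3f | equivalency p = %.3f | similarity p = %.3f / %.3f\n",
    object@pair, object@D, object@equivalencyP,
    object@similarityPAToB, object@similarityPBToA))
  cat(sprintf("  expansion %.3f  stability %.3f  unfilling %.3f  (%d replicates)\n",
    object@expansion, object@stability, object@unfilling, object@nReplicates))
})

#' Variable-selection result (correlation clustering / VIF filtering)
#'
#' @slot kept labels retained.
#' @slot dropped data.frame with columns label, reason
#'   ("correlation_cluster" or "vif") and statistic (|r| or VIF at removal).
#' @slot rThreshold,vifThreshold thresholds used.
#' @exportClass VariableSelection
setClass("VariableSelection",
  representation(
    kept = "character",
    dropped = "data.frame",
    rThreshold = "numeric",
    vifThreshold = "numeric"
  )
)

setValidity("VariableSelection", function(object) {
  if (length(object@kept) < 1L) return("kept must be non-empty")
  TRUE
})

setMethod("show", "VariableSelection", function(object) {
  cat(sprintf("VariableSelection: kept %s; dropped %d\n",
    paste(object@kept, collapse = ", "), nrow(object@dropped)))
})
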
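## Preprocessing: spatial thinning of records and predictor selection
## (correlation-dendrogram clustering followed by iterative VIF filtering).

#' Thin occurrence records to one per grid cell
#'
#' Keeps at most one record per thinning-grid cell per period (applied
#' identically to presences and fossils); within a cell the first record
#' in input order is retained. The thinning grid is anchored at `origin`.
#'
#' @param occ an \linkS4class{OccurrenceSet}.
#' @param cellSize thinning cell edge, map units (e.g. a 10-km rule).
#' @param origin grid anchor, default c(0, 0).
#' @return thinned \linkS4class{OccurrenceSet}; idempotent.
#' @export
thinToGrid <- function(occ, cellSize, origin = c(0, 0)) {
  stopifnot(cellSize > 0)
  r <- records(occ)
  if (nrow(r) == 0) return(occ)
  cellKey <- paste(
    floor((r$x - origin[1]) / cellSize),
    floor((r$y - origin[2]) / cellSize),
    r$period, sep = "_")
  keep <- !duplicated(cellKey)
  initialize(occ, records = r[keep, , drop = FALSE])
}

#' Select one variable per correlation cluster
#'
#' Variables are clustered by average-linkage (UPGMA) agglomeration on
#' the distance 1 - |r| over unmasked cells; the dendrogram is cut at
#' height 1 - rThreshold, and one variable is kept per cluster: the first
#' present in `preference`, otherwise the cluster member with maximal
#' variance. Average linkage does not guarantee all pairwise |r| among
#' kept variables fall below the threshold; violations are reported.
#'
#' @param stack a \linkS4class{ClimateStack} with >= 2 variables.
#' @param rThreshold Pearson correlation cut (default 0.7).
#' @param preference ordered labels expressing domain preference (e.g.
#'   variables tied to the species' biology).
#' @return a \linkS4class{VariableSelection}.
#' @export
correlationClusterSelect <- function(stack, rThreshold = 0.7,
                                     preference = character()) {
  env <- unmaskedEnv(stack)$env
  if (ncol(env) < 2) stop("need at least two variables")
  if (nrow(env) < 3) stop("need at least three unmasked cells")
  sds <- apply(env, 2, stats::sd)
  droppedConst <- colnames(env)[sds == 0]
  if (length(droppedConst))
    warning("zero-variance variable(s) dropped before clustering: ",
            paste(droppedConst, collapse = ", "))
  env <- env[, sds > 0, drop = FALSE]
  R <- stats::cor(env)
  d <- stats::as.dist(1 - abs(R))
  hc <- stats::hclust(d, method = "average")
  groups <- stats::cutree(hc, h = 1 - rThreshold)
  vars <- colnames(env)
  v <- apply(env, 2, stats::var)
  kept <- character()
  dropped <- data.frame(label = character(), reason = character(),
                        statistic = numeric(), stringsAsFactors = FALSE)
  for (g in sort(unique(groups))) {
    members <- vars[groups == g]
    pref <- preference[preference %in% members]
    keep <- if (length(pref)) pref[1] else members[which.max(v[members])]
    kept <- c(kept, keep)
    for (m in setdiff(members, keep))
      dropped <- rbind(dropped, data.frame(
        label = m, reason = "correlation_cluster",
        statistic = abs(R[m, keep]), stringsAsFactors = FALSE))
  }
  kept <- vars[vars %in% kept]  # preserve stack order
  if (length(kept) > 1) {
    Rk <- abs(R[kept, kept])
    diag(Rk) <- 0
    if (max(Rk) >= rThreshold)
      warning("kept variables still contain pairwise |r| >= ",
              rThreshold, " (max ", format(max(Rk), digits = 3),
              "); average linkage does not guarantee the bound")
  }
  for (m in droppedConst)
    dropped <- rbind(dropped, data.frame(
      label = m, reason = "correlation_cluster", statistic = 0,
      stringsAsFactors = FALSE))
  new("VariableSelection", kept = kept, dropped = dropped,
      rThreshold = rThreshold, vifThreshold = NA_real_)
}

# R^2 of an OLS regression of column j on the remaining columns
# (with intercept); +Inf VIF when the fit is numerically singular.
vifOne <- function(env, j) {
  y <- env[, j]
  X <- cbind(1, env[, -j, drop = FALSE])
  fit <- stats::lm.fit(X, y)
  res <- fit$residuals
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(Inf)
  r2 <- 1 - sum(res^2) / tss
  if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
}

#' Per-variable variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from an OLS regression of variable
#' j on all other variables over unmasked cells; +Inf for a numerically
#' singular fit.
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param vars variables to evaluate (default all).
#' @return named numeric vector of VIFs.
#' @export
vifValues <- function(stack, vars = variableNames(stack)) {
  env <- unmaskedEnv(stack)$env[, vars, drop = FALSE]
  if (ncol(env) < 2) stop("need at least two variables")
  vifs <- vapply(seq_len(ncol(env)), function(j) vifOne(env, j), numeric(1))
  stats::setNames(vifs, colnames(env))
}

#' Iterative variance-inflation-factor filtering
#'
#' Computes VIF_j = 1 / (1 - R^2_j) from an OLS regression of each
#' variable on all others over unmasked cells, repeatedly removing the
#' variable with the largest VIF until all fall below the threshold.
#' A numerically singular fit is treated as VIF = +Inf and removed first.
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param vars variables to consider (default all).
#' @param vifThreshold removal threshold (default 5).
#' @return a \linkS4class{VariableSelection} whose `dropped` records the
#'   VIF at removal.
#' @export
vifFilter <- function(stack, vars = variableNames(stack), vifThreshold = 5) {
  env <- unmaskedEnv(stack)$env[, vars, drop = FALSE]
  if (ncol(env) < 2) stop("need at least two variables")
  dropped <- data.frame(label = character(), reason = character(),
                        statistic = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (ncol(env) < 2) break
    vifs <- vapply(seq_len(ncol(env)), function(j) vifOne(env, j), numeric(1))
    names(vifs) <- colnames(env)
    if (max(vifs) < vifThreshold) break
    worst <- which.max(vifs)
    dropped <- rbind(dropped, data.frame(
      label = colnames(env)[worst], reason = "vif",
      statistic = vifs[worst], stringsAsFactors = FALSE))
    env <- env[, -worst, drop = FALSE]
  }
  new("VariableSelection", kept = colnames(env), dropped = dropped,
      rThreshold = NA_real_, vifThreshold = vifThreshold)
}

#' Restrict a stack to a subset of variables
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param vars labels to retain, in the order given.
#' @export
subsetVariables <- function(stack, vars) {
  missing <- setdiff(vars, variableNames(stack))
  if (length(missing))
    stop("variable(s) not in stack: ", paste(missing, collapse = ", "))
  initialize(stack, variables = gridValues(stack)[vars])
}
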
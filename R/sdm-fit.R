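## The three SDM algorithms: polynomial logistic GLM, random forest, and
## a Maxent-style penalized log-linear density model fitted by proximal
## gradient (FISTA) with L1 regularization.

## ---- feature construction ------------------------------------------------

# Per-variable polynomial powers 1..degree, standardized by training
# center/scale (no cross-products).
polyFeatures <- function(env, spec) {
  if (spec$degree == 0)
    return(matrix(numeric(0), nrow = nrow(env), ncol = 0))
  cols <- list()
  for (v in spec$variables)
    for (d in seq_len(spec$degree))
      cols[[paste0(v, "_p", d)]] <- env[, v]^d
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  sweep(sweep(X, 2, spec$center, `-`), 2, spec$scale, `/`)
}

# Standardization constants are weighted (population form), so integer
# row weights are exactly equivalent to row duplication.
newPolySpec <- function(env, degree, w = rep(1, nrow(env))) {
  spec <- list(type = "poly", degree = degree, variables = colnames(env))
  if (degree == 0) {
    spec$center <- numeric(0); spec$scale <- numeric(0)
    return(spec)
  }
  raw <- list()
  for (v in spec$variables)
    for (d in seq_len(degree)) raw[[paste0(v, "_p", d)]] <- env[, v]^d
  X <- do.call(cbind, raw)
  ctr <- apply(X, 2, stats::weighted.mean, w = w)
  scl <- sqrt(colSums(w * sweep(X, 2, ctr, `-`)^2) / sum(w))
  scl[scl == 0] <- 1
  spec$center <- ctr
  spec$scale <- scl
  spec
}

# Maxent feature classes: linear and quadratic terms of background-
# standardized variables, plus optional forward hinge features with knots
# at background quantiles.
maxentFeatures <- function(env, spec) {
  z <- sweep(sweep(env[, spec$variables, drop = FALSE], 2, spec$center, `-`),
             2, spec$scale, `/`)
  cols <- list()
  if ("linear" %in% spec$classes)
    for (v in spec$variables) cols[[paste0(v, "_lin")]] <- z[, v]
  if ("quadratic" %in% spec$classes)
    for (v in spec$variables) cols[[paste0(v, "_quad")]] <- z[, v]^2
  if ("hinge" %in% spec$classes)
    for (v in spec$variables)
      for (k in seq_along(spec$knots[[v]])) {
        kn <- spec$knots[[v]][k]
        cols[[paste0(v, "_h", k)]] <- pmax(0, z[, v] - kn)
      }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

newMaxentSpec <- function(bgEnv, classes) {
  vars <- colnames(bgEnv)
  ctr <- colMeans(bgEnv)
  scl <- apply(bgEnv, 2, stats::sd)
  scl[scl == 0] <- 1
  spec <- list(type = "maxent", classes = classes, variables = vars,
               center = ctr, scale = scl)
  if ("hinge" %in% classes) {
    z <- sweep(sweep(bgEnv, 2, ctr, `-`), 2, scl, `/`)
    spec$knots <- lapply(vars, function(v)
      unname(stats::quantile(z[, v], c(0.1, 0.3, 0.5, 0.7, 0.9))))
    names(spec$knots) <- vars
  }
  spec
}

## ---- GLM -----------------------------------------------------------------

binomialDeviance <- function(y, p, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(w * (y * log(p) + (1 - y) * log(1 - p)))
}

# Ridge-penalized logistic Newton fallback for separated data.
ridgeLogistic <- function(X, y, w, lambda = 1e-6, maxit = 100) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  pen <- c(0, rep(lambda, ncol(X)))
  for (i in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    p <- stats::plogis(eta)
    W <- w * p * (1 - p) + 1e-10
    g <- drop(crossprod(X1, w * (y - p))) - 2 * pen * beta
    H <- crossprod(X1, X1 * W) + 2 * diag(pen + 1e-12)
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-10) break
  }
  beta
}

#' Fit a weighted polynomial logistic GLM
#'
#' Binomial-logit fit by iteratively reweighted least squares on
#' per-variable polynomial expansions (powers 1..degree, standardized,
#' no cross-products). Row weights are honored, so weighted-background
#' tables (contrast mass equal to presence mass) fit as specified.
#' Complete separation triggers a lightly ridge-penalized refit
#' (L2 = 1e-6) with a warning. The fit metric is explained deviance
#' D^2 = 1 - dev_model / dev_null.
#'
#' @param table a \linkS4class{TrainingTable}.
#' @param degree polynomial degree (>= 0; 0 gives an intercept-only fit).
#' @return an \linkS4class{SDMModel} with algorithm "glm_poly".
#' @export
fitSdmGlm <- function(table, degree = 2) {
  d <- table@data
  env <- as.matrix(d[, table@variables, drop = FALSE])
  y <- d$label
  w <- d$weight
  spec <- newPolySpec(env, degree, w)
  X <- polyFeatures(env, spec)
  X1 <- cbind(1, X)
  fit <- suppressWarnings(
    stats::glm.fit(X1, y, weights = w, family = stats::binomial()))
  beta <- fit$coefficients
  separated <- !fit$converged || any(!is.finite(beta)) ||
    (length(beta) > 1 && max(abs(beta[-1])) > 30)
  if (separated && ncol(X) > 0) {
    warning("possible complete separation; refitting with a tiny ridge penalty")
    beta <- ridgeLogistic(X, y, w)
  }
  beta[!is.finite(beta)] <- 0
  p <- stats::plogis(drop(X1 %*% beta))
  dev <- binomialDeviance(y, p, w)
  p0 <- stats::weighted.mean(y, w)
  dev0 <- binomialDeviance(y, rep(p0, length(y)), w)
  d2 <- if (dev0 > 0) 1 - dev / dev0 else 0
  new("SDMModel", algorithm = "glm_poly", variables = table@variables,
      fit = list(coefficients = beta,
                 converged = fit$converged, separated = separated),
      featureSpec = spec, regMultiplier = NA_real_,
      variableRanges = table@variableRanges,
      fitMetric = c(deviance_explained = d2),
      importance = numeric(0))
}

## ---- random forest -------------------------------------------------------

#' Fit a random-forest SDM
#'
#' Regression forest on the 0/1 labels (presence vs pseudoabsence). Fit
#' metric is out-of-bag variance explained, 1 - MSE_oob / Var(label);
#' permutation importance is the mean increase in out-of-bag MSE when a
#' variable is permuted (the %IncMSE diagnostic).
#'
#' @param table a \linkS4class{TrainingTable}.
#' @param nTrees ensemble size (default 500; < 10 draws a warning).
#' @param seed RNG seed.
#' @return an \linkS4class{SDMModel} with algorithm "random_forest".
#' @export
fitSdmRf <- function(table, nTrees = 500, seed = 1L) {
  if (nTrees < 10) warning("nTrees < 10: forest will be unstable")
  d <- table@data
  x <- d[, table@variables, drop = FALSE]
  y <- as.numeric(d$label)
  if (length(unique(y)) < 2) stop("single-class table: cannot fit a forest")
  ## regression on the 0/1 labels is deliberate (probability-scale
  ## forest); silence randomForest's few-unique-values advisory
  rf <- withSeed(seed, withCallingHandlers(
    randomForest::randomForest(x = x, y = y, ntree = nTrees,
                               importance = TRUE),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  varExpl <- 1 - rf$mse[nTrees] / mean((y - mean(y))^2)
  imp <- rf$importance[, "%IncMSE"]
  new("SDMModel", algorithm = "random_forest", variables = table@variables,
      fit = rf, featureSpec = list(type = "rf"),
      regMultiplier = NA_real_,
      variableRanges = table@variableRanges,
      fitMetric = c(variance_explained = varExpl),
      importance = imp)
}

## ---- Maxent-style penalized log-linear model -----------------------------

# Smooth part of the objective and its gradient:
#   g(lambda) = -mean_pres(F_p lambda) + log( mean_bg exp(F_b lambda) )
maxentObjective <- function(lambda, Fp, Fb) {
  sb <- drop(Fb %*% lambda)
  -mean(drop(Fp %*% lambda)) + (logSumExp(sb) - log(nrow(Fb)))
}

maxentGradient <- function(lambda, Fp, Fb) {
  sb <- drop(Fb %*% lambda)
  wts <- exp(sb - logSumExp(sb))
  -colMeans(Fp) + drop(crossprod(Fb, wts))
}

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a Maxent-style penalized log-linear density model
#'
#' Maximizes the regularized log-likelihood of a Gibbs density over
#' background cells (with the presence samples added to the background,
#' as in the reference Maxent implementation): (1/m) sum_presence lambda.f(x) -
#' log sum_background (1/N) exp(lambda.f(x)) - sum_k beta_k |lambda_k|,
#' with per-feature penalties beta_k = regMultiplier * sqrt(var_bg(f_k)/m)
#' (m = number of presences). Solved by FISTA proximal gradient with
#' backtracking; the L1 proximal step produces exact zeros, so a large
#' multiplier shrinks all coefficients to 0. The fit metric is the gain
#' (the two likelihood terms at the optimum; 0 for the null model, larger
#' when the model concentrates on presence conditions). Suitability output
#' is the logistic transform of the linear score (a monotone transform:
#' rank-based measures such as AUC and D are invariant to it).
#'
#' @param table a \linkS4class{TrainingTable} whose contrast rows are the
#'   background sample.
#' @param features feature classes, subset of "linear", "quadratic",
#'   "hinge" (default linear + quadratic).
#' @param regMultiplier regularization multiplier (default 3).
#' @param maxit,tol solver controls.
#' @return an \linkS4class{SDMModel} with algorithm "maxent_like".
#' @export
fitSdmMaxent <- function(table, features = c("linear", "quadratic"),
                         regMultiplier = 3, maxit = 5000, tol = 1e-5) {
  d <- table@data
  env <- as.matrix(d[, table@variables, drop = FALSE])
  presEnv <- env[d$label == 1, , drop = FALSE]
  bgEnv <- env[d$label == 0, , drop = FALSE]
  m <- nrow(presEnv)
  if (m < 5) stop("need at least 5 presences")
  if (m < 10)
    warning("fewer than 10 presences; the penalized fit may be unstable")
  if (nrow(bgEnv) < m) stop("background must be at least as large as presences")
  spec <- newMaxentSpec(bgEnv, features)
  Fp <- maxentFeatures(presEnv, spec)
  ## presence samples are added to the background for the partition
  ## function (standard Maxent practice); this keeps the objective
  ## bounded even when presence and background conditions are separable
  Fb <- rbind(Fp, maxentFeatures(bgEnv, spec))
  beta <- regMultiplier * sqrt(pmax(apply(Fb, 2, stats::var), 1e-6) / m)
  ## FISTA with backtracking line search; convergence is declared on the
  ## KKT conditions of the L1 problem (|grad_k| <= beta_k on the inactive
  ## set, grad_k = -beta_k * sign(lambda_k) on the active set).
  kktViolation <- function(lambda, gr) {
    active <- lambda != 0
    max(c(abs(gr[active] + beta[active] * sign(lambda[active])),
          pmax(abs(gr[!active]) - beta[!active], 0), 0))
  }
  lambda <- numeric(ncol(Fb))
  yv <- lambda
  t_k <- 1
  L <- 1
  converged <- FALSE
  for (it in seq_len(maxit)) {
    g <- maxentObjective(yv, Fp, Fb)
    gr <- maxentGradient(yv, Fp, Fb)
    repeat {
      cand <- softThreshold(yv - gr / L, beta / L)
      dlt <- cand - yv
      if (maxentObjective(cand, Fp, Fb) <=
          g + sum(gr * dlt) + 0.5 * L * sum(dlt^2) + 1e-12) break
      L <- L * 2
      if (L > 1e12) stop("Maxent solver line search failed; gradient norm = ",
                         format(sqrt(sum(gr^2))))
    }
    tNew <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    yv <- cand + ((t_k - 1) / tNew) * (cand - lambda)
    lambda <- cand
    t_k <- tNew
    L <- max(L / 2, 1e-4)
    if (it %% 10 == 0 || it == 1) {
      grAt <- maxentGradient(lambda, Fp, Fb)
      if (kktViolation(lambda, grAt) < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    gr <- maxentGradient(lambda, Fp, Fb)
    stop("Maxent solver did not converge in ", maxit,
         " iterations; KKT violation = ",
         format(kktViolation(lambda, gr)),
         ", gradient norm = ", format(sqrt(sum(gr^2))))
  }
  gain <- -maxentObjective(lambda, Fp, Fb)
  new("SDMModel", algorithm = "maxent_like", variables = table@variables,
      fit = list(coefficients = stats::setNames(lambda, colnames(Fb)),
                 penalties = beta),
      featureSpec = spec, regMultiplier = regMultiplier,
      variableRanges = table@variableRanges,
      fitMetric = c(gain = gain),
      importance = numeric(0))
}

#' Fit any of the three SDM algorithms by name
#'
#' Dispatch wrapper used by the bootstrap and pipeline code.
#'
#' @param table a \linkS4class{TrainingTable}.
#' @param algorithm "glm_poly", "random_forest" or "maxent_like".
#' @param degree,nTrees,features,regMultiplier,seed forwarded controls.
#' @export
fitSdm <- function(table,
                   algorithm = c("glm_poly", "random_forest", "maxent_like"),
                   degree = 2, nTrees = 500,
                   features = c("linear", "quadratic"),
                   regMultiplier = 3, seed = 1L) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    glm_poly = fitSdmGlm(table, degree = degree),
    random_forest = fitSdmRf(table, nTrees = nTrees, seed = seed),
    maxent_like = fitSdmMaxent(table, features = features,
                               regMultiplier = regMultiplier))
}
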
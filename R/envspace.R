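## Environmental-space framework: pooled two-axis PCA, kernel occupancy
## grids (occurrence density o, environment density e, corrected
## occupancy z = o/e), Schoener's D, niche equivalency and similarity
## randomization tests, expansion/stability/unfilling and centroid shifts.

#' Fit the global PCA over pooled climate scenarios
#'
#' Pools the unmasked cells of every scenario, standardizes each variable
#' by the pooled mean and SD, and takes the first two eigenvectors of the
#' pooled correlation structure. Axis signs follow a deterministic
#' convention (the largest-magnitude loading on each axis is positive).
#'
#' @param stacks list of \linkS4class{ClimateStack} objects sharing >= 2
#'   variables.
#' @return a \linkS4class{PCASpace}.
#' @export
fitGlobalPCA <- function(stacks) {
  if (is(stacks, "ClimateStack")) stacks <- list(stacks)
  vars <- Reduce(intersect, lapply(stacks, variableNames))
  if (length(vars) < 2) stop("stacks must share at least two variables")
  env <- do.call(rbind, lapply(stacks, function(s)
    unmaskedEnv(s)$env[, vars, drop = FALSE]))
  ctr <- colMeans(env)
  scl <- apply(env, 2, stats::sd)
  if (any(scl == 0))
    stop("constant variable(s) in pooled space: ",
         paste(vars[scl == 0], collapse = ", "))
  Z <- sweep(sweep(env, 2, ctr, `-`), 2, scl, `/`)
  eg <- eigen(stats::cor(Z), symmetric = TRUE)
  L <- eg$vectors[, 1:2, drop = FALSE]
  rownames(L) <- vars
  colnames(L) <- c("PC1", "PC2")
  for (k in 1:2) {
    top <- which.max(abs(L[, k]))
    if (L[top, k] < 0) L[, k] <- -L[, k]
  }
  new("PCASpace", loadings = L, center = stats::setNames(ctr, vars),
      scale = stats::setNames(scl, vars),
      varianceFraction = eg$values[1:2] / sum(eg$values))
}

#' Project environments into the PCA space
#'
#' @param pca a \linkS4class{PCASpace}.
#' @param env numeric matrix with the PCA's variables as columns.
#' @return n x 2 score matrix.
#' @export
pcaScores <- function(pca, env) {
  vars <- rownames(pca@loadings)
  missing <- setdiff(vars, colnames(env))
  if (length(missing))
    stop("environment lacks PCA variable(s): ",
         paste(missing, collapse = ", "))
  Z <- sweep(sweep(env[, vars, drop = FALSE], 2, pca@center, `-`),
             2, pca@scale, `/`)
  Z %*% pca@loadings
}

# Extent (2 x 2: rows min/max, cols axes) of a score set, padded.
scoreExtent <- function(scores, padFraction = 0.05) {
  rng <- apply(scores, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  rbind(rng[1, ] - padFraction * span, rng[2, ] + padFraction * span)
}

# Per-axis plug-in bandwidth (normal reference rule, kde2d convention);
# falls back to 1/25 of the extent span for degenerate score sets.
plugInBandwidth <- function(scores, extent) {
  h <- c(MASS::bandwidth.nrd(scores[, 1]), MASS::bandwidth.nrd(scores[, 2]))
  span <- extent[2, ] - extent[1, ]
  h[h <= 0] <- span[h <= 0] / 25
  h
}

# Gaussian kernel density on an R x R grid over `extent`
# (rows = axis 1, columns = axis 2).
kdeGrid <- function(scores, R, extent, h) {
  MASS::kde2d(scores[, 1], scores[, 2], h = h, n = R,
              lims = c(extent[1, 1], extent[2, 1],
                       extent[1, 2], extent[2, 2]))$z
}

# Largest density value t such that dropping all cells with e <= t
# removes at most `frac` of the total e mass. Ratios o/e are only taken
# on the remaining support: the far numeric tail of a kernel density
# otherwise produces unbounded occupancy spikes where almost no
# environment exists.
eMassThreshold <- function(e, frac) {
  v <- sort(as.vector(e))
  cs <- cumsum(v)
  idx <- which(cs <= frac * cs[length(cs)])
  if (!length(idx)) 0 else v[max(idx)]
}

# Smallest cell set containing `mass` of the occupancy total (the
# kernel utilization-distribution contour); mass >= 1 degrades to z > 0.
zMembership <- function(z, mass) {
  if (mass >= 1) return(z > 0)
  v <- sort(as.vector(z), decreasing = TRUE)
  cs <- cumsum(v)
  tot <- cs[length(cs)]
  if (tot <= 0) return(z > 0)
  thr <- v[which(cs >= mass * tot)[1]]
  z >= thr & z > 0
}

zFromOE <- function(o, e, eMassDrop = 0.001) {
  z <- matrix(0, nrow(o), ncol(o))
  pos <- e > eMassThreshold(e, eMassDrop) & e > 0
  z[pos] <- o[pos] / e[pos]
  mx <- max(z)
  if (mx > 0) z <- z / mx
  z
}

#' Build a kernel occupancy grid in PCA space
#'
#' Projects occurrence and background environments into the PCA space,
#' estimates Gaussian kernel densities o (occurrences) and e (available
#' environment) on a shared R x R grid, and derives the corrected
#' occupancy z = o/e (where e > 0, else 0) rescaled to a maximum of 1.
#'
#' @param pca a \linkS4class{PCASpace}.
#' @param occEnv occurrence environments: n x p matrix (>= 5 rows).
#' @param bgEnv background environments (the scenario's available
#'   climate), same columns.
#' @param resolution grid resolution R (default 100).
#' @param extent optional shared 2 x 2 extent (rows min/max, cols axes);
#'   when comparing entities it must cover all their background scores.
#'   Default: this background's scores padded by `padFraction`.
#' @param padFraction extent padding (default 0.05).
#' @param bandwidthO,bandwidthE per-axis kernel bandwidths for o and e;
#'   default: normal-reference plug-in rule on the respective score set.
#' @param entityId,scenarioId labels.
#' @return a \linkS4class{NicheGrid}.
#' @export
buildNicheGrid <- function(pca, occEnv, bgEnv, resolution = 100L,
                           extent = NULL, padFraction = 0.05,
                           bandwidthO = NULL, bandwidthE = NULL,
                           entityId = "entity", scenarioId = "scenario") {
  if (nrow(occEnv) < 5) stop("need at least 5 occurrences")
  occS <- pcaScores(pca, occEnv)
  bgS <- pcaScores(pca, bgEnv)
  if (is.null(extent)) extent <- scoreExtent(bgS, padFraction)
  if (is.null(bandwidthE)) bandwidthE <- plugInBandwidth(bgS, extent)
  if (is.null(bandwidthO)) bandwidthO <- plugInBandwidth(occS, extent)
  R <- as.integer(resolution)
  o <- kdeGrid(occS, R, extent, bandwidthO)
  e <- kdeGrid(bgS, R, extent, bandwidthE)
  new("NicheGrid", resolution = R, extent = extent, o = o, e = e,
      z = zFromOE(o, e), bandwidth = bandwidthO,
      entityId = entityId, scenarioId = scenarioId)
}

#' Schoener's D niche overlap
#'
#' D = 1 - 1/2 * sum_ij |p_a,ij - p_b,ij| where p is the grid density
#' normalized to sum 1: the corrected occupancy z by default (the two
#' periods offer different available climates, which the o/e correction
#' accounts for), or the raw occurrence density o with corrected = FALSE.
#' D is symmetric and ranges from 0 (no overlap) to 1 (identical niches).
#'
#' @param a,b \linkS4class{NicheGrid}s on the same extent and resolution.
#' @param corrected use z (TRUE, default) or o (FALSE).
#' @return D in [0, 1].
#' @export
schoenerD <- function(a, b, corrected = TRUE) {
  if (a@resolution != b@resolution ||
      max(abs(a@extent - b@extent)) > 1e-9)
    stop("grids must share extent and resolution")
  pa <- if (corrected) a@z else a@o
  pb <- if (corrected) b@z else b@o
  sa <- sum(pa); sb <- sum(pb)
  if (sa <= 0 || sb <= 0) stop("grid with zero total density")
  1 - 0.5 * sum(abs(pa / sa - pb / sb))
}

#' Niche equivalency randomization test
#'
#' Pools the two occurrence sets and randomly reassigns records to two
#' groups of the original sizes; each replicate rebuilds both occupancy
#' grids against their fixed respective backgrounds and recomputes D.
#' The p-value is one-sided lower, p = (1 + #{D_null <= D_obs}) /
#' (replicates + 1): a small p means the observed overlap is less than
#' expected if the niches were identical (non-equivalency). A common
#' occurrence-kernel bandwidth (plug-in rule on the pooled occurrence
#' scores) is used for the observed and all null grids, so the observed
#' assignment is exchangeable with the replicates. Because each dataset
#' is spatially thinned (at most one record per cell), reassignment is
#' constrained the same way: a record present in both groups keeps one
#' copy in each, and only singleton records are shuffled — an
#' unconstrained permutation would create within-group duplicates the
#' observed datasets cannot contain, biasing null D downward.
#'
#' @param aOccEnv,bOccEnv occurrence environment matrices.
#' @param aBgEnv,bBgEnv background environment matrices for each side.
#' @param pca a \linkS4class{PCASpace}.
#' @param resolution grid resolution (default 100).
#' @param replicates number of reassignments (default 100).
#' @param seed RNG seed.
#' @param corrected passed to [schoenerD()].
#' @return list with elements `p`, `observedD` and `null` (the null D
#'   distribution).
#' @export
equivalencyTest <- function(aOccEnv, bOccEnv, aBgEnv, bBgEnv, pca,
                            resolution = 100L, replicates = 100L,
                            seed = 1L, corrected = TRUE) {
  if (replicates < 1) stop("replicates must be >= 1")
  R <- as.integer(resolution)
  aS <- pcaScores(pca, aOccEnv); bS <- pcaScores(pca, bOccEnv)
  aB <- pcaScores(pca, aBgEnv); bB <- pcaScores(pca, bBgEnv)
  extent <- scoreExtent(rbind(aB, bB))
  eA <- kdeGrid(aB, R, extent, plugInBandwidth(aB, extent))
  eB <- kdeGrid(bB, R, extent, plugInBandwidth(bB, extent))
  pooled <- rbind(aS, bS)
  nA <- nrow(aS)
  bw <- plugInBandwidth(pooled, extent)
  dOf <- function(sA, sB) {
    oA <- kdeGrid(sA, R, extent, bw)
    oB <- kdeGrid(sB, R, extent, bw)
    pa <- if (corrected) zFromOE(oA, eA) else oA
    pb <- if (corrected) zFromOE(oB, eB) else oB
    1 - 0.5 * sum(abs(pa / sum(pa) - pb / sum(pb)))
  }
  observed <- dOf(aS, bS)
  ## records duplicated across the two thinned datasets (identical
  ## environments) are pinned one-per-group; singletons are shuffled
  key <- apply(round(pooled, 9), 1, paste, collapse = "\r")
  dupKeys <- names(which(table(key) >= 2))
  pinned <- match(dupKeys, key)                       # one copy for group a
  pinnedB <- vapply(dupKeys, function(k) which(key == k)[2], integer(1))
  singles <- setdiff(seq_len(nrow(pooled)), c(pinned, pinnedB))
  nFreeA <- nA - length(pinned)
  if (nFreeA < 0 || nFreeA > length(singles)) {
    # degenerate duplication structure: fall back to a free permutation
    pinned <- integer(0); pinnedB <- integer(0)
    singles <- seq_len(nrow(pooled)); nFreeA <- nA
  }
  null <- withSeed(seed, vapply(seq_len(replicates), function(i) {
    idx <- safeSample(singles)
    dOf(pooled[c(pinned, idx[seq_len(nFreeA)]), , drop = FALSE],
        pooled[c(pinnedB, idx[-seq_len(nFreeA)]), , drop = FALSE])
  }, numeric(1)))
  list(p = (1 + sum(null <= observed)) / (replicates + 1),
       observedD = observed, null = null)
}

#' Niche similarity randomization test
#'
#' Compares the observed grid of entity `a` to grids built from random
#' occurrence draws for entity `b`. Under the default "random-points"
#' null (the literal construction: occurrences gathered at random from
#' the available environment) each replicate samples |b| background rows,
#' builds a null occupancy grid for b, and recomputes D against a's
#' observed grid. The "shift" null instead translates b's observed
#' occurrence scores so their centroid lands uniformly in the analysis
#' extent, preserving the niche's shape. For alternative = "greater",
#' p = (1 + #{D_null >= D_obs}) / (replicates + 1): small p means the
#' two niches are more similar than expected given b's available
#' environment. The pipeline runs the test in both directions.
#'
#' @param a observed \linkS4class{NicheGrid} for the first entity.
#' @param bOccEnv,bBgEnv occurrence and background environments of the
#'   second entity.
#' @param pca a \linkS4class{PCASpace}.
#' @param replicates number of null draws (default 100).
#' @param seed RNG seed.
#' @param alternative "greater" (more similar than chance, default) or
#'   "less".
#' @param nullModel "random-points" (default) or "shift".
#' @param corrected passed to [schoenerD()].
#' @return list with elements `p`, `observedD` and `null`.
#' @export
similarityTest <- function(a, bOccEnv, bBgEnv, pca, replicates = 100L,
                           seed = 1L, alternative = c("greater", "less"),
                           nullModel = c("random-points", "shift"),
                           corrected = TRUE) {
  if (replicates < 1) stop("replicates must be >= 1")
  alternative <- match.arg(alternative)
  nullModel <- match.arg(nullModel)
  R <- a@resolution
  extent <- a@extent
  bS <- pcaScores(pca, bOccEnv)
  bB <- pcaScores(pca, bBgEnv)
  nB <- nrow(bS)
  if (nullModel == "random-points" && nB > nrow(bB))
    stop("more occurrences than available background cells")
  eB <- kdeGrid(bB, R, extent, plugInBandwidth(bB, extent))
  bw <- plugInBandwidth(bS, extent)
  pa <- if (corrected) a@z else a@o
  pa <- pa / sum(pa)
  dAgainstA <- function(scores) {
    o <- kdeGrid(scores, R, extent, bw)
    pb <- if (corrected) zFromOE(o, eB) else o
    1 - 0.5 * sum(abs(pa - pb / sum(pb)))
  }
  observed <- dAgainstA(bS)
  null <- withSeed(seed, vapply(seq_len(replicates), function(i) {
    if (nullModel == "random-points") {
      dAgainstA(bB[sample.int(nrow(bB), nB), , drop = FALSE])
    } else {
      target <- stats::runif(2, extent[1, ], extent[2, ])
      dAgainstA(sweep(bS, 2, target - colMeans(bS), `+`))
    }
  }, numeric(1)))
  p <- if (alternative == "greater")
    (1 + sum(null >= observed)) / (replicates + 1)
  else (1 + sum(null <= observed)) / (replicates + 1)
  list(p = p, observedD = observed, null = null)
}

#' Niche expansion, stability and unfilling
#'
#' Within the analogue-environment region (cells where both scenarios'
#' environment densities exceed the `analogQuantile` quantile of their
#' positive values; 0 means simply e > 0 in both), expansion is the
#' z-weighted fraction of the paleo niche lying outside the current
#' niche, stability is its complement (expansion + stability = 1
#' exactly), and unfilling is the analogous fraction of the current
#' niche absent from the paleo niche.
#'
#' @param current,paleo \linkS4class{NicheGrid}s on a shared extent.
#' @param analogQuantile analogue-region quantile (default 0).
#' @param membershipMass niche membership is the smallest cell set
#'   holding this fraction of the grid's occupancy mass (a kernel
#'   utilization-distribution contour, default 0.95). With smooth kernel
#'   densities a literal z > 0 rule is degenerate — numerically tiny
#'   occupancy tails count as membership everywhere; set 1 to recover it.
#' @return named numeric: expansion, stability, unfilling.
#' @export
nicheDynamics <- function(current, paleo, analogQuantile = 0,
                          membershipMass = 0.95) {
  if (current@resolution != paleo@resolution ||
      max(abs(current@extent - paleo@extent)) > 1e-9)
    stop("grids must share extent and resolution")
  thr <- function(e) {
    if (analogQuantile <= 0) return(0)
    stats::quantile(e[e > 0], analogQuantile)
  }
  analog <- current@e > thr(current@e) & paleo@e > thr(paleo@e)
  if (!any(analog)) stop("empty analogue region")
  zC <- current@z; zP <- paleo@z
  inC <- zMembership(zC, membershipMass)
  inP <- zMembership(zP, membershipMass)
  denomP <- sum(zP[analog & inP])
  denomC <- sum(zC[analog & inC])
  if (denomP <= 0 || denomC <= 0)
    stop("no occupied cells inside the analogue region")
  expansion <- sum(zP[analog & inP & !inC]) / denomP
  unfilling <- sum(zC[analog & inC & !inP]) / denomC
  c(expansion = expansion, stability = 1 - expansion, unfilling = unfilling)
}

#' Niche centroid shifts in PCA space
#'
#' Density-weighted mean positions: `occShift` is the shift of the
#' occurrence-density centroid from a to b, `envShift` the same for the
#' available-environment density (the extent shift).
#'
#' @param a,b \linkS4class{NicheGrid}s on a shared extent.
#' @return list with 2-vectors `occShift` and `envShift`.
#' @export
centroidShift <- function(a, b) {
  if (a@resolution != b@resolution ||
      max(abs(a@extent - b@extent)) > 1e-9)
    stop("grids must share extent and resolution")
  R <- a@resolution
  ax1 <- seq(a@extent[1, 1], a@extent[2, 1], length.out = R)
  ax2 <- seq(a@extent[1, 2], a@extent[2, 2], length.out = R)
  centroid <- function(m) {
    tot <- sum(m)
    if (tot <= 0) stop("zero total density")
    c(sum(rowSums(m) * ax1), sum(colSums(m) * ax2)) / tot
  }
  list(occShift = centroid(b@o) - centroid(a@o),
       envShift = centroid(b@e) - centroid(a@e))
}
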
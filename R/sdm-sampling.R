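## Contrast-class sampling and training-table assembly for the SDMs.

#' Sample a background dataset over the territory
#'
#' Draws floor(fraction * n_unmasked_cells) distinct cells uniformly
#' without replacement; records are placed at cell centers with
#' role = "background".
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param fraction fraction of unmasked cells, in (0, 1]; default 0.2
#'   (20% of the points in the territory considered).
#' @param seed RNG seed.
#' @param period period label for the records.
#' @export
sampleBackground <- function(stack, fraction = 0.2, seed = 1L,
                             period = scenarioId(stack)) {
  stopifnot(fraction > 0, fraction <= 1)
  cells <- which(!nodataMask(stack))
  if (!length(cells)) stop("no unmasked cells to sample from")
  n <- floor(fraction * length(cells))
  if (n < 1) stop("fraction too small: no cells selected")
  pick <- withSeed(seed, safeSample(cells, n))
  d <- dim(nodataMask(stack))
  row <- ((pick - 1) %% d[1]) + 1L
  col <- ((pick - 1) %/% d[1]) + 1L
  co <- cellCoords(stack, row, col)
  newOccurrenceSet(co$x, co$y, role = "background", period = period)
}

#' Sample pseudoabsence cells avoiding presence cells
#'
#' Draws n distinct unmasked cells uniformly among those not containing
#' a presence record; role = "pseudoabsence". The default n equals the
#' number of presences.
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param presences \linkS4class{OccurrenceSet} of presences.
#' @param n number of pseudoabsences (default = number of presences).
#' @param seed RNG seed.
#' @export
samplePseudoabsences <- function(stack, presences, n = length(presences),
                                 seed = 1L,
                                 period = scenarioId(stack)) {
  d <- dim(nodataMask(stack))
  r <- records(presences)
  rc <- pointToCell(r$x, r$y, d[1], d[2], cellSize(stack), gridOrigin(stack))
  presIdx <- (rc$col - 1L) * d[1] + rc$row
  cells <- setdiff(which(!nodataMask(stack)), presIdx[!is.na(presIdx)])
  if (n > length(cells))
    stop("requested ", n, " pseudoabsences but only ", length(cells),
         " non-presence cells are available")
  pick <- withSeed(seed, safeSample(cells, n))
  row <- ((pick - 1) %% d[1]) + 1L
  col <- ((pick - 1) %/% d[1]) + 1L
  co <- cellCoords(stack, row, col)
  newOccurrenceSet(co$x, co$y, role = "pseudoabsence", period = period)
}

#' Assemble a presence/contrast training table
#'
#' Extracts environmental values at presence and contrast points. In
#' weighted-background mode each contrast row receives weight m/N (m
#' presences, N contrast rows) so total presence and contrast mass are
#' equal; otherwise all weights are 1.
#'
#' @param stack calibration \linkS4class{ClimateStack}.
#' @param presences presence \linkS4class{OccurrenceSet}.
#' @param contrast background or pseudoabsence \linkS4class{OccurrenceSet}.
#' @param contrastKind "background" or "pseudoabsence".
#' @param weighted logical; defaults to TRUE for background contrast
#'   (weighted-background mode) and FALSE otherwise.
#' @return a \linkS4class{TrainingTable}.
#' @export
buildTrainingTable <- function(stack, presences, contrast,
                               contrastKind = c("pseudoabsence", "background"),
                               weighted = match.arg(contrastKind) == "background") {
  contrastKind <- match.arg(contrastKind)
  presEnv <- extractEnv(stack, presences)
  contEnv <- extractEnv(stack, contrast)
  m <- nrow(presEnv); N <- nrow(contEnv)
  w <- c(rep(1, m), rep(if (weighted) m / N else 1, N))
  env <- rbind(presEnv, contEnv)
  d <- as.data.frame(env)
  d$label <- c(rep(1, m), rep(0, N))
  d$weight <- w
  rng <- rbind(min = apply(env, 2, min), max = apply(env, 2, max))
  new("TrainingTable", data = d, contrastKind = contrastKind,
      variableRanges = rng, variables = colnames(env))
}

# Build a TrainingTable directly from an environment matrix (internal,
# used by bootstrap splits).
tableFromData <- function(d, vars, contrastKind) {
  env <- as.matrix(d[, vars, drop = FALSE])
  rng <- rbind(min = apply(env, 2, min), max = apply(env, 2, max))
  # guard degenerate split ranges
  deg <- rng["max", ] <= rng["min", ]
  rng["max", deg] <- rng["min", deg] + 1e-9
  new("TrainingTable", data = d, contrastKind = contrastKind,
      variableRanges = rng, variables = vars)
}
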
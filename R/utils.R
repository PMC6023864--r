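## Internal helpers: seeded evaluation, grid geometry, numerics.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible 31-bit sub-seed from a master seed and a label.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# sample() without the length-1 "1:n" surprise
safeSample <- function(x, n = length(x), prob = NULL) {
  x[sample.int(length(x), n, prob = prob)]
}

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## ---- grid geometry -------------------------------------------------------
## row 1 = top (northernmost); origin = lower-left corner; half-open cells.

# x coordinates of cell centers, by column
colCenters <- function(ncol, cellSize, origin) {
  origin[1] + (seq_len(ncol) - 0.5) * cellSize
}

# y coordinates of cell centers, by row (row 1 = top)
rowCenters <- function(nrow, cellSize, origin) {
  origin[2] + (nrow - seq_len(nrow) + 0.5) * cellSize
}

# Map points to (row, col); NA where off-grid. Boundary points belong to
# the cell to the right/above.
pointToCell <- function(x, y, nrow, ncol, cellSize, origin) {
  col <- floor((x - origin[1]) / cellSize) + 1
  rowFromBottom <- floor((y - origin[2]) / cellSize) + 1
  row <- nrow - rowFromBottom + 1
  off <- col < 1 | col > ncol | row < 1 | row > nrow
  col[off] <- NA_integer_
  row[off] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# Environmental values at occurrence points: n x p matrix in stack
# variable order. Errors list the offending records.
extractEnv <- function(stack, occ) {
  r <- records(occ)
  d <- dim(nodataMask(stack))
  rc <- pointToCell(r$x, r$y, d[1], d[2], cellSize(stack), gridOrigin(stack))
  off <- is.na(rc$row)
  if (any(off))
    stop("occurrence record(s) off the grid: rows ",
         paste(which(off), collapse = ", "))
  idx <- cbind(rc$row, rc$col)
  masked <- nodataMask(stack)[idx]
  if (any(masked))
    stop("occurrence record(s) on masked cells: rows ",
         paste(which(masked), collapse = ", "))
  env <- vapply(gridValues(stack), function(m) m[idx], numeric(nrow(r)))
  env <- matrix(env, nrow = nrow(r),
                dimnames = list(NULL, variableNames(stack)))
  env
}

# Unmasked cells as an environment matrix plus their (row, col) indices.
unmaskedEnv <- function(stack) {
  keep <- which(!nodataMask(stack))
  env <- vapply(gridValues(stack), function(m) m[keep], numeric(length(keep)))
  env <- matrix(env, ncol = length(gridValues(stack)),
                dimnames = list(NULL, variableNames(stack)))
  d <- dim(nodataMask(stack))
  list(env = env,
       row = ((keep - 1) %% d[1]) + 1L,
       col = ((keep - 1) %/% d[1]) + 1L)
}

# Cell-center coordinates for linear cell indices of a stack grid.
cellCoords <- function(stack, row, col) {
  d <- dim(nodataMask(stack))
  data.frame(
    x = colCenters(d[2], cellSize(stack), gridOrigin(stack))[col],
    y = rowCenters(d[1], cellSize(stack), gridOrigin(stack))[row]
  )
}

newOccurrenceSet <- function(x, y, role, period, crsNote = "cartesian map units") {
  new("OccurrenceSet",
      records = data.frame(x = x, y = y, role = role, period = period,
                           stringsAsFactors = FALSE),
      crsNote = crsNote)
}
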
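## Raster and occurrence-table I/O.
##
## Raster dialect: ESRI ASCII grid (.asc) — a plain-text header
## (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value, in that
## order) followed by rows of values, top row first. Values round-trip
## at full double precision since the format is text.

#' Write a grid to an ESRI ASCII raster file
#'
#' @param map a \linkS4class{SuitabilityMap}, or a \linkS4class{ClimateStack}
#'   together with `variable` naming the layer to write.
#' @param path output file path.
#' @param variable for a ClimateStack, which variable to write.
#' @param nodata value written for masked cells (default -9999).
#' @return invisibly, the path.
#' @export
writeRaster <- function(map, path, variable = NULL, nodata = -9999) {
  if (is(map, "ClimateStack")) {
    if (is.null(variable) || !variable %in% variableNames(map))
      stop("writing a ClimateStack requires `variable` naming one layer")
    values <- gridValues(map)[[variable]]
    cs <- cellSize(map); org <- gridOrigin(map); mask <- nodataMask(map)
  } else if (is(map, "SuitabilityMap")) {
    values <- gridValues(map)
    cs <- cellSize(map); org <- gridOrigin(map); mask <- nodataMask(map)
  } else stop("map must be a ClimateStack or SuitabilityMap")
  values[mask | is.na(values)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(org[1], digits = 15)),
    paste("yllcorner", format(org[2], digits = 15)),
    paste("cellsize", format(cs, digits = 15)),
    paste("NODATA_value", format(nodata, digits = 15))
  ), con)
  apply(values, 1, function(r)
    writeLines(paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
                     collapse = " "), con))
  invisible(path)
}

# Parse one ESRI ASCII grid file into list(values, cellSize, origin, mask).
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("expected ", nr * nc, " values, found ", length(vals), " in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- m == nodata
  m[mask] <- NA_real_
  list(values = m, cellSize = hdr$cellsize,
       origin = c(hdr$xllcorner, hdr$yllcorner), mask = mask)
}

#' Read a set of single-layer rasters into a ClimateStack
#'
#' All files must share geometry; the nodata masks are unioned (a cell is
#' masked if masked in any layer).
#'
#' @param paths character vector of ESRI ASCII grid files.
#' @param labels variable labels, same length as paths.
#' @param scenarioId scenario label for the stack.
#' @return a \linkS4class{ClimateStack}.
#' @export
readRasterStack <- function(paths, labels, scenarioId = "scenario") {
  stopifnot(length(paths) == length(labels), length(paths) >= 1)
  layers <- lapply(paths, readAsciiGrid)
  ref <- layers[[1]]
  for (k in seq_along(layers)[-1]) {
    l <- layers[[k]]
    if (!identical(dim(l$values), dim(ref$values)) ||
        abs(l$cellSize - ref$cellSize) > 1e-9 ||
        any(abs(l$origin - ref$origin) > 1e-9))
      stop("raster geometry mismatch in layer '", labels[k],
           "' (", paths[k], ")")
  }
  mask <- Reduce(`|`, lapply(layers, `[[`, "mask"))
  vars <- lapply(layers, function(l) {
    m <- l$values
    m[mask] <- NA_real_   # harmonize: masked anywhere -> masked everywhere
    m
  })
  names(vars) <- labels
  new("ClimateStack", variables = vars, cellSize = ref$cellSize,
      origin = ref$origin, nodataMask = mask, scenarioId = scenarioId)
}

#' Write every variable of a stack as one ASCII grid per layer
#'
#' @param stack a \linkS4class{ClimateStack}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
writeClimateStack <- function(stack, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(variableNames(stack), ".asc"))
  names(paths) <- variableNames(stack)
  for (v in variableNames(stack)) writeRaster(stack, paths[[v]], variable = v)
  paths
}

#' Read an occurrence table from CSV
#'
#' Comma-separated, header row required, UTF-8. Rows with non-finite or
#' missing coordinates are dropped with a message giving the count.
#'
#' @param path CSV file path.
#' @param columnMap named character vector mapping internal fields
#'   (x, y, role, period) to CSV column names; role/period entries are
#'   optional and default to "presence" / "unknown" when the column is
#'   absent.
#' @return an \linkS4class{OccurrenceSet}.
#' @export
readOccurrences <- function(path,
                            columnMap = c(x = "x", y = "y",
                                          role = "role", period = "period")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (f in c("x", "y")) {
    col <- columnMap[[f]]
    if (is.null(col) || !col %in% names(df))
      stop("mandatory column for '", f, "' not found in ", path)
  }
  x <- suppressWarnings(as.numeric(df[[columnMap[["x"]]]]))
  y <- suppressWarnings(as.numeric(df[[columnMap[["y"]]]]))
  role <- if (!is.na(columnMap["role"]) && columnMap[["role"]] %in% names(df))
    as.character(df[[columnMap[["role"]]]]) else rep("presence", nrow(df))
  period <- if (!is.na(columnMap["period"]) && columnMap[["period"]] %in% names(df))
    as.character(df[[columnMap[["period"]]]]) else rep("unknown", nrow(df))
  bad <- !is.finite(x) | !is.finite(y)
  if (any(bad))
    message("readOccurrences: dropped ", sum(bad),
            " record(s) with non-finite coordinates")
  newOccurrenceSet(x[!bad], y[!bad], role[!bad], period[!bad])
}

#' Write an occurrence table to CSV
#'
#' @param occ an \linkS4class{OccurrenceSet}.
#' @param path output CSV path.
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(records(occ), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a report object to JSON
#'
#' @param x a data.frame or list report.
#' @param path output path.
#' @export
writeReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
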
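## Accessor generics: slots are never reached into from user code.

#' @rdname accessors
#' @param x a paleoniche S4 object
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))
#' @rdname accessors
#' @export
setGeneric("scenarioId", function(x) standardGeneric("scenarioId"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("occurrenceDensity", function(x) standardGeneric("occurrenceDensity"))
#' @rdname accessors
#' @export
setGeneric("environmentDensity", function(x) standardGeneric("environmentDensity"))
#' @rdname accessors
#' @export
setGeneric("gridExtent", function(x) standardGeneric("gridExtent"))
#' @rdname accessors
#' @export
setGeneric("fitMetric", function(x) standardGeneric("fitMetric"))
#' @rdname accessors
#' @export
setGeneric("algorithmName", function(x) standardGeneric("algorithmName"))
#' @rdname accessors
#' @export
setGeneric("variableImportance", function(x) standardGeneric("variableImportance"))
#' @rdname accessors
#' @export
setGeneric("variableRanges", function(x) standardGeneric("variableRanges"))
#' @rdname accessors
#' @export
setGeneric("keptVariables", function(x) standardGeneric("keptVariables"))
#' @rdname accessors
#' @export
setGeneric("droppedVariables", function(x) standardGeneric("droppedVariables"))

#' Accessors for paleoniche classes
#'
#' Read-only access to the slots of the core containers.
#'
#' @name accessors
#' @return The requested component.
NULL

#' @rdname accessors
setMethod("variableNames", "ClimateStack", function(x) names(x@variables))
#' @rdname accessors
setMethod("variableNames", "TrainingTable", function(x) x@variables)
#' @rdname accessors
setMethod("variableNames", "SDMModel", function(x) x@variables)

#' @rdname accessors
setMethod("gridValues", "ClimateStack", function(x) x@variables)
#' @rdname accessors
setMethod("gridValues", "SuitabilityMap", function(x) x@values)

#' @rdname accessors
setMethod("cellSize", "ClimateStack", function(x) x@cellSize)
#' @rdname accessors
setMethod("cellSize", "SuitabilityMap", function(x) x@cellSize)
#' @rdname accessors
setMethod("gridOrigin", "ClimateStack", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "SuitabilityMap", function(x) x@origin)
#' @rdname accessors
setMethod("nodataMask", "ClimateStack", function(x) x@nodataMask)
#' @rdname accessors
setMethod("nodataMask", "SuitabilityMap", function(x) x@nodataMask)
#' @rdname accessors
setMethod("scenarioId", "ClimateStack", function(x) x@scenarioId)
#' @rdname accessors
setMethod("scenarioId", "SuitabilityMap", function(x) x@scenarioId)
#' @rdname accessors
setMethod("scenarioId", "NicheGrid", function(x) x@scenarioId)

#' @rdname accessors
setMethod("records", "OccurrenceSet", function(x) x@records)

#' @rdname accessors
setMethod("occupancy", "NicheGrid", function(x) x@z)
#' @rdname accessors
setMethod("occurrenceDensity", "NicheGrid", function(x) x@o)
#' @rdname accessors
setMethod("environmentDensity", "NicheGrid", function(x) x@e)
#' @rdname accessors
setMethod("gridExtent", "NicheGrid", function(x) x@extent)

#' @rdname accessors
setMethod("fitMetric", "SDMModel", function(x) x@fitMetric)
#' @rdname accessors
setMethod("algorithmName", "SDMModel", function(x) x@algorithm)
#' @rdname accessors
setMethod("variableImportance", "SDMModel", function(x) x@importance)
#' @rdname accessors
setMethod("variableRanges", "SDMModel", function(x) x@variableRanges)
#' @rdname accessors
setMethod("variableRanges", "TrainingTable", function(x) x@variableRanges)

#' @rdname accessors
setMethod("keptVariables", "VariableSelection", function(x) x@kept)
#' @rdname accessors
setMethod("droppedVariables", "VariableSelection", function(x) x@dropped)

#' Number of records in an OccurrenceSet
#' @param x an OccurrenceSet
#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@records))

#' Tabulate an OverlapReport as a one-row data.frame
#'
#' @param x an OverlapReport
#' @param row.names,optional,... ignored (S3 compatibility)
#' @return one-row data.frame shaped like a niche-overlap results table.
#' @export
as.data.frame.OverlapReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    pair = x@pair,
    D = x@D,
    expansion = x@expansion,
    stability = x@stability,
    unfilling = x@unfilling,
    equivalency_p = x@equivalencyP,
    similarity_p_a_to_b = x@similarityPAToB,
    similarity_p_b_to_a = x@similarityPBToA,
    n_replicates = x@nReplicates,
    stringsAsFactors = FALSE
  )
}
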
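#' @rdname CohortSchema-class
#' @param x a \linkS4class{CohortSchema}, \linkS4class{Cohort} or other object
#'   carrying a schema.
#' @export
setGeneric("eventLabels", function(x) standardGeneric("eventLabels"))

#' @rdname CohortSchema-class
#' @export
setGeneric("terminalLabel", function(x) standardGeneric("terminalLabel"))

#' @rdname CohortSchema-class
#' @export
setGeneric("attributeNames", function(x) standardGeneric("attributeNames"))

#' @rdname CohortSchema-class
#' @export
setGeneric("baselineNames", function(x) standardGeneric("baselineNames"))

#' @rdname CohortSchema-class
#' @export
setGeneric("relevanceMap", function(x) standardGeneric("relevanceMap"))

#' Accessors for Cohort objects
#'
#' `baselineTable()` returns the one-row-per-individual demographics table,
#' `eventTable()` the harmonized chronological event stream, `schemaOf()` the
#' attached schema and `nIndividuals()` the number of individuals.
#'
#' @param x a \linkS4class{Cohort} (or object with a schema).
#' @return the corresponding slot contents.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("baselineTable", function(x) standardGeneric("baselineTable"))

#' @rdname cohort-accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname cohort-accessors
#' @export
setGeneric("schemaOf", function(x) standardGeneric("schemaOf"))

#' @rdname cohort-accessors
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))
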
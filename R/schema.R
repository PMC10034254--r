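#' Declare an event attribute or baseline variable
#'
#' Attributes are wholly categorical inside the model: originally-continuous
#' measurements (lab results, resource intensity weights, age, sojourn time)
#' are quantile-binned at encoding time into `bins` categories, so that every
#' prediction head is a softmax over a finite vocabulary. Categorical
#' variables declare their ordered level set directly; level index 0 is
#' reserved for the missing/padding code in every vocabulary.
#'
#' @param name variable name (must match the event/baseline table column).
#' @param type `"categorical"` or `"continuous"`.
#' @param levels ordered character vector of categories (categorical only).
#' @param bins number of quantile bins (continuous only; default 20).
#' @return a plain list of class `attributeDef` used in [cohortSchema()].
#' @export
attributeDef <- function(name, type = c("categorical", "continuous"),
                         levels = NULL, bins = 20L) {
  type <- match.arg(type)
  if (type == "categorical") {
    assertThat(is.character(levels) && length(levels) >= 1 &&
                 !anyDuplicated(levels),
               "categorical attribute '", name,
               "' needs a duplicate-free character 'levels' vocabulary")
  } else {
    assertThat(is.numeric(bins) && bins >= 2,
               "continuous attribute '", name, "' needs bins >= 2")
  }
  structure(list(name = name, type = type, levels = levels,
                 bins = as.integer(bins)),
            class = "attributeDef")
}

#' Construct a CohortSchema
#'
#' See \linkS4class{CohortSchema} for the meaning of each component. The
#' padding code is implicit: it always occupies index 0 of the label
#' vocabulary and of every attribute vocabulary, and is never listed in
#' `eventLabels` or in an attribute's levels.
#'
#' @param eventLabels ordered character vector of event-type codes.
#' @param terminalLabel optional terminal ("last observation") label; must be
#'   one of `eventLabels`. Its relevance set may contain at most `"sojourn"`.
#' @param attributes list of [attributeDef()] objects.
#' @param relevance named list label -> character vector of attribute names
#'   measured for that label.
#' @param baselineVars list of [attributeDef()] objects for the
#'   cross-sectional variables.
#' @param tableMap optional source-table mapping for [harmonizeTables()].
#' @return a validated \linkS4class{CohortSchema}.
#' @examples
#' sc <- cohortSchema(
#'   eventLabels = c("lab", "ed_visit", "last_obs"),
#'   terminalLabel = "last_obs",
#'   attributes = list(
#'     attributeDef("sojourn", "continuous", bins = 10),
#'     attributeDef("result", "categorical", levels = c("low", "norm", "high"))),
#'   relevance = list(lab = c("sojourn", "result"), ed_visit = "sojourn",
#'                    last_obs = "sojourn"),
#'   baselineVars = list(
#'     attributeDef("age", "continuous", bins = 8),
#'     attributeDef("sex", "categorical", levels = c("F", "M"))))
#' eventLabels(sc)
#' @export
cohortSchema <- function(eventLabels, terminalLabel = NA_character_,
                         attributes = list(), relevance = list(),
                         baselineVars = list(), tableMap = list()) {
  names(attributes) <- vapply(attributes, `[[`, "", "name")
  names(baselineVars) <- vapply(baselineVars, `[[`, "", "name")
  new("CohortSchema", eventLabels = eventLabels,
      terminalLabel = as.character(terminalLabel), attributes = attributes,
      relevance = relevance, baselineVars = baselineVars,
      tableMap = tableMap)
}

setValidity("CohortSchema", function(object) {
  msgs <- character()
  lab <- object@eventLabels
  if (!length(lab) || anyDuplicated(lab))
    msgs <- c(msgs, "eventLabels must be non-empty and duplicate-free")
  term <- object@terminalLabel
  if (!is.na(term) && !term %in% lab)
    msgs <- c(msgs, "terminalLabel must be one of eventLabels")
  anames <- names(object@attributes)
  for (a in object@attributes) {
    if (!inherits(a, "attributeDef"))
      msgs <- c(msgs, "attributes must be attributeDef objects")
  }
  if (!all(names(object@relevance) %in% lab))
    msgs <- c(msgs, "relevance names must be event labels")
  relAttrs <- unlist(object@relevance, use.names = FALSE)
  if (!all(relAttrs %in% anames))
    msgs <- c(msgs, "relevance refers to undeclared attributes")
  orphan <- setdiff(anames, relAttrs)
  if (length(orphan))
    msgs <- c(msgs, paste0("attribute(s) relevant for no label: ",
                           paste(orphan, collapse = ", ")))
  if (!is.na(term)) {
    extra <- setdiff(object@relevance[[term]] %||% character(), "sojourn")
    if (length(extra))
      msgs <- c(msgs, "terminal label may only have a sojourn-only relevance set")
  }
  for (nm in names(object@tableMap)) {
    tm <- object@tableMap[[nm]]
    if (is.null(tm$label) || !tm$label %in% lab)
      msgs <- c(msgs, paste0("tableMap '", nm, "' has no valid label"))
    if (length(tm$columns) && !all(tm$columns %in% anames))
      msgs <- c(msgs, paste0("tableMap '", nm, "' maps to undeclared attributes"))
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname CohortSchema-class
#' @export
setMethod("eventLabels", "CohortSchema", function(x) x@eventLabels)

#' @rdname CohortSchema-class
#' @export
setMethod("terminalLabel", "CohortSchema", function(x) x@terminalLabel)

#' @rdname CohortSchema-class
#' @export
setMethod("attributeNames", "CohortSchema", function(x) names(x@attributes))

#' @rdname CohortSchema-class
#' @export
setMethod("baselineNames", "CohortSchema", function(x) names(x@baselineVars))

#' @rdname CohortSchema-class
#' @export
setMethod("relevanceMap", "CohortSchema", function(x) x@relevance)

## Full label vocabulary including the reserved padding code at index 0.
labelVocabulary <- function(schema) c("<pad>", schema@eventLabels)

## Logical (C+1) x A matrix: is attribute a relevant for label code l (0-based
## row l+1)? Row 1 (the padding code) is all FALSE.
relevanceMatrix <- function(schema) {
  A <- attributeNames(schema)
  out <- matrix(FALSE, nrow = length(schema@eventLabels) + 1L,
                ncol = length(A),
                dimnames = list(labelVocabulary(schema), A))
  for (l in names(schema@relevance))
    out[l, schema@relevance[[l]]] <- TRUE
  out
}

setMethod("show", "CohortSchema", function(object) {
  cat("CohortSchema\n")
  cat("  labels:   ", paste(object@eventLabels, collapse = ", "),
      if (!is.na(object@terminalLabel))
        paste0(" (terminal: ", object@terminalLabel, ")"), "\n", sep = "")
  cat("  attributes: ", length(object@attributes), " (",
      paste(names(object@attributes), collapse = ", "), ")\n", sep = "")
  cat("  baseline:   ", length(object@baselineVars), " (",
      paste(names(object@baselineVars), collapse = ", "), ")\n", sep = "")
})

## ---- serialization to/from plain lists (YAML-able) ----

schemaToList <- function(schema) {
  defList <- function(d) list(name = d$name, type = d$type,
                              levels = d$levels, bins = d$bins)
  list(event_labels = schema@eventLabels,
       terminal_label = if (is.na(schema@terminalLabel)) NULL else schema@terminalLabel,
       attributes = lapply(schema@attributes, defList),
       relevance = schema@relevance,
       baseline_vars = lapply(schema@baselineVars, defList),
       table_map = schema@tableMap)
}

schemaFromList <- function(x) {
  mk <- function(d) attributeDef(d$name, d$type,
                                 levels = unlist(d$levels) %||% NULL,
                                 bins = d$bins %||% 20L)
  cohortSchema(eventLabels = unlist(x$event_labels),
               terminalLabel = x$terminal_label %||% NA_character_,
               attributes = lapply(unname(x$attributes), mk),
               relevance = lapply(x$relevance, unlist),
               baselineVars = lapply(unname(x$baseline_vars), mk),
               tableMap = x$table_map %||% list())
}

#' Read or write a schema as a YAML file
#'
#' @param schema a \linkS4class{CohortSchema}.
#' @param path file path.
#' @return `readSchema` returns a \linkS4class{CohortSchema};
#'   `writeSchema` returns `path` invisibly.
#' @export
writeSchema <- function(schema, path) {
  yaml::write_yaml(schemaToList(schema), path)
  invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) schemaFromList(yaml::read_yaml(path))
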
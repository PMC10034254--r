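#' Construct a Cohort
#'
#' Usually produced by [harmonizeTables()], [simulateCohort()] or
#' [generateCohort()]; the constructor validates referential integrity,
#' chronological ordering and attribute relevance.
#'
#' @param baseline data.frame with `patient_id` plus the schema's baseline
#'   variables.
#' @param events data.frame with `patient_id`, `position`, `label`, `date`
#'   and one column per schema attribute.
#' @param schema the \linkS4class{CohortSchema}.
#' @return a validated \linkS4class{Cohort}.
#' @export
newCohort <- function(baseline, events, schema) {
  for (a in attributeNames(schema))
    if (!a %in% names(events)) events[[a]] <- NA
  new("Cohort", baseline = baseline, events = events, schema = schema)
}

setValidity("Cohort", function(object) {
  msgs <- character()
  b <- object@baseline; e <- object@events; sc <- object@schema
  if (!"patient_id" %in% names(b)) msgs <- c(msgs, "baseline lacks patient_id")
  missingBase <- setdiff(baselineNames(sc), names(b))
  if (length(missingBase))
    msgs <- c(msgs, paste0("baseline lacks variable(s): ",
                           paste(missingBase, collapse = ", ")))
  need <- c("patient_id", "position", "label", "date")
  if (!all(need %in% names(e)))
    msgs <- c(msgs, paste0("events lacks column(s): ",
                           paste(setdiff(need, names(e)), collapse = ", ")))
  if (!length(msgs) && nrow(e)) {
    if (!all(e$patient_id %in% b$patient_id))
      msgs <- c(msgs, "events contain patient ids absent from baseline")
    if (!all(e$label %in% eventLabels(sc)))
      msgs <- c(msgs, "events contain labels outside the schema vocabulary")
    dd <- unlist(tapply(e$date, e$patient_id, function(d) diff(d) < 0),
                 use.names = FALSE)
    if (any(dd %||% FALSE))
      msgs <- c(msgs, "event dates decrease within an individual")
    if ("sojourn" %in% names(e) && any(e$sojourn < 0, na.rm = TRUE))
      msgs <- c(msgs, "negative sojourn times")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname cohort-accessors
#' @export
setMethod("baselineTable", "Cohort", function(x) x@baseline)

#' @rdname cohort-accessors
#' @export
setMethod("eventTable", "Cohort", function(x) x@events)

#' @rdname cohort-accessors
#' @export
setMethod("schemaOf", "Cohort", function(x) x@schema)

#' @rdname cohort-accessors
#' @export
setMethod("nIndividuals", "Cohort", function(x) nrow(x@baseline))

setMethod("show", "Cohort", function(object) {
  cat("Cohort: ", nrow(object@baseline), " individuals, ",
      nrow(object@events), " events\n", sep = "")
  if (nrow(object@events)) {
    tab <- table(object@events$label)
    cat("  events by label: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
    len <- table(factor(object@events$patient_id,
                        levels = object@baseline$patient_id))
    cat("  sequence length: mean ", round(mean(len), 2), ", max ", max(len),
        "\n", sep = "")
  }
})

#' Harmonize a demographics table and event tables into a Cohort
#'
#' Interleaves all transactional tables into one chronological event stream
#' per individual, the linked multi-table form of administrative health data:
#' a demographics table with one row per individual plus several event tables
#' with many rows per individual, joined by the patient id. Rows are ordered
#' by relative date within individual; same-day ties are broken by the order
#' of tables in the schema's `tableMap` (a fixed priority), then by source
#' row order, so harmonization is deterministic.
#'
#' @param demographics data.frame with `patient_id` and baseline columns.
#' @param eventTables named list of data.frames; names must match the
#'   schema's `tableMap` entries, which declare each table's event label, its
#'   relative-date column and its column-to-attribute mapping.
#' @param schema a \linkS4class{CohortSchema} with a non-empty `tableMap`.
#' @return a \linkS4class{Cohort}; attributes not belonging to a row's source
#'   table are `NA`. Patient ids are regenerated as sequential integers.
#' @export
harmonizeTables <- function(demographics, eventTables, schema) {
  assertThat("patient_id" %in% names(demographics),
             "demographics must have a patient_id column")
  assertThat(length(schema@tableMap) > 0, "schema has no tableMap")
  assertThat(all(names(eventTables) %in% names(schema@tableMap)),
             "event table(s) not declared in schema tableMap: ",
             paste(setdiff(names(eventTables), names(schema@tableMap)),
                   collapse = ", "))
  A <- attributeNames(schema)
  pieces <- list()
  for (pr in seq_along(schema@tableMap)) {
    nm <- names(schema@tableMap)[pr]
    if (!nm %in% names(eventTables)) next
    tm <- schema@tableMap[[nm]]
    tab <- eventTables[[nm]]
    if (!nrow(tab)) next
    dateCol <- tm$dateColumn %||% "date"
    assertThat(all(c("patient_id", dateCol) %in% names(tab)),
               "table '", nm, "' lacks patient_id or '", dateCol, "'")
    bad <- setdiff(tab$patient_id, demographics$patient_id)
    if (length(bad))
      stop("referential integrity: table '", nm, "' has patient id(s) ",
           "absent from demographics: ", paste(head(bad, 5), collapse = ", "),
           call. = FALSE)
    unmapped <- setdiff(names(tab), c("patient_id", dateCol, names(tm$columns)))
    if (length(unmapped))
      stop("schema error: table '", nm, "' has unmapped column(s): ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    p <- data.frame(patient_id = tab$patient_id, label = tm$label,
                    date = as.numeric(tab[[dateCol]]),
                    .priority = pr, .src = seq_len(nrow(tab)))
    for (a in A) p[[a]] <- NA
    for (src in names(tm$columns)) p[[tm$columns[[src]]]] <- tab[[src]]
    pieces[[nm]] <- p
  }
  ev <- if (length(pieces)) do.call(rbind, pieces) else {
    p <- data.frame(patient_id = integer(), label = character(),
                    date = numeric(), .priority = integer(), .src = integer())
    for (a in A) p[[a]] <- logical()
    p
  }
  ## regenerate sequential patient ids (input ids are never copied through)
  idMap <- seq_len(nrow(demographics))
  names(idMap) <- as.character(demographics$patient_id)
  base <- demographics
  base$patient_id <- idMap[as.character(demographics$patient_id)]
  ev$patient_id <- unname(idMap[as.character(ev$patient_id)])
  ord <- order(ev$patient_id, ev$date, ev$.priority, ev$.src)
  ev <- ev[ord, , drop = FALSE]
  ev$position <- if (nrow(ev)) {
    unlist(lapply(split(seq_len(nrow(ev)), ev$patient_id), seq_along),
           use.names = FALSE)
  } else integer()
  ev$.priority <- NULL; ev$.src <- NULL
  rownames(ev) <- NULL
  ev <- ev[, c("patient_id", "position", "label", "date", A)]
  base <- base[order(base$patient_id), c("patient_id", baselineNames(schema))]
  rownames(base) <- NULL
  newCohort(base, ev, schema)
}

#' Compute sojourn times (days since the previous event)
#'
#' Event timing is modelled through sojourn time: for event k > 1 the days
#' elapsed since event k-1 of the same individual; the first event's sojourn
#' is 0 (so no external study-start anchor is needed). Same-day events get
#' sojourn 0. The result is stored in the `sojourn` attribute column.
#'
#' @param cohort a \linkS4class{Cohort} with chronologically sorted events.
#' @return the cohort with the `sojourn` column filled.
#' @export
computeSojourn <- function(cohort) {
  e <- cohort@events
  if (!nrow(e)) return(cohort)
  d <- unlist(tapply(e$date, factor(e$patient_id, levels = unique(e$patient_id)),
                     function(x) c(0, diff(x))), use.names = FALSE)
  if (any(d < 0)) stop("ordering error: negative date difference", call. = FALSE)
  e$sojourn <- as.numeric(d)
  cohort@events <- e
  cohort
}

#' Truncate long event sequences at an empirical percentile
#'
#' Caps each individual's event count at the empirical `percentile` of the
#' per-individual counts, further bounded by `hardCap`; the chronologically
#' earliest events are kept. Long-sequence truncation keeps training tensors
#' bounded at the cost of not modelling the heaviest healthcare users.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param percentile fraction in (0, 1]; default 0.95.
#' @param hardCap absolute maximum events per individual; default 1000.
#' @return the truncated cohort, with attribute `"truncated"` giving the
#'   number of individuals that lost events and `"cap"` the applied cap.
#' @export
truncateSequences <- function(cohort, percentile = 0.95, hardCap = 1000L) {
  assertThat(percentile > 0 && percentile <= 1, "percentile must be in (0,1]")
  assertThat(hardCap >= 1, "hardCap must be >= 1")
  e <- cohort@events
  if (!nrow(e)) {
    attr(cohort, "truncated") <- 0L; attr(cohort, "cap") <- hardCap
    return(cohort)
  }
  counts <- table(e$patient_id)
  cap <- min(as.integer(quantile(as.integer(counts), percentile, type = 1)),
             as.integer(hardCap))
  keep <- e$position <= cap
  nTrunc <- length(unique(e$patient_id[!keep]))
  cohort@events <- e[keep, , drop = FALSE]
  rownames(cohort@events) <- NULL
  attr(cohort, "truncated") <- nTrunc
  attr(cohort, "cap") <- cap
  cohort
}

#' Read or write a Cohort as a two-file CSV directory
#'
#' The harmonized cohort round-trips to `baseline.csv` and `events.csv` in
#' `dir` (plus `schema.yaml` if `withSchema`).
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param dir directory (created if needed).
#' @param withSchema also write/read `schema.yaml`.
#' @param schema used by `readCohortDir` when `withSchema = FALSE`.
#' @return `writeCohortDir` returns `dir` invisibly; `readCohortDir` a
#'   \linkS4class{Cohort}.
#' @export
writeCohortDir <- function(cohort, dir, withSchema = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort@baseline, file.path(dir, "baseline.csv"), row.names = FALSE)
  write.csv(cohort@events, file.path(dir, "events.csv"), row.names = FALSE)
  if (withSchema) writeSchema(cohort@schema, file.path(dir, "schema.yaml"))
  invisible(dir)
}

#' @rdname writeCohortDir
#' @export
readCohortDir <- function(dir, schema = NULL) {
  if (is.null(schema)) schema <- readSchema(file.path(dir, "schema.yaml"))
  base <- read.csv(file.path(dir, "baseline.csv"))
  ev <- read.csv(file.path(dir, "events.csv"))
  newCohort(base, ev, schema)
}

## per-individual sequence lengths, in baseline order
sequenceLengths <- function(cohort) {
  as.integer(table(factor(cohort@events$patient_id,
                          levels = cohort@baseline$patient_id)))
}
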
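#' Patient-level analysis table of a cohort
#'
#' Materializes the relational view most cohort queries run against: one row
#' per individual with the baseline variables, the sequence length, total
#' follow-up time (last event date), per-label event counts and presence
#' indicators, and the per-individual mean of every continuous attribute
#' over the events where it is relevant.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @return data.frame keyed by `patient_id`.
#' @export
patientSummaryTable <- function(cohort) {
  sc <- cohort@schema
  b <- cohort@baseline
  e <- cohort@events
  out <- b[, c("patient_id", baselineNames(sc)), drop = FALSE]
  pid <- factor(e$patient_id, levels = b$patient_id)
  out$n_events <- as.integer(table(pid))
  fu <- tapply(e$date, pid, max)
  out$followup <- as.numeric(ifelse(is.na(fu), 0, fu))
  for (l in eventLabels(sc)) {
    cnt <- as.integer(table(factor(e$patient_id[e$label == l],
                                   levels = b$patient_id)))
    out[[paste0("n_", l)]] <- cnt
    out[[paste0("any_", l)]] <- as.integer(cnt > 0)
  }
  rel <- relevanceMap(sc)
  for (a in attributeNames(sc)) {
    if (sc@attributes[[a]]$type != "continuous") next
    okLabs <- names(rel)[vapply(rel, function(r) a %in% r, TRUE)]
    sel <- e$label %in% okLabs & !is.na(e[[a]])
    mn <- tapply(e[[a]][sel], factor(e$patient_id[sel], levels = b$patient_id),
                 mean)
    out[[paste0("mean_", a)]] <- as.numeric(mn)
  }
  rownames(out) <- NULL
  out
}

## ---- random query grammar ----
## A query is: up to 3 conjunctive predicates (equality on a categorical
## column with a value observed in the real data, or a one-sided range on a
## numeric column anchored at an observed quantile), then either one
## aggregate (COUNT, or AVG of a numeric column) or one GROUP BY on a
## categorical column whose normalized group distribution is compared.

randomQuery <- function(realTab, catCols, numCols) {
  nPred <- sample(0:3, 1)
  preds <- list()
  for (p in seq_len(nPred)) {
    if (length(catCols) && (runif(1) < 0.5 || !length(numCols))) {
      col <- sample(catCols, 1)
      val <- sample(unique(as.character(realTab[[col]])), 1)
      preds[[p]] <- list(kind = "eq", col = col, val = val)
    } else {
      col <- sample(numCols, 1)
      cut <- as.numeric(quantile(realTab[[col]], runif(1, 0.1, 0.9),
                                 na.rm = TRUE))
      preds[[p]] <- list(kind = if (runif(1) < 0.5) "ge" else "le",
                         col = col, val = cut)
    }
  }
  if (runif(1) < 0.5 && length(catCols)) {
    list(preds = preds, kind = "groupby", col = sample(catCols, 1))
  } else if (runif(1) < 0.5 || !length(numCols)) {
    list(preds = preds, kind = "count")
  } else {
    list(preds = preds, kind = "avg", col = sample(numCols, 1))
  }
}

queryText <- function(q) {
  sel <- switch(q$kind,
    count = "SELECT COUNT(*)",
    avg = paste0("SELECT AVG(", q$col, ")"),
    groupby = paste0("SELECT ", q$col, ", COUNT(*)"))
  wh <- if (length(q$preds)) {
    paste(" WHERE", paste(vapply(q$preds, function(p) switch(p$kind,
      eq = paste0(p$col, " = '", p$val, "'"),
      ge = paste0(p$col, " >= ", signif(p$val, 6)),
      le = paste0(p$col, " <= ", signif(p$val, 6))), ""),
      collapse = " AND "))
  } else ""
  gb <- if (q$kind == "groupby") paste0(" GROUP BY ", q$col) else ""
  paste0(sel, " FROM cohort", wh, gb)
}

applyPredicates <- function(tab, preds) {
  keep <- rep(TRUE, nrow(tab))
  for (p in preds) {
    keep <- keep & switch(p$kind,
      eq = as.character(tab[[p$col]]) == p$val,
      ge = tab[[p$col]] >= p$val,
      le = tab[[p$col]] <= p$val)
  }
  tab[keep & !is.na(keep), , drop = FALSE]
}

runQuery <- function(tab, q) {
  sub <- applyPredicates(tab, q$preds)
  switch(q$kind,
    count = nrow(sub),
    avg = if (nrow(sub)) mean(sub[[q$col]], na.rm = TRUE) else NA_real_,
    groupby = if (nrow(sub)) probTable(as.character(sub[[q$col]])) else NULL)
}

#' Random-cohort (query-fuzzing) utility assessment
#'
#' Generates `nQueries` random semantically and syntactically valid SELECT
#' queries from a fixed grammar — random conjunctive filters drawn from
#' values observed in the real data, then a count, a mean, or a group-by —
#' and applies each simultaneously to the real and synthetic patient-level
#' tables. Grouped results are compared with the Hellinger distance on the
#' normalized group distribution; scalar aggregates with the normalized
#' Euclidean distance `|a - b| / sqrt(a^2 + b^2)` (0 when both are 0). A
#' query empty on both sides is skipped; empty on exactly one side scores
#' the maximal distance 1. Fully reproducible by seed, and every generated
#' query is logged as SQL-like text.
#'
#' @param real,syn \linkS4class{Cohort} objects.
#' @param nQueries number of random queries (default 100).
#' @param seed RNG seed.
#' @return list with a per-query `log` data.frame and `hellinger` /
#'   `euclidean` mean/SD/median/IQR summaries.
#' @export
randomCohortAssessment <- function(real, syn, nQueries = 100L, seed = 1L) {
  realTab <- patientSummaryTable(real)
  synTab <- patientSummaryTable(syn)
  common <- setdiff(intersect(names(realTab), names(synTab)), "patient_id")
  realTab <- realTab[common]; synTab <- synTab[common]
  isCat <- vapply(realTab, function(x)
    is.character(x) || length(unique(x)) <= 8, TRUE)
  catCols <- names(realTab)[isCat]
  numCols <- names(realTab)[vapply(realTab, is.numeric, TRUE) & !isCat]
  logRows <- list()
  withSeed(seed, {
    for (qi in seq_len(nQueries)) {
      q <- randomQuery(realTab, catCols, numCols)
      rr <- runQuery(realTab, q)
      rs <- runQuery(synTab, q)
      kind <- if (q$kind == "groupby") "hellinger" else "euclidean"
      dist <- if (q$kind == "groupby") {
        if (is.null(rr) && is.null(rs)) NA_real_
        else if (is.null(rr) || is.null(rs)) 1
        else hellinger(rr, rs)
      } else {
        a <- rr; b <- rs
        if ((is.na(a) || !length(a)) && (is.na(b) || !length(b))) NA_real_
        else if (is.na(a) || is.na(b)) 1
        else if (a == 0 && b == 0) 0
        else abs(a - b) / sqrt(a^2 + b^2)
      }
      logRows[[qi]] <- data.frame(query = queryText(q), kind = kind,
                                  distance = dist,
                                  skipped = is.na(dist))
    }
  })
  log <- do.call(rbind, logRows)
  list(log = log,
       hellinger = summariseDistances(
         log$distance[log$kind == "hellinger" & !log$skipped]),
       euclidean = summariseDistances(
         log$distance[log$kind == "euclidean" & !log$skipped]))
}
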
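#' Configuration of the attribution-disclosure assessment
#'
#' @param quasiIdentifiers columns of the quasi-identifier table used for
#'   matching; defaults to age, sex and the death/hospitalization presence
#'   indicators where available.
#' @param threshold acceptable-risk bound; default 0.09, the common
#'   threshold for disclosure of clinical-trial and health data (equivalent
#'   to a minimal group size of 11 under maximum risk).
#' @param ageBand width (years) of the age bands used for matching a
#'   continuous age quasi-identifier; default 5.
#' @param sensitive the non-quasi-identifier attribute the adversary tries
#'   to learn; default `"comorbidity"`.
#' @param learn the "learns something new" indicator: `"majority"` (default)
#'   scores a match only when the majority sensitive value of the matched
#'   class equals the attacker record's value; `"always"` treats every match
#'   as learning (the maximum-risk scenario).
#' @return a named list of class `privacyConfig`.
#' @export
privacyConfig <- function(quasiIdentifiers = NULL, threshold = 0.09,
                          ageBand = 5, sensitive = "comorbidity",
                          learn = c("majority", "always")) {
  assertThat(threshold > 0 && threshold < 1, "threshold must be in (0,1)")
  structure(list(quasiIdentifiers = quasiIdentifiers, threshold = threshold,
                 ageBand = ageBand, sensitive = sensitive,
                 learn = match.arg(learn)),
            class = "privacyConfig")
}

#' Quasi-identifier table of a cohort
#'
#' One row per individual with the matching variables an adversary could
#' plausibly know: the baseline variables plus, for every event label, a
#' derived presence indicator (`any_<label>`) — covering death and
#' hospitalization indicators where those labels exist — and the sensitive
#' attribute.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @return data.frame.
#' @export
quasiIdentifierTable <- function(cohort) {
  patientSummaryTable(cohort)
}

## banded QI key per record; continuous QIs are banded, missing values get
## an explicit band of their own. `banded` (named logical) fixes which QIs
## to band; by default a numeric QI with more than 12 distinct values is
## treated as continuous.
qiBandDecision <- function(tables, qis) {
  vapply(qis, function(q) {
    any(vapply(tables, function(df) {
      x <- df[[q]]
      assertThat(!is.null(x), "quasi-identifier '", q, "' not in table")
      is.numeric(x) && length(unique(x)) > 12
    }, TRUE))
  }, TRUE)
}

qiKeys <- function(df, qis, ageBand, banded = NULL) {
  if (is.null(banded)) banded <- qiBandDecision(list(df), qis)
  parts <- lapply(qis, function(q) {
    x <- df[[q]]
    assertThat(!is.null(x), "quasi-identifier '", q, "' not in table")
    out <- if (is.numeric(x) && banded[[q]]) {
      as.character(floor(x / ageBand))
    } else as.character(x)
    out[is.na(out)] <- "<missing>"
    out
  })
  do.call(paste, c(parts, sep = "\r"))
}

#' Partition records into quasi-identifier equivalence classes
#'
#' Records sharing identical (banded) quasi-identifier values form an
#' equivalence class; the size of the class an attacking record matches
#' bounds its re-identification contribution at 1/size.
#'
#' @param df a record table (e.g. [quasiIdentifierTable()] output).
#' @param qis quasi-identifier column names.
#' @param ageBand band width for high-cardinality numeric QIs (default 5).
#' @param banded optional named logical fixing which QIs are banded; by
#'   default a numeric QI with more than 12 distinct values is. When two
#'   tables are compared the decision must be shared (the risk functions
#'   derive it jointly from both tables).
#' @return named list mapping each QI key to the integer row indices of its
#'   records.
#' @export
buildEquivalenceClasses <- function(df, qis, ageBand = 5, banded = NULL) {
  split(seq_len(nrow(df)), qiKeys(df, qis, ageBand, banded))
}

#' Attribution-disclosure risk in one attack direction
#'
#' Every attacking record is matched against the equivalence class with the
#' same (banded) quasi-identifier key in the target dataset. A matched
#' record contributes `1/class size` times a "learns something new"
#' indicator: whether the majority value of the sensitive attribute in the
#' matched class equals the attacker record's own sensitive value. The risk
#' is the average contribution over matched attackers scaled by the match
#' rate — equivalently, the sum of contributions over all attackers divided
#' by the number of attackers.
#'
#' @param real,syn \linkS4class{Cohort} objects or prepared record tables.
#' @param config a [privacyConfig()].
#' @param direction `"population_to_sample"` (real records attack the
#'   synthetic sample) or `"sample_to_population"`.
#' @return the risk in `[0, 1]`, with attributes `matchRate` and
#'   `nMatched`.
#' @export
attributionDisclosureRisk <- function(real, syn, config = privacyConfig(),
                                      direction = c("population_to_sample",
                                                    "sample_to_population")) {
  direction <- match.arg(direction)
  realTab <- if (is(real, "Cohort")) quasiIdentifierTable(real) else real
  synTab <- if (is(syn, "Cohort")) quasiIdentifierTable(syn) else syn
  qis <- config$quasiIdentifiers %||% defaultQis(realTab)
  if (direction == "population_to_sample") {
    attacker <- realTab; target <- synTab
  } else {
    attacker <- synTab; target <- realTab
  }
  sens <- config$sensitive
  assertThat(sens %in% names(attacker) && sens %in% names(target),
             "sensitive attribute '", sens, "' missing from a table")
  banded <- qiBandDecision(list(attacker, target), qis)
  tgtClasses <- buildEquivalenceClasses(target, qis, config$ageBand, banded)
  atkKeys <- qiKeys(attacker, qis, config$ageBand, banded)
  matched <- atkKeys %in% names(tgtClasses)
  if (!any(matched)) {
    warning("no quasi-identifier overlap between datasets: risk 0")
    r <- 0
    attr(r, "matchRate") <- 0; attr(r, "nMatched") <- 0L
    return(r)
  }
  ## per-class size and majority sensitive value in the target
  sizes <- lengths(tgtClasses)
  majority <- vapply(tgtClasses, function(ix) {
    v <- as.character(target[[sens]][ix])
    names(sort(table(v), decreasing = TRUE))[1]
  }, "")
  contrib <- numeric(nrow(attacker))
  mIdx <- which(matched)
  cls <- match(atkKeys[mIdx], names(tgtClasses))
  learns <- if (identical(config$learn %||% "majority", "always")) {
    rep(TRUE, length(mIdx))
  } else as.character(attacker[[sens]][mIdx]) == majority[cls]
  contrib[mIdx] <- (1 / sizes[cls]) * as.numeric(learns)
  risk <- sum(contrib) / nrow(attacker)
  attr(risk, "matchRate") <- mean(matched)
  attr(risk, "nMatched") <- sum(matched)
  risk
}

defaultQis <- function(tab) {
  cand <- c("age", "sex", "any_death", "any_last_obs", "any_hosp")
  out <- intersect(cand, names(tab))
  assertThat(length(out) > 0, "no default quasi-identifiers in table")
  out
}

#' Full two-direction privacy assessment
#'
#' Runs the attribution-disclosure estimator in both attack directions and
#' compares the larger risk to the threshold.
#'
#' @param real,syn \linkS4class{Cohort} objects or prepared record tables.
#' @param config a [privacyConfig()].
#' @return a \linkS4class{PrivacyReport}.
#' @export
assessPrivacy <- function(real, syn, config = privacyConfig()) {
  realTab <- if (is(real, "Cohort")) quasiIdentifierTable(real) else real
  synTab <- if (is(syn, "Cohort")) quasiIdentifierTable(syn) else syn
  qis <- config$quasiIdentifiers %||% defaultQis(realTab)
  config$quasiIdentifiers <- qis
  p2s <- attributionDisclosureRisk(realTab, synTab, config,
                                   "population_to_sample")
  s2p <- attributionDisclosureRisk(realTab, synTab, config,
                                   "sample_to_population")
  classes <- buildEquivalenceClasses(synTab, qis, config$ageBand,
                                     qiBandDecision(list(realTab, synTab),
                                                    qis))
  new("PrivacyReport", metrics = list(
    population_to_sample = as.numeric(p2s),
    sample_to_population = as.numeric(s2p),
    threshold = config$threshold,
    pass = max(as.numeric(p2s), as.numeric(s2p)) <= config$threshold,
    quasiIdentifiers = qis,
    matchCounts = c(population_to_sample = attr(p2s, "nMatched"),
                    sample_to_population = attr(s2p, "nMatched")),
    classSizes = summariseDistances(as.numeric(lengths(classes)))))
}

setMethod("show", "PrivacyReport", function(object) {
  m <- object@metrics
  cat("PrivacyReport (attribution disclosure)\n")
  cat(sprintf("  population -> sample risk: %.6f\n", m$population_to_sample))
  cat(sprintf("  sample -> population risk: %.6f\n", m$sample_to_population))
  cat(sprintf("  threshold %.2f: %s\n", m$threshold,
              if (m$pass) "PASS" else "FAIL"))
})
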
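#' Construct a SimulationSpec
#'
#' Low-level constructor; most users want [defaultSimulationSpec()], whose
#' documentation describes the component formats.
#'
#' @param nIndividuals,schema,baselineModel,strataRule,initProbs,kernels,attrModels,sojournModels,maxLength,seed
#'   see \linkS4class{SimulationSpec}.
#' @return a validated \linkS4class{SimulationSpec}.
#' @export
simulationSpec <- function(nIndividuals, schema, baselineModel, strataRule,
                           initProbs, kernels, attrModels = list(),
                           sojournModels = list(), maxLength = 60L,
                           seed = 1L) {
  new("SimulationSpec", nIndividuals = as.integer(nIndividuals),
      schema = schema, baselineModel = baselineModel, strataRule = strataRule,
      initProbs = initProbs, kernels = kernels, attrModels = attrModels,
      sojournModels = sojournModels, maxLength = as.integer(maxLength),
      seed = as.integer(seed))
}

setValidity("SimulationSpec", function(object) {
  msgs <- character()
  lab <- eventLabels(object@schema)
  term <- terminalLabel(object@schema)
  for (s in seq_along(object@kernels)) {
    K <- object@kernels[[s]]
    if (!is.matrix(K) || nrow(K) != length(lab) || ncol(K) != length(lab)) {
      msgs <- c(msgs, paste0("kernel ", s, " is not |labels| x |labels|"))
      next
    }
    if (any(K < 0) || any(K > 1))
      msgs <- c(msgs, paste0("kernel ", s, " has probabilities outside [0,1]"))
    if (any(abs(rowSums(K) - 1) > 1e-9))
      msgs <- c(msgs, paste0("kernel ", s, " has a non-stochastic row"))
    if (!is.na(term)) {
      ti <- match(term, lab)
      if (abs(K[ti, ti] - 1) > 1e-9)
        msgs <- c(msgs, paste0("kernel ", s, ": terminal label not absorbing"))
    }
  }
  if (length(object@initProbs) != length(object@kernels))
    msgs <- c(msgs, "initProbs and kernels must have one entry per stratum")
  if (length(msgs)) msgs else TRUE
})

#' A ready-made cohort simulator specification
#'
#' Emulates the structure of linked administrative health data: baseline
#' covariates (continuous age, binary sex, a small ordinal comorbidity
#' score), four heterogeneous event types — drug dispensation, emergency
#' department visit, hospitalization, and a terminal "last observation" —
#' with per-type attribute sets (sojourn time for every event; a resource
#' intensity weight measured only for ED visits and hospitalizations),
#' variable-length sequences ended by a terminal hazard, and baseline-driven
#' dynamics: the two sexes form two strata with distinct first-order Markov
#' kernels, so conditional generation has a target that is detectable with
#' modest samples (the stratum variable is categorical, hence carried into
#' the model without binning loss). No attempt is made to mimic any real
#' population's marginals.
#'
#' @param nIndividuals cohort size (default 2000).
#' @param maxLength maximum sequence length (default 60).
#' @param seed default simulation seed.
#' @return a \linkS4class{SimulationSpec}.
#' @export
defaultSimulationSpec <- function(nIndividuals = 2000L, maxLength = 60L,
                                  seed = 1L) {
  labs <- c("drug", "ed_visit", "hosp", "last_obs")
  schema <- cohortSchema(
    eventLabels = labs, terminalLabel = "last_obs",
    attributes = list(
      attributeDef("sojourn", "continuous", bins = 16L),
      attributeDef("riw", "continuous", bins = 12L)),
    relevance = list(drug = "sojourn",
                     ed_visit = c("sojourn", "riw"),
                     hosp = c("sojourn", "riw"),
                     last_obs = "sojourn"),
    baselineVars = list(
      attributeDef("age", "continuous", bins = 8L),
      attributeDef("sex", "categorical", levels = c("F", "M")),
      attributeDef("comorbidity", "categorical",
                   levels = as.character(0:5))))
  mk <- function(m) {
    rownames(m) <- colnames(m) <- labs
    m / rowSums(m)
  }
  ## stratum 1 (female): drug-dominated dynamics, low terminal hazard
  k1 <- mk(rbind(c(0.62, 0.20, 0.06, 0.12),
                 c(0.45, 0.35, 0.14, 0.06),
                 c(0.40, 0.25, 0.30, 0.05),
                 c(0.00, 0.00, 0.00, 1.00)))
  ## stratum 2 (male): more hospital-centred, higher terminal hazard
  k2 <- mk(rbind(c(0.35, 0.25, 0.25, 0.15),
                 c(0.20, 0.30, 0.40, 0.10),
                 c(0.15, 0.20, 0.55, 0.10),
                 c(0.00, 0.00, 0.00, 1.00)))
  simulationSpec(
    nIndividuals = nIndividuals, schema = schema,
    baselineModel = list(
      age = list(type = "normal", mean = 45, sd = 15, min = 18, max = 90),
      sex = list(type = "categorical", levels = c("F", "M"),
                 probs = c(0.49, 0.51)),
      comorbidity = list(type = "poisson", lambda = 1, max = 5)),
    strataRule = list(var = "sex", levels = c("F", "M")),
    initProbs = list(c(drug = 0.6, ed_visit = 0.3, hosp = 0.1, last_obs = 0),
                     c(drug = 0.4, ed_visit = 0.3, hosp = 0.3, last_obs = 0)),
    kernels = list(k1, k2),
    attrModels = list(
      riw = list(type = "gamma", shape = 2,
                 scale = c(drug = NA, ed_visit = 0.5, hosp = 1.5,
                           last_obs = NA),
                 strataFactor = c(1, 1.6))),
    sojournModels = list(
      drug = list(type = "geometric", mean = 12),
      ed_visit = list(type = "geometric", mean = 20),
      hosp = list(type = "geometric", mean = 30),
      last_obs = list(type = "geometric", mean = 15)),
    maxLength = maxLength, seed = seed)
}

## stratum index per baseline row, from the declarative rule: either numeric
## cutpoints (`breaks`) or an explicit category-to-stratum mapping (`levels`,
## one stratum per level)
strataIndex <- function(spec, baseline) {
  v <- baseline[[spec@strataRule$var]]
  if (!is.null(spec@strataRule$levels))
    return(match(as.character(v), spec@strataRule$levels))
  1L + findInterval(as.numeric(v), spec@strataRule$breaks)
}

#' Stratum index of each individual in a cohort
#'
#' Applies a simulation spec's stratum rule to a cohort's baseline table —
#' used to compare per-stratum transition structure between a generated
#' cohort and the ground-truth kernels.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param cohort a \linkS4class{Cohort}.
#' @return integer vector of stratum indices, one per individual.
#' @export
cohortStrata <- function(spec, cohort) strataIndex(spec, cohort@baseline)

#' Simulate a ground-truth cohort
#'
#' Per individual: draws baseline values from the spec's marginals, maps them
#' to a stratum, then iterates that stratum's Markov kernel from the initial
#' label distribution, emitting an event label, its relevant attributes and a
#' sojourn time at each step, until the terminal label or `maxLength`. Dates
#' are the cumulated sojourns. Bit-reproducible given `seed`.
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param seed simulation seed (defaults to the spec's).
#' @return a \linkS4class{Cohort} with sojourn times already filled.
#' @export
simulateCohort <- function(spec, seed = spec@seed) {
  withSeed(seed, {
    sc <- spec@schema
    n <- spec@nIndividuals
    labs <- eventLabels(sc)
    term <- terminalLabel(sc)
    termIdx <- if (is.na(term)) 0L else match(term, labs)
    base <- data.frame(patient_id = seq_len(n))
    for (v in baselineNames(sc)) {
      m <- spec@baselineModel[[v]]
      base[[v]] <- switch(m$type,
        normal = pmin(pmax(round(rnorm(n, m$mean, m$sd), 1), m$min), m$max),
        categorical = m$levels[sampleRows(
          matrix(m$probs, n, length(m$probs), byrow = TRUE), runif(n))],
        poisson = pmin(rpois(n, m$lambda), m$max),
        stop("unknown baseline model type: ", m$type))
      if (sc@baselineVars[[v]]$type == "categorical")
        base[[v]] <- as.character(base[[v]])
    }
    strat <- strataIndex(spec, base)
    ## label sequences: iterate kernels per individual
    seqs <- vector("list", n)
    for (i in seq_len(n)) {
      K <- spec@kernels[[strat[i]]]
      p0 <- spec@initProbs[[strat[i]]]
      lab <- integer(spec@maxLength)
      lab[1] <- sample.int(length(labs), 1L, prob = p0)
      L <- 1L
      while (L < spec@maxLength && lab[L] != termIdx) {
        L <- L + 1L
        lab[L] <- sample.int(length(labs), 1L, prob = K[lab[L - 1L], ])
      }
      seqs[[i]] <- lab[seq_len(L)]
    }
    lens <- lengths(seqs)
    ev <- data.frame(patient_id = rep(seq_len(n), lens),
                     position = unlist(lapply(lens, seq_len)),
                     label = labs[unlist(seqs)])
    ## sojourns: 0 at the first event, label-specific geometric afterwards
    soj <- numeric(nrow(ev))
    for (l in labs) {
      m <- spec@sojournModels[[l]]
      sel <- ev$label == l & ev$position > 1L
      soj[sel] <- rgeom(sum(sel), 1 / (1 + m$mean))
    }
    ev$sojourn <- soj
    ev$date <- unlist(tapply(soj, factor(ev$patient_id, levels = seq_len(n)),
                             cumsum), use.names = FALSE)
    ## attributes beyond sojourn, only where relevant
    rel <- relevanceMap(sc)
    for (a in setdiff(attributeNames(sc), "sojourn")) {
      m <- spec@attrModels[[a]]
      x <- rep(NA_real_, nrow(ev))
      for (l in labs) {
        if (!a %in% (rel[[l]] %||% character())) next
        sel <- ev$label == l
        sf <- m$strataFactor[strat[ev$patient_id[sel]]]
        x[sel] <- round(stats::rgamma(sum(sel), shape = m$shape,
                                      scale = m$scale[[l]] * sf), 2)
      }
      ev[[a]] <- x
    }
    ev <- ev[, c("patient_id", "position", "label", "date",
                 attributeNames(sc))]
    newCohort(base, ev, sc)
  })
}

#' Ground-truth transition matrix of a simulation stratum
#'
#' Returns the exact first-order kernel the simulator uses for `stratum`, as
#' a \linkS4class{TransitionMatrix} (terminal label excluded from the
#' contexts, since nothing ever follows it).
#'
#' @param spec a \linkS4class{SimulationSpec}.
#' @param stratum stratum index.
#' @return a \linkS4class{TransitionMatrix} of order 1.
#' @export
trueTransitionMatrix <- function(spec, stratum) {
  assertThat(stratum >= 1 && stratum <= length(spec@kernels),
             "unknown stratum: ", stratum)
  K <- spec@kernels[[stratum]]
  labs <- eventLabels(spec@schema)
  term <- terminalLabel(spec@schema)
  keep <- if (is.na(term)) labs else setdiff(labs, term)
  new("TransitionMatrix", order = 1L, contexts = keep, labels = labs,
      probs = K[keep, , drop = FALSE], counts = K[keep, , drop = FALSE] * NA)
}

setMethod("show", "SimulationSpec", function(object) {
  cat("SimulationSpec: ", object@nIndividuals, " individuals, ",
      length(object@kernels), " strata, max length ", object@maxLength,
      "\n", sep = "")
})
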
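## Shared fixtures, all built in code.

## Tiny three-label schema: A carries a categorical attribute, C is terminal.
toySchema <- function() {
  cohortSchema(
    eventLabels = c("A", "B", "C"),
    terminalLabel = "C",
    attributes = list(
      attributeDef("sojourn", "continuous", bins = 4L),
      attributeDef("val", "categorical", levels = c("x", "y"))),
    relevance = list(A = c("sojourn", "val"), B = "sojourn", C = "sojourn"),
    baselineVars = list(
      attributeDef("grp", "categorical", levels = c("g1", "g2"))))
}

## Build a toy cohort from a list of label-character vectors; dates advance
## by 1 day per event, the "val" attribute is "x" under label A.
toyCohort <- function(seqs, schema = toySchema()) {
  n <- length(seqs)
  base <- data.frame(patient_id = seq_len(n),
                     grp = rep(c("g1", "g2"), length.out = n))
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- seqs[[i]]
    data.frame(patient_id = i, position = seq_along(s), label = s,
               date = seq_along(s) - 1,
               sojourn = c(0, rep(1, length(s) - 1))[seq_along(s)],
               val = ifelse(s == "A", "x", NA))
  }))
  newCohort(base, ev, schema)
}

## Deterministic A->B->A chain spec (terminal never reached): every sequence
## alternates for exactly maxLength events, perfectly predictable.
chainSpec <- function(n = 60L, maxLength = 12L, seed = 1L) {
  labs <- c("A", "B", "last")
  schema <- cohortSchema(
    eventLabels = labs, terminalLabel = "last",
    attributes = list(attributeDef("sojourn", "continuous", bins = 2L)),
    relevance = list(A = "sojourn", B = "sojourn", last = "sojourn"),
    baselineVars = list(
      attributeDef("age", "continuous", bins = 3L)))
  K <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 1))
  rownames(K) <- colnames(K) <- labs
  simulationSpec(
    nIndividuals = n, schema = schema,
    baselineModel = list(age = list(type = "normal", mean = 50, sd = 5,
                                    min = 20, max = 80)),
    strataRule = list(var = "age", breaks = numeric(0)),
    initProbs = list(c(A = 1, B = 0, last = 0)),
    kernels = list(K),
    sojournModels = list(A = list(type = "geometric", mean = 2),
                         B = list(type = "geometric", mean = 2),
                         last = list(type = "geometric", mean = 2)),
    maxLength = maxLength, seed = seed)
}

## Small instance of the standard simulator for fast module tests.
quickSpec <- function(n = 300L, maxLength = 30L, seed = 1L) {
  defaultSimulationSpec(nIndividuals = n, maxLength = maxLength, seed = seed)
}

## Independent brute-force softmax cross entropy at one position.
bruteCE <- function(logits, trueCode) {
  -logits[trueCode + 1] + log(sum(exp(logits)))
}

## Reference 2nd-order transition matrix over labels A,B,C,D with terminal
## C (rows carry up to 0.01 printing/rounding slop).
exampleOrder2Matrix <- function() {
  m <- rbind(
    "A|B" = c(0.31, 0.29, 0.39, 0.00),
    "B|A" = c(0.42, 0.21, 0.22, 0.16),
    "A|D" = c(0.64, 0.11, 0.08, 0.18),
    "D|A" = c(0.38, 0.05, 0.23, 0.34),
    "B|D" = c(0.41, 0.31, 0.26, 0.02),
    "D|B" = c(0.01, 0.16, 0.57, 0.26),
    "A|A" = c(0.20, 0.40, 0.30, 0.10),
    "B|B" = c(0.36, 0.34, 0.25, 0.04),
    "D|D" = c(0.34, 0.48, 0.17, 0.01))
  colnames(m) <- c("A", "B", "C", "D")
  m
}
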
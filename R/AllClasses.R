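#' @import methods
NULL

#' CohortSchema: the declaration of a longitudinal cohort's structure
#'
#' A `CohortSchema` declares the vocabulary of event labels (with a reserved
#' padding code at index 0 and an optional terminal "last observation" label),
#' the event attributes with their category vocabularies or binning rules, the
#' relevance map saying which attributes are measured for which labels, the
#' baseline (cross-sectional) variables, and an optional mapping from source
#' event tables to labels and attribute columns used by [harmonizeTables()].
#'
#' @slot eventLabels ordered character vector of event-type codes (padding is
#'   implicit and always occupies vocabulary index 0).
#' @slot terminalLabel the label that terminates a sequence, or `NA`.
#' @slot attributes named list of attribute definitions as returned by
#'   [attributeDef()].
#' @slot relevance named list mapping each event label to the character vector
#'   of attribute names measured for that label.
#' @slot baselineVars named list of baseline variable definitions
#'   ([attributeDef()] with the same fields).
#' @slot tableMap named list describing source event tables for
#'   [harmonizeTables()]; each element has fields `label`, `dateColumn` and
#'   `columns` (named character: source column -> attribute name). Order of
#'   entries fixes the tie-break priority for same-day events.
#'
#' @seealso [cohortSchema()]
#' @export
setClass("CohortSchema",
  representation(eventLabels = "character", terminalLabel = "character",
                 attributes = "list", relevance = "list",
                 baselineVars = "list", tableMap = "list"))

#' Cohort: baseline table plus a harmonized chronological event stream
#'
#' @slot baseline data.frame keyed by `patient_id`, one row per individual,
#'   with one column per baseline variable in the schema.
#' @slot events data.frame with columns `patient_id`, `position`, `label`,
#'   `date` (days since study start) and one column per schema attribute
#'   (including `sojourn`, days since the individual's previous event);
#'   attributes outside the relevance set of a row's label are `NA`.
#' @slot schema the [CohortSchema-class] the cohort conforms to.
#' @export
setClass("Cohort",
  representation(baseline = "data.frame", events = "data.frame",
                 schema = "CohortSchema"))

#' PatientSequences: per-individual integer-coded sequences
#'
#' The encoding precursor produced by [encodeCohort()]: ragged per-individual
#' integer sequences, before fixed-window chunking. Code 0 is reserved for
#' padding/missing throughout.
#'
#' @slot labels list of integer vectors (one per individual), codes in 1..C.
#' @slot attrs list of integer matrices (length x A), code 0 where an
#'   attribute is irrelevant for the row's label.
#' @slot baseline integer matrix (n x B) of baseline codes (1-based).
#' @slot patientIds integer vector of the regenerated patient ids.
#' @slot codebook the invertible coding tables (see [encodeCohort()]).
#' @slot schema the schema used for the encoding.
#' @export
setClass("PatientSequences",
  representation(labels = "list", attrs = "list", baseline = "matrix",
                 patientIds = "integer", codebook = "list",
                 schema = "CohortSchema"))

#' EncodedSequences: fixed-window, zero-padded training tensors
#'
#' @slot labels integer matrix `[nChunks, window]`, 0 beyond the true length.
#' @slot attrs integer array `[nChunks, window, A]`, 0 where padded or
#'   irrelevant.
#' @slot baseline integer matrix `[nChunks, B]` (baseline codes repeated for
#'   every chunk of the same individual).
#' @slot lengths integer vector of true (pre-padding) chunk lengths.
#' @slot chunkOwner data.frame with `chunk`, `patient_id`, `ordinal` mapping
#'   chunks back to individuals so sequences can be re-assembled.
#' @slot codebook,schema carried over from [PatientSequences-class].
#' @slot window the configured window size.
#' @export
setClass("EncodedSequences",
  representation(labels = "matrix", attrs = "array", baseline = "matrix",
                 lengths = "integer", chunkOwner = "data.frame",
                 codebook = "list", schema = "CohortSchema",
                 window = "integer"))

#' SimulationSpec: ground-truth cohort simulator specification
#'
#' Declares a cohort-generating process with known statistical structure:
#' baseline marginals, a stratum rule mapping baseline values to a stratum
#' index, per-stratum first-order Markov kernels over event labels (with the
#' terminal label absorbing), per-label attribute conditionals and sojourn
#' distributions. Used as the oracle for utility-metric recovery tests.
#'
#' @slot nIndividuals number of individuals to simulate.
#' @slot schema the [CohortSchema-class] of the simulated cohort.
#' @slot baselineModel list of per-variable samplers (declarative; see
#'   [defaultSimulationSpec()]).
#' @slot strataRule list(`var`, `breaks`): stratum = 1 + number of breaks
#'   strictly below the value of `var`.
#' @slot initProbs list (per stratum) of initial label distributions over
#'   non-terminal labels.
#' @slot kernels list (per stratum) of row-stochastic transition matrices over
#'   all labels; the terminal row is absorbing.
#' @slot attrModels list of per-attribute conditional samplers.
#' @slot sojournModels list of per-label sojourn-time samplers (non-negative
#'   integer days).
#' @slot maxLength maximum sequence length per individual.
#' @slot seed default simulation seed.
#' @export
setClass("SimulationSpec",
  representation(nIndividuals = "integer", schema = "CohortSchema",
                 baselineModel = "list", strataRule = "list",
                 initProbs = "list", kernels = "list", attrModels = "list",
                 sojournModels = "list", maxLength = "integer",
                 seed = "integer"))

#' SequentialTreeModel: sequential tree-based synthesizer
#'
#' One variable is synthesized at a time in a fixed order; variable j is
#' predicted from variables 1..j-1 with a classification/regression tree and
#' sampled from the empirical donor pool of the leaf a partial synthetic row
#' is routed to. The first variable stores its empirical marginal.
#'
#' @slot order character vector: the synthesis order (permutation of columns).
#' @slot models list, one element per variable: either a marginal donor pool
#'   or a fitted tree plus leaf-wise donor pools.
#' @slot columns list of per-column metadata (type, factor levels).
#' @slot minLeaf minimum leaf size used at fit time.
#' @export
setClass("SequentialTreeModel",
  representation(order = "character", models = "list", columns = "list",
                 minLeaf = "integer"))

#' GeneratorModel: the conditional recurrent generative model
#'
#' Embedding maps for labels, attributes and baseline variables; a (possibly
#' multi-layer) LSTM core; and one linear output head per prediction target
#' (the label head of width C+1 including the padding class, and one head of
#' width C_i+1 per attribute), each consuming the concatenation of the
#' recurrent output and the embedded baseline characteristics.
#'
#' @slot params named list of parameter matrices (embeddings, LSTM gate
#'   weights per layer, head weights).
#' @slot config the [modelConfig()] list used for training.
#' @slot codebook,schema the coding tables and schema the model was trained
#'   against.
#' @slot lossTrace data.frame of per-epoch label/attribute/total losses.
#' @export
setClass("GeneratorModel",
  representation(params = "list", config = "list", codebook = "list",
                 schema = "CohortSchema", lossTrace = "data.frame"))

#' TransitionMatrix: empirical k-th order transition probabilities
#'
#' @slot order the order k (number of previous events conditioned on).
#' @slot contexts character vector of length-k label contexts (labels joined
#'   by `"|"`); contexts never contain the terminal label in a non-final
#'   position because nothing follows a terminal event.
#' @slot labels the next-event label vocabulary (matrix columns).
#' @slot probs row-stochastic matrix `[contexts, labels]`.
#' @slot counts raw transition counts of the same shape.
#' @export
setClass("TransitionMatrix",
  representation(order = "integer", contexts = "character",
                 labels = "character", probs = "matrix", counts = "matrix"))

#' UtilityReport: structured output of the generic utility assessment
#'
#' @slot metrics named list: percent difference in mean sequence length,
#'   event-distribution Hellinger, per-attribute Hellinger values and
#'   summaries, per-order transition-matrix comparisons, multivariate
#'   Hellinger, and random-cohort distance summaries (see [evaluateUtility()]).
#' @export
setClass("UtilityReport", representation(metrics = "list"))

#' PrivacyReport: structured output of the attribution-disclosure assessment
#'
#' @slot metrics named list with `population_to_sample` and
#'   `sample_to_population` risks, the threshold, the pass/fail decision,
#'   equivalence-class size distributions and per-direction match counts.
#' @export
setClass("PrivacyReport", representation(metrics = "list"))
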
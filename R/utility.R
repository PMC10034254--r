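#' Hellinger distance between two discrete distributions
#'
#' `H = sqrt(1 - sum_i sqrt(p_i q_i))`, bounded in `[0, 1]` with 0 meaning
#' identical distributions and 1 disjoint support. Inputs may be named
#' probability vectors (supports are unioned and aligned, absent categories
#' getting probability 0) or unnamed vectors of equal length.
#'
#' @param p,q non-negative weight vectors summing to 1 (within `tol`).
#' @param tol normalization tolerance (default 1e-6).
#' @return the distance.
#' @examples
#' hellinger(c(a = 0.5, b = 0.5), c(a = 0.9, b = 0.1))  # ~0.3249
#' @export
hellinger <- function(p, q, tol = 1e-6) {
  if (!is.null(names(p)) || !is.null(names(q))) {
    sup <- union(names(p), names(q))
    p <- stats::setNames(ifelse(sup %in% names(p), p[sup], 0), sup)
    q <- stats::setNames(ifelse(sup %in% names(q), q[sup], 0), sup)
    p[is.na(p)] <- 0; q[is.na(q)] <- 0
  } else assertThat(length(p) == length(q), "unnamed inputs must align")
  assertThat(all(p >= 0) && all(q >= 0), "negative probabilities")
  assertThat(abs(sum(p) - 1) < tol && abs(sum(q) - 1) < tol,
             "inputs not normalized within tolerance")
  ## the (1/sqrt 2) L2 form of sqrt(1 - sum(sqrt(p q))): algebraically
  ## identical, but exactly 0 for p == q and never pushed negative by
  ## floating-point cancellation
  min(1, sqrt(sum((sqrt(p) - sqrt(q))^2) / 2))
}

## tabulate a character vector into a named probability vector
probTable <- function(x, levels = NULL) {
  tab <- if (is.null(levels)) table(x) else table(factor(x, levels = levels))
  p <- as.numeric(tab) / sum(tab)
  stats::setNames(p, names(tab))
}

#' Compare per-individual sequence lengths between cohorts
#'
#' Reports `100 * |mean_syn - mean_real| / mean_real` plus shared-bin
#' histogram series for plotting the two length distributions.
#'
#' @param real,syn \linkS4class{Cohort} objects.
#' @param nBins number of histogram bins (default 30).
#' @return list with `meanReal`, `meanSyn`, `sdReal`, `sdSyn`,
#'   `percentDifference` and a `histogram` data.frame.
#' @export
sequenceLengthReport <- function(real, syn, nBins = 30L) {
  lr <- sequenceLengths(real); ls <- sequenceLengths(syn)
  assertThat(length(lr) > 0 && length(ls) > 0, "empty cohort")
  breaks <- seq(0, max(lr, ls), length.out = nBins + 1)
  h <- function(x) as.numeric(table(cut(x, breaks, include.lowest = TRUE)))
  list(meanReal = mean(lr), meanSyn = mean(ls),
       sdReal = sd(lr), sdSyn = sd(ls),
       percentDifference = 100 * abs(mean(ls) - mean(lr)) / mean(lr),
       histogram = data.frame(mid = (breaks[-1] + breaks[-nBins - 1]) / 2,
                              real = h(lr), syn = h(ls)))
}

#' Hellinger distance of the pooled event-label distributions
#'
#' The proportion of events belonging to each event type, compared across
#' cohorts.
#'
#' @param real,syn \linkS4class{Cohort} objects sharing a schema vocabulary.
#' @return the distance.
#' @export
eventDistributionHellinger <- function(real, syn) {
  levs <- eventLabels(real@schema)
  hellinger(probTable(real@events$label, levs),
            probTable(syn@events$label, levs))
}

#' Per-attribute Hellinger distances
#'
#' For each event attribute, compares its empirical distributions using only
#' events whose label makes the attribute relevant, so padded/missing values
#' never enter the comparison. Continuous attributes are compared on a
#' common quantile binning learned from the real cohort.
#'
#' @param real,syn \linkS4class{Cohort} objects.
#' @param schema schema (defaults to the real cohort's).
#' @return list with per-attribute `distances` (NA when an attribute is
#'   observed in neither cohort; 1 when observed in only one) and a
#'   `summary` (mean/SD/median/IQR over the defined values).
#' @export
attributeHellinger <- function(real, syn, schema = schemaOf(real)) {
  rel <- relevanceMap(schema)
  d <- stats::setNames(rep(NA_real_, length(attributeNames(schema))),
                       attributeNames(schema))
  for (a in attributeNames(schema)) {
    okLabs <- names(rel)[vapply(rel, function(r) a %in% r, TRUE)]
    xr <- real@events[[a]][real@events$label %in% okLabs]
    xs <- syn@events[[a]][syn@events$label %in% okLabs]
    xr <- xr[!is.na(xr)]; xs <- xs[!is.na(xs)]
    if (!length(xr) && !length(xs)) next            # undefined, excluded
    if (!length(xr) || !length(xs)) { d[a] <- 1; next }
    def <- schema@attributes[[a]]
    if (def$type == "continuous") {
      b <- makeBins(as.numeric(xr), def$bins)
      xr <- as.character(binCode(as.numeric(xr), b$breaks))
      xs <- as.character(binCode(as.numeric(xs), b$breaks))
    }
    d[a] <- hellinger(probTable(as.character(xr)),
                      probTable(as.character(xs)))
  }
  list(distances = d, summary = summariseDistances(d))
}

#' Empirical k-th order transition matrix of a cohort
#'
#' Counts every within-individual window of k+1 consecutive event labels
#' (windows never span individuals) and normalizes each k-label context row
#' into a next-label distribution. Contexts with zero observations are
#' omitted, so contexts containing the terminal label in a non-final
#' position never appear.
#'
#' @param cohort a \linkS4class{Cohort}.
#' @param k the order (number of previous events conditioned on).
#' @return a \linkS4class{TransitionMatrix}.
#' @export
estimateTransitionMatrix <- function(cohort, k = 1L) {
  k <- as.integer(k)
  assertThat(k >= 1, "order k must be >= 1")
  labs <- eventLabels(cohort@schema)
  e <- cohort@events
  seqs <- split(e$label, factor(e$patient_id, levels = unique(e$patient_id)))
  ctx <- character(); nxt <- character()
  for (s in seqs) {
    L <- length(s)
    if (L <= k) next
    idx <- seq_len(L - k)
    win <- vapply(idx, function(i) paste(s[i:(i + k - 1L)], collapse = "|"),
                  "")
    ctx <- c(ctx, win)
    nxt <- c(nxt, s[idx + k])
  }
  assertThat(length(ctx) > 0, "no countable windows of order ", k)
  counts <- table(ctx, factor(nxt, levels = labs))
  counts <- unclass(counts)
  probs <- counts / rowSums(counts)
  new("TransitionMatrix", order = k, contexts = rownames(counts),
      labels = labs, probs = probs, counts = counts)
}

#' Build a TransitionMatrix from explicit probabilities
#'
#' For comparing externally specified matrices (e.g. a published example or
#' a simulator kernel) with estimated ones.
#'
#' @param probs row-stochastic matrix; rownames are `"|"`-joined contexts,
#'   colnames the next-event labels.
#' @param order the order k (default: contexts' length).
#' @param normalize renormalize rows that are off by printing/rounding slop
#'   (at most 0.02); default `FALSE`, requiring exact rows.
#' @return a \linkS4class{TransitionMatrix}.
#' @export
transitionMatrix <- function(probs, order = NULL, normalize = FALSE) {
  assertThat(!is.null(rownames(probs)) && !is.null(colnames(probs)),
             "probs needs context rownames and label colnames")
  if (is.null(order))
    order <- length(strsplit(rownames(probs)[1], "|", fixed = TRUE)[[1]])
  tol <- if (normalize) 0.02 else 1e-6
  assertThat(all(abs(rowSums(probs) - 1) < tol), "rows must sum to 1")
  if (normalize) probs <- probs / rowSums(probs)
  new("TransitionMatrix", order = as.integer(order),
      contexts = rownames(probs), labels = colnames(probs),
      probs = as.matrix(probs), counts = as.matrix(probs) * NA)
}

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix (order ", object@order, "): ",
      length(object@contexts), " contexts x ", length(object@labels),
      " labels\n", sep = "")
  print(round(object@probs, 3))
})

#' Row-wise Hellinger comparison of two transition matrices
#'
#' Matches rows by context over the union of contexts and computes the
#' Hellinger distance between corresponding next-label distributions. A
#' context present in only one matrix is scored as maximal dissimilarity
#' (distance 1) by default — missing transition structure is a real
#' difference — or skipped with `unmatched = "skip"`.
#'
#' @param tReal,tSyn \linkS4class{TransitionMatrix} objects of equal order.
#' @param unmatched `"one"` (default) or `"skip"`.
#' @return list with per-context `distances` and a `summary`
#'   (mean/SD/median/IQR).
#' @export
compareTransitionMatrices <- function(tReal, tSyn,
                                      unmatched = c("one", "skip")) {
  unmatched <- match.arg(unmatched)
  assertThat(tReal@order == tSyn@order, "order mismatch: ", tReal@order,
             " vs ", tSyn@order)
  ctx <- union(tReal@contexts, tSyn@contexts)
  d <- stats::setNames(rep(NA_real_, length(ctx)), ctx)
  for (cx in ctx) {
    inR <- cx %in% tReal@contexts
    inS <- cx %in% tSyn@contexts
    if (inR && inS) {
      pr <- stats::setNames(tReal@probs[cx, ], tReal@labels)
      ps <- stats::setNames(tSyn@probs[cx, ], tSyn@labels)
      d[cx] <- hellinger(pr, ps)
    } else if (unmatched == "one") d[cx] <- 1
  }
  d <- d[!is.na(d)]          # with unmatched="skip", unmatched rows drop out
  list(distances = d, summary = summariseDistances(d))
}

#' Multivariate Hellinger distance between two numeric tables
#'
#' Fits a mean vector and covariance matrix to each table and evaluates the
#' Gaussian Bhattacharyya distance
#' `BD = (1/8) (m1-m2)' S^-1 (m1-m2) + (1/2) log(det S / sqrt(det S1 det S2))`
#' with `S = (S1+S2)/2`, returning `sqrt(1 - exp(-BD))`, a `[0,1]`-bounded
#' summary of overall multivariate similarity. Covariances are regularized
#' by adding `reg * trace/d` to the diagonal. Categorical columns should be
#' numeric-encoded first (see [encodeForMultivariate()]).
#'
#' @param real,syn numeric matrices or data.frames with identical columns.
#' @param reg diagonal regularization factor (default 1e-6).
#' @return the distance in `[0, 1]`.
#' @export
multivariateHellinger <- function(real, syn, reg = 1e-6) {
  X <- as.matrix(real); Y <- as.matrix(syn)
  assertThat(identical(colnames(X), colnames(Y)) && ncol(X) == ncol(Y),
             "tables must have identical columns")
  d <- ncol(X)
  regularize <- function(S) S + diag(reg * sum(diag(S)) / d, d)
  S1 <- regularize(stats::cov(X)); S2 <- regularize(stats::cov(Y))
  Sbar <- (S1 + S2) / 2
  ld <- function(S) {
    dt <- determinant(S, logarithm = TRUE)
    if (dt$sign <= 0) NA_real_ else as.numeric(dt$modulus)
  }
  l1 <- ld(S1); l2 <- ld(S2); lb <- ld(Sbar)
  if (anyNA(c(l1, l2, lb))) {
    v <- pmin(diag(S1), diag(S2))
    bad <- colnames(X)[v <= reg * max(v, 1)]
    stop("singular covariance after regularization; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dm <- colMeans(X) - colMeans(Y)
  bd <- 0.125 * as.numeric(crossprod(dm, solve(Sbar, dm))) +
    0.5 * (lb - 0.5 * (l1 + l2))
  sqrt(max(0, 1 - exp(-bd)))
}

#' Numeric-encode a cohort's patient-level table for multivariate comparison
#'
#' Categorical columns map to their integer codes and continuous columns to
#' their quantile-bin midpoints (bins learned from `reference`, default the
#' table itself), giving the common numeric encoding both tables must share
#' before [multivariateHellinger()].
#'
#' @param df patient-level data.frame (e.g. from [patientSummaryTable()]).
#' @param reference data.frame supplying factor levels and bin breaks.
#' @param bins quantile bins for continuous columns (default 20).
#' @return numeric matrix.
#' @export
encodeForMultivariate <- function(df, reference = df, bins = 20L) {
  out <- matrix(0, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  for (j in names(df)) {
    if (is.numeric(reference[[j]])) {
      b <- makeBins(as.numeric(reference[[j]]), bins)
      mids <- (b$breaks[-length(b$breaks)] + b$breaks[-1]) / 2
      out[, j] <- mids[binCode(as.numeric(df[[j]]), b$breaks)]
    } else {
      levs <- sort(unique(as.character(reference[[j]])))
      out[, j] <- match(as.character(df[[j]]), levs)
    }
    if (anyNA(out[, j]))    # individuals with no relevant event for a column
      out[is.na(out[, j]), j] <- median(out[, j], na.rm = TRUE)
  }
  out
}

#' Standardized mean difference for a continuous variable
#'
#' `|mean2 - mean1| / sqrt((sd1^2 + sd2^2) / 2)` — the scale-free,
#' sign-free imbalance measure; values above 0.1 are conventionally flagged
#' as potentially clinically important.
#'
#' @param mean1,sd1,mean2,sd2 group means and standard deviations.
#' @return the SMD (Inf, with a warning, when both SDs are 0 but means
#'   differ; 0 when the groups are identical and degenerate).
#' @export
smdContinuous <- function(mean1, sd1, mean2, sd2) {
  assertThat(sd1 >= 0 && sd2 >= 0, "standard deviations must be non-negative")
  denom <- sqrt((sd1^2 + sd2^2) / 2)
  if (denom == 0) {
    if (mean1 == mean2) return(0)
    warning("both SDs zero with unequal means: infinite SMD")
    return(Inf)
  }
  abs(mean2 - mean1) / denom
}

#' Standardized mean difference for a binary variable
#'
#' With `p = x/n` per group, `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2))/2)`.
#'
#' @param x1,n1 events and size in group 1.
#' @param x2,n2 events and size in group 2.
#' @return the SMD (see [smdContinuous()] for the degenerate conventions).
#' @export
smdBinary <- function(x1, n1, x2, n2) {
  assertThat(n1 > 0 && n2 > 0 && x1 >= 0 && x2 >= 0 && x1 <= n1 && x2 <= n2,
             "need 0 <= x <= n, n > 0")
  p1 <- x1 / n1; p2 <- x2 / n2
  smdContinuous(p1, sqrt(p1 * (1 - p1)), p2, sqrt(p2 * (1 - p2)))
}

#' Confidence-interval overlap
#'
#' With `L` the length of the intersection, returns
#' `100 * (L/width1 + L/width2) / 2`: the average percentage of each
#' interval covered by the overlap. Symmetric in the two intervals. A
#' zero-width interval contributes 1 to its ratio term if its point lies
#' inside the other interval, else 0 (flagged with a warning).
#'
#' @param lo1,hi1 first interval.
#' @param lo2,hi2 second interval.
#' @return overlap percentage in `[0, 100]`.
#' @export
ciOverlap <- function(lo1, hi1, lo2, hi2) {
  assertThat(lo1 <= hi1 && lo2 <= hi2, "need lo <= hi in each interval")
  L <- max(0, min(hi1, hi2) - max(lo1, lo2))
  ratio <- function(lo, hi, olo, ohi) {
    if (hi > lo) return(L / (hi - lo))
    warning("zero-width interval in ciOverlap")
    as.numeric(lo >= olo && lo <= ohi)
  }
  100 * (ratio(lo1, hi1, lo2, hi2) + ratio(lo2, hi2, lo1, hi1)) / 2
}

#' Run the full generic utility assessment
#'
#' Bundles the sequence-length comparison, the event-distribution and
#' per-attribute Hellinger distances, first- and second-order
#' transition-matrix comparisons, the multivariate Hellinger distance on the
#' encoded patient-level tables, and the random-cohort query assessment into
#' one \linkS4class{UtilityReport}.
#'
#' @param real,syn \linkS4class{Cohort} objects sharing a schema.
#' @param orders transition-matrix orders to compare (default `c(1, 2)`).
#' @param nQueries random queries (default 100; 0 disables).
#' @param seed RNG seed for the query generator.
#' @return a \linkS4class{UtilityReport}.
#' @export
evaluateUtility <- function(real, syn, orders = c(1L, 2L), nQueries = 100L,
                            seed = 1L) {
  tm <- lapply(orders, function(k) {
    cmp <- compareTransitionMatrices(estimateTransitionMatrix(real, k),
                                     estimateTransitionMatrix(syn, k))
    c(list(order = k), cmp)
  })
  names(tm) <- paste0("order", orders)
  realTab <- patientSummaryTable(real)
  synTab <- patientSummaryTable(syn)
  common <- setdiff(intersect(names(realTab), names(synTab)), "patient_id")
  mv <- multivariateHellinger(
    encodeForMultivariate(realTab[common], realTab[common]),
    encodeForMultivariate(synTab[common], realTab[common]))
  rq <- if (nQueries > 0) randomCohortAssessment(real, syn, nQueries, seed)
        else NULL
  new("UtilityReport", metrics = list(
    sequenceLength = sequenceLengthReport(real, syn),
    eventDistribution = eventDistributionHellinger(real, syn),
    attributes = attributeHellinger(real, syn),
    transitions = tm,
    multivariateHellinger = mv,
    randomCohorts = rq))
}

setMethod("show", "UtilityReport", function(object) {
  m <- object@metrics
  cat("UtilityReport\n")
  cat(sprintf("  %% difference in mean sequence length: %.2f%%\n",
              m$sequenceLength$percentDifference))
  cat(sprintf("  event-distribution Hellinger:          %.4f\n",
              m$eventDistribution))
  cat(sprintf("  attribute Hellinger mean (SD):         %.4f (%.4f)\n",
              m$attributes$summary$mean, m$attributes$summary$sd))
  for (tmx in m$transitions)
    cat(sprintf("  order-%d transition Hellinger mean (SD): %.4f (%.4f)\n",
                tmx$order, tmx$summary$mean, tmx$summary$sd))
  cat(sprintf("  multivariate Hellinger:                %.4f\n",
              m$multivariateHellinger))
  if (!is.null(m$randomCohorts))
    cat(sprintf("  random cohorts: Hellinger %.4f, norm. Euclidean %.4f\n",
                m$randomCohorts$hellinger$mean %||% NA,
                m$randomCohorts$euclidean$mean %||% NA))
})
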
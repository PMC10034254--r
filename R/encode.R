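## Quantile binning of an originally-continuous variable. Breaks are the
## empirical quantiles of the observed values; representatives are the
## per-bin medians, used when decoding a bin back to a value.
makeBins <- function(x, bins) {
  x <- x[!is.na(x)]
  assertThat(length(x) > 0, "no observed values to bin")
  br <- unique(as.numeric(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                   type = 7)))
  if (length(br) < 2) br <- c(br, br + 1)
  code <- binCode(x, br)
  reps <- as.numeric(tapply(x, factor(code, levels = seq_len(length(br) - 1)),
                            median))
  empty <- is.na(reps)
  reps[empty] <- ((br[-length(br)] + br[-1]) / 2)[empty]
  list(breaks = br, reps = reps, n = length(br) - 1L)
}

binCode <- function(x, breaks) {
  code <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  code[is.na(x)] <- NA_integer_
  code
}

## Build the codebook for one variable definition from observed values.
codebookEntry <- function(def, observed) {
  if (def$type == "categorical") {
    oov <- setdiff(unique(as.character(observed[!is.na(observed)])), def$levels)
    if (length(oov))
      stop("encoding error: value(s) outside the vocabulary of '", def$name,
           "': ", paste(head(oov, 10), collapse = ", "), call. = FALSE)
    list(type = "categorical", levels = def$levels, n = length(def$levels))
  } else {
    b <- makeBins(as.numeric(observed), def$bins)
    c(list(type = "continuous"), b)
  }
}

encodeValues <- function(entry, x) {
  if (entry$type == "categorical") {
    code <- match(as.character(x), entry$levels)
    code[is.na(x)] <- NA_integer_
    code
  } else binCode(as.numeric(x), entry$breaks)
}

decodeValues <- function(entry, code) {
  idx <- ifelse(is.na(code) | code == 0L, NA_integer_, code)  # 0 = missing
  if (entry$type == "categorical") entry$levels[idx] else entry$reps[idx]
}

#' Integer-encode a cohort against its schema
#'
#' Maps every event label, event attribute and baseline value to its
#' vocabulary index. Continuous variables are quantile-binned (the breaks are
#' learned here and stored in the codebook, making the mapping invertible to
#' bin representatives); categorical values are matched against their
#' declared levels, and an out-of-vocabulary value is an error. Attribute
#' values are masked to code 0 wherever the attribute is not relevant for the
#' row's label, and code 0 likewise encodes missing/padding everywhere.
#'
#' @param cohort a \linkS4class{Cohort} with sojourn times computed.
#' @param codebook optionally, a codebook from a previous call (e.g. encode a
#'   synthetic cohort with the bins learned on the real one).
#' @return a \linkS4class{PatientSequences} with per-individual integer
#'   sequences and the stored codebook.
#' @seealso [decodeCohort()] for the inverse, [chunkSequences()] for the
#'   training tensors.
#' @export
encodeCohort <- function(cohort, codebook = NULL) {
  sc <- cohort@schema
  e <- cohort@events
  b <- cohort@baseline
  assertThat(!anyNA(e$sojourn) || !nrow(e),
             "sojourn not computed; call computeSojourn() first")
  if (is.null(codebook)) {
    codebook <- list(labels = labelVocabulary(sc),
                     attrs = lapply(sc@attributes, function(d)
                       codebookEntry(d, e[[d$name]])),
                     baseline = lapply(sc@baselineVars, function(d)
                       codebookEntry(d, b[[d$name]])))
  }
  A <- attributeNames(sc)
  rel <- relevanceMatrix(sc)
  labCode <- match(e$label, sc@eventLabels)      # 1..C (pad 0 never observed)
  attrCodes <- matrix(0L, nrow = nrow(e), ncol = length(A),
                      dimnames = list(NULL, A))
  for (a in A) {
    code <- encodeValues(codebook$attrs[[a]], e[[a]])
    relevant <- rel[labCode + 1L, a]
    miss <- relevant & is.na(code)
    if (any(miss))
      stop("encoding error: missing value for relevant attribute '", a,
           "' in ", sum(miss), " event row(s)", call. = FALSE)
    code[!relevant] <- 0L                        # masked regardless of content
    attrCodes[, a] <- code
  }
  B <- baselineNames(sc)
  baseCodes <- matrix(0L, nrow = nrow(b), ncol = length(B),
                      dimnames = list(NULL, B))
  for (v in B) {
    code <- encodeValues(codebook$baseline[[v]], b[[v]])
    if (anyNA(code))
      stop("encoding error: missing/out-of-range baseline value in '", v, "'",
           call. = FALSE)
    baseCodes[, v] <- code
  }
  pid <- factor(e$patient_id, levels = b$patient_id)
  idx <- split(seq_len(nrow(e)), pid)
  new("PatientSequences",
      labels = lapply(idx, function(i) labCode[i]),
      attrs = lapply(idx, function(i) attrCodes[i, , drop = FALSE]),
      baseline = baseCodes, patientIds = as.integer(b$patient_id),
      codebook = codebook, schema = sc)
}

#' Split encoded sequences into fixed-size zero-padded chunks
#'
#' Each individual's sequence is cut into consecutive windows of at most
#' `window` events and padded with the reserved code 0 to exactly `window`,
#' producing the dense training tensors. `chunkOwner` records which
#' individual and which chunk ordinal each row came from, so
#' [reassembleSequences()] can invert the operation exactly.
#'
#' @param pseq a \linkS4class{PatientSequences}.
#' @param window chunk length (default 120).
#' @return an \linkS4class{EncodedSequences}.
#' @export
chunkSequences <- function(pseq, window = 120L) {
  window <- as.integer(window)
  assertThat(window >= 2, "window must be >= 2")
  A <- length(attributeNames(pseq@schema))
  n <- length(pseq@labels)
  owner <- list(); labRows <- list(); attrRows <- list(); lens <- integer()
  chunk <- 0L
  for (i in seq_len(n)) {
    lab <- pseq@labels[[i]]
    att <- pseq@attrs[[i]]
    L <- length(lab)
    if (L == 0) next
    starts <- seq(1L, L, by = window)
    for (k in seq_along(starts)) {
      s <- starts[k]; eidx <- min(s + window - 1L, L)
      len <- eidx - s + 1L
      chunk <- chunk + 1L
      labPad <- integer(window)
      labPad[seq_len(len)] <- lab[s:eidx]
      attPad <- matrix(0L, nrow = window, ncol = A)
      attPad[seq_len(len), ] <- att[s:eidx, , drop = FALSE]
      labRows[[chunk]] <- labPad
      attrRows[[chunk]] <- attPad
      lens[chunk] <- len
      owner[[chunk]] <- c(i, k)
    }
  }
  ownerM <- do.call(rbind, owner)
  labels <- do.call(rbind, labRows)
  attrs <- array(0L, dim = c(chunk, window, A),
                 dimnames = list(NULL, NULL, attributeNames(pseq@schema)))
  for (j in seq_len(chunk)) attrs[j, , ] <- attrRows[[j]]
  new("EncodedSequences",
      labels = labels, attrs = attrs,
      baseline = pseq@baseline[ownerM[, 1], , drop = FALSE],
      lengths = lens,
      chunkOwner = data.frame(chunk = seq_len(chunk),
                              patient_id = pseq@patientIds[ownerM[, 1]],
                              ordinal = ownerM[, 2]),
      codebook = pseq@codebook, schema = pseq@schema, window = window)
}

#' Re-assemble chunked sequences into per-individual sequences
#'
#' Inverse of [chunkSequences()]: concatenates each individual's chunks in
#' ordinal order and strips the padding.
#'
#' @param enc an \linkS4class{EncodedSequences}.
#' @return a \linkS4class{PatientSequences}.
#' @export
reassembleSequences <- function(enc) {
  ids <- unique(enc@chunkOwner$patient_id)
  labs <- list(); atts <- list(); base <- list()
  for (j in seq_along(ids)) {
    rows <- which(enc@chunkOwner$patient_id == ids[j])
    rows <- rows[order(enc@chunkOwner$ordinal[rows])]
    lab <- integer(); att <- NULL
    for (r in rows) {
      len <- enc@lengths[r]
      lab <- c(lab, enc@labels[r, seq_len(len)])
      att <- rbind(att, matrix(enc@attrs[r, seq_len(len), ],
                               nrow = len, dimnames = list(NULL, dimnames(enc@attrs)[[3]])))
    }
    labs[[j]] <- lab; atts[[j]] <- att
    base[[j]] <- enc@baseline[rows[1], ]
  }
  new("PatientSequences", labels = labs, attrs = atts,
      baseline = do.call(rbind, base), patientIds = as.integer(ids),
      codebook = enc@codebook, schema = enc@schema)
}

#' Decode integer sequences back to a Cohort
#'
#' Inverts the codebook: label codes become labels, categorical attribute
#' codes their category, continuous codes their bin representative (the
#' training-data median of the bin), and code 0 becomes `NA`. Event dates are
#' reconstructed by cumulating the decoded sojourn times from day 0, so
#' absolute dates are recovered up to each individual's study-start offset.
#'
#' @param pseq a \linkS4class{PatientSequences}.
#' @return a \linkS4class{Cohort}.
#' @export
decodeCohort <- function(pseq) {
  sc <- pseq@schema
  cb <- pseq@codebook
  A <- attributeNames(sc)
  B <- baselineNames(sc)
  n <- length(pseq@labels)
  evs <- list()
  for (i in seq_len(n)) {
    lab <- pseq@labels[[i]]
    if (!length(lab)) next
    d <- data.frame(patient_id = pseq@patientIds[i],
                    position = seq_along(lab),
                    label = cb$labels[lab + 1L])
    att <- pseq@attrs[[i]]
    for (a in A) d[[a]] <- decodeValues(cb$attrs[[a]], att[, a])
    d$date <- cumsum(ifelse(is.na(d$sojourn), 0, d$sojourn))
    evs[[length(evs) + 1L]] <- d
  }
  ev <- if (length(evs)) do.call(rbind, evs) else {
    d <- data.frame(patient_id = integer(), position = integer(),
                    label = character(), date = numeric())
    for (a in A) d[[a]] <- numeric()
    d
  }
  rownames(ev) <- NULL
  base <- data.frame(patient_id = pseq@patientIds)
  for (v in B) base[[v]] <- decodeValues(cb$baseline[[v]], pseq@baseline[, v])
  newCohort(base, ev[, c("patient_id", "position", "label", "date", A)], sc)
}

setMethod("show", "EncodedSequences", function(object) {
  cat("EncodedSequences: ", nrow(object@labels), " chunks x window ",
      object@window, " (", length(unique(object@chunkOwner$patient_id)),
      " individuals, ", dim(object@attrs)[3], " attributes)\n", sep = "")
})
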
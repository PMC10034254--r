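#' Training configuration for the recurrent generator
#'
#' All sizes are vocabulary-independent knobs; the vocabularies themselves
#' come from the codebook at fit time.
#'
#' @param hiddenSize LSTM hidden width (default 32).
#' @param nLayers number of stacked LSTM layers (default 1).
#' @param embLabel,embAttr,embBaseline embedding widths for the event label,
#'   each event attribute, and each baseline variable.
#' @param lambda non-negative tradeoff weight between the label loss and the
#'   attribute loss in the training objective (default 1).
#' @param batchSize,epochs,learningRate,optimizer optimisation settings;
#'   only `"adam"` is implemented.
#' @param window chunk length for training tensors (default 120).
#' @param includePadding if `TRUE`, padded positions are kept as prediction
#'   targets (the strict printed-formula mode); by default they are excluded
#'   from the averaged set so the model is never rewarded for predicting
#'   padding.
#' @param attrLossAggregate `"mean"` (default) averages the attribute loss
#'   over the contributing (individual, time, attribute) triples; `"sum"`
#'   leaves it as the raw masked sum.
#' @param gradClip global gradient-norm clip (default 5).
#' @param seed RNG seed for initialisation and batch shuffling.
#' @return a named list of class `modelConfig`.
#' @export
modelConfig <- function(hiddenSize = 32L, nLayers = 1L, embLabel = 8L,
                        embAttr = 6L, embBaseline = 4L, lambda = 1,
                        batchSize = 64L, epochs = 20L, learningRate = 0.01,
                        optimizer = "adam", window = 120L,
                        includePadding = FALSE,
                        attrLossAggregate = c("mean", "sum"),
                        gradClip = 5, seed = 1L) {
  assertThat(lambda >= 0, "lambda must be non-negative")
  assertThat(all(c(hiddenSize, nLayers, embLabel, embAttr, embBaseline,
                   batchSize, epochs) >= 1), "all sizes must be positive")
  assertThat(identical(optimizer, "adam"), "only the adam optimizer is implemented")
  structure(list(hiddenSize = as.integer(hiddenSize),
                 nLayers = as.integer(nLayers),
                 embLabel = as.integer(embLabel),
                 embAttr = as.integer(embAttr),
                 embBaseline = as.integer(embBaseline), lambda = lambda,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), learningRate = learningRate,
                 optimizer = optimizer, window = as.integer(window),
                 includePadding = isTRUE(includePadding),
                 attrLossAggregate = match.arg(attrLossAggregate),
                 gradClip = gradClip, seed = as.integer(seed)),
            class = "modelConfig")
}

#' One forward pass of the generator
#'
#' Feeding observations for times 1..t-1 yields predictions for times 2..t:
#' the returned logits at input position k are the model's distribution over
#' the event at position k+1. The returned state can be passed back in to
#' continue a sequence, and a fresh (all-zero) state is used when `state` is
#' `NULL`.
#'
#' @param model a \linkS4class{GeneratorModel}.
#' @param labels integer matrix `[n, t-1]` of label codes (0 = padding).
#' @param attrs integer array `[n, t-1, A]` of attribute codes.
#' @param baseline integer matrix `[n, B]` of baseline codes (1-based).
#' @param state a state returned by a previous call, or `NULL`.
#' @return list with `labelLogits` `[n, t-1, C+1]`, `attrLogits` (list of
#'   `[n, t-1, C_i+1]`) and `state`.
#' @export
forwardGenerator <- function(model, labels, attrs, baseline, state = NULL) {
  checkCodes(model, labels, attrs, baseline)
  out <- gmForward(model@params, labels, attrs, baseline, state = state)
  out[c("labelLogits", "attrLogits", "state")]
}

checkCodes <- function(model, labels, attrs, baseline) {
  nLab <- nrow(model@params$embLabel)
  assertThat(is.matrix(labels) && all(labels >= 0 & labels < nLab),
             "label codes out of range")
  assertThat(length(dim(attrs)) == 3 && all(dim(attrs)[1:2] == dim(labels)),
             "attrs shape inconsistent with labels")
  for (i in seq_along(model@params$embAttr))
    assertThat(all(attrs[, , i] >= 0 &
                     attrs[, , i] < nrow(model@params$embAttr[[i]])),
               "attribute codes out of range")
  assertThat(nrow(baseline) == nrow(labels), "baseline shape mismatch")
}

#' Masked cross-entropy loss for event labels
#'
#' Mean over the non-padded (individual, time) positions of
#' `-logit[true] + log(sum_j exp(logit[j]))`, the cross entropy between the
#' predicted and the true next event labels. Padded positions are excluded
#' from the averaged set.
#'
#' @param labelLogits array `[n, t, C+1]` of label logits.
#' @param trueLabels integer matrix `[n, t]` of true label codes.
#' @param padMask logical matrix `[n, t]`; `TRUE` where the position is a
#'   real (non-padding) prediction target.
#' @return scalar loss.
#' @export
labelLoss <- function(labelLogits, trueLabels, padMask) {
  n <- dim(labelLogits)[1]; Tt <- dim(labelLogits)[2]
  assertThat(any(padMask), "all positions padded: label loss undefined")
  tot <- 0; cnt <- 0
  for (t in seq_len(Tt)) {
    r <- ceRows(matrix(labelLogits[, t, ], nrow = n), trueLabels[, t],
                padMask[, t])
    tot <- tot + r$sum; cnt <- cnt + r$count
  }
  tot / cnt
}

#' Masked cross-entropy loss for event attributes
#'
#' Sums, over individuals, times and attributes, the per-attribute cross
#' entropy — but a triple contributes only when the attribute is relevant
#' for the *true* event label at that position (the indicator
#' `1(A_i | true)`) and the position is not padding. The result is the mean
#' over contributing triples (set `aggregate = "sum"` for the raw masked
#' sum).
#'
#' @param attrLogits list of arrays `[n, t, C_i+1]`, one per attribute.
#' @param trueLabels integer matrix `[n, t]` of true label codes.
#' @param trueAttrs integer array `[n, t, A]` of true attribute codes.
#' @param relevance logical `(C+1) x A` matrix as from `relevanceMatrix()`,
#'   or a \linkS4class{CohortSchema}.
#' @param padMask logical matrix `[n, t]`.
#' @param aggregate `"mean"` or `"sum"`.
#' @return scalar loss.
#' @export
attributeLoss <- function(attrLogits, trueLabels, trueAttrs, relevance,
                          padMask, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (is(relevance, "CohortSchema")) relevance <- relevanceMatrix(relevance)
  n <- dim(trueAttrs)[1]; Tt <- dim(trueAttrs)[2]; A <- dim(trueAttrs)[3]
  tot <- 0; cnt <- 0
  for (i in seq_len(A)) {
    for (t in seq_len(Tt)) {
      mask <- padMask[, t] & relevance[trueLabels[, t] + 1L, i]
      if (!any(mask)) next
      r <- ceRows(matrix(attrLogits[[i]][, t, ], nrow = n),
                  trueAttrs[, t, i], mask)
      tot <- tot + r$sum; cnt <- cnt + r$count
    }
  }
  assertThat(cnt > 0, "no relevant attribute triples: attribute loss undefined")
  if (aggregate == "mean") tot / cnt else tot
}

#' Combined training objective
#'
#' @param lossLabels,lossAttributes the two loss components.
#' @param lambda tradeoff weight for the attribute loss.
#' @return `lossLabels + lambda * lossAttributes`.
#' @export
totalLoss <- function(lossLabels, lossAttributes, lambda) {
  assertThat(is.finite(lossLabels) && is.finite(lossAttributes),
             "loss components must be finite")
  lossLabels + lambda * lossAttributes
}

## Loss + gradients for one batch of chunks (teacher forcing: inputs are the
## true events at 1..L-1, targets the true events at 2..L within each chunk).
gmBatchLossGrad <- function(params, enc, rows, cfg, rel, wantGrad = TRUE) {
  lab <- enc@labels[rows, , drop = FALSE]
  att <- enc@attrs[rows, , , drop = FALSE]
  base <- enc@baseline[rows, , drop = FALSE]
  len <- enc@lengths[rows]
  Tin <- max(len) - 1L
  if (Tin < 1) return(NULL)
  n <- length(rows)
  A <- dim(att)[3]
  inLab <- lab[, seq_len(Tin), drop = FALSE]
  inAtt <- att[, seq_len(Tin), , drop = FALSE]
  tgLab <- lab[, 1L + seq_len(Tin), drop = FALSE]
  tgAtt <- att[, 1L + seq_len(Tin), , drop = FALSE]
  padMask <- outer(len, seq_len(Tin), function(L, t) t <= L - 1L)
  if (cfg$includePadding) padMask[] <- TRUE
  fwd <- gmForward(params, inLab, inAtt, base, cache = wantGrad)
  ## label loss and its logit gradient
  labSum <- 0; labCnt <- 0
  dLab <- array(0, dim = dim(fwd$labelLogits))
  for (t in seq_len(Tin)) {
    r <- ceRows(matrix(fwd$labelLogits[, t, ], nrow = n), tgLab[, t],
                padMask[, t])
    labSum <- labSum + r$sum; labCnt <- labCnt + r$count
    dLab[, t, ] <- r$d
  }
  ## attribute loss with relevance masking on the true label
  attSum <- 0; attCnt <- 0
  dAttr <- lapply(fwd$attrLogits, function(a) array(0, dim = dim(a)))
  for (i in seq_len(A)) {
    for (t in seq_len(Tin)) {
      mask <- padMask[, t] & rel[tgLab[, t] + 1L, i]
      if (!any(mask)) next
      r <- ceRows(matrix(fwd$attrLogits[[i]][, t, ], nrow = n),
                  tgAtt[, t, i], mask)
      attSum <- attSum + r$sum; attCnt <- attCnt + r$count
      dAttr[[i]][, t, ] <- r$d
    }
  }
  lossLab <- labSum / max(labCnt, 1L)
  lossAtt <- if (attCnt > 0) {
    if (cfg$attrLossAggregate == "mean") attSum / attCnt else attSum
  } else 0
  loss <- lossLab + cfg$lambda * lossAtt
  grads <- NULL
  if (wantGrad) {
    dLab <- dLab / max(labCnt, 1L)
    aScale <- cfg$lambda * (if (cfg$attrLossAggregate == "mean")
      1 / max(attCnt, 1L) else 1)
    for (i in seq_len(A)) dAttr[[i]] <- dAttr[[i]] * aScale
    grads <- gmBackward(params, fwd, inLab, inAtt, base, dLab, dAttr)
  }
  list(loss = loss, lossLabels = lossLab, lossAttributes = lossAtt,
       nLabelTerms = labCnt, nAttrTerms = attCnt, grads = grads)
}

#' Train the conditional recurrent generator
#'
#' Teacher-forced next-event prediction on the chunked training tensors: at
#' every non-padded position the model predicts the next event's label and —
#' masked to the attributes relevant for the true next label — its
#' attributes, minimising `lossLabels + lambda * lossAttributes` with Adam.
#' The hidden state is reset at chunk boundaries (chunks are treated as
#' independent windows). Reproducible given the config seed under
#' single-threaded BLAS.
#'
#' @param enc an \linkS4class{EncodedSequences}.
#' @param config a [modelConfig()].
#' @return a \linkS4class{GeneratorModel} carrying the per-epoch loss trace
#'   (epoch 0 is the pre-training loss of the uniform-initialised heads).
#' @export
trainGenerator <- function(enc, config = modelConfig()) {
  assertThat(any(enc@lengths >= 2), "need at least one non-padded transition")
  sc <- enc@schema
  rel <- relevanceMatrix(sc)
  params <- initGeneratorParams(sc, enc@codebook, config)
  nChunks <- nrow(enc@labels)
  opt <- adamInit(params)
  trace <- list()
  evalLoss <- function(p) {
    r <- gmBatchLossGrad(p, enc, seq_len(nChunks), config, rel,
                         wantGrad = FALSE)
    c(labels = r$lossLabels, attributes = r$lossAttributes, total = r$loss)
  }
  l0 <- evalLoss(params)
  trace[[1]] <- c(epoch = 0, l0)
  withSeed(childSeed(config$seed, "train"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(nChunks)
      batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
      epLoss <- 0; epLab <- 0; epAtt <- 0; nb <- 0
      for (b in batches) {
        r <- gmBatchLossGrad(params, enc, b, config, rel)
        if (is.null(r)) next
        if (!is.finite(r$loss))
          stop("NaN/Inf training loss at epoch ", ep,
               " (label=", r$lossLabels, ", attr=", r$lossAttributes,
               "); try a lower learning rate", call. = FALSE)
        st <- adamStep(params, r$grads, opt, lr = config$learningRate,
                       clip = config$gradClip)
        params <- st$params; opt <- st$state
        epLoss <- epLoss + r$loss; epLab <- epLab + r$lossLabels
        epAtt <- epAtt + r$lossAttributes; nb <- nb + 1
      }
      trace[[ep + 1]] <- c(epoch = ep, labels = epLab / nb,
                           attributes = epAtt / nb, total = epLoss / nb)
    }
  })
  new("GeneratorModel", params = params, config = unclass(config),
      codebook = enc@codebook, schema = sc,
      lossTrace = as.data.frame(do.call(rbind, trace)))
}

setMethod("show", "GeneratorModel", function(object) {
  cfg <- object@config
  cat("GeneratorModel: hidden ", cfg$hiddenSize, " x ", cfg$nLayers,
      " layer(s), lambda ", cfg$lambda, "\n", sep = "")
  if (nrow(object@lossTrace)) {
    tr <- object@lossTrace
    cat("  loss: ", round(tr$total[1], 4), " (epoch 0) -> ",
        round(tr$total[nrow(tr)], 4), " (epoch ", max(tr$epoch), ")\n",
        sep = "")
  }
})

## temperature-scaled sampling from a logit matrix; temperature 0 => argmax.
## The padding class (column 1) is never emitted.
sampleFromLogits <- function(logits, temperature, u) {
  logits[, 1] <- -Inf
  if (temperature <= 0) return(max.col(logits, ties.method = "first") - 1L)
  z <- logits / temperature
  z <- z - apply(z, 1, max)
  p <- exp(z); p <- p / rowSums(p)
  sampleRows(p, u) - 1L
}

#' Generate a synthetic cohort from seeds
#'
#' Starting from sequential-tree-synthesized seeds (baseline characteristics
#' plus the first event), the trained model is iterated: at each step the
#' next event label is sampled from the label head's softmax, each attribute
#' relevant for that label is sampled from its head, all non-relevant
#' attributes are set to missing, and the sampled event is fed back in along
#' with the carried hidden state — so generation sees data in exactly the
#' masked format it was trained on. A sequence stops at the terminal label
#' or `maxLength`, and is trimmed at the first terminal event. Event dates
#' are reconstructed by cumulating the decoded sojourn-bin representatives.
#'
#' @param model a trained \linkS4class{GeneratorModel}.
#' @param seeds data.frame in the [seedTable()] layout (from
#'   [synthesizeSeeds()]), in raw (unencoded) values.
#' @param maxLength maximum sequence length including the seeded first event.
#' @param temperature softmax temperature; 1 samples the modelled
#'   distribution, 0 is deterministic argmax generation.
#' @param seed RNG seed.
#' @return a \linkS4class{Cohort}.
#' @export
generateCohort <- function(model, seeds, maxLength = 60L, temperature = 1,
                           seed = 1L) {
  sc <- model@schema
  cb <- model@codebook
  A <- attributeNames(sc)
  B <- baselineNames(sc)
  n <- nrow(seeds)
  rel <- relevanceMatrix(sc)
  term <- terminalLabel(sc)
  termCode <- if (is.na(term)) -1L else match(term, sc@eventLabels)
  ## encode seeds against the training codebook
  base <- matrix(0L, n, length(B), dimnames = list(NULL, B))
  for (v in B) {
    base[, v] <- encodeValues(cb$baseline[[v]], seeds[[v]])
    if (anyNA(base[, v]))
      stop("seeds violate schema: baseline '", v, "' has unencodable values",
           call. = FALSE)
  }
  lab1 <- match(as.character(seeds$first_label), sc@eventLabels)
  assertThat(!anyNA(lab1), "seeds violate schema: unknown first_label")
  att1 <- matrix(0L, n, length(A), dimnames = list(NULL, A))
  for (a in A) {
    code <- encodeValues(cb$attrs[[a]], seeds[[paste0("first_", a)]])
    code[!rel[lab1 + 1L, a]] <- 0L
    code[is.na(code)] <- 0L
    att1[, a] <- code
  }
  labsOut <- matrix(0L, n, maxLength)
  attsOut <- array(0L, dim = c(n, maxLength, length(A)),
                   dimnames = list(NULL, NULL, A))
  labsOut[, 1] <- lab1
  attsOut[, 1, ] <- att1
  alive <- lab1 != termCode
  lenOut <- rep(1L, n)
  withSeed(seed, {
    state <- freshState(model@params, n)
    curLab <- matrix(lab1, ncol = 1)
    curAtt <- array(att1, dim = c(n, 1, length(A)))
    step <- 1L
    while (any(alive) && step < maxLength) {
      act <- which(alive)
      subState <- lapply(state, function(s)
        list(h = s$h[act, , drop = FALSE], c = s$c[act, , drop = FALSE]))
      fwd <- gmForward(model@params, curLab[act, , drop = FALSE],
                       curAtt[act, , , drop = FALSE],
                       base[act, , drop = FALSE], state = subState)
      m <- length(act)
      nextLab <- sampleFromLogits(matrix(fwd$labelLogits[, 1, ], nrow = m),
                                  temperature, runif(m))
      nextAtt <- matrix(0L, m, length(A))
      for (i in seq_along(A)) {
        drawn <- sampleFromLogits(matrix(fwd$attrLogits[[i]][, 1, ], nrow = m),
                                  temperature, runif(m))
        nextAtt[, i] <- ifelse(rel[nextLab + 1L, i], drawn, 0L)
      }
      step <- step + 1L
      labsOut[cbind(act, step)] <- nextLab
      for (i in seq_along(A)) attsOut[cbind(act, step, i)] <- nextAtt[, i]
      lenOut[act] <- step
      for (l in seq_along(state)) {
        state[[l]]$h[act, ] <- fwd$state[[l]]$h
        state[[l]]$c[act, ] <- fwd$state[[l]]$c
      }
      curLab[act, 1] <- nextLab
      curAtt[act, 1, ] <- nextAtt
      alive[act] <- nextLab != termCode
    }
  })
  pseq <- new("PatientSequences",
              labels = lapply(seq_len(n), function(i)
                labsOut[i, seq_len(lenOut[i])]),
              attrs = lapply(seq_len(n), function(i)
                matrix(attsOut[i, seq_len(lenOut[i]), ], nrow = lenOut[i],
                       dimnames = list(NULL, A))),
              baseline = base, patientIds = seq_len(n), codebook = cb,
              schema = sc)
  decodeCohort(pseq)
}

#' Save or load a generator checkpoint
#'
#' The checkpoint is a single file bundling the parameters, the config, the
#' codebook, the loss trace and a schema fingerprint; loading re-validates
#' the fingerprint against the stored schema.
#'
#' @param model a \linkS4class{GeneratorModel}.
#' @param path file path.
#' @return `loadGeneratorModel` returns the model; `saveGeneratorModel`
#'   returns `path` invisibly.
#' @export
saveGeneratorModel <- function(model, path) {
  obj <- list(params = model@params, config = model@config,
              codebook = model@codebook,
              schema = schemaToList(model@schema),
              fingerprint = schemaFingerprint(model@schema),
              lossTrace = model@lossTrace)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveGeneratorModel
#' @export
loadGeneratorModel <- function(path) {
  obj <- readRDS(path)
  sc <- schemaFromList(obj$schema)
  assertThat(identical(schemaFingerprint(sc), obj$fingerprint),
             "checkpoint fingerprint mismatch")
  new("GeneratorModel", params = obj$params, config = obj$config,
      codebook = obj$codebook, schema = sc, lossTrace = obj$lossTrace)
}

## cheap rolling hash of the serialized schema; only used to catch loading a
## checkpoint against the wrong schema
schemaFingerprint <- function(schema) {
  v <- utf8ToInt(paste(deparse(schemaToList(schema)), collapse = ""))
  paste0("ls1-", sum(v * (seq_along(v) %% 97 + 1)) %% 1e9)
}
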
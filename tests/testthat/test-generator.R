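## small encoded dataset + initialized params shared across blocks
makeTinySetup <- function(n = 6, maxLength = 8, seed = 2, nLayers = 1) {
  co <- simulateCohort(quickSpec(n = n, maxLength = maxLength), seed = seed)
  enc <- chunkSequences(encodeCohort(co), window = maxLength)
  cfg <- modelConfig(hiddenSize = 4, nLayers = nLayers, embLabel = 3,
                     embAttr = 2, embBaseline = 2, lambda = 0.7,
                     epochs = 1, seed = 11)
  ns <- asNamespace("longsynth")
  params <- ns$initGeneratorParams(enc@schema, enc@codebook, cfg)
  set.seed(1)
  params <- rapply(params, function(x) x + rnorm(length(x), 0, 0.05),
                   how = "replace")
  model <- new("GeneratorModel", params = params, config = unclass(cfg),
               codebook = enc@codebook, schema = enc@schema,
               lossTrace = data.frame())
  list(enc = enc, cfg = cfg, params = params, model = model, ns = ns)
}

test_that("labelLoss equals brute-force softmax cross entropy", {
  ## uniform logits over C classes -> ln C
  C <- 7
  logits <- array(0, dim = c(3, 4, C))
  truth <- matrix(sample(0:(C - 1), 12, TRUE), 3, 4)
  mask <- matrix(TRUE, 3, 4)
  expect_equal(labelLoss(logits, truth, mask), log(C))
  ## saturated true class -> ~0
  sat <- array(0, dim = c(2, 1, 3))
  tr <- matrix(c(1L, 2L), 2, 1)
  sat[1, 1, 2] <- 1000; sat[2, 1, 3] <- 1000
  expect_lt(labelLoss(sat, tr, matrix(TRUE, 2, 1)), 1e-8)
  ## random 3 x 4 x 5 instance vs direct summation, partial padding
  set.seed(21)
  lg <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  tr2 <- matrix(sample(0:4, 12, TRUE), 3, 4)
  msk <- matrix(sample(c(TRUE, FALSE), 12, TRUE, prob = c(.8, .2)), 3, 4)
  msk[1, 1] <- TRUE
  oracle <- mean(vapply(which(msk), function(ix) {
    i <- row(msk)[ix]; t <- col(msk)[ix]
    bruteCE(lg[i, t, ], tr2[i, t])
  }, 0))
  expect_equal(labelLoss(lg, tr2, msk), oracle, tolerance = 1e-12)
  expect_error(labelLoss(lg, tr2, matrix(FALSE, 3, 4)), "padded")
})

test_that("attributeLoss masks by the true label's relevance", {
  ## 2 individuals, 3 steps, 2 attributes with mixed relevance
  set.seed(31)
  C1 <- 4; C2 <- 3; nLab <- 3        # label codes 0..2
  a1 <- array(rnorm(2 * 3 * C1), dim = c(2, 3, C1))
  a2 <- array(rnorm(2 * 3 * C2), dim = c(2, 3, C2))
  truth <- matrix(c(1L, 2L, 1L, 2L, 1L, 2L), 2, 3)
  attrs <- array(sample(0:2, 2 * 3 * 2, TRUE), dim = c(2, 3, 2))
  rel <- rbind(c(FALSE, FALSE),      # padding label: nothing relevant
               c(TRUE, FALSE),       # label 1 measures attr 1 only
               c(TRUE, TRUE))        # label 2 measures both
  mask <- matrix(TRUE, 2, 3); mask[2, 3] <- FALSE
  got <- attributeLoss(list(a1, a2), truth, attrs, rel, mask)
  ## brute-force masked summation
  terms <- c()
  for (i in 1:2) for (t in 1:3) for (k in 1:2) {
    if (!mask[i, t]) next
    if (!rel[truth[i, t] + 1, k]) next
    lg <- if (k == 1) a1[i, t, ] else a2[i, t, ]
    terms <- c(terms, bruteCE(lg, attrs[i, t, k]))
  }
  expect_equal(got, mean(terms), tolerance = 1e-12)
  expect_equal(attributeLoss(list(a1, a2), truth, attrs, rel, mask,
                             aggregate = "sum"),
               sum(terms), tolerance = 1e-12)
  ## all-relevant limit equals the unmasked mean cross entropy
  relAll <- rbind(c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, TRUE))
  maskAll <- matrix(TRUE, 2, 3)
  allTerms <- c()
  for (i in 1:2) for (t in 1:3) for (k in 1:2)
    allTerms <- c(allTerms, bruteCE(if (k == 1) a1[i, t, ] else a2[i, t, ],
                                    attrs[i, t, k]))
  expect_equal(attributeLoss(list(a1, a2), truth, attrs, relAll, maskAll),
               mean(allTerms), tolerance = 1e-12)
  ## empty relevance -> undefined mean
  relNone <- rbind(c(FALSE, FALSE), c(FALSE, FALSE), c(FALSE, FALSE))
  expect_error(attributeLoss(list(a1, a2), truth, attrs, relNone, mask),
               "no relevant")
  ## exact-zero masking: perturbing an irrelevant logit changes nothing
  a1p <- a1
  a1p[2, 3, 2] <- a1p[2, 3, 2] + 100      # padded position
  posIrr <- which(!rel[truth + 1L, 1])    # (i,t) where attr 1 irrelevant
  if (length(posIrr)) {
    i <- row(truth)[posIrr[1]]; t <- col(truth)[posIrr[1]]
    a1p[i, t, ] <- a1p[i, t, ] + rnorm(C1, 0, 50)
  }
  expect_identical(attributeLoss(list(a1p, a2), truth, attrs, rel, mask), got)
})

test_that("totalLoss is the lambda-weighted sum", {
  expect_equal(totalLoss(1.3, 2.1, 0), 1.3)
  expect_equal(totalLoss(0.8, 0.8, 1), 1.6)
  expect_equal(totalLoss(1.25, 0.5, 0.5), 1.5)
  expect_error(totalLoss(NaN, 1, 1), "finite")
})

test_that("forward honours the hidden-state chaining contract", {
  s <- makeTinySetup(nLayers = 2)
  enc <- s$enc
  rows <- which(enc@lengths >= 3)[1:3]
  lab <- enc@labels[rows, 1:2]
  att <- enc@attrs[rows, 1:2, , drop = FALSE]
  base <- enc@baseline[rows, ]
  full <- forwardGenerator(s$model, lab, att, base)
  ## single step returns one prediction per individual
  one <- forwardGenerator(s$model, lab[, 1, drop = FALSE],
                          att[, 1, , drop = FALSE], base)
  expect_equal(dim(one$labelLogits)[2], 1)
  ## two chained 1-step calls equal the 2-step call
  two <- forwardGenerator(s$model, lab[, 2, drop = FALSE],
                          att[, 2, , drop = FALSE], base,
                          state = one$state)
  expect_equal(one$labelLogits[, 1, ], full$labelLogits[, 1, ],
               tolerance = 1e-12)
  expect_equal(two$labelLogits[, 1, ], full$labelLogits[, 2, ],
               tolerance = 1e-12)
  for (k in seq_along(full$attrLogits))
    expect_equal(two$attrLogits[[k]][, 1, ], full$attrLogits[[k]][, 2, ],
                 tolerance = 1e-12)
  ## permuting individuals permutes outputs identically
  perm <- c(3, 1, 2)
  pf <- forwardGenerator(s$model, lab[perm, ], att[perm, , , drop = FALSE],
                         base[perm, ])
  expect_equal(pf$labelLogits, full$labelLogits[perm, , , drop = FALSE],
               tolerance = 1e-12)
  ## out-of-range codes are rejected
  badLab <- lab; badLab[1, 1] <- 99L
  expect_error(forwardGenerator(s$model, badLab, att, base), "out of range")
})

test_that("analytic gradients match central finite differences", {
  s <- makeTinySetup(nLayers = 2)
  ns <- s$ns
  rel <- ns$relevanceMatrix(s$enc@schema)
  rows <- seq_len(nrow(s$enc@labels))
  r <- ns$gmBatchLossGrad(s$params, s$enc, rows, s$cfg, rel)
  flat <- unlist(s$params); gflat <- unlist(r$grads)
  f <- function(v)
    ns$gmBatchLossGrad(utils::relist(v, s$params), s$enc, rows, s$cfg, rel,
                       wantGrad = FALSE)$loss
  set.seed(42)
  idx <- sample(length(flat), 50)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    vp <- flat; vp[i] <- vp[i] + eps
    vm <- flat; vm[i] <- vm[i] - eps
    (f(vp) - f(vm)) / (2 * eps)
  }, 0)
  relErr <- abs(num - gflat[idx]) / pmax(1e-6, abs(num) + abs(gflat[idx]))
  expect_lt(max(relErr), 1e-3)
})

test_that("epoch-0 loss matches the uniform-softmax closed form", {
  co <- simulateCohort(quickSpec(n = 40, maxLength = 12), seed = 3)
  enc <- chunkSequences(encodeCohort(co), window = 12)
  cfg <- modelConfig(hiddenSize = 8, epochs = 1, lambda = 0.6, seed = 5)
  m <- trainGenerator(enc, cfg)
  tr0 <- m@lossTrace[1, ]
  C <- length(enc@codebook$labels)
  expect_equal(tr0$labels, log(C), tolerance = 1e-9)
  ## attribute part: count-weighted mean of ln(C_i + 1) over relevant triples
  ns <- asNamespace("longsynth")
  rel <- ns$relevanceMatrix(enc@schema)
  cnt <- stats::setNames(numeric(length(enc@codebook$attrs)),
                         names(enc@codebook$attrs))
  for (r in seq_len(nrow(enc@labels))) {
    len <- enc@lengths[r]
    if (len < 2) next
    tg <- enc@labels[r, 2:len]
    for (a in seq_along(cnt)) cnt[a] <- cnt[a] + sum(rel[tg + 1L, a])
  }
  lnCi <- vapply(enc@codebook$attrs, function(e) log(e$n + 1), 0)
  expect_equal(tr0$attributes, sum(cnt * lnCi) / sum(cnt), tolerance = 1e-9)
  expect_equal(tr0$total, tr0$labels + 0.6 * tr0$attributes,
               tolerance = 1e-9)
})

test_that("the generator learns a deterministic chain perfectly", {
  spec <- chainSpec(n = 80, maxLength = 12)
  real <- simulateCohort(spec, seed = 21)
  enc <- chunkSequences(encodeCohort(real), window = 12)
  cfg <- modelConfig(hiddenSize = 8, embLabel = 4, embAttr = 2,
                     embBaseline = 2, epochs = 40, batchSize = 32,
                     learningRate = 0.03, window = 12, seed = 9)
  m <- trainGenerator(enc, cfg)
  ## training loss trends down
  expect_lt(tail(m@lossTrace$total, 1), m@lossTrace$total[1])
  ## held-out chains: next-label argmax accuracy 1.0
  held <- simulateCohort(spec, seed = 22)
  encH <- chunkSequences(encodeCohort(computeSojourn(held),
                                      codebook = enc@codebook), window = 12)
  rows <- seq_len(nrow(encH@labels))
  fwd <- forwardGenerator(m, encH@labels[rows, 1:11],
                          encH@attrs[rows, 1:11, , drop = FALSE],
                          encH@baseline[rows, , drop = FALSE])
  pred <- apply(fwd$labelLogits, c(1, 2), which.max) - 1L
  truth <- encH@labels[rows, 2:12]
  expect_equal(mean(pred == truth), 1.0)
  ## argmax generation reproduces the chain exactly
  synth <- suppressMessages(fitSeedSynthesizer(computeSojourn(real)))
  seeds <- synthesizeSeeds(synth, 30, seed = 2)
  syn0 <- generateCohort(m, seeds, maxLength = 12, temperature = 0, seed = 4)
  seqs <- split(eventTable(syn0)$label, eventTable(syn0)$patient_id)
  first <- as.character(seeds$first_label)
  for (i in seq_along(seqs)) {
    expectSeq <- rep(if (first[i] == "A") c("A", "B") else c("B", "A"), 6)
    expect_equal(unname(seqs[[i]]), expectSeq)
  }
  ## sampled generation follows the chain at almost every transition (the
  ## softmax retains a sliver of off-chain mass)
  syn1 <- generateCohort(m, seeds, maxLength = 12, temperature = 1, seed = 4)
  e1 <- eventTable(syn1)
  flips <- unlist(tapply(e1$label, e1$patient_id,
                         function(s) head(s, -1) != s[-1]))
  expect_gt(mean(flips), 0.98)
})

test_that("generation respects seeds, masking, terminal trimming", {
  s <- makeTinySetup(n = 30, maxLength = 10)
  co <- computeSojourn(simulateCohort(quickSpec(n = 30, maxLength = 10),
                                      seed = 2))
  synth <- suppressMessages(fitSeedSynthesizer(co))
  seeds <- synthesizeSeeds(synth, 25, seed = 6)
  ## maxLength 1: exactly the seeded first event
  g1 <- generateCohort(s$model, seeds, maxLength = 1, seed = 3)
  expect_equal(nrow(eventTable(g1)), 25)
  expect_equal(eventTable(g1)$label, as.character(seeds$first_label))
  ## temperature 0 is deterministic given seeds
  a <- generateCohort(s$model, seeds, maxLength = 8, temperature = 0, seed = 1)
  b <- generateCohort(s$model, seeds, maxLength = 8, temperature = 0, seed = 99)
  expect_identical(eventTable(a), eventTable(b))
  ## sampled generation: no events after a terminal label, masking holds
  g <- generateCohort(s$model, seeds, maxLength = 8, seed = 5)
  e <- eventTable(g)
  for (pid in unique(e$patient_id)) {
    sq <- e$label[e$patient_id == pid]
    wt <- which(sq == "last_obs")
    if (length(wt)) expect_equal(wt[1], length(sq))
  }
  expect_true(all(is.na(e$riw[!e$label %in% c("ed_visit", "hosp")])))
  expect_true(all(!is.na(e$riw[e$label %in% c("ed_visit", "hosp")])))
  ## same seed, same seeds -> identical output
  expect_identical(eventTable(g),
                   eventTable(generateCohort(s$model, seeds, maxLength = 8,
                                             seed = 5)))
})

test_that("model checkpoints round-trip through disk", {
  co <- simulateCohort(quickSpec(n = 20, maxLength = 8), seed = 13)
  enc <- chunkSequences(encodeCohort(co), window = 8)
  m <- trainGenerator(enc, modelConfig(hiddenSize = 4, epochs = 1, seed = 3))
  path <- tempfile(fileext = ".rds")
  saveGeneratorModel(m, path)
  m2 <- loadGeneratorModel(path)
  expect_equal(m2@params, m@params)
  expect_equal(m2@config, m@config)
  expect_equal(eventLabels(m2@schema), eventLabels(m@schema))
})
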
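test_that("hellinger matches closed forms and is a metric", {
  expect_equal(hellinger(c(a = .5, b = .5), c(a = .5, b = .5)), 0)
  expect_equal(hellinger(c(a = 1), c(b = 1)), 1)       # disjoint supports
  expect_equal(hellinger(c(.5, .5), c(.9, .1)),
               sqrt(1 - (sqrt(.45) + sqrt(.05))), tolerance = 1e-12)
  expect_equal(round(hellinger(c(.5, .5), c(.9, .1)), 4), 0.3249)
  expect_error(hellinger(c(.5, .6), c(.5, .5)), "normalized")
  ## metric properties on random distributions
  set.seed(14)
  for (i in 1:40) {
    rnd <- function() { x <- rgamma(4, 1); x / sum(x) }
    p <- rnd(); q <- rnd(); r <- rnd()
    expect_equal(hellinger(p, q), hellinger(q, p), tolerance = 1e-12)
    expect_gte(hellinger(p, q) + 1e-12, 0)
    expect_lte(hellinger(p, q), 1)
    expect_lte(hellinger(p, r), hellinger(p, q) + hellinger(q, r) + 1e-12)
    expect_equal(hellinger(p, p), 0, tolerance = 1e-12)
  }
})

test_that("sequence length comparison reports percent difference of means", {
  co <- toyCohort(list(c("A", "B"), c("A", "B", "A", "B")))
  expect_equal(sequenceLengthReport(co, co)$percentDifference, 0)
  dbl <- toyCohort(list(rep(c("A", "B"), 2), rep(c("A", "B", "A", "B"), 2)))
  expect_equal(sequenceLengthReport(co, dbl)$percentDifference, 100)
  ## reference full-scale means: 58.14 real vs 58.39 synthetic -> ~0.43%
  expect_equal(100 * abs(58.39 - 58.14) / 58.14, 0.43, tolerance = 0.005)
})

test_that("event distribution Hellinger uses pooled label proportions", {
  co <- toyCohort(list(c("A", "B"), c("B", "A")))
  expect_equal(eventDistributionHellinger(co, co), 0)
  ## swapping equal-frequency labels leaves the marginal unchanged
  sw <- toyCohort(list(c("B", "A"), c("A", "B")))
  expect_equal(eventDistributionHellinger(co, sw), 0)
  ## hand-tabulated toy: real (3A, 1B), syn (1A, 3B)
  r <- toyCohort(list(c("A", "A"), c("A", "B")))
  s <- toyCohort(list(c("B", "B"), c("B", "A")))
  hand <- sqrt(1 - (sqrt(.75 * .25) + sqrt(.25 * .75)))
  expect_equal(eventDistributionHellinger(r, s), hand, tolerance = 1e-12)
})

test_that("attribute Hellinger filters to relevant observations", {
  r <- toyCohort(list(c("A", "B", "A"), c("A", "C")))
  expect_equal(unname(attributeHellinger(r, r)$distances),
               c(0, 0))
  ## "val" observed only under A; stray B-row content must not leak in
  s <- toyCohort(list(c("A", "B", "A"), c("A", "C")))
  s@events$val[s@events$label == "A"] <- c("y", "y", "y")
  ## oracle: filter rows with label A, tabulate
  pr <- table(r@events$val[r@events$label == "A"]) /
    sum(r@events$label == "A")
  ps <- table(s@events$val[s@events$label == "A"]) /
    sum(s@events$label == "A")
  o <- hellinger(stats::setNames(as.numeric(pr), names(pr)),
                 stats::setNames(as.numeric(ps), names(ps)))
  got <- attributeHellinger(r, s)$distances
  expect_equal(unname(got["val"]), o)
  expect_equal(o, 1)    # x-only vs y-only: disjoint support
  ## summary matches a brute-force recomputation of the stored values
  sm <- attributeHellinger(r, s)$summary
  v <- unname(got)
  expect_equal(sm$mean, mean(v))
  expect_equal(sm$median, median(v))
})

test_that("transition matrices match brute-force window counting", {
  co <- toyCohort(list(c("A", "B", "A", "B", "C")))
  t1 <- estimateTransitionMatrix(co, 1)
  expect_equal(t1@probs["A", "B"], 1.0)
  expect_equal(t1@probs["B", "A"], 0.5)
  expect_equal(t1@probs["B", "C"], 0.5)
  expect_equal(unname(rowSums(t1@probs)), rep(1, nrow(t1@probs)))
  t2 <- estimateTransitionMatrix(co, 2)
  expect_setequal(t2@contexts, c("A|B", "B|A"))
  expect_equal(t2@probs["A|B", "A"], 0.5)
  expect_equal(t2@probs["A|B", "C"], 0.5)
  expect_equal(t2@probs["B|A", "B"], 1.0)
  ## windows never span individuals
  two <- toyCohort(list(c("A", "B"), c("B", "C")))
  tt <- estimateTransitionMatrix(two, 1)
  expect_equal(sum(tt@counts), 2)         # one window per individual
  expect_error(estimateTransitionMatrix(two, 3), "no countable windows")
})

test_that("transition-matrix comparison handles unmatched contexts", {
  tm <- transitionMatrix(exampleOrder2Matrix(), normalize = TRUE)
  expect_equal(tm@order, 2L)
  ## a matrix compared with itself gives mean 0
  cmp <- compareTransitionMatrices(tm, tm)
  expect_equal(unname(cmp$distances), rep(0, 9))
  expect_equal(cmp$summary$mean, 0)
  ## one row replaced by a disjoint-support row -> that row 1, others 0
  m2 <- exampleOrder2Matrix()
  m2["A|B", ] <- c(0, 0, 0, 1)            # real A|B row has mass off D only
  tm2 <- transitionMatrix(m2, normalize = TRUE)
  cmp2 <- compareTransitionMatrices(tm, tm2)
  expect_equal(unname(cmp2$distances["A|B"]), 1)
  expect_equal(unname(sort(cmp2$distances)[1:8]), rep(0, 8))
  ## unmatched context: scored 1 by default, droppable via "skip"
  m3 <- exampleOrder2Matrix()[1:8, ]
  tm3 <- transitionMatrix(m3, normalize = TRUE)
  cmpOne <- compareTransitionMatrices(tm, tm3)
  expect_equal(unname(cmpOne$distances["D|D"]), 1)
  cmpSkip <- compareTransitionMatrices(tm, tm3, unmatched = "skip")
  expect_false("D|D" %in% names(cmpSkip$distances))
  expect_error(compareTransitionMatrices(tm, estimateTransitionMatrix(
    toyCohort(list(c("A", "B", "A"))), 1)), "order mismatch")
})

test_that("estimated transition matrices converge to the kernel with n", {
  spec <- quickSpec(n = 5000, maxLength = 40, seed = 3)
  d <- vapply(c(500, 5000), function(n) {
    spec@nIndividuals <- as.integer(n)
    co <- simulateCohort(spec, seed = 31)
    strat <- cohortStrata(spec, co)
    keep <- baselineTable(co)$patient_id[strat == 1]
    sub <- newCohort(baselineTable(co)[strat == 1, ],
                     eventTable(co)[eventTable(co)$patient_id %in% keep, ],
                     schemaOf(co))
    compareTransitionMatrices(trueTransitionMatrix(spec, 1),
                              estimateTransitionMatrix(sub, 1))$summary$mean
  }, 0)
  expect_lt(d[2], d[1])
  expect_lt(d[2], 0.1)
  ## two independent estimates of the same kernel are close
  co1 <- simulateCohort(spec, seed = 41)
  co2 <- simulateCohort(spec, seed = 42)
  cmp <- compareTransitionMatrices(estimateTransitionMatrix(co1, 1),
                                   estimateTransitionMatrix(co2, 1))
  expect_lt(cmp$summary$mean, 0.1)
})

test_that("multivariate Hellinger matches the Gaussian closed form", {
  set.seed(6)
  X <- matrix(rnorm(4000), ncol = 2, dimnames = list(NULL, c("u", "v")))
  expect_equal(multivariateHellinger(X, X), 0, tolerance = 1e-9)
  ## univariate specialization: equal variances, mean gap delta
  x1 <- matrix(rnorm(50000, 0, 2), dimnames = list(NULL, "z"))
  x2 <- x1 + 1.5
  s2 <- var(as.numeric(x1))
  closed <- sqrt(1 - exp(-1.5^2 / (8 * s2)))
  expect_equal(multivariateHellinger(x1, x2, reg = 0), closed,
               tolerance = 1e-9)
  ## the default diagonal regularization is a negligible perturbation
  expect_equal(multivariateHellinger(x1, x2), closed, tolerance = 1e-5)
  ## affine invariance under a common map
  Y <- matrix(rnorm(4000, 1, 3), ncol = 2, dimnames = list(NULL, c("u", "v")))
  d0 <- multivariateHellinger(X, Y)
  set.seed(7)
  for (i in 1:5) {
    A <- matrix(rnorm(4), 2, 2); A <- A + diag(2) * 2   # well-conditioned
    b <- rnorm(2)
    tf <- function(M) {
      out <- M %*% A + matrix(b, nrow(M), 2, byrow = TRUE)
      colnames(out) <- colnames(M); out
    }
    expect_equal(multivariateHellinger(tf(X), tf(Y)), d0, tolerance = 1e-6)
  }
  ## singular inputs are reported with the offending column
  Z <- cbind(X, w = 0)
  expect_error(multivariateHellinger(Z, Z * 0 + cbind(X, w = 0)), NA)
})

test_that("SMD operators reproduce reference worked examples", {
  ## continuous: age and total follow-up time
  expect_equal(round(smdContinuous(43.32, 17.87, 44.79, 19.83), 3), 0.078)
  expect_equal(round(smdContinuous(1474.48, 772.23, 1077.88, 722.44), 3),
               0.530)
  expect_equal(smdContinuous(5, 1, 5, 1), 0)
  ## binary: mortality and hospitalization counts
  expect_equal(round(smdBinary(3299, 75660, 1440, 75660), 3), 0.141)
  expect_equal(round(smdBinary(22495, 75660, 21582, 75660), 3), 0.027)
  expect_equal(smdBinary(300, 1000, 300, 1000), 0)
  ## symmetry and scale invariance
  set.seed(8)
  for (i in 1:20) {
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- rgamma(1, 2); s2 <- rgamma(1, 2)
    expect_equal(smdContinuous(m1, s1, m2, s2), smdContinuous(m2, s2, m1, s1))
    k <- rgamma(1, 2)
    expect_equal(smdContinuous(k * m1, k * s1, k * m2, k * s2),
                 smdContinuous(m1, s1, m2, s2), tolerance = 1e-12)
    x1 <- sample(0:50, 1); x2 <- sample(0:50, 1)
    expect_equal(smdBinary(x1, 50, x2, 50), smdBinary(x2, 50, x1, 50))
  }
  ## degenerate: both SDs zero
  expect_warning(inf <- smdContinuous(1, 0, 2, 0))
  expect_equal(inf, Inf)
})

test_that("confidence-interval overlap averages the two coverage ratios", {
  expect_equal(ciOverlap(0.66, 0.75, 0.66, 0.75), 100)
  expect_equal(ciOverlap(0.1, 0.2, 0.5, 0.9), 0)
  expect_equal(ciOverlap(0.57, 0.67, 0.60, 0.68),
               100 * (0.07 / 0.10 + 0.07 / 0.08) / 2)
  expect_equal(round(ciOverlap(0.57, 0.67, 0.60, 0.68), 2), 78.75)
  expect_equal(ciOverlap(0.60, 0.68, 0.57, 0.67),
               ciOverlap(0.57, 0.67, 0.60, 0.68))
  expect_warning(z <- ciOverlap(0.5, 0.5, 0.4, 0.6))
  expect_equal(z, (1 + 0.0) * 100 / 2)
})

test_that("random queries are reproducible and identity-consistent", {
  co <- computeSojourn(simulateCohort(quickSpec(n = 150, maxLength = 15),
                                      seed = 5))
  rq <- randomCohortAssessment(co, co, nQueries = 40, seed = 9)
  expect_true(all(rq$log$distance[!rq$log$skipped] == 0))
  ## determinism: same seed gives the identical query list and distances
  rq2 <- randomCohortAssessment(co, co, nQueries = 40, seed = 9)
  expect_identical(rq$log, rq2$log)
  ## a different cohort gives distances in [0, 1]
  co2 <- computeSojourn(simulateCohort(quickSpec(n = 150, maxLength = 15),
                                       seed = 6))
  rq3 <- randomCohortAssessment(co, co2, nQueries = 40, seed = 9)
  ok <- rq3$log$distance[!rq3$log$skipped]
  expect_true(all(ok >= 0 & ok <= 1))
  ## normalized Euclidean closed form
  expect_equal(abs(3 - 4) / sqrt(3^2 + 4^2), 0.2)
  ## summaries match brute-force recomputation
  eu <- rq3$log$distance[rq3$log$kind == "euclidean" & !rq3$log$skipped]
  expect_equal(rq3$euclidean$mean, mean(eu))
  expect_equal(rq3$euclidean$iqr,
               unname(quantile(eu, .75) - quantile(eu, .25)))
})

test_that("evaluateUtility bundles all metrics coherently", {
  co <- computeSojourn(simulateCohort(quickSpec(n = 120, maxLength = 15),
                                      seed = 8))
  rep <- evaluateUtility(co, co, nQueries = 20, seed = 2)
  m <- rep@metrics
  expect_equal(m$sequenceLength$percentDifference, 0)
  expect_equal(m$eventDistribution, 0)
  expect_true(all(m$attributes$distances == 0, na.rm = TRUE))
  expect_equal(m$transitions$order1$summary$mean, 0)
  expect_equal(m$transitions$order2$summary$mean, 0)
  expect_equal(m$multivariateHellinger, 0, tolerance = 1e-9)
  expect_true(all(unlist(lapply(m$transitions, function(x) x$distances)) >= 0))
})
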
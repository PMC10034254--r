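# longsynth

Synthesis and evaluation of longitudinal health data with a conditional
recurrent generative model.

Access to individual-level administrative health data — dispensation
records, emergency department visits, hospitalizations, lab results — is
slow and restrictive, and longitudinal records are the hard case for data
synthesis: sequences vary in length across patients, every event type
carries its own attribute set, and most attribute cells are structurally
missing. `longsynth` is for biostatisticians and health-services
researchers who want to generate realistic synthetic cohorts from such
data, quantify how faithful the synthesis is, and check that its
attribution-disclosure risk is acceptable — all from R, with a built-in
cohort simulator so the entire pipeline is testable without restricted
data.

## The model

Generation has two stages:

1. **Sequential tree synthesis** of baseline characteristics and the
   first event: variables are synthesized in order, each from a
   CART-style tree on the previously synthesized variables, sampling from
   the donor pool of the reached leaf.
2. **A conditional LSTM** extends each individual event by event. Integer
   codes for the event label and attributes are embedded, run through the
   recurrent core, and one linear head per output — concatenating the
   hidden state with the embedded baseline characteristics — predicts the
   next event's label and attributes.

Training minimises, over parameters θ,

    min_θ { loss_labels + λ · loss_attributes }

where `loss_labels` is the softmax cross entropy of the predicted next
label over non-padded positions, and `loss_attributes` includes the
(n, t, i) term only when attribute *i* is measured for the *true* next
label — the indicator `1(A_i | true_{n,t})` — so the model learns each
attribute only where it exists. The same masking is applied during
generation: attributes irrelevant for the sampled label are set to
missing before the event is fed back in. Sequences end at a terminal
"last observation" label.

The evaluation suite implements Hellinger distances of event and
attribute distributions (relevance-filtered), row-wise comparison of
k-th order Markov transition matrices, a multivariate Hellinger distance
`sqrt(1 − exp(−BD))` from the Gaussian Bhattacharyya distance BD,
seeded random-query ("fuzzy SQL") cohort comparison, standardized mean
differences `|m₂ − m₁| / sqrt((s₁² + s₂²)/2)`, confidence-interval
overlap, and a two-direction attribution-disclosure risk estimator over
quasi-identifier equivalence classes with the conventional 0.09
threshold.

## Worked example

Simulate a ground-truth cohort, train, generate, and evaluate:

```r
library(longsynth)

spec  <- defaultSimulationSpec(nIndividuals = 500, maxLength = 40, seed = 1)
real  <- simulateCohort(spec)
enc   <- chunkSequences(encodeCohort(real), window = 40)
model <- trainGenerator(enc, modelConfig(hiddenSize = 24, epochs = 25,
                                         window = 40, seed = 2))
seeder <- fitSeedSynthesizer(real)
syn    <- generateCohort(model, synthesizeSeeds(seeder, 500, seed = 3),
                         maxLength = 40, seed = 4)
evaluateUtility(real, syn, nQueries = 50, seed = 5)
#> UtilityReport
#>   % difference in mean sequence length: 0.32%
#>   event-distribution Hellinger:          0.0206
#>   attribute Hellinger mean (SD):         0.0306 (0.0098)
#>   order-1 transition Hellinger mean (SD): 0.0257 (0.0042)
#>   order-2 transition Hellinger mean (SD): 0.0364 (0.0232)
#>   multivariate Hellinger:                0.2505
#>   random cohorts: Hellinger 0.0227, norm. Euclidean 0.1381

assessPrivacy(real, syn, privacyConfig(
  quasiIdentifiers = c("age", "sex", "any_hosp"), sensitive = "comorbidity"))
#> PrivacyReport (attribution disclosure)
#>   population -> sample risk: 0.018660
#>   sample -> population risk: 0.038282
#>   threshold 0.09: PASS
```

Reading the numbers: the generated cohort's mean sequence length is
within 0.32% of the real one; every Hellinger distance lies in [0, 1]
with 0 meaning identical distributions, so event-type proportions (0.021)
and per-attribute distributions (mean 0.031) are close, and the
first-order transition structure (0.026) is recovered slightly better
than the second-order one (0.036). Both attribution-disclosure risks sit
well under the 0.09 acceptability threshold, so no quasi-identifier
equivalence class is small enough to make matching plus attribute
learning likely.

The workload-aware operators work directly on published summaries, e.g.
an age of 43.32 (SD 17.87) in one group versus 44.79 (SD 19.83) in the
other:

```r
smdContinuous(43.32, 17.87, 44.79, 19.83)   # 0.078 — under the 0.1 flag
ciOverlap(0.66, 0.75, 0.69, 0.77)           # percent overlap of two CIs
```

A command-line wrapper for the full pipeline
(simulate-fixture / preprocess / fit-baseline / train / generate /
evaluate-utility / evaluate-privacy / end-to-end) lives at
`inst/cli/longsynth.R` and is driven by a YAML config; identical config
and seed reproduce every artifact byte-for-byte.

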
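---
title: "Methods: conditional recurrent synthesis of longitudinal health data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional recurrent synthesis of longitudinal health data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The data model

Administrative health data arrives as one cross-sectional demographics
table (one row per individual) linked by a patient identifier to several
transactional tables (dispensations, emergency department visits,
hospitalizations, laboratory tests, vital statistics), each with many rows
per individual. `longsynth` harmonizes this into a `Cohort`: a baseline
table plus a single chronological event stream in which every event has a
label (its type), a relative date, and a set of attributes whose relevance
depends on the label — a lab result exists only for lab events, a resource
intensity weight only for ED visits and hospitalizations. The relevance map
declared in the `CohortSchema` is the central device of the whole package:
it drives loss masking during training, attribute masking during
generation, and relevance filtering during evaluation.

Event timing is represented as *sojourn time*, the days elapsed since the
individual's previous event. The first event of each individual is given
sojourn 0: defining it as days since an external study-start would require
an anchor the event stream does not carry, whereas 0 keeps every sojourn
computable from the stream alone and makes date reconstruction a simple
cumulative sum. Sojourn time is treated as an attribute of every event
type, like any other.

The model is wholly categorical: every originally-continuous quantity
(age, lab results, resource weights, sojourn days) is quantile-binned
(default 20 bins) at encoding time, because both training losses are cross
entropies over a finite number of classes per output. Quantile binning
preserves the marginal shape with equal-mass bins; decoding maps a bin to
the median of the training values it contained. Code 0 is reserved in every
vocabulary for padding and missing values. Sequences longer than the
empirical 95th percentile of per-individual event counts are truncated
(hard cap 1000), which bounds tensor sizes at the cost of not representing
the heaviest healthcare users; training tensors are built by cutting each
sequence into windows of up to 120 events, zero-padded to exactly the
window length.

## The generative model

Synthesis has two stages. First, baseline characteristics and the first
event's values are drawn from a **sequential tree synthesizer**: variables
are synthesized one at a time (baseline variables, then the first-event
label, then its relevant attributes), each later variable by routing the
partial synthetic row down a classification/regression tree fitted on the
earlier variables and resampling from the donor pool of the reached leaf.
Donor-pool sampling guarantees that synthetic values are values that
occurred in the training data, needs no distributional assumptions, and —
with the default minimum leaf size of 5 — never reproduces a pool narrower
than five individuals. First-event attributes are fitted only on the
individuals whose first label makes them relevant, and drawn only when the
synthesized first label does, mirroring the recurrent model's masking.

Second, the **conditional recurrent model** extends each seeded individual
event by event. Architecture: learned embeddings for the event label, each
event attribute and each baseline variable; an LSTM over the concatenated
label + attribute embeddings; and one linear head per output (the next
label, each next attribute), each head consuming the LSTM output
concatenated with the embedded baseline characteristics — so every
prediction is conditioned on who the individual is. Feeding events
1..t-1 yields predictions for events 2..t, and the hidden state carries
the individual's history between calls.

Training is teacher-forced next-event prediction with two masked cross
entropies: a label loss averaged over non-padded positions, and an
attribute loss in which a (position, attribute) term contributes only when
that attribute is relevant for the *true* next label. The objective is
`lossLabels + lambda * lossAttributes` with `lambda = 1` by default.
Two reading choices are config-exposed rather than hard-coded: padded
positions are excluded from the averaged set by default (predicting
padding is not a skill worth rewarding; `includePadding = TRUE` restores
the strict uniform average), and the attribute loss is the mean over
contributing triples (`attrLossAggregate = "sum"` switches to the raw
masked sum). The label vocabulary retains class 0 so the loss matches the
full softmax over all classes including the padding code.

The LSTM, its backpropagation through time, and the Adam optimizer are
implemented in base R matrix code, since the recurrent model is the core
of the package. Correctness is enforced mechanically: the test suite
checks the analytic gradients of the full model (embeddings, both loss
masks, multi-layer LSTM, heads) against central finite differences, and
the zero-initialized heads make the epoch-0 loss exactly
`ln C + lambda * ln C_i` (count-weighted), which is asserted in closed
form. Hidden state is reset at chunk boundaries — chunks are treated as
independent windows, the simplest contract consistent with windowed
training. Gradients are clipped at global norm 5; a NaN loss aborts with
diagnostics rather than training through it.

Generation samples the next label from the label head's softmax
(temperature 1 by default; temperature 0 gives deterministic argmax
generation, useful for tests), samples each attribute relevant for the
*sampled* label, sets the rest to missing, and feeds the event back with
the carried state — so generation-time inputs have exactly the masked
shape of training-time inputs. The padding class is never emitted.
Sequences stop at the terminal "last observation" label or at the maximum
length, and are trimmed at the first terminal event. Dates are rebuilt by
cumulating decoded sojourn representatives.

## The cohort simulator

Every claim in the package is testable without restricted data because the
simulator generates cohorts with *known* structure: baseline age, sex and
a small comorbidity score; four event types (drug dispensation, ED visit,
hospitalization, terminal last-observation) with per-type attribute sets;
geometric sojourn distributions per type; and first-order Markov kernels
over the labels, one per baseline stratum, with the terminal label
absorbing. The two sexes form the two strata: a categorical stratum
variable passes through integer encoding losslessly, so the
baseline-conditioning pathway can be tested without the confound of
bin-boundary blur that a continuous stratum driver (e.g. age thresholded
at 50) would introduce. The defaults — 2000 individuals, maximum length
60, terminal hazards giving mean sequence length around 10 — are the
standing study conditions of the recovery experiments below.

What the simulator deliberately does not emulate: real marginals of any
population, high-cardinality code vocabularies (ICD), long-range
dependencies beyond first order, and informative missingness beyond the
relevance mechanism. Passing recovery tests therefore demonstrates that
the model captures low-order conditional dynamics and baseline effects at
desk scale — not that it reproduces the full complexity of administrative
records.

## Evaluation metrics

*Generic utility.* Sequence-length comparison (percent difference of
means), Hellinger distance of the pooled event-type distribution,
per-attribute Hellinger distances computed only over events whose label
makes the attribute relevant (so missing codes never contaminate the
comparison), and row-wise Hellinger comparison of empirical k-th order
transition matrices (windows never cross individuals; contexts observed in
only one dataset score the maximal distance 1 by default, switchable to
skipping, since absent transition structure is a real difference). The
Hellinger distance is computed in its `(1/sqrt 2) * ||sqrt(p) - sqrt(q)||`
form, which is exactly zero on identical inputs. A multivariate Hellinger
distance `sqrt(1 - exp(-BD))` is derived from the Gaussian Bhattacharyya
distance of the numeric-encoded patient-level tables (categorical columns
as integer codes, continuous columns as bin midpoints; covariances
regularized by `1e-6 * trace/d` on the diagonal). The random-cohort
assessment generates seeded, reproducible SELECT-style queries — up to
three conjunctive predicates drawn from values observed in the real data,
then a count, a mean, or a group-by — executed with base-R relational
operations against both patient-level tables and logged as SQL-like text;
grouped results are compared by Hellinger distance, scalar aggregates by
the normalized Euclidean distance `|a - b| / sqrt(a^2 + b^2)` (defined as
0 when both sides are 0, and 1 when exactly one side returns an empty
result).

*Workload-aware operators.* Standardized mean differences with the pooled
denominator (`|m2 - m1| / sqrt((s1^2 + s2^2)/2)`; proportions analogously)
and the confidence-interval overlap (mean fraction of each interval
covered by the intersection). These are intentionally plain closed forms:
the package does not fit survival models itself — it compares externally
estimated summaries, with the conventional 0.1 SMD flag for potentially
important imbalance.

*Privacy.* Attribution-disclosure risk over quasi-identifier equivalence
classes (default QIs: age banded to 5 years, sex, and derived death /
hospitalization presence indicators). Each attacking record that matches a
class in the target dataset contributes `1/class size` times a "learns
something new" indicator — by default, whether the class-majority value of
a sensitive attribute equals the attacker's own value; an always-learn
variant gives the maximum-risk bound. The risk is the mean contribution
over attackers, both attack directions are reported, and the larger risk
is compared with the conventional 0.09 threshold (the minimal-group-size-11
criterion). The estimator follows the matching + learning structure of
attribution-disclosure assessment as a documented interpretation;
alternative learn indicators from the disclosure-control literature can
be plugged in through the configuration.

## Numerical and design choices

* **Tie-breaking in harmonization**: same-day events are ordered by the
  schema's declared table priority, then source row order — determinism
  over any claim about true intra-day ordering.
* **Patient identifiers** in all outputs are regenerated sequential
  integers; input identifiers are never copied through.
* **Degenerate inputs**: empty event tables yield a valid zero-event
  cohort; a constant response or constant predictors in the tree
  synthesizer fall back to marginal sampling (logged); a zero-width
  confidence interval contributes 1 to its overlap term if its point lies
  in the other interval, else 0; both-SD-zero SMDs are 0 when means agree
  and flagged infinite otherwise.
* **Reproducibility**: one seed governs a pipeline run, with per-stage
  child seeds derived from it; simulation, tree synthesis, training,
  generation and query fuzzing are all bit-reproducible given the seed
  (single-threaded BLAS assumed for training). No artifact contains a
  timestamp, so identical config + seed give byte-identical outputs.

## Problem sizes used in the shipped experiments

The recovery experiment the test suite runs — and the scale at which the
package's claims are verified — uses 2000 simulated individuals, 4 event
labels, 2 event attributes, 2 baseline strata, maximum sequence length 60,
a hidden size of 32 and 60 training epochs. At this scale the generated
cohort's per-stratum first-order transition matrices sit within a few
hundredths (mean row-wise Hellinger distance) of the ground-truth kernels,
against a between-independent-simulations baseline of about 0.01, and the
mean generated sequence length matches the real cohort within a few
percent. Larger cohorts tighten both margins; the architecture has no
intrinsic dependence on these sizes.

## Known limitations

* First-order recovery is the design target of the shipped experiments;
  second-order structure is measured but inherits the generic softening of
  longer-range dependencies typical of windowed recurrent training.
* Continuous values are only as fine as their quantile bins; decoded
  values are bin representatives, not the original reals.
* The privacy estimator is structural, not adversarially optimized; a
  determined attack with auxiliary information is out of scope.
* Training is desk-scale CPU code. It is deliberately dependency-free,
  not performance-tuned; a GPU framework would be the right tool for
  cohorts orders of magnitude larger.
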
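---
title: "A simulated child avatar for investigative-interview training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A simulated child avatar for investigative-interview training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interviewsim)
```

## The problem

Interviewing a child witness well is hard, and practising on real children
is neither ethical nor scalable. Decades of research on child testimony
converge on a simple prescription: open, non-suggestive prompts (invitations,
facilitators, directives, clarifications) draw on recall memory and yield
accurate accounts, while closed, suggestive, repeated or developmentally
inappropriate questions draw on recognition memory and can implant incorrect
details. `interviewsim` implements a complete training simulator around that
prescription: a classifier that codes each interviewer question into the
eleven-type taxonomy used in this literature, a probabilistic child avatar
that rewards good questioning with accurate details and punishes poor
questioning with incorrect ones, automated feedback and modeling
interventions, and the agreement statistics used to audit the coding.

Everything here runs on synthetic data generated by the package itself;
no interview recordings or case material are included or required.

## Question coding: a hybrid classifier

### Statistical core

Questions are featurised as N-gram frequency counts. The default
configuration extracts character N-grams for every N from 1 to 5 — the
appropriate unit for languages without whitespace word boundaries, and a
serviceable one for English; `unit = "word"` is available as well. The
counts feed a gradient-boosted tree ensemble (via `xgboost`) with a softmax
objective over the taxonomy classes; prediction is the argmax of the
per-class probabilities with ties broken toward the lowest taxonomy code,
so results are reproducible to the byte.

The reference hyperparameters are 200 estimators, maximum depth 3, minimum
child weight 100, row and column subsampling 0.9, L1/L2 regularisation
0.05, and learning rate 0.01. These suit corpora of several thousand
questions. Minimum child weight in particular is a *per-leaf evidence*
requirement: on a corpus of a few hundred questions a leaf can never
accumulate 100 weight, trees degenerate to stumps and accuracy collapses to
chance. `tune_and_train()` therefore runs 5-fold cross-validation over a
small declared grid (depth 3 or 5; minimum child weight 10 or 100; joint
row/column subsampling 0.8 or 0.9; learning rate is never tuned) and takes
the best cell, preferring the reference values on ties. On the default
synthetic corpus CV rejects the 100 leaf weight and held-out accuracy rises
from roughly 15% to roughly 95%. With `cv = FALSE` the reference values are
used as-is.

### Class imbalance

Real question corpora are heavily imbalanced — invitations dominate,
multiple-choice questions are rare. The training pipeline rebalances the
80% training portion (stratified split; the 20% test portion is never
touched) with SMOTE followed by Tomek-link removal, both implemented in the
package: synthetic minority items are convex combinations of a minority
item and one of its five nearest same-class neighbours (Euclidean distance
in feature space; `k_neighbors` is configurable), and cross-class mutual
nearest-neighbour pairs are then deleted from both sides to clean the class
boundary. Rebalancing never removes a class entirely, and the imbalance
ratio never increases.

### The rule layer

Four deterministic rules wrap the model, in strict precedence:

1. **Greeting rule.** Rapport utterances ("Hello", "How old are you") match
   an if-then pattern list, bypass the model entirely, and carry the
   pseudo-label `greeting`. They are not one of the eleven types and are
   excluded from outcome counts and agreement statistics.
2. **Repetition rule.** A question is a repetition iff the Jaccard
   coefficient between its N-gram key set and that of the *immediately
   preceding* question (never the whole history) reaches a threshold.
   Jaccard ignores frequencies and ignores N-grams absent from both
   questions — the right behaviour for sparse question data. The default
   threshold is 0.5; `tune_jaccard_threshold()` sweeps candidates against
   labeled pairs when calibration data exist. Two empty feature sets have
   similarity 0 by convention, so two empty utterances are never declared
   repetitions. Repetition precedes the model because a repeated suggestive
   question is still a repetition — the taxonomy codes it as its own type.
3. **Suggestive-keyword override.** "Tell me about someone hurting you"
   *looks* like a focused invitation, but presumes an experience the child
   has not disclosed; it is re-coded `unspecific_suggestive`. Each keyword
   in the lexicon may name the topic whose prior disclosure by the avatar
   suppresses the override (once the child has talked about being hurt, the
   same wording is a legitimate invitation); keywords without a topic always
   trigger it. The override never changes an already not-recommended label.
4. **Topic tagging.** Recommended questions are tagged with every topic
   (e.g. `dad`) whose trigger strings occur in the text, in configuration
   order; tags key the avatar's prepared response lists. Not-recommended
   questions are never tagged — the avatar does not volunteer content in
   response to poor questions.

## The child avatar

Each of the 16 avatars crosses age (4/6), gender, and abuse status — eight
patterns, two avatars each, with one 4-year-old non-abused boy and one
6-year-old abused girl reserved as the modeling examples, leaving 14 for
interviews.

The memory model is deliberately simple and fully inspectable:

* **Nine relevant details** in fixed order, each emitted at most once; the
  last four are *conclusive* — jointly sufficient to judge the case
  correctly — for abused and non-abused avatars alike, so both case types
  are equally hard to conclude.
* **Elicitation probabilities.** A recommended question triggers a single
  categorical draw: relevant detail with probability `p_elicit`, neutral
  detail with `p_elicit`, otherwise nothing, where `p_elicit` is 0.20 for
  4-year-olds and 0.25 for 6-year-olds, reflecting the lower
  informativeness of younger children's responses. One draw per question
  (rather than independent relevant/neutral draws) because exactly one
  avatar answer is played per question; this is a documented
  interpretation choice. When the nine details are exhausted the relevant
  bin falls through to neutral.
* **Neutral details** come from per-topic ordered response lists; the
  lowest-numbered unplayed response among the question's tagged topics is
  played. Untagged questions and exhausted lists fall back to generic
  filler, which records no detail.
* **Incorrect details** can be created *only* by not-recommended questions:
  with probability 0.25 per question (uniform across the six types,
  configurable per type) the avatar asserts something contradicting its
  scripted memory — "Yes." to a closed or suggestive question. The 0.25
  default is a round value chosen so that a typical unskilled first
  interview of about twenty not-recommended questions creates around five
  incorrect details, the order of magnitude reported in avatar-training
  studies; it is a package default, not an estimated quantity.
* **Repetition and the yes-flip.** Re-asking the immediately preceding
  question flips the answer to "Yes" with probability 0.30 (configurable),
  at most once per question wording. A flipped "Yes" is logged as an
  incorrect detail unless the avatar is abused and the question contains a
  suggestive keyword, in which case the "Yes" happens to be consistent
  with its scripted memory. This truth-semantics shortcut is the crudest
  part of the model and is documented as such.

Because states reset between Monte-Carlo trials, the empirical
relevant-detail rate over repeated recommended-question events converges to
`p_elicit`; `estimate_elicitation_rate()` performs exactly this experiment
and is what `scripts/acceptance.R` reports.

## Sessions, outcomes, interventions

`run_interview()` plays a scripted question list against one avatar,
classifying each question in context and advancing the dialogue state; live
sessions use the protocol's 10-minute wall clock, scripted runs use a turn
cap so results are exactly reproducible. Five outcome measures summarise an
interview: counts of recommended and not-recommended questions (repetitions
count as not recommended; greetings count as nothing), the percentage of
recommended questions among the two, and the counts of relevant and
incorrect details.

`generate_feedback()` reproduces the between-interview feedback: the true
case outcome plus comments on two recommended and two not-recommended
questions sampled uniformly without replacement from the transcript
(shortfalls are noted when a category has fewer than two). Comment wording
is template text keyed by question type. `default_modeling_package()`
builds the observational-learning alternative: learning points followed by
four example interviews — good and bad, abused and non-abused — each
wrapped in its scenario and outcome, delivered as annotated text
transcripts.

## Evaluation

`cohens_kappa()` computes percent agreement and Cohen's κ between two
coders, with expected agreement from the marginal products and a
large-sample confidence interval in the Fleiss–Cohen–Everitt form (the
classical asymptotic variance; a package choice, since several CI
conventions coexist). Category-level agreement is available by collapsing
both sequences to recommended/not-recommended; coarsening can merge
discordant types into a concordant category but never the reverse, so
category-level percent agreement is always at least the type-level figure.
Chance agreement is reported as the marginal-based expectation rather than
any fixed nominal level. κ is undefined, and reported as such, when both
coders used one single shared label.

`batch_correlations()` computes the Pearson correlations between the
question-count and detail-count variables over a batch of interviews. By
construction of the response engine, more recommended questioning yields
more relevant details and more not-recommended questioning yields more
incorrect details, so batches simulated with `simulate_batch()` reproduce
the positive sign structure on both diagonals; the magnitudes depend on
interviewer behaviour and are not a claim about human data.

## The synthetic corpus

`generate_corpus()` builds labeled corpora from per-class template banks
(five or more templates per class, patterned on canonical examples of each
question type) with shared slot lexicons for names, places and activities —
shared precisely so that no slot token trivially identifies a class.
Suggestive items always contain a keyword from the suggestive lexicon,
which the rule layer shares. Repetition-labeled items are emitted
immediately after a host row from another class and duplicate it (verbatim
with probability `repetition_pair_fraction = 0.8` by default, otherwise
with one slot word swapped), giving the corpus genuine consecutive
near-duplicate pairs. The default class counts decay geometrically,
`round(150 * 0.85^(0:10))` over the eleven classes in taxonomy order
(834 questions, imbalance ratio 5), so the resampling path is exercised on
every default run; the profile is an arbitrary but fixed choice, since the
class distribution of real coded corpora varies by study. A `cjk_char` mode
collapses all whitespace, exercising the character-unit pathway used for
languages written without word boundaries.

What the generator does *not* emulate: natural paraphrase variation,
coder disagreement and label noise, vocabulary drift between training and
deployment, or any specific language's morphology. A classifier that is
95% accurate on this corpus is demonstrably *learning the mapping*, not
demonstrating field-ready accuracy; published agreement with human coders
on real multi-thousand-question corpora is far lower, and nothing at this
scale can reproduce it.

## Numerical and design notes

* All stochastic entry points take a `seed` and restore the caller's RNG
  state; identical seeds give byte-identical corpora, splits, resampled
  sets, CV tables, interviews and feedback. The boosting engine runs
  single-threaded for exact reproducibility.
* Default problem sizes — 834-question corpora, 10,000-trial elicitation
  estimates, batches of 100–150 interviews of 20–25 questions — were chosen
  as the smallest sizes at which every statistical property of interest
  (above-chance classification, binomial CI coverage of the elicitation
  rates, stable correlation signs) is decisively measurable.
* Degenerate inputs fail loudly and early: empty utterances, corpora with a
  class of fewer than two items (stratification) or fewer than
  `k_neighbors + 1` items (SMOTE), transcripts with no turns, mismatched
  label-sequence lengths, and incomplete 2×2 modeling designs all raise
  errors that name the offending input.
* Known limitations: repetition detection is lexical (Jaccard on N-grams;
  paraphrased repetitions pass), the suggestive lexicon is a small seed
  list rather than a learned resource, avatar utterances are template text
  with no generation, and the yes-flip contradiction check is a heuristic.
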
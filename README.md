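# interviewsim

Training simulator for investigative interviews of child witnesses.

Practising child forensic interviews on real children is neither ethical
nor scalable, yet interviewer skill — asking open, non-suggestive questions
instead of closed, leading ones — is the single strongest lever on the
accuracy of a child's account. `interviewsim` provides a complete
simulated-interview training loop for researchers and trainers in forensic
and developmental psychology:

* **Question coding.** Every interviewer utterance is coded into the
  eleven-type taxonomy of the child-interviewing literature (invitations,
  facilitators, directives, clarifications vs. option-posing, suggestive,
  repeated, inappropriate and multiple-choice questions), partitioned into
  5 *recommended* and 6 *not-recommended* types. The classifier is hybrid:
  character/word N-gram features (N = 1–5) feed a gradient-boosted tree
  ensemble, wrapped in deterministic rules — an if-then greeting rule, a
  repetition rule (Jaccard similarity ≥ threshold against the immediately
  preceding question), a suggestive-keyword override, and topic tagging.
* **A probabilistic child avatar.** Sixteen avatars (age 4/6 × gender ×
  abused/non-abused, two each) hold nine ordered relevant details in
  memory, the last four conclusive. A recommended question elicits a
  relevant detail with probability *p* = 0.20 (age 4) or 0.25 (age 6) and a
  neutral detail with the same probability; not-recommended questions can
  only create *incorrect* details, and re-asking the previous question may
  flip a truthful answer to "Yes".
* **Interventions and evaluation.** Automated feedback (case outcome plus
  two praised and two critiqued questions sampled from the transcript), a
  four-example good/bad × abused/non-abused modeling package, percent
  agreement and Cohen's κ with an asymptotic confidence interval, and
  outcome correlations over simulated interview batches.
* **Synthetic corpora.** A template-based generator produces labeled,
  class-imbalanced question corpora (with consecutive near-duplicate
  repetition pairs and keyword-bearing suggestive items), so the whole
  pipeline trains and tests with no sensitive data. Training rebalances
  classes with SMOTE + Tomek-link removal and tunes hyperparameters by
  5-fold cross-validation.

## Worked example

```r
library(interviewsim)

# 1. a labeled synthetic corpus and a trained classifier
corpus <- generate_corpus(default_corpus_spec(), seed = 7)
model  <- tune_and_train(corpus, seed = 7)
model
#> Question-type classifier (gradient-boosted trees)
#>   classes: 11  vocabulary: 3069 N-grams
#>   trained on 667 questions; held-out accuracy 95.2% (n = 167)
```

The corpus is 834 questions with class counts decaying geometrically
(ratio 5), so cross-validation and SMOTE + Tomek rebalancing both do real
work; held-out accuracy far above the 1/11 ≈ 9% chance level shows the
N-gram/boosting pipeline learns the type mapping.

```r
# 2. an interview against a six-year-old abused avatar
roster  <- build_roster()
profile <- subset(roster, age == 6 & abused & !reserved_for_modeling)[1, ]
pack    <- build_scenario_pack(profile, seed = 2)
questions <- c(
  "Hello",
  "Tell me everything that happened from the beginning to the end",
  "Tell me everything that happened from the beginning to the end",
  "Tell me about your dad",
  "Did your dad do something bad to you?",
  "Go ahead")
tr <- run_interview(questions, model, pack,
                    config = session_config(max_turns = 10, seed = 5))
for (t in tr$turns)
  cat(sprintf("%d. %-62s -> %s\n", t$index + 1, t$question_text,
              t$classified$qtype))
#> 1. Hello                                                          -> greeting
#> 2. Tell me everything that happened from the beginning to the end -> invitation_broad
#> 3. Tell me everything that happened from the beginning to the end -> repetition
#> 4. Tell me about your dad                                         -> invitation_focus
#> 5. Did your dad do something bad to you?                          -> specific_suggestive
#> 6. Go ahead                                                       -> facilitator
summarize_interview(tr)
#>   n_recommended n_not_recommended prop_recommended n_relevant n_incorrect
#> 1             3                 2               60          0           1
```

The greeting bypasses the model and counts toward nothing; the immediate
re-ask is coded `repetition` (a not-recommended type); the suggestive
question created one incorrect detail. `generate_feedback(tr, pack, seed = 3)`
then renders the case outcome and 2 + 2 sampled question comments.

```r
# 3. the avatar's elicitation rate, recovered by Monte-Carlo
estimate_elicitation_rate(pack, n_trials = 10000, seed = 1)$percent
#> [1] 24.71
```

10,000 reset-state recommended-question trials recover the age-6 rate of
25% within binomial noise (age-4 avatars recover 20%).

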
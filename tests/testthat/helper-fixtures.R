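# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small imbalanced corpus: same shape as the default spec, scaled down.
fixture_corpus_spec <- function() {
  labels <- question_types()$label
  counts <- stats::setNames(as.integer(round(60 * 0.85^(0:10))), labels)
  corpus_spec(per_class_counts = counts)
}

fixture_corpus <- function() {
  memo("corpus", generate_corpus(fixture_corpus_spec(), seed = 7))
}

# The full default training pipeline (CV tuning included) on the default
# synthetic corpus; trained once per test run.
acceptance_model <- function() {
  memo("acceptance_model",
       tune_and_train(generate_corpus(default_corpus_spec(), seed = 7),
                      seed = 7))
}

# A quick, accurate model for rule/session tests: production settings except
# a leaf weight suited to a few hundred rows; no CV pass.
fixture_model <- function() {
  memo("model", suppressWarnings(
    tune_and_train(fixture_corpus(),
                   booster_config(min_child_weight = 5),
                   seed = 7, cv = FALSE)
  ))
}

fixture_pack <- function(age = 6L, abused = TRUE, seed = 2L, ...) {
  roster <- build_roster()
  prof <- roster[roster$age == age & roster$abused == abused &
                   !roster$reserved_for_modeling, ][1L, ]
  build_scenario_pack(prof, seed = seed, ...)
}

# Minimal hand-built transcript for summary/feedback tests (no model).
fake_turn <- function(i, text, qtype, kind = "none", rtext = "...") {
  category <- if (qtype == GREETING_LABEL) NA_character_ else
    category_of(qtype)
  list(index = i, question_text = text,
       classified = interviewsim:::new_classified(
         text, c(x = 1L), qtype, category, character(0), "model"),
       response = structure(list(text = rtext, detail_kind = kind,
                                 conclusive = FALSE, topic = character(0)),
                            class = "avatar_response"))
}

fake_transcript <- function(turns) {
  structure(list(avatar_id = "avatar_03", seed = 1L, truncated = FALSE,
                 n_questions_offered = length(turns), turns = turns,
                 judgments = list(pre = NULL, post = NULL),
                 final_state = NULL),
            class = "interview_transcript")
}
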
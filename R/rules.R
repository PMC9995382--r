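#' Rule-layer configuration
#'
#' The deterministic rules wrapped around the statistical classifier:
#' greeting patterns handled by an if-then rule, a suggestive-keyword
#' lexicon that can override a recommended-looking prediction, topic
#' keywords that key the avatar's prepared response lists, and the Jaccard
#' threshold for repetition detection between consecutive questions.
#'
#' Each suggestive keyword may name the topic whose prior disclosure by the
#' avatar suppresses the override ("tell me about someone hurting you" is
#' suggestive only while the child has said nothing about being hurt);
#' keywords with an `NA` topic always trigger the override.
#'
#' @param greetings Character vector of regular expressions matched against
#'   the normalised utterance.
#' @param suggestive_keywords Data frame with columns `keyword` and `topic`
#'   (`NA` topic = unconditional).
#' @param topics Named list: topic id -> character vector of trigger strings.
#' @param jaccard_threshold Repetition threshold in (0, 1].
#' @return An object of class `rule_config`.
#' @export
rule_config <- function(greetings = default_greetings(),
                        suggestive_keywords = default_suggestive_keywords(),
                        topics = default_topics(),
                        jaccard_threshold = 0.5) {
  stopifnot(jaccard_threshold > 0, jaccard_threshold <= 1,
            is.data.frame(suggestive_keywords),
            all(c("keyword", "topic") %in% names(suggestive_keywords)))
  if (anyDuplicated(names(topics)))
    stop("topic ids must be unique", call. = FALSE)
  structure(
    list(greetings = greetings, suggestive_keywords = suggestive_keywords,
         topics = topics, jaccard_threshold = jaccard_threshold),
    class = "rule_config"
  )
}

#' @rdname rule_config
#' @export
default_greetings <- function() {
  c("^hello\\b", "^hi\\b", "^good (morning|afternoon)\\b",
    "^how old are you\\b", "^what is your name\\b", "^nice to meet you\\b",
    "^my name is\\b")
}

#' @rdname rule_config
#' @export
default_suggestive_keywords <- function() {
  data.frame(
    keyword = c("hurt", "hurting", "bad", "scary", "scared",
                "secret", "touch", "touched", "abuse",
                "something happened", "something to talk about"),
    topic = c("hurt", "hurt", "hurt", "hurt", "hurt",
              "hurt", "hurt", "hurt", "hurt",
              NA, NA),
    stringsAsFactors = FALSE
  )
}

#' @rdname rule_config
#' @export
default_topics <- function() {
  list(
    dad = c("dad", "daddy", "father"),
    mom = c("mom", "mommy", "mother"),
    school = c("school", "kindergarten", "teacher"),
    friends = c("friend", "friends", "kanta", "miura"),
    play = c("play", "game", "football", "tag"),
    hurt = c("hurt", "hurting", "pain", "scary", "scared", "secret",
             "touch", "touched")
  )
}

#' Dialogue context carried across turns
#'
#' Mutable interview state the rule layer needs: which topics the avatar has
#' already produced content about, the N-gram features of the immediately
#' preceding question (repetition looks back exactly one turn, never
#' further), and the turn counter.
#'
#' @return An object of class `dialogue_context`.
#' @export
dialogue_context <- function() {
  structure(
    list(mentioned_topics = character(0),
         previous_question_features = NULL,
         turn_index = 0L),
    class = "dialogue_context"
  )
}

#' Advance the dialogue context after a turn
#'
#' Caches the question's features for next-turn repetition detection, bumps
#' the turn counter, and records topics the avatar has now produced content
#' about (topic responses played, and the `hurt` topic once any
#' case-relevant detail has been disclosed, since the relevant details are
#' about the alleged experience).
#'
#' @param context A [dialogue_context()].
#' @param classified The turn's `classified_question`.
#' @param response The avatar's response for the turn (optional).
#' @return The updated context.
#' @export
advance_context <- function(context, classified, response = NULL) {
  context$previous_question_features <- classified$features
  context$turn_index <- context$turn_index + 1L
  if (!is.null(response)) {
    if (identical(response$detail_kind, "neutral") &&
        length(response$topic)) {
      context$mentioned_topics <-
        union(context$mentioned_topics, response$topic)
    }
    if (identical(response$detail_kind, "relevant")) {
      context$mentioned_topics <- union(context$mentioned_topics, "hurt")
    }
  }
  context
}

#' Greeting rule
#'
#' True iff the normalised utterance matches any configured greeting
#' pattern. Greetings bypass the statistical model entirely.
#'
#' @param text Utterance.
#' @param cfg A [rule_config()].
#' @return Logical scalar.
#' @export
match_greeting <- function(text, cfg = rule_config()) {
  if (length(cfg$greetings) == 0L) return(FALSE)
  x <- normalize_utterance(text, featurizer_config())
  any(vapply(cfg$greetings, function(p) grepl(p, x), logical(1)))
}

#' Repetition rule
#'
#' A question is a repetition iff the Jaccard similarity between its N-gram
#' key set and that of the immediately preceding question reaches the
#' configured threshold. The first question of an interview is never a
#' repetition. Frequencies are ignored (presence-only similarity).
#'
#' @param current Feature vector of the current question
#'   ([extract_ngrams()]).
#' @param context A [dialogue_context()].
#' @param cfg A [rule_config()].
#' @return Logical scalar.
#' @export
detect_repetition <- function(current, context, cfg = rule_config()) {
  prev <- context$previous_question_features
  if (is.null(prev)) return(FALSE)
  jaccard(current, prev) >= cfg$jaccard_threshold
}

#' Suggestive-keyword override
#'
#' A question that the model takes for a recommended type but that contains
#' a suggestive keyword whose topic the avatar has not yet disclosed is
#' re-coded `unspecific_suggestive`: "tell me about someone hurting you"
#' assumes an experience the child never mentioned. Once the avatar has
#' disclosed the linked topic, the same wording keeps its model label.
#' Not-recommended model labels are never changed.
#'
#' @param text Utterance.
#' @param model_qtype Label from [predict_type()].
#' @param context A [dialogue_context()].
#' @param cfg A [rule_config()].
#' @return A taxonomy label.
#' @export
suggestive_override <- function(text, model_qtype, context,
                                cfg = rule_config()) {
  if (category_of(model_qtype) != "recommended") return(model_qtype)
  x <- normalize_utterance(text, featurizer_config())
  kw <- cfg$suggestive_keywords
  for (i in seq_len(nrow(kw))) {
    if (grepl(paste0("\\b", kw$keyword[i], "\\b"), x)) {
      topic <- kw$topic[i]
      if (is.na(topic) || !(topic %in% context$mentioned_topics))
        return("unspecific_suggestive")
    }
  }
  model_qtype
}

#' Topic tagging
#'
#' Tags a *recommended* question with every topic whose trigger strings
#' occur in the normalised text, in configuration order; the avatar uses
#' the tags to pick a contextually fitting prepared response.
#' Not-recommended questions are never tagged.
#'
#' @param text Utterance.
#' @param qtype Taxonomy label (or the greeting pseudo-label).
#' @param cfg A [rule_config()].
#' @return Character vector of topic ids (possibly empty).
#' @export
tag_topics <- function(text, qtype, cfg = rule_config()) {
  if (qtype == GREETING_LABEL || category_of(qtype) != "recommended")
    return(character(0))
  x <- normalize_utterance(text, featurizer_config())
  hit <- vapply(cfg$topics, function(triggers) {
    any(vapply(triggers,
               function(tr) grepl(paste0("\\b", tr, "\\b"), x),
               logical(1)))
  }, logical(1))
  names(cfg$topics)[hit]
}

#' Classify a question in conversational context
#'
#' The full hybrid pathway, in strict precedence order: (1) greeting
#' if-then rule; (2) repetition rule (Jaccard against the immediately
#' preceding question) — a repeated suggestive question is still coded
#' `repetition`; (3) statistical model prediction; (4) suggestive-keyword
#' override; (5) topic tagging. Exactly one source is recorded. The
#' function is pure: the caller advances the context with
#' [advance_context()].
#'
#' @param text Utterance.
#' @param context A [dialogue_context()].
#' @param model An `interview_model`.
#' @param cfg A [rule_config()].
#' @return An object of class `classified_question`: `text`, `features`,
#'   `qtype`, `category` (`NA` for greetings), `topics`, `source` (one of
#'   `greeting_rule`, `repetition_rule`, `model`, `suggestive_override`),
#'   `scores` (model pathway only).
#' @export
classify_question <- function(text, context, model, cfg = rule_config()) {
  features <- extract_ngrams(text, model$featurizer_cfg)
  if (match_greeting(text, cfg)) {
    return(new_classified(text, features, GREETING_LABEL, NA_character_,
                          character(0), "greeting_rule"))
  }
  if (detect_repetition(features, context, cfg)) {
    return(new_classified(text, features, "repetition", "not_recommended",
                          character(0), "repetition_rule"))
  }
  pred <- predict_type(model, text)
  qtype <- suggestive_override(text, pred$qtype, context, cfg)
  source <- if (qtype != pred$qtype) "suggestive_override" else "model"
  topics <- tag_topics(text, qtype, cfg)
  new_classified(text, features, qtype, category_of(qtype), topics, source,
                 scores = pred$scores)
}

new_classified <- function(text, features, qtype, category, topics, source,
                           scores = NULL) {
  structure(
    list(text = text, features = features, qtype = qtype,
         category = category, topics = topics, source = source,
         scores = scores),
    class = "classified_question"
  )
}

#' @export
print.classified_question <- function(x, ...) {
  cat(sprintf("\"%s\"\n  -> %s (%s; source: %s)\n", x$text, x$qtype,
              ifelse(is.na(x$category), "rapport", x$category), x$source))
  if (length(x$topics)) cat("  topics:", paste(x$topics, collapse = ", "), "\n")
  invisible(x)
}

#' Tune the repetition threshold on labeled pairs
#'
#' Sweeps candidate Jaccard thresholds against consecutive question pairs
#' labeled as repetitions or not, and returns the threshold maximising
#' classification accuracy (ties: the largest, i.e. most conservative,
#' threshold).
#'
#' @param pairs Data frame with columns `first`, `second` (texts) and
#'   `is_repetition` (logical).
#' @param cfg A [featurizer_config()] for N-gram extraction.
#' @param grid Candidate thresholds.
#' @return List with `threshold` and the sweep data frame.
#' @export
tune_jaccard_threshold <- function(pairs, cfg = featurizer_config(),
                                   grid = seq(0.05, 1, by = 0.05)) {
  stopifnot(all(c("first", "second", "is_repetition") %in% names(pairs)))
  sims <- mapply(function(a, b) {
    jaccard(extract_ngrams(a, cfg), extract_ngrams(b, cfg))
  }, pairs$first, pairs$second)
  acc <- vapply(grid, function(th) {
    mean((sims >= th) == pairs$is_repetition)
  }, numeric(1))
  best <- max(grid[acc == max(acc)])
  list(threshold = best,
       sweep = data.frame(threshold = grid, accuracy = acc))
}
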
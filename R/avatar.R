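#' Build the avatar roster
#'
#' Sixteen child avatars, two for each of the eight feature patterns formed
#' by crossing age (4 or 6 years), gender (girl or boy) and abuse status.
#' Two avatars — a 4-year-old non-abused boy and a 6-year-old abused girl —
#' are reserved as the good/bad example cases of the modeling intervention
#' and are not used in simulated interviews, leaving 14 available.
#'
#' The per-question probability that a recommended question elicits a
#' relevant or a neutral detail is tied to age: 20% each for 4-year-olds,
#' 25% each for 6-year-olds, reflecting the lower informativeness of
#' younger children's answers to open prompts.
#'
#' @param seed Integer seed (kept for interface symmetry; roster composition
#'   is fixed by design).
#' @return Data frame with one row per avatar: `avatar_id`, `age`, `gender`,
#'   `abused`, `reserved_for_modeling`, `p_elicit`.
#' @export
build_roster <- function(seed = 1L) {
  patterns <- expand.grid(age = c(4L, 6L), gender = c("girl", "boy"),
                          abused = c(TRUE, FALSE),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  roster <- patterns[rep(seq_len(nrow(patterns)), each = 2L), ]
  roster$avatar_id <- sprintf("avatar_%02d", seq_len(nrow(roster)))
  roster$p_elicit <- ifelse(roster$age == 4L, 0.20, 0.25)
  roster$reserved_for_modeling <- FALSE
  # first member of the two reserved patterns
  res_boy  <- which(roster$age == 4L & roster$gender == "boy" &
                      !roster$abused)[1L]
  res_girl <- which(roster$age == 6L & roster$gender == "girl" &
                      roster$abused)[1L]
  roster$reserved_for_modeling[c(res_boy, res_girl)] <- TRUE
  rownames(roster) <- NULL
  roster[, c("avatar_id", "age", "gender", "abused",
             "reserved_for_modeling", "p_elicit")]
}

relevant_detail_bank <- function(abused) {
  if (abused) {
    list(
      background = c(
        "We moved to the new house after my birthday.",
        "Mom works late on weekdays now.",
        "I sleep in my own room since spring.",
        "Uncle Joe started living with us.",
        "He picks me up from {school} sometimes.",
        "Mom was away the night it happened.",
        "He told me we would play a special game."
      ),
      conclusive = c(
        "He came into my room when everyone was asleep.",
        "He touched me under my pajamas.",
        "He said it was our secret and I must not tell mom.",
        "It hurt and I cried, and it happened more than once."
      )
    )
  } else {
    list(
      background = c(
        "I got a new bike for my birthday.",
        "Dad takes me to {school} every morning.",
        "We visited grandma at the seaside in summer.",
        "My little brother broke my toy truck.",
        "I fell off the climbing frame at the park.",
        "The neighbour's dog barks at night sometimes.",
        "Mom and dad argued about the car once."
      ),
      conclusive = c(
        "The bruise on my leg is from falling off my bike.",
        "Nobody has ever touched me in a way I did not like.",
        "I made up the story because I was angry about the toy.",
        "Dad only helps me change for swimming class, mom knows."
      )
    )
  }
}

topic_response_bank <- function() {
  list(
    dad = c("Daddy is kind to me.", "Daddy never tells me fairytales.",
            "Sometimes daddy plays with me.", "Daddy cooks pancakes on Sunday."),
    mom = c("Mommy sings to me at bedtime.", "Mommy works at the hospital.",
            "Mommy gets cross when I am loud.", "I help mommy water the plants."),
    school = c("My teacher is called Miss Sato.", "We do drawing at school.",
               "I sit next to Kanta in class.", "We had a sports day at school."),
    friends = c("Kanta is my best friend.", "Miura has a big dog.",
                "We trade stickers at break.", "My friends came to my party."),
    play = c("I like playing tag the best.", "We play football in the garden.",
             "I am good at hide and seek.", "I got a puzzle with a dinosaur.")
  )
}

#' Build a scenario pack for an avatar
#'
#' A scenario pack is everything the response engine needs about one
#' avatar: the profile; an ordered memory of exactly nine relevant details
#' (the last four flagged conclusive — jointly sufficient to judge the case
#' correctly as abused or non-abused, so both case types are equally hard
#' to conclude); ordered topic response lists keyed by topic id; filler
#' and greeting lines; and the response probabilities. All detail text is
#' synthetic fixture material generated from small template banks.
#'
#' @param profile One row of [build_roster()] (data frame or list).
#' @param seed Integer seed controlling which background details are drawn.
#' @param yes_flip_probability Probability that re-asking the immediately
#'   preceding question flips the answer to "Yes".
#' @param incorrect_probability Per-question probability that a
#'   not-recommended question creates an incorrect detail; a single number
#'   or a named vector over the six not-recommended types.
#' @return An object of class `scenario_pack`.
#' @export
build_scenario_pack <- function(profile, seed = 1L,
                                yes_flip_probability = 0.30,
                                incorrect_probability = 0.25) {
  profile <- as.list(profile)
  stopifnot(profile$age %in% c(4L, 6L))
  nr_types <- question_types()$label[
    question_types()$category == "not_recommended"]
  if (length(incorrect_probability) == 1L) {
    incorrect_probability <- stats::setNames(
      rep(incorrect_probability, length(nr_types)), nr_types)
  }
  stopifnot(all(nr_types %in% names(incorrect_probability)))
  bank <- relevant_detail_bank(isTRUE(profile$abused))
  details <- with_seed(seed, {
    bg <- sample(bank$background, 5L)
    gsub("{school}", sample(c("school", "kindergarten"), 1L),
         c(bg, bank$conclusive), fixed = TRUE)
  })
  structure(
    list(
      profile = profile,
      relevant_details = details,
      conclusive = c(rep(FALSE, 5L), rep(TRUE, 4L)),
      topic_responses = topic_response_bank(),
      fillers = c("I don't remember.", "I don't know.", "Hmm.",
                  "I can't say."),
      greeting_replies = c("Hello.", "Hi.", "I'm okay."),
      confused_replies = c("I don't understand.", "That is too hard.",
                           "What do you mean?"),
      p_elicit = if (profile$age == 4L) 0.20 else 0.25,
      incorrect_probability = incorrect_probability[nr_types],
      yes_flip_probability = yes_flip_probability
    ),
    class = "scenario_pack"
  )
}

#' Write / read a scenario pack as YAML
#'
#' @param pack A `scenario_pack`.
#' @param path YAML file path.
#' @return `path` (write) or the restored `scenario_pack` (read).
#' @export
write_scenario_pack <- function(pack, path) {
  x <- unclass(pack)
  x$incorrect_probability <- as.list(x$incorrect_probability)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_scenario_pack
#' @export
read_scenario_pack <- function(path) {
  x <- yaml::read_yaml(path)
  x$incorrect_probability <- unlist(x$incorrect_probability)
  x$conclusive <- as.logical(x$conclusive)
  structure(x, class = "scenario_pack")
}

#' Fresh mutable avatar state for one interview
#'
#' Tracks the play pointer into the nine ordered relevant details, the
#' per-topic play pointers ("presentation order numbers"), the incorrect
#' details created so far, which question texts already triggered a
#' yes-flip, and the previous response.
#'
#' @param pack A `scenario_pack`.
#' @return An object of class `avatar_state`.
#' @export
new_avatar_state <- function(pack) {
  structure(
    list(next_relevant_index = 1L,
         topic_pointers = stats::setNames(
           rep(1L, length(pack$topic_responses)),
           names(pack$topic_responses)),
         incorrect_log = character(0),
         flipped_questions = character(0),
         emitted_relevant = character(0),
         last_response = NULL,
         filler_cursor = 0L),
    class = "avatar_state"
  )
}

#' Draw the answer kind for a classified question
#'
#' A single mutually exclusive categorical draw per question. For a
#' recommended question the avatar yields a relevant detail with
#' probability `p_elicit` (20% at age 4, 25% at age 6), a neutral detail
#' with the same probability, and otherwise nothing; once all nine relevant
#' details are exhausted the relevant bin falls through to neutral. A
#' not-recommended question yields an incorrect detail with the per-type
#' probability and otherwise nothing — it can never elicit relevant or
#' neutral details. Uses the current RNG stream; seed via callers.
#'
#' @param q A `classified_question`.
#' @param profile Avatar profile (row of [build_roster()] or
#'   `pack$profile`).
#' @param state An `avatar_state`.
#' @param pack The `scenario_pack` (for per-type incorrect probabilities).
#' @return One of `"relevant"`, `"neutral"`, `"incorrect"`, `"none"`.
#' @export
draw_answer_kind <- function(q, profile, state, pack) {
  u <- stats::runif(1L)
  if (identical(q$category, "recommended")) {
    p <- pack$p_elicit
    if (u < p) {
      if (state$next_relevant_index <= length(pack$relevant_details))
        return("relevant")
      return("neutral")
    }
    if (u < 2 * p) return("neutral")
    return("none")
  }
  p_inc <- pack$incorrect_probability[[q$qtype]]
  if (u < p_inc) "incorrect" else "none"
}

suggestive_hit <- function(text, rules) {
  x <- normalize_utterance(text, featurizer_config())
  any(vapply(rules$suggestive_keywords$keyword,
             function(k) grepl(paste0("\\b", k, "\\b"), x), logical(1)))
}

make_response <- function(text, detail_kind, conclusive = FALSE,
                          topic = character(0)) {
  structure(list(text = text, detail_kind = detail_kind,
                 conclusive = conclusive, topic = topic),
            class = "avatar_response")
}

#' Generate the avatar's answer to a classified question
#'
#' The answer-selection step: greetings get a scripted pleasantry;
#' re-asking the immediately preceding question (`repetition`) flips the
#' answer to "Yes" with probability `yes_flip_probability` — at most once
#' per question wording — which creates an incorrect detail whenever that
#' "Yes" contradicts the avatar's scripted memory; otherwise the previous
#' non-answer is repeated. For all other types one answer kind is drawn
#' ([draw_answer_kind()]): a relevant detail is the next item of the fixed
#' nine-detail order; a neutral detail is the lowest-numbered unplayed
#' response among the question's tagged topics (generic filler when
#' untagged or exhausted, recorded as no detail); an incorrect detail is an
#' assertion contradicting the scripted memory ("Yes" to a closed or
#' suggestive question) and is appended to the incorrect log.
#'
#' @param q A `classified_question`.
#' @param profile Avatar profile.
#' @param state An `avatar_state`.
#' @param pack The `scenario_pack`.
#' @param rules A [rule_config()] (for memory-consistency checks of flipped
#'   answers).
#' @return List with `response` (an `avatar_response`) and `state` (the
#'   advanced `avatar_state`).
#' @export
respond <- function(q, profile, state, pack, rules = rule_config()) {
  finish <- function(resp) {
    state$last_response <- resp
    list(response = resp, state = state)
  }

  if (identical(q$qtype, GREETING_LABEL)) {
    i <- stats::runif(1L)  # keep stream usage uniform per turn
    txt <- pack$greeting_replies[1L + floor(i * length(pack$greeting_replies))]
    return(finish(make_response(txt, "none")))
  }

  if (identical(q$qtype, "repetition")) {
    key <- normalize_utterance(q$text, featurizer_config())
    u <- stats::runif(1L)
    if (!(key %in% state$flipped_questions) &&
        u < pack$yes_flip_probability) {
      state$flipped_questions <- c(state$flipped_questions, key)
      contradicts <- !(isTRUE(pack$profile$abused) &&
                         suggestive_hit(q$text, rules))
      if (contradicts) {
        state$incorrect_log <- c(state$incorrect_log,
                                 paste0("yes-flip: ", q$text))
        return(finish(make_response("Yes.", "incorrect")))
      }
      return(finish(make_response("Yes.", "none")))
    }
    prev <- state$last_response
    txt <- if (!is.null(prev) && identical(prev$detail_kind, "none"))
      prev$text else pack$fillers[1L]
    return(finish(make_response(txt, "none")))
  }

  kind <- draw_answer_kind(q, profile, state, pack)

  if (kind == "relevant") {
    i <- state$next_relevant_index
    txt <- pack$relevant_details[i]
    state$next_relevant_index <- i + 1L
    state$emitted_relevant <- c(state$emitted_relevant, txt)
    return(finish(make_response(txt, "relevant",
                                conclusive = pack$conclusive[i])))
  }

  if (kind == "neutral") {
    # lowest presentation-order number among the question's tagged topics
    avail <- q$topics[vapply(q$topics, function(tp) {
      !is.null(pack$topic_responses[[tp]]) &&
        state$topic_pointers[[tp]] <= length(pack$topic_responses[[tp]])
    }, logical(1))]
    if (length(avail)) {
      ptrs <- state$topic_pointers[avail]
      tp <- avail[which.min(ptrs)]
      i <- state$topic_pointers[[tp]]
      txt <- pack$topic_responses[[tp]][i]
      state$topic_pointers[[tp]] <- i + 1L
      return(finish(make_response(txt, "neutral", topic = tp)))
    }
    kind <- "none"  # untagged or exhausted: generic filler, no detail
  }

  if (kind == "incorrect") {
    closed <- c("option_posing", "specific_suggestive",
                "unspecific_suggestive", "multiple_choice")
    txt <- if (q$qtype %in% closed) "Yes." else
      pack$confused_replies[1L + (length(state$incorrect_log) %%
                                    length(pack$confused_replies))]
    state$incorrect_log <- c(state$incorrect_log,
                             paste0(q$qtype, ": ", q$text))
    return(finish(make_response(txt, "incorrect")))
  }

  state$filler_cursor <- state$filler_cursor + 1L
  txt <- pack$fillers[1L + (state$filler_cursor %% length(pack$fillers))]
  finish(make_response(txt, "none"))
}

#' Ground truth of an avatar's case
#'
#' The material for outcome feedback: whether abuse is present and the four
#' conclusive details that jointly support the correct conclusion.
#'
#' @param pack A `scenario_pack`.
#' @return List with `outcome` (`"present"` / `"absent"`) and
#'   `conclusive_details` (character vector of length 4).
#' @export
case_ground_truth <- function(pack) {
  list(outcome = if (isTRUE(pack$profile$abused)) "present" else "absent",
       conclusive_details = pack$relevant_details[pack$conclusive])
}

#' Monte-Carlo estimate of the relevant-detail elicitation rate
#'
#' Simulates `n_trials` independent recommended-question events, resetting
#' the avatar state before each, and reports the percentage that yielded a
#' relevant detail. With state reset the nine-detail memory never exhausts,
#' so the estimate converges to the age-linked `p_elicit` (20% at age 4,
#' 25% at age 6).
#'
#' @param pack A `scenario_pack`.
#' @param n_trials Number of simulated question events.
#' @param seed Integer seed.
#' @return List with `percent` (estimate on the 0-100 scale), `n_trials`,
#'   and `ci95` (95% binomial Wald interval, percent scale).
#' @export
estimate_elicitation_rate <- function(pack, n_trials = 10000L, seed = 1L) {
  q <- new_classified("Tell me everything that happened.",
                      c(dummy = 1L), "invitation_broad", "recommended",
                      character(0), "model")
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_trials), function(i) {
      st <- new_avatar_state(pack)
      out <- respond(q, pack$profile, st, pack)
      identical(out$response$detail_kind, "relevant")
    }, logical(1)))
  })
  phat <- hits / n_trials
  se <- sqrt(phat * (1 - phat) / n_trials)
  list(percent = 100 * phat, n_trials = n_trials,
       ci95 = 100 * c(phat - 1.96 * se, phat + 1.96 * se))
}
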
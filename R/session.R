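#' Interview session configuration
#'
#' Live interviews end after a wall-clock time limit (the training protocol
#' allots 10 minutes per interview); scripted and simulated runs use a turn
#' cap instead so results are exactly reproducible. At least one of the two
#' limits must be set.
#'
#' @param max_turns Maximum number of question turns (`NULL` = unlimited).
#' @param time_limit Wall-clock limit in seconds (`NULL` = none; default
#'   600).
#' @param seed Integer seed for the avatar's stochastic answers.
#' @param avatar_id Identifier recorded in the transcript.
#' @param judgments Ask for pre/post case judgments (interactive use).
#' @return An object of class `session_config`.
#' @export
session_config <- function(max_turns = NULL, time_limit = 600, seed = 1L,
                           avatar_id = NULL, judgments = FALSE) {
  if (is.null(max_turns) && is.null(time_limit))
    stop("set at least one of max_turns / time_limit", call. = FALSE)
  structure(list(max_turns = max_turns, time_limit = time_limit,
                 seed = as.integer(seed), avatar_id = avatar_id,
                 judgments = judgments),
            class = "session_config")
}

#' Record a case judgment
#'
#' Pre- or post-interview assessment of the case: presence of abuse plus
#' confidence on the six-point scale from 50% ("guessing") to 100%
#' ("completely sure").
#'
#' @param presence `"present"` or `"absent"`.
#' @param confidence One of 50, 60, 70, 80, 90, 100.
#' @param narrative Optional free-text account.
#' @return A named list.
#' @export
case_judgment <- function(presence = c("present", "absent"),
                          confidence, narrative = "") {
  presence <- match.arg(presence)
  if (!confidence %in% c(50, 60, 70, 80, 90, 100))
    stop("confidence must be one of 50,60,70,80,90,100", call. = FALSE)
  list(presence = presence, confidence = as.integer(confidence),
       narrative = narrative)
}

#' Run a scripted interview
#'
#' Plays a list of interviewer questions against one avatar: each question
#' is classified in conversational context (greeting rule, repetition rule,
#' model, suggestive override, topic tags), answered by the response
#' engine, and the context advanced. Stops at `max_turns` (noted in the
#' transcript). Fully reproducible for a fixed script and seed.
#'
#' @param questions Character vector of interviewer questions, in order.
#' @param model An `interview_model`.
#' @param pack A `scenario_pack`.
#' @param rules A [rule_config()].
#' @param config A [session_config()].
#' @param pre_judgment,post_judgment Optional [case_judgment()] records.
#' @return An object of class `interview_transcript`: metadata, a list of
#'   turns (`index`, `question_text`, `classified`, `response`) and the
#'   final avatar state.
#' @export
run_interview <- function(questions, model, pack, rules = rule_config(),
                          config = session_config(max_turns = 50L),
                          pre_judgment = NULL, post_judgment = NULL) {
  stopifnot(inherits(pack, "scenario_pack"))
  n_max <- config$max_turns %||% length(questions)
  n_run <- min(length(questions), n_max)
  context <- dialogue_context()
  state <- new_avatar_state(pack)
  turns <- vector("list", n_run)
  with_seed(config$seed, {
    for (i in seq_len(n_run)) {
      q <- classify_question(questions[i], context, model, rules)
      out <- respond(q, pack$profile, state, pack, rules)
      state <- out$state
      context <- advance_context(context, q, out$response)
      turns[[i]] <- list(index = i - 1L, question_text = questions[i],
                         classified = q, response = out$response)
    }
  })
  structure(
    list(avatar_id = config$avatar_id %||% pack$profile$avatar_id,
         seed = config$seed,
         truncated = length(questions) > n_run,
         n_questions_offered = length(questions),
         turns = turns,
         judgments = list(pre = pre_judgment, post = post_judgment),
         final_state = state),
    class = "interview_transcript"
  )
}

#' @export
print.interview_transcript <- function(x, ...) {
  cat(sprintf("Interview with %s: %d turns%s\n",
              x$avatar_id %||% "<avatar>", length(x$turns),
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  s <- summarize_interview(x)
  cat(sprintf("  recommended %d | not recommended %d | relevant %d | incorrect %d\n",
              s$n_recommended, s$n_not_recommended, s$n_relevant, s$n_incorrect))
  invisible(x)
}

#' The five outcome measures of an interview
#'
#' Counts over the substantive (non-greeting) turns: number of recommended
#' questions, number of not-recommended questions (repetitions included),
#' the proportion of recommended questions among coded substantive
#' questions (percent; `NA` when there are none), the number of relevant
#' details elicited (each of the nine memory details counts once) and the
#' number of incorrect details created.
#'
#' @param transcript An `interview_transcript`.
#' @return One-row data frame with columns `n_recommended`,
#'   `n_not_recommended`, `prop_recommended`, `n_relevant`, `n_incorrect`.
#' @export
summarize_interview <- function(transcript) {
  cats <- vapply(transcript$turns,
                 function(t) t$classified$category %||% NA_character_,
                 character(1))
  kinds <- vapply(transcript$turns,
                  function(t) t$response$detail_kind, character(1))
  n_rec <- sum(cats == "recommended", na.rm = TRUE)
  n_not <- sum(cats == "not_recommended", na.rm = TRUE)
  n_rel <- length(unique(unlist(lapply(transcript$turns, function(t) {
    if (identical(t$response$detail_kind, "relevant")) t$response$text
  }))))
  data.frame(
    n_recommended = n_rec,
    n_not_recommended = n_not,
    prop_recommended = if (n_rec + n_not > 0)
      100 * n_rec / (n_rec + n_not) else NA_real_,
    n_relevant = n_rel,
    n_incorrect = sum(kinds == "incorrect")
  )
}

#' Draw a scripted interviewer question list
#'
#' A stochastic stand-in for a human interviewer: each question is drawn
#' from the recommended-template pool with probability `p_recommended` and
#' from the not-recommended pool otherwise. Template pools default to the
#' synthetic-corpus banks. Used to drive in-silico batches whose outcome
#' correlations mirror the engine's design (more recommended questions,
#' more relevant details; more not-recommended questions, more incorrect
#' details).
#'
#' @param p_recommended Probability in `[0, 1]` of drawing a recommended
#'   question.
#' @param n_questions Number of questions.
#' @param seed Integer seed.
#' @param templates List with character vectors `recommended` and
#'   `not_recommended`; defaults to pools built from
#'   [default_corpus_spec()].
#' @return Character vector of questions.
#' @export
simulate_interviewer <- function(p_recommended, n_questions, seed = 1L,
                                 templates = NULL) {
  stopifnot(p_recommended >= 0, p_recommended <= 1)
  templates <- templates %||% question_template_pools()
  with_seed(seed, {
    vapply(seq_len(n_questions), function(i) {
      pool <- if (stats::runif(1L) < p_recommended)
        templates$recommended else templates$not_recommended
      fill_template(sample(pool, 1L), default_slot_lexicons())
    }, character(1))
  })
}

#' Write / read a transcript as JSONL
#'
#' One JSON record per line: a header record (metadata and judgments)
#' followed by one record per turn. A read-back transcript reproduces the
#' written structure (the final avatar state travels in the header).
#'
#' @param transcript An `interview_transcript`.
#' @param path File path.
#' @return `path` (write) or the restored transcript (read).
#' @export
write_transcript <- function(transcript, path) {
  fs <- unclass(transcript$final_state)
  if (!is.null(fs$last_response)) fs$last_response <- unclass(fs$last_response)
  header <- list(record = "header", avatar_id = transcript$avatar_id,
                 seed = transcript$seed, truncated = transcript$truncated,
                 n_questions_offered = transcript$n_questions_offered,
                 judgments = transcript$judgments,
                 final_state = fs)
  lines <- c(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null",
                              digits = NA),
             vapply(transcript$turns, function(t) {
               as.character(jsonlite::toJSON(
                 list(record = "turn", index = t$index,
                      question_text = t$question_text,
                      classified = unclass(t$classified),
                      response = unclass(t$response)),
                 auto_unbox = TRUE, null = "null", digits = NA))
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_transcript
#' @export
read_transcript <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON)
  header <- recs[[1L]]
  turns <- lapply(recs[-1L], function(r) {
    cl <- r$classified
    feats <- unlist(cl$features)
    list(index = r$index, question_text = r$question_text,
         classified = new_classified(
           cl$text, stats::setNames(as.integer(feats), names(feats)),
           cl$qtype, cl$category %||% NA_character_,
           as.character(unlist(cl$topics)), cl$source,
           scores = if (!is.null(cl$scores)) unlist(cl$scores)),
         response = structure(
           list(text = r$response$text, detail_kind = r$response$detail_kind,
                conclusive = isTRUE(r$response$conclusive),
                topic = as.character(unlist(r$response$topic))),
           class = "avatar_response"))
  })
  fs <- header$final_state
  state <- structure(
    list(next_relevant_index = as.integer(fs$next_relevant_index),
         topic_pointers = stats::setNames(
           as.integer(unlist(fs$topic_pointers)),
           names(fs$topic_pointers)),
         incorrect_log = as.character(unlist(fs$incorrect_log)),
         flipped_questions = as.character(unlist(fs$flipped_questions)),
         emitted_relevant = as.character(unlist(fs$emitted_relevant)),
         last_response = fs$last_response,
         filler_cursor = as.integer(fs$filler_cursor)),
    class = "avatar_state")
  structure(
    list(avatar_id = header$avatar_id, seed = header$seed,
         truncated = isTRUE(header$truncated),
         n_questions_offered = header$n_questions_offered,
         turns = turns,
         judgments = header$judgments,
         final_state = state),
    class = "interview_transcript"
  )
}

#' Simulate a batch of interviews
#'
#' Runs `n_interviews` scripted interviews with interviewer quality
#' (`p_recommended`) drawn uniformly between `p_range[1]` and `p_range[2]`,
#' against avatars cycled from the non-reserved roster, and returns the
#' outcome measures per interview — the input for [batch_correlations()].
#'
#' @param n_interviews Number of interviews.
#' @param model An `interview_model`.
#' @param rules A [rule_config()].
#' @param n_questions Questions per interview.
#' @param p_range Range of interviewer quality.
#' @param seed Integer seed.
#' @return Data frame: one row per interview with `avatar_id`,
#'   `p_recommended` and the [summarize_interview()] columns.
#' @export
simulate_batch <- function(n_interviews, model, rules = rule_config(),
                           n_questions = 25L, p_range = c(0.1, 0.9),
                           seed = 1L) {
  roster <- build_roster()
  avail <- roster[!roster$reserved_for_modeling, , drop = FALSE]
  ps <- with_seed(derive_seed(seed, 11L),
                  stats::runif(n_interviews, p_range[1], p_range[2]))
  rows <- lapply(seq_len(n_interviews), function(i) {
    prof <- avail[1L + (i - 1L) %% nrow(avail), , drop = FALSE]
    pack <- build_scenario_pack(prof, seed = derive_seed(seed, 100L + i))
    qs <- simulate_interviewer(ps[i], n_questions,
                               seed = derive_seed(seed, 200L + i))
    tr <- run_interview(qs, model, pack, rules,
                        session_config(max_turns = n_questions,
                                       seed = derive_seed(seed, 300L + i)))
    cbind(data.frame(avatar_id = prof$avatar_id, p_recommended = ps[i]),
          summarize_interview(tr))
  })
  do.call(rbind, rows)
}
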
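praise_templates <- function() {
  c(invitation_broad = "Excellent open invitation: it lets the child tell the story in their own words.",
    invitation_focus = "Good focused invitation: open-ended narrative on a named topic.",
    facilitator = "Good facilitator: it keeps the child talking without leading.",
    directive = "Good directive question about content the child had already mentioned.",
    clarification = "Good clarification: checking what the child said without suggesting an answer.")
}

critique_templates <- function() {
  c(option_posing = "This closed question introduced content the child had not mentioned. Prefer an open invitation such as 'Tell me more about that'.",
    specific_suggestive = "This question assumes details the child never mentioned and signals the expected answer. It can create incorrect details.",
    unspecific_suggestive = "This question presses the child toward an expected disclosure. Let the child volunteer information instead.",
    repetition = "Re-asking the same question pressures children to change a truthful answer. Accept the first answer and move on.",
    inappropriate_utterance = "This wording is too demanding for a young child (compound, abstract, or time-estimation content). Ask one simple thing at a time.",
    multiple_choice = "Forcing a choice among options risks an inaccurate pick. Ask an open question instead.")
}

#' Generate the automated feedback report for an interview
#'
#' Two-part feedback delivered after an interview: the true outcome of the
#' case, and comments on up to two recommended and two not-recommended
#' questions sampled uniformly without replacement from the coded turns
#' (greetings excluded). When a category has fewer than two turns the
#' shortfall is noted. Comment wording comes from a per-type template
#' table; every quoted question appears verbatim in the transcript.
#'
#' @param transcript An `interview_transcript`.
#' @param pack The avatar's `scenario_pack` (for the case outcome).
#' @param seed Integer seed making the sample reproducible.
#' @return An object of class `feedback_report`: `case_outcome`, `praised`,
#'   `critiqued` (each a data frame of `question`, `qtype`, `comment`),
#'   `shortfall`.
#' @export
generate_feedback <- function(transcript, pack, seed = 1L) {
  if (length(transcript$turns) == 0L)
    stop("cannot generate feedback for an empty transcript", call. = FALSE)
  cats <- vapply(transcript$turns,
                 function(t) t$classified$category %||% NA_character_,
                 character(1))
  pick <- function(idx, n) if (length(idx) <= n) idx else sample(idx, n)
  sel <- with_seed(seed, list(rec = pick(which(cats == "recommended"), 2L),
                              not = pick(which(cats == "not_recommended"), 2L)))
  rec_idx <- sel$rec
  not_idx <- sel$not
  as_rows <- function(idx, templates) {
    if (!length(idx)) {
      return(data.frame(question = character(0), qtype = character(0),
                        comment = character(0)))
    }
    do.call(rbind, lapply(idx, function(i) {
      q <- transcript$turns[[i]]$classified
      data.frame(question = q$text, qtype = q$qtype,
                 comment = unname(templates[q$qtype]))
    }))
  }
  shortfall <- character(0)
  if (length(rec_idx) < 2L)
    shortfall <- c(shortfall, sprintf(
      "only %d recommended question(s) available for feedback", length(rec_idx)))
  if (length(not_idx) < 2L)
    shortfall <- c(shortfall, sprintf(
      "only %d not-recommended question(s) available for feedback",
      length(not_idx)))
  gt <- case_ground_truth(pack)
  structure(
    list(case_outcome = list(
           outcome = gt$outcome,
           epilogue = paste0(
             "The correct conclusion for this case was: abuse ",
             gt$outcome, ". The conclusive details were: ",
             paste(gt$conclusive_details, collapse = " "))),
         praised = as_rows(rec_idx, praise_templates()),
         critiqued = as_rows(not_idx, critique_templates()),
         shortfall = shortfall),
    class = "feedback_report"
  )
}

#' Render a feedback report as Markdown
#'
#' @param report A `feedback_report`.
#' @return Character vector of Markdown lines.
#' @export
render_feedback <- function(report) {
  lines <- c("# Interview feedback", "",
             "## Case outcome", report$case_outcome$epilogue, "",
             "## Questions that worked well")
  fmt <- function(df) {
    if (!nrow(df)) return("(none available)")
    unlist(lapply(seq_len(nrow(df)), function(i) {
      c(sprintf("- \"%s\" (%s)", df$question[i], df$qtype[i]),
        sprintf("  %s", df$comment[i]))
    }))
  }
  lines <- c(lines, fmt(report$praised), "",
             "## Questions to reconsider", fmt(report$critiqued))
  if (length(report$shortfall))
    lines <- c(lines, "", paste("Note:", report$shortfall))
  lines
}

#' Default learning points for the modeling intervention
#'
#' @return Character vector of instructional points on good and bad
#'   questioning.
#' @export
default_learning_points <- function() {
  c("Open the substantive phase with a broad invitation and let the child talk without interruption.",
    "Follow up with focused invitations and directives about content the child has already mentioned.",
    "Avoid introducing content the child has not mentioned; closed and suggestive questions can create incorrect details.",
    "Never repeat a question the child has already answered; repetition pressures children to change truthful answers.",
    "Keep wording short, concrete and single-barrelled; avoid time estimates and hypotheticals with young children.")
}

#' Assemble the modeling intervention package
#'
#' Observational learning material shown between interviews: ordered
#' learning points followed by four annotated example interviews covering
#' the full good/bad by abused/non-abused design, each wrapped in its
#' background scenario and case outcome. Examples are text transcripts.
#'
#' @param learning_points Character vector of instructional points.
#' @param examples List of exactly four elements with fields `quality`
#'   (`"good"`/`"bad"`), `abused` (logical), `scenario` (text),
#'   `transcript_text` (character vector), `outcome` (text).
#' @return An object of class `modeling_package`.
#' @export
modeling_package <- function(learning_points = default_learning_points(),
                             examples) {
  cells <- vapply(examples, function(e)
    paste(e$quality, ifelse(isTRUE(e$abused), "abused", "non_abused"),
          sep = "/"), character(1))
  wanted <- c("good/abused", "good/non_abused", "bad/abused",
              "bad/non_abused")
  missing <- setdiff(wanted, cells)
  if (length(missing) || length(examples) != 4L)
    stop("modeling package needs exactly the 2x2 example design; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(learning_points = learning_points,
                 examples = examples[match(wanted, cells)]),
            class = "modeling_package")
}

#' Build the default modeling package from simulated example interviews
#'
#' Generates the four example interviews against the two avatars reserved
#' for modeling (plus matched partners to cover both case types): good
#' examples use a high share of recommended questions, bad examples a low
#' share.
#'
#' @param model An `interview_model`.
#' @param rules A [rule_config()].
#' @param n_questions Questions per example interview.
#' @param seed Integer seed.
#' @return A `modeling_package`.
#' @export
default_modeling_package <- function(model, rules = rule_config(),
                                     n_questions = 12L, seed = 1L) {
  roster <- build_roster()
  reserved <- roster[roster$reserved_for_modeling, , drop = FALSE]
  abused_prof <- reserved[reserved$abused, , drop = FALSE]
  clean_prof <- reserved[!reserved$abused, , drop = FALSE]
  cells <- list(list(quality = "good", prof = abused_prof, p = 0.9),
                list(quality = "good", prof = clean_prof, p = 0.9),
                list(quality = "bad", prof = abused_prof, p = 0.1),
                list(quality = "bad", prof = clean_prof, p = 0.1))
  examples <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    pack <- build_scenario_pack(cell$prof, seed = derive_seed(seed, i))
    qs <- simulate_interviewer(cell$p, n_questions,
                               seed = derive_seed(seed, 10L + i))
    tr <- run_interview(qs, model, pack, rules,
                        session_config(max_turns = n_questions,
                                       seed = derive_seed(seed, 20L + i)))
    gt <- case_ground_truth(pack)
    list(quality = cell$quality, abused = isTRUE(cell$prof$abused),
         scenario = paste0(
           "Background: a report was filed concerning a ", cell$prof$age,
           "-year-old ", cell$prof$gender,
           ". Your task is to find out what, if anything, happened."),
         transcript_text = unlist(lapply(tr$turns, function(t)
           c(paste0("Interviewer: ", t$question_text),
             paste0("Child: ", t$response$text)))),
         outcome = paste0("Case outcome: abuse ", gt$outcome, "."))
  })
  modeling_package(examples = examples)
}

#' Deliver a modeling package as an ordered presentation script
#'
#' Pure formatting, in the fixed instructional order: the learning points,
#' then for each example its background scenario, the annotated transcript,
#' and the case outcome.
#'
#' @param package A `modeling_package`.
#' @return Character vector of presentation lines.
#' @export
deliver_modeling <- function(package) {
  stopifnot(inherits(package, "modeling_package"))
  lines <- c("# Learning points",
             paste0(seq_along(package$learning_points), ". ",
                    package$learning_points))
  for (e in package$examples) {
    lines <- c(lines, "",
               sprintf("# Example: %s interview, %s case", e$quality,
                       ifelse(e$abused, "abused", "non-abused")),
               "## Scenario", e$scenario,
               "## Interview", e$transcript_text,
               "## Outcome", e$outcome)
  }
  lines
}
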
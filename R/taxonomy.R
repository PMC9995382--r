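#' The eleven-type question taxonomy
#'
#' Investigative-interview research codes interviewer utterances into eleven
#' question types, partitioned into *recommended* questions (open, non-leading
#' prompts that draw on the child's recall memory) and *not-recommended*
#' questions (closed, suggestive, repeated, multiple-choice, or
#' developmentally inappropriate prompts that risk eliciting inaccurate
#' answers). This function returns the taxonomy as a data frame with one row
#' per type, in the canonical order used for integer label encoding.
#'
#' Greetings and other rapport utterances ("Hello", "How old are you") are
#' deliberately *not* part of the taxonomy: they are intercepted by an if-then
#' rule before the statistical classifier runs (see [classify_question()]) and
#' carry the pseudo-label `"greeting"`, excluded from all quality counts.
#'
#' @return A data frame with columns `label` (character), `code` (integer,
#'   0-based, stable across sessions), `category` (`"recommended"` or
#'   `"not_recommended"`) and `description`.
#' @examples
#' question_types()
#' table(question_types()$category)
#' @export
question_types <- function() {
  .taxonomy_table
}

.taxonomy_table <- data.frame(
  label = c(
    "invitation_broad", "invitation_focus", "facilitator", "directive",
    "clarification",
    "option_posing", "specific_suggestive", "unspecific_suggestive",
    "repetition", "inappropriate_utterance", "multiple_choice"
  ),
  code = 0:10,
  category = c(rep("recommended", 5), rep("not_recommended", 6)),
  description = c(
    "Open-ended and non-suggestive questions that elicit free narrative from children.",
    "Open-ended and non-suggestive questions that elicit narrative about the focused topic from children.",
    "Non-suggestive utterances that promote further narrative about content previously mentioned.",
    "Questions that focus the children's attention on content the child has already mentioned for further explanation.",
    "Attempts to clarify what the child has said.",
    "Closed questions that focus the children's attention on content the child has not yet mentioned without implying a specific type of answer.",
    "Questions that indicate what kind of answer is expected by assuming details that children have not mentioned.",
    "Questions that indicate what kind of answer is expected without assuming details that children have not mentioned.",
    "Questions continuously asking what the interviewer has already asked.",
    "Questions not appropriate for eliciting correct information from children (multiple details at once, difficult words, unclear grammar, temporal estimates, fantasy).",
    "Questions that focus the children's attention on specific answers, or force them to choose among options."
  ),
  stringsAsFactors = FALSE
)

#' Pseudo-label for greeting/rapport utterances
#'
#' Not one of the eleven taxonomy types; assigned by the greeting rule and
#' excluded from agreement statistics and outcome counts.
#' @export
GREETING_LABEL <- "greeting"

#' Map a question type to its category
#'
#' Pure lookup of the recommended / not-recommended partition. Vectorised.
#'
#' @param qtype Character vector of taxonomy labels.
#' @return Character vector, each element `"recommended"` or
#'   `"not_recommended"`.
#' @examples
#' category_of("invitation_broad")   # "recommended"
#' category_of("option_posing")      # "not_recommended"
#' @export
category_of <- function(qtype) {
  tab <- question_types()
  idx <- match(qtype, tab$label)
  if (anyNA(idx)) {
    bad <- unique(qtype[is.na(idx)])
    stop("unknown question type label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab$category[idx]
}

#' Integer label codes for model training
#'
#' @return Named integer vector mapping taxonomy label to its stable 0-based
#'   code.
#' @export
label_codes <- function() {
  tab <- question_types()
  stats::setNames(tab$code, tab$label)
}

#' Write the taxonomy to a YAML resource
#'
#' Serialises the taxonomy (label, code, category, description) so other
#' tools can consume the label space. [read_taxonomy()] restores it; a
#' round-trip is exact.
#'
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(path) {
  tab <- question_types()
  recs <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, ]))
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Read a taxonomy YAML resource
#'
#' @param path File written by [write_taxonomy()]. Defaults to the copy
#'   bundled with the package.
#' @return A data frame in the same shape as [question_types()].
#' @export
read_taxonomy <- function(path = system.file("extdata", "taxonomy.yaml",
                                             package = "interviewsim")) {
  recs <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(recs, function(r) {
    data.frame(label = r$label, code = as.integer(r$code),
               category = r$category, description = r$description,
               stringsAsFactors = FALSE)
  }))
  out[order(out$code), , drop = FALSE]
}
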
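#' Slot lexicons shared across all question templates
#'
#' Names, places and activities are shared across every class so no single
#' slot token trivially identifies a class.
#'
#' @return Named list of character vectors (`name`, `place`, `thing`).
#' @export
default_slot_lexicons <- function() {
  list(
    name = c("dad", "mom", "Kanta", "Miura", "your teacher", "your friend",
             "your brother", "grandma"),
    place = c("the park", "school", "your house", "the garden", "the pool",
              "the playground"),
    thing = c("football", "a game", "tag", "hide and seek", "drawing",
              "stickers")
  )
}

default_template_bank <- function() {
  list(
    invitation_broad = c(
      "Tell me everything that happened from the beginning to the end",
      "Tell me everything you remember about that day",
      "Tell me all about what happened",
      "Start at the beginning and tell me everything",
      "Tell me everything that happened, every little thing"),
    invitation_focus = c(
      "Tell me about your family",
      "Tell me more about {name}",
      "Tell me about {place}",
      "Tell me more about that time",
      "Tell me about your day at {place}"),
    facilitator = c(
      "Continue", "Go ahead", "Ok", "Uh huh, and then", "Tell me more"),
    directive = c(
      "Where did you go with {name}?",
      "What game did you play?",
      "Who was with you at {place}?",
      "When you played {thing}, who won?",
      "What happened next at {place}?"),
    clarification = c(
      "What did you say?",
      "I did not hear you well, so tell me again",
      "Can you say that once more?",
      "What do you mean by that?",
      "Say that last part again please"),
    option_posing = c(
      "Do you play with {name}?",
      "Did you go to {place}?",
      "Did {name} see you there?",
      "Do you like {thing}?",
      "Were you at {place} that day?"),
    specific_suggestive = c(
      "Did {name} do something bad to you?",
      "Is {name} a bad person?",
      "Did {name} hurt you at {place}?",
      "{name} touched you, didn't they?",
      "Did {name} tell you to keep it a secret?"),
    unspecific_suggestive = c(
      "I know that you have something to talk about, tell me!",
      "Tell me about someone hurting you",
      "Something bad happened, didn't it?",
      "You can tell me about the scary thing now",
      "I know something happened to you, so tell me"),
    repetition = c(
      "Tell me about your family",
      "Do you play with {name}?",
      "What game did you play?",
      "Did you go to {place}?",
      "Tell me about {place}"),
    inappropriate_utterance = c(
      "Where were you with {name}, and what were you doing after that?",
      "What is the relationship between mom and dad?",
      "How many minutes after lunch did {name} leave {place}?",
      "If you were {name}, what would you have done?",
      "Describe the chronological sequence of the events at {place}"),
    multiple_choice = c(
      "Did you go practicing {thing} with Kanta or Miura?",
      "Was it {name} or {name}?",
      "Did it happen at {place} or at {place}?",
      "Was it in the morning or at night?",
      "Did you play {thing} or {thing}?")
  )
}

fill_template <- function(template, lexicons) {
  out <- template
  for (slot in names(lexicons)) {
    pat <- paste0("{", slot, "}")
    while (grepl(pat, out, fixed = TRUE)) {
      out <- sub(pat, sample(lexicons[[slot]], 1L), out, fixed = TRUE)
    }
  }
  out
}

#' Synthetic-corpus specification
#'
#' Describes a labeled question corpus to generate: per-class counts (the
#' imbalance profile), per-class utterance templates with shared slot
#' lexicons, the suggestive-keyword lexicon (shared with the rule layer),
#' and how repetition items are emitted.
#'
#' @param per_class_counts Named integer vector over taxonomy labels.
#' @param template_bank Named list: label -> character vector of templates.
#' @param slot_lexicons Named list of slot fill-in values.
#' @param suggestive_lexicon Keywords guaranteed to occur in suggestive
#'   items.
#' @param repetition_pair_fraction Fraction of repetition rows emitted as a
#'   verbatim copy of the immediately preceding (host) row; the remainder
#'   are lightly perturbed near-duplicates.
#' @param language_mode `"latin_word"` (English templates) or `"cjk_char"`
#'   (the same templates collapsed to a whitespace-free form, exercising
#'   the character N-gram pathway used for languages without word
#'   boundaries).
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(per_class_counts,
                        template_bank = default_template_bank(),
                        slot_lexicons = default_slot_lexicons(),
                        suggestive_lexicon =
                          default_suggestive_keywords()$keyword,
                        repetition_pair_fraction = 0.8,
                        language_mode = c("latin_word", "cjk_char")) {
  language_mode <- match.arg(language_mode)
  stopifnot(all(per_class_counts >= 0),
            repetition_pair_fraction >= 0, repetition_pair_fraction <= 1)
  bad <- setdiff(names(per_class_counts), question_types()$label)
  if (length(bad))
    stop("unknown class labels: ", paste(bad, collapse = ", "),
         call. = FALSE)
  empty <- names(per_class_counts)[per_class_counts > 0 &
    !vapply(names(per_class_counts),
            function(l) length(template_bank[[l]]) > 0, logical(1))]
  if (length(empty))
    stop("no templates for requested class(es): ",
         paste(empty, collapse = ", "), call. = FALSE)
  structure(
    list(per_class_counts = per_class_counts,
         template_bank = template_bank, slot_lexicons = slot_lexicons,
         suggestive_lexicon = suggestive_lexicon,
         repetition_pair_fraction = repetition_pair_fraction,
         language_mode = language_mode),
    class = "corpus_spec"
  )
}

#' Default corpus specification
#'
#' Counts follow a geometric decay over the eleven classes in taxonomy
#' order — `round(150 * 0.85^(0:10))`, an imbalance ratio of 5 — so that
#' class rebalancing during training is exercised on every default run.
#'
#' @inheritParams corpus_spec
#' @return A `corpus_spec`.
#' @export
default_corpus_spec <- function(language_mode = c("latin_word", "cjk_char")) {
  labels <- question_types()$label
  counts <- stats::setNames(as.integer(round(150 * 0.85^(0:10))), labels)
  corpus_spec(per_class_counts = counts, language_mode = language_mode)
}

# whitespace-free transliteration for the character-unit pathway
collapse_cjk <- function(x) gsub("[ ]", "", x)

perturb_text <- function(x, lexicons) {
  # swap one slot word when possible; slot-free templates stay verbatim
  for (slot in names(lexicons)) {
    for (w in lexicons[[slot]]) {
      if (grepl(w, x, fixed = TRUE)) {
        repl <- sample(setdiff(lexicons[[slot]], w), 1L)
        return(sub(w, repl, x, fixed = TRUE))
      }
    }
  }
  x
}

#' Generate a labeled synthetic question corpus
#'
#' Emits `(text, label)` rows whose class counts match the specification
#' exactly. Repetition-labeled rows are placed immediately after a host row
#' drawn from another class and duplicate it (verbatim with probability
#' `repetition_pair_fraction`, otherwise a near-duplicate), so the corpus
#' contains consecutive near-duplicate pairs for the repetition pathway.
#' Suggestive-class templates always contain a suggestive-lexicon keyword.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec A [corpus_spec()].
#' @param seed Integer seed.
#' @return Data frame with columns `text` and `label`.
#' @export
generate_corpus <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "corpus_spec"))
  counts <- spec$per_class_counts
  with_seed(seed, {
    plain <- list()
    for (lab in names(counts)) {
      if (lab == "repetition" || counts[[lab]] == 0L) next
      tmpl <- sample(spec$template_bank[[lab]], counts[[lab]],
                     replace = TRUE)
      plain[[lab]] <- data.frame(
        text = vapply(tmpl, fill_template, character(1),
                      lexicons = spec$slot_lexicons),
        label = lab, row.names = NULL)
    }
    corpus <- do.call(rbind, plain)
    corpus <- corpus[sample(nrow(corpus)), , drop = FALSE]
    n_rep <- if ("repetition" %in% names(counts))
      counts[["repetition"]] else 0L
    if (n_rep > 0L) {
      hosts <- sort(sample(nrow(corpus), n_rep))
      out <- vector("list", nrow(corpus))
      for (i in seq_len(nrow(corpus))) {
        out[[i]] <- corpus[i, , drop = FALSE]
        if (i %in% hosts) {
          txt <- if (stats::runif(1L) < spec$repetition_pair_fraction)
            corpus$text[i] else perturb_text(corpus$text[i],
                                             spec$slot_lexicons)
          out[[i]] <- rbind(out[[i]],
                            data.frame(text = txt, label = "repetition"))
        }
      }
      corpus <- do.call(rbind, out)
    }
    if (spec$language_mode == "cjk_char") corpus$text <- collapse_cjk(corpus$text)
    rownames(corpus) <- NULL
    corpus
  })
}

#' Recommended / not-recommended question template pools
#'
#' Instantiable template pools for [simulate_interviewer()], drawn from a
#' corpus specification's bank (repetition templates excluded — scripted
#' repetitions arise only by literally re-asking).
#'
#' @param spec A [corpus_spec()].
#' @return List with character vectors `recommended` and `not_recommended`.
#' @export
question_template_pools <- function(spec = default_corpus_spec()) {
  tax <- question_types()
  rec <- unlist(spec$template_bank[tax$label[tax$category == "recommended"]],
                use.names = FALSE)
  not <- unlist(spec$template_bank[
    setdiff(tax$label[tax$category == "not_recommended"], "repetition")],
    use.names = FALSE)
  list(recommended = rec, not_recommended = not)
}

#' Write / read a corpus as CSV
#'
#' UTF-8 CSV with header `text,label`.
#'
#' @param corpus Data frame with `text` and `label`.
#' @param path File path.
#' @return `path` (write) or the corpus (read).
#' @export
write_corpus <- function(corpus, path) {
  utils::write.csv(corpus[, c("text", "label")], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
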
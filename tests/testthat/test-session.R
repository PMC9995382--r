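test_that("session config needs a limit; judgments validate the scale", {
  expect_error(session_config(max_turns = NULL, time_limit = NULL),
               "at least one")
  expect_silent(session_config(max_turns = 10, time_limit = NULL))
  expect_error(case_judgment("present", 55), "50,60,70,80,90,100")
  j <- case_judgment("absent", 80, "nothing happened")
  expect_equal(j$confidence, 80L)
})

test_that("scripted interviews run each question and honour the turn cap", {
  m <- fixture_model()
  pack <- fixture_pack()
  qs <- simulate_interviewer(0.5, 5, seed = 2)
  t5 <- run_interview(qs, m, pack,
                      config = session_config(max_turns = 10, seed = 3))
  expect_length(t5$turns, 5L)
  expect_false(t5$truncated)
  expect_equal(vapply(t5$turns, `[[`, 0L, "index"), 0:4)

  qs20 <- simulate_interviewer(0.5, 20, seed = 2)
  t10 <- run_interview(qs20, m, pack,
                       config = session_config(max_turns = 10, seed = 3))
  expect_length(t10$turns, 10L)
  expect_true(t10$truncated)

  # determinism: same script and seed give identical transcripts
  t10b <- run_interview(qs20, m, pack,
                        config = session_config(max_turns = 10, seed = 3))
  expect_equal(lapply(t10$turns, function(t) t$response),
               lapply(t10b$turns, function(t) t$response))
  expect_equal(summarize_interview(t10), summarize_interview(t10b))
})

test_that("outcome measures count substantive turns and details", {
  tr <- fake_transcript(list(
    fake_turn(0, "Hello", GREETING_LABEL),
    fake_turn(1, "Tell me everything", "invitation_broad", "relevant", "detail A"),
    fake_turn(2, "Go ahead", "facilitator", "relevant", "detail B"),
    fake_turn(3, "Tell me more", "invitation_focus"),
    fake_turn(4, "Did dad hurt you?", "specific_suggestive", "incorrect", "Yes."),
    fake_turn(5, "Did dad hurt you?", "repetition")))
  s <- summarize_interview(tr)
  expect_equal(s$n_recommended, 3L)
  expect_equal(s$n_not_recommended, 2L)  # repetition counts as not recommended
  expect_equal(s$prop_recommended, 60)
  expect_equal(s$n_relevant, 2L)
  expect_equal(s$n_incorrect, 1L)

  empty <- summarize_interview(fake_transcript(list()))
  expect_equal(empty$n_recommended + empty$n_not_recommended, 0L)
  expect_true(is.na(empty$prop_recommended))

  # a re-elicited identical detail counts once
  dup <- fake_transcript(list(
    fake_turn(0, "Tell me", "invitation_broad", "relevant", "detail A"),
    fake_turn(1, "Tell me", "invitation_broad", "relevant", "detail A")))
  expect_equal(summarize_interview(dup)$n_relevant, 1L)
})

test_that("the scripted interviewer honours its policy and seed", {
  tpl <- list(recommended = c("R one", "R two"), not_recommended = c("N one"))
  all_rec <- simulate_interviewer(1, 30, seed = 5, templates = tpl)
  expect_true(all(all_rec %in% tpl$recommended))
  none_rec <- simulate_interviewer(0, 30, seed = 5, templates = tpl)
  expect_true(all(none_rec == "N one"))
  expect_identical(simulate_interviewer(0.5, 30, seed = 9, templates = tpl),
                   simulate_interviewer(0.5, 30, seed = 9, templates = tpl))
})

test_that("transcripts round-trip through JSONL", {
  m <- fixture_model()
  pack <- fixture_pack()
  qs <- c("Hello", simulate_interviewer(0.5, 6, seed = 12))
  tr <- run_interview(qs, m, pack,
                      config = session_config(max_turns = 10, seed = 13))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_transcript(tr, path)
  tr2 <- read_transcript(path)
  expect_equal(length(tr2$turns), length(tr$turns))
  expect_equal(vapply(tr2$turns, `[[`, "", "question_text"),
               vapply(tr$turns, `[[`, "", "question_text"))
  expect_equal(vapply(tr2$turns, function(t) t$classified$qtype, ""),
               vapply(tr$turns, function(t) t$classified$qtype, ""))
  expect_equal(vapply(tr2$turns, function(t) t$response$detail_kind, ""),
               vapply(tr$turns, function(t) t$response$detail_kind, ""))
  expect_equal(summarize_interview(tr2), summarize_interview(tr))
  expect_equal(tr2$final_state$next_relevant_index,
               tr$final_state$next_relevant_index)
})
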
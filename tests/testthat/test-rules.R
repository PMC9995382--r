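test_that("greeting rule matches configured patterns only", {
  cfg <- rule_config()
  expect_true(match_greeting("Hello", cfg))
  expect_true(match_greeting("How old are you?", cfg))
  expect_false(match_greeting("Tell me everything that happened", cfg))
  none <- rule_config(greetings = character(0))
  expect_false(match_greeting("Hello", none))
})

test_that("repetition looks back exactly one turn through a Jaccard gate", {
  cfg <- rule_config(jaccard_threshold = 0.5)
  ctx <- dialogue_context()
  f1 <- extract_ngrams("Did you go to the park?")
  # first question: no predecessor, never a repetition
  expect_false(detect_repetition(f1, ctx, cfg))
  q1 <- interviewsim:::new_classified("Did you go to the park?", f1,
                                      "option_posing", "not_recommended",
                                      character(0), "model")
  ctx <- advance_context(ctx, q1)
  expect_equal(ctx$turn_index, 1L)
  expect_true(detect_repetition(f1, ctx, cfg))
  # below-threshold similarity is not a repetition
  a <- c(ab = 1, bc = 1); b <- c(bc = 1, cd = 1, de = 1)  # jaccard 0.25
  ctx$previous_question_features <- b
  expect_false(detect_repetition(a, ctx, cfg))
  ctx$previous_question_features <- a
  expect_true(detect_repetition(a, ctx, rule_config(jaccard_threshold = 1)))
})

test_that("suggestive keywords override recommended labels until disclosure", {
  cfg <- rule_config()
  ctx <- dialogue_context()
  expect_equal(
    suggestive_override("Tell me about someone hurting you",
                        "invitation_focus", ctx, cfg),
    "unspecific_suggestive")
  # after the avatar has disclosed the hurt topic the label is retained
  ctx$mentioned_topics <- "hurt"
  expect_equal(
    suggestive_override("Tell me about someone hurting you",
                        "invitation_focus", ctx, cfg),
    "invitation_focus")
  # no keyword: unchanged
  expect_equal(
    suggestive_override("Tell me about your family", "invitation_focus",
                        dialogue_context(), cfg),
    "invitation_focus")
  # never changes a not-recommended model label
  expect_equal(
    suggestive_override("Did dad hurt you?", "specific_suggestive",
                        dialogue_context(), cfg),
    "specific_suggestive")
})

test_that("topic tagging applies to recommended questions, in config order", {
  cfg <- rule_config()
  expect_equal(tag_topics("Tell me about your dad", "invitation_focus", cfg),
               "dad")
  expect_equal(tag_topics("Did your dad hurt you?", "specific_suggestive",
                          cfg),
               character(0))
  both <- tag_topics("Tell me about your mom and your dad",
                     "invitation_focus", cfg)
  expect_equal(both, c("dad", "mom"))  # config order, not text order
  expect_equal(tag_topics("Hello", GREETING_LABEL, cfg), character(0))
})

test_that("the classification pathway applies rules in strict precedence", {
  m <- fixture_model()
  cfg <- rule_config()
  ctx <- dialogue_context()
  g <- classify_question("Hello", ctx, m, cfg)
  expect_equal(g$qtype, GREETING_LABEL)
  expect_equal(g$source, "greeting_rule")
  expect_true(is.na(g$category))

  q1 <- classify_question("Tell me everything that happened from the beginning to the end",
                          ctx, m, cfg)
  expect_equal(q1$qtype, "invitation_broad")
  expect_equal(q1$source, "model")
  ctx <- advance_context(ctx, q1)

  # an immediately repeated substantive question is coded repetition, even
  # a suggestive one
  q2 <- classify_question("Tell me everything that happened from the beginning to the end",
                          ctx, m, cfg)
  expect_equal(q2$qtype, "repetition")
  expect_equal(q2$source, "repetition_rule")
  ctx2 <- dialogue_context()
  s1 <- classify_question("Did dad hurt you at school?", ctx2, m, cfg)
  ctx2 <- advance_context(ctx2, s1)
  s2 <- classify_question("Did dad hurt you at school?", ctx2, m, cfg)
  expect_equal(s2$qtype, "repetition")

  # override pathway records its source
  o <- classify_question("Tell me about someone hurting you",
                         dialogue_context(), m, cfg)
  if (o$source == "suggestive_override") {
    expect_equal(o$qtype, "unspecific_suggestive")
    expect_equal(o$topics, character(0))
  }
  # every utterance gets exactly one label and one source
  for (x in list(g, q1, q2, o)) {
    expect_length(x$qtype, 1L)
    expect_true(x$source %in% c("greeting_rule", "repetition_rule",
                                "model", "suggestive_override"))
  }
})

test_that("threshold tuning recovers a separating Jaccard threshold", {
  pairs <- data.frame(
    first = c("did you go to the park", "tell me about your family",
              "what game did you play", "do you play with dad",
              "where did you go", "tell me everything"),
    second = c("did you go to the park", "tell me about your family",
               "what did you say", "continue",
               "where did you go", "ok go ahead"),
    is_repetition = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE))
  out <- tune_jaccard_threshold(pairs)
  sims_rep <- out$sweep$accuracy[out$sweep$threshold == out$threshold]
  expect_equal(sims_rep, 1)
  expect_gt(out$threshold, 0)
  expect_lte(out$threshold, 1)
})
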
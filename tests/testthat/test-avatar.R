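rec_q <- function(topics = character(0)) {
  interviewsim:::new_classified("Tell me more", c(x = 1L),
                                "invitation_focus", "recommended",
                                topics, "model")
}
notrec_q <- function(qtype = "specific_suggestive",
                     text = "Did your dad hurt you?") {
  interviewsim:::new_classified(text, c(x = 1L), qtype,
                                "not_recommended", character(0), "model")
}

test_that("the roster has 16 avatars in 8 patterns with 2 reserved", {
  roster <- build_roster()
  expect_equal(nrow(roster), 16L)
  pat <- table(paste(roster$age, roster$gender, roster$abused))
  expect_equal(length(pat), 8L)
  expect_true(all(pat == 2L))
  expect_equal(sum(roster$reserved_for_modeling), 2L)
  expect_equal(sum(!roster$reserved_for_modeling), 14L)
  res <- roster[roster$reserved_for_modeling, ]
  expect_setequal(paste(res$age, res$gender, res$abused),
                  c("4 boy FALSE", "6 girl TRUE"))
  expect_equal(roster$p_elicit, ifelse(roster$age == 4, 0.20, 0.25))
})

test_that("scenario packs hold nine ordered details, last four conclusive", {
  for (abused in c(TRUE, FALSE)) {
    pack <- fixture_pack(abused = abused)
    expect_length(pack$relevant_details, 9L)
    expect_equal(anyDuplicated(pack$relevant_details), 0L)
    expect_equal(pack$conclusive, c(rep(FALSE, 5), rep(TRUE, 4)))
    gt <- case_ground_truth(pack)
    expect_equal(gt$outcome, if (abused) "present" else "absent")
    expect_equal(gt$conclusive_details, utils::tail(pack$relevant_details, 4))
  }
})

test_that("scenario packs round-trip through YAML", {
  pack <- fixture_pack(age = 4L, abused = FALSE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_pack(pack, path)
  pack2 <- read_scenario_pack(path)
  expect_equal(pack2$relevant_details, pack$relevant_details)
  expect_equal(pack2$conclusive, pack$conclusive)
  expect_equal(pack2$p_elicit, pack$p_elicit)
  expect_equal(pack2$incorrect_probability, pack$incorrect_probability)
  expect_equal(pack2$topic_responses, pack$topic_responses)
})

test_that("answer kinds respect the question category", {
  pack <- fixture_pack()
  state <- new_avatar_state(pack)
  withr::with_seed(21, {
    kinds_rec <- replicate(400, draw_answer_kind(rec_q(), pack$profile,
                                                 state, pack))
    kinds_not <- replicate(400, draw_answer_kind(notrec_q(), pack$profile,
                                                 state, pack))
  })
  expect_true(all(kinds_rec %in% c("relevant", "neutral", "none")))
  expect_true(all(kinds_not %in% c("incorrect", "none")))
  # exhausted memory never yields a tenth relevant detail
  state$next_relevant_index <- 10L
  withr::with_seed(22, {
    kinds_ex <- replicate(400, draw_answer_kind(rec_q(), pack$profile,
                                                state, pack))
  })
  expect_false(any(kinds_ex == "relevant"))
})

test_that("elicitation rates recover 20% (age 4) and 25% (age 6)", {
  for (age in c(4L, 6L)) {
    pack <- fixture_pack(age = age, abused = FALSE)
    est <- estimate_elicitation_rate(pack, n_trials = 4000L, seed = 31)
    target <- if (age == 4L) 20 else 25
    expect_gte(target, est$ci95[1])
    expect_lte(target, est$ci95[2])
  }
})

test_that("relevant details come out in fixed order, each at most once", {
  pack <- fixture_pack()
  pack$p_elicit <- 1  # force the relevant bin every draw
  state <- new_avatar_state(pack)
  emitted <- character(0)
  withr::with_seed(41, {
    for (i in 1:30) {
      out <- respond(rec_q(), pack$profile, state, pack)
      state <- out$state
      if (out$response$detail_kind == "relevant")
        emitted <- c(emitted, out$response$text)
    }
  })
  expect_equal(emitted, pack$relevant_details)  # all nine, exact order
  expect_equal(sum(duplicated(emitted)), 0L)
  expect_equal(state$emitted_relevant, pack$relevant_details)
})

test_that("neutral answers follow per-topic presentation order", {
  pack <- fixture_pack()
  state <- new_avatar_state(pack)
  dad <- character(0)
  withr::with_seed(43, {
    for (i in 1:200) {
      out <- respond(rec_q(topics = "dad"), pack$profile, state, pack)
      state <- out$state
      if (out$response$detail_kind == "neutral")
        dad <- c(dad, out$response$text)
    }
  })
  expect_equal(dad, pack$topic_responses$dad)  # exhausts the list in order
  # after exhaustion further neutral draws fall back to filler with no detail
  expect_equal(unname(state$topic_pointers["dad"]),
               length(pack$topic_responses$dad) + 1L)
})

test_that("not-recommended questioning creates logged incorrect details", {
  pack <- fixture_pack(abused = FALSE)
  state <- new_avatar_state(pack)
  n_inc <- 0L
  withr::with_seed(47, {
    for (i in 1:100) {
      out <- respond(notrec_q(), pack$profile, state, pack)
      state <- out$state
      if (out$response$detail_kind == "incorrect") {
        n_inc <- n_inc + 1L
        expect_equal(out$response$text, "Yes.")
      }
    }
  })
  expect_gt(n_inc, 0L)
  expect_length(state$incorrect_log, n_inc)
})

test_that("a repeated question flips to yes at most once per wording", {
  pack <- fixture_pack(abused = FALSE, yes_flip_probability = 1)
  state <- new_avatar_state(pack)
  rep_q <- interviewsim:::new_classified("Did your dad hurt you?", c(x = 1L),
                                         "repetition", "not_recommended",
                                         character(0), "repetition_rule")
  withr::with_seed(51, {
    out1 <- respond(rep_q, pack$profile, state, pack)
    state <- out1$state
    expect_equal(out1$response$text, "Yes.")
    expect_equal(out1$response$detail_kind, "incorrect")
    expect_length(state$incorrect_log, 1L)
    # same wording again: no second flip
    out2 <- respond(rep_q, pack$profile, state, pack)
    expect_equal(out2$response$detail_kind, "none")
    expect_length(out2$state$incorrect_log, 1L)
  })
  # zero flip probability: never flips
  pack0 <- fixture_pack(abused = FALSE, yes_flip_probability = 0)
  state0 <- new_avatar_state(pack0)
  withr::with_seed(52, {
    out <- respond(rep_q, pack0$profile, state0, pack0)
    expect_equal(out$response$detail_kind, "none")
  })
  # an abused avatar's yes to a repeated suggestive question is consistent
  # with memory, hence no incorrect detail
  packA <- fixture_pack(abused = TRUE, yes_flip_probability = 1)
  stateA <- new_avatar_state(packA)
  withr::with_seed(53, {
    outA <- respond(rep_q, packA$profile, stateA, packA)
    expect_equal(outA$response$text, "Yes.")
    expect_equal(outA$response$detail_kind, "none")
  })
})

test_that("identical seeds give identical response sequences", {
  pack <- fixture_pack()
  run <- function() {
    state <- new_avatar_state(pack)
    kinds <- character(0)
    withr::with_seed(61, {
      for (i in 1:50) {
        q <- if (i %% 3 == 0) notrec_q() else rec_q(topics = "mom")
        out <- respond(q, pack$profile, state, pack)
        state <- out$state
        kinds <- c(kinds, out$response$detail_kind)
      }
    })
    kinds
  }
  expect_identical(run(), run())
})
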
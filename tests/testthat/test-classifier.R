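test_that("stratified split preserves class proportions and is seeded", {
  one <- data.frame(text = sprintf("q%d", 1:100), label = "directive")
  s <- stratified_split(one, 0.2, seed = 3)
  expect_equal(nrow(s$train), 80L)
  expect_equal(nrow(s$test), 20L)
  expect_equal(sort(c(s$train$text, s$test$text)), sort(one$text))

  two <- data.frame(text = sprintf("q%d", 1:100),
                    label = rep(c("directive", "option_posing"), each = 50))
  s2 <- stratified_split(two, 0.2, seed = 3)
  expect_equal(as.integer(table(s2$test$label)), c(10L, 10L))

  s3 <- stratified_split(two, 0.2, seed = 3)
  expect_identical(s2, s3)
  s4 <- stratified_split(two, 0.2, seed = 4)
  expect_false(identical(sort(s2$test$text), sort(s4$test$text)))

  tiny <- data.frame(text = c("a", "b", "c"),
                     label = c("directive", "directive", "option_posing"))
  expect_error(stratified_split(tiny, 0.2), "2 items per class")
})

test_that("SMOTE+Tomek shrinks imbalance without destroying classes", {
  withr::with_seed(5, {
    xa <- matrix(rnorm(200 * 4, mean = 0), ncol = 4)
    xb <- matrix(rnorm(20 * 4, mean = 8), ncol = 4)
  })
  x <- rbind(xa, xb)
  y <- c(rep("maj", 200), rep("min", 20))
  out <- rebalance_smote_tomek(x, y, seed = 9)
  ratio_in <- 200 / 20
  tab <- table(out$labels)
  expect_lte(max(tab) / min(tab), ratio_in)
  expect_setequal(names(tab), c("maj", "min"))
  # synthetic minority points are convex combinations of minority points:
  # they stay inside the minority bounding box
  synth <- out$features[out$labels == "min", , drop = FALSE]
  for (j in 1:4) {
    expect_gte(min(synth[, j]), min(xb[, j]) - 1e-9)
    expect_lte(max(synth[, j]), max(xb[, j]) + 1e-9)
  }
  # determinism
  out2 <- rebalance_smote_tomek(x, y, seed = 9)
  expect_identical(out, out2)
})

test_that("balanced well-separated classes pass through unchanged", {
  withr::with_seed(6, {
    x <- rbind(matrix(rnorm(30 * 3, 0), ncol = 3),
               matrix(rnorm(30 * 3, 50), ncol = 3))
  })
  y <- rep(c("a", "b"), each = 30)
  out <- rebalance_smote_tomek(x, y, seed = 1)
  expect_equal(as.integer(table(out$labels)), c(30L, 30L))
  expect_equal(out$info$n_synthetic, 0L)
  expect_equal(out$info$n_tomek_removed, 0L)
})

test_that("a minority class below k+1 members raises an actionable error", {
  x <- matrix(rnorm(26 * 2), ncol = 2)
  y <- c(rep("maj", 22), rep("min", 4))
  expect_error(rebalance_smote_tomek(x, y, k_neighbors = 5),
               "smaller k_neighbors")
})

test_that("training beats chance on the synthetic corpus and is reproducible", {
  m <- fixture_model()
  acc <- m$training_report$heldout_accuracy
  n_test <- m$training_report$n_test
  expect_gt(acc, 1 / 11)
  # and decisively so
  expect_lt(binom.test(round(acc * n_test), n_test, 1 / 11,
                       alternative = "greater")$p.value, 1e-6)
  m2 <- suppressWarnings(
    tune_and_train(fixture_corpus(), booster_config(min_child_weight = 5),
                   seed = 7, cv = FALSE))
  expect_identical(m$training_report, m2$training_report)
})

test_that("label-permuted training collapses to chance accuracy", {
  corpus <- fixture_corpus()
  corpus$label <- withr::with_seed(13, sample(corpus$label))
  m <- suppressWarnings(
    tune_and_train(corpus, booster_config(min_child_weight = 5),
                   seed = 7, cv = FALSE))
  # chance is 1/11; allow generous binomial noise above it
  n_test <- m$training_report$n_test
  upper <- 1 / 11 + 5 * sqrt((1 / 11) * (10 / 11) / n_test)
  expect_lt(m$training_report$heldout_accuracy, upper)
})

test_that("prediction is pure, tie-stable, and memorises a tiny corpus", {
  m <- fixture_model()
  p1 <- predict_type(m, "Tell me about your family")
  p2 <- predict_type(m, "Tell me about your family")
  expect_identical(p1, p2)
  expect_equal(p1$qtype, names(p1$scores)[which.max(p1$scores)])
  expect_equal(sum(p1$scores), 1, tolerance = 1e-6)
  # out-of-vocabulary input maps to the model's constant zero-feature output
  # (digits never occur in the synthetic corpus)
  expect_false(any(c("0", "2") %in% m$vocabulary))
  z1 <- predict_type(m, "000 111")
  z2 <- predict_type(m, "222 333")
  expect_equal(z1$scores, z2$scores)

  # overfit oracle: a deep, unregularised configuration memorises 11
  # distinct items, one per class
  items <- data.frame(
    text = c("alpha one", "bravo two", "charlie three", "delta four",
             "echo five", "foxtrot six", "golf seven", "hotel eight",
             "india nine", "juliet ten", "kilo eleven"),
    label = question_types()$label)
  tiny <- items[rep(1:11, each = 5), ]
  deep <- suppressWarnings(tune_and_train(
    tiny, booster_config(max_depth = 6, min_child_weight = 1,
                         learning_rate = 0.3, reg_lambda = 0,
                         reg_alpha = 0),
    featurizer_config(), seed = 1, cv = FALSE, rebalance = FALSE))
  for (i in 1:11) {
    expect_equal(predict_type(deep, items$text[i])$qtype, items$label[i])
  }
})

test_that("a model artifact directory restores an equivalent classifier", {
  m <- fixture_model()
  dir <- withr::local_tempdir()
  save_model(m, dir)
  expect_true(all(file.exists(file.path(
    dir, c("booster.ubj", "vocabulary.txt", "featurizer.yaml",
           "labels.json", "report.json")))))
  m2 <- load_model(dir)
  for (txt in c("Tell me about your family", "Do you play with dad?",
                "What did you say?")) {
    expect_equal(predict_type(m2, txt)$scores, predict_type(m, txt)$scores,
                 tolerance = 1e-6)
  }
})
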
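#' Gradient-boosting hyperparameters
#'
#' Defaults are the production settings of the deployed question classifier:
#' 200 estimators, depth 3, min child weight 100, subsample and column
#' subsample 0.9, L2/L1 regularisation 0.05, learning rate 0.01. All but the
#' learning rate can be re-tuned by 5-fold cross-validation in
#' [tune_and_train()]; those defaults were chosen for a corpus of several
#' thousand questions, and CV typically selects a smaller `min_child_weight`
#' on small synthetic corpora.
#'
#' @param n_estimators Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param min_child_weight Minimum summed instance weight per leaf.
#' @param subsample,colsample_bytree Row / column subsampling rates in (0,1].
#' @param reg_lambda,reg_alpha L2 / L1 regularisation.
#' @param learning_rate Shrinkage per round.
#' @param random_seed Seed passed to the boosting engine.
#' @return An object of class `booster_config`.
#' @export
booster_config <- function(n_estimators = 200L, max_depth = 3L,
                           min_child_weight = 100, subsample = 0.9,
                           colsample_bytree = 0.9, reg_lambda = 0.05,
                           reg_alpha = 0.05, learning_rate = 0.01,
                           random_seed = 1L) {
  stopifnot(n_estimators >= 1L, max_depth >= 1L, min_child_weight > 0,
            subsample > 0, subsample <= 1,
            colsample_bytree > 0, colsample_bytree <= 1,
            learning_rate > 0)
  structure(
    list(n_estimators = as.integer(n_estimators),
         max_depth = as.integer(max_depth),
         min_child_weight = min_child_weight,
         subsample = subsample, colsample_bytree = colsample_bytree,
         reg_lambda = reg_lambda, reg_alpha = reg_alpha,
         learning_rate = learning_rate,
         random_seed = as.integer(random_seed)),
    class = "booster_config"
  )
}

#' Stratified train/test split
#'
#' Allocates each class separately so that per-class test proportions are
#' within one item of `test_fraction` times the class size.
#'
#' @param corpus Data frame with columns `text` and `label`.
#' @param test_fraction Fraction held out (default 0.20).
#' @param seed Integer seed; same seed gives an identical split.
#' @return List with data frames `train` and `test` (disjoint, exhaustive).
#' @export
stratified_split <- function(corpus, test_fraction = 0.2, seed = NULL) {
  stopifnot(is.data.frame(corpus), all(c("text", "label") %in% names(corpus)),
            test_fraction > 0, test_fraction < 1)
  sizes <- table(corpus$label)
  if (any(sizes < 2L))
    stop("stratified split needs >= 2 items per class; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  test_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(corpus)), corpus$label), function(ix) {
      n_test <- round(test_fraction * length(ix))
      if (n_test == 0L) integer(0) else sample(ix, n_test)
    }), use.names = FALSE)
  })
  list(train = corpus[-test_idx, , drop = FALSE],
       test  = corpus[test_idx, , drop = FALSE])
}

# Squared Euclidean distances between rows of (possibly sparse) matrices.
row_sq_dists <- function(a, b = a) {
  ra <- Matrix::rowSums(a^2)
  rb <- Matrix::rowSums(b^2)
  d2 <- outer(ra, rb, "+") - 2 * as.matrix(Matrix::tcrossprod(a, b))
  d2[d2 < 0] <- 0
  d2
}

#' Hybrid SMOTE + Tomek-link class rebalancing
#'
#' Balances an imbalanced multi-class training set in two steps: synthetic
#' minority oversampling (each synthetic point is a convex combination of a
#' minority point and one of its `k_neighbors` nearest same-class
#' neighbours) up to the majority class count, followed by removal of Tomek
#' links (pairs of mutual nearest neighbours with different labels; both
#' members are dropped). A class is never removed entirely.
#'
#' @param features Numeric matrix or `dgCMatrix`, rows = items.
#' @param labels Vector of class labels, one per row.
#' @param k_neighbors Number of same-class neighbours for interpolation.
#' @param seed Integer seed for reproducible resampling.
#' @return List with `features`, `labels`, and `info` (counts before/after).
#' @export
rebalance_smote_tomek <- function(features, labels, k_neighbors = 5L,
                                  seed = NULL) {
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  counts <- table(labels)
  if (length(counts) < 2L)
    stop("need at least two classes to rebalance", call. = FALSE)
  maxn <- max(counts)
  need <- maxn - counts
  small <- names(counts)[counts < maxn & counts < k_neighbors + 1L]
  if (length(small))
    stop("class(es) too small for SMOTE with k_neighbors = ", k_neighbors,
         " (need >= k+1 members): ", paste(small, collapse = ", "),
         "; use a smaller k_neighbors", call. = FALSE)

  synth <- with_seed(seed, {
    out <- list()
    for (cl in names(counts)[need > 0]) {
      idx <- which(labels == cl)
      xc <- features[idx, , drop = FALSE]
      d2 <- row_sq_dists(xc)
      diag(d2) <- Inf
      nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(k_neighbors)]))
      n_new <- need[[cl]]
      base <- sample(length(idx), n_new, replace = TRUE)
      pick <- nn[cbind(base, sample(k_neighbors, n_new, replace = TRUE))]
      gap <- stats::runif(n_new)
      newx <- xc[base, , drop = FALSE] +
        (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE]) * gap
      out[[cl]] <- newx
    }
    out
  })
  if (length(synth)) {
    x_all <- do.call(rbind, c(list(features), unname(synth)))
    y_all <- c(labels, rep(names(synth), vapply(synth, nrow, 0L)))
  } else {
    x_all <- features
    y_all <- labels
  }

  # Tomek links: mutual nearest neighbours across classes, both removed
  d2 <- row_sq_dists(x_all)
  diag(d2) <- Inf
  nn1 <- apply(d2, 1L, which.min)
  is_link <- seq_along(y_all) < nn1 &            # each pair once
    nn1[nn1] == seq_along(y_all) &
    y_all != y_all[nn1]
  drop <- unique(c(which(is_link), nn1[is_link]))
  if (length(drop)) {
    # never empty a class
    keep_counts <- table(y_all[-drop])
    lost <- setdiff(unique(y_all), names(keep_counts)[keep_counts > 0])
    if (length(lost))
      drop <- setdiff(drop, which(y_all %in% lost))
  }
  if (length(drop)) {
    x_all <- x_all[-drop, , drop = FALSE]
    y_all <- y_all[-drop]
  }
  list(features = x_all, labels = y_all,
       info = list(before = as.vector(counts),
                   before_labels = names(counts),
                   after = as.vector(table(y_all)),
                   after_labels = names(table(y_all)),
                   n_synthetic = sum(need), n_tomek_removed = length(drop)))
}

xgb_params <- function(cfg, num_class) {
  list(objective = "multi:softprob", num_class = num_class,
       max_depth = cfg$max_depth, min_child_weight = cfg$min_child_weight,
       subsample = cfg$subsample, colsample_bytree = cfg$colsample_bytree,
       lambda = cfg$reg_lambda, alpha = cfg$reg_alpha,
       eta = cfg$learning_rate, nthread = 1L, seed = cfg$random_seed)
}

fit_booster <- function(x, y_code, cfg, num_class) {
  dtr <- xgboost::xgb.DMatrix(x, label = y_code)
  xgboost::xgb.train(params = xgb_params(cfg, num_class), data = dtr,
                     nrounds = cfg$n_estimators, verbose = 0)
}

predict_scores <- function(booster, x, num_class) {
  p <- stats::predict(booster, xgboost::xgb.DMatrix(x))
  if (!is.matrix(p)) p <- matrix(p, ncol = num_class, byrow = TRUE)
  p
}

# Small fixed CV grid around the production settings; subsample and
# colsample move together to keep the grid at 8 cells.
cv_grid <- function(cfg) {
  g <- expand.grid(min_child_weight = c(100, 10),
                   max_depth = c(3L, 5L),
                   sampling = c(0.9, 0.8))
  g <- g[order(g$min_child_weight != cfg$min_child_weight,
               g$max_depth != cfg$max_depth,
               g$sampling != cfg$subsample), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Train the question-type classifier
#'
#' Full training pipeline: stratified 80/20 split, SMOTE + Tomek rebalancing
#' of the training portion, optional 5-fold cross-validated tuning over a
#' small grid centred on the production hyperparameters (learning rate is
#' never tuned), refit on the whole (rebalanced) training portion, and
#' held-out accuracy on the untouched test portion. Deterministic given
#' `seed`.
#'
#' @param corpus Data frame with `text` and `label` columns; labels must be
#'   taxonomy labels ([question_types()]).
#' @param booster_cfg A [booster_config()].
#' @param featurizer_cfg A [featurizer_config()].
#' @param seed Integer seed controlling split, rebalancing and CV folds.
#' @param cv Run the CV tuning pass (`FALSE` trains directly with
#'   `booster_cfg`).
#' @param test_fraction Held-out fraction.
#' @param rebalance Apply SMOTE + Tomek to the training portion.
#' @param k_neighbors SMOTE neighbourhood size.
#' @return An object of class `interview_model`.
#' @export
tune_and_train <- function(corpus, booster_cfg = booster_config(),
                           featurizer_cfg = featurizer_config(),
                           seed = 1L, cv = TRUE, test_fraction = 0.2,
                           rebalance = TRUE, k_neighbors = 5L) {
  stopifnot(is.data.frame(corpus), all(c("text", "label") %in% names(corpus)))
  tax <- question_types()
  bad <- setdiff(unique(corpus$label), tax$label)
  if (length(bad))
    stop("corpus labels outside the taxonomy: ", paste(bad, collapse = ", "),
         call. = FALSE)
  present <- tax$label[tax$label %in% corpus$label]
  if (length(present) < nrow(tax))
    warning("corpus covers ", length(present), " of ", nrow(tax),
            " taxonomy classes; training with a reduced label space",
            call. = FALSE)
  num_class <- length(present)

  split <- stratified_split(corpus, test_fraction, seed = derive_seed(seed, 1L))
  vt <- vectorize(split$train$text, featurizer_cfg)
  x_train <- vt$matrix
  vocab <- vt$vocabulary
  y_train <- split$train$label

  reb_info <- NULL
  if (rebalance) {
    reb <- rebalance_smote_tomek(x_train, y_train, k_neighbors = k_neighbors,
                                 seed = derive_seed(seed, 2L))
    x_train <- reb$features
    y_train <- reb$labels
    reb_info <- reb$info
  }
  code_of <- stats::setNames(seq_along(present) - 1L, present)
  y_code <- code_of[y_train]

  cv_table <- NULL
  chosen <- booster_cfg
  if (cv) {
    grid <- cv_grid(booster_cfg)
    folds <- with_seed(derive_seed(seed, 3L), {
      sample(rep_len(1:5, length(y_code)))
    })
    acc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      cfg_g <- booster_cfg
      cfg_g$min_child_weight <- grid$min_child_weight[g]
      cfg_g$max_depth <- grid$max_depth[g]
      cfg_g$subsample <- cfg_g$colsample_bytree <- grid$sampling[g]
      hits <- 0L
      for (f in 1:5) {
        tr <- folds != f
        bst <- fit_booster(x_train[tr, , drop = FALSE], y_code[tr],
                           cfg_g, num_class)
        p <- predict_scores(bst, x_train[!tr, , drop = FALSE], num_class)
        hits <- hits + sum(max.col(p, ties.method = "first") - 1L ==
                             y_code[!tr])
      }
      acc[g] <- hits / length(y_code)
    }
    cv_table <- cbind(grid, cv_accuracy = acc)
    best <- which.max(acc)  # first (closest to production defaults) on ties
    chosen$min_child_weight <- grid$min_child_weight[best]
    chosen$max_depth <- grid$max_depth[best]
    chosen$subsample <- chosen$colsample_bytree <- grid$sampling[best]
  }

  booster <- fit_booster(x_train, y_code, chosen, num_class)

  xt <- vectorize(split$test$text, featurizer_cfg, vocabulary = vocab)$matrix
  p <- predict_scores(booster, xt, num_class)
  pred <- present[max.col(p, ties.method = "first")]
  heldout <- mean(pred == split$test$label)

  structure(
    list(booster = booster, vocabulary = vocab, labels = present,
         featurizer_cfg = featurizer_cfg, booster_cfg = chosen,
         training_report = list(
           n_total = nrow(corpus), n_train = nrow(split$train),
           n_test = nrow(split$test),
           class_counts = as.list(table(corpus$label)),
           rebalance = reb_info,
           cv = cv_table,
           chosen_params = unclass(chosen),
           heldout_accuracy = heldout,
           seed = as.integer(seed))),
    class = "interview_model"
  )
}

#' @export
print.interview_model <- function(x, ...) {
  cat("Question-type classifier (gradient-boosted trees)\n")
  cat("  classes:", length(x$labels), " vocabulary:", length(x$vocabulary),
      "N-grams\n")
  cat(sprintf("  trained on %d questions; held-out accuracy %.1f%% (n = %d)\n",
              x$training_report$n_train, 100 * x$training_report$heldout_accuracy,
              x$training_report$n_test))
  invisible(x)
}

#' Predict the type of a single question
#'
#' Featurises the utterance with the model's vocabulary (out-of-vocabulary
#' N-grams are dropped), scores every class, and returns the argmax; ties
#' are broken toward the lowest taxonomy code. This is the bare statistical
#' prediction — [classify_question()] adds the greeting, repetition and
#' suggestive-keyword rules.
#'
#' @param model An `interview_model`.
#' @param text A single utterance.
#' @return List with `qtype` (label) and `scores` (named per-class
#'   probabilities summing to 1).
#' @export
predict_type <- function(model, text) {
  stopifnot(inherits(model, "interview_model"))
  x <- vectorize(text, model$featurizer_cfg,
                 vocabulary = model$vocabulary)$matrix
  p <- predict_scores(model$booster, x, length(model$labels))
  scores <- stats::setNames(as.numeric(p[1L, ]), model$labels)
  list(qtype = model$labels[which.max(scores)], scores = scores)
}

#' Accuracy of a trained model on a labeled corpus
#'
#' @param model An `interview_model`.
#' @param corpus Data frame with `text` and `label`.
#' @return List with `accuracy` and the vector of `predicted` labels.
#' @export
evaluate_model <- function(model, corpus) {
  x <- vectorize(corpus$text, model$featurizer_cfg,
                 vocabulary = model$vocabulary)$matrix
  p <- predict_scores(model$booster, x, length(model$labels))
  pred <- model$labels[max.col(p, ties.method = "first")]
  list(accuracy = mean(pred == corpus$label), predicted = pred)
}

#' Save / load a trained classifier as a model directory
#'
#' The artifact is a directory holding the booster state, the ordered
#' vocabulary (newline-delimited text), the featurizer configuration (YAML),
#' the label map (JSON) and the training report (JSON).
#'
#' @param model An `interview_model`.
#' @param dir Directory path (created if needed).
#' @return `dir` (save) or the restored `interview_model` (load).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$booster, file.path(dir, "booster.ubj"))
  write_vocabulary(model$vocabulary, file.path(dir, "vocabulary.txt"))
  fc <- model$featurizer_cfg
  fc$vocabulary <- NULL
  yaml::write_yaml(unclass(fc), file.path(dir, "featurizer.yaml"))
  jsonlite::write_json(as.list(stats::setNames(seq_along(model$labels) - 1L,
                                               model$labels)),
                       file.path(dir, "labels.json"), auto_unbox = TRUE)
  rep <- model$training_report
  rep$cv <- if (!is.null(rep$cv)) as.list(as.data.frame(rep$cv))
  jsonlite::write_json(rep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  fc <- yaml::read_yaml(file.path(dir, "featurizer.yaml"))
  featurizer_cfg <- featurizer_config(unit = fc$unit, n_min = fc$n_min,
                                      n_max = fc$n_max,
                                      lowercase = fc$lowercase,
                                      min_document_frequency =
                                        fc$min_document_frequency)
  labels_map <- jsonlite::read_json(file.path(dir, "labels.json"))
  labels <- names(sort(unlist(labels_map)))
  structure(
    list(booster = xgboost::xgb.load(file.path(dir, "booster.ubj")),
         vocabulary = read_vocabulary(file.path(dir, "vocabulary.txt")),
         labels = labels, featurizer_cfg = featurizer_cfg,
         booster_cfg = NULL,
         training_report = jsonlite::read_json(file.path(dir, "report.json"))),
    class = "interview_model"
  )
}
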
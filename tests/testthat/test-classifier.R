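test_that("tokenization produces unigrams and bigrams without stopwords", {
  tok <- neurotraj:::tokenize("The patient showed severe tremor at rest.",
                              ngram_max = 2L)[[1]]
  expect_true("tremor" %in% tok)
  expect_false("the" %in% tok)
  expect_true("severe_tremor" %in% tok)
})

test_that("vocabulary and document-term matrix are consistent", {
  toks <- neurotraj:::tokenize(c("tremor tremor falls", "falls reported",
                                 "memory loss"))
  vocab <- neurotraj:::build_vocabulary(toks, min_df = 2L)
  expect_identical(vocab, "falls")
  x <- neurotraj:::dtm(toks, c("tremor", "falls"))
  expect_equal(as.matrix(x),
               matrix(c(2, 0, 0, 1, 1, 0), 3, 2,
                      dimnames = list(NULL, c("tremor", "falls"))))
})

test_that("iterative stratification balances rare labels across folds", {
  set.seed(4)
  n <- 400
  labels <- cbind(common = rbinom(n, 1, 0.4), rare = rbinom(n, 1, 0.04))
  split <- suppressWarnings(make_split(labels, test_fraction = 0.2,
                                       n_folds = 5, seed = 2))
  expect_setequal(c(split$test_idx, split$trainval_idx), seq_len(n))
  expect_length(intersect(split$test_idx, split$trainval_idx), 0)
  # test share of each label close to 20%
  test_share <- colSums(labels[split$test_idx, , drop = FALSE]) /
    colSums(labels)
  expect_true(all(abs(test_share - 0.2) < 0.08))
  # rare positives spread over folds rather than piling into one
  rare_per_fold <- table(split$fold[labels[split$trainval_idx, "rare"] == 1])
  expect_true(max(rare_per_fold) - min(rare_per_fold) <= 2)
})

test_that("micro metrics match a hand-computed oracle", {
  pred <- rbind(c(1, 0), c(1, 1), c(0, 0))
  gold <- rbind(c(1, 0), c(0, 1), c(1, 1))
  rep <- evaluate_predictions(pred, gold)
  # tp = 2, fp = 1, fn = 2
  expect_equal(rep$micro_precision, 2 / 3)
  expect_equal(rep$micro_recall, 2 / 4)
  expect_equal(rep$micro_f1, 2 * (2 / 3) * (1 / 2) / (2 / 3 + 1 / 2))
  empty <- evaluate_predictions(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(empty$micro_f1, 0)
})

test_that("attribute retention applies precision-or-F1 at 0.8", {
  rep <- list(per_attribute = data.frame(
    attribute_id = c("a", "b", "c", "d"),
    precision = c(0.85, 0.5, 0.79, 0.8),
    f1 = c(0.2, 0.81, 0.79, 0.1)))
  expect_identical(retain_attributes(rep), c("a", "b", "d"))
})

test_that("Cohen's kappa matches hand oracles", {
  a <- c(1, 1, 0, 0, 1, 0, 1, 0, 1, 1)
  b <- c(1, 0, 0, 0, 1, 0, 1, 1, 1, 0)
  # po = 0.7, pa1 = 0.6, pb1 = 0.5 -> pe = 0.5, kappa = 0.4
  expect_equal(cohen_kappa(a, b)$pooled, 0.4)
  expect_equal(cohen_kappa(a, a)$pooled, 1)
  expect_true(is.na(cohen_kappa(rep(1, 4), rep(1, 4))$pooled))
})

test_that("both model families learn a small separable corpus", {
  sent <- render_sentences(nt_cohort, seed = 2)
  attrs <- setdiff(names(sent), c("donor_id", "text", "year"))
  labels <- as.matrix(sent[, attrs])
  n <- nrow(sent)
  idx <- seq_len(n) %% 5 == 0
  for (family in c("bow_logreg", "linear_svm")) {
    fit <- fit_sentence_classifier(sent$text[!idx],
                                   labels[!idx, , drop = FALSE],
                                   model_spec(family, C = 1))
    rep <- evaluate_predictions(predict(fit, sent$text[idx]),
                                labels[idx, , drop = FALSE])
    expect_gt(rep$micro_f1, 0.95)
  }
})

test_that("near-constant attributes fall back to a constant predictor", {
  texts <- c("tremor was reported", "the patient showed tremor",
             "memory loss", "falls reported")
  labels <- cbind(tremor = c(1, 1, 0, 0), never = c(0, 0, 0, 0))
  fit <- fit_sentence_classifier(texts, labels, model_spec("bow_logreg"))
  pred <- predict(fit, texts)
  expect_equal(unname(pred[, "never"]), rep(0L, 4))
})

test_that("final-model selection is two-stage with index tie-breaks", {
  trials <- data.frame(trial = 1:6,
                       mean_f1 = c(0.90, 0.92, 0.91, 0.89, 0.93, 0.70),
                       mean_precision = c(0.99, 0.95, 0.95, 0.98, 0.90, 1.0))
  specs <- lapply(1:6, function(i) model_spec("bow_logreg", C = i))
  tuning <- structure(list(trials = trials, specs = specs,
                           family = "bow_logreg"), class = "tuning_result")
  # top-5 by F1 excludes trial 6; best precision among them is trial 1
  spec <- select_final(tuning)
  expect_equal(attr(spec, "trial"), 1)
  expect_equal(spec$C, 1)
  # tie in precision breaks to the lower trial index
  trials$mean_precision <- c(0.95, 0.95, 0.95, 0.95, 0.95, 1.0)
  tuning$trials <- trials
  expect_equal(attr(select_final(tuning), "trial"), 1)
  expect_error(select_final(list(trials = NULL, specs = specs)),
               class = "neurotraj_validation_error")
})

test_that("hyperparameter tuning evaluates trials over the folds", {
  sent <- render_sentences(nt_cohort, seed = 13)
  set.seed(8)
  keep <- sample(seq_len(nrow(sent)), 400)
  sent <- sent[keep, ]
  attrs <- setdiff(names(sent), c("donor_id", "text", "year"))
  labels <- as.matrix(sent[, attrs])
  split <- suppressWarnings(make_split(labels, n_folds = 3, seed = 5))
  search <- list(model_spec("bow_logreg", C = 1),
                 model_spec("bow_logreg", C = 100))
  tuning <- suppressWarnings(tune_classifier("bow_logreg", sent$text, labels,
                                             split, search = search))
  expect_equal(nrow(tuning$trials), 2)
  expect_true(all(tuning$trials$mean_f1 >= 0 & tuning$trials$mean_f1 <= 1))
  spec <- select_final(tuning)
  expect_s3_class(spec, "model_spec")
})
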
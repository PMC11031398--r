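# Multilabel sentence classification of signs/symptoms: bag-of-words logistic
# regression and linear SVM baselines wrapped one-vs-rest, multilabel
# stratified splits, micro-averaged metrics, random-search tuning with the
# two-stage final-model selection rule, the attribute retention rule, and
# Cohen's kappa for interannotator agreement.

STOPWORDS <- c(
  "a", "about", "after", "again", "all", "also", "an", "and", "any", "are",
  "as", "at", "be", "because", "been", "before", "being", "between", "both",
  "but", "by", "can", "could", "did", "do", "does", "during", "each", "for",
  "from", "further", "had", "has", "have", "having", "he", "her", "here",
  "hers", "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "just", "me", "more", "most", "my", "no", "nor", "not", "now", "of", "off",
  "on", "once", "only", "or", "other", "our", "out", "over", "own", "s",
  "same", "she", "should", "so", "some", "such", "t", "than", "that", "the",
  "their", "them", "then", "there", "these", "they", "this", "those",
  "through", "to", "too", "under", "until", "up", "very", "was", "we", "were",
  "what", "when", "where", "which", "while", "who", "whom", "why", "will",
  "with", "would", "you", "your")

tokenize <- function(texts, ngram_max = 1L, stopwords = STOPWORDS) {
  txt <- tolower(texts)
  txt <- gsub("[^a-z]+", " ", txt)
  toks <- strsplit(trimws(txt), "\\s+")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk) & !(tk %in% stopwords)]
    if (ngram_max >= 2L && length(tk) >= 2L) {
      bi <- paste(tk[-length(tk)], tk[-1], sep = "_")
      tk <- c(tk, bi)
    }
    tk
  })
}

build_vocabulary <- function(token_list, min_df = 1L) {
  df_counts <- table(unlist(lapply(token_list, unique)))
  sort(names(df_counts[df_counts >= min_df]))
}

dtm <- function(token_list, vocab) {
  n <- length(token_list)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  idx <- stats::setNames(seq_along(vocab), vocab)
  for (i in seq_len(n)) {
    tk <- token_list[[i]]
    tk <- tk[tk %in% vocab]
    if (!length(tk)) next
    tb <- table(tk)
    ii <- c(ii, rep.int(i, length(tb)))
    jj <- c(jj, unname(idx[names(tb)]))
    xx <- c(xx, as.numeric(tb))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, length(vocab)),
                       dimnames = list(NULL, vocab))
}

# ---------------------------------------------------------------------------
# Multilabel stratified splitting (iterative stratification)

# Assign rows of a binary label matrix to length(proportions) subsets so that
# each label's positives are spread according to the proportions.
iterative_stratified_split <- function(labels, proportions, seed = 1) {
  labels <- as.matrix(labels)
  n <- nrow(labels)
  r <- length(proportions)
  with_seed(seed, {
    assign <- rep(NA_integer_, n)
    subset_desire <- proportions * n
    label_desire <- outer(colSums(labels), proportions) # labels x subsets
    remaining <- rep(TRUE, n)
    repeat {
      lab_counts <- colSums(labels[remaining, , drop = FALSE])
      lab_counts[lab_counts == 0] <- NA
      if (all(is.na(lab_counts))) break
      l <- which.min(lab_counts)
      rows <- which(remaining & labels[, l] == 1)
      rows <- rows[sample.int(length(rows))]
      for (i in rows) {
        cand <- which(label_desire[l, ] == max(label_desire[l, ]))
        if (length(cand) > 1) {
          cand <- cand[subset_desire[cand] == max(subset_desire[cand])]
        }
        j <- if (length(cand) > 1) sample(cand, 1) else cand
        assign[i] <- j
        remaining[i] <- FALSE
        subset_desire[j] <- subset_desire[j] - 1
        pos_labels <- which(labels[i, ] == 1)
        label_desire[pos_labels, j] <- label_desire[pos_labels, j] - 1
      }
    }
    for (i in which(remaining)) {
      cand <- which(subset_desire == max(subset_desire))
      j <- if (length(cand) > 1) sample(cand, 1) else cand
      assign[i] <- j
      subset_desire[j] <- subset_desire[j] - 1
    }
    assign
  })
}

#' Multilabel-stratified train/test split with cross-validation folds
#'
#' Splits sentences into a 20% hold-out test set and an 80%
#' training/validation set, then partitions the latter into `n_folds`
#' cross-validation folds, using iterative multilabel stratification so that
#' each attribute's positive sentences are spread evenly. Attributes with zero
#' positives are dropped from stratification with a warning.
#'
#' @param labels binary sentence x attribute matrix (or data.frame).
#' @param test_fraction hold-out fraction (default 0.20).
#' @param n_folds number of cross-validation folds (default 5).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return a `split_plan`: list with integer vectors `test_idx`, `trainval_idx`
#'   and `fold` (fold id per trainval row, aligned with `trainval_idx`).
#' @export
make_split <- function(labels, test_fraction = 0.2, n_folds = 5, seed = 1) {
  labels <- as.matrix(labels)
  zero <- colSums(labels) == 0
  if (any(zero)) {
    warning(sprintf("%d attribute(s) with zero positives excluded from stratification",
                    sum(zero)), call. = FALSE)
    labels_strat <- labels[, !zero, drop = FALSE]
  } else labels_strat <- labels
  top <- iterative_stratified_split(labels_strat,
                                    c(test_fraction, 1 - test_fraction),
                                    seed = seed)
  test_idx <- which(top == 1)
  trainval_idx <- which(top == 2)
  fold <- iterative_stratified_split(
    labels_strat[trainval_idx, , drop = FALSE],
    rep(1 / n_folds, n_folds), seed = seed + 1L)
  structure(list(test_idx = test_idx, trainval_idx = trainval_idx,
                 fold = fold, n_folds = n_folds,
                 test_fraction = test_fraction),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: %d test / %d train+validation sentences, %d folds\n",
              length(x$test_idx), length(x$trainval_idx), x$n_folds))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Metrics

#' Micro-averaged multilabel classification metrics
#'
#' Pools true/false positives/negatives over all sentence x attribute pairs
#' (micro averaging) and also reports per-attribute precision, recall and F1.
#' Undefined ratios (zero denominator) are reported as 0, the documented
#' convention for degenerate predictions.
#'
#' @param predictions,gold binary matrices of identical shape (attributes in
#'   columns).
#' @return a `metric_report`: list with `micro_precision`, `micro_recall`,
#'   `micro_f1`, pooled `counts`, and `per_attribute` data.frame.
#' @export
evaluate_predictions <- function(predictions, gold) {
  predictions <- as.matrix(predictions)
  gold <- as.matrix(gold)
  if (!all(dim(predictions) == dim(gold))) {
    nt_stop("prediction and gold matrices must have identical shape",
            "neurotraj_validation_error")
  }
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  tp <- colSums(predictions == 1 & gold == 1)
  fp <- colSums(predictions == 1 & gold == 0)
  fn <- colSums(predictions == 0 & gold == 1)
  tn <- colSums(predictions == 0 & gold == 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  TP <- sum(tp); FP <- sum(fp); FN <- sum(fn); TN <- sum(tn)
  mp <- safe_div(TP, TP + FP)
  mr <- safe_div(TP, TP + FN)
  mf <- safe_div(2 * mp * mr, mp + mr)
  per <- data.frame(
    attribute_id = colnames(gold) %||% paste0("attr", seq_along(tp)),
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = prec, recall = rec, f1 = f1, row.names = NULL,
    stringsAsFactors = FALSE)
  structure(list(micro_precision = mp, micro_recall = mr, micro_f1 = mf,
                 counts = c(tp = TP, fp = FP, fn = FN, tn = TN),
                 per_attribute = per),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("micro-precision %.3f | micro-recall %.3f | micro-F1 %.3f (%d attributes)\n",
              x$micro_precision, x$micro_recall, x$micro_f1,
              nrow(x$per_attribute)))
  invisible(x)
}

#' Attribute retention rule
#'
#' An attribute is kept if its per-attribute precision >= `precision_threshold`
#' OR its F1 >= `f1_threshold` (both default 0.8).
#'
#' @param report a `metric_report`.
#' @param precision_threshold,f1_threshold retention thresholds.
#' @return character vector of kept attribute ids.
#' @export
retain_attributes <- function(report, precision_threshold = 0.8,
                              f1_threshold = 0.8) {
  per <- report$per_attribute
  keep <- per$precision >= precision_threshold | per$f1 >= f1_threshold
  per$attribute_id[keep]
}

#' Cohen's kappa for interannotator agreement
#'
#' Chance-corrected agreement per attribute plus a pooled kappa over all
#' sentence x attribute cells. Attributes where both annotators are constant
#' have undefined kappa and are reported as `NA`.
#'
#' @param labels_a,labels_b binary matrices (same sentences scored by the two
#'   annotators) or vectors.
#' @return list with `per_attribute` (named numeric) and `pooled` kappa.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.matrix(labels_a); b <- as.matrix(labels_b)
  if (!all(dim(a) == dim(b))) {
    nt_stop("annotation matrices must have identical shape",
            "neurotraj_validation_error")
  }
  kappa1 <- function(x, y) {
    n <- length(x)
    po <- mean(x == y)
    pe <- mean(x == 1) * mean(y == 1) + mean(x == 0) * mean(y == 0)
    if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
    (po - pe) / (1 - pe)
  }
  per <- vapply(seq_len(ncol(a)), function(j) kappa1(a[, j], b[, j]),
                numeric(1))
  names(per) <- colnames(a) %||% paste0("attr", seq_len(ncol(a)))
  list(per_attribute = per, pooled = kappa1(as.vector(a), as.vector(b)))
}

# ---------------------------------------------------------------------------
# One-vs-rest baseline models

#' Specify a baseline sentence-classifier model
#'
#' @param family `"bow_logreg"` (bag-of-words logistic regression on word
#'   frequency) or `"linear_svm"`.
#' @param C regularization strength (inverse penalty).
#' @param ngram_max 1 for unigrams, 2 to add bigrams.
#' @param min_df minimum document frequency for vocabulary terms.
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("bow_logreg", "linear_svm"), C = 1,
                       ngram_max = 1L, min_df = 1L) {
  family <- match.arg(family)
  structure(list(family = family, C = C, ngram_max = as.integer(ngram_max),
                 min_df = as.integer(min_df)),
            class = "model_spec")
}

#' Fit a one-vs-rest multilabel sentence classifier
#'
#' Sentences are preprocessed through stop-word removal and count
#' vectorization; one binary classifier per attribute is fitted (logistic
#' regression via `glmnet` ridge with penalty `1/C`, or a linear SVM via
#' `e1071::svm` with cost `C`). Attributes constant in the training data get a
#' constant predictor.
#'
#' @param texts training sentences.
#' @param labels binary sentence x attribute matrix.
#' @param spec a [model_spec()].
#' @return a `traj_classifier` with a [predict()][predict.traj_classifier]
#'   method.
#' @export
fit_sentence_classifier <- function(texts, labels, spec = model_spec()) {
  labels <- as.matrix(labels)
  toks <- tokenize(texts, spec$ngram_max)
  vocab <- build_vocabulary(toks, spec$min_df)
  if (!length(vocab)) {
    nt_stop("empty vocabulary after preprocessing", "neurotraj_config_error")
  }
  x <- dtm(toks, vocab)
  n <- nrow(x)
  models <- vector("list", ncol(labels))
  names(models) <- colnames(labels)
  for (j in seq_len(ncol(labels))) {
    y <- labels[, j]
    if (length(unique(y)) < 2 || min(sum(y == 0), sum(y == 1)) < 2) {
      # (near-)constant attribute in training: majority-class predictor
      models[[j]] <- list(type = "constant",
                          value = as.integer(mean(y) > 0.5))
    } else if (spec$family == "bow_logreg") {
      # decreasing ridge path down to the target penalty: warm starts make the
      # small-lambda solution converge reliably
      target <- 1 / (spec$C * n)
      lams <- exp(seq(log(max(1, target * 1e4)), log(target), length.out = 25))
      fit <- suppressWarnings(
        glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lams,
                       standardize = FALSE, maxit = 2e5))
      models[[j]] <- list(type = "glmnet", fit = fit,
                          s = min(fit$lambda))
    } else {
      fit <- e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                        cost = spec$C, scale = FALSE)
      models[[j]] <- list(type = "svm", fit = fit)
    }
  }
  structure(list(spec = spec, vocab = vocab, models = models,
                 attributes = colnames(labels), retained = colnames(labels)),
            class = "traj_classifier")
}

#' Predict attribute labels for sentences
#'
#' @param object a `traj_classifier`.
#' @param texts sentences to classify.
#' @param ... unused.
#' @return binary matrix (sentences x attributes), restricted to the model's
#'   retained attribute set. Sentences with no known vocabulary yield all-zero
#'   rows for logistic models.
#' @export
predict.traj_classifier <- function(object, texts, ...) {
  toks <- tokenize(texts, object$spec$ngram_max)
  x <- dtm(toks, object$vocab)
  keep <- object$retained
  out <- matrix(0L, nrow(x), length(keep), dimnames = list(NULL, keep))
  for (a in keep) {
    m <- object$models[[a]]
    out[, a] <- switch(m$type,
      constant = rep(as.integer(m$value), nrow(x)),
      glmnet = as.integer(
        stats::predict(m$fit, x, type = "response", s = m$s)[, 1] > 0.5),
      svm = as.integer(as.character(stats::predict(m$fit, x)))
    )
  }
  out
}

#' Predict the full corpus with a trained classifier
#'
#' Thin wrapper over [predict.traj_classifier()] that keeps only the
#' attributes retained by [retain_attributes()] (set via `model$retained`).
#'
#' @param model a `traj_classifier`.
#' @param sentences character vector.
#' @return binary matrix of predictions over the retained attributes.
#' @export
predict_corpus <- function(model, sentences) {
  predict(model, sentences)
}

#' @export
print.traj_classifier <- function(x, ...) {
  cat(sprintf("One-vs-rest %s classifier: %d attributes (%d retained), vocabulary %d terms\n",
              x$spec$family, length(x$attributes), length(x$retained),
              length(x$vocab)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Tuning and final-model selection

sample_spec <- function(family) {
  model_spec(family = family,
             C = 10^stats::runif(1, -3, 3),
             ngram_max = sample(c(1L, 2L), 1),
             min_df = sample(c(1L, 2L, 5L), 1))
}

#' Random-search hyperparameter tuning over cross-validation folds
#'
#' Runs `n_trials` random hyperparameter draws; each trial is scored by the
#' mean micro-F1 and mean micro-precision over the cross-validation folds of
#' `split`. Failed trials are skipped with a warning.
#'
#' @param family model family (see [model_spec()]).
#' @param texts,labels the labeled sentences (full set; the split indexes it).
#' @param split a `split_plan` from [make_split()].
#' @param n_trials number of random draws (default 25).
#' @param seed integer seed (identical trial sequence under the same seed).
#' @param search optional list of fixed specs to evaluate instead of random
#'   draws.
#' @return a `tuning_result`: data.frame `trials` (trial, mean_f1,
#'   mean_precision) plus `specs` list.
#' @export
tune_classifier <- function(family, texts, labels, split, n_trials = 25,
                            seed = 1, search = NULL) {
  labels <- as.matrix(labels)
  tv <- split$trainval_idx
  specs <- if (!is.null(search)) search else with_seed(seed, {
    lapply(seq_len(n_trials), function(i) sample_spec(family))
  })
  rows <- list()
  for (t in seq_along(specs)) {
    res <- tryCatch({
      f1s <- numeric(split$n_folds); prs <- numeric(split$n_folds)
      for (k in seq_len(split$n_folds)) {
        tr <- tv[split$fold != k]; va <- tv[split$fold == k]
        fit <- fit_sentence_classifier(texts[tr], labels[tr, , drop = FALSE],
                                       specs[[t]])
        rep <- evaluate_predictions(predict(fit, texts[va]),
                                    labels[va, , drop = FALSE])
        f1s[k] <- rep$micro_f1; prs[k] <- rep$micro_precision
      }
      c(mean(f1s), mean(prs))
    }, error = function(e) {
      warning(sprintf("trial %d failed: %s", t, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      rows[[length(rows) + 1]] <- data.frame(
        trial = t, mean_f1 = res[1], mean_precision = res[2])
    }
  }
  structure(list(trials = do.call(rbind, rows), specs = specs,
                 family = family),
            class = "tuning_result")
}

#' Two-stage final-model selection
#'
#' Among the top five trials by mean micro-F1, selects the trial with the
#' highest mean micro-precision; ties break to the lowest trial index.
#'
#' @param tuning a `tuning_result` (or its `trials` data.frame with a `specs`
#'   attribute supplied via the `specs` argument).
#' @param top_n size of the F1 short-list (default 5).
#' @return the winning `model_spec`, with the trial index in attribute
#'   `"trial"`.
#' @export
select_final <- function(tuning, top_n = 5) {
  trials <- tuning$trials
  if (is.null(trials) || nrow(trials) == 0) {
    nt_stop("no successful tuning trials", "neurotraj_validation_error")
  }
  ord <- order(-trials$mean_f1, trials$trial)
  short <- trials[ord[seq_len(min(top_n, nrow(trials)))], ]
  best <- short[order(-short$mean_precision, short$trial), ][1, ]
  spec <- tuning$specs[[best$trial]]
  attr(spec, "trial") <- best$trial
  spec
}
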
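# Clinical-vs-neuropathological diagnosis concordance (accuracy verdicts,
# confusion matrix, Jaccard) and the trajectory-based diagnosis-prediction
# harness with verdict counting.

# donors may carry multiple neuropathological diagnoses; components are
# semicolon-joined in the nd_codes field ("AD;DLB" for the mixed dementia)
nd_components <- function(nd_code) sort(split_set(nd_code))

#' Clinical-diagnosis accuracy verdict for one donor
#'
#' Precedence rules: a donor is `accurate` when every ND component is matched
#' by a specific clinical diagnosis and no conflicting specific diagnosis for
#' another disorder is present; `ambiguous` when only part of a combined ND is
#' matched, when a matching CD co-occurs with a conflicting specific CD, or
#' when only umbrella classes (e.g. generic dementia) match; `inaccurate`
#' otherwise. With `strict = TRUE` an umbrella CD alongside an exact match
#' also downgrades to ambiguous.
#'
#' @param cd_classes character vector of the donor's clinical-diagnosis
#'   ontology classes.
#' @param nd_code the donor's ND code(s), semicolon-joined for combined NDs.
#' @param dictionary an `accuracy_dictionary`.
#' @param strict exact-match-precedence switch (default FALSE: an exact match
#'   plus an umbrella CD stays accurate).
#' @return list: `verdict` (one of accurate/ambiguous/inaccurate),
#'   `matched` classes, `rationale`.
#' @export
assign_cd_verdict <- function(cd_classes, nd_code, dictionary,
                              strict = FALSE) {
  comps <- nd_components(nd_code)
  missing <- setdiff(comps, names(dictionary$accurate))
  if (length(missing)) {
    nt_stop(paste("ND not covered by accuracy dictionary:", join_set(missing)),
            "neurotraj_config_error")
  }
  own_accurate <- unique(unlist(dictionary$accurate[comps]))
  own_ambiguous <- unique(unlist(dictionary$ambiguous[comps]))
  matched_comp <- vapply(comps, function(nd)
    any(cd_classes %in% dictionary$accurate[[nd]]), logical(1))
  other_nds <- setdiff(names(dictionary$accurate), comps)
  conflict <- any(vapply(other_nds, function(nd)
    any(setdiff(cd_classes, c(own_accurate, own_ambiguous)) %in%
          dictionary$accurate[[nd]]), logical(1)))
  umbrella <- any(cd_classes %in% own_ambiguous)
  matched <- intersect(cd_classes, c(own_accurate, own_ambiguous))
  verdict_of <- function(v, why) list(verdict = v, matched = matched,
                                      rationale = why)
  if (all(matched_comp)) {
    if (conflict) {
      return(verdict_of("ambiguous",
                        "specific match alongside a conflicting specific diagnosis"))
    }
    if (strict && umbrella) {
      return(verdict_of("ambiguous", "exact match but umbrella CD present (strict)"))
    }
    return(verdict_of("accurate", "specific clinical diagnosis matches the ND"))
  }
  if (any(matched_comp)) {
    return(verdict_of("ambiguous", "only part of the combined ND matched"))
  }
  if (umbrella) {
    return(verdict_of("ambiguous", "only an umbrella class matches"))
  }
  verdict_of("inaccurate", "no clinical diagnosis matches the ND")
}

#' Verdict for a model-predicted diagnosis
#'
#' `accurate` on exact (component-set) match, `ambiguous` when the prediction
#' matches part of a combined ND (e.g. AD predicted for an AD-DLB donor),
#' `inaccurate` otherwise.
#'
#' @param predicted_nd single predicted ND code (possibly semicolon-joined).
#' @param true_nd the donor's true ND code(s).
#' @return verdict string.
#' @export
assign_model_verdict <- function(predicted_nd, true_nd) {
  pc <- nd_components(predicted_nd)
  tc <- nd_components(true_nd)
  if (identical(pc, tc)) return("accurate")
  if (length(intersect(pc, tc))) return("ambiguous")
  "inaccurate"
}

#' Jaccard index between two donor sets
#'
#' @param nd_donor_set,cd_donor_set character vectors of donor ids.
#' @return |A intersect B| / |A union B|; 0 when both sets are empty.
#' @export
jaccard <- function(nd_donor_set, cd_donor_set) {
  a <- unique(nd_donor_set); b <- unique(cd_donor_set)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Clinical-vs-neuropathological concordance summary
#'
#' Assigns a verdict per donor, builds the ND x CD confusion matrix of
#' diagnosis observations (hue = CD observations divided by the total ND
#' observations per row), and per covered disorder the Jaccard score between
#' the ND donor set and the CD donor set together with the two directional
#' percentages (ND donors with the same CD; CD donors with the same ND).
#'
#' @param donor_meta data.frame with `donor_id`, `nd_codes`, `cd_classes`
#'   (semicolon-joined).
#' @param dictionary an `accuracy_dictionary`.
#' @param strict see [assign_cd_verdict()].
#' @return a `concordance_summary`: list with `verdicts` (data.frame),
#'   `confusion` (count matrix), `confusion_norm` (row-normalized),
#'   `per_disorder` (data.frame with n_nd, n_cd, jaccard, pct_nd_with_cd,
#'   pct_cd_with_nd) and `counts` (verdict tally).
#' @export
concordance_summary <- function(donor_meta, dictionary, strict = FALSE) {
  verdicts <- do.call(rbind, lapply(seq_len(nrow(donor_meta)), function(i) {
    v <- assign_cd_verdict(split_set(donor_meta$cd_classes[i]),
                           donor_meta$nd_codes[i], dictionary, strict)
    data.frame(donor_id = donor_meta$donor_id[i],
               nd_codes = donor_meta$nd_codes[i],
               verdict = v$verdict,
               matched = join_set(v$matched),
               rationale = v$rationale, stringsAsFactors = FALSE)
  }))
  nd_levels <- sort(unique(donor_meta$nd_codes))
  cd_levels <- sort(unique(unlist(lapply(donor_meta$cd_classes, split_set))))
  confusion <- matrix(0L, length(nd_levels), length(cd_levels),
                      dimnames = list(nd_levels, cd_levels))
  for (i in seq_len(nrow(donor_meta))) {
    for (cd in split_set(donor_meta$cd_classes[i])) {
      confusion[donor_meta$nd_codes[i], cd] <-
        confusion[donor_meta$nd_codes[i], cd] + 1L
    }
  }
  rs <- rowSums(confusion)
  confusion_norm <- sweep(confusion, 1, pmax(rs, 1), "/")
  disorders <- intersect(names(dictionary$accurate),
                         unique(unlist(lapply(donor_meta$nd_codes,
                                              nd_components))))
  per <- do.call(rbind, lapply(disorders, function(x) {
    nd_set <- donor_meta$donor_id[vapply(donor_meta$nd_codes, function(nds)
      x %in% nd_components(nds), logical(1))]
    cd_set <- donor_meta$donor_id[vapply(donor_meta$cd_classes, function(cds)
      any(split_set(cds) %in% dictionary$accurate[[x]]), logical(1))]
    inter <- length(intersect(nd_set, cd_set))
    data.frame(disorder = x, n_nd = length(nd_set), n_cd = length(cd_set),
               jaccard = jaccard(nd_set, cd_set),
               pct_nd_with_cd = if (length(nd_set)) 100 * inter / length(nd_set) else NA,
               pct_cd_with_nd = if (length(cd_set)) 100 * inter / length(cd_set) else NA,
               stringsAsFactors = FALSE)
  }))
  counts <- table(factor(verdicts$verdict,
                         levels = c("accurate", "ambiguous", "inaccurate")))
  structure(list(verdicts = verdicts, confusion = confusion,
                 confusion_norm = confusion_norm, per_disorder = per,
                 counts = counts),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Clinical-diagnosis concordance over %d donors: %d accurate, %d ambiguous, %d inaccurate\n",
              sum(x$counts), x$counts["accurate"], x$counts["ambiguous"],
              x$counts["inaccurate"]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Diagnosis prediction from trajectories

# Per-donor aggregated trajectory features: attribute observation-year counts,
# age at first observation (0 when never observed), sex and death age.
aggregate_features <- function(trajectory, donor_meta, attributes = NULL) {
  D <- count_matrix(trajectory, donor_meta$donor_id, attributes)
  first_age <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  obs <- trajectory[trajectory$present == 1 & !is.na(trajectory$age), ]
  obs <- obs[obs$donor_id %in% donor_meta$donor_id &
               obs$attribute_id %in% colnames(D), ]
  if (nrow(obs)) {
    fa <- stats::aggregate(age ~ donor_id + attribute_id, data = obs,
                           FUN = min)
    first_age[cbind(fa$donor_id, fa$attribute_id)] <- fa$age
  }
  colnames(first_age) <- paste0("first_age_", colnames(first_age))
  cbind(D, first_age,
        sex_female = as.numeric(donor_meta$sex == "F"),
        death_age = donor_meta$death_age)
}

# diagnosis-stratified fold assignment; classes smaller than `min_per_class`
# are pooled into one rare stratum for assignment (with a warning)
stratified_folds <- function(classes, k = 5, seed = 1, min_per_class = 5) {
  tab <- table(classes)
  rare <- names(tab[tab < min_per_class])
  strata <- classes
  if (length(rare)) {
    warning(paste("class(es) folded into a rare stratum for cross-validation:",
                  join_set(rare)), call. = FALSE)
    strata[strata %in% rare] <- ".rare"
  }
  with_seed(seed, {
    fold <- integer(length(classes))
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Trajectory-based diagnosis prediction harness
#'
#' Five diagnosis-stratified folds; in each fold a classifier is trained on
#' the remaining folds and the held-out donors are predicted exactly once.
#' Pooled test predictions receive verdicts against the neuropathological
#' ground truth ([assign_model_verdict()]), and the accurate / ambiguous /
#' inaccurate counts are tallied. The baseline classifier is a multinomial
#' logistic model over aggregated trajectory features (attribute counts,
#' first-observation ages, sex, age at death); `classifier = "grud"` uses the
#' decay-based recurrent network ([grud_fit()]).
#'
#' @param trajectory long observation data.frame (imputed, filtered).
#' @param donor_meta metadata for the modeling cohort (`donor_id`, `nd_codes`,
#'   `sex`, `death_age`).
#' @param classifier `"multinomial"` or `"grud"`.
#' @param n_folds number of folds (default 5).
#' @param seed integer seed (deterministic for the baseline classifier).
#' @param ... passed to the underlying classifier (e.g. `epochs`, `hidden`
#'   for the recurrent model).
#' @return a `prediction_harness`: list with `predictions` (donor_id, true,
#'   predicted, verdict, fold), `counts`, `accuracy`.
#' @export
run_prediction_harness <- function(trajectory, donor_meta,
                                   classifier = c("multinomial", "grud"),
                                   n_folds = 5, seed = 1, ...) {
  classifier <- match.arg(classifier)
  classes <- donor_meta$nd_codes
  fold <- stratified_folds(classes, k = n_folds, seed = seed)
  pred <- character(nrow(donor_meta))
  if (classifier == "multinomial") {
    x <- aggregate_features(trajectory, donor_meta)
    keep <- apply(x, 2, function(v) stats::sd(v) > 0)
    x <- scale(x[, keep, drop = FALSE])
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      df <- data.frame(.class = factor(classes[tr]), x[tr, , drop = FALSE],
                       check.names = FALSE)
      with_seed(seed + k, {
        fit <- nnet::multinom(.class ~ ., data = df, trace = FALSE,
                              maxit = 300, MaxNWts = 100000, decay = 0.1)
      })
      nd <- data.frame(x[!tr, , drop = FALSE], check.names = FALSE)
      pred[!tr] <- as.character(stats::predict(fit, newdata = nd))
    }
  } else {
    seqs <- build_sequences(trajectory, donor_meta)
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      fit <- grud_fit(seqs$sequences[tr], classes[tr],
                      static = seqs$static[tr, , drop = FALSE],
                      seed = seed + k, ...)
      pred[!tr] <- grud_predict(fit, seqs$sequences[!tr],
                                seqs$static[!tr, , drop = FALSE])
    }
  }
  verdict <- mapply(assign_model_verdict, pred, classes)
  counts <- table(factor(verdict,
                         levels = c("accurate", "ambiguous", "inaccurate")))
  structure(list(
    predictions = data.frame(donor_id = donor_meta$donor_id, true = classes,
                             predicted = pred, verdict = unname(verdict),
                             fold = fold, stringsAsFactors = FALSE),
    counts = counts,
    accuracy = unname(counts["accurate"] / sum(counts))),
    class = "prediction_harness")
}

#' @export
print.prediction_harness <- function(x, ...) {
  cat(sprintf("Diagnosis prediction over %d donors: %d accurate, %d ambiguous, %d inaccurate (accuracy %.2f)\n",
              nrow(x$predictions), x$counts["accurate"], x$counts["ambiguous"],
              x$counts["inaccurate"], x$accuracy))
  invisible(x)
}
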
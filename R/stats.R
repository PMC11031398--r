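# Descriptive-statistics machinery: dot statistics, permutation enrichment
# with BH-FDR, the diagnostic-importance chi-square test, pairwise
# observational/temporal Mann-Whitney profiling with sex balancing, and
# Kaplan-Meier survival after first symptom observation.

# donor x attribute matrix of distinct observation-year counts; rows cover
# every donor in `donor_ids` (zero rows for donors without observations)
count_matrix <- function(trajectory, donor_ids, attributes = NULL) {
  obs <- trajectory[trajectory$present == 1, , drop = FALSE]
  obs <- unique(obs[, c("donor_id", "year", "attribute_id")])
  if (is.null(attributes)) attributes <- sort(unique(obs$attribute_id))
  m <- matrix(0L, length(donor_ids), length(attributes),
              dimnames = list(donor_ids, attributes))
  obs <- obs[obs$donor_id %in% donor_ids & obs$attribute_id %in% attributes, ]
  if (nrow(obs)) {
    tb <- table(obs$donor_id, obs$attribute_id)
    m[rownames(tb), colnames(tb)] <- tb
  }
  m
}

#' Dot-plot statistics per attribute and diagnosis group
#'
#' For each attribute x group: the mean per-donor number of observation-years
#' (dot colour, display-capped at 5) and the proportion of the group's donors
#' with at least one observation (dot size).
#'
#' @param trajectory long observation data.frame.
#' @param donor_groups named character vector: donor_id -> group; every donor
#'   of the analysis cohort must appear (donors without observations count in
#'   the denominators).
#' @param attributes optional attribute universe (defaults to those observed).
#' @param color_cap display cap recorded as metadata (default 5).
#' @return data.frame: attribute_id, group, mean_observations,
#'   donor_proportion; attribute `color_cap`.
#' @export
dot_statistics <- function(trajectory, donor_groups, attributes = NULL,
                           color_cap = 5) {
  if (!length(donor_groups)) nt_stop("empty donor_groups",
                                     "neurotraj_validation_error")
  groups <- split(names(donor_groups), unname(donor_groups))
  if (any(vapply(groups, length, integer(1)) == 0)) {
    nt_stop("empty diagnosis group", "neurotraj_validation_error")
  }
  D <- count_matrix(trajectory, names(donor_groups), attributes)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    sub <- D[groups[[g]], , drop = FALSE]
    data.frame(attribute_id = colnames(D), group = g,
               mean_observations = colMeans(sub),
               donor_proportion = colMeans(sub > 0),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "color_cap") <- color_cap
  out
}

# all distinct permutations of a label multiset (used for exhaustive mode)
multiset_permutations <- function(labels) {
  n <- length(labels)
  out <- list()
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      out[[length(out) + 1]] <<- acc
      return(invisible())
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      recurse(remaining[-i], c(acc, v))
    }
  }
  recurse(labels, character(0))
  out
}

n_multiset_permutations <- function(labels) {
  tb <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tb + 1)))
}

#' One-sided permutation enrichment test
#'
#' Tests, per attribute x diagnosis group, whether the observed group
#' statistic (mean per-donor observation count, or donor proportion) exceeds a
#' random background obtained by permuting the diagnosis labels of the donors.
#' The one-sided p uses the upper tail with ties counted as greater-or-equal.
#' Sampled mode applies the add-one correction
#' p = (1 + #\{perm >= obs\}) / (1 + n_perm); exhaustive mode enumerates all
#' distinct label arrangements and reports the exact tail proportion.
#'
#' @param trajectory long observation data.frame.
#' @param donor_groups named character vector donor_id -> group (>= 2 groups).
#' @param n_perm number of label permutations (default 100000).
#' @param seed integer seed for the sampled mode.
#' @param statistic `"mean"` (default, matches the dot colour statistic) or
#'   `"proportion"`.
#' @param exhaustive `"auto"` (exhaustive when all distinct arrangements
#'   number at most `exhaustive_limit`), `"never"`, or `"always"`.
#' @param exhaustive_limit arrangement budget for auto mode (default 5000).
#' @param attributes optional attribute universe.
#' @return data.frame: attribute_id, group, observed, p_perm, plus attribute
#'   `"mode"` (`"exhaustive"` or `"sampled"`).
#' @export
permutation_enrichment <- function(trajectory, donor_groups,
                                   n_perm = 100000, seed = 1,
                                   statistic = c("mean", "proportion"),
                                   exhaustive = c("auto", "never", "always"),
                                   exhaustive_limit = 5000,
                                   attributes = NULL) {
  statistic <- match.arg(statistic)
  exhaustive <- match.arg(exhaustive)
  if (n_perm < 1) nt_stop("n_perm must be >= 1", "neurotraj_config_error")
  labels <- unname(donor_groups)
  if (length(unique(labels)) < 2) {
    nt_stop("need at least two diagnosis groups", "neurotraj_validation_error")
  }
  D <- count_matrix(trajectory, names(donor_groups), attributes)
  if (statistic == "proportion") D <- (D > 0) + 0
  glev <- sort(unique(labels))
  G <- length(glev)
  gsize <- vapply(glev, function(g) sum(labels == g), numeric(1))
  group_stat <- function(lab) {
    # G x A matrix of group means
    ind <- outer(glev, lab, "==") + 0
    (ind %*% D) / gsize
  }
  obs <- group_stat(labels)
  eps <- 1e-12
  n_arr <- n_multiset_permutations(labels)
  use_exhaustive <- exhaustive == "always" ||
    (exhaustive == "auto" && n_arr <= exhaustive_limit)
  if (use_exhaustive) {
    perms <- multiset_permutations(labels)
    ge <- matrix(0, G, ncol(D))
    for (p in perms) ge <- ge + (group_stat(p) >= obs - eps)
    pmat <- ge / length(perms)
    mode <- "exhaustive"
  } else {
    pmat <- with_seed(seed, {
      ge <- matrix(0, G, ncol(D))
      for (b in seq_len(n_perm)) {
        ge <- ge + (group_stat(sample(labels)) >= obs - eps)
      }
      (1 + ge) / (1 + n_perm)
    })
    mode <- "sampled"
  }
  out <- data.frame(
    attribute_id = rep(colnames(D), each = G),
    group = rep(glev, ncol(D)),
    observed = as.vector(obs),
    p_perm = as.vector(pmat),
    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values via [stats::p.adjust()]; inputs are validated to
#' lie in (0, 1].
#'
#' @param p_values numeric vector of p-values.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    nt_stop("p-values must lie in (0, 1]", "neurotraj_validation_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Full enrichment analysis with FDR and diagnostic-importance flags
#'
#' Combines [dot_statistics()], [permutation_enrichment()] and [bh_fdr()] into
#' the long-format enrichment result; significance is `q < q_threshold`
#' (default 0.1).
#'
#' @inheritParams permutation_enrichment
#' @param ontology optional `attribute_ontology` supplying the
#'   diagnostic-importance flag per attribute x group.
#' @param q_threshold FDR significance threshold (default 0.1).
#' @return `enrichment_result` data.frame: attribute_id, group,
#'   mean_observations, donor_proportion, p_perm, q, significant,
#'   diagnostic_importance.
#' @export
enrichment_analysis <- function(trajectory, donor_groups, ontology = NULL,
                                n_perm = 100000, seed = 1,
                                statistic = "mean", q_threshold = 0.1,
                                attributes = NULL, ...) {
  dots <- dot_statistics(trajectory, donor_groups, attributes)
  perm <- permutation_enrichment(trajectory, donor_groups, n_perm = n_perm,
                                 seed = seed, statistic = statistic,
                                 attributes = attributes, ...)
  out <- merge(dots, perm[, c("attribute_id", "group", "p_perm")],
               by = c("attribute_id", "group"))
  out$q <- bh_fdr(out$p_perm)
  out$significant <- out$q < q_threshold
  out$diagnostic_importance <- FALSE
  if (!is.null(ontology)) {
    imp <- lapply(stats::setNames(ontology$attribute_id,
                                  ontology$attribute_id),
                  function(a) diagnostic_importance_set(ontology, a))
    has <- out$attribute_id %in% names(imp)
    out$diagnostic_importance[has] <- mapply(function(a, g) g %in% imp[[a]],
                                             out$attribute_id[has],
                                             out$group[has])
  }
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Chi-square test for diagnostic-importance overrepresentation
#'
#' Pearson chi-square (two-sided, no continuity correction) on the 2x2
#' cross-tabulation of significant enrichment flags against a-priori
#' diagnostic-importance flags over the same attribute x diagnosis grid.
#'
#' @param significant_flags,apriori_flags logical vectors of equal length.
#' @return list with `chisq`, `p_value` and the 2x2 `table`.
#' @export
diagnostic_importance_chi2 <- function(significant_flags, apriori_flags) {
  if (length(significant_flags) != length(apriori_flags)) {
    nt_stop("flag vectors must align on the same grid",
            "neurotraj_validation_error")
  }
  tab <- table(factor(significant_flags, levels = c(TRUE, FALSE)),
               factor(apriori_flags, levels = c(TRUE, FALSE)))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    nt_stop("a margin of the 2x2 table is empty; the chi-square test is undefined (check that both flag vectors vary)",
            "neurotraj_validation_error")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

# ---------------------------------------------------------------------------
# Mann-Whitney U with exact enumeration under ties

#' Two-sided Mann-Whitney U test (exact for small samples, ties allowed)
#'
#' For small samples (all group assignments enumerable within `exact_limit`)
#' the exact two-sided p is the permutation probability that |U - n1 n2 / 2|
#' is at least as large as observed, which handles ties correctly. Larger
#' samples use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @param exact_limit maximum number of enumerated assignments (default
#'   20000).
#' @return list with `U` (statistic for `x`), `p_value` and `method`.
#' @export
mwu_test <- function(x, y, exact_limit = 20000) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  u_stat <- function(xx, yy) {
    r <- rank(c(xx, yy))
    sum(r[seq_along(xx)]) - length(xx) * (length(xx) + 1) / 2
  }
  U <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (choose(n1 + n2, n1) <= exact_limit) {
    pool <- c(x, y)
    combs <- utils::combn(n1 + n2, n1)
    devs <- apply(combs, 2, function(ix)
      abs(u_stat(pool[ix], pool[-ix]) - mu))
    p <- mean(devs >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    r <- rank(c(x, y))
    n <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "degenerate"))
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal"
  }
  list(U = U, p_value = p, method = method)
}

pairwise_mwu <- function(values_by_group, min_size = 2) {
  groups <- names(values_by_group)
  small <- vapply(values_by_group, length, integer(1)) < min_size
  if (any(small)) {
    warning(paste("group(s) skipped (too few donors):",
                  join_set(groups[small])), call. = FALSE)
    values_by_group <- values_by_group[!small]
    groups <- names(values_by_group)
  }
  if (length(groups) < 2) {
    return(data.frame(group1 = character(), group2 = character(),
                      U = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  pairs <- utils::combn(groups, 2)
  res <- apply(pairs, 2, function(gp) {
    t <- mwu_test(values_by_group[[gp[1]]], values_by_group[[gp[2]]])
    c(U = t$U, p = t$p_value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    U = res["U", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  class(out) <- c("pairwise_tests", "data.frame")
  out
}

#' Sex-balanced subsampling
#'
#' Within each diagnosis group, subsamples the majority sex down to the
#' minority count so both sexes are equally represented; groups missing one
#' sex entirely (or with unrecorded sex) are dropped with a warning.
#'
#' @param donor_meta data.frame with `donor_id` and `sex` (`"M"`/`"F"`).
#' @param donor_groups named character vector donor_id -> group.
#' @param seed integer seed.
#' @return character vector of retained donor ids.
#' @export
sex_balance_subsample <- function(donor_meta, donor_groups, seed = 1) {
  sex <- donor_meta$sex[match(names(donor_groups), donor_meta$donor_id)]
  if (anyNA(sex)) {
    bad_groups <- unique(unname(donor_groups)[is.na(sex)])
    warning(paste("group(s) dropped, missing sex:", join_set(bad_groups)),
            call. = FALSE)
    keep <- !unname(donor_groups) %in% bad_groups
    donor_groups <- donor_groups[keep]; sex <- sex[keep]
  }
  with_seed(seed, {
    out <- character(0)
    for (g in unique(unname(donor_groups))) {
      ids <- names(donor_groups)[donor_groups == g]
      sx <- sex[donor_groups == g]
      m <- ids[sx == "M"]; f <- ids[sx == "F"]
      k <- min(length(m), length(f))
      if (k == 0) {
        warning(sprintf("group %s has a single sex; excluded from balanced panel", g),
                call. = FALSE)
        next
      }
      out <- c(out, sample(m, k), sample(f, k))
    }
    out
  })
}

#' Pairwise tests on per-donor observation counts
#'
#' Distribution of the number of observation-years of one attribute per donor
#' within each group, compared by two-sided pairwise Mann-Whitney U tests with
#' BH correction. By default only donors with at least one observation enter
#' the distributions.
#'
#' @param trajectory long observation data.frame.
#' @param donor_groups named character vector donor_id -> group.
#' @param attribute attribute to profile.
#' @param only_observed drop donors without any observation (default TRUE).
#' @return `pairwise_tests` data.frame (group1, group2, U, p, q).
#' @export
observation_count_tests <- function(trajectory, donor_groups, attribute,
                                    only_observed = TRUE) {
  D <- count_matrix(trajectory, names(donor_groups), attribute)
  counts <- D[, 1]
  groups <- split(counts, unname(donor_groups))
  if (only_observed) groups <- lapply(groups, function(v) v[v > 0])
  pairwise_mwu(groups)
}

#' Pairwise tests on observation ages (temporal profiles)
#'
#' Ages at which one attribute was observed, pooled per group, compared by
#' two-sided pairwise Mann-Whitney U tests with BH correction. Also returns
#' per-group age summaries.
#'
#' @inheritParams observation_count_tests
#' @return list with `tests` (`pairwise_tests`) and `ages` (named list of age
#'   vectors per group).
#' @export
temporal_distribution_tests <- function(trajectory, donor_groups, attribute) {
  obs <- trajectory[trajectory$attribute_id == attribute &
                      trajectory$present == 1 & !is.na(trajectory$age), ]
  obs <- obs[obs$donor_id %in% names(donor_groups), ]
  ages <- split(obs$age, unname(donor_groups[obs$donor_id]))
  list(tests = pairwise_mwu(ages), ages = ages)
}

# ---------------------------------------------------------------------------
# Survival after first observation

#' Per-donor age at first observation of an attribute
#'
#' @param trajectory long observation data.frame.
#' @param attribute attribute id.
#' @param include_imputed imputed rows never precede the first real
#'   observation, so the default (TRUE) is equivalent for onset.
#' @return named numeric vector donor_id -> first observation age.
#' @export
first_observation_age <- function(trajectory, attribute,
                                  include_imputed = TRUE) {
  obs <- trajectory[trajectory$attribute_id == attribute &
                      trajectory$present == 1 & !is.na(trajectory$age), ]
  if (!include_imputed) obs <- obs[!obs$imputed, ]
  if (!nrow(obs)) return(stats::setNames(numeric(0), character(0)))
  tapply(obs$age, obs$donor_id, min)
}

#' Kaplan-Meier survival after first observation
#'
#' Product-limit estimate of survival time after the first observation of a
#' sign or symptom (duration = death age - first observation age), via
#' [survival::survfit()].
#'
#' @param durations numeric survival durations (years after first
#'   observation); negative durations are an error.
#' @param event 1 = death observed, 0 = censored (default all events).
#' @param groups optional group labels.
#' @return a `km_curve`: list with the `survfit` object and a tidy `table`
#'   (group, time, n_risk, n_event, surv).
#' @export
km_survival <- function(durations, event = rep(1L, length(durations)),
                        groups = NULL) {
  if (any(durations < 0)) {
    nt_stop("negative survival duration (death before first observation)",
            "neurotraj_validation_error")
  }
  df <- data.frame(time = durations, event = event)
  if (is.null(groups)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = df)
    grp <- rep("all", length(fit$time))
  } else {
    df$group <- groups
    fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
    grp <- if (is.null(fit$strata)) rep(unique(groups), length(fit$time)) else
      rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  tab <- data.frame(group = grp, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d event times, %d group(s)\n",
              nrow(x$table), length(unique(x$table$group))))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, xlab = "years after first observation",
       ylab = "survival probability", ...)
  invisible(x)
}

#' Pairwise survival comparisons after symptom onset
#'
#' Two-sided pairwise Mann-Whitney U tests on post-onset survival durations
#' with BH correction (the primary comparison); a log-rank test over all
#' groups is available as a non-default option.
#'
#' @param durations numeric post-onset durations.
#' @param groups group label per duration.
#' @param method `"mwu"` (default) or `"logrank"`.
#' @param event event indicator for the log-rank option.
#' @return `pairwise_tests` data.frame, or for `"logrank"` a list with
#'   `chisq` and `p_value`.
#' @export
survival_tests <- function(durations, groups, method = c("mwu", "logrank"),
                           event = rep(1L, length(durations))) {
  method <- match.arg(method)
  if (method == "mwu") {
    pairwise_mwu(split(durations, groups))
  } else {
    sd <- survival::survdiff(survival::Surv(durations, event) ~ groups)
    list(chisq = unname(sd$chisq),
         p_value = stats::pchisq(sd$chisq, length(sd$n) - 1,
                                 lower.tail = FALSE))
  }
}
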
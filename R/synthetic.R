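# Synthetic cohort generator. Produces donor metadata, year x attribute
# trajectories, clinical-diagnosis lists with controllable misdiagnosis, APOE
# genotypes and template-rendered labeled sentences with known gold labels,
# so that every downstream stage is testable without restricted donor records.

#' Define a synthetic disease profile
#'
#' @param nd_code neuropathological diagnosis code.
#' @param prevalence cohort fraction with this diagnosis.
#' @param attributes data.frame with columns `attribute_id`, `onset_mean`,
#'   `onset_sd` (onset age distribution, years) and `obs_prob` (per-year
#'   observation probability after onset).
#' @param persistence if `TRUE`, an attribute stays observed every year from
#'   its first observation until death; otherwise years are independent draws.
#' @param death_age_mean,death_age_sd optional disease-specific death-age
#'   distribution (falls back to the cohort-level one).
#' @param confusers CD classes this disease is typically misdiagnosed as.
#' @return a `disease_profile` list.
#' @export
disease_profile <- function(nd_code, prevalence, attributes,
                            persistence = TRUE,
                            death_age_mean = NULL, death_age_sd = NULL,
                            confusers = character()) {
  stopifnot(is.data.frame(attributes) || is.null(attributes))
  if (!is.null(attributes) && nrow(attributes)) {
    stopifnot(all(c("attribute_id", "onset_mean", "onset_sd", "obs_prob")
                  %in% names(attributes)))
    check_prob(attributes$obs_prob, "obs_prob")
  }
  structure(list(nd_code = nd_code, prevalence = prevalence,
                 attributes = attributes, persistence = persistence,
                 death_age_mean = death_age_mean,
                 death_age_sd = death_age_sd, confusers = confusers),
            class = "disease_profile")
}

#' Configure a synthetic cohort
#'
#' @param n_donors number of donors.
#' @param diseases list of [disease_profile()]s; prevalences must sum to 1.
#' @param misdiagnosis_rate probability that a donor's clinical-diagnosis list
#'   is replaced by a confuser diagnosis.
#' @param umbrella_cd_rate probability of appending a generic umbrella CD
#'   (e.g. `dementia`) to a donor's CD list.
#' @param sex_ratio fraction of female donors.
#' @param apoe44_prob named vector: ND code -> probability of the homozygous
#'   APOE4 genotype (default 0.02 for unlisted diagnoses).
#' @param death_age_mean,death_age_sd cohort-level death-age distribution,
#'   truncated to \[40, 100\].
#' @param autopsy_years inclusive range autopsies are drawn from.
#' @param background_rate probability per (donor, off-profile attribute) of a
#'   single stray observation at a random adult age (clinical noise).
#' @param umbrella_map named vector: ND code -> umbrella CD class.
#' @param seed integer seed; the same config and seed reproduce the cohort
#'   exactly.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_donors, diseases,
                          misdiagnosis_rate = 0, umbrella_cd_rate = 0,
                          sex_ratio = 0.5, apoe44_prob = NULL,
                          death_age_mean = 80, death_age_sd = 8,
                          autopsy_years = c(1998, 2020),
                          background_rate = 0,
                          umbrella_map = NULL, seed = 1) {
  prev <- vapply(diseases, function(d) d$prevalence, numeric(1))
  if (abs(sum(prev) - 1) > 1e-8) {
    nt_stop("disease prevalences must sum to 1", "neurotraj_config_error")
  }
  check_prob(misdiagnosis_rate, "misdiagnosis_rate")
  check_prob(umbrella_cd_rate, "umbrella_cd_rate")
  check_prob(sex_ratio, "sex_ratio")
  check_prob(background_rate, "background_rate")
  if (!is.null(apoe44_prob)) check_prob(apoe44_prob, "apoe44_prob")
  structure(list(n_donors = n_donors, diseases = diseases,
                 misdiagnosis_rate = misdiagnosis_rate,
                 umbrella_cd_rate = umbrella_cd_rate,
                 sex_ratio = sex_ratio, apoe44_prob = apoe44_prob,
                 death_age_mean = death_age_mean,
                 death_age_sd = death_age_sd,
                 autopsy_years = autopsy_years,
                 background_rate = background_rate,
                 umbrella_map = umbrella_map, seed = seed),
            class = "cohort_config")
}

# one-draw truncated normal via inverse CDF, so that the number of RNG draws
# never depends on the parameters (keeps common-random-number coupling valid)
rtruncnorm1 <- function(u, mean, sd, lo, hi) {
  p_lo <- stats::pnorm((lo - mean) / sd)
  p_hi <- stats::pnorm((hi - mean) / sd)
  if (p_hi <= p_lo) return(NA_real_)
  mean + sd * stats::qnorm(p_lo + u * (p_hi - p_lo))
}

#' Generate a synthetic cohort
#'
#' Deterministic under the config seed. Each donor receives a diagnosis by
#' prevalence, sex, death age, autopsy year (death year is taken as the
#' autopsy year), APOE genotype, a clinical-diagnosis list (accurate by
#' construction; perturb with [inject_misdiagnoses()] or via
#' `misdiagnosis_rate`) and a year x attribute trajectory: each profile
#' attribute gets a truncated-normal onset age, after which yearly
#' observations are Bernoulli draws (or persist, with the persistence flag).
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort`: list with `donors` (metadata data.frame),
#'   `trajectory` (long data.frame: donor_id, year, age, attribute_id,
#'   present, imputed), `truth` (generator ground truth) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_donors
    prev <- vapply(config$diseases, function(d) d$prevalence, numeric(1))
    codes <- vapply(config$diseases, function(d) d$nd_code, character(1))
    disease_idx <- sample.int(length(codes), n, replace = TRUE, prob = prev)
    sex <- ifelse(stats::runif(n) < config$sex_ratio, "F", "M")
    donors <- vector("list", n)
    traj <- vector("list", n)
    onset_truth <- vector("list", n)
    for (i in seq_len(n)) {
      prof <- config$diseases[[disease_idx[i]]]
      dam <- prof$death_age_mean %||% config$death_age_mean
      das <- prof$death_age_sd %||% config$death_age_sd
      death_age <- round(rtruncnorm1(stats::runif(1), dam, das, 40, 100))
      autopsy_year <- sample(seq(config$autopsy_years[1],
                                 config$autopsy_years[2]), 1)
      death_year <- autopsy_year
      birth_year <- death_year - death_age
      apoe_p <- if (!is.null(config$apoe44_prob) &&
                    prof$nd_code %in% names(config$apoe44_prob)) {
        config$apoe44_prob[[prof$nd_code]]
      } else 0.02
      apoe <- if (stats::runif(1) < apoe_p) "4/4" else {
        if (stats::runif(1) < 0.25) "3/4" else "3/3"
      }
      rows <- list()
      if (!is.null(prof$attributes) && nrow(prof$attributes)) {
        for (a in seq_len(nrow(prof$attributes))) {
          att <- prof$attributes[a, ]
          onset <- rtruncnorm1(stats::runif(1), att$onset_mean, att$onset_sd,
                               5, 100)
          ages <- if (!is.na(onset) && ceiling(onset) <= death_age) {
            seq(ceiling(onset), death_age)
          } else integer(0)
          # draw uniforms for the full span so changing obs_prob only flips
          # thresholds (common-random-number coupling)
          u <- stats::runif(length(ages))
          hit <- u < att$obs_prob
          if (any(hit)) {
            obs_ages <- if (isTRUE(prof$persistence)) {
              seq(ages[which(hit)[1]], death_age)
            } else ages[hit]
            rows[[length(rows) + 1]] <- data.frame(
              attribute_id = att$attribute_id, age = obs_ages,
              stringsAsFactors = FALSE)
            onset_truth[[i]] <- rbind(onset_truth[[i]], data.frame(
              donor_id = i, attribute_id = att$attribute_id,
              onset_age = obs_ages[1], stringsAsFactors = FALSE))
          }
        }
      }
      donors[[i]] <- data.frame(
        donor_id = sprintf("D%04d", i), nd_codes = prof$nd_code,
        cd_classes = prof$nd_code, sex = sex[i], death_age = death_age,
        autopsy_year = autopsy_year, death_year = death_year,
        apoe_genotype = apoe, n_chars = 1000L, stringsAsFactors = FALSE)
      traj[[i]] <- if (length(rows)) {
        r <- do.call(rbind, rows)
        data.frame(donor_id = sprintf("D%04d", i),
                   year = birth_year + r$age, age = r$age,
                   attribute_id = r$attribute_id, present = 1L,
                   imputed = FALSE, stringsAsFactors = FALSE)
      } else NULL
    }
    donors <- do.call(rbind, donors)
    trajectory <- do.call(rbind, traj[!vapply(traj, is.null, logical(1))])
    if (is.null(trajectory)) {
      trajectory <- data.frame(donor_id = character(), year = integer(),
                               age = integer(), attribute_id = character(),
                               present = integer(), imputed = logical(),
                               stringsAsFactors = FALSE)
    }
    # background noise: stray observations on off-profile attributes
    if (config$background_rate > 0) {
      all_attrs <- unique(unlist(lapply(config$diseases, function(d)
        if (is.null(d$attributes)) character() else d$attributes$attribute_id)))
      noise <- list()
      for (i in seq_len(n)) {
        prof <- config$diseases[[disease_idx[i]]]
        own <- if (is.null(prof$attributes)) character() else
          prof$attributes$attribute_id
        for (att in setdiff(all_attrs, own)) {
          if (stats::runif(1) < config$background_rate) {
            age <- sample(seq(30, donors$death_age[i]), 1)
            noise[[length(noise) + 1]] <- data.frame(
              donor_id = donors$donor_id[i],
              year = donors$death_year[i] - donors$death_age[i] + age,
              age = age, attribute_id = att, present = 1L, imputed = FALSE,
              stringsAsFactors = FALSE)
          }
        }
      }
      if (length(noise)) trajectory <- rbind(trajectory, do.call(rbind, noise))
    }
    # umbrella CDs: half of the affected donors receive the umbrella class in
    # addition to their specific diagnosis, the other half only ever received
    # the umbrella diagnosis (no specific clinical diagnosis on record)
    if (config$umbrella_cd_rate > 0 && !is.null(config$umbrella_map)) {
      add <- stats::runif(n) < config$umbrella_cd_rate
      replace_specific <- stats::runif(n) < 0.5
      for (i in which(add)) {
        um <- config$umbrella_map[donors$nd_codes[i]]
        if (!is.na(um)) {
          donors$cd_classes[i] <- if (replace_specific[i]) um else
            join_set(unique(c(split_set(donors$cd_classes[i]), um)))
        }
      }
    }
    truth <- list(disease = stats::setNames(codes[disease_idx],
                                            donors$donor_id),
                  onset = do.call(rbind, onset_truth),
                  cd_original = stats::setNames(donors$cd_classes,
                                                donors$donor_id))
    cohort <- structure(list(donors = donors, trajectory = trajectory,
                             truth = truth, config = config),
                        class = "synthetic_cohort")
    if (config$misdiagnosis_rate > 0) {
      cmap <- lapply(config$diseases, function(d) d$confusers)
      names(cmap) <- codes
      cmap <- cmap[vapply(cmap, length, integer(1)) > 0]
      if (length(cmap)) {
        cohort <- inject_misdiagnoses(cohort, cmap,
                                      rate = config$misdiagnosis_rate,
                                      seed = config$seed + 101L)
      }
    }
    cohort
  })
}

#' Perturb clinical-diagnosis lists with planted misdiagnoses
#'
#' Each donor whose diagnosis is covered by `confusion_map` has, with
#' probability `rate`, its CD list replaced by one of the confuser classes.
#' Original CD lists are retained in `cohort$truth$cd_original`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param confusion_map named list: ND code -> character vector of confuser CD
#'   classes.
#' @param rate misdiagnosis probability in \[0, 1\].
#' @param seed integer seed.
#' @return the cohort with perturbed `donors$cd_classes` and a logical
#'   `truth$misdiagnosed` vector.
#' @export
inject_misdiagnoses <- function(cohort, confusion_map, rate, seed = 1) {
  check_prob(rate, "rate")
  with_seed(seed, {
    donors <- cohort$donors
    mis <- rep(FALSE, nrow(donors))
    for (i in seq_len(nrow(donors))) {
      nd <- donors$nd_codes[i]
      conf <- confusion_map[[nd]]
      if (!is.null(conf) && length(conf) && stats::runif(1) < rate) {
        donors$cd_classes[i] <- sample(conf, 1)
        mis[i] <- TRUE
      }
    }
    cohort$donors <- donors
    cohort$truth$misdiagnosed <- stats::setNames(mis, donors$donor_id)
    cohort
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d donors, %d trajectory observations, %d diagnoses\n",
              nrow(x$donors), nrow(x$trajectory),
              length(unique(x$donors$nd_codes))))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sentence rendering

#' Default template bank
#'
#' Provides at least two surface forms per attribute (built from the attribute
#' name) plus label-free distractor sentences.
#'
#' @param attribute_ids attributes to cover.
#' @return list with `templates` (named list: attribute -> character vector of
#'   surface forms) and `distractors` (character vector).
#' @export
default_template_bank <- function(attribute_ids) {
  templates <- lapply(attribute_ids, function(a) {
    nm <- gsub("_", " ", a)
    c(sprintf("%s was reported", nm),
      sprintf("the patient showed %s", nm),
      sprintf("increasing %s according to the family", nm))
  })
  names(templates) <- attribute_ids
  distractors <- c(
    "Visited his sister regularly.",
    "Moved to a new house with support.",
    "Worked as a teacher before retirement.",
    "Went on holiday to France with the family.",
    "The general practitioner was informed.",
    "No particular events were recorded.",
    "Lived independently at home.",
    "Enjoyed gardening and reading.")
  list(templates = templates, distractors = distractors)
}

#' Render a labeled sentence table from a cohort
#'
#' Every trajectory observation is rendered as one year-anchored sentence
#' whose gold multilabel vector marks the observed attribute; with probability
#' `conjunction_rate` two same-year observations are merged into one two-hot
#' sentence. Distractor sentences carry the all-zero vector.
#'
#' @param cohort a `synthetic_cohort`.
#' @param template_bank see [default_template_bank()].
#' @param distractor_rate expected distractor sentences per observation.
#' @param conjunction_rate probability of merging two same-year observations.
#' @param seed integer seed.
#' @return data.frame: `donor_id`, `text`, `year`, then one 0/1 column per
#'   attribute appearing in the template bank.
#' @export
render_sentences <- function(cohort, template_bank = NULL,
                             distractor_rate = 0.3, conjunction_rate = 0.15,
                             seed = 1) {
  obs <- cohort$trajectory
  attrs <- sort(unique(obs$attribute_id))
  if (is.null(template_bank)) template_bank <- default_template_bank(attrs)
  missing <- setdiff(attrs, names(template_bank$templates))
  if (length(missing)) {
    nt_stop(paste("no template for attribute(s):", join_set(missing)),
            "neurotraj_config_error")
  }
  lab_attrs <- sort(names(template_bank$templates))
  with_seed(seed, {
    texts <- character(0); donor <- character(0); year <- integer(0)
    labels <- list()
    emit <- function(d, y, txt, atts) {
      texts[[length(texts) + 1]] <<- txt
      donor[[length(donor) + 1]] <<- d
      year[[length(year) + 1]] <<- y
      v <- stats::setNames(integer(length(lab_attrs)), lab_attrs)
      v[atts] <- 1L
      labels[[length(labels) + 1]] <<- v
    }
    render_one <- function(a) {
      forms <- template_bank$templates[[a]]
      forms[sample.int(length(forms), 1)]
    }
    year_wrap <- function(y, body) {
      style <- sample.int(3, 1)
      body <- paste0(toupper(substr(body, 1, 1)), substr(body, 2, nchar(body)))
      switch(style,
             sprintf("In %d %s.", y, tolower(body)),
             sprintf("%s in %d.", body, y),
             sprintf("Around %d %s.", y, tolower(body)))
    }
    if (nrow(obs)) {
      split_dy <- split(seq_len(nrow(obs)),
                        paste(obs$donor_id, obs$year, sep = "\r"))
      for (idx in split_dy) {
        i <- 1
        while (i <= length(idx)) {
          r <- obs[idx[i], ]
          if (i + 1 <= length(idx) && stats::runif(1) < conjunction_rate) {
            r2 <- obs[idx[i + 1], ]
            body <- paste(render_one(r$attribute_id), "and",
                          render_one(r2$attribute_id))
            emit(r$donor_id, r$year, year_wrap(r$year, body),
                 c(r$attribute_id, r2$attribute_id))
            i <- i + 2
          } else {
            emit(r$donor_id, r$year, year_wrap(r$year, render_one(r$attribute_id)),
                 r$attribute_id)
            i <- i + 1
          }
        }
      }
      n_distract <- stats::rpois(1, distractor_rate * nrow(obs))
      if (n_distract > 0) {
        for (k in seq_len(n_distract)) {
          i <- sample.int(nrow(cohort$donors), 1)
          d <- cohort$donors[i, ]
          y <- sample(seq(d$death_year - d$death_age + 20, d$death_year), 1)
          txt <- sample(template_bank$distractors, 1)
          if (stats::runif(1) < 0.5) {
            txt <- sprintf("In %d %s", y,
                           paste0(tolower(substr(txt, 1, 1)), substr(txt, 2, nchar(txt))))
          } else {
            y <- NA_integer_
          }
          emit(d$donor_id, y, txt, character(0))
        }
      }
    }
    lab_mat <- if (length(labels)) do.call(rbind, labels) else
      matrix(integer(0), 0, length(lab_attrs),
             dimnames = list(NULL, lab_attrs))
    out <- data.frame(donor_id = donor, text = texts, year = year,
                      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(lab_mat))
  })
}
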
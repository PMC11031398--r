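# Trajectory construction: collapse sentence-level predictions into per-donor
# binary year x attribute matrices, apply persistence imputation, and enforce
# the cohort-selection filters.

# Diagnosis allow-lists (editable): common single diagnoses admitted for
# modeling and clinical-accuracy analysis, plus the AD-DLB mixed dementia;
# the clustering cohort additionally admits psychiatric diagnoses and other
# mixed/rare dementias.
MODELING_SINGLE_ND <- c("CON", "AD", "PD", "PDD", "VD", "FTD", "DLB",
                        "ATAXIA", "MND", "PSP", "MS", "MSA")
MODELING_COMBINED_ND <- list(c("AD", "DLB"))
CLUSTERING_EXTRA_ND <- c("MDD", "BP", "SCZ", "PTSD", "ASD", "OCD",
                         "CBD", "AD-DLB", "AD-CA", "AD-VE", "PD-AD",
                         "DLB-SICC", "DEM-SICC", "DEM-SICC-AGD", "DEM-VE")

#' Collapse sentence-level predictions into per-donor trajectories
#'
#' Groups predictions per donor and converts them into a binary
#' absence/presence structure over (year, attribute): multiple sentences
#' flagging the same attribute in the same year collapse to one observation.
#' Predictions without a resolvable year are kept in a separate unknown-year
#' table and are excluded from temporal profiling, modeling and
#' dimensionality reduction.
#'
#' @param sentence_meta data.frame with `donor_id` and `year` (NA = unknown)
#'   per sentence, row-aligned with `predictions`.
#' @param predictions binary sentence x attribute matrix.
#' @param donor_meta optional data.frame with `donor_id`, `death_year` and
#'   `death_age` used to derive the observation age.
#' @return a `trajectory_set`: list with `observations` (donor_id, year, age,
#'   attribute_id, present, imputed) and `unknown_year` (donor_id,
#'   attribute_id, n_sentences).
#' @export
collapse_predictions <- function(sentence_meta, predictions,
                                 donor_meta = NULL) {
  predictions <- as.matrix(predictions)
  stopifnot(nrow(sentence_meta) == nrow(predictions))
  attrs <- colnames(predictions)
  hits <- which(predictions == 1, arr.ind = TRUE)
  if (nrow(hits)) {
    long <- data.frame(
      donor_id = sentence_meta$donor_id[hits[, 1]],
      year = sentence_meta$year[hits[, 1]],
      attribute_id = attrs[hits[, 2]],
      stringsAsFactors = FALSE)
  } else {
    long <- data.frame(donor_id = character(), year = integer(),
                       attribute_id = character(), stringsAsFactors = FALSE)
  }
  known <- long[!is.na(long$year), , drop = FALSE]
  unknown <- long[is.na(long$year), , drop = FALSE]
  obs <- unique(known[, c("donor_id", "year", "attribute_id")])
  obs <- obs[order(obs$donor_id, obs$year, obs$attribute_id), , drop = FALSE]
  obs$present <- if (nrow(obs)) 1L else integer(0)
  obs$imputed <- logical(nrow(obs))
  obs$age <- NA_integer_
  if (!is.null(donor_meta) && nrow(obs)) {
    i <- match(obs$donor_id, donor_meta$donor_id)
    birth <- donor_meta$death_year[i] - donor_meta$death_age[i]
    obs$age <- obs$year - birth
  }
  obs <- obs[, c("donor_id", "year", "age", "attribute_id", "present",
                 "imputed")]
  rownames(obs) <- NULL
  if (nrow(unknown)) {
    agg <- stats::aggregate(list(n_sentences = unknown$attribute_id),
                            by = unknown[, c("donor_id", "attribute_id")],
                            FUN = length)
  } else {
    agg <- data.frame(donor_id = character(), attribute_id = character(),
                      n_sentences = integer(), stringsAsFactors = FALSE)
  }
  structure(list(observations = obs, unknown_year = agg),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d observations (%d imputed) across %d donors; %d unknown-year entries\n",
              nrow(x$observations), sum(x$observations$imputed),
              length(unique(x$observations$donor_id)), nrow(x$unknown_year)))
  invisible(x)
}

#' Persistence imputation
#'
#' Neurodegeneration-associated attributes observed in donors with a
#' progressive neurodegenerative disease are assumed to remain present from
#' the first observation until death: missing years in that span are filled
#' in and flagged `imputed`. The rule is gated on both ontology flags and is
#' idempotent.
#'
#' @param trajectory long observation data.frame (as in
#'   `trajectory_set$observations`).
#' @param donor_meta data.frame with `donor_id`, `nd_codes` (semicolon-joined)
#'   and `death_year` (and `death_age` for ages). Donors with missing death
#'   year are skipped with a warning.
#' @param attr_ontology an `attribute_ontology`.
#' @param nd_ont an `nd_ontology`.
#' @return the trajectory with imputed rows appended.
#' @export
impute_persistence <- function(trajectory, donor_meta, attr_ontology, nd_ont) {
  if (!nrow(trajectory)) return(trajectory)
  assoc <- attr_ontology$attribute_id[
    attr_ontology$is_neurodegeneration_associated]
  progressive <- nd_ont$nd_code[nd_ont$is_progressive_neurodegenerative]
  is_prog_donor <- vapply(donor_meta$nd_codes, function(nds)
    any(split_set(nds) %in% progressive), logical(1))
  prog_ids <- donor_meta$donor_id[is_prog_donor]
  if (any(is_prog_donor & is.na(donor_meta$death_year))) {
    warning("death year missing for some progressive-disease donors; imputation skipped for them",
            call. = FALSE)
    prog_ids <- setdiff(prog_ids,
                        donor_meta$donor_id[is.na(donor_meta$death_year)])
  }
  target <- trajectory$donor_id %in% prog_ids &
    trajectory$attribute_id %in% assoc & !trajectory$imputed
  if (!any(target)) return(trajectory)
  key <- paste(trajectory$donor_id, trajectory$attribute_id, sep = "\r")
  new_rows <- list()
  for (k in unique(key[target])) {
    rows <- trajectory[key == k, , drop = FALSE]
    donor <- rows$donor_id[1]
    i <- match(donor, donor_meta$donor_id)
    death_year <- donor_meta$death_year[i]
    first <- min(rows$year[!rows$imputed])
    span <- seq(first, death_year)
    fill <- setdiff(span, rows$year)
    if (length(fill)) {
      age <- if (!is.null(donor_meta$death_age)) {
        fill - (death_year - donor_meta$death_age[i])
      } else NA_integer_
      new_rows[[length(new_rows) + 1]] <- data.frame(
        donor_id = donor, year = fill, age = age,
        attribute_id = rows$attribute_id[1], present = 1L, imputed = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(new_rows)) {
    trajectory <- rbind(trajectory, do.call(rbind, new_rows))
    trajectory <- trajectory[order(trajectory$donor_id, trajectory$attribute_id,
                                   trajectory$year), ]
    rownames(trajectory) <- NULL
  }
  trajectory
}

#' Cohort-selection filters
#'
#' Applies, in order: the character-count ingest filter (>500 characters when
#' an `n_chars` column is present), the autopsy-year filter (in or after
#' 1997), the purpose-specific diagnosis allow-list, and the
#' minimum-observation filter (non-control donors need at least
#' `min_observations` trajectory observations; imputed rows are not counted
#' unless `count_imputed`).
#'
#' @param donor_meta donor metadata data.frame (`donor_id`, `nd_codes`,
#'   `autopsy_year`, optionally `n_chars`).
#' @param trajectory long observation data.frame.
#' @param purpose `"trajectories"` (no diagnosis filter), `"modeling"`
#'   (common single diagnoses + AD-DLB) or `"clustering"` (modeling list plus
#'   psychiatric and mixed-dementia codes).
#' @param min_observations minimum trajectory observations (default 5).
#' @param min_autopsy_year default 1997.
#' @param min_chars default 500.
#' @param count_imputed whether imputed rows count toward the observation
#'   minimum (default FALSE, the conservative reading).
#' @param control_codes diagnosis codes exempt from the observation minimum.
#' @return list with `selected` (donor ids) and `exclusions` (data.frame
#'   donor_id, reason).
#' @export
filter_cohort <- function(donor_meta, trajectory,
                          purpose = c("trajectories", "modeling", "clustering"),
                          min_observations = 5, min_autopsy_year = 1997,
                          min_chars = 500, count_imputed = FALSE,
                          control_codes = "CON") {
  purpose <- match.arg(purpose)
  reasons <- character(0); excluded <- character(0)
  drop <- function(ids, why) {
    excluded <<- c(excluded, ids)
    reasons <<- c(reasons, rep(why, length(ids)))
  }
  keep <- donor_meta
  if ("n_chars" %in% names(keep)) {
    bad <- keep$donor_id[keep$n_chars <= min_chars]
    drop(bad, "insufficient_characters")
    keep <- keep[!keep$donor_id %in% bad, ]
  }
  bad <- keep$donor_id[is.na(keep$autopsy_year) |
                         keep$autopsy_year < min_autopsy_year]
  drop(bad, "autopsy_before_1997")
  keep <- keep[!keep$donor_id %in% bad, ]
  if (purpose != "trajectories") {
    allowed <- function(nds) {
      nds <- sort(split_set(nds))
      single_ok <- length(nds) == 1 && nds %in% MODELING_SINGLE_ND
      combined_ok <- any(vapply(MODELING_COMBINED_ND, function(cmb)
        identical(sort(cmb), nds), logical(1)))
      extra_ok <- purpose == "clustering" && length(nds) == 1 &&
        nds %in% CLUSTERING_EXTRA_ND
      single_ok || combined_ok || extra_ok
    }
    ok <- vapply(keep$nd_codes, allowed, logical(1))
    drop(keep$donor_id[!ok], "diagnosis_not_in_panel")
    keep <- keep[ok, ]
  }
  counted <- trajectory
  if (!count_imputed) counted <- counted[!counted$imputed, , drop = FALSE]
  n_obs <- table(counted$donor_id)
  obs_count <- as.integer(n_obs[keep$donor_id])
  obs_count[is.na(obs_count)] <- 0L
  is_control <- vapply(keep$nd_codes, function(nds)
    all(split_set(nds) %in% control_codes), logical(1))
  bad <- keep$donor_id[!is_control & obs_count < min_observations]
  drop(bad, "fewer_than_min_observations")
  keep <- keep[!keep$donor_id %in% bad, ]
  list(selected = keep$donor_id,
       exclusions = data.frame(donor_id = excluded, reason = reasons,
                               stringsAsFactors = FALSE))
}

#' Write a trajectory table to TSV
#'
#' @param trajectory long observation data.frame.
#' @param path output path.
#' @param coarsen_ages if `TRUE`, ages are coarsened to 5-year bin midpoints
#'   (the public-release dialect) and flagged in a `age_coarsened` column.
#' @export
write_trajectory <- function(trajectory, path, coarsen_ages = FALSE) {
  out <- trajectory
  if (coarsen_ages && "age" %in% names(out)) {
    out$age <- pmin(out$age %/% 5 * 5 + 2, 97)
    out$age_coarsened <- TRUE
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
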
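# Default synthetic study conditions: disease prevalences follow the relative
# donor counts of the common neuropathological diagnoses in the brain-bank
# cohort; onset ages, per-year observation rates and survival offsets are
# fixed, clinically plausible defaults (documented in the methods vignette).

attr_profile <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) data.frame(
    attribute_id = r[[1]], onset_mean = as.numeric(r[[2]]),
    onset_sd = as.numeric(r[[3]]), obs_prob = as.numeric(r[[4]]),
    stringsAsFactors = FALSE)))
}

#' Default synthetic disease profiles
#'
#' Fifteen diagnosis profiles (14 disorders plus control) with prevalences
#' proportional to the donor counts of the most common neuropathological
#' diagnoses, attribute onset-age distributions and per-year observation
#' probabilities. Confuser diagnoses mirror clinically frequent
#' misdiagnosis directions (e.g. MSA mistaken for PD).
#'
#' @return list of [disease_profile()]s with prevalences summing to 1.
#' @export
default_disease_profiles <- function() {
  counts <- c(AD = 720, ATAXIA = 20, BP = 49, CON = 445, DLB = 31, FTD = 220,
              MDD = 57, MND = 19, MS = 259, MSA = 61, PD = 134, PDD = 126,
              PSP = 91, SCZ = 24, VD = 64)
  prev <- counts / sum(counts)
  profs <- list(
    disease_profile("CON", prev["CON"], NULL),
    disease_profile("AD", prev["AD"], attr_profile(
      list("memory_impairment", 72, 6, .45), list("dementia", 75, 6, .55),
      list("disorientation", 77, 5, .30), list("apathy", 76, 6, .20),
      list("paranoia", 77, 5, .15), list("facade_behavior", 76, 5, .12),
      list("needs_assistance_adl", 79, 5, .30),
      list("admission_to_nursing_home", 81, 4, .25)),
      death_age_mean = 85, death_age_sd = 6, confusers = c("VD", "DLB")),
    disease_profile("PD", prev["PD"], attr_profile(
      list("tremor", 62, 8, .50), list("bradykinesia", 64, 8, .50),
      list("rigidity", 65, 8, .40), list("gait_disturbance", 68, 8, .35),
      list("impaired_mobility", 71, 7, .30), list("constipation", 66, 8, .20),
      list("impaired_smell", 60, 8, .15),
      list("rem_sleep_behavior_disorder", 60, 8, .12)),
      death_age_mean = 78, death_age_sd = 7, confusers = "MSA"),
    disease_profile("PDD", prev["PDD"], attr_profile(
      list("tremor", 60, 8, .45), list("bradykinesia", 62, 8, .50),
      list("rigidity", 63, 8, .40), list("gait_disturbance", 66, 8, .35),
      list("impaired_mobility", 69, 7, .30), list("dementia", 74, 6, .40),
      list("memory_impairment", 73, 6, .30), list("hallucinations", 73, 6, .20),
      list("bradyphrenia", 72, 6, .20)),
      death_age_mean = 80, death_age_sd = 6, confusers = "PD"),
    disease_profile("FTD", prev["FTD"], attr_profile(
      list("personality_change", 60, 7, .40), list("disinhibition", 61, 7, .35),
      list("compulsive_behavior", 62, 7, .30), list("apathy", 62, 7, .30),
      list("language_impairment", 63, 7, .25), list("aphasia", 64, 7, .20),
      list("dementia", 64, 7, .45), list("memory_impairment", 65, 7, .25)),
      death_age_mean = 70, death_age_sd = 7, confusers = "AD"),
    disease_profile("DLB", prev["DLB"], attr_profile(
      list("dementia", 74, 6, .45), list("hallucinations", 73, 6, .35),
      list("apraxias", 74, 6, .20), list("bradykinesia", 75, 6, .30),
      list("rigidity", 75, 6, .25),
      list("rem_sleep_behavior_disorder", 70, 7, .20),
      list("memory_impairment", 74, 6, .30)),
      death_age_mean = 79, death_age_sd = 6, confusers = c("AD", "PD")),
    disease_profile("VD", prev["VD"], attr_profile(
      list("dementia", 77, 6, .45), list("memory_impairment", 76, 6, .30),
      list("stroke_episode", 74, 7, .30), list("muscle_weakness", 76, 6, .25),
      list("hearing_problem", 75, 6, .15),
      list("urinary_incontinence", 79, 5, .20)),
      death_age_mean = 83, death_age_sd = 6, confusers = "AD"),
    disease_profile("MS", prev["MS"], attr_profile(
      list("impaired_mobility", 45, 10, .40), list("muscle_weakness", 43, 10, .35),
      list("fatigue", 40, 10, .35), list("numbness", 38, 10, .25),
      list("visual_impairment", 36, 9, .25), list("double_vision", 35, 9, .15),
      list("spasticity", 48, 10, .20), list("urinary_incontinence", 50, 10, .20)),
      death_age_mean = 70, death_age_sd = 10),
    disease_profile("MSA", prev["MSA"], attr_profile(
      list("bradykinesia", 58, 6, .40), list("rigidity", 59, 6, .30),
      list("ataxia", 58, 6, .35), list("orthostatic_hypotension", 60, 6, .30),
      list("urinary_incontinence", 59, 6, .30),
      list("muscle_fasciculation", 60, 6, .15),
      list("impaired_mobility", 62, 6, .35)),
      death_age_mean = 66, death_age_sd = 6, confusers = "PD"),
    disease_profile("PSP", prev["PSP"], attr_profile(
      list("postural_instability", 66, 6, .40), list("falls", 66, 6, .40),
      list("bradykinesia", 68, 6, .30), list("visual_impairment", 68, 6, .30),
      list("akinesia", 69, 6, .25), list("dementia", 71, 6, .20),
      list("dysarthria", 69, 6, .20)),
      death_age_mean = 74, death_age_sd = 6, confusers = "PD"),
    disease_profile("MND", prev["MND"], attr_profile(
      list("muscle_weakness", 60, 9, .50), list("muscle_atrophy", 61, 9, .40),
      list("muscle_fasciculation", 60, 9, .35), list("dysarthria", 63, 9, .30),
      list("dysphagia", 64, 9, .30), list("impaired_mobility", 63, 9, .30)),
      death_age_mean = 67, death_age_sd = 9),
    disease_profile("ATAXIA", prev["ATAXIA"], attr_profile(
      list("ataxia", 50, 12, .50), list("dysarthria", 55, 12, .30),
      list("gait_disturbance", 52, 12, .35), list("falls", 58, 12, .25)),
      death_age_mean = 72, death_age_sd = 10),
    disease_profile("MDD", prev["MDD"], attr_profile(
      list("depressed_mood", 45, 12, .40), list("feeling_suicidal", 48, 12, .15),
      list("insomnia", 46, 12, .20), list("anxiety", 46, 12, .20),
      list("loss_of_appetite", 47, 12, .15), list("fatigue", 47, 12, .20)),
      persistence = FALSE, death_age_mean = 75, death_age_sd = 10),
    disease_profile("BP", prev["BP"], attr_profile(
      list("mania", 35, 10, .30), list("depressed_mood", 37, 10, .30),
      list("psychosis", 40, 10, .15), list("restlessness", 38, 10, .20),
      list("feeling_suicidal", 40, 10, .12), list("insomnia", 37, 10, .20)),
      persistence = FALSE, death_age_mean = 73, death_age_sd = 10),
    disease_profile("SCZ", prev["SCZ"], attr_profile(
      list("psychosis", 28, 8, .40), list("delusions", 30, 8, .30),
      list("hallucinations", 30, 8, .30), list("paranoia", 32, 8, .20),
      list("apathy", 35, 8, .20), list("feeling_suicidal", 33, 8, .10)),
      persistence = FALSE, death_age_mean = 70, death_age_sd = 10)
  )
  profs
}

#' Default umbrella-CD map
#' @return named character vector ND code -> umbrella CD class.
#' @export
default_umbrella_map <- function() {
  c(AD = "dementia", VD = "dementia", FTD = "dementia", DLB = "dementia",
    PDD = "dementia", PD = "parkinsonism", MSA = "parkinsonism",
    PSP = "parkinsonism", MDD = "psychiatric disorder",
    BP = "psychiatric disorder", SCZ = "psychiatric disorder")
}

#' Default synthetic cohort configuration
#'
#' The standard study conditions used throughout the package's examples and
#' tests: prevalence-weighted diagnoses, 15% misdiagnosis rate along the
#' typical confusion directions, 20% umbrella-CD rate, APOE4/4 excess in the
#' Alzheimer-type dementias and 1% background observation noise.
#'
#' @param n_donors cohort size.
#' @param seed integer seed.
#' @param ... overrides passed to [cohort_config()].
#' @return a [cohort_config()].
#' @export
default_cohort_config <- function(n_donors = 600, seed = 1, ...) {
  args <- list(
    n_donors = n_donors, diseases = default_disease_profiles(),
    misdiagnosis_rate = 0.15, umbrella_cd_rate = 0.20,
    apoe44_prob = c(AD = 0.15, DLB = 0.10, PDD = 0.05, VD = 0.05, CON = 0.01),
    background_rate = 0.01, umbrella_map = default_umbrella_map(),
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}
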
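# Built-in example ontologies. The sign/symptom catalogue below is a synthetic
# stand-in constructed from standard neurological/psychiatric vocabulary: 90
# attributes across the 5 broad domains and 14 groupings, with plausible (but
# configurable, not authoritative) diagnostic-importance flags. The diagnosis
# table covers the common neuropathological diagnoses with their ICD-10 codes
# plus the mixed/rare dementia and psychiatric codes used by the cohort
# filters.

#' Example sign/symptom ontology (synthetic, 90 attributes)
#'
#' A complete attribute ontology suitable for demonstrations, tests and the
#' synthetic cohort generator: 90 signs/symptoms across the five broad domains
#' (psychiatric, cognitive, motor, sensory/autonomic, general) and 14
#' groupings. Diagnostic-importance sets and neurodegeneration-association
#' flags are illustrative defaults; in real analyses they come from the
#' curated ontology release and should be treated as input.
#'
#' @return an [attribute_ontology()] with 90 rows.
#' @export
example_attribute_ontology <- function() {
  spec <- list(
    # domain, grouping, attributes (name -> c(diagnostic importance codes))
    list("psychiatric", "disturbances in mood and behavior", list(
      depressed_mood = "MDD", mania = "BP", apathy = "FTD", agitation = "",
      aggression = "", irritability = "", emotional_lability = "",
      disinhibition = "FTD", personality_change = "FTD",
      facade_behavior = "AD", feeling_suicidal = "")),
    list("psychiatric", "psychotic symptoms", list(
      psychosis = "SCZ", hallucinations = "DLB", delusions = "",
      paranoia = "AD")),
    list("psychiatric", "anxiety and compulsive behavior", list(
      anxiety = "", restlessness = "", compulsive_behavior = "FTD")),
    list("cognitive", "cognitive and memory impairment", list(
      dementia = "AD;VD;DLB;PDD;FTD", memory_impairment = "AD",
      disorientation = "", confusion = "", impaired_judgement = "",
      impaired_concentration = "", bradyphrenia = "PDD",
      confabulation = "")),
    list("cognitive", "language and praxis", list(
      aphasia = "FTD", apraxias = "DLB", agnosia = "",
      language_impairment = "FTD", dyscalculia = "")),
    list("cognitive", "executive dysfunction", list(
      executive_dysfunction = "FTD")),
    list("motor", "extrapyramidal symptoms", list(
      bradykinesia = "PD;PDD;MSA;PSP", rigidity = "PD;PDD", tremor = "PD",
      dyskinesia = "", dystonia = "MSA", akinesia = "PSP",
      postural_instability = "PSP", chorea = "")),
    list("motor", "pyramidal and muscle signs", list(
      muscle_weakness = "MND;MS", muscle_atrophy = "MND",
      muscle_fasciculation = "MND;MSA", spasticity = "MS", paresis = "",
      myoclonus = "")),
    list("motor", "gait, coordination and bulbar signs", list(
      gait_disturbance = "PD", falls = "PSP", impaired_mobility = "MS",
      ataxia = "ATAXIA;MSA", dysarthria = "ATAXIA", dysphagia = "MND")),
    list("sensory/autonomic", "sensory disturbances", list(
      visual_impairment = "PSP;MS", hearing_problem = "VD",
      impaired_smell = "PD", numbness = "MS", neuropathic_pain = "",
      dizziness = "", vertigo = "", impaired_taste = "",
      double_vision = "MS")),
    list("sensory/autonomic", "autonomic dysfunction", list(
      urinary_incontinence = "MSA;VD", fecal_incontinence = "",
      constipation = "PD", orthostatic_hypotension = "MSA",
      hypersalivation = "", sexual_dysfunction = "MSA")),
    list("sensory/autonomic", "sleep disturbances", list(
      insomnia = "", rem_sleep_behavior_disorder = "DLB;PD",
      excessive_daytime_sleepiness = "")),
    list("general", "general functioning", list(
      fatigue = "MS", needs_assistance_adl = "", bedridden = "",
      admission_to_nursing_home = "", wandering = "", immobility = "",
      impaired_self_care = "", loss_of_initiative = "")),
    list("general", "systemic and other signs", list(
      weight_loss = "", weight_gain = "", loss_of_appetite = "",
      malaise = "", fever = "", headache = "", pain = "",
      epileptic_seizure = "", loss_of_consciousness = "",
      stroke_episode = "VD", infection_susceptibility = "",
      pressure_ulcers = ""))
  )
  rows <- do.call(rbind, lapply(spec, function(s) {
    data.frame(
      attribute_id = names(s[[3]]),
      domain = s[[1]], grouping = s[[2]],
      diagnostic_importance = unlist(s[[3]], use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }))
  # Neurodegeneration-associated: cognitive and motor attributes plus the
  # degeneration-linked autonomic/general ones; acute/systemic signs are not.
  non_assoc <- c("fever", "headache", "malaise", "infection_susceptibility",
                 "pressure_ulcers", "weight_gain", "pain", "vertigo",
                 "dizziness", "insomnia", "anxiety", "restlessness",
                 "agitation", "aggression", "irritability",
                 "emotional_lability", "depressed_mood", "mania",
                 "feeling_suicidal", "psychosis", "delusions",
                 "loss_of_consciousness", "epileptic_seizure",
                 "stroke_episode", "hearing_problem", "numbness",
                 "neuropathic_pain", "double_vision", "impaired_taste",
                 "loss_of_appetite", "social_withdrawal")
  rows$is_neurodegeneration_associated <- !(rows$attribute_id %in% non_assoc)
  rows$name <- gsub("_", " ", rows$attribute_id)
  stopifnot(nrow(rows) == 90)
  attribute_ontology(
    attribute_id = rows$attribute_id, name = rows$name, domain = rows$domain,
    grouping = rows$grouping,
    diagnostic_importance = rows$diagnostic_importance,
    is_neurodegeneration_associated = rows$is_neurodegeneration_associated
  )
}

#' Example neuropathological-diagnosis ontology
#'
#' The common neuropathological diagnoses with ICD-10 codes, plus the
#' psychiatric and mixed/rare dementia codes admitted by the clustering
#' cohort filter.
#'
#' @return an [nd_ontology()].
#' @export
example_nd_ontology <- function() {
  pn <- "progressive neurodegenerative"
  defs <- rbind(
    c("AD",       "Alzheimer's disease",                 pn,             "G30"),
    c("ATAXIA",   "Cerebellar ataxia",                   pn,             "G11"),
    c("BP",       "Bipolar disorder",                    "psychiatric",  "F31"),
    c("CON",      "Control donor",                       "control",      NA),
    c("DLB",      "Dementia with Lewy bodies",           pn,             "G31.8"),
    c("FTD",      "Frontotemporal dementia",             pn,             "G31.0"),
    c("MDD",      "Major depressive disorder",           "psychiatric",  "F32"),
    c("MND",      "Motor neuron disease",                pn,             "G12.2"),
    c("MS",       "Multiple sclerosis",                  "neuroinflammatory", "G35"),
    c("MSA",      "Multiple system atrophy",             pn,             "G23.2 G23.3"),
    c("PD",       "Parkinson's disease",                 pn,             "G20"),
    c("PDD",      "Parkinson's disease with dementia",   pn,             "G20"),
    c("PSP",      "Progressive supranuclear palsy",      pn,             NA),
    c("SCZ",      "Schizophrenia",                       "psychiatric",  "F20"),
    c("VD",       "Vascular dementia",                   "vascular",     "F01"),
    # additional codes used by the clustering allow-list
    c("CBD",      "Corticobasal degeneration",           pn,             NA),
    c("AD-DLB",   "Alzheimer's disease with Lewy bodies", pn,            NA),
    c("AD-CA",    "Alzheimer's disease with congophilic angiopathy", pn, NA),
    c("AD-VE",    "Alzheimer's disease with vascular encephalopathy", pn, NA),
    c("PD-AD",    "Parkinson's disease with Alzheimer pathology", pn,    NA),
    c("DLB-SICC", "Lewy body dementia with cortical involutive changes", pn, NA),
    c("DEM-SICC", "Dementia with senile involutive cortical changes", pn, NA),
    c("DEM-SICC-AGD", "Dementia with involutive changes and argyrophilic grains", pn, NA),
    c("DEM-VE",   "Dementia with vascular encephalopathy", "vascular",   NA),
    c("PTSD",     "Post-traumatic stress disorder",      "psychiatric",  "F43.1"),
    c("ASD",      "Autism spectrum disorder",            "psychiatric",  "F84"),
    c("OCD",      "Obsessive-compulsive disorder",       "psychiatric",  "F42")
  )
  nd_ontology(nd_code = defs[, 1], name = defs[, 2],
              category = defs[, 3], icd10 = defs[, 4])
}

#' Example clinical-diagnosis class hierarchy
#'
#' A small acyclic parent map over disease classes named after the ND codes,
#' with umbrella classes `dementia` (over AD, VD, FTD, DLB, PDD),
#' `parkinsonism` (over PD, PDD, MSA, PSP, DLB) and `motor neuron disease`
#' rooted in `disease`.
#'
#' @return named list: class -> character vector of parents.
#' @export
example_cd_hierarchy <- function() {
  list(
    disease = character(),
    dementia = "disease",
    parkinsonism = "disease",
    `psychiatric disorder` = "disease",
    AD = "dementia",
    VD = "dementia",
    FTD = "dementia",
    DLB = c("dementia", "parkinsonism"),
    PDD = c("dementia", "parkinsonism"),
    PD = "parkinsonism",
    MSA = "parkinsonism",
    PSP = "parkinsonism",
    ATAXIA = "disease",
    MND = "disease",
    MS = "disease",
    MDD = "psychiatric disorder",
    BP = "psychiatric disorder",
    SCZ = "psychiatric disorder",
    CON = "disease"
  )
}

#' Example accuracy dictionary for the 11 common disorders plus control
#'
#' PD and PDD share one accurate set (combined PD/PDD handling), as do the
#' components of the AD-DLB mixed dementia.
#'
#' @return an `accuracy_dictionary`.
#' @export
example_accuracy_dictionary <- function() {
  codes <- c("AD", "PD", "PDD", "VD", "FTD", "DLB", "ATAXIA", "MND",
             "PSP", "MS", "MSA", "CON")
  map <- stats::setNames(codes, codes)
  map["PDD"] <- "PD" # combined PD/PDD: one shared class set
  dict <- build_accuracy_dictionary(codes, example_cd_hierarchy(),
                                    nd_class_map = map)
  # PD donors may legitimately carry a PDD clinical label and vice versa
  dict$accurate$PD <- sort(unique(c(dict$accurate$PD, "PDD")))
  dict$accurate$PDD <- dict$accurate$PD
  dict
}
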
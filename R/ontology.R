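# Ontology data model and I/O: sign/symptom (clinical history) ontology,
# neuropathological-diagnosis ontology, and the clinical-diagnosis accuracy
# dictionary.

ATTR_DOMAINS <- c("psychiatric", "cognitive", "motor", "sensory/autonomic", "general")
ND_CATEGORIES <- c("progressive neurodegenerative", "psychiatric",
                   "neuroinflammatory", "vascular", "control", "other")

#' Construct a sign/symptom ontology table
#'
#' An attribute ontology holds one row per clinical sign or symptom with its
#' broad domain (one of psychiatric, cognitive, motor, sensory/autonomic,
#' general), a finer grouping label, the set of neuropathological diagnoses
#' (ND codes) for which the attribute is of a-priori diagnostic importance,
#' and a flag marking attributes associated with neurodegeneration (these are
#' the attributes eligible for persistence imputation).
#'
#' @param attribute_id unique short keys.
#' @param name human-readable labels (defaults to `attribute_id`).
#' @param domain one of the five broad domains per attribute.
#' @param grouping free-text grouping label per attribute.
#' @param diagnostic_importance semicolon-joined ND codes per attribute
#'   (`""` for none).
#' @param is_neurodegeneration_associated logical per attribute.
#' @param umls_id optional identifier per attribute.
#' @return a `data.frame` of class `attribute_ontology`.
#' @export
attribute_ontology <- function(attribute_id, name = attribute_id, domain,
                               grouping,
                               diagnostic_importance = "",
                               is_neurodegeneration_associated = FALSE,
                               umls_id = NA_character_) {
  df <- data.frame(
    attribute_id = as.character(attribute_id),
    name = as.character(name),
    domain = as.character(domain),
    grouping = as.character(grouping),
    diagnostic_importance = as.character(diagnostic_importance),
    is_neurodegeneration_associated = as.logical(is_neurodegeneration_associated),
    umls_id = as.character(umls_id),
    stringsAsFactors = FALSE
  )
  validate_attribute_ontology(df)
}

validate_attribute_ontology <- function(df) {
  required <- c("attribute_id", "name", "domain", "grouping",
                "diagnostic_importance", "is_neurodegeneration_associated")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    nt_stop(paste("ontology file is missing columns:", join_set(missing)),
            "neurotraj_schema_error")
  }
  if (nrow(df) == 0) {
    nt_stop("ontology file has no attribute rows", "neurotraj_schema_error")
  }
  if (anyDuplicated(df$attribute_id)) {
    nt_stop("duplicate attribute_id in ontology", "neurotraj_validation_error")
  }
  bad <- setdiff(unique(df$domain), ATTR_DOMAINS)
  if (length(bad)) {
    nt_stop(paste("unknown attribute domain(s):", join_set(bad)),
            "neurotraj_validation_error")
  }
  if (!"umls_id" %in% names(df)) df$umls_id <- NA_character_
  df$is_neurodegeneration_associated <-
    as.logical(df$is_neurodegeneration_associated)
  class(df) <- c("attribute_ontology", "data.frame")
  df
}

#' Read a sign/symptom ontology from TSV
#'
#' Expected columns: `attribute_id`, `name`, `domain`, `grouping`,
#' `diagnostic_importance` (semicolon-joined ND codes), and
#' `is_neurodegeneration_associated`; `umls_id` is optional.
#'
#' @param path TSV file path.
#' @return an `attribute_ontology` data frame.
#' @export
load_attribute_ontology <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                      colClasses = "character"),
    error = function(e) nt_stop(paste("cannot read ontology file:",
                                      conditionMessage(e)),
                                "neurotraj_schema_error")
  )
  if (nrow(df) > 0 && "diagnostic_importance" %in% names(df)) {
    df$diagnostic_importance[is.na(df$diagnostic_importance)] <- ""
  }
  validate_attribute_ontology(df)
}

#' Write a sign/symptom ontology to TSV
#' @param ontology an `attribute_ontology`.
#' @param path output path.
#' @export
write_attribute_ontology <- function(ontology, path) {
  utils::write.table(as.data.frame(ontology), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Diagnostic-importance set for one attribute
#' @param ontology an `attribute_ontology`.
#' @param attribute_id one attribute key.
#' @return character vector of ND codes.
#' @export
diagnostic_importance_set <- function(ontology, attribute_id) {
  i <- match(attribute_id, ontology$attribute_id)
  if (is.na(i)) nt_stop("unknown attribute_id", "neurotraj_validation_error")
  split_set(ontology$diagnostic_importance[i])
}

#' Construct a neuropathological-diagnosis ontology table
#'
#' @param nd_code unique short diagnosis codes (e.g. `"AD"`, `"MSA"`).
#' @param name full names.
#' @param category one of `"progressive neurodegenerative"`, `"psychiatric"`,
#'   `"neuroinflammatory"`, `"vascular"`, `"control"`, `"other"`.
#' @param icd10 optional ICD-10 codes.
#' @return a `data.frame` of class `nd_ontology` with a derived logical
#'   `is_progressive_neurodegenerative` column.
#' @export
nd_ontology <- function(nd_code, name = nd_code, category, icd10 = NA_character_) {
  df <- data.frame(
    nd_code = as.character(nd_code),
    name = as.character(name),
    icd10 = as.character(icd10),
    category = as.character(category),
    stringsAsFactors = FALSE
  )
  validate_nd_ontology(df)
}

validate_nd_ontology <- function(df) {
  required <- c("nd_code", "name", "category")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    nt_stop(paste("diagnosis ontology missing columns:", join_set(missing)),
            "neurotraj_schema_error")
  }
  if (nrow(df) == 0) {
    nt_stop("diagnosis ontology has no rows", "neurotraj_schema_error")
  }
  if (anyDuplicated(df$nd_code)) {
    nt_stop("duplicate nd_code", "neurotraj_validation_error")
  }
  bad <- setdiff(unique(df$category), ND_CATEGORIES)
  if (length(bad)) {
    nt_stop(paste("unknown diagnosis category:", join_set(bad)),
            "neurotraj_validation_error")
  }
  if (!"icd10" %in% names(df)) df$icd10 <- NA_character_
  df$is_progressive_neurodegenerative <-
    df$category == "progressive neurodegenerative"
  class(df) <- c("nd_ontology", "data.frame")
  df
}

#' Read a neuropathological-diagnosis ontology from TSV
#' @param path TSV with columns `nd_code`, `name`, `category` and optionally
#'   `icd10`.
#' @return an `nd_ontology` data frame.
#' @export
load_nd_ontology <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) nt_stop(paste("cannot read diagnosis ontology:",
                                      conditionMessage(e)),
                                "neurotraj_schema_error")
  )
  validate_nd_ontology(df)
}

#' Write a neuropathological-diagnosis ontology to TSV
#' @param ontology an `nd_ontology`.
#' @param path output path.
#' @export
write_nd_ontology <- function(ontology, path) {
  df <- as.data.frame(ontology)
  df$is_progressive_neurodegenerative <- NULL # derived
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Accuracy dictionary: which clinical-diagnosis ontology classes count as
# accurate / ambiguous for each neuropathological diagnosis.

#' Build the clinical-diagnosis accuracy dictionary
#'
#' For each covered ND code the accurate set contains the disease class the ND
#' maps to plus all of that class's descendants in the clinical-diagnosis
#' hierarchy; proper ancestors (umbrella terms such as generic "dementia")
#' form the ambiguous set. Several ND codes may map to the same class (e.g.
#' PD and PDD both to the Parkinson's disease class), in which case they share
#' one accurate set.
#'
#' @param nd_codes ND codes to cover.
#' @param cd_class_map named list: clinical-diagnosis class -> character
#'   vector of parent classes (acyclic hierarchy). Classes without parents
#'   must still appear (with `character()`).
#' @param nd_class_map named character vector mapping ND code -> its clinical
#'   disease class; defaults to the identity (class named like the code).
#' @return an object of class `accuracy_dictionary`: a list with named lists
#'   `accurate` and `ambiguous`.
#' @export
build_accuracy_dictionary <- function(nd_codes, cd_class_map,
                                      nd_class_map = NULL) {
  classes <- names(cd_class_map)
  if (is.null(classes)) {
    nt_stop("cd_class_map must be a named list", "neurotraj_config_error")
  }
  # cycle check via repeated ancestor expansion
  ancestors_of <- function(cl) {
    seen <- character()
    frontier <- cd_class_map[[cl]] %||% character()
    while (length(frontier)) {
      nxt <- setdiff(frontier, seen)
      if (cl %in% nxt) {
        nt_stop("cd_class_map hierarchy contains a cycle",
                "neurotraj_config_error")
      }
      seen <- c(seen, nxt)
      frontier <- unique(unlist(lapply(nxt, function(p)
        cd_class_map[[p]] %||% character())))
    }
    unique(seen)
  }
  descendants_of <- function(cl) {
    classes[vapply(classes, function(other)
      cl %in% ancestors_of(other), logical(1))]
  }
  if (is.null(nd_class_map)) {
    nd_class_map <- stats::setNames(nd_codes, nd_codes)
  }
  accurate <- list()
  ambiguous <- list()
  for (nd in nd_codes) {
    cls <- unname(nd_class_map[nd])
    if (is.na(cls) || !cls %in% classes) {
      nt_stop(sprintf("ND '%s' has no mapped clinical-diagnosis class", nd),
              "neurotraj_config_error")
    }
    acc <- unique(c(cls, descendants_of(cls)))
    amb <- setdiff(ancestors_of(cls), acc)
    accurate[[nd]] <- sort(acc)
    ambiguous[[nd]] <- sort(amb)
  }
  structure(list(accurate = accurate, ambiguous = ambiguous),
            class = "accuracy_dictionary")
}

#' Write an accuracy dictionary to JSON
#' @param dictionary an `accuracy_dictionary`.
#' @param path output path.
#' @export
write_accuracy_dictionary <- function(dictionary, path) {
  jsonlite::write_json(unclass(dictionary), path, auto_unbox = FALSE)
  invisible(path)
}

#' Read an accuracy dictionary from JSON
#' @param path JSON path written by [write_accuracy_dictionary()].
#' @return an `accuracy_dictionary`.
#' @export
load_accuracy_dictionary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$accurate <- lapply(x$accurate, as.character)
  x$ambiguous <- lapply(x$ambiguous, as.character)
  structure(x, class = "accuracy_dictionary")
}

#' Referential integrity between a trajectory/sentence table and an ontology
#'
#' @param attribute_ids character vector of attribute ids referenced by data.
#' @param ontology an `attribute_ontology`.
#' @return invisibly `TRUE`; errors if any id is not defined in the ontology.
#' @export
check_attribute_refs <- function(attribute_ids, ontology) {
  unknown <- setdiff(unique(attribute_ids), ontology$attribute_id)
  if (length(unknown)) {
    nt_stop(paste("attributes not in ontology:", join_set(unknown)),
            "neurotraj_validation_error")
  }
  invisible(TRUE)
}

#' @export
print.attribute_ontology <- function(x, ...) {
  cat(sprintf("Sign/symptom ontology: %d attributes, %d domains, %d groupings\n",
              nrow(x), length(unique(x$domain)), length(unique(x$grouping))))
  invisible(x)
}

#' @export
print.nd_ontology <- function(x, ...) {
  cat(sprintf("Neuropathological diagnosis ontology: %d diagnoses (%d progressive neurodegenerative)\n",
              nrow(x), sum(x$is_progressive_neurodegenerative)))
  invisible(x)
}

#' @export
print.accuracy_dictionary <- function(x, ...) {
  cat(sprintf("Accuracy dictionary covering %d neuropathological diagnoses\n",
              length(x$accurate)))
  invisible(x)
}
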
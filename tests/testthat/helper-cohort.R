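# Shared fixtures built once per test run: the example ontologies and a small
# default-condition synthetic cohort with imputation applied.

nt_attr_ont <- example_attribute_ontology()
nt_nd_ont <- example_nd_ontology()
nt_dict <- example_accuracy_dictionary()

nt_cohort <- generate_cohort(default_cohort_config(n_donors = 200, seed = 7))
nt_trajectory <- impute_persistence(nt_cohort$trajectory, nt_cohort$donors,
                                    nt_attr_ont, nt_nd_ont)

# hand-made three-donor trajectory used by several statistics tests
nt_tiny_trajectory <- data.frame(
  donor_id = c("d1", "d1", "d2", "d3", "d3", "d3"),
  year = c(2000L, 2001L, 2000L, 2001L, 2002L, 2003L),
  age = c(70L, 71L, 65L, 80L, 81L, 82L),
  attribute_id = c("tremor", "tremor", "tremor", "dementia", "dementia",
                   "tremor"),
  present = 1L, imputed = FALSE, stringsAsFactors = FALSE)

# adjusted Rand index between two partitions (Hubert & Arabie)
nt_ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# directly built synthetic group-count trajectory: each donor observes each
# attribute in `lambda[attribute]` random distinct years
nt_count_trajectory <- function(donor_ids, lambda, seed) {
  rows <- neurotraj:::with_seed(seed, {
    rows <- list()
    for (d in donor_ids) {
      for (a in names(lambda)) {
        k <- stats::rpois(1, lambda[[a]])
        if (k > 0) {
          yrs <- sample(1980:2015, min(k, 36))
          rows[[length(rows) + 1]] <- data.frame(
            donor_id = d, year = yrs, age = yrs - 1930L, attribute_id = a,
            present = 1L, imputed = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
    rows
  })
  if (!length(rows)) {
    return(data.frame(donor_id = character(), year = integer(),
                      age = integer(), attribute_id = character(),
                      present = integer(), imputed = logical()))
  }
  do.call(rbind, rows)
}
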
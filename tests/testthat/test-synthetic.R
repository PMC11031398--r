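test_that("cohort generation is deterministic in the seed", {
  cfg <- default_cohort_config(n_donors = 60, seed = 21)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$donors, b$donors)
  expect_identical(a$trajectory, b$trajectory)
  c_ <- generate_cohort(default_cohort_config(n_donors = 60, seed = 22))
  expect_false(identical(a$trajectory, c_$trajectory))
})

test_that("generated cohorts respect the configuration contract", {
  co <- nt_cohort
  expect_equal(nrow(co$donors), 200)
  expect_true(all(co$donors$death_age >= 40 & co$donors$death_age <= 100))
  expect_true(all(co$donors$autopsy_year >= 1998))
  expect_true(all(co$trajectory$present == 1))
  expect_true(all(co$trajectory$year <= co$donors$death_year[
    match(co$trajectory$donor_id, co$donors$donor_id)]))
  # observations never precede recorded onsets
  first_obs <- tapply(co$trajectory$age[!co$trajectory$imputed],
                      paste(co$trajectory$donor_id,
                            co$trajectory$attribute_id)[!co$trajectory$imputed],
                      min)
  expect_true(all(first_obs >= 0))
})

test_that("config validation rejects bad probabilities and prevalences", {
  profs <- default_disease_profiles()
  profs[[1]]$prevalence <- profs[[1]]$prevalence + 0.5
  expect_error(cohort_config(10, profs), class = "neurotraj_config_error")
  expect_error(default_cohort_config(10, misdiagnosis_rate = 1.5),
               class = "neurotraj_config_error")
})

test_that("misdiagnosis injection only rewrites clinical diagnoses", {
  cfg <- default_cohort_config(n_donors = 150, seed = 31,
                               misdiagnosis_rate = 0, umbrella_cd_rate = 0)
  clean <- generate_cohort(cfg)
  cmap <- list(AD = c("VD", "DLB"), PD = "MSA")
  mis <- inject_misdiagnoses(clean, cmap, rate = 0.5, seed = 5)
  expect_identical(mis$trajectory, clean$trajectory)
  expect_identical(mis$donors$nd_codes, clean$donors$nd_codes)
  changed <- mis$donors$cd_classes != clean$donors$cd_classes
  expect_true(any(changed))
  expect_true(all(mis$donors$nd_codes[changed] %in% names(cmap)))
  expect_identical(unname(which(mis$truth$misdiagnosed)), which(changed))
  # misdiagnosed CDs are drawn from the configured confusers
  for (i in which(changed)) {
    expect_true(all(strsplit(mis$donors$cd_classes[i], ";")[[1]] %in%
                      cmap[[mis$donors$nd_codes[i]]]))
  }
})

test_that("rendered sentences carry correct multilabel gold vectors", {
  sent <- render_sentences(nt_cohort, seed = 9)
  attrs <- setdiff(names(sent), c("donor_id", "text", "year"))
  labels <- as.matrix(sent[, attrs])
  expect_true(all(labels %in% c(0L, 1L)))
  # every trajectory observation appears in at least one sentence label
  obs <- nt_cohort$trajectory
  key_obs <- unique(paste(obs$donor_id, obs$year, obs$attribute_id))
  hit <- which(labels == 1, arr.ind = TRUE)
  key_sent <- unique(paste(sent$donor_id[hit[, 1]], sent$year[hit[, 1]],
                           attrs[hit[, 2]]))
  expect_true(all(key_obs %in% key_sent))
  # conjunction sentences are two-hot
  expect_true(any(rowSums(labels) == 2))
  # distractor sentences are all-zero
  expect_true(any(rowSums(labels) == 0))
  # deterministic given the seed
  expect_identical(sent, render_sentences(nt_cohort, seed = 9))
})

test_that("persistence flag extends generator observations to death", {
  prof <- list(disease_profile(
    "AD", 1, data.frame(attribute_id = "dementia", onset_mean = 70,
                        onset_sd = 2, obs_prob = 0.4),
    persistence = TRUE, death_age_mean = 80, death_age_sd = 2))
  co <- generate_cohort(cohort_config(20, prof, seed = 3))
  for (d in unique(co$trajectory$donor_id)) {
    rows <- co$trajectory[co$trajectory$donor_id == d, ]
    death <- co$donors$death_year[co$donors$donor_id == d]
    expect_equal(sort(rows$year), seq(min(rows$year), death))
  }
})
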
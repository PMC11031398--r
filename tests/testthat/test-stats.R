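test_that("dot statistics report group means and proportions", {
  groups <- c(d1 = "PD", d2 = "PD", d3 = "AD")
  dots <- dot_statistics(nt_tiny_trajectory, groups)
  pd_tremor <- dots[dots$group == "PD" & dots$attribute_id == "tremor", ]
  expect_equal(pd_tremor$mean_observations, (2 + 1) / 2)
  expect_equal(pd_tremor$donor_proportion, 1)
  ad_tremor <- dots[dots$group == "AD" & dots$attribute_id == "tremor", ]
  expect_equal(ad_tremor$mean_observations, 1)
  expect_equal(attr(dots, "color_cap"), 5)
  expect_error(dot_statistics(nt_tiny_trajectory, character(0)),
               class = "neurotraj_validation_error")
})

test_that("exhaustive permutation p-values are exact tail proportions", {
  groups <- c(d1 = "PD", d2 = "PD", d3 = "AD")
  res <- permutation_enrichment(nt_tiny_trajectory, groups,
                                exhaustive = "always")
  expect_equal(attr(res, "mode"), "exhaustive")
  # 3 distinct arrangements of the multiset {PD, PD, AD}; dementia counts are
  # (0, 0, 2), so the observed AD mean (2) is achieved in exactly 1 of 3
  ad_dem <- res[res$group == "AD" & res$attribute_id == "dementia", ]
  expect_equal(ad_dem$p_perm, 1 / 3)
  # tremor counts are (2, 1, 1): the PD mean (1.5) is matched in 2 of 3
  pd_tremor <- res[res$group == "PD" & res$attribute_id == "tremor", ]
  expect_equal(pd_tremor$p_perm, 2 / 3)
  # the AD tremor mean (1) is the minimum count: all arrangements >= it
  ad_tremor <- res[res$group == "AD" & res$attribute_id == "tremor", ]
  expect_equal(ad_tremor$p_perm, 1)
})

test_that("sampled p-values use the add-one correction and never reach 0", {
  groups <- c(d1 = "PD", d2 = "PD", d3 = "AD")
  res <- permutation_enrichment(nt_tiny_trajectory, groups, n_perm = 200,
                                seed = 4, exhaustive = "never")
  expect_equal(attr(res, "mode"), "sampled")
  expect_true(all(res$p_perm >= 1 / 201))
  expect_true(all(res$p_perm <= 1))
  # deterministic under the seed
  res2 <- permutation_enrichment(nt_tiny_trajectory, groups, n_perm = 200,
                                 seed = 4, exhaustive = "never")
  expect_equal(res$p_perm, res2$p_perm)
})

test_that("BH adjustment matches the hand oracle and validates input", {
  expect_equal(bh_fdr(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_error(bh_fdr(c(0.5, 0)), class = "neurotraj_validation_error")
  expect_error(bh_fdr(c(0.5, NA)), class = "neurotraj_validation_error")
})

test_that("diagnostic-importance chi-square matches the hand oracle", {
  sig <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 10, 10, 20))
  apriori <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 10, 10, 20))
  out <- diagnostic_importance_chi2(sig, apriori)
  expect_equal(out$chisq, 20 / 3, tolerance = 1e-12)
  expect_error(diagnostic_importance_chi2(rep(TRUE, 4), rep(TRUE, 4)),
               class = "neurotraj_validation_error")
})

test_that("exact Mann-Whitney matches oracles including ties", {
  sep <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p_value, 0.1)
  expect_equal(sep$method, "exact")
  tied <- mwu_test(c(5, 5, 5), c(0, 0, 0))
  expect_equal(tied$p_value, 0.1)
  same <- mwu_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
})

test_that("large-sample Mann-Whitney approximates the exact tail", {
  set.seed(11)
  x <- rnorm(120); y <- rnorm(130, 0.4)
  approx <- mwu_test(x, y)
  expect_equal(approx$method, "normal")
  ref <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value
  expect_equal(approx$p_value, ref, tolerance = 1e-8)
})

test_that("pairwise tests skip tiny groups and adjust p-values", {
  vals <- list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8), c = 9)
  expect_warning(out <- pairwise_mwu(vals), "too few donors")
  expect_equal(nrow(out), 1)
  expect_equal(out$q, out$p)
})

test_that("Kaplan-Meier estimates match hand oracles", {
  censored <- km_survival(c(1, 2, 3), event = c(1, 0, 1))
  expect_equal(censored$table$surv[censored$table$time == 1], 2 / 3)
  expect_equal(censored$table$surv[censored$table$time == 3], 0)
  uncensored <- km_survival(c(1, 2, 3))
  expect_equal(uncensored$table$surv, c(2 / 3, 1 / 3, 0))
  expect_error(km_survival(c(-1, 2)), class = "neurotraj_validation_error")
})

test_that("survival-after-onset pipeline runs on the synthetic cohort", {
  onset <- first_observation_age(nt_trajectory, "dementia")
  dm <- nt_cohort$donors
  dur <- dm$death_age[match(names(onset), dm$donor_id)] - onset
  groups <- dm$nd_codes[match(names(onset), dm$donor_id)]
  keep <- groups %in% c("AD", "PDD")
  expect_true(all(dur >= 0))
  tests <- survival_tests(dur[keep], groups[keep])
  expect_s3_class(tests, "pairwise_tests")
  expect_true(all(tests$p > 0 & tests$p <= 1))
  lr <- survival_tests(dur[keep], groups[keep], method = "logrank")
  expect_true(lr$p_value > 0 && lr$p_value <= 1)
})

test_that("sex-balanced subsampling equalizes sexes and warns as needed", {
  dm <- data.frame(donor_id = sprintf("d%02d", 1:20),
                   sex = rep(c("M", "F", "M", "M"), 5),
                   stringsAsFactors = FALSE)
  groups <- stats::setNames(rep(c("AD", "PD"), each = 10), dm$donor_id)
  kept <- sex_balance_subsample(dm, groups, seed = 2)
  for (g in c("AD", "PD")) {
    sx <- dm$sex[match(kept[groups[kept] == g], dm$donor_id)]
    expect_equal(sum(sx == "M"), sum(sx == "F"))
  }
  solo <- stats::setNames("AD", "d01") # d01 is male-only as a group
  expect_warning(out <- sex_balance_subsample(dm, solo, seed = 1),
                 "single sex")
  expect_length(out, 0)
})

test_that("temporal and count profiling run against grouped donors", {
  groups <- stats::setNames(nt_cohort$donors$nd_codes,
                            nt_cohort$donors$donor_id)
  keep <- groups %in% c("AD", "PD", "MS")
  groups <- groups[keep]
  tmp <- temporal_distribution_tests(nt_trajectory, groups, "dementia")
  expect_true(is.list(tmp$ages))
  cnt <- suppressWarnings(observation_count_tests(nt_trajectory, groups,
                                                  "dementia"))
  expect_true(all(cnt$q >= cnt$p - 1e-12))
})
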
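test_that("clinical-diagnosis verdicts follow the documented conventions", {
  d <- nt_dict
  expect_equal(assign_cd_verdict("AD", "AD", d)$verdict, "accurate")
  expect_equal(assign_cd_verdict(c("AD", "FTD"), "AD", d)$verdict,
               "ambiguous")
  expect_equal(assign_cd_verdict("dementia", "AD", d)$verdict, "ambiguous")
  expect_equal(assign_cd_verdict("PD", "AD", d)$verdict, "inaccurate")
  # umbrella alongside an exact match stays accurate unless strict
  expect_equal(assign_cd_verdict(c("AD", "dementia"), "AD", d)$verdict,
               "accurate")
  expect_equal(assign_cd_verdict(c("AD", "dementia"), "AD", d,
                                 strict = TRUE)$verdict, "ambiguous")
  # combined ND: partial match is ambiguous, full coverage accurate
  expect_equal(assign_cd_verdict("AD", "AD;DLB", d)$verdict, "ambiguous")
  expect_equal(assign_cd_verdict(c("AD", "DLB"), "AD;DLB", d)$verdict,
               "accurate")
  # PD and PDD share one accurate set
  expect_equal(assign_cd_verdict("PDD", "PD", d)$verdict, "accurate")
  expect_error(assign_cd_verdict("AD", "UNMAPPED", d),
               class = "neurotraj_config_error")
})

test_that("model verdicts distinguish exact, partial and wrong predictions", {
  expect_equal(assign_model_verdict("AD", "AD"), "accurate")
  expect_equal(assign_model_verdict("AD", "AD;DLB"), "ambiguous")
  expect_equal(assign_model_verdict("AD;DLB", "AD;DLB"), "accurate")
  expect_equal(assign_model_verdict("PD", "MSA"), "inaccurate")
})

test_that("Jaccard handles the empty-set convention", {
  expect_equal(jaccard(character(0), character(0)), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard("a", "a"), 1)
})

test_that("concordance summary partitions donors and tabulates confusion", {
  fl <- filter_cohort(nt_cohort$donors, nt_trajectory, "modeling")
  dm <- nt_cohort$donors[nt_cohort$donors$donor_id %in% fl$selected, ]
  cs <- concordance_summary(dm, nt_dict)
  expect_equal(sum(cs$counts), nrow(dm))
  expect_setequal(cs$verdicts$verdict,
                  intersect(c("accurate", "ambiguous", "inaccurate"),
                            cs$verdicts$verdict))
  expect_equal(sum(cs$confusion),
               sum(lengths(strsplit(dm$cd_classes, ";"))))
  expect_true(all(cs$confusion_norm >= 0 & cs$confusion_norm <= 1))
  expect_true(all(cs$per_disorder$jaccard >= 0 &
                    cs$per_disorder$jaccard <= 1))
  # directional percentages are consistent with the Jaccard numerator
  row <- cs$per_disorder[cs$per_disorder$disorder == "AD", ]
  inter <- row$pct_nd_with_cd / 100 * row$n_nd
  expect_equal(row$jaccard, inter / (row$n_nd + row$n_cd - inter))
})

test_that("stratified folds pool rare classes with a warning", {
  classes <- c(rep("AD", 20), rep("PD", 15), "MSA", "MSA", "MSA")
  expect_warning(fold <- neurotraj:::stratified_folds(classes, k = 5,
                                                      seed = 2),
                 "rare stratum")
  expect_length(fold, length(classes))
  expect_setequal(unique(fold), 1:5)
  # the common classes are near-evenly spread
  expect_true(max(table(fold[classes == "AD"])) <= 5)
})

test_that("the prediction harness is deterministic and beats chance", {
  fl <- filter_cohort(nt_cohort$donors, nt_trajectory, "modeling")
  dm <- nt_cohort$donors[nt_cohort$donors$donor_id %in% fl$selected, ]
  trf <- nt_trajectory[nt_trajectory$donor_id %in% dm$donor_id, ]
  h1 <- suppressWarnings(run_prediction_harness(trf, dm, "multinomial",
                                                seed = 3))
  h2 <- suppressWarnings(run_prediction_harness(trf, dm, "multinomial",
                                                seed = 3))
  expect_identical(h1$predictions, h2$predictions)
  expect_equal(sum(h1$counts), nrow(dm))
  # every donor predicted exactly once, in its own held-out fold
  expect_setequal(h1$predictions$donor_id, dm$donor_id)
  chance <- max(table(dm$nd_codes)) / nrow(dm)
  expect_gt(h1$accuracy, chance)
})
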